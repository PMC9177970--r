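# independent brute-force oracle for per-position hexamer scores
oracle_scores <- function(seqs, loop_starts, flanks, core_length, table) {
  lookup <- setNames(table$score, table$hexamer)
  out <- list()
  for (i in seq_along(seqs)) {
    for (abs_start in seq_len(nchar(seqs[i]) - 5)) {
      rel <- abs_start - loop_starts[i] + 1
      if (rel < 1 - flanks || rel > core_length + flanks - 5) next
      hex <- substr(seqs[i], abs_start, abs_start + 5)
      out[[length(out) + 1]] <- data.frame(seq_index = i, position = rel,
                                           score = unname(lookup[hex]))
    }
  }
  do.call(rbind, out)
}

test_that("positional_profile equals a single sequence's own scores", {
  tbl <- complete_hexamer_table()
  s <- "GATGACAAGTTC"
  prof <- positional_profile(s, tbl, flanks = 0, core_length = 12)
  lookup <- setNames(tbl$score, tbl$hexamer)
  expected <- unname(lookup[substring(s, 1:7, 6:12)])
  expect_equal(prof$mean_score, expected)
  expect_equal(prof$position, 1:7)
  expect_true(all(prof$n_seq == 1))
})

test_that("positional_profile matches the brute-force oracle on toys", {
  tbl <- complete_hexamer_table()
  set.seed(5)
  seqs <- vapply(1:4, function(i) {
    paste(sample(c("A", "C", "G", "T"), 48, replace = TRUE), collapse = "")
  }, character(1))
  windows <- tibble::tibble(seq = seqs, loop_start = 7L)
  prof <- positional_profile(windows, tbl, flanks = 6, core_length = 36)
  orc <- oracle_scores(seqs, rep(7, 4), 6, 36, tbl)
  agg <- aggregate(score ~ position, orc, mean)
  expect_equal(prof$position, agg$position)
  expect_equal(prof$mean_score, agg$score, tolerance = 1e-9)
  # permutation invariance in the sequence list
  prof2 <- positional_profile(windows[c(3, 1, 4, 2), ], tbl, flanks = 6,
                              core_length = 36)
  expect_equal(prof, prof2)
})

test_that("a position with no ESS starts reports ess_start_count zero", {
  tbl <- hexamer_table(all_hexamers(), rep(0, 4096), rep("NEUTRAL", 4096))
  prof <- positional_profile("ACGTACGTACGT", tbl, core_length = 12)
  expect_true(all(prof$ess_start_count == 0))
})

test_that("positional_profile errors on hexamers missing from the table", {
  tbl <- hexamer_table("AAAAAA", 1, "ESE")
  expect_error(positional_profile("AAAAAAC", tbl, core_length = 7),
               "absent from score table")
})

test_that("region means pool sequence-position pairs and conserve EFM", {
  tbl <- complete_hexamer_table()
  set.seed(6)
  seqs <- vapply(1:3, function(i) {
    paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
  }, character(1))
  windows <- tibble::tibble(seq = seqs, loop_start = 43L)
  regions <- ef_region_sets(helix_nt = 36)
  rm <- region_mean(windows, tbl, regions, flanks = 41, core_length = 36)
  # disjoint union: pooled EFL + ROEF mean equals the EFM mean (weighted)
  efl <- rm[rm$region == "EFL", ]
  roef <- rm[rm$region == "ROEF", ]
  efm <- rm[rm$region == "EFM", ]
  pooled <- (efl$mean_score * efl$n_positions +
               roef$mean_score * roef$n_positions) /
    (efl$n_positions + roef$n_positions)
  expect_equal(pooled, efm$mean_score, tolerance = 1e-12)
  expect_equal(efl$n_positions + roef$n_positions, efm$n_positions)

  # CR oracle by direct enumeration
  orc <- oracle_scores(seqs, rep(43, 3), 41, 36, tbl)
  cr <- orc$score[orc$position %in% regions$CR]
  expect_equal(rm$mean_score[rm$region == "CR"], mean(cr),
               tolerance = 1e-9)

  # grand mean over all covered positions equals the profile grand mean
  one <- region_mean(windows[1, ], tbl, list(ALL = 1:31), core_length = 36)
  prof1 <- positional_profile(windows[1, ], tbl, core_length = 36)
  expect_equal(one$mean_score,
               mean(prof1$mean_score[prof1$position %in% 1:31]),
               tolerance = 1e-12)

  expect_error(region_mean(windows, tbl, list(EMPTY = integer(0))),
               "empty region")
})

test_that("codon tokens follow the 4-per-hexamer convention", {
  expect_equal(codon_tokens_from_hexamers("AAAAAA"),
               tibble::tibble(codon = "AAA", count = 4L))
  tok <- codon_tokens_from_hexamers(c("GAAGAA", "AGAAGA"))
  expect_equal(tok, tibble::tibble(codon = c("AAG", "AGA", "GAA"),
                                   count = c(2L, 3L, 3L)))
  # conservation: total tokens = 4n for arbitrary inputs
  set.seed(7)
  for (n in c(1, 17, 240)) {
    hex <- sample(all_hexamers(), n)
    expect_equal(sum(codon_tokens_from_hexamers(hex)$count), 4 * n)
  }
  expect_error(codon_tokens_from_hexamers("AAA"), "non-hexamer")
})

test_that("codon splicing table matches a brute-force frequency oracle", {
  # zero-free toy: every codon appears in both sets
  set.seed(8)
  ese <- c(all_hexamers()[seq(1, 4096, by = 16)])  # 256 hexamers
  ess <- c(all_hexamers()[seq(8, 4096, by = 16)])
  ct <- build_codon_splicing_table(ese, ess, pseudocount = 0)
  no_zero <- ct$ese_count > 0 & ct$ess_count > 0
  # brute force on the zero-free rows
  etok <- codon_tokens_from_hexamers(ese)
  stok <- codon_tokens_from_hexamers(ess)
  for (i in which(no_zero)[1:20]) {
    ec <- etok$count[etok$codon == ct$codon[i]]
    sc <- stok$count[stok$codon == ct$codon[i]]
    expect_equal(ct$ln_ratio[i],
                 log((ec / sum(etok$count)) / (sc / sum(stok$count))),
                 tolerance = 1e-12)
    expect_equal(ct$count_ratio[i], ec / sc, tolerance = 1e-12)
  }
  expect_equal(sum(ct$ese_freq), 1, tolerance = 1e-12)
  expect_equal(sum(ct$ess_freq), 1, tolerance = 1e-12)
  expect_equal(sum(ct$ese_count), 4 * length(ese))

  # equal frequencies give a log-ratio of zero
  same <- build_codon_splicing_table(ese, ese)
  expect_true(all(abs(same$ln_ratio) < 1e-12))

  # direct arithmetic on a 10-hexamer toy: GAC appears 3 times of 40
  # tokens in the enhancer set and once of 40 in the silencer set, so
  # ln((3/40)/(1/40)) = ln 3 at pi = 0
  ese2 <- c("GACGAC", "GACGAA", "CCCCCC", "GGGGGG", "TTTTTT",
            "ACACAC", "AGAGAG", "ATATAT", "CACACA", "CGCGCG")
  ess2 <- c("GACCCC", "AAAAAA", "CCCCCC", "GGGGGG", "TTTTTT",
            "ACACAC", "AGAGAG", "ATATAT", "CACACA", "CGCGCG")
  ct2 <- build_codon_splicing_table(ese2, ess2, pseudocount = 0)
  gac <- ct2[ct2$codon == "GAC", ]
  expect_equal(gac$ese_count, 3L)
  expect_equal(gac$ess_count, 1L)
  expect_equal(gac$ln_ratio, log(3), tolerance = 1e-12)
  expect_equal(gac$count_ratio, 3, tolerance = 1e-12)
})

test_that("swapping ESE and ESS lists negates every ratio exactly", {
  set.seed(9)
  ese <- sample(all_hexamers(), 120)
  ess <- sample(setdiff(all_hexamers(), ese), 100)
  a <- build_codon_splicing_table(ese, ess)
  b <- build_codon_splicing_table(ess, ese)
  expect_equal(a$ln_ratio, -b$ln_ratio, tolerance = 1e-12)
  da <- dinucleotide_enrichment(ese, ess)
  db <- dinucleotide_enrichment(ess, ese)
  expect_equal(da$log_odds, -db$log_odds, tolerance = 1e-12)
})

test_that("control exon background trims splice-site consensus positions", {
  tbl <- complete_hexamer_table()
  lookup <- setNames(tbl$score, tbl$hexamer)
  # a 10-nt exon leaves exactly one hexamer, at positions 2-7
  exon10 <- "ACGTACGTAC"
  res <- control_exon_background(exon10, tbl)
  expect_equal(res$n_positions, 1L)
  expect_equal(res$mean_score, unname(lookup[substr(exon10, 2, 7)]))

  expect_warning(
    res2 <- control_exon_background(c(exon10, "ACGTACGTA"), tbl),
    "shorter than 10"
  )
  expect_equal(res2$n_skipped, 1L)

  # pooled mean over two toy exons by brute force
  e1 <- "GATGACAAGTTCAG"
  e2 <- "CCGATTGACAGTA"
  pool <- c(
    unname(lookup[substring(substr(e1, 2, nchar(e1) - 3), 1:5, 6:10)]),
    unname(lookup[substring(substr(e2, 2, nchar(e2) - 3), 1:4, 6:9)])
  )
  res3 <- control_exon_background(c(e1, e2), tbl)
  expect_equal(res3$mean_score, mean(pool), tolerance = 1e-12)
  expect_equal(res3$n_positions, length(pool))
})

test_that("dinucleotide enrichment counts 5 dinucleotides per hexamer", {
  same <- dinucleotide_enrichment(c("GATGAC", "ACGTAC"),
                                  c("GATGAC", "ACGTAC"))
  expect_true(all(abs(same$log_odds) < 1e-12))

  de <- dinucleotide_enrichment("GAGAGA", "CCCCCC")
  expect_gt(de$log_odds[de$dinucleotide == "GA"], 0)
  expect_gt(de$log_odds[de$dinucleotide == "AG"], 0)
  expect_lt(de$log_odds[de$dinucleotide == "CC"], 0)

  set.seed(10)
  hex <- sample(all_hexamers(), 33)
  de2 <- dinucleotide_enrichment(hex, hex)
  expect_equal(sum(de2$ese_count), 5 * 33)
})

test_that("group comparisons reproduce closed-form statistics", {
  df <- data.frame(v = c(1, 2, 3, 4, 5, 6),
                   g = rep(c("a", "b"), each = 3))
  out <- compare_groups(df, "v", "g", test = "t")
  expect_equal(out$statistic, -3.674235, tolerance = 1e-6)

  ident <- data.frame(v = c(1, 2, 3, 1, 2, 3),
                      g = rep(c("a", "b"), each = 3))
  expect_equal(compare_groups(ident, "v", "g", test = "t")$statistic, 0)
  expect_equal(compare_groups(ident, "v", "g", test = "t")$p_value, 1)

  three <- data.frame(v = c(1, 2, 3, 1, 2, 3, 1, 2, 3),
                      g = rep(c("a", "b", "c"), each = 3))
  expect_lt(compare_groups(three, "v", "g", test = "anova")$statistic,
            1e-12)

  const <- data.frame(v = rep(1, 6), g = rep(c("a", "b"), each = 3))
  expect_warning(res <- compare_groups(const, "v", "g", test = "t"),
                 "degenerate")
  expect_true(is.na(res$statistic))

  mw <- compare_groups(df, "v", "g", test = "mannwhitney")
  expect_equal(mw$p_value, wilcox.test(1:3, 4:6)$p.value)
})
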