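test_that("RSCU normalizes within synonymous families", {
  # 2-codon family with counts (3, 1) -> RSCU (1.5, 0.5)
  tb <- rscu(c(GAC = 3, GAT = 1))
  expect_equal(tb$rscu[tb$codon == "GAC"], 1.5)
  expect_equal(tb$rscu[tb$codon == "GAT"], 0.5)

  # uniform synonymous usage -> all RSCU 1 (fully observed families)
  counts <- setNames(rep(2, 64), all_codons())
  tb2 <- rscu(counts)
  expect_true(all(abs(tb2$rscu - 1) < 1e-12))

  # single-codon family: RSCU 1 whenever observed
  expect_equal(tb2$rscu[tb2$codon == "ATG"], 1)

  # family means equal 1 for fully observed families
  fam_means <- tapply(tb2$rscu, tb2$amino_acid, mean)
  expect_true(all(abs(fam_means - 1) < 1e-12))

  # per-1000 normalization sums to 1000
  expect_equal(sum(tb2$per_1000), 1000, tolerance = 1e-6)
  expect_error(rscu(c(XXX = 3)), "not in genetic code")
})

test_that("per1000 rescales counts", {
  out <- per1000(c(GAC = 1, GAT = 1, GAA = 2))
  expect_equal(out$per_1000, c(250, 250, 500))
  expect_equal(sum(out$per_1000), 1000)
  expect_equal(per1000(c(AAA = 7))$per_1000, 1000)
})

test_that("CAI follows the Sharp-Li geometric mean convention", {
  # counts (2, 1) give RSCU (4/3, 2/3), hence w = (1, 0.5)
  ref <- rscu(c(GAC = 2, GAT = 1, AAA = 1, AAG = 1))
  # only optimal codons -> CAI 1
  expect_equal(cai("GACGACAAA", ref), 1)
  # w = (1, 0.5): CAI = exp((0 + ln 0.5) / 2)
  expect_equal(cai("GACGAT", ref), sqrt(0.5), tolerance = 1e-12)
  # appending Met leaves CAI unchanged (excluded family)
  expect_equal(cai("GACGATATG", ref), cai("GACGAT", ref))
  # synonymous permutation invariance
  expect_equal(cai("GATGACAAAAAG", ref), cai("AAGGACAAAGAT", ref))
  expect_error(cai("GACGA", ref), "divisible by 3")
  expect_error(cai("CCC", ref), "undefined")
})

test_that("expected CAI is seed-reproducible and matches a uniform oracle", {
  # query whose GC content equals the uniform-sampler expectation, so the
  # GC-affinity weight is neutral and every family choice is equally
  # likely: 5 Lys (AAA/AAG) + 5 Asn (AAT/AAC), half G/C-ending
  q <- paste0("AAA", "AAG", "AAA", "AAG", "AAA",
              "AAC", "AAT", "AAC", "AAT", "AAC")
  ref <- rscu(c(AAA = 3, AAG = 1, AAT = 1, AAC = 3))
  res1 <- expected_cai(q, ref, n_random = 1000, seed = 33)
  res2 <- expected_cai(q, ref, n_random = 1000, seed = 33)
  expect_identical(res1, res2)

  # exhaustive oracle over all 2^10 equally likely re-encodings
  w <- c(AAA = 1, AAG = 1 / 3, AAT = 1 / 3, AAC = 1)
  combos <- expand.grid(rep(list(1:2), 10))
  fams <- list(c("AAA", "AAG"), c("AAT", "AAC"))
  cais <- apply(combos, 1, function(idx) {
    codons <- vapply(seq_len(10), function(i) {
      fams[[if (i <= 5) 1 else 2]][idx[i]]
    }, character(1))
    exp(mean(log(w[codons])))
  })
  expect_lt(abs(res1$null_mean - mean(cais)),
            4 * sd(cais) / sqrt(1000))
  expect_equal(res1$gc_null, res1$gc_query, tolerance = 0.01)

  # uniform reference: every w = 1, all random CAI = 1, sd = 0
  unif_ref <- rscu(setNames(rep(1, 64), all_codons()))
  res3 <- expected_cai("GACGATAAAAAG", unif_ref, n_random = 50, seed = 1)
  expect_equal(res3$null_mean, 1)
  expect_equal(res3$null_sd, 0)

  # optimal-codon query: no random sequence can beat it
  ref_d <- rscu(c(GAC = 3, GAT = 1, AAA = 2, AAG = 1))
  res4 <- expected_cai("GACGACAAA", ref_d, n_random = 200, seed = 2)
  expect_equal(res4$cai_query, 1)
  expect_lte(res4$p_greater, 1)
  expect_gte(res4$p_greater, 0)
})

test_that("expected CAI varies across seeds within its own noise", {
  ref <- rscu(c(GAC = 3, GAT = 1, AAA = 1, AAG = 2, GGA = 1, GGC = 2))
  q <- "GACGATAAAGGAGGCAAG"
  runs <- vapply(1:5, function(s) {
    expected_cai(q, ref, n_random = 400, seed = 100 + s)$null_mean
  }, numeric(1))
  sds <- expected_cai(q, ref, n_random = 400, seed = 100)$null_sd
  expect_lt(max(runs) - min(runs), 2 * 4 * sds / sqrt(400))
})

test_that("usage bias test is the exact two-sided binomial", {
  # 9 of 10 at p = 0.5: exact tail enumeration gives 22/1024
  res <- usage_bias_test(9, 10, 0.5)
  expect_equal(res$p_value, 0.021484375, tolerance = 1e-12)

  # loop-codon-1 style contrast: strong GAC excess over the genomic 0.54
  res2 <- usage_bias_test(184, 294, 0.54)
  expect_lt(res2$p_value, 0.01)
  expect_true(res2$significant)

  # observation at the expectation is not significant
  res3 <- usage_bias_test(54, 100, 0.54)
  expect_gt(res3$p_value, 0.5)
  expect_error(usage_bias_test(1, 2, 1.2), "in \\(0, 1\\)")
})

test_that("fragile/robust classification matches neighbour enumeration", {
  expect_equal(codon_fragility(c("GAA", "TGC", "GAC", "CAC")),
               c("FRAGILE", "FRAGILE", "ROBUST", "ROBUST"))
  expect_error(codon_fragility("TAA"), "stop")
  expect_error(codon_fragility("NNN"), "not a codon")

  # independent brute force over all 61 sense codons x 9 neighbours
  code <- genetic_code_table()
  stops <- code$codon[code$amino_acid == "*"]
  sense <- code$codon[code$amino_acid != "*"]
  brute <- vapply(sense, function(cd) {
    nb <- character(0)
    for (i in 1:3) {
      for (b in c("A", "C", "G", "T")) {
        if (substr(cd, i, i) != b) {
          x <- cd
          substr(x, i, i) <- b
          nb <- c(nb, x)
        }
      }
    }
    if (any(nb %in% stops)) "FRAGILE" else "ROBUST"
  }, character(1))
  expect_equal(codon_fragility(sense), unname(brute))
  # the partition is deterministic and non-trivial
  expect_gt(sum(brute == "FRAGILE"), 0)
  expect_gt(sum(brute == "ROBUST"), 0)
})

test_that("codon vector correlation reproduces closed forms", {
  x <- setNames(c(1, 2, 3, 4, 5), c("GAA", "GAC", "GAT", "AAA", "AAG"))
  expect_equal(correlate_codon_vectors(x, 2 * x + 1)$r, 1)
  expect_equal(correlate_codon_vectors(x, -x)$r, -1)

  y <- setNames(c(2, 1, 4, 3, 6), names(x))
  # hand formula
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlate_codon_vectors(x, y)$r, r_hand, tolerance = 1e-12)

  expect_error(correlate_codon_vectors(x[1:2], y[1:2]), "at least 3")
  expect_warning(res <- correlate_codon_vectors(setNames(rep(1, 4),
                                                         names(x)[1:4]),
                                                y[1:4]),
                 "zero variance")
  expect_true(is.na(res$r))
})
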