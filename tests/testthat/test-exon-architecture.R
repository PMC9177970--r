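test_that("split positions follow the first-downstream-nt convention", {
  motif <- toy_motif(loop_start = 10L)
  # intron after nt 9: first loop nt after the intron is position 1
  ev <- map_splits(toy_models(9L), motif)
  expect_equal(ev$loop_relative_position, 1L)
  expect_true(ev$within_loop)

  # intron after nt 45 (the loop's last nt): outside
  ev2 <- map_splits(toy_models(45L), motif)
  expect_equal(ev2$loop_relative_position, 37L)
  expect_false(ev2$within_loop)

  # intron after nt 27: position 19
  ev3 <- map_splits(toy_models(27L), motif)
  expect_equal(ev3$loop_relative_position, 19L)
  expect_true(ev3$within_loop)

  # an intron outside the motif span yields no event
  ev4 <- map_splits(toy_models(200L), motif)
  expect_equal(nrow(ev4), 0L)

  bad_motif <- toy_motif()
  bad_motif$cds_motif_start <- 250L
  expect_error(map_splits(toy_models(50L), bad_motif), "outside CDS")
})

test_that("motif exon counts bin into 1 / 2 / 3+", {
  motif <- toy_motif(loop_start = 10L)
  one <- count_motif_exons(toy_models(integer(0)), motif)
  expect_equal(one$per_motif$n_exons, 1L)
  three <- count_motif_exons(toy_models(c(20L, 60L)), motif)
  expect_equal(three$per_motif$n_exons, 3L)
  expect_equal(as.character(three$per_motif$exon_bin), "3+")
  expect_equal(three$contingency$exons_3plus, 1L)
})

test_that("chi-squared contingency matches closed forms and an oracle", {
  # proportional rows give zero
  expect_lt(chi2_contingency(rbind(c(10, 20), c(30, 60)))$chi2, 1e-12)
  # 2x2 diagonal: chi2 = 20
  expect_equal(chi2_contingency(rbind(c(10, 0), c(0, 10)))$chi2, 20)
  expect_error(chi2_contingency(rbind(c(0, 0), c(3, 4))), "zero marginal")

  # direct sum((O-E)^2 / E) oracle on random tables
  set.seed(12)
  for (i in 1:1000) {
    m <- matrix(rpois(6, lambda = 20) + 1, nrow = 2)
    got <- chi2_contingency(m)
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    expect_equal(got$chi2, sum((m - E)^2 / E), tolerance = 1e-9)
    expect_equal(got$df, 2)
  }
})

test_that("split enrichment conserves totals and uses the exact binomial", {
  make_events <- function(within, outside) {
    tibble::tibble(
      gene_id = "g", motif_index = 1L, motif_class = "CANONICAL",
      cds_insertion_point = 0L,
      loop_relative_position = c(sample(1:36, within, replace = TRUE),
                                 sample(37:72, outside, replace = TRUE)),
      within_loop = rep(c(TRUE, FALSE), c(within, outside)),
      donor_dinuc = NA_character_
    )
  }
  set.seed(13)
  res <- split_enrichment(make_events(87, 126))
  expect_equal(res$n_splits, 213L)
  expect_equal(res$expected_within, 71)
  expect_equal(res$expected_outside, 142)
  expect_equal(res$observed_within + res$observed_outside, res$n_splits)
  expect_equal(res$expected_within + res$expected_outside, 213)

  # 3 splits all within: two-sided exact p by outcome enumeration is
  # P(X = 3) alone, since no other outcome has probability <= (1/3)^3
  res3 <- split_enrichment(make_events(3, 0))
  expect_equal(res3$binomial_p, (1 / 3)^3, tolerance = 1e-12)
})

test_that("split position clusters count distinct positions per region", {
  ev <- tibble::tibble(
    gene_id = "g", motif_index = 1L, motif_class = "CANONICAL",
    cds_insertion_point = 0L,
    loop_relative_position = c(4L, 4L, 4L),
    within_loop = TRUE, donor_dinuc = NA_character_
  )
  out <- split_position_clusters(ev)
  expect_equal(out$n_distinct_positions, c(1L, 0L))
  expect_equal(out$n_events, c(3L, 0L))

  empty <- ev[0, ]
  out0 <- split_position_clusters(empty)
  expect_equal(out0$n_distinct_positions, c(0L, 0L))

  # generator ground truth: the configured distinct positions come back
  cfg <- sim_config(
    n_genes = 250L,
    split_model = list(mode = "two_cluster",
                       n_exon_probs = c(0, 1, 0),
                       within_loop_prob = 1,
                       cluster_weights = c(0.7, 0.3),
                       n_positions = c(2L, 5L, 9L, 14L),
                       c_positions = c(32L, 36L))
  )
  sim <- simulate_efhand_genes(cfg, seed = 14)
  ev2 <- map_splits(sim$gene_models, sim$motifs)
  got <- split_position_clusters(ev2)
  expect_equal(got$n_distinct_positions, c(4L, 2L))
  expect_setequal(unique(ev2$loop_relative_position),
                  c(2L, 5L, 9L, 14L, 32L, 36L))
})

test_that("loop-to-splice-site distances respect the exon length filter", {
  motif <- toy_motif(loop_start = 150L)
  motif$cds_motif_start <- 120L

  # loop (150, 185) inside exon (101, 300): distances 49 and 115
  models <- tibble::tibble(gene_id = "g1", exon_index = 1:3,
                           cds_start = c(1L, 101L, 301L),
                           cds_end = c(100L, 300L, 400L),
                           donor_dinuc = c("GT", "GT", NA))
  d <- loop_to_splice_site_distances(models, motif)
  expect_equal(d$dist_3ss, 49L)
  expect_equal(d$dist_5ss, 115L)

  # loop at exon start
  motif2 <- toy_motif(loop_start = 101L)
  motif2$cds_motif_start <- 95L
  expect_equal(loop_to_splice_site_distances(models, motif2)$dist_3ss, 0L)

  # an exon of exactly 400 nt is filtered (only exons < 400 kept)
  models400 <- toy_models(integer(0), cds_len = 400L)
  d400 <- loop_to_splice_site_distances(models400, toy_motif(10L))
  expect_equal(nrow(d400), 0L)

  # loop spanning two exons is excluded with a warning
  expect_warning(
    dd <- loop_to_splice_site_distances(toy_models(20L), toy_motif(10L)),
    "spanning"
  )
  expect_equal(nrow(dd), 0L)
})

test_that("donor dinucleotides classify as GT / GC / OTHER", {
  models <- tibble::tibble(gene_id = "g", exon_index = 1:5,
                           cds_start = c(1L, 101L, 201L, 301L, 401L),
                           cds_end = c(100L, 200L, 300L, 400L, 500L),
                           donor_dinuc = c("GT", "GC", "AT", NA, NA))
  expect_warning(out <- donor_class(models), "missing donor")
  expect_equal(out$donor_class, c("GT", "GC", "OTHER", "OTHER"))
  # U-containing annotation normalizes
  models$donor_dinuc <- c("GU", "GC", "GU", "GU", NA)
  expect_equal(donor_class(models)$donor_class, c("GT", "GC", "GT", "GT"))
})

test_that("binomial p-values are calibrated under uniform splits", {
  # null replicates: splits drawn uniformly over 108 motif positions of
  # which 36 are within the loop
  set.seed(15)
  n_rep <- 200L
  n_splits <- 300L
  pvals <- vapply(seq_len(n_rep), function(r) {
    pos <- sample(c(1:36, 37:108), n_splits, replace = TRUE)
    ev <- tibble::tibble(
      gene_id = "g", motif_index = 1L, motif_class = "CANONICAL",
      cds_insertion_point = 0L,
      loop_relative_position = as.integer(pos),
      within_loop = pos <= 36, donor_dinuc = NA_character_
    )
    split_enrichment(ev)$binomial_p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
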