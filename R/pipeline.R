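#' Simulate control coding exons
#'
#' Random coding exons with uniform amino-acid and synonymous-codon
#' choice, used as the neutral background against which motif-coding
#' regions are compared.
#'
#' @param n Number of exons.
#' @param length_nt Exon length in nt (divisible by 3).
#' @param seed Optional integer seed.
#' @return Tibble with columns `id`, `seq`.
#' @export
simulate_control_exons <- function(n = 200L, length_nt = 120L,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (length_nt %% 3L != 0L) abort("length_nt must be divisible by 3")
  code <- genetic_code_table()
  sense <- code[code$amino_acid != "*", ]
  fam <- split(sense$codon, sense$amino_acid)
  seqs <- vapply(seq_len(n), function(i) {
    aa <- sample(names(fam), length_nt / 3L, replace = TRUE)
    paste(vapply(aa, function(a) sample_codon(a, fam), character(1)),
          collapse = "")
  }, character(1))
  tibble(id = sprintf("ctrl%04d", seq_len(n)), seq = seqs)
}

#' Compare motif region scores with a control-exon background
#'
#' For each motif class and region, the difference between the region's
#' pooled hexamer-score mean and the control-exon mean.  The two-sided
#' test compares per-sequence region means against per-exon control means:
#' sequences and exons are the independent units (positions within one
#' sequence are overlapping hexamers and therefore correlated).
#'
#' @param windows Tibble with columns `seq`, `loop_start` and optionally
#'   `motif_class`.
#' @param table A `hexamer_table`.
#' @param control_exons Character vector or tibble (`seq`) of control
#'   exon sequences.
#' @param regions Named list of position sets (default
#'   [ef_region_sets()]).
#' @param flanks Flanking nt available around the loop core.
#' @param core_length Loop length in nt.
#' @param test Test passed to [compare_groups()].
#' @return Tibble: `motif_class`, `region`, `mean_score`, `control_mean`,
#'   `delta`, `statistic`, `p_value`, `n_positions`.
#' @export
compare_to_background <- function(windows, table, control_exons,
                                  regions = ef_region_sets(),
                                  flanks = 0L, core_length = 36L,
                                  test = "t") {
  if (!"motif_class" %in% names(windows)) windows$motif_class <- "ALL"
  ctrl <- control_exon_background(control_exons, table)
  # per-exon control means: exons are the independent units for testing
  # (positions within a sequence are overlapping hexamers, hence
  # correlated)
  if (is.data.frame(control_exons)) control_exons <- control_exons$seq
  lookup <- setNames(table$score, table$hexamer)
  ctrl_units <- vapply(control_exons[str_length(control_exons) >= 10L],
                       function(s) {
    trimmed <- str_sub(s, 2L, str_length(s) - 3L)
    mean(unname(lookup[sliding_kmers(norm_nt(trimmed), 6L)]))
  }, numeric(1))
  classes <- unique(windows$motif_class)
  map_dfr(classes, function(cl) {
    sub <- windows[windows$motif_class == cl, ]
    if (nrow(sub) == 0L) {
      inform(paste0("class ", cl, " empty; skipped"))
      return(NULL)
    }
    long <- hexamer_start_scores(sub, table, flanks = flanks,
                                 core_length = core_length)
    map_dfr(names(regions), function(rn) {
      in_region <- long[long$position %in% regions[[rn]], ]
      seq_units <- tapply(in_region$score, in_region$seq_index, mean)
      df <- tibble(
        value = c(as.numeric(seq_units), unname(ctrl_units)),
        group = rep(c("region", "control"),
                    c(length(seq_units), length(ctrl_units)))
      )
      cmp <- compare_groups(df, "value", "group", test = test)
      tibble(motif_class = cl, region = rn,
             mean_score = mean(in_region$score),
             control_mean = ctrl$mean_score,
             delta = mean(in_region$score) - ctrl$mean_score,
             statistic = cmp$statistic, p_value = cmp$p_value,
             n_positions = nrow(in_region))
    })
  })
}

#' Loop codon usage at coordinating positions
#'
#' Codon counts and fractions at selected loop codon positions across a
#' motif set, extracted from the CDS.
#'
#' @param cds Tibble (`id`, `seq`) of coding sequences.
#' @param motifs Motif tibble ([scan_motifs()] schema).
#' @param positions Loop codon positions to tabulate (default
#'   `c(1, 3, 5, 12)`).
#' @return Tibble: `loop_codon`, `codon`, `amino_acid`, `count`,
#'   `fraction` (within the position).
#' @export
loop_codon_usage <- function(cds, motifs, positions = c(1L, 3L, 5L, 12L)) {
  seq_of <- setNames(cds$seq, cds$id)
  code <- genetic_code_table()
  aa_of <- setNames(code$amino_acid, code$codon)
  map_dfr(positions, function(p) {
    starts <- motifs$loop_start + 3L * (p - 1L)
    codons <- str_sub(seq_of[motifs$gene_id], starts, starts + 2L)
    tab <- table(codons)
    tibble(loop_codon = p, codon = names(tab),
           amino_acid = unname(aa_of[names(tab)]),
           count = as.integer(tab),
           fraction = as.integer(tab) / sum(tab))
  })
}

#' Run the full analysis pipeline on simulated data
#'
#' Orchestrates the analysis end to end on generator output: simulate
#' genes and hexamer sets, rescan the proteins for loops, compute
#' positional and region score summaries against a control background,
#' the codon-level splicing table, loop codon usage and CAI statistics,
#' exon-split statistics, and the peak-enrichment randomization sweep.
#' Deterministic for a fixed `seed`: stage seeds are derived from it.
#'
#' @param config A `sim_config`.
#' @param seed Integer master seed.
#' @param n_sims Randomizations for the enrichment stage (>= 100).
#' @param pads Padding sweep for the enrichment stage.
#' @param n_control Number of simulated control exons.
#' @param expected_cai_n Random re-encodings for the expected-CAI null.
#' @return A `splice_report`: list with elements `region_summaries`,
#'   `profile`, `codon_table`, `loop_usage`, `usage_bias`, `cai`,
#'   `exon_structure`, `split_enrichment`, `split_clusters`,
#'   `enrichment`, `data` (the simulated inputs) and `provenance`.
#' @export
run_pipeline <- function(config = sim_config(), seed = 1L,
                         n_sims = 1000L, pads = c(0L, 3L, 6L, 9L),
                         n_control = 200L, expected_cai_n = 100L) {
  if (n_sims < 100L) abort("n_sims must be >= 100")
  seed <- as.integer(seed)
  sim <- simulate_efhand_genes(config, seed = seed)
  hex <- simulate_hexamer_sets(config, seed = seed + 1L)
  controls <- simulate_control_exons(n_control, seed = seed + 2L)

  # rescan the simulated proteins: recorded loops must be recovered
  scanned <- scan_motifs(sim$proteins, sim$cds)
  windows <- tibble(seq = sim$cds$seq[match(sim$motifs$gene_id,
                                            sim$cds$id)],
                    loop_start = sim$motifs$loop_start,
                    motif_class = sim$motifs$motif_class)
  flanks <- 3L * config$helix_codons + 5L
  profile <- positional_profile(windows, hex$table, flanks = flanks)
  regions <- ef_region_sets(helix_nt = 3L * config$helix_codons)
  region_summaries <- compare_to_background(windows, hex$table,
                                            controls, regions = regions,
                                            flanks = flanks)

  codon_table <- build_codon_splicing_table(hex$ese, hex$ess)
  loop_usage <- loop_codon_usage(sim$cds, sim$motifs)
  usage_bias <- loop_usage |>
    filter(.data$loop_codon == 1L, .data$codon %in% c("GAC", "GAT"))
  gac <- usage_bias$count[usage_bias$codon == "GAC"]
  n_asp <- sum(usage_bias$count)
  bias_test <- usage_bias_test(ifelse(length(gac) == 1L, gac, 0L),
                               n_asp, 0.54)

  # CAI of loop sequences against usage of the whole simulated CDS set
  all_counts <- table(unlist(lapply(sim$cds$seq, split_codons)))
  reference <- rscu(setNames(as.integer(all_counts), names(all_counts)))
  loop_seqs <- str_sub(sim$cds$seq[match(sim$motifs$gene_id, sim$cds$id)],
                       sim$motifs$loop_start, sim$motifs$loop_end)
  pooled_loops <- paste(loop_seqs, collapse = "")
  cai_stats <- expected_cai(pooled_loops, reference,
                            n_random = expected_cai_n, seed = seed + 3L)

  events <- map_splits(sim$gene_models, sim$motifs)
  exon_structure <- count_motif_exons(sim$gene_models, sim$motifs)
  split_enr <- if (nrow(events) > 0L) split_enrichment(events) else NULL
  split_clusters <- if (nrow(events) > 0L) {
    split_position_clusters(events)
  } else {
    NULL
  }

  # interval stage: each gene is its own sequence axis (0-based BED)
  cds_len <- str_length(sim$cds$seq)
  workspace <- tibble(chrom = sim$cds$id, start = 0L, end = cds_len)
  loop_bed <- tibble(chrom = sim$motifs$gene_id,
                     start = sim$motifs$loop_start - 1L,
                     end = sim$motifs$loop_end)
  motif_bed <- tibble(
    chrom = sim$motifs$gene_id,
    start = sim$motifs$cds_motif_start - 1L,
    end = sim$motifs$cds_motif_start + sim$motifs$motif_length_nt - 1L
  )
  peaks <- simulate_peaks(config, motif_bed, workspace, seed = seed + 4L)
  set.seed(seed + 5L)
  enrichment <- enrichment_sweep(peaks, motif_bed, workspace, pads = pads,
                                 n_sims = n_sims)

  out <- list(
    region_summaries = region_summaries,
    profile = profile,
    codon_table = codon_table,
    loop_usage = loop_usage,
    usage_bias = bias_test,
    cai = cai_stats,
    exon_structure = exon_structure$contingency,
    split_enrichment = split_enr,
    split_clusters = split_clusters,
    enrichment = enrichment,
    data = c(sim, list(hexamers = hex, controls = controls,
                       scanned = scanned, peaks = peaks,
                       workspace = workspace)),
    provenance = list(
      config_hash = rlang::hash(unclass(config)),
      seed = seed, n_sims = as.integer(n_sims),
      version = as.character(utils::packageVersion("calsplice"))
    )
  )
  class(out) <- "splice_report"
  out
}

#' Serialize a report to JSON
#'
#' Writes the report's result tables (not the raw simulated data) as a
#' deterministic JSON document: identical configuration and seed give
#' byte-identical output.
#'
#' @param report A `splice_report`.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_json <- function(report, path = NULL) {
  keep <- c("region_summaries", "profile", "codon_table", "loop_usage",
            "usage_bias", "cai", "exon_structure", "split_enrichment",
            "split_clusters", "enrichment", "provenance")
  payload <- report[keep]
  payload$profile <- as_tibble(payload$profile)
  payload$enrichment <- as_tibble(payload$enrichment)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' @export
print.splice_report <- function(x, ...) {
  cat("<splice_report>\n")
  cat("  motifs scanned:", nrow(x$data$scanned), "\n")
  cat("  region summaries:", nrow(x$region_summaries), "rows\n")
  if (!is.null(x$split_enrichment)) {
    cat(sprintf("  exon splits: %d (%.1f%% within loop, binomial p = %.3g)\n",
                x$split_enrichment$n_splits,
                100 * x$split_enrichment$within_fraction,
                x$split_enrichment$binomial_p))
  }
  cat(sprintf("  enrichment tests: %d (min q = %.3g)\n",
              nrow(x$enrichment), min(x$enrichment$q)))
  invisible(x)
}
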