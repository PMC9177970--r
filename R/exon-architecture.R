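#' Map intron insertion points into motif and loop coordinates
#'
#' Produces one split event per (intron insertion point x overlapping
#' motif).  An intron inserted after CDS nt `i` interrupts a motif when
#' the first downstream nucleotide (`i + 1`) lies within the motif span.
#' The split position is indexed by the first loop nucleotide downstream
#' of the intron: `loop_relative_position = i - loop_start + 2`.  A split
#' immediately before loop nt 1 therefore counts as within the loop at
#' position 1, and a split immediately after loop nt 36 is outside,
#' keeping exactly `loop_length_nt` within-loop positions.
#'
#' @param models Gene model tibble ([read_gene_models()] schema).
#' @param motifs Motif tibble ([scan_motifs()] schema: needs `gene_id`,
#'   `cds_motif_start`, `motif_length_nt`, `loop_start`,
#'   `loop_length_nt`, `motif_class`).
#' @return Tibble of split events: `gene_id`, `motif_index`,
#'   `motif_class`, `cds_insertion_point`, `loop_relative_position`,
#'   `within_loop`, `donor_dinuc`.
#' @export
map_splits <- function(models, motifs) {
  validate_gene_models(models)
  spans <- models |>
    group_by(.data$gene_id) |>
    summarise(cds_max = max(.data$cds_end), .groups = "drop")
  mt <- left_join(motifs, spans, by = "gene_id")
  mt$motif_index <- seq_len(nrow(mt))
  bad <- !is.na(mt$cds_max) &
    (mt$cds_motif_start + mt$motif_length_nt - 1L > mt$cds_max)
  if (any(bad)) {
    abort(paste0("motif outside CDS span for gene(s): ",
                 paste(unique(mt$gene_id[bad]), collapse = ", ")))
  }
  ins <- intron_insertion_points(models)
  if (nrow(ins) == 0L || nrow(mt) == 0L) {
    return(tibble(gene_id = character(0), motif_index = integer(0),
                  motif_class = character(0),
                  cds_insertion_point = integer(0),
                  loop_relative_position = integer(0),
                  within_loop = logical(0), donor_dinuc = character(0)))
  }
  joined <- dplyr::inner_join(ins, mt, by = "gene_id",
                              relationship = "many-to-many")
  motif_end <- joined$cds_motif_start + joined$motif_length_nt - 1L
  hit <- joined$cds_insertion_point + 1L >= joined$cds_motif_start &
    joined$cds_insertion_point + 1L <= motif_end
  joined <- joined[hit, ]
  pos <- joined$cds_insertion_point - joined$loop_start + 2L
  tibble(
    gene_id = joined$gene_id,
    motif_index = joined$motif_index,
    motif_class = joined$motif_class,
    cds_insertion_point = joined$cds_insertion_point,
    loop_relative_position = as.integer(pos),
    within_loop = pos >= 1L & pos <= joined$loop_length_nt,
    donor_dinuc = joined$donor_dinuc
  )
}

#' Count exons per motif
#'
#' Number of distinct exons overlapping each motif span, binned as 1, 2 or
#' >= 3, plus a class-by-bin contingency table.
#'
#' @inheritParams map_splits
#' @return List with `per_motif` (tibble: `gene_id`, `motif_index`,
#'   `motif_class`, `n_exons`, `exon_bin`) and `contingency` (tibble:
#'   `motif_class`, `exons_1`, `exons_2`, `exons_3plus`).
#' @export
count_motif_exons <- function(models, motifs) {
  validate_gene_models(models)
  mt <- motifs
  mt$motif_index <- seq_len(nrow(mt))
  per_motif <- map_dfr(seq_len(nrow(mt)), function(i) {
    g <- models[models$gene_id == mt$gene_id[i], ]
    m_start <- mt$cds_motif_start[i]
    m_end <- m_start + mt$motif_length_nt[i] - 1L
    n_ex <- sum(g$cds_end >= m_start & g$cds_start <= m_end)
    tibble(gene_id = mt$gene_id[i], motif_index = i,
           motif_class = mt$motif_class[i], n_exons = n_ex)
  })
  per_motif$exon_bin <- cut(per_motif$n_exons, c(0, 1, 2, Inf),
                            labels = c("1", "2", "3+"))
  contingency <- per_motif |>
    count(.data$motif_class, .data$exon_bin) |>
    pivot_wider(names_from = "exon_bin", values_from = "n",
                values_fill = 0L)
  for (col in c("1", "2", "3+")) {
    if (!col %in% names(contingency)) contingency[[col]] <- 0L
  }
  contingency <- contingency |>
    rename(exons_1 = "1", exons_2 = "2", exons_3plus = "3+") |>
    select("motif_class", "exons_1", "exons_2", "exons_3plus")
  list(per_motif = per_motif, contingency = contingency)
}

#' Pearson chi-squared test for an r x k contingency table
#'
#' Pearson chi-squared without continuity correction, df = (r-1)(k-1).
#'
#' @param table Numeric matrix (or coercible) of counts.
#' @return One-row tibble: `chi2`, `df`, `p_value`.
#' @export
#' @examples
#' chi2_contingency(rbind(c(79, 178, 39), c(15, 47, 4)))
chi2_contingency <- function(table) {
  m <- as.matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("contingency table has a zero marginal")
  }
  res <- suppressWarnings(chisq.test(m, correct = FALSE))
  if (any(res$expected <= 0)) abort("expected cell count <= 0")
  tibble(chi2 = unname(res$statistic), df = unname(res$parameter),
         p_value = res$p.value)
}

#' Exon-split enrichment within the chelation loop
#'
#' Tests whether intron insertion points fall inside the loop more often
#' than expected for a random position within the motif, assuming fixed
#' loop and motif lengths (default 36 and 108 nt, so the null
#' within-loop probability is 1/3).  An exact two-sided binomial test is
#' used for the within/outside counts, and a chi-squared test for
#' positional uniformity of the within-loop splits (adjacent positions
#' are pooled into equal-width bins when expected counts would fall
#' below 1).
#'
#' @param events Split events from [map_splits()].
#' @param loop_len Loop length in nt (default 36).
#' @param motif_len Motif length in nt (default 108).
#' @return One-row tibble: `n_splits`, `observed_within`,
#'   `expected_within`, `observed_outside`, `expected_outside`,
#'   `within_fraction`, `binomial_p`, `chi2_positional`, `chi2_p`.
#' @export
split_enrichment <- function(events, loop_len = 36L, motif_len = 108L) {
  n <- nrow(events)
  if (n < 1L) abort("need at least one split event")
  obs_within <- sum(events$within_loop)
  p0 <- loop_len / motif_len
  exp_within <- n * p0
  btest <- binom.test(obs_within, n, p0)
  pos <- events$loop_relative_position[events$within_loop]
  if (length(pos) > 0L) {
    bin_width <- max(1L, ceiling(loop_len / max(1L, length(pos))))
    breaks <- unique(c(seq(0L, loop_len, by = bin_width), loop_len))
    counts <- table(cut(pos, breaks))
    probs <- diff(breaks) / loop_len
    ch <- suppressWarnings(chisq.test(as.vector(counts), p = probs))
    chi2_pos <- unname(ch$statistic)
    chi2_p <- ch$p.value
  } else {
    chi2_pos <- NA_real_
    chi2_p <- NA_real_
  }
  tibble(n_splits = n, observed_within = obs_within,
         expected_within = exp_within,
         observed_outside = n - obs_within,
         expected_outside = n - exp_within,
         within_fraction = obs_within / n,
         binomial_p = btest$p.value,
         chi2_positional = chi2_pos, chi2_p = chi2_p)
}

#' Distinct split positions per loop region
#'
#' Descriptive counts of distinct within-loop split positions in the
#' N-terminal half of the chelation loop and in the C-terminal region
#' around the last loop codon, where exon splits cluster.
#'
#' @param events Split events from [map_splits()].
#' @param n_region Integer nt positions of the N-terminal region (default
#'   codons 1-6, nt 1-18).
#' @param c_region Integer nt positions of the C-terminal region (default
#'   codons 11-12 plus a 3-nt flank each side, nt 28-39).
#' @return Tibble with one row per region: `region`,
#'   `n_distinct_positions`, `n_events`.
#' @export
split_position_clusters <- function(events, n_region = 1:18,
                                    c_region = 28:39) {
  pos <- events$loop_relative_position
  summarise_region <- function(name, set) {
    in_set <- pos %in% set
    tibble(region = name,
           n_distinct_positions = length(unique(pos[in_set])),
           n_events = sum(in_set))
  }
  bind_rows(summarise_region("N_terminal", n_region),
            summarise_region("C_terminal", c_region))
}

#' Distances from loops to splice sites
#'
#' For loops encoded within a single exon, the distance from the exon's
#' acceptor (3'ss) to the loop start and from the loop end to the exon's
#' donor (5'ss).  Loops in exons of `max_exon_len` nt or longer are
#' filtered out; loops spanning an exon boundary are excluded with a
#' warning.
#'
#' @inheritParams map_splits
#' @param max_exon_len Exons at or above this length are excluded
#'   (default 400, i.e. only exons smaller than 400 nt are kept).
#' @return Tibble: `gene_id`, `motif_index`, `motif_class`, `exon_len`,
#'   `dist_3ss`, `dist_5ss`.
#' @export
loop_to_splice_site_distances <- function(models, motifs,
                                          max_exon_len = 400L) {
  validate_gene_models(models)
  mt <- motifs
  mt$motif_index <- seq_len(nrow(mt))
  spanning <- 0L
  rows <- map_dfr(seq_len(nrow(mt)), function(i) {
    g <- models[models$gene_id == mt$gene_id[i], ]
    ls <- mt$loop_start[i]
    le <- ls + mt$loop_length_nt[i] - 1L
    host <- g[g$cds_start <= ls & g$cds_end >= le, ]
    if (nrow(host) == 0L) {
      spanning <<- spanning + 1L
      return(NULL)
    }
    tibble(gene_id = mt$gene_id[i], motif_index = i,
           motif_class = mt$motif_class[i],
           exon_len = host$cds_end[1] - host$cds_start[1] + 1L,
           dist_3ss = ls - host$cds_start[1],
           dist_5ss = host$cds_end[1] - le)
  })
  if (spanning > 0L) {
    warn(sprintf("excluded %d loop(s) spanning exon boundaries", spanning))
  }
  if (is.null(rows) || nrow(rows) == 0L) {
    return(tibble(gene_id = character(0), motif_index = integer(0),
                  motif_class = character(0), exon_len = integer(0),
                  dist_3ss = integer(0), dist_5ss = integer(0)))
  }
  filter(rows, .data$exon_len < max_exon_len)
}

#' Classify intron donor dinucleotides
#'
#' Canonical human introns start with GT; a rare (~1%) variant class
#' starts with GC.  Anything else (or a missing annotation, with a
#' warning) is OTHER.
#'
#' @param models Gene model tibble with a `donor_dinuc` column.
#' @return Tibble: `gene_id`, `cds_insertion_point`, `donor_dinuc`,
#'   `donor_class` in `{GT, GC, OTHER}` — one row per intron.
#' @export
donor_class <- function(models) {
  ins <- intron_insertion_points(models)
  d <- norm_nt(ins$donor_dinuc)
  if (anyNA(d)) {
    warn(sprintf("%d intron(s) missing donor annotation; classed OTHER",
                 sum(is.na(d))))
  }
  cls <- dplyr::case_when(
    is.na(d) ~ "OTHER",
    d == "GT" ~ "GT",
    d == "GC" ~ "GC",
    TRUE ~ "OTHER"
  )
  mutate(ins, donor_class = cls)
}
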