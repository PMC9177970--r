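#' Default per-position residue frequencies for simulated EF-hand loops
#'
#' A qualitative digitization of the residue composition of human
#' canonical EF-hand chelation loops: Asp dominates (about a quarter of
#' all loop residues, required at position 1), Glu contributes about an
#' eighth (dominant at position 12), Gly is nearly invariant at position
#' 6, and charged residues account for roughly half the loop.  Every
#' per-position distribution is compatible with the 12-residue loop
#' consensus; the table is an editable input, not hard-coded truth.
#'
#' @return Tibble with columns `position` (1-12), `residue`, `prob`;
#'   probabilities sum to 1 within each position.
#' @export
default_loop_residue_freqs <- function() {
  spec <- list(
    `1` = c(D = 1),
    `2` = c(K = 0.40, A = 0.25, Q = 0.20, T = 0.15),
    `3` = c(D = 0.70, N = 0.20, S = 0.10),
    `4` = c(D = 0.30, N = 0.20, K = 0.20, G = 0.20, R = 0.10),
    `5` = c(D = 0.60, N = 0.15, S = 0.10, G = 0.10, E = 0.05),
    `6` = c(G = 0.90, K = 0.05, D = 0.05),
    `7` = c(L = 0.25, K = 0.25, E = 0.20, T = 0.15, A = 0.15),
    `8` = c(I = 0.40, L = 0.30, V = 0.25, M = 0.05),
    `9` = c(D = 0.30, S = 0.20, N = 0.20, E = 0.15, T = 0.15),
    `10` = c(A = 0.25, E = 0.25, G = 0.20, K = 0.20, F = 0.10),
    `11` = c(E = 0.30, A = 0.20, K = 0.20, T = 0.15, D = 0.15),
    `12` = c(E = 0.90, D = 0.10)
  )
  map_dfr(names(spec), function(p) {
    tibble(position = as.integer(p), residue = names(spec[[p]]),
           prob = unname(spec[[p]]))
  })
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic-data generator.
#' Defaults emulate the study conditions of the human canonical EF-hand
#' sample: 296 loops, loop residue frequencies per
#' [default_loop_residue_freqs()], wobble usage bias at loop codons 1
#' (GAC:GAT = 0.63:0.37) and 12 (GAG:GAA ~ 0.67:0.33 given Glu),
#' exon-count mix 79:178:39 for 1/2/3+ exons, hexamer class sizes
#' 1182 ESE / 1090 ESS, and a GC donor fraction of 1 percent.
#'
#' @param n_genes Number of simulated genes (one canonical loop each).
#' @param flank_codons Codons of non-motif sequence on each side of the
#'   motif (default 30).
#' @param helix_codons Helix codons on each side of the loop inside the
#'   motif (default 12, giving a 108-nt motif with a central 36-nt loop).
#' @param loop_residue_freqs Tibble (`position`, `residue`, `prob`).
#' @param codon_usage_bias Named list of per-loop-codon conditional codon
#'   weights, e.g. `list("1" = c(GAC = 0.63, GAT = 0.37))`; families not
#'   listed are sampled uniformly.
#' @param split_model List: `mode` (`"uniform"`, `"two_cluster"` or
#'   `"none"`), `n_exon_probs` (probabilities of 1, 2, 3 exons per
#'   motif), `within_loop_prob` (probability that a split falls inside
#'   the loop; default the observed 112/262), `cluster_weights`,
#'   `n_positions`, `c_positions` (loop nt positions of the two
#'   clusters, used by `two_cluster`).
#' @param hexamer_model List: `n_ese`, `n_ess`, `ga_enrichment` (target
#'   fold excess of GA dinucleotide frequency in the ESE set).
#' @param peak_model List: `n_peaks`, `peak_length`, `fold_in_motifs`
#'   (programmed per-peak overlap enrichment over motif intervals).
#' @param gc_donor_fraction Fraction of introns with a GC (rather than
#'   GT) donor dinucleotide.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 296L,
                       flank_codons = 30L,
                       helix_codons = 12L,
                       loop_residue_freqs = default_loop_residue_freqs(),
                       codon_usage_bias = list(
                         "1" = c(GAC = 0.63, GAT = 0.37),
                         "12" = c(GAG = 0.62, GAA = 0.30, GAC = 0.05,
                                  GAT = 0.03)
                       ),
                       split_model = list(
                         mode = "two_cluster",
                         n_exon_probs = c(79, 178, 39) / 296,
                         within_loop_prob = 112 / 262,
                         cluster_weights = c(0.7, 0.3),
                         n_positions = c(1L, 2L, 4L, 5L, 7L, 8L, 10L,
                                         13L, 16L, 17L),
                         c_positions = c(31L, 33L, 34L, 36L)
                       ),
                       hexamer_model = list(n_ese = 1182L, n_ess = 1090L,
                                            ga_enrichment = 2),
                       peak_model = list(n_peaks = 2000L,
                                         peak_length = 30L,
                                         fold_in_motifs = 1),
                       gc_donor_fraction = 0.01) {
  cfg <- list(n_genes = as.integer(n_genes),
              flank_codons = as.integer(flank_codons),
              helix_codons = as.integer(helix_codons),
              loop_residue_freqs = loop_residue_freqs,
              codon_usage_bias = codon_usage_bias,
              split_model = split_model,
              hexamer_model = hexamer_model,
              peak_model = peak_model,
              gc_donor_fraction = gc_donor_fraction)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  lf <- cfg$loop_residue_freqs
  sums <- tapply(lf$prob, lf$position, sum)
  if (any(abs(sums - 1) > 1e-8)) {
    abort("loop residue probabilities must sum to 1 per position")
  }
  pattern <- parse_prosite_pattern(ef_hand_consensus())
  for (p in sort(unique(lf$position))) {
    support <- lf$residue[lf$position == p & lf$prob > 0]
    type <- pattern$type[p]
    set <- pattern$residues[[p]]
    bad <- switch(type,
                  ANY = character(0),
                  REQUIRED = setdiff(support, set),
                  FORBIDDEN = intersect(support, set))
    if (length(bad) > 0L) {
      abort(sprintf(
        "loop position %d: residue(s) %s incompatible with the consensus",
        p, paste(bad, collapse = ", ")))
    }
  }
  probs <- cfg$split_model$n_exon_probs
  if (abs(sum(probs) - 1) > 1e-8) {
    abort("split_model$n_exon_probs must sum to 1")
  }
  if (!cfg$split_model$mode %in% c("uniform", "two_cluster", "none")) {
    abort("split_model$mode must be uniform, two_cluster or none")
  }
  if (cfg$peak_model$fold_in_motifs < 1) {
    abort("peak_model$fold_in_motifs must be >= 1")
  }
  if (cfg$hexamer_model$n_ese + cfg$hexamer_model$n_ess > 4096L) {
    abort("n_ese + n_ess must not exceed 4096")
  }
  invisible(cfg)
}

# Reverse-translate one amino acid: codon weights from the per-loop-codon
# bias when given, else family-uniform.
sample_codon <- function(aa, fam, bias = NULL) {
  cs <- fam[[aa]]
  if (!is.null(bias)) {
    w <- bias[intersect(names(bias), cs)]
    if (length(w) > 0L) {
      return(sample(names(w), 1L, prob = w / sum(w)))
    }
  }
  if (length(cs) == 1L) cs else sample(cs, 1L)
}

#' Simulate EF-hand genes
#'
#' Generates protein and CDS sequences carrying one canonical EF-hand
#' motif each, together with motif records and gene models.  Loop
#' residues are drawn position-wise from the configured frequencies
#' (always consensus-conforming); the CDS is reverse-translated with the
#' configured wobble bias at loop codons 1 and 12 and family-uniform
#' codon choice elsewhere; exon boundaries are drawn from the split
#' model.  All motif coordinates are correct by construction.
#'
#' @param config A `sim_config`.
#' @param seed Optional integer seed.
#' @return List with tibbles `proteins` (`id`, `seq`), `cds` (`id`,
#'   `seq`), `motifs` ([scan_motifs()] schema) and `gene_models`
#'   ([read_gene_models()] schema).
#' @export
simulate_efhand_genes <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  code <- genetic_code_table()
  sense <- code[code$amino_acid != "*", ]
  fam <- split(sense$codon, sense$amino_acid)
  aas <- names(fam)
  lf <- config$loop_residue_freqs
  loop_dists <- lapply(1:12, function(p) {
    sub <- lf[lf$position == p, ]
    setNames(sub$prob, sub$residue)
  })
  n_flank <- config$flank_codons
  n_helix <- config$helix_codons
  loop_aa_start <- n_flank + n_helix + 1L
  n_aa <- 2L * n_flank + 2L * n_helix + 12L
  loop_start_nt <- 3L * (loop_aa_start - 1L) + 1L
  motif_start_nt <- loop_start_nt - 3L * n_helix
  motif_len_nt <- 3L * (2L * n_helix + 12L)
  cds_len <- 3L * n_aa

  genes <- lapply(seq_len(config$n_genes), function(g) {
    loop <- vapply(loop_dists, function(d) {
      sample(names(d), 1L, prob = d)
    }, character(1))
    background <- function(n) sample(aas, n, replace = TRUE)
    prot <- c(background(n_flank + n_helix), loop,
              background(n_helix + n_flank))
    codons <- vapply(seq_along(prot), function(i) {
      loop_codon <- i - loop_aa_start + 1L
      bias <- if (loop_codon >= 1L && loop_codon <= 12L) {
        config$codon_usage_bias[[as.character(loop_codon)]]
      } else {
        NULL
      }
      sample_codon(prot[i], fam, bias)
    }, character(1))
    list(protein = paste(prot, collapse = ""),
         cds = paste(codons, collapse = ""))
  })
  ids <- sprintf("gene%04d", seq_len(config$n_genes))

  motifs <- tibble(
    gene_id = ids,
    motif_class = "CANONICAL",
    aa_start = loop_aa_start,
    cds_motif_start = motif_start_nt,
    motif_length_nt = motif_len_nt,
    loop_start = loop_start_nt,
    loop_end = loop_start_nt + 35L,
    loop_length_nt = 36L,
    frame = 0L,
    coordinating_codons = rep(list(c(1L, 3L, 5L, 9L, 12L)),
                              config$n_genes)
  )

  gene_models <- map_dfr(seq_len(config$n_genes), function(g) {
    splits <- draw_splits(config, motif_start_nt, loop_start_nt,
                          motif_len_nt)
    bounds <- c(0L, sort(splits), cds_len)
    n_ex <- length(bounds) - 1L
    donors <- ifelse(runif(max(0L, n_ex - 1L)) < config$gc_donor_fraction,
                     "GC", "GT")
    tibble(gene_id = ids[g], exon_index = seq_len(n_ex),
           cds_start = bounds[-length(bounds)] + 1L,
           cds_end = bounds[-1L],
           donor_dinuc = c(donors, NA_character_))
  })

  list(
    proteins = tibble(id = ids,
                      seq = map_chr(genes, "protein")),
    cds = tibble(id = ids, seq = map_chr(genes, "cds")),
    motifs = motifs,
    gene_models = gene_models
  )
}

# Draw the intron insertion points (CDS nt indices) for one gene.
draw_splits <- function(config, motif_start_nt, loop_start_nt,
                        motif_len_nt) {
  sm <- config$split_model
  if (sm$mode == "none") return(integer(0))
  n_exons <- sample(seq_along(sm$n_exon_probs), 1L, prob = sm$n_exon_probs)
  k <- n_exons - 1L
  if (k == 0L) return(integer(0))
  # candidate insertion points interrupt the motif: the first downstream
  # nt lies within [motif_start, motif_end]
  candidates <- (motif_start_nt - 1L):(motif_start_nt + motif_len_nt - 2L)
  if (sm$mode == "uniform") {
    return(sample(candidates, k))
  }
  # two_cluster: with probability within_loop_prob the split falls in the
  # loop and is drawn from the two position clusters; otherwise it falls
  # uniformly among the motif positions outside the loop
  loop_rel <- candidates - loop_start_nt + 2L
  outside <- candidates[loop_rel < 1L | loop_rel > 36L]
  p_within <- sm$within_loop_prob %||% 1
  draw_one <- function() {
    if (runif(1) < p_within) {
      cl <- sample(c("n", "c"), 1L, prob = sm$cluster_weights)
      pos <- if (cl == "n") sm$n_positions else sm$c_positions
      p <- if (length(pos) == 1L) pos else sample(pos, 1L)
      loop_start_nt + p - 2L
    } else {
      if (length(outside) == 1L) outside else sample(outside, 1L)
    }
  }
  pts <- integer(0)
  while (length(pts) < k) {
    pts <- unique(c(pts, draw_one()))
  }
  pts[seq_len(k)]
}

#' Simulate ESE/ESS hexamer sets
#'
#' Draws disjoint ESE and ESS hexamer sets from the 4096 possible
#' hexamers such that the GA dinucleotide frequency in the ESE set
#' exceeds the ESS set by the configured factor in expectation.  The ESS
#' set is sampled uniformly; the ESE set is then sampled from the
#' remainder with exponential tilting on each hexamer's GA-dinucleotide
#' count, with the tilt calibrated so the expected frequency ratio equals
#' `ga_enrichment`.  Scores are drawn so that ESE scores stochastically
#' dominate ESS scores (shifted normals); remaining hexamers are
#' NEUTRAL.
#'
#' @param config A `sim_config` (uses `hexamer_model`).
#' @param seed Optional integer seed.
#' @return List with `ese`, `ess` (character vectors) and `table` (a
#'   complete 4096-row `hexamer_table`).
#' @export
simulate_hexamer_sets <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  hm <- config$hexamer_model
  all_hex <- sort(do.call(paste0, expand.grid(rep(list(DNA_BASES), 6),
                                              stringsAsFactors = FALSE)))
  # GA cannot overlap itself, so a plain count equals the number of GA
  # dinucleotide positions
  ga_count <- str_count(all_hex, "GA")
  base_freq <- sum(ga_count) / (5 * length(all_hex))

  target <- hm$ga_enrichment
  if (target < 1) abort("ga_enrichment must be >= 1")

  # the ESS set is drawn uniformly (its expected GA frequency equals the
  # base frequency); the ESE set is then drawn from the remainder with
  # per-hexamer inclusion probabilities p_h = min(1, c * exp(theta*ga_h)),
  # with c fixing the expected set size and theta calibrated so the
  # expected GA frequency of the drawn set is target * base
  ess_idx <- sample.int(length(all_hex), hm$n_ess)
  remaining <- setdiff(seq_along(all_hex), ess_idx)
  g <- ga_count[remaining]
  n_ese <- hm$n_ese
  incl_prob <- function(theta) {
    # solve for the size-fixing constant in log space (the root can be
    # many orders of magnitude below 1)
    f <- function(x) sum(pmin(1, exp(x + theta * g))) - n_ese
    x <- stats::uniroot(f, c(-200, 0), extendInt = "upX",
                        tol = 1e-10)$root
    pmin(1, exp(x + theta * g))
  }
  ratio_at <- function(theta) {
    p <- incl_prob(theta)
    (sum(p * g) / (5 * n_ese)) / base_freq
  }
  theta <- 0
  if (target > 1) {
    if (ratio_at(25) <= target) {
      abort(sprintf("ga_enrichment %.2f not achievable (max %.2f)",
                    target, ratio_at(25)))
    }
    theta <- stats::uniroot(function(th) ratio_at(th) - target,
                            c(0, 25))$root
  }
  p <- incl_prob(theta)
  picked <- which(runif(length(p)) < p)
  # trim or top up uniformly to hit the exact set size
  if (length(picked) > n_ese) {
    picked <- sample(picked, n_ese)
  } else if (length(picked) < n_ese) {
    extra <- sample(setdiff(seq_along(p), picked), n_ese - length(picked))
    picked <- c(picked, extra)
  }
  ese_idx <- remaining[picked]
  ese <- all_hex[ese_idx]
  ess <- all_hex[ess_idx]
  label <- rep("NEUTRAL", length(all_hex))
  label[ese_idx] <- "ESE"
  label[ess_idx] <- "ESS"
  score <- rnorm(length(all_hex), mean = 0, sd = 0.5) +
    ifelse(label == "ESE", 1, ifelse(label == "ESS", -1, 0))
  list(ese = ese, ess = ess,
       table = hexamer_table(all_hex, score, label))
}

#' Simulate peak intervals with programmed motif enrichment
#'
#' Places peaks of fixed length in the workspace so that the expected
#' per-peak nucleotide overlap with the motif annotation equals
#' `fold_in_motifs` times the expectation under uniform placement.  Each
#' peak is, with a calibrated mixture probability, placed uniformly among
#' starts lying fully inside a motif interval, and otherwise uniformly
#' over all valid workspace starts; `fold_in_motifs = 1` reduces exactly
#' to the uniform null.
#'
#' @param config A `sim_config` (uses `peak_model`).
#' @param motifs Interval tibble of motif annotations (0-based
#'   half-open), each interval at least `peak_length` wide.
#' @param workspace Interval tibble; must contain the motif intervals.
#' @param seed Optional integer seed.
#' @return Interval tibble of peaks (`chrom`, `start`, `end`, `name`,
#'   `score`).
#' @export
simulate_peaks <- function(config = sim_config(), motifs, workspace,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  pm <- config$peak_model
  L <- as.integer(pm$peak_length)
  ws <- merge_intervals(workspace)
  ann <- merge_intervals(motifs)
  inside <- intersect_intervals(ann, ws)
  if (nrow(inside) == 0L || sum(inside$end - inside$start) <
      sum(ann$end - ann$start)) {
    abort("motif intervals must lie within the workspace")
  }
  if (any(ann$end - ann$start < L)) {
    abort("every motif interval must be at least peak_length wide")
  }
  index <- coverage_index(ann)
  sampler <- workspace_sampler(ws, L)
  # expected per-peak overlap under uniform placement, by enumerating all
  # valid starts
  sp <- sampler$samplers[[as.character(L)]]
  total_ov <- 0
  for (j in seq_len(nrow(ws))) {
    n_valid <- max(0, ws$end[j] - ws$start[j] - L + 1)
    if (n_valid == 0) next
    starts <- ws$start[j] + seq_len(n_valid) - 1
    seg <- tibble(chrom = ws$chrom[j], start = starts, end = starts + L)
    total_ov <- total_ov + sum(segment_overlaps(seg, index))
  }
  e_uniform <- total_ov / sp$total
  fold <- pm$fold_in_motifs
  q <- if (fold == 1) 0 else (fold - 1) * e_uniform / (L - e_uniform)
  if (q > 1) {
    abort(sprintf("fold_in_motifs %.2f not achievable with this geometry",
                  fold))
  }
  # sampler for starts fully inside motif intervals
  motif_sampler <- workspace_sampler(ann, L)
  in_motif <- runif(pm$n_peaks) < q
  peaks_out <- draw_placements(sampler, rep(L, sum(!in_motif)))
  peaks_in <- draw_placements(motif_sampler, rep(L, sum(in_motif)))
  peaks <- bind_rows(peaks_out, peaks_in)
  peaks$name <- sprintf("peak%05d", seq_len(nrow(peaks)))
  peaks$score <- 0
  sort_intervals(peaks)
}
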