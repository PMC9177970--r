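#' Per-sequence, per-position hexamer start scores
#'
#' The workhorse behind positional profiles and region means.  Each input
#' sequence is a CDS window containing a fixed-length core (e.g. the 36-nt
#' chelation loop) plus flanking context; the value attributed to position
#' i (1-based within the core; positions <= 0 and > core length address the
#' flanks) is the score of the hexamer *starting* at i.  Sequences lacking
#' context at a boundary position are dropped from that position only, and
#' per-position sequence counts are kept.
#'
#' @param windows Either a character vector of equal-length windows (core
#'   assumed to start at `flanks + 1`) or a tibble with columns `seq` and
#'   `loop_start` (1-based position of the core's first nt within `seq`).
#' @param table A `hexamer_table`.
#' @param flanks Number of flanking nt on each side of the core over which
#'   the profile extends.
#' @param core_length Core length in nt (default 36, the EF-hand loop).
#' @return Long tibble with columns `seq_index`, `position` (core-relative
#'   hexamer start), `hexamer`, `score`, `is_ess`.
#' @export
hexamer_start_scores <- function(windows, table, flanks = 0L,
                                 core_length = 36L) {
  if (is.character(windows)) {
    windows <- tibble(seq = windows, loop_start = flanks + 1L)
  }
  stopifnot(all(c("seq", "loop_start") %in% names(windows)))
  seqs <- norm_nt(windows$seq)
  lookup_score <- setNames(table$score, table$hexamer)
  lookup_label <- setNames(table$label, table$hexamer)
  pos_min <- 1L - as.integer(flanks)
  pos_max <- as.integer(core_length) + as.integer(flanks) - 5L
  out <- map_dfr(seq_along(seqs), function(i) {
    s <- seqs[i]
    n <- str_length(s)
    if (n < 6L) return(NULL)
    abs_start <- 1:(n - 5L)
    rel <- abs_start - windows$loop_start[i] + 1L
    keep <- rel >= pos_min & rel <= pos_max
    if (!any(keep)) return(NULL)
    abs_start <- abs_start[keep]
    rel <- rel[keep]
    hex <- str_sub(s, abs_start, abs_start + 5L)
    tibble(seq_index = i, position = rel, hexamer = hex)
  })
  if (nrow(out) == 0L) {
    return(tibble(seq_index = integer(0), position = integer(0),
                  hexamer = character(0), score = numeric(0),
                  is_ess = logical(0)))
  }
  score <- lookup_score[out$hexamer]
  if (anyNA(score)) {
    missing <- unique(out$hexamer[is.na(score)])
    abort(paste0("hexamer(s) absent from score table: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  out$score <- unname(score)
  out$is_ess <- unname(lookup_label[out$hexamer] == "ESS")
  out
}

#' Positional splicing-score profile
#'
#' Mean hexamer score per position across a set of aligned CDS windows,
#' with core position 1 being the loop's first nucleotide.  The value at
#' position i is the mean, over sequences, of the score of the hexamer
#' starting at i; `ess_start_count` tallies how many sequences have an
#' ESS-labelled hexamer starting there (a count of zero is the profile
#' analogue of a position entirely devoid of silencers).
#'
#' @inheritParams hexamer_start_scores
#' @return A `splice_profile` tibble with columns `position`,
#'   `mean_score`, `n_seq`, `ess_start_count`.
#' @export
#' @examples
#' tbl <- hexamer_table(c("AAAAAA", "AAAAAT"), c(1, -1), c("ESE", "ESS"))
#' positional_profile("AAAAAAAT", tbl, core_length = 8)
positional_profile <- function(windows, table, flanks = 0L,
                               core_length = 36L) {
  long <- hexamer_start_scores(windows, table, flanks = flanks,
                               core_length = core_length)
  prof <- long |>
    group_by(.data$position) |>
    summarise(mean_score = mean(.data$score), n_seq = n(),
              ess_start_count = sum(.data$is_ess), .groups = "drop") |>
    arrange(.data$position)
  attr(prof, "core_length") <- as.integer(core_length)
  class(prof) <- c("splice_profile", class(prof))
  prof
}

#' Region sets for EF-hand motif scoring
#'
#' Standard position sets (core-relative hexamer start positions) used to
#' summarise splicing scores: the chelation loop (EFL), its
#' Ca2+-coordinating residues (CR), the whole helix-loop-helix motif (EFM)
#' and the motif outside the loop (ROEF).  EFM is the disjoint union of
#' EFL and ROEF.
#'
#' Ca2+ in canonical EF-hands is chelated mainly through side-chain or
#' water-bridged oxygens of loop residues 1, 3, 5, 9 and 12; residue 7
#' contributes a backbone carbonyl and is excluded from CR by default but
#' can be added via `cr_codons`.
#'
#' @param loop_length Loop length in nt (default 36).
#' @param helix_nt Motif extension on each side of the loop in nt (default
#'   36, giving a 108-nt motif).
#' @param cr_codons Loop codon indices counted as coordinating (default
#'   `c(1, 3, 5, 9, 12)`).
#' @return Named list of integer position vectors: `EFL`, `CR`, `EFM`,
#'   `ROEF`.
#' @export
ef_region_sets <- function(loop_length = 36L, helix_nt = 36L,
                           cr_codons = c(1L, 3L, 5L, 9L, 12L)) {
  efl <- seq_len(loop_length)
  cr <- sort(unlist(lapply(cr_codons, function(cc) (3L * cc - 2L):(3L * cc))))
  efm <- (1L - helix_nt):(loop_length + helix_nt)
  list(EFL = efl, CR = cr, EFM = efm, ROEF = setdiff(efm, efl))
}

#' Region mean splicing scores
#'
#' Pools hexamer-start scores over (sequence x member position) pairs for
#' each named region and reports the mean, the number of pooled positions
#' and the standard error.
#'
#' @inheritParams hexamer_start_scores
#' @param regions Named list of integer vectors of core-relative positions
#'   (e.g. from [ef_region_sets()]).
#' @return Tibble with columns `region`, `mean_score`, `n_positions`
#'   (pooled sequence x position pairs actually scored), `sem`.
#' @export
region_mean <- function(windows, table, regions, flanks = 0L,
                        core_length = 36L) {
  if (length(regions) == 0L) abort("no regions given")
  if (any(lengths(regions) == 0L)) abort("empty region in `regions`")
  long <- hexamer_start_scores(windows, table, flanks = flanks,
                               core_length = core_length)
  map_dfr(names(regions), function(rn) {
    sub <- long[long$position %in% regions[[rn]], ]
    if (nrow(sub) == 0L) {
      abort(paste0("region '", rn, "' covers no scored positions"))
    }
    tibble(region = rn, mean_score = mean(sub$score),
           n_positions = nrow(sub),
           sem = sd(sub$score) / sqrt(nrow(sub)))
  })
}

#' Codon tokens contained in hexamers
#'
#' Every hexamer contributes its four length-3 substrings (offsets 0-3) as
#' codon tokens, so n hexamers yield exactly 4n tokens; this is the
#' counting convention behind the per-codon ESE/ESS frequency statistics
#' (e.g. 1182 enhancer hexamers give 4728 codon tokens).
#'
#' @param hexamers Character vector of 6-mers (U allowed, normalized to T).
#' @return Tibble with columns `codon`, `count`, one row per observed
#'   codon.
#' @export
#' @examples
#' codon_tokens_from_hexamers(c("GAAGAA", "AGAAGA"))
codon_tokens_from_hexamers <- function(hexamers) {
  hex <- norm_nt(hexamers)
  bad <- str_length(hex) != 6L | str_detect(hex, "[^ACGT]")
  if (any(bad)) {
    abort(paste0("non-hexamer input: ",
                 paste(unique(hexamers[bad]), collapse = ", ")))
  }
  tokens <- c(str_sub(hex, 1, 3), str_sub(hex, 2, 4),
              str_sub(hex, 3, 5), str_sub(hex, 4, 6))
  out <- as_tibble(table(codon = tokens))
  names(out) <- c("codon", "count")
  out$count <- as.integer(out$count)
  arrange(out, .data$codon)
}

#' Codon-level splicing table: ESEf/ESSf and ESEc/ESSc
#'
#' Tallies codon tokens in enhancer versus silencer hexamer sets and
#' derives, per codon, the log frequency ratio ln(ESEf/ESSf) and the count
#' ratio ESEc/ESSc.  A pseudocount guards zero counts:
#' `ln_ratio = ln[(e+pi)/(E+64 pi)] - ln[(s+pi)/(S+64 pi)]` where e, s are
#' the codon's token counts and E, S the totals.
#'
#' @param ese_hexamers,ess_hexamers Character vectors of hexamers.
#' @param pseudocount Pseudocount pi (default 0.5, Haldane); 0 is allowed
#'   when no zero counts exist.
#' @return A `codon_splicing_table`: tibble with 64 rows and columns
#'   `codon`, `ese_count`, `ess_count`, `ese_freq`, `ess_freq`,
#'   `ln_ratio`, `count_ratio`.
#' @export
build_codon_splicing_table <- function(ese_hexamers, ess_hexamers,
                                       pseudocount = 0.5) {
  if (length(ese_hexamers) == 0L || length(ess_hexamers) == 0L) {
    abort("both hexamer lists must be non-empty")
  }
  codons <- all_codons()
  fill_counts <- function(hexamers) {
    tok <- codon_tokens_from_hexamers(hexamers)
    cnt <- setNames(rep(0L, 64L), codons)
    cnt[tok$codon] <- tok$count
    cnt
  }
  e <- fill_counts(ese_hexamers)
  s <- fill_counts(ess_hexamers)
  p <- pseudocount
  ln_ratio <- log((e + p) / (sum(e) + 64 * p)) -
    log((s + p) / (sum(s) + 64 * p))
  out <- tibble(
    codon = codons,
    ese_count = unname(e),
    ess_count = unname(s),
    ese_freq = unname(e / sum(e)),
    ess_freq = unname(s / sum(s)),
    ln_ratio = unname(ln_ratio),
    count_ratio = unname((e + p) / (s + p))
  )
  class(out) <- c("codon_splicing_table", class(out))
  out
}

#' Control-exon background score
#'
#' Mean hexamer score over a control exon set with splice-site consensus
#' positions removed: the first nt and the last three nts of every exon
#' are trimmed (they shape the 3' and 5' splice-site consensus), then all
#' remaining hexamer start positions are pooled.  Exons shorter than 10 nt
#' leave no scorable hexamer after trimming and are skipped with a
#' warning.
#'
#' @param exons Character vector of exon CDS sequences (or tibble with a
#'   `seq` column).
#' @param table A `hexamer_table`.
#' @param weighting `"position"` pools all hexamer positions (default);
#'   `"exon"` averages per-exon means.
#' @return Tibble with columns `region` (`"CONTROL"`), `mean_score`,
#'   `n_positions`, `sem`, `n_exons`, `n_skipped`.
#' @export
control_exon_background <- function(exons, table,
                                    weighting = c("position", "exon")) {
  weighting <- match.arg(weighting)
  if (is.data.frame(exons)) exons <- exons$seq
  exons <- norm_nt(exons)
  len <- str_length(exons)
  short <- len < 10L
  if (any(short)) {
    warn(sprintf("skipping %d exon(s) shorter than 10 nt", sum(short)))
  }
  kept <- exons[!short]
  if (length(kept) == 0L) abort("no exon long enough to score")
  trimmed <- str_sub(kept, 2L, str_length(kept) - 3L)
  lookup <- setNames(table$score, table$hexamer)
  per_exon <- lapply(trimmed, function(s) {
    hex <- sliding_kmers(s, 6L)
    sc <- lookup[hex]
    if (anyNA(sc)) {
      abort(paste0("hexamer(s) absent from score table: ",
                   paste(unique(hex[is.na(sc)]), collapse = ", ")))
    }
    unname(sc)
  })
  pooled <- unlist(per_exon)
  mean_score <- if (weighting == "position") mean(pooled) else {
    mean(vapply(per_exon, mean, numeric(1)))
  }
  tibble(region = "CONTROL", mean_score = mean_score,
         n_positions = length(pooled),
         sem = sd(pooled) / sqrt(length(pooled)),
         n_exons = length(kept), n_skipped = sum(short))
}

#' Dinucleotide enrichment between hexamer sets
#'
#' Each hexamer contributes its five overlapping dinucleotides; the
#' log-odds for dinucleotide d is `ln(fESE(d) / fESS(d))` with a 0.5
#' pseudocount added to each of the 16 counts.  Positive values mark
#' dinucleotides overrepresented in the enhancer set (in published score
#' sets GA is strongly ESE-enriched, second only to CG).
#'
#' @param ese_hexamers,ess_hexamers Character vectors of hexamers.
#' @param pseudocount Pseudocount added to each dinucleotide count
#'   (default 0.5).
#' @return Tibble with columns `dinucleotide`, `ese_count`, `ess_count`,
#'   `log_odds`, 16 rows.
#' @export
dinucleotide_enrichment <- function(ese_hexamers, ess_hexamers,
                                    pseudocount = 0.5) {
  if (length(ese_hexamers) == 0L || length(ess_hexamers) == 0L) {
    abort("both hexamer lists must be non-empty")
  }
  dinucs <- sort(as.vector(outer(DNA_BASES, DNA_BASES, paste0)))
  count_dinucs <- function(hexamers) {
    hex <- norm_nt(hexamers)
    d <- sliding_kmers(hex, 2L)
    cnt <- setNames(rep(0L, 16L), dinucs)
    tab <- table(d)
    cnt[names(tab)] <- as.integer(tab)
    cnt
  }
  e <- count_dinucs(ese_hexamers)
  s <- count_dinucs(ess_hexamers)
  p <- pseudocount
  fe <- (e + p) / sum(e + p)
  fs <- (s + p) / sum(s + p)
  tibble(dinucleotide = dinucs, ese_count = unname(e),
         ess_count = unname(s), log_odds = unname(log(fe / fs)))
}

#' Compare score distributions between groups
#'
#' Standard two-sided group comparisons used for splicing-score contrasts:
#' pooled-variance two-sample t test, Wilcoxon-Mann-Whitney, or one-way
#' ANOVA for three or more groups.
#'
#' @param data Data frame with one value column and one group column.
#' @param value,group Column names (unquoted or character).
#' @param test One of `"t"`, `"mannwhitney"`, `"anova"`.
#' @return One-row tibble: `test`, `statistic`, `p_value`, `n_groups`,
#'   `n`.  Degenerate inputs (zero variance for the t test) return `NA`
#'   with a warning.
#' @export
#' @examples
#' df <- data.frame(v = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
#' compare_groups(df, v, g, test = "t")
compare_groups <- function(data, value, group,
                           test = c("t", "mannwhitney", "anova")) {
  test <- match.arg(test)
  v <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  if (nlevels(g) < 2L) abort("need at least 2 groups")
  if (any(table(g) < 2L)) abort("each group needs at least 2 values")
  res <- switch(test,
    t = {
      if (nlevels(g) != 2L) abort("t test needs exactly 2 groups")
      vs <- split(v, g)
      tryCatch(t.test(vs[[1]], vs[[2]], var.equal = TRUE),
               error = function(e) {
                 warn("degenerate variance; returning NA")
                 list(statistic = NA_real_, p.value = NA_real_)
               })
    },
    mannwhitney = {
      if (nlevels(g) != 2L) abort("Wilcoxon test needs exactly 2 groups")
      vs <- split(v, g)
      suppressWarnings(wilcox.test(vs[[1]], vs[[2]]))
    },
    anova = {
      fit <- aov(v ~ g)
      s <- summary(fit)[[1]]
      list(statistic = s[["F value"]][1], p.value = s[["Pr(>F)"]][1])
    }
  )
  stat <- unname(res$statistic %||% NA_real_)
  tibble(test = test, statistic = as.numeric(stat),
         p_value = as.numeric(res$p.value), n_groups = nlevels(g),
         n = length(v))
}
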