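#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of a codon is its observed count divided by the count expected if
#' all synonymous codons of its family were used equally:
#' `rscu(c) = count(c) / (family_total / family_size)`.  Families with zero
#' total get `NA`.
#'
#' @param counts Either a named numeric vector (names = codons) or a data
#'   frame with columns `codon` and `count`.  Codons absent from the input
#'   are counted as zero.
#' @param genetic_code Tibble mapping `codon` to `amino_acid` (default the
#'   standard code).
#' @return A `codon_usage_table`: tibble with columns `codon`,
#'   `amino_acid`, `count`, `per_1000`, `rscu` (64 rows).
#' @export
#' @examples
#' rscu(c(GAC = 3, GAT = 1))
rscu <- function(counts, genetic_code = genetic_code_table()) {
  if (is.data.frame(counts)) {
    counts <- setNames(counts$count, counts$codon)
  }
  names(counts) <- norm_nt(names(counts))
  unknown <- setdiff(names(counts), genetic_code$codon)
  if (length(unknown) > 0L) {
    abort(paste0("codon(s) not in genetic code: ",
                 paste(unknown, collapse = ", ")))
  }
  full <- setNames(rep(0, nrow(genetic_code)), genetic_code$codon)
  full[names(counts)] <- counts
  out <- genetic_code |>
    mutate(count = unname(full[.data$codon])) |>
    group_by(.data$amino_acid) |>
    mutate(rscu = if (sum(.data$count) > 0) {
      .data$count / (sum(.data$count) / n())
    } else {
      NA_real_
    }) |>
    ungroup() |>
    mutate(per_1000 = if (sum(.data$count) > 0) {
      1000 * .data$count / sum(.data$count)
    } else {
      NA_real_
    }) |>
    select("codon", "amino_acid", "count", "per_1000", "rscu")
  class(out) <- c("codon_usage_table", class(out))
  out
}

#' Codon usage per thousand codons
#'
#' @param counts Named numeric vector or data frame (`codon`, `count`).
#' @return Tibble with columns `codon`, `count`, `per_1000`;
#'   `per_1000` sums to 1000.
#' @export
per1000 <- function(counts) {
  if (is.data.frame(counts)) counts <- setNames(counts$count, counts$codon)
  if (sum(counts) <= 0) abort("total codon count must be positive")
  tibble(codon = norm_nt(names(counts)), count = unname(counts),
         per_1000 = unname(1000 * counts / sum(counts)))
}

# Split a CDS string into codons; errors on length not divisible by 3.
split_codons <- function(sequence) {
  sequence <- norm_nt(sequence)
  n <- str_length(sequence)
  if (n %% 3L != 0L) abort("CDS length must be divisible by 3")
  str_sub(sequence, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Relative adaptiveness w(c) = rscu(c) / max family rscu, from a reference
# codon_usage_table.
relative_adaptiveness <- function(reference) {
  reference |>
    group_by(.data$amino_acid) |>
    mutate(w = .data$rscu / max(.data$rscu)) |>
    ungroup()
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of relative adaptiveness values w of a sequence's
#' codons against a reference usage table, with `w(c) = rscu(c) / max
#' family rscu`.  Following the Sharp-Li convention, Met, Trp and stop
#' codons (single-codon families at the amino-acid level) are excluded
#' from the mean; `include_single_codon_families = TRUE` keeps them for
#' comparison with tools that differ on this point.
#'
#' @param sequence CDS string, length divisible by 3.
#' @param reference A `codon_usage_table` (from [rscu()]) giving reference
#'   usage.
#' @param include_single_codon_families Keep Met/Trp/stop codons in the
#'   geometric mean (default `FALSE`).
#' @return CAI in (0, 1].
#' @export
#' @examples
#' ref <- rscu(c(GAC = 3, GAT = 1, AAA = 1, AAG = 1))
#' cai("GACAAA", ref)
cai <- function(sequence, reference,
                include_single_codon_families = FALSE) {
  codons <- split_codons(sequence)
  wtab <- relative_adaptiveness(reference)
  w <- setNames(wtab$w, wtab$codon)
  aa <- setNames(wtab$amino_acid, wtab$codon)
  use <- codons
  if (!include_single_codon_families) {
    use <- use[!aa[use] %in% c("M", "W", "*")]
  }
  if (length(use) == 0L) abort("no codons left after exclusions")
  wv <- w[use]
  if (anyNA(wv)) {
    abort(paste0("reference RSCU undefined for family of codon(s): ",
                 paste(unique(use[is.na(wv)]), collapse = ", ")))
  }
  if (any(wv == 0)) {
    # a codon never seen in the reference would zero the geometric mean;
    # floor at a small positive w as CAI implementations commonly do
    wv[wv == 0] <- 0.01
  }
  exp(mean(log(wv)))
}

# GC count (0..3) of each codon, as a named vector over the given codons.
codon_gc <- function(codons) {
  setNames(str_count(codons, "[GC]"), codons)
}

#' Expected CAI under a GC- and amino-acid-matched null
#'
#' Generates random synonymous re-encodings of the query that preserve its
#' amino-acid *sequence* and match its GC content in expectation, then
#' reports the null mean/sd of CAI and the fraction of random sequences
#' with CAI at least as high as the query's.  Within each synonymous
#' family, codon c is sampled with weight `exp(alpha * gc(c))`; the single
#' GC-affinity parameter alpha is tuned by bisection until the sampler's
#' expected GC matches the query GC to within `gc_tol` (when attainable by
#' synonymous changes alone).
#'
#' @param sequence CDS string.
#' @param reference A `codon_usage_table` for CAI scoring.
#' @param n_random Number of random re-encodings (>= 2).
#' @param seed Optional integer seed for reproducibility.
#' @param gc_tol Relative GC matching tolerance (default 0.001).
#' @return One-row tibble: `cai_query`, `null_mean`, `null_sd`,
#'   `p_greater`, `gc_query`, `gc_null`, `n_random`.
#' @export
expected_cai <- function(sequence, reference, n_random = 500L, seed = NULL,
                         gc_tol = 0.001) {
  if (n_random < 2L) abort("n_random must be >= 2")
  if (!is.null(seed)) set.seed(as.integer(seed))
  codons <- split_codons(sequence)
  code <- genetic_code_table()
  aa_of <- setNames(code$amino_acid, code$codon)
  fam <- split(code$codon, code$amino_acid)
  aa_seq <- aa_of[codons]
  gc_query <- mean(unlist(strsplit(norm_nt(sequence), "")) %in% c("G", "C"))
  n_nt <- str_length(sequence)

  # expected GC fraction of the re-encoded sequence for affinity alpha
  exp_gc <- function(alpha) {
    per_pos <- vapply(aa_seq, function(a) {
      cs <- fam[[a]]
      g <- codon_gc(cs)
      wgt <- exp(alpha * g)
      sum(wgt * g) / sum(wgt)
    }, numeric(1))
    sum(per_pos) / n_nt
  }
  lo <- -30; hi <- 30
  alpha <- 0
  if (exp_gc(lo) > gc_query) {
    alpha <- lo
  } else if (exp_gc(hi) < gc_query) {
    alpha <- hi
  } else {
    for (i in 1:60) {
      alpha <- (lo + hi) / 2
      if (abs(exp_gc(alpha) - gc_query) < gc_tol * max(gc_query, 1e-9)) break
      if (exp_gc(alpha) < gc_query) lo <- alpha else hi <- alpha
    }
  }

  # per-position sampling weights under the tuned alpha
  pos_choices <- lapply(aa_seq, function(a) {
    cs <- fam[[a]]
    g <- codon_gc(cs)
    wgt <- exp(alpha * g)
    list(codons = cs, prob = wgt / sum(wgt))
  })
  cai_null <- vapply(seq_len(n_random), function(i) {
    enc <- vapply(pos_choices, function(pc) {
      if (length(pc$codons) == 1L) pc$codons else {
        sample(pc$codons, 1L, prob = pc$prob)
      }
    }, character(1))
    cai(paste(enc, collapse = ""), reference)
  }, numeric(1))
  cai_q <- cai(sequence, reference)
  tibble(cai_query = cai_q, null_mean = mean(cai_null),
         null_sd = sd(cai_null),
         p_greater = mean(cai_null >= cai_q),
         gc_query = gc_query, gc_null = exp_gc(alpha),
         n_random = as.integer(n_random))
}

#' Exact binomial test for a two-codon usage contrast
#'
#' Tests observed usage of one codon against its synonymous partner (k of
#' n) against a reference fraction p, using the exact two-sided binomial
#' test (summing point probabilities not exceeding that of the observed
#' count).
#'
#' @param k Observed count of the focal codon.
#' @param n Total count of the two-codon family.
#' @param p Reference fraction of the focal codon, in (0, 1).
#' @return One-row tibble: `k`, `n`, `observed_fraction`, `reference_p`,
#'   `p_value`, `significant` (at P < 0.01).
#' @export
#' @examples
#' usage_bias_test(184, 294, 0.54)
usage_bias_test <- function(k, n, p) {
  if (n < 1L) abort("n must be >= 1")
  if (p <= 0 || p >= 1) abort("reference fraction must be in (0, 1)")
  pv <- binom.test(k, n, p)$p.value
  tibble(k = as.integer(k), n = as.integer(n),
         observed_fraction = k / n, reference_p = p, p_value = pv,
         significant = pv < 0.01)
}

#' Fragile versus robust codon classification
#'
#' A sense codon is FRAGILE if any of its nine single-nucleotide
#' neighbours is a stop codon (TAA, TAG, TGA in the standard code) and
#' ROBUST if converting it to a stop requires at least two point
#' mutations.
#'
#' @param codon A sense codon (vectorized).
#' @param genetic_code Tibble mapping `codon` to `amino_acid`.
#' @return Character vector of `"FRAGILE"` / `"ROBUST"`.
#' @export
#' @examples
#' codon_fragility(c("GAA", "GAC"))
codon_fragility <- function(codon, genetic_code = genetic_code_table()) {
  codon <- norm_nt(codon)
  aa_of <- setNames(genetic_code$amino_acid, genetic_code$codon)
  unknown <- setdiff(codon, names(aa_of))
  if (length(unknown) > 0L) {
    abort(paste0("not a codon: ", paste(unknown, collapse = ", ")))
  }
  if (any(aa_of[codon] == "*")) {
    abort("stop codons are neither fragile nor robust")
  }
  stops <- genetic_code$codon[genetic_code$amino_acid == "*"]
  vapply(codon, function(cd) {
    chars <- strsplit(cd, "")[[1]]
    for (pos in 1:3) {
      for (b in setdiff(DNA_BASES, chars[pos])) {
        nb <- chars
        nb[pos] <- b
        if (paste(nb, collapse = "") %in% stops) return("FRAGILE")
      }
    }
    "ROBUST"
  }, character(1), USE.NAMES = FALSE)
}

#' Correlate two per-codon vectors over a codon subset
#'
#' Pearson correlation between two codon-indexed statistics (e.g. the
#' ln(ESEf/ESSf) splicing ratio versus a codon-usage contrast between
#' gene sets) restricted to a subset of codons.
#'
#' @param x,y Named numeric vectors indexed by codon, or data frames with
#'   `codon` plus one value column.
#' @param subset Character vector of codons to use (>= 3); default the
#'   intersection of names.
#' @return One-row tibble: `r`, `p_value`, `n`.  Zero variance yields
#'   `NA`.
#' @export
correlate_codon_vectors <- function(x, y, subset = NULL) {
  as_named <- function(v) {
    if (is.data.frame(v)) {
      val_col <- setdiff(names(v), "codon")[1]
      setNames(v[[val_col]], v$codon)
    } else {
      v
    }
  }
  x <- as_named(x); y <- as_named(y)
  subset <- subset %||% intersect(names(x), names(y))
  if (length(subset) < 3L) abort("subset must contain at least 3 codons")
  xv <- x[subset]; yv <- y[subset]
  if (anyNA(xv) || anyNA(yv)) abort("undefined values over the subset")
  if (sd(xv) == 0 || sd(yv) == 0) {
    warn("zero variance; correlation undefined")
    return(tibble(r = NA_real_, p_value = NA_real_, n = length(subset)))
  }
  ct <- cor.test(xv, yv, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value,
         n = length(subset))
}
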