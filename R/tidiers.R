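#' Tidy an enrichment result
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return The result as a plain tibble, one row per test.
#' @export
tidy.enrichment_result <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "null_values") <- NULL
  class(out) <- class(tibble())
  out
}

#' Summarise an enrichment result
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return One-row tibble with `fold`, `p_empirical` and `n_sims`.
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(fold = x$fold, p_empirical = x$p_empirical, n_sims = x$n_sims)
}

#' Tidy an enrichment sweep
#'
#' @param x An `enrichment_run` from [enrichment_sweep()].
#' @param ... Unused.
#' @return Plain tibble, one row per sample x pad.
#' @export
tidy.enrichment_run <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' Summarise a pipeline report
#'
#' @param x A `splice_report` from [run_pipeline()].
#' @param ... Unused.
#' @return One-row tibble with headline numbers: motif count, within-loop
#'   split fraction and its binomial p, loop-codon-1 GAC fraction, CAI
#'   versus expected CAI, and the minimum enrichment q-value.
#' @export
glance.splice_report <- function(x, ...) {
  gac <- x$usage_bias
  tibble(
    n_motifs = nrow(x$data$motifs),
    n_splits = x$split_enrichment$n_splits %||% 0L,
    within_loop_fraction = x$split_enrichment$within_fraction %||%
      NA_real_,
    split_binomial_p = x$split_enrichment$binomial_p %||% NA_real_,
    gac_fraction_codon1 = gac$observed_fraction,
    cai_loops = x$cai$cai_query,
    expected_cai = x$cai$null_mean,
    min_enrichment_q = min(x$enrichment$q)
  )
}
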