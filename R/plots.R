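#' Plot a positional splicing-score profile
#'
#' Mean hexamer score per position (columns), with positions whose
#' starting hexamer is never ESS-labelled marked along the baseline.  The
#' loop core starts at position 1.
#'
#' @param object A `splice_profile` from [positional_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.splice_profile <- function(object, ...) {
  df <- as_tibble(object)
  core_len <- attr(object, "core_length") %||% max(df$position)
  ggplot(df, aes(x = .data$position, y = .data$mean_score)) +
    geom_col(fill = "grey35") +
    geom_point(data = df[df$ess_start_count == 0L, ],
               aes(y = min(df$mean_score) - 0.05 * diff(range(df$mean_score))),
               shape = 15, colour = "grey70", size = 1) +
    geom_vline(xintercept = c(0.5, core_len + 0.5), linetype = "dotted") +
    labs(x = "position (nt, loop start = 1)",
         y = "mean hexamer splicing score") +
    theme_minimal()
}

#' Plot an enrichment null distribution
#'
#' Histogram of the simulated null statistic with the observed value
#' marked.
#'
#' @param object An `enrichment_result` from [enrichment_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  null_values <- attr(object, "null_values")
  if (is.null(null_values)) abort("result carries no null distribution")
  ggplot(tibble(null = null_values), aes(x = .data$null)) +
    geom_histogram(bins = 40, fill = "grey60") +
    geom_vline(xintercept = object$observed, colour = "red") +
    labs(x = paste0("null ", object$statistic[1]), y = "simulations",
         title = sprintf("observed = %.4g, fold = %.2f, p = %.3g",
                         object$observed, object$fold,
                         object$p_empirical)) +
    theme_minimal()
}

#' Plot codon-level splicing ratios
#'
#' ln(ESEf/ESSf) per codon, ordered by value.
#'
#' @param object A `codon_splicing_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.codon_splicing_table <- function(object, ...) {
  df <- as_tibble(object) |>
    arrange(.data$ln_ratio) |>
    mutate(codon = factor(.data$codon, levels = .data$codon))
  ggplot(df, aes(x = .data$codon, y = .data$ln_ratio)) +
    geom_col(fill = "grey35") +
    geom_hline(yintercept = 0) +
    labs(x = NULL, y = "ln(ESEf/ESSf)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Plot within-loop split positions
#'
#' Histogram of intron insertion positions in loop-relative coordinates.
#'
#' @param events Split events from [map_splits()].
#' @param loop_len Loop length in nt.
#' @return A ggplot object.
#' @export
plot_split_positions <- function(events, loop_len = 36L) {
  df <- count(events, .data$loop_relative_position)
  ggplot(df, aes(x = .data$loop_relative_position, y = .data$n)) +
    geom_col(fill = "grey35") +
    geom_vline(xintercept = c(0.5, loop_len + 0.5), linetype = "dotted") +
    labs(x = "loop-relative split position (nt)", y = "splits") +
    theme_minimal()
}
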