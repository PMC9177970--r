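#' Merge overlapping or book-ended intervals
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return Merged, sorted tibble with columns `chrom`, `start`, `end`.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) {
    return(tibble(chrom = character(0), start = integer(0),
                  end = integer(0)))
  }
  x <- arrange(intervals, .data$chrom, .data$start, .data$end)
  out_chrom <- character(0); out_start <- integer(0); out_end <- integer(0)
  cur_chrom <- x$chrom[1]; cur_start <- x$start[1]; cur_end <- x$end[1]
  if (nrow(x) > 1L) {
    for (i in 2:nrow(x)) {
      if (x$chrom[i] == cur_chrom && x$start[i] <= cur_end) {
        cur_end <- max(cur_end, x$end[i])
      } else {
        out_chrom <- c(out_chrom, cur_chrom)
        out_start <- c(out_start, cur_start)
        out_end <- c(out_end, cur_end)
        cur_chrom <- x$chrom[i]; cur_start <- x$start[i]; cur_end <- x$end[i]
      }
    }
  }
  tibble(chrom = c(out_chrom, cur_chrom),
         start = as.integer(c(out_start, cur_start)),
         end = as.integer(c(out_end, cur_end)))
}

# Intersect two merged interval sets (per chromosome sweep).
intersect_intervals <- function(a, b) {
  a <- merge_intervals(a); b <- merge_intervals(b)
  out <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- a[a$chrom == ch, ]; bi <- b[b$chrom == ch, ]
    for (i in seq_len(nrow(ai))) {
      s <- pmax(ai$start[i], bi$start); e <- pmin(ai$end[i], bi$end)
      keep <- s < e
      if (any(keep)) {
        out[[length(out) + 1L]] <- tibble(chrom = ch, start = s[keep],
                                          end = e[keep])
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(chrom = character(0), start = integer(0),
                  end = integer(0)))
  }
  sort_intervals(bind_rows(out))
}

# Map intervals (already clipped to the merged workspace) onto the
# flattened axis in which workspace intervals are laid end to end.
virtualize_intervals <- function(intervals, ws, cs_ws) {
  if (nrow(intervals) == 0L) {
    return(tibble(start = numeric(0), end = numeric(0)))
  }
  vstart <- numeric(nrow(intervals)); vend <- numeric(nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    j <- which(ws$chrom == intervals$chrom[i] &
                 ws$start <= intervals$start[i] &
                 ws$end >= intervals$end[i])[1]
    if (is.na(j)) abort("interval not contained in a workspace interval")
    vstart[i] <- cs_ws[j] + (intervals$start[i] - ws$start[j])
    vend[i] <- vstart[i] + (intervals$end[i] - intervals$start[i])
  }
  out <- tibble(start = vstart, end = vend)
  out[order(out$start), ]
}

# Prefix-sum coverage index over a merged interval set: for each
# chromosome, F(x) = total covered nt at coordinates < x, computable in
# O(log m) per query via findInterval.
coverage_index <- function(merged) {
  lapply(split(merged, merged$chrom), function(m) {
    m <- arrange(m, .data$start)
    w <- m$end - m$start
    list(starts = m$start, ends = m$end, cumw = c(0, cumsum(w)))
  })
}

coverage_before <- function(chrom_idx, x) {
  idx <- findInterval(x, chrom_idx$starts)
  out <- numeric(length(x))
  pos <- idx > 0L
  if (any(pos)) {
    i <- idx[pos]
    out[pos] <- chrom_idx$cumw[i] +
      pmin(pmax(x[pos] - chrom_idx$starts[i], 0),
           chrom_idx$ends[i] - chrom_idx$starts[i])
  }
  out
}

# Per-segment overlap (nt) with a merged annotation set.
segment_overlaps <- function(segments, index) {
  ov <- numeric(nrow(segments))
  for (ch in unique(segments$chrom)) {
    ci <- index[[ch]]
    sel <- segments$chrom == ch
    if (is.null(ci)) next
    ov[sel] <- coverage_before(ci, segments$end[sel]) -
      coverage_before(ci, segments$start[sel])
  }
  ov
}

#' Observed overlap statistic between segments and annotations
#'
#' `nt_overlap` is the total number of overlapping nucleotides summed over
#' segments (annotations are merged first, so double-covered annotation
#' nt are not double counted per segment); `segment_hits` is the number
#' of segments intersecting at least one annotation.
#'
#' @param segments,annotations Interval tibbles (`chrom`, `start`, `end`;
#'   0-based half-open).
#' @param statistic `"nt_overlap"` (default) or `"segment_hits"`.
#' @return A single number.
#' @export
#' @examples
#' seg <- tibble::tibble(chrom = "c", start = 10L, end = 20L)
#' ann <- tibble::tibble(chrom = "c", start = 15L, end = 30L)
#' observed_overlap(seg, ann)
observed_overlap <- function(segments, annotations,
                             statistic = c("nt_overlap", "segment_hits")) {
  statistic <- match.arg(statistic)
  if (nrow(segments) == 0L || nrow(annotations) == 0L) return(0)
  index <- coverage_index(merge_intervals(annotations))
  ov <- segment_overlaps(segments, index)
  if (statistic == "nt_overlap") sum(ov) else sum(ov > 0)
}

# Workspace sampler: precomputes, per distinct segment length, the valid
# start positions across merged workspace intervals.
workspace_sampler <- function(workspace, lengths) {
  ws <- merge_intervals(workspace)
  w <- ws$end - ws$start
  samplers <- lapply(unique(lengths), function(L) {
    valid <- pmax(0, w - L + 1)
    total <- sum(valid)
    if (total <= 0) {
      abort(sprintf("segment of length %d exceeds every workspace interval",
                    L))
    }
    list(L = L, cs = c(0, cumsum(valid)), total = total)
  })
  names(samplers) <- as.character(unique(lengths))
  list(ws = ws, samplers = samplers)
}

draw_placements <- function(sampler, lengths) {
  ws <- sampler$ws
  n <- length(lengths)
  chrom <- character(n); start <- numeric(n)
  for (Lc in names(sampler$samplers)) {
    sp <- sampler$samplers[[Lc]]
    sel <- which(lengths == sp$L)
    if (length(sel) == 0L) next
    r <- sample.int(sp$total, length(sel), replace = TRUE)
    j <- findInterval(r - 1, sp$cs)
    offset <- r - 1 - sp$cs[j]
    chrom[sel] <- ws$chrom[j]
    start[sel] <- ws$start[j] + offset
  }
  tibble(chrom = chrom, start = as.integer(start),
         end = as.integer(start + lengths))
}

#' Randomly re-place segments within a workspace
#'
#' Each segment is placed independently and uniformly over all start
#' positions at which it fits fully inside one workspace interval;
#' segment lengths are preserved and placements may overlap each other.
#'
#' @param segments Interval tibble; only the lengths are used.
#' @param workspace Interval tibble defining the universe for placement.
#' @param seed Optional integer seed.
#' @return Tibble of placed segments (`chrom`, `start`, `end`).
#' @export
randomize_segments <- function(segments, workspace, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  lengths <- segments$end - segments$start
  sampler <- workspace_sampler(workspace, lengths)
  draw_placements(sampler, lengths)
}

#' Randomization test for interval enrichment
#'
#' Compares the observed overlap of segments (e.g. CLIP peaks) with an
#' annotation set (e.g. motif-coding exonic intervals) against a null
#' distribution obtained by re-placing the segments uniformly within a
#' workspace (e.g. the transcribed regions).  The empirical p-value uses
#' add-one smoothing and is one-sided for enrichment by default:
#' `p = (1 + #\{sim >= observed\}) / (n_sims + 1)`.
#'
#' @param segments,annotations,workspace Interval tibbles.
#' @param n_sims Number of randomizations (>= 100).
#' @param seed Optional integer seed.
#' @param statistic `"nt_overlap"` (default) or `"segment_hits"`.
#' @param alternative `"enrichment"` (default) or `"depletion"`.
#' @param sample_id Label carried into the result.
#' @return An `enrichment_result`: one-row tibble with `sample_id`,
#'   `statistic`, `observed`, `null_mean`, `null_sd`, `fold`,
#'   `p_empirical`, `n_sims`; the simulated null values are attached as
#'   attribute `"null_values"`.
#' @export
enrichment_test <- function(segments, annotations, workspace,
                            n_sims = 10000L, seed = NULL,
                            statistic = c("nt_overlap", "segment_hits"),
                            alternative = c("enrichment", "depletion"),
                            sample_id = "sample") {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  if (n_sims < 100L) abort("n_sims must be >= 100")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (nrow(segments) == 0L || nrow(annotations) == 0L) {
    warn("empty segments or annotations; degenerate result")
    out <- tibble(sample_id = sample_id, statistic = statistic,
                  observed = 0, null_mean = 0, null_sd = 0, fold = NA_real_,
                  p_empirical = 1, n_sims = as.integer(n_sims))
    class(out) <- c("enrichment_result", class(out))
    return(out)
  }
  ann <- merge_intervals(annotations)
  index <- coverage_index(ann)
  ov_obs <- segment_overlaps(segments, index)
  observed <- if (statistic == "nt_overlap") sum(ov_obs) else sum(ov_obs > 0)
  lengths <- segments$end - segments$start

  # simulate on a single flattened axis: workspace intervals are laid end
  # to end, so placements and annotation overlap become pure arithmetic
  ws <- merge_intervals(workspace)
  w <- ws$end - ws$start
  cs_ws <- c(0, cumsum(w))
  ann_ws <- intersect_intervals(ann, ws)
  vann <- virtualize_intervals(ann_ws, ws, cs_ws)
  vstarts <- vann$start
  vcumw <- c(0, cumsum(vann$end - vann$start))
  vends <- vann$end
  cov_before <- function(x) {
    idx <- findInterval(x, vstarts)
    out <- numeric(length(x))
    pos <- idx > 0L
    if (any(pos)) {
      i <- idx[pos]
      out[pos] <- vcumw[i] + pmin(pmax(x[pos] - vstarts[i], 0),
                                  vends[i] - vstarts[i])
    }
    out
  }
  len_groups <- split(seq_along(lengths), lengths)
  samplers <- lapply(as.integer(names(len_groups)), function(L) {
    valid <- pmax(0, w - L + 1)
    if (sum(valid) <= 0) {
      abort(sprintf("segment of length %d exceeds every workspace interval",
                    L))
    }
    list(L = L, cs_valid = c(0, cumsum(valid)), total = sum(valid),
         n = length(len_groups[[as.character(L)]]))
  })
  null_values <- vapply(seq_len(n_sims), function(s) {
    total <- 0
    for (sp in samplers) {
      r <- sample.int(sp$total, sp$n, replace = TRUE)
      j <- findInterval(r - 1, sp$cs_valid)
      v <- cs_ws[j] + (r - 1 - sp$cs_valid[j])
      ov <- cov_before(v + sp$L) - cov_before(v)
      total <- total + if (statistic == "nt_overlap") sum(ov) else sum(ov > 0)
    }
    total
  }, numeric(1))
  null_mean <- mean(null_values)
  extreme <- if (alternative == "enrichment") {
    sum(null_values >= observed)
  } else {
    sum(null_values <= observed)
  }
  p_emp <- (1 + extreme) / (n_sims + 1)
  fold <- if (null_mean > 0) observed / null_mean else {
    inform("null mean is 0; fold computed with add-one smoothing")
    (observed + 1) / (null_mean + 1)
  }
  out <- tibble(sample_id = sample_id, statistic = statistic,
                observed = observed, null_mean = null_mean,
                null_sd = sd(null_values), fold = fold,
                p_empirical = p_emp, n_sims = as.integer(n_sims))
  attr(out, "null_values") <- null_values
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Pad annotation intervals
#'
#' Extends every interval by `pad` nt on both sides, clips to the
#' workspace (or to coordinate 0 when no workspace is given) and merges
#' the result.  Used to sweep padding around the first and last codons of
#' motif annotations (e.g. 3, 6 and 9 nt).
#'
#' @param annotations Interval tibble.
#' @param pad Non-negative padding in nt.
#' @param workspace Optional interval tibble to clip against.
#' @return Merged padded interval tibble.
#' @export
pad_annotations <- function(annotations, pad, workspace = NULL) {
  if (pad < 0) abort("pad must be >= 0")
  padded <- mutate(annotations,
                   start = pmax(0L, .data$start - as.integer(pad)),
                   end = .data$end + as.integer(pad))
  if (!is.null(workspace)) {
    intersect_intervals(padded, workspace)
  } else {
    merge_intervals(padded)
  }
}

#' Benjamini-Hochberg correction
#'
#' Step-up BH adjustment with monotonicity enforcement, plus the
#' customary q < 0.01 significance flag.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param alpha Significance threshold on q (default 0.01).
#' @return Tibble with columns `p`, `q`, `significant`.
#' @export
#' @examples
#' bh_correct(c(0.01, 0.02, 0.03, 0.04))
bh_correct <- function(p, alpha = 0.01) {
  if (any(p <= 0 | p > 1)) abort("p-values must be in (0, 1]")
  q <- p.adjust(p, method = "BH")
  tibble(p = p, q = q, significant = q < alpha)
}

#' Enrichment sweep over samples and paddings
#'
#' Runs [enrichment_test()] for every peak sample and every padding
#' value, then applies Benjamini-Hochberg correction across all tests.
#'
#' @param segments Interval tibble with an optional `sample_id` column
#'   (single sample assumed when absent).
#' @param annotations,workspace Interval tibbles.
#' @param pads Integer vector of paddings (default `c(0, 3, 6, 9)`).
#' @param n_sims,seed,statistic Passed to [enrichment_test()].
#' @return An `enrichment_run` tibble: one row per sample x pad with the
#'   `enrichment_result` columns plus `pad`, `q` and `significant`.
#' @export
enrichment_sweep <- function(segments, annotations, workspace,
                             pads = c(0L, 3L, 6L, 9L), n_sims = 10000L,
                             seed = NULL,
                             statistic = c("nt_overlap", "segment_hits")) {
  statistic <- match.arg(statistic)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (!"sample_id" %in% names(segments)) segments$sample_id <- "sample"
  by_sample <- split(segments, segments$sample_id)
  rows <- map_dfr(names(by_sample), function(sid) {
    map_dfr(pads, function(pd) {
      ann <- pad_annotations(annotations, pd, workspace = workspace)
      res <- enrichment_test(by_sample[[sid]], ann, workspace,
                             n_sims = n_sims, statistic = statistic,
                             sample_id = sid)
      mutate(as_tibble(res), pad = as.integer(pd))
    })
  })
  adj <- bh_correct(rows$p_empirical)
  out <- mutate(rows, q = adj$q, significant = adj$significant)
  class(out) <- c("enrichment_run", class(out))
  out
}
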