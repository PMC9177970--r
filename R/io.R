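#' Read a FASTA file into a tibble
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that returns a tibble
#' and applies the package's sequence conventions: sequences are uppercased
#' and, in nucleotide mode, U is normalized to T so that all downstream
#' sequence logic runs on the DNA alphabet.  Protein mode leaves letters
#' untouched apart from case.
#'
#' @param path Path to a FASTA file.
#' @param mode `"nt"` for nucleotide records (U normalized to T) or
#'   `"protein"`.
#' @return Tibble with columns `id` (first whitespace-delimited token of the
#'   header) and `seq`, in file order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", "GAUGAC"), f)
#' read_fasta(f, mode = "nt")
read_fasta <- function(path, mode = c("nt", "protein")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(paste0("no records in FASTA file: ", path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs <- str_to_upper(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    abort(paste0("empty sequence for record(s): ",
                 paste(ids[empty], collapse = ", ")))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate FASTA id(s): ", paste(dup, collapse = ", ")))
  }
  if (mode == "nt") seqs <- norm_nt(seqs)
  tibble(id = ids, seq = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param seqs Tibble with columns `id` and `seq`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  lines <- as.vector(rbind(paste0(">", seqs$id), seqs$seq))
  writeLines(lines, path)
  invisible(path)
}

#' Read a hexamer splicing-score table
#'
#' Reads a TSV with columns `hexamer`, `score` and `label` describing a set
#' of 6-mers with experimentally derived splicing scores (higher score =
#' stronger predicted exon inclusion) and an ESE/ESS/NEUTRAL class label.
#' Hexamers are normalized to the DNA alphabet (U to T) and validated:
#' every key must have length 6 over \{A,C,G,T\}, keys must be unique, and
#' labels must come from the three-value set.  The ESE and ESS class sizes
#' are reported via a message, mirroring the bookkeeping one does when
#' loading a published score set.
#'
#' @param path Path to the TSV.
#' @param quiet Suppress the class-count message.
#' @return A `hexamer_table`: tibble with columns `hexamer`, `score`,
#'   `label`, sorted by hexamer.
#' @export
read_hexamer_table <- function(path, quiet = FALSE) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("hexamer", "score", "label")
  if (!all(need %in% names(df))) {
    abort(paste0("hexamer table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  hexamer_table(df$hexamer, df$score, df$label, quiet = quiet)
}

#' Construct and validate a hexamer table
#'
#' @param hexamer Character vector of 6-mers (RNA or DNA alphabet).
#' @param score Numeric splicing scores; higher predicts stronger exon
#'   inclusion.
#' @param label Class labels, each one of `"ESE"`, `"ESS"`, `"NEUTRAL"`.
#' @param quiet Suppress the class-count message.
#' @return Tibble of class `hexamer_table` sorted by hexamer.
#' @export
#' @examples
#' hexamer_table(c("GAUGAC", "CCCCCC"), c(1.2, -0.8), c("ESE", "ESS"))
hexamer_table <- function(hexamer, score, label, quiet = TRUE) {
  hex <- norm_nt(hexamer)
  bad <- str_length(hex) != 6L | str_detect(hex, "[^ACGT]")
  if (any(bad)) {
    abort(paste0("invalid hexamer(s): ",
                 paste(unique(hexamer[bad]), collapse = ", ")))
  }
  dup <- unique(hex[duplicated(hex)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate hexamer(s): ", paste(dup, collapse = ", ")))
  }
  if (!all(label %in% c("ESE", "ESS", "NEUTRAL"))) {
    abort("labels must be ESE, ESS or NEUTRAL")
  }
  out <- tibble(hexamer = hex, score = as.numeric(score),
                label = as.character(label)) |>
    arrange(.data$hexamer)
  if (!quiet) {
    inform(sprintf("hexamer table: %d ESE, %d ESS, %d NEUTRAL",
                   sum(out$label == "ESE"), sum(out$label == "ESS"),
                   sum(out$label == "NEUTRAL")))
  }
  class(out) <- c("hexamer_table", class(out))
  out
}

#' Read a BED interval file
#'
#' Reads BED3+ (0-based half-open).  Columns beyond the first six are
#' ignored; `name` and `score` are filled with defaults when absent.
#'
#' @param path Path to a BED file.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `score`.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE, comment = "#")
  if (ncol(df) < 3L) abort("BED file needs at least 3 columns")
  out <- tibble(
    chrom = as.character(df[[1]]),
    start = as.integer(df[[2]]),
    end = as.integer(df[[3]]),
    name = if (ncol(df) >= 4L) as.character(df[[4]]) else ".",
    score = if (ncol(df) >= 5L) suppressWarnings(as.numeric(df[[5]])) else 0
  )
  out$score[is.na(out$score)] <- 0
  bad <- which(out$start < 0L | out$start >= out$end)
  if (length(bad) > 0L) {
    abort(paste0("invalid BED interval(s) at line(s): ",
                 paste(bad, collapse = ", "),
                 " (need 0 <= start < end)"))
  }
  out
}

#' Write intervals to BED
#'
#' Writes `chrom`, `start`, `end`, `name`, `score` as tab-separated BED.
#' For input already sorted by (chrom, start, end) the read/write pair
#' round-trips byte-identically.
#'
#' @param intervals Tibble with at least `chrom`, `start`, `end`; `name`
#'   and `score` default to `"."` and 0.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  name <- intervals$name %||% rep(".", nrow(intervals))
  score <- intervals$score %||% rep(0, nrow(intervals))
  lines <- paste(intervals$chrom, format(intervals$start, scientific = FALSE,
                                         trim = TRUE),
                 format(intervals$end, scientific = FALSE, trim = TRUE),
                 name, format(score, scientific = FALSE, trim = TRUE),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Sort intervals
#'
#' @param intervals Interval tibble as from [read_bed()].
#' @return The tibble sorted by (chrom, start, end).
#' @export
sort_intervals <- function(intervals) {
  arrange(intervals, .data$chrom, .data$start, .data$end)
}

#' Read gene models in CDS coordinates
#'
#' Reads a TSV with columns `gene_id`, `exon_index`, `cds_start`, `cds_end`
#' and optionally `donor_dinuc` (the first two nucleotides of the intron
#' following each exon).  Exons must tile the CDS contiguously: exon k+1
#' starts at exon k's end + 1.  Coordinates are 1-based inclusive.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `gene_id`, `exon_index`, `cds_start`,
#'   `cds_end`, `donor_dinuc` (NA where absent), validated per gene.
#' @export
read_gene_models <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene_id", "exon_index", "cds_start", "cds_end")
  if (!all(need %in% names(df))) {
    abort(paste0("gene model table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  if (!"donor_dinuc" %in% names(df)) df$donor_dinuc <- NA_character_
  out <- tibble(
    gene_id = as.character(df$gene_id),
    exon_index = as.integer(df$exon_index),
    cds_start = as.integer(df$cds_start),
    cds_end = as.integer(df$cds_end),
    donor_dinuc = as.character(df$donor_dinuc)
  ) |> arrange(.data$gene_id, .data$exon_index)
  validate_gene_models(out)
  out
}

# Enforce per-gene exon contiguity in CDS space.
validate_gene_models <- function(models) {
  split_models <- split(models, models$gene_id)
  for (g in names(split_models)) {
    m <- split_models[[g]]
    if (any(m$cds_start > m$cds_end)) {
      abort(paste0("gene ", g, ": exon with start > end"))
    }
    if (nrow(m) > 1L) {
      gaps <- m$cds_start[-1L] != m$cds_end[-nrow(m)] + 1L
      if (any(gaps)) {
        abort(paste0("gene ", g,
                     ": exons are not contiguous in CDS coordinates"))
      }
    }
  }
  invisible(models)
}

#' Intron insertion points of gene models
#'
#' An intron insertion point is an exon boundary interior to the CDS: the
#' intron falls between CDS nucleotide `cds_insertion_point` and
#' `cds_insertion_point + 1`.
#'
#' @param models Gene model tibble as from [read_gene_models()].
#' @return Tibble with columns `gene_id`, `cds_insertion_point`,
#'   `donor_dinuc` — one row per intron.
#' @export
#' @examples
#' m <- tibble::tibble(gene_id = "g", exon_index = 1:2,
#'                     cds_start = c(1L, 101L), cds_end = c(100L, 250L),
#'                     donor_dinuc = c("GT", NA))
#' intron_insertion_points(m)
intron_insertion_points <- function(models) {
  models |>
    arrange(.data$gene_id, .data$exon_index) |>
    group_by(.data$gene_id) |>
    filter(row_number() < n()) |>
    ungroup() |>
    transmute_insertion()
}

transmute_insertion <- function(df) {
  tibble(gene_id = df$gene_id,
         cds_insertion_point = df$cds_end,
         donor_dinuc = df$donor_dinuc)
}

#' Read a flat key-value configuration file
#'
#' Reads a flat YAML mapping used to configure simulations and pipeline
#' runs; nested keys are allowed and returned as nested lists.
#'
#' @param path Path to a YAML file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  yaml::read_yaml(path)
}
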