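# Shared fixtures, all built in code.

all_hexamers <- function() {
  sort(do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 6),
                                   stringsAsFactors = FALSE)))
}

# Deterministic complete 4096-hexamer table with pseudo-random but fixed
# scores in roughly [-2, 2]; labels all NEUTRAL unless overridden.
complete_hexamer_table <- function() {
  hex <- all_hexamers()
  v <- vapply(hex, function(h) sum(utf8ToInt(h) * 7:12), numeric(1))
  score <- ((v * 2654435761) %% 1000) / 250 - 2
  hexamer_table(hex, unname(score), rep("NEUTRAL", length(hex)))
}

# A tiny gene with one motif whose loop sits at CDS nt 10..45 inside a
# 108-nt motif starting at nt 1.
toy_motif <- function(loop_start = 10L, gene_id = "g1") {
  tibble::tibble(
    gene_id = gene_id, motif_class = "CANONICAL", aa_start = NA_integer_,
    cds_motif_start = 1L, motif_length_nt = 108L,
    loop_start = loop_start, loop_end = loop_start + 35L,
    loop_length_nt = 36L, frame = 0L,
    coordinating_codons = list(c(1L, 3L, 5L, 9L, 12L))
  )
}

toy_models <- function(boundaries, cds_len = 300L, gene_id = "g1") {
  bounds <- c(0L, sort(as.integer(boundaries)), cds_len)
  tibble::tibble(
    gene_id = gene_id, exon_index = seq_len(length(bounds) - 1L),
    cds_start = bounds[-length(bounds)] + 1L, cds_end = bounds[-1L],
    donor_dinuc = c(rep("GT", length(bounds) - 2L), NA_character_)
  )
}

# Random protein sequences biased toward near-consensus loops so that the
# scan has genuine positives and negatives to find.
random_loopish_protein <- function(n_aa = 60L) {
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
           "P", "Q", "R", "S", "T", "V", "W", "Y")
  core <- c("D", "K", "D", "G", "D", "G", "T", "I", "T", "T", "K", "E")
  s <- sample(aas, n_aa, replace = TRUE)
  if (runif(1) < 0.7) {
    at <- sample.int(n_aa - 11L, 1L)
    loop <- core
    n_mut <- sample(0:3, 1L)
    if (n_mut > 0L) {
      loop[sample.int(12L, n_mut)] <- sample(aas, n_mut, replace = TRUE)
    }
    s[at:(at + 11L)] <- loop
  }
  paste(s, collapse = "")
}
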