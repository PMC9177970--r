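#' The 12-residue EF-hand chelation-loop consensus
#'
#' The PROSITE-style pattern describing the canonical EF-hand loop: a
#' required Asp at position 1, a required acidic residue (Asp/Glu) at
#' position 12, permitted-residue sets (square brackets), forbidden-residue
#' sets (parentheses) and free positions (`x`).
#'
#' @return The consensus pattern string.
#' @export
#' @examples
#' parse_prosite_pattern(ef_hand_consensus())
ef_hand_consensus <- function() {
  "D-(W)-[DNS]-(ILVFYW)-[DENSTG]-[DNQGHRK]-(GP)-[LIVMC]-[DENQSTAGC]-x-x-[DE]"
}

#' Parse a PROSITE-style consensus pattern
#'
#' Tokens are separated by `-`.  A single letter is a required residue;
#' `[XY]` is a permitted set (REQUIRED constraint); `(XY)` a forbidden set
#' (FORBIDDEN constraint); `x` matches anything (ANY).  The EF-hand loop
#' consensus has exactly 12 positions, which is enforced by default.
#'
#' @param text Pattern string.
#' @param n_positions Required number of positions (default 12); use `NA`
#'   to accept any length.
#' @return A `consensus_pattern`: tibble with columns `position`, `type`
#'   (one of REQUIRED/FORBIDDEN/ANY) and `residues` (list column of
#'   single-letter sets).
#' @export
parse_prosite_pattern <- function(text, n_positions = 12L) {
  tokens <- str_split(text, "-")[[1]]
  if (!is.na(n_positions) && length(tokens) != n_positions) {
    abort(sprintf("pattern has %d elements; expected %d",
                  length(tokens), n_positions))
  }
  parse_token <- function(tok) {
    if (tok == "x" || tok == "X") {
      list(type = "ANY", residues = character(0))
    } else if (grepl("^\\[[A-Z]+\\]$", tok)) {
      list(type = "REQUIRED",
           residues = strsplit(substr(tok, 2, nchar(tok) - 1), "")[[1]])
    } else if (grepl("^\\([A-Z]+\\)$", tok)) {
      list(type = "FORBIDDEN",
           residues = strsplit(substr(tok, 2, nchar(tok) - 1), "")[[1]])
    } else if (grepl("^[A-Z]$", tok)) {
      list(type = "REQUIRED", residues = tok)
    } else {
      abort(paste0("unknown pattern token: '", tok, "'"))
    }
  }
  parsed <- lapply(tokens, parse_token)
  bad <- unlist(lapply(parsed, `[[`, "residues"))
  bad <- setdiff(bad, AA_ALPHABET)
  if (length(bad) > 0L) {
    abort(paste0("non-amino-acid letter(s) in pattern: ",
                 paste(bad, collapse = ", ")))
  }
  out <- tibble(
    position = seq_along(parsed),
    type = map_chr(parsed, "type"),
    residues = map(parsed, "residues")
  )
  class(out) <- c("consensus_pattern", class(out))
  out
}

# Does a single residue satisfy a single constraint?  The ambiguity letter
# X fails REQUIRED sets and passes FORBIDDEN/ANY (conservative matching).
residue_ok <- function(residue, type, residues) {
  switch(type,
         ANY = TRUE,
         REQUIRED = residue %in% residues,
         FORBIDDEN = !(residue %in% residues))
}

#' Check one window against a consensus pattern
#'
#' @param window Protein string whose length equals the number of pattern
#'   positions.
#' @param pattern A `consensus_pattern`.
#' @return Logical: does every position satisfy its constraint?
#' @export
matches_pattern <- function(window, pattern) {
  if (str_length(window) != nrow(pattern)) return(FALSE)
  chars <- strsplit(window, "")[[1]]
  for (i in seq_len(nrow(pattern))) {
    if (!residue_ok(chars[i], pattern$type[i], pattern$residues[[i]])) {
      return(FALSE)
    }
  }
  TRUE
}

#' Scan a protein for consensus matches
#'
#' Slides a window of the pattern's width along the protein and reports
#' every window (possibly overlapping) that satisfies all constraints, in
#' left-to-right order.
#'
#' @param seq Protein sequence (single string, 20-letter alphabet; `X`
#'   allowed and treated conservatively: it never satisfies a REQUIRED set
#'   and never violates a FORBIDDEN one).
#' @param pattern A `consensus_pattern` from [parse_prosite_pattern()].
#' @return Tibble with columns `aa_start` (1-based) and `match` (the
#'   matched window); zero rows when there is no match.
#' @export
#' @examples
#' p <- parse_prosite_pattern(ef_hand_consensus())
#' scan_protein("DKDGDGTITTKE", p)
scan_protein <- function(seq, pattern) {
  seq <- str_to_upper(seq)
  w <- nrow(pattern)
  n <- str_length(seq)
  if (n < w) return(tibble(aa_start = integer(0), match = character(0)))
  chars <- strsplit(seq, "")[[1]]
  # vectorized over windows: a position-i constraint is tested against the
  # residue stream shifted by i-1
  ok <- rep(TRUE, n - w + 1L)
  for (i in seq_len(w)) {
    res <- chars[seq.int(i, i + n - w)]
    ok_i <- switch(pattern$type[i],
                   ANY = rep(TRUE, length(res)),
                   REQUIRED = res %in% pattern$residues[[i]],
                   FORBIDDEN = !(res %in% pattern$residues[[i]]))
    ok <- ok & ok_i
  }
  starts <- which(ok)
  tibble(aa_start = starts,
         match = str_sub(seq, starts, starts + w - 1L))
}

#' Map a protein-level loop match to CDS nucleotide coordinates
#'
#' For a consensus match starting at amino acid `aa_start` of a protein
#' whose CDS begins at the first codon, the encoded loop occupies CDS
#' nucleotides `3*(aa_start-1)+1` through `3*(aa_start-1)+36` (1-based
#' inclusive; 12 codons).
#'
#' @param aa_start 1-based amino-acid index of the loop's first residue.
#' @param cds_length Length of the CDS in nucleotides (used to validate
#'   that the loop fits).
#' @param loop_codons Number of loop codons (default 12).
#' @return Tibble with columns `loop_start`, `loop_end`, `frame` (frame of
#'   `loop_start - 1` within the codon grid, always 0 here since loops are
#'   codon-aligned).
#' @export
#' @examples
#' map_loop_to_cds(10, cds_length = 300)
map_loop_to_cds <- function(aa_start, cds_length, loop_codons = 12L) {
  loop_start <- 3L * (as.integer(aa_start) - 1L) + 1L
  loop_end <- loop_start + 3L * loop_codons - 1L
  if (any(loop_end > cds_length)) {
    abort(sprintf("CDS too short (%d nt) for loop ending at nt %d",
                  cds_length, max(loop_end)))
  }
  tibble(loop_start = loop_start, loop_end = loop_end,
         frame = (loop_start - 1L) %% 3L)
}

#' Classify a Ca2+-binding motif
#'
#' Classification follows the four-group scheme used for human
#' calcium-binding sites: CANONICAL if the 12-residue loop fully matches
#' the EF-hand consensus; NONCANONICAL for EF-hands failing at least one
#' constraint; S100 when the caller marks the gene as belonging to the S100
#' family (their 14-residue pseudoloop does not fit the 12-position
#' pattern, so family membership is input metadata, not inferred); NONEF
#' for curated Ca2+-contact sites without EF-hand annotation.
#'
#' @param loop_seq Protein 12-mer of the candidate loop (may be `NA` for
#'   nonEF records).
#' @param pattern A `consensus_pattern`.
#' @param is_s100 Is the gene in the S100 family list?
#' @param is_ef_hand Is the motif annotated as an EF-hand?
#' @return One of `"CANONICAL"`, `"NONCANONICAL"`, `"S100"`, `"NONEF"`.
#' @export
classify_motif <- function(loop_seq, pattern, is_s100 = FALSE,
                           is_ef_hand = TRUE) {
  if (isTRUE(is_s100)) return("S100")
  if (!isTRUE(is_ef_hand)) return("NONEF")
  if (!is.na(loop_seq) && matches_pattern(loop_seq, pattern)) {
    "CANONICAL"
  } else {
    "NONCANONICAL"
  }
}

#' Scan proteins and build motif records
#'
#' Runs [scan_protein()] over a set of proteins, maps each consensus match
#' to CDS coordinates and classifies it.  The default motif extent places
#' the 36-nt loop centrally within a 108-nt helix-loop-helix motif (12
#' codons entering helix, 12 loop codons, 12 exiting codons); the helix
#' padding is configurable.
#'
#' @param proteins Tibble with `id`, `seq` (protein).
#' @param cds Tibble with `id`, `seq` (CDS nucleotide), ids matching
#'   `proteins`.
#' @param pattern A `consensus_pattern`; default the EF-hand loop
#'   consensus.
#' @param s100_genes Character vector of gene ids in the S100 family.
#' @param helix_codons Codons of helix on each side of the loop included in
#'   the motif span (default 12, giving a 108-nt motif).
#' @param coordinating_codons Loop codon indices of Ca2+-coordinating
#'   residues (default `c(1, 3, 5, 9, 12)`).
#' @return Motif tibble with one row per match: `gene_id`, `motif_class`,
#'   `aa_start`, `cds_motif_start`, `motif_length_nt`, `loop_start`,
#'   `loop_end`, `loop_length_nt`, `frame` and `coordinating_codons`
#'   (list column).
#' @export
scan_motifs <- function(proteins, cds, pattern = NULL,
                        s100_genes = character(0), helix_codons = 12L,
                        coordinating_codons = c(1L, 3L, 5L, 9L, 12L)) {
  pattern <- pattern %||% parse_prosite_pattern(ef_hand_consensus())
  cds_len <- setNames(str_length(cds$seq), cds$id)
  rows <- map_dfr(seq_len(nrow(proteins)), function(i) {
    id <- proteins$id[i]
    hits <- scan_protein(proteins$seq[i], pattern)
    if (nrow(hits) == 0L) return(NULL)
    mutate(hits, gene_id = id)
  })
  if (is.null(rows) || nrow(rows) == 0L) {
    return(empty_motif_tibble())
  }
  loops <- map_loop_to_cds(rows$aa_start, cds_length = max(cds_len))
  n_cds <- cds_len[rows$gene_id]
  if (any(loops$loop_end > n_cds)) {
    abort("consensus match maps outside its CDS")
  }
  motif_start <- pmax(1L, loops$loop_start - 3L * helix_codons)
  motif_end <- pmin(as.integer(n_cds), loops$loop_end + 3L * helix_codons)
  tibble(
    gene_id = rows$gene_id,
    motif_class = map_chr(seq_len(nrow(rows)), function(i) {
      classify_motif(rows$match[i], pattern,
                     is_s100 = rows$gene_id[i] %in% s100_genes)
    }),
    aa_start = rows$aa_start,
    cds_motif_start = motif_start,
    motif_length_nt = motif_end - motif_start + 1L,
    loop_start = loops$loop_start,
    loop_end = loops$loop_end,
    loop_length_nt = loops$loop_end - loops$loop_start + 1L,
    frame = loops$frame,
    coordinating_codons = rep(list(as.integer(coordinating_codons)),
                              nrow(rows))
  )
}

empty_motif_tibble <- function() {
  tibble(gene_id = character(0), motif_class = character(0),
         aa_start = integer(0), cds_motif_start = integer(0),
         motif_length_nt = integer(0), loop_start = integer(0),
         loop_end = integer(0), loop_length_nt = integer(0),
         frame = integer(0), coordinating_codons = list())
}
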