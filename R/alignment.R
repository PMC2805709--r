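# Aligned protein sequence sets: a tibble subclass with one row per sequence
# (seq_id, kingdom, sequence), all sequences the same gapped length.

#' The 20 canonical amino-acid one-letter codes
#'
#' @format Character vector of length 20, alphabetical.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Ambiguity / non-standard codes rejected by default: the entropy model is
# defined over amino-acid types only.
AA_AMBIGUOUS <- c("B", "Z", "X", "J", "U", "O")

KINGDOM_TAGS <- c("Ar", "B", "F", "P", "EE", "EA", "M", "V")

#' Construct an aligned sequence set
#'
#' Builds and validates the container used by all sequence-level stages:
#' a tibble with columns `seq_id`, `kingdom` and `sequence`, where every
#' sequence has the same length and uses only the 20 canonical amino-acid
#' letters plus the gap character `-`.
#'
#' @param seq_id Character vector of unique sequence identifiers.
#' @param sequence Character vector of gapped sequences (equal lengths).
#' @param kingdom Optional character vector of kingdom tags
#'   (`Ar`, `B`, `F`, `P`, `EE`, `EA`, `M`, `V`) or `NA`.
#' @param map_ambiguous_to_gap If `TRUE`, ambiguity codes (B, Z, X, J, U, O)
#'   are converted to gaps instead of raising an error.
#' @return A tibble of class `aligned_seqs`.
#' @export
aligned_seqs <- function(seq_id, sequence, kingdom = NA_character_,
                         map_ambiguous_to_gap = FALSE) {
  stopifnot(length(seq_id) == length(sequence), length(sequence) >= 1)
  if (anyDuplicated(seq_id)) {
    stop("duplicate seq_id: ", paste(unique(seq_id[duplicated(seq_id)]), collapse = ", "))
  }
  sequence <- toupper(sequence)
  sequence <- gsub(".", "-", sequence, fixed = TRUE)
  if (map_ambiguous_to_gap) {
    sequence <- gsub(sprintf("[%s]", paste(AA_AMBIGUOUS, collapse = "")),
                     "-", sequence)
  }
  lens <- nchar(sequence)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1])[1]
    stop(sprintf(
      "alignment is ragged: record %d ('%s') has length %d, expected %d",
      bad, seq_id[bad], lens[bad], lens[1]))
  }
  ok <- c(AA_ALPHABET, "-")
  for (i in seq_along(sequence)) {
    chars <- strsplit(sequence[i], "", fixed = TRUE)[[1]]
    illegal <- which(!chars %in% ok)
    if (length(illegal)) {
      stop(sprintf(
        "illegal character '%s' in record '%s' at column %d (not an amino-acid letter or gap)",
        chars[illegal[1]], seq_id[i], illegal[1]))
    }
  }
  kingdom <- as.character(kingdom)
  kingdom <- rep_len(kingdom, length(seq_id))
  bad_k <- !is.na(kingdom) & !kingdom %in% KINGDOM_TAGS
  if (any(bad_k)) {
    stop("unknown kingdom tag(s): ", paste(unique(kingdom[bad_k]), collapse = ", "))
  }
  out <- tibble::tibble(seq_id = as.character(seq_id),
                        kingdom = kingdom,
                        sequence = sequence)
  class(out) <- c("aligned_seqs", class(out))
  out
}

#' @export
print.aligned_seqs <- function(x, ...) {
  cat(sprintf("Aligned sequence set: %d sequences x %d columns\n",
              nrow(x), aln_length(x)))
  NextMethod()
}

#' Alignment length (number of columns)
#' @param aln An `aligned_seqs` object.
#' @return Integer number of columns.
#' @export
aln_length <- function(aln) {
  if (nrow(aln) == 0) return(0L)
  nchar(aln$sequence[1])
}

#' Alignment as a character matrix
#'
#' @param aln An `aligned_seqs` object.
#' @return Character matrix, sequences in rows (named by `seq_id`),
#'   alignment columns in columns.
#' @export
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequence, "", fixed = TRUE))
  rownames(m) <- aln$seq_id
  m
}

#' Read an aligned FASTA file
#'
#' Reads a protein multiple alignment in aligned-FASTA format. Lowercase
#' letters are normalised to uppercase and `.` gaps to `-`. A kingdom tag
#' is recognised when the FASTA description line carries a second
#' whitespace-separated token from the tag vocabulary (`Ar`, `B`, `F`, `P`,
#' `EE`, `EA`, `M`, `V`).
#'
#' @param path Path to an aligned FASTA file.
#' @param map_ambiguous_to_gap Convert ambiguity codes to gaps instead of
#'   failing (see [aligned_seqs()]).
#' @return An `aligned_seqs` tibble.
#' @export
read_alignment <- function(path, map_ambiguous_to_gap = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no sequences in ", path)
  headers <- names(set)
  tokens <- strsplit(headers, "\\s+")
  ids <- unname(vapply(tokens, `[`, "", 1L))
  kingdom <- vapply(tokens, function(tk) {
    if (length(tk) >= 2 && tk[2] %in% KINGDOM_TAGS) tk[2] else NA_character_
  }, "")
  aligned_seqs(ids, unname(as.character(set)), kingdom = unname(kingdom),
               map_ambiguous_to_gap = map_ambiguous_to_gap)
}

#' Write an aligned FASTA file
#'
#' @param aln An `aligned_seqs` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  hdr <- ifelse(is.na(aln$kingdom), aln$seq_id,
                paste(aln$seq_id, aln$kingdom))
  set <- Biostrings::BStringSet(aln$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Extract a column range from an alignment
#'
#' Columns are 1-based and the range is inclusive on both ends, matching
#' how positions are conventionally cited for domain boundaries.
#'
#' @param aln An `aligned_seqs` object.
#' @param first_col,last_col 1-based inclusive column bounds.
#' @return The sub-alignment as an `aligned_seqs` tibble.
#' @export
extract_region <- function(aln, first_col, last_col) {
  L <- aln_length(aln)
  if (!(first_col >= 1 && first_col <= last_col && last_col <= L)) {
    stop(sprintf("column range [%d, %d] out of bounds for alignment of length %d",
                 first_col, last_col, L))
  }
  aligned_seqs(aln$seq_id, substr(aln$sequence, first_col, last_col),
               kingdom = aln$kingdom)
}

#' Map alignment columns to residue numbers of one sequence
#'
#' For a chosen sequence (typically one with a solved structure), assigns
#' to the k-th non-gap column the residue number `start_number + k - 1`,
#' so that alignment hits can be reported in a structure's numbering
#' (e.g. Tyr267 of human chitotriosidase).
#'
#' @param aln An `aligned_seqs` object.
#' @param seq_id Identifier of the reference sequence.
#' @param start_number Residue number of its first non-gap position.
#' @return A tibble with columns `column`, `residue_letter` and
#'   `residue_number` (`NA` at gap columns), of class `residue_map` with
#'   attribute `seq_id`.
#' @export
build_residue_map <- function(aln, seq_id, start_number) {
  i <- match(seq_id, aln$seq_id)
  if (is.na(i)) stop("seq_id not found in alignment: ", seq_id)
  chars <- strsplit(aln$sequence[i], "", fixed = TRUE)[[1]]
  nongap <- chars != "-"
  num <- rep(NA_integer_, length(chars))
  num[nongap] <- start_number + seq_len(sum(nongap)) - 1L
  out <- tibble::tibble(column = seq_along(chars),
                        residue_letter = chars,
                        residue_number = num)
  attr(out, "seq_id") <- seq_id
  class(out) <- c("residue_map", class(out))
  out
}

#' Write a residue map as TSV
#'
#' @param rmap A `residue_map` tibble from [build_residue_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_residue_map <- function(rmap, path) {
  out <- rmap
  out$residue_number <- ifelse(is.na(out$residue_number), "gap",
                               as.character(out$residue_number))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
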