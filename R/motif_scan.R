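# Consensus motif scanning on conserved alignment columns.
#
# A motif is an ordered set of slots at fixed column offsets from an
# anchor; each slot names the residue types allowed there and the minimum
# fraction of (non-gap) sequences that must carry one of them. Matching is
# column-level: the motif is a conserved-position pattern tolerant of
# substitutions in individual sequences. Intervening "x" columns are
# unconstrained.

#' Define a motif
#'
#' @param motif_id Short name, e.g. `"YxR"`.
#' @param slots A list of slots, each a list with `offset` (integer column
#'   offset from the anchor; the first must be 0 and offsets strictly
#'   increase) and `types` (character vector or string of allowed
#'   one-letter codes).
#' @param min_occupancy Minimum fraction of non-gap residues at each slot
#'   column that must belong to the allowed set (default 0.5).
#' @return A list of class `motif_definition`.
#' @export
motif_definition <- function(motif_id, slots, min_occupancy = 0.5) {
  offs <- vapply(slots, function(s) as.integer(s$offset), 1L)
  if (offs[1] != 0L || any(diff(offs) <= 0)) {
    stop("slot offsets must start at 0 and strictly increase")
  }
  slots <- lapply(slots, function(s) {
    types <- s$types
    if (length(types) == 1 && nchar(types) > 1) {
      types <- strsplit(types, "", fixed = TRUE)[[1]]
    }
    list(offset = as.integer(s$offset), types = toupper(types))
  })
  structure(list(motif_id = motif_id, slots = slots,
                 min_occupancy = min_occupancy),
            class = "motif_definition")
}

#' The YxR motif (tyrosine / any / arginine)
#'
#' N-terminal motif of the chitinase insertion domain; the Tyr/Arg pair
#' forms a pi-cation interaction and hydrogen bonds to a catalytic
#' aspartate of the TIM barrel.
#' @param min_occupancy See [motif_definition()].
#' @return A `motif_definition`.
#' @export
motif_yxr <- function(min_occupancy = 0.5) {
  motif_definition("YxR",
                   list(list(offset = 0, types = "Y"),
                        list(offset = 2, types = "R")),
                   min_occupancy)
}

#' The \[E/D\]xx\[V/I\] motif (acidic / any / any / branched aliphatic)
#'
#' Central motif of the chitinase insertion domain, contacting the -1/-2
#' sugar subsites.
#' @param min_occupancy See [motif_definition()].
#' @return A `motif_definition`.
#' @export
motif_edxxvi <- function(min_occupancy = 0.5) {
  motif_definition("[E/D]xx[V/I]",
                   list(list(offset = 0, types = c("E", "D")),
                        list(offset = 3, types = c("V", "I"))),
                   min_occupancy)
}

#' Read motif definitions from JSON
#'
#' Format: an array of objects
#' `{"motif_id": "YxR", "slots": [{"offset": 0, "types": "Y"}, ...],
#'   "min_occupancy": 0.5}` (min_occupancy optional).
#'
#' @param path Path to a JSON file.
#' @return List of `motif_definition` objects.
#' @export
read_motif_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(m) {
    motif_definition(m$motif_id, m$slots,
                     min_occupancy = m$min_occupancy %||% 0.5)
  })
}

#' Scan an alignment for conserved motifs
#'
#' A hit is reported at anchor column a when, for every slot at offset o,
#' the fraction of non-gap residues at column a + o belonging to the
#' slot's allowed types reaches `min_occupancy` AND column a + o is
#' binned `high` or `moderate` in the conservation profile. Motifs whose
#' last slot would extend past the alignment end are not evaluated there.
#'
#' @param aln An `aligned_seqs` object.
#' @param conservation A `cid_profile` tibble (or any tibble with `column`
#'   and `bin`), typically from [profile_alignment()].
#' @param defs A `motif_definition` or list of them (default: the YxR and
#'   \[E/D\]xx\[V/I\] motifs).
#' @return Tibble of hits with columns `motif_id`, `anchor_column`,
#'   `slot_columns` (list), `slot_types` (list) and `occupancy` (list of
#'   per-slot matched fractions).
#' @export
scan_motifs <- function(aln, conservation,
                        defs = list(motif_yxr(), motif_edxxvi())) {
  if (inherits(defs, "motif_definition")) defs <- list(defs)
  L <- aln_length(aln)
  m <- aln_matrix(aln)
  conserved_ok <- conservation$bin[order(conservation$column)] %in%
    c("high", "moderate")
  slot_frac <- function(col, types) {
    chars <- m[, col]
    chars <- chars[chars != "-"]
    if (length(chars) == 0) return(0)
    mean(chars %in% types)
  }
  hits <- purrr::map(defs, function(def) {
    offs <- vapply(def$slots, `[[`, 1L, "offset")
    span <- max(offs)
    anchors <- seq_len(max(0L, L - span))
    rows <- purrr::map(anchors, function(a) {
      cols <- a + offs
      if (!all(conserved_ok[cols])) return(NULL)
      frac <- vapply(seq_along(def$slots), function(k) {
        slot_frac(cols[k], def$slots[[k]]$types)
      }, 1.0)
      if (any(frac < def$min_occupancy)) return(NULL)
      tibble::tibble(motif_id = def$motif_id, anchor_column = a,
                     slot_columns = list(cols),
                     slot_types = list(lapply(def$slots, `[[`, "types")),
                     occupancy = list(frac))
    })
    dplyr::bind_rows(rows)
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    out <- tibble::tibble(motif_id = character(), anchor_column = integer(),
                          slot_columns = list(), slot_types = list(),
                          occupancy = list())
  }
  out
}

#' Map motif hits to residue numbers of a reference structure
#'
#' @param hits Tibble from [scan_motifs()].
#' @param rmap A `residue_map` from [build_residue_map()].
#' @return Tibble with one row per hit slot: `motif_id`, `anchor_column`,
#'   `slot_column`, `residue_letter`, `residue_number` and `label`
#'   (e.g. `"Y267"`, or `"gap"` where the reference sequence is gapped).
#' @export
hit_to_residues <- function(hits, rmap) {
  if (nrow(hits) == 0) {
    return(tibble::tibble(motif_id = character(), anchor_column = integer(),
                          slot_column = integer(), residue_letter = character(),
                          residue_number = integer(), label = character()))
  }
  rows <- purrr::pmap(hits, function(motif_id, anchor_column, slot_columns, ...) {
    idx <- match(slot_columns, rmap$column)
    if (anyNA(idx)) stop("residue map does not cover the hit's columns")
    letter <- rmap$residue_letter[idx]
    number <- rmap$residue_number[idx]
    tibble::tibble(motif_id = motif_id, anchor_column = anchor_column,
                   slot_column = slot_columns,
                   residue_letter = letter, residue_number = number,
                   label = ifelse(is.na(number), "gap",
                                  paste0(letter, number)))
  })
  dplyr::bind_rows(rows)
}

#' Write a motif hit report as TSV
#'
#' @param hits Tibble from [scan_motifs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_hits <- function(hits, path) {
  flat <- tibble::tibble(
    motif_id = hits$motif_id,
    anchor_column = hits$anchor_column,
    slot_columns = vapply(hits$slot_columns, paste, "", collapse = ","),
    occupancy = vapply(hits$occupancy,
                       function(v) paste(sprintf("%.6g", v), collapse = ","), "")
  )
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
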