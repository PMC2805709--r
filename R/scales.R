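# Hydrophobicity scales.

#' Nozaki-Tanford hydrophobicity scale
#'
#' Side-chain transfer free energies (kcal/mol) from water to organic
#' solvent measured by Nozaki and Tanford (1971); residues for which no
#' transfer energy was measured carry 0.  This is the scale catalogued in
#' AAindex as NOZY710101 and is the default for hydropathy profiling.
#'
#' @format Named numeric vector over the 20 amino-acid one-letter codes.
#' @export
nozaki_tanford <- c(
  A = 0.5, R = 0.0, N = 0.0, D = 0.0, C = 0.0,
  Q = 0.0, E = 0.0, G = 0.0, H = 0.5, I = 1.8,
  L = 1.8, K = 0.0, M = 1.3, F = 2.5, P = 0.0,
  S = 0.0, T = 0.4, W = 3.4, Y = 2.3, V = 1.5
)

#' Resolve a hydrophobicity scale
#'
#' @param scale Either the string `"nozaki-tanford"`, a named numeric
#'   vector covering all 20 amino acids, or a path to a two-column TSV
#'   (residue, value).
#' @return Named numeric vector of length 20 in [AA_ALPHABET] order.
#' @export
hydrophobicity_scale <- function(scale = "nozaki-tanford") {
  if (is.character(scale) && length(scale) == 1) {
    if (identical(scale, "nozaki-tanford")) {
      values <- nozaki_tanford
    } else if (file.exists(scale)) {
      tab <- utils::read.table(scale, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      values <- stats::setNames(as.numeric(tab[[2]]), toupper(tab[[1]]))
    } else {
      stop("unknown hydrophobicity scale: ", scale)
    }
  } else if (is.numeric(scale) && !is.null(names(scale))) {
    values <- scale
  } else {
    stop("scale must be a name, a file path, or a named numeric vector")
  }
  missing <- setdiff(AA_ALPHABET, names(values))
  if (length(missing)) {
    stop("hydrophobicity scale lacks values for: ", paste(missing, collapse = ", "))
  }
  values[AA_ALPHABET]
}
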