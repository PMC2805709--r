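# Per-column conservation and hydropathy profiling: the computational core.
#
# For alignment column i with amino-acid type counts n_j over n_obs non-gap
# residues, P_j(i) = n_j / n_obs, the site entropy is
#   S(i) = -sum_j P_j(i) ln P_j(i)      (nats; 0 ln 0 = 0)
# and the conservation score is
#   C(i) = 1 - S(i) / ln(m)
# with m the number of amino-acid types considered (default 20). Columns
# with more than one gap are forced to C = 0 (non-conserved) after scoring.

#' Profiling configuration
#'
#' Collects the thresholds and scale used by [profile_alignment()].
#'
#' @param entropy_m `20` (the full amino-acid alphabet, the default) or
#'   `"observed"` to use the number of residue types observed in a column.
#' @param high_cut Conservation score at or above which a column is binned
#'   `high` (default 0.45).
#' @param moderate_cut Lower bound of the `moderate` bin (default 0.35);
#'   columns with `moderate_cut <= C < high_cut` are moderate, below is low.
#' @param neutral_majority Minimum combined fraction of glycine, alanine
#'   and proline for a conserved column to be classed `neutral`
#'   (default 0.5).
#' @param scale Hydrophobicity scale (see [hydrophobicity_scale()]).
#' @param hydrophobic_cut,hydrophilic_cut Mean-hydropathy thresholds for
#'   the hydrophobic / hydrophilic classes. Defaults: the midpoint of the
#'   configured scale's range for both, i.e. a single neutral point
#'   (1.7 kcal/mol for Nozaki-Tanford).
#' @return A list of class `profile_config`.
#' @export
profile_config <- function(entropy_m = 20,
                           high_cut = 0.45,
                           moderate_cut = 0.35,
                           neutral_majority = 0.5,
                           scale = "nozaki-tanford",
                           hydrophobic_cut = NULL,
                           hydrophilic_cut = NULL) {
  if (!(identical(entropy_m, "observed") ||
        (is.numeric(entropy_m) && entropy_m >= 2))) {
    stop("entropy_m must be a number >= 2 or \"observed\"")
  }
  stopifnot(moderate_cut <= high_cut, high_cut <= 1, moderate_cut >= 0,
            neutral_majority >= 0, neutral_majority <= 1)
  values <- hydrophobicity_scale(scale)
  mid <- (min(values) + max(values)) / 2
  cfg <- list(entropy_m = entropy_m,
              high_cut = high_cut,
              moderate_cut = moderate_cut,
              neutral_majority = neutral_majority,
              scale = values,
              hydrophobic_cut = hydrophobic_cut %||% mid,
              hydrophilic_cut = hydrophilic_cut %||% mid)
  class(cfg) <- "profile_config"
  cfg
}

#' Residue counts of one alignment column
#'
#' @param aln An `aligned_seqs` object.
#' @param column 1-based column index.
#' @return A list of class `column_profile` with elements `column`,
#'   `counts` (named integer vector over the observed types), `gap_count`
#'   and `n_obs`.
#' @export
column_counts <- function(aln, column) {
  L <- aln_length(aln)
  if (column < 1 || column > L) {
    stop(sprintf("column %d out of bounds (alignment has %d columns)", column, L))
  }
  chars <- substr(aln$sequence, column, column)
  gap_count <- sum(chars == "-")
  res <- chars[chars != "-"]
  counts <- table(factor(res, levels = AA_ALPHABET))
  counts <- counts[counts > 0]
  structure(list(column = as.integer(column),
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 gap_count = as.integer(gap_count),
                 n_obs = length(res)),
            class = "column_profile")
}

#' Shannon entropy of a column profile
#'
#' Computes S = -sum_j P_j ln P_j in nats over the observed amino-acid
#' types, with the convention 0 ln 0 = 0. Gaps are not a type and do not
#' enter the sum (they are handled separately by the gap rule).
#'
#' @param profile A `column_profile` from [column_counts()], or a named
#'   integer vector of counts.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(profile) {
  counts <- if (inherits(profile, "column_profile")) profile$counts else profile
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    stop("entropy undefined for an all-gap column (n_obs = 0); apply the gap rule first")
  }
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Conservation score from entropy
#'
#' C = 1 - S / ln(m), a dimensionless score in `[0, 1]`; 1 means a single
#' residue type, 0 the uniform distribution over all m types.
#'
#' @param S Entropy in nats.
#' @param m Number of amino-acid types considered (>= 2).
#' @return Conservation score in `[0, 1]`.
#' @export
conservation_score <- function(S, m = 20) {
  stopifnot(m >= 2)
  if (any(S < 0) || any(S > log(m) + 1e-12)) {
    stop(sprintf("entropy out of range: S must lie in [0, ln(%g)]", m))
  }
  pmax(0, 1 - S / log(m))
}

#' Bin conservation scores
#'
#' Partition of `[0, 1]`: `high` for C >= high_cut, `moderate` for
#' moderate_cut <= C < high_cut, `low` below.
#'
#' @param C Numeric vector of conservation scores.
#' @param high_cut,moderate_cut Bin boundaries (defaults 0.45 and 0.35).
#' @return Character vector in `{high, moderate, low}`.
#' @export
bin_conservation <- function(C, high_cut = 0.45, moderate_cut = 0.35) {
  stopifnot(all(C >= 0), all(C <= 1))
  dplyr::case_when(C >= high_cut ~ "high",
                   C >= moderate_cut ~ "moderate",
                   TRUE ~ "low")
}

#' Apply the gap rule to scored columns
#'
#' Columns with more than one gap are considered non-conserved: their
#' score is set to zero and the bin to `gap_zeroed`.
#'
#' @param records Tibble with at least `conservation` and `bin` columns.
#' @param gap_count Integer vector of per-column gap counts (defaults to
#'   `records$gap_count`).
#' @return The records with the rule applied.
#' @export
apply_gap_rule <- function(records, gap_count = records$gap_count) {
  hit <- gap_count > 1
  records$conservation[hit] <- 0
  records$bin[hit] <- "gap_zeroed"
  records
}

#' Column hydropathy
#'
#' The literal hydropathy of the column, sum_j n_j h_j (the count of each
#' amino acid times its hydrophobicity), together with its mean over the
#' observed residues so values are comparable across alignments of
#' different depth.
#'
#' @param profile A `column_profile`.
#' @param scale Named numeric hydrophobicity vector
#'   (see [hydrophobicity_scale()]).
#' @return List with `hydropathy_sum` and `hydropathy_mean`.
#' @export
column_hydropathy <- function(profile, scale = hydrophobicity_scale()) {
  counts <- profile$counts
  if (sum(counts) == 0) stop("hydropathy undefined for an all-gap column")
  s <- sum(counts * scale[names(counts)])
  list(hydropathy_sum = s, hydropathy_mean = s / sum(counts))
}

#' Physicochemical class of conserved columns
#'
#' Conserved columns (bin `high` or `moderate`) are classed `neutral` when
#' glycine, alanine and proline together make up at least
#' `neutral_majority` of the observed residues (these small residues are
#' typically conserved for backbone/turn geometry rather than side-chain
#' chemistry); otherwise `hydrophobic` when the mean hydropathy reaches
#' `hydrophobic_cut`, `hydrophilic` when it is at or below
#' `hydrophilic_cut`, else `unclassified`. Columns binned `low` or
#' `gap_zeroed` are never classified (`NA`).
#'
#' @param bin Character vector of conservation bins.
#' @param hydropathy_mean Numeric vector of column mean hydropathies.
#' @param neutral_fraction Numeric vector: fraction of observed residues
#'   that are G, A or P.
#' @param cfg A [profile_config()].
#' @return Character vector of classes (`NA` for unconserved columns).
#' @export
classify_position <- function(bin, hydropathy_mean, neutral_fraction,
                              cfg = profile_config()) {
  dplyr::case_when(
    !bin %in% c("high", "moderate") ~ NA_character_,
    neutral_fraction >= cfg$neutral_majority ~ "neutral",
    hydropathy_mean >= cfg$hydrophobic_cut ~ "hydrophobic",
    hydropathy_mean <= cfg$hydrophilic_cut ~ "hydrophilic",
    TRUE ~ "unclassified"
  )
}

#' Profile every column of an alignment
#'
#' Runs the full per-column analysis: residue counts, Shannon entropy,
#' conservation score and bin, the more-than-one-gap zeroing rule,
#' hydropathy (sum and mean) and physicochemical class.
#'
#' @param aln An `aligned_seqs` object.
#' @param cfg A [profile_config()].
#' @return A tibble of class `cid_profile` with one row per column:
#'   `column`, `n_obs`, `gap_count`, `entropy`, `conservation`, `bin`,
#'   `hydropathy_sum`, `hydropathy_mean`, `neutral_fraction`, `phys_class`.
#' @export
profile_alignment <- function(aln, cfg = profile_config()) {
  L <- aln_length(aln)
  rows <- purrr::map(seq_len(L), function(i) {
    prof <- column_counts(aln, i)
    if (prof$n_obs == 0) {
      return(tibble::tibble(column = i, n_obs = 0L, gap_count = prof$gap_count,
                            entropy = NA_real_, conservation = 0,
                            bin = "gap_zeroed",
                            hydropathy_sum = NA_real_, hydropathy_mean = NA_real_,
                            neutral_fraction = NA_real_))
    }
    S <- shannon_entropy(prof)
    m <- if (identical(cfg$entropy_m, "observed")) {
      max(2L, length(prof$counts))
    } else {
      cfg$entropy_m
    }
    C <- conservation_score(S, m)
    hyd <- column_hydropathy(prof, cfg$scale)
    gap_frac <- sum(prof$counts[names(prof$counts) %in% c("G", "A", "P")]) /
      prof$n_obs
    tibble::tibble(column = i, n_obs = prof$n_obs, gap_count = prof$gap_count,
                   entropy = S, conservation = C,
                   bin = bin_conservation(C, cfg$high_cut, cfg$moderate_cut),
                   hydropathy_sum = hyd$hydropathy_sum,
                   hydropathy_mean = hyd$hydropathy_mean,
                   neutral_fraction = gap_frac)
  })
  out <- dplyr::bind_rows(rows)
  out <- apply_gap_rule(out)
  out$phys_class <- classify_position(out$bin, out$hydropathy_mean,
                                      out$neutral_fraction, cfg)
  attr(out, "config") <- cfg
  class(out) <- c("cid_profile", class(out))
  out
}

#' Histogram of conservation scores
#'
#' Counts of alignment columns per conservation-score interval, as in the
#' inset histogram of a conservation profile figure.
#'
#' @param profile A `cid_profile` tibble.
#' @param binwidth Width of the score intervals (default 0.05).
#' @return Tibble with `lower`, `upper` and `n_columns`.
#' @export
conservation_histogram <- function(profile, binwidth = 0.05) {
  breaks <- seq(0, 1, by = binwidth)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  idx <- findInterval(profile$conservation, breaks, rightmost.closed = TRUE)
  tibble::tibble(lower = breaks[-length(breaks)],
                 upper = breaks[-1],
                 n_columns = tabulate(idx, nbins = length(breaks) - 1))
}

#' Summarise a conservation/hydropathy profile
#'
#' One-row overview: column counts per conservation bin and counts of
#' conserved columns per physicochemical class.
#'
#' @param x A `cid_profile` tibble.
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
#' @export
glance.cid_profile <- function(x, ...) {
  tibble::tibble(
    n_columns = nrow(x),
    n_high = sum(x$bin == "high"),
    n_moderate = sum(x$bin == "moderate"),
    n_low = sum(x$bin == "low"),
    n_gap_zeroed = sum(x$bin == "gap_zeroed"),
    n_hydrophobic = sum(x$phys_class == "hydrophobic", na.rm = TRUE),
    n_hydrophilic = sum(x$phys_class == "hydrophilic", na.rm = TRUE),
    n_neutral = sum(x$phys_class == "neutral", na.rm = TRUE)
  )
}

#' Tidy a profile (returns the per-column tibble unclassed)
#' @param x A `cid_profile`.
#' @param ... Unused.
#' @return A plain tibble.
#' @exportS3Method generics::tidy
#' @export
tidy.cid_profile <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cid_profile")
  attr(out, "config") <- NULL
  out
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Plot a conservation or hydropathy profile
#'
#' @param object A `cid_profile` tibble.
#' @param type `"conservation"` (bars by bin) or `"hydropathy"` (mean
#'   hydropathy bars coloured by class).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.cid_profile <- function(object, type = c("conservation", "hydropathy"),
                                 ...) {
  type <- match.arg(type)
  cfg <- attr(object, "config")
  if (type == "conservation") {
    ggplot2::ggplot(object,
                    ggplot2::aes(x = .data$column, y = .data$conservation,
                                 fill = .data$bin)) +
      ggplot2::geom_col() +
      ggplot2::scale_fill_manual(values = c(high = "black", moderate = "grey60",
                                            low = "white", gap_zeroed = "grey90"),
                                 drop = FALSE) +
      ggplot2::geom_hline(yintercept = c(cfg$moderate_cut, cfg$high_cut),
                          linetype = "dashed", colour = "grey40") +
      ggplot2::labs(x = "Alignment column", y = "Conservation C(i)") +
      ggplot2::theme_minimal()
  } else {
    dat <- dplyr::filter(object, !is.na(.data$hydropathy_mean))
    ggplot2::ggplot(dat,
                    ggplot2::aes(x = .data$column, y = .data$hydropathy_mean,
                                 fill = .data$phys_class)) +
      ggplot2::geom_col() +
      ggplot2::scale_fill_manual(values = c(hydrophobic = "steelblue",
                                            hydrophilic = "firebrick",
                                            neutral = "tan4",
                                            unclassified = "grey70"),
                                 na.value = "grey90") +
      ggplot2::labs(x = "Alignment column",
                    y = "Mean hydropathy (kcal/mol)") +
      ggplot2::theme_minimal()
  }
}

#' Write a profile as TSV
#'
#' Floats are serialised with six significant digits for stable diffs.
#'
#' @param profile A `cid_profile` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  out <- tidy.cid_profile(profile)
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], function(v) ifelse(is.na(v), "NA", sprintf("%.6g", v)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
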