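# Distance-based phylogeny: p-distances with pairwise gap deletion, an
# optional Kimura-style protein correction, and the Saitou-Nei
# neighbour-joining algorithm. Trees are returned as ape "phylo" objects
# so standard tooling (Newick I/O, plotting, topology comparison)
# applies directly.

#' p-distance between two aligned sequences
#'
#' Fraction of differing positions among columns where both sequences are
#' ungapped (pairwise deletion).
#'
#' @param aln An `aligned_seqs` object.
#' @param i,j Sequence identifiers or row indices.
#' @return Numeric in `[0, 1]`.
#' @export
p_distance <- function(aln, i, j) {
  idx <- function(k) if (is.character(k)) match(k, aln$seq_id) else as.integer(k)
  a <- strsplit(aln$sequence[idx(i)], "", fixed = TRUE)[[1]]
  b <- strsplit(aln$sequence[idx(j)], "", fixed = TRUE)[[1]]
  both <- a != "-" & b != "-"
  if (!any(both)) {
    stop("no mutually ungapped columns between sequences ", i, " and ", j)
  }
  mean(a[both] != b[both])
}

#' Kimura-style correction for protein p-distances
#'
#' d = -ln(1 - p - p^2/5), the multiple-hit correction used by classic
#' protein-alignment tools. The formula saturates as p approaches ~0.85;
#' saturated distances are capped at `cap` with a warning and flagged via
#' the `"saturated"` attribute.
#'
#' @param p Numeric vector of p-distances in `[0, 1]`.
#' @param cap Finite distance substituted for saturated values (default 10).
#' @return Corrected distances (attribute `saturated`: logical vector).
#' @export
kimura_correction <- function(p, cap = 10) {
  stopifnot(all(p >= 0), all(p <= 1))
  arg <- 1 - p - p^2 / 5
  sat <- arg <= 0
  d <- ifelse(sat, cap, -log(ifelse(sat, 1, arg)))
  d <- pmin(d, cap)
  if (any(sat)) {
    warning(sum(sat), " distance(s) saturated (p too large for the correction); capped at ", cap)
  }
  attr(d, "saturated") <- sat
  d
}

#' Pairwise distance matrix of an alignment
#'
#' @param aln An `aligned_seqs` object.
#' @param correction `"none"` (raw p-distance) or `"kimura"`.
#' @return Symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
distance_matrix <- function(aln, correction = c("none", "kimura")) {
  correction <- match.arg(correction)
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(aln$seq_id, aln$seq_id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- p_distance(aln, i, j)
      v <- if (correction == "kimura") as.numeric(kimura_correction(p)) else p
      d[i, j] <- d[j, i] <- v
    }
  }
  d
}

#' Neighbour-joining tree
#'
#' Classic Saitou-Nei agglomeration: at each step the pair (i, j)
#' minimising Q(i, j) = (n - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k)
#' is joined; branch lengths follow the standard split formula and
#' distances to the new node are d(u, k) = (d(i, k) + d(j, k) - d(i, j))/2.
#' On an additive (tree-realisable) matrix the output path lengths equal
#' the input distances exactly. Ties in Q are broken deterministically in
#' favour of the smallest (i, j) index pair; negative branch lengths are
#' clamped to zero with a warning (attribute `"clamped"` records whether
#' any were).
#'
#' @param dm Symmetric distance matrix with taxon dimnames (or a `dist`).
#' @return An unrooted `phylo` object (ape) on the matrix's taxa.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 2) stop("need at least 2 taxa")
  taxa <- rownames(dm)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n))
  stopifnot(isTRUE(all.equal(dm, t(dm))), all(diag(dm) == 0),
            all(is.finite(dm)), all(dm >= 0))
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  fmt <- function(x) sprintf("%.12g", x)
  # active nodes held as newick substrings
  labs <- taxa
  d <- dm
  if (n == 2) {
    tr <- ape::read.tree(text = sprintf("(%s:%s,%s:%s);", labs[1],
                                        fmt(clamp(d[1, 2] / 2)),
                                        labs[2], fmt(clamp(d[1, 2] / 2))))
    attr(tr, "clamped") <- clamped
    return(tr)
  }
  while (nrow(d) > 3) {
    nn <- nrow(d)
    r <- rowSums(d)
    q <- (nn - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # smallest Q; ties -> smallest i, then smallest j (upper triangle)
    best <- c(NA_integer_, NA_integer_); bestq <- Inf
    for (i in seq_len(nn - 1)) {
      for (j in (i + 1):nn) {
        if (q[i, j] < bestq - 1e-12) { bestq <- q[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    li <- clamp(d[i, j] / 2 + (r[i] - r[j]) / (2 * (nn - 2)))
    lj <- clamp(d[i, j] - (d[i, j] / 2 + (r[i] - r[j]) / (2 * (nn - 2))))
    new_lab <- sprintf("(%s:%s,%s:%s)", labs[i], fmt(li), labs[j], fmt(lj))
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(nn), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    labs <- c(labs[keep], new_lab)
    dimnames(d2) <- NULL
    d <- d2
  }
  if (nrow(d) == 3) {
    v1 <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
    v2 <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
    v3 <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    newick <- sprintf("(%s:%s,%s:%s,%s:%s);", labs[1], fmt(v1),
                      labs[2], fmt(v2), labs[3], fmt(v3))
  } else {
    newick <- sprintf("(%s:%s,%s:%s);", labs[1], fmt(clamp(d[1, 2] / 2)),
                      labs[2], fmt(clamp(d[1, 2] / 2)))
  }
  tr <- ape::read.tree(text = newick)
  if (clamped) warning("negative NJ branch length(s) clamped to zero")
  attr(tr, "clamped") <- clamped
  tr
}

#' Build a neighbour-joining tree from an alignment
#'
#' Convenience wrapper: [distance_matrix()] then [nj_tree()].
#'
#' @param aln An `aligned_seqs` object.
#' @param correction Distance correction, see [distance_matrix()].
#' @return A `phylo` object.
#' @export
aln_nj_tree <- function(aln, correction = c("none", "kimura")) {
  nj_tree(distance_matrix(aln, match.arg(correction)))
}

#' Write a tree in Newick format
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Path to a Newick file.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Write a distance matrix as square TSV
#'
#' @param dm Symmetric distance matrix with taxon dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  out <- data.frame(taxon = rownames(dm),
                    apply(dm, 2, function(v) sprintf("%.6g", v)),
                    check.names = FALSE)
  colnames(out) <- c("taxon", colnames(dm))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
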