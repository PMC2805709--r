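# Synthetic ground-truth generators: alignments with planted per-column
# compositions, protein-sugar complexes with planted contact geometry, and
# sequences evolved on a known tree. Every generator is deterministic
# under its seed, and ground truth is computed from the specification,
# never from the generated data.

# run code under a seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

#' Specify one synthetic alignment column
#'
#' @param composition Named numeric vector over amino-acid letters: exact
#'   integer counts (summing with `gap_count` to the number of sequences)
#'   or probabilities summing to 1, which are converted to exact counts by
#'   largest remainder. Exact-count realisation makes downstream class
#'   counts deterministic.
#' @param gap_count Number of gap characters in the column.
#' @return A list of class `column_spec`.
#' @export
column_spec <- function(composition, gap_count = 0L) {
  stopifnot(is.numeric(composition), !is.null(names(composition)),
            all(names(composition) %in% AA_ALPHABET),
            all(composition >= 0), gap_count >= 0)
  structure(list(composition = composition, gap_count = as.integer(gap_count)),
            class = "column_spec")
}

#' Specify a synthetic alignment
#'
#' @param n_seq Number of sequences.
#' @param columns List of [column_spec()] objects.
#' @param seed Integer RNG seed (controls how residues are distributed
#'   over sequences; counts themselves are exact).
#' @return A list of class `alignment_spec`.
#' @export
alignment_spec <- function(n_seq, columns, seed = 1L) {
  stopifnot(n_seq >= 1, length(columns) >= 1)
  structure(list(n_seq = as.integer(n_seq), columns = columns,
                 seed = as.integer(seed)),
            class = "alignment_spec")
}

# exact counts from a column_spec for an alignment of n sequences
.column_counts_exact <- function(cs, n) {
  comp <- cs$composition
  n_res <- n - cs$gap_count
  if (n_res < 0) stop("gap_count exceeds the number of sequences")
  if (abs(sum(comp) - 1) < 1e-9 && !all(comp == round(comp))) {
    # probabilities -> largest-remainder rounding to n_res
    raw <- comp * n_res
    counts <- floor(raw)
    rem <- n_res - sum(counts)
    if (rem > 0) {
      ord <- order(raw - counts, decreasing = TRUE)
      counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
    }
  } else {
    counts <- comp
    if (sum(counts) != n_res) {
      stop(sprintf("column composition (%d residues) + gap_count (%d) != n_seq (%d)",
                   sum(counts), cs$gap_count, n))
    }
  }
  counts <- counts[counts > 0]
  stats::setNames(as.integer(counts), names(counts))
}

#' Generate an alignment with planted column compositions
#'
#' Realises each column's composition exactly (the stated counts are the
#' empirical counts) and permutes the assignment of residues to sequences
#' with the seeded RNG. Ground truth per column — conservation bin and
#' physicochemical class — is computed from the specified counts under
#' `cfg`, not measured from the generated data.
#'
#' @param spec An [alignment_spec()].
#' @param cfg A [profile_config()] used for the ground-truth labels.
#' @return List with `alignment` (an `aligned_seqs`) and `truth` (tibble:
#'   `column`, `bin`, `phys_class`).
#' @export
gen_alignment <- function(spec, cfg = profile_config()) {
  n <- spec$n_seq
  L <- length(spec$columns)
  cols <- matrix("-", nrow = n, ncol = L)
  truth <- vector("list", L)
  .with_seed(spec$seed, {
    for (k in seq_len(L)) {
      cs <- spec$columns[[k]]
      counts <- .column_counts_exact(cs, n)
      chars <- c(rep(names(counts), counts), rep("-", cs$gap_count))
      cols[, k] <- sample(chars, n, replace = FALSE)
      truth[[k]] <- .column_truth(k, counts, cs$gap_count, cfg)
    }
  })
  seqs <- apply(cols, 1, paste, collapse = "")
  aln <- aligned_seqs(sprintf("syn%02d", seq_len(n)), seqs)
  list(alignment = aln, truth = dplyr::bind_rows(truth))
}

# intended bin and class for one column, straight from the spec counts
.column_truth <- function(column, counts, gap_count, cfg) {
  if (sum(counts) == 0 || gap_count > 1) {
    bin <- "gap_zeroed"
    cls <- NA_character_
  } else {
    S <- shannon_entropy(counts)
    m <- if (identical(cfg$entropy_m, "observed")) max(2L, length(counts))
         else cfg$entropy_m
    C <- conservation_score(S, m)
    bin <- bin_conservation(C, cfg$high_cut, cfg$moderate_cut)
    hmean <- sum(counts * cfg$scale[names(counts)]) / sum(counts)
    gap_frac <- sum(counts[names(counts) %in% c("G", "A", "P")]) / sum(counts)
    cls <- classify_position(bin, hmean, gap_frac, cfg)
  }
  tibble::tibble(column = column, bin = bin, phys_class = cls)
}

# --- the study-twin alignment ----------------------------------------------

# Mixture compositions used for moderately conserved columns: six residue
# types with counts 5,5,5,4,4,4 over 27 sequences give C(i) ~ 0.40
# (moderate) under m = 20.
.mix627 <- function(types) {
  stats::setNames(c(5, 5, 5, 4, 4, 4), types)
}

# Low-conservation filler: 20 types, seven doubled (C(i) ~ 0.02).
.filler27 <- function(shift = 0) {
  types <- AA_ALPHABET[(seq_len(20) + shift - 1) %% 20 + 1]
  stats::setNames(c(rep(2, 7), rep(1, 13)), types)
}

#' Synthetic twin of the CID study alignment
#'
#' A 27-sequence, 60-column alignment emulating the statistical structure
#' of the chitinase-insertion-domain study set: 32 conserved columns
#' (9 hydrophobic-high, 5 hydrophobic-moderate, 5 hydrophilic-high,
#' 2 hydrophilic-moderate, 5 neutral-high, 6 neutral-moderate), two
#' columns zeroed by the gap rule, and low-conservation filler. The
#' conserved columns include one planted YxR motif (anchor column 10:
#' all-Tyr, all-Arg at column 12) and one planted \[E/D\]xx\[V/I\] motif
#' (anchor column 30: all-Glu, all-Ile at column 33), mirroring how the
#' real domain's motif residues sit among its conserved positions.
#'
#' @param seed RNG seed for residue-to-sequence assignment.
#' @param n_seq Number of sequences (default 27).
#' @return As [gen_alignment()], plus `motif_anchors` (named list of the
#'   planted anchor columns).
#' @export
synthetic_cid_alignment <- function(seed = 1L, n_seq = 27L) {
  stopifnot(n_seq == 27L)  # compositions below are tuned to 27 sequences
  pure <- function(type) column_spec(stats::setNames(27, type))
  filler <- function(s) column_spec(.filler27(s))
  hyd_mod <- function(rot) {
    types <- c("I", "L", "F", "W", "Y", "M")
    column_spec(.mix627(types[(seq_len(6) + rot - 1) %% 6 + 1]))
  }
  phil_mod <- function(rot) {
    types <- c("D", "E", "K", "R", "N", "S")
    column_spec(.mix627(types[(seq_len(6) + rot - 1) %% 6 + 1]))
  }
  # G/A/P always carry the larger counts so the neutral majority (15/27)
  # holds regardless of which minor polar types fill the column
  neut_mod <- function(rot) {
    minors <- c("S", "T", "N", "Q", "H", "C")
    trio <- minors[(seq_len(3) + rot - 1) %% 6 + 1]
    column_spec(stats::setNames(c(5, 5, 5, 4, 4, 4), c("G", "A", "P", trio)))
  }
  cols <- c(
    lapply(1:9, filler),                               # 1-9   filler
    list(pure("Y")),                                   # 10    YxR anchor
    list(filler(10)),                                  # 11
    list(pure("R")),                                   # 12    YxR slot 2
    lapply(11:13, filler),                             # 13-15
    lapply(c("I", "L", "F", "W", "I"), pure),          # 16-20 hydrophobic high
    list(hyd_mod(0), hyd_mod(1)),                      # 21-22 hydrophobic mod
    list(pure("L")),                                   # 23    hydrophobic high
    list(hyd_mod(2), hyd_mod(3), hyd_mod(4)),          # 24-26 hydrophobic mod
    lapply(14:16, filler),                             # 27-29
    list(pure("E")),                                   # 30    [E/D]xx[V/I] anchor
    list(filler(17), filler(18)),                      # 31-32
    list(pure("I")),                                   # 33    [E/D]xx[V/I] slot 2
    list(filler(19)),                                  # 34
    list(pure("F")),                                   # 35    hydrophobic high
    lapply(c("D", "K", "N"), pure),                    # 36-38 hydrophilic high
    list(phil_mod(0), phil_mod(1)),                    # 39-40 hydrophilic mod
    lapply(c("G", "A", "P", "G", "A"), pure),          # 41-45 neutral high
    lapply(0:5, neut_mod),                             # 46-51 neutral mod
    list(column_spec(c(S = 25), gap_count = 2),        # 52-53 gap-zeroed
         column_spec(c(L = 20, K = 5), gap_count = 2)),
    lapply(1:7, filler)                                # 54-60 filler
  )
  out <- gen_alignment(alignment_spec(n_seq, cols, seed = seed))
  out$motif_anchors <- list(YxR = 10L, `[E/D]xx[V/I]` = 30L)
  out
}

# --- synthetic protein-sugar complexes --------------------------------------

#' Specify a synthetic protein-oligosaccharide complex
#'
#' Distances must sit inside the default [contact_criteria()] cutoffs;
#' decoy atoms are placed far beyond every cutoff.
#'
#' @param n_sugars Number of NAG rings (laid out along x, 10 A apart).
#' @param subsites Integer subsite labels, one per sugar (default
#'   `-1, -2, ...`).
#' @param n_hbonds Planted direct hydrogen bonds.
#' @param hbond_distance Donor-acceptor distance for planted bonds (A).
#' @param n_hydrophobic Planted carbon-carbon contacts.
#' @param cc_distance C-C distance for planted contacts (A).
#' @param salt_bridge Plant one Asp-Arg salt bridge away from the ligand.
#' @param salt_bridge_distance O-N distance (A).
#' @param pi_cation Plant one Tyr-Arg pi-cation pair away from the ligand.
#' @param pi_cation_distance Centroid-centroid distance (A).
#' @param water_bridge Plant one water-mediated hydrogen bond.
#' @param water_leg Length of each bridge leg (A).
#' @param n_decoys Decoy carbon atoms on a distant shell.
#' @param seed RNG seed (decoy placement).
#' @return A list of class `complex_spec`.
#' @export
complex_spec <- function(n_sugars = 3, subsites = -seq_len(n_sugars),
                         n_hbonds = 2, hbond_distance = 2.9,
                         n_hydrophobic = 1, cc_distance = 3.7,
                         salt_bridge = TRUE, salt_bridge_distance = 3.2,
                         pi_cation = TRUE, pi_cation_distance = 4.5,
                         water_bridge = FALSE, water_leg = 2.8,
                         n_decoys = 0, seed = 1L) {
  crit <- contact_criteria()
  if (n_hbonds > 0 && hbond_distance > crit$hbond_max_da) {
    stop("hbond_distance exceeds the default hydrogen-bond cutoff")
  }
  cc_cut <- 2 * crit$vdw_radii[["C"]] + crit$hydrophobic_tolerance
  if (n_hydrophobic > 0 && cc_distance > cc_cut) {
    stop("cc_distance exceeds the default hydrophobic cutoff")
  }
  if (salt_bridge && salt_bridge_distance > crit$salt_bridge_max) {
    stop("salt_bridge_distance exceeds the default salt-bridge cutoff")
  }
  if (pi_cation && pi_cation_distance > crit$pi_cation_max) {
    stop("pi_cation_distance exceeds the default pi-cation cutoff")
  }
  if (water_bridge && water_leg > crit$water_bridge_max) {
    stop("water_leg exceeds the default water-bridge cutoff")
  }
  stopifnot(length(subsites) == n_sugars, n_sugars >= 1)
  structure(list(n_sugars = n_sugars, subsites = as.integer(subsites),
                 n_hbonds = n_hbonds, hbond_distance = hbond_distance,
                 n_hydrophobic = n_hydrophobic, cc_distance = cc_distance,
                 salt_bridge = salt_bridge,
                 salt_bridge_distance = salt_bridge_distance,
                 pi_cation = pi_cation,
                 pi_cation_distance = pi_cation_distance,
                 water_bridge = water_bridge, water_leg = water_leg,
                 n_decoys = n_decoys, seed = as.integer(seed)),
            class = "complex_spec")
}

.pdb_line <- function(record, serial, name, resname, chain, resno, x, y, z,
                      element) {
  namef <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, namef, resname, chain, resno, x, y, z, 1, 0, element)
}

#' Generate a synthetic protein-sugar complex as a PDB file
#'
#' Writes a legal PDB file containing simplified NAG rings (six heavy ring
#' atoms plus O3/O6 hydroxyl oxygens), protein residues planted so that
#' each requested interaction is realised at its requested distance with
#' every other inter-atomic distance at least 1 A outside the default
#' cutoffs, optional bridging water, and optional decoy atoms on a distant
#' shell. Chemical realism beyond cutoff geometry is not attempted.
#'
#' @param spec A [complex_spec()].
#' @param path Output PDB path.
#' @return List with `path`, `model` (parsed back with
#'   [parse_structure()]), `ligand` (a [select_ligand()] selection with
#'   the spec's subsites) and `truth` (tibble of planted contacts: `kind`,
#'   `protein_resno`, `distance`, `subsite`, `water_mediated`).
#' @export
gen_complex <- function(spec, path = tempfile(fileext = ".pdb")) {
  lines <- character(0)
  serial <- 0L
  emit <- function(record, name, resname, chain, resno, pos, element) {
    serial <<- serial + 1L
    lines[length(lines) + 1L] <<- .pdb_line(record, serial, name, resname,
                                            chain, resno, pos[1], pos[2],
                                            pos[3], element)
  }
  truth <- list()
  note <- function(kind, resno, dist, subsite = NA_integer_, wm = FALSE) {
    truth[[length(truth) + 1L]] <<- tibble::tibble(
      kind = kind, protein_resno = resno, distance = dist,
      subsite = subsite, water_mediated = wm)
  }

  sugar_center <- function(s) c(10 * s, 0, 0)
  ring_atom <- function(s, k) {   # k in 1..6 -> C1..C5, O5
    ang <- (k - 1) * pi / 3
    sugar_center(s) + c(1.4 * cos(ang), 1.4 * sin(ang), 0)
  }
  o3_pos <- function(s) sugar_center(s) + c(0, 2.6, 0)
  o6_pos <- function(s) sugar_center(s) + c(0, -2.6, 0)

  resno <- 0L
  # planted direct hydrogen bonds: SER with OG at the requested distance
  # from a sugar O3, pointing mostly +z, remaining atoms strung farther out
  for (i in seq_len(spec$n_hbonds)) {
    s <- (i - 1) %% spec$n_sugars + 1
    th <- 2 * pi * (i - 1) / max(1, spec$n_hbonds)
    u <- c(0.3 * cos(th), 0.3 * sin(th), sqrt(1 - 0.09))
    base <- o3_pos(s)
    resno <- resno + 1L
    emit("ATOM", "N",  "SER", "A", resno, base + (spec$hbond_distance + 3.6) * u, "N")
    emit("ATOM", "CA", "SER", "A", resno, base + (spec$hbond_distance + 2.9) * u, "C")
    emit("ATOM", "C",  "SER", "A", resno, base + (spec$hbond_distance + 4.1) * u, "C")
    emit("ATOM", "O",  "SER", "A", resno, base + (spec$hbond_distance + 4.7) * u, "O")
    emit("ATOM", "CB", "SER", "A", resno, base + (spec$hbond_distance + 1.5) * u, "C")
    emit("ATOM", "OG", "SER", "A", resno, base + spec$hbond_distance * u, "O")
    note("hbond", resno, spec$hbond_distance, spec$subsites[s])
  }
  # planted hydrophobic contacts: ALA with CB straight below a ring carbon
  # (-z); contacts cycle over sugars first, then over ring carbons C1..C5
  for (i in seq_len(spec$n_hydrophobic)) {
    s <- (i - 1) %% spec$n_sugars + 1
    k <- ((i - 1) %/% spec$n_sugars) %% 5 + 1
    u <- c(0, 0, -1)
    base <- ring_atom(s, k)
    resno <- resno + 1L
    emit("ATOM", "N",  "ALA", "A", resno, base + (spec$cc_distance + 3.6) * u, "N")
    emit("ATOM", "CA", "ALA", "A", resno, base + (spec$cc_distance + 2.9) * u, "C")
    emit("ATOM", "C",  "ALA", "A", resno, base + (spec$cc_distance + 4.1) * u, "C")
    emit("ATOM", "O",  "ALA", "A", resno, base + (spec$cc_distance + 4.7) * u, "O")
    emit("ATOM", "CB", "ALA", "A", resno, base + spec$cc_distance * u, "C")
    note("hydrophobic", resno, spec$cc_distance, spec$subsites[s])
  }
  # water-mediated hydrogen bond on sugar 1's O6 (-y side)
  if (spec$water_bridge) {
    base <- o6_pos(1)
    u <- c(0, -1, 0)
    wpos <- base + spec$water_leg * u
    resno <- resno + 1L
    gap <- spec$water_leg + 2.2   # protein OG sits one leg beyond the water
    emit("ATOM", "N",  "SER", "A", resno, base + (gap + 3.6) * u, "N")
    emit("ATOM", "CA", "SER", "A", resno, base + (gap + 2.9) * u, "C")
    emit("ATOM", "C",  "SER", "A", resno, base + (gap + 4.1) * u, "C")
    emit("ATOM", "O",  "SER", "A", resno, base + (gap + 4.7) * u, "O")
    emit("ATOM", "CB", "SER", "A", resno, base + (gap + 1.5) * u, "C")
    emit("ATOM", "OG", "SER", "A", resno, base + gap * u, "O")
    note("hbond", resno, max(spec$water_leg, 2.2), spec$subsites[1], wm = TRUE)
    ser_water <- list(resno = resno, pos = wpos)
  }
  # remote Asp-Arg salt bridge (only OD1 within range of NH1)
  if (spec$salt_bridge) {
    resno <- resno + 1L
    emit("ATOM", "N",  "ASP", "A", resno, c(-33.0, 0.0, 0.0), "N")
    emit("ATOM", "CA", "ASP", "A", resno, c(-31.8, 0.6, 0.0), "C")
    emit("ATOM", "CB", "ASP", "A", resno, c(-31.0, -0.4, 0.0), "C")
    emit("ATOM", "CG", "ASP", "A", resno, c(-30.6, 0.4, 0.6), "C")
    emit("ATOM", "OD1", "ASP", "A", resno, c(-30.0, 0.0, 0.0), "O")
    asp_resno <- resno
    d <- spec$salt_bridge_distance
    resno <- resno + 1L
    emit("ATOM", "NH1", "ARG", "A", resno, c(-30.0 + d, 0.0, 0.0), "N")
    emit("ATOM", "NH2", "ARG", "A", resno, c(-30.0 + d + 1.3, 1.1, 0.0), "N")
    emit("ATOM", "NE",  "ARG", "A", resno, c(-30.0 + d + 1.3, -1.1, 0.0), "N")
    emit("ATOM", "CZ",  "ARG", "A", resno, c(-30.0 + d + 0.9, 0.0, 0.5), "C")
    note("salt_bridge", asp_resno, d)
  }
  # remote Tyr ring / Arg guanidinium pi-cation pair
  if (spec$pi_cation) {
    resno <- resno + 1L
    ring_names <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
    ring_angles <- c(90, 30, 150, -30, -150, -90) * pi / 180
    for (k in seq_along(ring_names)) {
      pos <- c(1.39 * cos(ring_angles[k]), -30 + 1.39 * sin(ring_angles[k]), 0)
      emit("ATOM", ring_names[k], "TYR", "A", resno, pos, "C")
    }
    tyr_resno <- resno
    d <- spec$pi_cation_distance
    resno <- resno + 1L
    emit("ATOM", "NH1", "ARG", "A", resno, c(d + 0.7, -30.0, 0.0), "N")
    emit("ATOM", "NH2", "ARG", "A", resno, c(d - 0.7, -30.0, 0.0), "N")
    emit("ATOM", "NE",  "ARG", "A", resno, c(d, -30.7, 0.0), "N")
    emit("ATOM", "CZ",  "ARG", "A", resno, c(d, -29.3, 0.0), "C")
    note("pi_cation", tyr_resno, d)
  }
  # sugars (chain B) and water (chain W)
  ring_names <- c("C1", "C2", "C3", "C4", "C5", "O5")
  for (s in seq_len(spec$n_sugars)) {
    for (k in 1:6) {
      emit("HETATM", ring_names[k], "NAG", "B", s, ring_atom(s, k),
           substr(ring_names[k], 1, 1))
    }
    emit("HETATM", "O3", "NAG", "B", s, o3_pos(s), "O")
    emit("HETATM", "O6", "NAG", "B", s, o6_pos(s), "O")
  }
  if (spec$water_bridge) {
    emit("HETATM", "O", "HOH", "W", 1L, ser_water$pos, "O")
  }
  # decoy carbons far outside every cutoff
  if (spec$n_decoys > 0) {
    .with_seed(spec$seed, {
      for (i in seq_len(spec$n_decoys)) {
        v <- stats::rnorm(3)
        v <- 80 * v / sqrt(sum(v^2))
        resno <- resno + 1L
        emit("ATOM", "CA", "GLY", "A", resno, v, "C")
      }
    })
  }
  lines <- c(lines, "END")
  writeLines(lines, path)

  model <- parse_structure(path)
  ligand <- select_ligand(model, residue_names = "NAG",
                          subsites = stats::setNames(spec$subsites,
                                                     seq_len(spec$n_sugars)))
  list(path = path, model = model, ligand = ligand,
       truth = if (length(truth)) dplyr::bind_rows(truth)
               else tibble::tibble(kind = character(), protein_resno = integer(),
                                   distance = numeric(), subsite = integer(),
                                   water_mediated = logical()))
}

# --- sequence evolution on a tree -------------------------------------------

#' Evolve ungapped protein sequences along a tree
#'
#' Uniform-rate substitution over the 20 amino acids (a 20-state
#' Jukes-Cantor analogue): along a branch of length b expected
#' substitutions/site, each site changes with probability
#' (19/20)(1 - exp(-20 b / 19)) and a changed site takes a uniform draw
#' from the other 19 residues. The root sequence is uniform over the 20
#' types.
#'
#' @param tree A rooted or unrooted `phylo` with branch lengths in
#'   expected substitutions per site.
#' @param sequence_length Number of sites.
#' @param seed RNG seed.
#' @return An ungapped `aligned_seqs` with one row per tip, in tip order.
#' @export
evolve_on_tree <- function(tree, sequence_length, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            all(tree$edge.length >= 0), sequence_length >= 1)
  tree <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- vector("list", max(tree$edge))
  .with_seed(seed, {
    seqs[[root]] <- sample.int(20L, sequence_length, replace = TRUE)
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      b <- tree$edge.length[e]
      p_change <- (19 / 20) * (1 - exp(-20 * b / 19))
      s <- seqs[[parent]]
      hit <- stats::runif(sequence_length) < p_change
      if (any(hit)) {
        # uniform over the 19 other residues
        s[hit] <- (s[hit] - 1L + sample.int(19L, sum(hit), replace = TRUE)) %% 20L + 1L
      }
      seqs[[child]] <- s
    }
  })
  out <- vapply(seq_len(n_tip), function(i) {
    paste(AA_ALPHABET[seqs[[i]]], collapse = "")
  }, "")
  aligned_seqs(tree$tip.label, out)
}
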