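# Geometric detection of protein-ligand and intra-protein interactions in
# PDB structures: hydrogen bonds, water-mediated hydrogen bonds,
# hydrophobic (carbon-carbon van der Waals) contacts, salt bridges and
# pi-cation pairs. All criteria are distance-based (plus an optional
# donor-H-acceptor angle when explicit hydrogens are present) and fully
# configurable; crystal structures generally lack hydrogens, so the
# distance criterion is the default gate.

WATER_NAMES <- c("HOH", "WAT", "H2O", "DOD")

#' Common sugar residue codes
#'
#' Hetero-residue names recognised as carbohydrate ligands by default;
#' NAG (N-acetyl-D-glucosamine) is the chitin monomer.
#' @format Character vector.
#' @export
SUGAR_CODES <- c("NAG", "NDG", "BMA", "MAN", "GLC", "BGC", "GAL", "FUC", "XYS")

#' Geometric contact criteria
#'
#' Defaults are conventional structural-biology cutoffs; every value is
#' adjustable.
#'
#' @param hbond_max_da Max donor-acceptor heavy-atom distance for a
#'   hydrogen bond, in Angstrom (default 3.5).
#' @param hbond_min_angle Min donor-H-acceptor angle in degrees, applied
#'   only when an explicit hydrogen is attached to a partner (default 90).
#' @param vdw_radii Named per-element van der Waals radii in Angstrom.
#' @param hydrophobic_tolerance Slack added to the C-C vdW radius sum
#'   (default 0.5).
#' @param salt_bridge_max Max anionic-O to cationic-N distance (default 4).
#' @param pi_cation_max Max aromatic-ring-centroid to cationic-group-
#'   centroid distance (default 6).
#' @param water_bridge_max Max length of each leg of a water-mediated
#'   hydrogen bond (default 3.5).
#' @return A list of class `contact_criteria`.
#' @export
contact_criteria <- function(hbond_max_da = 3.5,
                             hbond_min_angle = 90,
                             vdw_radii = c(C = 1.70, N = 1.55, O = 1.52,
                                           S = 1.80, P = 1.80, H = 1.20),
                             hydrophobic_tolerance = 0.5,
                             salt_bridge_max = 4.0,
                             pi_cation_max = 6.0,
                             water_bridge_max = 3.5) {
  vals <- c(hbond_max_da, hbond_min_angle, vdw_radii, hydrophobic_tolerance,
            salt_bridge_max, pi_cation_max, water_bridge_max)
  stopifnot(all(vals > 0))
  structure(list(hbond_max_da = hbond_max_da,
                 hbond_min_angle = hbond_min_angle,
                 vdw_radii = vdw_radii,
                 hydrophobic_tolerance = hydrophobic_tolerance,
                 salt_bridge_max = salt_bridge_max,
                 pi_cation_max = pi_cation_max,
                 water_bridge_max = water_bridge_max),
            class = "contact_criteria")
}

#' Parse a PDB-format structure
#'
#' Reads ATOM and HETATM records of the first model; alternate locations
#' other than blank or 'A' are dropped. Element symbols missing from the
#' file are inferred from the atom name.
#'
#' @param path Path to a PDB file.
#' @return A tibble of class `structure_model` with columns `serial`,
#'   `name`, `element`, `residue_name`, `chain`, `residue_number`,
#'   `insertion_code`, `x`, `y`, `z`, `occupancy`, `is_hetero`.
#' @export
parse_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, multi = FALSE)),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("no atoms parsed from ", path)
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  elem <- at$elesy
  miss <- is.na(elem) | elem == ""
  if (any(miss)) {
    # first alphabetic character of the atom name, e.g. "1HB" -> H, "CA" -> C
    elem[miss] <- toupper(sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", at$elety[miss]))
  }
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    stop("non-finite coordinates in ", path)
  }
  out <- tibble::tibble(
    serial = at$eleno,
    name = at$elety,
    element = toupper(elem),
    residue_name = at$resid,
    chain = ifelse(is.na(at$chain), "", at$chain),
    residue_number = at$resno,
    insertion_code = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    is_hetero = at$type == "HETATM"
  )
  class(out) <- c("structure_model", class(out))
  out
}

#' Apply a rigid-body transform to a structure
#'
#' @param model A `structure_model` tibble.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 numeric vector (Angstrom).
#' @return The transformed model.
#' @export
transform_structure <- function(model, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(rotation)
  model$x <- xyz[, 1] + translation[1]
  model$y <- xyz[, 2] + translation[2]
  model$z <- xyz[, 3] + translation[3]
  model
}

#' Select carbohydrate (or other hetero) ligand residues
#'
#' @param model A `structure_model` tibble.
#' @param residue_names Hetero residue names to select (default
#'   [SUGAR_CODES]).
#' @param chain Optional chain restriction.
#' @param subsites Optional named integer vector mapping
#'   `"chain:residue_number"` (or plain residue number, as character) to a
#'   signed sugar subsite label.
#' @return Tibble of class `ligand_selection`: one row per ligand residue
#'   with `chain`, `residue_number`, `residue_name`, `subsite` (NA when
#'   unassigned), ordered by chain then residue number.
#' @export
select_ligand <- function(model, residue_names = SUGAR_CODES, chain = NULL,
                          subsites = NULL) {
  lig <- model[model$is_hetero & model$residue_name %in% residue_names, ]
  if (!is.null(chain)) lig <- lig[lig$chain %in% chain, ]
  if (nrow(lig) == 0) {
    stop("no ligand residues matching {", paste(residue_names, collapse = ", "),
         "} found in the structure")
  }
  res <- dplyr::distinct(lig, .data$chain, .data$residue_number,
                         .data$residue_name)
  res <- dplyr::arrange(res, .data$chain, .data$residue_number)
  res$subsite <- NA_integer_
  if (!is.null(subsites)) {
    keys1 <- paste0(res$chain, ":", res$residue_number)
    keys2 <- as.character(res$residue_number)
    idx <- match(keys1, names(subsites))
    idx[is.na(idx)] <- match(keys2, names(subsites))[is.na(idx)]
    res$subsite[!is.na(idx)] <- as.integer(subsites[idx[!is.na(idx)]])
  }
  class(res) <- c("ligand_selection", class(res))
  res
}

# --- internal helpers -------------------------------------------------------

.lig_atoms <- function(model, ligand) {
  key <- paste(model$chain, model$residue_number, model$residue_name)
  sel <- paste(ligand$chain, ligand$residue_number, ligand$residue_name)
  out <- model[key %in% sel, ]
  out$subsite <- ligand$subsite[match(paste(out$chain, out$residue_number,
                                            out$residue_name), sel)]
  out
}

.protein_atoms <- function(model) {
  model[!model$is_hetero & !model$residue_name %in% WATER_NAMES, ]
}

.water_oxygens <- function(model) {
  model[model$residue_name %in% WATER_NAMES & model$element == "O", ]
}

# all-pairs distance table between two atom tibbles
.pair_distances <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble::tibble(i = integer(), j = integer(), distance = numeric()))
  }
  ax <- as.matrix(a[, c("x", "y", "z")])
  bx <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rowSums(bx^2), "+") - 2 * ax %*% t(bx)
  d2[d2 < 0] <- 0
  idx <- which(d2 >= 0, arr.ind = TRUE)
  tibble::tibble(i = idx[, 1], j = idx[, 2],
                 distance = sqrt(d2[idx]))
}

.contact_row <- function(kind, p, i, l, j, distance, subsite = NA_integer_,
                         water_mediated = FALSE, angle = NA_real_) {
  tibble::tibble(
    kind = kind,
    protein_chain = p$chain[i], protein_resno = p$residue_number[i],
    protein_resname = p$residue_name[i], protein_atom = p$name[i],
    partner_chain = l$chain[j], partner_resno = l$residue_number[j],
    partner_resname = l$residue_name[j], partner_atom = l$name[j],
    distance = distance, angle = angle,
    subsite = subsite, water_mediated = water_mediated
  )
}

.empty_contacts <- function() {
  .contact_row(character(0),
               tibble::tibble(chain = character(0), residue_number = integer(0),
                              residue_name = character(0), name = character(0)),
               integer(0),
               tibble::tibble(chain = character(0), residue_number = integer(0),
                              residue_name = character(0), name = character(0)),
               integer(0), numeric(0), integer(0), logical(0), numeric(0))
}

# Angle gate: for a candidate heavy-atom pair, if either partner carries an
# explicit covalent hydrogen (same residue, within 1.25 A), require at least
# one X-H...Y angle >= min_angle. Without hydrogens the pair passes.
.hbond_angle_ok <- function(model, a_row, b_row, min_angle) {
  hs <- model[model$element == "H", ]
  if (nrow(hs) == 0) return(TRUE)
  check_one <- function(donor, acceptor) {
    cand <- hs[hs$chain == donor$chain &
               hs$residue_number == donor$residue_number, ]
    if (nrow(cand) == 0) return(NA)
    dvec <- c(donor$x, donor$y, donor$z)
    avec <- c(acceptor$x, acceptor$y, acceptor$z)
    ok <- FALSE; found <- FALSE
    for (k in seq_len(nrow(cand))) {
      hvec <- c(cand$x[k], cand$y[k], cand$z[k])
      if (sqrt(sum((hvec - dvec)^2)) > 1.25) next
      found <- TRUE
      v1 <- dvec - hvec; v2 <- avec - hvec
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                 (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
      if (ang >= min_angle) ok <- TRUE
    }
    if (!found) NA else ok
  }
  r1 <- check_one(a_row, b_row)
  r2 <- check_one(b_row, a_row)
  if (is.na(r1) && is.na(r2)) return(TRUE)   # no H on either partner
  isTRUE(r1) || isTRUE(r2)
}

# --- detectors --------------------------------------------------------------

#' Detect protein-ligand hydrogen bonds
#'
#' Pairs a polar protein heavy atom (N, O or S) with a polar ligand atom
#' (N or O) at donor-acceptor distance at most `hbond_max_da`. Donor and
#' acceptor roles are not distinguished (element-based typing, no hydrogen
#' placement); when explicit hydrogens are present on a partner, the
#' X-H...Y angle must reach `hbond_min_angle` for at least one of them.
#'
#' @param model A `structure_model` tibble.
#' @param ligand A `ligand_selection` from [select_ligand()].
#' @param criteria A [contact_criteria()].
#' @return Tibble of contact records (`kind = "hbond"`).
#' @export
find_hbonds <- function(model, ligand, criteria = contact_criteria()) {
  p <- .protein_atoms(model)
  p <- p[p$element %in% c("N", "O", "S"), ]
  l <- .lig_atoms(model, ligand)
  l <- l[l$element %in% c("N", "O"), ]
  pd <- .pair_distances(p, l)
  pd <- pd[pd$distance <= criteria$hbond_max_da, ]
  if (nrow(pd) == 0) return(.empty_contacts())
  keep <- vapply(seq_len(nrow(pd)), function(k) {
    .hbond_angle_ok(model, p[pd$i[k], ], l[pd$j[k], ], criteria$hbond_min_angle)
  }, TRUE)
  pd <- pd[keep, ]
  if (nrow(pd) == 0) return(.empty_contacts())
  .contact_row("hbond", p, pd$i, l, pd$j, pd$distance,
               subsite = l$subsite[pd$j])
}

#' Detect water-mediated protein-ligand hydrogen bonds
#'
#' Finds bridges (protein polar atom)-(water oxygen)-(ligand polar atom)
#' with both legs at most `water_bridge_max`.
#'
#' @inheritParams find_hbonds
#' @return Tibble of contact records (`kind = "hbond"`,
#'   `water_mediated = TRUE`); the recorded distance is the longer leg.
#' @export
find_water_mediated_hbonds <- function(model, ligand,
                                       criteria = contact_criteria()) {
  w <- .water_oxygens(model)
  if (nrow(w) == 0) return(.empty_contacts())
  p <- .protein_atoms(model)
  p <- p[p$element %in% c("N", "O", "S"), ]
  l <- .lig_atoms(model, ligand)
  l <- l[l$element %in% c("N", "O"), ]
  pw <- .pair_distances(p, w)
  pw <- pw[pw$distance <= criteria$water_bridge_max, ]
  lw <- .pair_distances(l, w)
  lw <- lw[lw$distance <= criteria$water_bridge_max, ]
  if (nrow(pw) == 0 || nrow(lw) == 0) return(.empty_contacts())
  rows <- purrr::map(unique(pw$j), function(wk) {
    pi_ <- pw$i[pw$j == wk]
    li_ <- lw$i[lw$j == wk]
    if (length(pi_) == 0 || length(li_) == 0) return(NULL)
    grid <- expand.grid(i = pi_, j = li_)
    dmax <- pmax(pw$distance[match(paste(grid$i, wk), paste(pw$i, pw$j))],
                 lw$distance[match(paste(grid$j, wk), paste(lw$i, lw$j))])
    .contact_row("hbond", p, grid$i, l, grid$j, dmax,
                 subsite = l$subsite[grid$j], water_mediated = TRUE)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) .empty_contacts() else out
}

#' Detect hydrophobic (carbon-carbon) contacts
#'
#' Reports protein-ligand carbon pairs closer than the sum of the two
#' carbon van der Waals radii plus `hydrophobic_tolerance`.
#'
#' @inheritParams find_hbonds
#' @return Tibble of contact records (`kind = "hydrophobic"`).
#' @export
find_hydrophobic_contacts <- function(model, ligand,
                                      criteria = contact_criteria()) {
  if (!"C" %in% names(criteria$vdw_radii)) {
    stop("vdw_radii table lacks an entry for element C")
  }
  present <- unique(model$element[model$element != "H"])
  lack <- setdiff(present, names(criteria$vdw_radii))
  if (length(lack)) {
    stop("vdw_radii table lacks entries for element(s): ",
         paste(lack, collapse = ", "))
  }
  cut <- 2 * criteria$vdw_radii[["C"]] + criteria$hydrophobic_tolerance
  p <- .protein_atoms(model)
  p <- p[p$element == "C", ]
  l <- .lig_atoms(model, ligand)
  l <- l[l$element == "C", ]
  pd <- .pair_distances(p, l)
  pd <- pd[pd$distance <= cut, ]
  if (nrow(pd) == 0) return(.empty_contacts())
  .contact_row("hydrophobic", p, pd$i, l, pd$j, pd$distance,
               subsite = l$subsite[pd$j])
}

AROMATIC_RING_ATOMS <- list(
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

CATION_GROUP_ATOMS <- list(
  ARG = c("NE", "CZ", "NH1", "NH2"),
  LYS = c("NZ")
)

.group_centroids <- function(p, atom_map) {
  res <- dplyr::distinct(p[p$residue_name %in% names(atom_map), ],
                         .data$chain, .data$residue_number, .data$residue_name)
  rows <- purrr::pmap(res, function(chain, residue_number, residue_name) {
    want <- atom_map[[residue_name]]
    at <- p[p$chain == chain & p$residue_number == residue_number &
            p$name %in% want, ]
    if (nrow(at) < length(want)) return(NULL)   # incomplete side chain
    tibble::tibble(chain = chain, residue_number = residue_number,
                   residue_name = residue_name, name = "centroid",
                   x = mean(at$x), y = mean(at$y), z = mean(at$z))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(chain = character(), residue_number = integer(),
                          residue_name = character(), name = character(),
                          x = numeric(), y = numeric(), z = numeric())
  }
  out
}

#' Detect pi-cation interactions
#'
#' Pairs an aromatic ring centroid (Tyr, Phe, Trp, His) with a cationic
#' group centroid (Arg guanidinium, Lys ammonium) at most `pi_cation_max`
#' apart. Both partners are protein residues; the chitinase YxR motif's
#' Tyr/Arg pair is the motivating case.
#'
#' @inheritParams find_hbonds
#' @return Tibble of contact records (`kind = "pi_cation"`); the
#'   aromatic residue fills the `protein_*` columns and the cationic
#'   residue the `partner_*` columns.
#' @export
find_pi_cation <- function(model, criteria = contact_criteria()) {
  p <- .protein_atoms(model)
  arom <- .group_centroids(p, AROMATIC_RING_ATOMS)
  cat_ <- .group_centroids(p, CATION_GROUP_ATOMS)
  pd <- .pair_distances(arom, cat_)
  pd <- pd[pd$distance <= criteria$pi_cation_max, ]
  # drop self pairs (a His ring is never its own cation here, but guard)
  if (nrow(pd) == 0) return(.empty_contacts())
  same <- arom$chain[pd$i] == cat_$chain[pd$j] &
    arom$residue_number[pd$i] == cat_$residue_number[pd$j]
  pd <- pd[!same, ]
  if (nrow(pd) == 0) return(.empty_contacts())
  .contact_row("pi_cation", arom, pd$i, cat_, pd$j, pd$distance)
}

#' Detect salt bridges
#'
#' Pairs an anionic side-chain oxygen (Asp OD1/OD2, Glu OE1/OE2) with a
#' cationic side-chain nitrogen (Arg NE/NH1/NH2, Lys NZ, His ND1/NE2) at
#' most `salt_bridge_max` apart.
#'
#' @inheritParams find_hbonds
#' @return Tibble of contact records (`kind = "salt_bridge"`); the anionic
#'   residue fills the `protein_*` columns.
#' @export
find_salt_bridges <- function(model, criteria = contact_criteria()) {
  p <- .protein_atoms(model)
  anion <- p[(p$residue_name == "ASP" & p$name %in% c("OD1", "OD2")) |
             (p$residue_name == "GLU" & p$name %in% c("OE1", "OE2")), ]
  cation <- p[(p$residue_name == "ARG" & p$name %in% c("NE", "NH1", "NH2")) |
              (p$residue_name == "LYS" & p$name == "NZ") |
              (p$residue_name == "HIS" & p$name %in% c("ND1", "NE2")), ]
  pd <- .pair_distances(anion, cation)
  pd <- pd[pd$distance <= criteria$salt_bridge_max, ]
  if (nrow(pd) == 0) return(.empty_contacts())
  .contact_row("salt_bridge", anion, pd$i, cation, pd$j, pd$distance)
}

#' Run all detectors on a protein-ligand complex
#'
#' @inheritParams find_hbonds
#' @return Tibble of class `cid_contacts` concatenating direct and
#'   water-mediated hydrogen bonds, hydrophobic contacts, salt bridges and
#'   pi-cation pairs.
#' @export
find_contacts <- function(model, ligand, criteria = contact_criteria()) {
  out <- dplyr::bind_rows(
    find_hbonds(model, ligand, criteria),
    find_water_mediated_hbonds(model, ligand, criteria),
    find_hydrophobic_contacts(model, ligand, criteria),
    find_salt_bridges(model, criteria),
    find_pi_cation(model, criteria)
  )
  class(out) <- c("cid_contacts", class(out))
  out
}

#' Nearest-miss distances per interaction kind
#'
#' For calibration: the smallest candidate-pair distance per detector,
#' whether or not it passes the cutoff. Useful when a published contact
#' list is not recovered under one set of criteria.
#'
#' @inheritParams find_hbonds
#' @return Tibble with `kind`, `min_distance` and `cutoff`.
#' @export
contact_diagnostics <- function(model, ligand, criteria = contact_criteria()) {
  p <- .protein_atoms(model)
  l <- .lig_atoms(model, ligand)
  polar_p <- p[p$element %in% c("N", "O", "S"), ]
  polar_l <- l[l$element %in% c("N", "O"), ]
  cc_cut <- 2 * criteria$vdw_radii[["C"]] + criteria$hydrophobic_tolerance
  min_or_na <- function(d) if (nrow(d) == 0) NA_real_ else min(d$distance)
  arom <- .group_centroids(p, AROMATIC_RING_ATOMS)
  cat_ <- .group_centroids(p, CATION_GROUP_ATOMS)
  tibble::tibble(
    kind = c("hbond", "hydrophobic", "pi_cation"),
    min_distance = c(min_or_na(.pair_distances(polar_p, polar_l)),
                     min_or_na(.pair_distances(p[p$element == "C", ],
                                               l[l$element == "C", ])),
                     min_or_na(.pair_distances(arom, cat_))),
    cutoff = c(criteria$hbond_max_da, cc_cut, criteria$pi_cation_max)
  )
}

#' Per-subsite contact table
#'
#' Groups detected hydrogen bonds and hydrophobic contacts by sugar
#' subsite and by user-assigned residue groups (for example "TIM" for
#' barrel residues and "CID" for insertion-domain residues), listing
#' residues in one-letter + number form (e.g. `R446`).
#'
#' @inheritParams find_hbonds
#' @param residue_groups Named list mapping a group name to a vector of
#'   protein residue numbers; residues not listed fall in group `other`.
#' @return Tibble with one row per subsite and columns
#'   `<group>_hbond` / `<group>_hydrophobic` of comma-joined residue
#'   labels.
#' @export
contact_table <- function(model, ligand, residue_groups = list(),
                          criteria = contact_criteria()) {
  contacts <- dplyr::bind_rows(
    find_hbonds(model, ligand, criteria),
    find_water_mediated_hbonds(model, ligand, criteria),
    find_hydrophobic_contacts(model, ligand, criteria)
  )
  groups <- names(residue_groups)
  assign_group <- function(resno) {
    for (g in groups) if (resno %in% residue_groups[[g]]) return(g)
    "other"
  }
  all_groups <- unique(c(groups, "other"))
  subsites <- sort(unique(ligand$subsite), na.last = TRUE)
  rows <- purrr::map(subsites, function(ss) {
    sel <- if (is.na(ss)) contacts[is.na(contacts$subsite), ]
           else contacts[!is.na(contacts$subsite) & contacts$subsite == ss, ]
    row <- list(subsite = ss)
    for (g in all_groups) {
      for (kind in c("hbond", "hydrophobic")) {
        sub <- sel[sel$kind == kind, ]
        if (nrow(sub)) {
          grp <- vapply(sub$protein_resno, assign_group, "")
          sub <- sub[grp == g, ]
        }
        labels <- if (nrow(sub) == 0) "" else {
          aa1 <- vapply(sub$protein_resname, function(r) {
            out <- suppressWarnings(bio3d::aa321(r))
            if (is.na(out) || out == "X") r else out
          }, "")
          paste(sort(unique(paste0(aa1, sub$protein_resno))), collapse = ",")
        }
        row[[paste0(g, "_", kind)]] <- labels
      }
    }
    tibble::as_tibble(row)
  })
  dplyr::bind_rows(rows)
}

#' Plot detected contacts
#'
#' Dot plot of contact distances by interaction kind, coloured by subsite.
#'
#' @param object A `cid_contacts` tibble from [find_contacts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.cid_contacts <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$kind, y = .data$distance,
                               colour = factor(.data$subsite))) +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::labs(x = "Interaction kind", y = "Distance (Å)",
                  colour = "Subsite") +
    ggplot2::theme_minimal()
}

#' Write a contact report as TSV
#'
#' @param contacts Tibble of contact records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(contacts, path) {
  out <- as.data.frame(contacts)
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], function(v) ifelse(is.na(v), "NA", sprintf("%.6g", v)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
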