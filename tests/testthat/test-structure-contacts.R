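# Brute-force oracle: all-pairs distance scan over the raw atom table,
# reimplementing each criterion naively.
brute_count <- function(model, ligand, kind, criteria = contact_criteria()) {
  lig_keys <- paste(ligand$chain, ligand$residue_number)
  lig <- model[paste(model$chain, model$residue_number) %in% lig_keys, ]
  prot <- model[!model$is_hetero & !model$residue_name %in% c("HOH", "WAT"), ]
  n <- 0L
  if (kind == "hbond") {
    p <- prot[prot$element %in% c("N", "O", "S"), ]
    l <- lig[lig$element %in% c("N", "O"), ]
    for (i in seq_len(nrow(p))) for (j in seq_len(nrow(l))) {
      d <- sqrt((p$x[i] - l$x[j])^2 + (p$y[i] - l$y[j])^2 + (p$z[i] - l$z[j])^2)
      if (d <= criteria$hbond_max_da) n <- n + 1L
    }
  } else if (kind == "hydrophobic") {
    cut <- 2 * criteria$vdw_radii[["C"]] + criteria$hydrophobic_tolerance
    p <- prot[prot$element == "C", ]
    l <- lig[lig$element == "C", ]
    for (i in seq_len(nrow(p))) for (j in seq_len(nrow(l))) {
      d <- sqrt((p$x[i] - l$x[j])^2 + (p$y[i] - l$y[j])^2 + (p$z[i] - l$z[j])^2)
      if (d <= cut) n <- n + 1L
    }
  }
  n
}

test_that("parse_structure reads fixtures and keeps only the first model", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "HETATM    3  O3  NAG B   1       2.000   1.500   0.000  1.00  0.00           O",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ALA A   1       9.000   9.000   9.000  1.00  0.00           N",
    "ENDMDL",
    "END"), tf)
  m <- parse_structure(tf)
  expect_equal(nrow(m), 3L)
  expect_equal(m$x, c(0, 1.458, 2))
  expect_equal(m$element, c("N", "C", "O"))
  expect_equal(m$is_hetero, c(FALSE, FALSE, TRUE))

  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(parse_structure(empty))
})

test_that("ligand selection orders sugars and attaches subsite labels", {
  cx <- gen_complex(complex_spec(n_sugars = 3, subsites = c(-1L, -2L, -3L)))
  expect_equal(cx$ligand$residue_number, 1:3)
  expect_equal(cx$ligand$subsite, c(-1L, -2L, -3L))
  expect_error(select_ligand(cx$model, residue_names = "GAL"),
               "no ligand residues")
})

test_that("each detector recovers exactly its planted contacts", {
  cx <- gen_complex(complex_spec(n_sugars = 3, n_hbonds = 2,
                                 hbond_distance = 2.9,
                                 n_hydrophobic = 1, cc_distance = 3.7,
                                 salt_bridge = TRUE, pi_cation = TRUE,
                                 water_bridge = TRUE))
  hb <- find_hbonds(cx$model, cx$ligand)
  expect_equal(nrow(hb), 2L)
  expect_equal(hb$distance, rep(2.9, 2), tolerance = 1e-3)
  expect_equal(sort(hb$subsite), c(-2L, -1L))

  wm <- find_water_mediated_hbonds(cx$model, cx$ligand)
  expect_equal(nrow(wm), 1L)
  expect_true(all(wm$water_mediated))

  hp <- find_hydrophobic_contacts(cx$model, cx$ligand)
  expect_equal(nrow(hp), 1L)
  expect_equal(hp$distance, 3.7, tolerance = 1e-3)

  sb <- find_salt_bridges(cx$model)
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$protein_resname, "ASP")
  expect_equal(sb$partner_resname, "ARG")
  expect_equal(sb$distance, 3.2, tolerance = 1e-3)

  pc <- find_pi_cation(cx$model)
  expect_equal(nrow(pc), 1L)
  expect_equal(pc$protein_resname, "TYR")
  expect_equal(pc$distance, 4.5, tolerance = 1e-3)
})

test_that("geometry outside the cutoffs yields no contacts", {
  # hydrogen bond at 4.0 A: outside the 3.5 A default
  expect_error(complex_spec(hbond_distance = 4.0), "exceeds")
  cx <- gen_complex(complex_spec(n_sugars = 1, n_hbonds = 0,
                                 n_hydrophobic = 0, salt_bridge = FALSE,
                                 pi_cation = FALSE))
  expect_equal(nrow(find_hbonds(cx$model, cx$ligand)), 0L)
  expect_equal(nrow(find_hydrophobic_contacts(cx$model, cx$ligand)), 0L)
  expect_equal(nrow(find_salt_bridges(cx$model)), 0L)
  expect_equal(nrow(find_pi_cation(cx$model)), 0L)
  expect_equal(nrow(find_water_mediated_hbonds(cx$model, cx$ligand)), 0L)
})

test_that("decoy atoms introduce no false positives", {
  cx <- gen_complex(complex_spec(n_sugars = 2, n_hbonds = 2, n_hydrophobic = 2,
                                 salt_bridge = TRUE, pi_cation = TRUE,
                                 water_bridge = TRUE, n_decoys = 50, seed = 9))
  ct <- find_contacts(cx$model, cx$ligand)
  expect_equal(sum(ct$kind == "hbond" & !ct$water_mediated), 2L)
  expect_equal(sum(ct$kind == "hbond" & ct$water_mediated), 1L)
  expect_equal(sum(ct$kind == "hydrophobic"), 2L)
  expect_equal(sum(ct$kind == "salt_bridge"), 1L)
  expect_equal(sum(ct$kind == "pi_cation"), 1L)
})

test_that("detection is invariant under rigid rotation and translation", {
  cx <- gen_complex(complex_spec(n_sugars = 2, n_hbonds = 2, n_hydrophobic = 1,
                                 salt_bridge = TRUE, pi_cation = TRUE,
                                 water_bridge = TRUE))
  set.seed(31)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0), c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
  moved <- transform_structure(cx$model, Rz %*% Rx, c(12.3, -45.6, 7.8))
  before <- find_contacts(cx$model, cx$ligand)
  after <- find_contacts(moved, cx$ligand)
  expect_equal(nrow(after), nrow(before))
  expect_equal(sort(after$distance), sort(before$distance), tolerance = 1e-9)
  expect_equal(table(after$kind), table(before$kind))
})

test_that("shrinking any cutoff never adds contacts", {
  cx <- gen_complex(complex_spec(n_sugars = 2, n_hbonds = 2, n_hydrophobic = 1,
                                 salt_bridge = TRUE, pi_cation = TRUE))
  loose <- contact_criteria()
  tight <- contact_criteria(hbond_max_da = 2.5, hydrophobic_tolerance = 0.1,
                            salt_bridge_max = 2.5, pi_cation_max = 3.0,
                            water_bridge_max = 2.0)
  n_loose <- nrow(find_contacts(cx$model, cx$ligand, loose))
  n_tight <- nrow(find_contacts(cx$model, cx$ligand, tight))
  expect_lte(n_tight, n_loose)
  expect_equal(n_tight, 0L)
})

test_that("detector counts agree with the brute-force all-pairs oracle", {
  cx <- gen_complex(complex_spec(n_sugars = 3, n_hbonds = 3, n_hydrophobic = 2,
                                 water_bridge = FALSE, n_decoys = 20, seed = 4))
  expect_equal(nrow(find_hbonds(cx$model, cx$ligand)),
               brute_count(cx$model, cx$ligand, "hbond"))
  expect_equal(nrow(find_hydrophobic_contacts(cx$model, cx$ligand)),
               brute_count(cx$model, cx$ligand, "hydrophobic"))
})

test_that("explicit hydrogens enable the angle filter", {
  # donor O-H pointing away from the acceptor: angle ~ 0 deg, rejected;
  # pointing toward it: angle ~ 180 deg, kept
  mk <- function(hx) {
    tf <- tempfile(fileext = ".pdb")
    writeLines(c(
      "ATOM      1  OG  SER A   1       0.000   0.000   0.000  1.00  0.00           O",
      sprintf("ATOM      2  HG  SER A   1    %8.3f   0.000   0.000  1.00  0.00           H", hx),
      "HETATM    3  O3  NAG B   1       2.900   0.000   0.000  1.00  0.00           O",
      "END"), tf)
    tf
  }
  toward <- parse_structure(mk(0.95))
  away <- parse_structure(mk(-0.95))
  lig_t <- select_ligand(toward, "NAG")
  lig_a <- select_ligand(away, "NAG")
  expect_equal(nrow(find_hbonds(toward, lig_t)), 1L)
  expect_equal(nrow(find_hbonds(away, lig_a)), 0L)
})

test_that("contact_table groups residues by subsite and user-defined group", {
  cx <- gen_complex(complex_spec(n_sugars = 2, n_hbonds = 1, n_hydrophobic = 1,
                                 salt_bridge = FALSE, pi_cation = FALSE))
  hb_res <- cx$truth$protein_resno[cx$truth$kind == "hbond"]
  tab <- contact_table(cx$model, cx$ligand,
                       residue_groups = list(CID = hb_res))
  row1 <- tab[tab$subsite == -1, ]
  expect_equal(row1$CID_hbond, paste0("S", hb_res))
  expect_equal(row1$CID_hydrophobic, "")
  expect_true(nchar(row1$other_hydrophobic) > 0)  # the planted Ala
})

test_that("nearest-miss diagnostics report sub-cutoff and supra-cutoff minima", {
  cx <- gen_complex(complex_spec(n_sugars = 1, n_hbonds = 1,
                                 n_hydrophobic = 0, salt_bridge = FALSE,
                                 pi_cation = FALSE))
  diag <- contact_diagnostics(cx$model, cx$ligand)
  expect_equal(diag$min_distance[diag$kind == "hbond"], 2.9, tolerance = 1e-3)
  # no hydrophobic contact planted, but the nearest C-C distance is finite
  expect_true(is.finite(diag$min_distance[diag$kind == "hydrophobic"]))
  expect_gt(diag$min_distance[diag$kind == "hydrophobic"],
            diag$cutoff[diag$kind == "hydrophobic"])
})
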