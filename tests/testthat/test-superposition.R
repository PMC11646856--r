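test_that("Kabsch fit recovers planted rigid motions exactly", {
  set.seed(101)
  m <- matrix(rnorm(30), 10)
  fit0 <- kabsch_fit(m, m)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit0$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit0$fit_rmsd, 0, tolerance = 1e-12)
  # 90 degree rotation about z plus a translation
  R90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  tgt <- sweep(m %*% t(R90), 2, c(1, 2, 3), "+")
  fit <- kabsch_fit(m, tgt)
  expect_lt(fit$fit_rmsd, 1e-10)
  expect_equal(fit$rotation, R90, tolerance = 1e-10)
  expect_equal(fit$translation, c(1, 2, 3), tolerance = 1e-10)
  # degenerate point sets raise
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_fit(line, line + 1), "degenerate")
  expect_error(kabsch_fit(m[1:2, ], m[1:2, ]), "at least 3")
})

test_that("Kabsch RMSD matches an independent closed-form oracle on random clouds", {
  set.seed(202)
  for (i in 1:20) {
    a <- matrix(rnorm(30), 10)
    b <- matrix(rnorm(30), 10)
    fit <- kabsch_fit(a, b)
    expect_equal(fit$fit_rmsd, oracle_superposition_rmsd(a, b),
                 tolerance = 1e-6)
    # invariance to a pre-applied rigid motion of either cloud
    R <- tcrflex:::random_rotation()
    a2 <- sweep(a %*% t(R), 2, rnorm(3, sd = 5), "+")
    expect_equal(kabsch_fit(a2, b)$fit_rmsd, fit$fit_rmsd,
                 tolerance = 1e-8)
  }
})

test_that("backbone RMSD follows the root-mean-square displacement formula", {
  seg <- segment_atoms(rep(-2, 6), rep(2.2, 6))
  moved <- seg
  moved[, c("x", "y", "z")] <- sweep(as.matrix(seg[, c("x", "y", "z")]),
                                     2, c(3, 4, 0), "+")
  expect_equal(as.numeric(backbone_rmsd(seg, seg)), 0)
  expect_equal(as.numeric(backbone_rmsd(seg, moved)), 5.0)
  expect_lt(as.numeric(backbone_rmsd(seg, moved, superpose_first = TRUE)),
            1e-10)
  # superposed RMSD never exceeds the unsuperposed one
  set.seed(33)
  for (i in 1:10) {
    pert <- seg
    pert[, c("x", "y", "z")] <- as.matrix(seg[, c("x", "y", "z")]) +
      rnorm(nrow(seg) * 3, sd = 0.7)
    expect_lte(as.numeric(backbone_rmsd(seg, pert, superpose_first = TRUE)),
               as.numeric(backbone_rmsd(seg, pert)) + 1e-12)
    # symmetry
    expect_equal(as.numeric(backbone_rmsd(seg, pert)),
                 as.numeric(backbone_rmsd(pert, seg)), tolerance = 1e-12)
  }
})

test_that("per-residue heavy-atom RMSD evaluates the formula per residue", {
  seg <- segment_atoms(rep(-1.5, 3), rep(2.5, 3))
  # add side-chain-like atoms so one residue has 8 shared atoms
  extra <- do.call(rbind, lapply(1:4, function(k) {
    row <- seg[seg$imgt == 2 & seg$atom == "CA", ]
    row$atom <- paste0("CG", k); row$element <- "C"
    row$x <- row$x + k
    row
  }))
  a <- rbind(seg, extra)
  b <- a
  b$x[b$imgt == 2 & b$atom == "CG1"] <- b$x[b$imgt == 2 & b$atom == "CG1"] + 1
  out <- per_residue_heavy_rmsd(a, b)
  expect_equal(out$value[out$imgt == 2], 1 / sqrt(8))
  expect_equal(out$value[out$imgt == 1], 0)
  # random perturbations equal the direct formula
  set.seed(44)
  b2 <- a
  d <- matrix(rnorm(nrow(a) * 3, sd = 0.3), ncol = 3)
  b2[, c("x", "y", "z")] <- as.matrix(a[, c("x", "y", "z")]) + d
  out2 <- per_residue_heavy_rmsd(a, b2)
  for (r in unique(a$imgt)) {
    rows <- which(a$imgt == r)
    expect_equal(out2$value[out2$imgt == r],
                 sqrt(mean(rowSums(d[rows, , drop = FALSE]^2))),
                 tolerance = 1e-12)
  }
  # residue pair sharing no atoms is NA, not zero
  c1 <- a[a$imgt == 1 & a$atom %in% c("N", "CA"), ]
  c2 <- a[a$imgt == 1 & a$atom %in% c("C", "O"), ]
  out3 <- per_residue_heavy_rmsd(c1, c2)
  expect_true(is.na(out3$value))
})

test_that("framework alignment recovers rigid motion and isolates loop movement", {
  cx <- make_toy_complex(8)
  pair <- make_apo_holo_pair(cx, perturbation_spec("CDR3b",
                                                   rigid_displacement = 2,
                                                   seed = 9))
  apo <- align_tcr_framework(pair$apo, pair$holo)
  fr_a <- apo$atoms[apo$atoms$region %in% "FR", ]
  fr_h <- pair$holo$atoms[pair$holo$atoms$region %in% "FR", ]
  expect_lt(as.numeric(backbone_rmsd(fr_a, fr_h)), 1e-6)
  expect_equal(as.numeric(backbone_rmsd(loop_atoms(apo, "CDR3b"),
                                        loop_atoms(pair$holo, "CDR3b"))),
               2, tolerance = 1e-6)
  # a pure rigid motion of the whole molecule aligns back exactly
  ident <- make_apo_holo_pair(cx, perturbation_spec("CDR3b", seed = 2))
  back <- align_tcr_framework(ident$apo, ident$holo)
  m1 <- as.matrix(back$atoms[, c("x", "y", "z")])
  m2 <- as.matrix(ident$holo$atoms[
    ident$holo$atoms$role %in% c("tcr_alpha", "tcr_beta"), c("x", "y", "z")])
  expect_lt(max(abs(m1 - m2)), 1e-6)
  # missing FR residues: the fit uses the intersection only
  trimmed <- ident$apo
  drop <- trimmed$atoms$region %in% "FR" & trimmed$atoms$imgt <= 10
  trimmed$atoms <- trimmed$atoms[!drop, ]
  expect_silent(align_tcr_framework(trimmed, ident$holo))
})

test_that("MHC floor alignment reproduces planted peptide displacement profiles", {
  cx <- make_toy_complex(12)
  pair <- make_apo_holo_pair(cx, perturbation_spec("peptide",
                                                   internal_amplitude = 0.8,
                                                   seed = 5))
  apo <- align_mhc_floor(pair$apo, pair$holo)
  pep_a <- apo$atoms[apo$atoms$role == "peptide", ]
  pep_h <- pair$holo$atoms[pair$holo$atoms$role == "peptide", ]
  measured <- per_residue_heavy_rmsd(
    pep_a[pep_a$atom %in% c("N", "CA", "C", "O"), ],
    pep_h[pep_h$atom %in% c("N", "CA", "C", "O"), ])
  gt <- pair$ground_truth$expected_per_residue
  expect_equal(measured$value[match(gt$imgt, measured$imgt)], gt$value,
               tolerance = 1e-6)
})

test_that("dihedral computation matches construction and an independent oracle", {
  phi <- rep(-57 * pi / 180, 8); psi <- rep(-47 * pi / 180, 8)
  seg <- segment_atoms(phi, psi)
  dh <- compute_dihedrals(seg)
  expect_true(is.na(dh$phi[1]))     # no preceding residue
  expect_true(is.na(dh$psi[8]))     # no following residue
  expect_equal(dh$phi[-1], phi[-1], tolerance = 1e-6)
  expect_equal(dh$psi[-8], psi[-8], tolerance = 1e-6)
  # chain break suppresses angles across it
  broken <- seg
  move <- broken$imgt >= 5
  broken[move, c("x", "y", "z")] <-
    sweep(as.matrix(broken[move, c("x", "y", "z")]), 2, c(50, 0, 0), "+")
  dhb <- compute_dihedrals(broken)
  expect_true(is.na(dhb$psi[4]) && is.na(dhb$phi[5]))
  # random-geometry torsions match the independent four-point oracle
  set.seed(77)
  for (i in 1:25) {
    p <- matrix(rnorm(12, sd = 2), 4)
    expect_equal(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
  }
})

test_that("D-score follows its dihedral-difference definition", {
  seg <- segment_atoms(rep(-1.8, 5), rep(2.4, 5))
  a <- compute_dihedrals(seg)
  expect_equal(as.numeric(dscore(a, a)), 0)
  # single residue with phi differing by pi, psi equal -> 2(1 - cos pi) = 4
  b <- a
  b$phi[3] <- b$phi[3] + pi
  expect_equal(as.numeric(dscore(a, b)), 4.0, tolerance = 1e-12)
  # symmetry, 2*pi invariance and the 8n bound
  set.seed(55)
  b2 <- a
  b2$phi <- b2$phi + rnorm(5); b2$psi <- b2$psi + rnorm(5)
  expect_equal(as.numeric(dscore(a, b2)), as.numeric(dscore(b2, a)))
  b3 <- b2
  b3$phi <- b3$phi + 2 * pi
  expect_equal(as.numeric(dscore(a, b3)), as.numeric(dscore(a, b2)),
               tolerance = 1e-9)
  expect_lte(as.numeric(dscore(a, b2)), 8 * nrow(a))
  # missing angles are skipped, not imputed
  b4 <- b2
  b4$phi[2] <- NA
  expect_equal(attr(dscore(a, b4), "n_angle_pairs"), 7L)
  expect_error(dscore(a[0, ], b2[0, ]), "overlap")
})
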