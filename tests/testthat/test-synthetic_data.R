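test_that("toy TCRs are valid, idealised and deterministic", {
  tcr <- make_toy_tcr(31)
  # passes curation and region assignment by construction
  man <- filter_quality(list(tcr))
  expect_equal(length(man$records), 1L)
  expect_equal(nrow(man$rejections), 0L)
  # consecutive CA-CA spacing near 3.8 Angstrom
  for (ch in unique(tcr$atoms$chain_id)) {
    ca <- as.matrix(tcr$atoms[tcr$atoms$chain_id == ch &
                                tcr$atoms$atom == "CA", c("x", "y", "z")])
    d <- sqrt(rowSums(diff(ca)^2))
    expect_true(all(abs(d - 3.8) < 0.2))
  }
  # same seed -> byte-identical PDB
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  on.exit(unlink(c(f1, f2)))
  write_structure(make_toy_tcr(31), f1)
  write_structure(make_toy_tcr(31), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(tcr$atoms$x, make_toy_tcr(32)$atoms$x))
  # loop lengths are honoured
  short <- make_toy_tcr(1, loop_lengths = c(CDR1a = 5L, CDR2a = 5L,
                                            CDR3a = 7L, CDR1b = 5L,
                                            CDR2b = 5L, CDR3b = 7L))
  expect_equal(sum(short$atoms$role == "tcr_alpha" &
                     short$atoms$region %in% "CDR3" &
                     short$atoms$atom == "CA"), 7L)
})

test_that("toy pMHCs place anchor residues against the groove floor", {
  for (mode in c("P2_P9", "P2_P5_P9")) {
    pm <- make_toy_pmhc(17, anchor_mode = mode)
    floor_xyz <- as.matrix(pm$atoms[pm$atoms$region %in% "groove_floor",
                                    c("x", "y", "z")])
    min_floor_dist <- function(p) {
      ca <- as.numeric(pm$atoms[pm$atoms$role == "peptide" &
                                  pm$atoms$imgt == p &
                                  pm$atoms$atom == "CA", c("x", "y", "z")])
      min(sqrt(colSums((t(floor_xyz) - ca)^2)))
    }
    expect_lt(min_floor_dist(2), 4.5)
    expect_lt(min_floor_dist(9), 4.5)
    if (mode == "P2_P5_P9") expect_lt(min_floor_dist(5), 4.5)
    expect_equal(nrow(filter_quality(list(pm))$rejections), 0L)
  }
})

test_that("apo/holo pairs carry exact closed-form ground truth", {
  cx <- make_toy_complex(23)
  # pure translation: unsuperposed RMSD = delta, superposed ~ 0
  for (delta in c(0.5, 2.0, 4.5)) {
    pr <- make_apo_holo_pair(cx, perturbation_spec(
      "CDR3b", rigid_displacement = delta, seed = 7))
    expect_equal(pr$ground_truth$expected_unsuperposed_rmsd, delta,
                 tolerance = 1e-12)
    apo <- align_tcr_framework(pr$apo, pr$holo)
    expect_equal(as.numeric(backbone_rmsd(loop_atoms(apo, "CDR3b"),
                                          loop_atoms(pr$holo, "CDR3b"))),
                 delta, tolerance = 1e-6)
    expect_lt(as.numeric(backbone_rmsd(loop_atoms(apo, "CDR3b"),
                                       loop_atoms(pr$holo, "CDR3b"),
                                       superpose_first = TRUE)), 1e-6)
  }
  # pure rotation about the anchor axis: superposed RMSD ~ 0
  rot <- make_apo_holo_pair(cx, perturbation_spec("CDR3a",
                                                  rigid_rotation = 25,
                                                  seed = 3))
  apo_r <- align_tcr_framework(rot$apo, rot$holo)
  expect_gt(as.numeric(backbone_rmsd(loop_atoms(apo_r, "CDR3a"),
                                     loop_atoms(rot$holo, "CDR3a"))), 0.5)
  expect_lt(as.numeric(backbone_rmsd(loop_atoms(apo_r, "CDR3a"),
                                     loop_atoms(rot$holo, "CDR3a"),
                                     superpose_first = TRUE)), 1e-6)
  # internal deformation: superposed RMSD equals the bookkeeping closed form
  intl <- make_apo_holo_pair(cx, perturbation_spec("CDR3a",
                                                   internal_amplitude = 0.8,
                                                   seed = 4))
  apo_i <- align_tcr_framework(intl$apo, intl$holo)
  sup <- as.numeric(backbone_rmsd(loop_atoms(apo_i, "CDR3a"),
                                  loop_atoms(intl$holo, "CDR3a"),
                                  superpose_first = TRUE))
  expect_equal(sup, intl$ground_truth$expected_superposed_rmsd,
               tolerance = 1e-6)
  gt <- intl$ground_truth
  expect_equal(gt$expected_superposed_rmsd,
               sqrt(mean(rowSums(gt$displacement^2))), tolerance = 1e-9)
  # combined rigid + internal from explicit bookkeeping
  both <- make_apo_holo_pair(cx, perturbation_spec(
    "CDR3b", rigid_displacement = 1.5, internal_amplitude = 0.5, seed = 6))
  apo_b <- align_tcr_framework(both$apo, both$holo)
  expect_equal(as.numeric(backbone_rmsd(loop_atoms(apo_b, "CDR3b"),
                                        loop_atoms(both$holo, "CDR3b"))),
               both$ground_truth$expected_unsuperposed_rmsd,
               tolerance = 1e-6)
  expect_equal(as.numeric(backbone_rmsd(loop_atoms(apo_b, "CDR3b"),
                                        loop_atoms(both$holo, "CDR3b"),
                                        superpose_first = TRUE)),
               both$ground_truth$expected_superposed_rmsd,
               tolerance = 1e-6)
  expect_error(make_apo_holo_pair(pr <- make_toy_tcr(1),
                                  perturbation_spec("CDR3a", 1)),
               "holo complex")
})

test_that("loop families plant controllable cluster structure", {
  fams <- make_loop_families(3, 6, intra_sigma = 0.04, inter_sep = 6,
                             unique_seqs = 4, seed = 41)
  expect_length(fams, 18)
  expect_equal(attr(fams, "family"), rep(1:3, each = 6))
  expect_length(make_loop_families(0, 5), 0)
  # planted separation: between-family DTW far exceeds within-family
  dm <- build_distance_matrix(fams)
  fam <- attr(fams, "family")
  same <- dm[outer(fam, fam, "==") & row(dm) != col(dm)]
  diff_ <- dm[outer(fam, fam, "!=")]
  expect_gt(min(diff_) / max(same), 10)
  # sequence multiplicity steers the canonical/pseudo label
  expect_length(unique(vapply(fams[1:6], `[[`, "", "sequence")), 4L)
  two <- make_loop_families(1, 6, unique_seqs = 2, seed = 5)
  expect_length(unique(vapply(two, `[[`, "", "sequence")), 2L)
})

test_that("motif tables and repertoires are well-formed and seeded", {
  prof <- make_motif_table(list(`2` = list(aa = "L", prop = 0.7),
                                `5` = list(aa = "V", prop = 0.35)), 9)
  sums <- tapply(prof$proportion, prof$position, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  m <- build_simplified_motif(prof)
  expect_equal(as.character(m$band[m$position == 2 & m$aa == "L"]),
               "dominant")
  expect_equal(as.character(m$band[m$position == 5 & m$aa == "V"]), "high")
  expect_error(make_motif_table(list(`2` = list(aa = "L", prop = 1.2)), 9),
               "above 1")
  # repertoire: unique rows, deterministic, planted frequency recovered
  freqs <- default_gene_freqs()
  freqs$TRBV <- c(TRBV19 = 0.2, setNames(rep(0.8 / 9, 9),
                                         paste0("TRBV", 1:9)))
  tab <- make_background_repertoire(10000, freqs, seed = 13)
  expect_false(any(duplicated(tab)))
  expect_identical(tab, make_background_repertoire(10000, freqs, seed = 13))
  p_hat <- mean(tab$TRBV == "TRBV19")
  se <- sqrt(0.2 * 0.8 / 10000)
  expect_lt(abs(p_hat - 0.2), 3 * se)
  expect_error(make_background_repertoire(
    10, list(TRAV = c(a = 0.5), TRAJ = c(a = 1), TRBV = c(a = 1),
             TRBJ = c(a = 1))), "sum to 1")
})
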