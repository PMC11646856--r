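# synthetic_data: seeded generators of IMGT-numbered toy structures,
# apo/holo pairs with known ground-truth motions, loop families with planted
# cluster structure, motif tables and background repertoires. Geometry is
# idealised (planar-peptide backbone construction, 3.8 A consecutive-CA
# spacing); all metrics downstream are purely geometric so physical realism
# beyond that is not needed.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Atom rows for one chain built from phi/psi, with given IMGT numbers and
# sequence. CB is placed for every residue except glycine.
chain_atoms <- function(chain_id, role, imgt, aa, phi, psi, origin = c(0, 0, 0),
                        rotation = diag(3)) {
  bb <- build_backbone(phi, psi)
  rows <- list()
  for (i in seq_along(bb)) {
    atoms <- bb[[i]]
    if (aa[i] == "G") atoms$CB <- NULL
    for (nm in names(atoms)) {
      p <- as.vector(rotation %*% atoms[[nm]]) + origin
      rows[[length(rows) + 1L]] <- data.frame(
        chain_id = chain_id, role = role, imgt = imgt[i], ins = "",
        aa = aa[i], atom = nm,
        element = substr(nm, 1L, 1L),
        x = p[1L], y = p[2L], z = p[3L], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# phi/psi vectors for a chain: extended-strand baseline with seeded jitter;
# CDR3-range positions take a turn-like conformation so loops are non-planar.
jittered_dihedrals <- function(n, turn = rep(FALSE, n), jitter_deg = 8) {
  phi <- ifelse(turn, -60, -120) * pi / 180 +
    stats::rnorm(n, 0, jitter_deg * pi / 180)
  psi <- ifelse(turn, -40, 130) * pi / 180 +
    stats::rnorm(n, 0, jitter_deg * pi / 180)
  list(phi = phi, psi = psi)
}

tcr_chain_positions <- function(loop_lengths, chain = c("a", "b"),
                                config = region_config()) {
  chain <- match.arg(chain)
  l1 <- loop_lengths[paste0("CDR1", chain)]
  l2 <- loop_lengths[paste0("CDR2", chain)]
  l3 <- loop_lengths[paste0("CDR3", chain)]
  c(seq.int(1L, config$cdr1[1L] - 1L),
    seq.int(config$cdr1[1L], length.out = l1),
    seq.int(config$cdr1[2L] + 1L, config$cdr2[1L] - 1L),
    seq.int(config$cdr2[1L], length.out = l2),
    seq.int(config$cdr2[2L] + 1L, config$cdr3[1L] - 1L),
    seq.int(config$cdr3[1L], length.out = l3),
    seq.int(config$cdr3[2L] + 1L, config$variable_domain[2L]))
}

#' Generate a toy IMGT-numbered unbound TCR
#'
#' Builds both variable-domain chains with idealised backbone geometry and
#' seeded dihedral jitter, IMGT numbers covering positions 1-128 with the
#' configured CDR ranges partially occupied according to `loop_lengths`.
#' Deterministic under `seed`.
#'
#' @param seed Integer seed.
#' @param loop_lengths Named integer vector of CDR loop lengths.
#' @param structure_id Identifier.
#' @param resolution Nominal resolution written to the record.
#' @param config A [region_config()].
#' @return An `apo_tcr` [structure_record()] with regions assigned.
#' @export
make_toy_tcr <- function(seed = 1L,
                         loop_lengths = c(CDR1a = 7L, CDR2a = 6L, CDR3a = 9L,
                                          CDR1b = 7L, CDR2b = 6L, CDR3b = 10L),
                         structure_id = sprintf("toytcr%04d", seed),
                         resolution = 2.0, config = region_config()) {
  set.seed(seed)
  chains <- list()
  for (ch in c("a", "b")) {
    pos <- tcr_chain_positions(loop_lengths, ch, config)
    n <- length(pos)
    aa <- sample(AA20, n, replace = TRUE)
    turn <- pos >= config$cdr3[1L] & pos <= config$cdr3[2L]
    dh <- jittered_dihedrals(n, turn)
    origin <- if (ch == "a") c(0, 0, 0) else c(30, 0, 0)
    chains[[ch]] <- chain_atoms(toupper(ch),
                                if (ch == "a") "tcr_alpha" else "tcr_beta",
                                pos, aa, dh$phi, dh$psi, origin = origin)
  }
  rec <- structure_record(structure_id, "apo_tcr", do.call(rbind, chains),
                          resolution = resolution)
  assign_regions(rec, config)
}

#' Generate a toy IMGT-numbered unbound pMHC-I
#'
#' Builds an MHC heavy-chain antigen-binding domain (groove floor plus two
#' helices, positions 1-176) and a peptide laid above the floor. Anchor
#' residues (p2 and the C-terminus; additionally the middle position for
#' `P2_P5_P9`) are pulled to within 4.5 Angstrom of a floor atom.
#'
#' @param seed Integer seed.
#' @param peptide_length Peptide length (>= 8).
#' @param anchor_mode `"P2_P9"` or `"P2_P5_P9"`.
#' @param allele Allele name recorded on the structure.
#' @param structure_id Identifier.
#' @param resolution Nominal resolution.
#' @param config A [region_config()].
#' @return An `apo_pmhc` [structure_record()] with regions assigned.
#' @export
make_toy_pmhc <- function(seed = 1L, peptide_length = 9L,
                          anchor_mode = c("P2_P9", "P2_P5_P9"),
                          allele = sprintf("TOY*%02d:01", 1L + seed %% 50L),
                          structure_id = sprintf("toypmhc%04d", seed),
                          resolution = 2.0, config = region_config()) {
  anchor_mode <- match.arg(anchor_mode)
  stopifnot(peptide_length >= 8L)
  set.seed(seed + 7L)
  npos <- 176L
  aa_m <- sample(AA20, npos, replace = TRUE)
  helix <- seq_len(npos) %in% c(expand_ranges(config$alpha1_helix),
                                expand_ranges(config$alpha2_helix))
  dh <- jittered_dihedrals(npos, turn = helix)
  mhc <- chain_atoms("M", "mhc_heavy", seq_len(npos), aa_m, dh$phi, dh$psi)

  floor_idx <- mhc$imgt %in% expand_ranges(config$groove_floor)
  floor_xyz <- as.matrix(mhc[floor_idx, c("x", "y", "z")])
  ctr <- colMeans(floor_xyz)
  pc <- eigen(stats::cov(floor_xyz), symmetric = TRUE)$vectors
  e1 <- pc[, 1L]; up <- pc[, 3L]

  aa_p <- sample(AA20, peptide_length, replace = TRUE)
  dh_p <- jittered_dihedrals(peptide_length, jitter_deg = 4)
  pep <- chain_atoms("P", "peptide", seq_len(peptide_length), aa_p,
                     dh_p$phi, dh_p$psi)
  # centre the peptide above the floor, long axis along the floor's first PC
  pxyz <- as.matrix(pep[, c("x", "y", "z")])
  pctr <- colMeans(pxyz)
  ppc <- eigen(stats::cov(pxyz), symmetric = TRUE)$vectors
  Rp <- pc %*% t(ppc)
  if (det(Rp) < 0) Rp <- pc %*% diag(c(1, 1, -1)) %*% t(ppc)
  pxyz <- sweep(sweep(pxyz, 2L, pctr) %*% t(Rp), 2L, ctr + 7 * up, "+")
  pep[, c("x", "y", "z")] <- pxyz

  mid <- if (peptide_length == 9L) 5L else as.integer(ceiling(peptide_length / 2))
  anchors <- if (anchor_mode == "P2_P9") c(2L, peptide_length) else
    c(2L, mid, peptide_length)
  for (p in anchors) {
    sel <- pep$imgt == p
    ca <- as.numeric(pep[sel & pep$atom == "CA", c("x", "y", "z")])
    dists <- sqrt(colSums((t(floor_xyz) - ca)^2))
    nearest <- floor_xyz[which.min(dists), ]
    d <- min(dists)
    if (d > 4.0) {
      shift <- (1 - 4.0 / d) * (nearest - ca)
      pep[sel, c("x", "y", "z")] <-
        sweep(as.matrix(pep[sel, c("x", "y", "z")]), 2L, shift, "+")
    }
  }
  rec <- structure_record(structure_id, "apo_pmhc", rbind(mhc, pep),
                          resolution = resolution, allele = allele)
  rec <- assign_regions(rec, config)
  attr(rec, "anchor_mode") <- anchor_mode
  rec
}

#' Generate a toy TCR:pMHC-I holo complex
#'
#' Combines a toy TCR and toy pMHC, docking the TCR so that its CDR3a loop
#' sits over the N-terminal half of the peptide and the CDR3b loop over the
#' C-terminal half, a few Angstrom above the groove.
#'
#' @inheritParams make_toy_tcr
#' @inheritParams make_toy_pmhc
#' @param standoff Height of the CDR3 loops above the peptide, Angstrom.
#' @return A `holo_complex` [structure_record()] with regions assigned.
#' @export
make_toy_complex <- function(seed = 1L,
                             loop_lengths = c(CDR1a = 7L, CDR2a = 6L,
                                              CDR3a = 9L, CDR1b = 7L,
                                              CDR2b = 6L, CDR3b = 10L),
                             peptide_length = 9L,
                             anchor_mode = c("P2_P9", "P2_P5_P9"),
                             allele = sprintf("TOY*%02d:01", 1L + seed %% 50L),
                             structure_id = sprintf("toycplx%04d", seed),
                             resolution = 2.0, standoff = 4.0,
                             config = region_config()) {
  anchor_mode <- match.arg(anchor_mode)
  tcr <- make_toy_tcr(seed, loop_lengths, resolution = resolution,
                      config = config)
  pmhc <- make_toy_pmhc(seed, peptide_length, anchor_mode, allele = allele,
                        resolution = resolution, config = config)
  pep <- pmhc$atoms[pmhc$atoms$role == "peptide", ]
  floor_xyz <- as.matrix(pmhc$atoms[pmhc$atoms$region %in% "groove_floor",
                                    c("x", "y", "z")])
  pep_xyz <- as.matrix(pep[, c("x", "y", "z")])
  up <- unit3(colMeans(pep_xyz) - colMeans(floor_xyz))
  mid <- ceiling(peptide_length / 2)
  n_ctr <- colMeans(as.matrix(pep[pep$imgt <= mid, c("x", "y", "z")]))
  c_ctr <- colMeans(as.matrix(pep[pep$imgt > mid, c("x", "y", "z")]))

  loop_ctr <- function(rec, lt) {
    p <- loop_type_parts(lt)
    colMeans(as.matrix(rec$atoms[rec$atoms$role == p$role &
                                   rec$atoms$region %in% p$region,
                                 c("x", "y", "z")]))
  }
  fr_ctr <- colMeans(as.matrix(tcr$atoms[tcr$atoms$region %in% "FR",
                                         c("x", "y", "z")]))
  # coarse body placement: framework centred well above the groove
  shift <- (colMeans(pep_xyz) + 40 * up) - fr_ctr
  tcr$atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(tcr$atoms[, c("x", "y", "z")]), 2L, shift, "+")
  # then place each CDR loop segment over its binding site: CDR3a over the
  # peptide N-half, CDR3b over the C-half, CDR1/CDR2 loops over the helices.
  # The idealised chains are far more extended than a folded variable
  # domain, so the loops are positioned individually; all downstream
  # measures are geometric and unaffected by the loop-framework linkers.
  helix_ctr <- function(region, half) {
    h <- pmhc$atoms[pmhc$atoms$region %in% region, , drop = FALSE]
    rng <- range(h$imgt)
    midp <- mean(rng)
    sel <- if (half == "n") h$imgt <= midp else h$imgt > midp
    colMeans(as.matrix(h[sel, c("x", "y", "z")]))
  }
  targets <- list(
    CDR3a = n_ctr + standoff * up,
    CDR3b = c_ctr + standoff * up,
    CDR1a = helix_ctr("alpha2_helix", "n") + standoff * up,
    CDR2a = helix_ctr("alpha2_helix", "c") + standoff * up,
    CDR1b = helix_ctr("alpha1_helix", "c") + standoff * up,
    CDR2b = helix_ctr("alpha1_helix", "n") + standoff * up)
  for (lt in names(targets)) {
    p <- loop_type_parts(lt)
    rows <- tcr$atoms$role == p$role & !is.na(tcr$atoms$region) &
      tcr$atoms$region == p$region
    xyz <- as.matrix(tcr$atoms[rows, c("x", "y", "z")])
    tcr$atoms[rows, c("x", "y", "z")] <-
      sweep(xyz, 2L, targets[[lt]] - colMeans(xyz), "+")
  }

  atoms <- rbind(tcr$atoms, pmhc$atoms)
  rec <- structure_record(structure_id, "holo_complex", atoms,
                          resolution = resolution, allele = pmhc$allele)
  rec <- assign_regions(rec, config)
  attr(rec, "anchor_mode") <- anchor_mode
  rec
}

#' Perturbation specification for a synthetic apo/holo pair
#'
#' @param loop_type A CDR loop type or `"peptide"`.
#' @param rigid_displacement Translation magnitude, Angstrom.
#' @param rigid_rotation Rotation about the axis through the first and last
#'   residue CA of the region ("anchor axis"), degrees.
#' @param internal_amplitude Peak internal (deformation) displacement,
#'   Angstrom.
#' @param weight_profile `"midpeak"` (maximal mid-loop, zero at the loop
#'   ends), `"bimodal"` (zero at the ends and the middle position, maximal
#'   between the anchors -- the p2-p5-p9 peptide pattern) or `"uniform"`.
#' @param seed Integer seed for displacement directions.
#' @return A `perturbation_spec` list.
#' @export
perturbation_spec <- function(loop_type, rigid_displacement = 0,
                              rigid_rotation = 0, internal_amplitude = 0,
                              weight_profile = c("midpeak", "bimodal",
                                                 "uniform"),
                              seed = 1L) {
  weight_profile <- match.arg(weight_profile)
  stopifnot(rigid_displacement >= 0, internal_amplitude >= 0,
            loop_type %in% c(LOOP_TYPES, "peptide"))
  structure(list(loop_type = loop_type,
                 rigid_displacement = rigid_displacement,
                 rigid_rotation = rigid_rotation,
                 internal_amplitude = internal_amplitude,
                 weight_profile = weight_profile, seed = seed),
            class = "perturbation_spec")
}

# Region atom indices (into record$atoms) for a perturbation target.
perturb_region_idx <- function(record, loop_type) {
  at <- record$atoms
  if (loop_type == "peptide") {
    which(at$role == "peptide")
  } else {
    p <- loop_type_parts(loop_type)
    which(at$role == p$role & !is.na(at$region) & at$region == p$region)
  }
}

# Internal deformation field over the residues of a region. Per-residue
# displacements are constant within the residue (all atoms move jointly, so
# dihedral changes are well-defined) with magnitudes following the weight
# profile; their directions rotate along the loop (a "windmill", two seeded
# orthonormal directions), which makes the field nearly free of net
# translation and torque. A minimum-norm least-squares correction then
# projects the field exactly onto the rigid-null subspace of the region
# backbone, so the identity transform is the optimal Kabsch fit and the
# closed-form RMSD sqrt(sum d_i^2 / n) of the applied field equals the
# superposed RMSD exactly. Zero-weight loop ends receive only the (small)
# correction.
internal_deformation_field <- function(res_xbar, res_weights, res_natoms,
                                       amplitude, e1, e2) {
  L <- nrow(res_xbar)
  # angles spaced by cumulative weight: the weighted direction sum is a
  # Riemann sum over the full circle, so the raw field is nearly
  # translation-free and the exact correction below stays small
  wsum <- sum(res_weights)
  theta <- if (wsum > 0) {
    2 * pi * (cumsum(res_weights) - res_weights / 2) / wsum
  } else rep(0, L)
  base <- amplitude * res_weights *
    (cos(theta) %o% e1 + sin(theta) %o% e2)
  ctr <- colSums(res_natoms * res_xbar) / sum(res_natoms)
  xc <- sweep(res_xbar, 2L, ctr)
  # constraint matrix A (6 x 3L): zero net translation and torque over the
  # backbone atoms; residue r contributes n_r * I and n_r * skew(xc_r)
  A <- matrix(0, 6L, 3L * L)
  for (r in seq_len(L)) {
    cols <- (3L * r - 2L):(3L * r)
    A[1:3, cols] <- res_natoms[r] * diag(3L)
    A[4:6, cols] <- res_natoms[r] *
      matrix(c(0, xc[r, 3L], -xc[r, 2L],
               -xc[r, 3L], 0, xc[r, 1L],
               xc[r, 2L], -xc[r, 1L], 0), nrow = 3L)
  }
  project <- function(dvec) {
    lam <- tryCatch(solve(A %*% t(A), A %*% dvec), error = function(e) NULL)
    if (is.null(lam)) dvec else dvec - as.vector(t(A) %*% lam)
  }
  # fixed-point: project exactly onto the rigid-null space, then restore
  # the planted magnitude profile; corrections shrink across iterations so
  # the final (exact) projection barely perturbs the profile
  F <- matrix(project(as.vector(t(base))), ncol = 3L, byrow = TRUE)
  for (it in 1:40) {
    mags <- sqrt(rowSums(F^2))
    G <- F
    ok <- mags > 1e-12 & res_weights > 0
    G[ok, ] <- F[ok, ] * (amplitude * res_weights[ok] / mags[ok])
    G[!ok, ] <- 0
    Fnew <- matrix(project(as.vector(t(G))), ncol = 3L, byrow = TRUE)
    if (max(abs(Fnew - F)) < 1e-12) { F <- Fnew; break }
    F <- Fnew
  }
  F
}

#' Build a synthetic apo/holo pair with known ground-truth motion
#'
#' The holo form is the base complex unchanged; the apo form is the
#' relevant side of the complex (TCR chains for CDR perturbations, pMHC
#' chains for peptide perturbations) with the specified region rigidly
#' moved and/or internally deformed, then optionally placed in a random
#' rigid frame. Internal deformations are per-residue displacements along a
#' seeded direction, weighted by the profile, applied to all atoms of the
#' residue jointly and then projected orthogonal to rigid-body modes of the
#' region backbone; this makes the closed-form RMSD sqrt(sum d_i^2 / n)
#' exactly equal to the superposed backbone RMSD.
#'
#' @param base A holo-complex [structure_record()] (see
#'   [make_toy_complex()]).
#' @param spec A [perturbation_spec()].
#' @param global_motion Place the apo copy in a random rigid frame (so that
#'   frame alignment is actually exercised)?
#' @return List with `apo`, `holo` and `ground_truth` (applied
#'   displacements, expected unsuperposed and superposed backbone RMSD, and
#'   the expected per-residue backbone displacement profile).
#' @export
make_apo_holo_pair <- function(base, spec, global_motion = TRUE) {
  stopifnot(inherits(spec, "perturbation_spec"))
  if (base$state != "holo_complex") stop("base must be a holo complex")
  set.seed(spec$seed)
  side <- if (spec$loop_type == "peptide") "pmhc" else "tcr"
  keep_roles <- if (side == "tcr") c("tcr_alpha", "tcr_beta") else
    c("mhc_heavy", "beta2m", "peptide")
  apo_atoms <- base$atoms[base$atoms$role %in% keep_roles, , drop = FALSE]
  apo <- structure_record(paste0(base$structure_id, "_apo", spec$seed),
                          if (side == "tcr") "apo_tcr" else "apo_pmhc",
                          apo_atoms, resolution = base$resolution,
                          allele = base$allele)

  idx <- perturb_region_idx(apo, spec$loop_type)
  if (!length(idx)) stop("perturbation references a region absent from base: ",
                         spec$loop_type)
  at <- apo$atoms
  bb_idx <- idx[at$atom[idx] %in% BACKBONE_ATOMS]
  res_key <- paste(at$imgt, at$ins, sep = "|")
  res_levels <- unique(res_key[idx])
  L <- length(res_levels)

  # internal deformation
  D_all <- matrix(0, nrow(at), 3L)
  if (spec$internal_amplitude > 0) {
    e1 <- unit3(stats::rnorm(3L))
    e2 <- unit3(cross3(e1, unit3(stats::rnorm(3L))))
    w <- switch(spec$weight_profile,
                midpeak = if (L > 1L)
                  sin(pi * (seq_len(L) - 1L) / (L - 1L)) else 1,
                bimodal = if (L > 1L)
                  abs(sin(2 * pi * (seq_len(L) - 1L) / (L - 1L))) else 1,
                uniform = rep(1, L))
    X_bb <- as.matrix(at[bb_idx, c("x", "y", "z")])
    res_of_bb <- match(res_key[bb_idx], res_levels)
    res_xbar <- t(vapply(seq_len(L), function(r)
      colMeans(X_bb[res_of_bb == r, , drop = FALSE]), numeric(3L)))
    res_natoms <- tabulate(res_of_bb, L)
    Fres <- internal_deformation_field(res_xbar, w, res_natoms,
                                       spec$internal_amplitude, e1, e2)
    for (r in seq_len(L)) {
      rows <- idx[res_key[idx] == res_levels[r]]
      D_all[rows, ] <- matrix(Fres[r, ], nrow = length(rows), ncol = 3L,
                              byrow = TRUE)
    }
    at[idx, c("x", "y", "z")] <-
      as.matrix(at[idx, c("x", "y", "z")]) + D_all[idx, , drop = FALSE]
  }

  # rigid rotation about the anchor axis (first CA -> last CA of the region)
  if (spec$rigid_rotation != 0) {
    ca_rows <- idx[at$atom[idx] == "CA"]
    p1 <- as.numeric(at[ca_rows[1L], c("x", "y", "z")])
    p2 <- as.numeric(at[ca_rows[length(ca_rows)], c("x", "y", "z")])
    R <- axis_rotation(p2 - p1, spec$rigid_rotation * pi / 180)
    X <- as.matrix(at[idx, c("x", "y", "z")])
    at[idx, c("x", "y", "z")] <- sweep(sweep(X, 2L, p1) %*% t(R), 2L, p1, "+")
  }

  # rigid translation along a seeded direction
  u_rig <- unit3(stats::rnorm(3L))
  if (spec$rigid_displacement > 0) {
    X <- as.matrix(at[idx, c("x", "y", "z")])
    at[idx, c("x", "y", "z")] <-
      sweep(X, 2L, spec$rigid_displacement * u_rig, "+")
  }

  # ground truth from explicit per-atom bookkeeping (backbone atoms)
  X0 <- as.matrix(apo$atoms[bb_idx, c("x", "y", "z")])
  X1 <- as.matrix(at[bb_idx, c("x", "y", "z")])
  disp <- X1 - X0
  expected_unsuperposed <- sqrt(mean(rowSums(disp^2)))
  expected_superposed <- if (spec$internal_amplitude > 0) {
    sqrt(mean(rowSums(D_all[bb_idx, , drop = FALSE]^2)))
  } else 0
  bb_res <- res_key[bb_idx]
  per_res <- vapply(res_levels, function(k) {
    sqrt(mean(rowSums(D_all[bb_idx[bb_res == k], , drop = FALSE]^2)))
  }, 0)
  gt <- list(loop_type = spec$loop_type, spec = spec,
             displacement = disp, direction = u_rig,
             expected_unsuperposed_rmsd = expected_unsuperposed,
             expected_superposed_rmsd = expected_superposed,
             expected_per_residue = data.frame(
               imgt = as.integer(sub("\\|.*$", "", res_levels)),
               value = unname(per_res)))

  apo$atoms <- at
  if (global_motion) {
    R <- random_rotation()
    tr <- stats::rnorm(3L, 0, 10)
    fit <- structure(list(rotation = R, translation = tr, fit_rmsd = 0,
                          n_atoms = nrow(at), selection_name = "global"),
                     class = "superposition_result")
    apo <- transform_structure(apo, fit)
  }
  list(apo = apo, holo = base, ground_truth = gt)
}

#' Generate loop families with planted cluster structure
#'
#' `k` template loops separated in DTW space by at least `inter_sep`
#' Angstrom (rigid offsets of a common base loop in distinct directions);
#' each family has `m` members, the template plus Gaussian backbone noise of
#' scale `intra_sigma`, sharing `unique_seqs` distinct sequences. Anchors
#' are identical across all loops (never displaced), so anchor superposition
#' is exact.
#'
#' @param k Number of families.
#' @param m Members per family.
#' @param intra_sigma Within-family coordinate noise, Angstrom.
#' @param inter_sep Minimum between-template DTW separation, Angstrom.
#' @param unique_seqs Distinct sequences per family.
#' @param loop_len Loop length (residues).
#' @param loop_type Loop type label.
#' @param seed Integer seed.
#' @param id_prefix Prefix for generated loop ids.
#' @return List of `k * m` [loop_conformation()]s with attribute
#'   `"family"` (integer vector of planted family labels).
#' @export
make_loop_families <- function(k, m, intra_sigma = 0.05, inter_sep = 5,
                               unique_seqs = 5L, loop_len = 8L,
                               loop_type = "CDR3a", seed = 1L,
                               id_prefix = "fam") {
  if (k == 0L) return(structure(list(), family = integer()))
  set.seed(seed)
  n_total <- loop_len + 10L
  dh <- jittered_dihedrals(n_total, turn = rep(TRUE, n_total))
  base <- build_backbone(dh$phi, dh$psi)
  flat <- do.call(rbind, lapply(base, function(a)
    rbind(a$N, a$CA, a$C, a$O)))
  anchors_n <- flat[1:20, , drop = FALSE]
  loop_bb <- flat[20L + seq_len(4L * loop_len), , drop = FALSE]
  anchors_c <- flat[20L + 4L * loop_len + 1:20, , drop = FALSE]

  scale <- if (k > 1L) inter_sep / (2 * sin(pi / k)) else 0
  loops <- list()
  fam <- integer()
  for (j in seq_len(k)) {
    theta <- 2 * pi * (j - 1L) / max(k, 1L)
    offset <- scale * c(cos(theta), sin(theta), 0)
    seqs <- vapply(seq_len(unique_seqs), function(s)
      paste(sample(AA20, loop_len, replace = TRUE), collapse = ""), "")
    for (i in seq_len(m)) {
      noise <- matrix(stats::rnorm(length(loop_bb), 0, intra_sigma),
                      ncol = 3L)
      bb <- sweep(loop_bb + noise, 2L, offset, "+")
      loops[[length(loops) + 1L]] <- loop_conformation(
        sprintf("%s%02d_m%02d", id_prefix, j, i), loop_type,
        seqs[((i - 1L) %% unique_seqs) + 1L], bb, anchors_n, anchors_c)
      fam <- c(fam, j)
    }
  }
  attr(loops, "family") <- fam
  loops
}

#' Generate a motif table with planted anchors
#'
#' Builds a per-position amino-acid proportion table for one allele and
#' peptide length: at planted positions the stated amino acid takes the
#' stated proportion and the remainder is spread uniformly over the other
#' 19 amino acids; unplanted positions are uniform over all 20.
#'
#' @param anchors Named list: position (as character) -> `list(aa =, prop =)`.
#' @param peptide_length Peptide length.
#' @param allele Allele name.
#' @return A motif profile data frame (see [build_simplified_motif()]).
#' @export
make_motif_table <- function(anchors, peptide_length = 9L,
                             allele = "TOY*01:01") {
  rows <- list()
  for (pos in seq_len(peptide_length)) {
    key <- as.character(pos)
    if (key %in% names(anchors)) {
      aa <- anchors[[key]]$aa
      prop <- anchors[[key]]$prop
      if (prop > 1) stop("planted proportion above 1 at position ", pos)
      others <- setdiff(AA20, aa)
      rows[[length(rows) + 1L]] <- data.frame(
        allele = allele, length = peptide_length, position = pos,
        aa = c(aa, others),
        proportion = c(prop, rep((1 - prop) / length(others),
                                 length(others))),
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        allele = allele, length = peptide_length, position = pos,
        aa = AA20, proportion = rep(1 / 20, 20L), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a background TCR repertoire table
#'
#' `n` unique synthetic TCR rows with V/J gene calls sampled from the given
#' frequency vectors and random CDR sequences.
#'
#' @param n Number of rows.
#' @param gene_freqs Named list of named frequency vectors for columns
#'   `TRAV`, `TRAJ`, `TRBV`, `TRBJ`; each must sum to 1.
#' @param cdr3_length_range Inclusive range of CDR3 lengths.
#' @param seed Integer seed.
#' @return Data frame with gene calls and six CDR sequence columns; all rows
#'   unique.
#' @export
make_background_repertoire <- function(n = 5000L,
                                       gene_freqs = default_gene_freqs(),
                                       cdr3_length_range = c(10L, 18L),
                                       seed = 1L) {
  for (nm in names(gene_freqs)) {
    if (abs(sum(gene_freqs[[nm]]) - 1) > 1e-9) {
      stop("gene frequencies for ", nm, " do not sum to 1")
    }
  }
  set.seed(seed)
  pick <- function(freqs) sample(names(freqs), n, replace = TRUE,
                                 prob = freqs)
  rand_seq <- function(len) vapply(len, function(l)
    paste(sample(AA20, l, replace = TRUE), collapse = ""), "")
  tab <- data.frame(
    TRAV = pick(gene_freqs$TRAV), TRAJ = pick(gene_freqs$TRAJ),
    TRBV = pick(gene_freqs$TRBV), TRBJ = pick(gene_freqs$TRBJ),
    cdr1a = rand_seq(rep(6L, n)), cdr2a = rand_seq(rep(6L, n)),
    cdr3a = rand_seq(sample(seq.int(cdr3_length_range[1L],
                                    cdr3_length_range[2L]), n,
                            replace = TRUE)),
    cdr1b = rand_seq(rep(6L, n)), cdr2b = rand_seq(rep(6L, n)),
    cdr3b = rand_seq(sample(seq.int(cdr3_length_range[1L],
                                    cdr3_length_range[2L]), n,
                            replace = TRUE)),
    stringsAsFactors = FALSE)
  while (anyDuplicated(tab)) {
    dup <- which(duplicated(tab))
    tab$cdr3b[dup] <- rand_seq(rep(cdr3_length_range[2L], length(dup)))
  }
  tab
}

#' @rdname make_background_repertoire
#' @export
default_gene_freqs <- function() {
  mk <- function(prefix, k) {
    f <- rep(1 / k, k)
    names(f) <- paste0(prefix, seq_len(k))
    f
  }
  list(TRAV = mk("TRAV", 10L), TRAJ = mk("TRAJ", 8L),
       TRBV = mk("TRBV", 10L), TRBJ = mk("TRBJ", 8L))
}

#' Construct a complex with a planted half-split peptide contact pattern
#'
#' A hand-built holo complex in which CDR3a atoms sit 4 Angstrom from
#' peptide positions p1..p ceiling(N/2) only and CDR3b atoms 4 Angstrom
#' from the remaining positions only; all other CDR loops and the MHC are
#' kept out of contact range. Used to validate the peptide-half contact
#' profile.
#'
#' @param seed Integer seed.
#' @param peptide_length Peptide length.
#' @return A `holo_complex` [structure_record()] with regions assigned.
#' @export
make_half_contact_complex <- function(seed = 1L, peptide_length = 9L) {
  set.seed(seed)
  mid <- ceiling(peptide_length / 2)
  spacing <- 8  # CA-CA spacing wide enough that only the paired position is in range
  compact_residue <- function(chain_id, role, imgt, aa, ca) {
    # tight synthetic residue: backbone atoms within 0.8 A of the CA
    offs <- list(N = c(-0.8, 0, 0), CA = c(0, 0, 0), C = c(0.8, 0, 0),
                 O = c(0.8, 0.8, 0))
    do.call(rbind, lapply(names(offs), function(nm) {
      p <- ca + offs[[nm]]
      data.frame(chain_id = chain_id, role = role, imgt = imgt, ins = "",
                 aa = aa, atom = nm, element = substr(nm, 1L, 1L),
                 x = p[1L], y = p[2L], z = p[3L], stringsAsFactors = FALSE)
    }))
  }
  rows <- list()
  for (p in seq_len(peptide_length)) {
    rows[[length(rows) + 1L]] <- compact_residue(
      "P", "peptide", p, sample(AA20, 1L), c(spacing * p, 0, 0))
  }
  # CDR3a residues 4 A above the N-half positions, CDR3b above the C-half
  for (p in seq_len(mid)) {
    rows[[length(rows) + 1L]] <- compact_residue(
      "A", "tcr_alpha", 104L + p, sample(AA20, 1L), c(spacing * p, 0, 4))
  }
  for (p in seq.int(mid + 1L, peptide_length)) {
    rows[[length(rows) + 1L]] <- compact_residue(
      "B", "tcr_beta", 104L + p - mid, sample(AA20, 1L),
      c(spacing * p, 0, 4))
  }
  # remaining obligatory chains, far out of contact range
  rows[[length(rows) + 1L]] <- compact_residue("A", "tcr_alpha", 1L, "A",
                                               c(0, 500, 0))
  rows[[length(rows) + 1L]] <- compact_residue("B", "tcr_beta", 1L, "A",
                                               c(0, 600, 0))
  rows[[length(rows) + 1L]] <- compact_residue("M", "mhc_heavy", 10L, "A",
                                               c(0, 700, 0))
  rec <- structure_record(sprintf("halfdemo%04d", seed), "holo_complex",
                          do.call(rbind, rows), resolution = 2.0)
  assign_regions(rec)
}
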