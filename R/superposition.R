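# superposition: rigid-body fitting on named atom selections and the
# conformational-difference metrics (backbone RMSD, per-residue heavy-atom
# RMSD, dihedral D-score).

#' Least-squares rigid superposition (Kabsch)
#'
#' Fits the proper rotation `R` and translation `t` minimising the RMSD of
#' `R x + t` over the target, with correspondence given by row order.
#' Reflections are corrected so `det(R) = +1`.
#'
#' @param mobile,target Numeric n x 3 coordinate matrices, `n >= 3`.
#' @param selection_name Label stored in the result.
#' @return A `superposition_result`: list with `rotation` (3 x 3),
#'   `translation` (3-vector), `fit_rmsd` (Angstrom), `n_atoms`,
#'   `selection_name`.
#' @export
kabsch_fit <- function(mobile, target, selection_name = "selection") {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)) || ncol(mobile) != 3L) {
    stop("mobile and target must be equal-size n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 atoms to superpose")
  cm <- colMeans(mobile); ct <- colMeans(target)
  mc <- sweep(mobile, 2L, cm); tc <- sweep(target, 2L, ct)
  H <- crossprod(mc, tc)
  sv <- svd(H)
  if (min(sv$d) < 1e-10) {
    stop("degenerate (collinear or coincident) point set in superposition")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- ct - as.vector(R %*% cm)
  moved <- sweep(mobile %*% t(R), 2L, tr, "+")
  fit_rmsd <- sqrt(mean(rowSums((moved - target)^2)))
  structure(list(rotation = R, translation = tr, fit_rmsd = fit_rmsd,
                 n_atoms = n, selection_name = selection_name),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition on %s: %d atoms, fit RMSD %.4f A\n",
              x$selection_name, x$n_atoms, x$fit_rmsd))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 matrix.
#' @param fit A `superposition_result`.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, fit) {
  sweep(as.matrix(xyz) %*% t(fit$rotation), 2L, fit$translation, "+")
}

# Apply a transform to every atom of a structure record.
transform_structure <- function(record, fit) {
  xyz <- apply_transform(as.matrix(record$atoms[, c("x", "y", "z")]), fit)
  record$atoms$x <- xyz[, 1L]
  record$atoms$y <- xyz[, 2L]
  record$atoms$z <- xyz[, 3L]
  record
}

# Match atoms of two atom tables by (role, imgt, ins, atom name), restricted
# to `atom_names` and optionally to residues with complete backbone on both
# sides. Returns list(a = matrix, b = matrix, keys = residue keys).
matched_coords <- function(a, b, atom_names = BACKBONE_ATOMS,
                           require_complete = TRUE) {
  asel <- a[a$atom %in% atom_names, , drop = FALSE]
  bsel <- b[b$atom %in% atom_names, , drop = FALSE]
  ka <- paste(asel$role, asel$imgt, asel$ins, asel$atom, sep = "|")
  kb <- paste(bsel$role, bsel$imgt, bsel$ins, bsel$atom, sep = "|")
  common <- intersect(ka, kb)
  if (require_complete) {
    # keep only residues contributing all requested atom names on both sides
    res_of <- function(k) sub("\\|[^|]+$", "", k)
    cnt <- table(res_of(common))
    full <- names(cnt)[cnt == length(atom_names)]
    common <- common[res_of(common) %in% full]
  }
  ia <- match(common, ka); ib <- match(common, kb)
  list(a = as.matrix(asel[ia, c("x", "y", "z")]),
       b = as.matrix(bsel[ib, c("x", "y", "z")]),
       keys = common)
}

# Generic region alignment: fit `mobile` onto `target` using backbone atoms
# of the given region(s) on the given role(s); move the whole structure.
align_on_region <- function(mobile, target, roles, regions, selection_name) {
  msel <- mobile$atoms[mobile$atoms$role %in% roles &
                         !is.na(mobile$atoms$region) &
                         mobile$atoms$region %in% regions, , drop = FALSE]
  tsel <- target$atoms[target$atoms$role %in% roles &
                         !is.na(target$atoms$region) &
                         target$atoms$region %in% regions, , drop = FALSE]
  mc <- matched_coords(msel, tsel)
  n_res <- length(unique(sub("\\|[^|]+$", "", mc$keys)))
  if (n_res < 3L) {
    stop("fewer than 3 shared ", selection_name,
         " residues; cannot align structures")
  }
  fit <- kabsch_fit(mc$a, mc$b, selection_name = selection_name)
  out <- transform_structure(mobile, fit)
  attr(out, "superposition") <- fit
  out
}

#' Align an apo TCR onto a holo TCR on the framework regions
#'
#' The rigid transform is fitted on backbone atoms of framework (FR)
#' positions present in both structures, both chains pooled, and applied to
#' all apo coordinates.
#'
#' @param apo,holo [structure_record()]s containing `tcr_alpha` + `tcr_beta`
#'   with regions assigned.
#' @return The moved apo record; the fit is attached as attribute
#'   `"superposition"`.
#' @export
align_tcr_framework <- function(apo, holo) {
  align_on_region(apo, holo, c("tcr_alpha", "tcr_beta"), "FR",
                  "TCR framework")
}

#' Align an apo pMHC onto a holo pMHC on the groove floor
#'
#' As [align_tcr_framework()], fitted on backbone atoms of the MHC
#' groove-floor strands.
#'
#' @param apo,holo [structure_record()]s containing `mhc_heavy` with the
#'   `groove_floor` region assigned.
#' @return The moved apo record with attribute `"superposition"`.
#' @export
align_mhc_floor <- function(apo, holo) {
  align_on_region(apo, holo, "mhc_heavy", "groove_floor", "MHC groove floor")
}

rmsd_xyz <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

#' Backbone RMSD between corresponding residue selections
#'
#' RMSD over N, CA, C, O of residues matched by IMGT (number, insertion
#' code) within each role; residues lacking a complete backbone on either
#' side are excluded. With `superpose_first = TRUE` the selections are
#' Kabsch-fitted on those same atoms before measuring (the loop-deformation
#' mode, which removes bulk movement).
#'
#' @param a,b Atom data frames (e.g. region selections of two structures).
#' @param superpose_first Remove the best rigid fit first?
#' @return RMSD in Angstrom, with attribute `n_atoms`.
#' @export
backbone_rmsd <- function(a, b, superpose_first = FALSE) {
  mc <- matched_coords(a, b)
  if (nrow(mc$a) == 0L) stop("no matched residues with complete backbone")
  xa <- mc$a
  if (superpose_first) {
    fit <- kabsch_fit(xa, mc$b, selection_name = "loop backbone")
    xa <- apply_transform(xa, fit)
  }
  out <- rmsd_xyz(xa, mc$b)
  attr(out, "n_atoms") <- nrow(xa)
  out
}

#' Per-residue heavy-atom RMSD
#'
#' For each residue matched by IMGT (number, insertion code), the RMSD over
#' the heavy atoms shared by both sides (side chains included). The caller
#' is expected to have superposed the selections beforehand. Residue pairs
#' sharing no atoms are reported as `NA`, not zero.
#'
#' @param a,b Atom data frames of corresponding selections.
#' @return Data frame: `role`, `imgt`, `ins`, `value` (Angstrom), `n_atoms`.
#' @export
per_residue_heavy_rmsd <- function(a, b) {
  a <- a[a$element != "H", , drop = FALSE]
  b <- b[b$element != "H", , drop = FALSE]
  ka <- paste(a$role, a$imgt, a$ins, sep = "|")
  kb <- paste(b$role, b$imgt, b$ins, sep = "|")
  keys <- intersect(ka, kb)
  rows <- lapply(keys, function(k) {
    ai <- a[ka == k, , drop = FALSE]
    bi <- b[kb == k, , drop = FALSE]
    shared <- intersect(ai$atom, bi$atom)
    parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
    if (!length(shared)) {
      return(data.frame(role = parts[1L], imgt = as.integer(parts[2L]),
                        ins = ifelse(length(parts) > 2L, parts[3L], ""),
                        value = NA_real_, n_atoms = 0L,
                        stringsAsFactors = FALSE))
    }
    xa <- as.matrix(ai[match(shared, ai$atom), c("x", "y", "z")])
    xb <- as.matrix(bi[match(shared, bi$atom), c("x", "y", "z")])
    data.frame(role = parts[1L], imgt = as.integer(parts[2L]),
               ins = ifelse(length(parts) > 2L, parts[3L], ""),
               value = rmsd_xyz(xa, xb), n_atoms = length(shared),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$role, out$imgt, out$ins), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Backbone dihedral angles of a chain segment
#'
#' Computes standard phi (C[i-1]-N-CA-C) and psi (N-CA-C-N[i+1]) torsions in
#' (-pi, pi] for consecutive residues. Angles across a chain break (peptide
#' C-N distance above `break_tol`) and angles lacking a neighbour or a
#' backbone atom are `NA`.
#'
#' @param atoms Atom data frame of a single chain (one role).
#' @param break_tol Chain-break C-N distance threshold, Angstrom.
#' @return Data frame: `imgt`, `ins`, `phi`, `psi` (radians).
#' @export
compute_dihedrals <- function(atoms, break_tol = 2.5) {
  rt <- residue_table(atoms)
  if (length(unique(rt$chain_id)) > 1L) {
    stop("compute_dihedrals expects a single chain")
  }
  n <- nrow(rt)
  getat <- function(i, name) {
    r <- atoms[atoms$imgt == rt$imgt[i] & atoms$ins == rt$ins[i] &
                 atoms$atom == name, , drop = FALSE]
    if (nrow(r) != 1L) return(NULL)
    c(r$x, r$y, r$z)
  }
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    N <- getat(i, "N"); CA <- getat(i, "CA"); C <- getat(i, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (i > 1L) {
      Cp <- getat(i - 1L, "C")
      if (!is.null(Cp) && vnorm(N - Cp) <= break_tol) {
        phi[i] <- dihedral_angle(Cp, N, CA, C)
      }
    }
    if (i < n) {
      Nn <- getat(i + 1L, "N")
      if (!is.null(Nn) && vnorm(Nn - C) <= break_tol) {
        psi[i] <- dihedral_angle(N, CA, C, Nn)
      }
    }
  }
  data.frame(imgt = rt$imgt, ins = rt$ins, phi = phi, psi = psi,
             stringsAsFactors = FALSE)
}

#' Dihedral D-score between two conformations
#'
#' Sums, over residues matched by IMGT (number, insertion code),
#' `2 (1 - cos(phi_A - phi_B)) + 2 (1 - cos(psi_A - psi_B))`. Angle pairs
#' with a missing value on either side are skipped, not imputed; the number
#' of contributing angle pairs is attached as an attribute.
#'
#' @param a,b Dihedral tables from [compute_dihedrals()].
#' @param normalize Divide by the number of contributing angle pairs?
#'   (The raw sum is the default; the score is bounded by `8 * n_residues`.)
#' @return D-score (dimensionless) with attribute `n_angle_pairs`.
#' @export
dscore <- function(a, b, normalize = FALSE) {
  key_a <- paste(a$imgt, a$ins, sep = "|")
  key_b <- paste(b$imgt, b$ins, sep = "|")
  common <- intersect(key_a, key_b)
  ia <- match(common, key_a); ib <- match(common, key_b)
  total <- 0
  npairs <- 0L
  for (col in c("phi", "psi")) {
    va <- a[[col]][ia]; vb <- b[[col]][ib]
    ok <- !is.na(va) & !is.na(vb)
    total <- total + sum(2 * (1 - cos(va[ok] - vb[ok])))
    npairs <- npairs + sum(ok)
  }
  if (npairs == 0L) stop("no overlapping dihedral angles between the series")
  out <- if (normalize) total / npairs else total
  attr(out, "n_angle_pairs") <- npairs
  out
}
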