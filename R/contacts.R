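# contacts: heavy-atom contact detection between TCR CDR loops and the
# pMHC-I, per-position fingerprints, dominant-loop assignment and
# peptide-half contact profiles.

# Grid (cell-list) neighbour search: all pairs (i in A, j in B) with
# Euclidean distance strictly below cutoff. Cells have edge = cutoff, so
# only the 27 neighbouring cells of a query atom need scanning.
grid_close_pairs <- function(A, B, cutoff) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) == 0L || nrow(B) == 0L) {
    return(data.frame(i = integer(), j = integer(), distance = numeric()))
  }
  cell_b <- floor(B / cutoff)
  keys_b <- paste(cell_b[, 1L], cell_b[, 2L], cell_b[, 3L], sep = ",")
  index <- split(seq_len(nrow(B)), keys_b)
  cell_a <- floor(A / cutoff)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- integer(); out_j <- integer(); out_d <- numeric()
  for (i in seq_len(nrow(A))) {
    neigh <- sweep(offs, 2L, cell_a[i, ], "+")
    keys <- paste(neigh[, 1L], neigh[, 2L], neigh[, 3L], sep = ",")
    cand <- unlist(index[keys], use.names = FALSE)
    if (!length(cand)) next
    d <- sqrt(colSums((t(B[cand, , drop = FALSE]) - A[i, ])^2))
    hit <- d < cutoff
    if (any(hit)) {
      out_i <- c(out_i, rep.int(i, sum(hit)))
      out_j <- c(out_j, cand[hit])
      out_d <- c(out_d, d[hit])
    }
  }
  data.frame(i = out_i, j = out_j, distance = out_d)
}

#' Find TCR CDR to pMHC heavy-atom contacts in a complex
#'
#' All heavy-atom pairs between TCR CDR-loop atoms and pMHC (MHC heavy chain
#' or peptide) atoms at Euclidean distance strictly below the cutoff.
#' Non-CDR TCR atoms are ignored; only polymer heavy atoms are considered.
#' Uses a cell-list spatial index (equivalent to the all-pairs scan).
#'
#' @param holo A holo-complex [structure_record()] with regions assigned.
#' @param cutoff Contact distance cutoff in Angstrom (strict `<`).
#' @return Data frame of contact pairs: `structure_id`, `loop`, `tcr_role`,
#'   `tcr_imgt`, `tcr_ins`, `tcr_atom`, `target_role`, `target_imgt`,
#'   `target_ins`, `target_atom`, `distance`.
#' @export
find_contacts <- function(holo, cutoff = 5.0) {
  if (holo$state != "holo_complex") stop("find_contacts needs a holo complex")
  at <- holo$atoms
  if (!"peptide" %in% at$role) stop("complex lacks a peptide chain")
  tcr <- at[at$role %in% c("tcr_alpha", "tcr_beta") &
              !is.na(at$region) & at$region %in% c("CDR1", "CDR2", "CDR3") &
              at$element != "H", , drop = FALSE]
  pmhc <- at[at$role %in% c("mhc_heavy", "peptide") & at$element != "H", ,
             drop = FALSE]
  pr <- grid_close_pairs(tcr[, c("x", "y", "z")], pmhc[, c("x", "y", "z")],
                         cutoff)
  loop <- paste0(tcr$region[pr$i],
                 ifelse(tcr$role[pr$i] == "tcr_alpha", "a", "b"))
  out <- data.frame(
    structure_id = rep(holo$structure_id, nrow(pr)),
    loop = loop,
    tcr_role = tcr$role[pr$i], tcr_imgt = tcr$imgt[pr$i],
    tcr_ins = tcr$ins[pr$i], tcr_atom = tcr$atom[pr$i],
    target_role = pmhc$role[pr$j], target_imgt = pmhc$imgt[pr$j],
    target_ins = pmhc$ins[pr$j], target_atom = pmhc$atom[pr$j],
    distance = pr$distance,
    stringsAsFactors = FALSE)
  out <- out[order(out$loop, out$tcr_imgt, out$target_role, out$target_imgt,
                   out$tcr_atom, out$target_atom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-position contact fingerprint
#'
#' For each target position (MHC heavy-chain IMGT number or peptide
#' position), the fraction of its contacting atom pairs contributed by each
#' CDR loop. With contacts from several complexes, fractions are computed
#' per complex first and then averaged across the complexes contacting that
#' position, so heavily crystallised TCRs do not dominate.
#'
#' @param contacts Contact table from [find_contacts()] (one or many
#'   complexes row-bound).
#' @param target `"mhc"` or `"peptide"`.
#' @return A `contact_fingerprint` data frame: `position`, `loop`,
#'   `fraction`, `n_contacts` (total atom pairs at that position across
#'   complexes). Empty input gives an empty fingerprint.
#' @export
fingerprint <- function(contacts, target = c("mhc", "peptide")) {
  target <- match.arg(target)
  role <- if (target == "mhc") "mhc_heavy" else "peptide"
  sub <- contacts[contacts$target_role == role, , drop = FALSE]
  empty <- data.frame(position = integer(), loop = character(),
                      fraction = numeric(), n_contacts = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(sub)) {
    class(empty) <- c("contact_fingerprint", class(empty))
    attr(empty, "target") <- target
    return(empty)
  }
  rows <- list()
  for (pos in sort(unique(sub$target_imgt))) {
    p <- sub[sub$target_imgt == pos, ]
    per_complex <- lapply(split(p, p$structure_id), function(g) {
      tab <- table(factor(g$loop, levels = LOOP_TYPES))
      tab / sum(tab)
    })
    frac <- Reduce(`+`, per_complex) / length(per_complex)
    keep <- frac > 0
    rows[[length(rows) + 1L]] <- data.frame(
      position = pos, loop = names(frac)[keep],
      fraction = as.numeric(frac[keep]), n_contacts = nrow(p),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("contact_fingerprint", class(out))
  attr(out, "target") <- target
  out
}

#' Dominant contacting loop per target position
#'
#' The loop with the largest contact fraction at each position, emitted only
#' when that fraction strictly exceeds `min_fraction`. Exact ties are broken
#' by the fixed loop order CDR1a..CDR3b and recorded in the `"ties"`
#' attribute.
#'
#' @param fp A [fingerprint()].
#' @param min_fraction Dominance threshold (default 0.01, i.e. over 1% of a
#'   position's contacts).
#' @return Data frame: `position`, `loop`, `fraction`; attribute `"ties"`
#'   lists tied positions.
#' @export
dominant_loops <- function(fp, min_fraction = 0.01) {
  ties <- integer()
  rows <- list()
  for (pos in unique(fp$position)) {
    p <- fp[fp$position == pos, ]
    p <- p[order(match(p$loop, LOOP_TYPES)), ]
    best <- which.max(p$fraction)
    if (sum(p$fraction == p$fraction[best]) > 1L) ties <- c(ties, pos)
    if (p$fraction[best] > min_fraction) {
      rows[[length(rows) + 1L]] <- data.frame(
        position = pos, loop = p$loop[best], fraction = p$fraction[best],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), loop = character(),
               fraction = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ties") <- ties
  out
}

#' Peptide-half contact profile
#'
#' Aggregates loop contact fractions over the N-terminal half (p1 to
#' p ceiling(N/2)) and the C-terminal remainder of the peptide, weighting
#' positions by their contact counts, and reports which loop dominates each
#' half.
#'
#' @param fp A peptide-target [fingerprint()].
#' @param peptide_length Peptide length N.
#' @return List with `first_half` and `second_half` (named fraction
#'   vectors over loops) and `dominant` (length-2 character vector).
#' @export
peptide_half_profile <- function(fp, peptide_length) {
  if (attr(fp, "target") != "peptide") stop("need a peptide fingerprint")
  if (peptide_length < 8L) {
    warning("peptide shorter than 8 residues; halves are poorly defined")
  }
  mid <- ceiling(peptide_length / 2)
  halves <- list(first_half = fp[fp$position <= mid, , drop = FALSE],
                 second_half = fp[fp$position > mid, , drop = FALSE])
  agg <- lapply(halves, function(h) {
    w <- numeric(length(LOOP_TYPES)); names(w) <- LOOP_TYPES
    if (nrow(h)) {
      contrib <- h$fraction * h$n_contacts
      for (k in seq_len(nrow(h))) w[h$loop[k]] <- w[h$loop[k]] + contrib[k]
      if (sum(w) > 0) w <- w / sum(w)
    }
    w
  })
  dominant <- vapply(agg, function(w) {
    if (all(w == 0)) NA_character_ else names(w)[which.max(w)]
  }, "")
  list(first_half = agg$first_half, second_half = agg$second_half,
       dominant = dominant)
}

#' Partition MHC antigen-binding positions by TCR contact
#'
#' Positions carrying at least one retained contact go to `tcr_contact`;
#' the remaining positions of the antigen-binding domain set go to
#' `non_contact`. The partition is disjoint and covers the domain set.
#'
#' @param fp An MHC-target [fingerprint()].
#' @param antigen_binding_positions Integer vector of domain positions.
#' @return List with sorted integer vectors `tcr_contact`, `non_contact`.
#' @export
partition_mhc_positions <- function(fp, antigen_binding_positions) {
  contacted <- sort(unique(fp$position[fp$n_contacts > 0]))
  tcr_contact <- intersect(antigen_binding_positions, contacted)
  list(tcr_contact = sort(tcr_contact),
       non_contact = sort(setdiff(antigen_binding_positions, tcr_contact)))
}
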