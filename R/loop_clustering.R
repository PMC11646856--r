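# loop_clustering: anchor-aligned, length-independent DTW distances between
# CDR loop conformations, density-based clustering, canonical/pseudo
# labelling and the apo-holo cluster-shift taxonomy.

#' Construct a loop conformation
#'
#' A CDR loop with its backbone coordinates and the five flanking anchor
#' residues on each side (backbone only). Coordinates are ordered N to C,
#' four backbone atoms (N, CA, C, O) per residue.
#'
#' @param loop_id Unique identifier.
#' @param loop_type One of `r paste(LOOP_TYPES, collapse = ", ")`.
#' @param sequence One-letter amino-acid string of the loop.
#' @param backbone (4 * L) x 3 matrix of loop backbone coordinates.
#' @param anchors_n,anchors_c 20 x 3 matrices (5 residues x 4 backbone
#'   atoms) of the N- and C-side anchors.
#' @return An object of class `loop_conformation`.
#' @export
loop_conformation <- function(loop_id, loop_type, sequence, backbone,
                              anchors_n, anchors_c) {
  backbone <- as.matrix(backbone)
  anchors_n <- as.matrix(anchors_n); anchors_c <- as.matrix(anchors_c)
  if (nrow(anchors_n) != 20L || nrow(anchors_c) != 20L) {
    stop("anchors must contain exactly 5 residues (20 backbone atoms) per side")
  }
  if (nrow(backbone) %% 4L != 0L || nrow(backbone) == 0L) {
    stop("backbone must hold 4 atoms per residue and at least one residue")
  }
  if (nchar(sequence) != nrow(backbone) / 4L) {
    stop("sequence length does not match backbone residue count")
  }
  structure(list(loop_id = loop_id, loop_type = loop_type,
                 sequence = sequence, backbone = backbone,
                 anchors_n = anchors_n, anchors_c = anchors_c),
            class = "loop_conformation")
}

loop_length <- function(loop) nrow(loop$backbone) %/% 4L

#' Extract a CDR loop conformation from a structure
#'
#' Takes the loop residues of the given type plus the five residues
#' immediately flanking the loop on each side in the chain; all must have a
#' complete backbone.
#'
#' @param record A [structure_record()] with regions assigned.
#' @param loop_type One of `r paste(LOOP_TYPES, collapse = ", ")`.
#' @param loop_id Identifier; defaults to `<structure_id>:<loop_type>`.
#' @return A [loop_conformation()].
#' @export
extract_loop <- function(record, loop_type,
                         loop_id = paste(record$structure_id, loop_type,
                                         sep = ":")) {
  p <- loop_type_parts(loop_type)
  at <- record$atoms[record$atoms$role == p$role, , drop = FALSE]
  rt <- residue_table(at)
  in_loop <- !is.na(rt$region) & rt$region == p$region
  if (!any(in_loop)) stop("structure has no ", loop_type, " residues")
  i1 <- min(which(in_loop)); i2 <- max(which(in_loop))
  if (i1 <= 5L || i2 + 5L > nrow(rt)) {
    stop("fewer than 5 flanking anchor residues available for ", loop_type)
  }
  idx_loop <- which(in_loop)
  idx_n <- (i1 - 5L):(i1 - 1L)
  idx_c <- (i2 + 1L):(i2 + 5L)
  grab <- function(idx) {
    rows <- lapply(idx, function(i) {
      r <- at[at$imgt == rt$imgt[i] & at$ins == rt$ins[i] &
                at$atom %in% BACKBONE_ATOMS, , drop = FALSE]
      if (nrow(r) != 4L) stop("incomplete backbone in loop/anchor residue ",
                              rt$imgt[i], rt$ins[i], " of ", loop_type)
      r <- r[match(BACKBONE_ATOMS, r$atom), ]
      as.matrix(r[, c("x", "y", "z")])
    })
    do.call(rbind, rows)
  }
  loop_conformation(loop_id, loop_type,
                    paste(rt$aa[idx_loop], collapse = ""),
                    grab(idx_loop), grab(idx_n), grab(idx_c))
}

#' Superpose one loop onto another's anchor frame
#'
#' Kabsch fit of the 40 anchor backbone atoms (5 residues flanking each
#' side) of `a` onto those of `b`; the whole of `a` (anchors and loop) is
#' moved. Loop lengths need not match.
#'
#' @param a,b [loop_conformation()]s.
#' @return `a` moved into `b`'s anchor frame.
#' @export
anchor_superpose <- function(a, b) {
  fit <- kabsch_fit(rbind(a$anchors_n, a$anchors_c),
                    rbind(b$anchors_n, b$anchors_c),
                    selection_name = "loop anchors")
  a$backbone <- apply_transform(a$backbone, fit)
  a$anchors_n <- apply_transform(a$anchors_n, fit)
  a$anchors_c <- apply_transform(a$anchors_c, fit)
  attr(a, "superposition") <- fit
  a
}

# Residue-level local cost matrix: mean Euclidean distance over the four
# backbone atoms of the matched residue pair.
dtw_cost_matrix <- function(a, b) {
  la <- loop_length(a); lb <- loop_length(b)
  cost <- matrix(0, la, lb)
  for (k in 1:4) {
    ax <- a$backbone[seq(k, by = 4L, length.out = la), , drop = FALSE]
    bx <- b$backbone[seq(k, by = 4L, length.out = lb), , drop = FALSE]
    d2 <- outer(rowSums(ax^2), rowSums(bx^2), "+") - 2 * ax %*% t(bx)
    d2[d2 < 0] <- 0
    cost <- cost + sqrt(d2)
  }
  cost / 4
}

#' Dynamic-time-warping distance between two loop conformations
#'
#' Monotone, boundary-pinned warping over the residue sequences with local
#' cost equal to the mean Euclidean distance of the four backbone atoms of
#' the matched residue pair. The symmetric step pattern weights diagonal
#' steps 2 and horizontal/vertical steps 1, and the accumulated cost is
#' normalised by `n + m` (the warping-path length in step weights), making
#' the distance comparable across loop lengths. The caller superposes `a`
#' into `b`'s anchor frame first (see [anchor_superpose()]).
#'
#' @param a,b [loop_conformation()]s in a common frame.
#' @return Normalised DTW distance, Angstrom.
#' @export
dtw_distance <- function(a, b) {
  la <- loop_length(a); lb <- loop_length(b)
  if (la == 0L || lb == 0L) stop("empty loop in DTW")
  cost <- dtw_cost_matrix(a, b)
  D <- matrix(Inf, la + 1L, lb + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      c_ij <- cost[i, j]
      D[i + 1L, j + 1L] <- min(D[i, j] + 2 * c_ij,
                               D[i, j + 1L] + c_ij,
                               D[i + 1L, j] + c_ij)
    }
  }
  D[la + 1L, lb + 1L] / (la + lb)
}

#' Pairwise anchor-aligned DTW distance matrix
#'
#' For every unordered pair, the first loop is superposed onto the second's
#' anchor frame and the DTW distance computed. The result is symmetric with
#' a zero diagonal.
#'
#' @param loops List of [loop_conformation()]s of one loop type.
#' @return A `distance_matrix`: symmetric matrix with loop ids as dimnames.
#' @export
build_distance_matrix <- function(loops) {
  ids <- vapply(loops, function(l) l$loop_id, "")
  if (anyDuplicated(ids)) stop("duplicate loop_id in input")
  types <- unique(vapply(loops, function(l) l$loop_type, ""))
  if (length(types) > 1L) stop("all loops must share one loop_type")
  n <- length(loops)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- dtw_distance(anchor_superpose(loops[[i]], loops[[j]]),
                          loops[[j]])
        m[i, j] <- d
        m[j, i] <- d
      }
    }
  }
  class(m) <- c("distance_matrix", class(m))
  m
}

#' Cluster loop conformations and label canonical/pseudo clusters
#'
#' Runs density-based hierarchical clustering ([hdbscan_precomputed()]) on
#' the precomputed DTW distance matrix; unassigned loops are noise. Each
#' cluster is labelled *canonical* if it contains more than two unique loop
#' sequences, otherwise *pseudo*.
#'
#' @param dmat Distance matrix from [build_distance_matrix()].
#' @param sequences Named character vector of loop sequences (names = loop
#'   ids), or `NULL` to label all clusters canonical/pseudo-agnostically.
#' @param min_cluster_size Minimum cluster size (default 5).
#' @return Data frame: `loop_id`, `cluster` (integer, `NA` for noise),
#'   `status` (`"canonical"`, `"pseudo"`, `"noise"`), `label` (e.g.
#'   `"canonical 2"`). Carries a `run_id` attribute identifying the
#'   clustering run.
#' @export
cluster_loops <- function(dmat, sequences = NULL, min_cluster_size = 5L) {
  ids <- rownames(dmat)
  ord <- order(ids)   # deterministic input ordering by loop_id
  dmat <- dmat[ord, ord, drop = FALSE]
  ids <- ids[ord]
  labels <- hdbscan_precomputed(dmat, min_cluster_size = min_cluster_size)
  status <- rep("noise", length(ids))
  for (k in unique(labels[labels > 0L])) {
    members <- ids[labels == k]
    nseq <- if (is.null(sequences)) Inf else
      length(unique(sequences[members]))
    status[labels == k] <- if (nseq > 2L) "canonical" else "pseudo"
  }
  out <- data.frame(loop_id = ids,
                    cluster = ifelse(labels > 0L, labels, NA_integer_),
                    status = status,
                    stringsAsFactors = FALSE)
  out$label <- ifelse(out$status == "noise", "noise",
                      paste(out$status, out$cluster))
  attr(out, "run_id") <- sprintf("run-%d-%.10g", length(ids), sum(dmat))
  out
}

SHIFT_CATEGORIES <- c(
  "Canonical to Pseudo Cluster", "Canonical Cluster to Noise",
  "Canonical Cluster Same", "Canonical Cluster Shift", "Noise",
  "Noise to Canonical Cluster", "Noise to Pseudo Cluster",
  "Pseudo to Canonical", "Pseudo Cluster to Noise", "Pseudo Cluster Same",
  "Pseudo Cluster Shift")

#' Classify an apo to holo cluster shift
#'
#' Maps the (apo label, holo label) pair from one joint clustering of pooled
#' apo + holo loops to one of the eleven shift categories. The
#' classification is exhaustive and mutually exclusive over label pairs.
#'
#' @param apo_label,holo_label Label strings as produced by
#'   [cluster_loops()] (`"canonical k"`, `"pseudo k"`, `"noise"`).
#' @return One of `r length(SHIFT_CATEGORIES)` category strings.
#' @export
classify_shift <- function(apo_label, holo_label) {
  parse <- function(l) {
    if (l == "noise") return(list(status = "noise", k = NA_integer_))
    parts <- strsplit(l, " ", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !parts[1L] %in% c("canonical", "pseudo")) {
      stop("unrecognised cluster label: ", l)
    }
    list(status = parts[1L], k = as.integer(parts[2L]))
  }
  a <- parse(apo_label); h <- parse(holo_label)
  if (a$status == "canonical") {
    if (h$status == "canonical") {
      if (a$k == h$k) "Canonical Cluster Same" else "Canonical Cluster Shift"
    } else if (h$status == "pseudo") "Canonical to Pseudo Cluster"
    else "Canonical Cluster to Noise"
  } else if (a$status == "pseudo") {
    if (h$status == "canonical") "Pseudo to Canonical"
    else if (h$status == "noise") "Pseudo Cluster to Noise"
    else if (a$k == h$k) "Pseudo Cluster Same" else "Pseudo Cluster Shift"
  } else {
    if (h$status == "noise") "Noise"
    else if (h$status == "canonical") "Noise to Canonical Cluster"
    else "Noise to Pseudo Cluster"
  }
}

#' Tabulate cluster shifts per loop type
#'
#' Pairs apo and holo loop assignments of the same entity drawn from one
#' joint clustering run and counts the shift categories.
#'
#' @param assignments Data frame from [cluster_loops()] augmented with
#'   columns `entity_id`, `state` (`"apo"`/`"holo"`), `loop_type`.
#' @return Data frame of counts: `category` x one column per loop type.
#' @export
shift_count_table <- function(assignments) {
  stopifnot(all(c("entity_id", "state", "loop_type") %in% names(assignments)))
  out <- matrix(0L, nrow = length(SHIFT_CATEGORIES),
                ncol = length(LOOP_TYPES),
                dimnames = list(SHIFT_CATEGORIES, LOOP_TYPES))
  for (lt in unique(assignments$loop_type)) {
    sub <- assignments[assignments$loop_type == lt, ]
    for (ent in unique(sub$entity_id)) {
      ap <- sub[sub$entity_id == ent & sub$state == "apo", ]
      ho <- sub[sub$entity_id == ent & sub$state == "holo", ]
      for (i in seq_len(nrow(ap))) {
        for (j in seq_len(nrow(ho))) {
          cat_ <- classify_shift(ap$label[i], ho$label[j])
          out[cat_, lt] <- out[cat_, lt] + 1L
        }
      }
    }
  }
  data.frame(category = rownames(out), out, check.names = FALSE,
             row.names = NULL, stringsAsFactors = FALSE)
}
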