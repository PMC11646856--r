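# Density-based hierarchical clustering (HDBSCAN) on a precomputed distance
# matrix. No R implementation of HDBSCAN is available to this package, so the
# published algorithm is implemented directly: core distances -> mutual
# reachability -> single-linkage hierarchy (equivalent to the minimum
# spanning tree construction) -> condensed tree under a minimum cluster size
# -> Excess-of-Mass cluster selection.

#' HDBSCAN clustering of a precomputed distance matrix
#'
#' @param dmat Symmetric distance matrix (or `dist`).
#' @param min_cluster_size Minimum number of members a cluster may have.
#' @param min_samples Neighbourhood size for core distances (the point itself
#'   counts); defaults to `min_cluster_size` as in the reference
#'   implementation.
#' @return Integer vector of cluster labels, `0` = noise, clusters numbered
#'   `1..k` deterministically by their smallest member index.
#' @export
hdbscan_precomputed <- function(dmat, min_cluster_size = 5L,
                                min_samples = min_cluster_size) {
  dmat <- as.matrix(dmat)
  n <- nrow(dmat)
  if (n == 0L) return(integer(0L))
  if (n < min_cluster_size || n < 2L) return(rep(0L, n))
  if (max(abs(dmat - t(dmat))) > 1e-9) stop("distance matrix is not symmetric")

  # core distance: distance to the min_samples-th nearest neighbour,
  # counting the point itself as its own first neighbour
  core <- vapply(seq_len(n), function(i) {
    v <- sort(dmat[i, -i])
    k <- min(min_samples - 1L, length(v))
    if (k < 1L) 0 else v[k]
  }, 0)
  mreach <- pmax(dmat, outer(core, core, pmax))
  diag(mreach) <- 0

  hc <- stats::hclust(stats::as.dist(mreach), method = "single")
  merge <- hc$merge
  heights <- hc$height
  nm <- nrow(merge)

  counts <- integer(nm)
  for (k in seq_len(nm)) {
    a <- merge[k, 1L]; b <- merge[k, 2L]
    counts[k] <- (if (a < 0L) 1L else counts[a]) +
      (if (b < 0L) 1L else counts[b])
  }
  child_count <- function(x) if (x < 0L) 1L else counts[x]
  leaves_under <- function(node) {
    out <- integer(0L); stack <- node
    while (length(stack)) {
      x <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (x < 0L) out <- c(out, -x) else stack <- c(stack, merge[x, ])
    }
    out
  }
  lambda_of <- function(h) 1 / max(h, 1e-12)

  # condensed tree: clusters with birth lambda, stability, children, node
  cl_node <- integer(0L); cl_birth <- numeric(0L)
  cl_parent <- integer(0L); cl_stab <- numeric(0L)
  new_cluster <- function(node, birth, parent) {
    cl_node[length(cl_node) + 1L] <<- node
    cl_birth[length(cl_birth) + 1L] <<- birth
    cl_parent[length(cl_parent) + 1L] <<- parent
    cl_stab[length(cl_stab) + 1L] <<- 0
    length(cl_node)
  }
  root <- new_cluster(nm, 0, 0L)

  # iterative top-down condensation over (node, cluster) pairs
  stack <- list(c(nm, root))
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    node <- top[1L]; cl <- top[2L]
    lam <- lambda_of(heights[node])
    a <- merge[node, 1L]; b <- merge[node, 2L]
    sa <- child_count(a); sb <- child_count(b)
    big_a <- sa >= min_cluster_size
    big_b <- sb >= min_cluster_size
    if (big_a && big_b) {
      ca <- new_cluster(a, lam, cl)
      cb <- new_cluster(b, lam, cl)
      cl_stab[cl] <- cl_stab[cl] + (lam - cl_birth[cl]) * (sa + sb)
      if (a > 0L) stack[[length(stack) + 1L]] <- c(a, ca)
      if (b > 0L) stack[[length(stack) + 1L]] <- c(b, cb)
    } else if (big_a || big_b) {
      small <- if (big_a) sb else sa
      keep <- if (big_a) a else b
      cl_stab[cl] <- cl_stab[cl] + (lam - cl_birth[cl]) * small
      if (keep > 0L) stack[[length(stack) + 1L]] <- c(keep, cl)
      # a kept leaf (size 1) can only occur with min_cluster_size == 1
    } else {
      cl_stab[cl] <- cl_stab[cl] + (lam - cl_birth[cl]) * (sa + sb)
    }
  }

  nc <- length(cl_node)
  children <- lapply(seq_len(nc), function(i) which(cl_parent == i))
  selected <- rep(FALSE, nc)
  subtree_stab <- numeric(nc)
  # process deepest-first (indices are created parent-before-child)
  for (i in rev(seq_len(nc))) {
    kids <- children[[i]]
    if (!length(kids)) {
      selected[i] <- i != root
      subtree_stab[i] <- cl_stab[i]
    } else {
      ssum <- sum(subtree_stab[kids])
      if (i != root && cl_stab[i] >= ssum) {
        selected[i] <- TRUE
        # deselect all descendants
        desc <- kids
        while (length(desc)) {
          selected[desc] <- FALSE
          desc <- unlist(children[desc])
        }
        subtree_stab[i] <- cl_stab[i]
      } else {
        subtree_stab[i] <- ssum
      }
    }
  }

  labels <- rep(0L, n)
  sel_idx <- which(selected)
  member_min <- vapply(sel_idx, function(i) min(leaves_under(cl_node[i])), 0L)
  sel_idx <- sel_idx[order(member_min)]
  for (j in seq_along(sel_idx)) {
    labels[leaves_under(cl_node[sel_idx[j]])] <- j
  }
  labels
}
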