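# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation it checks.

# Torsion oracle: Gram-Schmidt projection construction with acos magnitude
# and a determinant-based sign (vs the package's atan2 route).
oracle_dihedral <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  nb2 <- b2 / sqrt(sum(b2^2))
  b1r <- p1 - p2; b3 <- p4 - p3
  v <- b1r - sum(b1r * nb2) * nb2
  w <- b3 - sum(b3 * nb2) * nb2
  cosang <- sum(v * w) / sqrt(sum(v^2) * sum(w^2))
  cosang <- max(-1, min(1, cosang))
  ang <- acos(cosang)
  # right-handed sign from the (v, w, axis) determinant
  if (det(cbind(v, w, nb2)) < 0) ang <- -ang
  -ang
}

# Exhaustive DTW oracle: minimum over all monotone boundary-pinned warping
# paths with the symmetric2 weighting (diagonal 2, horizontal/vertical 1),
# normalised by n + m. Plain recursion, no DP reuse.
oracle_dtw <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  rec <- function(i, j) {
    if (i == 1L && j == 1L) return(2 * cost[1L, 1L])
    best <- Inf
    if (i > 1L && j > 1L) best <- min(best, rec(i - 1L, j - 1L) + 2 * cost[i, j])
    if (i > 1L) best <- min(best, rec(i - 1L, j) + cost[i, j])
    if (j > 1L) best <- min(best, rec(i, j - 1L) + cost[i, j])
    best
  }
  rec(n, m) / (n + m)
}

# Residue-pair cost matrix for two loop conformations (mean backbone-atom
# distance), recomputed independently of the package internals.
oracle_loop_cost <- function(a, b) {
  la <- nrow(a$backbone) / 4L; lb <- nrow(b$backbone) / 4L
  cost <- matrix(0, la, lb)
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      d <- 0
      for (k in 1:4) {
        pa <- a$backbone[(i - 1L) * 4L + k, ]
        pb <- b$backbone[(j - 1L) * 4L + k, ]
        d <- d + sqrt(sum((pa - pb)^2))
      }
      cost[i, j] <- d / 4
    }
  }
  cost
}

# Horn's closed-form quaternion solution of the optimal rigid superposition
# (largest eigenvalue of the 4x4 Davenport matrix) -- an algorithmic route
# independent of the SVD-based Kabsch fit.
oracle_superposition_rmsd <- function(mobile, target) {
  mc <- sweep(mobile, 2, colMeans(mobile))
  tc <- sweep(target, 2, colMeans(target))
  S <- t(mc) %*% tc
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sq <- sum(mc^2) + sum(tc^2) - 2 * lam
  sqrt(max(sq, 0) / nrow(mobile))
}

# Kruskal-Wallis H from the textbook rank formula with tie correction.
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Exact two-sided Wilcoxon rank-sum p-value by complete enumeration of the
# label assignments (no ties assumed).
oracle_wilcoxon_p <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(pooled), na)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mu <- na * length(b) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# Atom table for a single synthetic chain segment built from phi/psi.
segment_atoms <- function(phi, psi, chain_id = "A", role = "peptide",
                          imgt = seq_along(psi)) {
  bb <- tcrflex:::build_backbone(phi, psi, with_cb = FALSE)
  do.call(rbind, lapply(seq_along(bb), function(i) {
    a <- bb[[i]]
    do.call(rbind, lapply(names(a), function(nm) {
      data.frame(chain_id = chain_id, role = role, imgt = imgt[i], ins = "",
                 aa = "A", atom = nm, element = substr(nm, 1, 1),
                 x = a[[nm]][1], y = a[[nm]][2], z = a[[nm]][3],
                 stringsAsFactors = FALSE)
    }))
  }))
}

# Random loop conformation with shared straight anchors.
random_loop <- function(len, loop_id, seed, sigma = 1.0,
                        loop_type = "CDR3a") {
  set.seed(seed)
  base <- matrix(stats::rnorm(4 * len * 3, sd = sigma), ncol = 3)
  base <- sweep(base, 2, c(0, 0, 0), "+") +
    cbind(rep(seq_len(len) * 3.8, each = 4), 0, 0)
  anchors_n <- cbind(seq(-20, -1), sin(1:20), cos(1:20))
  anchors_c <- cbind(seq(1, 20) + len * 3.8 + 4, cos(1:20), sin(1:20))
  loop_conformation(loop_id, loop_type,
                    paste(sample(LETTERS[1:20], len, replace = TRUE),
                          collapse = ""),
                    base, anchors_n, anchors_c)
}

# Select a region's atoms from a structure record.
region_atoms <- function(record, role, region) {
  at <- record$atoms
  at[at$role == role & !is.na(at$region) & at$region == region, ,
     drop = FALSE]
}

loop_atoms <- function(record, loop_type) {
  p <- tcrflex:::loop_type_parts(loop_type)
  region_atoms(record, p$role, p$region)
}
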