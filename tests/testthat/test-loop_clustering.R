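test_that("anchor superposition is the Kabsch fit of the 40 anchor atoms", {
  a <- random_loop(7, "a", 1)
  b <- random_loop(7, "b", 2)
  # a rigid motion of a loop is removed exactly
  R <- tcrflex:::random_rotation()
  moved <- a
  moved$backbone <- sweep(a$backbone %*% t(R), 2, c(4, -2, 7), "+")
  moved$anchors_n <- sweep(a$anchors_n %*% t(R), 2, c(4, -2, 7), "+")
  moved$anchors_c <- sweep(a$anchors_c %*% t(R), 2, c(4, -2, 7), "+")
  back <- anchor_superpose(moved, a)
  expect_lt(max(abs(back$backbone - a$backbone)), 1e-6)
  # delegation: equals kabsch_fit on the anchor atoms directly
  sup <- anchor_superpose(a, b)
  fit <- kabsch_fit(rbind(a$anchors_n, a$anchors_c),
                    rbind(b$anchors_n, b$anchors_c))
  expect_equal(attr(sup, "superposition")$fit_rmsd, fit$fit_rmsd)
  expect_equal(sup$backbone, apply_transform(a$backbone, fit))
  # loops of different lengths superpose on anchors alone
  c7 <- random_loop(4, "c", 3)
  expect_silent(anchor_superpose(c7, a))
})

test_that("DTW distance is symmetric, zero on identity, and matches path enumeration", {
  a <- random_loop(5, "a", 10)
  expect_equal(dtw_distance(a, a), 0)
  set.seed(123)
  for (i in 1:30) {
    la <- sample(2:6, 1); lb <- sample(2:6, 1)
    x <- random_loop(la, "x", 1000 + i)
    y <- random_loop(lb, "y", 2000 + i)
    d_xy <- dtw_distance(x, y)
    expect_equal(d_xy, dtw_distance(y, x), tolerance = 1e-12)
    expect_equal(d_xy, oracle_dtw(oracle_loop_cost(x, y)), tolerance = 1e-9)
  }
  # equal-length loops under a uniform translation: identity warping is
  # optimal and DTW equals the mean per-residue distance = |t|
  z <- random_loop(6, "z", 5)
  zt <- z
  zt$backbone <- sweep(z$backbone, 2, c(0, 0, 3), "+")
  expect_equal(dtw_distance(z, zt), 3, tolerance = 1e-9)
})

test_that("distance matrices are symmetric with zero diagonal and unique ids", {
  loops <- make_loop_families(2, 3, intra_sigma = 0.2, inter_sep = 4,
                              unique_seqs = 3, seed = 8)
  dm <- build_distance_matrix(loops)
  expect_equal(unname(diag(dm)), rep(0, length(loops)))
  expect_lt(max(abs(dm - t(dm))), 1e-9)
  expect_true(all(dm >= 0))
  # two identical conformations at different positions -> off-diagonal zero
  dup <- loops[c(1, 1)]
  dup[[2]]$loop_id <- "copy"
  dm2 <- build_distance_matrix(dup)
  expect_lt(dm2[1, 2], 1e-6)  # anchor-fit numerical noise only
  expect_error(build_distance_matrix(loops[c(1, 1)]), "duplicate")
})

test_that("density-based clustering recovers planted families and labels them", {
  fams <- make_loop_families(3, 8, intra_sigma = 0.05, inter_sep = 5,
                             unique_seqs = 5, seed = 21)
  dm <- build_distance_matrix(fams)
  seqs <- setNames(vapply(fams, function(l) l$sequence, ""),
                   vapply(fams, function(l) l$loop_id, ""))
  cl <- cluster_loops(dm, seqs, min_cluster_size = 5)
  expect_equal(length(unique(na.omit(cl$cluster))), 3L)
  expect_false(any(cl$status == "noise"))
  # clusters coincide with the planted families
  fam <- attr(fams, "family")[match(cl$loop_id,
                                    vapply(fams, `[[`, "", "loop_id"))]
  expect_equal(length(unique(paste(fam, cl$cluster))), 3L)
  expect_true(all(cl$status == "canonical"))  # 5 unique sequences each
  # a 2-unique-sequence family is pseudo
  pf <- make_loop_families(1, 8, intra_sigma = 0.05, unique_seqs = 2,
                           seed = 22, id_prefix = "pf")
  all_loops <- c(fams, pf)
  dm2 <- build_distance_matrix(all_loops)
  seqs2 <- setNames(vapply(all_loops, function(l) l$sequence, ""),
                    vapply(all_loops, function(l) l$loop_id, ""))
  cl2 <- cluster_loops(dm2, seqs2, min_cluster_size = 5)
  pseudo_ids <- cl2$loop_id[cl2$status == "pseudo"]
  expect_setequal(pseudo_ids, vapply(pf, `[[`, "", "loop_id"))
  # scattered singletons below min size are all noise
  singles <- lapply(1:4, function(i) {
    l <- random_loop(6, paste0("s", i), 300 + i, sigma = 3)
    l$backbone <- l$backbone + 40 * i
    l
  })
  dm3 <- build_distance_matrix(singles)
  cl3 <- cluster_loops(dm3, min_cluster_size = 5)
  expect_true(all(cl3$status == "noise"))
  # clustering is deterministic given the matrix
  expect_identical(cluster_loops(dm2, seqs2, 5)$label, cl2$label)
})

test_that("loop extraction pulls the loop plus five flanking anchors", {
  tcr <- make_toy_tcr(14)
  lc <- extract_loop(tcr, "CDR3a")
  expect_s3_class(lc, "loop_conformation")
  expect_equal(nrow(lc$anchors_n), 20L)
  expect_equal(nrow(lc$anchors_c), 20L)
  expect_equal(nchar(lc$sequence), nrow(lc$backbone) / 4L)
  p <- tcrflex:::loop_type_parts("CDR3a")
  seq_direct <- paste(unique(tcr$atoms[tcr$atoms$role == p$role &
                                         tcr$atoms$region %in% "CDR3",
                                       c("imgt", "aa")])$aa, collapse = "")
  expect_equal(lc$sequence, seq_direct)
})

test_that("cluster-shift classification is exhaustive over the 11 categories", {
  labels <- c("canonical 1", "canonical 2", "pseudo 1", "pseudo 2", "noise")
  got <- character()
  for (a in labels) for (h in labels) {
    got <- c(got, classify_shift(a, h))
  }
  expect_setequal(unique(got), tcrflex:::SHIFT_CATEGORIES)
  expect_equal(length(tcrflex:::SHIFT_CATEGORIES), 11L)
  expect_equal(classify_shift("canonical 3", "canonical 3"),
               "Canonical Cluster Same")
  expect_equal(classify_shift("canonical 3", "canonical 4"),
               "Canonical Cluster Shift")
  expect_equal(classify_shift("noise", "noise"), "Noise")
  expect_equal(classify_shift("pseudo 2", "canonical 1"),
               "Pseudo to Canonical")
  expect_equal(classify_shift("pseudo 2", "pseudo 2"), "Pseudo Cluster Same")
  expect_equal(classify_shift("pseudo 2", "pseudo 3"), "Pseudo Cluster Shift")
  expect_error(classify_shift("weird", "noise"), "unrecognised")
  # the count table covers all apo x holo pairs of each entity
  assignments <- data.frame(
    loop_id = c("a1", "a2", "h1"), label = c("noise", "pseudo 1", "noise"),
    cluster = c(NA, 1, NA), status = c("noise", "pseudo", "noise"),
    entity_id = "e1", state = c("apo", "apo", "holo"), loop_type = "CDR3a",
    stringsAsFactors = FALSE)
  tab <- shift_count_table(assignments)
  expect_equal(tab$CDR3a[tab$category == "Noise"], 1L)
  expect_equal(tab$CDR3a[tab$category == "Pseudo Cluster to Noise"], 1L)
  expect_equal(sum(tab[, -1]), 2L)
})

test_that("HDBSCAN handles edge cases deterministically", {
  # fewer points than the minimum cluster size: all noise, no error
  d <- as.matrix(dist(matrix(rnorm(9), 3)))
  expect_equal(hdbscan_precomputed(d, 5), rep(0L, 3))
  # two clean blobs
  set.seed(61)
  pts <- rbind(matrix(rnorm(24, 0, 0.05), ncol = 2),
               matrix(rnorm(24, 10, 0.05), ncol = 2))
  labs <- hdbscan_precomputed(as.matrix(dist(pts)), 5)
  expect_equal(sort(unique(labs)), c(1L, 2L))
  expect_equal(length(unique(labs[1:12])), 1L)
  expect_equal(length(unique(labs[13:24])), 1L)
  expect_error(hdbscan_precomputed(matrix(c(0, 1, 2, 0), 2), 1),
               "not symmetric")
})
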