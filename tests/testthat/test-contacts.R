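# Minimal hand-built complex: place single-atom-ish residues precisely.
tiny_complex <- function(placements) {
  rows <- do.call(rbind, lapply(seq_along(placements), function(i) {
    p <- placements[[i]]
    data.frame(chain_id = p$chain, role = p$role, imgt = p$imgt, ins = "",
               aa = "A", atom = p$atom %||% "CA", element = "C",
               x = p$xyz[1], y = p$xyz[2], z = p$xyz[3],
               stringsAsFactors = FALSE)
  }))
  assign_regions(structure_record("tiny", "holo_complex", rows,
                                  resolution = 2))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("contact detection honours the strict 5 Angstrom rule", {
  cx <- tiny_complex(list(
    list(chain = "A", role = "tcr_alpha", imgt = 110, xyz = c(0, 0, 4.9)),
    list(chain = "A", role = "tcr_alpha", imgt = 111, xyz = c(0, 0, 20)),
    list(chain = "B", role = "tcr_beta", imgt = 110, xyz = c(50, 0, 5.0)),
    list(chain = "B", role = "tcr_beta", imgt = 20, xyz = c(0, 1, 2)),  # FR
    list(chain = "P", role = "peptide", imgt = 5, xyz = c(0, 0, 0)),
    list(chain = "P", role = "peptide", imgt = 6, xyz = c(50, 0, 0)),
    list(chain = "M", role = "mhc_heavy", imgt = 10, xyz = c(200, 0, 0))))
  ct <- find_contacts(cx, cutoff = 5.0)
  # one CDR3a atom at 4.9 A; the pair at exactly 5.0 A is excluded; the
  # non-CDR TCR atom at 2.2 A is ignored
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$loop, "CDR3a")
  expect_equal(ct$distance, 4.9)
  expect_error(find_contacts(make_toy_tcr(1)), "holo complex")
})

test_that("spatial-index contact search equals the all-pairs brute force", {
  set.seed(91)
  for (rep in 1:6) {
    n_tcr <- 120; n_pmhc <- 380
    tcr <- data.frame(chain_id = "A", role = "tcr_alpha",
                      imgt = sample(105:117, n_tcr, TRUE), ins = "",
                      aa = "A", atom = "CA", element = "C",
                      x = runif(n_tcr, 0, 30), y = runif(n_tcr, 0, 30),
                      z = runif(n_tcr, 0, 30), stringsAsFactors = FALSE)
    pm <- data.frame(chain_id = c("P", "M")[1 + (seq_len(n_pmhc) %% 2)],
                     role = c("peptide", "mhc_heavy")[1 + (seq_len(n_pmhc) %% 2)],
                     imgt = sample(1:9, n_pmhc, TRUE), ins = "", aa = "A",
                     atom = "CA", element = "C",
                     x = runif(n_pmhc, 0, 30), y = runif(n_pmhc, 0, 30),
                     z = runif(n_pmhc, 0, 30), stringsAsFactors = FALSE)
    beta <- data.frame(chain_id = "B", role = "tcr_beta", imgt = 110,
                       ins = "", aa = "A", atom = "CA", element = "C",
                       x = 500, y = 500, z = 500, stringsAsFactors = FALSE)
    cx <- assign_regions(structure_record(paste0("rand", rep),
                                          "holo_complex",
                                          rbind(tcr, beta, pm)))
    ct <- find_contacts(cx, cutoff = 5.0)
    A <- as.matrix(tcr[, c("x", "y", "z")])
    B <- as.matrix(pm[, c("x", "y", "z")])
    brute <- sum(vapply(seq_len(nrow(A)), function(i)
      sum(sqrt(colSums((t(B) - A[i, ])^2)) < 5.0), 0))
    expect_equal(nrow(ct), brute)
  }
})

test_that("fingerprints count per position and normalise per complex", {
  mk_ct <- function(id, loops, pos) {
    data.frame(structure_id = id, loop = loops, tcr_role = "tcr_alpha",
               tcr_imgt = 110, tcr_ins = "", tcr_atom = "CA",
               target_role = "mhc_heavy", target_imgt = pos,
               target_ins = "", target_atom = "CA", distance = 4,
               stringsAsFactors = FALSE)
  }
  ct <- mk_ct("c1", c(rep("CDR1a", 7), rep("CDR2a", 3)), 65)
  fp <- fingerprint(ct, "mhc")
  expect_equal(fp$fraction[fp$loop == "CDR1a"], 0.7)
  expect_equal(fp$fraction[fp$loop == "CDR2a"], 0.3)
  expect_equal(unique(fp$n_contacts), 10L)
  # positions with zero contacts are absent; fractions sum to 1
  expect_false(66 %in% fp$position)
  sums <- tapply(fp$fraction, fp$position, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)))
  # multi-complex input: per-complex fractions averaged, not pooled
  ct2 <- rbind(mk_ct("c1", rep("CDR1a", 9), 65),   # 9 pairs, all CDR1a
               mk_ct("c2", c("CDR1a", "CDR2a"), 65))  # 1:1 split
  fp2 <- fingerprint(ct2, "mhc")
  expect_equal(fp2$fraction[fp2$loop == "CDR1a"], (1 + 0.5) / 2)
  expect_equal(fp2$fraction[fp2$loop == "CDR2a"], 0.25)
  # empty contact set -> empty fingerprint, no error
  fp0 <- fingerprint(ct[0, ], "peptide")
  expect_equal(nrow(fp0), 0L)
})

test_that("dominant-loop assignment applies the threshold and fixed tie order", {
  fp <- structure(data.frame(
    position = c(65, 65, 70, 70, 80),
    loop = c("CDR3a", "CDR3b", "CDR1a", "CDR2a", "CDR1b"),
    fraction = c(0.8, 0.2, 0.5, 0.5, 0.009),
    n_contacts = c(10, 10, 4, 4, 1000)),
    class = c("contact_fingerprint", "data.frame"), target = "mhc")
  dl <- dominant_loops(fp, min_fraction = 0.01)
  expect_equal(dl$loop[dl$position == 65], "CDR3a")
  expect_equal(dl$loop[dl$position == 70], "CDR1a")  # tie -> loop order
  expect_true(70 %in% attr(dl, "ties"))
  expect_false(80 %in% dl$position)  # below the 1% threshold
  # zero threshold assigns every contacted position
  expect_setequal(dominant_loops(fp, 0)$position, c(65, 70, 80))
})

test_that("peptide-half profiles recover a planted half-split pattern", {
  cx <- make_half_contact_complex(6)
  ct <- find_contacts(cx)
  fp <- fingerprint(ct, "peptide")
  # the construction puts CDR3a only on p1-p5 and CDR3b only on p6-p9
  expect_setequal(unique(fp$loop[fp$position <= 5]), "CDR3a")
  expect_setequal(unique(fp$loop[fp$position > 5]), "CDR3b")
  php <- peptide_half_profile(fp, 9)
  expect_equal(unname(php$dominant), c("CDR3a", "CDR3b"))
  expect_equal(unname(php$first_half["CDR3a"]), 1)
  expect_equal(unname(php$second_half["CDR3b"]), 1)
  # the half aggregate equals recomputation from the raw contact pairs
  raw_first <- table(ct$loop[ct$target_role == "peptide" &
                               ct$target_imgt <= 5])
  expect_equal(unname(php$first_half["CDR3a"]),
               unname(raw_first["CDR3a"] / sum(raw_first)))
  # a single uniformly contacting loop dominates both halves
  uni <- data.frame(structure_id = "u", loop = "CDR2b",
                    tcr_role = "tcr_beta", tcr_imgt = 58, tcr_ins = "",
                    tcr_atom = "CA", target_role = "peptide",
                    target_imgt = rep(1:9, 2), target_ins = "",
                    target_atom = "CA", distance = 4,
                    stringsAsFactors = FALSE)
  php2 <- peptide_half_profile(fingerprint(uni, "peptide"), 9)
  expect_equal(unname(php2$dominant), c("CDR2b", "CDR2b"))
  expect_warning(peptide_half_profile(fingerprint(uni, "peptide"), 7),
                 "shorter")
})

test_that("MHC position partition is disjoint and covers the domain", {
  fp <- structure(data.frame(position = c(58, 65, 155),
                             loop = "CDR1a", fraction = 1,
                             n_contacts = c(5, 2, 9)),
                  class = c("contact_fingerprint", "data.frame"),
                  target = "mhc")
  domain <- 1:180
  part <- partition_mhc_positions(fp, domain)
  expect_equal(part$tcr_contact, c(58, 65, 155))
  expect_equal(length(part$non_contact), 177L)
  expect_length(intersect(part$tcr_contact, part$non_contact), 0)
  expect_setequal(c(part$tcr_contact, part$non_contact), domain)
  # empty fingerprint: everything is non-contact
  fp0 <- structure(fp[0, ], class = class(fp), target = "mhc")
  part0 <- partition_mhc_positions(fp0, domain)
  expect_equal(part0$non_contact, domain)
})
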