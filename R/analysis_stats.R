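# analysis_stats: entity normalisation, comparison-group construction,
# binding-mode classification, nonparametric testing, per-position profiles
# and background-repertoire comparisons.

#' Normalise movement records by entity
#'
#' Replaces, for each (entity, loop/region, comparison, metric) cell, all
#' raw values by their mean, so every entity contributes exactly one value
#' to downstream statistics regardless of how many structure pairs it has.
#' Idempotent.
#'
#' @param records Movement table: data frame with columns `entity_id`,
#'   `loop_or_region`, `comparison`, `metric`, `value`.
#' @return Aggregated movement table, one row per cell.
#' @export
normalize_by_entity <- function(records) {
  stopifnot(all(c("entity_id", "loop_or_region", "comparison", "metric",
                  "value") %in% names(records)))
  agg <- stats::aggregate(
    value ~ entity_id + loop_or_region + comparison + metric,
    data = records, FUN = mean)
  agg <- agg[order(agg$metric, agg$comparison, agg$loop_or_region,
                   agg$entity_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg[, c("entity_id", "loop_or_region", "comparison", "metric", "value")]
}

#' Enumerate same-entity structure-pair comparisons
#'
#' Builds the comparison groups: `apo_apo` (all unordered apo pairs of one
#' entity), `apo_holo` (all apo x holo combinations), `holo_holo` (all
#' unordered holo pairs).
#'
#' @param apo_ids,holo_ids Character vectors of structure ids of one entity.
#' @return Data frame: `comparison`, `id_a`, `id_b`.
#' @export
comparison_pairs <- function(apo_ids, holo_ids) {
  rows <- list()
  pair_up <- function(ids, label) {
    if (length(ids) >= 2L) {
      cmb <- utils::combn(sort(ids), 2L)
      data.frame(comparison = label, id_a = cmb[1L, ], id_b = cmb[2L, ],
                 stringsAsFactors = FALSE)
    }
  }
  rows$aa <- pair_up(apo_ids, "apo_apo")
  rows$hh <- pair_up(holo_ids, "holo_holo")
  if (length(apo_ids) && length(holo_ids)) {
    g <- expand.grid(id_a = sort(apo_ids), id_b = sort(holo_ids),
                     stringsAsFactors = FALSE)
    rows$ah <- data.frame(comparison = "apo_holo", g, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(comparison = character(), id_a = character(),
                      id_b = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Compute movement metrics for all same-entity comparisons
#'
#' For every matched pair of one side, aligns the first structure onto the
#' second on the designated reference frame (TCR framework or MHC groove
#' floor) and computes, per loop or region, the unsuperposed backbone RMSD
#' (movement), the loop-superposed backbone RMSD (deformation), and the
#' D-score over the loop dihedrals.
#'
#' @param manifest A matched `dataset_manifest` (see [match_apo_holo()]).
#' @param side `"tcr"` or `"pmhc"`.
#' @return Movement table with one row per (entity, pair, region, metric).
#' @export
build_comparison_groups <- function(manifest, side = c("tcr", "pmhc")) {
  side <- match.arg(side)
  recs <- manifest$records
  states <- vapply(recs, function(r) r$state, "")
  apo_state <- if (side == "tcr") "apo_tcr" else "apo_pmhc"
  keys <- vapply(recs, function(r) {
    if (r$state == "holo_complex" || r$state == apo_state)
      entity_key(r, side) else NA_character_
  }, "")
  rows <- list()
  for (ent in sort(unique(stats::na.omit(keys)))) {
    apo_ids <- vapply(recs[keys == ent & !is.na(keys) & states == apo_state],
                      function(r) r$structure_id, "")
    holo_ids <- vapply(recs[keys == ent & !is.na(keys) &
                              states == "holo_complex"],
                       function(r) r$structure_id, "")
    if (!length(apo_ids) || !length(holo_ids)) next  # unpaired entity
    prs <- comparison_pairs(apo_ids, holo_ids)
    for (k in seq_len(nrow(prs))) {
      a <- get_record(manifest, prs$id_a[k])
      b <- get_record(manifest, prs$id_b[k])
      met <- tryCatch(
        pairwise_movement_metrics(a, b, side),
        error = function(e) NULL)
      if (is.null(met)) next
      met$entity_id <- ent
      met$comparison <- prs$comparison[k]
      met$id_a <- prs$id_a[k]; met$id_b <- prs$id_b[k]
      rows[[length(rows) + 1L]] <- met
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(entity_id = character(), loop_or_region = character(),
               comparison = character(), metric = character(),
               value = numeric(), id_a = character(), id_b = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[, c("entity_id", "loop_or_region", "comparison", "metric", "value",
          "id_a", "id_b")]
}

# Metrics for one aligned pair: backbone_rmsd / superposed_backbone_rmsd /
# dscore per CDR loop (tcr side) or per pMHC region (pmhc side).
pairwise_movement_metrics <- function(a, b, side) {
  rows <- list()
  add <- function(region_label, metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      loop_or_region = region_label, metric = metric, value = value,
      stringsAsFactors = FALSE)
  }
  if (side == "tcr") {
    a <- align_tcr_framework(a, b)
    for (lt in LOOP_TYPES) {
      p <- loop_type_parts(lt)
      sa <- a$atoms[a$atoms$role == p$role & !is.na(a$atoms$region) &
                      a$atoms$region == p$region, , drop = FALSE]
      sb <- b$atoms[b$atoms$role == p$role & !is.na(b$atoms$region) &
                      b$atoms$region == p$region, , drop = FALSE]
      add(lt, "backbone_rmsd", as.numeric(backbone_rmsd(sa, sb)))
      add(lt, "superposed_backbone_rmsd",
          as.numeric(backbone_rmsd(sa, sb, superpose_first = TRUE)))
      da <- compute_dihedrals(sa); db <- compute_dihedrals(sb)
      ds <- tryCatch(as.numeric(dscore(da, db)), error = function(e) NA_real_)
      add(lt, "dscore", ds)
    }
  } else {
    a <- align_mhc_floor(a, b)
    regions <- list(peptide = c("peptide", "peptide"),
                    groove_floor = c("mhc_heavy", "groove_floor"),
                    alpha1_helix = c("mhc_heavy", "alpha1_helix"),
                    alpha2_helix = c("mhc_heavy", "alpha2_helix"))
    for (nm in names(regions)) {
      role <- regions[[nm]][1L]; reg <- regions[[nm]][2L]
      sa <- a$atoms[a$atoms$role == role & !is.na(a$atoms$region) &
                      a$atoms$region == reg, , drop = FALSE]
      sb <- b$atoms[b$atoms$role == role & !is.na(b$atoms$region) &
                      b$atoms$region == reg, , drop = FALSE]
      if (!nrow(sa) || !nrow(sb)) next
      add(nm, "backbone_rmsd", as.numeric(backbone_rmsd(sa, sb)))
      if (nm == "peptide") {
        add(nm, "superposed_backbone_rmsd",
            as.numeric(backbone_rmsd(sa, sb, superpose_first = TRUE)))
      }
    }
  }
  do.call(rbind, rows)
}

#' Kruskal-Wallis test across groups
#'
#' Standard rank-based H with tie correction, delegated to
#' [stats::kruskal.test()]. When every value in every group is identical the
#' contract `H = 0, p = 1` applies (the rank test is undefined there).
#'
#' @param groups Named list of numeric vectors (entity-normalised values).
#' @return List with `statistic` (H), `p_value`, `df`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 1L))
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, p_value = 1, df = length(groups) - 1L,
                n = length(values)))
  }
  g <- factor(rep(names(groups) %||% seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), n = length(values))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Post hoc Wilcoxon rank-sum tests with Bonferroni-adjusted level
#'
#' Two-sided rank-sum test per requested pair; the corrected significance
#' level is `alpha / n_comparisons`.
#'
#' @param groups Named list of numeric vectors.
#' @param comparisons List of length-2 character vectors naming group pairs;
#'   defaults to all unordered pairs.
#' @param alpha Family-wise significance level.
#' @return Data frame: `group_a`, `group_b`, `p_raw`, `corrected_level`,
#'   `significant`.
#' @export
posthoc_wilcoxon_bonferroni <- function(groups, comparisons = NULL,
                                        alpha = 0.05) {
  if (is.null(comparisons)) {
    nm <- names(groups)
    comparisons <- utils::combn(nm, 2L, simplify = FALSE)
  }
  level <- alpha / length(comparisons)
  rows <- lapply(comparisons, function(cp) {
    ga <- groups[[cp[1L]]]; gb <- groups[[cp[2L]]]
    if (!length(ga) || !length(gb)) return(NULL)
    p <- suppressWarnings(
      stats::wilcox.test(ga, gb, alternative = "two.sided")$p.value)
    data.frame(group_a = cp[1L], group_b = cp[2L], p_raw = p,
               corrected_level = level, significant = p < level,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Classify the binding mode of an entity
#'
#' From all apo:holo backbone RMSD values of one entity: `flexible` if any
#' exceeds the flexible threshold and none is below the rigid threshold;
#' `rigid` if any is below the rigid threshold and none exceeds the flexible
#' one; `intermediate` otherwise. An entity exhibiting both behaviours
#' across contexts is flagged `dual_mode`.
#'
#' @param values Numeric apo:holo RMSD values (Angstrom), length >= 1.
#' @param rigid_below,flexible_above Thresholds in Angstrom.
#' @return List with `mode` and `dual_mode` flag.
#' @export
classify_binding_mode <- function(values, rigid_below = 0.5,
                                  flexible_above = 1.0) {
  stopifnot(length(values) >= 1L)
  has_flex <- any(values > flexible_above)
  has_rigid <- any(values < rigid_below)
  if (has_flex && has_rigid) {
    list(mode = "dual", dual_mode = TRUE)
  } else if (has_flex) {
    list(mode = "flexible", dual_mode = FALSE)
  } else if (has_rigid) {
    list(mode = "rigid", dual_mode = FALSE)
  } else {
    list(mode = "intermediate", dual_mode = FALSE)
  }
}

#' Entity-normalised per-position profile
#'
#' Averages per-residue values within entity first, then reports mean and
#' standard deviation across entities per IMGT position. Positions observed
#' in a single entity carry no dispersion (`sd = NA`).
#'
#' @param records Data frame: `entity_id`, `position`, `value`.
#' @return Data frame: `position`, `mean`, `sd`, `n_entities`.
#' @export
per_position_profile <- function(records) {
  stopifnot(all(c("entity_id", "position", "value") %in% names(records)))
  per_ent <- stats::aggregate(value ~ entity_id + position, data = records,
                              FUN = mean)
  out <- do.call(rbind, lapply(sort(unique(per_ent$position)), function(p) {
    v <- per_ent$value[per_ent$position == p]
    data.frame(position = p, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               n_entities = length(v))
  }))
  rownames(out) <- NULL
  out
}

#' Movement of pMHC regions split by TCR contact
#'
#' For each pMHC entity, the floor-aligned apo:holo backbone RMSD of the
#' peptide, of the MHC positions contacted by TCRs, and of the non-contacted
#' antigen-binding-domain positions.
#'
#' @param manifest Matched manifest.
#' @param partition Output of [partition_mhc_positions()].
#' @return Movement table over regions `peptide`, `mhc_tcr_contact`,
#'   `mhc_non_contact`.
#' @export
peptide_region_movement <- function(manifest, partition) {
  pairs <- manifest$pairs[manifest$pairs$side == "pmhc", , drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    apo <- get_record(manifest, pairs$apo_id[k])
    holo <- get_record(manifest, pairs$holo_id[k])
    apo <- align_mhc_floor(apo, holo)
    sel <- list(
      peptide = function(at) at$role == "peptide",
      mhc_tcr_contact = function(at) at$role == "mhc_heavy" &
        at$imgt %in% partition$tcr_contact,
      mhc_non_contact = function(at) at$role == "mhc_heavy" &
        at$imgt %in% partition$non_contact)
    for (nm in names(sel)) {
      sa <- apo$atoms[sel[[nm]](apo$atoms), , drop = FALSE]
      sb <- holo$atoms[sel[[nm]](holo$atoms), , drop = FALSE]
      if (!nrow(sa) || !nrow(sb)) next
      v <- tryCatch(as.numeric(backbone_rmsd(sa, sb)),
                    error = function(e) NA_real_)
      if (is.na(v)) next
      rows[[length(rows) + 1L]] <- data.frame(
        entity_id = pairs$entity_id[k], loop_or_region = nm,
        comparison = "apo_holo", metric = "backbone_rmsd", value = v,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(entity_id = character(),
                                      loop_or_region = character(),
                                      comparison = character(),
                                      metric = character(), value = numeric(),
                                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Anchor-mode-conditioned peptide movement profiles
#'
#' Splits per-residue peptide movement records by the anchoring mode of
#' their entity and computes an entity-normalised per-position profile for
#' each mode. Entities without an assigned mode are excluded.
#'
#' @param records Data frame: `entity_id`, `position`, `value`.
#' @param modes Named character vector: entity_id -> mode
#'   (`"P2_P9"`/`"P2_P5_P9"`/`NA`).
#' @return Named list of [per_position_profile()] tables, one per mode.
#' @export
anchor_conditioned_peptide_profile <- function(records, modes) {
  records$mode <- unname(modes[records$entity_id])
  records <- records[!is.na(records$mode), , drop = FALSE]
  lapply(split(records, records$mode), per_position_profile)
}

#' Sample a background TCR repertoire
#'
#' Uniform, seeded sampling without replacement of `n` unique TCR rows,
#' repeated `reps` times independently.
#'
#' @param repertoire Data frame of unique TCR rows (V/J calls + six CDRs).
#' @param n Rows per sample.
#' @param reps Number of samples.
#' @param seed Integer seed.
#' @return List of `reps` data frames.
#' @export
sample_background <- function(repertoire, n = 1000L, reps = 10L, seed = 1L) {
  if (nrow(repertoire) < n) {
    stop("repertoire has fewer rows (", nrow(repertoire),
         ") than the requested sample size ", n)
  }
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lapply(seq_len(reps), function(i) {
    repertoire[sample.int(nrow(repertoire), n), , drop = FALSE]
  })
}

# Strip allele suffixes: "TRBV19*01" -> "TRBV19".
harmonize_gene <- function(x) sub("\\*.*$", "", x)

#' Gene-usage enrichment of a dataset against a background
#'
#' Percent enrichment/depletion of each gene's frequency in the dataset
#' relative to its mean frequency over the background samples. Genes absent
#' from the background are flagged (`percent = NA`).
#'
#' @param dataset_genes Character vector of gene calls in the dataset.
#' @param background_samples List of data frames from [sample_background()].
#' @param gene_col Column of the background holding the gene call.
#' @return Data frame: `gene`, `dataset_freq`, `background_freq`, `percent`,
#'   `absent_from_background`.
#' @export
gene_usage_enrichment <- function(dataset_genes, background_samples,
                                  gene_col) {
  ds <- harmonize_gene(dataset_genes)
  ds_freq <- table(ds) / length(ds)
  bg_tabs <- lapply(background_samples, function(s) {
    g <- harmonize_gene(s[[gene_col]])
    table(g) / length(g)
  })
  genes <- sort(unique(c(names(ds_freq), unlist(lapply(bg_tabs, names)))))
  bg_freq <- vapply(genes, function(g) {
    mean(vapply(bg_tabs, function(tb) {
      if (g %in% names(tb)) as.numeric(tb[g]) else 0
    }, 0))
  }, 0)
  d <- vapply(genes, function(g) {
    if (g %in% names(ds_freq)) as.numeric(ds_freq[g]) else 0
  }, 0)
  percent <- ifelse(bg_freq > 0, 100 * (d - bg_freq) / bg_freq, NA_real_)
  data.frame(gene = genes, dataset_freq = d, background_freq = bg_freq,
             percent = percent, absent_from_background = bg_freq == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}
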