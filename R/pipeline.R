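# Pipeline orchestration: a run configuration holding every analysis
# threshold, and subcommands that read/write the CSV/JSON artifacts of each
# stage. Each stage is independently runnable; re-running with the same seed
# reproduces outputs bit-for-bit.

#' Pipeline run configuration
#'
#' Bundles every analysis parameter with its default: curation resolution
#' cutoff 3.50 A, contact cutoff 5.0 A, contact dominance threshold 1%,
#' HDBSCAN minimum cluster size 5, rigid/flexible binding-mode thresholds
#' 0.5/1.0 A, motif bands 60/30/20/10%, significance level 0.05, and the
#' synthetic-simulation sizes.
#'
#' @param output_dir Directory receiving all artifacts.
#' @param seed Integer master seed.
#' @param max_resolution,contact_cutoff,dominance_threshold,min_cluster_size,rigid_below,flexible_above,alpha Analysis thresholds.
#' @param motif_bands Named banding thresholds.
#' @param n_entities Number of simulated TCR:pMHC entities.
#' @param n_apo,n_holo Structures per entity and state.
#' @param background_n,background_reps Background sampling sizes.
#' @param regions A [region_config()].
#' @return A `run_config` list.
#' @export
run_config <- function(output_dir, seed = 1L, max_resolution = 3.50,
                       contact_cutoff = 5.0, dominance_threshold = 0.01,
                       min_cluster_size = 5L, rigid_below = 0.5,
                       flexible_above = 1.0, alpha = 0.05,
                       motif_bands = MOTIF_BANDS, n_entities = 3L,
                       n_apo = 3L, n_holo = 3L, background_n = 1000L,
                       background_reps = 10L, regions = region_config()) {
  stopifnot(max_resolution > 0, contact_cutoff > 0, dominance_threshold > 0,
            min_cluster_size > 0, rigid_below > 0, flexible_above > 0,
            all(diff(motif_bands) < 0))
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 max_resolution = max_resolution,
                 contact_cutoff = contact_cutoff,
                 dominance_threshold = dominance_threshold,
                 min_cluster_size = as.integer(min_cluster_size),
                 rigid_below = rigid_below, flexible_above = flexible_above,
                 alpha = alpha, motif_bands = motif_bands,
                 n_entities = as.integer(n_entities),
                 n_apo = as.integer(n_apo), n_holo = as.integer(n_holo),
                 background_n = as.integer(background_n),
                 background_reps = as.integer(background_reps),
                 regions = regions),
            class = "run_config")
}

stage_dir <- function(config, stage) {
  d <- file.path(config$output_dir, stage)
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

need_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing upstream artifact ", path, "; run the '", producer,
         "' stage first")
  }
  path
}

write_csv_det <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

# Small per-structure coordinate jitter emulating independent crystal forms.
jitter_structure <- function(record, sd = 0.05, new_id, state = record$state) {
  xyz <- as.matrix(record$atoms[, c("x", "y", "z")])
  record$atoms[, c("x", "y", "z")] <- xyz + stats::rnorm(length(xyz), 0, sd)
  record$structure_id <- new_id
  record$state <- state
  record
}

subset_side <- function(complex, side) {
  keep <- if (side == "tcr") c("tcr_alpha", "tcr_beta") else
    c("mhc_heavy", "beta2m", "peptide")
  at <- complex$atoms[complex$atoms$role %in% keep, , drop = FALSE]
  structure_record(complex$structure_id,
                   if (side == "tcr") "apo_tcr" else "apo_pmhc", at,
                   resolution = complex$resolution, allele = complex$allele)
}

run_simulate <- function(config) {
  dir <- stage_dir(config, "simulate")
  set.seed(config$seed)
  files <- list()
  motif_rows <- list()
  gene_rows <- list()
  freqs <- default_gene_freqs()
  for (e in seq_len(config$n_entities)) {
    eseed <- config$seed * 1000L + e
    mode <- if (e %% 2L == 1L) "P2_P9" else "P2_P5_P9"
    base <- make_toy_complex(eseed, anchor_mode = mode)
    # motif planted to match the generated peptide at the anchor positions
    pep <- residue_table(base$atoms)
    pep <- pep[pep$role == "peptide", ]
    plen <- nrow(pep)
    mid <- if (plen == 9L) 5L else ceiling(plen / 2)
    anchor_pos <- if (mode == "P2_P9") c(2L, plen) else c(2L, mid, plen)
    planted <- stats::setNames(
      lapply(anchor_pos, function(p) list(aa = pep$aa[p], prop = 0.7)),
      as.character(anchor_pos))
    motif_rows[[e]] <- make_motif_table(planted, plen, allele = base$allele)
    set.seed(eseed)
    genes <- vapply(freqs, function(f)
      sample(names(f), 1L, prob = f), "")
    gene_rows[[e]] <- data.frame(entity = e, t(genes),
                                 stringsAsFactors = FALSE)
    # holo replicates: jittered copies of the complex
    for (h in seq_len(config$n_holo)) {
      set.seed(eseed * 100L + h)
      rec <- jitter_structure(base, 0.05,
                              sprintf("ent%02d_holo%02d", e, h))
      f <- file.path(dir, paste0(rec$structure_id, ".pdb"))
      write_structure(rec, f)
      files[[length(files) + 1L]] <- data.frame(
        file = basename(f), structure_id = rec$structure_id,
        state = "holo_complex", allele = base$allele, entity = e,
        stringsAsFactors = FALSE)
    }
    # apo replicates per side: perturbed CDR3/peptide + jitter
    for (a in seq_len(config$n_apo)) {
      for (side in c("tcr", "pmhc")) {
        lt <- if (side == "tcr") "CDR3b" else "peptide"
        ps <- perturbation_spec(lt, rigid_displacement = 0.6 + 0.4 * a,
                                internal_amplitude = 0.4,
                                seed = eseed * 100L + 10L * a +
                                  (side == "pmhc"))
        pair <- make_apo_holo_pair(base, ps, global_motion = TRUE)
        set.seed(eseed * 100L + 50L + 10L * a + (side == "pmhc"))
        rec <- jitter_structure(pair$apo, 0.03,
                                sprintf("ent%02d_apo_%s%02d", e, side, a))
        f <- file.path(dir, paste0(rec$structure_id, ".pdb"))
        write_structure(rec, f)
        files[[length(files) + 1L]] <- data.frame(
          file = basename(f), structure_id = rec$structure_id,
          state = rec$state, allele = base$allele, entity = e,
          stringsAsFactors = FALSE)
      }
    }
  }
  write_csv_det(do.call(rbind, files), file.path(dir, "inputs.csv"))
  write_csv_det(do.call(rbind, motif_rows), file.path(dir, "motifs.csv"))
  write_csv_det(do.call(rbind, gene_rows), file.path(dir, "genes.csv"))
  rep_tab <- make_background_repertoire(
    n = max(3L * config$background_n, 3000L), seed = config$seed)
  write_csv_det(rep_tab, file.path(dir, "repertoire.csv"))
  invisible(dir)
}

role_map_for_state <- function(state) {
  switch(state,
         holo_complex = c(A = "tcr_alpha", B = "tcr_beta", M = "mhc_heavy",
                          P = "peptide"),
         apo_tcr = c(A = "tcr_alpha", B = "tcr_beta"),
         apo_pmhc = c(M = "mhc_heavy", P = "peptide"))
}

load_curated <- function(config) {
  sim <- stage_dir(config, "simulate")
  inputs <- utils::read.csv(need_artifact(file.path(sim, "inputs.csv"),
                                          "simulate"),
                            stringsAsFactors = FALSE)
  inputs <- inputs[order(inputs$structure_id), , drop = FALSE]
  records <- lapply(seq_len(nrow(inputs)), function(i) {
    read_structure(file.path(sim, inputs$file[i]),
                   role_map_for_state(inputs$state[i]),
                   state = inputs$state[i],
                   structure_id = inputs$structure_id[i],
                   allele = inputs$allele[i])
  })
  records <- lapply(records, assign_regions, config = config$regions)
  manifest <- filter_quality(records, config$max_resolution, config$regions)
  match_apo_holo(manifest)
}

run_curate <- function(config) {
  dir <- stage_dir(config, "curate")
  manifest <- load_curated(config)
  write_manifest_csv(manifest, file.path(dir, "manifest.csv"),
                     file.path(dir, "rejections.csv"))
  write_csv_det(manifest$pairs, file.path(dir, "pairs.csv"))
  invisible(dir)
}

run_movement <- function(config) {
  dir <- stage_dir(config, "movement")
  need_artifact(file.path(config$output_dir, "curate", "manifest.csv"),
                "curate")
  manifest <- load_curated(config)
  tcr <- build_comparison_groups(manifest, "tcr")
  pmhc <- build_comparison_groups(manifest, "pmhc")
  write_csv_det(rbind(tcr, pmhc), file.path(dir, "movement.csv"))
  invisible(dir)
}

run_deformation <- function(config) {
  dir <- stage_dir(config, "deformation")
  need_artifact(file.path(config$output_dir, "curate", "manifest.csv"),
                "curate")
  manifest <- load_curated(config)
  pairs <- manifest$pairs
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    apo <- get_record(manifest, pairs$apo_id[k])
    holo <- get_record(manifest, pairs$holo_id[k])
    if (pairs$side[k] == "tcr") {
      targets <- LOOP_TYPES
    } else {
      targets <- "peptide"
    }
    for (lt in targets) {
      if (lt == "peptide") {
        sa <- apo$atoms[apo$atoms$role == "peptide", , drop = FALSE]
        sb <- holo$atoms[holo$atoms$role == "peptide", , drop = FALSE]
      } else {
        p <- loop_type_parts(lt)
        sa <- apo$atoms[apo$atoms$role == p$role &
                          apo$atoms$region %in% p$region, , drop = FALSE]
        sb <- holo$atoms[holo$atoms$role == p$role &
                           holo$atoms$region %in% p$region, , drop = FALSE]
      }
      fitres <- tryCatch({
        mc <- matched_coords(sa, sb)
        fit <- kabsch_fit(mc$a, mc$b, "loop backbone")
        sa2 <- sa
        sa2[, c("x", "y", "z")] <-
          apply_transform(as.matrix(sa[, c("x", "y", "z")]), fit)
        per_residue_heavy_rmsd(sa2, sb)
      }, error = function(e) NULL)
      if (is.null(fitres)) next
      fitres$entity_id <- pairs$entity_id[k]
      fitres$loop_or_region <- lt
      fitres$apo_id <- pairs$apo_id[k]; fitres$holo_id <- pairs$holo_id[k]
      rows[[length(rows) + 1L]] <- fitres
    }
  }
  write_csv_det(do.call(rbind, rows), file.path(dir, "per_residue.csv"))
  invisible(dir)
}

run_cluster <- function(config) {
  dir <- stage_dir(config, "cluster")
  need_artifact(file.path(config$output_dir, "curate", "manifest.csv"),
                "curate")
  manifest <- load_curated(config)
  states <- vapply(manifest$records, function(r) r$state, "")
  assigns <- list()
  for (lt in LOOP_TYPES) {
    loops <- list(); meta <- list()
    for (r in manifest$records[states != "apo_pmhc"]) {
      lc <- tryCatch(extract_loop(r, lt), error = function(e) NULL)
      if (is.null(lc)) next
      loops[[length(loops) + 1L]] <- lc
      meta[[length(meta) + 1L]] <- data.frame(
        loop_id = lc$loop_id, loop_type = lt,
        state = if (r$state == "apo_tcr") "apo" else "holo",
        entity_id = entity_key(r, "tcr"), stringsAsFactors = FALSE)
    }
    if (length(loops) < 2L) next
    dm <- build_distance_matrix(loops)
    write_csv_det(data.frame(id = rownames(dm), dm, check.names = FALSE),
                  file.path(dir, paste0("distances_", lt, ".csv")))
    seqs <- stats::setNames(vapply(loops, function(l) l$sequence, ""),
                            vapply(loops, function(l) l$loop_id, ""))
    cl <- cluster_loops(dm, seqs, config$min_cluster_size)
    m <- do.call(rbind, meta)
    assigns[[lt]] <- merge(cl, m, by = "loop_id", sort = TRUE)
  }
  all_assign <- do.call(rbind, assigns)
  rownames(all_assign) <- NULL
  write_csv_det(all_assign, file.path(dir, "assignments.csv"))
  write_csv_det(shift_count_table(all_assign),
                file.path(dir, "shift_counts.csv"))
  invisible(dir)
}

run_contacts <- function(config) {
  dir <- stage_dir(config, "contacts")
  need_artifact(file.path(config$output_dir, "curate", "manifest.csv"),
                "curate")
  manifest <- load_curated(config)
  states <- vapply(manifest$records, function(r) r$state, "")
  contact_rows <- lapply(manifest$records[states == "holo_complex"],
                         find_contacts, cutoff = config$contact_cutoff)
  contacts <- do.call(rbind, contact_rows)
  write_csv_det(contacts, file.path(dir, "contacts.csv"))
  for (tgt in c("mhc", "peptide")) {
    fp <- fingerprint(contacts, tgt)
    write_csv_det(as.data.frame(fp),
                  file.path(dir, paste0("fingerprint_", tgt, ".csv")))
    dl <- dominant_loops(fp, config$dominance_threshold)
    write_csv_det(dl, file.path(dir, paste0("dominant_", tgt, ".csv")))
  }
  invisible(dir)
}

run_anchors <- function(config) {
  dir <- stage_dir(config, "anchors")
  sim <- stage_dir(config, "simulate")
  motifs <- read_motif_csv(need_artifact(file.path(sim, "motifs.csv"),
                                         "simulate"))
  lib <- build_simplified_motif(motifs, config$motif_bands)
  manifest <- load_curated(config)
  rows <- list()
  for (r in manifest$records) {
    if (!"peptide" %in% r$atoms$role) next
    rt <- residue_table(r$atoms)
    pep <- paste(rt$aa[rt$role == "peptide"], collapse = "")
    ann <- assign_mode(annotate_structure(pep, r$allele, lib))
    rows[[length(rows) + 1L]] <- data.frame(
      structure_id = r$structure_id, entity_id = entity_key(r, "pmhc"),
      peptide = pep, allele = r$allele,
      anchors = paste(ann$anchors, collapse = ";"),
      mode = ann$mode, stringsAsFactors = FALSE)
  }
  write_csv_det(do.call(rbind, rows), file.path(dir, "annotations.csv"))
  invisible(dir)
}

run_report <- function(config) {
  dir <- stage_dir(config, "report")
  out <- config$output_dir
  movement <- utils::read.csv(
    need_artifact(file.path(out, "movement", "movement.csv"), "movement"),
    stringsAsFactors = FALSE)
  per_res <- utils::read.csv(
    need_artifact(file.path(out, "deformation", "per_residue.csv"),
                  "deformation"), stringsAsFactors = FALSE)
  fp_mhc <- utils::read.csv(
    need_artifact(file.path(out, "contacts", "fingerprint_mhc.csv"),
                  "contacts"), stringsAsFactors = FALSE)
  ann <- utils::read.csv(
    need_artifact(file.path(out, "anchors", "annotations.csv"), "anchors"),
    stringsAsFactors = FALSE)
  sim <- stage_dir(config, "simulate")
  genes <- utils::read.csv(file.path(sim, "genes.csv"),
                           stringsAsFactors = FALSE)
  repertoire <- utils::read.csv(file.path(sim, "repertoire.csv"),
                                stringsAsFactors = FALSE)

  norm <- normalize_by_entity(movement)
  # loop movement comparison (apo:holo, unsuperposed backbone RMSD)
  ah <- norm[norm$comparison == "apo_holo" & norm$metric == "backbone_rmsd" &
               norm$loop_or_region %in% LOOP_TYPES, ]
  groups <- split(ah$value, ah$loop_or_region)
  groups <- groups[lengths(groups) > 0L]
  kw_loops <- if (length(groups) >= 2L) kruskal_wallis(groups) else NULL
  posthoc <- if (length(groups) >= 2L)
    posthoc_wilcoxon_bonferroni(groups, alpha = config$alpha) else NULL

  # binding modes per entity
  modes <- lapply(split(ah$value, ah$entity_id), classify_binding_mode,
                  rigid_below = config$rigid_below,
                  flexible_above = config$flexible_above)
  binding <- data.frame(entity_id = names(modes),
                        mode = vapply(modes, `[[`, "", "mode"),
                        dual = vapply(modes, `[[`, TRUE, "dual_mode"),
                        row.names = NULL, stringsAsFactors = FALSE)

  # pMHC region movement with the contact partition
  manifest <- load_curated(config)
  fp <- structure(fp_mhc, class = c("contact_fingerprint",
                                    class(fp_mhc)))
  attr(fp, "target") <- "mhc"
  domain <- sort(unique(manifest$records[[1L]]$atoms$imgt[
    manifest$records[[1L]]$atoms$role == "mhc_heavy"]))
  part <- partition_mhc_positions(fp, domain)
  region_move <- peptide_region_movement(manifest, part)
  region_norm <- normalize_by_entity(region_move)
  rgroups <- split(region_norm$value, region_norm$loop_or_region)
  kw_regions <- if (length(rgroups) >= 2L) kruskal_wallis(rgroups) else NULL

  # anchor-conditioned peptide profiles
  pep_res <- per_res[per_res$loop_or_region == "peptide", ]
  mode_by_entity <- stats::setNames(ann$mode, ann$entity_id)
  profiles <- anchor_conditioned_peptide_profile(
    data.frame(entity_id = pep_res$entity_id, position = pep_res$imgt,
               value = pep_res$value, stringsAsFactors = FALSE),
    mode_by_entity)

  # gene-usage enrichment against the sampled background
  bg <- sample_background(repertoire, config$background_n,
                          config$background_reps, seed = config$seed)
  enrich <- lapply(c("TRAV", "TRBV"), function(col) {
    gene_usage_enrichment(genes[[col]], bg, col)
  })
  names(enrich) <- c("TRAV", "TRBV")

  write_csv_det(norm, file.path(dir, "movement_normalized.csv"))
  write_csv_det(binding, file.path(dir, "binding_modes.csv"))
  write_csv_det(region_norm, file.path(dir, "pmhc_region_movement.csv"))
  summary <- list(
    seed = config$seed,
    parameters = config[c("max_resolution", "contact_cutoff",
                          "dominance_threshold", "min_cluster_size",
                          "rigid_below", "flexible_above", "alpha")],
    loop_movement_kruskal_wallis = kw_loops,
    loop_movement_posthoc = posthoc,
    pmhc_region_kruskal_wallis = kw_regions,
    binding_modes = binding,
    group_sizes = lapply(groups, length),
    anchor_profiles = profiles,
    gene_enrichment = enrich)
  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", null = "null", na = "null")
  writeLines(json, file.path(dir, "report.json"))
  invisible(dir)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (write synthetic inputs), `curate` (read, filter,
#' match), `movement` (framework/floor-aligned RMSD and D-score tables),
#' `deformation` (loop-superposed per-residue profiles), `cluster` (DTW
#' distance matrices, cluster assignments, shift counts), `contacts`
#' (contact pairs and fingerprints), `anchors` (motif annotation and
#' anchoring modes), `report` (entity-normalised statistics as JSON + CSV).
#' Stages consume the artifacts of earlier stages and fail with a
#' dependency error naming the missing file when run out of order.
#'
#' @param name Stage name.
#' @param config A [run_config()].
#' @return The stage output directory, invisibly.
#' @export
run_subcommand <- function(name = c("simulate", "curate", "movement",
                                    "deformation", "cluster", "contacts",
                                    "anchors", "report"),
                           config) {
  name <- match.arg(name)
  stopifnot(inherits(config, "run_config"))
  switch(name,
         simulate = run_simulate(config),
         curate = run_curate(config),
         movement = run_movement(config),
         deformation = run_deformation(config),
         cluster = run_cluster(config),
         contacts = run_contacts(config),
         anchors = run_anchors(config),
         report = run_report(config))
}

#' Run the full pipeline end-to-end
#'
#' @param config A [run_config()].
#' @param stages Stage names, in order.
#' @return `config$output_dir`, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "curate", "movement",
                                    "deformation", "cluster", "contacts",
                                    "anchors", "report")) {
  for (s in stages) run_subcommand(s, config)
  invisible(config$output_dir)
}
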