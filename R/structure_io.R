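# structure_io: PDB reading/writing, IMGT region semantics, curation filters
# and apo-holo matching.

#' Construct a structure record
#'
#' A structure record holds one IMGT-numbered structure (unbound TCR, unbound
#' pMHC-I, or TCR:pMHC-I complex) as a flat atom table plus metadata. Atom
#' tables have columns `chain_id`, `role`, `imgt`, `ins`, `aa`, `atom`,
#' `element`, `x`, `y`, `z` and (after [assign_regions()]) `region`.
#'
#' @param structure_id Identifier (PDB-style id, optionally with model index).
#' @param state One of `"apo_tcr"`, `"apo_pmhc"`, `"holo_complex"`.
#' @param atoms Atom data frame as described above.
#' @param resolution Crystallographic resolution in Angstrom, or `NA`.
#' @param allele MHC allele name, or `NA` (used in pMHC entity identity).
#' @return An object of class `structure_record`.
#' @export
structure_record <- function(structure_id, state, atoms, resolution = NA_real_,
                             allele = NA_character_) {
  state <- match.arg(state, c("apo_tcr", "apo_pmhc", "holo_complex"))
  stopifnot(is.data.frame(atoms))
  atoms$ins[is.na(atoms$ins)] <- ""
  if (!all(atoms$role %in% CHAIN_ROLES)) {
    stop("unknown chain role(s): ",
         paste(setdiff(unique(atoms$role), CHAIN_ROLES), collapse = ", "))
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in structure ", structure_id)
  }
  roles <- unique(atoms$role)
  if (state == "holo_complex") {
    need <- c("tcr_alpha", "tcr_beta", "mhc_heavy", "peptide")
    if (!all(need %in% roles)) {
      stop("holo_complex requires roles ", paste(need, collapse = ", "))
    }
  } else if (state == "apo_tcr") {
    if (!all(c("tcr_alpha", "tcr_beta") %in% roles) ||
        any(c("mhc_heavy", "peptide") %in% roles)) {
      stop("apo_tcr requires tcr_alpha + tcr_beta and no pMHC chains")
    }
  } else {
    if (!all(c("mhc_heavy", "peptide") %in% roles) ||
        any(c("tcr_alpha", "tcr_beta") %in% roles)) {
      stop("apo_pmhc requires mhc_heavy + peptide and no TCR chains")
    }
  }
  # order residues by (chain, imgt, insertion code); chain order = first seen
  ord <- order(match(atoms$chain_id, unique(atoms$chain_id)),
               atoms$imgt, atoms$ins)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  if (is.null(atoms$region)) atoms$region <- NA_character_
  structure(list(structure_id = structure_id, state = state,
                 resolution = resolution, allele = allele, atoms = atoms),
            class = "structure_record")
}

#' @export
print.structure_record <- function(x, ...) {
  cat("structure_record", x$structure_id, sprintf("(%s)", x$state), "\n")
  cat("  chains:", paste(sprintf("%s[%s]", unique(x$atoms$chain_id),
                                 x$atoms$role[!duplicated(x$atoms$chain_id)]),
                         collapse = " "), "\n")
  cat("  atoms:", nrow(x$atoms),
      " resolution:", ifelse(is.na(x$resolution), "NA", x$resolution), "\n")
  invisible(x)
}

# One row per residue, in atom-table order.
residue_table <- function(atoms) {
  if (is.null(atoms$region)) atoms$region <- NA_character_
  key <- paste(atoms$chain_id, atoms$imgt, atoms$ins, sep = "|")
  first <- !duplicated(key)
  out <- atoms[first, c("chain_id", "role", "imgt", "ins", "aa", "region")]
  out$key <- key[first]
  bb <- atoms[atoms$atom %in% BACKBONE_ATOMS, ]
  nbb <- table(paste(bb$chain_id, bb$imgt, bb$ins, sep = "|"))
  out$complete_backbone <- as.integer(nbb[out$key]) == 4L
  out$complete_backbone[is.na(out$complete_backbone)] <- FALSE
  rownames(out) <- NULL
  out
}

parse_resolution_remark <- function(lines) {
  hit <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (!length(hit)) return(NA_real_)
  tail_part <- sub("^.*RESOLUTION\\.?", "", hit[1L])
  m <- regmatches(tail_part, regexpr("[0-9]+\\.?[0-9]*", tail_part))
  if (!length(m)) return(NA_real_)
  as.numeric(m)
}

#' Read an IMGT-numbered structure from a PDB file
#'
#' Reads ATOM records from a PDB file (model 1 only), drops hydrogens,
#' waters/ligands (HETATM) and unmapped chains, resolves alternate locations
#' to the highest-occupancy conformer, and attaches chain roles. Residue
#' numbers found in the file are taken as IMGT numbers; the package never
#' renumbers (an external numbering tool can be hooked in via `renumber`).
#'
#' @param path Path to a PDB-format file.
#' @param role_map Named character vector mapping chain id to role (one of
#'   `r paste(CHAIN_ROLES, collapse = ", ")`).
#' @param state Structure state; see [structure_record()].
#' @param structure_id Identifier; defaults to the file base name.
#' @param allele Optional MHC allele name.
#' @param renumber Optional function applied to the atom table before record
#'   construction (external-numberer hook); must return an atom table.
#' @return A [structure_record()].
#' @export
read_structure <- function(path, role_map, state,
                           structure_id = sub("\\.pdb$", "", basename(path)),
                           allele = NA_character_, renumber = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("unparseable PDB file ", path, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  chains_present <- unique(at$chain)
  missing_chains <- setdiff(names(role_map), chains_present)
  if (length(missing_chains)) {
    stop("role_map references chain(s) absent from file: ",
         paste(missing_chains, collapse = ", "))
  }
  at <- at[at$chain %in% names(role_map), , drop = FALSE]
  # drop hydrogens/deuterium by element symbol (fall back to atom name)
  elesy <- at$elesy
  elesy[is.na(elesy) | elesy == ""] <- sub("^[0-9]*([A-Za-z]).*$", "\\1",
                                           at$elety[is.na(elesy) | elesy == ""])
  keep <- !(toupper(elesy) %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  elesy <- elesy[keep]
  # altLoc: keep the highest-occupancy conformer per (chain, resno, ins, name)
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -occ)
  at <- at[ord, , drop = FALSE]
  elesy <- elesy[ord]
  first <- !duplicated(key[ord])
  at <- at[first, , drop = FALSE]
  elesy <- elesy[first]
  ins <- at$insert
  ins[is.na(ins)] <- ""
  atoms <- data.frame(
    chain_id = at$chain,
    role = unname(role_map[at$chain]),
    imgt = as.integer(at$resno),
    ins = ins,
    aa = suppressWarnings(bio3d::aa321(at$resid)),
    atom = at$elety,
    element = toupper(elesy),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  atoms$aa[is.na(atoms$aa)] <- "X"
  if (!is.null(renumber)) atoms <- renumber(atoms)
  resolution <- parse_resolution_remark(readLines(path, n = 100L))
  structure_record(structure_id, state, atoms, resolution = resolution,
                   allele = allele)
}

#' Write a structure record to a PDB file
#'
#' Coordinates are written at standard PDB precision (1e-3 Angstrom); the
#' resolution, when present, is written as a REMARK 2 header so that
#' [read_structure()] round-trips it.
#'
#' @param record A [structure_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(record, path) {
  at <- record$atoms
  aa3 <- bio3d::aa123(at$aa)
  aa3[is.na(aa3) | at$aa == "X"] <- "UNK"
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", nrow(at)),
                   resno = at$imgt, resid = aa3,
                   eleno = seq_len(nrow(at)), elety = at$atom,
                   chain = at$chain_id, insert = at$ins,
                   o = rep(1, nrow(at)), b = rep(0, nrow(at)),
                   elesy = at$element, end = TRUE)
  if (!is.na(record$resolution)) {
    lines <- readLines(path)
    remark <- sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.",
                      record$resolution)
    writeLines(c(remark, lines), path)
  }
  invisible(path)
}

#' Assign IMGT region semantics to a structure
#'
#' Populates the `region` column of the atom table: TCR chains are
#' partitioned into `FR`/`CDR1`/`CDR2`/`CDR3` over the variable domain, the
#' MHC heavy chain into `groove_floor`/`alpha1_helix`/`alpha2_helix`, and
#' peptide chains are wholly `peptide`. Positions outside all configured
#' ranges keep `NA`.
#'
#' @param record A [structure_record()].
#' @param config A [region_config()].
#' @return The record with regions assigned.
#' @export
assign_regions <- function(record, config = region_config()) {
  at <- record$atoms
  at$region <- NA_character_
  for (role in unique(at$role)) {
    sel <- at$role == role
    pos <- at$imgt[sel]
    reg <- rep(NA_character_, sum(sel))
    if (role %in% c("tcr_alpha", "tcr_beta")) {
      vd <- pos >= config$variable_domain[1L] & pos <= config$variable_domain[2L]
      if (!any(vd)) {
        stop("chain with role ", role, " has no residues in the variable ",
             "domain range; cannot assign regions")
      }
      reg[vd] <- "FR"
      reg[pos >= config$cdr1[1L] & pos <= config$cdr1[2L]] <- "CDR1"
      reg[pos >= config$cdr2[1L] & pos <= config$cdr2[2L]] <- "CDR2"
      reg[pos >= config$cdr3[1L] & pos <= config$cdr3[2L]] <- "CDR3"
    } else if (role == "mhc_heavy") {
      reg[pos %in% expand_ranges(config$groove_floor)] <- "groove_floor"
      reg[pos >= config$alpha1_helix[1L] & pos <= config$alpha1_helix[2L]] <- "alpha1_helix"
      reg[pos >= config$alpha2_helix[1L] & pos <= config$alpha2_helix[2L]] <- "alpha2_helix"
    } else if (role == "peptide") {
      reg[] <- "peptide"
    }
    at$region[sel] <- reg
  }
  record$atoms <- at
  record
}

# Sequence of a region on a role, N->C (one-letter string).
region_sequence <- function(record, role, region) {
  rt <- residue_table(record$atoms)
  paste(rt$aa[rt$role == role & !is.na(rt$region) & rt$region == region],
        collapse = "")
}

#' Entity identity key of a structure
#'
#' TCR identity is the concatenation of the six CDR sequences; pMHC identity
#' is the peptide sequence plus the allele name. Holo complexes have both.
#'
#' @param record A [structure_record()] with regions assigned.
#' @param side `"tcr"` or `"pmhc"`.
#' @return A character key, or `NA` if the side is absent.
#' @export
entity_key <- function(record, side = c("tcr", "pmhc")) {
  side <- match.arg(side)
  roles <- unique(record$atoms$role)
  if (side == "tcr") {
    if (!all(c("tcr_alpha", "tcr_beta") %in% roles)) return(NA_character_)
    paste(vapply(LOOP_TYPES, function(lt) {
      p <- loop_type_parts(lt)
      region_sequence(record, p$role, p$region)
    }, ""), collapse = "|")
  } else {
    if (!"peptide" %in% roles) return(NA_character_)
    rt <- residue_table(record$atoms)
    pep <- paste(rt$aa[rt$role == "peptide"], collapse = "")
    paste(pep, record$allele, sep = "|")
  }
}

#' Apply the curation quality filters
#'
#' Removes structures with resolution above the cutoff ("resolution") and
#' structures whose analysis-critical residues lack a complete backbone
#' ("missing residues"): any CDR residue for TCR-containing states, any
#' peptide residue for pMHC-containing states. Side-chain gaps never reject.
#' Resolution exactly at the cutoff is retained (strictly-greater rule);
#' unknown resolution is retained.
#'
#' @param records List of [structure_record()]s (regions are assigned if
#'   missing).
#' @param max_resolution Resolution cutoff in Angstrom.
#' @param config A [region_config()].
#' @return A `dataset_manifest`: list with `records` (kept), `pairs`
#'   (`NULL` until [match_apo_holo()]), and `rejections` (data frame of
#'   `structure_id`, `reason`).
#' @export
filter_quality <- function(records, max_resolution = 3.50,
                           config = region_config()) {
  ids <- vapply(records, function(r) r$structure_id, "")
  kept <- list()
  rej <- list()
  for (r in records) {
    if (all(is.na(r$atoms$region))) r <- assign_regions(r, config)
    reason <- NA_character_
    if (!is.na(r$resolution) && r$resolution > max_resolution) {
      reason <- "resolution"
    } else {
      rt <- residue_table(r$atoms)
      bad <- FALSE
      if (any(c("tcr_alpha", "tcr_beta") %in% rt$role)) {
        cdr <- rt[!is.na(rt$region) & rt$region %in% c("CDR1", "CDR2", "CDR3") &
                    rt$role %in% c("tcr_alpha", "tcr_beta"), ]
        bad <- bad || any(!cdr$complete_backbone)
      }
      if ("peptide" %in% rt$role) {
        pep <- rt[rt$role == "peptide", ]
        bad <- bad || any(!pep$complete_backbone)
      }
      if (bad) reason <- "missing residues"
    }
    if (is.na(reason)) {
      kept[[length(kept) + 1L]] <- r
    } else {
      rej[[length(rej) + 1L]] <- data.frame(structure_id = r$structure_id,
                                            reason = reason,
                                            stringsAsFactors = FALSE)
    }
  }
  rejections <- if (length(rej)) do.call(rbind, rej) else
    data.frame(structure_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  structure(list(records = kept, pairs = NULL, rejections = rejections),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat("dataset_manifest:", length(x$records), "records,",
      if (is.null(x$pairs)) 0L else nrow(x$pairs), "pairs,",
      nrow(x$rejections), "rejections\n")
  invisible(x)
}

#' Match apo structures to holo complexes
#'
#' Pairs every apo TCR with every holo complex sharing its six-CDR sequence
#' key, and every apo pMHC with every holo complex sharing its peptide
#' sequence and allele name. All apo x holo combinations are kept (entity
#' normalisation downstream removes redundancy); unpaired structures remain
#' in `records` but are noted in `unpaired`.
#'
#' @param manifest A `dataset_manifest` from [filter_quality()] (regions
#'   assigned).
#' @return The manifest with `pairs` populated (data frame: `entity_id`,
#'   `side`, `apo_id`, `holo_id`) and an `unpaired` note table.
#' @export
match_apo_holo <- function(manifest) {
  recs <- manifest$records
  ids <- vapply(recs, function(r) r$structure_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate structure_id in manifest: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  states <- vapply(recs, function(r) r$state, "")
  holo <- recs[states == "holo_complex"]
  rows <- list()
  paired <- character()
  for (side in c("tcr", "pmhc")) {
    apo_state <- if (side == "tcr") "apo_tcr" else "apo_pmhc"
    apo <- recs[states == apo_state]
    if (!length(apo) || !length(holo)) next
    akeys <- vapply(apo, entity_key, "", side = side)
    hkeys <- vapply(holo, entity_key, "", side = side)
    for (i in seq_along(apo)) {
      hits <- which(hkeys == akeys[i] & !is.na(hkeys))
      for (j in hits) {
        rows[[length(rows) + 1L]] <- data.frame(
          entity_id = akeys[i], side = side,
          apo_id = apo[[i]]$structure_id, holo_id = holo[[j]]$structure_id,
          stringsAsFactors = FALSE)
        paired <- c(paired, apo[[i]]$structure_id, holo[[j]]$structure_id)
      }
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(entity_id = character(), side = character(),
               apo_id = character(), holo_id = character(),
               stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$side, pairs$entity_id, pairs$apo_id,
                       pairs$holo_id), , drop = FALSE]
  rownames(pairs) <- NULL
  manifest$pairs <- pairs
  unpaired <- setdiff(ids, unique(paired))
  manifest$unpaired <- data.frame(
    structure_id = unpaired,
    note = rep("no apo-holo match", length(unpaired)),
    stringsAsFactors = FALSE)
  manifest
}

# Fetch a record from a manifest (or list of records) by structure_id.
get_record <- function(manifest, structure_id) {
  recs <- if (inherits(manifest, "dataset_manifest")) manifest$records else manifest
  for (r in recs) if (r$structure_id == structure_id) return(r)
  stop("no record with structure_id ", structure_id)
}

#' Write / read a dataset manifest as CSV
#'
#' The manifest table has one row per record (`structure_id`, `state`,
#' `resolution`, `tcr_entity`, `pmhc_entity`); the rejection log is a second
#' CSV. Structures themselves stay in their PDB files.
#'
#' @param manifest A `dataset_manifest`.
#' @param path Output CSV path for the record table.
#' @param rejections_path Optional output path for the rejection log.
#' @return `path`, invisibly.
#' @export
write_manifest_csv <- function(manifest, path, rejections_path = NULL) {
  tab <- do.call(rbind, lapply(manifest$records, function(r) {
    data.frame(structure_id = r$structure_id, state = r$state,
               resolution = r$resolution, allele = r$allele,
               tcr_entity = entity_key(r, "tcr"),
               pmhc_entity = entity_key(r, "pmhc"),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  if (!is.null(rejections_path)) {
    utils::write.csv(manifest$rejections, rejections_path, row.names = FALSE)
  }
  invisible(path)
}
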