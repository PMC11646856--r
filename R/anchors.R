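# anchors: simplified per-position peptide motifs from amino-acid frequency
# tables, anchor-position inference, structure annotation and grouping into
# p2-p9 vs p2-p5-p9 anchoring modes.

MOTIF_BANDS <- c(dominant = 0.60, high = 0.30, medium = 0.20, low = 0.10)

#' Band the per-position amino-acid proportions of a motif
#'
#' Amino acids are banded *dominant* when their proportion exceeds 60% of
#' the observed usage at that position, *high* in (30%, 60%], *medium* in
#' (20%, 30%], *low* in (10%, 20%] and *very_low* at or below 10%. Band
#' boundaries are half-open with the upper edge inclusive of the lower band
#' ("over 60%" is strict), so exactly 0.60 is high, not dominant.
#'
#' @param profile Motif profile data frame: `allele`, `length`, `position`,
#'   `aa`, `proportion`; proportions at each position must sum to 1 (1e-6).
#' @param bands Named thresholds, strictly decreasing.
#' @return The profile with a `band` factor column (`simplified_motif`).
#' @export
build_simplified_motif <- function(profile, bands = MOTIF_BANDS) {
  stopifnot(all(c("allele", "length", "position", "aa", "proportion")
                %in% names(profile)))
  if (any(diff(bands) >= 0)) stop("band thresholds must be strictly decreasing")
  sums <- tapply(profile$proportion,
                 paste(profile$allele, profile$length, profile$position), sum)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("per-position proportions do not sum to 1")
  }
  p <- profile$proportion
  band <- rep("very_low", length(p))
  band[p > bands["low"]] <- "low"
  band[p > bands["medium"]] <- "medium"
  band[p > bands["high"]] <- "high"
  band[p > bands["dominant"]] <- "dominant"
  profile$band <- factor(band, levels = c(names(bands), "very_low"))
  class(profile) <- c("simplified_motif", class(profile))
  profile
}

#' Infer peptide anchor positions from a banded motif
#'
#' Positions holding any dominant or high amino acid are assumed to anchor
#' the peptide in the MHC binding groove.
#'
#' @param motif A [build_simplified_motif()] result (one allele/length).
#' @return Sorted integer vector of anchor positions (possibly empty).
#' @export
infer_anchor_positions <- function(motif) {
  sort(unique(motif$position[motif$band %in% c("dominant", "high")]))
}

#' Annotate a peptide with motif anchors
#'
#' Assigns anchors at the positions where the peptide's residue is itself a
#' dominant/high residue of the allele's motif; requires the motif library
#' to hold a motif for the same allele and peptide length. A missing motif
#' yields an unannotated result (`anchors = NULL`), not an error.
#'
#' @param peptide One-letter peptide sequence.
#' @param allele MHC allele name.
#' @param motif_library A [build_simplified_motif()] table, possibly holding
#'   several alleles and lengths.
#' @return An `anchor_annotation`: list with `peptide`, `allele`, `anchors`
#'   (integer vector or `NULL`), `mode` (`NA` until [assign_mode()]),
#'   `annotated` flag.
#' @export
annotate_structure <- function(peptide, allele, motif_library) {
  n <- nchar(peptide)
  m <- motif_library[motif_library$allele == allele &
                       motif_library$length == n, , drop = FALSE]
  out <- list(peptide = peptide, allele = allele, anchors = NULL,
              mode = NA_character_, annotated = FALSE)
  class(out) <- "anchor_annotation"
  if (!nrow(m)) return(out)
  hit <- integer()
  for (pos in sort(unique(m$position))) {
    aa_here <- substr(peptide, pos, pos)
    strong <- m$aa[m$position == pos & m$band %in% c("dominant", "high")]
    if (aa_here %in% strong) hit <- c(hit, pos)
  }
  out$anchors <- hit
  out$annotated <- TRUE
  out
}

#' Assign a peptide anchoring mode
#'
#' Groups an annotation into the two anchoring modes: peptides anchored at
#' p2, the middle position and the C-terminus are `P2_P5_P9`; anchor sets
#' contained in {p2, C-terminus} (including single-end cases, which are
#' assumed to be anchored by another residue type at the missing end) are
#' `P2_P9`. Other patterns fall back to the nearer of the two groups by
#' symmetric set distance over the mode-determining positions and are
#' flagged. Only p2, the middle position (p5 for nonamers, ceiling(N/2)
#' otherwise) and the C-terminal position determine the mode; anchors
#' elsewhere are retained but not mode-determining.
#'
#' @param annotation An [annotate_structure()] result.
#' @param peptide_length Peptide length; defaults to the annotated peptide.
#' @return The annotation with `mode` set (`"P2_P9"`, `"P2_P5_P9"`, or `NA`
#'   when no anchors exist) and a `fallback` flag when the nearest-group
#'   rule was used.
#' @export
assign_mode <- function(annotation, peptide_length = nchar(annotation$peptide)) {
  n <- peptide_length
  mid <- if (n == 9L) 5L else as.integer(ceiling(n / 2))
  cterm <- n
  a <- annotation$anchors
  annotation$fallback <- FALSE
  if (is.null(a) || !length(a)) {
    annotation$mode <- NA_character_
    return(annotation)
  }
  amode <- intersect(a, c(2L, mid, cterm))
  if (all(c(2L, mid, cterm) %in% amode)) {
    annotation$mode <- "P2_P5_P9"
  } else if (length(amode) && all(amode %in% c(2L, cterm))) {
    annotation$mode <- "P2_P9"
  } else {
    d29 <- length(setdiff(amode, c(2L, cterm))) +
      length(setdiff(c(2L, cterm), amode))
    d259 <- length(setdiff(amode, c(2L, mid, cterm))) +
      length(setdiff(c(2L, mid, cterm), amode))
    annotation$mode <- if (d29 <= d259) "P2_P9" else "P2_P5_P9"
    annotation$fallback <- TRUE
  }
  annotation
}

#' Read / write a motif library CSV
#'
#' Columns: `allele`, `length`, `position`, `aa`, `proportion`.
#'
#' @param path CSV path.
#' @return Motif profile data frame.
#' @export
read_motif_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_motif_csv
#' @param profile Motif profile data frame.
#' @export
write_motif_csv <- function(profile, path) {
  drop <- intersect("band", names(profile))
  utils::write.csv(profile[, setdiff(names(profile), drop)], path,
                   row.names = FALSE)
  invisible(path)
}
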