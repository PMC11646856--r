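#' IMGT region configuration
#'
#' Region delimitations used to attach structural semantics to IMGT-numbered
#' chains. TCR variable domains are partitioned into framework (FR) and the
#' three CDR loops using the standard IMGT delimitations; for the MHC class I
#' heavy chain the beta-sheet floor of the peptide-binding groove and the two
#' helices are delimited on the alpha1/alpha2 domain. All ranges are
#' overridable: the groove-floor strand set in particular is a documented
#' default, not a fixed convention.
#'
#' @param cdr1,cdr2,cdr3 Integer length-2 vectors, inclusive IMGT ranges of
#'   the CDR loops on TCR chains.
#' @param variable_domain Inclusive IMGT range of the TCR variable domain;
#'   positions inside it that are not in a CDR are framework.
#' @param groove_floor List of inclusive ranges of MHC heavy-chain positions
#'   forming the groove floor (beta strands under the peptide).
#' @param alpha1_helix,alpha2_helix Inclusive ranges of the two groove helices.
#' @return A list of class `region_config`.
#' @export
region_config <- function(cdr1 = c(27L, 38L),
                          cdr2 = c(56L, 65L),
                          cdr3 = c(105L, 117L),
                          variable_domain = c(1L, 128L),
                          groove_floor = list(c(1L, 49L), c(94L, 139L)),
                          alpha1_helix = c(50L, 86L),
                          alpha2_helix = c(140L, 176L)) {
  cfg <- list(cdr1 = cdr1, cdr2 = cdr2, cdr3 = cdr3,
              variable_domain = variable_domain,
              groove_floor = groove_floor,
              alpha1_helix = alpha1_helix, alpha2_helix = alpha2_helix)
  class(cfg) <- "region_config"
  cfg
}

# Expand a list of inclusive ranges (or one range) into a position vector.
expand_ranges <- function(r) {
  if (is.list(r)) {
    unlist(lapply(r, function(x) seq.int(x[1L], x[2L])))
  } else {
    seq.int(r[1L], r[2L])
  }
}

CHAIN_ROLES <- c("tcr_alpha", "tcr_beta", "mhc_heavy", "beta2m", "peptide")

LOOP_TYPES <- c("CDR1a", "CDR2a", "CDR3a", "CDR1b", "CDR2b", "CDR3b")

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# Map a loop type like "CDR3a" to its chain role and region name.
loop_type_parts <- function(loop_type) {
  stopifnot(loop_type %in% LOOP_TYPES)
  role <- if (endsWith(loop_type, "a")) "tcr_alpha" else "tcr_beta"
  list(role = role, region = substr(loop_type, 1L, 4L))
}
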