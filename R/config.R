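#' @title Gene family and label vocabularies
#' @description Constant vectors used across the package.
#' @name vocabularies
NULL

#' Dsr-pathway gene families screened for in each proteome
#'
#' The inventory of the dissimilatory sulfate-reduction pathway:
#' the core enzymes Sat, AprAB and DsrAB/DsrC, the membrane complexes
#' QmoAB(C) and DsrMK(JOP), plus the accessory markers DsrD (allosteric
#' activator of DsrAB, indicator of a reductive metabolism), DsrL
#' (NAD(P)-dependent oxidoreductase) and the DsrEFH sulfur-donor complex.
#'
#' @return Character vector of the 19 family names.
#' @export
dsr_families <- function() {
  c("dsrA", "dsrB", "dsrC", "dsrD", "dsrE", "dsrF", "dsrH", "dsrL",
    "dsrM", "dsrK", "dsrJ", "dsrO", "dsrP",
    "sat", "aprA", "aprB", "qmoA", "qmoB", "qmoC")
}

# families that may carry a type/subtype label on a typed reference
typed_families <- function() c("dsrAB_concat", "dsrA", "dsrB", "dsrL")

dsrab_type_labels <- function() {
  c("REDUCTIVE_BACTERIAL", "OXIDATIVE_BACTERIAL", "REDUCTIVE_ARCHAEAL")
}

dsrl_subtype_labels <- function() c("L1A", "L1B", "L2A", "L2B", "L2C")

# DsrL subtypes read as indicators of an oxidative sulfur metabolism;
# L2C is the reductive-context subtype.
dsrl_oxidative_subtypes <- function() c("L1A", "L1B", "L2A", "L2B")

# required for the full sulfate -> sulfide pathway; qmoC and dsrJOP are
# optional subunits (QmoAB(C), DsrMK(JOP))
full_pathway_required <- function() {
  c("sat", "aprA", "aprB", "qmoA", "qmoB",
    "dsrA", "dsrB", "dsrC", "dsrM", "dsrK")
}

sulfite_only_required <- function() c("dsrA", "dsrB", "dsrC", "dsrM", "dsrK")
sulfate_branch        <- function() c("sat", "aprA", "aprB", "qmoA", "qmoB")

gtdb_rank_prefixes <- function() {
  c(domain = "d__", phylum = "p__", class = "c__", order = "o__",
    family = "f__", genus = "g__", species = "s__")
}

#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline. Fractions are in
#' `[0,1]`; `presence_display_frac` is applied strictly (`>`), matching the
#' lineage display rule (a gene is shown for a lineage only if more than
#' 30% of its dsrAB-containing genomes carry it), while `clade_pass_frac`
#' is inclusive (`>=`), matching the primer clade-coverage rule (at least
#' 75% of clade members matched with at most one mismatch).
#'
#' @param presence_display_frac Strict lower bound for lineage-level gene
#'   presence display. Default 0.30.
#' @param clade_pass_frac Inclusive primer clade-coverage pass threshold.
#'   Default 0.75.
#' @param max_primer_mismatches Mismatch budget per primer. Default 1.
#' @param indel_filter_max_gap_frac Maximum per-column gap fraction kept by
#'   the alignment indel filter. Default 0.5.
#' @param coloc_window_genes Gene-index distance defining co-localization
#'   on a contig. Default 10.
#' @param typing_k Number of nearest typed references consulted. Default 5.
#' @param substitution_matrix Scoring matrix name. Default "BLOSUM62".
#' @param gap_open Affine gap opening penalty (a gap of length L costs
#'   `gap_open + L * gap_extend`). Default 11.
#' @param gap_extend Affine gap extension penalty. Default 1.
#' @param detect_frac Minimum fraction-of-self-score for a family hit.
#'   Default 0.3.
#' @param detect_margin Minimum normalized-score gap to the second-best
#'   family. Default 0.05.
#' @param target_ambiguity_is_mismatch If TRUE an ambiguity code on the
#'   target side of a primer comparison counts as a mismatch instead of
#'   using set-intersection semantics. Default FALSE.
#' @param merge_phylum_sublineages If TRUE GTDB sublineage suffixes
#'   (`_A` ... `_H`) are merged before lineage aggregation. Default TRUE.
#' @param rng_seed Integer seed for any randomized step. Default 1.
#' @return A list of class `dsr_config`.
#' @export
analysis_config <- function(presence_display_frac = 0.30,
                            clade_pass_frac = 0.75,
                            max_primer_mismatches = 1L,
                            indel_filter_max_gap_frac = 0.5,
                            coloc_window_genes = 10L,
                            typing_k = 5L,
                            substitution_matrix = "BLOSUM62",
                            gap_open = 11,
                            gap_extend = 1,
                            detect_frac = 0.3,
                            detect_margin = 0.05,
                            target_ambiguity_is_mismatch = FALSE,
                            merge_phylum_sublineages = TRUE,
                            rng_seed = 1L) {
  cfg <- list(
    presence_display_frac = presence_display_frac,
    clade_pass_frac = clade_pass_frac,
    max_primer_mismatches = as.integer(max_primer_mismatches),
    indel_filter_max_gap_frac = indel_filter_max_gap_frac,
    coloc_window_genes = as.integer(coloc_window_genes),
    typing_k = as.integer(typing_k),
    substitution_matrix = substitution_matrix,
    gap_open = gap_open,
    gap_extend = gap_extend,
    detect_frac = detect_frac,
    detect_margin = detect_margin,
    target_ambiguity_is_mismatch = isTRUE(target_ambiguity_is_mismatch),
    merge_phylum_sublineages = isTRUE(merge_phylum_sublineages),
    rng_seed = as.integer(rng_seed)
  )
  fracs <- c("presence_display_frac", "clade_pass_frac",
             "indel_filter_max_gap_frac", "detect_frac", "detect_margin")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      abort_config("%s must be a single value in [0,1], got %s", f, v)
  }
  for (f in c("max_primer_mismatches", "coloc_window_genes", "typing_k",
              "rng_seed")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L)
      abort_config("%s must be a non-negative integer", f)
  }
  if (cfg$typing_k < 1L) abort_config("typing_k must be >= 1")
  structure(cfg, class = "dsr_config")
}

#' Read / write an analysis configuration as YAML
#'
#' The YAML file holds a flat mapping whose keys mirror the arguments of
#' [analysis_config()]; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return [read_analysis_config()] returns a `dsr_config`;
#'   [write_analysis_config()] returns `path` invisibly.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) abort_config("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    abort_config("unknown config keys: %s", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @rdname read_analysis_config
#' @param config A `dsr_config` object.
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "dsr_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# short stable fingerprint of a config, stamped into output tables
config_hash <- function(config) {
  s <- paste(names(config), vapply(config, format, ""), sep = "=",
             collapse = ";")
  # stable 31-bit polynomial hash; avoids an external digest dependency
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
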