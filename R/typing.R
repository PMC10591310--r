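#' Filter alignment columns by gap fraction
#'
#' Keeps a column iff its gap fraction (characters `-` or `.`) is at most
#' `max_gap_frac`; the classical "indel filter" applied before distance or
#' tree computation on a DsrAB alignment.
#'
#' @param alignment_rows Character vector of equal-length gapped rows.
#' @param max_gap_frac Maximum tolerated per-column gap fraction.
#' @return List of class `dsr_column_mask`: `keep` (logical vector),
#'   `kept_count`.
#' @export
apply_indel_filter <- function(alignment_rows, max_gap_frac = 0.5) {
  if (length(alignment_rows) == 0L)
    abort_empty_input("no alignment rows")
  lens <- nchar(alignment_rows)
  if (length(unique(lens)) != 1L)
    abort_alignment("ragged alignment: row lengths %s",
                    paste(unique(lens), collapse = ", "))
  m <- do.call(rbind, strsplit(alignment_rows, ""))
  gap_frac <- colMeans(m == "-" | m == ".")
  keep <- gap_frac <= max_gap_frac
  structure(list(keep = keep, kept_count = sum(keep)),
            class = "dsr_column_mask")
}

# k-nearest typed references by normalized alignment score.
# Deterministic under reordering of refs: candidates sorted by
# (-norm_score, id).
knn_typed <- function(query, refs, config) {
  raw <- score_against(query, refs$residues, config$substitution_matrix,
                       config$gap_open, config$gap_extend)
  norm <- raw / refs$self_score
  ord <- order(-norm, refs$id)
  k <- min(config$typing_k, nrow(refs))
  data.frame(id = refs$id[ord][seq_len(k)],
             type_label = refs$type_label[ord][seq_len(k)],
             early_diverging = refs$early_diverging[ord][seq_len(k)],
             taxonomy = refs$taxonomy[ord][seq_len(k)],
             norm_score = norm[ord][seq_len(k)],
             stringsAsFactors = FALSE)
}

majority_call <- function(nn, family, query_id, partial = FALSE) {
  k <- nrow(nn)
  votes <- sort(table(nn$type_label), decreasing = TRUE)
  top_n <- as.integer(votes[1])
  tied <- sum(votes == votes[1]) > 1L
  label <- if (!tied && top_n > k / 2) names(votes)[1] else "UNCERTAIN"
  support <- top_n / k
  structure(list(query_id = query_id, family = family,
                 assigned_label = label,
                 support = support,
                 k_used = k,
                 nearest_ref_id = nn$id[1],
                 nearest_ref_taxonomy = nn$taxonomy[1],
                 early_diverging = sum(nn$early_diverging) >= k / 2,
                 partial = partial,
                 neighbors = nn),
            class = "dsr_type_call")
}

#' Classify DsrAB into its three major phylogenetic types
#'
#' The query (concatenated DsrA+DsrB when both subunits are present,
#' otherwise the single subunit, flagged `partial`) is scored against the
#' typed references of the matching family; the label is the majority
#' among the k nearest by normalized score, with `support` the agreeing
#' fraction. When no label reaches a strict majority of the k votes
#' (including vote ties) the call is `UNCERTAIN`. The `early_diverging`
#' flag is
#' inherited when at least half of the k nearest references carry it.
#'
#' @param dsrA_seq,dsrB_seq Amino-acid strings (either may be `NULL`).
#' @param typed_refs Typed reference data.frame (from
#'   [load_reference_db()]`$typed` or the generator).
#' @param config `dsr_config`.
#' @param query_id Id recorded in the call.
#' @return A `dsr_type_call` (fields `assigned_label` in
#'   REDUCTIVE_BACTERIAL / OXIDATIVE_BACTERIAL / REDUCTIVE_ARCHAEAL /
#'   UNCERTAIN, `support`, `nearest_ref_id`, `early_diverging`, ...).
#' @export
type_dsrab <- function(dsrA_seq = NULL, dsrB_seq = NULL, typed_refs,
                       config = analysis_config(), query_id = "query") {
  if (is.null(dsrA_seq) && is.null(dsrB_seq))
    abort_value("both DsrA and DsrB are absent; nothing to type")
  if (!is.null(dsrA_seq) && !is.null(dsrB_seq)) {
    fam <- "dsrAB_concat"; query <- paste0(dsrA_seq, dsrB_seq)
    partial <- FALSE
  } else if (!is.null(dsrA_seq)) {
    fam <- "dsrA"; query <- dsrA_seq; partial <- TRUE
  } else {
    fam <- "dsrB"; query <- dsrB_seq; partial <- TRUE
  }
  refs <- typed_refs[typed_refs$family == fam, , drop = FALSE]
  if (nrow(refs) == 0L)
    abort_config("no typed references of family %s", fam)
  majority_call(knn_typed(query, refs, config), fam, query_id, partial)
}

#' Classify DsrL into subclusters 1A/1B/2A/2B/2C
#'
#' Same nearest-typed-reference scheme as [type_dsrab()], over the DsrL
#' subtype references. Subtypes 1A/1B/2A/2B indicate an oxidative sulfur
#' metabolism; 2C a reductive one.
#'
#' @param dsrL_seq Amino-acid string.
#' @inheritParams type_dsrab
#' @return A `dsr_type_call` with `assigned_label` in L1A/L1B/L2A/L2B/L2C
#'   or UNCERTAIN.
#' @export
subtype_dsrl <- function(dsrL_seq, typed_refs, config = analysis_config(),
                         query_id = "query") {
  check_amino(dsrL_seq, "dsrL")
  refs <- typed_refs[typed_refs$family == "dsrL", , drop = FALSE]
  if (nrow(refs) == 0L) abort_config("no typed dsrL references")
  majority_call(knn_typed(dsrL_seq, refs, config), "dsrL", query_id)
}

#' Flag a lateral gene transfer candidate
#'
#' A dsrAB gene whose nearest typed references live in a different phylum
#' than its host genome is a candidate for lateral acquisition (the
#' classic example being Desulfotomaculum-group Bacillota carrying
#' Desulfobacterota-type dsrAB). The flag requires typing support of at
#' least 0.5; phyla are compared after GTDB sublineage merging. The flag
#' marks discordance only; it never asserts a transfer event.
#'
#' @param genome_taxonomy GTDB taxonomy string (or phylum) of the genome.
#' @param type_call A `dsr_type_call`.
#' @return List: `flagged` (logical), `note` (character).
#' @export
flag_lgt_candidate <- function(genome_taxonomy, type_call) {
  gphy <- taxonomy_phylum(genome_taxonomy)
  rphy <- taxonomy_phylum(type_call$nearest_ref_taxonomy)
  if (is.na(gphy) || !nzchar(gphy))
    abort_taxonomy("genome taxonomy lacks a phylum rank")
  if (is.na(rphy) || !nzchar(rphy))
    abort_taxonomy("reference taxonomy lacks a phylum rank")
  gphy <- normalize_phylum(gphy)
  rphy <- normalize_phylum(rphy)
  flagged <- gphy != rphy && type_call$support >= 0.5
  note <- if (flagged)
    sprintf("genome phylum %s vs nearest-reference phylum %s (support %.2f)",
            gphy, rphy, type_call$support)
  else ""
  list(flagged = flagged, note = note)
}

# accepts either a full GTDB string or a bare/prefixed phylum name
taxonomy_phylum <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NA_character_)
  if (grepl(";", x) || grepl("__", x)) {
    phy <- parse_gtdb_taxonomy(x)$phylum
    return(phy)
  }
  x
}
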