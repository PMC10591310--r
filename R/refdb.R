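#' Construct a reference family
#'
#' A reference family bundles the seed proteins used to detect one
#' Dsr-pathway gene family by local alignment. Seed self-scores (the score
#' of each seed aligned to itself) are precomputed because every query
#' score is normalized by the self-score of its best seed.
#'
#' @param family Family name, one of [dsr_families()].
#' @param seeds Amino-acid record table (>= 1 row).
#' @param seed_alignment Optional equal-length gapped rows (character
#'   vector, same order as seeds) whose degapped form must equal the seeds.
#' @param config `dsr_config` supplying the scoring parameters.
#' @return List of class `dsr_ref_family`.
#' @export
reference_family <- function(family, seeds, seed_alignment = NULL,
                             config = analysis_config()) {
  if (!family %in% dsr_families())
    abort_label_domain("unknown gene family '%s'", family)
  if (nrow(seeds) < 1L) abort_empty_input("family %s has no seeds", family)
  if (!is.null(seed_alignment)) {
    if (length(unique(nchar(seed_alignment))) != 1L)
      abort_alignment("seed alignment rows differ in length")
    degapped <- gsub("[-.]", "", seed_alignment)
    if (!identical(degapped, seeds$residues))
      abort_alignment("degapped alignment rows do not equal seed residues")
  }
  structure(list(family = family, seeds = seeds,
                 seed_alignment = seed_alignment,
                 self_scores = self_score(seeds$residues,
                                          config$substitution_matrix)),
            class = "dsr_ref_family")
}

typed_label_ok <- function(family, label) {
  if (family == "dsrL") label %in% dsrl_subtype_labels()
  else if (family %in% c("dsrA", "dsrB", "dsrAB_concat"))
    label %in% dsrab_type_labels()
  else FALSE
}

#' Load a reference database (FASTA + metadata TSV)
#'
#' The metadata TSV (columns `id`, `family`, `type_label`,
#' `early_diverging`, `taxonomy`, `uncultured_lineage`) labels every FASTA
#' record. Rows with an empty `type_label` become detection seeds of their
#' family; rows with a `type_label` become typed references (DsrAB type or
#' DsrL subtype) used for nearest-reference classification. `taxonomy` is
#' a GTDB-style 7-rank string; `early_diverging` is logical and only
#' admissible with reductive type labels; `uncultured_lineage` is an
#' integer 1-13 or empty.
#'
#' @param fasta_path Amino-acid FASTA of all reference sequences.
#' @param metadata_tsv_path Metadata TSV as described above.
#' @param config `dsr_config`.
#' @return List with elements `families` (named list of `dsr_ref_family`)
#'   and `typed` (data.frame of typed references).
#' @export
load_reference_db <- function(fasta_path, metadata_tsv_path,
                              config = analysis_config()) {
  rec <- read_fasta(fasta_path, "AMINO")
  meta <- utils::read.delim(metadata_tsv_path, sep = "\t",
                            colClasses = "character")
  required <- c("id", "family", "type_label", "early_diverging",
                "taxonomy", "uncultured_lineage")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    abort_schema("metadata TSV lacks column(s): %s",
                 paste(missing_cols, collapse = ", "))
  if (anyDuplicated(meta$id))
    abort_duplicate_id("duplicate metadata id(s): %s",
                       paste(unique(meta$id[duplicated(meta$id)]),
                             collapse = ", "))
  only_fasta <- setdiff(rec$id, meta$id)
  only_meta <- setdiff(meta$id, rec$id)
  if (length(only_fasta) || length(only_meta))
    abort_metadata("FASTA/metadata id mismatch (FASTA-only: %s; TSV-only: %s)",
                   paste(only_fasta, collapse = ","),
                   paste(only_meta, collapse = ","))
  meta <- meta[match(rec$id, meta$id), ]
  meta$residues <- rec$residues
  is_typed <- nzchar(meta$type_label)

  seeds <- meta[!is_typed, , drop = FALSE]
  bad_fam <- setdiff(unique(seeds$family), dsr_families())
  if (length(bad_fam))
    abort_label_domain("unknown seed family name(s): %s",
                       paste(bad_fam, collapse = ", "))
  families <- lapply(split(seeds, seeds$family), function(df) {
    reference_family(df$family[1],
                     seq_records(df$id, df$residues, "AMINO",
                                 description = ""),
                     config = config)
  })

  typed <- meta[is_typed, , drop = FALSE]
  if (nrow(typed)) {
    ok <- mapply(typed_label_ok, typed$family, typed$type_label)
    if (any(!ok))
      abort_label_domain("illegal type_label for family: %s",
                         paste(sprintf("%s/%s", typed$family[!ok],
                                       typed$type_label[!ok]),
                               collapse = ", "))
  }
  typed_df <- data.frame(
    id = typed$id, residues = typed$residues, family = typed$family,
    type_label = typed$type_label,
    early_diverging = toupper(typed$early_diverging) %in% c("TRUE", "T", "1"),
    taxonomy = typed$taxonomy,
    uncultured_lineage = suppressWarnings(as.integer(typed$uncultured_lineage)),
    stringsAsFactors = FALSE)
  bad_early <- typed_df$early_diverging &
    !typed_df$type_label %in% c("REDUCTIVE_BACTERIAL", "REDUCTIVE_ARCHAEAL",
                                "L2C")
  if (any(bad_early))
    abort_label_domain("early_diverging flagged on non-reductive label: %s",
                       paste(typed_df$id[bad_early], collapse = ", "))
  bad_lin <- !is.na(typed_df$uncultured_lineage) &
    (typed_df$uncultured_lineage < 1L | typed_df$uncultured_lineage > 13L)
  if (any(bad_lin))
    abort_value("uncultured_lineage outside 1-13: %s",
                paste(typed_df$id[bad_lin], collapse = ", "))
  typed_df$self_score <- self_score(typed_df$residues,
                                    config$substitution_matrix)
  list(families = families, typed = typed_df)
}

#' Canonical phylum name under GTDB sublineage merging
#'
#' GTDB provisionally splits some phyla into suffixed sublineages
#' (Bacillota_A ... Bacillota_H); for lineage-level counting these are
#' treated as one phylum. The rule strips any trailing run of
#' `_<CAPITALS>` tokens (applied to exhaustion so the function is
#' idempotent) and removes a leading `p__` prefix.
#'
#' @param name Phylum name, with or without the `p__` prefix.
#' @return Canonical phylum string (no prefix).
#' @export
normalize_phylum <- function(name) {
  if (any(!nzchar(name) | is.na(name)))
    abort_value("empty phylum name")
  out <- sub("^p__", "", name)
  sub("(_[A-Z]+)+$", "", out)
}

#' Parse a GTDB-style taxonomy string into named ranks
#'
#' @param taxonomy Strings like
#'   `"d__Bacteria;p__Desulfobacterota;c__...;s__..."`.
#' @return data.frame with columns domain...species (prefixes stripped).
#' @export
parse_gtdb_taxonomy <- function(taxonomy) {
  prefixes <- gtdb_rank_prefixes()
  out <- as.data.frame(matrix(NA_character_, length(taxonomy),
                              length(prefixes)),
                       stringsAsFactors = FALSE)
  names(out) <- names(prefixes)
  for (i in seq_along(taxonomy)) {
    parts <- trimws(strsplit(taxonomy[i], ";")[[1]])
    for (r in seq_along(prefixes)) {
      hit <- parts[startsWith(parts, prefixes[r])]
      if (length(hit))
        out[i, r] <- sub(prefixes[r], "", hit[1], fixed = TRUE)
    }
  }
  out
}

#' Load a genome taxonomy table
#'
#' TSV with columns `genome_id`, `taxonomy` (GTDB 7-rank string) and
#' optional `completeness`, `contamination` (percent).
#'
#' @param path TSV file.
#' @return data.frame with `genome_id`, the raw `taxonomy` string, parsed
#'   rank columns and the quality columns.
#' @export
load_taxonomy <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", colClasses = "character")
  if (!all(c("genome_id", "taxonomy") %in% names(tab)))
    abort_schema("taxonomy TSV needs columns genome_id, taxonomy")
  if (anyDuplicated(tab$genome_id))
    abort_duplicate_id("duplicate genome_id in taxonomy table")
  ranks <- parse_gtdb_taxonomy(tab$taxonomy)
  out <- cbind(data.frame(genome_id = tab$genome_id,
                          taxonomy = tab$taxonomy,
                          stringsAsFactors = FALSE), ranks)
  for (q in c("completeness", "contamination")) {
    v <- if (q %in% names(tab)) suppressWarnings(as.numeric(tab[[q]]))
         else NA_real_
    if (any(!is.na(v) & (v < 0 | v > 100)))
      abort_value("%s outside [0,100]", q)
    out[[q]] <- v
  }
  out
}

#' Load degenerate primer mixes from a TSV
#'
#' Columns: `mix_name`, `primer_name`, `iupac` (5'->3'), `orientation`
#' (FORWARD/REVERSE), optional `anchor_position`, `coordinate_reference`.
#' Variants are grouped by `mix_name`; a mix must be single-orientation.
#' Primer sequences are configuration input, never shipped constants.
#'
#' @param tsv_path Primer TSV.
#' @return Named list of `dsr_primer_mix` objects (fields `name`,
#'   `orientation`, `variants` data.frame).
#' @export
load_primers <- function(tsv_path) {
  tab <- utils::read.delim(tsv_path, sep = "\t", colClasses = "character")
  need <- c("mix_name", "primer_name", "iupac", "orientation")
  if (!all(need %in% names(tab)))
    abort_schema("primer TSV needs columns %s", paste(need, collapse = ", "))
  if (nrow(tab) == 0L) abort_empty_input("primer TSV is empty")
  if (anyDuplicated(tab$primer_name))
    abort_duplicate_id("duplicate primer_name(s): %s",
                       paste(unique(tab$primer_name[duplicated(tab$primer_name)]),
                             collapse = ", "))
  tab$iupac <- toupper(tab$iupac)
  for (i in seq_len(nrow(tab))) {
    chars <- strsplit(tab$iupac[i], "")[[1]]
    bad <- which(!chars %in% iupac_alphabet())
    if (length(bad))
      abort_alphabet("primer '%s': invalid IUPAC character '%s' at position %d",
                     tab$primer_name[i], chars[bad[1]], bad[1])
  }
  if (any(!tab$orientation %in% c("FORWARD", "REVERSE")))
    abort_orientation("orientation must be FORWARD or REVERSE")
  if (!"anchor_position" %in% names(tab)) tab$anchor_position <- NA
  if (!"coordinate_reference" %in% names(tab))
    tab$coordinate_reference <- NA_character_
  tab$anchor_position <- suppressWarnings(as.integer(tab$anchor_position))
  lapply(split(tab, tab$mix_name), function(df) {
    if (length(unique(df$orientation)) != 1L)
      abort_orientation("mix '%s' combines FORWARD and REVERSE variants",
                        df$mix_name[1])
    structure(list(name = df$mix_name[1], orientation = df$orientation[1],
                   variants = df[, c("primer_name", "iupac", "orientation",
                                     "anchor_position",
                                     "coordinate_reference")]),
              class = "dsr_primer_mix")
  })
}
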