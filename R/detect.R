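#' Assign a query protein to a Dsr-pathway gene family
#'
#' The query is scored against every seed of every reference family; the
#' per-family score is the maximum normalized score (raw Smith-Waterman
#' score divided by the self-score of the seed attaining it). The best
#' family is reported only if its normalized score reaches `detect_frac`
#' and its margin over the second-best family reaches `detect_margin`.
#' When the two top families are exactly dsrA and dsrB and only the margin
#' fails, the hit is reported as `UNASSIGNED_DSR` (a dsrAB gene that
#' cannot be attributed to one subunit, e.g. on a fragmented MAG).
#'
#' @param query Amino-acid string.
#' @param families Named list of `dsr_ref_family` objects.
#' @param config `dsr_config`.
#' @param query_id Id recorded in the hit (default "query").
#' @return A one-row data.frame (`query_id`, `family`, `best_seed_id`,
#'   `raw_score`, `norm_score`, `margin`) or `NULL` when no family
#'   qualifies.
#' @export
detect_family <- function(query, families, config = analysis_config(),
                          query_id = "query") {
  if (length(families) == 0L) abort_config("no reference families loaded")
  fam_names <- vapply(families, `[[`, "", "family")
  all_seeds <- unlist(lapply(families, function(f) f$seeds$residues),
                      use.names = FALSE)
  seed_ids <- unlist(lapply(families, function(f) f$seeds$id),
                     use.names = FALSE)
  seed_fams <- rep(fam_names, vapply(families,
                                     function(f) nrow(f$seeds), 0L))
  selfs <- unlist(lapply(families, `[[`, "self_scores"), use.names = FALSE)
  raw <- score_against(query, all_seeds, config$substitution_matrix,
                       config$gap_open, config$gap_extend)
  norm <- raw / selfs
  # per-family best normalized score, deterministic tie-break by seed order
  best_idx <- vapply(split(seq_along(norm), seed_fams),
                     function(ix) ix[which.max(norm[ix])], 0L)
  fam_norm <- norm[best_idx]
  ord <- order(-fam_norm, names(best_idx))
  top <- ord[1]
  second <- if (length(ord) > 1L) ord[2] else NA_integer_
  margin <- if (is.na(second)) fam_norm[top] else fam_norm[top] - fam_norm[second]
  if (fam_norm[top] < config$detect_frac) return(NULL)
  family <- names(best_idx)[top]
  if (margin < config$detect_margin) {
    pair <- sort(c(names(best_idx)[top], names(best_idx)[second]))
    if (identical(pair, c("dsrA", "dsrB"))) family <- "UNASSIGNED_DSR"
    else return(NULL)
  }
  i <- best_idx[top]
  data.frame(query_id = query_id, family = family,
             best_seed_id = seed_ids[i], raw_score = raw[i],
             norm_score = norm[i], margin = margin,
             stringsAsFactors = FALSE, row.names = NULL)
}

empty_hits <- function() {
  data.frame(query_id = character(), family = character(),
             best_seed_id = character(), raw_score = numeric(),
             norm_score = numeric(), margin = numeric(),
             contig_id = character(), gene_index = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Screen a proteome for Dsr-pathway genes
#'
#' Runs [detect_family()] on every protein of one genome and collects the
#' qualifying hits into a gene complement. Every protein is assigned to at
#' most one family; multiple copies of a family (e.g. two dsrAB loci) are
#' all retained. Hit lists are sorted by decreasing normalized score
#' within each family.
#'
#' @param proteome Amino-acid record table; `genome_id` must be set (all
#'   rows identical) and locus metadata is carried through when present.
#' @param refdb Reference database from [load_reference_db()] (or a bare
#'   named list of families).
#' @param config `dsr_config`.
#' @param lenient If TRUE an empty proteome yields an empty complement
#'   with a warning instead of an error.
#' @return List of class `dsr_complement`: `genome_id`, `hits`
#'   (data.frame), `proteome_size`.
#' @export
screen_genome <- function(proteome, refdb, config = analysis_config(),
                          lenient = FALSE) {
  families <- if (!is.null(refdb$families)) refdb$families else refdb
  if (nrow(proteome) == 0L) {
    if (!lenient) abort_empty_input("proteome is empty")
    warning("empty proteome; returning empty complement")
    return(structure(list(genome_id = NA_character_, hits = empty_hits(),
                          proteome_size = 0L), class = "dsr_complement"))
  }
  gid <- unique(proteome$genome_id)
  gid <- gid[!is.na(gid)]
  if (length(gid) != 1L)
    abort_value("proteome must carry exactly one genome_id, found: %s",
                paste(gid, collapse = ", "))
  hits <- vector("list", nrow(proteome))
  for (i in seq_len(nrow(proteome))) {
    h <- detect_family(proteome$residues[i], families, config,
                       query_id = proteome$id[i])
    if (!is.null(h)) {
      h$contig_id <- proteome$contig_id[i]
      h$gene_index <- proteome$gene_index[i]
      h$strand <- proteome$strand[i]
      hits[[i]] <- h
    }
  }
  hits <- do.call(rbind, c(list(empty_hits()), hits[!vapply(hits, is.null,
                                                            TRUE)]))
  hits <- hits[order(hits$family, -hits$norm_score, hits$query_id), ,
               drop = FALSE]
  row.names(hits) <- NULL
  structure(list(genome_id = gid, hits = hits,
                 proteome_size = nrow(proteome)),
            class = "dsr_complement")
}

# convenience: families present in a complement
complement_families <- function(complement) unique(complement$hits$family)

has_family <- function(complement, family) {
  family %in% complement$hits$family
}
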