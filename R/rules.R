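#' Are two gene loci co-localized?
#'
#' Tri-state test: `TRUE` iff both loci sit on the same contig with gene
#' indices at most `window` apart, `FALSE` if demonstrably not, `NA` when
#' either locus lacks contig/index metadata (fragmented MAGs).
#'
#' @param locusA,locusB Lists or one-row data.frames with `contig_id` and
#'   `gene_index`.
#' @param window Maximum gene-index distance (default 10).
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
colocalized <- function(locusA, locusB, window = 10L) {
  ca <- locusA$contig_id; cb <- locusB$contig_id
  ia <- locusA$gene_index; ib <- locusB$gene_index
  if (is.null(ca) || is.null(cb) || is.null(ia) || is.null(ib) ||
      is.na(ca) || is.na(cb) || is.na(ia) || is.na(ib))
    return(NA)
  if (ca != cb) return(FALSE)
  abs(ia - ib) <= window
}

# Core decision table for the direction of dissimilatory sulfur
# metabolism at one dsrAB locus. Pure function of the locus features so
# it can be enumerated exhaustively:
#   R1 archaeal reductive type            -> REDUCTIVE
#   R2 oxidative bacterial type           -> OXIDATIVE
#   R3 reductive bacterial type + dsrD    -> REDUCTIVE
#   R4 reductive bacterial type, no dsrD,
#      oxidative-indicator DsrL (1A/1B/2A/2B) -> OXIDATIVE, conflict
#   R5 reductive bacterial type, no dsrD, no dsrL, early diverging
#                                         -> REDUCTIVE
#   R6 anything else                      -> UNCERTAIN
# DsrEFH never decides a direction (imperfect predictor); it only joins
# the evidence trail in support of R2.
direction_rule <- function(dsrab_type, has_dsrD, dsrl_subtypes,
                           has_dsrEFH, early_diverging) {
  ev <- character(0)
  conflict <- FALSE
  oxi_l <- intersect(dsrl_subtypes, dsrl_oxidative_subtypes())
  direction <- "UNCERTAIN"
  if (identical(dsrab_type, "REDUCTIVE_ARCHAEAL")) {
    direction <- "REDUCTIVE"; ev <- "R1_archaeal_type"
  } else if (identical(dsrab_type, "OXIDATIVE_BACTERIAL")) {
    direction <- "OXIDATIVE"; ev <- "R2_oxidative_type"
    if (length(oxi_l)) ev <- c(ev, paste0("R2_support_dsrL_", oxi_l))
    if (has_dsrEFH) ev <- c(ev, "R2_support_dsrEFH")
  } else if (identical(dsrab_type, "REDUCTIVE_BACTERIAL")) {
    if (has_dsrD) {
      direction <- "REDUCTIVE"; ev <- "R3_dsrD_present"
      if ("L2C" %in% dsrl_subtypes) ev <- c(ev, "R3_support_dsrL_L2C")
    } else if (length(oxi_l)) {
      direction <- "OXIDATIVE"; conflict <- TRUE
      ev <- c("R4_no_dsrD_oxidative_dsrL",
              paste0("R4_dsrL_", oxi_l))
    } else if (length(dsrl_subtypes) == 0L && early_diverging) {
      direction <- "REDUCTIVE"; ev <- "R5_early_diverging"
    } else {
      ev <- "R6_unresolved"
    }
  } else {
    ev <- "R6_unresolved"
  }
  list(direction = direction, evidence = ev, conflict = conflict)
}

#' Infer the direction of sulfur metabolism at one dsrAB locus
#'
#' Applies the fixed-precedence decision rules combining the DsrAB type,
#' genome-wide dsrD presence, DsrL subtypes and DsrEFH: an archaeal
#' reductive or bacterial oxidative DsrAB decides directly (R1/R2);
#' reductive bacterial DsrAB is called reductive when dsrD is present
#' anywhere in the genome (R3), oxidative-with-conflict when dsrD is
#' absent but an oxidative-indicator DsrL (1A/1B/2A/2B) is encoded (R4),
#' reductive when dsrD and dsrL are both absent and the type call is
#' early-diverging (R5), and uncertain otherwise (R6). Co-localization of
#' supporting genes with the locus (same contig, within
#' `coloc_window_genes`) strengthens the evidence trail but never changes
#' the direction; DsrEFH is supporting evidence only.
#'
#' @param dsrab_type_call `dsr_type_call` for the locus.
#' @param complement `dsr_complement` of the genome.
#' @param dsrl_type_calls List of `dsr_type_call`s for the genome's DsrL
#'   copies (possibly empty), each optionally carrying a `locus` element.
#' @param config `dsr_config`.
#' @param locus Optional list(`contig_id`, `gene_index`) of the dsrAB
#'   locus.
#' @return List of class `dsr_locus_call`: `genome_id`, `locus`,
#'   `dsrab_type`, `direction`, `evidence`, `conflict`.
#' @export
call_locus_direction <- function(dsrab_type_call, complement,
                                 dsrl_type_calls = list(),
                                 config = analysis_config(),
                                 locus = NULL) {
  dsrl_subtypes <- vapply(dsrl_type_calls, `[[`, "", "assigned_label")
  dsrl_subtypes <- dsrl_subtypes[dsrl_subtypes != "UNCERTAIN"]
  has_dsrD <- has_family(complement, "dsrD")
  has_efh <- all(c("dsrE", "dsrF", "dsrH") %in% complement$hits$family)
  res <- direction_rule(dsrab_type_call$assigned_label, has_dsrD,
                        unique(dsrl_subtypes), has_efh,
                        isTRUE(dsrab_type_call$early_diverging))
  # annotate co-localization of supporting genes with this locus
  if (!is.null(locus)) {
    for (fam in c("dsrD", "dsrL")) {
      fh <- complement$hits[complement$hits$family == fam, , drop = FALSE]
      for (j in seq_len(nrow(fh))) {
        co <- colocalized(locus, fh[j, ], config$coloc_window_genes)
        if (isTRUE(co))
          res$evidence <- c(res$evidence,
                            sprintf("colocalized_%s_%s", fam, fh$query_id[j]))
      }
    }
  }
  structure(list(genome_id = complement$genome_id, locus = locus,
                 dsrab_type = dsrab_type_call$assigned_label,
                 direction = res$direction, evidence = res$evidence,
                 conflict = res$conflict),
            class = "dsr_locus_call")
}

#' Assess Dsr-pathway completeness of a genome
#'
#' `FULL_SULFATE_PATHWAY` requires sat, aprA, aprB, qmoA, qmoB, dsrA,
#' dsrB, dsrC, dsrM and dsrK (qmoC and dsrJ/O/P are optional subunits of
#' QmoAB(C) and DsrMK(JOP)). `SULFITE_ONLY` — the genetic potential to
#' reduce sulfite but not sulfate, as in gut Coriobacteriia — requires
#' the dsr core (dsrA, dsrB, dsrC, dsrM, dsrK) with the entire
#' sulfate-activation branch (sat, aprAB, qmoAB) absent. Anything else is
#' `PARTIAL`.
#'
#' @param complement `dsr_complement`.
#' @return List: `completeness` label, `missing` (families absent from the
#'   full-pathway requirement).
#' @export
assess_pathway_completeness <- function(complement) {
  fams <- complement_families(complement)
  missing <- setdiff(full_pathway_required(), fams)
  label <-
    if (length(missing) == 0L) "FULL_SULFATE_PATHWAY"
    else if (all(sulfite_only_required() %in% fams) &&
             !any(sulfate_branch() %in% fams)) "SULFITE_ONLY"
    else "PARTIAL"
  list(completeness = label, missing = missing)
}

#' Combine locus calls into a genome-level metabolism call
#'
#' A genome with at least one reductive and one oxidative dsrAB locus is
#' called `SWITCHABLE` (inferred capable of reversing the direction of
#' its dissimilatory sulfur metabolism); otherwise the unique direction
#' among its loci, or `UNCERTAIN` when none resolved.
#'
#' @param locus_calls List of `dsr_locus_call`s (>= 1).
#' @param complement `dsr_complement`.
#' @return List of class `dsr_metabolism_call`: `genome_id`,
#'   `genome_direction`, `locus_calls`, `completeness`, `missing`.
#' @export
call_genome_metabolism <- function(locus_calls, complement) {
  if (length(locus_calls) == 0L)
    abort_no_dsr("genome %s has no dsrAB locus", complement$genome_id)
  dirs <- vapply(locus_calls, `[[`, "", "direction")
  genome_direction <-
    if (any(dirs == "REDUCTIVE") && any(dirs == "OXIDATIVE")) "SWITCHABLE"
    else if (any(dirs == "REDUCTIVE")) "REDUCTIVE"
    else if (any(dirs == "OXIDATIVE")) "OXIDATIVE"
    else "UNCERTAIN"
  comp <- assess_pathway_completeness(complement)
  structure(list(genome_id = complement$genome_id,
                 genome_direction = genome_direction,
                 locus_calls = locus_calls,
                 completeness = comp$completeness,
                 missing = comp$missing),
            class = "dsr_metabolism_call")
}

#' Aggregate gene presence at lineage level
#'
#' For each lineage at the chosen rank, computes per-family the fraction
#' of dsrAB-containing genomes (those with a dsrA, dsrB or UNASSIGNED_DSR
#' hit) carrying the family, and a presence flag that is `TRUE` only when
#' the fraction strictly exceeds `presence_display_frac` (the "> 30%"
#' display rule). Genomes without dsrAB never enter the denominators.
#'
#' @param complements List of `dsr_complement`s.
#' @param taxonomy Taxonomy table from [load_taxonomy()].
#' @param rank One of "phylum", "class", "order", "family", "genus".
#' @param config `dsr_config`; `merge_phylum_sublineages` controls GTDB
#'   sublineage merging at phylum rank.
#' @return data.frame: `lineage`, `n_genomes`, `family`, `n_with`,
#'   `fraction`, `present`.
#' @export
aggregate_lineage <- function(complements, taxonomy, rank = "phylum",
                              config = analysis_config()) {
  if (!rank %in% c("phylum", "class", "order", "family", "genus"))
    abort_taxonomy("unsupported rank '%s'", rank)
  gids <- vapply(complements, `[[`, "", "genome_id")
  missing <- setdiff(gids, taxonomy$genome_id)
  if (length(missing))
    abort_taxonomy("genome(s) missing from taxonomy: %s",
                   paste(missing, collapse = ", "))
  has_dsrab <- vapply(complements, function(cp)
    any(c("dsrA", "dsrB", "UNASSIGNED_DSR") %in% cp$hits$family), TRUE)
  complements <- complements[has_dsrab]
  gids <- gids[has_dsrab]
  lin <- taxonomy[[rank]][match(gids, taxonomy$genome_id)]
  if (any(is.na(lin) | !nzchar(lin)))
    abort_taxonomy("genome(s) lack a %s rank: %s", rank,
                   paste(gids[is.na(lin) | !nzchar(lin)], collapse = ", "))
  if (rank == "phylum" && config$merge_phylum_sublineages)
    lin <- normalize_phylum(lin)
  fams <- c(dsr_families(), "UNASSIGNED_DSR")
  out <- list()
  for (l in sort(unique(lin))) {
    cps <- complements[lin == l]
    n <- length(cps)
    n_with <- vapply(fams, function(f)
      sum(vapply(cps, function(cp) f %in% cp$hits$family, TRUE)), 0L)
    out[[l]] <- data.frame(lineage = l, n_genomes = n, family = fams,
                           n_with = n_with, fraction = n_with / n,
                           present = n_with / n > config$presence_display_frac,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}
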