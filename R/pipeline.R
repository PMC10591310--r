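# Orchestration: screen -> type -> call -> aggregate, plus the report
# writers and the command-line entry point. All outputs are plain TSV with
# a single comment header carrying the package version and a config hash
# (no timestamps, so reruns are byte-identical).

# Pair dsrA and dsrB hits of one genome into dsrAB loci. Hits on the same
# contig within the co-localization window are paired nearest-first;
# leftovers become single-subunit (partial) loci; UNASSIGNED_DSR hits
# become loci typed UNCERTAIN downstream.
pair_dsrab_loci <- function(complement, config) {
  hits <- complement$hits
  a <- hits[hits$family == "dsrA", , drop = FALSE]
  b <- hits[hits$family == "dsrB", , drop = FALSE]
  u <- hits[hits$family == "UNASSIGNED_DSR", , drop = FALSE]
  loci <- list()
  used_b <- rep(FALSE, nrow(b))
  for (i in seq_len(nrow(a))) {
    j_best <- NA_integer_; d_best <- Inf
    for (j in seq_len(nrow(b))) {
      if (used_b[j]) next
      co <- colocalized(a[i, ], b[j, ], config$coloc_window_genes)
      d <- if (isTRUE(co)) abs(a$gene_index[i] - b$gene_index[j])
           else if (is.na(co) && sum(!used_b) == nrow(b) && nrow(a) == 1L &&
                    nrow(b) == 1L) 0  # no coordinates, unique pair
           else Inf
      if (d < d_best) { d_best <- d; j_best <- j }
    }
    if (!is.na(j_best) && is.finite(d_best)) {
      used_b[j_best] <- TRUE
      loci[[length(loci) + 1L]] <- list(dsrA = a[i, ], dsrB = b[j_best, ])
    } else {
      loci[[length(loci) + 1L]] <- list(dsrA = a[i, ], dsrB = NULL)
    }
  }
  for (j in which(!used_b))
    loci[[length(loci) + 1L]] <- list(dsrA = NULL, dsrB = b[j, ])
  for (kk in seq_len(nrow(u)))
    loci[[length(loci) + 1L]] <- list(dsrA = NULL, dsrB = NULL,
                                      unassigned = u[kk, ])
  loci
}

locus_coords <- function(locus) {
  anchor <- if (!is.null(locus$dsrA)) locus$dsrA
            else if (!is.null(locus$dsrB)) locus$dsrB
            else locus$unassigned
  list(contig_id = anchor$contig_id, gene_index = anchor$gene_index)
}

residue_of <- function(proteome, id) {
  proteome$residues[match(id, proteome$id)]
}

# analyse one genome end to end; returns row-per-locus and genome tables
analyse_genome <- function(proteome, refdb, taxonomy_row, config,
                           lenient = FALSE) {
  complement <- screen_genome(proteome, refdb, config, lenient = lenient)
  dsrl_hits <- complement$hits[complement$hits$family == "dsrL", ,
                               drop = FALSE]
  dsrl_calls <- lapply(seq_len(nrow(dsrl_hits)), function(i) {
    cl <- subtype_dsrl(residue_of(proteome, dsrl_hits$query_id[i]),
                       refdb$typed, config,
                       query_id = dsrl_hits$query_id[i])
    cl$locus <- list(contig_id = dsrl_hits$contig_id[i],
                     gene_index = dsrl_hits$gene_index[i])
    cl
  })
  loci <- pair_dsrab_loci(complement, config)
  locus_rows <- list(); locus_calls <- list()
  for (lc in loci) {
    coords <- locus_coords(lc)
    if (!is.null(lc$unassigned)) {
      tc <- structure(list(query_id = lc$unassigned$query_id,
                           family = "UNASSIGNED_DSR",
                           assigned_label = "UNCERTAIN", support = 0,
                           k_used = 0L, nearest_ref_id = NA_character_,
                           nearest_ref_taxonomy = NA_character_,
                           early_diverging = FALSE, partial = TRUE),
                      class = "dsr_type_call")
      ids <- c(lc$unassigned$query_id, NA_character_)
    } else {
      aseq <- if (!is.null(lc$dsrA)) residue_of(proteome, lc$dsrA$query_id)
      bseq <- if (!is.null(lc$dsrB)) residue_of(proteome, lc$dsrB$query_id)
      qid <- paste(stats::na.omit(c(if (!is.null(lc$dsrA)) lc$dsrA$query_id,
                                    if (!is.null(lc$dsrB)) lc$dsrB$query_id)),
                   collapse = "+")
      tc <- type_dsrab(aseq, bseq, refdb$typed, config, query_id = qid)
      ids <- c(if (is.null(lc$dsrA)) NA_character_ else lc$dsrA$query_id,
               if (is.null(lc$dsrB)) NA_character_ else lc$dsrB$query_id)
    }
    call <- call_locus_direction(tc, complement, dsrl_calls, config,
                                 locus = coords)
    lgt <- if (!is.na(tc$nearest_ref_taxonomy) &&
               !is.null(taxonomy_row) && nrow(taxonomy_row) == 1L)
      flag_lgt_candidate(taxonomy_row$taxonomy, tc)
    else list(flagged = FALSE, note = "")
    locus_calls[[length(locus_calls) + 1L]] <- call
    locus_rows[[length(locus_rows) + 1L]] <- data.frame(
      genome_id = complement$genome_id,
      contig = ifelse(is.null(coords$contig_id) || is.na(coords$contig_id),
                      NA_character_, coords$contig_id),
      gene_index = ifelse(is.null(coords$gene_index) ||
                            is.na(coords$gene_index),
                          NA_integer_, coords$gene_index),
      dsrA_id = ids[1], dsrB_id = ids[2],
      dsrab_type = tc$assigned_label,
      support = tc$support,
      nearest_ref = tc$nearest_ref_id,
      early_diverging = tc$early_diverging,
      partial = tc$partial,
      direction = call$direction,
      evidence = paste(call$evidence, collapse = ";"),
      conflict = call$conflict,
      lgt_flag = lgt$flagged,
      lgt_note = lgt$note,
      stringsAsFactors = FALSE)
  }
  metab <- if (length(locus_calls))
    call_genome_metabolism(locus_calls, complement)
  else NULL
  dsrl_df <- if (length(dsrl_calls)) data.frame(
    genome_id = complement$genome_id,
    query_id = vapply(dsrl_calls, `[[`, "", "query_id"),
    subtype = vapply(dsrl_calls, `[[`, "", "assigned_label"),
    support = vapply(dsrl_calls, `[[`, 0, "support"),
    stringsAsFactors = FALSE)
  else NULL
  list(complement = complement, locus_table = do.call(rbind, locus_rows),
       metabolism = metab, dsrl_table = dsrl_df)
}

#' Run the full screening pipeline over a set of genomes
#'
#' For every genome: detect Dsr-pathway genes, pair and type dsrAB loci,
#' subtype DsrL copies, call per-locus and genome-level direction, assess
#' pathway completeness and flag taxonomy-discordant (LGT candidate)
#' loci; then aggregate gene presence per lineage. Deterministic given
#' inputs and configuration.
#'
#' @param genome_dir Directory of per-genome protein FASTA files
#'   (`.faa`/`.fasta`/`.fa`; file stem = genome id), or `NULL` when
#'   `genomes` is given.
#' @param refdb_fasta,refdb_meta Reference database paths (see
#'   [load_reference_db()]); alternatively pass a loaded db via `refdb`.
#' @param taxonomy_path Taxonomy TSV (see [load_taxonomy()]); or a loaded
#'   data.frame via `taxonomy`.
#' @param config `dsr_config`.
#' @param genomes Optional named list of proteome record tables (overrides
#'   `genome_dir`).
#' @param refdb,taxonomy Optional pre-loaded objects.
#' @param out_dir If non-NULL, TSV reports are written here.
#' @param rank Aggregation rank (default "phylum").
#' @param lenient Tolerate empty proteomes and taxonomy gaps.
#' @return List of class `dsr_run_report`: `genome_calls`, `loci`,
#'   `dsrl_calls`, `lineage`, `complements`, `warnings`, `config`.
#' @export
run_screen_pipeline <- function(genome_dir = NULL, refdb_fasta = NULL,
                                refdb_meta = NULL, taxonomy_path = NULL,
                                config = analysis_config(),
                                genomes = NULL, refdb = NULL,
                                taxonomy = NULL, out_dir = NULL,
                                rank = "phylum", lenient = FALSE) {
  if (is.null(refdb))
    refdb <- load_reference_db(refdb_fasta, refdb_meta, config)
  if (is.null(taxonomy) && !is.null(taxonomy_path))
    taxonomy <- load_taxonomy(taxonomy_path)
  if (is.null(genomes)) {
    if (is.null(genome_dir) || !dir.exists(genome_dir))
      abort_empty_input("genome directory not found: %s", genome_dir)
    files <- sort(list.files(genome_dir, "\\.(faa|fasta|fa)$",
                             full.names = TRUE))
    if (length(files) == 0L)
      abort_empty_input("no genome FASTA files in %s", genome_dir)
    genomes <- stats::setNames(lapply(files, function(f) {
      rec <- read_fasta(f, "AMINO")
      gid <- tools::file_path_sans_ext(basename(f))
      rec$genome_id <- ifelse(is.na(rec$genome_id), gid, rec$genome_id)
      rec
    }), tools::file_path_sans_ext(basename(files)))
  }
  if (!is.null(taxonomy) && !lenient) {
    miss <- setdiff(names(genomes), taxonomy$genome_id)
    if (length(miss))
      abort_taxonomy("genome(s) missing from taxonomy: %s",
                     paste(miss, collapse = ", "))
  }
  genome_rows <- list(); locus_tables <- list(); dsrl_tables <- list()
  complements <- list(); warnings_df <- list()
  for (gid in names(genomes)) {
    tax_row <- if (!is.null(taxonomy))
      taxonomy[taxonomy$genome_id == gid, , drop = FALSE]
    res <- analyse_genome(genomes[[gid]], refdb, tax_row, config,
                          lenient = lenient)
    complements[[gid]] <- res$complement
    if (!is.null(res$locus_table))
      locus_tables[[gid]] <- res$locus_table
    if (!is.null(res$dsrl_table)) dsrl_tables[[gid]] <- res$dsrl_table
    m <- res$metabolism
    genome_rows[[gid]] <- data.frame(
      genome_id = gid,
      n_dsrab_loci = if (is.null(m)) 0L else length(m$locus_calls),
      genome_direction = if (is.null(m)) "NO_DSRAB" else m$genome_direction,
      completeness = if (is.null(m)) NA_character_ else m$completeness,
      missing_genes = if (is.null(m)) NA_character_
                      else paste(m$missing, collapse = ";"),
      stringsAsFactors = FALSE)
    if (!is.null(res$locus_table)) {
      lt <- res$locus_table
      for (i in seq_len(nrow(lt))) {
        if (lt$conflict[i])
          warnings_df[[length(warnings_df) + 1L]] <- data.frame(
            genome_id = gid, kind = "conflict",
            detail = lt$evidence[i], stringsAsFactors = FALSE)
        if (lt$lgt_flag[i])
          warnings_df[[length(warnings_df) + 1L]] <- data.frame(
            genome_id = gid, kind = "lgt_candidate",
            detail = lt$lgt_note[i], stringsAsFactors = FALSE)
        if (lt$dsrab_type[i] == "UNCERTAIN" && is.na(lt$dsrA_id[i]) &&
            is.na(lt$dsrB_id[i]))
          warnings_df[[length(warnings_df) + 1L]] <- data.frame(
            genome_id = gid, kind = "unassigned_dsr",
            detail = "dsrAB hit not attributable to one subunit",
            stringsAsFactors = FALSE)
      }
    }
  }
  lineage <- if (!is.null(taxonomy))
    aggregate_lineage(complements, taxonomy, rank, config)
  report <- structure(list(
    genome_calls = do.call(rbind, c(genome_rows, list(make.row.names = FALSE))),
    loci = if (length(locus_tables))
      do.call(rbind, c(locus_tables, list(make.row.names = FALSE))),
    dsrl_calls = if (length(dsrl_tables))
      do.call(rbind, c(dsrl_tables, list(make.row.names = FALSE))),
    lineage = lineage,
    complements = complements,
    warnings = if (length(warnings_df))
      do.call(rbind, c(warnings_df, list(make.row.names = FALSE)))
    else data.frame(genome_id = character(), kind = character(),
                    detail = character()),
    rank = rank,
    taxonomy = taxonomy,
    config = config), class = "dsr_run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

write_tsv_with_header <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dsrscreen %s config=%s",
                     as.character(utils::packageVersion("dsrscreen")),
                     config_hash(config)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write the TSV reports of a pipeline run
#'
#' Emits `genome_calls.tsv`, `loci.tsv`, `dsrl_calls.tsv`, `hits.tsv`,
#' `lineage_matrix.tsv` and `warnings.tsv` into `out_dir`. Output is
#' deterministic (fixed column order, no timestamps).
#'
#' @param report `dsr_run_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  write_tsv_with_header(report$genome_calls,
                        file.path(out_dir, "genome_calls.tsv"), cfg)
  if (!is.null(report$loci))
    write_tsv_with_header(report$loci, file.path(out_dir, "loci.tsv"), cfg)
  if (!is.null(report$dsrl_calls))
    write_tsv_with_header(report$dsrl_calls,
                          file.path(out_dir, "dsrl_calls.tsv"), cfg)
  hits <- do.call(rbind, c(lapply(report$complements, function(cp) {
    if (nrow(cp$hits) == 0L) return(NULL)
    cbind(data.frame(genome_id = cp$genome_id, stringsAsFactors = FALSE),
          cp$hits)
  }), list(make.row.names = FALSE)))
  if (!is.null(hits))
    write_tsv_with_header(hits, file.path(out_dir, "hits.tsv"), cfg)
  if (!is.null(report$lineage))
    write_tsv_with_header(lineage_matrix(report),
                          file.path(out_dir, "lineage_matrix.tsv"), cfg)
  write_tsv_with_header(report$warnings,
                        file.path(out_dir, "warnings.tsv"), cfg)
  invisible(out_dir)
}

#' Wide lineage presence/absence matrix
#'
#' Rows are lineages at the report's rank (dsrAB-containing genomes
#' only); columns are the 19 gene families (presence flag under the
#' strict > `presence_display_frac` rule) plus genome counts and a
#' direction summary.
#'
#' @param report `dsr_run_report` with a lineage table.
#' @return data.frame, one row per lineage.
#' @export
lineage_matrix <- function(report) {
  if (is.null(report$lineage)) abort_taxonomy("report has no lineage table")
  lin <- report$lineage
  fams <- c(dsr_families(), "UNASSIGNED_DSR")
  lineages <- unique(lin$lineage)
  out <- data.frame(lineage = lineages,
                    n_genomes = lin$n_genomes[match(lineages, lin$lineage)],
                    stringsAsFactors = FALSE)
  for (f in fams)
    out[[f]] <- lin$present[lin$family == f][match(lineages,
                                                   lin$lineage[lin$family == f])]
  # direction summary per lineage from the genome calls
  gc <- report$genome_calls
  if (!is.null(report$taxonomy)) {
    lin_of <- report$taxonomy[[report$rank]]
    if (report$rank == "phylum" && report$config$merge_phylum_sublineages)
      lin_of <- normalize_phylum(lin_of)
    names(lin_of) <- report$taxonomy$genome_id
    out$directions <- vapply(lineages, function(l) {
      ids <- names(lin_of)[lin_of == l]
      paste(sort(unique(gc$genome_direction[gc$genome_id %in% ids])),
            collapse = "/")
    }, "")
  }
  out
}

#' Summarize a genome catalogue table
#'
#' Reproduces catalogue-style summaries (genome, species and phylum
#' counts) from a TSV shaped like a supplementary genome table: required
#' columns `genome_id`, `domain`, `taxonomy` (GTDB string),
#' `genome_type` (isolate/MAG), `completeness`, `contamination`,
#' `dsrab_type`. Phyla are counted after GTDB sublineage merging
#' ([normalize_phylum()]); species are deduplicated on the `s__` field.
#'
#' @param table_path TSV path (or a data.frame).
#' @param group_by Optional column to split counts by (e.g. "domain" or
#'   "genome_type").
#' @param filters Named list restricting rows, e.g.
#'   `list(domain = "Archaea")`.
#' @return data.frame of counts: `group`, `n_genomes`, `n_species`,
#'   `n_phyla`.
#' @export
count_catalogue <- function(table_path, group_by = NULL,
                            filters = list()) {
  tab <- if (is.data.frame(table_path)) table_path
         else utils::read.delim(table_path, sep = "\t",
                                colClasses = "character")
  need <- c("genome_id", "domain", "taxonomy", "genome_type",
            "completeness", "contamination", "dsrab_type")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    abort_schema("catalogue lacks column(s): %s",
                 paste(missing_cols, collapse = ", "))
  for (f in names(filters))
    tab <- tab[tab[[f]] %in% filters[[f]], , drop = FALSE]
  ranks <- parse_gtdb_taxonomy(tab$taxonomy)
  tab$species <- ranks$species
  tab$phylum_merged <- ifelse(is.na(ranks$phylum), NA_character_,
                              normalize_phylum(ranks$phylum))
  groups <- if (is.null(group_by)) list(all = tab)
            else split(tab, tab[[group_by]])
  out <- do.call(rbind, lapply(names(groups), function(gname) {
    g <- groups[[gname]]
    data.frame(group = gname,
               n_genomes = nrow(g),
               n_species = length(unique(g$species[!is.na(g$species) &
                                                     nzchar(g$species)])),
               n_phyla = length(unique(g$phylum_merged[!is.na(g$phylum_merged)])),
               stringsAsFactors = FALSE)
  }))
  row.names(out) <- NULL
  out
}
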