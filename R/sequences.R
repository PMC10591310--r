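#' Sequence record tables
#'
#' Sequences are carried as plain data frames with one row per record and
#' columns `id`, `description`, `residues`, `genome_id`, `contig_id`,
#' `gene_index`, `strand`. The declared alphabet ("AMINO" or "NUCLEOTIDE")
#' is stored in the `alphabet` attribute. Locus metadata (`genome_id`,
#' `contig_id`, `gene_index`, `strand`) is optional (`NA` when absent) and
#' is round-tripped through FASTA headers as `key=value` tokens.
#'
#' @param id Character vector of unique record ids.
#' @param residues Character vector of sequences.
#' @param alphabet "AMINO" or "NUCLEOTIDE".
#' @param description Free-text descriptions.
#' @param genome_id,contig_id Optional grouping metadata.
#' @param gene_index Optional non-negative integer rank of the gene on its
#'   contig.
#' @param strand Optional "+" or "-".
#' @param validate Check residues against the alphabet (default TRUE).
#' @return A `data.frame` of records with attribute `alphabet`.
#' @export
seq_records <- function(id, residues, alphabet = c("AMINO", "NUCLEOTIDE"),
                        description = "", genome_id = NA_character_,
                        contig_id = NA_character_, gene_index = NA_integer_,
                        strand = NA_character_, validate = TRUE) {
  alphabet <- match.arg(alphabet)
  rec <- data.frame(id = as.character(id),
                    description = description,
                    residues = as.character(residues),
                    genome_id = genome_id,
                    contig_id = contig_id,
                    gene_index = as.integer(gene_index),
                    strand = strand,
                    stringsAsFactors = FALSE)
  attr(rec, "alphabet") <- alphabet
  if (validate) validate_records(rec)
  rec
}

amino_alphabet <- function() strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]
iupac_alphabet <- function() strsplit("ACGTRYSWKMBDHVN", "")[[1]]

alphabet_letters <- function(alphabet, allow_gaps = FALSE) {
  base <- if (alphabet == "AMINO") amino_alphabet() else iupac_alphabet()
  if (allow_gaps) c(base, "-", ".") else base
}

validate_records <- function(rec, allow_gaps = FALSE) {
  alphabet <- attr(rec, "alphabet")
  if (is.null(alphabet)) abort_config("records carry no alphabet attribute")
  if (nrow(rec) == 0L) return(invisible(rec))
  if (anyDuplicated(rec$id))
    abort_duplicate_id("duplicate record id(s): %s",
                       paste(unique(rec$id[duplicated(rec$id)]),
                             collapse = ", "))
  if (any(!nzchar(rec$residues)))
    abort_empty_input("record(s) with empty residues: %s",
                      paste(rec$id[!nzchar(rec$residues)], collapse = ", "))
  ok <- alphabet_letters(alphabet, allow_gaps)
  for (i in seq_len(nrow(rec))) {
    chars <- strsplit(toupper(rec$residues[i]), "")[[1]]
    bad <- which(!chars %in% ok)
    if (length(bad))
      abort_alphabet("record '%s': invalid %s character '%s' at position %d",
                     rec$id[i], alphabet, chars[bad[1]], bad[1])
  }
  # (contig_id, gene_index) must be unique within a genome when present
  has <- !is.na(rec$contig_id) & !is.na(rec$gene_index)
  if (any(has)) {
    key <- paste(rec$genome_id[has], rec$contig_id[has], rec$gene_index[has])
    if (anyDuplicated(key))
      abort_value("duplicate (contig_id, gene_index) within a genome: %s",
                  key[duplicated(key)][1])
  }
  invisible(rec)
}

locus_tokens <- c("genome", "contig", "index", "strand")

encode_description <- function(rec) {
  vapply(seq_len(nrow(rec)), function(i) {
    toks <- character(0)
    if (!is.na(rec$genome_id[i])) toks <- c(toks, paste0("genome=", rec$genome_id[i]))
    if (!is.na(rec$contig_id[i])) toks <- c(toks, paste0("contig=", rec$contig_id[i]))
    if (!is.na(rec$gene_index[i])) toks <- c(toks, paste0("index=", rec$gene_index[i]))
    if (!is.na(rec$strand[i])) toks <- c(toks, paste0("strand=", rec$strand[i]))
    trimws(paste(rec$description[i], paste(toks, collapse = " ")))
  }, "")
}

decode_description <- function(desc) {
  out <- list(description = desc,
              genome_id = NA_character_, contig_id = NA_character_,
              gene_index = NA_integer_, strand = NA_character_)
  if (!nzchar(desc)) return(out)
  toks <- strsplit(desc, "[[:space:]]+")[[1]]
  is_kv <- grepl("^(genome|contig|index|strand)=", toks)
  for (t in toks[is_kv]) {
    kv <- strsplit(t, "=", fixed = TRUE)[[1]]
    switch(kv[1],
           genome = out$genome_id <- kv[2],
           contig = out$contig_id <- kv[2],
           index  = out$gene_index <- as.integer(kv[2]),
           strand = out$strand <- kv[2])
  }
  out$description <- paste(toks[!is_kv], collapse = " ")
  out
}

#' Read a FASTA file into a record table
#'
#' Headers are split into `id` (first whitespace-delimited token) and
#' `description`; locus metadata tokens (`genome=`, `contig=`, `index=`,
#' `strand=`) embedded in the description are decoded into their columns.
#' Gap characters are rejected unless `keep_gaps = TRUE` (for reading
#' alignments).
#'
#' @param path FASTA file.
#' @param alphabet "AMINO" or "NUCLEOTIDE".
#' @param keep_gaps Permit `-`/`.` characters (alignment input).
#' @return Record table as from [seq_records()].
#' @export
read_fasta <- function(path, alphabet = c("AMINO", "NUCLEOTIDE"),
                       keep_gaps = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort_empty_input("no such file: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort_empty_input("empty FASTA file: %s", path)
  headers <- names(set)
  ids <- sub("[[:space:]].*$", "", headers)
  if (anyDuplicated(ids))
    abort_duplicate_id("duplicate FASTA id(s) in %s: %s", path,
                       paste(unique(ids[duplicated(ids)]), collapse = ", "))
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  meta <- lapply(desc, decode_description)
  rec <- seq_records(
    id = ids,
    residues = toupper(as.character(set)),
    alphabet = alphabet,
    description = vapply(meta, `[[`, "", "description"),
    genome_id = vapply(meta, `[[`, "", "genome_id"),
    contig_id = vapply(meta, `[[`, "", "contig_id"),
    gene_index = vapply(meta, `[[`, 1L, "gene_index"),
    strand = vapply(meta, `[[`, "", "strand"),
    validate = FALSE)
  validate_records(rec, allow_gaps = keep_gaps)
  rec
}

#' Write a record table to FASTA
#'
#' Locus metadata is appended to the description as `key=value` tokens so
#' that [read_fasta()] recovers the table field-by-field.
#'
#' @param rec Record table.
#' @param path Output file.
#' @param width Line wrap width. Default 60.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(rec, path, width = 60L) {
  desc <- encode_description(rec)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(rec))) {
    header <- if (nzchar(desc[i])) paste(rec$id[i], desc[i]) else rec$id[i]
    writeLines(paste0(">", header), con)
    s <- rec$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Derive gene order from a GFF3 file
#'
#' Assigns each feature a 1-based `gene_index` equal to the rank of its
#' start coordinate within its contig (seqid), the usual proxy for gene
#' order on a contig when an ordered FASTA is not available.
#'
#' @param gff_path GFF3 file.
#' @param feature_type Feature type to rank (default "CDS").
#' @param id_attribute Attribute naming the protein/gene (default "ID").
#' @return data.frame with columns `id`, `contig_id`, `gene_index`,
#'   `strand`.
#' @export
gene_index_from_gff <- function(gff_path, feature_type = "CDS",
                                id_attribute = "ID") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    abort_config("rtracklayer is required to read GFF3 input")
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  if (length(gr) == 0L)
    abort_empty_input("no '%s' features in %s", feature_type, gff_path)
  df <- data.frame(id = as.character(S4Vectors::mcols(gr)[[id_attribute]]),
                   contig_id = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$contig_id, df$start), ]
  df$gene_index <- stats::ave(df$start, df$contig_id,
                              FUN = function(x) rank(x, ties.method = "first"))
  df$gene_index <- as.integer(df$gene_index)
  df$strand[!df$strand %in% c("+", "-")] <- NA_character_
  df[, c("id", "contig_id", "gene_index", "strand")]
}
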