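# Shared fixtures, built once per test run. The reference set is the
# generator's stated world (defaults); tests that need different
# divergences build their own.

.fixture_env <- new.env()

fixture_gcfg <- function() generator_config(rng_seed = 7L)

fixture_refset <- function() {
  if (is.null(.fixture_env$refset))
    .fixture_env$refset <- generate_reference_set(fixture_gcfg())
  .fixture_env$refset
}

fixture_config <- function(...) analysis_config(...)

# minimal complement with the given families present (one synthetic hit
# each, no locus metadata) for rule-engine and aggregation tests
mock_complement <- function(genome_id, families, contigs = NULL,
                            indices = NULL) {
  n <- length(families)
  hits <- data.frame(
    query_id = paste0(genome_id, "_p", seq_len(n)),
    family = families,
    best_seed_id = paste0("seed_", families),
    raw_score = rep(100, n), norm_score = rep(0.9, n),
    margin = rep(0.5, n),
    contig_id = if (is.null(contigs)) rep(NA_character_, n) else contigs,
    gene_index = if (is.null(indices)) rep(NA_integer_, n) else indices,
    strand = rep("+", n), stringsAsFactors = FALSE)
  structure(list(genome_id = genome_id, hits = hits,
                 proteome_size = n + 5L),
            class = "dsr_complement")
}

mock_type_call <- function(label, support = 1.0, early = FALSE,
                           taxonomy = "d__Bacteria;p__Desulfobacterota;c__x;o__x;f__x;g__x;s__x y",
                           query_id = "q") {
  structure(list(query_id = query_id, family = "dsrAB_concat",
                 assigned_label = label, support = support, k_used = 5L,
                 nearest_ref_id = "ref1", nearest_ref_taxonomy = taxonomy,
                 early_diverging = early, partial = FALSE),
            class = "dsr_type_call")
}

mock_dsrl_call <- function(subtype, contig = NA_character_,
                           index = NA_integer_) {
  cl <- structure(list(query_id = "l", family = "dsrL",
                       assigned_label = subtype, support = 1.0,
                       k_used = 5L, nearest_ref_id = "refL",
                       nearest_ref_taxonomy = "d__B;p__X;c__x;o__x;f__x;g__x;s__x y",
                       early_diverging = FALSE, partial = FALSE),
                  class = "dsr_type_call")
  cl$locus <- list(contig_id = contig, gene_index = index)
  cl
}

# expected direction logic, written independently from the package rule
# engine as the hand-held specification of the decision table
expected_direction <- function(type, has_dsrD, dsrl, has_efh, early) {
  oxidative_l <- dsrl %in% c("L1A", "L1B", "L2A", "L2B")
  if (type == "REDUCTIVE_ARCHAEAL")
    return(list(direction = "REDUCTIVE", conflict = FALSE))
  if (type == "OXIDATIVE_BACTERIAL")
    return(list(direction = "OXIDATIVE", conflict = FALSE))
  if (type == "REDUCTIVE_BACTERIAL") {
    if (has_dsrD) return(list(direction = "REDUCTIVE", conflict = FALSE))
    if (oxidative_l) return(list(direction = "OXIDATIVE", conflict = TRUE))
    if (dsrl == "none" && early)
      return(list(direction = "REDUCTIVE", conflict = FALSE))
    return(list(direction = "UNCERTAIN", conflict = FALSE))
  }
  list(direction = "UNCERTAIN", conflict = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

make_mix <- function(name, iupacs, orientation = "FORWARD") {
  structure(list(name = name, orientation = orientation,
                 variants = data.frame(
                   primer_name = paste0(name, "_v", seq_along(iupacs)),
                   iupac = iupacs, orientation = orientation,
                   anchor_position = NA_integer_,
                   coordinate_reference = NA_character_,
                   stringsAsFactors = FALSE)),
            class = "dsr_primer_mix")
}
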