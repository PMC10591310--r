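# Deterministic synthetic-data generator. It emits (i) reference families
# with controlled within-family and between-type divergence, (ii) archetype
# genomes that mirror the recurring Dsr gene-complement configurations seen
# in real genomes and MAGs (canonical sulfate reducer, canonical sulfur
# oxidizer, dual-dsrAB switchers, sulfite-only gut organisms, early
# diverging lineages, ...), and (iii) nucleotide datasets with primer sites
# implanted at known positions carrying exactly planned mismatch counts.
# Evolution is positional substitution only: no indels, no rate
# heterogeneity. Identical configuration implies byte-identical output.

aa20 <- function() setdiff(amino_alphabet(), "X")

#' Generator configuration
#'
#' @param rng_seed Integer seed; the single RNG stream of a run.
#' @param family_length_range Amino-acid length range for family
#'   ancestors. Default c(180, 260).
#' @param n_seeds Seeds per family (and per type group). Default 5, so a
#'   type group can fill the default typing neighborhood (`typing_k`) on
#'   its own.
#' @param within_family_divergence Expected pairwise divergence within a
#'   family/type group. Default 0.15.
#' @param between_type_divergence Expected pairwise divergence between
#'   type groups of one family. Default 0.45 (must exceed within).
#' @param query_mutation_rate Substitution rate applied to genes emitted
#'   into scenario genomes. Default 0.10.
#' @param background Amino-acid background frequencies (named, 20
#'   residues). Default uniform.
#' @param decoys_per_genome Shuffled decoy proteins added per scenario
#'   genome. Default 8.
#' @param primer_backbone_length Length of generated nucleotide backbones.
#'   Default 800.
#' @return List of class `dsr_gen_config`.
#' @export
generator_config <- function(rng_seed = 1L,
                             family_length_range = c(180L, 260L),
                             n_seeds = 5L,
                             within_family_divergence = 0.15,
                             between_type_divergence = 0.45,
                             query_mutation_rate = 0.10,
                             background = NULL,
                             decoys_per_genome = 8L,
                             primer_backbone_length = 800L) {
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), aa20())
  }
  for (d in c(within_family_divergence, between_type_divergence,
              query_mutation_rate))
    if (d < 0 || d > 1) abort_config("divergences/rates must be in [0,1]")
  if (within_family_divergence >= between_type_divergence)
    abort_config("within_family_divergence (%.2f) must be < between_type_divergence (%.2f)",
                 within_family_divergence, between_type_divergence)
  structure(list(rng_seed = as.integer(rng_seed),
                 family_length_range = as.integer(family_length_range),
                 n_seeds = as.integer(n_seeds),
                 within_family_divergence = within_family_divergence,
                 between_type_divergence = between_type_divergence,
                 query_mutation_rate = query_mutation_rate,
                 background = background,
                 decoys_per_genome = as.integer(decoys_per_genome),
                 primer_backbone_length = as.integer(primer_backbone_length)),
            class = "dsr_gen_config")
}

random_protein <- function(len, background) {
  paste(sample(names(background), len, replace = TRUE, prob = background),
        collapse = "")
}

#' Mutate a sequence by positional substitution
#'
#' Each position is substituted independently with probability `rate`;
#' the replacement is drawn from the background excluding the current
#' residue, so `rate = 1` changes every position. Uses the current RNG
#' stream.
#'
#' @param seq Amino-acid string.
#' @param rate Substitution probability per position, in `[0,1]`.
#' @param background Named residue frequencies (default uniform over 20).
#' @return Mutated string.
#' @export
mutate_sequence <- function(seq, rate, background = NULL) {
  if (rate < 0 || rate > 1) abort_value("rate must be in [0,1]")
  if (is.null(background))
    background <- stats::setNames(rep(1 / 20, 20), aa20())
  chars <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  for (i in which(hit)) {
    p <- background
    p <- p[names(p) != chars[i]]
    chars[i] <- sample(names(p), 1L, prob = p)
  }
  paste(chars, collapse = "")
}

shuffle_sequence <- function(seq) {
  paste(sample(strsplit(seq, "")[[1]]), collapse = "")
}

dsrab_group_taxonomies <- function() c(
  REDUCTIVE_BACTERIAL =
    "d__Bacteria;p__Desulfobacterota;c__Desulfovibrionia;o__Desulfovibrionales;f__Desulfovibrionaceae;g__Desulfovibrio;s__Desulfovibrio synthetica",
  OXIDATIVE_BACTERIAL =
    "d__Bacteria;p__Pseudomonadota;c__Gammaproteobacteria;o__Chromatiales;f__Chromatiaceae;g__Allochromatium;s__Allochromatium synthetica",
  REDUCTIVE_ARCHAEAL =
    "d__Archaea;p__Halobacteriota;c__Archaeoglobi;o__Archaeoglobales;f__Archaeoglobaceae;g__Archaeoglobus;s__Archaeoglobus syntheticus",
  EARLY_DIVERGING =
    "d__Bacteria;p__Methylomirabilota;c__Methylomirabilia;o__Rokubacteriales;f__Rokubacteriaceae;g__Rokubacterium;s__Rokubacterium syntheticum")

dsrl_group_taxonomies <- function() c(
  L1A = "d__Bacteria;p__Pseudomonadota;c__Alphaproteobacteria;o__Rhodobacterales;f__Rhodobacteraceae;g__Rhodobacter;s__Rhodobacter syntheticus",
  L1B = "d__Bacteria;p__Bacteroidota;c__Chlorobia;o__Chlorobiales;f__Chlorobiaceae;g__Chlorobium;s__Chlorobium syntheticum",
  L2A = "d__Bacteria;p__Bacteroidota;c__Chlorobia;o__Chlorobiales;f__Chlorobiaceae;g__Chlorobium;s__Chlorobium ambiguum",
  L2B = "d__Bacteria;p__Nitrospinota;c__Nitrospinia;o__Nitrospinales;f__UBA7883;g__UBA7883;s__UBA7883 syntheticum",
  L2C = "d__Bacteria;p__Actinomycetota;c__Aquicultoria;o__Aquicultorales;f__Aquicultoraceae;g__Aquicultor;s__Aquicultor syntheticus")

#' Generate a typed synthetic reference set
#'
#' Builds random ancestors for all 19 Dsr-pathway families. The dsrA,
#' dsrB and dsrL ancestors are radiated into type groups (the three DsrAB
#' types plus an early-diverging reductive-bacterial group; the five DsrL
#' subclusters) separated by `between_type_divergence`; every group (and
#' every untyped family) receives `n_seeds` seeds at
#' `within_family_divergence`. Concatenated DsrA+DsrB references are
#' derived per group for typing of complete loci. Deterministic in
#' `rng_seed`.
#'
#' @param gcfg `dsr_gen_config`.
#' @param config `dsr_config` (scoring parameters for self-scores).
#' @return List: `families` (named list of `dsr_ref_family`), `typed`
#'   (typed reference data.frame), `label_map` (id/family/type_label/
#'   early_diverging for every typed reference).
#' @export
generate_reference_set <- function(gcfg = generator_config(),
                                   config = analysis_config()) {
  set.seed(gcfg$rng_seed)
  half_w <- gcfg$within_family_divergence / 2
  half_b <- gcfg$between_type_divergence / 2
  bg <- gcfg$background
  families <- list()
  typed_rows <- list()

  grp_seeds <- list()  # family -> group -> character vector of seeds
  for (fam in dsr_families()) {
    len <- sample(seq(gcfg$family_length_range[1],
                      gcfg$family_length_range[2]), 1L)
    ancestor <- random_protein(len, bg)
    if (fam %in% c("dsrA", "dsrB")) {
      groups <- c(dsrab_type_labels(), "EARLY_DIVERGING")
    } else if (fam == "dsrL") {
      groups <- dsrl_subtype_labels()
    } else {
      groups <- NA_character_
    }
    fam_seed_ids <- character(0)
    fam_seed_res <- character(0)
    grp_seeds[[fam]] <- list()
    for (g in groups) {
      base <- if (is.na(g)) ancestor
              else mutate_sequence(ancestor, half_b, bg)
      seeds <- vapply(seq_len(gcfg$n_seeds), function(i)
        mutate_sequence(base, half_w, bg), "")
      tag <- if (is.na(g)) "core" else g
      ids <- sprintf("seed_%s_%s_%d", fam, tag, seq_len(gcfg$n_seeds))
      fam_seed_ids <- c(fam_seed_ids, ids)
      fam_seed_res <- c(fam_seed_res, seeds)
      grp_seeds[[fam]][[tag]] <- seeds
      if (!is.na(g)) {
        label <- if (g == "EARLY_DIVERGING") "REDUCTIVE_BACTERIAL" else g
        tax <- if (fam == "dsrL") dsrl_group_taxonomies()[[g]]
               else dsrab_group_taxonomies()[[g]]
        typed_rows[[length(typed_rows) + 1L]] <- data.frame(
          id = sprintf("ref_%s_%s_%d", fam, tag, seq_len(gcfg$n_seeds)),
          residues = seeds, family = fam, type_label = label,
          early_diverging = g == "EARLY_DIVERGING",
          taxonomy = tax, uncultured_lineage = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
    families[[fam]] <- reference_family(
      fam, seq_records(fam_seed_ids, fam_seed_res, "AMINO"),
      config = config)
  }

  # concatenated DsrA+DsrB references, paired within each type group
  for (g in c(dsrab_type_labels(), "EARLY_DIVERGING")) {
    label <- if (g == "EARLY_DIVERGING") "REDUCTIVE_BACTERIAL" else g
    a <- grp_seeds[["dsrA"]][[g]]
    b <- grp_seeds[["dsrB"]][[g]]
    typed_rows[[length(typed_rows) + 1L]] <- data.frame(
      id = sprintf("ref_dsrABcat_%s_%d", g, seq_len(gcfg$n_seeds)),
      residues = paste0(a, b), family = "dsrAB_concat", type_label = label,
      early_diverging = g == "EARLY_DIVERGING",
      taxonomy = dsrab_group_taxonomies()[[g]],
      uncultured_lineage = NA_integer_, stringsAsFactors = FALSE)
  }
  typed <- do.call(rbind, typed_rows)
  row.names(typed) <- NULL
  typed$self_score <- self_score(typed$residues, config$substitution_matrix)
  list(families = families, typed = typed,
       label_map = typed[, c("id", "family", "type_label",
                             "early_diverging")],
       group_seeds = grp_seeds)
}

#' Write a reference set as FASTA + metadata TSV
#'
#' Emits the on-disk form consumed by [load_reference_db()]: one FASTA of
#' all seed and typed sequences, and a metadata TSV in which untyped rows
#' define detection families and typed rows define typed references.
#'
#' @param refset From [generate_reference_set()].
#' @param fasta_path,tsv_path Output paths.
#' @return Invisible list of the two paths.
#' @export
write_reference_db <- function(refset, fasta_path, tsv_path) {
  seed_rows <- do.call(rbind, lapply(refset$families, function(f)
    data.frame(id = f$seeds$id, residues = f$seeds$residues,
               family = f$family, type_label = "",
               early_diverging = "", taxonomy = "",
               uncultured_lineage = "", stringsAsFactors = FALSE)))
  typed <- refset$typed
  typed_rows <- data.frame(id = typed$id, residues = typed$residues,
                           family = typed$family,
                           type_label = typed$type_label,
                           early_diverging = ifelse(typed$early_diverging,
                                                    "TRUE", "FALSE"),
                           taxonomy = typed$taxonomy,
                           uncultured_lineage =
                             ifelse(is.na(typed$uncultured_lineage), "",
                                    typed$uncultured_lineage),
                           stringsAsFactors = FALSE)
  all_rows <- rbind(seed_rows, typed_rows)
  write_fasta(seq_records(all_rows$id, all_rows$residues, "AMINO"),
              fasta_path)
  utils::write.table(all_rows[, c("id", "family", "type_label",
                                  "early_diverging", "taxonomy",
                                  "uncultured_lineage")],
                     tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta_path, tsv = tsv_path))
}

# archetype table: per archetype a list of contigs; each contig is a list
# of c(family, group) gene slots (group NA for untyped families), plus the
# intended truth. Groups name the generator's type groups, so
# "EARLY_DIVERGING" selects the early-diverging reductive-bacterial refs.
archetype_definitions <- function() {
  RB <- "REDUCTIVE_BACTERIAL"; OB <- "OXIDATIVE_BACTERIAL"
  RA <- "REDUCTIVE_ARCHAEAL"; ED <- "EARLY_DIVERGING"
  g <- function(family, group = NA_character_) c(family, group)
  sulfate_branch_genes <- list(g("sat"), g("aprA"), g("aprB"),
                               g("qmoA"), g("qmoB"), g("qmoC"))
  core <- list(g("dsrC"), g("dsrM"), g("dsrK"))
  list(
    canonical_srm = list(
      taxonomy = "d__Bacteria;p__Desulfobacterota;c__Desulfovibrionia;o__Desulfovibrionales;f__Desulfovibrionaceae;g__Desulfovibrio;s__Desulfovibrio archetypus",
      contigs = list(
        ctg1 = c(list(g("dsrA", RB), g("dsrB", RB), g("dsrD")), core,
                 list(g("dsrJ"), g("dsrO"), g("dsrP"))),
        ctg2 = sulfate_branch_genes),
      loci = list(list(contig = "ctg1", type = RB, direction = "REDUCTIVE")),
      genome_direction = "REDUCTIVE",
      completeness = "FULL_SULFATE_PATHWAY"),
    canonical_som = list(
      taxonomy = "d__Bacteria;p__Pseudomonadota;c__Gammaproteobacteria;o__Chromatiales;f__Chromatiaceae;g__Allochromatium;s__Allochromatium archetypum",
      contigs = list(
        ctg1 = c(list(g("dsrA", OB), g("dsrB", OB), g("dsrE"), g("dsrF"),
                      g("dsrH"), g("dsrL", "L1A")), core),
        ctg2 = sulfate_branch_genes),
      loci = list(list(contig = "ctg1", type = OB, direction = "OXIDATIVE")),
      genome_direction = "OXIDATIVE",
      completeness = "FULL_SULFATE_PATHWAY"),
    desulfocapsaceae_dual = list(
      taxonomy = "d__Bacteria;p__Desulfobacterota;c__Desulfobulbia;o__Desulfobulbales;f__Desulfocapsaceae;g__Desulforhopalus;s__Desulforhopalus archetypus",
      contigs = list(
        ctg1 = list(g("dsrA", RB), g("dsrB", RB), g("dsrD")),
        ctg2 = list(g("dsrA", OB), g("dsrB", OB), g("dsrL", "L2A")),
        ctg3 = c(core, sulfate_branch_genes)),
      loci = list(list(contig = "ctg1", type = RB, direction = "REDUCTIVE"),
                  list(contig = "ctg2", type = OB, direction = "OXIDATIVE")),
      genome_direction = "SWITCHABLE",
      completeness = "FULL_SULFATE_PATHWAY"),
    coriobacteriia_sulfite = list(
      taxonomy = "d__Bacteria;p__Actinomycetota;c__Coriobacteriia;o__Coriobacteriales;f__Eggerthellaceae;g__Gordonibacter;s__Gordonibacter archetypus",
      contigs = list(
        ctg1 = list(g("dsrA", RB), g("dsrB", RB), g("dsrC"), g("dsrD"),
                    g("dsrM"), g("dsrK"))),
      loci = list(list(contig = "ctg1", type = RB, direction = "REDUCTIVE")),
      genome_direction = "REDUCTIVE",
      completeness = "SULFITE_ONLY"),
    verrucomicrobiota_conflict = list(
      taxonomy = "d__Bacteria;p__Verrucomicrobiota;c__Verrucomicrobiae;o__Opitutales;f__Opitutaceae;g__Opitutus;s__Opitutus archetypus",
      contigs = list(
        ctg1 = c(list(g("dsrA", RB), g("dsrB", RB), g("dsrL", "L1B")), core),
        ctg2 = list(g("sat"), g("aprA"), g("aprB"), g("qmoA"), g("qmoB"))),
      loci = list(list(contig = "ctg1", type = RB, direction = "OXIDATIVE",
                       conflict = TRUE)),
      genome_direction = "OXIDATIVE",
      completeness = "FULL_SULFATE_PATHWAY"),
    early_diverging_archaeon = list(
      taxonomy = "d__Archaea;p__Halobacteriota;c__Archaeoglobi;o__Archaeoglobales;f__Archaeoglobaceae;g__Archaeoglobus;s__Archaeoglobus archetypus",
      contigs = list(
        ctg1 = c(list(g("dsrA", RA), g("dsrB", RA)), core),
        ctg2 = list(g("sat"), g("aprA"), g("aprB"), g("qmoA"), g("qmoB"))),
      loci = list(list(contig = "ctg1", type = RA, direction = "REDUCTIVE")),
      genome_direction = "REDUCTIVE",
      completeness = "FULL_SULFATE_PATHWAY"),
    methylomirabilota_early = list(
      taxonomy = "d__Bacteria;p__Methylomirabilota;c__Methylomirabilia;o__Rokubacteriales;f__Rokubacteriaceae;g__Rokubacterium;s__Rokubacterium archetypum",
      contigs = list(
        ctg1 = c(list(g("dsrA", ED), g("dsrB", ED)), core),
        ctg2 = list(g("sat"), g("aprA"), g("aprB"), g("qmoA"), g("qmoB"))),
      loci = list(list(contig = "ctg1", type = RB, direction = "REDUCTIVE")),
      genome_direction = "REDUCTIVE",
      completeness = "FULL_SULFATE_PATHWAY"),
    actinomycetota_switch = list(
      taxonomy = "d__Bacteria;p__Actinomycetota;c__Thermoleophilia;o__Gaiellales;f__Gaiellaceae;g__Gaiella;s__Gaiella archetypa",
      contigs = list(
        ctg1 = list(g("dsrA", RB), g("dsrB", RB), g("dsrD"), g("dsrL", "L2C"),
                    g("dsrA", OB), g("dsrB", OB), g("dsrE"), g("dsrF"),
                    g("dsrH"), g("dsrL", "L2A")),
        ctg2 = c(core, sulfate_branch_genes)),
      loci = list(list(contig = "ctg1", type = RB, direction = "REDUCTIVE"),
                  list(contig = "ctg1", type = OB, direction = "OXIDATIVE")),
      genome_direction = "SWITCHABLE",
      completeness = "FULL_SULFATE_PATHWAY"),
    kapabacteria_reductive = list(
      taxonomy = "d__Bacteria;p__Bacteroidota;c__Kapabacteria;o__Kapabacteriales;f__UBA2268;g__UBA2268;s__UBA2268 archetypum",
      contigs = list(
        ctg1 = c(list(g("dsrA", RB), g("dsrB", RB), g("dsrD"),
                      g("dsrL", "L2C")), core),
        ctg2 = list(g("sat"), g("aprA"), g("aprB"), g("qmoA"), g("qmoB"))),
      loci = list(list(contig = "ctg1", type = RB, direction = "REDUCTIVE")),
      genome_direction = "REDUCTIVE",
      completeness = "FULL_SULFATE_PATHWAY"),
    nitrospirota_oxidative = list(
      taxonomy = "d__Bacteria;p__Nitrospirota_A;c__Thermodesulfovibrionia;o__Thermodesulfovibrionales;f__9FT-COMBO-42-15;g__9FT-COMBO-42-15;s__9FT-COMBO-42-15 archetypum",
      contigs = list(
        ctg1 = c(list(g("dsrA", OB), g("dsrB", OB), g("dsrL", "L2B")), core),
        ctg2 = list(g("sat"), g("aprA"), g("aprB"), g("qmoA"), g("qmoB"))),
      loci = list(list(contig = "ctg1", type = OB, direction = "OXIDATIVE")),
      genome_direction = "OXIDATIVE",
      completeness = "FULL_SULFATE_PATHWAY"),
    chloroflexota_reductive = list(
      taxonomy = "d__Bacteria;p__Chloroflexota;c__Anaerolineae;o__Anaerolineales;f__Anaerolineaceae;g__Anaerolinea;s__Anaerolinea archetypa",
      contigs = list(
        ctg1 = c(list(g("dsrA", RB), g("dsrB", RB), g("dsrD")), core),
        ctg2 = list(g("sat"), g("aprA"), g("aprB"), g("qmoA"), g("qmoB"),
                    g("qmoC"))),
      loci = list(list(contig = "ctg1", type = RB, direction = "REDUCTIVE")),
      genome_direction = "REDUCTIVE",
      completeness = "FULL_SULFATE_PATHWAY"),
    bare_dsrab_uncertain = list(
      taxonomy = "d__Bacteria;p__Spirochaetota;c__Spirochaetia;o__Spirochaetales;f__Spirochaetaceae;g__Spirochaeta;s__Spirochaeta archetypa",
      contigs = list(
        ctg1 = list(g("dsrA", RB), g("dsrB", RB), g("dsrC"))),
      loci = list(list(contig = "ctg1", type = RB, direction = "UNCERTAIN")),
      genome_direction = "UNCERTAIN",
      completeness = "PARTIAL"),
    decoys_only = list(
      taxonomy = "d__Bacteria;p__Bacillota_A;c__Clostridia;o__Clostridiales;f__Clostridiaceae;g__Clostridium;s__Clostridium archetypum",
      contigs = list(),
      loci = list(),
      genome_direction = NA_character_,
      completeness = NA_character_)
  )
}

#' Names of the built-in scenario archetypes
#' @return Character vector (12 scenario genomes plus `decoys_only`).
#' @export
archetype_names <- function() names(archetype_definitions())

#' Generate one scenario genome with ground truth
#'
#' Emits every intended gene of the archetype as a mutated copy
#' (`query_mutation_rate`) of a reference seed of the intended family and
#' type group, placed at its contig/gene-index slot, plus shuffled decoy
#' proteins on a separate contig. Uses the current RNG stream unless
#' `seed` is given.
#'
#' @param archetype One of [archetype_names()].
#' @param refset From [generate_reference_set()].
#' @param gcfg `dsr_gen_config`.
#' @param genome_id Genome id (default the archetype name).
#' @param seed Optional integer to seed the stream first.
#' @return List: `proteome` (record table), `truth` (list with intended
#'   complement, per-locus types/directions, genome direction,
#'   completeness, taxonomy).
#' @export
generate_genome <- function(archetype, refset, gcfg = generator_config(),
                            genome_id = archetype, seed = NULL) {
  defs <- archetype_definitions()
  if (!archetype %in% names(defs))
    abort_config("unknown archetype '%s'", archetype)
  if (!is.null(seed)) set.seed(seed)
  def <- defs[[archetype]]
  bg <- gcfg$background
  ids <- character(0); res <- character(0)
  contigs <- character(0); idxs <- integer(0)
  complement_truth <- integer(0)
  gene_n <- 0L
  for (ctg in names(def$contigs)) {
    slots <- def$contigs[[ctg]]
    for (i in seq_along(slots)) {
      fam <- slots[[i]][1]; grp <- slots[[i]][2]
      pool <- if (!is.na(grp)) refset$group_seeds[[fam]][[grp]]
              else refset$families[[fam]]$seeds$residues
      template <- pool[sample.int(length(pool), 1L)]
      gene_n <- gene_n + 1L
      ids <- c(ids, sprintf("%s_gene%02d_%s", genome_id, gene_n, fam))
      res <- c(res, mutate_sequence(template, gcfg$query_mutation_rate, bg))
      contigs <- c(contigs, ctg)
      idxs <- c(idxs, i)
      complement_truth[fam] <- sum(complement_truth[fam], 1L, na.rm = TRUE)
    }
  }
  # shuffled decoys on their own contig: family-like composition with no
  # conserved positional signal
  all_seeds <- unlist(lapply(refset$families, function(f) f$seeds$residues),
                      use.names = FALSE)
  for (d in seq_len(gcfg$decoys_per_genome)) {
    ids <- c(ids, sprintf("%s_decoy%02d", genome_id, d))
    res <- c(res, shuffle_sequence(all_seeds[sample.int(length(all_seeds),
                                                        1L)]))
    contigs <- c(contigs, "ctg_decoy")
    idxs <- c(idxs, d)
  }
  proteome <- seq_records(ids, res, "AMINO", genome_id = genome_id,
                          contig_id = contigs, gene_index = idxs,
                          strand = "+")
  truth <- list(genome_id = genome_id, archetype = archetype,
                complement = complement_truth,
                loci = def$loci,
                genome_direction = def$genome_direction,
                completeness = def$completeness,
                taxonomy = def$taxonomy)
  list(proteome = proteome, truth = truth)
}

#' Generate the full archetype genome suite
#'
#' The 12 scenario genomes (every archetype except `decoys_only`) under a
#' single RNG stream seeded with `gcfg$rng_seed`.
#'
#' @param refset From [generate_reference_set()].
#' @param gcfg `dsr_gen_config`.
#' @param archetypes Archetypes to emit (default all scenario genomes).
#' @return List: `genomes` (named list of proteome tables), `truths`
#'   (named list), `taxonomy` (data.frame `genome_id`, `taxonomy`).
#' @export
generate_genome_suite <- function(refset, gcfg = generator_config(),
                                  archetypes =
                                    setdiff(archetype_names(),
                                            "decoys_only")) {
  set.seed(gcfg$rng_seed + 1L)
  genomes <- list(); truths <- list()
  for (a in archetypes) {
    g <- generate_genome(a, refset, gcfg)
    genomes[[a]] <- g$proteome
    truths[[a]] <- g$truth
  }
  taxonomy <- data.frame(
    genome_id = names(truths),
    taxonomy = vapply(truths, `[[`, "", "taxonomy"),
    completeness = 95, contamination = 2,
    stringsAsFactors = FALSE, row.names = NULL)
  list(genomes = genomes, truths = truths, taxonomy = taxonomy)
}

# realize one concrete (non-degenerate) binding site for a primer and
# corrupt exactly `m` positions to mismatching bases
realize_site <- function(iupac, m) {
  masks <- encode_iupac(iupac, "primer")
  bases <- c("A", "C", "G", "T")
  site <- vapply(masks, function(mask) {
    sample(bases[bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0L], 1L)
  }, "")
  if (m > 0) {
    mutable <- which(masks != 15L)  # an N position cannot mismatch
    if (length(mutable) < m)
      abort_config("cannot place %d mismatches on primer %s", m, iupac)
    at <- sample(mutable, m)
    for (i in at) {
      outside <- bases[bitwAnd(masks[i], c(1L, 2L, 4L, 8L)) == 0L]
      site[i] <- sample(outside, 1L)
    }
  }
  paste(site, collapse = "")
}

#' Generate a nucleotide dataset with implanted primer sites
#'
#' For every row of the plan, a concrete binding site of the mix's first
#' variant is implanted into a random backbone at the given position with
#' exactly the planned mismatch count (REVERSE mixes are implanted as the
#' reverse complement so the scan semantics see the planned mismatches).
#' The truth coverage table is derived from the plan, not from scanning.
#'
#' @param mixes Named list of `dsr_primer_mix`.
#' @param plan data.frame with columns `sequence_id`, `clade_id`,
#'   `mix_name`, `mismatches`, and optional `position` (default: mixes
#'   spaced 150 nt apart from position 101).
#' @param gcfg `dsr_gen_config`.
#' @param max_mm Budget used for the truth coverage table. Default 1.
#' @return List: `sequences` (nucleotide records), `clades` (data.frame),
#'   `plan` (with realized positions), `truth` (clade x mix coverage).
#' @export
generate_primer_dataset <- function(mixes, plan,
                                    gcfg = generator_config(),
                                    max_mm = 1L) {
  set.seed(gcfg$rng_seed + 2L)
  need <- c("sequence_id", "clade_id", "mix_name", "mismatches")
  if (!all(need %in% names(plan)))
    abort_schema("plan needs columns %s", paste(need, collapse = ", "))
  if (!"position" %in% names(plan)) plan$position <- NA_integer_
  mix_default_pos <- stats::setNames(
    101L + 150L * (seq_along(mixes) - 1L), names(mixes))
  seq_ids <- unique(plan$sequence_id)
  backbones <- stats::setNames(vapply(seq_ids, function(s)
    paste(sample(c("A", "C", "G", "T"), gcfg$primer_backbone_length,
                 replace = TRUE), collapse = ""), ""), seq_ids)
  for (r in seq_len(nrow(plan))) {
    mix <- mixes[[plan$mix_name[r]]]
    if (is.null(mix)) abort_config("plan names unknown mix '%s'",
                                   plan$mix_name[r])
    iupac <- mix$variants$iupac[1]
    if (plan$mismatches[r] > nchar(iupac))
      abort_config("planned mismatches exceed primer length")
    pos <- plan$position[r]
    if (is.na(pos)) pos <- mix_default_pos[[plan$mix_name[r]]]
    plan$position[r] <- pos
    site <- realize_site(iupac, plan$mismatches[r])
    if (mix$orientation == "REVERSE") site <- revcomp_iupac(site)
    s <- backbones[[plan$sequence_id[r]]]
    if (pos + nchar(site) - 1L > nchar(s))
      abort_config("implant position %d beyond backbone", pos)
    substr(s, pos, pos + nchar(site) - 1L) <- site
    backbones[[plan$sequence_id[r]]] <- s
  }
  clades <- unique(plan[, c("sequence_id", "clade_id")])
  sequences <- seq_records(seq_ids, unname(backbones[seq_ids]),
                           "NUCLEOTIDE")
  truth <- do.call(rbind, lapply(split(plan, list(plan$clade_id,
                                                  plan$mix_name),
                                       drop = TRUE), function(df) {
    data.frame(clade_id = df$clade_id[1], mix_name = df$mix_name[1],
               n_sequences = nrow(df),
               n_covered = sum(df$mismatches <= max_mm),
               fraction = mean(df$mismatches <= max_mm),
               stringsAsFactors = FALSE)
  }))
  row.names(truth) <- NULL
  list(sequences = sequences, clades = clades, plan = plan, truth = truth)
}
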