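# Rule engine: co-localization, the exhaustive direction decision table,
# genome-level calls, pathway completeness, lineage aggregation.

test_that("colocalized is a tri-state window test", {
  l <- function(c, i) list(contig_id = c, gene_index = i)
  expect_true(colocalized(l("c1", 3), l("c1", 7), 10))
  expect_false(colocalized(l("c1", 1), l("c2", 1), 10))
  expect_false(colocalized(l("c1", 1), l("c1", 20), 10))
  expect_true(colocalized(l("c1", 1), l("c1", 11), 10))
  expect_false(colocalized(l("c1", 1), l("c1", 12), 10))
  expect_true(is.na(colocalized(l(NA, NA), l("c1", 3), 10)))
})

test_that("the direction rule table matches the hand-written specification exhaustively", {
  types <- c("REDUCTIVE_ARCHAEAL", "OXIDATIVE_BACTERIAL",
             "REDUCTIVE_BACTERIAL", "UNCERTAIN")
  dsrls <- c("none", "L1A", "L1B", "L2A", "L2B", "L2C")
  n <- 0
  for (ty in types) for (dd in c(TRUE, FALSE)) for (dl in dsrls)
    for (efh in c(TRUE, FALSE)) for (early in c(TRUE, FALSE)) {
      got <- dsrscreen:::direction_rule(
        ty, dd, if (dl == "none") character(0) else dl, efh, early)
      want <- expected_direction(ty, dd, dl, efh, early)
      info <- sprintf("type=%s dsrD=%s dsrL=%s efh=%s early=%s",
                      ty, dd, dl, efh, early)
      expect_equal(got$direction, want$direction, info = info)
      expect_equal(got$conflict, want$conflict, info = info)
      if (got$direction != "UNCERTAIN")
        expect_gt(length(got$evidence), 0)
      n <- n + 1
    }
  expect_equal(n, 192)
})

test_that("dsrEFH never changes a direction outcome, only evidence", {
  types <- c("REDUCTIVE_ARCHAEAL", "OXIDATIVE_BACTERIAL",
             "REDUCTIVE_BACTERIAL", "UNCERTAIN")
  dsrls <- c("none", "L1A", "L1B", "L2A", "L2B", "L2C")
  for (ty in types) for (dd in c(TRUE, FALSE)) for (dl in dsrls)
    for (early in c(TRUE, FALSE)) {
      dl_arg <- if (dl == "none") character(0) else dl
      with_efh <- dsrscreen:::direction_rule(ty, dd, dl_arg, TRUE, early)
      without <- dsrscreen:::direction_rule(ty, dd, dl_arg, FALSE, early)
      expect_identical(with_efh$direction, without$direction)
      expect_identical(with_efh$conflict, without$conflict)
    }
})

test_that("call_locus_direction wires complement evidence into the rules", {
  cfg <- fixture_config()
  # canonical sulfate reducer: reductive type + dsrD anywhere
  cp <- mock_complement("g1", c("dsrA", "dsrB", "dsrD", "dsrC"),
                        contigs = c("c1", "c1", "c1", "c1"),
                        indices = 1:4)
  call <- call_locus_direction(mock_type_call("REDUCTIVE_BACTERIAL"), cp,
                               list(), cfg,
                               locus = list(contig_id = "c1",
                                            gene_index = 1L))
  expect_equal(call$direction, "REDUCTIVE")
  expect_false(call$conflict)
  expect_true(any(grepl("^R3", call$evidence)))
  expect_true(any(grepl("colocalized_dsrD", call$evidence)))

  # canonical sulfur oxidizer with DsrL-1A and DsrEFH as support
  cp2 <- mock_complement("g2", c("dsrA", "dsrB", "dsrE", "dsrF", "dsrH",
                                 "dsrL"))
  call2 <- call_locus_direction(mock_type_call("OXIDATIVE_BACTERIAL"), cp2,
                                list(mock_dsrl_call("L1A")), cfg)
  expect_equal(call2$direction, "OXIDATIVE")
  expect_true("R2_support_dsrEFH" %in% call2$evidence)

  # no dsrD but oxidative-indicator DsrL on a reductive-typed locus
  cp3 <- mock_complement("g3", c("dsrA", "dsrB", "dsrL"))
  call3 <- call_locus_direction(mock_type_call("REDUCTIVE_BACTERIAL"), cp3,
                                list(mock_dsrl_call("L1B")), cfg)
  expect_equal(call3$direction, "OXIDATIVE")
  expect_true(call3$conflict)

  # early diverging without dsrD and dsrL
  cp4 <- mock_complement("g4", c("dsrA", "dsrB", "dsrC"))
  call4 <- call_locus_direction(
    mock_type_call("REDUCTIVE_ARCHAEAL"), cp4, list(), cfg)
  expect_equal(call4$direction, "REDUCTIVE")
})

test_that("genome calls combine loci symmetrically; zero loci error", {
  cp <- mock_complement("g", c("dsrA", "dsrB", "dsrD", "dsrL", "dsrC",
                               "dsrM", "dsrK", "sat", "aprA", "aprB",
                               "qmoA", "qmoB"))
  red <- call_locus_direction(mock_type_call("REDUCTIVE_BACTERIAL"), cp)
  oxi <- call_locus_direction(mock_type_call("OXIDATIVE_BACTERIAL"), cp)
  unc <- call_locus_direction(mock_type_call("UNCERTAIN"), cp)

  expect_equal(call_genome_metabolism(list(red, oxi), cp)$genome_direction,
               "SWITCHABLE")
  expect_equal(call_genome_metabolism(list(oxi, red), cp)$genome_direction,
               "SWITCHABLE")
  expect_equal(call_genome_metabolism(list(red), cp)$genome_direction,
               "REDUCTIVE")
  expect_equal(call_genome_metabolism(list(unc, unc), cp)$genome_direction,
               "UNCERTAIN")
  expect_error(call_genome_metabolism(list(), cp),
               class = "dsr_no_dsr_error")
})

test_that("pathway completeness distinguishes full, sulfite-only and partial", {
  full <- mock_complement("g", full_pathway_required())
  expect_equal(assess_pathway_completeness(full)$completeness,
               "FULL_SULFATE_PATHWAY")

  sulfite <- mock_complement("g", c("dsrA", "dsrB", "dsrC", "dsrD",
                                    "dsrM", "dsrK"))
  expect_equal(assess_pathway_completeness(sulfite)$completeness,
               "SULFITE_ONLY")

  partial <- mock_complement("g", c("dsrA", "dsrB"))
  res <- assess_pathway_completeness(partial)
  expect_equal(res$completeness, "PARTIAL")
  expect_length(res$missing, 8)

  # one sulfate-branch gene breaks SULFITE_ONLY
  mixed <- mock_complement("g", c("dsrA", "dsrB", "dsrC", "dsrM", "dsrK",
                                  "sat"))
  expect_equal(assess_pathway_completeness(mixed)$completeness, "PARTIAL")
})

test_that("lineage aggregation applies the strict > 30% display rule", {
  tax_str <- function(p) sprintf(
    "d__Bacteria;p__%s;c__C;o__O;f__F;g__G;s__G sp%%d", p)
  cps <- c(
    lapply(1:4, function(i) mock_complement(
      paste0("gA", i), c("dsrA", "dsrB", "dsrD"))),
    lapply(5:10, function(i) mock_complement(
      paste0("gA", i), c("dsrA", "dsrB"))))
  taxonomy <- data.frame(
    genome_id = paste0("gA", 1:10),
    phylum = rep("Desulfobacterota", 10),
    stringsAsFactors = FALSE)
  cfg <- fixture_config()
  lin <- aggregate_lineage(cps, taxonomy, "phylum", cfg)
  dsrD_row <- lin[lin$family == "dsrD", ]
  expect_equal(dsrD_row$fraction, 0.4)
  expect_true(dsrD_row$present)
  expect_equal(lin$n_genomes[1], 10)

  # exactly 3/10 fails the strict rule
  cps3 <- c(cps[1:3], cps[5:10],
            list(mock_complement("gA11", c("dsrA", "dsrB"))))
  taxonomy3 <- data.frame(genome_id = c(paste0("gA", c(1:3, 5:10)), "gA11"),
                          phylum = "Desulfobacterota")
  lin3 <- aggregate_lineage(cps3, taxonomy3, "phylum", cfg)
  d3 <- lin3[lin3$family == "dsrD", ]
  expect_equal(d3$fraction, 0.3)
  expect_false(d3$present)
  expect_false(lin3[lin3$family == "dsrL", ]$present)  # 0/10

  # genomes without dsrAB never enter the denominator
  cps_extra <- c(cps, list(mock_complement("gNoDsr", c("sat", "aprA"))))
  taxonomy_extra <- rbind(taxonomy,
                          data.frame(genome_id = "gNoDsr",
                                     phylum = "Desulfobacterota"))
  lin_extra <- aggregate_lineage(cps_extra, taxonomy_extra, "phylum", cfg)
  expect_equal(lin_extra$n_genomes[1], 10)

  # sublineage merging unifies Bacillota_A and Bacillota
  cps_b <- list(mock_complement("b1", c("dsrA", "dsrB", "dsrD")),
                mock_complement("b2", c("dsrA", "dsrB")))
  tax_b <- data.frame(genome_id = c("b1", "b2"),
                      phylum = c("Bacillota_A", "Bacillota"))
  lin_b <- aggregate_lineage(cps_b, tax_b, "phylum", cfg)
  expect_equal(unique(lin_b$lineage), "Bacillota")
  expect_equal(lin_b$n_genomes[1], 2)

  expect_error(aggregate_lineage(cps, taxonomy[1:5, ], "phylum", cfg),
               class = "dsr_taxonomy_error")
})
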