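# Typing layer: indel filter, nearest-typed-reference classification of
# DsrAB and DsrL, and LGT-candidate flagging.

test_that("apply_indel_filter keeps columns by gap fraction", {
  rows <- c("ACDEFGHIKLMNPQRSTVWY", "ACDEFGHIKLMNPQRSTVWY",
            "ACDEFGHIKLMNPQRSTVWY", "ACDEFGHIKLMNPQRSTVWY")
  m <- apply_indel_filter(rows, 0.5)
  expect_true(all(m$keep))
  expect_equal(m$kept_count, 20)

  rows2 <- c("A-C", "A-C", "AAC", "AAC")   # column 2 has 2/4 gaps
  expect_false(apply_indel_filter(rows2, 0.4)$keep[2])
  expect_true(apply_indel_filter(rows2, 0.5)$keep[2])

  rows3 <- c("A-", "A-", "A-", "A-")       # all-gap column
  expect_false(apply_indel_filter(rows3, 0.99)$keep[2])
  expect_true(all(apply_indel_filter(rows3, 1)$keep))

  rows4 <- c("A-C", "AAC", "A-C", "AAC")
  expect_equal(apply_indel_filter(rows4, 0)$kept_count, 2)

  expect_error(apply_indel_filter(c("AC", "A")),
               class = "dsr_alignment_error")
})

test_that("type_dsrab assigns self and mutated queries; ties are UNCERTAIN", {
  refset <- fixture_refset()
  cfg <- fixture_config()
  typed <- refset$typed

  ref <- typed[typed$family == "dsrAB_concat" &
                 typed$type_label == "REDUCTIVE_BACTERIAL" &
                 !typed$early_diverging, ][1, ]
  nA <- nchar(refset$group_seeds$dsrA$REDUCTIVE_BACTERIAL[1])
  tc <- type_dsrab(substr(ref$residues, 1, nA),
                   substr(ref$residues, nA + 1, nchar(ref$residues)),
                   typed, cfg)
  expect_equal(tc$assigned_label, "REDUCTIVE_BACTERIAL")
  expect_equal(tc$support, 1.0)
  expect_false(tc$partial)

  set.seed(11)
  for (g in c("OXIDATIVE_BACTERIAL", "REDUCTIVE_ARCHAEAL")) {
    qa <- mutate_sequence(refset$group_seeds$dsrA[[g]][1], 0.15)
    qb <- mutate_sequence(refset$group_seeds$dsrB[[g]][1], 0.15)
    tc <- type_dsrab(qa, qb, typed, cfg)
    expect_equal(tc$assigned_label, g)
  }

  # single subunit types as partial
  set.seed(12)
  qa <- mutate_sequence(refset$group_seeds$dsrA$OXIDATIVE_BACTERIAL[2], 0.1)
  tc <- type_dsrab(qa, NULL, typed, cfg)
  expect_equal(tc$assigned_label, "OXIDATIVE_BACTERIAL")
  expect_true(tc$partial)

  # constructed tie: two identical references with different labels, k = 2
  q <- random_aa(100)
  tie_refs <- data.frame(
    id = c("r1", "r2"), residues = c(q, q), family = "dsrAB_concat",
    type_label = c("REDUCTIVE_BACTERIAL", "OXIDATIVE_BACTERIAL"),
    early_diverging = FALSE,
    taxonomy = "d__B;p__X;c__x;o__x;f__x;g__x;s__x y",
    uncultured_lineage = NA_integer_,
    self_score = self_score(c(q, q)), stringsAsFactors = FALSE)
  expect_error(type_dsrab(NULL, NULL, typed, cfg), class = "dsr_value_error")
  tie_refs$family <- "dsrA"
  tc <- type_dsrab(q, NULL, tie_refs, analysis_config(typing_k = 2))
  expect_equal(tc$assigned_label, "UNCERTAIN")
  expect_equal(tc$support, 0.5)

  expect_error(type_dsrab("MKV", NULL, typed[typed$family == "dsrL", ], cfg),
               class = "dsr_config_error")
})

test_that("early-diverging flag is inherited from the reference neighborhood", {
  refset <- fixture_refset()
  cfg <- fixture_config()
  set.seed(13)
  qa <- mutate_sequence(refset$group_seeds$dsrA$EARLY_DIVERGING[1], 0.10)
  qb <- mutate_sequence(refset$group_seeds$dsrB$EARLY_DIVERGING[1], 0.10)
  tc <- type_dsrab(qa, qb, refset$typed, cfg)
  expect_equal(tc$assigned_label, "REDUCTIVE_BACTERIAL")
  expect_true(tc$early_diverging)

  # a plain reductive-bacterial query must not inherit the flag
  qa <- mutate_sequence(refset$group_seeds$dsrA$REDUCTIVE_BACTERIAL[1], 0.10)
  qb <- mutate_sequence(refset$group_seeds$dsrB$REDUCTIVE_BACTERIAL[1], 0.10)
  tc <- type_dsrab(qa, qb, refset$typed, cfg)
  expect_false(tc$early_diverging)
})

test_that("subtype_dsrl recovers subclusters", {
  refset <- fixture_refset()
  cfg <- fixture_config()
  typed <- refset$typed
  ref <- typed[typed$family == "dsrL" & typed$type_label == "L2C", ][1, ]
  tc <- subtype_dsrl(ref$residues, typed, cfg)
  expect_equal(tc$assigned_label, "L2C")
  expect_equal(tc$support, 1.0)

  set.seed(11)
  for (g in c("L1A", "L1B", "L2A", "L2B", "L2C")) {
    q <- mutate_sequence(refset$group_seeds$dsrL[[g]][2], 0.15)
    tc <- subtype_dsrl(q, typed, cfg)
    expect_equal(tc$assigned_label, g)
    expect_gte(tc$support, 0.6)
  }
})

test_that("typing is invariant to reference input order", {
  refset <- fixture_refset()
  cfg <- fixture_config()
  set.seed(14)
  q <- mutate_sequence(refset$group_seeds$dsrL$L1B[1], 0.12)
  t1 <- subtype_dsrl(q, refset$typed, cfg)
  shuffled <- refset$typed[sample(nrow(refset$typed)), ]
  t2 <- subtype_dsrl(q, shuffled, cfg)
  expect_equal(t1$assigned_label, t2$assigned_label)
  expect_equal(t1$support, t2$support)
  expect_equal(t1$nearest_ref_id, t2$nearest_ref_id)
})

test_that("flag_lgt_candidate flags phylum discordance with enough support", {
  dsb <- "d__Bacteria;p__Desulfobacterota;c__x;o__x;f__x;g__x;s__x y"
  tc <- mock_type_call("REDUCTIVE_BACTERIAL", support = 1.0, taxonomy = dsb)
  gen_bacillota <- "d__Bacteria;p__Bacillota_A;c__Clostridia;o__x;f__x;g__Desulfotomaculum;s__D r"
  res <- flag_lgt_candidate(gen_bacillota, tc)
  expect_true(res$flagged)
  expect_match(res$note, "Bacillota")

  gen_same <- "d__Bacteria;p__Desulfobacterota_B;c__x;o__x;f__x;g__x;s__x y"
  expect_false(flag_lgt_candidate(gen_same, tc)$flagged)

  tc_weak <- mock_type_call("REDUCTIVE_BACTERIAL", support = 0.4,
                            taxonomy = dsb)
  expect_false(flag_lgt_candidate(gen_bacillota, tc_weak)$flagged)

  expect_error(flag_lgt_candidate("d__Bacteria", tc),
               class = "dsr_taxonomy_error")
})
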