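# Primer evaluation: IUPAC semantics, mismatch counting, binding-site
# search against the naive oracle, clade coverage, amplicon finding.

test_that("iupac_match uses set-intersection semantics", {
  expect_true(iupac_match("R", "A"))
  expect_false(iupac_match("R", "C"))
  expect_true(iupac_match("N", "T"))
  expect_true(iupac_match("A", "N"))   # target N matches by default
  expect_false(iupac_match("A", "N", target_ambiguity_is_mismatch = TRUE))
  expect_error(iupac_match("A", "Z"), class = "dsr_alphabet_error")
})

test_that("count_mismatches is exact, indel-free and revcomp-symmetric", {
  expect_equal(count_mismatches("ACGT", "ACGT"), 0)
  expect_equal(count_mismatches("ACGT", "ACGA"), 1)
  expect_equal(count_mismatches("ACRT", "ACGT"), 0)
  expect_error(count_mismatches("ACGT", "ACG"), class = "dsr_length_error")

  set.seed(401)
  for (i in 1:50) {
    p <- random_iupac(sample(10:25, 1))
    w <- random_nt(nchar(p))
    mm <- count_mismatches(p, w)
    expect_identical(mm, oracle_count_mm(p, w))
    expect_identical(mm, count_mismatches(oracle_revcomp(p),
                                          oracle_revcomp(w)))
  }
})

test_that("best_binding finds implanted and constructed sites", {
  set.seed(402)
  primer <- "ACGTACGTACGTACGTACGT"
  backbone <- random_nt(400)
  # forward site with exactly one forced mismatch at position 101
  site <- primer
  substr(site, 7, 7) <- "C"   # G -> C at position 7: one mismatch
  s <- backbone
  substr(s, 101, 120) <- site
  b <- best_binding(primer, s)
  expect_equal(b$position, 101)
  expect_equal(b$strand, "+")
  expect_equal(b$mismatches, 1)

  # reverse primer equal to the revcomp of positions 151-170
  rev_primer <- oracle_revcomp(substr(s, 151, 170))
  b2 <- best_binding(rev_primer, s, orientation = "REVERSE")
  expect_equal(b2$position, 151)
  expect_equal(b2$strand, "-")
  expect_equal(b2$mismatches, 0)

  expect_error(best_binding(primer, "ACGT"), class = "dsr_length_error")
})

test_that("best_binding equals the exhaustive-scan oracle on random cases", {
  set.seed(403)
  for (i in 1:150) {
    p <- random_iupac(sample(8:14, 1), n_degenerate = sample(0:2, 1))
    s <- random_nt(sample(40:80, 1))
    ori <- sample(c("FORWARD", "REVERSE"), 1)
    got <- best_binding(p, s, orientation = ori)
    want <- oracle_best_binding(p, s, ori)
    expect_equal(got$position, want$position, info = paste(p, s, ori))
    expect_equal(got$mismatches, want$mismatches, info = paste(p, s, ori))
  }
})

test_that("is_covered ORs the mix variants and respects the budget", {
  set.seed(404)
  s <- random_nt(200)
  v2 <- substr(s, 61, 78)  # exact site for variant 2 only
  mix <- make_mix("mixA", c("GGGGGGGGGGGGGGGGGG", v2, "CCCCCCCCCCCCCCCCCC"))
  expect_true(is_covered(s, mix, max_mm = 0))

  # all variants far away at budget 1
  mix_bad <- make_mix("mixB", c("GGGGGGGGGGGGGGGGGG", "CCCCCCCCCCCCCCCCCC"))
  s_at <- paste(rep("AT", 100), collapse = "")
  expect_false(is_covered(s_at, mix_bad, max_mm = 1))
  expect_true(is_covered(s_at, mix_bad, max_mm = 18))  # budget = length

  # coverage is monotone in the mismatch budget
  set.seed(405)
  for (i in 1:20) {
    s2 <- random_nt(120)
    mix2 <- make_mix("m", random_iupac(12))
    cov <- vapply(0:12, function(k) is_covered(s2, mix2, k), TRUE)
    expect_true(all(diff(cov) >= 0))
    expect_true(cov[13])
  }
})

test_that("clade_coverage applies the inclusive >= 75% rule", {
  mixes <- list(m = make_mix("m", "ACGTACGTACGTACGT"))
  plan <- data.frame(
    sequence_id = paste0("s", 1:30),
    clade_id = rep(c("pass8of10", "fail7of10", "exact10"), each = 10),
    mix_name = "m",
    mismatches = c(c(rep(0, 4), rep(1, 4), 2, 3),
                   c(rep(0, 7), 2, 2, 2),
                   rep(0, 10)))
  gen <- generate_primer_dataset(mixes, plan,
                                 generator_config(rng_seed = 5))
  cc <- clade_coverage(gen$sequences, gen$clades, mixes$m,
                       fixture_config())
  cc <- cc[match(c("pass8of10", "fail7of10", "exact10"), cc$clade_id), ]
  expect_equal(cc$fraction, c(0.8, 0.7, 1.0))
  expect_equal(cc$passed, c(TRUE, FALSE, TRUE))
  expect_equal(cc$n_covered, c(8, 7, 10))

  clades_bad <- rbind(gen$clades,
                      data.frame(sequence_id = "ghost",
                                 clade_id = "empty_clade"))
  expect_error(clade_coverage(gen$sequences, clades_bad, mixes$m,
                              fixture_config()),
               class = "dsr_empty_clade_error")
})

test_that("find_amplicons enumerates in-window primer pairs", {
  set.seed(406)
  s <- random_nt(500)
  fwd <- substr(s, 50, 67)
  rev_site <- substr(s, 333, 350)
  fwd_mix <- make_mix("f", fwd, "FORWARD")
  rev_mix <- make_mix("r", oracle_revcomp(rev_site), "REVERSE")
  amp <- find_amplicons(fwd_mix, rev_mix, s, max_mm = 0,
                        min_len = 100, max_len = 400)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$start, 50)
  expect_equal(amp$end, 350)
  expect_equal(amp$fwd_mm + amp$rev_mm, 0)

  # no reverse site within budget -> empty
  none <- find_amplicons(fwd_mix, make_mix("r2", "GGGGGGGGGGGGGGGGGG",
                                           "REVERSE"),
                         s, max_mm = 0)
  expect_equal(nrow(none), 0)

  expect_error(find_amplicons(rev_mix, fwd_mix, s),
               class = "dsr_orientation_error")
})

test_that("find_amplicons equals the nested-loop oracle on random cases", {
  set.seed(407)
  for (i in 1:60) {
    s <- random_nt(sample(60:120, 1))
    fv <- vapply(1:2, function(j) random_iupac(8, 1), "")
    rv <- vapply(1:2, function(j) random_iupac(8, 1), "")
    fwd_mix <- make_mix("f", fv, "FORWARD")
    rev_mix <- make_mix("r", rv, "REVERSE")
    got <- find_amplicons(fwd_mix, rev_mix, s, max_mm = 2,
                          min_len = 20, max_len = 100)
    want <- oracle_amplicons(fv, rv, s, 2, 20, 100)
    row.names(got) <- row.names(want) <- NULL
    expect_equal(got, want, info = s)
  }
})
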