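# I/O layer: FASTA round trips, reference database loading, taxonomy and
# primer parsing, phylum normalization.

test_that("read_fasta parses headers and enforces its error contract", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">a", "MKV"), f)
  rec <- read_fasta(f, "AMINO")
  expect_equal(rec$id, "a")
  expect_equal(rec$residues, "MKV")

  writeLines(c(">a", "MKV", ">a", "ML"), f)
  expect_error(read_fasta(f, "AMINO"), class = "dsr_duplicate_id")

  writeLines(c(">a desc here", "MKJV"), f)  # J is not an amino acid here
  err <- tryCatch(read_fasta(f, "AMINO"), error = identity)
  expect_s3_class(err, "dsr_alphabet_error")
  expect_match(conditionMessage(err), "'a'")
  expect_match(conditionMessage(err), "position 3")

  file.create(f2 <- withr::local_tempfile(fileext = ".faa"))
  expect_error(read_fasta(f2, "AMINO"), class = "dsr_empty_input")
})

test_that("FASTA write/read round-trips 50 generated records field-by-field", {
  set.seed(42)
  n <- 50
  rec <- seq_records(
    id = sprintf("rec%02d", 1:n),
    residues = vapply(1:n, function(i) random_aa(sample(20:80, 1)), ""),
    alphabet = "AMINO",
    description = ifelse(1:n %% 2 == 0, "some text", ""),
    genome_id = ifelse(1:n %% 3 == 0, "gX", NA_character_),
    contig_id = ifelse(1:n %% 3 == 0, "c1", NA_character_),
    gene_index = ifelse(1:n %% 3 == 0, 1:n, NA_integer_),
    strand = ifelse(1:n %% 3 == 0, "+", NA_character_))
  f <- withr::local_tempfile(fileext = ".faa")
  write_fasta(rec, f)
  back <- read_fasta(f, "AMINO")
  expect_equal(back, rec, ignore_attr = "alphabet")
  expect_equal(attr(back, "alphabet"), "AMINO")
})

test_that("load_reference_db groups seeds and typed references", {
  set.seed(5)
  fa <- withr::local_tempfile(fileext = ".faa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  seqs <- vapply(1:5, function(i) random_aa(60), "")
  write_fasta(seq_records(paste0("s", 1:5), seqs, "AMINO"), fa)
  meta <- data.frame(
    id = paste0("s", 1:5),
    family = c("dsrD", "dsrD", "dsrD", "dsrL", "dsrL"),
    type_label = c("", "", "", "L2C", "L2C"),
    early_diverging = c("", "", "", "FALSE", "FALSE"),
    taxonomy = c("", "", "", "d__B;p__X;c__x;o__x;f__x;g__x;s__x y",
                 "d__B;p__X;c__x;o__x;f__x;g__x;s__x z"),
    uncultured_lineage = c("", "", "", "", "6"))
  write_tsv(meta, tsv)
  db <- load_reference_db(fa, tsv)
  expect_named(db$families, "dsrD")
  expect_equal(nrow(db$families$dsrD$seeds), 3)
  expect_equal(nrow(db$typed), 2)
  expect_equal(db$typed$uncultured_lineage, c(NA_integer_, 6L))

  # illegal label for the family
  meta$type_label[4] <- "L1A"; meta$family[4] <- "dsrD"
  write_tsv(meta, tsv)
  expect_error(load_reference_db(fa, tsv), class = "dsr_label_domain_error")

  # metadata mismatch
  write_tsv(meta[1:4, ], tsv)
  expect_error(load_reference_db(fa, tsv),
               class = "dsr_metadata_mismatch")
})

test_that("generator reference set survives a disk round trip intact", {
  refset <- fixture_refset()
  fa <- withr::local_tempfile(fileext = ".faa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_reference_db(refset, fa, tsv)
  db <- load_reference_db(fa, tsv)
  expect_length(db$families, 19)
  expect_setequal(names(db$families), dsr_families())
  got <- db$typed[match(refset$typed$id, db$typed$id),
                  c("id", "family", "type_label", "early_diverging")]
  row.names(got) <- NULL
  expect_equal(got, refset$label_map)
})

test_that("normalize_phylum merges GTDB sublineages and is idempotent", {
  expect_equal(normalize_phylum("Bacillota_A"), "Bacillota")
  expect_equal(normalize_phylum("Desulfobacterota"), "Desulfobacterota")
  expect_equal(normalize_phylum("p__Myxococcota_B"), "Myxococcota")
  # suffix-free candidate-phylum style names pass through
  expect_equal(normalize_phylum("SAR324"), "SAR324")
  expect_equal(normalize_phylum("CG2-30-53-67"), "CG2-30-53-67")
  expect_error(normalize_phylum(""), class = "dsr_value_error")

  cases <- c("Bacillota", paste0("Bacillota_", LETTERS[1:8]),
             "p__Nitrospirota_A", "Thermoproteota", "UBA9089",
             "Verrucomicrobiota_A_B")
  for (x in cases)
    expect_identical(normalize_phylum(normalize_phylum(x)),
                     normalize_phylum(x))
})

test_that("load_primers groups variants and enforces invariants", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(
    mix_name = c("DSR1762f", "DSR1762f", "DSR2107r"),
    primer_name = c("DSR1762f_a", "DSR1762f_b", "DSR2107r_a"),
    iupac = c("ACGTRYACGTAC", "ACGTKYACGTAC", "TTGGNACGTTCA"),
    orientation = c("FORWARD", "FORWARD", "REVERSE"),
    anchor_position = c(1762, 1762, 2107),
    coordinate_reference = "Desulfovibrio_vulgaris_dsrAB")
  write_tsv(tab, tsv)
  mixes <- load_primers(tsv)
  expect_named(mixes, c("DSR1762f", "DSR2107r"))
  expect_equal(nrow(mixes$DSR1762f$variants), 2)
  expect_equal(mixes$DSR2107r$orientation, "REVERSE")

  tab$iupac[1] <- "ACGX"
  write_tsv(tab, tsv)
  expect_error(load_primers(tsv), class = "dsr_alphabet_error")

  tab$iupac[1] <- "ACGT"
  tab$orientation[2] <- "REVERSE"
  write_tsv(tab, tsv)
  expect_error(load_primers(tsv), class = "dsr_orientation_error")

  tab$orientation[2] <- "FORWARD"
  tab$primer_name[2] <- "DSR1762f_a"
  write_tsv(tab, tsv)
  expect_error(load_primers(tsv), class = "dsr_duplicate_id")
})

test_that("the shipped synthetic primer sheet loads as grouped mixes", {
  tsv <- system.file("extdata", "synthetic_primers.tsv",
                     package = "dsrscreen")
  mixes <- load_primers(tsv)
  expect_setequal(names(mixes),
                  c("DSR190f", "DSR1762f", "DSR2107r", "rDSR1f", "rDSR4r"))
  expect_equal(nrow(mixes$DSR190f$variants), 2)
  expect_equal(mixes$DSR2107r$orientation, "REVERSE")
})

test_that("gene order can be derived from a GFF3 file", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "ctg1\tx\tCDS\t500\t900\t.\t+\t0\tID=p2",
    "ctg1\tx\tCDS\t10\t300\t.\t+\t0\tID=p1",
    "ctg2\tx\tCDS\t100\t400\t.\t-\t0\tID=p3",
    "ctg1\tx\tgene\t10\t300\t.\t+\t.\tID=gene1"), gff)
  idx <- gene_index_from_gff(gff)
  expect_equal(idx$gene_index[idx$id == "p1"], 1L)
  expect_equal(idx$gene_index[idx$id == "p2"], 2L)
  expect_equal(idx$gene_index[idx$id == "p3"], 1L)
  expect_equal(idx$strand[idx$id == "p3"], "-")
})

test_that("taxonomy and YAML config round-trip through their readers", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(
    genome_id = c("g1", "g2"),
    taxonomy = c("d__Bacteria;p__Bacillota_A;c__Clostridia;o__X;f__Y;g__Z;s__Z w",
                 "d__Archaea;p__Halobacteriota;c__Archaeoglobi;o__A;f__B;g__C;s__C d"),
    completeness = c(95.2, 88), contamination = c(1.1, 3)), tsv)
  tax <- load_taxonomy(tsv)
  expect_equal(tax$phylum, c("Bacillota_A", "Halobacteriota"))
  expect_equal(tax$domain, c("Bacteria", "Archaea"))
  expect_equal(tax$completeness, c(95.2, 88))

  yml <- withr::local_tempfile(fileext = ".yaml")
  cfg <- analysis_config(typing_k = 7, detect_frac = 0.25)
  write_analysis_config(cfg, yml)
  expect_equal(read_analysis_config(yml), cfg)
  expect_error(analysis_config(detect_frac = 1.5),
               class = "dsr_config_error")
})
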