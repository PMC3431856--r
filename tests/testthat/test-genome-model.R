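test_that("the packaged annotation parses into a 15.4 kb record with 38 features", {
  rec <- sesamia_annotation()
  expect_s3_class(rec, "mitogenome")
  expect_equal(rec$length, 15413L)
  expect_equal(nrow(rec$features), 38L)
  expect_equal(sum(rec$features$category == "PCG"), 13L)
  expect_equal(sum(rec$features$category == "tRNA"), 22L)
  expect_equal(sum(rec$features$category == "rRNA"), 2L)
  expect_equal(sum(rec$features$category == "control"), 1L)
  cox1 <- rec$features[rec$features$name == "cox1", ]
  expect_equal(c(cox1$start, cox1$end), c(1500L, 3030L))
  expect_equal(cox1$start_codon, "CGA")
  expect_equal(cox1$stop_codon, "T")
})

test_that("feature_length handles plain and origin-wrapping intervals", {
  expect_equal(feature_length(1500, 3030, 15413), 1531L)
  expect_equal(feature_length(14319, 15102, 15413), 784L)
  expect_equal(feature_length(15410, 5, 15413), 9L)
  expect_equal(feature_length(1, 1, 10), 1L)
})

test_that("coordinate-derived sizes match the printed size column except atp6", {
  rec <- sesamia_annotation()
  f <- rec$features
  derived <- feature_length(f$start, f$end, rec$length)
  mismatch <- f$name[derived != f$size_printed]
  expect_equal(mismatch, "atp6")
  expect_equal(derived[f$name == "atp6"], 678L)
  expect_equal(f$size_printed[f$name == "atp6"], 696)
})

test_that("extraction returns coding orientation, wraps the origin, and inverts", {
  rec <- mitogenome(
    tibble::tibble(name = c("g1", "g2"), category = "rRNA",
                   strand = c("F", "R"), start = c(1, 1), end = c(3, 3)),
    length = 6, sequence = "ATGCCC"
  )
  expect_equal(extract_feature_sequence(rec, rec$features[1, ]), "ATG")
  expect_equal(extract_feature_sequence(rec, rec$features[2, ]), "CAT")
  expect_equal(revcomp(revcomp("ATGCCC")), "ATGCCC")

  wrap <- mitogenome(
    tibble::tibble(name = "w", category = "rRNA", strand = "F",
                   start = 5, end = 2),
    length = 6, sequence = "ATGCCC"
  )
  expect_equal(extract_feature_sequence(wrap, wrap$features[1, ]), "CCAT")
})

test_that("record validation rejects malformed inputs", {
  f <- tibble::tibble(name = "x", category = "PCG", strand = "F",
                      start = 5, end = 20, start_codon = "ATG")
  expect_error(mitogenome(f, length = 10), "coordinates")
  expect_error(mitogenome(f, length = 20, sequence = strrep("A", 19)),
               "does not match")
  expect_error(mitogenome(f, length = 20, sequence = strrep("R", 20)),
               "unsupported characters")
  f2 <- tibble::tibble(name = c("c1", "c2"), category = "control",
                       strand = "F", start = c(1, 11), end = c(10, 20))
  expect_error(mitogenome(f2, length = 20), "duplicate control region")
  f3 <- tibble::tibble(name = "t1", category = "tRNA", strand = "F",
                       start = 1, end = 10)
  expect_error(mitogenome(f3, length = 20), "anticodon")
  expect_error(
    extract_feature_sequence(mitogenome(f[0, ], length = 10), "x"),
    "sequence required")
})

test_that("an empty feature table with a declared length is a valid record", {
  f <- tibble::tibble(name = character(), category = character(),
                      strand = character(), start = integer(), end = integer())
  rec <- mitogenome(f, length = 100)
  expect_equal(rec$length, 100L)
  expect_equal(nrow(rec$features), 0L)
})

test_that("GenBank and TSV round trips preserve the record", {
  sim <- simulate_mitogenome(genome_spec(seed = 42))
  rec <- sim$record

  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, gb)
  back <- read_genbank(gb)
  expect_equal(back$length, rec$length)
  expect_equal(back$sequence, rec$sequence)
  expect_equal(back$features$name, rec$features$name)
  expect_equal(back$features$start, rec$features$start)
  expect_equal(back$features$end, rec$features$end)
  expect_equal(back$features$strand, rec$features$strand)
  expect_equal(back$features$start_codon, rec$features$start_codon)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(rec, tsv)
  back2 <- read_feature_table(tsv, "tsv", sequence = rec$sequence)
  expect_equal(back2$features$name, rec$features$name)
  expect_equal(back2$features$anticodon, rec$features$anticodon)

  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c(genome = rec$sequence), fa)
  expect_equal(unname(read_fasta(fa)), rec$sequence)
})

test_that("unsupported GenBank feature keys are skipped with a warning", {
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       toy 40 bp    DNA     circular",
    "FEATURES             Location/Qualifiers",
    "     source          1..40",
    "     STS             1..10",
    "                     /gene=\"oddity\"",
    "     rRNA            1..40",
    "                     /gene=\"rrnX\"",
    "ORIGIN",
    paste("        1", paste(rep("atgcatgcat", 4), collapse = " ")),
    "//"), gb)
  expect_warning(rec <- read_genbank(gb), "STS")
  expect_equal(rec$features$name, "rrnX")
  expect_equal(nchar(rec$sequence), 40L)
})

test_that("extracted planted CDS equals the generator's record of it", {
  sim <- simulate_mitogenome(genome_spec(seed = 9))
  rec <- sim$record
  cds <- extract_feature_sequence(rec, "cox1")
  expect_equal(substr(cds, 1, 3), "CGA")
  expect_equal(substr(cds, nchar(cds), nchar(cds)), "T")
  body <- substr(cds, 4, nchar(cds) - 1)
  codons <- substring(body, seq(1, nchar(body) - 2, 3), seq(3, nchar(body), 3))
  planted <- sim$ledger$codons$codon[sim$ledger$codons$gene == "cox1"]
  expect_equal(codons, planted)
})
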