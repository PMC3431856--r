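test_that("start/stop classification covers complete and truncated stops", {
  r <- classify_start_stop("ATGAAATAA")
  expect_equal(r$start_codon, "ATG")
  expect_equal(r$stop_class, "complete_TAA")
  expect_equal(classify_start_stop("ATGAAATAG")$stop_class, "complete_TAG")
  expect_equal(classify_start_stop("ATGAAAT")$stop_class, "truncated_T")
  expect_equal(classify_start_stop("ATGAAATA")$stop_class, "truncated_TA")
  expect_equal(classify_start_stop("ATGAAACCC")$stop_class, "anomalous")
  expect_equal(classify_start_stop("ATGAAAG")$stop_class, "anomalous")
  expect_error(classify_start_stop("ATGA"), "shorter")
})

test_that("annotated start/stop codons of the planted genome classify as
          annotated, including cox1's CGA start and truncated stops", {
  sim <- simulate_mitogenome(genome_spec(seed = 4))
  rec <- sim$record
  f <- rec$features[rec$features$category == "PCG", ]
  for (i in seq_len(nrow(f))) {
    cls <- classify_start_stop(extract_feature_sequence(rec, f[i, ]))
    expect_equal(cls$start_codon, f$start_codon[i], label = f$name[i])
    expect_equal(cls$stop_codon, f$stop_codon[i], label = f$name[i])
  }
  cox1 <- classify_start_stop(extract_feature_sequence(rec, "cox1"))
  expect_equal(cox1$start_codon, "CGA")
  expect_equal(cox1$stop_class, "truncated_T")
})

test_that("the family map covers 62 sense codons with Leu and Ser split", {
  fam <- codon_families()
  expect_equal(nrow(fam), 62L)
  expect_false(any(c("TAA", "TAG") %in% fam$codon))
  expect_setequal(fam$codon[fam$family == "Leu1"], c("CTA", "CTC", "CTG", "CTT"))
  expect_setequal(fam$codon[fam$family == "Leu2"], c("TTA", "TTG"))
  expect_setequal(fam$codon[fam$family == "Ser1"], c("AGA", "AGC", "AGG", "AGT"))
  expect_setequal(fam$codon[fam$family == "Ser2"], c("TCA", "TCC", "TCG", "TCT"))
  expect_equal(fam$aa[fam$codon == "TGA"], "W")   # invertebrate mito code
  expect_equal(fam$aa[fam$codon == "ATA"], "M")
  expect_equal(unname(table(fam$family)["Phe"]), 2L)
})

test_that("codon extraction strips start plus complete or truncated stop", {
  one_gene <- function(seq, stop_codon) mitogenome(
    tibble::tibble(name = "g", category = "PCG", strand = "F",
                   start = 1, end = nchar(seq), start_codon = substr(seq, 1, 3),
                   stop_codon = stop_codon),
    length = nchar(seq), sequence = seq
  )
  cu <- codon_usage(one_gene("ATGAAATTTTAA", "TAA"))
  expect_equal(attr(cu, "total"), 2L)
  expect_equal(cu$count[cu$codon == "AAA"], 1L)
  expect_equal(cu$count[cu$codon == "TTT"], 1L)
  # 10 bp gene ending in truncated T: (10 - 3 - 1) / 3 = 2 codons
  cu2 <- codon_usage(one_gene("ATGAAATTTT", "T"))
  expect_equal(attr(cu2, "total"), 2L)
  # internal stop is flagged in QC and excluded from the sense table
  cu3 <- codon_usage(one_gene("ATGAAATAGTTTTAA", "TAA"))
  expect_equal(attr(cu3, "genes")$internal_stops, 1L)
  expect_equal(attr(cu3, "total"), sum(cu3$count))
  expect_equal(sum(cu3$count), 2L)
})

test_that("full codon table equals the generator's planted multiset", {
  sim <- simulate_mitogenome(genome_spec(seed = 7))
  cu <- codon_usage(sim$record)
  planted <- sim$ledger$codons$codon
  planted <- planted[!planted %in% c("TAA", "TAG")]
  exp_counts <- table(factor(planted, levels = cu$codon))
  expect_equal(cu$count, as.integer(exp_counts))
  expect_equal(attr(cu, "total"), length(planted))
})

test_that("per-thousand values normalise and RSCU averages one per family", {
  fam <- codon_families()
  fam$count <- 0L
  fam$count[fam$codon == "AAA"] <- 5L
  expect_equal(per_thousand(fam)$per_thousand[fam$codon == "AAA"], 1000)
  phe <- fam[fam$family == "Phe", ]
  phe$count <- c(1L, 3L)  # TTC, TTT
  r <- rscu(phe)
  expect_equal(sort(r$rscu), c(0.5, 1.5))

  sim <- simulate_mitogenome(genome_spec(seed = 10))
  cu <- codon_usage(sim$record)
  expect_equal(sum(cu$per_thousand), 1000, tolerance = 1e-9)
  sums <- cu |>
    dplyr::group_by(family) |>
    dplyr::summarise(total = sum(count), s = sum(rscu), deg = degeneracy[1])
  nz <- sums[sums$total > 0, ]
  expect_equal(nz$s, as.numeric(nz$deg))
  z <- sums[sums$total == 0, ]
  if (nrow(z) > 0) expect_true(all(is.na(z$s)))
  # equal counts within a family give RSCU 1 everywhere
  fam$count <- 2L
  expect_true(all(abs(rscu(fam)$rscu - 1) < 1e-12))
})

test_that("codon totals are invariant under rotation of the genome origin", {
  sim <- simulate_mitogenome(genome_spec(seed = 12))
  rec <- sim$record
  rot <- 4000L
  f <- rec$features
  f$start <- ((f$start - 1L + rot) %% rec$length) + 1L
  f$end <- ((f$end - 1L + rot) %% rec$length) + 1L
  for (col in c("anticodon_start", "anticodon_end")) {
    f[[col]] <- ((f[[col]] - 1L + rot) %% rec$length) + 1L
  }
  s <- strsplit(rec$sequence, "")[[1]]
  seq_rot <- paste(c(tail(s, rot), head(s, length(s) - rot)), collapse = "")
  rec2 <- mitogenome(f, length = rec$length, sequence = seq_rot)
  cu1 <- codon_usage(rec)
  cu2 <- codon_usage(rec2)
  expect_equal(cu2$count, cu1$count)
})

test_that("translation follows the invertebrate mitochondrial code", {
  expect_equal(translate_mt("ATAAGATGA", init_m = FALSE), "MSW")
  expect_equal(translate_mt("TTATTT", init_m = FALSE), "LF")
  expect_equal(translate_mt("CGAAAA"), "MK")   # nonstandard start reads M
  expect_equal(translate_mt("ATGNNATAA", init_m = FALSE), "MX*")
  expect_error(translate_mt("ATGA"), "multiple of 3")

  # planted CDS set agrees with an independent code-table lookup
  sim <- simulate_mitogenome(genome_spec(seed = 3))
  rec <- sim$record
  code <- Biostrings::getGeneticCode("5")
  f <- rec$features[rec$features$category == "PCG", ][1:4, ]
  for (i in seq_len(nrow(f))) {
    cds <- extract_feature_sequence(rec, f[i, ])
    cls <- classify_start_stop(cds)
    body <- substr(cds, 4, nchar(cds) - nchar(cls$stop_codon))
    got <- translate_mt(body, init_m = FALSE)
    cd <- substring(body, seq(1, nchar(body) - 2, 3), seq(3, nchar(body), 3))
    expect_equal(got, paste(unname(code[cd]), collapse = ""))
  }
})
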