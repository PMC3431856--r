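test_that("origin signature requires ATAGA plus a long enough T-run", {
  hit <- find_origin_signature(paste0("GCGC", "ATAGA", strrep("T", 19), "ACGT"))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$t_run, 19L)
  expect_equal(hit$start, 5L)
  expect_equal(hit$end, 9L + 19L)
  expect_equal(nrow(find_origin_signature(paste0("ATAGA", strrep("T", 5), "G"))), 0L)
  expect_equal(nrow(find_origin_signature("CCCCGGGGTTTTTTTTTTTT")), 0L)
  # the T-run may start within max_gap bases of the motif
  gap_hit <- find_origin_signature(paste0("ATAGA", "CA", strrep("T", 12)))
  expect_equal(gap_hit$gap, 2L)
})

test_that("microsatellites are maximal, canonical, and not sub-repeats", {
  ms <- find_microsatellites(paste0("GG", strrep("AT", 7), "GG"))
  expect_equal(nrow(ms), 1L)
  expect_equal(ms$unit, "AT")
  expect_equal(ms$copies, 7)
  expect_equal(c(ms$start, ms$end), c(3L, 16L))
  # TA run reports the minimal rotation AT
  expect_equal(find_microsatellites(paste0("G", strrep("TA", 6), "G"))$unit, "AT")
  expect_equal(nrow(find_microsatellites(strrep("AT", 4), min_copies = 5)), 0L)
  hom <- find_microsatellites(strrep("A", 12))
  expect_equal(hom$unit, "A")
  expect_equal(hom$copies, 12)
  # no ATAT-unit report over an (AT)n run at any unit size
  ms2 <- find_microsatellites(paste0("CC", strrep("AT", 10), "CC"))
  expect_true(all(ms2$period <= 2))
})

test_that("tandem detector finds planted 17-bp duplication and 8-bp
          decuplication with period, copies and identity", {
  set.seed(2)
  unit17 <- "ATTATAAATTTATAATA"
  copy2 <- unit17
  substr(copy2, 9, 9) <- "G"
  region <- paste0(rand_seq(30), "C", unit17, copy2, "C", rand_seq(30))
  tr <- find_tandem_repeats(region)
  hit <- tr[tr$period == 17, ]
  expect_equal(nrow(hit), 1L)
  expect_lte(hit$start, 32L)
  expect_gte(hit$end, 32 + 33L)
  expect_lt(hit$identity, 1)
  expect_gte(hit$copies, 2)

  sim <- simulate_mitogenome(genome_spec(seed = 1))
  region2 <- extract_feature_sequence(sim$record, "AT_rich")
  tr2 <- find_tandem_repeats(region2)
  plant <- sim$ledger$cr_plants
  p8 <- tr2[tr2$period == 8, ]
  expect_equal(nrow(p8), 1L)
  expect_equal(p8$consensus, "ATATTAAT")
  expect_gte(p8$copies, 9)
  expect_lte(abs(p8$start - plant$start[plant$kind == "tandem_8"]), 4)
  p17 <- tr2[tr2$period == 17, ]
  expect_equal(nrow(p17), 1L)
  expect_gte(p17$copies, 2)
})

test_that("tandem detections equal the exhaustive segment-enumeration oracle
          on random sequences", {
  set.seed(101)
  for (i in 1:10) {
    n <- sample(200:300, 1)
    region <- rand_seq(n)
    got <- find_tandem_repeats(region, dedup = FALSE)
    want <- oracle_tandem(region)
    got_key <- got[order(got$period, got$start),
                   c("period", "start", "end", "score")]
    expect_equal(as.data.frame(got_key), want, ignore_attr = TRUE)
  }
  # and on repeat-rich AT-biased sequences where hits are guaranteed
  for (i in 1:5) {
    region <- paste0(rand_seq(60, c(A = .4, T = .4, G = .1, C = .1)),
                     strrep("TTAGGA", sample(4:8, 1)),
                     rand_seq(60, c(A = .4, T = .4, G = .1, C = .1)))
    got <- find_tandem_repeats(region, dedup = FALSE)
    want <- oracle_tandem(region)
    got_key <- got[order(got$period, got$start),
                   c("period", "start", "end", "score")]
    expect_equal(as.data.frame(got_key), want, ignore_attr = TRUE)
    expect_gt(nrow(got), 0)
  }
})

test_that("stem-loop detector equals the exhaustive hairpin oracle and flags
          the TATA / G(A)nT flanks", {
  planted <- paste0("CCCCC", "TATA", "GCATCGAT", "TCTCTC", "ATCGATGC",
                    "GAAAAT", "CCCCC")
  sl <- find_stem_loops(planted)
  expect_equal(nrow(sl), 1L)
  expect_equal(sl$stem, 8L)
  expect_equal(sl$loop, 6L)
  expect_true(sl$tata_5prime)
  expect_true(sl$gaat_3prime)
  # best stem of 3 < min_stem of 5 yields nothing (A-only background
  # cannot pair, so only the planted GGG/CCC 3-stem exists)
  weak <- paste0("AAAAA", "GGG", "AAAA", "CCC", "AAAAA")
  expect_equal(nrow(find_stem_loops(weak)), 0L)

  set.seed(202)
  for (i in 1:15) {
    region <- rand_seq(sample(200:250, 1),
                       c(A = .3, T = .3, G = .2, C = .2))
    got <- find_stem_loops(region)
    want <- oracle_stem_loops(region)
    got_key <- as.data.frame(got[order(got$start, got$loop),
                                 c("start", "end", "stem", "loop")])
    want_key <- want[order(want$start, want$loop), ]
    expect_equal(got_key, want_key, ignore_attr = TRUE)
  }
})

test_that("detectors are position-covariant under a shift of the region", {
  set.seed(77)
  region <- paste0(rand_seq(40), "ATAGA", strrep("T", 15), rand_seq(40),
                   strrep("AT", 7), rand_seq(30))
  shift <- "GCGCGCGCGC"
  shifted <- paste0(shift, region)
  k <- nchar(shift)
  # hits touching the splice point may appear or vanish; every original
  # hit must reappear shifted by k
  o1 <- find_origin_signature(region); o2 <- find_origin_signature(shifted)
  expect_true(all((o1$start + k) %in% o2$start))
  m1 <- find_microsatellites(region); m2 <- find_microsatellites(shifted)
  expect_true(all((m1$start + k) %in% m2$start))
  t1 <- find_tandem_repeats(region, dedup = FALSE)
  t2 <- find_tandem_repeats(shifted, dedup = FALSE)
  expect_true(all(paste(t1$period, t1$start + k) %in%
                    paste(t2$period, t2$start)))
  s1 <- find_stem_loops(region); s2 <- find_stem_loops(shifted)
  s1_in <- s1[s1$start > 12, ]
  expect_true(all(paste(s1_in$start + k, s1_in$loop) %in%
                    paste(s2$start, s2$loop)))
})

test_that("fixed motifs report presence and absence at the named junctions", {
  with_plants <- simulate_mitogenome(
    genome_spec(seed = 21, plant_atactaa = TRUE, plant_poly_a = TRUE))
  m <- find_fixed_motifs(with_plants$record)
  expect_true(m$present[m$motif == "AAGCCTTA"])
  expect_true(m$present[m$motif == "ATACTAA"])
  expect_true(m$present[m$motif == "poly_A"])
  truth <- with_plants$ledger$motifs
  expect_equal(m$start[m$motif == "ATACTAA"],
               truth$start[truth$motif == "ATACTAA"])
  expect_equal(m$start[m$motif == "AAGCCTTA"],
               truth$start[truth$motif == "AAGCCTTA"])

  plain <- simulate_mitogenome(genome_spec(seed = 22))
  m2 <- find_fixed_motifs(plain$record)
  expect_true(m2$present[m2$motif == "AAGCCTTA"])
  expect_false(m2$present[m2$motif == "ATACTAA"])
  expect_false(m2$present[m2$motif == "poly_A"])

  norec <- mitogenome(tibble::tibble(name = "g", category = "rRNA",
                                     strand = "F", start = 1, end = 10),
                      length = 10, sequence = strrep("A", 10))
  expect_error(find_fixed_motifs(norec), "absent")
})

test_that("combined scan drops microsatellites doubled by a tandem report", {
  sim <- simulate_mitogenome(genome_spec(seed = 1))
  region <- extract_feature_sequence(sim$record, "AT_rich")
  combined <- scan_control_region(region)
  ms <- combined[combined$kind == "microsatellite", ]
  tr <- combined[combined$kind == "tandem_repeat", ]
  if (nrow(ms) > 0 && nrow(tr) > 0) {
    for (i in seq_len(nrow(ms))) {
      dup <- tr$period == ms$period[i] & tr$start <= ms$start[i] &
        tr$end >= ms$end[i]
      expect_false(any(dup & tr$score >= 2 * (ms$end[i] - ms$start[i] + 1 -
                                                ms$period[i])))
    }
  }
  expect_true(all(c("origin_signature", "tandem_repeat", "stem_loop") %in%
                    combined$kind))
})
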