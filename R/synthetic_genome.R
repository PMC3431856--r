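# Synthetic mitogenome generator. Given a gene-order template (default: the
# packaged S. inferens annotation), emits a full nucleotide sequence whose
# junction gaps reproduce the template exactly and whose regional base
# counts, interior codons, tRNA stem pairs and control-region structures are
# all recorded in a plant ledger, so every downstream module can be tested
# against ground truth.

# per-position sampling frequencies (A, T, G, C)
default_region_freqs <- function() {
  list(
    pcg_pos1 = c(A = 0.375, T = 0.502, G = 0.075, C = 0.048),
    pcg_pos2 = c(A = 0.295, T = 0.434, G = 0.090, C = 0.181),
    pcg_pos3 = c(A = 0.330, T = 0.422, G = 0.080, C = 0.168),
    rrna = c(A = 0.44, T = 0.40, G = 0.09, C = 0.07),
    spacer = c(A = 0.45, T = 0.45, G = 0.05, C = 0.05),
    control = c(A = 0.48, T = 0.48, G = 0.02, C = 0.02)
  )
}

#' Specification for a synthetic mitogenome
#'
#' The default emulates the S. inferens study conditions: the packaged
#' 38-feature annotation as gene-order template (hence its junction ledger),
#' AT-rich regional base frequencies with codon-position AT content near
#' 87.7/72.9/75.2%, an A+T-rich control region (~96% AT background;
#' ~92% AT over the whole region once the planted elements are in place)
#' carrying the
#' replication-origin signature (ATAGA + 19-bp poly-T), a TATA/G(A)nT-flanked
#' stem-loop, a duplicated 17-bp repeat, a decuplicated divergent 8-bp
#' repeat and an (AT)7 microsatellite, an AAGCCTTA motif in the trnW-trnC
#' overlap, and neither an ATACTAA motif in the trnS2-nad1 spacer nor a
#' poly-A run upstream of trnM.
#'
#' @param template A [mitogenome] (annotation only) providing gene order,
#'   strands, coordinates, anticodons and start/stop codons.
#' @param seed Integer seed; one stream drives every random choice.
#' @param freqs Region base-frequency list, see `default_region_freqs`.
#' @param trna_gu_rate,trna_mm_rate Per-pair probability of planting a G-U
#'   wobble (acceptor/anticodon stems) or a mismatch (acceptor stem only).
#' @param plant_aagcctta,plant_atactaa,plant_poly_a Fixed-motif switches.
#' @param plant_control Plant the control-region structures at all? `FALSE`
#'   gives a pure AT-rich background region.
#' @param cr_t_run Poly-T length of the origin signature (default 19).
#' @param cr_repeat17,cr_repeat8 Unit strings of the two planted tandem
#'   repeats.
#' @param cr_repeat8_copies Copy number of the 8-bp repeat (default 10).
#' @param cr_microsat_copies Copies of the (AT) microsatellite (default 7).
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(template = sesamia_annotation(), seed = 1,
                        freqs = default_region_freqs(),
                        trna_gu_rate = 0.04, trna_mm_rate = 0.025,
                        plant_aagcctta = TRUE, plant_atactaa = FALSE,
                        plant_poly_a = FALSE, plant_control = TRUE,
                        cr_t_run = 19,
                        cr_repeat17 = "ATTATAAATTTATAATA",
                        cr_repeat8 = "ATATTAAT",
                        cr_repeat8_copies = 10, cr_microsat_copies = 7) {
  structure(list(template = template, seed = seed, freqs = freqs,
                 trna_gu_rate = trna_gu_rate, trna_mm_rate = trna_mm_rate,
                 plant_aagcctta = plant_aagcctta, plant_atactaa = plant_atactaa,
                 plant_poly_a = plant_poly_a, plant_control = plant_control,
                 cr_t_run = cr_t_run,
                 cr_repeat17 = cr_repeat17, cr_repeat8 = cr_repeat8,
                 cr_repeat8_copies = cr_repeat8_copies,
                 cr_microsat_copies = cr_microsat_copies),
            class = "genome_spec")
}

COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G", N = "N")

sample_base <- function(n, freqs) {
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

# --- tRNA design ------------------------------------------------------------

# Solve the cloverleaf layout for a tRNA of length len with the anticodon at
# local position apos: DHU stem `dhu` (4, 3 or 0), TPsiC stem 3-6,
# discriminator 1 (0 as fallback). Returns arm positions or NULL.
solve_trna_layout <- function(len, apos, dhu = 4L) {
  U <- apos - 8L                      # room before the anticodon 5' stem
  W <- len - apos - 9L                # room after the anticodon 3' stem
  solve_up <- function() {
    for (d in unique(c(dhu, 3L, 0L))) {
      if (d == 0) return(list(d = 0L, s1 = U - 7L, ld = 0L))
      for (s1 in 1:3) for (s2 in 0:3) {
        ld <- U - 7L - 2L * d - s1 - s2
        if (ld >= 3 && ld <= 12) return(list(d = d, s1 = s1, s2 = s2, ld = ld))
      }
    }
    NULL
  }
  solve_dn <- function() {
    for (disc in c(1L, 0L)) for (k in c(4L, 5L, 3L, 6L)) for (lt in 3:12) {
      v <- W - 7L - disc - 2L * k - lt
      if (v >= 0 && v <= 23) return(list(disc = disc, k = k, lt = lt, v = v))
    }
    NULL
  }
  up <- solve_up()
  if (is.null(up) || (up$d == 0 && up$s1 < 0)) return(NULL)
  dn <- solve_dn()
  if (is.null(dn)) return(NULL)
  c(up, dn, list(len = len, apos = apos))
}

# sample one stem pair honouring pre-set bases; returns c(b5, b3, class)
plant_pair <- function(b5, b3, gu_rate, mm_rate, stem_base_freqs) {
  if (!is.na(b5) && !is.na(b3)) {
    return(c(b5, b3, unname(pair_class(b5, b3))))
  }
  if (is.na(b5) && !is.na(b3)) {
    return(c(unname(COMPLEMENT[b3]), b3, "WC"))
  }
  if (is.na(b5)) b5 <- sample_base(1, stem_base_freqs)
  if (!is.na(b3)) return(c(b5, b3, unname(pair_class(b5, b3))))
  u <- runif(1)
  if (u < mm_rate) {
    b3 <- switch(b5, A = "A", T = "T", G = "A", C = "T")
    cls <- "MM"
  } else if (u < mm_rate + gu_rate && b5 %in% c("G", "T")) {
    b3 <- if (b5 == "G") "T" else "G"
    cls <- "GU"
  } else {
    b3 <- unname(COMPLEMENT[b5])
    cls <- "WC"
  }
  c(b5, b3, cls)
}

#' Design a synthetic tRNA with a known cloverleaf structure
#'
#' Builds a tRNA sequence whose ground-truth structure is known by
#' construction: a 7-bp acceptor stem (AT-rich, optionally carrying planted
#' G-U and mismatch pairs), a fixed anticodon arm, and GC-armed DHU and
#' TPsiC stems surrounded by unpairable A-runs so the planted placement is
#' the unique score-optimal fold.
#'
#' @param len Length in nt (55-80).
#' @param apos Local position of the first anticodon base.
#' @param anticodon Anticodon triplet (default `"CAT"`).
#' @param dhu_stem Planted DHU stem length: 4, 3, or 0 for the trnS1-type
#'   missing arm.
#' @param gu_rate,mm_rate Planting rates for non-Watson-Crick pairs.
#' @param constraints Optional named character vector: local position ->
#'   fixed base (used when the tRNA overlaps already-written features).
#' @return List: `seq`, `apos`, `pairs` (tibble with planted pair classes),
#'   `layout`.
#' @export
synth_trna <- function(len, apos, anticodon = "CAT", dhu_stem = 4L,
                       gu_rate = 0.04, mm_rate = 0.025, constraints = NULL) {
  lay <- solve_trna_layout(len, apos, dhu_stem)
  if (is.null(lay)) abort(sprintf("no cloverleaf layout for len %d, anticodon at %d", len, apos))
  ch <- rep(NA_character_, len)
  if (!is.null(constraints)) {
    ch[as.integer(names(constraints))] <- unname(constraints)
  }
  stem_freqs <- c(A = 0.38, T = 0.40, G = 0.12, C = 0.10)
  pairs <- list()
  add_pairs <- function(pos5, pos3, arm, gu, mm) {
    for (i in seq_along(pos5)) {
      p <- plant_pair(ch[pos5[i]], ch[pos3[i]], gu, mm, stem_freqs)
      ch[pos5[i]] <<- p[1]; ch[pos3[i]] <<- p[2]
      pairs[[length(pairs) + 1]] <<- tibble(arm = arm, pos5 = pos5[i],
                                            pos3 = pos3[i], class = p[3])
    }
  }

  # anticodon arm (placement fixed by annotation)
  ac5 <- (apos - 7L):(apos - 3L)
  ac3 <- (apos + 9L):(apos + 5L)
  acod <- seq_chars(anticodon)
  for (i in 0:2) if (is.na(ch[apos + i])) ch[apos + i] <- acod[i + 1]
  # anticodon loop shoulders (positions apos-2, apos-1, apos+3, apos+4)
  for (p in c(apos - 2L, apos - 1L, apos + 3L, apos + 4L)) {
    if (is.na(ch[p])) ch[p] <- sample_base(1, c(A = 0.5, T = 0.5))
  }
  add_pairs(ac5, ac3, "anticodon", gu_rate, 0)

  # acceptor stem and discriminator; the discriminator must not pair with
  # position 1 (it would extend the stem) and the gene must not end in CCA
  # (a CCA tail would be trimmed before folding)
  acc3 <- (len - lay$disc):(len - lay$disc - 6L)
  add_pairs(1:7, acc3, "acceptor", gu_rate, mm_rate)
  if (lay$disc == 1 && is.na(ch[len])) {
    allowed <- switch(ch[1], A = c("A", "C"), T = c("T", "C"),
                      G = c("A", "G"), C = c("A", "C"))
    cand <- allowed[1]
    if (cand == "A" && identical(ch[len - 2], "C") &&
        identical(ch[len - 1], "C")) {
      cand <- allowed[allowed != "A"][1]
    }
    ch[len] <- cand
  }

  # DHU arm: GC stems, A loops (no alternative pairing in an A background)
  # unpaired spacers/loops are A-runs: A pairs with nothing among {A, G, C}
  # (and T would wobble-pair with the G of the GC arms), so the planted
  # placement of the free arms stays the unique score optimum
  fill_a <- function(pos) for (p in pos) if (is.na(ch[p])) ch[p] <<- "A"
  if (lay$d > 0) {
    dstart <- 7L + lay$s1 + 1L
    fill_a(span(8L, dstart - 1L))
    arm5 <- dstart:(dstart + lay$d - 1L)
    arm3 <- (dstart + 2L * lay$d + lay$ld - 1L):(dstart + lay$d + lay$ld)
    gc5 <- rep(c("G", "C"), length.out = lay$d)
    for (i in seq_along(arm5)) {
      p5 <- arm5[i]; p3 <- arm3[i]
      if (is.na(ch[p5]) && is.na(ch[p3])) {
        ch[p5] <- gc5[i]; ch[p3] <- unname(COMPLEMENT[gc5[i]])
      } else {
        p <- plant_pair(ch[p5], ch[p3], 0, 0, stem_freqs)
        ch[p5] <- p[1]; ch[p3] <- p[2]
      }
      pairs[[length(pairs) + 1]] <- tibble(arm = "DHU", pos5 = p5, pos3 = p3,
                                           class = unname(pair_class(ch[p5], ch[p3])))
    }
    fill_a(span(arm5[lay$d] + 1L, arm5[lay$d] + lay$ld))
    fill_a(span(arm3[1] + 1L, ac5[1] - 1L))
  } else {
    fill_a(span(8L, ac5[1] - 1L))
  }

  # TPsiC arm after the variable loop
  tstart <- apos + 10L + lay$v
  arm5 <- tstart:(tstart + lay$k - 1L)
  arm3 <- (tstart + 2L * lay$k + lay$lt - 1L):(tstart + lay$k + lay$lt)
  fill_a(span(apos + 10L, tstart - 1L))
  gc5 <- rep(c("G", "G", "C", "C"), length.out = lay$k)
  for (i in seq_along(arm5)) {
    p5 <- arm5[i]; p3 <- arm3[i]
    if (is.na(ch[p5]) && is.na(ch[p3])) {
      ch[p5] <- gc5[i]; ch[p3] <- unname(COMPLEMENT[gc5[i]])
    } else {
      p <- plant_pair(ch[p5], ch[p3], 0, 0, stem_freqs)
      ch[p5] <- p[1]; ch[p3] <- p[2]
    }
    pairs[[length(pairs) + 1]] <- tibble(arm = "TPsiC", pos5 = p5, pos3 = p3,
                                         class = unname(pair_class(ch[p5], ch[p3])))
  }
  fill_a(span(arm5[lay$k] + 1L, arm5[lay$k] + lay$lt))
  fill_a(which(is.na(ch)))

  pairs <- bind_rows(pairs)
  if (len >= 3 && collapse_chars(ch[(len - 2):len]) == "CCA") {
    # fallback for a constrained tail: re-pair the base at len - 2 as A:T so
    # the gene no longer ends in a trimmable CCA (class stays Watson-Crick)
    row <- which(pairs$pos3 == len - 2L)
    if (length(row) == 1 && pairs$class[row] == "WC") {
      ch[pairs$pos5[row]] <- "A"
      ch[len - 2L] <- "T"
    }
  }

  list(seq = collapse_chars(ch), apos = apos, pairs = pairs, layout = lay)
}

# --- control region ---------------------------------------------------------

mutate_copy <- function(unit, at, alt = 1) {
  ch <- seq_chars(unit)
  ch[at] <- setdiff(c("A", "T", "G", "C"), ch[at])[alt]
  collapse_chars(ch)
}

build_control_region <- function(spec, cr_len) {
  freqs <- spec$freqs$control
  plants <- list()
  parts <- character(0)
  pos <- 0L
  push <- function(s, kind = NA) {
    if (!is.na(kind)) {
      plants[[length(plants) + 1]] <<- tibble(kind = kind, start = pos + 1L,
                                              end = pos + nchar(s))
    }
    parts <<- c(parts, s)
    pos <<- pos + nchar(s)
  }
  filler <- function(n) if (n > 0) push(collapse_chars(sample_base(n, freqs)))

  if (!spec$plant_control) {
    filler(cr_len)
    return(list(seq = collapse_chars(parts), plants = bind_rows(plants)))
  }
  filler(5)
  push(paste0("ATAGA", strrep("T", spec$cr_t_run)), "origin_signature")
  push("A")                                       # terminates the T-run
  filler(8)
  stem <- "GCATCGAT"
  push(paste0("TATA", stem, "TCTCTC", revcomp(stem), "GAAAAT"), "stem_loop")
  filler(8)
  push("C")
  r17 <- paste0(spec$cr_repeat17, mutate_copy(spec$cr_repeat17, 9))
  push(r17, "tandem_17")
  push("C")
  # substitution positions and replacement bases vary irregularly from copy
  # to copy so the divergence itself is aperiodic (no harmonic outscores the
  # true period); first and last copies stay exact so the repeat spans fully
  u8 <- spec$cr_repeat8
  sub_pos <- c(3L, 5L, 4L, 7L, 6L, 3L, 5L, 4L, 7L, 6L)
  copies8 <- vapply(seq_len(spec$cr_repeat8_copies), function(i) {
    if (i == 1 || i == spec$cr_repeat8_copies) u8 else
      mutate_copy(u8, sub_pos[1 + (i - 1) %% length(sub_pos)],
                  alt = 1 + (i %% 2))
  }, character(1))
  push(collapse_chars(copies8), "tandem_8")
  push("C")
  push(strrep("AT", spec$cr_microsat_copies), "microsatellite_AT")
  push("C")
  # the poly-A element sits at the region's 3' end, i.e. directly upstream
  # of trnM on the circle
  tail_len <- if (spec$plant_poly_a) 12L else 0L
  remaining <- cr_len - pos - tail_len
  if (remaining < 0) abort("control-region plants exceed the region size")
  filler(remaining)
  if (spec$plant_poly_a) {
    push("C")
    push(strrep("A", 9), "poly_a")
    push("CT")
  }
  list(seq = collapse_chars(parts), plants = bind_rows(plants))
}

# --- the generator ----------------------------------------------------------

#' Simulate a mitogenome with fully known planted structure
#'
#' Deterministic given `spec$seed`. The output genome reproduces the
#' template's junction ledger exactly (coordinates are taken from the
#' template); protein-coding genes carry their assigned start/stop codons
#' and randomly sampled interior codons (stop codons avoided in frame);
#' tRNA genes are planted cloverleaves; rRNA, spacer and control-region
#' backgrounds are sampled i.i.d. from AT-rich frequencies; and the control
#' region carries the configured structural plants. Every planted quantity
#' is recorded in the returned ledger.
#'
#' @param spec A [genome_spec].
#' @return List with `record` (a [mitogenome] with sequence) and `ledger`
#'   (class `plant_ledger`).
#' @export
simulate_mitogenome <- function(spec = genome_spec()) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  tpl <- spec$template
  f <- tpl$features
  L <- tpl$length
  ch <- rep(NA_character_, L)

  put <- function(pos, bases) {
    conflict <- !is.na(ch[pos]) & ch[pos] != bases
    if (any(conflict)) {
      abort(sprintf("infeasible spec: conflicting base at position %d",
                    pos[which(conflict)[1]]))
    }
    ch[pos] <<- bases
  }
  # write `s` at genomic span in feature orientation
  put_oriented <- function(start, end, strand, s) {
    pos <- circular_positions(start, end, L)
    b <- seq_chars(s)
    if (strand == "R") { pos <- rev(pos); b <- unname(COMPLEMENT[b]) }
    put(pos, b)
  }

  # fixed motifs first: they constrain overlapping tRNAs
  motif_truth <- list()
  if (spec$plant_aagcctta) {
    i_c <- which(f$name == "trnC")
    put_oriented(f$start[i_c], f$start[i_c] + 7L, "F", "AAGCCTTA")
    motif_truth$aagcctta <- tibble(motif = "AAGCCTTA", start = f$start[i_c],
                                   end = f$start[i_c] + 7L)
  }
  if (spec$plant_atactaa) {
    i_u <- which(f$name == "trnS2"); i_d <- which(f$name == "nad1")
    at_start <- f$end[i_u] + 4L
    put_oriented(at_start, at_start + 6L, "F", "ATACTAA")
    motif_truth$atactaa <- tibble(motif = "ATACTAA", start = at_start,
                                  end = at_start + 6L)
  }

  # PCG start / stop codons
  pcg <- f[f$category == "PCG", ]
  for (i in seq_len(nrow(pcg))) {
    len_i <- feature_length(pcg$start[i], pcg$end[i], L)
    stop_i <- pcg$stop_codon[i]
    if (pcg$strand[i] == "F") {
      put_oriented(pcg$start[i], pcg$start[i] + 2L, "F", pcg$start_codon[i])
      put_oriented(pcg$end[i] - nchar(stop_i) + 1L, pcg$end[i], "F", stop_i)
    } else {
      put_oriented(pcg$end[i] - 2L, pcg$end[i], "R", pcg$start_codon[i])
      put_oriented(pcg$start[i], pcg$start[i] + nchar(stop_i) - 1L, "R", stop_i)
    }
  }

  # tRNAs: planted cloverleaves honouring already-written bases
  trna <- f[f$category == "tRNA", ]
  trna_pairs <- list()
  for (i in seq_len(nrow(trna))) {
    len_i <- feature_length(trna$start[i], trna$end[i], L)
    gpos <- circular_positions(trna$start[i], trna$end[i], L)
    if (trna$strand[i] == "R") gpos <- rev(gpos)
    fixed <- which(!is.na(ch[gpos]))
    cons <- NULL
    if (length(fixed) > 0) {
      vals <- ch[gpos[fixed]]
      if (trna$strand[i] == "R") vals <- unname(COMPLEMENT[vals])
      cons <- setNames(vals, fixed)
    }
    apos <- if (trna$strand[i] == "F") trna$anticodon_start[i] - trna$start[i] + 1L
            else trna$end[i] - trna$anticodon_end[i] + 1L
    dhu <- if (trna$name[i] == "trnS1") 0L else 4L
    tr <- synth_trna(len_i, as.integer(apos), trna$anticodon[i], dhu,
                     spec$trna_gu_rate, spec$trna_mm_rate, cons)
    put_oriented(trna$start[i], trna$end[i], trna$strand[i], tr$seq)
    trna_pairs[[trna$name[i]]] <- mutate(tr$pairs, gene = trna$name[i])
  }

  # PCG interiors, sampled codon-wise with per-position frequencies
  codon_rows <- list()
  base_mat <- rbind(spec$freqs$pcg_pos1, spec$freqs$pcg_pos2, spec$freqs$pcg_pos3)
  for (i in seq_len(nrow(pcg))) {
    len_i <- feature_length(pcg$start[i], pcg$end[i], L)
    stoplen <- nchar(pcg$stop_codon[i])
    n_codons <- (len_i - 3L - stoplen) %/% 3L
    gpos <- circular_positions(pcg$start[i], pcg$end[i], L)
    if (pcg$strand[i] == "R") gpos <- rev(gpos)
    codons <- character(n_codons)
    for (k in seq_len(n_codons)) {
      cpos <- gpos[(3 * k + 1):(3 * k + 3)]
      existing <- ch[cpos]
      if (pcg$strand[i] == "R") existing <- unname(COMPLEMENT[existing])
      bases <- existing
      free <- is.na(bases)
      for (p in which(free)) bases[p] <- sample_base(1, base_mat[p, ])
      cd <- collapse_chars(bases)
      if (cd %in% c("TAA", "TAG") && any(free)) {
        p <- max(which(free))
        bases[p] <- if (p == 3) "T" else "C"
        cd <- collapse_chars(bases)
      }
      towrite <- bases
      wpos <- cpos
      if (pcg$strand[i] == "R") towrite <- unname(COMPLEMENT[towrite])
      put(wpos, towrite)
      codons[k] <- cd
    }
    codon_rows[[pcg$name[i]]] <- tibble(gene = pcg$name[i], codon = codons)
  }

  # rRNAs
  rrna <- f[f$category == "rRNA", ]
  for (i in seq_len(nrow(rrna))) {
    gpos <- circular_positions(rrna$start[i], rrna$end[i], L)
    todo <- gpos[is.na(ch[gpos])]
    b <- sample_base(length(todo), spec$freqs$rrna)
    if (rrna$strand[i] == "R") b <- unname(COMPLEMENT[b])
    ch[todo] <- b
  }

  # control region
  ctrl <- f[f$category == "control", ]
  cr <- NULL
  if (nrow(ctrl) == 1) {
    cr_len <- feature_length(ctrl$start, ctrl$end, L)
    cr <- build_control_region(spec, cr_len)
    put_oriented(ctrl$start, ctrl$end, ctrl$strand, cr$seq)
  }

  # remaining spacer background
  todo <- which(is.na(ch))
  ch[todo] <- sample_base(length(todo), spec$freqs$spacer)

  seqstr <- collapse_chars(ch)
  rec <- mitogenome(f, length = L, id = sprintf("synthetic_%d", spec$seed),
                    sequence = seqstr)

  # --- ledger: direct bookkeeping of what was planted ---
  count_bases <- function(s) {
    cc <- seq_chars(s)
    tibble(a = sum(cc == "A"), t = sum(cc == "T"),
           g = sum(cc == "G"), c = sum(cc == "C"))
  }
  oriented_cat <- function(category) {
    ff <- f[f$category == category, ]
    paste(vapply(seq_len(nrow(ff)), function(i) {
      s <- collapse_chars(ch[circular_positions(ff$start[i], ff$end[i], L)])
      if (ff$strand[i] == "R") revcomp(s) else s
    }, character(1)), collapse = "")
  }
  base_counts <- bind_rows(
    whole_genome = count_bases(seqstr),
    PCGs = count_bases(oriented_cat("PCG")),
    tRNAs = count_bases(oriented_cat("tRNA")),
    rRNAs = count_bases(oriented_cat("rRNA")),
    control_region = count_bases(oriented_cat("control")),
    .id = "region"
  )
  codons <- bind_rows(codon_rows)
  cmat <- do.call(rbind, strsplit(codons$codon, "", fixed = TRUE))
  codon_pos <- purrr::map_dfr(1:3, function(p) {
    dplyr::bind_cols(tibble(position = p), count_bases(collapse_chars(cmat[, p])))
  })

  ledger <- structure(list(
    seed = spec$seed,
    genome_length = L,
    junction_gaps = junction_ledger(tpl),
    base_counts = base_counts,
    codons = codons,
    codon_position_counts = codon_pos,
    trna_pairs = bind_rows(trna_pairs),
    cr_plants = if (!is.null(cr)) cr$plants else tibble(),
    motifs = bind_rows(motif_truth),
    has_atactaa = isTRUE(spec$plant_atactaa),
    has_aagcctta = isTRUE(spec$plant_aagcctta),
    has_poly_a = isTRUE(spec$plant_poly_a)
  ), class = "plant_ledger")

  list(record = rec, ledger = ledger)
}

#' Simulate an amino-acid alignment on a tree
#'
#' Sites evolve independently under the 20-state equal-rates (Poisson)
#' model: on a branch of length `b` (expected substitutions per site) a site
#' changes with probability `(19/20) * (1 - exp(-20 b / 19))`, to a state
#' drawn uniformly from the other 19.
#'
#' @param tree A rooted or unrooted `phylo` with branch lengths.
#' @param columns Number of alignment columns.
#' @param seed Integer seed.
#' @return An [aa_alignment] over the tree's tip labels.
#' @export
simulate_alignment <- function(tree, columns, seed = 1) {
  stopifnot(!is.null(tree$edge.length))
  set.seed(seed)
  aas <- names(aa_bits())
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  states <- matrix(NA_character_, ntip + tree$Nnode, columns)
  states[root, ] <- sample(aas, columns, replace = TRUE)
  # preorder: parents before children
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[k, 1]; child <- ord$edge[k, 2]
    b <- ord$edge.length[k]
    p_change <- (19 / 20) * (1 - exp(-20 * b / 19))
    s <- states[parent, ]
    flip <- runif(columns) < p_change
    if (any(flip)) {
      s[flip] <- vapply(s[flip], function(cur)
        sample(setdiff(aas, cur), 1), character(1))
    }
    states[child, ] <- s
  }
  aa_alignment(setNames(apply(states[seq_len(ntip), , drop = FALSE], 1,
                              collapse_chars), tree$tip.label))
}
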