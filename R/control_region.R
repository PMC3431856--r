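# Structural scanners for the A+T-rich control region. All coordinates are
# 1-based closed and region-local (position 1 = first base of the supplied
# region string); find_fixed_motifs() works in genome coordinates.

#' Replication-origin signature: ATAGA motif followed by a poly-T stretch
#'
#' The light-strand replication origin of lepidopteran mitogenomes is marked
#' by the motif `ATAGA` followed by a long poly-T run. Each `ATAGA`
#' occurrence whose downstream T-run (starting within `max_gap` bases) is at
#' least `min_t_run` long is reported.
#'
#' @param region Nucleotide string (the control region).
#' @param min_t_run Minimum poly-T length (default 10; the S. inferens
#'   instance is 19 bp, the threshold admits shorter orthologs).
#' @param max_gap Maximum number of bases between the motif and the T-run.
#' @return Tibble: `kind`, `start`, `end` (motif start to T-run end),
#'   `t_run`, `gap`.
#' @export
find_origin_signature <- function(region, min_t_run = 10, max_gap = 5) {
  region <- check_nucleotides(region, "region")
  n <- nchar(region)
  ch <- seq_chars(region)
  hits <- gregexpr("ATAGA", region, fixed = TRUE)[[1]]
  out <- list()
  if (hits[1] != -1) {
    for (m in as.integer(hits)) {
      motif_end <- m + 4L
      cand <- motif_end + 1L + (0:max_gap)
      cand <- cand[cand <= n]
      p <- cand[which(ch[cand] == "T")[1]]
      if (is.na(p)) next
      run_end <- p
      while (run_end < n && ch[run_end + 1] == "T") run_end <- run_end + 1L
      t_run <- run_end - p + 1L
      if (t_run >= min_t_run) {
        out[[length(out) + 1]] <- tibble(kind = "origin_signature", start = m,
                                         end = run_end, t_run = t_run,
                                         gap = p - motif_end - 1L)
      }
    }
  }
  if (length(out) == 0) {
    tibble(kind = character(), start = integer(), end = integer(),
           t_run = integer(), gap = integer())
  } else bind_rows(out)
}

# lexicographically minimal rotation of a repeat unit
canonical_rotation <- function(unit) {
  u <- nchar(unit)
  if (u == 1) return(unit)
  rots <- vapply(seq_len(u), function(k)
    paste0(substr(unit, k, u), substr(unit, 1, k - 1)), character(1))
  sort(rots)[1]
}

# TRUE when unit is itself a repetition of a shorter unit
is_subrepeat <- function(unit) {
  u <- nchar(unit)
  if (u == 1) return(FALSE)
  divs <- which(u %% seq_len(u - 1) == 0)
  any(vapply(divs, function(p)
    strrep(substr(unit, 1, p), u / p) == unit, logical(1)))
}

#' Perfect microsatellite runs
#'
#' Maximal perfect tandem runs with unit length in `unit_range`. The unit is
#' reported in its lexicographically minimal rotation, and runs that are
#' sub-repeats of a smaller unit (e.g. `ATAT` over an `(AT)n` run) are
#' suppressed.
#'
#' @param region Nucleotide string.
#' @param unit_range Length-2 integer vector of unit sizes (default 1-6).
#' @param min_copies Minimum (fractional) copy number, default 5.
#' @return Tibble: `kind`, `start`, `end`, `unit`, `period`, `copies`.
#' @export
#' @examples
#' find_microsatellites(strrep("AT", 7), min_copies = 5)
find_microsatellites <- function(region, unit_range = c(1, 6), min_copies = 5) {
  region <- check_nucleotides(region, "region")
  ch <- seq_chars(region)
  n <- length(ch)
  out <- list()
  for (u in unit_range[1]:unit_range[2]) {
    if (n < 2 * u) next
    m <- ch[(u + 1):n] == ch[1:(n - u)]
    r <- rle(m)
    pos <- cumsum(c(1L, r$lengths))
    for (k in seq_along(r$lengths)) {
      if (!r$values[k]) next
      i <- pos[k]                       # first matching lag index
      span_start <- i
      span_end <- i + r$lengths[k] - 1L + u
      copies <- (span_end - span_start + 1) / u
      if (copies < min_copies) next
      unit <- collapse_chars(ch[span_start:(span_start + u - 1)])
      if (is_subrepeat(unit)) next
      out[[length(out) + 1]] <- tibble(
        kind = "microsatellite", start = span_start, end = span_end,
        unit = canonical_rotation(unit), period = u, copies = copies)
    }
  }
  if (length(out) == 0) {
    tibble(kind = character(), start = integer(), end = integer(),
           unit = character(), period = integer(), copies = numeric())
  } else bind_rows(out)
}

# Best-scoring segment of a numeric vector within [lo, hi], with the
# deterministic preference (score desc, start asc, end asc).
best_segment <- function(d, lo, hi) {
  best_score <- -Inf; best_start <- NA_integer_; best_end <- NA_integer_
  prefix <- 0
  min_prefix <- 0; min_prefix_idx <- lo - 1L
  for (j in lo:hi) {
    prefix <- prefix + d[j]
    score <- prefix - min_prefix
    if (score > best_score) {
      best_score <- score; best_start <- min_prefix_idx + 1L; best_end <- j
    }
    if (prefix < min_prefix) {
      min_prefix <- prefix; min_prefix_idx <- j
    }
  }
  list(score = best_score, start = best_start, end = best_end)
}

collect_segments <- function(d, lo, hi, min_score, acc) {
  if (lo > hi) return(acc)
  b <- best_segment(d, lo, hi)
  if (b$score < min_score) return(acc)
  acc[[length(acc) + 1]] <- b
  acc <- collect_segments(d, lo, b$start - 1L, min_score, acc)
  collect_segments(d, b$end + 1L, hi, min_score, acc)
}

tandem_consensus <- function(ch, start, end, p) {
  vapply(0:(p - 1), function(off) {
    col <- ch[seq(start + off, end, by = p)]
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[1]
  }, character(1)) |> collapse_chars()
}

#' Tandem repeat detection by self-alignment at every candidate period
#'
#' For each period `p` the region is scored against its own `p`-shift
#' (`match` for agreement, `mismatch` otherwise) and all disjoint maximal
#' scoring segments reaching `min_score` are reported, with fractional copy
#' number, column-majority consensus and percent identity. Reports at
#' different periods covering substantially the same span (harmonics) are
#' deduplicated, keeping the higher score.
#'
#' @param region Nucleotide string.
#' @param period_range Periods to scan, default 2-50.
#' @param match,mismatch,min_score Scoring parameters (defaults +2/-3/20).
#' @param dedup Deduplicate overlapping reports across periods? Default TRUE.
#' @return Tibble: `kind`, `start`, `end`, `period`, `copies`, `consensus`,
#'   `identity` (fraction), `score`.
#' @export
find_tandem_repeats <- function(region, period_range = c(2, 50),
                                match = 2, mismatch = -3, min_score = 20,
                                dedup = TRUE) {
  region <- check_nucleotides(region, "region")
  ch <- seq_chars(region)
  n <- length(ch)
  out <- list()
  pmax <- min(period_range[2], n %/% 2)
  if (period_range[1] <= pmax) {
    for (p in period_range[1]:pmax) {
      d <- ifelse(ch[(p + 1):n] == ch[1:(n - p)], match, mismatch)
      segs <- collect_segments(d, 1L, n - p, min_score, list())
      for (b in segs) {
        span_start <- b$start
        span_end <- b$end + p
        matches <- sum(ch[(b$start + p):(b$end + p)] == ch[b$start:b$end])
        out[[length(out) + 1]] <- tibble(
          kind = "tandem_repeat", start = span_start, end = span_end,
          period = p, copies = (span_end - span_start + 1) / p,
          consensus = tandem_consensus(ch, span_start, span_end, p),
          identity = matches / (b$end - b$start + 1),
          score = b$score)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(kind = character(), start = integer(), end = integer(),
                  period = integer(), copies = numeric(),
                  consensus = character(), identity = numeric(),
                  score = numeric()))
  }
  res <- bind_rows(out)
  if (dedup) res <- dedup_by_score(res)
  arrange(res, .data$start, .data$period)
}

# Greedy by score: drop a report whose span overlaps a better-scoring kept
# report by more than half of the shorter span.
dedup_by_score <- function(res) {
  res <- res[order(-res$score, res$start, res$period), ]
  keep <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    ok <- TRUE
    for (j in which(keep)) {
      ov <- min(res$end[i], res$end[j]) - max(res$start[i], res$start[j]) + 1
      shorter <- min(res$end[i] - res$start[i], res$end[j] - res$start[j]) + 1
      if (ov > shorter / 2) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  res[keep, ]
}

valid_pair <- function(a, b, allow_gu = TRUE) {
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  if (allow_gu) wc | (a == "G" & b == "T") | (a == "T" & b == "G") else wc
}

#' Hairpin (stem-loop) detection with flank motif annotation
#'
#' Enumerates all maximal bulge-free hairpins: a stem of at least `min_stem`
#' consecutive base pairs (Watson-Crick, plus G-U wobble when `allow_gu`)
#' around a loop whose length lies in `loop_range`. A hairpin is maximal when
#' the stem can be extended neither outward nor inward (inward extension
#' respecting the minimum loop). Each hit is annotated with the two flank
#' flags of the insect replication-initiation element: `tata_5prime` (a TATA
#' box within 10 nt upstream) and `gaat_3prime` (a `G(A)nT` run, 1-8 As,
#' within 10 nt downstream).
#'
#' @param region Nucleotide string.
#' @param min_stem Minimum stem length in bp (default 5).
#' @param loop_range Loop length range in nt (default 3-20).
#' @param allow_gu Allow G-U wobble pairs in the stem (default TRUE).
#' @return Tibble: `kind`, `start`, `end`, `stem`, `loop`,
#'   `tata_5prime`, `gaat_3prime`.
#' @export
find_stem_loops <- function(region, min_stem = 5, loop_range = c(3, 20),
                            allow_gu = TRUE) {
  region <- check_nucleotides(region, "region")
  ch <- seq_chars(region)
  n <- length(ch)
  out <- list()
  for (ls in 2:max(2, n - loop_range[1])) {         # loop start
    for (q in loop_range[1]:loop_range[2]) {
      a <- ls - 1L; b <- ls + q                      # innermost pair
      if (b > n) break
      if (!valid_pair(ch[a], ch[b], allow_gu)) next
      s <- 1L
      while (a - s >= 1 && b + s <= n && valid_pair(ch[a - s], ch[b + s], allow_gu)) {
        s <- s + 1L
      }
      # outward-maximal by construction of s; require inward-maximal too
      inward_ok <- q - 2 < loop_range[1] ||
        !valid_pair(ch[a + 1], ch[b - 1], allow_gu)
      if (s < min_stem || !inward_ok) next
      start <- a - s + 1L; end <- b + s - 1L
      up <- if (start > 1) collapse_chars(ch[max(1, start - 10):(start - 1)]) else ""
      dn <- if (end < n) collapse_chars(ch[(end + 1):min(n, end + 10)]) else ""
      out[[length(out) + 1]] <- tibble(
        kind = "stem_loop", start = start, end = end, stem = s, loop = q,
        tata_5prime = grepl("TATA", up, fixed = TRUE),
        gaat_3prime = grepl("GA{1,8}T", dn))
    }
  }
  if (length(out) == 0) {
    tibble(kind = character(), start = integer(), end = integer(),
           stem = integer(), loop = integer(),
           tata_5prime = logical(), gaat_3prime = logical())
  } else dplyr::distinct(bind_rows(out))
}

junction_window <- function(rec, up_name, down_name, pad = 20) {
  f <- rec$features
  iu <- which(f$name == up_name); id <- which(f$name == down_name)
  if (length(iu) == 0 || length(id) == 0) {
    abort(sprintf("junction %s-%s absent from the annotation", up_name, down_name))
  }
  lo <- max(1L, min(f$end[iu], f$start[id]) - pad)
  hi <- min(rec$length, max(f$end[iu], f$start[id]) + pad)
  list(lo = lo, hi = hi,
       seq = collapse_chars(seq_chars(rec$sequence)[lo:hi]))
}

#' Diagnostic fixed motifs at named junctions of the lepidopteran mitogenome
#'
#' Presence/absence report, in genome coordinates, for three conserved
#' elements: the `ATACTAA` motif in the trnS2-nad1 spacer, the 8-bp
#' `AAGCCTTA` motif in the trnW-trnC junction neighbourhood (+/- 20 nt), and
#' a poly-A run of at least 9 nt in the 30 nt upstream of trnM.
#'
#' @param rec A [mitogenome] with sequence.
#' @return Tibble: `motif`, `junction`, `present`, `start`, `end`
#'   (genome coordinates; NA when absent).
#' @export
find_fixed_motifs <- function(rec) {
  stopifnot(inherits(rec, "mitogenome"))
  if (is.null(rec$sequence)) abort("sequence required for motif search")
  f <- rec$features
  rows <- list()

  # ATACTAA in the trnS2-nad1 spacer
  iu <- which(f$name == "trnS2"); id <- which(f$name == "nad1")
  if (length(iu) == 0 || length(id) == 0) {
    abort("junction trnS2-nad1 absent from the annotation")
  }
  lo <- f$end[iu] + 1L; hi <- f$start[id] - 1L
  spacer <- if (hi >= lo) collapse_chars(seq_chars(rec$sequence)[lo:hi]) else ""
  m <- regexpr("ATACTAA", spacer, fixed = TRUE)
  rows$atactaa <- tibble(
    motif = "ATACTAA", junction = "trnS2-nad1", present = m[1] != -1,
    start = if (m[1] != -1) lo + m[1] - 1L else NA_integer_,
    end = if (m[1] != -1) lo + m[1] + 5L else NA_integer_)

  # AAGCCTTA around the trnW-trnC junction
  w <- junction_window(rec, "trnW", "trnC", pad = 20)
  m <- regexpr("AAGCCTTA", w$seq, fixed = TRUE)
  rows$aagcctta <- tibble(
    motif = "AAGCCTTA", junction = "trnW-trnC", present = m[1] != -1,
    start = if (m[1] != -1) w$lo + m[1] - 1L else NA_integer_,
    end = if (m[1] != -1) w$lo + m[1] + 6L else NA_integer_)

  # poly-A (>= 9) in the 30 nt upstream of trnM, on the circle
  im <- which(f$name == "trnM")
  if (length(im) == 0) abort("junction rrnS-trnM absent from the annotation (no trnM)")
  ch <- seq_chars(rec$sequence)
  upstream_pos <- ((f$start[im] - 30 - 1 + rec$length) %% rec$length) + 1
  pos <- circular_positions(upstream_pos,
                            ((f$start[im] - 2 + rec$length) %% rec$length) + 1,
                            rec$length)
  up <- collapse_chars(ch[pos])
  m <- regexpr("A{9,}", up)
  rows$poly_a <- tibble(
    motif = "poly_A", junction = "upstream-trnM", present = m[1] != -1,
    start = if (m[1] != -1) pos[m[1]] else NA_integer_,
    end = if (m[1] != -1) pos[m[1] + attr(m, "match.length") - 1L] else NA_integer_)

  bind_rows(rows)
}

#' Scan a control region with every structural detector
#'
#' Runs the origin-signature, microsatellite, tandem-repeat and stem-loop
#' detectors and binds their annotations. Microsatellite reports whose span
#' is covered by a higher-scoring tandem report at the same period are
#' dropped (they are the same repeat seen twice).
#'
#' @param region Nucleotide string (control region).
#' @param ... Passed through to the individual detectors.
#' @return Tibble of annotations; kind-specific columns are NA elsewhere.
#' @export
scan_control_region <- function(region, ...) {
  args <- list(...)
  call_with <- function(fn, allowed) {
    do.call(fn, c(list(region), args[names(args) %in% allowed]))
  }
  org <- call_with(find_origin_signature, c("min_t_run", "max_gap"))
  ms <- call_with(find_microsatellites, c("unit_range", "min_copies"))
  tr <- call_with(find_tandem_repeats,
                  c("period_range", "match", "mismatch", "min_score", "dedup"))
  sl <- call_with(find_stem_loops, c("min_stem", "loop_range", "allow_gu"))
  if (nrow(ms) > 0 && nrow(tr) > 0) {
    drop <- vapply(seq_len(nrow(ms)), function(i) {
      any(tr$period == ms$period[i] & tr$start <= ms$start[i] &
            tr$end >= ms$end[i] &
            tr$score >= 2 * (ms$end[i] - ms$start[i] + 1 - ms$period[i]))
    }, logical(1))
    ms <- ms[!drop, ]
  }
  bind_rows(org, ms, tr, sl) |> arrange(.data$start, .data$kind)
}
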