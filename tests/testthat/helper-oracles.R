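# Independent brute-force oracles used to validate the detectors and the
# cloverleaf folder. These deliberately use naive enumeration and their own
# scoring code, not the package's search routines.

rand_seq <- function(n, freqs = c(A = .25, T = .25, G = .25, C = .25)) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

# exhaustive tandem-repeat scan: for each period, enumerate every (start,
# end) segment of the lag profile via cumulative sums, then select segments
# greedily (max score, min start, min end) subject to disjointness
oracle_tandem <- function(region, period_range = c(2, 50), match = 2,
                          mismatch = -3, min_score = 20) {
  ch <- strsplit(region, "")[[1]]
  n <- length(ch)
  out <- list()
  for (p in period_range[1]:min(period_range[2], n %/% 2)) {
    d <- ifelse(ch[seq_len(n - p) + p] == ch[seq_len(n - p)], match, mismatch)
    cs <- c(0, cumsum(d))
    len <- length(d)
    segs <- expand.grid(i = seq_len(len), j = seq_len(len))
    segs <- segs[segs$i <= segs$j, ]
    segs$score <- cs[segs$j + 1] - cs[segs$i]
    segs <- segs[segs$score >= min_score, ]
    segs <- segs[order(-segs$score, segs$i, segs$j), ]
    taken <- logical(len)
    while (nrow(segs) > 0) {
      b <- segs[1, ]
      out[[length(out) + 1]] <- data.frame(period = p, start = b$i,
                                           end = b$j + p, score = b$score)
      taken[b$i:b$j] <- TRUE
      keep <- vapply(seq_len(nrow(segs)), function(r)
        !any(taken[segs$i[r]:segs$j[r]]), logical(1))
      segs <- segs[keep, , drop = FALSE]
    }
  }
  if (length(out) == 0) {
    return(data.frame(period = integer(), start = integer(),
                      end = integer(), score = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$period, res$start), ]
}

oracle_pair_ok <- function(a, b, allow_gu) {
  ok <- paste0(a, b) %in% c("AT", "TA", "GC", "CG")
  if (allow_gu) ok <- ok || paste0(a, b) %in% c("GT", "TG")
  ok
}

# exhaustive hairpin enumeration over every (outer 5' position, outer 3'
# position) pair: for each, the stem deepens inward pair by pair, so every
# (start, stem, loop) triple is visited via its nested validity prefix
oracle_stem_loops <- function(region, min_stem = 5, loop_range = c(3, 20),
                              allow_gu = TRUE) {
  ch <- strsplit(region, "")[[1]]
  n <- length(ch)
  pairmat <- outer(ch, ch, function(a, b) {
    p <- paste0(a, b)
    ok <- p %in% c("AT", "TA", "GC", "CG")
    if (allow_gu) ok <- ok | p %in% c("GT", "TG")
    ok
  })
  hits <- list()
  min_span <- 2 * min_stem + loop_range[1]
  for (i in seq_len(n)) {
    if (i + min_span - 1 > n) break
    for (jend in (i + min_span - 1):n) {
      span <- jend - i + 1
      kmax <- (span - 1) %/% 2
      m <- 0
      while (m < kmax && pairmat[i + m, jend - m]) m <- m + 1
      if (m < min_stem) next
      for (s in as.integer(min_stem:m)) {
        q <- span - 2L * s
        if (q < loop_range[1] || q > loop_range[2]) next
        outward_blocked <- i == 1 || jend == n || !pairmat[i - 1, jend + 1]
        inward_blocked <- (q - 2) < loop_range[1] || s == m
        if (outward_blocked && inward_blocked) {
          hits[[length(hits) + 1]] <- data.frame(start = i, end = jend,
                                                 stem = s, loop = q)
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      stem = integer(), loop = integer()))
  }
  unique(do.call(rbind, hits))
}

oracle_pair_score <- function(a, b) {
  p <- paste0(a, b)
  if (p %in% c("AT", "TA", "GC", "CG")) 2
  else if (p %in% c("GT", "TG")) 1
  else -1
}

# exhaustive arm-placement search for the cloverleaf score: enumerates every
# discriminator choice and every legal (start, stem, loop) placement of the
# DHU and TPsiC arms, scoring each candidate pair-by-pair from scratch
oracle_fold_score <- function(seq, apos) {
  if (endsWith(seq, "CCA")) seq <- substr(seq, 1, nchar(seq) - 3)
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  ac5 <- (apos - 7):(apos - 3)
  ac3 <- (apos + 5):(apos + 9)
  arm_candidates <- function(lo, hi, stems, max_lead = Inf) {
    scores <- 0                            # absent arm
    if (hi - lo + 1 > 0) {
      for (st in lo:hi) {
        if (st - lo > max_lead) break
        for (k in stems) for (l in 3:12) {
          last <- st + 2 * k + l - 1
          if (last > hi) next
          sc <- sum(vapply(seq_len(k), function(x)
            oracle_pair_score(ch[st + x - 1], ch[last - x + 1]), numeric(1)))
          scores <- c(scores, sc)
        }
      }
    }
    max(scores)
  }
  best <- -Inf
  for (d in c(0, 1)) {
    acc3 <- (L - d):(L - d - 6)
    if (ac3[5] > acc3[7] - 1) next
    acc <- sum(vapply(1:7, function(i)
      oracle_pair_score(ch[i], ch[acc3[i]]), numeric(1)))
    acs <- sum(vapply(1:5, function(i)
      oracle_pair_score(ch[ac5[i]], ch[rev(ac3)[i]]), numeric(1)))
    tot <- acc + acs +
      arm_candidates(8, ac5[1] - 1, 1:4) +
      arm_candidates(ac3[5] + 1, acc3[7] - 1, 1:6, max_lead = 23)
    best <- max(best, tot)
  }
  best
}

# joint (non-decomposed) enumeration over both free arms simultaneously;
# slow, used on a few instances to validate the per-arm decomposition
oracle_fold_score_joint <- function(seq, apos) {
  if (endsWith(seq, "CCA")) seq <- substr(seq, 1, nchar(seq) - 3)
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  ac5 <- (apos - 7):(apos - 3)
  ac3 <- (apos + 5):(apos + 9)
  placements <- function(lo, hi, stems, max_lead = Inf) {
    out <- list(NULL)                       # NULL = absent arm
    if (hi - lo + 1 > 0) {
      for (st in lo:hi) {
        if (st - lo > max_lead) break
        for (k in stems) for (l in 3:12) {
          if (st + 2 * k + l - 1 > hi) next
          out[[length(out) + 1]] <- c(st = st, k = k, l = l)
        }
      }
    }
    out
  }
  arm_pairs <- function(pl) {
    if (is.null(pl)) return(NULL)
    last <- pl["st"] + 2 * pl["k"] + pl["l"] - 1
    cbind(pl["st"] + seq_len(pl["k"]) - 1, last - seq_len(pl["k"]) + 1)
  }
  best <- -Inf
  for (d in c(0, 1)) {
    acc3 <- (L - d):(L - d - 6)
    if (ac3[5] > acc3[7] - 1) next
    fixed <- rbind(cbind(1:7, acc3), cbind(ac5, rev(ac3)))
    for (dp in placements(8, ac5[1] - 1, 1:4)) {
      for (tp in placements(ac3[5] + 1, acc3[7] - 1, 1:6, max_lead = 23)) {
        prs <- rbind(fixed, arm_pairs(dp), arm_pairs(tp))
        sc <- sum(vapply(seq_len(nrow(prs)), function(r)
          oracle_pair_score(ch[prs[r, 1]], ch[prs[r, 2]]), numeric(1)))
        best <- max(best, sc)
      }
    }
  }
  best
}

circular_positions_for_test <- function(i, j, L) {
  if (j >= i) i:j else c(i:L, 1:j)
}
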