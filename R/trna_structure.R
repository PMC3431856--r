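# Constrained cloverleaf folding of annotated mitochondrial tRNAs.
#
# The cloverleaf is modelled with fixed topology: a 7-bp acceptor stem pairing
# positions 1..7 against the 3' end (behind an optional 1-nt discriminator),
# a DHU arm of 0-4 bp (0 = the trnS1-type missing arm), the anticodon arm
# fixed by the annotated anticodon (5-bp stem, 7-nt loop with the anticodon
# at loop positions 3-5), and a TPsiC arm of 0-6 bp, with a variable loop of
# up to 23 nt before it. Pair scores: Watson-Crick +2, G-U wobble +1,
# mismatch -1. Arms occupy disjoint sequence intervals, so each arm placement
# is optimised independently; ties prefer a longer DHU stem, then a longer
# TPsiC stem, then a present discriminator, then the leftmost arm placement.

PAIR_WC <- c("AT", "TA", "GC", "CG")
PAIR_GU <- c("GT", "TG")

pair_class <- function(b5, b3) {
  p <- paste0(b5, b3)
  ifelse(p %in% PAIR_WC, "WC", ifelse(p %in% PAIR_GU, "GU", "MM"))
}

pair_score_of <- function(cls) c(WC = 2, GU = 1, MM = -1)[cls]

# score + pair table for a stem pairing pos5 (ascending) with pos3 (descending)
stem_pairs <- function(ch, pos5, pos3, arm) {
  cls <- pair_class(ch[pos5], ch[pos3])
  tibble(arm = arm, pos5 = pos5, pos3 = pos3,
         base5 = ch[pos5], base3 = ch[pos3], class = unname(cls))
}

# Best arm placement within region [lo, hi]: stem k in stem_range (k = 0
# allowed, meaning no arm), loop in loop_range, any leading offset. Leading
# offsets beyond max_lead are disallowed (used for the variable loop bound).
best_arm <- function(ch, lo, hi, stem_range, loop_range = c(3, 12),
                     max_lead = Inf) {
  width <- hi - lo + 1
  best <- list(score = 0, k = 0L, start = NA_integer_, loop = NA_integer_)
  if (width <= 0) return(best)
  for (k in stem_range[stem_range > 0]) {
    for (l in loop_range[1]:loop_range[2]) {
      span <- 2 * k + l
      if (span > width) next
      for (st in lo:(hi - span + 1)) {
        if (st - lo > max_lead) break
        pos5 <- st:(st + k - 1)
        pos3 <- (st + k + l + k - 1):(st + k + l)
        cls <- pair_class(ch[pos5], ch[pos3])
        sc <- sum(pair_score_of(cls))
        better <- sc > best$score ||
          (sc == best$score && (k > best$k ||
             (k == best$k && (is.na(best$start) || st < best$start))))
        if (better) best <- list(score = sc, k = k, start = st, loop = l)
      }
    }
  }
  best
}

#' Fold an annotated tRNA into its cloverleaf structure
#'
#' Among all arm placements satisfying the cloverleaf constraints, returns
#' the one maximising `2*WC + 1*GU - 1*MM` over all stem pairs. The anticodon
#' arm is anchored by the annotated anticodon; the acceptor stem pairs
#' positions 1..7 against the 3' end, with or without a 1-nt discriminator;
#' DHU (0-4 bp) and TPsiC (0-6 bp) arms are optimised within the intervals
#' between the fixed arms. A DHU stem of length 0 encodes the trnS1-type
#' missing DHU arm. A trailing CCA is trimmed before folding.
#'
#' @param seq tRNA nucleotide string, 55-80 nt.
#' @param anticodon_pos 1-based position of the first anticodon base within
#'   `seq`.
#' @return An object of class `cloverleaf`: list with `seq`, `score`,
#'   `arms` (tibble: arm, stem length, loop length, positions), `pairs`
#'   (tibble with per-pair classification), `discriminator` (0 or 1) and
#'   `dot_bracket`.
#' @export
fold_cloverleaf <- function(seq, anticodon_pos) {
  seq <- check_nucleotides(seq, "tRNA sequence")
  if (endsWith(seq, "CCA")) seq <- substr(seq, 1, nchar(seq) - 3)
  L <- nchar(seq)
  if (L < 55 || L > 80) abort(sprintf("tRNA length %d outside the supported 55-80 nt", L))
  if (anticodon_pos < 1 || anticodon_pos + 2 > L) abort("anticodon outside the sequence")
  ch <- seq_chars(seq)

  ac_loop_start <- anticodon_pos - 2L
  ac_loop_end <- anticodon_pos + 4L
  ac5 <- (ac_loop_start - 5L):(ac_loop_start - 1L)
  ac3 <- (ac_loop_end + 1L):(ac_loop_end + 5L)
  if (ac5[1] < 8 || ac3[5] > L - 7) {
    abort("no placement satisfies constraints: anticodon too close to the ends")
  }

  best <- NULL
  for (d in c(1L, 0L)) {
    acc3 <- (L - d):(L - d - 6L)            # pairs with 1..7, descending
    if (ac3[5] > acc3[7] - 1) next
    acc_tbl <- stem_pairs(ch, 1:7, acc3, "acceptor")
    acc_score <- sum(pair_score_of(acc_tbl$class))
    dhu <- best_arm(ch, 8L, ac5[1] - 1L, 0:4)
    tpc <- best_arm(ch, ac3[5] + 1L, acc3[7] - 1L, 0:6, max_lead = 23)
    ac_tbl <- stem_pairs(ch, ac5, rev(ac3), "anticodon")
    total <- acc_score + dhu$score + sum(pair_score_of(ac_tbl$class)) + tpc$score
    cand <- list(d = d, total = total, dhu = dhu, tpc = tpc,
                 acc_tbl = acc_tbl, ac_tbl = ac_tbl)
    if (is.null(best) || cand$total > best$total ||
        (cand$total == best$total &&
           (cand$dhu$k > best$dhu$k ||
              (cand$dhu$k == best$dhu$k && cand$tpc$k > best$tpc$k)))) {
      best <- cand
    }
  }
  if (is.null(best)) abort("no placement satisfies constraints")

  arm_tbl <- function(b, arm) {
    if (b$k == 0) {
      return(tibble(arm = arm, stem = 0L, loop = NA_integer_,
                    start5 = NA_integer_, start3 = NA_integer_))
    }
    tibble(arm = arm, stem = as.integer(b$k), loop = as.integer(b$loop),
           start5 = as.integer(b$start),
           start3 = as.integer(b$start + b$k + b$loop))
  }
  pairs <- best$acc_tbl
  if (best$dhu$k > 0) {
    b <- best$dhu
    pairs <- bind_rows(pairs, stem_pairs(
      ch, b$start:(b$start + b$k - 1),
      (b$start + 2 * b$k + b$loop - 1):(b$start + b$k + b$loop), "DHU"))
  }
  pairs <- bind_rows(pairs, best$ac_tbl)
  if (best$tpc$k > 0) {
    b <- best$tpc
    pairs <- bind_rows(pairs, stem_pairs(
      ch, b$start:(b$start + b$k - 1),
      (b$start + 2 * b$k + b$loop - 1):(b$start + b$k + b$loop), "TPsiC"))
  }

  arms <- bind_rows(
    tibble(arm = "acceptor", stem = 7L, loop = NA_integer_,
           start5 = 1L, start3 = as.integer(L - best$d - 6L)),
    arm_tbl(best$dhu, "DHU"),
    tibble(arm = "anticodon", stem = 5L, loop = 7L,
           start5 = ac5[1], start3 = ac3[1]),
    arm_tbl(best$tpc, "TPsiC")
  )

  db <- rep(".", L)
  db[pairs$pos5] <- "("
  db[pairs$pos3] <- ")"

  structure(
    list(seq = seq, score = unname(best$total), arms = arms, pairs = pairs,
         discriminator = best$d, anticodon_pos = as.integer(anticodon_pos),
         dot_bracket = collapse_chars(db)),
    class = "cloverleaf"
  )
}

#' @export
print.cloverleaf <- function(x, ...) {
  counts <- classify_pairs(x)
  cat(sprintf("<cloverleaf> %d nt, score %d; WC %d, GU %d, MM %d\n",
              nchar(x$seq), x$score, counts$wc, counts$gu, counts$mm))
  cat(" ", x$seq, "\n ", x$dot_bracket, "\n")
  invisible(x)
}

#' Count pair classes of a folded cloverleaf
#'
#' Watson-Crick (A-U/U-A/G-C/C-G), G-U wobble and mismatch counts over all
#' stem pairs. "Unmatched" pairs in the sense used for mitogenome tRNA
#' descriptions are `gu + mm`.
#'
#' @param struct A `cloverleaf` from [fold_cloverleaf()], or its `pairs`
#'   tibble.
#' @return One-row tibble: `wc`, `gu`, `mm`, `unmatched`, `total`.
#' @export
classify_pairs <- function(struct) {
  pairs <- if (inherits(struct, "cloverleaf")) struct$pairs else struct
  cls <- pairs$class
  tibble(wc = sum(cls == "WC"), gu = sum(cls == "GU"), mm = sum(cls == "MM"),
         unmatched = sum(cls != "WC"), total = length(cls))
}

#' @method tidy cloverleaf
#' @export
tidy.cloverleaf <- function(x, ...) x$pairs

#' @method glance cloverleaf
#' @export
glance.cloverleaf <- function(x, ...) {
  counts <- classify_pairs(x)
  dhu <- x$arms$stem[x$arms$arm == "DHU"]
  tpc <- x$arms$stem[x$arms$arm == "TPsiC"]
  tibble(length = nchar(x$seq), score = x$score,
         dhu_stem = dhu, tpsic_stem = tpc,
         discriminator = x$discriminator,
         wc = counts$wc, gu = counts$gu, mm = counts$mm)
}

#' Cloverleaf summaries for every annotated tRNA of a genome
#'
#' @param rec A [mitogenome] with sequence.
#' @return Tibble: one row per tRNA gene with arm lengths and pair-class
#'   counts; folded structures in attribute `"structures"`.
#' @export
trna_structure_report <- function(rec) {
  stopifnot(inherits(rec, "mitogenome"))
  if (is.null(rec$sequence)) abort("sequence required for tRNA folding")
  f <- rec$features[rec$features$category == "tRNA", ]
  structs <- list()
  rows <- purrr::map_dfr(seq_len(nrow(f)), function(i) {
    s <- extract_feature_sequence(rec, f[i, ])
    # anticodon position in coding orientation
    acs <- f$anticodon_start[i]; ace <- f$anticodon_end[i]
    apos <- if (f$strand[i] == "F") acs - f$start[i] + 1L else f$end[i] - ace + 1L
    st <- fold_cloverleaf(s, apos)
    structs[[f$name[i]]] <<- st
    dplyr::bind_cols(tibble(gene = f$name[i]), glance(st))
  })
  structure(rows, structures = structs)
}
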