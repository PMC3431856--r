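#' Junction ledger: intergenic spacers and overlaps around the circle
#'
#' For consecutive features sorted by start position, the signed gap is
#' `start(next) - end(this) - 1`; the ledger closes the circle with the
#' junction from the last feature back to the first. Positive gaps are
#' intergenic spacers, negative gaps overlaps, zero gaps abutting genes.
#' A feature fully nested inside another breaks the circular length identity
#' and is reported as an error.
#'
#' @param rec A [mitogenome] with at least one feature.
#' @return A tibble with columns `upstream`, `downstream`, `gap`, `class`
#'   (`"spacer"`, `"overlap"`, `"abutting"`), one row per junction (so
#'   `nrow` equals the number of features).
#' @export
#' @examples
#' junction_ledger(sesamia_annotation())
junction_ledger <- function(rec) {
  stopifnot(inherits(rec, "mitogenome"))
  f <- rec$features
  if (nrow(f) == 0) abort("junction ledger requires at least one feature")
  L <- rec$length
  n <- nrow(f)
  # effective linear end; a feature wrapping the origin extends past L
  end_eff <- ifelse(f$end >= f$start, f$end, f$end + L)
  if (n > 1) {
    nested <- which(end_eff[-n] >= end_eff[-1] & f$start[-n] <= f$start[-1])
    if (length(nested) > 0) {
      i <- nested[1]
      abort(sprintf("feature '%s' is nested inside '%s'; the junction ledger is undefined",
                    f$name[i + 1], f$name[i]))
    }
  }
  nxt <- c(2:n, 1)[seq_len(n)]
  if (n == 1) nxt <- 1L
  gap <- integer(n)
  if (n > 1) gap[1:(n - 1)] <- f$start[2:n] - end_eff[1:(n - 1)] - 1L
  gap[n] <- (f$start[1] + L) - end_eff[n] - 1L
  tibble(
    upstream = f$name,
    downstream = f$name[nxt],
    gap = as.integer(gap),
    class = dplyr::case_when(gap > 0 ~ "spacer", gap < 0 ~ "overlap", TRUE ~ "abutting")
  )
}

#' Summarise a junction ledger
#'
#' Counts and totals of spacers and overlaps. By default junctions adjacent
#' to the control region are excluded, matching the convention of describing
#' spacers "with the exception of the A+T-rich region".
#'
#' @param ledger A tibble from [junction_ledger()].
#' @param exclude Character vector of feature names whose junctions are
#'   excluded (default: names of control-region features if `rec` given, else
#'   `"AT_rich"`). Use `character(0)` to include every junction.
#' @return A one-row tibble: `spacer_count`, `spacer_total_bp`,
#'   `longest_spacer`, `overlap_count`, `overlap_total_bp`, `longest_overlap`.
#' @export
#' @examples
#' sesamia_annotation() |> junction_ledger() |> ledger_summary()
ledger_summary <- function(ledger, exclude = "AT_rich") {
  keep <- !(ledger$upstream %in% exclude | ledger$downstream %in% exclude)
  l <- ledger[keep, ]
  sp <- l$gap[l$gap > 0]
  ov <- l$gap[l$gap < 0]
  tibble(
    spacer_count = length(sp),
    spacer_total_bp = sum(sp),
    longest_spacer = if (length(sp)) max(sp) else 0L,
    overlap_count = length(ov),
    overlap_total_bp = sum(-ov),
    longest_overlap = if (length(ov)) max(-ov) else 0L
  )
}

#' Rotation-normalised gene-order signature
#'
#' Returns the ordered (name, strand) sequence starting at an anchor gene
#' (default `trnM`, the first gene of the lepidopteran arrangement), which
#' makes gene orders comparable regardless of where the coordinate origin
#' was placed.
#'
#' @param rec A [mitogenome].
#' @param anchor Anchor gene name; must be present.
#' @return A tibble with columns `name`, `strand` in rotated order, with the
#'   signature string (e.g. `"trnM+ trnI+ trnQ- ..."`) as attribute
#'   `"signature"`.
#' @export
gene_order_signature <- function(rec, anchor = "trnM") {
  stopifnot(inherits(rec, "mitogenome"))
  f <- rec$features
  i <- which(f$name == anchor)
  if (length(i) == 0) abort(sprintf("anchor gene '%s' is missing from the annotation", anchor))
  ord <- c(i[1]:nrow(f), seq_len(i[1] - 1))
  out <- f[ord, c("name", "strand")]
  attr(out, "signature") <- paste0(out$name, ifelse(out$strand == "F", "+", "-"),
                                   collapse = " ")
  out
}

#' Compare two gene orders and report displaced genes
#'
#' The query order is rotated against the reference over all possible
#' origins and the rotation with the fewest position/strand mismatches is
#' used (ties broken by smallest rotation); the displaced set is the union
#' of gene names at mismatching positions. Reflections are not normalised:
#' strand is biological signal.
#'
#' @param rec,ref [mitogenome] records to compare (same gene content).
#' @return Character vector of displaced gene names (empty when identical
#'   up to rotation). Genes private to either record are always reported.
#' @export
compare_gene_order <- function(rec, ref) {
  a <- rec$features[, c("name", "strand")]
  b <- ref$features[, c("name", "strand")]
  if (!setequal(a$name, b$name)) {
    return(sort(union(setdiff(a$name, b$name), setdiff(b$name, a$name))))
  }
  n <- nrow(a)
  lab_a <- paste0(a$name, a$strand)
  lab_b <- paste0(b$name, b$strand)
  best <- NULL
  best_miss <- n + 1L
  for (k in seq_len(n) - 1L) {
    rot <- ((seq_len(n) + k - 1L) %% n) + 1L
    miss <- which(lab_a[rot] != lab_b)
    if (length(miss) < best_miss) {
      best_miss <- length(miss)
      best <- sort(unique(c(a$name[rot][miss], b$name[miss])))
    }
  }
  best
}
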