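#' Nucleotide composition and strand skews of a sequence
#'
#' AT skew is (A - T)/(A + T) and GC skew is (G - C)/(G + C), the standard
#' strand-asymmetry statistics. `N` bases are counted separately and excluded
#' from percentages and skews; a skew whose denominator is zero is reported
#' as `NA`.
#'
#' @param seq Nucleotide string (A/C/G/T/N).
#' @return A one-row tibble: `a`, `t`, `g`, `c`, `other`, `length`,
#'   `at_content` (percent), `at_skew`, `gc_skew`.
#' @export
#' @examples
#' composition("AAAT")  # at_skew 0.5
composition <- function(seq) {
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) == 0) {
    abort("composition() requires a single non-empty nucleotide string")
  }
  seq <- check_nucleotides(seq)
  ch <- seq_chars(seq)
  a <- sum(ch == "A"); t <- sum(ch == "T")
  g <- sum(ch == "G"); c <- sum(ch == "C")
  other <- length(ch) - a - t - g - c
  acgt <- a + t + g + c
  tibble(
    a = a, t = t, g = g, c = c, other = other, length = length(ch),
    at_content = if (acgt > 0) 100 * (a + t) / acgt else NA_real_,
    at_skew = if (a + t > 0) (a - t) / (a + t) else NA_real_,
    gc_skew = if (g + c > 0) (g - c) / (g + c) else NA_real_
  )
}

# concatenated coding-orientation sequence of all features of one category
concat_category <- function(rec, category) {
  f <- rec$features[rec$features$category == category, ]
  if (nrow(f) == 0) return("")
  paste(vapply(seq_len(nrow(f)),
               function(i) extract_feature_sequence(rec, f[i, ]),
               character(1)), collapse = "")
}

#' Composition and skew per genome region
#'
#' One row per region in the layout of a comparative mitogenome composition
#' table: whole genome (majority strand), the concatenated protein-coding
#' genes, tRNAs and rRNAs (each in coding orientation), and the control
#' region.
#'
#' @param rec A [mitogenome] with sequence.
#' @return A tibble with column `region` followed by the columns of
#'   [composition()].
#' @export
region_composition_report <- function(rec) {
  stopifnot(inherits(rec, "mitogenome"))
  if (is.null(rec$sequence)) abort("sequence required for composition report")
  regions <- list(
    whole_genome = rec$sequence,
    PCGs = concat_category(rec, "PCG"),
    tRNAs = concat_category(rec, "tRNA"),
    rRNAs = concat_category(rec, "rRNA"),
    control_region = concat_category(rec, "control")
  )
  regions <- regions[vapply(regions, nchar, integer(1)) > 0]
  bind_rows(lapply(regions, composition), .id = "region")
}

#' AT content at the three codon positions of the protein-coding genes
#'
#' Codons are read in frame after removing each gene's initiation codon and
#' its (complete or truncated) termination codon, the same codon set used by
#' [codon_usage()].
#'
#' @param rec A [mitogenome] with sequence and annotated PCGs.
#' @return A tibble with columns `position` (1, 2, 3), `a`, `t`, `g`, `c`,
#'   `at_content`.
#' @export
codon_position_composition <- function(rec) {
  codons <- pcg_codons(rec)$codon
  if (length(codons) == 0) abort("no codons available: record has no usable PCGs")
  mat <- do.call(rbind, strsplit(codons, "", fixed = TRUE))
  purrr::map_dfr(1:3, function(p) {
    ch <- mat[, p]
    cmp <- composition(collapse_chars(ch))
    tibble(position = p, a = cmp$a, t = cmp$t, g = cmp$g, c = cmp$c,
           at_content = cmp$at_content)
  })
}
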