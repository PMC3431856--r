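# Invertebrate mitochondrial genetic code (NCBI transl_table 5: AGA/AGG = Ser,
# ATA = Met, TGA = Trp) and the codon-family split used for mitogenome codon
# usage reporting: Leu1 = CTN (4-fold), Leu2 = TTA/TTG (2-fold), Ser1 = AGN,
# Ser2 = TCN.

mito_code_env <- new.env(parent = emptyenv())

invertebrate_mito_code <- function() {
  if (is.null(mito_code_env$code)) {
    mito_code_env$code <- Biostrings::getGeneticCode("5")
  }
  mito_code_env$code
}

aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val")

#' Codon family map of the invertebrate mitochondrial code
#'
#' The 62 sense codons with their amino acid and synonymous family, Leu and
#' Ser each split into two families as conventional for mitogenome codon
#' usage plots (`Leu1` = CTN, `Leu2` = TTA/TTG, `Ser1` = AGN, `Ser2` = TCN).
#'
#' @return A tibble: `codon`, `aa` (single letter), `family`, `degeneracy`.
#' @export
codon_families <- function() {
  code <- invertebrate_mito_code()
  sense <- code[code != "*"]
  fam <- unname(aa3[sense])
  fam[sense == "L"] <- ifelse(substr(names(sense)[sense == "L"], 1, 2) == "CT",
                              "Leu1", "Leu2")
  fam[sense == "S"] <- ifelse(substr(names(sense)[sense == "S"], 1, 2) == "AG",
                              "Ser1", "Ser2")
  out <- tibble(codon = names(sense), aa = unname(sense), family = fam)
  out$degeneracy <- as.integer(table(out$family)[out$family])
  arrange(out, .data$family, .data$codon)
}

split_codons <- function(cds) {
  n <- nchar(cds) %/% 3
  if (n == 0) return(character(0))
  substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

#' Classify a protein-coding gene's initiation and termination codons
#'
#' The termination class is read from the CDS length modulo 3 and its
#' terminal bases: complete TAA/TAG stops for in-frame genes, the truncated
#' stops T and TA (completed to UAA by post-transcriptional polyadenylation)
#' for genes one or two bases short of frame. Any other terminal pattern is
#' flagged `"anomalous"`.
#'
#' @param cds Nucleotide string in coding orientation, length >= 6.
#' @return A one-row tibble: `start_codon`, `stop_codon` (the terminal bases,
#'   `""` if anomalous in frame 0), `stop_class` in `"complete_TAA"`,
#'   `"complete_TAG"`, `"truncated_TA"`, `"truncated_T"`, `"anomalous"`.
#' @export
#' @examples
#' classify_start_stop("ATGAAATAA")
classify_start_stop <- function(cds) {
  cds <- check_nucleotides(cds, "CDS")
  len <- nchar(cds)
  if (len < 6) abort("CDS shorter than 6 nt cannot be classified")
  start <- substr(cds, 1, 3)
  mod <- len %% 3
  if (mod == 0) {
    last3 <- substr(cds, len - 2, len)
    if (last3 == "TAA") cls <- "complete_TAA"
    else if (last3 == "TAG") cls <- "complete_TAG"
    else cls <- "anomalous"
    stop_codon <- if (cls == "anomalous") "" else last3
  } else if (mod == 1) {
    last1 <- substr(cds, len, len)
    cls <- if (last1 == "T") "truncated_T" else "anomalous"
    stop_codon <- if (cls == "anomalous") "" else last1
  } else {
    last2 <- substr(cds, len - 1, len)
    cls <- if (last2 == "TA") "truncated_TA" else "anomalous"
    stop_codon <- if (cls == "anomalous") "" else last2
  }
  tibble(start_codon = start, stop_codon = stop_codon, stop_class = cls)
}

# All interior codons of all PCGs (start and stop removed), with per-gene QC.
pcg_codons <- function(rec) {
  stopifnot(inherits(rec, "mitogenome"))
  if (is.null(rec$sequence)) abort("sequence required for codon extraction")
  f <- rec$features[rec$features$category == "PCG", ]
  codons <- character(0)
  genes <- vector("list", nrow(f))
  for (i in seq_len(nrow(f))) {
    cds <- extract_feature_sequence(rec, f[i, ])
    cls <- classify_start_stop(cds)
    stoplen <- nchar(cls$stop_codon)
    body <- substr(cds, 4, nchar(cds) - stoplen)
    cd <- split_codons(body)
    internal_stop <- sum(cd %in% c("TAA", "TAG"))
    genes[[i]] <- tibble(gene = f$name[i], length = nchar(cds),
                         start_codon = cls$start_codon,
                         stop_class = cls$stop_class,
                         n_codons = length(cd),
                         internal_stops = internal_stop)
    codons <- c(codons, cd)
  }
  list(codon = codons, genes = bind_rows(genes))
}

#' Codon usage table of the protein-coding genes
#'
#' Counts every interior codon of every PCG (initiation and termination
#' codons excluded, truncated stops included in the exclusion) over the 62
#' sense codons of the invertebrate mitochondrial code, with frequencies per
#' thousand codons and relative synonymous codon usage. In-frame internal
#' stop codons are reported in the per-gene QC attribute and excluded from
#' the sense-codon counts.
#'
#' @param rec A [mitogenome] with sequence and annotated PCGs.
#' @return A `codon_usage` tibble: `codon`, `aa`, `family`, `degeneracy`,
#'   `count`, `per_thousand`, `rscu`; attributes `total` (codon count) and
#'   `genes` (per-gene QC tibble).
#' @export
codon_usage <- function(rec) {
  px <- pcg_codons(rec)
  fam <- codon_families()
  counted <- table(factor(px$codon[px$codon %in% fam$codon], levels = fam$codon))
  fam$count <- as.integer(counted[fam$codon])
  fam <- per_thousand(fam)
  fam <- rscu(fam)
  structure(fam, total = sum(fam$count), genes = px$genes,
            class = c("codon_usage", class(fam)))
}

#' Codon frequencies per thousand codons
#'
#' @param table A tibble with columns `codon` and `count`.
#' @return The table with a `per_thousand` column, `1000 * count / total`.
#' @export
per_thousand <- function(table) {
  total <- sum(table$count)
  if (total == 0) abort("per-thousand values are undefined for an empty codon table")
  table$per_thousand <- 1000 * table$count / total
  table
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its count divided by the mean count of its synonymous
#' family, i.e. `count * degeneracy / family_total`. Families with zero total
#' get `NA` for all members (those codons are missing from the genome).
#'
#' @param table A tibble with columns `codon`, `family`, `degeneracy`, `count`.
#' @return The table with an `rscu` column.
#' @export
#' @examples
#' tab <- dplyr::filter(codon_families(), family == "Phe")
#' tab$count <- c(1, 3)  # TTC, TTT
#' rscu(tab)$rscu        # 0.5, 1.5
rscu <- function(table) {
  table |>
    group_by(.data$family) |>
    mutate(rscu = if (sum(.data$count) > 0)
      .data$count * .data$degeneracy / sum(.data$count) else NA_real_) |>
    ungroup()
}

#' Translate a coding sequence under the invertebrate mitochondrial code
#'
#' AGA/AGG read Ser, ATA reads Met and TGA reads Trp. Codons containing an
#' ambiguous base translate to `X`; stop codons to `*`. The first codon is
#' reported as `M` regardless of identity (nonstandard initiation codons such
#' as CGA are translated as methionine).
#'
#' @param cds Nucleotide string, length a multiple of 3 (trim truncated
#'   stops first).
#' @param init_m Should the first codon be forced to `M`? Default `TRUE`.
#' @return Amino-acid string.
#' @export
#' @examples
#' translate_mt("ATAAGATGA", init_m = FALSE)  # "MSW"
translate_mt <- function(cds, init_m = TRUE) {
  cds <- check_nucleotides(cds, "CDS")
  if (nchar(cds) %% 3 != 0) abort("CDS length must be a multiple of 3")
  code <- invertebrate_mito_code()
  cd <- split_codons(cds)
  aa <- unname(code[cd])
  aa[is.na(aa)] <- "X"
  aa[aa == "*"] <- "*"
  if (init_m && length(aa) > 0) aa[1] <- "M"
  collapse_chars(aa)
}
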