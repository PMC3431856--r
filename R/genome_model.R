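#' Construct an annotated circular mitogenome record
#'
#' The central container of the package: a circular genome of known length,
#' an ordered feature table, and (optionally) the nucleotide sequence.
#' Coordinates are 1-based closed intervals in GenBank convention; a feature
#' spanning the origin is stored as a single row with `end < start`. Strand
#' `"F"` is the majority strand; `"R"` features are reverse-complemented on
#' extraction.
#'
#' @param features A data frame with at least `name`, `category` (one of
#'   `"PCG"`, `"tRNA"`, `"rRNA"`, `"control"`), `strand` (`"F"`/`"R"`),
#'   `start`, `end`. Optional columns: `anticodon`, `anticodon_start`,
#'   `anticodon_end`, `start_codon`, `stop_codon`, plus any bookkeeping
#'   columns (e.g. `size_printed`, `spacer_printed`), which are retained.
#' @param length Genome length in bp. Defaults to the maximum feature end.
#' @param id Record identifier.
#' @param sequence Optional nucleotide string of exactly `length` bp
#'   (A/C/G/T/N; other ambiguity codes are rejected).
#' @return An object of class `mitogenome`: a list with elements `id`,
#'   `length`, `circular` (always `TRUE`), `features` (a tibble sorted by
#'   start position) and `sequence` (string or `NULL`).
#' @export
#' @examples
#' rec <- mitogenome(
#'   tibble::tibble(name = "gene1", category = "PCG", strand = "F",
#'                  start = 1, end = 9, start_codon = "ATG", stop_codon = "TAA"),
#'   length = 20, sequence = "ATGAAATAACCCCCGGGGGT"
#' )
#' rec
mitogenome <- function(features, length = NULL, id = "mitogenome", sequence = NULL) {
  features <- as_tibble(features)
  required <- c("name", "category", "strand", "start", "end")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols) > 0) {
    abort(paste0("features is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  for (col in c("anticodon", "start_codon", "stop_codon")) {
    if (!col %in% names(features)) features[[col]] <- NA_character_
  }
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (is.null(length)) {
    length <- if (nrow(features) > 0) max(features$end, features$start) else 0L
  }
  length <- as.integer(length)

  if (!is.null(sequence)) {
    sequence <- check_nucleotides(sequence)
    if (nchar(sequence) != length) {
      abort(sprintf("sequence length (%d) does not match declared genome length (%d)",
                    nchar(sequence), length))
    }
  }

  if (nrow(features) > 0) {
    bad <- which(features$start < 1 | features$start > length |
                   features$end < 1 | features$end > length)
    if (length(bad) > 0) {
      abort(sprintf("row %d ('%s'): coordinates outside [1, %d]",
                    bad[1], features$name[bad[1]], length))
    }
    if (!all(features$category %in% c("PCG", "tRNA", "rRNA", "control"))) {
      bad <- which(!features$category %in% c("PCG", "tRNA", "rRNA", "control"))[1]
      abort(sprintf("row %d ('%s'): unknown category '%s'",
                    bad, features$name[bad], features$category[bad]))
    }
    if (!all(features$strand %in% c("F", "R"))) {
      abort("strand must be 'F' or 'R' for every feature")
    }
    if (sum(features$category == "control") > 1) {
      abort("duplicate control region: at most one feature of category 'control' is permitted")
    }
    no_ac <- features$category == "tRNA" & (is.na(features$anticodon) | features$anticodon == "")
    if (any(no_ac)) {
      abort(sprintf("tRNA feature '%s' lacks an anticodon", features$name[which(no_ac)[1]]))
    }
    no_start <- features$category == "PCG" &
      (is.na(features$start_codon) | features$start_codon == "")
    if (any(no_start)) {
      abort(sprintf("PCG feature '%s' lacks a start codon", features$name[which(no_start)[1]]))
    }
    stop_len <- nchar(features$stop_codon)
    bad_stop <- !is.na(features$stop_codon) & !(stop_len %in% 1:3)
    if (any(bad_stop)) {
      abort(sprintf("feature '%s' has a stop codon of invalid length",
                    features$name[which(bad_stop)[1]]))
    }
    features <- arrange(features, .data$start, .data$end)
  }

  structure(
    list(id = id, length = length, circular = TRUE,
         features = features, sequence = sequence),
    class = "mitogenome"
  )
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s: %s bp circular, %d features, sequence %s\n",
              x$id, format(x$length, big.mark = ","), nrow(x$features),
              if (is.null(x$sequence)) "absent" else "present"))
  tab <- table(x$features$category)
  if (length(tab) > 0) {
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Length of a feature on the circular genome
#'
#' Closed-interval span; features wrapping the origin (`end < start`) span
#' the two arcs `start..L` and `1..end`.
#'
#' @param start,end 1-based closed coordinates (vectorised).
#' @param L Genome length in bp.
#' @return Integer vector of feature lengths in bp.
#' @export
#' @examples
#' feature_length(1500, 3030, 15413)   # 1531
#' feature_length(15410, 5, 15413)     # wraps the origin: 9
feature_length <- function(start, end, L) {
  stopifnot(all(start >= 1), all(end >= 1), all(start <= L), all(end <= L))
  as.integer(ifelse(end >= start, end - start + 1, (L - start + 1) + end))
}

#' Extract a feature's nucleotide sequence in coding orientation
#'
#' Substring of the genome on the circle; `"R"`-strand features are returned
#' reverse-complemented so the result always reads 5'->3' in the feature's
#' own orientation.
#'
#' @param rec A [mitogenome] with sequence present.
#' @param feature Feature name (string) or a one-row data frame / list with
#'   `strand`, `start`, `end`.
#' @return Character scalar.
#' @export
extract_feature_sequence <- function(rec, feature) {
  stopifnot(inherits(rec, "mitogenome"))
  if (is.null(rec$sequence)) abort("sequence required: record has no nucleotide sequence")
  if (is.character(feature) && length(feature) == 1) {
    idx <- which(rec$features$name == feature)
    if (length(idx) == 0) abort(sprintf("no feature named '%s'", feature))
    feature <- rec$features[idx[1], ]
  }
  pos <- circular_positions(as.integer(feature$start), as.integer(feature$end), rec$length)
  s <- collapse_chars(seq_chars(rec$sequence)[pos])
  if (identical(feature$strand, "R")) revcomp(s) else s
}

#' Read an annotated mitogenome from a TSV feature table or GenBank flat file
#'
#' The TSV dialect has header columns `name`, `category`, `strand`, `start`,
#' `end` and optionally `anticodon`, `anticodon_start`, `anticodon_end`,
#' `start_codon`, `stop_codon`, `size_printed`, `spacer_printed`. The GenBank
#' dialect is minimal: `LOCUS`, a `FEATURES` block with `gene`, `CDS`,
#' `tRNA`, `rRNA`, `misc_feature` and `D-loop` keys, and `ORIGIN`; all other
#' keys are skipped with a warning.
#'
#' @param path File path.
#' @param format `"tsv"` or `"genbank"`.
#' @param sequence Optional nucleotide string to attach (TSV input only).
#' @param id Record id for TSV input.
#' @return A [mitogenome].
#' @export
read_feature_table <- function(path, format = c("tsv", "genbank"),
                               sequence = NULL, id = NULL) {
  format <- match.arg(format)
  if (format == "genbank") return(read_genbank(path))

  tab <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(),
    category = readr::col_character(),
    strand = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    .default = readr::col_guess()
  ), progress = FALSE)
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed feature table at row %d: %s", probs$row[1], probs$expected[1]))
  }
  bad <- which(is.na(tab$start) | is.na(tab$end))
  if (length(bad) > 0) {
    abort(sprintf("malformed coordinates in row %d ('%s')", bad[1], tab$name[bad[1]]))
  }
  for (col in c("anticodon", "start_codon", "stop_codon")) {
    if (col %in% names(tab)) tab[[col]][which(tab[[col]] == "")] <- NA_character_
  }
  mitogenome(tab, id = id %||% basename(path), sequence = sequence)
}

#' The packaged annotation fixture of the Sesamia inferens mitogenome
#'
#' A verbatim transcription of the published annotation table of the
#' S. inferens mitogenome (GenBank JN039362): 37 genes plus the A+T-rich
#' region on a 15,413 bp circle, including the printed size and intergenic
#' spacer columns (kept for QC; coordinates are authoritative).
#'
#' @return A [mitogenome] without sequence.
#' @export
#' @examples
#' rec <- sesamia_annotation()
#' junction_ledger(rec)
sesamia_annotation <- function() {
  path <- system.file("extdata", "sesamia_table1.tsv", package = "mitomoth")
  rec <- read_feature_table(path, "tsv", id = "S_inferens_JN039362")
  rec$length <- 15413L
  rec
}

#' Internal consistency checks of an annotated feature table
#'
#' Compares coordinate-derived spans and junction gaps against the printed
#' `size_printed` / `spacer_printed` columns, when present. The published
#' S. inferens table carries three such inconsistencies: the atp6 span
#' (678 bp derived vs 696 printed), the rrnL-trnV junction (derived gap +1
#' vs printed 0), and consequently the spacer grand total (248 bp derived vs
#' 247 printed-column vs 257 in the running text).
#'
#' @param rec A [mitogenome].
#' @return A tibble with one row per discrepancy: `check`, `feature`,
#'   `printed`, `derived`.
#' @export
feature_table_qc <- function(rec) {
  stopifnot(inherits(rec, "mitogenome"))
  f <- rec$features
  out <- tibble(check = character(), feature = character(),
                printed = numeric(), derived = numeric())
  if ("size_printed" %in% names(f)) {
    derived <- feature_length(f$start, f$end, rec$length)
    bad <- which(!is.na(f$size_printed) & f$size_printed != derived)
    if (length(bad) > 0) {
      out <- bind_rows(out, tibble(check = "size", feature = f$name[bad],
                                   printed = as.numeric(f$size_printed[bad]),
                                   derived = as.numeric(derived[bad])))
    }
  }
  if ("spacer_printed" %in% names(f) && nrow(f) > 1) {
    led <- junction_ledger(rec)
    # spacer_printed on row i is the printed gap between feature i and i+1
    printed <- f$spacer_printed[match(led$upstream, f$name)]
    bad <- which(!is.na(printed) & printed != led$gap)
    if (length(bad) > 0) {
      out <- bind_rows(out, tibble(
        check = "spacer",
        feature = paste0(led$upstream[bad], "-", led$downstream[bad]),
        printed = as.numeric(printed[bad]),
        derived = as.numeric(led$gap[bad])
      ))
    }
  }
  out
}
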