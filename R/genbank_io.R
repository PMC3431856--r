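# Minimal GenBank flat-file dialect: LOCUS, FEATURES (CDS / tRNA / rRNA /
# D-loop / misc_feature), ORIGIN. Other keys are skipped with a warning.
# Strand R is serialized as complement(..); a feature wrapping the origin as
# join(start..L,1..end).

format_location <- function(start, end, strand, L) {
  loc <- if (end >= start) sprintf("%d..%d", start, end)
         else sprintf("join(%d..%d,1..%d)", start, L, end)
  if (strand == "R") sprintf("complement(%s)", loc) else loc
}

parse_location <- function(loc, row) {
  strand <- "F"
  if (grepl("^complement\\(", loc)) {
    strand <- "R"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    r1 <- as.integer(strsplit(parts[1], "..", fixed = TRUE)[[1]])
    r2 <- as.integer(strsplit(parts[2], "..", fixed = TRUE)[[1]])
    return(list(start = r1[1], end = r2[2], strand = strand))
  }
  nums <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1]])
  if (length(nums) != 2 || anyNA(nums)) {
    abort(sprintf("malformed coordinates in feature block near line %d: '%s'", row, loc))
  }
  list(start = nums[1], end = nums[2], strand = strand)
}

#' Write a mitogenome as a minimal GenBank flat file
#'
#' @param rec A [mitogenome].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(rec, path) {
  stopifnot(inherits(rec, "mitogenome"))
  key_of <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", control = "D-loop")
  lines <- c(
    sprintf("LOCUS       %s %d bp    DNA     circular", rec$id, rec$length),
    sprintf("DEFINITION  %s.", rec$id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", rec$length)
  )
  f <- rec$features
  for (i in seq_len(nrow(f))) {
    key <- key_of[[f$category[i]]]
    loc <- format_location(f$start[i], f$end[i], f$strand[i], rec$length)
    lines <- c(lines, sprintf("     %-15s %s", key, loc),
               sprintf("                     /gene=\"%s\"", f$name[i]))
    if (f$category[i] == "tRNA" && !is.na(f$anticodon[i])) {
      lines <- c(lines,
                 sprintf("                     /anticodon=\"%s\"", f$anticodon[i]))
      if ("anticodon_start" %in% names(f) && !is.na(f$anticodon_start[i])) {
        lines <- c(lines, sprintf("                     /anticodon_pos=\"%d..%d\"",
                                  f$anticodon_start[i], f$anticodon_end[i]))
      }
    }
    if (f$category[i] == "PCG") {
      lines <- c(lines, "                     /transl_table=5",
                 sprintf("                     /start_codon=\"%s\"", f$start_codon[i]))
      if (!is.na(f$stop_codon[i])) {
        lines <- c(lines, sprintf("                     /stop_codon=\"%s\"", f$stop_codon[i]))
      }
    }
  }
  if (!is.null(rec$sequence)) {
    lines <- c(lines, "ORIGIN")
    s <- tolower(rec$sequence)
    starts <- seq(1, nchar(s), by = 60)
    for (st in starts) {
      chunk <- substr(s, st, min(st + 59, nchar(s)))
      blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      lines <- c(lines, sprintf("%9d %s", st, paste(blocks, collapse = " ")))
    }
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

#' Read a minimal-dialect GenBank flat file
#'
#' @param path File path.
#' @return A [mitogenome].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0) abort("not a GenBank flat file: no LOCUS line")
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  id <- toks[2]
  len <- as.integer(toks[which(toks == "bp") - 1])
  cat_of <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
              `D-loop` = "control", misc_feature = "control")

  feat_start <- grep("^FEATURES", lines)
  origin_at <- grep("^ORIGIN", lines)
  feat_end <- if (length(origin_at)) origin_at[1] - 1 else length(lines)
  rows <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && !is.na(cur$category)) rows[[length(rows) + 1]] <<- cur
    cur <<- NULL
  }
  if (length(feat_start)) {
    for (ln in (feat_start[1] + 1):feat_end) {
      line <- lines[ln]
      if (grepl("^     \\S", line)) {                 # new feature key
        flush()
        toks <- strsplit(trimws(line), "\\s+")[[1]]
        key <- toks[1]
        if (key == "source") next
        if (!key %in% names(cat_of)) {
          warn(sprintf("skipping unsupported feature key '%s' (line %d)", key, ln))
          cur <- list(category = NA)
          next
        }
        loc <- parse_location(toks[2], ln)
        cur <- list(name = NA_character_, category = cat_of[[key]],
                    strand = loc$strand, start = loc$start, end = loc$end,
                    anticodon = NA_character_, anticodon_start = NA_integer_,
                    anticodon_end = NA_integer_, start_codon = NA_character_,
                    stop_codon = NA_character_)
      } else if (grepl("^\\s+/", line) && !is.null(cur)) {
        q <- trimws(line)
        val <- sub('^/[a-z_]+=?"?([^"]*)"?$', "\\1", q)
        if (startsWith(q, "/gene=")) cur$name <- val
        if (startsWith(q, "/anticodon=")) cur$anticodon <- val
        if (startsWith(q, "/anticodon_pos=")) {
          ac <- as.integer(strsplit(val, "..", fixed = TRUE)[[1]])
          cur$anticodon_start <- ac[1]; cur$anticodon_end <- ac[2]
        }
        if (startsWith(q, "/start_codon=")) cur$start_codon <- val
        if (startsWith(q, "/stop_codon=")) cur$stop_codon <- val
      }
    }
    flush()
  }
  features <- bind_rows(lapply(rows, as_tibble))
  sequence <- NULL
  if (length(origin_at)) {
    body <- lines[(origin_at[1] + 1):length(lines)]
    body <- body[!grepl("^//", body)]
    sequence <- toupper(gsub("[^a-zA-Z]", "", paste(body, collapse = "")))
    if (nchar(sequence) == 0) sequence <- NULL
  }
  if (nrow(features) == 0) {
    features <- tibble(name = character(), category = character(),
                       strand = character(), start = integer(), end = integer())
  }
  mitogenome(features, length = len, id = id, sequence = sequence)
}

#' Read / write FASTA nucleotide files
#'
#' Thin wrappers over Biostrings with 70-column wrapping on output.
#'
#' @param path File path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' @param seqs Named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70)
  invisible(path)
}

#' Write the feature table of a record as TSV
#'
#' @param rec A [mitogenome].
#' @param path Output path.
#' @export
write_feature_table <- function(rec, path) {
  readr::write_tsv(rec$features, path)
  invisible(path)
}
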