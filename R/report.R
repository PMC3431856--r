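#' Run the full mitogenome description workflow
#'
#' Ties the analysis stages together the way a mitogenome description is
#' assembled: annotation QC, junction ledger and summary, per-region
#' composition, codon usage/RSCU, control-region structural scan, fixed
#' motifs, tRNA cloverleaf summary, and (when an alignment is supplied)
#' phylogeny with bootstrap supports. Stages that need the nucleotide
#' sequence are skipped with an explicit notice when the record has none.
#'
#' @param rec A [mitogenome].
#' @param alignment Optional [aa_alignment] for the phylogeny stage.
#' @param out_dir Optional directory; each section is written as TSV (tables)
#'   or Newick/JSON there.
#' @param builder Tree builder for the phylogeny stage, `"nj"` or `"mp"`.
#' @param replicates Bootstrap replicates for the phylogeny stage.
#' @param seed Seed for the bootstrap stage.
#' @param control_params Named list passed to [scan_control_region()].
#' @return A `mitomoth_report` list of tibbles (and a `phylo` for the
#'   phylogeny stage), with skipped stages recorded in `$skipped`.
#' @export
run_full_report <- function(rec, alignment = NULL, out_dir = NULL,
                            builder = "nj", replicates = 100, seed = 1,
                            control_params = list()) {
  stopifnot(inherits(rec, "mitogenome"))
  unknown <- setdiff(names(control_params),
                     c("min_t_run", "max_gap", "unit_range", "min_copies",
                       "period_range", "match", "mismatch", "min_score",
                       "dedup", "min_stem", "loop_range", "allow_gu"))
  if (length(unknown) > 0) {
    abort(sprintf("unknown control-region parameter(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  report <- list()
  skipped <- character(0)

  ledger <- junction_ledger(rec)
  report$features <- rec$features
  report$qc <- feature_table_qc(rec)
  report$junctions <- ledger
  report$junction_summary <- ledger_summary(
    ledger, exclude = rec$features$name[rec$features$category == "control"])
  report$gene_order <- gene_order_signature(
    rec, anchor = if ("trnM" %in% rec$features$name) "trnM"
                  else rec$features$name[1])

  if (!is.null(rec$sequence)) {
    report$composition <- region_composition_report(rec)
    if (any(rec$features$category == "PCG")) {
      report$codon_positions <- codon_position_composition(rec)
      report$codon_usage <- codon_usage(rec)
    }
    ctrl <- rec$features[rec$features$category == "control", ]
    if (nrow(ctrl) == 1) {
      region <- extract_feature_sequence(rec, ctrl[1, ])
      report$control_region <- do.call(scan_control_region,
                                       c(list(region), control_params))
    }
    report$motifs <- tryCatch(find_fixed_motifs(rec),
                              error = function(e) { skipped <<- c(skipped,
                                paste("motifs:", conditionMessage(e))); NULL })
    if (any(rec$features$category == "tRNA")) {
      report$trna <- trna_structure_report(rec)
    }
  } else {
    skipped <- c(skipped,
                 "composition, codon usage, control region, motifs, tRNA folding: sequence absent")
  }

  if (!is.null(alignment)) {
    report$tree <- bootstrap_support(alignment, builder = builder,
                                     replicates = replicates, seed = seed)
    report$split_support <- attr(report$tree, "split_support")
  }
  report$skipped <- skipped
  class(report) <- "mitomoth_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(report)) {
      x <- report[[nm]]
      if (inherits(x, "data.frame")) {
        readr::write_tsv(x, file.path(out_dir, paste0(nm, ".tsv")))
      } else if (inherits(x, "phylo")) {
        write_newick(x, file.path(out_dir, paste0(nm, ".nwk")))
      }
    }
    jsonlite::write_json(
      list(id = rec$id, length = rec$length,
           junction_summary = report$junction_summary, skipped = skipped),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.mitomoth_report <- function(x, ...) {
  cat("<mitomoth_report> sections:",
      paste(setdiff(names(x), "skipped"), collapse = ", "), "\n")
  if (length(x$skipped) > 0) cat("skipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}

#' @method tidy mitogenome
#' @export
tidy.mitogenome <- function(x, ...) x$features

#' @method glance mitogenome
#' @export
glance.mitogenome <- function(x, ...) {
  tab <- table(x$features$category)
  tibble(id = x$id, length = x$length,
         n_features = nrow(x$features),
         n_pcg = sum(x$features$category == "PCG"),
         n_trna = sum(x$features$category == "tRNA"),
         n_rrna = sum(x$features$category == "rRNA"),
         has_sequence = !is.null(x$sequence))
}

#' @method glance codon_usage
#' @export
glance.codon_usage <- function(x, ...) {
  tibble(total_codons = attr(x, "total"),
         n_missing_codons = sum(x$count == 0),
         top_codon = x$codon[which.max(x$count)],
         top_family = x$family[which.max(x$count)])
}

#' @method tidy codon_usage
#' @export
tidy.codon_usage <- function(x, ...) {
  as_tibble(x)
}
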