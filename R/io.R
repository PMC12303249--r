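#' Read and write the JSON-Lines note corpus
#'
#' One note per line with fields `patient_id`, `note_id`, `note_date`
#' (ISO-8601), `specialty`, `text`. JSONL keeps multi-thousand-note corpora
#' streamable and diff-friendly.
#'
#' @param notes data.frame of notes (see [generate_cohort()]).
#' @param path file path.
#' @return `read_corpus_jsonl()` returns the notes data.frame;
#'   `write_corpus_jsonl()` returns `path` invisibly.
#' @export
write_corpus_jsonl <- function(notes, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(notes) > 0L) {
    lines <- vapply(seq_len(nrow(notes)), function(i) {
      jsonlite::toJSON(as.list(notes[i, c("patient_id", "note_id",
                                          "note_date", "specialty", "text")]),
                       auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cols <- c("patient_id", "note_id", "note_date", "specialty", "text")
  if (length(lines) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), 5), cols),
                         stringsAsFactors = FALSE)
    return(out)
  }
  rows <- lapply(lines, function(l) {
    as.data.frame(jsonlite::fromJSON(l)[cols], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read and write truth labels with review records
#'
#' CSV with columns `patient_id`, `truth_label`, `stratum`, `reviewer1`,
#' `reviewer2`, `consensus`, `disagreement`.
#'
#' @param labels data.frame (the `labels` element of an `access_cohort`).
#' @param path file path.
#' @export
write_labels_csv <- function(labels, path) {
  write.csv(labels, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(disagreement = "logical"))
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: the configuration, its FNV-1a
#' hash, the seed, the package version, and per-stage case counts. No
#' timestamps, so reruns of the same configuration are byte-identical.
#'
#' @param config list of run configuration values.
#' @param counts named list of per-stage case counts.
#' @param path output file.
#' @keywords internal
write_manifest <- function(config, counts, path) {
  cfg_json <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                            digits = NA))
  manifest <- list(package = "gtaccess",
                   version = as.character(utils::packageVersion("gtaccess")),
                   config = config, config_hash = fnv1a32(cfg_json),
                   counts = counts)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

metrics_report_entry <- function(ms) {
  entry <- list(n = ms$n, accuracy = ms$accuracy, f1 = ms$f1,
                precision = ms$precision, recall = ms$recall)
  if (!is.null(ms$ci)) entry$ci <- ms$ci
  entry
}

#' Render a metrics report as an aligned text table
#'
#' Mirrors the Accuracy / F1 / Precision / Recall column layout of the
#' package's JSON reports, rounded to 3 decimals.
#'
#' @param report named list of `metric_set` objects (rows).
#' @return character vector of table lines.
#' @export
format_metrics_table <- function(report) {
  fmt <- function(v) ifelse(is.na(v), "undef",
                            formatC(v, digits = 3, format = "f"))
  header <- sprintf("%-14s %5s %9s %9s %10s %8s", "Metrics", "No.",
                    "Accuracy", "F1 Score", "Precision", "Recall")
  rows <- vapply(names(report), function(nm) {
    ms <- report[[nm]]
    sprintf("%-14s %5d %9s %9s %10s %8s", nm, ms$n, fmt(ms$accuracy),
            fmt(ms$f1), fmt(ms$precision), fmt(ms$recall))
  }, character(1))
  c(header, rows)
}
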