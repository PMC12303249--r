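#' Triage a consolidated patient document
#'
#' Deterministic pre-classification routing: a patient with no snippets is an
#' automatic negative (there is nothing for the classifier to read); a
#' patient with at least `snippet_threshold` snippets, or whose consolidated
#' document exceeds `word_threshold` words, is an automatic positive (such a
#' concept burden was always associated with testing having been offered);
#' everyone else is routed to the classifier. "At least 20" is an inclusive
#' threshold; "exceeded 4,000 words" is strict. Word count is measured on the
#' cleaned consolidated document, the same text the classifier sees.
#'
#' @param doc a `patient_document` (see [consolidate_patient_document()]) or
#'   any list with `snippet_count` and `word_count`.
#' @param snippet_threshold automatic-positive snippet count (inclusive).
#' @param word_threshold automatic-positive word count (strict).
#' @return list of class `"triage_decision"` with `route` (one of
#'   `"AUTO_NEGATIVE"`, `"AUTO_POSITIVE"`, `"TO_CLASSIFIER"`) and `reason`
#'   (`"no_snippets"`, `"high_snippet_count"`, `"long_document"`, or
#'   `"default"`).
#' @export
triage_patient <- function(doc, snippet_threshold = 20L,
                           word_threshold = 4000L) {
  stopifnot(snippet_threshold > 0L, word_threshold > 0L)
  sc <- doc$snippet_count
  wc <- doc$word_count
  if (is.null(sc) || is.null(wc) || sc < 0L || wc < 0L) {
    stop("doc must carry non-negative snippet_count and word_count",
         call. = FALSE)
  }
  dec <- if (sc == 0L) {
    list(route = "AUTO_NEGATIVE", reason = "no_snippets")
  } else if (sc >= snippet_threshold) {
    list(route = "AUTO_POSITIVE", reason = "high_snippet_count")
  } else if (wc > word_threshold) {
    list(route = "AUTO_POSITIVE", reason = "long_document")
  } else {
    list(route = "TO_CLASSIFIER", reason = "default")
  }
  structure(dec, class = "triage_decision")
}

#' Triage every patient document in a corpus
#'
#' @param docs data.frame from [build_patient_documents()].
#' @inheritParams triage_patient
#' @return data.frame with columns `patient_id`, `route`, `reason`,
#'   `snippet_count`, `word_count`.
#' @export
triage_corpus <- function(docs, snippet_threshold = 20L,
                          word_threshold = 4000L) {
  rows <- lapply(seq_len(nrow(docs)), function(i) {
    d <- triage_patient(docs[i, , drop = FALSE], snippet_threshold,
                        word_threshold)
    data.frame(patient_id = docs$patient_id[i], route = d$route,
               reason = d$reason, snippet_count = docs$snippet_count[i],
               word_count = docs$word_count[i], stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(0), route = character(0),
               reason = character(0), snippet_count = integer(0),
               word_count = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
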