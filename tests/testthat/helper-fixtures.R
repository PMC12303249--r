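# Shared fixtures, built in code.

# a tiny corpus data.frame from parallel vectors
make_notes <- function(patient_id, text, note_id = NULL, note_date = NULL,
                       specialty = "medical oncology") {
  n <- length(text)
  data.frame(
    patient_id = rep_len(patient_id, n),
    note_id = if (is.null(note_id)) sprintf("N%03d", seq_len(n)) else note_id,
    note_date = if (is.null(note_date)) rep("2021-06-01", n) else note_date,
    specialty = rep_len(specialty, n),
    text = text, stringsAsFactors = FALSE)
}

# a note of `n` keyword-free filler words with phrases planted at given
# 0-based word positions; returns the text and records the plant positions
plant_phrases <- function(n, phrases, positions) {
  words <- rep("lorem", n)
  for (i in seq_along(phrases)) {
    pw <- strsplit(phrases[i], " ")[[1]]
    words[positions[i] + seq_along(pw)] <- pw
  }
  paste(words, collapse = " ")
}

# binary prediction/truth pair realizing a planned confusion matrix
planned_binary <- function(tp, fp, fn, tn) {
  truth <- c(rep("positive", tp + fn), rep("negative", fp + tn))
  pred <- c(rep("positive", tp), rep("negative", fn),
            rep("positive", fp), rep("negative", tn))
  list(pred = pred, truth = truth)
}

small_lexicon <- function() {
  gtaccess::as_lexicon(c("genetic testing", "germline", "gene panel"))
}
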