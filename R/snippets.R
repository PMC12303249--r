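#' Split text into whitespace-delimited words
#'
#' A "word" is a maximal run of non-whitespace characters, punctuation
#' attached. This is the word definition underlying the 100-word snippet
#' windows, snippet word counts, and the 4,000-word triage threshold, stated
#' explicitly so every count in the pipeline is reproducible.
#'
#' @param text character scalar (possibly empty).
#' @return character vector of words, zero-length for empty/blank input.
#' @examples
#' tokenize_words("BRCA1/2 testing  ordered.")
#' @export
tokenize_words <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  strsplit(trimws(text), "[[:space:]]+")[[1]]
}

count_words <- function(text) length(tokenize_words(text))

#' Clean consolidated text
#'
#' Removes characters outside a fixed whitelist (ASCII letters, digits,
#' space, and `. , ; : ? ! ( ) ' / -`), collapses whitespace runs to a single
#' space, and strips leading/trailing whitespace. Idempotent.
#'
#' @param text character scalar.
#' @return cleaned character scalar.
#' @examples
#' clean_text("  Genetic   testing™  done. ")
#' @export
clean_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) return("")
  x <- gsub("[^A-Za-z0-9 .,;:?!()'/\n\r\t-]", "", text)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Keyword lexicon for access to genetic testing
#'
#' `default_lexicon()` returns the built-in keyword list (genes, services,
#' and testing vocabulary that may indicate access to germline testing);
#' `read_lexicon()` loads a user lexicon from a plain-text file, one phrase
#' per line, `#` comments and blank lines ignored. Phrases are 1-5 words,
#' matched case-insensitively; duplicates after case-folding are an error.
#'
#' @param path path to a lexicon file.
#' @return character vector of class `"keyword_lexicon"`.
#' @export
default_lexicon <- function() {
  if (is.null(.gta_cache$lexicon)) {
    path <- system.file("extdata", "lexicon.txt", package = "gtaccess")
    .gta_cache$lexicon <- read_lexicon(path)
  }
  .gta_cache$lexicon
}

#' @rdname default_lexicon
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  as_lexicon(lines[nzchar(lines)])
}

#' @rdname default_lexicon
#' @param phrases character vector of keyword phrases.
#' @export
as_lexicon <- function(phrases) {
  stopifnot(is.character(phrases))
  phrases <- trimws(phrases)
  phrases <- phrases[nzchar(phrases)]
  if (length(phrases) == 0L) {
    stop("lexicon must contain at least one phrase", call. = FALSE)
  }
  if (anyDuplicated(tolower(phrases))) {
    stop("lexicon contains duplicate phrases after case-folding",
         call. = FALSE)
  }
  nw <- lengths(strsplit(phrases, "[[:space:]]+"))
  if (any(nw > 5L)) {
    stop("lexicon phrases must be at most 5 words", call. = FALSE)
  }
  structure(phrases, class = "keyword_lexicon")
}

# strip leading/trailing punctuation and case-fold, for whole-word matching
normalize_words <- function(words) {
  tolower(gsub("^[[:punct:]]+|[[:punct:]]+$", "", words))
}

#' Locate keyword hits in a note
#'
#' Case-insensitive whole-word phrase matching over the note's word sequence
#' (leading/trailing punctuation on a word is ignored, so "counseling." still
#' matches "counseling"). Overlapping hits of different phrases are all
#' reported; hits are sorted by position.
#'
#' @param text note text.
#' @param lexicon a `keyword_lexicon` (see [default_lexicon()]).
#' @return data.frame with columns `phrase`, `start_word`, `end_word`
#'   (0-based half-open word-index span of the matched phrase).
#' @export
find_keyword_hits <- function(text, lexicon) {
  if (!inherits(lexicon, "keyword_lexicon")) lexicon <- as_lexicon(lexicon)
  words <- normalize_words(tokenize_words(text))
  n <- length(words)
  out <- list()
  for (phrase in lexicon) {
    pw <- normalize_words(tokenize_words(phrase))
    k <- length(pw)
    if (n < k) next
    cand <- which(words[seq_len(n - k + 1L)] == pw[1L])
    if (k > 1L) {
      for (j in 2L:k) cand <- cand[words[cand + j - 1L] == pw[j]]
    }
    if (length(cand)) {
      out[[length(out) + 1L]] <- data.frame(
        phrase = phrase, start_word = cand - 1L, end_word = cand - 1L + k,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(phrase = character(0), start_word = integer(0),
                      end_word = integer(0), stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$start_word, hits$end_word, hits$phrase), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Extract context-window snippets from one note
#'
#' For every keyword hit, takes the window of `window` words before and after
#' the matched phrase, clipped to the note bounds. Windows within the same
#' note whose word ranges overlap are merged into a single snippet whose
#' keyword is the first contributing phrase; the merged ranges are pairwise
#' disjoint and sorted by position.
#'
#' @param text note text.
#' @param lexicon a `keyword_lexicon`.
#' @param window words of context on each side of a hit (default 100).
#' @param patient_id,note_id provenance identifiers carried onto snippets.
#' @return data.frame with columns `patient_id`, `note_id`, `keyword`,
#'   `start_word`, `end_word`, `text`.
#' @export
extract_snippets <- function(text, lexicon, window = 100L,
                             patient_id = NA_character_,
                             note_id = NA_character_) {
  stopifnot(window >= 1L)
  empty <- data.frame(patient_id = character(0), note_id = character(0),
                      keyword = character(0), start_word = integer(0),
                      end_word = integer(0), text = character(0),
                      stringsAsFactors = FALSE)
  hits <- find_keyword_hits(text, lexicon)
  if (nrow(hits) == 0L) return(empty)
  words <- tokenize_words(text)
  n <- length(words)
  s <- pmax(0L, hits$start_word - as.integer(window))
  e <- pmin(n, hits$end_word + as.integer(window))
  # merge overlapping windows (hits are position-sorted)
  ms <- s[1L]; me <- e[1L]; mk <- hits$phrase[1L]
  out_s <- integer(0); out_e <- integer(0); out_k <- character(0)
  if (nrow(hits) > 1L) {
    for (i in 2L:nrow(hits)) {
      if (s[i] < me) {
        me <- max(me, e[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me); out_k <- c(out_k, mk)
        ms <- s[i]; me <- e[i]; mk <- hits$phrase[i]
      }
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me); out_k <- c(out_k, mk)
  data.frame(
    patient_id = patient_id, note_id = note_id, keyword = out_k,
    start_word = out_s, end_word = out_e,
    text = vapply(seq_along(out_s), function(i) {
      paste(words[(out_s[i] + 1L):out_e[i]], collapse = " ")
    }, character(1)),
    stringsAsFactors = FALSE)
}

#' Extract snippets for a whole note corpus
#'
#' Applies [extract_snippets()] to every note. Notes are pre-screened with a
#' fast substring scan so that the (strictly more precise) word-level matcher
#' only runs on notes that could contain a keyword.
#'
#' @param notes data.frame with columns `patient_id`, `note_id`, `note_date`,
#'   `specialty`, `text` (see [generate_cohort()] / [read_corpus_jsonl()]).
#' @param lexicon a `keyword_lexicon`.
#' @param window context window size in words.
#' @return data.frame of snippets across all notes.
#' @export
extract_corpus_snippets <- function(notes, lexicon = default_lexicon(),
                                    window = 100L) {
  if (!inherits(lexicon, "keyword_lexicon")) lexicon <- as_lexicon(lexicon)
  stopifnot(all(c("patient_id", "note_id", "text") %in% names(notes)),
            window >= 1L)
  empty <- data.frame(patient_id = character(0), note_id = character(0),
                      keyword = character(0), start_word = integer(0),
                      end_word = integer(0), text = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(notes) == 0L) return(empty)
  # fast substring pre-screen: a strict superset of the whole-word matcher
  pre <- paste0("(?i)", paste(gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                                   as.character(lexicon)), collapse = "|"))
  cand <- which(grepl(pre, notes$text, perl = TRUE))
  if (length(cand) == 0L) return(empty)
  # tokenize and normalize all candidate notes in bulk
  words_list <- strsplit(trimws(notes$text[cand]), "[[:space:]]+")
  lens <- lengths(words_list)
  flat <- normalize_words(unlist(words_list, use.names = FALSE))
  norm_list <- split(flat, rep.int(seq_along(cand), lens))
  phrase_words <- lapply(as.character(lexicon), function(p) {
    normalize_words(tokenize_words(p))
  })
  acc <- vector("list", length(cand))
  n_out <- 0L
  for (ci in seq_along(cand)) {
    wn <- norm_list[[ci]]
    n <- length(wn)
    hs <- integer(0); he <- integer(0); hp <- character(0)
    for (pi in seq_along(phrase_words)) {
      pw <- phrase_words[[pi]]
      k <- length(pw)
      if (n < k) next
      at <- which(wn[seq_len(n - k + 1L)] == pw[1L])
      if (k > 1L) for (j in 2L:k) at <- at[wn[at + j - 1L] == pw[j]]
      if (length(at)) {
        hs <- c(hs, at - 1L); he <- c(he, at - 1L + k)
        hp <- c(hp, rep(as.character(lexicon)[pi], length(at)))
      }
    }
    if (!length(hs)) next
    ord <- order(hs, he, hp)
    hs <- hs[ord]; he <- he[ord]; hp <- hp[ord]
    s <- pmax(0L, hs - as.integer(window))
    e <- pmin(n, he + as.integer(window))
    # merge overlapping windows
    ms <- s[1L]; me <- e[1L]; mk <- hp[1L]
    out_s <- integer(0); out_e <- integer(0); out_k <- character(0)
    if (length(hs) > 1L) {
      for (j in 2L:length(hs)) {
        if (s[j] < me) {
          me <- max(me, e[j])
        } else {
          out_s <- c(out_s, ms); out_e <- c(out_e, me); out_k <- c(out_k, mk)
          ms <- s[j]; me <- e[j]; mk <- hp[j]
        }
      }
    }
    out_s <- c(out_s, ms); out_e <- c(out_e, me); out_k <- c(out_k, mk)
    words <- words_list[[ci]]
    n_out <- n_out + 1L
    acc[[n_out]] <- list(
      i = cand[ci], keyword = out_k, start_word = out_s, end_word = out_e,
      text = vapply(seq_along(out_s), function(j) {
        paste(words[(out_s[j] + 1L):out_e[j]], collapse = " ")
      }, character(1)))
  }
  if (n_out == 0L) return(empty)
  acc <- acc[seq_len(n_out)]
  reps <- vapply(acc, function(a) length(a$start_word), integer(1))
  idx <- rep.int(vapply(acc, `[[`, integer(1), "i"), reps)
  res <- data.frame(
    patient_id = notes$patient_id[idx], note_id = notes$note_id[idx],
    keyword = unlist(lapply(acc, `[[`, "keyword")),
    start_word = unlist(lapply(acc, `[[`, "start_word")),
    end_word = unlist(lapply(acc, `[[`, "end_word")),
    text = unlist(lapply(acc, `[[`, "text")), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Consolidate one patient's snippets into a single cleaned document
#'
#' Snippets are ordered chronologically by `(note_date, note_id, start_word)`
#' so evidence appears in care-timeline order, joined with a blank-line
#' separator, and cleaned with [clean_text()]. A patient with no snippets
#' yields an empty document with zero counts.
#'
#' @param snippets data.frame of snippets for one patient (possibly empty).
#' @param notes data.frame of note metadata providing `note_id` and
#'   `note_date` for ordering.
#' @param patient_id identifier, required when `snippets` is empty.
#' @return list of class `"patient_document"` with `patient_id`, `text`,
#'   `snippet_count`, `word_count`.
#' @export
consolidate_patient_document <- function(snippets, notes,
                                         patient_id = NULL) {
  if (nrow(snippets) == 0L) {
    if (is.null(patient_id)) {
      stop("patient_id required when no snippets are given", call. = FALSE)
    }
    return(patient_document(patient_id, "", 0L))
  }
  ids <- unique(snippets$patient_id)
  if (length(ids) != 1L) {
    stop("snippets span multiple patients: ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  date <- notes$note_date[match(snippets$note_id, notes$note_id)]
  ord <- order(date, snippets$note_id, snippets$start_word)
  text <- clean_text(paste(snippets$text[ord], collapse = "\n\n"))
  patient_document(ids, text, nrow(snippets))
}

patient_document <- function(patient_id, text, snippet_count) {
  structure(list(patient_id = patient_id, text = text,
                 snippet_count = as.integer(snippet_count),
                 word_count = count_words(text)),
            class = "patient_document")
}

#' @export
print.patient_document <- function(x, ...) {
  cat(sprintf("<patient_document %s: %d snippet(s), %d word(s)>\n",
              x$patient_id, x$snippet_count, x$word_count))
  invisible(x)
}

#' Build consolidated documents for every patient in a corpus
#'
#' Runs snippet extraction and consolidation for all patients, including
#' those with no keyword mentions (who receive an empty document and are
#' later triaged to an automatic negative).
#'
#' @inheritParams extract_corpus_snippets
#' @return data.frame with columns `patient_id`, `text`, `snippet_count`,
#'   `word_count`, one row per patient, in first-appearance order.
#' @export
build_patient_documents <- function(notes, lexicon = default_lexicon(),
                                    window = 100L) {
  snippets <- extract_corpus_snippets(notes, lexicon, window)
  ids <- unique(notes$patient_id)
  date <- notes$note_date[match(snippets$note_id, notes$note_id)]
  by_pat <- split(seq_len(nrow(snippets)), snippets$patient_id)
  text <- character(length(ids))
  count <- integer(length(ids))
  wc <- integer(length(ids))
  for (i in seq_along(ids)) {
    idx <- by_pat[[ids[i]]]
    if (is.null(idx)) next
    ord <- idx[order(date[idx], snippets$note_id[idx],
                     snippets$start_word[idx])]
    text[i] <- clean_text(paste(snippets$text[ord], collapse = "\n\n"))
    count[i] <- length(idx)
    wc[i] <- count_words(text[i])
  }
  data.frame(patient_id = ids, text = text, snippet_count = count,
             word_count = wc, stringsAsFactors = FALSE)
}
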