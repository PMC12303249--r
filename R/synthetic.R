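#' Log-normal parameters from a printed median and IQR
#'
#' All count/length distributions in the synthetic generator are log-normal,
#' parameterised directly from published summary statistics:
#' `meanlog = log(median)` and `sdlog = log(q75/q25) / (2 * qnorm(0.75))`.
#' The family is strictly positive and right-skewed, matching the
#' median-below-mean behaviour of clinical count data.
#'
#' @param median,q25,q75 the target median and quartiles (all positive,
#'   `q25 < median < q75`... strictness on the median is not required).
#' @return list with `meanlog` and `sdlog`.
#' @export
lnorm_from_quartiles <- function(median, q25, q75) {
  stopifnot(median > 0, q25 > 0, q75 > q25)
  list(meanlog = log(median), sdlog = log(q75 / q25) / (2 * qnorm(0.75)))
}

#' Synthetic cohort configuration
#'
#' Defaults encode the corpus statistics the generator emulates: four-category
#' label prevalences of 0.59 / 0.305 / 0.055 / 0.05 (Yes / No / NotApplicable
#' / NotSure), 21.5% of patients with no keyword mention anywhere (always
#' binary-negative), 13.5% high-burden patients (always "Yes"; their notes
#' naturally carry at least 20 snippets or a consolidated document over 4,000
#' words), notes per patient targeting median 42 (IQR 21-82), snippets per
#' patient targeting median 4 (IQR 1-10), snippet word counts targeting
#' median 199 (IQR 124-285), and a 14.5% initial reviewer-disagreement rate.
#'
#' @param n_patients number of patients to simulate.
#' @param label_probs named numeric of length 4 over
#'   `access_categories()`, summing to 1.
#' @param zero_snippet_frac probability a patient has no keyword mentions.
#' @param high_burden_frac probability a patient is high-burden.
#' @param notes_per_patient_dist,snippets_per_patient_dist,snippet_words_dist
#'   lists with `meanlog`/`sdlog` (see [lnorm_from_quartiles()]).
#' @param disagreement_rate probability the two initial reviewers disagree.
#' @param exact_fractions if `TRUE`, allocate label and stratum counts by
#'   largest remainder instead of sampling them, so a cohort of 100 patients
#'   has exactly 59 "Yes", 31 "No", 5 "NotApplicable", 5 "NotSure".
#' @param seed integer RNG seed.
#' @return list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_patients = 200L,
                          label_probs = c(Yes = 0.59, No = 0.305,
                                          NotApplicable = 0.055,
                                          NotSure = 0.05),
                          zero_snippet_frac = 0.215,
                          high_burden_frac = 0.135,
                          notes_per_patient_dist =
                            lnorm_from_quartiles(42, 21, 82),
                          snippets_per_patient_dist =
                            lnorm_from_quartiles(4, 1, 10),
                          snippet_words_dist =
                            lnorm_from_quartiles(199, 124, 285),
                          disagreement_rate = 0.145,
                          exact_fractions = FALSE,
                          seed = 20210101L) {
  if (n_patients < 0) stop("n_patients must be >= 0", call. = FALSE)
  if (!setequal(names(label_probs), access_categories())) {
    stop("label_probs must be named over access_categories()", call. = FALSE)
  }
  label_probs <- label_probs[access_categories()]
  if (any(label_probs < 0) || abs(sum(label_probs) - 1) > 1e-9) {
    stop("label_probs must be non-negative and sum to 1", call. = FALSE)
  }
  fr <- c(zero_snippet_frac, high_burden_frac, disagreement_rate)
  if (any(fr < 0 | fr > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (zero_snippet_frac + high_burden_frac > 1) {
    stop("zero_snippet_frac + high_burden_frac must be <= 1", call. = FALSE)
  }
  p_neg <- sum(label_probs[c("No", "NotApplicable", "NotSure")])
  if (high_burden_frac > label_probs[["Yes"]] + 1e-12) {
    stop("high_burden_frac cannot exceed P(Yes): high-burden patients are ",
         "always 'Yes'", call. = FALSE)
  }
  if (zero_snippet_frac > p_neg + 1e-12) {
    stop("zero_snippet_frac cannot exceed the total negative-label ",
         "probability", call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients), label_probs = label_probs,
    zero_snippet_frac = zero_snippet_frac,
    high_burden_frac = high_burden_frac,
    notes_per_patient_dist = notes_per_patient_dist,
    snippets_per_patient_dist = snippets_per_patient_dist,
    snippet_words_dist = snippet_words_dist,
    disagreement_rate = disagreement_rate,
    exact_fractions = isTRUE(exact_fractions),
    seed = as.integer(seed)), class = "cohort_config")
}

# ---- evidence phrase bank (fixed, versioned) --------------------------------
# Every evidence phrase contains at least one default-lexicon keyword and one
# category marker phrase that the heuristic mock backend keys on. All
# characters lie inside the clean_text() whitelist so word counts survive the
# pipeline unchanged.

phrase_bank <- function(label) {
  switch(label,
    Yes = c(
      "germline genetic testing was ordered at this visit and consent obtained",
      "referral placed to the genomic medicine service for genetic counseling",
      "BRCA1 and BRCA2 gene panel completed; results reviewed with the patient",
      "patient completed germline testing through Invitae with no pathogenic variant identified",
      "recommended germline genetic testing; order submitted to Myriad"),
    NotSure = c(
      "patient was considered for germline genetic testing but did not meet criteria at this time",
      "discussed genetic counseling; patient does not currently meet criteria for testing"),
    NotApplicable = c(
      "all breast cancer care including genetic counseling is received through community care outside the VA",
      "oncology management and any germline evaluation handled entirely by community care providers"),
    No = c(
      "family history reviewed; genetic testing was not discussed at this visit",
      "no referral for genetic counseling was made during this encounter"),
    stop("invalid label: ", label, call. = FALSE))
}

# marker phrases the heuristic backend scans for, in priority order
evidence_markers <- function() {
  list(
    Yes = c("testing was ordered", "referral placed", "panel completed",
            "completed germline testing", "order submitted"),
    NotApplicable = c("community care"),
    NotSure = c("did not meet criteria", "does not currently meet criteria"))
}

# distractor vocabulary: deliberately disjoint from every word of every
# default-lexicon phrase so zero-snippet patients can never match
filler_vocabulary <- function() {
  c("patient", "seen", "today", "follow", "up", "visit", "vitals", "stable",
    "denies", "pain", "fatigue", "nausea", "reviewed", "labs", "within",
    "normal", "limits", "imaging", "scheduled", "mammogram", "tolerating",
    "regimen", "well", "continue", "current", "plan", "discussed",
    "return", "clinic", "weeks", "medication", "list", "updated", "exam",
    "unremarkable", "no", "acute", "distress", "appetite", "good", "sleep",
    "adequate", "ambulating", "independently", "wound", "healing", "lymph",
    "nodes", "palpable", "left", "right", "tenderness", "swelling",
    "prescribed", "tamoxifen", "anastrozole", "tolerated", "infusion",
    "cycle", "completed.", "port", "flushed", "nutrition", "counselling",
    "referral;", "physical", "therapy", "ongoing", "blood", "pressure",
    "controlled", "diabetes", "managed", "social", "work", "consulted",
    "transportation", "arranged", "spouse", "present", "questions",
    "answered", "education", "provided", "handout", "given", "smoking",
    "cessation", "encouraged", "alcohol", "use:", "none", "exercise",
    "daily", "walking", "diet", "balanced", "weight", "steady", "mood",
    "euthymic", "anxiety", "mild", "coping", "fair", "support", "group")
}

note_specialties <- function() {
  c("medical oncology", "radiation oncology", "surgical oncology",
    "primary care", "gynecology", "palliative care")
}

single_word_keywords <- function() {
  c("germline", "BRCA", "BRCA1", "BRCA2", "PALB2", "CHEK2", "TP53", "PTEN",
    "Myriad", "Invitae")
}

filler_words <- function(n) {
  if (n <= 0L) return(character(0))
  sample(filler_vocabulary(), n, replace = TRUE)
}

# batch-generate `n` keyword-free filler notes with one RNG draw per quantity
filler_notes <- function(n, min_words = 20L, max_words = 120L) {
  if (n <= 0L) return(character(0))
  lens <- sample(min_words:max_words, n, replace = TRUE)
  words <- sample(filler_vocabulary(), sum(lens), replace = TRUE)
  grp <- factor(rep.int(seq_len(n), lens), levels = seq_len(n))
  unname(vapply(split(words, grp), paste, character(1), collapse = " "))
}

random_dates <- function(n) {
  days <- sample.int(730L, n, replace = TRUE) - 1L
  format(as.Date("2021-01-01") + days, "%Y-%m-%d")
}

# position (0-based) and length of the first lexicon keyword inside a phrase
keyword_position <- function(phrase) {
  cached <- .gta_cache$kw_pos[[phrase]]
  if (!is.null(cached)) return(cached)
  hits <- find_keyword_hits(phrase, default_lexicon())
  if (nrow(hits) == 0L) {
    stop("evidence phrase contains no lexicon keyword: ", phrase,
         call. = FALSE)
  }
  pos <- c(start = hits$start_word[1L],
           len = hits$end_word[1L] - hits$start_word[1L])
  if (is.null(.gta_cache$kw_pos)) .gta_cache$kw_pos <- list()
  .gta_cache$kw_pos[[phrase]] <- pos
  pos
}

# one chunk of `size` words whose embedded hit (a full evidence phrase or a
# bare keyword) sits near the centre, so the +/-100-word window around it
# covers the whole chunk
build_chunk <- function(size, hit_words, hit_kw_offset, hit_kw_len) {
  lp <- length(hit_words)
  centre <- max(0L, (size - hit_kw_len) %/% 2L - hit_kw_offset)
  a <- min(centre, size - lp)
  b <- size - lp - a
  c(filler_words(a), hit_words, filler_words(b))
}

#' Generate the text of one synthetic clinical note
#'
#' Evidence notes embed a category-consistent evidence phrase near a lexicon
#' keyword, padded with distractor filler so the note's single merged snippet
#' has exactly `target_words` words; notes longer than one context window
#' carry additional spaced bare keyword mentions so all windows merge into
#' one snippet. Zero-snippet notes are distractor filler only and contain no
#' lexicon keyword.
#'
#' Uses the current RNG state; wrap in `set.seed()` for reproducibility.
#'
#' @param label a four-category label (see [access_categories()]).
#' @param stratum one of `"zero_snippet"`, `"high_burden"`, `"normal"`.
#' @param target_words desired note word count; drawn from the default
#'   snippet word-count distribution when `NULL`. Ignored (drawn from a short
#'   administrative-note range) for zero-snippet notes.
#' @return character scalar: the note text.
#' @export
generate_note <- function(label, stratum = "normal", target_words = NULL) {
  assert_category(label)
  stratum <- match.arg(stratum, c("zero_snippet", "high_burden", "normal"))
  if (stratum == "zero_snippet" && label == "Yes") {
    stop("zero-snippet patients are always binary-negative; label 'Yes' is ",
         "inconsistent", call. = FALSE)
  }
  if (stratum == "high_burden" && label != "Yes") {
    stop("high-burden patients are always 'Yes'; got '", label, "'",
         call. = FALSE)
  }
  if (stratum == "zero_snippet") {
    n <- sample(20:120, 1L)
    return(paste(filler_words(n), collapse = " "))
  }
  if (is.null(target_words)) {
    d <- lnorm_from_quartiles(199, 124, 285)
    target_words <- max(20L, as.integer(round(rlnorm(1, d$meanlog, d$sdlog))))
  }
  w <- as.integer(target_words)
  phrase <- sample(phrase_bank(label), 1L)
  pw <- tokenize_words(phrase)
  kp <- keyword_position(phrase)
  w <- max(w, length(pw) + 4L)
  # chunk the note so consecutive keyword hits are < 200 words apart and all
  # context windows chain-merge into a single snippet spanning the whole note
  if (w <= 201L) {
    sizes <- w
  } else {
    m <- ceiling(w / 150)
    sizes <- c(rep(150L, m - 1L), w - 150L * (m - 1L))
    if (sizes[m] < 30L && m > 1L) {
      sizes <- c(sizes[seq_len(m - 2L)], sizes[m - 1L] + sizes[m])
    }
  }
  chunks <- vector("list", length(sizes))
  chunks[[1L]] <- build_chunk(sizes[1L], pw, kp[["start"]], kp[["len"]])
  if (length(sizes) > 1L) {
    for (i in 2L:length(sizes)) {
      kw <- sample(single_word_keywords(), 1L)
      chunks[[i]] <- build_chunk(sizes[i], kw, 0L, 1L)
    }
  }
  paste(unlist(chunks), collapse = " ")
}

# draw (snippet count, snippet word vector) for one snippet-bearing patient.
#
# Snippet lengths share a patient-level log-scale factor anti-correlated
# with the patient's snippet count: patients with many concept mentions have
# shorter, more repetitive snippets (in real corpora nearby windows overlap
# and merge). Most of the log-length variance (95%) sits at the patient
# level; the split is calibrated so the emergent consolidated-document
# median approaches its published value (800 words), which independent
# per-snippet draws structurally overshoot, while the marginal length
# distribution keeps its published median and IQR. The high-burden stratum
# is the natural upper tail of the same joint distribution (>= 20 snippets
# or > 4,000 total words), enforced by rejection so marginal medians stay at
# their calibrated values.
draw_snippet_profile <- function(config, high) {
  kd <- config$snippets_per_patient_dist
  wd <- config$snippet_words_dist
  sd_patient <- 0.95 * wd$sdlog
  sd_note <- sqrt(wd$sdlog^2 - sd_patient^2)
  slope <- if (kd$sdlog > 0) sd_patient / kd$sdlog else 0
  repeat {
    kc <- rlnorm(1, kd$meanlog, kd$sdlog)
    k <- min(100L, max(1L, as.integer(round(kc))))
    zk <- log(kc) - kd$meanlog
    w <- pmin(4000L, pmax(20L, as.integer(round(exp(
      wd$meanlog - slope * zk + rnorm(k, 0, sd_note))))))
    is_high <- (k >= 20L) || (sum(w) > 4000L)
    if (is_high == high) return(list(k = k, words = w))
  }
}

largest_remainder <- function(targets) {
  fl <- floor(targets)
  extra <- as.integer(round(sum(targets))) - as.integer(sum(fl))
  if (extra > 0L) {
    ord <- order(targets - fl, decreasing = TRUE)
    fl[ord[seq_len(extra)]] <- fl[ord[seq_len(extra)]] + 1L
  }
  as.integer(fl)
}

# joint (label, stratum) assignment preserving both marginals:
# zero-snippet mass is spread over the negative labels proportionally,
# high-burden mass is all "Yes", the normal stratum takes the remainder
allocate_cells <- function(config) {
  p <- config$label_probs
  pz <- config$zero_snippet_frac
  ph <- config$high_burden_frac
  neg <- c("No", "NotApplicable", "NotSure")
  p_neg <- sum(p[neg])
  joint <- rbind(
    zero_snippet = c(Yes = 0, pz * p[neg] / p_neg),
    high_burden = c(Yes = ph, No = 0, NotApplicable = 0, NotSure = 0),
    normal = c(Yes = p[["Yes"]] - ph, p[neg] - pz * p[neg] / p_neg))
  colnames(joint) <- access_categories()
  n <- config$n_patients
  if (!config$exact_fractions) {
    cells <- expand.grid(stratum = rownames(joint),
                         label = colnames(joint),
                         stringsAsFactors = FALSE)
    idx <- sample.int(nrow(cells), n, replace = TRUE,
                      prob = as.vector(joint))
    out <- cells[idx, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  # exact mode: largest-remainder on label marginals, then stratum totals,
  # then spread the zero-snippet quota over negative labels
  lab_tot <- largest_remainder(n * p)
  names(lab_tot) <- access_categories()
  str_tot <- largest_remainder(n * c(pz, ph, 1 - pz - ph))
  names(str_tot) <- c("zero_snippet", "high_burden", "normal")
  if (str_tot[["high_burden"]] > lab_tot[["Yes"]] ||
      str_tot[["zero_snippet"]] > sum(lab_tot[neg])) {
    stop("exact allocation infeasible for this configuration", call. = FALSE)
  }
  zero_by_lab <- largest_remainder(str_tot[["zero_snippet"]] *
                                     p[neg] / p_neg)
  names(zero_by_lab) <- neg
  if (any(zero_by_lab > lab_tot[neg])) {
    stop("exact allocation infeasible: zero-snippet quota exceeds a ",
         "negative label count", call. = FALSE)
  }
  rows <- character(0); labs <- character(0)
  add <- function(stratum, label, count) {
    if (count > 0L) {
      rows <<- c(rows, rep(stratum, count))
      labs <<- c(labs, rep(label, count))
    }
  }
  for (l in neg) add("zero_snippet", l, zero_by_lab[[l]])
  add("high_burden", "Yes", str_tot[["high_burden"]])
  add("normal", "Yes", lab_tot[["Yes"]] - str_tot[["high_burden"]])
  for (l in neg) add("normal", l, lab_tot[[l]] - zero_by_lab[[l]])
  perm <- sample.int(length(rows))
  data.frame(stratum = rows[perm], label = labs[perm],
             stringsAsFactors = FALSE)
}

#' Simulate dual independent review with adjudication
#'
#' The adjudicated consensus always equals the truth. With probability
#' `disagreement_rate` exactly one of the two reviewers (chosen at random) is
#' perturbed to a semantically adjacent category (Yes-NotSure, No-NotApplicable,
#' NotSure-No/Yes); otherwise both reviewers agree with the consensus.
#' Vectorised over `truth`; uses the current RNG state.
#'
#' @param truth character vector of four-category consensus labels.
#' @param disagreement_rate probability in `[0, 1]`.
#' @return data.frame with columns `reviewer1`, `reviewer2`, `consensus`,
#'   `disagreement` (logical).
#' @export
simulate_reviews <- function(truth, disagreement_rate = 0.145) {
  assert_category(truth)
  stopifnot(disagreement_rate >= 0, disagreement_rate <= 1)
  n <- length(truth)
  r1 <- truth
  r2 <- truth
  if (n > 0L) {
    dis <- runif(n) < disagreement_rate
    for (i in which(dis)) {
      nb <- category_neighbours(truth[i])
      perturbed <- if (length(nb) == 1L) nb else sample(nb, 1L)
      if (sample.int(2L, 1L) == 1L) r1[i] <- perturbed else r2[i] <- perturbed
    }
  } else {
    dis <- logical(0)
  }
  data.frame(reviewer1 = r1, reviewer2 = r2, consensus = truth,
             disagreement = dis, stringsAsFactors = FALSE)
}

#' Generate a labeled synthetic note corpus
#'
#' Produces, for each simulated patient, a set of dated clinical notes (free
#' text), a ground-truth four-category access label, a triage stratum tag,
#' and a simulated dual-review record. Zero-snippet patients contain no
#' lexicon keyword anywhere; high-burden patients naturally carry at least 20
#' snippets or a consolidated document exceeding 4,000 words; all other
#' patients carry label-consistent evidence phrases. The same configuration
#' (including seed) always yields a byte-identical corpus.
#'
#' @param config a [cohort_config()].
#' @return list of class `"access_cohort"` with elements `notes` (data.frame:
#'   `patient_id`, `note_id`, `note_date`, `specialty`, `text`), `labels`
#'   (data.frame: `patient_id`, `truth_label`, `stratum`, `reviewer1`,
#'   `reviewer2`, `consensus`, `disagreement`), and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  empty_notes <- data.frame(patient_id = character(0), note_id = character(0),
                            note_date = character(0), specialty = character(0),
                            text = character(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    labels <- data.frame(patient_id = character(0), truth_label = character(0),
                         stratum = character(0), reviewer1 = character(0),
                         reviewer2 = character(0), consensus = character(0),
                         disagreement = logical(0), stringsAsFactors = FALSE)
    return(structure(list(notes = empty_notes, labels = labels,
                          config = config), class = "access_cohort"))
  }
  with_seed(config$seed, {
    cells <- allocate_cells(config)
    nd <- config$notes_per_patient_dist
    pid <- sprintf("P%05d", seq_len(n))
    note_rows <- vector("list", n)
    for (i in seq_len(n)) {
      stratum <- cells$stratum[i]
      label <- cells$label[i]
      n_notes <- min(400L, max(1L, as.integer(round(
        rlnorm(1, nd$meanlog, nd$sdlog)))))
      if (stratum == "zero_snippet") {
        texts <- filler_notes(n_notes)
      } else {
        prof <- draw_snippet_profile(config, stratum == "high_burden")
        n_notes <- max(n_notes, prof$k)
        texts <- character(n_notes)
        ev_slots <- sample.int(n_notes, prof$k)
        for (j in seq_len(prof$k)) {
          texts[ev_slots[j]] <- generate_note(label, stratum, prof$words[j])
        }
        texts[-ev_slots] <- filler_notes(n_notes - prof$k)
      }
      note_rows[[i]] <- data.frame(
        patient_id = pid[i],
        note_id = sprintf("%s-N%03d", pid[i], seq_len(n_notes)),
        note_date = random_dates(n_notes),
        specialty = sample(note_specialties(), n_notes, replace = TRUE),
        text = texts, stringsAsFactors = FALSE)
    }
    reviews <- simulate_reviews(cells$label, config$disagreement_rate)
    labels <- data.frame(patient_id = pid, truth_label = cells$label,
                         stratum = cells$stratum, reviews,
                         stringsAsFactors = FALSE)
    notes <- do.call(rbind, note_rows)
    rownames(notes) <- NULL
    structure(list(notes = notes, labels = labels, config = config),
              class = "access_cohort")
  })
}

#' @export
print.access_cohort <- function(x, ...) {
  cat(sprintf("<access_cohort: %d patients, %d notes>\n",
              nrow(x$labels), nrow(x$notes)))
  invisible(x)
}
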