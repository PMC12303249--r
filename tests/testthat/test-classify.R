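test_that("binary consolidation maps exactly one category to positive", {
  expect_identical(consolidate_to_binary("Yes"), "positive")
  expect_identical(consolidate_to_binary(c("No", "NotApplicable", "NotSure")),
                   rep("negative", 3))
  expect_setequal(unique(consolidate_to_binary(access_categories())),
                  binary_levels())
  expect_error(consolidate_to_binary("Maybe"), "invalid label")
})

test_that("build_prompt substitutes the document exactly once", {
  tpl <- default_prompt_template()
  doc <- list(text = "UNIQUEDOCTOKEN alpha beta")
  p1 <- build_prompt(doc, tpl)
  expect_identical(
    lengths(regmatches(p1, gregexpr("UNIQUEDOCTOKEN", p1))), 1L)
  expect_identical(p1, build_prompt(doc, tpl))
  # the four category names appear in the rendered prompt
  for (nm in c("Yes", "No", "Not applicable", "Not sure")) {
    expect_match(p1, nm, fixed = TRUE)
  }
  # rendered word count = template word count + document word count - 1
  # (the placeholder itself is one template word)
  tpl_words <- length(tokenize_words(unclass(tpl)))
  expect_identical(length(tokenize_words(p1)), tpl_words - 1L + 3L)
  expect_error(build_prompt(list(text = "")), "AUTO_NEGATIVE")
})

test_that("template files must contain the placeholder exactly once", {
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("no placeholder here", bad)
  expect_error(read_prompt_template(bad), "exactly once")
})

test_that("parse_response extracts scaffolded answers and close variants", {
  cases <- list(
    list("ANSWER: Yes\nThe patient was referred for testing.", "Yes", TRUE),
    list("answer: not applicable\nRATIONALE: community care.",
         "NotApplicable", TRUE),
    list("Answer - unsure", "NotSure", TRUE),
    list("ANSWER: N/A", "NotApplicable", TRUE),
    list("ANSWER= no", "No", TRUE),
    list("ANSWER: Not sure", "NotSure", TRUE),
    list("I cannot determine this.", "NotSure", FALSE),
    list("", "NotSure", FALSE))
  for (cs in cases) {
    got <- parse_response(cs[[1]])
    expect_identical(got$category, cs[[2]], info = cs[[1]])
    expect_identical(got$parse_ok, cs[[3]], info = cs[[1]])
  }
})

test_that("parse_response round-trips every category under random wrapping", {
  pretty <- c(Yes = "Yes", No = "No", NotApplicable = "Not applicable",
              NotSure = "Not sure")
  set.seed(12)
  junk <- function() paste(sample(c("the", "model", "says", "clearly",
                                    "based", "on", "evidence"),
                                  sample(0:6, 1), replace = TRUE),
                           collapse = " ")
  for (rep in 1:25) {
    for (cat in names(pretty)) {
      resp <- sprintf("%s\nANSWER: %s\nRATIONALE: %s", junk(), pretty[[cat]],
                      junk())
      expect_identical(parse_response(resp)$category, cat)
      expect_true(parse_response(resp)$parse_ok)
    }
  }
})

test_that("generation settings default to the reference sampling values", {
  s <- generation_settings()
  expect_identical(s$temperature, 0.75)
  expect_identical(s$top_p, 0.9)
  expect_error(generation_settings(top_p = 0), "top_p")
  expect_error(generation_settings(temperature = -1))
})

test_that("scripted backend replays by patient id, prompt, then default", {
  be <- scripted_backend(list(p1 = "ANSWER: Yes", "full prompt" = "ANSWER: No"),
                         default = "ANSWER: Not sure")
  expect_identical(be$complete("anything", patient_id = "p1"), "ANSWER: Yes")
  expect_identical(be$complete("full prompt"), "ANSWER: No")
  expect_identical(be$complete("unknown"), "ANSWER: Not sure")
})

test_that("heuristic backend recovers planted categories at error rate 0", {
  co <- generate_cohort(cohort_config(n_patients = 60, seed = 21))
  docs <- build_patient_documents(co$notes)
  tri <- triage_corpus(docs)
  preds <- classify_cohort(docs, tri, heuristic_backend(error_rate = 0))
  truth <- co$labels$truth_label[match(preds$patient_id,
                                       co$labels$patient_id)]
  routed <- preds$route == "TO_CLASSIFIER"
  expect_true(all(preds$category[routed] == truth[routed]))
  expect_true(all(preds$parse_ok))
  # auto routes never carry raw responses
  expect_true(all(preds$raw_response[!routed] == ""))
})

test_that("heuristic backend error injection is calibrated and seeded", {
  be <- heuristic_backend(error_rate = 1, seed = 2)
  r <- be$complete("document mentions that testing was ordered today")
  expect_false(parse_response(r)$category == "Yes")
  expect_true(parse_response(r)$parse_ok)

  be1 <- heuristic_backend(error_rate = 0.1, seed = 7)
  flips <- vapply(1:1000, function(i) {
    parse_response(be1$complete("note: referral placed for counseling"))$category != "Yes"
  }, logical(1))
  se <- sqrt(0.1 * 0.9 / 1000)
  expect_lt(abs(mean(flips) - 0.1) , 3 * se)
  # same seed, same call order -> identical responses
  be2a <- heuristic_backend(error_rate = 0.3, seed = 5)
  be2b <- heuristic_backend(error_rate = 0.3, seed = 5)
  r1 <- vapply(1:50, function(i) be2a$complete("testing was ordered"),
               character(1))
  r2 <- vapply(1:50, function(i) be2b$complete("testing was ordered"),
               character(1))
  expect_identical(r1, r2)
})

test_that("classify_cohort short-circuits auto routes and survives failures", {
  # only zero-snippet patients: the backend must never be invoked
  bomb <- structure(list(name = "bomb",
                         complete = function(prompt, settings, patient_id) {
                           stop("backend must not be called")
                         }), class = "classifier_backend")
  docs <- data.frame(patient_id = c("a", "b"), text = c("", ""),
                     snippet_count = c(0L, 0L), word_count = c(0L, 0L),
                     stringsAsFactors = FALSE)
  tri <- triage_corpus(docs)
  preds <- classify_cohort(docs, tri, bomb)
  expect_identical(preds$binary, c("negative", "negative"))
  expect_true(all(preds$parse_ok))

  # scripted all-Yes: every routed patient positive
  docs2 <- rbind(docs, data.frame(patient_id = "c", text = "some germline text",
                                  snippet_count = 2L, word_count = 3L))
  tri2 <- triage_corpus(docs2)
  preds2 <- classify_cohort(docs2, tri2,
                            scripted_backend(default = "ANSWER: Yes"))
  expect_identical(preds2$binary[preds2$route == "TO_CLASSIFIER"], "positive")

  # per-patient failure is recorded, run continues; all-fail errors
  half_bomb <- structure(list(
    name = "half", complete = function(prompt, settings, patient_id) {
      if (identical(patient_id, "c")) stop("boom") else "ANSWER: No"
    }), class = "classifier_backend")
  docs3 <- rbind(docs2, data.frame(patient_id = "d",
                                   text = "more germline text",
                                   snippet_count = 1L, word_count = 3L))
  tri3 <- triage_corpus(docs3)
  preds3 <- classify_cohort(docs3, tri3, half_bomb)
  expect_false(preds3$parse_ok[preds3$patient_id == "c"])
  expect_identical(preds3$category[preds3$patient_id == "c"], "NotSure")
  expect_identical(preds3$category[preds3$patient_id == "d"], "No")
  expect_error(classify_cohort(docs3, tri3, bomb), "every routed patient")
})

test_that("end-to-end mock classification is deterministic", {
  co <- generate_cohort(cohort_config(n_patients = 40, seed = 77))
  docs <- build_patient_documents(co$notes)
  tri <- triage_corpus(docs)
  p1 <- classify_cohort(docs, tri, heuristic_backend(0.2, seed = 9))
  p2 <- classify_cohort(docs, tri, heuristic_backend(0.2, seed = 9))
  expect_identical(p1, p2)
})
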