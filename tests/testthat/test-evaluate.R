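test_that("confusion counts cells correctly", {
  ident <- confusion(rep("positive", 5), rep("positive", 5))
  expect_identical(unclass(ident)[c("tp", "fp", "fn", "tn")],
                   list(tp = 5L, fp = 0L, fn = 0L, tn = 0L))
  empty <- confusion(character(0), character(0))
  expect_identical(empty$tp + empty$fp + empty$fn + empty$tn, 0L)
  expect_error(confusion("positive", character(0)), "equal length")
  expect_error(confusion("yes", "positive"), "'positive' or 'negative'")
  p <- planned_binary(56, 4, 3, 37)
  cm <- confusion(p$pred, p$truth)
  expect_identical(c(cm$tp, cm$fp, cm$fn, cm$tn), c(56L, 4L, 3L, 37L))
})

test_that("metrics handle degenerate denominators with undefined markers", {
  m <- metrics(confusion_matrix(0, 0, 0, 10))
  expect_identical(m$accuracy, 1)
  expect_true(is.na(m$precision) && is.na(m$recall) && is.na(m$f1))
  m0 <- metrics(confusion_matrix(0, 0, 0, 0))
  expect_true(all(is.na(unlist(m0[c("accuracy", "precision", "recall",
                                    "f1")]))))
  expect_error(confusion_matrix(-1, 0, 0, 0), "non-negative")
})

test_that("f1 is the harmonic mean of precision and recall, pre-rounding", {
  set.seed(14)
  for (rep in 1:50) {
    cm <- confusion_matrix(sample(1:60, 1), sample(0:20, 1), sample(0:20, 1),
                           sample(1:60, 1))
    m <- metrics(cm)
    expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant under case reordering", {
  set.seed(15)
  pred <- sample(binary_levels(), 80, replace = TRUE)
  truth <- sample(binary_levels(), 80, replace = TRUE)
  perm <- sample.int(80)
  expect_identical(metrics(confusion(pred, truth)),
                   metrics(confusion(pred[perm], truth[perm])))
})

test_that("bootstrap CIs are degenerate where they must be", {
  p <- planned_binary(10, 0, 0, 10)
  bs <- bootstrap_ci(p$pred, p$truth, iterations = 200, seed = 3)
  for (m in c("accuracy", "precision", "recall", "f1")) {
    expect_identical(bs$ci[[m]]$lower, 1)
    expect_identical(bs$ci[[m]]$upper, 1)
  }
  # a single replicate yields an interval equal to that replicate's value
  q <- planned_binary(5, 2, 1, 4)
  one <- bootstrap_ci(q$pred, q$truth, iterations = 1, seed = 9)
  expect_identical(one$ci$accuracy$lower, one$ci$accuracy$upper)
  expect_identical(one$ci$accuracy$mean, one$ci$accuracy$lower)
  # seeded determinism
  a <- bootstrap_ci(q$pred, q$truth, iterations = 300, seed = 11)
  b <- bootstrap_ci(q$pred, q$truth, iterations = 300, seed = 11)
  expect_identical(a, b)
})

test_that("bootstrap means converge to the point estimates", {
  p <- planned_binary(40, 5, 4, 31)
  small <- bootstrap_ci(p$pred, p$truth, iterations = 200, seed = 5)
  big <- bootstrap_ci(p$pred, p$truth, iterations = 5000, seed = 5)
  for (m in c("accuracy", "precision", "recall", "f1")) {
    expect_lt(abs(big$ci[[m]]$mean - small[[m]]), 0.01)
    expect_lt(abs(big$ci[[m]]$mean - big[[m]]), 0.01)
  }
})

test_that("undefined replicates are skipped and counted", {
  # one lonely positive: many resamples lose it and recall is undefined
  p <- planned_binary(1, 0, 0, 9)
  bs <- bootstrap_ci(p$pred, p$truth, iterations = 500, seed = 21)
  expect_gt(bs$ci$recall$skipped, 0)
  expect_identical(bs$ci$recall$lower, 1)  # defined replicates are all 1
})

test_that("stratified_split balances every stratum to within one case", {
  set.seed(33)
  for (rep in 1:40) {
    n <- sample(3:120, 1)
    cases <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      consensus = sample(access_categories(), n, replace = TRUE),
      disagreement = sample(c(TRUE, FALSE), n, replace = TRUE))
    sp <- stratified_split(cases, seed = rep)
    expect_identical(nrow(sp), n)
    key <- paste(cases$consensus, cases$disagreement)
    for (k in unique(key)) {
      dev <- sum(sp$split == "development" & key == k)
      tst <- sum(sp$split == "testing" & key == k)
      expect_lte(abs(dev - tst), 1L)
    }
  }
  # a stratum of size one lands in exactly one half
  lone <- data.frame(patient_id = "solo", consensus = "Yes",
                     disagreement = FALSE)
  expect_identical(nrow(stratified_split(lone, seed = 1)), 1L)
  expect_identical(nrow(stratified_split(lone[0, ], seed = 1)), 0L)
})

test_that("an even composition reproduces identical label counts per half", {
  # strata engineered even so the halves match exactly
  comp <- c(Yes = 118, No = 62, NotApplicable = 10, NotSure = 10)
  cases <- data.frame(
    patient_id = sprintf("P%03d", 1:200),
    consensus = rep(names(comp), comp),
    disagreement = unlist(lapply(comp, function(m) {
      rep(c(FALSE, TRUE), c(m - 4, 4))
    })))
  sp <- stratified_split(cases, seed = 19)
  for (half in c("development", "testing")) {
    counts <- table(cases$consensus[sp$split == half])
    expect_identical(as.integer(counts[names(comp)]),
                     as.integer(comp / 2))
  }
})

test_that("agreed_subset filters on the disagreement flag", {
  rr <- data.frame(patient_id = sprintf("P%d", 1:10),
                   disagreement = rep(c(FALSE, TRUE), 5))
  expect_identical(agreed_subset(rr)$patient_id, sprintf("P%d", seq(1, 9, 2)))
  all_agree <- data.frame(patient_id = "x", disagreement = FALSE)
  expect_identical(agreed_subset(all_agree), all_agree)
  flipped <- rr
  flipped$disagreement <- !rr$disagreement
  expect_setequal(c(agreed_subset(rr)$patient_id,
                    agreed_subset(flipped)$patient_id),
                  rr$patient_id)
})

test_that("reviewer accuracy scores the binary consolidation", {
  consensus <- c("Yes", "Yes", "No", "NotSure", "NotApplicable")
  # reviewer matches consensus exactly
  r <- reviewer_accuracy(list(a = consensus), consensus)
  expect_identical(unname(r$per_reviewer), 1)
  # NotSure vs No disagree in category but agree in binary
  shifted <- c("Yes", "Yes", "NotSure", "No", "No")
  r2 <- reviewer_accuracy(list(a = shifted), consensus)
  expect_identical(unname(r2$per_reviewer), 1)
  # two reviewers at 0.8 and 1.0 -> mean 0.9
  r3 <- reviewer_accuracy(
    list(a = c("No", "Yes", "No", "No", "No"), b = consensus), consensus)
  expect_equal(unname(r3$per_reviewer), c(0.8, 1))
  expect_equal(r3$mean, 0.9)
  expect_warning(
    reviewer_accuracy(list(a = consensus, b = character(0)), consensus),
    "zero cases")
})

test_that("chi-square operations match the direct formula and stats oracle", {
  # identical proportions: statistic 0, p 1
  z <- chi_square_compare(10, 20, 10, 20)
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  set.seed(44)
  for (rep in 1:30) {
    na <- sample(10:80, 1); nb <- sample(10:80, 1)
    sa <- sample.int(na - 1, 1); sb <- sample.int(nb - 1, 1)
    tab <- rbind(c(sa, na - sa), c(sb, nb - sb))
    for (corr in c(FALSE, TRUE)) {
      ours <- chi_square_compare(sa, na, sb, nb, correct = corr)
      ref <- suppressWarnings(stats::chisq.test(tab, correct = corr))
      expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
    }
  }
  # k x 2 distribution comparison vs direct sum((O-E)^2/E)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    a <- sample(1:40, k, replace = TRUE)
    b <- sample(1:40, k, replace = TRUE)
    ours <- chi_square_distribution(a, b)
    obs <- cbind(a, b)
    expe <- outer(rowSums(obs), colSums(obs)) / sum(obs)
    expect_equal(ours$statistic, sum((obs - expe)^2 / expe),
                 tolerance = 1e-12)
    expect_identical(ours$df, (k - 1L))
    ref <- suppressWarnings(stats::chisq.test(obs, correct = FALSE))
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
  # k = 2 reduces to the two-proportion comparison without correction
  two <- chi_square_distribution(c(30, 70), c(45, 55))
  cmp <- chi_square_compare(30, 100, 45, 100, correct = FALSE)
  expect_equal(two$statistic, cmp$statistic, tolerance = 1e-12)
  expect_warning(chi_square_compare(0, 5, 0, 7), "zero expected")
})
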