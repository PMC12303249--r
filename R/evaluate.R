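#' Confusion matrix for binary access predictions
#'
#' `positive` means access to testing was identified. `tp` counts
#' positive-truth/positive-prediction, `fn` positive-truth/negative-prediction,
#' `fp` negative-truth/positive-prediction, `tn` the rest.
#'
#' @param predictions,truth aligned character vectors of
#'   `"positive"`/`"negative"`.
#' @return list of class `"confusion_matrix"` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(predictions, truth) {
  if (length(predictions) != length(truth)) {
    stop("predictions and truth must have equal length", call. = FALSE)
  }
  ok <- c("positive", "negative")
  if (!all(predictions %in% ok) || !all(truth %in% ok)) {
    stop("labels must be 'positive' or 'negative'", call. = FALSE)
  }
  confusion_matrix(
    tp = sum(predictions == "positive" & truth == "positive"),
    fp = sum(predictions == "positive" & truth == "negative"),
    fn = sum(predictions == "negative" & truth == "positive"),
    tn = sum(predictions == "negative" & truth == "negative"))
}

#' @rdname confusion
#' @param tp,fp,fn,tn non-negative cell counts.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix tp=%d fp=%d fn=%d tn=%d>\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(tp+tn)/n`, precision `tp/(tp+fp)`, recall `tp/(tp+fn)`, and F1
#' (the harmonic mean of precision and recall). Degenerate denominators yield
#' `NA` (the undefined marker): no predicted positives leaves precision (and
#' hence F1) undefined; no true positives in the truth leaves recall
#' undefined; an empty matrix leaves everything undefined. Values are exact;
#' rounding to 3 decimals happens only at presentation.
#'
#' @param cm a `confusion_matrix`.
#' @return list of class `"metric_set"` with `accuracy`, `precision`,
#'   `recall`, `f1`, and `n`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  acc <- if (n > 0) (cm$tp + cm$tn) / n else NA_real_
  prec <- if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else NA_real_
  rec <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else {
    NA_real_
  }
  structure(list(accuracy = acc, precision = prec, recall = rec, f1 = f1,
                 n = as.integer(n)), class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 3, ...) {
  fmt <- function(v) ifelse(is.na(v), "undef", formatC(v, digits = digits,
                                                       format = "f"))
  cat(sprintf("<metric_set n=%d accuracy=%s f1=%s precision=%s recall=%s>\n",
              x$n, fmt(x$accuracy), fmt(x$f1), fmt(x$precision),
              fmt(x$recall)))
  if (!is.null(x$ci)) {
    for (m in names(x$ci)) {
      ci <- x$ci[[m]]
      cat(sprintf("  %s: mean %s (%s to %s)%s\n", m, fmt(ci$mean),
                  fmt(ci$lower), fmt(ci$upper),
                  if (ci$skipped > 0) sprintf(" [%d undefined replicates skipped]",
                                              ci$skipped) else ""))
    }
  }
  invisible(x)
}

#' Percentile-bootstrap confidence intervals for classification metrics
#'
#' Resamples cases with replacement, n-out-of-n, `iterations` times and takes
#' the empirical `(1-level)/2` and `1-(1-level)/2` quantiles of each metric
#' across replicates, together with the bootstrap mean. Replicates in which a
#' metric is undefined (e.g. a resample with no predicted positives) are
#' skipped for that metric and counted; if every replicate is undefined the
#' metric's interval is `NA` with a warning. Deterministic for a fixed seed.
#'
#' @inheritParams confusion
#' @param iterations number of bootstrap replicates (default 5000).
#' @param level confidence level (default 0.95).
#' @param seed integer RNG seed.
#' @return a `metric_set` (point estimates on the full data) with an extra
#'   `ci` element: per metric, a list of `mean`, `lower`, `upper`, `skipped`.
#' @export
bootstrap_ci <- function(predictions, truth, iterations = 5000L,
                         level = 0.95, seed = 1L) {
  n <- length(truth)
  stopifnot(n >= 2L, iterations >= 1L, level > 0, level < 1)
  point <- metrics(confusion(predictions, truth))
  # each case falls in one confusion cell; a resample is a cell-count vector
  cell <- ifelse(predictions == "positive",
                 ifelse(truth == "positive", 1L, 2L),
                 ifelse(truth == "positive", 3L, 4L))
  boot <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * iterations, replace = TRUE),
                  nrow = n, ncol = iterations)
    m <- matrix(cell[idx], nrow = n, ncol = iterations)
    tp <- colSums(m == 1L); fp <- colSums(m == 2L)
    fn <- colSums(m == 3L); tn <- colSums(m == 4L)
    acc <- (tp + tn) / n
    prec <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
    rec <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
    f1 <- ifelse(!is.na(prec) & !is.na(rec) & prec + rec > 0,
                 2 * prec * rec / (prec + rec), NA_real_)
    list(accuracy = acc, precision = prec, recall = rec, f1 = f1)
  })
  alpha <- (1 - level) / 2
  ci <- lapply(names(boot), function(mname) {
    v <- boot[[mname]]
    skipped <- sum(is.na(v))
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      warning("all bootstrap replicates undefined for ", mname)
      return(list(mean = NA_real_, lower = NA_real_, upper = NA_real_,
                  skipped = skipped))
    }
    q <- unname(quantile(v, c(alpha, 1 - alpha)))
    list(mean = mean(v), lower = q[1L], upper = q[2L], skipped = skipped)
  })
  names(ci) <- names(boot)
  point$ci <- ci
  point
}

#' Stratified development/testing split
#'
#' Cases are stratified by the four-category consensus label crossed with the
#' reviewer-disagreement flag; each stratum is shuffled and allocated
#' proportionally, so both halves have near-identical label and disagreement
#' composition. When a stratum splits unevenly, the extra case alternates
#' between development and testing across strata (in sorted stratum order) so
#' neither half accumulates all the remainders. Deterministic per seed.
#'
#' @param cases data.frame with columns `patient_id`, `consensus`,
#'   `disagreement`.
#' @param fraction development-set fraction in `(0, 1)` (default 0.5).
#' @param seed integer RNG seed.
#' @return data.frame with columns `patient_id`, `split`
#'   (`"development"`/`"testing"`), in the input case order.
#' @export
stratified_split <- function(cases, fraction = 0.5, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  if (nrow(cases) == 0L) {
    return(data.frame(patient_id = character(0), split = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(cases$consensus, cases$disagreement, sep = "|")
  split_of <- character(nrow(cases))
  with_seed(seed, {
    toggle <- TRUE
    for (stratum in sort(unique(key))) {
      idx <- which(key == stratum)
      idx <- idx[sample.int(length(idx))]
      m <- length(idx)
      n_dev <- floor(m * fraction)
      if (m * fraction - n_dev > 1e-9) {
        if (toggle) n_dev <- n_dev + 1L
        toggle <- !toggle
      }
      split_of[idx[seq_len(n_dev)]] <- "development"
      if (n_dev < m) split_of[idx[(n_dev + 1L):m]] <- "testing"
    }
  })
  data.frame(patient_id = cases$patient_id, split = split_of,
             stringsAsFactors = FALSE)
}

#' Subset of cases without initial reviewer disagreement
#'
#' @param reviews data.frame with a logical `disagreement` column (e.g. the
#'   `labels` element of an `access_cohort`).
#' @return the rows of `reviews` where the two initial reviewers agreed.
#' @export
agreed_subset <- function(reviews) {
  stopifnot("disagreement" %in% names(reviews))
  reviews[!reviews$disagreement, , drop = FALSE]
}

#' Per-reviewer accuracy against the adjudicated consensus
#'
#' Accuracy is computed on the binary consolidation (the same scale used to
#' score the pipeline): the fraction of cases where the reviewer's
#' consolidated label matches the consolidated consensus. Reviewers with zero
#' cases are excluded with a warning. The mean is unweighted across
#' reviewers.
#'
#' @param reviewer_labels named list (or data.frame) of per-reviewer
#'   four-category label vectors.
#' @param consensus four-category consensus vector aligned with each
#'   reviewer's cases.
#' @return list with `per_reviewer` (named numeric) and `mean`.
#' @export
reviewer_accuracy <- function(reviewer_labels, consensus) {
  reviewer_labels <- as.list(reviewer_labels)
  truth_bin <- consolidate_to_binary(consensus)
  acc <- vapply(names(reviewer_labels), function(r) {
    lab <- reviewer_labels[[r]]
    if (length(lab) == 0L) {
      warning("reviewer '", r, "' has zero cases; excluded")
      return(NA_real_)
    }
    stopifnot(length(lab) == length(consensus))
    mean(consolidate_to_binary(lab) == truth_bin)
  }, numeric(1))
  acc <- acc[!is.na(acc)]
  list(per_reviewer = acc, mean = mean(acc))
}

#' Chi-square comparison of two proportions
#'
#' Pearson chi-square on the 2x2 correct/incorrect contingency table, with an
#' optional Yates continuity correction; the two-sided p-value comes from the
#' chi-square distribution with 1 degree of freedom.
#'
#' @param successes_a,n_a,successes_b,n_b counts and totals for the two
#'   groups.
#' @param correct apply the Yates continuity correction.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_square_compare <- function(successes_a, n_a, successes_b, n_b,
                               correct = FALSE) {
  stopifnot(n_a > 0, n_b > 0, successes_a <= n_a, successes_b <= n_b,
            successes_a >= 0, successes_b >= 0)
  obs <- rbind(c(successes_a, n_a - successes_a),
               c(successes_b, n_b - successes_b))
  pearson_chisq(obs, correct = correct)
}

#' Chi-square comparison of two category distributions
#'
#' Pearson chi-square on the k x 2 contingency table formed by two vectors of
#' category counts (e.g. the access-category distribution identified by the
#' pipeline against the expert-identified distribution), with `k - 1` degrees
#' of freedom.
#'
#' @param counts_a,counts_b aligned non-negative count vectors over the same
#'   categories.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_square_distribution <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == length(counts_b),
            all(counts_a >= 0), all(counts_b >= 0),
            sum(counts_a) > 0, sum(counts_b) > 0)
  pearson_chisq(cbind(counts_a, counts_b), correct = FALSE)
}

pearson_chisq <- function(obs, correct = FALSE) {
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  if (any(expected == 0)) {
    warning("zero expected cell; chi-square statistic undefined")
    return(list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_))
  }
  dev <- abs(obs - expected)
  if (correct) dev <- pmax(0, dev - 0.5)
  stat <- sum(dev^2 / expected)
  df <- (nrow(obs) - 1L) * (ncol(obs) - 1L)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}
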