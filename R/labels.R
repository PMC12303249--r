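#' Four-category access labels and their binary consolidation
#'
#' Chart review assigns each patient one of four categories describing access
#' to germline genetic testing: `"Yes"` (testing performed, recommended, or a
#' referral/consult to genetic counseling was placed), `"No"` (seen by a
#' relevant provider without meeting any "Yes" criterion), `"NotApplicable"`
#' (all breast-cancer care delivered through community care), and `"NotSure"`
#' (considered for testing but criteria not met). For evaluation the three
#' non-"Yes" categories are consolidated into a single negative class.
#'
#' @return `access_categories()` returns the four category names in canonical
#'   order; `binary_levels()` returns `c("positive", "negative")`.
#' @examples
#' access_categories()
#' consolidate_to_binary(c("Yes", "NotSure"))
#' @export
access_categories <- function() {
  c("Yes", "No", "NotApplicable", "NotSure")
}

#' @rdname access_categories
#' @export
binary_levels <- function() {
  c("positive", "negative")
}

assert_category <- function(x, what = "label") {
  bad <- !x %in% access_categories()
  if (any(bad)) {
    stop(sprintf("invalid %s: %s (expected one of %s)", what,
                 paste(unique(x[bad]), collapse = ", "),
                 paste(access_categories(), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Consolidate a four-category label to the binary outcome
#'
#' `"Yes"` maps to `"positive"` (access to testing identified); `"No"`,
#' `"NotApplicable"`, and `"NotSure"` all map to `"negative"`. Vectorised.
#'
#' @param label character vector of four-category labels.
#' @return character vector of `"positive"`/`"negative"`.
#' @export
consolidate_to_binary <- function(label) {
  assert_category(label)
  ifelse(label == "Yes", "positive", "negative")
}

# Adjacency used by the simulated reviewer-disagreement model: a disagreeing
# reviewer lands on a semantically neighbouring category, never an arbitrary
# one (Yes borders NotSure; No borders NotApplicable and NotSure).
category_neighbours <- function(label) {
  switch(label,
    Yes = "NotSure",
    No = c("NotApplicable", "NotSure"),
    NotApplicable = "No",
    NotSure = c("Yes", "No"),
    stop("invalid label: ", label, call. = FALSE))
}
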