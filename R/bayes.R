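# Bayes engine: pre-test probability via Naive Bayes over Ottawa findings,
# post-test probability via likelihood-ratio multiplication in odds form.
# Internally everything runs in log-odds so large LR products cannot
# overflow; exact zeros (negative result of a perfectly sensitive test) and
# infinities (positive result of a perfectly specific test) are
# short-circuited before the log transform.

#' Convert between probability and odds
#'
#' `prob_to_odds()` maps a probability `p` to odds `p / (1 - p)`; `p = 1`
#' maps to `Inf` (the declared infinite-odds sentinel). `odds_to_prob()`
#' inverts: `o / (1 + o)`, with `Inf` mapping to 1. Both are vectorised and
#' compose to the identity.
#'
#' @param p Probabilities in `[0, 1]`.
#' @param o Nonnegative odds (may be `Inf`).
#' @return Odds, respectively probabilities.
#' @export
prob_to_odds <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  ifelse(p == 1, Inf, p / (1 - p))
}

#' @rdname prob_to_odds
#' @export
odds_to_prob <- function(o) {
  if (any(is.na(o)) || any(o < 0)) stop("odds must be >= 0")
  ifelse(is.infinite(o), 1, o / (1 + o))
}

#' Pre-test SAH probability from Ottawa rule findings
#'
#' Naive Bayes over the clinical findings: the prevalence odds are multiplied
#' by `lr_positive` for each finding present and `lr_negative` for each
#' finding absent; unknown (unanswered) findings contribute LR 1. Findings
#' are conditionally independent given disease status, so the result does not
#' depend on item order.
#'
#' @param prevalence Baseline SAH prevalence, strictly inside `(0, 1)`.
#' @param findings Named character vector of item id to
#'   `"present"`/`"absent"`/`"unknown"`.
#' @param registry An `sah_registry` supplying the per-item likelihood ratios.
#' @return The pre-test probability.
#' @export
pretest_probability <- function(prevalence, findings, registry) {
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      is.na(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie strictly inside (0, 1)")
  }
  findings <- unlist(findings)
  unknown <- setdiff(names(findings), names(registry$items))
  if (length(unknown)) {
    stop("unknown Ottawa item(s): ", paste(unknown, collapse = ", "))
  }
  log_odds <- log(prevalence) - log1p(-prevalence)
  for (id in names(findings)) {
    item <- registry$items[[id]]
    log_odds <- log_odds + switch(findings[[id]],
      present = log(item$lr_positive),
      absent = log(item$lr_negative),
      unknown = 0,
      stop("invalid finding state for ", id, ": ", findings[[id]])
    )
  }
  stats::plogis(log_odds)
}

#' Likelihood ratio of an imaging result
#'
#' With sensitivity `s = sensitivity_at_time(test, hours)` and specificity
#' `c`: a positive result has LR `s / (1 - c)` (`Inf` when `c = 1`), a
#' negative result `(1 - s) / c` (exactly 0 when `s = 1`), and a test not
#' done is uninformative (LR 1).
#'
#' @param test An `sah_test`.
#' @param result One of `"positive"`, `"negative"`, `"not_done"`.
#' @param hours Nonnegative hours from symptom onset to test acquisition.
#' @return The likelihood ratio (may be 0 or `Inf`).
#' @export
likelihood_ratio <- function(test, result, hours) {
  result <- match.arg(result, IMAGING_STATES)
  if (result == "not_done") return(1)
  s <- sensitivity_at_time(test, hours)
  cc <- test$specificity
  if (result == "positive") {
    if (cc == 1) Inf else s / (1 - cc)
  } else {
    if (s == 1) 0 else (1 - s) / cc
  }
}

#' Post-test SAH probability from imaging results
#'
#' Bayes theorem in odds form: the pre-test odds are multiplied by the
#' likelihood ratio of every imaging result that was obtained (tests not done
#' contribute nothing), and the product is converted back to a probability.
#' The full trail of applied likelihood ratios is recorded so the posterior
#' is recomputable from the estimate alone. A zero LR (negative result of a
#' perfectly sensitive test) yields a posterior of exactly 0; an infinite LR
#' yields exactly 1; test order never matters.
#'
#' The returned estimate also carries the LP decision threshold implied by
#' the patient's procedural risk factors (see [adjusted_threshold()]), giving
#' the tool's three probabilities: pre-test, post-test, and threshold.
#'
#' @param pretest Pre-test probability in `[0, 1]`, typically from
#'   [pretest_probability()].
#' @param presentation An `sah_patient`.
#' @param registry An `sah_registry`.
#' @return An object of class `sah_estimate` with fields `pretest`,
#'   `posttest`, `threshold`, `difficulty`, and `applied_lrs` (a data frame
#'   with columns `source`, `result`, `lr`).
#' @export
posttest_probability <- function(pretest, presentation, registry) {
  if (!is.numeric(pretest) || length(pretest) != 1L || is.na(pretest) ||
      pretest < 0 || pretest > 1) {
    stop("pretest must be a probability in [0, 1]")
  }
  stopifnot(inherits(presentation, "sah_patient"),
            inherits(registry, "sah_registry"))
  validate_presentation(presentation, registry)

  results <- presentation$imaging_results
  applied <- names(results)[results != "not_done"]
  lrs <- vapply(applied, function(id)
    likelihood_ratio(registry$tests[[id]], results[[id]],
                     presentation$hours_since_onset), 0)

  # Short-circuit order: a zero LR (certain rule-out) dominates, then prior
  # certainty, then an infinite LR (certain rule-in).
  posttest <- if (any(lrs == 0)) {
    0
  } else if (pretest == 0) {
    0
  } else if (pretest == 1 || any(is.infinite(lrs))) {
    1
  } else {
    log_odds <- log(pretest) - log1p(-pretest) + sum(log(lrs))
    stats::plogis(log_odds)
  }

  difficulty <- difficulty_score(presentation$risk_factors, registry$weights)
  structure(
    list(pretest = pretest, posttest = posttest,
         threshold = adjusted_threshold(registry$thresholds, difficulty),
         difficulty = difficulty,
         applied_lrs = data.frame(
           source = applied,
           result = unname(results[applied]),
           lr = unname(lrs),
           stringsAsFactors = FALSE, row.names = NULL)),
    class = "sah_estimate"
  )
}

#' @export
print.sah_estimate <- function(x, ...) {
  cat(sprintf("SAH probability estimate\n  pre-test:  %s\n  post-test: %s\n  LP threshold: %s (difficulty %g)\n",
              format_prob(x$pretest), format_prob(x$posttest),
              format_prob(x$threshold), x$difficulty))
  if (nrow(x$applied_lrs)) {
    cat("  applied LRs:\n")
    for (i in seq_len(nrow(x$applied_lrs))) {
      cat(sprintf("    %s %s: LR %.4g\n", x$applied_lrs$source[i],
                  x$applied_lrs$result[i], x$applied_lrs$lr[i]))
    }
  }
  invisible(x)
}

format_prob <- function(p) {
  ifelse(p == 0, "0%", ifelse(p < 1e-4, sprintf("%.2e%%", p * 100),
                              sprintf("%.3g%%", p * 100)))
}
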