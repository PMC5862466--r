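# LP decision layer: procedural difficulty score, threshold adjustment, and
# the green/yellow/red zone classification. The weights never touch the
# post-test probability -- they only raise the threshold at which the
# procedure is worthwhile.

#' Lumbar-puncture difficulty score
#'
#' Sums the configured weight of each procedural risk factor present. A
#' patient with both difficult body habitus and antithrombotic use gets the
#' sum of both weights; no risk factors scores 0.
#'
#' @param risk_factors Character vector of risk factor ids present.
#' @param weights Named nonnegative numeric vector of per-factor weights
#'   (e.g. `registry$weights`).
#' @return The summed difficulty weight.
#' @export
difficulty_score <- function(risk_factors, weights) {
  risk_factors <- as.character(unlist(risk_factors))
  unknown <- setdiff(risk_factors, names(weights))
  if (length(unknown)) {
    stop("unknown risk factor(s): ", paste(unknown, collapse = ", "))
  }
  if (!length(risk_factors)) return(0)
  sum(weights[risk_factors])
}

#' LP testing threshold adjusted for procedural difficulty
#'
#' The base test threshold is scaled by `weight_scale^difficulty` and capped
#' at 0.99: each unit of procedural difficulty multiplies the post-test
#' probability required before lumbar puncture is worthwhile. Difficulty 0
#' returns the base threshold exactly.
#'
#' @param thresholds Named numeric vector with `base_test_threshold`,
#'   `yellow_band_ratio`, `weight_scale` (e.g. `registry$thresholds`).
#' @param difficulty Nonnegative summed difficulty weight.
#' @return The adjusted threshold probability.
#' @export
adjusted_threshold <- function(thresholds, difficulty) {
  if (!is.numeric(difficulty) || length(difficulty) != 1L || difficulty < 0) {
    stop("difficulty must be a single nonnegative number")
  }
  min(thresholds[["base_test_threshold"]] *
        thresholds[["weight_scale"]]^difficulty, 0.99)
}

classify_zone <- function(posttest, threshold, ratio) {
  if (posttest >= threshold * ratio) "green"
  else if (posttest <= threshold / ratio) "red"
  else "yellow"
}

#' Classify a probability estimate into an LP recommendation
#'
#' Compares the post-test probability with the difficulty-adjusted testing
#' threshold: green (LP indicated) when the post-test probability is at or
#' above `threshold * yellow_band_ratio`, red (LP not indicated) when at or
#' below `threshold / yellow_band_ratio`, and yellow in between, where
#' patient preference and physician judgment decide. A positive imaging
#' result makes the LP question moot (SAH already evident), flagged with
#' `terminal = TRUE`. The narrative lists the applied likelihood-ratio trail.
#'
#' @param estimate An `sah_estimate` from [posttest_probability()], produced
#'   on the same presentation.
#' @param presentation The `sah_patient` scored.
#' @param registry The `sah_registry` used.
#' @return An object of class `sah_recommendation` with fields `zone`
#'   (`"green"`/`"yellow"`/`"red"`), `pretest`, `posttest`, `threshold`,
#'   `difficulty`, `terminal`, `applied_lrs`, `narrative`.
#' @export
recommend <- function(estimate, presentation, registry) {
  stopifnot(inherits(estimate, "sah_estimate"),
            inherits(presentation, "sah_patient"),
            inherits(registry, "sah_registry"))
  difficulty <- difficulty_score(presentation$risk_factors, registry$weights)
  threshold <- adjusted_threshold(registry$thresholds, difficulty)
  ratio <- registry$thresholds[["yellow_band_ratio"]]
  zone <- classify_zone(estimate$posttest, threshold, ratio)
  terminal <- any(presentation$imaging_results == "positive")
  structure(
    list(zone = zone, pretest = estimate$pretest, posttest = estimate$posttest,
         threshold = threshold, difficulty = difficulty, terminal = terminal,
         applied_lrs = estimate$applied_lrs,
         narrative = build_narrative(estimate, zone, threshold, difficulty,
                                     terminal)),
    class = "sah_recommendation"
  )
}

build_narrative <- function(estimate, zone, threshold, difficulty, terminal) {
  lr_txt <- if (nrow(estimate$applied_lrs)) {
    paste(sprintf("%s %s (LR %.4g)", estimate$applied_lrs$source,
                  estimate$applied_lrs$result, estimate$applied_lrs$lr),
          collapse = "; ")
  } else "no imaging applied"
  zone_txt <- switch(zone,
    green = "lumbar puncture indicated",
    red = "lumbar puncture not indicated",
    yellow = "indeterminate: patient preference and physician judgment decide"
  )
  msg <- sprintf(
    "Pre-test probability %s; applied: %s; post-test probability %s. LP difficulty %g raises the testing threshold to %s. Zone %s: %s.",
    format_prob(estimate$pretest), lr_txt, format_prob(estimate$posttest),
    difficulty, format_prob(threshold), toupper(zone), zone_txt)
  if (terminal) {
    msg <- paste(msg,
      "Positive imaging already demonstrates the diagnosis; the lumbar-puncture question is moot.")
  }
  msg
}

#' Score a patient end to end
#'
#' Convenience pipeline: pre-test probability from the Ottawa findings,
#' post-test probability from the imaging results, and the zone
#' recommendation, in one call.
#'
#' @param presentation An `sah_patient`.
#' @param registry An `sah_registry` (the shipped default if omitted).
#' @return A list of class `sah_assessment` with elements `estimate` and
#'   `recommendation`.
#' @examples
#' reg <- default_registry()
#' pat <- patient_presentation(
#'   hours_since_onset = 1,
#'   ottawa_findings = c(sudden_onset = "present", instant_peak = "present",
#'                       exertion = "present", loc = "present"),
#'   imaging_results = c(noncontrast_ct = "negative")
#' )
#' sah_assess(pat, reg)
#' @export
sah_assess <- function(presentation, registry = default_registry()) {
  pre <- pretest_probability(registry$prevalence,
                             presentation$ottawa_findings, registry)
  est <- posttest_probability(pre, presentation, registry)
  rec <- recommend(est, presentation, registry)
  structure(list(estimate = est, recommendation = rec),
            class = "sah_assessment")
}

#' @export
print.sah_recommendation <- function(x, ...) {
  cat(sprintf("LP recommendation: zone %s%s\n", toupper(x$zone),
              if (x$terminal) " (terminal: positive imaging)" else ""))
  cat(" ", x$narrative, "\n")
  invisible(x)
}

#' @export
print.sah_assessment <- function(x, ...) {
  print(x$estimate)
  print(x$recommendation)
  invisible(x)
}
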