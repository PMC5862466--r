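# Synthetic ED headache cohorts with known ground truth. Findings and CT
# results are drawn conditionally on the latent SAH status using exactly the
# registry's parameters, so a well-specified scorer must be calibrated on its
# own cohorts -- the basis for the self-consistency tests.

#' Invert a likelihood-ratio pair to the implied sensitivity/specificity
#'
#' A binary finding with likelihood ratios `LR+ = sens / (1 - spec)` and
#' `LR- = (1 - sens) / spec` determines the pair uniquely:
#' `spec = (1 - LR+) / (LR- - LR+)` and `sens = LR+ * (1 - spec)`. Pairs
#' whose implied values fall outside `(0, 1)` (e.g. `LR+ = LR- = 1`) are not
#' realizable as a binary test and are rejected. This is what makes the
#' Naive-Bayes generator exactly consistent with the LR-based updater.
#'
#' @param lr_positive,lr_negative Likelihood ratios, `lr_positive > lr_negative > 0`.
#' @param item Optional item id used in error messages.
#' @return `list(sensitivity =, specificity =)`.
#' @export
lr_to_sens_spec <- function(lr_positive, lr_negative, item = "item") {
  if (!is.finite(lr_positive) || !is.finite(lr_negative) ||
      lr_positive <= lr_negative) {
    config_error(sprintf("%s: LR pair (%s, %s) is not realizable", item,
                         format(lr_positive), format(lr_negative)))
  }
  spec <- (1 - lr_positive) / (lr_negative - lr_positive)
  sens <- lr_positive * (1 - spec)
  if (!(spec > 0 && spec < 1 && sens > 0 && sens < 1)) {
    config_error(sprintf(
      "%s: LR pair (%s, %s) implies sensitivity/specificity outside (0, 1)",
      item, format(lr_positive), format(lr_negative)))
  }
  list(sensitivity = sens, specificity = spec)
}

#' Simulation configuration
#'
#' @param n_patients Cohort size, >= 1 (0 allowed for an empty cohort).
#' @param prevalence True SAH prevalence used to draw latent disease status,
#'   in `[0, 1]`.
#' @param registry The `sah_registry` whose parameters generate the data.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param onset Onset-to-scan time distribution:
#'   `list(dist = "lognormal", meanlog =, sdlog =)` or
#'   `list(dist = "exponential", rate =)`. The default is log-normal with
#'   median 4 h (`meanlog = log(4)`, `sdlog = 0.75`).
#' @param tests_done Character vector of registry test ids every simulated
#'   patient receives (default: non-contrast CT only).
#' @return A list of class `sah_sim_config`.
#' @export
simulation_config <- function(n_patients, prevalence, registry, seed = 1L,
                              onset = list(dist = "lognormal",
                                           meanlog = log(4), sdlog = 0.75),
                              tests_done = "noncontrast_ct") {
  stopifnot(n_patients >= 0, prevalence >= 0, prevalence <= 1,
            inherits(registry, "sah_registry"))
  missing_tests <- setdiff(tests_done, names(registry$tests))
  if (length(missing_tests)) {
    config_error(paste("tests_done not in registry:",
                       paste(missing_tests, collapse = ", ")))
  }
  structure(list(n_patients = as.integer(n_patients), prevalence = prevalence,
                 registry = registry, seed = as.integer(seed), onset = onset,
                 tests_done = tests_done),
            class = "sah_sim_config")
}

draw_onset <- function(onset, n) {
  switch(onset$dist,
    lognormal = stats::rlnorm(n, meanlog = onset$meanlog, sdlog = onset$sdlog),
    exponential = stats::rexp(n, rate = onset$rate),
    stop("unknown onset distribution: ", onset$dist)
  )
}

#' Simulate an ED headache cohort
#'
#' Each patient gets a latent SAH status drawn at the configured prevalence,
#' an onset-to-scan time from the configured distribution, each Ottawa
#' finding drawn from the sensitivity/specificity implied by its configured
#' LR pair (via [lr_to_sens_spec()]), and each performed imaging test drawn
#' from the registry's specificity and its time-evaluated sensitivity at the
#' patient's onset-to-scan time. Reproducible given the seed (Mersenne
#' Twister).
#'
#' @param config A [simulation_config()].
#' @return A data frame of class `sah_cohort`: columns `id`, `true_sah`
#'   (logical), `hours`, one column per Ottawa item
#'   (`"present"`/`"absent"`), and one `<test>_result` column per performed
#'   test (`"positive"`/`"negative"`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sah_sim_config"))
  reg <- config$registry
  n <- config$n_patients
  set.seed(config$seed, kind = "Mersenne-Twister")
  true_sah <- stats::runif(n) < config$prevalence
  hours <- draw_onset(config$onset, n)
  out <- data.frame(id = seq_len(n), true_sah = true_sah, hours = hours,
                    stringsAsFactors = FALSE)
  for (id in names(reg$items)) {
    it <- reg$items[[id]]
    ss <- lr_to_sens_spec(it$lr_positive, it$lr_negative, item = id)
    p_present <- ifelse(true_sah, ss$sensitivity, 1 - ss$specificity)
    out[[id]] <- ifelse(stats::runif(n) < p_present, "present", "absent")
  }
  for (tid in config$tests_done) {
    test <- reg$tests[[tid]]
    s <- sensitivity_at_time(test, hours)
    p_pos <- ifelse(true_sah, s, 1 - test$specificity)
    out[[paste0(tid, "_result")]] <-
      ifelse(stats::runif(n) < p_pos, "positive", "negative")
  }
  class(out) <- c("sah_cohort", "data.frame")
  attr(out, "tests_done") <- config$tests_done
  out
}

cohort_tests <- function(cohort) {
  td <- attr(cohort, "tests_done")
  if (!is.null(td)) return(td)
  sub("_result$", "", grep("_result$", names(cohort), value = TRUE))
}

#' Score a simulated cohort with the Bayes engine
#'
#' Vectorised pre-test/post-test computation over all patients: prevalence
#' odds updated by each finding's LR, then by each performed test's LR at the
#' patient's onset-to-scan time. Identical arithmetic to
#' [pretest_probability()]/[posttest_probability()], in log-odds.
#'
#' @param cohort An `sah_cohort`.
#' @param registry The registry to score with (use the generating registry
#'   for self-consistency checks).
#' @param prior Prevalence used as the prior; defaults to the registry's
#'   baseline prevalence.
#' @return The cohort with `pretest` and `posttest` columns added.
#' @export
score_cohort <- function(cohort, registry, prior = registry$prevalence) {
  n <- nrow(cohort)
  lo <- rep(log(prior) - log1p(-prior), n)
  for (id in names(registry$items)) {
    if (!id %in% names(cohort)) next
    it <- registry$items[[id]]
    lo <- lo + ifelse(cohort[[id]] == "present",
                      log(it$lr_positive), log(it$lr_negative))
  }
  pretest <- stats::plogis(lo)
  zero <- rep(FALSE, n)
  for (tid in cohort_tests(cohort)) {
    test <- registry$tests[[tid]]
    s <- sensitivity_at_time(test, cohort$hours)
    res <- cohort[[paste0(tid, "_result")]]
    lr <- ifelse(res == "positive", s / (1 - test$specificity), (1 - s) / test$specificity)
    zero <- zero | (res == "negative" & s == 1)
    lr[lr == 0] <- 1  # handled by `zero`; keep log finite
    lo <- lo + log(lr)
  }
  posttest <- stats::plogis(lo)
  posttest[zero] <- 0
  cohort$pretest <- pretest
  cohort$posttest <- posttest
  cohort
}

#' Calibration table for a scored cohort
#'
#' Bins patients by posterior probability into `n_bins` equal-width bins on
#' `[0, 1]` and compares each bin's mean posterior with the observed SAH rate.
#' When the scoring registry equals the generating registry, every occupied
#' bin's observed rate should lie within ~3 binomial standard errors of its
#' mean posterior. Empty bins are reported with `n = 0`, not dropped.
#'
#' @param cohort A scored `sah_cohort` (see [score_cohort()]); if `posttest`
#'   is absent it is computed with `registry`.
#' @param registry Registry used to score if needed.
#' @param n_bins Number of equal-width probability bins.
#' @return Data frame: `bin`, `p_low`, `p_high`, `n`, `mean_posterior`,
#'   `observed_rate`, `se` (binomial SE at the mean posterior).
#' @export
evaluate_calibration <- function(cohort, registry, n_bins = 10) {
  if (!"posttest" %in% names(cohort)) cohort <- score_cohort(cohort, registry)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  idx <- findInterval(cohort$posttest, breaks, rightmost.closed = TRUE)
  idx[idx > n_bins] <- n_bins
  out <- data.frame(bin = seq_len(n_bins),
                    p_low = breaks[-length(breaks)], p_high = breaks[-1])
  out$n <- vapply(out$bin, function(b) sum(idx == b), 0L)
  out$mean_posterior <- vapply(out$bin, function(b)
    if (any(idx == b)) mean(cohort$posttest[idx == b]) else NA_real_, 0)
  out$observed_rate <- vapply(out$bin, function(b)
    if (any(idx == b)) mean(cohort$true_sah[idx == b]) else NA_real_, 0)
  out$se <- ifelse(out$n > 0,
                   sqrt(pmax(out$mean_posterior * (1 - out$mean_posterior), 0) /
                          pmax(out$n, 1)),
                   NA_real_)
  out
}

#' Compare LP strategies on a simulated cohort
#'
#' Strategy A performs a lumbar puncture on every negative-CT patient;
#' strategy B only when the decision tool's zone is green (post-test
#' probability at or above `threshold * yellow_band_ratio`). An LP on a true
#' SAH patient counts as caught; a true SAH patient with negative CT and no
#' LP counts as missed. Positive-CT patients are diagnosed by imaging and
#' take no LP under either strategy. Simulated patients carry no LP risk
#' factors, so the threshold is the base test threshold.
#'
#' @param cohort A scored `sah_cohort`.
#' @param registry The registry supplying thresholds.
#' @return Data frame with one row per strategy: `strategy`, `n_lp`,
#'   `sah_caught_by_lp`, `sah_missed`.
#' @export
compare_strategies <- function(cohort, registry) {
  if (nrow(cohort) && !"posttest" %in% names(cohort)) {
    cohort <- score_cohort(cohort, registry)
  }
  ct_neg <- if (nrow(cohort)) cohort$noncontrast_ct_result == "negative"
            else logical(0)
  thr <- registry$thresholds[["base_test_threshold"]]
  ratio <- registry$thresholds[["yellow_band_ratio"]]
  green <- if (nrow(cohort)) cohort$posttest >= thr * ratio else logical(0)
  strat <- function(name, lp) {
    data.frame(strategy = name,
               n_lp = sum(lp),
               sah_caught_by_lp = sum(lp & cohort$true_sah),
               sah_missed = sum(ct_neg & cohort$true_sah & !lp),
               stringsAsFactors = FALSE)
  }
  rbind(strat("A_lp_all_ct_negative", ct_neg),
        strat("B_lp_green_zone_only", ct_neg & green))
}

#' Write / read a cohort as CSV
#'
#' One row per patient; the header is the fixed column set produced by
#' [simulate_cohort()] (plus `pretest`/`posttest` if scored).
#'
#' @param cohort An `sah_cohort`.
#' @param path CSV file path.
#' @return `path` invisibly; `read_cohort_csv()` returns the `sah_cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$true_sah <- as.logical(out$true_sah)
  class(out) <- c("sah_cohort", "data.frame")
  out
}
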