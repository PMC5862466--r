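# Evidence registry: load, validate and serve all model parameters from a
# provenance-annotated JSON config.

config_error <- function(msg) {
  stop(structure(
    class = c("sah_config_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

# Every leaf parameter is an object {value, ci, provenance}. `path` is the
# dotted location reported in error messages.
check_param <- function(leaf, path, lo = -Inf, hi = Inf,
                        open_lo = FALSE, open_hi = FALSE) {
  if (!is.list(leaf) || is.null(leaf$value)) {
    config_error(sprintf("%s: expected a {value, ci, provenance} object", path))
  }
  v <- leaf$value
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
    config_error(sprintf("%s.value: not a finite number", path))
  }
  v <- as.numeric(v)
  bad_lo <- if (open_lo) v <= lo else v < lo
  bad_hi <- if (open_hi) v >= hi else v > hi
  if (bad_lo || bad_hi) {
    config_error(sprintf(
      "%s.value: %s outside %s%s, %s%s", path, format(v),
      if (open_lo) "(" else "[", format(lo),
      format(hi), if (open_hi) ")" else "]"
    ))
  }
  ci <- leaf$ci
  if (!is.null(ci)) {
    ci <- as.numeric(unlist(ci))
    if (length(ci) != 2L || any(!is.finite(ci))) {
      config_error(sprintf("%s.ci: expected [low, high]", path))
    }
    if (ci[1] > v || v > ci[2]) {
      config_error(sprintf("%s.ci: point value %s outside [%s, %s]",
                           path, format(v), format(ci[1]), format(ci[2])))
    }
  }
  if (is.null(leaf$provenance) || !is.character(unlist(leaf$provenance))) {
    config_error(sprintf("%s.provenance: missing provenance string", path))
  }
  v
}

#' Test characteristics for one diagnostic test
#'
#' Bundles the sensitivity and specificity of a diagnostic test, optionally
#' with a time-dependent sensitivity: either an exponential decay model
#' `s0 * exp(-rate * hours)` or a set of half-open time bands `[low, high)`
#' with a constant sensitivity per band. At most one of the two time modes
#' may be set; with neither, sensitivity is constant in time.
#'
#' @param test_id Identifier string, e.g. `"noncontrast_ct"`.
#' @param label Display text.
#' @param sensitivity,specificity Proportions in `[0, 1]`.
#' @param sensitivity_ci,specificity_ci Optional `c(low, high)` bounds
#'   containing the point value.
#' @param time_model Optional `list(s0 =, rate =)` exponential decay model
#'   (`s0` a proportion, `rate >= 0` per hour).
#' @param stratified Optional data frame with columns `low`, `high`,
#'   `sensitivity` describing half-open time bands (`high = Inf` for the last).
#' @return An object of class `sah_test`.
#' @export
test_characteristics <- function(test_id, label, sensitivity, specificity,
                                 sensitivity_ci = NULL, specificity_ci = NULL,
                                 time_model = NULL, stratified = NULL) {
  chk_prop <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      config_error(sprintf("tests.%s.%s: proportion outside [0, 1]", test_id, what))
    }
    as.numeric(x)
  }
  chk_ci <- function(ci, point, what) {
    if (is.null(ci)) return(NULL)
    ci <- as.numeric(ci)
    if (length(ci) != 2L || ci[1] > point || point > ci[2]) {
      config_error(sprintf("tests.%s.%s: CI must satisfy low <= point <= high",
                           test_id, what))
    }
    ci
  }
  sensitivity <- chk_prop(sensitivity, "sensitivity")
  specificity <- chk_prop(specificity, "specificity")
  if (!is.null(time_model) && !is.null(stratified)) {
    config_error(sprintf(
      "tests.%s: at most one of time_model and stratified may be set", test_id))
  }
  if (!is.null(time_model)) {
    time_model$s0 <- chk_prop(time_model$s0, "time_model.s0")
    if (!is.numeric(time_model$rate) || time_model$rate < 0) {
      config_error(sprintf("tests.%s.time_model.rate: must be >= 0", test_id))
    }
    time_model <- list(s0 = time_model$s0, rate = as.numeric(time_model$rate))
  }
  if (!is.null(stratified)) {
    stratified <- as.data.frame(stratified)
    if (!all(c("low", "high", "sensitivity") %in% names(stratified))) {
      config_error(sprintf("tests.%s.stratified: need low/high/sensitivity", test_id))
    }
    stratified <- stratified[order(stratified$low), , drop = FALSE]
    stratified$high[is.na(stratified$high)] <- Inf
    for (s in stratified$sensitivity) chk_prop(s, "stratified.sensitivity")
    if (stratified$low[1] != 0 ||
        any(stratified$low[-1] != stratified$high[-nrow(stratified)])) {
      config_error(sprintf(
        "tests.%s.stratified: bands must tile [0, Inf) without gaps", test_id))
    }
  }
  structure(
    list(test_id = test_id, label = label,
         sensitivity = sensitivity, specificity = specificity,
         sensitivity_ci = chk_ci(sensitivity_ci, sensitivity, "sensitivity"),
         specificity_ci = chk_ci(specificity_ci, specificity, "specificity"),
         time_model = time_model, stratified = stratified),
    class = "sah_test"
  )
}

#' Evaluate a test's sensitivity at a given time since symptom onset
#'
#' For a test with an exponential decay model, returns
#' `s0 * exp(-rate * hours)`; for a stratified test, the sensitivity of the
#' half-open band `[low, high)` containing `hours`; otherwise the constant
#' point sensitivity. Vectorised over `hours`.
#'
#' @param test An `sah_test` object.
#' @param hours Nonnegative hours from symptom onset to test acquisition.
#' @return Sensitivity proportion(s), same length as `hours`.
#' @export
sensitivity_at_time <- function(test, hours) {
  stopifnot(inherits(test, "sah_test"))
  if (any(!is.finite(hours)) || any(hours < 0)) {
    stop("hours since symptom onset must be finite and >= 0")
  }
  if (!is.null(test$time_model)) {
    test$time_model$s0 * exp(-test$time_model$rate * hours)
  } else if (!is.null(test$stratified)) {
    idx <- findInterval(hours, c(test$stratified$low, Inf))
    test$stratified$sensitivity[idx]
  } else {
    rep_len(test$sensitivity, length(hours))
  }
}

parse_test <- function(doc, test_id) {
  path <- paste0("tests.", test_id)
  for (f in c("label", "sensitivity", "specificity")) {
    if (is.null(doc[[f]])) config_error(sprintf("%s.%s: missing", path, f))
  }
  sens <- check_param(doc$sensitivity, paste0(path, ".sensitivity"), 0, 1)
  spec <- check_param(doc$specificity, paste0(path, ".specificity"), 0, 1)
  tm <- NULL
  if (!is.null(doc$time_model)) {
    tm <- list(
      s0 = check_param(doc$time_model$s0, paste0(path, ".time_model.s0"), 0, 1),
      rate = check_param(doc$time_model$rate, paste0(path, ".time_model.rate"), 0)
    )
  }
  st <- NULL
  if (!is.null(doc$stratified)) {
    st <- data.frame(
      low = vapply(doc$stratified, function(b) as.numeric(b$low), 0),
      high = vapply(doc$stratified, function(b)
        if (is.null(b$high)) Inf else as.numeric(b$high), 0),
      sensitivity = vapply(doc$stratified, function(b)
        check_param(b$sensitivity, paste0(path, ".stratified.sensitivity"), 0, 1), 0)
    )
  }
  test_characteristics(
    test_id, label = as.character(doc$label),
    sensitivity = sens, specificity = spec,
    sensitivity_ci = if (!is.null(doc$sensitivity$ci))
      as.numeric(unlist(doc$sensitivity$ci)),
    specificity_ci = if (!is.null(doc$specificity$ci))
      as.numeric(unlist(doc$specificity$ci)),
    time_model = tm, stratified = st
  )
}

#' Path to a registry config shipped with the package
#'
#' @param preset `"decay"` for the default config, in which non-contrast CT
#'   sensitivity follows the exponential decay model, or `"stratified"` for
#'   the alternative preset using the time-band sensitivities
#'   (1.00 before 6 h, 0.89 from 6 h on).
#' @return File path to the JSON config.
#' @export
default_registry_path <- function(preset = c("decay", "stratified")) {
  preset <- match.arg(preset)
  fn <- c(decay = "registry-default.json", stratified = "registry-stratified.json")
  system.file("extdata", fn[[preset]], package = "sahrisk", mustWork = TRUE)
}

#' Load and validate an evidence registry
#'
#' Reads a JSON evidence-registry config (see
#' `system.file("extdata", "registry.schema.json", package = "sahrisk")` for
#' the format), validates every parameter, and returns a registry object.
#' Every numeric parameter in the config is a `{value, ci, provenance}`
#' object, so each number carries its source.
#'
#' Validation enforces: all proportions in `[0, 1]` with CI low <= point <=
#' high; prevalence strictly inside `(0, 1)`; the required tests
#' `noncontrast_ct` and `ct_angiogram` present; for each Ottawa item
#' `lr_positive >= 1 >= lr_negative > 0`; weights nonnegative;
#' `base_test_threshold * yellow_band_ratio < 1`. Violations raise an error
#' of class `sah_config_error` naming the offending path.
#'
#' @param source Path to a JSON file, a JSON string, or an already-parsed
#'   nested list with the same structure.
#' @return An object of class `sah_registry` with elements `prevalence`,
#'   `tests` (named list of [test_characteristics()]), `items` (named list
#'   with `lr_positive`/`lr_negative`), `weights`, `thresholds` (named
#'   numeric), and `doc` (the validated config, kept for serialization).
#' @seealso [write_registry()], [default_registry()]
#' @export
load_registry <- function(source = default_registry_path()) {
  doc <- if (is.list(source)) {
    source
  } else if (length(source) == 1L && is.character(source) && file.exists(source)) {
    jsonlite::fromJSON(source, simplifyVector = FALSE)
  } else if (is.character(source)) {
    jsonlite::fromJSON(source, simplifyVector = FALSE)
  } else {
    config_error("registry source must be a file path, JSON string or list")
  }
  for (k in c("baseline_prevalence", "tests", "ottawa_items", "weights",
              "thresholds")) {
    if (is.null(doc[[k]])) config_error(sprintf("%s: missing required section", k))
  }
  prevalence <- check_param(doc$baseline_prevalence, "baseline_prevalence",
                            0, 1, open_lo = TRUE, open_hi = TRUE)

  for (req in c("noncontrast_ct", "ct_angiogram")) {
    if (is.null(doc$tests[[req]])) {
      config_error(sprintf("tests.%s: required test missing", req))
    }
  }
  tests <- lapply(names(doc$tests), function(id) parse_test(doc$tests[[id]], id))
  names(tests) <- names(doc$tests)

  items <- lapply(names(doc$ottawa_items), function(id) {
    it <- doc$ottawa_items[[id]]
    path <- paste0("ottawa_items.", id)
    lrp <- check_param(it$lr_positive, paste0(path, ".lr_positive"))
    lrn <- check_param(it$lr_negative, paste0(path, ".lr_negative"))
    if (!(lrp >= 1 && 1 >= lrn && lrn > 0)) {
      config_error(sprintf(
        "%s: need lr_positive >= 1 >= lr_negative > 0 (got %s, %s)",
        path, format(lrp), format(lrn)))
    }
    list(item_id = id, label = as.character(it$label),
         lr_positive = lrp, lr_negative = lrn)
  })
  names(items) <- names(doc$ottawa_items)

  for (req in c("difficult_habitus", "antithrombotic_use")) {
    if (is.null(doc$weights[[req]])) {
      config_error(sprintf("weights.%s: required weight missing", req))
    }
  }
  weights <- vapply(names(doc$weights), function(id)
    check_param(doc$weights[[id]], paste0("weights.", id), 0), 0)

  thresholds <- c(
    base_test_threshold = check_param(doc$thresholds$base_test_threshold,
                                      "thresholds.base_test_threshold",
                                      0, 1, open_lo = TRUE, open_hi = TRUE),
    yellow_band_ratio = check_param(doc$thresholds$yellow_band_ratio,
                                    "thresholds.yellow_band_ratio", 1,
                                    open_lo = TRUE),
    weight_scale = check_param(doc$thresholds$weight_scale,
                               "thresholds.weight_scale", 1)
  )
  if (thresholds[["base_test_threshold"]] * thresholds[["yellow_band_ratio"]] >= 1) {
    config_error("thresholds: base_test_threshold * yellow_band_ratio must be < 1")
  }

  structure(
    list(prevalence = prevalence, tests = tests, items = items,
         weights = weights, thresholds = thresholds,
         doc = normalize_doc(doc)),
    class = "sah_registry"
  )
}

#' Load a registry shipped with the package
#'
#' @inheritParams default_registry_path
#' @return An `sah_registry`.
#' @export
default_registry <- function(preset = c("decay", "stratified")) {
  load_registry(default_registry_path(preset))
}

# jsonlite parses whole numbers as integer; coerce all numeric scalars to
# double so that load -> write -> load is the identity.
normalize_doc <- function(x) {
  if (is.list(x)) lapply(x, normalize_doc)
  else if (is.numeric(x)) as.numeric(x)
  else x
}

#' Serialize a registry back to its JSON config form
#'
#' Writing and re-loading a registry reproduces an identical object
#' (round-trip identity), so site-local edits can be made on the serialized
#' form without information loss.
#'
#' @param registry An `sah_registry`.
#' @param path Output file path; if `NULL`, the JSON text is returned.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_registry <- function(registry, path = NULL) {
  stopifnot(inherits(registry, "sah_registry"))
  json <- jsonlite::toJSON(registry$doc, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' @export
print.sah_registry <- function(x, ...) {
  cat("SAH evidence registry\n")
  cat(sprintf("  baseline prevalence: %.4g\n", x$prevalence))
  cat(sprintf("  tests: %s\n", paste(names(x$tests), collapse = ", ")))
  cat(sprintf("  Ottawa items: %s\n", paste(names(x$items), collapse = ", ")))
  cat(sprintf("  LP test threshold: %.4g (yellow ratio %.3g, weight scale %.3g)\n",
              x$thresholds[["base_test_threshold"]],
              x$thresholds[["yellow_band_ratio"]],
              x$thresholds[["weight_scale"]]))
  invisible(x)
}
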