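# Patient presentation: onset time, Ottawa findings, imaging results, LP risk
# factors. Findings may be "present", "absent" or "unknown"; an unanswered
# question must not bias the estimate, so "unknown" maps to LR 1 downstream.

FINDING_STATES <- c("present", "absent", "unknown")
IMAGING_STATES <- c("positive", "negative", "not_done")
RISK_FACTORS <- c("difficult_habitus", "antithrombotic_use")

#' Construct a patient presentation
#'
#' @param hours_since_onset Nonnegative hours from headache onset to
#'   evaluation/imaging.
#' @param ottawa_findings Named character vector mapping Ottawa item ids to
#'   `"present"`, `"absent"` or `"unknown"`. Items not named are treated as
#'   unknown.
#' @param imaging_results Named character vector mapping test ids to
#'   `"positive"`, `"negative"` or `"not_done"`. Tests not named are treated
#'   as not done.
#' @param risk_factors Character vector of LP procedural risk factors present,
#'   a subset of `c("difficult_habitus", "antithrombotic_use")`.
#' @return An object of class `sah_patient`.
#' @export
patient_presentation <- function(hours_since_onset,
                                 ottawa_findings = character(),
                                 imaging_results = character(),
                                 risk_factors = character()) {
  if (!is.numeric(hours_since_onset) || length(hours_since_onset) != 1L ||
      is.na(hours_since_onset) || hours_since_onset < 0) {
    stop("hours_since_onset must be a single nonnegative number")
  }
  ottawa_findings <- unlist(ottawa_findings)
  imaging_results <- unlist(imaging_results)
  risk_factors <- as.character(unlist(risk_factors))
  if (length(ottawa_findings) &&
      (is.null(names(ottawa_findings)) || any(names(ottawa_findings) == ""))) {
    stop("ottawa_findings must be a named vector of item states")
  }
  bad <- setdiff(unique(ottawa_findings), FINDING_STATES)
  if (length(bad)) {
    stop("invalid finding state(s): ", paste(bad, collapse = ", "))
  }
  if (length(imaging_results) &&
      (is.null(names(imaging_results)) || any(names(imaging_results) == ""))) {
    stop("imaging_results must be a named vector of result states")
  }
  bad <- setdiff(unique(imaging_results), IMAGING_STATES)
  if (length(bad)) {
    stop("invalid imaging result state(s): ", paste(bad, collapse = ", "))
  }
  structure(
    list(hours_since_onset = as.numeric(hours_since_onset),
         ottawa_findings = ottawa_findings,
         imaging_results = imaging_results,
         risk_factors = risk_factors),
    class = "sah_patient"
  )
}

#' Read a patient presentation from its JSON document form
#'
#' The document mirrors [patient_presentation()]: keys `hours_since_onset`
#' (required), `ottawa_findings` (object of item id to state),
#' `imaging_results` (object of test id to result), `risk_factors` (array),
#' and optionally `registry` (path to a registry override, returned as the
#' `registry_path` attribute). Unknown keys are rejected.
#'
#' @param source Path to a JSON file or a JSON string.
#' @return An `sah_patient`, with attribute `registry_path` if the document
#'   named a registry override.
#' @export
read_patient_json <- function(source) {
  doc <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  allowed <- c("hours_since_onset", "ottawa_findings", "imaging_results",
               "risk_factors", "registry")
  extra <- setdiff(names(doc), allowed)
  if (length(extra)) {
    stop("unknown key(s) in patient document: ", paste(extra, collapse = ", "))
  }
  if (is.null(doc$hours_since_onset)) stop("patient document: hours_since_onset missing")
  p <- patient_presentation(
    hours_since_onset = doc$hours_since_onset,
    ottawa_findings = vapply(doc$ottawa_findings, as.character, ""),
    imaging_results = vapply(doc$imaging_results, as.character, ""),
    risk_factors = as.character(unlist(doc$risk_factors))
  )
  if (!is.null(doc$registry)) attr(p, "registry_path") <- as.character(doc$registry)
  p
}

#' Serialize a patient presentation to JSON
#'
#' @param presentation An `sah_patient`.
#' @param path Output file; if `NULL` the JSON text is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_patient_json <- function(presentation, path = NULL) {
  stopifnot(inherits(presentation, "sah_patient"))
  doc <- list(
    hours_since_onset = presentation$hours_since_onset,
    ottawa_findings = as.list(presentation$ottawa_findings),
    imaging_results = as.list(presentation$imaging_results),
    risk_factors = as.list(presentation$risk_factors)
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

# Check that every id a presentation references exists in the registry.
validate_presentation <- function(presentation, registry) {
  unknown <- setdiff(names(presentation$ottawa_findings), names(registry$items))
  if (length(unknown)) {
    stop("unknown Ottawa item(s): ", paste(unknown, collapse = ", "))
  }
  unknown <- setdiff(names(presentation$imaging_results), names(registry$tests))
  if (length(unknown)) {
    stop("unknown imaging test(s): ", paste(unknown, collapse = ", "))
  }
  unknown <- setdiff(presentation$risk_factors, names(registry$weights))
  if (length(unknown)) {
    stop("unknown risk factor(s): ", paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.sah_patient <- function(x, ...) {
  cat(sprintf("SAH patient presentation, %.3g h since onset\n",
              x$hours_since_onset))
  pr <- function(v) if (length(v)) paste(names(v), v, sep = "=", collapse = ", ") else "none"
  cat("  findings:", pr(x$ottawa_findings), "\n")
  cat("  imaging:", pr(x$imaging_results), "\n")
  cat("  LP risk factors:",
      if (length(x$risk_factors)) paste(x$risk_factors, collapse = ", ") else "none",
      "\n")
  invisible(x)
}
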