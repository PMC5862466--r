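# Build small registries in code. Leaf parameters follow the config contract
# {value, ci, provenance}.

leaf <- function(value, ci = NULL) {
  list(value = value, ci = ci, provenance = "test fixture")
}

# items: named list of c(lr_positive, lr_negative)
# tests: named list of list(sensitivity=, specificity=, time_model=, stratified=)
make_registry_doc <- function(prevalence = 0.075,
                              items = list(sudden_onset = c(2, 0.5)),
                              tests = list(),
                              base_threshold = 0.01,
                              yellow_ratio = 3,
                              weight_scale = 1.5,
                              weights = c(difficult_habitus = 2,
                                          antithrombotic_use = 2)) {
  base_tests <- list(
    noncontrast_ct = list(
      label = "Non-contrast head CT",
      sensitivity = leaf(0.94, c(0.91, 0.96)),
      specificity = leaf(0.999),
      time_model = list(s0 = leaf(0.98), rate = leaf(0.01))
    ),
    ct_angiogram = list(
      label = "CT angiogram",
      sensitivity = leaf(0.98),
      specificity = leaf(0.999)
    )
  )
  for (id in names(tests)) {
    t <- tests[[id]]
    entry <- list(
      label = if (is.null(t$label)) id else t$label,
      sensitivity = leaf(t$sensitivity),
      specificity = leaf(t$specificity)
    )
    if (!is.null(t$time_model)) {
      entry$time_model <- list(s0 = leaf(t$time_model$s0),
                               rate = leaf(t$time_model$rate))
    }
    if (!is.null(t$stratified)) {
      entry$stratified <- lapply(seq_len(nrow(t$stratified)), function(i) {
        b <- t$stratified[i, ]
        list(low = b$low, high = if (is.infinite(b$high)) NULL else b$high,
             sensitivity = leaf(b$sensitivity))
      })
    }
    base_tests[[id]] <- entry
  }
  list(
    baseline_prevalence = leaf(prevalence),
    tests = base_tests,
    ottawa_items = lapply(items, function(lr) {
      list(label = "test item", lr_positive = leaf(lr[1]),
           lr_negative = leaf(lr[2]))
    }),
    weights = lapply(as.list(weights), leaf),
    thresholds = list(
      base_test_threshold = leaf(base_threshold),
      yellow_band_ratio = leaf(yellow_ratio),
      weight_scale = leaf(weight_scale)
    )
  )
}

tiny_registry <- function(...) load_registry(make_registry_doc(...))

# Registry whose non-contrast CT uses the time-band preset values.
stratified_bands <- data.frame(low = c(0, 6), high = c(6, Inf),
                               sensitivity = c(1.0, 0.89))
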