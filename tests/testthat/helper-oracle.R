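# Independent oracle for the Bayes engine: direct joint-probability
# computation under conditional independence, never touching odds or
# likelihood ratios. Items are specified by (sensitivity, specificity) of the
# finding as a "test" for disease; imaging tests by (s, c, result).

oracle_posterior <- function(prevalence, item_sens, item_spec, item_states,
                             test_sens = numeric(), test_spec = numeric(),
                             test_results = character()) {
  like_d <- prevalence
  like_nd <- 1 - prevalence
  for (i in seq_along(item_states)) {
    st <- item_states[[i]]
    if (st == "unknown") next
    if (st == "present") {
      like_d <- like_d * item_sens[i]
      like_nd <- like_nd * (1 - item_spec[i])
    } else {
      like_d <- like_d * (1 - item_sens[i])
      like_nd <- like_nd * item_spec[i]
    }
  }
  for (i in seq_along(test_results)) {
    r <- test_results[[i]]
    if (r == "not_done") next
    if (r == "positive") {
      like_d <- like_d * test_sens[i]
      like_nd <- like_nd * (1 - test_spec[i])
    } else {
      like_d <- like_d * (1 - test_sens[i])
      like_nd <- like_nd * test_spec[i]
    }
  }
  like_d / (like_d + like_nd)
}

# LR pair implied by a finding's sensitivity/specificity, for building the
# registry config that the implementation route consumes.
lr_pair_from_sens_spec <- function(sens, spec) {
  c(sens / (1 - spec), (1 - sens) / spec)
}
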