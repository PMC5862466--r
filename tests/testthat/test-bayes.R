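test_that("probability/odds conversions are exact and round-trip", {
  expect_identical(prob_to_odds(0.5), 1)
  expect_identical(odds_to_prob(1), 0.5)
  expect_identical(prob_to_odds(0), 0)
  expect_identical(odds_to_prob(0), 0)
  expect_equal(prob_to_odds(0.2), 0.25, tolerance = 1e-15)
  expect_identical(prob_to_odds(1), Inf)
  expect_identical(odds_to_prob(Inf), 1)
  expect_error(prob_to_odds(-0.1), "\\[0, 1\\]")
  expect_error(odds_to_prob(-1), ">= 0")
  p <- seq(0, 1 - 1e-9, length.out = 501)
  expect_equal(odds_to_prob(prob_to_odds(p)), p, tolerance = 1e-12)
})

test_that("pre-test probability is the Naive-Bayes odds update", {
  reg <- tiny_registry(items = list(a = c(4, 0.25), b = c(2, 0.5),
                                    c = c(1.5, 0.8)))
  # all unknown -> prior unchanged
  expect_equal(
    pretest_probability(0.075, c(a = "unknown", b = "unknown"), reg), 0.075,
    tolerance = 1e-15)
  # hand-derived: odds 0.05/0.95 * 4 = 0.2105263 -> p = 0.1739130
  expect_equal(pretest_probability(0.05, c(a = "present"), reg),
               0.2105263158 / 1.2105263158, tolerance = 1e-9)
  # order invariance
  f <- c(a = "present", b = "absent", c = "present")
  perm <- f[c(3, 1, 2)]
  expect_equal(pretest_probability(0.1, f, reg),
               pretest_probability(0.1, perm, reg), tolerance = 1e-15)
  expect_error(pretest_probability(0.1, c(nope = "present"), reg), "nope")
  expect_error(pretest_probability(0, c(a = "present"), reg), "\\(0, 1\\)")
})

test_that("odds-form pre-test equals brute-force joint enumeration", {
  set.seed(101)
  for (rep in 1:5) {
    k <- sample(2:4, 1)
    sens <- runif(k, 0.55, 0.95)
    spec <- runif(k, 0.55, 0.95)
    lrs <- lapply(seq_len(k), function(i) lr_pair_from_sens_spec(sens[i], spec[i]))
    names(lrs) <- paste0("it", seq_len(k))
    reg <- tiny_registry(items = lrs)
    prev <- runif(1, 0.01, 0.3)
    states_grid <- expand.grid(rep(list(c("present", "absent")), k),
                               stringsAsFactors = FALSE)
    for (r in seq_len(nrow(states_grid))) {
      st <- setNames(unlist(states_grid[r, ]), names(lrs))
      expect_equal(pretest_probability(prev, st, reg),
                   oracle_posterior(prev, sens, spec, st),
                   tolerance = 1e-12)
    }
  }
})

test_that("imaging likelihood ratios follow sens/spec and time", {
  reg <- tiny_registry()
  ct <- reg$tests$noncontrast_ct
  expect_identical(likelihood_ratio(ct, "not_done", 5), 1)
  # pooled-style constant test: LR+ = 0.94/0.001 = 940
  pooled <- test_characteristics("p", "pooled", 0.94, 0.999)
  expect_equal(likelihood_ratio(pooled, "positive", 0), 940, tolerance = 1e-9)
  # perfect sensitivity annihilates on a negative result
  perfect <- test_characteristics("x", "perfect", 1, 0.99)
  expect_identical(likelihood_ratio(perfect, "negative", 2), 0)
  # perfect specificity gives the infinite-LR sentinel on a positive result
  spec1 <- test_characteristics("y", "spec1", 0.9, 1)
  expect_identical(likelihood_ratio(spec1, "positive", 2), Inf)
  # time dependence flows through the decay model
  expect_equal(likelihood_ratio(ct, "negative", 12),
               (1 - 0.98 * exp(-0.12)) / 0.999, tolerance = 1e-12)
})

test_that("post-test probability is the odds update with a recomputable trail", {
  reg <- tiny_registry()
  none <- patient_presentation(2)
  est <- posttest_probability(0.3, none, reg)
  expect_equal(est$posttest, 0.3, tolerance = 1e-15)
  expect_identical(nrow(est$applied_lrs), 0L)

  # hand-derived with c = 1: LR- at 12 h = 1 - 0.98 exp(-0.12)
  reg_c1 <- load_registry(make_registry_doc(tests = list(
    noncontrast_ct = list(sensitivity = 0.94, specificity = 1,
                          time_model = list(s0 = 0.98, rate = 0.01)))))
  pat <- patient_presentation(12, imaging_results = c(noncontrast_ct = "negative"))
  est <- posttest_probability(0.10, pat, reg_c1)
  lrm <- 1 - 0.98 * exp(-0.12)
  expect_equal(est$posttest, (0.1 * lrm) / (0.1 * lrm + 0.9 * 1),
               tolerance = 1e-12)
  # trail recomputes the posterior (estimate invariant)
  odds <- prob_to_odds(est$pretest) * prod(est$applied_lrs$lr)
  expect_equal(odds_to_prob(odds), est$posttest, tolerance = 1e-12)

  # a perfectly sensitive negative CT yields exactly zero
  reg_s <- load_registry(make_registry_doc(tests = list(
    noncontrast_ct = list(sensitivity = 0.94, specificity = 0.999,
                          stratified = stratified_bands))))
  pat3 <- patient_presentation(3, imaging_results = c(noncontrast_ct = "negative"))
  expect_identical(posttest_probability(0.9, pat3, reg_s)$posttest, 0)

  expect_error(
    posttest_probability(0.1, patient_presentation(
      1, imaging_results = c(mystery_scan = "negative")), reg),
    "mystery_scan")
})

test_that("posterior equals brute-force enumeration across imaging states", {
  reg <- tiny_registry()
  s_ct <- function(h) 0.98 * exp(-0.01 * h)
  s_cta <- 0.98
  c_ct <- 0.999
  c_cta <- 0.999
  for (h in c(0.5, 4, 18)) {
    for (r_ct in c("positive", "negative", "not_done")) {
      for (r_cta in c("positive", "negative", "not_done")) {
        pat <- patient_presentation(h, imaging_results = c(
          noncontrast_ct = r_ct, ct_angiogram = r_cta))
        got <- posttest_probability(0.2, pat, reg)$posttest
        want <- oracle_posterior(0.2, numeric(), numeric(), character(),
                                 test_sens = c(s_ct(h), s_cta),
                                 test_spec = c(c_ct, c_cta),
                                 test_results = c(r_ct, r_cta))
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("posterior is monotone in the prior and order-invariant", {
  reg <- tiny_registry()
  pat <- patient_presentation(8, imaging_results = c(
    noncontrast_ct = "negative", ct_angiogram = "negative"))
  pre <- seq(0.001, 0.999, length.out = 200)
  post <- vapply(pre, function(p) posttest_probability(p, pat, reg)$posttest, 0)
  expect_true(all(diff(post) > 0))

  swapped <- patient_presentation(8, imaging_results = c(
    ct_angiogram = "negative", noncontrast_ct = "negative"))
  expect_equal(posttest_probability(0.4, pat, reg)$posttest,
               posttest_probability(0.4, swapped, reg)$posttest,
               tolerance = 1e-12)

  # adding a positive result with LR > 1 strictly increases the posterior
  pos <- patient_presentation(8, imaging_results = c(
    noncontrast_ct = "negative", ct_angiogram = "positive"))
  expect_gt(posttest_probability(0.4, pos, reg)$posttest,
            posttest_probability(0.4, pat, reg)$posttest)
})
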