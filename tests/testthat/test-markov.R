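test_that("transition counting matches hand counts and handles empty tables", {
  tb <- table_from_sequences(list(a1 = c("E", "E", "S", "S")))
  cnt <- count_transitions(tb, grouping = character())
  expect_equal(cnt["E", "E"], 1L)
  expect_equal(cnt["E", "S"], 1L)
  expect_equal(cnt["S", "S"], 1L)
  expect_equal(sum(cnt), 3L)
  empty <- tb[0, ]
  attr(empty, "occasion_levels") <- attr(tb, "occasion_levels")
  expect_equal(sum(count_transitions(empty, grouping = character())), 0L)
  bad <- tb; bad$state[1] <- "X"
  expect_error(count_transitions(bad, grouping = character()),
               "unknown behavioural state")
})

test_that("saturated first-order fit reproduces empirical proportions", {
  set.seed(101)
  for (r in 1:10) {
    cnt <- rcounts(mixing_matrix(), n_row = sample(20:200, 1))
    fit <- fit_markov(cnt, order = 1)
    P <- transition_probabilities(fit)
    expect_lt(max(abs(P - cnt / rowSums(cnt))), 1e-6)
  }
})

test_that("zero-order fit returns pooled column proportions", {
  set.seed(102)
  cnt <- rcounts(mixing_matrix(), 150)
  fit <- fit_markov(cnt, order = 0)
  P <- transition_probabilities(fit)
  pooled <- colSums(cnt) / sum(cnt)
  for (i in 1:4) expect_equal(unname(P[i, ]), unname(pooled), tolerance = 1e-10)
})

test_that("first-order log-likelihood dominates the nested zero-order fit", {
  set.seed(103)
  for (r in 1:20) {
    pairs <- sim_pairs(mixing_matrix(), 200)
    f0 <- fit_markov(pairs, order = 0)
    f1 <- fit_markov(pairs, order = 1)
    expect_gte(f1$logLik, f0$logLik - 1e-10)
    expect_lte(f1$logLik, 0)
  }
})

test_that("softmax inversion matches the closed-form examples", {
  B <- matrix(0, 4, 4, dimnames = list(STATES, STATES))
  expect_equal(unname(transition_probabilities(B)),
               matrix(0.25, 4, 4), tolerance = 1e-12)
  B["S", "E"] <- log(3)
  expect_equal(unname(transition_probabilities(B)["S", ]),
               c(0.5, 1/6, 1/6, 1/6), tolerance = 1e-12)
  expect_true(all(abs(rowSums(transition_probabilities(B)) - 1) < 1e-10))
})

test_that("simulate -> fit round trip recovers the matrix within 3 SE", {
  P <- mixing_matrix()
  set.seed(104)
  pairs <- sim_pairs(P, 4000)
  fit <- fit_markov(pairs, order = 1)
  Ph <- transition_probabilities(fit)
  cnt <- fit$counts[[1]]
  se <- sqrt(P * (1 - P) / rowSums(cnt))
  expect_true(all(abs(Ph - P) <= 3 * se))
})

test_that("additive multinomial logit agrees with an independent optimiser", {
  set.seed(105)
  pairs <- sim_pairs(mixing_matrix(), 400)
  pairs$treatment <- sample(c("A", "B"), nrow(pairs), TRUE)
  fa <- fit_markov(pairs, order = 1, strata = "treatment",
                   interactions = FALSE)
  fn <- nnet::multinom(
    factor(state_to, levels = STATES) ~ factor(state_from) + factor(treatment),
    pairs, trace = FALSE, maxit = 1000, reltol = 1e-14)
  expect_equal(fa$logLik, as.numeric(logLik(fn)), tolerance = 1e-6)
  expect_equal(fa$df, attr(logLik(fn), "df"))
})

test_that("LRT handles identity, nesting and reference-category invariance", {
  set.seed(106)
  pairs <- sim_pairs(mixing_matrix(), 300)
  f1 <- fit_markov(pairs, order = 1)
  same <- lrt(f1, f1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  f0 <- fit_markov(pairs, order = 0)
  expect_error(lrt(f1, f0), "nested")
  other <- sim_pairs(mixing_matrix(), 301)
  expect_error(lrt(fit_markov(other, order = 0), f1), "same data")
  # statistic does not depend on the reference state
  stats <- vapply(STATES, function(r)
    lrt(fit_markov(pairs, order = 0, ref = r),
        fit_markov(pairs, order = 1, ref = r))$statistic, 0)
  expect_lt(max(stats) - min(stats), 1e-6)
})

test_that("time-homogeneity test is an LRT against occasion-stratified fits", {
  set.seed(107)
  des <- one_group_design(2, 15, 6)
  tb <- generate_experiment(des, one_group_params(mixing_matrix()),
                            seed = 31, measure = FALSE)
  pairs <- markresight:::transition_pairs(tb)
  homo <- lrt(fit_markov(pairs, order = 1),
              fit_markov(pairs, order = 1, strata = "occasion"))
  expect_gte(homo$statistic, 0)
  expect_true(homo$df > 0)
  expect_true(homo$p.value >= 0 && homo$p.value <= 1)
})

test_that("treatment-matrix comparison detects differing matrices", {
  set.seed(108)
  P1 <- mixing_matrix()
  P2 <- P1; P2["E", ] <- c(0.10, 0.60, 0.15, 0.15)  # p_ES shifted by 0.3
  # 300 transitions per group, margins weighted toward the E/S states as in
  # an exposed/sheltered-dominated chain
  marg <- c(120, 90, 60, 30)
  rej <- 0
  for (r in 1:100) {
    t <- compare_treatment_matrices(list(a = rcounts(P1, marg),
                                         b = rcounts(P2, marg)))
    rej <- rej + (t$p.value < 0.05)
  }
  expect_gte(rej / 100, 0.9)
  # and keeps its size under the null
  rej0 <- 0
  for (r in 1:200) {
    t <- compare_treatment_matrices(list(a = rcounts(P1, marg),
                                         b = rcounts(P1, marg)))
    rej0 <- rej0 + (t$p.value < 0.05)
  }
  expect_gt(rej0 / 200, 0.01)
  expect_lt(rej0 / 200, 0.10)
  empty <- rcounts(P1, 0)
  expect_error(compare_treatment_matrices(list(a = rcounts(P1, 50), b = empty)),
               "no transitions")
})

test_that("per-cell proportion tests match exact binomial intuition", {
  c1 <- matrix(0L, 4, 4, dimnames = list(STATES, STATES))
  c2 <- c1
  c1["E", "S"] <- 40; c1["E", "E"] <- 60
  c2["E", "S"] <- 40; c2["E", "E"] <- 60
  t_eq <- compare_transition_cell("E", "S", c1, c2)
  expect_equal(t_eq$p.value, 1, tolerance = 1e-12)
  c2["E", "S"] <- 90; c2["E", "E"] <- 10
  t_df <- compare_transition_cell("E", "S", c1, c2)
  expect_lt(t_df$p.value, 1e-6)
  expect_false(t_df$flagged)
  small <- c1; small["S", "E"] <- 2; small["S", "S"] <- 1
  t_small <- compare_transition_cell("S", "E", small, small)
  expect_true(t_small$flagged)
  zero <- matrix(0L, 4, 4, dimnames = list(STATES, STATES))
  expect_error(compare_transition_cell("O", "E", zero, c1), "zero row margin")
  # Sidak adjustment reported when a family size is given
  t_fam <- compare_transition_cell("E", "S", c1, c2, n_comparisons = 4)
  expect_true(t_fam$p.sidak >= t_fam$p.value)
})
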