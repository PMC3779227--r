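test_that("design validation enforces phase partition and counts", {
  occ <- paste0("w", 1:4)
  expect_error(experiment_design("A", 0, 10, occ,
                                 setNames(rep("before", 4), occ)),
               "plots_per_treatment")
  expect_error(experiment_design("A", 3, 10, occ,
                                 setNames(c("before", "during", "before",
                                            "after"), occ)),
               "contiguous")
  expect_error(experiment_design("A", 3, 10, occ,
                                 setNames(rep("before", 3), occ[-1])),
               "every occasion")
  d <- experiment_design("A", 3, 10, occ,
                         setNames(c("before", "before", "during", "after"), occ))
  expect_s3_class(d, "experiment_design")
})

test_that("generator rejects invalid or missing parameters", {
  P <- mixing_matrix()
  bad <- P; bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(one_group_params(bad), "sum to 1")
  neg <- P; neg[1, 1] <- -0.1; neg[1, 2] <- P[1, 2] + P[1, 1] + 0.1 - 0.1
  neg[1, ] <- c(-0.1, 0.5, 0.3, 0.3)
  expect_error(one_group_params(neg), ">= 0")
  expect_error(one_group_params(P, alpha = -1), "alpha")
  # parameters keyed for the wrong phase -> configuration error
  des <- one_group_design(1, 2, 3)
  k <- tp_key("T", "during")
  p <- generator_params(setNames(list(P), k), setNames(3, k),
                        setNames(list(c(E = 1, S = 1, O = 1)), k))
  expect_error(generate_experiment(des, p), "configuration error")
})

test_that("identity transition matrix freezes every animal in its initial state", {
  P <- diag(4); dimnames(P) <- list(STATES, STATES)
  des <- one_group_design(1, 10, 6)
  tb <- generate_experiment(des, one_group_params(P), seed = 3)
  per_animal <- tapply(tb$state, tb$animal_id,
                       function(s) length(unique(s)))
  expect_true(all(per_animal == 1))
})

test_that("generated transition frequencies match the specified matrix", {
  P <- mixing_matrix()
  P["E", ] <- c(0.5, 0.3, 0.1, 0.1)   # target cell p_ES = 0.3
  des <- one_group_design(3, 25, 9)
  tb <- generate_experiment(des, one_group_params(P), seed = 11,
                            measure = FALSE)
  cnt <- count_transitions(tb, grouping = character())
  n_E <- sum(cnt["E", ])
  p_hat <- cnt["E", "S"] / n_E
  se <- sqrt(0.3 * 0.7 / n_E)
  expect_lt(abs(p_hat - 0.3), 3 * se)
})

test_that("generation is byte-identical for the same seed", {
  sc <- scenario_asymmetric_competition(animals_per_plot = 4)
  t1 <- generate_experiment(sc$design, sc$params, seed = 99)
  t2 <- generate_experiment(sc$design, sc$params, seed = 99)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("long-run state frequencies converge to the stationary distribution", {
  P <- mixing_matrix()
  pi <- stationary_distribution(P)
  set.seed(7)
  s <- simulate_chain(P, 1e5)
  freq <- table(factor(s, STATES)) / length(s)
  tv <- sum(abs(freq - pi)) / 2
  expect_lt(tv, 0.02)
})

test_that("generated step lengths stay in bounds and follow the truncated Pareto", {
  des <- one_group_design(3, 25, 9)
  tb <- generate_experiment(des, one_group_params(mixing_matrix(), alpha = 3),
                            seed = 5, measure = FALSE)
  drawn <- attr(tb, "steps")$drawn_m
  expect_true(all(drawn >= 0.1 & drawn <= 4))
  set.seed(8)
  x <- rtpareto(1e4, 3, 0.1, 4)
  ks <- suppressWarnings(
    stats::ks.test(x, function(q) ptpareto(q, 3, 0.1, 4)))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("resighting is Bernoulli with the specified per-state probability", {
  P <- mixing_matrix()
  # close transitions into L so every recorded L is a detection failure
  P[, "L"] <- 0; P <- P / rowSums(P)
  des <- one_group_design(3, 25, 9)
  tb <- generate_experiment(des, one_group_params(P, resight = c(E = 0.8, S = 0.8, O = 0.8)),
                            seed = 13, measure = FALSE)
  n <- nrow(tb)
  p_hat <- mean(tb$state != "L")
  expect_lt(abs(p_hat - 0.8), 3 * sqrt(0.8 * 0.2 / n))
})

test_that("asymmetric-competition scenario encodes the directional effects", {
  sc <- scenario_asymmetric_competition()
  p <- sc$params
  ctrl_b <- p$transition_matrix[[tp_key("0U25A", "before")]]
  ctrl_a <- p$transition_matrix[[tp_key("0U25A", "after")]]
  expect_identical(ctrl_b, ctrl_a)
  expect_identical(p$step_shape[[tp_key("0U25A", "before")]],
                   p$step_shape[[tp_key("0U25A", "after")]])
  urch <- p$transition_matrix[[tp_key("18U25A", "during")]]
  expect_lt(urch["E", "E"], ctrl_b["E", "E"])
  expect_gt(urch["E", "S"], ctrl_b["E", "S"])
  expect_gt(urch["S", "S"], ctrl_b["S", "S"])
  expect_lt(urch["S", "E"], ctrl_b["S", "E"])
  expect_lt(p$step_shape[[tp_key("18U25A", "during")]],
            p$step_shape[[tp_key("0U25A", "during")]])
  expect_lt(p$resight_prob[[tp_key("18U25A", "during")]]["E"],
            p$resight_prob[[tp_key("0U25A", "during")]]["E"])
  # estimated p_EE on a long realisation preserves the ordering
  set.seed(21)
  est_pEE <- function(P) {
    pr <- sim_pairs(P, 10000)
    cnt <- table(factor(pr$state_from, STATES), factor(pr$state_to, STATES))
    cnt["E", "E"] / sum(cnt["E", ])
  }
  expect_lt(est_pEE(urch), est_pEE(ctrl_b))
})

test_that("observation tables and generator parameters round-trip through disk", {
  sc <- scenario_asymmetric_competition(animals_per_plot = 3)
  tb <- generate_experiment(sc$design, sc$params, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_observations(tb, f)
  tb2 <- read_observations(f)
  expect_equal(as.data.frame(tb)[, 1:7], as.data.frame(tb2)[, 1:7])
  expect_identical(attr(tb2, "occasion_levels"), sc$design$occasions)
  g <- tempfile(fileext = ".yaml")
  write_generator_params(sc$params, g)
  p2 <- read_generator_params(g)
  expect_equal(p2$transition_matrix, sc$params$transition_matrix)
  expect_equal(p2$step_shape, sc$params$step_shape)
  expect_equal(p2$step_bounds, sc$params$step_bounds)
})
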