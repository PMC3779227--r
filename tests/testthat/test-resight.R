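test_that("percent resighted counts E, S, O and not L", {
  tb <- table_from_sequences(list(a = c("E", "E"), b = c("S", "L"),
                                  c = c("O", "L"), d = c("E", "L"),
                                  e = c("S", "E")))
  rs <- percent_resighted(tb)
  expect_equal(rs$percent[rs$occasion == "t1"], 100)
  expect_equal(rs$percent[rs$occasion == "t2"], 40)
  expect_equal(rs$n_cohort, c(5, 5))
})

test_that("mean resight percentage tracks the detection probability", {
  P <- mixing_matrix(); P[, "L"] <- 0; P <- P / rowSums(P)
  des <- one_group_design(3, 25, 9)
  tb <- generate_experiment(des, one_group_params(P, resight = c(E = 0.9, S = 0.9, O = 0.9)),
                            seed = 401, measure = FALSE)
  rs <- percent_resighted(tb)
  n_obs <- sum(rs$n_cohort)          # one detection trial per plot-occasion row
  se <- 100 * sqrt(0.9 * 0.1 / n_obs)
  expect_lt(abs(mean(rs$percent) - 90), 3 * se)
})

test_that("series percentages are permutation-invariant", {
  sc <- scenario_asymmetric_competition(animals_per_plot = 4)
  tb <- generate_experiment(sc$design, sc$params, seed = 402, measure = FALSE)
  r1 <- percent_resighted(tb)
  tb2 <- tb[sample(nrow(tb)), ]
  attr(tb2, "occasion_levels") <- attr(tb, "occasion_levels")
  r2 <- percent_resighted(tb2)
  expect_equal(r1, r2)
})

test_that("Greenhouse-Geisser epsilon hits its exact limits", {
  # two occasions force sphericity: epsilon exactly 1
  set.seed(403)
  s2 <- expand.grid(plot = paste0("p", 1:6), occasion = c("t1", "t2"))
  s2$treatment <- rep(rep(c("A", "B"), each = 3), 2)
  s2$percent <- 70 + rnorm(12, 0, 5)
  a2 <- rm_anova_gg(s2)
  expect_equal(a2$epsilon, 1)
  expect_equal(a2$table$df.gg, a2$table$df)
  # compound-symmetric covariance: epsilon near 1, bounded correctly
  t <- 4
  s4 <- do.call(rbind, lapply(1:40, function(i) {
    data.frame(plot = paste0("p", i), treatment = if (i <= 20) "A" else "B",
               occasion = paste0("t", 1:t),
               percent = 70 + rnorm(1, 0, 6) + rnorm(t, 0, 2))
  }))
  a4 <- rm_anova_gg(s4)
  expect_gt(a4$epsilon, 0.85)
  expect_lte(a4$epsilon, 1)
  expect_gte(a4$epsilon, 1 / (t - 1))
})

test_that("GG-adjusted p is never smaller for within terms in the rejection regime", {
  set.seed(404)
  for (r in 1:20) {
    s <- do.call(rbind, lapply(1:6, function(i) {
      tr <- if (i <= 3) "A" else "B"
      base <- cumsum(rnorm(5, 0, 4))    # time trend => F_time usually > 1
      data.frame(plot = paste0("p", i), treatment = tr,
                 occasion = paste0("t", 1:5),
                 percent = 70 + base + (tr == "B") * seq(0, 8, length.out = 5) +
                   rnorm(5, 0, 3))
    }))
    a <- rm_anova_gg(s)
    tab <- a$table
    for (term in c("Time", "Treatment:Time")) {
      i <- which(tab$term == term)
      # the correction never rejects where the uncorrected test does not
      if (tab$p[i] > 0.05) expect_gt(tab$p.gg[i], 0.05)
      if (tab$F[i] >= 2) expect_gte(tab$p.gg[i], tab$p[i] - 1e-12)
    }
  }
})

test_that("ANOVA table agrees with the multivariate-model cross-check", {
  set.seed(405)
  s <- do.call(rbind, lapply(1:6, function(i) {
    tr <- if (i <= 3) "A" else "B"
    data.frame(plot = paste0("p", i), treatment = tr,
               occasion = paste0("t", 1:4),
               percent = 70 + rnorm(4, 0, 5) + (tr == "B") * 6)
  }))
  a <- rm_anova_gg(s)
  # independent route: car's repeated-measures machinery on the wide mlm
  wide <- reshape(s, idvar = c("plot", "treatment"), timevar = "occasion",
                  direction = "wide")
  Y <- as.matrix(wide[, paste0("percent.t", 1:4)])
  mlm <- lm(Y ~ treatment, data = wide,
            contrasts = list(treatment = "contr.sum"))
  av <- car::Anova(mlm, idata = data.frame(occ = factor(paste0("t", 1:4))),
                   idesign = ~ occ, type = 3)
  sm <- summary(av, multivariate = FALSE)
  uni <- sm$univariate.tests
  expect_equal(a$table$F[a$table$term == "Treatment"],
               unname(uni["treatment", "F value"]), tolerance = 1e-8)
  expect_equal(a$table$F[a$table$term == "Time"],
               unname(uni["occ", "F value"]), tolerance = 1e-8)
  expect_equal(a$table$F[a$table$term == "Treatment:Time"],
               unname(uni["treatment:occ", "F value"]), tolerance = 1e-8)
  expect_equal(a$epsilon,
               unname(sm$pval.adjustments["occ", "GG eps"]), tolerance = 1e-8)
})

test_that("GG correction repairs type-I inflation under AR(1) correlation", {
  set.seed(406)
  rho <- 0.9; t <- 9
  # AR(1) correlation with a variance ramp across occasions: a strong
  # sphericity violation
  sds <- seq(4, 16, length.out = t)
  Sig <- rho^abs(outer(1:t, 1:t, "-")) * outer(sds, sds)
  L <- chol(Sig)
  reps <- 300
  rej_raw <- rej_gg <- 0
  for (r in 1:reps) {
    s <- do.call(rbind, lapply(1:6, function(i) {
      tr <- if (i <= 3) "A" else "B"
      data.frame(plot = paste0("p", i), treatment = tr,
                 occasion = paste0("t", 1:t),
                 percent = 70 + drop(rnorm(t) %*% L))
    }))
    a <- rm_anova_gg(s)
    i <- which(a$table$term == "Treatment:Time")
    rej_raw <- rej_raw + (a$table$p[i] < 0.05)
    rej_gg <- rej_gg + (a$table$p.gg[i] < 0.05)
  }
  expect_gt(rej_raw / reps, 0.08)   # uncorrected test is anticonservative
  expect_lte(rej_gg / reps, 0.08)   # GG correction restores the size
})

test_that("period pooling averages per plot and validates its mapping", {
  s <- data.frame(plot = rep(c("p1", "p2"), each = 3), treatment = "A",
                  occasion = rep(c("t1", "t2", "t3"), 2),
                  percent = c(10, 20, 30, 50, 50, 50))
  mp <- c(t1 = "P1", t2 = "P1", t3 = "P2")
  pooled <- pool_periods(s, mp)
  expect_equal(pooled$percent[pooled$plot == "p1" & pooled$period == "P1"], 15)
  expect_equal(pooled$percent[pooled$plot == "p1" & pooled$period == "P2"], 30)
  expect_true(all(pooled$percent[pooled$plot == "p2"] == 50))
  expect_error(pool_periods(s, mp[-1]), "unmapped")
  # constant series pools to the constant
  s$percent <- 42
  expect_true(all(pool_periods(s, mp)$percent == 42))
})

test_that("pooling then ANOVA equals ANOVA on pre-averaged data", {
  sc <- scenario_asymmetric_competition(animals_per_plot = 6)
  tb <- generate_experiment(sc$design, sc$params, seed = 407, measure = FALSE)
  rs <- percent_resighted(tb)
  pooled <- pool_periods(rs)
  manual <- aggregate(list(percent = rs$percent),
                      by = list(plot = rs$plot, treatment = rs$treatment,
                                period = rs$phase), FUN = mean)
  a1 <- rm_anova_gg(pooled, time = "period")
  a2 <- rm_anova_gg(manual, time = "period")
  expect_equal(a1$table$F, a2$table$F)
  expect_equal(a1$epsilon, a2$epsilon)
})

test_that("planned comparisons honour the Sidak family adjustment", {
  expect_equal(sidak_alpha(4), 1 - 0.95^(1/4))
  expect_equal(round(sidak_alpha(4), 2), 0.01)  # ~0.0127, prints as 0.0125-ish
  pooled <- data.frame(plot = rep(paste0("p", 1:6), each = 2),
                       treatment = rep(c("A", "A", "A", "B", "B", "B"),
                                       each = 2),
                       period = rep(c("before", "during"), 6),
                       percent = c(90, 88, 92, 91, 89, 90,
                                   91, 60, 90, 62, 92, 58))
  cmp <- list(
    list(a = c(treatment = "A", period = "during"),
         b = c(treatment = "A", period = "during")),        # self
    list(a = c(treatment = "B", period = "before"),
         b = c(treatment = "B", period = "during")),        # paired, strong
    list(a = c(treatment = "A", period = "during"),
         b = c(treatment = "B", period = "during")))        # between, strong
  tab <- planned_comparisons(pooled, cmp)
  expect_equal(tab$F[1], 0)
  expect_false(tab$significant[1])
  expect_true(tab$significant[2])
  expect_true(tab$significant[3])
  expect_equal(unique(tab$alpha_adjusted), sidak_alpha(3))
  bad <- list(list(a = c(treatment = "Z", period = "during"),
                   b = c(treatment = "A", period = "during")))
  expect_error(planned_comparisons(pooled, bad), "undefined cell")
})

test_that("incomplete or unbalanced series are refused", {
  s <- expand.grid(plot = paste0("p", 1:4), occasion = c("t1", "t2", "t3"))
  s$treatment <- rep(c("A", "A", "A", "B"), 3)
  s$percent <- 70
  expect_error(rm_anova_gg(s), "balanced")
  s2 <- s[-1, ]
  expect_error(rm_anova_gg(s2), "exactly one value")
})
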