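#' Percentage of tagged animals resighted per plot and occasion
#'
#' An animal counts as resighted on a visit when it was found anywhere in
#' the search zone — exposed, sheltered, or within the 1 m zone outside
#' the plot (states `E`, `S`, `O`); lost animals (`L`) do not count. The
#' denominator is the tagged cohort of the plot.
#'
#' @param table an observation table.
#' @param resight_states states counting as resighted (config; default
#'   `c("E", "S", "O")`).
#' @return Data frame of class `resight_series`: `plot`, `treatment`,
#'   `occasion`, `phase`, `n_cohort`, `n_resighted`, `percent`.
#' @export
percent_resighted <- function(table, resight_states = c("E", "S", "O")) {
  validate_observations(table)
  stopifnot(all(resight_states %in% MR_STATES))
  occ <- occasion_levels(table)
  cohort <- tapply(table$animal_id, table$plot,
                   function(a) length(unique(a)))
  if (any(cohort == 0)) stop("undefined: plot with empty tagged cohort")
  agg <- aggregate(list(n_resighted = table$state %in% resight_states),
                   by = list(plot = table$plot, treatment = table$treatment,
                             phase = table$phase, occasion = table$occasion),
                   FUN = sum)
  agg$n_cohort <- as.integer(cohort[agg$plot])
  agg$percent <- 100 * agg$n_resighted / agg$n_cohort
  agg <- agg[order(agg$treatment, agg$plot, match(agg$occasion, occ)),
             c("plot", "treatment", "occasion", "phase",
               "n_cohort", "n_resighted", "percent")]
  rownames(agg) <- NULL
  attr(agg, "occasion_levels") <- occ
  class(agg) <- c("resight_series", "data.frame")
  agg
}

#' Pool a resight series into experiment periods
#'
#' Averages the per-plot series within periods (e.g. weeks 1-3 / 4-6 /
#' 7-9 for a before / during / after design) to limit the number of
#' planned comparisons.
#'
#' @param series a [percent_resighted()] result (or data frame with
#'   `plot`, `treatment`, `occasion`, `percent`).
#' @param mapping named character vector occasion -> period covering all
#'   occasions; default maps each occasion to its `phase`.
#' @return Data frame with `plot`, `treatment`, `period`, `percent`.
#' @export
pool_periods <- function(series, mapping = NULL) {
  if (is.null(mapping)) {
    if (!"phase" %in% names(series))
      stop("no mapping given and series has no phase column")
    mapping <- tapply(series$phase, series$occasion, `[`, 1)
  }
  occ <- unique(series$occasion)
  unmapped <- setdiff(occ, names(mapping))
  if (length(unmapped))
    stop("unmapped occasion(s): ", paste(unmapped, collapse = ", "))
  series$period <- unname(mapping[series$occasion])
  out <- aggregate(list(percent = series$percent),
                   by = list(plot = series$plot,
                             treatment = series$treatment,
                             period = series$period),
                   FUN = mean)
  out[order(out$treatment, out$plot, out$period), ]
}

#' Two-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' The standard between (treatment) x within (time) univariate
#' repeated-measures decomposition with plots as subjects. The
#' Greenhouse-Geisser epsilon is estimated from the pooled within-group
#' covariance of the repeated measures and used to deflate the
#' within-subject degrees of freedom when sphericity fails; with only two
#' occasions sphericity holds trivially and epsilon is exactly 1.
#'
#' @param series a [percent_resighted()] (or pooled) data frame with
#'   columns `plot`, `treatment`, `percent` and a time column.
#' @param time name of the within-subject time column (default
#'   `"occasion"`, or `"period"` if present instead).
#' @return Object of class `rm_anova`: the ANOVA `table` (df, adjusted
#'   df, MS, F, unadjusted and GG-adjusted p) and `epsilon`.
#' @export
rm_anova_gg <- function(series, time = NULL) {
  if (is.null(time))
    time <- if ("occasion" %in% names(series)) "occasion" else "period"
  stopifnot(all(c("plot", "treatment", "percent", time) %in% names(series)))
  df <- data.frame(plot = factor(series$plot),
                   treatment = factor(series$treatment),
                   time = factor(series[[time]],
                                 levels = unique(series[[time]])),
                   y = series$percent)
  tt <- nlevels(df$time)
  g <- nlevels(df$treatment)
  # balance / completeness
  cell <- table(df$plot, df$time)
  if (any(cell != 1))
    stop("each plot must have exactly one value per time point (no imputation)")
  subj_tr <- tapply(as.character(df$treatment), df$plot, `[`, 1)
  n_per <- table(subj_tr)
  if (length(unique(n_per)) != 1)
    stop("design must be balanced across treatments")
  n <- unname(n_per[1])

  Y <- matrix(NA_real_, nlevels(df$plot), tt,
              dimnames = list(levels(df$plot), levels(df$time)))
  Y[cbind(as.integer(df$plot), as.integer(df$time))] <- df$y
  grp <- factor(subj_tr[levels(df$plot)])

  grand <- mean(Y)
  m_subj <- rowMeans(Y)
  m_time <- colMeans(Y)
  m_grp <- tapply(m_subj, grp, mean)
  m_gt <- apply(Y, 2, function(col) tapply(col, grp, mean))  # g x t
  if (g == 1) m_gt <- matrix(m_gt, nrow = 1)

  ss_total <- sum((Y - grand)^2)
  ss_subj <- tt * sum((m_subj - grand)^2)
  ss_treat <- n * tt * sum((m_grp - grand)^2)
  ss_err_b <- ss_subj - ss_treat
  ss_time <- g * n * sum((m_time - grand)^2)
  ss_int <- n * sum((m_gt - outer(as.vector(m_grp), rep(1, tt)) -
                       outer(rep(1, g), m_time) + grand)^2)
  ss_err_w <- ss_total - ss_subj - ss_time - ss_int

  df_treat <- g - 1
  df_err_b <- g * (n - 1)
  df_time <- tt - 1
  df_int <- (g - 1) * (tt - 1)
  df_err_w <- g * (n - 1) * (tt - 1)

  # GG epsilon from the pooled within-group covariance of the measures
  Yc <- Y
  for (lev in levels(grp)) {
    rows <- which(grp == lev)
    Yc[rows, ] <- sweep(Y[rows, , drop = FALSE], 2,
                        colMeans(Y[rows, , drop = FALSE]))
  }
  S <- crossprod(Yc) / (nrow(Y) - g)
  C <- qr.Q(qr(stats::contr.helmert(tt)))          # orthonormal, cols sum 0
  M <- t(C) %*% S %*% C
  eps <- sum(diag(M))^2 / (df_time * sum(M^2))
  eps <- min(max(eps, 1 / df_time), 1)

  ms <- function(ss, d) ss / d
  F_treat <- ms(ss_treat, df_treat) / ms(ss_err_b, df_err_b)
  F_time <- ms(ss_time, df_time) / ms(ss_err_w, df_err_w)
  F_int <- ms(ss_int, df_int) / ms(ss_err_w, df_err_w)

  tab <- data.frame(
    term = c("Treatment", "Error(between)", "Time", "Treatment:Time",
             "Error(within)"),
    df = c(df_treat, df_err_b, df_time, df_int, df_err_w),
    df.gg = c(df_treat, df_err_b, eps * df_time, eps * df_int,
              eps * df_err_w),
    MS = c(ms(ss_treat, df_treat), ms(ss_err_b, df_err_b),
           ms(ss_time, df_time), ms(ss_int, df_int),
           ms(ss_err_w, df_err_w)),
    F = c(F_treat, NA, F_time, F_int, NA),
    p = c(pf(F_treat, df_treat, df_err_b, lower.tail = FALSE), NA,
          pf(F_time, df_time, df_err_w, lower.tail = FALSE),
          pf(F_int, df_int, df_err_w, lower.tail = FALSE), NA),
    p.gg = c(pf(F_treat, df_treat, df_err_b, lower.tail = FALSE), NA,
             pf(F_time, eps * df_time, eps * df_err_w, lower.tail = FALSE),
             pf(F_int, eps * df_int, eps * df_err_w, lower.tail = FALSE),
             NA),
    stringsAsFactors = FALSE)
  structure(list(table = tab, epsilon = eps, n_subjects = nrow(Y),
                 n_times = tt, n_groups = g),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (%d groups x %d subjects x %d times)\n",
              x$n_groups, x$n_subjects / x$n_groups, x$n_times))
  cat(sprintf("Greenhouse-Geisser epsilon = %.4f\n", x$epsilon))
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Planned comparisons between treatment/period cells
#'
#' Per-comparison F tests (t squared) on per-plot cell means with a
#' family-adjusted significance threshold (Dunn-Sidak by default). Cells
#' from different treatments are compared with a two-sample t on plot
#' means; two periods of the same treatment are compared with a paired t
#' across its plots.
#'
#' @param pooled a [pool_periods()]-style data frame (`plot`, `treatment`,
#'   `period`, `percent`).
#' @param comparisons list of comparisons, each
#'   `list(a = c(treatment=, period=), b = c(treatment=, period=))`.
#' @param alpha base family-wise level (default 0.05).
#' @param alpha_adjusted optional explicit per-comparison threshold,
#'   overriding the Sidak computation (some published families use rounded
#'   thresholds such as 0.0125).
#' @return Data frame: one row per comparison with `F`, `df1`, `df2`, `p`,
#'   the threshold used and a significance flag.
#' @export
planned_comparisons <- function(pooled, comparisons, alpha = 0.05,
                                alpha_adjusted = NULL) {
  stopifnot(length(comparisons) >= 1)
  thr <- if (is.null(alpha_adjusted)) sidak_alpha(length(comparisons), alpha)
         else alpha_adjusted
  cell <- function(spec) {
    z <- pooled[pooled$treatment == spec[["treatment"]] &
                  pooled$period == spec[["period"]], ]
    if (nrow(z) == 0)
      stop("usage error: undefined cell ", spec[["treatment"]], "/",
           spec[["period"]])
    z
  }
  rows <- lapply(comparisons, function(cmp) {
    A <- cell(cmp$a); B <- cell(cmp$b)
    if (identical(cmp$a, cmp$b)) {
      res <- list(F = 0, df1 = 1, df2 = nrow(A) - 1, p = 1)
    } else if (cmp$a[["treatment"]] == cmp$b[["treatment"]]) {
      d <- A$percent[order(A$plot)] - B$percent[order(B$plot)]
      if (all(abs(d) < 1e-12)) {
        res <- list(F = 0, df1 = 1, df2 = length(d) - 1, p = 1)
      } else {
        t <- mean(d) / (sd(d) / sqrt(length(d)))
        res <- list(F = t^2, df1 = 1, df2 = length(d) - 1,
                    p = pf(t^2, 1, length(d) - 1, lower.tail = FALSE))
      }
    } else {
      na <- nrow(A); nb <- nrow(B)
      sp2 <- ((na - 1) * var(A$percent) + (nb - 1) * var(B$percent)) /
        (na + nb - 2)
      if (sp2 < 1e-12) {
        res <- list(F = 0, df1 = 1, df2 = na + nb - 2, p = 1)
      } else {
        t <- (mean(A$percent) - mean(B$percent)) /
          sqrt(sp2 * (1 / na + 1 / nb))
        res <- list(F = t^2, df1 = 1, df2 = na + nb - 2,
                    p = pf(t^2, 1, na + nb - 2, lower.tail = FALSE))
      }
    }
    data.frame(
      comparison = paste0(cmp$a[["treatment"]], ":", cmp$a[["period"]],
                          " vs ", cmp$b[["treatment"]], ":", cmp$b[["period"]]),
      F = res$F, df1 = res$df1, df2 = res$df2, p = res$p,
      alpha_adjusted = thr, significant = res$p < thr,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
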