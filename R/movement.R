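#' Classify animals as sedentary or mobile
#'
#' An animal is sedentary over an inter-survey interval when it moved at
#' most `threshold` metres, and mobile when it moved more. The default
#' 0.4 m matches the break in observed step-length histograms; 0.2 m and
#' 0.6 m are the usual sensitivity settings.
#'
#' @param steps a [step_distances()] result, or a data frame with a
#'   `distance_m` column.
#' @param threshold sedentary/mobile cut in metres (default 0.4).
#' @return The input with added columns `mobile` (logical), `label`
#'   (`"sedentary"`/`"mobile"`) and `threshold`, class `mobility_labels`.
#' @export
#' @examples
#' classify_mobility(data.frame(distance_m = c(0.1, 0.4, 0.41)))$label
classify_mobility <- function(steps, threshold = 0.4) {
  stopifnot(is.data.frame(steps), "distance_m" %in% names(steps),
            threshold >= 0)
  if (any(steps$distance_m < 0, na.rm = TRUE))
    stop("distances must be non-negative")
  out <- as.data.frame(steps)
  out$mobile <- out$distance_m > threshold
  out$label <- ifelse(out$mobile, "mobile", "sedentary")
  out$threshold <- threshold
  class(out) <- c("mobility_labels", "data.frame")
  out
}

#' Sedentary/mobile proportions by group
#'
#' @param labels a [classify_mobility()] result.
#' @param by grouping columns (default treatment x destination occasion).
#' @return Data frame with counts and the mobile proportion per group.
#' @export
mobility_proportions <- function(labels, by = c("treatment", "occasion_to")) {
  by <- intersect(by, names(labels))
  ag <- aggregate(labels["mobile"], labels[by],
                  function(z) c(n = length(z), mobile = sum(z)))
  out <- cbind(ag[by], n = ag$mobile[, "n"],
               n_mobile = ag$mobile[, "mobile"])
  out$prop_mobile <- out$n_mobile / out$n
  out
}

#' Binary GEE for repeated mobility outcomes
#'
#' Fits a marginal logistic model for a binary outcome observed repeatedly
#' on clustered subjects (animals across survey occasions) by generalised
#' estimating equations, with a working correlation structure
#' (`independence`, `exchangeable`, or `unstructured` — the default, which
#' makes no assumption about the correlation between time points) and
#' robust (sandwich) standard errors. Wald statistics are reported per
#' coefficient (`W = coefficient / robust SE`, compared to the standard
#' normal), and per term: for a multi-level factor both the joint Wald
#' chi-square and the single-df test on the sum (linear combination) of
#' its coefficients.
#'
#' @param formula model formula, e.g. `mobile ~ treatment + plot`.
#' @param data data frame containing outcome, covariates, `id` and `waves`.
#' @param id name of the cluster (animal) column.
#' @param waves name of the occasion column aligning observations within
#'   clusters (needed for the unstructured correlation).
#' @param corstr working correlation structure.
#' @param maxit,tol iteration controls.
#' @return Object of class `gee_fit`: `coefficients`, `robust.se`,
#'   `vcov` (sandwich), `wald` (per-coefficient table), `term_tests`,
#'   `corstr`, `working_correlation`, `n_clusters`, `iterations`.
#' @export
fit_gee_binary <- function(formula, data, id, waves = NULL,
                           corstr = c("unstructured", "independence",
                                      "exchangeable"),
                           maxit = 100, tol = 1e-10) {
  corstr <- match.arg(corstr)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.numeric(y)
  if (is.factor(y)) y <- as.numeric(y) - 1
  if (!all(y %in% c(0, 1))) stop("outcome must be binary")
  if (all(y == y[1]))
    warning("separation: all outcomes identical")
  X <- model.matrix(formula, mf)
  cl <- factor(data[[id]][as.integer(rownames(mf))])
  wv <- if (is.null(waves)) {
    stats::ave(seq_along(cl), cl, FUN = seq_along)
  } else as.integer(factor(data[[waves]][as.integer(rownames(mf))]))
  Tmax <- max(table(cl))
  if (corstr != "independence" && Tmax < 2)
    stop("non-independence structures need >= 2 observations per cluster")

  idx <- split(seq_along(y), cl)
  p <- ncol(X)
  beta <- tryCatch(coef(glm.fit2(X, y)), error = function(e) rep(0, p))
  R <- diag(max(wv))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    v <- mu * (1 - mu)
    v <- pmax(v, 1e-10)
    e <- (y - mu) / sqrt(v)
    # update working correlation
    if (corstr == "exchangeable") {
      num <- 0; den <- 0
      for (ix in idx) {
        ni <- length(ix)
        if (ni < 2) next
        ee <- e[ix]
        num <- num + (sum(ee)^2 - sum(ee^2)) / 2
        den <- den + ni * (ni - 1) / 2
      }
      alpha <- num / max(den - p, 1)
      alpha <- max(min(alpha, 0.99), -0.99)
      Tm <- max(wv)
      R <- matrix(alpha, Tm, Tm); diag(R) <- 1
    } else if (corstr == "unstructured") {
      Tm <- max(wv)
      Rnum <- matrix(0, Tm, Tm); Rden <- matrix(0, Tm, Tm)
      for (ix in idx) {
        w <- wv[ix]; ee <- e[ix]
        Rnum[w, w] <- Rnum[w, w] + outer(ee, ee)
        Rden[w, w] <- Rden[w, w] + 1
      }
      R <- Rnum / pmax(Rden, 1)
      d <- sqrt(diag(R)); d[d <= 0] <- 1
      R <- R / outer(d, d)
      diag(R) <- 1
      # guard against non-invertible estimates
      if (inherits(try(solve(R), silent = TRUE), "try-error"))
        R <- 0.95 * R + 0.05 * diag(Tm)
    }
    # estimating-equation update
    A <- matrix(0, p, p); u <- numeric(p)
    for (ix in idx) {
      w <- wv[ix]
      Xi <- X[ix, , drop = FALSE]
      vi <- v[ix]
      Di <- Xi * vi
      Vi <- sqrt(vi) * R[w, w, drop = FALSE] %*% diag(sqrt(vi), length(ix))
      Wi <- solve(Vi, cbind(Di, y[ix] - mu[ix]))
      A <- A + crossprod(Di, Wi[, seq_len(p), drop = FALSE])
      u <- u + drop(crossprod(Di, Wi[, p + 1]))
    }
    step <- solve(A, u)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  if (it == maxit && max(abs(step)) >= sqrt(tol))
    stop("fitting error: GEE did not converge in ", maxit, " iterations")

  # sandwich variance
  eta <- drop(X %*% beta); mu <- plogis(eta); v <- pmax(mu * (1 - mu), 1e-10)
  A <- matrix(0, p, p); M <- matrix(0, p, p)
  for (ix in idx) {
    w <- wv[ix]
    Xi <- X[ix, , drop = FALSE]
    vi <- v[ix]
    Di <- Xi * vi
    Vi <- sqrt(vi) * R[w, w, drop = FALSE] %*% diag(sqrt(vi), length(ix))
    Wi <- solve(Vi, cbind(Di, y[ix] - mu[ix]))
    A <- A + crossprod(Di, Wi[, seq_len(p), drop = FALSE])
    g <- drop(crossprod(Di, Wi[, p + 1]))
    M <- M + tcrossprod(g)
  }
  Ainv <- solve(A)
  V <- Ainv %*% M %*% t(Ainv)
  se <- sqrt(diag(V))
  W <- beta / se
  wald <- data.frame(coefficient = colnames(X), estimate = beta,
                     robust.se = se, W = W,
                     p.value = 2 * pnorm(-abs(W)),
                     stringsAsFactors = FALSE)
  rownames(wald) <- NULL

  # per-term tests
  terms_obj <- stats::terms(formula)
  assign <- attr(X, "assign")
  term_labels <- attr(terms_obj, "term.labels")
  term_tests <- NULL
  if (length(term_labels)) {
    term_tests <- do.call(rbind, lapply(seq_along(term_labels), function(k) {
      cols <- which(assign == k)
      Lb <- beta[cols]
      Vb <- V[cols, cols, drop = FALSE]
      chi <- tryCatch(drop(t(Lb) %*% solve(Vb, Lb)), error = function(e) NA)
      comb <- sum(Lb)
      comb_se <- sqrt(sum(Vb))
      data.frame(term = term_labels[k], df = length(cols),
                 wald.chisq = chi,
                 p.chisq = pchisq(chi, length(cols), lower.tail = FALSE),
                 W.combined = comb / comb_se,
                 p.combined = 2 * pnorm(-abs(comb / comb_se)),
                 stringsAsFactors = FALSE)
    }))
    rownames(term_tests) <- NULL
  }
  structure(list(coefficients = setNames(beta, colnames(X)),
                 robust.se = setNames(se, colnames(X)), vcov = V,
                 wald = wald, term_tests = term_tests, corstr = corstr,
                 working_correlation = R, n_clusters = length(idx),
                 iterations = it, formula = formula),
            class = "gee_fit")
}

# minimal logistic MLE for initialisation
glm.fit2 <- function(X, y) {
  stats::glm.fit(X, y, family = binomial())
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("Binary GEE (%s working correlation, %d clusters, %d iterations)\n",
              x$corstr, x$n_clusters, x$iterations))
  print(x$wald, digits = 4)
  if (!is.null(x$term_tests)) {
    cat("Term tests:\n")
    print(x$term_tests, digits = 4)
  }
  invisible(x)
}

#' G-test of independence with Williams's correction
#'
#' Log-likelihood-ratio test of independence for an r x c contingency
#' table: `G = 2 sum O log(O / E)` with expected counts from the margins
#' (empty cells contribute 0 by the `0 log 0 = 0` convention). Williams's
#' correction divides G by
#' `q = 1 + (N sum(1/r_i) - 1)(N sum(1/c_j) - 1) / (6 N (r-1)(c-1))`,
#' which tempers the type-I inflation of G at low counts; `q >= 1` always,
#' so the corrected statistic never exceeds the raw one.
#'
#' @param tab matrix of non-negative integer counts with positive margins.
#' @param correct apply Williams's correction (default `TRUE`).
#' @return Object of class `g_test`: `G`, `q`, `statistic` (corrected),
#'   `df`, `p.value`, `table`.
#' @export
#' @examples
#' g_test_williams(matrix(c(10, 10, 10, 10), 2))   # G = 0, p = 1
g_test_williams <- function(tab, correct = TRUE) {
  stopifnot(is.matrix(tab), all(tab >= 0), all(tab == round(tab)))
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("undefined: table has a zero margin")
  E <- outer(rs, cs) / N
  nz <- tab > 0
  G <- 2 * sum(tab[nz] * log(tab[nz] / E[nz]))
  G <- max(G, 0)
  r <- nrow(tab); cc <- ncol(tab)
  df <- (r - 1) * (cc - 1)
  q <- 1 + (N * sum(1 / rs) - 1) * (N * sum(1 / cs) - 1) / (6 * N * df)
  stat <- if (correct) G / q else G
  structure(list(G = G, q = q, statistic = stat, df = df,
                 p.value = pchisq(stat, df, lower.tail = FALSE),
                 corrected = correct, table = tab),
            class = "g_test")
}

#' @export
print.g_test <- function(x, ...) {
  cat(sprintf("G-test of independence: G = %.4g, Williams q = %.4f,\n",
              x$G, x$q))
  cat(sprintf("  %s = %.4g, df = %d, p = %.4g\n",
              if (x$corrected) "G/q" else "G", x$statistic, x$df, x$p.value))
  invisible(x)
}

#' Sidak-adjusted significance level for a comparison family
#'
#' Planned non-orthogonal comparison families use a per-family adjusted
#' alpha: the Dunn-Sidak level `1 - (1 - alpha)^(1/m)` for `m`
#' comparisons.
#'
#' @param m family size.
#' @param alpha base significance level (default 0.05).
#' @return Adjusted per-comparison alpha.
#' @export
#' @examples
#' sidak_alpha(4)   # ~0.0127
sidak_alpha <- function(m, alpha = 0.05) {
  stopifnot(m >= 1)
  1 - (1 - alpha)^(1 / m)
}
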