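#' Tabulate behavioural-state transitions
#'
#' Counts each observed consecutive pair (state at occasion t, state at
#' occasion t+1) within an animal, optionally split by grouping factors.
#' Transitions are never counted across animals. A pair spanning a phase
#' boundary is assigned to the phase of its destination occasion by default
#' (so the transition into the first manipulated occasion belongs to the
#' manipulation phase); set `phase_policy = "origin"` for the alternative.
#'
#' @param table an observation table.
#' @param grouping character vector of grouping columns (any of
#'   `"treatment"`, `"plot"`, `"phase"`, `"occasion"`); empty for pooled
#'   counts.
#' @param phase_policy `"destination"` or `"origin"`.
#' @return For empty `grouping` a single 4x4 integer matrix of class
#'   `transition_counts` (rows = preceding state, columns = succeeding
#'   state); otherwise a named list of such matrices, one per observed
#'   group combination.
#' @export
#' @examples
#' tb <- data.frame(animal_id = "a1", occasion = paste0("t", 1:4),
#'                  state = c("E", "E", "S", "S"))
#' count_transitions(tb, grouping = character())
count_transitions <- function(table, grouping = c("treatment", "phase"),
                              phase_policy = c("destination", "origin")) {
  phase_policy <- match.arg(phase_policy)
  validate_observations(table)
  pairs <- transition_pairs(table, phase_policy)
  if (length(grouping) == 0)
    return(tabulate_pairs(pairs))
  missing_cols <- setdiff(grouping, names(pairs))
  if (length(missing_cols))
    stop("grouping column(s) not in table: ", paste(missing_cols, collapse = ", "))
  key <- interaction(pairs[grouping], drop = TRUE, sep = ".", lex.order = TRUE)
  out <- lapply(split(pairs, key), tabulate_pairs)
  out
}

# long data frame of within-animal consecutive state pairs with factor columns
transition_pairs <- function(table, phase_policy = "destination") {
  occ_levels <- occasion_levels(table)
  tb <- table[order(table$animal_id,
                    match(table$occasion, occ_levels)), , drop = FALSE]
  same <- tb$animal_id[-1] == tb$animal_id[-nrow(tb)]
  consec <- diff(match(tb$occasion, occ_levels)) == 1
  i <- which(same & consec)
  j <- i + 1
  out <- data.frame(state_from = tb$state[i], state_to = tb$state[j],
                    stringsAsFactors = FALSE)
  for (col in c("treatment", "plot", "species")) {
    if (col %in% names(tb)) out[[col]] <- tb[[col]][i]
  }
  if ("phase" %in% names(tb))
    out$phase <- if (phase_policy == "destination") tb$phase[j] else tb$phase[i]
  out$occasion <- tb$occasion[j]    # transition labelled by destination visit
  out
}

tabulate_pairs <- function(pairs) {
  m <- table(factor(pairs$state_from, MR_STATES),
             factor(pairs$state_to, MR_STATES))
  m <- matrix(as.integer(m), 4, 4, dimnames = list(MR_STATES, MR_STATES))
  class(m) <- c("transition_counts", class(m))
  m
}

# multinomial log-likelihood of the saturated (empirical-proportion) model
sat_loglik <- function(counts) {
  rs <- rowSums(counts)
  ll <- 0
  for (i in seq_len(nrow(counts))) {
    nz <- counts[i, ] > 0
    if (rs[i] > 0)
      ll <- ll + sum(counts[i, nz] * log(counts[i, nz] / rs[i]))
  }
  ll
}

#' Fit a zero- or first-order Markov chain by multinomial log-linear ML
#'
#' The behavioural-state sequence model: under a first-order chain the
#' probability of state `j` at occasion `t+1` given state `i` at `t` is the
#' multinomial logit `p_ij = exp(beta_ij) / sum_k exp(beta_ik)` with one
#' reference state per linear predictor fixed at `beta = 0`; a zero-order
#' chain drops the dependence on the preceding state. Factors (treatment,
#' plot, phase, occasion) enter either fully crossed (`interactions =
#' TRUE`, the default, in which case the maximum-likelihood fit is the
#' closed-form empirical proportion within each stratum) or as main
#' effects on the logit scale (`interactions = FALSE`, fitted numerically
#' by BFGS on the multinomial log-likelihood). Zero cells are handled
#' without pseudo-counts: the MLE of a structural zero is 0.
#'
#' @param x an observation table, a `transition_counts` matrix, or a data
#'   frame of transition pairs (`state_from`, `state_to`, factors).
#' @param order chain order, 0 or 1.
#' @param strata character vector of conditioning factors (subset of
#'   `"treatment"`, `"plot"`, `"phase"`, `"occasion"`).
#' @param interactions cross the strata fully (`TRUE`) or fit additive
#'   logit main effects (`FALSE`).
#' @param ref reference state for the logit parameterisation (default
#'   `"E"`).
#' @param phase_policy passed to the transition tabulation for observation
#'   tables.
#' @return Object of class `markov_fit` with elements `order`, `strata`,
#'   `counts`, `probs`, `beta`, `logLik`, `df`, `n`.
#' @export
#' @examples
#' cnt <- matrix(c(9, 3, 0, 0,  2, 6, 1, 1,  1, 1, 2, 0,  0, 1, 0, 1), 4, 4,
#'               byrow = TRUE, dimnames = list(behaviour_states(), behaviour_states()))
#' class(cnt) <- c("transition_counts", class(cnt))
#' fit <- fit_markov(cnt)
#' transition_probabilities(fit)
fit_markov <- function(x, order = 1, strata = character(),
                       interactions = TRUE, ref = "E",
                       phase_policy = "destination") {
  stopifnot(order %in% c(0, 1), ref %in% MR_STATES)
  if (inherits(x, "transition_counts") ||
      (is.matrix(x) && all(dim(x) == c(4, 4)))) {
    pairs <- counts_to_pairs(x)
  } else if (is.data.frame(x) && all(c("state_from", "state_to") %in% names(x))) {
    pairs <- x
  } else {
    pairs <- transition_pairs(x, phase_policy)
  }
  bad <- setdiff(unique(c(pairs$state_from, pairs$state_to)), MR_STATES)
  if (length(bad)) stop("unknown state symbol(s): ", paste(bad, collapse = ", "))
  missing_cols <- setdiff(strata, names(pairs))
  if (length(missing_cols))
    stop("strata column(s) not available: ", paste(missing_cols, collapse = ", "))

  if (interactions || (length(strata) == 0)) {
    fit <- fit_markov_stratified(pairs, order, strata, ref)
  } else {
    fit <- fit_markov_additive(pairs, order, strata, ref)
  }
  fit$n <- nrow(pairs)
  fit
}

counts_to_pairs <- function(counts) {
  idx <- which(counts > 0, arr.ind = TRUE)
  data.frame(
    state_from = rep(MR_STATES[idx[, 1]], counts[counts > 0]),
    state_to = rep(MR_STATES[idx[, 2]], counts[counts > 0]),
    stringsAsFactors = FALSE)
}

fit_markov_stratified <- function(pairs, order, strata, ref) {
  if (length(strata)) {
    key <- interaction(pairs[strata], drop = TRUE, sep = ".", lex.order = TRUE)
    groups <- split(pairs, key)
  } else {
    groups <- list(pooled = pairs)
  }
  counts <- lapply(groups, tabulate_pairs)
  probs <- list(); beta <- list()
  ll <- 0; df <- 0L
  for (g in names(counts)) {
    cnt <- counts[[g]]
    if (order == 0) {
      cs <- colSums(cnt)
      n <- sum(cs)
      p <- if (n > 0) cs / n else rep(NA_real_, 4)
      P <- matrix(p, 4, 4, byrow = TRUE, dimnames = dimnames(cnt))
      nz <- cs > 0
      ll <- ll + sum(cs[nz] * log(p[nz]))
      df <- df + if (n > 0) 3L else 0L
    } else {
      rs <- rowSums(cnt)
      P <- cnt / ifelse(rs > 0, rs, NA)
      ll <- ll + sat_loglik(cnt)
      df <- df + 3L * sum(rs > 0)
    }
    probs[[g]] <- unclass(P)
    beta[[g]] <- beta_from_probs(unclass(P), ref)
  }
  structure(list(order = order, strata = strata, interactions = TRUE,
                 ref = ref, counts = counts, probs = probs, beta = beta,
                 logLik = ll, df = df, converged = TRUE),
            class = "markov_fit")
}

# logit coefficients relative to the reference state; rows whose reference
# probability is 0 use the row's largest cell as fallback reference
beta_from_probs <- function(P, ref) {
  B <- matrix(NA_real_, nrow(P), ncol(P), dimnames = dimnames(P))
  for (i in seq_len(nrow(P))) {
    if (anyNA(P[i, ])) next
    r <- if (P[i, ref] > 0) ref else MR_STATES[which.max(P[i, ])]
    B[i, ] <- log(P[i, ]) - log(P[i, r])
  }
  B
}

fit_markov_additive <- function(pairs, order, strata, ref) {
  fac <- strata
  if (order == 1) fac <- c("state_from", fac)
  if (length(fac) == 0)
    stop("additive fit needs at least one factor")
  df_model <- pairs[fac]
  df_model[] <- lapply(df_model, factor)
  X <- model.matrix(~ ., df_model)
  y <- match(pairs$state_to, MR_STATES)
  out_states <- setdiff(MR_STATES, ref)
  K <- length(out_states)
  p <- ncol(X)
  nll <- function(bv) {
    B <- matrix(bv, p, K)
    eta <- cbind(0, X %*% B)    # ref column first
    m <- apply(eta, 1, max)
    lse <- m + log(rowSums(exp(eta - m)))
    yi <- match(MR_STATES[y], c(ref, out_states))
    -sum(eta[cbind(seq_along(yi), yi)] - lse)
  }
  grd <- function(bv) {
    B <- matrix(bv, p, K)
    eta <- cbind(0, X %*% B)
    m <- apply(eta, 1, max)
    pr <- exp(eta - m) / rowSums(exp(eta - m))
    yi <- match(MR_STATES[y], c(ref, out_states))
    G <- matrix(0, p, K)
    for (k in seq_len(K)) {
      G[, k] <- -crossprod(X, (yi == k + 1) - pr[, k + 1])
    }
    as.vector(G)
  }
  opt <- optim(rep(0, p * K), nll, grd, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  if (opt$convergence != 0)
    stop("fitting error: multinomial logit did not converge (code ",
         opt$convergence, ")")
  B <- matrix(opt$par, p, K,
              dimnames = list(colnames(X), out_states))
  structure(list(order = order, strata = strata, interactions = FALSE,
                 ref = ref, coefficients = B, design_levels = lapply(df_model, levels),
                 logLik = -opt$value, df = p * K, converged = TRUE),
            class = "markov_fit")
}

#' @export
print.markov_fit <- function(x, ...) {
  cat(sprintf("Markov chain fit (order %d%s)\n", x$order,
              if (length(x$strata)) paste0(", strata: ",
                                           paste(x$strata, collapse = " x "),
                                           if (x$interactions) " [crossed]"
                                           else " [additive]") else ""))
  cat(sprintf("  logLik = %.3f, model df = %d, n = %d transitions\n",
              x$logLik, x$df, x$n))
  invisible(x)
}

#' @export
logLik.markov_fit <- function(object, ...) {
  structure(object$logLik, df = object$df, class = "logLik")
}

#' Transition probabilities from a fitted chain
#'
#' Applies the inverse multinomial-logit map `p_ij = exp(beta_ij) /
#' sum_k exp(beta_ik)` row by row. Accepts either a [fit_markov()] result
#' (returning one row-stochastic matrix per stratum, or a single matrix
#' when unstratified) or a raw 4x4 coefficient matrix with the reference
#' state's column fixed at 0.
#'
#' @param fit a `markov_fit` or a numeric coefficient matrix.
#' @return A row-stochastic matrix, or a named list of them.
#' @export
#' @examples
#' B <- matrix(0, 4, 4, dimnames = list(behaviour_states(), behaviour_states()))
#' transition_probabilities(B)           # uniform rows
transition_probabilities <- function(fit) {
  if (is.matrix(fit)) return(softmax_rows(fit))
  stopifnot(inherits(fit, "markov_fit"))
  if (!isTRUE(fit$interactions))
    stop("additive fits: use the coefficient matrix for specific factor levels")
  out <- lapply(fit$beta, softmax_rows)
  # preserve empirical rows for strata where a fallback reference was used
  for (g in names(out)) {
    emp <- fit$probs[[g]]
    keep <- !is.na(emp[, 1])
    out[[g]][keep, ] <- emp[keep, ]
  }
  if (length(out) == 1) out[[1]] else out
}

softmax_rows <- function(B) {
  P <- matrix(NA_real_, nrow(B), ncol(B), dimnames = dimnames(B))
  for (i in seq_len(nrow(B))) {
    if (anyNA(B[i, ])) next
    e <- exp(B[i, ] - max(B[i, ], na.rm = TRUE))
    P[i, ] <- e / sum(e)
  }
  P
}

#' Likelihood-ratio test between nested Markov-chain fits
#'
#' `statistic = 2 (logLik_alt - logLik_null)` referred to the chi-square
#' distribution with the difference in model degrees of freedom. Used for
#' the chain-order test (zero vs first order), the time-homogeneity test
#' (with vs without occasion in the strata) and any other nested pair.
#'
#' @param null,alt `markov_fit` objects on the same transitions, `null`
#'   nested in `alt`.
#' @return Object of class `mr_chisq_test`.
#' @export
lrt <- function(null, alt) {
  stopifnot(inherits(null, "markov_fit"), inherits(alt, "markov_fit"))
  if (null$n != alt$n)
    stop("usage error: fits are not on the same data (n differs)")
  nested <- null$order <= alt$order &&
    all(null$strata %in% alt$strata) &&
    null$df <= alt$df
  if (!nested)
    stop("usage error: 'null' is not nested in 'alt'")
  stat <- max(0, 2 * (alt$logLik - null$logLik))
  df <- alt$df - null$df
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p.value = p,
                 null = describe_markov(null), alt = describe_markov(alt)),
            class = "mr_chisq_test")
}

describe_markov <- function(f) {
  sprintf("order-%d chain%s", f$order,
          if (length(f$strata)) paste0(" | ", paste(f$strata, collapse = " x "))
          else "")
}

#' Test for treatment differences between transition matrices
#'
#' Likelihood-ratio test of the model with a separate saturated transition
#' matrix per group against the pooled single-matrix model.
#'
#' @param counts_by_group named list (>= 2) of 4x4 `transition_counts`.
#' @return Object of class `mr_chisq_test`.
#' @export
compare_treatment_matrices <- function(counts_by_group) {
  stopifnot(is.list(counts_by_group), length(counts_by_group) >= 2)
  tot <- vapply(counts_by_group, sum, 0)
  if (any(tot == 0))
    stop("usage error: group(s) with no transitions: ",
         paste(names(counts_by_group)[tot == 0], collapse = ", "))
  pooled <- Reduce(`+`, counts_by_group)
  ll_groups <- sum(vapply(counts_by_group, sat_loglik, 0))
  ll_pooled <- sat_loglik(pooled)
  df_groups <- sum(vapply(counts_by_group,
                          function(m) 3L * sum(rowSums(m) > 0), 0L))
  df_pooled <- 3L * sum(rowSums(pooled) > 0)
  stat <- max(0, 2 * (ll_groups - ll_pooled))
  chisq_test(stat, df_groups - df_pooled,
             null = "one transition matrix for all groups",
             alt = sprintf("separate matrices (%d groups)",
                           length(counts_by_group)))
}

#' Two-sample proportion test on a single transition cell
#'
#' Compares the empirical transition probability `n_ij / n_i.` between two
#' groups with the standard two-sample proportion chi-square test
#' (continuity correction off by default). Results on row margins below
#' `low_count` are flagged. When the comparison belongs to a family over
#' several transitions, a Sidak-adjusted p-value is reported alongside the
#' raw one.
#'
#' @param i,j preceding and succeeding states.
#' @param counts_1,counts_2 4x4 `transition_counts` for the two groups.
#' @param correct continuity correction (default `FALSE`).
#' @param n_comparisons optional family size for the Sidak adjustment.
#' @param low_count margin below which the result is flagged (default 5).
#' @return List of class `mr_prop_test`: `statistic`, `p.value`,
#'   `p.sidak`, `estimate` (the two proportions), `margins`, `flagged`.
#' @export
compare_transition_cell <- function(i, j, counts_1, counts_2,
                                    correct = FALSE, n_comparisons = NULL,
                                    low_count = 5) {
  stopifnot(i %in% MR_STATES, j %in% MR_STATES)
  x <- c(counts_1[i, j], counts_2[i, j])
  n <- c(sum(counts_1[i, ]), sum(counts_2[i, ]))
  if (any(n == 0))
    stop("undefined: zero row margin for preceding state ", i)
  pt <- suppressWarnings(prop.test(x, n, correct = correct))
  p_sidak <- if (is.null(n_comparisons)) NA_real_ else
    1 - (1 - pt$p.value)^n_comparisons
  structure(list(transition = paste0(i, "->", j),
                 statistic = unname(pt$statistic),
                 p.value = pt$p.value, p.sidak = p_sidak,
                 estimate = unname(pt$estimate), margins = n,
                 flagged = any(n < low_count)),
            class = "mr_prop_test")
}

#' @export
print.mr_prop_test <- function(x, ...) {
  cat(sprintf("Proportion test on transition %s: %.3f vs %.3f (n = %d, %d)\n",
              x$transition, x$estimate[1], x$estimate[2],
              x$margins[1], x$margins[2]))
  cat(sprintf("  X2 = %.4g, p = %.4g%s%s\n", x$statistic, x$p.value,
              if (!is.na(x$p.sidak)) sprintf(", Sidak p = %.4g", x$p.sidak) else "",
              if (x$flagged) " [low count]" else ""))
  invisible(x)
}
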