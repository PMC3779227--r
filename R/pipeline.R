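#' Analysis configuration
#'
#' Collects every tunable of the pipeline in one validated object. The
#' input is either a built-in scenario name (`"exp2"`, the nine-week
#' before/during/after design; `"exp1"`, the four-occasion press design)
#' or a CSV observation table.
#'
#' @param scenario `"exp2"`, `"exp1"`, or `NULL` when `input` is given.
#' @param input path to an observation CSV (overrides `scenario`).
#' @param seed integer seed for the generator.
#' @param control,urchin_addition,abalone_addition treatment codes of the
#'   control and manipulation arms.
#' @param mobility_threshold sedentary/mobile cut in metres.
#' @param bounds truncation bounds `(a, b)` in metres.
#' @param corstr GEE working correlation structure.
#' @param alpha base significance level.
#' @param stages character subset of
#'   `c("transitions", "movement", "stepdist", "resight")`.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(scenario = "exp2", input = NULL, seed = 1L,
                            control = "0U25A",
                            urchin_addition = "18U25A",
                            abalone_addition = "0U50A",
                            mobility_threshold = 0.4,
                            bounds = c(0.1, 4),
                            corstr = "unstructured",
                            alpha = 0.05,
                            stages = c("transitions", "movement",
                                       "stepdist", "resight")) {
  if (is.null(input)) {
    if (!scenario %in% c("exp1", "exp2"))
      stop("scenario must be 'exp1' or 'exp2' (or give an input CSV)")
  } else if (!file.exists(input)) {
    stop("input file does not exist: ", input)
  }
  stopifnot(mobility_threshold >= 0, length(bounds) == 2,
            bounds[1] > 0, bounds[2] > bounds[1],
            alpha > 0, alpha < 1,
            all(stages %in% c("transitions", "movement", "stepdist",
                              "resight")))
  structure(list(scenario = scenario, input = input, seed = as.integer(seed),
                 control = control, urchin_addition = urchin_addition,
                 abalone_addition = abalone_addition,
                 mobility_threshold = mobility_threshold,
                 bounds = bounds, corstr = corstr, alpha = alpha,
                 stages = stages),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file with (a subset of) the [analysis_config()] fields.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  x <- yaml::read_yaml(path)
  defaults <- formals(analysis_config)
  args <- modifyList(lapply(defaults[setdiff(names(defaults), "...")], eval),
                     x[names(x) %in% names(defaults)])
  do.call(analysis_config, args)
}

#' Run the full competition-behaviour analysis
#'
#' Orchestrates generate/load, transition analysis (chain-order,
#' time-homogeneity and treatment LRTs plus per-cell proportion tests),
#' mobility analysis (GEE with robust Wald tests and per-occasion
#' Williams-corrected G-tests), step-length distribution fitting
#' (Pareto/exponential families, AIC/BIC selection, shape LRTs) and
#' resightability analysis (repeated-measures ANOVA with
#' Greenhouse-Geisser correction and Sidak-adjusted planned comparisons),
#' and derives the qualitative competition flags. Stage failures are
#' recorded without aborting independent stages. Deterministic given the
#' seed.
#'
#' @param config an [analysis_config()].
#' @return Object of class `analysis_report`.
#' @export
#' @examples
#' \donttest{
#' rep <- run_analysis(analysis_config(scenario = "exp2", seed = 1))
#' rep$flags
#' }
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  t0 <- Sys.time()
  log <- character()
  note <- function(msg) {
    log <<- c(log, sprintf("[%5.1fs] %s",
                           as.numeric(difftime(Sys.time(), t0, units = "secs")),
                           msg))
  }
  stages <- list()
  run_stage <- function(name, expr) {
    if (!name %in% c("data", "flags") && !name %in% config$stages) return(NULL)
    res <- tryCatch(expr, error = function(e)
      structure(list(message = conditionMessage(e)), class = "stage_error"))
    note(paste(name, if (inherits(res, "stage_error")) "FAILED" else "done"))
    res
  }

  data <- run_stage("data", {
    if (!is.null(config$input)) {
      read_observations(config$input)
    } else {
      sc <- if (config$scenario == "exp2") scenario_asymmetric_competition()
            else scenario_interspecific_competition()
      generate_experiment(sc$design, sc$params, seed = config$seed)
    }
  })
  if (inherits(data, "stage_error")) {
    note("dependent stages skipped")
    return(structure(list(config = config, data = NULL, stages = list(),
                          flags = NULL, error = data$message, log = log,
                          version = as.character(utils::packageVersion("markresight"))),
                     class = "analysis_report"))
  }
  ctrl <- config$control
  arms <- intersect(c(config$urchin_addition, config$abalone_addition),
                    unique(data$treatment))

  stages$transitions <- run_stage("transitions", {
    ctrl_pairs <- transition_pairs(data[data$treatment == ctrl, ])
    homo <- lrt(fit_markov(ctrl_pairs, order = 1),
                fit_markov(ctrl_pairs, order = 1, strata = "occasion"))
    order_test <- lrt(fit_markov(ctrl_pairs, order = 0),
                      fit_markov(ctrl_pairs, order = 1))
    plot_test <- lrt(fit_markov(ctrl_pairs, order = 1),
                     fit_markov(ctrl_pairs, order = 1, strata = "plot"))
    cnt <- count_transitions(data, grouping = c("treatment", "phase"))
    during <- cnt[grepl("\\.during$", names(cnt))]
    names(during) <- sub("\\.during$", "", names(during))
    ctrl_during <- during[[ctrl]]
    treat_test <- if (length(during) >= 2)
      compare_treatment_matrices(during) else NULL
    cells <- list()
    for (arm in arms) {
      for (ij in list(c("E", "E"), c("E", "S"), c("S", "S"), c("S", "E"))) {
        cells[[paste0(arm, ":", ij[1], "->", ij[2])]] <-
          compare_transition_cell(ij[1], ij[2], ctrl_during, during[[arm]],
                                  n_comparisons = 4)
      }
    }
    list(order_test = order_test, homogeneity_test = homo,
         plot_test = plot_test, treatment_test = treat_test,
         matrices = lapply(during, function(m) {
           rs <- rowSums(m); m / ifelse(rs > 0, rs, NA)
         }),
         counts = during, cell_tests = cells)
  })

  steps <- step_distances(data)
  steps$plot_rep <- sub(".*_p", "rep", steps$plot)
  labels <- classify_mobility(steps, config$mobility_threshold)

  stages$movement <- run_stage("movement", {
    gee <- fit_gee_binary(mobile ~ treatment + plot_rep, data = labels,
                          id = "animal_id", waves = "occasion_to",
                          corstr = config$corstr)
    props <- mobility_proportions(labels)
    during <- labels[labels$phase == "during", ]
    gtests <- list()
    for (arm in arms) {
      for (occ in unique(during$occasion_to)) {
        sub <- during[during$occasion_to == occ &
                        during$treatment %in% c(ctrl, arm), ]
        tab <- table(factor(sub$treatment, c(ctrl, arm)),
                     factor(sub$label, c("sedentary", "mobile")))
        g <- tryCatch(g_test_williams(matrix(tab, 2)),
                      error = function(e) NULL)
        if (!is.null(g)) gtests[[paste0(arm, ":", occ)]] <- g
      }
    }
    list(gee = gee, proportions = props, g_tests = gtests,
         threshold = config$mobility_threshold)
  })

  stages$stepdist <- run_stage("stepdist", {
    during <- steps[steps$phase == "during", ]
    fits <- list(); selections <- list(); lrts <- list()
    for (tr in unique(during$treatment)) {
      smp <- step_sample(during$distance_m[during$treatment == tr],
                         bounds = config$bounds)
      fits[[tr]] <- lapply(
        c("truncated_pareto", "truncated_exponential", "pareto",
          "exponential"),
        function(f) fit_step_model(smp, f))
      names(fits[[tr]]) <- vapply(fits[[tr]], `[[`, "", "family")
      selections[[tr]] <- select_model(fits[[tr]])
    }
    for (arm in intersect(arms, names(fits))) {
      pooled <- step_sample(
        during$distance_m[during$treatment %in% c(ctrl, arm)],
        bounds = config$bounds)
      lrts[[paste0(ctrl, " vs ", arm)]] <- lrt_shape(
        list(fits[[ctrl]]$truncated_pareto, fits[[arm]]$truncated_pareto),
        fit_step_model(pooled, "truncated_pareto"))
    }
    list(fits = fits, selection = selections, shape_lrt = lrts)
  })

  stages$resight <- run_stage("resight", {
    series <- percent_resighted(data)
    anova <- rm_anova_gg(series)
    pooled <- pool_periods(series)
    cmps <- list()
    for (arm in arms) {
      cmps[[length(cmps) + 1]] <- list(
        a = c(treatment = ctrl, period = "during"),
        b = c(treatment = arm, period = "during"))
      if ("before" %in% pooled$period)
        cmps[[length(cmps) + 1]] <- list(
          a = c(treatment = arm, period = "before"),
          b = c(treatment = arm, period = "during"))
    }
    comparisons <- if (length(cmps))
      planned_comparisons(pooled, cmps, alpha = config$alpha) else NULL
    list(series = series, anova = anova, pooled = pooled,
         comparisons = comparisons)
  })

  flags <- run_stage("flags", competition_flags(data, config))

  structure(list(config = config, data = data, stages = stages,
                 flags = flags, error = NULL, log = log,
                 version = as.character(utils::packageVersion("markresight"))),
            class = "analysis_report")
}

#' Qualitative competition flags
#'
#' Tests the directional signature of asymmetric competition on the
#' manipulation-phase data: under urchin addition the probability of
#' abalone remaining exposed drops and the exposed-to-sheltered transition
#' rises; the mobile fraction rises under either urchin or extra-abalone
#' addition; resightability declines under urchin addition but not under
#' extra abalone. Each flag is a one-sided two-sample proportion test at
#' `alpha` of the stated directional prediction against the control.
#'
#' @param data an observation table.
#' @param config an [analysis_config()].
#' @return Named logical vector of flags (with the underlying tests as
#'   attribute `"tests"`). Flags for absent treatment arms are `NA`.
#' @export
competition_flags <- function(data, config = analysis_config()) {
  ctrl <- config$control
  urch <- config$urchin_addition
  abal <- config$abalone_addition
  alpha <- config$alpha
  cnt <- count_transitions(data, grouping = c("treatment", "phase"))
  during_key <- function(tr) paste0(tr, ".during")
  have <- function(tr) during_key(tr) %in% names(cnt)

  dir_test <- function(x, n, want = c("greater", "less")) {
    want <- match.arg(want)
    pt <- suppressWarnings(prop.test(x, n, correct = FALSE,
                                     alternative = want))
    list(flag = pt$p.value < alpha,
         estimates = unname(pt$estimate), p = pt$p.value)
  }

  tests <- list()
  flag <- c(pEE_down_urchin = NA, pES_up_urchin = NA,
            mobile_up_urchin = NA, mobile_up_abalone = NA,
            resight_down_urchin = NA, resight_down_abalone = NA)

  if (have(ctrl) && have(urch)) {
    c0 <- cnt[[during_key(ctrl)]]; c1 <- cnt[[during_key(urch)]]
    t1 <- dir_test(c(c0["E", "E"], c1["E", "E"]),
                   c(sum(c0["E", ]), sum(c1["E", ])), "greater")
    t2 <- dir_test(c(c0["E", "S"], c1["E", "S"]),
                   c(sum(c0["E", ]), sum(c1["E", ])), "less")
    flag["pEE_down_urchin"] <- t1$flag   # control > urchin
    flag["pES_up_urchin"] <- t2$flag     # control < urchin
    tests$pEE <- t1; tests$pES <- t2
  }

  steps <- step_distances(data)
  labels <- classify_mobility(steps, config$mobility_threshold)
  during <- labels[labels$phase == "during", ]
  mob <- function(tr) {
    z <- during[during$treatment == tr, ]
    c(sum(z$mobile), nrow(z))
  }
  res_dur <- data[data$phase == "during", ]
  res <- function(tr) {
    z <- res_dur[res_dur$treatment == tr, ]
    c(sum(z$state %in% c("E", "S", "O")), nrow(z))
  }
  for (spec in list(c("mobile_up_urchin", urch), c("mobile_up_abalone", abal))) {
    tr <- spec[2]
    if (tr %in% during$treatment && ctrl %in% during$treatment) {
      m0 <- mob(ctrl); m1 <- mob(tr)
      t <- dir_test(c(m0[1], m1[1]), c(m0[2], m1[2]), "less")
      flag[spec[1]] <- t$flag
      tests[[spec[1]]] <- t
    }
  }
  for (spec in list(c("resight_down_urchin", urch),
                    c("resight_down_abalone", abal))) {
    tr <- spec[2]
    if (tr %in% res_dur$treatment && ctrl %in% res_dur$treatment) {
      r0 <- res(ctrl); r1 <- res(tr)
      t <- dir_test(c(r0[1], r1[1]), c(r0[2], r1[2]), "greater")
      flag[spec[1]] <- t$flag
      tests[[spec[1]]] <- t
    }
  }
  attr(flag, "tests") <- tests
  flag
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Competition-behaviour analysis report (markresight", x$version, ")\n")
  if (!is.null(x$error)) {
    cat("  FAILED:", x$error, "\n")
    return(invisible(x))
  }
  cat("  scenario:", if (is.null(x$config$input)) x$config$scenario
      else x$config$input, " seed:", x$config$seed, "\n")
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cat("  stage", s, ":",
        if (inherits(st, "stage_error")) paste("FAILED -", st$message)
        else "ok", "\n")
  }
  if (!is.null(x$flags)) {
    cat("  flags:\n")
    for (f in names(x$flags))
      cat(sprintf("    %-22s %s\n", f, x$flags[f]))
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits fixed-column CSV tables per stage plus a JSON sidecar of all test
#' results, the configuration echo and the package version.
#'
#' @param report an [run_analysis()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- report$stages
  if (!is.null(st$transitions) && !inherits(st$transitions, "stage_error")) {
    mats <- st$transitions$matrices
    tab <- do.call(rbind, lapply(names(mats), function(g) {
      m <- mats[[g]]
      data.frame(group = g, state_from = rownames(m)[row(m)],
                 state_to = colnames(m)[col(m)], p = as.vector(m))
    }))
    write.csv(tab, file.path(dir, "transition_matrices.csv"),
              row.names = FALSE)
  }
  if (!is.null(st$movement) && !inherits(st$movement, "stage_error")) {
    write.csv(st$movement$proportions,
              file.path(dir, "mobility_proportions.csv"), row.names = FALSE)
    write.csv(st$movement$gee$wald, file.path(dir, "gee_wald.csv"),
              row.names = FALSE)
  }
  if (!is.null(st$stepdist) && !inherits(st$stepdist, "stage_error")) {
    sel <- do.call(rbind, lapply(names(st$stepdist$selection), function(tr)
      cbind(treatment = tr, st$stepdist$selection[[tr]])))
    write.csv(sel, file.path(dir, "step_model_selection.csv"),
              row.names = FALSE)
  }
  if (!is.null(st$resight) && !inherits(st$resight, "stage_error")) {
    write.csv(st$resight$series, file.path(dir, "resight_series.csv"),
              row.names = FALSE)
    write.csv(st$resight$anova$table, file.path(dir, "resight_anova.csv"),
              row.names = FALSE)
    if (!is.null(st$resight$comparisons))
      write.csv(st$resight$comparisons,
                file.path(dir, "resight_comparisons.csv"), row.names = FALSE)
  }
  side <- list(version = report$version,
               config = unclass(report$config),
               flags = as.list(report$flags),
               log = report$log)
  tst <- function(x) if (is.null(x)) NULL else
    list(statistic = x$statistic, df = x$df, p = x$p.value)
  if (!inherits(st$transitions, "stage_error")) {
    side$transition_tests <- list(
      order = tst(st$transitions$order_test),
      homogeneity = tst(st$transitions$homogeneity_test),
      treatment = tst(st$transitions$treatment_test))
  }
  jsonlite::write_json(side, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}
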