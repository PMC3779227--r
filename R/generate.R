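#' Simulate a first-order behavioural-state chain
#'
#' @param P 4x4 row-stochastic transition matrix (rows/cols E, S, O, L).
#' @param n_steps number of transitions to simulate.
#' @param init initial state; default a draw from the stationary
#'   distribution of `P`.
#' @return Character vector of `n_steps + 1` states.
#' @export
#' @examples
#' P <- matrix(0.25, 4, 4, dimnames = list(behaviour_states(), behaviour_states()))
#' simulate_chain(P, 10)
simulate_chain <- function(P, n_steps, init = NULL) {
  P <- canonical_matrix(check_transition_matrix(P))
  if (is.null(init)) {
    pi0 <- stationary_distribution(P)
    init <- sample(MR_STATES, 1, prob = pi0)
  }
  s <- character(n_steps + 1)
  s[1] <- init
  # presample uniforms; invert the row CDFs
  cp <- t(apply(P, 1, cumsum))
  u <- runif(n_steps)
  for (t in seq_len(n_steps)) {
    row <- cp[s[t], ]
    s[t + 1] <- MR_STATES[which(u[t] <= row + 1e-15)[1]]
  }
  s
}

# uniform point in the plot square
runif_square <- function(side) runif(2, 0, side)

# uniform point in the 1 m annulus surrounding the square (rejection)
runif_annulus <- function(side) {
  repeat {
    p <- runif(2, -1, side + 1)
    if (p[1] < 0 || p[1] > side || p[2] < 0 || p[2] > side) return(p)
  }
}

in_square <- function(p, side) all(p >= 0) && all(p <= side)
in_annulus <- function(p, side) {
  all(p >= -1) && all(p <= side + 1) && !in_square(p, side)
}

# destination at exact distance d from `from`, landing in the target region;
# directions are rejection-sampled, and for the square the distance itself is
# re-drawn when no direction can reach the region (geometrically impossible d)
step_destination <- function(from, d, region = c("square", "annulus"),
                             side, alpha, bounds, max_dir = 100) {
  region <- match.arg(region)
  ok <- function(p) if (region == "square") in_square(p, side) else
    in_annulus(p, side)
  for (redraw in 1:25) {
    for (k in seq_len(max_dir)) {
      th <- runif(1, 0, 2 * pi)
      p <- from + d * c(cos(th), sin(th))
      if (ok(p)) return(list(p = p, d = d))
    }
    if (region == "annulus") return(NULL)
    d <- rtpareto(1, alpha, bounds[1], bounds[2])
  }
  NULL
}

#' Generate a synthetic mark-resight observation table
#'
#' Realises the data-generating process the analysis assumes: each tagged
#' animal follows the first-order behavioural chain of its
#' `(treatment, phase)` group (the transition into an occasion is governed
#' by that occasion's phase); in-plot displacements between consecutive
#' positioned occasions are drawn from the group's truncated Pareto;
#' sheltered/exposed animals stay inside the 3 x 3 m plot, outside-state
#' animals sit in the 1 m surrounding annulus when the drawn step reaches
#' it (otherwise their position is unrecorded); animals whose latent state
#' is lost, or that escape detection (one Bernoulli resighting trial per
#' visit with the group's per-state probability), are recorded as `L` and
#' carry no position. Recorded positions are expressed as field
#' measurements: distances to the two nearest star pickets plus the
#' handedness flag used by [triangulate_position()].
#'
#' @param design an [experiment_design()].
#' @param params a [generator_params()] covering every
#'   `(treatment, phase)` in the design.
#' @param species species label stored on the records (default
#'   `"abalone"`); may be a named vector keyed by treatment.
#' @param seed integer seed; overrides `params$seed` when given.
#' @param measure also express positions as picket-distance field
#'   measurements (columns `d1_m`, `d2_m`, `picket_a`, `picket_b`,
#'   `orientation`); disable to speed up large simulation studies that
#'   only need coordinates.
#' @return Data frame of class `observation_table`, one row per animal per
#'   occasion, with attributes `occasion_levels`, `design`, `params`, and
#'   `steps` (the drawn step lengths, for generator cross-checks).
#' @export
#' @examples
#' sc <- scenario_asymmetric_competition(animals_per_plot = 5)
#' tb <- generate_experiment(sc$design, sc$params, seed = 1)
#' head(tb)
generate_experiment <- function(design, params, species = "abalone",
                                seed = NULL, measure = TRUE) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(params, "generator_params"))
  needed <- unique(tp_key(rep(design$treatments, each = length(design$occasions)),
                          rep(design$phases, times = length(design$treatments))))
  missing_keys <- setdiff(needed, names(params$transition_matrix))
  if (length(missing_keys))
    stop("configuration error: no parameters for group(s) ",
         paste(missing_keys, collapse = ", "))
  missing_keys <- setdiff(needed, names(params$step_shape))
  if (length(missing_keys))
    stop("configuration error: no step shape for group(s) ",
         paste(missing_keys, collapse = ", "))
  if (!is.null(seed)) set.seed(as.integer(seed))
  else if (!is.null(params$seed)) set.seed(params$seed)

  side <- 3
  frame <- plot_frame(side)
  a <- params$step_bounds["a"]; b <- params$step_bounds["b"]
  occ <- design$occasions
  n_occ <- length(occ)
  if (length(species) == 1 && is.null(names(species)))
    species <- setNames(rep(species, length(design$treatments)),
                        design$treatments)

  rows <- vector("list", 0L)
  steps <- vector("list", 0L)
  for (tr in design$treatments) {
    for (pl in seq_len(design$plots_per_treatment)) {
      plot_id <- sprintf("%s_p%d", tr, pl)
      for (an in seq_len(design$animals_per_plot)) {
        id <- sprintf("%s_a%02d", plot_id, an)
        key1 <- tp_key(tr, design$phases[[occ[1]]])
        P1 <- params$transition_matrix[[key1]]
        latent <- character(n_occ)
        latent[1] <- sample(MR_STATES, 1,
                            prob = stationary_distribution(P1))
        pos <- matrix(NA_real_, n_occ, 2)
        if (latent[1] %in% c("E", "S")) pos[1, ] <- runif_square(side)
        if (latent[1] == "O") pos[1, ] <- runif_annulus(side)
        for (t in 2:n_occ) {
          key <- tp_key(tr, design$phases[[occ[t]]])
          P <- params$transition_matrix[[key]]
          latent[t] <- sample(MR_STATES, 1, prob = P[latent[t - 1], ])
          if (latent[t] == "L") next
          region <- if (latent[t] == "O") "annulus" else "square"
          if (is.na(pos[t - 1, 1])) {
            pos[t, ] <- if (region == "square") runif_square(side)
                        else runif_annulus(side)
          } else {
            d <- rtpareto(1, params$step_shape[[key]], a, b)
            dest <- step_destination(pos[t - 1, ], d, region, side,
                                     params$step_shape[[key]], c(a, b))
            if (!is.null(dest)) {
              pos[t, ] <- dest$p
              steps[[length(steps) + 1L]] <- data.frame(
                animal_id = id, occasion_to = occ[t],
                drawn_m = dest$d, stringsAsFactors = FALSE)
            } # else: O-state step could not reach the annulus; no position
          }
        }
        # observation process: one resighting trial per visit
        recorded <- latent
        for (t in seq_len(n_occ)) {
          if (latent[t] == "L") next
          key <- tp_key(tr, design$phases[[occ[t]]])
          p_det <- params$resight_prob[[key]][[latent[t]]]
          if (runif(1) > p_det) recorded[t] <- "L"
        }
        x <- pos[, 1]; y <- pos[, 2]
        x[recorded == "L"] <- NA; y[recorded == "L"] <- NA
        pa <- pb <- ori <- rep(NA_character_, n_occ)
        d1 <- d2 <- rep(NA_real_, n_occ)
        if (measure) for (t in which(!is.na(x))) {
          np <- nearest_pickets(frame, c(x[t], y[t]))
          pa[t] <- np[1]; pb[t] <- np[2]
          d1[t] <- sqrt(sum((frame$pickets[np[1], ] - c(x[t], y[t]))^2))
          d2[t] <- sqrt(sum((frame$pickets[np[2], ] - c(x[t], y[t]))^2))
          ori[t] <- picket_orientation(frame, np[1], np[2], c(x[t], y[t]))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = id, species = unname(species[tr]), plot = plot_id,
          treatment = tr, phase = unname(design$phases[occ]),
          occasion = occ, state = recorded,
          x_m = x, y_m = y, d1_m = d1, d2_m = d2,
          picket_a = pa, picket_b = pb, orientation = ori,
          stringsAsFactors = FALSE)
      }
    }
  }
  tb <- do.call(rbind, rows)
  rownames(tb) <- NULL
  attr(tb, "occasion_levels") <- occ
  attr(tb, "design") <- design
  attr(tb, "params") <- params
  attr(tb, "steps") <- if (length(steps)) do.call(rbind, steps) else NULL
  class(tb) <- c("observation_table", "data.frame")
  tb
}

#' Write / read observation tables as CSV
#'
#' The CSV dialect has the fixed column order `animal_id`, `species`,
#' `plot`, `treatment`, `phase`, `occasion`, `state`, `x_m`, `y_m`,
#' `d1_m`, `d2_m`, `picket_a`, `picket_b`, `orientation`. Occasion order is
#' stored in a header comment and restored on read.
#'
#' @param table an observation table.
#' @param path file path.
#' @return `write_observations` returns `path` invisibly;
#'   `read_observations` returns an `observation_table`.
#' @export
write_observations <- function(table, path) {
  occ <- occasion_levels(table)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# occasions: ", paste(occ, collapse = ",")), con)
  write.csv(as.data.frame(table), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  first <- readLines(path, n = 1)
  occ <- NULL
  skip <- 0
  if (startsWith(first, "# occasions:")) {
    occ <- strsplit(sub("# occasions: *", "", first), ",")[[1]]
    skip <- 1
  }
  tb <- read.csv(path, skip = skip, stringsAsFactors = FALSE)
  validate_observations(tb)
  attr(tb, "occasion_levels") <- if (is.null(occ)) unique(tb$occasion) else occ
  class(tb) <- c("observation_table", "data.frame")
  tb
}

validate_observations <- function(tb) {
  req <- c("animal_id", "occasion", "state")
  if (!all(req %in% names(tb)))
    stop("observation table needs columns ", paste(req, collapse = ", "))
  bad <- setdiff(unique(tb$state), MR_STATES)
  if (length(bad))
    stop("unknown behavioural state(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(tb[c("animal_id", "occasion")]))
    stop("(animal, occasion) pairs must be unique")
  invisible(tb)
}

#' Write / read generator parameters as YAML
#'
#' @param params a [generator_params()].
#' @param path file path.
#' @export
write_generator_params <- function(params, path) {
  x <- list(
    step_bounds = as.list(params$step_bounds),
    seed = params$seed,
    step_shape = as.list(params$step_shape),
    resight_prob = lapply(params$resight_prob, as.list),
    transition_matrix = lapply(params$transition_matrix, function(P)
      lapply(seq_len(nrow(P)), function(i) as.list(P[i, ]))))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_generator_params
#' @export
read_generator_params <- function(path) {
  x <- yaml::read_yaml(path)
  Pm <- lapply(x$transition_matrix, function(rows) {
    P <- do.call(rbind, lapply(rows, function(r) unlist(r[MR_STATES])))
    dimnames(P) <- list(MR_STATES, MR_STATES)
    P
  })
  generator_params(
    transition_matrix = Pm,
    step_shape = unlist(x$step_shape),
    resight_prob = lapply(x$resight_prob, unlist),
    step_bounds = c(x$step_bounds$a, x$step_bounds$b),
    seed = x$seed)
}
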