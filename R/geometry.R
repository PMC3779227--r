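#' Star-picket reference frame of an experimental plot
#'
#' Plots are 3 x 3 m squares marked with five star pickets: one in each
#' corner and one in the centre. Coordinates are plot-local, origin at the
#' south-west corner picket, axes along the plot edges, units metres.
#'
#' @param side plot side length in metres (default 3).
#' @return An object of class `plot_frame`: a named list of picket
#'   coordinates `SW`, `SE`, `NE`, `NW`, `C`.
#' @export
#' @examples
#' plot_frame()
plot_frame <- function(side = 3) {
  stopifnot(side > 0)
  structure(
    list(pickets = rbind(
           SW = c(0, 0), SE = c(side, 0), NE = c(side, side),
           NW = c(0, side), C = c(side / 2, side / 2)),
         side = side),
    class = "plot_frame")
}

#' @export
print.plot_frame <- function(x, ...) {
  cat("Plot frame:", x$side, "x", x$side, "m; pickets:\n")
  print(x$pickets)
  invisible(x)
}

#' Reconstruct a position from two picket distances
#'
#' Field positions are recorded as the distances to the two nearest star
#' pickets plus a handedness flag resolving the two-fold ambiguity of the
#' circle intersection. The flag encodes which side of the directed picket
#' baseline (from `picket_a` to `picket_b`) the animal lies on: `"L"` for
#' the left half-plane (positive cross product), `"R"` for the right. This
#' is the computable form of the divers' rule of noting which picket was on
#' the right-hand side when facing the plot.
#'
#' @param frame a [plot_frame()].
#' @param picket_a,picket_b picket labels (e.g. `"SW"`, `"C"`).
#' @param d_a,d_b measured distances in metres (> 0).
#' @param orientation `"L"` or `"R"`, see Details.
#' @param tol near-tangency tolerance in metres (default 0.005, half the
#'   order of the reported field measurement error); circle gaps within
#'   `tol` are snapped to tangency with a warning.
#' @return Numeric length-2 vector `(x, y)` in metres.
#' @export
#' @examples
#' fr <- plot_frame()
#' triangulate_position(fr, "SW", "SE", 2.5, 2.5, "L")  # c(1.5, 2.0)
triangulate_position <- function(frame, picket_a, picket_b, d_a, d_b,
                                 orientation = c("L", "R"), tol = 0.005) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(frame, "plot_frame"),
            picket_a %in% rownames(frame$pickets),
            picket_b %in% rownames(frame$pickets),
            picket_a != picket_b)
  if (d_a <= 0 || d_b <= 0) stop("picket distances must be positive")
  A <- frame$pickets[picket_a, ]
  B <- frame$pickets[picket_b, ]
  base <- sqrt(sum((B - A)^2))
  if (base > d_a + d_b + tol || base < abs(d_a - d_b) - tol)
    stop("measurement error: circles of radii ", signif(d_a, 4), " and ",
         signif(d_b, 4), " about pickets ", picket_a, ", ", picket_b,
         " (baseline ", signif(base, 4), " m) do not intersect")
  l <- (d_a^2 - d_b^2 + base^2) / (2 * base)
  h2 <- d_a^2 - l^2
  if (h2 < 0) {
    warning("near-tangent circles; returning the touching point")
    h <- 0
  } else h <- sqrt(h2)
  u <- (B - A) / base               # unit vector along baseline
  n <- c(-u[2], u[1])               # left normal of A -> B
  s <- if (orientation == "L") 1 else -1
  p <- A + l * u + s * h * n
  unname(p)
}

#' Side of the picket baseline a point lies on
#'
#' Returns the handedness flag that [triangulate_position()] needs to
#' reconstruct `p` from distances to `picket_a` and `picket_b`.
#'
#' @inheritParams triangulate_position
#' @param p numeric length-2 position.
#' @return `"L"` or `"R"` (ties within 1e-9 broken toward the plot interior).
#' @export
picket_orientation <- function(frame, picket_a, picket_b, p) {
  A <- frame$pickets[picket_a, ]
  B <- frame$pickets[picket_b, ]
  cr <- (B[1] - A[1]) * (p[2] - A[2]) - (B[2] - A[2]) * (p[1] - A[1])
  if (abs(cr) <= 1e-9) {
    # degenerate: point on the baseline; break toward the plot centre
    ctr <- c(frame$side / 2, frame$side / 2)
    cr <- (B[1] - A[1]) * (ctr[2] - A[2]) - (B[2] - A[2]) * (ctr[1] - A[1])
  }
  if (cr >= 0) "L" else "R"
}

# two nearest pickets to p, in increasing distance order
nearest_pickets <- function(frame, p) {
  d <- sqrt(rowSums((frame$pickets - matrix(p, nrow(frame$pickets), 2,
                                            byrow = TRUE))^2))
  names(sort(d))[1:2]
}

#' Per-interval movement distances
#'
#' Computes the Euclidean distance between an animal's positions on
#' consecutive survey occasions. Intervals where either endpoint lacks a
#' position (lost animals, or outside-plot records without coordinates) are
#' skipped; the number of skipped intervals is attached as attribute
#' `"skipped"`.
#'
#' @param table an observation table (see [generate_experiment()] /
#'   [read_observations()]) with columns `animal_id`, `occasion`, `x_m`,
#'   `y_m` and the grouping columns `species`, `plot`, `treatment`, `phase`.
#' @param phase_policy which occasion's phase labels a step spanning a
#'   phase boundary: the `"destination"` (default) or `"origin"` occasion.
#' @return Data frame of class `step_records`: one row per usable interval
#'   with `animal_id`, `occasion_from`, `occasion_to`, grouping columns and
#'   `distance_m`.
#' @export
step_distances <- function(table, phase_policy = c("destination", "origin")) {
  phase_policy <- match.arg(phase_policy)
  occ_levels <- occasion_levels(table)
  tb <- table[order(table$animal_id,
                    match(table$occasion, occ_levels)), , drop = FALSE]
  same <- tb$animal_id[-1] == tb$animal_id[-nrow(tb)]
  consec <- diff(match(tb$occasion, occ_levels)) == 1
  i <- which(same & consec)           # index of interval origin rows
  j <- i + 1
  ok <- !is.na(tb$x_m[i]) & !is.na(tb$x_m[j]) &
        !is.na(tb$y_m[i]) & !is.na(tb$y_m[j])
  skipped <- sum(!ok)
  i <- i[ok]; j <- j[ok]
  ph <- if (phase_policy == "destination") tb$phase[j] else tb$phase[i]
  out <- data.frame(
    animal_id = tb$animal_id[i],
    species = tb$species[i],
    plot = tb$plot[i],
    treatment = tb$treatment[i],
    phase = ph,
    occasion_from = tb$occasion[i],
    occasion_to = tb$occasion[j],
    distance_m = sqrt((tb$x_m[j] - tb$x_m[i])^2 + (tb$y_m[j] - tb$y_m[i])^2),
    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  class(out) <- c("step_records", "data.frame")
  out
}

# occasion ordering: factor levels if available, else first appearance
occasion_levels <- function(table) {
  lv <- attr(table, "occasion_levels")
  if (!is.null(lv)) return(lv)
  if (is.factor(table$occasion)) return(levels(table$occasion))
  unique(table$occasion)
}

#' Repeatability of a triangulated baseline measurement
#'
#' Calibration utility mirroring the field protocol of measuring the
#' distances between picket pairs several times: returns the mean and
#' standard error of repeated measurements of a fixed distance.
#'
#' @param measurements numeric vector of repeated distance measurements (m).
#' @return List with `mean`, `se`, `n`.
#' @export
baseline_repeatability <- function(measurements) {
  stopifnot(is.numeric(measurements), length(measurements) >= 2)
  list(mean = mean(measurements),
       se = sd(measurements) / sqrt(length(measurements)),
       n = length(measurements))
}
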