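#' Escape-energy decay schedules
#'
#' The escape energy of the prey, E = (2 r - 1) E1(t), governs the switch
#' between exploration (|E| >= 1) and exploitation (|E| < 1) in Harris hawks
#' optimization. Baseline HHO decays the envelope E1 linearly from 2 to 0
#' over the run, which confines the optimizer to pure exploitation for the
#' whole second half of the iteration budget (E1 < 1 for t > T/2). The
#' nonlinear schedule used by NOL-HHO,
#'
#'   E1(t) = b_fin - (b_fin - b_ini) * (1 - exp((t/T)^5)) / (1 - e),
#'
#' keeps E1 near 2 for most of the run and collapses it rapidly near the end:
#' exploration stays possible late (E1 crosses 1 at about t = 0.91 T), and
#' the final iterations exploit aggressively.
#'
#' Both schedules satisfy E1(0) = 2, E1(T) = 0, and are strictly decreasing;
#' the nonlinear one dominates the linear one pointwise on (0, T).
#'
#' @param t Current iteration, 0 <= t <= T (vectorized).
#' @param T Total number of iterations.
#' @param b_ini,b_fin Initial and final values of the control parameter
#'   envelope at the two ends of the decay (defaults 0 and 2).
#' @return The envelope value E1(t) in `[0, 2]`.
#' @export
nonlinear_energy_factor <- function(t, T, b_ini = 0, b_fin = 2) {
  if (any(t < 0 | t > T)) stop("t must lie in [0, T]")
  b_fin - (b_fin - b_ini) * (1 - exp((t / T)^5)) / (1 - exp(1))
}

#' @rdname nonlinear_energy_factor
#' @export
linear_energy_factor <- function(t, T) {
  if (any(t < 0 | t > T)) stop("t must lie in [0, T]")
  2 * (1 - t / T)
}

#' Opposition-based learning transforms
#'
#' `opposite_point()` mirrors a point through the center of its box:
#' x* = a + b - x per dimension (an involution). `rol_transform()` is the
#' randomized variant used by NOL-HHO: x* = a + b - r * x with an
#' independent uniform(0,1) factor r per dimension, which spreads the
#' mirrored candidates over a region rather than a single reflection and
#' helps the population escape local optima. Mirrored coordinates that leave
#' the box are clamped to the nearest bound.
#'
#' @param x Numeric vector (a position), or a matrix with one position per
#'   row.
#' @param lower,upper Box bounds, recycled per dimension.
#' @param per_dimension If `TRUE` (default) the random factor is drawn
#'   independently for every coordinate; if `FALSE` a single scalar factor
#'   is drawn per position.
#' @return A vector or matrix of the same shape as `x`, inside the box.
#' @export
opposite_point <- function(x, lower, upper) {
  if (is.matrix(x)) {
    n <- nrow(x)
    matrix(lower, n, ncol(x), byrow = TRUE) +
      matrix(upper, n, ncol(x), byrow = TRUE) - x
  } else {
    lower + upper - x
  }
}

#' @rdname opposite_point
#' @export
rol_transform <- function(x, lower, upper, per_dimension = TRUE) {
  if (is.matrix(x)) {
    n <- nrow(x); d <- ncol(x)
    r <- if (per_dimension) matrix(stats::runif(n * d), n, d)
         else matrix(stats::runif(n), n, d)
    lo <- matrix(lower, n, d, byrow = TRUE)
    up <- matrix(upper, n, d, byrow = TRUE)
    pmin(pmax(lo + up - r * x, lo), up)
  } else {
    d <- length(x)
    r <- if (per_dimension) stats::runif(d) else stats::runif(1)
    pmin(pmax(lower + upper - r * x, lower), upper)
  }
}

#' Elitist survivor selection over a population and its mirrored copy
#'
#' Given the current population and the candidate positions produced by
#' random opposition-based learning, keeps the N fittest individuals of the
#' 2N-member union (minimization). The resulting population's mean fitness
#' never exceeds the original's, and the best-so-far individual is always
#' retained.
#'
#' @param positions N x dim matrix of current positions.
#' @param fitnesses Length-N vector of their objective values.
#' @param mirrored N x dim matrix of mirrored candidate positions.
#' @param mirrored_fitnesses Length-N vector of their objective values.
#' @return A list with `positions` (N x dim) and `fitnesses` (length N) of
#'   the selected survivors.
#' @export
select_survivors <- function(positions, fitnesses, mirrored,
                             mirrored_fitnesses) {
  stopifnot(nrow(positions) == nrow(mirrored),
            length(fitnesses) == nrow(positions),
            length(mirrored_fitnesses) == nrow(mirrored))
  n <- nrow(positions)
  all_pos <- rbind(positions, mirrored)
  all_fit <- c(fitnesses, mirrored_fitnesses)
  keep <- order(all_fit)[seq_len(n)]
  list(positions = all_pos[keep, , drop = FALSE], fitnesses = all_fit[keep])
}
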