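#' Configuration for a Harris hawks optimization run
#'
#' Defaults follow the standard evaluation protocol for this family of
#' optimizers: 30 search agents and 500 iterations. `schedule = "linear"`
#' with `rol = FALSE` gives baseline HHO; `schedule = "nonlinear"` with
#' `rol = TRUE` gives NOL-HHO (see [nonlinear_energy_factor()] and
#' [rol_transform()]).
#'
#' @param n_hawks Population size (default 30).
#' @param n_iterations Iteration budget T (default 500).
#' @param levy_beta Levy-flight stability index for the rapid-dive steps,
#'   in (1, 2] (default 1.5).
#' @param schedule Escape-energy envelope: `"linear"` or `"nonlinear"`.
#' @param rol Apply the random opposition-based learning step with elitist
#'   survivor selection once per iteration.
#' @param rol_per_dimension Draw the ROL random factor per dimension
#'   (default) rather than per individual.
#' @param b_ini,b_fin Envelope endpoints for the nonlinear schedule.
#' @param seed Optional integer seed; when given, the run seeds the random
#'   stream and is fully reproducible.
#' @param target_fitness Optional early-stop threshold: the run returns as
#'   soon as the best objective value is `<=` this target. Used by the code
#'   builder, where admissibility of a decoded word is equivalent to
#'   objective value 0.
#' @return A list of class `hho_config`.
#' @export
hho_config <- function(n_hawks = 30, n_iterations = 500, levy_beta = 1.5,
                       schedule = c("linear", "nonlinear"), rol = FALSE,
                       rol_per_dimension = TRUE, b_ini = 0, b_fin = 2,
                       seed = NULL, target_fitness = NULL) {
  schedule <- match.arg(schedule)
  stopifnot(n_hawks >= 1, n_iterations >= 1,
            levy_beta > 1, levy_beta <= 2)
  structure(list(n_hawks = as.integer(n_hawks),
                 n_iterations = as.integer(n_iterations),
                 levy_beta = levy_beta, schedule = schedule, rol = rol,
                 rol_per_dimension = rol_per_dimension,
                 b_ini = b_ini, b_fin = b_fin, seed = seed,
                 target_fitness = target_fitness),
            class = "hho_config")
}

#' Draw the per-hawk escape energy
#'
#' E = (2 r - 1) E1(t) with r uniform on (0, 1), drawn fresh for every hawk
#' at every iteration. |E| >= 1 routes the hawk to exploration, |E| < 1 to
#' exploitation; |E| is bounded by the envelope E1(t) <= 2.
#'
#' @param t Current iteration (0-based), 0 <= t < T.
#' @param T Iteration budget.
#' @param schedule `"linear"` or `"nonlinear"`.
#' @param b_ini,b_fin Envelope endpoints (nonlinear schedule only).
#' @return A scalar escape energy in `[-E1(t), E1(t)]`.
#' @export
escape_energy <- function(t, T, schedule = "linear", b_ini = 0, b_fin = 2) {
  e1 <- if (schedule == "nonlinear") {
    nonlinear_energy_factor(t, T, b_ini, b_fin)
  } else {
    linear_energy_factor(t, T)
  }
  (2 * stats::runif(1) - 1) * e1
}

#' Mantegna Levy-flight step
#'
#' Heavy-tailed random step used in the rapid-dive moves:
#' 0.01 * u * sigma / |v|^(1/beta) per dimension, with u, v standard normal
#' and sigma the Mantegna scale constant for the given stability index.
#'
#' @param dim Number of dimensions.
#' @param beta Stability index in (1, 2].
#' @return A numeric vector of `dim` steps.
#' @export
levy_step <- function(dim, beta = 1.5) {
  sigma <- (gamma(1 + beta) * sin(pi * beta / 2) /
              (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- stats::rnorm(dim) * sigma
  v <- stats::rnorm(dim)
  0.01 * u / abs(v)^(1 / beta)
}

.clamp <- function(x, lower, upper) pmin(pmax(x, lower), upper)

#' Initialize a hawk population
#'
#' Positions are i.i.d. uniform in the box; the best individual becomes the
#' initial rabbit (prey) position.
#'
#' @param lower,upper Per-dimension box bounds.
#' @param n_hawks Population size.
#' @param fn Objective function (minimized).
#' @param init_positions Optional matrix of candidate starting positions.
#' @return A list with `positions`, `fitnesses`, `rabbit_position`,
#'   `rabbit_fitness`.
#' @export
initialize_population <- function(lower, upper, n_hawks, fn,
                                  init_positions = NULL) {
  d <- length(lower)
  if (is.null(init_positions)) {
    X <- matrix(stats::runif(n_hawks * d), n_hawks, d)
    X <- matrix(lower, n_hawks, d, byrow = TRUE) +
      X * matrix(upper - lower, n_hawks, d, byrow = TRUE)
  } else {
    stopifnot(ncol(init_positions) == d)
    rows <- if (nrow(init_positions) >= n_hawks) {
      sample.int(nrow(init_positions), n_hawks)
    } else {
      sample.int(nrow(init_positions), n_hawks, replace = TRUE)
    }
    X <- init_positions[rows, , drop = FALSE]
  }
  mat_fn <- attr(fn, "matrix_fn")
  fit <- if (is.null(mat_fn)) {
    vapply(seq_len(n_hawks), function(i) fn(X[i, ]), 0)
  } else {
    mat_fn(X)
  }
  b <- which.min(fit)
  list(positions = X, fitnesses = fit,
       rabbit_position = X[b, ], rabbit_fitness = fit[b])
}

#' Exploration move (perch selection)
#'
#' With probability 1/2 the hawk perches relative to a random flock member:
#' X_rand - r1 |X_rand - 2 r2 X|; otherwise relative to the rabbit and the
#' flock average: (X_rabbit - X_mean) - r3 (lower + r4 (upper - lower)).
#' The result is clamped to the box.
#'
#' @param x Current position of the hawk.
#' @param positions N x dim matrix of all hawk positions.
#' @param rabbit Current rabbit (best) position.
#' @param mean_position Column means of `positions`.
#' @param lower,upper Box bounds.
#' @return The new (clamped) position.
#' @export
exploration_move <- function(x, positions, rabbit, mean_position,
                             lower, upper) {
  if (stats::runif(1) >= 0.5) {
    xr <- positions[sample.int(nrow(positions), 1), ]
    xnew <- xr - stats::runif(1) * abs(xr - 2 * stats::runif(1) * x)
  } else {
    xnew <- (rabbit - mean_position) -
      stats::runif(1) * (lower + stats::runif(1) * (upper - lower))
  }
  .clamp(xnew, lower, upper)
}

#' Exploitation move (besiege strategies)
#'
#' Implements the four standard attack branches, chosen by the escape
#' chance r ~ U(0,1) crossed with the escape-energy magnitude:
#' soft besiege (r >= 0.5, |E| >= 0.5), hard besiege (r >= 0.5, |E| < 0.5),
#' and their progressive-rapid-dive counterparts (r < 0.5) in which a dive
#' candidate Y (and, if Y fails, a Levy-flight candidate Z) replaces the
#' hawk only when strictly better -- the incumbent is never degraded in the
#' dive branches.
#'
#' @param x Current position.
#' @param fx Current objective value of `x`.
#' @param rabbit,mean_position Rabbit position and population mean.
#' @param E Escape energy, |E| < 1.
#' @param lower,upper Box bounds.
#' @param fn Objective function.
#' @param levy_beta Levy stability index for the dive steps.
#' @return A list with the new `position`, its `fitness`, and `n_evals`, the
#'   number of objective evaluations spent.
#' @export
exploitation_move <- function(x, fx, rabbit, mean_position, E, lower, upper,
                              fn, levy_beta = 1.5) {
  d <- length(x)
  r <- stats::runif(1)
  if (r >= 0.5) {
    if (abs(E) >= 0.5) {     # soft besiege
      J <- 2 * (1 - stats::runif(1))
      xnew <- (rabbit - x) - E * abs(J * rabbit - x)
    } else {                 # hard besiege
      xnew <- rabbit - E * abs(rabbit - x)
    }
    xnew <- .clamp(xnew, lower, upper)
    return(list(position = xnew, fitness = fn(xnew), n_evals = 1L))
  }
  # progressive rapid dives; soft uses the hawk itself, hard the flock mean
  base <- if (abs(E) >= 0.5) x else mean_position
  J <- 2 * (1 - stats::runif(1))
  Y <- .clamp(rabbit - E * abs(J * rabbit - base), lower, upper)
  fY <- fn(Y)
  if (fY < fx) return(list(position = Y, fitness = fY, n_evals = 1L))
  Z <- .clamp(Y + stats::runif(d) * levy_step(d, levy_beta), lower, upper)
  fZ <- fn(Z)
  if (fZ < fx) return(list(position = Z, fitness = fZ, n_evals = 2L))
  list(position = x, fitness = fx, n_evals = 2L)
}

#' Run Harris hawks optimization
#'
#' Minimizes an objective over a box. Each iteration computes the energy
#' envelope E1(t), draws a fresh escape energy per hawk and routes it to an
#' exploration or exploitation move; with `rol = TRUE` in the
#' configuration, every iteration additionally mirrors the whole population
#' through [rol_transform()] and keeps the N best of the 2N originals and
#' mirrors ([select_survivors()]). The best-so-far (rabbit) fitness trace is
#' non-increasing.
#'
#' @param objective An `hho_objective` from [benchmark_function()] (bounds
#'   are taken from it) or a plain function of a numeric vector.
#' @param lower,upper Box bounds (required when `objective` is a bare
#'   function; may be scalars, recycled to `dim`).
#' @param dim Dimension (only needed when bounds are given as scalars).
#' @param config An [hho_config()].
#' @param init_positions Optional matrix of initial hawk positions (one row
#'   per hawk, recycled or subsampled to the population size); by default
#'   the population is initialized uniformly in the box.
#' @return An object of class `hho_result`: a list with `best_fitness`,
#'   `best_position`, `trace` (best fitness after each iteration),
#'   `n_evals`, `iterations_run`, `config`, and `seed`.
#' @examples
#' sphere <- benchmark_function(1, dim = 2)
#' res <- hho_run(sphere, config = hho_config(n_iterations = 100, seed = 1))
#' res$best_fitness
#' @export
hho_run <- function(objective, lower = NULL, upper = NULL, dim = NULL,
                    config = hho_config(), init_positions = NULL) {
  if (inherits(objective, "hho_objective")) {
    fn <- objective$fn
    lower <- objective$lower
    upper <- objective$upper
  } else {
    fn <- match.fun(objective)
    if (is.null(lower) || is.null(upper))
      stop("lower and upper bounds are required for a bare objective")
    if (!is.null(dim)) {
      lower <- rep_len(lower, dim)
      upper <- rep_len(upper, dim)
    }
  }
  if (length(lower) != length(upper) || any(lower >= upper))
    stop("invalid box: need lower < upper elementwise")
  d <- length(lower)
  if (!is.null(config$seed)) set.seed(config$seed)

  N <- config$n_hawks
  T_total <- config$n_iterations
  nonlinear <- config$schedule == "nonlinear"
  target <- config$target_fitness

  pop <- initialize_population(lower, upper, N, fn, init_positions)
  X <- pop$positions
  fit <- pop$fitnesses
  rabbit <- pop$rabbit_position
  rabbit_fit <- pop$rabbit_fitness
  n_evals <- N
  trace <- numeric(T_total)
  lo_m <- matrix(lower, N, d, byrow = TRUE)
  up_m <- matrix(upper, N, d, byrow = TRUE)
  span_m <- up_m - lo_m
  uniform_box <- all(lower == lower[1]) && all(upper == upper[1])
  clamp_rows <- if (uniform_box) {
    function(m, rows) pmin(pmax(m, lower[1]), upper[1])
  } else {
    function(m, rows) pmin(pmax(m, lo_m[rows, , drop = FALSE]),
                           up_m[rows, , drop = FALSE])
  }
  # objectives can carry a "matrix_fn" attribute evaluating all rows at once
  mat_fn <- attr(fn, "matrix_fn")
  eval_rows <- if (is.null(mat_fn)) {
    function(m) vapply(seq_len(nrow(m)), function(i) fn(m[i, ]), 0)
  } else {
    mat_fn
  }

  # The hawk updates of one iteration are computed as a batch against the
  # population state at the start of the iteration (reference behavior);
  # per-row uniform draws recycle down matrix rows.
  done <- !is.null(target) && rabbit_fit <= target
  t_run <- 0L
  for (t in seq_len(T_total) - 1L) {
    if (done) break
    e1 <- if (nonlinear) {
      nonlinear_energy_factor(t, T_total, config$b_ini, config$b_fin)
    } else {
      linear_energy_factor(t, T_total)
    }
    xmean <- colMeans(X)
    E <- (2 * stats::runif(N) - 1) * e1
    explore <- abs(E) >= 1

    idx <- which(explore)
    if (length(idx) > 0L) {
      k <- length(idx)
      q <- stats::runif(k)
      s1 <- idx[q >= 0.5]
      s2 <- idx[q < 0.5]
      if (length(s1) > 0L) {
        kk <- length(s1)
        xr <- X[sample.int(N, kk, replace = TRUE), , drop = FALSE]
        X[s1, ] <- xr - stats::runif(kk) *
          abs(xr - 2 * stats::runif(kk) * X[s1, , drop = FALSE])
      }
      if (length(s2) > 0L) {
        kk <- length(s2)
        X[s2, ] <- matrix(rabbit - xmean, kk, d, byrow = TRUE) -
          stats::runif(kk) * (lo_m[s2, , drop = FALSE] +
                                stats::runif(kk) * span_m[s2, , drop = FALSE])
      }
      X[idx, ] <- clamp_rows(X[idx, , drop = FALSE], idx)
      fit[idx] <- eval_rows(X[idx, , drop = FALSE])
      n_evals <- n_evals + length(idx)
    }

    expl <- which(!explore)
    if (length(expl) > 0L) {
      r <- stats::runif(length(expl))
      soft <- abs(E[expl]) >= 0.5
      b1 <- expl[r >= 0.5 & soft]    # soft besiege
      b2 <- expl[r >= 0.5 & !soft]   # hard besiege
      b3 <- expl[r < 0.5 & soft]     # soft besiege, rapid dives
      b4 <- expl[r < 0.5 & !soft]    # hard besiege, rapid dives
      rab_row <- function(k) matrix(rabbit, k, d, byrow = TRUE)
      if (length(b1) > 0L) {
        k <- length(b1)
        J <- 2 * (1 - stats::runif(k))
        Xi <- X[b1, , drop = FALSE]
        X[b1, ] <- (rab_row(k) - Xi) - E[b1] * abs(J * rab_row(k) - Xi)
      }
      if (length(b2) > 0L) {
        k <- length(b2)
        Xi <- X[b2, , drop = FALSE]
        X[b2, ] <- rab_row(k) - E[b2] * abs(rab_row(k) - Xi)
      }
      direct <- c(b1, b2)
      if (length(direct) > 0L) {
        X[direct, ] <- clamp_rows(X[direct, , drop = FALSE], direct)
        fit[direct] <- eval_rows(X[direct, , drop = FALSE])
        n_evals <- n_evals + length(direct)
      }
      dives <- c(b3, b4)
      if (length(dives) > 0L) {
        k <- length(dives)
        J <- 2 * (1 - stats::runif(k))
        B <- rbind(X[b3, , drop = FALSE],
                   if (length(b4) > 0L)
                     matrix(xmean, length(b4), d, byrow = TRUE))
        Y <- rab_row(k) - E[dives] * abs(J * rab_row(k) - B)
        Y <- clamp_rows(Y, dives)
        fY <- eval_rows(Y)
        n_evals <- n_evals + k
        better <- fY < fit[dives]
        if (any(better)) {
          X[dives[better], ] <- Y[better, , drop = FALSE]
          fit[dives[better]] <- fY[better]
        }
        rest <- which(!better)
        if (length(rest) > 0L) {
          kk <- length(rest)
          sigma <- (gamma(1 + config$levy_beta) *
                      sin(pi * config$levy_beta / 2) /
                      (gamma((1 + config$levy_beta) / 2) * config$levy_beta *
                         2^((config$levy_beta - 1) / 2)))^(1 / config$levy_beta)
          lf <- 0.01 * (matrix(stats::rnorm(kk * d), kk, d) * sigma) /
            abs(matrix(stats::rnorm(kk * d), kk, d))^(1 / config$levy_beta)
          Z <- Y[rest, , drop = FALSE] + matrix(stats::runif(kk * d), kk, d) * lf
          rows <- dives[rest]
          Z <- clamp_rows(Z, rows)
          fZ <- eval_rows(Z)
          n_evals <- n_evals + kk
          bz <- fZ < fit[rows]
          if (any(bz)) {
            X[rows[bz], ] <- Z[bz, , drop = FALSE]
            fit[rows[bz]] <- fZ[bz]
          }
        }
      }
    }

    b <- which.min(fit)
    if (fit[b] < rabbit_fit) {
      rabbit_fit <- fit[b]
      rabbit <- X[b, ]
    }
    if (!is.null(target) && rabbit_fit <= target) done <- TRUE

    if (config$rol && !done) {
      mirrored <- rol_transform(X, lower, upper, config$rol_per_dimension)
      mfit <- eval_rows(mirrored)
      n_evals <- n_evals + N
      sel <- select_survivors(X, fit, mirrored, mfit)
      X <- sel$positions
      fit <- sel$fitnesses
      if (fit[1] < rabbit_fit) {
        rabbit_fit <- fit[1]
        rabbit <- X[1, ]
      }
      if (!is.null(target) && rabbit_fit <= target) done <- TRUE
    }
    trace[t + 1L] <- rabbit_fit
    t_run <- t + 1L
  }
  if (t_run < T_total) {
    trace[(t_run + 1L):T_total] <- rabbit_fit
  }

  structure(list(best_fitness = rabbit_fit, best_position = rabbit,
                 trace = trace, n_evals = n_evals,
                 iterations_run = t_run, config = config,
                 seed = config$seed),
            class = "hho_result")
}

#' @rdname hho_run
#' @details `nolhho_run()` is a convenience wrapper that runs NOL-HHO: the
#'   nonlinear energy schedule plus the per-iteration ROL mirroring step.
#' @param ... Arguments passed to [hho_config()].
#' @export
nolhho_run <- function(objective, lower = NULL, upper = NULL, dim = NULL,
                       ...) {
  hho_run(objective, lower, upper, dim,
          config = hho_config(schedule = "nonlinear", rol = TRUE, ...))
}

#' @export
print.hho_result <- function(x, ...) {
  cat(sprintf("HHO run: best fitness %.6g after %d iterations (%d evals)\n",
              x$best_fitness, x$iterations_run, x$n_evals))
  invisible(x)
}

#' Serialize an optimization result to JSON
#'
#' @param result An `hho_result`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
hho_result_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "hho_result"))
  obj <- list(best_fitness = result$best_fitness,
              best_position = result$best_position,
              n_evals = result$n_evals,
              iterations_run = result$iterations_run,
              seed = result$seed,
              config = unclass(result$config),
              trace = result$trace)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
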