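#' Classical benchmark objective functions F1--F23
#'
#' The standard 23-function test suite used throughout the swarm-optimization
#' literature: unimodal functions F1--F7, scalable multimodal functions
#' F8--F13, and fixed-dimension multimodal functions F14--F23 (Shekel's
#' foxholes, Kowalik, six-hump camel, Branin, Goldstein--Price, Hartmann 3/6,
#' Shekel 5/7/10).
#'
#' Each objective is described by an `hho_objective` list with fields
#' `id`, `name`, `dim`, `lower`, `upper` (per-dimension bounds), `f_min`
#' (known global optimum value), `x_min` (a known minimizer, or `NULL`),
#' `noisy` (`TRUE` only for F7, whose value includes additive uniform noise
#' drawn from the active random stream), and `fn`, the evaluator.
#'
#' All evaluators are minimized. F1--F13 are dimension-scalable (default 30);
#' F14--F23 have fixed small dimensions.
#'
#' @param dim Optional dimension override applied to the scalable functions
#'   F1--F13 (e.g. 100, 500 or 1000 for high-dimensional sweeps). The
#'   fixed-dimension functions F14--F23 are returned unchanged.
#' @return For `benchmark_suite()`, a list of 23 `hho_objective` objects in
#'   conventional order. For `benchmark_function()`, a single
#'   `hho_objective`.
#' @examples
#' suite <- benchmark_suite()
#' f1 <- suite[[1]]
#' f1$fn(rep(0, f1$dim))  # sphere optimum: 0
#' @export
benchmark_suite <- function(dim = NULL) {
  lapply(1:23, benchmark_function, dim = dim)
}

#' @rdname benchmark_suite
#' @param id Function index, 1 to 23 (or a string like `"F9"`).
#' @export
benchmark_function <- function(id, dim = NULL) {
  if (is.character(id)) id <- as.integer(sub("^[Ff]", "", id))
  if (!id %in% 1:23) stop("unknown benchmark function id: ", id)
  def <- .benchmark_defs[[id]]
  d <- def$dim
  if (!is.null(dim)) {
    if (id > 13) stop("F", id, " has fixed dimension ", d,
                      "; dim override applies only to F1-F13")
    stopifnot(dim >= 1)
    d <- as.integer(dim)
  }
  lower <- rep_len(def$lower, d)
  upper <- rep_len(def$upper, d)
  f_min <- if (is.function(def$f_min)) def$f_min(d) else def$f_min
  x_min <- if (is.null(def$x_min)) NULL
           else if (is.function(def$x_min)) def$x_min(d) else def$x_min
  structure(list(id = paste0("F", id), index = id, name = def$name,
                 dim = d, lower = lower, upper = upper,
                 f_min = f_min, x_min = x_min,
                 noisy = isTRUE(def$noisy), fn = def$fn),
            class = "hho_objective")
}

#' Evaluate a benchmark objective at a point
#'
#' @param spec An `hho_objective` from [benchmark_function()].
#' @param x Numeric vector of length `spec$dim`.
#' @return The objective value (scalar). Pure except for F7, which adds a
#'   uniform(0,1) noise term drawn from the active random stream.
#' @export
evaluate_objective <- function(spec, x) {
  stopifnot(inherits(spec, "hho_objective"))
  if (length(x) != spec$dim)
    stop("point has length ", length(x), " but objective dimension is ",
         spec$dim)
  spec$fn(as.numeric(x))
}

#' Benchmark suite manifest
#'
#' @param suite A list of objectives from [benchmark_suite()].
#' @return A data frame with one row per function: id, name, dim, bounds and
#'   the known optimum value.
#' @export
suite_manifest <- function(suite = benchmark_suite()) {
  data.frame(
    id = vapply(suite, `[[`, "", "id"),
    name = vapply(suite, `[[`, "", "name"),
    dim = vapply(suite, `[[`, 0L, "dim"),
    lower = vapply(suite, function(s) s$lower[1], 0),
    upper = vapply(suite, function(s) s$upper[1], 0),
    f_min = vapply(suite, `[[`, 0, "f_min")
  )
}

#' @export
print.hho_objective <- function(x, ...) {
  cat(sprintf("%s (%s), dim %d, box [%g, %g], f_min %g\n",
              x$id, x$name, x$dim, x$lower[1], x$upper[1], x$f_min))
  invisible(x)
}

## ---- evaluators -----------------------------------------------------------

# penalty term shared by F12/F13
.u_penalty <- function(x, a, k, m) {
  sum(ifelse(x > a, k * (x - a)^m, ifelse(x < -a, k * (-x - a)^m, 0)))
}

# Shekel's foxholes 5x5 grid
.f14_a <- rbind(rep(c(-32, -16, 0, 16, 32), 5),
                rep(c(-32, -16, 0, 16, 32), each = 5))

.f15_a <- c(0.1957, 0.1947, 0.1735, 0.16, 0.0844, 0.0627,
            0.0456, 0.0342, 0.0323, 0.0235, 0.0246)
.f15_b <- 1 / c(0.25, 0.5, 1, 2, 4, 6, 8, 10, 12, 14, 16)

.hart3_alpha <- c(1, 1.2, 3, 3.2)
.hart3_A <- matrix(c(3, 10, 30,
                     0.1, 10, 35,
                     3, 10, 30,
                     0.1, 10, 35), 4, 3, byrow = TRUE)
.hart3_P <- 1e-4 * matrix(c(3689, 1170, 2673,
                            4699, 4387, 7470,
                            1091, 8732, 5547,
                            381, 5743, 8828), 4, 3, byrow = TRUE)

.hart6_A <- matrix(c(10, 3, 17, 3.5, 1.7, 8,
                     0.05, 10, 17, 0.1, 8, 14,
                     3, 3.5, 1.7, 10, 17, 8,
                     17, 8, 0.05, 10, 0.1, 14), 4, 6, byrow = TRUE)
.hart6_P <- 1e-4 * matrix(c(1312, 1696, 5569, 124, 8283, 5886,
                            2329, 4135, 8307, 3736, 1004, 9991,
                            2348, 1451, 3522, 2883, 3047, 6650,
                            4047, 8828, 8732, 5743, 1091, 381), 4, 6,
                          byrow = TRUE)

.shekel_C <- matrix(c(4, 4, 4, 4,
                      1, 1, 1, 1,
                      8, 8, 8, 8,
                      6, 6, 6, 6,
                      3, 7, 3, 7,
                      2, 9, 2, 9,
                      5, 5, 3, 3,
                      8, 1, 8, 1,
                      6, 2, 6, 2,
                      7, 3.6, 7, 3.6), 10, 4, byrow = TRUE)
.shekel_beta <- c(0.1, 0.2, 0.2, 0.4, 0.4, 0.6, 0.3, 0.7, 0.5, 0.5)

.shekel_fn <- function(m) {
  force(m)
  function(x) {
    -sum(1 / (rowSums(sweep(.shekel_C[1:m, , drop = FALSE], 2, x)^2) +
                .shekel_beta[1:m]))
  }
}

.benchmark_defs <- list(
  list(name = "Sphere", dim = 30L, lower = -100, upper = 100, f_min = 0,
       x_min = function(d) rep(0, d),
       fn = function(x) sum(x^2)),
  list(name = "Schwefel 2.22", dim = 30L, lower = -10, upper = 10, f_min = 0,
       x_min = function(d) rep(0, d),
       fn = function(x) sum(abs(x)) + prod(abs(x))),
  list(name = "Schwefel 1.2", dim = 30L, lower = -100, upper = 100, f_min = 0,
       x_min = function(d) rep(0, d),
       fn = function(x) sum(cumsum(x)^2)),
  list(name = "Schwefel 2.21", dim = 30L, lower = -100, upper = 100,
       f_min = 0, x_min = function(d) rep(0, d),
       fn = function(x) max(abs(x))),
  list(name = "Rosenbrock", dim = 30L, lower = -30, upper = 30, f_min = 0,
       x_min = function(d) rep(1, d),
       fn = function(x) {
         d <- length(x)
         sum(100 * (x[-1] - x[-d]^2)^2 + (x[-d] - 1)^2)
       }),
  list(name = "Step", dim = 30L, lower = -100, upper = 100, f_min = 0,
       x_min = function(d) rep(-0.5, d),
       fn = function(x) sum(abs(x + 0.5)^2)),
  list(name = "Noisy quartic", dim = 30L, lower = -1.28, upper = 1.28,
       f_min = 0, x_min = NULL, noisy = TRUE,
       fn = function(x) sum(seq_along(x) * x^4) + stats::runif(1)),
  list(name = "Schwefel sine", dim = 30L, lower = -500, upper = 500,
       f_min = function(d) round(-418.9829 * d, 4),
       x_min = function(d) rep(420.9687, d),
       fn = function(x) sum(-x * sin(sqrt(abs(x))))),
  list(name = "Rastrigin", dim = 30L, lower = -5.12, upper = 5.12, f_min = 0,
       x_min = function(d) rep(0, d),
       fn = function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10)),
  list(name = "Ackley", dim = 30L, lower = -32, upper = 32, f_min = 0,
       x_min = function(d) rep(0, d),
       fn = function(x) {
         d <- length(x)
         -20 * exp(-0.2 * sqrt(sum(x^2) / d)) - exp(sum(cos(2 * pi * x)) / d) +
           20 + exp(1)
       }),
  list(name = "Griewank", dim = 30L, lower = -600, upper = 600, f_min = 0,
       x_min = function(d) rep(0, d),
       fn = function(x) {
         sum(x^2) / 4000 - prod(cos(x / sqrt(seq_along(x)))) + 1
       }),
  list(name = "Penalized 1", dim = 30L, lower = -50, upper = 50, f_min = 0,
       x_min = function(d) rep(-1, d),
       fn = function(x) {
         d <- length(x)
         y <- 1 + (x + 1) / 4
         pi / d * (10 * sin(pi * y[1])^2 +
                     sum((y[-d] - 1)^2 * (1 + 10 * sin(pi * y[-1])^2)) +
                     (y[d] - 1)^2) +
           .u_penalty(x, 10, 100, 4)
       }),
  list(name = "Penalized 2", dim = 30L, lower = -50, upper = 50, f_min = 0,
       x_min = function(d) rep(1, d),
       fn = function(x) {
         d <- length(x)
         0.1 * (sin(3 * pi * x[1])^2 +
                  sum((x[-d] - 1)^2 * (1 + sin(3 * pi * x[-1])^2)) +
                  (x[d] - 1)^2 * (1 + sin(2 * pi * x[d])^2)) +
           .u_penalty(x, 5, 100, 4)
       }),
  list(name = "Shekel's foxholes", dim = 2L, lower = -65.536, upper = 65.536,
       f_min = 0.998003837794, x_min = c(-31.97833, -31.97833),
       fn = function(x) {
         1 / (1 / 500 + sum(1 / (1:25 + colSums((x - .f14_a)^6))))
       }),
  list(name = "Kowalik", dim = 4L, lower = -5, upper = 5,
       f_min = 0.00030748599, x_min = c(0.192833, 0.190836, 0.123117,
                                        0.135766),
       fn = function(x) {
         sum((.f15_a - x[1] * (.f15_b^2 + .f15_b * x[2]) /
                (.f15_b^2 + .f15_b * x[3] + x[4]))^2)
       }),
  list(name = "Six-hump camel", dim = 2L, lower = -5, upper = 5,
       f_min = -1.031628453489877, x_min = c(0.08984201, -0.7126564),
       fn = function(x) {
         4 * x[1]^2 - 2.1 * x[1]^4 + x[1]^6 / 3 + x[1] * x[2] -
           4 * x[2]^2 + 4 * x[2]^4
       }),
  list(name = "Branin", dim = 2L, lower = c(-5, 0), upper = c(10, 15),
       f_min = 0.397887357729739, x_min = c(pi, 2.275),
       fn = function(x) {
         (x[2] - 5.1 / (4 * pi^2) * x[1]^2 + 5 / pi * x[1] - 6)^2 +
           10 * (1 - 1 / (8 * pi)) * cos(x[1]) + 10
       }),
  list(name = "Goldstein-Price", dim = 2L, lower = -2, upper = 2, f_min = 3,
       x_min = c(0, -1),
       fn = function(x) {
         (1 + (x[1] + x[2] + 1)^2 *
            (19 - 14 * x[1] + 3 * x[1]^2 - 14 * x[2] + 6 * x[1] * x[2] +
               3 * x[2]^2)) *
           (30 + (2 * x[1] - 3 * x[2])^2 *
              (18 - 32 * x[1] + 12 * x[1]^2 + 48 * x[2] - 36 * x[1] * x[2] +
                 27 * x[2]^2))
       }),
  list(name = "Hartmann 3", dim = 3L, lower = 0, upper = 1,
       f_min = -3.86277978729426,
       x_min = c(0.114589105956, 0.555648866928, 0.852546353262),
       fn = function(x) {
         -sum(.hart3_alpha *
                exp(-rowSums(.hart3_A * sweep(.hart3_P, 2, x)^2)))
       }),
  list(name = "Hartmann 6", dim = 6L, lower = 0, upper = 1,
       f_min = -3.32236801141551, x_min = c(0.20169, 0.150011, 0.476874,
                                            0.275332, 0.311652, 0.6573),
       fn = function(x) {
         -sum(.hart3_alpha *
                exp(-rowSums(.hart6_A * sweep(.hart6_P, 2, x)^2)))
       }),
  list(name = "Shekel 5", dim = 4L, lower = 0, upper = 10,
       f_min = -10.1531996790582,
       x_min = c(4.000037153561, 4.000133279252, 4.000037153561,
                 4.000133279252), fn = .shekel_fn(5)),
  list(name = "Shekel 7", dim = 4L, lower = 0, upper = 10,
       f_min = -10.4029405668187,
       x_min = c(4.000572925794, 4.000689378307, 3.999489697563,
                 3.999606149792), fn = .shekel_fn(7)),
  list(name = "Shekel 10", dim = 4L, lower = 0, upper = 10,
       f_min = -10.5364098166920,
       x_min = c(4.000746544892, 4.000592944625, 3.999663390357,
                 3.999509789589), fn = .shekel_fn(10))
)
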