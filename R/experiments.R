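#' Counter-based seed derivation
#'
#' Derives an independent per-run seed from a master seed and a run counter,
#' so that a whole experiment is reproducible from a single integer while
#' every run gets its own stream.
#'
#' @param master Master seed (integer).
#' @param index Run counter (>= 1).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  as.integer((as.double(master) %% 2147483647 * 48271 + index * 1009) %%
               2147483646) + 1L
}

#' Repeated-run benchmark comparison of HHO and NOL-HHO
#'
#' Runs each requested algorithm on each requested benchmark function for
#' `runs` independent seeded repetitions and reports the mean (AVG) and
#' standard deviation (STD) of the per-run best objective values, the
#' standard protocol for comparing stochastic optimizers.
#'
#' @param functions Benchmark function indices (default all 23).
#' @param algorithms Subset of `c("NOL-HHO", "HHO")`.
#' @param runs Independent repetitions per (algorithm, function) cell
#'   (default 30).
#' @param n_hawks,iterations Optimizer budget per run (defaults 30 and 500).
#' @param dim Optional dimension override for F1-F13.
#' @param seed Master seed; per-run seeds are derived with [derive_seed()]
#'   and recorded.
#' @return An object of class `hho_experiment`: a list with `summary` (data
#'   frame with columns id, algorithm, avg, std), `values` (named list of
#'   per-run best values), `seeds`, and the protocol echo.
#' @export
run_benchmark_table <- function(functions = 1:23,
                                algorithms = c("NOL-HHO", "HHO"),
                                runs = 30, n_hawks = 30, iterations = 500,
                                dim = NULL, seed = 1) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  rows <- list()
  values <- list()
  seeds <- list()
  counter <- 0L
  for (fi in functions) {
    spec <- benchmark_function(fi, dim = if (fi <= 13) dim else NULL)
    for (alg in algorithms) {
      run_seeds <- integer(runs)
      best <- numeric(runs)
      for (r in seq_len(runs)) {
        counter <- counter + 1L
        run_seeds[r] <- derive_seed(seed, counter)
        cfg <- if (alg == "NOL-HHO") {
          hho_config(n_hawks = n_hawks, n_iterations = iterations,
                     schedule = "nonlinear", rol = TRUE, seed = run_seeds[r])
        } else {
          hho_config(n_hawks = n_hawks, n_iterations = iterations,
                     seed = run_seeds[r])
        }
        best[r] <- hho_run(spec, config = cfg)$best_fitness
      }
      key <- paste(spec$id, alg, sep = ".")
      values[[key]] <- best
      seeds[[key]] <- run_seeds
      rows[[key]] <- data.frame(id = spec$id, dim = spec$dim,
                                algorithm = alg, avg = mean(best),
                                std = stats::sd(best))
    }
  }
  structure(list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
                 values = values, seeds = seeds,
                 runs = runs, n_hawks = n_hawks, iterations = iterations,
                 master_seed = seed),
            class = "hho_experiment")
}

#' @export
print.hho_experiment <- function(x, ...) {
  cat(sprintf("Benchmark experiment: %d runs, %d hawks, %d iterations\n",
              x$runs, x$n_hawks, x$iterations))
  s <- x$summary
  s$avg <- sprintf("%.2e", s$avg)
  s$std <- sprintf("%.2e", s$std)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Dimension sweep over the scalable benchmark functions
#'
#' Repeats the benchmark protocol of [run_benchmark_table()] at each of the
#' requested dimensions for the scalable functions F1-F13.
#'
#' @param dims Dimensions to test (e.g. `c(100, 500, 1000)`).
#' @param functions Scalable function indices (subset of 1:13).
#' @inheritParams run_benchmark_table
#' @return A data frame keyed by (id, dim, algorithm) with avg and std
#'   columns; per-run values in attribute `"values"`.
#' @export
run_dimension_sweep <- function(dims = c(100, 500, 1000), functions = 1:13,
                                algorithms = c("NOL-HHO", "HHO"), runs = 30,
                                n_hawks = 30, iterations = 500, seed = 1) {
  if (any(functions > 13)) stop("only F1-F13 are dimension-scalable")
  out <- list()
  vals <- list()
  for (dm in dims) {
    exp <- run_benchmark_table(functions, algorithms, runs, n_hawks,
                               iterations, dim = dm,
                               seed = derive_seed(seed, dm))
    out[[as.character(dm)]] <- exp$summary
    vals[[as.character(dm)]] <- exp$values
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(res, "values") <- vals
  res
}

#' Wilcoxon rank-sum comparison of two optimizers
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test on the per-run best values
#' of two algorithms, the standard nonparametric check that an observed
#' difference in repeated stochastic runs is significant (flagged at the 5%
#' level).
#'
#' @param a,b Numeric vectors of per-run best objective values (equal run
#'   counts).
#' @param alpha Significance level (default 0.05).
#' @return A list with `p_value`, `significant`, `statistic`, and `tied`
#'   (`TRUE` when every observation in both samples is identical, in which
#'   case p = 1 is reported with a warning).
#' @export
wilcoxon_compare <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) == length(b), length(a) >= 1)
  if (length(unique(c(a, b))) == 1L) {
    warning("all observations tied; reporting p = 1")
    return(list(p_value = 1, significant = FALSE, statistic = NA_real_,
                tied = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(p_value = wt$p.value, significant = wt$p.value < alpha,
       statistic = unname(wt$statistic), tied = FALSE)
}

#' Lower-bound grid for DNA storage codes
#'
#' Runs the NOL-HHO code builder for every requested (n, d) cell and
#' reports the constructed set sizes: each size M certifies
#' A^GC,NL(n, d, w) >= M with w = floor(n/2). Cells with n <= 6 are
#' additionally verified against the exact branch-and-bound maximum.
#'
#' @param n_range Word lengths.
#' @param d_range Function of n giving the distances to test (default
#'   `3:n`), or a fixed integer vector.
#' @param budget Named list of [grow_code_set()] arguments applied to every
#'   cell (e.g. `list(restarts = 400)`).
#' @param exact_upto Verify cells with n up to this value by
#'   [exhaustive_best()] (default 4; raise with care, the exact search is
#'   exponential).
#' @param seed Master seed.
#' @param out_dir Optional directory to write per-cell FASTA files and the
#'   grid CSV into.
#' @return A data frame with columns n, d, w, size, rate, and exact_max
#'   (`NA` where not verified).
#' @export
run_bound_grid <- function(n_range = 4:10, d_range = NULL, budget = list(),
                           exact_upto = 4, seed = 1, out_dir = NULL) {
  rows <- list()
  cell <- 0L
  for (n in n_range) {
    dd <- if (is.null(d_range)) 3:n else d_range[d_range <= n]
    for (d in dd) {
      cell <- cell + 1L
      w <- floor(n / 2)
      args <- c(list(n = n, d = d, w = w, seed = derive_seed(seed, cell)),
                budget)
      cs <- do.call(grow_code_set, args)
      exact <- NA_integer_
      if (n <= exact_upto) exact <- exhaustive_best(n, d, w)$size
      rows[[cell]] <- data.frame(n = n, d = d, w = w, size = cs$size,
                                 rate = code_rate(max(cs$size, 1), n),
                                 exact_max = exact)
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write_code_lines(cs, file.path(out_dir,
                                       sprintf("code_n%d_d%d_w%d.txt",
                                               n, d, w)))
      }
    }
  }
  grid <- do.call(rbind, rows)
  if (!is.null(out_dir))
    utils::write.csv(grid, file.path(out_dir, "bound_grid.csv"),
                     row.names = FALSE)
  grid
}

#' Published reference results
#'
#' Mean/standard-deviation results reported in the metaheuristics
#' literature for other optimizers (GA, PSO, BBO, FPA, GWO, BAT, FA, MFO,
#' DE) on the F1-F23 suite, and previously published lower bounds for
#' A^GC,NL(n, d, w) obtained with an altruistic search algorithm. These are
#' quoted constants for side-by-side display; the package never recomputes
#' them.
#'
#' @return A data frame.
#' @export
reference_benchmarks <- function() {
  utils::read.csv(system.file("extdata", "published_benchmark_results.csv",
                              package = "nolhho"))
}

#' @rdname reference_benchmarks
#' @export
reference_bounds <- function() {
  utils::read.csv(system.file("extdata", "published_lower_bounds.csv",
                              package = "nolhho"))
}
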