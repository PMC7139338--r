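#' Decode a continuous search vector into a DNA word
#'
#' The code builder searches the continuous box `[0, 4]^n`; a position is
#' decoded by flooring each coordinate (clamped into `[0, 4)`) to a base-4
#' digit and mapping digits to bases (A-0, G-1, C-2, T-3).
#'
#' @param v Numeric vector of length n with entries in `[0, 4]`.
#' @return A DNA word (character scalar).
#' @examples
#' decode_vector(c(0.2, 1.9, 2.5, 3.99))  # "AGCT"
#' @export
decode_vector <- function(v) {
  digits_to_dna(decode_digits(v))
}

decode_digits <- function(v) {
  as.integer(floor(pmin(pmax(v, 0), 4 - 1e-9)))
}

#' Penalty fitness of a candidate codeword
#'
#' The objective minimized by the inner NOL-HHO searches of the code
#' builder:
#'
#'   fitness = P * (adjacent equal pairs) + P * |GC count - w|
#'             + max(0, d - minDist(word, set))
#'
#' with `P = n + 1`, so that any constraint violation dominates any distance
#' shortfall, and `minDist` against an empty set defined as n. Fitness 0 is
#' equivalent to admissibility: the word is feasible (no-runlength, GC
#' weight w) and at Hamming distance >= d from every word already in the
#' set.
#'
#' @param word A DNA word (character) or its digit vector.
#' @param current Character vector of words already in the set (may be
#'   empty).
#' @param d Minimum distance threshold.
#' @param w GC weight.
#' @return The penalty fitness (0 iff admissible).
#' @export
candidate_fitness <- function(word, current, d, w) {
  dg <- if (is.character(word)) dna_to_digits(word) else as.integer(word)
  set_m <- if (length(current) == 0) {
    matrix(integer(), 0, length(dg))
  } else {
    m <- dna_to_digits(current)
    if (!is.matrix(m)) m <- matrix(m, nrow = 1)
    m
  }
  .penalty_fitness(dg, set_m, length(dg), d, w)
}

.penalty_fitness <- function(dg, set_m, n, d, w) {
  P <- n + 1
  nl <- sum(dg[-1L] == dg[-n])
  gc_dev <- abs(sum(dg == 1L | dg == 2L) - w)
  M <- nrow(set_m)
  md <- if (M == 0L) n else min(rowSums(set_m != rep(dg, each = M)))
  P * nl + P * gc_dev + max(0, d - md)
}

# Continuous objective over [0,4]^n for the inner searches. `hits` is an
# environment collecting every admissible decoded word evaluated, so the
# builder can break ties lexicographically. A vectorized variant evaluating
# a whole population at once is attached as the "matrix_fn" attribute.
.code_objective <- function(set_m, n, d, w, hits) {
  P <- n + 1
  M <- nrow(set_m)
  fn <- function(v) {
    dg <- as.integer(floor(pmin(pmax(v, 0), 4 - 1e-9)))
    f <- {
      nl <- sum(dg[-1L] == dg[-n])
      gc_dev <- abs(sum(dg == 1L | dg == 2L) - w)
      md <- if (M == 0L) n else min(rowSums(set_m != rep(dg, each = M)))
      P * nl + P * gc_dev + max(0, d - md)
    }
    if (f == 0) hits$words[[length(hits$words) + 1L]] <- dg
    f
  }
  # one-hot encoding of the current set: match counts against candidates
  # come from a single crossproduct, min distance from max matches
  S <- if (M > 0L) {
    s1h <- matrix(0, M, 4L * n)
    s1h[cbind(rep(seq_len(M), n),
              (rep(seq_len(n), each = M) - 1L) * 4L + as.vector(set_m) + 1L)] <- 1
    s1h
  }
  attr(fn, "matrix_fn") <- function(m) {
    k <- nrow(m)
    dgm <- floor(pmin(pmax(m, 0), 4 - 1e-9))
    nl <- if (n > 1) rowSums(dgm[, -1L, drop = FALSE] ==
                               dgm[, -n, drop = FALSE]) else 0
    gc_dev <- abs(rowSums(dgm == 1 | dgm == 2) - w)
    short <- if (M == 0L) {
      rep(max(0, d - n), k)
    } else {
      a1h <- matrix(0, k, 4L * n)
      a1h[cbind(rep(seq_len(k), n),
                (rep(seq_len(n), each = k) - 1L) * 4L + as.vector(dgm) + 1L)] <- 1
      matches <- tcrossprod(a1h, S)
      max_match <- matches[cbind(seq_len(k), max.col(matches, "first"))]
      pmax(0, d - (n - max_match))
    }
    f <- P * nl + P * gc_dev + short
    zero <- which(f == 0)
    for (i in zero) hits$words[[length(hits$words) + 1L]] <- as.integer(dgm[i, ])
    f
  }
  fn
}

#' Enumerate all feasible words
#'
#' All length-n words over {A, C, G, T} that satisfy the no-runlength
#' constraint and have exactly w G/C bases. There are 4 * 3^(n-1)
#' no-runlength words before the GC filter.
#'
#' @param n Word length.
#' @param w GC weight.
#' @param as_digits Return the digit matrix instead of character words.
#' @return Character vector of words (or an integer matrix, one word per
#'   row).
#' @export
enumerate_feasible_words <- function(n, w, as_digits = FALSE) {
  stopifnot(n >= 1, w >= 0, w <= n)
  m <- matrix(0:3, ncol = 1)
  if (n > 1) {
    for (pos in 2:n) {
      k <- nrow(m)
      # each word extends with the 3 digits different from its last digit
      last <- m[, pos - 1L]
      ext <- vapply(0:2, function(o) (last + o + 1L) %% 4L, integer(k))
      m <- cbind(m[rep(seq_len(k), 3), , drop = FALSE], as.vector(ext))
    }
  }
  gc <- rowSums(m == 1L | m == 2L)
  m <- m[gc == w, , drop = FALSE]
  if (as_digits) return(m)
  digits_to_dna(m)
}

#' Grow a DNA storage code set with NOL-HHO
#'
#' Builds a code set for parameters (n, d, w) one word at a time. Each
#' candidate word is found by running NOL-HHO (nonlinear energy schedule
#' plus ROL) over the continuous relaxation `[0, 4]^n` of the word space,
#' minimizing [candidate_fitness()] against the words accepted so far; a
#' run that reaches fitness 0 yields an admissible word, which is added to
#' the set. After `max_failures` consecutive unsuccessful searches the set
#' is considered maximal for the current trajectory.
#'
#' Restarts are perturbative: each round either drops a random fraction of
#' the incumbent set (ruin-and-recreate) or force-inserts a random feasible
#' word and evicts the kept words that conflict with it, then resumes
#' NOL-HHO growth. Force insertion is the classic plateau-escape move of
#' packing/clique search; pure incremental growth stalls on locally maximal
#' sets that are well below the best known packings. The largest valid set
#' seen over all rounds is returned; when a round ends below the incumbent
#' best, the search usually resumes from the best set.
#'
#' @param n Word length.
#' @param d Minimum pairwise Hamming distance (1 <= d <= n).
#' @param w GC weight (default `floor(n / 2)`).
#' @param hawks,iterations Population size and iteration cap of each inner
#'   NOL-HHO search. Evaluation is batched across the population, so wide,
#'   short searches are cheap; by default the population width adapts to
#'   the cell (at least 150 hawks, growing with the feasible-word count and
#'   the distance threshold). Searches stop early as soon as an admissible
#'   word is found, so successful searches cost far less than the cap.
#' @param max_failures Consecutive failed searches that end a growth phase.
#' @param restarts Number of perturbation rounds. More rounds only ever
#'   improve the result; large or tightly packed cells need thousands.
#' @param drop_fraction Upper bound on the fraction of the set dropped in a
#'   ruin round (at least one word is always dropped).
#' @param force_probability Probability that a round uses force insertion
#'   rather than random drops.
#' @param stop_size Optional early-exit: stop as soon as a set of at least
#'   this size has been found (useful when certifying that a known bound is
#'   attainable).
#' @param seed Optional seed; a seeded build is fully reproducible.
#' @param verbose Print progress every 100 rounds.
#' @return A validated [dna_code_set()].
#' @examples
#' \donttest{
#' cs <- grow_code_set(4, 3, 2, restarts = 150, seed = 1)
#' cs$size  # 12 is the true maximum for (4, 3, 2)
#' }
#' @export
grow_code_set <- function(n, d, w = floor(n / 2), hawks = NULL,
                          iterations = 10, max_failures = 3, restarts = 500,
                          drop_fraction = 0.125, force_probability = 0.5,
                          stop_size = NULL, seed = NULL, verbose = FALSE) {
  stopifnot(n >= 2, d >= 1, d <= n, w >= 0, w <= n)
  if (!is.null(seed)) set.seed(seed)
  lower <- rep(0, n)
  upper <- rep(4, n)
  pool <- enumerate_feasible_words(n, w, as_digits = TRUE)
  if (nrow(pool) == 0L)
    return(dna_code_set(character(0), n = n, d = d, w = w))
  if (is.null(hawks)) {
    # evaluation is batched, so the population is made as wide as the
    # feasible stratum allows: the pool-seeded initialization then screens
    # (up to) the whole stratum before recombination takes over
    hawks <- min(nrow(pool), 1200L)
  }
  cfg <- hho_config(n_hawks = hawks, n_iterations = iterations,
                    schedule = "nonlinear", rol = TRUE, target_fitness = 0)

  # hawks start on feasible words (uniform jitter within the decode cell),
  # so each search opens by screening a random sample of the feasible
  # stratum before the optimizer recombines
  seed_positions <- function(k) {
    rows <- sample.int(nrow(pool), min(k, nrow(pool)))
    pool[rows, , drop = FALSE] + matrix(stats::runif(length(rows) * n),
                                        length(rows), n)
  }
  search_word <- function(set_m) {
    hits <- new.env(parent = emptyenv())
    hits$words <- list()
    fn <- .code_objective(set_m, n, d, w, hits)
    res <- hho_run(fn, lower, upper, config = cfg,
                   init_positions = seed_positions(2L * hawks))
    if (res$best_fitness > 0 || length(hits$words) == 0L) return(NULL)
    found <- unique(vapply(hits$words, digits_to_dna, ""))
    dna_to_digits(sort(found)[1])  # lexicographically smallest admissible
  }

  grow_maximal <- function(set_m) {
    failures <- 0L
    while (failures < max_failures) {
      wd <- search_word(set_m)
      if (is.null(wd)) {
        failures <- failures + 1L
      } else {
        set_m <- rbind(set_m, wd, deparse.level = 0)
        failures <- 0L
      }
    }
    set_m
  }

  cur <- grow_maximal(matrix(integer(), 0, n))
  best <- cur
  for (round in seq_len(restarts)) {
    if (!is.null(stop_size) && nrow(best) >= stop_size) break
    if (nrow(cur) == 0L) break
    if (stats::runif(1) < force_probability) {
      wd <- pool[sample.int(nrow(pool), 1), ]
      # evict everything within distance d of wd (including a kept copy of
      # wd itself, at distance 0), then insert wd
      conflict <- rowSums(cur != rep(wd, each = nrow(cur))) < d
      cur <- rbind(cur[!conflict, , drop = FALSE], wd, deparse.level = 0)
    } else {
      k <- sample.int(max(1L, floor(nrow(cur) * drop_fraction)), 1)
      keep <- sample.int(nrow(cur), max(0L, nrow(cur) - k))
      cur <- cur[keep, , drop = FALSE]
    }
    cur <- grow_maximal(cur)
    if (nrow(cur) >= nrow(best)) {
      best <- cur
    } else if (stats::runif(1) < 0.7) {
      cur <- best
    }
    if (verbose && round %% 100 == 0)
      message(sprintf("round %d: current %d, best %d", round, nrow(cur),
                      nrow(best)))
  }
  dna_code_set(digits_to_dna(best), n = n, d = d, w = w)
}

#' Exact maximum code size by branch-and-bound clique search
#'
#' Enumerates every feasible word (no-runlength, GC weight w), builds the
#' compatibility graph (edge iff Hamming distance >= d) and finds a maximum
#' clique with a Tomita-style branch-and-bound using a greedy-coloring
#' bound. The result is the true value of A^GC,NL(n, d, w). Intended for
#' small n (the feasible-word graph grows as 3^n); dense instances
#' (small d) get slow beyond n = 5.
#'
#' @param n Word length (n <= 6 recommended).
#' @param d Minimum pairwise distance.
#' @param w GC weight (default `floor(n / 2)`).
#' @return A [dna_code_set()] of maximum size, with attribute
#'   `exact = TRUE`.
#' @examples
#' exhaustive_best(4, 4, 2)$size  # 4
#' @export
exhaustive_best <- function(n, d, w = floor(n / 2)) {
  stopifnot(d >= 1, d <= n)
  if (n > 6) stop("exact search is limited to n <= 6")
  fw <- enumerate_feasible_words(n, w, as_digits = TRUE)
  nv <- nrow(fw)
  adj <- vector("list", nv)
  for (i in seq_len(nv)) {
    di <- rowSums(fw != rep(fw[i, ], each = nv))
    adj[[i]] <- which(di >= d & seq_len(nv) != i)
  }
  res <- .max_clique_bb(adj)
  out <- dna_code_set(digits_to_dna(fw[res$vertices, , drop = FALSE]),
                      n = n, d = d, w = w)
  attr(out, "exact") <- TRUE
  out
}

# Tomita-style maximum clique: branch and bound with a greedy coloring
# upper bound, vertices expanded in decreasing color order.
.max_clique_bb <- function(adj) {
  nv <- length(adj)
  best_size <- 0L
  best_set <- integer()
  expand <- function(R, P) {
    if (length(P) == 0L) {
      if (length(R) > best_size) {
        best_size <<- length(R)
        best_set <<- R
      }
      return(invisible(NULL))
    }
    degP <- vapply(P, function(v) length(intersect(adj[[v]], P)), 0L)
    ord <- P[order(-degP)]
    col <- integer(nv)
    for (v in ord) {
      used <- col[intersect(adj[[v]], P)]
      cc <- 1L
      while (cc %in% used) cc <- cc + 1L
      col[v] <- cc
    }
    for (v in ord[order(-col[ord])]) {
      if (length(R) + col[v] <= best_size) return(invisible(NULL))
      expand(c(R, v), intersect(P, adj[[v]]))
      P <- P[P != v]
    }
    invisible(NULL)
  }
  expand(integer(), seq_len(nv))
  list(size = best_size, vertices = best_set)
}

#' Randomized greedy lower-bound baseline
#'
#' First-fit over random orderings of the feasible words: a word is kept
#' when its distance to every kept word is >= d. The best set over all
#' orderings is returned. A cheap independent baseline for cross-checking
#' the NOL-HHO builder.
#'
#' @param n,d,w Code parameters.
#' @param orderings Number of random orderings tried.
#' @param seed Optional seed.
#' @return A [dna_code_set()].
#' @export
greedy_baseline <- function(n, d, w = floor(n / 2), orderings = 200,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fw <- enumerate_feasible_words(n, w, as_digits = TRUE)
  nv <- nrow(fw)
  best <- NULL
  for (o in seq_len(orderings)) {
    ord <- sample.int(nv)
    kept <- matrix(integer(), 0, n)
    for (i in ord) {
      dg <- fw[i, ]
      M <- nrow(kept)
      ok <- M == 0L || min(rowSums(kept != rep(dg, each = M))) >= d
      if (ok) kept <- rbind(kept, dg)
    }
    if (is.null(best) || nrow(kept) > nrow(best)) best <- kept
  }
  dna_code_set(digits_to_dna(best), n = n, d = d, w = w)
}
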