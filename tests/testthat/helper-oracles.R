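# Independent straight-line oracles used to cross-check the package
# implementations. These deliberately avoid the package's own code paths.

# naive benchmark evaluators (loop-based, no shared helpers)
oracle_sphere <- function(x) {
  s <- 0
  for (v in x) s <- s + v * v
  s
}

oracle_rastrigin <- function(x) {
  s <- 0
  for (v in x) s <- s + v^2 - 10 * cos(2 * pi * v) + 10
  s
}

oracle_rosenbrock <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1))
    s <- s + 100 * (x[i + 1] - x[i]^2)^2 + (x[i] - 1)^2
  s
}

oracle_griewank <- function(x) {
  s <- 0
  p <- 1
  for (i in seq_along(x)) {
    s <- s + x[i]^2
    p <- p * cos(x[i] / sqrt(i))
  }
  s / 4000 - p + 1
}

# exhaustive enumeration of words over ACGT for small n
oracle_all_words <- function(n) {
  g <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), n))
  apply(g, 1, paste, collapse = "")
}

oracle_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sum(av != bv)
}

oracle_no_runlength <- function(word) {
  ch <- strsplit(word, "")[[1]]
  if (length(ch) < 2) return(TRUE)
  for (i in 2:length(ch)) if (ch[i] == ch[i - 1]) return(FALSE)
  TRUE
}

# exact two-sided rank-sum p-value by full enumeration of group assignments
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n)])
  combs <- utils::combn(length(pooled), n)
  stats <- apply(combs, 2, function(ix) sum(r[ix]))
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

# random feasible DNA word (no-runlength, given GC count) for fixtures
random_feasible_word <- function(n, w) {
  repeat {
    word <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  collapse = "")
    if (oracle_no_runlength(word) &&
        sum(strsplit(word, "")[[1]] %in% c("G", "C")) == w)
      return(word)
  }
}
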