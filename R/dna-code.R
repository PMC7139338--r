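#' Quaternary digit codec for DNA words
#'
#' DNA storage codewords are fixed-length strings over {A, C, G, T}. The
#' quaternary codec maps A-0, G-1, C-2, T-3, so each word of length n is a
#' base-4 integer vector of length n; `digits_to_dna()` inverts the mapping.
#'
#' @param words Character vector of DNA words (equal lengths not required
#'   here; constraint checks are per word).
#' @return For `dna_to_digits()`, an integer matrix with one row per word
#'   (or a vector for a single word); for `digits_to_dna()`, a character
#'   vector of words.
#' @examples
#' dna_to_digits("AGCT")        # 0 1 2 3
#' digits_to_dna(c(0, 1, 2, 3)) # "AGCT"
#' @export
dna_to_digits <- function(words) {
  stopifnot(is.character(words))
  out <- lapply(strsplit(toupper(words), ""), function(ch) {
    m <- match(ch, c("A", "G", "C", "T")) - 1L
    if (anyNA(m)) stop("invalid base in word: only A, C, G, T are allowed")
    m
  })
  if (length(out) == 1L) return(out[[1]])
  do.call(rbind, out)
}

#' @rdname dna_to_digits
#' @param digits Integer vector of base-4 digits (one word), or a matrix
#'   with one word per row.
#' @export
digits_to_dna <- function(digits) {
  bases <- c("A", "G", "C", "T")
  conv <- function(v) {
    if (length(v) == 0L) return("")
    if (any(v < 0 | v > 3)) stop("digits must lie in 0..3")
    paste(bases[v + 1L], collapse = "")
  }
  if (is.matrix(digits)) {
    if (nrow(digits) == 0L) return(character(0))
    apply(digits, 1, conv)
  } else {
    conv(as.integer(digits))
  }
}

#' No-runlength constraint
#'
#' A word satisfies the no-runlength constraint when no two adjacent bases
#' are equal, i.e. it contains no homopolymer of length 2 or more.
#' Homopolymer runs inflate synthesis and sequencing error rates and promote
#' secondary structure, so storage codes exclude them.
#'
#' @param words Character vector of DNA words.
#' @return Logical vector, one entry per word. Words of length < 2 pass
#'   vacuously.
#' @examples
#' has_no_runlength(c("CTAACG", "AGAGAG"))  # FALSE TRUE
#' @export
has_no_runlength <- function(words) {
  vapply(strsplit(toupper(words), ""), function(ch) {
    n <- length(ch)
    if (n < 2L) return(TRUE)
    !any(ch[-1] == ch[-n])
  }, logical(1))
}

#' GC content of DNA words
#'
#' Fraction of bases that are G or C. Storage codes fix the GC count (the
#' weight w, typically n/2) so that all codewords share similar melting
#' behavior.
#'
#' @param words Character vector of DNA words.
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @examples
#' gc_content("GTAC")  # 0.5
#' @export
gc_content <- function(words) {
  vapply(strsplit(toupper(words), ""), function(ch) {
    if (length(ch) == 0L) return(NA_real_)
    mean(ch %in% c("G", "C"))
  }, numeric(1))
}

#' Hamming distance between DNA words
#'
#' Number of positions at which two equal-length words differ. Storage code
#' sets require every distinct pair to be at distance >= d, which bounds
#' cross-hybridization between codewords and allows substitution errors to
#' be corrected.
#'
#' @param x,y DNA words (character scalars) of equal length.
#' @return Integer distance.
#' @examples
#' hamming_distance("AAAA", "TTTT")  # 4
#' @export
hamming_distance <- function(x, y) {
  a <- strsplit(toupper(x), "")[[1]]
  b <- strsplit(toupper(y), "")[[1]]
  if (length(a) != length(b)) stop("words must have equal length")
  sum(a != b)
}

#' All pairwise Hamming distances of a set of words
#'
#' @param words Character vector of equal-length DNA words.
#' @return An integer distance matrix.
#' @export
hamming_matrix <- function(words) {
  m <- dna_to_digits(words)
  if (!is.matrix(m)) m <- matrix(m, nrow = 1)
  n <- nrow(m)
  out <- matrix(0L, n, n, dimnames = list(words, words))
  for (i in seq_len(n)) {
    di <- m[i, ]
    for (j in seq_len(n)) out[i, j] <- sum(di != m[j, ])
  }
  out
}

#' Construct a DNA code set
#'
#' Bundles a vector of codewords with its design parameters (n, d, w) and
#' validates the result. A valid code set of size M certifies the lower
#' bound A^GC,NL(n, d, w) >= M: M length-n words, all with no-runlength
#' structure and exactly w G/C bases, every distinct pair at Hamming
#' distance >= d.
#'
#' @param words Character vector of DNA words.
#' @param n Word length.
#' @param d Minimum pairwise Hamming distance.
#' @param w GC weight (count of G/C bases per word). Defaults to
#'   `floor(n / 2)`.
#' @param validate Check the constraints on construction (default `TRUE`).
#' @return An object of class `dna_code_set`.
#' @export
dna_code_set <- function(words, n, d, w = floor(n / 2), validate = TRUE) {
  words <- unique(toupper(words))
  obj <- structure(list(words = words, n = as.integer(n), d = as.integer(d),
                        w = as.integer(w), size = length(words)),
                   class = "dna_code_set")
  if (validate) {
    rep <- validate_code_set(obj)
    if (!rep$pass)
      stop("invalid code set: ", rep$first_violation)
  }
  obj
}

#' @export
print.dna_code_set <- function(x, ...) {
  cat(sprintf("DNA code set: %d words, n = %d, d >= %d, GC weight %d (rate %.3f)\n",
              x$size, x$n, x$d, x$w, code_rate(x$size, x$n)))
  if (x$size > 0)
    cat("  ", paste(utils::head(x$words, 6), collapse = " "),
        if (x$size > 6) "..." else "", "\n")
  invisible(x)
}

#' Validate a candidate DNA storage code set
#'
#' Checks every word for length, alphabet, the no-runlength constraint and
#' the GC weight, checks for duplicates, and computes the minimum pairwise
#' Hamming distance. Violations are reported, not raised.
#'
#' @param candidate A `dna_code_set`, or a character vector of words (in
#'   which case `n`, `d`, `w` must be supplied).
#' @param n,d,w Code parameters (taken from the object when omitted).
#' @return A list of class `dna_code_report`: `pass`, `first_violation`
#'   (`NA` when passing), `min_distance` (for fewer than two words the
#'   sentinel n + 1), `gc_counts`, `nl_ok`, and `n_words`.
#' @export
validate_code_set <- function(candidate, n = NULL, d = NULL, w = NULL) {
  if (inherits(candidate, "dna_code_set")) {
    words <- candidate$words
    n <- candidate$n; d <- candidate$d; w <- candidate$w
  } else {
    words <- toupper(as.character(candidate))
    if (is.null(n) || is.null(d) || is.null(w))
      stop("n, d and w are required when validating a bare word vector")
  }
  viol <- NULL
  m <- length(words)
  gc_counts <- integer(m)
  nl_ok <- logical(m)
  if (m > 0) {
    lens <- nchar(words)
    if (any(lens != n) && is.null(viol))
      viol <- sprintf("word %d has length %d, expected %d",
                      which(lens != n)[1], lens[lens != n][1], n)
    bad <- grepl("[^ACGT]", words)
    if (any(bad) && is.null(viol))
      viol <- sprintf("word %d contains a non-ACGT character", which(bad)[1])
    nl_ok <- has_no_runlength(words)
    if (any(!nl_ok) && is.null(viol)) {
      i <- which(!nl_ok)[1]
      ch <- strsplit(words[i], "")[[1]]
      pos <- which(ch[-1] == ch[-length(ch)])[1]  # 0-based left index
      viol <- sprintf("word %d (%s) violates no-runlength at position %d",
                      i, words[i], pos)
    }
    gc_counts <- round(gc_content(words) * nchar(words))
    if (any(gc_counts != w) && is.null(viol)) {
      i <- which(gc_counts != w)[1]
      viol <- sprintf("word %d (%s) has GC count %d, expected %d",
                      i, words[i], gc_counts[i], w)
    }
    if (anyDuplicated(words) && is.null(viol))
      viol <- sprintf("duplicate word: %s", words[duplicated(words)][1])
  }
  min_d <- n + 1L  # sentinel: no pairs
  if (m >= 2 && all(nchar(words) == n)) {
    dm <- hamming_matrix(words)
    min_d <- min(dm[upper.tri(dm)])
    if (min_d < d && is.null(viol)) {
      idx <- which(dm == min_d & upper.tri(dm), arr.ind = TRUE)[1, ]
      viol <- sprintf("pair (%s, %s) at Hamming distance %d < %d",
                      words[idx[1]], words[idx[2]], min_d, d)
    }
  }
  structure(list(pass = is.null(viol),
                 first_violation = if (is.null(viol)) NA_character_ else viol,
                 min_distance = as.integer(min_d),
                 gc_counts = gc_counts, nl_ok = nl_ok, n_words = m,
                 n = n, d = d, w = w),
            class = "dna_code_report")
}

#' @export
print.dna_code_report <- function(x, ...) {
  cat(sprintf("Code set report (n=%d, d=%d, w=%d): %s\n", x$n, x$d, x$w,
              if (x$pass) "PASS" else paste("FAIL -", x$first_violation)))
  cat(sprintf("  %d words, min pairwise distance %d\n", x$n_words,
              x$min_distance))
  invisible(x)
}

#' @rdname validate_code_set
#' @param report A `dna_code_report`.
#' @param path Optional file path for the JSON report.
#' @export
code_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "dna_code_report"))
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Code rate of a DNA storage code
#'
#' R = log4(M) / n: the information carried per nucleotide by a code of M
#' words of length n. A full code (M = 4^n) has rate 1.
#'
#' @param M Number of codewords (>= 1).
#' @param n Word length.
#' @return The code rate.
#' @examples
#' code_rate(199, 9)  # ~0.42
#' @export
code_rate <- function(M, n) {
  stopifnot(M >= 1, n >= 1)
  log(M, base = 4) / n
}

#' Read and write codeword sets
#'
#' Codeword sets are exchanged either as FASTA (one record per codeword,
#' ids `word_1`, `word_2`, ...; via the Biostrings package) or as plain
#' one-word-per-line text.
#'
#' @param words Character vector of DNA words (or a `dna_code_set`).
#' @param path File path.
#' @return The character vector of words (readers), or `path` invisibly
#'   (writers).
#' @export
write_code_fasta <- function(words, path) {
  if (inherits(words, "dna_code_set")) words <- words$words
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("the Biostrings package is required for FASTA input/output")
  ss <- Biostrings::DNAStringSet(words)
  names(ss) <- paste0("word_", seq_along(words))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_code_fasta
#' @export
read_code_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("the Biostrings package is required for FASTA input/output")
  as.character(Biostrings::readDNAStringSet(path))
}

#' @rdname write_code_fasta
#' @export
write_code_lines <- function(words, path) {
  if (inherits(words, "dna_code_set")) words <- words$words
  writeLines(words, path)
  invisible(path)
}

#' @rdname write_code_fasta
#' @export
read_code_lines <- function(path) {
  words <- trimws(readLines(path))
  words[nzchar(words)]
}
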