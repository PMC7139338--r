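test_that("the quaternary codec maps A-0, G-1, C-2, T-3 and inverts", {
  expect_equal(dna_to_digits("AGCT"), c(0L, 1L, 2L, 3L))
  expect_equal(digits_to_dna(c(0, 1, 2, 3)), "AGCT")
  expect_equal(digits_to_dna(integer(0)), "")
  expect_error(dna_to_digits("AGXN"), "invalid base")
  expect_error(digits_to_dna(c(0, 4)), "0..3")
  set.seed(1)
  for (i in 1:200) {
    word <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                  collapse = "")
    expect_identical(digits_to_dna(dna_to_digits(word)), word)
  }
  # matrix round trip
  m <- dna_to_digits(c("ACGT", "TTTT"))
  expect_equal(dim(m), c(2L, 4L))
  expect_equal(digits_to_dna(m), c("ACGT", "TTTT"))
})

test_that("no-runlength detection matches exhaustive enumeration", {
  expect_false(has_no_runlength("CTAACG"))
  expect_true(has_no_runlength("AGAGAG"))
  expect_equal(has_no_runlength(c("AA", "AC", "A", "")), c(FALSE, TRUE, TRUE,
                                                           TRUE))
  words4 <- oracle_all_words(4)
  ours <- has_no_runlength(words4)
  theirs <- vapply(words4, oracle_no_runlength, TRUE, USE.NAMES = FALSE)
  expect_identical(ours, theirs)
  expect_equal(sum(ours), 4 * 3^3)  # 108 no-runlength words of length 4
})

test_that("GC content is the G+C fraction", {
  expect_equal(gc_content("GTAC"), 0.5)
  expect_equal(gc_content("AAAA"), 0)
  expect_equal(gc_content("GCGC"), 1)
  expect_equal(gc_content(c("GAT", "g")), c(1 / 3, 1))
})

test_that("Hamming distance satisfies the metric axioms", {
  expect_equal(hamming_distance("AAAA", "TTTT"), 4)
  expect_equal(hamming_distance("ACGT", "ACGT"), 0)
  expect_error(hamming_distance("ACG", "AC"), "equal length")
  set.seed(2)
  words <- replicate(30, paste(sample(c("A", "C", "G", "T"), 6,
                                      replace = TRUE), collapse = ""))
  for (i in 1:100) {
    tri <- sample(words, 3)
    dxy <- hamming_distance(tri[1], tri[2])
    dyz <- hamming_distance(tri[2], tri[3])
    dxz <- hamming_distance(tri[1], tri[3])
    expect_equal(dxy, hamming_distance(tri[2], tri[1]))      # symmetry
    expect_equal(dxy == 0, tri[1] == tri[2])                 # identity
    expect_lte(dxz, dxy + dyz)                               # triangle
    expect_equal(dxy, oracle_hamming(tri[1], tri[2]))        # oracle
  }
  dm <- hamming_matrix(c("AGAG", "TCTC", "AGAT"))
  expect_equal(dm["AGAG", "TCTC"], 4L)
  expect_equal(dm["AGAG", "AGAT"], 1L)
  expect_true(all(diag(dm) == 0L))
})

test_that("code-set validation reports each constraint violation", {
  rep1 <- validate_code_set(c("AGAG", "TCTC"), n = 4, d = 4, w = 2)
  expect_true(rep1$pass)
  expect_equal(rep1$min_distance, 4L)

  rep2 <- validate_code_set(c("CTAACG", "AGAGAT"), n = 6, d = 2, w = 3)
  expect_false(rep2$pass)
  expect_match(rep2$first_violation, "no-runlength at position 3")

  # singleton set passes vacuously with the n + 1 distance sentinel
  rep3 <- validate_code_set("AGAG", n = 4, d = 4, w = 2)
  expect_true(rep3$pass)
  expect_equal(rep3$min_distance, 5L)

  # GC weight violation
  rep4 <- validate_code_set(c("ATAT"), n = 4, d = 2, w = 2)
  expect_false(rep4$pass)
  expect_match(rep4$first_violation, "GC count")

  # distance violation names the offending pair
  rep5 <- validate_code_set(c("AGCA", "AGCT"), n = 4, d = 2, w = 2)
  expect_false(rep5$pass)
  expect_match(rep5$first_violation, "distance 1 < 2")

  # constructor refuses invalid sets, accepts valid ones
  expect_error(dna_code_set(c("AGCA", "AGCT"), 4, 2, 2), "invalid code set")
  cs <- dna_code_set(c("AGAG", "TCTC"), 4, 4, 2)
  expect_s3_class(cs, "dna_code_set")
  expect_equal(cs$size, 2L)

  # JSON report round trip
  js <- jsonlite::fromJSON(code_report_json(rep1))
  expect_true(js$pass)
  expect_equal(js$min_distance, 4L)
})

test_that("code rate follows log4(M)/n", {
  expect_equal(round(code_rate(199, 9), 2), 0.42)
  expect_equal(code_rate(4^6, 6), 1)
  expect_equal(code_rate(1, 10), 0)
  expect_error(code_rate(0, 4))
})

test_that("codeword sets round-trip through FASTA and plain text", {
  words <- c("AGAG", "TCTC", "AGTC")
  tf <- tempfile(fileext = ".fasta")
  write_code_fasta(words, tf)
  expect_equal(unname(read_code_fasta(tf)), words)
  expect_match(readLines(tf)[1], "^>word_1$")
  tl <- tempfile(fileext = ".txt")
  write_code_lines(dna_code_set(words, 4, 1, 2), tl)
  expect_equal(read_code_lines(tl), words)
  unlink(c(tf, tl))
})
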