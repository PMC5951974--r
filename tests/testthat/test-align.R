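test_that("an exact substring yields one full-length 100% hit", {
  set.seed(1)
  s <- hostdrift:::random_dna(5000, 0.45)
  q <- substr(s, 2001, 3000)
  h <- local_align(c(q = q), c(s = s))
  expect_equal(nrow(h), 1)
  expect_equal(h$identity, 100)
  expect_equal(h$length, 1000)
  expect_equal(c(h$qstart, h$qend, h$sstart, h$send), c(1, 1000, 2001, 3000))
  expect_equal(h$strand, "+")
})

test_that("sequences sharing no k-mer produce no hits", {
  q <- strrep("AC", 200)
  s <- strrep("GT", 200)  # revcomp of AC-repeat: minus-strand self-similarity
  h <- local_align(c(q = strrep("A", 300)), c(s = strrep("C", 300)),
                   min_identity = 10, max_evalue = 100)
  expect_equal(nrow(h), 0)
})

test_that("empty or N-rich sequences are rejected", {
  expect_error(local_align(c(q = ""), c(s = "ACGTACGT")), "empty")
  expect_error(local_align(c(q = strrep("N", 200)), c(s = strrep("ACGT", 50))),
               "N fraction")
})

test_that("seeded 90%-identity pairs agree with the Smith-Waterman oracle", {
  set.seed(42)
  for (rep in 1:5) {
    s <- hostdrift:::random_dna(1500, 0.45)
    q <- hostdrift:::mutate_bases(substr(s, 201, 1200), 100)  # 90% identity
    h <- local_align(c(q = q), c(s = s), min_identity = 70, max_evalue = 1)
    expect_gte(nrow(h), 1)
    o <- sw_oracle(q, s)
    expect_lt(abs(h$identity[1] - o$identity), 1.0)
    expect_lt(abs(h$score[1] - o$score) / o$score, 0.05)
  }
})

test_that("oracle equivalence holds across divergence levels on short pairs", {
  set.seed(7)
  for (n_sub in c(10, 50, 120)) {
    s <- hostdrift:::random_dna(2000, 0.5)
    q <- hostdrift:::mutate_bases(substr(s, 101, 1900), n_sub)
    h <- local_align(c(q = q), c(s = s), min_identity = 50, max_evalue = 1)
    o <- sw_oracle(q, s)
    expect_gte(nrow(h), 1)
    expect_lt(abs(h$score[1] - o$score) / o$score, 0.05)
  }
})

test_that("strand symmetry: reverse-complementing the query flips strand labels only", {
  set.seed(5)
  s <- hostdrift:::random_dna(4000, 0.45)
  q <- hostdrift:::mutate_bases(substr(s, 1001, 2000), 30)
  h1 <- local_align(c(q = q), c(s = s), min_identity = 80)
  h2 <- local_align(c(q = revcomp(q)), c(s = s), min_identity = 80)
  expect_equal(nrow(h1), nrow(h2))
  key <- function(h) paste(h$sstart, h$send, sep = "-")
  expect_setequal(key(h1), key(h2))
  expect_setequal(paste(key(h1), h1$strand),
                  paste(key(h2), chartr("+-", "-+", h2$strand)))
})

test_that("minus-strand hits are reported on original query coordinates", {
  set.seed(9)
  s <- hostdrift:::random_dna(3000, 0.5)
  q <- revcomp(substr(s, 501, 1500))
  h <- local_align(c(q = q), c(s = s))
  expect_equal(h$strand, "-")
  expect_equal(c(h$qstart, h$qend), c(1, 1000))
  expect_equal(c(h$sstart, h$send), c(501, 1500))
})

test_that("outfmt-6 export round-trips through a standard TSV reader", {
  set.seed(2)
  s <- hostdrift:::random_dna(2000, 0.5)
  h <- local_align(c(q = substr(s, 101, 700)), c(s = s))
  f <- tempfile()
  write_hits(h, f)
  tab <- utils::read.delim(f, header = FALSE)
  expect_equal(ncol(tab), 12)
  expect_equal(tab$V4, h$length)
  expect_equal(tab$V7, h$qstart)
})
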