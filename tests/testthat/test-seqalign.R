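lin <- scoring_scheme("nucleotide", match = 1, mismatch = -1,
                      gap_open = 0, gap_extend = -2)

test_that("global alignment reproduces hand-checked scores and identities", {
  a <- align_global("ACGT", "ACGT", lin)
  expect_equal(a$raw_score, 4)
  expect_equal(a$identity, 100)
  expect_equal(a$query_coverage, 1)

  b <- align_global("ACGT", "ACGA", lin)
  expect_equal(b$raw_score, 2)
  expect_equal(b$identity, 75)

  # one gap: 3 matches - 2 = 1 (enumeration-checked optimum)
  c <- align_global("ACGT", "AGT", lin)
  expect_equal(c$raw_score, 1)
})

test_that("local alignment handles identity and no-similarity extremes", {
  s <- scoring_scheme("nucleotide", match = 1, mismatch = -1,
                      gap_open = -2, gap_extend = -1)
  a <- align_local("ACGTACGT", "ACGTACGT", s)
  expect_equal(a$identity, 100)
  expect_equal(a$query_coverage, 1)

  b <- align_local("AAAA", "CCCC", s)
  expect_equal(b$raw_score, 0)
  expect_equal(unname(b$query_span), c(0, 0))
})

test_that("alignment scores match the independent DP oracle on random pairs", {
  s <- scoring_scheme("nucleotide", match = 1, mismatch = -1,
                      gap_open = -2, gap_extend = -1)
  set.seed(101)
  for (i in 1:100) {
    a <- random_dna_string(sample(1:8, 1))
    b <- random_dna_string(sample(1:8, 1))
    expect_equal(align_global(a, b, s)$raw_score,
                 oracle_score(a, b, "global", 1, -1, -2, -1))
    expect_equal(align_local(a, b, s)$raw_score,
                 oracle_score(a, b, "local", 1, -1, -2, -1))
  }
})

test_that("alignment score is symmetric in its arguments", {
  s <- scoring_scheme("nucleotide")
  set.seed(7)
  for (i in 1:20) {
    a <- random_dna_string(sample(3:12, 1))
    b <- random_dna_string(sample(3:12, 1))
    expect_equal(align_global(a, b, s)$raw_score,
                 align_global(b, a, s)$raw_score)
  }
})

test_that("alphabet mismatches are rejected", {
  expect_error(align_global("ACGT", "AC-T", lin), "alphabet")
  expect_error(align_global("", "ACGT", lin), "empty")
  expect_error(align_local("MKLV", "ACGT", scoring_scheme("protein")), NA)
})

test_that("E-value follows the Karlin-Altschul formula and its monotonicities", {
  sch <- scoring_scheme("protein") # K = 0.041, lambda = 0.267
  expect_equal(evalue(100, 1000, 1000, sch), 0.041 * 1e6 * exp(-26.7),
               tolerance = 1e-12)
  expect_equal(evalue(100, 1000, 1000, sch), 1.04e-7, tolerance = 0.01)
  # linear in n: doubling the database doubles E
  expect_equal(evalue(50, 200, 2000, sch), 2 * evalue(50, 200, 1000, sch))
  # monotone decreasing in S, vanishing at large S
  expect_true(evalue(60, 300, 300, sch) < evalue(50, 300, 300, sch))
  expect_lt(evalue(1e4, 300, 300, sch), 1e-300)
})

test_that("scoring scheme validates gap penalties and constants", {
  expect_error(scoring_scheme("nucleotide", gap_open = 5), "scores")
  expect_error(scoring_scheme("protein", karlin_K = -1), "karlin")
  sch <- scoring_scheme("nucleotide", match = 1, mismatch = -1,
                        gap_open = 0, gap_extend = -2)
  expect_equal(sch$karlin_lambda, log(3))
})

test_that("best_hits returns the verbatim self-hit and respects e_max", {
  prots <- stats::setNames(
    vapply(1:5, function(i) random_protein(80, seed = 300 + i), ""),
    paste0("p", 1:5))
  sch <- scoring_scheme("protein")
  h <- best_hits(prots["p2"], prots, sch, e_max = 1e-5)
  expect_equal(h$target, "p2")
  expect_equal(h$identity, 100)
  expect_equal(nrow(best_hits(prots["p2"], prots, sch, e_max = 0)), 0)
})

test_that("a planted diverged ortholog outranks shuffled decoys", {
  set.seed(11)
  q <- random_protein(150, seed = 401)
  ortho <- mutate_protein(q, 0.4, seed = 402) # ~60% identity
  decoys <- vapply(1:6, function(i)
    paste(sample(strsplit(q, "")[[1]]), collapse = ""), "")
  targets <- c(ortho = ortho, stats::setNames(decoys, paste0("d", 1:6)))
  h <- best_hits(c(q = q), targets, scoring_scheme("protein"))
  expect_equal(h$target, "ortho")
})

test_that("hit tables export in 12-column layout", {
  s <- scoring_scheme("nucleotide")
  al <- align_global("ACGTACGT", "ACGTACGA", s, "q1", "t1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(list(al), path)
  tab <- read.delim(path)
  expect_equal(ncol(tab), 12)
  expect_equal(tab$query, "q1")
})
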