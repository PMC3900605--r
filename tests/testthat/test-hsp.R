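test_that("identical sequences give a full-length top HSP", {
  s <- withr::with_seed(1, paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                                 collapse = ""))
  hits <- local_hsps(s, s)
  expect_equal(hits$raw_score[1], 300)
  expect_equal(hits$q_start[1], 1)
  expect_equal(hits$q_end[1], 300)
  expect_equal(hits$strand[1], "+")
  expect_lt(hits$e_value[1], 1e-50)
})

test_that("a reverse-complement match is found on the minus strand", {
  s <- withr::with_seed(2, paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                                 collapse = ""))
  hits <- local_hsps(s, revcomp(s))
  expect_equal(hits$strand[1], "-")
  expect_equal(hits$raw_score[1], 200)
  # coordinates are reported on the plus strand of the target
  expect_equal(hits$t_start[1], 1)
  expect_equal(hits$t_end[1], 200)
})

test_that("nucleotide engine equals the full-DP oracle on mutated pairs", {
  for (seed in 1:12) {
    withr::with_seed(seed, {
      len <- sample(200:500, 1)
      a <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
      b <- phagephylo:::mutate_seq(a, runif(1, 0.02, 0.15))
      if (seed %% 3 == 0) b <- revcomp(b)
      hits <- local_hsps(a, b, params = list(xdrop = 60, e_ceiling = 1e6))
      oracle <- oracle_best_ungapped_nt(a, b)
      expect_equal(max(hits$raw_score), oracle,
                   info = paste("seed", seed))
    })
  }
})

test_that("nucleotide engine equals the oracle on unrelated pairs", {
  for (seed in 21:26) {
    withr::with_seed(seed, {
      a <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
      hits <- local_hsps(a, b, params = list(xdrop = 60, e_ceiling = 1e6))
      oracle <- oracle_best_ungapped_nt(a, b)
      top <- if (nrow(hits)) max(hits$raw_score) else 0
      # the engine needs an exact 7-mer seed inside the optimal segment; a
      # chance optimum between unrelated sequences may lack one, so the engine
      # is a lower bound here (equality on homologous pairs is tested above)
      expect_lte(top, oracle)
      expect_gte(top, 7) # but some seeded hit always exists at 400 bp
    })
  }
})

test_that("translated mode finds a high-scoring self hit in any frame", {
  s <- withr::with_seed(3, phagephylo:::rand_coding_dna(300))
  hits <- local_hsps(s, s, mode = "translated")
  self <- hits[hits$q_frame == 1 & hits$t_frame == 1, ]
  expect_gte(nrow(self), 1)
  # a frame-1/frame-1 self alignment covers all 100 codons
  expect_equal(self$q_start[1], 1)
  expect_gte(max(hits$raw_score), 300) # BLOSUM62 diagonal is >= 4 on average
})

test_that("translated mode is strand-aware", {
  s <- withr::with_seed(4, phagephylo:::rand_coding_dna(300))
  hits <- local_hsps(s, revcomp(s), mode = "translated")
  expect_gte(nrow(hits), 1)
  best <- hits[1, ]
  expect_true(best$t_frame < 0) # best hit pairs frame +1 with a reverse frame
})

test_that("Karlin-Altschul statistics behave as documented", {
  s <- withr::with_seed(5, paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                                 collapse = ""))
  hits <- local_hsps(s, s, params = list(e_ceiling = 1e6))
  # E = K m n exp(-lambda S) on the log10 scale
  expect_equal(hits$log10_e,
               log10(0.46 * 400 * 400) - 1.28 * hits$raw_score / log(10),
               tolerance = 1e-10)
  # p = 1 - exp(-E), and bit score is an increasing transform of raw score
  expect_equal(hits$p_value, -expm1(-hits$e_value), tolerance = 1e-12)
  expect_false(is.unsorted(rev(hits$bit_score)))
})

test_that("the e-value ceiling filters hits", {
  withr::with_seed(6, {
    a <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  })
  loose <- local_hsps(a, b, params = list(e_ceiling = 1e6))
  strict <- local_hsps(a, b, params = list(e_ceiling = 1e-6))
  expect_gt(nrow(loose), nrow(strict))
  expect_true(all(strict$e_value <= 1e-6))
})

test_that("degenerate inputs are rejected", {
  expect_error(local_hsps("", "ACGT"), "non-empty")
  expect_error(local_hsps("ACGT", character(0)), "non-empty")
  expect_error(local_hsps("NNNNNNNNAC", "ACGTACGTACGT"), "ambiguity")
})
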