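true_cds_fixture <- function() {
  tibble::tibble(
    start = c(101, 601, 1501, 2401),
    end = c(400, 1200, 2100, 3000),
    strand = c("+", "-", "+", "-")
  )
}

test_that("perfect tools reproduce the truth exactly", {
  genome <- withr::with_seed(1, phagephylo:::rand_dna(3500))
  tracks <- simulate_predictor_tracks(genome, true_cds_fixture(), seed = 2)
  expect_named(tracks, paste0("tool_", 1:4))
  for (trk in tracks) {
    expect_equal(trk[, c("start", "end", "strand")],
                 dplyr::arrange(true_cds_fixture(), start))
  }
})

test_that("sensitivity controls how many true calls are kept", {
  genome <- withr::with_seed(3, phagephylo:::rand_dna(3500))
  n_kept <- replicate(100, {
    trk <- simulate_predictor_tracks(genome, true_cds_fixture(),
                                     sensitivities = 0.5)
    nrow(trk$tool_1)
  })
  expect_equal(mean(n_kept), 2, tolerance = 0.2)
})

test_that("start jitter moves only the 5' end, in frame", {
  genome <- withr::with_seed(4, phagephylo:::rand_dna(3500))
  truth <- true_cds_fixture()
  tracks <- simulate_predictor_tracks(genome, truth, start_jitter = 30,
                                      seed = 5)
  for (trk in tracks) {
    trk <- dplyr::arrange(trk, pmax(start, end))
    plus <- trk$strand == "+"
    # stop anchors are preserved: end on +, start on -
    expect_equal(trk$end[plus], truth$end[truth$strand == "+"])
    expect_equal(trk$start[!plus], truth$start[truth$strand == "-"])
    # 5' displacement is a multiple of 3 within the jitter bound
    d_plus <- trk$start[plus] - truth$start[truth$strand == "+"]
    d_minus <- trk$end[!plus] - truth$end[truth$strand == "-"]
    expect_true(all(c(d_plus, d_minus) %% 3 == 0))
    expect_true(all(abs(c(d_plus, d_minus)) <= 30))
  }
})

test_that("false positives appear at the configured rate", {
  genome <- withr::with_seed(6, phagephylo:::rand_dna(10000))
  tracks <- simulate_predictor_tracks(genome, true_cds_fixture()[0, ],
                                      sensitivities = rep(1, 20),
                                      fp_rate = 1, seed = 7)
  counts <- vapply(tracks, nrow, integer(1))
  expect_equal(mean(counts), 10, tolerance = 0.35) # ~10 per 10 kb at rate 1
  for (trk in tracks) {
    expect_true(all(trk$start >= 1 & trk$end <= 10000))
  }
})

test_that("consensus keeps candidates supported by enough tools", {
  trk <- list(
    tibble::tibble(start = c(1, 500), end = c(300, 800),
                   strand = c("+", "+")),
    tibble::tibble(start = 1, end = 300, strand = "+"),
    tibble::tibble(start = 1, end = 300, strand = "+")
  )
  cons <- consensus_cds(trk, min_support = 3)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$start, 1)
  expect_equal(cons$end, 300)
  expect_equal(cons$support, 3)
  # with a lower requirement the 2nd candidate still lacks support
  cons2 <- consensus_cds(trk, min_support = 2)
  expect_equal(nrow(cons2), 1)
})

test_that("consensus start is the majority vote, ties to the longest", {
  trk <- list(
    tibble::tibble(start = 10, end = 300, strand = "+"),
    tibble::tibble(start = 10, end = 300, strand = "+"),
    tibble::tibble(start = 40, end = 300, strand = "+")
  )
  expect_equal(consensus_cds(trk)$start, 10)
  tie <- list(
    tibble::tibble(start = 10, end = 300, strand = "+"),
    tibble::tibble(start = 40, end = 300, strand = "+"),
    tibble::tibble(start = c(10, 40), end = c(300, 300),
                   strand = c("+", "+"))
  )
  expect_equal(consensus_cds(tie)$start, 10) # 2:2 vote, longest CDS wins
})

test_that("minus-strand candidates anchor on their start coordinate", {
  trk <- list(
    tibble::tibble(start = 100, end = 400, strand = "-"),
    tibble::tibble(start = 100, end = 430, strand = "-"),
    tibble::tibble(start = 100, end = 400, strand = "-")
  )
  cons <- consensus_cds(trk)
  expect_equal(cons$stop_anchor, 100)
  expect_equal(cons$end, 400) # majority 5' end
  expect_equal(cons$strand, "-")
})

test_that("same stop anchor on opposite strands stays distinct", {
  trk <- list(
    tibble::tibble(start = c(100, 300), end = c(300, 500),
                   strand = c("+", "-")),
    tibble::tibble(start = c(100, 300), end = c(300, 500),
                   strand = c("+", "-")),
    tibble::tibble(start = c(100, 300), end = c(300, 500),
                   strand = c("+", "-"))
  )
  cons <- consensus_cds(trk)
  expect_equal(nrow(cons), 2)
})

test_that("jittered noisy tracks still yield the true stop anchors", {
  genome <- withr::with_seed(8, phagephylo:::rand_dna(3500))
  truth <- true_cds_fixture()
  tracks <- simulate_predictor_tracks(
    genome, truth, sensitivities = rep(0.95, 6), fp_rate = 0.2,
    start_jitter = 18, seed = 9
  )
  cons <- consensus_cds(tracks, min_support = 4)
  anchors <- ifelse(truth$strand == "+", truth$end, truth$start)
  expect_setequal(cons$stop_anchor, anchors)
})
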