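test_that("read depth accounting is exact", {
  asm <- simulate_collapsed_assembly(30000, 2000, 5000, 400, seed = 1)
  # every read contributes exactly read_length positions of depth
  expect_equal(sum(asm$coverage$depth), 5000 * 400)
  expect_equal(nrow(asm$coverage), 28000) # collapsed = genome - one repeat
  expect_equal(nchar(asm$sequence), 28000)
  expect_equal(asm$truth$ltr_start, 1L)
  expect_equal(asm$truth$ltr_end, 2000L)
})

test_that("the collapsed repeat shows the expected twofold depth", {
  asm <- simulate_collapsed_assembly(30000, 2000, 20000, 400, seed = 2)
  inside <- asm$coverage$depth[1:1600]      # clear of the boundary ramp
  outside <- asm$coverage$depth[2401:27600]
  expect_equal(mean(inside) / mean(outside), 2, tolerance = 0.05)
})

test_that("simulator input validation", {
  expect_error(simulate_collapsed_assembly(10000, 6000, 10, 100),
               "genome_length / 2")
  expect_error(simulate_collapsed_assembly(30000, 300, 10, 400),
               "read_length")
})

test_that("detection on a noiseless step profile is exact", {
  depth <- c(rep(20, 1000), rep(40, 3000), rep(20, 6000))
  call <- detect_elevated_segment(depth, smoothing_window = 201)
  expect_true(call$detected)
  expect_equal(call$start, 1001)
  expect_equal(call$end, 4000)
  expect_equal(call$length, 3000)
  expect_equal(call$coverage_ratio, 2)
  expect_equal(call$n_segments, 1)
})

test_that("a wrap-around elevated segment is handled circularly", {
  depth <- c(rep(40, 1500), rep(20, 7000), rep(40, 1500))
  call <- detect_elevated_segment(depth, smoothing_window = 201)
  expect_true(call$detected)
  expect_equal(call$start, 8501)
  expect_equal(call$end, 1500)
  expect_equal(call$length, 3000)
})

test_that("flat or fully elevated profiles yield no call", {
  flat <- detect_elevated_segment(rep(30, 5000), smoothing_window = 101)
  expect_false(flat$detected)
  expect_output(print(flat), "no elevated segment")
})

test_that("the longest of several segments wins and all are counted", {
  depth <- c(rep(20, 2000), rep(40, 500), rep(20, 2000), rep(40, 2000),
             rep(20, 3500))
  call <- detect_elevated_segment(depth, smoothing_window = 101)
  expect_equal(call$n_segments, 2)
  expect_equal(call$start, 4501)
  expect_equal(call$end, 6500)
})

test_that("detection recovers the repeat on simulated assemblies", {
  asm <- simulate_collapsed_assembly(100000, 3000, 30000, 300, seed = 3)
  call <- detect_elevated_segment(asm$coverage)
  expect_true(call$detected)
  expect_equal(call$n_segments, 1)
  # boundary bias is bounded by the read-length ramp
  expect_lt(abs(call$length - asm$truth$ltr_length),
            2 * asm$truth$read_length)
  expect_gt(call$coverage_ratio, 1.8)
})

test_that("short profiles are rejected", {
  expect_error(detect_elevated_segment(rep(10, 500)), "10 smoothing windows")
})

test_that("linearize rotates and accounts for both repeat copies", {
  seqchar <- withr::with_seed(4, phagephylo:::rand_dna(9000))
  depth <- c(rep(20, 2000), rep(40, 3000), rep(20, 4000))
  call <- detect_elevated_segment(depth, smoothing_window = 201)
  lin <- linearize(seqchar, call)
  expect_equal(lin$unique_length, 9000)
  expect_equal(lin$ltr_length, call$length)
  expect_equal(lin$total_length, 9000 + call$length)
  expect_equal(nchar(lin$sequence), 9000)
  # rotation puts the repeat start first
  expect_equal(substr(lin$sequence, 1, 10), substr(seqchar, call$start,
                                                   call$start + 9))
  no_call <- phagephylo:::ltr_call(detected = FALSE, L = 9000)
  expect_error(linearize(seqchar, no_call), "cannot linearize")
})

test_that("flank repeats are found near boundaries", {
  withr::with_seed(5, {
    left <- phagephylo:::rand_dna(1000)
    rep_unit <- strrep("ACGTT", 10) # 50 bp unit-5 tandem repeat
    mid <- phagephylo:::rand_dna(2000)
    right <- phagephylo:::rand_dna(5950)
    seqchar <- paste0(left, rep_unit, mid, right)
  })
  depth <- c(rep(20, 1000), rep(40, 2050), rep(20, 5950))
  call <- detect_elevated_segment(depth, smoothing_window = 201)
  call <- annotate_flank_repeats(call, seqchar, flank = 300)
  expect_s3_class(call$flank_repeats, "data.frame")
  hit <- dplyr::filter(call$flank_repeats, .data$unit_length == 5)
  expect_gte(nrow(hit), 1)
  # the planted 50-mer sits at 1001..1050; chance matches in the random
  # flanks may extend the maximal run by a few bases
  expect_lte(hit$start[1], 1001)
  expect_gte(hit$end[1], 1050)
  expect_lte(1050 - hit$end[1] + hit$start[1] - 1001, 10)
})
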