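test_that("NJ recovers an additive 4-taxon tree exactly", {
  # tree ((A:1,B:2):1,(C:3,D:1)); pairwise path lengths are additive
  d <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  # additivity round-trip: patristic distances reproduce the input matrix
  pm <- patristic_matrix(tr)
  expect_equal(pm[rownames(d), colnames(d)], d, tolerance = 1e-10)
  # topology: AB | CD split
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1));")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
})

test_that("NJ on 3 taxa solves the three-point formulas", {
  d <- matrix(c(0, 5, 7,
                5, 0, 8,
                7, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  # a = (dAB + dAC - dBC)/2 = 2, b = 3, c = 5
  pm <- patristic_matrix(tr)
  expect_equal(pm["A", "B"], 5)
  expect_equal(pm["A", "C"], 7)
  expect_equal(pm["B", "C"], 8)
  lens <- stats::setNames(tr$edge.length,
                          tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(lens[c("A", "B", "C")]), c(2, 3, 5))
})

test_that("patristic distances of a random tree are recovered after NJ", {
  tr <- random_pda_tree(paste0("t", 1:9), seed = 1)
  tr$edge.length <- withr::with_seed(2, stats::runif(nrow(tr$edge), 0.5, 3))
  pm <- patristic_matrix(tr)
  tr2 <- nj_tree(pm)
  expect_equal(patristic_matrix(tr2)[rownames(pm), colnames(pm)], pm,
               tolerance = 1e-8)
})

test_that("negative NJ branches are clamped without breaking the tree", {
  # non-additive noisy matrix that drives NJ to negative branch estimates
  d <- matrix(c(0, 1, 10, 10.2,
                1, 0, 10.1, 10,
                10, 10.1, 0, 0.1,
                10.2, 10, 0.1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("nj_tree rejects malformed matrices", {
  m <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(m))
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(nj_tree(bad))
  m3 <- matrix(c(0, 1, NaN, 1, 0, 1, NaN, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(m3), "finite")
  asym <- matrix(c(0, 1, 2, 0, 0, 1, 2, 1, 0), 3, 3,
                 dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(asym), "symmetric")
})

test_that("trees round-trip through Newick", {
  tr <- random_pda_tree(paste0("g", 1:7), seed = 3)
  tr$edge.length <- withr::with_seed(4, round(stats::runif(nrow(tr$edge),
                                                           0.1, 2), 4))
  nwk <- ape::write.tree(tr)
  back <- ape::read.tree(text = nwk)
  expect_equal(ape::dist.topo(tr, back), 0, ignore_attr = TRUE)
  expect_equal(sort(patristic_matrix(back)[tr$tip.label, tr$tip.label]),
               sort(patristic_matrix(tr)), tolerance = 1e-6)
})

test_that("group separation follows the between > max-within rule", {
  labs <- c("a1", "a2", "b1", "b2")
  d <- matrix(c(0, 2, 9, 8,
                2, 0, 9.5, 8.5,
                9, 9.5, 0, 3,
                8, 8.5, 3, 0), 4, 4, dimnames = list(labs, labs))
  groups <- tibble::tibble(genome = labs,
                           group = c("A", "A", "B", "B"))
  sep <- group_separation(d, groups)
  expect_true(sep$all_separated)
  expect_equal(sep$pairs$between_mean, mean(c(9, 8, 9.5, 8.5)))
  expect_equal(sep$pairs$within_max_a, 2)
  expect_equal(sep$pairs$within_max_b, 3)

  # pull one between-distance inside the within range: no longer separated
  d2 <- d
  d2["a1", "b1"] <- d2["b1", "a1"] <- 2.5
  sep2 <- group_separation(d2, groups)
  expect_false(sep2$all_separated)
})

test_that("singleton groups separate on the other group's within max", {
  labs <- c("a1", "a2", "out")
  d <- matrix(c(0, 2, 9,
                2, 0, 9,
                9, 9, 0), 3, 3, dimnames = list(labs, labs))
  groups <- tibble::tibble(genome = labs, group = c("A", "A", "solo"))
  sep <- group_separation(d, groups)
  expect_true(sep$all_separated)
  expect_true(is.na(sep$within$within_max[sep$within$group == "solo"]))
})

test_that("group separation warns about unknown taxa", {
  labs <- c("x", "y", "z")
  d <- matrix(c(0, 1, 2, 1, 0, 2, 2, 2, 0), 3, 3,
              dimnames = list(labs, labs))
  groups <- tibble::tibble(genome = c(labs, "ghost"),
                           group = c("A", "A", "B", "B"))
  expect_warning(sep <- group_separation(d, groups), "ghost")
  expect_equal(nrow(sep$pairs), 1)
})

test_that("random PDA trees are unrooted binary with the requested labels", {
  for (seed in 1:5) {
    tr <- random_pda_tree(paste0("n", 1:11), seed = seed)
    expect_true(ape::is.binary(tr))
    expect_false(ape::is.rooted(tr))
    expect_setequal(tr$tip.label, paste0("n", 1:11))
  }
  t1 <- random_pda_tree(letters[1:9], seed = 6)
  t2 <- random_pda_tree(letters[1:9], seed = 6)
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
})
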