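test_that("the attraction graph connects relatives and isolates strangers", {
  com <- test_community()
  g <- build_attraction_graph(com)
  expect_s3_class(g, "attraction_graph")
  expect_setequal(g$nodes, names(com$genomes))
  edge_key <- paste(pmin(g$edges$from, g$edges$to),
                    pmax(g$edges$from, g$edges$to))
  # all within-group pairs present
  for (grp in c("G1", "G2")) {
    members <- grep(grp, g$nodes, value = TRUE)
    pairs <- utils::combn(sort(members), 2)
    expect_true(all(paste(pairs[1, ], pairs[2, ]) %in% edge_key),
                info = grp)
  }
  # the outgroup is isolated
  expect_false(any(g$edges$from == "OUT" | g$edges$to == "OUT"))
})

test_that("attraction weights follow -log10(p)/200 capped at 1", {
  com <- test_community()
  g <- build_attraction_graph(com)
  expect_true(all(g$edges$attraction > 0 & g$edges$attraction <= 1))
  expect_equal(g$edges$attraction,
               pmin(1, -g$edges$log10_p / 200))
  expect_true(all(g$edges$log10_p >= -200)) # p floored at 1e-200
})

test_that("identical genomes reach the attraction cap", {
  s <- withr::with_seed(1, phagephylo:::rand_dna(2000))
  g <- build_attraction_graph(c(a = s, b = s,
                                c = withr::with_seed(2,
                                                     phagephylo:::rand_dna(2000))))
  ab <- g$edges[g$edges$from == "a" & g$edges$to == "b", ]
  expect_equal(ab$attraction, 1)
  expect_equal(ab$log10_p, -200)
})

test_that("a graph of unrelated genomes has no edges and warns", {
  gs <- withr::with_seed(3, c(a = phagephylo:::rand_dna(1500),
                              b = phagephylo:::rand_dna(1500),
                              c = phagephylo:::rand_dna(1500)))
  expect_warning(g <- build_attraction_graph(gs), "isolated")
  expect_equal(nrow(g$edges), 0)
  cl <- extract_clusters(g)
  expect_true(all(cl$singleton))
  expect_equal(length(unique(cl$cluster)), 3)
})

test_that("clusters are the connected components at the p cutoff", {
  com <- test_community()
  g <- build_attraction_graph(com)
  cl <- extract_clusters(g)
  expect_s3_class(cl, "group_assignment")
  # cluster labels match the ground-truth groups exactly (ARI = 1)
  truth <- com$groups$group[match(cl$node, com$groups$genome)]
  expect_equal(length(unique(paste(cl$cluster, truth))),
               length(unique(truth)))
  expect_true(cl$singleton[cl$node == "OUT"])
  expect_false(any(cl$singleton[cl$node != "OUT"]))
})

test_that("a strict p cutoff removes edges", {
  com <- test_community()
  g <- build_attraction_graph(com)
  cl_all <- extract_clusters(g, p_cutoff = 1)
  cl_none <- extract_clusters(g, p_cutoff = 1e-300)
  expect_true(all(cl_none$singleton))
  expect_lt(length(unique(cl_all$cluster)), length(unique(cl_none$cluster)))
})

test_that("the layout is deterministic given a seed", {
  com <- test_community()
  g <- build_attraction_graph(com)
  l1 <- layout_fr(g, iterations = 100, seed = 5)
  l2 <- layout_fr(g, iterations = 100, seed = 5)
  expect_identical(l1$x, l2$x)
  expect_identical(l1$y, l2$y)
  l3 <- layout_fr(g, iterations = 100, seed = 6)
  expect_false(identical(l1$x, l3$x))
})

test_that("the layout pulls connected groups together", {
  com <- test_community()
  g <- build_attraction_graph(com)
  lay <- layout_fr(g, iterations = 2000, seed = 7)
  pos <- as.matrix(lay[, c("x", "y")])
  rownames(pos) <- lay$node
  d <- as.matrix(stats::dist(pos))
  grp <- com$groups$group[match(lay$node, com$groups$genome)]
  same <- outer(grp, grp, "==") & upper.tri(d)
  diff <- outer(grp, grp, "!=") & upper.tri(d)
  expect_lt(mean(d[same]), mean(d[diff]))
})

test_that("3-D layouts and the energy trace are available", {
  com <- test_community()
  g <- build_attraction_graph(com)
  lay <- layout_fr(g, dims = 3, iterations = 50, seed = 8)
  expect_named(lay, c("node", "x", "y", "z"))
  expect_length(attr(lay, "energy"), 50)
  gl <- glance(lay)
  expect_equal(gl$iterations, 50)
  expect_true(is.finite(gl$energy_final))
})
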