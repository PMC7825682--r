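test_that("modularity matches hand-evaluated values", {
  net <- network_from_triangles()
  # two disjoint triangles split into the triangles: 2 * (3/6 - (6/12)^2)
  expect_identical(modularity_value(net, c(1, 1, 1, 2, 2, 2)), 0.5)
  expect_identical(modularity_value(net, rep(1, 6)), 0)
  # all-singletons is worse than the natural split
  expect_lt(modularity_value(net, 1:6), 0.5)
  empty <- cpapnet:::network_from_edges(c("a", "b"),
                                        data.frame(from = character(0),
                                                   to = character(0),
                                                   weight = numeric(0)))
  expect_warning(q <- modularity_value(empty, c(1, 2)), "no edges")
  expect_identical(q, 0)
})

test_that("single-cluster modularity is exactly zero on any graph", {
  set.seed(5)
  for (k in 1:10) {
    net <- random_small_network(sample(4:9, 1))
    if (nrow(net$edges) == 0) next
    n <- length(net$nodes)
    expect_identical(modularity_value(net, rep(1, n), weighted = TRUE), 0)
    expect_identical(modularity_value(net, rep(1, n), weighted = FALSE), 0)
  }
})

test_that("own modularity agrees with the igraph reference", {
  skip_if_not_installed("igraph")
  set.seed(17)
  for (k in 1:10) {
    net <- random_small_network(8)
    if (nrow(net$edges) == 0) next
    g <- as_igraph(net)
    mem <- sample(1:3, 8, replace = TRUE)
    expect_equal(modularity_value(net, mem, weighted = TRUE),
                 igraph::modularity(g, mem, weights = igraph::E(g)$weight))
    expect_equal(modularity_value(net, mem, weighted = FALSE),
                 igraph::modularity(g, mem))
  }
})

test_that("community detection finds the planted optimum on canonical graphs", {
  net <- network_from_triangles()
  part <- detect_communities(net)
  expect_equal(part$m, 2)
  expect_identical(part$modularity, 0.5)
  expect_equal(unname(part$membership[c("a", "b", "c")]), rep(1L, 3))
  expect_equal(unname(part$membership[c("d", "e", "f")]), rep(2L, 3))
  # complete graph: a single community
  pairs <- t(utils::combn(5, 2))
  k5 <- cpapnet:::network_from_edges(letters[1:5],
                                     data.frame(from = letters[pairs[, 1]],
                                                to = letters[pairs[, 2]],
                                                weight = 1))
  expect_equal(detect_communities(k5)$m, 1)
  expect_identical(detect_communities(k5)$modularity, 0)
})

test_that("detection dominates trivial partitions and tracks the oracle", {
  set.seed(23)
  for (k in 1:12) {
    net <- random_small_network(sample(5:8, 1))
    if (nrow(net$edges) == 0) next
    part <- detect_communities(net, seed = k)
    n <- length(net$nodes)
    expect_gte(part$modularity, modularity_value(net, rep(1, n)))
    expect_gte(part$modularity,
               suppressWarnings(modularity_value(net, seq_len(n))))
    oracle <- exhaustive_modularity_oracle(net)
    expect_gte(oracle$modularity + 1e-9, part$modularity)
    expect_lte(oracle$modularity - part$modularity, 0.02)
  }
})

test_that("the exhaustive oracle enumerates correctly", {
  # path of two nodes: best partition keeps the edge in one cluster
  p2 <- cpapnet:::network_from_edges(c("a", "b"),
                                     data.frame(from = "a", to = "b",
                                                weight = 1))
  o <- exhaustive_modularity_oracle(p2)
  expect_equal(o$m, 1)
  expect_identical(o$modularity, 0)
  o6 <- exhaustive_modularity_oracle(network_from_triangles())
  expect_identical(o6$modularity, 0.5)
  big <- random_small_network(11)
  expect_error(exhaustive_modularity_oracle(big), "10 nodes")
})

test_that("detection is invariant to node relabeling", {
  prof <- generate_clustered_cohort(separable_archetypes(),
                                    sizes = c(20L, 20L, 20L, 20L),
                                    flip_prob = 0.05, seed = 3)
  net <- build_network(prof)
  part <- detect_communities(net, seed = 5)
  set.seed(1)
  perm <- sample(nrow(prof))
  net_p <- build_network(prof[perm, ], threshold = 4)
  part_p <- detect_communities(net_p, seed = 5)
  expect_identical(
    adjusted_rand_index(part$membership[prof$id], part_p$membership[prof$id]),
    1)
})

test_that("own ARI matches the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(9)
  for (k in 1:5) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_identical(adjusted_rand_index(1:10, rep(1:5, 2) * 0 + 1:10), 1)
})

test_that("layout energy never increases and clusters separate", {
  prof <- generate_clustered_cohort(separable_archetypes()[1:2, ],
                                    sizes = c(12L, 12L), flip_prob = 0,
                                    seed = 4)
  net <- build_network(prof, threshold = 4)
  ly <- force_layout(net, iterations = 150, seed = 2)
  # monotone across coarse checkpoints
  checkpoints <- ly$energy[seq(15, 150, by = 15)]
  expect_true(all(diff(checkpoints) <= 1e-9))
  co <- ly$coordinates
  d <- as.matrix(dist(cbind(co$x, co$y)))
  same <- outer(prof$community, prof$community, "==")
  ut <- upper.tri(d)
  expect_lt(mean(d[ut & same]), mean(d[ut & !same]))
})

test_that("layout handles degenerate and symmetric graphs", {
  single <- cpapnet:::network_from_edges("a",
                                         data.frame(from = character(0),
                                                    to = character(0),
                                                    weight = numeric(0)))
  ly1 <- force_layout(single, iterations = 10, seed = 1)
  expect_equal(nrow(ly1$coordinates), 1)
  tri <- cpapnet:::network_from_edges(c("a", "b", "c"),
                                      data.frame(from = c("a", "a", "b"),
                                                 to = c("b", "c", "c"),
                                                 weight = 1))
  ly3 <- force_layout(tri, iterations = 400, seed = 3)
  d <- dist(cbind(ly3$coordinates$x, ly3$coordinates$y))
  expect_lt((max(d) - min(d)) / mean(d), 0.05)
})

test_that("layout-community agreement separates structure from noise", {
  prof <- generate_clustered_cohort(separable_archetypes(),
                                    sizes = c(15L, 15L, 15L, 15L),
                                    flip_prob = 0.05, seed = 6)
  net <- build_network(prof)
  part <- detect_communities(net, seed = 6)
  ly <- force_layout(net, iterations = 150, seed = 6)
  expect_lt(layout_community_agreement(ly, part), 1)
  # random coordinates and random partition: ratio near 1
  set.seed(8)
  fake_ly <- ly
  fake_ly$coordinates$x <- runif(60)
  fake_ly$coordinates$y <- runif(60)
  fake_part <- part
  fake_part$membership[] <- sample(1:4, 60, replace = TRUE)
  expect_lt(abs(layout_community_agreement(fake_ly, fake_part) - 1), 0.15)
  # single community is undefined
  one <- part
  one$membership[] <- 1L
  expect_error(layout_community_agreement(ly, one), "single community")
})
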