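test_that("centroids are member means and empty-Timer clusters drop", {
  d <- tibble::tibble(
    CCA1 = c(0, 2, 5, 1),
    CCA2 = c(0, 2, 5, 1),
    timer_angle = c(10, 20, 30, 40),
    timer_intensity = 1,
    timer_positive = c(TRUE, TRUE, TRUE, FALSE)
  )
  nodes <- suppressWarnings(cluster_centroids(d, c(1L, 1L, 2L, 3L)))
  expect_equal(nodes$CCA1[nodes$cluster == 1], 1) # mean of (0, 2)
  expect_equal(nodes$CCA2[nodes$cluster == 1], 1)
  expect_equal(nodes$mean_angle[nodes$cluster == 1], 15)
  # singleton cluster: centroid equals the cell's score
  expect_equal(nodes$CCA1[nodes$cluster == 2], 5)
  # cluster 3 has no Timer-positive members
  expect_warning(cluster_centroids(d, c(1L, 1L, 2L, 3L)), "3")
  expect_false(3 %in% nodes$cluster)
})

test_that("two nodes connect with one edge at their distance", {
  nodes <- tibble::tibble(cluster = 1:2, CCA1 = c(0, 5), CCA2 = 0,
                          mean_angle = c(10, 20), mean_intensity = 1,
                          n_cells = 5)
  net <- build_network(nodes)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$threshold, 5)
  expect_equal(net$threshold_percentile, 100)
})

test_that("three collinear nodes keep only sub-threshold edges", {
  nodes <- tibble::tibble(cluster = 1:3, CCA1 = c(0, 1, 3), CCA2 = 0,
                          mean_angle = c(10, 20, 30), mean_intensity = 1,
                          n_cells = 5)
  net <- build_network(nodes)
  # brute force over candidate thresholds confirms 2 is minimal connecting
  expect_equal(brute_force_connecting_threshold(nodes[c("CCA1", "CCA2")]), 2)
  expect_equal(net$threshold, 2)
  expect_equal(nrow(net$edges), 2)
  expect_equal(sort(net$edges$weight), c(1, 2))
  # the distance-3 pair is excluded
  expect_false(any(net$edges$from == 1 & net$edges$to == 3))
})

test_that("the connecting threshold equals MST bottleneck and brute force", {
  for (s in 1:50) {
    set.seed(400 + s)
    m <- sample(3:10, 1)
    nodes <- tibble::tibble(
      cluster = seq_len(m),
      CCA1 = runif(m, -3, 3), CCA2 = runif(m, -3, 3),
      mean_angle = runif(m, 0, 90), mean_intensity = 1, n_cells = 5
    )
    net <- build_network(nodes)
    bf <- brute_force_connecting_threshold(nodes[c("CCA1", "CCA2")])
    expect_equal(net$threshold, bf, tolerance = 1e-12)
    # MST edges are a subset of the network edges
    D <- as.matrix(dist(as.matrix(nodes[c("CCA1", "CCA2")])))
    g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                             weighted = TRUE)
    mst_w <- igraph::E(igraph::mst(g))$weight
    expect_equal(max(mst_w), net$threshold, tolerance = 1e-12)
    expect_gte(nrow(net$edges), m - 1)
    # the graph restricted to edges <= threshold is connected, and any
    # lower distinct distance disconnects it
    expect_true(all(net$edges$weight <= net$threshold))
    below <- max(c(-Inf, D[upper.tri(D)][D[upper.tri(D)] < bf]))
    if (is.finite(below)) {
      adj <- D <= below
      comp <- igraph::components(
        igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      )
      expect_gt(comp$no, 1)
    }
  }
})

test_that("tied distances at the threshold are all included", {
  # equilateral-ish square: four equal sides, two longer diagonals
  nodes <- tibble::tibble(cluster = 1:4,
                          CCA1 = c(0, 1, 1, 0), CCA2 = c(0, 0, 1, 1),
                          mean_angle = c(10, 20, 30, 40),
                          mean_intensity = 1, n_cells = 5)
  net <- build_network(nodes)
  expect_equal(net$threshold, 1)
  expect_equal(nrow(net$edges), 4) # all four unit sides, no diagonals
})

test_that("degenerate networks are handled explicitly", {
  one <- tibble::tibble(cluster = 1L, CCA1 = 0, CCA2 = 0, mean_angle = 5,
                        mean_intensity = 1, n_cells = 5)
  expect_warning(net <- build_network(one), "Single node")
  expect_equal(nrow(net$edges), 0)
  # coincident centroids produce zero-weight edges rather than failure
  two <- tibble::tibble(cluster = 1:2, CCA1 = 0, CCA2 = 0,
                        mean_angle = c(5, 10), mean_intensity = 1, n_cells = 5)
  net2 <- build_network(two)
  expect_equal(net2$edges$weight, 0)
})

test_that("grid mode reproduces a coarser but connected threshold", {
  set.seed(77)
  nodes <- tibble::tibble(cluster = 1:6, CCA1 = runif(6), CCA2 = runif(6),
                          mean_angle = runif(6, 0, 90), mean_intensity = 1,
                          n_cells = 5)
  exact <- build_network(nodes, mode = "exact")
  grid <- build_network(nodes, mode = "grid")
  expect_gte(grid$threshold, exact$threshold)
  expect_true(all(exact$edges$weight <= grid$threshold))
})
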