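test_that("threshold normalisation zeroes background and unit-scales signal", {
  panel <- tocky_panel(
    markers = c("A", "B"), timer_blue = "TB", timer_red = "TR",
    marker_thresholds = c(A = 100, B = 50), timer_thresholds = c(1, 1)
  )
  # span_quantile = 1 makes span = max - threshold exactly
  cells <- tibble::tibble(
    A = c(100, 50, 600),   # at threshold, below, threshold + span (500)
    B = c(50, 25, 150),
    TB = 0, TR = 0
  )
  norm <- threshold_normalize(cells, panel, span_quantile = 1)
  expect_equal(norm$A, c(0, 0, 1))
  expect_equal(norm$B, c(0, 0, 1))
  expect_true(all(as.matrix(norm[c("A", "B")]) >= 0))
  expect_equal(attr(norm, "spans"), c(A = 500, B = 100))

  # a marker constant at/below its threshold is flagged and dropped
  cells$B <- 10
  expect_warning(norm2 <- threshold_normalize(cells, panel, span_quantile = 1),
                 "B")
  expect_identical(attr(norm2, "markers"), "A")
  expect_false("B" %in% names(norm2))
})

test_that("PCA embedding is orthonormal and finds exact low rank", {
  set.seed(11)
  n <- 200
  basis <- qr.Q(qr(matrix(rnorm(25), 5, 5)))[, 1:2]
  X <- matrix(rnorm(n * 2), n, 2) %*% t(basis) # exactly rank 2 in 5 dims
  colnames(X) <- paste0("M", 1:5)
  d <- tibble::as_tibble(as.data.frame(X))
  emb <- pca_embed(d, markers = colnames(X))
  expect_equal(sum(emb$variance_fraction[1:2]), 1, tolerance = 1e-9)
  expect_equal(crossprod(emb$loadings), diag(5), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(emb$variance_fraction) <= 1e-12))

  # duplicating every cell leaves the informative loadings unchanged up to
  # sign (the null-space components are not identifiable)
  d2 <- dplyr::bind_rows(d, d)
  emb2 <- pca_embed(d2, markers = colnames(X))
  agree <- abs(colSums(emb$loadings[, 1:2] * emb2$loadings[, 1:2]))
  expect_equal(agree, rep(1, 2), tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(pca_embed(tibble::tibble(M = rep(1, 10)), markers = "M"),
               "zero variance")
})

test_that("k-means recovers planted blobs and is deterministic in the seed", {
  blob <- two_blob_cells()
  norm <- threshold_normalize(blob$cells, blob$panel)
  emb <- pca_embed(norm)
  cl <- kmeans_cluster(emb$scores, k = 2, seed = 5)
  # labels match the planted blobs up to permutation
  tab <- table(cl$labels, blob$truth)
  expect_equal(sum(apply(tab, 1, max)), length(blob$truth))

  cl2 <- kmeans_cluster(emb$scores, k = 2, seed = 5)
  expect_identical(cl$labels, cl2$labels)

  one <- kmeans_cluster(emb$scores, k = 1, seed = 5)
  expect_true(all(one$labels == 1L))
  expect_error(kmeans_cluster(emb$scores[1:3, ], k = 5, seed = 1),
               "between 1 and")
})

test_that("clustering does not depend on marker column order", {
  blob <- two_blob_cells()
  p1 <- blob$panel
  p2 <- tocky_panel(
    markers = rev(p1$markers),
    timer_blue = p1$timer_blue, timer_red = p1$timer_red,
    marker_thresholds = p1$marker_thresholds[rev(p1$markers)],
    timer_thresholds = p1$timer_thresholds
  )
  c1 <- precision_cluster(blob$cells, p1, k = 2, seed = 3)
  c2 <- precision_cluster(blob$cells, p2, k = 2, seed = 3)
  tab <- table(c1$labels, c2$labels)
  expect_equal(sum(tab > 0), 2) # identical partitions up to relabelling
})

test_that("cluster summaries report MFI, positivity and locus make-up", {
  panel <- tocky_panel(
    markers = c("A", "B"), timer_blue = "TB", timer_red = "TR",
    marker_thresholds = c(A = 100, B = 100), timer_thresholds = c(10, 10)
  )
  cells <- tibble::tibble(
    A = c(500, 500, 50, 150),
    B = c(200, 50, 60, 70),
    TB = c(100, 100, 0, 0), TR = c(0, 0, 0, 0),
    sample_id = c("s1", "s1", "s2", "s2")
  )
  cells <- timer_transform(cells, panel)
  labels <- c(1L, 1L, 2L, 2L)
  sm <- summarize_clusters(cells, labels, panel)
  a1 <- dplyr::filter(sm$marker_stats, cluster == 1, marker == "A")
  expect_equal(a1$mfi, 500)
  expect_equal(a1$pct_positive, 100)
  b1 <- dplyr::filter(sm$marker_stats, cluster == 1, marker == "B")
  expect_equal(b1$pct_positive, 50) # half above, half below threshold
  a2 <- dplyr::filter(sm$marker_stats, cluster == 2, marker == "A")
  expect_equal(a2$pct_positive, 50)
  expect_equal(sum(sm$counts$n_cells), nrow(cells))
  # locus composition counts only Timer-positive members
  lc <- dplyr::filter(sm$locus_composition, cluster == 1)
  expect_equal(sum(lc$n), 2)

  # an empty cluster yields NA rows and a warning
  expect_warning(sm3 <- summarize_clusters(cells, c(1L, 1L, 3L, 3L), panel),
                 "[Ee]mpty")
  empty <- dplyr::filter(sm3$marker_stats, cluster == 2)
  expect_true(all(is.na(empty$mfi)))
})

test_that("spike recovery metrics follow the confusion matrix exactly", {
  # all targets isolated in one pure cluster
  labels <- c(rep(1L, 50), rep(2L, 950))
  truth <- c(rep(TRUE, 50), rep(FALSE, 950))
  m <- evaluate_spike_recovery(labels, truth)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$accuracy, 1)

  # no cluster exceeds the enrichment cut: nothing predicted positive
  labels2 <- rep(1:10, each = 100)
  truth2 <- rep(c(TRUE, rep(FALSE, 9)), 100) # 10% targets everywhere
  m2 <- evaluate_spike_recovery(labels2, truth2)
  expect_equal(m2$sensitivity, 0)
  expect_equal(m2$specificity, 1)

  # TP=80, FP=20, FN=20, TN=880
  labels3 <- c(rep(1L, 100), rep(2L, 900))
  truth3 <- c(rep(TRUE, 80), rep(FALSE, 20), rep(TRUE, 20), rep(FALSE, 880))
  m3 <- evaluate_spike_recovery(labels3, truth3)
  expect_equal(m3$precision, 0.8)
  expect_equal(m3$sensitivity, 0.8)
  expect_equal(m3$accuracy, 0.96)
  expect_equal(m3$specificity, 880 / 900, tolerance = 1e-12)

  # enrichment cut is strictly greater-than
  labels4 <- rep(1L, 10)
  truth4 <- c(rep(TRUE, 2), rep(FALSE, 8)) # exactly 20%
  m4 <- evaluate_spike_recovery(labels4, truth4, enrich_fraction = 0.20)
  expect_equal(m4$n_enriched_clusters, 0)
})

test_that("percent-positive and MFI rank together for a genuine positive marker", {
  sim <- simulate_spikein_benchmark(n_cells = 4000, seed = 21)
  cl <- precision_cluster(sim$cells, sim$panel, k = 8, seed = 1)
  sm <- summarize_clusters(sim$cells, cl, sim$panel)
  m5 <- dplyr::filter(sm$marker_stats, marker == "M5")
  expect_gt(cor(m5$mfi, m5$pct_positive, method = "spearman",
                use = "complete.obs"), 0)
})
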