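test_that("locus percentages are taken against the parent population", {
  cells <- tibble::tibble(
    sample_id = rep("s1", 10),
    locus = factor(rep("Persistent", 10), levels = tocky_loci())
  )
  comp <- locus_composition(cells, c(s1 = 100))
  expect_equal(comp$percentage[comp$locus == "Persistent"], 10)
  expect_equal(sum(comp$percentage), 10)
  expect_equal(nrow(comp), 5)

  # trajectory equal to parent, uniform across loci
  cells2 <- tibble::tibble(
    sample_id = rep("s1", 25),
    locus = factor(rep(tocky_loci(), each = 5), levels = tocky_loci())
  )
  comp2 <- locus_composition(cells2, c(s1 = 25))
  expect_true(all(comp2$percentage == 20))

  # a sample with no trajectory cells scores 0 everywhere
  comp3 <- locus_composition(cells, c(s1 = 100, s2 = 40))
  expect_true(all(comp3$percentage[comp3$sample_id == "s2"] == 0))

  expect_warning(locus_composition(cells, c(s1 = 100, s3 = 0)), "s3")
  expect_error(locus_composition(cells, c(s1 = 5)), "Parent count smaller")
})

test_that("locus MFIs are plain means with NA for empty cells", {
  cells <- tibble::tibble(
    sample_id = c("s1", "s1", "s1"),
    locus = factor(c("New", "Persistent", "Persistent"),
                   levels = tocky_loci()),
    GITR = c(500, 100, 300)
  )
  prof <- locus_marker_profiles(cells, "GITR")
  expect_equal(prof$mfi[prof$locus == "New"], 500)
  expect_equal(prof$mfi[prof$locus == "Persistent"], 200)
  expect_true(is.na(prof$mfi[prof$locus == "Arrested"]))
  expect_equal(nrow(prof), 5)
})

test_that("the Mann-Whitney layer matches exact enumeration", {
  d <- tibble::tibble(
    locus = "Arrested",
    sample_id = paste0("s", 1:4),
    group = c("a", "a", "b", "b"),
    percentage = c(1, 2, 3, 4)
  )
  res <- compare_groups(d)
  # all mass of one group above the other: 2 of the 6 orderings as extreme
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(res$p_adjusted, res$p_value) # single test in the family
  expect_equal(res$method, "exact")
  # matches stats::wilcox.test's exact two-sided p
  expect_equal(res$p_value, wilcox.test(c(3, 4), c(1, 2))$p.value)

  # swapping group labels keeps p and negates the fold change
  d2 <- dplyr::mutate(d, group = ifelse(group == "a", "b", "a"))
  res2 <- compare_groups(d2)
  expect_equal(res2$p_value, res$p_value)
  expect_equal(res2$log2fc, -res$log2fc)

  # identical constant data carry no evidence
  d3 <- dplyr::mutate(d, percentage = 5)
  expect_equal(compare_groups(d3)$p_value, 1)

  expect_error(compare_groups(dplyr::mutate(d, group = "a")), "two groups")
  expect_error(compare_groups(d[-1, ]), "at least 2 samples")
})

test_that("BH adjustment agrees with an independent step-up reference", {
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(17)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    expect_lt(max(abs(p.adjust(p, "BH") - bh_oracle(p))), 1e-12)
  }
  # the family is adjusted jointly inside compare_groups
  d <- tibble::tibble(
    locus = rep(tocky_loci()[1:4], each = 4),
    sample_id = rep(paste0("s", 1:4), 4),
    group = rep(c("a", "a", "b", "b"), 4),
    percentage = rnorm(16)
  )
  res <- compare_groups(d)
  expect_equal(res$p_adjusted, p.adjust(res$p_value, "BH"))
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_true(all(res$p_adjusted <= 1))
})

test_that("cluster abundance statistics use percentages and pseudocounts", {
  # 2 clusters; experimental counts exactly double the control's
  cells <- tibble::tibble(
    sample_id = rep(c("c1", "c2", "k1", "k2"), times = c(30, 30, 30, 30)),
    group = rep(c("ctrl", "ctrl", "ko", "ko"), times = c(30, 30, 30, 30))
  )
  labels <- c(rep(c(1L, 2L), times = c(10, 20)),
              rep(c(1L, 2L), times = c(10, 20)),
              rep(c(1L, 2L), times = c(20, 10)),
              rep(c(1L, 2L), times = c(20, 10)))
  res <- cluster_abundance_stats(cells, labels, experimental = "ko",
                                 pseudocount = 0)
  r1 <- dplyr::filter(res, cluster == 1)
  expect_equal(r1$log2fc_counts, 1) # 20 vs 10 cells, epsilon cancels
  r2 <- dplyr::filter(res, cluster == 2)
  expect_equal(r2$log2fc_counts, -1)
  expect_equal(r1$mean_experimental, 100 * 20 / 30)

  # equal group means give a zero fold change
  res_eq <- cluster_abundance_stats(cells,
                                    rep(rep(c(1L, 2L), times = c(15, 15)), 4),
                                    experimental = "ko")
  expect_equal(res_eq$log2fc_counts, c(0, 0))

  # a cluster absent from the control group stays finite via the pseudocount
  labels_zero <- c(rep(1L, 60), rep(c(1L, 2L), times = c(20, 10)),
                   rep(c(1L, 2L), times = c(20, 10)))
  res_zero <- cluster_abundance_stats(cells, labels_zero,
                                      experimental = "ko")
  expect_true(is.finite(dplyr::filter(res_zero, cluster == 2)$log2fc_counts))
})

test_that("the planted late-locus accumulation is detected reliably", {
  n_rep <- 100
  sign_ok <- 0
  sig_ok <- 0
  for (r in seq_len(n_rep)) {
    sim <- simulate_cohort(n_control = 6, n_ko = 8, cells_per_sample = 400,
                           seed = 20000 + r)
    tc <- suppressWarnings(timer_transform(sim$cells, sim$panel))
    tp <- tc[tc$timer_positive, ]
    parent <- table(tp$sample_id)
    comp <- locus_composition(tp[c("sample_id", "group", "locus")],
                              stats::setNames(as.numeric(parent),
                                              names(parent)))
    res <- compare_groups(comp, experimental = "KO")
    arr <- dplyr::filter(res, locus == "Arrested")
    if (arr$log2fc > 0) sign_ok <- sign_ok + 1
    if (arr$p_adjusted < 0.05 && arr$log2fc > 0) sig_ok <- sig_ok + 1
  }
  expect_gte(sign_ok / n_rep, 0.95)
  expect_gte(sig_ok / n_rep, 0.95)
})

test_that("locus composition plots assemble without error", {
  comp <- tibble::tibble(
    locus = factor(rep(tocky_loci(), 2), levels = tocky_loci()),
    percentage = runif(10),
    group = rep(c("a", "b"), each = 5),
    sample_id = "s"
  )
  expect_s3_class(plot_locus_composition(comp), "ggplot")
})
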