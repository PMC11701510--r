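test_that("Timer standardisation follows the sample-sd convention", {
  d <- tibble::tibble(timer_angle = c(0, 90), timer_intensity = c(1, 3))
  # nrow >= 3 is required; pad with a midpoint to keep the check honest
  d3 <- tibble::tibble(timer_angle = c(0, 90, 45),
                       timer_intensity = c(1, 3, 2))
  Z <- standardize_timer(d3)
  expect_equal(apply(Z, 2, sd), c(Angle = 1, Intensity = 1))
  expect_equal(colMeans(Z), c(Angle = 0, Intensity = 0), tolerance = 1e-12)
  # hand value for the two-point column under sample sd:
  # (0, 90) centred is (-45, 45), sd = 63.64 -> +/- 0.7071
  expect_equal((c(0, 90) - 45) / sd(c(0, 90)),
               c(-1, 1) / sqrt(2), tolerance = 1e-12)

  Zl <- standardize_timer(d3, mode = "literal")
  expect_equal(apply(Zl, 2, sd), c(Angle = 1, Intensity = 1))
  expect_gt(mean(Zl[, "Angle"]), 0) # literal mode keeps the mean

  expect_error(
    standardize_timer(tibble::tibble(timer_angle = c(1, 1, 1),
                                     timer_intensity = 1:3)),
    "Constant"
  )
  expect_error(standardize_timer(d3[1:2, ]), "at least 3")
})

test_that("marker scaling centres, scales, and drops constant markers", {
  d <- tibble::tibble(A = c(1, 3), B = c(2, 4))
  S <- scale_markers(d, markers = c("A", "B"))
  expect_equal(S[, "A"], (c(1, 3) - 2) / sd(c(1, 3)), ignore_attr = TRUE)
  expect_equal(unname(S[, "A"]), c(-1, 1) / sqrt(2))
  # idempotence on already-standardised input
  d2 <- tibble::as_tibble(as.data.frame(S))
  expect_equal(scale_markers(d2, markers = c("A", "B")), S,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_warning(
    S3 <- scale_markers(tibble::tibble(A = c(1, 2, 3), B = 5),
                        markers = c("A", "B")),
    "B"
  )
  expect_identical(colnames(S3), "A")
  expect_error(scale_markers(tibble::tibble(A = c(1, 1)), markers = "A"),
               "constant")
})

test_that("the projection fixes its column space and kills its complement", {
  set.seed(30)
  n <- 40
  Z <- scale(cbind(rnorm(n), rnorm(n)))
  colnames(Z) <- c("Angle", "Intensity")
  # S inside span(Z)
  mix <- matrix(rnorm(8), 2, 4)
  S_in <- Z %*% mix
  colnames(S_in) <- paste0("M", 1:4)
  fit <- tocky_cca(S_in, Z)
  expect_lt(max(abs(fit$S_star - S_in)), 1e-9)
  expect_equal(fit$wa_scores, fit$lc_scores, tolerance = 1e-9)

  # S orthogonal to span(Z): residualise random columns against Z
  S_raw <- matrix(rnorm(n * 3), n, 3)
  S_orth <- apply(S_raw, 2, function(y) resid(lm(y ~ 0 + Z)))
  colnames(S_orth) <- paste0("M", 1:3)
  fit2 <- tocky_cca(S_orth, Z)
  expect_lt(max(fit2$singular_values), 1e-9)
})

test_that("S* equals independent least-squares fits on random instances", {
  for (s in 1:25) {
    set.seed(100 + s)
    n <- sample(6:50, 1)
    p <- sample(2:8, 1)
    Z <- cbind(rnorm(n), rnorm(n))
    colnames(Z) <- c("Angle", "Intensity")
    S <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("M", 1:p)))
    fit <- tocky_cca(S, Z)
    expect_lt(max(abs(fit$S_star - ols_fitted_oracle(S, Z))), 1e-9)
    # never more than two canonical axes
    sv_all <- svd(fit$S_star)$d
    if (length(sv_all) > 2) expect_lt(sv_all[3], 1e-8 * sv_all[1])
    # hat-matrix idempotence
    H <- Z %*% solve(crossprod(Z), t(Z))
    expect_lt(max(abs(H %*% H - H)), 1e-9)
    # score duality and orthonormal singular vectors
    expect_equal(fit$lc_scores,
                 fit$U %*% diag(fit$singular_values, nrow = 2),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(crossprod(fit$V), diag(2), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(sum(fit$axis_variance), 1, tolerance = 1e-12)
  }
})

test_that("row permutations permute cell scores and preserve the axes", {
  set.seed(9)
  n <- 30
  Z <- cbind(Angle = rnorm(n), Intensity = rnorm(n))
  S <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("M", 1:4)))
  fit <- tocky_cca(S, Z)
  perm <- sample(n)
  fit_p <- tocky_cca(S[perm, ], Z[perm, ])
  expect_equal(fit_p$singular_values, fit$singular_values, tolerance = 1e-9)
  expect_equal(abs(fit_p$V), abs(fit$V), tolerance = 1e-9)
  # with the sign convention the scores match exactly, row-permuted
  expect_equal(fit_p$wa_scores, fit$wa_scores[perm, ], tolerance = 1e-9)
  # sign convention: each marker-score column's largest entry is positive
  for (j in 1:2) expect_gt(fit$V[which.max(abs(fit$V[, j])), j], 0)
})

test_that("collinear Timer columns raise an actionable error", {
  n <- 10
  x <- rnorm(n)
  Z <- cbind(Angle = x, Intensity = x)
  S <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("M", 1:3)))
  expect_error(tocky_cca(S, Z), "ridge")
})

test_that("the data-frame interface restricts to Timer-positive cells", {
  sim <- simulate_cohort(n_control = 2, n_ko = 2, cells_per_sample = 200,
                         seed = 3)
  tc <- timer_transform(sim$cells, sim$panel)
  norm <- threshold_normalize(tc, sim$panel)
  fit <- tocky_cca(norm)
  expect_equal(nrow(fit$wa_scores), sum(tc$timer_positive))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1)
  expect_true(all(abs(fit$arrows) <= 1 + 1e-12))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
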