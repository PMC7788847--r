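test_that("spearman handles perfect monotone series and the hand example", {
  expect_equal(spearman(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(spearman(1:5, c(10, 8, 6, 4, 2))$rho, -1)
  s <- spearman(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(s$rho, 0.8)
  expect_equal(s$method, "exact permutation")
  # 4! = 24 permutations; |rho| >= 0.8 for 8 of them
  expect_equal(s$p, 8 / 24)

  big <- spearman(1:31, 1:31 + c(rep(0, 30), 0.5))
  expect_equal(big$method, "t-approximation")
  rho <- big$rho
  expect_equal(big$p, 2 * pt(-abs(rho * sqrt(29 / (1 - rho^2))), 29))

  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("spearman is invariant under strictly monotone transforms and order", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(12); y <- rnorm(12)
    r0 <- spearman(x, y)$rho
    expect_equal(spearman(exp(x), y)$rho, r0)
    expect_equal(spearman(x, y^3 + 2 * y)$rho, r0)
    ord <- sample(12)
    expect_equal(spearman(x[ord], y[ord])$rho, r0)
  }
})

test_that("Lin's CCC matches hand computations and penalizes shift", {
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 3, 4))$ccc, 4 / 7, tolerance = 1e-12)
  x <- c(1, 3, 5, 7)
  expect_equal(lin_ccc(x, x)$ccc, 1)
  expect_lt(lin_ccc(x, -x + 1)$ccc, 0)
  expect_error(lin_ccc(rep(2, 4), 1:4), "constant")

  cc <- lin_ccc(1:20 + rnorm(20, 0, 0.1), 1:20)
  expect_lte(cc$ci_low, cc$ccc)
  expect_gte(cc$ci_high, cc$ccc)
  expect_true(cc$ci_low >= -1 && cc$ci_high <= 1)
})

test_that("CCC is attenuated relative to Pearson over random series", {
  set.seed(8)
  for (i in 1:1000) {
    n <- sample(4:12, 1)
    x <- rnorm(n); y <- rnorm(n) + runif(1, -1, 1) * x
    if (sd(x) == 0 || sd(y) == 0) next
    cc <- lin_ccc(x, y)$ccc
    expect_lte(abs(cc), abs(cor(x, y)) + 1e-12)
  }
  # equality iff means and variances match
  x <- rnorm(50)
  y <- 2 + x                                     # mean shift only
  expect_lt(lin_ccc(x, y)$ccc, abs(cor(x, y)))
  z <- x[sample(50)]
  expect_equal(lin_ccc(x, x)$ccc, cor(x, x))
})

test_that("bootstrap CI is available and brackets the estimate", {
  set.seed(12)
  x <- runif(31, 0.5, 41.5); y <- x + rnorm(31, 0, 2)
  cb <- lin_ccc(x, y, ci = "bootstrap", boot_n = 500, boot_seed = 7)
  expect_lte(cb$ci_low, cb$ccc)
  expect_gte(cb$ci_high, cb$ccc)
  cb2 <- lin_ccc(x, y, ci = "bootstrap", boot_n = 500, boot_seed = 7)
  expect_identical(cb, cb2)
})

test_that("Bland-Altman bias and limits follow the definition", {
  z <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(z$bias, 0); expect_equal(z$loa_low, 0); expect_equal(z$loa_high, 0)

  h <- bland_altman(c(1, 2, 3), c(2, 4, 6))
  expect_equal(h$bias, -2, tolerance = 1e-12)
  expect_equal(h$sd_diff, 1, tolerance = 1e-12)
  expect_equal(h$loa_low, -3.96, tolerance = 1e-12)
  expect_equal(h$loa_high, -0.04, tolerance = 1e-12)

  # translation equivariance
  set.seed(3)
  x <- rnorm(15); y <- rnorm(15)
  b0 <- bland_altman(x, y)
  b1 <- bland_altman(x + 5, y)
  expect_equal(b1$bias, b0$bias + 5)
  expect_equal(b1$loa_low, b0$loa_low + 5)
  expect_equal(b1$loa_high, b0$loa_high + 5)

  # direction flips the sign and is recorded
  b2 <- bland_altman(x, y, direction = "y-x")
  expect_equal(b2$bias, -b0$bias)
  expect_equal(b2$direction, "y-x")
})

test_that("95% limits of agreement cover ~95% of normal differences", {
  set.seed(99)
  n <- 10000
  x <- rnorm(n, 10, 3); y <- x + rnorm(n, 0, 1)
  ba <- bland_altman(x, y)
  cover <- mean(ba$points$diff >= ba$loa_low & ba$points$diff <= ba$loa_high)
  expect_lt(abs(cover - 0.95), 0.01)
})

test_that("the assembled agreement analysis reports all three statistics", {
  set.seed(42)
  x <- runif(31, 0.5, 41.5)
  s <- paired_series(x, x + rnorm(31, 0, 2))
  d <- withr::local_tempdir()
  res <- validate_agreement(s, alpha = 0.05, plot_dir = d)
  expect_s3_class(res, "agreement_result")
  expect_true(res$significant)
  expect_gte(res$ccc, 0.9)
  expect_true(file.exists(file.path(d, "scatter.png")))
  expect_true(file.exists(file.path(d, "bland_altman.png")))
  pd <- read.csv(file.path(d, "plot_data.csv"))
  expect_equal(nrow(pd), 31)
  expect_equal(pd$diff, s$x - s$y)

  # statistics are invariant to pair ordering
  ord <- sample(31)
  res2 <- validate_agreement(paired_series(s$x[ord], s$y[ord]))
  expect_equal(res2$spearman_rho, res$spearman_rho)
  expect_equal(res2$ccc, res$ccc)
  expect_equal(res2$bias, res$bias)

  expect_error(paired_series(1:2, 1:2), "at least 3")
  expect_error(validate_agreement(paired_series(rep(1, 5), 1:5)), "constant")

  f <- file.path(d, "pairs.csv")
  write.csv(data.frame(label = s$labels, method_a_mm2 = s$x,
                       method_b_mm2 = s$y), f, row.names = FALSE)
  rt <- read_paired_series(f)
  expect_equal(rt$x, s$x); expect_equal(rt$y, s$y)
})
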