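test_that("IVW equals the weighted-least-squares-through-origin oracle", {
  # spec-style closed-form case: equal wald weights, ratios 0.5/0.6/0.4
  h <- make_harmonized(ratios = c(0.5, 0.6, 0.4), wald_se = rep(0.1, 3),
                       b_x = c(0.10, 0.20, 0.10))
  est <- ivw(h)
  expect_equal(est$beta, 0.5, tolerance = 1e-12)
  expect_equal(attr(est, "Q"), 2, tolerance = 1e-12)
  expect_equal(est$se, sqrt(1 / 300), tolerance = 1e-12)  # Q/(k-1) = 1
  # independent WLS oracle on random inputs
  set.seed(21)
  for (i in 1:20) {
    k <- sample(3:30, 1)
    h <- make_harmonized(rnorm(k), runif(k, 0.05, 0.5),
                         b_x = runif(k, 0.05, 0.3))
    wls <- unname(coef(lm(b_y ~ 0 + b_x, data = h,
                          weights = 1 / h$se_y^2)))
    expect_equal(ivw(h)$beta, wls, tolerance = 1e-10)
  }
})

test_that("homogeneous ratios give Q = 0 and fixed-effect scaling", {
  h <- make_harmonized(rep(0.5, 4), rep(0.1, 4))
  est <- ivw(h)
  expect_equal(est$beta, 0.5)
  expect_equal(attr(est, "Q"), 0)
  expect_equal(est$se, sqrt(1 / sum(h$weight)))
  expect_error(ivw(h[1, ]), "insufficient instruments")
})

test_that("Egger on perfectly proportional data matches IVW with zero intercept", {
  h <- make_harmonized(rep(0.3, 5), rep(0.1, 5), b_x = seq(0.1, 0.5, 0.1))
  e <- egger(h)
  expect_equal(e$intercept$beta, 0, tolerance = 1e-10)
  expect_equal(e$slope$beta, 0.3, tolerance = 1e-10)
  expect_error(egger(h[1:2, ]), "insufficient instruments")
})

test_that("Egger recovers a planted directional intercept", {
  # strong instruments, direct effect 0.1 on all SNPs: slope theta, intercept 0.1
  set.seed(31)
  intercepts <- vapply(1:40, function(i) {
    k <- 300
    b_x <- runif(k, 0.05, 0.3)
    se_y <- rep(0.02, k)
    b_y <- 0.2 * b_x + 0.1 + rnorm(k, 0, se_y)
    h <- make_harmonized(b_y / b_x, se_y / b_x, b_x = b_x)
    egger(h)$intercept$beta
  }, 0)
  expect_equal(mean(intercepts), 0.1, tolerance = 0.005)
})

test_that("weighted median interpolates the cumulative weight at 0.5", {
  h3 <- make_harmonized(c(0.1, 0.2, 0.9), c(0.1, 0.1, 0.1))
  expect_equal(weighted_median(h3, n_boot = 0)$beta, 0.2)
  # hand-enumerated interpolation oracle: ratios 1..4, weights .1/.2/.3/.4
  # cumulative midpoints .05/.20/.45/.80 -> 3 + (.5-.45)/(.8-.45) = 22/7
  h4 <- make_harmonized(c(1, 2, 3, 4), 1 / sqrt(c(0.1, 0.2, 0.3, 0.4)))
  expect_equal(weighted_median(h4, n_boot = 0)$beta, 22 / 7,
               tolerance = 1e-12)
  expect_equal(wmedian_oracle(h4$wald_ratio, h4$weight), 22 / 7,
               tolerance = 1e-12)
  expect_error(weighted_median(h3[1:2, ], n_boot = 0), "insufficient")
})

test_that("majority weight on the true ratio pins the weighted median", {
  # 60% of total weight at ratio exactly 0.25
  h <- make_harmonized(c(0.25, 0.25, 0.25, 0.8, -0.5),
                       rep(1 / sqrt(2), 5))
  expect_equal(weighted_median(h, n_boot = 0)$beta, 0.25)
  set.seed(41)
  for (i in 1:20) {
    k <- sample(5:25, 1)
    h <- make_harmonized(rnorm(k), runif(k, 0.05, 0.5))
    est <- weighted_median(h, n_boot = 0)$beta
    expect_gte(est, min(h$wald_ratio))
    expect_lte(est, max(h$wald_ratio))
  }
})

test_that("bootstrap standard errors are seed-reproducible", {
  h <- make_harmonized(rnorm(20, 0.2, 0.1), runif(20, 0.05, 0.2))
  a <- weighted_median(h, n_boot = 200, seed = 9)
  b <- weighted_median(h, n_boot = 200, seed = 9)
  expect_identical(a$se, b$se)
  expect_gt(a$se, 0)
})

test_that("weighted mode finds the dominant ratio cluster", {
  h0 <- make_harmonized(rep(0.4, 5), rep(0.1, 5))
  expect_equal(weighted_mode(h0, n_boot = 0)$beta, 0.4, tolerance = 1e-6)
  set.seed(51)
  cluster <- c(rnorm(7, 0.2, 0.005), rnorm(3, 1.0, 0.005))
  h <- make_harmonized(cluster, rep(0.1, 10))
  est <- weighted_mode(h, n_boot = 0)
  expect_lt(abs(est$beta - 0.2), 0.05)
  # independent fine-grid KDE argmax oracle
  bw <- 0.9 * min(sd(cluster), mad(cluster)) * 10^(-1 / 5)
  grid <- seq(min(cluster) - 3 * bw, max(cluster) + 3 * bw, length.out = 8001)
  dens <- vapply(grid, function(g)
    sum(h$weight * dnorm((g - cluster) / bw)), 0)
  expect_lt(abs(est$beta - grid[which.max(dens)]), 0.01)
  expect_error(weighted_mode(h, bandwidth_factor = 0, n_boot = 0),
               "degenerate kernel")
})

test_that("Cochran's Q matches its chi-square reference under the null", {
  h <- make_harmonized(rep(0.3, 6), rep(0.1, 6))
  q <- cochran_q(h)
  expect_equal(q$Q, 0)
  expect_equal(q$pvalue, 1)
  set.seed(61)
  qs <- vapply(1:200, function(i) {
    k <- 20
    se <- runif(k, 0.05, 0.2)
    h <- make_harmonized(0.1 + rnorm(k, 0, se), se)
    cochran_q(h, beta_ref = NULL)$Q
  }, 0)
  # chi-square_{19} mean oracle: E[Q] approx 19 (beta estimated)
  expect_lt(abs(mean(qs) - 19), 3 * sd(qs) / sqrt(200))
})

test_that("a gross outlier dominates the Q decomposition", {
  # with beta re-estimated the outlier share tends to (k-1)/k
  k <- 100
  ratios <- c(rep(0.2, k - 1), 500)
  h <- make_harmonized(ratios, rep(0.1, k))
  beta <- ivw(h)$beta
  qj <- h$weight * (h$wald_ratio - beta)^2
  expect_gt(qj[k] / sum(qj), 0.95)
})

test_that("i_squared follows its algebraic definition with a floor at 0", {
  expect_equal(i_squared(9, 10), 0)        # Q = k-1
  expect_equal(i_squared(18, 10), 0.5)     # Q = 2(k-1)
  expect_equal(i_squared(4, 10), 0)        # floored
  expect_equal(i_squared(0, 10), 0)
  set.seed(71)
  for (q in runif(20, 0, 100)) {
    v <- i_squared(q, 15)
    expect_gte(v, 0); expect_lt(v, 1)
  }
})

test_that("instrument-strength I2_GX is high for heterogeneous strong instruments", {
  h <- make_harmonized(rep(0.2, 10), rep(0.1, 10),
                       b_x = seq(0.05, 0.5, length.out = 10),
                       se_x = rep(0.01, 10))
  expect_gt(i_squared_gx(h), 0.9)
})

test_that("mean F and the weak-instrument flag follow the F > 10 bar", {
  h1 <- make_harmonized(0.5, 0.1, b_x = 0.1, se_x = 0.02)
  expect_equal(mean_f(h1)$mean_f, 25)
  h2 <- make_harmonized(c(0.5, 0.5), c(0.1, 0.1), b_x = c(1, 1),
                        se_x = 1 / sqrt(c(10, 30)))
  expect_equal(mean_f(h2)$mean_f, 20)
  expect_false(mean_f(h2)$weak_instruments)
  h3 <- make_harmonized(0.5, 0.1, b_x = sqrt(9.9), se_x = 1)
  expect_true(mean_f(h3)$weak_instruments)
})
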