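test_that("weekly hours map category lower bounds multiplicatively", {
  expect_equal(weekly_hours("everyday", ">3 h"), 21)
  expect_equal(weekly_hours("2-3/wk", ">3 h"), 6)
  expect_equal(weekly_hours("none", ">3 h"), 0)
  expect_equal(weekly_hours("4-5/wk", "1.5-2 h"), 6)
  expect_equal(weekly_hours("everyday", "1-1.5 h"), 7)
  expect_error(weekly_hours("daily", ">3 h"), "unknown frequency")
  expect_error(weekly_hours("none", "4 h"), "unknown duration")
})

test_that("extreme-exercise classification uses strict thresholds", {
  q <- data.frame(
    strenuous_freq = c("everyday", "none", "2-3/wk", "none", "1/wk"),
    strenuous_duration = c("1-1.5 h", "<15 min", ">3 h", "<15 min", "1-1.5 h"),
    other_freq = c("none", "none", "none", "everyday", "2-3/wk"),
    other_duration = c("<15 min", "<15 min", "<15 min", ">3 h", "1-1.5 h"))
  labels <- classify_extreme(q)
  # 7 h strenuous -> extreme; zero both -> control; exactly 6 h -> neither;
  # 21 h other -> extreme; modest mixed -> neither
  expect_identical(labels, c("extreme", "sedentary_control", "neither",
                             "extreme", "neither"))
  expect_identical(classify_extreme(q), labels)  # pure function
})

test_that("LOF filter keeps only rare nonsense/splice-site variants", {
  v <- data.frame(variant_id = paste0("v", 1:4),
                  gene = "G1",
                  consequence = c("nonsense", "nonsense", "missense",
                                  "splice-site"),
                  maf = c(0.005, 0.02, 0.001, 0.009))
  out <- lof_filter(v, 0.01)
  expect_identical(out$variant_id, c("v1", "v4"))
})

test_that("gene carrier collapsing is an indicator invariant to row order", {
  m <- matrix(c(1, 1, 0,
                0, 1, 0,
                0, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("v", 1:3)))
  v <- data.frame(variant_id = c("v1", "v2", "v3"),
                  gene = c("G1", "G1", "G2"))
  cv <- gene_carrier_vector(m, v, "G1")
  expect_identical(as.integer(cv), c(1L, 1L, 0L))  # double carrier counts once
  cv2 <- gene_carrier_vector(m, v[3:1, ], "G1")
  expect_identical(cv2, cv)
  empty <- gene_carrier_vector(m, v, "G9")
  expect_identical(as.integer(empty), rep(0L, 3))
  expect_true(attr(empty, "no_qualifying"))
})

test_that("Firth fit matches the penalized-likelihood grid on separated data", {
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)   # complete separation
  X <- cbind(1, carrier = x)
  fit <- firth_logistic(y, X)
  expect_true(all(is.finite(fit$coefficients)))
  # 2-D coarse-to-fine grid over the written-out penalized likelihood
  pll <- function(b0, b1) {
    eta <- b0 + b1 * x
    p <- plogis(eta); w <- p * (1 - p)
    info <- crossprod(X, X * w)
    sum(y * eta - log1p(exp(eta))) + 0.5 * log(det(info))
  }
  g <- expand.grid(b0 = seq(-5, 5, 0.1), b1 = seq(-5, 8, 0.1))
  g$ll <- mapply(pll, g$b0, g$b1)
  top <- g[which.max(g$ll), ]
  g2 <- expand.grid(b0 = seq(top$b0 - 0.2, top$b0 + 0.2, 5e-4),
                    b1 = seq(top$b1 - 0.2, top$b1 + 0.2, 5e-4))
  g2$ll <- mapply(pll, g2$b0, g2$b1)
  top2 <- g2[which.max(g2$ll), ]
  expect_equal(unname(fit$coefficients[2]), top2$b1, tolerance = 1e-3)
  expect_equal(unname(fit$coefficients[1]), top2$b0, tolerance = 1e-3)
})

test_that("Firth estimates are null-centred and label-flip antisymmetric", {
  set.seed(101)
  x <- rbinom(400, 1, 0.1)
  y <- rbinom(400, 1, 0.5)           # carrier frequency identical by class
  X <- cbind(1, carrier = x)
  fit <- firth_logistic(y, X)
  expect_lt(abs(fit$coefficients["carrier"]), 0.5)
  flip <- firth_logistic(1 - y, X)
  expect_equal(unname(flip$coefficients), -unname(fit$coefficients),
               tolerance = 1e-7)
  expect_error(firth_logistic(y, cbind(1, x, x)), "rank-deficient")
  expect_error(firth_logistic(rep(1, 10), cbind(1, rbinom(10, 1, 0.5))),
               "both classes")
})

test_that("burden scan ranks a strong signal gene first with valid FDR", {
  g <- gen_genotypes(genotype_sim_config(
    n_cases = 800, n_controls = 800, n_genes = 40, carrier_freq = 0.02,
    signal_genes = data.frame(gene = 7L, or = 10), seed = 17))
  scan <- burden_scan(g$carriers, g$variants, g$phenotypes,
                      covariates = c("cov1", "cov2"))
  expect_s3_class(scan, "gene_burden")
  expect_identical(scan$gene[1], "GENE007")
  expect_true(scan$significant[1])
  expect_gt(scan$odds_ratio[1], 3)
  expect_true(all(scan$fdr >= scan$pvalue))
  expect_true(all(scan$carriers_cases <= scan$n_cases))
})

test_that("BH adjustment equals the definitional step-up", {
  p <- c(0.001, 0.01, 0.02, 0.9)
  expect_equal(bh_fdr(p), c(0.004, 0.02, 4 * 0.02 / 3, 0.9))
  expect_equal(bh_fdr(p), bh_stepup_oracle(p))
  same <- rep(0.03, 5)
  expect_equal(bh_fdr(same), same)
  set.seed(102)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, bh_stepup_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    # adjusted values are monotone in the sorted-p order
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("Fisher exact 2x2 follows the sample odds ratio and enumeration", {
  r <- fisher_exact_2x2(matrix(c(2, 1, 1, 2), 2))
  expect_equal(r$odds_ratio, 4)
  expect_false(r$continuity_corrected)
  r2 <- fisher_exact_2x2(matrix(c(1, 11, 9, 3), 2))
  expect_equal(r2$pvalue, fisher_enum_oracle(1, 9, 11, 3), tolerance = 1e-12)
  # identical row proportions -> p = 1
  r3 <- fisher_exact_2x2(matrix(c(4, 8, 2, 4), 2))
  expect_equal(r3$pvalue, 1)
  r0 <- fisher_exact_2x2(matrix(c(0, 5, 5, 5), 2))
  expect_equal(r0$odds_ratio, 0)
  expect_false(r0$continuity_corrected)
  rdiag <- fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))
  expect_true(rdiag$continuity_corrected)
  expect_true(is.finite(rdiag$odds_ratio))
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})

test_that("set overlap against the whole universe is never enriched", {
  u <- sprintf("g%03d", 1:50)
  res <- set_overlap_test(u[1:12], u, u)
  expect_equal(res$overlap, 12)
  expect_equal(res$pvalue, 1)
  expect_error(set_overlap_test(c("zz"), u[1:5], u), "not within")
})

test_that("overlap p-values are near-uniform under the null", {
  set.seed(103)
  u <- sprintf("g%04d", 1:2000)
  pv <- vapply(1:400, function(i) {
    set_overlap_test(sample(u, 200), sample(u, 200), u)$pvalue
  }, 0)
  expect_lt(suppressWarnings(ks.test(pv, "punif"))$statistic, 0.1)
})

test_that("enrichment scan isolates a planted annotation", {
  set.seed(104)
  u <- sprintf("g%04d", 1:1000)
  target <- sample(u, 80)
  planted <- c(sample(target, 30), sample(setdiff(u, target), 20))
  nulls <- lapply(1:20, function(i) sample(u, 50))
  names(nulls) <- paste0("null", 1:20)
  sets <- c(list(planted = planted), nulls)
  res <- enrichment_scan(target, sets, u)
  expect_identical(res$annotation[1], "planted")
  expect_lt(res$fdr[1], 0.001)
  one <- enrichment_scan(target, list(only = planted), u)
  expect_equal(one$fdr, one$pvalue)
  expect_error(enrichment_scan(target, list(bad = c("nope")), u),
               "not within")
})
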