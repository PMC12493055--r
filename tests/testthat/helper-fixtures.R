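# Fixtures and independent oracles shared across test files.
# Oracles are deliberately written from the definitions, not by calling the
# implementation paths they check.

# Build an mr_harmonized table directly from ratio-space quantities.
make_harmonized <- function(ratios, wald_se, b_x = rep(1, length(ratios)),
                            se_x = rep(1e-6, length(ratios)),
                            p_x = rep(1e-8, length(ratios)),
                            p_y = rep(0.5, length(ratios))) {
  k <- length(ratios)
  h <- data.frame(
    variant_id = sprintf("v%03d", seq_len(k)),
    b_x = b_x, se_x = se_x, p_x = p_x,
    b_y = ratios * b_x, se_y = wald_se * abs(b_x), p_y = p_y,
    eaf = rep(0.3, k), stringsAsFactors = FALSE
  )
  h$wald_ratio <- h$b_y / h$b_x
  h$wald_se <- h$se_y / abs(h$b_x)
  h$weight <- 1 / h$wald_se^2
  h$f_stat <- (h$b_x / h$se_x)^2
  class(h) <- c("mr_harmonized", "data.frame")
  h
}

# A minimal summary-statistics row set built by hand.
make_sumstats <- function(n = 5, pvalue = rep(1e-6, n)) {
  data.frame(
    variant_id = sprintf("rs%d", seq_len(n)),
    chrom = as.character(rep_len(1:2, n)),
    pos = as.integer(seq_len(n) * 1e6),
    effect_allele = rep_len(c("A", "C"), n),
    other_allele = rep_len(c("G", "T"), n),
    eaf = rep(0.3, n), beta = seq(0.02, by = 0.01, length.out = n),
    se = rep(0.005, n), pvalue = pvalue, n = 10000L,
    stringsAsFactors = FALSE
  )
}

# Explicit no-ties Cox partial log-likelihood (risk-set definition).
cox_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Two-stage grid maximizer of the explicit partial likelihood.
cox_grid_oracle <- function(time, event, x, lo = -6, hi = 6) {
  g1 <- seq(lo, hi, by = 0.01)
  l1 <- vapply(g1, cox_partial_loglik, 0, time = time, event = event, x = x)
  b1 <- g1[which.max(l1)]
  g2 <- seq(b1 - 0.02, b1 + 0.02, by = 1e-5)
  l2 <- vapply(g2, cox_partial_loglik, 0, time = time, event = event, x = x)
  g2[which.max(l2)]
}

# Definitional BH step-up: adjusted_(i) = min_{j >= i} p_(j) m / j, capped.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- vapply(seq_len(m), function(i) min(1, min(ps[i:m] * m / (i:m))), 0)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Two-sided Fisher p by full enumeration of tables with fixed margins,
# using the conventional relative tolerance on the point probability.
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  obs <- stats::dhyper(a, c1, n - c1, r1)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Weighted-median by direct cumulative-weight definition (independent of
# the package's implementation path).
wmedian_oracle <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]; w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  stats::approx(s, r, xout = 0.5, rule = 2)$y
}

# Small no-ties survival fixtures for the grid-oracle comparison.
cox_fixtures <- function() {
  list(
    list(time = c(1, 2, 3, 4), event = c(1, 1, 1, 0), x = c(1, 0, 1, 0)),
    list(time = c(2, 5, 1, 4, 3), event = c(1, 0, 1, 1, 1),
         x = c(0.5, 1.2, -0.3, 0.1, 0.9)),
    list(time = c(3, 1, 2), event = c(1, 1, 1), x = c(0.5, 1, 0)),
    list(time = c(1.5, 2.5, 0.5, 3.5, 4.5), event = c(0, 1, 1, 1, 0),
         x = c(2, 0, 1, 1, 0)),
    list(time = c(4, 2, 6, 1, 3), event = c(1, 1, 0, 1, 1),
         x = c(-1, 0.4, 0.2, 0.8, -0.5))
  )
}
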