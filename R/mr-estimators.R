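# The MR estimator battery: IVW, MR-Egger, weighted median, weighted mode,
# plus heterogeneity and instrument-strength statistics.

mr_estimate <- function(method, beta, se, pvalue, n_snps) {
  structure(list(method = method, beta = beta, se = se,
                 pvalue = pvalue, n_snps = n_snps),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g (se %.4g), p = %.3g, k = %d\n",
              x$method, x$beta, x$se, x$pvalue, x$n_snps))
  invisible(x)
}

assert_harmonized <- function(h, k_min, caller) {
  check_columns(h, c("wald_ratio", "wald_se", "weight"), "harmonized table")
  if (nrow(h) < k_min)
    stop(caller, ": insufficient instruments (need >= ", k_min,
         ", got ", nrow(h), ")")
  invisible(h)
}

#' Inverse-variance weighted estimate (multiplicative random effects)
#'
#' The IVW estimate is the inverse-variance weighted mean of the per-SNP
#' Wald ratios.  Its standard error is the fixed-effect value
#' `sqrt(1 / sum(w))` inflated by `max(1, sqrt(Q / (k - 1)))`
#' (multiplicative random effects): excess heterogeneity widens the
#' interval, under-dispersion never narrows it.  Two-sided normal p-value.
#'
#' @param harmonized An `mr_harmonized` data frame with >= 2 rows.
#' @return An `mr_estimate`; attributes `Q` and `q_pvalue` carry Cochran's
#'   heterogeneity statistic about the IVW estimate.
#' @export
ivw <- function(harmonized) {
  assert_harmonized(harmonized, 2L, "ivw")
  w <- harmonized$weight
  r <- harmonized$wald_ratio
  k <- length(r)
  beta <- sum(w * r) / sum(w)
  q <- sum(w * (r - beta)^2)
  se_fixed <- sqrt(1 / sum(w))
  se <- se_fixed * max(1, sqrt(q / (k - 1)))
  est <- mr_estimate("IVW", beta, se, 2 * pnorm(-abs(beta / se)), k)
  attr(est, "Q") <- q
  attr(est, "q_pvalue") <- pchisq(q, k - 1, lower.tail = FALSE)
  est
}

#' MR-Egger regression (slope and intercept)
#'
#' Weighted linear regression of outcome betas on exposure betas with an
#' intercept, weights `1 / se_y^2`, after orienting every instrument so the
#' exposure beta is non-negative (negating the outcome beta in tandem) --
#' the conventional treatment that makes the intercept identifiable.  A
#' non-zero intercept indicates directional horizontal pleiotropy.  Standard
#' errors carry the same multiplicative random-effects inflation
#' `max(1, sigma_hat)` as IVW (df `k - 2`); p-values use the t-distribution
#' with `k - 2` df.
#'
#' @param harmonized An `mr_harmonized` data frame with >= 3 rows.
#' @return A list with `slope` and `intercept`, both `mr_estimate`s.
#' @export
egger <- function(harmonized) {
  assert_harmonized(harmonized, 3L, "egger")
  check_columns(harmonized, c("b_x", "b_y", "se_y"), "harmonized table")
  flip <- sign(harmonized$b_x)
  flip[flip == 0] <- 1
  bx <- harmonized$b_x * flip
  by <- harmonized$b_y * flip
  w <- 1 / harmonized$se_y^2
  k <- length(bx)
  fit <- lm(by ~ bx, weights = w)
  sigma <- summary(fit)$sigma  # sqrt(weighted RSS / (k - 2))
  se_raw <- sqrt(diag(vcov(fit))) / sigma   # unscaled (X'WX)^{-1} diagonal
  se <- se_raw * max(1, sigma)
  est <- coef(fit)
  tval <- est / se
  p <- 2 * pt(-abs(tval), df = k - 2)
  list(
    slope = mr_estimate("Egger-slope", unname(est["bx"]),
                        unname(se["bx"]), unname(p["bx"]), k),
    intercept = mr_estimate("Egger-intercept", unname(est["(Intercept)"]),
                            unname(se["(Intercept)"]),
                            unname(p["(Intercept)"]), k)
  )
}

# Weighted median of ratios: cumulative-weight interpolation (weights
# normalized; the j-th sorted ratio sits at cumulative weight S_j - w_j/2).
weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(s)])
  i <- max(which(s < 0.5))
  r[i] + (r[i + 1] - r[i]) * (0.5 - s[i]) / (s[i + 1] - s[i])
}

boot_se <- function(harmonized, point_fun, n_boot, seed) {
  if (n_boot < 1) return(NA_real_)
  set.seed(seed)
  k <- nrow(harmonized)
  draws <- matrix(rnorm(k * n_boot, harmonized$wald_ratio,
                        harmonized$wald_se), k, n_boot)
  sd(apply(draws, 2, point_fun, weights = harmonized$weight))
}

#' Weighted-median MR estimate
#'
#' The ratio at cumulative normalized inverse-variance weight 0.5 (linear
#' interpolation between bracketing sorted ratios); consistent when valid
#' instruments carry a majority of the weight.  The standard error is a
#' parametric bootstrap: ratios resampled from
#' `Normal(ratio_j, wald_se_j)`, the median recomputed per draw.
#'
#' @param harmonized An `mr_harmonized` data frame with >= 3 rows.
#' @param n_boot Bootstrap replicates (default 1000; 0 skips the bootstrap
#'   and returns `NA` standard error and p-value).
#' @param seed Seed for the bootstrap stream.
#' @return An `mr_estimate`.
#' @export
weighted_median <- function(harmonized, n_boot = 1000, seed = 1L) {
  assert_harmonized(harmonized, 3L, "weighted_median")
  beta <- weighted_median_point(harmonized$wald_ratio, harmonized$weight)
  se <- boot_se(harmonized,
                function(r, weights) weighted_median_point(r, weights),
                n_boot, seed)
  p <- if (is.na(se)) NA_real_ else 2 * pnorm(-abs(beta / se))
  mr_estimate("weighted-median", beta, se, p, nrow(harmonized))
}

# Argmax of the weighted Gaussian kernel density over the ratios.
weighted_mode_point <- function(ratios, weights, bandwidth) {
  d <- density(ratios, weights = weights / sum(weights), bw = bandwidth,
               n = 1024)
  d$x[which.max(d$y)]
}

# Modified-Silverman scale used for the mode bandwidth.  Identical ratios
# have zero spread; a tiny positive scale keeps the kernel proper (the
# argmax is that shared ratio regardless).
mode_bandwidth <- function(ratios, bandwidth_factor) {
  s <- min(sd(ratios), mad(ratios))
  if (s == 0) s <- max(sd(ratios), mad(ratios))
  if (s == 0) s <- max(abs(mean(ratios)) * 1e-6, 1e-8)
  bandwidth_factor * 0.9 * s * length(ratios)^(-1 / 5)
}

#' Weighted-mode MR estimate
#'
#' The argmax of a weighted Gaussian kernel density over the Wald ratios;
#' consistent when the largest group of instruments sharing a causal
#' estimate is valid.  Bandwidth is `bandwidth_factor` times a
#' modified-Silverman scale, `0.9 min(sd, mad) k^(-1/5)`.  Standard error by
#' the same parametric bootstrap as [weighted_median()].
#'
#' @inheritParams weighted_median
#' @param bandwidth_factor Multiplier on the modified-Silverman bandwidth.
#' @return An `mr_estimate`.
#' @export
weighted_mode <- function(harmonized, bandwidth_factor = 1,
                          n_boot = 1000, seed = 1L) {
  assert_harmonized(harmonized, 3L, "weighted_mode")
  bw <- mode_bandwidth(harmonized$wald_ratio, bandwidth_factor)
  if (!is.finite(bw) || bw <= 0)
    stop("weighted_mode: degenerate kernel bandwidth (", format(bw), ")")
  beta <- weighted_mode_point(harmonized$wald_ratio, harmonized$weight, bw)
  se <- boot_se(harmonized, function(r, weights) {
    b <- mode_bandwidth(r, bandwidth_factor)
    if (!is.finite(b) || b <= 0) b <- bw
    weighted_mode_point(r, weights, b)
  }, n_boot, seed)
  p <- if (is.na(se)) NA_real_ else 2 * pnorm(-abs(beta / se))
  mr_estimate("weighted-mode", beta, se, p, nrow(harmonized))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j (ratio_j - beta_ref)^2)`, referred to a chi-square with
#' `k - 1` degrees of freedom.
#'
#' @param harmonized An `mr_harmonized` data frame with >= 2 rows.
#' @param beta_ref Reference estimate (defaults to the IVW estimate).
#' @return A list with `Q` and `pvalue`.
#' @export
cochran_q <- function(harmonized, beta_ref = NULL) {
  assert_harmonized(harmonized, 2L, "cochran_q")
  if (is.null(beta_ref)) beta_ref <- ivw(harmonized)$beta
  q <- sum(harmonized$weight * (harmonized$wald_ratio - beta_ref)^2)
  list(Q = q, pvalue = pchisq(q, nrow(harmonized) - 1, lower.tail = FALSE))
}

#' I-squared: proportional excess of Q over its degrees of freedom
#'
#' `max(0, (Q - (k - 1)) / Q)`; 0 when `Q = 0`.
#'
#' @param Q Cochran's Q (>= 0).
#' @param k Number of instruments (>= 2).
#' @return A value in `[0, 1)`.
#' @export
i_squared <- function(Q, k) {
  check_positive(Q, "Q", strict = FALSE)
  check_count(k, "k", min = 2L)
  if (Q == 0) return(0)
  max(0, (Q - (k - 1)) / Q)
}

#' Instrument-strength I-squared (exposure-side dispersion, "I2_GX")
#'
#' The same excess-dispersion statistic applied to the exposure
#' associations: `Q_GX = sum(((b_x - b_bar_w) / se_x)^2)` about the
#' inverse-variance weighted mean exposure beta.  Values near 1 indicate
#' instrument heterogeneity far above sampling noise (strong, diverse
#' instruments); low values flag regression-dilution bias toward the null
#' in Egger-type estimates.
#'
#' @param harmonized An `mr_harmonized` data frame with >= 2 rows.
#' @return A value in `[0, 1)`.
#' @export
i_squared_gx <- function(harmonized) {
  check_columns(harmonized, c("b_x", "se_x"), "harmonized table")
  if (nrow(harmonized) < 2) stop("i_squared_gx: need >= 2 instruments")
  w <- 1 / harmonized$se_x^2
  bbar <- weighted.mean(harmonized$b_x, w)
  q <- sum(w * (harmonized$b_x - bbar)^2)
  i_squared(q, nrow(harmonized))
}

#' Mean instrument F-statistic
#'
#' Arithmetic mean of the per-instrument `(b_x / se_x)^2`; a mean below the
#' conventional bar of 10 flags weak instruments (estimate bias above 10%).
#'
#' @param harmonized An `mr_harmonized` data frame.
#' @return A list with `mean_f` and logical `weak_instruments`
#'   (`mean_f <= 10`).
#' @export
mean_f <- function(harmonized) {
  check_columns(harmonized, "f_stat", "harmonized table")
  if (!nrow(harmonized)) stop_param("harmonized table is empty")
  m <- mean(harmonized$f_stat)
  list(mean_f = m, weak_instruments = m <= 10)
}
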