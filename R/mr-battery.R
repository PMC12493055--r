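# Orchestration of the full two-sample MR battery and its report object.

#' Configuration for the MR battery
#'
#' Defaults mirror the conventional analysis settings: instrument p-value
#' cutoff 5e-5, clumping r-squared 0.001 within a 10,000 kb window,
#' palindrome MAF bar 0.42, radial outlier alpha 0.05, 1000 bootstrap
#' replicates for the median/mode standard errors.
#'
#' @param p_threshold Instrument selection p-value cutoff.
#' @param clump_r2,clump_window_kb Clumping threshold and window.
#' @param palindrome_maf Palindromic-variant MAF exclusion bar.
#' @param radial_alpha Per-SNP radial outlier significance level.
#' @param bandwidth_factor Weighted-mode bandwidth multiplier.
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param seed Seed for the bootstrap streams.
#' @param ld Optional pairwise r-squared lookup passed to [greedy_clump()].
#' @return A list of class `mr_config`.
#' @export
mr_config <- function(p_threshold = 5e-5, clump_r2 = 0.001,
                      clump_window_kb = 10000, palindrome_maf = 0.42,
                      radial_alpha = 0.05, bandwidth_factor = 1,
                      n_boot = 1000, seed = 1L, ld = NULL) {
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb,
                 palindrome_maf = palindrome_maf,
                 radial_alpha = radial_alpha,
                 bandwidth_factor = bandwidth_factor,
                 n_boot = n_boot, seed = as.integer(seed), ld = ld),
            class = "mr_config")
}

#' Run the full two-sample MR battery
#'
#' Stage order: instrument selection, LD clumping, harmonization (with
#' palindrome exclusion), radial-MR outlier removal (before any other
#' statistical test), the outcome-vs-exposure p-value pleiotropy filter,
#' then the estimator battery (IVW, Egger slope/intercept, weighted median,
#' weighted mode) and sensitivity statistics (Cochran's Q, I-squared both
#' variants, mean F, leave-one-out).  Every removal is logged with its
#' reason.
#'
#' @param exposure,outcome Summary-statistic data frames.
#' @param config An [mr_config()].
#' @return An object of class `mr_report`: estimates plus `cochran_q`,
#'   `q_pvalue`, `i_squared`, `i_squared_gx`, `mean_f`, `weak_instruments`,
#'   `egger_intercept`, `egger_intercept_p`, `radial_outlier_ids`,
#'   `n_snps_initial`, `n_snps_final`, `loo_table`, `n_loo_p_gt_05`,
#'   `removals`, `log`.
#' @export
run_mr_battery <- function(exposure, outcome, config = mr_config()) {
  if (!inherits(config, "mr_config")) stop_param("config must be an mr_config")
  log <- new_log()

  sel <- select_instruments(exposure, config$p_threshold)
  if (!nrow(sel)) stop("no instruments selected at p < ",
                       format(config$p_threshold))
  log <- log_add(log, "selected ", nrow(sel), " of ", nrow(exposure),
                 " exposure SNPs at p < ", format(config$p_threshold))
  n_initial <- nrow(sel)

  clumped <- greedy_clump(sel, config$ld, config$clump_window_kb,
                          config$clump_r2)
  n_clump_removed <- n_initial - nrow(clumped)
  log <- log_add(log, "clumping removed ", n_clump_removed, " SNPs")

  h <- harmonize(clumped, outcome, config$palindrome_maf)
  harm_removals <- attr(h, "removals")
  log <- log_add(log, "harmonization removed ", sum(harm_removals), " SNPs (",
                 paste(names(harm_removals), harm_removals, sep = "=",
                       collapse = ", "), ")")

  rad <- radial_outliers(h, config$radial_alpha)
  log <- log_add(log, "radial outliers removed: ",
                 length(rad$outlier_ids))
  h2 <- rad$cleaned

  h3 <- pleiotropy_filter(h2)
  pleio_removed <- attr(h3, "removed_ids")
  log <- log_add(log, "pleiotropy filter removed ", length(pleio_removed),
                 " SNPs (p_y < p_x)")

  est_ivw <- ivw(h3)
  est_egger <- egger(h3)
  est_med <- weighted_median(h3, config$n_boot, config$seed)
  est_mode <- weighted_mode(h3, config$bandwidth_factor, config$n_boot,
                            config$seed)
  q <- cochran_q(h3, est_ivw$beta)
  mf <- mean_f(h3)
  loo <- leave_one_out(h3)

  estimates <- data.frame(
    method = c("IVW", "Egger-slope", "Egger-intercept", "weighted-median",
               "weighted-mode"),
    beta = c(est_ivw$beta, est_egger$slope$beta, est_egger$intercept$beta,
             est_med$beta, est_mode$beta),
    se = c(est_ivw$se, est_egger$slope$se, est_egger$intercept$se,
           est_med$se, est_mode$se),
    pvalue = c(est_ivw$pvalue, est_egger$slope$pvalue,
               est_egger$intercept$pvalue, est_med$pvalue, est_mode$pvalue),
    n_snps = nrow(h3), stringsAsFactors = FALSE
  )

  removals <- c(clump = n_clump_removed,
                unmatched = unname(harm_removals["unmatched"]),
                harmonization = sum(harm_removals[c("incompatible",
                                                    "palindromic_maf",
                                                    "zero_b_x")]),
                radial = length(rad$outlier_ids),
                pleiotropy = length(pleio_removed))

  structure(list(
    estimates = estimates,
    cochran_q = q$Q, q_pvalue = q$pvalue,
    i_squared = i_squared(q$Q, nrow(h3)),
    i_squared_gx = i_squared_gx(h3),
    mean_f = mf$mean_f, weak_instruments = mf$weak_instruments,
    egger_intercept = est_egger$intercept$beta,
    egger_intercept_p = est_egger$intercept$pvalue,
    radial_outlier_ids = rad$outlier_ids,
    n_snps_initial = n_initial, n_snps_final = nrow(h3),
    removals = removals,
    loo_table = loo, n_loo_p_gt_05 = attr(loo, "n_p_gt_05"),
    harmonized = h3, log = log, config = config
  ), class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat("Two-sample MR report\n")
  cat(sprintf("  instruments: %d selected, %d analysed\n",
              x$n_snps_initial, x$n_snps_final))
  for (i in seq_len(nrow(x$estimates)))
    with(x$estimates[i, ], cat(sprintf(
      "  %-16s beta = %8.4f  se = %7.4f  p = %.3g\n",
      method, beta, se, pvalue)))
  cat(sprintf("  Cochran's Q = %.3f (p = %.3g), I2 = %.3f, I2_GX = %.3f\n",
              x$cochran_q, x$q_pvalue, x$i_squared, x$i_squared_gx))
  cat(sprintf("  mean F = %.2f%s\n", x$mean_f,
              if (x$weak_instruments) "  [weak instruments]" else ""))
  cat(sprintf("  radial outliers removed: %d; LOO rows with p > 0.05: %d\n",
              length(x$radial_outlier_ids), x$n_loo_p_gt_05))
  invisible(x)
}

#' Flatten an MR report to a statistic/value table
#'
#' One row per reported statistic, mirroring the layout of a published MR
#' sensitivity table.
#'
#' @param x An `mr_report`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return A data frame with columns `statistic` and `value`.
#' @export
as.data.frame.mr_report <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  e <- x$estimates
  stat <- c(paste(rep(e$method, each = 3), c("beta", "se", "pvalue")),
            "cochran_q", "q_pvalue", "i_squared", "i_squared_gx",
            "mean_f", "weak_instruments", "n_radial_outliers",
            "n_loo_p_gt_05", "n_snps_initial", "n_snps_final")
  val <- c(rbind(e$beta, e$se, e$pvalue),
           x$cochran_q, x$q_pvalue, x$i_squared, x$i_squared_gx,
           x$mean_f, as.numeric(x$weak_instruments),
           length(x$radial_outlier_ids), x$n_loo_p_gt_05,
           x$n_snps_initial, x$n_snps_final)
  data.frame(statistic = stat, value = val, stringsAsFactors = FALSE)
}
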