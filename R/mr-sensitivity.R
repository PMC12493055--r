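# Radial-MR outlier detection and leave-one-out sensitivity analysis.

#' Radial-MR outlier detection (single pass)
#'
#' Fits the radial IVW model -- the regression of `ratio_j * sqrt(w_j)` on
#' `sqrt(w_j)` through the origin, whose slope equals the fixed-effect IVW
#' estimate -- and flags instruments whose individual Q contribution
#' `Q_j = w_j (ratio_j - beta_radial)^2` exceeds the upper `alpha` tail of a
#' chi-square with 1 df.  Removal is a single pass: flagged SNPs are dropped
#' once and the cleaned table is returned for the rest of the battery.
#'
#' @param harmonized An `mr_harmonized` data frame with >= 3 rows.
#' @param alpha Per-SNP significance level (default 0.05); `alpha = 0`
#'   flags nothing.
#' @param iterate If `TRUE`, repeat removal until no SNP is flagged
#'   (off by default; the single pass is the reference behaviour).
#' @return A list with `outlier_ids`, `cleaned` (the retained
#'   `mr_harmonized` table), and `q_contributions` (per input SNP).
#' @export
radial_outliers <- function(harmonized, alpha = 0.05, iterate = FALSE) {
  assert_harmonized(harmonized, 3L, "radial_outliers")
  check_fraction(alpha, "alpha")
  one_pass <- function(h) {
    w <- h$weight
    beta <- sum(w * h$wald_ratio) / sum(w)
    qj <- w * (h$wald_ratio - beta)^2
    flagged <- pchisq(qj, 1, lower.tail = FALSE) < alpha
    list(flagged = flagged, qj = qj)
  }
  p1 <- one_pass(harmonized)
  if (all(p1$flagged)) stop("radial_outliers: every instrument flagged")
  outliers <- harmonized$variant_id[p1$flagged]
  cleaned <- harmonized[!p1$flagged, , drop = FALSE]
  if (iterate) {
    repeat {
      if (nrow(cleaned) < 3) break
      p <- one_pass(cleaned)
      if (!any(p$flagged) || all(p$flagged)) break
      outliers <- c(outliers, cleaned$variant_id[p$flagged])
      cleaned <- cleaned[!p$flagged, , drop = FALSE]
    }
  }
  rownames(cleaned) <- NULL
  class(cleaned) <- c("mr_harmonized", "data.frame")
  list(outlier_ids = outliers, cleaned = cleaned, q_contributions = p1$qj)
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate with each instrument removed in turn, to
#' identify SNPs exerting a disproportionate effect on the pooled result.
#'
#' @param harmonized An `mr_harmonized` data frame with >= 3 rows.
#' @return A data frame with one row per left-out SNP (`variant_id`,
#'   `beta`, `se`, `pvalue`); attribute `n_p_gt_05` counts rows with
#'   p > 0.05.
#' @export
leave_one_out <- function(harmonized) {
  assert_harmonized(harmonized, 3L, "leave_one_out")
  k <- nrow(harmonized)
  rows <- lapply(seq_len(k), function(i) {
    est <- ivw(harmonized[-i, , drop = FALSE])
    data.frame(variant_id = harmonized$variant_id[i], beta = est$beta,
               se = est$se, pvalue = est$pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_p_gt_05") <- sum(out$pvalue > 0.05)
  out
}
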