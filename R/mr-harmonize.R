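# Instrument selection, LD clumping, allele harmonization and the
# exposure/outcome p-value pleiotropy filter.

#' Select instrumental SNPs by exposure p-value
#'
#' Retains rows with `pvalue` strictly below the threshold (the conventional
#' sub-genome-wide cutoff for exercise instruments is 5e-5), preserving
#' input order.
#'
#' @param exposure Data frame of summary-statistic rows.
#' @param p_threshold Strict upper bound on the exposure p-value, in (0, 1).
#' @return The retained subset; a warning is raised if it is empty.
#' @export
select_instruments <- function(exposure, p_threshold = 5e-5) {
  check_columns(exposure, "pvalue", "exposure table")
  if (!nrow(exposure)) stop_param("exposure table is empty")
  if (p_threshold <= 0 || p_threshold >= 1)
    stop_param("p_threshold must be in (0, 1)")
  keep <- exposure$pvalue < p_threshold
  out <- exposure[keep, , drop = FALSE]
  if (!nrow(out))
    warning("no instruments pass p < ", format(p_threshold))
  rownames(out) <- NULL
  out
}

# Pairwise r^2 lookup. `ld_r2` may be NULL (no LD information: all pairs 0),
# a symmetric matrix with variant ids as dimnames, or a data frame with
# columns id1, id2, r2.  Missing entries are treated as 0.
ld_lookup <- function(ld_r2, id1, id2) {
  if (is.null(ld_r2)) return(NA_real_)
  if (is.matrix(ld_r2)) {
    if (id1 %in% rownames(ld_r2) && id2 %in% colnames(ld_r2))
      return(ld_r2[id1, id2])
    return(NA_real_)
  }
  hit <- (ld_r2$id1 == id1 & ld_r2$id2 == id2) |
         (ld_r2$id1 == id2 & ld_r2$id2 == id1)
  if (any(hit)) ld_r2$r2[which(hit)[1]] else NA_real_
}

#' Greedy LD clumping by ascending p-value
#'
#' Iterates instruments from the smallest p-value; a SNP is kept iff no
#' already-kept SNP on the same chromosome within `window_kb` has pairwise
#' r-squared at or above `r2_threshold` with it.  Within an LD block this
#' retains the SNP with the lowest p-value.  Pairs with no r-squared entry
#' are treated as unlinked (r2 = 0), with a logged warning the first time.
#'
#' @param instruments Data frame with `variant_id`, `chrom`, `pos`, `pvalue`.
#' @param ld_r2 Pairwise r-squared lookup: `NULL`, a named symmetric matrix,
#'   or a data frame with columns `id1`, `id2`, `r2`.
#' @param window_kb Clumping window in kilobases (default 10,000).
#' @param r2_threshold r-squared at or above which two SNPs are clumped
#'   (default 0.001).
#' @return The kept subset, in input-row order.
#' @export
greedy_clump <- function(instruments, ld_r2 = NULL,
                         window_kb = 10000, r2_threshold = 0.001) {
  check_columns(instruments, c("variant_id", "chrom", "pos", "pvalue"),
                "instrument table")
  if (!nrow(instruments)) return(instruments)
  check_positive(window_kb, "window_kb")
  check_positive(r2_threshold, "r2_threshold")
  ord <- order(instruments$pvalue)
  kept <- integer(0)
  missing_warned <- FALSE
  for (i in ord) {
    drop <- FALSE
    for (j in kept) {
      if (instruments$chrom[j] != instruments$chrom[i]) next
      if (abs(instruments$pos[j] - instruments$pos[i]) > window_kb * 1000) next
      r2 <- ld_lookup(ld_r2, instruments$variant_id[i],
                      instruments$variant_id[j])
      if (is.na(r2)) {
        if (!missing_warned && !is.null(ld_r2)) {
          warning("missing LD entries treated as r2 = 0")
          missing_warned <- TRUE
        }
        r2 <- 0
      }
      if (r2 >= r2_threshold) { drop <- TRUE; break }
    }
    if (!drop) kept <- c(kept, i)
  }
  out <- instruments[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Harmonize outcome associations onto exposure effect alleles
#'
#' Inner-joins exposure and outcome tables on `variant_id` and aligns each
#' outcome beta to the exposure effect allele: swapped allele labels negate
#' the outcome beta (and complement its frequency); strand flips are resolved
#' through allele complements for non-palindromic pairs; incompatible allele
#' pairs are dropped.  Palindromic variants (A/T or G/C) whose strand cannot
#' be resolved are kept only when the exposure minor-allele frequency is at
#' or below `palindrome_maf_limit` (default 0.42, the conventional
#' ambiguity bar).  Computes, per instrument, the Wald ratio `b_y / b_x`,
#' its first-order delta-method standard error `se_y / |b_x|`, the
#' inverse-variance weight and the instrument F-statistic `(b_x / se_x)^2`.
#'
#' @param exposure,outcome Summary-statistic data frames sharing variant ids.
#' @param palindrome_maf_limit Strict MAF bound above which palindromic
#'   variants are excluded.
#' @return A harmonized data frame (class `mr_harmonized`) with columns
#'   `variant_id`, `b_x`, `se_x`, `p_x`, `b_y`, `se_y`, `p_y`, `eaf`,
#'   `wald_ratio`, `wald_se`, `weight`, `f_stat`.  Attribute `removals`
#'   counts rows dropped by reason (`unmatched`, `incompatible`,
#'   `palindromic_maf`, `zero_b_x`).
#' @export
harmonize <- function(exposure, outcome, palindrome_maf_limit = 0.42) {
  need <- c("variant_id", "effect_allele", "other_allele", "eaf",
            "beta", "se", "pvalue")
  check_columns(exposure, need, "exposure table")
  check_columns(outcome, need, "outcome table")
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  removals <- c(unmatched = nrow(exposure) - length(shared),
                incompatible = 0L, palindromic_maf = 0L, zero_b_x = 0L)
  if (!length(shared)) stop_param("no shared variant ids to harmonize")

  ex <- exposure[match(shared, exposure$variant_id), ]
  ou <- outcome[match(shared, outcome$variant_id), ]

  b_y <- ou$beta
  status <- character(length(shared))
  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  same <- ou$effect_allele == ex$effect_allele &
          ou$other_allele == ex$other_allele
  swapped <- ou$effect_allele == ex$other_allele &
             ou$other_allele == ex$effect_allele
  flip_same <- !pal &
    unname(complement_allele(ou$effect_allele)) == ex$effect_allele &
    unname(complement_allele(ou$other_allele)) == ex$other_allele
  flip_swap <- !pal &
    unname(complement_allele(ou$effect_allele)) == ex$other_allele &
    unname(complement_allele(ou$other_allele)) == ex$effect_allele

  status[same | flip_same] <- "aligned"
  status[(swapped | flip_swap) & !(same | flip_same)] <- "swapped"
  status[status == ""] <- "incompatible"
  b_y[status == "swapped"] <- -b_y[status == "swapped"]

  # Palindrome exclusion uses the exposure-side MAF (the outcome frequency
  # plays no further role, which keeps allele relabeling exactly invariant).
  exp_maf <- pmin(ex$eaf, 1 - ex$eaf)
  drop_pal <- pal & exp_maf > palindrome_maf_limit
  removals["incompatible"] <- sum(status == "incompatible")
  removals["palindromic_maf"] <- sum(drop_pal & status != "incompatible")

  keep <- status != "incompatible" & !drop_pal
  zero_bx <- keep & ex$beta == 0
  removals["zero_b_x"] <- sum(zero_bx)
  keep <- keep & !zero_bx

  if (!any(keep)) stop("no instruments survive harmonization")

  h <- data.frame(
    variant_id = ex$variant_id[keep],
    b_x = ex$beta[keep], se_x = ex$se[keep], p_x = ex$pvalue[keep],
    b_y = b_y[keep], se_y = ou$se[keep], p_y = ou$pvalue[keep],
    eaf = ex$eaf[keep], stringsAsFactors = FALSE
  )
  h$wald_ratio <- h$b_y / h$b_x
  h$wald_se <- h$se_y / abs(h$b_x)
  h$weight <- 1 / h$wald_se^2
  h$f_stat <- (h$b_x / h$se_x)^2
  attr(h, "removals") <- removals
  class(h) <- c("mr_harmonized", "data.frame")
  h
}

#' Remove instruments better associated with the outcome than the exposure
#'
#' Drops instruments whose outcome p-value is strictly lower than their
#' exposure p-value, a guard against reverse causation and gross pleiotropy.
#'
#' @param harmonized An `mr_harmonized` data frame.
#' @return The retained subset; attribute `removed_ids` lists dropped
#'   variant ids.  Errors if nothing survives.
#' @export
pleiotropy_filter <- function(harmonized) {
  check_columns(harmonized, c("p_x", "p_y", "variant_id"), "harmonized table")
  if (!nrow(harmonized)) stop_param("harmonized table is empty")
  keep <- harmonized$p_y >= harmonized$p_x
  if (!any(keep)) stop("pleiotropy filter removed every instrument")
  out <- harmonized[keep, , drop = FALSE]
  attr(out, "removed_ids") <- harmonized$variant_id[!keep]
  attr(out, "removals") <- attr(harmonized, "removals")
  rownames(out) <- NULL
  class(out) <- c("mr_harmonized", "data.frame")
  out
}
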