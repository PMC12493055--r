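# Synthetic paired GWAS summary statistics with known causal ground truth.

#' Configuration for the summary-statistics simulator
#'
#' Describes a pair of GWAS (exposure and outcome) over independent
#' instruments, with a known causal effect `theta`, optional per-SNP
#' pleiotropic effects, planted gross outliers, palindromic allele pairs and
#' optional allele-label scrambling of the outcome file.
#'
#' Per-SNP direct (pleiotropic) effects on the outcome are drawn for a
#' Bernoulli(`invalid_fraction`) subset of SNPs: mean zero under
#' `pleiotropy_mode = "balanced"`, mean `pleiotropy_mean` under
#' `"directional"`, spread `pleiotropy_sd` in both cases.
#'
#' @param n_snps Number of independent instruments.
#' @param theta True causal effect of the exposure on the outcome
#'   (unitless beta scale).
#' @param n_exposure,n_outcome GWAS sample sizes; standard errors follow the
#'   `1/sqrt(2 p (1-p) n)` approximation.
#' @param maf_low,maf_high Minor-allele-frequency range, within (0, 0.5].
#' @param pleiotropy_mode One of `"none"`, `"balanced"`, `"directional"`.
#' @param pleiotropy_mean Mean of direct SNP-outcome effects under the
#'   directional mode (ignored otherwise).
#' @param pleiotropy_sd Spread of direct SNP-outcome effects.
#' @param invalid_fraction Proportion of SNPs carrying a pleiotropic effect.
#' @param outlier_fraction Proportion of SNPs planted as gross outliers
#'   (direct effect inflated at least tenfold over the pleiotropy scale).
#' @param palindrome_fraction Proportion of SNPs given A/T or G/C alleles.
#' @param allele_scramble If `TRUE`, roughly half the outcome rows have
#'   effect/other allele labels swapped with betas negated and frequencies
#'   complemented -- a consistent relabeling that harmonization must undo.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return An object of class `sumstat_sim_config`.
#' @export
sumstat_sim_config <- function(n_snps = 100, theta = 0,
                               n_exposure = 175000, n_outcome = 80000,
                               maf_low = 0.05, maf_high = 0.5,
                               pleiotropy_mode = c("none", "balanced", "directional"),
                               pleiotropy_mean = 0.1, pleiotropy_sd = 0.01,
                               invalid_fraction = 0, outlier_fraction = 0,
                               palindrome_fraction = 0.2,
                               allele_scramble = FALSE, seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  check_count(n_snps, "n_snps")
  check_count(n_exposure, "n_exposure", min = 2L)
  check_count(n_outcome, "n_outcome", min = 2L)
  if (!is.numeric(maf_low) || !is.numeric(maf_high) ||
      maf_low <= 0 || maf_high > 0.5 || maf_low > maf_high)
    stop_param("maf range must satisfy 0 < maf_low <= maf_high <= 0.5")
  check_fraction(invalid_fraction, "invalid_fraction")
  check_fraction(outlier_fraction, "outlier_fraction")
  check_fraction(palindrome_fraction, "palindrome_fraction")
  check_positive(pleiotropy_sd, "pleiotropy_sd", strict = FALSE)
  structure(list(
    n_snps = as.integer(n_snps), theta = theta,
    n_exposure = as.integer(n_exposure), n_outcome = as.integer(n_outcome),
    maf_low = maf_low, maf_high = maf_high,
    pleiotropy_mode = pleiotropy_mode, pleiotropy_mean = pleiotropy_mean,
    pleiotropy_sd = pleiotropy_sd, invalid_fraction = invalid_fraction,
    outlier_fraction = outlier_fraction,
    palindrome_fraction = palindrome_fraction,
    allele_scramble = isTRUE(allele_scramble), seed = as.integer(seed)
  ), class = "sumstat_sim_config")
}

# GWAS standard error under the standard asymptotic approximation.
gwas_se <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)

#' Simulate paired exposure/outcome GWAS summary statistics
#'
#' Draws, per SNP j, a true positive instrument effect (effect alleles are
#' oriented to the exposure-increasing allele, the state of instruments after
#' genome-wide selection), observed exposure beta with sampling noise, and an
#' outcome beta `theta * b_xj + alpha_j + noise`, where `alpha_j` is the
#' pleiotropic direct effect for the invalid subset and is inflated tenfold
#' for planted outliers.  Instruments are placed far apart on alternating
#' chromosomes (the post-clumping, LD-free state).
#'
#' @param config A [sumstat_sim_config()].
#' @return A list with elements `exposure` and `outcome`, each a data frame
#'   of summary-statistic rows (`variant_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`), plus a `truth` data
#'   frame recording per-SNP ground truth (`b_x_true`, `alpha`, `invalid`,
#'   `outlier`, `palindromic`, `scrambled`).
#' @export
gen_sumstats <- function(config) {
  if (!inherits(config, "sumstat_sim_config"))
    stop_param("config must be a sumstat_sim_config")
  set.seed(config$seed)
  k <- config$n_snps

  maf <- runif(k, config$maf_low, config$maf_high)
  se_x <- gwas_se(maf, config$n_exposure)
  se_y <- gwas_se(maf, config$n_outcome)

  # True instrument effects: positive, moderate strength (mean F well > 10
  # at the default sample sizes).
  b_x_true <- runif(k, 0.01, 0.05)
  b_x <- b_x_true + rnorm(k, 0, se_x)

  invalid <- runif(k) < config$invalid_fraction & config$pleiotropy_mode != "none"
  alpha <- numeric(k)
  mu <- if (config$pleiotropy_mode == "directional") config$pleiotropy_mean else 0
  alpha[invalid] <- rnorm(sum(invalid), mu, config$pleiotropy_sd)

  outlier <- runif(k) < config$outlier_fraction
  if (any(outlier)) {
    scale0 <- if (config$pleiotropy_sd > 0) config$pleiotropy_sd else stats::median(se_y)
    alpha[outlier] <- sample(c(-1, 1), sum(outlier), replace = TRUE) *
      10 * scale0 * runif(sum(outlier), 1, 1.5)
  }

  b_y <- config$theta * b_x_true + alpha + rnorm(k, 0, se_y)

  palindromic <- runif(k) < config$palindrome_fraction
  ea <- oa <- character(k)
  pal_pairs <- matrix(c("A", "T", "G", "C"), 2)
  pick_pal <- sample(1:2, k, replace = TRUE)
  flip <- sample(c(TRUE, FALSE), k, replace = TRUE)
  nonpal <- cbind(
    sample(ALLELES, k, replace = TRUE),
    NA_character_
  )
  for (j in seq_len(k)) {
    if (palindromic[j]) {
      pair <- pal_pairs[, pick_pal[j]]
      if (flip[j]) pair <- rev(pair)
      ea[j] <- pair[1]; oa[j] <- pair[2]
    } else {
      a1 <- nonpal[j, 1]
      choices <- setdiff(ALLELES, c(a1, unname(complement_allele(a1))))
      oa[j] <- sample(choices, 1)
      ea[j] <- a1
    }
  }

  # Effect allele is the minor or major allele at random.
  eaf <- ifelse(runif(k) < 0.5, maf, 1 - maf)

  ids <- sprintf("snp%05d", seq_len(k))
  chrom <- as.character(rep_len(1:22, k))
  pos <- as.integer(20e6 * (1 + (seq_len(k) - 1L) %/% 22L))

  mk <- function(beta, se, n) data.frame(
    variant_id = ids, chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa,
    eaf = eaf, beta = beta, se = se,
    pvalue = pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin),
    n = n, stringsAsFactors = FALSE
  )
  exposure <- mk(b_x, se_x, config$n_exposure)
  outcome <- mk(b_y, se_y, config$n_outcome)

  scrambled <- rep(FALSE, k)
  if (config$allele_scramble) {
    scrambled <- runif(k) < 0.5
    sw <- which(scrambled)
    tmp <- outcome$effect_allele[sw]
    outcome$effect_allele[sw] <- outcome$other_allele[sw]
    outcome$other_allele[sw] <- tmp
    outcome$beta[sw] <- -outcome$beta[sw]
    outcome$eaf[sw] <- 1 - outcome$eaf[sw]
  }

  truth <- data.frame(
    variant_id = ids, b_x_true = b_x_true, alpha = alpha,
    invalid = invalid, outlier = outlier, palindromic = palindromic,
    scrambled = scrambled, stringsAsFactors = FALSE
  )
  list(exposure = exposure, outcome = outcome, truth = truth,
       seed = config$seed)
}
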