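# Synthetic rare-variant genotype package: carrier matrix, phenotypes,
# variant annotation -- with per-gene carrier odds ratios as ground truth.

#' Configuration for the genotype simulator
#'
#' Emulates an extreme-exerciser vs sedentary-control rare-variant contrast
#' at desk scale.  Each gene carries two qualifying loss-of-function variants
#' (nonsense / splice-site, MAF below 1%) plus one non-qualifying decoy
#' (missense, common) to exercise the LOF filter.  For signal genes the case
#' carrier odds are multiplied by the configured odds ratio.
#'
#' @param n_cases,n_controls Group sizes.
#' @param n_genes Number of genes.
#' @param carrier_freq Per-gene background probability that a sample carries
#'   at least one qualifying variant; in (0, 1).  Kept small so that the
#'   per-variant allele frequency (about `carrier_freq / 4`) stays below the
#'   1% rare-variant bar.
#' @param signal_genes Data frame with columns `gene` (index in
#'   `1:n_genes`) and `or` (carrier odds ratio in cases, > 0); may be empty.
#' @param n_covariates Number of standard-normal nuisance covariates.
#' @param seed Integer seed.
#' @return An object of class `genotype_sim_config`.
#' @export
genotype_sim_config <- function(n_cases = 2000, n_controls = 2000,
                                n_genes = 200, carrier_freq = 0.02,
                                signal_genes = data.frame(gene = integer(),
                                                          or = numeric()),
                                n_covariates = 2, seed = 1L) {
  check_count(n_cases, "n_cases"); check_count(n_controls, "n_controls")
  check_count(n_genes, "n_genes")
  if (carrier_freq <= 0 || carrier_freq >= 1)
    stop_param("carrier_freq must be in (0, 1)")
  check_count(n_covariates, "n_covariates", min = 0L)
  signal_genes <- as.data.frame(signal_genes)
  if (nrow(signal_genes)) {
    check_columns(signal_genes, c("gene", "or"), "signal_genes")
    if (any(signal_genes$gene < 1 | signal_genes$gene > n_genes))
      stop_param("signal_genes$gene indices must lie in 1:n_genes")
    if (any(signal_genes$or <= 0)) stop_param("signal_genes$or must be > 0")
  }
  if (carrier_freq / 4 >= 0.01)
    warning("carrier_freq implies per-variant MAF >= 1%; ",
            "qualifying variants will fail the rare-variant filter")
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_genes = as.integer(n_genes), carrier_freq = carrier_freq,
    signal_genes = signal_genes, n_covariates = as.integer(n_covariates),
    seed = as.integer(seed)
  ), class = "genotype_sim_config")
}

#' Simulate a genotype/variant package
#'
#' @param config A [genotype_sim_config()].
#' @return A list with `carriers` (samples x variants 0/1 matrix with
#'   dimnames), `phenotypes` (data frame: `id`, `status` 1 = case,
#'   `sex`, covariate columns `cov1..covk`), and `variants` (annotation data
#'   frame: `variant_id`, `gene`, `consequence`, `maf`).
#' @export
gen_genotypes <- function(config) {
  if (!inherits(config, "genotype_sim_config"))
    stop_param("config must be a genotype_sim_config")
  set.seed(config$seed)
  n <- config$n_cases + config$n_controls
  status <- rep(c(1L, 0L), c(config$n_cases, config$n_controls))
  genes <- sprintf("GENE%03d", seq_len(config$n_genes))

  p0 <- config$carrier_freq
  odds0 <- p0 / (1 - p0)
  p_case <- rep(p0, config$n_genes)
  if (nrow(config$signal_genes)) {
    idx <- config$signal_genes$gene
    odds1 <- odds0 * config$signal_genes$or
    p_case[idx] <- odds1 / (1 + odds1)
  }

  # Two qualifying LOF variants + one common missense decoy per gene.
  n_var <- 3L * config$n_genes
  carriers <- matrix(0L, n, n_var)
  variant_id <- character(n_var)
  v_gene <- character(n_var)
  consequence <- character(n_var)
  maf <- numeric(n_var)

  for (g in seq_len(config$n_genes)) {
    pg <- ifelse(status == 1L, p_case[g], p0)
    carrier <- rbinom(n, 1L, pg)
    which_var <- 1L + (runif(n) < 0.5)  # assign carriers to variant 1 or 2
    cols <- (3L * (g - 1L)) + 1:3
    carriers[, cols[1]] <- carrier * (which_var == 1L)
    carriers[, cols[2]] <- carrier * (which_var == 2L)
    carriers[, cols[3]] <- rbinom(n, 1L, 0.1)  # decoy, unrelated to status
    variant_id[cols] <- sprintf("%s_v%d", genes[g], 1:3)
    v_gene[cols] <- genes[g]
    consequence[cols] <- c(sample(c("nonsense", "splice-site"), 2, replace = TRUE),
                           "missense")
    maf[cols] <- c(rep(p0 / 4, 2), 0.05)
  }

  ids <- sprintf("s%05d", seq_len(n))
  dimnames(carriers) <- list(ids, variant_id)

  phenotypes <- data.frame(
    id = ids, status = status,
    sex = sample(c("male", "female"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  if (config$n_covariates > 0) {
    covs <- matrix(rnorm(n * config$n_covariates), n)
    colnames(covs) <- paste0("cov", seq_len(config$n_covariates))
    phenotypes <- cbind(phenotypes, as.data.frame(covs))
  }

  variants <- data.frame(
    variant_id = variant_id, gene = v_gene,
    consequence = consequence, maf = maf, stringsAsFactors = FALSE
  )
  list(carriers = carriers, phenotypes = phenotypes, variants = variants,
       seed = config$seed)
}

#' Generate two gene sets with an exact overlap
#'
#' Fixture generator for the overlap/enrichment machinery: draws two subsets
#' of a synthetic gene universe sharing exactly `overlap` members.
#'
#' @param universe_size,size_a,size_b,overlap Counts; `overlap` must not
#'   exceed `min(size_a, size_b)`, and both sizes must fit in the universe
#'   (`size_a + size_b - overlap <= universe_size`).
#' @param seed Integer seed.
#' @return A list with character vectors `set_a`, `set_b`, `universe`.
#' @export
gen_gene_sets <- function(universe_size, size_a, size_b, overlap, seed = 1L) {
  check_count(universe_size, "universe_size")
  check_count(size_a, "size_a", min = 0L); check_count(size_b, "size_b", min = 0L)
  check_count(overlap, "overlap", min = 0L)
  if (overlap > min(size_a, size_b))
    stop_param("overlap must not exceed min(size_a, size_b)")
  if (size_a > universe_size || size_b > universe_size ||
      size_a + size_b - overlap > universe_size)
    stop_param("requested sets do not fit in the universe")
  set.seed(seed)
  universe <- sprintf("G%05d", seq_len(universe_size))
  shuffled <- sample(universe)
  shared <- shuffled[seq_len(overlap)]
  a_only <- shuffled[overlap + seq_len(size_a - overlap)]
  b_only <- shuffled[overlap + (size_a - overlap) + seq_len(size_b - overlap)]
  list(set_a = sort(c(shared, a_only)), set_b = sort(c(shared, b_only)),
       universe = universe)
}
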