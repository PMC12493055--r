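test_that("instrument selection uses a strict p-value inequality", {
  ex <- make_sumstats(4, pvalue = c(4e-5, 5e-5, 6e-5, 1e-9))
  sel <- select_instruments(ex, 5e-5)
  expect_identical(sel$variant_id, c("rs1", "rs4"))  # order preserved
  expect_warning(empty <- select_instruments(
    make_sumstats(3, pvalue = rep(0.5, 3)), 5e-5), "no instruments")
  expect_equal(nrow(empty), 0)
})

test_that("clumping keeps the lowest-p SNP within an LD block", {
  snps <- data.frame(variant_id = c("a", "b"), chrom = "1",
                     pos = c(1e6, 1e6 + 5000), pvalue = c(1e-6, 1e-5))
  ld <- data.frame(id1 = "a", id2 = "b", r2 = 0.5)
  kept <- greedy_clump(snps, ld, window_kb = 10000, r2_threshold = 0.001)
  expect_identical(kept$variant_id, "a")
})

test_that("unlinked or distant SNPs all survive clumping", {
  snps <- data.frame(variant_id = c("a", "b", "c"), chrom = "1",
                     pos = c(1e6, 2e6, 3e6), pvalue = c(1e-6, 1e-5, 1e-4))
  ld0 <- data.frame(id1 = c("a", "a", "b"), id2 = c("b", "c", "c"), r2 = 0)
  expect_equal(nrow(greedy_clump(snps, ld0)), 3)
  # correlated pair beyond the window is not clumped
  far <- data.frame(variant_id = c("a", "b"), chrom = "1",
                    pos = c(1e6, 1e6 + 2e7), pvalue = c(1e-6, 1e-5))
  ldf <- data.frame(id1 = "a", id2 = "b", r2 = 0.9)
  expect_equal(nrow(greedy_clump(far, ldf, window_kb = 10000)), 2)
  expect_equal(nrow(greedy_clump(far, ldf, window_kb = 30000)), 1)
})

test_that("missing LD entries are treated as unlinked with a warning", {
  snps <- data.frame(variant_id = c("a", "b"), chrom = "1",
                     pos = c(1e6, 1.1e6), pvalue = c(1e-6, 1e-5))
  ld <- data.frame(id1 = "x", id2 = "y", r2 = 1)
  expect_warning(kept <- greedy_clump(snps, ld), "missing LD")
  expect_equal(nrow(kept), 2)
})

make_pair <- function(ea_x, oa_x, ea_y, oa_y, eaf = 0.3, b_y = 0.05) {
  ex <- make_sumstats(1)
  ex$effect_allele <- ea_x; ex$other_allele <- oa_x; ex$eaf <- eaf
  ou <- ex
  ou$effect_allele <- ea_y; ou$other_allele <- oa_y
  ou$beta <- b_y
  list(ex = ex, ou = ou)
}

test_that("palindromic variants are excluded only above the MAF limit", {
  high <- make_pair("A", "T", "A", "T", eaf = 0.45)
  expect_error(harmonize(high$ex, high$ou), "no instruments survive")
  low <- make_pair("A", "T", "A", "T", eaf = 0.10)
  expect_equal(nrow(harmonize(low$ex, low$ou)), 1)
  # boundary: MAF exactly at the limit is retained (strict >)
  at <- make_pair("G", "C", "G", "C", eaf = 0.42)
  expect_equal(nrow(harmonize(at$ex, at$ou)), 1)
})

test_that("swapped outcome alleles negate the outcome beta", {
  straight <- make_pair("A", "G", "A", "G", b_y = 0.05)
  swapped <- make_pair("A", "G", "G", "A", b_y = -0.05)
  h1 <- harmonize(straight$ex, straight$ou)
  h2 <- harmonize(swapped$ex, swapped$ou)
  expect_identical(h1$b_y, h2$b_y)
  expect_identical(h1$wald_ratio, h2$wald_ratio)
})

test_that("strand flips resolve for non-palindromic pairs; mismatches drop", {
  flipped <- make_pair("A", "G", "T", "C", b_y = 0.05)   # complement
  expect_equal(harmonize(flipped$ex, flipped$ou)$b_y, 0.05)
  flipswap <- make_pair("A", "G", "C", "T", b_y = -0.05) # complement+swap
  expect_equal(harmonize(flipswap$ex, flipswap$ou)$b_y, 0.05)
  bad <- make_pair("A", "G", "A", "C")
  expect_error(harmonize(bad$ex, bad$ou), "no instruments survive")
})

test_that("Wald ratio machinery is computed on the harmonized scale", {
  p <- make_pair("A", "G", "A", "G", b_y = 0.05)
  h <- harmonize(p$ex, p$ou)
  expect_equal(h$wald_ratio, 0.05 / p$ex$beta)
  expect_equal(h$wald_se, p$ou$se / abs(p$ex$beta))
  expect_equal(h$weight, 1 / h$wald_se^2)
  expect_equal(h$f_stat, (p$ex$beta / p$ex$se)^2)
})

test_that("pleiotropy filter removes p_y < p_x with a strict inequality", {
  h <- make_harmonized(c(0.5, 0.5, 0.5), rep(0.1, 3),
                       p_x = c(1e-5, 1e-5, 1e-5),
                       p_y = c(1e-8, 1e-5, 0.5))
  out <- pleiotropy_filter(h)
  expect_identical(out$variant_id, c("v002", "v003"))  # equal p retained
  expect_identical(attr(out, "removed_ids"), "v001")
  all_bad <- make_harmonized(c(0.5, 0.5, 0.5), rep(0.1, 3),
                             p_x = rep(0.5, 3), p_y = rep(1e-8, 3))
  expect_error(pleiotropy_filter(all_bad), "every instrument")
})
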