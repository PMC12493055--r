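# File-format readers and writers: GWAS summary-statistic TSV, cohort CSV,
# variant annotation TSV, dense carrier-matrix TSV, newline-delimited gene
# sets.  All writers emit a '#'-prefixed header block (version, parameters,
# seed); all readers skip it.

SUMSTAT_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                  "other_allele", "eaf", "beta", "se", "pvalue", "n")

header_block <- function(params = list()) {
  lines <- c(paste0("# exals ",
                    as.character(utils::packageVersion("exals"))),
             paste0("# date: ", format(Sys.time(), "%Y-%m-%d")))
  for (nm in names(params))
    lines <- c(lines, paste0("# ", nm, ": ", params[[nm]]))
  lines
}

write_table_with_header <- function(df, path, params = list(), sep = "\t") {
  # doubles serialized with 17 significant digits: read-back is exact
  for (nm in names(df))
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_block(params), con)
  write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GWAS summary-statistics TSV
#'
#' Tab-separated with a header naming the nine required columns
#' (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pvalue`, `n`); positions are 1-based; `#`-prefixed lines
#' are skipped.  Allele case is normalized to upper.  Malformed rows
#' (non-positive `se`, p outside (0, 1], frequency outside (0, 1), alleles
#' outside A/C/G/T or identical) are rejected with their line numbers in a
#' warning; a missing column is a hard error naming it.
#'
#' @param path File path.
#' @return A validated data frame of summary-statistic rows.
#' @export
read_sumstats <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  check_columns(df, SUMSTAT_COLS, basename(path))
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)
  bad <- !is.finite(df$se) | df$se <= 0 |
    !is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1 |
    !is.finite(df$eaf) | df$eaf <= 0 | df$eaf >= 1 |
    !df$effect_allele %in% ALLELES | !df$other_allele %in% ALLELES |
    df$effect_allele == df$other_allele | !is.finite(df$beta)
  if (any(bad))
    warning("rejected ", sum(bad), " malformed row(s) at line(s): ",
            paste(which(bad), collapse = ", "))
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a GWAS summary-statistics TSV
#'
#' @param df Summary-statistic data frame.
#' @param path Output path.
#' @param params Named list echoed into the `#` header block.
#' @return The path, invisibly.
#' @export
write_sumstats <- function(df, path, params = list()) {
  check_columns(df, SUMSTAT_COLS, "summary statistics")
  write_table_with_header(df[, SUMSTAT_COLS], path, params)
}

#' Read a cohort CSV
#'
#' Comma-separated, header `id, dose, time, event, enrol_age, sex`, then
#' any covariate columns.  Rows with `event` outside \{0, 1\},
#' non-positive `time`, negative `dose` or a sex outside
#' \{male, female\} are rejected with line numbers.
#'
#' @param path File path.
#' @return A validated cohort data frame.
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  check_columns(df, c("id", "dose", "time", "event", "enrol_age", "sex"),
                basename(path))
  bad <- !df$event %in% c(0, 1) | !is.finite(df$time) | df$time <= 0 |
    !is.finite(df$dose) | df$dose < 0 | !df$sex %in% c("male", "female")
  if (any(bad))
    warning("rejected ", sum(bad), " malformed row(s) at line(s): ",
            paste(which(bad), collapse = ", "))
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a cohort CSV
#' @inheritParams write_sumstats
#' @export
write_cohort <- function(df, path, params = list()) {
  check_columns(df, c("id", "dose", "time", "event", "enrol_age", "sex"),
                "cohort table")
  write_table_with_header(df, path, params, sep = ",")
}

#' Read a variant annotation TSV
#'
#' Columns `variant_id`, `gene`, `consequence`, `maf`; consequence must be
#' one of nonsense, splice-site, missense, synonymous, other; `maf` in
#' (0, 0.5].
#'
#' @param path File path.
#' @return A validated annotation data frame.
#' @export
read_variants <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  check_columns(df, c("variant_id", "gene", "consequence", "maf"),
                basename(path))
  ok_cons <- c("nonsense", "splice-site", "missense", "synonymous", "other")
  bad_cons <- !df$consequence %in% ok_cons
  if (any(bad_cons))
    stop_param("unknown consequence value(s) at row(s) ",
               paste(which(bad_cons), collapse = ", "), ": ",
               paste(unique(df$consequence[bad_cons]), collapse = ", "))
  bad <- !is.finite(df$maf) | df$maf <= 0 | df$maf > 0.5
  if (any(bad))
    warning("rejected ", sum(bad), " row(s) with out-of-range maf at: ",
            paste(which(bad), collapse = ", "))
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a variant annotation TSV
#' @inheritParams write_sumstats
#' @export
write_variants <- function(df, path, params = list()) {
  check_columns(df, c("variant_id", "gene", "consequence", "maf"),
                "variant table")
  write_table_with_header(df, path, params)
}

#' Read a dense carrier matrix TSV
#'
#' Samples x variants; first column `id` holds sample ids, remaining
#' columns one variant each with 0/1 entries.  Any other value is a hard
#' error naming its position.
#'
#' @param path File path.
#' @return An integer 0/1 matrix with sample ids as row names.
#' @export
read_carrier_matrix <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  check_columns(df, "id", basename(path))
  m <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  bad <- which(!(m %in% c(0, 1)))
  if (length(bad))
    stop_param("carrier matrix contains non-0/1 value(s), first at entry ",
               bad[1])
  storage.mode(m) <- "integer"
  rownames(m) <- df$id
  m
}

#' Write a dense carrier matrix TSV
#' @param m Samples x variants 0/1 matrix with dimnames.
#' @inheritParams write_sumstats
#' @export
write_carrier_matrix <- function(m, path, params = list()) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table_with_header(df, path, params)
}

#' Read a newline-delimited gene set
#'
#' One symbol per line; blank and `#` lines skipped; duplicates removed
#' with a warning.
#'
#' @param path File path.
#' @return Character vector of unique symbols.
#' @export
read_gene_set <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (anyDuplicated(x)) {
    warning("gene set contains ", sum(duplicated(x)),
            " duplicate symbol(s); de-duplicated")
    x <- unique(x)
  }
  x
}

#' Write a newline-delimited gene set
#' @param genes Character vector of symbols.
#' @inheritParams write_sumstats
#' @export
write_gene_set <- function(genes, path, params = list()) {
  writeLines(c(header_block(params), genes), path)
  invisible(path)
}

#' Write an MR report as a flat TSV
#'
#' One row per statistic (the layout of a published MR sensitivity table).
#'
#' @param report An `mr_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mr_report <- function(report, path) {
  write_table_with_header(
    as.data.frame(report), path,
    params = list(seed = report$config$seed,
                  p_threshold = report$config$p_threshold))
}
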