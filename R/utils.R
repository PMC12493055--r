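# Internal validation and bookkeeping helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("exals_parameter_error", "error")))
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_param(name, " must be a single value in [0, 1], got ", format(x))
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && (if (strict) x > 0 else x >= 0)
  if (!ok) stop_param(name, " must be ", if (strict) "> 0" else ">= 0", ", got ", format(x))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == round(x)
  if (!ok) stop_param(name, " must be an integer >= ", min, ", got ", format(x))
  invisible(as.integer(x))
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_param(what, " is missing required column(s): ", paste(missing, collapse = ", "))
  invisible(df)
}

#' Derive a per-stage seed from a global seed
#'
#' One global seed expands to stage-level sub-seeds by a fixed counter scheme
#' (`seed + 1000 * stage_index`, wrapped into the positive 32-bit integer
#' range), so that an individual stage can be re-run alone and reproduce the
#' stream it saw inside a full pipeline run.
#'
#' @param seed Integer global seed.
#' @param stage_index Integer stage counter (0, 1, 2, ...).
#' @return A single integer seed.
#' @export
stage_seed <- function(seed, stage_index) {
  check_count(stage_index, "stage_index", min = 0L)
  as.integer((as.double(seed) + 1000 * stage_index) %% 2147483647)
}

# Complement map for strand logic; palindromic = allele pair A/T or G/C.
ALLELES <- c("A", "C", "G", "T")
complement_allele <- function(a) c(A = "T", C = "G", G = "C", T = "A")[a]
is_palindromic <- function(a1, a2) a2 == unname(complement_allele(a1))

new_log <- function() character(0)
log_add <- function(log, ...) c(log, paste0(...))
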