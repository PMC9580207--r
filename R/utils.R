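#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef predict median pchisq qt quantile rbinom rexp rnorm
#'   runif sd setNames t.test var wilcox.test uniroot cor
#' @importFrom utils head read.delim write.table
NULL

# Derive a reproducible child seed from a master seed and a stream index.
# Keeps results < 2^31 so they are valid R integer seeds, and keeps distinct
# (master, i) pairs on distinct streams for all practical loop lengths.
derive_seed <- function(master, i) {
  master <- as.double(master) %% 1000003
  as.integer((master * 8191 + as.double(i) * 131071 + 1) %% 2147483647L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_mirmark <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "mirmark_error")))
}

round_half_up <- function(x) floor(x + 0.5)

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
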