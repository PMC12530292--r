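#' @keywords internal
"_PACKAGE"

# Sample (n-1) standard deviation; NA-safe only when na.rm requested upstream.
samp_sd <- function(x) stats::sd(x)

#' Coefficient of variation
#'
#' Spatial-heterogeneity estimator used for campaign summaries:
#' \code{100 * sd(x) / mean(x)} with the sample (n-1) standard deviation.
#'
#' @param x numeric vector of at least two values.
#' @return The coefficient of variation in percent, or \code{NA_real_}
#'   (with a warning) when the mean is zero, where the CV is undefined.
#' @examples
#' cv(c(2, 4)) # 47.14
#' @export
cv <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("cv() needs at least two values", call. = FALSE)
  m <- mean(x)
  if (m == 0) {
    warning("cv(): mean is zero, coefficient of variation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  100 * stats::sd(x) / m
}

#' Log-plus-one transform
#'
#' Applied to prey density estimators before they enter models.
#'
#' @param x non-negative numeric vector.
#' @return \code{log(x + 1)}.
#' @export
ln1p <- function(x) {
  if (any(x < 0, na.rm = TRUE)) {
    stop("ln1p(): negative input", call. = FALSE)
  }
  log1p(x)
}

# Derive a stream of sub-seeds from one root seed so that stage-level reruns
# are reproducible independently of each other. Kept below 2^31 - 1.
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (as.integer(seed %% 100000L) * 101L + 7919L * seq_len(n)) %% 2147483647L
}

stop_if_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Read / write tab-separated tables
#'
#' Thin wrappers fixing the conventions used by all pipeline tables:
#' UTF-8, tab-delimited, header row, no quoting, no row names.
#'
#' @param path file path.
#' @param df data frame to write.
#' @return \code{read_tsv_table} returns a data.frame;
#'   \code{write_tsv_table} returns \code{path} invisibly.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
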