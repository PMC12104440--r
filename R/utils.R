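#' @importFrom stats median quantile rbinom rlnorm rnbinom rpois runif sd cor rnorm
#' @importFrom utils read.delim write.table
NULL

# stop() with call. = FALSE and sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min)
    abort("`%s` must be a single integer >= %d (got %s)", name, min,
          paste(format(x), collapse = ","))
  as.integer(x)
}

assert_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x))
    abort("`%s` must be a single number", name)
  ok <- if (strict_min) x > min else x >= min
  if (!ok || x > max)
    abort("`%s` = %g out of range", name, x)
  as.numeric(x)
}

DNA_BASES <- c("A", "C", "G", "T")
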