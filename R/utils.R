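#' @importFrom stats cor rnorm runif rbinom rnbinom sd var aov t.test TukeyHSD
#'   coef pbinom setNames complete.cases
#' @importFrom utils write.csv write.table read.csv read.delim head tail
NULL

# fail with a formatted message, no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_matrix2d <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("'%s' must be a numeric matrix", name)
  }
  invisible(x)
}

# resolve a logical selection mask against an image; NULL means all pixels
resolve_mask <- function(mask, dims) {
  if (is.null(mask)) {
    return(matrix(TRUE, dims[1], dims[2]))
  }
  if (!all(dim(mask) == dims)) {
    abort("mask dimensions (%s) do not match image dimensions (%s)",
          paste(dim(mask), collapse = "x"), paste(dims, collapse = "x"))
  }
  storage.mode(mask) <- "logical"
  mask
}

# significance stars at conventional thresholds
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "ns"))
}
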