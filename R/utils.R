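#' @useDynLib rodspt, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pnorm dnorm qnorm rnorm runif rbinom rgeom rpois
#'   rlnorm quantile sd var lm coef convolve approx t.test rgamma
#'   complete.cases integrate setNames
#' @importFrom utils head tail read.delim write.table
#' @importFrom graphics hist
NULL

# trapezoidal integral
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# truncated normal by rejection; truncation region (lo, hi)
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) {
    if (mean <= lo || mean >= hi)
      stop("degenerate truncated normal: mean outside (lo, hi)")
    return(rep(mean, n))
  }
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw > lo & draw < hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# signed area and centroid of a simple closed polygon (shoelace)
polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps)
    return(c(mean(x), mean(y)))
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
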