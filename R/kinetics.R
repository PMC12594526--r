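#' Windowed single-exponential decay rate
#'
#' Least-squares fit of log(abundance) against time over the samples
#' falling inside the window (edges inclusive); the decay rate is minus
#' the slope, 1/s. The default windows target the co-transcriptional
#' ([150, 210] s) and post-transcriptional ([300, 600] s) phases of an
#' mRNA decay assay.
#'
#' @param times sampling times, s (increasing).
#' @param abundance relative abundances (> 0), same length.
#' @param window length-2 numeric window in s.
#' @return Decay rate, 1/s.
#' @export
fit_decay_rate <- function(times, abundance, window = c(150, 210)) {
  stopifnot(length(times) == length(abundance), length(window) == 2)
  if (any(abundance <= 0)) stop("abundances must be positive")
  inw <- times >= window[1] & times <= window[2]
  if (sum(inw) < 3)
    stop("need at least 3 samples inside the window [",
         window[1], ", ", window[2], "]")
  -unname(coef(lm(log(abundance[inw]) ~ times[inw]))[2])
}

#' Per-replicate co- and post-transcriptional decay rates
#'
#' Applies [fit_decay_rate()] in both windows for each replicate of a
#' time-course table.
#'
#' @param timecourses data.frame with replicate, time_s, abundance.
#' @param w1,w2 windows (s) for k_d1 and k_d2.
#' @return data.frame with replicate, k_d1, k_d2; strain mean and SD in
#'   attributes \code{mean} and \code{sd}.
#' @export
decay_rates <- function(timecourses, w1 = c(150, 210), w2 = c(300, 600)) {
  reps <- split(timecourses, timecourses$replicate)
  out <- do.call(rbind, lapply(reps, function(d) data.frame(
    replicate = d$replicate[1],
    k_d1 = fit_decay_rate(d$time_s, d$abundance, w1),
    k_d2 = fit_decay_rate(d$time_s, d$abundance, w2))))
  rownames(out) <- NULL
  attr(out, "mean") <- c(k_d1 = mean(out$k_d1), k_d2 = mean(out$k_d2))
  attr(out, "sd") <- c(k_d1 = sd(out$k_d1), k_d2 = sd(out$k_d2))
  out
}

#' Compare decay rates between two strains
#'
#' Pooled-variance (equal-variance) two-sample t-test; two-tailed by
#' default, with a left-tailed option for testing whether group A's mean
#' is below group B's. Degenerate inputs with zero variance and equal
#' means return p = 1 by convention.
#'
#' @param a,b numeric rate vectors (each length >= 2).
#' @param tail "two" (default) or "left".
#' @param alpha significance level for the reported decision.
#' @return list with p (p-value), t (statistic), significant (logical at
#'   \code{alpha}).
#' @export
compare_rates <- function(a, b, tail = c("two", "left"), alpha = 0.05) {
  tail <- match.arg(tail)
  stopifnot(length(a) >= 2, length(b) >= 2)
  alt <- if (tail == "two") "two.sided" else "less"
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(p = 1, t = 0, significant = FALSE))
    p <- if (tail == "two" || mean(a) < mean(b)) 0 else 1
    return(list(p = p, t = sign(mean(a) - mean(b)) * Inf,
                significant = p < alpha))
  }
  tt <- t.test(a, b, var.equal = TRUE, alternative = alt)
  list(p = unname(tt$p.value), t = unname(tt$statistic),
       significant = tt$p.value < alpha)
}
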