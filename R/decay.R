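#' Simulate two-phase exponential mRNA decay time courses
#'
#' Relative abundance decays at rate \code{k_d1_true} (co-transcriptional
#' window) up to the switch time and at \code{k_d2_true} afterwards, with
#' the curve continuous at the junction. Each sample is multiplied by
#' lognormal noise with unit mean and coefficient of variation
#' \code{cv_noise}, emulating qPCR-style measurement error.
#'
#' @param config a [sim_config()] (uses k_d1_true, k_d2_true, cv_noise,
#'   seed).
#' @param sample_times strictly increasing sampling times, s.
#' @param n_replicates number of replicate curves.
#' @param t_switch time at which the decay rate changes, s.
#' @param A0 abundance at t = 0 (arbitrary units).
#' @return data.frame with replicate, time_s, abundance.
#' @export
simulate_decay <- function(config, sample_times, n_replicates = 3,
                           t_switch = 255, A0 = 1) {
  validate_sim_config(config)
  if (length(sample_times) == 0L)
    stop("sample_times must be non-empty")
  if (any(diff(sample_times) <= 0))
    stop("sample_times must be strictly increasing")
  if (!is.null(config$seed)) set.seed(config$seed)
  k1 <- config$k_d1_true; k2 <- config$k_d2_true
  mean_curve <- ifelse(sample_times <= t_switch,
                       A0 * exp(-k1 * sample_times),
                       A0 * exp(-k1 * t_switch) *
                         exp(-k2 * (sample_times - t_switch)))
  cv <- config$cv_noise
  out <- lapply(seq_len(n_replicates), function(r) {
    if (cv > 0) {
      s2 <- log(1 + cv^2)
      noise <- rlnorm(length(sample_times), meanlog = -s2 / 2,
                      sdlog = sqrt(s2))
    } else noise <- 1
    data.frame(replicate = r, time_s = sample_times,
               abundance = mean_curve * noise)
  })
  do.call(rbind, out)
}

#' Read decay time courses from delimited text
#'
#' Expects columns replicate, time_s, abundance (tab- or comma-separated
#' detected from the header line).
#'
#' @param path file path.
#' @return data.frame with replicate, time_s, abundance.
#' @export
read_decay <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  stopifnot(all(c("replicate", "time_s", "abundance") %in% names(df)))
  df
}
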