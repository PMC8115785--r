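#' Spike-train coincidence factor
#'
#' Chance-corrected, normalized count of co-occupied time bins between two
#' spike trains (Kistler's Gamma). Time `[0, T]` is divided into `K = T/p`
#' bins of width `p`; a bin holding several spikes counts as one occupied
#' bin. With `N1`, `N2` the occupied-bin counts of the two trains and
#' `N_coinc` the number of bins occupied in both,
#' \deqn{\Gamma_{12} = \frac{N_{coinc} - 2 N_1 N_2 / K}
#'                          {\tfrac{1}{2}(N_1 + N_2)} \cdot
#'                     \frac{1}{1 - 2 N_2 / K}.}
#' It equals 1 for identical trains, vanishes in expectation for independent
#' Poisson trains, and is negative for anti-correlated trains. It is not
#' symmetric: train 2 is the rate reference.
#'
#' @param train1,train2 spike times (ms) in `[0, T]`.
#' @param p bin width (ms).
#' @param T duration (ms).
#' @return the coincidence factor, or `NA` (undefined sentinel) when train 2
#'   is empty or the normalization `1 - 2 N2/K` is not positive.
#' @export
coincidence_factor <- function(train1, train2, p = 2, T) {
  if (p <= 0) stop("'p' must be > 0")
  K <- floor(T / p)
  b1 <- unique(pmin(floor(train1 / p), K - 1L))
  b2 <- unique(pmin(floor(train2 / p), K - 1L))
  N1 <- length(b1); N2 <- length(b2)
  norm <- 1 - 2 * N2 / K
  if (N2 == 0L || norm <= 0) return(NA_real_)
  Nco <- length(intersect(b1, b2))
  expected <- 2 * N1 * N2 / K
  (Nco - expected) / (0.5 * (N1 + N2)) / norm
}

#' Mean spike reliability over a set of trials
#'
#' Computes the coincidence factor per neuron between pairs of trials and
#' averages over neurons (and pairs), excluding undefined values. For more
#' than two trials, consecutive pairs (1,2), (2,3), ... are used, with the
#' later trial as the rate reference. The result, written Gamma-bar, is a
#' measure of trial-to-trial reliability: near 1 the network uses a
#' non-degenerate code, near 0 a highly degenerate one.
#'
#' @param trial_rasters list (length >= 2) of per-trial rasters, each a list
#'   of per-neuron spike-time vectors (ms), all on `[0, T]`.
#' @param p bin width (ms).
#' @param T duration (ms).
#' @return list with `gamma_mean` (the average; `NA` if every pair was
#'   undefined), `n_defined` and `n_undefined` pair counts.
#' @export
mean_reliability <- function(trial_rasters, p = 2, T) {
  stopifnot(length(trial_rasters) >= 2L)
  N <- length(trial_rasters[[1L]])
  vals <- c()
  for (k in seq_len(length(trial_rasters) - 1L)) {
    r1 <- trial_rasters[[k]]; r2 <- trial_rasters[[k + 1L]]
    vals <- c(vals, vapply(seq_len(N), function(m)
      coincidence_factor(r1[[m]], r2[[m]], p = p, T = T), numeric(1)))
  }
  n_un <- sum(is.na(vals))
  gm <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  list(gamma_mean = gm, n_defined = sum(!is.na(vals)), n_undefined = n_un)
}

#' Normalized mean-squared reconstruction error
#'
#' The MSE between stimulus and estimate divided by the MSE of a quiescent
#' network (estimate identically zero):
#' \eqn{\overline{MSE} = \sum (s - \hat s)^2 / \sum s^2}. Zero means perfect
#' reconstruction; 1 means performance equal to total silence.
#'
#' @param s stimulus samples.
#' @param s_hat estimate samples (same length).
#' @return the normalized MSE, or `NA` when `s` is identically zero.
#' @export
normalized_mse <- function(s, s_hat) {
  if (length(s) != length(s_hat)) stop("'s' and 's_hat' differ in length")
  denom <- sum(s^2)
  if (denom == 0) return(NA_real_)
  sum((s - s_hat)^2) / denom
}

#' Network activity
#'
#' Average firing rate per neuron: total spike count / (N * T), with T in
#' seconds.
#'
#' @param raster list of per-neuron spike-time vectors, or a `pc_sim` result.
#' @param N neuron count (taken from the raster when omitted).
#' @param T duration (ms).
#' @return activity in Hz.
#' @export
network_activity <- function(raster, N = NULL, T) {
  if (inherits(raster, "pc_sim")) {
    if (missing(T)) T <- raster$duration
    raster <- raster$raster$ideal_times
  }
  if (is.null(N)) N <- length(raster)
  if (T <= 0) stop("'T' must be > 0")
  sum(lengths(raster)) / (N * T / 1000)
}

#' Coding efficiency and its amplitude-weighted variants
#'
#' \eqn{E = 1 / (\overline{MSE} \cdot A)} in seconds: the efficiency is high
#' when a small error is achieved with few spikes. The variants weight by the
#' stimulus amplitude: \eqn{E_a = E \cdot a} and \eqn{E_{a^2} = E \cdot a^2},
#' compensating for the fact that small-amplitude stimuli are intrinsically
#' cheaper to encode.
#'
#' @param mse_norm normalized MSE (> 0).
#' @param activity network activity in Hz (> 0).
#' @param amplitude stimulus amplitude (needed for the variants).
#' @return for `efficiency()`, E in seconds (`NA` if either factor is not
#'   positive); the variants scale it by `amplitude` or `amplitude^2`.
#' @export
efficiency <- function(mse_norm, activity) {
  if (is.na(mse_norm) || is.na(activity) || mse_norm <= 0 || activity <= 0)
    return(NA_real_)
  1 / (mse_norm * activity)
}

#' @rdname efficiency
#' @export
efficiency_amp <- function(mse_norm, activity, amplitude)
  efficiency(mse_norm, activity) * amplitude

#' @rdname efficiency
#' @export
efficiency_power <- function(mse_norm, activity, amplitude)
  efficiency(mse_norm, activity) * amplitude^2

#' Full metrics report for a set of simulation trials
#'
#' Convenience wrapper computing Gamma-bar, normalized MSE, activity,
#' efficiency and its variants from one or more `pc_sim` results of the same
#' network and stimulus.
#'
#' @param sims list of `pc_sim` results (>= 1; Gamma-bar needs >= 2).
#' @param p coincidence bin width (ms).
#' @return an object of class `pc_metrics`: list with `gamma_mean`,
#'   `mse_norm`, `activity`, `efficiency`, `efficiency_amp`,
#'   `efficiency_power` and the parameters used. MSE and activity are
#'   averaged over trials.
#' @export
metrics_report <- function(sims, p = 2) {
  if (inherits(sims, "pc_sim")) sims <- list(sims)
  stopifnot(length(sims) >= 1L)
  T <- sims[[1L]]$duration
  mse <- mean(vapply(sims, function(r)
    normalized_mse(r$stimulus_values, r$estimate), numeric(1)))
  act <- mean(vapply(sims, function(r)
    network_activity(r$raster$ideal_times, N = r$N, T = T), numeric(1)))
  gm <- NA_real_
  gamma_flagged <- FALSE
  if (length(sims) >= 2L) {
    mr <- mean_reliability(lapply(sims, function(r) r$raster$ideal_times),
                           p = p, T = T)
    gm <- mr$gamma_mean
    # more undefined than defined pairs: the average is untrustworthy
    gamma_flagged <- mr$n_undefined > mr$n_defined
    if (gamma_flagged)
      warning("more than half of the neuron/trial pairs had an undefined ",
              "coincidence factor; Gamma-bar is based on a minority")
  }
  amp <- sims[[1L]]$stimulus_amplitude
  structure(list(gamma_mean = gm, mse_norm = mse, activity = act,
                 efficiency = efficiency(mse, act),
                 efficiency_amp = if (!is.null(amp))
                   efficiency_amp(mse, act, amp) else NA_real_,
                 efficiency_power = if (!is.null(amp))
                   efficiency_power(mse, act, amp) else NA_real_,
                 gamma_flagged = gamma_flagged,
                 params = list(p = p, n_trials = length(sims), T = T)),
            class = "pc_metrics")
}

#' @export
print.pc_metrics <- function(x, ...) {
  cat("<pc_metrics>\n")
  cat(sprintf("  Gamma-bar:       %s\n",
              ifelse(is.na(x$gamma_mean), "NA", sprintf("%.4f", x$gamma_mean))))
  cat(sprintf("  normalized MSE:  %.4g\n", x$mse_norm))
  cat(sprintf("  activity A:      %.4g Hz\n", x$activity))
  cat(sprintf("  efficiency E:    %.4g s\n", x$efficiency))
  cat(sprintf("  (p = %g ms, %d trial(s), T = %g ms)\n",
              x$params$p, x$params$n_trials, x$params$T))
  invisible(x)
}
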