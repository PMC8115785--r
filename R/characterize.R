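#' Single-neuron and network characterization protocols
#'
#' These functions reproduce standard electrophysiology protocols on model
#' neurons (frequency-current curves, phase-response curves, spike-triggered
#' averages) and network analyses (signal/noise cross-correlograms,
#' population rate, spike-triggered network activity). Protocol outputs are
#' `pc_protocol` objects: lists with `kind`, `x`, `y` and a `params` echo.
#'
#' @name characterize
NULL

new_protocol <- function(kind, x, y, params, extra = list()) {
  structure(c(list(kind = kind, x = x, y = y, params = params), extra),
            class = "pc_protocol")
}

#' @export
print.pc_protocol <- function(x, ...) {
  cat(sprintf("<pc_protocol> %s: %d points\n", x$kind, length(x$x)))
  invisible(x)
}

#' @export
plot.pc_protocol <- function(x, ...) {
  graphics::plot(x$x, x$y, type = "l",
                 xlab = x$params$xlab %||% "x", ylab = x$kind, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

single_neuron_bank <- function(bank) {
  if (!inherits(bank, "pc_filterbank") || bank$N != 1L)
    stop("this protocol needs a single-neuron filter bank (N = 1)")
  bank
}

#' Frequency-current curves from step-and-hold stimuli
#'
#' For each amplitude, drives a single neuron with a step-and-hold input and
#' reports (i) the instantaneous frequency of the first two spikes,
#' `1000/(t2 - t1)` Hz (undefined with fewer than two spikes), and (ii) the
#' mean frequency, spike count over the step duration. Integrator-like
#' (type-1) neurons show a continuous rise of the mean rate from near zero;
#' resonator-like (type-2) neurons respond discontinuously and fire doublets
#' at high amplitude.
#'
#' @param bank single-neuron [filter_bank()].
#' @param amplitudes step amplitudes to probe.
#' @param duration step duration (ms, after the onset).
#' @param onset step onset (ms); a nonzero onset exposes the onset
#'   transient that transient-responding (type-2) cells fire to.
#' @return list with elements `instantaneous` and `mean`, both
#'   `pc_protocol` objects over the amplitude axis, plus `spikes` (the real
#'   spike times per amplitude, step clock).
#' @export
fi_curves <- function(bank, amplitudes, duration = 2000, onset = 50) {
  bank <- single_neuron_bank(bank)
  res <- lapply(amplitudes, function(a) {
    s <- make_stimulus("step_and_hold", amplitude = a,
                       duration = duration + onset, dt = bank$dt,
                       onset = onset)
    sim <- simulate_network(bank, s)
    tt <- sim$raster$real_times[[1L]]
    tt[tt >= onset]
  })
  inst <- vapply(res, function(tt)
    if (length(tt) >= 2L) 1000 / (tt[2L] - tt[1L]) else NA_real_,
    numeric(1))
  mean_f <- vapply(res, function(tt) length(tt) / (duration / 1000),
                   numeric(1))
  params <- list(duration = duration, onset = onset, xlab = "amplitude")
  list(
    instantaneous = new_protocol("fI_instant", amplitudes, inst, params),
    mean = new_protocol("fI_mean", amplitudes, mean_f, params),
    spikes = res)
}

#' Inter-spike intervals of a spike train
#' @param times spike times (ms).
#' @return numeric vector of ISIs (ms).
#' @export
isis <- function(times) diff(sort(times))

## steady-state spikes of a constant-input run: drop the first
## `settle_frac` of the record
steady_spikes <- function(tt, duration, settle_frac = 0.4) {
  tt[tt >= settle_frac * duration]
}

#' Phase-response curve of a periodically firing neuron
#'
#' Drives the neuron with a constant base amplitude until it fires
#' periodically, then delivers a brief pulse at a set of phases of the
#' unperturbed inter-spike interval and reports the normalized shift of the
#' next spike (positive = spike advanced). For doublet-firing neurons the
#' reference interval can be the within-doublet (short) or between-doublet
#' (long) interval.
#'
#' @param bank single-neuron [filter_bank()].
#' @param base_amplitude constant drive.
#' @param pulse_amplitude pulse height (added to the base).
#' @param pulse_width pulse width (ms).
#' @param phases phases in `[0, 1)` of the reference interval.
#' @param interval `"next"` (the following ISI, whatever it is),
#'   `"within"` (short ISI of a doublet pair) or `"between"` (long ISI).
#' @param duration simulation length (ms).
#' @return a `pc_protocol` with `x` = phases, `y` = normalized phase shifts;
#'   `period` and the reference spike time are in `params`.
#' @export
prc <- function(bank, base_amplitude, pulse_amplitude, pulse_width = 0.1,
                phases = seq(0, 0.95, by = 0.05),
                interval = c("next", "within", "between"),
                duration = 3000) {
  bank <- single_neuron_bank(bank)
  interval <- match.arg(interval)
  base <- make_stimulus("constant", amplitude = base_amplitude,
                        duration = duration, dt = bank$dt)
  ref_run <- simulate_network(bank, base)
  tt <- steady_spikes(ref_run$raster$real_times[[1L]], duration)
  if (length(tt) < 4L)
    stop("no stable periodic firing at this base amplitude")
  isi <- diff(tt)
  pick <- switch(interval,
    "next" = 1L,
    "within" = which(isi <= stats::median(isi))[1L],
    "between" = which(isi > stats::median(isi))[1L])
  if (is.null(pick) || is.na(pick) || pick >= length(isi))
    stop("no interval of the requested kind in the steady spike train")
  t_ref <- tt[pick]
  period <- isi[pick]
  t_next <- tt[pick + 1L]
  shifts <- vapply(phases, function(ph) {
    probe <- make_pulse_probe(base_amplitude, pulse_amplitude, pulse_width,
                              pulse_time = t_ref + ph * period,
                              duration = duration, dt = bank$dt)
    run <- simulate_network(bank, probe)
    pt <- run$raster$real_times[[1L]]
    # reference spike must be preserved
    if (!any(abs(pt - t_ref) < 2 * bank$dt)) return(NA_real_)
    nxt <- pt[pt > t_ref + 2 * bank$dt]
    if (!length(nxt)) return(NA_real_)
    (t_next - nxt[1L]) / period        # positive = advanced
  }, numeric(1))
  new_protocol("PRC", phases, shifts,
               list(base_amplitude = base_amplitude,
                    pulse_amplitude = pulse_amplitude,
                    pulse_width = pulse_width, interval = interval,
                    period = period, t_ref = t_ref, xlab = "phase"))
}

#' Spike-triggered average stimulus
#'
#' Drives the neuron with causally exponentially filtered white noise
#' (time constant `tau`, the fast probe used for receptive-field mapping)
#' and averages the stimulus over a window preceding each emitted spike.
#'
#' @param bank single-neuron [filter_bank()].
#' @param noise_amplitude stimulus standard deviation.
#' @param tau probe filter time constant (ms).
#' @param duration simulation length (ms).
#' @param window pre-spike window (ms).
#' @param seed stimulus seed.
#' @return a `pc_protocol` with `x` = lags (ms, negative = before the
#'   spike), `y` = the average stimulus, `n_spikes` in `params`.
#' @export
sta <- function(bank, noise_amplitude, tau = 1, duration = 30000,
                window = 15, seed = 1L) {
  bank <- single_neuron_bank(bank)
  s <- make_stimulus("filtered_noise", amplitude = noise_amplitude,
                     duration = duration, dt = bank$dt, tau = tau,
                     filter_mode = "causal", seed = seed)
  sim <- simulate_network(bank, s)
  tt <- sim$raster$real_times[[1L]]
  sta_of_times(s, tt, window = window,
               params = list(noise_amplitude = noise_amplitude, tau = tau))
}

## STA of an arbitrary set of trigger times on a stimulus (also used for
## shuffle controls in tests)
sta_of_times <- function(stimulus, times, window = 15, params = list()) {
  dt <- stimulus$dt
  nw <- as.integer(round(window / dt))
  ks <- as.integer(round(times / dt)) + 1L
  ks <- ks[ks > nw & ks <= length(stimulus$values)]
  if (!length(ks)) stop("no usable trigger times for the STA")
  acc <- numeric(nw + 1L)
  for (k in ks) acc <- acc + stimulus$values[(k - nw):k]
  new_protocol("STA", x = seq(-nw, 0) * dt, y = acc / length(ks),
               params = c(params, list(window = window,
                                       n_spikes = length(ks),
                                       xlab = "lag (ms)")))
}

#' Modality of a protocol curve
#'
#' Operationalizes the unimodal/bimodal classification of response curves:
#' the curve is smoothed with a Gaussian kernel (`sigma`, in x-axis units)
#' and the number of sign changes of the smoothed curve is counted, ignoring
#' samples below `tol` times the curve's maximum magnitude. Zero sign
#' changes = unimodal (single-signed); one or more = bimodal/multimodal.
#'
#' @param y curve values on a uniform axis.
#' @param dx axis step.
#' @param sigma smoothing width in axis units.
#' @param tol relative dead-band: lobes smaller than `tol` times the
#'   dominant lobe are ignored (threshold-crossing protocols leave small
#'   ripples around zero that a visual classification would discount).
#' @return list with `n_sign_changes` and `label`.
#' @export
modality <- function(y, dx = 1, sigma = 1, tol = 0.2) {
  y <- y[!is.na(y)]
  if (!length(y)) return(list(n_sign_changes = NA_integer_, label = NA))
  ns <- max(1L, as.integer(round(sigma / dx)))
  kern <- stats::dnorm(seq(-3 * ns, 3 * ns), sd = ns)
  kern <- kern / sum(kern)
  # replicate the edges so the ends of the curve are not lost to the filter
  pad <- 3L * ns
  yp <- c(rep(y[1L], pad), y, rep(y[length(y)], pad))
  ys <- as.numeric(stats::filter(yp, kern, sides = 2))
  ys <- ys[(pad + 1L):(pad + length(y))]
  ys <- ys[!is.na(ys)]
  sgn <- sign(ys)
  sgn[abs(ys) < tol * max(abs(ys))] <- 0
  sgn <- sgn[sgn != 0]
  n <- sum(diff(sgn) != 0)
  list(n_sign_changes = n,
       label = if (n == 0) "unimodal" else "bimodal")
}

bin_counts <- function(times, binwidth, K) {
  b <- floor(times / binwidth) + 1
  b <- b[b >= 1 & b <= K]
  tabulate(b, nbins = K)
}

## cross-correlogram of two binned sequences, corrected for the chance
## coincidence level (the product of the mean counts): the covariance form
## that lets anti-correlated pairs go negative
ccg_counts <- function(x, y, max_lag_bins) {
  K <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  vapply(-max_lag_bins:max_lag_bins, function(l) {
    if (l >= 0) sum(xc[seq_len(K - l)] * yc[seq_len(K - l) + l])
    else sum(xc[seq_len(K + l) - l] * yc[seq_len(K + l)])
  }, numeric(1))
}

#' Signal and noise cross-correlograms between two neurons
#'
#' Given repeated trials of the same stimulus, the signal correlogram is the
#' cross-correlogram of the trial-averaged spike trains of the two neurons
#' (the correlation induced by common stimulus tuning); the noise
#' correlogram is the average over trials of the per-trial cross-correlogram
#' minus the signal correlogram (the correlation of the trial-to-trial
#' fluctuations). Correlograms are chance-corrected (mean counts
#' subtracted, so anti-correlated pairs are negative) and normalized by the
#' total average number of spikes of the pair per trial.
#'
#' @param trial_rasters list of per-trial rasters (each a list of per-neuron
#'   spike-time vectors), or a list of `pc_sim` objects.
#' @param a,b neuron indices.
#' @param T trial duration (ms).
#' @param binwidth correlogram bin (ms).
#' @param max_lag maximum lag (ms).
#' @return an object of class `pc_correlogram`: list with `lags` (ms),
#'   `signal`, `noise`, `normalization`, `pair`.
#' @export
correlograms <- function(trial_rasters, a, b, T, binwidth = 1,
                         max_lag = 50) {
  trial_rasters <- lapply(trial_rasters, function(r)
    if (inherits(r, "pc_sim")) r$raster$ideal_times else r)
  stopifnot(length(trial_rasters) >= 2L)
  K <- as.integer(floor(T / binwidth))
  ml <- as.integer(round(max_lag / binwidth))
  n_tr <- length(trial_rasters)
  xa <- matrix(0, n_tr, K); xb <- matrix(0, n_tr, K)
  for (i in seq_len(n_tr)) {
    xa[i, ] <- bin_counts(trial_rasters[[i]][[a]], binwidth, K)
    xb[i, ] <- bin_counts(trial_rasters[[i]][[b]], binwidth, K)
  }
  norm <- mean(rowSums(xa) + rowSums(xb))
  if (norm == 0) stop("silent neuron pair: correlogram undefined")
  sig <- ccg_counts(colMeans(xa), colMeans(xb), ml) / norm
  per_trial <- sapply(seq_len(n_tr), function(i)
    ccg_counts(xa[i, ], xb[i, ], ml))
  noise <- rowMeans(per_trial) / norm - sig
  structure(list(lags = (-ml:ml) * binwidth, signal = sig, noise = noise,
                 normalization = norm, pair = c(a, b),
                 params = list(binwidth = binwidth, max_lag = max_lag,
                               n_trials = n_tr, T = T)),
            class = "pc_correlogram")
}

#' @rdname correlograms
#' @export
signal_correlogram <- function(trial_rasters, a, b, T, binwidth = 1,
                               max_lag = 50) {
  cc <- correlograms(trial_rasters, a, b, T, binwidth, max_lag)
  new_protocol("signal_correlogram", cc$lags, cc$signal, cc$params)
}

#' @rdname correlograms
#' @export
noise_correlogram <- function(trial_rasters, a, b, T, binwidth = 1,
                              max_lag = 50) {
  cc <- correlograms(trial_rasters, a, b, T, binwidth, max_lag)
  new_protocol("noise_correlogram", cc$lags, cc$noise, cc$params)
}

#' @export
print.pc_correlogram <- function(x, ...) {
  cat(sprintf("<pc_correlogram> pair (%d, %d), lags +-%g ms, %d trials\n",
              x$pair[1L], x$pair[2L], max(x$lags), x$params$n_trials))
  invisible(x)
}

#' @export
plot.pc_correlogram <- function(x, ...) {
  graphics::plot(x$lags, x$signal, type = "l", col = "black",
                 xlab = "lag (ms)", ylab = "correlation", ...)
  graphics::lines(x$lags, x$noise, col = "red")
  graphics::legend("topright", c("signal", "noise"),
                   col = c("black", "red"), lty = 1, bty = "n")
  invisible(x)
}

#' Gaussian-smoothed population rate
#'
#' Convolves every spike with a normalized Gaussian kernel (default sigma =
#' 6 ms) and sums over the chosen neurons, yielding an instantaneous
#' population rate in spikes per second per neuron (a proxy for the local
#' field potential / network activity).
#'
#' @param raster per-neuron spike-time list or a `pc_sim`.
#' @param T duration (ms).
#' @param subset neuron indices to include (default all).
#' @param sigma Gaussian width (ms).
#' @param rate_dt sampling step of the rate trace (ms).
#' @return list with `t` (ms) and `rate` (Hz per neuron).
#' @export
population_rate <- function(raster, T, subset = NULL, sigma = 6,
                            rate_dt = 1) {
  if (inherits(raster, "pc_sim")) {
    if (missing(T)) T <- raster$duration
    raster <- raster$raster$real_times
  }
  if (is.null(subset)) subset <- seq_along(raster)
  K <- as.integer(round(T / rate_dt))
  counts <- numeric(K)
  for (m in subset) counts <- counts + bin_counts(raster[[m]], rate_dt, K)
  ns <- max(1L, as.integer(round(sigma / rate_dt)))
  kern <- stats::dnorm(seq(-4 * ns, 4 * ns), sd = sigma / rate_dt)
  kern <- kern / (sum(kern) * rate_dt / 1000)  # unit area per spike -> Hz
  sm <- as.numeric(stats::filter(counts, kern, sides = 2))
  sm[is.na(sm)] <- 0
  list(t = (seq_len(K) - 0.5) * rate_dt, rate = sm / length(subset))
}

#' Spike-triggered network activity
#'
#' Averages the Gaussian-smoothed population rate in a window around each
#' spike of a reference neuron subset: a measure of how strongly those
#' neurons are coupled to the overall network activity ("chorists" show a
#' tall central peak, "soloists" a flat profile).
#'
#' @param raster per-neuron spike-time list or a `pc_sim`.
#' @param subset reference neuron indices (their spikes trigger the
#'   averages).
#' @param T duration (ms).
#' @param rate_subset neurons entering the population rate (default all).
#' @param sigma Gaussian width (ms).
#' @param window half-width of the lag window (ms).
#' @param rate_dt rate sampling step (ms).
#' @return a `pc_protocol` with `x` = lags (ms) and `y` = average population
#'   rate (Hz/neuron); also carries the rate-vs-subset cross-correlogram as
#'   `rate_ccg`.
#' @export
spike_triggered_population_activity <- function(raster, subset, T,
                                                rate_subset = NULL,
                                                sigma = 6, window = 100,
                                                rate_dt = 1) {
  if (inherits(raster, "pc_sim")) {
    if (missing(T)) T <- raster$duration
    raster <- raster$raster$real_times
  }
  if (!length(subset)) stop("empty reference subset")
  pr <- population_rate(raster, T, subset = rate_subset, sigma = sigma,
                        rate_dt = rate_dt)
  nw <- as.integer(round(window / rate_dt))
  K <- length(pr$rate)
  acc <- numeric(2L * nw + 1L)
  n_used <- 0L
  for (m in subset) {
    ks <- as.integer(round(raster[[m]] / rate_dt)) + 1L
    ks <- ks[ks > nw & ks <= K - nw]
    for (k in ks) {
      acc <- acc + pr$rate[(k - nw):(k + nw)]
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0L) stop("no spikes in the reference subset")
  # rate-vs-neuron cross-correlogram: correlation of the population rate
  # with each reference neuron's own smoothed rate, averaged over neurons
  lags <- seq(-nw, nw)
  ccg <- numeric(2L * nw + 1L)
  n_cc <- 0L
  for (m in subset) {
    rm <- population_rate(raster[m], T, sigma = sigma, rate_dt = rate_dt)
    if (stats::sd(rm$rate) == 0) next
    for (i in seq_along(lags)) {
      l <- lags[i]
      if (l >= 0) {
        idx <- seq_len(K - l)
        ccg[i] <- ccg[i] + stats::cor(rm$rate[idx], pr$rate[idx + l])
      } else {
        idx <- seq_len(K + l)
        ccg[i] <- ccg[i] + stats::cor(rm$rate[idx - l], pr$rate[idx])
      }
    }
    n_cc <- n_cc + 1L
  }
  new_protocol("spike_triggered_network_activity",
               x = seq(-nw, nw) * rate_dt, y = acc / n_used,
               params = list(sigma = sigma, window = window,
                             n_spikes = n_used, xlab = "lag (ms)"),
               extra = list(rate_ccg = if (n_cc > 0) ccg / n_cc else NULL))
}
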