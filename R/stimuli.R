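#' Synthetic one-dimensional stimuli
#'
#' Generates the stimulus classes used throughout the package: constant
#' levels, step-and-hold currents, sinusoids, and exponentially filtered
#' white noise (an Ornstein-Uhlenbeck-like process with autocorrelation time
#' constant tau). For stochastic stimuli "amplitude" means the sample
#' standard deviation of the rescaled, mean-centred signal; for the
#' deterministic kinds it is the level (constant, step) or the peak (sine).
#'
#' @param kind one of `"constant"`, `"step_and_hold"`, `"sine"`,
#'   `"filtered_noise"`.
#' @param amplitude level / peak / target standard deviation (see above).
#' @param duration total duration (ms).
#' @param dt time step (ms).
#' @param frequency sine frequency in Hz.
#' @param onset step onset time (ms) for `step_and_hold` (0 before, level
#'   after).
#' @param tau autocorrelation time constant (ms) of the filtered noise.
#' @param filter_mode `"zero_phase"` (forward-backward exponential filtering;
#'   the stimulus used in network experiments) or `"causal"` (forward-only
#'   exponential filter, used for spike-triggered-average probes).
#' @param seed RNG seed (filtered noise only).
#' @return an object of class `pc_stimulus`: list with `dt`, `values`, and a
#'   `meta` record of the generating parameters.
#' @examples
#' s <- make_stimulus("filtered_noise", amplitude = 10, duration = 1000,
#'                    dt = 0.1, tau = 15, seed = 1)
#' sd(s$values)  # exactly 10
#' @export
make_stimulus <- function(kind = c("constant", "step_and_hold", "sine",
                                   "filtered_noise"),
                          amplitude, duration, dt = 0.1,
                          frequency = NULL, onset = 0, tau = NULL,
                          filter_mode = c("zero_phase", "causal"),
                          seed = NULL) {
  kind <- match.arg(kind)
  filter_mode <- match.arg(filter_mode)
  if (duration <= 0) stop("'duration' must be > 0")
  n <- as.integer(round(duration / dt))
  t <- (seq_len(n) - 1L) * dt
  v <- switch(kind,
    constant = rep(amplitude, n),
    step_and_hold = ifelse(t < onset, 0, amplitude),
    sine = {
      if (is.null(frequency)) stop("sine stimulus needs 'frequency' (Hz)")
      amplitude * sin(2 * pi * frequency * t / 1000)
    },
    filtered_noise = {
      if (is.null(tau) || tau <= 0) stop("filtered noise needs 'tau' > 0")
      if (amplitude <= 0) stop("filtered noise needs 'amplitude' > 0")
      if (!is.null(seed)) set.seed(seed)
      # white noise of variance 1/dt so the filtered variance is
      # grid-independent; a discarded pad of several tau at both ends makes
      # the kept stretch stationary (no filter start-up transient)
      pad <- as.integer(ceiling(6 * tau / dt))
      w <- stats::rnorm(n + 2L * pad, sd = 1 / sqrt(dt))
      x <- if (filter_mode == "zero_phase") exp_filter_zero_phase(w, tau, dt)
           else exp_filter_causal(w, tau, dt)
      x <- x[pad + seq_len(n)]
      x <- x - mean(x)
      s <- stats::sd(x)
      if (s == 0) stop("degenerate noise draw")
      x * (amplitude / s)
    })
  structure(list(dt = dt, values = v,
                 meta = list(kind = kind, amplitude = amplitude,
                             duration = duration, frequency = frequency,
                             onset = onset, tau = tau,
                             filter_mode = if (kind == "filtered_noise")
                               filter_mode else NULL,
                             seed = seed)),
            class = "pc_stimulus")
}

#' @export
print.pc_stimulus <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<pc_stimulus> kind = %s, %d samples, dt = %g ms (%g ms)\n",
              m$kind, length(x$values), x$dt, length(x$values) * x$dt))
  invisible(x)
}

#' @export
plot.pc_stimulus <- function(x, ...) {
  t <- (seq_along(x$values) - 1L) * x$dt
  graphics::plot(t, x$values, type = "l", xlab = "time (ms)",
                 ylab = "stimulus", ...)
  invisible(x)
}

## Causal first-order exponential filter with unit DC gain:
## y[k] = a*y[k-1] + (1-a)*x[k], a = exp(-dt/tau), zero initial state.
exp_filter_causal <- function(x, tau, dt) {
  a <- exp(-dt / tau)
  as.numeric(stats::filter((1 - a) * x, a, method = "recursive"))
}

#' Zero-phase exponential filtering
#'
#' Applies a unit-DC-gain causal exponential filter with time constant `tau`
#' forward in time and then backward, yielding a zero-phase (symmetric)
#' smoothing with autocorrelation time constant `tau`.
#'
#' @param x numeric samples.
#' @param tau filter time constant (ms).
#' @param dt sample step (ms).
#' @return filtered samples, same length as `x`.
#' @export
exp_filter_zero_phase <- function(x, tau, dt) {
  if (tau <= 0) stop("'tau' must be > 0")
  y <- exp_filter_causal(x, tau, dt)
  rev(exp_filter_causal(rev(y), tau, dt))
}

#' Bank of noise signals shared among neurons
#'
#' Creates `n_copies` independent filtered-noise signals and an assignment of
#' each of `N` neurons to one copy. `n_copies = 1` means all neurons receive
#' the same noise; `n_copies = N` means fully independent noise. Copies are
#' assigned in contiguous index blocks of size `ceiling(N / n_copies)` by
#' default, or at random (seeded) with `assignment = "random"`.
#'
#' @param N number of neurons.
#' @param n_copies number of distinct noise signals (1..N).
#' @param amplitude standard deviation of each copy.
#' @param tau autocorrelation time constant (ms).
#' @param duration signal duration (ms).
#' @param dt time step (ms).
#' @param seed RNG seed; copy `i` uses the substream `seed + i - 1`.
#' @param assignment `"blocks"` or `"random"`.
#' @return an object of class `pc_noisebank`: list with `n_copies`,
#'   `assignment` (neuron -> copy index), `copies` (list of `pc_stimulus`),
#'   `amplitude`.
#' @export
make_noise_bank <- function(N, n_copies, amplitude, tau, duration, dt = 0.1,
                            seed = 1L, assignment = c("blocks", "random")) {
  assignment <- match.arg(assignment)
  if (n_copies < 1L || n_copies > N)
    stop("'n_copies' must be between 1 and N")
  copies <- lapply(seq_len(n_copies), function(i)
    make_stimulus("filtered_noise", amplitude = amplitude,
                  duration = duration, dt = dt, tau = tau,
                  seed = seed + i - 1L))
  block <- ceiling(N / n_copies)
  assign <- pmin(((seq_len(N) - 1L) %/% block) + 1L, n_copies)
  if (assignment == "random") {
    set.seed(seed + n_copies)
    assign <- assign[sample.int(N)]
  }
  structure(list(n_copies = n_copies, assignment = assign, copies = copies,
                 amplitude = amplitude, tau = tau, dt = dt, seed = seed),
            class = "pc_noisebank")
}

#' @export
print.pc_noisebank <- function(x, ...) {
  cat(sprintf("<pc_noisebank> %d copies over %d neurons, sd = %g, tau = %g ms\n",
              x$n_copies, length(x$assignment), x$amplitude, x$tau))
  invisible(x)
}

#' Constant stimulus with a brief rectangular probe pulse
#'
#' A constant base level with one additive rectangular pulse, used for
#' phase-response-curve protocols. A pulse of width equal to `dt` elevates
#' exactly one sample.
#'
#' @param base_level constant base amplitude.
#' @param pulse_amplitude additive pulse height.
#' @param pulse_width pulse width (ms, >= dt).
#' @param pulse_time pulse onset (ms) within `[0, duration)`.
#' @param duration total duration (ms).
#' @param dt time step (ms).
#' @return a `pc_stimulus`.
#' @export
make_pulse_probe <- function(base_level, pulse_amplitude, pulse_width,
                             pulse_time, duration, dt = 0.1) {
  if (pulse_time < 0 || pulse_time >= duration)
    stop("pulse must lie inside [0, duration)")
  n <- as.integer(round(duration / dt))
  v <- rep(base_level, n)
  i0 <- as.integer(round(pulse_time / dt)) + 1L
  nw <- max(1L, as.integer(round(pulse_width / dt)))
  idx <- i0:min(n, i0 + nw - 1L)
  v[idx] <- v[idx] + pulse_amplitude
  structure(list(dt = dt, values = v,
                 meta = list(kind = "pulse_probe", amplitude = base_level,
                             pulse_amplitude = pulse_amplitude,
                             pulse_width = pulse_width,
                             pulse_time = pulse_time, duration = duration)),
            class = "pc_stimulus")
}

#' Read a one-dimensional signal from a single-column CSV
#'
#' Ingests an external signal (for example a recorded local-field-potential
#' trace) as a stimulus, given its sampling step.
#'
#' @param path CSV file with one numeric column (header optional) or the two
#'   columns `time_ms`, `value`.
#' @param dt sampling step of the recording (ms); ignored if the file has a
#'   `time_ms` column.
#' @return a `pc_stimulus` of kind `"external"`.
#' @export
read_stimulus_csv <- function(path, dt = NULL) {
  df <- utils::read.csv(path)
  if (!is.data.frame(df) || ncol(df) == 0L) stop("empty stimulus file")
  if ("value" %in% names(df) && "time_ms" %in% names(df)) {
    dt <- diff(df$time_ms[1:2])
    v <- df$value
  } else {
    if (is.null(dt)) stop("single-column input needs an explicit 'dt'")
    v <- df[[1L]]
  }
  structure(list(dt = dt, values = as.numeric(v),
                 meta = list(kind = "external", amplitude = stats::sd(v),
                             duration = length(v) * dt, source = path)),
            class = "pc_stimulus")
}

#' Write a stimulus as CSV with a JSON parameter sidecar
#'
#' @param s a `pc_stimulus`.
#' @param csv_path output CSV (`time_ms`, `value`).
#' @param json_path optional JSON sidecar with the `meta` record.
#' @return invisibly, `s`.
#' @export
write_stimulus_csv <- function(s, csv_path, json_path = NULL) {
  stopifnot(inherits(s, "pc_stimulus"))
  df <- data.frame(time_ms = (seq_along(s$values) - 1L) * s$dt,
                   value = s$values)
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(s$meta, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  invisible(s)
}
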