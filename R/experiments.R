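#' Configuration for a canned experiment
#'
#' Builds a validated configuration for [run_experiment()]. Defaults follow
#' the study conditions used throughout the package: networks of N = 100
#' neurons with Delta = 7.5 ms, a 2.5 s main stimulus preceded by a 500 ms
#' random start-stimulus for trial protocols, stimulus grids spanning
#' amplitudes 1-40 and autocorrelation time constants 2-150 ms, and noise
#' grids spanning relative amplitudes 0-1.5 with 1-100 noise copies. The
#' `scale` factor shrinks durations and trial counts proportionally for
#' desk-scale runs.
#'
#' @param experiment one of `"demo"`, `"sweep_efficiency"`, `"sweep_noise"`,
#'   `"correlations"`, `"coherence"`, `"single_neuron"`.
#' @param network population kind (see [build_population()]).
#' @param N neuron count.
#' @param delta,nu,mu,dt network parameters (ms / dimensionless).
#' @param amplitudes,taus stimulus grid (sweeps).
#' @param noise_rel,noise_copies noise grid (`sweep_noise`).
#' @param amplitude,tau fixed stimulus parameters (non-sweep experiments).
#' @param duration main-stimulus duration (ms, before scaling).
#' @param start_duration start-stimulus length (ms).
#' @param n_trials trials per condition (before scaling).
#' @param seed master seed; all RNG derives from it.
#' @param scale scale factor in (0, 1] applied to `duration` and `n_trials`.
#' @param normalize filter normalization mode.
#' @return an `pc_experiment_config` list.
#' @export
experiment_config <- function(experiment = c("demo", "sweep_efficiency",
                                             "sweep_noise", "correlations",
                                             "coherence", "single_neuron"),
                              network = "homogeneous", N = 100,
                              delta = 7.5, nu = 1.5, mu = 1.5, dt = 0.1,
                              amplitudes = c(1, 2.7, 5, 10, 20, 40),
                              taus = c(2, 5, 15, 50, 150),
                              noise_rel = c(0, 0.25, 0.5, 1, 1.5),
                              noise_copies = c(1, 2, 5, 10, 25, 100),
                              amplitude = 10, tau = 15,
                              duration = 2500, start_duration = 500,
                              n_trials = 10, seed = 1L, scale = 1,
                              normalize = "type1") {
  experiment <- match.arg(experiment)
  if (scale <= 0 || scale > 1) stop("'scale' must be in (0, 1]")
  if (experiment == "sweep_noise" && any(noise_copies > N))
    stop("noise_copies cannot exceed N")
  cfg <- list(experiment = experiment, network = network, N = N,
              delta = delta, nu = nu, mu = mu, dt = dt,
              amplitudes = amplitudes, taus = taus,
              noise_rel = noise_rel, noise_copies = noise_copies,
              amplitude = amplitude, tau = tau,
              duration = max(10 * delta, duration * scale),
              start_duration = start_duration,
              n_trials = max(2L, as.integer(ceiling(n_trials * scale))),
              seed = as.integer(seed), scale = scale,
              normalize = normalize)
  class(cfg) <- "pc_experiment_config"
  cfg
}

cfg_bank <- function(cfg, network = cfg$network) {
  filter_bank(network, N = cfg$N, delta = cfg$delta, nu = cfg$nu,
              mu = cfg$mu, dt = cfg$dt, seed = cfg$seed,
              normalize = cfg$normalize)
}

#' Run a canned experiment
#'
#' Dispatches on `config$experiment`:
#' \describe{
#'   \item{demo}{network responses to constant, 5 Hz and 80 Hz inputs
#'     (amplitude `config$amplitude`, spike costs as configured); returns a
#'     metrics table and the simulations.}
#'   \item{sweep_efficiency}{trial-pair protocol over the amplitude x tau
#'     grid; per cell: activity A, reliability Gamma-bar, normalized MSE and
#'     efficiency E (with amplitude-weighted variants), averaged over
#'     trials.}
#'   \item{sweep_noise}{fixed stimulus, grid of noise relative amplitude x
#'     number of noise copies; per cell A, MSE, E.}
#'   \item{correlations}{repeated trials of one stimulus with fresh noise
#'     per trial (half independent, half shared within blocks of 10);
#'     signal/noise correlograms for representative neuron pairs.}
#'   \item{coherence}{one long run of the same configuration;
#'     spike-triggered network activity per filter-kind subset.}
#'   \item{single_neuron}{f-I curves, PRC and STA for a type-1 and a type-2
#'     neuron.}
#' }
#' All randomness derives from `config$seed`; rerunning a config reproduces
#' its tables exactly.
#'
#' @param config an [experiment_config()].
#' @return a list with a `table` (tidy data frame) and experiment-specific
#'   result objects; every row of `table` carries the config parameters.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "pc_experiment_config"))
  switch(config$experiment,
    demo = run_demo(config),
    sweep_efficiency = run_sweep_efficiency(config),
    sweep_noise = run_sweep_noise(config),
    correlations = run_correlations(config),
    coherence = run_coherence(config),
    single_neuron = run_single_neuron(config))
}

cfg_cols <- function(cfg, ...) {
  data.frame(network = cfg$network, N = cfg$N, delta = cfg$delta,
             nu = cfg$nu, mu = cfg$mu, dt = cfg$dt, seed = cfg$seed,
             scale = cfg$scale, ...)
}

run_demo <- function(cfg) {
  bank <- cfg_bank(cfg)
  dur <- cfg$duration
  stims <- list(
    constant = make_stimulus("constant", amplitude = cfg$amplitude,
                             duration = dur, dt = cfg$dt),
    sine_5Hz = make_stimulus("sine", amplitude = cfg$amplitude,
                             duration = dur, dt = cfg$dt, frequency = 5),
    sine_80Hz = make_stimulus("sine", amplitude = cfg$amplitude,
                              duration = dur, dt = cfg$dt, frequency = 80))
  sims <- lapply(stims, function(s) simulate_network(bank, s))
  tab <- do.call(rbind, Map(function(nm, s, sim) {
    cfg_cols(cfg, stimulus = nm, amplitude = cfg$amplitude,
             mse_norm = normalized_mse(s$values, sim$estimate),
             activity = network_activity(sim))
  }, names(stims), stims, sims))
  rownames(tab) <- NULL
  list(table = tab, sims = sims)
}

sweep_cell <- function(bank, cfg, amplitude, tau, cell_seed) {
  s <- make_stimulus("filtered_noise", amplitude = amplitude,
                     duration = cfg$duration, dt = cfg$dt, tau = tau,
                     seed = cell_seed)
  sims <- run_trials(bank, s, n_trials = cfg$n_trials,
                     start_duration = cfg$start_duration,
                     seeds = cell_seed * 1000L + seq_len(cfg$n_trials))
  rep <- metrics_report(sims)
  data.frame(amplitude = amplitude, tau = tau,
             activity = rep$activity, gamma_mean = rep$gamma_mean,
             mse_norm = rep$mse_norm, efficiency = rep$efficiency,
             efficiency_amp = rep$efficiency_amp,
             efficiency_power = rep$efficiency_power,
             n_trials = cfg$n_trials)
}

run_sweep_efficiency <- function(cfg) {
  bank <- cfg_bank(cfg)
  grid <- expand.grid(amplitude = cfg$amplitudes, tau = cfg$taus)
  rows <- lapply(seq_len(nrow(grid)), function(i)
    cbind(cfg_cols(cfg),
          sweep_cell(bank, cfg, grid$amplitude[i], grid$tau[i],
                     cell_seed = cfg$seed + 17L * i)))
  list(table = do.call(rbind, rows))
}

run_sweep_noise <- function(cfg) {
  bank <- cfg_bank(cfg)
  grid <- expand.grid(noise_rel = cfg$noise_rel,
                      n_copies = cfg$noise_copies)
  dur <- cfg$duration
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    rel <- grid$noise_rel[i]; nc <- grid$n_copies[i]
    reps <- lapply(seq_len(cfg$n_trials), function(r) {
      # one stimulus per replicate, shared across all noise-grid cells
      s <- make_stimulus("filtered_noise", amplitude = cfg$amplitude,
                         duration = dur, dt = cfg$dt, tau = cfg$tau,
                         seed = cfg$seed + r)
      noise <- if (rel > 0)
        make_noise_bank(cfg$N, nc, amplitude = rel * cfg$amplitude,
                        tau = cfg$tau, duration = dur, dt = cfg$dt,
                        seed = cfg$seed + 500000L + 1000L * i + r)
      sim <- simulate_network(bank, s, noise = noise)
      c(mse = normalized_mse(s$values, sim$estimate),
        act = network_activity(sim))
    })
    mse <- mean(vapply(reps, `[[`, numeric(1), "mse"))
    act <- mean(vapply(reps, `[[`, numeric(1), "act"))
    cbind(cfg_cols(cfg),
          data.frame(amplitude = cfg$amplitude, tau = cfg$tau,
                     noise_rel = rel, n_copies = nc, mse_norm = mse,
                     activity = act, efficiency = efficiency(mse, act),
                     n_seeds = cfg$n_trials))
  })
  list(table = do.call(rbind, rows))
}

## noise composition of the correlation/coherence protocols: half the noise
## power independent per neuron, half shared within blocks of 10 neurons
correlation_noise <- function(cfg, dur, seed) {
  list(
    make_noise_bank(cfg$N, cfg$N, amplitude = 0.5, tau = cfg$tau,
                    duration = dur, dt = cfg$dt, seed = seed),
    make_noise_bank(cfg$N, max(1L, cfg$N %/% 10L), amplitude = 0.5,
                    tau = cfg$tau, duration = dur, dt = cfg$dt,
                    seed = seed + 250000L))
}

## representative neurons of the mixed network built by build_population:
## quarters in order type1 / off_type1 / type2 / off_type2. Shared-noise
## blocks span 10 consecutive neurons, so (a, a+1) shares a source and
## (a, a+12) does not.
mixed_indices <- function(N) {
  q <- N %/% 4L
  list(t1_a = 1L, t1_indep = min(13L, q), t1_shared = 2L, t1_off = q + 1L,
       t2_a = 2L * q + 1L, t2_indep = 2L * q + min(13L, q),
       t2_shared = 2L * q + 2L, t2_off = 3L * q + 1L)
}

run_correlations <- function(cfg) {
  cfg$network <- "type1_type2"
  bank <- cfg_bank(cfg)
  dur <- cfg$duration
  s <- make_stimulus("filtered_noise", amplitude = cfg$amplitude,
                     duration = dur, dt = cfg$dt, tau = cfg$tau,
                     seed = cfg$seed)
  rasters <- lapply(seq_len(cfg$n_trials), function(r) {
    noise <- correlation_noise(cfg, dur, seed = cfg$seed + 1000L * r)
    simulate_network(bank, s, noise = noise)$raster$ideal_times
  })
  ix <- mixed_indices(cfg$N)
  # pairs: same-kind on-on (independent noise), on-off, cross-kind, and an
  # on-on pair sharing a noise block
  pairs <- list(
    t1_on_on = c(ix$t1_a, ix$t1_indep),
    t1_on_off = c(ix$t1_a, ix$t1_off),
    t1_on_on_shared = c(ix$t1_a, ix$t1_shared),
    t2_on_on = c(ix$t2_a, ix$t2_indep),
    t2_on_off = c(ix$t2_a, ix$t2_off),
    t1_t2_on = c(ix$t1_a, ix$t2_a))
  cors <- lapply(pairs, function(p)
    correlograms(rasters, p[1L], p[2L], T = dur))
  tab <- do.call(rbind, Map(function(nm, cc)
    cbind(cfg_cols(cfg),
          data.frame(pair = nm, a = cc$pair[1L], b = cc$pair[2L],
                     lag_ms = cc$lags, signal = cc$signal,
                     noise = cc$noise)),
    names(cors), cors))
  rownames(tab) <- NULL
  list(table = tab, correlograms = cors, rasters = rasters)
}

run_coherence <- function(cfg) {
  cfg$network <- "type1_type2"
  bank <- cfg_bank(cfg)
  dur <- cfg$duration
  s <- make_stimulus("filtered_noise", amplitude = cfg$amplitude,
                     duration = dur, dt = cfg$dt, tau = cfg$tau,
                     seed = cfg$seed)
  noise <- correlation_noise(cfg, dur, seed = cfg$seed + 77L)
  sim <- simulate_network(bank, s, noise = noise)
  q <- cfg$N %/% 4L
  t1_on <- seq_len(q); t2_on <- (2L * q + 1L):(3L * q)
  stna <- list(
    type1 = spike_triggered_population_activity(sim, t1_on, T = dur),
    type2 = spike_triggered_population_activity(sim, t2_on, T = dur))
  tab <- do.call(rbind, Map(function(nm, pr)
    cbind(cfg_cols(cfg),
          data.frame(subset = nm, lag_ms = pr$x, stna = pr$y)),
    names(stna), stna))
  rownames(tab) <- NULL
  list(table = tab, stna = stna, sim = sim,
       rate = population_rate(sim, T = dur))
}

run_single_neuron <- function(cfg) {
  mk <- function(kind) filter_bank(list(neuron_spec(kind)), delta = cfg$delta,
                                   nu = cfg$nu, mu = cfg$mu, dt = cfg$dt,
                                   normalize = cfg$normalize)
  amps <- seq(0.5, 8, by = 0.5)
  # the bimodal (type-2) filter has a negative window integral, so its
  # protocols are run on the sign-inverted variant, which positive drives
  # excite; this is purely a sign convention
  banks <- list(type1 = mk("type1"), type2 = mk("off_type2"))
  prc_pars <- list(type1 = c(base = 0.9, pulse = 1.5),
                   type2 = c(base = 2.2, pulse = 3.7))
  sta_amp <- c(type1 = 0.45, type2 = 1.1)
  out <- lapply(names(banks), function(nm) {
    b <- banks[[nm]]
    fi <- fi_curves(b, amplitudes = amps,
                    duration = 1000 * max(cfg$scale, 0.5))
    pp <- prc_pars[[nm]]
    pr <- tryCatch(
      prc(b, base_amplitude = pp[["base"]], pulse_amplitude = pp[["pulse"]],
          interval = if (nm == "type2") "within" else "next"),
      error = function(e) NULL)
    list(fi = fi, prc = pr,
         sta = sta(b, noise_amplitude = sta_amp[[nm]],
                   duration = 30000 * max(cfg$scale, 0.25),
                   seed = cfg$seed))
  })
  names(out) <- names(banks)
  tab <- do.call(rbind, Map(function(nm, r)
    cbind(cfg_cols(cfg),
          data.frame(neuron = nm, amplitude = r$fi$mean$x,
                     f_instant = r$fi$instantaneous$y,
                     f_mean = r$fi$mean$y)),
    names(out), out))
  rownames(tab) <- NULL
  list(table = tab, protocols = out)
}

#' Compare efficiency sweeps of two network kinds
#'
#' Joins two `sweep_efficiency` tables on their (amplitude, tau) grid and
#' reports per-cell efficiency ratios, plus a summary flag for the
#' low-amplitude / fast-fluctuation quadrant (amplitudes and taus up to
#' their grid medians), where heterogeneous populations are expected to be
#' the more efficient.
#'
#' @param tab_a,tab_b sweep tables (`$table` of [run_experiment()] results);
#'   ratios are `a / b`.
#' @return list with `table` (grid plus `efficiency_ratio`) and
#'   `low_amp_fast_tau_median_ratio`.
#' @export
compare_networks <- function(tab_a, tab_b) {
  key <- c("amplitude", "tau")
  if (!identical(tab_a[key], tab_b[key]))
    stop("the two sweeps use different stimulus grids")
  ratio <- tab_a$efficiency / tab_b$efficiency
  out <- cbind(tab_a[key],
               data.frame(efficiency_a = tab_a$efficiency,
                          efficiency_b = tab_b$efficiency,
                          efficiency_ratio = ratio))
  quad <- out$amplitude <= stats::median(unique(out$amplitude)) &
    out$tau <= stats::median(unique(out$tau))
  list(table = out,
       low_amp_fast_tau_median_ratio =
         stats::median(ratio[quad], na.rm = TRUE))
}
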