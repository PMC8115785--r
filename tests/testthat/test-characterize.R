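# single-neuron fixtures: the type-2 protocols run on the variant whose
# window integral is positive (the sign a positive drive excites)
t1_bank <- filter_bank(list(neuron_spec("type1")), delta = 7.5, nu = 1.5,
                       mu = 1.5, dt = 0.1)
t2_bank <- filter_bank(list(neuron_spec("off_type2")), delta = 7.5,
                       nu = 1.5, mu = 1.5, dt = 0.1)

test_that("type-1 cells have a continuous f-I curve, type-2 cells fire doublets", {
  amps <- c(0, 0.5, 0.75, 1, 1.5, 2, 3)
  fi1 <- fi_curves(t1_bank, amps, duration = 1500)
  expect_equal(fi1$mean$y[1L], 0)
  expect_true(all(diff(fi1$mean$y) >= 0))            # rate grows with drive
  pos <- fi1$mean$y[fi1$mean$y > 0]
  expect_lt(pos[1L], 30)                             # onset from low rates
  expect_gt(max(fi1$mean$y), 50)
  # type-2: periodic doublet firing at high amplitude -> strongly bimodal
  # ISI distribution (short within-doublet, long between-doublet intervals)
  s <- make_stimulus("constant", amplitude = 3, duration = 2000, dt = 0.1)
  tt <- simulate_network(t2_bank, s)$raster$real_times[[1L]]
  isi <- isis(tt[tt > 500])
  expect_gt(length(isi), 10)
  short <- isi[isi <= median(isi)]; long <- isi[isi > median(isi)]
  expect_gt(min(long) / max(short), 3)               # two separated modes
})

test_that("phase-response curves separate integrators from resonators", {
  p0 <- prc(t1_bank, base_amplitude = 0.9, pulse_amplitude = 0)
  expect_equal(p0$y, rep(0, length(p0$y)), tolerance = 1e-9)
  p1 <- prc(t1_bank, base_amplitude = 0.9, pulse_amplitude = 1.5)
  expect_true(any(p1$y > 0, na.rm = TRUE))
  expect_true(all(p1$y >= -1e-9, na.rm = TRUE))      # single-signed: unimodal
  expect_equal(modality(p1$y, dx = 0.05, sigma = 0.05)$label, "unimodal")
  p2 <- prc(t2_bank, base_amplitude = 2.2, pulse_amplitude = 3.7,
            interval = "within")
  expect_true(any(p2$y > 0, na.rm = TRUE) && any(p2$y < 0, na.rm = TRUE))
  expect_equal(modality(p2$y, dx = 0.05, sigma = 0.05)$label, "bimodal")
})

test_that("spike-triggered averages are unimodal for type 1, bimodal for type 2", {
  s1 <- sta(t1_bank, noise_amplitude = 1.0, duration = 30000, seed = 4)
  expect_equal(modality(s1$y, dx = 0.1)$label, "unimodal")
  s2 <- sta(t2_bank, noise_amplitude = 1.1, duration = 30000, seed = 4)
  expect_equal(modality(s2$y, dx = 0.1)$label, "bimodal")
  # classification is stable across the grid resolution
  t2c <- filter_bank(list(neuron_spec("off_type2")), delta = 7.5, nu = 1.5,
                     mu = 1.5, dt = 0.25)
  s2c <- sta(t2c, noise_amplitude = 1.1, duration = 30000, seed = 4)
  expect_equal(modality(s2c$y, dx = 0.25)$label, "bimodal")
  # shuffle oracle: Poisson surrogate triggers on the same stimulus -> flat
  stim <- make_stimulus("filtered_noise", amplitude = 1.1,
                        duration = 30000, dt = 0.1, tau = 1,
                        filter_mode = "causal", seed = 4)
  set.seed(11)
  fake <- sort(runif(s2$params$n_spikes, 20, 30000))
  flat <- pcsnet:::sta_of_times(stim, fake, window = 15)
  se <- 1.1 / sqrt(length(fake))
  expect_lt(max(abs(flat$y)), 4 * se)
})

test_that("correlogram estimators agree with a brute-force lag count", {
  set.seed(33)
  trials <- lapply(1:3, function(i)
    list(random_train(25, 400), random_train(30, 400)))
  cc <- correlograms(trials, 1, 2, T = 400, binwidth = 2, max_lag = 20)
  # brute force: chance-corrected pair counts over all spike pairs per lag
  K <- 200L; ml <- 10L
  binned <- lapply(trials, function(tr) lapply(tr, function(tt)
    tabulate(floor(tt / 2) + 1, nbins = K)))
  brute_ccg <- function(x, y) {
    xc <- x - mean(x); yc <- y - mean(y)
    sapply(-ml:ml, function(l) {
      s <- 0
      for (t in seq_len(K)) {
        u <- t + l
        if (u >= 1 && u <= K) s <- s + xc[t] * yc[u]
      }
      s
    })
  }
  xa <- colMeans(do.call(rbind, lapply(binned, `[[`, 1L)))
  xb <- colMeans(do.call(rbind, lapply(binned, `[[`, 2L)))
  norm <- mean(sapply(trials, function(tr) length(unlist(tr))))
  expect_equal(cc$signal, brute_ccg(xa, xb) / norm, tolerance = 1e-9)
  per <- sapply(binned, function(b) brute_ccg(b[[1L]], b[[2L]]))
  expect_equal(cc$noise, rowMeans(per) / norm - cc$signal,
               tolerance = 1e-9)
  # mirrored pair symmetry
  cc_ba <- correlograms(trials, 2, 1, T = 400, binwidth = 2, max_lag = 20)
  expect_equal(cc_ba$signal, rev(cc$signal), tolerance = 1e-12)
})

test_that("identical trials have an exactly zero noise correlogram", {
  set.seed(5)
  one <- list(random_train(20, 300), random_train(22, 300))
  cc <- correlograms(list(one, one, one), 1, 2, T = 300)
  expect_equal(cc$noise, rep(0, length(cc$lags)), tolerance = 1e-12)
  expect_error(correlograms(list(list(numeric(0), numeric(0)),
                                 list(numeric(0), numeric(0))),
                            1, 2, T = 300), "silent")
})

test_that("network correlation structure follows tuning and shared noise", {
  cfg <- experiment_config("correlations", N = 100, amplitude = 2.7,
                           tau = 15, duration = 2000, n_trials = 16,
                           seed = 5)
  res <- run_experiment(cfg)
  ctr <- function(cc, comp) {
    sel <- abs(cc$lags) <= 5
    mean(cc[[comp]][sel])
  }
  cors <- res$correlograms
  # similar tuning: positive signal correlations; on vs off: negative
  expect_gt(ctr(cors$t1_on_on, "signal"), 0)
  expect_gt(ctr(cors$t2_on_on, "signal"), 0)
  expect_lt(ctr(cors$t1_on_off, "signal"), 0)
  expect_lt(ctr(cors$t2_on_off, "signal"), 0)
  # similar tuning + independent noise: negative noise correlations
  expect_lt(ctr(cors$t1_on_on, "noise"), 0)
  expect_lt(ctr(cors$t2_on_on, "noise"), 0)
  # on vs off with independent noise: positive
  expect_gt(ctr(cors$t1_on_off, "noise"), 0)
  # a shared noise source turns the noise correlation positive
  expect_gt(ctr(cors$t1_on_on_shared, "noise"), 0)
})

test_that("population rate integrates to the spike count and STNA is localized", {
  set.seed(8)
  raster <- lapply(1:5, function(m) random_train(40, 2000))
  pr <- population_rate(raster, T = 2000, sigma = 6, rate_dt = 1)
  # unit-area kernel: integral of the per-neuron rate recovers the counts
  expect_equal(sum(pr$rate) * 1e-3 * 5, 200, tolerance = 200 * 0.05)
  # synchronized volleys: every neuron spikes at the same event times, so
  # the spike-triggered population activity peaks exactly at lag 0
  events <- seq(100, 1900, by = 50)
  sync <- lapply(1:5, function(m) events)
  stna <- spike_triggered_population_activity(sync, subset = 1L, T = 2000,
                                              window = 40)
  c0 <- which(stna$x == 0)
  expect_equal(stna$y[c0], max(stna$y))
  # jittering the other neurons flattens the central peak of neuron 1
  jit <- c(list(events), lapply(2:5, function(m)
    sort(events + runif(length(events), -20, 20))))
  stna_j <- spike_triggered_population_activity(jit, subset = 1L, T = 2000,
                                                window = 40)
  expect_gt(stna$y[c0], stna_j$y[c0])
  expect_error(spike_triggered_population_activity(sync, integer(0),
                                                   T = 2000), "empty")
})
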