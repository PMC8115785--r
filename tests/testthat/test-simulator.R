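test_that("a silent network stays silent and decodes to zero", {
  bank <- small_bank("homogeneous", N = 4, nu = 1.5, mu = 1.5)
  s <- make_stimulus("constant", amplitude = 0, duration = 200, dt = 0.1)
  sim <- simulate_network(bank, s)
  expect_equal(sum(lengths(sim$raster$ideal_times)), 0L)
  expect_equal(sim$estimate, rep(0, 2000))
  expect_equal(sim$residual, s$values)
})

test_that("a single neuron fires once when its own waveform just clears threshold", {
  bank <- filter_bank(list(neuron_spec("type1")), delta = 7.5, nu = 0.2,
                      mu = 10, dt = 0.1)
  # stimulus = the neuron's own filter, scaled so the windowed projection
  # marginally exceeds the threshold; large mu blocks immediate refiring
  g <- bank$g[, 1L]
  nrm2 <- sum(bank$g[1:76, 1L]^2) * 0.1
  a <- (bank$theta_base[1L] * 1.05) / nrm2
  s <- make_stimulus("constant", amplitude = 0, duration = 150, dt = 0.1)
  s$values[501:(500 + length(g))] <- a * g
  sim <- simulate_network(bank, s)
  tt <- sim$raster$ideal_times[[1L]]
  expect_gte(length(tt), 1L)
  expect_equal(tt[1L], 50, tolerance = 0.5)
  # the firing decision agrees with the brute-force error-difference oracle
  empty <- list(ideal_times = list(numeric(0)))
  d <- cost_delta_oracle(empty, bank, s, list(1L, tt[1L]))
  expect_gt(d, 2 * bank$nu)
  # one bin earlier the oracle refuses
  d0 <- cost_delta_oracle(empty, bank, s, list(1L, tt[1L] - 0.1))
  expect_lt(d0, 2 * bank$nu)
})

test_that("decoding is linear and anchored at ideal times", {
  bank <- small_bank("homogeneous", N = 4)
  r1 <- list(ideal_times = list(c(10), numeric(0), numeric(0), numeric(0)))
  r2 <- list(ideal_times = list(numeric(0), c(25.5), c(40), numeric(0)))
  e1 <- decode_estimate(r1, bank, n_grid = 1000)
  e2 <- decode_estimate(r2, bank, n_grid = 1000)
  both <- list(ideal_times = Map(c, r1$ideal_times, r2$ideal_times))
  expect_equal(decode_estimate(both, bank, n_grid = 1000), e1 + e2)
  expect_equal(decode_estimate(list(ideal_times = rep(list(numeric(0)), 4)),
                               bank, 100), rep(0, 100))
  # single spike at T reproduces the filter shifted to T
  k0 <- 101L
  expect_equal(e1[k0:(k0 + 50)], bank$g[1:51, 1L])
  expect_equal(e1[1:100], rep(0, 100))
  expect_error(decode_estimate(list(ideal_times = list(10.05, numeric(0),
                                                       numeric(0),
                                                       numeric(0))),
                               bank, 100), "off the grid")
})

test_that("real spikes trail ideal spikes by exactly Delta", {
  bank <- small_bank("homogeneous", N = 4)
  s <- make_stimulus("sine", amplitude = 5, duration = 300, dt = 0.1,
                     frequency = 5)
  sim <- simulate_network(bank, s)
  for (m in 1:4)
    expect_equal(sim$raster$real_times[[m]] - sim$raster$ideal_times[[m]],
                 rep(7.5, length(sim$raster$ideal_times[[m]])))
  # at most one spike per neuron per bin
  for (m in 1:4)
    expect_true(all(diff(sim$raster$ideal_times[[m]]) > 0.1 - 1e-9))
})

test_that("fire/no-fire decisions match the error-difference oracle on random networks", {
  set.seed(202)
  n_checked <- 0L
  for (case in 1:25) {
    N <- sample(2:6, 1)
    kinds <- sample(c("type1", "off_type1", "type2", "off_type2"), N,
                    replace = TRUE)
    bank <- filter_bank(lapply(kinds, neuron_spec), delta = 5,
                        nu = runif(1, 0.2, 1.5), mu = runif(1, 0.2, 1.5),
                        dt = 0.5, t_max = 25)
    s <- make_stimulus("filtered_noise", amplitude = runif(1, 2, 8),
                       duration = 150, dt = 0.5, tau = 10, seed = case)
    sim <- simulate_network(bank, s, keep_traces = TRUE)
    nD <- 10L
    spk <- do.call(rbind, lapply(seq_len(N), function(m) {
      ti <- sim$raster$ideal_times[[m]]
      if (!length(ti)) return(NULL)
      data.frame(m = m, k = as.integer(round(ti / 0.5)) + 1L + nD)
    }))
    df <- exp(-0.5 / bank$tau_adapt)
    steps <- sample((nD + 1L):300L, 12L)
    for (k in steps) {
      past <- spk[!is.null(spk) & spk$k < k, , drop = FALSE]
      raster <- list(ideal_times = lapply(seq_len(N), function(m)
        (past$k[past$m == m] - nD - 1L) * 0.5))
      adapt <- vapply(seq_len(N), function(m) {
        ks <- past$k[past$m == m]
        sum(bank$mu * df^(k - ks))
      }, numeric(1))
      deltas <- vapply(seq_len(N), function(m)
        cost_delta_oracle(raster, bank, s,
                          list(m, (k - nD - 1L) * 0.5)), numeric(1))
      margins <- deltas - 2 * (bank$nu + adapt)
      mstar <- which.max(margins)
      first_fired <- if (is.null(spk)) FALSE else any(spk$k == k)
      expect_equal(margins[mstar] > 0, first_fired,
                   label = sprintf("case %d step %d", case, k))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 100L)
})

test_that("noiseless dynamics are time-invariant up to a grid shift", {
  bank <- small_bank("type1_type2", N = 4, nu = 1, mu = 1)
  sig <- make_stimulus("filtered_noise", amplitude = 5, duration = 300,
                       dt = 0.1, tau = 10, seed = 31)$values
  shift_bins <- 40L
  mk <- function(lead) {
    s <- make_stimulus("constant", amplitude = 0,
                       duration = 100 + lead * 0.1 + 300, dt = 0.1)
    s$values[(1001 + lead):(1000 + lead + length(sig))] <- sig
    s
  }
  s1 <- simulate_network(bank, mk(0L))
  s2 <- simulate_network(bank, mk(shift_bins))
  n_spk <- sum(lengths(s1$raster$ideal_times))
  expect_gt(n_spk, 10L)
  for (m in 1:4)
    expect_equal(s2$raster$ideal_times[[m]],
                 s1$raster$ideal_times[[m]] + shift_bins * 0.1,
                 tolerance = 1e-9)
})

test_that("spike costs damp the ping-pong between sign-flipped twins", {
  # under the backdated (ideal) anchoring a spike lifts its twin to exactly
  # threshold, never above, so the ping-pong cascade only exists in the
  # emitted-PSP (real-anchor) dynamics; the adaptation increment mu must
  # damp it there
  mk <- function(mu) filter_bank(list(neuron_spec("type1"),
                                      neuron_spec("off_type1")),
                                 delta = 7.5, nu = 0.5, mu = mu, dt = 0.1)
  s <- make_stimulus("sine", amplitude = 6, duration = 300, dt = 0.1,
                     frequency = 5)
  alternations <- function(sim) {
    ev <- rbind(data.frame(t = sim$raster$ideal_times[[1L]], m = 1L),
                data.frame(t = sim$raster$ideal_times[[2L]], m = 2L))
    ev <- ev[order(ev$t), ]
    if (nrow(ev) < 2L) return(c(flips = 0, n = nrow(ev)))
    c(flips = sum(diff(ev$m) != 0 & diff(ev$t) < 10), n = nrow(ev))
  }
  a0 <- alternations(simulate_network(mk(0), s, lateral_anchor = "real"))
  a1 <- alternations(simulate_network(mk(1.5), s, lateral_anchor = "real"))
  expect_lt(a1[["flips"]], a0[["flips"]])
  expect_lt(a1[["n"]], a0[["n"]])
})

test_that("trial runs restrict to the main window deterministically", {
  bank <- small_bank("homogeneous", N = 4)
  s <- make_stimulus("filtered_noise", amplitude = 5, duration = 300,
                     dt = 0.1, tau = 10, seed = 8)
  same <- run_trials(bank, s, n_trials = 2, start_duration = 100,
                     seeds = c(3, 3))
  expect_identical(same[[1L]]$raster$ideal_times,
                   same[[2L]]$raster$ideal_times)
  diff_seeds <- run_trials(bank, s, n_trials = 2, start_duration = 100,
                           seeds = c(3, 4))
  expect_equal(diff_seeds[[1L]]$duration, 300)
  for (tr in diff_seeds) {
    expect_equal(tr$stimulus_values, s$values)
    expect_true(all(unlist(tr$raster$ideal_times) >= 0))
    expect_true(all(unlist(tr$raster$ideal_times) < 300))
    expect_lt(normalized_mse(s$values, tr$estimate), 1)
  }
  zero_start <- run_trials(bank, s, n_trials = 2, start_duration = 0,
                           seeds = c(1, 2))
  expect_identical(zero_start[[1L]]$raster, zero_start[[2L]]$raster)
})

test_that("membrane traces reproduce the windowed residual projection", {
  bank <- small_bank("homogeneous", N = 4)
  dt <- 0.1; nD <- 75L
  s <- make_stimulus("constant", amplitude = 0, duration = 200, dt = dt)
  s$values[101:(100 + nrow(bank$g))] <- 3 * bank$g[, 1L]
  sim <- simulate_network(bank, s, keep_traces = TRUE)
  spk <- do.call(rbind, lapply(1:4, function(m) {
    ti <- sim$raster$ideal_times[[m]]
    if (!length(ti)) return(NULL)
    data.frame(m = m, k = as.integer(round(ti / dt)) + 1L + nD)
  }))
  for (k in seq(nD + 1L, 1900L, by = 13L)) {
    if (!is.null(spk) && any(spk$k == k)) next   # trace is post-firing there
    past <- spk[spk$k < k, , drop = FALSE]
    raster <- list(ideal_times = lapply(1:4, function(m)
      (past$k[past$m == m] - nD - 1L) * dt))
    est <- decode_estimate(raster, bank, n_grid = k)
    w <- (k - nD):k
    v <- sum(bank$g[1:(nD + 1L), 1L] * (s$values[w] - est[w])) * dt
    expect_equal(sim$membrane[1L, k], v, tolerance = 1e-9)
    expect_gte(sim$threshold[1L, k], bank$theta_base[1L] - 1e-12)
  }
})

test_that("rasters export to CSV with both clocks", {
  bank <- small_bank("homogeneous", N = 4)
  s <- make_stimulus("sine", amplitude = 5, duration = 200, dt = 0.1,
                     frequency = 5)
  sim <- simulate_network(bank, s)
  path <- tempfile(fileext = ".csv")
  df <- write_raster_csv(sim, path)
  back <- read.csv(path)
  expect_equal(nrow(back), sum(lengths(sim$raster$ideal_times)))
  expect_equal(back$real_time_ms - back$ideal_time_ms,
               rep(7.5, nrow(back)))
  # full bundle: traces + manifest
  dir <- tempfile()
  write_sim_bundle(sim, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$delta, 7.5)
  expect_equal(man$n_spikes, nrow(back))
  tr <- read.csv(file.path(dir, "traces.csv"))
  expect_equal(tr$estimate, sim$estimate, tolerance = 1e-10)
})
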