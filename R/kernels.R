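#' Time-domain kernels on a uniform grid
#'
#' A `pc_kernel` is a finitely supported real-valued function of time sampled
#' on a uniform grid: sample `i` sits at time `origin_time + (i-1)*dt` (ms).
#' Kernels represent a neuron's representing filter `g`, the derived input
#' filter `g_in`, the lateral/output coupling filters, and the threshold
#' adaptation kernel.
#'
#' @param values numeric vector of samples.
#' @param dt time step in ms (> 0).
#' @param origin_time time (ms) of the first sample; 0 for causal kernels.
#' @return An object of class `pc_kernel`.
#' @export
pc_kernel <- function(values, dt, origin_time = 0) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a single positive number (ms)")
  structure(list(values = as.numeric(values), dt = dt,
                 origin_time = origin_time),
            class = "pc_kernel")
}

#' @export
print.pc_kernel <- function(x, ...) {
  cat(sprintf("<pc_kernel> %d samples, dt = %g ms, support [%g, %g] ms\n",
              length(x$values), x$dt, x$origin_time,
              x$origin_time + (length(x$values) - 1L) * x$dt))
  invisible(x)
}

#' @export
plot.pc_kernel <- function(x, ...) {
  t <- x$origin_time + (seq_along(x$values) - 1L) * x$dt
  graphics::plot(t, x$values, type = "l", xlab = "time (ms)",
                 ylab = "kernel value", ...)
  invisible(x)
}

#' Times of the samples of a kernel
#' @param x a `pc_kernel`.
#' @return numeric vector of sample times (ms).
#' @export
kernel_times <- function(x) {
  stopifnot(inherits(x, "pc_kernel"))
  x$origin_time + (seq_along(x$values) - 1L) * x$dt
}

## Integral of f over [0, delta] as a sample sum * dt, both endpoint samples
## included. This convention makes the discrete coupling identity
## -g_out(Delta) = 2*(theta - nu) exact (the discrete convolution at lag Delta
## touches all nD+1 samples of g on [0, Delta]).
window_integral <- function(values, dt, delta, square = FALSE) {
  nD <- delta_bins(delta, dt)
  idx <- seq_len(min(nD + 1L, length(values)))
  v <- values[idx]
  if (square) v <- v * v
  sum(v) * dt
}

delta_bins <- function(delta, dt) {
  nD <- delta / dt
  if (abs(nD - round(nD)) > 1e-8)
    stop("'delta' must be an integer multiple of 'dt'")
  as.integer(round(nD))
}

#' Default time grid for representing filters
#'
#' Filters are evaluated on `[0, t_max]` ms; `t_max = 50` comfortably covers
#' the decay of the Gamma-function bases used here.
#'
#' @param dt time step (ms).
#' @param t_max upper edge of the grid (ms).
#' @return numeric vector of times starting at 0.
#' @export
default_t_grid <- function(dt = 0.1, t_max = 50) seq(0, t_max, by = dt)

#' Gamma-function basis kernel
#'
#' The representing filters of all neurons are built from the basis
#' \eqn{\Gamma_n(t) = t^n e^{-t}} (t in ms), a causal, smoothly decaying
#' waveform with its peak at \eqn{t = n}.
#'
#' @param n non-negative integer order.
#' @param t_grid uniform time grid in ms starting at 0.
#' @return a causal `pc_kernel`.
#' @examples
#' g <- gamma_basis(3, default_t_grid(0.1))
#' kernel_times(g)[which.max(g$values)]  # peak at t = n = 3 ms
#' @export
gamma_basis <- function(n, t_grid = default_t_grid()) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n))
    stop("'n' must be a single non-negative integer")
  check_uniform_grid(t_grid)
  dt <- t_grid[2L] - t_grid[1L]
  pc_kernel(t_grid^n * exp(-t_grid), dt = dt)
}

check_uniform_grid <- function(t_grid) {
  if (length(t_grid) < 2L) stop("time grid needs at least two samples")
  if (abs(t_grid[1L]) > 1e-12) stop("time grid must start at 0")
  d <- diff(t_grid)
  if (max(abs(d - d[1L])) > 1e-9) stop("time grid must be uniform")
  invisible(TRUE)
}

#' Specification of one neuron's representing filter
#'
#' @param filter_kind one of `"type1"`, `"type2"`, `"off_type1"`,
#'   `"off_type2"`, `"heterogeneous"`. Type-1 filters are the unimodal
#'   \eqn{\Gamma_3} basis (integrator-like neurons); type-2 filters are
#'   \eqn{\Gamma_3(t)(0.2 - 0.8\sin(0.6 t))}, a bimodal waveform giving
#'   resonator-like neurons; `off_*` kinds are the sign-inverted copies.
#'   Heterogeneous filters are \eqn{\Gamma_3(t)(0.2 \pm 0.8 f(\psi t))} with
#'   `f` sin or cos.
#' @param psi modulation frequency parameter in \[0, 1.5\] (heterogeneous only).
#' @param phase_basis `"sin"` or `"cos"` (heterogeneous only).
#' @param sign +1 or -1: the sign of the 0.8 modulation term (heterogeneous
#'   only).
#' @return an object of class `pc_neuron_spec`.
#' @export
neuron_spec <- function(filter_kind, psi = NULL, phase_basis = NULL,
                        sign = 1) {
  filter_kind <- match.arg(filter_kind,
    c("type1", "type2", "off_type1", "off_type2", "heterogeneous"))
  if (filter_kind == "heterogeneous") {
    if (is.null(psi) || psi < 0 || psi > 1.5)
      stop("heterogeneous filters need 'psi' in [0, 1.5]")
    phase_basis <- match.arg(phase_basis, c("sin", "cos"))
    if (!sign %in% c(-1, 1)) stop("'sign' must be +1 or -1")
  }
  structure(list(filter_kind = filter_kind, psi = psi,
                 phase_basis = phase_basis, sign = sign),
            class = "pc_neuron_spec")
}

#' Construct a representing filter from a neuron specification
#'
#' @param spec a [neuron_spec()].
#' @param t_grid uniform time grid (ms) starting at 0.
#' @param truncate drop trailing samples with `|g| < 1e-6 * max|g|`.
#' @return a causal `pc_kernel` (not yet normalized).
#' @export
make_representing_filter <- function(spec, t_grid = default_t_grid(),
                                     truncate = TRUE) {
  stopifnot(inherits(spec, "pc_neuron_spec"))
  check_uniform_grid(t_grid)
  base <- t_grid^3 * exp(-t_grid)
  v <- switch(spec$filter_kind,
    type1     = base,
    off_type1 = -base,
    type2     = base * (0.2 - 0.8 * sin(0.6 * t_grid)),
    off_type2 = -base * (0.2 - 0.8 * sin(0.6 * t_grid)),
    heterogeneous = {
      f <- if (spec$phase_basis == "sin") sin else cos
      base * (0.2 + spec$sign * 0.8 * f(spec$psi * t_grid))
    })
  dt <- t_grid[2L] - t_grid[1L]
  if (truncate) {
    tol <- 1e-6 * max(abs(v))
    keep <- which(abs(v) >= tol)
    if (length(keep) > 0L) v <- v[seq_len(max(keep))]
  }
  pc_kernel(v, dt = dt)
}

#' Build a population of neuron specifications
#'
#' Population compositions: `"homogeneous"` = half type-1 on-cells, half
#' off-cells; `"type1_type2"` = quarters of type-1 / off-type-1 / type-2 /
#' off-type-2; `"heterogeneous"` = half sin-modulated, half cos-modulated,
#' each half split between + and - modulation sign, with the modulation
#' frequency psi drawn uniformly in \[0, 1.5\] per neuron.
#'
#' @param kind population kind.
#' @param N neuron count, divisible by the number of groups (2 or 4).
#' @param seed RNG seed for the heterogeneous psi draws.
#' @return list of [neuron_spec()] objects of length `N`.
#' @export
build_population <- function(kind = c("homogeneous", "type1_type2",
                                      "heterogeneous"),
                             N, seed = 1L) {
  kind <- match.arg(kind)
  n_groups <- if (kind == "type1_type2" || kind == "heterogeneous") 4L else 2L
  if (N %% n_groups != 0L)
    stop(sprintf("'N' must be divisible by %d for kind '%s'", n_groups, kind))
  if (kind == "homogeneous") {
    kinds <- rep(c("type1", "off_type1"), each = N / 2L)
    return(lapply(kinds, neuron_spec))
  }
  if (kind == "type1_type2") {
    kinds <- rep(c("type1", "off_type1", "type2", "off_type2"), each = N / 4L)
    return(lapply(kinds, neuron_spec))
  }
  # heterogeneous: sin+/sin-/cos+/cos- quarters, psi ~ U(0, 1.5) per neuron
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = .GlobalEnv))
    set.seed(seed)
    expr
  }
  psi <- withr_seed(stats::runif(N, 0, 1.5))
  basis <- rep(c("sin", "sin", "cos", "cos"), each = N / 4L)
  sgn <- rep(c(1, -1, 1, -1), each = N / 4L)
  lapply(seq_len(N), function(i)
    neuron_spec("heterogeneous", psi = psi[i], phase_basis = basis[i],
                sign = sgn[i]))
}

#' Normalize representing filters to a common window norm
#'
#' Filters are rescaled so that \eqn{\int_0^\Delta g^2 dx} equals a common
#' target, which makes the base thresholds identical across neurons. Target
#' `"type1"` (default) uses the window norm of the raw \eqn{\Gamma_3} filter
#' (about 5.6 for Delta = 7.5 ms), leaving the canonical type-1 filter
#' unchanged and filter peak amplitudes in roughly \[1, 2\]; target `"unit"`
#' rescales to norm-squared 1, for which the nu = 0 base threshold is exactly
#' 0.5.
#'
#' @param filters list of causal `pc_kernel`s sharing one `dt`.
#' @param delta the coding delay Delta (ms).
#' @param target `"type1"`, `"unit"`, or a positive number (the target
#'   norm-squared).
#' @return list with `filters` (rescaled kernels) and `scale` (the per-filter
#'   multipliers).
#' @export
normalize_population <- function(filters, delta, target = "type1") {
  stopifnot(length(filters) >= 1L)
  dt <- filters[[1L]]$dt
  for (f in filters)
    if (abs(f$dt - dt) > 1e-12) stop("all kernels must share one dt")
  norm2 <- vapply(filters, function(f)
    window_integral(f$values, dt, delta, square = TRUE), numeric(1))
  if (any(norm2 <= 1e-12 * max(norm2, 1)))
    stop("degenerate filter: identically zero on [0, Delta]; ",
         "its input filter would vanish")
  target_norm2 <- if (identical(target, "type1")) {
    g1 <- gamma_basis(3, seq(0, delta, by = dt))
    window_integral(g1$values, dt, delta, square = TRUE)
  } else if (identical(target, "unit")) 1
  else if (is.numeric(target) && length(target) == 1L && target > 0) target
  else stop("unknown normalization target")
  scale <- sqrt(target_norm2 / norm2)
  out <- Map(function(f, s) pc_kernel(f$values * s, dt, f$origin_time),
             filters, scale)
  list(filters = out, scale = scale)
}

#' Derive the input filter from a representing filter
#'
#' The input filter is the time-flipped, Delta-shifted restriction of the
#' representing filter: \eqn{g_{in}(t) = g(\Delta - t)} on \eqn{t \in
#' [0, \Delta]}. Samples outside that window (the acausal part) are discarded.
#'
#' @param g causal `pc_kernel`.
#' @param delta the coding delay Delta (ms, > 0, integer multiple of dt).
#' @return a `pc_kernel` with support `[0, Delta]`.
#' @export
derive_input_filter <- function(g, delta) {
  stopifnot(inherits(g, "pc_kernel"))
  if (delta <= 0)
    stop("'delta' must be > 0: with Delta = 0 the input filter reduces to ",
         "a single point")
  nD <- delta_bins(delta, g$dt)
  gi <- seq.int(nD + 1L, 1L)           # g index for g_in sample i: g(Delta - t)
  v <- ifelse(gi <= length(g$values), g$values[gi], 0)
  pc_kernel(v, g$dt)
}

#' Base spiking threshold of a neuron
#'
#' \eqn{\Theta = \frac{1}{2}\int_0^\Delta g(x)^2 dx + \nu}. For causal
#' filters this is constant in simulation time. With an L2-normalized filter
#' and nu = 0 it equals exactly 1/2.
#'
#' @param g causal `pc_kernel`.
#' @param delta the coding delay (ms).
#' @param nu linear spike cost.
#' @return the threshold (dimensionless).
#' @export
base_threshold <- function(g, delta, nu = 0) {
  stopifnot(inherits(g, "pc_kernel"))
  0.5 * window_integral(g$values, g$dt, delta, square = TRUE) + nu
}

## Full lateral filter between ordered pair (m, j):
##   g_lat[m][j](t) = -(g_in[m] * g_j)(t) (discrete convolution * dt),
## support [0, Delta + support(g_j)].
lateral_filter_values <- function(g_in_m, g_j, dt) {
  -stats::convolve(g_in_m, rev(g_j), type = "open") * dt
}

#' Lateral (or output) coupling filter between two neurons
#'
#' \eqn{g^{lat}_{mj}(t) = -(g^{in}_m * g_j)(t)}: the recurrent kernel through
#' which a spike of neuron `j` suppresses the already-represented part of the
#' signal in neuron `m`'s membrane potential. With `m == j` this is the
#' output (self) filter. Only lags at and beyond Delta act in the simulation
#' (a spike decided at `T + Delta` cannot influence earlier decisions).
#'
#' @param bank a [filter_bank()].
#' @param m,j neuron indices (1-based).
#' @return a causal `pc_kernel` over lags `[0, Delta + support(g_j)]`.
#' @export
lateral_filter <- function(bank, m, j) {
  stopifnot(inherits(bank, "pc_filterbank"))
  v <- lateral_filter_values(bank$g_in[, m], bank$g[, j], bank$dt)
  pc_kernel(v, bank$dt)
}

#' Build the full filter bank of a network
#'
#' Constructs, for a population of neuron specifications: the normalized
#' representing filters, the input filters, the lateral/output coupling
#' kernels used by the simulator, and the (identical) base thresholds.
#'
#' @param population a population kind (`"homogeneous"`, `"type1_type2"`,
#'   `"heterogeneous"`) or a list of [neuron_spec()] objects.
#' @param N neuron count (only used when `population` is a kind string).
#' @param delta coding delay Delta (ms); must be an integer multiple of `dt`.
#' @param nu linear spike cost (raises every threshold; sparsifies the code).
#' @param mu adaptation increment added to a neuron's threshold at each of its
#'   own spikes.
#' @param tau_adapt decay time constant of the threshold adaptation (ms).
#' @param dt simulation time step (ms).
#' @param seed RNG seed (heterogeneous psi draws).
#' @param normalize normalization target passed to [normalize_population()],
#'   or `"none"`.
#' @param t_max kernel truncation time (ms).
#' @return an object of class `pc_filterbank` with elements `N`, `dt`,
#'   `delta`, `nu`, `mu`, `tau_adapt`, `specs`, `g` (L x N matrix of
#'   representing-filter samples), `g_in` ((nD+1) x N matrix), `theta_base`
#'   (per-neuron threshold), `scale`, and `glat` (N x N x (nD+L) array:
#'   `glat[m, j, i]` is the lateral filter `-(g_in_m * g_j)` at lag
#'   `(i-1)*dt` -- the postsynaptic-potential waveform a spike of neuron j,
#'   emitted at decision time t, contributes to neuron m's membrane
#'   potential at `t + (i-1)*dt`).
#' @examples
#' bank <- filter_bank("homogeneous", N = 4, delta = 7.5, nu = 0.5, mu = 0.5)
#' bank$theta_base
#' @export
filter_bank <- function(population, N = NULL, delta = 7.5, nu = 1.5,
                        mu = 1.5, tau_adapt = 60, dt = 0.1, seed = 1L,
                        normalize = "type1", t_max = 50) {
  specs <- if (is.character(population)) {
    if (is.null(N)) stop("'N' is required when 'population' is a kind")
    build_population(population, N, seed = seed)
  } else population
  stopifnot(all(vapply(specs, inherits, logical(1), "pc_neuron_spec")))
  N <- length(specs)
  nD <- delta_bins(delta, dt)
  t_grid <- seq(0, t_max, by = dt)
  filters <- lapply(specs, make_representing_filter, t_grid = t_grid)
  scale <- rep(1, N)
  if (!identical(normalize, "none")) {
    nrm <- normalize_population(filters, delta, target = normalize)
    filters <- nrm$filters
    scale <- nrm$scale
  }
  L <- max(vapply(filters, function(f) length(f$values), integer(1)), nD + 1L)
  G <- vapply(filters, function(f) c(f$values, numeric(L - length(f$values))),
              numeric(L))
  Gin <- vapply(seq_len(N), function(m)
    derive_input_filter(pc_kernel(G[, m], dt), delta)$values,
    numeric(nD + 1L))
  Gin <- matrix(Gin, nrow = nD + 1L)
  theta <- 0.5 * colSums(G[seq_len(nD + 1L), , drop = FALSE]^2) * dt + nu
  bank <- structure(list(
    N = N, dt = dt, delta = delta, nu = nu, mu = mu, tau_adapt = tau_adapt,
    specs = specs, g = G, g_in = Gin, theta_base = theta, scale = scale,
    normalize = normalize, seed = seed,
    glat = NULL), class = "pc_filterbank")
  bank$glat <- derive_coupling_filters(bank)
  bank
}

#' Lateral coupling array of a filter bank
#'
#' Computes `glat[m, j, i]`, the lateral filter \eqn{-(g^{in}_m * g_j)}
#' evaluated at lag `(i-1)*dt` since the emission (decision) time of a spike
#' of neuron `j`: the recurrent postsynaptic-potential waveform through which
#' that spike suppresses the already-represented signal in neuron m's
#' membrane potential. Its value at lag Delta is `-2 * (theta_base - nu)` for
#' `j = m`. Duplicate filters are detected and computed once.
#'
#' @param bank a `pc_filterbank` with `g` and `g_in` populated.
#' @return an `N x N x (nD + L)` numeric array (`nD = Delta/dt`, `L` the
#'   representing-filter length).
#' @export
derive_coupling_filters <- function(bank) {
  stopifnot(inherits(bank, "pc_filterbank"))
  G <- bank$g; Gin <- bank$g_in; dt <- bank$dt
  N <- bank$N; L <- nrow(G); nD <- nrow(Gin) - 1L
  key <- apply(G, 2L, function(v) paste(signif(v, 12), collapse = ","))
  uniq <- !duplicated(key)
  uidx <- match(key, key[uniq])         # neuron -> unique filter id
  U <- sum(uniq)
  Gu <- G[, uniq, drop = FALSE]
  Ginu <- Gin[, uniq, drop = FALSE]
  # pairwise convolutions at lags 0..(nD+L-1):
  # conv[l] = sum_i gin[i] * g_j[l - i], 0-based
  Lout <- nD + L
  out_u <- array(0, dim = c(U, U, Lout))
  idx <- outer(seq_len(Lout) - 1L, seq_len(nD + 1L) - 1L, "-") + 1L
  idx[idx < 1L | idx > L] <- 0L
  for (ju in seq_len(U)) {
    gj <- c(0, Gu[, ju])                # index 1 = "outside support"
    Mj <- matrix(gj[idx + 1L], nrow = Lout)
    out_u[, ju, ] <- t(-(Mj %*% Ginu) * dt)
  }
  out <- array(0, dim = c(N, N, Lout))
  for (m in seq_len(N)) out[m, , ] <- out_u[uidx[m], uidx, ]
  out
}

#' @export
print.pc_filterbank <- function(x, ...) {
  kinds <- vapply(x$specs, function(s) s$filter_kind, character(1))
  cat(sprintf("<pc_filterbank> N = %d, dt = %g ms, Delta = %g ms, nu = %g, mu = %g\n",
              x$N, x$dt, x$delta, x$nu, x$mu))
  cat("  composition:",
      paste(sprintf("%s x%d", names(table(kinds)), table(kinds)),
            collapse = ", "), "\n")
  cat(sprintf("  base threshold: %.6g (tau_adapt = %g ms)\n",
              x$theta_base[1L], x$tau_adapt))
  invisible(x)
}

#' Serialize a filter bank to a JSON descriptor plus a kernel-sample CSV
#'
#' @param bank a `pc_filterbank`.
#' @param json_path path for the JSON descriptor (specs, seed, Delta, nu, mu,
#'   dt, normalization mode).
#' @param csv_path path for the sampled representing-filter values
#'   (columns `neuron_id`, `time_ms`, `value`).
#' @return invisibly, the descriptor list.
#' @export
write_filter_bank <- function(bank, json_path, csv_path) {
  stopifnot(inherits(bank, "pc_filterbank"))
  desc <- list(
    N = bank$N, dt = bank$dt, delta = bank$delta, nu = bank$nu, mu = bank$mu,
    tau_adapt = bank$tau_adapt, seed = bank$seed,
    normalize = if (is.character(bank$normalize)) bank$normalize
                else as.numeric(bank$normalize),
    specs = lapply(bank$specs, function(s)
      list(filter_kind = s$filter_kind, psi = s$psi,
           phase_basis = s$phase_basis, sign = s$sign)))
  jsonlite::write_json(desc, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  L <- nrow(bank$g)
  df <- data.frame(
    neuron_id = rep(seq_len(bank$N), each = L),
    time_ms = rep((seq_len(L) - 1L) * bank$dt, times = bank$N),
    value = as.vector(bank$g))
  utils::write.csv(df, csv_path, row.names = FALSE)
  invisible(desc)
}
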