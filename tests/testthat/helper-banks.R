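# shared small fixtures, built once per test run

small_bank <- local({
  cache <- new.env(parent = emptyenv())
  function(kind = "homogeneous", N = 4, nu = 0.5, mu = 0.5, dt = 0.1,
           normalize = "type1", seed = 1L) {
    key <- paste(kind, N, nu, mu, dt, normalize, seed, sep = "|")
    if (is.null(cache[[key]]))
      cache[[key]] <- filter_bank(kind, N = N, delta = 7.5, nu = nu,
                                  mu = mu, dt = dt, seed = seed,
                                  normalize = normalize)
    cache[[key]]
  }
})

# brute-force double-sum convolution oracle on short kernels
conv_oracle <- function(a, b, dt) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a))
    for (j in seq_along(b))
      out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j] * dt
  out
}

# random spike train on [0, T)
random_train <- function(n, T) sort(stats::runif(n, 0, T))
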