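# Shared fixtures, built lazily once per test run and cached.
# All synthetic audio in tests uses 22050 Hz to keep runtimes short; the
# band of interest (0.5-9 kHz) is fully below Nyquist at that rate.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 2 sites x 3 individuals, strong signatures, 4-6 calls each
small_pop <- function() {
  fixture("small_pop", function() {
    generate_population(population_config(
      n_regions = 1, n_sites_per_region = 2, n_individuals_per_site = 3,
      calls_per_individual = c(4, 6), signature_strength = 800,
      call_jitter = 100, sample_rate = 22050, seed = 42
    ))
  })
}

small_spcc <- function() {
  fixture("small_spcc", function() spcc_matrix(small_pop()))
}

# deterministic non-call test tone with noise margins
tone_clip <- function(freq = 3000, dur = 0.3, sr = 22050, pad = 0.15,
                      snr_lin = 10, seed = 99) {
  set.seed(seed)
  n <- round(dur * sr)
  tone <- sin(2 * pi * freq * seq_len(n) / sr) * 0.7
  n_pad <- round(pad * sr)
  clip <- c(numeric(n_pad), tone, numeric(n_pad))
  noise_sd <- sqrt(mean(tone^2)) / snr_lin
  list(waveform = clip + rnorm(length(clip), 0, noise_sd), sample_rate = sr,
       begin_s = n_pad / sr, end_s = (n_pad + n) / sr)
}

# brute-force SPCC oracle: enumerate all full-overlap lags with cor()
spcc_oracle <- function(a, b) {
  x <- if (ncol(a) <= ncol(b)) a else b
  y <- if (ncol(a) <= ncol(b)) b else a
  nx <- ncol(x)
  best <- 0
  for (lag in 0:(ncol(y) - nx)) {
    win <- y[, (lag + 1):(lag + nx), drop = FALSE]
    if (stats::sd(x) > 0 && stats::sd(win) > 0) {
      best <- max(best, stats::cor(as.vector(x), as.vector(win)))
    }
  }
  min(best, 1)
}

# exact 1-D Wasserstein between two discrete atom sets (independent of the
# histogram/CDF implementation under test): integrate |F1 - F2| over the
# segments between consecutive atom positions
wasserstein_oracle <- function(x_atoms, x_mass, y_atoms, y_mass) {
  grid <- sort(unique(c(x_atoms, y_atoms)))
  f1 <- stats::stepfun(x_atoms, c(0, cumsum(x_mass)))
  f2 <- stats::stepfun(y_atoms, c(0, cumsum(y_mass)))
  total <- 0
  for (i in seq_len(length(grid) - 1)) {
    mid <- (grid[i] + grid[i + 1]) / 2
    total <- total + abs(f1(mid) - f2(mid)) * (grid[i + 1] - grid[i])
  }
  total
}

bin_atoms <- function(values, n_bins, domain = c(0, 1)) {
  w <- (domain[2] - domain[1]) / n_bins
  idx <- pmin(n_bins, floor((values - domain[1]) / w) + 1)
  centers <- domain[1] + (seq_len(n_bins) - 0.5) * w
  mass <- tabulate(idx, n_bins) / length(values)
  keep <- mass > 0
  list(atoms = centers[keep], mass = mass[keep])
}
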