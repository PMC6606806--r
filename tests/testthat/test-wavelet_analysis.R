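test_that("periodized DWT is orthonormal with perfect reconstruction", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(c(32, 48, 64, 96), 1)
    lvl <- sample(1:3, 1)
    ord <- sample(2:6, 1)
    x <- rnorm(n)
    w <- dwt_periodic(x, lvl, ord)
    expect_lt(rel_l2(idwt_periodic(w), x), 1e-9)
    energy <- sum(w$approx^2) + sum(unlist(w$details)^2)
    expect_lt(abs(energy - sum(x^2)) / sum(x^2), 1e-9)
  }
  expect_error(dwt_periodic(rnorm(46), 2), "not divisible")
})

test_that("constant series have zero detail energy", {
  w <- dwt_periodic(rep(3.7, 64), 3, 4)
  expect_lt(max(abs(unlist(w$details))), 1e-10)
  expect_equal(wave_smooth(rep(2.5, 46), 2), rep(2.5, 46))
})

test_that("a unit impulse transforms to the circular filter correlation", {
  n <- 32
  x <- c(1, rep(0, n - 1))
  flt <- daubechies_filter(4)
  w <- dwt_periodic(x, 1, 4)
  # brute-force circular correlation downsampled by 2
  a_or <- d_or <- numeric(n / 2)
  for (k in 0:(n / 2 - 1)) {
    for (l in seq_len(flt$length)) {
      xi <- ((2 * k + l - 1) %% n) + 1
      a_or[k + 1] <- a_or[k + 1] + flt$h[l] * x[xi]
      d_or[k + 1] <- d_or[k + 1] + flt$g[l] * x[xi]
    }
  }
  expect_equal(w$approx, a_or)
  expect_equal(w$details[[1]], d_or)
})

test_that("wavelet smoothing keeps the wave, the mean, and contracts noise", {
  x <- cos(2 * pi * (0:45) / 23)
  expect_lt(rel_l2(wave_smooth(x, 2), x), 0.10)
  set.seed(31)
  for (rep in 1:10) {
    z <- rnorm(46, mean = 5)
    s <- wave_smooth(z, 2)
    expect_lt(abs(mean(s) - mean(z)), 1e-6 * max(1, abs(mean(z))))
    expect_lt(var(s), var(z))
  }
  expect_error(wave_smooth(rnorm(46), 6), "too deep")
})

test_that("MODWT conserves energy on the circle", {
  set.seed(17)
  for (n in c(46, 61, 100)) {
    x <- rnorm(n)
    m <- modwt_periodic(x, 2, 4)
    energy <- sum(m$smooth^2) + sum(unlist(m$details)^2)
    expect_lt(abs(energy - sum(x^2)) / sum(x^2), 1e-9)
  }
})

test_that("Morlet CWT is linear and localizes a cosine at its period", {
  expect_equal(Mod(morlet_cwt(rep(0, 46))$W), matrix(0, length(scale_grid()), 46))
  expect_error(morlet_cwt(rnorm(46), scales = numeric(0)), "empty")
  set.seed(23)
  x <- rnorm(46); y <- rnorm(46); a <- 1.7; b <- -0.4
  Wsum <- a * morlet_cwt(x)$W + b * morlet_cwt(y)$W
  expect_lt(max(Mod(morlet_cwt(a * x + b * y)$W - Wsum)), 1e-9)
  for (p in c(8, 12, 16)) {
    cw <- morlet_cwt(cos(2 * pi * (0:91) / p))
    center <- 46
    pk <- cw$scales[which.max(Mod(cw$W[, center]))]
    grid_step <- max(cw$scales[-1] / cw$scales[-length(cw$scales)])
    expect_lt(abs(log(to_bins_per_cycle(pk) / p)), log(grid_step) * 1.5)
  }
})

test_that("scale-to-period conversion follows the Morlet closed form", {
  expect_equal(to_bins_per_cycle(10, 6), 10 * 4 * pi / (6 + sqrt(38)))
  expect_equal(to_bins_per_cycle(10, 6), 10.33043, tolerance = 1e-5)
  s <- c(2, 5, 20)
  expect_equal(to_bins_per_cycle(3 * s), 3 * to_bins_per_cycle(s))
  expect_error(to_bins_per_cycle(-1), "> 0")
  # a 12-bin period at the default E. coli bin width sits in the
  # 800-1,600 kb band
  expect_true(12 * bin_width_bp(ecoli_genome()) / 1000 > 800 &&
                12 * bin_width_bp(ecoli_genome()) / 1000 < 1600)
})

test_that("cone of influence is the symmetric e-folding boundary", {
  b <- coi(46)
  expect_equal(b[1], 0)
  expect_equal(b[46], 0)
  expect_equal(max(b), (46 - 1) %/% 2 / sqrt(2))
  expect_equal(b, rev(b))
  n <- 47  # odd: single central maximum at (n-1)/(2 sqrt(2))
  expect_equal(max(coi(n)), (n - 1) / 2 / sqrt(2))
})

test_that("coherence of a series with itself is 1 in phase inside the coi", {
  set.seed(41)
  x <- rnorm(46)
  cm <- wavelet_coherence(x, x)
  expect_gte(min(cm$coherence[cm$in_coi]), 0.99)
  expect_lt(max(abs(cm$phase[cm$in_coi])), 0.05)
})

test_that("a quarter-period delay shows as a pi/2 phase at the wave scale", {
  t <- 0:45
  x <- cos(2 * pi * t / 12)
  y <- cos(2 * pi * (t - 3) / 12)
  cm <- wavelet_coherence(x, y)
  si <- which.min(abs(cm$periods - 12))
  ok <- cm$in_coi[si, ]
  expect_true(any(ok))
  expect_lt(max(abs(cm$phase[si, ok] - pi / 2)), 0.2)
})

test_that("coherence is bounded, symmetric, and lower for independent noise", {
  set.seed(53)
  med_indep <- replicate(20, {
    cm <- wavelet_coherence(rnorm(46), rnorm(46))
    expect_true(all(cm$coherence >= 0 & cm$coherence <= 1 + 1e-9))
    median(cm$coherence[cm$in_coi])
  })
  x <- rnorm(46)
  med_ident <- median({cm <- wavelet_coherence(x, x); cm$coherence[cm$in_coi]})
  expect_lt(median(med_indep), med_ident)
  y <- rnorm(46)
  a <- wavelet_coherence(x, y); b <- wavelet_coherence(y, x)
  expect_lt(max(abs(a$coherence - b$coherence)), 1e-9)
  expect_lt(max(abs(a$phase + b$phase)), 1e-9)
  expect_error(wavelet_coherence(x, y[1:20]), "lengths differ")
  expect_error(wavelet_coherence(rep(1, 46), y), "zero-variance")
})

test_that("coherence at the wave scale grows with mutation yield", {
  g <- ecoli_genome()
  mean_band_coh <- function(rate_per_line) {
    spec <- sim_spec(g, rate_per_line,
                     wave_components = list(list(amplitude = 0.5,
                                                 period_kb = 1200,
                                                 phase = 0)),
                     symmetric = TRUE, n_lines = 20L,
                     generations_per_line = 500, seed = 97L)
    ser <- bin_mutations(simulate_experiment(spec)$records, g)
    cm <- wavelet_coherence(ser$counts, ccw_series(ser$counts))
    band <- cm$periods >= 8 & cm$periods <= 16
    mean(cm$coherence[band, , drop = FALSE][cm$in_coi[band, , drop = FALSE]])
  }
  cohs <- vapply(c(0.005, 0.05, 0.5), mean_band_coh, numeric(1))
  expect_true(all(diff(cohs) > 0))
})
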