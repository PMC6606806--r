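test_that("wave intensity follows the cosine model and its symmetry", {
  g <- ecoli_genome()
  flat <- sim_spec(g, 0.1, wave_components = list(), seed = 1)
  expect_equal(wave_intensity(flat, c(1, 1000, g$length_bp)), rep(1, 3))
  spec <- sim_spec(g, 0.1,
                   wave_components = list(list(amplitude = 0.5,
                                               period_kb = g$length_bp / 4000,
                                               phase = 0)),
                   symmetric = FALSE, seed = 1)
  grid <- seq(1, g$length_bp, by = 1000)
  lam <- wave_intensity(spec, grid)
  d <- (grid - g$ori_position_bp) %% g$length_bp
  expect_equal(lam, 1 + 0.5 * cos(2 * pi * d / (g$length_bp / 4)))
  # symmetric: equal intensity at mirrored offsets about the origin
  sym <- sim_spec(g, 0.1,
                  wave_components = list(list(amplitude = 0.4,
                                              period_kb = 1200, phase = 0)),
                  symmetric = TRUE, seed = 1)
  for (x in c(5e4, 5e5, 1.7e6)) {
    up <- ((g$ori_position_bp + x - 1) %% g$length_bp) + 1
    dn <- ((g$ori_position_bp - x - 1) %% g$length_bp) + 1
    expect_equal(wave_intensity(sym, up), wave_intensity(sym, dn))
  }
  expect_error(sim_spec(g, 0.1,
                        wave_components = list(list(amplitude = 1.5,
                                                    period_kb = 1200,
                                                    phase = 0)),
                        seed = 1),
               "negative")
})

test_that("simulated totals are Poisson at the configured rate", {
  g <- ecoli_genome()
  spec <- mmr_like_preset(g, seed = 5)
  ds <- simulate_experiment(spec)
  mu <- 40 * 650 * 0.113    # expected yield ~ 2,938
  expect_lt(abs(nrow(ds$records) - mu), 4 * sqrt(mu))
  expect_equal(ds$meta$total_generations, 26000)
  expect_equal(length(unique(ds$records$line_id)), 40)
  # fixed seed -> identical dataset
  ds2 <- simulate_experiment(mmr_like_preset(g, seed = 5))
  expect_identical(ds$records, ds2$records)
})

test_that("the position sampler matches the target intensity", {
  g <- ecoli_genome()
  spec <- sim_spec(g, 2.5,
                   wave_components = list(list(amplitude = 0.5,
                                               period_kb = 1200, phase = 0)),
                   symmetric = TRUE, n_lines = 40L,
                   generations_per_line = 1000, seed = 13L)
  ds <- simulate_experiment(spec)      # ~ 1e5 draws
  ser <- bin_mutations(ds$records, g)
  expected <- ds$true_bin_intensity / sum(ds$true_bin_intensity) *
    nrow(ds$records)
  expect_lt(max(abs(ser$counts / expected - 1)), 0.05)
})

test_that("a symmetric intensity yields mirror-balanced bin counts", {
  g <- ecoli_genome()
  spec <- sim_spec(g, 2.5,
                   wave_components = list(list(amplitude = 0.5,
                                               period_kb = 1200, phase = 0)),
                   symmetric = TRUE, n_lines = 40L,
                   generations_per_line = 1000, seed = 29L)
  ds <- simulate_experiment(spec)
  # ground truth is mirror-symmetric about the origin point at the start
  # of bin 1: bin b pairs with bin 47 - b (1 with 46, ..., 23 with 24)
  tr <- ds$true_bin_intensity
  expect_equal(tr[1:23], tr[46:24], tolerance = 0.02)
  cnt <- bin_mutations(ds$records, g)$counts
  diffs <- cnt[1:23] - cnt[46:24]
  bt <- binom.test(sum(diffs > 0), sum(diffs != 0))
  expect_gt(bt$p.value, 0.01)
})

test_that("zero-amplitude simulations are uniform over bins", {
  g <- ecoli_genome()
  pass <- 0L
  for (r in 1:100) {
    spec <- sim_spec(g, 0.5, wave_components = list(), n_lines = 5L,
                     generations_per_line = 200, seed = 2000L + r)
    cnt <- bin_mutations(simulate_experiment(spec)$records, g)$counts
    if (suppressWarnings(chisq.test(cnt)$p.value) > 0.01) pass <- pass + 1L
  }
  expect_gte(pass, 95L)
})

test_that("hot-spot enrichment places A:T transitions at NAC sites", {
  g <- genome_map("mini", 50000, 1, n_bins = 10)
  spec <- sim_spec(g, 1, wave_components = list(), n_lines = 10L,
                   generations_per_line = 200,
                   hotspot = list(nac_multiplier = 10), seed = 43L)
  ds <- simulate_experiment(spec)
  expect_equal(nchar(ds$reference), 50000)
  cls <- classify_context(ds$records, ds$reference)
  hot_frac <- mean(cls$context == "hotspot_NAC" &
                     cls$class == "AT_to_GC_transition")
  # ~1/8 of sites are hot spots; at 10x enrichment the expected hot-spot
  # fraction is m*nh/(m*nh + L - nh) with nh ~ L/8, i.e. ~0.59
  expect_gt(hot_frac, 0.5)
  # the filter removes exactly those records
  kept <- filter_hotspots(ds$records, ds$reference)
  expect_equal(nrow(kept), sum(!(cls$context == "hotspot_NAC" &
                                   cls$class == "AT_to_GC_transition")))
})

test_that("the MMR-like preset is a valid study-scale configuration", {
  spec <- mmr_like_preset(seed = 3)
  expect_s3_class(spec, "sim_spec")
  expect_equal(spec$n_lines * spec$generations_per_line, 26000)
  lam <- wave_intensity(spec, seq(1, spec$genome$length_bp, by = 5000))
  expect_gte(min(lam), 0)
  # ~3-fold peak-to-trough swing of the underlying wave
  expect_gt(max(lam) / min(lam), 2)
  expect_lt(max(lam) / min(lam), 6)
})
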