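test_that("bin_mutations conserves counts and matches a brute-force rebin", {
  g <- ecoli_genome()
  expect_equal(bin_mutations(mutation_records(character(0), numeric(0),
                                              character(0), character(0)),
                             g)$counts,
               rep(0, 46))
  set.seed(11)
  pos <- sample.int(g$length_bp, 10000, replace = TRUE)
  rec <- mutation_records("l1", pos, "A", "G")
  ser <- bin_mutations(rec, g)
  expect_equal(sum(ser$counts), 10000)
  oracle <- rep(0, 46)
  w <- g$length_bp / 46
  for (p in pos) {
    off <- (p - g$ori_position_bp) %% g$length_bp
    oracle[floor(off / w) + 1] <- oracle[floor(off / w) + 1] + 1
  }
  expect_equal(ser$counts, oracle)
})

test_that("one mutation per bin center gives unit counts", {
  g <- toy_genome(4600, 100, 46)
  w <- g$length_bp / g$n_bins
  centers <- ((g$ori_position_bp + floor((seq_len(46) - 0.5) * w) - 1) %%
                g$length_bp) + 1
  rec <- mutation_records("l", centers, "A", "G")
  expect_equal(bin_mutations(rec, g)$counts, rep(1, 46))
})

test_that("genome rate is the pooled per-generation rate x 1000", {
  expect_equal(genome_rate(0, 100), 0)
  expect_error(genome_rate(10, 0), "generations")
  # scale equivariance: multiplying counts and generations by c > 0
  set.seed(5)
  for (i in 1:20) {
    n <- rpois(1, 100) + 1; gen <- runif(1, 10, 1e6); c_ <- runif(1, .1, 50)
    expect_equal(genome_rate(n * c_, gen * c_), genome_rate(n, gen))
  }
  # pooled rate equals the generation-weighted mean of per-line rates
  counts <- rpois(40, 30); gens <- runif(40, 400, 900)
  pooled <- genome_rate(sum(counts), sum(gens))
  weighted <- sum(gens / sum(gens) * genome_rate(counts, gens))
  expect_equal(pooled, weighted, tolerance = 1e-12)
})

test_that("bootstrap rate CL collapses for identical lines and is seeded", {
  cl <- rate_cl95(rep(6, 10), rep(600, 10), n_boot = 1000, seed = 3)
  r <- 1000 * 6 / 600
  expect_equal(unname(cl), c(r, r))
  set.seed(77)
  counts <- rpois(15, 40); gens <- rep(600, 15)
  a <- rate_cl95(counts, gens, n_boot = 2000, seed = 1)
  b <- rate_cl95(counts, gens, n_boot = 2000, seed = 1)
  expect_identical(a, b)
  expect_error(rate_cl95(5, 600), "2 lines")
})

test_that("bootstrap CL covers the true rate at roughly nominal level", {
  # 40 lines, Poisson counts at 0.1/generation, 600 generations/line
  cover <- 0L
  for (r in 1:100) {
    set.seed(1000 + r)
    counts <- rpois(40, 0.1 * 600)
    cl <- rate_cl95(counts, rep(600, 40), n_boot = 1000, seed = r)
    if (cl[["low"]] <= 100 && 100 <= cl[["high"]]) cover <- cover + 1L
  }
  expect_gte(cover, 93L)
})

test_that("mean rate series and its CL match the direct formula", {
  s1 <- binned_series(rep(2, 8), 10, "a")
  ms <- mean_rate_series(list(s1, s1, s1))
  expect_equal(ms$mean_rate, s1$rates)
  expect_equal(ms$cl_high - ms$cl_low, rep(0, 8))
  s2 <- binned_series(c(1, 3, rep(2, 6)), 10, "b")
  expect_equal(mean_rate_series(list(s1, s2))$mean_rate[1], 0.15)
  set.seed(21)
  sl <- lapply(1:10, function(i) binned_series(rpois(12, 20), 100,
                                               paste0("s", i)))
  ms <- mean_rate_series(sl)
  m <- sapply(sl, function(s) s$rates)
  for (b in c(1, 5, 12)) {
    expect_equal(ms$mean_rate[b], mean(m[b, ]))
    se <- sd(m[b, ]) / sqrt(10)
    expect_equal(ms$cl_high[b], mean(m[b, ]) + qt(0.975, 9) * se)
  }
  expect_error(mean_rate_series(list(s1)), "at least 2")
  expect_error(mean_rate_series(list(s1, binned_series(1:4, 10))),
               "mismatched")
})

test_that("signal binning normalizes to the reference gene weight", {
  g <- toy_genome(1000, 1, 10)
  set.seed(8)
  pos <- sample.int(1000, 200, replace = TRUE)
  wgt <- runif(200)
  sig <- bin_signal(pos, wgt, g, reference_gene_weight = sum(wgt))
  expect_equal(sum(sig), 1)
  oracle <- rep(0, 10)
  for (i in seq_along(pos)) {
    b <- naive_bin(pos[i], g)
    oracle[b] <- oracle[b] + wgt[i]
  }
  expect_equal(sig, oracle / sum(wgt))
  expect_equal(bin_signal(pos, rep(0, 200), g, 5), rep(0, 10))
  expect_error(bin_signal(pos, wgt, g, 0), "> 0")
})

test_that("pooling is generation-weighted and feeds the rate table", {
  s1 <- binned_series(rep(10, 46), 1000, "a")
  s2 <- binned_series(rep(40, 46), 3000, "b")
  p <- pool_series(list(s1, s2))
  expect_equal(p$total_generations, 4000)
  expect_equal(p$rates, rep(50 / 4000, 46))
  rec <- mutation_records(rep(c("l1", "l2"), c(3, 5)),
                          c(10, 20, 30, 40, 50, 60, 70, 80),
                          "A", "G")
  meta <- experiment_meta("x", 2, 1200, c(500, 700))
  tab <- rate_table(list(list(meta = meta, records = rec)), n_boot = 1000)
  expect_equal(tab$bps_count, 8)
  expect_equal(tab$rate_per_gen_x1000, 1000 * 8 / 1200)
  expect_true(tab$cl95_low <= tab$rate_per_gen_x1000 &
                tab$rate_per_gen_x1000 <= tab$cl95_high)
})
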