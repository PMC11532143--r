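test_that("simulation is bitwise deterministic given a seed", {
  cfg <- sim_config(duration = 8, offline_gap = c(1, 2), seed = 42)
  a <- simulate_batch(cfg)
  b <- simulate_batch(cfg)
  expect_identical(a$batch, b$batch)
  expect_identical(a$truth$cer, b$truth$cer)
  c <- simulate_batch(sim_config(duration = 8, offline_gap = c(1, 2),
                                 seed = 43))
  expect_false(identical(a$batch$series$ph$values,
                         c$batch$series$ph$values))
})

test_that("generated batches satisfy every dataset invariant", {
  for (seed in 1:3) {
    res <- simulate_batch(sim_config(duration = 10, offline_gap = c(1, 2),
                                     seed = seed))
    expect_length(validate_batch(res$batch), 0L)
    expect_equal(res$truth$rq, res$truth$cer / res$truth$our)
  }
})

test_that("noiseless outlet fractions close to 100 percent", {
  res <- simulate_batch(sim_config(duration = 10, offline_gap = c(1, 2),
                                   noise_scale = 0, seed = 2))
  s <- res$batch$series
  total_out <- s$o2_out$values + s$co2_out$values + s$n2_out$values
  total_in <- s$o2_in$values + s$co2_in$values + s$n2_in$values
  expect_equal(total_out, rep(100, length(total_out)), tolerance = 1e-9)
  expect_equal(total_in, rep(100, length(total_in)), tolerance = 1e-9)
})

test_that("gas_rates inverts the generator exactly at the sampling times", {
  cfg <- sim_config(duration = 10, offline_gap = c(1, 2), noise_scale = 0,
                    seed = 3)
  res <- simulate_batch(cfg)
  s <- res$batch$series
  t_at <- s$o2_out$times
  tr <- fermfuse:::sim_truth_at(cfg, t_at)
  g <- gas_rates(cfg$air_flow, tr$m,
                 s$co2_in$values, s$o2_in$values, s$n2_in$values,
                 s$co2_out$values, s$o2_out$values, s$n2_out$values)
  expect_lt(max(rel_err(g$cer, tr$cer)), 1e-6)
  expect_lt(max(rel_err(g$our, tr$our)), 1e-6)
})

test_that("zero growth leaves maintenance-only respiration and flat biomass", {
  # no feed either, so broth mass (hence outlet dilution) stays constant
  cfg <- sim_config(duration = 10, offline_gap = c(1, 2), mu_max = 0,
                    feed_rate = 0, noise_scale = 0, seed = 4)
  res <- simulate_batch(cfg)
  tr <- res$truth
  expect_equal(tr$biomass, rep(cfg$x0, length(tr$times)))
  expect_equal(tr$our, rep(cfg$our_maint * cfg$x0, length(tr$times)),
               tolerance = 1e-12)
  # constant O2 deficit at the outlet
  o2 <- res$batch$series$o2_out$values
  expect_lt(max(o2) - min(o2), 1e-9)
  expect_lt(max(o2), cfg$inlet[["o2"]])
})

test_that("anomaly injection modifies only the named interval and is recorded", {
  res <- simulate_batch(sim_config(duration = 10, offline_gap = c(1, 2),
                                   noise_scale = 0, seed = 5))
  before <- res$batch$series$co2_in$values
  out <- inject_anomaly(res$batch,
                        list(variable = "co2_in", type = "step", start = 4,
                             duration = 2, magnitude = 0.03), res$truth)
  after <- out$batch$series$co2_in$values
  tt <- out$batch$series$co2_in$times
  hit <- tt >= 4 & tt < 6
  expect_equal(after[!hit], before[!hit])
  expect_equal(after[hit], before[hit] + 0.03)
  expect_length(out$truth$anomalies, 1L)

  expect_error(inject_anomaly(res$batch, list(variable = "zz", type = "step",
                                              start = 1, duration = 1,
                                              magnitude = 1)),
               "unknown variable")
  expect_error(inject_anomaly(res$batch,
                              list(variable = "co2_in", type = "step",
                                   start = 9, duration = 5, magnitude = 1)),
               "outside")
  # an empty anomaly list leaves the generated batch untouched
  again <- simulate_batch(sim_config(duration = 10, offline_gap = c(1, 2),
                                     noise_scale = 0, seed = 5,
                                     anomalies = list()))
  expect_identical(again$batch, res$batch)
})

test_that("study generation jitters batches and stunts designated outliers", {
  study <- simulate_study(4, sim_config(duration = 12, offline_gap = c(1, 2),
                                        seed = 9), outliers = 2)
  expect_length(study, 4L)
  caps <- vapply(study, function(s) s$truth$config$capacity, numeric(1))
  expect_lt(caps[2], 0.5 * min(caps[-2]))
  # distinct seeds give distinct but same-shape batches
  expect_false(identical(study[[1]]$batch$series$ph$values,
                         study[[3]]$batch$series$ph$values))
  expect_identical(study[[1]]$batch$series$ph$times,
                   study[[3]]$batch$series$ph$times)
})
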