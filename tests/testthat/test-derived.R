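test_that("gas_rates reproduces the hand-computed balance example", {
  # 2 % O2 deficit and 2 % CO2 surplus at equal N2: both rates
  # 1000 * 0.02 * 60/22.4 = 53.571 mmol kg^-1 h^-1, RQ = 1
  g <- gas_rates(f_air_in = 1000, m = 1.0,
                 y_co2_in = 0.04, y_o2_in = 20.96, y_n2_in = 79.00,
                 y_co2_out = 2.04, y_o2_out = 18.96, y_n2_out = 79.00)
  expect_equal(g$cer, 53.571, tolerance = 1e-4)
  expect_equal(g$our, 53.571, tolerance = 1e-4)
  expect_equal(g$rq, 1.0)

  # no exchange: inlet == outlet
  g0 <- gas_rates(1000, 1, 0.04, 20.96, 79, 0.04, 20.96, 79)
  expect_equal(g0$cer, 0)
  expect_equal(g0$our, 0)
  expect_true(is.na(g0$rq))

  # linear in air flow, RQ invariant
  g2 <- gas_rates(2000, 1, 0.04, 20.96, 79, 2.04, 18.96, 79)
  expect_equal(g2$cer, 2 * g$cer)
  expect_equal(g2$our, 2 * g$our)
  expect_equal(g2$rq, g$rq)

  expect_error(gas_rates(1000, 1, 0.04, 20.96, 79, 2.04, 18.96, 0),
               "y_n2_out")
})

test_that("gas_rates is unit-flag consistent between percent and fraction", {
  pct <- gas_rates(800, 1.2, 0.04, 20.96, 79, 1.5, 19.4, 79.1)
  frac <- gas_rates(800, 1.2, 0.0004, 0.2096, 0.79, 0.015, 0.194, 0.791,
                    percent = FALSE)
  expect_equal(pct$cer, frac$cer, tolerance = 1e-12)
  expect_equal(pct$our, frac$our, tolerance = 1e-12)
})

test_that("RQ identity rq * our == cer holds wherever our is nonzero", {
  set.seed(31)
  for (k in 1:50) {
    g <- gas_rates(stats::runif(1, 100, 2000), stats::runif(1, 0.5, 2),
                   0.04, 20.96, 79,
                   stats::runif(1, 0.05, 3), stats::runif(1, 17, 20.9),
                   stats::runif(1, 78, 80))
    if (!is.na(g$rq)) expect_equal(g$rq * g$our, g$cer, tolerance = 1e-12)
  }
})

test_that("derivative estimation is exact on lines and central on parabolas", {
  lin <- ferm_ts("M", seq(0, 5, by = 0.5), 3 * seq(0, 5, by = 0.5) + 1)
  expect_equal(estimate_dmdt(lin)$values, rep(3, 11), tolerance = 1e-10)
  par <- ferm_ts("M", c(0, 1, 2), c(0, 1, 4))
  expect_equal(estimate_dmdt(par)$values[2], 2)  # (4 - 0) / 2
  const <- ferm_ts("M", 0:4, rep(2, 5))
  expect_equal(estimate_dmdt(const)$values, rep(0, 5))
  expect_error(estimate_dmdt(ferm_ts("M", 0:1, 1:2)), "three points")
})

test_that("process_rate implements the component balance", {
  # closed batch, M = a t: R equals the slope
  expect_equal(process_rate(3), 3)
  expect_equal(process_rate(0, inflow = 5, outflow = 2), -3)
  # transfer absorbing everything leaves no reaction
  expect_equal(process_rate(4, inflow = 1, outflow = 0, transfer = 3), 0)
})

test_that("specific rates scale by the averaging denominators", {
  tr <- specific_rates(2, m_avg = 1, od_m_avg = 10)
  expect_equal(tr$r, 2)
  expect_equal(tr$q, 0.2)
  expect_equal(specific_rates(0, 1, 10)$q, 0)
  tr2 <- specific_rates(2, m_avg = 1, od_m_avg = 20)
  expect_equal(tr2$q, tr$q / 2)
  expect_equal(tr2$r, tr$r)
  expect_error(specific_rates(1, 0, 1), "m_avg")
})

test_that("yield coefficients are identical across the three rate levels", {
  ti <- specific_rates(2, 1.5, 12)
  tj <- specific_rates(4, 1.5, 12)
  expect_equal(yield_coefficient(ti, tj), 0.5)
  expect_equal(yield_coefficient(ti, ti), 1)
  # scaling both rates leaves the yield unchanged
  expect_equal(yield_coefficient(specific_rates(6, 1.5, 12),
                                 specific_rates(12, 1.5, 12)), 0.5)
  # mismatched denominators are rejected
  tj2 <- specific_rates(4, 3.0, 12)
  expect_error(yield_coefficient(ti, tj2), "denominators")
  expect_error(yield_coefficient(ti, specific_rates(0, 1.5, 12)), "zero")
})

test_that("add_gas_rates appends derived columns on the fused grid", {
  res <- simulate_batch(sim_config(duration = 6, offline_gap = c(1, 2),
                                   seed = 6))
  fr <- add_gas_rates(fuse_batch(res$batch))
  expect_true(all(c("CER", "OUR", "RQ") %in% names(fr$data)))
  expect_equal(fr$data$RQ * fr$data$OUR, fr$data$CER, tolerance = 1e-9)
  expect_error(add_gas_rates(fuse_batch(make_toy_batch())), "lacks column")
})
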