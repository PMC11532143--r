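test_that("spearman screen matches the brute-force rank oracle, with ties", {
  df <- data.frame(x = c(1, 2, 2, 4), y = c(1, 3, 2, 4))
  scr <- spearman_screen(df, targets = "y", factors = "x")
  expect_equal(scr$rho["y", "x"], oracle_spearman(df$x, df$y),
               tolerance = 1e-12)

  set.seed(14)
  for (k in 1:60) {
    n <- sample(4:50, 1)
    x <- sample(1:8, n, replace = TRUE)   # heavy ties
    y <- x + sample(0:4, n, replace = TRUE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    scr <- spearman_screen(data.frame(x = x, y = y), "y", "x")
    expect_equal(scr$rho["y", "x"], oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
})

test_that("spearman screen hits +/-1 on strict monotone pairs and NA on constants", {
  x <- c(1, 4, 9, 11, 30)
  scr <- spearman_screen(data.frame(x = x, up = exp(x), down = -x^3),
                         targets = "x")
  expect_equal(scr$rho["x", "up"], 1)
  expect_equal(scr$rho["x", "down"], -1)
  scr2 <- spearman_screen(data.frame(x = x, const = rep(2, 5)), "x")
  expect_true(is.na(scr2$rho["x", "const"]))
})

test_that("spearman p-values are sound at both small and large n", {
  # n = 5, perfect monotone, no ties: exact two-sided p = 2/5! = 1/60
  scr <- spearman_screen(data.frame(x = 1:5, y = c(2, 5, 9, 11, 20)), "y")
  expect_equal(scr$p["y", "x"], 1 / 60, tolerance = 1e-12)
  # large n, independent columns: p should not be degenerate
  set.seed(3)
  scr2 <- spearman_screen(data.frame(x = stats::rnorm(100),
                                     y = stats::rnorm(100)), "y")
  expect_gt(scr2$p["y", "x"], 0.001)
})

test_that("resampling onto a common grid is exact for affine columns", {
  mk <- function(times, slope) {
    fused_frame(times,
                data.frame(a = slope * times, b = 2 - times),
                data.frame(variable = c("a", "b"), source = "online",
                           method = "native_grid"))
  }
  frames <- list(b1 = mk(seq(0, 10, 0.25), 2), b2 = mk(seq(0, 12, 0.4), 2))
  rs <- resample_common_grid(frames, max_points = 37)
  expect_equal(rs$batches$b1[, "a"], 2 * rs$grid, tolerance = 1e-12)
  expect_equal(rs$batches$b2[, "b"], 2 - rs$grid, tolerance = 1e-12)

  frames$b2$data$c <- frames$b2$data$a
  frames$b2$provenance <- rbind(frames$b2$provenance,
                                data.frame(variable = "c", source = "online",
                                           method = "native_grid"))
  expect_error(resample_common_grid(frames), "b2")
  expect_error(resample_common_grid(frames[1], variables = "zz"), "zz")
})

test_that("flat PCA collapses identical batches and exposes a planted outlier", {
  study <- simulate_study(6, sim_config(duration = 24, seed = 11),
                          outliers = 5)
  frames <- lapply(study, function(s) add_gas_rates(fuse_batch(s$batch)))
  rs <- resample_common_grid(frames, max_points = 300)
  pf <- pca_flat(batch_matrix_flat(rs))
  expect_true(all(diff(pf$explained) <= 1e-12))
  expect_lte(sum(pf$explained), 1 + 1e-9)
  sc <- pf$scores[, 1:2]
  cent <- colMeans(sc[-5, , drop = FALSE])
  d <- sqrt(rowSums(sweep(sc, 2, cent)^2))
  expect_identical(unname(which.max(d)), 5L)

  # byte-identical batches land on the same score point
  flat <- batch_matrix_flat(rs)
  flat2 <- rbind(flat, flat[1, , drop = FALSE])
  rownames(flat2) <- c(rownames(flat), "dup")
  pf2 <- pca_flat(flat2)
  expect_equal(pf2$scores["dup", ], pf2$scores[1, ], tolerance = 1e-8)

  expect_error(pca_flat(flat[1, , drop = FALSE]), "fewer batches")
})

test_that("time-resolved PCA smooths trajectories and keeps unit loadings", {
  study <- simulate_study(3, sim_config(duration = 24, seed = 17))
  frames <- lapply(study, function(s) add_gas_rates(fuse_batch(s$batch)))
  rs <- resample_common_grid(frames, max_points = 200)
  pt <- pca_time(batch_matrix_stacked(rs))
  expect_equal(unname(apply(pt$loadings, 2, function(v) sqrt(sum(v^2)))),
               rep(1, 2), tolerance = 1e-9)
  expect_identical(nrow(pt$trajectories), 3L * 200L)
  # the sign convention makes the dominant loading positive
  for (k in 1:2) {
    expect_gte(pt$loadings[which.max(abs(pt$loadings[, k])), k], 0)
  }
  expect_error(pca_time(batch_matrix_stacked(rs), sg_window = 10), "odd")
})

test_that("Savitzky-Golay smoothing is exact on low-degree polynomials", {
  x <- seq(0, 1, length.out = 101)
  y <- 2 - 3 * x + 0.5 * x^3
  sm <- signal::sgolayfilt(y, p = 3, n = 11)
  interior <- 6:96
  expect_equal(sm[interior], y[interior], tolerance = 1e-10)
})

test_that("a step disturbance is localized in time and attributed to its variable", {
  study <- simulate_study(4, sim_config(duration = 24, seed = 21))
  study[[3]]$batch <- inject_anomaly(
    study[[3]]$batch,
    list(variable = "do", type = "step", start = 12, duration = 2,
         magnitude = -30))$batch
  frames <- lapply(study, function(s) add_gas_rates(fuse_batch(s$batch)))
  vars <- c("do", "ph", "stirring", "CER", "OUR", "weight", "feed_rate")
  rs <- resample_common_grid(frames, variables = vars, max_points = 300)
  pt <- pca_time(batch_matrix_stacked(rs), n_components = 3)
  loc <- locate_disturbance(pt, "batch03")
  w <- 11 * diff(rs$grid[1:2])
  expect_gte(loc$time, 12 - w)
  expect_lte(loc$time, 14 + w)
  expect_true("do" %in% loc$ranking[1:3])
})
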