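make_frame_with_target <- function(duration = 6, seed = 8,
                                   target_fun = NULL) {
  res <- simulate_batch(sim_config(duration = duration,
                                   offline_gap = c(1, 2), seed = seed))
  fr <- add_gas_rates(fuse_batch(res$batch))
  list(frame = fr, truth = res$truth)
}

test_that("sample assembly counts rows and rejects target-in-features", {
  x <- make_frame_with_target()
  n <- length(x$frame$times)
  s <- assemble_samples(list(b1 = x$frame), feature_spec())
  expect_identical(nrow(s$X), n)
  expect_identical(s$dropped, 0L)
  expect_identical(colnames(s$X), feature_spec()$features)

  expect_error(feature_spec(features = c("ph", "biomass")), "features")
  expect_error(assemble_samples(list(b1 = x$frame),
                                feature_spec(target = "nope")),
               "lacks column")
})

test_that("anomalous spans from a fault report are excluded from samples", {
  x <- make_frame_with_target()
  rep <- list(intervals = data.frame(start = 1, end = 2, rule = "mean_band",
                                     statistic = 0, tag = "sustained"))
  s <- assemble_samples(list(b1 = x$frame), feature_spec(),
                        exclude = list(b1 = rep))
  inside <- sum(x$frame$times >= 1 & x$frame$times <= 2)
  expect_identical(s$dropped, inside)
  expect_true(all(s$time < 1 | s$time > 2))
})

test_that("the 8:2 split is an exact deterministic partition", {
  x <- make_frame_with_target()
  s <- assemble_samples(list(b1 = x$frame), feature_spec())
  for (n in c(5L, 7L, 10L, 123L)) {
    ss <- subset_samples_for_test(s, seq_len(n))
    sp <- split_train_val(ss, seed = 99)
    expect_identical(length(sp$train$y), as.integer(round(0.8 * n)))
    expect_identical(length(sp$val$y), as.integer(round(0.2 * n)))
    expect_length(intersect(sp$train$time, sp$val$time), 0L)
    expect_setequal(c(sp$train$time, sp$val$time), ss$time)
    sp2 <- split_train_val(ss, seed = 99)
    expect_identical(sp$train$time, sp2$train$time)
  }
  expect_error(split_train_val(subset_samples_for_test(s, 1:4)), "at least 5")
})

test_that("a realizable linear target is fit to numerical precision", {
  x <- make_frame_with_target()
  fr <- x$frame
  spec <- feature_spec(features = c("OUR", "weight", "stirring"),
                       target = "lin_target")
  fr$data$lin_target <- 2 * fr$data$OUR - 5 * fr$data$weight + 0.1
  fr$provenance <- rbind(fr$provenance,
                         data.frame(variable = "lin_target",
                                    source = "online", method = "derived"))
  s <- assemble_samples(list(b1 = fr), spec)
  sp <- split_train_val(s, seed = 2)
  m <- fit_soft_sensor(sp$train, regressor_linear(), val = sp$val)
  pred <- predict_stream(m, fr, spec)
  expect_identical(pred$times, fr$times)
  expect_lt(sqrt(mean((pred$values - fr$data$lin_target)^2)), 1e-6)
  expect_lt(m$losses$val, 1e-10)
})

test_that("the MLP learns a noisy nonlinear map to within twice the noise sd", {
  set.seed(77)
  n <- 600
  X <- cbind(a = stats::runif(n, -1, 1), b = stats::runif(n, -1, 1))
  sigma <- 0.05
  y <- sin(2 * X[, "a"]) + X[, "b"]^2 + stats::rnorm(n, 0, sigma)
  s <- structure(list(X = X, y = y, time = seq_len(n),
                      batch = rep("b", n), dropped = 0L),
                 class = "sample_set")
  sp <- split_train_val(s, seed = 5)
  m <- fit_soft_sensor(sp$train, regressor_mlp(epochs = 500), val = sp$val,
                       seed = 5)
  Zv <- sweep(sweep(sp$val$X, 2, m$center, "-"), 2, m$scale, "/")
  rmse <- sqrt(mean((fermfuse:::regressor_predict(m$fit, Zv) - sp$val$y)^2))
  expect_lt(rmse, 2 * sigma)
  # loss curve is recorded and converges
  expect_identical(nrow(m$losses), 500L)
  expect_lt(utils::tail(m$losses$train, 1), m$losses$train[1])
})

test_that("a constant target yields a constant predictor", {
  x <- make_frame_with_target()
  fr <- x$frame
  spec <- feature_spec(features = c("OUR", "weight"), target = "const_t")
  fr$data$const_t <- rep(3.5, length(fr$times))
  fr$provenance <- rbind(fr$provenance,
                         data.frame(variable = "const_t", source = "online",
                                    method = "derived"))
  s <- assemble_samples(list(b1 = fr), spec)
  m <- fit_soft_sensor(s, regressor_mlp(epochs = 50), seed = 3)
  pred <- predict_stream(m, fr, spec)
  expect_equal(pred$values, rep(3.5, length(fr$times)), tolerance = 1e-2)
})

test_that("serialization round-trips predictions bitwise", {
  x <- make_frame_with_target()
  s <- assemble_samples(list(b1 = x$frame), feature_spec())
  sp <- split_train_val(s, seed = 4)
  m <- fit_soft_sensor(sp$train, regressor_mlp(epochs = 30), seed = 4)
  p1 <- predict_stream(m, x$frame, feature_spec())
  path <- file.path(withr::local_tempdir(), "model.rds")
  saveRDS(m, path)
  p2 <- predict_stream(readRDS(path), x$frame, feature_spec())
  expect_identical(p1$values, p2$values)
})

test_that("predictions are stateless across streaming order", {
  x <- make_frame_with_target()
  s <- assemble_samples(list(b1 = x$frame), feature_spec())
  m <- fit_soft_sensor(s, regressor_linear())
  full <- predict_stream(m, x$frame, feature_spec())
  # predict on a reversed-row frame subset: values depend only on the row
  idx <- c(50, 10, 200)
  sub <- fused_frame(x$frame$times[sort(idx)],
                     x$frame$data[sort(idx), ],
                     x$frame$provenance)
  ps <- predict_stream(m, sub, feature_spec())
  expect_equal(ps$values, full$values[sort(idx)], tolerance = 1e-12)
})
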