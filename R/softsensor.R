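# Soft-sensing pipeline: assemble per-time-point feature vectors from the
# fused frame, train a pluggable regressor against offline-labelled
# targets, and predict the target (typically biomass) on the fused grid
# in streaming fashion.
#
# The regressor is a contract (fit + predict + plain-list serialization);
# two implementations ship: a linear least-squares baseline and a
# feed-forward multilayer perceptron trained with Adam. Features are
# z-scored with training-set statistics only; the statistics travel with
# the model so streaming prediction is self-contained.

#' Feature specification for the soft sensor
#'
#' The default feature set is the routinely available online channels of
#' a fed-batch run plus the derived gas-exchange rates; the default
#' target is biomass.
#'
#' @param features Character vector of fused-frame column names.
#' @param target Target column name; must not appear in `features`.
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(features = c("stirring", "do", "feed_rate", "ph",
                                      "temperature", "weight", "air_flow",
                                      "acid_pump", "inspection_pump",
                                      "CER", "OUR"),
                         target = "biomass") {
  if (target %in% features) {
    stop("target '", target, "' must not be among the features", call. = FALSE)
  }
  structure(list(features = features, target = target),
            class = "feature_spec")
}

#' Assemble training samples from fused frames
#'
#' One sample per grid point carrying all features and a target value;
#' rows with any missing entry are dropped and counted. Spans flagged
#' anomalous by a fault report can be excluded, mirroring the manual
#' removal of process anomalies before training.
#'
#' @param frames Named list of [fused_frame()]s.
#' @param spec A [feature_spec()].
#' @param exclude Optional named list of `fault_report`s (per batch);
#'   samples inside anomalous intervals are dropped.
#' @return An object of class `sample_set`: list with `X` (matrix), `y`,
#'   `time`, `batch`, `dropped`.
#' @export
assemble_samples <- function(frames, spec = feature_spec(), exclude = NULL) {
  stopifnot(inherits(spec, "feature_spec"))
  if (inherits(frames, "fused_frame")) frames <- list(batch = frames)
  if (is.null(names(frames))) names(frames) <- paste0("batch", seq_along(frames))
  Xs <- list(); ys <- list(); tts <- list(); bbs <- list()
  dropped <- 0L
  for (b in names(frames)) {
    f <- frames[[b]]
    need <- c(spec$features, spec$target)
    miss <- setdiff(need, names(f$data))
    if (length(miss)) {
      stop("batch '", b, "' lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    X <- as.matrix(f$data[spec$features])
    y <- f$data[[spec$target]]
    keep <- stats::complete.cases(X) & !is.na(y)
    if (!is.null(exclude) && !is.null(exclude[[b]])) {
      iv <- exclude[[b]]$intervals
      for (k in seq_len(nrow(iv))) {
        keep <- keep & !(f$times >= iv$start[k] & f$times <= iv$end[k])
      }
    }
    dropped <- dropped + sum(!keep)
    Xs[[b]] <- X[keep, , drop = FALSE]
    ys[[b]] <- y[keep]
    tts[[b]] <- f$times[keep]
    bbs[[b]] <- rep(b, sum(keep))
  }
  X <- do.call(rbind, Xs)
  if (!nrow(X)) stop("no usable samples", call. = FALSE)
  structure(list(X = X, y = unlist(ys, use.names = FALSE),
                 time = unlist(tts, use.names = FALSE),
                 batch = unlist(bbs, use.names = FALSE),
                 dropped = dropped),
            class = "sample_set")
}

subset_samples <- function(s, idx) {
  structure(list(X = s$X[idx, , drop = FALSE], y = s$y[idx],
                 time = s$time[idx], batch = s$batch[idx],
                 dropped = s$dropped),
            class = "sample_set")
}

# run code under a local RNG state so pipeline seeds don't clobber the
# caller's stream
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Random train/validation split at a fixed ratio
#'
#' An exact partition: `round(ratio * n)` training samples, the rest
#' validation, deterministic for a given seed. The split is random over
#' pooled samples by default; set `by_batch = TRUE` to hold out whole
#' batches instead (methodologically safer when batches are few, since
#' neighbouring time points are strongly dependent).
#'
#' @param s A `sample_set`.
#' @param ratio Training fraction (default 0.8, the conventional 8:2).
#' @param seed Integer seed.
#' @param by_batch Block the split by batch label?
#' @return List `train`, `val` of `sample_set`s.
#' @export
split_train_val <- function(s, ratio = 0.8, seed = 1L, by_batch = FALSE) {
  stopifnot(inherits(s, "sample_set"))
  n <- length(s$y)
  if (n < 5L) stop("need at least 5 samples to split", call. = FALSE)
  if (by_batch) {
    ub <- unique(s$batch)
    n_tr <- max(1L, round(ratio * length(ub)))
    tr_b <- with_local_seed(seed, sample(ub, n_tr))
    idx <- which(s$batch %in% tr_b)
  } else {
    n_tr <- round(ratio * n)
    idx <- with_local_seed(seed, sample.int(n, n_tr))
  }
  list(train = subset_samples(s, sort(idx)),
       val = subset_samples(s, setdiff(seq_len(n), idx)))
}

## ---- regressor contract -------------------------------------------------
## A regressor is a list with class c("<kind>_regressor", "ferm_regressor")
## and methods regressor_fit() / regressor_predict(); fitted models are
## plain R lists, so saveRDS/readRDS round-trips reproduce predictions
## bitwise.

#' Linear least-squares baseline regressor
#' @return A regressor usable with [fit_soft_sensor()].
#' @export
regressor_linear <- function() {
  structure(list(kind = "linear"),
            class = c("linear_regressor", "ferm_regressor"))
}

#' Feed-forward multilayer perceptron regressor
#'
#' A fully connected network with tanh hidden units and a linear output,
#' trained full-batch with Adam on the mean-squared error. The default
#' depth is six layers (input, four hidden, output). Inputs are expected
#' standardized (the soft-sensor pipeline does this); the target is
#' standardized internally and restored at prediction.
#'
#' @param hidden Hidden-layer widths (default `c(32, 16, 8, 4)`).
#' @param epochs Training epochs (default 600).
#' @param lr Adam step size (default 0.01).
#' @return A regressor usable with [fit_soft_sensor()].
#' @export
regressor_mlp <- function(hidden = c(32L, 16L, 8L, 4L), epochs = 600L,
                          lr = 0.01) {
  structure(list(kind = "mlp", hidden = as.integer(hidden),
                 epochs = as.integer(epochs), lr = lr),
            class = c("mlp_regressor", "ferm_regressor"))
}

regressor_fit <- function(reg, X, y, Xval = NULL, yval = NULL, seed = 1L) {
  UseMethod("regressor_fit")
}

regressor_predict <- function(fit, X) UseMethod("regressor_predict")

#' @export
regressor_fit.linear_regressor <- function(reg, X, y, Xval = NULL,
                                           yval = NULL, seed = 1L) {
  Xa <- cbind(1, X)
  beta <- qr.coef(qr(Xa), y)
  beta[is.na(beta)] <- 0
  fit <- structure(list(kind = "linear", beta = beta),
                   class = c("linear_fit", "ferm_fit"))
  losses <- data.frame(
    epoch = 1L,
    train = mean((regressor_predict(fit, X) - y)^2),
    val = if (is.null(Xval)) NA_real_ else
      mean((regressor_predict(fit, Xval) - yval)^2))
  list(fit = fit, losses = losses)
}

#' @export
regressor_predict.linear_fit <- function(fit, X) {
  as.numeric(cbind(1, X) %*% fit$beta)
}

mlp_forward <- function(W, b, X) {
  acts <- list(X)
  L <- length(W)
  A <- X
  for (l in seq_len(L)) {
    Z <- A %*% W[[l]] + matrix(b[[l]], nrow(A), length(b[[l]]), byrow = TRUE)
    A <- if (l < L) tanh(Z) else Z
    acts[[l + 1L]] <- A
  }
  acts
}

#' @export
regressor_fit.mlp_regressor <- function(reg, X, y, Xval = NULL, yval = NULL,
                                        seed = 1L) {
  y_mu <- mean(y); y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  yz <- (y - y_mu) / y_sd
  sizes <- c(ncol(X), reg$hidden, 1L)
  L <- length(sizes) - 1L
  with_local_seed(seed, {
    W <- lapply(seq_len(L), function(l) {
      matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                          sd = sqrt(1 / sizes[l])), sizes[l], sizes[l + 1L])
    })
    b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1L]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    n <- nrow(X)
    tr_loss <- numeric(reg$epochs); va_loss <- rep(NA_real_, reg$epochs)
    for (ep in seq_len(reg$epochs)) {
      acts <- mlp_forward(W, b, X)
      pred <- acts[[L + 1L]][, 1L]
      err <- pred - yz
      tr_loss[ep] <- mean(err^2)
      if (!is.finite(tr_loss[ep])) {
        stop("non-finite training loss at epoch ", ep, call. = FALSE)
      }
      delta <- matrix(2 * err / n, ncol = 1L)
      for (l in rev(seq_len(L))) {
        gW <- crossprod(acts[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- (delta %*% t(W[[l]])) * (1 - acts[[l]]^2)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhW <- mW[[l]] / (1 - beta1^ep); vhW <- vW[[l]] / (1 - beta2^ep)
        mhb <- mb[[l]] / (1 - beta1^ep); vhb <- vb[[l]] / (1 - beta2^ep)
        W[[l]] <- W[[l]] - reg$lr * mhW / (sqrt(vhW) + eps)
        b[[l]] <- b[[l]] - reg$lr * mhb / (sqrt(vhb) + eps)
      }
      if (!is.null(Xval)) {
        pv <- mlp_forward(W, b, Xval)[[L + 1L]][, 1L] * y_sd + y_mu
        va_loss[ep] <- mean((pv - yval)^2)
      }
    }
    fit <- structure(list(kind = "mlp", W = W, b = b, y_mu = y_mu,
                          y_sd = y_sd),
                     class = c("mlp_fit", "ferm_fit"))
    list(fit = fit,
         losses = data.frame(epoch = seq_len(reg$epochs),
                             train = tr_loss * y_sd^2, val = va_loss))
  })
}

#' @export
regressor_predict.mlp_fit <- function(fit, X) {
  L <- length(fit$W)
  mlp_forward(fit$W, fit$b, X)[[L + 1L]][, 1L] * fit$y_sd + fit$y_mu
}

#' Fit a soft sensor on a training sample set
#'
#' Features are z-scored with training-set statistics (stored in the
#' model); the regressor is fitted and per-epoch train/validation losses
#' are recorded for a convergence report.
#'
#' @param train A `sample_set` (training portion).
#' @param regressor [regressor_mlp()] (default) or [regressor_linear()].
#' @param val Optional `sample_set` for validation-loss tracking.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `soft_sensor`: list with `fit`,
#'   `feature_names`, `center`, `scale`, `target`, `losses`.
#' @export
fit_soft_sensor <- function(train, regressor = regressor_mlp(), val = NULL,
                            seed = 1L) {
  stopifnot(inherits(train, "sample_set"))
  ctr <- colMeans(train$X)
  scl <- apply(train$X, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Z <- sweep(sweep(train$X, 2L, ctr, "-"), 2L, scl, "/")
  Zv <- NULL; yv <- NULL
  if (!is.null(val)) {
    Zv <- sweep(sweep(val$X, 2L, ctr, "-"), 2L, scl, "/")
    yv <- val$y
  }
  res <- regressor_fit(regressor, Z, train$y, Zv, yv, seed = seed)
  structure(list(fit = res$fit, feature_names = colnames(train$X),
                 center = ctr, scale = scl, losses = res$losses),
            class = "soft_sensor")
}

#' Predict the target over a fused frame (streaming mode)
#'
#' Applies the stored feature statistics and the fitted regressor to
#' every grid point; predictions are stateless per point, so streaming
#' order is irrelevant.
#'
#' @param model A fitted `soft_sensor`.
#' @param frame A [fused_frame()] carrying the model's features.
#' @param spec The [feature_spec()] used at training time.
#' @return A [ferm_ts()] of predictions on the frame grid.
#' @export
predict_stream <- function(model, frame, spec = feature_spec()) {
  stopifnot(inherits(model, "soft_sensor"), inherits(frame, "fused_frame"))
  miss <- setdiff(model$feature_names, names(frame$data))
  if (length(miss)) {
    stop("frame lacks feature(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(model$feature_names, spec$features)) {
    stop("feature spec does not match the fitted model", call. = FALSE)
  }
  X <- as.matrix(frame$data[model$feature_names])
  Z <- sweep(sweep(X, 2L, model$center, "-"), 2L, model$scale, "/")
  ferm_ts(paste0(spec$target, "_pred"), frame$times,
          regressor_predict(model$fit, Z), source = "online")
}
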