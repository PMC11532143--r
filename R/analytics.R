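# Multi-batch key-feature analytics: Spearman critical-factor screening
# and two PCA procedures over comparable batches.
#
# Both PCA views start from batches resampled onto a common grid and
# z-scored per column (process variables span incommensurate units — rpm
# next to pH — so unscaled PCA would be dominated by the largest unit):
#  * flat view: each batch flattened to one row (variable x time columns);
#    batches become points in (PC1, PC2) — outlier batches separate.
#  * time view: rows are (batch, time point), columns are variables; PC1/
#    PC2 become per-batch trajectories, Savitzky-Golay smoothed, whose
#    excursions localize disturbances in time, attributed to variables
#    through the loadings.

#' Resample fused batches onto a shared grid
#'
#' All batches must carry the same variable set and span the grid. Linear
#' resampling (exact on affine signals) brings each variable onto the
#' grid.
#'
#' @param frames Named list of [fused_frame()]s (names = batch ids).
#' @param grid Numeric grid; default: the intersection of the batch spans
#'   sampled at `max_points` equally spaced times.
#' @param variables Variables to keep; default: common to all frames
#'   (must then be identical across frames).
#' @param max_points Cap on default-grid length (default 2000), bounding
#'   the flat-matrix column count.
#' @return A list with `grid`, `variables`, and `batches`: per batch a
#'   matrix `length(grid) x length(variables)`.
#' @export
resample_common_grid <- function(frames, grid = NULL, variables = NULL,
                                 max_points = 2000L) {
  stopifnot(length(frames) >= 1L)
  if (is.null(names(frames))) names(frames) <- paste0("batch", seq_along(frames))
  varsets <- lapply(frames, function(f) sort(names(f$data)))
  if (is.null(variables)) {
    variables <- varsets[[1L]]
    for (b in names(frames)) {
      if (!setequal(varsets[[b]], variables)) {
        miss <- c(setdiff(variables, varsets[[b]]),
                  setdiff(varsets[[b]], variables))
        stop("batch '", b, "' variable set mismatch: ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
    }
  } else {
    for (b in names(frames)) {
      miss <- setdiff(variables, names(frames[[b]]$data))
      if (length(miss)) {
        stop("batch '", b, "' missing variable(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
    }
  }
  lo <- max(vapply(frames, function(f) min(f$times), numeric(1L)))
  hi <- min(vapply(frames, function(f) max(f$times), numeric(1L)))
  if (is.null(grid)) {
    if (hi <= lo) stop("batch spans do not overlap", call. = FALSE)
    n <- min(max_points, max(vapply(frames, function(f) length(f$times),
                                    integer(1L))))
    grid <- seq(lo, hi, length.out = n)
  } else {
    for (b in names(frames)) {
      f <- frames[[b]]
      if (min(grid) < min(f$times) || max(grid) > max(f$times)) {
        stop("batch '", b, "' does not span the grid", call. = FALSE)
      }
    }
  }
  batches <- lapply(frames, function(f) {
    m <- vapply(variables, function(v) {
      stats::approx(f$times, f$data[[v]], xout = grid, method = "linear",
                    rule = 2)$y
    }, numeric(length(grid)))
    dimnames(m) <- list(NULL, variables)
    m
  })
  list(grid = grid, variables = variables, batches = batches)
}

#' Flatten resampled batches into a batch-by-(variable x time) matrix
#'
#' @param rs Output of [resample_common_grid()].
#' @return Matrix, one row per batch, columns named `var@t<index>`.
#' @export
batch_matrix_flat <- function(rs) {
  mat <- t(vapply(rs$batches, function(m) as.numeric(m),
                  numeric(length(rs$grid) * length(rs$variables))))
  colnames(mat) <- as.vector(outer(seq_along(rs$grid), rs$variables,
                                   function(i, v) paste0(v, "@t", i)))
  mat
}

#' Stack resampled batches into a (batch x time)-by-variable matrix
#'
#' @param rs Output of [resample_common_grid()].
#' @return List: `X` (rows ordered batch-major), `batch`, `time`.
#' @export
batch_matrix_stacked <- function(rs) {
  X <- do.call(rbind, rs$batches)
  list(X = X,
       batch = rep(names(rs$batches), each = length(rs$grid)),
       time = rep(rs$grid, times = length(rs$batches)))
}

spearman_p <- function(rho, n, x = NULL, y = NULL) {
  if (is.na(rho) || n < 3L) return(NA_real_)
  if (n <= 10L && !is.null(x) && !anyDuplicated(x) && !anyDuplicated(y)) {
    # exact null distribution over rank permutations
    return(stats::cor.test(x, y, method = "spearman",
                           alternative = "two.sided", exact = TRUE)$p.value)
  }
  if (abs(rho) >= 1) return(0)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' Spearman screen of process factors against performance targets
#'
#' Rank correlation (average ranks on ties) of every target column
#' against every factor column of a pooled observation table, with
#' two-sided p-values: exact for n <= 10 without ties, the large-sample
#' t approximation otherwise. Constant columns yield `NA` (undefined
#' rank correlation). No multiple-testing correction is applied by
#' default; Benjamini-Hochberg is available.
#'
#' @param data A data.frame of paired observations (rows) of all columns.
#' @param targets Character vector of target column names (e.g. titer,
#'   rate, yield, biomass).
#' @param factors Character vector of factor column names; default: all
#'   non-target columns.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return An object of class `correlation_screen`: list with `rho` and
#'   `p` matrices (targets x factors) and `n`.
#' @export
spearman_screen <- function(data, targets, factors = NULL,
                            p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(is.data.frame(data), all(targets %in% names(data)))
  if (is.null(factors)) factors <- setdiff(names(data), targets)
  stopifnot(all(factors %in% names(data)))
  if (nrow(data) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  rho <- matrix(NA_real_, length(targets), length(factors),
                dimnames = list(targets, factors))
  p <- rho
  for (ti in targets) {
    for (fa in factors) {
      ok <- stats::complete.cases(data[[ti]], data[[fa]])
      x <- data[[ti]][ok]; y <- data[[fa]][ok]
      if (sum(ok) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) next
      r <- suppressWarnings(stats::cor(x, y, method = "spearman"))
      rho[ti, fa] <- r
      p[ti, fa] <- suppressWarnings(spearman_p(r, sum(ok), x, y))
    }
  }
  if (p_adjust == "BH") {
    p[] <- stats::p.adjust(p, method = "BH")
  }
  structure(list(rho = rho, p = p, n = nrow(data)),
            class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat(sprintf("<correlation_screen> %d observations\n", x$n))
  cat("rho:\n"); print(round(x$rho, 3))
  invisible(x)
}

# z-score matrix columns; constant columns are left at 0 and reported
zscore_columns <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  keep <- sdv > 0
  Z <- sweep(X, 2L, mu, "-")
  Z[, keep] <- sweep(Z[, keep, drop = FALSE], 2L, sdv[keep], "/")
  Z[, !keep] <- 0
  list(Z = Z, constant = !keep)
}

# deterministic sign: the largest-|loading| entry of each component is
# positive
fix_signs <- function(rotation, scores) {
  for (k in seq_len(ncol(rotation))) {
    j <- which.max(abs(rotation[, k]))
    if (rotation[j, k] < 0) {
      rotation[, k] <- -rotation[, k]
      scores[, k] <- -scores[, k]
    }
  }
  list(rotation = rotation, scores = scores)
}

#' Batch-level PCA on flattened trajectories
#'
#' Each batch is one observation (its whole multivariate trajectory
#' flattened to a row, columns z-scored); batches become points in score
#' space, where similar batches cluster and deviant batches separate.
#'
#' @param flat Matrix from [batch_matrix_flat()] (rows = batches).
#' @param n_components Number of components (default 2); must not exceed
#'   the number of batches.
#' @return List: `scores` (batch x component), `explained` (variance
#'   ratios, non-increasing), `loadings`. Component signs are fixed so
#'   each loading's largest-magnitude entry is positive.
#' @export
pca_flat <- function(flat, n_components = 2L) {
  if (nrow(flat) < n_components) {
    stop("fewer batches than components", call. = FALSE)
  }
  z <- zscore_columns(flat)
  pc <- stats::prcomp(z$Z, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  fs <- fix_signs(pc$rotation[, seq_len(k), drop = FALSE],
                  pc$x[, seq_len(k), drop = FALSE])
  ev <- pc$sdev^2
  list(scores = fs$scores, explained = (ev / sum(ev))[seq_len(k)],
       loadings = fs$rotation)
}

#' Time-resolved PCA with Savitzky-Golay smoothing
#'
#' Batches are stacked as (batch, time) rows over the process variables;
#' PCA reduces each time point to (PC1, PC2), and each batch's component
#' trajectory is Savitzky-Golay smoothed. Peaks in a trajectory localize
#' disturbances in time; the loadings attribute them to variables.
#'
#' @param stacked List from [batch_matrix_stacked()].
#' @param sg_window Odd SG window length in grid points (default 11).
#' @param sg_order SG polynomial order (default 3), less than `sg_window`.
#' @param n_components Components to keep (default 2).
#' @return List: `trajectories` (data.frame `batch`, `time`, `PC1`, ...,
#'   smoothed), `raw_scores`, `loadings` (unit-norm columns, sign-fixed),
#'   `explained`.
#' @export
pca_time <- function(stacked, sg_window = 11L, sg_order = 3L,
                     n_components = 2L) {
  sg_window <- as.integer(sg_window)
  if (sg_window %% 2L == 0L || sg_window <= sg_order) {
    stop("sg_window must be odd and exceed sg_order", call. = FALSE)
  }
  X <- stacked$X
  if (nrow(X) < ncol(X)) stop("need at least as many rows as variables",
                              call. = FALSE)
  z <- zscore_columns(X)
  pc <- stats::prcomp(z$Z, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  fs <- fix_signs(pc$rotation[, seq_len(k), drop = FALSE],
                  pc$x[, seq_len(k), drop = FALSE])
  scores <- fs$scores
  colnames(scores) <- paste0("PC", seq_len(k))
  out <- data.frame(batch = stacked$batch, time = stacked$time,
                    stringsAsFactors = FALSE)
  smoothed <- scores
  for (b in unique(stacked$batch)) {
    idx <- which(stacked$batch == b)
    if (length(idx) >= sg_window) {
      for (cc in seq_len(k)) {
        smoothed[idx, cc] <- signal::sgolayfilt(scores[idx, cc],
                                                p = sg_order, n = sg_window)
      }
    }
  }
  ev <- pc$sdev^2
  list(trajectories = cbind(out, as.data.frame(smoothed)),
       raw_scores = cbind(out, as.data.frame(scores)),
       loadings = fs$rotation,
       explained = (ev / sum(ev))[seq_len(k)])
}

#' Locate a process disturbance in time and attribute it to variables
#'
#' Compares one batch's smoothed component trajectories against the
#' across-batch median, removes the smooth between-batch divergence with
#' a wide Savitzky-Golay baseline, and finds the component and time of
#' the largest residual excursion. The loadings of that component, ranked
#' by magnitude, attribute the disturbance to process variables: a sharp
#' peak confined to one batch's trajectory indicates one or more
#' variables departing from the normal pattern at that time.
#'
#' @param pt Output of [pca_time()].
#' @param batch Batch id of the suspect batch.
#' @param baseline_window Odd SG window (grid points) for the smooth
#'   divergence baseline (default 51; use several process time
#'   constants).
#' @return List: `component`, `time` (of the peak excursion),
#'   `excursion` (its magnitude), `ranking` (variables by absolute
#'   loading on that component), `profile` (data.frame of the residual
#'   excursion per component over time).
#' @export
locate_disturbance <- function(pt, batch, baseline_window = 51L) {
  tj <- pt$trajectories
  stopifnot(batch %in% tj$batch)
  pcs <- grep("^PC", names(tj), value = TRUE)
  tt <- unique(tj$time)
  prof <- data.frame(time = tt)
  best <- list(excursion = -Inf)
  for (pc in pcs) {
    m <- matrix(tj[[pc]], nrow = length(tt))
    colnames(m) <- unique(tj$batch)
    ref <- apply(m[, colnames(m) != batch, drop = FALSE], 1L, stats::median)
    d <- m[, batch] - ref
    base <- if (length(d) > baseline_window) {
      signal::sgolayfilt(d, p = 3, n = baseline_window)
    } else rep(mean(d), length(d))
    exc <- abs(d - base)
    prof[[pc]] <- exc
    i <- which.max(exc)
    if (exc[i] > best$excursion) {
      best <- list(component = pc, time = tt[i], excursion = exc[i])
    }
  }
  ld <- abs(pt$loadings[, best$component])
  list(component = best$component, time = best$time,
       excursion = best$excursion,
       ranking = names(sort(ld, decreasing = TRUE)), profile = prof)
}
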