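# Per-series cleaning: spike filtering, gap filling, normalization, and
# section averaging of at-line instrument cycles.

#' Moving-median filter
#'
#' Robust smoothing for single-point sensor spikes. Windows shrink
#' symmetrically at the series ends, so the output keeps the input grid.
#' Intended for online streams; at-line/offline series are sparse enough
#' that filtering is normally left off.
#'
#' @param ts A [ferm_ts()], gap-free.
#' @param window Odd positive integer window length, at most the series
#'   length. `window = 1` is the identity.
#' @return A [ferm_ts()] on the same grid.
#' @export
filter_series <- function(ts, window = 5L) {
  stopifnot(is_ferm_ts(ts))
  n <- length(ts$times)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("`window` must be an odd positive integer", call. = FALSE)
  }
  if (window > n) stop("`window` exceeds series length", call. = FALSE)
  if (window == 1L) return(ts)
  h <- (window - 1L) %/% 2L
  out <- vapply(seq_len(n), function(i) {
    stats::median(ts$values[max(1L, i - h):min(n, i + h)])
  }, numeric(1L))
  ferm_ts(ts$variable, ts$times, out, source = ts$source, unit = ts$unit)
}

#' Fill missing markers in a series
#'
#' Three policies:
#' \describe{
#'   \item{`mean`}{each gap takes the mean of its adjacent non-missing
#'     neighbours (the single neighbour at the series edge); with
#'     `global_mean = TRUE`, the mean of all non-missing values instead.}
#'   \item{`interp`}{piecewise-linear interpolation in time; leading and
#'     trailing gaps hold the nearest value.}
#'   \item{`zero`}{gaps become 0.}
#' }
#' Non-missing values are never altered.
#'
#' @param ts A [ferm_ts()], possibly containing `NA`.
#' @param method One of `"interp"`, `"mean"`, `"zero"`.
#' @param global_mean Use the series mean rather than adjacent neighbours
#'   under `method = "mean"`.
#' @return A gap-free [ferm_ts()].
#' @export
fill_gaps <- function(ts, method = c("interp", "mean", "zero"),
                      global_mean = FALSE) {
  stopifnot(is_ferm_ts(ts))
  method <- match.arg(method)
  v <- ts$values
  miss <- is.na(v)
  if (!any(miss)) return(ts)
  if (method != "zero" && all(miss)) {
    stop("cannot ", method, "-fill an all-missing series", call. = FALSE)
  }
  if (method == "zero") {
    v[miss] <- 0
  } else if (method == "mean" && global_mean) {
    v[miss] <- mean(v, na.rm = TRUE)
  } else if (method == "mean") {
    ok <- which(!miss)
    for (i in which(miss)) {
      prev <- ok[ok < i]
      nxt <- ok[ok > i]
      nb <- c(if (length(prev)) v[max(prev)], if (length(nxt)) v[min(nxt)])
      v[i] <- mean(nb)
    }
  } else { # interp
    v <- stats::approx(ts$times[!miss], v[!miss], xout = ts$times,
                       method = "linear", rule = 2)$y
  }
  ferm_ts(ts$variable, ts$times, v, source = ts$source, unit = ts$unit)
}

#' Section-average an at-line series over instrument cycles
#'
#' At-line instruments (off-gas mass spectrometry) deliver one or a few
#' readings per measurement cycle; all readings inside a cycle are
#' replaced by their mean, stamped at the cycle midpoint. Cycles with no
#' readings emit no point.
#'
#' @param ts A [ferm_ts()] with `source = "at_line"`.
#' @param cycle Cycle duration in hours (default 20 min, a typical
#'   multi-channel spectrometer sweep).
#' @param origin Time of the first cycle start (hours), default 0.
#' @return A [ferm_ts()] with at most one point per cycle.
#' @export
section_average <- function(ts, cycle = 1 / 3, origin = 0) {
  stopifnot(is_ferm_ts(ts))
  if (ts$source != "at_line") {
    stop("section averaging applies to at-line series only", call. = FALSE)
  }
  if (cycle <= 0) stop("`cycle` must be positive", call. = FALSE)
  sec <- floor((ts$times - origin) / cycle)
  mids <- tapply(ts$times, sec, function(x) x, simplify = FALSE)
  keys <- sort(unique(sec))
  t_out <- origin + (keys + 0.5) * cycle
  v_out <- vapply(keys, function(k) mean(ts$values[sec == k], na.rm = TRUE),
                  numeric(1L))
  keep <- is.finite(v_out)
  ferm_ts(ts$variable, t_out[keep], v_out[keep], source = "at_line",
          unit = ts$unit)
}

#' Normalize a series, recording the statistics for inversion
#'
#' `zscore` centres to mean 0 / sd 1; `minmax` maps the range to `[0, 1]`.
#' The location/scale pair is attached as the `"norm_stats"` attribute so
#' downstream analytics can report in original units via
#' [denormalize_series()].
#'
#' @param ts A gap-free [ferm_ts()].
#' @param method `"zscore"` (default) or `"minmax"`.
#' @return A normalized [ferm_ts()] carrying `attr(, "norm_stats")`.
#' @export
normalize_series <- function(ts, method = c("zscore", "minmax")) {
  stopifnot(is_ferm_ts(ts))
  method <- match.arg(method)
  if (anyNA(ts$values)) stop("series must be gap-free", call. = FALSE)
  if (method == "zscore") {
    loc <- mean(ts$values)
    scl <- stats::sd(ts$values)
    if (!is.finite(scl) || scl == 0) {
      stop("zero variance: zscore undefined", call. = FALSE)
    }
  } else {
    loc <- min(ts$values)
    scl <- max(ts$values) - loc
    if (scl == 0) stop("constant series: minmax undefined", call. = FALSE)
  }
  out <- ferm_ts(ts$variable, ts$times, (ts$values - loc) / scl,
                 source = ts$source, unit = ts$unit)
  attr(out, "norm_stats") <- list(method = method, location = loc,
                                  scale = scl)
  out
}

#' Invert [normalize_series()]
#'
#' @param ts A normalized series carrying `"norm_stats"`, or any series
#'   plus an explicit `stats` list.
#' @param stats A `list(location, scale)`; defaults to the attribute.
#' @return The series in original units.
#' @export
denormalize_series <- function(ts, stats = attr(ts, "norm_stats")) {
  stopifnot(is_ferm_ts(ts))
  if (is.null(stats)) stop("no normalization statistics available", call. = FALSE)
  ferm_ts(ts$variable, ts$times, ts$values * stats$scale + stats$location,
          source = ts$source, unit = ts$unit)
}

#' Default per-source fill policy
#'
#' Interpolation for online streams (dense, smooth), adjacent-neighbour
#' mean for at-line (matches per-cycle gap repair), and no automatic zero
#' filling — zeros are physically meaningful and only inserted on request.
#'
#' @param source Source class string.
#' @return A fill method string accepted by [fill_gaps()].
#' @export
default_fill_method <- function(source) {
  switch(source, online = "interp", at_line = "mean", offline = "interp",
         stop("unknown source class: ", source, call. = FALSE))
}
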