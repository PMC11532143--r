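# Fusing heterogeneous streams onto the online time grid.
#
# The online sensors define the reference grid (they are dense and
# regular); sparser at-line and offline streams are brought onto it by
# nearest-time alignment and degree-1 (two-point) Lagrange interpolation,
# i.e. piecewise-linear interpolation between bracketing observations.
# Higher-degree Lagrange polynomials are deliberately not offered: on the
# long gaps of at-line/offline data they oscillate.

#' Alignment specification for batch fusion
#'
#' @param method Default interpolation method per variable:
#'   `"lagrange_linear"` or `"nearest"`. A named character vector overrides
#'   per variable.
#' @param extrapolation Outside the observed span of a sparse series:
#'   `"hold"` (repeat the nearest observation, flagged in provenance) or
#'   `"error"`.
#' @param tie_break For equidistant nearest-time ties: `"earlier"`
#'   (default, never uses future data) or `"later"`.
#' @param atline_cycle Section-averaging cycle for at-line series, hours.
#' @return An object of class `alignment_spec`.
#' @export
alignment_spec <- function(method = "lagrange_linear",
                           extrapolation = c("hold", "error"),
                           tie_break = c("earlier", "later"),
                           atline_cycle = 1 / 3) {
  extrapolation <- match.arg(extrapolation)
  tie_break <- match.arg(tie_break)
  bad <- setdiff(method, c("lagrange_linear", "nearest"))
  if (length(bad)) stop("unknown alignment method: ", bad[1L], call. = FALSE)
  structure(list(method = method, extrapolation = extrapolation,
                 tie_break = tie_break, atline_cycle = atline_cycle),
            class = "alignment_spec")
}

#' Nearest-time alignment of a series onto a grid
#'
#' Each grid point takes the value of the temporally closest observation.
#' Equidistant ties go to the earlier observation by default (causality:
#' no future data).
#'
#' @param ts A non-empty [ferm_ts()].
#' @param grid Strictly increasing numeric target times (hours).
#' @param tie_break `"earlier"` or `"later"`.
#' @return A [ferm_ts()] on `grid`; its values are a subset of the input
#'   values.
#' @export
align_nearest <- function(ts, grid, tie_break = c("earlier", "later")) {
  stopifnot(is_ferm_ts(ts))
  tie_break <- match.arg(tie_break)
  if (!length(ts$times)) stop("empty series", call. = FALSE)
  idx <- nearest_index(ts$times, grid, tie_break)
  ferm_ts(ts$variable, grid, ts$values[idx], source = ts$source,
          unit = ts$unit)
}

nearest_index <- function(times, grid, tie_break = "earlier") {
  lo <- findInterval(grid, times)          # last obs <= grid point (0 if none)
  hi <- pmin(lo + 1L, length(times))
  lo2 <- pmax(lo, 1L)
  d_lo <- abs(grid - times[lo2])
  d_hi <- abs(times[hi] - grid)
  use_lo <- lo >= 1L &
    (d_lo < d_hi | (d_lo == d_hi & tie_break == "earlier"))
  ifelse(use_lo, lo2, hi)
}

#' Two-point Lagrange (piecewise-linear) interpolation onto a grid
#'
#' Inside the observed span this is exact linear interpolation between the
#' bracketing observations (and exact at the knots). Outside the span the
#' `extrapolation` policy applies.
#'
#' @param ts A [ferm_ts()] with at least two observations.
#' @param grid Target times (hours).
#' @param extrapolation `"hold"` (repeat the boundary observation) or
#'   `"error"`.
#' @return A [ferm_ts()] on `grid`.
#' @export
interp_lagrange <- function(ts, grid, extrapolation = c("hold", "error")) {
  stopifnot(is_ferm_ts(ts))
  extrapolation <- match.arg(extrapolation)
  if (length(ts$times) < 2L) {
    stop("need at least two observations to interpolate", call. = FALSE)
  }
  if (extrapolation == "error" &&
      (min(grid) < min(ts$times) || max(grid) > max(ts$times))) {
    stop("grid exceeds the observed span of ", ts$variable, call. = FALSE)
  }
  y <- stats::approx(ts$times, ts$values, xout = grid, method = "linear",
                     rule = 2)$y
  ferm_ts(ts$variable, grid, y, source = ts$source, unit = ts$unit)
}

#' Fuse all streams of a batch onto the online time grid
#'
#' The procedure, per source class:
#' \enumerate{
#'   \item online series define the grid (union of their time points) and
#'     are carried over unchanged (interpolated only if an online series
#'     misses some grid points);
#'   \item at-line series are section-averaged over the instrument cycle,
#'     then interpolated onto the grid;
#'   \item offline series are first anchored — each observation snapped to
#'     the nearest grid time — then interpolated between anchors.
#' }
#' The result is rectangular: one value per variable per grid point, with
#' per-column provenance. Fusion is idempotent: re-fusing
#' [fused_to_batch()] output reproduces the frame.
#'
#' @param b A valid [batch_dataset()] with at least one online series.
#' @param spec An [alignment_spec()].
#' @param section_average Apply at-line section averaging (step 1)?
#'   Default `TRUE`.
#' @return A [fused_frame()].
#' @export
fuse_batch <- function(b, spec = alignment_spec(), section_average = TRUE) {
  stopifnot(inherits(b, "batch_dataset"))
  viol <- validate_batch(b)
  if (length(viol)) {
    stop("invalid batch: ", paste(viol, collapse = "; "), call. = FALSE)
  }
  src <- vapply(b$series, function(s) s$source, character(1L))
  grid <- sort(unique(unlist(lapply(b$series[src == "online"],
                                    function(s) s$times))))
  method_for <- function(v) {
    if (length(spec$method) > 1L || !is.null(names(spec$method))) {
      m <- spec$method[[v]] %||% "lagrange_linear"
    } else {
      m <- spec$method
    }
    m
  }

  cols <- list()
  prov <- list()
  for (s in b$series) {
    v <- s$variable
    held <- length(s$times) &&
      (min(grid) < min(s$times) || max(grid) > max(s$times))
    if (s$source == "online") {
      if (identical(s$times, grid)) {
        vals <- s$values
        meth <- "native_grid"
      } else {
        vals <- interp_lagrange(s, grid, spec$extrapolation)$values
        meth <- "lagrange_linear"
      }
      if (anyNA(vals)) vals <- fill_gaps(
        ferm_ts(v, grid, vals, "online"), default_fill_method("online"))$values
    } else {
      s2 <- if (anyNA(s$values)) {
        fill_gaps(s, default_fill_method(s$source))
      } else s
      if (s$source == "at_line" && section_average) {
        s2 <- section_average(s2, cycle = spec$atline_cycle)
        step1 <- "section_mean+"
      } else step1 <- ""
      if (s$source == "offline") {
        # anchor: snap each offline timestamp to its nearest grid time
        anchor_idx <- nearest_index(grid, s2$times, spec$tie_break)
        at <- grid[anchor_idx]
        keep <- !duplicated(at)
        s2 <- ferm_ts(v, at[keep], s2$values[keep], source = "offline",
                      unit = s2$unit)
        step1 <- "anchor+"
      }
      m <- method_for(v)
      if (m == "nearest") {
        vals <- align_nearest(s2, grid, spec$tie_break)$values
        meth <- paste0(step1, "nearest")
      } else {
        if (length(s2$times) < 2L) {
          stop("variable '", v, "' has <2 points after step 1; ",
               "cannot interpolate", call. = FALSE)
        }
        vals <- interp_lagrange(s2, grid, spec$extrapolation)$values
        meth <- paste0(step1, "lagrange_linear")
      }
      held <- min(grid) < min(s2$times) || max(grid) > max(s2$times)
    }
    if (held && s$source != "online") meth <- paste0(meth, "+hold")
    cols[[v]] <- vals
    prov[[v]] <- data.frame(variable = v, source = s$source, method = meth,
                            stringsAsFactors = FALSE)
  }
  fused_frame(grid, as.data.frame(cols, check.names = FALSE),
              do.call(rbind, c(prov, list(make.row.names = FALSE))))
}
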