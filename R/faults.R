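# Rule-based device-fault identification.
#
# Two generic rules over a rolling time window, instantiated by default
# for the CO2-in-air self-check of an off-gas mass spectrometer (the
# instrument periodically samples ambient air, whose CO2 content is
# tightly bounded — the rolling mean drifting outside 0.02-0.05 % or a
# rolling coefficient of variation above 0.1 both indicate a device that
# needs correction).

#' Construct a fault rule
#'
#' @param kind `"mean_band"` (rolling mean must stay inside
#'   `[lower, upper]`) or `"cv_threshold"` (rolling sd/mean must stay at
#'   or below `cv_max`).
#' @param lower,upper Band bounds for `mean_band` (defaults: the ambient
#'   CO2 band 0.02-0.05 %).
#' @param cv_max CV ceiling for `cv_threshold` (default 0.1).
#' @param window Rolling window length in hours (default 1), centred on
#'   each observation.
#' @return An object of class `fault_rule`.
#' @export
fault_rule <- function(kind = c("mean_band", "cv_threshold"),
                       lower = 0.02, upper = 0.05, cv_max = 0.1,
                       window = 1) {
  kind <- match.arg(kind)
  if (kind == "mean_band" && lower >= upper) {
    stop("mean_band requires lower < upper", call. = FALSE)
  }
  if (kind == "cv_threshold" && cv_max <= 0) {
    stop("cv_threshold requires cv_max > 0", call. = FALSE)
  }
  if (window <= 0) stop("window must be positive", call. = FALSE)
  structure(list(kind = kind, lower = lower, upper = upper,
                 cv_max = cv_max, window = window), class = "fault_rule")
}

# rolling statistic over a centred time window on a possibly irregular grid
rolling_stat <- function(times, values, window, fn) {
  half <- window / 2
  vapply(seq_along(times), function(i) {
    fn(values[times >= times[i] - half & times <= times[i] + half])
  }, numeric(1L))
}

empty_report <- function() {
  data.frame(start = numeric(0), end = numeric(0), rule = character(0),
             statistic = numeric(0), tag = character(0),
             stringsAsFactors = FALSE)
}

# turn a logical flag vector into merged intervals
flags_to_intervals <- function(times, flag, stat, rule, window) {
  if (!any(flag)) return(empty_report())
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- data.frame(start = times[starts[r$values]],
                   end = times[ends[r$values]],
                   i0 = starts[r$values], i1 = ends[r$values])
  # merge runs separated by less than one window
  if (nrow(iv) > 1L) {
    keep <- logical(nrow(iv))
    keep[1L] <- TRUE
    cur <- 1L
    for (k in 2:nrow(iv)) {
      if (iv$start[k] - iv$end[cur] <= window + 1e-12) {
        iv$end[cur] <- iv$end[k]
        iv$i1[cur] <- iv$i1[k]
      } else {
        cur <- k
        keep[k] <- TRUE
      }
    }
    iv <- iv[keep, , drop = FALSE]
  }
  data.frame(
    start = iv$start, end = iv$end, rule = rule,
    statistic = vapply(seq_len(nrow(iv)), function(k) {
      mean(stat[iv$i0[k]:iv$i1[k]])
    }, numeric(1L)),
    tag = ifelse(iv$end - iv$start < window, "transient", "sustained"),
    stringsAsFactors = FALSE
  )
}

as_fault_report <- function(intervals, verdict) {
  structure(list(intervals = intervals, verdict = verdict),
            class = "fault_report")
}

#' @export
print.fault_report <- function(x, ...) {
  cat(sprintf("<fault_report> verdict: %s (%d interval%s)\n", x$verdict,
              nrow(x$intervals), if (nrow(x$intervals) == 1L) "" else "s"))
  if (nrow(x$intervals)) print(x$intervals, row.names = FALSE)
  invisible(x)
}

#' Mean-band fault check
#'
#' The rolling mean of the monitored signal over `rule$window` must stay
#' inside `[lower, upper]`; excursions are merged into maximal anomalous
#' intervals (runs closer than one window are joined; intervals shorter
#' than one window are tagged `"transient"`).
#'
#' Note this check is *not* invariant to rescaling the signal — the band
#' is absolute — unlike [cv_check()].
#'
#' @param ts A gap-free [ferm_ts()].
#' @param rule A `mean_band` [fault_rule()].
#' @return A `fault_report`: interval table plus an overall verdict.
#' @export
mean_band_check <- function(ts, rule = fault_rule("mean_band")) {
  stopifnot(is_ferm_ts(ts), inherits(rule, "fault_rule"))
  if (rule$kind != "mean_band") stop("rule kind must be mean_band", call. = FALSE)
  check_window(ts, rule)
  mu <- rolling_stat(ts$times, ts$values, rule$window, mean)
  flag <- mu < rule$lower | mu > rule$upper
  iv <- flags_to_intervals(ts$times, flag, mu, "mean_band", rule$window)
  as_fault_report(iv, if (nrow(iv)) "anomalous" else "normal")
}

#' Coefficient-of-variation fault check
#'
#' Per rolling window, CV = sample standard deviation / mean; windows with
#' CV above `cv_max` become anomalous intervals. CV is scale-free, so this
#' check is invariant to positive rescaling of the signal. Windows whose
#' mean is zero leave CV undefined; such stretches are reported with tag
#' `"indeterminate"` and do not contribute to the anomalous verdict.
#'
#' @param ts A gap-free [ferm_ts()].
#' @param rule A `cv_threshold` [fault_rule()].
#' @return A `fault_report`.
#' @export
cv_check <- function(ts, rule = fault_rule("cv_threshold")) {
  stopifnot(is_ferm_ts(ts), inherits(rule, "fault_rule"))
  if (rule$kind != "cv_threshold") {
    stop("rule kind must be cv_threshold", call. = FALSE)
  }
  check_window(ts, rule)
  mu <- rolling_stat(ts$times, ts$values, rule$window, mean)
  sdv <- rolling_stat(ts$times, ts$values, rule$window,
                      function(x) if (length(x) > 1L) stats::sd(x) else 0)
  cv <- ifelse(mu != 0, sdv / mu, NA_real_)
  undef <- is.na(cv)
  flag <- !undef & cv > rule$cv_max
  iv <- flags_to_intervals(ts$times, flag, cv, "cv_threshold", rule$window)
  if (any(undef)) {
    iv2 <- flags_to_intervals(ts$times, undef,
                              rep(NA_real_, length(cv)), "cv_threshold",
                              rule$window)
    iv2$tag <- "indeterminate"
    iv <- rbind(iv, iv2)
    iv <- iv[order(iv$start), , drop = FALSE]
  }
  anom <- nrow(iv[iv$tag != "indeterminate", , drop = FALSE]) > 0L
  as_fault_report(iv, if (anom) "anomalous" else "normal")
}

check_window <- function(ts, rule) {
  if (anyNA(ts$values)) stop("series must be gap-free", call. = FALSE)
  if (length(ts$times) < 2L || diff(range(ts$times)) < rule$window) {
    stop("window longer than series span", call. = FALSE)
  }
  invisible(TRUE)
}

#' Scan a monitored signal against a set of fault rules
#'
#' Runs every rule and unions their anomalous intervals. The verdict is
#' `"normal"` iff no rule fires — the instrument is accepted only when all
#' predetermined criteria hold.
#'
#' @param ts A gap-free [ferm_ts()].
#' @param rules Non-empty list of [fault_rule()]s. Default: the ambient-CO2
#'   instantiation (mean band 0.02-0.05 plus CV ceiling 0.1).
#' @return A `fault_report` with the union of per-rule intervals, sorted
#'   by start.
#' @export
fault_scan <- function(ts, rules = list(fault_rule("mean_band"),
                                        fault_rule("cv_threshold"))) {
  if (!length(rules)) stop("empty rule list", call. = FALSE)
  reports <- lapply(rules, function(r) {
    switch(r$kind,
           mean_band = mean_band_check(ts, r),
           cv_threshold = cv_check(ts, r))
  })
  iv <- do.call(rbind, lapply(reports, function(r) r$intervals))
  iv <- iv[order(iv$start), , drop = FALSE]
  rownames(iv) <- NULL
  anom <- any(vapply(reports, function(r) r$verdict == "anomalous",
                     logical(1L)))
  as_fault_report(iv, if (anom) "anomalous" else "normal")
}
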