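# Derived physiological parameters from fused data.
#
# Off-gas balance: CER (carbon-dioxide evolution rate) and OUR (oxygen
# uptake rate) from inlet/outlet gas compositions via the inert-gas (N2)
# balance, RQ = CER/OUR. With compositions y in % and the molar volume
# 22.4 L/mol at standard conditions:
#
#   CER = F_air_in/m * (y_N2_in * y_CO2_out / y_N2_out - y_CO2_in)/100
#         * 60/22.4                              [mmol CO2 kg^-1 h^-1]
#   OUR = F_air_in/m * (y_O2_in - y_N2_in * y_O2_out / y_N2_out)/100
#         * 60/22.4                              [mmol O2  kg^-1 h^-1]
#
# (F_air_in in ml/min, m in kg; the /100 converts percent to mole
# fraction — omitting it inflates both rates a hundredfold. The molar
# volume is not temperature-corrected.)
#
# Offline-anchored rates at three levels, from the component balance
# dM/dt = F_in*c_in - F_out*c_out + R + T:
#   R (process, amount/h), r = R/m_avg (reactor), q = R/(OD*m)_avg (cell),
# and yield coefficients Y_i/j = R_i/R_j = r_i/r_j = q_i/q_j.

#' Gas-exchange rates from inlet/outlet compositions
#'
#' Vectorized over time points. Inputs are mole fractions of CO2, O2 and
#' N2 at the bioreactor inlet and outlet, in percent by default. The
#' nitrogen balance corrects for the gas-volume change between inlet and
#' outlet; `y_n2_out` must therefore be positive.
#'
#' @param f_air_in Air inlet flow, ml/min.
#' @param m Broth mass, kg (positive).
#' @param y_co2_in,y_o2_in,y_n2_in Inlet mole fractions.
#' @param y_co2_out,y_o2_out,y_n2_out Outlet mole fractions.
#' @param percent Are fractions expressed in percent (default) rather than
#'   fraction-of-one? The percent-to-fraction conversion is applied
#'   exactly once, keyed off this flag.
#' @return A data.frame with columns `cer`, `our`
#'   (mmol kg^-1 h^-1) and `rq` (dimensionless; `NA` where `our == 0`).
#' @export
gas_rates <- function(f_air_in, m, y_co2_in, y_o2_in, y_n2_in,
                      y_co2_out, y_o2_out, y_n2_out, percent = TRUE) {
  if (any(y_n2_out <= 0)) stop("y_n2_out must be positive", call. = FALSE)
  if (any(m <= 0)) stop("broth mass must be positive", call. = FALSE)
  if (any(f_air_in < 0)) stop("air flow must be non-negative", call. = FALSE)
  conv <- if (percent) 1 / 100 else 1
  k <- f_air_in / m * conv * 60 / 22.4
  cer <- k * (y_n2_in * y_co2_out / y_n2_out - y_co2_in)
  our <- k * (y_o2_in - y_n2_in * y_o2_out / y_n2_out)
  rq <- ifelse(our != 0, cer / our, NA_real_)
  data.frame(cer = cer, our = our, rq = rq)
}

#' Default fused-column mapping for the gas balance
#'
#' Names the fused-frame columns that play each role in [gas_rates()].
#' Override entries to match your column names.
#'
#' @param ... Named overrides, e.g. `m = "broth_weight"`.
#' @return Named list of column names.
#' @export
gas_mapping <- function(...) {
  map <- list(f_air_in = "air_flow", m = "weight",
              y_co2_in = "co2_in", y_o2_in = "o2_in", y_n2_in = "n2_in",
              y_co2_out = "co2_out", y_o2_out = "o2_out",
              y_n2_out = "n2_out")
  utils::modifyList(map, list(...))
}

#' Append CER, OUR and RQ columns to a fused frame
#'
#' @param frame A [fused_frame()] containing the mapped columns.
#' @param mapping A [gas_mapping()].
#' @param percent Compositions in percent? Passed to [gas_rates()].
#' @return The frame with `CER`, `OUR` and (when OUR is nonzero on the
#'   whole grid) `RQ` appended, provenance `derived_gas_balance`. RQ is
#'   undefined where OUR is zero; since fused frames admit no missing
#'   values, the RQ column is omitted with a warning in that case.
#' @export
add_gas_rates <- function(frame, mapping = gas_mapping(), percent = TRUE) {
  stopifnot(inherits(frame, "fused_frame"))
  need <- unlist(mapping)
  missing_cols <- setdiff(need, names(frame$data))
  if (length(missing_cols)) {
    stop("fused frame lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  g <- frame$data
  rates <- gas_rates(g[[mapping$f_air_in]], g[[mapping$m]],
                     g[[mapping$y_co2_in]], g[[mapping$y_o2_in]],
                     g[[mapping$y_n2_in]], g[[mapping$y_co2_out]],
                     g[[mapping$y_o2_out]], g[[mapping$y_n2_out]],
                     percent = percent)
  data <- frame$data
  data$CER <- rates$cer
  data$OUR <- rates$our
  prov <- frame$provenance
  add <- c("CER", "OUR")
  if (anyNA(rates$rq)) {
    warning("OUR is zero at some grid points; RQ column omitted")
  } else {
    data$RQ <- rates$rq
    add <- c(add, "RQ")
  }
  prov <- rbind(prov, data.frame(variable = add, source = "online",
                                 method = "derived_gas_balance",
                                 stringsAsFactors = FALSE))
  fused_frame(frame$times, data, prov)
}

#' Time derivative of a cumulative-amount series
#'
#' Central differences on interior points (exact for any affine signal,
#' second-order on smooth ones), one-sided differences at the ends.
#' Supports non-uniform grids.
#'
#' @param ts A gap-free [ferm_ts()] with at least three points.
#' @param smooth_window Optional odd window for moving-median
#'   pre-smoothing (`NULL` to disable, the default).
#' @return A [ferm_ts()] of the derivative on the same grid.
#' @export
estimate_dmdt <- function(ts, smooth_window = NULL) {
  stopifnot(is_ferm_ts(ts))
  if (length(ts$times) < 3L) stop("need at least three points", call. = FALSE)
  if (anyNA(ts$values)) stop("series must be gap-free", call. = FALSE)
  if (!is.null(smooth_window)) ts <- filter_series(ts, smooth_window)
  t <- ts$times; v <- ts$values; n <- length(t)
  d <- numeric(n)
  d[1L] <- (v[2L] - v[1L]) / (t[2L] - t[1L])
  d[n] <- (v[n] - v[n - 1L]) / (t[n] - t[n - 1L])
  if (n > 2L) {
    i <- 2:(n - 1L)
    d[i] <- (v[i + 1L] - v[i - 1L]) / (t[i + 1L] - t[i - 1L])
  }
  ferm_ts(paste0("d", ts$variable, "_dt"), t, d, source = ts$source,
          unit = paste0(ts$unit, "/h"))
}

#' Process-level reaction rate from the component balance
#'
#' `R = dM/dt - F_in*c_in + F_out*c_out - T`: the reaction term of the
#' balance of substance i over the whole reactor. In a closed batch with
#' no transfer, R reduces to the accumulation derivative.
#'
#' @param dm_dt Accumulation rate of the substance, amount/h.
#' @param inflow `F_in * c_in`, amount/h (default 0).
#' @param outflow `F_out * c_out`, amount/h (default 0).
#' @param transfer Transfer rate to other phases/terms, amount/h
#'   (default 0; rarely instrumented).
#' @return Process-level rate R, amount/h. Vectorized.
#' @export
process_rate <- function(dm_dt, inflow = 0, outflow = 0, transfer = 0) {
  dm_dt - inflow + outflow - transfer
}

#' Reactor- and cell-specific rates from a process rate
#'
#' @param R Process-level rate, amount/h.
#' @param m_avg Mean broth mass over the estimation interval, kg (> 0).
#' @param od_m_avg Mean of OD x mass over the interval (> 0); the
#'   biomass-amount proxy for cell-specific rates.
#' @return An object of class `rate_triple`: list with `R`,
#'   `r = R / m_avg` (amount kg^-1 h^-1) and `q = R / od_m_avg`
#'   (amount per OD-kg per h). Vectorized over `R`.
#' @export
specific_rates <- function(R, m_avg, od_m_avg) {
  if (any(m_avg <= 0)) stop("m_avg must be positive", call. = FALSE)
  if (any(od_m_avg <= 0)) stop("od_m_avg must be positive", call. = FALSE)
  structure(list(R = R, r = R / m_avg, q = R / od_m_avg,
                 m_avg = m_avg, od_m_avg = od_m_avg),
            class = "rate_triple")
}

#' Yield coefficient of substance i on substance j
#'
#' `Y_i/j = R_i/R_j`, which equals `r_i/r_j` and `q_i/q_j` whenever both
#' triples share the same averaging denominators — the three levels are
#' the same ratio. The cross-level agreement is asserted to 1e-9 relative
#' tolerance as a consistency check.
#'
#' @param ti,tj [specific_rates()] triples for substances i and j.
#' @return Numeric yield coefficient(s).
#' @export
yield_coefficient <- function(ti, tj) {
  stopifnot(inherits(ti, "rate_triple"), inherits(tj, "rate_triple"))
  if (any(tj$R == 0)) stop("zero denominator rate", call. = FALSE)
  y <- ti$R / tj$R
  rel <- function(a, b) abs(a - b) / pmax(abs(a), abs(b), .Machine$double.xmin)
  if (any(rel(ti$r / tj$r, y) > 1e-9) || any(rel(ti$q / tj$q, y) > 1e-9)) {
    stop("rate levels disagree: triples do not share averaging denominators",
         call. = FALSE)
  }
  y
}
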