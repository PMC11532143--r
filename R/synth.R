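# Synthetic fed-batch fermentation generator.
#
# Emits the three stream classes the fusion pipeline assumes — dense
# regular online sensors, slow at-line off-gas compositions, sparse
# irregular offline assays — from a smooth logistic biomass trajectory
# with growth-linked + maintenance oxygen demand. Outlet gas fractions
# are obtained by inverting the off-gas balance from the target CER/OUR
# (nitrogen by closure to 100 %), so running the forward pipeline on a
# noiseless batch must reproduce the ground truth: the generator and the
# derivation are exact inverses up to interpolation error.
#
# Deliberately simple kinetics: the fusion/derivation machinery, not the
# biology, is under test here, so substrate ODEs are avoided.

#' Simulator configuration
#'
#' Defaults describe a typical laboratory fed-batch run: 72 h, online
#' sensors every minute, one off-gas reading per 20-min instrument cycle,
#' manual assays every 2-4 h; dry-air inlet; logistic growth.
#'
#' @param duration Batch duration, h.
#' @param online_dt Online cadence, h (default 1 min).
#' @param atline_cycle At-line instrument cycle, h (default 20 min);
#'   readings are stamped at cycle midpoints.
#' @param offline_gap Range (h) of the uniform gap between consecutive
#'   offline samples (default 2-4 h).
#' @param lag Lag-phase duration, h: the specific growth rate ramps from
#'   ~0 to `mu_max` around `t = lag`; biomass equals `x0` at `t = lag`.
#' @param lag_tau Sharpness of the lag-to-growth transition, h (the time
#'   constant of the growth-rate ramp).
#' @param mu_max Maximum specific growth rate, 1/h.
#' @param x0 Biomass (OD600) at `t = lag`.
#' @param capacity Carrying capacity (OD600).
#' @param our_growth Growth-linked O2 demand, mmol O2 per OD per kg.
#' @param our_maint Maintenance O2 demand, mmol O2 per OD per kg per h.
#' @param rq Respiratory quotient (scalar target profile).
#' @param air_flow Air inlet flow, ml/min.
#' @param m0 Initial broth mass, kg.
#' @param feed_start Feed start time, h.
#' @param feed_rate Mass feed rate, kg/h.
#' @param product_spec Specific production rate (titer units per OD h).
#' @param inlet Named inlet composition in percent (sums to 100).
#' @param noise Named per-variable Gaussian noise standard deviations;
#'   entries override the defaults.
#' @param noise_scale Global multiplier on all noise sigmas (0 =
#'   noiseless).
#' @param seed Integer seed; a batch is bitwise reproducible given its
#'   config.
#' @param anomalies List of anomaly specs applied after generation (see
#'   [inject_anomaly()]).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration = 72, online_dt = 1 / 60,
                       atline_cycle = 1 / 3, offline_gap = c(2, 4),
                       lag = 10, lag_tau = 1.5, mu_max = 0.25, x0 = 0.2,
                       capacity = 40,
                       our_growth = 15, our_maint = 0.6, rq = 1.05,
                       air_flow = 1000, m0 = 0.8, feed_start = 8,
                       feed_rate = 0.005, product_spec = 0.01,
                       inlet = c(o2 = 20.96, co2 = 0.04, n2 = 79.00),
                       noise = list(), noise_scale = 1, seed = 1L,
                       anomalies = list()) {
  stopifnot(duration > 0, online_dt > 0, atline_cycle > 0,
            length(offline_gap) == 2L, all(offline_gap > 0),
            noise_scale >= 0)
  if (duration < 2 * offline_gap[2L]) {
    stop("duration must cover at least two offline samples", call. = FALSE)
  }
  if (abs(sum(inlet) - 100) > 1e-9) {
    stop("inlet composition must sum to 100 %", call. = FALSE)
  }
  base_noise <- list(
    ph = 0.01, do = 0.5, temperature = 0.05, stirring = 2, air_flow = 2,
    weight = 0.002, feed_rate = 0, acid_pump = 0.02, inspection_pump = 0.02,
    o2_in = 0.02, co2_in = 0.001, n2_in = 0.02,
    o2_out = 0.02, co2_out = 0.01, n2_out = 0.02,
    biomass = 0.5, titer = 0.2)
  structure(list(duration = duration, online_dt = online_dt,
                 atline_cycle = atline_cycle, offline_gap = offline_gap,
                 lag = lag, lag_tau = lag_tau, mu_max = mu_max, x0 = x0,
                 capacity = capacity,
                 our_growth = our_growth, our_maint = our_maint, rq = rq,
                 air_flow = air_flow, m0 = m0, feed_start = feed_start,
                 feed_rate = feed_rate, product_spec = product_spec,
                 inlet = inlet,
                 noise = utils::modifyList(base_noise, noise),
                 noise_scale = noise_scale, seed = as.integer(seed),
                 anomalies = anomalies),
            class = "sim_config")
}

# Noiseless process state at arbitrary times.
#
# Growth: logistic kinetics with a smoothly ramping specific growth rate
#   mu(t) = mu_max / (1 + exp(-(t - lag)/lag_tau)),
# which gives a genuinely flat lag phase (respiration ~ maintenance only)
# followed by the exponential/stationary phases. The logistic ODE with
# time-varying mu has the closed form X = K / (1 + u),
# u(t) = u(lag) * exp(-(Imu(t) - Imu(lag))), Imu = int mu dt.
sim_truth_at <- function(cfg, t) {
  tau <- cfg$lag_tau
  imu <- function(s) {
    cfg$mu_max * tau * log1p(exp((s - cfg$lag) / tau))
  }
  mu <- cfg$mu_max / (1 + exp(-(t - cfg$lag) / tau))
  u0 <- (cfg$capacity - cfg$x0) / cfg$x0
  u <- u0 * exp(-(imu(t) - imu(cfg$lag)))
  x <- cfg$capacity / (1 + u)
  dx <- mu * x * (1 - x / cfg$capacity)
  our <- cfg$our_growth * dx + cfg$our_maint * x
  cer <- cfg$rq * our
  m <- cfg$m0 + cfg$feed_rate * pmax(t - cfg$feed_start, 0)
  # invert the off-gas balance for outlet fractions, N2 by closure
  cconv <- cfg$air_flow / m * 60 / 22.4 / 100
  n2_out <- 100 * cfg$inlet[["n2"]] / (100 + (cer - our) / cconv)
  co2_out <- n2_out * (cer / cconv + cfg$inlet[["co2"]]) / cfg$inlet[["n2"]]
  o2_out <- n2_out * (cfg$inlet[["o2"]] - our / cconv) / cfg$inlet[["n2"]]
  if (any(c(n2_out, co2_out, o2_out) < 0)) {
    stop("configuration produces negative outlet fractions", call. = FALSE)
  }
  list(x = x, dx = dx, our = our, cer = cer, m = m,
       n2_out = n2_out, co2_out = co2_out, o2_out = o2_out,
       titer = cfg$product_spec * cumtrapz_at(cfg, t))
}

# int_0^t X ds for the product trajectory, by trapezoid on a fine
# internal grid (the ramped-mu biomass curve has no elementary integral)
cumtrapz_at <- function(cfg, t) {
  if (!length(t)) return(numeric(0))
  tg <- seq(0, max(cfg$duration, max(t)), by = min(cfg$online_dt, 0.02))
  tau <- cfg$lag_tau
  imu <- function(s) cfg$mu_max * tau * log1p(exp((s - cfg$lag) / tau))
  u0 <- (cfg$capacity - cfg$x0) / cfg$x0
  xg <- cfg$capacity / (1 + u0 * exp(-(imu(tg) - imu(cfg$lag))))
  cum <- c(0, cumsum(diff(tg) * (xg[-1L] + xg[-length(xg)]) / 2))
  stats::approx(tg, cum, xout = t, rule = 2)$y
}

sim_noise <- function(cfg, var, n) {
  s <- (cfg$noise[[var]] %||% 0) * cfg$noise_scale
  if (s == 0) numeric(n) else stats::rnorm(n, 0, s)
}

#' Simulate one fed-batch fermentation
#'
#' Generates the online, at-line and offline streams of one batch at
#' their native cadences, with per-variable Gaussian noise, and the
#' noiseless ground truth on the online grid. Anomalies listed in the
#' config are injected afterwards.
#'
#' @param cfg A [sim_config()].
#' @param batch_id Batch identifier (default derived from the seed).
#' @return List with `batch` (a [batch_dataset()]) and `truth`: times
#'   (the online grid), noiseless `biomass`, `cer`, `our`, `rq`
#'   trajectories, the `config`, and injected `anomalies`.
#' @export
simulate_batch <- function(cfg = sim_config(),
                           batch_id = sprintf("sim%03d", cfg$seed)) {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(cfg$seed, {
    t_on <- seq(0, cfg$duration, by = cfg$online_dt)
    tr <- sim_truth_at(cfg, t_on)
    do_clean <- pmax(100 - 1.2 * tr$our, 5)
    online <- list(
      ph = 7.0 - 0.01 * tr$x,
      do = do_clean,
      temperature = rep(37, length(t_on)),
      stirring = 300 + 4 * tr$our,
      air_flow = rep(cfg$air_flow, length(t_on)),
      weight = tr$m,
      feed_rate = ifelse(t_on >= cfg$feed_start, cfg$feed_rate, 0),
      acid_pump = rep(0.5, length(t_on)),
      inspection_pump = rep(1.0, length(t_on)))
    series <- lapply(names(online), function(v) {
      ferm_ts(v, t_on, online[[v]] + sim_noise(cfg, v, length(t_on)),
              source = "online")
    })

    t_at <- seq(cfg$atline_cycle / 2, cfg$duration, by = cfg$atline_cycle)
    tra <- sim_truth_at(cfg, t_at)
    atline <- list(
      o2_in = rep(cfg$inlet[["o2"]], length(t_at)),
      co2_in = rep(cfg$inlet[["co2"]], length(t_at)),
      n2_in = rep(cfg$inlet[["n2"]], length(t_at)),
      o2_out = tra$o2_out, co2_out = tra$co2_out, n2_out = tra$n2_out)
    series <- c(series, lapply(names(atline), function(v) {
      ferm_ts(v, t_at, atline[[v]] + sim_noise(cfg, v, length(t_at)),
              source = "at_line", unit = "%")
    }))

    t_off <- 0
    while (TRUE) {
      nxt <- t_off[length(t_off)] +
        stats::runif(1, cfg$offline_gap[1L], cfg$offline_gap[2L])
      if (nxt > cfg$duration) break
      t_off <- c(t_off, nxt)
    }
    tro <- sim_truth_at(cfg, t_off)
    series <- c(series, list(
      ferm_ts("biomass", t_off,
              pmax(tro$x + sim_noise(cfg, "biomass", length(t_off)), 0),
              source = "offline", unit = "OD600"),
      ferm_ts("titer", t_off,
              pmax(tro$titer + sim_noise(cfg, "titer", length(t_off)), 0),
              source = "offline", unit = "g/kg")))

    meta <- batch_meta(batch_id, strain = "synthetic",
                       medium = "synthetic fed-batch",
                       operation_conditions = list(
                         air_flow_ml_min = cfg$air_flow,
                         initial_mass_kg = cfg$m0),
                       control_strategy = "simulated")
    b <- batch_dataset(meta, series)
    truth <- list(times = t_on, biomass = tr$x, cer = tr$cer, our = tr$our,
                  rq = tr$cer / tr$our, config = cfg, anomalies = list())
    for (a in cfg$anomalies) {
      res <- inject_anomaly(b, a, truth)
      b <- res$batch
      truth <- res$truth
    }
    list(batch = b, truth = truth)
  })
}

#' Inject a sensor anomaly into a batch
#'
#' Supported types: `"step"` (additive offset over the interval),
#' `"drift"` (linear ramp from 0 to `magnitude` over the interval), and
#' `"variance_burst"` (added zero-mean noise whose sd is `magnitude`
#' times the absolute segment mean, i.e. `magnitude` is the injected
#' coefficient of variation). The injected interval is recorded in the
#' ground truth when one is supplied.
#'
#' @param b A [batch_dataset()].
#' @param spec List with `variable`, `type`, `start`, `duration`,
#'   `magnitude`.
#' @param truth Optional ground-truth list to annotate.
#' @return List with modified `batch` and `truth` (the latter `NULL` if
#'   not supplied).
#' @export
inject_anomaly <- function(b, spec, truth = NULL) {
  stopifnot(inherits(b, "batch_dataset"))
  v <- spec$variable
  if (is.null(b$series[[v]])) stop("unknown variable: ", v, call. = FALSE)
  s <- b$series[[v]]
  t0 <- spec$start; t1 <- spec$start + spec$duration
  if (t0 < min(s$times) - 1e-9 || t1 > max(s$times) + 1e-9) {
    stop("anomaly interval outside batch span", call. = FALSE)
  }
  idx <- which(s$times >= t0 & s$times < t1)
  if (length(idx)) {
    vals <- s$values
    vals[idx] <- switch(
      spec$type,
      step = vals[idx] + spec$magnitude,
      drift = vals[idx] + spec$magnitude * (s$times[idx] - t0) /
        spec$duration,
      variance_burst = vals[idx] +
        stats::rnorm(length(idx), 0,
                     spec$magnitude * abs(mean(vals[idx]))),
      stop("unknown anomaly type: ", spec$type, call. = FALSE))
    b$series[[v]] <- ferm_ts(v, s$times, vals, source = s$source,
                             unit = s$unit)
  }
  if (!is.null(truth)) {
    truth$anomalies <- c(truth$anomalies, list(spec))
  }
  list(batch = b, truth = truth)
}

#' Simulate a multi-batch study
#'
#' Draws `n_batches` batches from a common config with small lognormal
#' jitter on the growth parameters; designated outlier batches get a
#' strong perturbation (stunted growth: reduced capacity and growth
#' rate, emulating a nutrient-limited run) so that batch-level analytics
#' have a known deviant to find.
#'
#' @param n_batches Number of batches (>= 2).
#' @param cfg Template [sim_config()]; per-batch seeds are derived from
#'   `cfg$seed`.
#' @param outliers Integer indices of outlier batches.
#' @param jitter Lognormal sd of the parameter jitter (default 0.03).
#' @return Named list of `simulate_batch()` results.
#' @export
simulate_study <- function(n_batches, cfg = sim_config(),
                           outliers = integer(0), jitter = 0.03) {
  stopifnot(n_batches >= 2L)
  with_local_seed(cfg$seed, {
    jit <- function(x, f = jitter) x * exp(stats::rnorm(1, 0, f))
    out <- list()
    for (i in seq_len(n_batches)) {
      ci <- cfg
      ci$seed <- cfg$seed + i
      ci$mu_max <- jit(cfg$mu_max)
      ci$capacity <- jit(cfg$capacity)
      ci$our_growth <- jit(cfg$our_growth)
      ci$rq <- jit(cfg$rq, jitter / 3)
      if (i %in% outliers) {
        ci$capacity <- cfg$capacity * 0.35
        ci$mu_max <- cfg$mu_max * 0.5
      }
      class(ci) <- "sim_config"
      id <- sprintf("batch%02d", i)
      out[[id]] <- simulate_batch(ci, batch_id = id)
    }
    out
  })
}
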