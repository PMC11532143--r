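#' Construct a single-variable fermentation time series
#'
#' The atomic data object of the package: the measurements of one process
#' variable for one batch, on an elapsed-time axis (decimal hours since
#' inoculation), tagged with the class of its data source.
#'
#' @param variable Variable name (e.g. `"pH"`, `"o2_out"`).
#' @param times Numeric vector of elapsed hours since inoculation,
#'   strictly increasing.
#' @param values Numeric vector, same length as `times`. `NA` is the
#'   explicit missing marker and is only legal before gap filling.
#' @param source Data-source class: `"online"` (regular, high-frequency
#'   bioreactor sensors), `"at_line"` (near-process instruments such as
#'   off-gas mass spectrometry, slow/irregular cadence) or `"offline"`
#'   (manual lab assays).
#' @param unit Unit string, informational.
#' @return An object of class `ferm_ts`.
#' @export
ferm_ts <- function(variable, times, values,
                    source = c("online", "at_line", "offline"),
                    unit = "") {
  source <- match.arg(source)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have equal length", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(variable = as.character(variable), unit = as.character(unit),
         source = source, times = times, values = values),
    class = "ferm_ts"
  )
}

#' @export
print.ferm_ts <- function(x, ...) {
  cat(sprintf("<ferm_ts> %s [%s] (%s), %d points, %.3f-%.3f h, %d missing\n",
              x$variable, x$unit, x$source, length(x$times),
              if (length(x$times)) min(x$times) else NA_real_,
              if (length(x$times)) max(x$times) else NA_real_,
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
length.ferm_ts <- function(x) length(x$times)

is_ferm_ts <- function(x) inherits(x, "ferm_ts")

#' Batch metadata
#'
#' Descriptive information for one fermentation batch. Only `batch_id` is
#' mandatory; the rest mirrors what an experiment-design record carries:
#' strain, medium, operating conditions and control strategy. `start_time`
#' (ISO-8601 wall clock of inoculation) is required when source tables use
#' wall-clock timestamps rather than elapsed hours.
#'
#' @param batch_id Unique batch identifier (character scalar).
#' @param strain,medium,control_strategy Free-text descriptors.
#' @param operation_conditions Named list of key-value settings.
#' @param start_time Inoculation wall-clock time (ISO-8601 string) or `NULL`.
#' @param scale_specs Named list of [scale_spec()] objects, keyed by variable,
#'   for register-coded channels.
#' @return An object of class `batch_meta`.
#' @export
batch_meta <- function(batch_id, strain = "", medium = "",
                       operation_conditions = list(),
                       control_strategy = "", start_time = NULL,
                       scale_specs = list()) {
  if (missing(batch_id) || !nzchar(as.character(batch_id)[1L])) {
    stop("`batch_id` is required", call. = FALSE)
  }
  structure(
    list(batch_id = as.character(batch_id)[1L],
         strain = as.character(strain),
         medium = as.character(medium),
         operation_conditions = as.list(operation_conditions),
         control_strategy = as.character(control_strategy),
         start_time = start_time,
         scale_specs = scale_specs),
    class = "batch_meta"
  )
}

#' All streams of one fermentation batch
#'
#' Bundles the metadata and every [ferm_ts()] stream of a batch; the unit
#' of fusion and of multi-batch analytics.
#'
#' @param meta A [batch_meta()] object.
#' @param series A list of [ferm_ts()] objects (any order); no two may
#'   share a variable name.
#' @return An object of class `batch_dataset`; `series` is named by variable.
#' @export
batch_dataset <- function(meta, series = list()) {
  if (!inherits(meta, "batch_meta")) stop("`meta` must be a batch_meta", call. = FALSE)
  if (!all(vapply(series, is_ferm_ts, logical(1L)))) {
    stop("all elements of `series` must be ferm_ts objects", call. = FALSE)
  }
  nm <- vapply(series, function(s) s$variable, character(1L))
  if (anyDuplicated(nm)) {
    stop("duplicate variable name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  names(series) <- nm
  structure(list(meta = meta, series = series), class = "batch_dataset")
}

#' @export
print.batch_dataset <- function(x, ...) {
  cat(sprintf("<batch_dataset> %s: %d series\n", x$meta$batch_id,
              length(x$series)))
  for (s in x$series) {
    cat(sprintf("  %-22s %-8s %5d pts\n", s$variable, s$source,
                length(s$times)))
  }
  invisible(x)
}

#' Validate a batch dataset against the domain invariants
#'
#' A reporting operation: it never throws. Each violated rule yields one
#' message naming the offending series.
#'
#' Checked rules: times strictly increasing; times/values equal length;
#' no duplicate variable names; at least one online series (required for
#' fusion); all-`NA` series flagged.
#'
#' @param b A [batch_dataset()] (or anything; non-batches are reported,
#'   not rejected).
#' @return Character vector of violations; empty iff the batch is valid.
#' @export
validate_batch <- function(b) {
  out <- character(0)
  if (!inherits(b, "batch_dataset")) {
    return("not a batch_dataset object")
  }
  nm <- vapply(b$series, function(s) s$variable, character(1L))
  if (anyDuplicated(nm)) {
    out <- c(out, paste0("duplicate variable: ",
                         paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  for (s in b$series) {
    if (length(s$times) != length(s$values)) {
      out <- c(out, paste0(s$variable, ": times/values length mismatch"))
    }
    if (length(s$times) > 1L && any(diff(s$times) <= 0)) {
      out <- c(out, paste0(s$variable, ": non-increasing times"))
    }
    if (length(s$values) > 0L && all(is.na(s$values))) {
      out <- c(out, paste0(s$variable, ": all values missing"))
    }
    if (!s$source %in% c("online", "at_line", "offline")) {
      out <- c(out, paste0(s$variable, ": unknown source class"))
    }
  }
  src <- vapply(b$series, function(s) s$source, character(1L))
  if (!any(src == "online")) {
    out <- c(out, "no online series (required for fusion)")
  }
  out
}

#' A fused, rectangular view of a batch
#'
#' All variables aligned onto the online time grid: one value per variable
#' per grid point, no missing markers, plus per-column provenance (source
#' class and the alignment/fill method applied).
#'
#' @param times Numeric grid (the online time points), strictly increasing.
#' @param data A data.frame of aligned columns, `length(times)` rows.
#' @param provenance A data.frame with columns `variable`, `source`,
#'   `method`, one row per column of `data`.
#' @return An object of class `fused_frame`.
#' @export
fused_frame <- function(times, data, provenance) {
  times <- as.numeric(times)
  if (nrow(data) != length(times)) {
    stop("`data` must have one row per grid point", call. = FALSE)
  }
  if (any(diff(times) <= 0)) stop("grid must be strictly increasing", call. = FALSE)
  if (anyNA(data)) stop("fused frame may not contain missing values", call. = FALSE)
  if (!setequal(provenance$variable, names(data)) ||
      nrow(provenance) != ncol(data)) {
    stop("provenance must describe exactly the data columns", call. = FALSE)
  }
  structure(list(times = times, data = data, provenance = provenance),
            class = "fused_frame")
}

#' @export
print.fused_frame <- function(x, ...) {
  cat(sprintf("<fused_frame> %d grid points x %d variables (%.3f-%.3f h)\n",
              length(x$times), ncol(x$data), min(x$times), max(x$times)))
  print(x$provenance, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.fused_frame <- function(x, ...) {
  cbind(data.frame(time = x$times), x$data)
}

#' Reinterpret a fused frame as a batch of online series
#'
#' Every column becomes an online [ferm_ts()] on the fused grid. Useful for
#' re-running fusion (idempotence) or feeding fused variables to per-series
#' tools such as the fault scanner.
#'
#' @param frame A [fused_frame()].
#' @param meta Optional [batch_meta()]; a stub is created when omitted.
#' @return A [batch_dataset()].
#' @export
fused_to_batch <- function(frame, meta = NULL) {
  stopifnot(inherits(frame, "fused_frame"))
  if (is.null(meta)) meta <- batch_meta("fused")
  series <- lapply(names(frame$data), function(v) {
    ferm_ts(v, frame$times, frame$data[[v]], source = "online")
  })
  batch_dataset(meta, series)
}
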