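# On-disk batch layout: one directory per batch,
#   meta.yaml   key-value metadata (batch_id mandatory)
#   online.csv / atline.csv / offline.csv
#     first column `time` (decimal hours, or wall-clock if meta has
#     start_time), remaining columns one variable each, header mandatory.
# A cell is empty when the variable was not observed at that time and the
# literal string "NA" when a reading exists but is missing (explicit
# sentinel, so fill operations stay auditable).

SOURCE_FILES <- c(online = "online.csv", at_line = "atline.csv",
                  offline = "offline.csv")

# %.17g survives text -> double round trips bitwise
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1L))
  out
}

#' Save a batch dataset as a portable directory of delimited tables
#'
#' Writes `meta.yaml` plus one CSV per source class present. Values are
#' written with enough digits to round-trip bitwise through [load_batch()].
#'
#' @param b A [batch_dataset()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_batch <- function(b, path) {
  stopifnot(inherits(b, "batch_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  units <- lapply(b$series, function(s) s$unit)
  meta <- list(
    batch_id = b$meta$batch_id,
    strain = b$meta$strain,
    medium = b$meta$medium,
    operation_conditions = b$meta$operation_conditions,
    control_strategy = b$meta$control_strategy,
    start_time = b$meta$start_time,
    scale_specs = lapply(b$meta$scale_specs, unclass),
    units = units
  )
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))

  src <- vapply(b$series, function(s) s$source, character(1L))
  for (cls in names(SOURCE_FILES)) {
    ss <- b$series[src == cls]
    if (!length(ss)) next
    times <- sort(unique(unlist(lapply(ss, function(s) s$times))))
    tab <- matrix("", nrow = length(times), ncol = length(ss) + 1L)
    tab[, 1L] <- fmt_num(times)
    for (j in seq_along(ss)) {
      idx <- match(ss[[j]]$times, times)
      tab[idx, j + 1L] <- fmt_num(ss[[j]]$values)
    }
    con <- file(file.path(path, SOURCE_FILES[[cls]]), "w")
    writeLines(paste(c("time", names(ss)), collapse = ","), con)
    writeLines(apply(tab, 1L, paste, collapse = ","), con)
    close(con)
  }
  invisible(path)
}

parse_time_column <- function(txt, start_time, file) {
  num <- suppressWarnings(as.numeric(txt))
  if (!anyNA(num)) return(num)
  # wall-clock timestamps: need the inoculation time to convert to elapsed h
  if (is.null(start_time)) {
    stop("non-numeric time column in ", file,
         " and no start_time in metadata", call. = FALSE)
  }
  t0 <- as.POSIXct(start_time, tz = "UTC")
  tt <- as.POSIXct(txt, tz = "UTC")
  if (anyNA(tt)) stop("unparseable timestamp in ", file, call. = FALSE)
  as.numeric(difftime(tt, t0, units = "hours"))
}

#' Load a batch dataset from a batch directory
#'
#' Inverse of [save_batch()]. Wall-clock time columns are converted to
#' elapsed hours using `start_time` from `meta.yaml`. Unparseable numeric
#' cells are reported with their row and column.
#'
#' @param path Batch directory.
#' @return A [batch_dataset()].
#' @export
load_batch <- function(path) {
  meta_file <- file.path(path, "meta.yaml")
  if (!file.exists(meta_file)) {
    stop("missing metadata file (meta.yaml) in ", path, call. = FALSE)
  }
  m <- yaml::read_yaml(meta_file)
  if (is.null(m$batch_id)) stop("metadata lacks batch_id", call. = FALSE)
  scale_specs <- lapply(m$scale_specs, function(s) {
    scale_spec(s$scale_lo, s$scale_hi, s$full_scale)
  })
  meta <- batch_meta(m$batch_id,
                     strain = m$strain %||% "",
                     medium = m$medium %||% "",
                     operation_conditions = m$operation_conditions %||% list(),
                     control_strategy = m$control_strategy %||% "",
                     start_time = m$start_time,
                     scale_specs = scale_specs)
  units <- m$units %||% list()

  series <- list()
  for (cls in names(SOURCE_FILES)) {
    f <- file.path(path, SOURCE_FILES[[cls]])
    if (!file.exists(f)) next
    tab <- utils::read.csv(f, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
    if (ncol(tab) < 2L) next
    times <- parse_time_column(tab[[1L]], meta$start_time, basename(f))
    for (v in names(tab)[-1L]) {
      txt <- tab[[v]]
      obs <- nzchar(txt)                     # empty cell = not observed
      vals <- rep(NA_real_, sum(obs))
      keep <- txt[obs]
      not_na <- keep != "NA"
      parsed <- suppressWarnings(as.numeric(keep[not_na]))
      if (anyNA(parsed)) {
        bad <- which(obs)[which(not_na)[which(is.na(parsed))[1L]]]
        stop(sprintf("non-numeric value in %s, row %d, column '%s': \"%s\"",
                     basename(f), bad, v, txt[bad]), call. = FALSE)
      }
      vals[not_na] <- parsed
      series[[length(series) + 1L]] <-
        ferm_ts(v, times[obs], vals, source = cls,
                unit = units[[v]] %||% "")
    }
  }
  batch_dataset(meta, series)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a fused frame to a delimited file
#'
#' CSV export writes full-precision values so that re-importing reproduces
#' the frame bitwise; a provenance sidecar (`<stem>.provenance.csv`) records
#' how each column was aligned.
#'
#' @param frame A [fused_frame()].
#' @param path Output file path.
#' @param format Only `"csv"` is supported.
#' @param sidecar Write the provenance sidecar? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
export_frame <- function(frame, path, format = c("csv"), sidecar = TRUE) {
  format <- match.arg(format)
  stopifnot(inherits(frame, "fused_frame"))
  if (!length(frame$times) || !ncol(frame$data)) {
    stop("nothing to export: empty frame", call. = FALSE)
  }
  df <- as.data.frame(frame)
  con <- file(path, "w")
  writeLines(paste(names(df), collapse = ","), con)
  body <- do.call(cbind, lapply(df, fmt_num))
  writeLines(apply(body, 1L, paste, collapse = ","), con)
  close(con)
  if (sidecar) {
    utils::write.csv(frame$provenance,
                     paste0(tools::file_path_sans_ext(path),
                            ".provenance.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Import a fused frame written by [export_frame()]
#'
#' @param path CSV path; the provenance sidecar is read when present,
#'   otherwise columns are marked `online`/`imported`.
#' @return A [fused_frame()].
#' @export
import_frame <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "numeric")
  stopifnot("time" %in% names(df))
  prov_file <- paste0(tools::file_path_sans_ext(path), ".provenance.csv")
  vars <- setdiff(names(df), "time")
  if (file.exists(prov_file)) {
    prov <- utils::read.csv(prov_file, stringsAsFactors = FALSE)
  } else {
    prov <- data.frame(variable = vars, source = "online",
                       method = "imported", stringsAsFactors = FALSE)
  }
  fused_frame(df$time, df[vars], prov)
}
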