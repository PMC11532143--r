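# Scaled-integer register codec for instrument transport payloads.
# Off-gas mass spectrometers ship compositions over Modbus-style registers
# as integers on a fixed transmission scale; engineering units are
# recovered by the inverse affine map. The scale triplet is instrument
# configuration, carried per variable in the batch metadata.

#' Register scaling specification
#'
#' @param scale_lo Preset minimum detection value (engineering units).
#' @param scale_hi Preset maximum detection value; must exceed `scale_lo`.
#' @param full_scale Maximum transmission value (e.g. 65535 for a 16-bit
#'   register); must be positive.
#' @return An object of class `scale_spec`.
#' @export
scale_spec <- function(scale_lo, scale_hi, full_scale = 65535) {
  if (!is.finite(scale_lo) || !is.finite(scale_hi) || scale_hi <= scale_lo) {
    stop("scale_hi must exceed scale_lo", call. = FALSE)
  }
  if (!is.finite(full_scale) || full_scale <= 0) {
    stop("full_scale must be positive", call. = FALSE)
  }
  structure(list(scale_lo = scale_lo, scale_hi = scale_hi,
                 full_scale = full_scale), class = "scale_spec")
}

#' Encode measured values onto the transport scale
#'
#' `raw = (measured - scale_lo) / (scale_hi - scale_lo) * full_scale`,
#' rounded half-up to the nearest integer. Out-of-range inputs raise
#' rather than clamp, so sensor saturation surfaces downstream instead of
#' being silently flattened.
#'
#' @param measured Numeric vector in `[scale_lo, scale_hi]`.
#' @param spec A [scale_spec()].
#' @return Integer-valued numeric vector in `[0, full_scale]`.
#' @export
encode_register <- function(measured, spec) {
  stopifnot(inherits(spec, "scale_spec"))
  if (any(measured < spec$scale_lo | measured > spec$scale_hi, na.rm = TRUE)) {
    stop("measured value outside [scale_lo, scale_hi]", call. = FALSE)
  }
  raw <- (measured - spec$scale_lo) / (spec$scale_hi - spec$scale_lo) *
    spec$full_scale
  floor(raw + 0.5)  # round half-up
}

#' Decode transport-scale values back to engineering units
#'
#' Inverse of [encode_register()] up to the quantization step
#' `(scale_hi - scale_lo) / full_scale`.
#'
#' @param raw Numeric vector in `[0, full_scale]`.
#' @param spec A [scale_spec()].
#' @return Numeric vector in engineering units.
#' @export
decode_register <- function(raw, spec) {
  stopifnot(inherits(spec, "scale_spec"))
  if (any(raw < 0 | raw > spec$full_scale, na.rm = TRUE)) {
    stop("raw value outside [0, full_scale]", call. = FALSE)
  }
  spec$scale_lo + raw / spec$full_scale * (spec$scale_hi - spec$scale_lo)
}
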