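#' Two-point conductivity calibration
#'
#' Builds the affine map from conductivity-meter readings to NaCl
#' concentration using two reference plates of known concentration
#' (conventionally 50 mM and 100 mM NGM plates read at room temperature).
#' The map interpolates the two reference points exactly and extrapolates
#' linearly beyond them.
#'
#' @param readings Two meter readings (any monotone conductivity unit).
#' @param conc_mM The two known concentrations, in mM.
#' @return An object of class `conductivity_calibration` with fields
#'   `slope` and `intercept`.
#' @examples
#' cal <- calibrate_conductivity(c(4.1, 7.9), c(50, 100))
#' predict(cal, c(4.1, 6.0))
#' @export
calibrate_conductivity <- function(readings, conc_mM = c(50, 100)) {
  if (length(readings) != 2 || length(conc_mM) != 2) {
    stop("exactly two (reading, concentration) reference pairs are required",
         call. = FALSE)
  }
  if (readings[1] == readings[2]) {
    stop("reference readings must be distinct", call. = FALSE)
  }
  if (conc_mM[1] == conc_mM[2]) {
    stop("reference concentrations must be distinct", call. = FALSE)
  }
  slope <- diff(conc_mM) / diff(readings)
  structure(
    list(slope = slope,
         intercept = conc_mM[1] - slope * readings[1],
         readings = readings, conc_mM = conc_mM),
    class = "conductivity_calibration"
  )
}

#' @rdname calibrate_conductivity
#' @param object A `conductivity_calibration`.
#' @param reading Meter readings to convert (vectorised).
#' @param ... Unused.
#' @return `predict()` returns concentrations in mM.
#' @export
predict.conductivity_calibration <- function(object, reading, ...) {
  object$intercept + object$slope * reading
}

#' @export
print.conductivity_calibration <- function(x, ...) {
  cat(sprintf("<conductivity_calibration> mM = %.6g + %.6g * reading\n",
              x$intercept, x$slope))
  invisible(x)
}
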