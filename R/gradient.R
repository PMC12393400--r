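#' Describe an assay plate
#'
#' Bundles the geometry and physical constants of a chemotaxis assay plate:
#' its radius, the depth of the poured agar, the baseline NaCl concentration
#' of the medium, and the diffusion coefficient of NaCl through the agar.
#' These are the constants of the point-source diffusion model used by
#' [predict_concentration()].
#'
#' @param radius_cm Plate radius in cm. Default 2.5 (a 50 mm plate).
#' @param agar_depth_cm Depth of the poured agar in cm. Default 0.35, a
#'   typical pour for a 50 mm NGM plate.
#' @param baseline_mM Baseline NaCl concentration of the medium in mM
#'   (NGM is approximately 50 mM).
#' @param diffusion_cm2_s Diffusion coefficient of NaCl in cm^2/s.
#'   Default 1.590e-5, the value for 5 M NaCl in an aqueous medium.
#'
#' @return An object of class `plate_model`.
#' @examples
#' plate_model()
#' @export
plate_model <- function(radius_cm = 2.5,
                        agar_depth_cm = 0.35,
                        baseline_mM = 50,
                        diffusion_cm2_s = 1.590e-5) {
  vals <- c(radius_cm = radius_cm, agar_depth_cm = agar_depth_cm,
            baseline_mM = baseline_mM, diffusion_cm2_s = diffusion_cm2_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    bad <- names(vals)[!is.finite(vals) | vals <= 0]
    stop("plate_model fields must be finite and strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(as.list(vals), class = "plate_model")
}

#' @export
print.plate_model <- function(x, ...) {
  cat("<plate_model>\n",
      sprintf("  radius: %.2f cm  agar depth: %.2f cm\n",
              x$radius_cm, x$agar_depth_cm),
      sprintf("  baseline: %.1f mM NaCl  D: %.3e cm^2/s\n",
              x$baseline_mM, x$diffusion_cm2_s), sep = "")
  invisible(x)
}

#' Convert a pipetted drop to moles of solute
#'
#' @param volume_uL Drop volume in microlitres.
#' @param molarity_M Solution molarity in mol/L.
#' @return Moles of solute (numeric, vectorised).
#' @examples
#' moles_from_drop(4, 5)    # 4 uL of 5 M NaCl -> 2e-5 mol
#' moles_from_drop(1.6, 5)  # 8e-6 mol
#' @export
moles_from_drop <- function(volume_uL, molarity_M) {
  if (any(volume_uL < 0) || any(molarity_M < 0)) {
    stop("volume and molarity must be non-negative", call. = FALSE)
  }
  volume_uL * 1e-6 * molarity_M
}

#' Build a drop schedule
#'
#' A drop schedule is a tibble with one row per applied NaCl drop, holding
#' the moles delivered and the time elapsed between application and the
#' moment the gradient is evaluated (usually assay start). Rows are the
#' `n` point sources summed by [predict_concentration()].
#'
#' @param volume_uL,molarity_M,hours_before Parallel vectors describing the
#'   drops as pipetted: volume, molarity, and hours between application and
#'   evaluation.
#' @return A tibble with columns `moles` (mol) and `elapsed_s` (s), class
#'   `drop_schedule`.
#' @examples
#' drop_schedule(c(4, 4, 1.6), 5, c(22, 5, 2))
#' @export
drop_schedule <- function(volume_uL, molarity_M, hours_before) {
  n <- max(length(volume_uL), length(molarity_M), length(hours_before))
  out <- tibble::tibble(
    moles = moles_from_drop(rep_len(volume_uL, n), rep_len(molarity_M, n)),
    elapsed_s = rep_len(hours_before, n) * 3600
  )
  validate_drop_schedule(out)
}

#' @rdname drop_schedule
#' @param moles,elapsed_s Drop sizes (mol) and elapsed diffusion times (s),
#'   for schedules specified directly in model units.
#' @export
drop_schedule_raw <- function(moles, elapsed_s) {
  n <- max(length(moles), length(elapsed_s))
  out <- tibble::tibble(moles = rep_len(moles, n),
                        elapsed_s = rep_len(elapsed_s, n))
  validate_drop_schedule(out)
}

validate_drop_schedule <- function(x) {
  if (any(x$moles < 0)) stop("drop moles must be >= 0", call. = FALSE)
  if (any(x$elapsed_s <= 0)) {
    stop("elapsed diffusion time must be strictly positive (a drop applied ",
         "at the evaluation instant makes the kernel singular)",
         call. = FALSE)
  }
  class(x) <- c("drop_schedule", class(x))
  x
}

#' The printed three-drop NaCl schedule
#'
#' The standard schedule for building a salt gradient on a 50 mm assay
#' plate: drops of 4, 4 and 1.6 uL of 5 M NaCl applied 22, 5 and 2 hours
#' before the assay (the first drop is applied within a 20-24 h window;
#' 22 h is the midpoint).
#'
#' @return A [drop_schedule()] tibble with three rows.
#' @examples
#' standard_salt_schedule()
#' @export
standard_salt_schedule <- function() {
  drop_schedule(volume_uL = c(4, 4, 1.6), molarity_M = 5,
                hours_before = c(22, 5, 2))
}

#' Concentration contribution of a single drop
#'
#' Evaluates the instantaneous point-source diffusion kernel for one drop
#' of `moles` mol of NaCl spreading laterally through an agar sheet of
#' depth `d` for `elapsed_s` seconds:
#' \deqn{c(t_i, r) = \frac{10^6 N_i}{4 \pi d D t_i}
#'       e^{-r^2 / (4 D t_i)}}
#' where the 1e6 factor converts mol/cm^3 to mM. The kernel treats the
#' agar as an unbounded plane; no correction is applied at the plate wall.
#'
#' @param moles Moles of NaCl in the drop.
#' @param elapsed_s Seconds since the drop was applied.
#' @param r_cm Distance from the drop (the salt peak) in cm. Vectorised.
#' @param plate A [plate_model()] supplying agar depth and diffusivity.
#' @return Concentration contribution in mM.
#' @examples
#' drop_contribution(2e-5, 7200, r_cm = 0)
#' @export
drop_contribution <- function(moles, elapsed_s, r_cm, plate = plate_model()) {
  if (any(moles < 0)) stop("moles must be >= 0", call. = FALSE)
  if (any(elapsed_s <= 0)) stop("elapsed_s must be > 0", call. = FALSE)
  if (any(r_cm < 0)) stop("r_cm must be >= 0", call. = FALSE)
  d <- plate$agar_depth_cm
  D <- plate$diffusion_cm2_s
  1e6 * moles / (4 * pi * d * D * elapsed_s) *
    exp(-r_cm^2 / (4 * D * elapsed_s))
}

#' Predict NaCl concentration at a distance from the salt peak
#'
#' Superposes the diffusion contributions of every drop in a schedule on
#' top of the plate's baseline concentration:
#' \deqn{C(r) = C_o + \sum_{i=1}^{n} c(t_i, r).}
#' `r_cm` is measured from the salt peak (the point where the drops were
#' applied), not from the plate center.
#'
#' @param schedule A [drop_schedule()]; an empty schedule returns the
#'   baseline everywhere.
#' @param plate A [plate_model()].
#' @param r_cm Distances from the peak in cm (vectorised).
#' @return Concentration in mM, one value per element of `r_cm`.
#' @examples
#' predict_concentration(standard_salt_schedule(), plate_model(),
#'                       r_cm = c(0, 1.25))
#' @export
predict_concentration <- function(schedule, plate = plate_model(), r_cm = 0) {
  stopifnot(is.data.frame(schedule))
  contrib <- vapply(
    r_cm,
    function(r) {
      if (nrow(schedule) == 0) return(0)
      sum(drop_contribution(schedule$moles, schedule$elapsed_s, r, plate))
    },
    numeric(1)
  )
  plate$baseline_mM + contrib
}

#' Predict the concentration field over the whole plate
#'
#' Evaluates [predict_concentration()] on a regular Cartesian grid covering
#' the plate's bounding box. Coordinates are in mm with the origin at the
#' plate center; the salt peak sits at `(peak_offset_mm, 0)`. Nodes beyond
#' the plate radius are retained but flagged `on_plate = FALSE`.
#'
#' @param schedule A [drop_schedule()].
#' @param plate A [plate_model()].
#' @param grid_spacing_mm Grid spacing in mm.
#' @param peak_offset_mm Distance of the salt peak from the plate center in
#'   mm. Default 12.5 (a point midway between center and wall of a 50 mm
#'   plate). Must be smaller than the plate radius.
#' @return A tibble of class `concentration_field` with columns `x_mm`,
#'   `y_mm`, `r_mm` (distance to the peak), `conc_mM` and `on_plate`.
#'   The plate, schedule and peak position travel along as attributes.
#' @examples
#' field <- predict_field(standard_salt_schedule(), grid_spacing_mm = 2)
#' dplyr::filter(field, on_plate) |> dplyr::summarise(max(conc_mM))
#' @export
predict_field <- function(schedule, plate = plate_model(),
                          grid_spacing_mm = 1, peak_offset_mm = 12.5) {
  if (grid_spacing_mm <= 0) stop("grid_spacing_mm must be > 0", call. = FALSE)
  radius_mm <- plate$radius_cm * 10
  if (peak_offset_mm >= radius_mm) {
    stop("peak_offset_mm must be smaller than the plate radius",
         call. = FALSE)
  }
  ax <- seq(-radius_mm, radius_mm, by = grid_spacing_mm)
  grid <- tidyr::expand_grid(x_mm = ax, y_mm = ax)
  r_mm <- sqrt((grid$x_mm - peak_offset_mm)^2 + grid$y_mm^2)
  out <- tibble::tibble(
    x_mm = grid$x_mm,
    y_mm = grid$y_mm,
    r_mm = r_mm,
    conc_mM = predict_concentration(schedule, plate, r_cm = r_mm / 10),
    on_plate = sqrt(grid$x_mm^2 + grid$y_mm^2) <= radius_mm
  )
  structure(out,
            class = c("concentration_field", class(out)),
            plate = plate,
            peak_mm = c(peak_offset_mm, 0),
            grid_spacing_mm = grid_spacing_mm)
}

#' Plot a predicted concentration field
#'
#' @param object A `concentration_field` from [predict_field()].
#' @param ... Unused.
#' @return A ggplot: filled concentration raster with the plate outline and
#'   the salt peak marked.
#' @method autoplot concentration_field
#' @export
autoplot.concentration_field <- function(object, ...) {
  peak <- attr(object, "peak_mm")
  plate <- attr(object, "plate")
  radius_mm <- plate$radius_cm * 10
  circ <- tibble::tibble(theta = seq(0, 2 * pi, length.out = 181),
                         x_mm = radius_mm * cos(.data$theta),
                         y_mm = radius_mm * sin(.data$theta))
  ggplot2::ggplot(dplyr::filter(object, .data$on_plate),
                  ggplot2::aes(.data$x_mm, .data$y_mm)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$conc_mM)) +
    ggplot2::geom_path(data = circ, linewidth = 0.3) +
    ggplot2::annotate("point", x = peak[1], y = peak[2], shape = 3) +
    ggplot2::scale_fill_viridis_c(name = "NaCl (mM)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}
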