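#' Locomotor parameters of a simulated worm
#'
#' Parameters of the run-and-tumble walker used by
#' [simulate_chemotaxis_tracks()]. The walker advances at constant speed,
#' its heading diffuses with Gaussian noise, and it reorients abruptly
#' (a pirouette) at a baseline rate that is suppressed while the sensed
#' NaCl concentration is rising — the klinokinetic strategy by which
#' C. elegans climbs salt gradients.
#'
#' @param speed_mm_s Crawling speed in mm/s. Default 0.15, a typical adult
#'   crawl.
#' @param heading_noise Heading diffusion in rad/sqrt(s).
#' @param pirouette_rate Baseline pirouette rate in 1/s.
#' @param beta Dimensionless chemotaxis gain: the per-step pirouette
#'   probability is scaled by `max(0, 1 - beta * dC/dt)` where `dC/dt` is
#'   the low-pass-filtered concentration change (mM/s) the worm
#'   experiences. `beta = 0` gives an unbiased walk.
#' @param sensory_timescale_s Time constant (s) of the exponential filter
#'   applied to the sensed concentration derivative.
#' @return A list of class `worm_params`.
#' @export
worm_params <- function(speed_mm_s = 0.15,
                        heading_noise = 0.7,
                        pirouette_rate = 0.25,
                        beta = 0,
                        sensory_timescale_s = 1) {
  if (speed_mm_s <= 0) stop("speed_mm_s must be > 0", call. = FALSE)
  if (heading_noise < 0 || pirouette_rate < 0 || beta < 0 ||
      sensory_timescale_s < 0) {
    stop("rates, noise and gain must be >= 0", call. = FALSE)
  }
  structure(list(speed_mm_s = speed_mm_s, heading_noise = heading_noise,
                 pirouette_rate = pirouette_rate, beta = beta,
                 sensory_timescale_s = sensory_timescale_s),
            class = "worm_params")
}

# Bilinear interpolator over the regular grid of a concentration_field.
field_interpolator <- function(field) {
  ax <- sort(unique(field$x_mm))
  ay <- sort(unique(field$y_mm))
  h <- attr(field, "grid_spacing_mm")
  # expand_grid orders y fastest within x
  m <- matrix(field$conc_mM, nrow = length(ay), ncol = length(ax))
  function(x, y) {
    fx <- pmin(pmax((x - ax[1]) / h, 0), length(ax) - 1L - 1e-9)
    fy <- pmin(pmax((y - ay[1]) / h, 0), length(ay) - 1L - 1e-9)
    ix <- floor(fx); iy <- floor(fy)
    tx <- fx - ix;  ty <- fy - iy
    i1 <- iy + 1L; i2 <- iy + 2L; j1 <- ix + 1L; j2 <- ix + 2L
    m[cbind(i1, j1)] * (1 - tx) * (1 - ty) +
      m[cbind(i1, j2)] * tx * (1 - ty) +
      m[cbind(i2, j1)] * (1 - tx) * ty +
      m[cbind(i2, j2)] * tx * ty
  }
}

# Reflect positions that stepped beyond the plate wall back inside, and
# mirror the heading about the wall tangent at the crossing point.
reflect_at_wall <- function(x, y, heading, radius_mm) {
  r <- sqrt(x^2 + y^2)
  out <- r > radius_mm
  if (any(out)) {
    phi <- atan2(y[out], x[out])
    r_new <- pmax(2 * radius_mm - r[out], 0)
    x[out] <- r_new * cos(phi)
    y[out] <- r_new * sin(phi)
    heading[out] <- 2 * phi + pi - heading[out]
  }
  list(x = x, y = y, heading = heading)
}

#' Simulate chemotaxis assay tracks on a concentration field
#'
#' Generates per-frame worm positions in the dialect produced by plate
#' trackers: one row per (track, frame) with coordinates in mm and a
#' detection flag. Worms start at a common drop point, perform a
#' run-and-tumble walk with klinokinetic gradient climbing (see
#' [worm_params()]), reflect off the plate wall, and suffer random
#' detection gaps during which their coordinates are missing but their
#' track id is retained (re-detection resumes the same id).
#'
#' @param field A `concentration_field` from [predict_field()]; it must
#'   cover the whole plate.
#' @param n_worms Number of worms (tracks).
#' @param duration_s Assay duration in seconds (default 420 = 7 min).
#' @param frame_rate Acquisition rate in frames/s (default 3.75). The
#'   frame count is `round(duration_s * frame_rate)`; frames are indexed
#'   from 0 at assay start.
#' @param start_xy Common start position in mm (default the plate center).
#' @param worms A [worm_params()] object.
#' @param gap_prob Per-frame probability that a detected worm starts a
#'   detection gap.
#' @param mean_gap_frames Mean gap length in frames (geometric).
#' @param split_on_redetect If `TRUE`, each re-detection after a gap opens
#'   a new track id (a stress-test dialect some trackers emit) instead of
#'   resuming the old one.
#' @param seed Integer seed; the simulation is fully deterministic given
#'   the seed.
#' @return A tibble with columns `track_id`, `frame`, `time_s`, `x_mm`,
#'   `y_mm`, `detected`, sorted by (track_id, frame). The peak position
#'   is attached as attribute `peak_mm`.
#' @examples
#' field <- predict_field(standard_salt_schedule(), grid_spacing_mm = 2)
#' tr <- simulate_chemotaxis_tracks(field, n_worms = 2, duration_s = 30,
#'                                  seed = 1)
#' head(tr)
#' @export
simulate_chemotaxis_tracks <- function(field,
                                       n_worms = 8,
                                       duration_s = 420,
                                       frame_rate = 3.75,
                                       start_xy = c(0, 0),
                                       worms = worm_params(),
                                       gap_prob = 0.01,
                                       mean_gap_frames = 5,
                                       split_on_redetect = FALSE,
                                       seed = 1L) {
  stopifnot(inherits(field, "concentration_field"))
  plate <- attr(field, "plate")
  radius_mm <- plate$radius_cm * 10
  if (max(abs(field$x_mm)) < radius_mm || max(abs(field$y_mm)) < radius_mm) {
    stop("field does not cover the plate", call. = FALSE)
  }
  if (gap_prob < 0 || gap_prob > 1) stop("gap_prob must be in [0, 1]",
                                         call. = FALSE)
  conc_at <- field_interpolator(field)
  n_frames <- round(duration_s * frame_rate)
  dt <- 1 / frame_rate
  alpha <- dt / (worms$sensory_timescale_s + dt)

  set.seed(seed)
  x <- rep(start_xy[1], n_worms)
  y <- rep(start_xy[2], n_worms)
  heading <- stats::runif(n_worms, 0, 2 * pi)
  dcdt_hat <- numeric(n_worms)
  c_prev <- conc_at(x, y)

  xs <- matrix(NA_real_, nrow = n_frames, ncol = n_worms)
  ys <- matrix(NA_real_, nrow = n_frames, ncol = n_worms)
  xs[1, ] <- x; ys[1, ] <- y
  for (f in seq_len(n_frames - 1L)) {
    heading <- heading + stats::rnorm(n_worms, 0,
                                      worms$heading_noise * sqrt(dt))
    x <- x + worms$speed_mm_s * dt * cos(heading)
    y <- y + worms$speed_mm_s * dt * sin(heading)
    refl <- reflect_at_wall(x, y, heading, radius_mm)
    x <- refl$x; y <- refl$y; heading <- refl$heading
    conc <- conc_at(x, y)
    dcdt_hat <- dcdt_hat + alpha * ((conc - c_prev) / dt - dcdt_hat)
    c_prev <- conc
    p_pir <- pmin(worms$pirouette_rate * dt *
                    pmax(0, 1 - worms$beta * dcdt_hat), 1)
    pir <- stats::runif(n_worms) < p_pir
    if (any(pir)) heading[pir] <- stats::runif(sum(pir), 0, 2 * pi)
    xs[f + 1L, ] <- x
    ys[f + 1L, ] <- y
  }

  detected <- matrix(TRUE, nrow = n_frames, ncol = n_worms)
  for (w in seq_len(n_worms)) {
    f <- 1L
    while (f <= n_frames) {
      if (stats::runif(1) < gap_prob) {
        len <- stats::rgeom(1, 1 / mean_gap_frames) + 1L
        detected[f:min(f + len - 1L, n_frames), w] <- FALSE
        f <- f + len
      } else {
        f <- f + 1L
      }
    }
  }

  frames <- seq_len(n_frames) - 1L
  out <- purrr::map_dfr(seq_len(n_worms), function(w) {
    det <- detected[, w]
    id <- if (split_on_redetect) {
      bout <- cumsum(det & !dplyr::lag(det, default = TRUE)) + 1L
      sprintf("worm_%03d_%02d", w, bout)
    } else {
      sprintf("worm_%03d", w)
    }
    tibble::tibble(
      track_id = id,
      frame = frames,
      time_s = frames / frame_rate,
      x_mm = ifelse(det, xs[, w], NA_real_),
      y_mm = ifelse(det, ys[, w], NA_real_),
      detected = det
    )
  })
  out <- dplyr::arrange(out, .data$track_id, .data$frame)
  attr(out, "peak_mm") <- attr(field, "peak_mm")
  out
}
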