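#' Count thrashes in a bend-angle series
#'
#' A thrash is one reversal of the direction of the worm's midbody bend.
#' The counter registers a reversal each time the angle, having moved at
#' least `hysteresis_rad` away from the running extremum in one direction,
#' turns back — the computational analogue of an observer counting each
#' flex to one side, with the hysteresis gate suppressing noise-driven
#' micro-reversals.
#'
#' @param series A bend series: tibble with `time_s` and `bend_rad`
#'   (e.g. from [simulate_bend_series()]).
#' @param hysteresis_rad Minimum excursion (rad) from the running extremum
#'   before a direction change counts. Default 10 degrees.
#' @return A one-row tibble: `n_thrashes`, `duration_s`, `rate_per_min`
#'   (count normalized to the 1-minute scoring window).
#' @examples
#' count_thrashes(simulate_bend_series(1, noise_sd = 0, duration_s = 60))
#' @export
count_thrashes <- function(series, hysteresis_rad = 10 * pi / 180) {
  if (hysteresis_rad < 0) stop("hysteresis_rad must be >= 0", call. = FALSE)
  stopifnot(is.data.frame(series), nrow(series) > 0,
            all(c("time_s", "bend_rad") %in% names(series)))
  x <- series$bend_rad
  if (any(!is.finite(x))) stop("bend series must be finite", call. = FALSE)
  count <- 0L
  direction <- 0L       # 0 = not yet established, +1 rising, -1 falling
  extremum <- x[1]
  lo <- x[1]; hi <- x[1]
  for (v in x[-1]) {
    if (direction == 0L) {
      lo <- min(lo, v); hi <- max(hi, v)
      if (v - lo >= hysteresis_rad) {
        direction <- 1L; extremum <- v
      } else if (hi - v >= hysteresis_rad) {
        direction <- -1L; extremum <- v
      }
    } else if (direction == 1L) {
      if (v > extremum) {
        extremum <- v
      } else if (extremum - v >= hysteresis_rad) {
        count <- count + 1L; direction <- -1L; extremum <- v
      }
    } else {
      if (v < extremum) {
        extremum <- v
      } else if (v - extremum >= hysteresis_rad) {
        count <- count + 1L; direction <- 1L; extremum <- v
      }
    }
  }
  dt <- stats::median(diff(series$time_s))
  duration_s <- max(series$time_s) - min(series$time_s) + dt
  tibble::tibble(n_thrashes = count, duration_s = duration_s,
                 rate_per_min = count * 60 / duration_s)
}

# Grid-cell indices (i, j) traversed by the segment p0 -> p1, in traversal
# order. Cells are squares of side `s` with corners on origin + k*s.
segment_cells <- function(p0, p1, s, origin) {
  crossings <- function(a0, a1, o) {
    if (a0 == a1) return(numeric(0))
    lo <- ceiling((min(a0, a1) - o) / s)
    hi <- floor((max(a0, a1) - o) / s)
    if (lo > hi) return(numeric(0))
    t <- (o + (lo:hi) * s - a0) / (a1 - a0)
    t[t > 0 & t < 1]
  }
  tx <- crossings(p0[1], p1[1], origin[1])
  ty <- crossings(p0[2], p1[2], origin[2])
  t <- sort(unique(c(0, tx, ty, 1)))
  mid <- (t[-length(t)] + t[-1]) / 2
  xm <- p0[1] + mid * (p1[1] - p0[1])
  ym <- p0[2] + mid * (p1[2] - p0[2])
  cbind(floor((xm - origin[1]) / s), floor((ym - origin[2]) / s))
}

#' Count grid squares traversed by a track
#'
#' Scores roaming the way a gridded plate overlay is scored: the number
#' of distinct 3 x 3 mm squares the worm's path enters. Consecutive
#' recorded positions are joined by straight segments, and every cell a
#' segment passes through is credited, so coarse sampling does not skip
#' cells. `count = "crossings"` instead returns the number of cell
#' boundary crossings along the path.
#'
#' @param track A single-worm track tibble (`x_mm`, `y_mm`, `detected`).
#' @param square_mm Grid square side in mm (default 3).
#' @param origin_mm Position of a grid corner, mm (default the plate
#'   center; any offset re-anchors the overlay).
#' @param count `"squares"` (distinct cells, default) or `"crossings"`.
#' @return An integer count.
#' @examples
#' tr <- tibble::tibble(x_mm = c(1.5, 31.5), y_mm = 1.5, detected = TRUE)
#' roaming_squares(tr)  # 30 mm straight path from a cell center: 11
#' @export
roaming_squares <- function(track, square_mm = 3, origin_mm = c(0, 0),
                            count = c("squares", "crossings")) {
  count <- match.arg(count)
  if (square_mm <= 0) stop("square_mm must be > 0", call. = FALSE)
  pts <- track
  if ("detected" %in% names(pts)) pts <- dplyr::filter(pts, .data$detected)
  if (nrow(pts) == 0) stop("track has no detected positions", call. = FALSE)
  p <- cbind(pts$x_mm, pts$y_mm)
  cells <- matrix(floor((p[1, ] - origin_mm) / square_mm), ncol = 2)
  if (nrow(p) > 1) {
    for (k in seq_len(nrow(p) - 1)) {
      cells <- rbind(cells,
                     segment_cells(p[k, ], p[k + 1, ], square_mm, origin_mm))
    }
  }
  if (count == "squares") {
    nrow(unique(cells))
  } else {
    changed <- rowSums(abs(diff(cells))) > 0
    sum(changed)
  }
}

#' Per-frame lawn-aversion ratio
#'
#' The aversion ratio at a frame is the number of worms outside the
#' bacterial lawn divided by the total number of worms on the plate.
#'
#' @param occupancy A long occupancy table: tibble with `frame`, `worm`,
#'   `outside` (logical), one row per worm per frame (e.g. from
#'   [simulate_lawn_occupancy()]).
#' @return A tibble with `frame`, `n_outside`, `n_total`, `ratio`.
#' @export
aversion_ratio <- function(occupancy) {
  stopifnot(is.data.frame(occupancy),
            all(c("frame", "worm", "outside") %in% names(occupancy)))
  if (nrow(occupancy) == 0) stop("occupancy table is empty", call. = FALSE)
  per <- dplyr::summarise(dplyr::group_by(occupancy, .data$frame),
                          n_outside = sum(.data$outside),
                          n_total = dplyr::n(), .groups = "drop")
  if (length(unique(per$n_total)) != 1)
    stop("worm count must be constant across frames", call. = FALSE)
  if (per$n_total[1] == 0) stop("zero worms", call. = FALSE)
  dplyr::mutate(per, ratio = .data$n_outside / .data$n_total)
}

#' Scalar aversion summary for a plate
#'
#' Reduces the per-frame ratio series to one number per plate: the
#' time-average over the full recording (default) or the final-frame
#' ratio.
#'
#' @inheritParams aversion_ratio
#' @param method `"mean"` (time-average, default) or `"final"`.
#' @return A single ratio in \[0, 1\].
#' @export
aversion_summary <- function(occupancy, method = c("mean", "final")) {
  method <- match.arg(method)
  per <- aversion_ratio(occupancy)
  if (method == "mean") mean(per$ratio) else per$ratio[which.max(per$frame)]
}
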