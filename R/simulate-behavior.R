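#' Simulate a midbody bend-angle series
#'
#' Produces the signal scored in a thrashing assay: a sinusoidal midbody
#' bend angle (one full swimming cycle gives two direction reversals,
#' i.e. two thrashes) with optional additive Gaussian noise.
#'
#' @param frequency_hz Swimming cycle frequency in Hz (>= 0; 0 gives a
#'   constant series).
#' @param noise_sd SD of additive Gaussian angle noise, rad.
#' @param duration_s Recording length in seconds (default 60, the scoring
#'   window of the assay).
#' @param sample_rate Samples per second.
#' @param amplitude Bend amplitude in rad (default 0.7, about 40 degrees).
#' @param seed Integer seed, used only when `noise_sd > 0`.
#' @return A tibble with columns `time_s` and `bend_rad`.
#' @examples
#' simulate_bend_series(1, noise_sd = 0, duration_s = 2, sample_rate = 10)
#' @export
simulate_bend_series <- function(frequency_hz, noise_sd = 0,
                                 duration_s = 60, sample_rate = 30,
                                 amplitude = 0.7, seed = 1L) {
  if (frequency_hz < 0) stop("frequency_hz must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  n <- round(duration_s * sample_rate)
  t <- (seq_len(n) - 1L) / sample_rate
  bend <- amplitude * sin(2 * pi * frequency_hz * t)
  if (noise_sd > 0) {
    set.seed(seed)
    bend <- bend + stats::rnorm(n, 0, noise_sd)
  }
  tibble::tibble(time_s = t, bend_rad = bend)
}

#' Simulate a roaming-assay track
#'
#' Emulates the 16-hour single-worm excursion scored by the roaming assay.
#' `"roamer"` mode produces persistent, nearly ballistic motion that
#' sweeps many grid squares; `"dweller"` mode produces localized motion
#' around the release point (step 0 keeps the worm exactly there).
#'
#' @param mode `"roamer"` or `"dweller"`.
#' @param duration_h Track duration in hours (default 16).
#' @param frame_interval_s Seconds between recorded positions.
#' @param step_mm Distance moved per frame. Defaults: 1.5 (roamer),
#'   0.15 (dweller).
#' @param turn_sd Heading noise per frame in rad (roamer mode).
#' @param plate_radius_mm Plate radius; motion reflects at the wall.
#' @param start_xy Release point in mm.
#' @param seed Integer seed.
#' @return A track tibble (`track_id`, `frame`, `time_s`, `x_mm`, `y_mm`,
#'   `detected`).
#' @export
simulate_roaming_track <- function(mode = c("roamer", "dweller"),
                                   duration_h = 16,
                                   frame_interval_s = 60,
                                   step_mm = NULL,
                                   turn_sd = 0.35,
                                   plate_radius_mm = 25,
                                   start_xy = c(0, 0),
                                   seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(step_mm)) step_mm <- if (mode == "roamer") 1.5 else 0.15
  if (step_mm < 0) stop("step_mm must be >= 0", call. = FALSE)
  n <- round(duration_h * 3600 / frame_interval_s)
  set.seed(seed)
  x <- numeric(n); y <- numeric(n)
  x[1] <- start_xy[1]; y[1] <- start_xy[2]
  if (mode == "roamer") {
    heading <- stats::runif(1, 0, 2 * pi)
    for (f in 2:n) {
      heading <- heading + stats::rnorm(1, 0, turn_sd)
      xn <- x[f - 1] + step_mm * cos(heading)
      yn <- y[f - 1] + step_mm * sin(heading)
      refl <- reflect_at_wall(xn, yn, heading, plate_radius_mm)
      x[f] <- refl$x; y[f] <- refl$y; heading <- refl$heading
    }
  } else {
    # mean-reverting wander around the release point
    for (f in 2:n) {
      x[f] <- start_xy[1] + 0.8 * (x[f - 1] - start_xy[1]) +
        step_mm * stats::rnorm(1)
      y[f] <- start_xy[2] + 0.8 * (y[f - 1] - start_xy[2]) +
        step_mm * stats::rnorm(1)
    }
  }
  tibble::tibble(
    track_id = paste0(mode, "_01"),
    frame = seq_len(n) - 1L,
    time_s = (seq_len(n) - 1L) * frame_interval_s,
    x_mm = x, y_mm = y,
    detected = TRUE
  )
}

#' Simulate a lawn-occupancy recording
#'
#' Emulates the aversion assay: a cohort of worms on a seeded plate,
#' recorded at 1 frame per minute for 20 hours, each worm switching
#' between inside-lawn and outside-lawn states as a two-state Markov
#' chain.
#'
#' @param n_worms Number of worms on the plate.
#' @param leave_prob Per-frame probability an inside worm leaves the lawn.
#' @param return_prob Per-frame probability an outside worm returns.
#' @param duration_h Recording length in hours (default 20).
#' @param frames_per_min Recording rate (default 1).
#' @param start_outside Logical (recycled): initial state per worm.
#' @param seed Integer seed.
#' @return A tibble with columns `frame`, `worm`, `outside` (logical),
#'   one row per worm per frame.
#' @export
simulate_lawn_occupancy <- function(n_worms = 15,
                                    leave_prob = 0.01,
                                    return_prob = 0.08,
                                    duration_h = 20,
                                    frames_per_min = 1,
                                    start_outside = FALSE,
                                    seed = 1L) {
  if (leave_prob < 0 || leave_prob > 1 || return_prob < 0 || return_prob > 1)
    stop("leave_prob and return_prob must be probabilities", call. = FALSE)
  n_frames <- round(duration_h * 60 * frames_per_min)
  set.seed(seed)
  state <- rep_len(start_outside, n_worms)
  out <- matrix(FALSE, nrow = n_frames, ncol = n_worms)
  out[1, ] <- state
  for (f in 2:n_frames) {
    u <- stats::runif(n_worms)
    state <- ifelse(state, u >= return_prob, u < leave_prob)
    out[f, ] <- state
  }
  tibble::tibble(
    frame = rep(seq_len(n_frames) - 1L, times = n_worms),
    worm = rep(sprintf("worm_%02d", seq_len(n_worms)), each = n_frames),
    outside = as.vector(out)
  )
}

#' Simulate a per-neuron expression table
#'
#' Builds an expression table for the co-transmission mapper: each neuron
#' carries the set of neurotransmission loci it expresses. Loci are drawn
#' independently per neuron with probability `expr_prob`, except for
#' neurons named in `assign`, whose expressed sets are taken verbatim
#' (overriding the random draw entirely).
#'
#' @param neurons A data frame with columns `neuron`, `class`, `category`,
#'   `region` (see [neuron_roster()] for the expected vocabularies).
#' @param loci Character vector of locus identifiers.
#' @param expr_prob Scalar or per-locus named vector of expression
#'   probabilities in \[0, 1\].
#' @param assign Named list: neuron name -> character vector of loci that
#'   neuron expresses, honored exactly.
#' @param seed Integer seed.
#' @return An expression table: the input columns plus a list-column
#'   `loci`.
#' @examples
#' ns <- tibble::tibble(neuron = c("A", "B"), class = c("A", "B"),
#'                      category = "sensory", region = "head")
#' simulate_expression_table(ns, loci = c("unc-17", "eat-4"),
#'                           assign = list(A = c("unc-17", "eat-4")))
#' @export
simulate_expression_table <- function(neurons,
                                      loci,
                                      expr_prob = 0.2,
                                      assign = list(),
                                      seed = 1L) {
  stopifnot(is.data.frame(neurons),
            all(c("neuron", "class", "category", "region") %in%
                  names(neurons)))
  p <- if (length(expr_prob) == 1) stats::setNames(rep(expr_prob,
                                                       length(loci)), loci)
       else expr_prob[loci]
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("expr_prob must give a probability for every locus", call. = FALSE)
  unknown <- setdiff(unlist(assign), loci)
  if (length(unknown) > 0)
    stop("assign references loci outside `loci`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  set.seed(seed)
  expressed <- purrr::map(neurons$neuron, function(nm) {
    if (nm %in% names(assign)) return(as.character(assign[[nm]]))
    loci[stats::runif(length(loci)) < p]
  })
  out <- tibble::as_tibble(neurons)
  out$loci <- expressed
  out
}
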