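#' Assay geometry for the chemotaxis outcome
#'
#' Fixes the reference frame of a chemotaxis assay: where the salt peak
#' and the worm drop point sit, how long the assay ran, the acquisition
#' rate, and the length of the scoring window at the end of the assay.
#'
#' @param peak_mm Salt-peak position, mm, length 2. Default `c(12.5, 0)`:
#'   12.5 mm from the center of a 50 mm plate.
#' @param start_mm Worm drop point, mm (the plate center by default).
#' @param duration_s Assay duration in seconds (default 420 = 7 min).
#' @param frame_rate Frames per second (default 3.75).
#' @param window_s Length of the terminal scoring window in seconds
#'   (default 60: the final minute). Must not exceed the duration.
#' @return A list of class `assay_geometry`.
#' @export
assay_geometry <- function(peak_mm = c(12.5, 0),
                           start_mm = c(0, 0),
                           duration_s = 420,
                           frame_rate = 3.75,
                           window_s = 60) {
  if (window_s > duration_s)
    stop("window_s must not exceed duration_s", call. = FALSE)
  if (window_s <= 0 || duration_s <= 0 || frame_rate <= 0)
    stop("durations and frame_rate must be positive", call. = FALSE)
  structure(list(peak_mm = peak_mm, start_mm = start_mm,
                 duration_s = duration_s, frame_rate = frame_rate,
                 window_s = window_s),
            class = "assay_geometry")
}

#' Read a tracker-exported position table
#'
#' Reads the CSV dialect emitted by plate trackers: one row per
#' (track, frame) with x/y coordinates. Rows whose coordinates cannot be
#' parsed (blank, non-numeric) are kept but marked undetected — they are
#' the detection gaps that [impute_carry_forward()] later fills. Row
#' order is normalized to (track_id, frame).
#'
#' @param file Path to the CSV file.
#' @param columns Named character vector mapping the canonical names
#'   `track_id`, `frame`, `time_s`, `x_mm`, `y_mm` to the header names in
#'   the file. `time_s` may be omitted, in which case it is derived from
#'   the frame index and `frame_rate`.
#' @param frame_rate Frames per second, used only to reconstruct `time_s`
#'   when the file has no time column.
#' @return A track tibble with columns `track_id`, `frame`, `time_s`,
#'   `x_mm`, `y_mm`, `detected`.
#' @export
parse_tracks <- function(file,
                         columns = c(track_id = "track_id", frame = "frame",
                                     time_s = "time_s", x_mm = "x_mm",
                                     y_mm = "y_mm"),
                         frame_rate = 3.75) {
  raw <- readr::read_csv(file, col_types = readr::cols(
    .default = readr::col_character()))
  required <- c("track_id", "frame", "x_mm", "y_mm")
  missing_map <- setdiff(required, names(columns))
  if (length(missing_map) > 0)
    stop("column map must name: ", paste(missing_map, collapse = ", "),
         call. = FALSE)
  missing_cols <- setdiff(unname(columns[required]), names(raw))
  if (length(missing_cols) > 0)
    stop("input file lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  x <- suppressWarnings(as.numeric(raw[[columns[["x_mm"]]]]))
  y <- suppressWarnings(as.numeric(raw[[columns[["y_mm"]]]]))
  det <- is.finite(x) & is.finite(y)
  frame <- suppressWarnings(as.integer(raw[[columns[["frame"]]]]))
  if (any(is.na(frame)))
    stop("frame column contains unparseable values", call. = FALSE)
  time_s <- if ("time_s" %in% names(columns) &&
                columns[["time_s"]] %in% names(raw)) {
    suppressWarnings(as.numeric(raw[[columns[["time_s"]]]]))
  } else {
    frame / frame_rate
  }
  out <- tibble::tibble(
    track_id = raw[[columns[["track_id"]]]],
    frame = frame,
    time_s = time_s,
    x_mm = ifelse(det, x, NA_real_),
    y_mm = ifelse(det, y, NA_real_),
    detected = det
  )
  dup <- dplyr::count(out, .data$track_id, .data$frame) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate (track_id, frame) pairs: ",
         paste(utils::head(paste0(dup$track_id, "@", dup$frame), 5),
               collapse = ", "), call. = FALSE)
  }
  dplyr::arrange(out, .data$track_id, .data$frame)
}

#' Write a track table in the tracker CSV dialect
#'
#' Inverse of [parse_tracks()]: undetected frames are written with blank
#' coordinates, so a write/parse round trip is the identity.
#'
#' @param tracks A track tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_tracks <- function(tracks, file) {
  out <- dplyr::mutate(
    tracks,
    x_mm = ifelse(.data$detected, as.character(.data$x_mm), ""),
    y_mm = ifelse(.data$detected, as.character(.data$y_mm), "")
  )
  readr::write_csv(dplyr::select(out, "track_id", "frame", "time_s",
                                 "x_mm", "y_mm"), file, na = "")
  invisible(file)
}

#' Carry-forward imputation of detection gaps
#'
#' Fills detection gaps in a single track by repeating the last observed
#' position until the worm is re-detected — the rule used when a worm
#' exits the camera field or two worms intersect. Frames before the first
#' detection are excluded (never back-filled); a terminal gap carries the
#' last observed position to the end of the frame range.
#'
#' @param track Rows of a single track (tibble with `frame`, `time_s`,
#'   `x_mm`, `y_mm`, `detected`).
#' @param frames Integer frame range to cover (default: the track's first
#'   frame through its last).
#' @param frame_rate Frames per second, used to assign times to frames the
#'   track table does not contain.
#' @return A gap-free tibble over `frames` (from the first detection on)
#'   with columns `frame`, `time_s`, `x_mm`, `y_mm`, `imputed`.
#' @examples
#' tr <- tibble::tibble(frame = c(0L, 3L), time_s = c(0, 0.8),
#'                      x_mm = c(0, 3), y_mm = 0, detected = TRUE)
#' impute_carry_forward(tr, frames = 0:3)
#' @export
impute_carry_forward <- function(track, frames = NULL, frame_rate = 3.75) {
  det <- dplyr::filter(track, .data$detected)
  if (nrow(det) == 0) {
    warning("track has no detected frames; nothing to impute",
            call. = FALSE)
    return(tibble::tibble(frame = integer(), time_s = numeric(),
                          x_mm = numeric(), y_mm = numeric(),
                          imputed = logical()))
  }
  if (is.null(frames)) frames <- seq(min(track$frame), max(track$frame))
  frames <- frames[frames >= min(det$frame)]  # never back-fill
  grid <- tibble::tibble(frame = as.integer(frames))
  out <- dplyr::left_join(grid,
                          dplyr::select(det, "frame", "time_s",
                                        "x_mm", "y_mm"),
                          by = "frame")
  out$imputed <- is.na(out$x_mm)
  out <- tidyr::fill(out, "x_mm", "y_mm", .direction = "down")
  out$time_s <- ifelse(is.na(out$time_s), out$frame / frame_rate,
                       out$time_s)
  out
}

#' Chemotaxis outcome for one worm
#'
#' The assay outcome: the worm's mean Euclidean distance from the salt
#' peak, averaged over every frame of the final scoring window (the last
#' minute by default), with detection gaps filled by carry-forward
#' imputation. A worm last seen before the window still contributes,
#' through the terminal carry-forward of its last observed position.
#'
#' @param track Rows of a single track.
#' @param geometry An [assay_geometry()].
#' @return A one-row tibble: `track_id`, `mean_distance_mm`,
#'   `n_frames_in_window`, `n_imputed_frames`; or a zero-row tibble (with
#'   a warning) when the track has no frame at or before the window end.
#' @export
worm_outcome <- function(track, geometry = assay_geometry()) {
  id <- if (nrow(track) > 0 && "track_id" %in% names(track))
    track$track_id[1] else NA_character_
  n_frames <- round(geometry$duration_s * geometry$frame_rate)
  last_frame <- n_frames - 1L
  # closed window [duration - window_s, duration] mapped to frame indices
  first_window_frame <- ceiling((geometry$duration_s - geometry$window_s) *
                                  geometry$frame_rate)
  imp <- withCallingHandlers(
    impute_carry_forward(track, frames = 0:last_frame,
                         frame_rate = geometry$frame_rate),
    warning = function(w) invokeRestart("muffleWarning")
  )
  win <- dplyr::filter(imp, .data$frame >= first_window_frame)
  if (nrow(win) == 0) {
    warning("track ", id, " has no observed or imputable frame in the ",
            "scoring window; excluded", call. = FALSE)
    return(tibble::tibble(track_id = character(),
                          mean_distance_mm = numeric(),
                          n_frames_in_window = integer(),
                          n_imputed_frames = integer()))
  }
  d <- sqrt((win$x_mm - geometry$peak_mm[1])^2 +
              (win$y_mm - geometry$peak_mm[2])^2)
  tibble::tibble(
    track_id = id,
    mean_distance_mm = mean(d),
    n_frames_in_window = nrow(win),
    n_imputed_frames = sum(win$imputed)
  )
}

#' Per-plate chemotaxis summary
#'
#' Applies [worm_outcome()] to every track on a plate and aggregates:
#' each retained worm contributes one (equally weighted) mean distance.
#' Tracks with no usable frame in the scoring window are dropped and
#' counted.
#'
#' @param tracks A track tibble (multiple tracks).
#' @param geometry An [assay_geometry()].
#' @return A list with `worms` (one [worm_outcome()] row per retained
#'   track) and `plate` (one row: `n_worms`, `n_excluded`,
#'   `mean_distance_mm`, `sd_distance_mm`).
#' @export
plate_summary <- function(tracks, geometry = assay_geometry()) {
  if (nrow(tracks) == 0) {
    warning("empty track table", call. = FALSE)
    worms <- tibble::tibble(track_id = character(),
                            mean_distance_mm = numeric(),
                            n_frames_in_window = integer(),
                            n_imputed_frames = integer())
    return(list(worms = worms,
                plate = tibble::tibble(n_worms = 0L, n_excluded = 0L,
                                       mean_distance_mm = NA_real_,
                                       sd_distance_mm = NA_real_)))
  }
  ids <- unique(tracks$track_id)
  worms <- purrr::map_dfr(ids, function(id) {
    suppressWarnings(
      worm_outcome(dplyr::filter(tracks, .data$track_id == id), geometry))
  })
  list(
    worms = worms,
    plate = tibble::tibble(
      n_worms = nrow(worms),
      n_excluded = length(ids) - nrow(worms),
      mean_distance_mm = mean(worms$mean_distance_mm),
      sd_distance_mm = stats::sd(worms$mean_distance_mm)
    )
  )
}

#' Plot chemotaxis tracks
#'
#' @param tracks A track tibble.
#' @param geometry An [assay_geometry()]; the peak and start are marked.
#' @return A ggplot of track paths (detected frames only).
#' @export
plot_tracks <- function(tracks, geometry = assay_geometry()) {
  ggplot2::ggplot(dplyr::filter(tracks, .data$detected),
                  ggplot2::aes(.data$x_mm, .data$y_mm,
                               group = .data$track_id,
                               colour = .data$track_id)) +
    ggplot2::geom_path(alpha = 0.7, show.legend = FALSE) +
    ggplot2::annotate("point", x = geometry$peak_mm[1],
                      y = geometry$peak_mm[2], shape = 3, size = 3) +
    ggplot2::annotate("point", x = geometry$start_mm[1],
                      y = geometry$start_mm[2], shape = 1, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}
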