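# Independent brute-force oracles used across the suite.

# Chemotaxis outcome by explicit frame loop: for every assay frame, the
# worm's position is the most recent detected position at or before that
# frame; the outcome is the mean distance to the peak over window frames
# that have a position.
oracle_worm_outcome <- function(track, geometry) {
  n_frames <- round(geometry$duration_s * geometry$frame_rate)
  w0 <- ceiling((geometry$duration_s - geometry$window_s) *
                  geometry$frame_rate)
  det <- track[track$detected, , drop = FALSE]
  det <- det[order(det$frame), , drop = FALSE]
  if (nrow(det) == 0) return(NA_real_)
  dists <- c()
  for (f in w0:(n_frames - 1L)) {
    k <- which(det$frame <= f)
    if (length(k) == 0) next
    k <- max(k)
    dists <- c(dists, sqrt((det$x_mm[k] - geometry$peak_mm[1])^2 +
                             (det$y_mm[k] - geometry$peak_mm[2])^2))
  }
  if (length(dists) == 0) return(NA_real_)
  mean(dists)
}

# Random small track table (detection gaps included) for oracle tests.
random_track_table <- function(n_tracks, n_frames, frame_rate = 1) {
  do.call(rbind, lapply(seq_len(n_tracks), function(i) {
    det <- stats::runif(n_frames) > 0.3
    if (!any(det)) det[sample(n_frames, 1)] <- TRUE
    tibble::tibble(
      track_id = sprintf("t%02d", i),
      frame = seq_len(n_frames) - 1L,
      time_s = (seq_len(n_frames) - 1L) / frame_rate,
      x_mm = ifelse(det, stats::runif(n_frames, -20, 20), NA_real_),
      y_mm = ifelse(det, stats::runif(n_frames, -20, 20), NA_real_),
      detected = det
    )
  }))
}

# Exact two-sided Mann-Whitney p by a second, independent derivation:
# U counted pairwise (ties worth 1/2) for every subset assignment.
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  N <- length(pooled)
  u_pairs <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_pairs(x, y)
  mu <- n1 * (N - n1) / 2
  subsets <- utils::combn(N, n1)
  u_all <- apply(subsets, 2, function(idx)
    u_pairs(pooled[idx], pooled[-idx]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Union-of-crosses co-transmission count by explicit double loop.
oracle_cotx_count <- function(table, crosses) {
  loci <- if (is.list(table$loci)) table$loci else
    strsplit(as.character(table$loci), ";", fixed = TRUE)
  hit <- rep(FALSE, nrow(table))
  for (k in seq_len(nrow(crosses))) {
    for (i in seq_len(nrow(table))) {
      if (crosses$driver_locus[k] %in% loci[[i]] &&
          crosses$reporter_locus[k] %in% loci[[i]]) hit[i] <- TRUE
    }
  }
  sum(hit)
}

# Small helper: stationary single-worm track at a fixed point.
stationary_track <- function(x, y, n_frames, frame_rate = 3.75,
                             id = "w1") {
  tibble::tibble(
    track_id = id,
    frame = seq_len(n_frames) - 1L,
    time_s = (seq_len(n_frames) - 1L) / frame_rate,
    x_mm = x, y_mm = y, detected = TRUE
  )
}
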