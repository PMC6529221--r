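# Four-quadrant optogenetic assay metrics: quadrant assignment, the preference
# index PI = (flies in Q2+Q3 - flies in Q1+Q4) / total, the single-value PI
# over the final 5 s of each light-ON epoch, normalised locomotion deltas, and
# Flybowl whole-field locomotion.
#
# Quadrant layout: angular sectors around the arena centre, with Q2/Q3 one
# diagonal (opposing) pair and Q1/Q4 the other, so the PI sign convention works
# out to positive = more flies in the Q2+Q3 pair. Counter-clockwise from the
# positive x axis the sectors are Q1 [0,90), Q2 [90,180), Q4 [180,270),
# Q3 [270,360) degrees.

#' Arena geometry for the quadrant assay
#'
#' @param diameter_mm Arena diameter (100 mm for the standard choice chamber).
#' @param centre Arena centre in mm, length 2.
#' @return List of class `lh_arena`.
#' @export
quadrant_arena <- function(diameter_mm = 100, centre = c(0, 0)) {
  stopifnot(diameter_mm > 0, length(centre) == 2)
  structure(list(diameter_mm = diameter_mm, centre = as.numeric(centre)),
            class = "lh_arena")
}

# sector order counter-clockwise from angle 0
.sector_labels <- c("Q1", "Q2", "Q4", "Q3")

#' Assign arena positions to quadrants
#'
#' Vectorised over positions. Points exactly on a boundary ray go to the
#' lower-indexed adjacent quadrant; the arena centre itself goes to Q1
#' (both documented tie-breaks). Points outside the arena are an error.
#'
#' @param x,y Positions in mm.
#' @param arena A [quadrant_arena()].
#' @return Character vector of `"Q1"`..`"Q4"`.
#' @export
assign_quadrant <- function(x, y, arena = quadrant_arena()) {
  stopifnot(inherits(arena, "lh_arena"))
  dx <- x - arena$centre[1]; dy <- y - arena$centre[2]
  r <- sqrt(dx^2 + dy^2)
  if (any(r > arena$diameter_mm / 2 + 1e-9)) {
    stop("position(s) outside the arena", call. = FALSE)
  }
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  sector <- pmin(floor(ang / 90), 3) + 1L
  lab <- .sector_labels[sector]
  on_boundary <- (ang %% 90) < 1e-9
  if (any(on_boundary)) {
    prev <- .sector_labels[((sector - 2L) %% 4L) + 1L]
    lab[on_boundary] <- pmin(lab[on_boundary], prev[on_boundary])
  }
  lab[r < 1e-9] <- "Q1"
  lab
}

validate_schedule <- function(schedule) {
  need <- c("start_s", "end_s", "state")
  if (!all(need %in% names(schedule))) {
    stop("schedule needs columns start_s, end_s, state", call. = FALSE)
  }
  if (any(schedule$end_s <= schedule$start_s)) {
    stop("schedule epochs must have end_s > start_s", call. = FALSE)
  }
  s <- schedule[order(schedule$start_s), ]
  if (nrow(s) > 1 && any(s$start_s[-1] < s$end_s[-nrow(s)] - 1e-9)) {
    stop("schedule epochs overlap", call. = FALSE)
  }
  invisible(schedule)
}

#' Standard quadrant-assay stimulation schedule
#'
#' The two-minute trial: 30 s acclimatisation (lights off), 30 s illumination
#' of one opposing quadrant pair, 30 s off, 30 s illumination of the other
#' pair.
#'
#' @param acclimatise_s,on_s,off_s Epoch lengths in seconds.
#' @param first_pair,second_pair Illuminated quadrant pairs, comma-separated.
#' @param intensity_uW_mm2 LED intensity.
#' @return Tibble with columns `start_s`, `end_s`, `state`, `quadrants`,
#'   `intensity_uW_mm2`.
#' @export
quadrant_schedule <- function(acclimatise_s = 30, on_s = 30, off_s = 30,
                              first_pair = "Q2,Q3", second_pair = "Q1,Q4",
                              intensity_uW_mm2 = 25.2) {
  t1 <- acclimatise_s; t2 <- t1 + on_s; t3 <- t2 + off_s; t4 <- t3 + on_s
  out <- tibble::tibble(
    start_s = c(0, t1, t2, t3),
    end_s = c(t1, t2, t3, t4),
    state = c("off", "on", "off", "on"),
    quadrants = c(NA, first_pair, NA, second_pair),
    intensity_uW_mm2 = c(0, intensity_uW_mm2, 0, intensity_uW_mm2))
  validate_schedule(out)
}

#' Flybowl whole-field stimulation schedule
#'
#' 30 s acclimatisation followed by three 5 s whole-field illuminations of
#' increasing intensity with recovery gaps.
#'
#' @param acclimatise_s,on_s,gap_s Epoch lengths in seconds.
#' @param intensities_uW_mm2 The three intensities, weakest first
#'   (3.59, 11.88, 25.2 by default).
#' @return Schedule tibble as in [quadrant_schedule()], with
#'   `quadrants = "whole_field"` for ON epochs.
#' @export
flybowl_schedule <- function(acclimatise_s = 30, on_s = 5, gap_s = 30,
                             intensities_uW_mm2 = c(3.59, 11.88, 25.2)) {
  starts <- acclimatise_s + (seq_along(intensities_uW_mm2) - 1) * (on_s + gap_s)
  rows <- list(tibble::tibble(start_s = 0, end_s = acclimatise_s,
                              state = "off", quadrants = NA_character_,
                              intensity_uW_mm2 = 0))
  for (i in seq_along(starts)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      start_s = starts[i], end_s = starts[i] + on_s, state = "on",
      quadrants = "whole_field", intensity_uW_mm2 = intensities_uW_mm2[i])
    rows[[length(rows) + 1]] <- tibble::tibble(
      start_s = starts[i] + on_s,
      end_s = starts[i] + on_s + if (i < length(starts)) gap_s else 10,
      state = "off", quadrants = NA_character_, intensity_uW_mm2 = 0)
  }
  validate_schedule(dplyr::bind_rows(rows))
}

schedule_on_epochs <- function(schedule) {
  schedule[schedule$state == "on", , drop = FALSE]
}

epoch_at <- function(time_s, schedule) {
  out <- rep(NA_integer_, length(time_s))
  for (i in seq_len(nrow(schedule))) {
    sel <- time_s >= schedule$start_s[i] & time_s < schedule$end_s[i]
    out[sel] <- i
  }
  out
}

#' Preference-index time series
#'
#' Per frame, `PI = (flies in Q2 and Q3 - flies in Q1 and Q4) / total`. With
#' `relabel_on = TRUE` (default) quadrant labels are normalised per light-ON
#' epoch so the illuminated pair maps to Q2/Q3 — both ON epochs then
#' contribute with a consistent sign and positive PI means attraction to
#' light. With `relabel_on = FALSE` the raw geometric labels are used
#' throughout.
#'
#' @param track Data frame with columns `time_s`, `fly_id`, `x_mm`, `y_mm`.
#' @param schedule Schedule tibble (see [quadrant_schedule()]).
#' @param arena A [quadrant_arena()].
#' @param relabel_on Normalise labels to the illuminated pair per ON epoch.
#' @return Tibble of class `lh_pi_series`: `time_s`, `pi`, `n_flies`, `state`.
#'   Frames with zero tracked flies get `pi = NA` and are flagged in the
#'   `dropped_frames` attribute.
#' @examples
#' sim <- generate_quadrant_trial(arena_design(n_flies = 20, bias = 0.5,
#'                                             seed = 7))
#' pi <- pi_timeseries(sim$track, sim$schedule)
#' single_value_pi(pi, sim$schedule)
#' @export
pi_timeseries <- function(track, schedule, arena = quadrant_arena(),
                          relabel_on = TRUE) {
  stopifnot(all(c("time_s", "fly_id", "x_mm", "y_mm") %in% names(track)))
  validate_schedule(schedule)
  q <- assign_quadrant(track$x_mm, track$y_mm, arena)
  ep <- epoch_at(track$time_s, schedule)
  lit <- rep(FALSE, nrow(track))
  in_pair23 <- q %in% c("Q2", "Q3")
  on_rows <- which(schedule$state == "on")
  counted_as_23 <- in_pair23
  for (i in on_rows) {
    pair <- strsplit(schedule$quadrants[i], ",")[[1]]
    sel <- !is.na(ep) & ep == i
    if (relabel_on && !identical(sort(pair), c("Q2", "Q3"))) {
      counted_as_23[sel] <- q[sel] %in% pair
    }
    lit[sel] <- q[sel] %in% pair
  }
  df <- tibble::tibble(time_s = track$time_s, counted = counted_as_23)
  agg <- dplyr::summarise(dplyr::group_by(df, .data$time_s),
                          n_flies = dplyr::n(),
                          pi = (sum(.data$counted) - sum(!.data$counted)) /
                            dplyr::n(), .groups = "drop")
  agg$state <- ifelse(is.na(epoch_at(agg$time_s, schedule)), "off",
                      schedule$state[epoch_at(agg$time_s, schedule)])
  out <- agg[, c("time_s", "pi", "n_flies", "state")]
  class(out) <- c("lh_pi_series", class(out))
  attr(out, "dropped_frames") <- numeric(0)
  out
}

#' Single-value preference index
#'
#' The mean PI over the final 5 s of each of the two light-ON epochs, the two
#' window means averaged with equal weight.
#'
#' @param series An `lh_pi_series` (or tibble with `time_s`, `pi`).
#' @param schedule Schedule tibble with exactly two ON epochs of at least
#'   `window_s` seconds.
#' @param window_s Window length, default 5 s.
#' @return A single number in \[-1, 1\].
#' @export
single_value_pi <- function(series, schedule, window_s = 5) {
  validate_schedule(schedule)
  on <- schedule_on_epochs(schedule)
  if (nrow(on) != 2) stop("schedule must contain exactly two ON epochs",
                          call. = FALSE)
  if (any(on$end_s - on$start_s < window_s)) {
    stop(sprintf("ON epoch shorter than the %g s window", window_s),
         call. = FALSE)
  }
  means <- vapply(seq_len(2), function(i) {
    sel <- series$time_s >= on$end_s[i] - window_s & series$time_s < on$end_s[i]
    mean(series$pi[sel], na.rm = TRUE)
  }, numeric(1))
  mean(means)
}

# millimetres per pixel of the tracking camera
PX_MM <- 0.12

# Per-fly locomotion metrics over a time window. Returns one row per fly.
window_metrics <- function(track, t0, t1, arena, min_disp_px = 0.5) {
  sel <- track$time_s >= t0 & track$time_s < t1
  win <- track[sel, , drop = FALSE]
  win <- win[order(win$fly_id, win$time_s), ]
  by_fly <- split(win, win$fly_id)
  rows <- lapply(by_fly, function(w) {
    dx <- diff(w$x_mm); dy <- diff(w$y_mm)
    dt <- diff(w$time_s)
    disp_px <- sqrt(dx^2 + dy^2) / PX_MM
    duration <- sum(dt)
    forward <- if (duration > 0) sum(disp_px) / duration else 0
    # heading from frame-to-frame displacement; sub-noise steps contribute 0
    moving <- disp_px >= min_disp_px
    heading <- atan2(dy, dx) * 180 / pi
    turn <- 0
    if (sum(moving) >= 2) {
      h <- heading[moving]
      dh <- abs(((diff(h) + 180) %% 360) - 180)
      turn <- sum(dh) / duration
    }
    dist_c <- mean(sqrt((w$x_mm - arena$centre[1])^2 +
                          (w$y_mm - arena$centre[2])^2) / PX_MM)
    tibble::tibble(fly_id = w$fly_id[1],
                   forward_px_s = forward, turning_deg_s = turn,
                   distance_from_center_px = dist_c,
                   n_frames = nrow(w))
  })
  dplyr::bind_rows(rows)
}

#' Normalised locomotion change under stimulation
#'
#' For each fly, the chosen metric is averaged over the 5 s window immediately
#' before light onset and over the first 5 s of the first ON epoch; the delta
#' is `(stim_mean - pre_mean) / pre_mean`. Only flies that stay inside the
#' illuminated quadrants for the full stimulation window are included; flies
#' with a zero pre-stimulation mean (delta undefined) are excluded with a
#' reason.
#'
#' @param track Track data frame (`time_s`, `fly_id`, `x_mm`, `y_mm`).
#' @param schedule Schedule tibble with at least one ON epoch of >= 5 s.
#' @param metric One of `"forward_px_s"`, `"turning_deg_s"`,
#'   `"distance_from_center_px"`.
#' @param arena A [quadrant_arena()].
#' @param window_s Analysis window, default 5 s.
#' @return Tibble with one row per fly: `fly_id`, `metric`, `pre_mean`,
#'   `stim_mean`, `delta`, `included`, `reason`.
#' @export
delta_metric <- function(track, schedule,
                         metric = c("forward_px_s", "turning_deg_s",
                                    "distance_from_center_px"),
                         arena = quadrant_arena(), window_s = 5) {
  metric <- match.arg(metric)
  validate_schedule(schedule)
  on <- schedule_on_epochs(schedule)
  if (nrow(on) == 0) stop("schedule has no ON epoch", call. = FALSE)
  if (on$end_s[1] - on$start_s[1] < window_s) {
    stop("first ON epoch shorter than the analysis window", call. = FALSE)
  }
  t_on <- on$start_s[1]
  pair <- strsplit(on$quadrants[1], ",")[[1]]
  pre <- window_metrics(track, t_on - window_s, t_on, arena)
  stim <- window_metrics(track, t_on, t_on + window_s, arena)
  # gate: fly must stay inside the lit quadrants for the full stim window
  stim_sel <- track$time_s >= t_on & track$time_s < t_on + window_s
  stim_track <- track[stim_sel, , drop = FALSE]
  stayed <- vapply(split(stim_track, stim_track$fly_id), function(w) {
    all(assign_quadrant(w$x_mm, w$y_mm, arena) %in% pair)
  }, logical(1))
  out <- dplyr::inner_join(
    pre[, c("fly_id", metric)], stim[, c("fly_id", metric)],
    by = "fly_id", suffix = c("_pre", "_stim"))
  names(out) <- c("fly_id", "pre_mean", "stim_mean")
  out$metric <- metric
  out$stayed <- stayed[as.character(out$fly_id)]
  out$reason <- dplyr::case_when(
    !out$stayed ~ "left illuminated quadrants during window",
    out$pre_mean == 0 ~ "zero pre-stimulation mean; delta undefined",
    TRUE ~ NA_character_)
  out$included <- is.na(out$reason)
  out$delta <- ifelse(out$included,
                      (out$stim_mean - out$pre_mean) / out$pre_mean, NA_real_)
  attr(out, "window_s") <- window_s
  attr(out, "normalisation") <- "pre-stimulation mean"
  out[, c("fly_id", "metric", "pre_mean", "stim_mean", "delta", "included",
          "reason")]
}

#' Flybowl per-fly locomotion in a stimulation window
#'
#' Mean forward locomotion (path length per second, in camera pixels at
#' ~0.12 mm/px) of each fly over one 5 s whole-field ON window — by default
#' the strongest (third) stimulation.
#'
#' @param track Track data frame (`time_s`, `fly_id`, `x_mm`, `y_mm`).
#' @param schedule Flybowl schedule with three whole-field ON epochs of
#'   increasing intensity (see [flybowl_schedule()]).
#' @param which_epoch ON epoch to analyse (1-3), default 3 (strongest).
#' @param arena Arena geometry (centre used for the distance metric only).
#' @return Tibble with `fly_id`, `locomotion_px_s`.
#' @export
flybowl_locomotion <- function(track, schedule, which_epoch = 3,
                               arena = quadrant_arena()) {
  validate_schedule(schedule)
  on <- schedule_on_epochs(schedule)
  if (!all(on$quadrants == "whole_field")) {
    stop("flybowl schedule must be whole-field", call. = FALSE)
  }
  if (nrow(on) < which_epoch) {
    stop(sprintf("schedule has no ON epoch %d", which_epoch), call. = FALSE)
  }
  if (nrow(on) >= 3 && is.unsorted(on$intensity_uW_mm2)) {
    stop("flybowl ON intensities must increase", call. = FALSE)
  }
  m <- window_metrics(track, on$start_s[which_epoch], on$end_s[which_epoch],
                      arena)
  tibble::tibble(fly_id = m$fly_id, locomotion_px_s = m$forward_px_s)
}

#' Fill short tracking gaps by linear interpolation
#'
#' Regularises each fly's track onto the full frame grid, linearly
#' interpolating runs of up to `max_gap` consecutive missing frames. Flies
#' with longer gaps are returned unfilled and listed in the
#' `flies_with_long_gaps` attribute so gated analyses can drop them.
#'
#' @param track Track data frame.
#' @param frame_rate Frames per second.
#' @param max_gap Longest interpolatable run of missing frames, default 3.
#' @return The regularised track tibble.
#' @export
interpolate_track_gaps <- function(track, frame_rate, max_gap = 3) {
  dt <- 1 / frame_rate
  grid <- seq(min(track$time_s), max(track$time_s), by = dt)
  long_gap <- character(0)
  out <- lapply(split(track, track$fly_id), function(w) {
    have <- round((w$time_s - grid[1]) / dt) + 1
    missing_runs <- rle(!(seq_along(grid) %in% have))
    worst <- if (any(missing_runs$values)) {
      max(missing_runs$lengths[missing_runs$values])
    } else 0
    if (worst > max_gap) {
      long_gap <<- c(long_gap, as.character(w$fly_id[1]))
      return(w)
    }
    if (worst == 0) return(w)
    tibble::tibble(time_s = grid, fly_id = w$fly_id[1],
                   x_mm = stats::approx(w$time_s, w$x_mm, xout = grid,
                                        rule = 2)$y,
                   y_mm = stats::approx(w$time_s, w$y_mm, xout = grid,
                                        rule = 2)$y)
  })
  res <- dplyr::bind_rows(out)
  attr(res, "flies_with_long_gaps") <- long_gap
  res
}
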