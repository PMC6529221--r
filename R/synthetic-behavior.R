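# Synthetic behavioural data with known ground truth: quadrant-arena and
# Flybowl trajectories, tethered-flight wingbeat sessions, and screen-level
# preference-index tables.
#
# The quadrant walker makes region membership (which diagonal quadrant pair a
# fly currently occupies) an explicit two-state Markov chain — enter/exit
# probabilities per frame derived from the designed bias — with a reflecting
# random walk inside the current quadrant. Direction-biased walks have no
# closed-form quadrant occupancy; the explicit chain keeps the designed
# stationary occupancy exactly analytic: P(lit) = p_enter / (p_enter + p_exit).

#' Design for an arena trajectory simulation
#'
#' @param arena_kind `"four_quadrant"` (choice assay, 100 mm) or `"flybowl"`
#'   (whole-field stimulation).
#' @param diameter_mm Arena diameter; defaults 100 (quadrant) / 50 (flybowl).
#' @param n_flies Flies per trial (20 per group in the valence assay; each fly
#'   separately for the Flybowl).
#' @param frame_rate Tracking frame rate, Hz (30 for the cameras used here).
#' @param schedule Stimulation schedule tibble; defaults to
#'   [quadrant_schedule()] / [flybowl_schedule()] by kind.
#' @param bias Attraction to illuminated quadrants in \[-1, 1\]; the designed
#'   stationary PI during ON epochs equals `bias`.
#' @param base_switch_prob Per-frame probability scale of switching quadrant
#'   pair; enter/exit probabilities are
#'   `base_switch_prob * (1 + bias)` / `base_switch_prob * (1 - bias)`.
#' @param speed_mm_s Walking speed scale.
#' @param speed_gains Multiplicative speed gain per ON epoch (flybowl),
#'   recycled over ON epochs; the ground-truth locomotion change.
#' @param speed_cv Coefficient of variation of per-frame step length.
#' @param seed Integer seed.
#' @return A list of class `arena_design`.
#' @export
arena_design <- function(arena_kind = c("four_quadrant", "flybowl"),
                         diameter_mm = NULL, n_flies = 20, frame_rate = 30,
                         schedule = NULL, bias = 0, base_switch_prob = 0.05,
                         speed_mm_s = 10, speed_gains = 1, speed_cv = 0.1,
                         seed = 1L) {
  arena_kind <- match.arg(arena_kind)
  if (is.null(diameter_mm)) {
    diameter_mm <- if (arena_kind == "four_quadrant") 100 else 50
  }
  if (is.null(schedule)) {
    schedule <- if (arena_kind == "four_quadrant") quadrant_schedule()
    else flybowl_schedule()
  }
  validate_schedule(schedule)
  if (n_flies < 1) stop("n_flies must be >= 1", call. = FALSE)
  if (abs(bias) > 1) stop("bias must be in [-1, 1]", call. = FALSE)
  structure(list(arena_kind = arena_kind, diameter_mm = diameter_mm,
                 n_flies = as.integer(n_flies), frame_rate = frame_rate,
                 schedule = schedule, bias = bias,
                 base_switch_prob = base_switch_prob,
                 speed_mm_s = speed_mm_s, speed_gains = speed_gains,
                 speed_cv = speed_cv, seed = as.integer(seed)),
            class = "arena_design")
}

# angular sector index (0..3, counter-clockwise) -> quadrant label
.sector_of_angle <- function(ang) pmin(floor((ang %% 360) / 90), 3) + 1L

#' Simulate a four-quadrant assay trial
#'
#' Each fly carries a quadrant state evolving as a two-state Markov chain over
#' the diagonal pairs (per-frame enter/exit probabilities set by the design's
#' bias during ON epochs, symmetric during OFF), and performs a reflecting
#' Gaussian random walk inside its current quadrant. Positions never leave the
#' arena.
#'
#' @param design An [arena_design()] with `arena_kind = "four_quadrant"`.
#' @return List with `track` (tibble `time_s, fly_id, x_mm, y_mm`),
#'   `schedule`, `arena`, `design` and `ground_truth` (the per-frame
#'   enter/exit probabilities and the designed stationary lit-pair occupancy).
#' @export
generate_quadrant_trial <- function(design) {
  stopifnot(inherits(design, "arena_design"),
            design$arena_kind == "four_quadrant")
  arena <- quadrant_arena(design$diameter_mm)
  sched <- design$schedule
  n <- design$n_flies
  dt <- 1 / design$frame_rate
  times <- seq(0, max(sched$end_s) - dt, by = dt)
  r_max <- design$diameter_mm / 2 - 1
  r_min <- 1
  step_sd <- design$speed_mm_s * dt
  p0 <- design$base_switch_prob
  p_enter <- min(1, p0 * (1 + design$bias))
  p_exit <- max(0, min(1, p0 * (1 - design$bias)))
  with_rng(design$seed, {
    sector <- sample.int(4, n, replace = TRUE) - 1L  # angular sector 0..3
    theta <- sector * 90 + stats::runif(n, 5, 85)
    r <- sqrt(stats::runif(n, (r_min / r_max)^2, 1)) * r_max
    xs <- matrix(NA_real_, length(times), n)
    ys <- matrix(NA_real_, length(times), n)
    ep <- epoch_at(times, sched)
    for (t in seq_along(times)) {
      on_epoch <- !is.na(ep[t]) && sched$state[ep[t]] == "on" &&
        !identical(sched$quadrants[ep[t]], "whole_field")
      lit_pair <- if (on_epoch) strsplit(sched$quadrants[ep[t]], ",")[[1]]
      else character(0)
      lab <- .sector_labels[sector + 1L]
      in_lit <- lab %in% lit_pair
      p_switch <- if (on_epoch) ifelse(in_lit, p_exit, p_enter) else p0
      do_switch <- stats::runif(n) < p_switch
      rot <- ifelse(stats::runif(n) < 0.5, -90, 90)
      theta <- ifelse(do_switch, theta + rot, theta)
      sector <- ifelse(do_switch, (sector + rot / 90) %% 4, sector)
      # reflecting walk inside the current sector
      x <- r * cos(theta * pi / 180)
      y <- r * sin(theta * pi / 180)
      x <- x + stats::rnorm(n, sd = step_sd)
      y <- y + stats::rnorm(n, sd = step_sd)
      r_new <- sqrt(x^2 + y^2)
      r_new <- ifelse(r_new > r_max, 2 * r_max - r_new, r_new)
      r_new <- pmax(pmin(r_new, r_max), r_min)
      th_new <- (atan2(y, x) * 180 / pi) %% 360
      rel <- ((th_new - sector * 90) %% 360)
      rel <- ifelse(rel > 180, rel - 360, rel)    # (-180, 180]
      rel <- abs(rel)                              # reflect at lower boundary
      rel <- ifelse(rel > 90, 180 - rel, rel)      # reflect at upper boundary
      rel <- pmax(pmin(rel, 89.5), 0.5)
      theta <- sector * 90 + rel
      r <- r_new
      xs[t, ] <- r * cos(theta * pi / 180)
      ys[t, ] <- r * sin(theta * pi / 180)
    }
    track <- tibble::tibble(
      time_s = rep(times, times = n),
      fly_id = rep(sprintf("fly%02d", seq_len(n)), each = length(times)),
      x_mm = as.numeric(xs), y_mm = as.numeric(ys))
    list(track = track, schedule = sched, arena = arena, design = design,
         ground_truth = list(p_enter = p_enter, p_exit = p_exit,
                             occupancy_lit = p_enter / (p_enter + p_exit),
                             stationary_pi = design$bias))
  })
}

#' Simulate a Flybowl whole-field trial
#'
#' Flies walk with persistent heading and Gaussian step-length noise inside a
#' circular arena (reflecting wall). During each whole-field ON epoch the mean
#' step length is multiplied by the design's speed gain for that epoch — the
#' ground truth for locomotion recovery.
#'
#' @param design An [arena_design()] with `arena_kind = "flybowl"`.
#' @return List with `track`, `schedule`, `arena`, `design`, `ground_truth`
#'   (expected locomotion in px/s per ON epoch).
#' @export
generate_flybowl_trial <- function(design) {
  stopifnot(inherits(design, "arena_design"), design$arena_kind == "flybowl")
  arena <- quadrant_arena(design$diameter_mm)
  sched <- design$schedule
  on <- schedule_on_epochs(sched)
  gains <- rep(design$speed_gains, length.out = nrow(on))
  n <- design$n_flies
  dt <- 1 / design$frame_rate
  times <- seq(0, max(sched$end_s) - dt, by = dt)
  r_max <- design$diameter_mm / 2 - 1
  with_rng(design$seed, {
    ang0 <- stats::runif(n, 0, 2 * pi)
    r0 <- sqrt(stats::runif(n)) * (r_max - 1)
    x <- r0 * cos(ang0); y <- r0 * sin(ang0)
    heading <- stats::runif(n, 0, 2 * pi)
    xs <- matrix(NA_real_, length(times), n)
    ys <- matrix(NA_real_, length(times), n)
    ep <- epoch_at(times, sched)
    on_idx <- which(sched$state == "on")
    for (t in seq_along(times)) {
      gain <- 1
      if (!is.na(ep[t]) && sched$state[ep[t]] == "on") {
        gain <- gains[match(ep[t], on_idx)]
      }
      mu <- design$speed_mm_s * dt * gain
      step <- pmax(stats::rnorm(n, mu, design$speed_cv * mu), 0)
      heading <- heading + stats::rnorm(n, sd = 0.4)
      xn <- x + step * cos(heading)
      yn <- y + step * sin(heading)
      rn <- sqrt(xn^2 + yn^2)
      hit <- rn > r_max
      if (any(hit)) {  # bounce back towards the centre
        heading[hit] <- atan2(-yn[hit], -xn[hit]) +
          stats::rnorm(sum(hit), sd = 0.3)
        xn[hit] <- x[hit]; yn[hit] <- y[hit]
      }
      x <- xn; y <- yn
      xs[t, ] <- x; ys[t, ] <- y
    }
    track <- tibble::tibble(
      time_s = rep(times, times = n),
      fly_id = rep(sprintf("fly%02d", seq_len(n)), each = length(times)),
      x_mm = as.numeric(xs), y_mm = as.numeric(ys))
    expected <- design$speed_mm_s * gains / PX_MM
    list(track = track, schedule = sched, arena = arena, design = design,
         ground_truth = list(expected_locomotion_px_s = expected))
  })
}

#' Design for a tethered-flight session
#'
#' Defaults follow the standard rig protocol: six blocks of randomly
#' interleaved 10 s trials (three visual conditions crossed with LED
#' stim/no-stim), wingbeat parameters sampled at 1 kHz, stimulation at 5 s for
#' 500 ms.
#'
#' @param n_flies Flies per genotype group.
#' @param n_blocks Blocks (repetitions) per fly.
#' @param trial_length_s,stim_onset_s,stim_duration_s Trial timing, seconds.
#' @param sample_rate Hz.
#' @param visual_conditions Visual condition labels.
#' @param yaw_step,thrust_step,freq_step Designed step change of each
#'   parameter during stimulation (amplitude units / Hz); active only in LED
#'   trials of effector-carrying flies. After LED offset the effect decays
#'   exponentially with `decay_tau_s`.
#' @param decay_tau_s Post-offset decay time constant, seconds.
#' @param base_amp,base_freq Baseline wingbeat amplitude (a.u.) and
#'   frequency (Hz).
#' @param noise_sd_amp,noise_sd_freq White measurement noise SD per sample.
#' @param trial_offset_sd SD of the slow per-trial baseline offset (removed
#'   by the 100 ms pre-onset baseline subtraction).
#' @param has_effector Whether these flies carry the optogenetic effector.
#' @param seed Integer seed.
#' @return A list of class `flight_design`.
#' @export
flight_design <- function(n_flies = 6, n_blocks = 6, trial_length_s = 10,
                          stim_onset_s = 5, stim_duration_s = 0.5,
                          sample_rate = 1000,
                          visual_conditions = c("dark", "stationary_stripe",
                                                "closed_loop_stripe"),
                          yaw_step = 0, thrust_step = 0, freq_step = 0,
                          decay_tau_s = 0.5, base_amp = 1, base_freq = 200,
                          noise_sd_amp = 0.05, noise_sd_freq = 1,
                          trial_offset_sd = 0.02, has_effector = TRUE,
                          seed = 1L) {
  if (stim_onset_s + stim_duration_s > trial_length_s) {
    stop("stimulation window must lie inside the trial", call. = FALSE)
  }
  if (sample_rate <= 0) stop("sample_rate must be positive", call. = FALSE)
  structure(list(n_flies = as.integer(n_flies), n_blocks = as.integer(n_blocks),
                 trial_length_s = trial_length_s, stim_onset_s = stim_onset_s,
                 stim_duration_s = stim_duration_s, sample_rate = sample_rate,
                 visual_conditions = visual_conditions, yaw_step = yaw_step,
                 thrust_step = thrust_step, freq_step = freq_step,
                 decay_tau_s = decay_tau_s, base_amp = base_amp,
                 base_freq = base_freq, noise_sd_amp = noise_sd_amp,
                 noise_sd_freq = noise_sd_freq,
                 trial_offset_sd = trial_offset_sd,
                 has_effector = isTRUE(has_effector), seed = as.integer(seed)),
            class = "flight_design")
}

# step-with-decay effect time course on the trial's time grid
effect_profile <- function(times, design) {
  on <- design$stim_onset_s; off <- on + design$stim_duration_s
  e <- numeric(length(times))
  e[times >= on & times < off] <- 1
  post <- times >= off
  e[post] <- exp(-(times[post] - off) / design$decay_tau_s)
  e
}

#' Simulate a tethered-flight session
#'
#' For each fly and block, one trial per combination of visual condition and
#' LED stim/no-stim, randomly interleaved within the block. LED trials of
#' effector-carrying flies embed the designed step responses (yaw realised as
#' an antisymmetric left/right amplitude change, thrust as a symmetric one).
#'
#' @param design A [flight_design()].
#' @return List with `traces` (long tibble: `time_s, freq_hz, amp_left,
#'   amp_right, led_on, visual_condition, trial_id, block_id, fly_id,
#'   has_effector`), `design`, and `ground_truth` (the designed step sizes).
#' @export
generate_flight_session <- function(design) {
  stopifnot(inherits(design, "flight_design"))
  ns <- round(design$trial_length_s * design$sample_rate)
  times <- (seq_len(ns) - 1) / design$sample_rate
  prof <- effect_profile(times, design)
  combos <- expand.grid(visual = design$visual_conditions,
                        stim = c(FALSE, TRUE), stringsAsFactors = FALSE)
  led <- times >= design$stim_onset_s &
    times < design$stim_onset_s + design$stim_duration_s
  with_rng(design$seed, {
    pieces <- list()
    trial_counter <- 0L
    for (f in seq_len(design$n_flies)) {
      fly <- sprintf("fly%02d", f)
      for (b in seq_len(design$n_blocks)) {
        order_idx <- sample.int(nrow(combos))
        for (i in order_idx) {
          trial_counter <- trial_counter + 1L
          stim <- combos$stim[i]
          active <- stim && design$has_effector
          e <- if (active) prof else numeric(ns)
          off <- stats::rnorm(1, sd = design$trial_offset_sd)
          amp_l <- design$base_amp + off + design$yaw_step * e / 2 +
            design$thrust_step * e / 2 +
            stats::rnorm(ns, sd = design$noise_sd_amp)
          amp_r <- design$base_amp + off - design$yaw_step * e / 2 +
            design$thrust_step * e / 2 +
            stats::rnorm(ns, sd = design$noise_sd_amp)
          freq <- design$base_freq + off + design$freq_step * e +
            stats::rnorm(ns, sd = design$noise_sd_freq)
          pieces[[trial_counter]] <- tibble::tibble(
            time_s = times, freq_hz = freq, amp_left = amp_l,
            amp_right = amp_r, led_on = led & stim,
            visual_condition = combos$visual[i],
            trial_id = sprintf("t%05d", trial_counter),
            block_id = b, fly_id = fly,
            has_effector = design$has_effector)
        }
      }
    }
    list(traces = dplyr::bind_rows(pieces), design = design,
         ground_truth = list(yaw_step = design$yaw_step,
                             thrust_step = design$thrust_step,
                             freq_step = design$freq_step))
  })
}

#' Simulate a screen-level preference-index table
#'
#' Per-replicate single-value PIs for a control line and a set of screened
#' lines, Gaussian around per-line means. Under the global null every line
#' shares the control mean.
#'
#' @param n_lines Screened lines (besides the control).
#' @param n_per_group Replicates (groups of flies) per line.
#' @param control_id Control line label.
#' @param control_mean Control mean PI (empty-driver controls show mild
#'   attraction to the red light; 0.2 by default).
#' @param effects Named numeric vector of mean shifts for specific lines
#'   (others are null).
#' @param sd Replicate SD of the PI.
#' @param seed Integer seed.
#' @return Tibble `line_id, replicate, pi` (PI clamped to \[-1, 1\]).
#' @export
generate_screen_data <- function(n_lines = 50, n_per_group = 10,
                                 control_id = "empty_split",
                                 control_mean = 0.2, effects = NULL,
                                 sd = 0.25, seed = 1L) {
  lines <- sprintf("LH%04d", seq_len(n_lines))
  with_rng(seed, {
    all_ids <- c(control_id, lines)
    mu <- stats::setNames(rep(control_mean, length(all_ids)), all_ids)
    if (!is.null(effects)) {
      bad <- setdiff(names(effects), all_ids)
      if (length(bad)) stop("unknown line(s) in effects: ",
                            paste(bad, collapse = ", "), call. = FALSE)
      mu[names(effects)] <- mu[names(effects)] + effects
    }
    df <- tidyr::expand_grid(line_id = all_ids,
                             replicate = seq_len(n_per_group))
    df$pi <- pmax(-1, pmin(1, stats::rnorm(nrow(df), mu[df$line_id], sd)))
    df
  })
}
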