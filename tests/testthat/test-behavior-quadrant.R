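test_that("quadrant assignment follows the sector layout and tie-breaks", {
  arena <- quadrant_arena()
  # sector mid-angles
  for (q in names(Q_ANGLE)) {
    expect_identical(assign_quadrant(30 * cos(Q_ANGLE[q] * pi / 180),
                                     30 * sin(Q_ANGLE[q] * pi / 180), arena),
                     q)
  }
  # boundary rays go to the lower-indexed adjacent quadrant
  expect_identical(assign_quadrant(0, 30, arena), "Q1")   # 90 deg: Q1|Q2
  expect_identical(assign_quadrant(-30, 0, arena), "Q2")  # 180 deg: Q2|Q4
  expect_identical(assign_quadrant(0, -30, arena), "Q3")  # 270 deg: Q4|Q3
  expect_identical(assign_quadrant(30, 0, arena), "Q1")   # 0 deg: Q3|Q1
  expect_identical(assign_quadrant(0, 0, arena), "Q1")    # centre
  expect_error(assign_quadrant(100, 100, arena), "outside")

  # uniform points occupy each sector about equally
  set.seed(71)
  n <- 10000
  r <- sqrt(runif(n)) * 49
  th <- runif(n, 0, 2 * pi)
  q <- assign_quadrant(r * cos(th), r * sin(th), arena)
  se <- sqrt(0.25 * 0.75 / n)
  for (lbl in c("Q1", "Q2", "Q3", "Q4")) {
    expect_lt(abs(mean(q == lbl) - 0.25), 3 * se)
  }
})

test_that("the PI formula and sign conventions are honoured", {
  sched <- quadrant_schedule()
  # 13 flies in Q2+Q3, 7 in Q1+Q4 -> PI = 0.3 (frame inside first ON epoch)
  angles <- c(rep(Q_ANGLE["Q2"], 7), rep(Q_ANGLE["Q3"], 6),
              rep(Q_ANGLE["Q1"], 4), rep(Q_ANGLE["Q4"], 3))
  track <- static_track(angles, times = c(35, 36))
  pis <- pi_timeseries(track, sched)
  expect_equal(unique(pis$pi), 0.3)
  expect_equal(unique(pis$n_flies), 20L)

  # all flies in the illuminated pair -> PI = 1
  track_all <- static_track(rep(c(Q_ANGLE["Q2"], Q_ANGLE["Q3"]), 10),
                            times = c(35))
  expect_equal(pi_timeseries(track_all, sched)$pi, 1)

  # 10 vs 10 split -> 0
  track_half <- static_track(rep(c(Q_ANGLE["Q2"], Q_ANGLE["Q1"]), 10),
                             times = c(35))
  expect_equal(pi_timeseries(track_half, sched)$pi, 0)

  # second ON epoch illuminates Q1+Q4: relabelling flips the raw sign
  track_on2 <- static_track(rep(c(Q_ANGLE["Q1"], Q_ANGLE["Q4"]), 10),
                            times = c(95))
  expect_equal(pi_timeseries(track_on2, sched, relabel_on = TRUE)$pi, 1)
  expect_equal(pi_timeseries(track_on2, sched, relabel_on = FALSE)$pi, -1)
  # PI always stays within [-1, 1]
  expect_true(all(abs(pis$pi) <= 1))
})

test_that("single-value PI averages the final 5 s of both ON windows", {
  sched <- quadrant_schedule()
  t <- seq(0, 119.9, by = 0.1)
  const <- tibble::tibble(time_s = t, pi = 0.4)
  expect_equal(single_value_pi(const, sched), 0.4)

  # +1 in the first ON window, -1 in the second
  pm <- tibble::tibble(time_s = t, pi = ifelse(t < 75, 1, -1))
  expect_equal(single_value_pi(pm, sched), 0)

  # window means 0.2 and 0.6 -> 0.4; values outside the windows are ignored
  pw <- tibble::tibble(
    time_s = t,
    pi = dplyr::case_when(t >= 55 & t < 60 ~ 0.2,
                          t >= 115 & t < 120 ~ 0.6,
                          TRUE ~ -0.9))
  expect_equal(single_value_pi(pw, sched), 0.4)

  short <- tibble::tibble(start_s = c(0, 10), end_s = c(10, 13),
                          state = c("off", "on"),
                          quadrants = c(NA, "Q2,Q3"),
                          intensity_uW_mm2 = c(0, 1))
  expect_error(single_value_pi(const, short), "two ON epochs")
})

# fly walking back and forth along a radial segment in a given quadrant at a
# constant speed (px/s), sampled at 30 fps
shuttle_track <- function(fly_id, quadrant, speed_px_s, t0, t1,
                          r0 = 20, r1 = 40) {
  ts <- seq(t0, t1 - 1 / 30, by = 1 / 30)
  step_mm <- speed_px_s * PX_MM_TEST / 30
  disp <- cumsum(c(0, rep(step_mm, length(ts) - 1)))
  span <- r1 - r0
  pos <- abs((disp %% (2 * span)) - span) + r0  # triangle wave in radius
  ang <- Q_ANGLE[quadrant] * pi / 180
  tibble::tibble(time_s = ts, fly_id = fly_id,
                 x_mm = pos * cos(ang), y_mm = pos * sin(ang))
}
PX_MM_TEST <- 0.12

test_that("delta metrics normalise to the pre-stimulation mean and gate on staying lit", {
  sched <- quadrant_schedule()  # first ON epoch 30-60 s, lit pair Q2,Q3
  # fly01: 10 px/s before onset, 15 px/s during, always inside Q2
  f1 <- dplyr::bind_rows(shuttle_track("fly01", "Q2", 10, 25, 30),
                         shuttle_track("fly01", "Q2", 15, 30, 35))
  # fly02: stationary
  f2 <- tibble::tibble(time_s = seq(25, 35 - 1 / 30, by = 1 / 30),
                       fly_id = "fly02", x_mm = -25, y_mm = 25)
  # fly03: starts lit, steps into Q1 at 33 s
  ts3 <- seq(25, 35 - 1 / 30, by = 1 / 30)
  f3 <- tibble::tibble(time_s = ts3, fly_id = "fly03",
                       x_mm = ifelse(ts3 < 33, -20, 20) * cos(pi / 4),
                       y_mm = 20 * sin(pi / 4))
  f3$x_mm <- abs(f3$x_mm) * ifelse(ts3 < 33, -1, 1)
  track <- dplyr::bind_rows(f1, f2, f3)

  dm <- delta_metric(track, sched, "forward_px_s")
  r1 <- dm[dm$fly_id == "fly01", ]
  expect_true(r1$included)
  expect_equal(r1$pre_mean, 10, tolerance = 0.02)
  expect_equal(r1$stim_mean, 15, tolerance = 0.02)
  expect_equal(r1$delta, 0.5, tolerance = 0.05)

  r2 <- dm[dm$fly_id == "fly02", ]
  expect_false(r2$included)
  expect_match(r2$reason, "zero pre-stimulation")

  r3 <- dm[dm$fly_id == "fly03", ]
  expect_false(r3$included)
  expect_match(r3$reason, "left illuminated")
})

test_that("flybowl locomotion reports per-fly pixel speeds in the strongest window", {
  sched <- flybowl_schedule()
  on3 <- sched[sched$state == "on", ][3, ]
  # 1 px per frame at 30 fps -> 30 px/s
  ts <- seq(on3$start_s, on3$end_s - 1 / 30, by = 1 / 30)
  f1 <- tibble::tibble(time_s = ts, fly_id = "fly01",
                       x_mm = -10 + cumsum(c(0, rep(PX_MM_TEST,
                                                    length(ts) - 1))),
                       y_mm = 0)
  f2 <- tibble::tibble(time_s = ts, fly_id = "fly02", x_mm = 5, y_mm = 5)
  f3 <- tibble::tibble(time_s = ts, fly_id = "fly03",
                       x_mm = -10 + cumsum(c(0, rep(2 * PX_MM_TEST,
                                                    length(ts) - 1))),
                       y_mm = 0)
  loco <- flybowl_locomotion(dplyr::bind_rows(f1, f2, f3), sched)
  expect_equal(loco$locomotion_px_s[loco$fly_id == "fly01"], 30,
               tolerance = 1e-6)
  expect_equal(loco$locomotion_px_s[loco$fly_id == "fly02"], 0)
  expect_equal(loco$locomotion_px_s[loco$fly_id == "fly03"], 60,
               tolerance = 1e-6)
  expect_error(flybowl_locomotion(f1, quadrant_schedule()), "whole-field")
})

test_that("the quadrant walker honours its Markov design", {
  # no preference: long-run PI centred on zero
  d0 <- arena_design(n_flies = 20, bias = 0, seed = 81)
  sim0 <- generate_quadrant_trial(d0)
  pis <- pi_timeseries(sim0$track, sim0$schedule)
  # flies mix between pairs every ~1/p0 frames; a conservative SE uses the
  # number of independent fly-epochs rather than raw frames
  expect_lt(abs(mean(pis$pi)), 0.1)
  expect_true(all(abs(pis$pi) <= 1))

  # positions never leave the arena
  r <- sqrt(sim0$track$x_mm^2 + sim0$track$y_mm^2)
  expect_true(all(r <= d0$diameter_mm / 2 + 1e-9))

  # deterministic attraction: all flies end in the lit pair; with the second
  # epoch lighting Q1+Q4 the raw-label PI of the final window is -1
  d1 <- arena_design(n_flies = 12, bias = 1, base_switch_prob = 0.3,
                     seed = 82)
  sim1 <- generate_quadrant_trial(d1)
  pis1 <- pi_timeseries(sim1$track, sim1$schedule, relabel_on = FALSE)
  final <- pis1$pi[pis1$time_s >= 115]
  expect_true(all(final == -1))

  # designed two-state stationary occupancy: long single ON epoch
  long_on <- tibble::tibble(start_s = c(0, 10), end_s = c(10, 310),
                            state = c("off", "on"),
                            quadrants = c(NA, "Q2,Q3"),
                            intensity_uW_mm2 = c(0, 25.2))
  db <- arena_design(n_flies = 20, bias = 0.5, schedule = long_on, seed = 83)
  simb <- generate_quadrant_trial(db)
  expect_equal(simb$ground_truth$occupancy_lit, 0.75)
  q <- assign_quadrant(simb$track$x_mm, simb$track$y_mm, simb$arena)
  late <- simb$track$time_s > 60  # well past burn-in
  occ <- mean(q[late] %in% c("Q2", "Q3"))
  expect_lt(abs(occ - 0.75), 0.03)

  # same seed reproduces the trajectory exactly
  simb2 <- generate_quadrant_trial(db)
  expect_identical(simb$track, simb2$track)
})
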