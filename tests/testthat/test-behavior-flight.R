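# small fast flight design used throughout (reduced sampling rate; the
# analysis is rate-agnostic)
small_flight <- function(...) {
  flight_design(n_flies = 4, n_blocks = 3, sample_rate = 100,
                visual_conditions = "closed_loop_stripe", ...)
}

test_that("yaw and thrust follow their definitions and symmetries", {
  df <- tibble::tibble(amp_left = c(1.2, 1, 0.8), amp_right = c(1.0, 1, 0.9))
  expect_equal(yaw(df), c(0.2, 0, -0.1))
  expect_equal(thrust(df), c(2.2, 2, 1.7))
  swapped <- tibble::tibble(amp_left = df$amp_right, amp_right = df$amp_left)
  expect_equal(yaw(swapped), -yaw(df))
  expect_equal(thrust(swapped), thrust(df))
  expect_error(yaw(tibble::tibble(amp_left = 1)), "amp_right")
})

test_that("identical stim and no-stim trials give an exactly zero response", {
  d <- small_flight(noise_sd_amp = 0, noise_sd_freq = 0, trial_offset_sd = 0,
                    yaw_step = 0, seed = 91)
  sim <- generate_flight_session(d)
  r <- fly_response(sim$traces, "yaw")
  expect_true(all(abs(r$per_fly) < 1e-12))
  expect_true(all(abs(r$mean_response) < 1e-12))
  expect_equal(r$n_flies, 4)
})

test_that("response traces are baseline-zero by construction", {
  d <- small_flight(yaw_step = 0.3, seed = 92)
  sim <- generate_flight_session(d)
  for (par in c("yaw", "thrust", "freq")) {
    r <- fly_response(sim$traces, par)
    base <- r$time_rel >= -0.1 & r$time_rel < 0
    expect_lt(max(abs(colMeans(r$per_fly[base, ]))), 1e-10)
  }
})

test_that("a designed yaw step is recovered at the plateau", {
  d <- flight_design(n_flies = 6, n_blocks = 6, sample_rate = 200,
                     visual_conditions = "closed_loop_stripe",
                     yaw_step = 0.3, seed = 93)
  sim <- generate_flight_session(d)
  r <- fly_response(sim$traces, "yaw")
  stim_win <- r$time_rel >= 0.05 & r$time_rel < d$stim_duration_s
  per_fly_plateau <- colMeans(r$per_fly[stim_win, ])
  est <- mean(per_fly_plateau)
  se <- stats::sd(per_fly_plateau) / sqrt(length(per_fly_plateau))
  expect_lt(abs(est - 0.3), 3 * se + 1e-3)
})

test_that("flight-stop trials are excluded whole", {
  d <- small_flight(seed = 94)
  sim <- generate_flight_session(d)
  victim <- sim$traces$trial_id[1]
  tr <- sim$traces
  tr$freq_hz[tr$trial_id == victim][5] <- 50
  kept <- drop_stopped_trials(tr)
  expect_false(victim %in% kept$trial_id)
  expect_identical(attr(kept, "dropped_trials"), victim)
})

test_that("per-timepoint rank-sum matches the exact null and wilcox.test", {
  # complete separation with 6 vs 6 flies: exact p = 2 / choose(12, 6)
  mk_resp <- function(mat) {
    structure(list(time_rel = seq_len(nrow(mat)) * 1e-3 - 0.005,
                   per_fly = mat, mean_response = rowMeans(mat),
                   n_flies = ncol(mat), parameter = "yaw",
                   visual_condition = "dark", stim_onset_s = 5),
              class = "lh_response_trace")
  }
  set.seed(95)
  a <- matrix(rnorm(10 * 6, 10), 10, 6,
              dimnames = list(NULL, paste0("a", 1:6)))
  b <- matrix(rnorm(10 * 6, 0), 10, 6,
              dimnames = list(NULL, paste0("b", 1:6)))
  res <- per_timepoint_test(mk_resp(a), mk_resp(b))
  expect_equal(res$p, rep(2 / choose(12, 6), 10), tolerance = 1e-12)
  expect_true(all(res$significant))

  # identical groups: nothing significant
  res_same <- per_timepoint_test(mk_resp(a), mk_resp(a))
  expect_false(any(res_same$significant))

  # agreement with wilcox.test on random data, and symmetry in group order
  x <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, paste0("a", 1:6)))
  y <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, paste0("b", 1:6)))
  res_xy <- per_timepoint_test(mk_resp(x), mk_resp(y))
  res_yx <- per_timepoint_test(mk_resp(y), mk_resp(x))
  expect_equal(res_xy$p, res_yx$p)
  for (i in c(1, 7, 20)) {
    expect_equal(res_xy$p[i],
                 stats::wilcox.test(x[i, ], y[i, ], exact = TRUE)$p.value)
  }

  # large groups take the normal path and stay close to wilcox.test
  xl <- matrix(rnorm(5 * 15), 5, 15, dimnames = list(NULL, paste0("a", 1:15)))
  yl <- matrix(rnorm(5 * 15), 5, 15, dimnames = list(NULL, paste0("b", 1:15)))
  res_l <- per_timepoint_test(mk_resp(xl), mk_resp(yl))
  for (i in 1:5) {
    ref <- stats::wilcox.test(xl[i, ], yl[i, ], exact = FALSE,
                              correct = TRUE)$p.value
    expect_equal(res_l$p[i], ref, tolerance = 1e-10)
  }
  expect_error(per_timepoint_test(mk_resp(a[, 1:2, drop = FALSE]),
                                  mk_resp(b)), "at least 3")
})

test_that("a zero-effect session rejects at the attainable exact level", {
  d <- flight_design(n_flies = 6, n_blocks = 6, sample_rate = 100,
                     visual_conditions = "dark", yaw_step = 0, seed = 96)
  sim_a <- generate_flight_session(d)
  d2 <- d; d2$seed <- 97L; d2$has_effector <- FALSE
  sim_b <- generate_flight_session(d2)
  ra <- fly_response(sim_a$traces, "yaw", "dark")
  rb <- fly_response(sim_b$traces, "yaw", "dark")
  res <- per_timepoint_test(ra, rb)
  # exact attainable two-sided level below 0.05 for 6 vs 6
  cdf <- stats::pwilcox(0:36, 6, 6)
  attain <- max(cdf[2 * cdf < 0.05])
  level <- 2 * attain
  rate <- mean(res$significant)
  se <- sqrt(level * (1 - level) / nrow(res))
  expect_lt(abs(rate - level), 3 * se)
})

test_that("abs-yaw uses per-trial baseline subtraction before rectification", {
  d <- small_flight(yaw_step = 0.4, noise_sd_amp = 0, trial_offset_sd = 0,
                    seed = 98)
  sim <- generate_flight_session(d)
  r <- fly_response(sim$traces, "abs_yaw")
  stim_win <- r$time_rel >= 0.05 & r$time_rel < d$stim_duration_s
  # noise-free: |yaw| response equals the designed |step|
  expect_equal(mean(r$mean_response[stim_win]), 0.4, tolerance = 1e-9)
})
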