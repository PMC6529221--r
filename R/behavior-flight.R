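# Tethered-flight analysis: yaw and thrust from left/right wingbeat
# amplitudes, per-trial baseline subtraction (100 ms before LED onset),
# stim-minus-no-stim mean response traces per fly, and per-timepoint Wilcoxon
# rank-sum comparisons between genotype groups.

#' Yaw and thrust from wingbeat amplitudes
#'
#' Yaw turning is the left minus right wingbeat amplitude; thrust is their
#' sum.
#'
#' @param traces Data frame with `amp_left` and `amp_right` columns.
#' @return Numeric vector, one value per row.
#' @export
yaw <- function(traces) {
  if (!all(c("amp_left", "amp_right") %in% names(traces))) {
    stop("need amp_left and amp_right columns", call. = FALSE)
  }
  traces$amp_left - traces$amp_right
}

#' @rdname yaw
#' @export
thrust <- function(traces) {
  if (!all(c("amp_left", "amp_right") %in% names(traces))) {
    stop("need amp_left and amp_right columns", call. = FALSE)
  }
  traces$amp_left + traces$amp_right
}

trace_parameter <- function(traces, parameter) {
  switch(parameter,
         yaw = yaw(traces),
         abs_yaw = yaw(traces),  # |.| applied after baseline subtraction
         thrust = thrust(traces),
         freq = traces$freq_hz,
         stop(sprintf("unknown parameter '%s'", parameter), call. = FALSE))
}

#' Drop trials with mid-trial flight stops
#'
#' A trial where the wingbeat frequency falls below `freq_floor` at any sample
#' (the fly stopped flying) is excluded whole.
#'
#' @param traces Long trace tibble (see [generate_flight_session()]).
#' @param freq_floor Minimum credible flight frequency, Hz.
#' @return The filtered tibble; dropped trial ids in the `dropped_trials`
#'   attribute.
#' @export
drop_stopped_trials <- function(traces, freq_floor = 120) {
  bad <- unique(traces$trial_id[traces$freq_hz < freq_floor])
  out <- traces[!(traces$trial_id %in% bad), , drop = FALSE]
  attr(out, "dropped_trials") <- bad
  out
}

#' Per-fly baseline-subtracted response trace
#'
#' For one flight parameter and one visual condition: each trial's parameter
#' series has the mean of the 100 ms before LED onset subtracted; stim trials
#' and no-stim trials are then averaged separately over blocks, and the
#' response is the stim mean minus the no-stim mean, per fly. (For
#' `parameter = "abs_yaw"` the absolute value is taken after the per-trial
#' baseline subtraction, before averaging.) The group mean weights flies
#' equally.
#'
#' @param traces Long trace tibble (schema of [generate_flight_session()]).
#' @param parameter `"yaw"`, `"abs_yaw"`, `"thrust"` or `"freq"`.
#' @param visual_condition Which visual condition to analyse.
#' @param stim_onset_s Nominal LED onset; by default inferred from the
#'   earliest `led_on` sample.
#' @param baseline_s Baseline window before onset, default 0.1 s.
#' @return An `lh_response_trace`: list with `time_rel` (s relative to LED
#'   onset), `per_fly` (samples x flies matrix), `mean_response`, `n_flies`,
#'   `parameter`, `visual_condition`.
#' @export
fly_response <- function(traces, parameter = c("yaw", "abs_yaw", "thrust",
                                               "freq"),
                         visual_condition = "closed_loop_stripe",
                         stim_onset_s = NULL, baseline_s = 0.1) {
  parameter <- match.arg(parameter)
  tr <- traces[traces$visual_condition == visual_condition, , drop = FALSE]
  if (nrow(tr) == 0) {
    stop(sprintf("no trials for visual condition '%s'", visual_condition),
         call. = FALSE)
  }
  if (is.null(stim_onset_s)) {
    if (!any(tr$led_on)) stop("cannot infer LED onset: no led_on samples",
                              call. = FALSE)
    stim_onset_s <- min(tr$time_s[tr$led_on])
  }
  tr$value <- trace_parameter(tr, parameter)
  stim_of_trial <- tapply(tr$led_on, tr$trial_id, any)
  flies <- sort(unique(tr$fly_id))
  times <- sort(unique(tr$time_s))
  time_rel <- times - stim_onset_s
  base_win <- times >= stim_onset_s - baseline_s & times < stim_onset_s
  per_fly <- matrix(NA_real_, length(times), length(flies),
                    dimnames = list(NULL, flies))
  for (fi in seq_along(flies)) {
    ft <- tr[tr$fly_id == flies[fi], , drop = FALSE]
    ids <- unique(ft$trial_id)
    if (!any(stim_of_trial[ids]) || !any(!stim_of_trial[ids])) {
      stop(sprintf("fly %s lacks stim or no-stim trials for '%s'",
                   flies[fi], visual_condition), call. = FALSE)
    }
    acc <- list(stim = NULL, nostim = NULL)
    cnt <- c(stim = 0, nostim = 0)
    for (id in ids) {
      w <- ft[ft$trial_id == id, , drop = FALSE]
      w <- w[order(w$time_s), ]
      v <- w$value - mean(w$value[base_win])
      if (parameter == "abs_yaw") v <- abs(v)
      key <- if (stim_of_trial[[id]]) "stim" else "nostim"
      acc[[key]] <- if (is.null(acc[[key]])) v else acc[[key]] + v
      cnt[key] <- cnt[key] + 1
    }
    per_fly[, fi] <- acc$stim / cnt["stim"] - acc$nostim / cnt["nostim"]
  }
  structure(list(time_rel = time_rel, per_fly = per_fly,
                 mean_response = rowMeans(per_fly),
                 n_flies = length(flies), parameter = parameter,
                 visual_condition = visual_condition,
                 stim_onset_s = stim_onset_s),
            class = "lh_response_trace")
}

#' @export
print.lh_response_trace <- function(x, ...) {
  cat(sprintf(
    "<lh_response_trace> %s (%s), %d flies, %d samples [%.2f, %.2f] s rel. onset\n",
    x$parameter, x$visual_condition, x$n_flies, length(x$time_rel),
    min(x$time_rel), max(x$time_rel)))
  invisible(x)
}

#' Tidy a response trace
#' @param x An `lh_response_trace`.
#' @param ... Unused.
#' @return Long tibble: `time_rel`, `fly_id`, `response`, plus the group mean
#'   repeated as `mean_response`.
#' @method tidy lh_response_trace
#' @export
tidy.lh_response_trace <- function(x, ...) {
  tibble::tibble(
    time_rel = rep(x$time_rel, times = ncol(x$per_fly)),
    fly_id = rep(colnames(x$per_fly), each = length(x$time_rel)),
    response = as.numeric(x$per_fly),
    mean_response = rep(x$mean_response, times = ncol(x$per_fly)))
}

# Two-sided rank-sum p-values for each row of two matrices (samples x flies).
# Exact null via the Mann-Whitney U distribution when both groups have <= 10
# members and the row has no ties; otherwise normal approximation with tie
# correction and continuity correction.
ranksum_rows <- function(a, b, exact_max_n = 10) {
  na <- ncol(a); nb <- ncol(b)
  use_exact_base <- na <= exact_max_n && nb <= exact_max_n
  cdf <- NULL
  if (use_exact_base) cdf <- stats::pwilcox(0:(na * nb), na, nb)
  p <- numeric(nrow(a)); u_stat <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    x <- a[i, ]; y <- b[i, ]
    r <- rank(c(x, y))
    u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    u_stat[i] <- u
    tied <- any(duplicated(c(x, y)))
    if (use_exact_base && !tied) {
      p_low <- cdf[u + 1]
      p_high <- 1 - (if (u >= 1) cdf[u] else 0)
      p[i] <- min(1, 2 * min(p_low, p_high))
    } else {
      n_tot <- na + nb
      ties <- table(r)
      sigma2 <- na * nb / 12 *
        (n_tot + 1 - sum(ties^3 - ties) / (n_tot * (n_tot - 1)))
      mu <- na * nb / 2
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p[i] <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(u = u_stat, p = p)
}

#' Per-timepoint rank-sum comparison of two response-trace groups
#'
#' At each sample, a two-sided Wilcoxon rank-sum test between the per-fly
#' response values of the two groups (e.g. effector versus empty-driver
#' control), flagged at `p < alpha` with no multiplicity correction — the
#' convention for marking significant stretches on response-trace plots.
#' The exact null distribution is used for group sizes up to 10 (without
#' ties); larger groups use the normal approximation with continuity
#' correction.
#'
#' @param group_a,group_b `lh_response_trace` objects on the same time grid,
#'   each with at least 3 flies.
#' @param alpha Significance level, default 0.05.
#' @param decimate_to Optional sampling rate (Hz) to decimate to before
#'   testing (keeps every k-th sample); `NULL` tests at native resolution.
#' @return Tibble: `time_rel`, `u`, `p`, `significant`.
#' @export
per_timepoint_test <- function(group_a, group_b, alpha = 0.05,
                               decimate_to = NULL) {
  stopifnot(inherits(group_a, "lh_response_trace"),
            inherits(group_b, "lh_response_trace"))
  if (group_a$n_flies < 3 || group_b$n_flies < 3) {
    stop("need at least 3 flies per group", call. = FALSE)
  }
  if (length(group_a$time_rel) != length(group_b$time_rel) ||
      max(abs(group_a$time_rel - group_b$time_rel)) > 1e-9) {
    stop("groups must share one time grid", call. = FALSE)
  }
  keep <- seq_along(group_a$time_rel)
  if (!is.null(decimate_to)) {
    native <- 1 / stats::median(diff(group_a$time_rel))
    k <- max(1L, round(native / decimate_to))
    keep <- seq(1L, length(keep), by = k)
  }
  res <- ranksum_rows(group_a$per_fly[keep, , drop = FALSE],
                      group_b$per_fly[keep, , drop = FALSE])
  tibble::tibble(time_rel = group_a$time_rel[keep], u = res$u, p = res$p,
                 significant = res$p < alpha)
}
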