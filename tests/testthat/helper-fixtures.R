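# Shared fixture builders and independent oracles. Everything here is kept
# deliberately naive (explicit loops, sorting) so it stays independent of the
# vectorised implementation paths it checks.

# mask from a logical/0-1 array with defaults
mk_mask <- function(arr, ...) {
  lh_mask(array(as.logical(arr), dim = dim(arr)), ...)
}

# brute-force voxel counts for two masks, by explicit per-voxel loop
oracle_overlap_counts <- function(a, b) {
  da <- a$data; db <- b$data
  n_a <- 0L; n_b <- 0L; n_ab <- 0L
  for (i in seq_along(da)) {
    if (da[i]) n_a <- n_a + 1L
    if (db[i]) n_b <- n_b + 1L
    if (da[i] && db[i]) n_ab <- n_ab + 1L
  }
  list(n_a = n_a, n_b = n_b, n_ab = n_ab)
}

oracle_overlap_scores <- function(a, b) {
  cnt <- oracle_overlap_counts(a, b)
  p1 <- 100 * cnt$n_ab / cnt$n_a
  p2 <- 100 * cnt$n_ab / cnt$n_b
  list(p1 = p1, p2 = p2, mean = (p1 + p2) / 2,
       max = max(p1, p2), min = min(p1, p2))
}

# exhaustive Otsu: minimise within-class variance over every bin cut
oracle_otsu <- function(x, bins = 256L) {
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  bi <- pmin(findInterval(x, edges, rightmost.closed = TRUE), bins)
  centers <- (edges[-1] + edges[-(bins + 1L)]) / 2
  best_t <- NA_real_; best_w <- Inf
  for (k in seq_len(bins - 1L)) {
    lo <- bi <= k; hi <- !lo
    if (!any(lo) || !any(hi)) next
    v <- function(sel) {
      vals <- centers[bi[sel]]
      sum((vals - mean(vals))^2)
    }
    wcv <- v(lo) + v(hi)
    if (wcv < best_w - 1e-12) { best_w <- wcv; best_t <- edges[k + 1L] }
  }
  best_t
}

# type-7 quantile by explicit sort-and-interpolate
oracle_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# naive O(n^3) complete-linkage agglomeration; returns cluster membership at k
oracle_complete_linkage_k <- function(mat, k) {
  n <- nrow(mat)
  d <- as.matrix(stats::dist(mat))
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- max(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  memb <- integer(n)
  for (i in seq_along(clusters)) memb[clusters[[i]]] <- i
  memb
}

# brute-force BH step-up adjusted p-values
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# a small track where each fly sits at a fixed angle/radius every frame
static_track <- function(angles_deg, radius = 30, times = c(0, 1)) {
  df <- expand.grid(time_s = times, id = seq_along(angles_deg))
  df$fly_id <- sprintf("fly%02d", df$id)
  df$x_mm <- radius * cos(angles_deg[df$id] * pi / 180)
  df$y_mm <- radius * sin(angles_deg[df$id] * pi / 180)
  tibble::as_tibble(df[, c("time_s", "fly_id", "x_mm", "y_mm")])
}

# mid-sector angles for each quadrant label
Q_ANGLE <- c(Q1 = 45, Q2 = 135, Q4 = 225, Q3 = 315)
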