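# Synthetic registered stacks with known ground truth.
#
# The generator emulates what the mask pipeline sees in a real screen: several
# replicate confocal stacks of one line, co-registered to a template grid, each
# showing the same branched arbor displaced by a small residual registration
# error, over a noisy background. Ground truth (the canonical arbor voxel set
# and the drawn displacements) is carried alongside so recovery can be tested
# without re-deriving anything from files.

# Evaluate expr under a fixed seed without disturbing the caller's RNG stream.
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic per-object substream seed from a session seed.
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k * 1000003) %% (.Machine$integer.max - 1)) + 1L
}

#' Parameters for the synthetic arbor generator
#'
#' Defaults mirror the study's 20x acquisition scaled down spatially: a
#' 64 x 64 x 32 grid at 0.56 x 0.56 x 1.0 um spacing. The arbor is a union of
#' capsule-shaped branches traced by random walks — the simplest shape with
#' the elongated, partially overlapping neurites the pipeline has to segment.
#' Replicate-to-replicate jitter is a rigid translation (residual registration
#' error); its default of one x/y voxel (0.56 um) is a modelling choice, since
#' registration error is not characterised upstream.
#'
#' @param grid_shape Voxels per axis, length 3.
#' @param voxel_spacing Micrometres per voxel, length 3.
#' @param n_branches Number of branches.
#' @param branch_length Length of each branch in micrometres.
#' @param tube_radius Capsule radius in micrometres.
#' @param intensity_fg,intensity_bg Foreground/background intensity
#'   (arbitrary units); fg must exceed bg.
#' @param noise_sd Additive Gaussian noise SD (same units).
#' @param jitter_sd Replicate displacement SD per axis, micrometres.
#' @param seed Integer seed.
#' @return A list of class `arbor_params`.
#' @export
arbor_params <- function(grid_shape = c(64, 64, 32),
                         voxel_spacing = c(0.56, 0.56, 1.0),
                         n_branches = 6, branch_length = 18,
                         tube_radius = 1.0,
                         intensity_fg = 1.0, intensity_bg = 0.1,
                         noise_sd = 0.02, jitter_sd = 0.56, seed = 1L) {
  if (any(grid_shape < 1)) stop("grid_shape must be positive", call. = FALSE)
  if (branch_length <= 0 || tube_radius <= 0) {
    stop("branch_length and tube_radius must be positive", call. = FALSE)
  }
  if (intensity_fg <= intensity_bg) {
    stop("intensity_fg must exceed intensity_bg", call. = FALSE)
  }
  if (noise_sd < 0 || jitter_sd < 0) {
    stop("noise_sd and jitter_sd must be >= 0", call. = FALSE)
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 n_branches = as.integer(n_branches),
                 branch_length = branch_length, tube_radius = tube_radius,
                 intensity_fg = intensity_fg, intensity_bg = intensity_bg,
                 noise_sd = noise_sd, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "arbor_params")
}

# Precompute integer voxel offsets within radius (um) of a voxel center.
ball_offsets <- function(radius, spacing) {
  r_vox <- ceiling(radius / spacing)
  g <- expand.grid(dx = -r_vox[1]:r_vox[1], dy = -r_vox[2]:r_vox[2],
                   dz = -r_vox[3]:r_vox[3])
  d <- sqrt((g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 +
              (g$dz * spacing[3])^2)
  as.matrix(g[d <= radius + 1e-9, , drop = FALSE])
}

# Trace the canonical arbor as a set of path points (um), reflecting random
# walks inside a margin box, then voxelize as a union of capsules.
trace_arbor <- function(params) {
  extent <- params$grid_shape * params$voxel_spacing
  margin <- params$tube_radius + 2 * max(params$voxel_spacing)
  for (ax in 1:3) {
    if (extent[ax] <= 2 * margin + 2) {
      stop(sprintf(
        "grid too small to contain arbor along %s: extent %.2f um, need > %.2f um",
        c("x", "y", "z")[ax], extent[ax], 2 * margin + 2), call. = FALSE)
    }
  }
  lo <- rep(margin, 3); hi <- extent - margin
  step <- 1.0
  sub <- 0.45 * min(params$voxel_spacing)  # sub-step so capsules stay connected
  pts <- list()
  path <- matrix(extent / 2, nrow = 1)  # anchor: grid centre
  for (b in seq_len(params$n_branches)) {
    start <- path[sample.int(nrow(path), 1), ]
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    n_steps <- max(2L, round(params$branch_length / step))
    branch <- matrix(NA_real_, n_steps + 1L, 3)
    branch[1, ] <- start
    p <- start
    for (s in seq_len(n_steps)) {
      dir <- dir + stats::rnorm(3, sd = 0.35)
      dir <- dir / sqrt(sum(dir^2))
      p_new <- p + dir * step
      # reflect at the margin box
      for (ax in 1:3) {
        if (p_new[ax] < lo[ax]) { p_new[ax] <- 2 * lo[ax] - p_new[ax]; dir[ax] <- -dir[ax] }
        if (p_new[ax] > hi[ax]) { p_new[ax] <- 2 * hi[ax] - p_new[ax]; dir[ax] <- -dir[ax] }
      }
      branch[s + 1L, ] <- p_new
      p <- p_new
    }
    path <- rbind(path, branch)
    # densify for voxelization
    for (s in seq_len(n_steps)) {
      seg <- branch[s + 1L, ] - branch[s, ]
      len <- sqrt(sum(seg^2))
      ts <- seq(0, 1, by = min(1, sub / max(len, 1e-9)))
      pts[[length(pts) + 1L]] <-
        sweep(outer(ts, seg), 2, branch[s, ], "+")
    }
  }
  do.call(rbind, pts)
}

voxelize_points <- function(pts, params) {
  gs <- params$grid_shape; sp <- params$voxel_spacing
  centers <- round(sweep(pts, 2, sp, "/") - 0.5) + 1L  # 1-based voxel index
  centers <- unique(centers)
  offs <- ball_offsets(params$tube_radius, sp)
  all_idx <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    shifted <- sweep(centers, 2, offs[o, ], "+")
    keep <- shifted[, 1] >= 1 & shifted[, 1] <= gs[1] &
      shifted[, 2] >= 1 & shifted[, 2] <= gs[2] &
      shifted[, 3] >= 1 & shifted[, 3] <= gs[3]
    s <- shifted[keep, , drop = FALSE]
    all_idx[[o]] <- (s[, 3] - 1L) * gs[1] * gs[2] + (s[, 2] - 1L) * gs[1] + s[, 1]
  }
  sort(unique(unlist(all_idx)))
}

shift_voxel_set <- function(idx, grid_shape, shift_vox) {
  a <- arrayInd(idx, grid_shape)
  s <- sweep(a, 2, as.integer(shift_vox), "+")
  keep <- s[, 1] >= 1 & s[, 1] <= grid_shape[1] &
    s[, 2] >= 1 & s[, 2] <= grid_shape[2] &
    s[, 3] >= 1 & s[, 3] <= grid_shape[3]
  s <- s[keep, , drop = FALSE]
  (s[, 3] - 1L) * grid_shape[1] * grid_shape[2] +
    (s[, 2] - 1L) * grid_shape[1] + s[, 1]
}

render_voxel_set <- function(idx, params) {
  gs <- params$grid_shape
  vol <- array(params$intensity_bg, dim = gs)
  vol[idx] <- params$intensity_fg
  if (params$noise_sd > 0) {
    vol <- vol + array(stats::rnorm(prod(gs), sd = params$noise_sd), dim = gs)
  }
  lh_volume(vol, params$voxel_spacing, space_id = "synthetic")
}

#' Generate replicate stacks of one synthetic arbor
#'
#' Draws one canonical arbor, then renders `n_replicates` stacks on the
#' identical grid, each containing the arbor rigidly displaced by an
#' independent Gaussian jitter (rounded to whole voxels so the displaced
#' ground-truth voxel set stays exact) plus additive Gaussian noise.
#'
#' @param params An [arbor_params()].
#' @param n_replicates Number of stacks.
#' @return A list with `stacks` (list of [lh_volume]) and `ground_truth`: the
#'   canonical arbor voxel indices (`voxel_idx`), the continuous displacement
#'   draws in micrometres (`shifts_um`, n x 3), the applied integer voxel
#'   shifts (`shifts_vox`), per-replicate displaced voxel sets
#'   (`replicate_voxel_idx`) and the generating `params`.
#' @export
generate_replicate_stacks <- function(params, n_replicates = 3L) {
  stopifnot(inherits(params, "arbor_params"), n_replicates >= 1)
  with_rng(params$seed, {
    pts <- trace_arbor(params)
    truth_idx <- voxelize_points(pts, params)
    shifts_um <- matrix(stats::rnorm(3 * n_replicates, sd = params$jitter_sd),
                        ncol = 3, byrow = TRUE)
    shifts_vox <- round(sweep(shifts_um, 2, params$voxel_spacing, "/"))
    stacks <- vector("list", n_replicates)
    rep_idx <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      rep_idx[[r]] <- shift_voxel_set(truth_idx, params$grid_shape,
                                      shifts_vox[r, ])
      stacks[[r]] <- render_voxel_set(rep_idx[[r]], params)
    }
    list(stacks = stacks,
         ground_truth = list(voxel_idx = truth_idx, shifts_um = shifts_um,
                             shifts_vox = shifts_vox,
                             replicate_voxel_idx = rep_idx, params = params))
  })
}

#' Design for a mask pair with exact overlap ground truth
#'
#' @param target_fraction Designed directional overlap of A in B, in \[0, 1\]:
#'   `|A intersect B| = round(target_fraction * size_a)` exactly.
#' @param size_a,size_b Voxel counts of the two masks.
#' @param grid_shape,voxel_spacing Grid the pair lives on.
#' @param seed Integer seed (used when rendering stacks from the design).
#' @return A list of class `overlap_design`.
#' @export
overlap_design <- function(target_fraction, size_a, size_b,
                           grid_shape = c(64, 64, 32),
                           voxel_spacing = c(0.56, 0.56, 1.0), seed = 1L) {
  if (target_fraction < 0 || target_fraction > 1) {
    stop("target_fraction must be in [0, 1]", call. = FALSE)
  }
  if (size_a < 1 || size_b < 1) stop("sizes must be >= 1", call. = FALSE)
  k <- round(target_fraction * size_a)
  if (k > size_b) {
    stop("infeasible design: target_fraction * size_a exceeds size_b",
         call. = FALSE)
  }
  structure(list(target_fraction = target_fraction, size_a = as.integer(size_a),
                 size_b = as.integer(size_b), k = as.integer(k),
                 grid_shape = as.integer(grid_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 seed = as.integer(seed)),
            class = "overlap_design")
}

# Linear raster order inside a rod of cross-section s x s along x, offset to
# the grid: index m (0-based) -> voxel (x0 + m %/% s^2, y0 + ..., z0 + ...).
rod_voxels <- function(m_range, s, x0, y0, z0, grid_shape) {
  m <- m_range
  x <- x0 + m %/% (s * s)
  r <- m %% (s * s)
  y <- y0 + r %/% s
  z <- z0 + r %% s
  if (any(x > grid_shape[1]) || any(y > grid_shape[2]) || any(z > grid_shape[3])) {
    stop("infeasible design: masks do not fit the grid", call. = FALSE)
  }
  (z - 1L) * grid_shape[1] * grid_shape[2] + (y - 1L) * grid_shape[1] + x
}

#' Generate a mask pair with exact designed overlap
#'
#' Constructs two compact rod-shaped masks A and B on one grid whose
#' intersection contains exactly `round(target_fraction * size_a)` voxels, by
#' laying both out along a shared raster order (A's tail is B's head). The
#' exact construction makes the pair a ground-truth fixture for overlap
#' recovery.
#'
#' @param design An [overlap_design()].
#' @return List with `a`, `b` ([lh_mask]) and `k` (designed intersection count).
#' @export
generate_mask_pair <- function(design) {
  stopifnot(inherits(design, "overlap_design"))
  gs <- design$grid_shape
  k <- design$k
  gap <- if (k == 0L) 2L else 0L
  total <- design$size_a + gap * 1L + (design$size_b - k)
  # chunky cross-section: aim to use about half the x extent
  s <- max(3, ceiling(sqrt(total / max(gs[1] / 2, 4))))
  len <- ceiling(total / (s * s)) + 1L
  if (s + 4 > min(gs[2], gs[3]) || len + 4 > gs[1]) {
    stop("infeasible design: masks do not fit the grid", call. = FALSE)
  }
  x0 <- max(1L, (gs[1] - len) %/% 2L)
  y0 <- max(1L, (gs[2] - s) %/% 2L)
  z0 <- max(1L, (gs[3] - s) %/% 2L)
  gap_lin <- gap * s * s
  idx_a <- rod_voxels(0:(design$size_a - 1L), s, x0, y0, z0, gs)
  b_start <- design$size_a - k + gap_lin
  idx_b <- rod_voxels(b_start:(b_start + design$size_b - 1L), s, x0, y0, z0, gs)
  mk <- function(idx, ct) {
    arr <- array(FALSE, gs)
    arr[idx] <- TRUE
    lh_mask(arr, design$voxel_spacing, space_id = "synthetic", cell_type = ct)
  }
  list(a = mk(idx_a, "typeA"), b = mk(idx_b, "typeB"), k = k)
}

#' Render replicate stacks for both masks of a designed pair
#'
#' Produces per-cell-type replicate intensity stacks from a designed mask pair
#' so the full mask pipeline can be tested against the designed overlap. The
#' rendering keeps the ground-truth voxel sets fixed (no jitter — jitter would
#' change the true intersection, not merely the measurement) and adds
#' background/foreground intensities plus Gaussian noise.
#'
#' @param pair Output of [generate_mask_pair()].
#' @param design The [overlap_design()] used (supplies seed and grid).
#' @param n_replicates Stacks per cell type.
#' @param intensity_fg,intensity_bg,noise_sd Rendering intensities.
#' @return List with `stacks_a`, `stacks_b` (lists of [lh_volume]).
#' @export
render_pair_stacks <- function(pair, design, n_replicates = 3L,
                               intensity_fg = 1.0, intensity_bg = 0.1,
                               noise_sd = 0.02) {
  stopifnot(inherits(design, "overlap_design"))
  p <- arbor_params(grid_shape = design$grid_shape,
                    voxel_spacing = design$voxel_spacing,
                    intensity_fg = intensity_fg, intensity_bg = intensity_bg,
                    noise_sd = noise_sd, seed = design$seed)
  with_rng(design$seed, {
    idx_a <- which(pair$a$data)
    idx_b <- which(pair$b$data)
    list(stacks_a = lapply(seq_len(n_replicates),
                           function(i) render_voxel_set(idx_a, p)),
         stacks_b = lapply(seq_len(n_replicates),
                           function(i) render_voxel_set(idx_b, p)))
  })
}
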