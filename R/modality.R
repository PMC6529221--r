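# Modality-averaged input maps: take one exemplar mask per input neuron with a
# given sensory modality, average them voxelwise, and restrict to a neuropil
# region — the machinery behind "where in the lateral horn does each modality
# land" maps.

#' Average exemplars into a modality map
#'
#' Voxelwise arithmetic mean of exemplar masks or volumes (binary masks count
#' as 0/1), restricted to a region of interest. The result is a scalar field
#' in \[0, 1\]: the fraction of exemplars occupying each voxel.
#'
#' @param exemplars Non-empty list of [lh_mask] or [lh_volume] on one grid,
#'   one exemplar per cell type.
#' @param region [lh_mask] region of interest (e.g. the lateral horn neuropil).
#' @param modality Label recorded on the output.
#' @return An `lh_modality_map`: list with `mean_volume` ([lh_volume], zero
#'   outside the region), `modality`, `n_exemplars`, `region_id`.
#' @export
average_modality <- function(exemplars, region, modality = "unknown") {
  if (length(exemplars) == 0L) stop("need at least one exemplar", call. = FALSE)
  stopifnot(inherits(region, "lh_mask"))
  for (e in exemplars) {
    stopifnot(inherits(e, "lh_volume"))
    assert_same_grid(e, region)
  }
  acc <- array(0, dim(region$data))
  for (e in exemplars) acc <- acc + as.numeric(e$data)
  mean_vol <- lh_volume(acc / length(exemplars), region$spacing, region$origin,
                        region$space_id)
  mean_vol <- restrict_to_region(mean_vol, region)
  structure(list(mean_volume = mean_vol, modality = as.character(modality),
                 n_exemplars = length(exemplars),
                 region_id = region$cell_type),
            class = "lh_modality_map")
}

#' @export
print.lh_modality_map <- function(x, ...) {
  cat(sprintf("<lh_modality_map> %s: mean of %d exemplars in region '%s'\n",
              x$modality, x$n_exemplars, x$region_id))
  invisible(x)
}

#' Occupancy of a modality map over a region partition
#'
#' For each sub-region of a partition of the map's region (e.g. a
#' ventral/dorsal split), the fraction of the map's mass — the sum of mean
#' occupancy values — falling inside it. Over a true partition the fractions
#' sum to 1, so a modality "restricted to a ventral zone" shows up as a
#' ventral fraction near 1.
#'
#' @param map An `lh_modality_map`.
#' @param region_partition Named list of [lh_mask] sub-regions that together
#'   cover every voxel where the map is nonzero.
#' @return Tibble with columns `sub_region`, `mass`, `fraction`.
#' @export
modality_occupancy <- function(map, region_partition) {
  stopifnot(inherits(map, "lh_modality_map"), length(region_partition) >= 1)
  mv <- map$mean_volume
  cover <- array(FALSE, dim(mv$data))
  for (r in region_partition) {
    stopifnot(inherits(r, "lh_mask"))
    assert_same_grid(mv, r)
    cover <- cover | r$data
  }
  if (any(mv$data > 0 & !cover)) {
    stop("partition does not cover the map's support", call. = FALSE)
  }
  total <- sum(mv$data)
  if (total == 0) stop("map has zero mass", call. = FALSE)
  nm <- names(region_partition) %||% paste0("sub", seq_along(region_partition))
  mass <- vapply(region_partition,
                 function(r) sum(mv$data[r$data]), numeric(1))
  tibble::tibble(sub_region = nm, mass = unname(mass),
                 fraction = unname(mass) / total)
}

#' Split a region by a plane through its centroid
#'
#' Defines two half-regions by a plane through the region's voxel centroid,
#' perpendicular to a named axis — the operationalisation of qualitative
#' "ventral vs dorsal" zones. Voxels exactly on the plane go to the lower half.
#'
#' @param region An [lh_mask].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return Named list of two [lh_mask]: `lower`, `upper`.
#' @export
split_region_at_centroid <- function(region, axis = c("z", "x", "y")) {
  stopifnot(inherits(region, "lh_mask"))
  axis <- match.arg(axis)
  ax <- match(axis, c("x", "y", "z"))
  if (sum(region$data) == 0) stop("empty region", call. = FALSE)
  idx <- arrayInd(which(region$data), dim(region$data))
  centroid <- mean(idx[, ax])
  coords <- slice.index(region$data, ax)
  lower <- region; upper <- region
  lower$data <- region$data & (coords <= centroid)
  upper$data <- region$data & (coords > centroid)
  lower$cell_type <- paste0(region$cell_type, "_lower_", axis)
  upper$cell_type <- paste0(region$cell_type, "_upper_", axis)
  list(lower = lower, upper = upper)
}
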