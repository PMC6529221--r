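# Registered-volume containers and on-disk formats.
#
# All voxelwise analysis in this package presupposes that every volume lives on
# one common registered grid (a template space such as JFRC2013). The two
# containers below carry the grid metadata needed to enforce that, and the IO
# functions round-trip it through NRRD (canonical, carries spacing natively)
# and multi-page TIFF (spacing must be supplied by the caller).
#
# Coordinate convention: 0-based voxel indices, x fastest (R array order,
# dim = c(nx, ny, nz)); world position in micrometres = origin + index * spacing.

#' Create a registered scalar volume
#'
#' A `lh_volume` is a 3D scalar image on a registered grid: intensity data plus
#' the voxel spacing, world origin and the identifier of the template space the
#' stack was registered to. It is the raw material from which binary masks are
#' built.
#'
#' @param data 3D numeric array of intensities (arbitrary units), all finite.
#' @param spacing Numeric length-3, micrometres per voxel along x, y, z.
#'   Strictly positive.
#' @param origin Numeric length-3, world-space offset of voxel (0,0,0) in
#'   micrometres.
#' @param space_id Template space identifier, e.g. `"JFRC2013"`. Volumes in
#'   different template spaces are never comparable voxelwise.
#' @return An object of class `lh_volume`.
#' @examples
#' v <- lh_volume(array(runif(8 * 8 * 4), dim = c(8, 8, 4)))
#' v
#' @export
lh_volume <- function(data, spacing = c(0.56, 0.56, 1.0), origin = c(0, 0, 0),
                      space_id = "synthetic") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("`data` must be finite everywhere", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive values (um/voxel)", call. = FALSE)
  }
  if (length(origin) != 3L) stop("`origin` must have length 3", call. = FALSE)
  structure(
    list(data = data * 1.0, spacing = spacing, origin = origin,
         space_id = as.character(space_id)),
    class = "lh_volume"
  )
}

#' Create a binary mask on a registered grid
#'
#' A `lh_mask` is a boolean volume tagged with the biological metadata the
#' overlap analysis groups by: cell type, arbor compartment (the axon/dendrite
#' split, or "membrane" for local neurons where the split cannot be made at
#' light level), polarity class, neurotransmitter and sensory modality.
#'
#' @param data 3D logical (or coercible 0/1) array.
#' @inheritParams lh_volume
#' @param cell_type Cell-type label, e.g. `"PV5a1"`.
#' @param compartment One of `"axon"`, `"dendrite"`, `"membrane"`, `"whole"`.
#' @param polarity_class One of `"LHON"`, `"LHLN"`, `"LHIN"`, `"MBON"`,
#'   `"DAN"`, `"PN"`, `"other"`.
#' @param transmitter One of `"ACh"`, `"GABA"`, `"Glu"`, `"mixed"`, `"unknown"`.
#' @param modality One of `"olfactory"`, `"mechanosensory"`, `"temperature"`,
#'   `"visual"`, `"taste"`, `"none"`.
#' @return An object of class `lh_mask` (also `lh_volume`).
#' @export
lh_mask <- function(data, spacing = c(0.56, 0.56, 1.0), origin = c(0, 0, 0),
                    space_id = "synthetic", cell_type = "unknown",
                    compartment = c("whole", "axon", "dendrite", "membrane"),
                    polarity_class = c("other", "LHON", "LHLN", "LHIN", "MBON",
                                       "DAN", "PN"),
                    transmitter = c("unknown", "ACh", "GABA", "Glu", "mixed"),
                    modality = c("none", "olfactory", "mechanosensory",
                                 "temperature", "visual", "taste")) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1))) {
      stop("numeric mask data must contain only 0 and 1", call. = FALSE)
    }
    storage <- array(data != 0, dim = dim(data))
  } else if (is.logical(data)) {
    if (anyNA(data)) stop("mask data must not contain NA", call. = FALSE)
    storage <- data
  } else {
    stop("`data` must be logical or 0/1 numeric", call. = FALSE)
  }
  v <- lh_volume(array(0, dim = dim(data)), spacing, origin, space_id)
  structure(
    list(data = storage, spacing = v$spacing, origin = v$origin,
         space_id = v$space_id,
         cell_type = as.character(cell_type),
         compartment = match.arg(compartment),
         polarity_class = match.arg(polarity_class),
         transmitter = match.arg(transmitter),
         modality = match.arg(modality)),
    class = c("lh_mask", "lh_volume")
  )
}

#' @export
print.lh_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<lh_volume> %d x %d x %d voxels @ %.3g x %.3g x %.3g um [%s]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$space_id))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.lh_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<lh_mask> %d x %d x %d voxels @ %.3g x %.3g x %.3g um [%s]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$space_id))
  cat(sprintf("  %s / %s / %s; %d true voxels (%.2f%%)\n",
              x$cell_type, x$compartment, x$polarity_class,
              sum(x$data), 100 * mean(x$data)))
  invisible(x)
}

#' Number of true voxels in a mask
#' @param mask A [lh_mask].
#' @return Integer voxel count.
#' @export
mask_size <- function(mask) {
  stopifnot(inherits(mask, "lh_mask"))
  sum(mask$data)
}

#' Convert a volume or mask to a long tibble
#'
#' One row per voxel (or per true voxel for masks), with 0-based indices and
#' world coordinates in micrometres. Mainly useful for plotting slices and for
#' small-scale verification.
#'
#' @param x A [lh_volume] or [lh_mask].
#' @param ... Unused.
#' @return A tibble with columns `ix, iy, iz, x_um, y_um, z_um` and `value`.
#' @method tidy lh_volume
#' @export
tidy.lh_volume <- function(x, ...) {
  d <- dim(x$data)
  idx <- which(if (is.logical(x$data)) x$data else array(TRUE, d))
  a <- arrayInd(idx, d) - 1L
  tibble::tibble(
    ix = a[, 1], iy = a[, 2], iz = a[, 3],
    x_um = x$origin[1] + a[, 1] * x$spacing[1],
    y_um = x$origin[2] + a[, 2] * x$spacing[2],
    z_um = x$origin[3] + a[, 3] * x$spacing[3],
    value = if (is.logical(x$data)) TRUE else as.numeric(x$data[idx])
  )
}

#' Check that two volumes share one registered grid
#'
#' Voxelwise comparison is only meaningful between images on the identical
#' grid in the identical template space. This passes silently iff shapes match,
#' spacings agree within 1e-6 relative tolerance, and the space identifiers are
#' equal; otherwise it raises an error naming the differing attribute.
#'
#' @param a,b [lh_volume] or [lh_mask] objects.
#' @return Invisibly `TRUE` on success.
#' @export
assert_same_grid <- function(a, b) {
  stopifnot(inherits(a, "lh_volume"), inherits(b, "lh_volume"))
  if (!identical(dim(a$data), dim(b$data))) {
    stop(sprintf("grid shape mismatch: %s vs %s",
                 paste(dim(a$data), collapse = "x"),
                 paste(dim(b$data), collapse = "x")), call. = FALSE)
  }
  rel <- abs(a$spacing - b$spacing) / pmax(a$spacing, b$spacing)
  if (any(rel > 1e-6)) {
    stop(sprintf("voxel spacing mismatch: (%s) vs (%s)",
                 paste(signif(a$spacing, 6), collapse = ", "),
                 paste(signif(b$spacing, 6), collapse = ", ")), call. = FALSE)
  }
  if (!identical(a$space_id, b$space_id)) {
    stop(sprintf("template space mismatch: '%s' vs '%s'", a$space_id,
                 b$space_id), call. = FALSE)
  }
  invisible(TRUE)
}

#' Restrict a volume or mask to a region
#'
#' Sets everything outside `region` to background (0 for volumes, `FALSE` for
#' masks) and leaves the inside untouched — the operation used to display only
#' the voxels inside a neuropil such as the lateral horn.
#'
#' @param v A [lh_volume] or [lh_mask].
#' @param region A [lh_mask] on the same grid.
#' @return An object of the same class as `v`.
#' @export
restrict_to_region <- function(v, region) {
  stopifnot(inherits(region, "lh_mask"))
  assert_same_grid(v, region)
  out <- v
  if (is.logical(v$data)) {
    out$data <- v$data & region$data
  } else {
    out$data <- v$data * as.numeric(region$data)
  }
  out
}

# ---- NRRD -------------------------------------------------------------------

nrrd_type <- function(data) if (is.logical(data)) "uint8" else "double"

#' Write a volume or mask as NRRD
#'
#' Minimal NRRD writer: attached header, little-endian `raw` or `gzip`
#' encoding, `double` for intensity volumes and `uint8` for masks. Spacing,
#' origin, template space and mask metadata are stored in the header
#' (key-value fields), and mask metadata is mirrored in a JSON sidecar
#' (`<path>.json`).
#'
#' @param v A [lh_volume] or [lh_mask].
#' @param path Output file path.
#' @param encoding `"raw"` or `"gzip"`.
#' @return Invisibly, `path`.
#' @export
write_nrrd <- function(v, path, encoding = c("raw", "gzip")) {
  stopifnot(inherits(v, "lh_volume"))
  encoding <- match.arg(encoding)
  d <- dim(v$data)
  hdr <- c(
    "NRRD0004",
    sprintf("type: %s", nrrd_type(v$data)),
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("spacings: %.17g %.17g %.17g",
            v$spacing[1], v$spacing[2], v$spacing[3]),
    sprintf("encoding: %s", encoding),
    "endian: little",
    sprintf("lhscreen.origin:=%.17g %.17g %.17g",
            v$origin[1], v$origin[2], v$origin[3]),
    sprintf("lhscreen.space_id:=%s", v$space_id)
  )
  is_mask <- inherits(v, "lh_mask")
  if (is_mask) {
    hdr <- c(hdr,
             sprintf("lhscreen.cell_type:=%s", v$cell_type),
             sprintf("lhscreen.compartment:=%s", v$compartment),
             sprintf("lhscreen.polarity_class:=%s", v$polarity_class),
             sprintf("lhscreen.transmitter:=%s", v$transmitter),
             sprintf("lhscreen.modality:=%s", v$modality))
  }
  payload <- if (is.logical(v$data)) {
    writeBin_raw <- as.raw(as.integer(v$data))
    writeBin_raw
  } else {
    raw_con <- rawConnection(raw(0), "wb")
    writeBin(as.numeric(v$data), raw_con, size = 8, endian = "little")
    x <- rawConnectionValue(raw_con)
    close(raw_con)
    x
  }
  if (encoding == "gzip") payload <- memCompress(payload, "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(charToRaw("\n"), con)
  writeBin(payload, con)
  if (is_mask) {
    jsonlite::write_json(
      list(cell_type = v$cell_type, compartment = v$compartment,
           polarity_class = v$polarity_class, transmitter = v$transmitter,
           modality = v$modality, space_id = v$space_id,
           spacing_um = v$spacing, origin_um = v$origin),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a volume or mask from NRRD
#'
#' Supports the subset written by [write_nrrd()]: 3D, attached header,
#' little-endian raw or gzip encoding, `double` or `uint8` sample types.
#' Files whose header carries mask metadata come back as [lh_mask].
#'
#' @param path NRRD file path.
#' @return An [lh_volume] or [lh_mask].
#' @export
read_nrrd <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD000[0-9]$", magic)) {
    stop(sprintf("corrupt NRRD header in '%s': bad magic '%s'", path, magic),
         call. = FALSE)
  }
  fields <- list(); kv <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0L) {
      stop(sprintf("corrupt NRRD header in '%s': no blank line before data",
                   path), call. = FALSE)
    }
    if (line == "") break
    if (grepl("^#", line)) next
    if (grepl(":=", line, fixed = TRUE)) {
      p <- regmatches(line, regexpr(":=", line), invert = TRUE)[[1]]
      kv[[p[1]]] <- p[2]
    } else {
      p <- regmatches(line, regexpr(": ", line), invert = TRUE)[[1]]
      fields[[tolower(p[1])]] <- p[2]
    }
  }
  need <- c("type", "sizes", "encoding")
  miss <- setdiff(need, names(fields))
  if (length(miss)) {
    stop(sprintf("corrupt NRRD header in '%s': missing field(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  sizes <- as.integer(strsplit(trimws(fields$sizes), "\\s+")[[1]])
  if (length(sizes) != 3L || anyNA(sizes)) {
    stop(sprintf("NRRD '%s': only 3D volumes supported", path), call. = FALSE)
  }
  n <- prod(sizes)
  payload <- readBin(con, "raw", n = file.size(path))
  if (identical(fields$encoding, "gzip")) {
    payload <- memDecompress(payload, "gzip")
  } else if (!identical(fields$encoding, "raw")) {
    stop(sprintf("NRRD '%s': unsupported encoding '%s'", path,
                 fields$encoding), call. = FALSE)
  }
  type <- fields$type
  data <- switch(
    type,
    "double" = readBin(payload, "numeric", n = n, size = 8, endian = "little"),
    "float" = readBin(payload, "numeric", n = n, size = 4, endian = "little"),
    "uint8" = as.integer(payload[seq_len(n)]),
    stop(sprintf("NRRD '%s': unsupported type '%s'", path, type),
         call. = FALSE)
  )
  if (length(data) < n) {
    stop(sprintf("corrupt NRRD '%s': truncated data block", path), call. = FALSE)
  }
  arr <- array(data[seq_len(n)], dim = sizes)
  spacing <- if (!is.null(fields$spacings)) {
    as.numeric(strsplit(trimws(fields$spacings), "\\s+")[[1]])
  } else c(1, 1, 1)
  origin <- if (!is.null(kv$lhscreen.origin)) {
    as.numeric(strsplit(trimws(kv$lhscreen.origin), "\\s+")[[1]])
  } else c(0, 0, 0)
  space_id <- kv$lhscreen.space_id %||% "unknown"
  if (type == "uint8" && !is.null(kv$lhscreen.compartment)) {
    lh_mask(arr == 1L, spacing, origin, space_id,
            cell_type = kv$lhscreen.cell_type %||% "unknown",
            compartment = kv$lhscreen.compartment,
            polarity_class = kv$lhscreen.polarity_class %||% "other",
            transmitter = kv$lhscreen.transmitter %||% "unknown",
            modality = kv$lhscreen.modality %||% "none")
  } else if (type == "uint8") {
    lh_mask(arr == 1L, spacing, origin, space_id)
  } else {
    lh_volume(arr, spacing, origin, space_id)
  }
}

# ---- TIFF -------------------------------------------------------------------

#' Write a volume as a multi-page TIFF
#'
#' One 32-bit float page per z slice. TIFF carries no voxel-spacing metadata in
#' this path, so reading it back requires the spacing to be supplied (the 20x
#' acquisition spacing 0.56 x 0.56 x 1.0 um is the usual value). Intensities
#' are written as-is; values outside \[0,1\] are rescaled with a warning since
#' the TIFF float path expects normalised data.
#'
#' @param v A [lh_volume].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_tiff_stack <- function(v, path) {
  stopifnot(inherits(v, "lh_volume"))
  data <- if (is.logical(v$data)) array(as.numeric(v$data), dim(v$data)) else v$data
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > 1) {
    warning("intensities rescaled to [0,1] for TIFF float storage")
    data <- (data - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  }
  pages <- lapply(seq_len(dim(data)[3]), function(k) t(data[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a multi-page TIFF stack as a volume
#'
#' @param path TIFF file path.
#' @param spacing Voxel spacing in micrometres per axis. TIFF files written by
#'   this package carry no spacing metadata, so it must be supplied here;
#'   omitting it is an error, never a silent default.
#' @param origin,space_id As in [lh_volume()].
#' @return An [lh_volume].
#' @export
read_tiff_stack <- function(path, spacing, origin = c(0, 0, 0),
                            space_id = "unknown") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (missing(spacing) || is.null(spacing)) {
    stop(sprintf(paste0("TIFF '%s' carries no voxel spacing; supply `spacing` ",
                        "(um per axis) explicitly"), path), call. = FALSE)
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) {
                      stop(sprintf("unreadable TIFF '%s': %s", path,
                                   conditionMessage(e)), call. = FALSE)
                    })
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  d2 <- dim(pages[[1]])
  arr <- array(0, dim = c(d2[2], d2[1], nz))
  for (k in seq_len(nz)) arr[, , k] <- t(pages[[k]])
  lh_volume(arr, spacing, origin, space_id)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
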