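#' @useDynLib cav3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Label codes used throughout the package
#'
#' Segmentations are integer arrays over three classes: tissue background,
#' vessel lumen and neointima. These constants give the codes meaning.
#'
#' @format Integer scalars: `LBL_BACKGROUND = 0L`, `LBL_LUMEN = 1L`,
#'   `LBL_NEOINTIMA = 2L`.
#' @name label-codes
NULL

#' @rdname label-codes
#' @export
LBL_BACKGROUND <- 0L
#' @rdname label-codes
#' @export
LBL_LUMEN <- 1L
#' @rdname label-codes
#' @export
LBL_NEOINTIMA <- 2L

#' 3-D volume with anisotropic physical spacing
#'
#' A reconstructed specimen: a 3-D (or 3-D plus channel) numeric array with
#' per-axis voxel spacing and an origin, both in micrometers. Axis order is
#' `(z, y, x)` with z the section order; multichannel data adds a trailing
#' channel dimension. All physical coordinates refer to voxel centers, so
#' voxel `(k, i, j)` (1-based) sits at
#' `origin + ((k-1) sz, (i-1) sy, (j-1) sx)`.
#'
#' @param data numeric array, `dim` of length 3 (`nz, ny, nx`) or 4
#'   (`nz, ny, nx, nchannel`).
#' @param spacing numeric length-3, `(z, y, x)` voxel spacing in um;
#'   strictly positive.
#' @param origin numeric length-3, physical position of voxel `(1, 1, 1)`
#'   in um.
#' @param channel_names optional character vector naming the channels.
#' @return An object of class `vol3d`.
#' @export
vol3d <- function(data, spacing, origin = c(0, 0, 0), channel_names = NULL) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (nd != 3 && nd != 4)
    stop("volume data must be a 3-D array or 3-D + channel", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (z, y, x) in um",
         call. = FALSE)
  if (length(origin) != 3 || any(!is.finite(origin)))
    stop("origin must be 3 finite values (z, y, x) in um", call. = FALSE)
  if (!is.null(channel_names)) {
    if (nd != 4 || length(channel_names) != dim(data)[4])
      stop("channel_names length must match the channel dimension",
           call. = FALSE)
    channel_names <- as.character(channel_names)
  }
  structure(list(data = data, spacing = spacing, origin = origin,
                 channel_names = channel_names),
            class = "vol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vol3d> %s voxels (z,y,x%s), spacing %s um, origin %s um\n",
              paste(d[1:3], collapse = "x"),
              if (length(d) == 4) sprintf(",%d channels", d[4]) else "",
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' Labelled 3-D volume
#'
#' A segmentation result: integer codes over background (0), lumen (1) and
#' neointima (2), sharing the spatial conventions of [vol3d()].
#'
#' @param data integer 3-D array with values in `{0, 1, 2}`.
#' @inheritParams vol3d
#' @return An object of class `label_volume`.
#' @seealso [label-codes]
#' @export
label_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3)
    stop("label data must be a 3-D array", call. = FALSE)
  storage.mode(data) <- "integer"
  bad <- !(data %in% c(0L, 1L, 2L))
  if (any(bad))
    stop(sprintf("label values must be in {0, 1, 2}; found %s",
                 paste(unique(data[bad])[1:min(3, sum(bad))], collapse = ", ")),
         call. = FALSE)
  v <- vol3d(array(as.numeric(data), dim(data)), spacing, origin)
  structure(list(data = data, spacing = v$spacing, origin = v$origin),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  tab <- tabulate(x$data + 1L, nbins = 3L)
  cat(sprintf(
    "<label_volume> %s voxels, spacing %s um; background %d, lumen %d, neointima %d\n",
    paste(d, collapse = "x"), paste(signif(x$spacing, 4), collapse = "x"),
    tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Ordered stack of serial sections
#'
#' The raw input of the pipeline: an ordered list of 2-D section images (all
#' the same shape, values in `[0, 1]` after load) with the in-plane pixel
#' size and the physical section thickness. Multichannel sections are arrays
#' `[y, x, channel]` (channel-last).
#'
#' @param sections list of numeric matrices (or `[y, x, channel]` arrays),
#'   ordered from the first cut section onward.
#' @param pixel_size_xy in-plane pixel size, um/pixel.
#' @param section_thickness physical thickness of each section, um.
#' @param channel_names optional character vector naming the channels.
#' @return An object of class `section_stack`.
#' @export
section_stack <- function(sections, pixel_size_xy, section_thickness,
                          channel_names = NULL) {
  if (!is.list(sections) || length(sections) == 0)
    stop("sections must be a non-empty list of 2-D images", call. = FALSE)
  dims <- lapply(sections, function(s) dim(as.array(s)))
  ref <- dims[[1]]
  same <- vapply(dims, function(d) identical(d, ref), logical(1))
  if (!all(same))
    stop(sprintf("sections %s differ in shape from section 1",
                 paste(which(!same), collapse = ", ")), call. = FALSE)
  if (length(ref) != 2 && length(ref) != 3)
    stop("each section must be 2-D or 2-D + channel", call. = FALSE)
  if (!is.numeric(pixel_size_xy) || pixel_size_xy <= 0)
    stop("pixel_size_xy must be > 0", call. = FALSE)
  if (!is.numeric(section_thickness) || section_thickness <= 0)
    stop("section_thickness must be > 0", call. = FALSE)
  structure(list(sections = lapply(sections, as.array),
                 pixel_size_xy = as.numeric(pixel_size_xy),
                 section_thickness = as.numeric(section_thickness),
                 channel_names = channel_names),
            class = "section_stack")
}

#' @export
print.section_stack <- function(x, ...) {
  d <- dim(x$sections[[1]])
  cat(sprintf(
    "<section_stack> %d sections of %s px, %.4g um/px, %.4g um thick\n",
    length(x$sections), paste(d[1:2], collapse = "x"),
    x$pixel_size_xy, x$section_thickness))
  invisible(x)
}

#' @export
length.section_stack <- function(x) length(x$sections)

n_channels <- function(x) {
  d <- if (inherits(x, "section_stack")) dim(x$sections[[1]]) else dim(x$data)
  if (length(d) >= (if (inherits(x, "section_stack")) 3 else 4))
    d[length(d)] else 1L
}

#' Physical position of voxel indices
#'
#' Converts 1-based `(z, y, x)` voxel indices to physical um coordinates
#' under the voxel-center convention.
#'
#' @param volume a [vol3d()] or [label_volume()].
#' @param idx numeric matrix (n x 3) or length-3 vector of 1-based indices.
#' @return n x 3 matrix of `(z, y, x)` positions in um.
#' @export
voxel_to_um <- function(volume, idx) {
  idx <- rbind(idx)
  sweep(sweep(idx - 1, 2, volume$spacing, "*"), 2, volume$origin, "+")
}
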