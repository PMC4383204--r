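sidecar_path <- function(path) {
  if (dir.exists(path)) file.path(path, "metadata.yaml")
  else paste0(path, ".meta.yaml")
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (file.exists(sp)) yaml::read_yaml(sp) else NULL
}

#' Write a section stack as multi-page TIFF plus metadata sidecar
#'
#' Images go to a single multi-page TIFF (one page per section); spacings,
#' channel names and the payload kind go to a plain-text YAML sidecar
#' (`<path>.meta.yaml`) with keys `kind`, `spacing_z_um`, `spacing_xy_um`,
#' `channel_names`. Intensities are quantized to the chosen bit depth;
#' label stacks (`kind = "labels"`) are stored as 8-bit raw codes without
#' rescaling, so their round trip is bit-exact.
#'
#' @param stack a [section_stack()].
#' @param path output `.tif` path.
#' @param kind `"intensity"` or `"labels"`.
#' @param bits bits per sample for intensities (8 or 16).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, kind = c("intensity", "labels"),
                        bits = 16L) {
  stopifnot(inherits(stack, "section_stack"))
  kind <- match.arg(kind)
  pages <- if (kind == "labels")
    lapply(stack$sections, function(s) {
      m <- as.array(s)
      storage.mode(m) <- "double"
      m / 255
    })
  else lapply(stack$sections, function(s) {
    m <- as.array(s)
    m[m < 0] <- 0; m[m > 1] <- 1
    m
  })
  ok <- tiff::writeTIFF(pages, path,
                        bits.per.sample = if (kind == "labels") 8L
                        else as.integer(bits))
  if (!isTRUE(ok == length(pages)) && !isTRUE(ok))
    stop(sprintf("failed to write '%s'", path), call. = FALSE)
  meta <- list(kind = kind,
               spacing_z_um = stack$section_thickness,
               spacing_xy_um = stack$pixel_size_xy)
  if (!is.null(stack$channel_names)) meta$channel_names <- stack$channel_names
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a section stack from TIFF
#'
#' Accepts either a multi-page TIFF or a directory of per-section TIFFs
#' named with a zero-padded index (lexicographic order is section order).
#' Pixel spacings come from the YAML sidecar written by [write_stack()] or,
#' failing that, from the explicit arguments; missing spacing is an error —
#' the reader never applies silent defaults. Integer pixel data are
#' rescaled to `[0, 1]` by the type maximum, except label payloads
#' (`kind = "labels"` in the sidecar or `kind` argument) which keep their
#' raw integer codes.
#'
#' @param path multi-page TIFF file or directory of TIFFs.
#' @param pixel_size_xy,section_thickness spacings in um; required when no
#'   sidecar is present.
#' @param kind payload kind override (`NULL`: sidecar, default intensity).
#' @return a [section_stack()].
#' @export
read_stack <- function(path, pixel_size_xy = NULL, section_thickness = NULL,
                       kind = NULL) {
  meta <- read_sidecar(path)
  if (is.null(kind)) kind <- if (!is.null(meta$kind)) meta$kind else "intensity"
  px <- if (!is.null(pixel_size_xy)) pixel_size_xy else meta$spacing_xy_um
  th <- if (!is.null(section_thickness)) section_thickness else meta$spacing_z_um
  if (is.null(px) || is.null(th))
    stop(paste0("missing spacing metadata for '", path, "': supply ",
                "pixel_size_xy and section_thickness or a metadata sidecar"),
         call. = FALSE)
  as_is <- kind == "labels"
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) == 0)
      stop(sprintf("no TIFF files in '%s'", path), call. = FALSE)
    secs <- lapply(files, function(f) tiff::readTIFF(f, as.is = as_is))
    names(secs) <- basename(files)
  } else {
    if (!file.exists(path)) stop(sprintf("no such file: '%s'", path),
                                 call. = FALSE)
    secs <- tiff::readTIFF(path, all = TRUE, as.is = as_is)
    names(secs) <- sprintf("page %d", seq_along(secs))
  }
  dims <- lapply(secs, dim)
  bad <- !vapply(dims, function(d) identical(d, dims[[1]]), logical(1))
  if (any(bad))
    stop(sprintf("inconsistent section shapes: %s",
                 paste(names(secs)[bad], collapse = ", ")), call. = FALSE)
  if (as_is) secs <- lapply(secs, function(m) {
    storage.mode(m) <- "integer"
    m
  })
  section_stack(unname(secs), px, th, channel_names = meta$channel_names)
}

#' Assemble an aligned stack into a volume
#'
#' Pure restacking with no resampling: slice `k` of the volume is section
#' `k`, so per-section sums are preserved; voxel spacing is
#' `(section_thickness, pixel_size_xy, pixel_size_xy)`.
#'
#' @param stack a [section_stack()].
#' @param origin physical position of voxel `(1, 1, 1)`, um.
#' @return a [vol3d()] (or a [label_volume()] when the sections are integer
#'   label images).
#' @export
assemble_volume <- function(stack, origin = c(0, 0, 0)) {
  stopifnot(inherits(stack, "section_stack"))
  n <- length(stack)
  d2 <- dim(stack$sections[[1]])
  is_lab <- all(vapply(stack$sections, is.integer, logical(1)))
  dims <- c(n, d2)
  a <- array(if (is_lab) 0L else 0, dim = dims)
  for (k in seq_len(n)) {
    if (length(d2) == 2) a[k, , ] <- stack$sections[[k]]
    else a[k, , , ] <- stack$sections[[k]]
  }
  spacing <- c(stack$section_thickness, stack$pixel_size_xy,
               stack$pixel_size_xy)
  if (is_lab && length(d2) == 2) label_volume(a, spacing, origin)
  else vol3d(a, spacing, origin, channel_names = stack$channel_names)
}

#' Write / read volumes as multi-page TIFF with a sidecar
#'
#' One TIFF page per z-slice (channels stored per page, channel-last);
#' spacing and origin go to the YAML sidecar. [write_labels()] stores
#' integer codes as 8-bit without rescaling so the round trip is bit-exact;
#' [write_volume()] quantizes intensities to 16 bits.
#'
#' @param volume a [vol3d()].
#' @param path output `.tif` path.
#' @return `path` invisibly (writers); a [vol3d()] / [label_volume()]
#'   (readers).
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "vol3d"))
  d <- dim(volume$data)
  pages <- lapply(seq_len(d[1]), function(k) {
    m <- if (length(d) == 4) volume$data[k, , , , drop = TRUE]
    else volume$data[k, , ]
    m[m < 0] <- 0; m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(list(kind = "volume",
                        spacing_um = as.list(volume$spacing),
                        origin_um = as.list(volume$origin),
                        channel_names = volume$channel_names),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  meta <- read_sidecar(path)
  if (!is.null(meta) && is.null(meta$spacing_um) &&
      !is.null(meta$spacing_z_um)) {
    # a section stack on disk: assemble it
    return(assemble_volume(read_stack(path)))
  }
  if (is.null(meta) || is.null(meta$spacing_um))
    stop(sprintf("missing spacing sidecar for '%s'", path), call. = FALSE)
  as_is <- identical(meta$kind, "labels")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = as_is)
  d2 <- dim(pages[[1]])
  a <- array(0, c(length(pages), d2))
  for (k in seq_along(pages)) {
    if (length(d2) == 2) a[k, , ] <- pages[[k]] else a[k, , , ] <- pages[[k]]
  }
  spacing <- unlist(meta$spacing_um)
  origin <- if (!is.null(meta$origin_um)) unlist(meta$origin_um) else c(0, 0, 0)
  if (as_is) label_volume(a, spacing, origin)
  else vol3d(a, spacing, origin,
             channel_names = unlist(meta$channel_names))
}

#' @rdname write_volume
#' @param labels a [label_volume()].
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  d <- dim(labels$data)
  pages <- lapply(seq_len(d[1]), function(k) labels$data[k, , ] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  yaml::write_yaml(list(kind = "labels",
                        spacing_um = as.list(labels$spacing),
                        origin_um = as.list(labels$origin)),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_volume
#' @export
read_labels <- function(path) {
  out <- read_volume(path)
  if (!inherits(out, "label_volume"))
    stop(sprintf("'%s' does not hold a label volume", path), call. = FALSE)
  out
}
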