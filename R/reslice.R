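#' Deterministic in-plane frame for a cutting plane
#'
#' Builds two in-plane unit vectors for a plane with the given normal: the
#' coordinate axis least parallel to the normal is projected onto the plane
#' and normalized (Gram-Schmidt), and the second vector completes a
#' right-handed triple `(normal, f1, f2)`. Deterministic and continuous
#' along smooth centerlines except where the selected axis switches.
#'
#' @param normal `(z, y, x)` vector; need not be unit length, must be
#'   nonzero.
#' @return list with unit vectors `normal`, `f1`, `f2`.
#' @export
plane_frame <- function(normal) {
  n <- as.numeric(normal)
  nn <- sqrt(sum(n^2))
  if (!is.finite(nn) || nn == 0) stop("zero normal", call. = FALSE)
  n <- n / nn
  axes <- diag(3)
  pick <- which.min(abs(n))          # first minimum wins: z, then y, then x
  e <- axes[pick, ]
  f1 <- e - sum(e * n) * n
  f1 <- f1 / sqrt(sum(f1^2))
  f2 <- c(n[2] * f1[3] - n[3] * f1[2],
          n[3] * f1[1] - n[1] * f1[3],
          n[1] * f1[2] - n[2] * f1[1])
  list(normal = n, f1 = f1, f2 = f2)
}

# Shared plane sampler over vol3d/label_volume; fr is a plane_frame() list.
resample_plane_raw <- function(volume, center, fr, size, pixel_size, nearest) {
  dims <- dim(volume$data)
  if (length(dims) == 4) {
    out <- array(0, c(size, size, dims[4]))
    for (c in seq_len(dims[4]))
      out[, , c] <- cpp_resample_plane(
        as.numeric(volume$data[, , , c]), dims[1:3], volume$spacing,
        volume$origin, center, fr$f1, fr$f2, as.integer(size), pixel_size,
        nearest, 0)
    out
  } else {
    cpp_resample_plane(as.numeric(volume$data), dims, volume$spacing,
                       volume$origin, center, fr$f1, fr$f2, as.integer(size),
                       pixel_size, nearest, 0)
  }
}

#' Sample an arbitrary plane from a volume
#'
#' The core of virtual re-sectioning: resamples a volume on a square plane
#' through `center` with the given normal. Pixel `(i, j)` (0-based) of the
#' emitted image sits at
#' `center + (i - size/2) pixel_size f1 + (j - size/2) pixel_size f2` with
#' `(f1, f2)` the deterministic frame of [plane_frame()]. Intensities are
#' sampled trilinearly, labels nearest-neighbor (so label images remain in
#' `{0, 1, 2}`); positions outside the volume read as background 0.
#'
#' @param volume a [vol3d()] or [label_volume()].
#' @param center `(z, y, x)` plane center in um.
#' @param normal `(z, y, x)` plane normal (nonzero).
#' @param size emitted image edge, pixels.
#' @param pixel_size emitted pixel size, um.
#' @param interpolation `"linear"` or `"nearest"`; label volumes always use
#'   nearest.
#' @return An object of class `cross_section`: `image`, `center`, `normal`,
#'   `frame` (list `f1`, `f2`), `pixel_size`.
#' @export
resample_plane <- function(volume, center, normal, size, pixel_size,
                           interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (inherits(volume, "label_volume")) interpolation <- "nearest"
  fr <- plane_frame(normal)
  img <- resample_plane_raw(volume, as.numeric(center), fr, size, pixel_size,
                            interpolation == "nearest")
  if (inherits(volume, "label_volume")) storage.mode(img) <- "integer"
  structure(list(image = img, center = as.numeric(center), normal = fr$normal,
                 frame = fr[c("f1", "f2")], pixel_size = pixel_size),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> %dx%d px at %.4g um/px, center (%s) um\n",
              nrow(x$image), ncol(x$image), x$pixel_size,
              paste(signif(x$center, 4), collapse = ", ")))
  invisible(x)
}

#' Vessel centerline
#'
#' Ordered physical positions along the lumen axis with unit tangents and
#' cumulative arclength, all in um.
#'
#' @param points n x 3 matrix of `(z, y, x)` um positions.
#' @param tangents n x 3 matrix of unit tangents.
#' @return An object of class `centerline` with `points`, `tangents`,
#'   `arclength` (cumulative, starting at 0).
#' @export
centerline <- function(points, tangents) {
  points <- as.matrix(points); tangents <- as.matrix(tangents)
  if (nrow(points) < 2) stop("a centerline needs >= 2 points", call. = FALSE)
  if (!all(dim(points) == dim(tangents)))
    stop("points and tangents must have matching shape", call. = FALSE)
  nrm <- sqrt(rowSums(tangents^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("tangents must be unit vectors", call. = FALSE)
  seg <- sqrt(rowSums(diff(points)^2))
  structure(list(points = points, tangents = tangents,
                 arclength = c(0, cumsum(seg))),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, %.4g um long\n",
              nrow(x$points), max(x$arclength)))
  invisible(x)
}

#' Extract the lumen centerline from a label volume
#'
#' Computes the per-slice centroid of the lumen in physical coordinates,
#' smooths the centroid track with a centered moving average (shrinking at
#' the ends), and estimates unit tangents by central differences (one-sided
#' at the endpoints). The analyzed region must contain a single lumen
#' component per slice: analysis is per unbranched vessel segment, so crop
#' to one branch (orifice to the next major bifurcation) before extraction.
#'
#' @param labels a [label_volume()].
#' @param class label code to track (default lumen).
#' @param smoothing_window moving-average window, sections (default 5).
#' @return a [centerline()].
#' @export
extract_centerline <- function(labels, class = LBL_LUMEN,
                               smoothing_window = 5) {
  stopifnot(inherits(labels, "label_volume"))
  nz <- dim(labels$data)[1]
  has <- vapply(seq_len(nz), function(k) any(labels$data[k, , ] == class),
                logical(1))
  ks <- which(has)
  if (length(ks) < 3)
    stop("lumen must be present in >= 3 z-slices", call. = FALSE)
  ks <- ks[1]:ks[length(ks)]
  if (!all(has[ks]))
    stop("lumen is interrupted along z; crop to a contiguous segment",
         call. = FALSE)
  cent <- matrix(NA_real_, length(ks), 3)
  for (i in seq_along(ks)) {
    m <- labels$data[ks[i], , ] == class
    cc <- cpp_label_components_2d(array(as.integer(m), dim(m)))
    ncomp <- max(cc)
    if (ncomp > 1)
      stop(sprintf(
        paste0("slice %d has %d lumen components; crop the volume to a ",
               "single unbranched vessel segment"), ks[i], ncomp),
        call. = FALSE)
    idx <- which(m, arr.ind = TRUE)
    cent[i, ] <- c(ks[i], mean(idx[, 1]), mean(idx[, 2]))
  }
  pts <- voxel_to_um(labels, cent)
  w <- max(1L, as.integer(smoothing_window))
  half <- w %/% 2
  sm <- pts
  if (half > 0) {
    n <- nrow(pts)
    for (i in seq_len(n)) {
      lo <- max(1, i - half); hi <- min(n, i + half)
      sm[i, ] <- colMeans(pts[lo:hi, , drop = FALSE])
    }
  }
  n <- nrow(sm)
  tg <- matrix(NA_real_, n, 3)
  tg[1, ] <- sm[2, ] - sm[1, ]
  tg[n, ] <- sm[n, ] - sm[n - 1, ]
  if (n > 2) tg[2:(n - 1), ] <- sm[3:n, ] - sm[1:(n - 2), ]
  tg <- tg / sqrt(rowSums(tg^2))
  centerline(sm, tg)
}

#' Perpendicular cross-section series along a centerline
#'
#' The virtual re-sectioning operation: emits cross-sections at regular
#' arclength intervals, each perpendicular to the local centerline tangent.
#' Positions and tangents between centerline samples are linearly
#' interpolated (tangents renormalized). The series has
#' `floor(total_arclength / step) + 1` members.
#'
#' @param volume optional [vol3d()] to sample trilinearly (may be `NULL`).
#' @param labels optional [label_volume()] to sample nearest-neighbor.
#' @param cl a [centerline()].
#' @param step arclength spacing of the series, um (> 0).
#' @param size emitted image edge, pixels.
#' @param pixel_size emitted pixel size, um.
#' @return list of entries `list(s, intensity, labels)` where `s` is the
#'   arclength (um) and the other two are [resample_plane()] cross-sections
#'   (or `NULL` when the corresponding input was not given).
#' @export
perpendicular_series <- function(volume = NULL, labels = NULL, cl, step,
                                 size, pixel_size) {
  stopifnot(inherits(cl, "centerline"))
  if (is.null(volume) && is.null(labels))
    stop("need at least one of volume, labels", call. = FALSE)
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  total <- max(cl$arclength)
  svals <- seq(0, by = step, length.out = floor(total / step) + 1)
  interp <- function(mat, s)
    vapply(1:3, function(j) stats::approx(cl$arclength, mat[, j], s,
                                          rule = 2)$y, numeric(1))
  out <- vector("list", length(svals))
  for (i in seq_along(svals)) {
    p <- interp(cl$points, svals[i])
    tg <- interp(cl$tangents, svals[i])
    tg <- tg / sqrt(sum(tg^2))
    out[[i]] <- list(
      s = svals[i],
      intensity = if (!is.null(volume))
        resample_plane(volume, p, tg, size, pixel_size, "linear"),
      labels = if (!is.null(labels))
        resample_plane(labels, p, tg, size, pixel_size, "nearest"))
  }
  out
}

#' Write a centerline as CSV
#'
#' Columns: `arclength_um, z_um, y_um, x_um, tz, ty, tx`.
#' @param cl a [centerline()].
#' @param path output file.
#' @export
write_centerline <- function(cl, path) {
  df <- data.frame(arclength_um = cl$arclength,
                   z_um = cl$points[, 1], y_um = cl$points[, 2],
                   x_um = cl$points[, 3],
                   tz = cl$tangents[, 1], ty = cl$tangents[, 2],
                   tx = cl$tangents[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
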