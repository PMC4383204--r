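#' Channel-weighted vessel enhancement
#'
#' The computational core of virtual angiography: a voxelwise weighted sum
#' of the channels (negative weights subtract, mimicking digital
#' subtraction of background staining), suppression of everything below a
#' threshold, and clipping to `[0, 1]`. With collagen-rich vessel walls
#' bright in one autofluorescence channel, this highlights the vasculature
#' and suppresses the parenchyma.
#'
#' @param volume a multichannel [vol3d()] (a single-channel volume counts
#'   as one channel).
#' @param weights per-channel coefficients, length = channel count, at
#'   least one nonzero.
#' @param suppression_threshold intensities below this are set to 0.
#' @return a single-channel [vol3d()].
#' @export
enhance_channels <- function(volume, weights, suppression_threshold = 0) {
  stopifnot(inherits(volume, "vol3d"))
  d <- dim(volume$data)
  nch <- if (length(d) == 4) d[4] else 1L
  if (length(weights) != nch)
    stop(sprintf("%d weights for %d channels", length(weights), nch),
         call. = FALSE)
  if (all(weights == 0))
    stop("at least one weight must be nonzero", call. = FALSE)
  if (length(d) == 4) {
    out <- array(0, d[1:3])
    for (c in seq_len(nch)) out <- out + weights[c] * volume$data[, , , c]
  } else out <- weights[1] * volume$data
  out[out < suppression_threshold] <- 0
  out[out < 0] <- 0; out[out > 1] <- 1
  vol3d(out, volume$spacing, volume$origin)
}

#' Maximum intensity projection
#'
#' Projects a volume by taking the per-ray maximum, either along a
#' coordinate axis or along an arbitrary direction (realized by resampling
#' planes perpendicular to the direction and max-reducing them).
#'
#' @param volume a [vol3d()] (single channel).
#' @param axis `"z"`, `"y"` or `"x"`.
#' @param direction optional `(z, y, x)` vector; overrides `axis`.
#' @param size,pixel_size plane geometry for directional projection;
#'   defaults derived from the volume.
#' @return 2-D numeric matrix.
#' @export
mip <- function(volume, axis = c("z", "y", "x"), direction = NULL,
                size = NULL, pixel_size = NULL) {
  stopifnot(inherits(volume, "vol3d"))
  data <- volume$data
  if (length(dim(data)) == 4) data <- data[, , , 1]
  if (is.null(direction)) {
    axis <- match.arg(axis)
    margin <- switch(axis, z = c(2, 3), y = c(1, 3), x = c(1, 2))
    return(apply(data, margin, max))
  }
  fr <- plane_frame(direction)
  ext <- (dim(data) - 1) * volume$spacing
  c0 <- volume$origin + ext / 2
  corners <- as.matrix(expand.grid(c(0, ext[1]), c(0, ext[2]), c(0, ext[3])))
  rel <- sweep(corners, 2, ext / 2, "-")
  if (is.null(pixel_size)) pixel_size <- min(volume$spacing)
  if (is.null(size))
    size <- 2L * as.integer(ceiling(max(abs(rel %*% fr$f1),
                                        abs(rel %*% fr$f2)) / pixel_size))
  tproj <- rel %*% fr$normal
  steps <- seq(min(tproj), max(tproj), by = pixel_size)
  out <- matrix(-Inf, size, size)
  v3 <- vol3d(data, volume$spacing, volume$origin)
  for (t in steps) {
    pl <- resample_plane_raw(v3, c0 + t * fr$normal, fr, size, pixel_size,
                             nearest = FALSE)
    out <- pmax(out, pl)
  }
  out
}
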