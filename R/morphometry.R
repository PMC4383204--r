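#' Neointimal Index of a single cross-section
#'
#' `NI = 100 A_neointima / (A_neointima + A_lumen)`: the fraction of the
#' original vessel cross-section (bounded by the internal elastic lamina)
#' occupied by neointima, in percent. Unit-free: areas may be um^2 or pixel
#' counts as long as both use the same units.
#'
#' @param neointimal_area,luminal_area areas >= 0, not both 0.
#' @return NI in percent.
#' @export
ni <- function(neointimal_area, luminal_area) {
  if (any(neointimal_area < 0) || any(luminal_area < 0))
    stop("areas must be >= 0", call. = FALSE)
  tot <- neointimal_area + luminal_area
  if (any(tot == 0)) stop("no vessel in section", call. = FALSE)
  100 * neointimal_area / tot
}

#' Neointimal Index from a label image
#'
#' Areas by pixel counting of the label codes (lumen 1, neointima 2) times
#' the pixel area; no subpixel boundary fitting, so NI and NVI stay mutually
#' consistent (both are voxel/pixel counting measures).
#'
#' @param section 2-D integer label image in `{0, 1, 2}` (a matrix or the
#'   `image` of a label [resample_plane()] cross-section).
#' @param pixel_area area of one pixel, um^2 (default 1: areas in pixels).
#' @return list with `neointimal_area`, `luminal_area` (in the units set by
#'   `pixel_area`) and `ni` (percent).
#' @export
ni_from_label_section <- function(section, pixel_area = 1) {
  if (inherits(section, "cross_section")) section <- section$image
  n_neo <- sum(section == LBL_NEOINTIMA)
  n_lum <- sum(section == LBL_LUMEN)
  if (n_neo + n_lum == 0)
    stop("no vessel in section (no lumen or neointima pixels)", call. = FALSE)
  list(neointimal_area = n_neo * pixel_area,
       luminal_area = n_lum * pixel_area,
       ni = ni(n_neo, n_lum))
}

#' Neointimal Volume Index from class volumes
#'
#' `NVI = 100 V_neointima / (V_neointima + V_lumen)`: the volumetric
#' generalization of the NI over a reconstructed vessel segment, insensitive
#' to the orientation of any individual section.
#'
#' @param v_neointima,v_lumen volumes (voxels or um^3, consistently).
#' @return NVI in percent (full precision; reports conventionally round to
#'   3 decimals).
#' @export
nvi_percent <- function(v_neointima, v_lumen) {
  if (v_neointima < 0 || v_lumen < 0) stop("volumes must be >= 0", call. = FALSE)
  if (v_neointima + v_lumen == 0)
    stop("no vessel voxels in segment", call. = FALSE)
  100 * v_neointima / (v_neointima + v_lumen)
}

# Nearest-centerline arclength for every non-background voxel (um).
voxel_arclengths <- function(labels, cl) {
  idx <- which(labels$data != LBL_BACKGROUND, arr.ind = TRUE)
  pos <- voxel_to_um(labels, idx)
  best <- rep(Inf, nrow(pos))
  s_at <- rep(NA_real_, nrow(pos))
  for (i in seq_len(nrow(cl$points))) {
    d2 <- (pos[, 1] - cl$points[i, 1])^2 + (pos[, 2] - cl$points[i, 2])^2 +
      (pos[, 3] - cl$points[i, 3])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    s_at[upd] <- cl$arclength[i]
  }
  list(index = idx, arclength = s_at)
}

#' Neointimal Volume Index of a labelled segment
#'
#' Counts lumen and neointima voxels of a [label_volume()] (optionally
#' restricted to voxels whose nearest-centerline arclength lies in
#' `mask_range`) and forms the NVI. Both voxel counts and um^3 volumes are
#' reported.
#'
#' @param labels a [label_volume()].
#' @param mask_range optional `c(s_min, s_max)` arclength window in um;
#'   requires `cl`.
#' @param cl a [centerline()], needed only with `mask_range`.
#' @return list with `v_neointima_voxels`, `v_lumen_voxels`,
#'   `v_neointima_plus_lumen_voxels`, the matching `_um3` volumes and
#'   `nvi` (percent).
#' @export
nvi <- function(labels, mask_range = NULL, cl = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  if (is.null(mask_range)) {
    cv <- class_volumes(labels)
    v_n <- cv$voxels[cv$class == LBL_NEOINTIMA]
    v_l <- cv$voxels[cv$class == LBL_LUMEN]
  } else {
    if (is.null(cl))
      stop("mask_range requires a centerline", call. = FALSE)
    va <- voxel_arclengths(labels, cl)
    keep <- va$arclength >= mask_range[1] & va$arclength <= mask_range[2]
    cls <- labels$data[va$index][keep]
    v_n <- sum(cls == LBL_NEOINTIMA)
    v_l <- sum(cls == LBL_LUMEN)
  }
  vx <- prod(labels$spacing)
  list(v_neointima_voxels = v_n,
       v_lumen_voxels = v_l,
       v_neointima_plus_lumen_voxels = v_n + v_l,
       v_neointima_um3 = v_n * vx,
       v_lumen_um3 = v_l * vx,
       v_neointima_plus_lumen_um3 = (v_n + v_l) * vx,
       nvi = nvi_percent(v_n, v_l))
}

#' Apparent thickness of an obliquely cut layer
#'
#' An oblique cut at `tilt_deg` from the perpendicular stretches a layer of
#' true thickness `t` to `t / cos(tilt)` in the section plane — the linear
#' measurement bias that motivates area- and volume-based indices.
#'
#' @param true_thickness um.
#' @param tilt_deg degrees in `[0, 90)`.
#' @return apparent thickness, um.
#' @export
oblique_thickness <- function(true_thickness, tilt_deg) {
  if (any(tilt_deg < 0) || any(tilt_deg >= 90))
    stop("tilt_deg must be in [0, 90)", call. = FALSE)
  true_thickness / cos(tilt_deg * pi / 180)
}

#' Maximal radial neointimal width of a label section
#'
#' Measures the apparent wall thickness the way a linear caliper measurement
#' would: rays are cast from the lumen centroid over a grid of directions
#' and the length of neointima crossed along each ray is accumulated; the
#' maximum over directions is returned. On an obliquely cut vessel this
#' maximum grows like `1 / cos(tilt)` along the stretch direction.
#'
#' @param section 2-D label image (matrix or label cross-section).
#' @param pixel_size um/pixel (default 1: width in pixels).
#' @param n_angles number of ray directions.
#' @param ray_step sampling step along rays, pixels.
#' @return maximal radial neointimal width in the units of `pixel_size`.
#' @export
radial_wall_width <- function(section, pixel_size = 1, n_angles = 360,
                              ray_step = 0.25) {
  if (inherits(section, "cross_section")) section <- section$image
  lum <- which(section == LBL_LUMEN, arr.ind = TRUE)
  ctr <- if (nrow(lum) > 0) colMeans(lum)
  else colMeans(which(section == LBL_NEOINTIMA, arr.ind = TRUE))
  ny <- nrow(section); nx <- ncol(section)
  rmax <- sqrt(ny^2 + nx^2)
  rr <- seq(0, rmax, by = ray_step)
  best <- 0
  for (a in seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]) {
    iy <- round(ctr[1] + rr * sin(a)); ix <- round(ctr[2] + rr * cos(a))
    ok <- iy >= 1 & iy <= ny & ix >= 1 & ix <= nx
    vals <- section[cbind(iy[ok], ix[ok])]
    w <- sum(vals == LBL_NEOINTIMA) * ray_step
    if (w > best) best <- w
  }
  best * pixel_size
}

#' Morphometry of a cross-section series
#'
#' Builds the standard per-section NI table from a series of label
#' cross-sections, plus segment-level voxel totals.
#'
#' @param series either a list from [perpendicular_series()] or a label
#'   [section_stack()] (conventional stack-plane analysis, arclength taken
#'   as section index times thickness).
#' @param provenance `"conventional_stack_plane"` or
#'   `"corrected_perpendicular"`.
#' @param pixel_size um/pixel override; defaults to the series' own.
#' @return An object of class `morphometry_result`: `per_section`
#'   data.frame (`arclength_um, neointimal_area_um2, luminal_area_um2,
#'   ni_percent`), `segment` list (voxel/area totals and `nvi`), and
#'   `provenance`. Sections with no vessel pixels are dropped (recorded in
#'   the `n_empty` field).
#' @export
morphometry_series <- function(series,
                               provenance = c("corrected_perpendicular",
                                              "conventional_stack_plane"),
                               pixel_size = NULL) {
  provenance <- match.arg(provenance)
  if (inherits(series, "section_stack")) {
    px <- if (is.null(pixel_size)) series$pixel_size_xy else pixel_size
    entries <- lapply(seq_along(series$sections), function(k)
      list(s = (k - 1) * series$section_thickness,
           img = series$sections[[k]]))
  } else {
    entries <- lapply(series, function(e) {
      img <- if (!is.null(e$labels)) e$labels$image else e$intensity$image
      list(s = e$s, img = img)
    })
    px <- if (is.null(pixel_size)) {
      first <- series[[1]]
      if (!is.null(first$labels)) first$labels$pixel_size
      else first$intensity$pixel_size
    } else pixel_size
  }
  rows <- lapply(entries, function(e) {
    n_neo <- sum(e$img == LBL_NEOINTIMA); n_lum <- sum(e$img == LBL_LUMEN)
    if (n_neo + n_lum == 0) return(NULL)
    data.frame(arclength_um = e$s,
               neointimal_area_um2 = n_neo * px^2,
               luminal_area_um2 = n_lum * px^2,
               ni_percent = ni(n_neo, n_lum))
  })
  keep <- !vapply(rows, is.null, logical(1))
  per <- do.call(rbind, rows[keep])
  v_n <- sum(per$neointimal_area_um2); v_l <- sum(per$luminal_area_um2)
  structure(list(per_section = per,
                 segment = list(v_neointima_area_um2 = v_n,
                                v_lumen_area_um2 = v_l,
                                nvi = nvi_percent(v_n, v_l)),
                 provenance = provenance,
                 n_empty = sum(!keep)),
            class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf("<morphometry_result> %s: %d sections, mean NI %.2f, NVI %.3f\n",
              x$provenance, nrow(x$per_section), mean(x$per_section$ni_percent),
              x$segment$nvi))
  invisible(x)
}

#' Compare conventional and corrected NI series
#'
#' Reproduces the standard full / proximal / distal comparison: per part it
#' reports mean and sd of each series and a paired t-test (t, df = n - 1,
#' two-sided p) of conventional against corrected NI, sections matched by
#' arclength order.
#'
#' @param conventional,corrected [morphometry_series()] results with equal
#'   section counts.
#' @param split_um proximal/distal boundary as arclength in um; default the
#'   arclength midpoint.
#' @return data.frame with rows `full`, `proximal`, `distal` and columns
#'   `n, mean_conventional, sd_conventional, mean_corrected, sd_corrected,
#'   t, df, p`.
#' @export
compare_series <- function(conventional, corrected, split_um = NULL) {
  a <- conventional$per_section; b <- corrected$per_section
  if (nrow(a) != nrow(b))
    stop(sprintf("section count mismatch: %d vs %d", nrow(a), nrow(b)),
         call. = FALSE)
  if (is.null(split_um)) split_um <- stats::median(b$arclength_um)
  parts <- list(full = rep(TRUE, nrow(b)),
                proximal = b$arclength_um <= split_um,
                distal = b$arclength_um > split_um)
  out <- lapply(names(parts), function(p) {
    sel <- parts[[p]]
    x <- a$ni_percent[sel]; y <- b$ni_percent[sel]
    if (sum(sel) >= 2 && stats::sd(x - y) > 0) {
      tt <- stats::t.test(x, y, paired = TRUE)
      tval <- unname(tt$statistic); df <- unname(tt$parameter)
      pval <- tt$p.value
    } else {
      tval <- 0; df <- sum(sel) - 1; pval <- 1
    }
    data.frame(part = p, n = sum(sel),
               mean_conventional = mean(x), sd_conventional = stats::sd(x),
               mean_corrected = mean(y), sd_corrected = stats::sd(y),
               t = tval, df = df, p = pval)
  })
  do.call(rbind, out)
}

#' Write a morphometry result as CSV
#'
#' One row per cross-section (`provenance, arclength_um,
#' area_neointima_um2, area_lumen_um2, ni_percent`) plus one segment summary
#' row carrying the NVI.
#'
#' @param result a [morphometry_series()] result.
#' @param path output CSV file.
#' @export
write_morphometry <- function(result, path) {
  per <- result$per_section
  df <- data.frame(provenance = result$provenance,
                   row = "section",
                   arclength_um = per$arclength_um,
                   area_neointima_um2 = per$neointimal_area_um2,
                   area_lumen_um2 = per$luminal_area_um2,
                   ni_percent = per$ni_percent)
  seg <- data.frame(provenance = result$provenance, row = "segment",
                    arclength_um = NA_real_,
                    area_neointima_um2 = result$segment$v_neointima_area_um2,
                    area_lumen_um2 = result$segment$v_lumen_area_um2,
                    ni_percent = round(result$segment$nvi, 3))
  utils::write.csv(rbind(df, seg), path, row.names = FALSE)
  invisible(path)
}
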