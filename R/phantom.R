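#' Synthetic vessel specification
#'
#' Describes an annular vessel phantom with analytic ground truth: a lumen of
#' (possibly varying) radius inside a neointimal annulus bounded by the outer
#' radius (the internal elastic lamina surrogate), embedded in tissue
#' background. The centerline is either a straight segment or a circular arc
#' lying in the z-y plane, parameterized by arclength so the lumen radius
#' profile has the same meaning for both shapes.
#'
#' The straight centerline runs along +z; the arc starts heading +z and
#' curves toward +y with the given arc radius. Intensities are dimensionless
#' in `[0, 1]`; additive Gaussian noise of sd `noise_sd` is applied when the
#' voxel volume is rendered.
#'
#' @param centerline_kind `"straight"` or `"circular_arc"`.
#' @param length_um straight centerline length, um (straight only).
#' @param arc_radius_um radius of the centerline arc, um (arc only); must
#'   exceed `outer_radius_um` so the vessel cannot self-intersect.
#' @param arc_angle_deg angular extent of the arc, degrees in (0, 180].
#' @param outer_radius_um external boundary of the neointima, um.
#' @param lumen_radius_um lumen radius: a scalar (constant profile) or a
#'   function of the arclength fraction `s` in `[0, 1]` returning um; must
#'   stay strictly inside `(0, outer_radius_um)`.
#' @param background_intensity,lumen_intensity,neointima_intensity class
#'   intensities in `[0, 1]`.
#' @param noise_sd additive per-voxel Gaussian noise sd (>= 0); models
#'   uncorrelated scanner noise.
#' @param texture_sd amplitude (sd) of a smooth 3-D random texture field
#'   added to all classes (>= 0, default 0); models tissue microstructure
#'   (cells, collagen bundles) that, unlike voxel noise, continues across
#'   neighboring sections and is what section-to-section registration of
#'   real tissue locks onto.
#' @param texture_scale_um correlation length of the texture field, um; a
#'   scalar or per-axis `(z, y, x)` lengths — fibrous tissue is anisotropic,
#'   with structures elongated along the fiber axis.
#' @param center_yx_um optional `(y, x)` um offset of the vessel from the
#'   volume center (straight vessels only); useful for multi-vessel scenes.
#' @return An object of class `vessel_spec`.
#' @export
vessel_spec <- function(centerline_kind = c("straight", "circular_arc"),
                        length_um = NULL, arc_radius_um = NULL,
                        arc_angle_deg = NULL, outer_radius_um,
                        lumen_radius_um,
                        background_intensity = 0.2,
                        lumen_intensity = 0.9,
                        neointima_intensity = 0.55,
                        noise_sd = 0, texture_sd = 0, texture_scale_um = 10,
                        center_yx_um = c(0, 0)) {
  centerline_kind <- match.arg(centerline_kind)
  if (!is.numeric(outer_radius_um) || outer_radius_um <= 0)
    stop("outer_radius_um must be > 0", call. = FALSE)
  rfun <- if (is.function(lumen_radius_um)) lumen_radius_um
          else { r0 <- as.numeric(lumen_radius_um); function(s) rep(r0, length(s)) }
  sg <- seq(0, 1, length.out = 101)
  rv <- rfun(sg)
  if (any(!is.finite(rv)) || any(rv <= 0) || any(rv >= outer_radius_um))
    stop("lumen radius profile must satisfy 0 < r(s) < outer_radius_um",
         call. = FALSE)
  if (centerline_kind == "straight") {
    if (is.null(length_um) || length_um <= 0)
      stop("straight vessels need length_um > 0", call. = FALSE)
  } else {
    if (is.null(arc_radius_um) || is.null(arc_angle_deg))
      stop("arc vessels need arc_radius_um and arc_angle_deg", call. = FALSE)
    if (arc_radius_um <= outer_radius_um)
      stop("arc_radius_um must exceed outer_radius_um (vessel may not self-intersect)",
           call. = FALSE)
    if (arc_angle_deg <= 0 || arc_angle_deg > 180)
      stop("arc_angle_deg must be in (0, 180]", call. = FALSE)
  }
  ints <- c(background_intensity, lumen_intensity, neointima_intensity)
  if (any(ints < 0) || any(ints > 1))
    stop("class intensities must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (texture_sd < 0 || any(texture_scale_um <= 0))
    stop("texture_sd must be >= 0 and texture_scale_um > 0", call. = FALSE)
  structure(list(centerline_kind = centerline_kind,
                 length_um = length_um,
                 arc_radius_um = arc_radius_um,
                 arc_angle_deg = arc_angle_deg,
                 outer_radius_um = outer_radius_um,
                 lumen_radius = rfun,
                 background_intensity = background_intensity,
                 lumen_intensity = lumen_intensity,
                 neointima_intensity = neointima_intensity,
                 noise_sd = noise_sd,
                 texture_sd = texture_sd,
                 texture_scale_um = texture_scale_um,
                 center_yx_um = as.numeric(center_yx_um)),
            class = "vessel_spec")
}

#' Total centerline arclength of a phantom, um
#' @param spec a [vessel_spec()].
#' @export
vessel_arclength <- function(spec) {
  if (spec$centerline_kind == "straight") spec$length_um
  else spec$arc_radius_um * spec$arc_angle_deg * pi / 180
}

#' Analytic Neointimal Index of a phantom cross-section
#'
#' The NI of the exact phantom geometry at arclength fraction `s`:
#' `100 (R^2 - r(s)^2) / R^2` with `R` the outer radius and `r` the lumen
#' radius profile, i.e. 100 x neointimal area / (neointimal + luminal area)
#' for the perfect perpendicular annulus.
#'
#' @param spec a [vessel_spec()].
#' @param s arclength fraction(s) in `[0, 1]`.
#' @return NI in percent (vectorized over `s`).
#' @export
analytic_ni <- function(spec, s) {
  if (any(s < 0 | s > 1)) stop("s must lie in [0, 1]", call. = FALSE)
  R <- spec$outer_radius_um
  r <- spec$lumen_radius(s)
  100 * (R^2 - r^2) / R^2
}

#' Analytic lumen and neointima volumes of a phantom, um^3
#'
#' Perpendicular cross-sections of the phantom are exact annuli centered on
#' the centerline, so both for straight segments and circular arcs the class
#' volumes are the arclength integrals of the cross-sectional areas
#' (for arcs this is the theorem of Pappus applied per annulus).
#'
#' @param spec a [vessel_spec()].
#' @param n_grid arclength quadrature points for varying lumen profiles.
#' @return list with `lumen_um3`, `neointima_um3`, `total_um3`.
#' @export
analytic_vessel_volume <- function(spec, n_grid = 4096) {
  L <- vessel_arclength(spec)
  sg <- seq(0, 1, length.out = n_grid)
  r2 <- spec$lumen_radius(sg)^2
  lumen <- pi * mean(r2) * L              # trapezoid on a uniform grid
  total <- pi * spec$outer_radius_um^2 * L
  list(lumen_um3 = lumen, neointima_um3 = total - lumen, total_um3 = total)
}

# Centerline point, tangent and radius at arclength fraction s, in the frame
# of a generated volume. Returns matrices (n x 3, (z,y,x) um).
phantom_centerline <- function(spec, geom, s) {
  if (spec$centerline_kind == "straight") {
    p <- cbind(geom$z0 + s * spec$length_um, geom$cy, geom$cx)
    tg <- matrix(rep(c(1, 0, 0), each = length(s)), ncol = 3)
  } else {
    phi <- s * spec$arc_angle_deg * pi / 180
    p <- cbind(geom$Cz + spec$arc_radius_um * sin(phi),
               geom$Cy - spec$arc_radius_um * cos(phi),
               geom$Cx)
    tg <- cbind(cos(phi), sin(phi), 0)
  }
  list(points = p, tangents = tg)
}

# Stationary band-limited unit-variance Gaussian field: voxel white noise
# box-smoothed to the given correlation length (scalar or per-axis
# (z, y, x) um), then standardized. Draws from the caller's RNG stream.
smooth_noise_field <- function(extent, spacing, scale_um) {
  scale_um <- rep_len(as.numeric(scale_um), 3)
  win <- pmax(1L, as.integer(round(scale_um / spacing)))
  win <- win + (1L - win %% 2L)             # next odd
  G <- array(stats::rnorm(prod(extent)), dim = extent)
  G <- box_smooth(G, win)
  (G - mean(G)) / stats::sd(G)
}

# Internal: placement of the phantom centerline inside a volume of physical
# extent ext (z,y,x um, voxel-center span).
phantom_geometry <- function(spec, ext) {
  if (spec$centerline_kind == "straight") {
    list(z0 = (ext[1] - spec$length_um) / 2,
         cy = ext[2] / 2 + spec$center_yx_um[1],
         cx = ext[3] / 2 + spec$center_yx_um[2])
  } else {
    alpha <- spec$arc_angle_deg * pi / 180
    Rc <- spec$arc_radius_um
    # bbox of the raw arc (Cz = Cy = 0): z in [zmin, zmax], y in [-Rc, ymax]
    zmin <- Rc * min(0, sin(alpha), if (alpha > pi / 2) 1 else NULL)
    zmax <- Rc * max(0, sin(alpha), if (alpha > pi / 2) 1 else NULL)
    ymax <- Rc * max(-1, -cos(alpha))
    R <- spec$outer_radius_um
    list(Cz = ext[1] / 2 - (zmin + zmax) / 2,
         Cy = ext[2] / 2 - (-Rc + ymax) / 2,
         Cx = ext[3] / 2)
  }
}

#' Render a vessel phantom as voxel data with ground-truth labels
#'
#' Rasterizes a [vessel_spec()] onto a regular grid. Voxel membership is
#' decided at the voxel center in physical (um) coordinates: a voxel is
#' lumen when its distance from the centerline is below the local lumen
#' radius, neointima in the annulus up to the outer radius, background
#' elsewhere. The intensity volume holds the class intensities plus additive
#' Gaussian noise (sd `noise_sd`) clipped to `[0, 1]`.
#'
#' @param spec a [vessel_spec()].
#' @param spacing `(z, y, x)` voxel spacing in um.
#' @param extent `(z, y, x)` voxel counts.
#' @param seed optional integer seed for the noise draw; when `NULL` the
#'   current RNG state is used.
#' @return list with `volume` ([vol3d()]) and `labels` ([label_volume()]).
#' @export
generate_vessel_volume <- function(spec, spacing, extent, seed = NULL) {
  spacing <- as.numeric(spacing); extent <- as.integer(extent)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be 3 positive values", call. = FALSE)
  if (length(extent) != 3 || any(extent < 2))
    stop("extent must be 3 voxel counts >= 2", call. = FALSE)
  ext <- (extent - 1) * spacing
  geom <- phantom_geometry(spec, ext)
  R <- spec$outer_radius_um

  # containment check with >= 1 voxel margin; report the first bad arclength
  sg <- seq(0, 1, length.out = 257)
  cl <- phantom_centerline(spec, geom, sg)$points
  lo <- sweep(cl, 2, rep(R, 3), "-"); hi <- sweep(cl, 2, rep(R, 3), "+")
  bad <- which(lo[, 1] < spacing[1] - 1e-9 | hi[, 1] > ext[1] - spacing[1] + 1e-9 |
               lo[, 2] < spacing[2] - 1e-9 | hi[, 2] > ext[2] - spacing[2] + 1e-9 |
               lo[, 3] < spacing[3] - 1e-9 | hi[, 3] > ext[3] - spacing[3] + 1e-9)
  if (spec$centerline_kind == "straight") {
    # a straight vessel may run through the block (no end caps inside the
    # volume); only the annulus needs the in-plane margin
    bad <- which(lo[, 2] < spacing[2] - 1e-9 | hi[, 2] > ext[2] - spacing[2] + 1e-9 |
                 lo[, 3] < spacing[3] - 1e-9 | hi[, 3] > ext[3] - spacing[3] + 1e-9)
  }
  if (length(bad) > 0)
    stop(sprintf("vessel exceeds the volume extent at arclength %.3f um",
                 sg[bad[1]] * vessel_arclength(spec)), call. = FALSE)

  nz <- extent[1]; ny <- extent[2]; nx <- extent[3]
  zc <- (seq_len(nz) - 1) * spacing[1]
  yc <- (seq_len(ny) - 1) * spacing[2]
  xc <- (seq_len(nx) - 1) * spacing[3]
  lab <- array(0L, dim = c(nz, ny, nx))

  if (spec$centerline_kind == "straight") {
    r2 <- outer((yc - geom$cy)^2, (xc - geom$cx)^2, "+")
    in_outer <- r2 < R^2
    # axial membership is half-open [z0, z1) so stacked segments tile and
    # voxel-center counts are unbiased along the axis
    z1 <- geom$z0 + spec$length_um
    for (k in seq_len(nz)) {
      if (zc[k] < geom$z0 || zc[k] >= z1) next
      s <- (zc[k] - geom$z0) / spec$length_um
      rl <- spec$lumen_radius(s)
      sl <- array(0L, dim = c(ny, nx))
      sl[in_outer] <- 2L
      sl[r2 < rl^2] <- 1L
      lab[k, , ] <- sl
    }
  } else {
    alpha <- spec$arc_angle_deg * pi / 180
    Rc <- spec$arc_radius_um
    dx2 <- (xc - geom$Cx)^2
    for (k in seq_len(nz)) {
      a <- zc[k] - geom$Cz
      b <- yc - geom$Cy
      rho <- sqrt(a^2 + b^2)
      phi <- atan2(a, -b)
      inarc <- phi >= 0 & phi < alpha & rho > 0
      if (!any(inarc)) next
      dring2 <- (rho - Rc)^2                     # per y
      d2 <- outer(dring2, dx2, "+")              # (y, x)
      rl <- spec$lumen_radius(pmin(pmax(phi / alpha, 0), 1))
      sl <- array(0L, dim = c(ny, nx))
      sl[inarc & (d2 < R^2)] <- 2L               # recycle inarc down columns
      sl[inarc & (d2 < rl^2)] <- 1L
      lab[k, , ] <- sl
    }
  }

  ints <- c(spec$background_intensity, spec$lumen_intensity,
            spec$neointima_intensity)
  vol <- array(ints[lab + 1L], dim = dim(lab))
  if (spec$noise_sd > 0 || spec$texture_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
    }
    if (spec$texture_sd > 0)
      vol <- vol + spec$texture_sd *
        smooth_noise_field(dim(lab), spacing, spec$texture_scale_um)
    if (spec$noise_sd > 0)
      vol <- vol + array(stats::rnorm(length(vol), 0, spec$noise_sd), dim(vol))
    vol[vol < 0] <- 0; vol[vol > 1] <- 1
  }
  list(volume = vol3d(vol, spacing),
       labels = label_volume(lab, spacing),
       geometry = geom)
}

#' Sectioning plan for the virtual microtome
#'
#' Describes how a volume is cut into serial sections: in-plane pixel size
#' (default 0.369 um/pixel, the 20x whole-slide scan resolution), section
#' thickness (default 4 um), a tilt between the cutting-plane normal and the
#' vessel axis at the origin, and per-section random rigid misplacement
#' (normal in-plane translation jitter and rotation) drawn from one RNG
#' stream seeded explicitly, in section order.
#'
#' @param pixel_size_xy um/pixel, > 0.
#' @param section_thickness um, > 0.
#' @param tilt_deg degrees between the cutting normal and +z, in `[0, 90)`.
#' @param tilt_azimuth_deg in-plane direction the normal tilts toward:
#'   0 = +y (the plane a circular-arc phantom curves in), 180 = -y.
#' @param jitter_sd_px per-section translation sd, pixels.
#' @param rotation_sd_deg per-section rotation sd, degrees.
#' @param seed integer RNG seed for the misplacement draws.
#' @param n_sections optional fixed number of sections; default spans the
#'   volume along the cutting normal.
#' @param size_px optional section edge length in pixels; default covers the
#'   volume's in-plane footprint.
#' @return An object of class `sectioning_spec`.
#' @export
sectioning_spec <- function(pixel_size_xy = 0.369, section_thickness = 4,
                            tilt_deg = 0, tilt_azimuth_deg = 0,
                            jitter_sd_px = 0, rotation_sd_deg = 0,
                            seed = 1L, n_sections = NULL, size_px = NULL) {
  if (pixel_size_xy <= 0) stop("pixel_size_xy must be > 0", call. = FALSE)
  if (section_thickness <= 0) stop("section_thickness must be > 0", call. = FALSE)
  if (tilt_deg < 0 || tilt_deg >= 90)
    stop("tilt_deg must be in [0, 90)", call. = FALSE)
  if (jitter_sd_px < 0 || rotation_sd_deg < 0)
    stop("jitter_sd_px and rotation_sd_deg must be >= 0", call. = FALSE)
  structure(list(pixel_size_xy = pixel_size_xy,
                 section_thickness = section_thickness,
                 tilt_deg = tilt_deg, tilt_azimuth_deg = tilt_azimuth_deg,
                 jitter_sd_px = jitter_sd_px,
                 rotation_sd_deg = rotation_sd_deg,
                 seed = as.integer(seed), n_sections = n_sections,
                 size_px = size_px),
            class = "sectioning_spec")
}

# Cutting normal of a sectioning plan, (z, y, x) unit vector.
sectioning_normal <- function(plan) {
  tau <- plan$tilt_deg * pi / 180
  az <- plan$tilt_azimuth_deg * pi / 180
  c(cos(tau), sin(tau) * cos(az), sin(tau) * sin(az))
}

#' Virtually section a volume into a serial stack
#'
#' Simulates physical sectioning: the volume is resampled on planes
#' perpendicular to a (possibly tilted) cutting axis, one section per
#' `section_thickness` step, and each section is then perturbed by a random
#' rigid transform (translation jitter and rotation about the section
#' center). The exact inverse transforms are returned as ground truth so
#' registration can be validated against them. Label sections are perturbed
#' identically with nearest-neighbor interpolation.
#'
#' @param volume a [vol3d()] (single channel).
#' @param labels optional [label_volume()] sharing the volume's grid.
#' @param plan a [sectioning_spec()].
#' @return list with `stack` (intensity [section_stack()]), `labels` (label
#'   [section_stack()] or `NULL`), `transforms` (data.frame
#'   `section_index, dx_px, dy_px, theta_deg` of the ground-truth inverse
#'   transforms, see [rigid2d()]), `applied` (the forward perturbations),
#'   `centers_um` (per-section plane centers), `normal` and `frame`.
#' @export
section_volume <- function(volume, labels = NULL, plan) {
  stopifnot(inherits(volume, "vol3d"), inherits(plan, "sectioning_spec"))
  if (length(dim(volume$data)) != 4) nch <- 1L else nch <- dim(volume$data)[4]
  n <- sectioning_normal(plan)
  fr <- plane_frame(n)
  ext <- (dim(volume$data)[1:3] - 1) * volume$spacing
  c0 <- volume$origin + ext / 2
  corners <- as.matrix(expand.grid(c(0, ext[1]), c(0, ext[2]), c(0, ext[3])))
  rel <- sweep(corners, 2, ext / 2, "-")
  proj_n <- rel %*% n
  if (is.null(plan$n_sections)) {
    t0 <- min(proj_n) + plan$section_thickness / 2
    tk <- seq(t0, max(proj_n), by = plan$section_thickness)
  } else {
    k <- plan$n_sections
    tk <- (seq_len(k) - (k + 1) / 2) * plan$section_thickness
  }
  size <- plan$size_px
  if (is.null(size)) {
    half <- max(abs(rel %*% fr$f1), abs(rel %*% fr$f2))
    size <- 2L * as.integer(ceiling(half / plan$pixel_size_xy))
  }
  has_seed <- !is.null(plan$seed)
  if (has_seed) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(plan$seed)
  }
  ctr_px <- (size + 1) / 2                      # 1-based section center
  secs <- vector("list", length(tk))
  lsecs <- if (!is.null(labels)) vector("list", length(tk)) else NULL
  applied <- vector("list", length(tk))
  centers <- matrix(NA_real_, length(tk), 3)
  for (i in seq_along(tk)) {
    ctr <- c0 + tk[i] * n
    centers[i, ] <- ctr
    img <- resample_plane_raw(volume, ctr, fr, size, plan$pixel_size_xy,
                              nearest = FALSE)
    dx <- stats::rnorm(1, 0, plan$jitter_sd_px)
    dy <- stats::rnorm(1, 0, plan$jitter_sd_px)
    th <- stats::rnorm(1, 0, plan$rotation_sd_deg)
    P <- rigid2d(dx, dy, th, center = c(ctr_px, ctr_px))
    applied[[i]] <- P
    secs[[i]] <- apply_rigid2d(img, P, interpolation = "linear")
    if (!is.null(labels)) {
      lim <- resample_plane_raw(labels, ctr, fr, size, plan$pixel_size_xy,
                                nearest = TRUE)
      lim <- apply_rigid2d(lim, P, interpolation = "nearest")
      storage.mode(lim) <- "integer"
      lsecs[[i]] <- lim
    }
  }
  inv <- lapply(applied, invert_rigid2d)
  tf <- data.frame(section_index = seq_along(tk),
                   dx_px = vapply(inv, `[[`, 0, "dx"),
                   dy_px = vapply(inv, `[[`, 0, "dy"),
                   theta_deg = vapply(inv, `[[`, 0, "theta"))
  list(stack = section_stack(secs, plan$pixel_size_xy, plan$section_thickness),
       labels = if (!is.null(labels))
         section_stack(lsecs, plan$pixel_size_xy, plan$section_thickness),
       transforms = tf, applied = applied,
       centers_um = centers, normal = n, frame = fr)
}
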