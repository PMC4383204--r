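# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code under fixed seeds; nothing is read from disk.

# Standard straight annular phantom (outer 50 um, lumen 25 um -> NI 75).
standard_straight_spec <- function(...)
  vessel_spec("straight", length_um = 95, outer_radius_um = 50,
              lumen_radius_um = 25, ...)

# Small through-running vessel: spans the whole z extent, so the only class
# boundaries are the two cylinder walls (no artificial end caps).
through_vessel <- function(noise_sd = 0, seed = NULL) {
  spec <- vessel_spec("straight", length_um = 50, outer_radius_um = 16,
                      lumen_radius_um = 8, noise_sd = noise_sd)
  generate_vessel_volume(spec, c(2, 1, 1), c(24, 40, 40), seed = seed)
}

# Two parallel vessels in fibrous textured myocardium: the registration
# scene. Texture is anisotropic (elongated along z like myocyte bundles) so
# neighboring 4 um sections share in-plane structure, which is what real
# section-to-section alignment locks onto.
two_vessel_scene <- function(noise_sd = 0.02, texture_sd = 0.12,
                             texture_scale = c(40, 6, 6), seed = 99) {
  sa <- vessel_spec("straight", length_um = 130, outer_radius_um = 20,
                    lumen_radius_um = 10, center_yx_um = c(-15, -12),
                    noise_sd = noise_sd, texture_sd = texture_sd,
                    texture_scale_um = texture_scale)
  sb <- vessel_spec("straight", length_um = 130, outer_radius_um = 14,
                    lumen_radius_um = 7, center_yx_um = c(16, 14))
  ga <- generate_vessel_volume(sa, c(2, 1, 1), c(68, 100, 100), seed = seed)
  gb <- generate_vessel_volume(sb, c(2, 1, 1), c(68, 100, 100))
  lab <- ga$labels$data
  sel <- gb$labels$data > 0
  lab[sel] <- gb$labels$data[sel]
  v <- ga$volume$data
  ints <- c(NA, 0.9, 0.55)
  v[sel] <- ints[gb$labels$data[sel] + 1L]
  list(vol = vol3d(v, c(2, 1, 1)), lab = label_volume(lab, c(2, 1, 1)))
}

# 6-neighbor erosion mask: TRUE where a voxel and all its in-bounds
# 6-neighbors share the same label (used for scripted seed placement).
erode_labels <- function(a) {
  nz <- dim(a)[1]; ny <- dim(a)[2]; nx <- dim(a)[3]
  ok <- array(TRUE, dim(a))
  ok[2:nz, , ] <- ok[2:nz, , ] & (a[2:nz, , ] == a[1:(nz - 1), , ])
  ok[1:(nz - 1), , ] <- ok[1:(nz - 1), , ] & (a[1:(nz - 1), , ] == a[2:nz, , ])
  ok[, 2:ny, ] <- ok[, 2:ny, ] & (a[, 2:ny, ] == a[, 1:(ny - 1), ])
  ok[, 1:(ny - 1), ] <- ok[, 1:(ny - 1), ] & (a[, 1:(ny - 1), ] == a[, 2:ny, ])
  ok[, , 2:nx] <- ok[, , 2:nx] & (a[, , 2:nx] == a[, , 1:(nx - 1)])
  ok[, , 1:(nx - 1)] <- ok[, , 1:(nx - 1)] & (a[, , 1:(nx - 1)] == a[, , 2:nx])
  ok
}

# Scripted seed placement: n random voxels per class from the eroded
# ground-truth core.
scripted_seeds <- function(gt, n_per_class = 10, seed = 42) {
  core <- erode_labels(gt)
  set.seed(seed)
  seed_set(do.call(rbind, lapply(0:2, function(cl) {
    idx <- which(gt == cl & core, arr.ind = TRUE)
    idx <- idx[sample(nrow(idx), n_per_class), , drop = FALSE]
    data.frame(z = idx[, 1], y = idx[, 2], x = idx[, 3], class = cl)
  })))
}

dice_per_class <- function(got, want)
  vapply(0:2, function(cl) {
    a <- got == cl; b <- want == cl
    2 * sum(a & b) / (sum(a) + sum(b))
  }, numeric(1))

# Independent brute-force oracle for the seeded geodesic labeling: per-class
# Bellman-Ford relaxation to a fixed point, then argmin with lowest-class
# ties. Mirrors the documented cost definition with plain R loops.
oracle_segment <- function(vol, spacing, seeds, beta, smooth_window = 1L,
                           eps = 1e-6) {
  d <- dim(vol); nz <- d[1]; ny <- d[2]; nx <- d[3]
  v <- vol
  if (smooth_window > 1L) {
    half <- smooth_window %/% 2L
    for (axis in 1:3) {
      nv <- array(0, d)
      for (z in 1:nz) for (y in 1:ny) for (x in 1:nx) {
        nv[z, y, x] <- switch(axis,
          mean(v[max(1, z - half):min(nz, z + half), y, x]),
          mean(v[z, max(1, y - half):min(ny, y + half), x]),
          mean(v[z, y, max(1, x - half):min(nx, x + half)]))
      }
      v <- nv
    }
  }
  grad <- array(0, d)
  for (z in 1:nz) for (y in 1:ny) for (x in 1:nx) {
    acc <- 0
    zp <- min(nz, z + 1); zm <- max(1, z - 1)
    if (zp > zm) acc <- acc + ((v[zp, y, x] - v[zm, y, x]) /
                                 ((zp - zm) * spacing[1]))^2
    yp <- min(ny, y + 1); ym <- max(1, y - 1)
    if (yp > ym) acc <- acc + ((v[z, yp, x] - v[z, ym, x]) /
                                 ((yp - ym) * spacing[2]))^2
    xp <- min(nx, x + 1); xm <- max(1, x - 1)
    if (xp > xm) acc <- acc + ((v[z, y, xp] - v[z, y, xm]) /
                                 ((xp - xm) * spacing[3]))^2
    grad[z, y, x] <- sqrt(acc)
  }
  w_edge <- function(a, b, h)
    eps * h + (v[a[1], a[2], a[3]] - v[b[1], b[2], b[3]])^2 +
    beta * 0.5 * (grad[a[1], a[2], a[3]] + grad[b[1], b[2], b[3]]) * h
  nbrs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1))
  hvec <- spacing[c(1, 1, 2, 2, 3, 3)]
  dists <- lapply(0:2, function(cl) {
    D <- array(Inf, d)
    sel <- seeds[seeds$class == cl, , drop = FALSE]
    for (i in seq_len(nrow(sel))) D[sel$z[i], sel$y[i], sel$x[i]] <- 0
    repeat {
      changed <- FALSE
      for (z in 1:nz) for (y in 1:ny) for (x in 1:nx) for (k in 1:6) {
        p <- c(z, y, x) + nbrs[k, ]
        if (p[1] < 1 || p[1] > nz || p[2] < 1 || p[2] > ny ||
            p[3] < 1 || p[3] > nx) next
        cand <- D[p[1], p[2], p[3]] + w_edge(c(z, y, x), p, hvec[k])
        if (cand < D[z, y, x]) {
          D[z, y, x] <- cand
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    D
  })
  lab <- array(0L, d)
  for (z in 1:nz) for (y in 1:ny) for (x in 1:nx)
    lab[z, y, x] <- which.min(c(dists[[1]][z, y, x], dists[[2]][z, y, x],
                                dists[[3]][z, y, x])) - 1L
  for (i in seq_len(nrow(seeds)))
    lab[seeds$z[i], seeds$y[i], seeds$x[i]] <- seeds$class[i]
  lab
}

# Random oracle instance generator (dims <= 8, continuous intensities so
# exact cost ties cannot occur away from seeds).
random_segment_instance <- function() {
  d <- sample(3:8, 3, replace = TRUE)
  spacing <- sample(list(c(4, 0.369, 0.369), c(2, 1, 1), c(1, 1, 1)), 1)[[1]]
  vol <- array(runif(prod(d)), d)
  ns <- sample(3:6, 1)
  idx <- sample(prod(d), ns)
  seeds <- data.frame(
    z = (idx - 1) %% d[1] + 1,
    y = ((idx - 1) %/% d[1]) %% d[2] + 1,
    x = (idx - 1) %/% (d[1] * d[2]) + 1,
    class = c(0L, 1L, 2L, sample(0:2, ns - 3, replace = TRUE)))
  list(vol = vol, spacing = spacing, seeds = seeds,
       beta = sample(c(0, 0.5, 1, 2), 1),
       smooth_window = sample(c(1L, 3L), 1))
}

# Per-section recovery errors of stack transforms against the perturbations
# actually applied by section_volume (residual transform after undoing).
stack_recovery_errors <- function(est, applied, reference) {
  truth <- lapply(seq_along(applied), function(k)
    compose_rigid2d(applied[[reference]], invert_rigid2d(applied[[k]])))
  t(vapply(seq_along(est), function(k) {
    E <- compose_rigid2d(est[[k]], invert_rigid2d(truth[[k]]))
    c(px = sqrt(E$dx^2 + E$dy^2), deg = abs(E$theta))
  }, c(px = 0, deg = 0)))
}
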