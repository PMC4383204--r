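test_that("plane frames are orthonormal and right-handed for any normal", {
  set.seed(17)
  normals <- rbind(diag(3), -diag(3),
                   matrix(stats::rnorm(30), ncol = 3))
  for (i in seq_len(nrow(normals))) {
    n <- normals[i, ]
    if (sqrt(sum(n^2)) < 1e-3) next
    fr <- plane_frame(n)
    expect_equal(sum(fr$normal^2), 1, tolerance = 1e-9)
    expect_equal(sum(fr$f1^2), 1, tolerance = 1e-9)
    expect_equal(sum(fr$f2^2), 1, tolerance = 1e-9)
    expect_lt(abs(sum(fr$normal * fr$f1)), 1e-9)
    expect_lt(abs(sum(fr$normal * fr$f2)), 1e-9)
    expect_lt(abs(sum(fr$f1 * fr$f2)), 1e-9)
    cross <- c(fr$normal[2] * fr$f1[3] - fr$normal[3] * fr$f1[2],
               fr$normal[3] * fr$f1[1] - fr$normal[1] * fr$f1[3],
               fr$normal[1] * fr$f1[2] - fr$normal[2] * fr$f1[1])
    expect_equal(cross, fr$f2, tolerance = 1e-9)
  }
  expect_error(plane_frame(c(0, 0, 0)), "zero normal")
})

test_that("an axis-aligned plane through voxel centers reproduces the slice", {
  spec <- vessel_spec("straight", length_um = 95, outer_radius_um = 30,
                      lumen_radius_um = 15)
  g <- generate_vessel_volume(spec, c(1, 1, 1), c(100, 80, 80))
  cs <- resample_plane(g$labels, center = c(50, 39.5, 39.5),
                       normal = c(1, 0, 0), size = 80, pixel_size = 1)
  expect_identical(cs$image, g$labels$data[51, , ])
  expect_true(all(cs$image %in% 0:2))
})

test_that("straight-tube centerlines have axial tangents and full arclength", {
  spec <- vessel_spec("straight", length_um = 95, outer_radius_um = 30,
                      lumen_radius_um = 15)
  g <- generate_vessel_volume(spec, c(1, 1, 1), c(100, 80, 80))
  cl <- extract_centerline(g$labels)
  expect_lt(max(abs(sweep(cl$tangents, 2, c(1, 0, 0)))), 1e-6)
  expect_equal(max(cl$arclength), 95, tolerance = 2.5)
  expect_equal(cl$arclength[1], 0)
  expect_true(all(diff(cl$arclength) > 0))
})

test_that("arc centerline tangents match the analytic derivative", {
  # a moderately curved arc: per-slice centroids are valid while the axis
  # stays within ~45 degrees of the stack normal
  arc <- vessel_spec("circular_arc", arc_radius_um = 200, arc_angle_deg = 40,
                     outer_radius_um = 50, lumen_radius_um = 25)
  g <- generate_vessel_volume(arc, c(1, 1, 1), c(250, 180, 110))
  cl <- extract_centerline(g$labels)
  geom <- g$geometry
  phi <- atan2(cl$points[, 1] - geom$Cz, -(cl$points[, 2] - geom$Cy))
  want <- cbind(cos(phi), sin(phi), 0)
  ang <- acos(pmin(1, rowSums(want * cl$tangents))) * 180 / pi
  # exclude one outer radius at each end: the flat end caps pull the
  # per-slice centroids off the axis there
  interior <- cl$arclength >= 50 & cl$arclength <= max(cl$arclength) - 50
  expect_lt(max(ang[interior]), 2)
})

test_that("multiple lumen branches in one slice are refused with guidance", {
  sa <- vessel_spec("straight", length_um = 46, outer_radius_um = 10,
                    lumen_radius_um = 5, center_yx_um = c(-10, 0))
  sb <- vessel_spec("straight", length_um = 46, outer_radius_um = 10,
                    lumen_radius_um = 5, center_yx_um = c(10, 0))
  ga <- generate_vessel_volume(sa, c(2, 1, 1), c(24, 60, 40))
  gb <- generate_vessel_volume(sb, c(2, 1, 1), c(24, 60, 40))
  lab <- ga$labels$data
  sel <- gb$labels$data > 0
  lab[sel] <- gb$labels$data[sel]
  expect_error(extract_centerline(label_volume(lab, c(2, 1, 1))),
               "unbranched")
})

test_that("perpendicular reslicing turns a tilted tube ellipse into a circle", {
  spec <- vessel_spec("straight", length_um = 190, outer_radius_um = 50,
                      lumen_radius_um = 25)
  g <- generate_vessel_volume(spec, c(1, 1, 1), c(200, 120, 120))
  plan <- sectioning_spec(pixel_size_xy = 1, section_thickness = 4,
                          tilt_deg = 60, seed = 1, size_px = 260)
  cut <- section_volume(g$volume, g$labels, plan)
  mid <- cut$labels$sections[[length(cut$labels) %/% 2]]
  idx <- which(mid > 0, arr.ind = TRUE)
  ratio_stack <- sqrt(eigen(stats::cov(idx))$values)
  expect_equal(ratio_stack[1] / ratio_stack[2], 2, tolerance = 0.1)
  # reslice perpendicular to the centerline tangent: a circle again
  cl <- extract_centerline(g$labels)
  k <- which.min(abs(cl$arclength - max(cl$arclength) / 2))
  cs <- resample_plane(g$labels, cl$points[k, ], cl$tangents[k, ],
                       size = 130, pixel_size = 1)
  idx2 <- which(cs$image > 0, arr.ind = TRUE)
  ratio_perp <- sqrt(eigen(stats::cov(idx2))$values)
  expect_equal(ratio_perp[1] / ratio_perp[2], 1, tolerance = 0.05)
  # and the annulus area matches pi (R^2 - r^2) within 3%
  area <- sum(cs$image == 2)
  expect_equal(area, pi * (50^2 - 25^2), tolerance = 0.03)
})

test_that("perpendicular series has the documented count and constant normals", {
  spec <- vessel_spec("straight", length_um = 112, outer_radius_um = 30,
                      lumen_radius_um = 15)
  g <- generate_vessel_volume(spec, c(1, 1, 1), c(118, 80, 80))
  cl <- extract_centerline(g$labels)
  # 108 um of tube stepped at 4 um -> 28 cross-sections
  cl_crop <- centerline(cl$points[cl$arclength <= 108.01, ],
                        cl$tangents[cl$arclength <= 108.01, ])
  ser <- perpendicular_series(NULL, g$labels, cl_crop, step = 4,
                              size = 70, pixel_size = 1)
  expect_length(ser, 28)
  for (e in ser[c(1, 14, 28)])
    expect_equal(e$labels$normal, c(1, 0, 0), tolerance = 1e-6)
  nis <- vapply(ser, function(e) ni_from_label_section(e$labels)$ni,
                numeric(1))
  expect_true(all(abs(nis - 75) < 2))
})

test_that("resampling is invariant under a rotation of the volume", {
  g <- through_vessel(noise_sd = 0.04, seed = 23)
  v <- g$volume
  # rotate the volume a quarter turn in the (y, x) plane: y' = x, x' = -y
  rot_data <- aperm(v$data[, , dim(v$data)[3]:1], c(1, 3, 2))
  vr <- vol3d(rot_data, v$spacing[c(1, 3, 2)])
  ext <- (dim(v$data) - 1) * v$spacing
  ctr <- ext / 2
  ctr_r <- (dim(rot_data) - 1) * vr$spacing / 2
  n <- c(0.6, 0.64, 0.48); n <- n / sqrt(sum(n^2))
  n_r <- c(n[1], n[3], -n[2])
  cs <- resample_plane(v, ctr, n, size = 24, pixel_size = 1)
  cs_r <- resample_plane(vr, ctr_r, n_r, size = 24, pixel_size = 1)
  # frames differ by an in-plane rotation/flip; compare rotation-invariant
  # summaries of the sampled plane
  expect_equal(mean(cs$image), mean(cs_r$image), tolerance = 0.02)
  expect_equal(stats::sd(cs$image), stats::sd(cs_r$image), tolerance = 0.02)
  expect_equal(stats::quantile(cs$image, c(0.1, 0.5, 0.9)),
               stats::quantile(cs_r$image, c(0.1, 0.5, 0.9)),
               tolerance = 0.05)
})

test_that("centerline CSV export carries positions, tangents and arclength", {
  g <- through_vessel()
  cl <- extract_centerline(g$labels)
  p <- file.path(tempdir(), "cl.csv")
  write_centerline(cl, p)
  df <- utils::read.csv(p)
  expect_named(df, c("arclength_um", "z_um", "y_um", "x_um",
                     "tz", "ty", "tx"))
  expect_equal(nrow(df), nrow(cl$points))
  expect_equal(df$arclength_um, cl$arclength)
})
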