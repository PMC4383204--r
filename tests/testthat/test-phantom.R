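test_that("straight phantom renders an exact annulus with analytic NI 75", {
  spec <- standard_straight_spec()
  g <- generate_vessel_volume(spec, c(1, 1, 1), c(100, 110, 110))
  expect_s3_class(g$labels, "label_volume")
  # every slice inside the vessel is a circular annulus around the center
  mid <- g$labels$data[50, , ]
  idx <- which(mid > 0, arr.ind = TRUE)
  r <- sqrt((idx[, 1] - 55.5)^2 + (idx[, 2] - 55.5)^2)
  expect_true(all(r[mid[idx] == 1] < 25))
  expect_true(all(r[mid[idx] == 2] >= 25 - 1e-9 & r[mid[idx] == 2] < 50))
  expect_equal(analytic_ni(spec, 0.5), 75)
  expect_equal(ni_from_label_section(mid)$ni, 75, tolerance = 0.01)
  # piecewise-constant intensities without noise
  expect_length(unique(as.numeric(g$volume$data)), 3)
})

test_that("analytic NI handles occlusion limits and inverts round trip", {
  spec0 <- vessel_spec("straight", length_um = 10, outer_radius_um = 50,
                       lumen_radius_um = 1e-6)
  expect_equal(analytic_ni(spec0, 0), 100, tolerance = 1e-9)
  q <- 59.705
  specq <- vessel_spec("straight", length_um = 10, outer_radius_um = 50,
                       lumen_radius_um = 50 * sqrt(1 - q / 100))
  expect_equal(analytic_ni(specq, 0.3), q, tolerance = 1e-9)
  expect_equal(analytic_ni(standard_straight_spec(), c(0, 1)), c(75, 75))
  expect_error(analytic_ni(standard_straight_spec(), 1.2), "0, 1")
})

test_that("label volumes match closed-form class volumes and converge with spacing", {
  spec <- standard_straight_spec()
  av <- analytic_vessel_volume(spec)
  errs <- vapply(c(2, 1), function(h) {
    g <- generate_vessel_volume(spec, c(h, h, h), round(c(100, 110, 110) / h))
    cv <- class_volumes(g$labels)
    abs(cv$volume_um3[cv$name == "lumen"] / av$lumen_um3 - 1)
  }, numeric(1))
  # O(h) bound with a fixed constant: |err| <= 2% per um of spacing
  expect_lt(errs[1], 0.02 * 2)
  expect_lt(errs[2], 0.02)
})

test_that("arc phantom voxel volume matches the revolved-annulus closed form", {
  arc <- vessel_spec("circular_arc", arc_radius_um = 200, arc_angle_deg = 90,
                     outer_radius_um = 50, lumen_radius_um = 25)
  g <- generate_vessel_volume(arc, c(2, 2, 2), c(160, 160, 56))
  cv <- class_volumes(g$labels)
  av <- analytic_vessel_volume(arc)
  expect_equal(cv$volume_um3[cv$name == "neointima"], av$neointima_um3,
               tolerance = 0.03)
  expect_equal(cv$volume_um3[cv$name == "lumen"], av$lumen_um3,
               tolerance = 0.03)
})

test_that("a vessel exceeding the extent reports the offending arclength", {
  spec <- vessel_spec("straight", length_um = 50, outer_radius_um = 56,
                      lumen_radius_um = 25)
  expect_error(generate_vessel_volume(spec, c(1, 1, 1), c(100, 110, 110)),
               "arclength")
  expect_error(
    generate_vessel_volume(
      vessel_spec("circular_arc", arc_radius_um = 500, arc_angle_deg = 90,
                  outer_radius_um = 50, lumen_radius_um = 25),
      c(1, 1, 1), c(100, 110, 110)),
    "arclength")
})

test_that("vessel_spec rejects inconsistent geometry", {
  expect_error(vessel_spec("straight", length_um = 10, outer_radius_um = 20,
                           lumen_radius_um = 25), "lumen radius")
  expect_error(vessel_spec("circular_arc", arc_radius_um = 40,
                           arc_angle_deg = 90, outer_radius_um = 50,
                           lumen_radius_um = 25), "self-intersect")
})

test_that("untilted unperturbed sectioning reproduces axis-aligned slices", {
  spec <- vessel_spec("straight", length_um = 95, outer_radius_um = 30,
                      lumen_radius_um = 15)
  g <- generate_vessel_volume(spec, c(1, 1, 1), c(100, 80, 80))
  plan <- sectioning_spec(pixel_size_xy = 1, section_thickness = 1,
                          jitter_sd_px = 0, rotation_sd_deg = 0, seed = 7,
                          n_sections = 99, size_px = 80)
  cut <- section_volume(g$volume, g$labels, plan)
  expect_length(cut$stack, 99)
  expect_true(all(abs(as.matrix(cut$transforms[, 2:4])) < 1e-12))
  k <- 50
  kz <- round(cut$centers_um[k, 1]) + 1
  expect_identical(cut$labels$sections[[k]], g$labels$data[kz, , ])
  cut2 <- section_volume(g$volume, g$labels, plan)
  expect_identical(cut$stack$sections, cut2$stack$sections)
  expect_identical(cut$transforms, cut2$transforms)
})

test_that("a 60-degree tilt stretches the vessel outline into a 2:1 ellipse", {
  spec <- vessel_spec("straight", length_um = 190, outer_radius_um = 50,
                      lumen_radius_um = 25)
  g <- generate_vessel_volume(spec, c(1, 1, 1), c(200, 120, 120))
  plan <- sectioning_spec(pixel_size_xy = 1, section_thickness = 4,
                          tilt_deg = 60, seed = 1, size_px = 260)
  cut <- section_volume(g$volume, g$labels, plan)
  mid <- cut$labels$sections[[length(cut$labels) %/% 2]]
  idx <- which(mid > 0, arr.ind = TRUE)
  ev <- eigen(stats::cov(idx))$values
  expect_equal(sqrt(ev[1] / ev[2]), 2, tolerance = 0.08)
})

test_that("restacking with the ground-truth inverse transforms undoes jitter", {
  g <- through_vessel(noise_sd = 0.03, seed = 5)
  # jitter only, nearest path: exact inversion
  plan <- sectioning_spec(pixel_size_xy = 1, section_thickness = 2,
                          jitter_sd_px = 4, rotation_sd_deg = 0, seed = 21,
                          n_sections = 23, size_px = 60)
  cut <- section_volume(g$volume, g$labels, plan)
  inv <- table_to_transforms(cut$transforms, center = c(30.5, 30.5))
  fixed <- apply_transforms(cut$labels, inv, "nearest")
  plan0 <- sectioning_spec(pixel_size_xy = 1, section_thickness = 2,
                           jitter_sd_px = 0, rotation_sd_deg = 0, seed = 21,
                           n_sections = 23, size_px = 60)
  cut0 <- section_volume(g$volume, g$labels, plan0)
  expect_identical(fixed$sections, cut0$labels$sections)
  # with rotations, linear path: close to the unperturbed sections
  planr <- sectioning_spec(pixel_size_xy = 1, section_thickness = 2,
                           jitter_sd_px = 4, rotation_sd_deg = 2, seed = 22,
                           n_sections = 23, size_px = 60)
  cutr <- section_volume(g$volume, g$labels, planr)
  invr <- table_to_transforms(cutr$transforms, center = c(30.5, 30.5))
  fixr <- apply_transforms(cutr$stack, invr, "linear")
  cut0i <- section_volume(g$volume, NULL, plan0)
  err <- mapply(function(a, b) mean(abs(a - b)),
                fixr$sections, cut0i$stack$sections)
  expect_lt(max(err), 0.05)
})

test_that("texture adds shared structure but keeps labels untouched", {
  spec <- vessel_spec("straight", length_um = 50, outer_radius_um = 16,
                      lumen_radius_um = 8, texture_sd = 0.1)
  g <- generate_vessel_volume(spec, c(2, 1, 1), c(24, 40, 40), seed = 2)
  g0 <- through_vessel()
  expect_identical(g$labels$data, g0$labels$data)
  expect_gt(length(unique(as.numeric(g$volume$data))), 3)
  expect_true(all(g$volume$data >= 0 & g$volume$data <= 1))
})
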