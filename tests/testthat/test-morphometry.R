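test_that("NI follows its defining ratio and limiting cases", {
  expect_equal(ni(50, 50), 50)
  expect_equal(ni(0, 10), 0)
  expect_equal(ni(10, 0), 100)
  expect_equal(ni(3 * 7, 3 * 3), ni(7, 3))       # scale invariance
  expect_error(ni(0, 0), "no vessel")
  expect_error(ni(-1, 2), ">= 0")
})

test_that("NI from a label image counts pixels and ignores pixel size", {
  n <- 101
  ctr <- (n + 1) / 2
  r <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
  img <- array(0L, c(n, n))
  img[r < 20] <- 2L
  img[r < 10] <- 1L
  res <- ni_from_label_section(img)
  expect_equal(res$ni, 75, tolerance = 0.03 * 75)
  res2 <- ni_from_label_section(img, pixel_area = 0.369^2)
  expect_equal(res2$ni, res$ni)
  expect_equal(res2$neointimal_area, res$neointimal_area * 0.369^2)
  expect_error(ni_from_label_section(array(0L, c(5, 5))), "no vessel")
})

test_that("NVI reproduces the voxel-count worked example at 3 decimals", {
  v_n <- 153952L
  v_l <- 257856L - 153952L
  lab <- label_volume(array(c(rep(2L, v_n), rep(1L, v_l)),
                            c(v_n + v_l, 1, 1)),
                      spacing = c(1, 1, 1))
  res <- nvi(lab)
  expect_equal(res$v_neointima_voxels, 153952)
  expect_equal(res$v_neointima_plus_lumen_voxels, 257856)
  expect_equal(round(res$nvi, 3), 59.705)
  expect_equal(nvi_percent(153952, 257856 - 153952),
               100 * 153952 / 257856)
})

test_that("NVI handles degenerate segments and arclength masks", {
  lab0 <- label_volume(array(1L, c(4, 4, 4)), c(1, 1, 1))
  expect_equal(nvi(lab0)$nvi, 0)
  labx <- label_volume(array(0L, c(4, 4, 4)), c(1, 1, 1))
  expect_error(nvi(labx), "no vessel")
  # masking to half the arclength of a uniform tube halves the voxel counts
  g <- through_vessel()
  cl <- extract_centerline(g$labels)
  full <- nvi(g$labels)
  half <- nvi(g$labels, mask_range = c(0, max(cl$arclength) / 2), cl = cl)
  expect_equal(half$nvi, full$nvi, tolerance = 0.02)
  expect_equal(half$v_neointima_plus_lumen_voxels /
                 full$v_neointima_plus_lumen_voxels, 0.5, tolerance = 0.08)
  expect_error(nvi(g$labels, mask_range = c(0, 10)), "centerline")
})

test_that("NVI of a constant-profile phantom equals the analytic NI", {
  spec <- standard_straight_spec()
  g <- generate_vessel_volume(spec, c(1, 1, 1), c(100, 110, 110))
  res <- nvi(g$labels)
  expect_equal(res$nvi, 75, tolerance = 0.02)
  expect_equal(res$nvi,
               100 * res$v_neointima_um3 /
                 (res$v_neointima_um3 + res$v_lumen_um3),
               tolerance = 1e-12)
})

test_that("oblique thickness follows 1/cos and rejects grazing angles", {
  expect_equal(oblique_thickness(10, 60), 20)
  expect_equal(oblique_thickness(7.3, 0), 7.3)
  expect_error(oblique_thickness(10, 90), "90")
  expect_error(oblique_thickness(10, -5), "90")
})

test_that("series morphometry aggregates areas and bounds percentages", {
  spec <- vessel_spec("straight", length_um = 112, outer_radius_um = 30,
                      lumen_radius_um = 15)
  g <- generate_vessel_volume(spec, c(1, 1, 1), c(118, 80, 80))
  cl <- extract_centerline(g$labels)
  ser <- perpendicular_series(NULL, g$labels, cl, step = 8, size = 70,
                              pixel_size = 1)
  res <- morphometry_series(ser, "corrected_perpendicular")
  expect_s3_class(res, "morphometry_result")
  expect_true(all(res$per_section$ni_percent >= 0 &
                    res$per_section$ni_percent <= 100))
  expect_true(res$segment$nvi >= 0 && res$segment$nvi <= 100)
  # conventional analysis of the same labels from the stack-plane view
  conv <- morphometry_series(
    section_stack(lapply(seq_len(dim(g$labels$data)[1]),
                         function(k) {
                           m <- g$labels$data[k, , ]
                           storage.mode(m) <- "integer"
                           m
                         }), 1, 1),
    "conventional_stack_plane")
  expect_equal(mean(conv$per_section$ni_percent),
               mean(res$per_section$ni_percent), tolerance = 0.5)
})

test_that("paired comparison reproduces a hand-computed t statistic", {
  mk_res <- function(vals, prov) {
    per <- data.frame(arclength_um = 10 * (seq_along(vals) - 1),
                      neointimal_area_um2 = vals,
                      luminal_area_um2 = 100 - vals,
                      ni_percent = vals)
    structure(list(per_section = per,
                   segment = list(v_neointima_area_um2 = sum(vals),
                                  v_lumen_area_um2 = sum(100 - vals),
                                  nvi = ni(sum(vals), sum(100 - vals))),
                   provenance = prov, n_empty = 0L),
              class = "morphometry_result")
  }
  conv <- mk_res(c(2, 4, 6), "conventional_stack_plane")
  corr <- mk_res(c(1, 2, 3), "corrected_perpendicular")
  cmp <- compare_series(conv, corr)
  full <- cmp[cmp$part == "full", ]
  expect_equal(full$t, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(full$df, 2)
  # identical series: t = 0, p = 1
  cmp0 <- compare_series(conv, conv)
  expect_equal(cmp0$t, c(0, 0, 0))
  expect_equal(cmp0$p, c(1, 1, 1))
  expect_error(compare_series(conv, mk_res(c(1, 2), "corrected_perpendicular")),
               "mismatch")
})

test_that("radial wall width doubles under a 60-degree oblique cut", {
  n <- 121; ctr <- (n + 1) / 2
  yy <- (1:n) - ctr
  # perpendicular annulus r in [10, 20]
  r0 <- sqrt(outer(yy^2, yy^2, "+"))
  perp <- array(0L, c(n, n)); perp[r0 < 20] <- 2L; perp[r0 < 10] <- 1L
  # 2:1 stretched ellipse annulus (oblique at 60 degrees)
  re <- sqrt(outer(yy^2, (yy / 2)^2, "+"))
  obl <- array(0L, c(n, n)); obl[re < 20] <- 2L; obl[re < 10] <- 1L
  w_perp <- radial_wall_width(perp)
  w_obl <- radial_wall_width(obl)
  expect_equal(w_perp, 10, tolerance = 0.1)
  expect_equal(w_obl / w_perp, 2, tolerance = 0.1)
})

test_that("morphometry CSV export includes the segment summary row", {
  g <- through_vessel()
  cl <- extract_centerline(g$labels)
  ser <- perpendicular_series(NULL, g$labels, cl, step = 8, size = 44,
                              pixel_size = 1)
  res <- morphometry_series(ser)
  p <- file.path(tempdir(), "morph.csv")
  write_morphometry(res, p)
  df <- utils::read.csv(p)
  expect_true("segment" %in% df$row)
  seg <- df[df$row == "segment", ]
  expect_equal(seg$ni_percent, round(res$segment$nvi, 3))
})
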