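disk_mask <- function(r, pad = 10) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  (yy - c0)^2 + (xx - c0)^2 <= r^2
}

ellipse_mask <- function(a, b, theta = 0, pad = 10) {
  n <- 2 * (a + pad) + 1
  c0 <- a + pad + 1
  yy <- matrix(seq_len(n), n, n) - c0; xx <- t(yy)
  xr <- xx * cos(theta) + yy * sin(theta)
  yr <- -xx * sin(theta) + yy * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

test_that("a filled square is its own convex filled hull", {
  m <- matrix(FALSE, 14, 14)
  m[3:12, 3:12] <- TRUE
  sh <- region_shape(m)
  expect_equal(sh$area, 100)
  expect_equal(sh$convex_area, 100)
  expect_equal(sh$filled_area, 100)
  expect_equal(sh$solidity, 1)
})

test_that("disk metrology matches analytic values", {
  sh <- region_shape(disk_mask(50))
  expect_equal(sh$area, pi * 50^2, tolerance = 0.02)
  expect_equal(sh$perimeter, 2 * pi * 50, tolerance = 0.03)
  expect_lt(sh$eccentricity, 0.1)
  expect_equal(sh$major_axis, 100, tolerance = 0.03)
})

test_that("ellipse axes and eccentricity match analytic values", {
  sh <- region_shape(ellipse_mask(40, 20))
  expect_equal(sh$major_axis, 80, tolerance = 0.03)
  expect_equal(sh$minor_axis, 40, tolerance = 0.03)
  expect_equal(sh$eccentricity, sqrt(1 - 0.25), tolerance = 0.025)
  expect_equal(sh$eccentricity, 0.866, tolerance = 0.02 / 0.866)
})

test_that("features obey the k^2 / k scaling law", {
  base <- region_shape(ellipse_mask(12, 8))
  for (k in c(2, 4)) {
    sc <- region_shape(ellipse_mask(12 * k, 8 * k))
    expect_equal(sc$area / base$area, k^2, tolerance = 0.05)
    expect_equal(sc$perimeter / base$perimeter, k, tolerance = 0.05)
    expect_equal(sc$major_axis / base$major_axis, k, tolerance = 0.05)
  }
})

test_that("features are rotation-robust", {
  ref <- region_shape(ellipse_mask(30, 15))
  for (th in c(pi / 6, pi / 4, 1.1)) {
    rot <- region_shape(ellipse_mask(30, 15, theta = th))
    expect_equal(rot$area, ref$area, tolerance = 0.05)
    expect_equal(rot$perimeter, ref$perimeter, tolerance = 0.05)
    expect_equal(rot$eccentricity, ref$eccentricity, tolerance = 0.05)
  }
})

test_that("area orderings hold on random blobs", {
  set.seed(31)
  for (k in 1:10) {
    m <- random_blob_mask(40, 40, sample(2:4, 1))
    lab <- label_components(m)
    for (id in seq_len(max(lab))) {
      sh <- region_shape(lab == id)
      expect_gte(sh$convex_area, sh$filled_area)
      expect_gte(sh$filled_area, sh$area)
      expect_lte(sh$solidity, 1)
      expect_gte(sh$major_axis, sh$minor_axis)
      expect_lt(sh$eccentricity, 1)
    }
  }
})

test_that("filled area counts interior holes", {
  m <- matrix(FALSE, 20, 20)
  m[5:15, 5:15] <- TRUE
  m[9:11, 9:11] <- FALSE   # punch a hole
  sh <- region_shape(m)
  expect_equal(sh$area, 121 - 9)
  expect_equal(sh$filled_area, 121)
  expect_error(region_shape(matrix(FALSE, 3, 3)), "empty")
})

test_that("slide tumor features sum per-component shapes", {
  m <- matrix(FALSE, 30, 30)
  m[2:11, 2:11] <- TRUE
  single <- slide_tumor_features(clean_mask(m))
  expect_equal(unname(single["total_area"]), unname(single["main_area"]))
  expect_equal(unname(single["total_perimeter"]), unname(single["main_perimeter"]))

  m[16:25, 16:25] <- TRUE
  both <- slide_tumor_features(clean_mask(m))
  expect_equal(unname(both["total_area"]), 200)
  expect_equal(unname(both["main_area"]), 100)

  set.seed(32)
  rb <- random_blob_mask(48, 48, 4)
  tm <- clean_mask(rb)
  f <- slide_tumor_features(tm)
  kept <- tm$components$id[tm$components$retained]
  shapes <- lapply(kept, function(id) region_shape(tm$labels == id))
  expect_equal(unname(f["total_area"]),
               sum(vapply(shapes, `[[`, 0, "area")))
  expect_equal(unname(f["total_perimeter"]),
               sum(vapply(shapes, `[[`, 0, "perimeter")))
  expect_equal(unname(f["total_perimeter_by_area"]),
               sum(vapply(shapes, `[[`, 0, "perimeter")) /
                 sum(vapply(shapes, `[[`, 0, "area")))

  empty <- clean_mask(matrix(FALSE, 5, 5))
  expect_warning(na_row <- slide_tumor_features(empty), "empty")
  expect_true(all(is.na(na_row)))
  expect_length(canonical_tumor_features(), 15)
})

test_that("nuclei segmentation recovers synthetic scenes", {
  blank <- array(250, c(32, 32, 3))
  expect_equal(max(segment_nuclei(blank)), 0)

  scene <- generate_nuclei_image(20, seed = 41)
  lab <- segment_nuclei(scene$img)
  expect_equal(max(lab), 20)
  # every segmented nucleus matches one ground-truth ellipse with IoU > 0.7
  h <- nrow(lab); w <- ncol(lab)
  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (id in seq_len(max(lab))) {
    seg <- lab == id
    cy <- mean(yy[seg]); cx <- mean(xx[seg])
    gt <- which.min((scene$truth$cy - cy)^2 + (scene$truth$cx - cx)^2)
    tr <- scene$truth[gt, ]
    xr <- (xx - tr$cx) * cos(tr$theta) + (yy - tr$cy) * sin(tr$theta)
    yr <- -(xx - tr$cx) * sin(tr$theta) + (yy - tr$cy) * cos(tr$theta)
    gt_mask <- (xr / tr$a)^2 + (yr / tr$b)^2 <= 1
    expect_gt(sum(seg & gt_mask) / sum(seg | gt_mask), 0.7)
    expect_equal(sum(seg), tr$area, tolerance = 0.1)
  }
})

test_that("hierarchical thresholding adapts its depth to the scene", {
  # three intensity strata: white background, mid cytoplasm, dark nuclei;
  # a single Otsu level would lump cytoplasm with nuclei
  set.seed(42)
  img <- array(rep(240, 64 * 64 * 3) + rnorm(64 * 64 * 3, 0, 2), c(64, 64, 3))
  img[20:45, 20:45, ] <- 170 + rnorm(26 * 26 * 3, 0, 4)
  img[28:36, 28:36, ] <- 60 + rnorm(9 * 9 * 3, 0, 4)
  lab <- segment_nuclei(img, min_area = 10)
  expect_equal(max(lab), 1)
  expect_equal(sum(lab > 0), 81, tolerance = 0.15)
})

test_that("nuclei totals add over patches", {
  circ <- generate_nuclei_image(1, semi_major = c(10, 10),
                                semi_minor = c(10, 10), seed = 43)
  f1 <- slide_nuclei_features(list(circ$img))
  expect_equal(unname(f1["nuc_total_area"]), pi * 100, tolerance = 0.1)
  expect_equal(unname(f1["nuc_count"]), 1)
  f2 <- slide_nuclei_features(list(circ$img, circ$img))
  expect_equal(unname(f2["nuc_total_area"]), 2 * unname(f1["nuc_total_area"]))
  expect_equal(unname(f2["nuc_total_perimeter"]),
               2 * unname(f1["nuc_total_perimeter"]))
  expect_warning(z <- slide_nuclei_features(list(array(250, c(16, 16, 3)))),
                 "no nuclei")
  expect_true(all(z == 0))
})

test_that("patient aggregation averages slide rows", {
  sf <- data.frame(slide_id = c("a", "b", "c"),
                   total_area = c(10, 20, 7), main_area = c(4, 6, 7))
  map <- data.frame(slide_id = c("a", "b", "c"),
                    patient_id = c("p1", "p1", "p2"))
  out <- aggregate_patients(sf, map)
  expect_equal(out$total_area, c(15, 7))
  expect_equal(out$main_area, c(5, 7))
  # permuting slide order changes nothing
  out2 <- aggregate_patients(sf[c(3, 1, 2), ], map)
  expect_equal(out, out2)
  # a patient whose only slide is unusable is excluded with a warning
  sf$total_area[3] <- NA
  expect_warning(out3 <- aggregate_patients(sf, map), "excluded")
  expect_equal(out3$patient_id, "p1")
})
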