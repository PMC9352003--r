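test_that("segmentation recovers a disc and ignores a background-only frame", {
  expect_equal(sum(segment_fruit(blank_image(50, 50, 255))), 0)

  img <- paint(blank_image(160, 160), disc_where(160, 160, 80, 80, 60), apple_red)
  mask <- segment_fruit(img)
  expect_lt(abs(sum(mask) - pi * 60^2) / (pi * 60^2), 0.02)
})

test_that("specular holes inside the fruit are filled", {
  img <- paint(blank_image(160, 160), disc_where(160, 160, 80, 80, 60), apple_red)
  img <- paint(img, disc_where(160, 160, 70, 70, 5), c(255, 255, 255))
  mask <- segment_fruit(img)
  expect_true(all(mask[disc_where(160, 160, 70, 70, 5)] == 1))
})

test_that("largest_contour traces the biggest component as a closed polygon", {
  m <- matrix(0L, 20, 20); m[6:15, 6:15] <- 1L
  ct <- largest_contour(m)
  expect_equal(nrow(ct$points), 36)                    # 10x10 boundary ring
  expect_true(all(m[cbind(ct$points[, 2], ct$points[, 1])] == 1))
  # closed: consecutive points (and the wrap-around pair) are 8-connected
  gaps <- rbind(diff(ct$points), ct$points[1, ] - ct$points[nrow(ct$points), ])
  expect_true(all(pmax(abs(gaps[, 1]), abs(gaps[, 2])) <= 1))
  expect_equal(unname(ct$centroid), c(10.5, 10.5))

  two <- matrix(0L, 100, 100)
  two[disc_where(100, 100, 30, 30, 15)] <- 1L
  two[disc_where(100, 100, 75, 75, 8)] <- 1L
  ct2 <- largest_contour(two)
  expect_lt(max(abs(ct2$centroid - c(30, 30))), 0.5)   # larger disc wins

  full <- matrix(1L, 12, 17)
  ct3 <- largest_contour(full)
  expect_equal(nrow(ct3$points), 2 * (12 + 17) - 4)    # border ring

  expect_error(largest_contour(matrix(0L, 5, 5)), class = "fujigrade_no_contour")
})

test_that("defect extraction is confined to dark pixels inside the fruit", {
  h <- w <- 120
  img <- paint(blank_image(h, w), disc_where(h, w, 60, 60, 45), apple_red)
  fruit <- matrix(as.integer(disc_where(h, w, 60, 60, 45)), h, w)

  expect_equal(sum(extract_defects(img, fruit)), 0)    # uniform healthy peel

  blob <- disc_where(h, w, 50, 70, 6) & disc_where(h, w, 60, 60, 45)
  img2 <- paint(img, blob, defect_dark)
  dm <- extract_defects(img2, fruit)
  expect_equal(sum(dm), sum(blob))                     # exact pixel count

  img3 <- paint(img2, disc_where(h, w, 10, 10, 4), defect_dark)  # outside fruit
  dm3 <- extract_defects(img3, fruit)
  expect_equal(sum(dm3), sum(blob))
  expect_true(all(dm3 <= fruit))

  expect_error(extract_defects(img, matrix(0L, h, w)), class = "fujigrade_no_fruit")
})

test_that("defect ratio matches the critical-ratio arithmetic and its raster analogue", {
  # 3 mm spot on a 70 mm fruit, as exact areas; 0.18% at printed precision
  expect_equal(round(critical_defect_ratio(3, 70) * 100, 2), 0.18)
  expect_equal(critical_defect_ratio(3, 70), (3 / 70)^2)

  h <- w <- 90
  fruit <- matrix(as.integer(disc_where(h, w, 45, 45, 35)), h, w)
  expect_equal(defect_ratio(matrix(0L, h, w), fruit), 0)

  # rasterized 3 px spot on a 70 px fruit (sub-pixel centre)
  f2 <- matrix(as.integer(disc_where(h, w, 45, 45, 35)), h, w)
  d2 <- matrix(as.integer(disc_where(h, w, 40.5, 40, 1.5)), h, w) * f2
  t_raster <- defect_ratio(d2, f2)
  expect_lt(abs(t_raster - 0.00184) / 0.00184, 0.15)

  expect_error(defect_ratio(matrix(0L, 3, 3), matrix(0L, 3, 3)),
               class = "fujigrade_division_undefined")
  bad <- matrix(0L, h, w); bad[1, 1] <- 1L
  expect_error(defect_ratio(bad, fruit), class = "fujigrade_invalid_parameter")
})
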