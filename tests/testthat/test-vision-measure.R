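test_that("raw moments equal brute-force double-loop summation", {
  m5 <- matrix(0L, 5, 5); m5[2:4, c(1, 3, 5)] <- 1L
  for (p in 0:2) for (q in 0:2) {
    expect_equal(raw_moment(m5, p, q), moment_loops(m5, p, q))
  }

  set.seed(11)
  for (i in 1:5) {
    h <- sample(10:64, 1); w <- sample(10:64, 1)
    m <- matrix(rbinom(h * w, 1, 0.3), h, w)
    for (pq in list(c(0, 0), c(1, 0), c(0, 1), c(2, 1))) {
      expect_equal(raw_moment(m, pq[1], pq[2]), moment_loops(m, pq[1], pq[2]))
    }
  }
})

test_that("moments and centroid behave like area and centre of mass", {
  sq <- matrix(0L, 21, 21); sq[6:16, 6:16] <- 1L
  expect_equal(raw_moment(sq, 0, 0), 121)               # m00 = pixel count
  expect_equal(unname(contour_centroid(sq)), c(11, 11)) # symmetric centre

  one <- matrix(0L, 10, 10); one[3, 7] <- 1L            # (x, y) = (7, 3)
  expect_equal(unname(contour_centroid(one)), c(7, 3))

  disc <- matrix(as.integer(disc_where(90, 120, 60, 45, 30)), 90, 120)
  expect_lt(max(abs(contour_centroid(disc) - c(60, 45))), 0.5)

  # exact translation equivariance
  m <- matrix(0L, 40, 40); m[disc_where(40, 40, 15, 18, 8)] <- 1L
  shifted <- matrix(0L, 40, 40); shifted[disc_where(40, 40, 24, 23, 8)] <- 1L
  expect_equal(contour_centroid(shifted) - contour_centroid(m), c(x_c = 9, y_c = 5))

  expect_error(contour_centroid(matrix(0L, 4, 4)), class = "fujigrade_division_undefined")
})

test_that("aspect ratio reflects horizontal/vertical extents", {
  circ <- largest_contour(matrix(as.integer(disc_where(130, 130, 65, 65, 50)), 130, 130))
  expect_equal(aspect_ratio(circ), 1, tolerance = 0.02)

  ell <- largest_contour(matrix(as.integer(ellipse_where(260, 300, 150, 130, 120, 100)), 260, 300))
  expect_equal(aspect_ratio(ell), 1.2, tolerance = 0.02)

  sq <- matrix(0L, 30, 30); sq[8:22, 8:22] <- 1L
  expect_equal(aspect_ratio(largest_contour(sq)), 1)

  flat <- cbind(x = 1:5, y = rep(3, 5))
  expect_error(aspect_ratio(flat), class = "fujigrade_degenerate_contour")
})

test_that("maximum cross diameter equals twice the largest centroid radius", {
  disc <- largest_contour(matrix(as.integer(disc_where(130, 130, 65, 65, 50)), 130, 130))
  expect_equal(max_cross_diameter(disc), 100, tolerance = 1)

  ell <- largest_contour(matrix(as.integer(ellipse_where(180, 200, 100, 90, 80, 60)), 180, 200))
  expect_equal(max_cross_diameter(ell), 160, tolerance = 1)
})

test_that("convex-hull restriction agrees with brute force over all boundary points", {
  shapes <- list(
    matrix(as.integer(disc_where(100, 100, 50, 50, 40)), 100, 100),
    matrix(as.integer(ellipse_where(120, 160, 80, 60, 70, 40)), 120, 160),
    {m <- matrix(0L, 80, 80); m[10:60, 20:70] <- 1L; m[40:70, 10:40] <- 1L; m}
  )
  for (m in shapes) {
    ct <- largest_contour(m)
    brute <- 2 * sqrt(max((ct$points[, 1] - ct$centroid[1])^2 +
                            (ct$points[, 2] - ct$centroid[2])^2))
    expect_equal(max_cross_diameter(ct), brute)
  }
})

test_that("appearance measurements are translation invariant within tolerance", {
  base <- render_apple(image_spec(diameter_px = 120, aspect = 1.08,
                                  defect_fraction = 0.01, center = c(128, 128),
                                  seed = 5))
  shifted <- render_apple(image_spec(diameter_px = 120, aspect = 1.08,
                                     defect_fraction = 0.01, center = c(150, 110),
                                     seed = 5))
  m1 <- measure_apple(base$image)
  m2 <- measure_apple(shifted$image)
  expect_lt(abs(m1$wp - m2$wp), 1)
  expect_lt(abs(m1$lambda - m2$lambda), 0.02)
  expect_lt(abs(m1$t - m2$t) / m1$t, 0.05)
})
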