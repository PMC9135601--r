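marker_scene <- function(seed = 1, width = 192, height = 192, side = 60,
                         physical = 5, warp = NULL, noise = 2,
                         radius = 30) {
  scene_spec(seed = seed, width = width, height = height,
             lesion_center = c(width * 0.68, height * 0.68),
             lesion_base_radius = radius, noise_sigma = noise,
             marker = list(side_px = side, position = c(14, 14),
                           physical_side = physical, quiet_zone = 10,
                           warp = warp))
}

test_that("a four-point homography maps corners exactly onto the square", {
  unit <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  H <- fit_homography(unit, 1)
  expect_equal(H, diag(3), tolerance = 1e-12)

  sq <- rbind(c(10, 20), c(70, 20), c(70, 80), c(10, 80))
  H2 <- fit_homography(sq, 5)
  # fronto-parallel case reduces to the pure scale factor 5/60
  pts <- cbind(runif(5, 0, 100), runif(5, 0, 100))
  mapped <- woundimg:::apply_homography(H2, pts)
  expect_equal(mapped, (pts - rep(c(10, 20), each = 5)) * 5 / 60,
               tolerance = 1e-9)

  set.seed(19)
  for (i in 1:10) {
    ang <- sort(runif(4, 0, 2 * pi))
    quad <- cbind(50 + (30 + runif(4, 0, 15)) * cos(ang),
                  50 + (30 + runif(4, 0, 15)) * sin(ang))
    H3 <- fit_homography(quad, 4)
    expect_equal(woundimg:::apply_homography(H3, quad),
                 rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4)),
                 tolerance = 1e-9)
  }
  colin <- rbind(c(0, 0), c(1, 1), c(2, 2), c(3, 3))
  expect_error(fit_homography(colin, 1), "degenerate")
})

test_that("the fronto-parallel marker is detected within a pixel", {
  sc <- generate_scene(marker_scene(seed = 4))
  mm <- detect_marker(sc$image, 5)
  expect_equal(dim(mm$corners), c(4, 2))
  err <- sqrt(rowSums((mm$corners - sc$truth$marker_corners)^2))
  expect_true(all(err <= 1))
})

test_that("scenes without a marker raise a detection error", {
  sc <- generate_scene(scene_spec(seed = 9))
  expect_error(detect_marker(sc$image, 5), "candidate")
})

test_that("a perspective-warped marker is located within 1.5 pixels", {
  W <- matrix(c(0.95, 0.05, 8,
                -0.03, 0.97, 12,
                1e-4, 5e-5, 1), 3, 3, byrow = TRUE)
  sc <- generate_scene(marker_scene(seed = 12, warp = W))
  mm <- detect_marker(sc$image, 5)
  # match detected corners to truth by nearest neighbour
  err <- apply(mm$corners, 1, function(p)
    min(sqrt(rowSums((sc$truth$marker_corners -
                      matrix(p, 4, 2, byrow = TRUE))^2))))
  expect_true(all(err <= 1.5))
})

test_that("lines joining adjacent marker corners measure the physical side", {
  sc <- generate_scene(marker_scene(seed = 7))
  mm <- detect_marker(sc$image, 5)
  for (i in 1:4) {
    seg <- rbind(mm$corners[i, ], mm$corners[i %% 4 + 1, ])
    expect_equal(measure_polyline(mm, seg)$length_cm, 5, tolerance = 1e-6)
  }
})

test_that("a 120 px line with a 60 px / 5 cm marker measures 10 cm", {
  sc <- generate_scene(marker_scene(seed = 15))
  mm <- detect_marker(sc$image, 5)
  line <- rbind(c(40, 150), c(160, 150))
  m <- measure_polyline(mm, line)
  expect_equal(m$length_cm, 10, tolerance = 1e-6)
  expect_equal(sum(m$per_segment_cm), m$length_cm)
})

test_that("measurements are stable under a doubled rendering resolution", {
  sc1 <- generate_scene(marker_scene(seed = 22))
  sc2 <- generate_scene(marker_scene(seed = 22, width = 384, height = 384,
                                     side = 120, radius = 60))
  m1 <- measure_polyline(detect_marker(sc1$image, 5),
                         rbind(c(40, 150), c(160, 150)))
  m2 <- measure_polyline(detect_marker(sc2$image, 5),
                         rbind(c(80, 300), c(320, 300)))
  expect_equal(m2$length_cm, m1$length_cm, tolerance = 0.02 * m1$length_cm)
})

test_that("measurement is invariant under global translation", {
  corners <- rbind(c(30, 40), c(90, 40), c(90, 100), c(30, 100))
  pts <- rbind(c(10, 10), c(50, 80), c(120, 40))
  m0 <- measure_polyline(marker_model(corners, 5), pts)
  shift <- c(17, -9)
  m1 <- measure_polyline(
    marker_model(corners + rep(shift, each = 4), 5),
    pts + rep(shift, each = 3))
  expect_equal(m1$length_cm, m0$length_cm, tolerance = 1e-9)
})

test_that("length is additive over polyline subdivision", {
  corners <- rbind(c(0, 0), c(60, 0), c(60, 60), c(0, 60))
  mm <- marker_model(corners, 5)
  a <- c(5, 7); b <- c(100, 131)
  whole <- measure_polyline(mm, rbind(a, b))$length_cm
  mid <- (a + b) / 2
  split <- measure_polyline(mm, rbind(a, mid, b))$length_cm
  expect_equal(split, whole, tolerance = 1e-9)
})

test_that("degenerate polylines are rejected", {
  mm <- marker_model(rbind(c(0, 0), c(60, 0), c(60, 60), c(0, 60)), 5)
  expect_error(measure_polyline(mm, matrix(c(1, 2), 1, 2)), "at least 2")
})
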