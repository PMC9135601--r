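test_that("psnr matches its closed form and conventions", {
  set.seed(2)
  m <- matrix(sample(0:254, 30 * 30, TRUE), 30, 30)
  a <- raster_image(m)
  expect_equal(psnr(a, a), 99)                       # identical-image cap
  b <- raster_image(m + 1)
  expect_equal(psnr(a, b), 10 * log10(255^2), tolerance = 1e-9)
  expect_equal(psnr(a, b), 48.13, tolerance = 0.005)
  for (i in 1:5) {
    x <- raster_image(matrix(sample(0:255, 100, TRUE), 10, 10))
    y <- raster_image(matrix(sample(0:255, 100, TRUE), 10, 10))
    expect_identical(psnr(x, y), psnr(y, x))         # MSE symmetry
  }
  expect_error(psnr(a, raster_image(matrix(0, 2, 2))), "size")
})

test_that("nearest-neighbour enlargement expands pixels into blocks", {
  em <- as_edge_map(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  big <- enlarge_binary(em, 4, 4)
  expect_true(all(big$edges[1:2, 1:2]))
  expect_equal(sum(big$edges), 4)
  expect_identical(enlarge_binary(em, 2, 2)$edges, em$edges)  # identity
  expect_error(enlarge_binary(em, 1, 4), "at least")
  # edge fraction is preserved up to row/column rounding
  set.seed(41)
  for (i in 1:5) {
    msk <- matrix(runif(15 * 11) < 0.3, 11, 15)
    em2 <- as_edge_map(msk)
    big2 <- enlarge_binary(em2, 33, 22)
    reps <- table(floor((0:21) * 11 / 22))  # per-source-row replication
    expect_equal(sum(big2$edges) / (33 * 22), mean(msk), tolerance = 0.1)
  }
})

test_that("edge-map comparison reproduces hand-counted confusions", {
  ref <- as_edge_map(matrix(c(TRUE, FALSE, FALSE,
                              TRUE, FALSE, FALSE,
                              FALSE, FALSE, FALSE), 3, 3, byrow = TRUE))
  tst <- as_edge_map(matrix(c(TRUE, TRUE, FALSE,
                              FALSE, FALSE, FALSE,
                              FALSE, FALSE, FALSE), 3, 3, byrow = TRUE))
  cmp <- compare_edge_maps(ref, tst)
  expect_equal(c(cmp$tp, cmp$fp, cmp$fn, cmp$tn), c(1, 1, 1, 6))
  expect_equal(cmp$accuracy, 7 / 9)
  expect_equal(cmp$precision, 0.5)
  expect_equal(cmp$recall, 0.5)
  expect_equal(cmp$f1, 0.5)
  expect_equal(cmp$f1,
               2 * cmp$precision * cmp$recall / (cmp$precision + cmp$recall))
})

test_that("self-comparison and degenerate maps follow the conventions", {
  set.seed(3)
  em <- as_edge_map(matrix(runif(64) < 0.2, 8, 8))
  cmp <- compare_edge_maps(em, em)
  expect_equal(c(cmp$accuracy, cmp$precision, cmp$recall, cmp$f1),
               c(1, 1, 1, 1))
  empty <- as_edge_map(matrix(FALSE, 8, 8))
  dcmp <- compare_edge_maps(empty, empty)
  expect_equal(dcmp$accuracy, 1)
  expect_equal(c(dcmp$precision, dcmp$recall, dcmp$f1), c(0, 0, 0))
  expect_setequal(dcmp$degenerate, c("precision", "recall", "f1"))
  expect_error(compare_edge_maps(em, as_edge_map(matrix(FALSE, 4, 4))),
               "size")
})

test_that("confusion counts always partition the pixel grid", {
  set.seed(17)
  for (i in 1:10) {
    r <- as_edge_map(matrix(runif(12 * 9) < runif(1), 9, 12))
    t_ <- as_edge_map(matrix(runif(12 * 9) < runif(1), 9, 12))
    cmp <- compare_edge_maps(r, t_)
    expect_equal(cmp$tp + cmp$fp + cmp$fn + cmp$tn, 9 * 12)
  }
})

test_that("the sweep handles empty scene lists and unachievable rates", {
  rep0 <- run_rate_sweep(list(), c(0.25))
  expect_equal(nrow(rep0$details), 0)
  expect_error(run_rate_sweep(list(), c(0.3)), "not achievable")
})

test_that("an identity-rate sweep returns capped PSNR and perfect indicators", {
  scenes <- scene_batch(scene_spec(width = 96, height = 96,
                                   lesion_base_radius = 22), 1, 5)
  rep1 <- run_rate_sweep(scenes, 1)
  expect_equal(rep1$details$recon_psnr, 99)
  expect_equal(rep1$details$seg_psnr, 99)
  expect_equal(rep1$details$accuracy, 1)
  expect_equal(rep1$details$f1, 1)
})

test_that("the sweep is deterministic and reports achievable rates only", {
  scenes <- scene_batch(scene_spec(width = 96, height = 96,
                                   lesion_base_radius = 22), 2, 9)
  r1 <- run_rate_sweep(scenes, c(0.25, 0.5625))
  r2 <- run_rate_sweep(scenes, c(0.25, 0.5625))
  expect_identical(r1$details, r2$details)
  expect_true(all(r1$details$rate %in% c(0.25, 0.5625)))
  expect_equal(nrow(r1$details), 4)       # 2 scenes x 2 rates
  expect_equal(nrow(r1$cluster_psnr), 12) # x 3 clusters
  f <- withr::local_tempfile(fileext = ".csv")
  g <- withr::local_tempfile(fileext = ".json")
  write_sweep_report(r1, f, g)
  expect_true(file.exists(f) && file.exists(g))
  expect_equal(nrow(utils::read.csv(f)), 4)
})
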