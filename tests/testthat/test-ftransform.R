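test_that("uniform triangular partition matches hand-evaluated memberships", {
  p <- build_partition(4, 2)
  expect_equal(p$basis[, 1], c(1, 2/3, 1/3, 0))
  expect_equal(p$basis[, 2], c(0, 1/3, 2/3, 1))
  ident <- build_partition(4, 4)
  expect_equal(ident$basis, diag(4))
  expect_error(build_partition(3, 4), "axis_length")
  expect_error(build_partition(8, 1), "node_count")
})

test_that("Ruspini condition holds for every catalogue partition", {
  for (len in c(4, 5, 8, 13, 16, 192)) {
    for (n in c(2, 3, min(len, 7))) {
      p <- build_partition(len, n)
      expect_equal(rowSums(p$basis), rep(1, len), tolerance = 1e-9)
      # where a node falls on a pixel, its basic function attains 1 there
      # and every other basic function vanishes
      for (k in seq_len(n)) {
        if (p$nodes[k] == floor(p$nodes[k])) {
          expect_equal(p$basis[p$nodes[k] + 1, k], 1)
          expect_equal(sum(p$basis[p$nodes[k] + 1, -k]), 0)
        }
      }
    }
  }
})

test_that("rate_to_blocks picks the closest catalogue geometry", {
  g <- rate_to_blocks(0.25)
  expect_equal(c(g$block_side, g$coeff_side), c(4, 2))
  expect_equal(g$achieved_rate, 0.25)
  expect_false(g$identity)
  g2 <- rate_to_blocks(0.0625)
  expect_equal(c(g2$block_side, g2$coeff_side), c(8, 2))
  expect_equal(g2$achieved_rate, 0.0625)
  expect_true(rate_to_blocks(1)$identity)
  expect_error(rate_to_blocks(0), "\\(0, 1\\]")
  expect_error(rate_to_blocks(1.2), "\\(0, 1\\]")
  # independent argmin over an enumerated catalogue, ties to smaller block
  catalogue <- do.call(rbind, lapply(c(4, 8, 16), function(B)
    cbind(B = B, b = 2:(B - 1), rho = (2:(B - 1))^2 / B^2)))
  set.seed(21)
  for (r in runif(20, 0.01, 0.99)) {
    got <- rate_to_blocks(r)
    d <- abs(catalogue[, "rho"] - r)
    best <- catalogue[d == min(d), , drop = FALSE]
    pick <- best[order(best[, "B"], best[, "b"]), , drop = FALSE][1, ]
    expect_equal(c(got$block_side, got$coeff_side),
                 unname(pick[c("B", "b")]))
  }
})

test_that("compression of a constant image stores the constant everywhere", {
  img <- const_img(77, 16, 16)
  for (geom in list(c(4, 2), c(8, 3), c(8, 5))) {
    cb <- ft_compress(img, geom[1], geom[2])
    expect_equal(range(cb$coeff_grid), c(77, 77))
    expect_identical(ft_decompress(cb)$pixels, img$pixels)
    expect_identical(coefficients_as_image(cb)$pixels,
                     matrix(77, nrow(cb$coeff_grid), ncol(cb$coeff_grid)))
  }
})

test_that("compress/decompress match the brute-force double-sum oracle", {
  # the worked single block: intensities 0..15 row-major
  blk <- matrix(0:15, 4, 4, byrow = TRUE)
  cb <- ft_compress(raster_image(blk), 4, 2)
  expect_equal(cb$coeff_grid, oracle_ft_block(blk, 2), tolerance = 1e-9)
  rec <- oracle_ift_block(oracle_ft_block(blk, 2), 4, 4)
  expect_identical(ft_decompress(cb)$pixels,
                   {r <- floor(rec + 0.5); r[r < 0] <- 0; r[r > 255] <- 255; r})
  # 100 random 4x4 single-block images over {0, 128, 255}
  set.seed(42)
  for (i in 1:100) {
    b4 <- matrix(sample(c(0, 128, 255), 16, TRUE), 4, 4)
    cb4 <- ft_compress(raster_image(b4), 4, 2)
    expect_equal(cb4$coeff_grid, oracle_ft_block(b4, 2), tolerance = 1e-9)
    expect_equal(woundimg:::inverse_grid(cb4, cb4$coeff_grid),
                 oracle_ift_block(cb4$coeff_grid, 4, 4), tolerance = 1e-9)
  }
})

test_that("a 192x192 band at B=4,b=2 stores exactly a quarter of the pixels", {
  set.seed(3)
  img <- raster_image(matrix(sample(0:255, 192 * 192, TRUE), 192, 192), "R")
  cb <- ft_compress(img, 4, 2)
  expect_equal(dim(cb$coeff_grid), c(96, 96))
  expect_equal(length(cb$coeff_grid) / length(img$pixels), 0.25)
  expect_equal(cb$achieved_rate, 0.25)
  ci <- coefficients_as_image(cb)
  expect_equal(c(image_height(ci), image_width(ci)), c(96, 96))
})

test_that("coefficients and reconstructions stay inside [0,255]", {
  set.seed(13)
  img <- raster_image(matrix(sample(c(0, 255), 24 * 20, TRUE), 24, 20))
  cb <- ft_compress(img, 8, 3)
  expect_true(all(cb$coeff_grid >= 0 & cb$coeff_grid <= 255))
  rec <- ft_decompress(cb)
  expect_true(all(rec$pixels >= 0 & rec$pixels <= 255))
  expect_equal(c(image_height(rec), image_width(rec)), c(24, 20))
})

test_that("edge blocks are shrunk, never padded", {
  set.seed(17)
  img <- raster_image(matrix(sample(0:255, 19 * 22, TRUE), 19, 22))
  cb <- ft_compress(img, 8, 3)
  expect_equal(cb$row_sizes, c(8, 8, 3))
  expect_equal(cb$col_sizes, c(8, 8, 6))
  expect_equal(length(cb$row_sizes) * length(cb$col_sizes),
               ceiling(19 / 8) * ceiling(22 / 8))
  rec <- ft_decompress(cb)
  expect_equal(c(image_height(rec), image_width(rec)), c(19, 22))
})

test_that("two-plateau sources keep their plateau values away from the cut", {
  m <- matrix(60, 16, 16); m[, 9:16] <- 200
  cb <- ft_compress(raster_image(m), 4, 2)
  ci <- coefficients_as_image(cb)
  expect_true(all(ci$pixels[, 1:3] == 60))
  expect_true(all(ci$pixels[, 6:8] == 200))
})

test_that("reconstruction PSNR is non-decreasing in the achieved rate", {
  scenes <- scene_batch(scene_spec(width = 96, height = 96,
                                   lesion_base_radius = 22), 3, 101)
  rates <- c(0.0625, 0.25, 0.5625)
  mean_psnr <- vapply(rates, function(r) {
    g <- rate_to_blocks(r)
    mean(vapply(scenes, function(sc) {
      b <- split_bands(sc$image)$R
      psnr(b, ft_decompress(ft_compress(b, g$block_side, g$coeff_side)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_psnr) >= 0))
})

test_that("sidecar serialization round-trips the representation", {
  set.seed(23)
  img <- raster_image(matrix(sample(0:255, 20 * 28, TRUE), 20, 28), "G")
  cb <- ft_compress(img, 4, 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_ftc(cb, f)
  back <- read_ftc(f)
  expect_equal(back$coeff_grid, cb$coeff_grid, tolerance = 1e-12)
  # decoded text can differ in the last binary digit; at worst this flips a
  # value sitting exactly on a rounding boundary by one gray level
  expect_lte(max(abs(ft_decompress(back)$pixels - ft_decompress(cb)$pixels)),
             1)
  expect_equal(back$band, "G")
})

test_that("invalid geometries are rejected", {
  img <- const_img(0, 16, 16)
  expect_error(ft_compress(img, 4, 4), "smaller")
  expect_error(ft_compress(img, 4, 1), "at least 2")
  expect_error(ft_compress(const_img(0, 3, 3), 4, 2), "at least block_side")
})
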