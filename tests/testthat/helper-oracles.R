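# Independent oracles and small image builders shared across the suite.
# The oracles deliberately use naive double-sum / per-pixel formulations so
# they stay independent of the vectorized implementation they check.

const_img <- function(value, h = 8, w = 8, band = "GRAY")
  raster_image(matrix(value, h, w), band)

# vertical step: left half `lo`, right half `hi`
step_img <- function(h = 24, w = 24, lo = 0, hi = 255) {
  m <- matrix(lo, h, w)
  m[, (w %/% 2 + 1):w] <- hi
  raster_image(m)
}

# horizontal plateaus of the given values, equal heights
plateau_img <- function(values, h_each = 12, w = 24, noise_sd = 0,
                        seed = NULL) {
  m <- do.call(rbind, lapply(values, function(v) matrix(v, h_each, w)))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    m <- m + matrix(rnorm(length(m), 0, noise_sd), nrow(m), ncol(m))
  }
  m <- floor(m + 0.5); m[m < 0] <- 0; m[m > 255] <- 255
  raster_image(m)
}

disk_img <- function(h = 64, w = 64, r = 20, inside = 40, outside = 220) {
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), w), h, w)
  m <- matrix(outside, h, w)
  m[(xs - cx)^2 + (ys - cy)^2 < r^2] <- inside
  raster_image(m)
}

# Brute-force direct F-transform of one block: triangular partition with
# nodes at the first and last pixel, naive double sums.
oracle_triangle <- function(len, n, k, x) {
  h <- (len - 1) / (n - 1)
  node <- k * h
  max(0, 1 - abs(x - node) / h)
}

oracle_ft_block <- function(block, b) {
  hb <- nrow(block); wb <- ncol(block)
  F <- matrix(0, b, b)
  for (k in 0:(b - 1)) for (l in 0:(b - 1)) {
    num <- 0; da <- 0; db <- 0
    for (i in 0:(hb - 1)) for (j in 0:(wb - 1))
      num <- num + block[i + 1, j + 1] *
        oracle_triangle(hb, b, k, i) * oracle_triangle(wb, b, l, j)
    for (i in 0:(hb - 1)) da <- da + oracle_triangle(hb, b, k, i)
    for (j in 0:(wb - 1)) db <- db + oracle_triangle(wb, b, l, j)
    F[k + 1, l + 1] <- num / (da * db)
  }
  F
}

oracle_ift_block <- function(F, hb, wb) {
  b <- nrow(F)
  out <- matrix(0, hb, wb)
  for (i in 0:(hb - 1)) for (j in 0:(wb - 1)) {
    s <- 0
    for (k in 0:(b - 1)) for (l in 0:(b - 1))
      s <- s + F[k + 1, l + 1] *
        oracle_triangle(hb, b, k, i) * oracle_triangle(wb, b, l, j)
    out[i + 1, j + 1] <- s
  }
  out
}

# naive fuzzy c-means on weighted gray levels; independent of the package
oracle_fcm <- function(values, weights, v0, m = 2, iters = 200) {
  v <- v0
  for (it in seq_len(iters)) {
    d2 <- outer(values, v, `-`)^2
    d2[d2 < 1e-300] <- 1e-300
    w <- d2^(-1 / (m - 1))
    u <- w / rowSums(w)
    v <- colSums(weights * u^m * values) / colSums(weights * u^m)
  }
  sort(v)
}

# 4-connected flood fill of `open` cells from the border; returns reachable
flood_from_border <- function(open) {
  h <- nrow(open); w <- ncol(open)
  reach <- matrix(FALSE, h, w)
  reach[1, ] <- open[1, ]; reach[h, ] <- open[h, ]
  reach[, 1] <- reach[, 1] | open[, 1]; reach[, w] <- reach[, w] | open[, w]
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-h, ]
    grown[-h, ] <- grown[-h, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -w]
    grown[, -w] <- grown[, -w] | reach[, -1]
    grown <- grown & open
    if (identical(grown, reach)) return(reach)
    reach <- grown
  }
}

# number of 8-connected components of a logical matrix (tiny BFS)
count_components8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  n <- 0
  idx <- which(mask)
  for (p in idx) {
    if (seen[p]) next
    n <- n + 1
    queue <- p
    seen[p] <- TRUE
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      r <- (q - 1) %% h + 1; cc <- (q - 1) %/% h + 1
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; ccc <- cc + dc
        if (rr < 1 || rr > h || ccc < 1 || ccc > w) next
        pp <- (ccc - 1) * h + rr
        if (mask[pp] && !seen[pp]) { seen[pp] <- TRUE; queue <- c(queue, pp) }
      }
    }
  }
  n
}

# build an edge_map object directly from a logical matrix
as_edge_map <- function(mask, params = canny_params()) {
  structure(list(edges = mask, width = ncol(mask), height = nrow(mask),
                 params = params),
            class = "edge_map")
}
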