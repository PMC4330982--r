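# Fixtures and independent oracles shared across the suite.

# brute-force elementwise maximum across planes, pixel by pixel
mip_oracle <- function(arr) {
  out <- matrix(-Inf, dim(arr)[1], dim(arr)[2])
  for (i in seq_len(dim(arr)[1])) {
    for (j in seq_len(dim(arr)[2])) {
      for (p in seq_len(dim(arr)[3])) {
        if (arr[i, j, p] > out[i, j]) out[i, j] <- arr[i, j, p]
      }
    }
  }
  out
}

# binary disk image with optional Gaussian noise floor
disk_image <- function(h, w, centers, radius, fg = 1000, bg = 100,
                       noise_sd = 3, seed = 1) {
  set.seed(seed)
  img <- matrix(bg, h, w)
  for (ctr in centers) {
    d <- sqrt(outer((seq_len(h) - ctr[1])^2, (seq_len(w) - ctr[2])^2, "+"))
    img <- pmax(img, bg + (fg - bg) * (d <= radius))
  }
  img + matrix(rnorm(h * w, 0, noise_sd), h, w)
}

# synthetic foci patch: background + k Gaussian spots at given (row, col)
spot_image <- function(h, w, spots, amp = 1000, sigma = 1.5, bg = 200,
                       noise_sd = 5, seed = 1) {
  set.seed(seed)
  img <- matrix(bg, h, w)
  for (sp in spots) {
    d2 <- outer((seq_len(h) - sp[1])^2, (seq_len(w) - sp[2])^2, "+")
    img <- img + amp * exp(-d2 / (2 * sigma^2))
  }
  img + matrix(rnorm(h * w, 0, noise_sd), h, w)
}

# a full-image disk mask built through the package's segmentation so tests
# exercising count_foci get a realistic nucleus_mask object
disk_mask <- function(h, w, center, radius) {
  dapi <- disk_image(h, w, list(center), radius, noise_sd = 0)
  cfg <- foci_config(nucleus_area_px = c(10, h * w))
  masks <- segment_nuclei(dapi, cfg)
  stopifnot(length(masks) == 1)
  masks[[1]]
}

# match detected nuclei to truth nuclei by centroid proximity
match_truth <- function(records, truth_nuclei, max_dist = 5) {
  vapply(seq_len(nrow(records)), function(i) {
    d <- sqrt((truth_nuclei$cy - records$centroid_row[i])^2 +
                (truth_nuclei$cx - records$centroid_col[i])^2)
    j <- which.min(d)
    if (d[j] < max_dist) j else NA_integer_
  }, integer(1))
}

# shoelace polygon area of the convex hull of pixel centres: an oracle for
# solidity that is independent of the package's lattice-point counting
solidity_oracle <- function(mask) {
  rc <- arrayInd(mask$pixels, mask$dim)
  pts <- unique(cbind(rc[, 2], rc[, 1]))
  hp <- pts[grDevices::chull(pts), , drop = FALSE]
  x <- hp[, 1]; y <- hp[, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  length(mask$pixels) / area
}
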