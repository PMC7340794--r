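# shared fixture builders (everything generated in code, nothing stored)

# straight synthetic curve between two points, same structure as the
# generator's curves
straight_curve <- function(x0, y0, x1, y1) {
  u <- seq(0, 1, length.out = 11)
  fx <- stats::splinefun(u, x0 + u * (x1 - x0), method = "natural")
  fy <- stats::splinefun(u, y0 + u * (y1 - y0), method = "natural")
  ug <- seq(0, 1, length.out = 1001)
  pts <- cbind(fx(ug), fy(ug))
  seg <- sqrt(rowSums(diff(pts)^2))
  structure(list(control = cbind(c(x0, x1), c(y0, y1)), points = pts,
                 arc = c(0, cumsum(seg)), length = sum(seg),
                 fx = fx, fy = fy),
            class = "synthetic_curve")
}

# straight horizontal trace at exactly y (nm), spanning [x0, x1]
straight_trace <- function(y, x0, x1, pixel_size = 10) {
  n <- max(16, round((x1 - x0) / pixel_size))
  cols <- seq(x0, x1, length.out = n) / pixel_size + 0.5
  rows <- rep(y / pixel_size + 0.5, n)
  fit_spline(cbind(rows, cols), pixel_size, smoothing = 0)
}

# image of a straight horizontal tube built from an analytic transverse
# profile (profile_fun takes nm offsets from the tube axis)
tube_image <- function(profile_fun, y_center = 1000, width = 3000,
                       height = 2000, pixel_size = 10) {
  nr <- height / pixel_size; nc <- width / pixel_size
  yy <- (seq_len(nr) - 0.5) * pixel_size - y_center
  col <- profile_fun(yy)
  sr_image(matrix(rep(col, nc), nr, nc), pixel_size)
}

# small random binary mask from thresholded blurred noise
random_mask <- function(seed, n = 80) {
  set.seed(seed)
  img <- sr_image(matrix(stats::runif(n * n), n, n), 10)
  b <- blur_image(img, 25)
  binarize(b, "otsu")$mask
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
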