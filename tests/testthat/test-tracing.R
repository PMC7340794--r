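test_that("gaussian blur conserves intensity and obeys the semigroup", {
  set.seed(5)
  img <- sr_image(matrix(runif(80 * 80), 80, 80), 10)
  expect_identical(blur_image(img, 0)$values, img$values)
  expect_error(blur_image(img, -1), ">= 0")

  # interior intensity conservation
  delta <- sr_image(matrix(0, 81, 81), 10)
  delta$values[41, 41] <- 100
  b <- blur_image(delta, 20)
  expect_lt(abs(sum(b$values) - 100) / 100, 1e-6)

  # a blurred point source is a Gaussian of sigma = 2 px (20 nm / 10 nm/px)
  mid <- b$values[41, ]
  prof <- transverse_profile(((1:81) - 41) * 10, mid)
  fit <- fit_profile(prof, "gaussian")
  expect_rel_equal(fit$params[["w"]], 20, 0.02)

  # two blurs compose like one blur of sqrt(s1^2 + s2^2)
  b2 <- blur_image(blur_image(delta, 15), 20)
  b1 <- blur_image(delta, sqrt(15^2 + 20^2))
  expect_lt(max(abs(b2$values - b1$values)) / max(b1$values), 1e-3)
})

test_that("binarize separates populations and reports its threshold", {
  v <- matrix(0, 20, 20); v[5:15, 5:15] <- 100
  img <- sr_image(v, 10)
  bm <- binarize(img, "otsu")
  expect_identical(bm$mask, v > 50)
  expect_true(bm$threshold > 0 && bm$threshold < 100)

  fx <- binarize(sr_image(matrix(c(40, 60), 2, 2), 10), "fixed",
                 fixed_value = 50)
  expect_identical(fx$mask, matrix(c(FALSE, TRUE), 2, 2))

  expect_error(binarize(sr_image(matrix(1, 5, 5), 10), "otsu"),
               "no contrast")

  li <- binarize(img, "li")
  expect_identical(li$mask, v > 50)
})

test_that("skeletonize thins to one pixel width and preserves structure", {
  # 1-px straight line is unchanged
  line <- matrix(FALSE, 10, 30); line[5, 3:28] <- TRUE
  expect_identical(skeletonize(line), line)

  # filled rectangle reduces to a single 1-px centerline
  rect <- matrix(FALSE, 12, 26); rect[4:8, 3:24] <- TRUE
  sk <- skeletonize(rect)
  expect_true(all(sk[rect == FALSE] == FALSE))       # subset of input
  paths <- extract_lines(sk, min_length = 0, pixel_size = 1)
  expect_equal(length(paths), 1)

  # no 2x2 all-true block anywhere (checked by shifting)
  no_blocks <- function(m) {
    blk <- m[-nrow(m), -ncol(m)] & m[-1, -ncol(m)] &
      m[-nrow(m), -1] & m[-1, -1]
    !any(blk)
  }
  expect_true(no_blocks(sk))

  # empty mask stays empty
  expect_identical(skeletonize(matrix(FALSE, 5, 5)), matrix(FALSE, 5, 5))
})

test_that("skeleton of a thick sine tube follows the generating curve", {
  n <- 200
  m <- matrix(FALSE, 80, n)
  xs <- seq_len(n)
  ys <- 40 + 12 * sin(xs / 15)
  for (i in xs) {
    lo <- max(1, round(ys[i]) - 5); hi <- min(80, round(ys[i]) + 5)
    m[lo:hi, i] <- TRUE
  }
  sk <- skeletonize(m)
  idx <- which(sk, arr.ind = TRUE)
  # distance of each skeleton pixel to the curve
  d <- vapply(seq_len(nrow(idx)), function(k)
    min(sqrt((idx[k, 2] - xs)^2 + (idx[k, 1] - ys)^2)), numeric(1))
  expect_lt(max(d[idx[, 2] > 5 & idx[, 2] < n - 5]), 1.5)
})

test_that("extract_lines splits at junctions and filters by length", {
  # straight 100-px skeleton: one path with all pixels
  line <- matrix(FALSE, 10, 110); line[5, 6:105] <- TRUE
  paths <- extract_lines(line, min_length = 500, pixel_size = 10)
  expect_equal(length(paths), 1)
  expect_equal(nrow(paths[[1]]), 100)

  # short segment below min_length disappears
  seg <- matrix(FALSE, 10, 10); seg[5, 3:7] <- TRUE
  expect_equal(length(extract_lines(seg, min_length = 200,
                                    pixel_size = 10)), 0)

  # T-shaped skeleton: junction-free paths that avoid the branch pixel
  tmask <- matrix(FALSE, 16, 16)
  tmask[5, 2:14] <- TRUE
  tmask[5:13, 8] <- TRUE
  paths <- extract_lines(tmask, min_length = 0, pixel_size = 10)
  expect_gte(length(paths), 2)
  for (p in paths) {
    expect_false(any(p[, 1] == 5 & p[, 2] == 8))  # branch pixel dropped
    # brute force: internal degree within the path is at most 2
    for (i in seq_len(nrow(p))) {
      adj <- abs(p[, 1] - p[i, 1]) <= 1 & abs(p[, 2] - p[i, 2]) <= 1
      expect_lte(sum(adj) - 1, 2)
    }
    # consecutive pixels are 8-connected, no repeats
    expect_true(all(pmax(abs(diff(p[, 1])), abs(diff(p[, 2]))) == 1))
    expect_equal(anyDuplicated(paste(p[, 1], p[, 2])), 0)
  }
})

test_that("path invariants hold across random masks", {
  for (seed in 1:25) {
    sk <- skeletonize(random_mask(seed))
    # one-pixel width: no 2x2 block
    blk <- sk[-nrow(sk), -ncol(sk)] & sk[-1, -ncol(sk)] &
      sk[-nrow(sk), -1] & sk[-1, -1]
    expect_false(any(blk))
    paths <- extract_lines(sk, min_length = 0, pixel_size = 10)
    seen <- character(0)
    for (p in paths) {
      key <- paste(p[, 1], p[, 2])
      expect_equal(anyDuplicated(c(seen, key)), 0)  # pixel in <= 1 path
      seen <- c(seen, key)
      if (nrow(p) > 1)
        expect_true(all(pmax(abs(diff(p[, 1])), abs(diff(p[, 2]))) == 1))
    }
  }
})

test_that("fit_spline reproduces lines and analytic tangents", {
  # collinear points: constant tangent along the diagonal
  path <- cbind(1:20, 1:20)
  tr <- fit_spline(path, pixel_size = 10, smoothing = 0)
  tp <- trace_points(tr, seq(0.1, 0.9, by = 0.1))
  expect_true(all(abs(tp$tangent[, 1] - sqrt(0.5)) < 1e-6))
  expect_true(all(abs(sqrt(rowSums(tp$tangent^2)) - 1) < 1e-9))

  # parabola y = x^2/40: tangent angle matches the analytic derivative
  xs <- seq(-20, 20)
  path2 <- cbind(xs^2 / 40 + 5, xs + 25)   # (row, col) samples, exact
  tr2 <- fit_spline(path2, pixel_size = 1, smoothing = 0)
  tp2 <- trace_points(tr2, seq(0.2, 0.8, by = 0.05))
  xcol <- tp2$xy[, 1] - 24.5               # x relative to the vertex
  ang_fit <- atan2(tp2$tangent[, 2], tp2$tangent[, 1])
  ang_true <- atan(xcol / 20)
  expect_lt(max(abs(ang_fit - ang_true)), 1e-3)

  expect_error(fit_spline(cbind(1:3, 1:3), 10), "too short")
})

test_that("spline curvature decreases monotonically with smoothing", {
  set.seed(6)
  xs <- seq_len(60)
  path <- cbind(round(30 + 10 * sin(xs / 8) + rnorm(60, 0, 0.8)), xs)
  curv <- vapply(c(1e-9, 1e-7, 1e-5, 1e-3), function(lam) {
    tr <- fit_spline(path, pixel_size = 10, smoothing = lam)
    s <- seq(0.05, 0.95, length.out = 200)
    d1 <- tr$deriv(s)
    dd <- diff(d1) / diff(s)
    sum(rowSums(dd^2)) * mean(diff(s))
  }, numeric(1))
  expect_true(all(diff(curv) <= 1e-6 * curv[1]))
})

test_that("trace_filaments finds well-separated straight filaments", {
  # three horizontal Gaussian-profile tubes
  nr <- 200; nc <- 300
  rows <- matrix(0, nr, nc)
  for (r0 in c(40, 100, 160))
    rows <- rows + exp(-((row(rows) - r0)^2) / (2 * 2.5^2))
  img <- sr_image(rows, 10)
  traces <- trace_filaments(img, blur_sigma = 20, min_length = 1000)
  expect_equal(length(traces), 3)
  for (tr in traces) {
    tp <- trace_points(tr, seq(0.1, 0.9, length.out = 50))
    yr <- tp$xy[, 2]
    truth <- c(40, 100, 160)[which.min(abs(mean(yr) / 10 - c(40, 100, 160)))]
    rmse <- sqrt(mean((yr - (truth - 0.5) * 10)^2))
    expect_lt(rmse, 10)  # within 1 px RMS
  }

  # blank image: no traces
  expect_equal(length(trace_filaments(sr_image(matrix(0, 50, 50), 10))), 0)

  # determinism
  t2 <- trace_filaments(img, blur_sigma = 20, min_length = 1000)
  expect_identical(lapply(traces, `[[`, "pixel_path"),
                   lapply(t2, `[[`, "pixel_path"))
  # sorted by length, descending
  lens <- vapply(traces, `[[`, 0, "length")
  expect_true(all(diff(lens) <= 0))
})
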