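test_that("cylinder model evaluates exactly as specified", {
  x <- seq(-40, 40, by = 0.01)
  # degenerate annulus r1 = 0: semicircular profile, value h * r2 at center
  y0 <- eval_model("cylinder", c(h = 2, c = 0, r1 = 0, r2 = 20), x)
  expect_equal(y0[x == 0], 2 * 20)
  expect_equal(y0, 2 * sqrt(pmax(20^2 - x^2, 0)))

  # continuity at |x - c| = r1
  p <- c(h = 1.5, c = 3, r1 = 10, r2 = 25)
  eps <- 1e-9
  left <- eval_model("cylinder", p, 3 + 10 - eps)
  right <- eval_model("cylinder", p, 3 + 10 + eps)
  expect_lt(abs(left - right), 1e-3)
  expect_lt(abs(left - 1.5 * sqrt(25^2 - 10^2)), 1e-3)

  # integral equals h * pi * (r2^2 - r1^2) / 2 (half-annulus area)
  y <- eval_model("cylinder", p, x)
  num <- sum(y) * 0.01
  expect_rel_equal(num, 1.5 * pi * (25^2 - 10^2) / 2, 1e-5)

  expect_error(eval_model("cylinder", c(h = 1, c = 0, r1 = 5, r2 = 5), x),
               "r1 < r2")
})

test_that("noise-free fits recover the generating parameters", {
  x <- seq(-150, 150, by = 1)

  # gaussian with default initialization
  pg <- c(h = 100, c = 5, w = 20, b = 2)
  fg <- fit_profile(transverse_profile(x, eval_model("gaussian", pg, x)),
                    "gaussian")
  expect_lt(max(abs(fg$params[names(pg)] - pg) / pmax(abs(pg), 1)), 1e-8)

  # bigaussian with default initialization; p2p = |c2 - c1|
  pb <- c(h1 = 80, c1 = -50, w1 = 15, h2 = 90, c2 = 50, w2 = 18, b = 3)
  fb <- fit_profile(transverse_profile(x, eval_model("bigaussian", pb, x)),
                    "bigaussian")
  expect_lt(max(abs(fb$params[names(pb)] - pb) / pmax(abs(pb), 1)), 1e-6)
  expect_lt(abs(fb$peak_to_peak - 100), 1e-6)

  # trigaussian, cylinder, multicylinder from perturbed-truth starts
  pt <- c(h1 = 70, c1 = -60, w1 = 14, h2 = 75, c2 = 60, w2 = 16,
          h3 = 20, c3 = 0, w3 = 40, b = 1)
  ft <- fit_profile(transverse_profile(x, eval_model("trigaussian", pt, x)),
                    "trigaussian", init = pt * 1.05)
  expect_lt(max(abs(ft$params[names(pt)] - pt) / pmax(abs(pt), 1)), 1e-6)
  expect_lt(abs(ft$peak_to_peak - 120), 1e-5)

  pc <- c(h = 2, c = 4, r1 = 30, r2 = 60)
  fc <- fit_profile(transverse_profile(x, eval_model("cylinder", pc, x)),
                    "cylinder", init = pc * 1.02)
  expect_lt(max(abs(fc$params[names(pc)] - pc) / pmax(abs(pc), 1)), 1e-6)

  pm <- c(i1 = 2, i2 = 1.5, i3 = 1, c = 0, a = 5, e_x = 3, b = 0.5)
  fm <- fit_profile(transverse_profile(x, eval_model("multicylinder", pm, x)),
                    "multicylinder", init = pm * 1.02)
  expect_lt(max(abs(fm$params[names(pm)] - pm) / pmax(abs(pm), 1)), 1e-6)
})

test_that("peak-to-peak is invariant under shift and scaling", {
  x <- seq(-200, 200, by = 1)
  pb <- c(h1 = 60, c1 = -45, w1 = 16, h2 = 60, c2 = 45, w2 = 16, b = 2)
  base <- fit_profile(transverse_profile(x, eval_model("bigaussian", pb, x)),
                      "bigaussian")$peak_to_peak
  shifted <- pb; shifted[c("c1", "c2")] <- shifted[c("c1", "c2")] + 30
  f_shift <- fit_profile(transverse_profile(
    x, eval_model("bigaussian", shifted, x)), "bigaussian")$peak_to_peak
  f_scale <- fit_profile(transverse_profile(
    x, 7.5 * eval_model("bigaussian", pb, x)), "bigaussian")$peak_to_peak
  expect_lt(abs(base - 90), 1e-6)
  expect_lt(abs(f_shift - base), 1e-6)
  expect_lt(abs(f_scale - base), 1e-6)
})

test_that("overlapping bi-Gaussian peaks are recovered on average", {
  # separation 1.2 w with 1% noise: mean recovered separation within 2%
  x <- seq(-120, 120, by = 2)
  w <- 25; sep <- 1.2 * w
  pb <- c(h1 = 100, c1 = -sep / 2, w1 = w, h2 = 100, c2 = sep / 2,
          w2 = w, b = 0)
  clean <- eval_model("bigaussian", pb, x)
  set.seed(7)
  recovered <- replicate(200, {
    noisy <- clean + rnorm(length(x), 0, 0.01 * max(clean))
    fit_profile(transverse_profile(x, noisy), "bigaussian",
                init = pb)$peak_to_peak
  })
  expect_rel_equal(mean(recovered), sep, 0.02)
})

test_that("profiles extracted from a straight tube are symmetric and match
           the generating cross-section", {
  axis_fine <- seq(-160, 160, by = 0.25)
  shell <- project_shell(40, 60, "uniform", axis_fine)
  blurred <- apply_precision(shell, 0.25, 8)
  pf <- stats::approxfun(axis_fine, blurred, yleft = 0, yright = 0)
  img <- tube_image(pf, y_center = 1000, width = 3000, height = 2000,
                    pixel_size = 10)
  tr <- straight_trace(1000, 200, 2800, pixel_size = 10)
  prof <- extract_profiles(img, tr, half_width = 150, step = 25,
                           axis_step = 1)
  expect_equal(range(prof$axis), c(-150, 150))
  # symmetry
  sym_err <- max(abs(prof$values - rev(prof$values)))
  expect_lt(sym_err, 0.02 * max(prof$values))
  # matches the analytic profile convolved with the pixel kernel: compare
  # against the analytic values directly within 3% RMS (pixelization is
  # absorbed by the tolerance)
  ana <- pf(prof$axis)
  scale <- sum(prof$values * ana) / sum(ana^2)
  rms <- sqrt(mean((prof$values - scale * ana)^2))
  expect_lt(rms, 0.03 * max(scale * ana))
})

test_that("segment statistics use unweighted sample moments", {
  expect_error(aggregate_segments(list(), numeric(0)), "no segments")

  s <- aggregate_segments(list(30, 40), c(2000, 3000))
  expect_equal(s$mean, 35)
  expect_equal(s$sd, sqrt(50))
  expect_equal(s$n_segments, 2)
  expect_equal(s$total_length, 5)

  same <- aggregate_segments(list(50, 50, 50), rep(1000, 3))
  expect_equal(same$sd, 0)

  # sample moments of simulated segments match the direct formulas
  set.seed(8)
  p2p <- rnorm(9, 137, 10)
  st <- aggregate_segments(as.list(p2p), rep(3000, 9))
  expect_equal(st$mean, sum(p2p) / 9)
  expect_equal(st$sd, sqrt(sum((p2p - mean(p2p))^2) / 8))
})

test_that("xz projection stacks per-plane profiles", {
  set.seed(9)
  # uniform stack: every row of the projection is constant
  ustack <- sr_image(array(3, c(4, 60, 120)), 10, pixel_size_z = 50)
  tr <- straight_trace(300, 150, 1050, pixel_size = 10)
  proj <- xz_projection(ustack, tr, half_width = 100, step = 25,
                        axis_step = 2)
  expect_equal(dim(proj$values)[1], 4)
  expect_lt(max(apply(proj$values, 1, function(r) diff(range(r)))), 1e-9)

  # single-plane stack row equals the 2D profile
  plane <- matrix(runif(60 * 120), 60, 120)
  stack1 <- sr_image(array(plane, c(1, 60, 120)), 10, pixel_size_z = 50)
  p1 <- xz_projection(stack1, tr, half_width = 100, step = 25, axis_step = 2)
  p2d <- extract_profiles(sr_image(plane, 10), tr, half_width = 100,
                          step = 25, axis_step = 2)
  expect_equal(as.numeric(p1$values[1, ]), p2d$values)

  expect_error(xz_projection(sr_image(plane, 10), tr), "3D")
})

test_that("xz projection of a hollow 3D tube recovers the tube diameter", {
  R <- 60
  geom <- labeling_geometry(structure_radius = R, linker_igg = 0,
                            sigma_loc = 2)
  curve <- straight_curve(500, 1500, 5500, 1500)
  truth <- ground_truth(list(curve), geom, expansion = 1, density = 4000,
                        background_density = 0, field = c(6000, 3000),
                        three_d = TRUE, seed = 11)
  tab <- sample_localizations(truth)
  stack <- render_stack(tab, pixel_size = 10, z_step = 20,
                        xlim = c(0, 6000), ylim = c(0, 3000),
                        zlim = c(-90, 90))
  tr <- straight_trace(1500, 700, 5300, pixel_size = 10)
  proj <- xz_projection(stack, tr, half_width = 120, step = 20,
                        axis_step = 2)
  mid <- which.min(abs(seq(-90, 90, by = 20) + 10))  # plane covering z ~ 0
  prof <- transverse_profile(seq(-120, 120, by = 2), proj$values[mid, ])
  fit <- fit_profile(prof, "bigaussian")
  expect_rel_equal(fit$peak_to_peak, 2 * R, 0.05)
})

test_that("fit intensity tracks relative labeling density", {
  x <- seq(-120, 120, by = 1)
  pb <- c(h1 = 40, c1 = -35, w1 = 14, h2 = 42, c2 = 35, w2 = 15, b = 1)
  prof <- transverse_profile(x, eval_model("bigaussian", pb, x))
  f1 <- fit_profile(prof, "bigaussian")
  prof2 <- transverse_profile(x, 2 * prof$values)
  f2 <- fit_profile(prof2, "bigaussian")
  expect_rel_equal(relative_label_density(f2),
                   2 * relative_label_density(f1), 1e-6)

  # synthetic tubes with 1:3 density ratio
  axis_fine <- seq(-130, 130, by = 0.25)
  shell <- apply_precision(project_shell(40, 60, "uniform", axis_fine),
                           0.25, 8)
  pf <- stats::approxfun(axis_fine, shell, yleft = 0, yright = 0)
  img1 <- tube_image(function(v) 300 * pf(v), pixel_size = 10)
  img3 <- tube_image(function(v) 900 * pf(v), pixel_size = 10)
  tr <- straight_trace(1000, 200, 2800, pixel_size = 10)
  d1 <- relative_label_density(fit_profile(extract_profiles(img1, tr,
    half_width = 120, axis_step = 2), "bigaussian"))
  d3 <- relative_label_density(fit_profile(extract_profiles(img3, tr,
    half_width = 120, axis_step = 2), "bigaussian"))
  expect_rel_equal(d3 / d1, 3, 0.1)
})
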