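#' Averaged transverse intensity profile
#'
#' Container for the perpendicular line profiles averaged along a trace:
#' a centered nm axis (strictly increasing, symmetric about 0) and the mean
#' intensity at each offset.
#'
#' @param axis nm offsets (uniform grid).
#' @param values averaged intensities.
#' @param n_lines number of contributing line profiles.
#' @param trace_id optional identifier.
#' @return Object of class `transverse_profile`.
#' @export
transverse_profile <- function(axis, values, n_lines = 1L, trace_id = NA) {
  stopifnot(length(axis) == length(values), n_lines >= 1)
  if (any(diff(axis) <= 0)) stop("profile axis must be strictly increasing")
  structure(list(axis = as.numeric(axis), values = as.numeric(values),
                 n_lines = as.integer(n_lines), trace_id = trace_id),
            class = "transverse_profile")
}

#' @export
print.transverse_profile <- function(x, ...) {
  cat(sprintf("<transverse_profile: %d points, [%.1f, %.1f] nm, %d lines>\n",
              length(x$axis), min(x$axis), max(x$axis), x$n_lines))
  invisible(x)
}

#' Extract and average perpendicular profiles along a trace
#'
#' At spline evaluation points spaced `step` nm apart in arc length, a line
#' of length `2 * half_width` perpendicular to the local tangent is sampled
#' from the image by bilinear interpolation on a uniform nm grid.  Lines
#' that leave the image are dropped; the remaining lines are averaged.
#'
#' @param image an [sr_image()] (2D, or one plane of a stack).
#' @param trace a `filament_trace` from [fit_spline()]/[trace_filaments()].
#' @param half_width half profile extent in nm.
#' @param step spacing of evaluation points along the trace, nm.
#' @param axis_step sampling step across the profile, nm.
#' @return A [transverse_profile()].
#' @export
extract_profiles <- function(image, trace, half_width = 250, step = 25,
                             axis_step = 2) {
  stopifnot(inherits(trace, "filament_trace"))
  if (half_width <= 0 || step <= 0) stop("half_width and step must be > 0")
  v <- image$values
  if (is_3d(image)) stop("extract_profiles needs a 2D image; see xz_projection")
  n_s <- max(2L, ceiling(trace$length / step) + 1L)
  s <- seq(0, 1, length.out = n_s)
  tp <- trace_points(trace, s)
  offs <- seq(-half_width, half_width, by = axis_step)
  normal <- cbind(-tp$tangent[, 2], tp$tangent[, 1])
  acc <- numeric(length(offs))
  n_ok <- 0L
  for (i in seq_len(n_s)) {
    xq <- tp$xy[i, 1] + offs * normal[i, 1]
    yq <- tp$xy[i, 2] + offs * normal[i, 2]
    line <- bilinear_sample(v, image, xq, yq)
    if (anyNA(line)) next
    acc <- acc + line
    n_ok <- n_ok + 1L
  }
  if (n_ok == 0L) stop("trace lies (partly) outside the image everywhere")
  transverse_profile(offs, acc / n_ok, n_lines = n_ok)
}

#' Evaluate a cross-section model
#'
#' The five transverse-profile models for (hollow) filament cross sections:
#'
#' * `gaussian`: `h * exp(-(x - c)^2 / (2 w^2)) + b`
#' * `bigaussian`: sum of two Gaussians (`h1, c1, w1, h2, c2, w2`) plus `b`
#' * `trigaussian`: sum of three Gaussians plus `b`
#' * `cylinder`: projection of a uniform annulus with inner/outer radii
#'   `r1 < r2`, amplitude `h`, centered at `c`:
#'   `h * (sqrt(r2^2 - d^2) - sqrt(r1^2 - d^2))` for `d = |x - c| < r1`,
#'   `h * sqrt(r2^2 - d^2)` for `r1 <= d < r2`, else 0
#' * `multicylinder`: three concentric annuli tied to the 25 nm microtubule
#'   core and a shell-thickness parameter `a`, scaled by the expansion
#'   factor `e_x`, with amplitudes `i1, i2, i3`, common center `c` and
#'   offset `b`; shell radii `(12.5 e_x - 2a, 12.5 e_x - a)`,
#'   `(21.25 e_x, 21.25 e_x + a)`, `(12.5 e_x + a, 12.5 e_x + 2a)`
#'
#' @param model model name.
#' @param params named numeric vector/list of parameters (see above).
#' @param x nm offsets.
#' @return Intensities at `x`.
#' @export
eval_model <- function(model, params, x) {
  p <- as.list(params)
  g <- function(h, c0, w, x) h * exp(-(x - c0)^2 / (2 * w^2))
  switch(model,
    gaussian = g(p$h, p$c, p$w, x) + p$b,
    bigaussian = g(p$h1, p$c1, p$w1, x) + g(p$h2, p$c2, p$w2, x) + p$b,
    trigaussian = g(p$h1, p$c1, p$w1, x) + g(p$h2, p$c2, p$w2, x) +
      g(p$h3, p$c3, p$w3, x) + p$b,
    cylinder = cyl_term(p$h, p$c, p$r1, p$r2, x),
    multicylinder = {
      ex <- p$e_x; a <- p$a
      cyl_term(p$i1, p$c, 25 * ex / 2 - 2 * a, 25 * ex / 2 - a, x) +
        cyl_term(p$i2, p$c, 42.5 * ex / 2, 42.5 * ex / 2 + a, x) +
        cyl_term(p$i3, p$c, 25 * ex / 2 + a, 25 * ex / 2 + 2 * a, x) + p$b
    },
    stop("unknown model: ", model))
}

cyl_term <- function(h, c0, r1, r2, x) {
  if (r1 < 0 || r2 <= r1) stop("cylinder model requires 0 <= r1 < r2")
  d2 <- (x - c0)^2
  h * (sqrt(pmax(r2^2 - d2, 0)) - sqrt(pmax(r1^2 - d2, 0)))
}

model_param_names <- function(model) {
  switch(model,
    gaussian = c("h", "c", "w", "b"),
    bigaussian = c("h1", "c1", "w1", "h2", "c2", "w2", "b"),
    trigaussian = c("h1", "c1", "w1", "h2", "c2", "w2", "h3", "c3", "w3", "b"),
    cylinder = c("h", "c", "r1", "r2"),
    multicylinder = c("i1", "i2", "i3", "c", "a", "e_x", "b"),
    stop("unknown model: ", model))
}

# deterministic initial guesses for each model
default_inits <- function(model, axis, y) {
  dx <- axis[2] - axis[1]
  ys <- stats::filter(y, rep(1 / 3, 3), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  b0 <- min(y)
  h0 <- max(y) - b0
  hm <- range(which(y >= b0 + h0 / 2))
  whm <- (axis[hm[2]] - axis[hm[1]]) / 2
  pk <- which(diff(sign(diff(ys))) == -2) + 1
  two_peaks <- NULL
  if (length(pk) >= 2) {
    top <- pk[order(ys[pk], decreasing = TRUE)][1:2]
    two_peaks <- sort(axis[top])
  }
  # local width of the peak nearest x0, from its half-maximum crossings
  peak_width <- function(x0) {
    i <- which.min(abs(axis - x0))
    half <- b0 + (y[i] - b0) / 2
    il <- i; while (il > 1 && y[il] > half) il <- il - 1
    ir <- i; while (ir < length(y) && y[ir] > half) ir <- ir + 1
    max((axis[ir] - axis[il]) / 2.355, 2 * dx)
  }
  cand_centers <- list()
  if (!is.null(two_peaks)) cand_centers <- c(cand_centers, list(two_peaks))
  mid <- (axis[hm[1]] + axis[hm[2]]) / 2
  cand_centers <- c(cand_centers,
                    list(mid + c(-whm, whm) / 1.5),
                    list(mid + c(-whm, whm) / 2))
  w0 <- max(whm / 2, 2 * dx)
  switch(model,
    gaussian = list(c(h = h0, c = sum(axis * (y - b0)) / max(sum(y - b0),
                      .Machine$double.eps), w = max(whm / 1.177, 2 * dx),
                      b = b0)),
    bigaussian = unlist(lapply(cand_centers, function(cc) {
      wsep <- max((cc[2] - cc[1]) / 2, 2 * dx)
      wloc <- c(peak_width(cc[1]), peak_width(cc[2]))
      # separation-scaled widths first: the conventional seeding for
      # sidewall fitting; per-peak and spike-narrow widths as fallbacks
      wsp <- max(3 * dx, whm / 10)
      list(c(h1 = h0, c1 = cc[1], w1 = wsep,
             h2 = h0, c2 = cc[2], w2 = wsep, b = b0),
           c(h1 = h0, c1 = cc[1], w1 = wloc[1],
             h2 = h0, c2 = cc[2], w2 = wloc[2], b = b0),
           c(h1 = h0, c1 = cc[1], w1 = wsp,
             h2 = h0, c2 = cc[2], w2 = wsp, b = b0))
    }), recursive = FALSE),
    trigaussian = lapply(cand_centers, function(cc)
      c(h1 = h0, c1 = cc[1], w1 = w0, h2 = h0, c2 = cc[2], w2 = w0,
        h3 = h0 / 4, c3 = mean(cc), w3 = 2 * whm, b = b0)),
    cylinder = {
      r2g <- max(whm * 1.2, 4 * dx)
      r1g <- if (!is.null(two_peaks)) max(diff(two_peaks) / 2, dx)
             else r2g / 3
      list(c(h = h0 / max(sqrt(max(r2g^2 - r1g^2, dx^2)), dx), c = mid,
             r1 = min(r1g, 0.8 * r2g), r2 = r2g))
    },
    multicylinder = {
      exg <- if (!is.null(two_peaks)) max(diff(two_peaks) / 25, 0.5)
             else max(whm / 25, 0.5)
      list(c(i1 = h0 / max(whm, dx), i2 = h0 / max(whm, dx),
             i3 = h0 / max(whm, dx), c = mid, a = 2.5, e_x = exg, b = b0))
    })
}

#' Fit a cross-section model to a transverse profile
#'
#' Nonlinear least squares (Levenberg-Marquardt).  Initialization follows
#' deterministic heuristics (bi-Gaussian centers from the two highest local
#' maxima of the lightly smoothed profile, with half-maximum fallbacks;
#' cylinder radii from half-maximum crossings); all candidate starts are
#' optimized and the lowest-residual fit wins, so the result is a pure
#' function of the profile and `init`.
#'
#' Peak-to-peak distance: `|c2 - c1|` for the bi-Gaussian; the two
#' outermost centers for the tri-Gaussian; the distance between the two
#' maxima of the fitted curve (located numerically) for the cylinder
#' models.
#'
#' @param profile a [transverse_profile()].
#' @param model one of `"gaussian"`, `"bigaussian"`, `"trigaussian"`,
#'   `"cylinder"`, `"multicylinder"`.
#' @param init optional named starting values (overrides the heuristics).
#' @param max_separation optional upper bound (nm) on the fitted peak
#'   separation; fits violating it are discarded.  Used by the forward
#'   model, where the projected shell bounds the peak positions.
#' @return A `profile_fit`: list with `model`, `params`, `residual_rms`,
#'   `peak_to_peak` (NA for the single Gaussian) and `fitted`.
#' @export
fit_profile <- function(profile, model = "bigaussian", init = NULL,
                        max_separation = NULL) {
  stopifnot(inherits(profile, "transverse_profile"))
  x <- profile$axis; y <- profile$values
  pn <- model_param_names(model)
  if (length(x) < length(pn) + 2)
    stop("profile has too few points for the ", model, " model")
  inits <- if (!is.null(init)) list(unlist(init)[pn]) else
    default_inits(model, x, y)
  resid_fn <- function(p) {
    pv <- stats::setNames(as.numeric(p), pn)
    pv <- repair_params(model, pv)
    eval_model(model, pv, x) - y
  }
  span <- max(x) - min(x)
  fits <- list()
  for (p0 in inits) {
    o <- tryCatch(
      minpack.lm::nls.lm(par = as.numeric(p0[pn]), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(o)) next
    pv0 <- repair_params(model, stats::setNames(as.numeric(o$par), pn))
    fits[[length(fits) + 1]] <-
      list(par = pv0, deviance = o$deviance,
           valid = fit_plausible(model, pv0, x, max_separation))
  }
  if (length(fits) == 0) stop("fit did not converge for model ", model)
  valid <- Filter(function(f) f$valid, fits)
  best <- if (length(valid) > 0) {
    # near-equal optima (within 30% residual) are resolved in favor of the
    # smallest peak separation: the conservative sidewall estimate, which
    # also hands over continuously from the merged-profile optimum to the
    # sharp-peak optimum as the sidewalls become resolved
    dmin <- min(vapply(valid, `[[`, 0, "deviance"))
    near <- Filter(function(f) f$deviance <= 1.3 * dmin, valid)
    sep <- vapply(near, function(f) {
      cn <- intersect(names(f$par), c("c1", "c2", "c3"))
      if (length(cn) >= 2) max(f$par[cn]) - min(f$par[cn])
      else f$deviance / dmin  # single-center models: by residual
    }, numeric(1))
    near[[which.min(sep)]]
  } else {
    fits[[which.min(vapply(fits, `[[`, 0, "deviance"))]]
  }
  pv <- best$par
  check_degenerate(model, pv, x)
  fitted <- eval_model(model, pv, x)
  rms <- sqrt(mean((fitted - y)^2))
  structure(list(model = model, params = pv,
                 residual_rms = rms,
                 peak_to_peak = peak_to_peak(model, pv, x),
                 n_lines = profile$n_lines,
                 trace_id = profile$trace_id,
                 fitted = fitted),
            class = "profile_fit")
}

# sanity screen for a converged fit: components must describe structure
# inside the profile window
fit_plausible <- function(model, p, x, max_separation = NULL) {
  span <- max(x) - min(x)
  cn <- intersect(names(p), c("c", "c1", "c2", "c3"))
  if (any(p[cn] < min(x) | p[cn] > max(x))) return(FALSE)
  if (!is.null(max_separation) && length(cn) >= 2 &&
      max(p[cn]) - min(p[cn]) > max_separation) return(FALSE)
  wn <- intersect(names(p), c("w", "w1", "w2", "w3"))
  if (length(wn) && any(p[wn] > span / 2)) return(FALSE)
  hn <- intersect(names(p), c("h", "h1", "h2", "h3", "i1", "i2", "i3"))
  if (length(hn) && any(p[hn] < 0)) return(FALSE)
  TRUE
}

# canonical form: positive widths, c1 < c2 (< c3), ordered radii
repair_params <- function(model, p) {
  wn <- intersect(names(p), c("w", "w1", "w2", "w3"))
  p[wn] <- abs(p[wn])
  if (model %in% c("bigaussian", "trigaussian")) {
    if (p["c1"] > p["c2"]) {
      tmp <- p[c("h1", "c1", "w1")]
      p[c("h1", "c1", "w1")] <- p[c("h2", "c2", "w2")]
      p[c("h2", "c2", "w2")] <- tmp
    }
  }
  if (model == "cylinder") {
    p[c("r1", "r2")] <- sort(abs(p[c("r1", "r2")]))
    if (p["r2"] <= p["r1"]) p["r2"] <- p["r1"] + 1e-9
  }
  if (model == "multicylinder") {
    p["a"] <- abs(p["a"]); p["e_x"] <- abs(p["e_x"])
    # keep the inner shell radii positive and the shells ordered
    amax <- 0.49 * 25 * p["e_x"] / 2
    if (p["a"] > amax) p["a"] <- amax
    if (p["a"] < 1e-6) p["a"] <- 1e-6
  }
  p
}

check_degenerate <- function(model, p, x) {
  dx <- x[2] - x[1]
  wn <- intersect(names(p), c("w", "w1", "w2", "w3"))
  if (length(wn) && any(p[wn] < dx / 100))
    stop("degenerate fit: Gaussian width collapsed")
  if (model == "cylinder" && (p["r2"] - p["r1"]) < 1e-6)
    stop("degenerate fit: cylinder annulus collapsed (r1 ~ r2)")
  invisible(TRUE)
}

peak_to_peak <- function(model, p, x) {
  switch(model,
    gaussian = NA_real_,
    bigaussian = abs(p[["c2"]] - p[["c1"]]),
    trigaussian = {
      cs <- c(p[["c1"]], p[["c2"]], p[["c3"]])
      max(cs) - min(cs)
    },
    cylinder = ,
    multicylinder = numeric_p2p(model, p, x))
}

# distance between the two maxima of the fitted curve, located numerically
numeric_p2p <- function(model, p, x) {
  grid <- seq(min(x), max(x), length.out = 4001)
  yv <- eval_model(model, p, grid)
  pk <- which(diff(sign(diff(yv))) == -2) + 1
  plateau <- which(yv >= max(yv) - 1e-12 * max(abs(yv)))
  if (length(pk) >= 2) {
    top <- pk[order(yv[pk], decreasing = TRUE)][1:2]
    abs(diff(grid[top]))
  } else if (length(plateau) > 1) {
    # symmetric double maximum resolved as the plateau extremes
    abs(grid[max(plateau)] - grid[min(plateau)])
  } else NA_real_
}

#' Relative labeling density of a fit
#'
#' The fitted intensity amplitude is proportional to the label density:
#' `h` for single-component models, the sum of component amplitudes for
#' multi-component models.
#'
#' @param fit a `profile_fit`.
#' @return Numeric amplitude (intensity units of the profile).
#' @export
relative_label_density <- function(fit) {
  p <- fit$params
  switch(fit$model,
    gaussian = p[["h"]],
    bigaussian = p[["h1"]] + p[["h2"]],
    trigaussian = p[["h1"]] + p[["h2"]] + p[["h3"]],
    cylinder = p[["h"]],
    multicylinder = p[["i1"]] + p[["i2"]] + p[["i3"]])
}

#' Per-segment peak-to-peak statistics
#'
#' Unweighted sample mean and standard deviation (n - 1 denominator) of the
#' per-segment peak-to-peak distances, as displayed in per-segment
#' histograms with an overlaid normal curve.
#'
#' @param fits list of `profile_fit` objects (or numeric p2p values).
#' @param lengths segment lengths in nm (same order).
#' @return List with `per_segment_p2p` (nm), `mean`, `sd`, `n_segments`,
#'   `total_length` (micrometer), class `segment_statistics`.
#' @export
aggregate_segments <- function(fits, lengths) {
  if (length(fits) == 0) stop("no segments to aggregate")
  if (length(fits) != length(lengths))
    stop("fits and lengths must have equal length")
  p2p <- vapply(fits, function(f)
    if (is.numeric(f)) f else f$peak_to_peak, numeric(1))
  structure(list(per_segment_p2p = p2p,
                 mean = mean(p2p),
                 sd = if (length(p2p) > 1) stats::sd(p2p) else 0,
                 n_segments = length(p2p),
                 total_length = sum(lengths) / 1000),
            class = "segment_statistics")
}

#' @export
print.segment_statistics <- function(x, ...) {
  cat(sprintf("%.1f +/- %.1f nm (mean +/- sd), n = %d segments, %.1f um total\n",
              x$mean, x$sd, x$n_segments, x$total_length))
  invisible(x)
}

#' xz projection of a 3D stack along a lateral trace
#'
#' For each z plane the averaged perpendicular profile along the (lateral)
#' trace is computed; stacking these profiles row by row yields a side-view
#' image whose rows are z planes and whose columns are transverse nm
#' offsets.
#'
#' @param stack a 3D [sr_image()] (`planes x rows x cols`).
#' @param trace a `filament_trace` defined in the lateral plane.
#' @param half_width half profile extent in nm.
#' @param step,axis_step sampling steps, nm (see [extract_profiles()]).
#' @return A 2D [sr_image()]; pixel size along x is `axis_step`, along y
#'   the stack's plane spacing.
#' @export
xz_projection <- function(stack, trace, half_width = 250, step = 25,
                          axis_step = 2) {
  if (!is_3d(stack)) stop("xz_projection requires a 3D stack")
  nz <- dim(stack$values)[1]
  rows <- vector("list", nz)
  for (k in seq_len(nz)) {
    plane <- sr_image(stack$values[k, , ], stack$pixel_size_xy,
                      origin = stack$origin)
    prof <- extract_profiles(plane, trace, half_width = half_width,
                             step = step, axis_step = axis_step)
    rows[[k]] <- prof$values
  }
  m <- do.call(rbind, rows)
  sr_image(m, pixel_size_xy = axis_step,
           origin = c(-half_width, 0))
}

#' Export fit results to a data frame
#'
#' @param fits list of `profile_fit` objects.
#' @return data.frame with model, parameters (as JSON), peak-to-peak,
#'   residual RMS and line counts.
#' @export
fits_to_df <- function(fits) {
  do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(trace = i, model = f$model,
               peak_to_peak = f$peak_to_peak,
               residual_rms = f$residual_rms,
               n_lines = f$n_lines,
               params = as.character(jsonlite::toJSON(as.list(f$params),
                                                      auto_unbox = TRUE,
                                                      digits = 10)))
  }))
}
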