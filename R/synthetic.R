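# Seeded synthetic SMLM data: ground-truth filaments with hollow-cylinder
# label shells, localization noise and uniform background.  One explicit
# integer seed drives a local RNG stream; the global RNG state is restored
# afterwards.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate smooth random ground-truth curves
#'
#' The set shares a random base direction; each curve runs along its own
#' jittered direction at an evenly spaced perpendicular offset (a
#' quasi-parallel arrangement, as in a field of view crossed by several
#' filament stretches), as a cubic spline through control points jittered
#' perpendicular to the chord with amplitude set by `curvature_scale`
#' (0 gives straight segments).  Curves are redrawn until all pairwise
#' distances are at least `min_separation` (bounded retries).
#' Reproducible by `seed`.
#'
#' @param n number of curves (>= 1).
#' @param field field of view `c(width, height)` in nm.
#' @param curvature_scale dimensionless jitter amplitude per control-point
#'   spacing (typical 0 to 0.1).
#' @param min_separation minimum pairwise curve distance, nm.
#' @param seed integer seed.
#' @param max_retries redraw attempts before giving up.
#' @return List of curve objects (`synthetic_curve`), each with dense
#'   `points` (nm), cumulative `arc` and total `length`.
#' @export
generate_curves <- function(n, field = c(20000, 20000),
                            curvature_scale = 0.005,
                            min_separation = 1000, seed = 1,
                            max_retries = 200) {
  stopifnot(n >= 1, all(field > 0))
  with_seed(seed, {
    theta0 <- stats::runif(1, 0, pi)
    curves <- list()
    tries <- 0
    while (length(curves) < n) {
      i <- length(curves) + 1
      cand <- random_curve(field, curvature_scale, theta0,
                           offset_frac = 0.2 + 0.6 * (i - 0.5) / n)
      if (all(vapply(curves, function(cv)
        min_curve_distance(cv, cand) >= min_separation, logical(1)))) {
        curves[[length(curves) + 1]] <- cand
      } else {
        tries <- tries + 1
        if (tries > max_retries)
          stop("cannot place ", n, " curves with min_separation = ",
               min_separation, " nm after ", max_retries, " retries")
      }
    }
    curves
  })
}

random_curve <- function(field, curvature_scale, theta0 = NULL,
                         offset_frac = 0.5) {
  margin <- 0.08 * min(field)
  theta <- if (is.null(theta0)) stats::runif(1, 0, pi) else
    theta0 + stats::rnorm(1, 0, 0.05)
  dir <- c(cos(theta), sin(theta))
  nrm <- c(-dir[2], dir[1])
  mid <- field / 2
  span <- sum(abs(nrm * field)) / 2
  off <- (offset_frac - 0.5 + stats::runif(1, -0.03, 0.03)) * 2 * span
  center <- mid + off * nrm
  center <- pmin(pmax(center, 1.5 * margin), field - 1.5 * margin)
  # largest |t| range keeping center + t * dir inside the margins
  t_lo <- -Inf; t_hi <- Inf
  for (ax in 1:2) {
    if (abs(dir[ax]) < 1e-12) next
    tt <- sort(c((margin - center[ax]) / dir[ax],
                 (field[ax] - margin - center[ax]) / dir[ax]))
    t_lo <- max(t_lo, tt[1]); t_hi <- min(t_hi, tt[2])
  }
  spacing <- 2000
  tgrid <- seq(t_lo, t_hi, length.out = max(4L, ceiling((t_hi - t_lo) /
                                                         spacing) + 1L))
  offs <- if (curvature_scale > 0)
    stats::rnorm(length(tgrid), 0, curvature_scale * spacing) else
    rep(0, length(tgrid))
  ctrl <- cbind(center[1] + tgrid * dir[1] + offs * nrm[1],
                center[2] + tgrid * dir[2] + offs * nrm[2])
  ctrl[, 1] <- pmin(pmax(ctrl[, 1], margin), field[1] - margin)
  ctrl[, 2] <- pmin(pmax(ctrl[, 2], margin), field[2] - margin)
  u <- seq(0, 1, length.out = nrow(ctrl))
  fx <- stats::splinefun(u, ctrl[, 1], method = "natural")
  fy <- stats::splinefun(u, ctrl[, 2], method = "natural")
  ug <- seq(0, 1, length.out = 1001)
  pts <- cbind(fx(ug), fy(ug))
  seg <- sqrt(rowSums(diff(pts)^2))
  structure(list(control = ctrl, points = pts,
                 arc = c(0, cumsum(seg)), length = sum(seg),
                 fx = fx, fy = fy),
            class = "synthetic_curve")
}

min_curve_distance <- function(a, b) {
  pa <- a$points[seq(1, nrow(a$points), by = 10), , drop = FALSE]
  pb <- b$points[seq(1, nrow(b$points), by = 10), , drop = FALSE]
  min(sqrt(outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2))
}

# position and unit tangent at arc-length fraction(s) f in [0, 1]
curve_at <- function(curve, f) {
  starget <- f * curve$length
  u <- stats::approx(curve$arc, seq(0, 1, length.out = length(curve$arc)),
                     xout = starget, rule = 2)$y
  xy <- cbind(curve$fx(u), curve$fy(u))
  d <- cbind(curve$fx(u, deriv = 1), curve$fy(u, deriv = 1))
  nrm <- sqrt(rowSums(d^2)); nrm[nrm == 0] <- 1
  list(xy = xy, tangent = d / nrm)
}

#' Ground-truth description for the synthetic generator
#'
#' @param curves from [generate_curves()].
#' @param geometry a [labeling_geometry()] describing the label shell.
#' @param expansion expansion factor applied to the shell radii.
#' @param density filament localizations per micrometer of filament.
#' @param background_density background localizations per square
#'   micrometer.
#' @param sigma_loc localization precision, nm (default: the geometry's).
#' @param field field of view `c(width, height)`, nm.
#' @param three_d keep axial offsets in a `z` column.
#' @param seed integer seed for [sample_localizations()].
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(curves, geometry, expansion = 1,
                         density = 600, background_density = 2,
                         sigma_loc = NULL, field = c(20000, 20000),
                         three_d = FALSE, seed = 1) {
  stopifnot(density >= 0, background_density >= 0)
  if (is.null(sigma_loc)) sigma_loc <- geometry$sigma_loc
  structure(list(curves = curves, geometry = geometry,
                 expansion = expansion, density = density,
                 background_density = background_density,
                 sigma_loc = sigma_loc, field = field,
                 three_d = isTRUE(three_d), seed = as.integer(seed)),
            class = "ground_truth")
}

#' Sample a localization table from a ground truth
#'
#' The number of filament localizations is Poisson with mean
#' `density x total filament length`.  Each localization takes a uniform
#' arc position, a uniform azimuth on the label cylinder, a radial offset
#' drawn from the geometry's fluorophore shell (scaled by the expansion
#' flags), and isotropic Gaussian localization noise `sigma_loc`.
#' Background localizations are uniform over the field.  Fully reproducible
#' from `truth$seed`.
#'
#' @param truth a [ground_truth()].
#' @return A [localization_table()] (with `z` when `truth$three_d`).
#' @export
sample_localizations <- function(truth) {
  g <- truth$geometry
  rr <- shell_radii(g, truth$expansion)
  total_len <- sum(vapply(truth$curves, `[[`, 0, "length"))
  with_seed(truth$seed, {
    n_fil <- stats::rpois(1, truth$density * total_len / 1000)
    lens <- vapply(truth$curves, `[[`, 0, "length")
    ci <- if (n_fil > 0)
      sample.int(length(truth$curves), n_fil, replace = TRUE,
                 prob = lens) else integer(0)
    xs <- ys <- zs <- numeric(n_fil)
    for (k in seq_along(truth$curves)) {
      sel <- which(ci == k)
      if (length(sel) == 0) next
      f <- stats::runif(length(sel))
      ca <- curve_at(truth$curves[[k]], f)
      phi <- stats::runif(length(sel), 0, 2 * pi)
      r <- sample_shell_radius(length(sel), rr)
      lat <- r * cos(phi)         # in-plane offset along the normal
      ax <- r * sin(phi)          # axial offset
      nx <- -ca$tangent[, 2]; ny <- ca$tangent[, 1]
      xs[sel] <- ca$xy[, 1] + lat * nx
      ys[sel] <- ca$xy[, 2] + lat * ny
      zs[sel] <- ax
    }
    n_bg <- stats::rpois(1, truth$background_density *
                            prod(truth$field) / 1e6)
    bx <- stats::runif(n_bg, 0, truth$field[1])
    by <- stats::runif(n_bg, 0, truth$field[2])
    bz <- stats::runif(n_bg, -rr[2], rr[2])
    x <- c(xs, bx); y <- c(ys, by); z <- c(zs, bz)
    n <- length(x)
    if (truth$sigma_loc > 0 && n > 0) {
      x <- x + stats::rnorm(n, 0, truth$sigma_loc)
      y <- y + stats::rnorm(n, 0, truth$sigma_loc)
      z <- z + stats::rnorm(n, 0, truth$sigma_loc)
    }
    localization_table(frame = seq_len(n), x = x, y = y,
                       z = if (truth$three_d) z else NULL,
                       intensity = stats::rexp(n, 1 / 1000),
                       uncertainty = rep(truth$sigma_loc, n))
  })
}

sample_shell_radius <- function(n, rr) {
  if (rr[1] >= rr[2] - 1e-12) rep(rr[1], n)
  else sqrt(stats::runif(n, rr[1]^2, rr[2]^2))  # uniform area density
}

#' Render a localization table into a 3D stack
#'
#' Bins `z` into planes of thickness `z_step` and renders each slab with
#' [render_histogram()] on a common lateral grid.
#'
#' @param table a [localization_table()] with a `z` column.
#' @param pixel_size lateral pixel size, nm.
#' @param z_step plane thickness, nm.
#' @param xlim,ylim lateral extents, nm.
#' @param zlim axial extent `c(min, max)`, nm.
#' @return A 3D [sr_image()].
#' @export
render_stack <- function(table, pixel_size = 10, z_step = 25,
                         xlim, ylim, zlim = NULL) {
  if (is.null(table$z)) stop("render_stack needs a z column")
  if (is.null(zlim)) zlim <- range(table$z)
  edges <- seq(zlim[1], zlim[2] + z_step, by = z_step)
  planes <- vector("list", length(edges) - 1)
  for (k in seq_along(planes)) {
    sel <- table$z >= edges[k] & table$z < edges[k + 1]
    sub <- table[sel, , drop = FALSE]
    planes[[k]] <- if (nrow(sub) == 0) NULL else
      render_histogram(validate_localization_table(sub), pixel_size,
                       mode = "counts", xlim = xlim, ylim = ylim)$values
  }
  d <- NULL
  for (p in planes) if (!is.null(p)) { d <- dim(p); break }
  if (is.null(d)) stop("no localizations in any plane")
  v <- array(0, c(length(planes), d[1], d[2]))
  for (k in seq_along(planes))
    if (!is.null(planes[[k]])) v[k, , ] <- planes[[k]]
  sr_image(v, pixel_size, pixel_size_z = z_step,
           origin = c(xlim[1], ylim[1]))
}

#' Build a complete synthetic fixture
#'
#' Samples localizations, renders a counts-mode image over the full field
#' (so the image origin is exact), and assembles a manifest holding every
#' ground-truth parameter for later assertions.  Regenerating from the
#' manifest reproduces the fixture bit for bit.
#'
#' @param truth a [ground_truth()].
#' @param pixel_size render pixel size, nm (default 10).
#' @return List with `image` ([sr_image()]), `table`
#'   ([localization_table()]) and `manifest` (plain list, JSON-ready).
#' @export
make_fixture <- function(truth, pixel_size = 10) {
  table <- sample_localizations(truth)
  image <- render_histogram(table, pixel_size, mode = "counts",
                            xlim = c(0, truth$field[1]),
                            ylim = c(0, truth$field[2]))
  g <- truth$geometry
  manifest <- list(
    seed = truth$seed,
    expansion = truth$expansion,
    density = truth$density,
    background_density = truth$background_density,
    sigma_loc = truth$sigma_loc,
    field = truth$field,
    three_d = truth$three_d,
    pixel_size = pixel_size,
    n_curves = length(truth$curves),
    curve_lengths = vapply(truth$curves, `[[`, 0, "length"),
    geometry = g[setdiff(names(g), "fluorophore_distribution")],
    shell_radii = shell_radii(g, truth$expansion),
    n_localizations = nrow(table))
  list(image = image, table = table, manifest = manifest)
}
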