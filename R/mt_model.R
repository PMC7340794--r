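#' Labeling geometry of an immunostained (expanded) microtubule
#'
#' Describes where the fluorophores sit relative to the microtubule wall
#' and how that shell scales with gel expansion.  The microtubule is a
#' hollow cylinder of outer radius `structure_radius` (12.5 nm); the
#' immunolabel adds a radial linker: 17.5 nm for a primary + secondary IgG
#' stack (`linker_igg`), plus an optional DNA linker of `dna_bases` bases.
#'
#' `linker_conformation` selects the effective fluorophore position:
#'
#' * `"free"` — unexpanded, unanchored label: antibody orientations are
#'   averaged, giving an effective ring at
#'   `structure_radius + orientation_factor * linker length`;
#' * `"extended"` — gel-anchored label under expansion: the linker is taut,
#'   the fluorophore ring sits at the full radial extent (dsDNA linkers use
#'   the B-DNA rise of 0.34 nm/base);
#' * `"coiled"` — single-stranded DNA that coiled during gelation: the DNA
#'   contribution is the worm-like-chain end-to-end distance
#'   `sqrt(2 * persistence * contour)` with `ss_rise` nm contour per base.
#'
#' `expands_structure`/`expands_linker` control which radial lengths scale
#' with the expansion factor: pre-expansion labels are embedded in the gel
#' and dilate with it (both `TRUE`); post-expansion labels are applied to
#' the already expanded structure (`expands_linker = FALSE`).
#' `sigma_loc` is the localization-precision blur (nm) applied to the
#' projected profile.
#'
#' @param name preset name (informational).
#' @param structure_radius microtubule outer radius, nm.
#' @param linker_igg radial extent of the antibody stack, nm.
#' @param dna_bases DNA linker length in bases (0 for none).
#' @param linker_conformation `"free"`, `"extended"` or `"coiled"`.
#' @param orientation_factor mean outward projection of a freely oriented
#'   label (used by `"free"`).
#' @param expands_structure,expands_linker logical expansion flags.
#' @param sigma_loc localization precision (Gaussian sigma), nm.
#' @param fluorophore_distribution `"ring"` (thin shell at the label
#'   radius), `"uniform"` (uniform density over the label shell), or a
#'   radial density function `rho(r)`.
#' @param dna_rise,ss_rise,ss_persistence DNA model constants, nm.
#' @return Object of class `labeling_geometry`.
#' @export
labeling_geometry <- function(name = "custom",
                              structure_radius = 12.5,
                              linker_igg = 17.5,
                              dna_bases = 0,
                              linker_conformation = c("extended", "coiled",
                                                      "free"),
                              orientation_factor = 0.65,
                              expands_structure = TRUE,
                              expands_linker = TRUE,
                              sigma_loc = 6,
                              fluorophore_distribution = "ring",
                              dna_rise = 0.34,
                              ss_rise = 0.6,
                              ss_persistence = 2.5) {
  linker_conformation <- match.arg(linker_conformation)
  stopifnot(structure_radius >= 0, linker_igg >= 0, dna_bases >= 0,
            sigma_loc >= 0, orientation_factor > 0, orientation_factor <= 1)
  structure(list(name = name,
                 structure_radius = structure_radius,
                 linker_igg = linker_igg,
                 dna_bases = dna_bases,
                 linker_conformation = linker_conformation,
                 orientation_factor = orientation_factor,
                 expands_structure = isTRUE(expands_structure),
                 expands_linker = isTRUE(expands_linker),
                 sigma_loc = sigma_loc,
                 fluorophore_distribution = fluorophore_distribution,
                 dna_rise = dna_rise,
                 ss_rise = ss_rise,
                 ss_persistence = ss_persistence),
            class = "labeling_geometry")
}

#' @export
print.labeling_geometry <- function(x, ...) {
  cat(sprintf("<labeling_geometry '%s': r=%.1f nm + linker %.2f nm (%s), sigma_loc=%.1f nm, %s-labeling>\n",
              x$name, x$structure_radius, linker_extent(x),
              x$linker_conformation, x$sigma_loc,
              if (x$expands_linker) "pre" else "post"))
  invisible(x)
}

#' DNA linker length
#'
#' Extended double-stranded DNA uses the B-DNA rise (0.34 nm per base);
#' coiled single-stranded DNA uses the worm-like-chain end-to-end estimate
#' `sqrt(2 * persistence * contour)` with `ss_rise` nm of contour per base.
#'
#' @param bases number of bases (>= 0).
#' @param conformation `"extended"` or `"coiled"`.
#' @param rise B-DNA rise per base, nm.
#' @param ss_rise ssDNA contour length per base, nm.
#' @param persistence ssDNA persistence length, nm.
#' @return Length in nm.
#' @export
dna_linker_length <- function(bases, conformation = c("extended", "coiled"),
                              rise = 0.34, ss_rise = 0.6, persistence = 2.5) {
  conformation <- match.arg(conformation)
  stopifnot(bases >= 0)
  if (bases == 0) return(0)
  switch(conformation,
    extended = bases * rise,
    coiled = sqrt(2 * persistence * bases * ss_rise))
}

# total radial linker extent (nm) after conformation handling
linker_extent <- function(geometry) {
  g <- geometry
  dna <- if (g$dna_bases > 0) {
    conf <- if (g$linker_conformation == "coiled") "coiled" else "extended"
    dna_linker_length(g$dna_bases, conf, rise = g$dna_rise,
                      ss_rise = g$ss_rise, persistence = g$ss_persistence)
  } else 0
  L <- g$linker_igg + dna
  if (g$linker_conformation == "free") L <- g$orientation_factor * L
  L
}

# fluorophore shell radii [r_in, r_out] at a given expansion factor
shell_radii <- function(geometry, expansion) {
  g <- geometry
  es <- if (g$expands_structure) expansion else 1
  el <- if (g$expands_linker) expansion else 1
  rs <- g$structure_radius * es
  L <- linker_extent(g) * el
  if (identical(g$fluorophore_distribution, "ring"))
    c(rs + L, rs + L)
  else
    c(rs, rs + L)
}

#' Project a cylindrically symmetric label shell onto the transverse axis
#'
#' Computes the 1D projection `P(x)` of a cylinder-shell fluorophore
#' density: for a density `rho(r)` (per unit cross-section area),
#' `P(x) = 2 * integral rho(r) r / sqrt(r^2 - x^2) dr`.  For a uniform
#' density this is the classic hollow-cylinder profile
#' `sqrt(r_out^2 - x^2) - sqrt(r_in^2 - x^2)` (the cylinder model shape);
#' the output is normalized to unit area.
#'
#' @param r_in,r_out shell radii, nm (`0 <= r_in < r_out`).
#' @param density `"uniform"` or a function `rho(r)`.
#' @param axis nm grid covering at least `[-r_out, r_out]`.
#' @return Numeric vector of unit-area projected density on `axis`.
#' @export
project_shell <- function(r_in, r_out, density = "uniform", axis) {
  if (r_in < 0 || r_out <= r_in) stop("need 0 <= r_in < r_out")
  dx <- axis[2] - axis[1]
  if (identical(density, "uniform")) {
    y <- sqrt(pmax(r_out^2 - axis^2, 0)) - sqrt(pmax(r_in^2 - axis^2, 0))
  } else if (is.function(density)) {
    y <- vapply(axis, function(x0) {
      umax <- sqrt(max(r_out^2 - x0^2, 0))
      if (umax == 0) return(0)
      u <- seq(0, umax, length.out = 257)
      r <- sqrt(x0^2 + u^2)
      fr <- ifelse(r >= r_in & r <= r_out, density(r), 0)
      2 * sum((fr[-1] + fr[-length(fr)]) / 2 * diff(u))
    }, numeric(1))
  } else stop("density must be \"uniform\" or a function")
  s <- sum(y) * dx
  if (s <= 0) stop("projected density has zero mass on this axis")
  y / s
}

# exact bin-integrated projection of a thin ring of radius R
project_ring <- function(R, axis) {
  dx <- axis[2] - axis[1]
  cdf <- function(t) {
    t <- pmin(pmax(t, -R), R)
    0.5 + asin(t / R) / pi
  }
  y <- (cdf(axis + dx / 2) - cdf(axis - dx / 2)) / dx
  y / (sum(y) * dx)
}

#' Blur a projected profile by the localization precision
#'
#' Convolution with a normalized Gaussian kernel on the (uniform) axis;
#' zero padding outside.  Area is conserved (up to mass blurred past the
#' axis ends); `sigma = 0` is the identity.
#'
#' @param values profile values on a uniform axis.
#' @param dx axis step, nm.
#' @param sigma Gaussian sigma, nm (>= 0).
#' @return Blurred values.
#' @export
apply_precision <- function(values, dx, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(values)
  r <- ceiling(5 * sigma / dx)
  k <- stats::dnorm(seq(-r, r) * dx, sd = sigma)
  k <- k / sum(k)
  padded <- c(rep(0, r), values, rep(0, r))
  out <- stats::filter(padded, k, sides = 2)
  as.numeric(out)[(r + 1):(r + length(values))]
}

# standard evaluation axis of a geometry at a given expansion: the window
# scales with the outer shell radius plus blur margin.  The number of grid
# points is held fixed (the step adapts), so the whole axis -- and with it
# the fitted peak-to-peak -- varies continuously with the expansion
# factor; a fixed step would append grid points in discrete jumps.
profile_axis <- function(r_max, sigma, dx = 0.25) {
  half <- r_max + 5 * sigma + 25
  n_half <- ceiling(100 / dx)  # 801 points at the default dx
  seq(-half, half, length.out = 2 * n_half + 1)
}

geometry_axis <- function(geometry, expansion, dx = 0.25) {
  if (inherits(geometry, "labeling_mix")) {
    r_max <- max(shell_radii(geometry$pre, expansion)[2],
                 shell_radii(geometry$post, expansion)[2])
    sigma <- max(geometry$pre$sigma_loc, geometry$post$sigma_loc)
  } else {
    r_max <- shell_radii(geometry, expansion)[2]
    sigma <- geometry$sigma_loc
  }
  profile_axis(r_max, sigma, dx)
}

#' Predict the transverse profile of a labeled (expanded) microtubule
#'
#' Builds the fluorophore shell at the requested expansion factor, projects
#' it onto the transverse axis ([project_shell()]), and blurs it with the
#' localization precision ([apply_precision()]).  The result is an even,
#' unit-area profile.
#'
#' @param geometry a [labeling_geometry()] or mix preset (see
#'   [geometry_preset()]).
#' @param expansion linear expansion factor (>= 1).
#' @param dx axis step, nm.
#' @param axis optional explicit nm axis (must cover the shell).
#' @return A `predicted_profile`: list with `axis`, `values`, `geometry`,
#'   `expansion`.
#' @export
predict_profile <- function(geometry, expansion = 1, dx = 0.25,
                            axis = NULL) {
  if (expansion < 1) stop("expansion factor must be >= 1")
  if (inherits(geometry, "labeling_mix"))
    return(predict_profile_mix(geometry, expansion, dx, axis))
  stopifnot(inherits(geometry, "labeling_geometry"))
  rr <- shell_radii(geometry, expansion)
  if (is.null(axis)) axis <- geometry_axis(geometry, expansion, dx)
  dxa <- axis[2] - axis[1]
  values <- shell_projection(geometry, rr, axis)
  values <- apply_precision(values, dxa, geometry$sigma_loc)
  values <- values / (sum(values) * dxa)
  structure(list(axis = axis, values = values, geometry = geometry,
                 expansion = expansion),
            class = "predicted_profile")
}

shell_projection <- function(geometry, rr, axis) {
  fd <- geometry$fluorophore_distribution
  if (identical(fd, "ring")) project_ring(rr[1], axis)
  else if (identical(fd, "uniform")) project_shell(rr[1], rr[2], "uniform",
                                                   axis)
  else project_shell(rr[1], rr[2], fd, axis)
}

predict_profile_mix <- function(mix, expansion, dx = 0.25, axis = NULL) {
  r_pre <- shell_radii(mix$pre, expansion)
  r_post <- shell_radii(mix$post, expansion)
  if (is.null(axis)) axis <- geometry_axis(mix, expansion, dx)
  dxa <- axis[2] - axis[1]
  vp <- apply_precision(shell_projection(mix$pre, r_pre, axis), dxa,
                        mix$pre$sigma_loc)
  vq <- apply_precision(shell_projection(mix$post, r_post, axis), dxa,
                        mix$post$sigma_loc)
  vp <- vp / (sum(vp) * dxa); vq <- vq / (sum(vq) * dxa)
  v <- mix$ratio * vp + vq
  v <- v / (sum(v) * dxa)
  structure(list(axis = axis, values = v, geometry = mix,
                 expansion = expansion),
            class = "predicted_profile")
}

#' Superpose pre- and post-labeling profiles
#'
#' Weighted sum `ratio * pre + post`, renormalized to unit area.  Models
#' the dilution of pre-expansion label relative to post-expansion label.
#'
#' @param pre_profile,post_profile `predicted_profile`s on the same axis.
#' @param pre_to_post_ratio weight of the pre profile (>= 0).
#' @return A `predicted_profile`.
#' @export
superpose <- function(pre_profile, post_profile, pre_to_post_ratio) {
  if (pre_to_post_ratio < 0) stop("ratio must be >= 0")
  if (length(pre_profile$axis) != length(post_profile$axis) ||
      max(abs(pre_profile$axis - post_profile$axis)) > 1e-9)
    stop("profiles must share an axis")
  dx <- pre_profile$axis[2] - pre_profile$axis[1]
  v <- pre_to_post_ratio * pre_profile$values + post_profile$values
  v <- v / (sum(v) * dx)
  structure(list(axis = pre_profile$axis, values = v,
                 geometry = list(pre = pre_profile$geometry,
                                 post = post_profile$geometry,
                                 ratio = pre_to_post_ratio),
                 expansion = post_profile$expansion),
            class = "predicted_profile")
}

#' Peak-to-peak distance of a predicted profile
#'
#' Fits the bi-Gaussian cross-section model to the predicted profile and
#' returns the distance between the two fitted centers, exactly as done for
#' measured profiles.
#'
#' @param geometry a [labeling_geometry()] (or mix), or a
#'   `predicted_profile` to reuse directly.
#' @param expansion expansion factor (ignored when a profile is given).
#' @return Peak-to-peak distance in nm.
#' @export
predict_p2p <- function(geometry, expansion = 1) {
  prof <- if (inherits(geometry, "predicted_profile")) geometry
          else predict_profile(geometry, expansion)
  fit_predicted_p2p(prof)
}

fit_predicted_p2p <- function(prof) {
  ys <- stats::filter(prof$values, rep(1 / 3, 3), sides = 2)
  ys[is.na(ys)] <- prof$values[is.na(ys)]
  n_max <- sum(diff(sign(diff(ys))) == -2)
  if (n_max < 2)
    stop("no resolvable sidewalls: predicted profile is unimodal")
  tp <- transverse_profile(prof$axis, prof$values)
  # the blurred shell projection has its maxima strictly inside the outer
  # shell radius (by about half the blur width), so fitted sidewall peaks
  # beyond that are spurious
  g <- prof$geometry
  if (inherits(g, "labeling_mix")) {
    r_out <- max(shell_radii(g$pre, prof$expansion)[2],
                 shell_radii(g$post, prof$expansion)[2])
    sigma <- max(g$pre$sigma_loc, g$post$sigma_loc)
  } else if (!is.null(g$structure_radius)) {
    r_out <- shell_radii(g, prof$expansion)[2]
    sigma <- g$sigma_loc
  } else r_out <- NULL
  max_sep <- if (is.null(r_out)) NULL else
    max(2 * (r_out - 0.5 * sigma), r_out)
  fit <- fit_profile(tp, "bigaussian", max_separation = max_sep)
  unname(fit$peak_to_peak)
}

#' Infer the molecular expansion factor from a measured peak-to-peak
#' distance
#'
#' Inverts [predict_p2p()] by bracketed root finding over expansion factors
#' in `[1, 10]`; valid because the predicted peak-to-peak distance
#' increases strictly with expansion for the shipped geometries.  The
#' result is reported at full precision and rounded to one decimal.
#'
#' @param measured_p2p measured peak-to-peak distance, nm.
#' @param geometry a [labeling_geometry()].
#' @param interval search bracket for the expansion factor.
#' @return List with `expansion` (full precision) and `rounded` (one
#'   decimal).
#' @export
infer_expansion_factor <- function(measured_p2p, geometry,
                                   interval = c(1, 10)) {
  f1 <- predict_p2p(geometry, interval[1])
  if (measured_p2p < f1 - 1e-9)
    stop(sprintf(
      "sub-unity expansion: measured %.1f nm is below the unexpanded prediction %.1f nm",
      measured_p2p, f1))
  if (abs(measured_p2p - f1) <= 1e-9)
    return(list(expansion = interval[1], rounded = round(interval[1], 1)))
  root <- stats::uniroot(function(e) predict_p2p(geometry, e) - measured_p2p,
                         interval = interval, tol = 1e-9)
  list(expansion = root$root, rounded = round(root$root, 1))
}

#' Effective linkage error under expansion
#'
#' Post-expansion labeling leaves the label unexpanded, so on the
#' biological scale the linkage error shrinks by the expansion factor
#' (`label_error / expansion`).  Pre-expansion labels are magnified with
#' the specimen; on the expanded/image scale the error grows to
#' `label_error * expansion`.
#'
#' @param label_error physical label size, nm (e.g. 17.5 for IgG stacks).
#' @param expansion expansion factor (>= 1).
#' @param mode `"post"` (divide) or `"pre"` (multiply).
#' @return Linkage error in nm.
#' @export
effective_linkage_error <- function(label_error, expansion,
                                    mode = c("post", "pre")) {
  mode <- match.arg(mode)
  stopifnot(label_error >= 0, expansion >= 1)
  switch(mode,
    post = label_error / expansion,
    pre = label_error * expansion)
}

#' Expanded (and antibody-broadened) structure diameter
#'
#' @param core_diameter unexpanded structure diameter, nm.
#' @param expansion expansion factor.
#' @param label_error optional pre-expansion label size, nm; when given,
#'   the broadened diameter `core * e + 2 * label_error * e` is returned in
#'   the `broadened` field.
#' @return List with `expanded` (nm) and, if requested, `broadened` (nm).
#' @export
expanded_diameter <- function(core_diameter, expansion, label_error = NULL) {
  out <- list(expanded = core_diameter * expansion)
  if (!is.null(label_error))
    out$broadened <- core_diameter * expansion +
      2 * effective_linkage_error(label_error, expansion, "pre")
  out
}

#' Geometry preset catalogue
#'
#' Reads the labeling-geometry presets shipped with the package
#' (`inst/extdata/geometries.yaml`).  The catalogue pins the parameter set
#' (fluorophore shells, conformations, localization blur) used for all
#' quantitative predictions.
#'
#' @return Named list of preset definitions.
#' @export
geometry_catalogue <- function() {
  path <- system.file("extdata", "geometries.yaml", package = "lineprofiler")
  yaml::read_yaml(path)
}

#' Construct a geometry from a catalogue preset
#'
#' @param name preset name; see [geometry_catalogue()] for the list.
#' @return A [labeling_geometry()], or a `labeling_mix` for superposition
#'   presets.
#' @export
geometry_preset <- function(name) {
  cat_ <- geometry_catalogue()
  if (!name %in% names(cat_))
    stop("unknown geometry preset '", name, "'; available: ",
         paste(names(cat_), collapse = ", "))
  spec <- cat_[[name]]
  if (identical(spec$type, "mix")) {
    structure(list(name = name,
                   pre = geometry_preset(spec$pre),
                   post = geometry_preset(spec$post),
                   ratio = spec$ratio),
              class = "labeling_mix")
  } else {
    spec$type <- NULL
    do.call(labeling_geometry, c(list(name = name), spec))
  }
}
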