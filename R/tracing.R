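#' Gaussian blur of a rendered image
#'
#' Separable Gaussian convolution with sigma given in nm and converted to
#' pixels via the image pixel size.  The kernel is normalized and applied
#' with zero padding, so total intensity is conserved for structures away
#' from the border; `sigma = 0` is the identity.
#'
#' @param image an [sr_image()] (2D).
#' @param sigma Gaussian standard deviation in nm (>= 0).
#' @return Blurred [sr_image()].
#' @export
blur_image <- function(image, sigma) {
  stopifnot(inherits(image, "sr_image"))
  if (sigma < 0) stop("blur sigma must be >= 0")
  if (sigma == 0) return(image)
  spx <- sigma / image$pixel_size_xy
  k <- gauss_kernel(spx)
  v <- image$values
  if (is_3d(image)) {
    for (p in seq_len(dim(v)[1])) v[p, , ] <- sep_conv2(v[p, , ], k)
  } else {
    v <- sep_conv2(v, k)
  }
  out <- image
  out$values <- v
  out
}

gauss_kernel <- function(sigma_px) {
  r <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(seq(-r, r), sd = sigma_px)
  k / sum(k)
}

# separable 2D convolution, zero padded
sep_conv2 <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  conv_cols <- function(mm) {
    padded <- rbind(matrix(0, r, ncol(mm)), mm, matrix(0, r, ncol(mm)))
    f <- stats::filter(padded, k, sides = 2)
    matrix(f[(r + 1):(r + nrow(mm)), ], nrow(mm), ncol(mm))
  }
  t(conv_cols(t(conv_cols(m))))
}

#' Threshold an image to a binary mask
#'
#' Converts the grayscale image to binary; pixels strictly above the
#' threshold become `TRUE`.  `otsu` maximizes between-class variance on a
#' 256-bin histogram; `li` iterates the minimum cross-entropy threshold;
#' `fixed` uses `fixed_value` directly.
#'
#' @param image an [sr_image()] (2D).
#' @param method `"otsu"`, `"li"` or `"fixed"`.
#' @param fixed_value threshold intensity for `method = "fixed"`.
#' @return List with `mask` (logical matrix) and `threshold` (the value
#'   used), classed `binary_mask`.
#' @export
binarize <- function(image, method = c("otsu", "li", "fixed"),
                     fixed_value = NULL) {
  method <- match.arg(method)
  v <- image$values
  if (method != "fixed" && max(v) == min(v))
    stop("no contrast: constant image cannot be thresholded automatically")
  thr <- switch(method,
    otsu = otsu_threshold(v),
    li = li_threshold(v),
    fixed = {
      if (is.null(fixed_value)) stop("fixed method requires fixed_value")
      fixed_value
    })
  structure(list(mask = v > thr, threshold = thr,
                 pixel_size_xy = image$pixel_size_xy,
                 origin = image$origin),
            class = "binary_mask")
}

otsu_threshold <- function(v, nbins = 256L) {
  rng <- range(v)
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- as.numeric(tabulate(findInterval(v, br, rightmost.closed = TRUE),
                           nbins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h); total <- w[nbins]
  mu <- cumsum(h * mids); mu_t <- mu[nbins]
  w0 <- w[-nbins]; w1 <- total - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, nbins - 1L)
  between[valid] <- (mu_t * w0[valid] - total * mu[-nbins][valid])^2 /
    (w0[valid] * w1[valid])
  mids[which.max(between)]
}

li_threshold <- function(v, tol = 1e-6, maxit = 100L) {
  t0 <- mean(v)
  for (i in seq_len(maxit)) {
    fg <- v[v > t0]; bg <- v[v <= t0]
    if (length(fg) == 0 || length(bg) == 0) break
    mf <- mean(fg); mb <- mean(bg)
    if (mb <= 0) mb <- .Machine$double.eps
    if (mf <= 0) mf <- .Machine$double.eps
    t1 <- (mf - mb) / (log(mf) - log(mb))
    if (!is.finite(t1)) break
    if (abs(t1 - t0) < tol) return(t1)
    t0 <- t1
  }
  t0
}

#' Thin a binary mask to a one-pixel-wide skeleton
#'
#' Iterative morphological thinning (Zhang-Suen) followed by a
#' topology-preserving cleanup that removes redundant pixels from any
#' remaining 2x2 blocks.  The skeleton is a subset of the input mask,
#' preserves connectivity, and contains no 2x2 all-true block.
#'
#' @param mask a `binary_mask` (from [binarize()]) or a logical matrix.
#' @return Object of the same type with the thinned mask.
#' @export
skeletonize <- function(mask) {
  m <- if (inherits(mask, "binary_mask")) mask$mask else mask
  storage.mode(m) <- "logical"
  sk <- zhang_suen(m)
  sk <- clean_skeleton(sk)
  sk <- break_blocks(sk)
  if (inherits(mask, "binary_mask")) {
    out <- mask
    out$mask <- sk
    out
  } else sk
}

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# neighbors in the Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW)
zs_neighbors <- function(m) {
  list(p2 = shift_mat(m, 1, 0),   # value of the pixel above -> shifted down
       p3 = shift_mat(m, 1, -1),
       p4 = shift_mat(m, 0, -1),
       p5 = shift_mat(m, -1, -1),
       p6 = shift_mat(m, -1, 0),
       p7 = shift_mat(m, -1, 1),
       p8 = shift_mat(m, 0, 1),
       p9 = shift_mat(m, 1, 1))
}

zhang_suen <- function(m) {
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      nb <- zs_neighbors(m)
      bsum <- Reduce(`+`, lapply(nb, as.numeric))
      seq9 <- nb[c("p2","p3","p4","p5","p6","p7","p8","p9","p2")]
      a <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8)
        a <- a + (!seq9[[i]] & seq9[[i + 1]])
      if (pass == 1) {
        cond3 <- !(nb$p2 & nb$p4 & nb$p6)
        cond4 <- !(nb$p4 & nb$p6 & nb$p8)
      } else {
        cond3 <- !(nb$p2 & nb$p4 & nb$p8)
        cond4 <- !(nb$p2 & nb$p6 & nb$p8)
      }
      del <- m & bsum >= 2 & bsum <= 6 & a == 1L & cond3 & cond4
      if (any(del)) {
        m <- m & !del
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# number of 8-connected components ("arcs") formed by the foreground
# pixels of the 8-neighborhood of (r, c)
neighbor_arcs <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  ring_dr <- c(-1, -1, -1, 0, 1, 1, 1, 0)
  ring_dc <- c(-1, 0, 1, 1, 1, 0, -1, -1)
  fg <- which(vapply(1:8, function(i) {
    rr <- r + ring_dr[i]; cc <- c + ring_dc[i]
    rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && m[rr, cc]
  }, logical(1)))
  if (length(fg) <= 1) return(length(fg))
  pos <- cbind(ring_dr[fg], ring_dc[fg])
  comp <- seq_along(fg)
  for (i in seq_along(fg)) for (j in seq_along(fg)) {
    if (i < j && max(abs(pos[i, ] - pos[j, ])) <= 1)
      comp[comp == comp[j]] <- comp[i]
  }
  length(unique(comp))
}

# simple-point test: removal cannot disconnect anything locally
local_degree_ok <- function(m, r, c) {
  n <- neighbor_arcs(m, r, c)
  n >= 1 && n == 1
}

# crossing number: half the number of value changes when walking the
# 8-neighborhood ring in circular order; 1 = endpoint, 2 = path pixel,
# >= 3 = branch point
crossing_number <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  ring_dr <- c(-1, -1, -1, 0, 1, 1, 1, 0)
  ring_dc <- c(-1, 0, 1, 1, 1, 0, -1, -1)
  vals <- vapply(1:8, function(i) {
    rr <- r + ring_dr[i]; cc <- c + ring_dc[i]
    rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && m[rr, cc]
  }, logical(1))
  sum(vals != c(vals[-1], vals[1])) / 2
}

# remove redundant pixels (staircase corners, 2x2 block fillers): any pixel
# with >= 2 neighbors whose neighborhood forms a single connected arc
# (crossing number <= 1) can be dropped without changing topology.
# Sequential row-major sweeps keep the result deterministic.
clean_skeleton <- function(m) {
  repeat {
    nb <- neighbor_count(m)
    cand <- which(m & nb >= 2, arr.ind = TRUE)
    if (nrow(cand) == 0) return(m)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    changed <- FALSE
    for (k in seq_len(nrow(cand))) {
      r <- cand[k, 1]; c <- cand[k, 2]
      if (!m[r, c]) next
      if (local_neighbors(m, r, c) - 1 < 3) next  # keep path and end pixels
      m[r, c] <- FALSE
      if (local_degree_ok(m, r, c)) changed <- TRUE
      else m[r, c] <- TRUE
    }
    if (!changed) return(m)
  }
}

# enforce the one-pixel-width guarantee on the rare configurations (e.g. a
# 2x2 center of an even-width X crossing) where no simple point exists: one
# block pixel is removed deterministically, preferring topology-safe picks
break_blocks <- function(m) {
  repeat {
    blk <- m & shift_mat(m, -1, 0) & shift_mat(m, 0, -1) &
      shift_mat(m, -1, -1)
    idx <- which(blk, arr.ind = TRUE)
    if (nrow(idx) == 0) return(m)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    r <- idx[1, 1]; c <- idx[1, 2]
    cand <- rbind(c(r, c), c(r, c + 1), c(r + 1, c), c(r + 1, c + 1))
    removed <- FALSE
    for (k in 1:4) {
      rr <- cand[k, 1]; cc <- cand[k, 2]
      m[rr, cc] <- FALSE
      if (local_degree_ok(m, rr, cc)) { removed <- TRUE; break }
      m[rr, cc] <- TRUE
    }
    if (!removed) m[cand[1, 1], cand[1, 2]] <- FALSE
    m <- clean_skeleton(m)
  }
}

local_neighbors <- function(m, r, c) {
  rs <- max(1, r - 1):min(nrow(m), r + 1)
  cs <- max(1, c - 1):min(ncol(m), c + 1)
  sum(m[rs, cs])
}

#' Prune short side branches from a skeleton
#'
#' Boundary noise on a thick tube produces short spurs off the centerline
#' after thinning.  Chains that run from an endpoint into a junction within
#' `max_length` nm are deleted (the junction pixel is kept); the cleanup
#' repeats until stable so the centerline heals into a single chain.
#' Isolated short chains (no junction) are never removed here; the length
#' filter in [extract_lines()] decides their fate.
#'
#' @param mask a `binary_mask` holding a skeleton, or a logical matrix.
#' @param max_length maximum spur length in nm.
#' @param pixel_size nm/px (taken from the mask when available).
#' @return Same type as `mask`, pruned.
#' @export
prune_spurs <- function(mask, max_length, pixel_size = NULL) {
  m <- if (inherits(mask, "binary_mask")) mask$mask else mask
  if (is.null(pixel_size)) {
    pixel_size <- if (inherits(mask, "binary_mask"))
      mask$pixel_size_xy else stop("pixel_size required")
  }
  max_px <- max_length / pixel_size
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  repeat {
    nb <- neighbor_count(m)
    ends <- which(m & nb == 1, arr.ind = TRUE)
    if (nrow(ends) == 0) break
    ends <- ends[order(ends[, 1], ends[, 2]), , drop = FALSE]
    removed_any <- FALSE
    for (k in seq_len(nrow(ends))) {
      r <- ends[k, 1]; c <- ends[k, 2]
      if (!m[r, c] || nb[r, c] != 1) next
      chain <- matrix(c(r, c), 1, 2)
      len <- 0
      prev <- c(-1L, -1L)
      repeat {
        nxt <- NULL
        for (i in 1:8) {
          rr <- r + offs[i, 1]; cc <- c + offs[i, 2]
          if (rr < 1 || rr > nrow(m) || cc < 1 || cc > ncol(m)) next
          if (m[rr, cc] && !(rr == prev[1] && cc == prev[2])) {
            nxt <- c(rr, cc); break
          }
        }
        if (is.null(nxt)) { chain <- NULL; break }     # isolated chain
        if (nb[nxt[1], nxt[2]] >= 3) break             # reached a junction
        len <- len + sqrt(sum((nxt - c(r, c))^2))
        if (len > max_px) { chain <- NULL; break }     # too long: keep
        chain <- rbind(chain, nxt)
        prev <- c(r, c); r <- nxt[1]; c <- nxt[2]
      }
      if (!is.null(chain)) {
        m[chain] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
    m <- clean_skeleton(m)
  }
  if (inherits(mask, "binary_mask")) { mask$mask <- m; mask } else m
}

neighbor_count <- function(m) {
  n <- matrix(0L, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    n <- n + shift_mat(m, dr, dc)
  }
  n
}

#' Split a skeleton into junction-free pixel paths
#'
#' Junction pixels (more than two skeleton neighbors) are treated as
#' breakpoints and discarded; the remaining pixels form chains of internal
#' degree at most two, which are traversed from an endpoint (closed loops
#' are opened at the lexicographically smallest pixel).  Paths shorter than
#' `min_length` (nm, measured along the 8-connected chain) are dropped.
#'
#' @param skeleton a `binary_mask` holding a 1-px-wide skeleton, or a
#'   logical matrix.
#' @param min_length minimum path length in nm.
#' @param pixel_size nm/px (taken from the mask when available).
#' @return List of integer matrices, each `n x 2` of (row, col) pixel
#'   coordinates in traversal order.
#' @export
extract_lines <- function(skeleton, min_length = 0,
                          pixel_size = NULL) {
  m <- if (inherits(skeleton, "binary_mask")) skeleton$mask else skeleton
  if (is.null(pixel_size)) {
    pixel_size <- if (inherits(skeleton, "binary_mask"))
      skeleton$pixel_size_xy else stop("pixel_size required")
  }
  # a branch point has crossing number >= 3 (three separate chains meet);
  # corner pixels with 3 mutually touching neighbors have crossing number
  # 2 and stay ordinary path pixels
  jx <- which(m & neighbor_count(m) >= 3, arr.ind = TRUE)
  m2 <- m
  for (k in seq_len(nrow(jx)))
    if (crossing_number(m, jx[k, 1], jx[k, 2]) >= 3)
      m2[jx[k, 1], jx[k, 2]] <- FALSE
  paths <- list()
  visited <- matrix(FALSE, nrow(m2), ncol(m2))
  nb2 <- neighbor_count(m2)
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  px_idx <- which(m2, arr.ind = TRUE)
  if (nrow(px_idx) == 0) return(paths)
  ord <- order(px_idx[, 2], px_idx[, 1])  # column-major lexicographic
  px_idx <- px_idx[ord, , drop = FALSE]
  endpoint_first <- order(nb2[px_idx] != 1)  # endpoints first, stable
  px_idx <- px_idx[endpoint_first, , drop = FALSE]
  for (k in seq_len(nrow(px_idx))) {
    r0 <- px_idx[k, 1]; c0 <- px_idx[k, 2]
    if (visited[r0, c0]) next
    path <- walk_chain(m2, visited, r0, c0, offs)
    visited <- path$visited
    pp <- shortcut_path(path$pixels)
    if (nrow(pp) < 2) next
    steps <- sqrt(rowSums((pp[-1, , drop = FALSE] -
                           pp[-nrow(pp), , drop = FALSE])^2))
    if (sum(steps) * pixel_size >= min_length)
      paths[[length(paths) + 1]] <- pp
  }
  paths
}

# drop redundant corner pixels: whenever the predecessor and successor of a
# path pixel touch each other directly, the pixel in between is skipped
shortcut_path <- function(pp) {
  repeat {
    n <- nrow(pp)
    if (n < 3) return(pp)
    drop <- rep(FALSE, n)
    changed <- FALSE
    i <- 2
    while (i < n) {
      if (max(abs(pp[i - 1, ] - pp[i + 1, ])) <= 1) {
        drop[i] <- TRUE
        changed <- TRUE
        i <- i + 2
      } else i <- i + 1
    }
    if (!changed) return(pp)
    pp <- pp[!drop, , drop = FALSE]
  }
}

walk_chain <- function(m, visited, r0, c0, offs) {
  pixels <- matrix(c(r0, c0), 1, 2)
  visited[r0, c0] <- TRUE
  r <- r0; c <- c0
  repeat {
    nxt <- NULL
    for (i in seq_len(nrow(offs))) {
      rr <- r + offs[i, 1]; cc <- c + offs[i, 2]
      if (rr < 1 || rr > nrow(m) || cc < 1 || cc > ncol(m)) next
      if (m[rr, cc] && !visited[rr, cc]) { nxt <- c(rr, cc); break }
    }
    if (is.null(nxt)) break
    pixels <- rbind(pixels, nxt)
    visited[nxt[1], nxt[2]] <- TRUE
    r <- nxt[1]; c <- nxt[2]
  }
  # if we started mid-chain (loop opened at lexicographic minimum), walk the
  # other direction too and prepend
  r <- r0; c <- c0
  repeat {
    nxt <- NULL
    for (i in seq_len(nrow(offs))) {
      rr <- r + offs[i, 1]; cc <- c + offs[i, 2]
      if (rr < 1 || rr > nrow(m) || cc < 1 || cc > ncol(m)) next
      if (m[rr, cc] && !visited[rr, cc]) { nxt <- c(rr, cc); break }
    }
    if (is.null(nxt)) break
    pixels <- rbind(nxt, pixels)
    visited[nxt[1], nxt[2]] <- TRUE
    r <- nxt[1]; c <- nxt[2]
  }
  list(pixels = unname(pixels), visited = visited)
}

#' Fit a smoothing spline to a pixel path
#'
#' The path is parameterized by normalized cumulative chord length and each
#' nm coordinate is fit by a cubic smoothing spline (`smoothing` is the
#' roughness-penalty weight lambda; 0 gives an interpolating natural cubic
#' spline).  Tangents come from the first derivative and are normalized to
#' unit length.
#'
#' @param path integer `n x 2` matrix of (row, col) pixel coordinates.
#' @param pixel_size nm/px.
#' @param smoothing roughness penalty lambda (>= 0).
#' @param origin nm coordinates of the top-left image corner.
#' @return A `filament_trace`: list with `pixel_path`, `length` (nm), the
#'   spline evaluators and `smoothing`.
#' @export
fit_spline <- function(path, pixel_size, smoothing = 0, origin = c(0, 0)) {
  if (nrow(path) < 4) stop("path too short for cubic spline (need >= 4 points)")
  x <- origin[1] + (path[, 2] - 0.5) * pixel_size
  y <- origin[2] + (path[, 1] - 0.5) * pixel_size
  d <- sqrt(diff(x)^2 + diff(y)^2)
  u <- c(0, cumsum(d)) / sum(d)
  keep <- c(TRUE, diff(u) > 1e-12)
  x <- x[keep]; y <- y[keep]; u <- u[keep]
  if (length(u) < 4) stop("path too short for cubic spline (need >= 4 points)")
  if (smoothing <= 0) {
    fx <- stats::splinefun(u, x, method = "natural")
    fy <- stats::splinefun(u, y, method = "natural")
    evalxy <- function(s) cbind(fx(s), fy(s))
    evald <- function(s) cbind(fx(s, deriv = 1), fy(s, deriv = 1))
  } else {
    sx <- stats::smooth.spline(u, x, lambda = smoothing, cv = NA,
                               all.knots = TRUE, keep.data = FALSE)
    sy <- stats::smooth.spline(u, y, lambda = smoothing, cv = NA,
                               all.knots = TRUE, keep.data = FALSE)
    evalxy <- function(s) cbind(stats::predict(sx, s)$y,
                                stats::predict(sy, s)$y)
    evald <- function(s) cbind(stats::predict(sx, s, deriv = 1)$y,
                               stats::predict(sy, s, deriv = 1)$y)
  }
  sgrid <- seq(0, 1, length.out = max(100L, 4L * length(u)))
  pts <- evalxy(sgrid)
  len <- sum(sqrt(rowSums(diff(pts)^2)))
  structure(list(pixel_path = path,
                 eval = evalxy,
                 deriv = evald,
                 length = len,
                 smoothing = smoothing,
                 pixel_size = pixel_size),
            class = "filament_trace")
}

#' Evaluate a trace: positions and unit tangents
#'
#' @param trace a `filament_trace`.
#' @param s arc parameter values in `[0, 1]`.
#' @return List with `xy` (`n x 2` nm) and `tangent` (`n x 2`, unit norm).
#' @export
trace_points <- function(trace, s) {
  xy <- trace$eval(s)
  d <- trace$deriv(s)
  nrm <- sqrt(rowSums(d^2))
  nrm[nrm == 0] <- 1
  list(xy = xy, tangent = d / nrm)
}

#' @export
print.filament_trace <- function(x, ...) {
  cat(sprintf("<filament_trace: %d px, length %.1f nm, smoothing %.3g>\n",
              nrow(x$pixel_path), x$length, x$smoothing))
  invisible(x)
}

#' Trace filamentous structures in a rendered image
#'
#' Runs the full detection pipeline: Gaussian blur, thresholding, thinning,
#' junction-free line extraction, length filtering and smoothing-spline
#' fitting.  Deterministic; traces are returned sorted by length
#' (descending).
#'
#' @param image an [sr_image()] (2D).
#' @param blur_sigma pre-threshold blur in nm.
#' @param threshold_method `"otsu"`, `"li"` or `"fixed"`.
#' @param threshold_value threshold for the fixed method.
#' @param min_length minimum filament length in nm.
#' @param fill_holes fill enclosed holes in the binary mask before
#'   thinning (holes in sparsely sampled tubes otherwise become loops).
#' @param spur_length side branches up to this length (nm) are pruned from
#'   the skeleton before line extraction.
#' @param smoothing spline roughness penalty; `NULL` scales a base penalty
#'   with the path length in pixels.
#' @return List of `filament_trace` objects.
#' @export
trace_filaments <- function(image, blur_sigma = 20,
                            threshold_method = "otsu",
                            threshold_value = NULL,
                            min_length = 500,
                            fill_holes = TRUE,
                            spur_length = 300,
                            smoothing = NULL) {
  stopifnot(inherits(image, "sr_image"))
  if (max(image$values) == min(image$values)) return(list())
  b <- blur_image(image, blur_sigma)
  bm <- binarize(b, method = threshold_method, fixed_value = threshold_value)
  if (fill_holes)
    bm$mask <- EBImage::fillHull(bm$mask * 1L) > 0
  sk <- skeletonize(bm)
  if (spur_length > 0) sk <- prune_spurs(sk, spur_length)
  paths <- extract_lines(sk, min_length = min_length,
                         pixel_size = image$pixel_size_xy)
  traces <- list()
  for (p in paths) {
    if (nrow(p) < 4) next
    lam <- if (is.null(smoothing)) 1e-7 * nrow(p) else smoothing
    tr <- tryCatch(fit_spline(p, image$pixel_size_xy, smoothing = lam,
                              origin = image$origin),
                   error = function(e) NULL)
    if (!is.null(tr)) traces[[length(traces) + 1]] <- tr
  }
  if (length(traces) > 1)
    traces <- traces[order(vapply(traces, `[[`, 0, "length"),
                           decreasing = TRUE)]
  traces
}

#' Export traces to a data frame
#'
#' @param traces list of `filament_trace` objects.
#' @param n_points evaluation points per trace.
#' @return data.frame with trace id, arc position, x/y (nm) and tangent
#'   angle (rad); write with [utils::write.csv()] for interchange.
#' @export
traces_to_df <- function(traces, n_points = 100) {
  if (length(traces) == 0)
    return(data.frame(trace = integer(), s = numeric(), x = numeric(),
                      y = numeric(), tangent_angle = numeric()))
  do.call(rbind, lapply(seq_along(traces), function(i) {
    s <- seq(0, 1, length.out = n_points)
    tp <- trace_points(traces[[i]], s)
    data.frame(trace = i, s = s, x = tp$xy[, 1], y = tp$xy[, 2],
               tangent_angle = atan2(tp$tangent[, 2], tp$tangent[, 1]))
  }))
}
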