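#' @useDynLib spindletrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median lm.fit optimize rnorm runif setNames coef lm pf qf
#' @importFrom utils head tail write.csv read.csv
NULL

# ---------------------------------------------------------------------------
# Image container
# ---------------------------------------------------------------------------

#' 3D fluorescence image stack
#'
#' A minimal container for a 3D grid of intensities with anisotropic physical
#' voxel sizes. The intensity array is indexed `[x, y, z]`; voxel `(i, j, k)`
#' (1-based) has its physical center at `((i-0.5)*dx, (j-0.5)*dy, (k-0.5)*dz)`
#' micron, so all feature coordinates live in a continuous physical frame.
#'
#' @param intensities numeric 3D array of non-negative fluorescence values
#'   (arbitrary units). A matrix is promoted to a single-plane stack.
#' @param voxel_size numeric length-3, micron per voxel along (x, y, z).
#' @return an object of class `image_stack` with elements `intensities` and
#'   `voxel_size`.
#' @export
image_stack <- function(intensities, voxel_size = c(0.1, 0.1, 0.5)) {
  if (is.matrix(intensities)) {
    intensities <- array(intensities, dim = c(dim(intensities), 1L))
  }
  stopifnot(is.array(intensities), length(dim(intensities)) == 3L)
  if (!all(is.finite(intensities))) {
    stop("image_stack: all intensities must be finite")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("image_stack: voxel_size must be 3 positive values (micron)")
  }
  structure(list(intensities = intensities, voxel_size = voxel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<image_stack %d x %d x %d voxels, voxel %.3g x %.3g x %.3g um>\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

# A geometry is just the grid shape + voxel sizes; accept a stack or a list.
as_geometry <- function(x) {
  if (inherits(x, "image_stack")) {
    list(dim = dim(x$intensities), voxel_size = x$voxel_size)
  } else if (is.list(x) && !is.null(x$dim) && !is.null(x$voxel_size)) {
    list(dim = as.integer(x$dim), voxel_size = as.numeric(x$voxel_size))
  } else {
    stop("expected an image_stack or a list(dim=, voxel_size=)")
  }
}

# Physical extent of the grid (micron)
geometry_extent <- function(geom) geom$dim * geom$voxel_size

#' Maximum-intensity projection along z
#'
#' @param stack an [image_stack] (or bare 3D array).
#' @return a 2D matrix indexed `[x, y]` of per-column maxima.
#' @export
max_intensity_projection <- function(stack) {
  a <- if (inherits(stack, "image_stack")) stack$intensities else stack
  nz <- dim(a)[3]
  out <- a[, , 1]
  if (nz > 1) for (k in 2:nz) out <- pmax(out, a[, , k])
  out
}

# ---------------------------------------------------------------------------
# Feature types
# ---------------------------------------------------------------------------

check_sigma <- function(sigma) {
  sigma <- as.numeric(sigma)
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  if (length(sigma) != 3L || any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("invalid parameter: widths (sigma) must be 3 strictly positive values",
         call. = FALSE)
  }
  sigma
}

check_point <- function(p, what) {
  p <- as.numeric(p)
  if (length(p) != 3L || any(!is.finite(p))) {
    stop(sprintf("invalid parameter: %s must be a finite 3-vector (micron)", what),
         call. = FALSE)
  }
  p
}

#' Gaussian spot feature
#'
#' A point source of fluorescence (for example a spindle-pole body together
#' with the unresolved short microtubules anchored at it). Intensity at probe
#' position x is `A exp(-((x-x0)/sx)^2 - ((y-y0)/sy)^2 - ((z-z0)/sz)^2)`,
#' with no normalization constant, so `A` is the peak intensity. Seven free
#' parameters: amplitude, center (3) and widths (3).
#'
#' @param amplitude peak intensity, > 0 (arbitrary units).
#' @param center length-3 position (micron).
#' @param sigma length-3 Gaussian widths (micron), all > 0.
#' @return an object of classes `mt_spot`, `mt_feature`.
#' @export
mt_spot <- function(amplitude, center, sigma) {
  if (!is.finite(amplitude) || amplitude <= 0) {
    stop("invalid parameter: amplitude must be positive", call. = FALSE)
  }
  structure(list(amplitude = as.numeric(amplitude),
                 center = check_point(center, "center"),
                 sigma = check_sigma(sigma)),
            class = c("mt_spot", "mt_feature"))
}

#' Gaussian line feature
#'
#' A straight microtubule or bundle: the integral of point Gaussians along
#' the straight centerline from `start` to `end`, parameterized by normalized
#' arc length t in `[0, 1]`. Ten free parameters: amplitude, two endpoints
#' (3 each) and widths (3). A degenerate line with `start == end` renders
#' identically to a spot of the same amplitude and widths.
#'
#' @param amplitude intensity scale (arbitrary units), > 0.
#' @param start,end length-3 endpoint positions (micron).
#' @param sigma length-3 Gaussian widths (micron), all > 0.
#' @return an object of classes `mt_line`, `mt_feature`.
#' @export
mt_line <- function(amplitude, start, end, sigma) {
  if (!is.finite(amplitude) || amplitude <= 0) {
    stop("invalid parameter: amplitude must be positive", call. = FALSE)
  }
  structure(list(amplitude = as.numeric(amplitude),
                 start = check_point(start, "start"),
                 end = check_point(end, "end"),
                 sigma = check_sigma(sigma)),
            class = c("mt_line", "mt_feature"))
}

#' Gaussian curve feature
#'
#' A curved microtubule described by an intrinsic-geometry model: a start
#' point, an initial unit tangent (stored as azimuth/polar angles, 2 free
#' parameters), and a Fourier model of the planar curvature
#' `K(t) = k0 + sum_i p_i cos(i w t) + q_i sin(i w t)` over normalized arc
#' length t in `[0, 1]`. The centerline is reconstructed by stepping the
#' tangent (see [reconstruct_curve]) and the intensity is the Gaussian line
#' integral along it, evaluated by Gauss quadrature. With `n_fourier = 2`
#' there are 15 free shape/intensity parameters: amplitude (1), origin (3),
#' tangent angles (2), curvature coefficients k0, w, p1..p2, q1..q2 (6) and
#' widths (3). The arc length `L` is carried as a separate shape parameter
#' that the optimizer may additionally refine (see `fit_length` in
#' [fit_local]).
#'
#' @param amplitude intensity scale, > 0.
#' @param origin length-3 start position (micron).
#' @param tangent either a length-3 direction vector (normalized internally)
#'   or a length-2 vector of (azimuth, polar) angles in radians.
#' @param curvature list or numeric vector with elements `k0`, `w`,
#'   `p` (length N) and `q` (length N); units 1/micron for k0, p, q and a
#'   dimensionless angular frequency for w.
#' @param length arc length L in micron, > 0.
#' @param sigma length-3 Gaussian widths (micron).
#' @return an object of classes `mt_curve`, `mt_feature`.
#' @export
mt_curve <- function(amplitude, origin, tangent, curvature, length, sigma) {
  if (!is.finite(amplitude) || amplitude <= 0) {
    stop("invalid parameter: amplitude must be positive", call. = FALSE)
  }
  if (!is.finite(length) || length <= 0) {
    stop("invalid parameter: curve length must be positive", call. = FALSE)
  }
  ang <- if (base::length(tangent) == 3L) vec_to_angles(tangent) else as.numeric(tangent)
  if (base::length(ang) != 2L || any(!is.finite(ang))) {
    stop("invalid parameter: tangent must be a 3-vector or 2 angles", call. = FALSE)
  }
  cc <- as_curvature_coeffs(curvature)
  structure(list(amplitude = as.numeric(amplitude),
                 origin = check_point(origin, "origin"),
                 tangent_angles = ang,
                 curvature = cc,
                 length = as.numeric(length),
                 sigma = check_sigma(sigma)),
            class = c("mt_curve", "mt_feature"))
}

as_curvature_coeffs <- function(x) {
  if (is.list(x)) {
    stopifnot(!is.null(x$k0), !is.null(x$w), !is.null(x$p), !is.null(x$q),
              length(x$p) == length(x$q))
    list(k0 = as.numeric(x$k0), w = as.numeric(x$w),
         p = as.numeric(x$p), q = as.numeric(x$q))
  } else {
    # flat numeric: k0, w, p1..pN, q1..qN
    x <- as.numeric(x)
    N <- (length(x) - 2L) / 2L
    stopifnot(N >= 1L, N == round(N))
    list(k0 = x[1], w = x[2], p = x[3:(2 + N)], q = x[(3 + N):(2 + 2 * N)])
  }
}

#' Convert tangent angles to a unit vector and back
#'
#' Azimuth is measured in the XY plane from +x; polar is the angle from +z.
#' @param angles length-2 (azimuth, polar) in radians.
#' @return `angles_to_vec`: unit 3-vector; `vec_to_angles`: length-2 angles.
#' @export
angles_to_vec <- function(angles) {
  phi <- angles[1]; th <- angles[2]
  c(cos(phi) * sin(th), sin(phi) * sin(th), cos(th))
}

#' @rdname angles_to_vec
#' @param v a non-zero 3-vector.
#' @export
vec_to_angles <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("degenerate tangent: zero vector", call. = FALSE)
  v <- v / n
  c(atan2(v[2], v[1]) %% (2 * pi), acos(max(-1, min(1, v[3]))))
}

#' @export
print.mt_feature <- function(x, ...) {
  cat(sprintf("<%s A=%.3g>\n", class(x)[1], x$amplitude))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Composite model
# ---------------------------------------------------------------------------

#' Composite image model
#'
#' A uniform background level plus an ordered collection of features. The
#' render of a composite model is exactly the background plus the sum of the
#' per-feature renders. The topology tag records the biological organization
#' (monopolar/bipolar spindle, astral, or free-form) and the attachment map
#' records which line/curve start points were seeded at which spot center.
#'
#' @param background uniform background intensity B0, >= 0.
#' @param features list of [mt_spot], [mt_line] and/or [mt_curve] objects.
#' @param topology one of "monopolar", "bipolar", "astral", "free".
#' @param attachments optional integer vector (same length as `features`):
#'   for each feature, the index of the spot its start is anchored to, or NA.
#' @return an object of class `composite_model`.
#' @export
composite_model <- function(background = 0, features = list(),
                            topology = c("free", "monopolar", "bipolar", "astral"),
                            attachments = NULL) {
  topology <- match.arg(topology)
  if (!is.finite(background) || background < 0) {
    stop("background must be a non-negative number")
  }
  stopifnot(all(vapply(features, inherits, TRUE, "mt_feature")))
  if (is.null(attachments)) attachments <- rep(NA_integer_, length(features))
  structure(list(background = as.numeric(background), features = features,
                 topology = topology, attachments = as.integer(attachments)),
            class = "composite_model")
}

#' @export
print.composite_model <- function(x, ...) {
  tt <- table(vapply(x$features, function(f) class(f)[1], ""))
  cat(sprintf("<composite_model [%s] B0=%.3g: %s>\n", x$topology, x$background,
              if (length(tt)) paste(tt, names(tt), collapse = ", ") else "empty"))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Rendering
# ---------------------------------------------------------------------------

#' Render a feature onto a voxel grid
#'
#' Evaluates the feature's continuous Gaussian intensity model at the voxel
#' centers of the target geometry. `render_feature` dispatches on feature
#' class; the type-specific entry points are [render_spot], [render_line]
#' and [render_curve].
#'
#' @param feature an `mt_feature`.
#' @param geometry an [image_stack] or `list(dim=, voxel_size=)`.
#' @param ... passed to the type-specific renderer.
#' @return numeric 3D array with the geometry's dimensions.
#' @export
render_feature <- function(feature, geometry, ...) UseMethod("render_feature")

#' @export
render_feature.mt_spot <- function(feature, geometry, ...) {
  render_spot(feature, geometry)
}

#' @export
render_feature.mt_line <- function(feature, geometry, ...) {
  render_line(feature, geometry, ...)
}

#' @export
render_feature.mt_curve <- function(feature, geometry, ...) {
  render_curve(feature, geometry, ...)
}

#' @rdname render_feature
#' @param spot an [mt_spot].
#' @export
render_spot <- function(spot, geometry) {
  g <- as_geometry(geometry)
  v <- cpp_spot_render(g$dim, g$voxel_size, spot$amplitude, spot$center,
                       spot$sigma, FALSE)$values
  array(v, dim = g$dim)
}

#' @rdname render_feature
#' @param line an [mt_line].
#' @param method `"erf"` evaluates the closed form of the line integral in
#'   terms of error functions (exact and fast; the default); `"quadrature"`
#'   uses composite Gauss-Legendre integration along the centerline.
#' @param quad_order Gauss-Legendre nodes per panel for the quadrature paths.
#' @export
render_line <- function(line, geometry, method = c("erf", "quadrature"),
                        quad_order = 32) {
  method <- match.arg(method)
  g <- as_geometry(geometry)
  bad <- !all(is.finite(c(line$amplitude, line$start, line$end, line$sigma)))
  if (bad) stop("invalid parameter: non-finite line parameters", call. = FALSE)
  if (method == "erf") {
    v <- cpp_line_render_erf(g$dim, g$voxel_size, line$amplitude, line$start,
                             line$end, line$sigma, FALSE)$values
    array(v, dim = g$dim)
  } else {
    L <- sqrt(sum((line$end - line$start)^2))
    qn <- centerline_quadrature(function(t) {
      cbind(line$start[1] + (line$end[1] - line$start[1]) * t,
            line$start[2] + (line$end[2] - line$start[2]) * t,
            line$start[3] + (line$end[3] - line$start[3]) * t)
    }, L, line$sigma, quad_order)
    v <- cpp_gauss_sum_render(g$dim, g$voxel_size, line$amplitude, qn$points,
                              qn$weights, line$sigma)
    array(v, dim = g$dim)
  }
}

# Composite Gauss-Legendre nodes/weights over t in [0,1] for a centerline of
# arc length L: panel count scales with L relative to the transverse width so
# that the Gaussian integrand is smooth within each panel.
centerline_quadrature <- function(position_fun, L, sigma, quad_order = 32) {
  panels <- max(1L, ceiling(L / (2 * min(sigma[1:2]))))
  edges <- seq(0, 1, length.out = panels + 1L)
  gl <- pracma::gaussLegendre(quad_order, 0, 1)
  tq <- as.vector(outer(gl$x, diff(edges)) +
                  rep(edges[-length(edges)], each = quad_order))
  wq <- as.vector(outer(gl$w, diff(edges)))
  list(points = position_fun(tq), weights = wq, t = tq)
}

#' @rdname render_feature
#' @param curve an [mt_curve].
#' @param dt reconstruction step (micron of arc length) for the centerline;
#'   defaults to `length/2000`.
#' @export
render_curve <- function(curve, geometry, quad_order = 32, dt = NULL) {
  g <- as_geometry(geometry)
  if (is.null(dt)) dt <- curve$length / 2000
  pts <- reconstruct_curve(curve$origin, angles_to_vec(curve$tangent_angles),
                           curve$curvature, curve$length, dt)
  qn <- centerline_quadrature(function(t) interp_path(pts, t), curve$length,
                              curve$sigma, quad_order)
  v <- cpp_gauss_sum_render(g$dim, g$voxel_size, curve$amplitude, qn$points,
                            qn$weights, curve$sigma)
  array(v, dim = g$dim)
}

# Linear interpolation of an ordered path (rows = points, equally spaced in
# normalized arc length) at normalized positions t in [0,1].
interp_path <- function(points, t) {
  n <- nrow(points)
  s <- t * (n - 1) + 1
  i0 <- pmin(pmax(floor(s), 1), n - 1)
  f <- s - i0
  points[i0, , drop = FALSE] * (1 - f) + points[i0 + 1, , drop = FALSE] * f
}

#' Render a composite model
#'
#' The uniform background plus the sum of all per-feature renders. Feature
#' order does not affect the result.
#'
#' @param model a [composite_model].
#' @param geometry an [image_stack] or `list(dim=, voxel_size=)`.
#' @param ... passed on to the per-feature renderers.
#' @return numeric 3D array.
#' @export
render_model <- function(model, geometry, ...) {
  g <- as_geometry(geometry)
  out <- array(model$background, dim = g$dim)
  for (f in model$features) out <- out + render_feature(f, g, ...)
  out
}

# ---------------------------------------------------------------------------
# Curve geometry engine
# ---------------------------------------------------------------------------

#' Signed local curvature of a planar parametric curve
#'
#' Computes `K(t) = (x'y'' - y'x'') / (x'^2 + y'^2)^(3/2)` for a curve given
#' by polynomial coefficients in t (ascending powers). The curvature is the
#' in-plane (XY) curvature; the Z component of the centerline is assumed
#' linear in t and does not contribute.
#'
#' @param xcoef,ycoef numeric vectors of polynomial coefficients (ascending:
#'   `a0, a1, ..., an`).
#' @param t numeric vector of parameter values.
#' @return numeric vector of signed curvature (1/micron).
#' @export
local_curvature <- function(xcoef, ycoef, t) {
  d1 <- function(co) if (length(co) > 1) co[-1] * seq_len(length(co) - 1) else 0
  xp <- d1(xcoef); yp <- d1(ycoef)
  xpp <- d1(xp); ypp <- d1(yp)
  ev <- function(co, t) drop(outer(t, seq_along(co) - 1, `^`) %*% co)
  x1 <- ev(xp, t); y1 <- ev(yp, t)
  x2 <- ev(xpp, t); y2 <- ev(ypp, t)
  sp <- x1^2 + y1^2
  if (any(sp <= .Machine$double.eps)) {
    stop("degenerate tangent: vanishing XY speed", call. = FALSE)
  }
  (x1 * y2 - y1 * x2) / sp^1.5
}

#' Curvature of a sampled centerline by finite differences
#'
#' Central-difference estimate of the signed XY curvature at the interior
#' points of an ordered, (approximately) equally spaced path.
#'
#' @param xy two-column matrix of XY positions along the path.
#' @return numeric vector, length `nrow(xy) - 2`.
#' @export
sampled_curvature <- function(xy) {
  n <- nrow(xy)
  stopifnot(n >= 3)
  i <- 2:(n - 1)
  x1 <- (xy[i + 1, 1] - xy[i - 1, 1]) / 2
  y1 <- (xy[i + 1, 2] - xy[i - 1, 2]) / 2
  x2 <- xy[i + 1, 1] - 2 * xy[i, 1] + xy[i - 1, 1]
  y2 <- xy[i + 1, 2] - 2 * xy[i, 2] + xy[i - 1, 2]
  sp <- x1^2 + y1^2
  (x1 * y2 - y1 * x2) / sp^1.5
}

#' Fit a Fourier curvature model
#'
#' Least-squares fit of `K(t) = k0 + sum_{i=1..N} p_i cos(i w t) +
#' q_i sin(i w t)` to curvature samples. For fixed angular frequency `w` the
#' model is linear; `w` itself is profiled out by a grid search followed by
#' golden-section refinement of the residual sum of squares.
#'
#' @param t numeric vector of sample parameters (normalized arc length).
#' @param K numeric vector of curvature samples (1/micron).
#' @param N number of Fourier terms (>= 1); N = 2 is the working default for
#'   yeast astral microtubules, selected by comparing fit residuals across N.
#' @param w_range search range for the angular frequency.
#' @return list with `k0`, `w`, `p`, `q`, and `rss` (residual sum of squares).
#' @export
fit_curvature_fourier <- function(t, K, N = 2, w_range = c(0.25, 20)) {
  stopifnot(N >= 1, length(t) == length(K))
  if (length(t) < 2 * N + 2) {
    stop("under-determined: need at least 2N+2 curvature samples", call. = FALSE)
  }
  design <- function(w) {
    X <- matrix(1, length(t), 1 + 2 * N)
    for (i in seq_len(N)) {
      X[, 1 + i] <- cos(i * w * t)
      X[, 1 + N + i] <- sin(i * w * t)
    }
    X
  }
  rss_w <- function(w) {
    fit <- lm.fit(design(w), K)
    sum(fit$residuals^2)
  }
  grid <- seq(w_range[1], w_range[2], length.out = 160)
  vals <- vapply(grid, rss_w, 0)
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(rss_w, c(lo, hi), tol = 1e-12)
  w <- opt$minimum
  fit <- lm.fit(design(w), K)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  list(k0 = unname(co[1]), w = w, p = unname(co[2:(1 + N)]),
       q = unname(co[(2 + N):(1 + 2 * N)]), rss = sum(fit$residuals^2))
}

#' Reconstruct a curve centerline from intrinsic geometry
#'
#' Starting at `origin` with unit tangent `tangent`, steps the tangent with
#' the Fourier curvature model: `T(t+dt) = T(t) + N(t) K(t/L) dt` where
#' `N = (-Ty, Tx, 0)` is the in-plane normal (a pi/2 rotation of the tangent
#' in XY), then `x(t+dt) = x(t) + dt T(t)`. The tangent is renormalized to
#' unit length after every step so that the parameter remains arc length
#' (the raw update inflates |T| at second order in dt). Curvature acts only
#' in the XY plane, so the Z component of the centerline stays linear.
#'
#' @param origin length-3 start point (micron).
#' @param tangent initial tangent; length-3 vector (normalized internally) or
#'   length-2 (azimuth, polar) angles.
#' @param curvature Fourier curvature coefficients (list with k0, w, p, q),
#'   evaluated at normalized arc length t/L in `[0, 1]`.
#' @param length total arc length L (micron), > 0.
#' @param dt step size (micron of arc length), 0 < dt < L.
#' @return matrix of 3D points (rows ordered along the curve); the first row
#'   equals `origin` and the cumulative arc length equals L within one step.
#' @export
reconstruct_curve <- function(origin, tangent, curvature, length, dt) {
  stopifnot(length > 0)
  if (!(dt > 0) || dt >= length) {
    stop("step too large: require 0 < dt < length", call. = FALSE)
  }
  Tv <- if (base::length(tangent) == 2L) angles_to_vec(tangent) else as.numeric(tangent)
  nrm <- sqrt(sum(Tv^2))
  if (nrm == 0) stop("degenerate tangent: zero vector", call. = FALSE)
  Tv <- Tv / nrm
  cc <- as_curvature_coeffs(curvature)
  n_steps <- ceiling(length / dt)
  pts <- cpp_reconstruct_curve(as.numeric(origin), Tv, cc$k0, cc$w,
                               cc$p, cc$q, as.numeric(length), n_steps)
  pts
}

#' Arc length of an ordered polyline
#' @param points matrix of 3D points (rows ordered along the path).
#' @return total chord-summed length (micron).
#' @export
path_length <- function(points) {
  if (nrow(points) < 2) return(0)
  sum(sqrt(rowSums(diff(points)^2)))
}

# ---------------------------------------------------------------------------
# Parameter packing
# ---------------------------------------------------------------------------

#' Free-parameter vector of a feature
#'
#' Packs the free parameters into a named numeric vector: 7 for a spot
#' (A, center, widths), 10 for a line (A, start, end, widths), and, with
#' N = 2 Fourier terms, 15 for a curve (A, origin, 2 tangent angles, k0, w,
#' p1..p2, q1..q2, widths). The curve's arc length is a separate shape
#' parameter (see [mt_curve]) and is not part of the packed vector.
#'
#' @param feature an `mt_feature`.
#' @return named numeric vector.
#' @export
feature_params <- function(feature) UseMethod("feature_params")

#' @export
feature_params.mt_spot <- function(feature) {
  c(A = feature$amplitude,
    x0 = feature$center[1], y0 = feature$center[2], z0 = feature$center[3],
    sx = feature$sigma[1], sy = feature$sigma[2], sz = feature$sigma[3])
}

#' @export
feature_params.mt_line <- function(feature) {
  c(A = feature$amplitude,
    x0 = feature$start[1], y0 = feature$start[2], z0 = feature$start[3],
    x1 = feature$end[1], y1 = feature$end[2], z1 = feature$end[3],
    sx = feature$sigma[1], sy = feature$sigma[2], sz = feature$sigma[3])
}

#' @export
feature_params.mt_curve <- function(feature) {
  cc <- feature$curvature
  N <- length(cc$p)
  v <- c(A = feature$amplitude,
         x0 = feature$origin[1], y0 = feature$origin[2], z0 = feature$origin[3],
         azimuth = feature$tangent_angles[1], polar = feature$tangent_angles[2],
         k0 = cc$k0, w = cc$w,
         setNames(cc$p, paste0("p", seq_len(N))),
         setNames(cc$q, paste0("q", seq_len(N))),
         sx = feature$sigma[1], sy = feature$sigma[2], sz = feature$sigma[3])
  v
}

#' Replace the free parameters of a feature
#'
#' Inverse of [feature_params]: rebuilds the feature from a packed parameter
#' vector (same ordering).
#'
#' @param feature an `mt_feature` providing the type and fixed attributes.
#' @param par numeric vector as produced by [feature_params].
#' @return the updated feature.
#' @export
set_feature_params <- function(feature, par) UseMethod("set_feature_params")

#' @export
set_feature_params.mt_spot <- function(feature, par) {
  feature$amplitude <- par[1]
  feature$center <- par[2:4]
  feature$sigma <- par[5:7]
  feature
}

#' @export
set_feature_params.mt_line <- function(feature, par) {
  feature$amplitude <- par[1]
  feature$start <- par[2:4]
  feature$end <- par[5:7]
  feature$sigma <- par[8:10]
  feature
}

#' @export
set_feature_params.mt_curve <- function(feature, par) {
  N <- length(feature$curvature$p)
  feature$amplitude <- par[1]
  feature$origin <- par[2:4]
  feature$tangent_angles <- par[5:6]
  feature$curvature <- list(k0 = par[7], w = par[8],
                            p = par[9:(8 + N)], q = par[(9 + N):(8 + 2 * N)])
  feature$sigma <- par[(9 + 2 * N):(11 + 2 * N)]
  feature
}

#' Anchor point of a feature for matching and tracking
#'
#' Spots are anchored at their center; lines and curves at their free-end tip
#' (the `end` of a line, the distal end of a reconstructed curve).
#'
#' @param feature an `mt_feature`.
#' @return length-3 position (micron).
#' @export
feature_tip <- function(feature) UseMethod("feature_tip")

#' @export
feature_tip.mt_spot <- function(feature) feature$center

#' @export
feature_tip.mt_line <- function(feature) feature$end

#' @export
feature_tip.mt_curve <- function(feature) {
  pts <- reconstruct_curve(feature$origin, angles_to_vec(feature$tangent_angles),
                           feature$curvature, feature$length,
                           feature$length / 1000)
  pts[nrow(pts), ]
}

#' Length of a feature (micron)
#'
#' Spots have length 0; lines the Euclidean start-end distance; curves their
#' arc length.
#' @param feature an `mt_feature`.
#' @return scalar length in micron.
#' @export
feature_length <- function(feature) UseMethod("feature_length")

#' @export
feature_length.mt_spot <- function(feature) 0

#' @export
feature_length.mt_line <- function(feature) {
  sqrt(sum((feature$end - feature$start)^2))
}

#' @export
feature_length.mt_curve <- function(feature) feature$length
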