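# Detection: initial feature guesses from an image stack. Pole (SPB)
# finding by Otsu thresholding plus an extended-maxima H-transform on the
# maximum-intensity projection, angular scanning for straight microtubules,
# principal-axis endpoint finding for bipolar spindles, and ridge-following
# curve tracing for bent astral microtubules.

#' Detection configuration
#'
#' @param gaussian_sigma smoothing widths in voxels (x, y, z) for the 3D
#'   Gaussian pre-filter.
#' @param hmax_height H-maxima suppression height in intensity units, or
#'   `NULL` to use 3x the robust noise scale (1.4826 x MAD) of the image.
#' @param dphi angular bin width (radians) of the polar transform.
#' @param dr radial step (voxels) of the polar transform.
#' @param peak_prominence minimum peak prominence as a fraction of the
#'   maximum of the angular intensity function.
#' @param background background estimator; only `"median"` is provided (the
#'   median intensity of the unfiltered image).
#' @param min_length,max_length length cutoffs (micron) for line/curve
#'   guesses; `max_length = NULL` means the image diagonal.
#' @param stop_factor the radial/tracing walk stops where intensity drops
#'   below `stop_factor` times the background ("comparable to background").
#' @param r_min inner radius (voxels) excluded around a pole when scanning.
#' @param steerable_scale ridge-filter smoothing scale in voxels (about the
#'   expected filament width).
#' @param trace_step step length (voxels) of the curve tracer.
#' @param psf_sigma initial Gaussian widths (micron) assigned to line/curve
#'   guesses (the microscope point-spread function scale).
#' @param spot_sigma initial widths (micron) for pole (spot) guesses.
#' @param max_guesses cap on the number of line guesses per pole (strongest
#'   angular peaks first).
#' @return a list of class `detection_config`.
#' @export
detection_config <- function(gaussian_sigma = c(1, 1, 0.5), hmax_height = NULL,
                             dphi = 2 * pi / 180, dr = 0.5,
                             peak_prominence = 0.25, background = "median",
                             min_length = 0.3, max_length = NULL,
                             stop_factor = 1.2, r_min = 2,
                             steerable_scale = 1.5, trace_step = 1,
                             psf_sigma = c(0.15, 0.15, 0.35),
                             spot_sigma = c(0.2, 0.2, 0.45),
                             max_guesses = 8) {
  stopifnot(all(gaussian_sigma > 0), dphi > 0, dr > 0, peak_prominence > 0,
            min_length > 0, stop_factor > 0, r_min >= 0, trace_step > 0)
  if (!is.null(max_length)) stopifnot(min_length < max_length)
  structure(list(gaussian_sigma = gaussian_sigma, hmax_height = hmax_height,
                 dphi = dphi, dr = dr, peak_prominence = peak_prominence,
                 background = background, min_length = min_length,
                 max_length = max_length, stop_factor = stop_factor,
                 r_min = r_min, steerable_scale = steerable_scale,
                 trace_step = trace_step, psf_sigma = psf_sigma,
                 spot_sigma = spot_sigma, max_guesses = max_guesses),
            class = "detection_config")
}

# --- small image utilities -------------------------------------------------

# 1D Gaussian convolution along dimension `d` of a 3D array, replicate
# padding at the borders, kernel normalized to unit sum.
gauss_filter_dim <- function(a, sigma, d) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  dd <- dim(a)
  perm <- c(d, setdiff(1:3, d))
  m <- matrix(aperm(a, perm), nrow = dd[d])
  n <- nrow(m)
  padded <- rbind(m[rep(1, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * padded[j:(j + n - 1), , drop = FALSE]
  }
  aperm(array(out, dd[perm]), order(perm))
}

#' Preprocess a stack: 3D Gaussian filter and maximum-intensity projection
#'
#' Smooths the stack with a separable 3D Gaussian (to enhance tubulin
#' intensity against voxel noise) and computes the maximum-intensity
#' projection of the filtered stack along z. The input is not modified.
#'
#' @param stack an [image_stack].
#' @param config a [detection_config].
#' @return list with `filtered` (an [image_stack]), `mip` (matrix indexed
#'   `[x, y]`), and `background` (median of the unfiltered image).
#' @export
preprocess <- function(stack, config = detection_config()) {
  a <- stack$intensities
  for (d in 1:3) a <- gauss_filter_dim(a, config$gaussian_sigma[d], d)
  filtered <- image_stack(a, stack$voxel_size)
  list(filtered = filtered, mip = max_intensity_projection(filtered),
       background = median(stack$intensities))
}

# Bilinear interpolation on a matrix at continuous (1-based) index
# coordinates; out-of-range coordinates are clamped to the border.
bilinear <- function(m, xi, yi) {
  nx <- nrow(m); ny <- ncol(m)
  xi <- pmin(pmax(xi, 1), nx); yi <- pmin(pmax(yi, 1), ny)
  x0 <- pmin(floor(xi), nx - 1L); y0 <- pmin(floor(yi), ny - 1L)
  fx <- xi - x0; fy <- yi - y0
  m[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    m[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    m[cbind(x0, y0 + 1)] * (1 - fx) * fy +
    m[cbind(x0 + 1, y0 + 1)] * fx * fy
}

# Morphological grayscale reconstruction of `seed` under `mask`
# (8-connected geodesic dilation to stability; raster sweeps in C++).
grayscale_reconstruct <- function(seed, mask) {
  cpp_gray_reconstruct(as.matrix(seed), as.matrix(mask))
}

# Extended-maxima H-transform: TRUE where the image carries a regional
# maximum after suppressing maxima shallower than h.
extended_maxima <- function(m, h) {
  rec <- grayscale_reconstruct(m - h, m)
  # regional maxima of the reconstruction: reconstruction of (rec - eps)
  # fails to reach rec exactly on maxima plateaus
  eps <- max(h * 1e-3, .Machine$double.eps * 64)
  rec2 <- grayscale_reconstruct(rec - eps, rec)
  (rec - rec2) > eps / 2
}

otsu_mask <- function(m) {
  rng <- range(m)
  if (diff(rng) <= 0) stop("no-pole: image has zero dynamic range", call. = FALSE)
  norm <- (m - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  norm > th
}

# Intensity-weighted z centroid (micron) of the stack column(s) under a
# window around continuous index (xi, yi).
z_centroid <- function(stack, xi, yi, background, window = 1L) {
  a <- stack$intensities
  d <- dim(a)
  i0 <- max(1L, round(xi) - window); i1 <- min(d[1], round(xi) + window)
  j0 <- max(1L, round(yi) - window); j1 <- min(d[2], round(yi) + window)
  col <- apply(a[i0:i1, j0:j1, , drop = FALSE], 3, sum)
  w <- pmax(col - length(i0:i1) * length(j0:j1) * background, 0)
  zi <- seq_len(d[3])
  if (sum(w) <= 0) {
    zc <- (d[3] + 1) / 2
  } else {
    zc <- sum(w * zi) / sum(w)
  }
  (zc - 0.5) * stack$voxel_size[3]
}

#' Find the spindle pole body in a stack
#'
#' Otsu thresholding of the MIP followed by an extended-maxima H-transform;
#' the brightest extended maximum inside the foreground gives the pole. The
#' XY position is refined to sub-voxel accuracy by an intensity-weighted
#' centroid over a 3x3 neighborhood; z comes from the intensity-weighted
#' centroid of the z column under the pole. Ties between equal maxima break
#' deterministically toward the lowest linear index.
#'
#' @param mip a 2D MIP matrix (`[x, y]`), typically from [preprocess].
#' @param stack the corresponding [image_stack] (for the z estimate and the
#'   background level).
#' @param config a [detection_config].
#' @return list with `position` (x, y, z in micron), `index` (voxel indices)
#'   and `value` (MIP intensity at the pole).
#' @export
find_pole <- function(mip, stack, config = detection_config()) {
  bg <- median(stack$intensities)
  h <- config$hmax_height
  if (is.null(h)) {
    h <- 3 * 1.4826 * median(abs(stack$intensities - bg))
    if (h <= 0) h <- 1e-3 * max(abs(range(mip - bg)), 1e-12)
  }
  fg <- otsu_mask(mip)
  em <- extended_maxima(mip, h) & fg
  if (!any(em)) em <- fg
  if (!any(em)) stop("no-pole: empty foreground after thresholding", call. = FALSE)
  vals <- ifelse(em, mip, -Inf)
  best <- which.max(vals)  # which.max takes the lowest index on ties
  ij <- arrayInd(best, dim(mip))
  i <- ij[1]; j <- ij[2]
  nx <- nrow(mip); ny <- ncol(mip)
  iw <- max(1, i - 1):min(nx, i + 1)
  jw <- max(1, j - 1):min(ny, j + 1)
  w <- pmax(mip[iw, jw, drop = FALSE] - bg, 0)
  if (sum(w) <= 0) w[] <- 1
  xi <- sum(outer(iw, rep(1, length(jw))) * w) / sum(w)
  yi <- sum(outer(rep(1, length(iw)), jw) * w) / sum(w)
  vx <- stack$voxel_size
  z <- z_centroid(stack, xi, yi, bg)
  list(position = c((xi - 0.5) * vx[1], (yi - 0.5) * vx[2], z),
       index = c(i, j), value = mip[i, j])
}

#' Angular intensity function around a pole
#'
#' Transforms the MIP to a polar representation I(r, phi) about the pole and
#' radially integrates the background-subtracted, bilinearly interpolated
#' intensity out to the image border, giving a periodic angular intensity
#' function I(phi) whose peaks mark candidate microtubule directions.
#'
#' @param mip 2D MIP matrix (`[x, y]`).
#' @param pole pole position, micron (x, y) (extra elements ignored).
#' @param config a [detection_config].
#' @param voxel_size (dx, dy) micron per voxel of the MIP.
#' @param r_max outer integration radius in voxels (`NULL`: to the image
#'   border). Shorter windows act as matched filters for short
#'   microtubules, whose signal is otherwise diluted by pure-noise samples
#'   at large radii.
#' @return list with `phi` (bin centers, radians in `[0, 2pi)`) and
#'   `intensity` (radially integrated, background-subtracted).
#' @export
angular_intensity <- function(mip, pole, config = detection_config(),
                              voxel_size = c(0.1, 0.1), r_max = NULL) {
  nx <- nrow(mip); ny <- ncol(mip)
  xi <- pole[1] / voxel_size[1] + 0.5
  yi <- pole[2] / voxel_size[2] + 0.5
  if (xi < 1 || xi > nx || yi < 1 || yi > ny) {
    stop("invalid-pole: pole lies outside the image", call. = FALSE)
  }
  bg <- median(mip)
  nphi <- max(8L, round(2 * pi / config$dphi))
  phi <- (seq_len(nphi) - 1) * 2 * pi / nphi
  out <- numeric(nphi)
  for (b in seq_len(nphi)) {
    co <- cos(phi[b]); si <- sin(phi[b])
    rmax <- ray_border_distance(xi, yi, co, si, nx, ny)
    if (!is.null(r_max)) rmax <- min(rmax, r_max)
    if (rmax <= config$r_min) next
    rs <- seq(config$r_min, rmax, by = config$dr)
    vals <- bilinear(mip, xi + rs * co, yi + rs * si) - bg
    out[b] <- sum(vals) * config$dr
  }
  list(phi = phi, intensity = out)
}

# Distance (in voxel units) from (xi, yi) to the image border along (co, si).
ray_border_distance <- function(xi, yi, co, si, nx, ny) {
  ts <- c(if (co > 0) (nx - xi) / co else if (co < 0) (1 - xi) / co else Inf,
          if (si > 0) (ny - yi) / si else if (si < 0) (1 - yi) / si else Inf)
  max(0, min(ts))
}

# Peaks of a periodic signal with a prominence criterion. Prominence of a
# peak: height above the higher of the two deepest valleys separating it
# from higher terrain (circular). Ties break toward the lowest angle index.
circular_peaks <- function(y, min_prominence) {
  n <- length(y)
  if (n < 3) return(integer(0))
  left <- y[c(n, 1:(n - 1))]; right <- y[c(2:n, 1)]
  cand <- which(y > left & y >= right)
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    lo_l <- y[i]; j <- i
    repeat {
      j <- if (j == 1) n else j - 1
      if (j == i) break
      lo_l <- min(lo_l, y[j])
      if (y[j] > y[i]) break
    }
    lo_r <- y[i]; j <- i
    repeat {
      j <- if (j == n) 1 else j + 1
      if (j == i) break
      lo_r <- min(lo_r, y[j])
      if (y[j] > y[i]) break
    }
    prom <- y[i] - max(lo_l, lo_r)
    if (all(y <= y[i])) prom <- y[i] - min(y)  # global maximum
    keep[k] <- prom >= min_prominence
  }
  cand[keep]
}

#' Detect straight microtubules emanating from a pole
#'
#' One line guess per prominent peak of the angular intensity function. The
#' line length is found by fixing the peak angle and increasing the radius
#' until the (smoothed, interpolated) polar intensity becomes comparable to
#' the background, i.e. drops below `stop_factor x background`. Guesses
#' shorter than the minimum or longer than the maximum length cutoff are
#' discarded. Endpoint z positions are initialized from intensity-weighted
#' z centroids of the stack columns under the endpoints.
#'
#' @param mip smoothed MIP matrix (from [preprocess]).
#' @param stack the (unfiltered) [image_stack].
#' @param pole pole position (x, y, z) in micron, from [find_pole].
#' @param config a [detection_config].
#' @param background background level for the stopping criterion; `NULL`
#'   (default) uses the median of `stack`. Pass the original image's
#'   background when scanning a residual image.
#' @return list of [mt_line] guesses (possibly empty).
#' @export
detect_lines_from_pole <- function(mip, stack, pole, config = detection_config(),
                                   background = NULL) {
  vx <- stack$voxel_size
  bg <- if (is.null(background)) median(stack$intensities) else background
  # multi-scale angular scan: radial windows act as matched filters — short
  # microtubules vanish in a border-length integral (most samples are pure
  # noise) but stand out in a short window. Peaks from all scales are
  # pooled and deduplicated by angle, keeping the most significant.
  scales <- c(10, 20, NA)
  found_phi <- numeric(0); found_z <- numeric(0)
  for (sc in scales) {
    ai <- angular_intensity(mip, pole, config, vx[1:2],
                            r_max = if (is.na(sc)) NULL else sc)
    if (max(ai$intensity, -Inf) <= 0) next
    pk <- circular_peaks(ai$intensity,
                         config$peak_prominence * max(ai$intensity, 0))
    if (length(pk) == 0) next
    # significance floor: a peak must rise above the angular noise level,
    # estimated robustly from the below-median bins (microtubule signal
    # only adds intensity, so the lower half of I(phi) is noise)
    med_i <- median(ai$intensity)
    below <- med_i - ai$intensity[ai$intensity < med_i]
    noise_i <- if (length(below) > 0) 1.4826 * median(below) else 0
    pk <- pk[ai$intensity[pk] >= med_i + 1.5 * noise_i]
    nphi <- length(ai$phi)
    dphi_bin <- 2 * pi / nphi
    for (b in pk) {
      # sub-bin refinement: parabola through the peak and its neighbors
      y0 <- ai$intensity[if (b == 1) nphi else b - 1]
      y1 <- ai$intensity[b]
      y2 <- ai$intensity[if (b == nphi) 1 else b + 1]
      denom <- y0 - 2 * y1 + y2
      off <- if (abs(denom) > 1e-12) 0.5 * (y0 - y2) / denom else 0
      found_phi <- c(found_phi, ai$phi[b] + max(-0.5, min(0.5, off)) * dphi_bin)
      found_z <- c(found_z, (y1 - med_i) / max(noise_i, 1e-9))
    }
  }
  # deduplicate pooled peaks within 4 degrees, strongest first
  phis <- numeric(0)
  for (k in order(-found_z)) {
    dd <- abs(((found_phi[k] - phis + pi) %% (2 * pi)) - pi)
    if (length(phis) == 0 || min(dd) > 4 * pi / 180) {
      phis <- c(phis, found_phi[k])
    }
  }
  phis <- utils::head(phis, config$max_guesses)
  max_len <- config$max_length
  if (is.null(max_len)) {
    max_len <- sqrt(sum((dim(stack$intensities)[1:2] * vx[1:2])^2))
  }
  xi <- pole[1] / vx[1] + 0.5; yi <- pole[2] / vx[2] + 0.5
  guesses <- list()
  for (phi in phis) {
    co <- cos(phi); si <- sin(phi)
    rmax <- ray_border_distance(xi, yi, co, si, nrow(mip), ncol(mip))
    if (rmax <= config$r_min) next
    # start beyond the pole spot's influence radius: close to the pole the
    # profile is dominated by (or, on residual images, hollowed out by) the
    # spot rather than the microtubule
    r_start <- max(config$r_min, 2 * config$spot_sigma[1] / vx[1])
    rs <- seq(r_start, rmax, by = config$dr)
    if (length(rs) < 4) next
    prof <- bilinear(mip, xi + rs * co, yi + rs * si)
    # stop where the profile stays at background level over ~1 PSF width
    # (3 consecutive samples), so single noise dips do not truncate a line
    low <- prof < config$stop_factor * bg
    run3 <- which(low & c(low[-1], TRUE) & c(low[-(1:2)], TRUE, TRUE))
    r_end <- if (length(run3) == 0) rmax else rs[run3[1]]
    # require genuine signal: a run of 3 consecutive above-threshold samples
    # before the stop (the pole spot's own skirt only yields 1-2)
    hi3 <- (!low) & c(!low[-1], FALSE) & c(!low[-(1:2)], FALSE, FALSE)
    if (length(run3) > 0 && !any(hi3[seq_len(run3[1])])) next  # no signal
    L <- r_end * vx[1]
    if (L < config$min_length || L > max_len) next
    ex <- pole[1] + L * co; ey <- pole[2] + L * si
    ez <- z_centroid(stack, ex / vx[1] + 0.5, ey / vx[2] + 0.5, bg)
    mid_r <- r_end / 2
    amp <- max(bilinear(mip, xi + mid_r * co, yi + mid_r * si) - bg,
               0.05 * max(bg, 1e-6))
    guesses[[length(guesses) + 1]] <-
      mt_line(amp, start = pole, end = c(ex, ey, ez), sigma = config$psf_sigma)
  }
  guesses
}

#' Detect a bipolar spindle
#'
#' Otsu thresholding of the MIP, connected-component analysis of the
#' foreground, and a principal-axis orientation of the largest component.
#' The two spindle-pole bodies are the maximally distant high-intensity
#' points along that axis; the spindle is the line connecting them. Polar
#' microtubules emanating from each pole are then found with
#' [detect_lines_from_pole], excluding directions along the spindle axis.
#'
#' @inheritParams detect_lines_from_pole
#' @param min_spindle_length minimum pole separation (micron) for a bipolar
#'   call; below this a `no-spindle` error is raised.
#' @return list with `spots` (two [mt_spot] guesses), `spindle` (an
#'   [mt_line]), and `polar_lines` (possibly empty list of [mt_line]).
#' @export
detect_bipolar <- function(mip, stack, config = detection_config(),
                           min_spindle_length = 0.5) {
  vx <- stack$voxel_size
  bg <- median(stack$intensities)
  fg <- otsu_mask(mip)
  if (!any(fg)) stop("no-spindle: empty foreground", call. = FALSE)
  labels <- EBImage::bwlabel(EBImage::Image(fg * 1))
  labels <- array(labels, dim = dim(mip))
  sizes <- tabulate(labels[labels > 0])
  comp <- labels == which.max(sizes)
  # a dim spindle bundle can split the foreground into two pole blobs; if
  # the largest component is too small to span a spindle, use the two
  # largest components together
  comp_extent <- function(cp) {
    ij <- which(cp, arr.ind = TRUE)
    if (nrow(ij) < 2) return(0)
    sqrt(sum(((apply(ij, 2, max) - apply(ij, 2, min)) * vx[1:2])^2))
  }
  if (comp_extent(comp) < min_spindle_length && length(sizes) >= 2) {
    top2 <- order(-sizes)[1:2]
    comp <- labels == top2[1] | labels == top2[2]
  }
  idx <- which(comp, arr.ind = TRUE)
  w <- pmax(mip[comp] - bg, 0)
  if (sum(w) <= 0) w <- rep(1, nrow(idx))
  mu <- colSums(idx * w) / sum(w)
  cen <- sweep(idx, 2, mu)
  cov <- crossprod(cen * sqrt(w)) / sum(w)
  ev <- eigen(cov, symmetric = TRUE)
  axis <- ev$vectors[, 1]
  # high-intensity pixels of the component: top half of its dynamic range
  hi <- comp & (mip >= bg + 0.5 * (max(mip[comp]) - bg))
  hidx <- which(hi, arr.ind = TRUE)
  if (nrow(hidx) < 2) hidx <- idx
  proj <- as.vector(sweep(hidx, 2, mu) %*% axis)
  # pole position: intensity-weighted centroid of the extreme high-intensity
  # cluster at each end of the axis (single extreme pixels are edge-biased)
  end_centroid <- function(side) {
    p <- if (side > 0) proj else -proj
    sel <- p >= max(p) - 2
    w2 <- pmax(mip[hidx[sel, , drop = FALSE]] - bg, 1e-9)
    colSums(hidx[sel, , drop = FALSE] * w2) / sum(w2)
  }
  p_lo <- end_centroid(-1); p_hi <- end_centroid(1)
  sep_um <- sqrt(sum(((p_hi - p_lo) * vx[1:2])^2))
  if (sep_um < min_spindle_length) {
    stop("no-spindle: endpoints closer than the minimum spindle length",
         call. = FALSE)
  }
  mk_pole <- function(pij) {
    z <- z_centroid(stack, pij[1], pij[2], bg)
    pos <- c((pij[1] - 0.5) * vx[1], (pij[2] - 0.5) * vx[2], z)
    amp <- max(bilinear(mip, pij[1], pij[2]) - bg, 0.05 * max(bg, 1e-6))
    mt_spot(amp, pos, config$spot_sigma)
  }
  s1 <- mk_pole(p_lo); s2 <- mk_pole(p_hi)
  amp_sp <- max(bilinear(mip, (p_lo[1] + p_hi[1]) / 2, (p_lo[2] + p_hi[2]) / 2) - bg,
                0.05 * max(bg, 1e-6))
  spindle <- mt_line(amp_sp, s1$center, s2$center, config$psf_sigma)
  # polar lines from each pole, away from the spindle axis
  polar <- list()
  for (pole_i in 1:2) {
    pole <- list(s1, s2)[[pole_i]]$center
    other <- list(s2, s1)[[pole_i]]$center
    toward <- atan2(other[2] - pole[2], other[1] - pole[1])
    cand <- detect_lines_from_pole(mip, stack, pole, config)
    for (ln in cand) {
      ang <- atan2(ln$end[2] - pole[2], ln$end[1] - pole[1])
      dang <- abs(((ang - toward + pi) %% (2 * pi)) - pi)
      if (dang > pi / 6) polar[[length(polar) + 1]] <- ln
    }
  }
  list(spots = list(s1, s2), spindle = spindle, polar_lines = polar)
}

#' Residual-hotspot line proposals
#'
#' Candidate lines seeded from bright local maxima of a (residual) MIP: each
#' hotspot at radius r from the pole proposes a line from the pole through
#' the hotspot, slightly longer than r. Hotspots must clear a robust noise
#' floor (2x the MAD-based scale above the median of the MIP) and lie
#' beyond the pole's spot radius. Used by the feature-count addition phase,
#' where angular integration dilutes short microtubules and directions
#' partially explained by already-fitted features.
#'
#' @param mip smoothed MIP of the (residual) stack.
#' @param stack the (residual) [image_stack] (for z initialization).
#' @param pole pole position (x, y, z), micron.
#' @param config a [detection_config].
#' @param max_candidates number of hotspots proposed (strongest first).
#' @param background background level of the original image; hotspots must
#'   also exceed `stop_factor x background` (the "comparable to background"
#'   criterion). `NULL` uses the median of `stack`.
#' @return list of [mt_line] guesses.
#' @export
hotspot_lines <- function(mip, stack, pole, config = detection_config(),
                          max_candidates = 3, background = NULL) {
  vx <- stack$voxel_size
  if (is.null(background)) background <- median(stack$intensities)
  med <- median(mip)
  noise <- 1.4826 * median(abs(mip - med))
  floor_v <- max(med + 2 * noise, config$stop_factor * background)
  xi <- pole[1] / vx[1] + 0.5; yi <- pole[2] / vx[2] + 0.5
  r_excl <- max(config$r_min, 2 * config$spot_sigma[1] / vx[1])
  # local maxima of the MIP above the floor, outside the pole region
  nx <- nrow(mip); ny <- ncol(mip)
  isx <- function(s) pmin(pmax(seq_len(nx) + s, 1), nx)
  isy <- function(s) pmin(pmax(seq_len(ny) + s, 1), ny)
  locmax <- mip >= floor_v
  for (sx in -1:1) for (sy in -1:1) {
    if (sx == 0 && sy == 0) next
    locmax <- locmax & (mip >= mip[isx(sx), isy(sy)])
  }
  idx <- which(locmax, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list())
  rr <- sqrt((idx[, 1] - xi)^2 + (idx[, 2] - yi)^2)
  ok <- rr > r_excl
  idx <- idx[ok, , drop = FALSE]; rr <- rr[ok]
  if (nrow(idx) == 0) return(list())
  vals <- mip[idx]
  ord <- order(-vals)
  out <- list()
  max_len <- config$max_length
  if (is.null(max_len)) max_len <- sqrt(sum((dim(stack$intensities)[1:2] * vx[1:2])^2))
  bg <- median(stack$intensities)
  for (k in utils::head(ord, max_candidates)) {
    # line from the pole through the hotspot, extended ~2 voxels beyond
    L <- (rr[k] + 2) * vx[1]
    if (L < config$min_length || L > max_len) next
    dirv <- c(idx[k, 1] - xi, idx[k, 2] - yi) / rr[k]
    ex <- pole[1] + L * dirv[1]; ey <- pole[2] + L * dirv[2]
    ez <- z_centroid(stack, idx[k, 1], idx[k, 2], bg)
    amp <- max(vals[k] - med, 0.05 * max(bg, 1e-6))
    out[[length(out) + 1]] <-
      mt_line(amp, start = pole, end = c(ex, ey, ez), sigma = config$psf_sigma)
  }
  out
}

# --- curve tracing ---------------------------------------------------------

# Ridge orientation fields from the smoothed MIP: eigen-analysis of the 2D
# Hessian. Returns closures giving the ridge direction (unit vector of the
# eigenvector across which curvature is weakest) at continuous positions.
ridge_fields <- function(mip, scale) {
  m <- gauss_filter_dim(gauss_filter_dim(array(mip, c(dim(mip), 1)), scale, 1),
                        scale, 2)[, , 1]
  nx <- nrow(m); ny <- ncol(m)
  cx <- function(mm) (mm[c(2:nx, nx), ] - mm[c(1, 1:(nx - 1)), ]) / 2
  cy <- function(mm) (mm[, c(2:ny, ny)] - mm[, c(1, 1:(ny - 1))]) / 2
  gxx <- cx(cx(m)); gyy <- cy(cy(m)); gxy <- cy(cx(m))
  list(
    smoothed = m,
    direction = function(xi, yi) {
      a <- bilinear(gxx, xi, yi); b <- bilinear(gxy, xi, yi)
      c2 <- bilinear(gyy, xi, yi)
      # eigenvector of [[a,b],[b,c2]] for the larger (least negative)
      # eigenvalue = along-ridge direction on a bright ridge
      tr <- (a + c2) / 2; dlt <- sqrt(((a - c2) / 2)^2 + b^2)
      l1 <- tr + dlt
      v <- c(b, l1 - a)
      if (sum(v^2) < 1e-24) v <- c(l1 - c2, b)
      if (sum(v^2) < 1e-24) v <- c(1, 0)
      v / sqrt(sum(v^2))
    })
}

#' Trace a curved filament from a starting point
#'
#' Enhances line-like structure with a second-order ridge filter (Hessian
#' eigen-analysis of the scale-smoothed MIP) and iteratively steps along the
#' local ridge orientation, keeping the step direction consistent with the
#' previous one. The walk stops when the image intensity drops below
#' `stop_factor x background`, when the path leaves the image, or when the
#' local turn exceeds 90 degrees. The traced path is then condensed into an
#' [mt_curve] guess: a parametric polynomial (degree 4 in XY, 1 in Z) is fit
#' to the path, its sampled curvature is modeled with [fit_curvature_fourier]
#' (N = 2), and the initial tangent and arc length are read off the
#' polynomial.
#'
#' @param mip smoothed MIP matrix (from [preprocess]).
#' @param stack the (unfiltered) [image_stack].
#' @param start start position (x, y) or (x, y, z), micron.
#' @param direction initial direction (2-vector, XY).
#' @param config a [detection_config].
#' @param max_steps safety cap on the number of steps.
#' @return list with `path` (matrix of traced XY positions, micron) and
#'   `curve` (an [mt_curve] guess, or `NULL` if the path is too short).
#' @export
trace_curve <- function(mip, stack, start, direction,
                        config = detection_config(), max_steps = 1000) {
  vx <- stack$voxel_size
  bg <- median(stack$intensities)
  rf <- ridge_fields(mip, config$steerable_scale)
  xi <- start[1] / vx[1] + 0.5; yi <- start[2] / vx[2] + 0.5
  nx <- nrow(mip); ny <- ncol(mip)
  if (xi < 1 || xi > nx || yi < 1 || yi > ny) {
    stop("empty-path: start position outside the image", call. = FALSE)
  }
  if (sum(direction[1:2]^2) == 0) {
    stop("empty-path: zero initial direction", call. = FALSE)
  }
  if (bilinear(mip, xi, yi) < config$stop_factor * bg) {
    stop("empty-path: start intensity is at background level", call. = FALSE)
  }
  dirv <- direction[1:2] / sqrt(sum(direction[1:2]^2))
  path <- matrix(c(xi, yi), ncol = 2)
  for (s in seq_len(max_steps)) {
    v <- rf$direction(xi, yi)
    if (sum(v * dirv) < 0) v <- -v
    if (sum(v * dirv) < cos(pi / 2)) break  # sharper than 90 degrees
    xi2 <- xi + config$trace_step * v[1]
    yi2 <- yi + config$trace_step * v[2]
    if (xi2 < 1 || xi2 > nx || yi2 < 1 || yi2 > ny) break
    if (bilinear(mip, xi2, yi2) < config$stop_factor * bg) break
    xi <- xi2; yi <- yi2; dirv <- v
    path <- rbind(path, c(xi, yi))
  }
  path_um <- cbind((path[, 1] - 0.5) * vx[1], (path[, 2] - 0.5) * vx[2])
  curve <- NULL
  if (nrow(path) >= 8) curve <- path_to_curve(path_um, stack, config)
  list(path = path_um, curve = curve)
}

# Condense a traced 2D path into an mt_curve guess via the parametric
# polynomial (degree 4 in XY, 1 in Z) and the Fourier curvature model.
path_to_curve <- function(path_um, stack, config, n_xy = 4) {
  n <- nrow(path_um)
  seg <- sqrt(rowSums(diff(path_um)^2))
  tt <- c(0, cumsum(seg)) / sum(seg)
  fitp <- function(y, deg) unname(coef(lm(y ~ poly(tt, degree = deg, raw = TRUE))))
  xc <- fitp(path_um[, 1], n_xy)
  yc <- fitp(path_um[, 2], n_xy)
  xc[is.na(xc)] <- 0; yc[is.na(yc)] <- 0
  ts <- seq(0.02, 0.98, length.out = 40)
  K <- local_curvature(xc, yc, ts)
  fk <- fit_curvature_fourier(ts, K, N = 2)
  bg <- median(stack$intensities)
  vx <- stack$voxel_size
  zs <- vapply(seq_len(n), function(i) {
    z_centroid(stack, path_um[i, 1] / vx[1] + 0.5, path_um[i, 2] / vx[2] + 0.5, bg)
  }, 0)
  zfit <- unname(coef(lm(zs ~ tt)))
  # arc length of the polynomial centerline (XY; Z is nearly flat)
  tf <- seq(0, 1, length.out = 400)
  ev <- function(co, t) drop(outer(t, seq_along(co) - 1, `^`) %*% co)
  pl <- cbind(ev(xc, tf), ev(yc, tf))
  L3 <- path_length(cbind(pl, ev(zfit, tf)))
  d1 <- function(co) co[-1] * seq_len(length(co) - 1)
  tan0 <- c(ev(d1(xc), 0), ev(d1(yc), 0), zfit[2])
  if (sqrt(sum(tan0^2)) == 0) return(NULL)
  mid <- path_um[ceiling(n / 2), ]
  amp <- max(bilinear(max_intensity_projection(stack),
                      mid[1] / vx[1] + 0.5, mid[2] / vx[2] + 0.5) - bg,
             0.05 * max(bg, 1e-6))
  mt_curve(amp, origin = c(path_um[1, ], zfit[1]), tangent = tan0,
           curvature = list(k0 = fk$k0, w = fk$w, p = fk$p, q = fk$q),
           length = L3, sigma = config$psf_sigma)
}

#' Detect features in a stack for a given spindle topology
#'
#' Structure-specific dispatcher producing the initial guess consumed by the
#' optimizer: monopolar (one pole spot plus radiating lines), bipolar (two
#' pole spots plus the spindle line and any polar lines), or astral (bipolar
#' plus ridge-traced curves from each pole).
#'
#' @param stack an [image_stack].
#' @param structure one of "monopolar", "bipolar", "astral".
#' @param config a [detection_config].
#' @return object of class `initial_guess`: list with `features` (typed
#'   feature list), `background` (median intensity), `provenance` (character,
#'   one entry per feature), `topology` and `attachments`.
#' @export
detect_features <- function(stack, structure = c("monopolar", "bipolar", "astral"),
                            config = detection_config()) {
  structure_tag <- match.arg(structure)
  pp <- preprocess(stack, config)
  feats <- list(); prov <- character(0); attach <- integer(0)
  if (structure_tag == "monopolar") {
    pole <- find_pole(pp$mip, stack, config)
    amp <- max(pole$value - pp$background, 0.05 * max(pp$background, 1e-6))
    feats <- list(mt_spot(amp, pole$position, config$spot_sigma))
    prov <- "pole"
    attach <- NA_integer_
    lines <- detect_lines_from_pole(pp$mip, stack, pole$position, config)
    for (ln in lines) {
      feats[[length(feats) + 1]] <- ln
      prov <- c(prov, "angular-scan")
      attach <- c(attach, 1L)
    }
  } else {
    bp <- detect_bipolar(pp$mip, stack, config)
    feats <- c(bp$spots, list(bp$spindle), bp$polar_lines)
    prov <- c("pole", "pole", "spindle",
              rep("angular-scan", length(bp$polar_lines)))
    attach <- c(NA_integer_, NA_integer_, 1L,
                rep(NA_integer_, length(bp$polar_lines)))
    if (structure_tag == "astral") {
      for (pole_i in 1:2) {
        pole <- bp$spots[[pole_i]]$center
        other <- bp$spots[[3 - pole_i]]$center
        toward <- atan2(other[2] - pole[2], other[1] - pole[1])
        ai <- angular_intensity(pp$mip, pole, config, stack$voxel_size[1:2])
        # blank the spindle direction before peak finding: its peak is far
        # brighter than any astral filament and would dominate the
        # prominence criterion
        dang_all <- abs(((ai$phi - toward + pi) %% (2 * pi)) - pi)
        masked <- ai$intensity
        masked[dang_all <= pi / 6] <- min(ai$intensity)
        pk <- circular_peaks(masked, config$peak_prominence * max(masked, 0))
        for (b in pk) {
          dang <- abs(((ai$phi[b] - toward + pi) %% (2 * pi)) - pi)
          if (dang <= pi / 6) next
          dir0 <- c(cos(ai$phi[b]), sin(ai$phi[b]))
          tc <- tryCatch(
            trace_curve(pp$mip, stack,
                        pole[1:2] + dir0 * 3 * stack$voxel_size[1], dir0, config),
            error = function(e) NULL)
          if (!is.null(tc) && !is.null(tc$curve) &&
              tc$curve$length >= config$min_length) {
            feats[[length(feats) + 1]] <- tc$curve
            prov <- c(prov, "ridge-trace")
            attach <- c(attach, pole_i)
          }
        }
      }
      # drop straight polar lines that duplicate traced curves
    }
  }
  structure(list(features = feats, background = pp$background,
                 provenance = prov, topology = structure_tag,
                 attachments = attach),
            class = "initial_guess")
}

#' @export
print.initial_guess <- function(x, ...) {
  cat(sprintf("<initial_guess [%s]: %d features (%s), B0=%.4g>\n",
              x$topology, length(x$features),
              paste(unique(x$provenance), collapse = ", "), x$background))
  invisible(x)
}
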