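# Synthetic 3D spindle images with ground truth and calibrated SNR: the
# validation substrate for benchmarking detection and localization.

#' Simulation configuration
#'
#' Defaults emulate monopolar-spindle stacks of fission yeast imaged by
#' spinning-disk confocal microscopy: 6.4 x 6.4 x 3.5 micron volumes at
#' 0.1 micron XY / 0.5 micron Z voxels, 0-7 microtubules of 0.5-3 micron
#' radiating from a bright pole. Feature amplitudes are *peak* centerline
#' brightnesses (a microtubule's fluorophore density per unit length does
#' not depend on its length), held fixed while the noise level is varied to
#' reach a target SNR.
#'
#' The noise model is Poisson-like: the background is itself a photon
#' signal, so the clean feature render is placed on a uniform background
#' rate `b` and each voxel receives Gaussian noise with variance
#' `gain x rate` (clipped at zero). The target SNR (mean background-
#' subtracted microtubule intensity over the image median, see
#' [compute_snr]) fixes `b`: more background photons mean both a higher
#' noise floor and a lower SNR, as in low-excitation live-cell imaging.
#'
#' @param dim image shape in voxels (nx, ny, nz).
#' @param voxel_size micron per voxel (dx, dy, dz).
#' @param structure "monopolar", "bipolar" or "astral".
#' @param n_mt_range inclusive integer range for the microtubule count
#'   (monopolar) or astral-curve count (astral).
#' @param length_range microtubule length range, micron.
#' @param mt_amplitude peak brightness of a single microtubule/bundle line.
#' @param spot_amplitude peak brightness of the pole (SPB) spot.
#' @param spindle_amplitude peak brightness of the bipolar spindle bundle.
#' @param sigma_mt,sigma_spot Gaussian widths (micron) of microtubules and
#'   poles (the PSF scale).
#' @param background additional uniform model background B0 (on top of the
#'   SNR-calibrated background rate).
#' @param noise "poisson" (variance = gain x rate), "gaussian"
#'   (constant sd = gain x background rate) or "none".
#' @param gain noise scale factor (arbitrary-unit variance per unit rate).
#' @param target_snr target signal-to-noise ratio; `Inf` adds no calibrated
#'   background.
#' @param spindle_length_range pole separation range for bipolar/astral.
#' @param z_fraction_max maximum |dz|/L of a microtubule (spindles lie
#'   mostly in-plane in a confocal slab).
#' @param seed RNG seed.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(dim = c(64, 64, 7), voxel_size = c(0.1, 0.1, 0.5),
                              structure = c("monopolar", "bipolar", "astral"),
                              n_mt_range = c(0, 7), length_range = c(0.5, 3),
                              mt_amplitude = 5, spot_amplitude = 15,
                              spindle_amplitude = 15,
                              sigma_mt = c(0.15, 0.15, 0.35),
                              sigma_spot = c(0.2, 0.2, 0.45),
                              background = 0,
                              noise = c("poisson", "gaussian", "none"),
                              gain = 1, target_snr = 1.25,
                              spindle_length_range = c(2, 3.5),
                              z_fraction_max = 0.25, seed = 1) {
  structure_tag <- match.arg(structure)
  noise <- match.arg(noise)
  stopifnot(all(dim >= 1), all(voxel_size > 0), n_mt_range[1] >= 0,
            length_range[1] > 0, target_snr > 0, gain > 0)
  ext <- dim * voxel_size
  if (length_range[2] > min(ext[1:2]) / 2) {
    stop("config error: maximum microtubule length exceeds the image half-extent")
  }
  structure(list(dim = as.integer(dim), voxel_size = voxel_size,
                 structure = structure_tag, n_mt_range = n_mt_range,
                 length_range = length_range, mt_amplitude = mt_amplitude,
                 spot_amplitude = spot_amplitude,
                 spindle_amplitude = spindle_amplitude,
                 sigma_mt = sigma_mt, sigma_spot = sigma_spot,
                 background = background, noise = noise, gain = gain,
                 target_snr = target_snr,
                 spindle_length_range = spindle_length_range,
                 z_fraction_max = z_fraction_max, seed = seed),
            class = "simulation_config")
}

# Draw a random microtubule line from a pole, kept inside the usable volume.
draw_mt_line <- function(pole, cfg, margin = 0.2) {
  ext <- cfg$dim * cfg$voxel_size
  zlim <- c(min(0.5, ext[3] / 4), ext[3] - min(0.5, ext[3] / 4))
  for (try in 1:100) {
    L <- runif(1, cfg$length_range[1], cfg$length_range[2])
    phi <- runif(1, 0, 2 * pi)
    cz <- runif(1, -cfg$z_fraction_max, cfg$z_fraction_max)
    cxy <- sqrt(1 - cz^2)
    dir <- c(cos(phi) * cxy, sin(phi) * cxy, cz)
    end <- pole + L * dir
    if (end[1] > margin && end[1] < ext[1] - margin &&
        end[2] > margin && end[2] < ext[2] - margin &&
        end[3] > zlim[1] && end[3] < zlim[2]) {
      return(list(end = end, length = L, phi = phi))
    }
  }
  NULL
}

# Scale a feature's amplitude so its rendered peak equals `peak`.
peak_normalize <- function(feature, geom, peak) {
  mx <- max(render_feature(feature, geom))
  feature$amplitude <- feature$amplitude * peak / mx
  feature
}

#' Simulate a 3D spindle image with ground truth
#'
#' Draws a composite model uniformly from the configured ranges (monopolar:
#' central pole spot plus K radiating lines; bipolar: two pole spots joined
#' by a spindle line; astral: a bipolar spindle plus curved filaments from
#' the poles), renders it, adds the SNR-calibrated background rate and
#' noise, and returns the noisy stack together with the exact generating
#' features. Reproducible: the same config (including seed) gives a
#' bit-identical image and truth.
#'
#' @param cfg a [simulation_config].
#' @return list with `image` (an [image_stack]) and `truth` (class
#'   `ground_truth`): the generating model (`model`, whose background equals
#'   B0 plus the calibrated rate so re-rendering it reproduces the clean
#'   image exactly), microtubule features (`microtubules`), their `tips` and
#'   `lengths`, the pole positions, `background_rate`, `realized_snr` and
#'   the seed.
#' @export
simulate_image <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  geom <- list(dim = cfg$dim, voxel_size = cfg$voxel_size)
  ext <- cfg$dim * cfg$voxel_size
  center <- ext / 2
  feats <- list(); is_mt <- logical(0)

  if (cfg$structure == "monopolar") {
    pole <- center + c(runif(2, -0.3, 0.3), 0)
    feats <- list(mt_spot(cfg$spot_amplitude, pole, cfg$sigma_spot))
    is_mt <- FALSE
    K <- if (cfg$n_mt_range[2] > cfg$n_mt_range[1]) {
      sample(cfg$n_mt_range[1]:cfg$n_mt_range[2], 1)
    } else cfg$n_mt_range[1]
    for (k in seq_len(K)) {
      mt <- draw_mt_line(pole, cfg)
      if (is.null(mt)) next
      ln <- mt_line(1, pole, mt$end, cfg$sigma_mt)
      feats[[length(feats) + 1]] <- peak_normalize(ln, geom, cfg$mt_amplitude)
      is_mt <- c(is_mt, TRUE)
    }
  } else {
    sl <- runif(1, cfg$spindle_length_range[1], cfg$spindle_length_range[2])
    phi <- runif(1, 0, 2 * pi)
    ax <- c(cos(phi), sin(phi), 0)
    p1 <- center - ax * sl / 2
    p2 <- center + ax * sl / 2
    feats <- list(mt_spot(cfg$spot_amplitude, p1, cfg$sigma_spot),
                  mt_spot(cfg$spot_amplitude, p2, cfg$sigma_spot),
                  peak_normalize(mt_line(1, p1, p2, cfg$sigma_mt), geom,
                                 cfg$spindle_amplitude))
    is_mt <- c(FALSE, FALSE, FALSE)
    if (cfg$structure == "astral") {
      K <- max(1, cfg$n_mt_range[1])
      if (cfg$n_mt_range[2] > K) K <- sample(K:min(cfg$n_mt_range[2], 2), 1)
      for (k in seq_len(K)) {
        cv <- draw_astral_curve(if (k %% 2) p2 else p1,
                                if (k %% 2) ax else -ax, cfg)
        if (is.null(cv)) next
        feats[[length(feats) + 1]] <- peak_normalize(cv, geom, cfg$mt_amplitude)
        is_mt <- c(is_mt, TRUE)
      }
    }
  }

  model <- composite_model(cfg$background, feats, topology = cfg$structure)
  clean_signal <- render_model(model, geom) - cfg$background

  # calibrate the background rate b from the target SNR
  mts <- which(is_mt)
  excl <- spot_exclusion(feats)
  b <- 0
  if (is.finite(cfg$target_snr) && length(mts) > 0) {
    fp <- lapply(feats[mts], footprint_voxels, geom = geom, exclude = excl)
    m_sig <- mean(vapply(fp, function(ix) mean(clean_signal[ix]), 0))
    b <- m_sig / cfg$target_snr
  } else if (is.finite(cfg$target_snr)) {
    # no microtubules: calibrate on the nominal amplitude
    b <- cfg$mt_amplitude * 0.75 / cfg$target_snr
  }
  rate <- clean_signal + cfg$background + b
  noisy <- switch(cfg$noise,
    none = rate,
    poisson = pmax(rate + sqrt(cfg$gain * pmax(rate, 0)) *
                     array(rnorm(length(rate)), dim = dim(rate)), 0),
    gaussian = pmax(rate + sqrt(cfg$gain) * b *
                      array(rnorm(length(rate)), dim = dim(rate)), 0))
  image <- image_stack(noisy, cfg$voxel_size)

  truth_model <- model
  truth_model$background <- cfg$background + b
  truth <- structure(list(
    model = truth_model,
    microtubules = feats[mts],
    tips = lapply(feats[mts], feature_tip),
    lengths = vapply(feats[mts], feature_length, 0),
    poles = lapply(feats[!is_mt & vapply(feats, inherits, TRUE, "mt_spot")],
                   function(f) f$center),
    background_rate = b,
    seed = cfg$seed,
    config = cfg), class = "ground_truth")
  truth$realized_snr <- tryCatch(compute_snr(image, truth),
                                 error = function(e) NA_real_)
  list(image = image, truth = truth)
}

# Random curved astral microtubule growing outward from a pole.
draw_astral_curve <- function(pole, outward, cfg, margin = 0.3) {
  ext <- cfg$dim * cfg$voxel_size
  base_phi <- atan2(outward[2], outward[1])
  for (try in 1:100) {
    L <- runif(1, max(1, cfg$length_range[1]), min(3.5, ext[1] / 2))
    phi <- base_phi + runif(1, -pi / 3, pi / 3)
    cc <- list(k0 = runif(1, -0.5, 0.5), w = runif(1, 2, 8),
               p = runif(2, -0.3, 0.3), q = runif(2, -0.3, 0.3))
    cv <- mt_curve(1, pole, c(phi, pi / 2), cc, L, cfg$sigma_mt)
    pts <- reconstruct_curve(pole, angles_to_vec(c(phi, pi / 2)), cc, L, L / 500)
    ok <- all(pts[, 1] > margin & pts[, 1] < ext[1] - margin &
              pts[, 2] > margin & pts[, 2] < ext[2] - margin &
              pts[, 3] > 0.3 & pts[, 3] < ext[3] - 0.3)
    if (ok) return(cv)
  }
  NULL
}

# Voxel indices within one sigma (elliptical norm) of a feature centerline.
# `exclude` is an optional list(centers = list of 3-vectors, radius): voxels
# within `radius` of any center are dropped (used to keep the bright pole
# spot out of a microtubule's SNR footprint).
footprint_voxels <- function(feature, geom, exclude = NULL) {
  sig <- feature$sigma
  if (inherits(feature, "mt_line")) {
    L <- feature_length(feature)
    n <- max(2, ceiling(L / (min(sig[1:2]) / 2)))
    tt <- seq(0, 1, length.out = n)
    pts <- outer(tt, feature$end - feature$start) +
      rep(feature$start, each = n)
  } else if (inherits(feature, "mt_curve")) {
    pts <- reconstruct_curve(feature$origin,
                             angles_to_vec(feature$tangent_angles),
                             feature$curvature, feature$length,
                             min(sig[1:2]) / 2)
  } else {
    pts <- matrix(feature$center, 1)
  }
  mark <- array(FALSE, geom$dim)
  nb <- ceiling(sig / geom$voxel_size)
  for (r in seq_len(nrow(pts))) {
    ci <- pts[r, ] / geom$voxel_size + 0.5
    i0 <- pmax(1, floor(ci - nb)); i1 <- pmin(geom$dim, ceiling(ci + nb))
    if (any(i0 > i1)) next
    for (k in i0[3]:i1[3]) for (j in i0[2]:i1[2]) for (i in i0[1]:i1[1]) {
      d <- (c(i, j, k) - 0.5) * geom$voxel_size - pts[r, ]
      if (sum((d / sig)^2) <= 1) mark[i, j, k] <- TRUE
    }
  }
  ix <- which(mark)
  if (!is.null(exclude) && length(exclude$centers) > 0 && length(ix) > 0) {
    sub <- arrayInd(ix, geom$dim)
    pos <- sweep(sub - 0.5, 2, geom$voxel_size, `*`)
    keep <- rep(TRUE, length(ix))
    for (ctr in exclude$centers) {
      d2 <- rowSums(sweep(pos, 2, ctr)^2)
      keep <- keep & d2 > exclude$radius^2
    }
    if (any(keep)) ix <- ix[keep]
  }
  ix
}

# Exclusion zones around the pole spots of a feature list/model.
spot_exclusion <- function(features) {
  spots <- Filter(function(f) inherits(f, "mt_spot"), features)
  if (length(spots) == 0) return(NULL)
  list(centers = lapply(spots, function(s) s$center),
       radius = 2 * max(vapply(spots, function(s) max(s$sigma[1:2]), 0)))
}

#' Signal-to-noise ratio of an image given its ground truth
#'
#' SNR is defined per microtubule as the mean background-subtracted image
#' intensity over the microtubule's footprint (voxels within one sigma of
#' its centerline, excluding the immediate neighborhood of pole spots,
#' whose fluorescence is not the microtubule's) divided by the background
#' intensity, taken as the median intensity of the image; the image SNR is
#' the average over microtubules.
#' The ratio is invariant under rescaling the whole image and grows without
#' bound as the noise floor vanishes.
#'
#' @param image an [image_stack].
#' @param truth a `ground_truth` (or any list with a `microtubules` element
#'   of line/curve features).
#' @return scalar SNR.
#' @export
compute_snr <- function(image, truth) {
  mts <- truth$microtubules
  if (length(mts) == 0) {
    stop("undefined SNR: ground truth contains no microtubules", call. = FALSE)
  }
  geom <- as_geometry(image)
  med <- median(image$intensities)
  if (med <= 0) return(Inf)
  excl <- if (!is.null(truth$model)) spot_exclusion(truth$model$features) else NULL
  vals <- vapply(mts, function(f) {
    ix <- footprint_voxels(f, geom, exclude = excl)
    (mean(image$intensities[ix]) - med) / med
  }, 0)
  mean(vals)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth [%s]: %d microtubules, SNR %.3g, seed %d>\n",
              x$config$structure, length(x$microtubules),
              x$realized_snr, x$seed))
  invisible(x)
}
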