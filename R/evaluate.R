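# Scoring detections against ground truth (correct/spurious/missed and
# sub-pixel localization errors as a function of SNR) and extraction of
# dynamic-instability events from length time-series.

#' Classify detected microtubules against ground truth
#'
#' Greedy nearest-first one-to-one matching on tip-to-tip distance: the
#' globally closest (detection, truth) pair within `match_radius` is matched
#' first, then the next closest among the remainder, and so on. A detected
#' microtubule whose tip is farther than `match_radius` from the tip of
#' every simulated microtubule is spurious; simulated microtubules with no
#' matched detection are missed. Pole spots are excluded: only line/curve
#' features count as microtubules.
#'
#' @param detected list of features (e.g. `fit$model$features`), or a
#'   `composite_model`.
#' @param truth a `ground_truth` from [simulate_image].
#' @param match_radius matching criterion in micron (default 0.5).
#' @return object of class `detection_report`: counts (`n_true`,
#'   `n_detected`, `n_correct`, `n_spurious`, `n_missed`), a `matches` data
#'   frame (detection index, truth index, per-axis signed errors in micron,
#'   distance), per-truth `truth_status` and lengths of correct/missed
#'   microtubules.
#' @export
classify_detections <- function(detected, truth, match_radius = 0.5) {
  stopifnot(match_radius > 0)
  if (inherits(detected, "composite_model")) detected <- detected$features
  is_mt <- vapply(detected, function(f) {
    inherits(f, "mt_line") || inherits(f, "mt_curve")
  }, TRUE)
  det <- detected[is_mt]
  det_tips <- lapply(det, feature_tip)
  true_tips <- truth$tips
  nd <- length(det_tips); nt <- length(true_tips)
  D <- matrix(Inf, nd, nt)
  if (nd > 0 && nt > 0) {
    for (a in seq_len(nd)) for (b in seq_len(nt)) {
      D[a, b] <- sqrt(sum((det_tips[[a]] - true_tips[[b]])^2))
    }
  }
  matches <- data.frame(detected = integer(0), truth = integer(0),
                        ex = numeric(0), ey = numeric(0), ez = numeric(0),
                        distance = numeric(0))
  Dw <- D
  while (nd > 0 && nt > 0 && any(is.finite(Dw)) && min(Dw) <= match_radius) {
    ij <- arrayInd(which.min(Dw), dim(Dw))
    a <- ij[1]; b <- ij[2]
    err <- det_tips[[a]] - true_tips[[b]]
    matches <- rbind(matches, data.frame(
      detected = a, truth = b, ex = err[1], ey = err[2], ez = err[3],
      distance = Dw[a, b]))
    Dw[a, ] <- Inf; Dw[, b] <- Inf
  }
  truth_status <- rep("missed", nt)
  truth_status[matches$truth] <- "correct"
  det_status <- rep("spurious", nd)
  det_status[matches$detected] <- "correct"
  structure(list(
    matches = matches,
    n_true = nt, n_detected = nd,
    n_correct = nrow(matches),
    n_spurious = nd - nrow(matches),
    n_missed = nt - nrow(matches),
    truth_status = truth_status, det_status = det_status,
    length_correct = truth$lengths[truth_status == "correct"],
    length_missed = truth$lengths[truth_status == "missed"],
    length_detected = vapply(det, feature_length, 0)),
    class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("<detection_report: %d true, %d detected -> %d correct, %d spurious, %d missed>\n",
              x$n_true, x$n_detected, x$n_correct, x$n_spurious, x$n_missed))
  invisible(x)
}

#' Localization errors of correctly detected microtubules
#'
#' Per-axis absolute tip errors in micron and in per-axis pixel units, and
#' the "3D pixel-normalized error": the Euclidean norm of the per-axis
#' errors after dividing each by that axis's pixel size. A 3D error below 1
#' means sub-pixel localization in the combined sense.
#'
#' @param report a `detection_report` from [classify_detections].
#' @param voxel_size (dx, dy, dz) micron per voxel.
#' @return list with the per-match vectors (`err_x_um` etc., `err_3d_px`)
#'   and a `summary` data frame of means and standard errors; `n = 0`
#'   (flagged via `empty = TRUE`) when there are no matches.
#' @export
position_errors <- function(report, voxel_size = c(0.1, 0.1, 0.5)) {
  m <- report$matches
  if (nrow(m) == 0) {
    return(list(empty = TRUE, n = 0, summary = data.frame()))
  }
  ex <- abs(m$ex); ey <- abs(m$ey); ez <- abs(m$ez)
  px <- m$ex / voxel_size[1]; py <- m$ey / voxel_size[2]
  pz <- m$ez / voxel_size[3]
  e3 <- sqrt(px^2 + py^2 + pz^2)
  se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  list(empty = FALSE, n = nrow(m),
       err_x_um = ex, err_y_um = ey, err_z_um = ez,
       err_x_px = abs(px), err_y_px = abs(py), err_z_px = abs(pz),
       err_3d_px = e3,
       summary = data.frame(
         metric = c("err_xy_um", "err_z_um", "err_xy_px", "err_z_px", "err_3d_px"),
         mean = c(mean(c(ex, ey)), mean(ez), mean(c(abs(px), abs(py))),
                  mean(abs(pz)), mean(e3)),
         se = c(se(c(ex, ey)), se(ez), se(c(abs(px), abs(py))), se(abs(pz)),
                se(e3))))
}

#' Benchmark the pipeline across SNR levels
#'
#' For each SNR level and repetition: simulate a stack, run the full
#' per-frame pipeline (detection, local and global fitting, feature-count
#' selection), classify detections with the tip-distance criterion and
#' accumulate localization errors. Per-image failures are logged and
#' counted, never fatal (their truths count as missed). Seeded and
#' deterministic: image `r` at level `i` uses seed
#' `base_seed + 7919 * (i - 1) + r`.
#'
#' @param sim_cfg a [simulation_config] (its `target_snr` and `seed` are
#'   overridden per image).
#' @param snr_levels numeric vector of SNR levels.
#' @param reps_per_level repetitions per level (scalar or vector).
#' @param base_seed base RNG seed.
#' @param match_radius matching criterion (micron).
#' @param det_config a [detection_config].
#' @param control a [fit_control].
#' @param alpha f-test level for feature-count selection.
#' @param progress print one line per level?
#' @return list with `table` (per-level data frame: snr, n_images, n_true,
#'   correct_pct, spurious_pct, missed_pct, mean per-axis and 3D pixel
#'   errors, mean lengths of correct and missed microtubules, failures) and
#'   `per_image` (data frame of per-image counts).
#' @export
snr_sweep <- function(sim_cfg = simulation_config(),
                      snr_levels = c(0.75, 1, 1.25, 1.5, 3, 5),
                      reps_per_level = 50, base_seed = 1,
                      match_radius = 0.5,
                      det_config = detection_config(),
                      control = fit_control(),
                      alpha = 0.05, progress = FALSE) {
  stopifnot(all(reps_per_level >= 1))
  reps <- rep_len(reps_per_level, length(snr_levels))
  rows <- list(); per_image <- list()
  for (i in seq_along(snr_levels)) {
    snr <- snr_levels[i]
    n_true <- n_corr <- n_spur <- n_miss <- n_fail <- 0L
    e3 <- ex <- ez <- numeric(0)
    len_c <- len_m <- numeric(0)
    for (r in seq_len(reps[i])) {
      cfg <- sim_cfg
      cfg$target_snr <- snr
      cfg$seed <- base_seed + 7919L * (i - 1L) + r
      sim <- simulate_image(cfg)
      rep_r <- tryCatch({
        fit <- fit_frame(sim$image, structure = cfg$structure,
                         det_config = det_config, control = control,
                         alpha = alpha)
        classify_detections(fit$model, sim$truth, match_radius)
      }, error = function(e) {
        n_fail <<- n_fail + 1L
        classify_detections(list(), sim$truth, match_radius)
      })
      n_true <- n_true + rep_r$n_true
      n_corr <- n_corr + rep_r$n_correct
      n_spur <- n_spur + rep_r$n_spurious
      n_miss <- n_miss + rep_r$n_missed
      len_c <- c(len_c, rep_r$length_correct)
      len_m <- c(len_m, rep_r$length_missed)
      pe <- position_errors(rep_r, cfg$voxel_size)
      if (!pe$empty) {
        e3 <- c(e3, pe$err_3d_px)
        ex <- c(ex, pe$err_x_px, pe$err_y_px)
        ez <- c(ez, pe$err_z_px)
      }
      per_image[[length(per_image) + 1]] <- data.frame(
        snr = snr, seed = cfg$seed, n_true = rep_r$n_true,
        n_correct = rep_r$n_correct, n_spurious = rep_r$n_spurious)
    }
    rows[[i]] <- data.frame(
      snr = snr, n_images = reps[i], n_true = n_true,
      correct_pct = if (n_true > 0) 100 * n_corr / n_true else NA_real_,
      spurious_pct = if (n_corr + n_spur > 0) {
        100 * n_spur / (n_corr + n_spur)
      } else NA_real_,
      missed_pct = if (n_true > 0) 100 * n_miss / n_true else NA_real_,
      mean_err_xy_px = if (length(ex)) mean(ex) else NA_real_,
      mean_err_z_px = if (length(ez)) mean(ez) else NA_real_,
      mean_err_3d_px = if (length(e3)) mean(e3) else NA_real_,
      mean_len_correct = if (length(len_c)) mean(len_c) else NA_real_,
      mean_len_missed = if (length(len_m)) mean(len_m) else NA_real_,
      failures = n_fail)
    if (progress) {
      message(sprintf("SNR %.2f: correct %.1f%%, 3D err %.2f px",
                      snr, rows[[i]]$correct_pct, rows[[i]]$mean_err_3d_px))
    }
  }
  list(table = do.call(rbind, rows), per_image = do.call(rbind, per_image))
}

#' Detect polymerization/depolymerization events in a length series
#'
#' Segments a microtubule length-vs-time series into dynamic-instability
#' events: maximal contiguous runs of at least `min_points` points whose
#' linear fit has coefficient of determination at least `min_r2` and whose
#' fitted length change is at least `min_delta` in magnitude. Runs are
#' extended greedily while the fit criterion holds; adjacent events share at
#' most their boundary point, which belongs to the earlier event. The sign
#' of the slope sets the kind; the speed is the fitted slope.
#'
#' @param time numeric vector of times (seconds), increasing.
#' @param length numeric vector of lengths (micron), same length.
#' @param min_points minimum points per event (default 3).
#' @param min_delta minimum absolute length change (micron, default 0.5).
#' @param min_r2 minimum R^2 of the linear fit (default 0.8).
#' @return data.frame with one row per event: kind ("polymerization" or
#'   "depolymerization"), t_start, t_end, n_points, delta_um (fitted slope
#'   times duration), speed_um_s, speed_um_min, r2. Zero rows when no run
#'   qualifies.
#' @export
detect_dynamic_events <- function(time, length, min_points = 3,
                                  min_delta = 0.5, min_r2 = 0.8) {
  n <- base::length(time)
  stopifnot(n == base::length(length), min_points >= 3)
  events <- list()
  lin <- function(i, j) {
    tt <- time[i:j]; yy <- length[i:j]
    X <- cbind(1, tt)
    cf <- qr.solve(X, yy)
    res <- yy - X %*% cf
    sst <- sum((yy - mean(yy))^2)
    r2 <- if (sst > 0) 1 - sum(res^2) / sst else 0
    list(slope = cf[2], r2 = r2)
  }
  i <- 1L
  while (i <= n - min_points + 1L) {
    j <- i + min_points - 1L
    f <- lin(i, j)
    if (f$r2 < min_r2) { i <- i + 1L; next }
    while (j < n) {
      f2 <- lin(i, j + 1L)
      if (f2$r2 < min_r2) break
      j <- j + 1L
      f <- f2
    }
    # trim trailing points that degrade the fit (e.g. the first points of
    # the next phase swallowed by the greedy extension)
    while (j - i + 1L > min_points) {
      ftrim <- lin(i, j - 1L)
      if (ftrim$r2 <= f$r2) break
      j <- j - 1L
      f <- ftrim
    }
    delta <- f$slope * (time[j] - time[i])
    if (abs(delta) >= min_delta) {
      events[[base::length(events) + 1]] <- data.frame(
        kind = if (f$slope > 0) "polymerization" else "depolymerization",
        t_start = time[i], t_end = time[j], n_points = j - i + 1L,
        delta_um = delta, speed_um_s = f$slope,
        speed_um_min = f$slope * 60, r2 = f$r2)
      i <- j   # boundary point belongs to the earlier event
    } else {
      i <- i + 1L
    }
  }
  if (base::length(events) == 0) {
    return(data.frame(kind = character(0), t_start = numeric(0),
                      t_end = numeric(0), n_points = integer(0),
                      delta_um = numeric(0), speed_um_s = numeric(0),
                      speed_um_min = numeric(0), r2 = numeric(0)))
  }
  do.call(rbind, events)
}

#' Summarize dynamic-instability events
#'
#' Collects polymerization and depolymerization speed distributions and,
#' for every polymerization event immediately followed (within the same
#' track) by a depolymerization, the total polymerized length preceding the
#' catastrophe.
#'
#' @param events a data.frame as from [detect_dynamic_events], optionally
#'   with a `track_id` column; or a list of such data frames (one per
#'   track).
#' @return list with `poly_speeds_um_min`, `depoly_speeds_um_min` and
#'   `catastrophe_growth_um` (length changes of growth events that ended in
#'   a catastrophe).
#' @export
summarize_dynamics <- function(events) {
  if (is.data.frame(events)) {
    if (is.null(events$track_id)) events$track_id <- 1L
    events <- split(events, events$track_id)
  }
  poly <- numeric(0); depoly <- numeric(0); cat_growth <- numeric(0)
  for (ev in events) {
    if (nrow(ev) == 0) next
    ev <- ev[order(ev$t_start), , drop = FALSE]
    poly <- c(poly, ev$speed_um_min[ev$kind == "polymerization"])
    depoly <- c(depoly, ev$speed_um_min[ev$kind == "depolymerization"])
    if (nrow(ev) > 1) {
      for (k in seq_len(nrow(ev) - 1)) {
        if (ev$kind[k] == "polymerization" &&
            ev$kind[k + 1] == "depolymerization") {
          cat_growth <- c(cat_growth, ev$delta_um[k])
        }
      }
    }
  }
  list(poly_speeds_um_min = poly, depoly_speeds_um_min = depoly,
       catastrophe_growth_um = cat_growth)
}
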