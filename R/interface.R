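# Runnable surface: per-frame detect + fit, the movie pipeline
# (detect -> optimize per frame, then track), file I/O (TIFF, JSON, CSV,
# YAML) and the command-line entry point.

#' Detect and fit a single frame
#'
#' The per-frame analysis: structure-specific detection produces an initial
#' composite model; each feature is refined locally; a global joint fit
#' (including the background) follows; finally the feature count is
#' optimized with [optimize_feature_count], proposing additional line
#' candidates from the residual image at the fitted pole position(s).
#'
#' @param stack an [image_stack].
#' @param structure "monopolar", "bipolar" or "astral".
#' @param det_config a [detection_config].
#' @param control a [fit_control].
#' @param alpha f-test level for the feature-count selection.
#' @param max_features cap on line/curve features.
#' @return a `fit_result` (see [fit_local]).
#' @export
fit_frame <- function(stack, structure = "monopolar",
                      det_config = detection_config(),
                      control = fit_control(), alpha = 0.05,
                      max_features = 8) {
  guess <- detect_features(stack, structure, det_config)
  model <- composite_model(guess$background, guess$features,
                           topology = guess$topology,
                           attachments = guess$attachments)
  for (i in seq_along(model$features)) {
    model <- fit_local(model, stack, i, control)$model
  }
  # a capped first global pass: the feature-count optimization re-fits
  # globally at the end, so full convergence here is not needed
  control1 <- control
  control1$maxiter <- min(control$maxiter, 25)
  fit <- fit_global(model, stack, control1)
  poles <- lapply(Filter(function(f) inherits(f, "mt_spot"),
                         fit$model$features), function(f) f$center)
  bg0 <- median(stack$intensities)
  proposer <- function(resid_stack) {
    pp <- preprocess(resid_stack, det_config)
    cands <- list()
    for (pole in poles) {
      cands <- c(cands, tryCatch(
        detect_lines_from_pole(pp$mip, resid_stack, pole, det_config,
                               background = bg0),
        error = function(e) list()))
    }
    if (length(cands) > 1) {
      cands <- cands[order(-vapply(cands, function(f) f$amplitude, 0))]
    }
    # residual-hotspot-seeded lines: bright leftover blobs pin down both
    # the direction and the radius of microtubules the angular scan dilutes
    # (short ones, or directions partially claimed by fitted neighbors)
    for (pole in poles) {
      cands <- c(cands, hotspot_lines(pp$mip, resid_stack, pole, det_config,
                                      background = bg0))
    }
    utils::head(cands, 4)
  }
  optimize_feature_count(fit$model, stack, proposer, alpha = alpha,
                         max_features = max_features, control = control)
}

# ---------------------------------------------------------------------------
# TIFF input/output
# ---------------------------------------------------------------------------

TIFF_SCALE <- 32768

#' Read and write image stacks as multi-page TIFF
#'
#' Stacks are written as one float32 page per z plane (frames concatenated
#' for movies), scaled by a fixed factor of 32768 to fit the [0, 1] storage
#' range of the TIFF writer. Reading auto-detects: float pages within
#' [0, 1] are rescaled by the same factor, integer pages (e.g. external
#' 16-bit microscopy data) are kept as raw counts.
#'
#' @param stack an [image_stack] (or for movies, a list of them).
#' @param path file path.
#' @return `read_image_stack` returns an [image_stack]; `read_movie_tiff` a
#'   list of them; writers return the path invisibly.
#' @export
write_image_stack <- function(stack, path) {
  write_movie_tiff(list(stack), path)
}

#' @rdname write_image_stack
#' @param stacks list of [image_stack] (the frames of a movie).
#' @export
write_movie_tiff <- function(stacks, path) {
  pages <- list()
  for (s in stacks) {
    a <- s$intensities / TIFF_SCALE
    if (max(a) > 1) stop("intensities too large for the fixed TIFF scale")
    for (k in seq_len(dim(a)[3])) {
      pages[[length(pages) + 1]] <- t(a[, , k])  # page rows = y
    }
  }
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                                   compression = "none"))
  invisible(path)
}

#' @rdname write_image_stack
#' @param nz number of z planes per frame (`NULL`: all pages are one frame).
#' @param voxel_size (dx, dy, dz) micron per voxel.
#' @export
read_image_stack <- function(path, voxel_size = c(0.1, 0.1, 0.5)) {
  frames <- read_movie_tiff(path, nz = NULL, voxel_size = voxel_size)
  frames[[1]]
}

#' @rdname write_image_stack
#' @export
read_movie_tiff <- function(path, nz = NULL, voxel_size = c(0.1, 0.1, 0.5)) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) {
                      stop("input error: unreadable TIFF: ", conditionMessage(e))
                    })
  if (length(pages) == 0) stop("input error: empty TIFF")
  # float32 pages carry our fixed scale; integer pages (external microscopy
  # data, normalized to [0,1] by the reader) are restored to raw counts
  bits <- attr(pages[[1]], "bits.per.sample")
  scale <- if (!is.null(bits) && bits == 32) TIFF_SCALE else 2^bits - 1
  if (is.null(bits)) scale <- 1
  arr3 <- function(pg) {
    a <- array(0, dim = c(ncol(pg[[1]]), nrow(pg[[1]]), length(pg)))
    for (k in seq_along(pg)) {
      a[, , k] <- t(pg[[k]]) * scale
    }
    a
  }
  if (is.null(nz)) nz <- length(pages)
  if (length(pages) %% nz != 0) {
    stop("input error: page count is not a multiple of nz")
  }
  n_frames <- length(pages) / nz
  lapply(seq_len(n_frames), function(f) {
    image_stack(arr3(pages[(f - 1) * nz + seq_len(nz)]), voxel_size)
  })
}

# ---------------------------------------------------------------------------
# JSON serialization of features and fits
# ---------------------------------------------------------------------------

feature_to_list <- function(f) {
  if (inherits(f, "mt_spot")) {
    list(type = "spot", units = "um",
         parameters = list(amplitude = f$amplitude, center = f$center,
                           sigma = f$sigma))
  } else if (inherits(f, "mt_line")) {
    list(type = "line", units = "um",
         parameters = list(amplitude = f$amplitude, start = f$start,
                           end = f$end, sigma = f$sigma))
  } else {
    list(type = "curve", units = "um",
         parameters = list(amplitude = f$amplitude, origin = f$origin,
                           tangent_angles = f$tangent_angles,
                           curvature = f$curvature, length = f$length,
                           sigma = f$sigma))
  }
}

feature_from_list <- function(x) {
  p <- x$parameters
  switch(x$type,
    spot = mt_spot(p$amplitude, unlist(p$center), unlist(p$sigma)),
    line = mt_line(p$amplitude, unlist(p$start), unlist(p$end),
                   unlist(p$sigma)),
    curve = mt_curve(p$amplitude, unlist(p$origin),
                     unlist(p$tangent_angles),
                     list(k0 = p$curvature$k0, w = p$curvature$w,
                          p = unlist(p$curvature$p), q = unlist(p$curvature$q)),
                     p$length, unlist(p$sigma)),
    stop("unknown feature type: ", x$type))
}

#' Serialize features or a composite model to JSON
#'
#' Features are written as records `{type, parameters, units: "um"}`;
#' composite models additionally carry the background level, topology tag
#' and attachment map. [read_features_json] is the exact inverse.
#'
#' @param x a `composite_model`, a list of features, or a `fit_result`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_features_json <- function(x, path) {
  if (inherits(x, "fit_result")) {
    payload <- list(kind = "fit_result",
                    model = model_to_list(x$model), rss = x$rss,
                    rss_initial = x$rss_initial,
                    uncertainties = x$uncertainties,
                    diagnostics = x$diagnostics)
  } else if (inherits(x, "composite_model")) {
    payload <- list(kind = "composite_model", model = model_to_list(x))
  } else {
    payload <- list(kind = "features", features = lapply(x, feature_to_list))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

model_to_list <- function(m) {
  list(background = m$background, topology = m$topology,
       attachments = m$attachments,
       features = lapply(m$features, feature_to_list))
}

model_from_list <- function(x) {
  composite_model(x$background,
                  lapply(x$features, feature_from_list),
                  topology = x$topology,
                  attachments = unlist(x$attachments))
}

#' @rdname write_features_json
#' @export
read_features_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  switch(x$kind,
    fit_result = {
      m <- model_from_list(x$model)
      new_fit_result(m, x$rss, x$rss_initial,
                     unlist(x$uncertainties), x$diagnostics)
    },
    composite_model = model_from_list(x$model),
    features = lapply(x$features, feature_from_list),
    stop("unknown JSON payload kind: ", x$kind))
}

# ---------------------------------------------------------------------------
# Movie pipeline
# ---------------------------------------------------------------------------

#' Pipeline run configuration
#'
#' @param input path to a multi-page TIFF ((T,Z,Y,X) pages), an
#'   [image_stack], or a list of stacks (frames).
#' @param output_dir directory for all written artifacts (created if
#'   needed), or `NULL` to write nothing.
#' @param structure spindle topology to detect.
#' @param nz z planes per frame when reading a movie TIFF.
#' @param voxel_size (dx, dy, dz) micron.
#' @param frame_interval seconds between frames, > 0.
#' @param det_config a [detection_config].
#' @param control a [fit_control].
#' @param alpha f-test level.
#' @param max_features cap on line/curve features per frame.
#' @param max_link_cost,max_gap,min_frames tracker settings (micron,
#'   frames, frames); see [link_features] and [prune_short_tracks].
#' @param write_model_tiff also write the rendered best-fit model stacks?
#' @param seed RNG seed recorded in the outputs.
#' @return a list of class `run_config`.
#' @export
run_config <- function(input, output_dir = NULL,
                       structure = c("monopolar", "bipolar", "astral"),
                       nz = NULL, voxel_size = c(0.1, 0.1, 0.5),
                       frame_interval = 1,
                       det_config = detection_config(),
                       control = fit_control(), alpha = 0.05,
                       max_features = 8, max_link_cost = 1, max_gap = 1,
                       min_frames = 3, write_model_tiff = FALSE, seed = 1) {
  stopifnot(frame_interval > 0)
  structure(list(input = input, output_dir = output_dir,
                 structure = match.arg(structure), nz = nz,
                 voxel_size = voxel_size, frame_interval = frame_interval,
                 det_config = det_config, control = control, alpha = alpha,
                 max_features = max_features, max_link_cost = max_link_cost,
                 max_gap = max_gap, min_frames = min_frames,
                 write_model_tiff = write_model_tiff, seed = seed),
            class = "run_config")
}

#' Run the full movie pipeline
#'
#' Frame by frame: detection, local fits, global fit and feature-count
#' optimization ([fit_frame]); then linking across time and pruning of
#' short-lived features. Per-frame fit failures are flagged and the run
#' continues. Deterministic given the configuration. When an output
#' directory is set, writes per-frame fitted features
#' (`frame_NNN_fit.json`), `tracks.csv`, `summary.json` and optionally the
#' rendered model stacks.
#'
#' @param cfg a [run_config].
#' @return list with `frames` (per-frame `fit_result` or `NULL` on
#'   failure), `tracks` (pruned), `all_tracks`, `summary` (data frame of
#'   per-frame RSS, feature counts, timing) — invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  frames <- if (is.character(cfg$input)) {
    read_movie_tiff(cfg$input, cfg$nz, cfg$voxel_size)
  } else if (inherits(cfg$input, "image_stack")) {
    list(cfg$input)
  } else {
    cfg$input
  }
  if (length(frames) == 0) stop("input error: no frames")
  out <- cfg$output_dir
  if (!is.null(out) && !dir.exists(out)) {
    dir.create(out, recursive = TRUE)
  }
  fits <- vector("list", length(frames))
  summary_rows <- list()
  for (f0 in seq_along(frames)) {
    t0 <- proc.time()[3]
    fit <- tryCatch(
      fit_frame(frames[[f0]], cfg$structure, cfg$det_config, cfg$control,
                cfg$alpha, cfg$max_features),
      error = function(e) {
        message(sprintf("frame %d: fit failed (%s)", f0, conditionMessage(e)))
        NULL
      })
    fits[[f0]] <- fit
    summary_rows[[f0]] <- data.frame(
      frame = f0,
      n_features = if (is.null(fit)) NA_integer_ else length(fit$model$features),
      rss = if (is.null(fit)) NA_real_ else fit$rss,
      seconds = round(proc.time()[3] - t0, 2),
      failed = is.null(fit))
    if (!is.null(out) && !is.null(fit)) {
      write_features_json(fit, file.path(out, sprintf("frame_%03d_fit.json", f0)))
      if (cfg$write_model_tiff) {
        write_image_stack(
          image_stack(render_model(fit$model, frames[[f0]]), cfg$voxel_size),
          file.path(out, sprintf("frame_%03d_model.tif", f0)))
      }
    }
  }
  per_frame_features <- lapply(fits, function(f) {
    if (is.null(f)) list() else f$model$features
  })
  all_tracks <- link_features(per_frame_features, cfg$max_link_cost,
                              cfg$max_gap, cfg$frame_interval)
  tracks <- prune_short_tracks(all_tracks, cfg$min_frames)
  summary <- do.call(rbind, summary_rows)
  if (!is.null(out)) {
    write.csv(tracks_to_df(tracks), file.path(out, "tracks.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(n_frames = length(frames), structure = cfg$structure,
           seed = cfg$seed, n_tracks = length(tracks),
           n_tracks_unpruned = length(all_tracks),
           frames = summary),
      file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  invisible(list(frames = fits, tracks = tracks, all_tracks = all_tracks,
                 summary = summary))
}

# ---------------------------------------------------------------------------
# Command-line interface
# ---------------------------------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: spindletrack <command> [--flags]",
    "commands:",
    "  simulate  --output PATH [--structure S] [--snr X] [--reps N] [--seed N]",
    "  detect    --input TIFF --output JSON [--structure S] [--voxel-size dx dy dz]",
    "  fit       --input TIFF --output DIR [--structure S] [--alpha A] [--nz N]",
    "  track     --input TIFF --output DIR [--structure S] [--min-frames N] [--nz N]",
    "  validate  --output CSV [--snr X1 X2 ...] [--reps N] [--seed N]",
    "  dynamics  --input tracks.csv --output events.csv",
    "common flags: --voxel-size dx dy dz, --frame-interval S, --alpha A,",
    "  --min-frames N, --seed N, --config FILE.yaml (settings override flags)",
    sep = "\n")
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      stop("usage error: unexpected argument: ", a, call. = FALSE)
    }
    key <- gsub("-", "_", substring(a, 3))
    vals <- character(0)
    while (i < length(args) && !startsWith(args[i + 1], "--")) {
      i <- i + 1
      vals <- c(vals, args[i])
    }
    flags[[key]] <- if (length(vals) == 0) TRUE else vals
    i <- i + 1
  }
  if (!is.null(flags$config)) {
    cfg <- yaml::read_yaml(flags$config)
    names(cfg) <- gsub("-", "_", names(cfg))
    flags <- utils::modifyList(flags, cfg)  # YAML overrides flags
  }
  flags
}

cli_num <- function(flags, key, default = NULL) {
  v <- flags[[key]]
  if (is.null(v)) return(default)
  as.numeric(v)
}

cli_structure <- function(flags) {
  s <- flags$structure
  if (is.null(s)) return("monopolar")
  if (!s %in% c("monopolar", "bipolar", "astral")) {
    stop("usage error: unknown --structure: ", s, call. = FALSE)
  }
  s
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write synthetic stacks + ground truth),
#' `detect` (initial guesses from a TIFF), `fit` (per-frame detect + fit),
#' `track` (full movie pipeline), `validate` (SNR sweep benchmark) and
#' `dynamics` (event calling on a tracks CSV). A thin wrapper script is
#' installed at `inst/cli/spindletrack`.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return integer exit status: 0 on success, 2 on usage errors, 1 on
#'   runtime errors (a diagnostic is printed).
#' @export
mt_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0 || argv[1] %in% c("-h", "--help", "help")) {
    cat(cli_usage(), "\n")
    return(if (length(argv) == 0) 2L else 0L)
  }
  cmd <- argv[1]
  run <- function() {
    flags <- parse_cli_flags(argv[-1])
    vox <- cli_num(flags, "voxel_size", c(0.1, 0.1, 0.5))
    need <- function(key) {
      if (is.null(flags[[key]])) {
        stop("usage error: missing --", gsub("_", "-", key), call. = FALSE)
      }
      flags[[key]]
    }
    switch(cmd,
      simulate = {
        out <- need("output")
        reps <- as.integer(cli_num(flags, "reps", 1))
        seed <- as.integer(cli_num(flags, "seed", 1))
        snr <- cli_num(flags, "snr", 1.25)
        cfg0 <- simulation_config(structure = cli_structure(flags),
                                  voxel_size = vox, target_snr = snr,
                                  seed = seed)
        if (reps == 1 && grepl("\\.tiff?$", out)) {
          sim <- simulate_image(cfg0)
          write_image_stack(sim$image, out)
          write_features_json(sim$truth$model, sub("\\.tiff?$", "_truth.json", out))
        } else {
          if (!dir.exists(out)) dir.create(out, recursive = TRUE)
          manifest <- list()
          for (r in seq_len(reps)) {
            cfg0$seed <- seed + r - 1L
            sim <- simulate_image(cfg0)
            ip <- file.path(out, sprintf("image_%04d.tif", r))
            write_image_stack(sim$image, ip)
            write_features_json(sim$truth$model,
                                file.path(out, sprintf("truth_%04d.json", r)))
            manifest[[r]] <- data.frame(seed = cfg0$seed,
                                        snr = sim$truth$realized_snr,
                                        path = basename(ip))
          }
          write.csv(do.call(rbind, manifest),
                    file.path(out, "manifest.csv"), row.names = FALSE)
        }
        0L
      },
      detect = {
        stack <- read_image_stack(need("input"), voxel_size = vox)
        guess <- detect_features(stack, cli_structure(flags))
        write_features_json(guess$features, need("output"))
        0L
      },
      fit = ,
      track = {
        cfg <- run_config(
          input = need("input"), output_dir = need("output"),
          structure = cli_structure(flags),
          nz = if (is.null(flags$nz)) NULL else as.integer(cli_num(flags, "nz")),
          voxel_size = vox,
          frame_interval = cli_num(flags, "frame_interval", 1),
          alpha = cli_num(flags, "alpha", 0.05),
          min_frames = if (cmd == "fit") 1 else
            as.integer(cli_num(flags, "min_frames", 3)),
          seed = as.integer(cli_num(flags, "seed", 1)))
        run_pipeline(cfg)
        0L
      },
      validate = {
        out <- need("output")
        snr <- cli_num(flags, "snr", c(1.25, 3))
        reps <- as.integer(cli_num(flags, "reps", 20))
        seed <- as.integer(cli_num(flags, "seed", 1))
        sweep <- snr_sweep(simulation_config(voxel_size = vox),
                           snr_levels = snr, reps_per_level = reps,
                           base_seed = seed, progress = TRUE)
        write.csv(sweep$table, out, row.names = FALSE)
        0L
      },
      dynamics = {
        df <- read.csv(need("input"))
        evs <- lapply(split(df, df$track_id), function(d) {
          detect_dynamic_events(d$time_s, d$length_um)
        })
        for (id in names(evs)) {
          if (nrow(evs[[id]]) > 0) evs[[id]]$track_id <- as.integer(id)
        }
        evs <- do.call(rbind, evs[vapply(evs, nrow, 0L) > 0])
        if (is.null(evs)) {
          evs <- data.frame(kind = character(0), t_start = numeric(0),
                            t_end = numeric(0), n_points = integer(0),
                            delta_um = numeric(0), speed_um_s = numeric(0),
                            speed_um_min = numeric(0), r2 = numeric(0),
                            track_id = integer(0))
        }
        write.csv(evs, need("output"), row.names = FALSE)
        0L
      },
      stop("usage error: unknown command: ", cmd, call. = FALSE))
  }
  tryCatch(run(), error = function(e) {
    msg <- conditionMessage(e)
    message("spindletrack: ", msg)
    if (grepl("^usage error", msg)) 2L else 1L
  })
}
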