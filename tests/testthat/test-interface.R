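# I/O round trips, movie pipeline, and the command-line entry point.

test_that("TIFF stacks round-trip through write/read", {
  geom <- test_geom(24, 20, 5)
  set.seed(8)
  stack <- image_stack(array(runif(prod(geom$dim), 0, 50), dim = geom$dim),
                       geom$voxel_size)
  tf <- tempfile(fileext = ".tif")
  write_image_stack(stack, tf)
  back <- read_image_stack(tf, voxel_size = geom$voxel_size)
  expect_equal(dim(back$intensities), geom$dim)
  expect_lt(max(abs(back$intensities - stack$intensities)) /
              max(stack$intensities), 1e-6)
  # movie: frames concatenated along pages
  tf2 <- tempfile(fileext = ".tif")
  write_movie_tiff(list(stack, stack), tf2)
  frames <- read_movie_tiff(tf2, nz = 5, voxel_size = geom$voxel_size)
  expect_length(frames, 2)
  expect_equal(frames[[2]]$intensities, frames[[1]]$intensities)
  unlink(c(tf, tf2))
  # unreadable input
  expect_error(read_image_stack(tempfile()), "input error")
})

test_that("the movie pipeline tracks a simulated monopolar movie", {
  # 5-frame movie of one persistent microtubule with slow tip motion
  geom <- test_geom(48, 48, 7)
  ext <- geom$dim * geom$voxel_size
  pole <- ext / 2
  frames <- lapply(1:5, function(f) {
    L <- 1.6 + 0.1 * f
    endp <- pole + L * c(cos(0.6), sin(0.6), 0)
    ln <- mt_line(1, pole, endp, c(0.15, 0.15, 0.35))
    ln$amplitude <- 5 / max(render_line(ln, geom))
    m <- composite_model(3, list(mt_spot(15, pole, c(0.2, 0.2, 0.45)), ln))
    image_stack(render_model(m, geom), geom$voxel_size)
  })
  out_dir <- file.path(tempdir(), "pipe_test")
  cfg <- run_config(frames, output_dir = out_dir, structure = "monopolar",
                    frame_interval = 5, min_frames = 3)
  res <- run_pipeline(cfg)
  expect_length(res$frames, 5)
  expect_false(any(res$summary$failed))
  expect_gte(length(res$tracks), 1)
  # the longest track follows the growing microtubule
  main <- res$tracks[[which.max(vapply(res$tracks,
                                       function(t) length(t$frames), 0L))]]
  expect_gte(length(main$frames), 3)
  ls <- length_series(main)
  expect_equal(ls$time, (main$frames - 1) * 5)
  # artifacts written
  expect_true(file.exists(file.path(out_dir, "tracks.csv")))
  expect_true(file.exists(file.path(out_dir, "summary.json")))
  expect_true(file.exists(file.path(out_dir, "frame_001_fit.json")))
  # determinism: rerunning gives identical track tables
  res2 <- run_pipeline(cfg)
  expect_equal(tracks_to_df(res$tracks), tracks_to_df(res2$tracks))
  unlink(out_dir, recursive = TRUE)
})

test_that("pipeline stage order is detection -> optimization -> tracking", {
  # the per-frame fits never see other frames: a frame-permuted movie gives
  # permuted per-frame features (no temporal coupling before tracking)
  geom <- test_geom(40, 40, 5)
  pole <- geom$dim * geom$voxel_size / 2
  mk <- function(L) {
    ln <- mt_line(1, pole, pole + c(L, 0, 0), c(0.15, 0.15, 0.35))
    ln$amplitude <- 5 / max(render_line(ln, geom))
    m <- composite_model(3, list(mt_spot(15, pole, c(0.2, 0.2, 0.45)), ln))
    image_stack(render_model(m, geom), geom$voxel_size)
  }
  f1 <- mk(1.5); f2 <- mk(1.9)
  r12 <- run_pipeline(run_config(list(f1, f2), min_frames = 1))
  r21 <- run_pipeline(run_config(list(f2, f1), min_frames = 1))
  l12 <- vapply(r12$frames, function(f) {
    feature_length(f$model$features[[2]])
  }, 0)
  expect_equal(l12, rev(vapply(r21$frames, function(f) {
    feature_length(f$model$features[[2]])
  }, 0)), tolerance = 1e-6)
})

test_that("empty input raises an input error", {
  expect_error(run_pipeline(run_config(list())), "input error")
})

test_that("CLI: usage errors, simulate determinism, validate smoke", {
  expect_equal(mt_cli(character(0)), 2L)
  expect_equal(suppressMessages(mt_cli(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(mt_cli(c("detect", "--output", "x.json"))), 2L)
  expect_equal(suppressMessages(
    mt_cli(c("simulate", "--output", tempfile(fileext = ".tif"),
             "--structure", "weird"))), 2L)
  # simulate twice with the same seed -> identical TIFF bytes
  t1 <- tempfile(fileext = ".tif"); t2 <- tempfile(fileext = ".tif")
  expect_equal(mt_cli(c("simulate", "--output", t1, "--seed", "7",
                        "--snr", "3")), 0L)
  expect_equal(mt_cli(c("simulate", "--output", t2, "--seed", "7",
                        "--snr", "3")), 0L)
  expect_identical(readBin(t1, "raw", file.size(t1)),
                   readBin(t2, "raw", file.size(t2)))
  # detect on the simulated stack writes a feature JSON
  oj <- tempfile(fileext = ".json")
  expect_equal(mt_cli(c("detect", "--input", t1, "--output", oj)), 0L)
  feats <- read_features_json(oj)
  expect_true(length(feats) >= 1)
  unlink(c(t1, t2, oj))
})

test_that("CLI validate writes a sweep CSV", {
  oc <- tempfile(fileext = ".csv")
  expect_equal(suppressMessages(
    mt_cli(c("validate", "--snr", "5", "--reps", "2", "--seed", "1",
             "--output", oc))), 0L)
  sw <- read.csv(oc)
  expect_true(all(c("snr", "correct_pct", "mean_err_3d_px") %in% names(sw)))
  expect_equal(nrow(sw), 1)
  unlink(oc)
})

test_that("CLI dynamics extracts events from a tracks CSV", {
  tc <- tempfile(fileext = ".csv"); oc <- tempfile(fileext = ".csv")
  tt <- seq(0, 50, by = 5)
  df <- data.frame(track_id = 1, frame = seq_along(tt), time_s = tt,
                   type = "line",
                   length_um = c(seq(1, 2.5, length.out = 6),
                                 seq(2.2, 1.0, length.out = 5)),
                   tip_x = 0, tip_y = 0, tip_z = 0, amplitude = 1)
  write.csv(df, tc, row.names = FALSE)
  expect_equal(mt_cli(c("dynamics", "--input", tc, "--output", oc)), 0L)
  evs <- read.csv(oc)
  expect_gte(nrow(evs), 2)
  expect_setequal(unique(evs$kind), c("polymerization", "depolymerization"))
  unlink(c(tc, oc))
})

test_that("the astral pipeline detects and fits curved filaments", {
  cfg <- simulation_config(structure = "astral", target_snr = 4, seed = 3)
  sim <- simulate_image(cfg)
  guess <- detect_features(sim$image, "astral")
  expect_true("ridge-trace" %in% guess$provenance)
  expect_equal(sum(guess$provenance == "pole"), 2)
  expect_equal(sum(guess$provenance == "spindle"), 1)
  fit <- suppressWarnings(fit_frame(sim$image, "astral", max_features = 4))
  rep <- classify_detections(fit$model, sim$truth)
  expect_gte(rep$n_correct, 1)  # at least one astral filament tip recovered
})
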