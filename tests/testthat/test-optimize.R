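# Non-linear least-squares fitting and f-test feature-count selection.

test_that("residual RSS follows its definition", {
  ph <- noiseless_monopolar(c(50, 170), c(2, 1.3))
  # model rendered from itself: zero residual
  expect_equal(residual_rss(ph$model, ph$stack), 0)
  # uniform image with matching background-only model
  geom <- test_geom(20, 20, 5)
  uni <- image_stack(array(2.5, dim = geom$dim), geom$voxel_size)
  expect_equal(residual_rss(composite_model(2.5, list()), uni), 0)
  # adding 1 to every voxel: RSS = number of voxels
  plus1 <- image_stack(ph$stack$intensities + 1, ph$stack$voxel_size)
  expect_equal(residual_rss(ph$model, plus1), length(plus1$intensities),
               tolerance = 1e-9)
})

test_that("local fit recovers a perturbed spot to sub-centivoxel accuracy", {
  ph <- noiseless_monopolar(numeric(0), numeric(0))
  model <- ph$model
  true_center <- model$features[[1]]$center
  model$features[[1]]$center <- true_center + c(0.05, -0.05, 0.25)  # 0.5 vox
  fit <- fit_local(model, ph$stack, 1)
  got <- fit$model$features[[1]]$center
  expect_lt(max(abs(got[1:2] - true_center[1:2])), 0.001)  # 0.01 XY voxel
  expect_lte(fit$rss, fit$rss_initial + 1e-9)
})

test_that("an already-optimal model is a fixed point of the local fit", {
  ph <- noiseless_monopolar(35, 2)
  fit <- fit_local(ph$model, ph$stack, 2)
  p0 <- feature_params(ph$model$features[[2]])
  p1 <- feature_params(fit$model$features[[2]])
  expect_lt(max(abs(p1 - p0) / pmax(abs(p0), 1)), 1e-7)
})

test_that("local fit recovers a doubled line amplitude within 1 percent", {
  ph <- noiseless_monopolar(80, 2.2)
  model <- ph$model
  true_amp <- model$features[[2]]$amplitude
  model$features[[2]]$amplitude <- 2 * true_amp
  fit <- fit_local(model, ph$stack, 2)
  expect_lt(abs(fit$model$features[[2]]$amplitude - true_amp) / true_amp, 0.01)
})

test_that("global fit recovers two perturbed spots and the background", {
  geom <- test_geom(48, 48, 7)
  s1 <- mt_spot(12, c(1.6, 2.4, 1.75), c(0.2, 0.2, 0.45))
  s2 <- mt_spot(9, c(3.4, 2.2, 1.75), c(0.2, 0.2, 0.45))
  truth <- composite_model(2, list(s1, s2))
  img <- image_stack(render_model(truth, geom), geom$voxel_size)
  pert <- truth
  pert$features[[1]]$center <- s1$center + c(0.05, 0.04, 0.2)
  pert$features[[2]]$center <- s2$center + c(-0.04, 0.05, -0.2)
  pert$background <- 1.4
  fit <- fit_global(pert, img)
  expect_lt(max(abs(fit$model$features[[1]]$center[1:2] - s1$center[1:2])),
            0.001)
  expect_lt(max(abs(fit$model$features[[2]]$center[1:2] - s2$center[1:2])),
            0.001)
  expect_lt(abs(fit$model$background - 2), 0.01)
  # background-only image: B0 converges to the uniform level
  uni <- image_stack(array(3.7, dim = geom$dim), geom$voxel_size)
  fit0 <- fit_global(composite_model(1, list()), uni)
  expect_equal(fit0$model$background, 3.7, tolerance = 1e-6)
})

test_that("noisy single-line fit localizes the endpoint within one XY voxel", {
  cfg <- simulation_config(n_mt_range = c(1, 1), target_snr = 3, seed = 77)
  sim <- simulate_image(cfg)
  guess <- detect_features(sim$image, "monopolar")
  model <- composite_model(guess$background, guess$features,
                           topology = "monopolar")
  for (i in seq_along(model$features)) {
    model <- fit_local(model, sim$image, i)$model
  }
  fit <- fit_global(model, sim$image)
  lines <- Filter(function(f) inherits(f, "mt_line"), fit$model$features)
  expect_gte(length(lines), 1)
  d <- min(vapply(lines, function(l) {
    sqrt(sum((l$end[1:2] - sim$truth$tips[[1]][1:2])^2))
  }, 0))
  expect_lt(d, 0.1)
})

test_that("f-test matches the F-distribution oracle", {
  # equal RSS: F = 0, never significant
  ft0 <- f_test(100, 10, 100, 20, 1000)
  expect_false(ft0$significant)
  expect_equal(ft0$F, 0)
  # worked numbers: F = ((200-100)/10)/(100/1000) = 100
  ft <- f_test(200, 10, 100, 20, 1020)
  expect_equal(ft$F, (100 / 10) / (100 / 1000), tolerance = 1e-12)
  expect_equal(ft$F_crit, qf(0.95, 10, 1000), tolerance = 1e-12)
  expect_equal(ft$p_value, pf(ft$F, 10, 1000, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(ft$significant)
  # alpha -> 1: everything with any improvement becomes significant
  ft1 <- f_test(101, 10, 100, 20, 1020, alpha = 0.999)
  expect_true(ft1$significant)
  # perfect complex fit counts as significant
  expect_true(f_test(10, 5, 0, 15, 100)$significant)
  # degenerate arguments error
  expect_error(f_test(10, 20, 5, 10, 100), "invalid f-test")
})

test_that("RSS never increases across local, global and count stages", {
  set.seed(3)
  for (rep_i in 1:3) {
    k <- sample(1:3, 1)
    ph <- noiseless_monopolar(runif(k, 0, 360) + (0:(k - 1)) * 100,
                              runif(k, 1, 2.5))
    guess <- detect_features(ph$stack, "monopolar")
    model <- composite_model(guess$background, guess$features,
                             topology = "monopolar")
    rss <- residual_rss(model, ph$stack)
    for (i in seq_along(model$features)) {
      fl <- fit_local(model, ph$stack, i)
      expect_lte(fl$rss, rss * (1 + 1e-9))
      model <- fl$model; rss <- fl$rss
    }
    fg <- fit_global(model, ph$stack)
    expect_lte(fg$rss, rss * (1 + 1e-9))
    oc <- optimize_feature_count(fg$model, ph$stack, NULL)
    expect_lte(oc$rss, fg$rss * (1 + 1e-9))
  }
})

test_that("feature-count selection: recovery of dropped and spurious guesses", {
  ph <- noiseless_monopolar(c(20, 140, 260), c(2.2, 1.6, 2.6))
  truth_tips <- ph$tips
  proposer_for <- function(stack, pole) {
    bg0 <- median(stack$intensities)
    function(resid) {
      pp <- preprocess(resid)
      cands <- tryCatch(
        detect_lines_from_pole(pp$mip, resid, pole, background = bg0),
        error = function(e) list())
      c(cands, hotspot_lines(pp$mip, resid, pole, background = bg0))
    }
  }
  # seeded with only 2 of the 3 true lines
  guess <- detect_features(ph$stack, "monopolar")
  model <- composite_model(guess$background, guess$features,
                           topology = "monopolar")
  model$features <- model$features[1:3]  # spot + first two lines
  model$attachments <- model$attachments[1:3]
  for (i in seq_along(model$features)) {
    model <- fit_local(model, ph$stack, i)$model
  }
  fit <- fit_global(model, ph$stack)
  pole <- fit$model$features[[1]]$center
  oc <- optimize_feature_count(fit$model, ph$stack,
                               proposer_for(ph$stack, pole))
  n_lines <- sum(vapply(oc$model$features, inherits, TRUE, "mt_line"))
  expect_equal(n_lines, 3)
  # seeded with 2 extra spurious guesses: count comes back to 3
  guess2 <- detect_features(ph$stack, "monopolar")
  model2 <- composite_model(guess2$background, guess2$features,
                            topology = "monopolar")
  ext <- dim(ph$stack$intensities)[1:2] * 0.1
  for (ang in c(80, 320)) {
    a <- ang * pi / 180
    model2$features[[length(model2$features) + 1]] <-
      mt_line(1, ph$pole, ph$pole + 1.5 * c(cos(a), sin(a), 0),
              c(0.15, 0.15, 0.35))
    model2$attachments <- c(model2$attachments, 1L)
  }
  for (i in seq_along(model2$features)) {
    model2 <- fit_local(model2, ph$stack, i)$model
  }
  fit2 <- fit_global(model2, ph$stack)
  oc2 <- optimize_feature_count(fit2$model, ph$stack,
                                proposer_for(ph$stack, pole))
  n_lines2 <- sum(vapply(oc2$model$features, inherits, TRUE, "mt_line"))
  expect_equal(n_lines2, 3)
  # pure background: no lines retained
  geom <- test_geom(40, 40, 5)
  uni <- image_stack(array(2, dim = geom$dim), geom$voxel_size)
  base <- composite_model(2, list(mt_spot(1, c(2, 2, 1.25), c(0.2, 0.2, 0.45))))
  oc0 <- optimize_feature_count(base, uni,
                                proposer_for(uni, c(2, 2, 1.25)))
  expect_equal(sum(vapply(oc0$model$features, inherits, TRUE, "mt_line")), 0)
})

test_that("fit uncertainties are finite and scale with noise", {
  cfg1 <- simulation_config(n_mt_range = c(1, 1), target_snr = 5, seed = 11)
  sim1 <- simulate_image(cfg1)
  m <- sim1$truth$model
  f1 <- fit_global(m, sim1$image)
  expect_true(all(is.finite(f1$uncertainties)))
  cfg2 <- cfg1; cfg2$target_snr <- 1
  sim2 <- simulate_image(cfg2)
  f2 <- fit_global(sim2$truth$model, sim2$image)
  # lower SNR -> larger parameter uncertainties (compare amplitudes' se sum)
  expect_gt(sum(f2$uncertainties), sum(f1$uncertainties))
})
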