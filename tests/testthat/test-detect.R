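# Detection: preprocessing, pole finding, angular scanning, bipolar
# endpoints, curve tracing. Oracles are noiseless rendered phantoms.

test_that("preprocessing leaves constant images unchanged and reduces noise variance", {
  geom <- test_geom(32, 32, 5)
  const <- image_stack(array(4, dim = geom$dim), geom$voxel_size)
  pp <- preprocess(const)
  expect_equal(pp$filtered$intensities, const$intensities, tolerance = 1e-12)
  expect_true(all(abs(pp$mip - 4) < 1e-12))
  # single bright voxel: MIP max at its (x, y)
  a <- array(0, dim = geom$dim); a[10, 20, 3] <- 100
  pp2 <- preprocess(image_stack(a, geom$voxel_size))
  expect_equal(as.integer(arrayInd(which.max(pp2$mip), dim(pp2$mip))),
               c(10L, 20L))
  # smoothing reduces the variance of white noise
  set.seed(1)
  noisy <- image_stack(array(rnorm(prod(geom$dim), 10, 2), dim = geom$dim),
                       geom$voxel_size)
  pp3 <- preprocess(noisy)
  expect_lt(var(as.vector(pp3$filtered$intensities)),
            var(as.vector(noisy$intensities)))
})

test_that("pole finding is sub-voxel accurate on noiseless phantoms and fails cleanly", {
  ph <- noiseless_monopolar(c(30, 200), c(2, 1.2))
  pp <- preprocess(ph$stack)
  pole <- find_pole(pp$mip, ph$stack)
  expect_lt(sqrt(sum((pole$position[1:2] - ph$pole[1:2])^2)), 0.1)
  expect_lt(abs(pole$position[3] - ph$pole[3]), 0.5)
  # flat image: no-pole error
  flat <- image_stack(array(1, dim = c(16, 16, 3)))
  expect_error(find_pole(max_intensity_projection(flat), flat), "no-pole")
})

test_that("angular intensity is flat for a radially symmetric blob", {
  geom <- test_geom(41, 41, 5)
  sp <- mt_spot(10, c(2.05, 2.05, 1.25), c(0.5, 0.5, 0.6))
  stack <- image_stack(render_spot(sp, geom) + 1, geom$voxel_size)
  pp <- preprocess(stack)
  ai <- angular_intensity(pp$mip, c(2.05, 2.05), voxel_size = c(0.1, 0.1))
  # constant within a small relative band (border clipping aside)
  expect_lt(diff(range(ai$intensity)) / max(abs(ai$intensity)), 0.05)
  # a pole outside the image errors
  expect_error(angular_intensity(pp$mip, c(10, 10)), "invalid-pole")
})

test_that("angular intensity peaks at the microtubule angle and rotates with the image", {
  ph <- noiseless_monopolar(60, 2)
  pp <- preprocess(ph$stack)
  ai <- angular_intensity(pp$mip, ph$pole)
  phi_hat <- ai$phi[which.max(ai$intensity)]
  expect_lt(abs(phi_hat - 60 * pi / 180), 3 * pi / 180)
  # rotating the stack by 90 degrees rotates the peak by pi/2
  rot <- ph$stack
  rot$intensities <- aperm(rot$intensities, c(2, 1, 3))[, dim(rot$intensities)[1]:1, ]
  ppr <- preprocess(image_stack(rot$intensities, rot$voxel_size))
  air <- angular_intensity(ppr$mip,
                           c(ph$pole[2],
                             dim(rot$intensities)[2] * 0.1 - ph$pole[1]))
  phi_rot <- air$phi[which.max(air$intensity)]
  expect_lt(abs(((phi_rot - phi_hat + pi / 2 + pi) %% (2 * pi)) - pi),
            4 * pi / 180)
})

test_that("line detection recovers exactly the microtubules above the length cutoff", {
  angles <- c(15, 110, 245)
  lens <- c(2.2, 1.3, 2.8)
  ph <- noiseless_monopolar(angles, lens)
  pp <- preprocess(ph$stack)
  pole <- find_pole(pp$mip, ph$stack)
  guesses <- detect_lines_from_pole(pp$mip, ph$stack, pole$position)
  expect_length(guesses, 3)
  got <- sort(vapply(guesses, function(g) {
    (atan2(g$end[2] - g$start[2], g$end[1] - g$start[1]) * 180 / pi) %% 360
  }, 0))
  # guesses initialize the optimizer; a few degrees of bias (pole-estimate
  # coupling between lines) is refined away by the fit
  expect_true(all(abs(sort(got) - sort(angles)) < 5))
  # spot-only phantom: empty list
  ph0 <- noiseless_monopolar(numeric(0), numeric(0))
  pp0 <- preprocess(ph0$stack)
  pole0 <- find_pole(pp0$mip, ph0$stack)
  expect_length(detect_lines_from_pole(pp0$mip, ph0$stack, pole0$position), 0)
  # a microtubule below the minimum length cutoff is not reported
  ph_s <- noiseless_monopolar(80, 1.5)
  pp_s <- preprocess(ph_s$stack)
  cfg_s <- detection_config(min_length = 2)
  pole_s <- find_pole(pp_s$mip, ph_s$stack, cfg_s)
  expect_length(detect_lines_from_pole(pp_s$mip, ph_s$stack, pole_s$position,
                                       cfg_s), 0)
})

test_that("detected line guesses always satisfy the length cutoffs", {
  set.seed(17)
  cfgd <- detection_config()
  for (rep_i in 1:10) {
    k <- sample(0:4, 1)
    ph <- noiseless_monopolar(runif(k, 0, 360), runif(k, 0.6, 2.8))
    pp <- preprocess(ph$stack)
    pole <- tryCatch(find_pole(pp$mip, ph$stack), error = function(e) NULL)
    if (is.null(pole)) next
    guesses <- detect_lines_from_pole(pp$mip, ph$stack, pole$position)
    for (g in guesses) {
      L <- feature_length(g)
      expect_gte(L, cfgd$min_length)
      ext <- dim(ph$stack$intensities)[1:2] * 0.1
      expect_lte(L, sqrt(sum(ext^2)))
      expect_true(all(g$start[1:2] >= 0 & g$start[1:2] <= ext))
    }
  }
})

test_that("detection is deterministic", {
  ph <- noiseless_monopolar(c(40, 190), c(2, 1.6))
  g1 <- detect_features(ph$stack, "monopolar")
  g2 <- detect_features(ph$stack, "monopolar")
  expect_identical(g1$features, g2$features)
})

test_that("round-trip: detected line count equals true count over seeded phantoms", {
  set.seed(99)
  ok <- 0; total <- 0
  for (rep_i in 1:50) {
    k <- sample(1:4, 1)
    # well-separated angles so peaks are resolvable
    base <- runif(1, 0, 90)
    angles <- (base + (0:(k - 1)) * (360 / k) + runif(k, -20, 20)) %% 360
    lens <- runif(k, 1.2, 2.8)
    ph <- noiseless_monopolar(angles, lens)
    g <- detect_features(ph$stack, "monopolar")
    n_lines <- sum(vapply(g$features, inherits, TRUE, "mt_line"))
    total <- total + 1
    if (n_lines == k) ok <- ok + 1
  }
  expect_gte(ok / total, 0.9)
})

test_that("bipolar detection finds the spindle endpoints and orientation", {
  geom <- test_geom(64, 64, 7)
  ext <- geom$dim * geom$voxel_size
  ctr <- ext / 2
  build_bipolar <- function(angle_deg, sep = 3) {
    ax <- c(cos(angle_deg * pi / 180), sin(angle_deg * pi / 180), 0)
    p1 <- ctr - ax * sep / 2; p2 <- ctr + ax * sep / 2
    sl <- mt_line(1, p1, p2, c(0.15, 0.15, 0.35))
    sl$amplitude <- 8 / max(render_line(sl, geom))
    feats <- list(mt_spot(15, p1, c(0.2, 0.2, 0.45)),
                  mt_spot(15, p2, c(0.2, 0.2, 0.45)), sl)
    m <- composite_model(3, feats, topology = "bipolar")
    list(stack = image_stack(render_model(m, geom), geom$voxel_size),
         p1 = p1, p2 = p2)
  }
  bp <- build_bipolar(25)
  pp <- preprocess(bp$stack)
  det <- detect_bipolar(pp$mip, bp$stack)
  sep_hat <- sqrt(sum((det$spots[[2]]$center[1:2] - det$spots[[1]]$center[1:2])^2))
  expect_lt(abs(sep_hat - 3), 0.2)
  # orientation rotates with the phantom
  bp2 <- build_bipolar(115)
  pp2 <- preprocess(bp2$stack)
  det2 <- detect_bipolar(pp2$mip, bp2$stack)
  d1 <- det$spindle$end - det$spindle$start
  d2 <- det2$spindle$end - det2$spindle$start
  a1 <- atan2(d1[2], d1[1]) * 180 / pi
  a2 <- atan2(d2[2], d2[1]) * 180 / pi
  expect_lt(abs((((a2 - a1) - 90 + 180) %% 180) - 0) %% 180, 6)
  # monopolar phantom: degenerate endpoints -> no-spindle error
  ph <- noiseless_monopolar(numeric(0), numeric(0))
  ppm <- preprocess(ph$stack)
  expect_error(detect_bipolar(ppm$mip, ph$stack), "no-spindle")
})

test_that("curve tracing follows straight and bent filaments", {
  geom <- test_geom(64, 64, 7)
  # straight filament: traced path collinear with truth
  ln <- mt_line(1, c(1.2, 3.2, 1.75), c(5, 3.2, 1.75), c(0.15, 0.15, 0.35))
  ln$amplitude <- 8 / max(render_line(ln, geom))
  stack <- image_stack(render_line(ln, geom) + 2, geom$voxel_size)
  pp <- preprocess(stack)
  tc <- trace_curve(pp$mip, stack, c(1.3, 3.2), c(1, 0))
  expect_gt(nrow(tc$path), 15)
  expect_lt(max(abs(tc$path[, 2] - 3.2)), 0.1)   # < 1 voxel off-axis
  # constant-curvature filament: recovered mean curvature within 15%
  k_true <- 0.5
  cc <- list(k0 = k_true, w = 1, p = c(0, 0), q = c(0, 0))
  cv <- mt_curve(1, c(1.2, 2.2, 1.75), c(1, 0, 0), cc, 3, c(0.15, 0.15, 0.35))
  cv$amplitude <- 8 / max(render_curve(cv, geom))
  stk2 <- image_stack(render_curve(cv, geom) + 2, geom$voxel_size)
  pp2 <- preprocess(stk2)
  tc2 <- trace_curve(pp2$mip, stk2, c(1.3, 2.25), c(1, 0))
  expect_false(is.null(tc2$curve))
  K_mean <- mean(abs(sampled_curvature(tc2$path)))
  expect_lt(abs(K_mean - k_true) / k_true, 0.15)
  # start in pure background: empty-path error
  flat <- image_stack(array(2, dim = geom$dim), geom$voxel_size)
  ppf <- preprocess(flat)
  expect_error(trace_curve(ppf$mip, flat, c(1, 1), c(1, 0)), "empty-path")
})
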