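# Feature models: Gaussian renders, curve geometry engine, parameter packing.

test_that("spot render matches the point-Gaussian model", {
  geom <- test_geom()
  # center placed exactly on a voxel center
  sp <- mt_spot(2, c(2.05, 2.05, 1.75), c(0.2, 0.2, 0.4))
  r <- render_spot(sp, geom)
  expect_equal(r[21, 21, 4], 2)                         # peak = amplitude
  sp1 <- mt_spot(1, c(1.05, 2.05, 1.75), c(1, 0.2, 0.4))
  r1 <- render_spot(sp1, geom)
  expect_equal(r1[21, 21, 4], exp(-1), tolerance = 1e-12)  # one-sigma offset
  # integral over a fine grid equals A pi^(3/2) sx sy sz (no normalization)
  g2 <- test_geom(150, 150, 100, c(0.02, 0.02, 0.05))
  sp2 <- mt_spot(1.5, c(1.5, 1.5, 2.5), c(0.3, 0.25, 0.5))
  got <- sum(render_spot(sp2, g2)) * prod(g2$voxel_size)
  expect_rel_equal(got, 1.5 * pi^1.5 * 0.3 * 0.25 * 0.5, 0.01)
})

test_that("spot render rejects non-positive widths", {
  expect_error(mt_spot(1, c(1, 1, 1), c(0, 0.2, 0.4)), "invalid parameter")
  expect_error(mt_spot(1, c(1, 1, 1), c(0.1, -0.2, 0.4)), "invalid parameter")
  expect_error(mt_spot(-2, c(1, 1, 1), c(0.1, 0.2, 0.4)), "invalid parameter")
})

test_that("line render agrees with a fine-step numerical integration oracle", {
  geom <- test_geom()
  p0 <- c(1, 1.3, 1.5); p1 <- c(3, 2.2, 2.1)
  sg <- c(0.15, 0.18, 0.4); A <- 3
  ln <- mt_line(A, p0, p1, sg)
  r <- render_line(ln, geom)
  # trapezoid oracle at a handful of probe voxels
  tt <- seq(0, 1, length.out = 1e5)
  for (probe in list(c(15, 18, 4), c(20, 17, 4), c(11, 14, 3))) {
    xp <- (probe - 0.5) * geom$voxel_size
    pos <- outer(tt, p1 - p0) + rep(p0, each = length(tt))
    f <- A * exp(-((xp[1] - pos[, 1]) / sg[1])^2 -
                   ((xp[2] - pos[, 2]) / sg[2])^2 -
                   ((xp[3] - pos[, 3]) / sg[3])^2)
    orc <- pracma::trapz(tt, f)
    expect_rel_equal(r[probe[1], probe[2], probe[3]], orc, 1e-8)
  }
})

test_that("degenerate line (start == end) renders identically to a spot", {
  geom <- test_geom()
  sp <- mt_spot(2, c(2.05, 2.05, 1.75), c(0.2, 0.2, 0.4))
  ld <- mt_line(2, c(2.05, 2.05, 1.75), c(2.05, 2.05, 1.75), c(0.2, 0.2, 0.4))
  expect_equal(render_line(ld, geom), render_spot(sp, geom))
})

test_that("erf and quadrature line renders agree on randomized lines", {
  geom <- test_geom()
  set.seed(11)
  worst <- 0
  for (i in 1:20) {
    p0 <- c(runif(2, 0.5, 3.5), runif(1, 0.8, 2.7))
    p1 <- c(runif(2, 0.5, 3.5), runif(1, 0.8, 2.7))
    sg <- c(runif(1, 0.1, 0.25), runif(1, 0.1, 0.25), runif(1, 0.3, 0.5))
    A <- runif(1, 0.5, 5)
    ln <- mt_line(A, p0, p1, sg)
    re <- render_line(ln, geom, method = "erf")
    rq <- render_line(ln, geom, method = "quadrature")
    worst <- max(worst, max(abs(re - rq)) / max(re))
  }
  expect_lt(worst, 1e-6)
})

test_that("local curvature reproduces analytic cases", {
  # straight line x = t, y = 0
  expect_equal(local_curvature(c(0, 1), c(0, 0), 0.3), 0)
  # circle of radius R: |K| = 1/R (polynomial approximation not needed:
  # use the sampled-path route)
  R <- 2
  tt <- seq(0, pi / 2, length.out = 2001)
  xy <- cbind(R * cos(tt), R * sin(tt))
  K <- sampled_curvature(xy)
  expect_equal(mean(abs(K)), 1 / R, tolerance = 1e-4)
  # parabola x = t, y = t^2 at t = 0: K = 2
  expect_equal(local_curvature(c(0, 1), c(0, 0, 1), 0), 2)
  # vanishing XY speed errors out
  expect_error(local_curvature(c(0, 0), c(0, 0), 0.5), "degenerate tangent")
})

test_that("Fourier curvature fit recovers known coefficients", {
  tt <- seq(0, 1, length.out = 60)
  # constant curvature: k0 recovered, higher terms vanish
  fit0 <- fit_curvature_fourier(tt, rep(0.7, 60), N = 2)
  expect_equal(fit0$k0, 0.7, tolerance = 1e-8)
  expect_true(all(abs(c(fit0$p, fit0$q)) < 1e-6))
  # noiseless round trip at N = 2
  truth <- list(k0 = 0.3, w = 4.2, p = c(0.25, -0.1), q = c(-0.15, 0.2))
  K <- truth$k0 +
    truth$p[1] * cos(truth$w * tt) + truth$q[1] * sin(truth$w * tt) +
    truth$p[2] * cos(2 * truth$w * tt) + truth$q[2] * sin(2 * truth$w * tt)
  fit <- fit_curvature_fourier(tt, K, N = 2)
  expect_equal(fit$w, truth$w, tolerance = 1e-5)
  expect_equal(fit$k0, truth$k0, tolerance = 1e-6)
  expect_equal(fit$p, truth$p, tolerance = 1e-6)
  expect_equal(fit$q, truth$q, tolerance = 1e-6)
  # nested models: N = 1 fit of an N = 2 signal has a larger residual
  fit1 <- fit_curvature_fourier(tt, K, N = 1)
  expect_gt(fit1$rss, fit$rss)
  # under-determined input errors out
  expect_error(fit_curvature_fourier(tt[1:4], K[1:4], N = 2),
               "under-determined")
})

test_that("curve reconstruction: straight limit, circle, convergence", {
  zero_k <- list(k0 = 0, w = 1, p = c(0, 0), q = c(0, 0))
  pts <- reconstruct_curve(c(1, 2, 3), c(1, 0, 0), zero_k, 2, 0.001)
  expect_equal(pts[1, ], c(1, 2, 3))                      # starts at origin
  expect_equal(pts[nrow(pts), ], c(3, 2, 3), tolerance = 1e-9)
  expect_rel_equal(path_length(pts), 2, 1e-9)
  # constant curvature: circular arc, endpoint within 1e-3 L of analytic
  k <- 0.5; L <- 3
  const_k <- list(k0 = k, w = 1, p = c(0, 0), q = c(0, 0))
  pts <- reconstruct_curve(c(0, 0, 0), c(1, 0, 0), const_k, L, L / 1e4)
  endp <- pts[nrow(pts), ]
  anal <- c(sin(k * L) / k, (1 - cos(k * L)) / k, 0)
  expect_lt(sqrt(sum((endp - anal)^2)), 1e-3 * L)
  # halving dt shrinks the endpoint error (first-order convergence)
  e_for <- function(dt) {
    p <- reconstruct_curve(c(0, 0, 0), c(1, 0, 0), const_k, L, dt)
    sqrt(sum((p[nrow(p), ] - anal)^2))
  }
  expect_lt(e_for(L / 2000), e_for(L / 1000))
  expect_lt(e_for(L / 4000), e_for(L / 2000))
  # step-size validation
  expect_error(reconstruct_curve(c(0, 0, 0), c(1, 0, 0), const_k, 1, 2),
               "step too large")
})

test_that("curvature of a reconstructed curve matches the input model", {
  truth <- list(k0 = 0.4, w = 3, p = c(0.2, -0.1), q = c(0.1, 0.15))
  L <- 2.5
  pts <- reconstruct_curve(c(0, 0, 0), c(1, 0.2, 0), truth, L, 1e-4)
  K_fd <- sampled_curvature(pts[, 1:2])
  tt <- seq(0, 1, length.out = nrow(pts))[-c(1, nrow(pts))]
  K_in <- truth$k0 +
    truth$p[1] * cos(truth$w * tt) + truth$q[1] * sin(truth$w * tt) +
    truth$p[2] * cos(2 * truth$w * tt) + truth$q[2] * sin(2 * truth$w * tt)
  expect_lt(max(abs(K_fd - K_in)) / max(abs(K_in)), 0.01)
})

test_that("zero-curvature curve renders like the equivalent straight line", {
  geom <- test_geom()
  p0 <- c(1, 1.3, 1.5); p1 <- c(3, 2.2, 2.1)
  sg <- c(0.15, 0.18, 0.4); A <- 3
  u <- p1 - p0; L <- sqrt(sum(u^2))
  cv <- mt_curve(A, p0, u, list(k0 = 0, w = 1, p = c(0, 0), q = c(0, 0)),
                 L, sg)
  rl <- render_line(mt_line(A, p0, p1, sg), geom)
  rc <- render_curve(cv, geom)
  expect_lt(max(abs(rc - rl)), 1e-6 * A)
})

test_that("curve render converges in quadrature order and is linear in A", {
  geom <- test_geom()
  cc <- list(k0 = 0.5, w = 3, p = c(0.2, 0.1), q = c(-0.1, 0.05))
  cv <- mt_curve(2, c(1, 1, 1.75), c(1, 0.3, 0), cc, 2.5, c(0.15, 0.15, 0.35))
  r20 <- render_curve(cv, geom, quad_order = 20)
  r40 <- render_curve(cv, geom, quad_order = 40)
  expect_lt(max(abs(r20 - r40)) / max(r40), 1e-6)
  cv2 <- cv; cv2$amplitude <- 4
  expect_equal(render_curve(cv2, geom, quad_order = 20), 2 * r20,
               tolerance = 1e-12)
})

test_that("composite model renders additively and order-independently", {
  geom <- test_geom()
  s <- mt_spot(5, c(2, 2, 1.75), c(0.2, 0.2, 0.45))
  l <- mt_line(3, c(2, 2, 1.75), c(3.5, 2.5, 1.75), c(0.15, 0.15, 0.35))
  empty <- composite_model(1.5, list())
  expect_true(all(render_model(empty, geom) == 1.5))
  one <- composite_model(0, list(s))
  expect_equal(render_model(one, geom), render_spot(s, geom))
  ab <- composite_model(2, list(s, l))
  ba <- composite_model(2, list(l, s))
  expect_equal(render_model(ab, geom), render_model(ba, geom))
  expect_equal(render_model(ab, geom),
               2 + render_spot(s, geom) + render_line(l, geom))
})

test_that("free-parameter counts are 7 / 10 / 15", {
  s <- mt_spot(1, c(1, 1, 1), c(0.2, 0.2, 0.4))
  l <- mt_line(1, c(1, 1, 1), c(2, 2, 1), c(0.2, 0.2, 0.4))
  cv <- mt_curve(1, c(1, 1, 1), c(1, 0, 0),
                 list(k0 = 0.1, w = 2, p = c(0, 0), q = c(0, 0)), 1.5,
                 c(0.2, 0.2, 0.4))
  expect_length(feature_params(s), 7)
  expect_length(feature_params(l), 10)
  expect_length(feature_params(cv), 15)
  # packing round trip
  for (f in list(s, l, cv)) {
    p <- feature_params(f)
    f2 <- set_feature_params(f, as.numeric(p) * 1)
    expect_equal(feature_params(f2), p)
  }
})

test_that("rendering is translation-equivariant on the voxel lattice", {
  geom <- test_geom()
  shift <- c(0.3, -0.2, 0.5)  # 3, -2, 1 voxels
  l <- mt_line(3, c(1.5, 2, 1.25), c(3, 2.8, 1.75), c(0.15, 0.15, 0.35))
  l2 <- l; l2$start <- l$start + shift; l2$end <- l$end + shift
  r1 <- render_line(l, geom)
  r2 <- render_line(l2, geom)
  expect_equal(r2[9:34, 4:25, 2:7], r1[6:31, 6:27, 1:6], tolerance = 1e-12)
})

test_that("feature JSON serialization round-trips exactly", {
  s <- mt_spot(1.5, c(1.1, 2.2, 1.3), c(0.21, 0.19, 0.42))
  l <- mt_line(2.5, c(1, 1, 1), c(2.7, 2.1, 1.4), c(0.15, 0.16, 0.35))
  cv <- mt_curve(0.8, c(1, 1, 1), c(1, 0.4, 0.1),
                 list(k0 = 0.3, w = 2.5, p = c(0.1, -0.2), q = c(0, 0.05)),
                 1.7, c(0.15, 0.15, 0.35))
  m <- composite_model(2.25, list(s, l, cv), topology = "astral",
                       attachments = c(NA, 1L, 1L))
  tf <- tempfile(fileext = ".json")
  write_features_json(m, tf)
  m2 <- read_features_json(tf)
  expect_equal(m2$background, m$background)
  expect_equal(m2$topology, m$topology)
  expect_equal(m2$features, m$features)
  unlink(tf)
})
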