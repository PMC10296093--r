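# Shared fixtures: small geometries and noiseless phantom builders used
# across the test files. All fixtures are generated in code.

test_geom <- function(nx = 40, ny = 40, nz = 7, vox = c(0.1, 0.1, 0.5)) {
  list(dim = c(nx, ny, nz), voxel_size = vox)
}

# Noiseless monopolar phantom: pole spot + K lines on a uniform background.
# Returns the stack, the model, and the true line features.
noiseless_monopolar <- function(angles_deg, lengths,
                                geom = test_geom(64, 64, 7),
                                background = 3, mt_amp = 5, spot_amp = 15,
                                sigma_mt = c(0.15, 0.15, 0.35),
                                sigma_spot = c(0.2, 0.2, 0.45)) {
  ext <- geom$dim * geom$voxel_size
  pole <- c(ext[1] / 2, ext[2] / 2, ext[3] / 2)
  feats <- list(mt_spot(spot_amp, pole, sigma_spot))
  for (i in seq_along(angles_deg)) {
    a <- angles_deg[i] * pi / 180
    endp <- pole + lengths[i] * c(cos(a), sin(a), 0)
    ln <- mt_line(1, pole, endp, sigma_mt)
    mx <- max(render_line(ln, geom))
    ln$amplitude <- mt_amp / mx
    feats[[length(feats) + 1]] <- ln
  }
  model <- composite_model(background, feats, topology = "monopolar")
  stack <- image_stack(render_model(model, geom), geom$voxel_size)
  list(stack = stack, model = model, pole = pole,
       lines = feats[-1],
       tips = lapply(feats[-1], feature_tip))
}

# A mock ground-truth object usable with classify_detections/compute_snr.
as_mock_truth <- function(phantom) {
  structure(list(
    model = phantom$model,
    microtubules = phantom$lines,
    tips = phantom$tips,
    lengths = vapply(phantom$lines, feature_length, 0),
    poles = list(phantom$pole),
    background_rate = phantom$model$background,
    seed = 0L,
    config = list(structure = "monopolar")), class = "ground_truth")
}

expect_rel_equal <- function(actual, expected, tol = 1e-6) {
  expect_lt(abs(actual - expected) / max(abs(expected), .Machine$double.eps),
            tol)
}
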