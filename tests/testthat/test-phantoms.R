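test_that("phantom generation is bit-identical under a fixed seed", {
  a <- generate_phantom(phantom_spec(seed = 42))
  b <- generate_phantom(phantom_spec(seed = 42))
  expect_identical(a$frame, b$frame)
  expect_identical(a$mask, b$mask)
  d <- generate_phantom(phantom_spec(seed = 43))
  expect_false(identical(a$frame, d$frame))
  expect_identical(a$mask, d$mask)  # geometry, not noise, defines the truth
})

test_that("echo structure: hypoechoic interior, hyperechoic rim, exact threshold recovery", {
  sp <- phantom_spec(semi_axes = c(20, 10), blur_sigma = 0,
                     speckle_shape = Inf)
  ph <- generate_phantom(sp)
  u2_rim <- nervetrace:::ellipse_u2(sp$frame_size, sp$center,
                                    sp$semi_axes + sp$rim_thickness,
                                    sp$rotation)
  rim_band <- u2_rim <= 1 & ph$mask == 0
  expect_lt(mean(ph$frame[ph$mask == 1]), mean(ph$frame[rim_band]))
  thr <- 255 * (sp$interior_level + sp$background_level) / 2
  expect_identical(matrix(as.integer(ph$frame < thr), 300, 300), ph$mask)
})

test_that("mask equals exhaustive pixel-centre-in-ellipse enumeration", {
  sp <- phantom_spec(semi_axes = c(20, 10), rotation = 0)
  ph <- generate_phantom(sp)
  # independent scalar-loop oracle over a window around the ellipse
  cnt <- 0L
  for (r in 100:200) {
    for (cc in 100:200) {
      dx <- cc - sp$center[2]; dy <- r - sp$center[1]
      inside <- (dx / 20)^2 + (dy / 10)^2 <= 1
      cnt <- cnt + as.integer(inside)
      expect_identical(ph$mask[r, cc], as.integer(inside))
    }
  }
  expect_equal(sum(ph$mask), cnt)
  expect_lt(abs(sum(ph$mask) - pi * 20 * 10) / (pi * 20 * 10), 0.02)
})

test_that("an ellipse that does not fit the frame is rejected", {
  expect_error(phantom_spec(semi_axes = c(160, 80)),
               class = "nervetrace_sizing_error")
  expect_error(phantom_spec(center = c(10, 150), semi_axes = c(30, 20)),
               class = "nervetrace_sizing_error")
  expect_error(phantom_spec(interior_level = 0.5, background_level = 0.4),
               class = "nervetrace_config_error")
})

test_that("dataset generation respects size, frame dims, determinism and strata", {
  ds <- generate_dataset(20, phantom_ranges(), seed = 3)
  expect_length(ds, 20)
  expect_true(all(vapply(ds, function(el) all(dim(el$frame) == c(300, 300)),
                         logical(1))))
  ds2 <- generate_dataset(20, phantom_ranges(), seed = 3)
  expect_identical(lapply(ds, `[[`, "frame"), lapply(ds2, `[[`, "frame"))

  hard <- generate_dataset(8, phantom_ranges(hard_fraction = 1), seed = 4)
  for (el in hard) {
    expect_gte(el$spec$semi_axes[1] / el$spec$semi_axes[2], 2.5)
    expect_gte(el$spec$blur_sigma, 2)
    expect_identical(el$stratum, "hard")
  }
})

test_that("degenerate single-point ranges pin every sampled parameter; invalid ranges error", {
  rg <- phantom_ranges(semi_major = c(30, 30), aspect = c(2, 2),
                       rotation = c(10, 10), rim_thickness = c(3, 3),
                       interior_level = c(0.2, 0.2),
                       background_level = c(0.5, 0.5),
                       rim_level = c(0.8, 0.8), blur_sigma = c(1, 1),
                       speckle_shape = c(8, 8), center_jitter = 0,
                       hard_fraction = 0)
  el <- generate_dataset(1, rg, seed = 1)[[1]]
  expect_equal(el$spec$semi_axes, c(30, 15))
  expect_equal(el$spec$rotation, 10)
  expect_equal(el$spec$blur_sigma, 1)
  expect_error(phantom_ranges(semi_major = c(40, 20)),
               class = "nervetrace_config_error")
})

test_that("ground-truth mask morphometry matches the generating ellipse", {
  ds <- generate_dataset(6, phantom_ranges(), seed = 12)
  for (el in ds) {
    true_area <- pi * prod(el$spec$semi_axes)
    expect_lt(abs(measure_mask(el$mask)$mncsa - true_area) / true_area, 0.03)
  }
})

test_that("annotation perturbation: identity at zero, bounded at magnitude 2, connected", {
  disc <- make_disc(20)
  expect_identical(perturb_annotation(disc, 0, 1), disc)
  for (s in 1:100) {
    pm <- perturb_annotation(disc, 2, s)
    expect_gt(seg_metrics(pm, disc)$iou, 0.7)
  }
  for (s in 1:10) {
    pm <- perturb_annotation(disc, 4, s)
    expect_lte(max(nervetrace:::label_components8(pm)), 1L)
  }
})

test_that("stronger outline blur weakens the rim intensity gradient", {
  rim_grad <- function(blur, seed) {
    sp <- phantom_spec(frame_size = c(96, 96), center = c(48, 48),
                       semi_axes = c(20, 12), blur_sigma = blur,
                       speckle_shape = 30, seed = seed)
    ph <- generate_phantom(sp)
    u2 <- nervetrace:::ellipse_u2(sp$frame_size, sp$center, sp$semi_axes,
                                  sp$rotation)
    band <- abs(sqrt(u2) - 1) < 0.25
    g <- abs(diff(ph$frame))
    mean(g[band[-1, ] | band[-nrow(band), ]])
  }
  grads <- vapply(c(0, 1, 2.5), function(b)
    mean(vapply(1:20, function(s) rim_grad(b, s), numeric(1))), numeric(1))
  expect_true(all(diff(grads) < 0))
})
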