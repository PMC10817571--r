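test_that("principal component keeps the largest blob; count checked against igraph", {
  m <- matrix(0L, 40, 40)
  m[5:14, 5:14] <- 1L           # 100 px
  m[30:34, 30:35] <- 1L         # 30 px
  out <- principal_component_mask(m)
  expect_equal(sum(out), 100)
  expect_true(all(out[5:14, 5:14] == 1L))

  single <- make_disc(8)
  expect_identical(principal_component_mask(single), single)

  set.seed(17)
  for (i in 1:50) {
    bm <- random_blob_mask(48, sample(1:4, 1))
    pc <- principal_component_mask(bm)
    expect_lte(oracle_n_components(pc), 1L)
    # labelling itself agrees with the independent graph-based count
    expect_equal(max(nervetrace:::label_components8(bm)),
                 oracle_n_components(bm))
  }
})

test_that("contour tracing: 3x3 square, boundary membership, flip symmetry", {
  sq <- matrix(0L, 5, 5); sq[2:4, 2:4] <- 1L
  ct <- trace_contour(sq)
  expect_equal(nrow(ct), 8)
  expect_true(all(ct %in% 2:4))

  set.seed(18)
  for (i in 1:10) {
    sp <- phantom_spec(frame_size = c(72, 72), center = c(36, 36),
                       semi_axes = c(runif(1, 10, 18), runif(1, 5, 9)),
                       rotation = runif(1, -40, 40))
    m <- generate_phantom(sp)$mask
    ct <- trace_contour(m)
    expect_false(any(duplicated(paste(ct[, 1], ct[, 2]))))
    for (k in seq_len(nrow(ct))) {
      r <- ct[k, 1]; cc <- ct[k, 2]
      expect_equal(m[r, cc], 1L)
      nb <- m[max(1, r - 1):min(nrow(m), r + 1),
              max(1, cc - 1):min(ncol(m), cc + 1)]
      expect_true(any(nb == 0L) || r %in% c(1, nrow(m)) || cc %in% c(1, ncol(m)))
    }
    fl <- trace_contour(nervetrace:::flip_matrix(m, "v"))
    fl_back <- cbind(nrow(m) + 1L - fl[, 1], fl[, 2])
    expect_setequal(paste(fl_back[, 1], fl_back[, 2]), paste(ct[, 1], ct[, 2]))
  }
  expect_error(trace_contour(matrix(0L, 4, 4)), class = "nervetrace_empty_mask")
  tiny <- matrix(0L, 4, 4); tiny[2, 2] <- 1L
  expect_error(trace_contour(tiny), class = "nervetrace_degenerate_shape")
})

test_that("axis-aligned 10x20 rectangle yields the closed-form measures", {
  m <- matrix(0L, 30, 40); m[11:20, 11:30] <- 1L
  mm <- measure_mask(m)
  expect_equal(mm$mncsa, 200)
  expect_equal(mm$circumference, 56)
  expect_equal(mm$d1, 19)
  expect_equal(mm$d2, 9)
  expect_equal(mm$rect_angle, 0, tolerance = 1e-9)
  # half-pixel-pad mode restores area-consistent sizing
  mp <- measure_mask(m, pad = TRUE)
  expect_equal(mp$d1, 20); expect_equal(mp$d2, 10)
  expect_gte(mp$d1 * mp$d2, mp$mncsa)
  # physical calibration scales lengths linearly, areas quadratically
  mm2 <- measure_mask(m, mm_per_pixel = 0.1)
  expect_equal(mm2$mncsa, 2); expect_equal(mm2$d1, 1.9)
  expect_identical(mm2$units, "mm")
})

test_that("a 30-px-radius disc measures like a circle", {
  d <- make_disc(30)
  mm <- measure_mask(d)
  expect_lt(abs(mm$mncsa - pi * 900) / (pi * 900), 0.02)
  expect_lt(abs(mm$d1 - mm$d2) / mm$d1, 0.03)
  expect_gte(mm$circumference^2, 4 * pi * mm$mncsa * 0.95)
})

test_that("minimum-area rectangle matches a 0.01-degree brute-force sweep", {
  th <- 30 * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts <- cbind(c(0, 4, 4, 0), c(0, 0, 2, 2)) %*% t(rot)
  r <- min_bounding_rect(pts)
  expect_equal(c(r$width, r$height), c(4, 2), tolerance = 1e-9)
  expect_equal(r$angle, 30, tolerance = 0.02)

  set.seed(19)
  for (i in 1:100) {
    n <- sample(5:25, 1)
    p <- cbind(rnorm(n, sd = 5), rnorm(n, sd = 2)) %*%
      matrix(c(cos(i), sin(i), -sin(i), cos(i)), 2, 2)
    mine <- min_bounding_rect(p)
    sweep <- oracle_min_rect_sweep(p)
    expect_lte(mine$area, sweep$area * (1 + 1e-9))  # calipers never worse
    expect_lt(abs(mine$area - sweep$area) / sweep$area, 0.005)
    expect_equal(sort(c(mine$width, mine$height), decreasing = TRUE),
                 sweep$sides, tolerance = 0.005 * max(sweep$sides))
  }
})

test_that("phantom ground truth recovers pi*a*b and the ellipse rectangle sides", {
  rg <- phantom_ranges(aspect = c(1.5, 2.4))
  ds <- generate_dataset(8, rg, seed = 23)
  for (el in ds) {
    a <- el$spec$semi_axes[1]; b <- el$spec$semi_axes[2]
    mm <- measure_mask(el$mask)
    expect_lt(abs(mm$mncsa - pi * a * b) / (pi * a * b), 0.03)
    expect_lt(abs(mm$d1 - 2 * a), 2)
    expect_lt(abs(mm$d2 - 2 * b), 2)
  }
})

test_that("measures are invariant to translation and monotone under dilation", {
  set.seed(24)
  sp <- phantom_spec(frame_size = c(80, 80), center = c(40, 40),
                     semi_axes = c(15, 8), rotation = 20)
  m <- generate_phantom(sp)$mask
  m0 <- measure_mask(m)
  shifted <- matrix(0L, 80, 80)
  shifted[11:80, 1:70] <- m[1:70, 11:80]
  ms <- measure_mask(shifted)
  expect_equal(ms$mncsa, m0$mncsa)
  expect_equal(ms$circumference, m0$circumference, tolerance = 1e-9)
  expect_equal(ms$d1, m0$d1, tolerance = 1e-9)

  dilate1 <- function(mm) {
    out <- mm
    out[-1, ] <- pmax(out[-1, ], mm[-nrow(mm), ])
    out[-nrow(out), ] <- pmax(out[-nrow(out), ], mm[-1, ])
    out[, -1] <- pmax(out[, -1], mm[, -ncol(mm)])
    out[, -ncol(out)] <- pmax(out[, -ncol(out)], mm[, -1])
    out
  }
  md <- measure_mask(dilate1(m))
  expect_gte(md$mncsa, m0$mncsa)
  expect_gte(md$d1, m0$d1 - 1e-9)
  expect_gte(md$d2, m0$d2 - 1e-9)

  expect_identical(measure_mask(matrix(0L, 10, 10))$status, "empty")
  tiny <- matrix(0L, 10, 10); tiny[5, 5:6] <- 1L
  expect_identical(measure_mask(tiny)$status, "degenerate")
})
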