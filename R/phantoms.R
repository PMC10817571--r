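#' Phantom specification for a synthetic nerve ultrasound frame
#'
#' A phantom frame emulates a cropped transverse B-mode view of the wrist:
#' a single hypoechoic (dark) elliptical nerve cross-section surrounded by a
#' hyperechoic (bright) epineurium rim on a mid-grey speckled background.
#' The ellipse geometry is the ground truth from which morphometric
#' parameters (area, circumference, diameters) are exactly recoverable.
#'
#' @param frame_size integer vector (rows, cols) of the frame, default 300x300.
#' @param center ellipse centre as (row, col); default frame centre.
#' @param semi_axes (a, b): semi-axis lengths in pixels, `a` along the
#'   rotated major direction. Both must be >= 3 px.
#' @param rotation rotation of the `a` axis from the image horizontal, degrees.
#' @param rim_thickness epineurium rim thickness in pixels.
#' @param interior_level,background_level,rim_level mean echogenicity of the
#'   nerve interior, background and rim on \[0, 1\]; must satisfy
#'   interior < background < rim.
#' @param blur_sigma Gaussian blur applied to the echogenicity map (pixels);
#'   emulates out-of-plane averaging and poor outline definition.
#' @param speckle_shape shape parameter of the multiplicative gamma speckle
#'   (mean 1, variance 1/shape); `Inf` disables the noise.
#' @param seed integer seed making the frame reproducible.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_dataset()]
#' @export
phantom_spec <- function(frame_size = c(300L, 300L),
                         center = NULL,
                         semi_axes = c(25, 14),
                         rotation = 0,
                         rim_thickness = 3,
                         interior_level = 0.18,
                         background_level = 0.45,
                         rim_level = 0.75,
                         blur_sigma = 1,
                         speckle_shape = 8,
                         seed = 1L) {
  frame_size <- rep(as.integer(frame_size), length.out = 2L)
  if (is.null(center)) center <- (frame_size + 1) / 2
  spec <- structure(
    list(frame_size = frame_size, center = as.numeric(center),
         semi_axes = as.numeric(semi_axes), rotation = as.numeric(rotation),
         rim_thickness = as.numeric(rim_thickness),
         interior_level = as.numeric(interior_level),
         background_level = as.numeric(background_level),
         rim_level = as.numeric(rim_level),
         blur_sigma = as.numeric(blur_sigma),
         speckle_shape = as.numeric(speckle_shape),
         seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (any(semi_axes < 3)) {
      nt_stop("semi_axes must both be >= 3 px", "nervetrace_config_error")
    }
    if (!(interior_level < background_level && background_level < rim_level)) {
      nt_stop("echogenicity levels must satisfy interior < background < rim",
              "nervetrace_config_error")
    }
    if (blur_sigma < 0) {
      nt_stop("blur_sigma must be >= 0", "nervetrace_config_error")
    }
    # outer ellipse (nerve + rim) must fit inside the frame
    a <- semi_axes[1] + rim_thickness
    b <- semi_axes[2] + rim_thickness
    th <- rotation * pi / 180
    half_w <- sqrt((a * cos(th))^2 + (b * sin(th))^2)  # column extent
    half_h <- sqrt((a * sin(th))^2 + (b * cos(th))^2)  # row extent
    if (center[1] - half_h < 1 || center[1] + half_h > frame_size[1] ||
        center[2] - half_w < 1 || center[2] + half_w > frame_size[2]) {
      nt_stop("ellipse (including rim) does not fit inside the frame",
              "nervetrace_sizing_error")
    }
  })
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %dx%d px, centre (%.1f, %.1f), semi-axes (%.1f, %.1f) @ %.1f deg\n",
    x$frame_size[1], x$frame_size[2], x$center[1], x$center[2],
    x$semi_axes[1], x$semi_axes[2], x$rotation))
  cat(sprintf("  levels int/bg/rim %.2f/%.2f/%.2f, rim %.1f px, blur %.1f px, speckle shape %s, seed %d\n",
              x$interior_level, x$background_level, x$rim_level,
              x$rim_thickness, x$blur_sigma, format(x$speckle_shape), x$seed))
  invisible(x)
}

# squared elliptical coordinate of every pixel centre: value <= 1 inside
# the ellipse with the given semi-axes
ellipse_u2 <- function(frame_size, center, semi_axes, rotation) {
  h <- frame_size[1]; w <- frame_size[2]
  dr <- matrix(seq_len(h) - center[1], h, w)
  dc <- matrix(seq_len(w) - center[2], h, w, byrow = TRUE)
  th <- rotation * pi / 180
  xp <- dc * cos(th) + dr * sin(th)
  yp <- -dc * sin(th) + dr * cos(th)
  (xp / semi_axes[1])^2 + (yp / semi_axes[2])^2
}

#' Render a synthetic ultrasound frame and its ground-truth nerve mask
#'
#' The echogenicity map (interior / rim / background levels) is blurred with
#' an isotropic Gaussian of `blur_sigma`, multiplied by gamma speckle with
#' mean 1, clipped to \[0, 1\] and quantised to 8 bits. The mask marks the
#' pixels whose centres lie inside the *unblurred* ellipse: the anatomical
#' truth is fixed, only the imaging of it degrades.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `frame` (integer matrix, 0-255), `mask` (0/1 integer
#'   matrix of identical dimensions) and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 7))
#' range(ph$frame); sum(ph$mask)
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  fs <- spec$frame_size
  u2_in <- ellipse_u2(fs, spec$center, spec$semi_axes, spec$rotation)
  u2_out <- ellipse_u2(fs, spec$center,
                       spec$semi_axes + spec$rim_thickness, spec$rotation)
  mask <- matrix(0L, fs[1], fs[2])
  mask[u2_in <= 1] <- 1L

  echo <- matrix(spec$background_level, fs[1], fs[2])
  echo[u2_out <= 1] <- spec$rim_level
  echo[u2_in <= 1] <- spec$interior_level

  if (spec$blur_sigma > 0) {
    echo <- eb_op(echo, function(im)
      EBImage::gblur(im, sigma = spec$blur_sigma, boundary = "replicate"))
  }
  if (is.finite(spec$speckle_shape)) {
    noise <- with_seed(spec$seed,
      matrix(stats::rgamma(fs[1] * fs[2], shape = spec$speckle_shape,
                           rate = spec$speckle_shape), fs[1], fs[2]))
    echo <- echo * noise
  }
  frame <- matrix(as.integer(round(pmin(pmax(echo, 0), 1) * 255)), fs[1], fs[2])
  list(frame = frame, mask = mask, spec = spec)
}

#' Covariate ranges for phantom dataset generation
#'
#' Each range is sampled uniformly per image. A `hard_fraction` of images is
#' drawn from a hard stratum (aspect ratio >= 2.5 and strong outline blur)
#' mimicking the elongated, blurred nerve appearances on which segmentation
#' quality degrades; the remainder form the easy stratum.
#'
#' @param scale multiplies all geometric ranges (semi-axes, rim, jitter,
#'   blur) so the same relative anatomy can be rendered into smaller frames.
#' @param semi_major,aspect,rotation,rim_thickness ranges `c(min, max)` for
#'   the ellipse geometry; the minor semi-axis is `semi_major / aspect`.
#' @param interior_level,background_level,rim_level echogenicity ranges.
#' @param blur_sigma,speckle_shape imaging-degradation ranges.
#' @param center_jitter maximal offset of the nerve centre from the frame
#'   centre, pixels.
#' @param hard_fraction fraction of images drawn from the hard stratum.
#' @param hard_aspect,hard_blur ranges replacing `aspect` and `blur_sigma`
#'   in the hard stratum.
#' @return A list of class `phantom_ranges`.
#' @export
phantom_ranges <- function(scale = 1,
                           semi_major = c(28, 48),
                           aspect = c(1.2, 2.4),
                           rotation = c(-25, 25),
                           rim_thickness = c(2, 4),
                           interior_level = c(0.10, 0.25),
                           background_level = c(0.35, 0.55),
                           rim_level = c(0.65, 0.90),
                           blur_sigma = c(0, 1.5),
                           speckle_shape = c(4, 12),
                           center_jitter = 15,
                           hard_fraction = 0.2,
                           hard_aspect = c(2.5, 3.5),
                           hard_blur = c(2, 4)) {
  r <- list(semi_major = semi_major * scale, aspect = aspect,
            rotation = rotation, rim_thickness = rim_thickness * scale,
            interior_level = interior_level,
            background_level = background_level, rim_level = rim_level,
            blur_sigma = blur_sigma * scale, speckle_shape = speckle_shape,
            center_jitter = center_jitter * scale,
            hard_fraction = hard_fraction, hard_aspect = hard_aspect,
            hard_blur = hard_blur * scale)
  for (nm in setdiff(names(r), c("center_jitter", "hard_fraction"))) {
    v <- r[[nm]]
    if (length(v) != 2 || any(!is.finite(v)) || v[1] > v[2]) {
      nt_stop(sprintf("range `%s` must be c(min, max) with min <= max", nm),
              "nervetrace_config_error")
    }
  }
  if (r$hard_fraction < 0 || r$hard_fraction > 1) {
    nt_stop("hard_fraction must be in [0, 1]", "nervetrace_config_error")
  }
  structure(r, class = "phantom_ranges")
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

#' Generate a phantom dataset with ground-truth masks and specs
#'
#' @param n number of images (the full study size is 600).
#' @param ranges a [phantom_ranges()] object.
#' @param seed master seed; every image receives its own derived seed.
#' @param frame_size frame dimensions (rows, cols), default 300x300.
#' @return A list of length `n`; each element has `frame`, `mask`, `spec`,
#'   `id` and `stratum` (`"easy"` or `"hard"`). True morphometry is
#'   recoverable from each `spec`.
#' @export
generate_dataset <- function(n = 600L, ranges = phantom_ranges(), seed = 1L,
                             frame_size = c(300L, 300L)) {
  if (n < 1) nt_stop("n must be >= 1", "nervetrace_config_error")
  if (!inherits(ranges, "phantom_ranges")) ranges <- do.call(phantom_ranges, ranges)
  frame_size <- rep(as.integer(frame_size), length.out = 2L)
  specs <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      hard <- stats::runif(1) < ranges$hard_fraction
      a <- runif1(ranges$semi_major)
      asp <- runif1(if (hard) ranges$hard_aspect else ranges$aspect)
      b <- max(a / asp, 3)
      blur <- runif1(if (hard) ranges$hard_blur else ranges$blur_sigma)
      ctr <- (frame_size + 1) / 2 +
        stats::runif(2, -ranges$center_jitter, ranges$center_jitter)
      sp <- phantom_spec(
        frame_size = frame_size, center = ctr, semi_axes = c(a, b),
        rotation = runif1(ranges$rotation),
        rim_thickness = runif1(ranges$rim_thickness),
        interior_level = runif1(ranges$interior_level),
        background_level = runif1(ranges$background_level),
        rim_level = runif1(ranges$rim_level),
        blur_sigma = blur,
        speckle_shape = runif1(ranges$speckle_shape),
        seed = sample.int(.Machine$integer.max - 1L, 1L))
      attr(sp, "stratum") <- if (hard) "hard" else "easy"
      sp
    })
  })
  lapply(seq_len(n), function(i) {
    ph <- generate_phantom(specs[[i]])
    ph$id <- sprintf("img%04d", i)
    ph$stratum <- attr(specs[[i]], "stratum")
    ph
  })
}

#' Simulate an imperfect manual annotation of a nerve mask
#'
#' Displaces the mask boundary by a smooth random radial field (a low-order
#' Fourier series in the polar angle about the mask centroid, normalised so
#' its root-mean-square equals `magnitude`). This stands in for human tracing
#' variability when exercising the manual-vs-automatic agreement analysis.
#'
#' @param mask binary matrix.
#' @param magnitude RMS boundary displacement in pixels; 0 returns the input
#'   unchanged.
#' @param seed integer seed.
#' @param harmonics number of Fourier harmonics in the radial field.
#' @return A binary matrix; always a single 8-connected component.
#' @export
perturb_annotation <- function(mask, magnitude, seed = 1L, harmonics = 3L) {
  assert_mask(mask)
  if (magnitude < 0) nt_stop("magnitude must be >= 0", "nervetrace_config_error")
  if (magnitude == 0 || sum(mask) == 0) return(mask)
  idx <- which(mask == 1, arr.ind = TRUE)
  ctr <- colMeans(idx)  # (row, col)
  co <- with_seed(seed, stats::rnorm(2L * harmonics + 1L))
  # RMS over the angle of a0 + sum(ak cos k t + bk sin k t)
  rms <- sqrt(co[1]^2 + sum(co[-1]^2) / 2)
  co <- co * magnitude / rms
  delta <- function(theta) {
    d <- rep(co[1], length(theta))
    for (k in seq_len(harmonics)) {
      d <- d + co[2 * k] * cos(k * theta) + co[2 * k + 1] * sin(k * theta)
    }
    d
  }
  h <- nrow(mask); w <- ncol(mask)
  pad <- ceiling(3 * magnitude) + 2
  r0 <- max(1, min(idx[, 1]) - pad); r1 <- min(h, max(idx[, 1]) + pad)
  c0 <- max(1, min(idx[, 2]) - pad); c1 <- min(w, max(idx[, 2]) + pad)
  rr <- matrix(r0:r1, r1 - r0 + 1, c1 - c0 + 1)
  cc <- matrix(c0:c1, r1 - r0 + 1, c1 - c0 + 1, byrow = TRUE)
  dy <- rr - ctr[1]; dx <- cc - ctr[2]
  theta <- atan2(dy, dx)
  rho <- sqrt(dx^2 + dy^2)
  rho_src <- pmax(rho - delta(theta), 0)
  src_r <- ctr[1] + rho_src * sin(theta)
  src_c <- ctr[2] + rho_src * cos(theta)
  # bilinear sampling of the source mask keeps the displaced boundary as
  # smooth as the radial field itself (a rounded lookup leaves pixel-scale
  # notches that badly inflate the traced circumference)
  fr <- pmin(pmax(as.vector(src_r), 1), h)
  fc <- pmin(pmax(as.vector(src_c), 1), w)
  r_lo <- pmin(floor(fr), h - 1L); c_lo <- pmin(floor(fc), w - 1L)
  tr_ <- fr - r_lo; tc_ <- fc - c_lo
  v <- mask[cbind(r_lo, c_lo)] * (1 - tr_) * (1 - tc_) +
    mask[cbind(r_lo + 1, c_lo)] * tr_ * (1 - tc_) +
    mask[cbind(r_lo, c_lo + 1)] * (1 - tr_) * tc_ +
    mask[cbind(r_lo + 1, c_lo + 1)] * tr_ * tc_
  out <- matrix(0L, h, w)
  out[r0:r1, c0:c1] <- matrix(as.integer(v >= 0.5), r1 - r0 + 1, c1 - c0 + 1)
  principal_component_mask(out)
}
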