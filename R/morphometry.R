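#' Keep only the largest 8-connected foreground component
#'
#' Thresholded network outputs occasionally contain stray blobs; nerve
#' morphometry is defined on the principal component only. Empty masks pass
#' through unchanged; ties resolve to the component found first in scan
#' order.
#'
#' @param mask binary matrix.
#' @return A binary matrix with at most one connected component.
#' @export
principal_component_mask <- function(mask) {
  assert_mask(mask)
  lab <- label_components8(mask)
  nlab <- max(lab)
  if (nlab <= 1L) return(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = nlab)
  keep <- which.max(sizes)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[lab == keep] <- 1L
  out
}

# clockwise Moore neighbourhood starting west
.moore <- cbind(dr = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
                dc = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L))

#' Trace the closed boundary polygon of a single-component mask
#'
#' Moore-neighbour tracing through boundary pixel centres, the automated
#' analogue of manually outlining the interface between the hypoechoic
#' nerve interior and the hyperechoic epineurium. The polygon is closed
#' implicitly (last vertex connects to the first) and oriented
#' counter-clockwise (positive shoelace area in (col, row) coordinates).
#'
#' @param mask binary matrix with exactly one 8-connected component of at
#'   least 4 pixels.
#' @return An n x 2 matrix with columns `row`, `col` of boundary pixel
#'   centres.
#' @export
trace_contour <- function(mask) {
  assert_mask(mask)
  area <- sum(mask)
  if (area == 0) nt_stop("mask is empty", "nervetrace_empty_mask")
  if (area < 4) nt_stop("mask area < 4 px is degenerate", "nervetrace_degenerate_shape")
  h <- nrow(mask); w <- ncol(mask)
  at <- function(r, c) r >= 1 && r <= h && c >= 1 && c <= w && mask[r, c] == 1
  fg <- which(mask == 1, arr.ind = TRUE)
  r0 <- min(fg[, 1])
  c0 <- min(fg[fg[, 1] == r0, 2])  # topmost, then leftmost: west neighbour is bg
  p <- c(r0, c0); b <- c(r0, c0 - 1L)
  start_state <- c(p, b)
  pts <- list(p)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 8L * area + 8L) break  # safety: cannot happen for valid masks
    # direction index of b relative to p
    rel <- b - p
    i <- which(.moore[, 1] == rel[1] & .moore[, 2] == rel[2])
    found <- FALSE
    prev <- b
    for (k in seq_len(8L)) {
      j <- ((i - 1L + k) %% 8L) + 1L
      cand <- p + .moore[j, ]
      if (at(cand[1], cand[2])) {
        b <- prev
        p <- cand
        found <- TRUE
        break
      }
      prev <- cand
    }
    if (!found) break  # isolated pixel (excluded by the area precondition)
    if (all(c(p, b) == start_state)) break
    pts[[length(pts) + 1L]] <- p
  }
  m <- do.call(rbind, pts)
  # drop consecutive duplicates and a repeated closing vertex
  dup <- c(FALSE, rowSums(abs(diff(m))) == 0)
  m <- m[!dup, , drop = FALSE]
  if (nrow(m) > 1 && all(m[nrow(m), ] == m[1, ])) m <- m[-nrow(m), , drop = FALSE]
  # enforce counter-clockwise orientation
  x <- m[, 2]; y <- m[, 1]
  a2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (a2 < 0) m <- m[nrow(m):1, , drop = FALSE]
  colnames(m) <- c("row", "col")
  m
}

polygon_perimeter <- function(pts) {
  if (nrow(pts) < 2) return(0)
  d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), , drop = FALSE])^2))
  sum(d)
}

#' Minimum-area bounding rectangle of a point set
#'
#' Convex hull followed by rotating calipers: the minimum-area enclosing
#' rectangle has a side collinear with a hull edge, so only hull-edge
#' orientations need to be examined.
#'
#' @param points n x 2 matrix of (x, y) coordinates.
#' @return A list with `width` and `height` (rectangle sides,
#'   `width >= height`; `width` lies along `angle`), `angle` (degrees in
#'   \[-90, 90)), `area` and `center`.
#' @export
min_bounding_rect <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 1) nt_stop("no points", "nervetrace_empty_mask")
  x <- points[, 1]; y <- points[, 2]
  if (nrow(points) == 1) {
    return(list(width = 0, height = 0, angle = 0, area = 0,
                center = c(x[1], y[1])))
  }
  hull <- grDevices::chull(x, y)
  hp <- points[hull, , drop = FALSE]
  nh <- nrow(hp)
  if (nh < 2) {
    return(list(width = 0, height = 0, angle = 0, area = 0,
                center = colMeans(points)))
  }
  best <- NULL
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    e <- hp[j, ] - hp[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    th <- unname(atan2(e[2], e[1]))
    ct <- cos(-th); st <- sin(-th)
    rx <- hp[, 1] * ct - hp[, 2] * st
    ry <- hp[, 1] * st + hp[, 2] * ct
    wdt <- diff(range(rx)); hgt <- diff(range(ry))
    if (is.null(best) || wdt * hgt < best$area - 1e-12) {
      cx <- mean(range(rx)); cy <- mean(range(ry))
      best <- list(width = wdt, height = hgt,
                   angle = th * 180 / pi, area = wdt * hgt,
                   center = unname(c(cx * cos(th) - cy * sin(th),
                                     cx * sin(th) + cy * cos(th))))
    }
  }
  # canonical orientation: width >= height, angle of the width side in [-90, 90)
  if (best$height > best$width) {
    best <- list(width = best$height, height = best$width,
                 angle = best$angle + 90, area = best$area,
                 center = best$center)
  }
  a <- best$angle %% 180
  if (a >= 90) a <- a - 180
  best$angle <- a
  best
}

norm_angle <- function(a) {
  a <- a %% 180
  if (a >= 90) a - 180 else a
}

#' Morphometric parameters of a binary nerve mask
#'
#' Computes the cross-sectional area (foreground pixel count), the traced
#' circumference (perimeter of the boundary polygon through pixel centres,
#' steps of 1 or sqrt(2) px) and the two diameters of the minimum-area
#' bounding rectangle of the outline: `d1` is the side whose direction lies
#' within 45 degrees of the image horizontal (the radial-ulnar axis), `d2`
#' the perpendicular side (dorsal-palmar); at exactly 45 degrees the longer
#' side is `d1`. Coordinates are pixel centres, so an axis-aligned W x H
#' rectangle measures (W-1) x (H-1) across; `pad = TRUE` adds one pixel per
#' diameter for area-consistent sizing.
#'
#' Masks with more than one component are reduced to their largest
#' 8-connected component first. Empty or sub-4-pixel masks yield
#' `NA` measures with `status` `"empty"` or `"degenerate"`.
#'
#' @param mask binary matrix.
#' @param mm_per_pixel physical calibration; with the default 1.0 all
#'   quantities are in pixel units.
#' @param pad logical; add the half-pixel border (1 px per diameter).
#' @return An object of class `morph_measures`: `mncsa` (area), `circumference`,
#'   `d1`, `d2`, `rect_angle` (degrees of the d1 side), `units`, `status`.
#' @export
measure_mask <- function(mask, mm_per_pixel = 1, pad = FALSE) {
  assert_mask(mask)
  mask <- principal_component_mask(mask)
  area_px <- sum(mask)
  units <- if (mm_per_pixel == 1) "px" else "mm"
  empty_out <- function(status) {
    structure(list(mncsa = NA_real_, circumference = NA_real_, d1 = NA_real_,
                   d2 = NA_real_, rect_angle = NA_real_, units = units,
                   status = status), class = "morph_measures")
  }
  if (area_px == 0) return(empty_out("empty"))
  if (area_px < 4) return(empty_out("degenerate"))
  ctr <- trace_contour(mask)
  perim <- polygon_perimeter(ctr)
  rect <- min_bounding_rect(cbind(x = ctr[, "col"], y = ctr[, "row"]))
  phi <- rect$angle  # angle of `width` side, [-90, 90)
  if (abs(phi) < 45) {
    d1 <- rect$width; d2 <- rect$height; a1 <- phi
  } else if (abs(phi) > 45) {
    d1 <- rect$height; d2 <- rect$width; a1 <- norm_angle(phi + 90)
  } else if (rect$width >= rect$height) {
    d1 <- rect$width; d2 <- rect$height; a1 <- phi
  } else {
    d1 <- rect$height; d2 <- rect$width; a1 <- norm_angle(phi + 90)
  }
  if (pad) { d1 <- d1 + 1; d2 <- d2 + 1 }
  structure(list(mncsa = area_px * mm_per_pixel^2,
                 circumference = perim * mm_per_pixel,
                 d1 = d1 * mm_per_pixel, d2 = d2 * mm_per_pixel,
                 rect_angle = a1, units = units, status = "ok"),
            class = "morph_measures")
}

#' @export
print.morph_measures <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("<morph_measures> %s mask\n", x$status))
  } else {
    cat(sprintf("MNCSA %.1f %s^2, circumference %.1f %s, D1 %.1f, D2 %.1f %s (angle %.1f deg)\n",
                x$mncsa, x$units, x$circumference, x$units, x$d1, x$d2,
                x$units, x$rect_angle))
  }
  invisible(x)
}
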