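# Shared fixtures and independent oracles, all generated in code.

make_disc <- function(radius, size = 2L * radius + 21L,
                      center = (size + 1) / 2) {
  xx <- matrix(seq_len(size), size, size)
  yy <- t(xx)
  matrix(as.integer((xx - center)^2 + (yy - center)^2 <= radius^2), size, size)
}

random_mask <- function(h, w, p = 0.5) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}

random_blob_mask <- function(size = 48L, n_blobs = 3L) {
  m <- matrix(0L, size, size)
  xx <- matrix(seq_len(size), size, size); yy <- t(xx)
  for (i in seq_len(n_blobs)) {
    r <- stats::runif(1, 2, 7)
    cx <- stats::runif(1, r + 1, size - r)
    cy <- stats::runif(1, r + 1, size - r)
    m[(xx - cx)^2 + (yy - cy)^2 <= r^2] <- 1L
  }
  m
}

# per-pixel double-loop confusion oracle
oracle_confusion <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (pred[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1L
      else if (pred[i, j] == 1 && truth[i, j] == 0) fp <- fp + 1L
      else if (pred[i, j] == 0 && truth[i, j] == 1) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# brute-force minimum-area rectangle: sweep rotation angles on a fine grid
oracle_min_rect_sweep <- function(points, step_deg = 0.01) {
  angles <- seq(0, 90, by = step_deg) * pi / 180
  x <- points[, 1]; y <- points[, 2]
  best_area <- Inf; best_sides <- c(NA, NA)
  for (th in angles) {
    rx <- x * cos(th) + y * sin(th)
    ry <- -x * sin(th) + y * cos(th)
    wdt <- diff(range(rx)); hgt <- diff(range(ry))
    if (wdt * hgt < best_area) {
      best_area <- wdt * hgt
      best_sides <- sort(c(wdt, hgt), decreasing = TRUE)
    }
  }
  list(area = best_area, sides = best_sides)
}

# independent 8-connected component count via igraph
oracle_n_components <- function(mask) {
  fg <- which(mask == 1)
  if (!length(fg)) return(0L)
  h <- nrow(mask)
  idx <- which(mask == 1, arr.ind = TRUE)
  key <- (idx[, 2] - 1L) * h + idx[, 1]
  from <- integer(0); to <- integer(0)
  for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    nb_r <- idx[, 1] + d[1]; nb_c <- idx[, 2] + d[2]
    ok <- nb_r >= 1 & nb_r <= h & nb_c >= 1 & nb_c <= ncol(mask)
    ok[ok] <- mask[cbind(nb_r[ok], nb_c[ok])] == 1
    if (any(ok)) {
      from <- c(from, which(ok))
      to <- c(to, match((nb_c[ok] - 1L) * h + nb_r[ok], key))
    }
  }
  g <- igraph::make_empty_graph(n = length(key), directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  igraph::components(g)$no
}

# exact permutation p-value for Spearman (tiny n only)
oracle_perm_spearman_p <- function(x, y) {
  n <- length(x)
  stopifnot(n <= 7)
  rs_of <- function(yy) stats::cor(rank(x), rank(yy))
  obs <- abs(rs_of(y))
  perms <- gtools_permutations(n)
  rs <- apply(perms, 1, function(pp) abs(rs_of(y[pp])))
  mean(rs >= obs - 1e-12)
}

# all permutations of 1..n (small n), avoiding external dependencies
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

# frozen scaled-study conditions used by end-to-end checks: 60 phantoms at
# 128 px rendered geometry, 64 px model input with 3 pooling stages,
# 8 base channels, 20 epochs with mini-batches of 5 images
scaled_study_config <- function(seed = 11L) {
  study_config(n_images = 60L, frame_size = 128L, input_size = 64L,
               depth = 3L, base_channels = 8L, epochs = 20L,
               batch_size = 5L, annot_magnitude = 1, seed = seed)
}

micro_study_config <- function(seed = 5L) {
  study_config(n_images = 12L, frame_size = 64L, input_size = 32L,
               depth = 2L, base_channels = 4L, epochs = 2L,
               batch_size = 3L, annot_magnitude = 1, seed = seed)
}
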