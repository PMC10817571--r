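#' Configuration for an encoder-decoder segmentation network
#'
#' Both architectures share the encoder layout: `depth` stages of two 3x3
#' same-padded convolutions (ReLU) followed by 2x2 stride-2 max-pooling,
#' with channel widths doubling per stage from `base_channels`. At the
#' defaults (256-pixel input, depth 5) the encoder bottoms out at an 8x8
#' feature map. The decoder returns to full resolution: U-Net with learned
#' 2x2 transposed convolutions and skip concatenations, SegNet by unpooling
#' through the recorded max-pooling indices (no skip connections, fewer
#' parameters). A final 1x1 convolution and sigmoid yield per-pixel nerve
#' probabilities.
#'
#' @param architecture `"unet"` or `"segnet"`.
#' @param input_size input side length in pixels; must be divisible by
#'   `2^depth`.
#' @param depth number of pooling stages.
#' @param base_channels channel width of the first encoder stage.
#' @param seed integer seed for weight initialisation.
#' @return An object of class `seg_model_config`.
#' @export
seg_model_config <- function(architecture = c("unet", "segnet"),
                             input_size = 256L, depth = 5L,
                             base_channels = 16L, seed = 1L) {
  architecture <- match.arg(architecture)
  input_size <- as.integer(input_size)
  depth <- as.integer(depth)
  if (depth < 1L || input_size %% (2L^depth) != 0L) {
    nt_stop("input_size must be divisible by 2^depth", "nervetrace_config_error")
  }
  structure(list(architecture = architecture, input_size = input_size,
                 depth = depth, base_channels = as.integer(base_channels),
                 seed = as.integer(seed)),
            class = "seg_model_config")
}

#' Build a U-Net segmentation model
#'
#' @param config a [seg_model_config()] (its `architecture` field is
#'   ignored by the dedicated builders).
#' @return An object of class `seg_model`.
#' @seealso [build_segnet()], [predict_mask()], [train_segmodel()]
#' @export
build_unet <- function(config = seg_model_config("unet")) {
  d <- config$depth
  ch <- config$base_channels * 2L^(0:(d - 1L))
  cb <- config$base_channels * 2L^d
  params <- with_seed(config$seed, {
    p <- list()
    cin <- 1L
    for (s in seq_len(d)) {
      p[[sprintf("enc%d_conv1", s)]] <- init_conv3(cin, ch[s])
      p[[sprintf("enc%d_conv2", s)]] <- init_conv3(ch[s], ch[s])
      cin <- ch[s]
    }
    p[["bot_conv1"]] <- init_conv3(ch[d], cb)
    p[["bot_conv2"]] <- init_conv3(cb, cb)
    for (s in d:1) {
      up_in <- if (s == d) cb else ch[s + 1L]
      p[[sprintf("dec%d_up", s)]] <- init_upconv(up_in, ch[s])
      p[[sprintf("dec%d_conv1", s)]] <- init_conv3(2L * ch[s], ch[s])
      p[[sprintf("dec%d_conv2", s)]] <- init_conv3(ch[s], ch[s])
    }
    p[["out"]] <- init_conv1(ch[1], 1L)
    p
  })
  structure(list(architecture = "unet", input_size = config$input_size,
                 depth = d, base_channels = config$base_channels,
                 channels = ch, bottleneck_channels = cb,
                 params = params, seed = config$seed),
            class = "seg_model")
}

#' Build a SegNet segmentation model
#'
#' SegNet reuses the U-Net encoder but records the argmax index of every
#' max-pooling window; its decoder upsamples by placing activations back at
#' those positions (unpooling) instead of learning transposed convolutions,
#' and has no skip concatenations, so it trains fewer parameters than the
#' U-Net at the same configuration.
#'
#' @inheritParams build_unet
#' @return An object of class `seg_model`.
#' @export
build_segnet <- function(config = seg_model_config("segnet")) {
  d <- config$depth
  ch <- config$base_channels * 2L^(0:(d - 1L))
  params <- with_seed(config$seed, {
    p <- list()
    cin <- 1L
    for (s in seq_len(d)) {
      p[[sprintf("enc%d_conv1", s)]] <- init_conv3(cin, ch[s])
      p[[sprintf("enc%d_conv2", s)]] <- init_conv3(ch[s], ch[s])
      cin <- ch[s]
    }
    for (s in d:1) {
      tc <- if (s > 1L) ch[s - 1L] else ch[1]
      p[[sprintf("dec%d_conv1", s)]] <- init_conv3(ch[s], tc)
      p[[sprintf("dec%d_conv2", s)]] <- init_conv3(tc, tc)
    }
    p[["out"]] <- init_conv1(ch[1], 1L)
    p
  })
  structure(list(architecture = "segnet", input_size = config$input_size,
                 depth = d, base_channels = config$base_channels,
                 channels = ch, bottleneck_channels = ch[d],
                 params = params, seed = config$seed),
            class = "seg_model")
}

#' Number of trainable parameters of a segmentation model
#' @param model a `seg_model`.
#' @return Integer count of weights and biases.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, function(l) length(l$W) + length(l$b), numeric(1)))
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model> %s: %dx%d input, depth %d, base %d channels, %s parameters\n",
              toupper(x$architecture), x$input_size, x$input_size, x$depth,
              x$base_channels, format(n_params(x), big.mark = ",")))
  invisible(x)
}

# ---- forward / backward -------------------------------------------------

# x: (H*W) x 1 matrix of intensities in [0,1]. Returns the per-pixel
# probability vector plus (when keep = TRUE) the tape needed for backprop
# and the spatial size of the bottleneck feature map.
seg_forward <- function(model, x, keep = FALSE) {
  H <- W <- as.integer(sqrt(nrow(x)))
  if (H * W != nrow(x)) nt_stop("input is not square", "nervetrace_geometry_error")
  if (H %% (2L^model$depth) != 0L) {
    nt_stop("input side not divisible by 2^depth", "nervetrace_geometry_error")
  }
  p <- model$params
  d <- model$depth
  t_ <- x
  enc <- vector("list", d)
  skips <- vector("list", d)
  for (s in seq_len(d)) {
    cin <- ncol(t_)
    c1 <- conv3_fwd(t_, H, W, p[[sprintf("enc%d_conv1", s)]]$W,
                    p[[sprintf("enc%d_conv1", s)]]$b, keep)
    r1 <- relu_fwd(c1$y)
    c2 <- conv3_fwd(r1$y, H, W, p[[sprintf("enc%d_conv2", s)]]$W,
                    p[[sprintf("enc%d_conv2", s)]]$b, keep)
    r2 <- relu_fwd(c2$y)
    pl <- maxpool_fwd(r2$y, H, W)
    enc[[s]] <- list(X1 = c1$X, m1 = r1$m, X2 = c2$X, m2 = r2$m,
                     K = pl$K, H = H, W = W, cin = cin)
    if (model$architecture == "unet") skips[[s]] <- r2$y
    t_ <- pl$y
    H <- H %/% 2L; W <- W %/% 2L
  }
  bot <- NULL
  dec <- vector("list", d)
  if (model$architecture == "unet") {
    cb1 <- conv3_fwd(t_, H, W, p$bot_conv1$W, p$bot_conv1$b, keep)
    rb1 <- relu_fwd(cb1$y)
    cb2 <- conv3_fwd(rb1$y, H, W, p$bot_conv2$W, p$bot_conv2$b, keep)
    rb2 <- relu_fwd(cb2$y)
    bot <- list(X1 = cb1$X, m1 = rb1$m, X2 = cb2$X, m2 = rb2$m,
                H = H, W = W, cin = ncol(t_))
    t_ <- rb2$y
    bneck <- c(H, W)
    for (s in d:1) {
      nm <- sprintf("dec%d", s)
      u <- upconv_fwd(t_, H, W, p[[paste0(nm, "_up")]]$W, p[[paste0(nm, "_up")]]$b)
      H <- 2L * H; W <- 2L * W
      cat_ <- cbind(skips[[s]], u)
      c1 <- conv3_fwd(cat_, H, W, p[[paste0(nm, "_conv1")]]$W,
                      p[[paste0(nm, "_conv1")]]$b, keep)
      r1 <- relu_fwd(c1$y)
      c2 <- conv3_fwd(r1$y, H, W, p[[paste0(nm, "_conv2")]]$W,
                      p[[paste0(nm, "_conv2")]]$b, keep)
      r2 <- relu_fwd(c2$y)
      dec[[s]] <- list(x_up = if (keep) t_ else NULL, X1 = c1$X, m1 = r1$m,
                       X2 = c2$X, m2 = r2$m, H = H, W = W)
      t_ <- r2$y
    }
  } else {
    bneck <- c(H, W)
    for (s in d:1) {
      nm <- sprintf("dec%d", s)
      u <- unpool_scatter(t_, enc[[s]]$K, enc[[s]]$H, enc[[s]]$W)
      H <- enc[[s]]$H; W <- enc[[s]]$W
      c1 <- conv3_fwd(u, H, W, p[[paste0(nm, "_conv1")]]$W,
                      p[[paste0(nm, "_conv1")]]$b, keep)
      r1 <- relu_fwd(c1$y)
      c2 <- conv3_fwd(r1$y, H, W, p[[paste0(nm, "_conv2")]]$W,
                      p[[paste0(nm, "_conv2")]]$b, keep)
      r2 <- relu_fwd(c2$y)
      dec[[s]] <- list(X1 = c1$X, m1 = r1$m, X2 = c2$X, m2 = r2$m,
                       H = H, W = W, cin = ncol(u))
      t_ <- r2$y
    }
  }
  logit <- add_bias(t_ %*% p$out$W, p$out$b)
  list(prob = sigmoid(logit), logit = logit,
       tape = if (keep) list(enc = enc, bot = bot, dec = dec, t_last = t_) else NULL,
       bottleneck = bneck, H = H, W = W)
}

# dlogit: gradient of the loss wrt the pre-sigmoid output, (H*W) x 1.
# Returns a gradient list parallel to model$params.
seg_backward <- function(model, fwd, dlogit) {
  p <- model$params
  d <- model$depth
  tape <- fwd$tape
  g <- list()
  g$out <- list(W = crossprod(tape$t_last, dlogit), b = colSums(dlogit))
  dt <- dlogit %*% t(p$out$W)
  dskips <- vector("list", d)
  if (model$architecture == "unet") {
    for (s in seq_len(d)) {  # decoder stages, full-res first
      nm <- sprintf("dec%d", s)
      tp <- tape$dec[[s]]
      ch_s <- model$channels[s]
      b2 <- conv3_bwd(relu_bwd(dt, tp$m2), tp$X2, p[[paste0(nm, "_conv2")]]$W,
                      tp$H, tp$W, ch_s)
      g[[paste0(nm, "_conv2")]] <- list(W = b2$dW, b = b2$db)
      b1 <- conv3_bwd(relu_bwd(b2$dx, tp$m1), tp$X1, p[[paste0(nm, "_conv1")]]$W,
                      tp$H, tp$W, 2L * ch_s)
      g[[paste0(nm, "_conv1")]] <- list(W = b1$dW, b = b1$db)
      dskips[[s]] <- b1$dx[, seq_len(ch_s), drop = FALSE]
      du <- b1$dx[, ch_s + seq_len(ch_s), drop = FALSE]
      bu <- upconv_bwd(du, tp$x_up, p[[paste0(nm, "_up")]]$W, ch_s,
                       tp$H %/% 2L, tp$W %/% 2L)
      g[[paste0(nm, "_up")]] <- list(W = bu$dW, b = bu$db)
      dt <- bu$dx
    }
    tb <- tape$bot
    b2 <- conv3_bwd(relu_bwd(dt, tb$m2), tb$X2, p$bot_conv2$W, tb$H, tb$W,
                    model$bottleneck_channels)
    g$bot_conv2 <- list(W = b2$dW, b = b2$db)
    b1 <- conv3_bwd(relu_bwd(b2$dx, tb$m1), tb$X1, p$bot_conv1$W, tb$H, tb$W,
                    tb$cin)
    g$bot_conv1 <- list(W = b1$dW, b = b1$db)
    dt <- b1$dx
  } else {
    for (s in seq_len(d)) {
      nm <- sprintf("dec%d", s)
      tp <- tape$dec[[s]]
      tc <- if (s > 1L) model$channels[s - 1L] else model$channels[1]
      b2 <- conv3_bwd(relu_bwd(dt, tp$m2), tp$X2, p[[paste0(nm, "_conv2")]]$W,
                      tp$H, tp$W, tc)
      g[[paste0(nm, "_conv2")]] <- list(W = b2$dW, b = b2$db)
      b1 <- conv3_bwd(relu_bwd(b2$dx, tp$m1), tp$X1, p[[paste0(nm, "_conv1")]]$W,
                      tp$H, tp$W, tp$cin)
      g[[paste0(nm, "_conv1")]] <- list(W = b1$dW, b = b1$db)
      dt <- unpool_gather(b1$dx, tape$enc[[s]]$K)
    }
  }
  for (s in d:1) {  # encoder stages, deepest first
    te <- tape$enc[[s]]
    dpool <- unpool_scatter(dt, te$K, te$H, te$W)
    if (!is.null(dskips[[s]])) dpool <- dpool + dskips[[s]]
    b2 <- conv3_bwd(relu_bwd(dpool, te$m2), te$X2,
                    p[[sprintf("enc%d_conv2", s)]]$W, te$H, te$W,
                    model$channels[s])
    g[[sprintf("enc%d_conv2", s)]] <- list(W = b2$dW, b = b2$db)
    b1 <- conv3_bwd(relu_bwd(b2$dx, te$m1), te$X1,
                    p[[sprintf("enc%d_conv1", s)]]$W, te$H, te$W, te$cin)
    g[[sprintf("enc%d_conv1", s)]] <- list(W = b1$dW, b = b1$db)
    dt <- b1$dx
  }
  g
}

# scale a frame to [0,1] and flatten to the (H*W) x 1 layout
frame_to_input <- function(frame) {
  v <- as.numeric(frame)
  if (length(v) && max(v) > 1) v <- v / 255
  matrix(v, ncol = 1L)
}

#' Predict per-pixel nerve probabilities
#'
#' @param object a `seg_model` or `seg_fit`.
#' @param newdata a square matrix matching the model input size (8-bit
#'   intensities or values already in \[0, 1\]).
#' @param type `"prob"` for the probability map, `"mask"` for the
#'   thresholded binary mask.
#' @param threshold binarisation threshold for `type = "mask"`.
#' @param ... unused.
#' @return A matrix of probabilities in (0, 1), or a 0/1 integer matrix.
#' @export
predict.seg_model <- function(object, newdata, type = c("prob", "mask"),
                              threshold = 0.5, ...) {
  type <- match.arg(type)
  if (!is.matrix(newdata) || nrow(newdata) != object$input_size ||
      ncol(newdata) != object$input_size) {
    nt_stop(sprintf("newdata must be a %dx%d matrix",
                    object$input_size, object$input_size),
            "nervetrace_geometry_error")
  }
  fwd <- seg_forward(object, frame_to_input(newdata))
  pm <- matrix(fwd$prob, object$input_size, object$input_size)
  if (type == "prob") pm else matrix(as.integer(pm >= threshold),
                                     object$input_size, object$input_size)
}

#' Binarise a model's probability output into a nerve mask
#'
#' @param model a `seg_model` (or `seg_fit`).
#' @param frame square intensity matrix at the model input size.
#' @param threshold probability cut-off; pixels with probability >=
#'   `threshold` become foreground.
#' @return A 0/1 integer matrix the size of the input.
#' @export
predict_mask <- function(model, frame, threshold = 0.5) {
  if (inherits(model, "seg_fit")) model <- model$model
  predict.seg_model(model, frame, type = "mask", threshold = threshold)
}
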