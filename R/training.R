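#' Binary cross-entropy between predicted probabilities and a binary mask
#'
#' Mean over pixels of `-(y log p + (1 - y) log(1 - p))`, with probabilities
#' clipped to `[eps, 1 - eps]` so a saturated sigmoid cannot produce
#' `log(0)`.
#'
#' @param prob numeric vector/matrix of probabilities.
#' @param mask binary vector/matrix of the same length.
#' @param eps clipping constant, default `1e-7`.
#' @return Nonnegative scalar loss.
#' @export
bce_loss <- function(prob, mask, eps = 1e-7) {
  if (length(prob) != length(mask)) {
    nt_stop("prob and mask differ in size", "nervetrace_geometry_error")
  }
  p <- pmin(pmax(as.numeric(prob), eps), 1 - eps)
  y <- as.numeric(mask)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

adam_init <- function(params) {
  lapply(params, function(l) list(mW = array(0, dim(l$W)), vW = array(0, dim(l$W)),
                                  mb = numeric(length(l$b)), vb = numeric(length(l$b))))
}

adam_step <- function(params, grads, state, t, lr, beta1, beta2, eps) {
  for (nm in names(params)) {
    s <- state[[nm]]; g <- grads[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mhatW <- s$mW / (1 - beta1^t); vhatW <- s$vW / (1 - beta2^t)
    mhatb <- s$mb / (1 - beta1^t); vhatb <- s$vb / (1 - beta2^t)
    params[[nm]]$W <- params[[nm]]$W - lr * mhatW / (sqrt(vhatW) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * mhatb / (sqrt(vhatb) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

#' Train a segmentation model with Adam and binary cross-entropy
#'
#' Each epoch shuffles the training pairs (seeded) and divides them into
#' `n_batches` mini-batches (the last possibly smaller); gradients are
#' averaged within a batch. Validation loss is computed after each epoch
#' with no weight updates. Every source of randomness derives from `seed`,
#' so the same call reproduces the same fit and loss history exactly.
#'
#' @param model a `seg_model` from [build_unet()] or [build_segnet()].
#' @param train_pairs,val_pairs lists of `list(frame, mask)` pairs at the
#'   model input size (frames 8-bit or already in \[0, 1\]).
#' @param epochs number of epochs (study default 20).
#' @param n_batches mini-batches per epoch (study default 5); ignored when
#'   `batch_size` is given.
#' @param batch_size optional explicit batch size.
#' @param lr,beta1,beta2,adam_eps Adam hyperparameters.
#' @param seed integer seed for shuffling.
#' @param verbose print per-epoch losses.
#' @return An object of class `seg_fit`: the trained `model`, a `history`
#'   data frame (`epoch`, `train_loss`, `val_loss`) and the call settings.
#' @export
train_segmodel <- function(model, train_pairs, val_pairs, epochs = 20L,
                           n_batches = 5L, batch_size = NULL, lr = 1e-3,
                           beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-7,
                           seed = 1L, verbose = FALSE) {
  if (!inherits(model, "seg_model")) {
    nt_stop("model must be a seg_model", "nervetrace_type_error")
  }
  n <- length(train_pairs)
  if (n < 1 || length(val_pairs) < 1) {
    nt_stop("training and validation sets must be non-empty", "nervetrace_size_error")
  }
  if (epochs < 1) nt_stop("epochs must be >= 1", "nervetrace_config_error")
  if (is.null(batch_size)) {
    if (n_batches < 1 || n_batches > n) {
      nt_stop("n_batches must be in [1, number of training pairs]",
              "nervetrace_size_error")
    }
    batch_size <- ceiling(n / n_batches)
  }
  xs <- lapply(train_pairs, function(p) frame_to_input(p$frame))
  ys <- lapply(train_pairs, function(p) matrix(as.numeric(p$mask), ncol = 1L))
  vx <- lapply(val_pairs, function(p) frame_to_input(p$frame))
  vy <- lapply(val_pairs, function(p) matrix(as.numeric(p$mask), ncol = 1L))

  state <- adam_init(model$params)
  tstep <- 0L
  history <- data.frame(epoch = seq_len(epochs), train_loss = NA_real_,
                        val_loss = NA_real_)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_losses <- numeric(n)
      pos <- 1L
      while (pos <= n) {
        take <- ord[pos:min(pos + batch_size - 1L, n)]
        grads <- NULL
        for (i in take) {
          fwd <- seg_forward(model, xs[[i]], keep = TRUE)
          li <- bce_loss(fwd$prob, ys[[i]])
          if (!is.finite(li)) {
            nt_stop(sprintf("non-finite training loss at epoch %d", ep),
                    "nervetrace_divergence_error")
          }
          ep_losses[match(i, ord)] <- li
          dlogit <- (fwd$prob - ys[[i]]) / length(ys[[i]])
          g <- seg_backward(model, fwd, dlogit)
          grads <- if (is.null(grads)) g else {
            for (nm in names(g)) {
              grads[[nm]]$W <- grads[[nm]]$W + g[[nm]]$W
              grads[[nm]]$b <- grads[[nm]]$b + g[[nm]]$b
            }
            grads
          }
        }
        for (nm in names(grads)) {
          grads[[nm]]$W <- grads[[nm]]$W / length(take)
          grads[[nm]]$b <- grads[[nm]]$b / length(take)
        }
        tstep <- tstep + 1L
        upd <- adam_step(model$params, grads, state, tstep, lr, beta1, beta2,
                         adam_eps)
        model$params <- upd$params
        state <- upd$state
        pos <- pos + batch_size
      }
      vl <- mean(vapply(seq_along(vx), function(i) {
        bce_loss(seg_forward(model, vx[[i]])$prob, vy[[i]])
      }, numeric(1)))
      if (!is.finite(vl)) {
        nt_stop(sprintf("non-finite validation loss at epoch %d", ep),
                "nervetrace_divergence_error")
      }
      history$train_loss[ep] <- mean(ep_losses)
      history$val_loss[ep] <- vl
      if (verbose) {
        message(sprintf("epoch %2d  train %.4f  val %.4f", ep,
                        history$train_loss[ep], vl))
      }
    }
  })
  structure(list(model = model, history = history,
                 settings = list(epochs = epochs, n_batches = n_batches,
                                 batch_size = batch_size, lr = lr,
                                 beta1 = beta1, beta2 = beta2,
                                 adam_eps = adam_eps, seed = seed,
                                 n_train = n, n_val = length(val_pairs))),
            class = "seg_fit")
}

#' @export
print.seg_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<seg_fit> %s trained %d epochs on %d images (seed %d)\n",
              toupper(x$model$architecture), nrow(h), x$settings$n_train,
              x$settings$seed))
  cat(sprintf("  loss: train %.4f -> %.4f, val %.4f -> %.4f\n",
              h$train_loss[1], h$train_loss[nrow(h)],
              h$val_loss[1], h$val_loss[nrow(h)]))
  invisible(x)
}

#' @export
summary.seg_fit <- function(object, ...) {
  cat(sprintf("%s fit: %s parameters, %d epochs, batch size %d, lr %g\n",
              toupper(object$model$architecture),
              format(n_params(object$model), big.mark = ","),
              object$settings$epochs, object$settings$batch_size,
              object$settings$lr))
  print(object$history)
  invisible(object$history)
}

#' @export
predict.seg_fit <- function(object, newdata, ...) {
  predict.seg_model(object$model, newdata, ...)
}

#' @export
coef.seg_fit <- function(object, ...) {
  unlist(lapply(object$model$params, function(l) c(as.numeric(l$W), l$b)))
}

#' Plot training and validation loss curves
#' @param x a `seg_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.seg_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "binary cross-entropy",
                    main = sprintf("%s loss", toupper(x$model$architecture)),
                    ...)
  graphics::legend("topright", c("training", "validation"), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}
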