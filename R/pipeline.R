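#' Configuration for a full synthetic segmentation study
#'
#' Bundles every knob of the end-to-end pipeline: phantom generation,
#' splitting and augmentation, the two architectures, training, prediction,
#' morphometry and the agreement analysis. The defaults mirror the study
#' conditions: 600 images at 300x300 cropped geometry, 256-pixel model
#' input with 5 pooling stages, 20 epochs in 5 mini-batches. All randomness
#' derives from the single `seed`, from which one named sub-seed per stage
#' is drawn, so two runs of the same configuration agree bit for bit.
#'
#' @param n_images dataset size.
#' @param frame_size phantom frame side (pixels).
#' @param input_size,depth,base_channels network configuration (see
#'   [seg_model_config()]).
#' @param epochs,n_batches,lr training configuration.
#' @param batch_size optional explicit mini-batch size; overrides
#'   `n_batches` (see [train_segmodel()]).
#' @param threshold probability threshold for mask binarisation.
#' @param mm_per_pixel physical calibration for morphometry.
#' @param annot_magnitude RMS boundary displacement (px) of the simulated
#'   manual annotation arm.
#' @param manual_arm `"perturbed"` compares CNNs against simulated manual
#'   tracings; `"truth"` compares against pristine ground truth.
#' @param ranges [phantom_ranges()]; the default scales the standard
#'   geometry to `frame_size`.
#' @param seed master seed.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_images = 600L, frame_size = 300L,
                         input_size = 256L, depth = 5L, base_channels = 16L,
                         epochs = 20L, n_batches = 5L, batch_size = NULL,
                         lr = 1e-3,
                         threshold = 0.5, mm_per_pixel = 1,
                         annot_magnitude = 2,
                         manual_arm = c("perturbed", "truth"),
                         ranges = NULL, seed = 1L) {
  manual_arm <- match.arg(manual_arm)
  if (is.null(ranges)) ranges <- phantom_ranges(scale = frame_size / 300)
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 6L))
  structure(list(n_images = as.integer(n_images),
                 frame_size = as.integer(frame_size),
                 input_size = as.integer(input_size), depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 epochs = as.integer(epochs), n_batches = as.integer(n_batches),
                 batch_size = batch_size, lr = lr, threshold = threshold, mm_per_pixel = mm_per_pixel,
                 annot_magnitude = annot_magnitude, manual_arm = manual_arm,
                 ranges = ranges, seed = as.integer(seed),
                 seeds = list(data = sub[1], split = sub[2], augment = sub[3],
                              model = sub[4], train = sub[5], annot = sub[6])),
            class = "study_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("study stage '%s' failed: %s", stage, conditionMessage(e)),
      class = c("nervetrace_stage_error", "nervetrace_error")))
  })
}

measures_row <- function(id, source, mm) {
  data.frame(id = id, source = source, mncsa = mm$mncsa,
             circumference = mm$circumference, d1 = mm$d1, d2 = mm$d2,
             rect_angle = mm$rect_angle, units = mm$units, status = mm$status)
}

#' Run the full synthetic study: generate, train, evaluate, compare
#'
#' Executes the whole pipeline for both architectures on one phantom
#' dataset: generation, 3/4-1/12-1/6 split, flip augmentation, training,
#' prediction on the held-out test partition, per-image segmentation
#' metrics with IoU distribution, morphometry of truth / simulated-manual /
#' predicted masks, and the manual-vs-CNN agreement statistics (Spearman,
#' Bland-Altman) for each of the four morphometric measures, plus
#' between-model t-tests on the per-image metrics.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory to which split manifest, loss curves,
#'   metric and agreement tables are written as CSV.
#' @param verbose print per-epoch training losses.
#' @return An object of class `nerve_study`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  ds <- run_stage("generate",
    generate_dataset(config$n_images, config$ranges, config$seeds$data,
                     rep(config$frame_size, 2L)))
  ids <- vapply(ds, `[[`, character(1), "id")
  split <- run_stage("split", split_dataset(ids, config$seeds$split))
  prep <- run_stage("preprocess", lapply(ds, function(el) {
    pr <- crop_and_resize_pair(el$frame, el$mask, NULL, config$input_size)
    list(id = el$id, stratum = el$stratum, frame = pr$frame, mask = pr$mask,
         spec = el$spec)
  }))
  names(prep) <- ids
  train_pairs <- run_stage("augment",
    augment_flips(prep[split$train], config$seeds$augment))
  val_pairs <- prep[split$validation]
  test_pairs <- prep[split$test]

  fits <- list(); preds <- list()
  for (arch in c("unet", "segnet")) {
    cfg <- seg_model_config(arch, config$input_size, config$depth,
                            config$base_channels, config$seeds$model)
    model <- if (arch == "unet") build_unet(cfg) else build_segnet(cfg)
    fits[[arch]] <- run_stage(paste0("train_", arch),
      train_segmodel(model, train_pairs, val_pairs, epochs = config$epochs,
                     n_batches = config$n_batches,
                     batch_size = config$batch_size, lr = config$lr,
                     seed = config$seeds$train, verbose = verbose))
    preds[[arch]] <- run_stage(paste0("predict_", arch),
      lapply(test_pairs, function(p)
        predict_mask(fits[[arch]], p$frame, config$threshold)))
  }

  metrics <- list()
  for (arch in c("unet", "segnet")) {
    per <- do.call(rbind, lapply(seq_along(test_pairs), function(i) {
      cc <- confusion(preds[[arch]][[i]], test_pairs[[i]]$mask)
      sm <- metrics_from_counts(cc)
      data.frame(id = test_pairs[[i]]$id, stratum = test_pairs[[i]]$stratum,
                 tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
                 precision = sm$precision, recall = sm$recall,
                 dice = sm$dice, iou = sm$iou)
    }))
    metrics[[arch]] <- list(per_image = per, summary = summarize_metrics(per))
  }
  stratum <- do.call(rbind, lapply(c("unet", "segnet"), function(arch) {
    per <- metrics[[arch]]$per_image
    data.frame(model = arch,
               easy_mean_iou = mean(per$iou[per$stratum == "easy"]),
               hard_mean_iou = mean(per$iou[per$stratum == "hard"]))
  }))

  manual <- run_stage("manual_arm", {
    if (config$manual_arm == "truth") {
      lapply(test_pairs, `[[`, "mask")
    } else {
      aseed <- with_seed(config$seeds$annot,
                         sample.int(.Machine$integer.max - 1L, length(test_pairs)))
      lapply(seq_along(test_pairs), function(i)
        perturb_annotation(test_pairs[[i]]$mask, config$annot_magnitude,
                           aseed[i]))
    }
  })

  morph <- run_stage("morphometry", do.call(rbind, c(
    lapply(seq_along(test_pairs), function(i)
      measures_row(test_pairs[[i]]$id, "truth",
                   measure_mask(test_pairs[[i]]$mask, config$mm_per_pixel))),
    lapply(seq_along(test_pairs), function(i)
      measures_row(test_pairs[[i]]$id, "manual",
                   measure_mask(manual[[i]], config$mm_per_pixel))),
    lapply(seq_along(test_pairs), function(i)
      measures_row(test_pairs[[i]]$id, "unet",
                   measure_mask(preds$unet[[i]], config$mm_per_pixel))),
    lapply(seq_along(test_pairs), function(i)
      measures_row(test_pairs[[i]]$id, "segnet",
                   measure_mask(preds$segnet[[i]], config$mm_per_pixel))))))

  agreement <- run_stage("agreement", {
    rows <- list()
    for (meas in c("mncsa", "circumference", "d1", "d2")) {
      man <- morph[morph$source == "manual", meas]
      for (arch in c("unet", "segnet")) {
        cnn <- morph[morph$source == arch, meas]
        ok <- is.finite(man) & is.finite(cnn)
        if (sum(ok) < 3) {
          rows[[length(rows) + 1L]] <- data.frame(
            measure = meas, model = arch, n = sum(ok), rs = NA_real_,
            p = NA_real_, band = "other", mean_diff = NA_real_,
            sd_diff = NA_real_, loa_low = NA_real_, loa_high = NA_real_,
            coverage = NA_real_)
          next
        }
        sc <- tryCatch(spearman_corr(man[ok], cnn[ok]),
                       error = function(e) list(rs = NA_real_, p = NA_real_,
                                                band = "other"))
        ba <- bland_altman(man[ok], cnn[ok])
        rows[[length(rows) + 1L]] <- data.frame(
          measure = meas, model = arch, n = sum(ok), rs = sc$rs, p = sc$p,
          band = sc$band, mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
          loa_low = ba$loa_low, loa_high = ba$loa_high,
          coverage = ba$coverage)
      }
    }
    do.call(rbind, rows)
  })

  ttests <- do.call(rbind, lapply(c("precision", "recall", "dice", "iou"),
    function(m) {
      tt <- two_sample_t(metrics$unet$per_image[[m]],
                         metrics$segnet$per_image[[m]])
      data.frame(metric = m, t = tt$t, df = tt$df, p = tt$p)
    }))

  study <- structure(
    list(config = config, split = split, fits = fits, metrics = metrics,
         stratum = stratum, morph = morph, agreement = agreement,
         ttests = ttests, predictions = preds, manual = manual,
         test_ids = vapply(test_pairs, `[[`, character(1), "id")),
    class = "nerve_study")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_split_manifest(split, file.path(out_dir, "split.csv"))
    for (arch in c("unet", "segnet")) {
      utils::write.csv(fits[[arch]]$history,
                       file.path(out_dir, sprintf("loss_%s.csv", arch)),
                       row.names = FALSE)
      utils::write.csv(metrics[[arch]]$per_image,
                       file.path(out_dir, sprintf("metrics_%s.csv", arch)),
                       row.names = FALSE)
      utils::write.csv(metrics[[arch]]$summary$summary,
                       file.path(out_dir, sprintf("metrics_summary_%s.csv", arch)),
                       row.names = FALSE)
    }
    utils::write.csv(morph, file.path(out_dir, "morphometry.csv"),
                     row.names = FALSE)
    utils::write.csv(agreement, file.path(out_dir, "agreement.csv"),
                     row.names = FALSE)
    utils::write.csv(ttests, file.path(out_dir, "ttests.csv"),
                     row.names = FALSE)
  }
  study
}

#' @export
print.nerve_study <- function(x, ...) {
  cat(sprintf("<nerve_study> %d images (train %d / val %d / test %d), input %dx%d\n",
              x$config$n_images, length(x$split$train),
              length(x$split$validation), length(x$split$test),
              x$config$input_size, x$config$input_size))
  for (arch in c("unet", "segnet")) {
    s <- x$metrics[[arch]]$summary
    m <- s$summary
    cat(sprintf("  %-6s ", toupper(arch)))
    cat(paste(sprintf("%s %.3f+/-%.3f", m$metric, m$mean, m$sd),
              collapse = "  "), "\n")
    cat(sprintf("         IoU mode %.1f, min %.3f\n", s$iou_mode, s$iou_min))
  }
  cat("  Agreement (manual vs CNN):\n")
  a <- x$agreement
  for (i in seq_len(nrow(a))) {
    cat(sprintf("    %-13s %-6s rs = %6.3f (%s), mean diff %7.3f, LoA [%.3f, %.3f]\n",
                a$measure[i], a$model[i], a$rs[i], a$band[i], a$mean_diff[i],
                a$loa_low[i], a$loa_high[i]))
  }
  invisible(x)
}

#' Plot study loss curves for both architectures
#' @param x a `nerve_study`.
#' @param ... unused.
#' @export
plot.nerve_study <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (arch in c("unet", "segnet")) plot(x$fits[[arch]])
  invisible(x)
}
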