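# The two training loops of the cascade: the cord localizer (T2w, one
# full-volume patch, batch 1) and the multiclass tumor segmenter
# (two-contrast cord crops, patch grid, batch 8).

#' Preprocess a subject to standard space
#'
#' Resamples both contrasts (linear), the labels and the cord mask
#' (nearest) to the target spacing, centre crops-or-pads to the fixed
#' shape, and z-score normalises the images.
#'
#' @param subject A `subject_record`.
#' @param preproc A [preproc_config()].
#' @return List of standard-space arrays `t2w`, `gd_t1w` (normalised),
#'   `labels` (4D), `cord` (3D), plus `record` and `subject_id`.
#' @export
preprocess_subject <- function(subject, preproc = preproc_config()) {
  t2 <- preprocess_volume(subject$t2w, preproc, "image")
  g1 <- preprocess_volume(subject$gd_t1w, preproc, "image")
  cord <- preprocess_volume(subject$cord_mask, preproc, "mask")
  lab <- array(0, dim = c(preproc$crop_shape, 4L))
  for (c in 1:4) {
    lv <- image_volume(subject$labels$data[, , , c], subject$labels$spacing)
    lab[, , , c] <- preprocess_volume(lv, preproc, "mask")$vol$data
  }
  list(subject_id = subject$subject_id, t2w = t2$vol$data,
       gd_t1w = g1$vol$data, labels = lab, cord = cord$vol$data,
       record = t2$record, meta = subject$meta)
}

stage_net_config <- function(stage) {
  if (stage == "localizer") {
    unet_config(in_channels = 1L, out_channels = 1L, depth = 4L,
                base_filters = 8L)
  } else {
    unet_config(in_channels = 2L, out_channels = 4L, depth = 4L,
                base_filters = 16L)
  }
}

stage_train_config <- function(stage, preproc, seed = 1L) {
  if (stage == "localizer") {
    train_config(batch_size = 1L, patch_size = preproc$crop_shape,
                 stride = NULL, seed = seed)
  } else {
    train_config(batch_size = 8L, patch_size = c(128L, 128L, 32L),
                 stride = c(64L, 64L, 32L), seed = seed)
  }
}

# One gradient evaluation on a sample; returns loss and the parameter
# gradients (already averaged over the sample's voxels via the loss).
sample_grad <- function(model, x, y, smooth) {
  fwd <- unet_forward(model, x, training = TRUE)
  lg <- multiclass_dice_loss_grad(fwd$prob, y, smooth)
  dlogits <- lg$dpred * fwd$prob * (1 - fwd$prob)
  list(loss = lg$loss, grads = unet_backward(model, fwd$cache, dlogits))
}

add_grads <- function(a, b) {
  for (nm in names(a)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}
scale_grads <- function(a, s) lapply(a, function(x) x * s)

#' Train one stage of the cascade
#'
#' Trains the localizer (Dice loss on the cord tube mask from T2w) or
#' the multiclass segmenter (multiclass Dice loss on two-contrast crops
#' around the cord mask) with Adam, cosine-annealed learning rate,
#' random affine augmentation and early stopping. The validation loss is
#' computed on full validation volumes assembled by stitched inference —
#' the quantity early stopping protects. Fully reproducible from the
#' configuration seeds.
#'
#' @param cohort A `phantom_cohort`, or a list of `subject_record`s plus
#'   a manifest.
#' @param stage `"localizer"` or `"segmenter"`.
#' @param net_cfg A [unet_config()]; stage default when `NULL`.
#' @param cfg A [train_config()]; stage default when `NULL`.
#' @param preproc A [preproc_config()].
#' @param cascade A [cascade_config()] (bounding-box margin for the
#'   segmenter crops; patch/stride come from `cfg`).
#' @param split A split tibble from [split_dataset()]; computed from
#'   `cfg$seed` when `NULL`.
#' @param use_cascade `FALSE` trains the segmenter on the full standard
#'   crop instead of cord crops (the single-step comparison arm).
#' @param verbose Print one line per epoch.
#' @return A `trained_model`: `model` (weights at the best validation
#'   epoch), `log` (tibble epoch/lr/train_loss/val_loss), `best_epoch`,
#'   `stopped_epoch`, `stage`, `split`.
#' @export
train_model <- function(cohort, stage = c("localizer", "segmenter"),
                        net_cfg = NULL, cfg = NULL,
                        preproc = preproc_config(),
                        cascade = cascade_config(),
                        split = NULL, use_cascade = TRUE, verbose = FALSE) {
  stage <- match.arg(stage)
  subjects <- cohort$subjects
  manifest <- cohort$manifest
  if (is.null(subjects) || is.null(manifest)) {
    stop("`cohort` must provide $subjects and $manifest", call. = FALSE)
  }
  net_cfg <- net_cfg %||% stage_net_config(stage)
  cfg <- cfg %||% stage_train_config(stage, preproc)
  if (any(cfg$patch_size %% 2^net_cfg$depth != 0)) {
    stop("patch size must be divisible by 2^depth", call. = FALSE)
  }
  split <- split %||% split_dataset(manifest, seed = substream_seed(cfg$seed, "split"))
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  train_ids <- split$subject_id[split$split == "train"]
  val_ids <- split$subject_id[split$split == "validation"]
  if (!length(train_ids)) stop("empty training set", call. = FALSE)

  prep <- lapply(subjects, preprocess_subject, preproc = preproc)
  names(prep) <- ids

  # per-subject training/validation samples in standard space
  make_sample <- function(p) {
    if (stage == "localizer") {
      list(images = list(p$t2w),
           target = array(p$cord, dim = c(dim(p$cord), 1L)))
    } else {
      if (use_cascade) {
        bbox <- mask_to_bbox(p$cord, cascade$bbox_margin_mm,
                             preproc$target_spacing)
      } else {
        bbox <- bbox3d(c(0L, 0L, 0L), dim(p$t2w))
      }
      lab <- array(0, dim = c(bbox_shape(bbox), 4L))
      for (c in 1:4) lab[, , , c] <- crop_to_bbox(p$labels[, , , c], bbox)
      list(images = list(crop_to_bbox(p$gd_t1w, bbox),
                         crop_to_bbox(p$t2w, bbox)),
           target = lab)
    }
  }
  tr_samples <- lapply(prep[train_ids], make_sample)
  val_samples <- lapply(prep[val_ids], make_sample)

  model <- build_unet(net_cfg, seed = substream_seed(cfg$seed, "init"))
  state <- adam_init(model$params)
  smooth <- cfg$loss_smooth
  depth <- net_cfg$depth

  # assemble the (padded, channel-stacked) input and target of a sample
  to_xy <- function(sm) {
    imgs <- sm$images
    if (stage == "localizer") {
      d <- dim(imgs[[1]])
      x <- array(imgs[[1]], dim = c(d, 1L))
      list(x = x, y = sm$target, offset = c(0L, 0L, 0L), padded = d)
    } else {
      pads <- lapply(imgs, pad_for_patching, patch = cfg$patch_size,
                     depth = depth)
      d <- dim(pads[[1]]$data)
      x <- array(c(pads[[1]]$data, pads[[2]]$data), dim = c(d, 2L))
      yt <- array(0, dim = c(d, 4L))
      off <- pads[[1]]$offset; os <- pads[[1]]$orig_shape
      yt[(off[1] + 1):(off[1] + os[1]), (off[2] + 1):(off[2] + os[2]),
         (off[3] + 1):(off[3] + os[3]), ] <- sm$target
      list(x = x, y = yt, offset = off, padded = d)
    }
  }

  val_loss_fn <- function() {
    if (!length(val_samples)) return(NA_real_)
    mean(vapply(val_samples, function(sm) {
      if (stage == "localizer") {
        prob <- forward_infer(model, sm$images[[1]])
        dice_loss(prob[, , , 1], sm$target[, , , 1], smooth)
      } else {
        vc <- cascade_config(seg_patch = cfg$patch_size,
                             seg_stride = cfg$stride %||% cfg$patch_size)
        soft <- segment_tumor(sm$images[[1]], sm$images[[2]], model, vc)
        multiclass_dice_loss(soft, sm$target, smooth)
      }
    }, numeric(1)))
  }

  log_rows <- list()
  best_val <- Inf; best_params <- model$params; best_epoch <- 0L
  val_hist <- numeric(0)
  stopped <- cfg$max_epochs

  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- cosine_lr(epoch - 1, cfg$max_epochs, cfg$lr, cfg$lr_min)
    set.seed(substream_seed(cfg$seed, paste0("epoch-", epoch)))
    ord <- sample(seq_along(tr_samples))
    epoch_losses <- c()

    if (stage == "localizer") {
      for (si in ord) {
        sm <- tr_samples[[si]]
        if (cfg$augment) {
          aug <- augment(sm$images, sm$target, preproc$target_spacing, cfg)
          sm <- list(images = aug$images, target = aug$labels)
        }
        xy <- to_xy(sm)
        g <- sample_grad(model, xy$x, xy$y, smooth)
        st <- adam_step(model$params, g$grads, state, lr)
        model$params <- st$params; state <- st$state
        epoch_losses <- c(epoch_losses, g$loss)
      }
    } else {
      # augment each subject once per epoch, then batch patches globally
      aug_xy <- lapply(tr_samples, function(sm) {
        if (cfg$augment) {
          aug <- augment(sm$images, sm$target, preproc$target_spacing, cfg)
          sm <- list(images = aug$images, target = aug$labels)
        }
        to_xy(sm)
      })
      stride <- cfg$stride %||% cfg$patch_size
      refs <- list()
      for (si in seq_along(aug_xy)) {
        d3 <- dim(aug_xy[[si]]$x)[1:3]
        og <- extract_patches(array(0, dim = d3), cfg$patch_size, stride)$origins
        if (cfg$random_offset) {
          room <- d3 - cfg$patch_size
          og <- t(apply(og, 1, function(o) {
            jit <- vapply(1:3, function(k) sample(seq(-stride[k], stride[k]), 1),
                          numeric(1))
            pmin(pmax(o + jit, 0), room)
          }))
        }
        for (r in seq_len(nrow(og))) {
          refs[[length(refs) + 1]] <- list(si = si, o = og[r, ])
        }
      }
      refs <- refs[sample(seq_along(refs))]
      nb <- ceiling(length(refs) / cfg$batch_size)
      for (b in seq_len(nb)) {
        batch <- refs[((b - 1) * cfg$batch_size + 1):min(b * cfg$batch_size,
                                                         length(refs))]
        acc <- NULL; bl <- 0
        for (rf in batch) {
          xy <- aug_xy[[rf$si]]
          o <- rf$o; ps <- cfg$patch_size
          xi <- (o[1] + 1):(o[1] + ps[1]); yi <- (o[2] + 1):(o[2] + ps[2])
          zi <- (o[3] + 1):(o[3] + ps[3])
          g <- sample_grad(model,
                           xy$x[xi, yi, zi, , drop = FALSE],
                           xy$y[xi, yi, zi, , drop = FALSE], smooth)
          acc <- if (is.null(acc)) g$grads else add_grads(acc, g$grads)
          bl <- bl + g$loss
        }
        acc <- scale_grads(acc, 1 / length(batch))
        st <- adam_step(model$params, acc, state, lr)
        model$params <- st$params; state <- st$state
        epoch_losses <- c(epoch_losses, bl / length(batch))
      }
    }

    vl <- val_loss_fn()
    val_hist <- c(val_hist, vl)
    # without a validation set, fall back to the training loss for
    # best-weight tracking (tiny cohorts)
    track <- if (is.finite(vl)) vl else mean(epoch_losses)
    if (track < best_val) {
      best_val <- track; best_params <- model$params; best_epoch <- epoch
    }
    log_rows[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, train_loss = mean(epoch_losses), val_loss = vl)
    if (verbose) {
      message(sprintf("[%s] epoch %3d lr %.5f train %.4f val %.4f",
                      stage, epoch, lr, mean(epoch_losses), vl))
    }
    if (length(val_hist) && !anyNA(val_hist) &&
        early_stop_check(val_hist, cfg$patience, cfg$min_delta)) {
      stopped <- epoch
      break
    }
  }

  model$params <- best_params
  structure(list(model = model, log = dplyr::bind_rows(log_rows),
                 best_epoch = best_epoch, best_val_loss = best_val,
                 stopped_epoch = stopped, stage = stage, cfg = cfg,
                 net_cfg = net_cfg, split = split),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s: stopped at epoch %d, best epoch %d (val loss %.4f)\n",
              x$stage, x$stopped_epoch, x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' One-row summary of a training run
#'
#' @param x A `trained_model`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @importFrom generics glance
#' @export
glance.trained_model <- function(x, ...) {
  tibble::tibble(stage = x$stage, epochs_run = nrow(x$log),
                 best_epoch = x$best_epoch, best_val_loss = x$best_val_loss,
                 n_params = n_params(x$model))
}

#' @export
generics::glance
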