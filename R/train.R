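# Losses, augmentation, patch sampling, schedules, early stopping,
# dataset splitting, and the training loops for the two cascade stages.

#' Training configuration
#'
#' @param lr Initial learning rate (0.001 for both stages).
#' @param max_epochs Maximum number of epochs (200).
#' @param patience Early-stopping patience in epochs (50).
#' @param min_delta Minimal validation-loss decrease counted as an
#'   improvement (0.001); smaller or equal changes do not reset patience.
#' @param batch_size 1 for the localizer (one full-volume patch), 8 for
#'   the segmenter.
#' @param patch_size,stride Voxel triples; the localizer uses a single
#'   patch equal to the standard crop, the segmenter a 128 x 128 x 32
#'   patch with 64 x 64 x 32 stride by default.
#' @param augment Apply random affine augmentation during training.
#' @param aug_rotate_deg Rotation amplitude (degrees) about one randomly
#'   chosen axis.
#' @param aug_scale Scaling amplitude in the sagittal plane (fraction).
#' @param aug_translate Translation amplitude in the sagittal plane
#'   (fraction of extent).
#' @param loss_smooth Smoothing epsilon in the Dice loss denominator.
#' @param lr_min Final learning rate of the cosine annealing cycle.
#' @param random_offset Use random patch offsets instead of the
#'   deterministic stride grid when sampling training patches.
#' @param seed Master seed for initialisation, shuffling and
#'   augmentation substreams.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 0.001, max_epochs = 200L, patience = 50L,
                         min_delta = 0.001, batch_size = 1L,
                         patch_size = c(512L, 256L, 32L), stride = NULL,
                         augment = TRUE, aug_rotate_deg = 5,
                         aug_scale = 0.10, aug_translate = 0.03,
                         loss_smooth = 1, lr_min = 0,
                         random_offset = FALSE, seed = 1L) {
  stopifnot(patience <= max_epochs, batch_size >= 1L,
            all(patch_size > 0), lr > 0)
  if (!is.null(stride)) stopifnot(all(stride > 0), all(stride <= patch_size))
  structure(list(lr = lr, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 batch_size = as.integer(batch_size),
                 patch_size = as.integer(patch_size),
                 stride = if (!is.null(stride)) as.integer(stride),
                 augment = isTRUE(augment),
                 aug_rotate_deg = aug_rotate_deg, aug_scale = aug_scale,
                 aug_translate = aug_translate,
                 loss_smooth = loss_smooth, lr_min = lr_min,
                 random_offset = isTRUE(random_offset),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p*g) + smooth) / (sum(p) + sum(g) + smooth)` over all
#' voxels of one channel; differentiable in the prediction.
#'
#' @param pred Soft prediction in `[0, 1]`.
#' @param target Binary target of the same shape.
#' @param smooth Smoothing epsilon (default 1).
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred, target, smooth = 1) {
  if (!all(dim(pred) == dim(target)) &&
      !(is.null(dim(pred)) && length(pred) == length(target))) {
    stop("pred and target shapes differ", call. = FALSE)
  }
  1 - (2 * sum(pred * target) + smooth) / (sum(pred) + sum(target) + smooth)
}

# loss + gradient wrt pred, for one channel
dice_loss_grad <- function(pred, target, smooth = 1) {
  inter <- sum(pred * target)
  denom <- sum(pred) + sum(target) + smooth
  loss <- 1 - (2 * inter + smooth) / denom
  dpred <- -(2 * target * denom - (2 * inter + smooth)) / denom^2
  list(loss = loss, dpred = dpred)
}

#' Multiclass Dice loss
#'
#' Unweighted mean of the per-channel soft Dice loss over all channels
#' (for the tumor segmenter: tumor, cavity, edema and the whole-lesion
#' channel alike).
#'
#' @param pred 4D soft prediction `(X, Y, Z, C)`.
#' @param target 4D binary target of the same shape.
#' @param smooth Smoothing epsilon.
#' @return Scalar loss in `[0, 1]`.
#' @export
multiclass_dice_loss <- function(pred, target, smooth = 1) {
  dp <- dim(pred); dt <- dim(target)
  if (length(dp) != 4L || !all(dp == dt)) {
    stop("pred and target must be 4D arrays of identical shape", call. = FALSE)
  }
  mean(vapply(seq_len(dp[4]), function(c) {
    dice_loss(pred[, , , c], target[, , , c], smooth)
  }, numeric(1)))
}

multiclass_dice_loss_grad <- function(pred, target, smooth = 1) {
  C <- dim(pred)[4]
  dpred <- array(0, dim = dim(pred))
  loss <- 0
  for (c in seq_len(C)) {
    r <- dice_loss_grad(pred[, , , c], target[, , , c], smooth)
    loss <- loss + r$loss / C
    dpred[, , , c] <- r$dpred / C
  }
  list(loss = loss, dpred = dpred)
}

#' Cosine-annealed learning rate
#'
#' One annealing cycle over `max_epochs`:
#' `lr_min + (lr0 - lr_min) * (1 + cos(pi * epoch / max_epochs)) / 2`.
#'
#' @param epoch Epoch in `[0, max_epochs]`.
#' @param max_epochs Cycle length.
#' @param lr0 Initial learning rate.
#' @param lr_min Final learning rate (default 0).
#' @return Learning rate.
#' @export
cosine_lr <- function(epoch, max_epochs, lr0 = 0.001, lr_min = 0) {
  stopifnot(epoch >= 0, epoch <= max_epochs)
  lr_min + (lr0 - lr_min) * (1 + cos(pi * epoch / max_epochs)) / 2
}

#' Early-stopping decision
#'
#' Stop when no epoch in the last `patience` epochs improved the best
#' validation loss by strictly more than `min_delta`.
#'
#' @param val_loss_history Numeric vector of per-epoch validation losses.
#' @param patience Number of epochs without improvement tolerated.
#' @param min_delta Improvement threshold (strict).
#' @return `TRUE` if training should stop.
#' @export
early_stop_check <- function(val_loss_history, patience, min_delta = 0.001) {
  n <- length(val_loss_history)
  stopifnot(n >= 1)
  best <- val_loss_history[1]
  last_improve <- 1L
  if (n > 1) {
    for (t in 2:n) {
      if (val_loss_history[t] < best - min_delta) {
        best <- val_loss_history[t]
        last_improve <- t
      } else {
        best <- min(best, val_loss_history[t])
      }
    }
  }
  (n - last_improve) >= patience
}

axis_origins <- function(len, patch, stride) {
  if (len < patch) stop("volume smaller than patch; pad first", call. = FALSE)
  if (stride <= 0) stop("stride must be positive", call. = FALSE)
  o <- seq.int(0L, len - patch, by = stride)
  if (o[length(o)] + patch < len) o <- c(o, len - patch)
  as.integer(o)
}

#' Extract a deterministic patch grid
#'
#' Origins form the full stride grid; when the grid does not end exactly
#' at the volume border, a final origin per axis is clamped so the last
#' patch ends at the border — every voxel is covered by at least one
#' patch.
#'
#' @param vol 3D array or 4D `(X, Y, Z, C)` array.
#' @param patch_size,stride Integer triples.
#' @return List with `origins` (matrix, one 0-based voxel origin per row)
#'   and `patches` (list of arrays, channel dimension preserved).
#' @export
extract_patches <- function(vol, patch_size, stride) {
  d3 <- dim(vol)[1:3]
  has_ch <- length(dim(vol)) == 4L
  ox <- axis_origins(d3[1], patch_size[1], stride[1])
  oy <- axis_origins(d3[2], patch_size[2], stride[2])
  oz <- axis_origins(d3[3], patch_size[3], stride[3])
  origins <- as.matrix(expand.grid(ox, oy, oz, KEEP.OUT.ATTRS = FALSE))
  colnames(origins) <- NULL
  patches <- lapply(seq_len(nrow(origins)), function(r) {
    o <- origins[r, ]
    if (has_ch) {
      vol[(o[1] + 1):(o[1] + patch_size[1]),
          (o[2] + 1):(o[2] + patch_size[2]),
          (o[3] + 1):(o[3] + patch_size[3]), , drop = FALSE]
    } else {
      vol[(o[1] + 1):(o[1] + patch_size[1]),
          (o[2] + 1):(o[2] + patch_size[2]),
          (o[3] + 1):(o[3] + patch_size[3]), drop = FALSE]
    }
  })
  list(origins = origins, patches = patches)
}

# Random affine draw: rotation about one random axis (physical space, so
# anisotropic voxels are handled), scaling and translation restricted to
# the sagittal (superior-inferior x anterior-posterior) plane.
draw_affine <- function(dims, spacing, cfg) {
  axis <- sample(1:3, 1)
  angle <- stats::runif(1, -cfg$aug_rotate_deg, cfg$aug_rotate_deg) * pi / 180
  sc <- 1 + stats::runif(1, -cfg$aug_scale, cfg$aug_scale)
  tr <- stats::runif(2, -cfg$aug_translate, cfg$aug_translate) * dims[1:2]
  ca <- cos(angle); sa <- sin(angle)
  R <- diag(3)
  ij <- setdiff(1:3, axis)
  R[ij[1], ij[1]] <- ca; R[ij[2], ij[2]] <- ca
  R[ij[1], ij[2]] <- -sa; R[ij[2], ij[1]] <- sa
  S <- diag(spacing)
  A <- solve(S) %*% R %*% S %*% diag(c(sc, sc, 1))
  t_vox <- c(tr, 0)
  list(axis = axis, angle_deg = angle * 180 / pi, scale = sc,
       translate_vox = t_vox, A = A)
}

apply_affine <- function(arr, A, t_vox, nearest) {
  d <- dim(arr)
  centre <- (d[1:3] - 1) / 2
  Minv <- solve(A)
  shift <- -as.vector(Minv %*% t_vox)
  if (length(d) == 3L) {
    cpp_affine_sample(arr, d, Minv, centre, shift, nearest)
  } else {
    out <- array(0, dim = d)
    for (c in seq_len(d[4])) {
      out[, , , c] <- cpp_affine_sample(arr[, , , c], d[1:3], Minv, centre,
                                        shift, nearest)
    }
    out
  }
}

#' Random affine augmentation of an aligned sample
#'
#' Draws one rotation (uniform within the amplitude, about one randomly
#' chosen axis, in physical space), one sagittal-plane scaling and one
#' sagittal-plane translation, and applies the identical geometric
#' transform to every image channel (linear interpolation) and every
#' label channel (nearest interpolation, re-binarised).
#'
#' @param images List of 3D arrays (the contrasts), or a single array.
#' @param labels 4D binary array, or `NULL`.
#' @param spacing Voxel spacing, mm (for anisotropy-correct rotation).
#' @param cfg A [train_config()] supplying the amplitudes.
#' @return List with `images`, `labels` and `transform` (the drawn
#'   parameters and voxel-space matrix).
#' @export
augment <- function(images, labels, spacing, cfg = train_config()) {
  single <- !is.list(images)
  if (single) images <- list(images)
  dims <- dim(images[[1]])[1:3]
  tf <- draw_affine(dims, spacing, cfg)
  images <- lapply(images, apply_affine, A = tf$A, t_vox = tf$translate_vox,
                   nearest = FALSE)
  if (!is.null(labels)) {
    labels <- apply_affine(labels, tf$A, tf$translate_vox, nearest = TRUE)
    labels[labels != 0] <- 1
  }
  list(images = if (single) images[[1]] else images, labels = labels,
       transform = tf)
}

#' Split a cohort into train/validation/test by subject
#'
#' Subject-level split with fractions (0.6, 0.2, 0.2) by default;
#' validation and test sizes are floored and the remainder goes to
#' training. Reproducible from the seed; seeds 1..12 give the repeated
#' random splittings used for aggregation.
#'
#' @param manifest Data frame with a `subject_id` column (or a
#'   `phantom_cohort`).
#' @param fractions Numeric length-3 summing to 1.
#' @param seed Split seed.
#' @return A tibble `subject_id`, `split` with attribute `"seed"`.
#' @export
split_dataset <- function(manifest, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (inherits(manifest, "phantom_cohort")) manifest <- manifest$manifest
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3L)
  n <- nrow(manifest)
  if (n < 3L) stop("need at least 3 subjects to split", call. = FALSE)
  n_val <- floor(n * fractions[2])
  n_test <- floor(n * fractions[3])
  n_train <- n - n_val - n_test
  ord <- with_seed(seed, sample.int(n))
  split <- rep(NA_character_, n)
  split[ord[seq_len(n_train)]] <- "train"
  split[ord[n_train + seq_len(n_val)]] <- "validation"
  split[ord[n_train + n_val + seq_len(n_test)]] <- "test"
  out <- tibble::tibble(subject_id = manifest$subject_id, split = split)
  attr(out, "seed") <- as.integer(seed)
  out
}

# ---- optimiser ----

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
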