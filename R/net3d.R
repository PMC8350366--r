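# Modified 3D U-Net: encoder-decoder with instance normalisation, leaky
# ReLU, dropout, and deep supervision realised as 1x1x1 segmentation heads
# at the two coarsest decoder levels whose logits are trilinearly
# upsampled and summed into the final logits before the sigmoid.
#
# The network is a computation-graph contract implemented directly:
# `unet_forward()` runs the graph and (in training mode) keeps the caches
# that `unet_backward()` consumes to produce exact analytic gradients.

#' U-Net configuration
#'
#' @param in_channels Input channels: 1 for the cord localizer (T2w), 2
#'   for the tumor segmenter (Gd-T1w + T2w).
#' @param out_channels Output channels: 1 (cord) or 4 (tumor, cavity,
#'   edema, whole).
#' @param depth Number of downsampling levels (default 4). Input patch
#'   dimensions must be divisible by `2^depth`.
#' @param base_filters Filters of the first convolution (8 for the
#'   localizer, 16 for the segmenter); doubles at each level.
#' @param dropout_rate Dropout probability applied after each encoder
#'   block during training.
#' @param leaky_slope Negative-region slope of the leaky ReLU.
#' @param deep_supervision Add auxiliary segmentation heads at the two
#'   coarsest decoder levels (default `TRUE`; ignored when `depth < 2`).
#' @return A `unet_config` list.
#' @export
unet_config <- function(in_channels = 1L, out_channels = 1L, depth = 4L,
                        base_filters = 8L, dropout_rate = 0.3,
                        leaky_slope = 0.01, deep_supervision = TRUE) {
  stopifnot(depth >= 1L, base_filters >= 1L, in_channels >= 1L,
            out_channels >= 1L, dropout_rate >= 0, dropout_rate < 1)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 dropout_rate = dropout_rate,
                 leaky_slope = leaky_slope,
                 deep_supervision = isTRUE(deep_supervision)),
            class = "unet_config")
}

# Deep-supervision decoder levels: the two coarsest, excluding the
# full-resolution level (its head is the main one).
ds_levels <- function(cfg) {
  if (!cfg$deep_supervision) return(integer(0))
  lv <- c(cfg$depth - 1L, cfg$depth - 2L)
  lv[lv >= 1L]
}

unet_layer_plan <- function(cfg) {
  f <- cfg$base_filters * 2^(0:cfg$depth)
  rows <- list()
  add <- function(name, type, cin, cout, k) {
    n <- if (type == "conv") k^3 * cin * cout + cout else 2 * cout
    rows[[length(rows) + 1]] <<- tibble::tibble(
      name = name, type = type, in_ch = cin, out_ch = cout, k = k, n_params = n)
  }
  for (i in 0:cfg$depth) {
    cin <- if (i == 0) cfg$in_channels else f[i]
    add(sprintf("enc%d_conv1", i), "conv", cin, f[i + 1], 3L)
    add(sprintf("enc%d_in1", i), "inorm", f[i + 1], f[i + 1], 0L)
    add(sprintf("enc%d_conv2", i), "conv", f[i + 1], f[i + 1], 3L)
    add(sprintf("enc%d_in2", i), "inorm", f[i + 1], f[i + 1], 0L)
  }
  for (j in (cfg$depth - 1):0) {
    # channel projection after trilinear upsampling (1x1x1)
    add(sprintf("dec%d_up", j), "conv", f[j + 2], f[j + 1], 1L)
    add(sprintf("dec%d_upin", j), "inorm", f[j + 1], f[j + 1], 0L)
    add(sprintf("dec%d_conv1", j), "conv", 2L * f[j + 1], f[j + 1], 3L)
    add(sprintf("dec%d_in1", j), "inorm", f[j + 1], f[j + 1], 0L)
    add(sprintf("dec%d_conv2", j), "conv", f[j + 1], f[j + 1], 3L)
    add(sprintf("dec%d_in2", j), "inorm", f[j + 1], f[j + 1], 0L)
  }
  add("head", "conv", f[1], cfg$out_channels, 1L)
  for (j in ds_levels(cfg)) {
    add(sprintf("ds%d", j), "conv", f[j + 1], cfg$out_channels, 1L)
  }
  dplyr::bind_rows(rows)
}

#' Build a modified 3D U-Net
#'
#' Instantiates the network parameters (He initialisation for
#' convolutions, unit gain for instance normalisation) and the
#' architecture table.
#'
#' @param cfg A [unet_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A `unet_model` with elements `cfg`, `params` (flat named list)
#'   and `architecture` (tibble of layers with parameter counts).
#' @export
build_unet <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "unet_config"))
  plan <- unet_layer_plan(cfg)
  params <- with_seed(seed, {
    p <- list()
    for (r in seq_len(nrow(plan))) {
      nm <- plan$name[r]
      if (plan$type[r] == "conv") {
        fan_in <- plan$k[r]^3 * plan$in_ch[r]
        p[[paste0(nm, "_W")]] <- matrix(
          stats::rnorm(fan_in * plan$out_ch[r], sd = sqrt(2 / fan_in)),
          nrow = fan_in, ncol = plan$out_ch[r])
        p[[paste0(nm, "_b")]] <- rep(0, plan$out_ch[r])
      } else {
        p[[paste0(nm, "_g")]] <- rep(1, plan$out_ch[r])
        p[[paste0(nm, "_b")]] <- rep(0, plan$out_ch[r])
      }
    }
    p
  })
  structure(list(cfg = cfg, params = params, architecture = plan),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> depth %d, base %d, %d -> %d channels, %s deep supervision\n",
              x$cfg$depth, x$cfg$base_filters, x$cfg$in_channels,
              x$cfg$out_channels,
              if (length(ds_levels(x$cfg))) "with" else "no"))
  cat(sprintf("  %d layers, %d parameters\n", nrow(x$architecture),
              n_params(x)))
  invisible(x)
}

#' Total parameter count of a network
#' @param model A `unet_model`.
#' @return Integer.
#' @export
n_params <- function(model) sum(vapply(model$params, length, integer(1)))

check_patch_dims <- function(cfg, d) {
  if (any(d[1:3] %% 2^cfg$depth != 0)) {
    stop(sprintf("patch dimensions (%s) must be divisible by 2^depth = %d",
                 paste(d[1:3], collapse = "x"), 2^cfg$depth), call. = FALSE)
  }
  if (d[4] != cfg$in_channels) {
    stop(sprintf("input has %d channels, config expects %d", d[4],
                 cfg$in_channels), call. = FALSE)
  }
}

conv_block_fwd <- function(params, name, x, slope) {
  c1 <- nn_conv_fwd(params, paste0(name, "_conv1"), x, 3L)
  a1 <- nn_inlrelu_fwd(params, paste0(name, "_in1"), c1$y, slope)
  c2 <- nn_conv_fwd(params, paste0(name, "_conv2"), a1$y, 3L)
  a2 <- nn_inlrelu_fwd(params, paste0(name, "_in2"), c2$y, slope)
  list(y = a2$y, cache = list(c1 = c1$cache, a1 = a1$cache,
                              c2 = c2$cache, a2 = a2$cache))
}

conv_block_bwd <- function(params, cache, gy, grads, slope) {
  r <- nn_inlrelu_bwd(params, cache$a2, gy, grads); grads <- r$grads
  r <- nn_conv_bwd(params, cache$c2, r$dx, grads); grads <- r$grads
  r <- nn_inlrelu_bwd(params, cache$a1, r$dx, grads); grads <- r$grads
  r <- nn_conv_bwd(params, cache$c1, r$dx, grads); grads <- r$grads
  list(dx = r$dx, grads = grads)
}

# Full forward pass. x: (X, Y, Z, in_channels). Returns sigmoid
# probabilities, pre-sigmoid logits and (training mode) the cache.
unet_forward <- function(model, x, training = FALSE) {
  cfg <- model$cfg
  p <- model$params
  check_patch_dims(cfg, dim(x))
  D <- cfg$depth
  cache <- list(enc = vector("list", D + 1), pool = vector("list", D),
                drop = vector("list", D + 1), dec = vector("list", D),
                up = vector("list", D), upact = vector("list", D),
                cat_split = vector("list", D))
  skips <- vector("list", D)
  cur <- x
  for (i in 0:D) {
    blk <- conv_block_fwd(p, sprintf("enc%d", i), cur, cfg$leaky_slope)
    cache$enc[[i + 1]] <- blk$cache
    dr <- nn_dropout_fwd(blk$y, cfg$dropout_rate, training)
    cache$drop[i + 1] <- list(dr$cache) # may be NULL; keep the slot
    if (i < D) {
      skips[[i + 1]] <- dr$y
      mp <- nn_maxpool_fwd(dr$y)
      cache$pool[[i + 1]] <- mp$cache
      cur <- mp$y
    } else {
      cur <- dr$y
    }
  }
  dec_out <- vector("list", D)
  for (j in (D - 1):0) {
    up <- nn_upsample_fwd(cur)
    cache$up[[j + 1]] <- dim(cur)
    uc <- nn_conv_fwd(p, sprintf("dec%d_up", j), up, 1L)
    cache$upconv <- c(cache$upconv, stats::setNames(list(uc$cache), as.character(j)))
    ua <- nn_inlrelu_fwd(p, sprintf("dec%d_upin", j), uc$y, cfg$leaky_slope)
    cache$upact[[j + 1]] <- ua$cache
    skip <- skips[[j + 1]]
    xcat <- array(c(skip, ua$y), dim = c(dim(skip)[1:3], dim(skip)[4] + dim(ua$y)[4]))
    cache$cat_split[[j + 1]] <- dim(skip)[4]
    blk <- conv_block_fwd(p, sprintf("dec%d", j), xcat, cfg$leaky_slope)
    cache$dec[[j + 1]] <- blk$cache
    dec_out[[j + 1]] <- blk$y
    cur <- blk$y
  }
  head <- nn_conv_fwd(p, "head", dec_out[[1]], 1L)
  cache$head <- head$cache
  logits <- head$y
  cache$ds <- list()
  for (j in ds_levels(cfg)) {
    dsc <- nn_conv_fwd(p, sprintf("ds%d", j), dec_out[[j + 1]], 1L)
    cache$ds[[as.character(j)]] <- dsc$cache
    t <- dsc$y
    for (s in seq_len(j)) t <- nn_upsample_fwd(t)
    logits <- logits + t
  }
  list(prob = sigmoid(logits), logits = logits,
       cache = if (training) cache else NULL)
}

# Backward pass from d(loss)/d(logits); returns the parameter-gradient
# list aligned with model$params.
unet_backward <- function(model, cache, dlogits) {
  cfg <- model$cfg
  p <- model$params
  D <- cfg$depth
  grads <- lapply(p, function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else rep(0, length(x)))
  ddec <- vector("list", D)

  r <- nn_conv_bwd(p, cache$head, dlogits, grads); grads <- r$grads
  ddec[[1]] <- r$dx
  for (j in ds_levels(cfg)) {
    g <- dlogits
    # transpose of the j-fold trilinear upsampling chain
    for (s in seq_len(j)) {
      half <- dim(g); half <- c(half[1:3] %/% 2L, cfg$out_channels)
      g <- nn_upsample_bwd(g, half)
    }
    r <- nn_conv_bwd(p, cache$ds[[as.character(j)]], g, grads); grads <- r$grads
    ddec[[j + 1]] <- if (is.null(ddec[[j + 1]])) r$dx else ddec[[j + 1]] + r$dx
  }

  dbottom <- NULL
  for (j in 0:(D - 1)) {
    gy <- ddec[[j + 1]]
    r <- conv_block_bwd(p, cache$dec[[j + 1]], gy, grads, cfg$leaky_slope)
    grads <- r$grads
    nskip <- cache$cat_split[[j + 1]]
    d <- dim(r$dx)
    dskip <- r$dx[, , , seq_len(nskip), drop = FALSE]
    dup <- r$dx[, , , (nskip + 1):d[4], drop = FALSE]
    cache$dskip[[j + 1]] <- dskip
    r2 <- nn_inlrelu_bwd(p, cache$upact[[j + 1]], dup, grads); grads <- r2$grads
    r2 <- nn_conv_bwd(p, cache$upconv[[as.character(j)]], r2$dx, grads)
    grads <- r2$grads
    dprev <- nn_upsample_bwd(r2$dx, cache$up[[j + 1]])
    if (j == D - 1) {
      dbottom <- dprev
    } else {
      ddec[[j + 2]] <- if (is.null(ddec[[j + 2]])) dprev else ddec[[j + 2]] + dprev
    }
  }

  dcur <- dbottom
  for (i in D:0) {
    dcur <- nn_dropout_bwd(cache$drop[[i + 1]], dcur)
    r <- conv_block_bwd(p, cache$enc[[i + 1]], dcur, grads, cfg$leaky_slope)
    grads <- r$grads
    if (i > 0) {
      # gradient flowing to the previous level: through this level's
      # pooling, plus the skip-connection contribution saved earlier
      dcur <- nn_maxpool_bwd(cache$pool[[i]], r$dx) + cache$dskip[[i]]
    }
  }
  grads
}

#' Run inference on one patch
#'
#' Deterministic forward pass (dropout disabled). Output channels are
#' independent sigmoids — not softmax-normalised — so per-voxel channel
#' sums may exceed 1; this is what allows a whole-lesion channel alongside
#' the structure channels.
#'
#' @param model A `unet_model`.
#' @param patch 4D array `(X, Y, Z, in_channels)`, dimensions divisible by
#'   `2^depth`.
#' @return 4D array `(X, Y, Z, out_channels)` of probabilities in (0, 1).
#' @export
forward_infer <- function(model, patch) {
  if (length(dim(patch)) == 3L) {
    dim(patch) <- c(dim(patch), 1L)
  }
  unet_forward(model, patch, training = FALSE)$prob
}
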