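# NIfTI I/O and deterministic spatial/intensity preprocessing.
#
# The pipeline operates in a standard space of (1, 1, 2) mm voxels on a
# fixed centre crop; every preprocessing step records enough geometry to
# map predictions back onto the native scan.

CANONICAL_ORIENTATION <- "SAR" # axis 1 -> Superior, 2 -> Anterior, 3 -> Right

#' Preprocessing configuration
#'
#' @param target_spacing Standard-space voxel spacing in mm
#'   (superior-inferior, anterior-posterior, right-left). Default
#'   `c(1, 1, 2)`.
#' @param crop_shape Fixed centre crop-or-pad size in voxels. Default
#'   `c(512, 256, 32)`, i.e. a 51.2 x 25.6 x 6.4 cm field of view at the
#'   default spacing, sized for adult spinal cord anatomy.
#' @return A `preproc_config` list.
#' @export
preproc_config <- function(target_spacing = c(1, 1, 2),
                           crop_shape = c(512L, 256L, 32L)) {
  target_spacing <- as.numeric(target_spacing)
  crop_shape <- as.integer(crop_shape)
  stopifnot(length(target_spacing) == 3L, all(target_spacing > 0),
            length(crop_shape) == 3L, all(crop_shape > 0))
  structure(list(target_spacing = target_spacing, crop_shape = crop_shape),
            class = "preproc_config")
}

canonical_affine <- function(spacing) {
  a <- matrix(0, 4, 4)
  a[3, 1] <- spacing[1] # axis 1 steps along world +z (superior)
  a[2, 2] <- spacing[2] # axis 2 along world +y (anterior)
  a[1, 3] <- spacing[3] # axis 3 along world +x (right)
  a[4, 4] <- 1
  a
}

#' Read a NIfTI volume
#'
#' Reads a 3D (image) or 4D (multi-channel label) NIfTI file, reorients
#' the data to the pipeline's canonical axis order (superior-inferior,
#' anterior-posterior, right-left) when the header carries an orientation,
#' and extracts the voxel spacing.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return An `image_volume` for 3D files; a `label_volume` for 4-channel
#'   4D files (channel order tumor, cavity, edema, whole).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  ori <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (!is.na(ori) && ori != CANONICAL_ORIENTATION) {
    hdr <- RNifti::niftiHeader(img)
    if (hdr$qform_code > 0 || hdr$sform_code > 0) {
      RNifti::orientation(img) <- CANONICAL_ORIENTATION
    }
  }
  sp <- RNifti::pixdim(img)[1:3]
  d <- dim(img)
  dat <- array(as.numeric(img), dim = d)
  if (length(d) == 3L) {
    image_volume(dat, sp)
  } else if (length(d) == 4L && d[4] == 4L) {
    label_volume(dat, sp)
  } else {
    stop("unsupported NIfTI dimensionality: ", paste(d, collapse = "x"),
         call. = FALSE)
  }
}

#' Write a volume to NIfTI
#'
#' Writes an `image_volume` (3D) or `label_volume` (4D, channel order
#' tumor, cavity, edema, whole) with voxel spacing and the canonical
#' orientation encoded in the header.
#'
#' @param vol An `image_volume` or `label_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::qform(img) <- structure(canonical_affine(vol$spacing), code = 2L)
  nd <- length(dim(vol$data))
  RNifti::pixdim(img) <- if (nd == 4L) c(vol$spacing, 1) else vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume to a target spacing
#'
#' Grid size per axis is `round(extent / target_spacing)` (round half to
#' even, at least 1 voxel), so physical extent is preserved to within one
#' voxel per axis. Voxel centres follow the half-voxel convention.
#'
#' @param vol An `image_volume`.
#' @param target_spacing Numeric length-3, mm; strictly positive.
#' @param interp `"linear"` for images, `"nearest"` for masks (keeps
#'   binary masks binary).
#' @return Resampled `image_volume`.
#' @export
resample <- function(vol, target_spacing, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0)) {
    stop("`target_spacing` must be 3 strictly positive numbers", call. = FALSE)
  }
  d <- dim(vol$data)
  out_dims <- pmax(1L, as.integer(round_even(d * vol$spacing / target_spacing)))
  out <- cpp_resample(vol$data, as.integer(d), vol$spacing,
                      out_dims, target_spacing, interp == "nearest")
  image_volume(out, target_spacing)
}

new_spatial_record <- function(native_shape, native_spacing, std_spacing,
                               resampled_shape, crop_lo, crop_shape) {
  structure(list(native_shape = as.integer(native_shape),
                 native_spacing = as.numeric(native_spacing),
                 std_spacing = as.numeric(std_spacing),
                 resampled_shape = as.integer(resampled_shape),
                 crop_lo = as.integer(crop_lo),
                 crop_shape = as.integer(crop_shape)),
            class = "spatial_record")
}

#' @export
print.spatial_record <- function(x, ...) {
  cat(sprintf("<spatial_record> native %s @ (%s) mm -> resampled %s @ (%s) mm -> crop %s (lo %s)\n",
              paste(x$native_shape, collapse = "x"),
              paste(x$native_spacing, collapse = ","),
              paste(x$resampled_shape, collapse = "x"),
              paste(x$std_spacing, collapse = ","),
              paste(x$crop_shape, collapse = "x"),
              paste(x$crop_lo, collapse = ",")))
  invisible(x)
}

crop_pad_array <- function(arr, crop_shape, fill = 0) {
  d <- dim(arr)[1:3]
  t <- as.integer(crop_shape)
  crop_lo <- ifelse(d >= t, (d - t) %/% 2L, -((t - d) %/% 2L))
  out <- array(fill, dim = t)
  is_ <- pmax(0L, crop_lo)                  # source start (0-based)
  ie <- pmin(d, crop_lo + t)                # source end (exclusive)
  ds <- is_ - crop_lo                       # dest start (0-based)
  out[(ds[1] + 1):(ds[1] + ie[1] - is_[1]),
      (ds[2] + 1):(ds[2] + ie[2] - is_[2]),
      (ds[3] + 1):(ds[3] + ie[3] - is_[3])] <-
    arr[(is_[1] + 1):ie[1], (is_[2] + 1):ie[2], (is_[3] + 1):ie[3]]
  list(data = out, crop_lo = crop_lo)
}

#' Centre crop-or-pad to a fixed shape
#'
#' Axes larger than the target are centre-cropped; smaller axes are
#' symmetrically zero-padded. Odd differences put the extra voxel on the
#' high-index side. The returned record maps any output voxel back to the
#' input grid.
#'
#' @param vol An `image_volume`.
#' @param crop_shape Integer length-3 target shape.
#' @return List with elements `vol` (shape exactly `crop_shape`) and
#'   `record` (a `spatial_record`).
#' @export
center_crop_or_pad <- function(vol, crop_shape) {
  cp <- crop_pad_array(vol$data, crop_shape)
  rec <- new_spatial_record(dim(vol$data), vol$spacing, vol$spacing,
                            dim(vol$data), cp$crop_lo, crop_shape)
  list(vol = image_volume(cp$data, vol$spacing), record = rec)
}

#' Z-score intensity normalisation
#'
#' Subtracts the mean intensity and divides by the standard deviation over
#' all voxels, so the output has mean 0 and standard deviation 1.
#' Constant-intensity volumes are rejected rather than silently producing
#' NaN.
#'
#' @param vol An `image_volume`.
#' @return Normalised `image_volume`.
#' @export
zscore_normalize <- function(vol) {
  m <- mean(vol$data)
  s <- sqrt(mean((vol$data - m)^2)) # population sd: {0,2} maps to {-1,+1}
  if (!is.finite(s) || s < 1e-12) {
    stop("constant-intensity volume: z-score normalisation is undefined",
         call. = FALSE)
  }
  image_volume((vol$data - m) / s, vol$spacing)
}

#' Preprocess one volume to standard space
#'
#' Composes the full spatial chain: resample to the target spacing, centre
#' crop-or-pad to the fixed shape, and (for images) z-score normalise.
#'
#' @param vol An `image_volume`.
#' @param cfg A [preproc_config()].
#' @param kind `"image"` (linear resampling + normalisation) or `"mask"`
#'   (nearest resampling, no normalisation).
#' @return List `vol` (standard space) and `record` (a `spatial_record`
#'   covering resample + crop).
#' @export
preprocess_volume <- function(vol, cfg = preproc_config(),
                              kind = c("image", "mask")) {
  kind <- match.arg(kind)
  native_shape <- dim(vol$data)
  native_spacing <- vol$spacing
  rs <- resample(vol, cfg$target_spacing,
                 interp = if (kind == "image") "linear" else "nearest")
  cp <- crop_pad_array(rs$data, cfg$crop_shape)
  out <- image_volume(cp$data, cfg$target_spacing)
  if (kind == "image") out <- zscore_normalize(out)
  rec <- new_spatial_record(native_shape, native_spacing, cfg$target_spacing,
                            dim(rs$data), cp$crop_lo, cfg$crop_shape)
  list(vol = out, record = rec)
}

# Undo the crop/pad: place a standard-space 3D array back onto the
# pre-crop resampled grid.
uncrop_array <- function(arr, record) {
  out <- array(0, dim = record$resampled_shape)
  lo <- record$crop_lo
  t <- record$crop_shape
  rs <- record$resampled_shape
  is_ <- pmax(0L, lo)
  ie <- pmin(rs, lo + t)
  ds <- is_ - lo
  out[(is_[1] + 1):ie[1], (is_[2] + 1):ie[2], (is_[3] + 1):ie[3]] <-
    arr[(ds[1] + 1):(ds[1] + ie[1] - is_[1]),
        (ds[2] + 1):(ds[2] + ie[2] - is_[2]),
        (ds[3] + 1):(ds[3] + ie[3] - is_[3])]
  out
}

#' Map a standard-space prediction back to native space
#'
#' Inverts the preprocessing chain recorded by [preprocess_volume()] (or
#' [center_crop_or_pad()]): un-crops/un-pads onto the resampled grid, then
#' resamples back to the native grid. Labels use nearest interpolation so
#' masks stay binary.
#'
#' @param pred A `label_volume` or `image_volume` in standard space (shape
#'   must equal the record's crop shape).
#' @param record The `spatial_record` produced for the same subject.
#' @return Object of the same class with native shape and spacing.
#' @export
invert_to_native <- function(pred, record) {
  if (!inherits(record, "spatial_record")) {
    stop("`record` must be a spatial_record", call. = FALSE)
  }
  d <- dim(pred$data)[1:3]
  if (!all(d == record$crop_shape)) {
    stop("prediction shape does not match the record's crop shape",
         call. = FALSE)
  }
  invert_one <- function(arr, nearest) {
    full <- uncrop_array(arr, record)
    cpp_resample(full, record$resampled_shape, record$std_spacing,
                 record$native_shape, record$native_spacing, nearest)
  }
  if (inherits(pred, "label_volume")) {
    ch <- lapply(seq_len(dim(pred$data)[4]),
                 function(i) invert_one(pred$data[, , , i], nearest = TRUE))
    label_volume(array(unlist(ch), dim = c(record$native_shape, 4L)),
                 record$native_spacing)
  } else {
    image_volume(invert_one(pred$data, nearest = FALSE),
                 record$native_spacing)
  }
}
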