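# Synthetic two-contrast spinal cord tumor phantoms.
#
# Each phantom is a curved tubular cord with a CSF sheath inside a
# background tissue block, carrying an intramedullary tumor and,
# probabilistically, an adjacent edema and a (possibly disjoint) syrinx
# cavity. The two contrasts follow the qualitative radiology of IMSCT:
# on T2w, cavity > edema > tumor >= cord > background in mean intensity;
# on Gd-enhanced T1w, tumor enhancement depends on tumor type
# (hemangioblastoma strong, ependymoma moderate, astrocytoma none or
# moderate) and the cavity never enhances.

TUMOR_TYPES <- c("astrocytoma", "ependymoma", "hemangioblastoma")
# cohort proportions of the three main IMSCT types (astro:epend:heman)
TUMOR_TYPE_WEIGHTS <- c(astrocytoma = 101, ependymoma = 122, hemangioblastoma = 120)

#' Phantom cohort specification
#'
#' Defines the study conditions the generator emulates: sagittal volumes
#' with heterogeneous native resolution (in-plane 0.34-1.33 mm, slice
#' thickness 1.5-5.2 mm), a 13 mm-diameter curved cord inside a 30 mm
#' localization tube, and cohort class imbalance (67% of subjects have a
#' cavity, 51% have edema).
#'
#' @param extent_mm Physical field of view in mm (superior-inferior,
#'   anterior-posterior, right-left). The native voxel grid is derived
#'   from this extent and the per-subject drawn spacing, so the
#'   resampler is genuinely exercised. Default `c(96, 48, 48)`
#'   (desk-scale).
#' @param inplane_range Range the sagittal in-plane resolution (mm) is
#'   drawn from, applied to the first two axes.
#' @param thickness_range Range the slice thickness (mm, right-left axis)
#'   is drawn from.
#' @param tumor_type One of `"astrocytoma"`, `"ependymoma"`,
#'   `"hemangioblastoma"`, or `NULL` to draw per subject with cohort
#'   weights 101:122:120.
#' @param p_cavity,p_edema Probability a subject has a cavity / edema.
#' @param intensity_table Mean intensity per (tissue, contrast) pair plus
#'   enhancement amplitudes; see defaults. Must respect the T2w ordering
#'   cavity > edema > tumor >= cord > background.
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   units).
#' @param curvature_amp Amplitude (mm) of the cord centreline sinusoid.
#' @param cord_diameter,tube_diameter Cord and localization-tube
#'   diameters in mm (13 and 30).
#' @param csf_thickness CSF sheath thickness in mm.
#' @param n_tumor_blobs Number of tumor blobs (multifocal lesions are
#'   optional; default 1).
#' @param volumes_cm3 Median/log-sd of the log-normal component volume
#'   draws, scaled to the phantom field of view.
#' @param seed Default master seed used by [generate_cohort()].
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(extent_mm = c(96, 48, 48),
                         inplane_range = c(0.34, 1.33),
                         thickness_range = c(1.5, 5.2),
                         tumor_type = NULL,
                         p_cavity = 0.67,
                         p_edema = 0.51,
                         intensity_table = NULL,
                         noise_sd = 2,
                         curvature_amp = 3,
                         cord_diameter = 13,
                         tube_diameter = 30,
                         csf_thickness = 3,
                         n_tumor_blobs = 1L,
                         volumes_cm3 = list(tumor = c(median = 1.2, sdlog = 0.35),
                                            cavity = c(median = 1.5, sdlog = 0.35)),
                         seed = 1L) {
  if (is.null(intensity_table)) {
    intensity_table <- list(
      t2w = c(background = 10, cord = 40, csf = 75, tumor = 50,
              edema = 65, cavity = 90),
      gd_t1w = c(background = 10, cord = 45, csf = 25, tumor = 45,
                 edema = 40, cavity = 25),
      enhancement = c(none = 0, moderate = 20, strong = 40))
  }
  stopifnot(length(extent_mm) == 3L, all(extent_mm > 0),
            all(inplane_range > 0), all(thickness_range > 0),
            p_cavity >= 0, p_cavity <= 1, p_edema >= 0, p_edema <= 1,
            noise_sd >= 0, curvature_amp >= 0,
            cord_diameter > 0, tube_diameter > cord_diameter,
            n_tumor_blobs >= 1L)
  t2 <- intensity_table$t2w
  if (!(t2["cavity"] > t2["edema"] && t2["edema"] > t2["tumor"] &&
        t2["tumor"] >= t2["cord"] && t2["cord"] > t2["background"])) {
    stop("intensity_table violates the T2w ordering cavity > edema > tumor >= cord > background",
         call. = FALSE)
  }
  if (!is.null(tumor_type)) tumor_type <- match.arg(tumor_type, TUMOR_TYPES)
  structure(list(extent_mm = as.numeric(extent_mm),
                 inplane_range = inplane_range,
                 thickness_range = thickness_range,
                 tumor_type = tumor_type,
                 p_cavity = p_cavity, p_edema = p_edema,
                 intensity_table = intensity_table,
                 noise_sd = noise_sd, curvature_amp = curvature_amp,
                 cord_diameter = cord_diameter,
                 tube_diameter = tube_diameter,
                 csf_thickness = csf_thickness,
                 n_tumor_blobs = as.integer(n_tumor_blobs),
                 volumes_cm3 = volumes_cm3,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Radial squared distance (mm^2) of every voxel from the centreline, as a
# 3D array. Centreline is given per S-I slice in mm.
radial_dist2 <- function(grid, spacing, centre_y, centre_z) {
  y_mm <- (seq_len(grid[2]) - 0.5) * spacing[2]
  z_mm <- (seq_len(grid[3]) - 0.5) * spacing[3]
  out <- array(0, dim = grid)
  for (i in seq_len(grid[1])) {
    out[i, , ] <- outer((y_mm - centre_y[i])^2, (z_mm - centre_z[i])^2, `+`)
  }
  out
}

rasterize_cord_core <- function(grid, spacing, curvature_amp,
                                cord_diameter = 13, tube_diameter = 30) {
  extent <- grid * spacing
  if (curvature_amp > 0) {
    wavelength <- stats::runif(1, 0.7, 1.3) * extent[1]
    phase <- stats::runif(2, 0, 2 * pi)
  } else {
    wavelength <- extent[1]
    phase <- c(0, 0)
  }
  s_mm <- (seq_len(grid[1]) - 0.5) * spacing[1]
  centre_y <- extent[2] / 2 + curvature_amp * sin(2 * pi * s_mm / wavelength + phase[1])
  centre_z <- extent[3] / 2 + (curvature_amp / 3) * sin(2 * pi * s_mm / wavelength + phase[2])
  r2 <- radial_dist2(grid, spacing, centre_y, centre_z)
  list(centerline = cbind(s = s_mm, y = centre_y, z = centre_z),
       cord_mask = (r2 <= (cord_diameter / 2)^2) * 1,
       tube_mask = (r2 <= (tube_diameter / 2)^2) * 1,
       r2 = r2)
}

#' Rasterize a curved cord and its localization tube
#'
#' Builds a smooth sinusoidal centreline running the full
#' superior-inferior extent, a ~13 mm-diameter cord tube around it, and
#' the 30 mm-diameter localization tube that strictly contains the cord.
#'
#' @param grid_shape Integer length-3 voxel grid.
#' @param spacing Voxel spacing, mm.
#' @param curvature_amp Sinusoid amplitude, mm; 0 gives a straight
#'   centreline at the transverse centre.
#' @param seed Integer seed (wavelength/phase draws).
#' @return List with `centerline` (matrix of per-slice mm coordinates),
#'   `cord_mask` and `tube_mask` (binary 3D arrays).
#' @export
rasterize_cord <- function(grid_shape, spacing, curvature_amp = 3, seed = 1L) {
  spacing <- as.numeric(spacing)
  stopifnot(all(spacing > 0), length(grid_shape) == 3L)
  check_cord_fits(grid_shape * spacing, curvature_amp, 13, 3)
  out <- with_seed(seed, rasterize_cord_core(as.integer(grid_shape), spacing,
                                             curvature_amp))
  out[c("centerline", "cord_mask", "tube_mask")]
}

check_cord_fits <- function(extent, curvature_amp, cord_diameter, csf_thickness) {
  need <- cord_diameter + 2 * csf_thickness + 2 * curvature_amp
  if (min(extent[2:3]) < need) {
    stop(sprintf(paste0("grid too small for cord geometry: transverse extent ",
                        "%.1f mm < required %.1f mm"),
                 min(extent[2:3]), need), call. = FALSE)
  }
  invisible(TRUE)
}

# Ellipsoid aligned with the centreline: half-lengths (a, b, c) in mm,
# centred at S-I position s0 on the centreline.
centerline_ellipsoid <- function(grid, spacing, centerline, s0, abc) {
  s_mm <- centerline[, "s"]
  ds2 <- ((s_mm - s0) / abc[1])^2
  y_mm <- (seq_len(grid[2]) - 0.5) * spacing[2]
  z_mm <- (seq_len(grid[3]) - 0.5) * spacing[3]
  out <- array(0, dim = grid)
  active <- which(ds2 < 1)
  for (i in active) {
    dy2 <- ((y_mm - centerline[i, "y"]) / abc[2])^2
    dz2 <- ((z_mm - centerline[i, "z"]) / abc[3])^2
    out[i, , ] <- (outer(dy2, dz2, `+`) <= 1 - ds2[i]) * 1
  }
  out
}

#' Generate one phantom subject
#'
#' Draws the native resolution, cord geometry, component shapes and
#' intensities for a single subject. Deterministic given
#' `(spec, subject_seed)`.
#'
#' @param spec A [phantom_spec()].
#' @param subject_seed Integer seed for this subject.
#' @param subject_id Identifier string.
#' @return A `subject_record` with elements `gd_t1w`, `t2w`
#'   (`image_volume`), `labels` (`label_volume`), `cord_mask` (binary
#'   `image_volume`, the 30 mm tube) and `meta`.
#' @export
generate_subject <- function(spec, subject_seed, subject_id = sprintf("sub-%06d", subject_seed)) {
  stopifnot(inherits(spec, "phantom_spec"))
  check_cord_fits(spec$extent_mm, spec$curvature_amp, spec$cord_diameter,
                  spec$csf_thickness)
  with_seed(subject_seed, {
    ip <- stats::runif(1, spec$inplane_range[1], spec$inplane_range[2])
    th <- stats::runif(1, spec$thickness_range[1], spec$thickness_range[2])
    spacing <- c(ip, ip, th)
    grid <- pmax(4L, as.integer(round(spec$extent_mm / spacing)))
    extent <- grid * spacing

    cord <- rasterize_cord_core(grid, spacing, spec$curvature_amp,
                                spec$cord_diameter, spec$tube_diameter)
    cord_r <- spec$cord_diameter / 2
    csf_mask <- (cord$r2 <= (cord_r + spec$csf_thickness)^2) & !(cord$cord_mask > 0)

    tumor_type <- spec$tumor_type %||%
      sample(TUMOR_TYPES, 1, prob = TUMOR_TYPE_WEIGHTS)
    has_cavity <- stats::runif(1) < spec$p_cavity
    has_edema <- stats::runif(1) < spec$p_edema

    draw_abc <- function(median_cm3, sdlog) {
      v_mm3 <- stats::rlnorm(1, meanlog = log(median_cm3 * 1000), sdlog = sdlog)
      b <- stats::runif(1, 3.5, min(5.5, cord_r - 0.5))
      cc <- stats::runif(1, 3.5, min(5.5, cord_r - 0.5))
      a <- max(3 * v_mm3 / (4 * pi * b * cc), 2 * spacing[1])
      c(a, b, cc)
    }

    tv <- spec$volumes_cm3$tumor
    abc_t <- draw_abc(tv[["median"]], tv[["sdlog"]])
    s0 <- stats::runif(1, 0.3, 0.7) * extent[1]
    tumor <- centerline_ellipsoid(grid, spacing, cord$centerline, s0, abc_t) *
      cord$cord_mask
    if (spec$n_tumor_blobs > 1L) {
      for (b in seq_len(spec$n_tumor_blobs - 1L)) {
        abc_b <- draw_abc(tv[["median"]] / 2, tv[["sdlog"]])
        sb <- min(max(s0 + sample(c(-1, 1), 1) * stats::runif(1, 15, 30),
                      0.1 * extent[1]), 0.9 * extent[1])
        tumor <- pmin(tumor + centerline_ellipsoid(grid, spacing,
                                                   cord$centerline, sb, abc_b) *
                        cord$cord_mask, 1)
      }
    }

    edema <- array(0, dim = grid)
    if (has_edema) {
      ext_si <- stats::runif(1, 5, 10)
      abc_e <- c(abc_t[1] + ext_si,
                 min(abc_t[2] + 1.5, cord_r - 0.2),
                 min(abc_t[3] + 1.5, cord_r - 0.2))
      edema <- centerline_ellipsoid(grid, spacing, cord$centerline, s0, abc_e) *
        cord$cord_mask * (1 - tumor)
    }

    cavity <- array(0, dim = grid)
    if (has_cavity) {
      cv <- spec$volumes_cm3$cavity
      abc_c <- draw_abc(cv[["median"]], cv[["sdlog"]])
      gap <- stats::runif(1, -4, 18)
      side <- sample(c(-1, 1), 1)
      place_cavity <- function(s1) {
        s1 <- min(max(s1, 0.12 * extent[1]), 0.88 * extent[1])
        centerline_ellipsoid(grid, spacing, cord$centerline, s1, abc_c) *
          cord$cord_mask * (1 - tumor) * (1 - edema)
      }
      off <- abc_t[1] + abc_c[1] + gap
      cavity <- place_cavity(s0 + side * off)
      if (sum(cavity) == 0) cavity <- place_cavity(s0 - side * off)
      if (sum(cavity) == 0) {
        # large lesions can fill the cord: carve a cystic component out of
        # the tumor instead (tumoral cyst), keeping channels disjoint
        cavity <- centerline_ellipsoid(grid, spacing, cord$centerline,
                                       min(max(s0 + side * off,
                                               0.12 * extent[1]),
                                           0.88 * extent[1]), abc_c) *
          cord$cord_mask
        tumor <- tumor * (1 - cavity)
        edema <- edema * (1 - cavity)
      }
    }

    enhancement <- switch(tumor_type,
      hemangioblastoma = "strong",
      ependymoma = "moderate",
      astrocytoma = sample(c("none", "moderate"), 1))

    it <- spec$intensity_table
    paint <- function(base) {
      v <- array(base[["background"]], dim = grid)
      v[cord$cord_mask > 0] <- base[["cord"]]
      v[csf_mask] <- base[["csf"]]
      v[edema > 0] <- base[["edema"]]
      v[tumor > 0] <- base[["tumor"]]
      v[cavity > 0] <- base[["cavity"]]
      v
    }
    t2 <- paint(it$t2w)
    g1 <- paint(it$gd_t1w)
    g1[tumor > 0] <- it$gd_t1w[["tumor"]] + it$enhancement[[enhancement]]
    if (spec$noise_sd > 0) {
      t2 <- t2 + stats::rnorm(length(t2), sd = spec$noise_sd)
      g1 <- g1 + stats::rnorm(length(g1), sd = spec$noise_sd)
    }

    labels <- label_volume(array(c(tumor, cavity, edema), dim = c(grid, 3L)),
                           spacing)
    structure(list(subject_id = subject_id,
                   gd_t1w = image_volume(g1, spacing),
                   t2w = image_volume(t2, spacing),
                   labels = labels,
                   cord_mask = image_volume(cord$tube_mask, spacing),
                   meta = list(tumor_type = tumor_type,
                               has_edema = has_edema,
                               has_cavity = has_cavity,
                               enhancement = enhancement,
                               native_spacing = spacing,
                               seed = as.integer(subject_seed))),
              class = "subject_record")
  })
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s: %s (%s enhancement), edema=%s, cavity=%s\n",
              x$subject_id, x$meta$tumor_type, x$meta$enhancement,
              x$meta$has_edema, x$meta$has_cavity))
  print(x$t2w)
  invisible(x)
}

#' Generate a phantom cohort
#'
#' Generates `n` independent subjects from one master seed (one named
#' substream per subject) and, optionally, writes each subject's four
#' NIfTI files plus a manifest CSV.
#'
#' @param n Number of subjects (>= 1).
#' @param spec A [phantom_spec()].
#' @param seed Master seed; default `spec$seed`.
#' @param outdir Output directory, or `NULL` to keep the cohort in
#'   memory only.
#' @return A `phantom_cohort` list with `subjects` (list of
#'   `subject_record`) and `manifest` (tibble with one row per subject).
#' @export
generate_cohort <- function(n, spec = phantom_spec(), seed = spec$seed,
                            outdir = NULL) {
  stopifnot(n >= 1)
  subjects <- vector("list", n)
  rows <- vector("list", n)
  if (!is.null(outdir) && !dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir, call. = FALSE)
  }
  for (i in seq_len(n)) {
    sid <- sprintf("sub-%03d", i)
    sseed <- substream_seed(seed, paste0("phantom-", i))
    rec <- generate_subject(spec, sseed, subject_id = sid)
    subjects[[i]] <- rec
    rows[[i]] <- tibble::tibble(
      subject_id = sid,
      tumor_type = rec$meta$tumor_type,
      has_edema = rec$meta$has_edema,
      has_cavity = rec$meta$has_cavity,
      spacing_si = rec$meta$native_spacing[1],
      spacing_ap = rec$meta$native_spacing[2],
      spacing_rl = rec$meta$native_spacing[3],
      seed = sseed)
    if (!is.null(outdir)) {
      write_nifti(rec$t2w, file.path(outdir, paste0(sid, "_T2w.nii.gz")))
      write_nifti(rec$gd_t1w, file.path(outdir, paste0(sid, "_GdT1w.nii.gz")))
      write_nifti(rec$labels, file.path(outdir, paste0(sid, "_labels.nii.gz")))
      write_nifti(rec$cord_mask, file.path(outdir, paste0(sid, "_cordmask.nii.gz")))
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(outdir)) {
    utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(subjects = subjects, manifest = manifest, spec = spec,
                 seed = as.integer(seed)),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d subjects (seed %d)\n",
              length(x$subjects), x$seed))
  cat(sprintf("  cavity: %.0f%%, edema: %.0f%%\n",
              100 * mean(x$manifest$has_cavity),
              100 * mean(x$manifest$has_edema)))
  print(table(x$manifest$tumor_type))
  invisible(x)
}
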