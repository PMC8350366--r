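# End-to-end phantom benchmark: generate a desk-scale cohort, train a
# reduced localizer and segmenter, run the cascade on held-out subjects
# and evaluate in standard space. This is the package's reference
# experiment; the acceptance script and the end-to-end tests both run it.

#' Desk-scale experiment configuration
#'
#' A reduced configuration matched to the default 96 x 48 x 48 mm phantom
#' field of view: standard space 96 x 48 x 24 voxels at (1, 1, 2) mm,
#' depth-3 networks (base 4 localizer / base 8 segmenter), 32 x 32 x 16
#' patches with 16 x 16 x 16 stride, and short cosine-annealed training.
#'
#' @param seed Global seed.
#' @param max_epochs Maximum epochs per stage (one cosine annealing
#'   cycle spans this length; 10 is where the desk-scale phantom losses
#'   plateau).
#' @param patience Early-stopping patience.
#' @return A `run_config`.
#' @export
desk_run_config <- function(seed = 1L, max_epochs = 10L, patience = 10L) {
  preproc <- preproc_config(target_spacing = c(1, 1, 2),
                            crop_shape = c(96L, 48L, 24L))
  run_config(
    preproc = preproc,
    phantom = phantom_spec(seed = seed),
    localizer_net = unet_config(1L, 1L, depth = 3L, base_filters = 4L),
    segmenter_net = unet_config(2L, 4L, depth = 3L, base_filters = 8L),
    localizer_train = train_config(batch_size = 1L,
                                   patch_size = preproc$crop_shape,
                                   max_epochs = max_epochs,
                                   patience = patience,
                                   seed = substream_seed(seed, "localizer")),
    segmenter_train = train_config(batch_size = 8L,
                                   patch_size = c(32L, 32L, 16L),
                                   stride = c(16L, 16L, 16L),
                                   max_epochs = max_epochs,
                                   patience = patience,
                                   seed = substream_seed(seed, "segmenter")),
    cascade = cascade_config(localizer_patch = preproc$crop_shape,
                             seg_patch = c(32L, 32L, 16L),
                             seg_stride = c(16L, 16L, 16L)),
    seed = seed)
}

#' Run the end-to-end phantom experiment
#'
#' Generates `n` phantoms, trains both cascade stages on the train split,
#' then runs the full cascade on the held-out test subjects and
#' evaluates in standard space: per-structure Dice (cohort convention,
#' with false positives scoring zero, and restricted to subjects having
#' the structure), localization Dice against the 30 mm tube,
#' bounding-box inclusion of the whole lesion, and detection rates.
#'
#' @param n Cohort size.
#' @param config A `run_config`, e.g. [desk_run_config()].
#' @param verbose Print epoch logs.
#' @return A list: `metrics` (per-subject tibble), `report`
#'   (`metrics_report`), `localization` (per-subject tibble with cord
#'   Dice and bbox inclusion), `summary` (named numeric vector of the
#'   headline statistics), `fits` (the two `trained_model`s), `split`.
#' @export
run_phantom_experiment <- function(n = 40L, config = desk_run_config(),
                                   verbose = FALSE) {
  cohort <- generate_cohort(n, config$phantom,
                            seed = substream_seed(config$seed, "phantom"))
  split <- split_dataset(cohort$manifest,
                         seed = substream_seed(config$seed, "split"))

  fit_loc <- train_model(cohort, "localizer", config$localizer_net,
                         config$localizer_train, config$preproc,
                         config$cascade, split = split, verbose = verbose)
  fit_seg <- train_model(cohort, "segmenter", config$segmenter_net,
                         config$segmenter_train, config$preproc,
                         config$cascade, split = split, verbose = verbose)

  test_ids <- split$subject_id[split$split == "test"]
  ids <- cohort$manifest$subject_id
  test_subjects <- cohort$subjects[match(test_ids, ids)]

  per_subj <- list(); loc_rows <- list()
  for (s in test_subjects) {
    prep <- preprocess_subject(s, config$preproc)
    res <- run_cascade(s, fit_loc$model, fit_seg$model, config$cascade,
                       config$preproc, config$postproc)
    gt_std <- label_volume(prep$labels, config$preproc$target_spacing)
    df <- evaluate_subject(res$std_labels, gt_std,
                           config$preproc$target_spacing, config$metrics,
                           subject_id = s$subject_id)
    per_subj[[s$subject_id]] <- df
    loc_mask <- localize_cord(image_volume(prep$t2w, config$preproc$target_spacing),
                              fit_loc$model, config$cascade)
    incl <- bbox_inclusion(gt_std, res$bbox)
    loc_rows[[s$subject_id]] <- tibble::tibble(
      subject_id = s$subject_id,
      cord_dice = dice_score(loc_mask, prep$cord),
      bbox_fully_contained = incl$fully_contained,
      bbox_fraction = incl$fraction)
  }
  metrics <- dplyr::bind_rows(per_subj)
  localization <- dplyr::bind_rows(loc_rows)
  report <- aggregate_metrics(metrics)

  cohort_dice <- function(st) {
    x <- metrics$dice[metrics$structure == st]
    mean(x, na.rm = TRUE)
  }
  restricted_dice <- function(st) {
    x <- metrics$dice[metrics$structure == st & metrics$gt_present]
    if (!length(x)) NA_real_ else mean(x)
  }
  summary <- c(
    whole_dice = cohort_dice("whole"),
    tumor_dice = cohort_dice("tumor"),
    cavity_dice = cohort_dice("cavity"),
    edema_dice = cohort_dice("edema"),
    cavity_dice_restricted = restricted_dice("cavity"),
    edema_dice_restricted = restricted_dice("edema"),
    localization_dice = mean(localization$cord_dice),
    bbox_inclusion_rate = mean(localization$bbox_fully_contained),
    cavity_fraction = mean(cohort$manifest$has_cavity),
    edema_fraction = mean(cohort$manifest$has_edema))

  list(metrics = metrics, report = report, localization = localization,
       summary = summary, fits = list(localizer = fit_loc, segmenter = fit_seg),
       split = split, manifest = cohort$manifest)
}
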