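# Visual QC: slice views with label overlays, training curves, and
# metric summaries.

#' Plot a sagittal slice of a subject with label overlay
#'
#' @param subject A `subject_record`.
#' @param contrast `"t2w"` or `"gd_t1w"`.
#' @param slice Right-left slice index; defaults to the middle slice.
#' @param labels Overlay the ground-truth labels.
#' @return A ggplot object.
#' @export
plot_subject_slice <- function(subject, contrast = c("t2w", "gd_t1w"),
                               slice = NULL, labels = TRUE) {
  contrast <- match.arg(contrast)
  vol <- subject[[contrast]]
  d <- dim(vol$data)
  slice <- slice %||% ((d[3] + 1) %/% 2)
  df <- expand.grid(si = seq_len(d[1]), ap = seq_len(d[2]))
  df$intensity <- as.vector(vol$data[, , slice])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ap, y = .data$si)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed(ratio = vol$spacing[1] / vol$spacing[2]) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(title = sprintf("%s %s (slice %d)", subject$subject_id,
                                  contrast, slice),
                  x = "anterior-posterior", y = "superior-inferior") +
    ggplot2::theme_minimal()
  if (labels) {
    ov <- NULL
    for (st in c("tumor", "cavity", "edema")) {
      m <- label_channel(subject$labels, st)[, , slice]
      idx <- which(m > 0, arr.ind = TRUE)
      if (nrow(idx)) {
        ov <- rbind(ov, data.frame(si = idx[, 1], ap = idx[, 2],
                                   structure = st))
      }
    }
    if (!is.null(ov)) {
      p <- p + ggplot2::geom_tile(data = ov,
                                  ggplot2::aes(colour = .data$structure),
                                  fill = NA, linewidth = 0.1, alpha = 0.6)
    }
  }
  p
}

#' Training curves of a fitted stage
#'
#' @param object A `trained_model`.
#' @param ... Unused.
#' @return A ggplot object (train and validation loss by epoch).
#' @export
autoplot.trained_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("train_loss", "val_loss"),
                            names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(title = sprintf("%s training", object$stage),
                  y = "multiclass Dice loss") +
    ggplot2::theme_minimal()
}

#' Per-structure Dice summary of a metrics report
#'
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot object (mean +/- sd per structure).
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- object$summary[object$summary$metric == "dice", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$structure, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::labs(y = "Dice (mean +/- sd across splits)", x = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
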