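# broom-style accessors and ggplot2 graphics for the fitted objects.

#' @export
tidy.pedvisit_pretrain <- function(x, ...) x$history

#' @export
glance.pedvisit_pretrain <- function(x, ...) {
  final <- dplyr::filter(x$history, .data$split == "val",
                         .data$epoch == max(.data$epoch))
  tibble::tibble(
    epochs = max(x$history$epoch),
    final_val_loss = final$loss,
    final_val_aps = final$aps,
    final_val_auc = final$auc,
    n_layers = x$config$n_layers,
    d_model = x$config$d_model,
    attention_mode = x$config$attention_mode
  )
}

#' @export
tidy.pedvisit_finetune <- function(x, ...) x$history

#' @export
glance.pedvisit_finetune <- function(x, ...) {
  tibble::tibble(
    task = x$task, n_classes = x$n_classes,
    epochs_run = max(x$history$epoch),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss
  )
}

#' @export
tidy.pedvisit_lr <- function(x, ...) x$history

#' @export
glance.pedvisit_lr <- function(x, ...) {
  tibble::tibble(task = x$task, n_classes = x$n_classes,
                 epochs_run = max(x$history$epoch),
                 best_epoch = x$best_epoch)
}

training_curve_plot <- function(history, title) {
  ggplot2::ggplot(history,
                  ggplot2::aes(x = .data$epoch, y = .data$loss,
                               colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", colour = NULL,
                  title = title) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pedvisit_pretrain <- function(object, ...) {
  training_curve_plot(object$history, "Masked-diagnosis pre-training")
}

#' @export
autoplot.pedvisit_finetune <- function(object, ...) {
  training_curve_plot(object$history,
                      paste0("Fine-tuning (", object$task, ")"))
}

#' @export
autoplot.class_metrics <- function(object, ...) {
  pc <- object$per_class
  if (!is.null(pc$roc)) {
    curves <- tidyr::unnest(dplyr::select(pc, "label", "roc"), "roc")
    return(
      ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                           group = .data$label)) +
        ggplot2::geom_line(alpha = 0.4) +
        ggplot2::geom_abline(linetype = "dashed") +
        ggplot2::labs(x = "false positive rate", y = "true positive rate",
                      title = "Per-class ROC curves") +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(dplyr::filter(pc, !is.na(.data$auc)),
                  ggplot2::aes(x = stats::reorder(.data$label, .data$auc),
                               y = .data$auc)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "one-vs-rest ROC AUC",
                  title = "Per-class AUC") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fairness_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$level, y = .data$mean_auc)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::facet_wrap(~attribute, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "per-patient mean ROC AUC",
                  title = "Subgroup performance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Scatter plot of a 2-D embedding projection
#'
#' @param proj A [project_embeddings_2d()] tibble.
#' @return A ggplot.
#' @export
plot_embedding_map <- function(proj) {
  p <- ggplot2::ggplot(proj, ggplot2::aes(x = .data$x, y = .data$y))
  if ("chapter" %in% names(proj)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$chapter))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::geom_text(ggplot2::aes(label = .data$token), size = 2,
                         vjust = -0.6, check_overlap = TRUE) +
    ggplot2::labs(title = "Token embeddings (t-SNE)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cohort_summary <- function(object, ...) {
  ggplot2::ggplot(object$attributes,
                  ggplot2::aes(x = .data$level, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~attribute, scales = "free") +
    ggplot2::labs(x = NULL, y = "patients", title = "Cohort composition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
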