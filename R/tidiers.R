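#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an FPCM state
#'
#' @param x an `fpcm_state` from [fpcm_segment()].
#' @param ... unused.
#' @return Tibble with one row per cluster: id, centre, eta.
#' @export
tidy.fpcm_state <- function(x, ...) {
  tibble::tibble(cluster = seq_len(nrow(x$V)),
                 center = x$V[, 1],
                 eta = x$eta)
}

#' @rdname tidy.fpcm_state
#' @export
glance.fpcm_state <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$V),
    iterations = x$iterations_run,
    converged = x$converged,
    objective = utils::tail(x$objective_trace, 1))
}

#' @export
autoplot.fpcm_state <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$objective_trace),
                       objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$objective)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(title = "FPCM objective trace", x = "iteration",
                  y = "objective") +
    ggplot2::theme_minimal()
}

#' Tidy a feature-selection result
#'
#' @param x a `dgwo_selection` from [dgwo_select()].
#' @param ... unused.
#' @return Tibble with one row per feature: name, continuous position,
#'   selected flag.
#' @export
tidy.dgwo_selection <- function(x, ...) {
  tibble::tibble(feature = x$all_features,
                 position = x$best_position,
                 selected = x$mask == 1L)
}

#' @rdname tidy.dgwo_selection
#' @export
glance.dgwo_selection <- function(x, ...) {
  tibble::tibble(best_fitness = x$best_fitness,
                 n_selected = x$n_selected,
                 n_features = length(x$mask),
                 iterations = length(x$fitness_trace))
}

#' @export
autoplot.dgwo_selection <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$fitness_trace),
                       best_error = object$fitness_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$best_error)) +
    ggplot2::geom_step() +
    ggplot2::labs(title = "DGWO best-so-far classification error",
                  x = "iteration", y = "CV error") +
    ggplot2::theme_minimal()
}

#' Tidy an evaluation report
#'
#' @param x an [eval_report()].
#' @param ... unused.
#' @return Long tibble (metric, value).
#' @export
tidy.eval_report <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, cols = dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  dplyr::bind_cols(x$metrics, tibble::tibble(auc = x$auc))
}

#' @export
autoplot.eval_report <- function(object, ...) {
  if (is.null(object$roc)) stop("autoplot.eval_report: no ROC (no scores)")
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("ROC (AUC = %.3f)", object$auc),
                  x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Tidy k-fold evaluation results
#'
#' @param x a `kfold_eval` from [kfold_evaluate()].
#' @param ... unused.
#' @return The per-fold metric tibble.
#' @export
tidy.kfold_eval <- function(x, ...) x$folds

#' @rdname tidy.kfold_eval
#' @export
glance.kfold_eval <- function(x, ...) {
  m <- x$summary[x$summary$statistic == "mean", -1]
  s <- x$summary[x$summary$statistic == "sd", -1]
  names(s) <- paste0(names(s), "_sd")
  dplyr::bind_cols(m, s)
}

#' Tidy a trained model's history
#'
#' @param x a `haetn_model`.
#' @param ... unused.
#' @return The per-epoch history tibble.
#' @export
tidy.haetn_model <- function(x, ...) x$history

#' @rdname tidy.haetn_model
#' @export
glance.haetn_model <- function(x, ...) {
  n_par <- sum(vapply(flatten_params(x$params), length, integer(1)))
  last <- x$history[nrow(x$history), ]
  tibble::tibble(epochs = last$epoch, n_parameters = n_par,
                 train_loss = last$loss, train_accuracy = last$accuracy,
                 val_loss = last$val_loss, val_accuracy = last$val_accuracy)
}

#' @export
autoplot.haetn_model <- function(object, ...) {
  h <- object$history
  df <- tidyr::pivot_longer(h, cols = -"epoch", names_to = "series",
                            values_to = "value")
  df$metric <- ifelse(grepl("loss", df$series), "loss", "accuracy")
  df$split <- ifelse(grepl("^val", df$series), "validation", "train")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = "Training history", x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a volume slice
#'
#' @param vol a [volume_image()] or [label_volume()].
#' @param z slice index along the third axis (default: middle).
#' @return A ggplot raster of the slice.
#' @export
plot_slice <- function(vol, z = NULL) {
  a <- if (inherits(vol, "label_volume")) vol$labels else vol$data
  if (length(dim(a)) == 3) {
    if (is.null(z)) z <- ceiling(dim(a)[3] / 2)
    a <- a[, , z]
  }
  df <- tibble::tibble(
    x = rep(seq_len(nrow(a)), times = ncol(a)),
    y = rep(seq_len(ncol(a)), each = nrow(a)),
    value = as.vector(a))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (inherits(vol, "label_volume")) {
    p + ggplot2::scale_fill_viridis_c(option = "turbo")
  } else {
    p + ggplot2::scale_fill_gradient(low = "black", high = "white")
  }
}
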