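# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @exportS3Method generics::tidy
tidy.metrics_report <- function(x, ...) {
  x$per_class
}

#' @exportS3Method generics::glance
glance.metrics_report <- function(x, ...) {
  dplyr::mutate(x$overall, n = x$n)
}

#' @exportS3Method generics::tidy
tidy.emofuse_result <- function(x, ...) {
  x$per_fold
}

#' @exportS3Method generics::glance
glance.emofuse_result <- function(x, ...) {
  x$summary
}

#' @exportS3Method generics::tidy
tidy.dcca_model <- function(x, ...) {
  x$history
}

#' @exportS3Method generics::glance
glance.dcca_model <- function(x, ...) {
  tibble::tibble(output_dim = x$output_dim, r = x$r, alpha = x$alpha,
                 beta = x$beta, arch = x$spec$arch,
                 final_total_correlation = -utils::tail(x$history$val_loss, 1),
                 steps = nrow(x$history))
}

#' @exportS3Method ggplot2::autoplot
autoplot.train_history <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, dplyr::any_of(c("epoch", "train_loss",
                                          "val_loss"))),
    -"epoch", names_to = "split", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy / CCA loss",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.emofuse_result <- function(object, level = "trial", ...) {
  dat <- dplyr::filter(object$per_fold, .data$level == !!level)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$method, y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "accuracy (%)",
                  title = sprintf("Leave-one-subject-out accuracy (%s level)",
                                  level)) +
    ggplot2::theme_minimal()
}
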