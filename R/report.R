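#' Evaluation report for a classification experiment
#'
#' @param truth Character vector of true labels.
#' @param predicted Character vector of predicted labels, same length.
#' @param config Plain list snapshot of the configuration that produced
#'   the run (stored verbatim for reproducibility audits).
#' @param seed Integer seed of the run.
#' @return A `posture_eval` with elements `confusion` (square count
#'   matrix, rows = truth), `per_class` (named accuracy vector),
#'   `overall`, `n_obs`, `config` and `seed`.
#' @export
evaluation_report <- function(truth, predicted, config = list(), seed = NA_integer_) {
  if (length(truth) != length(predicted) || length(truth) < 1L) {
    stop("`truth` and `predicted` must be non-empty and equal length",
         call. = FALSE)
  }
  classes <- sort(unique(c(truth, predicted)))
  confusion <- table(factor(truth, levels = classes),
                     factor(predicted, levels = classes))
  confusion <- unclass(as.matrix(confusion))
  names(dimnames(confusion)) <- c("truth", "predicted")
  per_class <- diag(confusion) / rowSums(confusion)
  structure(
    list(confusion = confusion,
         per_class = per_class,
         overall = sum(diag(confusion)) / sum(confusion),
         n_obs = length(truth),
         config = config,
         seed = seed),
    class = "posture_eval"
  )
}

#' @export
print.posture_eval <- function(x, ...) {
  cat(sprintf("<posture_eval> overall accuracy %.4f on %d observations\n",
              x$overall, x$n_obs))
  print(round(x$per_class, 4))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.posture_eval <- function(x, ...) {
  tibble::tibble(
    class = names(x$per_class),
    n = as.integer(rowSums(x$confusion)),
    accuracy = as.numeric(x$per_class)
  )
}

#' @exportS3Method generics::glance
glance.posture_eval <- function(x, ...) {
  tibble::tibble(
    overall_accuracy = x$overall,
    n_obs = x$n_obs,
    n_classes = length(x$per_class),
    seed = x$seed
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.posture_eval <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(as.table(object$confusion)))
  names(df) <- c("truth", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("Confusion matrix (overall accuracy %.1f%%)",
                                  100 * object$overall)) +
    ggplot2::theme_minimal()
}
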