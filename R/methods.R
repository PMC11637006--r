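#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.dsc_config <- function(x, ...) {
  cat(sprintf(
    "<dsc_config: K=%d, r_topics=%d, epochs=%d, batch=%d, lr=%g (%s), alpha_max=%g over %d epochs>\n",
    x$K, x$r_topics, x$epochs, x$batch_size, x$learning_rate, x$optimizer,
    x$alpha_max, x$T_ramp))
  abl <- c(tfidf = x$use_tfidf, embeddings = x$use_embeddings,
           topic_loss = x$use_topic_loss, cluster_loss = x$use_cluster_loss)
  if (!all(abl)) {
    cat("  ablated:", paste(names(abl)[!abl], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.dsc_model <- function(x, ...) {
  cat(sprintf(
    "<dsc_model: %d-cluster double-target encoder (hidden %d, rep %d)>\n",
    x$config$K, x$config$hidden_size, x$config$r_rep))
  if (nrow(x$trace) > 0) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  %d epochs, %d steps; final L_train %.4f (alpha %.3f)\n",
                x$config$epochs, nrow(x$trace), last$loss_train, last$alpha))
  }
  invisible(x)
}

#' Tidy the per-step training trace of a fitted model
#'
#' @param x A `dsc_model`.
#' @param ... Unused.
#' @return The per-step trace tibble (`epoch`, `step`, `alpha`, `lr`, `n`,
#'   `loss_cluster`, `loss_topic`, `loss_train`).
#' @export
tidy.dsc_model <- function(x, ...) {
  x$trace
}

#' One-row summary of a fitted model
#'
#' @param x A `dsc_model`.
#' @param ... Unused.
#' @return A one-row tibble: cluster count, representation size, epochs,
#'   steps, and the final loss components.
#' @export
glance.dsc_model <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble(
    K = x$config$K, r_topics = x$config$r_topics, r_rep = x$config$r_rep,
    hidden_size = x$config$hidden_size, epochs = x$config$epochs,
    steps = nrow(x$trace), alpha_final = last$alpha,
    loss_cluster = last$loss_cluster, loss_topic = last$loss_topic,
    loss_train = last$loss_train
  )
}

#' Plot the training loss trace
#'
#' Per-step joint, topic and cluster losses over training, with the
#' climbing cluster-loss weight on a second panel.
#'
#' @param object A `dsc_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dsc_model <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace,
                            c("loss_train", "loss_topic", "loss_cluster"),
                            names_to = "component", values_to = "loss")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$loss,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "training step", y = "loss",
                  title = "Double-target training trace") +
    ggplot2::theme_minimal()
}

#' Plot a difficulty sweep result
#'
#' Convenience plot of a metric against the vocabulary-overlap level, one
#' line per method, from a tibble with columns `overlap`, `method` and the
#' chosen metric.
#'
#' @param results Tibble with `overlap`, `method` and `metric` columns.
#' @param metric Column name to plot (default `"nmi"`).
#' @return A ggplot object.
#' @export
plot_difficulty <- function(results, metric = "nmi") {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$overlap, y = .data[[metric]],
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "shared-vocabulary overlap", y = toupper(metric)) +
    ggplot2::theme_minimal()
}
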