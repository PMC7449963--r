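#' @importFrom ggplot2 ggplot aes autoplot geom_line geom_point geom_vline
#'   geom_hline labs theme_minimal annotate
NULL

#' Plot an aggregate footprint profile
#'
#' Mean signal around the motif with the motif edges marked.
#'
#' @param object An `aggregate_profile` from [aggregate_footprints()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aggregate_profile <- function(object, ...) {
  L <- attr(object, "motif_len")
  ggplot(as_tibble(object), aes(x = .data$offset, y = .data$value)) +
    geom_line(color = "#2c5aa0") +
    geom_vline(xintercept = c(0, L), linetype = "dashed", color = "grey40") +
    labs(x = "position relative to motif start (bp)",
         y = "mean signal",
         title = sprintf("aggregate footprint (n = %d sites)",
                         attr(object, "n_sites"))) +
    theme_minimal()
}

#' Volcano plot of differential TF binding
#'
#' Standardized differential binding score against -log10 p-value, one
#' point per motif.
#'
#' @param volcano Tibble from [differential_binding()].
#' @param p_cutoff Significance line (default 0.05).
#' @param label_top Label this many motifs by |score| (default 5).
#' @return A ggplot object.
#' @export
plot_volcano <- function(volcano, p_cutoff = 0.05, label_top = 5L) {
  top <- volcano |>
    arrange(dplyr::desc(abs(.data$differential_score))) |>
    utils::head(label_top)
  ggplot(volcano, aes(x = .data$differential_score, y = .data$neg_log10_p)) +
    geom_point(aes(color = .data$p_value < p_cutoff), show.legend = FALSE) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "#c23b22")) +
    geom_hline(yintercept = -log10(p_cutoff), linetype = "dashed",
               color = "grey40") +
    ggplot2::geom_text(data = top,
                       aes(label = .data$motif_id), vjust = -0.6, size = 3) +
    labs(x = "differential binding score (z)", y = "-log10(p)") +
    theme_minimal()
}

#' Plot a bound/unbound mixture fit
#'
#' Histogram of log(1 + score) with the fitted components and threshold.
#'
#' @param object A `bound_fit` from [fit_bound_classifier()].
#' @param scores The score vector the fit was made on.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bound_fit <- function(object, scores, ...) {
  x <- log1p(scores)
  p <- ggplot(tibble(x = x), aes(x = .data$x)) +
    ggplot2::geom_histogram(aes(y = ggplot2::after_stat(.data$density)),
                            bins = 50, fill = "grey80", color = "grey60") +
    labs(x = "log(1 + footprint score)", y = "density") +
    theme_minimal()
  if (!object$degenerate) {
    grid <- seq(min(x), max(x), length.out = 300)
    comp <- bind_rows(lapply(1:2, function(k) {
      tibble(x = grid, component = factor(k),
             density = object$params$weight[k] *
               stats::dnorm(grid, object$params$mean[k], object$params$sd[k]))
    }))
    p <- p +
      geom_line(data = comp,
                aes(y = .data$density, color = .data$component)) +
      geom_vline(xintercept = log1p(object$threshold), linetype = "dashed")
  }
  p
}

#' Plot the motif overlap tree
#'
#' Dendrogram of motifs by binding-site overlap distance; the cut height
#' used for flat clusters is marked.
#'
#' @param tree A `motif_tree` from [build_tree()].
#' @return Invisibly, the `hclust` object (base graphics plot as side
#'   effect).
#' @export
plot_motif_tree <- function(tree) {
  if (is.null(tree$hclust)) abort("tree has fewer than 2 leaves")
  plot(tree$hclust, ylab = "binding-site overlap distance", xlab = "",
       sub = "", main = "motif clustering by TFBS overlap")
  graphics::abline(h = tree$cut, lty = 2, col = "grey40")
  invisible(tree$hclust)
}
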