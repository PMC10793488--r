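#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_vline
#'   geom_line geom_point geom_pointrange geom_errorbar geom_col labs
#'   theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot methods for neumo result objects
#'
#' `autoplot()` methods return ggplot objects: the resampling-null histogram
#' (optionally with the observed count), the stability trace with the chosen
#' resolution, a forest plot of the pooled mean differences, and stacked
#' per-sample state fractions.
#'
#' @param object A result object.
#' @param observed Optional observed attenuated-gene count drawn on the null
#'   histogram.
#' @param ... Unused.
#' @return A `ggplot`.
#' @name neumo-autoplot
NULL

#' @rdname neumo-autoplot
#' @method autoplot neumo_null
#' @export
autoplot.neumo_null <- function(object, observed = NULL, ...) {
  p <- ggplot(tidy(object), aes(x = .data$attenuated)) +
    geom_histogram(bins = 50, fill = "grey40") +
    labs(x = sprintf("Attenuated genes per draw of %d", object$n_draw),
         y = "Iterations",
         title = "Resampling null of the attenuated-gene count") +
    theme_minimal()
  if (!is.null(observed)) {
    p <- p + geom_vline(xintercept = observed, colour = "red",
                        linetype = "dashed")
  }
  p
}

#' @rdname neumo-autoplot
#' @method autoplot neumo_stability
#' @export
autoplot.neumo_stability <- function(object, ...) {
  ggplot(object$trace, aes(x = .data$resolution, y = .data$mean_ari)) +
    geom_line() +
    geom_point() +
    geom_errorbar(aes(ymin = .data$mean_ari - .data$sd_ari,
                      ymax = .data$mean_ari + .data$sd_ari), width = 0.01) +
    geom_vline(xintercept = object$chosen_resolution, colour = "red",
               linetype = "dashed") +
    labs(x = "Clustering resolution", y = "Mean ARI vs reference",
         title = "Reseeded clustering stability") +
    theme_minimal()
}

#' @rdname neumo-autoplot
#' @method autoplot neumo_pooled
#' @export
autoplot.neumo_pooled <- function(object, ...) {
  per <- tidy(object)
  pooled <- tibble(study = sprintf("Pooled (%s)", object$model),
                   effect = object$effect, ci_low = object$ci_low,
                   ci_high = object$ci_high, weight = NA_real_,
                   se = object$se)
  d <- dplyr::bind_rows(per, pooled)
  d$study <- factor(d$study, levels = rev(d$study))
  ggplot(d, aes(x = .data$effect, y = .data$study)) +
    geom_pointrange(aes(xmin = .data$ci_low, xmax = .data$ci_high)) +
    geom_vline(xintercept = 0, linetype = "dotted") +
    labs(x = "Mean difference (case - control)", y = NULL,
         title = "Meta-analysis of score differences") +
    theme_minimal()
}

#' @rdname neumo-autoplot
#' @method autoplot neumo_deconv
#' @export
autoplot.neumo_deconv <- function(object, ...) {
  ggplot(tidy(object),
         aes(x = .data$sample, y = .data$fraction, fill = .data$state)) +
    geom_col() +
    labs(x = NULL, y = "State fraction",
         title = "Guide-constrained NMF state fractions") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Running-sum enrichment plot for one gene set
#'
#' @param ranks Tibble with `gene` and `score` columns.
#' @param gene_set Character vector of gene ids.
#' @param weight Hit-increment exponent (see [enrichment_score()]).
#' @return A `ggplot` of the running enrichment statistic.
#' @export
plot_enrichment <- function(ranks, gene_set, weight = 1) {
  r <- enrichment_score(ranks, gene_set, weight = weight)
  ggplot(r$running, aes(x = .data$rank, y = .data$running)) +
    geom_line() +
    geom_vline(xintercept = r$peak_index, colour = "red",
               linetype = "dashed") +
    labs(x = "Rank", y = "Running enrichment score",
         title = sprintf("ES = %.3f (peak at rank %d)", r$es, r$peak_index)) +
    theme_minimal()
}
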