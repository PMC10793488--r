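#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidiers for neumo result objects
#'
#' Broom-style methods: `tidy()` returns the per-unit table of a result
#' (per-iteration null counts, per-study effects, per-sample fractions, the
#' stability trace), `glance()` a one-row model summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name neumo-tidiers
NULL

#' @rdname neumo-tidiers
#' @method tidy neumo_null
#' @export
tidy.neumo_null <- function(x, ...) {
  tibble(iteration = seq_len(x$n_iter), attenuated = x$counts)
}

#' @rdname neumo-tidiers
#' @method glance neumo_null
#' @export
glance.neumo_null <- function(x, ...) {
  tibble(n_iter = x$n_iter, n_draw = x$n_draw,
         min = x$min, max = x$max,
         median = unname(stats::median(x$counts)),
         q025 = unname(x$quantiles[["2.5%"]]),
         q975 = unname(x$quantiles[["97.5%"]]),
         seed = x$seed)
}

#' @rdname neumo-tidiers
#' @method tidy neumo_pooled
#' @export
tidy.neumo_pooled <- function(x, ...) {
  x$studies |>
    mutate(se = sqrt(.data$variance),
           ci_low = .data$effect - 1.96 * .data$se,
           ci_high = .data$effect + 1.96 * .data$se) |>
    dplyr::select("study", "effect", "se", "ci_low", "ci_high", "weight")
}

#' @rdname neumo-tidiers
#' @method glance neumo_pooled
#' @export
glance.neumo_pooled <- function(x, ...) {
  tibble(effect = x$effect, se = x$se, ci_low = x$ci_low,
         ci_high = x$ci_high, tau2 = x$tau2, q = x$q,
         model = x$model, n_studies = nrow(x$studies))
}

#' @rdname neumo-tidiers
#' @method tidy neumo_deconv
#' @export
tidy.neumo_deconv <- function(x, ...) {
  as_tibble(as.table(x$fractions), .name_repair = "minimal") |>
    stats::setNames(c("state", "sample", "fraction"))
}

#' @rdname neumo-tidiers
#' @method glance neumo_deconv
#' @export
glance.neumo_deconv <- function(x, ...) {
  tibble(
    n_genes = nrow(x$signatures), n_states = ncol(x$signatures),
    n_samples = ncol(x$fractions),
    best_restart = x$best_restart,
    final_loss = x$loss_trace[[x$best_restart]][x$iterations],
    iterations = x$iterations, converged = x$converged, seed = x$seed
  )
}

#' @rdname neumo-tidiers
#' @method tidy neumo_stability
#' @export
tidy.neumo_stability <- function(x, ...) x$trace

#' @rdname neumo-tidiers
#' @method glance neumo_stability
#' @export
glance.neumo_stability <- function(x, ...) {
  tibble(chosen_resolution = x$chosen_resolution,
         never_decreased = x$never_decreased,
         n_resolutions = nrow(x$trace), base_seed = x$base_seed)
}
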