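#' Build a binary gene-by-state guide matrix from marker enrichments
#'
#' Assigns a gene to a state when its log2 fold-enrichment for that state
#' meets the cutoff (default 0.58, i.e. about 1.5-fold). Genes passing for
#' more than one state are ambiguous markers and are dropped with a warning;
#' genes passing for none are dropped silently. Every retained gene row has
#' exactly one 1.
#'
#' @param marker_table Tibble with a `gene` column and one numeric log2
#'   fold-enrichment column per state (>= 2 states).
#' @param cutoff Log2 fold-enrichment threshold (inclusive).
#' @return A tibble of class `neumo_guide`: `gene` plus one 0/1 column per
#'   state, with the cutoff recorded in the `"provenance"` attribute. Errors
#'   if any state ends with zero markers.
#' @examples
#' mt <- tibble::tibble(gene = c("S100A8", "VCAN", "HLA-DRA", "CD74"),
#'                      Neu = c(1.2, 0.9, -0.5, -1.1),
#'                      DC = c(-0.4, -0.2, 1.4, 2.0))
#' build_guide_matrix(mt)
#' @export
build_guide_matrix <- function(marker_table, cutoff = 0.58) {
  m <- as_gene_matrix(marker_table, "marker_table")
  if (ncol(m) < 2L) abort("`marker_table` must have at least 2 states.")
  pass <- m >= cutoff
  n_pass <- rowSums(pass)
  ambiguous <- n_pass > 1L
  if (any(ambiguous)) {
    warn(sprintf("Ambiguous markers dropped (pass cutoff for several states): %s",
                 paste(rownames(m)[ambiguous], collapse = ", ")))
  }
  keep <- n_pass == 1L
  g <- matrix(as.integer(pass[keep, , drop = FALSE]),
              ncol = ncol(m), dimnames = list(rownames(m)[keep], colnames(m)))
  empty <- colSums(g) == 0L
  if (any(empty)) {
    abort(sprintf("No marker passed the cutoff for state(s): %s",
                  paste(colnames(g)[empty], collapse = ", ")))
  }
  out <- as_gene_tibble(g)
  attr(out, "provenance") <- list(cutoff = cutoff, n_input = nrow(m),
                                  n_ambiguous = sum(ambiguous))
  class(out) <- c("neumo_guide", class(out))
  out
}

#' Read / write a guide matrix as TSV
#'
#' The layout is one `gene` column plus one 0/1 column per state, the same
#' layout used by published marker supplements.
#'
#' @param path TSV path.
#' @export
read_guide_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "gene"
  m <- as_gene_matrix(x, path)
  if (!all(m %in% c(0, 1))) abort("Guide entries must be 0 or 1.")
  if (any(rowSums(m) != 1L)) {
    abort("Every guide gene row must have exactly one state assignment.")
  }
  out <- as_gene_tibble(m)
  out[-1] <- lapply(out[-1], as.integer)
  class(out) <- c("neumo_guide", class(out))
  out
}

#' @rdname read_guide_matrix
#' @param guide A guide tibble.
#' @export
write_guide_matrix <- function(guide, path) {
  readr::write_tsv(as_tibble(as.data.frame(guide)), path)
  invisible(path)
}

nmf_loss <- function(x, s, f) sum((x - s %*% f)^2)

#' Guide-constrained (semi-supervised) NMF deconvolution
#'
#' Factorizes a nonnegative linear-scale expression matrix of marker genes as
#' `X ~ S F`, where the signature matrix `S` (genes x states) is constrained
#' to be zero wherever the guide matrix is zero and the fraction matrix `F`
#' (states x samples) is nonnegative. Squared Frobenius reconstruction error
#' is minimized by multiplicative updates; masked signature entries are
#' initialized at zero and clamped to zero after every update, so the mask is
#' satisfied exactly. Several random restarts are run and the one with the
#' lowest final loss is kept. At output, signature columns are normalized to
#' a common column sum (absorbing the scale into `F`) and fraction columns
#' are renormalized onto the unit simplex.
#'
#' Deconvolution should be run on linear CPM (not log) of the guide genes:
#' the additive mixing model is only meaningful on a linear scale.
#'
#' @param expr Gene-by-sample tibble (or matrix) of nonnegative linear-scale
#'   expression; genes must be a subset of the guide genes.
#' @param guide Guide matrix (see [build_guide_matrix()]).
#' @param n_restarts Number of random restarts.
#' @param max_iter Maximum multiplicative-update iterations per restart.
#' @param tol Convergence: stop when the relative loss change drops below
#'   `tol`.
#' @param seed Integer seed (restart initializations are derived from it).
#' @return An object of class `neumo_deconv`: list with `signatures`
#'   (genes x states matrix respecting the mask), `fractions` (states x
#'   samples, simplex columns), `loss_trace` (list of per-iteration losses,
#'   one per restart), `best_restart`, `converged`, `iterations`, `seed`.
#'   Methods: [tidy()], [glance()], [autoplot()], [state_fraction()].
#' @export
fit_semisupervised_nmf <- function(expr, guide, n_restarts = 10,
                                   max_iter = 2000, tol = 1e-6, seed) {
  x <- as_gene_matrix(expr, "expr")
  g <- as_gene_matrix(guide, "guide")
  if (any(x < 0)) abort("`expr` must be nonnegative (use linear CPM, not log).")
  zero_samp <- colSums(x) == 0
  if (any(zero_samp)) {
    abort(sprintf("Samples with all-zero expression: %s",
                  paste(colnames(x)[zero_samp], collapse = ", ")))
  }
  extra <- setdiff(rownames(x), rownames(g))
  if (length(extra)) {
    abort(sprintf("Genes of `expr` missing from the guide: %s",
                  paste(utils::head(extra, 5L), collapse = ", ")))
  }
  g <- g[rownames(x), , drop = FALSE]
  n_restarts <- check_count(n_restarts, "n_restarts")
  max_iter <- check_count(max_iter, "max_iter")
  seed <- check_seed(seed)
  k <- ncol(g)
  n_samp <- ncol(x)
  eps <- 1e-12
  mask <- g == 1
  scale0 <- mean(x)

  runs <- lapply(seq_len(n_restarts), function(r) {
    with_seed(seed + r - 1L, {
      s <- matrix(0, nrow(x), k, dimnames = dimnames(g))
      s[mask] <- stats::runif(sum(mask), 0.5, 1.5) * scale0
      f <- matrix(stats::runif(k * n_samp, 0.5, 1.5), k, n_samp,
                  dimnames = list(colnames(g), colnames(x)))
      trace <- numeric(0)
      prev <- Inf
      it <- 0L
      converged <- FALSE
      while (it < max_iter) {
        it <- it + 1L
        s <- s * (x %*% t(f)) / (s %*% f %*% t(f) + eps)
        s[!mask] <- 0
        f <- f * (t(s) %*% x) / (t(s) %*% s %*% f + eps)
        cur <- nmf_loss(x, s, f)
        trace[it] <- cur
        if (is.finite(prev) && prev > 0 && abs(prev - cur) / prev < tol) {
          converged <- TRUE
          break
        }
        prev <- cur
      }
      list(s = s, f = f, trace = trace, converged = converged, iter = it)
    })
  })

  final <- vapply(runs, function(r) r$trace[length(r$trace)], numeric(1))
  best <- which.min(final)
  s <- runs[[best]]$s
  f <- runs[[best]]$f
  # resolve the per-state scale ambiguity, then simplex-normalize fractions
  csum <- colSums(s)
  csum[csum == 0] <- eps
  s <- sweep(s, 2, csum, "/") * nrow(s)
  f <- f * csum / nrow(s)
  tot <- colSums(f)
  tot[tot == 0] <- eps
  f <- sweep(f, 2, tot, "/")

  structure(
    list(signatures = s, fractions = f,
         loss_trace = lapply(runs, `[[`, "trace"),
         best_restart = best,
         converged = runs[[best]]$converged,
         iterations = runs[[best]]$iter,
         seed = seed),
    class = "neumo_deconv"
  )
}

#' Extract one state's per-sample fraction from a deconvolution fit
#'
#' @param fit A `neumo_deconv` object.
#' @param state State name (e.g. `"Neu"`).
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
state_fraction <- function(fit, state) {
  stopifnot(inherits(fit, "neumo_deconv"))
  if (!state %in% rownames(fit$fractions)) {
    abort(sprintf("Unknown state '%s'; available: %s", state,
                  paste(rownames(fit$fractions), collapse = ", ")))
  }
  fit$fractions[state, ]
}

#' @export
print.neumo_deconv <- function(x, ...) {
  cat(sprintf(
    "Guide-constrained NMF fit: %d genes, %d states, %d samples; best restart %d (%s, %d iterations)\n",
    nrow(x$signatures), ncol(x$signatures), ncol(x$fractions),
    x$best_restart, if (x$converged) "converged" else "max_iter reached",
    x$iterations))
  invisible(x)
}
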