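as_labeling <- function(x, arg = "labeling") {
  if (is.data.frame(x)) {
    if (!all(c("item", "cluster") %in% names(x))) {
      abort(sprintf("`%s` tibble must have columns `item` and `cluster`.", arg))
    }
    if (anyDuplicated(x$item)) abort(sprintf("Duplicate items in `%s`.", arg))
    return(stats::setNames(as.character(x$cluster), as.character(x$item)))
  }
  stats::setNames(as.character(x), names(x))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items
#' (Hubert-Arabie form), computed from the contingency table: with
#' `index = sum(choose(n_ij, 2))`, `expected = sum(choose(a_i, 2)) *
#' sum(choose(b_j, 2)) / choose(n, 2)` and `max_term` the average of the two
#' marginal sums, ARI = (index - expected) / (max_term - expected). It is 1
#' exactly when the partitions coincide, near 0 for independent labelings,
#' and can be negative for worse-than-chance agreement.
#'
#' @param a,b Cluster labelings: vectors (aligned by position, or by name if
#'   both are named) or tibbles with `item` and `cluster` columns. The item
#'   universes must match.
#' @return A single number <= 1.
#' @examples
#' adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1)) # -0.5
#' @export
adjusted_rand_index <- function(a, b) {
  a <- as_labeling(a, "a")
  b <- as_labeling(b, "b")
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      abort("The two labelings cover different item sets.")
    }
    b <- b[names(a)]
  }
  if (length(a) != length(b)) abort("Labelings must cover the same items.")
  n <- length(a)
  tab <- table(a, b)
  index <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(n, 2)
  max_term <- (ai + bj) / 2
  if (max_term == expected) return(1)  # both partitions trivial
  (index - expected) / (max_term - expected)
}

#' Select a clustering resolution by reseeded stability
#'
#' At each resolution of the grid, a reference clustering is produced at
#' `base_seed` and `n_reseeds` further clusterings at derived seeds
#' (`base_seed + i`); the mean adjusted Rand index of the reseeded runs
#' against the reference measures stability at that resolution. The chosen
#' resolution is the one immediately before the first strict decrease of the
#' mean ARI along the grid; if the mean ARI never decreases, the last grid
#' point is chosen and flagged.
#'
#' @param cluster_fn A function `(data, resolution, seed) -> labeling`
#'   (vector or `item`/`cluster` tibble), deterministic given its arguments.
#'   [knn_louvain_clusterer()] provides a reference implementation.
#' @param data Passed through to `cluster_fn`.
#' @param resolutions Strictly increasing resolution grid.
#' @param n_reseeds Reseeded runs per resolution.
#' @param base_seed Integer seed of the reference runs.
#' @param tol Decrease tolerance: a drop must exceed `tol` to count
#'   (default 0, i.e. any strict decrease).
#' @return An object of class `neumo_stability`: list with `trace` (tibble:
#'   `resolution`, `mean_ari`, `sd_ari`, `n_reseeds`), `chosen_resolution`,
#'   `never_decreased` flag, `base_seed`. Methods: [tidy()], [autoplot()].
#' @export
stability_sweep <- function(cluster_fn, data,
                            resolutions = seq(0.10, 0.50, by = 0.05),
                            n_reseeds = 100, base_seed, tol = 0) {
  if (any(diff(resolutions) <= 0)) {
    abort("`resolutions` must be strictly increasing.")
  }
  n_reseeds <- check_count(n_reseeds, "n_reseeds")
  base_seed <- check_seed(base_seed)
  rows <- lapply(resolutions, function(res) {
    ref <- as_labeling(cluster_fn(data, res, base_seed))
    aris <- vapply(seq_len(n_reseeds), function(i) {
      lab <- as_labeling(cluster_fn(data, res, base_seed + i))
      if (length(lab) != length(ref)) {
        abort("cluster_fn returned a labeling over a different item set.")
      }
      adjusted_rand_index(ref, lab)
    }, numeric(1))
    tibble(resolution = res, mean_ari = mean(aris),
           sd_ari = stats::sd(aris), n_reseeds = n_reseeds)
  })
  trace <- dplyr::bind_rows(rows)
  drops <- which(diff(trace$mean_ari) < -tol)
  never <- length(drops) == 0L
  chosen <- if (never) {
    resolutions[length(resolutions)]
  } else {
    resolutions[drops[1]]
  }
  structure(
    list(trace = trace, chosen_resolution = chosen,
         never_decreased = never, base_seed = base_seed),
    class = "neumo_stability"
  )
}

#' Reference clustering contract: k-nearest-neighbour graph + Louvain
#'
#' Returns a `cluster_fn` for [stability_sweep()]: it builds a shared
#' k-nearest-neighbour graph on the rows of a numeric matrix and runs
#' Louvain modularity community detection, with `resolution` passed through
#' as the modularity resolution parameter and the seed fixed before the
#' (stochastic) community search.
#'
#' @param k Number of nearest neighbours.
#' @return A function `(data, resolution, seed)` returning a cluster vector.
#' @export
knn_louvain_clusterer <- function(k = 10) {
  force(k)
  function(data, resolution, seed) {
    if (!requireNamespace("igraph", quietly = TRUE)) {
      abort("The knn+Louvain reference clusterer requires igraph.")
    }
    m <- as.matrix(data)
    n <- nrow(m)
    d <- as.matrix(stats::dist(m))
    edges <- do.call(rbind, lapply(seq_len(n), function(i) {
      nb <- order(d[i, ])[2:(min(k, n - 1) + 1)]
      cbind(i, nb)
    }))
    gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
    gr <- igraph::simplify(gr)
    lab <- with_seed(seed, {
      igraph::membership(igraph::cluster_louvain(gr, resolution = resolution))
    })
    as.integer(lab)
  }
}

#' Overlap coefficient of two gene sets
#'
#' `|intersect(a, b)| / min(|a|, |b|)`: 1 exactly when one set contains the
#' other, 0 for disjoint sets. Symmetric in its arguments.
#'
#' @param a,b Nonempty character vectors.
#' @return A number in `[0, 1]`.
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0L || length(b) == 0L) {
    abort("Overlap coefficient undefined for empty sets.")
  }
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Pairwise overlap-coefficient matrix over a gene-set collection
#'
#' @param sets Uniquely named list of nonempty gene sets.
#' @return A symmetric numeric matrix with unit diagonal.
#' @export
pairwise_overlap <- function(sets) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("`sets` must be a uniquely named list.")
  }
  if (any(lengths(sets) == 0L)) abort("All sets must be nonempty.")
  n <- length(sets)
  out <- diag(1, n)
  dimnames(out) <- list(names(sets), names(sets))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        out[i, j] <- out[j, i] <- overlap_coefficient(sets[[i]], sets[[j]])
      }
    }
  }
  out
}
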