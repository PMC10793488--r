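#' Read and write gene-set collections in GMT format
#'
#' GMT files carry one gene set per line: name, description, then
#' tab-separated gene ids. `read_gmt()` errors on duplicate set names and on
#' lines with no genes; `write_gmt()` round-trips a collection (within-set
#' gene order is not significant).
#'
#' @param path Path to a `.gmt` file.
#' @return `read_gmt()`: a named list of character vectors with a
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nms <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(nms)) {
    abort(sprintf("Duplicate set names in GMT: %s",
                  paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  if (any(lengths(parts) < 3L)) {
    abort(sprintf("GMT lines with no genes: %s",
                  paste(nms[lengths(parts) < 3L], collapse = ", ")))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nms
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[`, character(1), 2L), nms)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("`sets` must be a uniquely named list.")
  }
  if (any(lengths(sets) == 0L)) abort("Empty gene sets cannot be written.")
  desc <- descriptions %||% attr(sets, "descriptions") %||%
    stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Order a (gene, score) tibble descending by score, ties broken by gene id.
rank_genes <- function(ranks) {
  if (!all(c("gene", "score") %in% names(ranks))) {
    abort("`ranks` must have columns `gene` and `score`.")
  }
  if (anyDuplicated(ranks$gene)) abort("Ranked gene ids must be unique.")
  ranks[order(-ranks$score, ranks$gene), ]
}

# Fast ES from the sorted hit positions within a ranking of length n.
# w: |score|^weight aligned to the ranking. Returns c(es, peak).
es_from_positions <- function(idx, w, n) {
  idx <- sort(idx)
  k <- length(idx)
  wh <- w[idx]
  denom <- sum(wh)
  hits <- if (denom > 0) cumsum(wh) / denom else seq_len(k) / k
  miss <- 1 / (n - k)
  at_hit <- hits - (idx - seq_len(k)) * miss
  before_hit <- c(0, hits[-k]) - (idx - seq_len(k)) * miss
  hi <- max(at_hit)
  lo <- min(before_hit)
  if (hi >= -lo) c(hi, idx[which.max(at_hit)]) else c(lo, idx[which.min(before_hit)])
}

#' Weighted Kolmogorov-Smirnov enrichment score with leading edge
#'
#' The classic GSEA running statistic on a preranked list: walking down the
#' ranking, in-set genes ("hits") add `|score|^weight` normalized by the sum
#' over in-set hits, and out-of-set genes subtract `1/(N - N_hit)`. The
#' enrichment score is the running-sum value of maximal absolute deviation
#' from zero. The leading edge is the in-set genes at or before the peak for
#' a positive score, at or after it for a negative one.
#'
#' @param ranks Tibble with columns `gene` (unique) and `score` (typically a
#'   log2 fold change); sorted internally, ties broken by gene id.
#' @param gene_set Character vector of gene ids.
#' @param weight Exponent on `|score|` for hit increments (1 = classic
#'   weighted statistic; 0 = unweighted Kolmogorov-Smirnov).
#' @return A list with `es` (in `[-1, 1]`), `peak_index`, `leading_edge`,
#'   and `running` (tibble of the running sum for plotting).
#' @examples
#' rl <- tibble::tibble(gene = paste0("g", 1:5), score = c(5, 4, 3, 2, 1))
#' enrichment_score(rl, c("g1", "g2"))$es
#' @export
enrichment_score <- function(ranks, gene_set, weight = 1) {
  rl <- rank_genes(ranks)
  n <- nrow(rl)
  hit <- rl$gene %in% gene_set
  k <- sum(hit)
  if (k == 0L) abort("No gene of the set is present in the ranking.")
  if (k == n) abort("The set covers every ranked gene; miss step undefined.")
  w <- abs(rl$score)^weight
  denom <- sum(w[hit])
  inc <- numeric(n)
  inc[hit] <- if (denom > 0) w[hit] / denom else 1 / k
  inc[!hit] <- -1 / (n - k)
  running <- cumsum(inc)
  peak <- which.max(abs(running))
  es <- running[peak]
  le <- if (es > 0) {
    rl$gene[hit & seq_len(n) <= peak]
  } else if (es < 0) {
    rl$gene[hit & seq_len(n) >= peak]
  } else character()
  list(es = es, peak_index = peak, leading_edge = le,
       running = tibble(rank = seq_len(n), gene = rl$gene, running = running))
}

#' Preranked gene-set enrichment analysis
#'
#' Computes the weighted enrichment score of every set against a preranked
#' list, a permutation null obtained by permuting the gene labels of the
#' scores (equivalently: placing the set at random positions), per-sign
#' normalized enrichment scores (NES = ES divided by the mean absolute null
#' ES of matching sign), matching-sign permutation p-values with the add-one
#' convention, and FDR by the pooled-null-NES procedure (the proportion of
#' pooled null NES at least as extreme, normalized by the proportion of
#' observed NES at least as extreme, capped at 1).
#'
#' @inheritParams enrichment_score
#' @param gene_sets Named list of gene sets (see [read_gmt()]).
#' @param n_perm Number of permutations (a warning is raised below 100).
#' @param min_size,max_size Set-size bounds after intersecting with the
#'   ranked genes; sets outside are dropped, sets with no ranked gene are
#'   skipped with a warning.
#' @param seed Integer seed.
#' @return A tibble with columns `set`, `size`, `es`, `nes`, `pvalue`,
#'   `fdr`, and a `leading_edge` list-column.
#' @export
preranked_gsea <- function(ranks, gene_sets, n_perm = 1000, weight = 1,
                           min_size = 5, max_size = 2000, seed) {
  n_perm <- check_count(n_perm, "n_perm")
  if (n_perm < 100) warn("n_perm < 100 gives unstable FDR estimates.")
  seed <- check_seed(seed)
  rl <- rank_genes(ranks)
  n <- nrow(rl)
  w <- abs(rl$score)^weight

  overlap <- lapply(gene_sets, function(s) which(rl$gene %in% s))
  none <- lengths(overlap) == 0L
  if (any(none)) {
    warn(sprintf("Sets with no ranked gene skipped: %s",
                 paste(names(gene_sets)[none], collapse = ", ")))
  }
  keep <- lengths(overlap) >= min_size & lengths(overlap) <= max_size &
    lengths(overlap) < n
  overlap <- overlap[keep]
  if (length(overlap) == 0L) abort("No gene set passed the size filter.")

  obs <- purrr::imap(overlap, function(idx, nm) {
    r <- enrichment_score(rl, rl$gene[idx], weight = weight)
    tibble(set = nm, size = length(idx), es = r$es,
           leading_edge = list(r$leading_edge))
  }) |> dplyr::bind_rows()

  null_nes <- vector("list", length(overlap))
  nes <- pval <- numeric(nrow(obs))
  with_seed(seed, {
    for (j in seq_along(overlap)) {
      k <- length(overlap[[j]])
      null_es <- vapply(seq_len(n_perm), function(i) {
        es_from_positions(sample.int(n, k), w, n)[1]
      }, numeric(1))
      pos_mean <- mean(null_es[null_es > 0])
      neg_mean <- mean(abs(null_es[null_es < 0]))
      # same arithmetic path as the null, so equal-ES placements tie exactly
      es <- es_from_positions(overlap[[j]], w, n)[1]
      if (es >= 0) {
        nes[j] <- if (is.finite(pos_mean) && pos_mean > 0) es / pos_mean else 0
        pval[j] <- (1 + sum(null_es >= es)) / (1 + sum(null_es >= 0))
      } else {
        nes[j] <- if (is.finite(neg_mean) && neg_mean > 0) es / neg_mean else 0
        pval[j] <- (1 + sum(null_es <= es)) / (1 + sum(null_es < 0))
      }
      nn <- numeric(length(null_es))
      pos <- null_es >= 0
      nn[pos] <- if (is.finite(pos_mean) && pos_mean > 0) null_es[pos] / pos_mean else 0
      nn[!pos] <- if (is.finite(neg_mean) && neg_mean > 0) null_es[!pos] / neg_mean else 0
      null_nes[[j]] <- nn
    }
  })
  pooled <- unlist(null_nes)
  fdr <- vapply(nes, function(x) {
    if (x >= 0) {
      num <- mean(pooled[pooled >= 0] >= x)
      den <- mean(nes[nes >= 0] >= x)
    } else {
      num <- mean(pooled[pooled < 0] <= x)
      den <- mean(nes[nes < 0] <= x)
    }
    if (!is.finite(num) || !is.finite(den) || den == 0) return(1)
    min(1, num / den)
  }, numeric(1))

  obs |>
    mutate(nes = nes, pvalue = pval, fdr = fdr) |>
    dplyr::select("set", "size", "es", "nes", "pvalue", "fdr", "leading_edge")
}

#' Filter enrichment results by NES and FDR
#'
#' Inclusive thresholds (`nes >= nes_min`, `fdr <= fdr_max`), matching the
#' convention "normalized enrichment score >= 2.5 and FDR <= 0.05" used to
#' pick the consensus source sets. Boundary results (exactly at a threshold)
#' are flagged in a `boundary` column so a strict reading can be audited.
#'
#' @param results Output of [preranked_gsea()].
#' @param nes_min Minimum (absolute) NES.
#' @param fdr_max Maximum FDR.
#' @param direction `"positive"` keeps `nes >= nes_min`, `"negative"` keeps
#'   `nes <= -nes_min`, `"both"` uses `|nes| >= nes_min`.
#' @return The filtered tibble (order preserved) with a `boundary` flag.
#' @export
select_enriched <- function(results, nes_min = 2.5, fdr_max = 0.05,
                            direction = c("positive", "negative", "both")) {
  direction <- match.arg(direction)
  keep <- switch(direction,
    positive = results$nes >= nes_min,
    negative = results$nes <= -nes_min,
    both = abs(results$nes) >= nes_min
  ) & results$fdr <= fdr_max
  out <- results[keep, , drop = FALSE]
  mutate(out, boundary = abs(.data$nes) == nes_min | .data$fdr == fdr_max)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of drawing
#' the observed-or-larger overlap between the query and the set when
#' sampling `|query|` genes from the universe.
#'
#' @param query Character vector of genes of interest (must be contained in
#'   the universe).
#' @param universe Character vector of all analyzed genes.
#' @param gene_sets Named list of gene sets (intersected with the universe).
#' @return A tibble with columns `set`, `set_size`, `overlap`, `p`.
#' @export
hypergeometric_ora <- function(query, universe, gene_sets) {
  query <- unique(query)
  universe <- unique(universe)
  bad <- setdiff(query, universe)
  if (length(bad)) {
    abort(sprintf("Query genes outside the universe: %s",
                  paste(utils::head(bad, 5L), collapse = ", ")))
  }
  n_u <- length(universe)
  n_q <- length(query)
  purrr::imap(gene_sets, function(s, nm) {
    s <- intersect(s, universe)
    k <- length(intersect(query, s))
    tibble(set = nm, set_size = length(s), overlap = k,
           p = if (length(s) == 0L || n_q == 0L) 1 else
             stats::phyper(k - 1, length(s), n_u - length(s), n_q,
                           lower.tail = FALSE))
  }) |> dplyr::bind_rows()
}
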