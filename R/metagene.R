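#' Majority-vote consensus over leading-edge gene sets
#'
#' Returns the genes appearing in at least a given fraction of the supplied
#' leading-edge sets. The ">= 50% of the enriched gene sets" reading is
#' implemented as a membership count of at least `n_sets / 2` (so 3 of 6, or
#' 5 of 10); set `strict = TRUE` for a strict majority (`> n_sets / 2`).
#'
#' @param leading_edges List of character vectors (one per enriched set).
#' @param threshold Required fraction of sets.
#' @param strict Require membership strictly above the threshold.
#' @return Character vector of consensus genes (sorted).
#' @export
majority_leading_edge <- function(leading_edges, threshold = 0.5,
                                  strict = FALSE) {
  if (length(leading_edges) == 0L) abort("`leading_edges` must be nonempty.")
  check_number(threshold, "threshold", 0, 1, inclusive_lower = FALSE)
  counts <- table(unlist(lapply(leading_edges, unique)))
  cut <- threshold * length(leading_edges)
  keep <- if (strict) counts > cut else counts >= cut
  sort(names(counts)[keep])
}

#' Build a consensus metagene signature from two exposure arms
#'
#' Intersects the majority leading-edge genes of the exposed and unexposed
#' arms into one signature (the construction behind the 39-gene NeuMo
#' metagene), recording the provenance needed to regenerate it.
#'
#' @param majority_yes,majority_no Majority leading-edge gene sets of the two
#'   arms (see [majority_leading_edge()]).
#' @param name Signature name.
#' @param provenance Optional list stored alongside (e.g. source set names
#'   and the NES/FDR/majority thresholds used upstream).
#' @return An object of class `neumo_signature`: list with `name`, `genes`,
#'   `provenance`. An empty intersection is allowed but warned about.
#' @export
consensus_signature <- function(majority_yes, majority_no, name = "NeuMo",
                                provenance = list()) {
  genes <- sort(intersect(unique(majority_yes), unique(majority_no)))
  if (length(genes) == 0L) warn("Consensus signature is empty.")
  structure(
    list(name = name, genes = genes,
         provenance = c(provenance,
                        list(n_yes = length(unique(majority_yes)),
                             n_no = length(unique(majority_no))))),
    class = "neumo_signature"
  )
}

#' @export
print.neumo_signature <- function(x, ...) {
  cat(sprintf("Metagene signature '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Write / read a signature as a single-set GMT with a JSON provenance sidecar
#'
#' @param sig A `neumo_signature`.
#' @param path Path to the `.gmt` file; provenance goes to `<path>.json`.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "neumo_signature"))
  write_gmt(stats::setNames(list(sig$genes), sig$name), path)
  jsonlite::write_json(sig$provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  sets <- read_gmt(path)
  prov <- if (file.exists(paste0(path, ".json"))) {
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  } else list()
  structure(list(name = names(sets)[1], genes = sort(sets[[1]]),
                 provenance = prov),
            class = "neumo_signature")
}

#' Score samples with a metagene signature
#'
#' The score of a sample is the unweighted mean log2CPM over the signature
#' genes present in the expression matrix.
#'
#' @param expr Gene-by-sample log2CPM tibble (see [log2cpm()]).
#' @param signature A `neumo_signature` or a character vector of genes.
#' @param missing_policy What to do when signature genes are absent from the
#'   matrix: `"intersect_warn"` (default; score the present genes and warn)
#'   or `"error"`.
#' @return A tibble with columns `sample`, `score`, `n_genes_used`.
#' @export
score_samples <- function(expr, signature,
                          missing_policy = c("intersect_warn", "error")) {
  missing_policy <- match.arg(missing_policy)
  genes <- if (inherits(signature, "neumo_signature")) signature$genes else signature
  m <- as_gene_matrix(expr, "expr")
  present <- intersect(genes, rownames(m))
  if (length(present) == 0L) abort("No signature gene is present in `expr`.")
  if (length(present) < length(genes)) {
    msg <- sprintf("%d of %d signature genes absent from the matrix.",
                   length(genes) - length(present), length(genes))
    if (missing_policy == "error") abort(msg) else warn(msg)
  }
  sub <- m[present, , drop = FALSE]
  tibble(sample = colnames(m), score = unname(colMeans(sub)),
         n_genes_used = length(present))
}

#' Expand a signature by correlation with its score
#'
#' Returns the genes whose expression has Pearson correlation at least
#' `r_min` with the signature score across samples. Constant genes (undefined
#' correlation) are excluded.
#'
#' @param expr Gene-by-sample log2CPM tibble.
#' @param scores Score tibble from [score_samples()] (or a numeric vector
#'   named by sample).
#' @param r_min Correlation threshold (inclusive).
#' @return Character vector of genes.
#' @export
expand_signature <- function(expr, scores, r_min = 0.7) {
  m <- as_gene_matrix(expr, "expr")
  s <- if (is.data.frame(scores)) {
    stats::setNames(scores$score, scores$sample)
  } else scores
  s <- s[colnames(m)]
  if (anyNA(s)) abort("`scores` must cover every sample of `expr`.")
  if (ncol(m) < 3L) abort("Correlation expansion needs at least 3 samples.")
  sds <- apply(m, 1, stats::sd)
  ok <- sds > 0
  r <- as.vector(stats::cor(t(m[ok, , drop = FALSE]), s))
  rownames(m)[ok][r >= r_min]
}

#' Compare metagene scores between two groups
#'
#' Unpaired comparisons use the Wilcoxon rank-sum test; paired comparisons
#' (via `paired_by`) use the Wilcoxon signed-rank test. The reported delta is
#' `mean(group1) - mean(group2)` with groups in the order of `levels` (or
#' sorted unique labels).
#'
#' @param scores Tibble with `sample` and `score` columns.
#' @param groups Named vector or tibble (`sample`, `group`) assigning each
#'   sample to one of exactly two groups.
#' @param paired_by Optional named vector or tibble (`sample`, `subject`)
#'   pairing samples across the groups; pairs must be complete.
#' @param levels Optional length-2 vector fixing the group order.
#' @return A one-row tibble: `delta`, `p_value`, `test`, `n1`, `n2`.
#' @export
compare_scores <- function(scores, groups, paired_by = NULL, levels = NULL) {
  g <- if (is.data.frame(groups)) {
    stats::setNames(as.character(groups$group), groups$sample)
  } else stats::setNames(as.character(groups), names(groups))
  g <- g[scores$sample]
  if (anyNA(g)) abort("`groups` must label every scored sample.")
  lev <- levels %||% sort(unique(g))
  if (length(lev) != 2L) abort("Exactly 2 groups are required.")
  x <- scores$score[g == lev[1]]
  y <- scores$score[g == lev[2]]
  if (length(x) < 2L || length(y) < 2L) {
    abort("Each group needs at least 2 samples.")
  }
  if (is.null(paired_by)) {
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    test <- "wilcoxon rank-sum"
  } else {
    pb <- if (is.data.frame(paired_by)) {
      stats::setNames(as.character(paired_by$subject), paired_by$sample)
    } else stats::setNames(as.character(paired_by), names(paired_by))
    s1 <- scores$sample[g == lev[1]]
    s2 <- scores$sample[g == lev[2]]
    subj <- pb[s1]
    match2 <- s2[match(subj, pb[s2])]
    if (anyNA(subj) || anyNA(match2)) abort("Incomplete pairs in `paired_by`.")
    x <- scores$score[match(s1, scores$sample)]
    y <- scores$score[match(match2, scores$sample)]
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    test <- "wilcoxon signed-rank"
  }
  tibble(delta = mean(x) - mean(y), p_value = wt$p.value, test = test,
         n1 = length(x), n2 = length(y))
}

#' Pool per-study mean differences by inverse-variance meta-analysis
#'
#' Each study contributes the mean difference `mean1 - mean2` with variance
#' `sd1^2/n1 + sd2^2/n2`. The fixed-effect model weights by inverse variance;
#' the random-effects model adds the DerSimonian-Laird between-study variance
#' tau^2 to every study variance before weighting. The 95% confidence
#' interval is `effect +/- 1.96 * SE`.
#'
#' @param studies Tibble with columns `study`, `n1`, `n2`, `mean1`, `mean2`,
#'   `sd1`, `sd2` (group 1 is the case group, e.g. M-MDSC).
#' @param model `"random"` (default) or `"fixed"`.
#' @return An object of class `neumo_pooled`: list with `effect`, `ci_low`,
#'   `ci_high`, `se`, `tau2`, `model`, and a per-study tibble (`studies`,
#'   with effects, variances and normalized weights). Methods: [tidy()],
#'   [glance()], [autoplot()].
#' @export
pool_mean_differences <- function(studies, model = c("random", "fixed")) {
  model <- match.arg(model)
  need <- c("study", "n1", "n2", "mean1", "mean2", "sd1", "sd2")
  if (!all(need %in% names(studies))) {
    abort(sprintf("`studies` must have columns: %s", paste(need, collapse = ", ")))
  }
  if (nrow(studies) < 1L) abort("At least one study is required.")
  if (any(studies$n1 < 2 | studies$n2 < 2)) abort("Group sizes must be >= 2.")
  if (any(studies$sd1 < 0 | studies$sd2 < 0)) abort("SDs must be nonnegative.")
  yi <- studies$mean1 - studies$mean2
  vi <- studies$sd1^2 / studies$n1 + studies$sd2^2 / studies$n2
  if (all(vi == 0)) abort("Every study has zero variance; pooling is degenerate.")
  wi_fixed <- 1 / vi
  k <- length(yi)
  # DerSimonian-Laird tau^2
  fixed_eff <- sum(wi_fixed * yi) / sum(wi_fixed)
  q <- sum(wi_fixed * (yi - fixed_eff)^2)
  c_dl <- sum(wi_fixed) - sum(wi_fixed^2) / sum(wi_fixed)
  tau2 <- if (model == "random" && k > 1L) max(0, (q - (k - 1)) / c_dl) else 0
  wi <- 1 / (vi + tau2)
  effect <- sum(wi * yi) / sum(wi)
  se <- sqrt(1 / sum(wi))
  structure(
    list(effect = effect, se = se,
         ci_low = effect - 1.96 * se, ci_high = effect + 1.96 * se,
         tau2 = tau2, q = q, model = model,
         studies = mutate(studies, effect = yi, variance = vi,
                          weight = wi / sum(wi))),
    class = "neumo_pooled"
  )
}

#' @export
print.neumo_pooled <- function(x, ...) {
  cat(sprintf("%s-effects pooled mean difference: %.3f [%.3f, %.3f] (tau2 = %.4f, %d studies)\n",
              if (x$model == "random") "Random" else "Fixed",
              x$effect, x$ci_low, x$ci_high, x$tau2, nrow(x$studies)))
  invisible(x)
}

#' Per-cell gene-expression module score
#'
#' In the default mode, each cell's score is the mean expression over the
#' module genes minus the mean over control genes drawn from
#' expression-matched bins: all measured genes are binned by average
#' expression into `n_bins` bins and `n_ctrl` controls are sampled (with the
#' given seed) from the bin of each module gene. With `n_ctrl = 0` the score
#' is the plain mean over module genes.
#'
#' @param cell_expr Cells-by-genes expression matrix (e.g. log-normalized
#'   counts; rows are cells) or a tibble with a `cell` column.
#' @param gene_set Character vector of module genes.
#' @param n_bins Number of average-expression bins.
#' @param n_ctrl Control genes sampled per module gene (0 = simple mean).
#' @param seed Integer seed for control sampling.
#' @return A named numeric vector of per-cell scores.
#' @export
module_score_cells <- function(cell_expr, gene_set, n_bins = 24,
                               n_ctrl = 100, seed = 0L) {
  if (is.data.frame(cell_expr)) {
    cells <- as.character(cell_expr[[1]])
    m <- as.matrix(cell_expr[-1])
    rownames(m) <- cells
  } else {
    m <- as.matrix(cell_expr)
  }
  genes <- colnames(m)
  present <- intersect(gene_set, genes)
  if (length(present) == 0L) abort("No module gene is measured in `cell_expr`.")
  set_mean <- rowMeans(m[, present, drop = FALSE])
  if (n_ctrl == 0) return(set_mean)
  n_bins <- check_count(n_bins, "n_bins")
  n_ctrl <- check_count(n_ctrl, "n_ctrl")
  seed <- check_seed(seed)
  avg <- colMeans(m)
  bins <- cut(rank(avg, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  names(bins) <- genes
  ctrl <- with_seed(seed, {
    unlist(lapply(present, function(g) {
      pool <- genes[bins == bins[[g]] & genes != g]
      if (length(pool) == 0L) pool <- genes[genes != g]
      sample(pool, min(n_ctrl, length(pool)), replace = FALSE)
    }))
  })
  set_mean - rowMeans(m[, unique(ctrl), drop = FALSE])
}
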