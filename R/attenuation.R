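#' Ratio of log2 fold changes (glucocorticoid attenuation statistic)
#'
#' For a gene differentially expressed in the same direction with and without
#' dexamethasone exposure, the statistic is the exposed-arm log2 fold change
#' divided by the unexposed-arm log2 fold change. By construction it is
#' positive (or zero); a value strictly between 0 and 1 indicates attenuation
#' of the expression difference by the drug, a value above 1 potentiation.
#'
#' @param fc_yes,fc_no Log2 fold changes in the exposed (Yes-DEX) and
#'   unexposed (No-DEX) arms. Vectorized.
#' @return `fc_yes / fc_no`.
#' @examples
#' ratio_of_log2fc(0.11, 0.27) # ~0.41: attenuated
#' @export
ratio_of_log2fc <- function(fc_yes, fc_no) {
  if (any(fc_no == 0)) abort("Ratio undefined: `fc_no` contains zeros.")
  if (any(fc_yes * fc_no < 0)) {
    abort("Discordant fold changes (opposite signs); exclude them before taking ratios.")
  }
  fc_yes / fc_no
}

#' Classify genes as attenuated, potentiated, neutral, or discordant
#'
#' Joins exposed- and unexposed-arm fold changes, computes the ratio of
#' log2 fold changes for same-direction genes, and classifies each gene:
#' `attenuated` for ratio in (0, 1), `potentiated` for ratio > 1, `neutral`
#' for ratio exactly 1, and `discordant` (undefined ratio, `NA`) when the
#' fold changes have opposite signs or the denominator is zero.
#'
#' @param de_yes,de_no DE tables (tibbles with `gene` and `log2fc`), e.g.
#'   from [paired_de()] or [read_deg_table()].
#' @param restrict_to Genes to classify (typically the DEGs shared by both
#'   arms). Each must carry a fold change in both tables.
#' @return A tibble with columns `gene`, `fc_yes`, `fc_no`, `ratio`, `klass`.
#'   Class counts are available via `dplyr::count(out, klass)`.
#' @export
classify_attenuation <- function(de_yes, de_no, restrict_to) {
  restrict_to <- unique(as.character(restrict_to))
  missing_g <- setdiff(restrict_to, intersect(de_yes$gene, de_no$gene))
  if (length(missing_g)) {
    abort(sprintf("Genes missing a fold change: %s",
                  paste(utils::head(missing_g, 5L), collapse = ", ")))
  }
  fcp <- dplyr::inner_join(
    dplyr::select(de_yes, "gene", fc_yes = "log2fc"),
    dplyr::select(de_no, "gene", fc_no = "log2fc"),
    by = "gene"
  )
  fcp <- fcp[match(restrict_to, fcp$gene), ]
  fcp |>
    mutate(
      ratio = ifelse(.data$fc_yes * .data$fc_no > 0,
                     .data$fc_yes / .data$fc_no, NA_real_),
      klass = dplyr::case_when(
        is.na(.data$ratio) ~ "discordant",
        .data$ratio < 1 & .data$ratio > 0 ~ "attenuated",
        .data$ratio == 1 ~ "neutral",
        TRUE ~ "potentiated"
      )
    )
}

#' Summarize DEG overlap between exposure arms
#'
#' Counts, at a given FDR cutoff, the up- and down-regulated DEGs in each
#' arm, the DEGs shared between arms, the arm-unique DEGs, and the shared
#' DEGs whose fold changes point in the same direction (the substrate of the
#' attenuation analysis).
#'
#' @param de_yes,de_no DE tables with `gene`, `log2fc`, `fdr`.
#' @param fdr_max DEG definition: `fdr < fdr_max`.
#' @return A one-row tibble with columns `up_yes`, `down_yes`, `up_no`,
#'   `down_no`, `shared`, `unique_yes`, `unique_no`, `same_direction`, plus a
#'   `same_direction_genes` list-column with the shared same-direction genes.
#' @export
summarize_deg_overlap <- function(de_yes, de_no, fdr_max = 0.05) {
  deg_yes <- dplyr::filter(de_yes, .data$fdr < fdr_max)
  deg_no <- dplyr::filter(de_no, .data$fdr < fdr_max)
  shared <- intersect(deg_yes$gene, deg_no$gene)
  fc_y <- deg_yes$log2fc[match(shared, deg_yes$gene)]
  fc_n <- deg_no$log2fc[match(shared, deg_no$gene)]
  same_dir <- shared[fc_y * fc_n > 0]
  n_shared <- length(shared)
  tibble(
    up_yes = sum(deg_yes$log2fc > 0), down_yes = sum(deg_yes$log2fc < 0),
    up_no = sum(deg_no$log2fc > 0), down_no = sum(deg_no$log2fc < 0),
    shared = n_shared,
    unique_yes = nrow(deg_yes) - n_shared,
    unique_no = nrow(deg_no) - n_shared,
    same_direction = length(same_dir),
    same_direction_genes = list(same_dir)
  )
}

#' Resampling null distribution for the attenuated-gene count
#'
#' Under the null hypothesis that the DEGs are not special with respect to
#' attenuation, the number of attenuated genes among `n_draw` genes should
#' look like a random draw from the full universe of same-direction analyzed
#' genes. Each iteration samples `n_draw` genes (without replacement by
#' default) from the universe and counts ratios strictly in (0, 1).
#'
#' @param universe Tibble with columns `fc_yes` and `fc_no` (all
#'   same-direction, nonzero `fc_no`), e.g. built by joining two DE tables
#'   over all analyzed genes.
#' @param n_draw Genes sampled per iteration (the observed DEG count).
#' @param n_iter Number of iterations.
#' @param replace Sample with replacement instead (not the default).
#' @param seed Integer seed.
#' @return An object of class `neumo_null`: list with `counts` (length
#'   `n_iter`), `n_iter`, `n_draw`, `min`, `max`, `quantiles`, `seed`.
#'   Methods: [tidy()], [glance()], [autoplot()].
#' @export
attenuation_null <- function(universe, n_draw = 666, n_iter = 100000,
                             replace = FALSE, seed) {
  n_draw <- check_count(n_draw, "n_draw")
  n_iter <- check_count(n_iter, "n_iter")
  seed <- check_seed(seed)
  ratio <- ratio_of_log2fc(universe$fc_yes, universe$fc_no)
  n <- length(ratio)
  if (!replace && n < n_draw) {
    abort(sprintf("Universe (%d genes) is smaller than n_draw (%d).", n, n_draw))
  }
  atten <- ratio > 0 & ratio < 1
  counts <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      sum(atten[sample.int(n, n_draw, replace = replace)])
    }, integer(1))
  })
  structure(
    list(counts = counts, n_iter = n_iter, n_draw = n_draw,
         min = min(counts), max = max(counts),
         quantiles = stats::quantile(counts, c(0.025, 0.25, 0.5, 0.75, 0.975)),
         replace = replace, seed = seed),
    class = "neumo_null"
  )
}

#' Compare an observed attenuated-gene count to its resampling null
#'
#' The empirical p-value uses the add-one convention
#' `(1 + #\{null >= observed\}) / (n_iter + 1)`, so it is never zero.
#' `outside_range` flags an observed count beyond the null minimum-maximum
#' range in either direction.
#'
#' @param observed Observed count of attenuated genes (in `[0, n_draw]`).
#' @param null A `neumo_null` from [attenuation_null()].
#' @return A one-row tibble with `observed`, `p_value`, `outside_range`,
#'   `null_min`, `null_max`.
#' @export
attenuation_test <- function(observed, null) {
  stopifnot(inherits(null, "neumo_null"))
  observed <- check_count(observed, "observed", min = 0L)
  if (observed > null$n_draw) abort("`observed` exceeds n_draw.")
  tibble(
    observed = observed,
    p_value = (1 + sum(null$counts >= observed)) / (null$n_iter + 1),
    outside_range = observed > null$max || observed < null$min,
    null_min = null$min, null_max = null$max
  )
}

#' Equivalent change index for two fold changes
#'
#' A bounded measure of agreement between two log2 fold changes (e.g. the
#' same contrast in two studies): `sign(a * b) * min(|a|, |b|) / max(|a|, |b|)`.
#' It equals 1 for equal nonzero changes, -1 for exactly opposite ones, and 0
#' when one input is zero. Vectorized and symmetric in its arguments.
#'
#' @param fc_a,fc_b Log2 fold changes.
#' @return Values in `[-1, 1]`.
#' @examples
#' equivalent_change_index(0.5, 1.0)
#' @export
equivalent_change_index <- function(fc_a, fc_b) {
  if (any(fc_a == 0 & fc_b == 0)) {
    abort("ECI undefined when both fold changes are zero.")
  }
  sign(fc_a * fc_b) * pmin(abs(fc_a), abs(fc_b)) / pmax(abs(fc_a), abs(fc_b))
}

#' @export
print.neumo_null <- function(x, ...) {
  cat(sprintf(
    "Resampling null: %d iterations of %d genes %s replacement (seed %d)\n",
    x$n_iter, x$n_draw, if (x$replace) "with" else "without", x$seed))
  cat(sprintf("  attenuated-count range [%d, %d], median %g\n",
              x$min, x$max, stats::median(x$counts)))
  invisible(x)
}
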