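#' Read a gene-by-sample count matrix
#'
#' Reads counts from TSV (genes as rows, header of sample ids, first column
#' gene ids) or MatrixMarket (`.mtx` with `<stem>.genes.tsv` and
#' `<stem>.samples.tsv` index files alongside). Errors on duplicate gene ids
#' (naming them) and on non-integer entries. Sample metadata can be joined
#' from a sidecar TSV with a `sample` column; it is attached as the
#' `"sample_meta"` attribute.
#'
#' @param path Path to the counts file.
#' @param format `"tsv"` or `"mtx"`.
#' @param meta Optional path to a sample-metadata TSV.
#' @return A tibble with a `gene` column plus one integer column per sample.
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx"), meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "tsv") {
    x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    names(x)[1] <- "gene"
    m <- as_gene_matrix(x, path)
  } else {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    g <- readr::read_tsv(paste0(stem, ".genes.tsv"), col_names = "gene",
                         show_col_types = FALSE, progress = FALSE)$gene
    s <- readr::read_tsv(paste0(stem, ".samples.tsv"), col_names = "sample",
                         show_col_types = FALSE, progress = FALSE)$sample
    if (anyDuplicated(g)) {
      abort(sprintf("Duplicate gene ids: %s",
                    paste(unique(g[duplicated(g)]), collapse = ", ")))
    }
    dimnames(m) <- list(g, s)
  }
  if (any(m < 0) || any(m != floor(m))) {
    abort("Counts must be nonnegative integers.")
  }
  if (anyDuplicated(colnames(m))) abort("Sample ids must be unique.")
  out <- as_gene_tibble(m)
  out[-1] <- lapply(out[-1], as.integer)
  if (!is.null(meta)) {
    md <- readr::read_tsv(meta, show_col_types = FALSE, progress = FALSE)
    attr(out, "sample_meta") <- md
  }
  out
}

#' Write a count matrix to TSV or MatrixMarket
#'
#' @param counts Gene-by-sample tibble (or matrix with gene rownames).
#' @param path Output path; for `"mtx"` the gene and sample index files are
#'   written alongside as `<stem>.genes.tsv` / `<stem>.samples.tsv`.
#' @param format `"tsv"` or `"mtx"`.
#' @return Invisibly, `path`.
#' @export
write_count_matrix <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  m <- as_gene_matrix(counts, "counts")
  if (format == "tsv") {
    readr::write_tsv(as_gene_tibble(m), path)
  } else {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    readr::write_tsv(tibble(gene = rownames(m)), paste0(stem, ".genes.tsv"),
                     col_names = FALSE)
    readr::write_tsv(tibble(sample = colnames(m)), paste0(stem, ".samples.tsv"),
                     col_names = FALSE)
  }
  invisible(path)
}

cpm_matrix <- function(m) {
  lib <- colSums(m)
  if (any(lib == 0)) {
    abort(sprintf("Samples with zero total counts: %s",
                  paste(colnames(m)[lib == 0], collapse = ", ")))
  }
  sweep(m, 2, lib, "/") * 1e6
}

#' Remove genes with low expression across libraries
#'
#' Keeps exactly the genes with counts-per-million strictly greater than
#' `cpm_min` in strictly more than `min_samples` samples (the conventional
#' "more than 1 CPM in more than 3 samples" rule). CPM is computed on the
#' unfiltered library sizes, so the rule is independent of which other genes
#' are removed and the filter is idempotent.
#'
#' @param counts Gene-by-sample count tibble.
#' @param cpm_min CPM threshold (strict).
#' @param min_samples Sample-count threshold (strict: a gene needs
#'   `> min_samples` qualifying samples).
#' @return The filtered count tibble. If every gene is removed a warning is
#'   raised and an empty tibble returned.
#' @export
filter_low_expression <- function(counts, cpm_min = 1, min_samples = 3) {
  m <- as_gene_matrix(counts, "counts")
  cpm <- cpm_matrix(m)
  keep <- rowSums(cpm > cpm_min) > min_samples
  if (!any(keep)) warn("All genes removed by the expression filter.")
  counts[keep, , drop = FALSE]
}

#' Log2 counts-per-million transform
#'
#' Computes `log2(count / library_size * 1e6 + pseudocount)` per entry, using
#' raw library sizes (no normalization factors).
#'
#' @param counts Gene-by-sample count tibble.
#' @param pseudocount Positive value added inside the log (default 1, so a
#'   zero count maps to 0).
#' @return A tibble of the same shape on the log2CPM scale.
#' @export
log2cpm <- function(counts, pseudocount = 1) {
  check_number(pseudocount, "pseudocount", 0, Inf, inclusive_lower = FALSE)
  m <- as_gene_matrix(counts, "counts")
  as_gene_tibble(log2(cpm_matrix(m) + pseudocount))
}

#' Paired differential expression on log2CPM
#'
#' A simple paired test between case (MDSC) and control (Mono) samples:
#' the per-gene log2 fold change is the mean over subjects of the
#' case-minus-control log2CPM difference, the p-value comes from a two-sided
#' paired t-test on those per-subject differences, and FDR is the
#' Benjamini-Hochberg adjustment over all tested genes. Downstream stages
#' consume only (log2FC, FDR) pairs, so externally computed tables (e.g. from
#' a count-model fit) can be used interchangeably via [read_deg_table()].
#'
#' Degenerate genes: zero variance of differences with zero mean difference
#' gives p = 1; zero variance with a nonzero mean difference gives the
#' smallest representable p and is flagged in the `degenerate` column.
#'
#' @param expr Gene-by-sample log2CPM tibble (see [log2cpm()]).
#' @param meta Sample metadata tibble with columns `sample`, `subject`, and
#'   `cell_type`.
#' @param case,control Values of `cell_type` defining the comparison
#'   (case vs control).
#' @param group_label Optional label stored in the `group` column (e.g.
#'   `"Yes-DEX"`).
#' @return A tibble with columns `gene`, `log2fc`, `pvalue`, `fdr`,
#'   `degenerate`, and `group`.
#' @export
paired_de <- function(expr, meta, case = "MDSC", control = "Mono",
                      group_label = NA_character_) {
  m <- as_gene_matrix(expr, "expr")
  need <- c("sample", "subject", "cell_type")
  if (!all(need %in% names(meta))) {
    abort("`meta` must have columns sample, subject, cell_type.")
  }
  meta <- dplyr::filter(meta, .data$cell_type %in% c(case, control),
                        .data$sample %in% colnames(m))
  wide <- tidyr::pivot_wider(meta[need], names_from = "cell_type",
                             values_from = "sample")
  if (!all(c(case, control) %in% names(wide)) ||
      anyNA(wide[[case]]) || anyNA(wide[[control]])) {
    abort("Every subject must have exactly one case and one control sample.")
  }
  n <- nrow(wide)
  if (n < 2L) abort("Paired testing needs at least 2 subject pairs.")

  d <- m[, wide[[case]], drop = FALSE] - m[, wide[[control]], drop = FALSE]
  mu <- rowMeans(d)
  sd_d <- apply(d, 1, stats::sd)
  tstat <- mu / (sd_d / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  degenerate <- sd_d == 0
  p[degenerate & mu == 0] <- 1
  p[degenerate & mu != 0] <- .Machine$double.xmin
  tibble(
    gene = rownames(m), log2fc = unname(mu), pvalue = unname(p),
    fdr = benjamini_hochberg(unname(p)),
    degenerate = unname(degenerate & mu != 0),
    group = group_label
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Validates the inputs and applies the standard step-up adjustment
#' (via [stats::p.adjust()]), preserving input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in `[0, 1]`, same order as the input.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjamini_hochberg <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0) || any(pvalues > 1)) {
    abort("`pvalues` must be numeric values in [0, 1].")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Load an externally computed differential-expression table
#'
#' Reads a DE table from TSV, CSV, or XLSX with a column mapping, returning
#' the standard layout consumed by the attenuation and enrichment stages.
#' This is the entry point for published supplementary DEG tables.
#'
#' @param path Path to the table. `.xlsx` requires the readxl package.
#' @param gene_col,log2fc_col,fdr_col Names of the source columns.
#' @param pvalue_col Optional p-value column; `NA` if absent.
#' @param group_label Optional label stored in `group`.
#' @param sheet Sheet name or index for XLSX input.
#' @return Tibble with columns `gene`, `log2fc`, `pvalue`, `fdr`, `group`.
#' @export
read_deg_table <- function(path, gene_col = "gene", log2fc_col = "log2fc",
                           fdr_col = "fdr", pvalue_col = NULL,
                           group_label = NA_character_, sheet = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        abort("Reading .xlsx requires the readxl package.")
      }
      readxl::read_excel(path, sheet = sheet)
    },
    csv = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  )
  need <- c(gene_col, log2fc_col, fdr_col, pvalue_col)
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(sprintf("Columns not found in %s: %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  tibble(
    gene = as.character(x[[gene_col]]),
    log2fc = as.numeric(x[[log2fc_col]]),
    pvalue = if (is.null(pvalue_col)) NA_real_ else as.numeric(x[[pvalue_col]]),
    fdr = as.numeric(x[[fdr_col]]),
    group = group_label
  )
}
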