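#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble is_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map_chr map2 imap
#' @importFrom tidyr pivot_longer pivot_wider
NULL

# Convert a gene-by-sample tibble (first column `gene`) to a numeric matrix.
as_gene_matrix <- function(x, arg = "x") {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort(sprintf("`%s` matrix must have gene rownames.", arg))
    return(x)
  }
  if (!is.data.frame(x)) abort(sprintf("`%s` must be a data frame or matrix.", arg))
  if (!"gene" %in% names(x)) {
    abort(sprintf("`%s` must contain a `gene` column followed by one column per sample.", arg))
  }
  genes <- as.character(x$gene)
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    abort(sprintf("Duplicate gene ids in `%s`: %s", arg,
                  paste(utils::head(dup, 5L), collapse = ", ")))
  }
  m <- as.matrix(x[setdiff(names(x), "gene")])
  if (!is.numeric(m)) abort(sprintf("Sample columns of `%s` must be numeric.", arg))
  rownames(m) <- genes
  m
}

# Inverse of as_gene_matrix().
as_gene_tibble <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  dplyr::bind_cols(tibble(gene = rownames(m)), as_tibble(m))
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         inclusive_lower = TRUE, inclusive_upper = TRUE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (inclusive_lower) x >= lower else x > lower) &&
    (if (inclusive_upper) x <= upper else x < upper)
  if (!ok) abort(sprintf("`%s` must be a single number in the required range.", name))
  as.numeric(x)
}

check_seed <- function(seed) {
  if (is.null(seed)) abort("`seed` must be supplied for reproducibility.")
  check_count(seed, "seed", min = 0L)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
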