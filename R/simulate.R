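#' Simulate a paired MDSC/monocyte count study with planted fold changes
#'
#' Generates negative-binomial RNA-seq counts for a paired design in which
#' every subject contributes one myeloid-derived suppressor cell (MDSC) sample
#' and one conventional monocyte (Mono) sample, split into a
#' glucocorticoid-exposed arm (`dex_group = "Yes"`) and an unexposed arm
#' (`"No"`). A chosen fraction of genes is differentially expressed between
#' the paired cell types; in the exposed arm the planted log2 fold change is
#' multiplied by `attenuation_factor`, emulating drug attenuation of
#' differential expression.
#'
#' Counts follow a mean-dispersion negative binomial. Within-pair correlation
#' is induced by a shared lognormal subject factor multiplying both samples
#' of a pair. Fold changes are applied symmetrically (`2^(+b/2)` to the MDSC
#' mean, `2^(-b/2)` to the Mono mean) so library sizes stay comparable.
#'
#' @param n_genes Number of genes.
#' @param n_pairs_yes,n_pairs_no Number of subject pairs in the exposed and
#'   unexposed arms. Defaults mirror a small paired clinical study (6 and 12).
#' @param de_fraction Fraction of genes that are truly differentially
#'   expressed (MDSC vs Mono), in `[0, 1]`.
#' @param mean_abs_log2fc Mean absolute planted log2 fold change for DE genes
#'   (magnitudes are gamma-distributed around this mean, signs random).
#' @param attenuation_factor Multiplier in `(0, 1]` applied to each planted
#'   log2 fold change in the exposed arm; 1 means no attenuation.
#' @param dispersion Negative-binomial dispersion (constant across genes).
#' @param lib_size Target expected library size per sample.
#' @param seed Integer seed; identical inputs reproduce identical counts.
#'
#' @return An object of class `neumo_sim_paired`: a list with
#'   `counts` (tibble, `gene` column plus one column per sample),
#'   `sample_meta` (tibble: `sample`, `subject`, `cell_type`, `dex_group`),
#'   `truth` (tibble: `gene`, `is_de`, `true_log2fc`, `attenuation_factor`,
#'   `dispersion`), `params`, and `seed`. Non-DE genes have `true_log2fc`
#'   exactly 0.
#' @examples
#' sim <- simulate_paired_counts(n_genes = 200, n_pairs_yes = 3,
#'                               n_pairs_no = 4, seed = 1)
#' dplyr::count(sim$truth, is_de)
#' @export
simulate_paired_counts <- function(n_genes = 2000, n_pairs_yes = 6,
                                   n_pairs_no = 12, de_fraction = 0.1,
                                   mean_abs_log2fc = 1,
                                   attenuation_factor = 0.5,
                                   dispersion = 0.1, lib_size = 2e6,
                                   seed) {
  n_genes <- check_count(n_genes, "n_genes")
  n_pairs_yes <- check_count(n_pairs_yes, "n_pairs_yes")
  n_pairs_no <- check_count(n_pairs_no, "n_pairs_no")
  check_number(de_fraction, "de_fraction", 0, 1)
  check_number(mean_abs_log2fc, "mean_abs_log2fc", 0, Inf)
  check_number(attenuation_factor, "attenuation_factor", 0, 1,
               inclusive_lower = FALSE)
  check_number(dispersion, "dispersion", 0, Inf, inclusive_lower = FALSE)
  lib_size <- check_count(lib_size, "lib_size")
  seed <- check_seed(seed)

  n_pairs <- n_pairs_yes + n_pairs_no
  genes <- sprintf("g%05d", seq_len(n_genes))

  out <- with_seed(seed, {
    rel <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1.2)
    base_mu <- rel / sum(rel) * lib_size

    n_de <- round(de_fraction * n_genes)
    is_de <- c(rep(TRUE, n_de), rep(FALSE, n_genes - n_de))
    beta <- numeric(n_genes)
    if (n_de > 0) {
      mag <- stats::rgamma(n_de, shape = 4, rate = 4 / max(mean_abs_log2fc, 1e-8))
      beta[seq_len(n_de)] <- mag * sample(c(-1, 1), n_de, replace = TRUE)
    }

    subjects <- sprintf("subj%02d", seq_len(n_pairs))
    dex <- c(rep("Yes", n_pairs_yes), rep("No", n_pairs_no))
    subj_factor <- stats::rlnorm(n_pairs, meanlog = 0, sdlog = 0.3)

    samples <- as.vector(rbind(paste0(subjects, "_MDSC"),
                               paste0(subjects, "_Mono")))
    counts <- matrix(0L, n_genes, 2L * n_pairs,
                     dimnames = list(genes, samples))
    for (i in seq_len(n_pairs)) {
      b <- if (dex[i] == "Yes") beta * attenuation_factor else beta
      mu_mdsc <- base_mu * subj_factor[i] * 2^(b / 2)
      mu_mono <- base_mu * subj_factor[i] * 2^(-b / 2)
      counts[, 2L * i - 1L] <- stats::rnbinom(n_genes, mu = mu_mdsc,
                                              size = 1 / dispersion)
      counts[, 2L * i] <- stats::rnbinom(n_genes, mu = mu_mono,
                                         size = 1 / dispersion)
    }

    meta <- tibble(
      sample = samples,
      subject = rep(subjects, each = 2L),
      cell_type = rep(c("MDSC", "Mono"), times = n_pairs),
      dex_group = rep(dex, each = 2L)
    )
    truth <- tibble(
      gene = genes, is_de = is_de, true_log2fc = beta,
      attenuation_factor = attenuation_factor, dispersion = dispersion
    )
    list(counts = as_gene_tibble(counts), sample_meta = meta, truth = truth)
  })

  structure(
    c(out, list(
      params = list(n_genes = n_genes, n_pairs_yes = n_pairs_yes,
                    n_pairs_no = n_pairs_no, de_fraction = de_fraction,
                    mean_abs_log2fc = mean_abs_log2fc,
                    attenuation_factor = attenuation_factor,
                    dispersion = dispersion, lib_size = lib_size),
      seed = seed
    )),
    class = "neumo_sim_paired"
  )
}

#' Simulate mixture expression profiles from guide-respecting signatures
#'
#' Draws nonnegative state signatures that are zero exactly where the guide
#' matrix is zero, per-sample state fractions from a symmetric Dirichlet, and
#' linear-scale expression `X = S %*% F` plus zero-truncated Gaussian noise.
#' Signature columns are normalized to a common column sum so that mixing
#' fractions are identifiable (see the methods vignette).
#'
#' @param guide A guide matrix as returned by [build_guide_matrix()], or any
#'   tibble with a `gene` column and one binary 0/1 column per state.
#' @param n_samples Number of mixture samples.
#' @param alpha Symmetric Dirichlet concentration for the true fractions.
#' @param noise_sd Standard deviation of additive Gaussian noise (clipped at
#'   zero) on the expression scale.
#' @param fractions Optional states-by-samples matrix overriding the Dirichlet
#'   draw (columns must lie on the unit simplex); used to plant exact designs
#'   such as pure samples.
#' @param seed Integer seed.
#'
#' @return An object of class `neumo_sim_mix`: `expression` (tibble, genes by
#'   samples, linear scale), `true_fractions` (states x samples matrix whose
#'   columns sum to 1), `signatures` (tibble), `noise_sd`, `seed`.
#' @examples
#' guide <- tibble::tibble(gene = paste0("g", 1:6),
#'                         Neu = c(1, 1, 1, 0, 0, 0),
#'                         DC = c(0, 0, 0, 1, 1, 1))
#' mix <- simulate_mixtures(guide, n_samples = 5, seed = 1)
#' colSums(mix$true_fractions)
#' @export
simulate_mixtures <- function(guide, n_samples, alpha = 1, noise_sd = 0,
                              fractions = NULL, seed) {
  g <- as_gene_matrix(guide, "guide")
  if (ncol(g) < 2L) abort("`guide` must have at least 2 states.")
  if (!all(g %in% c(0, 1))) abort("`guide` entries must be 0 or 1.")
  if (any(rowSums(g) == 0)) {
    abort("`guide` contains gene rows with no state assignment (all zero).")
  }
  if (any(colSums(g) == 0)) abort("Every state needs at least one marker gene.")
  n_samples <- check_count(n_samples, "n_samples")
  check_number(alpha, "alpha", 0, Inf, inclusive_lower = FALSE)
  check_number(noise_sd, "noise_sd", 0, Inf)
  seed <- check_seed(seed)
  k <- ncol(g)

  if (!is.null(fractions)) {
    fractions <- as.matrix(fractions)
    if (nrow(fractions) != k || ncol(fractions) != n_samples ||
        any(fractions < 0) ||
        any(abs(colSums(fractions) - 1) > 1e-12)) {
      abort("`fractions` must be a states x samples matrix with simplex columns.")
    }
  }

  out <- with_seed(seed, {
    sig <- matrix(0, nrow(g), k, dimnames = dimnames(g))
    nz <- g == 1
    sig[nz] <- stats::rgamma(sum(nz), shape = 2, rate = 0.1)
    # equal column sums: removes the per-state scale ambiguity of X = S F
    sig <- sweep(sig, 2, colSums(sig), "/") * nrow(g)

    f <- fractions
    if (is.null(f)) {
      f <- matrix(stats::rgamma(k * n_samples, shape = alpha, rate = 1),
                  nrow = k)
      f <- sweep(f, 2, colSums(f), "/")
    }
    dimnames(f) <- list(colnames(g), sprintf("mix%03d", seq_len(n_samples)))

    x <- sig %*% f
    if (noise_sd > 0) {
      x <- pmax(x + matrix(stats::rnorm(length(x), sd = noise_sd),
                           nrow = nrow(x)), 0)
    }
    colnames(x) <- colnames(f)
    list(expression = as_gene_tibble(x), true_fractions = f,
         signatures = as_gene_tibble(sig))
  })

  structure(c(out, list(noise_sd = noise_sd, alpha = alpha, seed = seed)),
            class = "neumo_sim_mix")
}

#' Simulate a single-cell population with planted discrete states
#'
#' Cells are assigned to states with the given proportions; each state has a
#' disjoint set of marker genes whose expected expression is `fold_up` times
#' the baseline in cells of that state. Counts are Poisson around the
#' state-specific means, so cells of the same state share one expected
#' profile.
#'
#' @param n_cells Number of cells.
#' @param state_props Vector of state proportions summing to 1 (length >= 2).
#' @param n_marker_genes_per_state Markers per state (disjoint across states).
#' @param n_noise_genes Additional genes with no state effect.
#' @param fold_up Expected marker up-regulation factor (> 1).
#' @param baseline_mean Baseline Poisson mean per gene.
#' @param seed Integer seed.
#'
#' @return An object of class `neumo_sim_cells`: `counts` (cells x genes
#'   integer matrix with cell rownames), `true_state` (character vector per
#'   cell), `marker_sets` (named list of marker gene sets), `seed`.
#' @examples
#' cells <- simulate_cells(100, c(0.5, 0.5), fold_up = 8, seed = 1)
#' table(cells$true_state)
#' @export
simulate_cells <- function(n_cells, state_props,
                           n_marker_genes_per_state = 20,
                           n_noise_genes = 200, fold_up = 8,
                           baseline_mean = 0.5, seed) {
  n_cells <- check_count(n_cells, "n_cells")
  if (length(state_props) < 2L) {
    abort("`state_props` must describe at least 2 states.")
  }
  if (any(state_props <= 0) || abs(sum(state_props) - 1) > 1e-8) {
    abort("`state_props` must be positive and sum to 1.")
  }
  n_mk <- check_count(n_marker_genes_per_state, "n_marker_genes_per_state")
  n_noise <- check_count(n_noise_genes, "n_noise_genes", min = 0L)
  check_number(fold_up, "fold_up", 1, Inf, inclusive_lower = FALSE)
  check_number(baseline_mean, "baseline_mean", 0, Inf, inclusive_lower = FALSE)
  seed <- check_seed(seed)

  k <- length(state_props)
  states <- paste0("state", seq_len(k))
  marker_sets <- stats::setNames(
    lapply(seq_len(k), function(i) sprintf("%s_m%03d", states[i], seq_len(n_mk))),
    states
  )
  genes <- c(unlist(marker_sets, use.names = FALSE),
             if (n_noise > 0) sprintf("noise_%04d", seq_len(n_noise)))

  out <- with_seed(seed, {
    lab <- sample(states, n_cells, replace = TRUE, prob = state_props)
    lambda <- matrix(baseline_mean, n_cells, length(genes),
                     dimnames = list(sprintf("cell%05d", seq_len(n_cells)),
                                     genes))
    for (s in states) {
      lambda[lab == s, marker_sets[[s]]] <- baseline_mean * fold_up
    }
    counts <- matrix(stats::rpois(length(lambda), lambda),
                     nrow = n_cells, dimnames = dimnames(lambda))
    list(counts = counts, true_state = lab)
  })

  structure(c(out, list(marker_sets = marker_sets,
                        params = list(fold_up = fold_up,
                                      baseline_mean = baseline_mean),
                        seed = seed)),
            class = "neumo_sim_cells")
}

#' Write a simulated paired study to disk
#'
#' Writes the counts (TSV and/or MatrixMarket with gene/sample index files),
#' sample metadata, truth table, and a JSON sidecar echoing all generator
#' parameters together with the seed.
#'
#' @param sim A `neumo_sim_paired` object.
#' @param dir Output directory (created if missing).
#' @param format `"tsv"`, `"mtx"`, or both.
#' @return Invisibly, the paths written.
#' @export
write_sim_study <- function(sim, dir, format = "tsv") {
  stopifnot(inherits(sim, "neumo_sim_paired"))
  format <- match.arg(format, c("tsv", "mtx"), several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if ("tsv" %in% format) {
    p <- file.path(dir, "counts.tsv")
    write_count_matrix(sim$counts, p, format = "tsv")
    paths <- c(paths, p)
  }
  if ("mtx" %in% format) {
    p <- file.path(dir, "counts.mtx")
    write_count_matrix(sim$counts, p, format = "mtx")
    paths <- c(paths, p)
  }
  readr::write_tsv(sim$sample_meta, file.path(dir, "sample_meta.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  jsonlite::write_json(c(sim$params, list(seed = sim$seed)),
                       file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paths, file.path(dir, c("sample_meta.tsv", "truth.tsv",
                                      "params.json"))))
}

#' @export
print.neumo_sim_paired <- function(x, ...) {
  cat(sprintf(
    "Simulated paired study: %d genes, %d+%d pairs (Yes/No-DEX), %d DE genes (seed %d)\n",
    nrow(x$truth), x$params$n_pairs_yes, x$params$n_pairs_no,
    sum(x$truth$is_de), x$seed))
  invisible(x)
}

#' @export
print.neumo_sim_mix <- function(x, ...) {
  cat(sprintf("Simulated mixtures: %d genes x %d samples, %d states, noise_sd %g (seed %d)\n",
              nrow(x$expression), ncol(x$expression) - 1L,
              nrow(x$true_fractions), x$noise_sd, x$seed))
  invisible(x)
}

#' @export
print.neumo_sim_cells <- function(x, ...) {
  cat(sprintf("Simulated cells: %d cells x %d genes, %d states (seed %d)\n",
              nrow(x$counts), ncol(x$counts), length(x$marker_sets), x$seed))
  invisible(x)
}
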