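library(dplyr)

# Two-state toy guide matrix: 6 Neu markers, 6 DC markers.
toy_guide <- function(n_per_state = 6) {
  tibble::tibble(
    gene = c(sprintf("neu_%02d", seq_len(n_per_state)),
             sprintf("dc_%02d", seq_len(n_per_state))),
    Neu = rep(c(1L, 0L), each = n_per_state),
    DC = rep(c(0L, 1L), each = n_per_state)
  )
}

# Guide over the first 12 genes of a simulated study's gene universe.
toy_guide_from_genes <- function(genes) {
  tibble::tibble(gene = genes[1:12],
                 Neu = rep(c(1L, 0L), each = 6),
                 DC = rep(c(0L, 1L), each = 6))
}

# A ranked list with distinct scores and deterministic gene ids.
toy_ranks <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    gene = sprintf("g%03d", seq_len(n)),
    score = sort(stats::rnorm(n), decreasing = TRUE)
  ))
}

# Independent brute-force enrichment score: literal walk down the ranking.
# Used as the oracle against the package's two ES code paths.
brute_es <- function(scores_desc, hit_positions, weight = 1) {
  n <- length(scores_desc)
  hit <- seq_len(n) %in% hit_positions
  w <- abs(scores_desc)^weight
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) w[i] / sum(w[hit]) else -1 / (n - sum(hit))
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Paired DE tables for both exposure arms of a simulated study.
sim_de_tables <- function(sim, pseudocount = 1) {
  em <- log2cpm(sim$counts, pseudocount = pseudocount)
  lapply(c(Yes = "Yes", No = "No"), function(arm) {
    meta <- dplyr::filter(sim$sample_meta, dex_group == arm)
    paired_de(em[c("gene", meta$sample)], meta,
              group_label = paste0(arm, "-DEX"))
  })
}
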