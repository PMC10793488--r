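stage_offsets <- c(simulate = 1L, de = 2L, attenuation = 3L, gsea = 4L,
                   signature = 5L, score = 6L, deconvolve = 7L,
                   stability = 8L, overlap = 9L)

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("Config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a YAML path or a list.")
  if (is.null(config$seed)) abort("Config field missing: seed")
  if (is.null(config$outdir)) abort("Config field missing: outdir")
  config$seed <- check_seed(config$seed)
  for (p in names(config$paths %||% list())) {
    if (!file.exists(config$paths[[p]])) {
      abort(sprintf("Config field paths.%s: file not found (%s)",
                    p, config$paths[[p]]))
    }
  }
  config
}

require_upstream <- function(path, stage, needed_by) {
  if (!file.exists(path)) {
    abort(sprintf(
      "Stage '%s' needs output of stage '%s' (missing: %s); run it first or provide the path in the config.",
      needed_by, stage, path))
  }
  path
}

#' Run pipeline stages from a single configuration
#'
#' Orchestrates the analysis stages over a shared configuration (a YAML file
#' or list) with one global seed fanned out to per-stage seeds by fixed
#' offsets. Each stage writes TSV/JSON outputs under `outdir` and consumes
#' its predecessors' outputs by path; a manifest at `outdir/manifest.json`
#' records the stages run, every applied parameter, the per-stage seeds, and
#' MD5 checksums of all outputs, so a run is fully specified by its manifest
#' and reruns are byte-identical.
#'
#' Config layout (all stage blocks optional; defaults shown in the stage
#' functions): `seed`, `outdir`, `paths` (existing input files: `counts`,
#' `sample_meta`, `gmt`, `guide`, `de_yes`, `de_no`), and per-stage parameter
#' blocks `simulate`, `de`, `attenuation`, `gsea`, `signature`, `score`,
#' `deconvolve`, `stability`, `overlap`.
#'
#' @param config YAML path or list.
#' @param stages Ordered subset of `c("simulate", "de", "attenuation",
#'   "gsea", "signature", "score", "deconvolve", "stability", "overlap")`.
#' @return Invisibly, the manifest (also written to
#'   `outdir/manifest.json`).
#' @export
run_pipeline <- function(config, stages = c("simulate", "de", "attenuation")) {
  cfg <- read_pipeline_config(config)
  bad <- setdiff(stages, names(stage_offsets))
  if (length(bad)) {
    abort(sprintf("Unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  out <- cfg$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, stages = list())
  outputs <- character()
  path_of <- function(key, default) cfg$paths[[key]] %||% file.path(out, default)

  for (st in stages) {
    seed_st <- cfg$seed + stage_offsets[[st]]
    params <- cfg[[st]] %||% list()
    written <- switch(st,
      simulate = {
        sim <- do.call(simulate_paired_counts,
                       c(params, list(seed = seed_st)))
        write_sim_study(sim, file.path(out, "simulate"))
      },
      de = {
        counts_p <- require_upstream(
          path_of("counts", "simulate/counts.tsv"), "simulate", "de")
        meta_p <- require_upstream(
          path_of("sample_meta", "simulate/sample_meta.tsv"), "simulate", "de")
        counts <- read_count_matrix(counts_p)
        meta <- readr::read_tsv(meta_p, show_col_types = FALSE,
                                progress = FALSE)
        counts <- filter_low_expression(counts,
                                        cpm_min = params$cpm_min %||% 1,
                                        min_samples = params$min_samples %||% 3)
        em <- log2cpm(counts, pseudocount = params$pseudocount %||% 1)
        ps <- character()
        for (arm in c("Yes", "No")) {
          meta_arm <- dplyr::filter(meta, .data$dex_group == arm)
          de <- paired_de(em[c("gene", meta_arm$sample)], meta_arm,
                          group_label = paste0(arm, "-DEX"))
          p <- file.path(out, sprintf("de_%s.tsv", tolower(arm)))
          readr::write_tsv(de, p)
          ps <- c(ps, p)
        }
        ps
      },
      attenuation = {
        de_yes <- readr::read_tsv(
          require_upstream(path_of("de_yes", "de_yes.tsv"), "de", st),
          show_col_types = FALSE, progress = FALSE)
        de_no <- readr::read_tsv(
          require_upstream(path_of("de_no", "de_no.tsv"), "de", st),
          show_col_types = FALSE, progress = FALSE)
        ov <- summarize_deg_overlap(de_yes, de_no,
                                    fdr_max = params$fdr_max %||% 0.05)
        shared_dir <- ov$same_direction_genes[[1]]
        rec <- classify_attenuation(de_yes, de_no, shared_dir)
        universe <- classify_attenuation(
          de_yes, de_no, intersect(de_yes$gene, de_no$gene)) |>
          dplyr::filter(.data$klass != "discordant")
        nul <- attenuation_null(
          universe,
          n_draw = params$n_draw %||% max(length(shared_dir), 1L),
          n_iter = params$n_iter %||% 10000, seed = seed_st)
        tst <- attenuation_test(sum(rec$klass == "attenuated"), nul)
        readr::write_tsv(rec, file.path(out, "attenuation_records.tsv"))
        readr::write_tsv(tidy(nul), file.path(out, "null_counts.tsv"))
        jsonlite::write_json(
          c(as.list(glance(nul)), as.list(tst),
            as.list(dplyr::select(ov, -"same_direction_genes"))),
          file.path(out, "null_summary.json"), auto_unbox = TRUE, digits = NA)
        file.path(out, c("attenuation_records.tsv", "null_counts.tsv",
                         "null_summary.json"))
      },
      gsea = {
        gmt_p <- require_upstream(path_of("gmt", "sets.gmt"), "gsea", st)
        sets <- read_gmt(gmt_p)
        ps <- character()
        for (arm in c("yes", "no")) {
          de <- readr::read_tsv(
            require_upstream(path_of(paste0("de_", arm),
                                     sprintf("de_%s.tsv", arm)), "de", st),
            show_col_types = FALSE, progress = FALSE)
          res <- preranked_gsea(
            dplyr::select(de, "gene", score = "log2fc"), sets,
            n_perm = params$n_perm %||% 1000,
            weight = params$weight %||% 1,
            min_size = params$min_size %||% 5,
            max_size = params$max_size %||% 2000, seed = seed_st)
          p <- file.path(out, sprintf("gsea_%s.tsv", arm))
          readr::write_tsv(
            mutate(res, leading_edge = purrr::map_chr(
              .data$leading_edge, paste, collapse = ",")), p)
          write_gmt(stats::setNames(res$leading_edge, res$set),
                    file.path(out, sprintf("leading_edge_%s.gmt", arm)))
          ps <- c(ps, p, file.path(out, sprintf("leading_edge_%s.gmt", arm)))
        }
        ps
      },
      signature = {
        les <- lapply(c("yes", "no"), function(arm) {
          res <- readr::read_tsv(
            require_upstream(file.path(out, sprintf("gsea_%s.tsv", arm)),
                             "gsea", st),
            show_col_types = FALSE, progress = FALSE) |>
            mutate(leading_edge = strsplit(.data$leading_edge, ","))
          sel <- select_enriched(res, nes_min = params$nes_min %||% 2.5,
                                 fdr_max = params$fdr_max %||% 0.05)
          majority_leading_edge(sel$leading_edge,
                                threshold = params$threshold %||% 0.5)
        })
        sig <- consensus_signature(les[[1]], les[[2]],
                                   name = params$name %||% "NeuMo")
        write_signature(sig, file.path(out, "signature.gmt"))
        file.path(out, c("signature.gmt", "signature.gmt.json"))
      },
      score = {
        counts <- read_count_matrix(require_upstream(
          path_of("counts", "simulate/counts.tsv"), "simulate", st))
        sig <- read_signature(require_upstream(
          path_of("signature", "signature.gmt"), "signature", st))
        em <- log2cpm(counts, pseudocount = params$pseudocount %||% 1)
        sc <- score_samples(em, sig)
        readr::write_tsv(sc, file.path(out, "scores.tsv"))
        file.path(out, "scores.tsv")
      },
      deconvolve = {
        guide <- read_guide_matrix(require_upstream(
          path_of("guide", "guide.tsv"), "deconvolve", st))
        counts <- read_count_matrix(require_upstream(
          path_of("counts", "simulate/counts.tsv"), "simulate", st))
        m <- as_gene_matrix(counts, "counts")
        cpm <- cpm_matrix(m)
        keep <- intersect(guide$gene, rownames(cpm))
        fit <- fit_semisupervised_nmf(
          as_gene_tibble(cpm[keep, , drop = FALSE]), guide,
          n_restarts = params$n_restarts %||% 10,
          max_iter = params$max_iter %||% 2000,
          tol = params$tol %||% 1e-6, seed = seed_st)
        readr::write_tsv(tidy(fit), file.path(out, "fractions.tsv"))
        jsonlite::write_json(as.list(glance(fit)),
                             file.path(out, "deconv_fit.json"),
                             auto_unbox = TRUE, digits = NA)
        file.path(out, c("fractions.tsv", "deconv_fit.json"))
      },
      stability = {
        sim <- simulate_cells(
          n_cells = params$n_cells %||% 200,
          state_props = params$state_props %||% c(0.5, 0.5),
          fold_up = params$fold_up %||% 8, seed = seed_st)
        sw <- stability_sweep(
          knn_louvain_clusterer(k = params$k %||% 10),
          log1p(sim$counts),
          resolutions = params$resolutions %||% seq(0.1, 0.5, 0.05),
          n_reseeds = params$n_reseeds %||% 20, base_seed = seed_st)
        readr::write_tsv(tidy(sw), file.path(out, "stability_trace.tsv"))
        jsonlite::write_json(as.list(glance(sw)),
                             file.path(out, "stability.json"),
                             auto_unbox = TRUE, digits = NA)
        file.path(out, c("stability_trace.tsv", "stability.json"))
      },
      overlap = {
        sets <- read_gmt(require_upstream(
          path_of("gmt", "sets.gmt"), "overlap", st))
        om <- pairwise_overlap(sets)
        readr::write_tsv(as_gene_tibble(om) |> dplyr::rename(set = "gene"),
                         file.path(out, "overlap.tsv"))
        file.path(out, "overlap.tsv")
      }
    )
    manifest$stages[[st]] <- list(
      seed = seed_st,
      params = if (length(params)) params else NULL,
      outputs = as.list(unname(tools::md5sum(unname(written))))
    )
    outputs <- c(outputs, written)
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
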