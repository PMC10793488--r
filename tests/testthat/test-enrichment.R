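test_that("GMT collections round-trip and are validated", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "sets.gmt")
  sets <- list(setA = c("a", "b", "c"), setB = c("c", "d"))
  write_gmt(sets, p, descriptions = c(setA = "first", setB = "second"))
  back <- read_gmt(p)
  expect_equal(lapply(back, sort), lapply(sets, sort), ignore_attr = TRUE)
  expect_equal(attr(back, "descriptions")[["setA"]], "first")

  writeLines(c("dup\td\ta\tb", "dup\td\tc"), p)
  expect_error(read_gmt(p), "Duplicate")
  writeLines(c("ok\td\ta", "empty\td"), p)
  expect_error(read_gmt(p), "empty")
  expect_error(write_gmt(list(x = character()), p), "Empty")
})

test_that("enrichment score reproduces the hand-enumerated running sum", {
  rl <- tibble::tibble(gene = paste0("g", 1:5), score = c(5, 4, 3, 2, 1))
  r <- enrichment_score(rl, c("g1", "g2"), weight = 1)
  expect_equal(r$running$running, c(5 / 9, 1, 2 / 3, 1 / 3, 0))
  expect_equal(r$es, 1)
  expect_equal(sort(r$leading_edge), c("g1", "g2"))

  rb <- enrichment_score(rl, c("g4", "g5"), weight = 1)
  expect_lt(rb$es, 0)
  expect_equal(sort(rb$leading_edge), c("g4", "g5"))

  # unweighted single hit at rank 1 peaks immediately: full deviation of 1
  # before any miss step is taken (cross-checked against fgsea)
  r1 <- enrichment_score(rl, "g1", weight = 0)
  expect_equal(r1$es, 1)
  expect_equal(r1$peak_index, 1)

  expect_error(enrichment_score(rl, "absent"), "present")
  expect_error(enrichment_score(rl, rl$gene), "miss step")
})

test_that("enrichment score stays in [-1, 1] with contained leading edges", {
  withr::with_seed(11, {
    for (i in 1:20) {
      n <- sample(10:60, 1)
      rl <- tibble::tibble(gene = sprintf("g%03d", 1:n),
                           score = stats::rnorm(n))
      set <- sample(rl$gene, sample(2:min(8, n - 1), 1))
      r <- enrichment_score(rl, set)
      expect_true(r$es >= -1 && r$es <= 1)
      expect_true(all(r$leading_edge %in% set))
    }
  })
})

test_that("both ES code paths agree with a brute-force oracle and with fgsea", {
  withr::with_seed(12, {
    rl <- tibble::tibble(gene = sprintf("g%03d", 1:100),
                         score = sort(stats::rnorm(100), decreasing = TRUE))
    for (i in 1:10) {
      set <- sample(rl$gene, sample(3:15, 1))
      idx <- which(rl$gene %in% set)
      es_main <- enrichment_score(rl, set)$es
      es_fast <- neumo:::es_from_positions(idx, abs(rl$score), 100)[1]
      es_brute <- brute_es(rl$score, idx)
      expect_equal(es_main, es_brute)
      expect_equal(es_fast, es_brute)
      es_fgsea <- fgsea::calcGseaStat(rl$score, idx, gseaParam = 1)
      expect_equal(es_main, es_fgsea, tolerance = 1e-9)
    }
  })
})

test_that("permutation p-values match exhaustive enumeration on small rankings", {
  rl <- tibble::tibble(gene = paste0("g", 1:8),
                       score = c(3.2, 2.5, 1.9, 1.2, 0.7, 0.3, -0.4, -1.1))
  for (set in list(c("g1", "g3"), c("g2", "g5", "g7"))) {
    k <- length(set)
    n_perm <- 4000
    res <- suppressWarnings(
      preranked_gsea(rl, stats::setNames(list(set), "s"), n_perm = n_perm,
                     min_size = 2, seed = 77))
    # oracle: enumerate all C(8, k) placements with the brute-force walker
    combos <- utils::combn(8, k)
    enum_es <- apply(combos, 2, function(idx)
      brute_es(rl$score, idx))
    obs <- res$es[1]
    eps <- 1e-9  # placements with mathematically equal ES tie with the observed
    if (obs >= 0) {
      p_exact <- (sum(enum_es >= obs - eps & enum_es >= 0)) / sum(enum_es >= 0)
    } else {
      p_exact <- (sum(enum_es <= obs + eps)) / sum(enum_es < 0)
    }
    expect_lt(abs(res$pvalue[1] - p_exact), 2 / sqrt(n_perm))
  }
})

test_that("GSEA is seed-deterministic and calibrated on shuffled scores", {
  pvals <- c()
  nes_abs <- c()
  withr::with_seed(13, {
    for (rep in 1:20) {
      rl <- tibble::tibble(gene = sprintf("g%03d", 1:300),
                           score = stats::rnorm(300))
      sets <- stats::setNames(
        lapply(1:20, function(i) sample(rl$gene, 10)),
        sprintf("set%02d", 1:20))
      res <- preranked_gsea(rl, sets, n_perm = 200, seed = 1000 + rep)
      pvals <- c(pvals, res$pvalue)
      nes_abs <- c(nes_abs, abs(res$nes))
    }
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.04)
  expect_lt(abs(stats::median(nes_abs) - 1), 0.15)

  rl <- toy_ranks(100)
  sets <- list(a = rl$gene[c(1, 4, 9, 20, 33, 50)],
               b = rl$gene[c(2, 40, 60, 80, 90, 99)])
  r1 <- preranked_gsea(rl, sets, n_perm = 200, seed = 5)
  r2 <- preranked_gsea(rl, sets, n_perm = 200, seed = 5)
  expect_identical(r1$nes, r2$nes)
  expect_identical(r1$fdr, r2$fdr)
})

test_that("a planted top-loaded set is detected with high power", {
  hits <- vapply(1:100, function(rep) {
    withr::with_seed(3000 + rep, {
      n <- 300
      scores <- sort(stats::rnorm(n, sd = 1), decreasing = TRUE)
      genes <- sprintf("g%03d", 1:n)
      planted <- sample(genes[1:40], 12)  # concentrated near the top
      decoys <- stats::setNames(lapply(1:5, function(i) sample(genes, 12)),
                                sprintf("decoy%d", 1:5))
      rl <- tibble::tibble(gene = genes, score = scores)
      res <- preranked_gsea(rl, c(list(planted = planted), decoys),
                            n_perm = 150, seed = 3000 + rep)
      row <- res[res$set == "planted", ]
      row$nes > 0 && row$fdr <= 0.05
    })
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("threshold selection is inclusive and direction-aware", {
  res <- tibble::tibble(set = c("at", "below", "neg", "weakneg"),
                        size = 10, es = c(0.8, 0.7, -0.8, -0.5),
                        nes = c(2.5, 2.49, -2.6, -1.0),
                        pvalue = 0.001, fdr = c(0.05, 0.01, 0.01, 0.01),
                        leading_edge = list("a", "b", "c", "d"))
  pos <- select_enriched(res)
  expect_equal(pos$set, "at")
  expect_true(pos$boundary)
  neg <- select_enriched(res, direction = "negative")
  expect_equal(neg$set, "neg")
})

test_that("hypergeometric ORA matches closed-form tail probabilities", {
  universe <- sprintf("u%02d", 1:20)
  res <- hypergeometric_ora(universe[1:5], universe,
                            list(hit = universe[1:5]))
  expect_equal(res$p, 1 / choose(20, 5))

  uni100 <- sprintf("u%03d", 1:100)
  res0 <- hypergeometric_ora(uni100[1:5], uni100,
                             list(miss = uni100[6:10]))
  expect_equal(res0$overlap, 0)
  expect_gte(res0$p, 0.5)

  res_empty <- hypergeometric_ora(character(), uni100,
                                  list(s = uni100[1:5]))
  expect_equal(res_empty$p, 1)

  expect_error(hypergeometric_ora(c("u001", "zzz"), uni100, list(s = uni100)),
               "zzz")
})
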