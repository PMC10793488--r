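test_that("majority leading edge counts membership against n_sets/2", {
  sets <- list(c("a", "b"), c("a", "c"), c("a", "d"))
  expect_equal(majority_leading_edge(sets), "a")
  expect_equal(majority_leading_edge(list(c("x", "y"))), c("x", "y"))
  expect_length(majority_leading_edge(list("a", "b", "c")), 0)

  # at exactly half: default keeps, strict majority drops
  half <- list(c("a", "b"), c("a", "c"), c("b", "d"), c("c", "d"))
  expect_true("a" %in% majority_leading_edge(half))          # 2 >= 2
  expect_false("a" %in% majority_leading_edge(half, strict = TRUE))
})

test_that("consensus signature is a commutative idempotent intersection", {
  s1 <- consensus_signature(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(s1$genes, c("b", "c"))
  s2 <- consensus_signature(c("b", "c", "d"), c("a", "b", "c"))
  expect_equal(s1$genes, s2$genes)
  s3 <- consensus_signature(s1$genes, s1$genes)
  expect_equal(s3$genes, s1$genes)
  expect_warning(consensus_signature("a", "b"), "empty")
})

test_that("signatures regenerate from stored provenance and round-trip disk", {
  les_yes <- list(c("a", "b", "x"), c("a", "b", "y"), c("a", "z"))
  les_no <- list(c("a", "c"), c("a", "b"))
  sig <- consensus_signature(
    majority_leading_edge(les_yes), majority_leading_edge(les_no),
    provenance = list(threshold = 0.5, leading_edges_yes = les_yes,
                      leading_edges_no = les_no))
  rebuilt <- consensus_signature(
    majority_leading_edge(sig$provenance$leading_edges_yes,
                          threshold = sig$provenance$threshold),
    majority_leading_edge(sig$provenance$leading_edges_no,
                          threshold = sig$provenance$threshold))
  expect_equal(rebuilt$genes, sig$genes)

  p <- file.path(withr::local_tempdir(), "sig.gmt")
  write_signature(sig, p)
  back <- read_signature(p)
  expect_equal(back$genes, sig$genes)
  expect_equal(back$provenance$threshold, 0.5)
})

test_that("sample scores are the mean log2CPM over present signature genes", {
  em <- tibble::tibble(gene = c("a", "b", "c"),
                       s1 = c(1, 3, 100), s2 = c(2, 2, -5))
  sc <- score_samples(em, c("a", "b"))
  expect_equal(sc$score, c(2, 2))
  expect_equal(sc$n_genes_used, c(2, 2))

  # constant matrix over the signature genes
  cm <- tibble::tibble(gene = c("a", "b"), s1 = c(7, 7), s2 = c(7, 7))
  expect_equal(score_samples(cm, c("a", "b"))$score, c(7, 7))

  expect_warning(sc2 <- score_samples(em, c("a", "b", "zz")), "absent")
  expect_equal(sc2$score, c(2, 2))
  expect_error(score_samples(em, c("a", "zz"), missing_policy = "error"),
               "absent")
  expect_error(score_samples(em, "zz"), "No signature gene")
})

test_that("scoring is row-order invariant and affine-equivariant", {
  withr::with_seed(21, {
    m <- matrix(stats::rnorm(200), 20, 10,
                dimnames = list(sprintf("g%02d", 1:20),
                                sprintf("s%02d", 1:10)))
    em <- dplyr::bind_cols(tibble::tibble(gene = rownames(m)),
                           tibble::as_tibble(m))
    sig <- sample(rownames(m), 6)
    base <- score_samples(em, sig)
    shuffled <- em[sample(nrow(em)), ]
    expect_equal(score_samples(shuffled, sig)$score, base$score)

    scaled <- em
    scaled[-1] <- 3 * scaled[-1] + 2
    expect_equal(score_samples(scaled, sig)$score, 3 * base$score + 2)
  })
})

test_that("correlation expansion finds exactly-planted correlated genes", {
  withr::with_seed(22, {
    n <- 20
    s <- stats::rnorm(n)
    sstd <- (s - mean(s)) / stats::sd(s)
    r_target <- 0.8
    # genes with sample correlation exactly 0.8: r*s + sqrt(1-r^2)*e_perp
    planted <- t(vapply(1:25, function(i) {
      e <- stats::rnorm(n)
      e <- stats::residuals(stats::lm(e ~ sstd))
      e <- e / stats::sd(e)
      r_target * sstd + sqrt(1 - r_target^2) * e
    }, numeric(n)))
    noise <- matrix(stats::rnorm(25 * n), 25, n)
    m <- rbind(planted, noise)
    rownames(m) <- c(sprintf("hit%02d", 1:25), sprintf("null%02d", 1:25))
    colnames(m) <- sprintf("s%02d", 1:n)
    em <- dplyr::bind_cols(tibble::tibble(gene = rownames(m)),
                           tibble::as_tibble(m))
    scores <- tibble::tibble(sample = colnames(m), score = s)
    found <- expand_signature(em, scores, r_min = 0.7)
    sens <- mean(sprintf("hit%02d", 1:25) %in% found)
    expect_gte(sens, 0.9)
    # a gene equal to the score itself is always found; its negation never
    em2 <- dplyr::bind_rows(em, tibble::tibble(gene = "self", !!!as.list(
      stats::setNames(s, colnames(m)))))
    em2 <- dplyr::bind_rows(em2, tibble::tibble(gene = "anti", !!!as.list(
      stats::setNames(-s, colnames(m)))))
    found2 <- expand_signature(em2, scores, r_min = 0.7)
    expect_true("self" %in% found2)
    expect_false("anti" %in% found2)
  })
  expect_error(
    expand_signature(tibble::tibble(gene = "a", s1 = 1, s2 = 2),
                     tibble::tibble(sample = c("s1", "s2"), score = 1:2)),
    "3 samples")
})

test_that("group comparisons reproduce exact rank-sum probabilities", {
  sc <- tibble::tibble(sample = paste0("s", 1:6), score = c(1, 2, 3, 10, 11, 12))
  grp <- tibble::tibble(sample = sc$sample, group = rep(c("lo", "hi"), each = 3))
  res <- compare_scores(sc, grp, levels = c("lo", "hi"))
  expect_equal(res$delta, -9)
  expect_equal(res$p_value, 0.1)  # most extreme of C(6,3)=20 labelings
  expect_equal(res$test, "wilcoxon rank-sum")

  same <- tibble::tibble(sample = paste0("s", 1:6),
                         score = rep(c(1, 2, 3), 2))
  res2 <- compare_scores(same, grp)
  expect_equal(res2$delta, 0)
  expect_equal(res2$p_value, 1)

  # paired route uses the signed-rank test
  pairs <- tibble::tibble(sample = sc$sample,
                          subject = rep(c("a", "b", "c"), 2))
  res3 <- compare_scores(sc, grp, paired_by = pairs, levels = c("lo", "hi"))
  expect_equal(res3$test, "wilcoxon signed-rank")
  expect_equal(res3$delta, -9)

  expect_error(compare_scores(sc, tibble::tibble(sample = sc$sample,
                                                 group = "one")), "2 groups")
})

test_that("detection power increases with the group shift", {
  power_at <- function(shift) {
    mean(vapply(1:100, function(i) {
      withr::with_seed(4000 + i, {
        sc <- tibble::tibble(
          sample = paste0("s", 1:20),
          score = c(stats::rnorm(10), stats::rnorm(10, mean = shift)))
        grp <- tibble::tibble(sample = sc$sample,
                              group = rep(c("a", "b"), each = 10))
        compare_scores(sc, grp)$p_value < 0.05
      })
    }, logical(1)))
  }
  expect_gt(power_at(2), power_at(0.5))
})

test_that("meta-analytic pooling matches closed forms and metafor", {
  one <- tibble::tibble(study = "s1", n1 = 8, n2 = 8, mean1 = 3, mean2 = 2,
                        sd1 = 1, sd2 = 1)
  fit1 <- pool_mean_differences(one)
  se1 <- sqrt(1 / 8 + 1 / 8)
  expect_equal(fit1$effect, 1)
  expect_equal(fit1$ci_low, 1 - 1.96 * se1)
  expect_equal(fit1$ci_high, 1 + 1.96 * se1)

  two <- dplyr::bind_rows(one, dplyr::mutate(one, study = "s2"))
  fit2 <- pool_mean_differences(two)
  expect_equal(fit2$effect, 1)
  expect_equal(fit2$se, se1 / sqrt(2))
  expect_equal(fit2$tau2, 0)

  het <- tibble::tibble(study = c("a", "b", "c"), n1 = c(10, 14, 8),
                        n2 = c(10, 12, 9), mean1 = c(2.0, 3.5, 1.2),
                        mean2 = c(1.0, 1.1, 1.4), sd1 = c(1, 1.5, 0.8),
                        sd2 = c(1.1, 1.2, 0.7))
  fixed <- pool_mean_differences(het, model = "fixed")
  random <- pool_mean_differences(het, model = "random")
  expect_gte(random$tau2, 0)
  expect_lte(random$ci_low, fixed$ci_low)
  expect_gte(random$ci_high, fixed$ci_high)

  yi <- het$mean1 - het$mean2
  vi <- het$sd1^2 / het$n1 + het$sd2^2 / het$n2
  mf_dl <- metafor::rma(yi = yi, vi = vi, method = "DL")
  expect_equal(random$effect, as.numeric(mf_dl$beta), tolerance = 1e-10)
  expect_equal(random$tau2, mf_dl$tau2, tolerance = 1e-10)
  expect_equal(random$se, mf_dl$se, tolerance = 1e-10)
  mf_fe <- metafor::rma(yi = yi, vi = vi, method = "FE")
  expect_equal(fixed$effect, as.numeric(mf_fe$beta), tolerance = 1e-10)

  expect_equal(sum(tidy(random)$weight), 1)
  expect_error(pool_mean_differences(dplyr::mutate(one, sd1 = 0, sd2 = 0)),
               "degenerate")
})

test_that("module scores separate planted cell states", {
  cells <- simulate_cells(500, c(0.5, 0.5), fold_up = 8, seed = 31)
  expr <- log1p(cells$counts)
  sc <- module_score_cells(expr, cells$marker_sets$state1, seed = 32)
  sc_again <- module_score_cells(expr, cells$marker_sets$state1, seed = 32)
  expect_identical(sc, sc_again)

  in_state <- cells$true_state == "state1"
  # rank-sum AUC
  auc <- (sum(rank(sc)[in_state]) - sum(in_state) * (sum(in_state) + 1) / 2) /
    (sum(in_state) * sum(!in_state))
  expect_gte(auc, 0.9)

  # simple mode on a constant matrix is constant
  cm <- matrix(5, 10, 6, dimnames = list(paste0("c", 1:10), paste0("g", 1:6)))
  expect_equal(unname(module_score_cells(cm, c("g1", "g2"), n_ctrl = 0)),
               rep(5, 10))
  expect_error(module_score_cells(cm, "zz"), "measured")
})
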