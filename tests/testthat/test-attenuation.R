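test_that("ratio of log2 fold changes matches printed and derived cases", {
  expect_equal(round(ratio_of_log2fc(0.11, 0.27), 2), 0.41)
  expect_equal(ratio_of_log2fc(0.8, 0.8), 1)
  expect_equal(ratio_of_log2fc(-0.5, -0.25), 2)
  expect_error(ratio_of_log2fc(0.5, 0), "zero")
  expect_error(ratio_of_log2fc(0.5, -0.5), "Discordant")

  # scale invariance under sign-preserving rescaling
  withr::with_seed(1, {
    a <- stats::runif(20, 0.1, 2)
    b <- stats::runif(20, 0.1, 2)
    expect_equal(ratio_of_log2fc(3 * a, 3 * b), ratio_of_log2fc(a, b))
    expect_equal(ratio_of_log2fc(-a, -b), ratio_of_log2fc(a, b))
  })
})

test_that("attenuation classes follow the ratio regions", {
  de_yes <- tibble::tibble(
    gene = c("att", "mild", "neutral", "pot", "disc"),
    log2fc = c(0.2 * 1, 0.9 * 1, 1, 1.5, -0.5))
  de_no <- tibble::tibble(gene = de_yes$gene, log2fc = c(1, 1, 1, 1, 0.5))
  rec <- classify_attenuation(de_yes, de_no, de_yes$gene)
  expect_equal(rec$klass,
               c("attenuated", "attenuated", "neutral", "potentiated",
                 "discordant"))
  expect_true(is.na(rec$ratio[rec$klass == "discordant"]))
  counts <- dplyr::count(rec, klass)
  expect_equal(counts$n[counts$klass == "attenuated"], 2)

  expect_error(classify_attenuation(de_yes, de_no, c("att", "missing")),
               "missing")
})

test_that("DEG overlap summary counts up/down, shared and same-direction", {
  de_yes <- tibble::tibble(gene = letters[1:6],
                           log2fc = c(2, -1, 0.5, 1, -2, 0.3),
                           fdr = c(0.01, 0.01, 0.2, 0.04, 0.01, 0.5))
  de_no <- tibble::tibble(gene = letters[1:6],
                          log2fc = c(1, 1, 2, 2, -1, 1),
                          fdr = c(0.01, 0.01, 0.01, 0.2, 0.01, 0.01))
  ov <- summarize_deg_overlap(de_yes, de_no)
  expect_equal(ov$up_yes, 2)    # a, d
  expect_equal(ov$down_yes, 2)  # b, e
  expect_equal(ov$up_no, 4)     # a, b, c, f
  expect_equal(ov$down_no, 1)   # e
  expect_equal(ov$shared, 3)    # a, b, e
  expect_equal(ov$unique_yes, 1)
  expect_equal(ov$unique_no, 2)
  expect_setequal(ov$same_direction_genes[[1]], c("a", "e"))
})

test_that("resampling null matches hypergeometric expectation", {
  # 10 genes, exactly 5 attenuated, draws of 4: mean = 4 * 5/10 = 2
  universe <- tibble::tibble(fc_yes = c(rep(0.5, 5), rep(2, 5)),
                             fc_no = rep(1, 10))
  nul <- attenuation_null(universe, n_draw = 4, n_iter = 50000, seed = 42)
  expect_true(abs(mean(nul$counts) - 2) < 0.05)
  expect_true(all(nul$counts >= 0 & nul$counts <= 4))
  expect_length(nul$counts, 50000)

  nul2 <- attenuation_null(universe, n_draw = 4, n_iter = 50000, seed = 42)
  expect_identical(nul$counts, nul2$counts)

  expect_error(attenuation_null(universe, n_draw = 11, n_iter = 10, seed = 1),
               "smaller")
})

test_that("a saturated universe gives every iteration the full count", {
  universe <- tibble::tibble(fc_yes = rep(0.3, 20), fc_no = rep(1, 20))
  nul <- attenuation_null(universe, n_draw = 5, n_iter = 200, seed = 2)
  expect_true(all(nul$counts == 5))
})

test_that("the empirical attenuation test flags out-of-range counts", {
  universe <- tibble::tibble(fc_yes = c(rep(0.5, 50), rep(2, 50)),
                             fc_no = rep(1, 100))
  nul <- attenuation_null(universe, n_draw = 20, n_iter = 1000, seed = 3)
  res <- attenuation_test(nul$max + 1, nul)
  expect_equal(res$p_value, 1 / 1001)
  expect_true(res$outside_range)

  res0 <- attenuation_test(0L, nul)
  expect_true(res0$outside_range)

  med <- as.integer(round(stats::median(nul$counts)))
  resm <- attenuation_test(med, nul)
  expect_true(abs(resm$p_value - 0.5) < 0.1)
})

test_that("empirical p-values are uniform when the observed count is a null draw", {
  withr::with_seed(9, {
    # wide count support so the empirical p lattice is fine enough for KS
    atten <- c(rep(TRUE, 900), rep(FALSE, 1100))
    universe <- tibble::tibble(fc_yes = ifelse(atten, 0.5, 2),
                               fc_no = rep(1, 2000))
    nul <- attenuation_null(universe, n_draw = 500, n_iter = 10000, seed = 91)
    obs <- vapply(1:500, function(i) {
      sum(atten[sample.int(2000, 500)])
    }, integer(1))
    pvals <- vapply(obs, function(o) attenuation_test(o, nul)$p_value,
                    numeric(1))
    ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
    expect_gt(ks$p.value, 0.01)
  })
})

test_that("without attenuation the observed count sits inside the null range", {
  inside <- vapply(1:100, function(i) {
    sim <- simulate_paired_counts(n_genes = 1000, n_pairs_yes = 6,
                                  n_pairs_no = 6, de_fraction = 0.2,
                                  mean_abs_log2fc = 1.5,
                                  attenuation_factor = 1, seed = 2000 + i)
    de <- sim_de_tables(sim)
    ov <- summarize_deg_overlap(de$Yes, de$No)
    shared_dir <- ov$same_direction_genes[[1]]
    if (length(shared_dir) < 10) return(NA)  # degenerate draw, no test
    rec <- classify_attenuation(de$Yes, de$No, shared_dir)
    universe <- classify_attenuation(de$Yes, de$No,
                                     intersect(de$Yes$gene, de$No$gene)) |>
      dplyr::filter(klass != "discordant")
    nul <- attenuation_null(universe, n_draw = length(shared_dir),
                            n_iter = 200, seed = i)
    obs <- sum(rec$klass == "attenuated")
    obs >= nul$min && obs <= nul$max
  }, logical(1))
  expect_gte(mean(inside, na.rm = TRUE), 0.95)
})

test_that("equivalent change index is bounded, symmetric and signed", {
  expect_equal(equivalent_change_index(1, 1), 1)
  expect_equal(equivalent_change_index(1, -1), -1)
  expect_equal(equivalent_change_index(0.5, 1), 0.5)
  expect_equal(equivalent_change_index(0, 1), 0)
  expect_error(equivalent_change_index(0, 0), "undefined")

  withr::with_seed(4, {
    a <- stats::rnorm(50)
    b <- stats::rnorm(50)
    expect_equal(equivalent_change_index(a, b), equivalent_change_index(b, a))
    expect_true(all(abs(equivalent_change_index(a, b)) <= 1))
  })
})
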