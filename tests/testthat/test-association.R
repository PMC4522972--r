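test_that("the correlation screen composes per-feature Pearson tests with BH", {
  set.seed(81)
  n <- 40
  feats <- tibble::tibble(sample_id = paste0("s", 1:n),
                          f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
  target <- tibble::tibble(sample_id = feats$sample_id,
                           value = feats$f1 * 0.8 + rnorm(n, 0, 0.5))
  res <- correlation_screen(feats, target)
  for (i in seq_len(nrow(res))) {
    pc <- pearson_correlation(feats[[res$feature[i]]], target$value)
    expect_equal(res$estimate[i], pc$estimate, tolerance = 1e-12)
    expect_equal(res$p_value[i], pc$p_value, tolerance = 1e-12)
  }
  expect_equal(res$fdr, benjamini_hochberg(res$p_value))

  # the target correlates perfectly with itself when included as a feature
  feats$self <- target$value
  res2 <- correlation_screen(feats, target)
  expect_equal(res2$estimate[res2$feature == "self"], 1)
})

test_that("unusable features are excluded with reasons, not errors", {
  set.seed(82)
  n <- 30
  feats <- tibble::tibble(sample_id = paste0("s", 1:n), good = rnorm(n),
                          flat = 1, sparse = c(rnorm(2), rep(NA, n - 2)))
  target <- setNames(rnorm(n), feats$sample_id)
  expect_message(res <- correlation_screen(feats, target), "2 feature")
  expect_equal(res$feature, "good")
  excl <- attr(res, "excluded")
  expect_setequal(excl$feature, c("flat", "sparse"))
})

test_that("a null screen stays quiet under FDR control", {
  # under a global null, BH yields zero discoveries in ~95% of datasets
  n <- 50
  clean <- vapply(1:20, function(seed) {
    set.seed(8300 + seed)
    feats <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 200), n, 200)))
    feats$sample_id <- paste0("s", 1:n)
    target <- setNames(rnorm(n), feats$sample_id)
    sum(correlation_screen(feats, target)$fdr <= 0.05) == 0
  }, logical(1))
  expect_gte(mean(clean), 0.85)
})

test_that("the one-tailed Mann-Whitney matches exact enumeration", {
  res <- mann_whitney_one_tailed(c(1, 2), c(3, 4), alternative = "B_greater")
  expect_equal(res$u, 0)           # no A value exceeds any B value
  expect_equal(res$p_value, 1 / 6) # 1 of choose(4,2) orderings as extreme
  expect_true(res$exact)

  same <- mann_whitney_one_tailed(c(5, 1, 3), c(5, 1, 3))
  expect_gte(same$p_value, 0.5)
  expect_error(mann_whitney_one_tailed(numeric(0), 1:3), "non-empty")
})

test_that("U statistics and one-sided p-values obey their identities", {
  set.seed(84)
  for (rep in 1:50) {
    a <- rnorm(sample(2:12, 1)); b <- rnorm(sample(2:12, 1))
    res_b <- mann_whitney_one_tailed(a, b, "B_greater")
    res_a <- mann_whitney_one_tailed(a, b, "A_greater")
    u_b <- mann_whitney_one_tailed(b, a, "A_greater")$u
    expect_equal(res_b$u + u_b, length(a) * length(b))  # tie-free complement
    if (res_b$exact) {
      # p_less + p_greater exceeds 1 by exactly P(U = u_obs)
      expect_equal(res_b$p_value + res_a$p_value,
                   1 + dwilcox(res_b$u, length(a), length(b)), tolerance = 1e-12)
    }
  }
})

test_that("exact and normal-approximation p-values agree for moderate n", {
  set.seed(85)
  for (rep in 1:20) {
    a <- rnorm(15); b <- rnorm(15, 0.3)
    exact_p <- mann_whitney_one_tailed(a, b, "B_greater")$p_value
    approx_p <- suppressWarnings(wilcox.test(a, b, alternative = "less",
                                             exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(exact_p - approx_p), 0.02)
  }
})

test_that("stromal comparison detects higher scores in reactive stroma", {
  set.seed(86)
  scores <- tibble::tibble(sample_id = paste0("s", 1:60),
                           score = c(rnorm(20), rnorm(40, 1.2)))
  stromal <- tibble::tibble(sample_id = scores$sample_id,
                            stroma = rep(c("+", "++", "+++"), each = 20))
  res <- stromal_test(scores, stromal)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$n_low_stroma, 20)
  expect_equal(res$n_reactive, 40)
  res_unpooled <- stromal_test(scores, stromal, pool_high = FALSE)
  expect_equal(res_unpooled$n_reactive, 20)
})
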