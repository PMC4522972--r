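test_that("classic Welch reproduces the closed-form worked example", {
  res <- robust_welch_test(c(1, 2, 3), c(4, 5, 6), mode = "classic")
  expect_equal(res$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(round(res$p_value, 4), 0.0213)
})

test_that("classic mode agrees with t.test on random inputs", {
  set.seed(11)
  for (rep in 1:50) {
    x <- rnorm(sample(3:20, 1)); y <- rnorm(sample(3:20, 1), sample(0:2, 1))
    res <- robust_welch_test(x, y, mode = "classic")
    tt <- t.test(x, y)
    expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$df, unname(tt$parameter), tolerance = 1e-10)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("identical groups give a null statistic in both modes", {
  x <- c(1.2, 3.4, 2.2, 0.7)
  for (mode in c("robust", "classic")) {
    res <- robust_welch_test(x, x, mode = mode)
    expect_equal(res$statistic, 0)
    expect_equal(res$p_value, 1)
  }
})

test_that("robust mode holds its nominal size under the null", {
  set.seed(12)
  p <- replicate(5000, robust_welch_test(rnorm(20), rnorm(20))$p_value)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.015)
})

test_that("zero dispersion yields an infinite statistic or a clear error", {
  res <- robust_welch_test(c(1, 1, 1), c(2, 2, 2))
  expect_equal(res$statistic, -Inf)
  expect_equal(res$p_value, 0)
  expect_error(robust_welch_test(c(1, 1, 1), c(1, 1, 1)), "no dispersion")
  expect_error(robust_welch_test(c(1, 2), c(1, 2, 3)), ">= 3")
})

test_that("Benjamini-Hochberg matches its definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(13)
  for (rep in 1:50) {
    p <- round(runif(sample(2:30, 1)), sample(1:4, 1))
    expect_equal(benjamini_hochberg(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("derivation recovers planted genes with correct signs", {
  co <- simulate_cohort(sim_config(n_samples = 60, n_genes = 400,
                                   n_signature_genes = 40, seed = 31))
  fit <- derive_signature(co$expression, truth_labels(co))
  planted <- co$truth_signature
  hits <- dplyr::inner_join(fit$signature, planted, by = "gene",
                            suffix = c("_got", "_true"))
  expect_gte(nrow(hits), 0.6 * nrow(planted))
  expect_true(all(hits$coefficient_got == hits$coefficient_true))
  expect_lte(sum(!fit$signature$gene %in% planted$gene), 0.02 * 400)
})

test_that("flipping the group labels negates statistics and coefficients", {
  co <- simulate_cohort(sim_config(n_samples = 40, n_genes = 150,
                                   n_signature_genes = 20, seed = 37))
  lab <- truth_labels(co)
  flipped <- dplyr::mutate(lab, label = factor(
    dplyr::case_match(as.character(label), "high" ~ "low", "low" ~ "high",
                      .default = "excluded"),
    levels = levels(label)))
  f1 <- derive_signature(co$expression, lab)
  f2 <- derive_signature(co$expression, flipped)
  expect_equal(f2$table$statistic, -f1$table$statistic)
  expect_equal(f2$table$p_value, f1$table$p_value)
  expect_equal(f2$table$fdr, f1$table$fdr)
  common <- intersect(f1$signature$gene, f2$signature$gene)
  expect_setequal(f1$signature$gene, f2$signature$gene)
  expect_equal(f2$signature$coefficient[match(common, f2$signature$gene)],
               -f1$signature$coefficient[match(common, f1$signature$gene)])
})

test_that("selection is monotone in the FDR threshold and in effect size", {
  co <- simulate_cohort(sim_config(n_samples = 60, n_genes = 300,
                                   n_signature_genes = 30, seed = 41))
  lab <- truth_labels(co)
  sel <- lapply(c(0.01, 0.05, 0.2), function(thr) {
    suppressWarnings(derive_signature(co$expression, lab,
                                      fdr_threshold = thr)$signature$gene)
  })
  expect_true(all(sel[[1]] %in% sel[[2]]))
  expect_true(all(sel[[2]] %in% sel[[3]]))

  sens <- vapply(c(0.5, 1.0, 1.5, 2.0), function(eff) {
    cohort <- simulate_cohort(sim_config(n_samples = 60, n_genes = 300,
                                         n_signature_genes = 30,
                                         effect_size = eff, seed = 43))
    fit <- suppressWarnings(derive_signature(cohort$expression,
                                             truth_labels(cohort)))
    mean(cohort$truth_signature$gene %in% fit$signature$gene)
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
})

test_that("threshold edge cases behave as contracted", {
  co <- simulate_cohort(sim_config(n_samples = 40, n_genes = 100,
                                   n_signature_genes = 10, seed = 47))
  expect_warning(
    fit <- derive_signature(co$expression, truth_labels(co), fold_threshold = Inf),
    "empty signature")
  expect_equal(nrow(fit$signature), 0L)

  # genes with too much missingness are dropped and counted
  e <- co$expression
  e[1, -1] <- NA
  fit2 <- derive_signature(e, truth_labels(co))
  expect_equal(fit2$n_dropped, 1L)
  expect_false(e$gene[1] %in% fit2$table$gene)
})
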