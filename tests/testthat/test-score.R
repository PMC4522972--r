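test_that("the signature score is the signed sum of expression values", {
  expr <- tibble::tibble(gene = c("A", "B"), s1 = c(3, 1), s2 = c(0, 0))
  sig <- gene_signature(c("A", "B"), c(1L, -1L))
  sc <- score_samples(expr, sig)
  expect_equal(sc$score, c(2, 0))  # 3 - 1, and 0 - 0
  expect_equal(sc$matched_genes, c(2L, 2L))
})

test_that("scoring equals an explicit per-sample loop oracle", {
  set.seed(51)
  for (rep in 1:50) {
    e <- rand_expr(sample(5:30, 1), sample(2:10, 1), na_frac = 0.05)
    k <- sample(2:nrow(e), 1)
    genes <- sample(e$gene, k)
    sig <- gene_signature(genes, sample(c(-1L, 1L), k, replace = TRUE))
    sc <- score_samples(e, sig)
    m <- as.matrix(e[-1]); rownames(m) <- e$gene
    for (j in seq_len(ncol(m))) {
      acc <- 0
      for (i in seq_len(nrow(sig))) {
        v <- m[sig$gene[i], j]
        if (!is.na(v)) acc <- acc + sig$coefficient[i] * v
      }
      expect_equal(sc$score[j], acc, tolerance = 1e-12)
    }
  }
})

test_that("scores are linear in expression and odd under coefficient flips", {
  set.seed(52)
  e <- rand_expr(20, 8)
  sig <- gene_signature(sample(e$gene, 10), rep_len(c(1L, -1L), 10))
  sc <- score_samples(e, sig)
  e3 <- e; e3[-1] <- e3[-1] * 3
  expect_equal(score_samples(e3, sig)$score, 3 * sc$score, tolerance = 1e-12)
  flipped <- gene_signature(sig$gene, -sig$coefficient)
  expect_equal(score_samples(e, flipped)$score, -sc$score, tolerance = 1e-12)
})

test_that("absent signature genes are reported without touching the scores", {
  e <- rand_expr(10, 4)
  sig <- gene_signature(c(e$gene[1:3]), c(1L, -1L, 1L))
  sc <- score_samples(e, sig)
  sig_plus <- gene_signature(c(sig$gene, "NOT_THERE"), c(sig$coefficient, 1L))
  sc2 <- score_samples(e, sig_plus)
  expect_equal(sc2$score, sc$score)
  expect_equal(attr(sc2, "missing_genes"), "NOT_THERE")
  expect_equal(sc2$matched_genes + length(attr(sc2, "missing_genes")),
               rep(nrow(sig_plus), nrow(sc2)))
  sig_none <- gene_signature(c("X1", "X2"), c(1L, -1L))
  expect_error(score_samples(e, sig_none), "no signature gene")
})

test_that("standardize and scale_by_n variants transform as documented", {
  set.seed(53)
  e <- rand_expr(12, 6)
  sig <- gene_signature(e$gene[1:4], c(1L, -1L, 1L, -1L))
  raw <- score_samples(e, sig)
  scaled <- score_samples(e, sig, scale_by_n = TRUE)
  expect_equal(scaled$score, raw$score / raw$matched_genes, tolerance = 1e-12)

  std <- score_samples(e, sig, standardize = TRUE)
  m <- as.matrix(e[-1]); rownames(m) <- e$gene
  z <- t(scale(t(m[sig$gene, ])))
  expect_equal(std$score, colSums(z * sig$coefficient), tolerance = 1e-12,
               ignore_attr = TRUE)
  # standardization kills sensitivity to per-gene location shifts
  e_shift <- e; e_shift[2, -1] <- e_shift[2, -1] + 100
  expect_equal(score_samples(e_shift, sig, standardize = TRUE)$score, std$score,
               tolerance = 1e-9)
})

test_that("median dichotomization follows the ties-go-low rule", {
  sc <- tibble::tibble(sample_id = paste0("s", 1:3), score = c(1, 2, 3))
  expect_equal(as.character(dichotomize_scores(sc)$group), c("low", "low", "high"))
  sc4 <- tibble::tibble(sample_id = paste0("s", 1:4), score = c(1, 2, 3, 4))
  expect_equal(as.character(dichotomize_scores(sc4)$group),
               c("low", "low", "high", "high"))
  expect_error(dichotomize_scores(tibble::tibble(sample_id = c("a", "b"),
                                                 score = c(2, 2))), "identical")
})

test_that("median dichotomization balances groups up to ties and transforms", {
  set.seed(54)
  for (rep in 1:100) {
    n <- sample(2:40, 1)
    sc <- tibble::tibble(sample_id = paste0("s", 1:n),
                         score = round(rnorm(n), sample(c(0, 6), 1)))
    if (min(sc$score) == max(sc$score)) next
    g <- dichotomize_scores(sc)
    ties <- sum(sc$score == median(sc$score))
    # with ties sent low, the imbalance is bounded by twice the tie count
    expect_lte(abs(sum(g$group == "high") - sum(g$group == "low")), 2 * ties)
    sc2 <- dplyr::mutate(sc, score = exp(score))  # strictly increasing map
    expect_equal(dichotomize_scores(sc2)$group, g$group)
  }
})

test_that("stratified dichotomization uses within-stratum medians", {
  sc <- tibble::tibble(sample_id = paste0("s", 1:6),
                       score = c(1, 2, 3, 10, 20, 30))
  strata <- tibble::tibble(sample_id = sc$sample_id,
                           er = rep(c("neg", "pos"), each = 3))
  g <- dichotomize_scores(sc, stratify_by = strata)
  expect_equal(as.character(g$group), rep(c("low", "low", "high"), 2))
  # pooled median (6.5) would instead call all of stratum 1 low
  g_pooled <- dichotomize_scores(sc)
  expect_equal(as.character(g_pooled$group),
               c("low", "low", "low", "high", "high", "high"))
})
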