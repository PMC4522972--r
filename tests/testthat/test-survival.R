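km_surv_at <- function(km, t) {
  tab <- km$table[km$table$n_event > 0, ]
  tab$survival[match(t, tab$time)]
}

test_that("Kaplan-Meier reproduces hand-worked product-limit examples", {
  d <- tibble::tibble(sample_id = c("a", "b", "c"), time = c(1, 2, 3), event = 1)
  km <- kaplan_meier(d)
  expect_equal(km_surv_at(km, c(1, 2, 3)), c(2 / 3, 1 / 3, 0))

  d2 <- tibble::tibble(sample_id = c("a", "b", "c"), time = c(1, 2, 3),
                       event = c(0, 1, 1))  # first subject censored at 1
  km2 <- kaplan_meier(d2)
  expect_equal(km_surv_at(km2, c(2, 3)), c(1 / 2, 0))
  expect_true(all(km2$table$survival <= 1))
  expect_true(all(diff(km2$table$survival) <= 1e-12))

  expect_error(kaplan_meier(tibble::tibble(sample_id = character(),
                                           time = numeric(), event = integer())),
               "no usable")
})

test_that("without censoring the KM estimate is one minus the empirical CDF", {
  set.seed(71)
  d <- tibble::tibble(sample_id = paste0("s", 1:40),
                      time = sample(1:15, 40, replace = TRUE), event = 1)
  km <- kaplan_meier(d)
  ev <- km$table[km$table$n_event > 0, ]
  expect_equal(ev$survival, 1 - ecdf(d$time)(ev$time), tolerance = 1e-12)
})

test_that("log-rank matches the hypergeometric O/E/V oracle", {
  d6 <- tibble::tibble(sample_id = paste0("s", 1:6),
                       time = c(1, 3, 5, 2, 4, 6), event = 1,
                       grp = rep(c("A", "B"), each = 3))
  lr <- log_rank(d6, "grp")
  oracle <- logrank_oracle(d6$time, d6$event, d6$grp)
  expect_equal(lr$chi_square, oracle$chi_square, tolerance = 1e-12)

  set.seed(72)
  for (rep in 1:100) {
    d <- rand_surv_data(sample(10:60, 1))
    d$grp <- rbinom(nrow(d), 1, 0.5)
    d$time <- round(d$time, 1)  # induce ties
    if (length(unique(d$grp)) < 2 || sum(d$event) == 0) next
    lr <- log_rank(d, "grp")
    expect_equal(lr$chi_square, logrank_oracle(d$time, d$event, d$grp)$chi_square,
                 tolerance = 1e-9)
    expect_gte(lr$chi_square, 0)
    expect_true(lr$p_value >= 0 && lr$p_value <= 1)
  }
})

test_that("log-rank on identical groups is null; duplication scales chi-square", {
  base <- tibble::tibble(time = c(2, 4, 6, 8), event = c(1, 1, 0, 1))
  two <- dplyr::bind_rows(dplyr::mutate(base, grp = "A"),
                          dplyr::mutate(base, grp = "B"))
  two$sample_id <- paste0("s", seq_len(nrow(two)))
  lr <- log_rank(two, "grp")
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)

  set.seed(73)
  d <- rand_surv_data(30)
  d$grp <- rep(c(0, 1), 15)
  chi1 <- log_rank(d, "grp")$chi_square
  d3 <- dplyr::bind_rows(d, d, d)
  d3$sample_id <- paste0("s", seq_len(nrow(d3)))
  # asymptotic: duplication introduces ties, so the (n-d)/(n-1) variance
  # correction keeps the match approximate rather than exact
  expect_equal(log_rank(d3, "grp")$chi_square, 3 * chi1, tolerance = 0.1)

  expect_error(log_rank(dplyr::mutate(d, grp = 1), "grp"), ">= 2")
})

test_that("Cox fitting recovers a known log hazard ratio", {
  set.seed(74)
  n <- 2000
  grp <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.1 * exp(0.7 * grp))
  t_c <- runif(n, 0, quantile(t_ev, 0.7) * 2)
  d <- tibble::tibble(sample_id = paste0("s", 1:n), time = pmin(t_ev, t_c),
                      event = as.integer(t_ev <= t_c), grp = grp)
  fit <- cox_fit(d, "grp")
  expect_lt(abs(fit$table$estimate - 0.7), 0.1)
  expect_equal(fit$table$hazard_ratio, exp(fit$table$estimate))
  expect_true(fit$table$conf_low < fit$table$hazard_ratio &
                fit$table$hazard_ratio < fit$table$conf_high)
})

test_that("the partial-likelihood score vanishes at the fitted coefficients", {
  set.seed(75)
  for (rep in 1:20) {
    d <- rand_surv_data(40, 3)
    fit <- cox_fit(d, c("x1", "x2", "x3"))
    g <- efron_score(fit$table$estimate, d$time, d$event,
                     as.matrix(d[c("x1", "x2", "x3")]))
    expect_lt(max(abs(g)), 1e-6)
  }
})

test_that("Cox estimates transform correctly under rescaling", {
  set.seed(76)
  d <- rand_surv_data(150, 2)
  fit <- cox_fit(d, c("x1", "x2"))
  # time-unit change leaves coefficients alone
  d_days <- dplyr::mutate(d, time = time * 30.44)
  expect_equal(cox_fit(d_days, c("x1", "x2"))$table$estimate,
               fit$table$estimate, tolerance = 1e-8)
  # covariate scaled by c fits coef / c
  d_sc <- dplyr::mutate(d, x1 = x1 * 4)
  expect_equal(cox_fit(d_sc, c("x1", "x2"))$table$estimate[1],
               fit$table$estimate[1] / 4, tolerance = 1e-8)
})

test_that("degenerate Cox inputs are refused by name", {
  set.seed(77)
  d <- rand_surv_data(30)
  d$flat <- 1
  expect_error(cox_fit(d, c("x1", "flat")), "`flat` is constant")
  expect_error(cox_fit(dplyr::mutate(d, event = 0L), "x1"), ">= 1 event")
})

test_that("the interaction LRT is nonnegative and scale-invariant", {
  set.seed(78)
  for (rep in 1:10) {
    co <- simulate_cohort(sim_config(n_samples = 150, n_genes = 20,
                                     n_signature_genes = 5, seed = 700 + rep))
    sc <- score_samples(co$expression, co$truth_signature)
    d <- dplyr::inner_join(co$clinical, sc[c("sample_id", "score")],
                           by = "sample_id")
    res <- interaction_lrt(d)
    expect_gte(res$statistic, 0)
    expect_true(res$p_value >= 0 && res$p_value <= 1)
    # affine rescaling of a continuous score is absorbed by the coefficients
    d2 <- dplyr::mutate(d, score = 3.7 * score - 11)
    expect_equal(interaction_lrt(d2)$statistic, res$statistic, tolerance = 1e-6)
  }
})

test_that("the interaction LRT requires two informative arms", {
  co <- simulate_cohort(sim_config(n_samples = 80, n_genes = 20,
                                   n_signature_genes = 5, seed = 79))
  sc <- score_samples(co$expression, co$truth_signature)
  d <- dplyr::inner_join(co$clinical, sc[c("sample_id", "score")], by = "sample_id")
  expect_error(interaction_lrt(dplyr::mutate(d, treatment = 1)), "both treatment arms")
  d0 <- dplyr::mutate(d, event = ifelse(treatment == 1, 0L, event))
  expect_error(interaction_lrt(d0), ">= 1 event")
})
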