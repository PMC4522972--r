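# Independent oracles and small generators shared across the test files.
# Each oracle implements its quantity from the definition (explicit loops,
# enumeration), never by calling the code path it checks.

# Benjamini-Hochberg by the step-up definition with an explicit double loop:
# q_i = min over j with p_(j) >= p_(i) of min(1, p_(j) * m / rank_(j)).
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in seq_len(m)) {
      rank_j <- which(ord == j)  # rank of p[j] among sorted p
      if (p[j] >= p[i]) {
        best <- min(best, min(1, p[j] * m / rank_j))
      }
    }
    q[i] <- best
  }
  q
}

# Two-group log-rank from the per-event-time 2x2 hypergeometric moments.
logrank_oracle <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & group == g1)
    d_t <- sum(event == 1 & time == t)
    d1_t <- sum(event == 1 & time == t & group == g1)
    o_minus_e <- o_minus_e + (d1_t - d_t * n1_t / n_t)
    if (n_t > 1) {
      v <- v + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  list(chi_square = o_minus_e^2 / v, o_minus_e = o_minus_e, v = v)
}

# Gradient of the Efron-approximation Cox partial log-likelihood.
efron_score <- function(beta, time, event, x) {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  grad <- rep(0, ncol(x))
  for (t in sort(unique(time[event == 1]))) {
    dead <- which(event == 1 & time == t)
    risk <- which(time >= t)
    d <- length(dead)
    sw_r <- sum(w[risk])
    sx_r <- colSums(x[risk, , drop = FALSE] * w[risk])
    sw_d <- sum(w[dead])
    sx_d <- colSums(x[dead, , drop = FALSE] * w[dead])
    grad <- grad + colSums(x[dead, , drop = FALSE])
    for (l in seq_len(d) - 1) {
      grad <- grad - (sx_r - (l / d) * sx_d) / (sw_r - (l / d) * sw_d)
    }
  }
  grad
}

# Exponential two-group survival data with uniform censoring.
rand_surv_data <- function(n, n_covariates = 2, censor_frac = 0.3) {
  x <- matrix(rnorm(n * n_covariates), n, n_covariates,
              dimnames = list(NULL, paste0("x", seq_len(n_covariates))))
  beta <- rnorm(n_covariates, 0, 0.5)
  t_ev <- rexp(n, 0.1 * exp(drop(x %*% beta)))
  t_c <- if (censor_frac > 0) runif(n, 0, quantile(t_ev, 1 - censor_frac) * 2)
  else rep(Inf, n)
  tibble::tibble(sample_id = paste0("r", seq_len(n)),
                 time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c)) |>
    cbind(as.data.frame(x)) |> tibble::as_tibble()
}

# Ground-truth activation labels of a simulated cohort as a grouping table.
truth_labels <- function(cohort) {
  tibble::tibble(
    sample_id = cohort$truth_activation$sample_id,
    label = factor(ifelse(cohort$truth_activation$activation == 1, "high", "low"),
                   levels = c("high", "low", "excluded")))
}

# Small random expression tibble (genes x samples) with optional missingness.
rand_expr <- function(n_genes, n_samples, na_frac = 0) {
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  if (na_frac > 0) m[runif(length(m)) < na_frac] <- NA
  tibble::as_tibble(as.data.frame(m), rownames = "gene")
}
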