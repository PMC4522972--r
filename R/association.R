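# Correlation screens and the one-tailed Mann-Whitney stromal comparison.

#' Correlate a target variable against a panel of features
#'
#' Pearson correlation of each feature column against the target, with
#' pairwise-complete handling of missing values (RPPA panels routinely have
#' per-antibody dropouts) and Benjamini-Hochberg adjustment across all
#' features tested. Features with fewer than 3 complete pairs or zero
#' variance are excluded with a logged reason (attribute `excluded`), not an
#' error.
#'
#' @param features Tibble with `sample_id` plus numeric feature columns.
#' @param target Tibble (`sample_id` + one numeric column) or named vector.
#' @return A tibble `feature`, `n`, `estimate`, `p_value`, `fdr` in input
#'   column order, with attribute `excluded` (tibble `feature`, `reason`).
#' @export
correlation_screen <- function(features, target) {
  tgt <- as_sample_values(target, arg = "target")
  if (!is.data.frame(features) || !"sample_id" %in% names(features)) {
    stop("features must be a data frame with `sample_id`", call. = FALSE)
  }
  feat_cols <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                       "sample_id")
  if (length(feat_cols) == 0) stop("no numeric feature columns", call. = FALSE)
  tv <- tgt$value[match(features$sample_id, tgt$sample_id)]
  rows <- list(); excluded <- list()
  for (f in feat_cols) {
    fv <- features[[f]]
    ok <- complete.cases(fv, tv)
    if (sum(ok) < 3) {
      excluded[[f]] <- "fewer than 3 complete pairs"
      next
    }
    if (sd(fv[ok]) == 0 || sd(tv[ok]) == 0) {
      excluded[[f]] <- "zero variance"
      next
    }
    ct <- cor.test(fv[ok], tv[ok], method = "pearson")
    rows[[f]] <- tibble::tibble(feature = f, n = sum(ok),
                                estimate = unname(ct$estimate),
                                p_value = ct$p.value)
  }
  if (length(rows) == 0) stop("no testable features", call. = FALSE)
  out <- dplyr::bind_rows(rows)
  out$fdr <- benjamini_hochberg(out$p_value)
  attr(out, "excluded") <- tibble::tibble(feature = names(excluded),
                                          reason = unlist(excluded, use.names = FALSE))
  if (length(excluded) > 0) {
    message(length(excluded), " feature(s) excluded from the correlation screen")
  }
  out
}

#' Symmetric pairwise-complete Pearson correlation matrix
#'
#' @param features Tibble with `sample_id` plus numeric feature columns.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(features) {
  if (!is.data.frame(features) || !"sample_id" %in% names(features)) {
    stop("features must be a data frame with `sample_id`", call. = FALSE)
  }
  m <- as.matrix(features[setdiff(names(features), "sample_id")])
  cor(m, use = "pairwise.complete.obs")
}

#' One-tailed Mann-Whitney test
#'
#' U statistic with midranked ties. The p-value is exact (full enumeration,
#' via [stats::wilcox.test()]) when `n_A * n_B <= 400` and there are no
#' ties, otherwise the normal approximation with tie and continuity
#' corrections is used. `alternative = "B_greater"` tests whether values in
#' `b` tend to exceed those in `a`.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param alternative `"B_greater"` or `"A_greater"`.
#' @return A one-row tibble: `u` (the U statistic of group A), `p_value`,
#'   `exact` (logical).
#' @export
mann_whitney_one_tailed <- function(a, b, alternative = c("B_greater", "A_greater")) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) * length(b) <= 400) && !ties
  wt <- suppressWarnings(wilcox.test(
    a, b, alternative = if (alternative == "B_greater") "less" else "greater",
    exact = exact, correct = TRUE))
  tibble::tibble(u = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Compare signature scores across stromal-reactivation groups
#'
#' One-tailed Mann-Whitney test of scores in samples with low stromal
#' reactivation (group `1` / `+`) against samples with moderate-or-high
#' reactivation (groups `2`-`3` / `++`/`+++`, pooled by default), with the
#' alternative that the reactive-stroma group has the greater scores.
#'
#' @param scores Tibble `sample_id`, `score`, or a named vector.
#' @param stromal Tibble with `sample_id` and a stromal grade column coded
#'   `1`/`2`/`3` or `+`/`++`/`+++`.
#' @param pool_high Pool grades 2 and 3 into one comparison group.
#' @return A one-row tibble: `u`, `p_value`, `exact`, `n_low_stroma`,
#'   `n_reactive`.
#' @export
stromal_test <- function(scores, stromal, pool_high = TRUE) {
  sv <- as_sample_values(scores, value = if (is.data.frame(scores) &&
                                             "score" %in% names(scores)) "score",
                         arg = "scores")
  if (!is.data.frame(stromal) || !"sample_id" %in% names(stromal)) {
    stop("stromal must be a data frame with `sample_id`", call. = FALSE)
  }
  gcol <- setdiff(names(stromal), "sample_id")[1]
  g_raw <- as.character(stromal[[gcol]][match(sv$sample_id, stromal$sample_id)])
  grade <- dplyr::case_match(g_raw, c("1", "+") ~ 1L, c("2", "++") ~ 2L,
                             c("3", "+++") ~ 3L, .default = NA_integer_)
  if (all(is.na(grade))) stop("no recognizable stromal grades (1/2/3 or +/++/+++)",
                              call. = FALSE)
  low <- sv$value[!is.na(grade) & grade == 1]
  high <- sv$value[!is.na(grade) & grade >= if (pool_high) 2 else 3]
  res <- mann_whitney_one_tailed(low, high, alternative = "B_greater")
  res$n_low_stroma <- length(low)
  res$n_reactive <- length(high)
  res
}
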