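# Validation of a signature score against proteomic truth labels.

#' Pearson correlation with a t-based test
#'
#' Standard Pearson `r` with a two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df (via
#' [stats::cor.test()]); pairs with missing values are dropped.
#'
#' @param x,y Numeric vectors of equal length with >= 3 complete pairs and
#'   nonzero variance.
#' @return A one-row tibble: `estimate` (r), `statistic` (t), `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance: correlation undefined", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate), statistic = unname(ct$statistic),
                 p_value = ct$p.value, n = length(x))
}

#' ROC curve and AUC of a score against binary truth labels
#'
#' The AUC is computed as the Mann-Whitney U statistic of high-vs-low scores
#' divided by `n_pos * n_neg`, with ties counting 1/2 — identical to the
#' trapezoidal area under the threshold-sweep ROC curve. The p-value tests
#' AUC = 0.5 with the two-sided normal-approximation Mann-Whitney test
#' (tie-corrected, continuity-corrected). Samples labelled `excluded` are
#' dropped before the computation.
#'
#' @param scores Tibble `sample_id`, `score` (e.g. [score_samples()]), or a
#'   named numeric vector.
#' @param truth Truth labels (tibble `sample_id`, `label` in
#'   `high`/`low`/`excluded`), e.g. from [sd_groups()].
#' @return A `roc_result`: `auc`, `p_value`, `n_pos`, `n_neg`, and `curve`
#'   (tibble `threshold`, `fpr`, `tpr` from a sweep over unique scores,
#'   anchored at (0,0) and (1,1)).
#' @export
roc_auc <- function(scores, truth) {
  d <- as_sample_values(scores, value = if (is.data.frame(scores) &&
                                            "score" %in% names(scores)) "score",
                        arg = "scores")
  if (!is.data.frame(truth) || !all(c("sample_id", "label") %in% names(truth))) {
    stop("truth must be a data frame with `sample_id` and `label`", call. = FALSE)
  }
  lab <- as.character(truth$label[match(d$sample_id, truth$sample_id)])
  keep <- !is.na(lab) & lab %in% c("high", "low") & !is.na(d$value)
  s <- d$value[keep]
  pos <- lab[keep] == "high"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("need >= 1 high and >= 1 low truth label among scored samples", call. = FALSE)
  }
  r <- rank(s)
  u <- sum(r[pos]) - n_pos * (n_pos + 1) / 2
  auc <- u / (n_pos * n_neg)
  p <- suppressWarnings(
    wilcox.test(s[pos], s[!pos], alternative = "two.sided",
                exact = FALSE, correct = TRUE)$p.value)
  thr <- sort(unique(s), decreasing = TRUE)
  curve <- tibble::tibble(
    threshold = c(Inf, thr),
    fpr = c(0, vapply(thr, function(t) mean(s[!pos] >= t), numeric(1))),
    tpr = c(0, vapply(thr, function(t) mean(s[pos] >= t), numeric(1))))
  if (curve$fpr[nrow(curve)] < 1 || curve$tpr[nrow(curve)] < 1) {
    curve <- rbind(curve, tibble::tibble(threshold = -Inf, fpr = 1, tpr = 1))
  }
  structure(list(auc = auc, p_value = p, n_pos = n_pos, n_neg = n_neg,
                 curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC = %.3f (p = %.3g), %d high vs %d low>\n",
              x$auc, x$p_value, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
#' @method tidy roc_result
tidy.roc_result <- function(x, ...) x$curve

#' @export
#' @method glance roc_result
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, p_value = x$p_value, n_pos = x$n_pos,
                 n_neg = x$n_neg)
}
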