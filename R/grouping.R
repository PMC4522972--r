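# Dichotomization of per-sample protein values into high/low/excluded labels.

new_group_labels <- function(sample_id, label) {
  tibble::tibble(sample_id = sample_id,
                 label = factor(label, levels = c("high", "low", "excluded")))
}

#' Protein grouping rules
#'
#' Split samples into `high` / `low` / `excluded` groups from a per-sample
#' protein value, under one of three rules:
#'
#' * `quartile_groups()`: value >= Q3 is `high`, <= Q1 `low`, the rest
#'   excluded. Quartiles use linear-interpolation quantiles (R type 7, the
#'   convention interpolating at index `(n - 1) * p`); boundary ties join the
#'   extreme group.
#' * `zscore_groups()`: z = (x - mean) / SD (sample SD); z > `threshold` is
#'   `high`, z < `-threshold` `low`, else excluded.
#' * `sd_groups()`: value > mean + `k` * SD is `high`, < mean - `k` * SD
#'   `low`, else excluded (symmetric cut-offs).
#' * `median_groups()`: value > median is `high`, <= median `low`; nothing
#'   excluded (balanced truth labels for calibration checks).
#'
#' Missing values are labelled `excluded`.
#'
#' @param protein A data frame with `sample_id` and one numeric value column,
#'   or a named numeric vector.
#' @param value Name of the value column when `protein` has several.
#' @param threshold z-score cut-off (default 0.2).
#' @param k Number of SDs from the mean (default 1).
#' @return A tibble with columns `sample_id` and `label`
#'   (`high`/`low`/`excluded`).
#' @export
quartile_groups <- function(protein, value = NULL) {
  d <- as_sample_values(protein, value, arg = "protein")
  v <- d$value
  ok <- !is.na(v)
  if (sum(ok) < 8) stop("quartile_groups needs >= 8 non-missing values", call. = FALSE)
  q <- quantile(v[ok], c(0.25, 0.75), type = 7, names = FALSE)
  if (q[1] == q[2]) stop("no separation: Q1 equals Q3", call. = FALSE)
  label <- rep("excluded", length(v))
  label[ok & v >= q[2]] <- "high"
  label[ok & v <= q[1]] <- "low"
  new_group_labels(d$sample_id, label)
}

#' @rdname quartile_groups
#' @export
zscore_groups <- function(protein, threshold = 0.2, value = NULL) {
  d <- as_sample_values(protein, value, arg = "protein")
  v <- d$value
  ok <- !is.na(v)
  if (sum(ok) < 3) stop("zscore_groups needs >= 3 non-missing values", call. = FALSE)
  s <- sd(v[ok])
  if (s == 0) stop("zero standard deviation: cannot z-score", call. = FALSE)
  z <- (v - mean(v[ok])) / s
  label <- rep("excluded", length(v))
  label[ok & z > threshold] <- "high"
  label[ok & z < -threshold] <- "low"
  new_group_labels(d$sample_id, label)
}

#' @rdname quartile_groups
#' @export
sd_groups <- function(protein, k = 1.0, value = NULL) {
  d <- as_sample_values(protein, value, arg = "protein")
  v <- d$value
  ok <- !is.na(v)
  if (sum(ok) < 3) stop("sd_groups needs >= 3 non-missing values", call. = FALSE)
  s <- sd(v[ok])
  if (s == 0) stop("zero standard deviation: cannot form SD cut-offs", call. = FALSE)
  m <- mean(v[ok])
  label <- rep("excluded", length(v))
  label[ok & v > m + k * s] <- "high"
  label[ok & v < m - k * s] <- "low"
  new_group_labels(d$sample_id, label)
}

#' @rdname quartile_groups
#' @export
median_groups <- function(protein, value = NULL) {
  d <- as_sample_values(protein, value, arg = "protein")
  v <- d$value
  ok <- !is.na(v)
  if (sum(ok) < 2) stop("median_groups needs >= 2 non-missing values", call. = FALSE)
  if (min(v[ok]) == max(v[ok])) stop("all values identical: no separation", call. = FALSE)
  med <- median(v[ok])
  label <- rep("excluded", length(v))
  label[ok & v > med] <- "high"
  label[ok & v <= med] <- "low"
  new_group_labels(d$sample_id, label)
}
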