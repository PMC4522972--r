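# Sigscore computation and dichotomization of scores.

#' Score samples with a signed signature (Sigscore)
#'
#' For each sample `j` the score is the signed sum over the signature genes
#' found in the matrix: `score_j = sum_i S_i * e_ij`, with `S_i` the +1/-1
#' coefficient and `e_ij` the (log-scale) expression value. This is the raw
#' signature score; two opt-in variants support cross-platform transfer:
#' `standardize` z-scores each gene across samples before summing, and
#' `scale_by_n` divides by the number of matched genes. Signature genes
#' absent from the matrix are skipped and reported; a missing expression
#' value contributes 0 to that sample's sum (and is not counted in
#' `matched_genes` for that sample).
#'
#' @param expr Expression tibble (`gene` + sample columns).
#' @param signature A [gene_signature()] (or data frame with `gene`,
#'   `coefficient`).
#' @param standardize Z-score each gene across samples first (genes with
#'   zero variance contribute 0).
#' @param scale_by_n Divide each score by its number of matched genes.
#' @return A tibble `sample_id`, `score`, `matched_genes`, with attributes
#'   `missing_genes` (symbols absent from the matrix), `standardized`,
#'   `scaled_by_n`.
#' @export
score_samples <- function(expr, signature, standardize = FALSE,
                          scale_by_n = FALSE) {
  m <- expr_matrix(expr)
  if (!is.data.frame(signature) || !all(c("gene", "coefficient") %in% names(signature))) {
    stop("signature must have columns `gene` and `coefficient`", call. = FALSE)
  }
  if (nrow(signature) == 0) stop("empty signature", call. = FALSE)
  sig_genes <- trimws(signature$gene)
  rownames(m) <- trimws(rownames(m))
  matched <- intersect(sig_genes, rownames(m))
  missing <- setdiff(sig_genes, rownames(m))
  if (length(matched) == 0) {
    stop("no signature gene found in the matrix; signature genes: ",
         paste(head(sig_genes, 5), collapse = ", "),
         " ...; matrix symbols look like: ",
         paste(head(rownames(m), 5), collapse = ", "), call. = FALSE)
  }
  sub <- m[matched, , drop = FALSE]
  if (standardize) {
    mu <- rowMeans(sub, na.rm = TRUE)
    sdv <- apply(sub, 1, sd, na.rm = TRUE)
    sdv[sdv == 0 | is.na(sdv)] <- Inf  # zero-variance genes contribute 0
    sub <- (sub - mu) / sdv
  }
  coef <- signature$coefficient[match(matched, sig_genes)]
  contrib <- sub * coef
  score <- colSums(contrib, na.rm = TRUE)
  n_matched <- colSums(!is.na(contrib))
  if (scale_by_n) score <- score / pmax(n_matched, 1)
  out <- tibble::tibble(sample_id = colnames(m), score = unname(score),
                        matched_genes = unname(n_matched))
  attr(out, "missing_genes") <- missing
  attr(out, "standardized") <- standardize
  attr(out, "scaled_by_n") <- scale_by_n
  out
}

#' Dichotomize signature scores
#'
#' Labels each sample `high` (score above the median) or `low` (at or below
#' it); ties at the median deliberately go `low`, the conservative choice
#' for a "high score = poor outcome" reading. With `stratify_by` the median
#' is computed within each stratum (e.g. ER status).
#'
#' @param scores Tibble with `sample_id` and `score` (e.g. from
#'   [score_samples()]), or a named numeric vector.
#' @param method Only `"median"` is implemented.
#' @param stratify_by Optional tibble `sample_id` + one stratum column, or a
#'   vector of strata aligned with `scores`.
#' @return A tibble `sample_id`, `group` (factor `high`/`low`).
#' @export
dichotomize_scores <- function(scores, method = "median", stratify_by = NULL) {
  method <- match.arg(method, "median")
  d <- as_sample_values(scores, value = if (is.data.frame(scores) &&
                                            "score" %in% names(scores)) "score",
                        arg = "scores")
  if (nrow(d) < 2) stop("need >= 2 samples to dichotomize", call. = FALSE)
  if (is.null(stratify_by)) {
    stratum <- rep("all", nrow(d))
  } else if (is.data.frame(stratify_by)) {
    if (!"sample_id" %in% names(stratify_by) || ncol(stratify_by) < 2) {
      stop("stratify_by needs `sample_id` plus one stratum column", call. = FALSE)
    }
    scol <- setdiff(names(stratify_by), "sample_id")[1]
    stratum <- as.character(stratify_by[[scol]][match(d$sample_id, stratify_by$sample_id)])
  } else {
    if (length(stratify_by) != nrow(d)) {
      stop("stratify_by vector must match the number of scores", call. = FALSE)
    }
    stratum <- as.character(stratify_by)
  }
  group <- character(nrow(d))
  for (s in unique(stratum)) {
    idx <- which(stratum == s)
    v <- d$value[idx]
    if (length(v) > 0 && min(v) == max(v)) {
      stop("all scores identical", if (!is.null(stratify_by)) paste0(" in stratum '", s, "'"),
           ": cannot dichotomize", call. = FALSE)
    }
    med <- median(v)
    group[idx] <- ifelse(v > med, "high", "low")
  }
  tibble::tibble(sample_id = d$sample_id,
                 group = factor(group, levels = c("high", "low")))
}
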