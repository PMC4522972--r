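# Shared internal helpers: table <-> matrix conversion and input validation.

# Expression tables are tibbles whose first column, `gene`, holds unique
# symbols (or probe ids before collapsing); every other column is one sample.

expr_matrix <- function(expr) {
  validate_expression(expr)
  m <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene
  m
}

expr_tibble <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  tibble::as_tibble(as.data.frame(m), rownames = "gene")
}

validate_expression <- function(expr, arg = "expr") {
  if (!is.data.frame(expr) || ncol(expr) < 2) {
    stop(arg, " must be a data frame with a `gene` column plus >=1 sample column",
         call. = FALSE)
  }
  if (names(expr)[1] != "gene") {
    stop(arg, ": first column must be named `gene` (got `", names(expr)[1], "`)",
         call. = FALSE)
  }
  dup_g <- unique(expr$gene[duplicated(expr$gene)])
  if (length(dup_g) > 0) {
    stop(arg, ": duplicated gene ids: ", paste(head(dup_g, 5), collapse = ", "),
         call. = FALSE)
  }
  samp <- names(expr)[-1]
  dup_s <- unique(samp[duplicated(samp)])
  if (length(dup_s) > 0) {
    stop(arg, ": duplicated sample ids: ", paste(head(dup_s, 5), collapse = ", "),
         call. = FALSE)
  }
  not_num <- samp[!vapply(expr[samp], is.numeric, logical(1))]
  if (length(not_num) > 0) {
    stop(arg, ": non-numeric sample columns: ", paste(head(not_num, 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(expr)
}

# Accept per-sample values as a tibble (sample_id + one value column) or a
# named numeric vector; return tibble(sample_id, value).
as_sample_values <- function(x, value = NULL, arg = "x") {
  if (is.numeric(x)) {
    if (is.null(names(x))) {
      stop(arg, ": a numeric vector must carry sample ids as names", call. = FALSE)
    }
    return(tibble::tibble(sample_id = names(x), value = unname(x)))
  }
  if (!is.data.frame(x) || !"sample_id" %in% names(x)) {
    stop(arg, " must be a data frame with a `sample_id` column or a named numeric vector",
         call. = FALSE)
  }
  if (is.null(value)) {
    cand <- setdiff(names(x)[vapply(x, is.numeric, logical(1))], "sample_id")
    if (length(cand) != 1) {
      stop(arg, ": cannot guess the value column among {",
           paste(cand, collapse = ", "), "}; pass `value`", call. = FALSE)
    }
    value <- cand
  }
  if (!value %in% names(x)) stop(arg, ": no column `", value, "`", call. = FALSE)
  if (anyDuplicated(x$sample_id)) stop(arg, ": duplicated sample ids", call. = FALSE)
  tibble::tibble(sample_id = as.character(x$sample_id), value = as.numeric(x[[value]]))
}

# Deterministic per-component seeds derived from one global seed, so the
# random stream of one cohort component is unchanged when another grows.
stream_seed <- function(seed, stream) {
  offsets <- c(activation = 1, protein = 2, expression = 3,
               clinical = 4, survival = 5, censoring = 6)
  if (!stream %in% names(offsets)) stop("unknown stream: ", stream, call. = FALSE)
  as.integer(((as.double(seed) %% 97003) * 20011 + offsets[[stream]] * 1009) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
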