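#' Read a gene-by-sample expression matrix
#'
#' Reads a tab-delimited matrix (first column gene/probe ids, header row of
#' sample ids) or a GCT 1.2 file into a tidy expression table: a tibble with
#' a `gene` column followed by one numeric column per sample. Values are
#' expected on log scale; empty cells become `NA` (explicit missingness, not
#' zero).
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"tsv"`, or `"gct"`.
#' @return A tibble with columns `gene`, then one column per sample.
#' @export
read_expression_matrix <- function(path, format = c("auto", "tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "gct") {
    if (length(lines) < 3 || !startsWith(lines[1], "#1.2")) {
      stop("not a GCT 1.2 file (missing '#1.2' header): ", path, call. = FALSE)
    }
    dims <- as.integer(strsplit(lines[2], "\t")[[1]][1:2])
    body <- lines[-(1:2)]
    parsed <- parse_delim_matrix(body, path, drop_cols = 2L)
    if (nrow(parsed) != dims[1] || (ncol(parsed) - 1L) != dims[2]) {
      stop(sprintf("GCT dimension line says %d x %d but body is %d x %d: %s",
                   dims[1], dims[2], nrow(parsed), ncol(parsed) - 1L, path),
           call. = FALSE)
    }
    return(parsed)
  }
  parse_delim_matrix(lines, path, drop_cols = 1L)
}

# Parse header + rows; drop_cols = number of leading id/annotation columns
# (1 for TSV, 2 for GCT Name/Description). First id column becomes `gene`.
parse_delim_matrix <- function(lines, path, drop_cols) {
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("no data rows in ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-seq_len(drop_cols)]
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup) > 0) {
    stop("duplicated sample ids in header of ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  genes <- trimws(vapply(rows, `[[`, character(1), 1))
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g) > 0) {
    stop("duplicated gene ids in ", path, ": ",
         paste(head(dup_g, 5), collapse = ", "), call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow = length(rows), ncol = length(sample_ids))
  for (i in seq_along(rows)) {
    cells <- rows[[i]][-seq_len(drop_cols)]
    length(cells) <- length(sample_ids)
    cells[!nzchar(cells) | cells %in% c("NA", "na", "NaN")] <- NA
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(!is.na(cells) & is.na(num))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' at data row %d, sample column '%s' in %s",
                   cells[bad[1]], i, sample_ids[bad[1]], path), call. = FALSE)
    }
    vals[i, ] <- num
  }
  rownames(vals) <- genes
  colnames(vals) <- sample_ids
  out <- expr_tibble(vals)
  validate_expression(out, arg = path)
  out
}

#' Write an expression table
#'
#' @param expr Expression tibble (`gene` column plus sample columns).
#' @param path Output path.
#' @param format `"tsv"` or `"gct"` (GCT 1.2; the Description column is
#'   filled with the gene id).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  validate_expression(expr)
  m <- expr_matrix(expr)
  fmt <- function(x) {
    out <- formatC(x, digits = 10, format = "g")
    out[is.na(x)] <- "NA"
    out
  }
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], if (format == "gct") rownames(m)[i], fmt(m[i, ])),
          collapse = "\t")
  }, character(1))
  header <- paste(c("gene", if (format == "gct") "Description", colnames(m)),
                  collapse = "\t")
  if (format == "gct") {
    header <- sub("^gene", "Name", header)
    lines <- c("#1.2", paste(nrow(m), ncol(m), sep = "\t"), header, body)
  } else {
    lines <- c(header, body)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Collapse probe-level rows to gene level by averaging
#'
#' When several probes map to the same gene symbol the collapsed value is the
#' arithmetic mean of the probe values, per sample, ignoring missing probes.
#' Probes absent from the map are dropped (with a message giving the count).
#'
#' @param expr Probe-level expression tibble (`gene` column holds probe ids).
#' @param probe_map Data frame with columns `probe` and `gene` (many probes
#'   per gene allowed; each probe maps to exactly one gene).
#' @return Gene-level expression tibble.
#' @export
collapse_probes_to_genes <- function(expr, probe_map) {
  validate_expression(expr)
  if (!is.data.frame(probe_map) || !all(c("probe", "gene") %in% names(probe_map))) {
    stop("probe_map must have columns `probe` and `gene`", call. = FALSE)
  }
  map <- tibble::tibble(probe = trimws(as.character(probe_map$probe)),
                        gene = trimws(as.character(probe_map$gene)))
  if (any(!nzchar(map$gene))) stop("probe_map: empty gene symbols", call. = FALSE)
  if (anyDuplicated(map$probe)) {
    stop("probe_map: probes mapping to more than one symbol: ",
         paste(unique(map$probe[duplicated(map$probe)])[1:min(5, sum(duplicated(map$probe)))],
               collapse = ", "), call. = FALSE)
  }
  m <- expr_matrix(expr)
  keep <- rownames(m) %in% map$probe
  if (!any(keep)) stop("no probes in `expr` are present in `probe_map`", call. = FALSE)
  if (any(!keep)) {
    message(sum(!keep), " unmapped probe(s) dropped")
  }
  m <- m[keep, , drop = FALSE]
  genes <- map$gene[match(rownames(m), map$probe)]
  out <- rowsum(ifelse(is.na(m), 0, m), genes, reorder = FALSE) /
    rowsum((!is.na(m)) * 1, genes, reorder = FALSE)
  out[is.nan(out)] <- NA_real_
  expr_tibble(out)
}

#' Construct a signed gene signature
#'
#' A signature is an ordered set of gene symbols, each carrying a coefficient
#' of +1 (up-regulated in the high-protein group) or -1 (down-regulated).
#'
#' @param gene Character vector of unique gene symbols.
#' @param coefficient Integer vector of +1/-1, recycled if length 1.
#' @param name Signature name.
#' @return A `gene_signature` tibble with columns `gene` and `coefficient`.
#' @export
gene_signature <- function(gene, coefficient, name = "signature") {
  gene <- trimws(as.character(gene))
  if (length(coefficient) == 1) coefficient <- rep(coefficient, length(gene))
  coefficient <- as.integer(coefficient)
  if (length(gene) != length(coefficient)) {
    stop("gene and coefficient lengths differ", call. = FALSE)
  }
  if (length(gene) > 0) {
    if (any(!nzchar(gene))) stop("empty gene symbols in signature", call. = FALSE)
    if (anyDuplicated(gene)) {
      stop("duplicated genes in signature: ",
           paste(unique(gene[duplicated(gene)]), collapse = ", "), call. = FALSE)
    }
    if (!all(coefficient %in% c(-1L, 1L))) {
      stop("signature coefficients must be -1 or +1", call. = FALSE)
    }
  }
  out <- tibble::tibble(gene = gene, coefficient = coefficient)
  class(out) <- c("gene_signature", class(out))
  attr(out, "sig_name") <- name
  out
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature '%s': %d genes (%d up, %d down)>\n",
              attr(x, "sig_name") %||% "signature", nrow(x),
              sum(x$coefficient == 1), sum(x$coefficient == -1)))
  NextMethod()
}

#' Read / write a signed signature
#'
#' Two on-disk forms are supported: a two-column TSV (`gene`, `coefficient`
#' in -1/+1) and a GMT-like pair of lines `NAME_UP g1 g2 ...` /
#' `NAME_DOWN g3 ...` (tab-separated, `_UP` genes get +1, `_DOWN` -1).
#'
#' @param path File path; `format = "auto"` treats `.gmt` as GMT, else TSV.
#' @param format `"auto"`, `"tsv"`, or `"gmt"`.
#' @return A [gene_signature()].
#' @export
read_signature <- function(path, format = c("auto", "tsv", "gmt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (format == "gmt") {
    genes <- character(0); coefs <- integer(0); name <- NULL
    for (ln in lines) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      set <- f[1]
      sgn <- if (grepl("_UP$", set)) 1L else if (grepl("_DOWN$", set)) -1L else
        stop("GMT set name must end in _UP or _DOWN: ", set, call. = FALSE)
      name <- name %||% sub("_(UP|DOWN)$", "", set)
      genes <- c(genes, f[-1]); coefs <- c(coefs, rep(sgn, length(f) - 1))
    }
    return(gene_signature(genes, coefs, name = name %||% "signature"))
  }
  has_header <- grepl("^gene\t", lines[1])
  rows <- strsplit(if (has_header) lines[-1] else lines, "\t", fixed = TRUE)
  genes <- vapply(rows, `[[`, character(1), 1)
  raw <- vapply(rows, function(r) r[2], character(1))
  coefs <- suppressWarnings(as.numeric(raw))
  if (any(is.na(coefs)) || any(!coefs %in% c(-1, 1))) {
    stop("signature coefficients must be -1 or +1 (got: ",
         paste(unique(raw[is.na(coefs) | !coefs %in% c(-1, 1)]), collapse = ", "),
         ") in ", path, call. = FALSE)
  }
  gene_signature(genes, as.integer(coefs),
                 name = sub("\\.[^.]*$", "", basename(path)))
}

#' @param sig A [gene_signature()].
#' @rdname read_signature
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "gene_signature"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("gene\tcoefficient",
               paste(sig$gene, sig$coefficient, sep = "\t")),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read and validate a clinical table
#'
#' Expects a CSV with one row per sample. Column names can be remapped via
#' `column_map` (names = canonical names, values = names in the file).
#' Canonical columns: `sample_id`, `time` (months, >= 0), `event` (0/1),
#' `treatment` (0/1), `er_status` (`pos`/`neg`/`unknown`), `age`,
#' `tumor_size`, `grade`, `nodal_status`. Rows with missing `time` or
#' `event` are kept but flagged (`survival_ok = FALSE`) so survival
#' operations can exclude them.
#'
#' @param path CSV path.
#' @param column_map Optional named character vector remapping columns.
#' @return A validated tibble.
#' @export
read_clinical_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) stop("column_map: no column `", src, "` in ", path, call. = FALSE)
      names(df)[names(df) == src] <- canon
    }
  }
  validate_clinical(df)
}

validate_clinical <- function(df) {
  if (!"sample_id" %in% names(df)) stop("clinical table needs `sample_id`", call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("clinical table: duplicated sample ids: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)])[1:3], collapse = ", "),
         call. = FALSE)
  }
  if ("time" %in% names(df) && any(df$time < 0, na.rm = TRUE)) {
    stop("clinical table: negative survival time", call. = FALSE)
  }
  if ("event" %in% names(df) && !all(df$event %in% c(0, 1) | is.na(df$event))) {
    stop("clinical table: event must be 0/1", call. = FALSE)
  }
  if ("treatment" %in% names(df) && !all(df$treatment %in% c(0, 1) | is.na(df$treatment))) {
    stop("clinical table: treatment must be 0/1", call. = FALSE)
  }
  if ("er_status" %in% names(df)) {
    er <- tolower(as.character(df$er_status))
    er[is.na(er)] <- "unknown"
    ok <- er %in% c("pos", "neg", "unknown")
    if (!all(ok)) stop("clinical table: er_status must be pos/neg/unknown", call. = FALSE)
    df$er_status <- er
  }
  df$survival_ok <- if (all(c("time", "event") %in% names(df))) {
    !is.na(df$time) & !is.na(df$event)
  } else {
    FALSE
  }
  tibble::as_tibble(df)
}

#' Write a simulated cohort to plain-text files
#'
#' Writes `expression.tsv`, `protein.tsv`, `clinical.csv`,
#' `truth_signature.tsv`, `truth_activation.tsv` and a `config.yaml` echo
#' into `dir`, the same formats the readers in this package consume.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(cohort$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(cohort$protein, file.path(dir, "protein.tsv"), progress = FALSE)
  readr::write_csv(cohort$clinical[setdiff(names(cohort$clinical), "survival_ok")],
                   file.path(dir, "clinical.csv"), progress = FALSE)
  write_signature(cohort$truth_signature, file.path(dir, "truth_signature.tsv"))
  readr::write_tsv(cohort$truth_activation, file.path(dir, "truth_activation.tsv"),
                   progress = FALSE)
  yaml::write_yaml(unclass(cohort$config), file.path(dir, "config.yaml"))
  invisible(dir)
}
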