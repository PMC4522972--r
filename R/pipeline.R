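# End-to-end orchestration: file-based pipeline runs and cohort-to-cohort
# transfer validation with a leakage guard.

default_pipeline_config <- function() {
  list(
    grouping = list(method = "quartile", threshold = 0.2, k = 1.0),
    derivation = list(fdr = 0.05, p = NULL, fold = NULL, mode = "robust"),
    scoring = list(standardize = FALSE, scale_by_n = FALSE),
    dichotomize = list(stratify = NULL),
    truth = list(method = "sd", k = 1.0),
    covariates = c("age", "tumor_size", "grade", "nodal_status", "er_status"),
    treatment = "treatment",
    seed = 1L)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      merge_config(base[[nm]], user[[nm]])
    } else {
      user[[nm]]
    }
  }
  base
}

group_samples <- function(protein, grouping) {
  switch(grouping$method,
         quartile = quartile_groups(protein),
         zscore = zscore_groups(protein, threshold = grouping$threshold %||% 0.2),
         sd = sd_groups(protein, k = grouping$k %||% 1.0),
         median = median_groups(protein),
         stop("unknown grouping method: ", grouping$method, call. = FALSE))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full signature pipeline on files
#'
#' Orchestrates group -> derive -> score -> validate -> survive on
#' tab-delimited/CSV inputs and writes every stage artifact plus a
#' reproducibility manifest into `out_dir`. All input paths are checked
#' before any stage runs; stage failures are reported with the stage name,
#' and artifacts written by earlier stages are preserved.
#'
#' @param config A named list or path to a YAML file. Recognized fields:
#'   `expression`, `protein`, `clinical` (paths; required), `probe_map`
#'   (optional path, columns `probe`/`gene`), `grouping`
#'   (`method` = quartile/zscore/sd/median plus `threshold`/`k`),
#'   `derivation` (`fdr`, `p`, `fold`, `mode`), `scoring` (`standardize`,
#'   `scale_by_n`), `dichotomize` (`stratify` = clinical column or `NULL`),
#'   `truth` (`method`, `k`; proteomic truth rule for the ROC),
#'   `covariates`, `treatment`, `seed`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_pipeline_config(), config)
  paths <- c(expression = cfg$expression, protein = cfg$protein,
             clinical = cfg$clinical, probe_map = cfg$probe_map)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing) > 0) {
    stop("input file(s) not found: ",
         paste(sprintf("%s (%s)", missing, names(missing)), collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  expr <- stage("read_expression", {
    e <- read_expression_matrix(cfg$expression)
    if (!is.null(cfg$probe_map)) {
      pm <- readr::read_tsv(cfg$probe_map, show_col_types = FALSE, progress = FALSE)
      e <- collapse_probes_to_genes(e, pm)
    }
    e
  })
  protein <- stage("read_protein",
                   readr::read_tsv(cfg$protein, show_col_types = FALSE, progress = FALSE))
  clinical <- stage("read_clinical", read_clinical_table(cfg$clinical))

  labels <- stage("group", group_samples(protein, cfg$grouping))
  readr::write_tsv(labels, file.path(out_dir, "labels.tsv"), progress = FALSE)
  message(sprintf("stage=group method=%s high=%d low=%d excluded=%d",
                  cfg$grouping$method, sum(labels$label == "high"),
                  sum(labels$label == "low"), sum(labels$label == "excluded")))

  fit <- stage("derive", derive_signature(
    expr, labels, fdr_threshold = cfg$derivation$fdr,
    p_threshold = cfg$derivation$p, fold_threshold = cfg$derivation$fold,
    mode = cfg$derivation$mode))
  write_signature(fit$signature, file.path(out_dir, "signature.tsv"))
  readr::write_tsv(fit$table, file.path(out_dir, "de_table.tsv"), progress = FALSE)
  message(sprintf("stage=derive tested=%d selected=%d dropped=%d",
                  nrow(fit$table), nrow(fit$signature), fit$n_dropped))

  results <- list(labels = labels, signature_fit = fit)
  status <- "complete"
  if (nrow(fit$signature) == 0) {
    status <- "empty_signature"
  } else {
    scores <- stage("score", score_samples(
      expr, fit$signature, standardize = isTRUE(cfg$scoring$standardize),
      scale_by_n = isTRUE(cfg$scoring$scale_by_n)))
    readr::write_tsv(scores, file.path(out_dir, "scores.tsv"), progress = FALSE)
    message(sprintf("stage=score samples=%d matched_genes=%d", nrow(scores),
                    max(scores$matched_genes)))

    val <- stage("validate", {
      truth <- group_samples(protein, c(cfg$truth, list(
        method = cfg$truth$method %||% "sd")))
      roc <- roc_auc(scores, truth)
      pv <- as_sample_values(protein, arg = "protein")
      idx <- match(scores$sample_id, pv$sample_id)
      corr <- pearson_correlation(scores$score, pv$value[idx])
      list(roc = roc, correlation = corr)
    })
    jsonlite::write_json(
      list(auc = val$roc$auc, p_value = val$roc$p_value, n_pos = val$roc$n_pos,
           n_neg = val$roc$n_neg, pearson_r = val$cor$estimate,
           pearson_p = val$cor$p_value, curve = val$roc$curve),
      file.path(out_dir, "roc.json"), auto_unbox = TRUE, digits = NA)
    message(sprintf("stage=validate auc=%.3f r=%.3f", val$roc$auc,
                    val$correlation$estimate))

    surv <- stage("survive", {
      strat <- cfg$dichotomize$stratify
      groups <- dichotomize_scores(
        scores, stratify_by = if (!is.null(strat)) clinical[c("sample_id", strat)])
      km <- kaplan_meier(clinical, group = groups)
      lr <- log_rank(clinical, group = groups)
      d <- dplyr::inner_join(clinical, scores[c("sample_id", "score")],
                             by = "sample_id")
      cox_uni <- cox_fit(d, "score")
      covs <- intersect(cfg$covariates, names(d))
      cox_multi <- if (length(covs) > 0) cox_fit(d, c("score", covs)) else NULL
      inter <- NULL
      trt <- cfg$treatment
      if (trt %in% names(d) && length(unique(stats::na.omit(d[[trt]]))) == 2 &&
          all(tapply(d$event[d$survival_ok], d[[trt]][d$survival_ok], sum) > 0)) {
        inter <- interaction_lrt(d, score = "score", treatment = trt)
      }
      list(score_groups = groups, km = km, log_rank = lr, cox_univariate = cox_uni,
           cox_multivariable = cox_multi, interaction = inter)
    })
    readr::write_tsv(surv$score_groups, file.path(out_dir, "score_groups.tsv"),
                     progress = FALSE)
    jsonlite::write_json(
      list(km = surv$km$table, log_rank = surv$log_rank,
           cox_univariate = surv$cox_univariate$table,
           cox_multivariable = if (!is.null(surv$cox_multivariable))
             surv$cox_multivariable$table,
           interaction = if (!is.null(surv$interaction)) list(
             statistic = surv$interaction$statistic,
             p_value = surv$interaction$p_value)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    message(sprintf("stage=survive events=%d logrank_p=%.3g interaction_p=%s",
                    surv$log_rank$n_events, surv$log_rank$p_value,
                    if (is.null(surv$interaction)) "NA" else
                      format(surv$interaction$p_value, digits = 3)))
    results <- c(results, list(scores = scores, validation = val, survival = surv))
  }

  manifest <- list(
    package = "sigscore",
    package_version = as.character(utils::packageVersion("sigscore")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    status = status,
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("expression", "protein", "clinical",
                                       "probe_map"))],
    inputs = lapply(as.list(paths), function(p) list(
      path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  results$manifest <- manifest
  invisible(results)
}

as_cohort_triplet <- function(x, arg) {
  if (inherits(x, "synthetic_cohort")) {
    return(list(expression = x$expression, protein = x$protein,
                clinical = x$clinical))
  }
  if (is.list(x) && all(c("expression", "protein") %in% names(x))) {
    return(list(expression = x$expression, protein = x$protein,
                clinical = x$clinical))
  }
  stop(arg, " must be a synthetic_cohort or a list with expression/protein",
       call. = FALSE)
}

#' Derive on one cohort, validate on an independent one
#'
#' The signature is derived exclusively from the training cohort (protein
#' grouping + differential expression); the test cohort is then scored with
#' that frozen signature and evaluated — ROC/AUC against its own proteomic
#' truth labels, Pearson correlation of score vs protein, and, when the
#' test cohort has clinical data with two treatment arms, the
#' treatment-by-score interaction LRT. Overlapping sample ids between the
#' cohorts are refused (leakage guard).
#'
#' @param train,test Cohorts: [simulate_cohort()] results or lists with
#'   `expression`, `protein`, and optionally `clinical`.
#' @param grouping,derivation,scoring,truth Stage settings as in
#'   [run_pipeline()].
#' @return A `transfer_report`: `applicable`, `signature_fit`,
#'   `scores_test`, `roc`, `correlation_train`, `correlation_test`,
#'   `interaction` (or `NULL`).
#' @export
run_transfer_validation <- function(train, test,
                                    grouping = list(method = "quartile"),
                                    derivation = list(),
                                    scoring = list(),
                                    truth = list(method = "sd", k = 1.0)) {
  tr <- as_cohort_triplet(train, "train")
  te <- as_cohort_triplet(test, "test")
  overlap <- intersect(names(tr$expression)[-1], names(te$expression)[-1])
  if (length(overlap) > 0) {
    stop("train/test sample ids overlap (leakage): ",
         paste(head(overlap, 5), collapse = ", "), call. = FALSE)
  }
  grouping <- merge_config(default_pipeline_config()$grouping, grouping)
  derivation <- merge_config(default_pipeline_config()$derivation, derivation)
  scoring <- merge_config(default_pipeline_config()$scoring, scoring)

  labels <- group_samples(tr$protein, grouping)
  fit <- derive_signature(tr$expression, labels,
                          fdr_threshold = derivation$fdr,
                          p_threshold = derivation$p,
                          fold_threshold = derivation$fold,
                          mode = derivation$mode)
  if (nrow(fit$signature) == 0) {
    return(structure(list(applicable = FALSE, signature_fit = fit,
                          scores_test = NULL, roc = NULL,
                          correlation_train = NULL, correlation_test = NULL,
                          interaction = NULL),
                     class = "transfer_report"))
  }
  sc_args <- list(standardize = isTRUE(scoring$standardize),
                  scale_by_n = isTRUE(scoring$scale_by_n))
  scores_tr <- do.call(score_samples, c(list(tr$expression, fit$signature), sc_args))
  scores_te <- do.call(score_samples, c(list(te$expression, fit$signature), sc_args))

  truth_labels <- group_samples(te$protein, merge_config(list(method = "sd", k = 1.0),
                                                         truth))
  roc <- roc_auc(scores_te, truth_labels)

  pv_tr <- as_sample_values(tr$protein, arg = "protein")
  pv_te <- as_sample_values(te$protein, arg = "protein")
  cor_tr <- pearson_correlation(scores_tr$score,
                                pv_tr$value[match(scores_tr$sample_id, pv_tr$sample_id)])
  cor_te <- pearson_correlation(scores_te$score,
                                pv_te$value[match(scores_te$sample_id, pv_te$sample_id)])

  inter <- NULL
  if (!is.null(te$clinical) && "treatment" %in% names(te$clinical)) {
    d <- te$clinical
    arms <- unique(stats::na.omit(d$treatment))
    ok <- d$survival_ok %||% rep(TRUE, nrow(d))
    if (length(arms) == 2 &&
        all(tapply(d$event[ok], d$treatment[ok], sum) > 0)) {
      inter <- interaction_lrt(d, score = scores_te, treatment = "treatment")
    }
  }
  structure(list(applicable = TRUE, signature_fit = fit, scores_test = scores_te,
                 roc = roc, correlation_train = cor_tr, correlation_test = cor_te,
                 interaction = inter),
            class = "transfer_report")
}

#' @export
print.transfer_report <- function(x, ...) {
  if (!x$applicable) {
    cat("<transfer_report: not applicable (empty training signature)>\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("<transfer_report: %d-gene signature | test AUC %.3f ",
                     "(p %.3g) | r train %.2f / test %.2f%s>\n"),
              nrow(x$signature_fit$signature), x$roc$auc, x$roc$p_value,
              x$correlation_train$estimate, x$correlation_test$estimate,
              if (is.null(x$interaction)) "" else
                sprintf(" | interaction p %.3g", x$interaction$p_value)))
  invisible(x)
}

#' @export
#' @method glance transfer_report
glance.transfer_report <- function(x, ...) {
  if (!x$applicable) {
    return(tibble::tibble(applicable = FALSE, n_signature_genes = 0L,
                          auc = NA_real_, auc_p = NA_real_, r_train = NA_real_,
                          r_test = NA_real_, interaction_p = NA_real_))
  }
  tibble::tibble(applicable = TRUE,
                 n_signature_genes = nrow(x$signature_fit$signature),
                 auc = x$roc$auc, auc_p = x$roc$p_value,
                 r_train = x$correlation_train$estimate,
                 r_test = x$correlation_test$estimate,
                 interaction_p = if (is.null(x$interaction)) NA_real_ else
                   x$interaction$p_value)
}
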