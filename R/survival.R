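# Kaplan-Meier, log-rank, Cox models, and the treatment-interaction LRT.
# Estimation is delegated to the survival package (Efron ties throughout);
# this file owns input validation, the tidy surfaces, and the nested-model
# likelihood-ratio interaction test.

prepare_surv_data <- function(data, time, event) {
  if (!is.data.frame(data)) stop("data must be a data frame", call. = FALSE)
  for (col in c(time, event)) {
    if (!col %in% names(data)) stop("no column `", col, "` in data", call. = FALSE)
  }
  keep <- !is.na(data[[time]]) & !is.na(data[[event]])
  if ("survival_ok" %in% names(data)) keep <- keep & data$survival_ok
  d <- data[keep, , drop = FALSE]
  if (nrow(d) == 0) stop("no usable (time, event) rows", call. = FALSE)
  if (any(d[[time]] < 0)) stop("negative survival times", call. = FALSE)
  if (!all(d[[event]] %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  d
}

resolve_group <- function(data, group) {
  if (is.character(group) && length(group) == 1 && group %in% names(data)) {
    return(as.character(data[[group]]))
  }
  if (is.data.frame(group)) {
    gcol <- setdiff(names(group), "sample_id")[1]
    if (!"sample_id" %in% names(group) || is.na(gcol)) {
      stop("group table needs `sample_id` plus one group column", call. = FALSE)
    }
    return(as.character(group[[gcol]][match(data$sample_id, group$sample_id)]))
  }
  if (length(group) == nrow(data)) return(as.character(group))
  stop("group must be a column name, a sample_id-keyed table, or a vector",
       call. = FALSE)
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimate via [survival::survfit()]; at tied times events are
#' handled before censorings, and censored subjects leave the risk set after
#' their time.
#'
#' @param data Clinical data frame with time/event columns (rows flagged
#'   `survival_ok = FALSE` by [read_clinical_table()] are excluded).
#' @param group Optional grouping: a column name in `data`, a tibble
#'   (`sample_id` + group column, e.g. from [dichotomize_scores()]), or a
#'   vector.
#' @param time,event Column names (defaults `"time"`, `"event"`).
#' @return A `km_curve`: `table` (tibble `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`, `std_err`) and the underlying
#'   `survfit` object.
#' @export
kaplan_meier <- function(data, group = NULL, time = "time", event = "event") {
  d <- prepare_surv_data(data, time, event)
  if (is.null(group)) {
    d$..group <- "all"
  } else {
    d$..group <- resolve_group(d, group)
    d <- d[!is.na(d$..group), , drop = FALSE]
  }
  fit <- survival::survfit(
    as.formula(sprintf("survival::Surv(%s, %s) ~ ..group", time, event)),
    data = d, conf.type = "log")
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep("all", length(sm$time)) else
    sub("^\\.\\.group=", "", as.character(sm$strata))
  tab <- tibble::tibble(group = grp, time = sm$time, n_risk = sm$n.risk,
                        n_event = sm$n.event, n_censor = sm$n.censor,
                        survival = sm$surv, std_err = sm$std.err)
  structure(list(table = tab, fit = fit, grouped = !is.null(group)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve>\n")
  print(x$fit)
  invisible(x)
}

#' @export
#' @method tidy km_curve
tidy.km_curve <- function(x, ...) x$table

#' Two-group log-rank test
#'
#' Standard log-rank chi-square via [survival::survdiff()]:
#' `chi^2 = (sum(O - E))^2 / sum(V)` accumulated over event times, referred
#' to a chi-square distribution with `k - 1` df.
#'
#' @inheritParams kaplan_meier
#' @param group Grouping with >= 2 non-empty levels (same forms as in
#'   [kaplan_meier()]).
#' @return A one-row tibble: `chi_square`, `df`, `p_value`, `n`, `n_events`.
#' @export
log_rank <- function(data, group, time = "time", event = "event") {
  d <- prepare_surv_data(data, time, event)
  d$..group <- resolve_group(d, group)
  d <- d[!is.na(d$..group), , drop = FALSE]
  if (length(unique(d$..group)) < 2) {
    stop("log-rank needs >= 2 non-empty groups", call. = FALSE)
  }
  if (sum(d[[event]]) == 0) stop("log-rank needs >= 1 event", call. = FALSE)
  sd <- survival::survdiff(
    as.formula(sprintf("survival::Surv(%s, %s) ~ ..group", time, event)),
    data = d)
  tibble::tibble(chi_square = sd$chisq, df = length(sd$n) - 1,
                 p_value = pchisq(sd$chisq, length(sd$n) - 1, lower.tail = FALSE),
                 n = nrow(d), n_events = sum(d[[event]]))
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Efron-approximation partial likelihood (via
#' [survival::coxph()]) and reports, per covariate, the coefficient, hazard
#' ratio, Wald 95% CI `exp(coef +/- 1.96 * SE)`, and Wald p-value.
#' Character/logical covariates are treated as factors; a covariate that is
#' constant on the analysis rows is rejected by name. Monotone likelihood
#' (perfect separation) is flagged: the fit is returned with
#' `converged = FALSE` and a warning rather than an error.
#'
#' @inheritParams kaplan_meier
#' @param covariates Character vector of model terms; plain column names
#'   and interaction terms like `"treatment:score"` are accepted.
#' @param ties Tie handling, default `"efron"`.
#' @return A `cox_fit`: `table` (tibble `term`, `estimate`, `std_error`,
#'   `hazard_ratio`, `conf_low`, `conf_high`, `p_value`), `loglik` (at the
#'   fitted coefficients), `n`, `n_events`, `converged`, and the underlying
#'   `coxph` fit.
#' @export
cox_fit <- function(data, covariates, time = "time", event = "event",
                    ties = "efron") {
  d <- prepare_surv_data(data, time, event)
  if (sum(d[[event]]) < 1) stop("Cox model needs >= 1 event", call. = FALSE)
  plain <- unique(unlist(strsplit(covariates, ":", fixed = TRUE)))
  for (cv in plain) {
    if (!cv %in% names(d)) stop("no covariate column `", cv, "`", call. = FALSE)
    vals <- d[[cv]][!is.na(d[[cv]])]
    if (length(unique(vals)) < 2) {
      stop("covariate `", cv, "` is constant: unidentifiable", call. = FALSE)
    }
    if (is.character(d[[cv]]) || is.logical(d[[cv]])) d[[cv]] <- factor(d[[cv]])
  }
  fml <- as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ",
                           paste(covariates, collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = ties,
                    control = survival::coxph.control(eps = 1e-11, toler.chol = 1e-13,
                                                      iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  if (!converged) {
    warning("monotone likelihood suspected: coefficients may be unstable",
            call. = FALSE)
  }
  cf <- summary(fit)$coefficients
  tab <- tibble::tibble(
    term = rownames(cf), estimate = cf[, "coef"],
    std_error = cf[, "se(coef)"], hazard_ratio = exp(cf[, "coef"]),
    conf_low = exp(cf[, "coef"] - 1.96 * cf[, "se(coef)"]),
    conf_high = exp(cf[, "coef"] + 1.96 * cf[, "se(coef)"]),
    p_value = cf[, "Pr(>|z|)"])
  structure(list(table = tab, loglik = fit$loglik[2], n = fit$n,
                 n_events = fit$nevent, converged = converged, fit = fit,
                 ties = ties),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit (%s ties): n = %d, events = %d, loglik = %.3f%s>\n",
              x$ties, x$n, x$n_events, x$loglik,
              if (x$converged) "" else ", NOT CONVERGED"))
  print(x$table)
  invisible(x)
}

#' @export
#' @method tidy cox_fit
tidy.cox_fit <- function(x, ...) x$table

#' @export
#' @method glance cox_fit
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, loglik = x$loglik,
                 converged = x$converged,
                 concordance = unname(x$fit$concordance["concordance"]))
}

#' Likelihood-ratio test for a treatment-by-score interaction
#'
#' Fits two nested Cox models — full:
#' `treatment + score + treatment:score (+ covariates)`; reduced:
#' `treatment + score (+ covariates)` — and compares them with
#' `LRT = 2 * (loglik_full - loglik_reduced)` on 1 df. A significant test
#' means the score modifies the treatment effect (predictive, not merely
#' prognostic, value). The score is used as supplied — continuous by
#' default, or pre-dichotomized by the caller.
#'
#' @inheritParams kaplan_meier
#' @param score Column name in `data`, or a tibble (`sample_id`, `score`)
#'   joined onto `data`.
#' @param treatment Name of the 0/1 treatment-arm column.
#' @param covariates Optional additional adjustment terms.
#' @return An `interaction_lrt`: `statistic`, `df`, `p_value`, and the
#'   `full` and `reduced` [cox_fit()] objects.
#' @export
interaction_lrt <- function(data, score = "score", treatment = "treatment",
                            covariates = NULL, time = "time", event = "event") {
  if (is.data.frame(score)) {
    sv <- as_sample_values(score, value = if ("score" %in% names(score)) "score",
                           arg = "score")
    data$..score <- sv$value[match(data$sample_id, sv$sample_id)]
    score <- "..score"
  }
  d <- prepare_surv_data(data, time, event)
  if (!treatment %in% names(d)) stop("no column `", treatment, "`", call. = FALSE)
  arms <- unique(d[[treatment]][!is.na(d[[treatment]])])
  if (length(arms) < 2) stop("both treatment arms must be present", call. = FALSE)
  ev_by_arm <- tapply(d[[event]], d[[treatment]], sum)
  if (any(ev_by_arm == 0)) {
    stop("each treatment arm needs >= 1 event", call. = FALSE)
  }
  reduced_terms <- c(treatment, score, covariates)
  full_terms <- c(reduced_terms, paste0(treatment, ":", score))
  full <- cox_fit(d, full_terms, time = time, event = event)
  reduced <- cox_fit(d, reduced_terms, time = time, event = event)
  if (!full$converged || !reduced$converged) {
    stop("interaction LRT: Cox model failed to converge", call. = FALSE)
  }
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  structure(list(statistic = stat, df = 1L,
                 p_value = pchisq(stat, 1, lower.tail = FALSE),
                 full = full, reduced = reduced),
            class = "interaction_lrt")
}

#' @export
print.interaction_lrt <- function(x, ...) {
  cat(sprintf("<interaction_lrt: chi^2(1) = %.3f, p = %.4g>\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' @export
#' @method glance interaction_lrt
glance.interaction_lrt <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 loglik_full = x$full$loglik, loglik_reduced = x$reduced$loglik,
                 n = x$full$n, n_events = x$full$n_events)
}

#' @export
#' @method tidy interaction_lrt
tidy.interaction_lrt <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$full$table, model = "full"),
    dplyr::mutate(x$reduced$table, model = "reduced"))
}
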