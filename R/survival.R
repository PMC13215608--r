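#' Patient-level survival records from a clustered cohort
#'
#' One row per patient: follow-up time runs from the first eligible
#' assessment (day 0) to the recorded death day, or to the censoring day for
#' patients without a recorded death (right-censoring at the end of observed
#' follow-up). The patient's final-cluster label is attached as a
#' baseline-style covariate through the pool's pattern membership.
#'
#' @param records an [assessment_records()] table (post-exclusion).
#' @param pool a `traj_pool` built from these records.
#' @param labels final cluster labels, one per pool pattern.
#' @return data.frame: `patient_id`, `time`, `event`, `cluster`, `age`, `sex`.
#' @export
survival_table <- function(records, pool, labels) {
  pat_cluster <- rep(labels, times = lengths(pool$members))
  names(pat_cluster) <- unlist(pool$members, use.names = FALSE)
  first <- records[!duplicated(records$patient_id), , drop = FALSE]
  first <- first[first$patient_id %in% names(pat_cluster), , drop = FALSE]
  data.frame(
    patient_id = first$patient_id,
    time = ifelse(is.na(first$death_day), first$censor_day, first$death_day),
    event = as.integer(!is.na(first$death_day)),
    cluster = as.integer(pat_cluster[first$patient_id]),
    age = first$age,
    sex = first$sex,
    stringsAsFactors = FALSE
  )
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimate of the survival function under right-censoring,
#' overall or per group.
#'
#' @param data data.frame with `time` and `event` columns (1 = death,
#'   0 = censored).
#' @param group_by optional column name to stratify on (e.g. `"cluster"`).
#' @return data.frame step-function table: `group` (or `"all"`), `time`,
#'   `n_risk`, `n_event`, `survival`.
#' @export
km_curve <- function(data, group_by = NULL) {
  if (nrow(data) < 1L) stop("no records")
  if (any(data$time < 0)) stop("negative survival times")
  if (is.null(group_by)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = data)
    groups <- rep("all", length(fit$time))
  } else {
    f <- stats::as.formula(paste("survival::Surv(time, event) ~", group_by))
    fit <- survival::survfit(f, data = data)
    groups <- if (is.null(fit$strata)) {
      rep(as.character(data[[group_by]][1]), length(fit$time))
    } else {
      rep(sub("^.*=", "", names(fit$strata)), fit$strata)
    }
  }
  data.frame(group = groups, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, survival = fit$surv,
             stringsAsFactors = FALSE)
}

#' Cox proportional-hazards model for cluster membership
#'
#' Fits `Surv(time, event) ~ cluster + age + sex` by partial likelihood
#' (Efron tie handling by default), with the cluster factor releveled so
#' hazard ratios are relative to `reference_cluster`. The `sex` term is
#' dropped automatically when only one sex is present.
#'
#' @param data a [survival_table()] data.frame.
#' @param reference_cluster cluster id used as the reference group.
#' @param ties `"efron"` or `"breslow"`.
#' @param covariates additional adjustment columns (default age and sex).
#' @param robust use robust (sandwich) standard errors.
#' @return object of class `cox_result`: data.frame `table` (per-term `coef`,
#'   `hr`, `se`, `z`, `p`, `lower`, `upper`), plus `ties`, `converged`,
#'   `formula`, `fit` (the underlying `coxph` object).
#' @export
cox_fit <- function(data, reference_cluster = 1L, ties = c("efron", "breslow"),
                    covariates = c("age", "sex"), robust = FALSE) {
  ties <- match.arg(ties)
  if (length(unique(data$time[data$event == 1])) < 2L) {
    stop("need at least two distinct event times")
  }
  df <- data
  df$cluster <- stats::relevel(factor(df$cluster),
                               ref = as.character(reference_cluster))
  covariates <- covariates[vapply(covariates, function(v) {
    length(unique(df[[v]])) > 1L
  }, logical(1))]
  rhs <- paste(c("cluster", covariates), collapse = " + ")
  f <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- survival::coxph(f, data = df, ties = ties, robust = robust)
  if (any(abs(stats::coef(fit)) > 15)) {
    stop("monotone partial likelihood (complete separation) detected")
  }
  s <- summary(fit)
  se_col <- if (robust) "robust se" else "se(coef)"
  tab <- data.frame(
    term = rownames(s$coefficients),
    coef = s$coefficients[, "coef"],
    hr = exp(s$coefficients[, "coef"]),
    se = s$coefficients[, se_col],
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab$z <- tab$coef / tab$se
  tab$p <- 2 * stats::pnorm(-abs(tab$z))
  tab$lower <- exp(tab$coef - 1.96 * tab$se)
  tab$upper <- exp(tab$coef + 1.96 * tab$se)
  structure(list(table = tab, ties = ties,
                 converged = fit$info["convergence"] %||% TRUE,
                 formula = deparse(f), fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat("<cox_result> ", x$formula, " (ties=", x$ties, ")\n", sep = "")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Sex-imbalance sensitivity analyses
#'
#' Three artifacts probing whether cluster-mortality associations depend on
#' sex: sex-stratified Kaplan-Meier tables, sex-specific Cox models adjusted
#' for age, and a model with cluster-by-sex interaction terms (with per-term
#' Wald p-values). With a single-sex input the interaction model is skipped
#' with a warning.
#'
#' @param data a [survival_table()] data.frame.
#' @param reference_cluster reference cluster id.
#' @return list: `km_by_sex`, `cox_by_sex` (named list of `cox_result`),
#'   `interaction` (`cox_result` or `NULL`), `interaction_p` (named Wald
#'   p-values of the interaction terms, or `NULL`).
#' @export
sensitivity_suite <- function(data, reference_cluster = 1L) {
  km <- km_curve(transform(data,
                           sexcluster = paste(sex, cluster, sep = ":")),
                 group_by = "sexcluster")
  sexes <- unique(data$sex)
  cox_by_sex <- lapply(sexes, function(sx) {
    cox_fit(data[data$sex == sx, , drop = FALSE], reference_cluster,
            covariates = "age")
  })
  names(cox_by_sex) <- sexes
  interaction <- NULL
  ip <- NULL
  if (length(sexes) < 2L) {
    warning("single-sex input: interaction model skipped")
  } else {
    df <- data
    df$cluster <- stats::relevel(factor(df$cluster),
                                 ref = as.character(reference_cluster))
    fit <- survival::coxph(
      survival::Surv(time, event) ~ cluster * sex + age, data = df,
      ties = "efron")
    s <- summary(fit)$coefficients
    terms <- grep(":", rownames(s), value = TRUE)
    ip <- 2 * stats::pnorm(-abs(s[terms, "coef"] / s[terms, "se(coef)"]))
    names(ip) <- terms
    interaction <- fit
  }
  list(km_by_sex = km, cox_by_sex = cox_by_sex, interaction = interaction,
       interaction_p = ip)
}
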