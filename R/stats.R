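#' Upper-tail interquartile-range outlier rule
#'
#' Flags values strictly greater than `Q3 + 1.5 * IQR`, with quartiles by the
#' linear-interpolation (type 7) sample-quantile convention. Only the upper
#' tail is tested. Inputs with fewer than 4 finite values pass through
#' unflagged.
#'
#' @param values numeric vector (may contain NA).
#' @return list with `kept` (values not flagged), `excluded` (logical flags
#'   aligned with the input) and `threshold`.
#' @export
exclude_outliers <- function(values) {
  excluded <- rep(FALSE, length(values))
  fin <- is.finite(values)
  if (sum(fin) < 4) {
    return(list(kept = values[!excluded], excluded = excluded,
                threshold = Inf))
  }
  q <- stats::quantile(values[fin], c(0.25, 0.75), type = 7, names = FALSE)
  thr <- q[2] + 1.5 * (q[2] - q[1])
  excluded <- fin & values > thr
  list(kept = values[!excluded], excluded = excluded, threshold = thr)
}

#' Two-group comparison
#'
#' Unpaired two-sided Student t-test (pooled variance) or Mann-Whitney U
#' test. The choice is the caller's, as is conventional for mixed
#' parametric/non-parametric variable sets.
#'
#' @param x,y numeric vectors, one per group.
#' @param method `"t_test"` or `"mann_whitney"`.
#' @return list with `statistic` (t, or the U statistic), `p_value`,
#'   `method`.
#' @export
group_compare <- function(x, y, method = c("t_test", "mann_whitney")) {
  method <- match.arg(method)
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  if (method == "t_test") {
    if (length(x) < 2 || length(y) < 2) {
      stop("t-test requires at least 2 values per group")
    }
    ht <- stats::t.test(x, y, var.equal = TRUE)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value, method = method)
}

# control/patient and male/female coded 0/1; numeric input is validated.
.encode_binary <- function(v, name) {
  if (is.numeric(v)) {
    if (!all(v %in% c(0, 1))) stop("numeric column '", name, "' must be 0/1")
    return(as.numeric(v))
  }
  v <- as.character(v)
  levels <- switch(name,
                   group = c("control", "patient"),
                   sex = c("male", "female"),
                   stop("no 0/1 coding defined for column '", name, "'"))
  if (!all(v %in% levels)) {
    stop("column '", name, "' must take values ", paste(levels, collapse = "/"))
  }
  as.numeric(v == levels[2])
}

.zscore <- function(v, name) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) {
    stop("column '", name, "' is constant; design is collinear")
  }
  (v - mean(v)) / s
}

#' Standardized-beta linear regression
#'
#' Fits an ordinary least-squares model of `dependent` on `independent` plus
#' covariates after z-scoring every continuous variable (mean 0, SD 1, n-1
#' denominator). The binary columns `group` and `sex` are coded
#' control = 0 / patient = 1 and male = 0 / female = 1 and are not rescaled.
#' The reported standardized beta is the coefficient of `independent`; in
#' the univariable continuous case it equals the Pearson correlation. The
#' 95% CI is `beta +/- t(0.975, df) * SE` with the classical OLS standard
#' error. Rows with missing values in any used column are dropped and
#' counted.
#'
#' @param table data frame of subject records.
#' @param dependent,independent column names.
#' @param covariates character vector of additional column names (default
#'   none).
#' @return a `regression_result`: `beta_std`, `ci95` (length 2), `p_value`,
#'   `n`, `n_dropped`, `covariates`, `dependent`, `independent`.
#' @export
regress_standardized <- function(table, dependent, independent,
                                 covariates = character()) {
  cols <- c(dependent, independent, covariates)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- table[, cols, drop = FALSE]
  complete <- stats::complete.cases(df)
  n_dropped <- sum(!complete)
  df <- df[complete, , drop = FALSE]

  for (nm in cols) {
    if (nm %in% c("group", "sex")) {
      df[[nm]] <- .encode_binary(df[[nm]], nm)
    } else {
      df[[nm]] <- .zscore(as.numeric(df[[nm]]), nm)
    }
  }
  n <- nrow(df)
  if (n < length(cols) + 1) stop("too few complete rows for the design")

  fml <- stats::as.formula(paste(
    sprintf("`%s`", dependent), "~",
    paste(sprintf("`%s`", c(independent, covariates)), collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear design; aliased term(s): ", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  row <- sprintf("`%s`", independent)
  if (!row %in% rownames(sm)) row <- independent
  beta <- sm[row, "Estimate"]
  se <- sm[row, "Std. Error"]
  dfree <- fit$df.residual
  ci <- beta + c(-1, 1) * stats::qt(0.975, dfree) * se
  structure(list(beta_std = unname(beta), ci95 = ci,
                 p_value = unname(sm[row, "Pr(>|t|)"]),
                 n = n, n_dropped = n_dropped,
                 covariates = covariates,
                 dependent = dependent, independent = independent),
            class = "regression_result")
}

.mri_measures <- c("wmh_rel_volume", "ki_nawm", "vl_nawm", "ki_wmh", "vl_wmh")

.assoc_row <- function(res, measure, analysis) {
  data.frame(measure = measure, analysis = analysis,
             beta = res$beta_std, ci_lo = res$ci95[1], ci_hi = res$ci95[2],
             p = res$p_value, n = res$n, stringsAsFactors = FALSE)
}

#' Group association report (cohort characteristics table)
#'
#' For each MRI measure present (`wmh_rel_volume`, `ki_nawm`, `vl_nawm`,
#' `ki_wmh`, `vl_wmh`): group means +/- SEM, plus the univariable and the
#' age/sex-adjusted multivariable standardized beta of group (control = 0,
#' patient = 1) with the measure as dependent variable.
#'
#' @param cohort data frame of subject records (columns `group`, `age`,
#'   `sex` and the MRI measures).
#' @return a `table1_report`: list with data frames `means` (measure, group,
#'   mean, sem, n) and `associations`
#'   (measure, analysis, beta, ci_lo, ci_hi, p, n).
#' @export
run_table1 <- function(cohort) {
  g <- as.character(cohort$group)
  if (length(unique(g)) < 2) stop("cohort must contain both groups")
  measures <- intersect(.mri_measures, names(cohort))
  if (length(measures) == 0) stop("no MRI measure columns found")

  means <- do.call(rbind, lapply(measures, function(m) {
    do.call(rbind, lapply(c("control", "patient"), function(gr) {
      v <- cohort[[m]][g == gr & is.finite(cohort[[m]])]
      data.frame(measure = m, group = gr, mean = mean(v),
                 sem = stats::sd(v) / sqrt(length(v)), n = length(v),
                 stringsAsFactors = FALSE)
    }))
  }))

  assoc <- do.call(rbind, lapply(measures, function(m) {
    uni <- regress_standardized(cohort, m, "group")
    multi <- regress_standardized(cohort, m, "group", c("age", "sex"))
    rbind(.assoc_row(uni, m, "univariable"),
          .assoc_row(multi, m, "multivariable"))
  }))
  structure(list(means = means, associations = assoc), class = "table1_report")
}

#' VEGFA association report within one group
#'
#' Applies the upper-tail IQR outlier rule to plasma VEGFA within the
#' selected group, then reports the univariable and age/sex-adjusted
#' standardized beta of VEGFA for each MRI measure as dependent variable.
#'
#' @param cohort data frame of subject records including `vegfa`.
#' @param group_filter `"patient"` or `"control"`.
#' @return a `table2_report`: list with `associations` data frame,
#'   `n_outliers` removed, `group`.
#' @export
run_table2 <- function(cohort, group_filter = c("patient", "control")) {
  group_filter <- match.arg(group_filter)
  if (!"vegfa" %in% names(cohort)) stop("cohort lacks a 'vegfa' column")
  sub <- cohort[as.character(cohort$group) == group_filter, , drop = FALSE]
  out <- exclude_outliers(sub$vegfa)
  sub <- sub[!out$excluded, , drop = FALSE]
  measures <- intersect(.mri_measures, names(sub))
  if (nrow(sub) < 5) stop("too few subjects after filtering for regression")

  assoc <- do.call(rbind, lapply(measures, function(m) {
    uni <- regress_standardized(sub, m, "vegfa")
    multi <- regress_standardized(sub, m, "vegfa", c("age", "sex"))
    rbind(.assoc_row(uni, m, "univariable"),
          .assoc_row(multi, m, "multivariable"))
  }))
  structure(list(associations = assoc, n_outliers = sum(out$excluded),
                 group = group_filter),
            class = "table2_report")
}
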