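# Validation statistics: Kaplan-Meier, log-rank, adjusted Cox PH with
# Schoenfeld diagnostics and cluster-robust variance, RMST (unadjusted and
# pseudo-value adjusted), the likelihood-ratio interaction test, the
# Schoenfeld power formula, Spearman correlation and BH adjustment.
#
# Standard estimators are delegated to the survival package (Efron ties
# throughout; median CIs by the log-log transform). The power formula,
# pseudo-value RMST adjustment and the thin tidy wrappers are local.

surv_from_records <- function(records) {
  assert_columns(records, c("duration_months", "event"), "survival records")
  if (any(records$duration_months < 0)) {
    irs_abort("negative durations in survival records", "irscore_schema_error")
  }
  survival::Surv(records$duration_months, as.integer(records$event))
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with log-log (Brookmeyer-Crowley style)
#' confidence intervals; median survival is the first time the curve drops
#' to 0.5 or below (possibly unbounded).
#'
#' @param records Survival-record tibble (`duration_months`, `event`, plus
#'   an optional grouping column).
#' @param group_col Name of a grouping column in `records`, or `NULL` for a
#'   single curve.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `irs_km` wrapping the `survfit` object, with
#'   [tidy()] (step function: time, n_risk, n_event, survival, CI, group)
#'   and [glance()] (per group: n, events, median with CI) methods and an
#'   [ggplot2::autoplot()] method.
#' @export
km_estimate <- function(records, group_col = NULL, conf_level = 0.95) {
  y <- surv_from_records(records)
  if (is.null(group_col)) {
    dat <- data.frame(.group = factor(rep("all", nrow(records))))
  } else {
    assert_columns(records, group_col, "survival records")
    dat <- data.frame(.group = factor(records[[group_col]]))
  }
  fit <- survival::survfit(y ~ .group, data = dat, conf.type = "log-log",
                           conf.int = conf_level)
  structure(
    list(fit = fit, group_col = group_col %||% "all",
         groups = levels(dat$.group), n = nrow(records)),
    class = "irs_km"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname km_estimate
#' @param x An `irs_km` object.
#' @param ... Unused.
#' @export
tidy.irs_km <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(x$groups[1], length(s$time)) else {
    sub("^\\.group=", "", as.character(s$strata))
  }
  tibble::tibble(
    group = grp, time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    n_censor = s$n.censor, survival = s$surv,
    conf_low = s$lower, conf_high = s$upper
  )
}

#' @rdname km_estimate
#' @export
glance.irs_km <- function(x, ...) {
  tab <- summary(x$fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1, dimnames = list(x$groups[1], names(tab)))
  tibble::tibble(
    group = sub("^\\.group=", "", rownames(tab)),
    n = tab[, "records"], events = tab[, "events"],
    median = tab[, "median"],
    median_low = tab[, "0.95LCL"], median_high = tab[, "0.95UCL"]
  )
}

#' Log-rank test
#'
#' Two-sided log-rank chi-square test of survival-curve differences across
#' two or more groups.
#'
#' @param records Survival-record tibble with a grouping column.
#' @param group_col Name of the grouping column.
#' @return A tibble: `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(records, group_col) {
  assert_columns(records, group_col, "survival records")
  g <- factor(records[[group_col]])
  if (nlevels(g) < 2 || any(table(g) == 0)) {
    irs_abort("log-rank needs at least two non-empty groups", "irscore_usage_error")
  }
  y <- surv_from_records(records)
  sd <- survival::survdiff(y ~ g)
  df <- length(sd$n) - 1
  tibble::tibble(
    statistic = sd$chisq, df = df,
    p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE)
  )
}

#' Fit an (adjusted) Cox proportional-hazards model
#'
#' Maximizes the partial likelihood with Efron tie handling. When
#' `cluster_col` is given (patients contributing several lines), robust
#' sandwich standard errors grouped by cluster are reported alongside the
#' model-based ones, and Wald tests use the robust variance.
#'
#' @param records Tibble with `duration_months`, `event`, the covariate
#'   columns, and optionally a cluster column.
#' @param covariates Character vector of covariate column names.
#' @param cluster_col Optional cluster column name.
#' @return An object of class `irs_cox` wrapping the `coxph` fit, with
#'   [tidy()] (per term: coefficient, hazard ratio with CI, model and
#'   robust SEs, p-value) and [glance()] (n, events, concordance, partial
#'   log-likelihood, tie method).
#' @export
fit_coxph <- function(records, covariates, cluster_col = NULL) {
  assert_columns(records, covariates, "records")
  y <- surv_from_records(records)
  dat <- as.data.frame(records[, c(covariates, cluster_col), drop = FALSE],
                       check.names = FALSE)
  dat$.y <- y
  fml <- stats::as.formula(
    paste(".y ~", paste(sprintf("`%s`", covariates), collapse = " + "))
  )
  fit <- tryCatch(
    if (is.null(cluster_col)) {
      survival::coxph(fml, data = dat, ties = "efron", model = TRUE, x = TRUE)
    } else {
      survival::coxph(fml, data = dat, ties = "efron", model = TRUE, x = TRUE,
                      cluster = dat[[cluster_col]])
    },
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite", conditionMessage(w))) {
        irs_abort(sprintf("Cox fit failed: %s", conditionMessage(w)),
                  "irscore_fitting_error")
      }
      suppressWarnings(if (is.null(cluster_col)) {
        survival::coxph(fml, data = dat, ties = "efron", model = TRUE, x = TRUE)
      } else {
        survival::coxph(fml, data = dat, ties = "efron", model = TRUE, x = TRUE,
                        cluster = dat[[cluster_col]])
      })
    }
  )
  if (any(!is.finite(stats::coef(fit)))) {
    irs_abort("Cox fit produced non-finite coefficients (separation?)",
              "irscore_fitting_error")
  }
  structure(
    list(fit = fit, covariates = covariates, cluster_col = cluster_col,
         tie_method = "efron"),
    class = "irs_cox"
  )
}

#' @rdname fit_coxph
#' @param x An `irs_cox` object.
#' @param conf_level Confidence level for hazard-ratio intervals.
#' @param ... Unused.
#' @export
tidy.irs_cox <- function(x, conf_level = 0.95, ...) {
  sm <- summary(x$fit, conf.int = conf_level)
  co <- sm$coefficients
  robust <- "robust se" %in% colnames(co)
  se_model <- co[, "se(coef)"]
  se_used <- if (robust) co[, "robust se"] else se_model
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = rownames(co),
    estimate = co[, "coef"],
    hazard_ratio = exp(co[, "coef"]),
    conf_low = exp(co[, "coef"] - z * se_used),
    conf_high = exp(co[, "coef"] + z * se_used),
    std_error = se_model,
    robust_se = if (robust) co[, "robust se"] else NA_real_,
    p_value = co[, ncol(co)]
  )
}

#' @rdname fit_coxph
#' @export
glance.irs_cox <- function(x, ...) {
  f <- x$fit
  tibble::tibble(
    n = f$n, n_events = f$nevent,
    concordance = unname(f$concordance["concordance"]),
    partial_log_likelihood = f$loglik[length(f$loglik)],
    tie_method = x$tie_method
  )
}

#' Schoenfeld proportional-hazards diagnostics
#'
#' Tests each covariate's scaled Schoenfeld residuals for association with
#' time, plus the global chi-square test with df equal to the number of
#' covariates.
#'
#' @param fit An `irs_cox` object from [fit_coxph()].
#' @param transform Time transform passed to [survival::cox.zph()]
#'   (default `"km"`).
#' @return A tibble: `term` (covariates plus `GLOBAL`), `chisq`, `df`,
#'   `p_value`.
#' @export
check_ph <- function(fit, transform = "km") {
  stopifnot(inherits(fit, "irs_cox"))
  z <- survival::cox.zph(fit$fit, transform = transform)
  tab <- z$table
  tibble::tibble(
    term = rownames(tab), chisq = unname(tab[, "chisq"]),
    df = unname(tab[, "df"]), p_value = unname(tab[, "p"])
  )
}

# area under the product-limit curve up to tau (point estimate only)
km_area <- function(time, event, tau) {
  o <- order(time)
  time <- time[o]; event <- event[o]
  n <- length(time)
  at_risk <- n
  surv <- 1
  area <- 0
  last_t <- 0
  for (i in seq_len(n)) {
    t_i <- min(time[i], tau)
    area <- area + surv * (t_i - last_t)
    last_t <- t_i
    if (time[i] >= tau) return(area)
    if (event[i]) {
      # handle ties: count all events at this time against current risk set
      if (i == n || time[i + 1] != time[i]) {
        d <- sum(event[time == time[i]])
        r <- sum(time >= time[i])
        surv <- surv * (1 - d / r)
      }
    }
  }
  area + surv * max(tau - last_t, 0)
}

#' Restricted mean survival time
#'
#' RMST is the area under the Kaplan-Meier curve up to the horizon `tau`.
#' Unadjusted per-group estimates and their difference use the survival
#' package's restricted-mean machinery (Greenwood-based standard errors).
#' With `covariates`, the group difference is adjusted by linear regression
#' of leave-one-out pseudo-values on group plus covariates, with
#' heteroscedasticity-robust (HC1) standard errors.
#'
#' @param records Survival-record tibble; `group_col` optional for a
#'   single-arm RMST.
#' @param tau Horizon in months; must not exceed the largest observed time
#'   in any group.
#' @param group_col Optional grouping column name (two groups for a
#'   difference).
#' @param covariates Optional character vector of adjustment covariate
#'   columns (requires `group_col`).
#' @param conf_level Confidence level.
#' @return A list of class `irs_rmst`: `by_group` (tibble of group, rmst,
#'   std_error, CI), `difference` (tibble, present when two groups), `tau`,
#'   `adjusted` flag.
#' @export
rmst <- function(records, tau, group_col = NULL, covariates = NULL,
                 conf_level = 0.95) {
  y_all <- surv_from_records(records)
  grp <- if (is.null(group_col)) factor(rep("all", nrow(records))) else {
    assert_columns(records, group_col, "survival records")
    factor(records[[group_col]])
  }
  for (g in levels(grp)) {
    if (max(records$duration_months[grp == g]) < tau) {
      irs_abort(sprintf("tau = %g exceeds follow-up in group '%s'", tau, g),
                "irscore_usage_error")
    }
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  by_group <- purrr::map(levels(grp), function(g) {
    t_g <- records$duration_months[grp == g]
    e_g <- as.integer(records$event[grp == g])
    if (tau <= min(t_g)) {
      # nothing can happen before tau: the curve is flat at 1
      est <- tau
      se <- 0
    } else {
      fit_g <- survival::survfit(survival::Surv(t_g, e_g) ~ 1)
      tab <- summary(fit_g, rmean = tau)$table
      est <- unname(tab[["rmean"]])
      se <- unname(tab[["se(rmean)"]])
    }
    tibble::tibble(group = g, rmst = est, std_error = se,
                   conf_low = est - z * se, conf_high = est + z * se)
  }) |> dplyr::bind_rows()
  difference <- NULL
  if (nlevels(grp) == 2) {
    d <- by_group$rmst[2] - by_group$rmst[1]
    se <- sqrt(sum(by_group$std_error^2))
    difference <- tibble::tibble(
      contrast = paste(levels(grp)[2], "-", levels(grp)[1]),
      estimate = d, std_error = se,
      conf_low = d - z * se, conf_high = d + z * se,
      p_value = 2 * stats::pnorm(-abs(d / se)), adjusted = FALSE
    )
    if (!is.null(covariates)) {
      difference <- rmst_adjusted(records, tau, grp, covariates, z)
    }
  } else if (!is.null(covariates)) {
    irs_abort("covariate-adjusted RMST needs exactly two groups",
              "irscore_usage_error")
  }
  structure(
    list(by_group = by_group, difference = difference, tau = tau,
         adjusted = !is.null(covariates)),
    class = "irs_rmst"
  )
}

# leave-one-out pseudo-value regression for the adjusted RMST difference
rmst_adjusted <- function(records, tau, grp, covariates, z) {
  assert_columns(records, covariates, "survival records")
  n <- nrow(records)
  t_all <- records$duration_months
  e_all <- as.integer(records$event)
  theta_full <- km_area(t_all, e_all, tau)
  pseudo <- vapply(seq_len(n), function(i) {
    n * theta_full - (n - 1) * km_area(t_all[-i], e_all[-i], tau)
  }, numeric(1))
  df <- data.frame(pseudo = pseudo, .group = grp,
                   records[, covariates, drop = FALSE], check.names = FALSE)
  fml <- stats::as.formula(paste(
    "pseudo ~ .group +", paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  lmfit <- stats::lm(fml, data = df)
  X <- stats::model.matrix(lmfit)
  e <- stats::residuals(lmfit)
  bread <- solve(crossprod(X))
  meat <- crossprod(X * e)
  vc <- bread %*% meat %*% bread * n / (n - ncol(X))  # HC1
  term <- paste0(".group", levels(grp)[2])
  est <- stats::coef(lmfit)[term]
  se <- sqrt(vc[term, term])
  tibble::tibble(
    contrast = paste(levels(grp)[2], "-", levels(grp)[1]),
    estimate = unname(est), std_error = se,
    conf_low = unname(est) - z * se, conf_high = unname(est) + z * se,
    p_value = 2 * stats::pnorm(-abs(est / se)), adjusted = TRUE
  )
}

#' @export
print.irs_rmst <- function(x, ...) {
  cat(sprintf("RMST at tau = %g months%s\n", x$tau,
              if (x$adjusted) " (covariate-adjusted difference)" else ""))
  print(as.data.frame(x$by_group), row.names = FALSE)
  if (!is.null(x$difference)) print(as.data.frame(x$difference), row.names = FALSE)
  invisible(x)
}

#' Likelihood-ratio test for a marker-by-treatment interaction
#'
#' Fits nested Cox models with and without the interaction between the
#' treatment indicator and the marker, both adjusted for `covariates` and
#' (optionally) clustered by patient when patients contribute a record per
#' treatment. The statistic is twice the difference in maximized partial
#' log-likelihoods; a significant test indicates the marker is predictive
#' (treatment-effect modifying), not merely prognostic.
#'
#' @param records Tibble with `duration_months`, `event`, the treatment and
#'   marker columns, adjustment covariates, and a cluster column.
#' @param treatment_col,marker_col Names of the treatment and marker
#'   columns.
#' @param covariates Optional character vector of adjustment covariates.
#' @param cluster_col Cluster column name (default `"patient_id"`); set
#'   `NULL` for independent records.
#' @return A tibble: `statistic`, `df`, `p_value`.
#' @export
lrt_interaction <- function(records, treatment_col, marker_col,
                            covariates = NULL, cluster_col = "patient_id") {
  assert_columns(records, c(treatment_col, marker_col, covariates), "records")
  base_terms <- c(sprintf("`%s`", c(treatment_col, marker_col, covariates)))
  full_terms <- c(base_terms, sprintf("`%s`:`%s`", treatment_col, marker_col))
  reduced <- fit_coxph_terms(records, base_terms, cluster_col)
  full <- fit_coxph_terms(records, full_terms, cluster_col)
  ll_r <- reduced$loglik[length(reduced$loglik)]
  ll_f <- full$loglik[length(full$loglik)]
  df <- length(stats::coef(full)) - length(stats::coef(reduced))
  if (df <= 0) {
    irs_abort("full model does not nest additional interaction terms",
              "irscore_usage_error")
  }
  stat <- max(2 * (ll_f - ll_r), 0)
  tibble::tibble(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

fit_coxph_terms <- function(records, terms, cluster_col) {
  y <- surv_from_records(records)
  dat <- as.data.frame(records, check.names = FALSE)
  dat$.y <- y
  fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  if (is.null(cluster_col)) {
    survival::coxph(fml, data = dat, ties = "efron")
  } else {
    survival::coxph(fml, data = dat, ties = "efron",
                    cluster = dat[[cluster_col]])
  }
}

#' Power / sample size for a two-group Cox comparison (Schoenfeld formula)
#'
#' Required events d = (z[1-alpha/2] + z[1-beta])^2 / (p (1-p) (ln HR)^2),
#' with n = d / event_rate; given `n`, the power is obtained by inverting
#' the formula. Exactly one of `n` and `power` must be supplied.
#'
#' @param hazard_ratio Hazard ratio to detect (> 0, not 1).
#' @param n Total sample size (solve for power), or `NULL`.
#' @param power Target power (solve for n), or `NULL`.
#' @param allocation Fraction allocated to one group (default 0.5).
#' @param event_rate Expected fraction of subjects with an event (0, 1].
#' @param alpha Two-sided significance level.
#' @return A tibble: `n`, `n_events`, `power`, `hazard_ratio`,
#'   `allocation`, `event_rate`, `alpha`.
#' @export
#' @examples
#' power_cox(hazard_ratio = 0.5, n = 180, event_rate = 0.5) # ~0.90 power
power_cox <- function(hazard_ratio, n = NULL, power = NULL, allocation = 0.5,
                      event_rate, alpha = 0.05) {
  stopifnot(hazard_ratio > 0, allocation > 0, allocation < 1,
            event_rate > 0, event_rate <= 1, alpha > 0, alpha < 1)
  if (is.null(n) == is.null(power)) {
    irs_abort("supply exactly one of n and power", "irscore_usage_error")
  }
  z_a <- stats::qnorm(1 - alpha / 2)
  effect <- allocation * (1 - allocation) * log(hazard_ratio)^2
  if (hazard_ratio == 1) {
    warning("hazard_ratio = 1: power equals alpha")
    if (is.null(power)) {
      return(tibble::tibble(n = n, n_events = n * event_rate, power = alpha,
                            hazard_ratio = hazard_ratio, allocation = allocation,
                            event_rate = event_rate, alpha = alpha))
    }
    irs_abort("cannot solve sample size for hazard_ratio = 1", "irscore_usage_error")
  }
  if (is.null(power)) {
    d <- n * event_rate
    pw <- stats::pnorm(sqrt(d * effect) - z_a)
    return(tibble::tibble(n = n, n_events = d, power = pw,
                          hazard_ratio = hazard_ratio, allocation = allocation,
                          event_rate = event_rate, alpha = alpha))
  }
  z_b <- stats::qnorm(power)
  d <- (z_a + z_b)^2 / effect
  tibble::tibble(n = d / event_rate, n_events = d, power = power,
                 hazard_ratio = hazard_ratio, allocation = allocation,
                 event_rate = event_rate, alpha = alpha)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties.
#'
#' @param x,y Paired numeric vectors (n >= 3, finite, non-constant).
#' @return The correlation coefficient.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    irs_abort("need paired vectors of length >= 3", "irscore_usage_error")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    irs_abort("inputs must be finite", "irscore_usage_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    irs_abort("Spearman correlation undefined for constant input",
              "irscore_usage_error")
  }
  stats::cor(x, y, method = "spearman")
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`; adjusted
#' values never decrease and preserve the ordering of the input p-values.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}
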