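# The Immunotherapy Response Score: locked-model scoring, re-derivation by
# cross-validated Lasso-penalized Cox regression, and threshold selection.
#
# The locked score is
#   IRS = 0.273758*TMB + 0.112641*PD-1 + 0.061904*PD-L1
#         - 0.077011*TOP2A - 0.057991*ADAM12
# on transformed features (log2 TMB; centered log2 nRPM), dichotomized at
# 0.873569 (High = score >= threshold = more likely to benefit from
# PD-(L)1 monotherapy). The score is oriented so that higher values mean
# LOWER hazard: it is the negative of the Cox hazard linear predictor.

#' Score patients with the locked IRS model
#'
#' Accepts either a raw biomarker table (columns `tmb` plus nRPM per model
#' gene; transformed internally via [transform_biomarkers()]) or an
#' already-transformed feature table (columns `TMB`, `PD-1`, `PD-L1`,
#' `ADAM12`, `TOP2A`). The score is the coefficient-weighted sum of the
#' transformed features; `group` is `"High"` iff `score >= spec$threshold`.
#'
#' @param biomarkers Tibble with `patient_id` and either raw (`tmb` + nRPM)
#'   or transformed feature columns.
#' @param spec An `irs_model_spec` from [load_model_spec()].
#' @return A tibble: `patient_id`, the transformed feature columns, `score`,
#'   `group` (factor Low/High).
#' @export
#' @examples
#' spec <- load_model_spec()
#' compute_irs(
#'   tibble::tibble(patient_id = "P1", TMB = log2(10),
#'                  `PD-1` = 0, `PD-L1` = 0, ADAM12 = 0, TOP2A = 0),
#'   spec
#' )
compute_irs <- function(biomarkers, spec = load_model_spec()) {
  feats <- names(spec$coefficients)
  if ("tmb" %in% names(biomarkers)) {
    features <- transform_biomarkers(biomarkers, spec)
  } else {
    features <- biomarkers
  }
  missing <- setdiff(feats, names(features))
  if (length(missing) > 0) {
    irs_abort(sprintf("cannot score: missing feature%s %s",
                      if (length(missing) > 1) "s" else "",
                      paste(missing, collapse = ", ")),
              "irscore_scoring_error")
  }
  assert_columns(features, "patient_id", "feature table")
  x <- as.matrix(features[, feats])
  if (any(!is.finite(x))) {
    irs_abort("non-finite feature values; cannot score", "irscore_scoring_error")
  }
  score <- drop(x %*% spec$coefficients[feats])
  features |>
    dplyr::select("patient_id", dplyr::all_of(feats),
                  dplyr::any_of("tmb_high")) |>
    dplyr::mutate(
      score = score,
      group = factor(dplyr::if_else(score >= spec$threshold, "High", "Low"),
                     levels = c("Low", "High"))
    )
}

#' Re-derive the score by cross-validated Lasso-penalized Cox regression
#'
#' Fits a Lasso-penalized Cox model of the survival records on candidate
#' features over a path of 100 log-spaced penalties (from the smallest
#' penalty that zeroes every coefficient down to 1e-3 of it), choosing the
#' penalty that maximizes the cross-validated concordance index over
#' `n_folds` folds stratified by event status; ties in concordance are
#' broken toward the sparser (more penalized) model. Coefficients for the
#' features left non-zero are then finalized by unpenalized Cox regression.
#' Features are standardized internally for the penalized fit; reported
#' coefficients are on the original transformed-feature scale.
#'
#' @param survival Survival-record tibble (`patient_id`, `duration_months`,
#'   `event`).
#' @param features Tibble of `patient_id` plus numeric candidate feature
#'   columns; constant columns are dropped with a warning.
#' @param n_folds Number of cross-validation folds (default 5).
#' @param seed Integer seed controlling fold assignment (required for
#'   reproducibility).
#' @return An object of class `irs_fit` with elements `selected_features`,
#'   `penalized_coefficients`, `refit_coefficients` (Cox hazard scale),
#'   `irs_coefficients` (benefit-oriented, i.e. negated hazard scale, the
#'   scale of the locked equation), `lambda_path` (tibble of penalty,
#'   cv_concordance, nonzero), `chosen_penalty`, `cv_seed`, `refit` (the
#'   `coxph` fit), `n`, `n_events`. Has [tidy()] and [glance()] methods.
#' @export
fit_lasso_cox <- function(survival, features, n_folds = 5, seed = 1) {
  assert_columns(survival, c("patient_id", "duration_months", "event"),
                 "survival table")
  assert_columns(features, "patient_id", "features table")
  dat <- dplyr::inner_join(
    dplyr::select(survival, "patient_id", "duration_months", "event"),
    features, by = "patient_id"
  )
  feat_cols <- setdiff(names(dat), c("patient_id", "duration_months", "event"))
  feat_cols <- feat_cols[vapply(dat[feat_cols], is.numeric, logical(1))]
  if (length(feat_cols) == 0) {
    irs_abort("no numeric candidate features", "irscore_fitting_error")
  }
  x <- as.matrix(dat[, feat_cols])
  if (any(!is.finite(x))) {
    irs_abort("candidate features must be finite", "irscore_fitting_error")
  }
  constant <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(constant)) {
    warning(sprintf("dropping constant candidate feature(s): %s",
                    paste(feat_cols[constant], collapse = ", ")))
    feat_cols <- feat_cols[!constant]
    x <- x[, feat_cols, drop = FALSE]
  }
  n_events <- sum(dat$event)
  if (n_events == 0) {
    irs_abort("no events in the survival records; cannot fit", "irscore_fitting_error")
  }
  if (n_events < 2 * n_folds) {
    irs_abort(sprintf("need at least %d events for %d-fold CV (have %d)",
                      2 * n_folds, n_folds, n_events),
              "irscore_fitting_error")
  }
  y <- survival::Surv(dat$duration_months, dat$event)

  # folds stratified by event indicator, fixed by seed
  foldid <- integer(nrow(dat))
  with_seed_if(seed, {
    for (ev in unique(dat$event)) {
      idx <- which(dat$event == ev)
      foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })

  cvfit <- with_seed_if(seed, glmnet::cv.glmnet(
    x, y, family = "cox", type.measure = "C", foldid = foldid,
    nlambda = 100, lambda.min.ratio = 1e-3, standardize = TRUE
  ))
  path <- tibble::tibble(
    penalty = cvfit$lambda,
    cv_concordance = cvfit$cvm,
    nonzero = unname(cvfit$nzero)
  )
  # maximize CV concordance; ties toward the sparser model (larger penalty)
  best <- max(path$cv_concordance)
  chosen <- max(path$penalty[path$cv_concordance >= best - 1e-12])
  pen_coef <- drop(as.matrix(stats::coef(cvfit$glmnet.fit, s = chosen)))
  selected <- names(pen_coef)[pen_coef != 0]

  refit_coef <- stats::setNames(numeric(0), character(0))
  refit <- NULL
  if (length(selected) > 0) {
    refit_dat <- data.frame(
      time = dat$duration_months, event = as.integer(dat$event),
      dat[, selected, drop = FALSE], check.names = FALSE
    )
    fml <- stats::as.formula(paste(
      "survival::Surv(time, event) ~",
      paste(sprintf("`%s`", selected), collapse = " + ")
    ))
    refit <- survival::coxph(fml, data = refit_dat, ties = "efron")
    if (!is.null(refit$info) || any(!is.finite(stats::coef(refit)))) {
      irs_abort("unpenalized refit failed to converge", "irscore_fitting_error")
    }
    refit_coef <- stats::setNames(stats::coef(refit), selected)
  }
  structure(
    list(
      selected_features = selected,
      penalized_coefficients = pen_coef,
      refit_coefficients = refit_coef,
      irs_coefficients = -refit_coef,
      lambda_path = path,
      chosen_penalty = chosen,
      cv_seed = seed,
      refit = refit,
      n = nrow(dat),
      n_events = n_events
    ),
    class = "irs_fit"
  )
}

#' @export
print.irs_fit <- function(x, ...) {
  cat(sprintf("Lasso-Cox fit: n = %d, events = %d, chosen penalty = %.5g\n",
              x$n, x$n_events, x$chosen_penalty))
  cat(sprintf("Selected features (%d): %s\n", length(x$selected_features),
              paste(x$selected_features, collapse = ", ")))
  if (length(x$irs_coefficients) > 0) {
    cat("Benefit-oriented refit coefficients:\n")
    print(round(x$irs_coefficients, 6))
  }
  invisible(x)
}

#' @rdname fit_lasso_cox
#' @param x An `irs_fit` object.
#' @param ... Unused.
#' @export
tidy.irs_fit <- function(x, ...) {
  if (length(x$selected_features) == 0) {
    return(tibble::tibble(
      term = character(), penalized = numeric(), hazard_coef = numeric(),
      irs_coef = numeric(), std_error = numeric(), p_value = numeric()
    ))
  }
  sm <- summary(x$refit)$coefficients
  tibble::tibble(
    term = x$selected_features,
    penalized = x$penalized_coefficients[x$selected_features],
    hazard_coef = x$refit_coefficients,
    irs_coef = x$irs_coefficients,
    std_error = sm[, "se(coef)"],
    p_value = sm[, "Pr(>|z|)"]
  )
}

#' @rdname fit_lasso_cox
#' @export
glance.irs_fit <- function(x, ...) {
  at <- which.min(abs(x$lambda_path$penalty - x$chosen_penalty))
  tibble::tibble(
    n = x$n,
    n_events = x$n_events,
    n_selected = length(x$selected_features),
    chosen_penalty = x$chosen_penalty,
    cv_concordance = x$lambda_path$cv_concordance[at]
  )
}

#' Select a dichotomization threshold for a risk score
#'
#' Scans candidate thresholds on the 1% percentile grid of the scores. At
#' each candidate with at least `min_group` patients on each side, the
#' unadjusted hazard ratio of High (score >= threshold) vs Low is computed
#' by Cox regression. The returned threshold is the one giving the largest
#' High fraction among candidates whose hazard ratio is at most
#' `hr_target`; the full HR-vs-fraction curve is returned so the trade-off
#' can be inspected.
#'
#' @param scores Numeric vector of per-patient scores.
#' @param survival Survival-record tibble aligned with `scores` (same order;
#'   columns `duration_months`, `event`).
#' @param hr_target Maximum acceptable unadjusted hazard ratio for High vs
#'   Low.
#' @param min_group Minimum patients required on each side of a candidate
#'   cut (default 10; smaller cuts are skipped).
#' @return A list of class `irs_threshold`: `threshold` (`NA` if no
#'   candidate satisfies the target), `hr_target`, and `curve` (tibble of
#'   `threshold`, `hr`, `high_fraction`).
#' @export
select_threshold <- function(scores, survival, hr_target, min_group = 10) {
  assert_columns(survival, c("duration_months", "event"), "survival table")
  if (length(scores) != nrow(survival)) {
    irs_abort("scores and survival records are not aligned", "irscore_usage_error")
  }
  if (stats::sd(scores) == 0) {
    irs_abort("all scores are equal; one side is empty at every cut",
              "irscore_threshold_error")
  }
  grid <- unique(stats::quantile(scores, probs = seq(0.01, 0.99, by = 0.01),
                                 type = 7, names = FALSE))
  rows <- purrr::map(grid, function(t) {
    high <- scores >= t
    if (sum(high) < min_group || sum(!high) < min_group) return(NULL)
    fit <- survival::coxph(
      survival::Surv(survival$duration_months, survival$event) ~ high,
      ties = "efron"
    )
    tibble::tibble(threshold = t, hr = unname(exp(stats::coef(fit))),
                   high_fraction = mean(high))
  })
  curve <- dplyr::bind_rows(rows)
  if (nrow(curve) == 0) {
    irs_abort("no candidate threshold leaves enough patients on both sides",
              "irscore_threshold_error")
  }
  ok <- curve$hr <= hr_target
  chosen <- if (any(ok)) {
    cand <- curve[ok, ]
    cand$threshold[which.max(cand$high_fraction)]
  } else {
    NA_real_
  }
  structure(
    list(threshold = chosen, hr_target = hr_target, curve = curve),
    class = "irs_threshold"
  )
}

#' @export
print.irs_threshold <- function(x, ...) {
  if (is.na(x$threshold)) {
    cat(sprintf("No threshold achieves HR <= %.3g (%d candidates).\n",
                x$hr_target, nrow(x$curve)))
  } else {
    at <- which.min(abs(x$curve$threshold - x$threshold))
    cat(sprintf(
      "Threshold %.6g: HR %.3f, High fraction %.1f%% (target HR <= %.3g)\n",
      x$threshold, x$curve$hr[at], 100 * x$curve$high_fraction[at], x$hr_target
    ))
  }
  invisible(x)
}
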