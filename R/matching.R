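# Propensity-score caliper matching and balance diagnostics.
#
# Used for treatment-group comparisons confounded by indication (e.g.
# first-line monotherapy vs combination): a logistic propensity model,
# greedy 1:1 nearest-neighbor matching without replacement on the logit
# propensity scale with a 0.25-SD caliper, and post-match balance tests.

#' Fit a propensity model
#'
#' Logistic regression of the binary treatment indicator on the listed
#' covariates. Constant covariates are dropped with a warning; perfect
#' separation is an error.
#'
#' @param cohort Tibble with the treatment and covariate columns.
#' @param treatment_col Name of the binary treatment column (logical, 0/1,
#'   or two-level factor; the second level / `TRUE` / `1` is "treated").
#' @param covariates Character vector of covariate column names.
#' @return `cohort` with a `propensity` column appended (fitted treatment
#'   probability); the `glm` fit is attached as attribute `"model"`.
#' @export
fit_propensity <- function(cohort, treatment_col, covariates) {
  assert_columns(cohort, c(treatment_col, covariates), "cohort")
  tr <- as_treatment(cohort[[treatment_col]])
  keep <- covariates[vapply(covariates, function(cv) {
    v <- cohort[[cv]]
    ok <- length(unique(v)) > 1
    if (!ok) warning(sprintf("dropping constant covariate '%s'", cv))
    ok
  }, logical(1))]
  if (length(keep) == 0) {
    irs_abort("no non-constant covariates for the propensity model",
              "irscore_fitting_error")
  }
  dat <- data.frame(.treated = tr, cohort[, keep, drop = FALSE],
                    check.names = FALSE)
  fml <- stats::as.formula(
    paste(".treated ~", paste(sprintf("`%s`", keep), collapse = " + "))
  )
  fit <- stats::glm(fml, family = stats::binomial(), data = dat)
  p <- stats::fitted(fit)
  if (!fit$converged || any(p < 1e-10) || any(p > 1 - 1e-10)) {
    irs_abort("propensity model did not converge (perfect separation?)",
              "irscore_fitting_error")
  }
  out <- dplyr::mutate(cohort, propensity = unname(p))
  attr(out, "model") <- fit
  out
}

as_treatment <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (is.factor(x)) {
    if (nlevels(x) != 2) irs_abort("treatment must be binary", "irscore_usage_error")
    return(as.integer(x == levels(x)[2]))
  }
  u <- sort(unique(x))
  if (length(u) != 2) irs_abort("treatment must be binary", "irscore_usage_error")
  as.integer(x == u[2])
}

#' Greedy nearest-neighbor caliper matching
#'
#' 1:1 matching without replacement of treated to control units on the
#' logit of the propensity score (the Rosenbaum-Rubin convention; set
#' `scale = "probability"` for the raw scale). The caliper is `caliper_sd`
#' times the standard deviation of the (logit) scores over the whole
#' cohort. Treated units are processed in descending propensity order,
#' ties shuffled by `seed`; a treated unit with no unmatched control
#' within the caliper is dropped and listed, never silently discarded.
#'
#' @param cohort Tibble with a `propensity` column (from
#'   [fit_propensity()]), the treatment column, and an id column.
#' @param treatment_col Name of the binary treatment column.
#' @param id_col Name of the unit id column (default `"patient_id"`).
#' @param caliper_sd Caliper width in standard deviations (default 0.25).
#' @param scale `"logit"` (default) or `"probability"`.
#' @param seed Integer seed for tie shuffling.
#' @return An object of class `match_result`: `pairs` (tibble of
#'   treated_id, control_id, distance), `dropped_treated`,
#'   `caliper_width`, `scale`, `propensity` (named vector). [tidy()]
#'   returns the pairs.
#' @export
nn_match <- function(cohort, treatment_col, id_col = "patient_id",
                     caliper_sd = 0.25, scale = c("logit", "probability"),
                     seed = 1) {
  scale <- match.arg(scale)
  assert_columns(cohort, c(treatment_col, id_col, "propensity"), "cohort")
  stopifnot(caliper_sd > 0)
  tr <- as_treatment(cohort[[treatment_col]]) == 1L
  if (!any(tr) || all(tr)) {
    irs_abort("both arms must be non-empty", "irscore_usage_error")
  }
  sc <- cohort$propensity
  if (scale == "logit") sc <- stats::qlogis(pmin(pmax(sc, 1e-12), 1 - 1e-12))
  caliper <- caliper_sd * stats::sd(sc)
  ids <- as.character(cohort[[id_col]])

  t_idx <- which(tr)
  # descending treated propensity; ties broken by a seeded shuffle
  t_idx <- with_seed_if(seed, t_idx[order(-sc[t_idx], sample(length(t_idx)))])
  c_idx <- which(!tr)
  available <- rep(TRUE, length(c_idx))
  pairs <- vector("list", length(t_idx))
  dropped <- character(0)
  for (k in seq_along(t_idx)) {
    i <- t_idx[k]
    d <- abs(sc[c_idx] - sc[i])
    d[!available] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= caliper) {
      pairs[[k]] <- tibble::tibble(
        treated_id = ids[i], control_id = ids[c_idx[j]], distance = d[j]
      )
      available[j] <- FALSE
    } else {
      dropped <- c(dropped, ids[i])
    }
  }
  pairs <- dplyr::bind_rows(pairs)
  if (nrow(pairs) == 0) {
    irs_abort("no treated unit could be matched within the caliper",
              "irscore_matching_error")
  }
  if (length(dropped) > 0) {
    irs_log("dropped %d unmatchable treated unit(s)", length(dropped))
  }
  structure(
    list(
      pairs = pairs, dropped_treated = dropped, caliper_width = caliper,
      caliper_sd = caliper_sd, scale = scale,
      propensity = stats::setNames(cohort$propensity, ids)
    ),
    class = "match_result"
  )
}

#' @rdname nn_match
#' @param x A `match_result`.
#' @param ... Unused.
#' @export
tidy.match_result <- function(x, ...) x$pairs

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "Propensity match: %d pairs, %d treated dropped; caliper %.4f (%s scale, %.2f SD)\n",
    nrow(x$pairs), length(x$dropped_treated), x$caliper_width, x$scale, x$caliper_sd
  ))
  invisible(x)
}

#' Extract the matched cohort
#'
#' Subsets the original cohort to the units retained in the matched pairs.
#'
#' @param cohort The cohort passed to [nn_match()].
#' @param match A `match_result`.
#' @param id_col Unit id column name.
#' @return The matched subset of `cohort`.
#' @export
matched_cohort <- function(cohort, match, id_col = "patient_id") {
  keep <- c(match$pairs$treated_id, match$pairs$control_id)
  dplyr::filter(cohort, as.character(.data[[id_col]]) %in% keep)
}

#' Post-match covariate balance tests
#'
#' Two-sided t-test for each continuous covariate and two-sided Fisher's
#' exact test for each categorical covariate, comparing arms of the
#' matched cohort; covariates with p < `alpha` are flagged as imbalanced.
#'
#' @param cohort Matched cohort tibble (see [matched_cohort()]).
#' @param treatment_col Name of the binary treatment column.
#' @param covariates Character vector of covariate column names.
#' @param alpha Flagging threshold (default 0.05).
#' @return A tibble: `covariate`, `test` (`"t"` or `"fisher"`), `p_value`,
#'   `flagged`.
#' @export
balance_table <- function(cohort, treatment_col, covariates, alpha = 0.05) {
  assert_columns(cohort, c(treatment_col, covariates), "cohort")
  tr <- as_treatment(cohort[[treatment_col]]) == 1L
  rows <- purrr::map(covariates, function(cv) {
    v <- cohort[[cv]]
    if (is.numeric(v)) {
      p <- if (stats::sd(v[tr]) == 0 && stats::sd(v[!tr]) == 0 &&
               isTRUE(all.equal(mean(v[tr]), mean(v[!tr])))) {
        1  # identical degenerate arms
      } else {
        stats::t.test(v[tr], v[!tr])$p.value
      }
      tibble::tibble(covariate = cv, test = "t", p_value = p)
    } else {
      tab <- table(factor(tr, levels = c(FALSE, TRUE)), as.character(v))
      p <- stats::fisher.test(tab)$p.value
      tibble::tibble(covariate = cv, test = "fisher", p_value = p)
    }
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(flagged = .data$p_value < alpha)
}

#' Standardized mean differences between arms
#'
#' SMD = (mean treated - mean control) / pooled SD, the conventional
#' balance summary before and after matching (categorical covariates are
#' expanded to indicators).
#'
#' @inheritParams balance_table
#' @return A tibble: `covariate`, `smd`.
#' @export
standardized_differences <- function(cohort, treatment_col, covariates) {
  assert_columns(cohort, c(treatment_col, covariates), "cohort")
  tr <- as_treatment(cohort[[treatment_col]]) == 1L
  rows <- purrr::map(covariates, function(cv) {
    v <- cohort[[cv]]
    cols <- if (is.numeric(v)) stats::setNames(list(v), cv) else {
      lv <- sort(unique(as.character(v)))[-1]
      stats::setNames(lapply(lv, function(l) as.numeric(v == l)),
                      paste0(cv, "=", lv))
    }
    purrr::imap(cols, function(x, nm) {
      s <- sqrt((stats::var(x[tr]) + stats::var(x[!tr])) / 2)
      tibble::tibble(covariate = nm,
                     smd = if (s == 0) 0 else (mean(x[tr]) - mean(x[!tr])) / s)
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}
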