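spec <- load_model_spec()

feature_row <- function(TMB = 0, pd1 = 0, pdl1 = 0, adam12 = 0, top2a = 0,
                        id = "X") {
  tibble::tibble(patient_id = id, TMB = TMB, `PD-1` = pd1, `PD-L1` = pdl1,
                 ADAM12 = adam12, TOP2A = top2a)
}

test_that("the locked equation reproduces hand-evaluated scores and groups", {
  # all-zero predictor -> 0, Low
  r0 <- compute_irs(feature_row(), spec)
  expect_equal(r0$score, 0)
  expect_equal(as.character(r0$group), "Low")
  # TMB 10 Muts/Mb (log2 = 3.321928), centered expressions 0 -> High
  r1 <- compute_irs(feature_row(TMB = log2(10)), spec)
  expect_equal(r1$score, 0.273758 * log2(10), tolerance = 1e-9)
  expect_equal(r1$score, 0.909405, tolerance = 1e-5)
  expect_equal(as.character(r1$group), "High")
  # ... and additionally ADAM12 at +2 pulls it back below the threshold
  r2 <- compute_irs(feature_row(TMB = log2(10), adam12 = 2), spec)
  expect_equal(r2$score, 0.273758 * log2(10) - 2 * 0.057991, tolerance = 1e-9)
  expect_equal(as.character(r2$group), "Low")
  # raw biomarker input goes through the transforms first
  raw <- tibble::tibble(
    patient_id = "Y", tmb = 10,
    `PD-1` = spec$gene_medians[["PD-1"]], `PD-L1` = spec$gene_medians[["PD-L1"]],
    ADAM12 = spec$gene_medians[["ADAM12"]], TOP2A = spec$gene_medians[["TOP2A"]]
  )
  expect_equal(compute_irs(raw, spec)$score, 0.909405, tolerance = 1e-6)
  # missing feature errors by name
  expect_error(compute_irs(dplyr::select(feature_row(), -"ADAM12"), spec),
               "ADAM12", class = "irscore_scoring_error")
})

test_that("group assignment flips exactly at the locked threshold", {
  eps <- 1e-9
  at <- spec$threshold / spec$coefficients[["TMB"]]
  just_below <- compute_irs(feature_row(TMB = at - eps), spec)
  just_above <- compute_irs(feature_row(TMB = at), spec)
  expect_equal(as.character(just_below$group), "Low")
  expect_equal(as.character(just_above$group), "High")
})

test_that("the score is linear and monotone with the published signs", {
  withr::with_seed(5, {
    a <- feature_row(rnorm(1), rnorm(1), rnorm(1), rnorm(1), rnorm(1), id = "A")
    b <- feature_row(rnorm(1), rnorm(1), rnorm(1), rnorm(1), rnorm(1), id = "B")
  })
  avg <- a
  for (cl in c("TMB", "PD-1", "PD-L1", "ADAM12", "TOP2A")) {
    avg[[cl]] <- (a[[cl]] + b[[cl]]) / 2
  }
  expect_equal(compute_irs(avg, spec)$score,
               (compute_irs(a, spec)$score + compute_irs(b, spec)$score) / 2,
               tolerance = 1e-12)
  base <- compute_irs(feature_row(), spec)$score
  bump <- function(...) compute_irs(feature_row(...), spec)$score - base
  expect_gt(bump(TMB = 1), 0)
  expect_gt(bump(pd1 = 1), 0)
  expect_gt(bump(pdl1 = 1), 0)
  expect_lt(bump(adam12 = 1), 0)
  expect_lt(bump(top2a = 1), 0)
})

test_that("the penalty path shrinks to the empty model and drops constants", {
  cfg <- sim_config(n_patients = 400, seed = 21)
  bio <- gen_biomarkers(cfg)
  out <- gen_outcomes(bio, cfg)
  feats <- transform_biomarkers(bio, spec) |>
    dplyr::select(-"tmb_high") |>
    dplyr::mutate(flat = 1.0)
  expect_warning(
    fit <- fit_lasso_cox(out, feats, seed = 9),
    "constant"
  )
  expect_false("flat" %in% fit$selected_features)
  # the largest penalty on the path zeroes every coefficient
  expect_equal(fit$lambda_path$nonzero[1], 0)
  # refit coefficients are keyed exactly by the selected features
  expect_identical(names(fit$refit_coefficients), fit$selected_features)
  # reproducibility under the seed
  fit2 <- suppressWarnings(fit_lasso_cox(out, feats, seed = 9))
  expect_identical(fit$chosen_penalty, fit2$chosen_penalty)
  expect_identical(fit$refit_coefficients, fit2$refit_coefficients)
  expect_error(
    suppressWarnings(
      fit_lasso_cox(dplyr::mutate(out, event = FALSE), feats, seed = 1)
    ),
    class = "irscore_fitting_error"
  )
})

test_that("unpenalized refit recovers the locked coefficients on simulated data", {
  cfg <- sim_config(n_patients = 3000, seed = 31)
  bio <- gen_biomarkers(cfg)
  out <- gen_outcomes(bio, cfg)
  feats <- transform_biomarkers(bio, spec) |> dplyr::select(-"tmb_high")
  fit <- fit_lasso_cox(out, feats, seed = 31)
  td <- tidy(fit)
  for (f in names(spec$coefficients)) {
    row <- td[td$term == f, ]
    expect_equal(nrow(row), 1L)
    expect_lt(abs(row$irs_coef - spec$coefficients[[f]]), 3 * row$std_error)
  }
})

test_that("threshold selection maximizes the High fraction under the HR cap", {
  cfg <- sim_config(n_patients = 600, seed = 41)
  bio <- gen_biomarkers(cfg)
  out <- gen_outcomes(bio, cfg)
  scores <- compute_irs(bio, spec)$score
  sel <- select_threshold(scores, out, hr_target = 0.6)
  expect_false(is.na(sel$threshold))
  # exhaustive recomputation over the same grid
  grid <- unique(stats::quantile(scores, probs = seq(0.01, 0.99, 0.01),
                                 type = 7, names = FALSE))
  best_frac <- -1; best_t <- NA
  for (t in grid) {
    high <- scores >= t
    if (sum(high) < 10 || sum(!high) < 10) next
    hr <- exp(coef(survival::coxph(
      survival::Surv(out$duration_months, out$event) ~ high, ties = "efron"
    )))
    if (hr <= 0.6 && mean(high) > best_frac) {
      best_frac <- mean(high); best_t <- t
    }
  }
  expect_equal(sel$threshold, best_t)
  at <- which.min(abs(sel$curve$threshold - sel$threshold))
  expect_lte(sel$curve$hr[at], 0.6)

  # scores unrelated to outcome: no cut reaches a strong HR target
  null_scores <- withr::with_seed(7, rnorm(length(scores)))
  null_sel <- select_threshold(null_scores, out, hr_target = 0.6)
  expect_true(is.na(null_sel$threshold))
  expect_true(all(abs(log(null_sel$curve$hr)) < log(2.5)))
  # degenerate all-equal scores error
  expect_error(select_threshold(rep(1, nrow(out)), out, hr_target = 0.6),
               class = "irscore_threshold_error")
})
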