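# End-to-end reproduction of the published cohort analyses from a
# patient-level supplementary table. The patient-level discovery and
# validation data are distributed only as a supplementary file under a
# restricted data-sharing agreement, so no copy ships with the package;
# this function documents the expected layout and runs the full locked
# pipeline when a copy is supplied.

#' Reproduce the locked-model cohort analyses from patient-level data
#'
#' Expects a CSV with one row per analyzed therapy line and columns:
#' `patient_id`, `cohort` (`discovery` / `validation`), `age`, `gender`,
#' `tumor_type`, `line_number`, `therapy_type` (e.g. `PD-1` / `PD-L1` or
#' `monotherapy` / `combination`), `tmb`, nRPM columns `PD-1`, `PD-L1`,
#' `ADAM12`, `TOP2A`, and endpoint columns `rwpfs_months`, `rwpfs_event`,
#' `os_months`, `os_event`. For each cohort it applies the locked model
#' (scoring every patient and counting IRS-High), estimates Kaplan-Meier
#' median rwPFS by IRS group, fits adjusted Cox models for rwPFS and OS
#' (age, gender, line number, most-prevalent tumor type vs others, therapy
#' type), and computes the 24-month RMST of rwPFS by IRS group.
#'
#' @param path Path to the patient-level CSV described above.
#' @param spec The locked `irs_model_spec`.
#' @return A list per cohort: `n`, `n_high`, `km_median` (by IRS group),
#'   `rwpfs_ahr`, `os_ahr` (adjusted hazard ratios for High vs Low),
#'   `rmst24_high` (24-month restricted mean rwPFS, IRS-High).
#' @export
reproduce_validation_analysis <- function(path, spec = load_model_spec()) {
  if (!file.exists(path)) {
    irs_abort(sprintf(
      paste0("patient-level supplementary table not found at '%s'; ",
             "it is restricted by data-sharing agreements and must be ",
             "obtained from the study authors"), path),
      "irscore_io_error")
  }
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(dat, c("patient_id", "cohort", "age", "gender", "tumor_type",
                        "line_number", "therapy_type", "tmb",
                        names(spec$gene_medians),
                        "rwpfs_months", "rwpfs_event", "os_months", "os_event"),
                 "patient-level table")
  purrr::map(split(dat, dat$cohort), function(cd) {
    scored <- compute_irs(cd, spec)
    cd$irs_group <- scored$group
    top_type <- names(which.max(table(cd$tumor_type)))
    cd$tumor_top <- cd$tumor_type == top_type
    rw <- dplyr::transmute(
      cd, patient_id = .data$patient_id,
      duration_months = .data$rwpfs_months, event = .data$rwpfs_event,
      irs_group = .data$irs_group, age = .data$age, gender = .data$gender,
      line_number = .data$line_number, tumor_top = .data$tumor_top,
      therapy_type = .data$therapy_type
    )
    os <- dplyr::mutate(rw, duration_months = cd$os_months, event = cd$os_event)
    covs <- c("irs_group", "age", "gender", "line_number", "tumor_top",
              "therapy_type")
    km <- glance(km_estimate(rw, "irs_group"))
    rw_fit <- tidy(fit_coxph(rw, covs, cluster_col = "patient_id"))
    os_fit <- tidy(fit_coxph(os, covs, cluster_col = "patient_id"))
    r24 <- rmst(rw, tau = 24, group_col = "irs_group")
    list(
      n = nrow(cd),
      n_high = sum(cd$irs_group == "High"),
      km_median = stats::setNames(km$median, km$group),
      rwpfs_ahr = rw_fit$hazard_ratio[rw_fit$term == "irs_groupHigh"],
      os_ahr = os_fit$hazard_ratio[os_fit$term == "irs_groupHigh"],
      rmst24_high = r24$by_group$rmst[r24$by_group$group == "High"]
    )
  })
}
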