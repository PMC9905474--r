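# Biomarker normalization and transforms.
#
# Expression targets are measured in normalized reads per million (nRPM):
# raw counts are converted to per-sample RPM, then rescaled so that the
# median housekeeping gene matches its reads-per-million in a reference
# sample run alongside. Model features are log2(nRPM + 1) centered at
# frozen per-gene medians; TMB enters as log2(max(TMB, floor)) and is not
# centered.

#' Normalize raw panel counts to nRPM
#'
#' Per-sample reads per million are computed over all reads (targets plus
#' housekeeping); the scale factor is the median over housekeeping targets
#' of reference RPM / sample RPM, and nRPM = sample RPM x factor. The
#' normalization is scale-equivariant: multiplying every raw count by a
#' constant leaves nRPM unchanged.
#'
#' @param raw_counts Named numeric vector of target read counts.
#' @param housekeeping_counts Named numeric vector of housekeeping read
#'   counts (at least one positive).
#' @param reference_rpm Named numeric vector of reference RPM for the
#'   housekeeping targets (names must cover `housekeeping_counts`).
#' @return Named numeric vector of nRPM, one entry per target in
#'   `raw_counts`.
#' @export
#' @examples
#' normalize_nrpm(
#'   c(GENE1 = 500, GENE2 = 0),
#'   housekeeping_counts = c(HK1 = 1000, HK2 = 750, HK3 = 1500),
#'   reference_rpm = c(HK1 = 2000, HK2 = 1500, HK3 = 3000)
#' )
normalize_nrpm <- function(raw_counts, housekeeping_counts, reference_rpm) {
  stopifnot(length(housekeeping_counts) >= 1)
  if (all(housekeeping_counts <= 0)) {
    irs_abort("all housekeeping counts are zero; cannot normalize",
              "irscore_normalization_error")
  }
  missing_ref <- setdiff(names(housekeeping_counts), names(reference_rpm))
  if (length(missing_ref) > 0) {
    irs_abort(sprintf("reference RPM missing for housekeeping target%s: %s",
                      if (length(missing_ref) > 1) "s" else "",
                      paste(missing_ref, collapse = ", ")),
              "irscore_normalization_error")
  }
  total <- sum(raw_counts) + sum(housekeeping_counts)
  if (total <= 0) {
    irs_abort("total read count is zero", "irscore_normalization_error")
  }
  rpm <- raw_counts / total * 1e6
  hk_rpm <- housekeeping_counts / total * 1e6
  pos <- housekeeping_counts > 0
  factor <- stats::median(reference_rpm[names(housekeeping_counts)[pos]] / hk_rpm[pos])
  rpm * factor
}

#' Center log2-transformed expression at frozen gene medians
#'
#' Feature value = log2(nRPM + 1) - log2(median + 1). The +1 pseudocount
#' keeps zero measurements finite; the medians are frozen constants carried
#' by the model spec, never re-estimated per batch, so scoring is
#' deterministic per sample.
#'
#' @param nrpm Named numeric vector of nRPM values.
#' @param gene_medians Named numeric vector of frozen median nRPM; must
#'   cover every gene in `nrpm`.
#' @return Named numeric vector of centered log2 values.
#' @export
center_log2 <- function(nrpm, gene_medians) {
  missing <- setdiff(names(nrpm), names(gene_medians))
  if (length(missing) > 0) {
    irs_abort(sprintf("no centering median configured for gene%s: %s",
                      if (length(missing) > 1) "s" else "",
                      paste(missing, collapse = ", ")),
              "irscore_config_error")
  }
  if (any(gene_medians[names(nrpm)] < 0)) {
    irs_abort("gene medians must be non-negative", "irscore_config_error")
  }
  log2(nrpm + 1) - log2(gene_medians[names(nrpm)] + 1)
}

#' log2-transform tumor mutation burden
#'
#' TMB enters the model as log2(max(TMB, floor)); the floor keeps zero
#' mutation counts finite. TMB is not median-centered.
#'
#' @param tmb Numeric vector of TMB in mutations/megabase (>= 0).
#' @param floor Positive floor in Muts/Mb (default 0.5).
#' @return Numeric vector of log2 TMB.
#' @export
#' @examples
#' transform_tmb(c(0, 1, 10)) # -1, 0, 3.3219
transform_tmb <- function(tmb, floor = 0.5) {
  stopifnot(floor > 0)
  if (any(tmb < 0, na.rm = TRUE)) {
    irs_abort("TMB must be non-negative", "irscore_schema_error")
  }
  log2(pmax(tmb, floor))
}

#' Call TMB-High status
#'
#' TMB-High is TMB at or above the cutoff (default 10 Muts/Mb).
#'
#' @param tmb Numeric vector of TMB in Muts/Mb.
#' @param cutoff TMB-High cutoff in Muts/Mb.
#' @return Logical vector (`TRUE` = TMB-High).
#' @export
call_tmb_high <- function(tmb, cutoff = 10) {
  stopifnot(cutoff > 0)
  if (any(tmb < 0, na.rm = TRUE)) {
    irs_abort("TMB must be non-negative", "irscore_schema_error")
  }
  tmb >= cutoff
}

#' Transform a biomarker table into model features
#'
#' Applies [transform_tmb()] to the `tmb` column and [center_log2()] to
#' every model gene column, producing the transformed feature table the
#' scoring equation consumes (columns `TMB`, `PD-1`, `PD-L1`, `ADAM12`,
#' `TOP2A`).
#'
#' @param biomarkers Tibble with columns `patient_id`, `tmb`, and one nRPM
#'   column per model gene.
#' @param spec An `irs_model_spec` from [load_model_spec()].
#' @return Tibble of `patient_id` plus one column per transformed feature,
#'   and `tmb_high` (logical).
#' @export
transform_biomarkers <- function(biomarkers, spec = load_model_spec()) {
  genes <- names(spec$gene_medians)
  assert_columns(biomarkers, c("patient_id", "tmb", genes), "biomarkers table")
  out <- tibble::tibble(
    patient_id = biomarkers$patient_id,
    TMB = transform_tmb(biomarkers$tmb, spec$tmb_floor)
  )
  for (g in genes) {
    if (any(biomarkers[[g]] < 0, na.rm = TRUE)) {
      irs_abort(sprintf("negative nRPM in column '%s'", g), "irscore_schema_error")
    }
    out[[g]] <- as.numeric(log2(biomarkers[[g]] + 1) - log2(spec$gene_medians[[g]] + 1))
  }
  out$tmb_high <- call_tmb_high(biomarkers$tmb, spec$tmb_high_cutoff)
  out
}
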