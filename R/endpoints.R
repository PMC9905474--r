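# Survival endpoint derivation per therapy line.
#
# rwPFS is time-to-next-therapy: line start to the line's effective end.
# The effective end is the first qualifying of: death (event), start of the
# subsequent therapy line (event); otherwise last record date if the line is
# still ongoing (censored) or the latest member end date (censored).

#' Effective end date of a therapy line
#'
#' Applies the four end-date rules for a single line:
#' (a) treatment ongoing — censored at `last_record_date`;
#' (b) death — event at `death_date`;
#' (c) a subsequent therapy line exists — event at its start;
#' (d) otherwise — censored at the latest member course end date.
#' When both a death and a next line exist the earlier date wins; on a tie
#' the precedence is death > next line. "Ongoing" means no death or next
#' line exists and the line's latest member end is within `merge_gap_days`
#' of `last_record_date`.
#'
#' @param line_start Line start date.
#' @param latest_member_end Latest end date among the line's member courses.
#' @param next_line_start Start date of the patient's next line, or `NA`.
#' @param death_date Date of death, or `NA`.
#' @param last_record_date Date of last follow-up record (required).
#' @param rules A [line_rules()] object (supplies the ongoing window).
#' @return A list with elements `date`, `event` (logical), `reason`
#'   (`"ongoing"`, `"death"`, `"next_line"`, `"latest_end"`).
#' @export
#' @examples
#' d0 <- as.Date("2020-01-01")
#' effective_end(d0, d0 + 210, next_line_start = d0 + 300,
#'               death_date = d0 + 400, last_record_date = d0 + 500)
effective_end <- function(line_start, latest_member_end, next_line_start = NA,
                          death_date = NA, last_record_date,
                          rules = line_rules()) {
  if (is.na(last_record_date) || last_record_date < line_start) {
    irs_abort("last_record_date must be present and not precede the line start",
              "irscore_ordering_error")
  }
  if (!is.na(next_line_start) && next_line_start < line_start) {
    irs_abort("next line starts before the current line", "irscore_ordering_error")
  }
  if (!is.na(death_date) && death_date < line_start) {
    irs_abort("death precedes the line start", "irscore_ordering_error")
  }
  has_death <- !is.na(death_date)
  has_next <- !is.na(next_line_start)
  if (has_death || has_next) {
    # earliest qualifying event date wins; tie goes to death
    if (has_death && (!has_next || death_date <= next_line_start)) {
      return(list(date = death_date, event = TRUE, reason = "death"))
    }
    return(list(date = next_line_start, event = TRUE, reason = "next_line"))
  }
  ongoing <- !is.na(latest_member_end) &&
    as.numeric(last_record_date - latest_member_end) <= rules$merge_gap_days
  if (ongoing || is.na(latest_member_end)) {
    return(list(date = last_record_date, event = FALSE, reason = "ongoing"))
  }
  list(date = latest_member_end, event = FALSE, reason = "latest_end")
}

#' Real-world progression-free survival (time to next therapy) per line
#'
#' One record per non-adjuvant therapy line. Duration is (effective end -
#' line start) in days, reported in months (days / 30.4375). The next-line
#' rule uses the start of the patient's next line of any kind.
#'
#' @param lines Classified line tibble from [derive_lines()] /
#'   [classify_lines()].
#' @param patients Patients tibble (columns `patient_id`, `death_date`,
#'   `last_record_date`).
#' @param rules A [line_rules()] object.
#' @return A survival-record tibble: `patient_id`, `line_number`,
#'   `endpoint` (`"rwPFS"`), `duration_months`, `event`,
#'   `effective_end_reason`.
#' @export
compute_rwpfs <- function(lines, patients, rules = line_rules()) {
  assert_columns(lines, c("patient_id", "line_number", "start_date",
                          "latest_member_end", "is_adjuvant"), "lines table")
  assert_columns(patients, c("patient_id", "death_date", "last_record_date"),
                 "patients table")
  prepared <- lines |>
    dplyr::arrange(.data$patient_id, .data$line_number) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(next_line_start = dplyr::lead(.data$start_date)) |>
    dplyr::ungroup() |>
    dplyr::left_join(
      dplyr::select(patients, "patient_id", "death_date", "last_record_date"),
      by = "patient_id"
    ) |>
    dplyr::filter(!.data$is_adjuvant)
  recs <- purrr::pmap(
    list(prepared$start_date, prepared$latest_member_end,
         prepared$next_line_start, prepared$death_date,
         prepared$last_record_date),
    function(s, e, nx, dd, lr) effective_end(s, e, nx, dd, lr, rules = rules)
  )
  out <- tibble::tibble(
    patient_id = prepared$patient_id,
    line_number = prepared$line_number,
    endpoint = "rwPFS",
    duration_months = days_to_months(
      as.numeric(purrr::map_dbl(recs, ~ as.numeric(.x$date)) -
                   as.numeric(prepared$start_date))
    ),
    event = purrr::map_lgl(recs, "event"),
    effective_end_reason = purrr::map_chr(recs, "reason")
  )
  if (any(out$duration_months < 0)) {
    irs_abort("negative rwPFS duration derived; inconsistent input dates",
              "irscore_consistency_error")
  }
  out
}

#' Overall survival per line
#'
#' Duration from line start to death (event) or to the last record date
#' (censored), in months.
#'
#' @inheritParams compute_rwpfs
#' @return A survival-record tibble with `endpoint = "OS"` and
#'   `effective_end_reason` either `"death"` or `"ongoing"` (alive at last
#'   record).
#' @export
compute_os <- function(lines, patients, rules = line_rules()) {
  assert_columns(lines, c("patient_id", "line_number", "start_date", "is_adjuvant"),
                 "lines table")
  assert_columns(patients, c("patient_id", "death_date", "last_record_date"),
                 "patients table")
  prepared <- lines |>
    dplyr::filter(!.data$is_adjuvant) |>
    dplyr::left_join(
      dplyr::select(patients, "patient_id", "death_date", "last_record_date"),
      by = "patient_id"
    )
  if (any(!is.na(prepared$death_date) & prepared$death_date < prepared$start_date)) {
    irs_abort("death precedes a line start", "irscore_ordering_error")
  }
  event <- !is.na(prepared$death_date)
  end <- dplyr::if_else(event, prepared$death_date, prepared$last_record_date)
  out <- tibble::tibble(
    patient_id = prepared$patient_id,
    line_number = prepared$line_number,
    endpoint = "OS",
    duration_months = days_to_months(as.numeric(end - prepared$start_date)),
    event = event,
    effective_end_reason = dplyr::if_else(event, "death", "ongoing")
  )
  if (any(out$duration_months < 0)) {
    irs_abort("negative OS duration derived; inconsistent input dates",
              "irscore_consistency_error")
  }
  out
}
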