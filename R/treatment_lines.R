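# Line-of-therapy inference from per-dose medication records.
#
# Two stages: (1) per patient+agent, doses within the merge window collapse
# into courses with a single start and end date; (2) courses, taken in start
# order, either join the current open line or open a new one, by the
# late-start and low-overlap rules. A third pass sets classification flags
# (combination, checkpoint-inhibitor class, adjuvant).

IO_CLASSES <- c("PD-1", "PD-L1", "CTLA4")
ADJUVANT_CLASSES <- c("chemotherapy", "hormonal")

#' Line-of-therapy rule set
#'
#' The four tunable constants of the line-assignment algorithm, all in days
#' except the overlap fraction:
#' * `merge_gap_days` (90): doses of the same agent separated by at most
#'   this many days merge into one course.
#' * `new_line_delay_days` (30): a course starting strictly more than this
#'   many days after the current line's start opens a new line.
#' * `overlap_fraction_min` (0.50): a course whose overlap with the current
#'   line span, as a fraction of the course's own duration, is strictly
#'   below this opens a new line.
#' * `adjuvant_gap_days` (180): a first line of only chemo/hormonal agents
#'   ending at least this many days before the next line is adjuvant.
#'
#' @param merge_gap_days,new_line_delay_days,overlap_fraction_min,adjuvant_gap_days
#'   Rule constants; defaults as above.
#' @return An object of class `line_rules`.
#' @export
line_rules <- function(merge_gap_days = 90, new_line_delay_days = 30,
                       overlap_fraction_min = 0.50, adjuvant_gap_days = 180) {
  stopifnot(
    merge_gap_days > 0, new_line_delay_days > 0, adjuvant_gap_days > 0,
    overlap_fraction_min > 0, overlap_fraction_min <= 1
  )
  structure(
    list(
      merge_gap_days = merge_gap_days,
      new_line_delay_days = new_line_delay_days,
      overlap_fraction_min = overlap_fraction_min,
      adjuvant_gap_days = adjuvant_gap_days
    ),
    class = "line_rules"
  )
}

# duration in days counting a single-day interval as 1
interval_days <- function(start, end) {
  pmax(as.numeric(end - start) + 1, 1)
}

# days of intersection between [s1,e1] and [s2,e2]; a shared single day is 1
overlap_days <- function(s1, e1, s2, e2) {
  pmax(as.numeric(pmin(e1, e2) - pmax(s1, s2)) + 1, 0)
}

#' Merge per-dose records into treatment courses
#'
#' Per patient and agent, records are sorted by start date and consecutive
#' records merge into one course while the next record starts within
#' `merge_gap_days` of the running course's latest end (overlapping records
#' always merge; for single-day doses this is the plain gap between doses).
#' Merging never crosses agents.
#'
#' @param medications Medication tibble with columns `patient_id`, `agent`,
#'   `class`, `start_date`, `end_date` (see [read_cohort()]).
#' @param rules A [line_rules()] object.
#' @return A tibble of courses: `patient_id`, `agent`, `class`, `course_id`,
#'   `start_date`, `end_date`, `source_record_ids` (list column of input row
#'   numbers).
#' @export
merge_courses <- function(medications, rules = line_rules()) {
  assert_columns(medications, c("patient_id", "agent", "class", "start_date", "end_date"),
                 "medications table")
  if (any(medications$end_date < medications$start_date)) {
    irs_abort("medication end_date precedes start_date", "irscore_schema_error")
  }
  if (nrow(medications) == 0) {
    return(tibble::tibble(
      patient_id = character(), agent = character(), class = character(),
      course_id = integer(), start_date = as.Date(character()),
      end_date = as.Date(character()), source_record_ids = list()
    ))
  }
  meds <- medications |>
    dplyr::mutate(.record_id = dplyr::row_number()) |>
    dplyr::arrange(.data$patient_id, .data$agent, .data$start_date, .data$end_date)

  merged <- meds |>
    dplyr::group_by(.data$patient_id, .data$agent) |>
    dplyr::group_modify(function(g, key) {
      run_end <- g$end_date[1]
      grp <- integer(nrow(g))
      grp[1] <- 1L
      for (i in seq_len(nrow(g))[-1]) {
        gap <- as.numeric(g$start_date[i] - run_end)
        if (gap <= rules$merge_gap_days) {
          grp[i] <- grp[i - 1]
          run_end <- max(run_end, g$end_date[i])
        } else {
          grp[i] <- grp[i - 1] + 1L
          run_end <- g$end_date[i]
        }
      }
      g |>
        dplyr::mutate(.grp = grp) |>
        dplyr::group_by(.data$.grp) |>
        dplyr::summarise(
          class = .data$class[1],
          start_date = min(.data$start_date),
          end_date = max(.data$end_date),
          source_record_ids = list(.data$.record_id),
          .groups = "drop"
        ) |>
        dplyr::select(-".grp")
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$patient_id, .data$start_date,
                   dplyr::desc(interval_days(.data$start_date, .data$end_date)),
                   .data$agent) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(course_id = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", "agent", "class", "course_id",
                  "start_date", "end_date", "source_record_ids")
  merged
}

#' Assign treatment courses to non-overlapping lines of therapy
#'
#' Courses are processed per patient in start-date order (ties: longer
#' course first, then agent name). Each course joins the current open line
#' unless it starts strictly more than `new_line_delay_days` after the
#' line's start, or its overlap with the line span — intersection days over
#' the course's own duration (a shared single day counts as 1, minimum
#' duration 1 day) — is strictly below `overlap_fraction_min`; either
#' condition opens a new line. The line span grows to cover its members.
#'
#' @param courses Course tibble from [merge_courses()].
#' @param rules A [line_rules()] object.
#' @return A tibble of lines: `patient_id`, `line_number`, `start_date`,
#'   `latest_member_end`, `n_courses`, `agents`, `classes`, `course_ids`
#'   (list columns). The per-course audit trail (which rule fired) is
#'   attached as attribute `"audit"` and via [line_audit()].
#' @export
assign_lines <- function(courses, rules = line_rules()) {
  assert_columns(courses, c("patient_id", "agent", "class", "start_date", "end_date"),
                 "courses table")
  if (nrow(courses) == 0) {
    out <- tibble::tibble(
      patient_id = character(), line_number = integer(),
      start_date = as.Date(character()), latest_member_end = as.Date(character()),
      n_courses = integer(), agents = list(), classes = list(), course_ids = list()
    )
    attr(out, "audit") <- tibble::tibble(
      patient_id = character(), agent = character(),
      start_date = as.Date(character()), end_date = as.Date(character()),
      line_number = integer(), rule = character()
    )
    return(out)
  }
  per_patient <- courses |>
    dplyr::mutate(.cid = if ("course_id" %in% names(courses)) .data$course_id else dplyr::row_number()) |>
    dplyr::arrange(.data$patient_id, .data$start_date,
                   dplyr::desc(interval_days(.data$start_date, .data$end_date)),
                   .data$agent) |>
    dplyr::group_split(.data$patient_id)

  res <- purrr::map(per_patient, function(g) {
    n <- nrow(g)
    line_no <- integer(n)
    rule <- character(n)
    line_no[1] <- 1L
    rule[1] <- "opened_first_line"
    line_start <- g$start_date[1]
    line_end <- g$end_date[1]
    for (i in seq_len(n)[-1]) {
      late <- as.numeric(g$start_date[i] - line_start) > rules$new_line_delay_days
      frac <- overlap_days(line_start, line_end, g$start_date[i], g$end_date[i]) /
        interval_days(g$start_date[i], g$end_date[i])
      if (late) {
        line_no[i] <- line_no[i - 1] + 1L
        rule[i] <- "new_line_late_start"
        line_start <- g$start_date[i]
        line_end <- g$end_date[i]
      } else if (frac < rules$overlap_fraction_min) {
        line_no[i] <- line_no[i - 1] + 1L
        rule[i] <- "new_line_low_overlap"
        line_start <- g$start_date[i]
        line_end <- g$end_date[i]
      } else {
        line_no[i] <- line_no[i - 1]
        rule[i] <- "joined_line"
        line_end <- max(line_end, g$end_date[i])
      }
    }
    audit <- tibble::tibble(
      patient_id = g$patient_id, agent = g$agent,
      start_date = g$start_date, end_date = g$end_date,
      line_number = line_no, rule = rule
    )
    lines <- g |>
      dplyr::mutate(line_number = line_no) |>
      dplyr::group_by(.data$patient_id, .data$line_number) |>
      dplyr::summarise(
        start_date = min(.data$start_date),
        latest_member_end = max(.data$end_date),
        n_courses = dplyr::n(),
        agents = list(.data$agent),
        classes = list(.data$class),
        course_ids = list(.data$.cid),
        .groups = "drop"
      )
    list(lines = lines, audit = audit)
  })
  out <- dplyr::bind_rows(purrr::map(res, "lines"))
  attr(out, "audit") <- dplyr::bind_rows(purrr::map(res, "audit"))
  out
}

#' Retrieve the line-assignment audit trail
#'
#' @param lines Result of [assign_lines()] or [derive_lines()].
#' @return Tibble with one row per course and the rule that placed it.
#' @export
line_audit <- function(lines) {
  a <- attr(lines, "audit")
  if (is.null(a)) {
    irs_abort("no audit trail attached; pass the result of assign_lines()",
              "irscore_usage_error")
  }
  a
}

#' Classify therapy lines
#'
#' Sets, per line:
#' * `is_combination`: more than one distinct agent among member courses;
#' * `io_class`: checkpoint-inhibitor exposure — `none`, `PD-1`, `PD-L1`,
#'   `CTLA4`, or `mixed` when members span several of these classes;
#' * `is_adjuvant`: a patient's first line consisting only of chemotherapy
#'   and/or hormonal agents that concluded at least `adjuvant_gap_days`
#'   before the next line's start. Adjuvant lines are retained but flagged,
#'   and `systemic_line_number` skips them (it is `NA` for the adjuvant
#'   line itself).
#'
#' @param lines Line tibble from [assign_lines()].
#' @param rules A [line_rules()] object.
#' @return `lines` with columns `is_combination`, `io_class`, `is_adjuvant`,
#'   `systemic_line_number` added.
#' @export
classify_lines <- function(lines, rules = line_rules()) {
  assert_columns(lines, c("patient_id", "line_number", "start_date",
                          "latest_member_end", "agents", "classes"), "lines table")
  audit <- attr(lines, "audit")
  out <- lines |>
    dplyr::arrange(.data$patient_id, .data$line_number) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(
      next_line_start = dplyr::lead(.data$start_date),
      is_combination = purrr::map_int(.data$agents, dplyr::n_distinct) > 1L,
      io_class = purrr::map_chr(.data$classes, function(cl) {
        io <- intersect(unique(cl), IO_CLASSES)
        if (length(io) == 0) "none" else if (length(io) == 1) io else "mixed"
      }),
      is_adjuvant = .data$line_number == 1L &
        purrr::map_lgl(.data$classes, ~ all(.x %in% ADJUVANT_CLASSES)) &
        !is.na(.data$next_line_start) &
        as.numeric(.data$next_line_start - .data$latest_member_end) >= rules$adjuvant_gap_days,
      systemic_line_number = dplyr::if_else(
        .data$is_adjuvant, NA_integer_, cumsum(!.data$is_adjuvant)
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"next_line_start")
  attr(out, "audit") <- audit
  out
}

#' Derive classified therapy lines from medication records
#'
#' Convenience pipeline: [merge_courses()] then [assign_lines()] then
#' [classify_lines()].
#'
#' @inheritParams merge_courses
#' @return Classified line tibble (see [classify_lines()]); audit trail
#'   attached.
#' @export
#' @examples
#' meds <- tibble::tibble(
#'   patient_id = "P1", agent = "pembrolizumab", class = "PD-1",
#'   start_date = as.Date("2020-01-01") + c(0, 21, 42),
#'   end_date = as.Date("2020-01-01") + c(0, 21, 42)
#' )
#' derive_lines(meds)
derive_lines <- function(medications, rules = line_rules()) {
  medications |>
    merge_courses(rules) |>
    assign_lines(rules) |>
    classify_lines(rules)
}
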