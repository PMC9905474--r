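test_that("doses merge into courses by the 90-day rule (boundary inclusive)", {
  # single dose
  one <- merge_courses(make_meds("drugA", 0))
  expect_equal(nrow(one), 1L)
  expect_equal(as.numeric(one$start_date - D0), 0)
  expect_equal(as.numeric(one$end_date - D0), 0)
  # days 0, 60, 200: gap 140 > 90 splits
  split <- merge_courses(make_meds("drugA", c(0, 60, 200)))
  expect_equal(nrow(split), 2L)
  expect_equal(as.numeric(split$start_date - D0), c(0, 200))
  expect_equal(as.numeric(split$end_date - D0), c(60, 200))
  # days 0, 90: gap exactly 90 merges
  merged <- merge_courses(make_meds("drugA", c(0, 90)))
  expect_equal(nrow(merged), 1L)
  expect_equal(as.numeric(merged$end_date - D0), 90)
  # merging never crosses agents
  two_agents <- merge_courses(
    dplyr::bind_rows(make_meds("drugA", 0), make_meds("drugB", 10))
  )
  expect_equal(nrow(two_agents), 2L)
})

test_that("courses join or open lines per the 30-day and 50%-overlap rules", {
  # single course -> one line
  l1 <- assign_lines(merge_courses(make_meds("drugA", 0, 100)))
  expect_equal(l1$line_number, 1L)
  # A [0,180], B [20,150]: B starts within 30 d, fully nested -> one line
  comb <- derive_lines(dplyr::bind_rows(
    make_meds("drugA", 0, 180), make_meds("drugB", 20, 150)
  ))
  expect_equal(nrow(comb), 1L)
  expect_true(comb$is_combination)
  # A [0,100], B [40,300]: B starts day 40 > 30 -> two lines
  two <- assign_lines(merge_courses(dplyr::bind_rows(
    make_meds("drugA", 0, 100), make_meds("drugB", 40, 300)
  )))
  expect_equal(nrow(two), 2L)
  expect_equal(line_audit(two)$rule,
               c("opened_first_line", "new_line_late_start"))
  # low overlap fires when the late-start rule does not:
  # A [0,10], B [25,300]: B starts day 25 <= 30 but overlap 0 < 50%
  low <- assign_lines(merge_courses(dplyr::bind_rows(
    make_meds("drugA", 0, 10), make_meds("drugB", 25, 300)
  )))
  expect_equal(nrow(low), 2L)
  expect_equal(line_audit(low)$rule[2], "new_line_low_overlap")
})

test_that("classification flags combination, IO class and adjuvant lines", {
  mono <- derive_lines(make_meds("pembrolizumab", c(0, 21, 42), class = "PD-1"))
  expect_false(mono$is_combination)
  expect_equal(mono$io_class, "PD-1")
  expect_false(mono$is_adjuvant)

  combo <- derive_lines(dplyr::bind_rows(
    make_meds("pembrolizumab", c(0, 21), class = "PD-1"),
    make_meds("carboplatin", c(0, 21), class = "chemotherapy")
  ))
  expect_true(combo$is_combination)
  expect_equal(combo$io_class, "PD-1")

  # first-line chemo ending day 100, next line day 290: gap 190 >= 180
  adj <- derive_lines(dplyr::bind_rows(
    make_meds("carboplatin", c(0, 80), c(0, 100), class = "chemotherapy"),
    make_meds("pembrolizumab", 290, class = "PD-1")
  ))
  expect_equal(adj$is_adjuvant, c(TRUE, FALSE))
  expect_equal(adj$systemic_line_number, c(NA_integer_, 1L))
  # gap 170 < 180: not adjuvant
  nadj <- derive_lines(dplyr::bind_rows(
    make_meds("carboplatin", c(0, 80), c(0, 100), class = "chemotherapy"),
    make_meds("pembrolizumab", 270, class = "PD-1")
  ))
  expect_equal(nadj$is_adjuvant, c(FALSE, FALSE))
  # IO class is mixed when PD-1 and CTLA4 share a line
  mixed <- derive_lines(dplyr::bind_rows(
    make_meds("nivolumab", 0, class = "PD-1"),
    make_meds("ipilimumab", 0, class = "CTLA4")
  ))
  expect_equal(mixed$io_class, "mixed")
})

test_that("line assignment partitions courses and ignores input row order", {
  meds <- dplyr::bind_rows(
    make_meds("drugA", c(0, 30, 200), c(5, 35, 240)),
    make_meds("drugB", c(10, 210), c(60, 260)),
    make_meds("drugC", 400, 430)
  )
  ref <- derive_lines(meds)
  # every course in exactly one line
  expect_equal(sum(ref$n_courses), nrow(merge_courses(meds)))
  ids <- sort(unlist(ref$course_ids))
  expect_equal(ids, seq_along(ids))
  for (seed in 1:5) {
    perm <- withr::with_seed(seed, meds[sample(nrow(meds)), ])
    got <- derive_lines(perm)
    expect_equal(
      dplyr::select(got, -"course_ids"), dplyr::select(ref, -"course_ids")
    )
  }
})

test_that("re-running assignment on its own line spans is idempotent", {
  meds <- dplyr::bind_rows(
    make_meds("drugA", c(0, 40, 300), c(20, 80, 350)),
    make_meds("drugB", c(45, 305), c(100, 330))
  )
  lines1 <- assign_lines(merge_courses(meds))
  # treat each line span as a single course and re-assign
  implied <- tibble::tibble(
    patient_id = lines1$patient_id,
    agent = paste0("line", lines1$line_number),
    class = "chemotherapy",
    start_date = lines1$start_date,
    end_date = lines1$latest_member_end
  )
  lines2 <- assign_lines(implied)
  expect_equal(nrow(lines2), nrow(lines1))
  expect_equal(lines2$start_date, lines1$start_date)
  expect_equal(lines2$latest_member_end, lines1$latest_member_end)
})

test_that("production line assignment agrees with the brute-force oracle", {
  starts <- c(0, 20, 45, 120, 250)
  durs <- c(0, 40, 150)
  grid <- expand.grid(s = starts, d = durs)
  ivs <- data.frame(s = grid$s, e = grid$s + grid$d)
  # all ordered pairs, same and different agents
  for (i in seq_len(nrow(ivs))) {
    for (j in seq_len(nrow(ivs))) {
      for (agents in list(c("a", "a"), c("a", "b"))) {
        s <- c(ivs$s[i], ivs$s[j]); e <- c(ivs$e[i], ivs$e[j])
        got <- production_lines(agents, s, e)
        want <- oracle_lines(agents, s, e)
        expect_equal(got, want, info = sprintf(
          "agents=%s s=%s e=%s", paste(agents, collapse = ","),
          paste(s, collapse = ","), paste(e, collapse = ",")
        ))
      }
    }
  }
  # random 3-course histories
  withr::with_seed(42, {
    for (rep in 1:60) {
      k <- sample(2:4, 1)
      s <- sample(seq(0, 400, by = 5), k, replace = TRUE)
      e <- s + sample(c(0, 20, 60, 120), k, replace = TRUE)
      agents <- sample(letters[1:3], k, replace = TRUE)
      expect_equal(production_lines(agents, s, e), oracle_lines(agents, s, e))
    }
  })
})
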