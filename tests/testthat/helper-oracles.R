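# Shared fixtures and independent reference implementations used as oracles.

D0 <- as.Date("2020-01-01")

# quick builder for dose-level medication records (days relative to D0)
make_meds <- function(agent, start_days, end_days = start_days,
                      class = "chemotherapy", patient_id = "P1") {
  tibble::tibble(
    patient_id = patient_id, agent = agent, class = class,
    start_date = D0 + start_days, end_date = D0 + end_days
  )
}

make_patients <- function(patient_id = "P1", death_day = NA,
                          last_record_day = 1000) {
  tibble::tibble(
    patient_id = patient_id, age = 65, gender = "F", tumor_type = "NSCLC",
    death_date = if (is.na(death_day)) as.Date(NA) else D0 + death_day,
    last_record_date = D0 + last_record_day
  )
}

# Brute-force reference implementation of the course-merging and
# line-assignment rules, written as plain loops over integer day grids and
# kept independent of the production (grouped/vectorized) path.
oracle_lines <- function(agent, start, end) {
  stopifnot(length(agent) == length(start), length(end) == length(start))
  # stage 1: merge per agent, sorted by start; gap measured from running end
  courses <- list()
  for (a in unique(agent)) {
    idx <- which(agent == a)
    idx <- idx[order(start[idx], end[idx])]
    cs <- start[idx[1]]; ce <- end[idx[1]]
    for (i in idx[-1]) {
      if (start[i] - ce <= 90) {
        ce <- max(ce, end[i])
      } else {
        courses[[length(courses) + 1]] <- list(agent = a, start = cs, end = ce)
        cs <- start[i]; ce <- end[i]
      }
    }
    courses[[length(courses) + 1]] <- list(agent = a, start = cs, end = ce)
  }
  # stage 2: order by start, longer first, then agent name
  starts <- vapply(courses, `[[`, numeric(1), "start")
  ends <- vapply(courses, `[[`, numeric(1), "end")
  agents <- vapply(courses, `[[`, character(1), "agent")
  dur <- pmax(ends - starts + 1, 1)
  o <- order(starts, -dur, agents)
  starts <- starts[o]; ends <- ends[o]; agents <- agents[o]
  line_of <- integer(length(o))
  line_of[1] <- 1L
  ls <- starts[1]; le <- ends[1]
  for (i in seq_along(o)[-1]) {
    ov <- max(min(le, ends[i]) - max(ls, starts[i]) + 1, 0)
    frac <- ov / max(ends[i] - starts[i] + 1, 1)
    if (starts[i] - ls > 30 || frac < 0.5) {
      line_of[i] <- line_of[i - 1] + 1L
      ls <- starts[i]; le <- ends[i]
    } else {
      line_of[i] <- line_of[i - 1]
      le <- max(le, ends[i])
    }
  }
  data.frame(agent = agents, start = starts, end = ends, line = line_of)
}

# production path on the same history, reduced to the oracle's shape
production_lines <- function(agent, start, end) {
  meds <- make_meds(agent, start, end)
  lines <- assign_lines(merge_courses(meds))
  audit <- line_audit(lines)
  data.frame(
    agent = audit$agent,
    start = as.numeric(audit$start_date - D0),
    end = as.numeric(audit$end_date - D0),
    line = audit$line_number
  )
}

# two-sided Fisher exact p for a 2x2 table by direct hypergeometric
# enumeration (sum of all table probabilities <= observed probability)
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  prob <- function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }
  p_obs <- prob(a)
  xs <- max(0, k - n):min(k, m)
  sum(vapply(xs, prob, numeric(1))[vapply(xs, prob, numeric(1)) <= p_obs * (1 + 1e-7)])
}

# exponential survival records for closed-form checks
exp_records <- function(n, rate, cens = Inf) {
  t <- stats::rexp(n, rate)
  ctime <- if (is.finite(cens)) rep(cens, n) else rep(Inf, n)
  tibble::tibble(
    patient_id = sprintf("S%05d", seq_len(n)),
    duration_months = pmin(t, ctime),
    event = t <= ctime
  )
}
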