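rec <- function(time, event, ...) {
  tibble::tibble(patient_id = sprintf("R%03d", seq_along(time)),
                 duration_months = time, event = event, ...)
}

test_that("Kaplan-Meier reproduces hand product-limit values", {
  # no events -> flat curve, unbounded median
  flat <- km_estimate(rec(c(5, 8, 12), c(FALSE, FALSE, FALSE)))
  expect_true(all(tidy(flat)$survival == 1))
  expect_true(is.na(glance(flat)$median))
  # three events at 1, 2, 3 -> steps 2/3, 1/3, 0; median 2
  km <- km_estimate(rec(1:3, rep(TRUE, 3)))
  expect_equal(tidy(km)$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(glance(km)$median, 2)
  # without censoring KM equals the empirical survival function
  withr::with_seed(2, t <- rexp(200, 0.2))
  km2 <- tidy(km_estimate(rec(t, rep(TRUE, 200))))
  emp <- vapply(km2$time, function(x) mean(t > x), numeric(1))
  expect_equal(km2$survival, emp, tolerance = 1e-12)
})

test_that("KM median approaches the exponential closed form", {
  withr::with_seed(3, r <- exp_records(10000, rate = 0.1))
  km <- km_estimate(r)
  expect_equal(glance(km)$median, log(2) / 0.1, tolerance = 0.04)
})

test_that("log-rank matches the hand observed-minus-expected computation", {
  # identical groups -> statistic 0, p 1
  same <- rec(c(1, 2, 3, 1, 2, 3), rep(TRUE, 6),
              grp = rep(c("a", "b"), each = 3))
  lr0 <- logrank_test(same, "grp")
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)
  # A = {1, 2} events, B = {3, 4} events:
  # O_A = 2, E_A = 1/2 + 1/3 = 5/6, V = 1/4 + 2/9 = 17/36
  # chi-square = (2 - 5/6)^2 / (17/36) = 2.882353
  ab <- rec(c(1, 2, 3, 4), rep(TRUE, 4), grp = c("A", "A", "B", "B"))
  lr <- logrank_test(ab, "grp")
  expect_equal(lr$statistic, (2 - 5 / 6)^2 / (17 / 36), tolerance = 1e-9)
  expect_equal(lr$df, 1)
})

test_that("Cox fits recover known hazard structure with Efron ties", {
  withr::with_seed(4, {
    n <- 4000
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.1 * 2^x)
    r <- rec(t, rep(TRUE, n), x = x)
  })
  fit <- fit_coxph(r, "x")
  td <- tidy(fit)
  # HR within 3 SE of the true rate ratio 2
  expect_lt(abs(td$estimate - log(2)), 3 * td$std_error)
  expect_equal(td$hazard_ratio, exp(td$estimate), tolerance = 1e-12)
  g <- glance(fit)
  expect_equal(g$n, n)
  expect_equal(g$tie_method, "efron")
  expect_gt(g$concordance, 0.5)
  # null covariate: HR ~ 1
  withr::with_seed(5, r$z <- rnorm(n))
  tdz <- tidy(fit_coxph(r, "z"))
  expect_lt(abs(tdz$estimate), 3 * tdz$std_error)
})

test_that("clustered fits report robust standard errors", {
  withr::with_seed(6, {
    n <- 300
    id <- rep(sprintf("C%03d", 1:150), each = 2)
    frail <- rep(rexp(150), each = 2)
    x <- rnorm(n)
    t <- rexp(n, 0.1 * frail)
    r <- tibble::tibble(patient_id = id, duration_months = t,
                        event = TRUE, x = x)
  })
  td <- tidy(fit_coxph(r, "x", cluster_col = "patient_id"))
  expect_false(is.na(td$robust_se))
  expect_gt(td$robust_se, 0)
})

test_that("log-rank and the Cox score view of a two-group contrast agree", {
  # on tie-free data the two-group log-rank equals the Cox score test
  withr::with_seed(7, {
    t <- c(rexp(60, 0.1), rexp(60, 0.15))
    r <- rec(t, rep(TRUE, 120), grp = rep(c("a", "b"), each = 60))
  })
  lr <- logrank_test(r, "grp")
  sc <- survival::coxph(
    survival::Surv(r$duration_months, r$event) ~ r$grp, ties = "breslow"
  )$score
  expect_equal(lr$statistic, unname(sc), tolerance = 1e-6)
})

test_that("Schoenfeld diagnostics have the right shape and detect reversal", {
  withr::with_seed(8, {
    n <- 500
    x <- rnorm(n)
    r <- rec(rexp(n, 0.1 * exp(0.4 * x)), rep(TRUE, n), x = x)
  })
  ph <- check_ph(fit_coxph(r, "x"))
  expect_equal(ph$term, c("x", "GLOBAL"))
  expect_equal(ph$df, c(1, 1))  # single covariate: global df = 1
  expect_gt(ph$p_value[2], 0.001)  # PH holds here
  # an effect that reverses over time violates PH detectably
  withr::with_seed(9, {
    n <- 800
    x <- rbinom(n, 1, 0.5)
    t1 <- rexp(n, 0.3 * exp(+1.2 * x))   # early: harmful
    t2 <- 3 + rexp(n, 0.3 * exp(-1.2 * x)) # late: protective
    t <- ifelse(t1 < 3, t1, t2)
    r2 <- rec(t, rep(TRUE, n), x = x)
  })
  ph2 <- check_ph(fit_coxph(r2, "x"))
  expect_lt(ph2$p_value[2], 0.01)
})

test_that("RMST matches tau with no events and the exponential closed form", {
  none <- rmst(rec(c(30, 40, 50), rep(FALSE, 3)), tau = 24)
  expect_equal(none$by_group$rmst, 24)
  withr::with_seed(10, r <- exp_records(10000, rate = 0.1, cens = 40))
  est <- rmst(r, tau = 12)
  expect_equal(est$by_group$rmst, (1 - exp(-0.1 * 12)) / 0.1, tolerance = 0.02)
  expect_error(rmst(rec(c(5, 6), c(TRUE, TRUE)), tau = 24), "tau",
               class = "irscore_usage_error")
})

test_that("adjusted RMST difference tracks the unadjusted one under no confounding", {
  withr::with_seed(11, {
    n <- 400
    grp <- rep(c("ctl", "trt"), each = n / 2)
    t <- rexp(n, ifelse(grp == "trt", 0.05, 0.1))
    r <- tibble::tibble(
      patient_id = sprintf("R%03d", 1:n),
      duration_months = pmin(t, 30), event = t <= 30,
      grp = grp, age = rnorm(n, 65, 8)
    )
  })
  un <- rmst(r, tau = 24, group_col = "grp")
  ad <- rmst(r, tau = 24, group_col = "grp", covariates = "age")
  expect_true(ad$adjusted)
  expect_equal(ad$difference$estimate, un$difference$estimate, tolerance = 0.35)
  expect_gt(ad$difference$estimate, 0)
})

test_that("the interaction LRT is zero for forced-equal models and df = 1", {
  withr::with_seed(12, {
    n <- 200
    marker <- rep(rbinom(n / 2, 1, 0.5), each = 2)
    treat <- rep(c(0, 1), n / 2)
    id <- rep(sprintf("P%03d", 1:(n / 2)), each = 2)
    t <- rexp(n, 0.1)
    r <- tibble::tibble(patient_id = id, duration_months = t, event = TRUE,
                        treat = treat, marker = marker)
  })
  res <- lrt_interaction(r, "treat", "marker")
  expect_equal(res$df, 1)  # binary x binary
  expect_gte(res$statistic, 0)
  expect_true(res$p_value <= 1 && res$p_value >= 0)
  # interaction coefficient forced to zero (constant marker): full = reduced
  same <- suppressWarnings(lrt_interaction(
    dplyr::mutate(r, marker = 0L * marker), "treat", "marker"
  ))
  # marker constant -> interaction column constant -> statistic 0
  expect_equal(same$statistic, 0, tolerance = 1e-8)
  expect_equal(same$p_value, 1, tolerance = 1e-8)
})

test_that("the Schoenfeld power formula matches its published design point", {
  # n = 180, HR 0.5, 1:1, 50% events, alpha 0.05 -> ~90% power
  pw <- power_cox(hazard_ratio = 0.5, n = 180, event_rate = 0.5)
  expect_equal(pw$power, 0.9, tolerance = 0.01)
  expect_equal(pw$n_events, 90)
  # HR 1 degenerates to alpha with a warning
  expect_warning(p1 <- power_cox(hazard_ratio = 1, n = 180, event_rate = 0.5))
  expect_equal(p1$power, 0.05)
  # solving for n inverts solving for power
  n_needed <- power_cox(hazard_ratio = 0.5, power = 0.9, event_rate = 0.5)$n
  expect_equal(power_cox(hazard_ratio = 0.5, n = n_needed,
                         event_rate = 0.5)$power, 0.9, tolerance = 1e-9)
  # monotone in n and |log HR|
  ns <- c(60, 120, 180, 240)
  pws <- vapply(ns, function(n) power_cox(0.5, n = n, event_rate = 0.5)$power,
                numeric(1))
  expect_true(all(diff(pws) > 0))
  hrs <- c(0.8, 0.65, 0.5, 0.35)
  pwh <- vapply(hrs, function(h) power_cox(h, n = 180, event_rate = 0.5)$power,
                numeric(1))
  expect_true(all(diff(pwh) > 0))
})

test_that("Spearman correlation matches the hand rank formula and validates input", {
  x <- c(3, 1, 4, 1, 5)
  y <- c(2, 7, 1, 8, 2)
  # brute-force rank formula with average ranks for ties
  rx <- rank(x); ry <- rank(y)
  hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_corr(x, y), hand, tolerance = 1e-12)
  expect_equal(spearman_corr(1:10, (1:10)^3), 1)
  expect_equal(spearman_corr(1:10, -(1:10)), -1)
  expect_error(spearman_corr(rep(1, 5), 1:5), class = "irscore_usage_error")
})

test_that("BH adjustment never decreases p-values and preserves order", {
  withr::with_seed(13, p <- runif(50)^2)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_equal(order(adj[order(p)]), seq_along(p))
  expect_equal(adj, p.adjust(p, method = "BH"))
})

test_that("Cox partial likelihood is invariant to positive time rescaling", {
  withr::with_seed(14, {
    n <- 200
    x <- rnorm(n)
    r <- rec(rexp(n, 0.1 * exp(0.3 * x)), rep(TRUE, n), x = x)
  })
  f1 <- glance(fit_coxph(r, "x"))
  r2 <- dplyr::mutate(r, duration_months = duration_months * 7.3)
  f2 <- glance(fit_coxph(r2, "x"))
  expect_equal(f1$partial_log_likelihood, f2$partial_log_likelihood,
               tolerance = 1e-8)
})
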