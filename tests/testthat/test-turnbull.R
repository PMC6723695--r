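test_that("innermost intervals match hand and brute-force enumeration", {
  o1 <- event_observations(0, "interval", left = c(0, 0), right = c(1, 1))
  expect_equal(innermost_intervals(o1), data.frame(left = 0, right = 1))

  o2 <- event_observations(0, "interval", left = c(1, 2), right = c(3, 4))
  expect_equal(innermost_intervals(o2), data.frame(left = 2, right = 3))

  # exact + interval + right-censored + truncation, against brute force
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:9, 1)
    kind <- sample(c("exact", "interval", "right_censored"), n, TRUE)
    left <- sample(1:10, n, TRUE)
    right <- ifelse(kind == "exact", left,
                    ifelse(kind == "interval", left + sample(1:4, n, TRUE), Inf))
    entry <- ifelse(runif(n) < 0.3, pmax(0, left - sample(1:3, n, TRUE)), 0)
    obs <- event_observations(entry, kind, left, right)
    got <- innermost_intervals(obs)
    want <- brute_innermost(obs)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$right, want$right)
    expect_equal(got$left, want$left, tolerance = 1e-6)
  }
})

test_that("right-censored-only data put all mass beyond the last censoring age", {
  obs <- event_observations(0, "right_censored", left = c(50, 60, 70),
                            right = Inf)
  fit <- turnbull(obs)
  expect_equal(nrow(fit$support), 1L)
  expect_equal(fit$support$left, 70)
  expect_equal(fit$support$right, Inf)
  expect_equal(fit$support$mass, 1)
})

test_that("exact untruncated times give the empirical distribution", {
  tt <- c(3, 3, 5, 8, 8, 8)
  obs <- event_observations(0, "exact", left = tt, right = tt)
  fit <- turnbull(obs)
  expect_equal(fit$support$right, c(3, 5, 8))
  expect_equal(fit$support$mass, c(2, 1, 3) / 6, tolerance = 1e-9)
})

test_that("with events and right censoring only, the NPMLE equals Kaplan-Meier", {
  set.seed(7)
  n <- 120
  tt <- rweibull(n, 2, 60)
  cc <- runif(n, 20, 90)
  ev <- tt <= cc
  obs <- event_observations(0, ifelse(ev, "exact", "right_censored"),
                            left = ifelse(ev, tt, cc),
                            right = ifelse(ev, tt, Inf))
  fit <- turnbull(obs, tol = 1e-12, max_iter = 1e5)
  km <- survival::survfit(survival::Surv(pmin(tt, cc), ev) ~ 1)
  et <- km$time[km$n.event > 0]
  expect_lt(max(abs(predict(fit, et)$surv -
                    summary(km, times = et)$surv)), 1e-6)
})

test_that("EM log-likelihood is non-decreasing and matches a grid oracle", {
  # two innermost intervals: fine 1-d grid over the simplex
  obs <- event_observations(
    0, rep("interval", 10),
    left = c(1, 1, 1, 1, 2, 2, 2, 2, 1, 1),
    right = c(2, 2, 2, 2, 4, 4, 4, 4, 4, 4))
  fit <- turnbull(obs, tol = 1e-12, max_iter = 1e5)
  expect_true(all(diff(fit$loglik_trace) > -1e-10))
  iv <- innermost_intervals(obs)
  expect_equal(nrow(iv), 2L)
  # brute force: mass p on first interval; count subjects covering each
  A <- cbind(obs$left < iv$right[1] & obs$right >= iv$right[1],
             obs$left < iv$right[2] & obs$right >= iv$right[2])
  p <- seq(1e-6, 1 - 1e-6, by = 1e-5)
  ll <- vapply(p, function(pp)
    sum(log(A %*% c(pp, 1 - pp))), numeric(1))
  expect_lt(abs(fit$loglik - max(ll)), 1e-4)

  # three innermost intervals with truncation: two-stage grid refinement
  obs2 <- event_observations(
    entry_age = c(0, 0, 1, 1, 0, 2, 0, 0, 1, 0),
    kind = c("interval", "interval", "interval", "exact", "interval",
             "right_censored", "interval", "exact", "interval", "interval"),
    left = c(1, 2, 3, 5, 1, 6, 2, 5, 3, 1),
    right = c(3, 5, 5, 5, 5, Inf, 3, 5, 6, 3))
  fit2 <- turnbull(obs2, tol = 1e-12, max_iter = 1e5)
  expect_true(all(diff(fit2$loglik_trace) > -1e-10))
  iv2 <- turnbull(obs2)$support
  K <- nrow(iv2)
  tb_ll <- function(s) {
    enc <- curemr:::.tb_encode(obs2)
    ivc <- curemr:::.tb_innermost(enc)
    A <- outer(enc$lcode, ivc$lcode, `<=`) & outer(enc$rcode, ivc$rcode, `>=`)
    H <- outer(enc$ecode, ivc$lcode, `<=`)
    sum(log(A %*% s)) - sum(log(H %*% s))
  }
  grid_opt <- function(center, width, step) {
    best <- -Inf; arg <- NULL
    v1 <- seq(max(center[1] - width, 1e-9), min(center[1] + width, 1), by = step)
    v2 <- seq(max(center[2] - width, 1e-9), min(center[2] + width, 1), by = step)
    for (a in v1) for (b in v2) {
      if (a + b >= 1 - 1e-9) next
      val <- tb_ll(c(a, b, 1 - a - b))
      if (val > best) { best <- val; arg <- c(a, b) }
    }
    list(best = best, arg = arg)
  }
  g1 <- grid_opt(c(0.4, 0.3), 0.4, 0.02)
  g2 <- grid_opt(g1$arg, 0.02, 5e-4)
  g3 <- grid_opt(g2$arg, 5e-4, 2e-5)
  expect_equal(K, 3L)
  expect_lt(abs(fit2$loglik - g3$best), 1e-4)
  expect_gte(fit2$loglik, g3$best - 1e-6)
})

test_that("left truncation is handled: estimate matches the conditional truth", {
  set.seed(11)
  n <- 2500
  t <- round(rweibull(n, 2, 60))
  a <- round(runif(n, 20, 50))
  keep <- t > a
  obs <- event_observations(entry_age = a[keep], kind = "exact",
                            left = t[keep], right = t[keep])
  fit <- turnbull(obs, tol = 1e-9, max_iter = 5e4)
  a0 <- min(a[keep])
  grid <- seq(30, 100, by = 5)
  Ftrue <- (pweibull(grid, 2, 60) - pweibull(a0, 2, 60)) /
    (1 - pweibull(a0, 2, 60))
  expect_lt(max(abs(predict(fit, grid)$cum_inc - Ftrue)), 0.06)
})

test_that("cure-fraction data leave a tail defect near the susceptible mass", {
  set.seed(12)
  n <- 5000
  d <- data.frame(male = rbinom(n, 1, 0.5), high = rbinom(n, 1, 0.5))
  dd <- simulate_event_times(d, mixture_truth(), mode = "twb",
                             recruit_age = rep(110, n))
  fit <- turnbull(event_observations(dd$entry_age, dd$kind, dd$left, dd$right))
  pi_bar <- mean(plogis(qlogis(0.0303) + log(2.85) * d$male +
                          log(1.62) * d$high))
  plateau <- max(fit$support$cum_mass[is.finite(fit$support$right)])
  expect_lt(abs(plateau - pi_bar), 0.03)
  # monotone cumulative curve; survival 1 before the first support point
  pr <- predict(fit, seq(0, 120, by = 1))
  expect_true(all(diff(pr$cum_inc) >= -1e-12))
  expect_equal(pr$surv[1], 1)
})

test_that("interval-censored longitudinal data recover the generating curve", {
  set.seed(13)
  n <- 2000
  d <- data.frame(male = rbinom(n, 1, 0.5), high = rbinom(n, 1, 0.5))
  exams <- seq(30, 80, by = 3)
  dd <- simulate_event_times(d, mixture_truth(), mode = "cvdfacts",
                             exam_ages = exams, onset_resolution = "exact")
  fit <- turnbull(event_observations(dd$entry_age, dd$kind, dd$left, dd$right))
  # compare at exam ages against the true conditional mixture curve
  tr <- mixture_truth()
  pi_i <- plogis(qlogis(0.0303) + log(2.85) * dd$male + log(1.62) * dd$high)
  Ft <- function(t) pggd(t, 4.16, exp(-2.37), 1.42)
  grid <- exams[-1]
  Ftrue <- vapply(grid, function(t)
    mean(pi_i * (Ft(t) - Ft(exams[1])) / (1 - pi_i * Ft(exams[1]))),
    numeric(1))
  got <- predict(fit, grid)$cum_inc
  expect_lt(max(abs(got - Ftrue)), 0.05)
})

test_that("degenerate and invalid inputs error clearly", {
  expect_error(turnbull(event_observations(0, "exact", 1, 1)[0, ]), "no obs")
  expect_error(event_observations(0, "interval", 3, 2), "left < right")
  expect_error(event_observations(5, "exact", 3, 3), "entry_age")
  expect_error(event_observations(0, "weird", 1, 2), "kind")
})
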