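skip_if_not_installed("survival")

test_that("symmetric two-subject likelihood is maximized at beta = 0", {
  d <- crdata(data.frame(id = 1:2, time = c(1, 1), status = 1L,
                         z = c(0.7, -0.7)))
  fit <- cscox(d, cause = 1)
  expect_equal(unname(coef(fit)), 0, tolerance = 1e-8)
})

test_that("four-subject fit matches the closed-form grid-search oracle", {
  # explicit Breslow product over the nested risk sets
  Lfun <- function(b) exp(b) / (2 * exp(b) + 2) * 1 / (exp(b) + 2) *
    exp(b) / (exp(b) + 1)
  grid <- seq(-5, 5, by = 1e-4)
  b_oracle <- grid[which.max(Lfun(grid))]
  fit <- cscox(four_subject_crdata(), cause = 1)
  expect_equal(unname(coef(fit)), b_oracle, tolerance = 1e-4)
  expect_equal(fit$loglik[["fitted"]], log(Lfun(coef(fit))),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("estimates, errors, likelihood and baseline match survival::coxph", {
  set.seed(20)
  for (i in 1:20) {
    d <- random_crdata(n = 50, m = 3)
    df <- as.data.frame(d)
    for (k in 1:2) {
      fit <- cscox(d, cause = k)
      oracle <- survival::coxph(
        survival::Surv(time, status == k) ~ x1 + x2 + x3,
        data = df, ties = "breslow")
      expect_equal(unname(coef(fit)), unname(coef(oracle)),
                   tolerance = 1e-4)
      expect_equal(unname(fit$se), unname(sqrt(diag(vcov(oracle)))),
                   tolerance = 1e-4)
      expect_equal(fit$loglik[["fitted"]], oracle$loglik[2],
                   tolerance = 1e-8, ignore_attr = TRUE)
      bh <- survival::basehaz(oracle, centered = FALSE)
      expect_equal(fit$baseline(bh$time), bh$hazard, tolerance = 1e-8)
    }
  }
})

test_that("log partial likelihood at beta = 0 is minus the sum of log risk-set sizes", {
  d <- four_subject_crdata()
  expect_equal(cox_loglik(d, 1, 0), -sum(log(c(4, 3, 2, 1))))
  # maximality: no perturbation of the fit improves the likelihood
  set.seed(21)
  d <- random_crdata(n = 40)
  fit <- cscox(d, cause = 1)
  ll_hat <- cox_loglik(d, 1, coef(fit))
  for (i in 1:100) {
    eps <- rnorm(3); eps <- 0.1 * eps / sqrt(sum(eps^2))
    expect_lte(cox_loglik(d, 1, coef(fit) + eps), ll_hat + 1e-10)
  }
})

test_that("baseline hazard has the closed form at beta = 0 and is monotone", {
  d <- crdata(data.frame(id = 1:2, time = c(1, 2), status = 1L,
                         x1 = c(0.5, -0.5)))
  H <- nelson_aalen_baseline(d, cause = 1, beta = 0)
  expect_equal(H(1), 0.5)
  expect_equal(H(2), 1.5)
  expect_equal(H(0.5), 0)
  # no events of the requested cause: identically zero
  H0 <- nelson_aalen_baseline(d, cause = 2, beta = 0)
  expect_true(all(H0(c(0, 1, 2, 3)) == 0))
  set.seed(22)
  d <- random_crdata(n = 40)
  fit <- cscox(d, cause = 1)
  tt <- sort(unique(d$time))
  expect_true(all(diff(fit$baseline(tt)) >= 0))
  expect_equal(fit$baseline(0), 0)
})

test_that("fit is scale-equivariant and invariant to relabeling the other cause", {
  set.seed(23)
  d <- random_crdata(n = 60)
  fit <- cscox(d, cause = 1)
  df <- as.data.frame(d); df$x1 <- df$x1 * 3
  fit3 <- cscox(crdata(df), cause = 1)
  expect_equal(coef(fit3)[["x1"]], coef(fit)[["x1"]] / 3, tolerance = 1e-8)
  expect_equal(coef(fit3)[["x2"]], coef(fit)[["x2"]], tolerance = 1e-8)
  # cause-2 events relabeled censored: identical cause-1 fit
  df <- as.data.frame(d); df$status[df$status == 2L] <- 0L
  expect_equal(coef(cscox(crdata(df), cause = 1)), coef(fit),
               tolerance = 1e-12)
  # score ~ 0 and positive-definite information at the optimum
  expect_lt(max(abs(fit$score)), 1e-8)
  expect_true(all(eigen(solve(fit$vcov))$values > 0))
})

test_that("transition fit reduces to the flat cause-specific problem", {
  set.seed(24)
  n <- 40
  df <- data.frame(id = 1:n, time = round(rexp(n), 3) + 0.01,
                   status = sample(0:1, n, replace = TRUE),
                   x1 = rnorm(n), x2 = rnorm(n))
  df$status[1] <- 1L
  long <- data.frame(id = df$id, from = 2L, to = 4L, entry = 0,
                     exit = df$time, status = df$status,
                     cause = ifelse(df$status == 1L, 1L, NA_integer_),
                     x1 = df$x1, x2 = df$x2)
  ft <- cscox_transition(long, 2, 4)
  ff <- cscox(crdata(df), cause = 1)
  expect_equal(coef(ft), coef(ff), tolerance = 1e-10)
  expect_error(cscox_transition(long, 3, 4), "no records")
  long$status <- 0L
  expect_error(cscox_transition(long, 2, 4), "no events")
})

test_that("all five transitions of the chemo-analog cohort give converged fits", {
  w <- simulate_chemo_analog(seed = 41)
  long <- to_long_transitions(w)
  for (tr in list(c(1, 2), c(1, 4), c(2, 3), c(2, 4), c(3, 4))) {
    fit <- cscox_transition(long, tr[1], tr[2],
                            covariates = paste0("cov", 1:6))
    expect_true(fit$converged)
    expect_gte(fit$n_events, 1L)
  }
})

test_that("parameter recovery at large n is within asymptotic error", {
  d <- simulate_crdata(n = 5000, seed = 99)
  fit <- cscox(d, cause = 1)
  expect_true(all(abs(coef(fit) - c(-0.5, 0.01, 0.02)) < 3 * fit$se))
})

test_that("degenerate inputs are rejected, monotone likelihood is flagged", {
  d <- crdata(data.frame(id = 1:4, time = 1:4, status = 1L,
                         x1 = rep(1, 4), x2 = rnorm(4)))
  expect_error(cscox(d, cause = 1), "constant covariate")
  # perfectly separating covariate: likelihood increases without bound
  sep <- crdata(data.frame(id = 1:6, time = c(1, 2, 3, 10, 11, 12),
                           status = c(1, 1, 1, 0, 0, 0),
                           x1 = c(5, 5, 5, -5, -5, -5) + rnorm(6, 0, 0.01)))
  expect_warning(cscox(sep, cause = 1), "did not converge")
})
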