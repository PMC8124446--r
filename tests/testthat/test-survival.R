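sim_surv <- function(n, beta = 0, x = rnorm(n), cens = 0.01,
                     base = 0.03) {
  t_ev <- rexp(n, base * exp(beta * x))
  t_c <- if (cens > 0) rexp(n, cens) else Inf
  data.frame(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c), x = x)
}

test_that("a constant covariate reports HR 1 and p 1", {
  set.seed(1)
  d <- sim_surv(40)
  d$z <- 0
  expect_warning(fit <- fit_cox(d, "z"), "constant")
  expect_equal(fit$hr[fit$term == "z"], 1)
  expect_equal(fit$p[fit$term == "z"], 1)
})

test_that("the Cox estimate matches brute-force likelihood maximization", {
  set.seed(2)
  d <- sim_surv(6, beta = 0.5, cens = 0)
  fit <- fit_cox(d, "x")
  b_oracle <- oracle_cox_beta(d$x, d$time, d$event)
  expect_lt(abs(fit$beta - b_oracle), 1e-6)
})

test_that("a planted log hazard ratio is recovered at scale", {
  set.seed(3)
  hits <- 0
  for (r in 1:30) {
    d <- sim_surv(1000, beta = log(2))
    hr <- fit_cox(d, "x")$hr
    if (hr > 1.8 && hr < 2.2) hits <- hits + 1
  }
  expect_gte(hits, 27) # >= 90%
})

test_that("perfect separation raises an error naming the covariate", {
  d <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                  event = c(1, 1, 1, 1, 1, 1),
                  x = c(5, 4, 3, 2, 1, 0)) # covariate sorted with time
  expect_error(suppressWarnings(fit_cox(d, "x")), "x")
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  # three events at 1, 2, 3: S = 2/3, 1/3, 0
  d <- data.frame(time = c(1, 2, 3), event = 1)
  km <- kaplan_meier(d)
  expect_equal(km$surv, c(1, 2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(km$time[1], 0)
  # no events: flat at 1
  d0 <- data.frame(time = c(1, 2, 3), event = 0)
  expect_true(all(kaplan_meier(d0)$surv == 1))
  # duplicating every record leaves the curve unchanged
  km2 <- kaplan_meier(rbind(d, d))
  expect_equal(unique(km2$surv), unique(km$surv), tolerance = 1e-12)
  # curves are non-increasing and the initial at-risk count is n
  expect_true(all(diff(km$surv) <= 0))
  expect_equal(km$n_risk[1], 3)
})

test_that("the log-rank test matches a direct computation and edge cases", {
  # identical groups: chi-square 0, p 1
  d <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 1))
  both <- rbind(cbind(d, g = "a"), cbind(d, g = "b"))
  lr0 <- logrank_test(both, "g")
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)
  # 8-patient example against the O-E/V definition
  d8 <- data.frame(time = c(1, 3, 4, 6, 2, 5, 7, 9),
                   event = c(1, 1, 0, 1, 1, 1, 1, 0),
                   g = rep(c("a", "b"), each = 4))
  lr <- logrank_test(d8, "g")
  expect_equal(lr$chisq, oracle_logrank(d8$time, d8$event, d8$g),
               tolerance = 1e-9)
  # one empty group errors
  d8$g <- factor(d8$g, levels = c("a", "b", "c"))
  d8b <- d8[d8$g == "a", ]
  expect_error(logrank_test(d8b, "g"), "two non-empty groups")
})

test_that("log-rank p-values are uniform under the null", {
  set.seed(11)
  ps <- replicate(400, {
    d <- data.frame(time = rexp(60, 0.05), event = 1,
                    g = rep(c("a", "b"), 30))
    logrank_test(d, "g")$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("median split halves the cohort with ties going low", {
  s <- median_split(1:22)
  expect_equal(as.integer(table(s)), c(11L, 11L))
  s2 <- median_split(c(1, 2, 2, 3))
  expect_equal(as.character(s2), c("low", "low", "low", "high"))
  # order invariance
  v <- c(5, 1, 9, 3, 7, 2)
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_identical(median_split(v)[perm], median_split(v[perm]))
  expect_error(median_split(c(2, 2, 2)), "no median split")
})

test_that("Holm adjustment matches the hand computation and its oracle", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(holm_adjust(c(0.1, 1.2)), "0, 1")
  set.seed(5)
  for (r in 1:20) {
    p <- runif(sample(1:12, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, oracle_holm(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= pmin(length(p) * p, 1) + 1e-12)) # <= Bonferroni
  }
})

test_that("association tests cover the standard cases", {
  expect_equal(spearman_test(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_test(1:10, -(1:10)^3)$rho, -1)
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
  set.seed(6)
  x <- rnorm(20)
  tt <- students_t_test(c(x, x), rep(c("a", "b"), each = 20))
  expect_equal(tt$t, 0, tolerance = 1e-12)
  expect_equal(tt$p, 1, tolerance = 1e-12)
  # Welch variant runs
  expect_true(students_t_test(rnorm(20), rep(c("a", "b"), 10),
                              var_equal = FALSE)$p >= 0)
})

test_that("time-dependent Cox reduces to the standard fit with no transplants", {
  set.seed(7)
  d <- sim_surv(80, beta = 0.4)
  d$transplant_time <- NA_real_
  fit_td <- fit_cox_timedep(d, "x")
  fit <- fit_cox(d, "x")
  expect_equal(fit_td$beta[fit_td$term == "x"],
               fit$beta[fit$term == "x"], tolerance = 1e-9)
})

test_that("a transplant indicator constant from time zero is rejected", {
  set.seed(8)
  d <- sim_surv(30, beta = 0)
  d$transplant_time <- 0
  expect_error(fit_cox_timedep(d, "x"), "non-identifiable")
  d$transplant_time <- d$time + 1
  expect_error(fit_cox_timedep(d, "x"), "strictly before")
})

test_that("the counting-process likelihood matches hand-enumerated risk sets", {
  # 5 patients; patient 2 transplanted at t = 1.5, at risk with the switched
  # indicator at patient 4's event (t = 3) and at their own (t = 4)
  d <- data.frame(time = c(1, 4, 5, 3, 6), event = c(1, 1, 0, 1, 1),
                  transplant_time = c(NA, 1.5, NA, NA, NA))
  fit <- fit_cox_timedep(d, character(0), timedep_name = "tx")
  # hand-enumerated risk sets with z_i(t) = 1(t >= tx_i):
  # t=1: all five at risk, all z = 0; t=3: risk {2,3,4,5}, z2 = 1, event 4;
  # t=4: risk {2,3,5}, event 2 (z=1); t=6: risk {5}, event 5
  ll <- function(b) {
    -log(5) +
      (0 - log(exp(b) + 3)) +
      (b - log(exp(b) + 2)) +
      0
  }
  b_oracle <- stats::optimize(function(b) -ll(b), c(-20, 20),
                              tol = 1e-12)$minimum
  expect_lt(abs(fit$beta[fit$term == "tx"] - b_oracle), 1e-6)
  expect_equal(fit$loglik, ll(fit$beta[fit$term == "tx"]), tolerance = 1e-9)
})
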