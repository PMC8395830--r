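test_that("risk scores are the stated linear combination and commute", {
  expect_equal(risk_score(0.5, 1, 1, 0, 0, 0), 0)
  expect_equal(risk_score(0.5, 7, 9, 1, 0, 0), 0.5)
  expect_equal(risk_score(0.8, 1.2, 0.3, 0.5, -1.0, 2.0), -0.2)
  # gene terms commute
  expect_equal(risk_score(0.8, 1.2, 0.3, 0.5, -1.0, 2.0),
               risk_score(0.8, 0.3, 1.2, 0.5, 2.0, -1.0))
  # vectorized over samples
  expect_equal(risk_score(c(0, 1), c(1, 1), c(2, 2), 1, 1, 1), c(3, 4))
})

test_that("median stratification follows the strict-above rule", {
  s <- setNames(1:10, paste0("P", 1:10))
  st <- stratify_median(s)
  expect_length(st$high, 5)
  expect_length(st$low, 5)

  s2 <- setNames(c(1, 2, 2, 3), paste0("P", 1:4))
  st2 <- stratify_median(s2)
  expect_equal(st2$high, "P4")
  expect_setequal(st2$low, c("P1", "P2", "P3"))

  set.seed(10)
  s3 <- setNames(rnorm(101), sprintf("P%03d", 1:101))
  st3 <- stratify_median(s3)
  expect_equal(length(st3$high), sum(s3 > sort(s3)[51]))
  expect_equal(sort(c(st3$high, st3$low)), sort(names(s3)))

  expect_error(stratify_median(setNames(rep(1, 5), paste0("P", 1:5))),
               "identical")
})

test_that("log-rank test matches a tabular observed-minus-expected oracle", {
  grp <- rep(c("a", "b"), c(4, 4))
  time <- c(2, 5, 7, 11, 3, 6, 9, 13) # all distinct: tie-free oracle
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)

  # textbook log-rank: O-E and hypergeometric variance summed at event times
  o_minus_e <- 0
  v <- 0
  for (t in sort(time[event == 1])) {
    at_risk <- time >= t
    d <- sum(time == t & event == 1)
    n1 <- sum(at_risk & grp == "a")
    n <- sum(at_risk)
    d1 <- sum(time == t & event == 1 & grp == "a")
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oracle_stat <- o_minus_e^2 / v
  got <- logrank_test(grp, time, event)
  expect_equal(got$statistic, oracle_stat, tolerance = 1e-9)
  expect_equal(got$p_value, pchisq(oracle_stat, 1, lower.tail = FALSE))

  same <- logrank_test(rep(c("a", "b"), each = 4), rep(time[1:4], 2),
                       rep(event[1:4], 2))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)
  expect_error(logrank_test(rep("a", 4), time[1:4], event[1:4]), "two")
})

test_that("the Cox coefficient maximizes the partial likelihood (grid oracle)", {
  x <- c(0, 0, 0, 1, 1, 1)
  time <- c(5, 8, 11, 1, 3, 9)
  event <- c(1, 0, 1, 1, 1, 1)
  # tie-free partial log-likelihood, coded independently
  pll <- function(b) {
    s <- 0
    for (i in which(event == 1)) {
      rs <- time >= time[i]
      s <- s + b * x[i] - log(sum(exp(b * x[rs])))
    }
    s
  }
  oracle <- stats::optimize(pll, c(-5, 5), maximum = TRUE)$maximum
  fit <- univariate_cox(x, time, event)
  expect_equal(fit$coef, oracle, tolerance = 1e-3)
  expect_false(fit$flagged)

  expect_error(univariate_cox(rep(1, 6), time, event), "constant")
  expect_error(univariate_cox(x, time, rep(0, 6)), "2 events")
})

test_that("Cox slope recovery and log-rank power behave on simulated data", {
  d <- simulate_ph(1000, coef = 0.7, seed = 5)
  fit <- univariate_cox(d$feature, d$os_time, d$os_event)
  expect_lt(abs(fit$coef - 0.7), 0.1)

  d0 <- simulate_ph(500, coef = 0, seed = 6)
  fit0 <- univariate_cox(d0$feature, d0$os_time, d0$os_event)
  expect_lt(abs(fit0$coef), 0.1)

  # hazard ratio 3 between groups of 100: overwhelming power
  rej <- 0
  for (s in 1:5) {
    set.seed(200 + s)
    grp <- rep(c("high", "low"), each = 100)
    t_ev <- rexp(200, 0.002 * ifelse(grp == "high", 3, 1))
    cens <- runif(200, 0, 2000)
    p <- logrank_test(grp, pmin(t_ev, cens), as.integer(t_ev <= cens))$p_value
    rej <- rej + (p < 0.05)
  }
  expect_equal(rej, 5)
})

test_that("triplet survival summaries stratify planted-risk cohorts", {
  cfg <- cohort_config(n_tumor = 300, n_normal = 30, n_tf = 4, n_rbp = 4,
                       n_ase = 4, n_de_tf = 1, n_de_rbp = 1, n_de_ase = 1,
                       planted_triplets = list(triplet_spec(1, 1, 1)),
                       risk_betas = c(ase = 1.5, tf = 1, rbp = 1), seed = 71)
  co <- generate_cohort(cfg)
  trip <- tibble::tibble(
    tf = c("TF001", "TF002"), rbp = c("RBP001", "RBP002"),
    event_id = co$psi$event_id[c(1, 2)]
  )
  sm <- summarize_survival(trip, co$psi, co$tf_expr, co$rbp_expr, co$clinical)
  per <- tidy(sm)
  expect_equal(nrow(per), 2L)
  expect_false(any(per$failed))
  # the planted triplet's score must stratify survival
  expect_lt(per$logrank_p[1], 0.05)
  g <- glance(sm)
  expect_equal(g$n_tested, 2L)
  expect_match(g$frac_significant_label, "^[0-9]+\\.[0-9]{2}%$")
  expect_equal(g$frac_significant,
               round(100 * g$n_significant / g$n_tested, 2))

  expect_error(summarize_survival(trip[0, ], co$psi, co$tf_expr, co$rbp_expr,
                                  co$clinical), "no triplets")
})

test_that("KM coordinates track the product-limit estimator", {
  grp <- rep(c("high", "low"), each = 4)
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- rep(1L, 8)
  km <- km_coordinates(grp, time, event)
  hi <- km[km$group == "high", ]
  expect_equal(hi$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(hi$n_risk, 4:1)
})
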