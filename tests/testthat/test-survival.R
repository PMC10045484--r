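# golden-section maximizer of the hand-written partial likelihood, used as
# the independent oracle for single-covariate fits
grid_cox_beta <- function(records, covariate, lo = -5, hi = 5) {
  f <- function(b) cox_loglik(records, covariate, b)
  opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-10)
  opt$maximum
}

test_that("cox_fit maximizes the Breslow partial likelihood (grid oracle, toy)", {
  rec <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 1, 1),
                    x = c(0, 1, 0, 1))
  # fewer than 10 events is rejected; repeat the pattern with jitter
  rec <- do.call(rbind, replicate(5, rec, simplify = FALSE))
  rec$time <- rec$time + rep(seq(0, 0.4, 0.1), each = 4) # break exact ties
  fit <- cox_fit(rec, "x")
  expect_true(fit$converged)
  expect_equal(unname(fit$coef), grid_cox_beta(rec, "x"), tolerance = 1e-4)
  # the fit's loglik is at least the oracle maximum
  expect_gte(fit$loglik + 1e-8, cox_loglik(rec, "x", grid_cox_beta(rec, "x")))
})

test_that("cox_fit equals grid search on random small instances", {
  set.seed(55)
  for (rep in 1:10) {
    n <- 20
    x <- rnorm(n)
    rec <- data.frame(time = rexp(n, exp(0.5 * x)),
                      event = rbinom(n, 1, 0.8), x = x)
    if (sum(rec$event) < 10) next
    fit <- cox_fit(rec, "x")
    expect_equal(unname(fit$coef), grid_cox_beta(rec, "x"), tolerance = 1e-3)
  }
})

test_that("cox_fit agrees with survival::coxph under both tie conventions", {
  set.seed(19)
  n <- 120
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.5)
  rec <- data.frame(time = round(rexp(n, exp(0.6 * x1 - 0.4 * x2)), 1) + 0.1,
                    event = rbinom(n, 1, 0.7), x1 = x1, x2 = x2)
  for (t in c("breslow", "efron")) {
    fit <- cox_fit(rec, c("x1", "x2"), ties = t)
    ph <- survival::coxph(survival::Surv(time, event) ~ x1 + x2, data = rec,
                          ties = t)
    expect_equal(unname(fit$coef), unname(coef(ph)), tolerance = 1e-6)
    expect_equal(fit$loglik, ph$loglik[2], tolerance = 1e-8)
  }
})

test_that("cox_fit recovers a known hazard ratio", {
  set.seed(4)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  rec <- data.frame(time = rexp(n, 0.1 * exp(0.7 * x)), event = 1L, x = x)
  fit <- cox_fit(rec, "x")
  expect_lt(abs(unname(fit$coef) - 0.7), 0.15)
})

test_that("cox_fit rejects degenerate inputs", {
  rec <- toy_survival()
  rec$z <- 1
  expect_error(cox_fit(rec, "z"), "zero-variance covariate.*z")
  few <- rec[1:12, ]
  few$event <- c(rep(1L, 5), rep(0L, 7))
  expect_error(cox_fit(few, "x"), ">= 10 events")
  # perfect separation: all events in one group, with the covariate ordering
  # the times monotonically
  n <- 30
  sep <- data.frame(time = c(1:15, 101:115), event = 1L,
                    x = rep(c(1, 0), each = 15))
  expect_error(cox_fit(sep, "x"), "divergence|monotone")
})

test_that("risk score is the stated linear form", {
  m <- expression_matrix(rbind(gA = c(1, 2, 3, 4), gB = c(4, 3, 2, 1)),
                         c("gA", "gB"), sprintf("s%d", 1:4),
                         layer = "lognorm")
  beta <- c(gA = 0.5, gB = -0.2)
  rs <- risk_score(m, beta, zscore = FALSE)
  expect_equal(rs$score, 0.5 * c(1, 2, 3, 4) - 0.2 * c(4, 3, 2, 1))
  # z-scored variant centers the cohort
  rs_z <- risk_score(m, beta)
  expect_equal(mean(rs_z$score), 0)
  # zero coefficients give zero scores
  expect_true(all(risk_score(m, c(gA = 0, gB = 0), zscore = FALSE)$score == 0))
  # linearity: adding c to one gene shifts every score by beta * c
  m2 <- expression_matrix(em_values(m) + rbind(rep(2, 4), rep(0, 4)),
                          m$gene_ids, m$obs_ids, layer = "lognorm")
  expect_equal(risk_score(m2, beta, zscore = FALSE)$score,
               rs$score + 0.5 * 2)
  expect_error(risk_score(m, c(gC = 1)), "absent.*gC")
})

test_that("dichotomize splits at the median with ties going low", {
  rs <- data.frame(sample_id = sprintf("s%d", 1:4), score = c(-1, 0, 1, 2))
  d <- dichotomize(rs)
  expect_setequal(d$sample_id[d$group == "high"], c("s3", "s4"))
  d3 <- dichotomize(setNames(c(5, 7, 9), c("a", "b", "c")))
  expect_identical(d3$group, c("low", "low", "high"))
  expect_error(dichotomize(setNames(rep(1, 4), letters[1:4])), "degenerate")
})

test_that("KM estimate matches hand product-limit computations", {
  rec <- data.frame(time = c(1, 2, 3), event = c(1, 0, 1))
  km <- km_estimate(rec)
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 3], 0)
  # no events: survival stays 1
  rec0 <- data.frame(time = 1:4, event = 0)
  expect_true(all(km_estimate(rec0)$survival == 1))
  # all events, distinct times: empirical survival (n-k)/n
  recn <- data.frame(time = 1:5, event = 1)
  expect_equal(km_estimate(recn)$survival, (5 - 1:5) / 5)
  # survival is non-increasing within each group
  rec2 <- toy_survival(n = 40)
  km2 <- km_estimate(rec2, rep(c("a", "b"), 20))
  for (g in c("a", "b"))
    expect_true(all(diff(km2$survival[km2$group == g]) <= 1e-12))
})

test_that("log-rank behaves at the null, under label swap, and with power", {
  # identical data in both groups (jittered to avoid complete ties)
  set.seed(10)
  base <- toy_survival(n = 40, beta = 0)
  rec <- rbind(base, transform(base, time = time * (1 + 1e-9)))
  lr <- logrank_test(rec, rep(c("g1", "g2"), each = 40))
  expect_lt(lr$chi_square, 1e-3)
  expect_gt(lr$p, 0.97)

  # label-swap invariance
  rec2 <- toy_survival(n = 60, beta = 1, seed = 2)
  g <- rep(c("A", "B"), 30)
  swapped <- ifelse(g == "A", "B", "A")
  expect_equal(logrank_test(rec2, g)$chi_square,
               logrank_test(rec2, swapped)$chi_square)

  # strong effect is detected
  rec3 <- toy_survival(n = 200, beta = log(3), seed = 3)
  expect_lt(logrank_test(rec3, c("hi", "lo")[rec3$x + 1])$p, 0.001)

  expect_error(logrank_test(rec3, rep("one", 200)), "exactly 2")
  g0 <- rep(c("A", "B"), each = 100)
  rec3$event[g0 == "B"] <- 0
  expect_error(logrank_test(rec3, g0), "no events")
})

test_that("log-rank chi-square matches the hand O-E-V computation", {
  rec <- data.frame(time = c(1, 2, 3, 4, 5, 6), event = c(1, 1, 0, 1, 1, 1))
  g <- c("A", "B", "A", "B", "A", "B")
  # hand computation with hypergeometric variance at each event time
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(rec$time[rec$event == 1]))) {
    at_risk <- rec$time >= t
    d <- sum(rec$time == t & rec$event == 1)
    n <- sum(at_risk); n1 <- sum(at_risk & g == "A")
    d1 <- sum(rec$time == t & rec$event == 1 & g == "A")
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + d1 - e1
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(logrank_test(rec, g)$chi_square, o_minus_e^2 / v,
               tolerance = 1e-12)
})

test_that("concordance index handles perfect, reversed, tied and null orderings", {
  rec <- data.frame(time = c(1, 2, 3, 4), event = 1)
  expect_equal(concordance_index(rec, c(4, 3, 2, 1)), 1)
  expect_equal(concordance_index(rec, c(1, 2, 3, 4)), 0)
  expect_equal(concordance_index(rec, rep(1, 4)), 0.5)
  # agrees with the survival package on censored data
  set.seed(12)
  rec2 <- data.frame(time = rexp(80), event = rbinom(80, 1, 0.7))
  sc <- rnorm(80)
  cidx <- concordance_index(rec2, sc)
  ref <- survival::concordance(survival::Surv(time, event) ~ sc,
                               data = rec2, reverse = TRUE)$concordance
  expect_equal(cidx, ref, tolerance = 1e-12)
  # null scores give C near 0.5
  set.seed(13)
  rec3 <- data.frame(time = rexp(400), event = 1)
  expect_lt(abs(concordance_index(rec3, rnorm(400)) - 0.5), 0.05)
  expect_error(concordance_index(data.frame(time = c(1, 1), event = c(0, 0)),
                                 1:2), "no comparable")
})
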