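# PSI, splice-event ratios, quartile stratification, Kaplan-Meier,
# log-rank, Cox regression.

test_that("psi_per_isoform normalises within genes and flags zero genes", {
  tpm <- matrix(c(6, 3, 1, 0, 0, 0), 3, 2,
                dimnames = list(c("t1", "t2", "t3"), c("p1", "p2")))
  gm <- c(t1 = "G", t2 = "G", t3 = "G")
  psi <- psi_per_isoform(tpm, gm)
  expect_equal(psi[, "p1"], c(t1 = 0.6, t2 = 0.3, t3 = 0.1))
  expect_true(all(is.na(psi[, "p2"])))
  # single-isoform gene: psi 1
  one <- psi_per_isoform(matrix(5, 1, 1, dimnames = list("tx", "p")),
                         c(tx = "G1"))
  expect_equal(unname(one[1, 1]), 1)
  expect_error(psi_per_isoform(tpm, c(t1 = "G", t2 = "G")), "without gene")
  # conservation: per-gene column sums are 1 wherever defined
  set.seed(47)
  tpm2 <- matrix(rexp(60), 6, 10,
                 dimnames = list(sprintf("t%d", 1:6), sprintf("p%d", 1:10)))
  gm2 <- setNames(rep(c("A", "B"), each = 3), rownames(tpm2))
  psi2 <- psi_per_isoform(tpm2, gm2)
  for (g in c("A", "B")) {
    expect_equal(unname(colSums(psi2[gm2 == g, ])), rep(1, 10),
                 tolerance = 1e-9)
  }
})

test_that("splice_event_ratio sums PSI over named sets", {
  tpm <- matrix(c(0.3, 0.2, 0.25, 0.25) * 10, 4, 1,
                dimnames = list(c("i201", "i204", "i203", "i202"), "p1"))
  gm <- setNames(rep("G", 4), rownames(tpm))
  psi <- psi_per_isoform(tpm, gm)
  r <- splice_event_ratio(psi, c("i201", "i204"), "i203")
  expect_equal(unname(r), (0.3 + 0.2) / 0.25)
  # numerator all zero -> 0; zero denominator -> NA
  tpm0 <- matrix(c(0, 0, 1, 1), 4, 1, dimnames = dimnames(tpm))
  psi0 <- psi_per_isoform(tpm0, gm)
  expect_equal(unname(splice_event_ratio(psi0, c("i201", "i204"), "i203")), 0)
  expect_true(is.na(splice_event_ratio(psi0, "i203", "i201")))
  expect_error(splice_event_ratio(psi, "i201", "zz"), "unknown")
  # permuting patients permutes ratios identically
  set.seed(53)
  tpmn <- matrix(rexp(40), 4, 10, dimnames = list(rownames(tpm),
                                                  sprintf("p%d", 1:10)))
  psin <- psi_per_isoform(tpmn, gm)
  perm <- sample(10)
  expect_equal(unname(splice_event_ratio(psin, "i201", "i203")[perm]),
               unname(splice_event_ratio(psin[, perm], "i201", "i203")))
})

test_that("quartile_stratify uses nearest-rank quartiles with stable ties", {
  g <- quartile_stratify(setNames(1:8, letters[1:8]))
  expect_identical(g$low_group, c("a", "b"))
  expect_identical(g$high_group, c("g", "h"))
  # n = 519 -> 129 per group
  set.seed(59)
  g519 <- quartile_stratify(setNames(rnorm(519), sprintf("P%03d", 1:519)))
  expect_identical(length(g519$low_group), 129L)
  expect_identical(length(g519$high_group), 129L)
  expect_length(intersect(g519$low_group, g519$high_group), 0)
  # all equal: stable id order, flagged degenerate
  ge <- quartile_stratify(setNames(rep(1, 8), letters[8:1]))
  expect_true(ge$degenerate)
  expect_identical(ge$low_group, letters[1:2])
  expect_error(quartile_stratify(setNames(1:7, letters[1:7])), ">= 8")
})

test_that("km_estimator reproduces the product-limit worked example", {
  km <- km_estimator(1:5, rep(1, 5))
  expect_equal(km$curve$surv, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km$median_survival, 3)
  # all censored: S = 1 everywhere, median undefined
  kmc <- km_estimator(1:5, rep(0, 5))
  expect_identical(nrow(kmc$curve), 0L)
  expect_true(is.na(kmc$median_survival))
  # no censoring: S equals the empirical survival function; monotone
  set.seed(61)
  t <- rexp(50)
  km2 <- km_estimator(t, rep(1, 50))
  expect_equal(km2$curve$surv,
               vapply(km2$curve$time, function(u) mean(t > u), numeric(1)))
  expect_true(all(diff(km2$curve$surv) <= 1e-12))
  # with censoring, matches the hand oracle
  ev <- rbinom(50, 1, 0.6)
  km3 <- km_estimator(t, ev)
  o <- oracle_km(t, ev)
  expect_equal(km3$curve$surv, o$surv)
})

test_that("merged identical groups give the same KM curve as each group", {
  set.seed(67)
  t <- rexp(30); ev <- rbinom(30, 1, 0.7)
  one <- km_estimator(t, ev)
  both <- km_estimator(c(t, t), c(ev, ev))
  expect_equal(both$curve$surv, one$curve$surv)
})

test_that("logrank_test matches the hand-computed toy example and survdiff", {
  # identical groups duplicated: chi-square 0
  t <- c(1, 2, 3, 4); ev <- c(1, 1, 0, 1)
  expect_equal(logrank_test(t, ev, t, ev)$chi_square, 0)
  # toy: group a deaths at 1, 2; group b deaths at 3, 4
  # hand tabulation over event times 1..4 (all at risk until their time):
  # t=1: n=8, na=4, d=1 -> e=0.5, v=0.25
  # t=2: n=6 (a:3 left? both groups risk >= t) ...
  ta <- c(1, 2, 5, 6); tb <- c(3, 4, 7, 8)
  eva <- c(1, 1, 0, 0); evb <- c(1, 1, 0, 0)
  res <- logrank_test(ta, eva, tb, evb)
  o_minus_e <- 0; v <- 0
  time <- c(ta, tb); event <- c(eva, evb); grp <- rep(0:1, each = 4)
  for (tt in c(1, 2, 3, 4)) {
    risk <- time >= tt
    n <- sum(risk); na <- sum(risk & grp == 0)
    d <- sum(time == tt & event == 1)
    da <- sum(time == tt & event == 1 & grp == 0)
    o_minus_e <- o_minus_e + da - d * na / n
    v <- v + d * (na / n) * (1 - na / n) * (n - d) / (n - 1)
  }
  expect_equal(res$chi_square, o_minus_e^2 / v)
  # symmetric in group labels
  res_sw <- logrank_test(tb, evb, ta, eva)
  expect_equal(res$chi_square, res_sw$chi_square)
  # cross-check against the survival package
  if (requireNamespace("survival", quietly = TRUE)) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
    expect_equal(res$chi_square, sd$chisq, tolerance = 1e-9)
  }
  expect_error(logrank_test(1:3, c(0, 0, 0), 4:6, c(0, 0, 0)), "no events")
})

test_that("cox_univariate matches the grid-search oracle on tiny examples", {
  # binary covariate, no ties, n = 3
  x <- c(0, 1, 0); t <- c(1, 2, 3); ev <- c(1, 1, 1)
  fit <- cox_univariate(x, t, ev)
  expect_lt(abs(fit$beta - oracle_cox_grid(x, t, ev)), 2e-3)
  set.seed(71)
  n_checked <- 0
  while (n_checked < 10) {
    x <- rnorm(3); t <- sort(rexp(3)); ev <- c(1, 1, 1)
    b0 <- oracle_cox_grid(x, t, ev)
    if (abs(b0) > 3) next   # monotone-likelihood draws have no interior max
    fit <- cox_univariate(x, t, ev)
    expect_lt(abs(fit$beta - b0), 2e-3)
    n_checked <- n_checked + 1
  }
  expect_error(cox_univariate(rep(1, 5), 1:5, rep(1, 5)), "constant")
  expect_error(cox_univariate(1:5, 1:5, rep(0, 5)), "no events")
})

test_that("cox_univariate agrees with survival::coxph (Breslow and Efron)", {
  skip_if_not_installed("survival")
  set.seed(73)
  n <- 120
  x <- rnorm(n)
  t <- round(rexp(n, exp(0.5 * x)), 2)   # rounding induces ties
  t[t == 0] <- 0.01
  ev <- rbinom(n, 1, 0.8)
  for (ties in c("breslow", "efron")) {
    fit <- cox_univariate(x, t, ev, ties = ties)
    ref <- survival::coxph(survival::Surv(t, ev) ~ x, ties = ties)
    expect_equal(fit$beta, unname(ref$coefficients), tolerance = 1e-6)
    expect_equal(fit$se, unname(sqrt(ref$var[1, 1])), tolerance = 1e-6)
  }
})

test_that("cox beta is shift-invariant in the covariate", {
  set.seed(79)
  x <- rnorm(40); t <- rexp(40); ev <- rbinom(40, 1, 0.7)
  f1 <- cox_univariate(x, t, ev)
  f2 <- cox_univariate(x + 100, t, ev)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-7)
})

test_that("stratify_survival wires PSI stratification end to end", {
  cfg <- sim_config(n_patients = 200L, seed = 5L)
  co <- simulate_survival(cfg)
  st <- stratify_survival(co$psi, co$survival)
  expect_identical(length(st$groups$low_group), 50L)
  expect_s3_class(st$km_low, "km_curve")
  expect_lt(st$logrank$p, 0.05)      # planted hazard effect is detectable
  expect_gt(st$cox$hr, 1)
})
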