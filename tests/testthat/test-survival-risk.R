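test_that("univariate Cox fits match a grid search of the partial likelihood", {
  x <- c(0.5, -1.2, 2.0, -0.3)
  time <- c(2, 5, 1, 8); event <- c(1, 1, 1, 1)   # distinct event times
  fit <- fit_univariate_cox(x, time, event)
  grid <- seq(-5, 5, by = 0.001)
  ll <- vapply(grid, cox_partial_loglik, numeric(1), x = x, time = time,
               event = event)
  expect_equal(fit$coef, grid[which.max(ll)], tolerance = 0.01)
  expect_false(fit$separation)

  const <- fit_univariate_cox(rep(1, 10), 1:10, rep(1, 10))
  expect_equal(const$coef, 0)
  expect_true(const$untestable)
  expect_error(fit_univariate_cox(rnorm(5), 1:5, c(1, 0, 0, 0, 0)),
               ">= 2 events")
})

test_that("Cox coefficients are unbiased under the null and recover a true hazard", {
  set.seed(61)
  null_coefs <- replicate(100, {
    x <- rnorm(60)
    tt <- rexp(60, rate = 0.1)
    fit_univariate_cox(x, tt, rep(1, 60))$coef
  })
  expect_lt(abs(mean(null_coefs)), 0.1)

  betas <- vapply(1:25, function(s) {
    set.seed(s)
    x <- rnorm(200)
    cfg <- sim_config(signature_hazard_beta = 1, censor_rate = 0.3, seed = s)
    surv <- simulate_survival(cfg, x)
    fit_univariate_cox(x, surv$os_time, surv$os_event)$coef
  }, numeric(1))
  expect_equal(mean(betas), 1, tolerance = 0.2)
})

test_that("risk scores are the coefficient-weighted expression sums", {
  expr <- matrix(1:6, nrow = 2,
                 dimnames = list(c("f1", "f2"), c("p1", "p2", "p3")))
  expect_equal(unname(compute_risk_score(expr, c(f1 = 0, f2 = 0))),
               c(0, 0, 0))
  expect_equal(unname(compute_risk_score(expr["f1", , drop = FALSE],
                                         c(f1 = 2))),
               c(2, 6, 10))
  one <- matrix(3, 1, 1, dimnames = list("f1", "p1"))
  expect_equal(unname(compute_risk_score(one, c(f1 = 2))), 6)
  expect_error(compute_risk_score(expr, c(ghost = 1)), "ghost")

  set.seed(71)
  m <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("f", 1:5), paste0("p", 1:10)))
  cf <- setNames(rnorm(5), rownames(m))
  brute <- sapply(1:10, function(j) {
    s <- 0
    for (i in 1:5) s <- s + m[i, j] * cf[paste0("f", i)]
    s
  })
  expect_equal(unname(compute_risk_score(m, cf)), unname(brute))
})

test_that("median stratification splits patients with ties going low", {
  s <- setNames(c(1, 2, 3, 4), paste0("p", 1:4))
  st <- stratify(s)
  expect_equal(unname(st$group), c("low", "low", "high", "high"))
  odd <- stratify(setNames(c(1, 2, 3), paste0("p", 1:3)))
  expect_equal(unname(odd$group["p2"]), "low")
  expect_error(stratify(rep(1, 4)), "identical")
  expect_error(stratify(1), ">= 2")

  set.seed(81)
  sc <- setNames(rnorm(31), paste0("p", 1:31))
  st2 <- stratify(sc)
  expect_identical(unname(st2$group),
                   unname(ifelse(sc > median(sc), "high", "low")))
  # invariance under a strictly monotone transform of the scores
  st3 <- stratify(exp(sc))
  expect_identical(st3$group, st2$group)
})

test_that("Kaplan-Meier steps match the hand-computed product limit", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1), rep("all", 3))
  expect_equal(km$curves$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$medians$median, 2)

  cens <- km_curve(c(4, 7, 9), c(0, 0, 0), rep("all", 3))
  expect_true(all(cens$curves$surv == 1))
  expect_true(is.na(cens$medians$median))

  # deaths at 1, 3, 4 with a censor at 2: S = 4/5, 4/5*2/3, 4/15
  five <- km_curve(c(1, 2, 3, 4, 10), c(1, 0, 1, 1, 0), rep("all", 5))
  ev <- five$curves[five$curves$n_event > 0, ]
  expect_equal(ev$surv, c(4 / 5, 8 / 15, 4 / 15))

  set.seed(91)
  tt <- rexp(40); evs <- rbinom(40, 1, 0.7)
  g <- rep(c("a", "b"), 20)
  kc <- km_curve(tt, evs, g)
  for (gg in c("a", "b")) {
    s <- kc$curves$surv[kc$curves$group == gg]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("the log-rank test matches the observed-minus-expected computation", {
  tt <- c(1, 2, 3, 1, 2, 3); evs <- rep(1, 6)
  g <- rep(c("a", "b"), each = 3)
  same <- logrank_test(tt, evs, g)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  t6 <- c(1, 3, 5, 2, 4, 9); e6 <- c(1, 1, 0, 1, 1, 1)
  g6 <- rep(c("x", "y"), each = 3)
  got <- logrank_test(t6, e6, g6)
  want <- brute_logrank(t6, e6, g6)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-8)
  expect_equal(got$p, want$p, tolerance = 1e-8)
  # label swap leaves the statistic untouched
  sw <- logrank_test(t6, e6, ifelse(g6 == "x", "y", "x"))
  expect_equal(sw$statistic, got$statistic)
  expect_error(logrank_test(t6, e6, rep("x", 6)), "two")
})

test_that("risk model scaling and stratification invariants hold", {
  set.seed(101)
  m <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("f", 1:6), paste0("p", 1:10)))
  cf <- setNames(rnorm(6), rownames(m))
  s1 <- compute_risk_score(m, cf)
  s2 <- compute_risk_score(m, cf * 3)
  expect_equal(s2, s1 * 3)
  expect_identical(stratify(s1)$group, stratify(s2)$group)
})

test_that("building a pilot-sized risk model warns and separates planted risk", {
  cfg <- sim_config(seed = 41L, n_circ_loci = 60L, n_lnc = 40L,
                    n_mrna = 60L)
  ds <- simulate_dataset(cfg)
  counts <- rbind(ds$lnc, ds$mrna)[1:20, ]
  sf <- estimate_size_factors(setNames(ds$meta$total_linear_mapped_reads,
                                       ds$meta$sample_id))
  expect_warning(
    rm <- build_risk_model(counts, sf, ds$meta),
    "unstable")
  expect_setequal(names(rm$scores), ds$meta$sample_id)
  expect_equal(sort(unique(unname(rm$group))), c("high", "low"))
  expect_s3_class(rm$os$km$fit, "survfit")
  expect_true(rm$os$logrank$p >= 0 && rm$os$logrank$p <= 1)
})
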