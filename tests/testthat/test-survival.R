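test_that("Cox fit matches a 1-D grid/optimise oracle of the Breslow partial likelihood", {
  tm <- c(1, 2, 3, 4, 5, 6)
  ev <- rep(1, 6)
  x <- c(1, 0, 1, 0, 0, 1)
  ## independent Breslow partial log-likelihood, maximised numerically
  pll <- function(b) {
    ll <- 0
    for (i in order(tm)) {
      risk <- tm >= tm[i]
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    ll
  }
  bhat <- optimize(pll, c(-5, 5), maximum = TRUE)$maximum
  f <- coxFit(x, tm, ev)
  expect_equal(unname(f$beta), bhat, tolerance = 1e-4)
  expect_true(f$converged)
  expect_false(f$separated)
})

test_that("separation and degenerate covariates are flagged, not silent", {
  ## x perfectly ordered with failure times: monotone likelihood
  f <- suppressWarnings(coxFit(c(1, 0), c(1, 2), c(1, 1)))
  expect_true(f$separated || !f$converged)
  expect_error(coxFit(rep(1, 5), 1:5, rep(1, 5)), "constant covariate")
  expect_error(coxFit(1:5, 1:5, rep(0, 5)), "at least one event")
})

test_that("planted proportional-hazards effect is recovered at n = 500", {
  cfg <- simConfig(seed = 404)
  set.seed(404)
  expr <- matrix(rnorm(50 * 500), 50, 500,
                 dimnames = list(sprintf("g%02d", 1:50), sprintf("s%03d", 1:500)))
  sv <- simulateSurvival(cfg, expr, gene = "g07")
  expect_equal(mean(1 - sv$surv$event), 0.2, tolerance = 0.05)
  f <- coxFit(as.numeric(expr["g07", ]), sv$surv$time, sv$surv$event)
  expect_lt(abs(unname(f$beta) - 0.7), 0.15)
})

test_that("the partial likelihood is invariant to shifts and equivariant to scaling", {
  set.seed(42)
  n <- 120
  x <- rnorm(n)
  tm <- rexp(n, exp(0.5 * x))
  ev <- rbinom(n, 1, 0.85)
  f <- coxFit(x, tm, ev)
  fShift <- coxFit(x + 10, tm, ev)
  expect_equal(f$beta, fShift$beta, tolerance = 1e-6, ignore_attr = TRUE)
  fScale <- coxFit(x * 4, tm, ev)
  expect_equal(unname(f$beta) / 4, unname(fScale$beta), tolerance = 1e-6)
})

test_that("univariate screen retains a strong gene among nulls and can retain nothing", {
  set.seed(55)
  expr <- matrix(rnorm(51 * 200), 51, 200,
                 dimnames = list(c("driver", sprintf("null%02d", 1:50)), NULL))
  lp <- 1.2 * expr["driver", ]
  tm <- rexp(200, 0.05 * exp(lp))
  scr <- univariateScreen(expr, tm, rep(1, 200))
  expect_true(scr$retained[scr$geneId == "driver"])
  expect_lte(sum(scr$retained & scr$geneId != "driver"), 2)

  set.seed(56)
  nullExpr <- matrix(rnorm(20 * 80), 20, 80,
                     dimnames = list(sprintf("n%02d", 1:20), NULL))
  scr0 <- univariateScreen(nullExpr, rexp(80, 0.05), rbinom(80, 1, 0.8))
  if (!any(scr0$retained)) {
    expect_message(
      expect_null(buildRiskModel(nullExpr, rexp(80, 0.05), rbinom(80, 1, 0.8),
                                 screen = scr0)),
      "no signature")
  }
})

test_that("risk model keeps the top |z| genes, scores linearly and splits at the median", {
  set.seed(57)
  n <- 300
  expr <- matrix(rnorm(30 * n), 30, n,
                 dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:n)))
  lp <- 0.9 * expr["g01", ] - 0.7 * expr["g02", ]
  tm <- rexp(n, 0.05 * exp(lp))
  ev <- rbinom(n, 1, 0.85)
  model <- buildRiskModel(expr, tm, ev, signatureSize = 4)
  expect_true(all(c("g01", "g02") %in% signatureGenes(model)))
  rs <- riskScores(model, expr)
  expect_equal(unname(rs),
               as.numeric(crossprod(expr[signatureGenes(model), ], model@beta)))
  grp <- riskGroups(model, expr)
  expect_equal(sum(grp == "high"), sum(rs > median(rs)))
  ## risk score correlates with the true linear predictor
  expect_gt(cor(rs, lp, method = "spearman"), 0.9)
  expect_output(show(model), "CoxRiskModel")
})

test_that("single positive-coefficient gene gives risk ordering equal to expression ordering", {
  set.seed(58)
  n <- 150
  expr <- matrix(rnorm(2 * n), 2, n, dimnames = list(c("gA", "gB"), NULL))
  tm <- rexp(n, 0.05 * exp(expr["gA", ]))
  model <- buildRiskModel(expr, tm, rep(1, n), signatureSize = 1)
  expect_equal(signatureGenes(model), "gA")
  rs <- riskScores(model, expr)
  expect_equal(order(rs), order(expr["gA", ] * sign(model@beta[1])))
})

test_that("KM estimates are proper survival curves and log-rank matches the O-E oracle", {
  tm <- c(1, 2, 3, 4, 5, 6)
  ev <- rep(1, 6)
  grp <- rep(c("g1", "g2"), each = 3)
  res <- kmLogrank(grp, tm, ev)
  ## independent O-E / variance summation over the six event times
  O1 <- 3; E1 <- 0; V <- 0
  for (t in tm) {
    n1 <- sum(tm >= t & grp == "g1"); n2 <- sum(tm >= t & grp == "g2")
    n <- n1 + n2
    E1 <- E1 + n1 / n
    if (n > 1) V <- V + n1 * n2 * (n - 1) / (n^2 * (n - 1))
  }
  expect_equal(res$chisq, (O1 - E1)^2 / V, tolerance = 1e-6)
  expect_equal(res$p, pchisq((O1 - E1)^2 / V, 1, lower.tail = FALSE),
               tolerance = 1e-6)

  s <- summary(res$fit)$surv
  expect_true(all(diff(s[1:3]) <= 0))

  dup <- kmLogrank(rep(c("a", "b"), each = 6), rep(tm, 2), rep(ev, 2))
  expect_equal(dup$chisq, 0, tolerance = 1e-10)
  expect_equal(dup$p, 1, tolerance = 1e-6)

  expect_warning(none <- kmLogrank(grp, tm, rep(0, 6)), "no events")
  expect_equal(none$p, 1)
  expect_true(all(summary(none$fit)$surv == 1))
})
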