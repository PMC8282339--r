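test_that("Sidak adjustment", {
  expect_equal(sidakAdjust(0.04, 1), 0.04)
  expect_equal(sidakAdjust(0.01, 3), 1 - 0.99^3)
  expect_equal(round(sidakAdjust(0.01, 3), 4), 0.0297)
  expect_equal(sidakAdjust(1, 5), 1)
  expect_error(sidakAdjust(1.2, 2), "\\[0, 1\\]")
})

test_that("paired comparison: identical conditions give null contrasts", {
  d <- data.frame(patient = rep(1:8, each = 2),
                  condition = rep(c("with", "without"), 8),
                  group = rep(c("cancer", "normal"), each = 8),
                  value = rep(rnorm(8, 7.2, 0.1), each = 2))
  res <- pairedConditionTest(d)
  expect_equal(res$contrasts$estimate, c(0, 0), tolerance = 1e-10)
  expect_true(all(res$contrasts$p_sidak > 0.99))
})

test_that("single-group balanced design reproduces the paired t-test", {
  set.seed(14)
  n <- 12
  base <- rnorm(n, 7.2, 0.1)
  d <- data.frame(patient = rep(seq_len(n), each = 2),
                  condition = rep(c("with", "without"), n),
                  group = "all",
                  value = c(rbind(base + 0.15 + rnorm(n, 0, 0.05), base)))
  res <- pairedConditionTest(d)
  w <- d$value[d$condition == "with"]; wo <- d$value[d$condition == "without"]
  tt <- t.test(w, wo, paired = TRUE)
  expect_equal(res$contrasts$p, tt$p.value, tolerance = 1e-6)
  expect_equal(res$contrasts$estimate, unname(tt$estimate),
               tolerance = 1e-8)
})

test_that("interaction p-value is uniform under the null", {
  set.seed(99)
  nSim <- 400
  ps <- vapply(seq_len(nSim), function(i) {
    n <- 10
    d <- data.frame(patient = rep(seq_len(2 * n), each = 2),
                    condition = rep(c("A", "B"), 2 * n),
                    group = rep(c("g1", "g2"), each = 2 * n),
                    value = rnorm(4 * n) + rep(rnorm(2 * n), each = 2))
    pairedConditionTest(d)$interaction_p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("chi-squared trend: null, signal vs permutation oracle, degenerate", {
  nul <- chi2Trend(cbind(c(10, 10, 10), c(20, 20, 20)))
  expect_equal(unname(nul["chi2"]), 0, tolerance = 1e-12)
  expect_equal(unname(nul["p"]), 1)

  tab <- rbind(c(10, 30), c(20, 20), c(30, 10)) # 2x3 trend table
  res <- chi2Trend(tab)
  expect_lt(res["p"], 0.05)

  # Monte-Carlo permutation oracle: permute group labels, recompute
  set.seed(1)
  labels <- rep(rep(seq_len(nrow(tab)), times = 2),
                times = c(t(tab)))
  groups <- rep(rep(1:2, nrow(tab)), times = c(t(tab)))
  obs <- unname(res["chi2"])
  perm <- replicate(4000, {
    g <- sample(groups)
    unname(suppressWarnings(chi2Trend(table(labels, g)))["chi2"])
  })
  pPerm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(pPerm - res["p"]), 3 * sqrt(res["p"] / 4000) + 0.005)

  expect_error(chi2Trend(matrix(c(5, 5), nrow = 1)), ">= 2 ordinal")
  expect_warning(chi2Trend(rbind(c(0, 0), c(5, 5), c(2, 8))), "zero-margin")
})

test_that("Spearman: perfect ranks, reversal, null behavior", {
  x <- c(1, 3, 7, 9, 15)
  expect_equal(unname(spearmanCor(x, x * 2 + 1)["rho"]), 1)
  expect_equal(unname(spearmanCor(x, rev(x))["rho"]), -1)
  const <- spearmanCor(rep(1, 5), 1:5)
  expect_true(is.na(const["rho"]))

  set.seed(7)
  rejects <- mean(replicate(500, {
    unname(spearmanCor(rnorm(50), rnorm(50))["p"]) < 0.05
  }))
  expect_lt(abs(rejects - 0.05), 0.03)

  # cross-check against cor.test's rho with ties
  set.seed(8)
  a <- sample(1:5, 30, replace = TRUE); b <- sample(1:5, 30, replace = TRUE)
  expect_equal(unname(spearmanCor(a, b)["rho"]),
               unname(suppressWarnings(
                 cor.test(a, b, method = "spearman")$estimate)),
               tolerance = 1e-12)
})

test_that("multiple linear regression: exactness and CI coverage", {
  d <- data.frame(x1 = 1:20, x2 = rep(c(0, 1), 10))
  d$y <- 2 + 0.5 * d$x1 - 1.5 * d$x2
  fit <- olsRegress(y ~ x1 + x2, d)
  expect_equal(fit$coefficients$estimate, c(2, 0.5, -1.5), tolerance = 1e-10)

  fit0 <- olsRegress(y ~ 1, d)
  expect_equal(fit0$coefficients$estimate, mean(d$y))

  d$x3 <- d$x1 * 2
  expect_error(olsRegress(y ~ x1 + x3, d), "aliased: x3")

  set.seed(3)
  cover <- mean(replicate(200, {
    n <- 60
    x <- rnorm(n)
    y <- 1 + 0.8 * x + rnorm(n)
    ci <- olsRegress(y ~ x, data.frame(x = x, y = y))$coefficients[2, ]
    ci$lower <= 0.8 && 0.8 <= ci$upper
  }))
  expect_gt(cover, 0.90)
  expect_lt(cover, 0.99)
})

test_that("binomial logistic: null, separation, simulated recovery", {
  set.seed(4)
  d <- data.frame(x = rnorm(400), y = rbinom(400, 1, 0.5))
  f <- logisticBinomial(y ~ x, d)
  ci <- f$oddsRatios[2, ]
  expect_true(ci$lower <= 1 && 1 <= ci$upper)

  sep <- data.frame(x = c(-(10:1), 1:10), y = rep(c(0, 1), each = 10))
  expect_error(logisticBinomial(y ~ x, sep), "separation")

  expect_error(logisticBinomial(y ~ x, data.frame(x = rnorm(10),
                                                  y = rep(1, 10))),
               "both outcome classes")

  # node-metastasis slope ln(1.54) per 10 mM/min recovered at n = 2000
  co <- simulateCohort(cohortSpec(nPatients = 2000), seed = 41)
  f2 <- logisticBinomial(node_status ~ nbc_flux + nbcn1_score + nhe1_score,
                         co$patients)
  ci2 <- f2$oddsRatios[f2$oddsRatios$term == "nbc_flux", ]
  expect_true(ci2$lower^10 <= 1.54 && 1.54 <= ci2$upper^10)
})

test_that("logistic MLE matches direct likelihood maximization", {
  set.seed(5)
  n <- 150
  d <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  d$y <- rbinom(n, 1, plogis(-0.3 + 0.9 * d$x1 - 0.6 * d$x2))
  fit <- logisticBinomial(y ~ x1 + x2, d)
  nll <- function(b) {
    eta <- b[1] + b[2] * d$x1 + b[3] * d$x2
    -sum(d$y * eta - log1p(exp(eta)))
  }
  opt <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(fit$coefficients$estimate, opt$par, tolerance = 1e-4)
})

test_that("ordinal logistic: closed-form thresholds, reduction, recovery", {
  # intercept-only: thresholds are the observed cumulative logits
  y <- factor(rep(c("a", "b", "c"), times = c(30, 50, 20)), ordered = TRUE)
  d <- data.frame(y = y, one = 1)
  fit <- logisticOrdinal(y ~ 1, d)
  cum <- cumsum(c(30, 50)) / 100
  expect_equal(unname(fit$thresholds), qlogis(cum), tolerance = 1e-4)

  # two-level outcome reduces to binomial logistic
  set.seed(6)
  d2 <- data.frame(x = rnorm(300))
  d2$y <- factor(rbinom(300, 1, plogis(0.5 + 0.8 * d2$x)), ordered = TRUE)
  ofit <- logisticOrdinal(y ~ x, d2)
  bfit <- logisticBinomial(y ~ x, transform(d2, y = as.integer(y) - 1))
  expect_equal(ofit$coefficients$estimate, bfit$coefficients$estimate[2],
               tolerance = 1e-4)

  # proportional-odds slope recovery within its CI
  set.seed(16)
  n <- 800
  x <- rnorm(n)
  eta <- 1.1 * x
  u <- runif(n)
  cum1 <- plogis(-0.8 - eta); cum2 <- plogis(0.9 - eta)
  yy <- factor(ifelse(u < cum1, 1, ifelse(u < cum2, 2, 3)), ordered = TRUE)
  rfit <- logisticOrdinal(y ~ x, data.frame(y = yy, x = x))
  ci <- rfit$coefficients[1, ]
  expect_true(ci$lower <= 1.1 && 1.1 <= ci$upper)
})

test_that("reference-level encoding does not change fitted probabilities", {
  co <- simulateCohort(cohortSpec(nPatients = 300), seed = 51)
  d <- co$patients
  f1 <- logisticBinomial(ki67_group ~ delta_phi + histology, d)
  d2 <- d
  d2$histology <- relevel(d$histology, "lobular")
  f2 <- logisticBinomial(ki67_group ~ delta_phi + histology, d2)
  expect_equal(unname(f1$fit$fitted.values), unname(f2$fit$fitted.values),
               tolerance = 1e-9)
})

test_that("cohort descriptives reproduce the table layout", {
  co <- simulateCohort(cohortSpec(nPatients = 110), seed = 61)
  de <- cohortDescriptives(co$patients)
  expect_equal(de$n_patients, 110)
  expect_true(all(c("median", "q1", "q3") %in% names(de$age)))
  expect_equal(sum(de$histology$n), 110)
  expect_equal(sum(de$histology$pct), 100, tolerance = 0.5)
})
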