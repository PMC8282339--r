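test_that("probe collapse keeps the max-mean probe, deterministic ties", {
  m <- rbind(G1_at1 = c(2, 4), G1_at2 = c(4, 6), G2_at1 = c(1, 1))
  colnames(m) <- c("s1", "s2")
  pm <- data.frame(probe = rownames(m), gene = c("G1", "G1", "G2"))
  g <- collapseProbes(m, pm)
  expect_equal(g["G1", ], c(s1 = 4, s2 = 6))        # mean 5 beats mean 3
  expect_equal(g["G2", ], c(s1 = 1, s2 = 1))        # single probe unchanged

  # exact tie: lexicographically first probe id wins
  m2 <- rbind(G1_b = c(1, 3), G1_a = c(3, 1))
  colnames(m2) <- c("s1", "s2")
  pm2 <- data.frame(probe = rownames(m2), gene = "G1")
  expect_message(g2 <- collapseProbes(m2, pm2), "lexicographically")
  expect_equal(unname(attr(g2, "chosenProbes")["G1"]), "G1_a")

  expect_error(collapseProbes(m, pm[0, ]), "empty probe map")
  expect_warning(collapseProbes(rbind(m, X_at1 = c(0, 0)), pm), "unmapped")
})

test_that("cross-sample standardization uses the population SD", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5))
  colnames(m) <- paste0("s", 1:3)
  z <- standardizeMatrix(m)
  expect_equal(unname(z["g1", ]), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-12)          # population SD divisor n
  expect_equal(round(unname(z["g1", 1]), 4), -1.2247)
  expect_equal(unname(z["g2", ]), c(0, 0, 0))
  expect_equal(attr(z, "zeroSD"), "g2")
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_error(standardizeMatrix(m[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("combine-and-restandardize removes batch structure", {
  set.seed(11)
  base <- matrix(rnorm(5 * 40), 5, 40,
                 dimnames = list(paste0("g", 1:5), paste0("a", 1:40)))
  d1 <- base[, 1:20]; d2 <- base[, 21:40] * 3 + 7
  colnames(d2) <- paste0("b", 1:20)
  z <- combineAndRestandardize(list(d1, d2))
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_equal(unname(apply(z, 1, function(x) sqrt(mean((x - mean(x))^2)))),
               rep(1, 5), tolerance = 1e-12)
  # per-dataset gene means agree after standardization (batch removed)
  m1 <- rowMeans(z[, 1:20]); m2 <- rowMeans(z[, 21:40])
  expect_equal(unname(m1), -unname(m2), tolerance = 1e-12)

  # a single dataset: second pass is a no-op
  z1 <- standardizeMatrix(d1)
  z2 <- combineAndRestandardize(list(d1))
  expect_equal(z2, z1, tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(combineAndRestandardize(list(d1, matrix(1:4, 2, 2,
    dimnames = list(c("x1", "x2"), c("c1", "c2"))))), "empty gene")
})

test_that("nearest-centroid subtype assignment", {
  ce <- syntheticCentroids()
  # a sample equal to a centroid gets that label
  m <- ce[, c("basal", "lumA")]
  colnames(m) <- c("sA", "sB")
  expect_equal(unname(assignSubtypes(m, ce)), c("basal", "lumA"))

  # well-separated synthetic subtypes: >= 99% accuracy at noise SD 0.1
  spec <- expressionStudySpec(datasetSizes = c(d1 = 150, d2 = 150),
                              noiseSD = 0.1, batchLocation = c(0, 0),
                              batchScale = c(1, 1), probesPerGene = 1)
  sim <- simulateExpressionStudy(spec, seed = 12)
  g <- collapseProbes(sim$probeMatrix, sim$probeMap)
  lab <- assignSubtypes(standardizeMatrix(g), ce)
  expect_gte(mean(lab == unname(sim$truth$subtype)), 0.99)

  expect_error(assignSubtypes(m[1:3, ], ce), "centroid genes")
})

test_that("z-score stratification honors thresholds and the death rule", {
  z <- c(0.6, -0.7, 0.2)
  st <- stratifyByZ(z, time = c(5, 5, 5), event = c(1, 1, 1),
                    stratificationRule(minDeaths = 1))
  expect_equal(as.character(st$group), c("high", "low", NA))
  expect_false(st$usedFallback)

  # 9 deaths in the high group at primary thresholds -> fallback 0.3/-0.3
  set.seed(2)
  z2 <- c(rep(0.7, 9), rep(0.4, 30), rep(-0.7, 40), rnorm(40, 0, 0.1))
  ev <- c(rep(1, 9), rep(1, 30), rep(1, 40), rep(0, 40))
  st2 <- stratifyByZ(z2, time = rep(3, length(z2)), event = ev)
  expect_true(st2$usedFallback)
  expect_equal(unname(st2$thresholds), c(0.3, -0.3))
  expect_gte(unname(st2$deaths["high"]), 10)

  expect_error(stratifyByZ(c(0.1, -0.1, 0.2), time = rep(1, 3),
                           event = rep(1, 3)),
               "stratification error")
})

test_that("Kaplan-Meier estimator matches the hand product-limit", {
  allCens <- kmCurve(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(allCens$surv == 1))

  km <- kmCurve(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km$surv[km$time == 1], 2 / 3)
  expect_equal(km$surv[km$time == 2], 1 / 3)
  expect_equal(km$surv[km$time == 3], 1 / 3)   # censored tick, flat
  expect_equal(km$n_censor[km$time == 3], 1)

  single <- kmCurve(1, 1)
  expect_equal(single$surv, 0)
  expect_error(kmCurve(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank and Wilcoxon: nulls, hand computation, cross-check", {
  # two identical groups: statistic 0
  tt <- c(1, 2, 3, 4, 1, 2, 3, 4)
  ee <- c(1, 1, 0, 1, 1, 1, 0, 1)
  gg <- rep(c("a", "b"), each = 4)
  lr <- logrankTest(tt, ee, gg)
  expect_equal(unname(lr["chi2"]), 0, tolerance = 1e-12)
  expect_equal(unname(lr["p"]), 1)

  # toy data, hand-computed O-E/V
  t2 <- c(1, 2, 3, 4, 5, 6)
  e2 <- c(1, 1, 1, 1, 1, 0)
  g2 <- c("a", "b", "a", "b", "a", "b")
  # event times 1..5; at t=1: n=6 (3a,3b), death in a: E_a = 1/2, V = 1/4 * (3*3)/(36) ... accumulate
  oe <- pHflux:::.weightedOE(t2, e2, factor(g2))
  handU <- (1 - 3 / 6) + (0 - 2 / 5) + (1 - 2 / 4) + (0 - 1 / 3) + (1 - 1 / 2)
  expect_equal(unname(oe$U), handU, tolerance = 1e-9)
  handV <- (3 * 3) / 36 + (2 * 3) / 25 + (2 * 2) / 16 + (1 * 2) / 9 +
    (1 * 1) / 4
  expect_equal(unname(oe$V[1, 1]), handV, tolerance = 1e-9)

  # independent cross-check of the log-rank path against survival::survdiff
  set.seed(19)
  tt3 <- rexp(60, rep(c(0.1, 0.2), each = 30))
  ee3 <- rbinom(60, 1, 0.8)
  gg3 <- rep(c("a", "b"), each = 30)
  sd0 <- survival::survdiff(survival::Surv(tt3, ee3) ~ gg3)
  expect_equal(unname(logrankTest(tt3, ee3, gg3)["chi2"]),
               unname(sd0$chisq), tolerance = 1e-9)

  # with constant weights the Wilcoxon machinery equals the log-rank
  oeW <- pHflux:::.weightedOE(tt3, ee3, factor(gg3),
                              weightFun = function(n) 1)
  expect_equal(pHflux:::.oeChi2(oeW)["chi2"], logrankTest(tt3, ee3, gg3)["chi2"])
  # and at-risk weights differ from it on real data
  expect_false(isTRUE(all.equal(
    unname(gehanBreslowWilcoxon(tt3, ee3, gg3)["chi2"]),
    unname(logrankTest(tt3, ee3, gg3)["chi2"]))))

  expect_error(logrankTest(c(1, 2), c(0, 0), c("a", "b")), "no events")
})

test_that("Mantel-Haenszel hazard ratio", {
  tt <- c(1, 2, 3, 4, 1, 2, 3, 4)
  ee <- c(1, 1, 0, 1, 1, 1, 0, 1)
  gg <- factor(rep(c("low", "high"), each = 4), levels = c("low", "high"))
  hr <- hazardRatioMH(tt, ee, gg)
  expect_equal(unname(hr["hr"]), 1, tolerance = 1e-12)

  # swapped group labels give the reciprocal
  set.seed(23)
  t2 <- rexp(200, rep(c(0.1, 0.2), each = 100))
  e2 <- rep(1, 200)
  g2 <- factor(rep(c("low", "high"), each = 100), levels = c("low", "high"))
  h1 <- hazardRatioMH(t2, e2, g2)
  h2 <- hazardRatioMH(t2, e2, factor(g2, levels = c("high", "low")))
  expect_equal(unname(h1["hr"]), 1 / unname(h2["hr"]), tolerance = 1e-9)

  # exponential groups with rate ratio 2 at n = 1000: truth in the CI
  set.seed(29)
  t3 <- rexp(1000, rep(c(0.05, 0.10), each = 500))
  e3 <- rep(1, 1000)
  g3 <- factor(rep(c("low", "high"), each = 500), levels = c("low", "high"))
  h3 <- hazardRatioMH(t3, e3, g3)
  expect_true(h3["lower"] <= 2 && 2 <= h3["upper"])
})

test_that("partial correlation", {
  set.seed(31)
  x <- rnorm(100); y <- 0.5 * x + rnorm(100)
  expect_equal(unname(partialCorrelation(x, y)["r"]), cor(x, y),
               tolerance = 1e-12)
  expect_equal(unname(partialCorrelation(x, x)["r"]), 1)

  # x and y driven only by a shared covariate: partial r near zero
  z <- rnorm(500)
  x2 <- 2 * z + rnorm(500, 0, 0.5)
  y2 <- -1.5 * z + rnorm(500, 0, 0.5)
  pc <- partialCorrelation(x2, y2, covariates = z)
  expect_lt(abs(pc["r"]), 0.12)
  expect_gt(abs(cor(x2, y2)), 0.5)          # the marginal r is large

  expect_error(partialCorrelation(x2, y2, covariates = cbind(z, z)),
               "rank-deficient")
})

test_that("full meta-analysis keeps exact normalization identities", {
  sim <- simulateExpressionStudy(expressionStudySpec(), seed = 17)
  cd <- SummarizedExperiment::colData(sim$study)
  meta <- suppressMessages(survivalMetaAnalysis(
    sim$probeMatrix, sim$probeMap, cd$dataset, cd$time, cd$event,
    centroids = sim$truth$spec$centroids,
    targets = data.frame(gene = "SLC4A7", subtype = NA)))
  z <- meta$z
  expect_lt(max(abs(rowMeans(z))), 1e-9)
  sdp <- apply(z, 1, function(x) sqrt(mean((x - mean(x))^2)))
  expect_lt(max(abs(sdp - 1)), 1e-9)
  # whole-population survival contrast ran and reported its thresholds
  r <- meta$results[["SLC4A7|all"]]
  expect_s4_class(r, "SurvivalResult")
  expect_true(all(c("high", "low") %in% names(r@thresholds)))
})
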