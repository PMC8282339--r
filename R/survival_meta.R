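#' Collapse probe-level rows to one row per gene
#'
#' For genes measured by several probes, keeps the probe with the largest
#' mean intensity across samples; exact ties resolve to the
#' lexicographically first probe id (logged via message). Unmapped probes
#' are dropped with a warning.
#'
#' @param mat probes x samples matrix (rownames = probe ids).
#' @param probeMap data.frame with columns `probe`, `gene`.
#' @return genes x samples matrix, with attribute `chosenProbes`.
#' @export
collapseProbes <- function(mat, probeMap) {
  if (!nrow(probeMap)) stop("empty probe map")
  unmapped <- setdiff(rownames(mat), probeMap$probe)
  if (length(unmapped)) {
    warning("dropping ", length(unmapped), " unmapped probe(s)")
    mat <- mat[rownames(mat) %in% probeMap$probe, , drop = FALSE]
  }
  gene <- probeMap$gene[match(rownames(mat), probeMap$probe)]
  means <- rowMeans(mat)
  chosen <- vapply(split(seq_len(nrow(mat)), gene), function(idx) {
    m <- means[idx]
    best <- idx[m == max(m)]
    if (length(best) > 1) {
      best <- best[order(rownames(mat)[best])][1]
      message("probe tie for gene resolved lexicographically: ",
              rownames(mat)[best])
    }
    best[1]
  }, integer(1))
  out <- mat[chosen, , drop = FALSE]
  rownames(out) <- names(chosen)
  attr(out, "chosenProbes") <- setNames(rownames(mat)[chosen], names(chosen))
  out
}

#' Cross-sample standardization (population SD)
#'
#' Per gene: subtract the mean across samples and divide by the
#' population standard deviation (divisor n). Genes with zero SD are set
#' to 0 and recorded in the `zeroSD` attribute.
#'
#' @param mat genes x samples matrix (>= 2 samples).
#' @return standardized matrix with attribute `zeroSD`.
#' @export
standardizeMatrix <- function(mat) {
  if (ncol(mat) < 2) stop("need >= 2 samples to standardize")
  mu <- rowMeans(mat)
  sdp <- sqrt(rowMeans((mat - mu)^2))
  zero <- sdp == 0
  sdp[zero] <- 1
  out <- (mat - mu) / sdp
  out[zero, ] <- 0
  attr(out, "zeroSD") <- rownames(mat)[zero]
  out
}

#' Combine standardized datasets and re-standardize
#'
#' Standardizes each dataset separately, column-concatenates them over the
#' shared gene universe (the intersection, logged when genes are lost),
#' then applies a second round of cross-sample standardization to the
#' combined matrix.
#'
#' @param mats list of genes x samples matrices (one per dataset).
#' @return combined standardized matrix with attribute `sharedGenes`.
#' @export
combineAndRestandardize <- function(mats) {
  stopifnot(is.list(mats), length(mats) >= 1)
  shared <- Reduce(intersect, lapply(mats, rownames))
  if (!length(shared)) stop("empty gene intersection across datasets")
  lost <- unique(unlist(lapply(mats, function(m)
    setdiff(rownames(m), shared))))
  if (length(lost))
    message(length(lost), " gene(s) outside the shared universe dropped")
  std <- lapply(mats, function(m)
    standardizeMatrix(m[shared, , drop = FALSE]))
  combined <- do.call(cbind, std)
  out <- standardizeMatrix(combined)
  attr(out, "sharedGenes") <- shared
  out
}

#' Nearest-centroid molecular subtype assignment
#'
#' Assigns each sample the subtype whose centroid has the largest Spearman
#' correlation over the centroid genes. Correlation ties resolve
#' deterministically to the first centroid column (logged).
#'
#' @param mat genes x samples matrix.
#' @param centroids genes x subtypes centroid matrix.
#' @param minGeneFraction minimum fraction of centroid genes that must be
#'   present in `mat` (default 0.8).
#' @return named character vector of subtype labels per sample.
#' @export
assignSubtypes <- function(mat, centroids, minGeneFraction = 0.8) {
  common <- intersect(rownames(centroids), rownames(mat))
  if (length(common) < minGeneFraction * nrow(centroids))
    stop(sprintf("only %d/%d centroid genes present in the matrix",
                 length(common), nrow(centroids)))
  m <- mat[common, , drop = FALSE]
  ce <- centroids[common, , drop = FALSE]
  cors <- cor(m, ce, method = "spearman")
  labels <- apply(cors, 1, function(r) {
    best <- which(r == max(r))
    if (length(best) > 1)
      message("centroid correlation tie; first centroid kept")
    colnames(ce)[best[1]]
  })
  setNames(labels, colnames(mat))
}

#' Stratify samples by expression z-score
#'
#' High = `z > zHigh`, low = `z < zLow`, middle excluded. When either
#' group holds fewer than `minDeaths` deaths, the fallback thresholds are
#' applied and reported. An empty group after fallback is an error.
#'
#' @param z named numeric z-scores.
#' @param time,event aligned survival time and status (0/1).
#' @param rule a [StratificationRule-class].
#' @return list with `group` (factor "low"/"high", NA = excluded),
#'   `thresholds` (named c(high, low)), `usedFallback`, `deaths`
#'   (named c(high, low)).
#' @export
stratifyByZ <- function(z, time, event, rule = stratificationRule()) {
  stopifnot(length(z) == length(time), length(time) == length(event))
  cut1 <- function(hi, lo) {
    g <- rep(NA_character_, length(z))
    g[z > hi] <- "high"; g[z < lo] <- "low"
    factor(g, levels = c("low", "high"))
  }
  deathsIn <- function(g) c(
    high = sum(event[which(g == "high")], na.rm = TRUE),
    low = sum(event[which(g == "low")], na.rm = TRUE))

  g <- cut1(rule@zHigh, rule@zLow)
  d <- deathsIn(g)
  used <- c(high = rule@zHigh, low = rule@zLow)
  fallback <- FALSE
  if (any(d < rule@minDeaths)) {
    g <- cut1(rule@fallbackHigh, rule@fallbackLow)
    d <- deathsIn(g)
    used <- c(high = rule@fallbackHigh, low = rule@fallbackLow)
    fallback <- TRUE
  }
  if (!any(g == "high", na.rm = TRUE) || !any(g == "low", na.rm = TRUE))
    stop("stratification error: empty group after fallback thresholds")
  list(group = g, thresholds = used, usedFallback = fallback, deaths = d)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator via [survival::survfit()], returned as a tidy
#' table with censor marks.
#'
#' @param time,event survival time (>= 0) and status (0/1).
#' @param group optional grouping factor.
#' @return data.frame with columns group, time, n_risk, n_event, n_censor,
#'   surv.
#' @export
kmCurve <- function(time, event, group = NULL) {
  if (any(time < 0)) stop("negative survival time")
  if (is.null(group)) group <- factor(rep("all", length(time)))
  group <- droplevels(factor(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  if (length(levels(group)) == 1) {
    strata <- rep(levels(group), length(fit$time))
  } else {
    strata <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, n_censor = fit$n.censor,
             surv = fit$surv, stringsAsFactors = FALSE)
}

# weighted O-E machinery shared by the log-rank and Gehan-Breslow-Wilcoxon
# tests and the Mantel-Haenszel hazard ratio; weightFun maps the total
# number at risk at an event time to the weight of that time
.weightedOE <- function(time, event, group, weightFun = function(n) 1) {
  group <- droplevels(factor(group))
  k <- nlevels(group)
  if (k < 2) stop("need >= 2 groups")
  if (sum(event) < 1) stop("no events")
  eventTimes <- sort(unique(time[event == 1]))
  O <- E <- rep(0, k)
  U <- rep(0, k - 1)                      # weighted O-E, first k-1 groups
  V <- matrix(0, k - 1, k - 1)            # its covariance
  for (t in eventTimes) {
    atRisk <- time >= t
    n <- sum(atRisk)
    d <- sum(event == 1 & time == t)
    ng <- tabulate(group[atRisk], nbins = k)
    dg <- tabulate(group[event == 1 & time == t], nbins = k)
    eg <- d * ng / n
    w <- weightFun(n)
    O <- O + dg; E <- E + eg
    U <- U + w * (dg - eg)[-k]
    if (n > 1) {
      covFactor <- d * (n - d) / (n - 1)
      for (i in seq_len(k - 1)) for (j in seq_len(k - 1)) {
        V[i, j] <- V[i, j] + w^2 * covFactor *
          (ng[i] * ((i == j) * n - ng[j])) / n^2
      }
    }
  }
  list(O = O, E = E, U = U, V = V, k = k, levels = levels(group))
}

.oeChi2 <- function(oe) {
  chi2 <- tryCatch(drop(t(oe$U) %*% solve(oe$V) %*% oe$U),
                   error = function(e) NA_real_)
  df <- oe$k - 1
  c(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Log-rank (Mantel-Cox) test
#'
#' Unweighted observed-minus-expected test over event times; p from
#' chi-squared with groups-1 df.
#'
#' @param time,event survival data; `group` a factor with >= 2 levels.
#' @param group grouping factor.
#' @return named numeric `c(chi2, df, p)`.
#' @export
logrankTest <- function(time, event, group) {
  .oeChi2(.weightedOE(time, event, group))
}

#' Gehan-Breslow-Wilcoxon test
#'
#' The log-rank machinery with each event time weighted by the total
#' number at risk, emphasizing early survival differences.
#'
#' @inheritParams logrankTest
#' @return named numeric `c(chi2, df, p)`.
#' @export
gehanBreslowWilcoxon <- function(time, event, group) {
  .oeChi2(.weightedOE(time, event, group, weightFun = function(n) n))
}

#' Mantel-Haenszel hazard ratio for two groups
#'
#' `HR = (O1/E1) / (O2/E2)` with a normal-approximation confidence
#' interval on the log scale (`SE = sqrt(1/E1 + 1/E2)`). The reference
#' (denominator) group is the first factor level, so with levels
#' c("low", "high") an HR above 1 means worse survival in the
#' high-expression group.
#'
#' @inheritParams logrankTest
#' @param level confidence level (default 0.95).
#' @return named numeric `c(hr, lower, upper)`.
#' @export
hazardRatioMH <- function(time, event, group, level = 0.95) {
  oe <- .weightedOE(time, event, group)
  if (oe$k != 2) stop("hazard ratio needs exactly 2 groups")
  if (any(oe$E == 0)) stop("zero expected events in a group")
  if (any(oe$O == 0)) stop("need >= 1 observed event per group")
  # group order: (reference, comparison) = factor levels 1, 2
  lhr <- log((oe$O[2] / oe$E[2]) / (oe$O[1] / oe$E[1]))
  se <- sqrt(1 / oe$E[1] + 1 / oe$E[2])
  q <- qnorm(1 - (1 - level) / 2)
  c(hr = exp(lhr), lower = exp(lhr - q * se), upper = exp(lhr + q * se))
}

#' Compare survival between z-score-defined expression groups
#'
#' Applies [stratifyByZ()], then builds Kaplan-Meier curves and compares
#' the groups by the log-rank and Gehan-Breslow-Wilcoxon tests and the
#' Mantel-Haenszel hazard ratio (high vs low expression).
#'
#' @param z named numeric z-scores.
#' @param time,event aligned survival data.
#' @param rule a [StratificationRule-class].
#' @return a [SurvivalResult-class].
#' @export
survivalByZGroups <- function(z, time, event, rule = stratificationRule()) {
  st <- stratifyByZ(z, time, event, rule)
  keep <- !is.na(st$group)
  g <- droplevels(st$group[keep])
  tt <- time[keep]; ee <- event[keep]
  new("SurvivalResult",
      km = kmCurve(tt, ee, g),
      logrank = logrankTest(tt, ee, g),
      wilcoxon = gehanBreslowWilcoxon(tt, ee, g),
      hazardRatio = hazardRatioMH(tt, ee, g),
      thresholds = st$thresholds,
      groupSizes = setNames(as.integer(table(g)), levels(g)),
      groupDeaths = setNames(as.integer(st$deaths[c("low", "high")]),
                             c("low", "high")))
}

#' Partial correlation
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' projection on the covariates; with no covariates this is the plain
#' Pearson correlation. p from the t approximation on `n - k - 2` df.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric matrix/data.frame of covariates.
#' @return named numeric `c(r, p, n)`.
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) {
    n <- sum(complete.cases(x, y))
    r <- cor(x, y, use = "complete.obs")
    df <- n - 2
  } else {
    covariates <- as.matrix(covariates)
    ok <- complete.cases(x, y, covariates)
    x <- x[ok]; y <- y[ok]
    cc <- covariates[ok, , drop = FALSE]
    n <- length(x)
    if (n <= ncol(cc) + 2) stop("need n > covariates + 2")
    if (qr(cbind(1, cc))$rank < ncol(cc) + 1)
      stop("rank-deficient covariate matrix")
    rx <- stats::resid(lm(x ~ cc))
    ry <- stats::resid(lm(y ~ cc))
    r <- cor(rx, ry)
    df <- n - ncol(cc) - 2
  }
  tstat <- r * sqrt(df / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(tstat), df)
  c(r = r, p = p, n = n)
}

#' Full transcriptomic survival meta-analysis
#'
#' The complete pipeline: collapse probes, standardize each dataset,
#' combine and re-standardize, assign molecular subtypes by nearest
#' centroid, and run the z-score-stratified survival comparison for each
#' requested gene within each requested subtype (or the whole population
#' with `subtype = NA`).
#'
#' @param probeMatrix probes x samples matrix.
#' @param probeMap data.frame probe -> gene.
#' @param dataset dataset id per sample.
#' @param time,event survival annotations per sample.
#' @param centroids genes x subtypes centroid matrix.
#' @param targets data.frame with columns `gene`, `subtype` (NA = all
#'   samples).
#' @param rule a [StratificationRule-class].
#' @param zWithinSubtype when TRUE, z-scores are recomputed within each
#'   target subtype's sample subset before thresholding; the default
#'   (FALSE) thresholds the combined-population z-scores.
#' @return list with `z` (combined standardized matrix), `subtype`
#'   (assigned labels), and `results` (named list of
#'   [SurvivalResult-class] per "gene|subtype" target; failed strata carry
#'   the error message instead).
#' @export
survivalMetaAnalysis <- function(probeMatrix, probeMap, dataset, time, event,
                                 centroids, targets,
                                 rule = stratificationRule(),
                                 zWithinSubtype = FALSE) {
  geneMat <- collapseProbes(probeMatrix, probeMap)
  mats <- lapply(split(seq_len(ncol(geneMat)), dataset),
                 function(i) geneMat[, i, drop = FALSE])
  z <- combineAndRestandardize(mats)
  # restore original sample order
  z <- z[, colnames(geneMat), drop = FALSE]
  subtype <- assignSubtypes(z, centroids)
  results <- list()
  for (i in seq_len(nrow(targets))) {
    gene <- targets$gene[i]; st <- targets$subtype[i]
    key <- paste(gene, ifelse(is.na(st), "all", st), sep = "|")
    idx <- if (is.na(st)) seq_along(subtype) else which(subtype == st)
    zg <- z[gene, idx]
    if (zWithinSubtype && length(idx) > 1) {
      zg <- (zg - mean(zg)) / sqrt(mean((zg - mean(zg))^2))
    }
    results[[key]] <- tryCatch(
      survivalByZGroups(zg, time[idx], event[idx], rule),
      error = function(e) conditionMessage(e))
  }
  list(z = z, subtype = subtype, results = results)
}
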