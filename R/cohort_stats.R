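#' Sidak multiple-comparisons adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, clipped to `[0, 1]`.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @param m number of comparisons (>= 1).
#' @return adjusted p-value(s).
#' @export
sidakAdjust <- function(p, m) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (m < 1) stop("m must be >= 1")
  pmin(pmax(1 - (1 - p)^m, 0), 1)
}

#' Paired +/-CO2/HCO3- comparison with a patient random intercept
#'
#' Fits `value ~ condition * group + (1 | patient)` by REML (the
#' mixed-effects analysis behind the paired condition comparisons), then
#' reports per-group condition contrasts with Sidak adjustment across
#' groups and the condition-by-group interaction p-value. With a single
#' group the model reduces to `value ~ condition + (1 | patient)` and, for
#' balanced complete data, reproduces the paired t-test.
#'
#' @param data data.frame with columns `value`, `condition` (2 levels),
#'   `group`, `patient`.
#' @return list with `contrasts` (data.frame: group, estimate, se, df, p,
#'   p_sidak), `interaction_p` (NA for a single group), `converged`,
#'   `method` ("mixed" or the paired-t fallback).
#' @export
pairedConditionTest <- function(data) {
  need <- c("value", "condition", "group", "patient")
  if (!all(need %in% names(data)))
    stop("data needs columns: ", paste(need, collapse = ", "))
  data$condition <- factor(data$condition)
  data$group <- factor(data$group)
  if (nlevels(data$condition) != 2)
    stop("condition must have exactly 2 levels")
  both <- tapply(data$condition, data$patient,
                 function(x) length(unique(x)) == 2)
  if (sum(both, na.rm = TRUE) < 2)
    stop("need >= 2 patients observed under both conditions")
  oneGroup <- nlevels(data$group) < 2

  fit <- tryCatch({
    form <- if (oneGroup) value ~ condition + (1 | patient)
            else value ~ condition * group + (1 | patient)
    suppressMessages(lmerTest::lmer(form, data = data, REML = TRUE))
  }, error = function(e) NULL)

  if (!is.null(fit)) {
    emm <- emmeans::emmeans(fit, if (oneGroup) ~condition else ~condition |
                              group, lmer.df = "satterthwaite")
    ctr <- summary(emmeans::contrast(emm, "pairwise",
                                     by = if (oneGroup) NULL else "group"))
    res <- data.frame(
      group = if (oneGroup) levels(data$group) else as.character(ctr$group),
      estimate = ctr$estimate, se = ctr$SE, df = ctr$df,
      p = ctr$p.value, stringsAsFactors = FALSE)
    res$p_sidak <- sidakAdjust(res$p, nrow(res))
    interP <- NA_real_
    if (!oneGroup) {
      av <- anova(fit, type = 3)
      interP <- av["condition:group", "Pr(>F)"]
    }
    return(list(contrasts = res, interaction_p = interP, converged = TRUE,
                method = "mixed"))
  }

  # fallback: paired t per group
  res <- do.call(rbind, lapply(levels(data$group), function(g) {
    d <- data[data$group == g, ]
    w <- stats::reshape(d[, c("patient", "condition", "value")],
                        idvar = "patient", timevar = "condition",
                        direction = "wide")
    x <- w[[2]] - w[[3]]
    tt <- stats::t.test(w[[2]], w[[3]], paired = TRUE)
    data.frame(group = g, estimate = unname(tt$estimate),
               se = sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))),
               df = unname(tt$parameter), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  res$p_sidak <- sidakAdjust(res$p, nrow(res))
  list(contrasts = res, interaction_p = NA_real_, converged = FALSE,
       method = "paired_t_fallback")
}

#' Chi-squared test for trend (Cochran-Armitage)
#'
#' Tests for a monotone trend in a binary outcome across ordered
#' categories (e.g. a 6-level IHC score), using integer scores. Rows
#' (ordinal levels) with zero margin are dropped with a warning.
#'
#' @param tab matrix of counts, ordinal levels x 2 groups (columns =
#'   binary outcome), or the transpose of that.
#' @return named numeric `c(chi2, df, p)`.
#' @export
chi2Trend <- function(tab) {
  tab <- as.matrix(tab)
  if (ncol(tab) != 2 && nrow(tab) == 2) tab <- t(tab)
  if (ncol(tab) != 2) stop("need an ordinal-by-binary count table")
  if (nrow(tab) < 2) stop("need >= 2 ordinal levels")
  zero <- rowSums(tab) == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-margin level(s)")
    tab <- tab[!zero, , drop = FALSE]
  }
  if (nrow(tab) < 2) stop("need >= 2 ordinal levels with nonzero margin")
  pt <- stats::prop.trend.test(tab[, 1], rowSums(tab),
                               score = seq_len(nrow(tab)))
  c(chi2 = unname(pt$statistic), df = 1, p = pt$p.value)
}

#' Spearman rank correlation
#'
#' Mid-rank Spearman rho with a t-approximation p-value
#' (`t = rho * sqrt((n-2)/(1-rho^2))` on n-2 df). Ties allowed.
#'
#' @param x,y numeric vectors, n >= 3.
#' @return named numeric `c(rho, p, n)`.
#' @export
spearmanCor <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    out <- c(rho = NA_real_, p = NA_real_, n = n)
    attr(out, "reason") <- "constant input: rho undefined"
    return(out)
  }
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  c(rho = rho, p = p, n = n)
}

# shared coefficient table for the regression wrappers
.coefTable <- function(est, se, df = Inf, level = 0.95) {
  q <- if (is.finite(df)) qt(1 - (1 - level) / 2, df) else
    qnorm(1 - (1 - level) / 2)
  stat <- est / se
  p <- if (is.finite(df)) 2 * pt(-abs(stat), df) else 2 * pnorm(-abs(stat))
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             lower = unname(est - q * se), upper = unname(est + q * se),
             p = unname(p), stringsAsFactors = FALSE)
}

#' Multiple linear regression
#'
#' Least-squares fit with Wald confidence intervals. Categorical
#' covariates use their declared factor reference levels; a rank-deficient
#' design is an error naming the aliased columns.
#'
#' @param formula model formula.
#' @param data data.frame.
#' @param level confidence level (default 0.95).
#' @return list with `coefficients` (term, estimate, se, lower, upper, p),
#'   `sigma`, `r_squared`, `n`, `fit` (the lm object).
#' @export
olsRegress <- function(formula, data, level = 0.95) {
  fit <- lm(formula, data = data)
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design; aliased: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  sm <- summary(fit)
  ct <- .coefTable(coef(fit), sm$coefficients[, "Std. Error"],
                   df = fit$df.residual, level = level)
  list(coefficients = ct, sigma = sm$sigma, r_squared = sm$r.squared,
       n = length(fit$residuals), fit = fit)
}

#' Binomial logistic regression with odds ratios
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' ([stats::glm()]), reporting odds ratios with Wald confidence intervals.
#' Complete or quasi-complete separation is detected (fitted probabilities
#' collapsing to 0/1 or non-convergence) and raised as an error rather
#' than silently returning divergent estimates.
#'
#' @param formula model formula with a binary outcome.
#' @param data data.frame.
#' @param level confidence level (default 0.95).
#' @return list with `coefficients` (log-odds scale), `oddsRatios` (term,
#'   or, lower, upper, p), `logLik`, `converged`, `n`, `fit`.
#' @export
logisticBinomial <- function(formula, data, level = 0.95) {
  mf <- stats::model.frame(formula, data)
  yv <- stats::model.response(mf)
  if (is.factor(yv)) yv <- as.integer(yv) - 1
  if (length(unique(yv)) < 2)
    stop("both outcome classes must be present")
  fit <- suppressWarnings(stats::glm(formula, data = data,
                                     family = stats::binomial()))
  eps <- 1e-8
  fitted <- fit$fitted.values
  sepLike <- (!fit$converged) ||
    (any(fitted < eps | fitted > 1 - eps) &&
       any(abs(coef(fit)) > 15, na.rm = TRUE))
  if (sepLike)
    stop("separation detected: logistic estimates are unbounded")
  if (any(is.na(coef(fit))))
    stop("rank-deficient design; aliased: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  se <- summary(fit)$coefficients[, "Std. Error"]
  ct <- .coefTable(coef(fit), se, df = Inf, level = level)
  ors <- data.frame(term = ct$term, or = exp(ct$estimate),
                    lower = exp(ct$lower), upper = exp(ct$upper), p = ct$p,
                    stringsAsFactors = FALSE)
  list(coefficients = ct, oddsRatios = ors,
       logLik = as.numeric(stats::logLik(fit)), converged = fit$converged,
       n = length(fitted), fit = fit)
}

#' Ordinal (proportional-odds) logistic regression
#'
#' Cumulative-logit maximum-likelihood fit via [MASS::polr()]. The
#' convention matches [logisticBinomial()]: positive coefficients raise
#' the odds of higher outcome levels. Thresholds must come out strictly
#' increasing, otherwise the fit is flagged as non-converged. With a
#' 2-level outcome the model coincides with binomial logistic regression.
#'
#' @param formula model formula with an ordered-factor (or coercible)
#'   outcome with >= 2 levels present.
#' @param data data.frame.
#' @param level confidence level (default 0.95).
#' @return list with `coefficients`, `oddsRatios`, `thresholds`,
#'   `logLik`, `converged`, `n`, `fit`.
#' @export
logisticOrdinal <- function(formula, data, level = 0.95) {
  mf <- stats::model.frame(formula, data)
  yv <- stats::model.response(mf)
  if (!is.ordered(yv)) yv <- factor(yv, ordered = TRUE)
  yv <- droplevels(yv)
  if (nlevels(yv) < 2) stop("need >= 2 outcome levels present")
  data2 <- data
  data2[[as.character(formula[[2]])]] <- yv
  if (nlevels(yv) == 2) {
    # the cumulative-logit model with two levels is binomial logistic
    data2[[as.character(formula[[2]])]] <- as.integer(yv) - 1L
    b <- logisticBinomial(formula, data2, level = level)
    return(list(coefficients = b$coefficients[-1, , drop = FALSE],
                oddsRatios = b$oddsRatios[-1, , drop = FALSE],
                thresholds = c("1|2" = -b$coefficients$estimate[1]),
                logLik = b$logLik, converged = b$converged, n = b$n,
                fit = b$fit))
  }
  fit <- suppressWarnings(MASS::polr(formula, data = data2, Hess = TRUE))
  thr <- fit$zeta
  converged <- fit$convergence == 0 && !is.unsorted(thr)
  if (!converged)
    warning("ordinal fit flagged: non-convergence or non-monotone thresholds")
  se <- sqrt(diag(stats::vcov(fit)))[seq_along(coef(fit))]
  ct <- .coefTable(coef(fit), se, df = Inf, level = level)
  ors <- data.frame(term = ct$term, or = exp(ct$estimate),
                    lower = exp(ct$lower), upper = exp(ct$upper), p = ct$p,
                    stringsAsFactors = FALSE)
  list(coefficients = ct, oddsRatios = ors, thresholds = thr,
       logLik = as.numeric(stats::logLik(fit)), converged = converged,
       n = fit$n, fit = fit)
}

#' Descriptive summary of a clinical cohort table
#'
#' Reproduces the layout of a clinicopathological characteristics table:
#' n, median (IQR) for continuous covariates, counts (percent) for
#' categorical ones.
#'
#' @param patients cohort data.frame (as from [simulateCohort()] or
#'   [readClinicalTable()]).
#' @return named list of summaries.
#' @export
cohortDescriptives <- function(patients) {
  qs <- function(x) {
    q <- stats::quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE)
    c(median = unname(q[1]), q1 = unname(q[2]), q3 = unname(q[3]))
  }
  tabPct <- function(x) {
    tb <- table(x)
    data.frame(level = names(tb), n = as.integer(tb),
               pct = round(100 * as.integer(tb) / sum(tb), 1),
               stringsAsFactors = FALSE)
  }
  out <- list(n_patients = nrow(patients))
  if ("age" %in% names(patients)) out$age <- qs(patients$age)
  if ("tumor_size_mm" %in% names(patients))
    out$tumor_size_mm <- qs(patients$tumor_size_mm)
  for (v in c("histology", "grade", "er_group", "her2", "ki67_group",
              "node_status"))
    if (v %in% names(patients)) out[[v]] <- tabPct(patients[[v]])
  out
}
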