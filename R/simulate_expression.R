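#' Synthetic molecular-subtype centroid matrix
#'
#' A deterministic gene x subtype centroid matrix for the five intrinsic
#' breast cancer subtypes (normal-like, luminal A, luminal B,
#' HER2-enriched, basal-like). The marker genes follow the expected
#' biology — ESR1/PGR high in luminal tumors, ERBB2 high in HER2-enriched,
#' MKI67 high in proliferative subtypes, SLC4A7 highest in luminal A and
#' low in HER2-enriched/basal-like, SLC16A1/SLC16A3 high in basal-like —
#' and the remaining genes carry reproducible pseudo-random structure.
#' This is a synthetic stand-in fixture, not a published classifier.
#'
#' @param nGenes total number of genes (>= 8; default 50).
#' @return numeric matrix, genes x 5 subtypes.
#' @export
syntheticCentroids <- function(nGenes = 50) {
  stopifnot(nGenes >= 8)
  subtypes <- c("normal", "lumA", "lumB", "her2", "basal")
  markers <- rbind(
    SLC9A1  = c(0.10, 0.20, 0.05, -0.10, -0.15),
    SLC4A7  = c(0.30, 0.60, 0.20, -0.40, -0.50),
    SLC16A1 = c(-0.25, -0.15, 0.10, 0.20, 0.50),
    SLC16A3 = c(-0.40, -0.20, 0.15, 0.25, 0.60),
    ESR1    = c(0.25, 0.75, 0.60, -0.60, -0.75),
    PGR     = c(0.25, 0.65, 0.40, -0.50, -0.65),
    ERBB2   = c(-0.15, -0.20, 0.10, 1.00, -0.25),
    MKI67   = c(-0.60, -0.40, 0.40, 0.30, 0.75))
  colnames(markers) <- subtypes
  extra <- nGenes - nrow(markers)
  if (extra > 0) {
    seedState <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(seedState))
      assign(".Random.seed", seedState, .GlobalEnv), add = TRUE)
    set.seed(197001)
    filler <- matrix(round(rnorm(extra * 5, 0, 0.45), 3), nrow = extra,
                     dimnames = list(sprintf("GENE%03d", seq_len(extra)),
                                     subtypes))
    markers <- rbind(markers, filler)
  }
  markers
}

#' Specification of a synthetic multi-dataset expression study
#'
#' Defaults emulate the seven-cohort, 1457-patient transcriptomic
#' meta-analysis: seven datasets with fixed sizes summing to 1457,
#' subtype mixing proportions, per-dataset location/scale batch shifts,
#' probe-level redundancy, and survival whose hazard depends on the
#' z-score group of chosen genes within chosen subtypes. Default survival
#' effects: hazard ratio 2.18 on SLC4A7 within luminal A and 2.14 within
#' basal-like tumors.
#'
#' @param datasetSizes named integer vector of samples per dataset.
#' @param mixing subtype mixing proportions (must sum to 1).
#' @param centroids gene x subtype centroid matrix.
#' @param noiseSD within-subtype expression SD.
#' @param batchLocation,batchScale per-dataset location/scale shifts.
#' @param probesPerGene integer vector recycled over genes: number of
#'   probes measuring each gene.
#' @param survivalEffects list of `list(gene=, subtype=, hr=)` effects.
#' @param hazardForm "group" (hazard acts on the z > zHigh / z < zLow
#'   group contrast so the group hazard ratio equals `hr` exactly) or
#'   "linear" (log-hazard linear in z with slope `log(hr)`).
#' @param rule a [StratificationRule-class] supplying the z thresholds.
#' @param baselineHazard,censoringRate exponential rates per year.
#' @param adminCensorYears administrative censoring horizon.
#' @return a validated spec (list) for [simulateExpressionStudy()].
#' @export
expressionStudySpec <- function(
    datasetSizes = c(vandeVijver = 295, GSE2034 = 286, GSE11121 = 200,
                     GSE3143 = 158, GSE1992 = 170, Guo = 189, Calza = 159),
    mixing = c(normal = 0.10, lumA = 0.35, lumB = 0.20, her2 = 0.12,
               basal = 0.23),
    centroids = syntheticCentroids(),
    noiseSD = 0.8,
    batchLocation = seq(-1.5, 1.5, length.out = length(datasetSizes)),
    batchScale = seq(0.8, 1.25, length.out = length(datasetSizes)),
    probesPerGene = c(2, 1, 3, 1),
    survivalEffects = list(
      list(gene = "SLC4A7", subtype = "lumA", hr = 2.18),
      list(gene = "SLC4A7", subtype = "basal", hr = 2.14)),
    hazardForm = c("group", "linear"),
    rule = stratificationRule(),
    baselineHazard = 0.06, censoringRate = 0.04, adminCensorYears = 15) {
  hazardForm <- match.arg(hazardForm)
  spec <- as.list(environment())
  if (abs(sum(mixing) - 1) > 1e-8)
    stop("spec error: mixing proportions must sum to 1")
  if (baselineHazard <= 0 || censoringRate < 0)
    stop("spec error: hazards must be positive")
  if (qr(centroids)$rank < ncol(centroids))
    stop("spec error: singular centroid matrix")
  for (ef in survivalEffects) {
    if (!ef$gene %in% rownames(centroids))
      stop("spec error: survival-effect gene missing from centroids: ",
           ef$gene)
    if (!ef$subtype %in% c(colnames(centroids), NA))
      stop("spec error: unknown survival-effect subtype: ", ef$subtype)
  }
  structure(spec, class = "expressionStudySpec")
}

#' Simulate a multi-dataset expression study with survival
#'
#' Draws each sample's expression around its subtype centroid, applies
#' per-dataset location/scale batch shifts, expands genes to probe-level
#' rows, and draws exponential survival times whose hazard depends on the
#' chosen genes' z-score groups (computed from the clean, batch-free
#' expression across all samples) with independent exponential plus
#' administrative censoring.
#'
#' @param spec an [expressionStudySpec()].
#' @param seed integer RNG seed.
#' @return list with `probeMatrix` (probes x samples), `probeMap`
#'   (data.frame probe, gene), `study` ([ExpressionStudy-class] holding
#'   the probe-level matrix and survival annotations), and `truth`
#'   (subtype labels, clean gene matrix, z-scores and group codes of the
#'   effect genes, generating hazard ratios).
#' @export
simulateExpressionStudy <- function(spec = expressionStudySpec(), seed = 1) {
  stopifnot(inherits(spec, "expressionStudySpec"))
  set.seed(seed)
  genes <- rownames(spec$centroids)
  subtypes <- colnames(spec$centroids)
  nTot <- sum(spec$datasetSizes)
  dataset <- rep(names(spec$datasetSizes), spec$datasetSizes)
  sampleIds <- sprintf("%s_s%03d", dataset,
                       unlist(lapply(spec$datasetSizes, seq_len)))

  subtype <- sample(subtypes, nTot, replace = TRUE, prob = spec$mixing)
  clean <- spec$centroids[, subtype, drop = FALSE] +
    matrix(rnorm(length(genes) * nTot, 0, spec$noiseSD), nrow = length(genes))
  dimnames(clean) <- list(genes, sampleIds)

  # z of the clean matrix across all samples (population SD) is the ground
  # truth the double-standardization pipeline is expected to recover
  popZ <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))

  logHaz <- rep(log(spec$baselineHazard), nTot)
  truthGroups <- list()
  for (ef in spec$survivalEffects) {
    z <- popZ(clean[ef$gene, ])
    inSub <- subtype == ef$subtype
    if (spec$hazardForm == "group") {
      u <- ifelse(z > spec$rule@zHigh, 1, ifelse(z < spec$rule@zLow, 0, 0.5))
      logHaz[inSub] <- logHaz[inSub] + log(ef$hr) * (u[inSub] - 0.5)
    } else {
      logHaz[inSub] <- logHaz[inSub] + log(ef$hr) * z[inSub]
      u <- z
    }
    truthGroups[[paste(ef$gene, ef$subtype, sep = "|")]] <-
      list(z = z, u = u, hr = ef$hr, subtype = ef$subtype, gene = ef$gene)
  }
  tDeath <- rexp(nTot, rate = exp(logHaz))
  tCens <- pmin(rexp(nTot, rate = max(spec$censoringRate, 1e-12)),
                spec$adminCensorYears)
  time <- pmin(tDeath, tCens)
  event <- as.integer(tDeath <= tCens)

  # batch shifts per dataset, identical across genes
  obs <- clean
  for (d in seq_along(spec$datasetSizes)) {
    i <- dataset == names(spec$datasetSizes)[d]
    obs[, i] <- obs[, i] * spec$batchScale[d] + spec$batchLocation[d]
  }

  # probe-level expansion: probe j of a gene is the gene signal plus a
  # fixed probe offset and probe-specific noise
  nProbes <- rep_len(spec$probesPerGene, length(genes))
  probeRows <- list(); probeMap <- list()
  for (g in seq_along(genes)) {
    for (j in seq_len(nProbes[g])) {
      pid <- sprintf("%s_at%d", genes[g], j)
      probeRows[[pid]] <- obs[g, ] - 0.3 * (j - 1) +
        rnorm(nTot, 0, 0.05)
      probeMap[[pid]] <- genes[g]
    }
  }
  probeMatrix <- do.call(rbind, probeRows)
  probeMap <- data.frame(probe = names(probeMap),
                         gene = unlist(probeMap), row.names = NULL,
                         stringsAsFactors = FALSE)

  study <- expressionStudy(probeMatrix, dataset = dataset, time = time,
                           event = event)
  list(probeMatrix = probeMatrix, probeMap = probeMap, study = study,
       truth = list(subtype = setNames(subtype, sampleIds), clean = clean,
                    groups = truthGroups, logHazard = logHaz,
                    spec = spec))
}
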