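#' Canonical correspondence analysis of variants against habitat gradients
#'
#' Constrained ordination (ter Braak) of the variant x sample count table
#' against temperature and depth as linear predictors, via [vegan::cca()].
#' Scores are reported in species-conditional scaling ("scaling 2"), the
#' convention consumed by the ordination cluster test. Per-predictor
#' explained fractions are partial constrained inertias (each predictor
#' conditioned on the other).
#'
#' @param counts variant x sample matrix of non-negative counts (or a
#'   [VariantTable-class]).
#' @param env data.frame with one row per sample and numeric columns
#'   (default `temperature_C` and `depth_um`) used as constraints.
#' @param predictors column names of `env` to use.
#' @return list with `eigenvalues` (constrained axes), `speciesScores`
#'   (variants), `siteScores` (samples), `totalInertia`,
#'   `constrainedInertia`, `explainedFraction`, `perPredictor` (named
#'   vector of partial fractions), and `model` (the vegan fit).
#' @export
ccaOrdination <- function(counts, env,
                          predictors = c("temperature_C", "depth_um")) {
  if (is(counts, "VariantTable")) counts <- variantCounts(counts)
  stopifnot(ncol(counts) == nrow(env), all(predictors %in% names(env)))
  for (p in predictors) {
    if (stats::sd(env[[p]]) == 0)
      stop("degenerate constraint: predictor '", p, "' is constant")
  }
  comm <- t(counts)
  keepSp <- colSums(comm) > 0
  keepSite <- rowSums(comm) > 0
  comm <- comm[keepSite, keepSp, drop = FALSE]
  envUse <- env[keepSite, predictors, drop = FALSE]
  fmla <- stats::as.formula(paste("comm ~", paste(predictors, collapse = " + ")))
  m <- vegan::cca(fmla, data = envUse)
  perPred <- vapply(predictors, function(p) {
    others <- setdiff(predictors, p)
    f <- if (length(others))
      stats::as.formula(paste("comm ~", p, "+ Condition(",
                              paste(others, collapse = " + "), ")"))
    else stats::as.formula(paste("comm ~", p))
    vegan::cca(f, data = envUse)$CCA$tot.chi / m$tot.chi
  }, numeric(1))
  list(
    eigenvalues = m$CCA$eig,
    speciesScores = vegan::scores(m, display = "species", scaling = 2,
                                  choices = seq_len(m$CCA$rank)),
    siteScores = vegan::scores(m, display = "sites", scaling = 2,
                               choices = seq_len(m$CCA$rank)),
    totalInertia = m$tot.chi,
    constrainedInertia = m$CCA$tot.chi,
    explainedFraction = m$CCA$tot.chi / m$tot.chi,
    perPredictor = perPred,
    model = m)
}

#' Permutation test for nonrandom clustering of a group in ordination space
#'
#' Tests whether the variants of one putative ecotype form a tight cluster
#' in ordination space: the statistic is the mean squared Euclidean
#' distance of the group's points to their centroid, and the null
#' distribution comes from size-preserving random relabelings of group
#' membership among all points. Small statistics mean tight clustering, so
#' p = (1 + #\{permuted statistic <= observed\}) / (nPerm + 1).
#'
#' @param scores numeric matrix of ordination scores (points x axes),
#'   typically the first two constrained axes of [ccaOrdination()].
#' @param members logical or integer index of the group's rows, or
#'   character rownames.
#' @param nPerm number of permutations (>= 1).
#' @param seed optional integer seed.
#' @return list with `statistic`, `p`, `nPerm`, `n` (group size), and
#'   `testable` (FALSE for groups of fewer than 2 points, whose p is NA).
#' @export
ordtestCluster <- function(scores, members, nPerm = 999, seed = NULL) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  scores <- as.matrix(scores)
  idx <- if (is.character(members)) match(members, rownames(scores))
         else if (is.logical(members)) which(members) else as.integer(members)
  if (anyNA(idx)) stop("unknown group members")
  k <- length(idx)
  if (k < 2)
    return(list(statistic = NA_real_, p = NA_real_, nPerm = nPerm,
                n = k, testable = FALSE))
  spread <- function(i) {
    pts <- scores[i, , drop = FALSE]
    ctr <- colMeans(pts)
    mean(rowSums((pts - rep(ctr, each = nrow(pts)))^2))
  }
  obs <- spread(idx)
  n <- nrow(scores)
  withSeed(seed, {
    perm <- vapply(seq_len(nPerm), function(b) spread(sample.int(n, k)),
                   numeric(1))
    list(statistic = obs, p = (1 + sum(perm <= obs)) / (nPerm + 1),
         nPerm = nPerm, n = k, testable = TRUE)
  })
}

#' G-test of independence on a contingency table
#'
#' Log-likelihood-ratio test: G = 2 sum O ln(O/E) over cells with O > 0,
#' expected counts under independence, df = (r-1)(c-1), p from the
#' chi-square approximation. All-zero rows or columns are dropped with a
#' warning.
#'
#' @param tab matrix of non-negative counts.
#' @return list with `G`, `df`, `p`.
#' @examples
#' gTest(matrix(c(30, 10, 10, 30), 2))
#' @export
gTest <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  zr <- rowSums(tab) == 0; zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("dropping all-zero rows/columns")
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least a 2x2 table after dropping zero margins")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  pos <- tab > 0
  G <- 2 * sum(tab[pos] * log(tab[pos] / E[pos]))
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(G = G, df = df, p = stats::pchisq(G, df, lower.tail = FALSE))
}

#' Test whether putative ecotypes respond differently over a perturbation
#'
#' Distinctness of response: generalized linear modelling of the PE
#' composition over time with a PE x time interaction. In mode "glm" (the
#' default) the heterogeneity p-value is the interaction deviance of the
#' multinomial trend model, fitted in its Poisson log-linear form
#' (`count ~ pe + timepoint + pe:time`); per-timepoint totals are absorbed
#' by the timepoint factor, so the test is calibrated for compositional
#' count tables, which a naive independent-binomial interaction test is
#' not. Mode "ancova" instead uses an analysis-of-covariance F test on
#' arcsine-square-root transformed proportions. Per-PE slopes come from
#' binomial-family share regressions and carry direction labels:
#' "up"/"down" when the slope's p < alpha, "-" otherwise.
#'
#' @param counts PE x timepoint matrix of counts (columns ordered by
#'   `timepoints`). Column totals are the per-timepoint sequencing depth.
#' @param timepoints numeric vector of times (default: numeric column
#'   names).
#' @param mode "glm" or "ancova".
#' @param alpha significance level for direction labels (default 0.05).
#' @return list with `interactionP`, `perPE` (data.frame: pe, slope, p,
#'   direction), and `mode`.
#' @export
perturbationTrend <- function(counts, timepoints = NULL,
                              mode = c("glm", "ancova"), alpha = 0.05) {
  mode <- match.arg(mode)
  counts <- as.matrix(counts)
  if (is.null(timepoints)) timepoints <- as.numeric(colnames(counts))
  if (length(unique(timepoints)) < 2) stop("need at least 2 timepoints")
  totals <- colSums(counts)
  long <- data.frame(
    pe = factor(rep(rownames(counts), ncol(counts))),
    time = rep(timepoints, each = nrow(counts)),
    k = as.vector(counts),
    n = rep(totals, each = nrow(counts)))
  if (mode == "glm") {
    long$tf <- factor(long$time)
    full <- stats::glm(k ~ pe + tf + pe:time, family = stats::poisson,
                       data = long)
    red <- stats::glm(k ~ pe + tf, family = stats::poisson, data = long)
    dev <- red$deviance - full$deviance
    ddf <- red$df.residual - full$df.residual
    interactionP <- stats::pchisq(dev, ddf, lower.tail = FALSE)
  } else {
    long$y <- asin(sqrt(pmin(pmax(long$k / long$n, 0), 1)))
    full <- stats::lm(y ~ pe * time, data = long)
    red <- stats::lm(y ~ pe + time, data = long)
    interactionP <- stats::anova(red, full)[2, "Pr(>F)"]
  }
  perPE <- do.call(rbind, lapply(rownames(counts), function(p) {
    d <- long[long$pe == p, ]
    fit <- if (mode == "glm")
      stats::glm(cbind(k, n - k) ~ time, family = stats::binomial, data = d)
    else stats::lm(asin(sqrt(k / n)) ~ time, data = d)
    cf <- summary(fit)$coefficients
    slope <- cf["time", 1]; pv <- cf["time", 4]
    data.frame(pe = p, slope = slope, p = pv,
               direction = if (pv < alpha) (if (slope > 0) "up" else "down")
                           else "-",
               stringsAsFactors = FALSE)
  }))
  list(interactionP = interactionP, perPE = perPE, mode = mode)
}

#' Test ecological interchangeability within one putative ecotype
#'
#' Within a PE, fits binomial-family regressions over time of (i) each
#' HFS variant's share of the PE's sequences and (ii) the pooled LFS to
#' HFS ratio. Non-significant slopes indicate that the PE's membership
#' moves in unison — the variants are ecologically interchangeable.
#'
#' @param counts variant x timepoint count matrix for one PE's variants.
#' @param classes character vector per variant: "dominant", "HFS" or
#'   "LFS".
#' @param timepoints numeric vector of times (default: numeric column
#'   names).
#' @return data.frame with columns `component`, `slope`, `p`.
#' @export
withinPEHomogeneity <- function(counts, classes, timepoints = NULL) {
  counts <- as.matrix(counts)
  if (is.null(timepoints)) timepoints <- as.numeric(colnames(counts))
  if (length(unique(timepoints)) < 2) stop("need at least 2 timepoints")
  stopifnot(length(classes) == nrow(counts))
  peTotal <- colSums(counts)
  isHfs <- classes %in% c("dominant", "HFS")
  rows <- list()
  fitShare <- function(k, n, label) {
    fit <- stats::glm(cbind(k, pmax(n - k, 0)) ~ timepoints,
                      family = stats::binomial)
    cf <- summary(fit)$coefficients
    data.frame(component = label, slope = cf["timepoints", 1],
               p = cf["timepoints", 4], stringsAsFactors = FALSE)
  }
  for (i in which(isHfs)) {
    lab <- rownames(counts)[i]
    if (is.null(lab)) lab <- paste0("hfs", i)
    rows[[length(rows) + 1]] <- fitShare(counts[i, ], peTotal, lab)
  }
  if (any(!isHfs) && any(isHfs)) {
    lfs <- colSums(counts[!isHfs, , drop = FALSE])
    hfsTot <- colSums(counts[isHfs, , drop = FALSE])
    rows[[length(rows) + 1]] <- fitShare(lfs, lfs + hfsTot, "LFS:HFS")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
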