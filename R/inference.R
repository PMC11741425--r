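# Grid-search inference of the instability parameters (m, tauE, tauK)
# against an empirical repeat length distribution.

#' Log-space least-squares distance between count distributions
#'
#' Both raw count vectors are extended with zeros to the boundary length,
#' given a pseudocount of one in every bin, normalized, and compared by
#' the sum over bins of squared differences of log frequencies.  The log
#' scale upweights the sparsely populated tail, which carries the
#' information about instability rates; the metric is symmetric and zero
#' exactly when the pseudocount-normalized distributions coincide.
#'
#' @param model,empirical raw (non-normalized) counts: numeric vectors or
#'   [LengthDistribution-class] objects.
#' @param LBoundary number of length bins compared.
#' @return Non-negative scalar metric value.
#' @examples
#' fitMetric(c(9, 0), c(4, 1), LBoundary = 2)  # about 1.3695
#' @export
fitMetric <- function(model, empirical, LBoundary = 100L) {
  tobins <- function(x) {
    v <- if (is(x, "LengthDistribution")) rawCounts(x) else as.numeric(x)
    length(v) <- LBoundary
    v[is.na(v)] <- 0
    v
  }
  q <- function(v) { v <- v + 1; v / sum(v) }
  qm <- q(tobins(model)); qe <- q(tobins(empirical))
  sum((log(qm) - log(qe))^2)
}

#' Grid search over instability parameter combinations
#'
#' For every combination of multiplier and exponents, builds the
#' parameterized rate curves, evolves the joint distribution through the
#' progressive schedule and scores the late-time repeat distribution
#' against the empirical counts with [fitMetric()].  Combinations whose
#' boundary bin accumulates are flagged but still scored.
#'
#' @param empirical raw empirical counts ([LengthDistribution-class] or
#'   numeric).
#' @param denovo de novo per-target rates for L = 1..8 (see
#'   [buildRateCurves()]).
#' @param contextRates named substitution/B rates.
#' @param mValues multipliers to try (default the 6 powers of two 1..32).
#' @param tauValues exponent grid for both tauE and tauK (default 0 to 5
#'   in steps of 0.1).
#' @param schedule kernel schedule.
#' @param LBoundary boundary length.
#' @param genomeRepeatTotal repeat total used for the initial state (set
#'   it to the empirical total so model and data counts share a scale).
#' @param pA initial-state focal-unit fraction (default from the
#'   lengthen/shorten rates).
#' @param fusionMode fusion pair allocation mode (see
#'   [stepDeterministic()]).
#' @param verbose print one progress line per multiplier.
#' @return list with \code{table} (m, tauE, tauK, metric, boundaryFlag),
#'   \code{best} (the argmin [InstabilityParams-class]) and
#'   \code{bestMetric}.
#' @export
gridSearch <- function(empirical, denovo, contextRates,
                       mValues = c(1, 2, 4, 8, 16, 32),
                       tauValues = seq(0, 5, by = 0.1),
                       schedule = kernelSchedule(), LBoundary = 100L,
                       genomeRepeatTotal = NULL, pA = NULL,
                       fusionMode = "occupancy", verbose = FALSE) {
  emp <- if (is(empirical, "LengthDistribution")) rawCounts(empirical)
         else as.numeric(empirical)
  if (is.null(genomeRepeatTotal)) genomeRepeatTotal <- sum(emp)
  if (is.null(pA)) {
    mu <- contextRates[["lengthen"]]; nu <- contextRates[["shorten"]]
    pA <- if (mu + nu > 0) mu / (mu + nu) else 0.3
  }
  st0 <- geometricJointState(pA, genomeRepeatTotal / (pA * (1 - pA)),
                             LBoundary)
  grid <- expand.grid(tauK = tauValues, tauE = tauValues, m = mValues)
  grid <- grid[, c("m", "tauE", "tauK")]
  metric <- numeric(nrow(grid))
  bflag <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    params <- instabilityParams(grid$m[i], grid$tauE[i], grid$tauK[i])
    rates <- buildRateCurves(denovo, params, contextRates, LBoundary)
    ev <- evolveState(st0, rates, schedule, snapshotEvery = 0,
                      fusionMode = fusionMode)
    cnt <- countsA(ev$state)
    # compare shapes at matched genome size: the kernel's slow residual
    # growth factor is arbitrary, and the pseudocount floor of the metric
    # is sensitive to the overall count scale
    if (sum(cnt) > 0) cnt <- cnt * sum(emp) / sum(cnt)
    metric[i] <- fitMetric(cnt, emp, LBoundary)
    bflag[i] <- boundaryFlag(ev$state)
    if (verbose && i %% length(tauValues)^2 == 0)
      message(sprintf("grid: m = %g done (%d/%d)", grid$m[i], i,
                      nrow(grid)))
  }
  tab <- cbind(grid, metric = metric, boundaryFlag = bflag)
  ibest <- which.min(metric)
  list(table = tab,
       best = instabilityParams(tab$m[ibest], tab$tauE[ibest],
                                tab$tauK[ibest]),
       bestMetric = metric[ibest])
}

#' Poisson-resampling consistency interval for the grid metric
#'
#' The statistical uncertainty of the empirically estimated rates is
#' propagated to the metric: event counts behind the substitution and
#' per-length indel rate estimates are Poisson resampled, each resampled
#' rate set is evolved at the best-fit parameters, and the metric of the
#' resulting distribution against the empirical counts is recorded.  The
#' one-sided 95\% threshold discards the top 5\% of the resampled metric
#' values; grid combinations at or below the threshold are consistent
#' with the best fit.  Per-bin two-sided 95\% envelopes of the resampled
#' distributions are also returned (top and bottom 2.5\% discarded).
#'
#' @param best best-fit [InstabilityParams-class].
#' @param denovoCounts list describing the estimation counts: elements
#'   \code{context} (data.frame from [estimateContextRates()]: events,
#'   sites per category), \code{indel} (data.frame from
#'   [estimateIndelRates()]\code{$table} restricted to L = 1..8),
#'   \code{nOffspring}, and optional \code{bRates}.
#' @param empirical raw empirical counts.
#' @param gridTable grid result table from [gridSearch()].
#' @param nResamples number of Poisson resamples (default 200).
#' @param schedule,LBoundary,genomeRepeatTotal,pA,fusionMode as in
#'   [gridSearch()].
#' @param seed RNG seed.
#' @return list with \code{threshold}, \code{metrics} (resampled metric
#'   values), \code{consistent} (logical per grid row), and
#'   \code{envelope} (per-bin lower/upper counts).
#' @export
consistencyInterval <- function(best, denovoCounts, empirical, gridTable,
                                nResamples = 200,
                                schedule = kernelSchedule(),
                                LBoundary = 100L,
                                genomeRepeatTotal = NULL, pA = NULL,
                                fusionMode = "occupancy", seed = NULL) {
  emp <- if (is(empirical, "LengthDistribution")) rawCounts(empirical)
         else as.numeric(empirical)
  if (is.null(genomeRepeatTotal)) genomeRepeatTotal <- sum(emp)
  ctx <- denovoCounts$context
  ind <- denovoCounts$indel
  nOff <- denovoCounts$nOffspring
  .with_seed(seed, {
    metrics <- numeric(nResamples)
    dists <- matrix(0, nrow = nResamples, ncol = LBoundary)
    for (k in seq_len(nResamples)) {
      cr <- setNames(rpois(nrow(ctx), ctx$events) /
                       (2 * ctx$sites * nOff), ctx$category)
      if (!is.null(denovoCounts$bRates)) cr <- c(cr, denovoCounts$bRates)
      resTab <- ind
      resTab$rate <- rpois(nrow(ind), ind$events) / ind$targets
      curves <- perTargetCurves(resTab, lengths = 1:8)
      curves <- lapply(curves, function(v) { v[!is.finite(v)] <- 0; v })
      rates <- buildRateCurves(curves, best, cr, LBoundary)
      mu <- cr[["lengthen"]]; nu <- cr[["shorten"]]
      p0 <- if (!is.null(pA)) pA else
        if (mu + nu > 0) mu / (mu + nu) else 0.3
      st0 <- geometricJointState(p0, genomeRepeatTotal / (p0 * (1 - p0)),
                                 LBoundary)
      ev <- evolveState(st0, rates, schedule, snapshotEvery = 0,
                        fusionMode = fusionMode)
      cnt <- countsA(ev$state)
      if (sum(cnt) > 0) cnt <- cnt * sum(emp) / sum(cnt)
      dists[k, ] <- cnt
      metrics[k] <- fitMetric(cnt, emp, LBoundary)
    }
    dropTop <- max(1L, round(0.05 * nResamples))
    threshold <- sort(metrics)[nResamples - dropTop]
    dropEnv <- round(0.025 * nResamples)
    env <- apply(dists, 2L, function(v) {
      v <- sort(v)
      v[c(dropEnv + 1L, nResamples - dropEnv)]
    })
    list(threshold = threshold, metrics = metrics,
         consistent = gridTable$metric <= threshold,
         envelope = data.frame(length = seq_len(LBoundary),
                               lower = env[1L, ], upper = env[2L, ]))
  })
}
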