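# Deterministic / stochastic evolution of the joint repeat length
# distribution under the mutation kernel.

.KERNEL_PROCESSES <- c("sub_lengthen", "sub_shorten", "sub_fission",
                       "sub_fusion", "expansion", "contraction",
                       "insertion_fission", "b_deletion_fusion",
                       "create_A1", "destroy_A1", "b_insert", "b_delete")

.rates_as_list <- function(rates) {
  cr <- rates@contextRates
  list(lengthen = cr[["lengthen"]], shorten = cr[["shorten"]],
       fission = cr[["fission"]], fusion = cr[["fusion"]],
       createA1 = cr[["createA1"]], destroyA1 = cr[["destroyA1"]],
       bInsert = cr[["bInsert"]], bDelete = cr[["bDelete"]],
       b1DeleteFusion = cr[["b1DeleteFusion"]],
       expansion = rates@expansion, contraction = rates@contraction,
       insertion = rates@insertion)
}

.fusion_mode_code <- function(fusionMode) {
  match(match.arg(fusionMode, c("occupancy", "even")),
        c("occupancy", "even")) - 1L
}

#' Extend de novo instability rates with the power-law parameterization
#'
#' De novo per-target rates for lengths 1..8 (where trio estimates are
#' reliable) are kept as estimated; the rate at L = 9 is \code{m} times
#' the rate at L = 8, and rates for L > 9 follow
#' rate(9) (L/9)^tau with the curve's own exponent (insertion shares the
#' expansion exponent).  Every per-length value is capped at 0.1.
#'
#' @param denovo list (or data.frame) with numeric elements
#'   \code{expansion}, \code{contraction}, \code{insertion}: per-target
#'   rates for L = 1..8 (longer vectors are truncated to 8).
#' @param params an [InstabilityParams-class].
#' @param contextRates named substitution / B-indel rates (see
#'   [rateModel()]).
#' @param LBoundary boundary length of the curves (default 100).
#' @return A [RateModel-class] whose curves embed the parameterization.
#' @examples
#' dn <- list(expansion = rep(1e-6, 8), contraction = rep(2e-6, 8),
#'            insertion = rep(1e-7, 8))
#' buildRateCurves(dn, instabilityParams(2, 1.7, 2.0), LBoundary = 60)
#' @export
buildRateCurves <- function(denovo, params, contextRates = numeric(),
                            LBoundary = 100L) {
  LBoundary <- as.integer(LBoundary)
  one <- function(base, tau) {
    base <- as.numeric(base)
    if (length(base) < 8L || any(!is.finite(base[1:8])))
      stop("de novo rates must be finite for L = 1..8")
    v <- numeric(LBoundary)
    v[1:8] <- base[1:8]
    if (LBoundary >= 9L) {
      L <- 9:LBoundary
      v[L] <- params@m * base[8L] * (L / 9)^tau
    }
    pmin(v, 0.1)
  }
  rateModel(contextRates = contextRates,
            expansion = one(denovo$expansion, params@tauE),
            contraction = one(denovo$contraction, params@tauK),
            insertion = one(denovo$insertion, params@tauE),
            LBoundary = LBoundary)
}

.flux_table <- function(res, LB, normalized = FALSE) {
  tab <- data.frame(
    process = rep(.KERNEL_PROCESSES, times = LB),
    length = rep(seq_len(LB), each = length(.KERNEL_PROCESSES)),
    influx = as.vector(res$fluxInA),
    outflux = as.vector(res$fluxOutA),
    influxB = as.vector(res$fluxInB),
    outfluxB = as.vector(res$fluxOutB))
  if (normalized) {
    tot <- vapply(split(tab$influx + tab$outflux, tab$length), sum, 0)
    tot <- tot[as.character(tab$length)]
    nz <- tot > 0
    tab$influx[nz] <- tab$influx[nz] / tot[nz]
    tab$outflux[nz] <- tab$outflux[nz] / tot[nz]
  }
  attr(tab, "normalized") <- normalized
  tab
}

#' One aggregated deterministic kernel step
#'
#' Applies, simultaneously and from the pre-step state, the expected count
#' changes of every mutational process, each scaled by 10^r: lengthening /
#' shortening / fission / fusion substitutions, expansions, contractions,
#' non-motif insertion fission, B1-deletion fusion, A1 creation and loss,
#' and B-string indels.  Gains above the boundary reflect onto the
#' boundary bin.
#'
#' @param state a [JointState-class].
#' @param rates a [RateModel-class] with \code{LBoundary} matching the
#'   state.
#' @param r time-rescaling exponent; all rates are multiplied by 10^r so
#'   one iteration represents 10^r generations.
#' @param fusionMode \code{"occupancy"} (default): fusion pairs are drawn
#'   occupancy-weighted from the length distribution; \code{"even"}: the
#'   two fused counts are subtracted evenly from all bins the product
#'   could have drawn from.
#' @param clampNegative if FALSE (default) a negative count aborts with an
#'   error (the linear-mutation bound was violated); if TRUE counts are
#'   floored at zero, as during super-linear burn-in stages.
#' @return list with \code{state} (the updated [JointState-class]) and
#'   \code{flux} (per-process per-bin influx/outflux data.frame).
#' @examples
#' st <- jointState(c(`5` = 1000), c(`1` = 50), LBoundary = 20)
#' rm <- rateModel(c(fission = 1e-3), LBoundary = 20)
#' stepDeterministic(st, rm)$state
#' @export
stepDeterministic <- function(state, rates, r = 0,
                              fusionMode = "occupancy",
                              clampNegative = FALSE) {
  stopifnot(rates@LBoundary == state@LBoundary)
  res <- kernel_step_cpp(state@countsA, state@countsB,
                         .rates_as_list(rates), 10^r,
                         .fusion_mode_code(fusionMode),
                         FALSE, clampNegative)
  newState <- state
  newState@countsA <- res$countsA
  newState@countsB <- res$countsB
  newState@generation <- state@generation + 10^r
  list(state = newState, flux = .flux_table(res, state@LBoundary))
}

#' One stochastic kernel step
#'
#' As [stepDeterministic()], but the total expected influx and outflux of
#' each length bin are replaced by independent Poisson draws (individual
#' transitions are not constrained to balance), and counts are floored at
#' zero.
#'
#' @inheritParams stepDeterministic
#' @param seed RNG seed (NULL leaves the RNG state alone).
#' @return The updated [JointState-class].
#' @export
stepStochastic <- function(state, rates, r = 0, seed = NULL,
                           fusionMode = "occupancy") {
  stopifnot(rates@LBoundary == state@LBoundary)
  res <- .with_seed(seed,
    kernel_step_cpp(state@countsA, state@countsB, .rates_as_list(rates),
                    10^r, .fusion_mode_code(fusionMode), TRUE, TRUE))
  state@countsA <- res$countsA
  state@countsB <- res$countsB
  state@generation <- state@generation + 10^r
  state
}

#' Progressive time-rescaling schedules
#'
#' A schedule is a data.frame of stages; in stage k all rates are
#' multiplied by 10^r\[k\] for iterations\[k\] iterations, so each
#' iteration stands for 10^r\[k\] generations.  The \code{"default"}
#' preset runs 1e4 iterations at r = 5, 4, 3, 2, then 1e5 at r = 1 and
#' 1e6 at r = 0 (at least 1e9 generations in total, refined at
#' progressively finer time steps); \code{"fast"} keeps the r = 5..3
#' stages only, which already represents 1.11e9 generations and resolves
#' every bin whose per-repeat rate is at most 1e-4 per generation in the
#' linear regime.
#'
#' @param preset \code{"default"} or \code{"fast"}.
#' @return data.frame with columns \code{r} and \code{iterations}.
#' @export
kernelSchedule <- function(preset = c("default", "fast")) {
  switch(match.arg(preset),
    default = data.frame(r = c(5L, 4L, 3L, 2L, 1L, 0L),
                         iterations = c(1e4, 1e4, 1e4, 1e4, 1e5, 1e6)),
    fast = data.frame(r = c(5L, 4L, 3L), iterations = c(1e4, 1e4, 1e4)))
}

#' Evolve a joint state through a progressive schedule
#'
#' Runs the kernel through the stages of \code{schedule}; a count above
#' \code{boundaryTrigger} in the boundary bin advances to the next stage
#' early (the signature of non-equilibrating, expansion-dominated
#' parameters).  Within super-linear stages counts are floored at zero;
#' accuracy is restored by the later, finer stages.
#'
#' @inheritParams stepDeterministic
#' @param schedule data.frame with columns \code{r}, \code{iterations}
#'   (see [kernelSchedule()]).
#' @param stochastic Poisson-sample the per-bin changes instead of using
#'   expectations.
#' @param seed RNG seed for stochastic mode.
#' @param snapshotEvery record a state snapshot every this many
#'   generations (default 1e6; 0 disables snapshots).
#' @param boundaryTrigger early-advance threshold for the boundary bin
#'   count (default 1000).
#' @return list with \code{state} (final [JointState-class], with
#'   \code{boundaryFlag} set when the boundary bin holds at least
#'   \code{boundaryTrigger} counts) and \code{trajectory} (data.frame of
#'   snapshots: generation, length, countA, countB).
#' @examples
#' st <- geometricJointState(0.3, 1e6, LBoundary = 40)
#' rm <- rateModel(c(lengthen = 5e-9, shorten = 8e-9), LBoundary = 40)
#' ev <- evolveState(st, rm, kernelSchedule("fast"))
#' ev$state
#' @export
evolveState <- function(state, rates, schedule = kernelSchedule(),
                        stochastic = FALSE, seed = NULL,
                        snapshotEvery = 1e6, boundaryTrigger = 1000,
                        fusionMode = "occupancy") {
  stopifnot(rates@LBoundary == state@LBoundary,
            all(c("r", "iterations") %in% names(schedule)))
  res <- .with_seed(if (stochastic) seed else NULL,
    kernel_evolve_cpp(state@countsA, state@countsB, .rates_as_list(rates),
                      as.integer(schedule$r), as.numeric(schedule$iterations),
                      boundaryTrigger, .fusion_mode_code(fusionMode),
                      stochastic, snapshotEvery, state@generation))
  out <- state
  out@countsA <- res$countsA
  out@countsB <- res$countsB
  out@generation <- res$generation
  out@boundaryFlag <- res$boundaryFlag
  snaps <- res$snapshots
  LB <- state@LBoundary
  trajectory <- if (nrow(snaps)) {
    do.call(rbind, lapply(seq_len(nrow(snaps)), function(i) {
      data.frame(generation = snaps[i, 1L], length = seq_len(LB),
                 countA = snaps[i, 1L + seq_len(LB)],
                 countB = snaps[i, 1L + LB + seq_len(LB)])
    }))
  } else {
    data.frame(generation = numeric(), length = integer(),
               countA = numeric(), countB = numeric())
  }
  list(state = out, trajectory = trajectory)
}

#' Check the linear-mutation bound
#'
#' The aggregated update approximates single-event-per-generation dynamics
#' only while the summed per-repeat mutation rate (scaled by 10^r) stays
#' at or below 0.1 in every populated length bin.
#'
#' @inheritParams stepDeterministic
#' @return list with \code{ok} (logical) and \code{offending} (populated
#'   bins violating the bound).
#' @export
checkLinearBound <- function(state, rates, r = 0) {
  LB <- state@LBoundary
  L <- seq_len(LB)
  cr <- rates@contextRates
  perRepeat <- 2 * cr[["lengthen"]] +
    2 * cr[["shorten"]] * (L >= 2) +
    cr[["fission"]] * pmax(L - 2, 0) +
    cr[["destroyA1"]] * (L == 1) +
    rates@expansion * L +
    rates@contraction * L * (L >= 2) +
    rates@insertion * L * (L >= 2)
  scaled <- 10^r * perRepeat
  offending <- which(scaled > 0.1 & state@countsA > 0)
  list(ok = length(offending) == 0L, offending = offending,
       perRepeat = scaled)
}

#' Single-generation flux decomposition
#'
#' Applies the kernel for one generation (r = 0) and reports, per length
#' bin and mutational process, the expected influx and outflux of the
#' repeat distribution; when \code{normalize} is TRUE the total flux
#' magnitude (|in| + |out|) is scaled to one within each bin.  At steady
#' state the net flux of every bin vanishes.
#'
#' @inheritParams stepDeterministic
#' @param normalize normalize per bin to unit total flux magnitude.
#' @return data.frame with columns process, length, influx, outflux (A
#'   side) and influxB/outfluxB (B side, unnormalized).
#' @export
fluxDecomposition <- function(state, rates, normalize = TRUE,
                              fusionMode = "occupancy") {
  res <- kernel_step_cpp(state@countsA, state@countsB,
                         .rates_as_list(rates), 1,
                         .fusion_mode_code(fusionMode), FALSE, TRUE)
  .flux_table(res, state@LBoundary, normalized = normalize)
}

#' Geometric joint state of an i.i.d. genome
#'
#' Expected counts of maximal A runs and B strings in an i.i.d. sequence
#' of \code{genomeLength} units with A fraction \code{pA}:
#' NA(L) = G (1-pA)^2 pA^L and NB(l) = G pA^2 (1-pA)^l.  This is the
#' repeat content of a randomly shuffled genome and the standard initial
#' condition for kernel runs.
#'
#' @param pA focal-unit fraction of the genome.
#' @param genomeLength genome size in units.
#' @param LBoundary boundary length.
#' @return A [JointState-class].
#' @export
geometricJointState <- function(pA, genomeLength, LBoundary = 100L) {
  LBoundary <- as.integer(LBoundary)
  L <- seq_len(LBoundary)
  pB <- 1 - pA
  jointState(genomeLength * pB^2 * pA^L, genomeLength * pA^2 * pB^L,
             LBoundary = LBoundary)
}
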