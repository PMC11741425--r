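#' @import methods
#' @importFrom stats median quantile rpois runif lm confint coef approx setNames
#' @importFrom utils head tail write.table read.table
#' @useDynLib repeatflux, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Motif equivalence class
#'
#' A repeat motif together with all motifs that describe the same tandem
#' repeat on either strand: every rotation of the unit and every rotation of
#' its reverse complement (e.g. the class of \code{"AC"} is
#' \{AC, CA, GT, TG\}).  The canonical \code{unit} is the lexicographically
#' smallest member.
#'
#' @slot unit canonical repeat unit (character, 1--6 nt over ACGT).
#' @slot members all equivalent motifs (character vector).
#' @seealso [motifClass()]
#' @export
setClass("MotifClass",
  representation(unit = "character", members = "character"))

setValidity("MotifClass", function(object) {
  msgs <- character()
  if (length(object@unit) != 1L || !nzchar(object@unit))
    msgs <- c(msgs, "unit must be a single non-empty string")
  if (grepl("[^ACGT]", object@unit))
    msgs <- c(msgs, "unit must be over the ACGT alphabet")
  if (any(nchar(object@members) != nchar(object@unit)))
    msgs <- c(msgs, "all members must have the unit's length")
  if (!identical(object@unit, sort(object@members)[1L]))
    msgs <- c(msgs, "unit must be the lexicographically smallest member")
  if (length(msgs)) msgs else TRUE
})

#' Repeat length distribution
#'
#' Counts of maximal contiguous repeat runs indexed by length in repeat
#' units (bin \code{L} of \code{counts} holds the number of runs of exactly
#' \code{L} complete units).  \code{raw} always retains the untransformed
#' counts so that normalization and low-occupancy truncation are
#' reversible.
#'
#' @slot counts numeric vector; element L is the count (or frequency, when
#'   \code{normalized}) at length L.
#' @slot raw the raw (non-normalized, untruncated) counts.
#' @slot unitLength motif unit length in nucleotides.
#' @slot normalized logical; do \code{counts} sum to one?
#' @slot truncationLength smallest length whose raw count fell below the
#'   truncation threshold, or \code{NULL} when no truncation applied.
#' @seealso [lengthDistribution()], [countRepeats()], [normalizeDistribution()]
#' @export
setClass("LengthDistribution",
  representation(counts = "numeric", raw = "numeric",
                 unitLength = "integer", normalized = "logical",
                 truncationLength = "integerOrNULL"))

setValidity("LengthDistribution", function(object) {
  msgs <- character()
  if (any(object@counts < 0) || any(object@raw < 0))
    msgs <- c(msgs, "counts must be non-negative")
  if (object@normalized && length(object@counts) &&
      abs(sum(object@counts) - 1) > 1e-12)
    msgs <- c(msgs, "normalized counts must sum to 1 within 1e-12")
  if (length(msgs)) msgs else TRUE
})

#' Bootstrap envelope of a length distribution
#'
#' Per-bin 95\% confidence envelope obtained by resampling fixed-size
#' genome segments with replacement.
#'
#' @slot lower,upper per-length envelope bounds (numeric vectors).
#' @slot point the point-estimate counts.
#' @slot nResamples number of bootstrap resamples.
#' @slot segmentLength segment size in bp.
#' @export
setClass("BootstrapEnvelope",
  representation(lower = "numeric", upper = "numeric", point = "numeric",
                 nResamples = "integer", segmentLength = "integer"))

setValidity("BootstrapEnvelope", function(object) {
  if (any(object@lower > object@upper + 1e-9))
    "lower envelope must not exceed upper envelope" else TRUE
})

#' Joint repeat / non-repeat length state
#'
#' The pair of length distributions evolved by the mutation kernel: counts
#' of focal-motif (A) repeats and of non-motif (B) strings, both indexed
#' 1..\code{LBoundary} with a reflective boundary at \code{LBoundary}.
#' Counts are real-valued expectations in deterministic mode.
#'
#' @slot countsA,countsB expected counts per length bin.
#' @slot LBoundary reflective boundary length (default 100).
#' @slot generation number of generations evolved so far.
#' @slot boundaryFlag TRUE when the boundary bin accumulated at least 1000
#'   counts, the signature of non-equilibrating (expansion-dominated)
#'   parameters.
#' @seealso [jointState()], [evolveState()]
#' @export
setClass("JointState",
  representation(countsA = "numeric", countsB = "numeric",
                 LBoundary = "integer", generation = "numeric",
                 boundaryFlag = "logical"))

setValidity("JointState", function(object) {
  msgs <- character()
  if (length(object@countsA) != object@LBoundary ||
      length(object@countsB) != object@LBoundary)
    msgs <- c(msgs, "countsA and countsB must have length LBoundary")
  if (any(object@countsA < 0) || any(object@countsB < 0))
    msgs <- c(msgs, "counts must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Mutation rate model consumed by the kernel
#'
#' Context-classified substitution rates, B-string indel rates, and
#' per-target length-dependent expansion / contraction / non-motif
#' insertion rate curves over 1..\code{LBoundary}.  All rates are per
#' target site per offspring generation; every per-length curve value is
#' capped at 0.1.
#'
#' @slot contextRates named numeric: \code{lengthen}, \code{shorten},
#'   \code{fission}, \code{fusion}, \code{createA1}, \code{destroyA1}
#'   (the six three-unit-context substitution categories) plus
#'   \code{bInsert}, \code{bDelete}, \code{b1DeleteFusion} for B strings.
#' @slot expansion,contraction,insertion per-target rate curves, one value
#'   per length 1..LBoundary.
#' @slot LBoundary boundary length of the curves.
#' @seealso [rateModel()], [buildRateCurves()]
#' @export
setClass("RateModel",
  representation(contextRates = "numeric", expansion = "numeric",
                 contraction = "numeric", insertion = "numeric",
                 LBoundary = "integer"))

.CONTEXT_RATE_NAMES <- c("lengthen", "shorten", "fission", "fusion",
                         "createA1", "destroyA1",
                         "bInsert", "bDelete", "b1DeleteFusion")

setValidity("RateModel", function(object) {
  msgs <- character()
  if (!all(.CONTEXT_RATE_NAMES %in% names(object@contextRates)))
    msgs <- c(msgs, paste("contextRates must contain:",
                          paste(.CONTEXT_RATE_NAMES, collapse = ", ")))
  curves <- list(object@expansion, object@contraction, object@insertion)
  if (any(vapply(curves, length, 1L) != object@LBoundary))
    msgs <- c(msgs, "rate curves must have length LBoundary")
  if (any(unlist(curves) < 0) || any(object@contextRates < 0))
    msgs <- c(msgs, "rates must be non-negative")
  if (any(unlist(curves) > 0.1 + 1e-15))
    msgs <- c(msgs, "per-length per-target rates must be capped at 0.1")
  if (any(object@contextRates >= 1))
    msgs <- c(msgs, "rates must lie in [0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Instability-rate curve parameters
#'
#' The three inferred degrees of freedom describing per-target instability
#' rates above the reliably estimated length range: a multiplier \code{m}
#' applied at L = 9 relative to L = 8, and power-law exponents
#' \code{tauE} (expansion) and \code{tauK} (contraction) governing
#' rate(L) = rate(9) (L/9)^tau for L > 9.  The non-motif insertion
#' exponent is identically \code{tauE}.
#'
#' @slot m multiplier at L = 9 (>= 1).
#' @slot tauE,tauK power-law exponents, each in [0, 5].
#' @seealso [instabilityParams()], [deltaTau()]
#' @export
setClass("InstabilityParams",
  representation(m = "numeric", tauE = "numeric", tauK = "numeric"))

setValidity("InstabilityParams", function(object) {
  msgs <- character()
  if (object@m < 1) msgs <- c(msgs, "m must be >= 1")
  if (object@tauE < 0 || object@tauE > 5 ||
      object@tauK < 0 || object@tauK > 5)
    msgs <- c(msgs, "tauE and tauK must lie in [0, 5]")
  if (length(msgs)) msgs else TRUE
})

#' Numerical steady-state solution
#'
#' Solution of one of the nested steady-state ODE approximations on a
#' length grid, constrained to a reference (kernel) distribution at the
#' lengths of theoretical interest L* (expansion/contraction balance) and
#' L_max (expected occupancy falls below one repeat).
#'
#' @slot lengths,values the solution grid and P(L) values.
#' @slot equation which approximation was solved: \code{"local"} (diffusion
#'   + directional flux only), \code{"fission_out"} (adds fission losses),
#'   or \code{"full_fission"} (third-order form including fission influx).
#' @slot LStar,LMax the characteristic lengths used for the constraints.
#' @slot constraints data.frame of constraint lengths and values.
#' @slot negative TRUE if the solution dips below zero anywhere.
#' @export
setClass("SteadyStateSolution",
  representation(lengths = "numeric", values = "numeric",
                 equation = "character", LStar = "numeric", LMax = "numeric",
                 constraints = "data.frame", negative = "logical"))

setValidity("SteadyStateSolution", function(object) {
  if (length(object@lengths) != length(object@values))
    "lengths and values must match" else TRUE
})
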