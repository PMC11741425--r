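# Constructors, accessors and show methods for the core S4 containers.

#' Construct a LengthDistribution
#'
#' @param counts numeric vector of counts; element \code{L} is the count at
#'   length \code{L} (repeat units), or a named vector whose names are
#'   lengths.
#' @param unitLength motif unit length in nucleotides.
#' @return A [LengthDistribution-class] object.
#' @examples
#' lengthDistribution(c(`1` = 100, `3` = 5))
#' @export
lengthDistribution <- function(counts, unitLength = 1L) {
  if (!is.null(names(counts))) {
    L <- as.integer(names(counts))
    if (any(is.na(L)) || any(L < 1))
      stop("names of 'counts' must be positive integer lengths")
    dense <- numeric(max(L, 0L))
    dense[L] <- as.numeric(counts)
    counts <- dense
  }
  new("LengthDistribution", counts = as.numeric(counts),
      raw = as.numeric(counts), unitLength = as.integer(unitLength),
      normalized = FALSE, truncationLength = NULL)
}

#' @describeIn lengthDistribution Counts (or frequencies) per length bin.
#' @param x,object a \code{LengthDistribution}.
#' @export
distCounts <- function(x) x@counts

#' @describeIn lengthDistribution Raw counts as stored at construction.
#' @export
rawCounts <- function(x) x@raw

#' @describeIn lengthDistribution Lengths (units) with any support in the
#'   dense representation.
#' @export
distLengths <- function(x) seq_along(x@counts)

#' @describeIn lengthDistribution Is the distribution normalized?
#' @export
isNormalized <- function(x) x@normalized

#' @describeIn lengthDistribution Truncation length (or NULL).
#' @export
truncationLength <- function(x) x@truncationLength

#' @describeIn lengthDistribution View in nucleotide lengths: a data.frame
#'   with length in units, length in nt (L x unit length), and count.
#' @export
asNucleotideView <- function(x) {
  L <- distLengths(x)
  data.frame(length_units = L, length_nt = L * x@unitLength,
             count = x@counts)
}

setMethod("show", "LengthDistribution", function(object) {
  n <- length(object@counts)
  cat("LengthDistribution (unit ", object@unitLength, " nt, ",
      if (object@normalized) "normalized" else "raw", ")\n", sep = "")
  cat("  bins: 1..", n, ";  total: ",
      format(sum(object@counts)), "\n", sep = "")
  if (!is.null(object@truncationLength))
    cat("  truncated at L =", object@truncationLength, "\n")
})

#' Construct a JointState
#'
#' @param countsA,countsB initial A-repeat and B-string counts per length
#'   bin; recycled/zero-padded to \code{LBoundary}.
#' @param LBoundary reflective boundary length.
#' @param generation generation counter (default 0).
#' @return A [JointState-class].
#' @examples
#' jointState(c(`1` = 1000, `2` = 300), c(`1` = 500), LBoundary = 50)
#' @export
jointState <- function(countsA, countsB, LBoundary = 100L, generation = 0) {
  pad <- function(x, n) {
    if (!is.null(names(x))) {
      L <- as.integer(names(x))
      dense <- numeric(n)
      keep <- L <= n
      dense[L[keep]] <- as.numeric(x[keep])
      # mass beyond the boundary reflects onto the boundary bin
      dense[n] <- dense[n] + sum(as.numeric(x[!keep]))
      return(dense)
    }
    x <- as.numeric(x)
    if (length(x) > n) {
      x[n] <- sum(x[n:length(x)])
      x <- x[seq_len(n)]
    }
    c(x, numeric(n - length(x)))
  }
  LBoundary <- as.integer(LBoundary)
  new("JointState", countsA = pad(countsA, LBoundary),
      countsB = pad(countsB, LBoundary), LBoundary = LBoundary,
      generation = as.numeric(generation), boundaryFlag = FALSE)
}

#' @describeIn jointState A-repeat counts.
#' @param x a \code{JointState}.
#' @export
countsA <- function(x) x@countsA

#' @describeIn jointState B-string counts.
#' @export
countsB <- function(x) x@countsB

#' @describeIn jointState The reflective boundary length.
#' @export
LBoundary <- function(x) x@LBoundary

#' @describeIn jointState Generations evolved.
#' @export
generation <- function(x) x@generation

#' @describeIn jointState Boundary-accumulation flag (>= 1000 counts in the
#'   boundary bin; the signature of non-equilibrating parameters).
#' @export
boundaryFlag <- function(x) x@boundaryFlag

#' @describeIn jointState Total genome length represented by the state,
#'   sum(L * NA(L)) + sum(L * NB(L)), in repeat units.
#' @export
totalLength <- function(x) {
  L <- seq_len(x@LBoundary)
  sum(L * x@countsA) + sum(L * x@countsB)
}

setMethod("show", "JointState", function(object) {
  cat("JointState (LBoundary ", object@LBoundary, ")\n", sep = "")
  cat("  generation:", format(object@generation, big.mark = ","), "\n")
  cat("  repeats:", format(sum(object@countsA)),
      " B strings:", format(sum(object@countsB)), "\n")
  if (object@boundaryFlag)
    cat("  ** boundary accumulation (non-equilibrating parameters) **\n")
})

#' Construct a RateModel
#'
#' @param contextRates named numeric vector of per-target substitution and
#'   B-indel rates; see [RateModel-class] for required names. Missing
#'   names default to zero.
#' @param expansion,contraction,insertion per-target rate curves over
#'   1..LBoundary; scalars are recycled.
#' @param LBoundary boundary length.
#' @return A [RateModel-class].
#' @examples
#' rateModel(c(lengthen = 4.77e-9, shorten = 8.08e-9), LBoundary = 50)
#' @export
rateModel <- function(contextRates = numeric(), expansion = 0,
                      contraction = 0, insertion = 0, LBoundary = 100L) {
  LBoundary <- as.integer(LBoundary)
  cr <- setNames(numeric(length(.CONTEXT_RATE_NAMES)), .CONTEXT_RATE_NAMES)
  if (length(contextRates)) {
    bad <- setdiff(names(contextRates), .CONTEXT_RATE_NAMES)
    if (length(bad))
      stop("unknown context rate name(s): ", paste(bad, collapse = ", "))
    cr[names(contextRates)] <- contextRates
  }
  expand <- function(v) {
    v <- as.numeric(v)
    if (length(v) == 1L) v <- rep(v, LBoundary)
    if (length(v) != LBoundary)
      stop("rate curves must be scalar or length LBoundary")
    v
  }
  new("RateModel", contextRates = cr, expansion = expand(expansion),
      contraction = expand(contraction), insertion = expand(insertion),
      LBoundary = LBoundary)
}

#' @describeIn rateModel Named context substitution / B-indel rates.
#' @param x a \code{RateModel}.
#' @export
contextRates <- function(x) x@contextRates

#' @describeIn rateModel Per-target expansion rate curve.
#' @export
expansionRates <- function(x) x@expansion

#' @describeIn rateModel Per-target contraction rate curve.
#' @export
contractionRates <- function(x) x@contraction

#' @describeIn rateModel Per-target non-motif insertion rate curve.
#' @export
insertionRates <- function(x) x@insertion

setMethod("show", "RateModel", function(object) {
  cat("RateModel (LBoundary ", object@LBoundary, ")\n", sep = "")
  cr <- object@contextRates
  cat("  substitutions:",
      paste(names(cr), signif(cr, 3), sep = "=", collapse = " "), "\n")
  cat("  expansion(8) =", signif(object@expansion[8], 3),
      " contraction(8) =", signif(object@contraction[8], 3),
      " insertion(8) =", signif(object@insertion[8], 3), "\n")
})

#' Construct InstabilityParams
#'
#' @param m multiplier at L = 9 (>= 1).
#' @param tauE,tauK power-law exponents in [0, 5]; the insertion exponent
#'   is fixed to \code{tauE}.
#' @return An [InstabilityParams-class].
#' @examples
#' deltaTau(instabilityParams(2, 1.7, 2.0))
#' @export
instabilityParams <- function(m, tauE, tauK) {
  new("InstabilityParams", m = as.numeric(m), tauE = as.numeric(tauE),
      tauK = as.numeric(tauK))
}

#' @describeIn instabilityParams The contraction-bias exponent difference
#'   tauK - tauE; steady states require a positive value.
#' @param x an \code{InstabilityParams}.
#' @export
deltaTau <- function(x) x@tauK - x@tauE

setMethod("show", "InstabilityParams", function(object) {
  cat(sprintf("InstabilityParams: m = %g, tauE = %g, tauK = %g (deltaTau = %g)\n",
              object@m, object@tauE, object@tauK, deltaTau(object)))
})

setMethod("show", "MotifClass", function(object) {
  cat("MotifClass ", object@unit, ": {",
      paste(object@members, collapse = ", "), "}\n", sep = "")
})

setMethod("show", "SteadyStateSolution", function(object) {
  cat("SteadyStateSolution (", object@equation, ")\n", sep = "")
  cat("  domain: [", min(object@lengths), ", ", max(object@lengths),
      "]  L* = ", signif(object@LStar, 4), "  Lmax = ",
      signif(object@LMax, 4), "\n", sep = "")
  if (object@negative) cat("  ** solution has negative values **\n")
})

setMethod("show", "BootstrapEnvelope", function(object) {
  cat("BootstrapEnvelope: ", object@nResamples, " resamples of ",
      object@segmentLength, " bp segments over ", length(object@point),
      " bins\n", sep = "")
})
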