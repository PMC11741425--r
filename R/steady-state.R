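# Analytic and numerical characterization of steady states: geometric
# short-length regime, characteristic lengths L* and Lmax, and the nested
# steady-state ODE approximations for the long repeat regime.

#' Geometric equilibrium of the short repeat regime
#'
#' Under two-way substitutions alone the steady state equals the run
#' length statistics of a random sequence with focal-base probability
#' mu/(mu + nu): P(L) proportional to (mu/(mu + nu))^L.  When a reference
#' distribution is supplied the normalization is fixed by matching its
#' L = 1 mass.
#'
#' @param mu lengthening (B-to-A) substitution rate.
#' @param nu shortening (A-to-B) substitution rate.
#' @param LRange lengths to evaluate (default 1:10).
#' @param reference optional reference values (numeric indexed by length,
#'   or a [LengthDistribution-class]); the output is scaled so its first
#'   bin matches \code{reference[LRange[1]]}.
#' @return Numeric vector over \code{LRange} (normalized to sum to one
#'   when no reference is given).
#' @export
geometricEquilibrium <- function(mu, nu, LRange = 1:10, reference = NULL) {
  if (mu + nu <= 0) stop("mu + nu must be positive")
  p <- mu / (mu + nu)
  v <- p^LRange
  if (!is.null(reference)) {
    ref <- if (is(reference, "LengthDistribution")) distCounts(reference)
           else as.numeric(reference)
    v <- v * ref[LRange[1L]] / v[1L]
  } else v <- v / sum(v)
  setNames(v, LRange)
}

#' Length where contraction balances expansion
#'
#' Under the shared-multiplier power-law parameterization the expansion
#' and contraction curves cross at
#' L* = 9 (epsilon_8 / kappa_8)^(1 / deltaTau) (the multiplier m
#' cancels), clipped to \[9, LBoundary\].  L* depends only on deltaTau
#' and the L = 8 rate ratio, so it is constant along lines of constant
#' deltaTau.
#'
#' @param rates a [RateModel-class] (the L = 8 curve values are the
#'   de novo rates) or a list with \code{expansion}/\code{contraction}
#'   vectors covering L = 8.
#' @param params an [InstabilityParams-class] with deltaTau > 0.
#' @param LBoundary upper clip (default from \code{rates} when it is a
#'   RateModel, else 100).
#' @return L* (real-valued).
#' @export
computeLStar <- function(rates, params, LBoundary = NULL) {
  dt <- deltaTau(params)
  if (dt <= 0)
    stop("expansion and contraction curves do not cross for deltaTau <= 0")
  if (is(rates, "RateModel")) {
    e8 <- rates@expansion[8L]; k8 <- rates@contraction[8L]
    if (is.null(LBoundary)) LBoundary <- rates@LBoundary
  } else {
    e8 <- rates$expansion[8L]; k8 <- rates$contraction[8L]
    if (is.null(LBoundary)) LBoundary <- 100L
  }
  min(max(9 * (e8 / k8)^(1 / dt), 9), LBoundary)
}

#' Truncation length of a distribution in a finite genome
#'
#' The smallest length at which fewer than one repeat is expected:
#' P(L) * total < 1.
#'
#' @param x normalized probabilities (numeric indexed by length), a
#'   [LengthDistribution-class], or a [JointState-class] (whose raw
#'   repeat counts are used directly).
#' @param total genome-wide repeat total (ignored for a
#'   \code{JointState}).
#' @return Integer length; 1 when the distribution is empty.
#' @export
computeLMax <- function(x, total = NULL) {
  counts <- if (is(x, "JointState")) countsA(x)
    else if (is(x, "LengthDistribution")) {
      if (is.null(total)) stop("'total' required for a distribution")
      distCounts(x) / sum(distCounts(x)) * total
    } else {
      if (is.null(total)) stop("'total' required for a probability vector")
      as.numeric(x) / sum(x) * total
    }
  below <- which(counts < 1)
  if (!length(below)) length(counts) + 1L else below[1L]
}

# Continuous per-target rate curves of the power-law parameterization
# (capped at 0.1, matching the kernel).
.curve_fun <- function(rate8, m, tau) {
  function(L) pmin(0.1, m * rate8 * (L / 9)^tau)
}

# Differentiation matrices on a uniform grid (2nd-order central interior,
# one-sided at the edges).
.diff_matrix <- function(n, h, order = 1L) {
  D <- matrix(0, n, n)
  if (order == 1L) {
    for (i in 2:(n - 1L)) { D[i, i - 1L] <- -1 / (2 * h); D[i, i + 1L] <- 1 / (2 * h) }
    D[1L, 1:3] <- c(-3, 4, -1) / (2 * h)
    D[n, (n - 2L):n] <- c(1, -4, 3) / (2 * h)
  } else {
    for (i in 2:(n - 1L)) {
      D[i, (i - 1L):(i + 1L)] <- c(1, -2, 1) / h^2
    }
    D[1L, 1:4] <- c(2, -5, 4, -1) / h^2
    D[n, (n - 3L):n] <- c(-1, 4, -5, 2) / h^2
  }
  D
}

#' Solve a nested steady-state ODE approximation of the long repeat tail
#'
#' Solves, on a uniform length grid between round(L*) and Lmax, one of
#' the nested approximations of the steady-state equation for the long
#' repeat regime (fusion neglected throughout; all rates per target):
#' \describe{
#'   \item{\code{"local"}}{0.5 (d^2/dL^2)\[(eps+kap) L P\] -
#'     (d/dL)\[(eps-kap) L P\] = 0 — diffusion and directional flux from
#'     expansion/contraction only (valid for strong contraction bias).}
#'   \item{\code{"fission_out"}}{adds the loss term -(nu + iota) L P for
#'     fission of length-L repeats (moderate contraction bias).}
#'   \item{\code{"full_fission"}}{the length-derivative (third-order)
#'     form that also retains fission influx from longer repeats, with
#'     the vanishing-net-flux constraint imposed through a third
#'     reference value at Lmax - 1 (weak contraction bias).}
#' }
#' Solutions are pinned to the reference distribution at L1 = round(L*)
#' and L2 = Lmax (and L3 = Lmax - 1 for the third-order form); reference
#' values at non-integer lengths are log-linearly interpolated.
#'
#' @param equation which approximation to solve.
#' @param params an [InstabilityParams-class] (deltaTau > 0).
#' @param denovo list with per-target \code{expansion},
#'   \code{contraction}, \code{insertion} rates covering L = 8 (the
#'   power-law anchors).
#' @param nu the A-to-B substitution rate entering the fission terms.
#' @param reference a [JointState-class] (kernel steady state) providing
#'   the constraint values and Lmax.
#' @param gridStep grid resolution in length units (default 0.25).
#' @param LBoundary clip for L* (default from the reference state).
#' @return A [SteadyStateSolution-class].
#' @export
solveSteadyODE <- function(equation = c("local", "fission_out",
                                        "full_fission"),
                           params, denovo, nu, reference,
                           gridStep = 0.25, LBoundary = NULL) {
  equation <- match.arg(equation)
  if (deltaTau(params) <= 0)
    stop("steady-state solutions require deltaTau > 0")
  if (is.null(LBoundary)) LBoundary <- LBoundary(reference)
  epsf <- .curve_fun(denovo$expansion[8L], params@m, params@tauE)
  kapf <- .curve_fun(denovo$contraction[8L], params@m, params@tauK)
  iotf <- .curve_fun(denovo$insertion[8L], params@m, params@tauE)
  LStar <- computeLStar(list(expansion = denovo$expansion,
                             contraction = denovo$contraction),
                        params, LBoundary)
  counts <- countsA(reference)
  LMax <- computeLMax(reference)
  L1 <- round(LStar)
  if (LMax <= L1 + 2)
    stop("reference truncates too close to L*: no long-repeat domain")
  # log-linear interpolation of the reference counts
  refAt <- function(L) {
    lo <- floor(L); hi <- ceiling(L)
    if (lo == hi) return(counts[lo])
    exp(log(counts[lo]) + (L - lo) *
          (log(counts[hi]) - log(counts[lo])))
  }
  n <- max(8L, ceiling((LMax - L1) / gridStep) + 1L)
  grid <- seq(L1, LMax, length.out = n)
  h <- grid[2L] - grid[1L]
  a <- (epsf(grid) + kapf(grid)) * grid
  b <- (epsf(grid) - kapf(grid)) * grid
  cc <- (nu + iotf(grid)) * grid
  D1 <- .diff_matrix(n, h, 1L)
  D2 <- .diff_matrix(n, h, 2L)
  M <- switch(equation,
    local = 0.5 * D2 %*% diag(a) - D1 %*% diag(b),
    fission_out = 0.5 * D2 %*% diag(a) - D1 %*% diag(b) - diag(cc),
    full_fission = {
      D3 <- D1 %*% D2
      0.5 * D3 %*% diag(a) - D2 %*% diag(b) - D1 %*% diag(cc) -
        2 * diag(nu + iotf(grid))
    })
  rhs <- numeric(n)
  # constraint rows: first and last grid points, plus Lmax - 1 for the
  # third-order equation
  constrIdx <- c(1L, n)
  constrL <- c(grid[1L], grid[n])
  if (equation == "full_fission") {
    i3 <- which.min(abs(grid - (LMax - 1)))
    constrIdx <- c(constrIdx, i3)
    constrL <- c(constrL, grid[i3])
  }
  constrV <- vapply(constrL, refAt, 0)
  # solutions decay over several orders of magnitude across the domain;
  # solving for the ratio to the (log-interpolated) reference profile
  # keeps the unknowns O(1) and the system well conditioned
  scale <- vapply(grid, refAt, 0)
  M <- M %*% diag(scale)
  for (k in seq_along(constrIdx)) {
    M[constrIdx[k], ] <- 0
    M[constrIdx[k], constrIdx[k]] <- 1
    rhs[constrIdx[k]] <- constrV[k] / scale[constrIdx[k]]
  }
  sol <- tryCatch(solve(M, rhs), error = function(e)
    qr.solve(M, rhs, tol = 1e-14))
  if (any(!is.finite(sol)))
    stop("steady-state ODE solve did not converge")
  sol <- sol * scale
  new("SteadyStateSolution", lengths = grid, values = as.numeric(sol),
      equation = equation, LStar = LStar, LMax = as.numeric(LMax),
      constraints = data.frame(length = constrL, value = constrV),
      negative = any(sol < 0))
}

#' Classify the dynamical regime of a parameter combination
#'
#' deltaTau <= 0 never reaches steady state (the edge case tauK = tauE is
#' asymptotically expansion-biased under the shared parameterization);
#' positive deltaTau splits into weakly (< 0.5), intermediate (< 1) and
#' strongly contraction-biased regimes, matching which nested steady-state
#' approximation suffices.  The numeric thresholds are heuristics
#' reflecting where fission influx and outflux stop being negligible.
#'
#' @param params an [InstabilityParams-class].
#' @param thresholds the two deltaTau cut points (default c(0.5, 1)).
#' @return list with \code{label} and \code{deltaTau}.
#' @export
classifyRegime <- function(params, thresholds = c(0.5, 1)) {
  dt <- deltaTau(params)
  label <- if (dt <= 0) "unstable"
    else if (dt < thresholds[1L]) "weakly_contraction_biased"
    else if (dt < thresholds[2L]) "intermediate"
    else "strongly_contraction_biased"
  list(label = label, deltaTau = dt)
}

#' @describeIn solveSteadyODE Solution values at the grid points (for
#'   comparison, interpolated to integer lengths with \code{approx}).
#' @param object a \code{SteadyStateSolution}.
#' @param at lengths at which to evaluate.
#' @export
solutionAt <- function(object, at) {
  stats::approx(object@lengths, object@values, xout = at)$y
}
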