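# Independent brute-force oracle for contiguous repeat counting, built on
# the regex engine rather than the package's frame-wise scanner.  Maximal
# runs of complete motif copies are located with gregexpr per member
# motif; overlapping detections are deduplicated with the same
# longest-run-first greedy rule the package defines.

oracle_count_runs <- function(seq, motif) {
  n <- nchar(repeatflux::motifUnit(motif))
  len <- nchar(seq)
  cand <- list()
  for (m in repeatflux::motifMembers(motif)) {
    # overlapping matches via lookahead (a run in one frame may overlap a
    # run of the same member in another frame), restricted to run starts
    # (no further copy of m immediately before the match)
    g <- gregexpr(paste0("(?=((?:", m, ")+))"), seq, perl = TRUE)[[1]]
    if (g[1] == -1) next
    starts <- as.integer(g)
    units <- attr(g, "capture.length")[, 1] %/% n
    atStart <- starts <= n |
      substring(seq, starts - n, starts - 1L) != m
    keep <- units >= 1 & atStart
    cand[[m]] <- cbind(start = starts[keep],
                       end = starts[keep] + units[keep] * n - 1L,
                       units = units[keep])
  }
  cand <- do.call(rbind, cand)
  countsA <- numeric(0)
  covered <- logical(len)
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(-cand[, "units"], cand[, "start"]), , drop = FALSE]
    kept_units <- integer(0)
    for (i in seq_len(nrow(cand))) {
      s <- cand[i, "start"]; e <- cand[i, "end"]
      if (!any(covered[s:e])) {
        covered[s:e] <- TRUE
        kept_units <- c(kept_units, cand[i, "units"])
      }
    }
    if (length(kept_units)) countsA <- tabulate(kept_units)
  }
  # B strings: maximal uncovered non-N stretches
  chars <- strsplit(seq, "")[[1]]
  free <- !covered & chars != "N"
  r <- rle(free)
  blens <- r$lengths[r$values]
  countsB <- if (length(blens)) tabulate(blens) else numeric(0)
  list(A = countsA, B = countsB)
}

# Random test sequence over ACGT with occasional N
random_seq <- function(len, pN = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
               prob = c((1 - pN) / 4, (1 - pN) / 4, (1 - pN) / 4,
                        (1 - pN) / 4, pN)), collapse = "")
}

# The package's reference rate calibration, shared across tests
fix_rates <- repeatflux::defaultRateSet()

# Substitution-only two-way rate model (all B -> A channels at mu, all
# A -> B channels at nu), the setting of the analytic short-length theory
twoWayRateModel <- function(mu, nu, LBoundary) {
  repeatflux::rateModel(c(lengthen = mu, fusion = mu, createA1 = mu,
                          shorten = nu, fission = nu, destroyA1 = nu),
                        LBoundary = LBoundary)
}

# Context rates with the B-string background indels switched off: the
# biased B indel drift has no steady state and is orthogonal to the
# repeat-instability dynamics under test
contextNoB <- function() {
  cr <- fix_rates$contextRates
  cr[c("bInsert", "bDelete", "b1DeleteFusion")] <- 0
  cr
}

expect_counts_equal <- function(a, b) {
  la <- length(a); lb <- length(b)
  n <- max(la, lb)
  expect_equal(c(a, numeric(n - la)), c(b, numeric(n - lb)),
               ignore_attr = TRUE)
}
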