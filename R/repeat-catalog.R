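# Genome-wide contiguous repeat-length distributions per motif
# equivalence class.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp <- function(s) {
  paste(rev(.COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
}

.rotations <- function(s) {
  n <- nchar(s)
  vapply(seq_len(n) - 1L, function(k)
    paste0(substring(s, k + 1L, n), substring(s, 1L, k)), "")
}

#' Motif equivalence class of a repeat unit
#'
#' All motifs describing the same tandem repeat on either strand: the
#' rotations of \code{unit} and of its reverse complement.  Histograms of
#' equivalent motifs (e.g. A = A/T, AC = AC/CA/TG/GT) are summed when
#' counting.
#'
#' @param unit repeat unit, 1--6 nt over ACGT (case-insensitive).
#' @return A [MotifClass-class].
#' @examples
#' motifClass("AC")   # {AC, CA, GT, TG}
#' @export
motifClass <- function(unit) {
  unit <- toupper(unit)
  if (!nzchar(unit) || grepl("[^ACGT]", unit))
    stop("'unit' must be a non-empty string over A/C/G/T")
  members <- sort(unique(c(.rotations(unit), .rotations(.revcomp(unit)))))
  new("MotifClass", unit = members[1L], members = members)
}

#' @describeIn motifClass Member motifs of the class.
#' @param x a \code{MotifClass}.
#' @export
motifMembers <- function(x) x@members

#' @describeIn motifClass Canonical (lexicographically smallest) unit.
#' @export
motifUnit <- function(x) x@unit

#' @describeIn motifClass Unit length in nucleotides.
#' @export
unitLength <- function(x) nchar(x@unit)

# Coerce genome input (character vector, DNAString, DNAStringSet) to an
# uppercase character vector of contig sequences.
.as_contigs <- function(x) {
  nm <- if (is.character(x)) names(x) else NULL
  if (is(x, "DNAStringSet")) x <- as.character(x)   # keeps names
  else if (is(x, "DNAString")) x <- as.character(x)
  out <- toupper(as.character(x))
  if (!is.null(nm)) names(out) <- nm else names(out) <- names(x)
  out
}

# Maximal runs of consecutive complete copies of `member` in one contig,
# scanned in all nchar(member) frames.  Returns matrix [start, end, units].
.member_runs <- function(chars, member) {
  n <- nchar(member)
  len <- length(chars)
  if (len < n) return(matrix(numeric(0), ncol = 3L))
  mb <- strsplit(member, "")[[1]]
  # match[i]: complete copy of member starts at i
  match <- chars[seq_len(len - n + 1L)] == mb[1L]
  if (n > 1L) for (k in 2L:n)
    match <- match & chars[seq.int(k, len - n + k)] == mb[k]
  out <- vector("list", n)
  for (f in seq_len(n) - 1L) {
    idx <- seq.int(f + 1L, len - n + 1L, by = n)
    r <- rle(match[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) next
    units <- r$lengths[keep]
    s <- idx[starts[keep]]
    out[[f + 1L]] <- cbind(s, s + units * n - 1L, units)
  }
  do.call(rbind, c(out, list(matrix(numeric(0), ncol = 3L))))
}

#' Count contiguous repeats of a motif class
#'
#' Scans a genome for maximal runs of consecutive complete motif copies
#' (no interruptions, no partial motifs), in all \code{n} frames for unit
#' length \code{n}, summing over all motifs in the equivalence class.
#' Overlapping detections of the same genomic interval by rotationally
#' equivalent members are deduplicated by keeping, per interval, the single
#' longest frame-consistent run.  Non-motif (B) string lengths are counted
#' analogously as the maximal stretches not covered by any kept run;
#' \code{N} breaks both repeat and non-repeat runs and belongs to neither.
#'
#' @param x genome: character vector of contigs, \code{DNAString} or
#'   \code{DNAStringSet}.
#' @param motif a [MotifClass-class] (or a unit string).
#' @return A list with elements \code{A} (repeat run lengths, in repeat
#'   units) and \code{B} (non-motif string lengths, in nucleotides; equal
#'   to units for mononucleotide motifs), both [LengthDistribution-class].
#' @examples
#' countRepeats("AAACAA", motifClass("A"))
#' @export
countRepeats <- function(x, motif) {
  if (is.character(motif) && length(motif) == 1L) motif <- motifClass(motif)
  contigs <- .as_contigs(x)
  n <- unitLength(motif)
  countsA <- numeric(0)
  countsB <- numeric(0)
  add <- function(tab, lens) {
    if (!length(lens)) return(tab)
    m <- max(lens)
    if (length(tab) < m) tab <- c(tab, numeric(m - length(tab)))
    t2 <- tabulate(lens, nbins = length(tab))
    tab + t2
  }
  for (ct in contigs) {
    if (!nzchar(ct)) next
    if (grepl("[^ACGTN]", ct))
      stop("sequence contains characters outside A/C/G/T/N")
    chars <- strsplit(ct, "")[[1]]
    runs <- do.call(rbind, lapply(motifMembers(motif),
                                  function(mm) .member_runs(chars, mm)))
    kept <- matrix(numeric(0), ncol = 3L)
    if (nrow(runs)) {
      runs <- runs[order(-runs[, 3L], runs[, 1L]), , drop = FALSE]
      covered <- logical(length(chars))
      keep <- logical(nrow(runs))
      for (i in seq_len(nrow(runs))) {
        s <- runs[i, 1L]; e <- runs[i, 2L]
        if (!any(covered[s:e])) {
          covered[s:e] <- TRUE
          keep[i] <- TRUE
        }
      }
      kept <- runs[keep, , drop = FALSE]
    } else covered <- logical(length(chars))
    countsA <- add(countsA, kept[, 3L])
    # B strings: uncovered, non-N stretches
    free <- !covered & chars != "N"
    r <- rle(free)
    countsB <- add(countsB, r$lengths[r$values])
  }
  list(A = lengthDistribution(countsA, unitLength = n),
       B = lengthDistribution(countsB, unitLength = 1L))
}

#' Normalize a length distribution to a probability distribution
#'
#' Divides every bin by the total count; raw counts are retained in the
#' \code{raw} slot.  Idempotent.
#'
#' @param x a [LengthDistribution-class] with positive total.
#' @return The normalized distribution.
#' @export
normalizeDistribution <- function(x) {
  tot <- sum(x@counts)
  if (tot <= 0) stop("cannot normalize an all-zero distribution")
  x@counts <- x@counts / tot
  x@normalized <- TRUE
  validObject(x)
  x
}

#' Truncate a distribution at the first low-occupancy length
#'
#' Removes all bins at and above the first length whose raw count falls
#' below \code{minCount}; later bins are dropped even if they again exceed
#' the threshold.  This accounts for assembly-length differences that
#' affect sampling noise in cross-species comparisons.
#'
#' @param x a [LengthDistribution-class].
#' @param minCount occupancy threshold (default 30).
#' @return The truncated distribution, with \code{truncationLength} set
#'   when truncation occurred.
#' @export
truncateLowOccupancy <- function(x, minCount = 30) {
  low <- which(x@raw < minCount)
  if (!length(low)) return(x)
  t <- low[1L]
  x@truncationLength <- as.integer(t)
  x@counts <- x@counts[seq_len(t - 1L)]
  x@raw <- x@raw[seq_len(t - 1L)]
  x
}

#' Discard short contigs before counting
#'
#' Short-read assemblies contain many short contigs from poorly sequenced
#' regions; contigs shorter than \code{minLength} bp are removed.
#'
#' @param x genome (character vector or \code{DNAStringSet}).
#' @param minLength minimum contig length in bp (default 10000).
#' @return The filtered genome, same class as the input.
#' @export
filterContigs <- function(x, minLength = 10000) {
  if (is(x, "DNAStringSet")) return(x[Biostrings::width(x) >= minLength])
  x[nchar(x) >= minLength]
}

#' Per-bin median distribution across species
#'
#' @param dists list of normalized [LengthDistribution-class] objects;
#'   bins absent from a species are treated as zero, and no truncation is
#'   applied before taking the median.
#' @return A [LengthDistribution-class] of per-bin medians (not itself
#'   normalized).
#' @export
medianDistribution <- function(dists) {
  if (!length(dists)) stop("need at least one distribution")
  maxL <- max(vapply(dists, function(d) length(d@counts), 1L))
  mat <- vapply(dists, function(d) {
    v <- d@counts
    c(v, numeric(maxL - length(v)))
  }, numeric(maxL))
  med <- apply(matrix(mat, nrow = maxL), 1L, median)
  d <- lengthDistribution(med, unitLength = dists[[1L]]@unitLength)
  d
}

# Evaluate expr with a temporary RNG state seeded by `seed` (NULL = leave
# the RNG alone).
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Repeat distribution of a uniformly shuffled genome
#'
#' Pools all nucleotides across contigs, permutes them uniformly at
#' random, redistributes them into contigs of the original lengths, and
#' counts repeats.  For an i.i.d. sequence the resulting run-length
#' distribution decays geometrically, so this provides the random-sequence
#' baseline against which the genomic excess of long repeats is measured.
#'
#' @param x genome (character vector or \code{DNAStringSet}).
#' @param motif a [MotifClass-class].
#' @param seed RNG seed (NULL leaves the RNG state alone).
#' @return The \code{A}-side [LengthDistribution-class] of the shuffled
#'   genome.
#' @export
shuffledBaseline <- function(x, motif, seed = NULL) {
  contigs <- .as_contigs(x)
  bases <- unlist(strsplit(contigs, ""), use.names = FALSE)
  shuffled <- .with_seed(seed, sample(bases))
  lens <- nchar(contigs)
  stops <- cumsum(lens)
  starts <- stops - lens + 1L
  newContigs <- vapply(seq_along(lens), function(i)
    paste(shuffled[starts[i]:stops[i]], collapse = ""), "")
  countRepeats(newContigs, motif)$A
}

# Split contigs into `segment`-bp contiguous non-overlapping pieces,
# discarding sub-segment tails.
.segment_genome <- function(contigs, segment) {
  segs <- character(0)
  for (ct in contigs) {
    k <- nchar(ct) %/% segment
    if (k < 1L) next
    starts <- (seq_len(k) - 1L) * segment + 1L
    segs <- c(segs, substring(ct, starts, starts + segment - 1L))
  }
  segs
}

#' Bootstrap envelope of a genome-wide repeat length distribution
#'
#' The genome is divided into contiguous non-overlapping segments
#' (sub-segment chromosome ends are discarded) and the per-segment repeat
#' length distributions are resampled with replacement \code{n} times; the
#' per-bin 95\% envelope discards the top and bottom 2.5\% of resampled
#' values (25 each side for the default n = 1000).
#'
#' @param x genome (character vector or \code{DNAStringSet}); total usable
#'   length must reach one segment.
#' @param motif a [MotifClass-class].
#' @param n number of resamples (default 1000).
#' @param segment segment length in bp (default 1e6).
#' @param seed RNG seed.
#' @return A [BootstrapEnvelope-class].
#' @export
bootstrapEnvelope <- function(x, motif, n = 1000, segment = 1e6,
                              seed = NULL) {
  contigs <- .as_contigs(x)
  segs <- .segment_genome(contigs, as.integer(segment))
  if (!length(segs))
    stop("genome is shorter than one segment (", segment, " bp)")
  perSeg <- lapply(segs, function(s) countRepeats(s, motif)$A@counts)
  maxL <- max(vapply(perSeg, length, 1L), 1L)
  mat <- vapply(perSeg, function(v) c(v, numeric(maxL - length(v))),
                numeric(maxL))
  mat <- matrix(mat, nrow = maxL)
  point <- rowSums(mat)
  nseg <- ncol(mat)
  res <- .with_seed(seed, {
    vapply(seq_len(n), function(i) {
      pick <- sample.int(nseg, nseg, replace = TRUE)
      rowSums(mat[, pick, drop = FALSE])
    }, numeric(maxL))
  })
  res <- matrix(res, nrow = maxL)
  drop <- round(25 * n / 1000)
  lo <- numeric(maxL); hi <- numeric(maxL)
  for (b in seq_len(maxL)) {
    v <- sort(res[b, ])
    keep <- v[seq.int(drop + 1L, n - drop)]
    lo[b] <- keep[1L]; hi[b] <- keep[length(keep)]
  }
  new("BootstrapEnvelope", lower = lo, upper = hi, point = point,
      nResamples = as.integer(n), segmentLength = as.integer(segment))
}

#' Read a genome FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] (multi-record, gzip
#' transparently supported).
#'
#' @param path FASTA file path.
#' @return A \code{DNAStringSet}.
#' @export
readGenome <- function(path) Biostrings::readDNAStringSet(path)

#' Write length distributions as TSV
#'
#' @param dists named list of [LengthDistribution-class] objects (names are
#'   motif units).
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeDistributionTSV <- function(dists, file) {
  rows <- lapply(names(dists), function(mu) {
    d <- dists[[mu]]
    L <- distLengths(d)
    raw <- d@raw
    tot <- sum(raw)
    data.frame(motif = mu, length_units = L, length_nt = L * d@unitLength,
               count = raw,
               frequency = if (tot > 0) raw / tot else 0)
  })
  tab <- do.call(rbind, rows)
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read length distributions from TSV
#'
#' @param file TSV written by [writeDistributionTSV()].
#' @return Named list of [LengthDistribution-class] objects.
#' @export
readDistributionTSV <- function(file) {
  tab <- read.table(file, sep = "\t", header = TRUE,
                    colClasses = c(motif = "character"))
  out <- lapply(split(tab, tab$motif), function(df) {
    lengthDistribution(setNames(df$count, df$length_units),
                       unitLength = df$length_nt[1L] %/% df$length_units[1L])
  })
  out
}
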