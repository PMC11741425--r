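# Synthetic inputs with known ground truth: i.i.d. genomes, de novo trio
# mutation tables, popSTR-style locus tables, and kernel-generated
# pseudo-empirical distributions.

#' Generate an i.i.d. random genome
#'
#' Bases are drawn independently; with \code{pA} given, the focal base A
#' has probability \code{pA} and C/G/T share the remainder equally, so
#' that A-run lengths are geometric with ratio \code{pA} in expectation.
#'
#' @param length genome length in bp.
#' @param pA probability of the focal base (alternative to
#'   \code{composition}).
#' @param composition named probabilities for A, C, G, T (overrides
#'   \code{pA}).
#' @param seed RNG seed.
#' @param name contig name (default \code{"chr1"}).
#' @return Named character vector with one contig.
#' @examples
#' g <- generateIIDGenome(1e4, pA = 0.3, seed = 1)
#' @export
generateIIDGenome <- function(length, pA = 0.25, composition = NULL,
                              seed = NULL, name = "chr1") {
  if (is.null(composition)) {
    composition <- c(A = pA, C = (1 - pA) / 3, G = (1 - pA) / 3,
                     T = (1 - pA) / 3)
  }
  if (abs(sum(composition) - 1) > 1e-9)
    stop("base probabilities must sum to 1")
  s <- .with_seed(seed, paste(sample(names(composition), length,
                                     replace = TRUE,
                                     prob = composition), collapse = ""))
  setNames(s, name)
}

#' Write mutation records as a minimal VCF
#'
#' Records are emitted as VCF 4.2 with a single sample column (the
#' proband genotype), 1-based positions and left-aligned indels, so that
#' the same readers used for real call sets apply to synthetic tables.
#'
#' @param records data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt} (and optionally \code{proband}).
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeMutationVCF <- function(records, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=repeatflux-synthetic",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "PROBAND", sep = "\t")), con)
  if (nrow(records)) {
    o <- order(records$chrom, records$pos)
    writeLines(paste(records$chrom[o], records$pos[o], ".",
                     records$ref[o], records$alt[o], ".", "PASS", ".",
                     "GT", "0/1", sep = "\t"), con)
  }
  invisible(file)
}

#' Read a mutation table from VCF
#'
#' Uses [VariantAnnotation::readVcf()]; multi-allelic records are
#' expanded.
#'
#' @param file VCF path (plain or bgzipped).
#' @return data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}.
#' @export
readMutationVCF <- function(file) {
  vcf <- VariantAnnotation::readVcf(file)
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(rr)),
             pos = BiocGenerics::start(rr),
             ref = as.character(rr$REF),
             alt = as.character(rr$ALT))
}

# Sites (contig, pos) of each substitution context category for member b.
.context_sites <- function(chars, b) {
  n <- length(chars)
  if (n < 3L) return(list())
  mid <- chars[2:(n - 1L)]
  left <- chars[1:(n - 2L)]
  right <- chars[3:n]
  ok <- mid != "N" & left != "N" & right != "N"
  isb <- mid == b
  nA <- (left == b) + (right == b)
  pos <- 2:(n - 1L)
  list(lengthen = pos[ok & !isb & nA == 1L],
       fusion = pos[ok & !isb & nA == 2L],
       createA1 = pos[ok & !isb & nA == 0L],
       shorten = pos[ok & isb & nA == 1L],
       fission = pos[ok & isb & nA == 2L],
       destroyA1 = pos[ok & isb & nA == 0L])
}

#' Generate a de novo trio mutation table under known rates
#'
#' Substitutions are placed per context category at the truth rates times
#' the diploid number of context sites and offspring; single-unit indels
#' are placed per repeat at the length-dependent truth rates (per-repeat
#' rates; expansions insert the member base, contractions delete one
#' unit, non-motif insertions split runs of at least two units).  Counts
#' are Poisson distributed around their expectations.
#'
#' @param genome named character vector of contigs.
#' @param contextRates named truth rates (per context site per
#'   generation): any of lengthen, shorten, fusion, fission, createA1,
#'   destroyA1.
#' @param indelRates list with per-repeat truth rate vectors
#'   \code{expansion}, \code{contraction}, \code{insertion} indexed by
#'   repeat length.
#' @param nOffspring number of offspring genomes.
#' @param motif motif class whose members receive events (default the
#'   A/T class); events are generated for each member at the same truth
#'   rates, matching the estimator's pooled counting.  Substituted or
#'   inserted non-motif bases are drawn from outside the class, which
#'   keeps cross-member reclassification of generated events to the
#'   unavoidable minimum (a gain event whose reference base is the other
#'   member is also a loss event for that member).
#' @param seed RNG seed.
#' @return data.frame of mutation records (chrom, pos, ref, alt).
#' @export
generateTrioTable <- function(genome, contextRates = numeric(),
                              indelRates = list(), nOffspring = 100,
                              motif = motifClass("A"), seed = NULL) {
  .with_seed(seed, {
    chars_all <- .contig_chars(genome)
    others <- setdiff(c("A", "C", "G", "T"), motifMembers(motif))
    recs <- list()
    for (cn in names(chars_all)) for (member in motifMembers(motif)) {
      cc <- chars_all[[cn]]
      sites <- .context_sites(cc, member)
      for (cat in intersect(names(contextRates), names(sites))) {
        p <- sites[[cat]]
        if (!length(p)) next
        nev <- rpois(1L, contextRates[[cat]] * 2 * nOffspring * length(p))
        if (!nev) next
        gain <- cat %in% c("lengthen", "fusion", "createA1")
        if (gain) {
          # placement restricted to non-class reference bases so the
          # event is not simultaneously a loss for the other member;
          # the event total still reflects the full context-site count
          p <- p[cc[p] %in% others]
          if (!length(p)) next
        }
        at <- sample(p, nev, replace = TRUE)
        recs[[length(recs) + 1L]] <- data.frame(
          chrom = cn, pos = at, ref = cc[at],
          alt = if (gain) member else sample(others, nev, replace = TRUE))
      }
      if (length(indelRates)) {
        # enumerate member-base runs (start, length)
        r <- rle(cc == member)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        runs <- cbind(starts[r$values], r$lengths[r$values])
        if (nrow(runs)) for (i in seq_len(nrow(runs))) {
          s <- runs[i, 1L]; L <- runs[i, 2L]
          if (s < 2L) next  # need an anchor base before the run
          anchor <- cc[s - 1L]
          rate <- function(v) if (L <= length(v) && is.finite(v[L])) v[L] else 0
          nexp <- rpois(1L, rate(indelRates$expansion) * 2 * nOffspring)
          ncon <- if (L >= 2L)
            rpois(1L, rate(indelRates$contraction) * 2 * nOffspring) else 0L
          nins <- if (L >= 2L)
            rpois(1L, rate(indelRates$insertion) * 2 * nOffspring) else 0L
          if (nexp) recs[[length(recs) + 1L]] <- data.frame(
            chrom = cn, pos = rep(s - 1L, nexp), ref = anchor,
            alt = paste0(anchor, member))
          if (ncon) recs[[length(recs) + 1L]] <- data.frame(
            chrom = cn, pos = rep(s - 1L, ncon),
            ref = paste0(anchor, member), alt = anchor)
          if (nins) recs[[length(recs) + 1L]] <- data.frame(
            chrom = cn, pos = rep(s, nins), ref = member,
            alt = paste0(member, sample(others, nins, replace = TRUE)))
        }
      }
    }
    out <- if (length(recs)) do.call(rbind, recs) else
      data.frame(chrom = character(), pos = integer(),
                 ref = character(), alt = character())
    rownames(out) <- NULL
    out
  })
}

#' Kernel-generated pseudo-empirical repeat length distribution
#'
#' Evolves the joint distribution under known instability parameters to
#' late time, scales the final repeat counts to a target genome-wide
#' repeat total, and optionally adds per-bin Poisson sampling noise.
#' Serves as a stand-in for a genome-derived empirical distribution in
#' closed-loop inference tests (synthetic; not derived from any real
#' assembly).
#'
#' @param params truth [InstabilityParams-class].
#' @param denovo de novo per-target rates for L = 1..8 (list with
#'   expansion/contraction/insertion), as for [buildRateCurves()].
#' @param contextRates named substitution/B rates (see [rateModel()]).
#' @param schedule kernel schedule (default [kernelSchedule()]).
#' @param genomeRepeatTotal total repeat count to scale to.
#' @param LBoundary boundary length (default 100).
#' @param pA initial-state focal-unit fraction (default from the
#'   lengthen/shorten rates).
#' @param noise add Poisson noise per bin (default TRUE).
#' @param seed RNG seed (for the noise).
#' @return A [LengthDistribution-class] of raw counts over
#'   1..\code{LBoundary}.
#' @export
generatePseudoEmpirical <- function(params, denovo, contextRates,
                                    schedule = kernelSchedule(),
                                    genomeRepeatTotal = 1e6,
                                    LBoundary = 100L, pA = NULL,
                                    noise = TRUE, seed = NULL) {
  rates <- buildRateCurves(denovo, params, contextRates, LBoundary)
  if (is.null(pA)) {
    mu <- rates@contextRates[["lengthen"]]
    nu <- rates@contextRates[["shorten"]]
    pA <- if (mu + nu > 0) mu / (mu + nu) else 0.3
  }
  st <- geometricJointState(pA, genomeRepeatTotal / (pA * (1 - pA)),
                            LBoundary)
  ev <- evolveState(st, rates, schedule, snapshotEvery = 0)
  counts <- countsA(ev$state)
  counts <- counts * genomeRepeatTotal / sum(counts)
  if (noise) counts <- .with_seed(seed, rpois(length(counts), counts))
  lengthDistribution(counts)
}

#' Generate a popSTR-style locus and event table under known rates
#'
#' Loci carry a reference repeat length and a number of trios passing
#' quality filters; single-unit insertion/deletion events are drawn per
#' allele transmission (two per passing trio) at per-repeat truth rates
#' indexed by the locus reference length.
#'
#' @param insertionRates,deletionRates per-repeat truth rates indexed by
#'   repeat length.
#' @param refLengths reference repeat length of each locus (one entry per
#'   locus).
#' @param nTrios passing trios per locus (scalar or vector).
#' @param seed RNG seed.
#' @return list with \code{loci} (locus, refLength, passingTrios) and
#'   \code{events} (locus, probandLength, parentalLengths, phase, units).
#' @export
generatePopstrTable <- function(insertionRates, deletionRates, refLengths,
                                nTrios = 100, seed = NULL) {
  .with_seed(seed, {
    nl <- length(refLengths)
    trios <- rep_len(nTrios, nl)
    loci <- data.frame(locus = seq_len(nl), refLength = refLengths,
                       passingTrios = trios)
    evs <- list()
    rate <- function(v, L) if (L <= length(v) && is.finite(v[L])) v[L] else 0
    for (i in seq_len(nl)) {
      L <- refLengths[i]
      transmissions <- 2 * trios[i]
      nIns <- rpois(1L, rate(insertionRates, L) * transmissions)
      nDel <- rpois(1L, rate(deletionRates, L) * transmissions)
      if (nIns + nDel == 0) next
      units <- c(rep(1L, nIns), rep(-1L, nDel))
      evs[[length(evs) + 1L]] <- data.frame(
        locus = i, probandLength = L + units,
        parentalLengths = paste(rep(L, 4L), collapse = ","),
        phase = NA, units = units)
    }
    events <- if (length(evs)) do.call(rbind, evs) else
      data.frame(locus = integer(), probandLength = numeric(),
                 parentalLengths = character(), phase = logical(),
                 units = integer())
    list(loci = loci, events = events)
  })
}

#' Plausible default de novo instability rates
#'
#' A reference per-target rate set for the focal mononucleotide motif
#' used by examples, tests and the demonstration pipeline: substitution
#' context rates as reported from pooled trio data, and per-target
#' expansion/contraction/insertion rates for L = 1..8 that rise steeply
#' through L = 5..8, cross the substitution scale near L = 7, keep a
#' mild initial expansion bias (expansion/contraction about 1.23 at
#' L = 8, placing the expansion-contraction balance near L = 18 when
#' the exponent difference is 0.3), and keep non-motif insertion roughly
#' five-fold below expansion.
#'
#' @return list with \code{contextRates} (named vector for [rateModel()])
#'   and \code{denovo} (per-target curves for L = 1..8).
#' @export
defaultRateSet <- function() {
  list(
    contextRates = c(lengthen = 4.77e-9, shorten = 8.08e-9,
                     fusion = 2.87e-9, fission = 4.54e-9,
                     createA1 = 3.97e-9, destroyA1 = 6.45e-9,
                     bInsert = 1.44e-10, bDelete = 4.56e-12,
                     b1DeleteFusion = 2.89e-10),
    denovo = list(
      expansion   = c(1.5e-10, 2.5e-10, 6e-10, 1.6e-9, 5e-9,
                      1.5e-8, 4e-8, 8e-8),
      contraction = c(1.0e-10, 1.8e-10, 4.5e-10, 1.2e-9, 4e-9,
                      1.2e-8, 3.2e-8, 6.5e-8),
      insertion   = c(3e-11, 5e-11, 1.2e-10, 3e-10, 1e-9,
                      3e-9, 8e-9, 1.6e-8)))
}
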