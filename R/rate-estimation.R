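# Per-generation mutation rate estimation from de novo trio tables and
# popSTR-style locus tables.  Rate estimation works on the mononucleotide
# A/B abstraction: for a focal member base b, every other base is "B".

.contig_chars <- function(genome) {
  contigs <- .as_contigs(genome)
  if (is.null(names(contigs)))
    names(contigs) <- paste0("contig", seq_along(contigs))
  lapply(contigs, function(s) strsplit(s, "")[[1]])
}

#' Mask windows with no observed substitutions
#'
#' VCF-style call sets carry no depth information for unmutated positions,
#' so fixed-size windows containing no substitution across the combined
#' dataset are taken to reflect mappability problems and are excluded from
#' all rate denominators.
#'
#' @param records mutation table (data.frame with \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}); only single-nucleotide records count as
#'   substitutions.
#' @param genome character vector of contigs (or \code{DNAStringSet}).
#' @param window window size in bp (default 1e5).
#' @return data.frame of masked windows (\code{chrom}, \code{start},
#'   \code{end}), with the window size as attribute \code{"window"}.
#' @export
maskLowCoverage <- function(records, genome, window = 1e5) {
  contigs <- .as_contigs(genome)
  if (is.null(names(contigs)))
    names(contigs) <- paste0("contig", seq_along(contigs))
  isSub <- nchar(records$ref) == 1L & nchar(records$alt) == 1L
  recs <- records[isSub, , drop = FALSE]
  out <- list()
  for (cn in names(contigs)) {
    len <- nchar(contigs[[cn]])
    nw <- ceiling(len / window)
    if (nw < 1L) next
    hit <- rep(FALSE, nw)
    p <- recs$pos[recs$chrom == cn]
    if (length(p)) hit[unique(pmin((p - 1L) %/% window + 1L, nw))] <- TRUE
    empty <- which(!hit)
    if (length(empty))
      out[[cn]] <- data.frame(chrom = cn,
                              start = (empty - 1L) * window + 1L,
                              end = pmin(empty * window, len))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric())
  rownames(res) <- NULL
  attr(res, "window") <- window
  res
}

#' Replace masked windows by N
#'
#' Returns the genome with every masked window overwritten with \code{N},
#' so that downstream context-site and repeat counting automatically
#' exclude masked regions from denominators.
#'
#' @param genome character vector of contigs.
#' @param mask data.frame from [maskLowCoverage()] (NULL = no masking).
#' @return Character vector of contigs.
#' @export
applyMask <- function(genome, mask = NULL) {
  contigs <- .as_contigs(genome)
  if (is.null(names(contigs)))
    names(contigs) <- paste0("contig", seq_along(contigs))
  if (is.null(mask) || !nrow(mask)) return(contigs)
  for (i in seq_len(nrow(mask))) {
    cn <- mask$chrom[i]
    s <- mask$start[i]; e <- mask$end[i]
    substr(contigs[[cn]], s, e) <- strrep("N", e - s + 1L)
  }
  contigs
}

# Classify one substitution against member base b given its two reference
# neighbours.  Categories depend only on whether b is gained or lost at
# the middle position and on the number of b neighbours.
.classify_sub_one <- function(ref, alt, left, right, b) {
  gain <- alt == b && ref != b
  loss <- ref == b && alt != b
  if (!gain && !loss) return("other")
  nA <- (left == b) + (right == b)
  if (gain) c("createA1", "lengthen", "fusion")[nA + 1L]
  else c("destroyA1", "shorten", "fission")[nA + 1L]
}

#' Classify substitutions by trinucleotide context
#'
#' Each single-nucleotide substitution is classified against the focal
#' member base by the reference three-unit context around the mutated
#' site: \code{lengthen} (ABB>AAB / BBA>BAA), \code{shorten} (AAB>ABB /
#' BAA>BBA), \code{fusion} (ABA>AAA), \code{fission} (AAA>ABA),
#' \code{createA1} (BBB>BAB), \code{destroyA1} (BAB>BBB), or
#' \code{other} (no change in member-base content, indels, or a context
#' running off the contig end).
#'
#' @param records mutation table (\code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}).
#' @param genome character vector of contigs.
#' @param member focal member base (e.g. \code{"A"} or \code{"T"}).
#' @return Character vector of categories, one per record.
#' @export
classifySubstitutions <- function(records, genome, member = "A") {
  chars <- .contig_chars(genome)
  n <- nrow(records)
  out <- rep("other", n)
  for (i in seq_len(n)) {
    if (nchar(records$ref[i]) != 1L || nchar(records$alt[i]) != 1L) next
    cc <- chars[[records$chrom[i]]]
    p <- records$pos[i]
    if (is.null(cc) || p < 2L || p > length(cc) - 1L) next
    if (cc[p - 1L] == "N" || cc[p + 1L] == "N") next
    out[i] <- .classify_sub_one(toupper(records$ref[i]),
                                toupper(records$alt[i]),
                                cc[p - 1L], cc[p + 1L], member)
  }
  out
}

# Count trinucleotide context sites per category for member base b.
# Positions with N in the window are skipped.  Returns named vector with
# the six categories.
.context_site_counts <- function(chars, b) {
  n <- length(chars)
  counts <- setNames(numeric(6), c("lengthen", "shorten", "fusion",
                                   "fission", "createA1", "destroyA1"))
  if (n < 3L) return(counts)
  mid <- chars[2:(n - 1L)]
  left <- chars[1:(n - 2L)]
  right <- chars[3:n]
  ok <- mid != "N" & left != "N" & right != "N"
  isb_m <- mid == b
  nA <- (left == b) + (right == b)
  # middle is B: a b gain here lengthens (1 nb), fuses (2 nb), creates (0)
  counts["lengthen"] <- sum(ok & !isb_m & nA == 1L)
  counts["fusion"] <- sum(ok & !isb_m & nA == 2L)
  counts["createA1"] <- sum(ok & !isb_m & nA == 0L)
  # middle is b: a b loss shortens (1 nb), splits (2 nb), destroys (0)
  counts["shorten"] <- sum(ok & isb_m & nA == 1L)
  counts["fission"] <- sum(ok & isb_m & nA == 2L)
  counts["destroyA1"] <- sum(ok & isb_m & nA == 0L)
  counts
}

#' Estimate context-classified substitution rates
#'
#' Per-category, per-target, per-generation rates: category event count
#' divided by the diploid number of matching trinucleotide context sites
#' in the unmasked genome and by the number of offspring genomes.  Events
#' and sites are pooled over the motif-class member bases (e.g. A and T),
#' so rates never stratify by repeat length.
#'
#' @param records mutation table.
#' @param genome character vector of contigs.
#' @param nOffspring number of offspring genomes in the dataset.
#' @param mask optional data.frame from [maskLowCoverage()].
#' @param motif a [MotifClass-class] (mononucleotide; default class of A).
#' @return data.frame with category, events, sites (haploid context-site
#'   count), and rate; plus the genome-average substitution rate as
#'   attribute \code{"averageRate"}.
#' @export
estimateContextRates <- function(records, genome, nOffspring, mask = NULL,
                                 motif = motifClass("A")) {
  if (unitLength(motif) != 1L)
    stop("context rate estimation is defined for mononucleotide motifs")
  masked <- applyMask(genome, mask)
  chars <- .contig_chars(masked)
  cats <- c("lengthen", "shorten", "fusion", "fission",
            "createA1", "destroyA1")
  events <- setNames(numeric(6), cats)
  sites <- setNames(numeric(6), cats)
  for (b in motifMembers(motif)) {
    cl <- classifySubstitutions(records, masked, member = b)
    tb <- table(factor(cl, levels = cats))
    events <- events + as.numeric(tb)
    for (cc in chars) sites <- sites + .context_site_counts(cc, b)
  }
  rate <- ifelse(sites > 0, events / (2 * sites * nOffspring), NA_real_)
  out <- data.frame(category = cats, events = as.numeric(events),
                    sites = as.numeric(sites), rate = rate)
  nSub <- sum(nchar(records$ref) == 1L & nchar(records$alt) == 1L)
  seqable <- sum(vapply(chars, function(cc) sum(cc != "N"), 0))
  attr(out, "averageRate") <- nSub / (2 * seqable) / nOffspring
  out
}

#' @describeIn estimateContextRates Convert the estimate to the named
#'   vector consumed by [rateModel()] (B-string rates must be supplied
#'   separately or default to zero).
#' @param x data.frame returned by \code{estimateContextRates}.
#' @param bRates optional named numeric with \code{bInsert},
#'   \code{bDelete}, \code{b1DeleteFusion}.
#' @export
asContextRateVector <- function(x, bRates = NULL) {
  v <- setNames(x$rate, x$category)
  v[is.na(v)] <- 0
  if (!is.null(bRates)) v <- c(v, bRates)
  v
}

# Maximal run of base b containing or touching position p (insertion
# anchor semantics: touching means the run starts at p + 1 or ends at p).
.run_at <- function(cc, p, b) {
  n <- length(cc)
  s <- p + 1L; e <- p
  while (s > 1L && cc[s - 1L] == b) s <- s - 1L
  while (e < n && cc[e + 1L] == b) e <- e + 1L
  if (e < s) c(0L, 0L, 0L) else as.integer(c(s, e, e - s + 1L))
}

#' Classify indels against a mononucleotide repeat
#'
#' Records are first normalized to their left-aligned representation,
#' then attributed to the maximal reference run of the member base
#' touching the event.  Insertions consisting solely of the member base
#' touching a run (or a single member base anywhere) are expansions;
#' deletions of member bases inside a run are contractions; insertions of
#' non-member bases strictly inside a run are non-motif insertions;
#' deletions overlapping both member and non-member bases are partial
#' deletions.  Pure non-member indels are classified as B-string events
#' (\code{b_insertion} / \code{b_deletion}, with the length of the
#' affected B string recorded in \code{bLength}).
#'
#' @param records mutation table; indels follow VCF convention (shared
#'   anchor base, 1-based positions).
#' @param genome character vector of contigs.
#' @param member focal member base.
#' @return data.frame with type, units (signed unit change),
#'   parentalLength (reference run length), and bLength.
#' @export
classifyIndels <- function(records, genome, member = "A") {
  chars <- .contig_chars(genome)
  n <- nrow(records)
  type <- rep("other", n)
  units <- integer(n)
  parental <- integer(n)
  bLength <- integer(n)
  for (i in seq_len(n)) {
    ref <- toupper(records$ref[i]); alt <- toupper(records$alt[i])
    if (nchar(ref) == nchar(alt)) next
    cc <- chars[[records$chrom[i]]]
    if (is.null(cc)) next
    p <- records$pos[i]
    if (substr(ref, 1L, 1L) != substr(alt, 1L, 1L)) next  # not anchored
    ins <- nchar(alt) > nchar(ref)
    seqs <- if (ins) substring(alt, 2L) else substring(ref, 2L)
    k <- nchar(seqs)
    # left-align: shift the event left while the base before the anchor
    # equals the last base of the inserted/deleted sequence
    while (p > 1L && cc[p] == substring(seqs, k, k)) {
      seqs <- paste0(substring(seqs, k, k), substring(seqs, 1L, k - 1L))
      p <- p - 1L
    }
    sb <- strsplit(seqs, "")[[1]]
    allA <- all(sb == member)
    noneA <- all(sb != member)
    run <- .run_at(cc, p, member)
    if (ins) {
      if (allA) {
        type[i] <- "expansion"; units[i] <- k
        parental[i] <- run[3L]
      } else if (noneA && run[3L] > 0L && p >= run[1L] && p < run[2L]) {
        # strictly inside a run: splits it
        type[i] <- "non_motif_insertion"
        parental[i] <- run[3L]
      } else if (noneA) {
        type[i] <- "b_insertion"
        s <- p; while (s > 1L && cc[s] != member && cc[s] != "N") s <- s - 1L
        e <- p + 1L
        while (e < length(cc) && cc[e] != member && cc[e] != "N") e <- e + 1L
        bLength[i] <- max(0L, e - s - 1L)
      }
    } else {
      del_s <- p + 1L; del_e <- p + k
      if (del_e > length(cc)) next
      delb <- cc[del_s:del_e]
      if (all(delb == member)) {
        type[i] <- "contraction"; units[i] <- -k
        parental[i] <- run[3L]
      } else if (all(delb != member)) {
        s <- del_s; while (s > 1L && cc[s - 1L] != member && cc[s - 1L] != "N")
          s <- s - 1L
        e <- del_e; while (e < length(cc) && cc[e + 1L] != member &&
                           cc[e + 1L] != "N") e <- e + 1L
        bLength[i] <- e - s + 1L
        type[i] <- if (bLength[i] == 1L) "b1_deletion_fusion" else "b_deletion"
        units[i] <- -k
      } else {
        type[i] <- "partial_deletion"
        parental[i] <- run[3L]
      }
    }
  }
  data.frame(type = type, units = units, parentalLength = parental,
             bLength = bLength)
}

#' Poisson confidence intervals for binned rate estimates
#'
#' For each bin, \code{nSamples} Poisson draws around the observed event
#' count are converted to rates; the top and bottom \code{drop} values are
#' removed and the range of the rest is the 95\% interval.
#'
#' @param counts observed event counts per bin.
#' @param denominators per-bin rate denominators.
#' @param nSamples number of Poisson resamples (default 200).
#' @param drop values removed from each tail (default 5).
#' @param seed RNG seed.
#' @return data.frame with \code{ciLow}, \code{ciHigh} per bin.
#' @export
poissonCI <- function(counts, denominators, nSamples = 200, drop = 5,
                      seed = NULL) {
  .with_seed(seed, {
    lo <- hi <- rep(NA_real_, length(counts))
    for (i in seq_along(counts)) {
      if (!is.finite(denominators[i]) || denominators[i] <= 0) next
      v <- sort(rpois(nSamples, counts[i]) / denominators[i])
      keep <- v[seq.int(drop + 1L, nSamples - drop)]
      lo[i] <- keep[1L]; hi[i] <- keep[length(keep)]
    }
    data.frame(ciLow = lo, ciHigh = hi)
  })
}

#' Estimate length-stratified indel rates from de novo calls
#'
#' Per-repeat-length, per-type rates: event counts at parental length L
#' divided by the diploid number of repeats of length L in the unmasked
#' genome and the number of offspring.  The tabulated rate is per repeat;
#' dividing by the per-repeat target size L gives the per-target rate the
#' mutation kernel consumes (see [perTargetCurves()]).  Only single-unit
#' events enter the kernel's rate curves; the full unit-change spectrum is
#' recorded.  B-string indel rates are estimated as per-unit averages.
#'
#' @inheritParams estimateContextRates
#' @param maxLength largest repeat length tabulated (default 30).
#' @param seed RNG seed for the Poisson confidence intervals.
#' @return list with \code{table} (type, length, events, targets, rate,
#'   ciLow, ciHigh; rate is NA where the genome has no repeat of that
#'   length), \code{spectrum} (signed unit change counts), and
#'   \code{bRates} (named per-unit rates for B-string events).
#' @export
estimateIndelRates <- function(records, genome, nOffspring, mask = NULL,
                               motif = motifClass("A"), maxLength = 30,
                               seed = NULL) {
  if (unitLength(motif) != 1L)
    stop("indel rate estimation is defined for mononucleotide motifs")
  masked <- applyMask(genome, mask)
  cat_counts <- countRepeats(masked, motif)
  nrep <- rawCounts(cat_counts$A)
  nrep <- c(nrep, numeric(max(0, maxLength - length(nrep))))[1:maxLength]
  bdist <- rawCounts(cat_counts$B)
  bUnits <- sum(seq_along(bdist) * bdist)
  types <- c("expansion", "contraction", "non_motif_insertion")
  ev <- matrix(0, nrow = maxLength, ncol = 3L,
               dimnames = list(NULL, types))
  spectrum <- integer(0)
  bev <- c(b_insertion = 0, b_deletion = 0, b1_deletion_fusion = 0)
  for (b in motifMembers(motif)) {
    cl <- classifyIndels(records, masked, member = b)
    sel <- cl$type %in% types & cl$parentalLength >= 1L &
      cl$parentalLength <= maxLength
    # the kernel models single-unit changes; multi-unit events are
    # tabulated in the spectrum but excluded from the rate curves
    single <- sel & abs(cl$units) <= 1L
    for (tt in types) {
      idx <- single & cl$type == tt
      if (any(idx))
        ev[, tt] <- ev[, tt] +
          tabulate(cl$parentalLength[idx], nbins = maxLength)
    }
    spectrum <- c(spectrum, cl$units[sel & cl$type != "non_motif_insertion"])
    for (tt in names(bev)) bev[tt] <- bev[tt] + sum(cl$type == tt)
  }
  denom <- 2 * nrep * nOffspring
  tabs <- lapply(types, function(tt) {
    rate <- ifelse(nrep > 0, ev[, tt] / denom, NA_real_)
    ci <- poissonCI(ev[, tt], denom, seed = seed)
    data.frame(type = tt, length = seq_len(maxLength),
               events = ev[, tt], targets = denom, rate = rate,
               ciLow = ci$ciLow, ciHigh = ci$ciHigh)
  })
  spec <- as.data.frame(table(spectrum), stringsAsFactors = FALSE)
  names(spec) <- c("units", "count")
  if (nrow(spec)) spec$units <- as.integer(spec$units)
  list(table = do.call(rbind, tabs), spectrum = spec,
       bRates = c(bInsert = unname(bev["b_insertion"]) /
                    (2 * bUnits * nOffspring),
                  bDelete = unname(bev["b_deletion"]) /
                    (2 * bUnits * nOffspring),
                  b1DeleteFusion = unname(bev["b1_deletion_fusion"]) /
                    (2 * bUnits * nOffspring)))
}

#' Per-target rate curves from a per-repeat rate table
#'
#' Converts the tabulated per-repeat rates to the per-target convention
#' of the kernel: expansion, contraction and non-motif insertion have
#' per-repeat target size L, so per-target rate = tabulated rate / L.
#'
#' @param table data.frame as produced by [estimateIndelRates()] (or
#'   [popstrRates()]).
#' @param lengths lengths to extract (default 1..8, the reliable de novo
#'   range).
#' @return list with numeric \code{expansion}, \code{contraction},
#'   \code{insertion} vectors over \code{lengths} (NA where undefined).
#' @export
perTargetCurves <- function(table, lengths = 1:8) {
  get <- function(tt) {
    sub <- table[table$type == tt & table$length %in% lengths, ]
    v <- rep(NA_real_, length(lengths))
    v[match(sub$length, lengths)] <- sub$rate / sub$length
    v
  }
  list(expansion = get("expansion"), contraction = get("contraction"),
       insertion = get("non_motif_insertion"))
}

#' Longest contiguous repeat within locus coordinates
#'
#' @param genome character vector of contigs.
#' @param chrom,start,end 1-based inclusive locus coordinates.
#' @param motif a [MotifClass-class].
#' @return Longest pure run length in repeat units (0 when no complete
#'   motif copy lies in the interval).
#' @export
popstrLongestRun <- function(genome, chrom, start, end,
                             motif = motifClass("A")) {
  contigs <- .as_contigs(genome)
  if (is.null(names(contigs)))
    names(contigs) <- paste0("contig", seq_along(contigs))
  seqs <- substring(contigs[[chrom]], start, end)
  d <- countRepeats(seqs, motif)$A
  if (!length(distCounts(d))) 0L else max(which(distCounts(d) > 0))
}

#' Assign the parental origin length of an unphased repeat mutation
#'
#' Phased events keep their phase-designated parental length; unphased
#' events are attributed to the parental allele minimizing the absolute
#' length difference to the proband allele, with ties broken towards the
#' smaller parental length.
#'
#' @param probandLength proband repeat length.
#' @param parentalLengths numeric vector of the four parental allele
#'   lengths.
#' @param phase \code{NA}/\code{"unknown"} for unphased; otherwise an
#'   index (1..4) or a value naming the phased parental length.
#' @return The parental origin length.
#' @export
popstrAssignParent <- function(probandLength, parentalLengths,
                               phase = NA) {
  if (!is.na(phase) && !identical(phase, "unknown")) {
    if (is.numeric(phase) && phase >= 1 && phase <= length(parentalLengths))
      return(parentalLengths[phase])
    return(as.numeric(phase))
  }
  d <- abs(parentalLengths - probandLength)
  cand <- parentalLengths[d == min(d)]
  min(cand)
}

#' Length-stratified insertion/deletion rates from a popSTR-style table
#'
#' Events are binned by parental origin length (insertions conflate
#' expansions and non-motif insertions, as the caller cannot distinguish
#' them); the denominator at length L is the sum over loci of reference
#' length L of twice the number of passing trios (two transmitted parental
#' alleles per trio).
#'
#' @param events data.frame with \code{locus}, \code{probandLength},
#'   \code{parentalLengths} (list column or comma-separated string),
#'   \code{phase}, and signed \code{units}.
#' @param loci data.frame with \code{locus}, \code{refLength},
#'   \code{passingTrios} (already filtered to loci whose reported
#'   reference length agrees with an independent measurement).
#' @param maxLength largest length tabulated (default 30).
#' @param seed RNG seed for the Poisson confidence intervals.
#' @return data.frame with type (insertion/deletion), length, events,
#'   targets, rate, ciLow, ciHigh.
#' @export
popstrRates <- function(events, loci, maxLength = 30, seed = NULL) {
  denom <- numeric(maxLength)
  sel <- loci$refLength >= 1 & loci$refLength <= maxLength
  agg <- tapply(2 * loci$passingTrios[sel], loci$refLength[sel], sum)
  denom[as.integer(names(agg))] <- agg
  insEv <- numeric(maxLength); delEv <- numeric(maxLength)
  for (i in seq_len(nrow(events))) {
    pl <- events$parentalLengths[[i]]
    if (is.character(pl)) pl <- as.numeric(strsplit(pl, ",")[[1]])
    origin <- popstrAssignParent(events$probandLength[i], pl,
                                 events$phase[i])
    if (origin < 1 || origin > maxLength) next
    if (events$units[i] > 0) insEv[origin] <- insEv[origin] + 1
    else if (events$units[i] < 0) delEv[origin] <- delEv[origin] + 1
  }
  mk <- function(tt, evv) {
    rate <- ifelse(denom > 0, evv / denom, NA_real_)
    ci <- poissonCI(evv, denom, seed = seed)
    data.frame(type = tt, length = seq_len(maxLength), events = evv,
               targets = denom, rate = rate, ciLow = ci$ciLow,
               ciHigh = ci$ciHigh)
  }
  rbind(mk("insertion", insEv), mk("deletion", delEv))
}

#' Power-law fit of a length-stratified rate curve
#'
#' Linear regression in log-log space of the per-target rate over the fit
#' range (default lengths 12..19, the portion of popSTR estimates
#' resembling a power law).  The 99.9\% confidence interval of the slope
#' is propagated to a range of intercepts at L = 9, each expressed as a
#' multiplier over a reference L = 8 per-target rate.
#'
#' @param table rate table (as from [popstrRates()] or
#'   [estimateIndelRates()]); rates are per repeat and are divided by L
#'   for the fit.
#' @param type which rate type to fit.
#' @param fitLengths lengths used (default 12:19).
#' @param refRate8 reference per-target rate at L = 8 (the de novo
#'   estimate) used to express the intercept as the multiplier m.
#' @return list with \code{slope} (the power-law exponent tau),
#'   \code{slopeCI} (99.9\%), \code{rate9} (fitted per-target rate at
#'   L = 9), \code{m}, \code{mRange}, and \code{fitLengths}.
#' @export
fitPowerLaw <- function(table, type = "insertion", fitLengths = 12:19,
                        refRate8 = NULL) {
  sub <- table[table$type == type & table$length %in% fitLengths, ]
  perTarget <- sub$rate / sub$length
  ok <- is.finite(perTarget) & perTarget > 0
  if (sum(ok) < 3L)
    stop("need at least 3 finite positive rates in the fit range")
  x <- log(sub$length[ok]); y <- log(perTarget[ok])
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2L])
  ci <- suppressWarnings(confint(fit, "x", level = 0.999))
  # intercepts at L = 9 for the slope range, pivoting on the fit centroid
  xb <- mean(x); yb <- mean(y)
  at9 <- function(s) exp(yb + s * (log(9) - xb))
  rate9 <- at9(slope)
  out <- list(slope = slope, slopeCI = c(ci[1L], ci[2L]), rate9 = rate9,
              fitLengths = fitLengths[ok])
  if (!is.null(refRate8)) {
    out$m <- rate9 / refRate8
    out$mRange <- sort(c(at9(ci[1L]), at9(ci[2L]))) / refRate8
  }
  out
}
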