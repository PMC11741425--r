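test_that("substitutions classify by trinucleotide context", {
  g <- c(chr1 = "CAACGGACATAAACC")
  #       123456789012345
  recs <- data.frame(
    chrom = "chr1",
    pos = c(4, 12, 9, 13, 6, 2),
    ref = c("C", "A", "A", "A", "G", "A"),
    alt = c("A", "C", "T", "C", "A", "G"))
  cl <- classifySubstitutions(recs, g, member = "A")
  # pos 4: A-A-C with middle C -> A, one A neighbour: lengthen
  expect_identical(cl[1], "lengthen")
  # pos 12: A-A-A middle lost: fission
  expect_identical(cl[2], "fission")
  # pos 9: C-A-T, A lost with no A neighbours: destroyA1
  expect_identical(cl[3], "destroyA1")
  # pos 13: A-A-C, A lost with one A neighbour: shorten
  expect_identical(cl[4], "shorten")
  # pos 6: G-G-A gains A with ... G-A-C? pos6 = G, neighbours G and A:
  # one A neighbour: lengthen
  expect_identical(cl[5], "lengthen")
  # pos 2: A gained nothing (A -> G is a loss); neighbours C, A: shorten
  expect_identical(cl[6], "shorten")
  # context off the contig end is unclassifiable
  edge <- data.frame(chrom = "chr1", pos = 1, ref = "C", alt = "A")
  expect_identical(classifySubstitutions(edge, g), "other")
})

test_that("fusion context requires both neighbours to be the member base", {
  g <- c(chr1 = "GACAG")
  rec <- data.frame(chrom = "chr1", pos = 3, ref = "C", alt = "A")
  expect_identical(classifySubstitutions(rec, g, "A"), "fusion")
  rec2 <- data.frame(chrom = "chr1", pos = 3, ref = "C", alt = "T")
  expect_identical(classifySubstitutions(rec2, g, "A"), "other")
})

test_that("windows without substitutions are masked", {
  g <- c(chr1 = strrep("ACGT", 500))  # 2000 bp, two 1 kb windows
  recs <- data.frame(chrom = "chr1", pos = 123, ref = "A", alt = "G")
  m <- maskLowCoverage(recs, g, window = 1000)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 1001)
  expect_equal(m$end, 2000)
  # substitutions everywhere: empty mask
  recs2 <- data.frame(chrom = "chr1", pos = c(10, 1500),
                      ref = "A", alt = "G")
  expect_equal(nrow(maskLowCoverage(recs2, g, window = 1000)), 0)
  # masked windows are excluded from downstream counting
  masked <- applyMask(g, m)
  expect_equal(nchar(gsub("[^N]", "", masked[[1]])), 1000)
})

test_that("masked-fraction matches the Poisson zero class on uniform data", {
  set.seed(12)
  g <- generateIIDGenome(4e5, pA = 0.25, seed = 3)
  rate <- 2e-5   # per-site; expected hits per 1e4 window = 0.2... choose
  win <- 1e4
  pos <- which(runif(4e5) < rate)
  recs <- data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "G")
  m <- maskLowCoverage(recs, g, window = win)
  fracMasked <- nrow(m) / (4e5 / win)
  expect_lt(abs(fracMasked - exp(-rate * win)), 0.15)
})

test_that("indels classify as expansion, contraction or splitting insertion", {
  g <- c(chr1 = paste0("GC", strrep("A", 8), "GCCA"))
  # expansion: +A at the run (left-aligned anchor at pos 2)
  recs <- data.frame(chrom = "chr1",
                     pos = c(2, 2, 5, 11),
                     ref = c("C", "CAA", "A", "G"),
                     alt = c("CA", "C", "AG", "GC"))
  cl <- classifyIndels(recs, g, member = "A")
  expect_identical(cl$type[1], "expansion")
  expect_identical(cl$units[1], 1L)
  expect_identical(cl$parentalLength[1], 8L)
  expect_identical(cl$type[2], "contraction")
  expect_identical(cl$units[2], -2L)
  expect_identical(cl$parentalLength[2], 8L)
  # G inserted strictly inside the A run: splits it
  expect_identical(cl$type[3], "non_motif_insertion")
  expect_identical(cl$parentalLength[3], 8L)
  # C inserted after G: a B-string insertion
  expect_identical(cl$type[4], "b_insertion")
})

test_that("right-shifted indel records are left-aligned before classification", {
  g <- c(chr1 = paste0("GC", strrep("A", 8), "GCCA"))
  # the same +A expansion written at the right edge of the run
  rec <- data.frame(chrom = "chr1", pos = 9, ref = "A", alt = "AA")
  cl <- classifyIndels(rec, g, member = "A")
  expect_identical(cl$type, "expansion")
  expect_identical(cl$parentalLength, 8L)
})

test_that("estimated indel rates recover the generating truth", {
  truth <- list(expansion   = c(0, 0, 1e-6, 3e-6, 1e-5, 3e-5, 1e-4, 3e-4),
                contraction = c(0, 1e-6, 1e-6, 2e-6, 8e-6, 2e-5, 8e-5, 2e-4),
                insertion   = c(0, 5e-7, 5e-7, 1e-6, 3e-6, 8e-6, 2e-5, 6e-5))
  g <- generateIIDGenome(6e5, pA = 0.35, seed = 21)
  recs <- generateTrioTable(g, indelRates = truth, nOffspring = 300,
                            seed = 22)
  est <- estimateIndelRates(recs, g, nOffspring = 300, maxLength = 10,
                            seed = 23)
  tab <- est$table[est$table$length %in% 3:8, ]
  key <- c(expansion = "expansion", contraction = "contraction",
           non_motif_insertion = "insertion")
  tab$truth <- mapply(function(tt, L) truth[[key[tt]]][L],
                      tab$type, tab$length)
  covered <- tab$truth >= tab$ciLow & tab$truth <= tab$ciHigh
  expect_gte(mean(covered[tab$truth > 0]), 0.8)
  # lengths with no repeats in the genome give NA, not zero
  expect_true(all(is.na(est$table$rate[est$table$targets == 0])))
  # the generator emits only single-unit events
  expect_true(all(abs(est$spectrum$units) == 1))
})

test_that("rates never stratify substitution categories by repeat length", {
  # the context estimator returns one rate per category, with no length
  # dimension anywhere in its output
  g <- generateIIDGenome(1e5, pA = 0.3, seed = 31)
  recs <- generateTrioTable(g, c(lengthen = 1e-6), nOffspring = 50,
                            seed = 32)
  est <- estimateContextRates(recs, g, nOffspring = 50)
  expect_identical(names(est), c("category", "events", "sites", "rate"))
  expect_equal(nrow(est), 6)
  # zero records: all-zero rates; doubling offspring halves rates
  none <- estimateContextRates(recs[0, ], g, nOffspring = 50)
  expect_true(all(none$rate == 0))
  twice <- estimateContextRates(recs, g, nOffspring = 100)
  expect_equal(twice$rate, est$rate / 2)
})

test_that("per-target conversion divides per-repeat rates by L", {
  tab <- data.frame(type = rep(c("expansion", "contraction",
                                 "non_motif_insertion"), each = 8),
                    length = rep(1:8, 3), rate = rep(8e-6, 24))
  cur <- perTargetCurves(tab)
  expect_equal(cur$expansion, 8e-6 / (1:8))
  expect_equal(cur$insertion[8], 1e-6)
})

test_that("the longest contiguous run within locus coordinates is measured", {
  g <- c(chr1 = paste0("CC", strrep("A", 7), "G", strrep("A", 12), "CC"))
  expect_equal(popstrLongestRun(g, "chr1", 1, nchar(g[[1]]),
                                motifClass("A")), 12)
  expect_equal(popstrLongestRun(g, "chr1", 3, 9, motifClass("A")), 7)
  expect_equal(popstrLongestRun(g, "chr1", 1, 2, motifClass("A")), 0)
  # an interval covering exactly one pure run returns its length
  expect_equal(popstrLongestRun(g, "chr1", 10 + 1, 10 + 12,
                                motifClass("A")), 12)
})

test_that("parental origin is the closest parental allele with ties to the smaller", {
  expect_equal(popstrAssignParent(11, c(10, 14, 9, 15)), 10)
  expect_equal(popstrAssignParent(11, c(10, 12, 9, 15)), 10)  # tie 10 vs 12
  # a phased record keeps its assignment regardless of distance
  expect_equal(popstrAssignParent(11, c(10, 14, 9, 15), phase = 4), 15)
})

test_that("popSTR rates divide events by allele transmissions at the reference length", {
  loci <- data.frame(locus = 1, refLength = 12, passingTrios = 100)
  events <- data.frame(locus = 1, probandLength = 13,
                       parentalLengths = "12,12,12,12",
                       phase = NA, units = 1L)
  events <- rbind(events, events)
  tab <- popstrRates(events, loci, maxLength = 20, seed = 1)
  ins <- tab[tab$type == "insertion" & tab$length == 12, ]
  expect_equal(ins$targets, 200)
  expect_equal(ins$rate, 2 / 200)
  # no passing trios at a length: missing rate
  expect_true(is.na(tab$rate[tab$type == "deletion" & tab$length == 15]))
  # recovery at known truth
  tp <- generatePopstrTable(insertionRates = c(rep(0, 9), rep(2e-3, 21)),
                            deletionRates = c(rep(0, 9), rep(1e-3, 21)),
                            refLengths = rep(10:25, each = 30),
                            nTrios = 200, seed = 7)
  est <- popstrRates(tp$events, tp$loci, maxLength = 30, seed = 8)
  ins <- est[est$type == "insertion" & est$length %in% 10:25, ]
  expect_gte(mean(ins$ciLow <= 2e-3 & 2e-3 <= ins$ciHigh), 0.8)
})

test_that("Poisson confidence intervals behave at the edges", {
  ci0 <- poissonCI(0, 100, seed = 1)
  expect_equal(ci0$ciLow, 0)
  expect_equal(ci0$ciHigh, 0)
  ci <- poissonCI(100, 1000, seed = 2)
  expect_lt(ci$ciLow, 0.1)
  expect_gt(ci$ciHigh, 0.1)
  expect_lt(ci$ciHigh - ci$ciLow, 4 * 2 * sqrt(100) / 1000)
  expect_identical(poissonCI(c(5, 50), c(10, 10), seed = 9),
                   poissonCI(c(5, 50), c(10, 10), seed = 9))
  expect_true(is.na(poissonCI(5, 0, seed = 1)$ciLow))
})

test_that("log-log regression recovers power-law exponents", {
  L <- 1:30
  tab <- data.frame(type = "insertion", length = L,
                    rate = 3e-7 * L^2.5 * L)   # per-repeat = per-target * L
  fit <- fitPowerLaw(tab, "insertion", fitLengths = 12:19, refRate8 = 3e-7 * 8^2.5 / 2)
  expect_equal(fit$slope, 2.5, tolerance = 1e-10)
  expect_equal(fit$rate9, 3e-7 * 9^2.5, tolerance = 1e-8)
  expect_equal(fit$m, 2 * (9 / 8)^2.5, tolerance = 1e-8)
  # constant per-target rate: zero exponent
  tab0 <- data.frame(type = "insertion", length = L, rate = 1e-6 * L)
  expect_equal(fitPowerLaw(tab0, "insertion")$slope, 0, tolerance = 1e-10)
  expect_error(fitPowerLaw(tab0[tab0$length > 28, ], "insertion"),
               "at least 3")
})
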