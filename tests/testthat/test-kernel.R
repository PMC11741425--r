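test_that("parameterized rate curves extend the de novo anchors", {
  dn <- list(expansion = rep(1e-6, 8), contraction = rep(2e-6, 8),
             insertion = rep(1e-7, 8))
  rm_ <- buildRateCurves(dn, instabilityParams(2, 1, 2), LBoundary = 40)
  expect_equal(expansionRates(rm_)[1:8], dn$expansion)
  expect_equal(expansionRates(rm_)[9], 2e-6)       # m x rate(8)
  expect_equal(expansionRates(rm_)[18], 4e-6)      # (18/9)^1 doubling
  expect_equal(insertionRates(rm_)[18], 4e-7)      # insertion shares tauE
  # tau = 0: constant above L = 8
  rm0 <- buildRateCurves(dn, instabilityParams(4, 0, 0), LBoundary = 40)
  expect_equal(unique(expansionRates(rm0)[9:40]), 4e-6)
  # cap at 0.1 is monotone once reached
  rmBig <- buildRateCurves(list(expansion = rep(1e-3, 8),
                                contraction = rep(1e-3, 8),
                                insertion = rep(1e-3, 8)),
                           instabilityParams(32, 5, 5), LBoundary = 60)
  capped <- which(expansionRates(rmBig) >= 0.1)
  expect_equal(expansionRates(rmBig)[capped], rep(0.1, length(capped)))
  expect_true(all(diff(capped) == 1))
  expect_error(buildRateCurves(list(expansion = rep(NA_real_, 8),
                                    contraction = rep(1e-6, 8),
                                    insertion = rep(1e-6, 8)),
                               instabilityParams(1, 1, 1)), "finite")
})

test_that("a kernel step applies the transition rules exactly", {
  LB <- 20L
  # all rates zero: identity
  st <- jointState(c(`3` = 10, `7` = 5), c(`1` = 2), LBoundary = LB)
  out <- stepDeterministic(st, rateModel(LBoundary = LB))
  expect_identical(countsA(out$state), countsA(st))
  expect_identical(countsB(out$state), countsB(st))

  # substitution fission of L = 5 at rate 1e-3: e = 3 events
  st5 <- jointState(c(`5` = 1000), numeric(LB), LBoundary = LB)
  res <- stepDeterministic(st5, rateModel(c(fission = 1e-3), LBoundary = LB))
  A <- countsA(res$state)
  expect_equal(A[5], 997)
  expect_equal(A[1:3], rep(2, 3))
  expect_equal(countsB(res$state)[1], 3)
  expect_equal(totalLength(res$state), 5000)  # length conserved

  # expansion at L = 10, rate 1e-4 per target, target size L
  st10 <- jointState(c(`10` = 1000), numeric(LB), LBoundary = LB)
  res <- stepDeterministic(st10, rateModel(expansion = c(rep(0, 9), 1e-4,
                                                         rep(0, 10)),
                                           LBoundary = LB))
  A <- countsA(res$state)
  expect_equal(A[10], 999)
  expect_equal(A[11], 1)
  expect_equal(totalLength(res$state), 10001)
})

test_that("fission and fusion bookkeeping changes repeat counts by the event count", {
  LB <- 30L
  st <- jointState(c(`9` = 1000), c(`1` = 500), LBoundary = LB)
  # fission: e = mu * (L-2) * N = 1e-3 * 7 * 1000 = 7; repeat count +7
  res <- stepDeterministic(st, rateModel(c(fission = 1e-3), LBoundary = LB))
  expect_equal(sum(countsA(res$state)) - 1000, 7)
  # fission length budget: A loses e units to B1 per event
  expect_equal(totalLength(res$state), totalLength(st))
  # fusion: E = mu * NB1 = 2e-3 * 500 = 1; repeat count -1, B1 -1
  res <- stepDeterministic(st, rateModel(c(fusion = 2e-3), LBoundary = LB))
  expect_equal(sum(countsA(res$state)) - 1000, -1)
  expect_equal(countsB(res$state)[1], 499)
  expect_equal(totalLength(res$state), totalLength(st))
  # insertion fission: e = iota*L*N; fragments total L, plus one B1
  sti <- jointState(c(`10` = 1000), numeric(LB), LBoundary = LB)
  res <- stepDeterministic(sti, rateModel(insertion = 1e-4, LBoundary = LB))
  expect_equal(sum(countsA(res$state)) - 1000, 1)   # e = 1e-4*10*1000 = 1
  expect_equal(countsB(res$state)[1], 1)
  expect_equal(totalLength(res$state), 10001)
})

test_that("total genome length is conserved under substitutions alone", {
  LB <- 60L
  rm_ <- twoWayRateModel(4.77e-9, 8.08e-9, LB)
  st <- geometricJointState(0.371, 1e7, LB)
  t0 <- totalLength(st)
  ev <- evolveState(st, rm_, data.frame(r = 3, iterations = 2000),
                    snapshotEvery = 0, boundaryTrigger = Inf)
  expect_lt(abs(totalLength(ev$state) - t0) / t0, 1e-9)
})

test_that("the deterministic step refuses states violating the linear bound", {
  LB <- 15L
  st <- jointState(c(`10` = 100), numeric(LB), LBoundary = LB)
  rm_ <- rateModel(expansion = 0.1, LBoundary = LB)
  # per-repeat outflux 0.1 * 10 = 1 per generation: negative count
  expect_error(stepDeterministic(st, rm_, r = 1), "bound")
  # with clamping the step is taken and counts stay non-negative
  out <- stepDeterministic(st, rm_, r = 1, clampNegative = TRUE)$state
  expect_true(all(countsA(out) >= 0))
})

test_that("the linear-mutation bound check flags offending populated bins", {
  LB <- 20L
  st <- jointState(c(`10` = 100), numeric(LB), LBoundary = LB)
  expect_true(checkLinearBound(st, rateModel(LBoundary = LB))$ok)
  eps <- rep(0, LB); eps[10] <- 0.05
  rm_ <- rateModel(expansion = eps, LBoundary = LB)
  chk <- checkLinearBound(st, rm_, r = 0)
  expect_false(chk$ok)              # 0.05 * 10 = 0.5 > 0.1
  expect_identical(chk$offending, 10L)
  expect_true(checkLinearBound(st, rm_, r = -1)$ok)
  # unpopulated bins never offend
  st2 <- jointState(c(`2` = 100), numeric(LB), LBoundary = LB)
  expect_true(checkLinearBound(st2, rm_, r = 0)$ok)
})

test_that("gains above the boundary reflect onto the boundary bin", {
  LB <- 10L
  st <- jointState(c(`9` = 100, `10` = 50), numeric(LB), LBoundary = LB)
  eps <- rep(1e-3, LB)
  res <- stepDeterministic(st, rateModel(expansion = eps, LBoundary = LB))
  A <- countsA(res$state)
  # L = 9 loses e9 = 0.9 to bin 10; bin 10's own expansions reflect back
  expect_equal(A[9], 100 - 0.9)
  expect_equal(A[10], 50 + 0.9)
  expect_equal(sum(countsA(res$state)), 150)
})

test_that("fusion products are drawn from the length distribution twice", {
  LB <- 30L
  st <- jointState(c(`2` = 600, `5` = 400), c(`1` = 100), LBoundary = LB)
  res <- stepDeterministic(st, rateModel(c(fusion = 1e-2), LBoundary = LB))
  A <- countsA(res$state)
  E <- 1e-2 * 100
  w <- c(0.6, 0.4)
  # products at j + k + 1: 2+2+1=5, 2+5+1=8 (x2), 5+5+1=11
  expect_equal(A[8] - 0, 2 * E * w[1] * w[2])
  expect_equal(A[11], E * w[2]^2)
  expect_equal(A[5] - 400, E * w[1]^2 - 2 * E * w[2])
  # the per-event "even removal" mode spreads removals evenly below the
  # product length (it requires occupancy in every low bin)
  stFull <- jointState(rep(100, 6), c(`1` = 100), LBoundary = LB)
  resO <- stepDeterministic(stFull, rateModel(c(fusion = 1e-2),
                                              LBoundary = LB))
  resE <- stepDeterministic(stFull, rateModel(c(fusion = 1e-2),
                                              LBoundary = LB),
                            fusionMode = "even")
  expect_equal(sum(countsA(resE$state)), sum(countsA(resO$state)))
  expect_equal(totalLength(resE$state), totalLength(resO$state))
  expect_false(identical(countsA(resE$state), countsA(resO$state)))
})

test_that("stochastic steps average to the deterministic step", {
  LB <- 40L
  rs <- fix_rates
  rm_ <- buildRateCurves(rs$denovo, instabilityParams(2, 1.5, 2),
                         rs$contextRates, LB)
  # integer counts: the zero floor never distorts the mean when bins
  # with outflux hold whole repeats
  g <- geometricJointState(0.37, 1e6, LB)
  st <- jointState(round(countsA(g)), round(countsB(g)), LBoundary = LB)
  det <- countsA(stepDeterministic(st, rm_, r = 3)$state)
  # zero rates: stochastic step is the identity
  same <- stepStochastic(st, rateModel(LBoundary = LB), seed = 1)
  expect_identical(countsA(same), countsA(st))
  # fixed seed reproduces the trajectory
  s1 <- stepStochastic(st, rm_, r = 3, seed = 42)
  s2 <- stepStochastic(st, rm_, r = 3, seed = 42)
  expect_identical(countsA(s1), countsA(s2))
  # mean over replicates within 3 empirical SEs per bin
  set.seed(9)
  n <- 2000
  acc <- acc2 <- numeric(LB)
  for (k in seq_len(n)) {
    a <- countsA(stepStochastic(st, rm_, r = 3))
    acc <- acc + a
    acc2 <- acc2 + a^2
  }
  m <- acc / n
  sdv <- sqrt(pmax(acc2 / n - m^2, 0))
  # per-bin variance of one step is total influx + outflux, which is at
  # least the absolute expected change: floor the empirical SE there so
  # bins whose rare events never fired are not scored with zero spread
  se <- pmax(sdv, sqrt(abs(det - countsA(st))), 1e-12) / sqrt(n)
  expect_true(all(abs(m - det) <= 3.5 * se))
})

test_that("a stage at r matches ten times the iterations at r - 1", {
  LB <- 40L
  rs <- fix_rates
  rm_ <- buildRateCurves(rs$denovo, instabilityParams(2, 1.5, 2),
                         rs$contextRates, LB)
  st <- geometricJointState(0.37, 1e6, LB)
  e1 <- evolveState(st, rm_, data.frame(r = 1, iterations = 10),
                    snapshotEvery = 0, boundaryTrigger = Inf)$state
  e0 <- evolveState(st, rm_, data.frame(r = 0, iterations = 100),
                    snapshotEvery = 0, boundaryTrigger = Inf)$state
  keep <- countsA(e0) > 1e-12
  rel <- abs(countsA(e1) - countsA(e0))[keep] / countsA(e0)[keep]
  expect_lt(max(rel), 1e-6)
})

test_that("evolution records snapshots and a generation counter", {
  LB <- 30L
  rm_ <- twoWayRateModel(5e-9, 8e-9, LB)
  st <- geometricJointState(0.37, 1e6, LB)
  ev <- evolveState(st, rm_, data.frame(r = 5, iterations = 100),
                    snapshotEvery = 2e6, boundaryTrigger = Inf)
  expect_equal(generation(ev$state), 1e7)
  expect_equal(sort(unique(ev$trajectory$generation)),
               seq(2e6, 1e7, by = 2e6))
  expect_identical(colnames(ev$trajectory),
                   c("generation", "length", "countA", "countB"))
})

test_that("flux decomposition balances bookkeeping per process", {
  LB <- 25L
  st <- jointState(c(`5` = 100, `10` = 50), c(`1` = 20), LBoundary = LB)
  # single-process: expansion outflux at L equals influx at L + 1
  fx <- fluxDecomposition(st, rateModel(expansion = 1e-4, LBoundary = LB),
                          normalize = FALSE)
  ex <- fx[fx$process == "expansion", ]
  expect_equal(ex$influx[6], ex$outflux[5])
  expect_equal(ex$influx[11], ex$outflux[10])
  expect_equal(sum(fx[fx$process != "expansion", "influx"]), 0)
  # normalized table: |in| + |out| sums to 1 in every active bin
  fxn <- fluxDecomposition(st, twoWayRateModel(5e-9, 8e-9, LB))
  tot <- tapply(fxn$influx + fxn$outflux, fxn$length, sum)
  active <- tot > 0
  expect_equal(as.numeric(tot[active]), rep(1, sum(active)))
})

test_that("substitution-only evolution is stationary at the geometric state", {
  LB <- 60L
  mu <- 4.77e-9; nu <- 8.08e-9
  rm_ <- twoWayRateModel(mu, nu, LB)
  ge <- geometricJointState(mu / (mu + nu), 1e7, LB)
  fx <- fluxDecomposition(ge, rm_, normalize = FALSE)
  net <- tapply(fx$influx - fx$outflux, fx$length, sum)
  gross <- tapply(fx$influx + fx$outflux, fx$length, sum)
  pop <- which(countsA(ge) >= 1)
  expect_lt(max(abs(net[pop]) / gross[pop]), 1e-6)
})

test_that("equilibrium shape is independent of the initial condition", {
  LB <- 50L
  rs <- fix_rates
  rm_ <- buildRateCurves(rs$denovo, instabilityParams(2, 1.5, 2),
                         contextNoB(), LB)
  sch <- data.frame(r = c(5, 4, 3), iterations = c(5e4, 1e4, 1e4))
  stG <- geometricJointState(0.371, 1e8, LB)
  stU <- jointState(rep(1e8 / LB, LB), rep(1e8 / LB, LB), LBoundary = LB)
  a <- countsA(evolveState(stG, rm_, sch, snapshotEvery = 0,
                           boundaryTrigger = Inf)$state)
  b <- countsA(evolveState(stU, rm_, sch, snapshotEvery = 0,
                           boundaryTrigger = Inf)$state)
  pa <- a / sum(a); pb <- b / sum(b)
  keep <- pa > 1e-12
  # the substitution-dominated short bins agree to ~1e-5; across the
  # instability tail the nearly decoupled short/long growth modes leave a
  # persistent admixture offset of a few 1e-4 (see the methods vignette)
  expect_lt(max(abs(pa[1:3] - pb[1:3]) / pa[1:3]), 1e-4)
  expect_lt(max(abs(pa[keep] - pb[keep]) / pa[keep]), 1e-3)
})

test_that("non-equilibrating parameters accumulate at the boundary monotonically", {
  LB <- 40L
  rs <- fix_rates
  rm_ <- buildRateCurves(rs$denovo, instabilityParams(2, 2.5, 1.5),
                         contextNoB(), LB)
  st <- geometricJointState(0.371, 1e9, LB)
  ev <- evolveState(st, rm_, data.frame(r = 5, iterations = 2e4),
                    snapshotEvery = 2e7, boundaryTrigger = Inf)
  bd <- ev$trajectory$countA[ev$trajectory$length == LB]
  expect_gt(length(bd), 5)
  expect_true(all(diff(bd) >= -1e-9 * max(bd)))
  expect_true(boundaryFlag(evolveState(st, rm_,
    data.frame(r = 5, iterations = 2e5), snapshotEvery = 0,
    boundaryTrigger = Inf)$state))
})
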