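# Posterior inclusion probabilities, model selection, confusion accounting
# and stability traces.

# fabricate a ChainSamples object from explicit indicator/coefficient draws
fakeSamples <- function(gamma, beta = NULL) {
  D <- dim(gamma)[1]; G <- dim(gamma)[2]
  if (is.null(beta)) beta <- array(0, dim(gamma))
  snvIDs <- sprintf("g%d", seq_len(G))
  Sig <- array(0, c(D, 2, 2))
  Sig[, 1, 1] <- 1; Sig[, 2, 2] <- 1
  new("ChainSamples", gamma = gamma, beta = beta,
      betaFixed = array(0, c(D, 1, 2)), q = matrix(0.5, D, 2),
      SigmaP = Sig, SigmaS = Sig, SigmaE = Sig, famEffects = NULL,
      subjEffects = NULL, snvIDs = snvIDs, fixedNames = "(Intercept)",
      traitNames = c("t1", "t2"),
      config = chainConfig(nIterations = D + 1L, burnIn = 1L, thinning = 1L,
                           seed = 1L),
      priors = priorSpec(b = G))
}

test_that("PIPs are indicator frequencies with complements summing to one", {
  gam <- array(0L, c(4, 2, 2))
  gam[, 1, 1] <- c(1L, 0L, 1L, 1L)
  s <- fakeSamples(gam)
  pips <- inclusionProbabilities(s)
  expect_equal(pips$pip[pips$snv == "g1" & pips$trait == "t1"], 0.75)
  expect_equal(pips$pip[pips$snv == "g2" & pips$trait == "t2"], 0)
  expect_equal(pips$exclusionProb, 1 - pips$pip)
})

test_that("median probability model includes ties at the threshold and is monotone", {
  gam <- array(0L, c(100, 3, 2))
  gam[1:93, 1, 1] <- 1L      # A: 0.93
  gam[1:50, 2, 1] <- 1L      # B: 0.50
  gam[1:49, 3, 1] <- 1L      # C: 0.49
  pips <- inclusionProbabilities(fakeSamples(gam))
  sel <- medianProbabilityModel(pips, 0.5)
  t1sel <- sel$selected$snv[sel$selected$trait == "t1"]
  expect_setequal(t1sel, c("g1", "g2"))

  none <- medianProbabilityModel(pips, 1.0)
  expect_equal(nrow(none$selected), 0L)

  loose <- medianProbabilityModel(pips, 0.3)
  strict <- medianProbabilityModel(pips, 0.5)
  key <- function(s) paste(s$selected$snv, s$selected$trait)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("confusion counts satisfy the set identities", {
  gam <- array(0L, c(10, 4, 2))
  gam[, 1, 1] <- 1L                       # select g1 for t1
  gam[, 2, 2] <- 1L                       # select g2 for t2
  pips <- inclusionProbabilities(fakeSamples(gam))
  sel <- medianProbabilityModel(pips)
  truth <- list(causal1 = c("g1", "g3"), causal2 = c("g4"),
                snvIDs = sprintf("g%d", 1:4))
  cc <- confusionCounts(sel, truth, traitNames = c("t1", "t2"))
  expect_equal(cc$tp, c(1L, 0L))
  expect_equal(cc$fp, c(0L, 1L))
  expect_equal(cc$fn, c(1L, 1L))
  # TP + FN = |causal|, TP + FP = |selected| per trait
  expect_equal(cc$tp + cc$fn, c(2L, 1L))
  nsel <- table(factor(sel$selected$trait, levels = c("t1", "t2")))
  expect_equal(cc$tp + cc$fp, as.integer(nsel))
})

test_that("an empty selection against 15 causal trait-2 SNVs gives 15 false negatives", {
  gam <- array(0L, c(10, 20, 2))
  pips <- inclusionProbabilities(fakeSamples(gam))
  sel <- medianProbabilityModel(pips)
  ids <- sprintf("g%d", 1:20)
  truth <- list(causal1 = ids[1:14], causal2 = ids[1:15], snvIDs = ids)
  cc <- confusionCounts(sel, truth, traitNames = c("t1", "t2"))
  expect_equal(cc$fn[2], 15L)
  expect_equal(cc$tp, c(0L, 0L))
  # a selected SNV outside the truth universe is an error
  gam2 <- array(1L, c(10, 1, 2))
  sel2 <- medianProbabilityModel(inclusionProbabilities(fakeSamples(gam2)))
  truthSmall <- list(causal1 = "zz", causal2 = "zz", snvIDs = "zz")
  expect_error(confusionCounts(sel2, truthSmall, c("t1", "t2")),
               "not covered")
})

test_that("coefficient summaries condition on inclusion and flag never-included SNVs", {
  gam <- array(0L, c(3, 2, 2))
  bet <- array(0, c(3, 2, 2))
  gam[, 1, 1] <- 1L
  bet[, 1, 1] <- c(1, 2, 3)
  cs <- coefficientSummaries(fakeSamples(gam, bet))
  row <- cs[cs$snv == "g1" & cs$trait == "t1", ]
  expect_equal(row$condMean, 2)
  expect_equal(row$nInclusionDraws, 3L)
  expect_equal(row$modelAvgMean, 2)        # included in every draw
  never <- cs[cs$snv == "g2" & cs$trait == "t1", ]
  expect_equal(never$flag, "no-inclusion")
  expect_true(is.na(never$condMean))
  expect_equal(never$exclusionProb, 1)
  expect_equal(never$modelAvgMean, 0)
})

test_that("PIP stability traces are flat for constant chains and settle for alternating ones", {
  D <- 200
  gam <- array(0L, c(D, 2, 2))
  gam[, 1, 1] <- 1L                        # constant inclusion
  gam[, 2, 1] <- rep(c(1L, 0L), D / 2)     # alternating
  st <- pipStability(fakeSamples(gam), nSegments = 10)
  expect_true(all(st$trace[, 1, 1] == 1))
  expect_equal(st$finalHalfDrift[1, 1], 0)
  expect_equal(st$trace[10, 2, 1], 0.5, tolerance = 1e-12)
  expect_lt(st$finalHalfDrift[2, 1], 0.01)
})

test_that("after-the-fact thinning moves PIPs only within Monte Carlo error", {
  dat <- microDataset(seed = 23, nFam = 6, nSub = 5, nVis = 2, G = 3,
                      beta = matrix(c(1.5, 0, 0, 1.2, 0, 0), 3, 2))
  fit <- runChain(dat, priorSpec(),
                  chainConfig(nIterations = 2200, burnIn = 200,
                              thinning = 1, seed = 8))
  pips <- inclusionProbabilities(fit)
  sub <- fit
  keep <- seq(1, nDraws(fit), by = 2)
  sub@gamma <- fit@gamma[keep, , , drop = FALSE]
  sub@beta <- fit@beta[keep, , , drop = FALSE]
  sub@betaFixed <- fit@betaFixed[keep, , , drop = FALSE]
  sub@q <- fit@q[keep, , drop = FALSE]
  sub@SigmaP <- fit@SigmaP[keep, , , drop = FALSE]
  sub@SigmaS <- fit@SigmaS[keep, , , drop = FALSE]
  sub@SigmaE <- fit@SigmaE[keep, , , drop = FALSE]
  sub@config <- chainConfig(nIterations = length(keep) + 1L, burnIn = 1L,
                            thinning = 1L, seed = 8L)
  pipsSub <- inclusionProbabilities(sub)
  tol <- pmax(4 * (pips$mcse + pipsSub$mcse), 0.02)
  expect_true(all(abs(pips$pip - pipsSub$pip) <= tol))
})
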