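# Pedigree templates, Mendelian gene dropping, and the generative phenotype
# model's moment structure.

test_that("a one-couple two-offspring template gives a family of four", {
  cfg <- simConfig(nFamilies = 1, offspringRange = c(2, 2), generations = 1)
  ped <- simulatePedigreeStructure(cfg, seed = 1)
  expect_equal(nIndividuals(ped), 4L)
  expect_equal(sum(pedTable(ped)$founder), 2L)
})

test_that("pedigree simulation is deterministic in the seed and varies across seeds", {
  cfg <- simConfig(nFamilies = 5)
  a <- simulatePedigreeStructure(cfg, seed = 10)
  b <- simulatePedigreeStructure(cfg, seed = 10)
  c <- simulatePedigreeStructure(cfg, seed = 11)
  expect_identical(pedTable(a), pedTable(b))
  expect_false(identical(pedTable(a), pedTable(c)))
})

test_that("the default 20-family template lands in the extended-pedigree size range", {
  ped <- simulatePedigreeStructure(simConfig(nFamilies = 20), seed = 4)
  n <- nIndividuals(ped)
  expect_gte(n, 20 * 21)
  expect_lte(n, 20 * 75)
  expect_gte(n / 20, 21)
  expect_lte(n / 20, 75)
})

test_that("gene dropping is Mendelian-consistent for every child", {
  cfg <- simConfig(nFamilies = 6)
  ped <- simulatePedigreeStructure(cfg, seed = 8)
  geno <- dropGenes(ped, mafs = c(0.5, 0.2, 0.05), seed = 9)
  p <- pedTable(ped)
  d <- dosages(geno)
  key <- paste(p$fid, p$iid)
  ok <- TRUE
  for (i in which(!p$founder)) {
    fa <- d[match(paste(p$fid[i], p$father[i]), key), ]
    mo <- d[match(paste(p$fid[i], p$mother[i]), key), ]
    # attainable dosage range given parental genotypes
    lo <- (fa == 2) + (mo == 2)
    hi <- 2 - (fa == 0) - (mo == 0)
    ok <- ok && all(d[i, ] >= lo & d[i, ] <= hi)
  }
  expect_true(ok)
})

test_that("offspring of 0x0 and 2x2 crosses are forced homozygous", {
  ped <- PedigreeSet(data.frame(
    fid = "F1", iid = c("f", "m", paste0("k", 1:30)),
    father = c(NA, NA, rep("f", 30)), mother = c(NA, NA, rep("m", 30)),
    sex = c(1, 2, rep(1, 30))))
  for (sd_ in 1:3) {
    g <- dosages(dropGenes(ped, mafs = c(0.5, 0.5), seed = sd_))
    expect_true(all(g %in% 0:2))
    for (j in 1:2) {
      if (g[1, j] == 0 && g[2, j] == 0) expect_true(all(g[-(1:2), j] == 0))
      if (g[1, j] == 2 && g[2, j] == 2) expect_true(all(g[-(1:2), j] == 2))
    }
  }
})

test_that("phenotype layers reproduce the variance-components decomposition", {
  # no genetic/covariate effects; check Var, within-subject and
  # within-family covariances against sigma arithmetic, 3 settings
  settings <- list(
    list(sp = c(2, 2), ss = c(3, 3), se = c(2, 2)),
    list(sp = c(1, 3), ss = c(2, 1), se = c(3, 2)),
    list(sp = c(3, 1), ss = c(1, 2), se = c(1, 3)))
  for (s in settings) {
    cfg <- simConfig(nFamilies = 200, offspringRange = c(2, 2),
                     generations = 1, marryProb = 0, nVisits = 2,
                     mafs = 0.3, intercepts = c(0, 0),
                     betaSex = c(0, 0), betaAge = c(0, 0),
                     betaSmoke = c(0, 0),
                     sigmaP = s$sp, sigmaS = s$ss, sigmaE = s$se,
                     rhoP = 0, rhoS = 0, rhoE = 0)
    ped <- simulatePedigreeStructure(cfg, seed = 50)
    geno <- dropGenes(ped, cfg$mafs, seed = 51)
    sim <- simulatePhenotypes(ped, geno, cfg, seed = 52)
    ph <- phenoTable(sim$pheno)
    for (k in 1:2) {
      y <- ph[[paste0("y", k)]]
      tot_true <- s$sp[k]^2 + s$ss[k]^2 + s$se[k]^2
      # observations within a family are correlated, so aggregate to
      # family-level means before computing standard errors
      vFam <- tapply(y^2, ph$fid, mean)      # known zero mean
      expect_lt(abs(mean(vFam) - tot_true),
                3 * sd(vFam) / sqrt(length(vFam)))

      y1 <- y[ph$visit == 1]; y2 <- y[ph$visit == 2]
      cvFam <- tapply(y1 * y2, ph$fid[ph$visit == 1], mean)
      expect_lt(abs(mean(cvFam) - (s$sp[k]^2 + s$ss[k]^2)),
                3 * sd(cvFam) / sqrt(length(cvFam)))

      # within-family cross-subject at visit 1: founder couple members
      first <- ph[ph$visit == 1, ]
      a <- first[[paste0("y", k)]][first$iid == "I001"]
      b <- first[[paste0("y", k)]][first$iid == "I002"]
      cf <- a * b
      expect_lt(abs(mean(cf) - s$sp[k]^2), 3 * sd(cf) / sqrt(length(cf)))
    }
  }
})

test_that("with all variances zero the traits are exactly intercept + dosage effects", {
  ped <- flatPedigree(2, 5)
  geno <- dropGenes(ped, mafs = c(0.4, 0.3), seed = 3)
  cfg <- simConfig(nFamilies = 2, mafs = c(0.4, 0.3),
                   causal = data.frame(g = 1, beta1 = -5.46, beta2 = -8.70),
                   intercepts = c(80, 120), betaSex = c(0, 0),
                   betaAge = c(0, 0), betaSmoke = c(0, 0),
                   sigmaP = c(0, 0), sigmaS = c(0, 0), sigmaE = c(0, 0),
                   nVisits = 2)
  sim <- simulatePhenotypes(ped, geno, cfg, seed = 4)
  ph <- phenoTable(sim$pheno)
  d1 <- dosages(geno)[match(paste(ph$fid, ph$iid),
                            paste(sampleInfo(geno)$fid,
                                  sampleInfo(geno)$iid)), 1]
  expect_equal(ph$y1, 80 - 5.46 * d1, tolerance = 1e-6)
  expect_equal(ph$y2, 120 - 8.70 * d1, tolerance = 1e-6)
})

test_that("zero cross-trait correlations give independent trait residuals", {
  cfg <- simConfig(nFamilies = 400, offspringRange = c(3, 3),
                   generations = 1, marryProb = 0, nVisits = 2, mafs = 0.3,
                   intercepts = c(0, 0), betaSex = c(0, 0),
                   betaAge = c(0, 0), betaSmoke = c(0, 0),
                   sigmaP = c(1, 1), sigmaS = c(1, 1), sigmaE = c(1, 1),
                   rhoP = 0, rhoS = 0, rhoE = 0)
  ped <- simulatePedigreeStructure(cfg, seed = 60)
  geno <- dropGenes(ped, cfg$mafs, seed = 61)
  sim <- simulatePhenotypes(ped, geno, cfg, seed = 62)
  ph <- phenoTable(sim$pheno)
  r <- cor(ph$y1, ph$y2)
  expect_lt(abs(r), 3 / sqrt(nrow(ph)))
})

test_that("phenotype simulation is deterministic given (cfg, seed)", {
  sc1 <- recoveryScenario(seed = 12, G = 4)
  sc2 <- recoveryScenario(seed = 12, G = 4)
  sc3 <- recoveryScenario(seed = 13, G = 4)
  expect_identical(sc1$data@Y, sc2$data@Y)
  expect_false(identical(sc1$data@Y, sc3$data@Y))
})

test_that("the benchmark scenario titrates noise and excludes the null-effect SNV from truth", {
  sc <- gawLikeScenario(noiseCount = 1, seed = 30)
  expect_equal(nSNVs(sc$data), 16L)
  expect_equal(length(sc$truth$causal1), 14L)   # 15 causal minus the null row
  expect_equal(length(sc$truth$causal2), 14L)
  expect_false("v47958037" %in% sc$truth$causal1)
  expect_false("v47958037" %in% sc$truth$causal2)
  expect_equal(nObs(sc$data), 3L * max(sc$data@subjIdx))
})

test_that("the full titration frame has 105 candidate columns", {
  sc <- gawLikeScenario(noiseCount = 90, seed = 31)
  expect_equal(nSNVs(sc$data), 105L)
})

test_that("LD pairs built by copy-with-flip reach the target r2", {
  ped <- flatPedigree(40, 25)             # 1000 founders
  lp <- data.frame(source = 1, target = 2, eps = 0.02)
  geno <- dropGenes(ped, mafs = c(0.3, 0.3), seed = 70, ldPairs = lp)
  expect_gte(ldR2(geno, "snv01", "snv02"), 0.8)
})
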