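# Full-conditional closed forms, chain mechanics and state invariants.

test_that("the Beta update for q has the conjugate parameters", {
  expect_equal(pedsur:::.qPosteriorParams(0, 3, a = 1, b = 3),
               c(shape1 = 1, shape2 = 6))
  expect_equal(pedsur:::.qPosteriorParams(3, 3, a = 1, b = 3),
               c(shape1 = 4, shape2 = 3))
})

test_that("random-effect full conditionals match an independent joint-Gaussian conditioning", {
  # equal-precision special case: Sigma_p = Sigma_e = I, one residual r
  mom <- pedsur:::.effectConditionalMoments(diag(2), diag(2), c(1.2, -0.4),
                                            m = 1)
  expect_equal(mom$mean, c(0.6, -0.2), tolerance = 1e-12)
  expect_equal(mom$cov, diag(0.5, 2), tolerance = 1e-12)

  # balanced case checked against Schur-complement conditioning of the
  # joint normal of (p, d_1, ..., d_m), d_j = p + e_j
  Sp <- matrix(c(0.7, 0.3, 0.3, 0.9), 2)
  Se <- matrix(c(1.1, -0.2, -0.2, 0.8), 2)
  m <- 3
  D <- matrix(c(0.5, 1.0, -0.7, 0.2, 0.1, 0.9), m, 2, byrow = TRUE)
  V <- rbind(cbind(Sp, do.call(cbind, rep(list(Sp), m))),
             cbind(do.call(rbind, rep(list(Sp), m)),
                   kronecker(matrix(1, m, m), Sp) +
                     kronecker(diag(m), Se)))
  dvec <- as.numeric(t(D))
  condMean <- V[1:2, -(1:2)] %*% solve(V[-(1:2), -(1:2)], dvec)
  condCov <- V[1:2, 1:2] -
    V[1:2, -(1:2)] %*% solve(V[-(1:2), -(1:2)], t(V[1:2, -(1:2)]))
  mom <- pedsur:::.effectConditionalMoments(Sp, Se, colSums(D), m = m)
  expect_equal(mom$mean, as.numeric(condMean), tolerance = 1e-10)
  expect_equal(mom$cov, condCov, tolerance = 1e-10)
})

test_that("inverse-Wishart posterior parameters count contributing vectors", {
  M <- matrix(rnorm(10), 5, 2)
  pp <- pedsur:::.iwPosteriorParams(3, diag(0.01, 2), M)
  expect_equal(pp$df, 8)
  expect_equal(pp$scale, diag(0.01, 2) + crossprod(M), tolerance = 1e-12)
  # zero vectors leave the prior scale untouched
  p0 <- pedsur:::.iwPosteriorParams(3, diag(0.01, 2), matrix(0, 7, 2))
  expect_equal(p0$df, 10)
  expect_equal(p0$scale, diag(0.01, 2), tolerance = 1e-15)
})

test_that("inverse-Wishart draws have the analytic mean scale/(df - 3)", {
  set.seed(5)
  df <- 12; S <- matrix(c(2, 0.5, 0.5, 1.5), 2)
  draws <- replicate(4000, pedsur:::.riw(df, S))
  m <- apply(draws, c(1, 2), mean)
  expect_equal(m, S / (df - 3), tolerance = 0.05)
})

test_that("the collapsed inclusion update matches brute-force quadrature", {
  set.seed(8)
  x <- c(0.6, -0.4, 1.1, -0.9, 0.2, -0.6)   # centered dosage column
  u <- c(1.4, -0.5, 2.2, -1.7, 0.3, -1.1)   # partial residual
  v <- 0.8; tau2 <- 2.5; q <- 0.2
  st <- pedsur:::.snvInclusionStats(sum(x^2), sum(x * u), v, tau2)
  pGibbs <- 1 / (1 + exp(-(st$logBF + log(q) - log(1 - q))))
  lik <- function(beta) {
    vapply(beta, function(b)
      prod(dnorm(u, x * b, sqrt(v))) * dnorm(b, 0, sqrt(tau2)), numeric(1))
  }
  m1 <- integrate(lik, -20, 20, rel.tol = 1e-10)$value
  m0 <- prod(dnorm(u, 0, sqrt(v)))
  pQuad <- q * m1 / (q * m1 + (1 - q) * m0)
  expect_equal(pGibbs, pQuad, tolerance = 1e-4)
  # uninformative (all-zero) column: BF = 1, inclusion prob = q
  st0 <- pedsur:::.snvInclusionStats(0, 0, v, tau2)
  expect_equal(st0$logBF, 0, tolerance = 1e-12)
  # spike = slab limit: tau2 -> 0 gives BF -> 1
  stS <- pedsur:::.snvInclusionStats(sum(x^2), sum(x * u), v, 1e-12)
  expect_equal(stS$logBF, 0, tolerance = 1e-4)
})

test_that("the regression block draws from the conjugate normal-normal posterior", {
  # single coefficient, known variance: posterior mean/var in closed form
  dat <- microDataset(seed = 2, nFam = 2, nSub = 2, nVis = 1, G = 1,
                      covariate = FALSE)
  pr <- priorSpec(a = 1, b = 1, tau2 = 1, v0 = 4, nu0 = 6, S0 = diag(2))
  st <- initState(dat, pr, seed = 1)
  st$P[] <- 0; st$S[] <- 0
  st$Se <- diag(2)               # known residual covariance, independent
  st$Sp <- diag(2); st$Ss <- diag(2)
  prep <- attr(st, "prep")
  y1 <- prep$Y[, 1]
  vpost <- 1 / (nrow(prep$X) + 1 / pr@v0)     # X is the intercept column
  mpost <- vpost * sum(y1)
  set.seed(99)
  draws <- replicate(6000, pedsur:::.updateRegression(st, prep, pr)$betaF[1, 1])
  expect_lt(abs(mean(draws) - mpost), 5 * sqrt(vpost / 6000))
  expect_lt(abs(var(draws) - vpost), 0.15 * vpost)
})

test_that("initState is deterministic, least-squares based, and errors on singular designs", {
  dat <- microDataset(seed = 3, nFam = 3, nSub = 4, nVis = 2, G = 2)
  pr <- properPriors()
  s1 <- initState(dat, pr, seed = 4)
  s2 <- initState(dat, pr, seed = 4)
  expect_identical(s1$betaF, s2$betaF)
  expect_identical(s1$Se, s2$Se)
  expect_true(all(s1$gamma == 0L))
  expect_equal(s1$q, rep(0.5, 2))            # a = b = 2

  # zero response with an orthonormal-column design gives zero coefficients
  dat0 <- dat
  dat0@Y[] <- 0
  s0 <- initState(dat0, pr, seed = 1)
  expect_equal(max(abs(s0$betaF)), 0)

  datc <- dat
  datc@X <- cbind(datc@X, datc@X[, 2])       # duplicated column
  colnames(datc@X) <- c(colnames(dat@X), "dup")
  datc@fixedNames <- colnames(datc@X)
  expect_error(initState(datc, pr, seed = 1), "singular")
})

test_that("initial residual covariance tracks the generating sigma_e within 20%", {
  dat <- microDataset(seed = 6, nFam = 40, nSub = 10, nVis = 3, G = 2,
                      Se = diag(c(4, 9)))
  st <- initState(dat, properPriors(), seed = 1)
  expect_lt(abs(st$Se[1, 1] - 4) / 4, 0.2)
  expect_lt(abs(st$Se[2, 2] - 9) / 9, 0.2)
})

test_that("logJoint equals a hand-summed density on a two-observation toy", {
  ped <- flatPedigree(1, 2)
  geno <- GenotypeMatrix(matrix(c(0, 1), 2, 1, dimnames = list(NULL, "g1")),
                         data.frame(fid = "F01", iid = c("i01", "i02")))
  ph <- data.frame(fid = "F01", iid = c("i01", "i02"), visit = 1,
                   y1 = c(1.3, 0.2), y2 = c(-0.4, 0.8))
  dat <- assembleDataset(ped, PhenotypeTable(ph), geno)
  pr <- priorSpec(a = 2, b = 3, tau2 = 1.5, v0 = 2, nu0 = 5, S0 = diag(2))
  st <- initState(dat, pr, seed = 1)
  st$betaF <- matrix(c(0.5, -0.2), 1, 2)
  st$gamma <- matrix(c(1L, 0L), 1, 2)
  st$bsnv <- matrix(c(0.7, 0), 1, 2)
  st$q <- c(0.3, 0.6)
  st$P <- matrix(c(0.1, -0.3), 1, 2)
  st$S <- matrix(c(0.2, 0.1, -0.1, 0.4), 2, 2)
  st$Sp <- diag(c(1.2, 0.8)); st$Ss <- diag(2); st$Se <- diag(c(0.9, 1.1))
  prep <- attr(st, "prep")
  st$fit <- prep$X %*% st$betaF + prep$Gc %*% (st$gamma * st$bsnv)

  lj <- logJoint(st, dat, pr)

  dn2 <- function(v, S) {                   # hand 2-D normal log density
    -log(2 * pi) - 0.5 * log(det(S)) -
      0.5 * as.numeric(t(v) %*% solve(S) %*% v)
  }
  diw <- function(S, nu, S0) {
    -nu * log(2) - 0.5 * log(pi) - lgamma(nu / 2) - lgamma((nu - 1) / 2) +
      nu / 2 * log(det(S0)) - (nu + 3) / 2 * log(det(S)) -
      0.5 * sum(diag(S0 %*% solve(S)))
  }
  E <- prep$Y - st$fit - st$P[prep$famIdx, ] - st$S[prep$subjIdx, ]
  hand <- sum(vapply(1:2, function(i) dn2(E[i, ], st$Se), numeric(1))) +
    sum(dnorm(st$betaF, 0, sqrt(2), log = TRUE)) +
    dnorm(0.7, 0, sqrt(1.5), log = TRUE) +
    log(0.3) + log(1 - 0.6) +               # gamma = (1, 0)
    dbeta(0.3, 2, 3, log = TRUE) + dbeta(0.6, 2, 3, log = TRUE) +
    dn2(st$P[1, ], st$Sp) +
    sum(vapply(1:2, function(i) dn2(st$S[i, ], st$Ss), numeric(1))) +
    diw(st$Sp, 5, diag(2)) + diw(st$Ss, 5, diag(2)) + diw(st$Se, 5, diag(2))
  expect_equal(lj, hand, tolerance = 1e-10)

  # inflating residuals strictly decreases the log joint under Sigma_e = I
  st2 <- st
  st2$Se <- diag(2)
  base <- logJoint(st2, dat, pr)
  expect_true(is.finite(base))
  stBig <- st2
  stBig$betaF[1, 1] <- stBig$betaF[1, 1] + 10   # blow up residuals
  stBig$fit <- prep$X %*% stBig$betaF + prep$Gc %*% (stBig$gamma * stBig$bsnv)
  expect_lt(logJoint(stBig, dat, pr), base)
})

test_that("logJoint is invariant under family relabeling", {
  dat <- microDataset(seed = 9, nFam = 3, nSub = 2, nVis = 2, G = 2)
  pr <- properPriors()
  st <- initState(dat, pr, seed = 2)
  set.seed(11)
  st <- gibbsSweep(st, dat, pr)
  lj1 <- logJoint(st, dat, pr)
  # relabel families 1<->3 everywhere
  perm <- c(3L, 2L, 1L)
  dat2 <- dat
  dat2@famIdx <- perm[dat@famIdx]
  dat2@subjFam <- perm[dat@subjFam]
  st2 <- st
  st2$P <- st$P[order(perm), , drop = FALSE]
  attr(st2, "prep") <- NULL
  lj2 <- logJoint(st2, dat2, pr)
  expect_equal(lj1, lj2, tolerance = 1e-10)
})

test_that("chain bookkeeping: draw counts, determinism, and univariate constraint", {
  dat <- microDataset(seed = 13, nFam = 3, nSub = 3, nVis = 2, G = 2)
  pr <- properPriors()
  cfg <- chainConfig(nIterations = 100, burnIn = 50, thinning = 10,
                     seed = 5)
  fit <- runChain(dat, pr, cfg)
  expect_equal(nDraws(fit), 5L)
  fit2 <- runChain(dat, pr, cfg)
  expect_identical(fit@gamma, fit2@gamma)
  expect_identical(fit@SigmaE, fit2@SigmaE)

  uni <- runChain(dat, pr, chainConfig(nIterations = 60, burnIn = 20,
                                       thinning = 2, seed = 5,
                                       mode = "univariate"))
  expect_true(all(uni@SigmaP[, 1, 2] == 0))
  expect_true(all(uni@SigmaS[, 1, 2] == 0))
  expect_true(all(uni@SigmaE[, 1, 2] == 0))
})

test_that("sweeps preserve state invariants and keep moving", {
  dat <- microDataset(seed = 14, nFam = 2, nSub = 3, nVis = 2, G = 2,
                      beta = matrix(c(1, 0, 0.5, 0), 2, 2))
  pr <- properPriors()
  st <- initState(dat, pr, seed = 3)
  set.seed(21)
  prev <- NULL
  for (i in 1:50) {
    st <- gibbsSweep(st, dat, pr)
    for (S in list(st$Sp, st$Ss, st$Se)) {
      expect_true(S[1, 1] > 0 && S[2, 2] > 0)
      expect_lt(S[1, 2]^2, S[1, 1] * S[2, 2])
      expect_equal(S[1, 2], S[2, 1])
    }
    expect_true(all(st$q > 0 & st$q < 1))
    expect_true(all(st$gamma %in% c(0L, 1L)))
    if (i == 25) prev <- st
  }
  expect_false(identical(prev$betaF, st$betaF))
})

test_that("coefficients back-transform to the raw trait scale", {
  # strong single-SNV effect; standardized fit must report raw-scale beta
  dat <- microDataset(seed = 15, nFam = 10, nSub = 6, nVis = 2, G = 2,
                      beta = matrix(c(3, 0, 2, 0), 2, 2),
                      Sp = diag(0.2, 2), Ss = diag(0.2, 2),
                      Se = diag(0.3, 2), intercepts = c(5, -3))
  fit <- runChain(dat, priorSpec(),
                  chainConfig(nIterations = 800, burnIn = 200, thinning = 2,
                              seed = 6))
  cs <- coefficientSummaries(fit)
  b11 <- cs$condMean[cs$snv == "g1" & cs$trait == "trait1"]
  b12 <- cs$condMean[cs$snv == "g1" & cs$trait == "trait2"]
  expect_equal(b11, 3, tolerance = 0.3)
  expect_equal(b12, 2, tolerance = 0.3)
})
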