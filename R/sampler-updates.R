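## Full-conditional updates of the bivariate Gibbs sampler. The chain state
## is an internal list (fields betaF P x 2, bsnv G x 2, gamma G x 2, q[2],
## P I x 2, S N x 2, Sp/Ss/Se 2 x 2, fit n x 2); `prep` is the fitting-scale
## data prepared by .prepData(). All conjugate parameter computations are
## factored into small pure helpers so they can be checked against
## hand-derived closed forms.

.inv2 <- function(S) {
  det <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2, 2) / det
}

## Cholesky with a single symmetrize + jitter retry.
.spdChol <- function(A) {
  A <- (A + t(A)) / 2
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch))
    ch <- chol(A + diag(1e-10 * max(diag(A), 1), nrow(A)))
  ch
}

## Inverse-Wishart draw: Sigma = W^{-1}, W ~ Wishart(df, scale^{-1}).
.riw <- function(df, scale) {
  W <- rWishart(1L, df, .inv2(scale))[, , 1L]
  S <- .inv2(W)
  (S + t(S)) / 2
}

## log density of IW(nu, S0) at Sigma (2x2)
.diwLog <- function(Sigma, nu, S0) {
  p <- 2
  ldS0 <- determinant(S0, logarithm = TRUE)$modulus
  ldSg <- determinant(Sigma, logarithm = TRUE)$modulus
  lgamma2 <- lgamma(nu / 2) + lgamma((nu - 1) / 2) + 0.5 * log(pi)
  as.numeric(nu / 2 * ldS0 - nu * p / 2 * log(2) - lgamma2 -
               (nu + p + 1) / 2 * ldSg -
               0.5 * sum(diag(S0 %*% .inv2(Sigma))))
}

## Beta posterior parameters for an inclusion probability.
.qPosteriorParams <- function(nIncluded, nTotal, a, b) {
  c(shape1 = a + nIncluded, shape2 = b + nTotal - nIncluded)
}

## Full-conditional moments of a bivariate random effect with prior
## N2(0, SigmaRE) and m observation-level bivariate residuals (summed in
## residSum) with noise SigmaE.
.effectConditionalMoments <- function(SigmaRE, SigmaE, residSum, m) {
  W <- .inv2(SigmaE)
  prec <- .inv2(SigmaRE) + m * W
  cov <- .inv2(prec)
  list(mean = as.numeric(cov %*% (W %*% residSum)), cov = (cov + t(cov)) / 2)
}

## Inverse-Wishart posterior parameters given effect vectors (rows of M).
.iwPosteriorParams <- function(nu0, S0, M) {
  list(df = nu0 + nrow(M), scale = S0 + crossprod(M))
}

## Spike-and-slab conditional Bayes factor for one SNV column: response u
## (partial residual), noise variance v, slab variance tau2. Returns the
## posterior slab moments and log Bayes factor for inclusion vs exclusion.
.snvInclusionStats <- function(xtx, xtu, v, tau2) {
  Vn <- 1 / (xtx / v + 1 / tau2)
  mn <- Vn * xtu / v
  logBF <- 0.5 * (log(Vn) - log(tau2)) + 0.5 * mn^2 / Vn
  list(mean = mn, var = Vn, logBF = logBF)
}

## ---------------------------------------------------------------------------
## Data preparation
## ---------------------------------------------------------------------------

.prepData <- function(data, standardize = TRUE) {
  Y <- data@Y
  ctr <- c(0, 0); scl <- c(1, 1)
  if (standardize) {
    ctr <- colMeans(Y)
    scl <- apply(Y, 2L, sd)
    if (any(scl == 0)) scl[scl == 0] <- 1
    Y <- sweep(sweep(Y, 2L, ctr), 2L, scl, "/")
  }
  gcenter <- colMeans(data@G)
  Gc <- sweep(data@G, 2L, gcenter)
  I <- max(data@famIdx)
  N <- max(data@subjIdx)
  famObs <- tabulate(data@famIdx, I)
  subjM <- tabulate(data@subjIdx, N)
  list(Y = Y, X = data@X, Gc = Gc, famIdx = data@famIdx,
       subjIdx = data@subjIdx, subjFam = data@subjFam,
       n = nrow(Y), I = I, N = N, G = ncol(Gc), P = ncol(data@X),
       famObs = famObs, subjM = subjM,
       famGroups = split(seq_len(I), famObs),
       subjGroups = split(seq_len(N), subjM),
       xtxSNV = colSums(Gc^2),
       traitCenter = ctr, traitScale = scl, gCenter = gcenter)
}

.resolvePriors <- function(priors, G) {
  if (is.na(priors@b)) priors@b <- as.numeric(G)
  priors
}

## ---------------------------------------------------------------------------
## Initialization
## ---------------------------------------------------------------------------

.initStateInternal <- function(prep, priors, seed) {
  set.seed(as.integer(seed))
  betaF <- matrix(0, prep$P, 2L)
  res <- matrix(0, prep$n, 2L)
  for (k in 1:2) {
    fit_k <- lm.fit(prep$X, prep$Y[, k])
    if (fit_k$rank < prep$P)
      stop("singular fixed-effect design (rank ", fit_k$rank, " < ",
           prep$P, ")")
    betaF[, k] <- fit_k$coefficients
    res[, k] <- fit_k$residuals
  }
  ## residual-based diagonal covariance estimates: pooled within-subject
  ## variance estimates sigma_e^2; the remainder is split between the
  ## family and subject layers
  se2 <- c(0, 0); sp2 <- c(0, 0)
  for (k in 1:2) {
    subj_mean <- rowsum(res[, k], prep$subjIdx) / prep$subjM
    within_ss <- sum((res[, k] - subj_mean[prep$subjIdx])^2)
    df_within <- prep$n - prep$N
    tot <- var(res[, k])
    se2[k] <- if (df_within > 0) within_ss / df_within else tot / 3
    sp2[k] <- max((tot - se2[k]) / 2, 0.05 * tot)
  }
  list(betaF = betaF,
       bsnv = matrix(0, prep$G, 2L),
       gamma = matrix(0L, prep$G, 2L),
       q = rep(priors@a / (priors@a + priors@b), 2L),
       P = matrix(0, prep$I, 2L),
       S = matrix(0, prep$N, 2L),
       Sp = diag(sp2, 2L), Ss = diag(sp2, 2L), Se = diag(se2, 2L),
       fit = prep$X %*% betaF)
}

## ---------------------------------------------------------------------------
## Bivariate updates
## ---------------------------------------------------------------------------

.updateRegression <- function(st, prep, pr) {
  act1 <- which(st$gamma[, 1L] == 1L)
  act2 <- which(st$gamma[, 2L] == 1L)
  A1 <- cbind(prep$X, prep$Gc[, act1, drop = FALSE])
  A2 <- cbind(prep$X, prep$Gc[, act2, drop = FALSE])
  P1 <- ncol(A1); P2 <- ncol(A2)
  d1 <- c(rep(1 / pr@v0, prep$P), rep(1 / pr@tau2, length(act1)))
  d2 <- c(rep(1 / pr@v0, prep$P), rep(1 / pr@tau2, length(act2)))
  W <- .inv2(st$Se)
  r <- prep$Y - st$P[prep$famIdx, , drop = FALSE] -
    st$S[prep$subjIdx, , drop = FALSE]
  L11 <- W[1, 1] * crossprod(A1) + diag(d1, P1)
  L22 <- W[2, 2] * crossprod(A2) + diag(d2, P2)
  L12 <- W[1, 2] * crossprod(A1, A2)
  Lam <- rbind(cbind(L11, L12), cbind(t(L12), L22))
  b <- c(crossprod(A1, W[1, 1] * r[, 1L] + W[1, 2] * r[, 2L]),
         crossprod(A2, W[1, 2] * r[, 1L] + W[2, 2] * r[, 2L]))
  ch <- .spdChol(Lam)
  mean_ <- backsolve(ch, forwardsolve(t(ch), b))
  draw <- mean_ + backsolve(ch, rnorm(P1 + P2))
  st$betaF[, 1L] <- draw[seq_len(prep$P)]
  if (length(act1)) st$bsnv[act1, 1L] <- draw[prep$P + seq_along(act1)]
  st$betaF[, 2L] <- draw[P1 + seq_len(prep$P)]
  if (length(act2)) st$bsnv[act2, 2L] <- draw[P1 + prep$P + seq_along(act2)]
  st$fit <- cbind(A1 %*% draw[seq_len(P1)], A2 %*% draw[P1 + seq_len(P2)])
  st
}

.updateIndicators <- function(st, prep, pr) {
  R <- prep$Y - st$P[prep$famIdx, , drop = FALSE] -
    st$S[prep$subjIdx, , drop = FALSE]
  for (k in 1:2) {
    kk <- 3L - k
    cc <- st$Se[k, kk] / st$Se[kk, kk]
    v <- st$Se[k, k] - st$Se[k, kk] * cc
    lq <- log(st$q[k]) - log1p(-st$q[k])
    for (g in seq_len(prep$G)) {
      x <- prep$Gc[, g]
      old <- if (st$gamma[g, k] == 1L) st$bsnv[g, k] else 0
      rk <- R[, k] - st$fit[, k] + x * old
      u <- rk - cc * (R[, kk] - st$fit[, kk])
      stats <- .snvInclusionStats(prep$xtxSNV[g], sum(x * u), v, pr@tau2)
      p_inc <- 1 / (1 + exp(-(stats$logBF + lq)))
      if (runif(1L) < p_inc) {
        bnew <- rnorm(1L, stats$mean, sqrt(stats$var))
        st$gamma[g, k] <- 1L
        st$bsnv[g, k] <- bnew
        st$fit[, k] <- st$fit[, k] + x * (bnew - old)
      } else {
        st$gamma[g, k] <- 0L
        st$bsnv[g, k] <- 0
        if (old != 0) st$fit[, k] <- st$fit[, k] - x * old
      }
    }
  }
  st
}

.updateQ <- function(st, prep, pr, sharedQ = FALSE) {
  if (sharedQ) {
    s <- sum(st$gamma)
    par <- .qPosteriorParams(s, 2L * prep$G, pr@a, pr@b)
    st$q[] <- rbeta(1L, par[1L], par[2L])
  } else {
    for (k in 1:2) {
      s <- sum(st$gamma[, k])
      par <- .qPosteriorParams(s, prep$G, pr@a, pr@b)
      st$q[k] <- rbeta(1L, par[1L], par[2L])
    }
  }
  st
}

.updateFamilyEffects <- function(st, prep) {
  R <- prep$Y - st$fit - st$S[prep$subjIdx, , drop = FALSE]
  Rf <- rowsum(R, prep$famIdx)
  W <- .inv2(st$Se)
  Pinv <- .inv2(st$Sp)
  for (grp in seq_along(prep$famGroups)) {
    idx <- prep$famGroups[[grp]]
    m <- prep$famObs[idx[1L]]
    cov <- .inv2(Pinv + m * W)
    cov <- (cov + t(cov)) / 2
    M <- Rf[idx, , drop = FALSE] %*% t(cov %*% W)
    st$P[idx, ] <- M + matrix(rnorm(2L * length(idx)), length(idx), 2L) %*%
      chol(cov)
  }
  st
}

.updateSubjectEffects <- function(st, prep) {
  R <- prep$Y - st$fit - st$P[prep$famIdx, , drop = FALSE]
  Rs <- rowsum(R, prep$subjIdx)
  W <- .inv2(st$Se)
  Sinv <- .inv2(st$Ss)
  for (grp in seq_along(prep$subjGroups)) {
    idx <- prep$subjGroups[[grp]]
    m <- prep$subjM[idx[1L]]
    cov <- .inv2(Sinv + m * W)
    cov <- (cov + t(cov)) / 2
    M <- Rs[idx, , drop = FALSE] %*% t(cov %*% W)
    st$S[idx, ] <- M + matrix(rnorm(2L * length(idx)), length(idx), 2L) %*%
      chol(cov)
  }
  st
}

.updateCovariances <- function(st, prep, pr) {
  pp <- .iwPosteriorParams(pr@nu0, pr@S0, st$P)
  st$Sp <- .riw(pp$df, pp$scale)
  ps <- .iwPosteriorParams(pr@nu0, pr@S0, st$S)
  st$Ss <- .riw(ps$df, ps$scale)
  E <- prep$Y - st$fit - st$P[prep$famIdx, , drop = FALSE] -
    st$S[prep$subjIdx, , drop = FALSE]
  pe <- .iwPosteriorParams(pr@nu0, pr@S0, E)
  st$Se <- .riw(pe$df, pe$scale)
  st
}

## One fixed-scan sweep: regression -> indicators -> q -> family effects ->
## subject effects -> covariances (skipped when Sigma's are held fixed).
.sweep <- function(st, prep, pr, sharedQ = FALSE, updateSigma = TRUE) {
  st <- .updateRegression(st, prep, pr)
  st <- .updateIndicators(st, prep, pr)
  st <- .updateQ(st, prep, pr, sharedQ)
  st <- .updateFamilyEffects(st, prep)
  st <- .updateSubjectEffects(st, prep)
  if (updateSigma) st <- .updateCovariances(st, prep, pr)
  st
}
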