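## Chain-level machinery: initialization, the exported sweep, the chain
## runner (bivariate and univariate modes) and the unnormalized log joint
## used for testing.

#' Initialize the Gibbs chain state
#'
#' Regression coefficients start at the per-trait least-squares fit of the
#' fixed-effects-only model, all inclusion indicators at 0, q at its prior
#' mean a/(a+b), random effects at 0, and the covariance layers at diagonal
#' residual-based estimates (pooled within-subject variance for the residual
#' layer, the remainder split between family and subject).
#'
#' @param data a [ModelDataset-class].
#' @param priors a [PriorSpec-class] (b = NA is resolved to G).
#' @param seed integer seed.
#' @param standardize fit on standardized traits (the chain default); the
#'   exported state utilities default to the raw scale for transparency.
#' @return The state list (fields betaF, bsnv, gamma, q, P, S, Sp, Ss, Se,
#'   fit) with the prepared data attached as attribute "prep".
#' @export
initState <- function(data, priors, seed, standardize = FALSE) {
  prep <- .prepData(data, standardize)
  pr <- .resolvePriors(priors, prep$G)
  st <- .initStateInternal(prep, pr, seed)
  attr(st, "prep") <- prep
  attr(st, "priors") <- pr
  st
}

#' Run one fixed-scan Gibbs sweep
#'
#' Applies, in order: joint regression-coefficient update (both traits,
#' whitened by the residual covariance), each SNV-by-trait inclusion
#' indicator (slab coefficient integrated out analytically), the inclusion
#' probabilities q, family effects, subject effects, and the covariance
#' layers. Uses R's current RNG stream; seed with `set.seed()` for
#' reproducibility.
#'
#' @param state a state list from [initState()].
#' @param data the [ModelDataset-class] it was initialized on.
#' @param priors a [PriorSpec-class].
#' @param sharedQ pool the inclusion probability across traits.
#' @param updateSigma set FALSE to hold the covariance layers fixed.
#' @return The updated state (attributes preserved).
#' @export
gibbsSweep <- function(state, data, priors, sharedQ = FALSE,
                       updateSigma = TRUE) {
  prep <- attr(state, "prep")
  if (is.null(prep)) prep <- .prepData(data, FALSE)
  pr <- .resolvePriors(priors, prep$G)
  out <- .sweep(state, prep, pr, sharedQ, updateSigma)
  attr(out, "prep") <- prep
  attr(out, "priors") <- pr
  out
}

#' Unnormalized log joint density of the full hierarchy
#'
#' Sum of the bivariate Gaussian log-likelihood of the visit-level residuals
#' and the log priors of every latent quantity (coefficients, indicators,
#' q, random effects, covariance matrices). A testing aid: any valid Gibbs
#' move leaves this finite, and hand-computable on toy states.
#'
#' @param state a state list (see [initState()]).
#' @param data the matching [ModelDataset-class].
#' @param priors a [PriorSpec-class].
#' @return A finite numeric scalar.
#' @export
logJoint <- function(state, data, priors) {
  prep <- attr(state, "prep")
  if (is.null(prep)) prep <- .prepData(data, FALSE)
  pr <- .resolvePriors(priors, prep$G)
  st <- state
  for (S in list(st$Sp, st$Ss, st$Se))
    if (S[1, 2] != S[2, 1] || S[1, 1] <= 0 ||
        S[1, 2]^2 >= S[1, 1] * S[2, 2])
      stop("state covariance matrix is not symmetric positive definite")
  dmvn2 <- function(E, Sigma) {
    W <- .inv2(Sigma)
    ld <- determinant(Sigma, logarithm = TRUE)$modulus
    q <- rowSums((E %*% W) * E)
    as.numeric(-nrow(E) * log(2 * pi) - nrow(E) / 2 * ld - 0.5 * sum(q))
  }
  E <- prep$Y - st$fit - st$P[prep$famIdx, , drop = FALSE] -
    st$S[prep$subjIdx, , drop = FALSE]
  ll <- dmvn2(E, st$Se)
  lp <- sum(dnorm(st$betaF, 0, sqrt(pr@v0), log = TRUE))
  act <- st$gamma == 1L
  if (any(act)) lp <- lp + sum(dnorm(st$bsnv[act], 0, sqrt(pr@tau2),
                                     log = TRUE))
  for (k in 1:2) {
    s <- sum(st$gamma[, k])
    lp <- lp + s * log(st$q[k]) + (prep$G - s) * log1p(-st$q[k]) +
      dbeta(st$q[k], pr@a, pr@b, log = TRUE)
  }
  lp <- lp + dmvn2(st$P, st$Sp) + dmvn2(st$S, st$Ss)
  lp <- lp + .diwLog(st$Sp, pr@nu0, pr@S0) + .diwLog(st$Ss, pr@nu0, pr@S0) +
    .diwLog(st$Se, pr@nu0, pr@S0)
  ll + lp
}

#' Run the Gibbs chain
#'
#' Deterministic given the configuration seed. In univariate mode the two
#' traits are fitted by independent single-trait chains (one derived seed
#' per trait) and every stored covariance draw has exactly zero
#' off-diagonals. Stored coefficient draws are back-transformed to the raw
#' trait scale when the chain standardizes internally; SNV dosages are
#' always centered for fitting, so reported intercepts refer to the
#' centered-dosage design.
#'
#' @param data a [ModelDataset-class].
#' @param priors a [PriorSpec-class]; b = NA resolves to G.
#' @param cfg a [ChainConfig-class].
#' @return A [ChainSamples-class].
#' @export
runChain <- function(data, priors, cfg) {
  prep <- .prepData(data, cfg@standardize)
  pr <- .resolvePriors(priors, prep$G)
  if (cfg@mode == "univariate")
    return(.runChainUnivariate(data, prep, pr, cfg))

  nD <- (cfg@nIterations - cfg@burnIn) %/% cfg@thinning
  G <- prep$G; P <- prep$P
  gam <- array(0L, c(nD, G, 2L))
  bet <- array(0, c(nD, G, 2L))
  bfx <- array(0, c(nD, P, 2L))
  qd <- matrix(0, nD, 2L)
  SP <- array(0, c(nD, 2L, 2L)); SS <- SP; SE <- SP
  famE <- if (cfg@keepEffects) array(0, c(nD, prep$I, 2L)) else NULL
  subE <- if (cfg@keepEffects) array(0, c(nD, prep$N, 2L)) else NULL

  st <- .initStateInternal(prep, pr, cfg@seed)
  updateSigma <- is.null(cfg@fixedSigma)
  if (!updateSigma) {
    st$Sp <- as.matrix(cfg@fixedSigma$Sp)
    st$Ss <- as.matrix(cfg@fixedSigma$Ss)
    st$Se <- as.matrix(cfg@fixedSigma$Se)
  }
  d <- 0L
  for (it in seq_len(cfg@nIterations)) {
    st <- .sweep(st, prep, pr, cfg@sharedQ, updateSigma)
    if (it > cfg@burnIn && (it - cfg@burnIn) %% cfg@thinning == 0L) {
      d <- d + 1L
      gam[d, , ] <- st$gamma
      bet[d, , ] <- st$bsnv
      bfx[d, , ] <- st$betaF
      qd[d, ] <- st$q
      SP[d, , ] <- st$Sp; SS[d, , ] <- st$Ss; SE[d, , ] <- st$Se
      if (cfg@keepEffects) {
        famE[d, , ] <- st$P
        subE[d, , ] <- st$S
      }
    }
  }
  .makeChainSamples(gam, bet, bfx, qd, SP, SS, SE, famE, subE, prep, data,
                    cfg, pr)
}

.makeChainSamples <- function(gam, bet, bfx, qd, SP, SS, SE, famE, subE,
                              prep, data, cfg, pr) {
  scl <- prep$traitScale; ctr <- prep$traitCenter
  for (k in 1:2) {
    bet[, , k] <- bet[, , k] * scl[k]
    bfx[, , k] <- bfx[, , k] * scl[k]
    bfx[, 1L, k] <- bfx[, 1L, k] + ctr[k]
  }
  rescale <- function(A) {
    A[, 1L, 1L] <- A[, 1L, 1L] * scl[1L]^2
    A[, 2L, 2L] <- A[, 2L, 2L] * scl[2L]^2
    A[, 1L, 2L] <- A[, 1L, 2L] * scl[1L] * scl[2L]
    A[, 2L, 1L] <- A[, 1L, 2L]
    A
  }
  SP <- rescale(SP); SS <- rescale(SS); SE <- rescale(SE)
  if (!is.null(famE))
    for (k in 1:2) famE[, , k] <- famE[, , k] * scl[k]
  if (!is.null(subE))
    for (k in 1:2) subE[, , k] <- subE[, , k] * scl[k]
  new("ChainSamples", gamma = gam, beta = bet, betaFixed = bfx, q = qd,
      SigmaP = SP, SigmaS = SS, SigmaE = SE, famEffects = famE,
      subjEffects = subE, snvIDs = data@snvInfo$id,
      fixedNames = data@fixedNames, traitNames = data@traitNames,
      config = cfg, priors = pr)
}

## ---------------------------------------------------------------------------
## Univariate mode: two independent single-trait chains
## ---------------------------------------------------------------------------

.runChainUnivariate <- function(data, prep, pr, cfg) {
  nD <- (cfg@nIterations - cfg@burnIn) %/% cfg@thinning
  G <- prep$G; P <- prep$P
  gam <- array(0L, c(nD, G, 2L))
  bet <- array(0, c(nD, G, 2L))
  bfx <- array(0, c(nD, P, 2L))
  qd <- matrix(0, nD, 2L)
  SP <- array(0, c(nD, 2L, 2L)); SS <- SP; SE <- SP
  famE <- if (cfg@keepEffects) array(0, c(nD, prep$I, 2L)) else NULL
  subE <- if (cfg@keepEffects) array(0, c(nD, prep$N, 2L)) else NULL
  for (k in 1:2) {
    tr <- .runUniTrait(prep, pr, cfg, k, cfg@seed + 1000003L * k)
    gam[, , k] <- tr$gamma
    bet[, , k] <- tr$bsnv
    bfx[, , k] <- tr$betaF
    qd[, k] <- tr$q
    SP[, k, k] <- tr$sp2
    SS[, k, k] <- tr$ss2
    SE[, k, k] <- tr$se2
    if (cfg@keepEffects) {
      famE[, , k] <- tr$P
      subE[, , k] <- tr$S
    }
  }
  .makeChainSamples(gam, bet, bfx, qd, SP, SS, SE, famE, subE, prep, data,
                    cfg, pr)
}

## Single-trait spike-and-slab mixed-model Gibbs chain (scalar variances,
## inverse-gamma sigma^2 ~ IG(nu0/2, S0[k,k]/2) priors — the 1-D marginal of
## the inverse-Wishart layer).
.runUniTrait <- function(prep, pr, cfg, k, seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  y <- prep$Y[, k]
  X <- prep$X; Gc <- prep$Gc
  n <- prep$n; G <- prep$G; P <- prep$P
  ls <- lm.fit(X, y)
  if (ls$rank < P) stop("singular fixed-effect design")
  betaF <- ls$coefficients
  subj_mean <- rowsum(ls$residuals, prep$subjIdx) / prep$subjM
  df_within <- n - prep$N
  tot <- var(ls$residuals)
  se2 <- if (df_within > 0)
    sum((ls$residuals - subj_mean[prep$subjIdx])^2) / df_within else tot / 3
  sp2 <- max((tot - se2) / 2, 0.05 * tot)
  ss2 <- sp2
  bsnv <- numeric(G); gamma <- integer(G)
  q <- pr@a / (pr@a + pr@b)
  Pv <- numeric(prep$I); Sv <- numeric(prep$N)
  fit <- as.numeric(X %*% betaF)
  fixedSigma <- !is.null(cfg@fixedSigma)
  if (fixedSigma) {
    sp2 <- cfg@fixedSigma$Sp[k, k]
    ss2 <- cfg@fixedSigma$Ss[k, k]
    se2 <- cfg@fixedSigma$Se[k, k]
  }
  s0kk <- pr@S0[k, k]

  nD <- (cfg@nIterations - cfg@burnIn) %/% cfg@thinning
  out <- list(gamma = matrix(0L, nD, G), bsnv = matrix(0, nD, G),
              betaF = matrix(0, nD, P), q = numeric(nD), sp2 = numeric(nD),
              ss2 = numeric(nD), se2 = numeric(nD),
              P = if (cfg@keepEffects) matrix(0, nD, prep$I) else NULL,
              S = if (cfg@keepEffects) matrix(0, nD, prep$N) else NULL)
  d <- 0L
  for (it in seq_len(cfg@nIterations)) {
    ## regression coefficients (active set jointly)
    act <- which(gamma == 1L)
    A <- cbind(X, Gc[, act, drop = FALSE])
    dprior <- c(rep(1 / pr@v0, P), rep(1 / pr@tau2, length(act)))
    r <- y - Pv[prep$famIdx] - Sv[prep$subjIdx]
    Lam <- crossprod(A) / se2 + diag(dprior, ncol(A))
    b <- crossprod(A, r) / se2
    ch <- .spdChol(Lam)
    mean_ <- backsolve(ch, forwardsolve(t(ch), b))
    draw <- mean_ + backsolve(ch, rnorm(ncol(A)))
    betaF <- draw[seq_len(P)]
    bsnv[] <- 0
    if (length(act)) bsnv[act] <- draw[P + seq_along(act)]
    fit <- as.numeric(A %*% draw)
    ## indicators
    lq <- log(q) - log1p(-q)
    for (g in seq_len(G)) {
      x <- Gc[, g]
      old <- bsnv[g]
      u <- r - fit + x * old
      stats <- .snvInclusionStats(prep$xtxSNV[g], sum(x * u), se2, pr@tau2)
      p_inc <- 1 / (1 + exp(-(stats$logBF + lq)))
      if (runif(1L) < p_inc) {
        bnew <- rnorm(1L, stats$mean, sqrt(stats$var))
        gamma[g] <- 1L
        fit <- fit + x * (bnew - old)
        bsnv[g] <- bnew
      } else {
        gamma[g] <- 0L
        if (old != 0) fit <- fit - x * old
        bsnv[g] <- 0
      }
    }
    ## q
    par <- .qPosteriorParams(sum(gamma), G, pr@a, pr@b)
    q <- rbeta(1L, par[1L], par[2L])
    ## family effects
    R1 <- y - fit - Sv[prep$subjIdx]
    Rf <- rowsum(R1, prep$famIdx)[, 1L]
    vf <- 1 / (1 / sp2 + prep$famObs / se2)
    Pv <- rnorm(prep$I, vf * Rf / se2, sqrt(vf))
    ## subject effects
    R2 <- y - fit - Pv[prep$famIdx]
    Rs <- rowsum(R2, prep$subjIdx)[, 1L]
    vs <- 1 / (1 / ss2 + prep$subjM / se2)
    Sv <- rnorm(prep$N, vs * Rs / se2, sqrt(vs))
    ## variances
    if (!fixedSigma) {
      sp2 <- 1 / rgamma(1L, (pr@nu0 + prep$I) / 2,
                        rate = (s0kk + sum(Pv^2)) / 2)
      ss2 <- 1 / rgamma(1L, (pr@nu0 + prep$N) / 2,
                        rate = (s0kk + sum(Sv^2)) / 2)
      e <- y - fit - Pv[prep$famIdx] - Sv[prep$subjIdx]
      se2 <- 1 / rgamma(1L, (pr@nu0 + n) / 2, rate = (s0kk + sum(e^2)) / 2)
    }
    if (it > cfg@burnIn && (it - cfg@burnIn) %% cfg@thinning == 0L) {
      d <- d + 1L
      out$gamma[d, ] <- gamma
      out$bsnv[d, ] <- bsnv
      out$betaF[d, ] <- betaF
      out$q[d] <- q
      out$sp2[d] <- sp2; out$ss2[d] <- ss2; out$se2[d] <- se2
      if (cfg@keepEffects) {
        out$P[d, ] <- Pv
        out$S[d, ] <- Sv
      }
    }
  }
  out
}
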