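## Sampler-validation machinery: exact posterior inclusion probabilities by
## joint model enumeration (small G, covariance layers fixed), and the
## joint-distribution ("getting it right") test comparing prior-predictive
## draws against Gibbs-with-data-resimulation draws.

#' Exact posterior inclusion probabilities by model enumeration
#'
#' With the family, subject and residual covariance layers held fixed, every
#' latent Gaussian quantity can be integrated in closed form: for each joint
#' model (one inclusion vector per trait) the marginal likelihood is a
#' 2n-dimensional Gaussian whose covariance stacks the three layers plus the
#' prior covariance of the integrated coefficients. Enumerating all
#' 2^G x 2^G joint models with Beta-Bernoulli model weights gives exact
#' PIPs, independent of any MCMC. Practical only for small G (<= 6 or so).
#'
#' @param data a [ModelDataset-class].
#' @param priors a [PriorSpec-class] (b = NA resolves to G).
#' @param Sp,Ss,Se fixed 2x2 covariance matrices of the three layers.
#' @return G x 2 matrix of exact PIPs (rows named by SNV id).
#' @export
exactInclusionProbabilities <- function(data, priors, Sp, Ss, Se) {
  prep <- .prepData(data, standardize = FALSE)
  pr <- .resolvePriors(priors, prep$G)
  G <- prep$G; n <- prep$n
  if (G > 8L) stop("enumeration over 4^G models is impractical for G > 8")

  famM <- outer(prep$famIdx, prep$famIdx, "==") * 1
  subM <- outer(prep$subjIdx, prep$subjIdx, "==") * 1
  V0 <- kronecker(Sp, famM) + kronecker(Ss, subM) + kronecker(Se, diag(n))
  yv <- c(prep$Y[, 1L], prep$Y[, 2L])

  models <- as.matrix(expand.grid(rep(list(0:1), G)))
  lw_model <- function(nInc)            # Beta-Bernoulli marginal log weight
    lbeta(pr@a + nInc, pr@b + G - nInc) - lbeta(pr@a, pr@b)

  nM <- nrow(models)
  ll <- matrix(NA_real_, nM, nM)        # [model1, model2]
  for (m1 in seq_len(nM)) {
    act1 <- which(models[m1, ] == 1L)
    X1 <- cbind(prep$X, prep$Gc[, act1, drop = FALSE])
    d1 <- c(rep(pr@v0, prep$P), rep(pr@tau2, length(act1)))
    for (m2 in seq_len(nM)) {
      act2 <- which(models[m2, ] == 1L)
      X2 <- cbind(prep$X, prep$Gc[, act2, drop = FALSE])
      d2 <- c(rep(pr@v0, prep$P), rep(pr@tau2, length(act2)))
      XJ <- rbind(cbind(X1, matrix(0, n, ncol(X2))),
                  cbind(matrix(0, n, ncol(X1)), X2))
      V <- V0 + XJ %*% (c(d1, d2) * t(XJ))
      ch <- chol((V + t(V)) / 2)
      z <- forwardsolve(t(ch), yv)
      ll[m1, m2] <- -n * log(2 * pi) - sum(log(diag(ch))) -
        0.5 * sum(z^2)
    }
  }
  n1 <- rowSums(models)
  lpost <- ll + outer(lw_model(n1), lw_model(n1), "+")
  lpost <- lpost - max(lpost)
  w <- exp(lpost)
  w <- w / sum(w)
  pip <- matrix(0, G, 2L, dimnames = list(data@snvInfo$id, NULL))
  for (g in seq_len(G)) {
    inc <- models[, g] == 1L
    pip[g, 1L] <- sum(w[inc, ])
    pip[g, 2L] <- sum(w[, inc])
  }
  pip
}

#' Joint-distribution (Geweke) test of the Gibbs sampler
#'
#' Compares two simulators of the joint distribution of (parameters, data):
#' the marginal-conditional simulator (independent draws from the prior,
#' data simulated once from each) and the successive-conditional simulator
#' (alternate data re-simulation and one Gibbs sweep). If every full
#' conditional is correct the two agree; a z-score far outside +/-4 on any
#' monitored functional exposes a bug. Priors must be proper and mildly
#' informative for the test to have power.
#'
#' @param data a small [ModelDataset-class] supplying the design (its trait
#'   values are ignored and re-simulated).
#' @param priors a proper [PriorSpec-class].
#' @param nDraws draws per arm.
#' @param seed integer seed.
#' @return data.frame with one row per monitored functional: means under
#'   both arms, the autocorrelation-adjusted standard error, and z.
#' @export
gewekeJointTest <- function(data, priors, nDraws = 20000L, seed = 1L) {
  prep <- .prepData(data, standardize = FALSE)
  pr <- .resolvePriors(priors, prep$G)
  set.seed(as.integer(seed))

  priorDraw <- function() {
    Sp <- .riw(pr@nu0, pr@S0); Ss <- .riw(pr@nu0, pr@S0)
    Se <- .riw(pr@nu0, pr@S0)
    q <- rbeta(2L, pr@a, pr@b)
    gamma <- matrix(rbinom(2L * prep$G, 1L, rep(q, each = prep$G)),
                    prep$G, 2L)
    bsnv <- matrix(rnorm(2L * prep$G, 0, sqrt(pr@tau2)), prep$G, 2L) * gamma
    betaF <- matrix(rnorm(2L * prep$P, 0, sqrt(pr@v0)), prep$P, 2L)
    P <- matrix(rnorm(2L * prep$I), prep$I, 2L) %*% chol(Sp)
    S <- matrix(rnorm(2L * prep$N), prep$N, 2L) %*% chol(Ss)
    st <- list(betaF = betaF, bsnv = bsnv, gamma = gamma, q = q, P = P,
               S = S, Sp = Sp, Ss = Ss, Se = Se,
               fit = prep$X %*% betaF + prep$Gc %*% (gamma * bsnv))
    st
  }
  simData <- function(st) {
    E <- matrix(rnorm(2L * prep$n), prep$n, 2L) %*% chol(st$Se)
    st$fit + st$P[prep$famIdx, , drop = FALSE] +
      st$S[prep$subjIdx, , drop = FALSE] + E
  }
  fun <- function(st) {
    c(beta0_1 = st$betaF[1L, 1L], beta0_2 = st$betaF[1L, 2L],
      q1 = st$q[1L], q2 = st$q[2L],
      gb_11 = st$gamma[1L, 1L] * st$bsnv[1L, 1L],
      gb_22 = st$gamma[min(2L, prep$G), 2L] *
        st$bsnv[min(2L, prep$G), 2L],
      Sp11 = st$Sp[1, 1], Sp12 = st$Sp[1, 2], Sp22 = st$Sp[2, 2],
      Ss11 = st$Ss[1, 1], Ss22 = st$Ss[2, 2],
      Se11 = st$Se[1, 1], Se12 = st$Se[1, 2], Se22 = st$Se[2, 2],
      p_11 = st$P[1L, 1L], s_12 = st$S[1L, 2L])
  }

  nf <- length(fun(priorDraw()))
  mc <- matrix(0, nDraws, nf)
  for (i in seq_len(nDraws)) {
    st <- priorDraw()
    mc[i, ] <- fun(st)
  }
  sc <- matrix(0, nDraws, nf)
  st <- priorDraw()
  for (i in seq_len(nDraws)) {
    prep$Y <- simData(st)
    st <- .sweep(st, prep, pr, sharedQ = FALSE, updateSigma = TRUE)
    sc[i, ] <- fun(st)
  }
  nm <- names(fun(st))
  se_mc <- apply(mc, 2L, sd) / sqrt(nDraws)
  se_sc <- apply(sc, 2L, .batchSE)
  z <- (colMeans(mc) - colMeans(sc)) / sqrt(se_mc^2 + se_sc^2)
  data.frame(functional = nm, meanPrior = colMeans(mc),
             meanGibbs = colMeans(sc), se = sqrt(se_mc^2 + se_sc^2), z = z,
             row.names = NULL)
}

## Batch-means Monte Carlo standard error (non-overlapping batches).
.batchSE <- function(x, nBatches = 20L) {
  n <- length(x)
  nb <- min(nBatches, n)
  bm <- tapply(x, ceiling(seq_along(x) / (n / nb)), mean)
  sd(bm) / sqrt(length(bm))
}
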