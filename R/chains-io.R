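## Chain draw persistence: a versioned JSON representation of ChainSamples
## so fits can be written by one process and summarized by another.

#' Write chain draws to a JSON file
#'
#' @param samples a [ChainSamples-class].
#' @param path output path (.json).
#' @return `path`, invisibly.
#' @export
writeChains <- function(samples, path) {
  cfg <- samples@config
  pr <- samples@priors
  obj <- list(
    format = "pedsur-chains", version = 1L,
    snvIDs = samples@snvIDs, fixedNames = samples@fixedNames,
    traitNames = samples@traitNames,
    config = list(nIterations = cfg@nIterations, burnIn = cfg@burnIn,
                  thinning = cfg@thinning, seed = cfg@seed, mode = cfg@mode,
                  standardize = cfg@standardize, sharedQ = cfg@sharedQ),
    priors = list(a = pr@a, b = pr@b, tau2 = pr@tau2, v0 = pr@v0,
                  nu0 = pr@nu0, S0 = pr@S0),
    gamma = samples@gamma, beta = samples@beta,
    betaFixed = samples@betaFixed, q = samples@q,
    SigmaP = samples@SigmaP, SigmaS = samples@SigmaS,
    SigmaE = samples@SigmaE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read chain draws written by [writeChains()]
#'
#' @param path path to the JSON file.
#' @return A [ChainSamples-class].
#' @export
readChains <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "pedsur-chains"))
    stop(path, " is not a pedsur chain file")
  cfgl <- obj$config
  cfg <- chainConfig(nIterations = cfgl$nIterations, burnIn = cfgl$burnIn,
                     thinning = cfgl$thinning, seed = cfgl$seed,
                     mode = cfgl$mode, standardize = cfgl$standardize,
                     sharedQ = cfgl$sharedQ)
  prl <- obj$priors
  pr <- priorSpec(a = prl$a, b = prl$b, tau2 = prl$tau2, v0 = prl$v0,
                  nu0 = prl$nu0, S0 = matrix(unlist(prl$S0), 2L, 2L))
  arr <- function(x) array(as.numeric(x), dim(x))
  gam <- array(as.integer(obj$gamma), dim(obj$gamma))
  new("ChainSamples", gamma = gam, beta = arr(obj$beta),
      betaFixed = arr(obj$betaFixed), q = as.matrix(obj$q),
      SigmaP = arr(obj$SigmaP), SigmaS = arr(obj$SigmaS),
      SigmaE = arr(obj$SigmaE), famEffects = NULL, subjEffects = NULL,
      snvIDs = as.character(obj$snvIDs),
      fixedNames = as.character(obj$fixedNames),
      traitNames = as.character(obj$traitNames), config = cfg, priors = pr)
}
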