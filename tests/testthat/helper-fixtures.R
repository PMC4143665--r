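# Small in-code fixtures shared across test files.

# a single trio family: two founders and their child
trioPedigree <- function() {
  PedigreeSet(data.frame(
    fid = "F1", iid = c("dad", "mom", "kid"),
    father = c(NA, NA, "dad"), mother = c(NA, NA, "mom"),
    sex = c(1, 2, 1), stringsAsFactors = FALSE))
}

# unrelated-singleton "pedigree": nFam families x nSub founder subjects
flatPedigree <- function(nFam, nSub) {
  PedigreeSet(data.frame(
    fid = rep(sprintf("F%02d", seq_len(nFam)), each = nSub),
    iid = rep(sprintf("i%02d", seq_len(nSub)), nFam),
    father = NA, mother = NA, sex = 1L, stringsAsFactors = FALSE))
}

# a complete micro model dataset built from the generative model itself:
# nFam families x nSub subjects x nVis visits, G SNVs at common MAFs
microDataset <- function(seed = 1, nFam = 2, nSub = 3, nVis = 2, G = 2,
                         beta = NULL, covariate = TRUE,
                         Sp = diag(0.5, 2), Ss = diag(0.5, 2),
                         Se = diag(1, 2), intercepts = c(0, 0)) {
  set.seed(seed)
  ped <- flatPedigree(nFam, nSub)
  n <- nFam * nSub
  dos <- matrix(rbinom(n * G, 2, 0.35), n, G,
                dimnames = list(NULL, sprintf("g%d", seq_len(G))))
  while (any(apply(dos, 2, var) == 0))
    dos <- matrix(rbinom(n * G, 2, 0.35), n, G, dimnames = dimnames(dos))
  geno <- GenotypeMatrix(dos, pedTable(ped)[, c("fid", "iid")])
  if (is.null(beta)) beta <- matrix(0, G, 2)
  P <- matrix(rnorm(2 * nFam), nFam, 2) %*% chol(Sp)
  S <- matrix(rnorm(2 * n), n, 2) %*% chol(Ss)
  fidx <- rep(seq_len(nFam), each = nSub)
  gfx <- dos %*% beta
  x <- rnorm(n)
  rows <- lapply(seq_len(nVis), function(t) {
    E <- matrix(rnorm(2 * n), n, 2) %*% chol(Se)
    data.frame(fid = pedTable(ped)$fid, iid = pedTable(ped)$iid, visit = t,
               y1 = intercepts[1] + gfx[, 1] + P[fidx, 1] + S[, 1] + E[, 1],
               y2 = intercepts[2] + gfx[, 2] + P[fidx, 2] + S[, 2] + E[, 2],
               x = x, stringsAsFactors = FALSE)
  })
  pheno <- PhenotypeTable(do.call(rbind, rows))
  assembleDataset(ped, pheno, geno,
                  covariatesX = if (covariate) "x" else character(0))
}

# proper, mildly informative priors for sampler-validation runs
properPriors <- function() {
  priorSpec(a = 2, b = 2, tau2 = 1, v0 = 1, nu0 = 6, S0 = diag(2))
}
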