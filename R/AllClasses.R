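#' @include pedsur-package.R
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("listOrNULL", c("list", "NULL"))

## ---------------------------------------------------------------------------
## PedigreeSet
## ---------------------------------------------------------------------------

#' Pedigree structure for a set of families
#'
#' Holds one row per individual with family id, individual id, parental ids
#' (NA for founders) and sex (1 = male, 2 = female, NA = unknown). The
#' `founder` column is derived: an individual is a founder iff both parents
#' are missing. Individual ids must be unique within a family, every
#' non-missing parent must resolve within the same family, and the parent
#' graph must be acyclic with at least one founder per family.
#'
#' @slot ped data.frame with columns fid, iid, father, mother, sex, founder.
#' @seealso [readPedigree()], [simulatePedigreeStructure()]
#' @export
setClass("PedigreeSet", representation(ped = "data.frame"))

.validPedigree <- function(object) {
  ped <- object@ped
  need <- c("fid", "iid", "father", "mother", "sex", "founder")
  if (!all(need %in% names(ped)))
    return(sprintf("pedigree table must have columns %s",
                   paste(need, collapse = ", ")))
  msgs <- character(0)
  for (f in unique(ped$fid)) {
    fam <- ped[ped$fid == f, , drop = FALSE]
    dup <- fam$iid[duplicated(fam$iid)]
    if (length(dup))
      msgs <- c(msgs, sprintf("duplicate individual id '%s' in family '%s'",
                              dup[1L], f))
    for (col in c("father", "mother")) {
      bad <- setdiff(fam[[col]][!is.na(fam[[col]])], fam$iid)
      if (length(bad))
        msgs <- c(msgs, sprintf("%s id '%s' in family '%s' does not resolve",
                                col, bad[1L], f))
    }
    if (length(msgs)) next
    if (!any(is.na(fam$father) & is.na(fam$mother)))
      msgs <- c(msgs, sprintf("family '%s' has no founder", f))
    cyc <- .pedigreeCycle(fam)
    if (!is.null(cyc))
      msgs <- c(msgs, sprintf(
        "pedigree cycle detected in family '%s' involving individual '%s'",
        f, cyc))
  }
  exp <- is.na(ped$father) & is.na(ped$mother)
  if (!length(msgs) && !identical(as.logical(ped$founder), as.logical(exp)))
    msgs <- c(msgs, "founder flag inconsistent with missing-parent status")
  if (length(msgs)) msgs else TRUE
}

## Kahn-style peel: if some individuals can never be removed as "parentless",
## the parent graph has a cycle; returns an offending iid or NULL.
.pedigreeCycle <- function(fam) {
  remaining <- fam$iid
  parents <- fam[, c("father", "mother")]
  repeat {
    has_par <- (!is.na(parents$father) & parents$father %in% remaining) |
      (!is.na(parents$mother) & parents$mother %in% remaining)
    removable <- remaining[!has_par[match(remaining, fam$iid)]]
    if (!length(removable)) return(remaining[1L])
    remaining <- setdiff(remaining, removable)
    if (!length(remaining)) return(NULL)
  }
}

setValidity("PedigreeSet", .validPedigree)

#' Construct a PedigreeSet from a data.frame
#'
#' @param ped data.frame with columns fid, iid, father, mother, sex
#'   (parental NA or "0" means founder).
#' @return A [PedigreeSet-class] object.
#' @export
PedigreeSet <- function(ped) {
  for (col in c("fid", "iid", "father", "mother"))
    ped[[col]] <- as.character(ped[[col]])
  ped$father[ped$father %in% "0"] <- NA_character_
  ped$mother[ped$mother %in% "0"] <- NA_character_
  ped$sex <- suppressWarnings(as.integer(ped$sex))
  ped$sex[!ped$sex %in% c(1L, 2L)] <- NA_integer_
  ped$founder <- is.na(ped$father) & is.na(ped$mother)
  rownames(ped) <- NULL
  new("PedigreeSet", ped = ped)
}

#' @describeIn PedigreeSet-class number of families
#' @param x,object a PedigreeSet
#' @export
nFamilies <- function(x) length(unique(x@ped$fid))

#' @describeIn PedigreeSet-class number of individuals
#' @export
nIndividuals <- function(x) nrow(x@ped)

#' @describeIn PedigreeSet-class underlying data.frame
#' @export
pedTable <- function(x) x@ped

setMethod("show", "PedigreeSet", function(object) {
  p <- object@ped
  sizes <- table(p$fid)
  cat(sprintf("PedigreeSet: %d individuals in %d families\n",
              nrow(p), length(sizes)))
  cat(sprintf("  family size: mean %.1f, range %d-%d; %d founders\n",
              mean(sizes), min(sizes), max(sizes), sum(p$founder)))
})

## ---------------------------------------------------------------------------
## PhenotypeTable
## ---------------------------------------------------------------------------

#' Long-format longitudinal bivariate phenotypes
#'
#' One row per (individual, visit). Canonical columns: fid, iid, visit,
#' y1, y2, optionally htn and med flags, plus any covariate columns. The two
#' traits are assumed measured at the same visits: a row must carry both
#' trait values or neither.
#'
#' @slot pheno data.frame in canonical long format.
#' @slot traitNames original names of the two trait columns.
#' @export
setClass("PhenotypeTable",
         representation(pheno = "data.frame", traitNames = "character"))

setValidity("PhenotypeTable", function(object) {
  ph <- object@pheno
  need <- c("fid", "iid", "visit", "y1", "y2")
  if (!all(need %in% names(ph)))
    return(sprintf("phenotype table must have columns %s",
                   paste(need, collapse = ", ")))
  key <- paste(ph$fid, ph$iid, ph$visit, sep = "\r")
  if (anyDuplicated(key))
    return(sprintf("duplicated (individual, visit) pair: %s",
                   gsub("\r", "/", key[duplicated(key)][1L])))
  half <- xor(is.na(ph$y1), is.na(ph$y2))
  if (any(half))
    return(paste0("one trait observed and the other missing at a visit ",
                  "(individual ", ph$iid[half][1L], ", visit ",
                  ph$visit[half][1L], "): the model assumes both traits ",
                  "are measured at the same set of time points"))
  if (length(object@traitNames) != 2L)
    return("traitNames must have length 2")
  TRUE
})

#' Construct a PhenotypeTable
#'
#' @param pheno data.frame with canonical columns (see
#'   [PhenotypeTable-class]).
#' @param traitNames length-2 character, display names of the traits.
#' @return A [PhenotypeTable-class] object, rows sorted by
#'   (family, individual, visit).
#' @export
PhenotypeTable <- function(pheno, traitNames = c("trait1", "trait2")) {
  for (col in c("fid", "iid")) pheno[[col]] <- as.character(pheno[[col]])
  pheno$visit <- as.integer(pheno$visit)
  pheno <- pheno[order(pheno$fid, pheno$iid, pheno$visit), , drop = FALSE]
  rownames(pheno) <- NULL
  new("PhenotypeTable", pheno = pheno, traitNames = as.character(traitNames))
}

#' @describeIn PhenotypeTable-class underlying data.frame
#' @param x,object a PhenotypeTable
#' @export
phenoTable <- function(x) x@pheno

#' @describeIn PhenotypeTable-class visit counts m_ij per subject
#' @export
visitCounts <- function(x) {
  ph <- x@pheno
  cnt <- table(paste(ph$fid, ph$iid, sep = "\r"))
  setNames(as.integer(cnt), gsub("\r", "/", names(cnt)))
}

setMethod("show", "PhenotypeTable", function(object) {
  ph <- object@pheno
  m <- visitCounts(object)
  cat(sprintf(
    "PhenotypeTable: %d observations on %d subjects (visits/subject %d-%d)\n",
    nrow(ph), length(m), min(m), max(m)))
  cat(sprintf("  traits: %s, %s; covariates: %s\n",
              object@traitNames[1L], object@traitNames[2L],
              paste(setdiff(names(ph),
                            c("fid", "iid", "visit", "y1", "y2")),
                    collapse = ", ")))
})

## ---------------------------------------------------------------------------
## GenotypeMatrix
## ---------------------------------------------------------------------------

#' Subject-by-SNV minor-allele dosage matrix
#'
#' Dosages are 0, 1, 2 (number of minor alleles) or NA. Row order matches
#' the `samples` table (fid, iid); columns are named by SNV id.
#'
#' @slot dosage numeric matrix, subjects x SNVs, entries in \{0, 1, 2, NA\}.
#' @slot samples data.frame with columns fid, iid, one row per matrix row.
#' @slot snvInfo data.frame with columns id, pos (and optionally ref, alt).
#' @export
setClass("GenotypeMatrix",
         representation(dosage = "matrix", samples = "data.frame",
                        snvInfo = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosage
  if (nrow(object@samples) != nrow(d))
    return("samples table and dosage matrix disagree on subject count")
  if (nrow(object@snvInfo) != ncol(d))
    return("snvInfo and dosage matrix disagree on SNV count")
  if (anyDuplicated(object@snvInfo$id))
    return(sprintf("duplicate SNV id '%s'",
                   object@snvInfo$id[duplicated(object@snvInfo$id)][1L]))
  bad <- d[!is.na(d) & !(d %in% c(0, 1, 2))]
  if (length(bad))
    return(sprintf("dosage value %s outside {0, 1, 2}", format(bad[1L])))
  TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosage numeric matrix (subjects x SNVs), entries 0/1/2/NA.
#' @param samples data.frame with columns fid, iid.
#' @param snvInfo data.frame with column id (and optionally pos, ref, alt);
#'   defaults to the matrix column names.
#' @return A [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(dosage, samples, snvInfo = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(snvInfo))
    snvInfo <- data.frame(id = colnames(dosage), pos = seq_len(ncol(dosage)))
  snvInfo$id <- as.character(snvInfo$id)
  colnames(dosage) <- snvInfo$id
  samples$fid <- as.character(samples$fid)
  samples$iid <- as.character(samples$iid)
  rownames(samples) <- NULL
  rownames(snvInfo) <- NULL
  new("GenotypeMatrix", dosage = dosage, samples = samples, snvInfo = snvInfo)
}

#' @describeIn GenotypeMatrix-class the dosage matrix
#' @param x,object a GenotypeMatrix
#' @export
dosages <- function(x) x@dosage

#' @describeIn GenotypeMatrix-class SNV metadata table
#' @export
snvInfo <- function(x) x@snvInfo

#' @describeIn GenotypeMatrix-class sample (fid, iid) table
#' @export
sampleInfo <- function(x) x@samples

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d subjects x %d SNVs (%d missing calls)\n",
              nrow(object@dosage), ncol(object@dosage),
              sum(is.na(object@dosage))))
})

## ---------------------------------------------------------------------------
## ModelDataset
## ---------------------------------------------------------------------------

#' Index-aligned dataset ready for model fitting
#'
#' Produced by [assembleDataset()]. Observation rows (one per subject-visit)
#' are shared by both traits; `famIdx`/`subjIdx` map each row to its family
#' and subject, `subjFam` maps subjects to families, and the design is split
#' into fixed-covariate columns `X` (intercept, time-invariant, time-varying)
#' and raw SNV dosage columns `G` (centering happens inside the sampler).
#'
#' @slot Y numeric matrix n x 2 of trait values.
#' @slot X numeric matrix n x P of fixed covariates (first column intercept).
#' @slot G numeric matrix n x G of SNV dosages.
#' @slot famIdx,subjIdx integer vectors of length n (1-based indices).
#' @slot subjFam integer vector, family index of each subject.
#' @slot obsKey data.frame (fid, iid, visit) for each row.
#' @slot snvInfo data.frame of retained SNVs (id, pos, maf).
#' @slot traitNames,fixedNames character metadata.
#' @export
setClass("ModelDataset",
         representation(Y = "matrix", X = "matrix", G = "matrix",
                        famIdx = "integer", subjIdx = "integer",
                        subjFam = "integer", obsKey = "data.frame",
                        snvInfo = "data.frame", traitNames = "character",
                        fixedNames = "character"))

setValidity("ModelDataset", function(object) {
  n <- nrow(object@Y)
  if (ncol(object@Y) != 2L) return("Y must have exactly 2 trait columns")
  if (nrow(object@X) != n || nrow(object@G) != n ||
      length(object@famIdx) != n || length(object@subjIdx) != n ||
      nrow(object@obsKey) != n)
    return("observation-level components are not row-aligned")
  if (anyNA(object@Y) || anyNA(object@X) || anyNA(object@G))
    return("model dataset must be complete (no missing values)")
  if (length(object@subjFam) != max(object@subjIdx))
    return("subjFam length must equal the number of subjects")
  if (nrow(object@snvInfo) != ncol(object@G))
    return("snvInfo must describe every SNV column")
  TRUE
})

#' @describeIn ModelDataset-class number of observation rows
#' @param x,object a ModelDataset
#' @export
nObs <- function(x) nrow(x@Y)

#' @describeIn ModelDataset-class number of SNV columns
#' @export
nSNVs <- function(x) ncol(x@G)

setMethod("show", "ModelDataset", function(object) {
  cat(sprintf(
    "ModelDataset: %d observations, %d subjects, %d families, G = %d SNVs\n",
    nrow(object@Y), max(object@subjIdx), max(object@famIdx), ncol(object@G)))
  cat(sprintf("  traits: %s; fixed effects: %s\n",
              paste(object@traitNames, collapse = ", "),
              paste(object@fixedNames, collapse = ", ")))
})

## ---------------------------------------------------------------------------
## PriorSpec / ChainConfig
## ---------------------------------------------------------------------------

#' Prior hyperparameters for the bivariate model
#'
#' @slot a,b Beta hyperparameters of the inclusion probability q. The default
#'   b = NA is resolved to G (the number of candidate SNVs) at fit time,
#'   giving marginal prior inclusion odds of 1/G.
#' @slot tau2 slab variance of an included SNV coefficient (on the fitting
#'   scale; traits are standardized internally by default).
#' @slot v0 prior variance of intercept/covariate coefficients.
#' @slot nu0 inverse-Wishart degrees of freedom (>= 3 for a finite mean).
#' @slot S0 inverse-Wishart 2x2 scale matrix, shared by the family, subject
#'   and residual covariance priors.
#' @export
setClass("PriorSpec",
         representation(a = "numeric", b = "numeric", tau2 = "numeric",
                        v0 = "numeric", nu0 = "numeric", S0 = "matrix"))

setValidity("PriorSpec", function(object) {
  if (object@a <= 0 || (!is.na(object@b) && object@b <= 0))
    return("Beta hyperparameters a, b must be positive")
  if (object@tau2 <= 0) return("slab variance tau2 must be positive")
  if (object@v0 <= 0) return("fixed-effect prior variance v0 must be positive")
  if (object@nu0 <= 1) return("inverse-Wishart df nu0 must exceed dim - 1 = 1")
  S0 <- object@S0
  if (!isTRUE(all.equal(S0, t(S0))) || any(eigen(S0, TRUE)$values <= 0))
    return("S0 must be symmetric positive definite")
  TRUE
})

#' @param a,b,tau2,v0,nu0,S0 see [PriorSpec-class].
#' @describeIn PriorSpec-class constructor with the package defaults.
#' @export
priorSpec <- function(a = 1, b = NA_real_, tau2 = 100, v0 = 1e4, nu0 = 3,
                      S0 = diag(0.01, 2)) {
  new("PriorSpec", a = a, b = b, tau2 = tau2, v0 = v0, nu0 = nu0,
      S0 = as.matrix(S0))
}

setMethod("show", "PriorSpec", function(object) {
  cat(sprintf(
    "PriorSpec: gamma ~ Bern(q), q ~ Beta(%g, %s); slab tau2 = %g, v0 = %g\n",
    object@a, if (is.na(object@b)) "G" else format(object@b), object@tau2,
    object@v0))
  cat(sprintf("  Sigma priors: IW(nu0 = %g, S0 = [%g, %g; %g, %g])\n",
              object@nu0, object@S0[1, 1], object@S0[1, 2], object@S0[2, 1],
              object@S0[2, 2]))
})

#' MCMC schedule and mode
#'
#' @slot nIterations total Gibbs sweeps.
#' @slot burnIn sweeps discarded before storage.
#' @slot thinning store every thinning-th post-burn-in sweep.
#' @slot seed integer seed for the chain's RNG stream.
#' @slot mode "bivariate" or "univariate" (off-diagonals of all covariance
#'   layers forced to zero; traits modeled independently).
#' @slot standardize standardize traits to mean 0 / SD 1 for fitting
#'   (coefficients are reported back on the raw trait scale).
#' @slot sharedQ single inclusion probability pooled across traits rather
#'   than one q per trait.
#' @slot fixedSigma optional list(Sp, Ss, Se) of covariance matrices held
#'   fixed (covariance updates disabled); NULL for the full sampler.
#' @slot keepEffects store family/subject random-effect draws.
#' @export
setClass("ChainConfig",
         representation(nIterations = "integer", burnIn = "integer",
                        thinning = "integer", seed = "integer",
                        mode = "character", standardize = "logical",
                        sharedQ = "logical", fixedSigma = "listOrNULL",
                        keepEffects = "logical"))

setValidity("ChainConfig", function(object) {
  if (object@burnIn >= object@nIterations)
    return("burnIn must be smaller than nIterations")
  if (object@thinning < 1L) return("thinning must be >= 1")
  if (!object@mode %in% c("bivariate", "univariate"))
    return("mode must be 'bivariate' or 'univariate'")
  if (!is.null(object@fixedSigma) &&
      !all(c("Sp", "Ss", "Se") %in% names(object@fixedSigma)))
    return("fixedSigma must be a list with elements Sp, Ss, Se")
  TRUE
})

#' @param nIterations,burnIn,thinning,seed,mode,standardize,sharedQ,fixedSigma,keepEffects
#'   see [ChainConfig-class].
#' @describeIn ChainConfig-class constructor.
#' @export
chainConfig <- function(nIterations = 6000L, burnIn = 1000L, thinning = 10L,
                        seed = 1L, mode = "bivariate", standardize = TRUE,
                        sharedQ = FALSE, fixedSigma = NULL,
                        keepEffects = FALSE) {
  new("ChainConfig", nIterations = as.integer(nIterations),
      burnIn = as.integer(burnIn), thinning = as.integer(thinning),
      seed = as.integer(seed), mode = mode, standardize = standardize,
      sharedQ = sharedQ, fixedSigma = fixedSigma, keepEffects = keepEffects)
}

setMethod("show", "ChainConfig", function(object) {
  cat(sprintf(
    "ChainConfig: %d sweeps (burn-in %d, thin %d -> %d draws), mode %s, seed %d\n",
    object@nIterations, object@burnIn, object@thinning,
    (object@nIterations - object@burnIn) %/% object@thinning, object@mode,
    object@seed))
})

## ---------------------------------------------------------------------------
## ChainSamples
## ---------------------------------------------------------------------------

#' Thinned post-burn-in draws from a fitted chain
#'
#' Coefficient draws are stored on the raw trait scale (back-transformed if
#' the chain standardized the traits). `beta` holds the SNV coefficient of
#' each draw, 0 when the SNV was excluded; `gamma` holds the inclusion
#' indicators — the chain's realization of the visited model space.
#'
#' @slot gamma integer array draws x G x 2.
#' @slot beta numeric array draws x G x 2 (0 where gamma = 0).
#' @slot betaFixed numeric array draws x P x 2.
#' @slot q numeric matrix draws x 2 (identical columns when sharedQ).
#' @slot SigmaP,SigmaS,SigmaE numeric arrays draws x 2 x 2.
#' @slot famEffects optional array draws x I x 2 (NULL unless kept).
#' @slot subjEffects optional array draws x N x 2 (NULL unless kept).
#' @slot snvIDs,fixedNames,traitNames character metadata.
#' @slot config the [ChainConfig-class] used.
#' @slot priors the resolved [PriorSpec-class] (b filled in).
#' @export
setClass("ChainSamples",
         representation(gamma = "array", beta = "array", betaFixed = "array",
                        q = "matrix", SigmaP = "array", SigmaS = "array",
                        SigmaE = "array", famEffects = "ANY",
                        subjEffects = "ANY", snvIDs = "character",
                        fixedNames = "character", traitNames = "character",
                        config = "ChainConfig", priors = "PriorSpec"))

setValidity("ChainSamples", function(object) {
  d <- dim(object@gamma)
  if (length(d) != 3L || d[3L] != 2L)
    return("gamma must be a draws x G x 2 array")
  if (!identical(dim(object@beta), d))
    return("beta and gamma dimensions must agree")
  expected <- (object@config@nIterations - object@config@burnIn) %/%
    object@config@thinning
  if (d[1L] != expected)
    return(sprintf("draw count %d != (nIterations - burnIn)/thinning = %d",
                   d[1L], expected))
  for (nm in c("SigmaP", "SigmaS", "SigmaE")) {
    S <- slot(object, nm)
    for (i in seq_len(dim(S)[1L])) {
      m <- S[i, , ]
      if (m[1, 1] <= 0 || m[2, 2] <= 0 ||
          m[1, 2]^2 >= m[1, 1] * m[2, 2] + 1e-12)
        return(sprintf("stored %s draw %d is not positive definite", nm, i))
    }
  }
  TRUE
})

#' @describeIn ChainSamples-class number of stored draws
#' @param x,object a ChainSamples
#' @export
nDraws <- function(x) dim(x@gamma)[1L]

setMethod("show", "ChainSamples", function(object) {
  d <- dim(object@gamma)
  cat(sprintf("ChainSamples: %d draws, G = %d SNVs x 2 traits (%s mode)\n",
              d[1L], d[2L], object@config@mode))
  pip <- apply(object@gamma, c(2L, 3L), mean)
  top <- order(-apply(pip, 1L, max))[seq_len(min(5L, d[2L]))]
  cat("  top PIPs:\n")
  for (g in top)
    cat(sprintf("    %-14s %s=%.3f %s=%.3f\n", object@snvIDs[g],
                object@traitNames[1L], pip[g, 1L],
                object@traitNames[2L], pip[g, 2L]))
})
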