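## Synthetic-data generator: multigenerational pedigree templates, Mendelian
## gene dropping with optional tight-linkage LD pairs, and the bivariate
## longitudinal phenotype model used generatively. Defaults emulate the
## benchmark study conditions: 20 extended pedigrees averaging ~42 subjects,
## 3 visits per subject, blood-pressure-scale traits.

## The 15 causal SNVs of the benchmark scenario: position, founder MAF and
## per-dosage additive effects on trait 1 (DBP) and trait 2 (SBP). The SNV
## at 47958037 carries a null printed effect and so belongs to neither
## causal truth set.
.benchmarkCausalSNVs <- function() {
  data.frame(
    id = c("v47912898", "v47913455", "v47924216", "v47955326", "v47956424",
           "v47957741", "v47957996", "v47958037", "v47973345", "v48040283",
           "v48040284", "v48054461", "v48061725", "v48069438", "v48091219"),
    pos = c(47912898, 47913455, 47924216, 47955326, 47956424, 47957741,
            47957996, 47958037, 47973345, 48040283, 48040284, 48054461,
            48061725, 48069438, 48091219),
    maf = c(0.0049, 0.0049, 0.0066, 0.0066, 0.3777, 0.0016, 0.0301, 0.3420,
            0.0082, 0.0318, 0.0131, 0.1187, 0.0050, 0.0065, 0.0065),
    beta1 = c(1.71, -5.46, 1.35, -1.93, -1.50, -5.08, -4.64, 0.00, 2.14,
              -6.22, -6.95, 0.46, 1.79, -1.78, 2.54),
    beta2 = c(2.34, -8.70, 1.84, -2.63, -2.38, -8.10, -7.39, 0.00, 2.92,
              -9.91, -11.1, 0.63, 2.44, -2.43, 3.46),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles the pedigree template, genotype frequencies, causal effects,
#' covariate generators and the three covariance layers of the generative
#' model. Defaults give blood-pressure-scale traits with within-trait
#' variance split across family, subject and visit layers and cross-trait
#' correlation 0.7 in each layer.
#'
#' @param nFamilies number of families.
#' @param offspringRange integer range of children per couple.
#' @param marryProb probability a non-terminal-generation child marries in
#'   (bringing a founder spouse and offspring).
#' @param generations number of descendant generations below the founder
#'   couple.
#' @param nVisits visits per subject.
#' @param mafs founder minor-allele frequency per SNV (length G).
#' @param causal data.frame with columns g (SNV index), beta1, beta2: the
#'   per-dosage additive effects. SNVs absent from `causal` (or with a zero
#'   coefficient for a trait) are not in that trait's causal set.
#' @param intercepts,betaSex,betaAge,betaSmoke length-2 numeric: trait-wise
#'   intercepts and covariate effects (sex is a female indicator; smoking a
#'   subject-constant indicator; age in years, time-varying).
#' @param ageRange baseline-age uniform range; `ageIncrement` years between
#'   visits; `smokePrev` smoking prevalence.
#' @param sigmaP,sigmaS,sigmaE length-2 SDs of the family, subject and
#'   residual layers; `rhoP`, `rhoS`, `rhoE` the cross-trait correlations.
#' @param ldPairs optional data.frame(source, target, eps): the target SNV's
#'   founder alleles copy the source's with per-allele flip probability eps
#'   and the two loci are transmitted in perfect linkage, giving dosage
#'   r-squared near (1 - 2 eps)^2.
#' @param medication optional list(htnThreshold, medProb, medEffect): visits
#'   whose latent trait-2 value reaches htnThreshold mark the subject
#'   hypertensive; such subjects take medication with probability medProb,
#'   and medicated hypertensive observations are shifted by the length-2
#'   medEffect (typically negative).
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(nFamilies = 20L, offspringRange = c(2L, 5L),
                      marryProb = 0.7, generations = 3L, nVisits = 3L,
                      mafs = rep(0.2, 10L), causal = NULL,
                      intercepts = c(75, 120), betaSex = c(3, 5),
                      betaAge = c(0.3, 0.5), betaSmoke = c(2, 3),
                      ageRange = c(20, 70), ageIncrement = 3,
                      smokePrev = 0.2, sigmaP = c(4, 6), sigmaS = c(6, 9),
                      sigmaE = c(5, 7), rhoP = 0.7, rhoS = 0.7, rhoE = 0.7,
                      ldPairs = NULL, medication = NULL) {
  cfg <- list(nFamilies = as.integer(nFamilies),
              offspringRange = as.integer(offspringRange),
              marryProb = marryProb, generations = as.integer(generations),
              nVisits = as.integer(nVisits), mafs = mafs, causal = causal,
              intercepts = intercepts, betaSex = betaSex, betaAge = betaAge,
              betaSmoke = betaSmoke, ageRange = ageRange,
              ageIncrement = ageIncrement, smokePrev = smokePrev,
              sigmaP = sigmaP, sigmaS = sigmaS, sigmaE = sigmaE,
              rhoP = rhoP, rhoS = rhoS, rhoE = rhoE, ldPairs = ldPairs,
              medication = medication)
  class(cfg) <- "SimConfig"
  stopifnot(cfg$nFamilies >= 1L, cfg$generations >= 1L, cfg$nVisits >= 1L,
            all(cfg$mafs > 0), all(cfg$mafs <= 0.5),
            all(c(sigmaP, sigmaS, sigmaE) >= 0),
            all(abs(c(rhoP, rhoS, rhoE)) < 1))
  if (!is.null(causal)) {
    stopifnot(all(c("g", "beta1", "beta2") %in% names(causal)),
              all(causal$g >= 1L), all(causal$g <= length(mafs)))
  }
  if (!is.null(ldPairs))
    stopifnot(all(c("source", "target", "eps") %in% names(ldPairs)),
              all(ldPairs$eps >= 0), all(ldPairs$eps < 0.5))
  cfg
}

#' Simulate a multigenerational pedigree set
#'
#' Each family starts from a founder couple; couples have a uniform number
#' of children in `offspringRange`, and each child of a non-terminal
#' generation marries a new founder with probability `marryProb` and
#' reproduces. With the defaults (20 families, 2-5 offspring, 3
#' generations) family sizes average around 40, in the 21-75 range typical
#' of large extended blood-pressure pedigrees.
#'
#' @param cfg a [simConfig()] object.
#' @param seed integer seed (deterministic output).
#' @return A [PedigreeSet-class].
#' @export
simulatePedigreeStructure <- function(cfg, seed) {
  set.seed(as.integer(seed))
  rows <- vector("list", cfg$nFamilies)
  for (f in seq_len(cfg$nFamilies)) {
    fid <- sprintf("F%02d", f)
    counter <- 0L
    nid <- function() {
      counter <<- counter + 1L
      sprintf("I%03d", counter)
    }
    fa <- nid(); mo <- nid()
    fam <- data.frame(fid = fid, iid = c(fa, mo),
                      father = NA_character_, mother = NA_character_,
                      sex = c(1L, 2L), stringsAsFactors = FALSE)
    couples <- list(c(fa, mo))
    for (gen in seq_len(cfg$generations)) {
      nxt <- list()
      for (cp in couples) {
        kid_choices <- cfg$offspringRange[1L]:cfg$offspringRange[2L]
        nkids <- kid_choices[sample.int(length(kid_choices), 1L)]
        for (k in seq_len(nkids)) {
          kid <- nid()
          ksex <- sample(1:2, 1L)
          fam <- rbind(fam, data.frame(
            fid = fid, iid = kid, father = cp[1L], mother = cp[2L],
            sex = ksex, stringsAsFactors = FALSE))
          if (gen < cfg$generations && runif(1L) < cfg$marryProb) {
            sp <- nid()
            fam <- rbind(fam, data.frame(
              fid = fid, iid = sp, father = NA_character_,
              mother = NA_character_, sex = 3L - ksex,
              stringsAsFactors = FALSE))
            nxt[[length(nxt) + 1L]] <-
              if (ksex == 1L) c(kid, sp) else c(sp, kid)
          }
        }
      }
      couples <- nxt
      if (!length(couples)) break
    }
    rows[[f]] <- fam
  }
  PedigreeSet(do.call(rbind, rows))
}

#' Drop genes through a pedigree
#'
#' Founder alleles are drawn Bernoulli(maf) per chromosome; each non-founder
#' inherits one uniformly chosen allele from each parent. SNVs are
#' independent unless `cfg-style` LD pairs are given, in which case the
#' target locus copies the source's founder alleles with flip probability
#' eps and shares its transmissions (perfect linkage).
#'
#' @param ped a [PedigreeSet-class].
#' @param mafs founder minor-allele frequencies, length G.
#' @param seed integer seed.
#' @param ldPairs optional data.frame(source, target, eps); see [simConfig()].
#' @param ensureSegregating if TRUE, founder alleles of a monomorphic column
#'   are redrawn (conditioning each SNV on being polymorphic, as genotyped
#'   panels are).
#' @return A [GenotypeMatrix-class] with SNV ids `snv01`, `snv02`, ...
#'   (positions 1..G) unless the caller renames them.
#' @export
dropGenes <- function(ped, mafs, seed, ldPairs = NULL,
                      ensureSegregating = FALSE) {
  set.seed(as.integer(seed))
  p <- ped@ped
  n <- nrow(p)
  G <- length(mafs)
  key <- paste(p$fid, p$iid, sep = "\r")
  fa_row <- match(paste(p$fid, p$father, sep = "\r"), key)
  mo_row <- match(paste(p$fid, p$mother, sep = "\r"), key)

  A1 <- matrix(0L, n, G)   # paternal-origin allele
  A2 <- matrix(0L, n, G)   # maternal-origin allele
  founders <- which(p$founder)
  for (g in seq_len(G)) {
    A1[founders, g] <- rbinom(length(founders), 1L, mafs[g])
    A2[founders, g] <- rbinom(length(founders), 1L, mafs[g])
    if (ensureSegregating) {
      while (sum(A1[founders, g]) + sum(A2[founders, g]) == 0L) {
        A1[founders, g] <- rbinom(length(founders), 1L, mafs[g])
        A2[founders, g] <- rbinom(length(founders), 1L, mafs[g])
      }
    }
  }
  if (!is.null(ldPairs)) {
    flip <- function(a, eps) {
      do_flip <- rbinom(length(a), 1L, eps) == 1L
      ifelse(do_flip, 1L - a, a)
    }
    for (r in seq_len(nrow(ldPairs))) {
      s <- ldPairs$source[r]; t <- ldPairs$target[r]; e <- ldPairs$eps[r]
      A1[founders, t] <- flip(A1[founders, s], e)
      A2[founders, t] <- flip(A2[founders, s], e)
    }
  }

  ## transmit in pedigree order (parents precede children after peeling)
  order_idx <- .generationOrder(p, fa_row, mo_row)
  for (i in order_idx) {
    if (p$founder[i]) next
    pick_f <- runif(G) < 0.5          # which of father's alleles
    pick_m <- runif(G) < 0.5
    if (!is.null(ldPairs)) {          # perfect linkage: share transmissions
      for (r in seq_len(nrow(ldPairs))) {
        pick_f[ldPairs$target[r]] <- pick_f[ldPairs$source[r]]
        pick_m[ldPairs$target[r]] <- pick_m[ldPairs$source[r]]
      }
    }
    fi <- fa_row[i]; mi <- mo_row[i]
    A1[i, ] <- ifelse(pick_f, A1[fi, ], A2[fi, ])
    A2[i, ] <- ifelse(pick_m, A1[mi, ], A2[mi, ])
  }
  dos <- A1 + A2
  colnames(dos) <- sprintf("snv%02d", seq_len(G))
  GenotypeMatrix(dos, data.frame(fid = p$fid, iid = p$iid,
                                 stringsAsFactors = FALSE),
                 data.frame(id = colnames(dos), pos = seq_len(G),
                            stringsAsFactors = FALSE))
}

## Row order in which parents always precede children. Gene dropping needs
## both parents of every non-founder.
.generationOrder <- function(p, fa_row, mo_row) {
  nonf <- !p$founder
  if (any(nonf & (is.na(fa_row) | is.na(mo_row))))
    stop("gene dropping requires both parents of every non-founder")
  n <- nrow(p)
  placed <- p$founder
  ord <- which(placed)
  while (length(ord) < n) {
    ready <- which(!placed & placed[ifelse(is.na(fa_row), 1L, fa_row)] &
                     placed[ifelse(is.na(mo_row), 1L, mo_row)])
    if (!length(ready)) stop("pedigree is not acyclic")
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  ord
}

#' Simulate bivariate longitudinal phenotypes
#'
#' Applies the generative model: for subject j of family i at visit t,
#' y_ijtk = b0k + sex*bsex_k + smoke*bsmoke_k + age_ijt*bage_k +
#' sum_g beta_gk SNV_ijg + p_ik + s_ijk + e_ijtk, with p_i ~ N2(0, Sigma_p)
#' per family, s_ij ~ N2(0, Sigma_s) per subject and e_ijt ~ N2(0, Sigma_e)
#' per visit. The optional medication layer is applied afterwards so the
#' adjustment preprocessing can be exercised end-to-end.
#'
#' @param ped a [PedigreeSet-class].
#' @param geno a [GenotypeMatrix-class] aligned with `ped` (as produced by
#'   [dropGenes()]).
#' @param cfg a [simConfig()].
#' @param seed integer seed.
#' @return list with `pheno` (a [PhenotypeTable-class] with covariate
#'   columns sex, smoke, age and flags htn, med) and `truth`, a list with
#'   causal1/causal2 (SNV ids with a nonzero effect on each trait), the
#'   G x 2 effect matrix `beta`, the three true covariance matrices, the
#'   fixed-effect values, and the medication settings used.
#' @export
simulatePhenotypes <- function(ped, geno, cfg, seed) {
  set.seed(as.integer(seed))
  p <- ped@ped
  n <- nrow(p)
  G <- ncol(geno@dosage)
  stopifnot(length(cfg$mafs) == G)

  mk_cov <- function(sig, rho) {
    matrix(c(sig[1L]^2, rho * sig[1L] * sig[2L],
             rho * sig[1L] * sig[2L], sig[2L]^2), 2L, 2L)
  }
  Sp <- mk_cov(cfg$sigmaP, cfg$rhoP)
  Ss <- mk_cov(cfg$sigmaS, cfg$rhoS)
  Se <- mk_cov(cfg$sigmaE, cfg$rhoE)
  for (S in list(Sp, Ss, Se))
    if (any(eigen(S, TRUE)$values < -1e-12))
      stop("requested covariance matrix is not positive semi-definite")

  beta <- matrix(0, G, 2L)
  if (!is.null(cfg$causal)) {
    beta[cfg$causal$g, 1L] <- cfg$causal$beta1
    beta[cfg$causal$g, 2L] <- cfg$causal$beta2
  }

  rmvn2 <- function(m, S) {
    ch <- chol(S + diag(1e-12, 2L))
    matrix(rnorm(2L * m), m, 2L) %*% ch
  }
  fams <- unique(p$fid)
  P <- rmvn2(length(fams), Sp)
  S2 <- rmvn2(n, Ss)

  sexf <- as.numeric(p$sex == 2L)
  sexf[is.na(sexf)] <- 0
  smoke <- rbinom(n, 1L, cfg$smokePrev)
  age0 <- runif(n, cfg$ageRange[1L], cfg$ageRange[2L])
  gene_fx <- geno@dosage %*% beta       # n x 2

  nv <- cfg$nVisits
  rows <- vector("list", nv)
  famIdx <- match(p$fid, fams)
  for (t in seq_len(nv)) {
    E <- rmvn2(n, Se)
    age_t <- age0 + (t - 1L) * cfg$ageIncrement
    mu1 <- cfg$intercepts[1L] + cfg$betaSex[1L] * sexf +
      cfg$betaSmoke[1L] * smoke + cfg$betaAge[1L] * age_t + gene_fx[, 1L] +
      P[famIdx, 1L] + S2[, 1L]
    mu2 <- cfg$intercepts[2L] + cfg$betaSex[2L] * sexf +
      cfg$betaSmoke[2L] * smoke + cfg$betaAge[2L] * age_t + gene_fx[, 2L] +
      P[famIdx, 2L] + S2[, 2L]
    rows[[t]] <- data.frame(fid = p$fid, iid = p$iid, visit = t,
                            y1 = mu1 + E[, 1L], y2 = mu2 + E[, 2L],
                            sex = sexf, smoke = smoke, age = age_t,
                            htn = 0L, med = 0L, stringsAsFactors = FALSE)
  }
  ph <- do.call(rbind, rows)

  med_cfg <- cfg$medication
  if (!is.null(med_cfg)) {
    ph$htn <- as.integer(ph$y2 >= med_cfg$htnThreshold)
    skey <- paste(ph$fid, ph$iid, sep = "\r")
    htn_subj <- unique(skey[ph$htn == 1L])
    takes <- htn_subj[runif(length(htn_subj)) < med_cfg$medProb]
    ph$med <- as.integer(skey %in% takes & ph$htn == 1L)
    sel <- ph$med == 1L
    ph$y1[sel] <- ph$y1[sel] + med_cfg$medEffect[1L]
    ph$y2[sel] <- ph$y2[sel] + med_cfg$medEffect[2L]
  }

  ids <- geno@snvInfo$id
  truth <- list(causal1 = ids[beta[, 1L] != 0],
                causal2 = ids[beta[, 2L] != 0],
                beta = beta, SigmaP = Sp, SigmaS = Ss, SigmaE = Se,
                intercepts = cfg$intercepts, betaSex = cfg$betaSex,
                betaAge = cfg$betaAge, betaSmoke = cfg$betaSmoke,
                medication = med_cfg, snvIDs = ids)
  list(pheno = PhenotypeTable(ph, traitNames = c("dbp", "sbp")),
       truth = truth)
}

#' Parameter-recovery scenario
#'
#' A compact benchmark with known truth: 20 two-generation families
#' (roughly 10 subjects each), 3 visits, G = 10 SNVs of which the first two
#' are causal for both traits with strong rare-variant effects
#' (beta pairs (-8, -10) and (-7.5, -9) at MAFs 0.04 and 0.05). The
#' covariance layers are scaled down from the blood-pressure defaults so
#' that per-SNV information at this sample size matches a full-size family
#' study, making the causal effects recoverable by design.
#'
#' @param seed integer seed.
#' @param nullEffects set TRUE to zero out the causal effects (an all-noise
#'   scenario for multiplicity checks); `G` overrides the SNV count.
#' @param G number of SNVs (extra SNVs beyond the first two are noise at
#'   MAFs uniform on (0.1, 0.4)).
#' @return list with `data` (a [ModelDataset-class]) and `truth`.
#' @export
recoveryScenario <- function(seed, nullEffects = FALSE, G = 10L) {
  set.seed(as.integer(seed) + 13L)
  stopifnot(G >= 2L)
  mafs <- c(0.04, 0.05, runif(G - 2L, 0.1, 0.4))
  causal <- if (nullEffects) NULL else
    data.frame(g = 1:2, beta1 = c(-8, -7.5), beta2 = c(-10, -9))
  cfg <- simConfig(nFamilies = 20L, offspringRange = c(2L, 3L),
                   generations = 2L, marryProb = 0.6, mafs = mafs,
                   causal = causal, sigmaP = c(2, 3), sigmaS = c(3, 4.5),
                   sigmaE = c(2.5, 3.5), rhoP = 0.5, rhoS = 0.5, rhoE = 0.5)
  ped <- simulatePedigreeStructure(cfg, seed)
  geno <- dropGenes(ped, mafs, seed + 1L, ensureSegregating = TRUE)
  sim <- simulatePhenotypes(ped, geno, cfg, seed + 2L)
  dat <- assembleDataset(ped, sim$pheno, geno,
                         covariatesX = c("sex", "smoke"),
                         covariatesZ = "age")
  list(data = dat, truth = sim$truth, ped = ped, geno = geno,
       pheno = sim$pheno, config = cfg)
}

#' Benchmark scenario: 15 causal blood-pressure SNVs plus titrated noise
#'
#' Generates 20 extended pedigrees with 3 visits per subject and the 15
#' causal SNVs of the benchmark frame (their published founder MAFs and
#' additive effect pairs; the null-effect SNV at 47958037 belongs to neither
#' causal set), plus `noiseCount` null SNVs at MAFs uniform on (0.05, 0.45).
#' With noiseCount = 90 the candidate set has the 105 columns of the full
#' titration; noiseCount = 1 gives G = 16.
#'
#' @param noiseCount number of noise SNVs (the titration used 1, 15, 30, 60
#'   and 90).
#' @param seed integer seed.
#' @param ldNoisePairs optional integer: that many noise SNVs are simulated
#'   in tight LD (eps = 0.02) with randomly chosen nonzero-effect causal
#'   SNVs instead of independently.
#' @return list with `data` (a [ModelDataset-class]), `truth` (see
#'   [simulatePhenotypes()]), and the underlying `ped`, `geno`, `pheno`.
#' @export
gawLikeScenario <- function(noiseCount, seed, ldNoisePairs = 0L) {
  tab <- .benchmarkCausalSNVs()
  nC <- nrow(tab)
  set.seed(as.integer(seed) + 7L)
  noise_maf <- runif(noiseCount, 0.05, 0.45)
  mafs <- c(tab$maf, noise_maf)
  ldPairs <- NULL
  if (ldNoisePairs > 0L) {
    stopifnot(ldNoisePairs <= noiseCount)
    eligible <- which((tab$beta1 != 0 | tab$beta2 != 0) & tab$maf >= 0.03)
    src <- sample(eligible, ldNoisePairs, replace = ldNoisePairs > length(eligible))
    ldPairs <- data.frame(source = src,
                          target = nC + seq_len(ldNoisePairs),
                          eps = 0.02)
  }
  cfg <- simConfig(mafs = mafs,
                   causal = data.frame(g = seq_len(nC), beta1 = tab$beta1,
                                       beta2 = tab$beta2))
  ped <- simulatePedigreeStructure(cfg, seed)
  geno <- dropGenes(ped, mafs, seed + 1L, ldPairs = ldPairs,
                    ensureSegregating = TRUE)
  ids <- c(tab$id, sprintf("noise%02d", seq_len(noiseCount)))
  pos <- c(tab$pos, max(tab$pos) + seq_len(noiseCount) * 1000)
  colnames(geno@dosage) <- ids
  geno@snvInfo <- data.frame(id = ids, pos = pos, stringsAsFactors = FALSE)
  sim <- simulatePhenotypes(ped, geno, cfg, seed + 2L)
  sim$truth$snvIDs <- ids
  sim$truth$causal1 <- ids[seq_len(nC)][tab$beta1 != 0]
  sim$truth$causal2 <- ids[seq_len(nC)][tab$beta2 != 0]
  dat <- assembleDataset(ped, sim$pheno, geno,
                         covariatesX = c("sex", "smoke"),
                         covariatesZ = "age")
  list(data = dat, truth = sim$truth, ped = ped, geno = geno,
       pheno = sim$pheno)
}
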