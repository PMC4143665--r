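## Phenotype and genotype hygiene: antihypertensive-medication adjustment of
## blood-pressure traits, minor-allele frequency, composite LD r2, and the
## LD discounting of false positives.

#' Adjust a blood-pressure trait for antihypertensive medication
#'
#' Among hypertensive observations (htn = 1), the observation-level mean
#' difference delta = mean(BP | med = 1) - mean(BP | med = 0) is estimated,
#' and every htn = 1, med = 1 observation is replaced by observed - delta,
#' imputing its value without medication. All other rows are unchanged.
#' Visits are pooled: the strata are observation-level, not subject-level.
#'
#' @param pheno a [PhenotypeTable-class] with htn and med columns.
#' @param trait 1 or 2: which trait to adjust.
#' @return list with `pheno` (adjusted [PhenotypeTable-class]) and `report`,
#'   a list with elements delta, nMedicated, nUnmedicated (htn = 1 stratum
#'   sizes), nAdjusted, trait, and pooling = "observations".
#' @export
adjustForMedication <- function(pheno, trait) {
  stopifnot(trait %in% c(1L, 2L))
  ph <- pheno@pheno
  if (!all(c("htn", "med") %in% names(ph)))
    stop("phenotype table has no htn/med columns")
  ycol <- paste0("y", trait)
  h1 <- ph$htn == 1
  med1 <- which(h1 & ph$med == 1)
  med0 <- which(h1 & ph$med == 0)
  if (length(med1) == 0L) {
    report <- list(delta = NA_real_, nMedicated = 0L,
                   nUnmedicated = length(med0), nAdjusted = 0L,
                   trait = trait, pooling = "observations")
    return(list(pheno = pheno, report = report))
  }
  if (length(med0) == 0L)
    stop("cannot estimate medication effect: no htn = 1, med = 0 stratum")
  delta <- mean(ph[[ycol]][med1]) - mean(ph[[ycol]][med0])
  ph[[ycol]][med1] <- ph[[ycol]][med1] - delta
  report <- list(delta = delta, nMedicated = length(med1),
                 nUnmedicated = length(med0), nAdjusted = length(med1),
                 trait = trait, pooling = "observations")
  list(pheno = PhenotypeTable(ph, pheno@traitNames), report = report)
}

#' Minor allele frequency of one SNV
#'
#' Allele frequency over non-missing dosages, folded to min(f, 1 - f).
#' Invariant under subject permutation.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param snv SNV id.
#' @return frequency in [0, 0.5].
#' @export
snvMAF <- function(geno, snv) {
  x <- .snvColumn(geno, snv)
  x <- x[!is.na(x)]
  if (!length(x)) stop("SNV '", snv, "' has no non-missing dosages")
  f <- sum(x) / (2 * length(x))
  min(f, 1 - f)
}

.snvColumn <- function(geno, snv) {
  if (!snv %in% colnames(geno@dosage)) stop("unknown SNV id '", snv, "'")
  geno@dosage[, snv]
}

#' Composite LD between two SNVs
#'
#' Squared Pearson correlation of the dosage vectors over subjects with both
#' genotypes non-missing (phase-free, as appropriate for unphased family
#' data). Symmetric in its arguments and invariant under relabeling which
#' allele is minor (dosage -> 2 - dosage).
#'
#' @param geno a [GenotypeMatrix-class].
#' @param snvA,snvB SNV ids.
#' @return r-squared in [0, 1].
#' @export
ldR2 <- function(geno, snvA, snvB) {
  a <- .snvColumn(geno, snvA)
  b <- .snvColumn(geno, snvB)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L) stop("fewer than 2 shared non-missing subjects")
  if (var(a) == 0) stop("SNV '", snvA, "' has zero dosage variance")
  if (var(b) == 0) stop("SNV '", snvB, "' has zero dosage variance")
  cor(a, b)^2
}

#' Partition selected noise SNVs into LD-explained and unexplained
#'
#' A selected noise SNV ("false positive") is LD-explained if its maximum
#' dosage r-squared with any selected true positive reaches the threshold —
#' its selection is then attributed to the indirect effect of a causal SNV
#' it tags rather than to a multiplicity failure.
#'
#' @param selectedNoise character, ids of selected non-causal SNVs.
#' @param selectedTrue character, ids of selected causal SNVs.
#' @param geno a [GenotypeMatrix-class] covering all the ids.
#' @param threshold r-squared cutoff in (0, 1]; default 0.8.
#' @return list with `ldExplained`, `unexplained` (character vectors) and
#'   `maxR2` (named numeric, per noise SNV; NA when selectedTrue is empty).
#' @export
discountLDFalsePositives <- function(selectedNoise, selectedTrue, geno,
                                     threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  if (!length(selectedNoise))
    return(list(ldExplained = character(0), unexplained = character(0),
                maxR2 = setNames(numeric(0), character(0))))
  if (!length(selectedTrue))
    return(list(ldExplained = character(0), unexplained = selectedNoise,
                maxR2 = setNames(rep(NA_real_, length(selectedNoise)),
                                 selectedNoise)))
  maxr2 <- vapply(selectedNoise, function(fp)
    max(vapply(selectedTrue, function(tp) ldR2(geno, fp, tp), numeric(1L))),
    numeric(1L))
  explained <- maxr2 >= threshold
  list(ldExplained = selectedNoise[explained],
       unexplained = selectedNoise[!explained],
       maxR2 = maxr2)
}
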