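## File intake/output: FAM pedigrees, long phenotype CSV, VCF / dosage-CSV
## genotypes. All readers feed the S4 containers in AllClasses.R and all
## write/read pairs round-trip exactly.

#' Read a PLINK-style FAM pedigree file
#'
#' Whitespace-delimited, 5 or 6 columns: family id, individual id, father,
#' mother, sex, and an optional phenotype column which is ignored. Parent
#' code "0" means founder.
#'
#' @param path path to the FAM file.
#' @return A [PedigreeSet-class].
#' @export
readPedigree <- function(path) {
  raw <- read.table(path, header = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (!ncol(raw) %in% c(5L, 6L))
    stop("FAM file must have 5 or 6 whitespace-delimited columns, found ",
         ncol(raw))
  names(raw)[1:5] <- c("fid", "iid", "father", "mother", "sex")
  PedigreeSet(raw[, 1:5])
}

#' Write a PedigreeSet as a FAM file
#'
#' @param ped a [PedigreeSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePedigree <- function(ped, path) {
  p <- ped@ped
  out <- data.frame(fid = p$fid, iid = p$iid,
                    father = ifelse(is.na(p$father), "0", p$father),
                    mother = ifelse(is.na(p$mother), "0", p$mother),
                    sex = ifelse(is.na(p$sex), "0", p$sex),
                    pheno = "-9")
  write.table(out, path, quote = FALSE, sep = " ", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a long-format phenotype CSV
#'
#' @param path CSV path (with header).
#' @param schema named list mapping canonical roles to column names:
#'   fid, iid, visit, trait1, trait2, and optionally htn, med. Columns not
#'   named in the schema are carried through as covariates.
#' @return A [PhenotypeTable-class], sorted by (family, individual, visit).
#' @export
readPhenotypesLong <- function(path,
                               schema = list(fid = "fid", iid = "iid",
                                             visit = "visit",
                                             trait1 = "trait1",
                                             trait2 = "trait2",
                                             htn = "htn", med = "med")) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("fid", "iid", "visit", "trait1", "trait2")
  missing_roles <- setdiff(need, names(schema))
  if (length(missing_roles))
    stop("schema must name columns for: ", paste(missing_roles, collapse = ", "))
  for (role in names(schema)) {
    col <- schema[[role]]
    if (!col %in% names(raw)) {
      if (role %in% need)
        stop("column '", col, "' (role ", role, ") not found in ", path)
      next
    }
  }
  canon <- c(fid = "fid", iid = "iid", visit = "visit", trait1 = "y1",
             trait2 = "y2", htn = "htn", med = "med")
  out <- raw
  for (role in names(canon)) {
    col <- schema[[role]]
    if (!is.null(col) && col %in% names(out))
      names(out)[names(out) == col] <- canon[[role]]
  }
  PhenotypeTable(out, traitNames = c(schema$trait1, schema$trait2))
}

#' Write a PhenotypeTable as CSV
#'
#' Canonical column names are used (fid, iid, visit, trait columns under
#' their display names, covariates as-is), so the file re-reads with the
#' matching schema.
#'
#' @param pheno a [PhenotypeTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePhenotypesLong <- function(pheno, path) {
  ph <- pheno@pheno
  names(ph)[names(ph) == "y1"] <- pheno@traitNames[1L]
  names(ph)[names(ph) == "y2"] <- pheno@traitNames[2L]
  write.csv(ph, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read genotype dosages from VCF or a dosage CSV
#'
#' For VCF, only the GT field is used: the dosage is the ALT-allele count,
#' with "./." (or any missing allele) mapped to NA. Sample names of the form
#' `fid_iid` are split on the first underscore; plain names become the iid
#' with an empty fid to be resolved against the pedigree at assembly.
#' For CSV, the file must have columns fid, iid followed by one column per
#' SNV holding literal dosages; any value outside \{0, 1, 2\} is an error.
#'
#' @param path input path.
#' @param fmt "vcf" or "dosage_csv".
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, fmt = c("vcf", "dosage_csv")) {
  fmt <- match.arg(fmt)
  if (fmt == "vcf") .readGenotypesVCF(path) else .readGenotypesCSV(path)
}

.readGenotypesVCF <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  alt_count <- function(s) {
    if (is.na(s)) return(NA_real_)
    al <- strsplit(s, "[/|]")[[1L]]
    if (any(al == ".")) return(NA_real_)
    sum(al != "0")
  }
  dos <- t(apply(gt, 1L, function(row) vapply(row, alt_count, numeric(1L))))
  if (nrow(gt) == 1L) dos <- matrix(dos, nrow = 1L,
                                    dimnames = dimnames(gt))
  dos <- t(dos)                         # subjects x SNVs
  samp <- colnames(gt)
  has_us <- grepl("_", samp, fixed = TRUE)
  samples <- data.frame(
    fid = ifelse(has_us, sub("_.*$", "", samp), ""),
    iid = ifelse(has_us, sub("^[^_]*_", "", samp), samp),
    stringsAsFactors = FALSE)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  info <- data.frame(id = ids, pos = as.numeric(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  GenotypeMatrix(dos, samples, info)
}

.readGenotypesCSV <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("fid", "iid") %in% names(raw)))
    stop("dosage CSV must have leading columns fid, iid")
  snv_cols <- setdiff(names(raw), c("fid", "iid"))
  dos <- as.matrix(raw[, snv_cols, drop = FALSE])
  storage.mode(dos) <- "double"
  bad <- dos[!is.na(dos) & !(dos %in% c(0, 1, 2))]
  if (length(bad))
    stop("dosage value ", format(bad[1L]), " outside {0, 1, 2} in ", path)
  GenotypeMatrix(dos, raw[, c("fid", "iid")],
                 data.frame(id = snv_cols, pos = seq_along(snv_cols),
                            stringsAsFactors = FALSE))
}

#' Write a GenotypeMatrix as a dosage CSV
#'
#' @param geno a [GenotypeMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDosageCSV <- function(geno, path) {
  out <- cbind(geno@samples, as.data.frame(geno@dosage, check.names = FALSE))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a GenotypeMatrix as a minimal VCF (GT field only)
#'
#' Genotypes are emitted unphased with dosage d written as the canonical
#' unordered GT (0/0, 0/1, 1/1 or ./.). Sample columns are named `fid_iid`.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param path output path.
#' @param chrom chromosome label for all records.
#' @return `path`, invisibly.
#' @export
writeGenotypesVCF <- function(geno, path, chrom = "3") {
  info <- geno@snvInfo
  ref <- if ("ref" %in% names(info)) info$ref else rep("A", nrow(info))
  alt <- if ("alt" %in% names(info)) info$alt else rep("G", nrow(info))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  samp <- paste(geno@samples$fid, geno@samples$iid, sep = "_")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samp), collapse = "\t")), con)
  for (g in seq_len(nrow(info))) {
    d <- geno@dosage[, g]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    writeLines(paste(c(chrom, format(info$pos[g], scientific = FALSE),
                       info$id[g], ref[g], alt[g], ".", "PASS", ".", "GT",
                       gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Assemble an index-aligned model dataset
#'
#' Cross-resolves pedigree, phenotypes and genotypes, builds the fixed-effect
#' design (intercept + time-invariant + time-varying covariates) shared by
#' both traits, and attaches the SNV dosage columns. Monomorphic SNVs (zero
#' variance among the modeled subjects) are dropped with a warning and G
#' updated. The observation row count equals the total number of visits.
#'
#' @param ped a [PedigreeSet-class].
#' @param pheno a [PhenotypeTable-class].
#' @param geno a [GenotypeMatrix-class].
#' @param covariatesX character, names of time-invariant covariate columns.
#' @param covariatesZ character, names of time-varying covariate columns.
#' @param snvs character or NULL: subset of SNV ids to include (default all).
#' @param onMissingGenotype "error" (default) or "drop": what to do with
#'   phenotyped individuals lacking a complete genotype record.
#' @return A [ModelDataset-class].
#' @export
assembleDataset <- function(ped, pheno, geno, covariatesX = character(0),
                            covariatesZ = character(0), snvs = NULL,
                            onMissingGenotype = c("error", "drop")) {
  onMissingGenotype <- match.arg(onMissingGenotype)
  ph <- pheno@pheno
  ph <- ph[!is.na(ph$y1) & !is.na(ph$y2), , drop = FALSE]
  pt <- ped@ped
  pkey <- paste(pt$fid, pt$iid, sep = "\r")
  okey <- paste(ph$fid, ph$iid, sep = "\r")
  if (length(bad <- setdiff(okey, pkey)))
    stop("phenotyped individual not in pedigree: ", gsub("\r", "/", bad[1L]))

  gs <- geno@samples
  gkey <- paste(gs$fid, gs$iid, sep = "\r")
  if (any(gs$fid == "")) {              # VCF without fid_iid sample names
    m <- match(gs$iid, pt$iid)
    if (anyDuplicated(pt$iid) || anyNA(m))
      stop("cannot resolve genotype sample ids against the pedigree ",
           "(individual ids are not globally unique)")
    gkey <- paste(pt$fid[m], gs$iid, sep = "\r")
  }
  dos <- geno@dosage
  if (!is.null(snvs)) {
    miss <- setdiff(snvs, colnames(dos))
    if (length(miss)) stop("unknown SNV id: ", miss[1L])
    dos <- dos[, snvs, drop = FALSE]
  }
  gmatch <- match(okey, gkey)
  subj_keys <- unique(okey)
  sk_match <- match(subj_keys, gkey)
  incomplete <- vapply(sk_match, function(i)
    is.na(i) || anyNA(dos[i, ]), logical(1L))
  no_geno <- subj_keys[incomplete]
  if (length(no_geno)) {
    msg <- sprintf("%d phenotyped individual(s) without complete genotypes (e.g. %s)",
                   length(no_geno), gsub("\r", "/", no_geno[1L]))
    if (onMissingGenotype == "error")
      stop(msg, "; use onMissingGenotype = 'drop' to drop them")
    warning(msg, "; dropped")
    keep <- !(okey %in% no_geno)
    ph <- ph[keep, , drop = FALSE]
    okey <- okey[keep]
    gmatch <- gmatch[keep]
  }

  covs <- c(covariatesX, covariatesZ)
  if (length(miss <- setdiff(covs, names(ph))))
    stop("covariate column not found: ", miss[1L])
  for (cv in covs)
    if (anyNA(ph[[cv]]))
      stop("missing values in covariate '", cv,
           "'; covariate imputation is not performed")

  n <- nrow(ph)
  X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  if (length(covs)) {
    X <- cbind(1, as.matrix(ph[, covs, drop = FALSE]))
    colnames(X) <- c("(Intercept)", covs)
    storage.mode(X) <- "double"
  }
  Gmat <- dos[gmatch, , drop = FALSE]
  rownames(Gmat) <- NULL

  ## monomorphism filter on the modeled subjects (one row per subject)
  subj_rows <- !duplicated(okey)
  poly <- apply(Gmat[subj_rows, , drop = FALSE], 2L, function(x) var(x) > 0)
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic SNV(s) dropped: ",
            paste(colnames(Gmat)[!poly], collapse = ", "))
    Gmat <- Gmat[, poly, drop = FALSE]
  }

  fam_levels <- unique(ph$fid)
  famIdx <- match(ph$fid, fam_levels)
  subj_levels <- unique(okey)
  subjIdx <- match(okey, subj_levels)
  subjFam <- famIdx[match(subj_levels, okey)]

  info <- geno@snvInfo[match(colnames(Gmat), geno@snvInfo$id), , drop = FALSE]
  info$maf <- apply(Gmat[subj_rows, , drop = FALSE], 2L, function(x) {
    f <- sum(x) / (2 * length(x)); min(f, 1 - f)
  })
  rownames(info) <- NULL

  new("ModelDataset", Y = cbind(ph$y1, ph$y2), X = X, G = Gmat,
      famIdx = as.integer(famIdx), subjIdx = as.integer(subjIdx),
      subjFam = as.integer(subjFam),
      obsKey = data.frame(fid = ph$fid, iid = ph$iid, visit = ph$visit,
                          stringsAsFactors = FALSE),
      snvInfo = info, traitNames = pheno@traitNames,
      fixedNames = colnames(X))
}
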