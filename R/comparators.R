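## The two baselines: the Bayesian univariate model (traits fitted
## independently) and a measured-genotype-style single-SNV mixed-model scan
## with Bonferroni correction.

#' Fit the Bayesian univariate comparator
#'
#' Delegates to [runChain()] with mode = "univariate": the off-diagonals of
#' all three covariance layers are zero, so the two traits are modeled
#' independently (each by its own single-trait spike-and-slab chain with a
#' derived seed).
#'
#' @param data a [ModelDataset-class].
#' @param priors a [PriorSpec-class].
#' @param cfg a [ChainConfig-class]; its mode is overridden.
#' @return A [ChainSamples-class].
#' @export
runUnivariate <- function(data, priors, cfg) {
  cfg@mode <- "univariate"
  runChain(data, priors, cfg)
}

#' Measured-genotype-style single-SNV mixed-model scan
#'
#' For one trait and each SNV in turn, fits by maximum likelihood the linear
#' mixed model trait ~ covariates + SNV dosage + (1 | family) and the same
#' model without the SNV, and tests the SNV by the 1-df likelihood-ratio
#' test. A single visit (default the first) per subject is used, matching
#' the comparator's inability to model longitudinal data; `visit = "all"`
#' uses every visit and adds a subject-level random intercept.
#'
#' @param data a [ModelDataset-class].
#' @param trait 1 or 2.
#' @param visit "first" or "all".
#' @return data.frame with one row per SNV: snv, beta, se, chisq, p.
#'   Zero-variance or collinear SNVs get NA p with a warning.
#' @export
mgaScan <- function(data, trait = 1L, visit = c("first", "all")) {
  visit <- match.arg(visit)
  stopifnot(trait %in% c(1L, 2L))
  df <- data.frame(y = data@Y[, trait], data@X[, -1L, drop = FALSE],
                   fam = factor(data@famIdx), subj = factor(data@subjIdx),
                   check.names = FALSE)
  covs <- setdiff(colnames(data@X), "(Intercept)")
  keep <- if (visit == "first") !duplicated(data@subjIdx) else
    rep(TRUE, nrow(df))
  re <- if (visit == "first") "(1 | fam)" else "(1 | fam) + (1 | subj)"
  base_rhs <- paste(c(covs, re), collapse = " + ")
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  out <- data.frame(snv = data@snvInfo$id, beta = NA_real_, se = NA_real_,
                    chisq = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  dfx <- df[keep, , drop = FALSE]
  f0 <- stats::as.formula(paste("y ~", base_rhs))
  m0 <- suppressMessages(suppressWarnings(
    lme4::lmer(f0, data = dfx, REML = FALSE, control = ctrl)))
  ll0 <- as.numeric(logLik(m0))
  Xcov <- cbind(1, as.matrix(dfx[, covs, drop = FALSE]))
  for (g in seq_len(ncol(data@G))) {
    snv <- data@G[keep, g]
    if (var(snv) == 0) {
      warning("SNV '", data@snvInfo$id[g],
              "' has zero dosage variance; skipped")
      next
    }
    if (qr(cbind(Xcov, snv))$rank <= ncol(Xcov)) {
      warning("SNV '", data@snvInfo$id[g],
              "' is collinear with the covariates; skipped")
      next
    }
    dfx$snv <- snv
    f1 <- stats::as.formula(paste("y ~", base_rhs, "+ snv"))
    m1 <- suppressMessages(suppressWarnings(
      lme4::lmer(f1, data = dfx, REML = FALSE, control = ctrl)))
    cc <- summary(m1)$coefficients
    stat <- max(2 * (as.numeric(logLik(m1)) - ll0), 0)
    out$beta[g] <- cc["snv", "Estimate"]
    out$se[g] <- cc["snv", "Std. Error"]
    out$chisq[g] <- stat
    out$p[g] <- pchisq(stat, df = 1L, lower.tail = FALSE)
  }
  out
}

#' Bonferroni selection over a scan
#'
#' @param scan data.frame from [mgaScan()].
#' @param alpha family-wise level in (0, 1).
#' @param nTests number of tests corrected for (at least the number of
#'   non-missing p-values; the benchmark design corrects for the full
#'   candidate count, e.g. 105 = 90 noise + 15 causal).
#' @return list with `selected` (SNV ids with p <= alpha/nTests),
#'   `threshold`, `alpha`, `nTests`, and the scan with a `selected` column.
#' @export
bonferroniSelect <- function(scan, alpha = 0.05, nTests = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  nAvail <- sum(!is.na(scan$p))
  if (is.null(nTests)) nTests <- nAvail
  if (nTests < nAvail)
    stop("nTests must be at least the number of computed p-values")
  thr <- alpha / nTests
  scan$selected <- !is.na(scan$p) & scan$p <= thr
  list(selected = scan$snv[scan$selected], threshold = thr, alpha = alpha,
       nTests = nTests, scan = scan)
}
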