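## Turning chain draws into inferential outputs: posterior inclusion
## probabilities with Monte Carlo standard errors, the median probability
## model, confusion accounting against simulation truth, coefficient
## summaries conditional on inclusion, and PIP stability traces.

#' Posterior inclusion probabilities
#'
#' The PIP of SNV g for trait k is the frequency of gamma_gk = 1 across the
#' stored (post-burn-in, thinned) draws — the MCMC estimate of the sum of
#' posterior model probabilities over visited models containing the SNV.
#' Monte Carlo standard errors use non-overlapping batch means (20 batches).
#'
#' @param samples a [ChainSamples-class].
#' @return data.frame with one row per SNV x trait: snv, trait, pip,
#'   mcse, exclusionProb (= 1 - pip).
#' @export
inclusionProbabilities <- function(samples) {
  if (nDraws(samples) < 1L) stop("chain has no stored draws")
  G <- dim(samples@gamma)[2L]
  out <- expand.grid(snv = samples@snvIDs,
                     trait = samples@traitNames,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$pip <- NA_real_; out$mcse <- NA_real_
  for (k in 1:2) {
    for (g in seq_len(G)) {
      x <- samples@gamma[, g, k]
      row <- (k - 1L) * G + g
      out$pip[row] <- mean(x)
      out$mcse[row] <- .batchSE(x)
    }
  }
  out$exclusionProb <- 1 - out$pip
  out
}

#' Median probability model selection
#'
#' Selects the SNV-trait pairs whose posterior inclusion probability is
#' larger than or equal to the threshold (default 0.5, the median
#' probability model; ties at the threshold are included). Lower thresholds
#' select supersets.
#'
#' @param pips data.frame from [inclusionProbabilities()].
#' @param threshold probability in (0, 1].
#' @return list with `selected` (data.frame snv, trait, pip) and
#'   `threshold`.
#' @export
medianProbabilityModel <- function(pips, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  sel <- pips[pips$pip >= threshold, c("snv", "trait", "pip"), drop = FALSE]
  rownames(sel) <- NULL
  list(selected = sel, threshold = threshold)
}

#' Confusion counts of a selection against simulation truth
#'
#' @param selection result of [medianProbabilityModel()].
#' @param truth a simulation truth list (fields causal1, causal2, snvIDs;
#'   see [simulatePhenotypes()]).
#' @param traitNames length-2 character naming the traits as they appear in
#'   the selection (defaults to the usual dbp/sbp labels).
#' @return data.frame with one row per trait: tp, fp, fn and the id lists
#'   as comma-separated strings.
#' @export
confusionCounts <- function(selection, truth,
                            traitNames = c("dbp", "sbp")) {
  sel <- selection$selected
  unknown <- setdiff(sel$snv, truth$snvIDs)
  if (length(unknown))
    stop("selected SNV not covered by the truth set: ", unknown[1L])
  out <- data.frame(trait = traitNames, tp = NA_integer_, fp = NA_integer_,
                    fn = NA_integer_, tpIDs = "", fpIDs = "",
                    stringsAsFactors = FALSE)
  for (k in 1:2) {
    causal <- if (k == 1L) truth$causal1 else truth$causal2
    chosen <- sel$snv[sel$trait == traitNames[k]]
    tp <- intersect(chosen, causal)
    fp <- setdiff(chosen, causal)
    fn <- setdiff(causal, chosen)
    out$tp[k] <- length(tp); out$fp[k] <- length(fp); out$fn[k] <- length(fn)
    out$tpIDs[k] <- paste(tp, collapse = ",")
    out$fpIDs[k] <- paste(fp, collapse = ",")
  }
  out
}

#' Coefficient summaries per SNV and trait
#'
#' Primary summaries condition on inclusion: mean, SD and central 95%
#' interval of the coefficient over the draws in which the SNV was in the
#' model, with the count of conditioning draws (estimates based on few
#' inclusion draws deserve caution). The model-averaged (unconditional)
#' mean, with exclusion draws contributing 0, is also reported. SNVs never
#' included are flagged and their conditional fields left NA.
#'
#' @param samples a [ChainSamples-class].
#' @return data.frame with one row per SNV x trait: snv, trait, pip,
#'   exclusionProb, nInclusionDraws, condMean, condSD, condLower, condUpper,
#'   modelAvgMean, flag.
#' @export
coefficientSummaries <- function(samples) {
  if (nDraws(samples) < 1L) stop("chain has no stored draws")
  G <- dim(samples@gamma)[2L]
  rows <- vector("list", 2L * G)
  for (k in 1:2) {
    for (g in seq_len(G)) {
      inc <- samples@gamma[, g, k] == 1L
      b <- samples@beta[, g, k]
      pip <- mean(inc)
      if (any(inc)) {
        bi <- b[inc]
        qs <- quantile(bi, c(0.025, 0.975), names = FALSE)
        rows[[(k - 1L) * G + g]] <- data.frame(
          snv = samples@snvIDs[g], trait = samples@traitNames[k],
          pip = pip, exclusionProb = 1 - pip, nInclusionDraws = sum(inc),
          condMean = mean(bi), condSD = sd(bi), condLower = qs[1L],
          condUpper = qs[2L], modelAvgMean = mean(b), flag = "",
          stringsAsFactors = FALSE)
      } else {
        rows[[(k - 1L) * G + g]] <- data.frame(
          snv = samples@snvIDs[g], trait = samples@traitNames[k],
          pip = 0, exclusionProb = 1, nInclusionDraws = 0L,
          condMean = NA_real_, condSD = NA_real_, condLower = NA_real_,
          condUpper = NA_real_, modelAvgMean = 0, flag = "no-inclusion",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stability of cumulative posterior inclusion probabilities
#'
#' Splits the stored draws into segments and reports the cumulative PIP
#' after each segment plus the maximum absolute change over the final half
#' of the chain — inclusion frequencies that stabilize early indicate the
#' PIP estimates are trustworthy despite the size of the model space.
#'
#' @param samples a [ChainSamples-class].
#' @param nSegments number of segments (>= 2).
#' @return list with `trace` (array nSegments x G x 2 of cumulative PIPs)
#'   and `finalHalfDrift` (G x 2 matrix of max |change| over the final
#'   half).
#' @export
pipStability <- function(samples, nSegments = 10L) {
  stopifnot(nSegments >= 2L)
  D <- nDraws(samples)
  G <- dim(samples@gamma)[2L]
  ends <- unique(round(seq_len(nSegments) * D / nSegments))
  trace <- array(NA_real_, c(length(ends), G, 2L))
  for (k in 1:2)
    for (g in seq_len(G)) {
      cum <- cumsum(samples@gamma[, g, k]) / seq_len(D)
      trace[, g, k] <- cum[ends]
    }
  half <- which(ends > D / 2)
  drift <- apply(trace, c(2L, 3L), function(tr)
    max(tr[half]) - min(tr[half]))
  dimnames(drift) <- list(samples@snvIDs, samples@traitNames)
  list(trace = trace, finalHalfDrift = drift, segmentEnds = ends)
}
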