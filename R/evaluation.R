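#' Number of candidate residue pairs
#'
#' Count of pairs (i < j) with `j - i >= minSeparation` in a chain of N
#' residues: `T (T + 1) / 2` with `T = max(0, N - minSeparation)`.  For a
#' 100-residue protein with the standard separation of 5 this gives 4560
#' potential contacts.
#'
#' @param N chain length.
#' @param minSeparation minimum sequence separation (default 5).
#' @return integer count.
#' @export
nCandidatePairs <- function(N, minSeparation = 5L) {
  stopifnot(N >= 0)
  T <- max(0L, N - as.integer(minSeparation))
  T * (T + 1L) / 2L
}

#' Number of predictions in the top fraction of candidate pairs
#'
#' @param nPairs number of candidate pairs.
#' @param fraction fraction of pairs taken as predictions (default 0.01,
#'   the "top 1%" convention).
#' @return integer count (ceiling).
#' @export
topFractionCount <- function(nPairs, fraction = 0.01) {
  as.integer(ceiling(nPairs * fraction))
}

#' Accuracy curve of a ranked prediction list
#'
#' For each N in 1..`nMax`, the accuracy is the proportion of true
#' contacts among the N highest-scoring mapped predictions.  Predictions
#' whose columns are absent from the mapping are dropped before ranking.
#' If fewer mapped predictions than `nMax` are available the curve is
#' truncated with a message.
#'
#' @param ranked data.frame from [rankPairs()] (columns `i`, `j`,
#'   `score`).
#' @param cmap [ContactMap] ground truth over structure residues.
#' @param mapping column-to-residue mapping (default: identity).
#' @param nMax maximum number of predictions (default: number of residues
#'   in `cmap`, the top-L convention).
#' @return data.frame with columns `n`, `accuracy` and `fracL`
#'   (n / number of residues).
#' @export
evaluateRanking <- function(ranked, cmap, mapping = NULL, nMax = NULL) {
  L <- nrow(contactMatrix(cmap))
  if (is.null(mapping)) mapping <- identityMapping(L)
  if (is.null(nMax)) nMax <- L
  lut <- rep(NA_integer_, max(mapping$map$column, ranked$i, ranked$j))
  lut[mapping$map$column] <- mapping$map$residue
  ri <- lut[ranked$i]
  rj <- lut[ranked$j]
  okm <- !is.na(ri) & !is.na(rj)
  ri <- ri[okm]; rj <- rj[okm]
  if (length(ri) < nMax) {
    message(sprintf("only %d mapped predictions available; curve truncated (requested %d)",
                    length(ri), nMax))
    nMax <- length(ri)
  }
  if (nMax < 1L) stop("no mapped predictions to evaluate")
  truth <- contactMatrix(cmap)[cbind(ri[seq_len(nMax)], rj[seq_len(nMax)])]
  n <- seq_len(nMax)
  data.frame(n = n, accuracy = cumsum(truth) / n, fracL = n / L)
}

# internal alias used by the alpha-fitting code
accuracyCurve <- evaluateRanking

#' Percent AUC improvement between two accuracy curves
#'
#' Trapezoidal area under each accuracy-vs-number-of-predictions curve;
#' returns `100 (AUC_combined - AUC_base) / AUC_base`.
#'
#' @param curveBase,curveCombined data.frames from [evaluateRanking()]
#'   sharing the same `n` grid.
#' @return percent improvement (can be negative).
#' @export
aucImprovement <- function(curveBase, curveCombined) {
  if (!isTRUE(all.equal(curveBase$n, curveCombined$n)))
    stop("curves must share the same prediction-count grid")
  if (length(curveBase$n) == 1L) {
    a0 <- curveBase$accuracy; a1 <- curveCombined$accuracy
  } else {
    a0 <- pracma::trapz(curveBase$n, curveBase$accuracy)
    a1 <- pracma::trapz(curveCombined$n, curveCombined$accuracy)
  }
  if (a0 == 0) stop("base curve has zero AUC (degenerate)")
  100 * (a1 - a0) / a0
}

#' Evaluate score variants for one family against its structures
#'
#' Implements the per-family protocol: structures failing the coverage
#' rule are dropped; among structures with unique sequences at most
#' `maxStructures` (default 30) with the best resolution are kept (ties
#' broken by lexicographically smallest identifier); accuracy curves are
#' averaged across the retained structures so families with many
#' structures are not over-represented; AUCs and the percent improvement
#' of each variant over `"base"` are computed on the averaged curves.
#'
#' @param scoreVariants named list of [ScoreMatrix] objects; must contain
#'   `"base"`, other entries are compared against it.
#' @param structures list of [StructureChain] objects.
#' @param domainSeq domain sequence the alignment columns correspond to.
#' @param definition,threshold,minSeparation contact definition (defaults
#'   `"cbeta"`, 8 A, 5).
#' @param maxStructures cap on structures per family (default 30).
#' @param minCoverage mapping coverage threshold (default 0.8).
#' @param nMax prediction-count cap for the curves (default L).
#' @return list with `curves` (named list of averaged data.frames),
#'   `auc` (named), `improvementPct` (named, excludes base),
#'   `nStructures`.
#' @export
familyEvaluation <- function(scoreVariants, structures, domainSeq,
                             definition = "cbeta", threshold = 8,
                             minSeparation = 5L, maxStructures = 30L,
                             minCoverage = 0.8, nMax = NULL) {
  stopifnot("base" %in% names(scoreVariants))
  maps <- lapply(structures, function(ch)
    suppressWarnings(mapColumnsToStructure(domainSeq, ch, minCoverage)))
  keep <- which(vapply(maps, `[[`, logical(1), "passes"))
  if (!length(keep)) stop("no structure passes the coverage rule")
  structures <- structures[keep]; maps <- maps[keep]
  # unique sequences, best resolution first, ties by identifier
  seqs <- vapply(structures, chainSequence, character(1))
  res <- vapply(structures, function(ch) ch@resolution, numeric(1))
  ids <- vapply(structures, function(ch) ch@id, character(1))
  ord <- order(res, ids)
  ord <- ord[!duplicated(seqs[ord])]
  ord <- utils::head(ord, maxStructures)
  structures <- structures[ord]; maps <- maps[ord]

  ranked <- lapply(scoreVariants, rankPairs)
  allCurves <- lapply(seq_along(structures), function(k) {
    cmap <- contactMap(structures[[k]], definition, threshold, minSeparation)
    lapply(ranked, evaluateRanking, cmap = cmap, mapping = maps[[k]],
           nMax = nMax)
  })
  nMin <- min(vapply(allCurves, function(cs)
    min(vapply(cs, nrow, integer(1))), integer(1)))
  curves <- lapply(names(scoreVariants), function(v) {
    acc <- rowMeans(sapply(allCurves, function(cs)
      cs[[v]]$accuracy[seq_len(nMin)]))
    data.frame(n = seq_len(nMin), accuracy = acc,
               fracL = seq_len(nMin) / nchar(domainSeq))
  })
  names(curves) <- names(scoreVariants)
  auc <- vapply(curves, function(cv)
    if (nrow(cv) > 1L) pracma::trapz(cv$n, cv$accuracy) else cv$accuracy,
    numeric(1))
  others <- setdiff(names(scoreVariants), "base")
  imp <- vapply(others, function(v)
    aucImprovement(curves[["base"]], curves[[v]]), numeric(1))
  list(curves = curves, auc = auc, improvementPct = imp,
       nStructures = length(structures))
}

#' Improvement as a function of the contact-distance threshold
#'
#' For each threshold (Cb definition), recomputes the family contact maps
#' and the percent AUC improvement of the combined score over the
#' amino-acid score, and averages across families.
#'
#' @param families list of families, each a list with `aa`, `codon`
#'   ([ScoreMatrix]) and `chain` ([StructureChain]).
#' @param thresholds positive, strictly ascending Cb distance thresholds
#'   in Angstrom.
#' @param alpha combination power (default [defaultAlpha()] of the base
#'   method).
#' @param minSeparation,eps,nMax passed through.
#' @return data.frame with columns `threshold` and `meanImprovementPct`.
#' @export
thresholdSweep <- function(families, thresholds, alpha = NULL,
                           minSeparation = 5L, eps = 1e-10, nMax = NULL) {
  stopifnot(all(thresholds > 0))
  if (any(duplicated(thresholds))) stop("duplicate thresholds in input")
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  if (is.null(alpha)) alpha <- defaultAlpha(scoreMethod(families[[1]]$aa))
  imp <- sapply(thresholds, function(th) {
    mean(vapply(families, function(fam) {
      cmap <- contactMap(fam$chain, "cbeta", th, minSeparation)
      comb <- combineScores(fam$aa, fam$codon, alpha, eps)
      base <- evaluateRanking(rankPairs(fam$aa), cmap, nMax = nMax)
      cc <- evaluateRanking(rankPairs(comb), cmap, nMax = nMax)
      aucImprovement(base, cc)
    }, numeric(1)))
  })
  data.frame(threshold = thresholds, meanImprovementPct = imp)
}
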