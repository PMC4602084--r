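#' Combine amino-acid and codon score matrices
#'
#' The codon-aware combined score
#' `S(i,j) = max(S_AA(i,j), eps)^alpha / max(S_C(i,j), eps)`:
#' it grows with the strength of the amino-acid-level correlation and
#' shrinks with the strength of the codon-level correlation, demoting
#' pairs whose correlation is also strong at the codon level.  Scores
#' that can be negative (MIp, APC-corrected PSICOV) are clamped to the
#' floor `eps` before exponentiation so the ratio stays finite and
#' order-preserving among positive scores.
#'
#' @param sAA [ScoreMatrix] from the amino-acid alignment.
#' @param sC [ScoreMatrix] from the codon alignment (same method family,
#'   same L and minSeparation).
#' @param alpha positive power weighting the amino-acid term.
#' @param eps positive floor applied to both numerator base and
#'   denominator (default 1e-10).
#' @return a [ScoreMatrix] with method `"combined"`.
#' @export
combineScores <- function(sAA, sC, alpha, eps = 1e-10) {
  stopifnot(alpha > 0, eps > 0)
  if (!all(dim(scoreValues(sAA)) == dim(scoreValues(sC))))
    stop("amino-acid and codon score matrices differ in size")
  if (sAA@minSeparation != sC@minSeparation)
    stop("minSeparation mismatch between the two score matrices")
  S <- pmax(scoreValues(sAA), eps)^alpha / pmax(scoreValues(sC), eps)
  diag(S) <- 0
  ScoreMatrix(S, "combined", sAA@alphabetTag, sAA@minSeparation)
}

#' Default combination powers per method
#'
#' The powers that maximise the median AUC improvement for each base
#' method on large natural-family benchmarks: 2.5 for DCA and MI, 1.7
#' for OMES and 11.2 for PSICOV (run without APC).
#'
#' @param method method label.
#' @return numeric alpha.
#' @export
defaultAlpha <- function(method = c("DCA", "MI", "OMES", "PSICOV", "PSICOV*", "MIp")) {
  method <- match.arg(method)
  c(DCA = 2.5, MI = 2.5, OMES = 1.7, PSICOV = 11.2, `PSICOV*` = 11.2,
    MIp = 2.5)[[method]]
}

familyImprovement <- function(fam, alpha, eps = 1e-10, nMax = NULL) {
  comb <- combineScores(fam$aa, fam$codon, alpha, eps)
  base <- accuracyCurve(rankPairs(fam$aa), fam$contacts, nMax = nMax)
  cc <- accuracyCurve(rankPairs(comb), fam$contacts, nMax = nMax)
  aucImprovement(base, cc)
}

#' Fit the combination power alpha on a set of families
#'
#' For every alpha on the grid, computes the per-family percent AUC
#' improvement of the combined score over the amino-acid-only score
#' (accuracy-vs-number-of-predictions curves over the top 1..L
#' predictions) and records the median across families; returns the
#' maximising alpha.  Ties take the smallest alpha.
#'
#' @param families list of families, each a list with components `aa`
#'   ([ScoreMatrix]), `codon` ([ScoreMatrix]) and `contacts`
#'   ([ContactMap] ground truth on the same columns).
#' @param grid ordered alpha values (default 0.1 to 20 in steps of 0.1).
#' @param eps score floor passed to [combineScores()].
#' @param nMax cap on the number of predictions in the accuracy curve
#'   (default: the alignment length L).
#' @return list with `grid`, `medianImprovement` (per grid point),
#'   `alphaMax`, and `improvementsAtMax` (per family, percent).
#' @export
fitAlpha <- function(families, grid = seq(0.1, 20, by = 0.1), eps = 1e-10,
                     nMax = NULL) {
  if (length(families) < 1L) stop("need at least one family")
  if (length(grid) < 1L) stop("alpha grid must be nonempty")
  imp <- sapply(grid, function(a)
    stats::median(vapply(families, familyImprovement, numeric(1),
                         alpha = a, eps = eps, nMax = nMax)))
  kmax <- which.max(imp)
  alphaMax <- grid[kmax]
  perFam <- vapply(families, familyImprovement, numeric(1),
                   alpha = alphaMax, eps = eps, nMax = nMax)
  res <- list(grid = grid, medianImprovement = imp, alphaMax = alphaMax,
              improvementsAtMax = perFam)
  class(res) <- "AlphaFitResult"
  res
}

#' @export
print.AlphaFitResult <- function(x, ...) {
  cat(sprintf("AlphaFitResult: alphaMax = %.2f, median improvement %.2f%% (%d grid points, %d families)\n",
              x$alphaMax, max(x$medianImprovement), length(x$grid),
              length(x$improvementsAtMax)))
  invisible(x)
}

#' Random-split cross-validation of the fitted alpha
#'
#' Repeatedly halves the family set at random, fits `alphaMax` on the
#' learning half and records the median percent AUC improvement that
#' alpha achieves on the test half.  Agreement between learning and test
#' distributions indicates the fitted power does not overfit the family
#' set.
#'
#' @param families as in [fitAlpha()]; at least 2.
#' @param nSplits number of random splits.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param grid alpha grid for the learning-half fit.
#' @param eps,nMax passed through.
#' @return list with vectors `test` and `learning` (median improvements
#'   per split), `alpha` (fitted per split), and means of both.
#' @export
cvAlphaStability <- function(families, nSplits = 200L, seed,
                             grid = seq(0.1, 20, by = 0.1), eps = 1e-10,
                             nMax = NULL) {
  if (length(families) < 2L) stop("need at least two families")
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  nf <- length(families)
  half <- floor(nf / 2)
  test <- learning <- alphas <- numeric(nSplits)
  for (k in seq_len(nSplits)) {
    idx <- sample.int(nf, half)
    fitL <- fitAlpha(families[idx], grid = grid, eps = eps, nMax = nMax)
    learning[k] <- max(fitL$medianImprovement)
    alphas[k] <- fitL$alphaMax
    test[k] <- stats::median(vapply(families[-idx], familyImprovement,
                                    numeric(1), alpha = fitL$alphaMax,
                                    eps = eps, nMax = nMax))
  }
  list(test = test, learning = learning, alpha = alphas,
       meanTest = mean(test), meanLearning = mean(learning))
}
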