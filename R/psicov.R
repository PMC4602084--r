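#' Sparse inverse-covariance (PSICOV-style) pair scores
#'
#' One-hot encodes q-1 states per column (the gap is the dropped
#' reference state), forms the weighted sample covariance matrix, shrinks
#' it towards its diagonal until positive definite, and estimates a
#' sparse precision matrix by L1-penalised inverse covariance (graphical
#' lasso) with penalty `rho`.  The pair score is the L1 norm of the
#' corresponding precision block,
#' `S(i,j) = sum_ab | Theta(i,a; j,b) |`, with the average product
#' correction subtracted when `applyApc` is on.  The no-APC variant is
#' labelled `PSICOV*`.
#'
#' A sequence-diversity guard mirrors the original tool's refusal to run
#' on shallow alignments: with `diversityCheck` on, alignments with
#' `Meff < minMeff` are rejected.
#'
#' @param msa an [Msa].
#' @param rho L1 penalty (default 0.001, the original's fast setting).
#' @param applyApc subtract the APC term (default TRUE; FALSE gives
#'   `PSICOV*`).
#' @param diversityCheck enforce the `minMeff` diversity threshold.
#' @param minMeff minimum effective sequence number (default 125).
#' @param identityThreshold reweighting threshold (default 0.8).
#' @param minSeparation minimum sequence separation for ranking.
#' @param maxIter,tol graphical-lasso iteration cap and tolerance.
#' @param maxDim refuse `L*(q-1)` above this size unless raised.
#' @return a [ScoreMatrix] with method `"PSICOV"` or `"PSICOV*"`.
#' @export
psicovScores <- function(msa, rho = 0.001, applyApc = TRUE,
                         diversityCheck = TRUE, minMeff = 125,
                         identityThreshold = 0.8, minSeparation = 5L,
                         maxIter = 100L, tol = 1e-4, maxDim = 20000L) {
  q <- alphabetSize(msaAlphabet(msa))
  L <- nCol(msa)
  p <- L * (q - 1L)
  if (p > maxDim)
    stop(sprintf("L*(q-1) = %d exceeds maxDim = %d; raise maxDim to override",
                 p, maxDim))
  if (identityThreshold < 1) {
    cw <- computeWeights(msa, identityThreshold)
    seqWeights(msa) <- cw$weights
  }
  w <- seqWeights(msa)
  Meff <- sum(w)
  if (diversityCheck && Meff < minMeff)
    stop(sprintf(paste0("alignment did not pass this method's threshold for ",
                        "sequence diversity (Meff = %.1f < %g); set ",
                        "diversityCheck = FALSE to override"), Meff, minMeff))
  X <- as.matrix(oneHot(msa, dropGap = TRUE))
  wn <- w / Meff
  mu <- colSums(X * wn)
  Xc <- sweep(X, 2L, mu, "-")
  S <- crossprod(Xc * sqrt(wn))               # weighted covariance

  # shrink towards the diagonal until positive definite
  dS <- diag(diag(S))
  gamma <- 0
  repeat {
    Ssh <- (1 - gamma) * S + gamma * dS + 1e-8 * mean(diag(S)) * diag(p)
    ok <- tryCatch({ chol(Ssh); TRUE }, error = function(e) FALSE)
    if (ok) break
    gamma <- gamma + 0.05
    if (gamma > 1) stop("covariance matrix could not be made positive definite")
  }

  fit <- glasso_cpp(Ssh, rho, as.integer(maxIter), tol)
  if (!fit$converged)
    stop(sprintf("graphical lasso did not converge (final duality-gap criterion %.3g)",
                 fit$crit))
  Theta <- fit$theta

  Sm <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    ri <- ((i - 1L) * (q - 1L) + 1L):(i * (q - 1L))
    for (j in (i + 1L):L) {
      rj <- ((j - 1L) * (q - 1L) + 1L):(j * (q - 1L))
      Sm[i, j] <- sum(abs(Theta[ri, rj]))
    }
  }
  out <- ScoreMatrix(Sm + t(Sm), if (applyApc) "PSICOV" else "PSICOV*",
                     alphabetTag(msaAlphabet(msa)), minSeparation)
  if (applyApc) {
    corrected <- apcCorrect(out)
    out <- ScoreMatrix(scoreValues(corrected), "PSICOV",
                       out@alphabetTag, out@minSeparation)
  }
  out
}
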