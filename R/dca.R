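#' Mean-field direct coupling analysis (DCA)
#'
#' The mean-field recipe: identity-based sequence reweighting, heavily
#' pseudocounted frequencies, connected correlation matrix
#' `C(i,a; j,b) = f(i,a;j,b) - f(i,a) f(j,b)` over q-1 states per site
#' (the gap is the gauge state and is dropped), couplings `e = -C^-1`,
#' and for every pair a two-site "direct" distribution
#' `P_dir(a,b) ~ exp(e_ij(a,b)) mu_i(a) mu_j(b)` whose fields `mu` are
#' fitted to the single-site marginals by iterative proportional fitting.
#' The score is the direct information
#' `DI(i,j) = sum_ab P_dir(a,b) log[ P_dir(a,b) / (f(i,a) f(j,b)) ]`,
#' which is nonnegative and symmetric.
#'
#' @param msa an [Msa] (amino-acid or codon alphabet).
#' @param lambda pseudocount weight; default `Meff` (the standard
#'   mean-field choice).  Must be > 0 in practice or `C` is singular.
#' @param identityThreshold reweighting identity threshold (default 0.8);
#'   set to 1 to keep the weights already stored in the alignment.
#' @param minSeparation minimum sequence separation for ranking.
#' @param tol convergence tolerance of the two-site fit (default 1e-4).
#' @param maxIter maximum iterations of the two-site fit (default 500).
#' @param maxDim refuse problems with `L*(q-1)` above this size unless
#'   raised; guards against accidental huge codon-alphabet inversions.
#' @return a [ScoreMatrix] with method `"DCA"` holding DI values.
#' @export
mfdcaScores <- function(msa, lambda = NULL, identityThreshold = 0.8,
                        minSeparation = 5L, tol = 1e-4, maxIter = 500L,
                        maxDim = 20000L) {
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
  Meff <- sum(seqWeights(msa))
  if (Meff <= 1) stop("effective number of sequences must exceed 1")
  if (is.null(lambda)) lambda <- Meff
  freq <- siteFrequencies(msa, lambda = lambda, useWeights = TRUE)

  keep <- which(((seq_len(L * q) - 1L) %% q) + 1L <= q - 1L)  # drop gap state
  Fv <- as.vector(t(freq@fi))
  C <- freq@fij[keep, keep] - outer(Fv[keep], Fv[keep])
  invC <- tryCatch(solve(C), error = function(e)
    stop("connected correlation matrix is singular; use a pseudocount lambda > 0 (",
         conditionMessage(e), ")"))

  S <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    ri <- ((i - 1L) * (q - 1L) + 1L):(i * (q - 1L))
    fi <- freq@fi[i, ]
    for (j in (i + 1L):L) {
      rj <- ((j - 1L) * (q - 1L) + 1L):(j * (q - 1L))
      W <- matrix(1, q, q)
      W[1:(q - 1L), 1:(q - 1L)] <- exp(-invC[ri, rj])
      fj <- freq@fi[j, ]
      S[i, j] <- directInformation(W, fi, fj, tol, maxIter)
    }
  }
  ScoreMatrix(S + t(S), "DCA", freq@tag, minSeparation)
}

# two-site model: fit fields by iterative proportional fitting, return DI
directInformation <- function(W, fi, fj, tol = 1e-4, maxIter = 500L) {
  q <- length(fi)
  mu1 <- rep(1 / q, q)
  mu2 <- rep(1 / q, q)
  for (it in seq_len(maxIter)) {
    s1 <- as.vector(W %*% mu2)
    new1 <- fi / s1; new1 <- new1 / sum(new1)
    s2 <- as.vector(crossprod(W, new1))
    new2 <- fj / s2; new2 <- new2 / sum(new2)
    d <- max(abs(new1 - mu1), abs(new2 - mu2))
    mu1 <- new1; mu2 <- new2
    if (d < tol) break
  }
  P <- W * outer(mu1, mu2)
  P <- P / sum(P)
  E <- outer(fi, fj)
  sum(P * log(P / E))
}
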