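#' Single-site and pair frequency model of an alignment
#'
#' Holds the (optionally reweighted and pseudocounted) empirical
#' frequencies of an [Msa]: single-site frequencies `f(i,a)` as an L x q
#' matrix and pair frequencies `f(i,a; j,b)` as an (Lq) x (Lq) matrix in
#' site-major blocks of size q.  With pseudocount weight lambda,
#' `f(i,a) = (lambda/q + n_i(a)) / (lambda + Meff)` and pair frequencies
#' use `lambda/q^2` off the diagonal blocks (`lambda/q` on the matching
#' diagonal of block (i,i), keeping the single-site marginal exact).
#'
#' @slot fi L x q matrix of single-site frequencies.
#' @slot fij (Lq) x (Lq) matrix of pair frequencies.
#' @slot lambda pseudocount weight (same units as Meff).
#' @slot Meff effective number of sequences behind the counts.
#' @slot L,q dimensions.
#' @slot tag alphabet tag of the source alignment.
#' @aliases FrequencyModel
#' @exportClass FrequencyModel
setClass("FrequencyModel",
  representation(fi = "matrix", fij = "matrix", lambda = "numeric",
                 Meff = "numeric", L = "integer", q = "integer",
                 tag = "character"))

setValidity("FrequencyModel", function(object) {
  msg <- character()
  if (!all(dim(object@fi) == c(object@L, object@q)))
    msg <- c(msg, "fi must be L x q")
  if (!all(dim(object@fij) == rep(object@L * object@q, 2L)))
    msg <- c(msg, "fij must be (Lq) x (Lq)")
  if (any(object@fi < -1e-12 | object@fi > 1 + 1e-12))
    msg <- c(msg, "frequencies must lie in [0, 1]")
  rs <- rowSums(object@fi)
  if (any(abs(rs - 1) > 1e-9))
    msg <- c(msg, "single-site frequencies must sum to 1 per site")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FrequencyModel", function(object) {
  cat(sprintf("FrequencyModel <%s>: L = %d, q = %d, lambda = %.3g, Meff = %.2f\n",
              object@tag, object@L, object@q, object@lambda, object@Meff))
})

#' Count site and pair frequencies of an alignment
#'
#' @param msa an [Msa].
#' @param lambda pseudocount weight, >= 0, in units of sequences (the
#'   mean-field DCA convention; `lambda = Meff` is the usual DCA choice,
#'   `lambda = 0` plain counting for MI/OMES).
#' @param useWeights use the per-sequence weights stored in `msa`
#'   (default) or treat all sequences equally.
#' @return a [FrequencyModel].
#' @export
siteFrequencies <- function(msa, lambda = 0, useWeights = TRUE) {
  stopifnot(lambda >= 0)
  L <- nCol(msa)
  q <- alphabetSize(msaAlphabet(msa))
  w <- if (useWeights) seqWeights(msa) else rep(1, nSeq(msa))
  Meff <- sum(w)
  X <- oneHot(msa, dropGap = FALSE)
  ci <- as.vector(Matrix::crossprod(X, w))               # Lq counts
  cij <- as.matrix(Matrix::crossprod(X, X * w))          # (Lq) x (Lq)
  denom <- lambda + Meff
  fi <- matrix((lambda / q + ci) / denom, L, q, byrow = TRUE)
  fij <- (lambda / q^2 + cij) / denom
  # diagonal blocks: f(i,a; i,b) = delta_ab * f(i,a)
  for (i in seq_len(L)) {
    ix <- ((i - 1L) * q + 1L):(i * q)
    blk <- matrix(0, q, q)
    diag(blk) <- (lambda / q + ci[ix]) / denom
    fij[ix, ix] <- blk
  }
  new("FrequencyModel", fi = fi, fij = fij, lambda = lambda,
      Meff = Meff, L = L, q = as.integer(q),
      tag = alphabetTag(msaAlphabet(msa)))
}

# rows of fij belonging to site i
siteBlock <- function(freq, i) ((i - 1L) * freq@q + 1L):(i * freq@q)

#' Per-column Shannon entropies (natural log)
#'
#' @param freq a [FrequencyModel].
#' @return numeric vector of L entropies in nats.
#' @export
columnEntropies <- function(freq) {
  apply(freq@fi, 1L, function(p) { p <- p[p > 0]; -sum(p * log(p)) })
}
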