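#' Symmetric pair-score matrix
#'
#' The common container all coevolution scorers return: a symmetric L x L
#' matrix of pair scores tagged with the method, the alphabet it was
#' computed on, and the minimum sequence separation used when ranking.
#' The diagonal and pairs closer than `minSeparation` are not meaningful
#' and are excluded by [rankPairs()].
#'
#' @slot scores symmetric numeric L x L matrix.
#' @slot method one of `"OMES"`, `"MI"`, `"MIp"`, `"DCA"`, `"PSICOV"`,
#'   `"PSICOV*"`, `"combined"`.
#' @slot alphabetTag `"aa"` or `"codon"`.
#' @slot minSeparation minimum `j - i` for a pair to be ranked.
#' @aliases ScoreMatrix
#' @exportClass ScoreMatrix
setClass("ScoreMatrix",
  representation(scores = "matrix", method = "character",
                 alphabetTag = "character", minSeparation = "integer"))

setValidity("ScoreMatrix", function(object) {
  msg <- character()
  s <- object@scores
  if (nrow(s) != ncol(s)) msg <- c(msg, "scores must be square")
  if (max(abs(s - t(s)), na.rm = TRUE) > 1e-8)
    msg <- c(msg, "scores must be symmetric")
  if (object@minSeparation < 1L) msg <- c(msg, "minSeparation must be >= 1")
  if (length(msg)) msg else TRUE
})

ScoreMatrix <- function(scores, method, alphabetTag, minSeparation = 5L) {
  scores <- (scores + t(scores)) / 2
  diag(scores) <- 0
  new("ScoreMatrix", scores = scores, method = method,
      alphabetTag = alphabetTag, minSeparation = as.integer(minSeparation))
}

#' @describeIn ScoreMatrix the raw L x L score matrix.
#' @param x a [ScoreMatrix].
#' @export
scoreValues <- function(x) x@scores

#' @describeIn ScoreMatrix the method label.
#' @export
scoreMethod <- function(x) x@method

setMethod("show", "ScoreMatrix", function(object) {
  cat(sprintf("ScoreMatrix [%s, %s]: L = %d, minSeparation = %d\n",
              object@method, object@alphabetTag, nrow(object@scores),
              object@minSeparation))
})

# block aggregation helper: (Lq) x (Lq) -> L x L sums per site block
blockSums <- function(bigmat, L, q) {
  G <- Matrix::sparseMatrix(i = seq_len(L * q), j = rep(seq_len(L), each = q), x = 1)
  as.matrix(Matrix::crossprod(G, bigmat %*% G))
}

#' OMES (observed-minus-expected-squared) pair scores
#'
#' `S(i,j) = sum_ab (OBS_ab - EXP_ab)^2` where OBS is the observed number
#' of sequences with state a at i and b at j, and `EXP = M f(i,a) f(j,b)`.
#' Counts come from the frequency model, so pass `lambda = 0` (the
#' formula has no smoothing); with reweighting, M is Meff.
#'
#' @param freq a [FrequencyModel] with `lambda = 0`.
#' @param minSeparation minimum sequence separation for ranking (default 5).
#' @return a [ScoreMatrix] with method `"OMES"`.
#' @export
omesScores <- function(freq, minSeparation = 5L) {
  if (freq@lambda != 0)
    stop("OMES is defined on raw counts; use a FrequencyModel with lambda = 0")
  Fv <- as.vector(t(freq@fi))                     # site-major Lq vector
  D <- freq@fij - outer(Fv, Fv)
  S <- freq@Meff^2 * blockSums(D * D, freq@L, freq@q)
  ScoreMatrix(S, "OMES", freq@tag, minSeparation)
}

#' Mutual information pair scores
#'
#' `S(i,j) = sum_ab f(i,a;j,b) log[ f(i,a;j,b) / (f(i,a) f(j,b)) ]` with
#' natural logarithms and the convention `0 log 0 = 0`.  The sum runs over
#' all q states including the gap.
#'
#' @param freq a [FrequencyModel].
#' @inheritParams omesScores
#' @return a [ScoreMatrix] with method `"MI"`.
#' @export
miScores <- function(freq, minSeparation = 5L) {
  Fv <- as.vector(t(freq@fi))
  E <- outer(Fv, Fv)
  P <- freq@fij
  Tm <- matrix(0, nrow(P), ncol(P))
  pos <- P > 0
  Tm[pos] <- P[pos] * log(P[pos] / E[pos])
  S <- blockSums(Tm, freq@L, freq@q)
  diag(S) <- 0
  ScoreMatrix(S, "MI", freq@tag, minSeparation)
}

#' Average product correction (MIp)
#'
#' Subtracts the APC background term
#' `APC(i,j) = MI(i,.) MI(j,.) / MIbar`, where `MI(i,.)` is the mean score
#' of column i with all other columns and `MIbar` the mean over all
#' off-diagonal pairs.  Output scores can be negative.
#'
#' @param sm a [ScoreMatrix] (typically MI-type).
#' @return a [ScoreMatrix] with method `"MIp"` (or `"<method>-APC"` for
#'   non-MI inputs).
#' @export
apcCorrect <- function(sm) {
  S <- scoreValues(sm)
  L <- nrow(S)
  if (L < 2L) stop("need at least two columns")
  off <- S; diag(off) <- NA
  mi <- rowMeans(off, na.rm = TRUE)
  mbar <- mean(off[upper.tri(off)], na.rm = TRUE)
  if (mbar == 0) {
    warning("mean background score is zero (degenerate alignment); returning zeros")
    out <- matrix(0, L, L)
  } else {
    out <- S - outer(mi, mi) / mbar
    diag(out) <- 0
  }
  method <- if (scoreMethod(sm) == "MI") "MIp" else paste0(scoreMethod(sm), "-APC")
  ScoreMatrix(out, method, sm@alphabetTag, sm@minSeparation)
}

#' Rank column pairs by score
#'
#' Valid pairs (`j - i >= minSeparation`) sorted by descending score, ties
#' broken by ascending `(i, j)`; positions are 1-based.
#'
#' @param sm a [ScoreMatrix].
#' @return data.frame with columns `i`, `j`, `score`.
#' @export
rankPairs <- function(sm) {
  S <- scoreValues(sm)
  L <- nrow(S)
  sep <- sm@minSeparation
  idx <- which(upper.tri(S) & (col(S) - row(S) >= sep), arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], score = S[idx])
  df <- df[order(-df$score, df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write ranked pair scores to a tab-separated file
#'
#' Columns `i  j  score  method  alphabet`, 1-based positions, in
#' [rankPairs()] order.
#'
#' @param sm a [ScoreMatrix].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeScores <- function(sm, path) {
  df <- rankPairs(sm)
  df$method <- scoreMethod(sm)
  df$alphabet <- sm@alphabetTag
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score file written by [writeScores()]
#'
#' @param path tab-separated score file.
#' @param L alignment length (inferred from the largest index if missing).
#' @param minSeparation minimum separation to record.
#' @return a [ScoreMatrix].
#' @export
readScores <- function(path, L = NULL, minSeparation = 5L) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (is.null(L)) L <- max(df$i, df$j)
  S <- matrix(0, L, L)
  S[cbind(df$i, df$j)] <- df$score
  S[cbind(df$j, df$i)] <- df$score
  ScoreMatrix(S, method = if (nrow(df)) df$method[1] else "unknown",
              alphabetTag = if (nrow(df)) df$alphabet[1] else "aa",
              minSeparation = minSeparation)
}
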