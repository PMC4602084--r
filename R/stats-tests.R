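#' Exact sign test on per-family improvements
#'
#' Two-sided exact binomial test on the number of positive versus
#' negative improvements; zero improvements are dropped.
#'
#' @param deltas numeric vector of per-family improvements.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return p-value.
#' @export
signTest <- function(deltas, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  d <- deltas[deltas != 0]
  if (!length(d)) stop("all improvements are zero; sign test undefined")
  stats::binom.test(sum(d > 0), length(d), p = 0.5,
                    alternative = alternative)$p.value
}

#' Wilcoxon signed-rank test with an exact null under ties
#'
#' Zero improvements are dropped and ties in absolute value receive
#' mid-ranks.  In exact mode the null distribution of
#' `W = sum of ranks of positive values` is computed by enumerating the
#' 2^n sign assignments through a generating-function convolution (exact
#' even with tied ranks); in asymptotic mode a normal approximation with
#' tie correction and continuity correction is used.  `"auto"` uses the
#' exact null for n <= 25.
#'
#' @param deltas numeric vector.
#' @param mode `"auto"`, `"exact"` or `"asymptotic"`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return p-value.
#' @export
wilcoxonSignedRank <- function(deltas, mode = c("auto", "exact", "asymptotic"),
                               alternative = c("two.sided", "greater", "less")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  d <- deltas[deltas != 0]
  n <- length(d)
  if (!n) stop("all improvements are zero; signed-rank test undefined")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (mode == "auto") mode <- if (n <= 25L) "exact" else "asymptotic"
  if (mode == "exact") {
    r2 <- as.integer(round(2 * r))      # mid-ranks are multiples of 1/2
    W2 <- as.integer(round(2 * W))
    tot <- sum(r2)
    counts <- numeric(tot + 1L)          # counts[w+1] = #assignments with W2 = w
    counts[1L] <- 1
    for (rk in r2) {
      shifted <- c(rep(0, rk), counts[seq_len(tot + 1L - rk)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    pGe <- sum(probs[(W2 + 1L):(tot + 1L)])
    pLe <- sum(probs[1L:(W2 + 1L)])
    p <- switch(alternative,
                two.sided = min(1, 2 * min(pGe, pLe)),
                greater = pGe,
                less = pLe)
  } else {
    mu <- sum(r) / 2
    tiecor <- sum(tapply(r, r, length)^3 - tapply(r, r, length)) / 48
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tiecor)
    z <- W - mu
    cc <- 0.5                            # continuity correction
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm((abs(z) - cc) / sigma,
                                             lower.tail = FALSE),
                greater = stats::pnorm((z - cc) / sigma, lower.tail = FALSE),
                less = stats::pnorm((z + cc) / sigma))
    p <- min(1, max(p, .Machine$double.xmin))
  }
  p
}

#' Summary of per-family improvements
#'
#' Counts of improved/worsened/tied families, the median improvement and
#' both nonparametric p-values (Wilcoxon signed-rank and sign test,
#' two-sided).
#'
#' @param deltas numeric vector of per-family percent improvements; at
#'   least 2.
#' @return list of class `ImprovementSummary` with fields `nImproved`,
#'   `nWorsened`, `nTied`, `medianImprovement`, `pWilcoxon`, `pSign`.
#' @export
summarizeImprovements <- function(deltas) {
  if (length(deltas) < 2L) stop("need at least two families")
  out <- list(nImproved = sum(deltas > 0),
              nWorsened = sum(deltas < 0),
              nTied = sum(deltas == 0),
              medianImprovement = stats::median(deltas),
              pWilcoxon = wilcoxonSignedRank(deltas),
              pSign = signTest(deltas))
  class(out) <- "ImprovementSummary"
  out
}

#' @export
print.ImprovementSummary <- function(x, ...) {
  cat(sprintf("Improved %d / worsened %d / tied %d; median %.3f%%\n",
              x$nImproved, x$nWorsened, x$nTied, x$medianImprovement))
  cat(sprintf("Wilcoxon signed-rank p = %.3g; sign test p = %.3g\n",
              x$pWilcoxon, x$pSign))
  invisible(x)
}
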