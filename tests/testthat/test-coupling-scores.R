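test_that("OMES matches hand enumeration and the brute-force oracle", {
  # factorised columns: observed == expected everywhere -> 0
  st <- cbind(rep(1:2, each = 4), rep(1:2, times = 4))
  m <- Msa(cbind(st, st[, 1]), aminoAcidAlphabet())
  S <- scoreValues(omesScores(siteFrequencies(m)))
  expect_equal(S[1, 2], 0, tolerance = 1e-12)

  # perfectly correlated 2x2 split of 8 sequences: 4 cells of (4-2)^2
  m2 <- Msa(cbind(rep(c(1L, 2L), each = 4), rep(c(3L, 4L), each = 4)),
            aminoAcidAlphabet())
  S2 <- scoreValues(omesScores(siteFrequencies(m2)))
  expect_equal(S2[1, 2], 16)

  # random msa vs quadruple-loop oracle
  m3 <- randomMsa(20, 6, seed = 14)
  expect_equal(scoreValues(omesScores(siteFrequencies(m3))),
               oracleOmes(m3), tolerance = 1e-10)
})

test_that("MI matches closed forms and the summation oracle", {
  # independent columns in exact product configuration -> 0
  st <- cbind(rep(1:2, each = 2), rep(3:4, times = 2))
  m <- Msa(st, aminoAcidAlphabet())
  expect_equal(scoreValues(miScores(siteFrequencies(m)))[1, 2], 0,
               tolerance = 1e-12)

  # perfectly correlated 50/50 binary columns -> ln 2
  m2 <- Msa(cbind(rep(c(1L, 2L), each = 25), rep(c(7L, 9L), each = 25)),
            aminoAcidAlphabet())
  expect_equal(scoreValues(miScores(siteFrequencies(m2)))[1, 2], log(2),
               tolerance = 1e-12)

  # random msa vs oracle to 1e-10
  m3 <- randomMsa(20, 8, seed = 21)
  expect_equal(scoreValues(miScores(siteFrequencies(m3))),
               oracleMi(m3), tolerance = 1e-10)
})

test_that("MI is bounded by the smaller column entropy", {
  for (seed in c(4, 44)) {
    m <- randomMsa(25, 7, seed = seed)
    fr <- siteFrequencies(m)
    S <- scoreValues(miScores(fr))
    H <- columnEntropies(fr)
    bound <- outer(H, H, pmin)
    expect_true(all(S <= bound + 1e-9))
  }
})

test_that("APC correction matches arithmetic and zeroes constant matrices", {
  # constant off-diagonal MI: APC = c*c/c = c -> MIp identically 0
  Sc <- matrix(0.37, 6, 6); diag(Sc) <- 0
  sm <- codonCMA:::ScoreMatrix(Sc, "MI", "aa", 5L)
  expect_equal(max(abs(scoreValues(apcCorrect(sm)))), 0, tolerance = 1e-12)

  # L=3 hand-computed case
  S3 <- matrix(0, 3, 3)
  S3[1, 2] <- S3[2, 1] <- 0.4
  S3[1, 3] <- S3[3, 1] <- 0.2
  S3[2, 3] <- S3[3, 2] <- 0.1
  sm3 <- codonCMA:::ScoreMatrix(S3, "MI", "aa", 1L)
  got <- scoreValues(apcCorrect(sm3))
  expect_equal(got, oracleApc(S3), tolerance = 1e-12)
  # spot-check one cell fully by hand:
  # MI(1,.)=0.3, MI(2,.)=0.25, MIbar=(0.4+0.2+0.1)/3
  expect_equal(got[1, 2], 0.4 - 0.3 * 0.25 / (0.7 / 3), tolerance = 1e-12)

  # symmetry preserved on random symmetric input
  set.seed(3)
  R <- matrix(runif(64), 8, 8); R <- (R + t(R)) / 2; diag(R) <- 0
  out <- scoreValues(apcCorrect(codonCMA:::ScoreMatrix(R, "MI", "aa", 5L)))
  expect_equal(out, t(out))

  # degenerate all-zero matrix warns and returns zeros
  z <- codonCMA:::ScoreMatrix(matrix(0, 4, 4), "MI", "aa", 1L)
  expect_warning(zz <- apcCorrect(z), "degenerate")
  expect_equal(max(abs(scoreValues(zz))), 0)
})

test_that("OMES and MI vanish together on factorised tables", {
  # joint counts exactly the product of the margins
  st <- cbind(rep(c(1L, 1L, 2L, 2L), 3), rep(c(3L, 4L), 6))
  m <- Msa(st, aminoAcidAlphabet())
  fr <- siteFrequencies(m)
  expect_equal(scoreValues(miScores(fr))[1, 2], 0, tolerance = 1e-12)
  expect_equal(scoreValues(omesScores(fr))[1, 2], 0, tolerance = 1e-12)
})

test_that("pair ranking respects separation, order and ties", {
  S <- matrix(0, 7, 7)
  S[1, 6] <- S[6, 1] <- 0.5
  S[1, 7] <- S[7, 1] <- 0.5
  S[2, 7] <- S[7, 2] <- 0.9
  sm <- codonCMA:::ScoreMatrix(S, "MI", "aa", 5L)
  rp <- rankPairs(sm)
  # exactly the pairs with j - i >= 5
  expect_equal(nrow(rp), 3L)
  expect_equal(rp$i, c(2L, 1L, 1L))
  expect_equal(rp$j, c(7L, 6L, 7L))   # tie 0.5/0.5 broken by (i, j)

  # random matrix vs naive sort oracle
  set.seed(6)
  R <- matrix(runif(100), 10, 10); R <- (R + t(R)) / 2; diag(R) <- 0
  smr <- codonCMA:::ScoreMatrix(R, "MI", "aa", 3L)
  rp2 <- rankPairs(smr)
  pairs <- which(upper.tri(R) & col(R) - row(R) >= 3, arr.ind = TRUE)
  ord <- order(-R[pairs], pairs[, 1], pairs[, 2])
  expect_equal(rp2$i, pairs[ord, 1], ignore_attr = TRUE)
  expect_equal(rp2$j, pairs[ord, 2], ignore_attr = TRUE)
})

test_that("scorers are invariant to row permutation and equivariant to column permutation", {
  m <- randomMsa(30, 6, seed = 19)
  fr <- siteFrequencies(m)
  rowPerm <- Msa(msaStates(m)[sample(30), ], msaAlphabet(m))
  colPerm <- sample(6)
  colM <- Msa(msaStates(m)[, colPerm], msaAlphabet(m))
  for (fn in list(function(x) scoreValues(miScores(siteFrequencies(x))),
                  function(x) scoreValues(omesScores(siteFrequencies(x))))) {
    expect_equal(fn(rowPerm), fn(m), tolerance = 1e-10)
    expect_equal(fn(colM), fn(m)[colPerm, colPerm], tolerance = 1e-10)
  }
})

test_that("mean-field DCA recovers planted structure and stays symmetric", {
  # i.i.d. uniform columns: DI is pure inversion noise, bounded
  m <- randomMsa(500, 10, seed = 42)
  di <- mfdcaScores(m)
  expect_true(all(scoreValues(di) >= -1e-10))
  expect_equal(scoreValues(di), t(scoreValues(di)))
  expect_lt(max(scoreValues(di)), 0.2)

  # a perfectly covarying column pair dominates the ranking
  set.seed(7)
  st <- matrix(sample.int(21, 500 * 10, replace = TRUE), 500, 10)
  st[, 8] <- st[, 2]
  rd <- rankPairs(mfdcaScores(Msa(st, aminoAcidAlphabet())))
  expect_equal(c(rd$i[1], rd$j[1]), c(2L, 8L))
})

test_that("DCA separates planted couplings from noise at depth M = 2000", {
  m <- randomMsa(2000, 10, seed = 8)
  di <- mfdcaScores(m)
  expect_lt(max(scoreValues(di)), 0.05)
})

test_that("singular correlation matrix without pseudocount is diagnosed", {
  st <- matrix(rep(c(1L, 2L), each = 10), 20, 6)   # degenerate columns
  m <- Msa(st, aminoAcidAlphabet())
  expect_error(mfdcaScores(m, lambda = 0, identityThreshold = 1),
               "pseudocount|singular")
})

test_that("codon-alphabet solvers refuse oversized problems", {
  m <- randomMsa(20, 400, codonAlphabet(), seed = 2)
  expect_error(mfdcaScores(m), "maxDim")
  expect_error(psicovScores(m, diversityCheck = FALSE), "maxDim")
})

test_that("PSICOV-style scorer top-ranks planted pairs and shrinks noise", {
  set.seed(7)
  st <- matrix(sample.int(21, 500 * 10, replace = TRUE), 500, 10)
  st[, 8] <- st[, 2]
  ps <- psicovScores(Msa(st, aminoAcidAlphabet()), applyApc = FALSE)
  expect_equal(scoreMethod(ps), "PSICOV*")
  rp <- rankPairs(ps)
  expect_equal(c(rp$i[1], rp$j[1]), c(2L, 8L))

  # independent columns: no pair stands out (max within 10x median)
  m3 <- randomMsa(500, 10, seed = 9)
  r3 <- rankPairs(psicovScores(m3, applyApc = FALSE))
  expect_lt(max(r3$score), 10 * stats::median(r3$score))
})

test_that("PSICOV diversity guard mirrors the shallow-alignment refusal", {
  m <- randomMsa(50, 8, seed = 10)
  st <- msaStates(m); st[1:40, ] <- st[rep(1, 40), ]   # collapse diversity
  m <- Msa(st, msaAlphabet(m))
  expect_error(psicovScores(m), "diversity")
  expect_s4_class(psicovScores(m, diversityCheck = FALSE, applyApc = FALSE),
                  "ScoreMatrix")
})

test_that("APC on PSICOV scores zeroes a constant score matrix", {
  Sc <- matrix(2.2, 8, 8); diag(Sc) <- 0
  sm <- codonCMA:::ScoreMatrix(Sc, "PSICOV*", "aa", 5L)
  expect_equal(max(abs(scoreValues(apcCorrect(sm)))), 0, tolerance = 1e-12)
})

test_that("PSICOV at vanishing penalty approaches dense inverse-covariance scores", {
  m <- randomMsa(4000, 6, seed = 5)
  ps <- psicovScores(m, rho = 1e-8, applyApc = FALSE, diversityCheck = FALSE)
  # independent oracle: direct inversion of the same shrunk covariance
  cw <- computeWeights(m, 0.8)
  w <- cw$weights / sum(cw$weights)
  X <- as.matrix(codonCMA:::oneHot(m, dropGap = TRUE))
  mu <- colSums(X * w)
  Xc <- sweep(X, 2, mu, "-")
  S0 <- crossprod(Xc * sqrt(w))
  S <- S0 + 1e-8 * mean(diag(S0)) * diag(ncol(S0))
  Th <- solve(S)
  or <- matrix(0, 6, 6)
  for (i in 1:5) for (j in (i + 1):6)
    or[i, j] <- sum(abs(Th[((i - 1) * 20 + 1):(i * 20),
                           ((j - 1) * 20 + 1):(j * 20)]))
  v1 <- scoreValues(ps)[upper.tri(or)]
  v2 <- (or + t(or))[upper.tri(or)]
  expect_gt(stats::cor(v1, v2), 0.99)
  expect_lt(max(abs(v1 - v2) / v2), 0.05)
})

test_that("score files round-trip through the tab-separated interface", {
  m <- randomMsa(30, 8, seed = 23)
  sm <- miScores(siteFrequencies(m))
  f <- tempfile(fileext = ".tsv")
  writeScores(sm, f)
  sm2 <- readScores(f, L = 8)
  expect_equal(rankPairs(sm2), rankPairs(sm), tolerance = 1e-12)
})
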