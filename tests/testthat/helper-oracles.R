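# Independent brute-force oracles and fixture builders shared by the suite.
# The oracles deliberately use naive double/quadruple loops and stay
# independent of the package's vectorised implementations.

randomMsa <- function(M, L, alphabet = aminoAcidAlphabet(), seed = NULL,
                      noGap = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  q <- alphabetSize(alphabet)
  hi <- if (noGap) q - 1L else q
  Msa(matrix(sample.int(hi, M * L, replace = TRUE), M, L), alphabet)
}

# naive per-cell single and pair frequency counter (weighted, pseudocounted)
oracleFrequencies <- function(msa, lambda = 0, w = NULL) {
  st <- msaStates(msa)
  M <- nrow(st); L <- ncol(st)
  q <- alphabetSize(msaAlphabet(msa))
  if (is.null(w)) w <- seqWeights(msa)
  Meff <- sum(w)
  fi <- matrix(lambda / q, L, q)
  for (i in seq_len(L)) for (s in seq_len(M))
    fi[i, st[s, i]] <- fi[i, st[s, i]] + w[s]
  fi <- fi / (lambda + Meff)
  fij <- array(lambda / q^2, c(L, L, q, q))
  for (i in seq_len(L)) for (j in seq_len(L)) if (i != j)
    for (s in seq_len(M))
      fij[i, j, st[s, i], st[s, j]] <- fij[i, j, st[s, i], st[s, j]] + w[s]
  fij <- fij / (lambda + Meff)
  list(fi = fi, fij = fij, Meff = Meff)
}

# quadruple-loop MI oracle (natural log, 0 log 0 = 0), lambda = 0
oracleMi <- function(msa) {
  o <- oracleFrequencies(msa, lambda = 0)
  L <- nrow(o$fi); q <- ncol(o$fi)
  S <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) if (i != j) {
    acc <- 0
    for (a in seq_len(q)) for (b in seq_len(q)) {
      p <- o$fij[i, j, a, b]
      if (p > 0) acc <- acc + p * log(p / (o$fi[i, a] * o$fi[j, b]))
    }
    S[i, j] <- acc
  }
  S
}

# quadruple-loop OMES oracle on raw (weighted) counts
oracleOmes <- function(msa) {
  o <- oracleFrequencies(msa, lambda = 0)
  L <- nrow(o$fi); q <- ncol(o$fi)
  M <- o$Meff
  S <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) if (i != j) {
    acc <- 0
    for (a in seq_len(q)) for (b in seq_len(q)) {
      obs <- M * o$fij[i, j, a, b]
      expd <- M * o$fi[i, a] * o$fi[j, b]
      acc <- acc + (obs - expd)^2
    }
    S[i, j] <- acc
  }
  S
}

# arithmetic APC oracle
oracleApc <- function(S) {
  L <- nrow(S)
  off <- S; diag(off) <- NA
  mi <- rowMeans(off, na.rm = TRUE)
  mbar <- mean(off[upper.tri(off)], na.rm = TRUE)
  out <- S - outer(mi, mi) / mbar
  diag(out) <- 0
  out
}

# brute-force pairwise-identity reweighting oracle
oracleWeights <- function(msa, threshold = 0.8) {
  st <- msaStates(msa)
  M <- nrow(st)
  n <- integer(M)
  for (s in seq_len(M)) for (t in seq_len(M))
    if (mean(st[s, ] == st[t, ]) >= threshold) n[s] <- n[s] + 1L
  list(weights = 1 / n, Meff = sum(1 / n))
}

# build a consistent synthetic CDS set for a protein Msa (independent of
# buildCodonMsa): sample a codon for each residue from the inverted code
randomCdsFor <- function(proteinMsa, seed = 1) {
  set.seed(seed)
  code <- standardGeneticCode()
  byAa <- split(names(code), unname(code))
  ab <- msaAlphabet(proteinMsa)
  g <- gapIndex(ab)
  out <- character(nSeq(proteinMsa))
  for (s in seq_len(nSeq(proteinMsa))) {
    row <- msaStates(proteinMsa)[s, ]
    res <- ab@symbols[row[row != g]]
    codons <- vapply(res, function(a) sample(byAa[[a]], 1L), character(1))
    out[s] <- paste(codons, collapse = "")
  }
  stats::setNames(out, seqIds(proteinMsa))
}

# small toy chain: residues given as a list of atom matrices
toyChain <- function(atomList, sequence = NULL, id = "toy") {
  L <- length(atomList)
  if (is.null(sequence)) sequence <- strrep("A", L)
  cb <- t(vapply(atomList, function(m) m[1, ], numeric(3)))
  StructureChain(sequence, cb, atomList, id = id)
}

# brute-force contact oracle over residue atom sets
oracleContacts <- function(atomList, threshold, strict = FALSE,
                           minSep = 5L) {
  L <- length(atomList)
  cm <- matrix(FALSE, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) if (abs(i - j) >= minSep) {
    dmin <- Inf
    for (a in seq_len(nrow(atomList[[i]])))
      for (b in seq_len(nrow(atomList[[j]])))
        dmin <- min(dmin, sqrt(sum((atomList[[i]][a, ] - atomList[[j]][b, ])^2)))
    cm[i, j] <- if (strict) dmin < threshold else dmin <= threshold
  }
  cm
}

# brute-force two-sided Wilcoxon signed-rank p-value by enumerating all
# 2^n sign assignments
oracleWilcoxonExact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  pGe <- mean(Ws >= W - 1e-9)
  pLe <- mean(Ws <= W + 1e-9)
  min(1, 2 * min(pGe, pLe))
}

# shared small planted-family fixture for module tests (cheaper than the
# full study conditions)
smallFamily <- function(seed = 3L, M = 600L) {
  cfg <- simulationConfig(L = 20L, M = M, nContacts = 8L, nConfounds = 3L,
                          sweeps = 80L, burnin = 20L, seed = seed)
  sampleFamily(cfg)
}

pairKey <- function(m) paste(m[, 1], m[, 2])
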