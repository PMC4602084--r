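#' Configuration of the synthetic family generator
#'
#' The generator emulates the dissociation between amino-acid-level and
#' codon-level correlation.  Contact pairs receive couplings that act on
#' codon states only through their translated amino acids, so their
#' correlation is visible at the amino-acid level and inherited (not
#' amplified) at the codon level.  Confound pairs receive a strong
#' coupling between synonymous codon usage at the two sites plus a weaker
#' amino-acid-level term, giving pairs that are strongly correlated at
#' the codon level, moderately correlated at the amino-acid level, and
#' not in contact.  Sequences are sampled independently (no phylogeny) by
#' Gibbs sampling from the resulting pairwise model over the 61 sense
#' codons.
#'
#' @param L number of sites (>= 12).
#' @param M number of sequences (>= 50).
#' @param nContacts number of planted contact pairs (sequence separation
#'   >= 5, max degree 2 per site, acyclic).
#' @param nConfounds number of planted confound pairs.
#' @param betaAaRange range of the amino-acid coupling strength for
#'   contact pairs; each pair draws its strength uniformly from this
#'   range so contacts span strong to marginal signal.
#' @param betaSyn synonymous-usage coupling strength of confound pairs.
#' @param betaConfoundAa amino-acid coupling strength of confound pairs
#'   (weaker than a typical contact).
#' @param sweeps equilibration Gibbs sweeps per sequence after burn-in.
#' @param burnin burn-in sweeps.
#' @param seed RNG seed (mandatory; the family is deterministic given it).
#' @return list of class `SimulationConfig`.
#' @export
simulationConfig <- function(L = 30L, M = 2000L, nContacts = 26L,
                             nConfounds = 8L, betaAaRange = c(0.8, 2.5),
                             betaSyn = 4, betaConfoundAa = 1.1,
                             sweeps = 200L, burnin = 50L, seed = 1L) {
  stopifnot(L >= 12L, M >= 50L, nContacts >= 0L, nConfounds >= 0L,
            length(betaAaRange) == 2L, betaAaRange[1] <= betaAaRange[2],
            betaSyn >= 0, betaConfoundAa >= 0, sweeps >= 1L, burnin >= 0L)
  if (nContacts > L - 1L || nConfounds > floor(L / 2))
    stop("infeasible pair placement: too many planted pairs for L sites")
  cfg <- list(L = as.integer(L), M = as.integer(M),
              nContacts = as.integer(nContacts),
              nConfounds = as.integer(nConfounds),
              betaAaRange = betaAaRange, betaSyn = betaSyn,
              betaConfoundAa = betaConfoundAa, sweeps = as.integer(sweeps),
              burnin = as.integer(burnin), seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

# greedy sampler of planted contact edges: sequence separation >= minSep,
# max degree 2, no cycles (components are paths, which keeps the contact
# set geometrically realisable), no duplicates; restarts on dead ends.
sampleContactEdges <- function(L, n, minSep = 5L, restarts = 50L) {
  cand0 <- which(outer(seq_len(L), seq_len(L),
                       function(i, j) j - i >= minSep), arr.ind = TRUE)
  for (r in seq_len(restarts)) {
    cand <- cand0[sample.int(nrow(cand0)), , drop = FALSE]
    degree <- integer(L)
    comp <- seq_len(L)                     # union-find by relabelling
    edges <- matrix(0L, 0L, 2L)
    for (k in seq_len(nrow(cand))) {
      if (nrow(edges) == n) break
      i <- cand[k, 1]; j <- cand[k, 2]
      if (degree[i] >= 2L || degree[j] >= 2L) next
      if (comp[i] == comp[j]) next
      edges <- rbind(edges, c(i, j))
      degree[i] <- degree[i] + 1L; degree[j] <- degree[j] + 1L
      comp[comp == comp[j]] <- comp[i]
    }
    if (nrow(edges) == n) return(edges)
  }
  stop("infeasible pair placement: could not place ", n, " contact edges")
}

# confound pairs: separation >= minSep, mutually disjoint, distinct from
# the contact edges (they may share sites with contacts; they only need
# to be non-contacts, which the chain embedding guarantees).
sampleConfoundEdges <- function(L, n, contacts, minSep = 5L) {
  cand <- which(outer(seq_len(L), seq_len(L),
                      function(i, j) j - i >= minSep), arr.ind = TRUE)
  if (nrow(contacts)) {
    key <- paste(contacts[, 1], contacts[, 2])
    cand <- cand[!(paste(cand[, 1], cand[, 2]) %in% key), , drop = FALSE]
  }
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  used <- logical(L)
  edges <- matrix(0L, 0L, 2L)
  for (k in seq_len(nrow(cand))) {
    if (nrow(edges) == n) break
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used[i] || used[j]) next
    edges <- rbind(edges, c(i, j))
    used[i] <- used[j] <- TRUE
  }
  if (nrow(edges) < n)
    stop("infeasible pair placement: could not place ", n, " confound edges")
  edges
}

senseCodonInfo <- function() {
  code <- standardGeneticCode()
  sense <- which(code != "*")
  aa <- code[sense]
  # synonymous index: position of the codon within its amino acid's block
  synIdx <- stats::ave(seq_along(aa), aa, FUN = seq_along)
  list(codonIdx = sense, aa = unname(aa), synIdx = as.integer(synIdx))
}

#' Sample a synthetic family with planted couplings
#'
#' Gibbs-samples `M` independent coding sequences of `L` codons from a
#' pairwise model (see [simulationConfig()] for the model design),
#' translates them into the paired protein alignment, and embeds a
#' synthetic single-atom chain whose 8-Angstrom contact map equals the
#' planted contact set exactly.
#'
#' @param cfg a [simulationConfig()].
#' @return list of class `PlantedFamily` with components `codon` and
#'   `protein` ([Msa]), `trueContacts`, `aaCoupled`, `codonConfound`
#'   (2-column matrices of 1-based pairs), `chain` ([StructureChain]),
#'   `seed` and `config`.
#' @export
sampleFamily <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  info <- senseCodonInfo()
  K <- length(info$codonIdx)               # 61 sense codons
  aaLevels <- unique(info$aa)

  contacts <- sampleContactEdges(cfg$L, cfg$nContacts)
  confounds <- sampleConfoundEdges(cfg$L, cfg$nConfounds, contacts)

  edges <- rbind(contacts, confounds)
  emats <- vector("list", nrow(edges))
  betas <- runif(cfg$nContacts, cfg$betaAaRange[1], cfg$betaAaRange[2])
  for (k in seq_len(cfg$nContacts)) {
    sigma <- sample(aaLevels)              # random aa "interaction partner" map
    names(sigma) <- aaLevels
    emats[[k]] <- betas[k] * outer(info$aa, info$aa,
                                   function(a, b) sigma[a] == b)
  }
  for (k in seq_len(cfg$nConfounds)) {
    tau <- sample(aaLevels)
    names(tau) <- aaLevels
    syn <- cfg$betaSyn * outer(info$synIdx, info$synIdx, "==")
    aaPart <- cfg$betaConfoundAa * outer(info$aa, info$aa,
                                         function(a, b) tau[a] == b)
    emats[[cfg$nContacts + k]] <- syn + aaPart
  }

  h <- matrix(0, K, cfg$L)
  init <- matrix(sample.int(K, cfg$M * cfg$L, replace = TRUE) - 1L,
                 cfg$M, cfg$L)
  states0 <- gibbs_sample_cpp(h, edges - 1L, emats, init,
                              cfg$burnin + cfg$sweeps)
  codonStates <- matrix(info$codonIdx[states0 + 1L], cfg$M, cfg$L)

  cAb <- codonAlphabet()
  codonMsa <- Msa(codonStates, cAb,
                  ids = sprintf("sim%05d", seq_len(cfg$M)))
  proteinMsa <- translateMsa(codonMsa)

  consensus <- apply(msaStates(proteinMsa), 2L, function(col) {
    tb <- tabulate(col, nbins = 21L)
    aminoAcidAlphabet()@symbols[which.max(tb[1:20])]
  })
  chain <- makeSyntheticChain(contacts, cfg$L,
                              seed = cfg$seed + 104729L,
                              sequence = paste(consensus, collapse = ""))
  out <- list(codon = codonMsa, protein = proteinMsa,
              trueContacts = contacts, aaCoupled = contacts,
              codonConfound = confounds, chain = chain,
              seed = cfg$seed, config = cfg)
  class(out) <- "PlantedFamily"
  out
}

#' @export
print.PlantedFamily <- function(x, ...) {
  cat(sprintf("PlantedFamily (seed %d): %d x %d codon MSA, %d contacts, %d confounds\n",
              x$seed, nSeq(x$codon), nCol(x$codon), nrow(x$trueContacts),
              nrow(x$codonConfound)))
  invisible(x)
}

#' Verify the codon/amino-acid dissociation of planted confounds
#'
#' Checks, per planted confound pair, that its codon-level MI exceeds the
#' 95th percentile of the non-planted pairs and that its amino-acid-level
#' MI is below the median amino-acid MI of the planted contact pairs --
#' i.e. the generator really produces pairs that are strongly correlated
#' at the codon level while being weaker than a typical contact at the
#' amino-acid level.
#'
#' @param family a `PlantedFamily` from [sampleFamily()].
#' @return list with `applicable`, per-pair logical `pass`, and a
#'   data.frame `detail`.
#' @export
confoundDissociationCheck <- function(family) {
  if (nrow(family$codonConfound) == 0L || family$config$betaSyn == 0)
    return(list(applicable = FALSE, pass = logical(0),
                detail = data.frame(),
                note = "no synonymous confound couplings planted"))
  miC <- scoreValues(miScores(siteFrequencies(family$codon)))
  miA <- scoreValues(miScores(siteFrequencies(family$protein)))
  L <- nCol(family$codon)
  sep <- 5L
  valid <- which(upper.tri(miC) & (col(miC) - row(miC) >= sep), arr.ind = TRUE)
  planted <- rbind(family$trueContacts, family$codonConfound)
  key <- function(m) paste(m[, 1], m[, 2])
  nonPlanted <- valid[!(key(valid) %in% key(planted)), , drop = FALSE]
  q95codon <- stats::quantile(miC[nonPlanted], 0.95, names = FALSE)
  medAaContacts <- stats::median(miA[family$trueContacts])
  detail <- data.frame(i = family$codonConfound[, 1],
                       j = family$codonConfound[, 2],
                       codonMI = miC[family$codonConfound],
                       aaMI = miA[family$codonConfound])
  detail$pass <- detail$codonMI > q95codon & detail$aaMI < medAaContacts
  if (!all(detail$pass))
    message("confound pairs failing the dissociation check:\n",
            paste(utils::capture.output(print(detail[!detail$pass, ])),
                  collapse = "\n"))
  list(applicable = TRUE, pass = detail$pass, detail = detail,
       codonMI95 = q95codon, aaMIMedianContacts = medAaContacts)
}

#' Embed a synthetic chain realising a planted contact set
#'
#' Places single-atom (Cb-only) residues so that every planted contact
#' pair lies closer than 6 Angstrom and every non-contact pair with
#' sequence separation >= 5 lies farther than 9 Angstrom, via constrained
#' random embedding with rejection.  The resulting chain's Cb contact map
#' at 8 Angstrom equals the planted set exactly, for any of the three
#' contact definitions (single-atom residues make them coincide).
#'
#' @param contacts 2-column matrix of planted pairs (may be empty).
#' @param L chain length.
#' @param seed RNG seed.
#' @param sequence optional one-letter sequence (default: seeded random).
#' @param contactDist planted pairs are placed closer than this (6 A).
#' @param clearDist non-contact pairs are kept farther than this (9 A).
#' @param maxTries rejection-sampling cap per component.
#' @return a [StructureChain] with one atom per residue.
#' @export
makeSyntheticChain <- function(contacts, L, seed, sequence = NULL,
                               contactDist = 6, clearDist = 9,
                               maxTries = 2000L) {
  set.seed(seed)
  contacts <- if (length(contacts)) as.matrix(contacts) else matrix(0L, 0L, 2L)
  if (is.null(sequence))
    sequence <- paste(sample(AA_LETTERS, L, replace = TRUE), collapse = "")
  # connected components of the contact graph
  comp <- seq_len(L)
  if (nrow(contacts)) for (k in seq_len(nrow(contacts))) {
    a <- contacts[k, 1]; b <- contacts[k, 2]
    comp[comp == comp[b]] <- comp[a]
  }
  compIds <- unique(comp)
  # lay components sequentially along x with adaptive clearance, so even
  # extended path components cannot approach each other
  coords <- matrix(NA_real_, L, 3L)
  adj <- lapply(seq_len(L), function(i)
    c(contacts[contacts[, 1] == i, 2], contacts[contacts[, 2] == i, 1]))
  offset <- 0
  for (ci in seq_along(compIds)) {
    nodes <- which(comp == compIds[ci])
    if (length(nodes) == 1L) {
      coords[nodes, ] <- c(offset, 0, 0)
      offset <- offset + clearDist + 6
      next
    }
    placed <- placeComponent(nodes, adj, c(0, 0, 0), contactDist, clearDist,
                             maxTries)
    placed[, 1] <- placed[, 1] - min(placed[, 1]) + offset
    coords[nodes, ] <- placed
    offset <- max(placed[, 1]) + clearDist + 6
  }
  # final verification of the embedding contract
  d <- as.matrix(stats::dist(coords))
  cmTruth <- contactMapFromPairs(contacts, L)@contacts
  sepOk <- abs(row(d) - col(d)) >= 5L
  if (nrow(contacts) && any(d[contacts] >= contactDist))
    stop("embedding failed: a planted pair is not in contact; try sparser contacts")
  viol <- d <= clearDist & sepOk & !cmTruth
  if (any(viol))
    stop("embedding failed: a non-contact pair is too close; try sparser contacts")
  StructureChain(sequence, coords, id = sprintf("synthetic-%d", seed),
                 resolution = 1.5)
}

# sequentially embed one path-shaped component; general components fall
# back to whole-component rejection in a ball.
placeComponent <- function(nodes, adj, center, contactDist, clearDist,
                           maxTries) {
  deg <- lengths(adj[nodes])
  isPath <- all(deg <= 2L) && sum(deg == 1L) == 2L
  n <- length(nodes)
  pairsMat <- t(utils::combn(n, 2L))
  edgeHere <- matrix(FALSE, n, n)
  for (a in seq_len(n)) for (b in adj[[nodes[a]]]) {
    bb <- match(b, nodes)
    if (!is.na(bb)) edgeHere[a, bb] <- edgeHere[bb, a] <- TRUE
  }
  sepHere <- abs(outer(nodes, nodes, "-")) >= 5L
  for (try in seq_len(maxTries)) {
    P <- matrix(NA_real_, n, 3L)
    if (isPath) {
      ord <- pathOrder(nodes, adj)
      oi <- match(ord, nodes)
      P[oi[1], ] <- center
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      for (k in 2:n) {
        step <- runif(1, 0.75 * contactDist, 0.95 * contactDist)
        newDir <- dir + 0.45 * rnorm(3)
        dir <- newDir / sqrt(sum(newDir^2))
        P[oi[k], ] <- P[oi[k - 1], ] + step * dir
      }
    } else {
      radius <- 3 * sqrt(n) * contactDist / 2
      P <- matrix(center, n, 3L, byrow = TRUE) +
        matrix(runif(3L * n, -radius, radius), n, 3L)
    }
    d <- as.matrix(stats::dist(P))
    okContact <- all(d[edgeHere & upper.tri(d)] < contactDist)
    free <- !edgeHere & sepHere & upper.tri(d)
    okClear <- all(d[free] > clearDist)
    if (okContact && okClear) return(P)
  }
  stop("embedding failed after ", maxTries,
       " attempts; try sparser contacts")
}

pathOrder <- function(nodes, adj) {
  ends <- nodes[vapply(nodes, function(i)
    sum(adj[[i]] %in% nodes) == 1L, logical(1))]
  cur <- min(ends)
  ord <- cur
  prev <- -1L
  while (length(ord) < length(nodes)) {
    nxt <- setdiff(intersect(adj[[cur]], nodes), prev)
    prev <- cur
    cur <- nxt[1]
    ord <- c(ord, cur)
  }
  ord
}

#' Write a planted family to disk
#'
#' Writes the codon FASTA, protein FASTA, a tab-separated truth table of
#' planted pairs and a PDB file of the synthetic chain.
#'
#' @param family a `PlantedFamily`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeFamily <- function(family, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMsa(family$codon, file.path(dir, "codon.fasta"))
  writeMsa(family$protein, file.path(dir, "protein.fasta"))
  truth <- rbind(
    data.frame(i = family$trueContacts[, 1], j = family$trueContacts[, 2],
               class = "contact"),
    data.frame(i = family$codonConfound[, 1], j = family$codonConfound[, 2],
               class = "confound"))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeChainPdb(family$chain, file.path(dir, "chain.pdb"))
  invisible(dir)
}
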