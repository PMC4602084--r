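test_that("candidate pair counting matches brute force and the 100-residue case", {
  expect_equal(nCandidatePairs(100, 5), 4560)
  expect_equal(topFractionCount(nCandidatePairs(100, 5), 0.01), 46L)
  expect_equal(nCandidatePairs(6, 5), 1)
  expect_equal(nCandidatePairs(5, 5), 0)
  for (N in c(0, 1, 7, 23, 100, 200)) for (sep in c(1, 3, 5, 10)) {
    brute <- sum(outer(seq_len(N), seq_len(N), function(i, j) j - i >= sep))
    expect_equal(nCandidatePairs(N, sep), brute)
  }
})

test_that("Cbeta contacts use inclusive thresholds and respect separation", {
  # residues 1 and 7 exactly 8.0 A apart -> contact at 8 (inclusive)
  cb <- matrix(0, 8, 3)
  cb[, 1] <- c(0, 100, 200, 300, 400, 500, 8, 600)
  ch <- StructureChain(strrep("A", 8), cb)
  cm <- contactMap(ch, "cbeta", 8, 5)
  expect_true(contactMatrix(cm)[1, 7])
  expect_equal(nContacts(cm), 1L)
  # same geometry at separation < 5 is excluded
  cb2 <- cb; cb2[4, ] <- c(8, 0, 0)
  cm2 <- contactMap(StructureChain(strrep("A", 8), cb2), "cbeta", 8, 5)
  expect_false(contactMatrix(cm2)[1, 4])
})

test_that("contact maps match the brute-force oracle for all definitions", {
  set.seed(91)
  L <- 30
  atoms <- lapply(seq_len(L), function(i) {
    n <- sample(1:4, 1)
    matrix(rnorm(3 * n, mean = i * 3, sd = 2), n, 3)
  })
  ch <- toyChain(atoms)
  for (def in c("all_atom", "physical")) {
    th <- if (def == "physical") 3.5 else 8
    cm <- contactMap(ch, def, th, 5)
    expect_equal(contactMatrix(cm),
                 oracleContacts(atoms, th, strict = def == "physical"),
                 ignore_attr = TRUE)
  }
  # single-atom residues: cbeta and all_atom coincide
  single <- lapply(seq_len(L), function(i) atoms[[i]][1, , drop = FALSE])
  chS <- toyChain(single)
  expect_equal(contactMatrix(contactMap(chS, "cbeta", 8, 5)),
               contactMatrix(contactMap(chS, "all_atom", 8, 5)))
})

test_that("contact maps are monotone in the distance threshold", {
  set.seed(17)
  ch <- toyChain(lapply(1:25, function(i)
    matrix(rnorm(3, mean = i * 2.5, sd = 3), 1, 3)))
  prev <- NULL
  for (th in c(4, 6, 8, 12, 20)) {
    cur <- contactMatrix(contactMap(ch, "cbeta", th, 5))
    if (!is.null(prev)) expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("physical contacts are a subset of all-atom contacts", {
  set.seed(23)
  atoms <- lapply(1:20, function(i) matrix(rnorm(6, i * 2, 2), 2, 3))
  ch <- toyChain(atoms)
  phys <- contactMatrix(contactMap(ch, "physical"))
  alla <- contactMatrix(contactMap(ch, "all_atom", 8))
  expect_true(all(alla[phys]))
})

test_that("glycine residues use the Calpha coordinate", {
  pdb <- tempfile(fileext = ".pdb")
  mk <- function(serial, elety, res, resno, x)
    sprintf("ATOM  %5d  %-3s%4s A%4d    %8.3f%8.3f%8.3f  1.00  1.00           %s",
            serial, elety, res, resno, x, 0, 0, substr(elety, 1, 1))
  lines <- c(
    mk(1, "CA", "ALA", 1, 0), mk(2, "CB", "ALA", 1, 1),
    mk(3, "CA", "GLY", 2, 10),                      # glycine: no CB
    mk(4, "CA", "TRP", 3, 20), mk(5, "CB", "TRP", 3, 21),
    mk(6, "CA", "MET", 4, 30),                      # missing CB -> CA fallback
    "END")
  writeLines(lines, pdb)
  ch <- readStructureChain(pdb)
  expect_equal(chainSequence(ch), "AGWM")
  expect_equal(ch@cbeta[1, 1], 1)    # ALA uses CB
  expect_equal(ch@cbeta[2, 1], 10)   # GLY uses CA
  expect_equal(ch@cbeta[3, 1], 21)
  expect_equal(ch@cbeta[4, 1], 30)   # fallback counted
  expect_equal(attr(ch, "cbFallbacks"), 1L)
})

test_that("physical contact fraction matches the brute-force oracle", {
  # every contacting pair also in physical contact -> 1.0
  cb <- matrix(c(0, 0, 0, 3, 0, 0, 100, 0, 0, 103, 0, 0, 200, 0, 0,
                 203, 0, 0, 1.5, 0, 0), ncol = 3, byrow = TRUE)
  ch <- toyChain(lapply(seq_len(nrow(cb)), function(i) cb[i, , drop = FALSE]))
  expect_equal(physicalContactFraction(ch, "cbeta", 8), 1.0)

  # contacts exist but no pair is within 3.5 A -> 0.0
  cb2 <- matrix(0, 10, 3); cb2[, 1] <- c(0, 30, 60, 90, 120, 6, 150, 180, 210, 240)
  ch2 <- toyChain(lapply(1:10, function(i) cb2[i, , drop = FALSE]))
  expect_equal(physicalContactFraction(ch2, "cbeta", 8), 0.0)

  # randomised chain vs naive scan (compact enough that contacts exist)
  set.seed(41)
  atoms <- lapply(1:30, function(i) matrix(rnorm(6, i * 1.4, 2.2), 2, 3))
  ch3 <- toyChain(atoms)
  o8 <- oracleContacts(atoms, 8, strict = FALSE)
  o35 <- oracleContacts(atoms, 3.5, strict = TRUE)
  expect_gt(sum(o8[upper.tri(o8)]), 0)
  expect_equal(physicalContactFraction(ch3, "all_atom", 8),
               sum(o35 & o8) / sum(o8))

  # degenerate input: no contacts at all
  far <- lapply(1:8, function(i) matrix(c(i * 50, 0, 0), 1, 3))
  expect_error(physicalContactFraction(toyChain(far), "cbeta", 8),
               "degenerate")
})

test_that("column-to-structure mapping handles identity, loops and junk", {
  set.seed(19)
  dom <- paste(sample(c("A", "C", "D", "E", "F", "G", "H", "K"), 30,
                      replace = TRUE), collapse = "")
  cb <- matrix(rnorm(90), 30, 3)
  ch <- StructureChain(dom, cb)
  mp <- mapColumnsToStructure(dom, ch)
  expect_equal(mp$coverage, 1)
  expect_true(mp$passes)
  expect_equal(mp$map$column, mp$map$residue)

  # a 3-residue loop missing from the ATOM sequence
  atomSeq <- paste0(substr(dom, 1, 10), substr(dom, 14, 30))
  ch2 <- StructureChain(atomSeq, cb[-(11:13), , drop = FALSE])
  mp2 <- mapColumnsToStructure(dom, ch2)
  expect_equal(mp2$coverage, 27 / 30)
  expect_false(any(mp2$map$column %in% 11:13))
  expect_equal(mp2$map$residue, seq_len(27))

  # unrelated sequences fail the 80% rule
  junk <- strrep("W", 30)
  expect_warning(mp3 <- mapColumnsToStructure(dom, StructureChain(junk, cb)),
                 "80")
  expect_false(mp3$passes)
})

test_that("accuracy curves implement the top-N definition", {
  cmap <- contactMapFromPairs(rbind(c(1, 10), c(2, 12), c(3, 14)), 20)
  perfect <- data.frame(i = c(1, 2, 3), j = c(10, 12, 14), score = 3:1)
  cv <- evaluateRanking(perfect, cmap, nMax = 3)
  expect_equal(cv$accuracy, rep(1, 3))

  # 4 true contacts among the top 10 -> accuracy 0.4 at N = 10
  truthPairs <- rbind(c(1, 10), c(2, 12), c(3, 14), c(4, 16))
  cmap2 <- contactMapFromPairs(truthPairs, 20)
  ranked <- data.frame(i = c(1, 2, 3, 4, 1, 2, 3, 4, 5, 6),
                       j = c(10, 12, 14, 16, 11, 13, 15, 17, 18, 19),
                       score = 10:1)
  cv2 <- evaluateRanking(ranked, cmap2, nMax = 10)
  expect_equal(cv2$accuracy[10], 0.4)

  # truncation is announced when fewer predictions exist
  expect_message(cv3 <- evaluateRanking(perfect, cmap, nMax = 50),
                 "truncated")
  expect_equal(nrow(cv3), 3L)

  # random ranking accuracy approximates the contact density
  set.seed(29)
  L <- 40
  pairs <- which(upper.tri(matrix(0, L, L)) &
                 col(matrix(0, L, L)) - row(matrix(0, L, L)) >= 5,
                 arr.ind = TRUE)
  truth <- pairs[sample(nrow(pairs), 80), ]
  cmapR <- contactMapFromPairs(truth, L)
  rnd <- data.frame(i = pairs[, 1], j = pairs[, 2],
                    score = runif(nrow(pairs)))
  rnd <- rnd[order(-rnd$score), ]
  cvR <- evaluateRanking(rnd, cmapR, nMax = nrow(rnd))
  dens <- 80 / nrow(pairs)
  expect_lt(abs(cvR$accuracy[nrow(rnd)] - dens), 1e-9)  # exact at full depth
  se <- sqrt(dens * (1 - dens) / 200)
  expect_lt(abs(cvR$accuracy[200] - dens), 4 * se)
})

test_that("AUC improvement matches trapezoid arithmetic and symmetry algebra", {
  c1 <- data.frame(n = 1:5, accuracy = c(0.2, 0.3, 0.4, 0.4, 0.5))
  expect_equal(aucImprovement(c1, c1), 0)
  c2 <- c1; c2$accuracy <- 2 * c1$accuracy
  expect_equal(aucImprovement(c1, c2), 100)

  # hand-specified pair of curves: trapezoid by hand
  a <- data.frame(n = 1:5, accuracy = c(0.1, 0.2, 0.2, 0.3, 0.6))
  b <- data.frame(n = 1:5, accuracy = c(0.2, 0.2, 0.4, 0.5, 0.5))
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2)
  expect_equal(aucImprovement(a, b), 100 * (trap(b$accuracy) - trap(a$accuracy)) /
                 trap(a$accuracy), tolerance = 1e-12)

  # exact algebraic relation between the two orientations
  impAB <- aucImprovement(a, b)
  impBA <- aucImprovement(b, a)
  A <- trap(a$accuracy); B <- trap(b$accuracy)
  expect_equal(impAB, 100 * (B - A) / A, tolerance = 1e-12)
  expect_equal(impBA, 100 * (A - B) / B, tolerance = 1e-12)

  expect_error(aucImprovement(a, data.frame(n = 1:4, accuracy = rep(1, 4))),
               "grid")
  z <- data.frame(n = 1:5, accuracy = rep(0, 5))
  expect_error(aucImprovement(z, a), "zero AUC")
})

test_that("family evaluation averages structures, caps at 30 and is order-invariant", {
  set.seed(37)
  fam <- smallFamily(seed = 71, M = 300)
  L <- nCol(fam$protein)
  sAA <- miScores(siteFrequencies(fam$protein))
  sC <- miScores(siteFrequencies(fam$codon))
  comb <- combineScores(sAA, sC, 2.5)
  dom <- chainSequence(fam$chain)

  # 40 jittered copies with unique sequences: exactly 30 retained
  mkCopy <- function(k) {
    cb <- fam$chain@cbeta + matrix(rnorm(3 * L, 0, 0.05), L, 3)
    seqk <- chainSequence(fam$chain)
    p <- ((k - 1) %% L) + 1
    letter <- if (k <= 20) "W" else "Y"
    if (substr(seqk, p, p) == letter) letter <- "H"
    substr(seqk, p, p) <- letter                      # unique sequence
    StructureChain(seqk, cb, id = sprintf("copy%02d", k),
                   resolution = 1 + k / 100)
  }
  structures <- lapply(1:40, mkCopy)
  fe <- familyEvaluation(list(base = sAA, combined = comb), structures, dom)
  expect_equal(fe$nStructures, 30L)

  # averaging: with two structures the family curve is the mean curve
  two <- structures[1:2]
  feA <- familyEvaluation(list(base = sAA), two[1], dom)
  feB <- familyEvaluation(list(base = sAA), two[2], dom)
  feAB <- familyEvaluation(list(base = sAA), two, dom)
  nmin <- min(nrow(feA$curves$base), nrow(feB$curves$base))
  expect_equal(feAB$curves$base$accuracy[seq_len(nmin)],
               (feA$curves$base$accuracy[seq_len(nmin)] +
                feB$curves$base$accuracy[seq_len(nmin)]) / 2,
               tolerance = 1e-12)

  # single structure: family result equals that structure's own curve
  fe1 <- familyEvaluation(list(base = sAA), structures[3], dom)
  mp3 <- mapColumnsToStructure(dom, structures[[3]])
  cm3 <- contactMap(structures[[3]], "cbeta", 8, 5)
  direct <- evaluateRanking(rankPairs(sAA), cm3, mp3)
  expect_equal(fe1$curves$base$accuracy,
               direct$accuracy[seq_len(nrow(fe1$curves$base))],
               tolerance = 1e-12)

  # input order of structures does not matter
  fe2 <- familyEvaluation(list(base = sAA, combined = comb),
                          rev(structures), dom)
  expect_equal(fe2$auc, fe$auc, tolerance = 1e-12)
  expect_equal(fe2$improvementPct, fe$improvementPct, tolerance = 1e-12)

  # all structures failing coverage is an error
  junk <- StructureChain(strrep("W", L), fam$chain@cbeta)
  expect_error(suppressWarnings(
    familyEvaluation(list(base = sAA), list(junk), dom)), "coverage")
})

test_that("threshold sweep validates input and shows the planted-contact peak", {
  fams <- lapply(c(81, 82, 83), function(s) {
    fam <- smallFamily(seed = s, M = 500)
    list(aa = miScores(siteFrequencies(fam$protein)),
         codon = miScores(siteFrequencies(fam$codon)),
         chain = fam$chain)
  })
  expect_error(thresholdSweep(fams, c(8, 8)), "duplicate")
  expect_error(thresholdSweep(fams, c(8, 6)), "ascending")

  sw <- thresholdSweep(fams, c(7, 8), alpha = 2.5)
  expect_equal(nrow(sw), 2L)
  # single threshold reduces to the mean of per-family improvements
  one <- thresholdSweep(fams, 8, alpha = 2.5)
  per <- vapply(fams, function(fam) {
    cmap <- contactMap(fam$chain, "cbeta", 8, 5)
    comb <- combineScores(fam$aa, fam$codon, 2.5)
    aucImprovement(evaluateRanking(rankPairs(fam$aa), cmap),
                   evaluateRanking(rankPairs(comb), cmap))
  }, numeric(1))
  expect_equal(one$meanImprovementPct, mean(per), tolerance = 1e-12)

  # contacts are planted below 6 A: improvement at 8 A exceeds the value
  # at a threshold so large that contact status is nearly uninformative
  swWide <- thresholdSweep(fams, c(8, 60), alpha = 2.5)
  expect_gt(swWide$meanImprovementPct[1], swWide$meanImprovementPct[2])
})
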