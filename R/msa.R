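#' Multiple sequence alignment over an alphabet
#'
#' An `Msa` stores an M x L matrix of integer state indices over an
#' [Alphabet], together with the record identifiers and optional
#' per-sequence weights.  Weights in (0, 1] arise from identity-based
#' reweighting ([computeWeights()]); their sum is the effective number of
#' sequences Meff.
#'
#' @slot states integer matrix, M x L, values in `1:alphabetSize(alphabet)`.
#' @slot ids character vector of M record identifiers.
#' @slot alphabet the [Alphabet] the states index into.
#' @slot weights numeric vector of M sequence weights in (0, 1].
#' @aliases Msa
#' @exportClass Msa
setClass("Msa",
  representation(states = "matrix", ids = "character",
                 alphabet = "Alphabet", weights = "numeric"))

setValidity("Msa", function(object) {
  msg <- character()
  st <- object@states
  if (!is.numeric(st) || nrow(st) < 1L || ncol(st) < 1L)
    msg <- c(msg, "states must be a numeric M x L matrix with M, L >= 1")
  q <- alphabetSize(object@alphabet)
  if (any(st < 1L | st > q | st != round(st)))
    msg <- c(msg, "state indices must be integers in [1, q]")
  if (length(object@ids) != nrow(st))
    msg <- c(msg, "ids length must equal number of sequences")
  if (length(object@weights) != nrow(st))
    msg <- c(msg, "weights length must equal number of sequences")
  if (any(object@weights <= 0 | object@weights > 1))
    msg <- c(msg, "weights must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct an Msa from a state matrix
#'
#' @param states integer matrix (M x L) of 1-based state indices.
#' @param ids record identifiers (default `seq1`, `seq2`, ...).
#' @param alphabet an [Alphabet].
#' @param weights optional per-sequence weights in (0, 1]; default all 1.
#' @return an [Msa].
#' @export
Msa <- function(states, alphabet, ids = NULL, weights = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  dimnames(states) <- NULL
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(states)))
  if (is.null(weights)) weights <- rep(1, nrow(states))
  new("Msa", states = states, ids = unname(as.character(ids)),
      alphabet = alphabet, weights = unname(as.numeric(weights)))
}

#' @describeIn Msa number of sequences M.
#' @param x an [Msa].
#' @export
nSeq <- function(x) nrow(x@states)

#' @describeIn Msa number of alignment columns L.
#' @export
nCol <- function(x) ncol(x@states)

#' @describeIn Msa the M x L integer state matrix.
#' @export
msaStates <- function(x) x@states

#' @describeIn Msa the record identifiers.
#' @export
seqIds <- function(x) x@ids

#' @describeIn Msa the [Alphabet] of the alignment.
#' @export
msaAlphabet <- function(x) x@alphabet

#' @describeIn Msa per-sequence weights.
#' @export
seqWeights <- function(x) x@weights

#' @describeIn Msa replace per-sequence weights.
#' @param value numeric vector of weights in (0, 1].
#' @export
`seqWeights<-` <- function(x, value) {
  x@weights <- as.numeric(value)
  validObject(x)
  x
}

setMethod("show", "Msa", function(object) {
  cat(sprintf("Msa: %d sequences x %d columns over <%s> alphabet (Meff = %.2f)\n",
              nSeq(object), nCol(object), alphabetTag(object@alphabet),
              sum(object@weights)))
})

## ---- tokenisation ---------------------------------------------------------

tokenizeSequence <- function(seq, alphabet, id = "?") {
  seq <- toupper(seq)
  if (alphabetTag(alphabet) == "aa") {
    tokens <- strsplit(chartr(".", "-", seq), "")[[1]]
  } else {
    if (nchar(seq) %% 3L != 0L)
      stop(sprintf("record '%s': length %d is not divisible by 3", id, nchar(seq)))
    seq <- chartr(".U", "-T", seq)
    tokens <- substring(seq, seq(1, nchar(seq), by = 3),
                        seq(3, nchar(seq), by = 3))
    # any ambiguity (N etc.) or partial gap maps the whole codon to gap
    tokens[!grepl("^[ACGT]{3}$", tokens)] <- alphabet@gap
  }
  idx <- match(tokens, alphabet@symbols)
  idx[is.na(idx)] <- gapIndex(alphabet)
  idx
}

parseStockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seqs <- character()
  for (ln in lines) {
    ln <- trimws(ln, which = "right")
    if (!nzchar(ln) || startsWith(ln, "#") || ln == "//") next
    parts <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(parts) != 2L) next
    nm <- parts[1]
    seqs[nm] <- if (nm %in% names(seqs)) paste0(seqs[[nm]], parts[2]) else parts[2]
  }
  seqs
}

#' Read a multiple sequence alignment
#'
#' Reads FASTA (plain or wrapped) or Stockholm 1.0 alignments and encodes
#' them over the given alphabet.  Tokens outside the alphabet (unknown
#' residues such as `X`, ambiguous codons) are mapped to the gap state;
#' Stockholm `.` characters are treated as gaps and markup lines are
#' ignored.
#'
#' @param path file path.
#' @param alphabet target [Alphabet] ([aminoAcidAlphabet()] or
#'   [codonAlphabet()]).
#' @param format `"fasta"` or `"stockholm"`.
#' @return an [Msa]; ids preserved in file order.
#' @export
readMsa <- function(path, alphabet, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    seqs <- stats::setNames(as.character(ss), names(ss))
  } else {
    seqs <- parseStockholm(path)
  }
  if (length(seqs) == 0L) stop("no sequences found in ", path)
  rows <- mapply(tokenizeSequence, seqs, names(seqs),
                 MoreArgs = list(alphabet = alphabet), SIMPLIFY = FALSE)
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) {
    bad <- names(rows)[which(lens != lens[1])[1]]
    stop(sprintf("ragged alignment: record '%s' has %d columns, expected %d",
                 bad, lens[[bad]], lens[1]))
  }
  Msa(do.call(rbind, rows), alphabet, ids = names(seqs))
}

#' Write an alignment to FASTA or Stockholm
#'
#' Codon alignments are written as nucleotide FASTA with `-` gaps in
#' triplets, so a written codon MSA reads back identically.
#'
#' @param msa an [Msa].
#' @param path output file path.
#' @param format `"fasta"` or `"stockholm"`.
#' @param width line width for FASTA wrapping.
#' @return invisibly, `path`.
#' @export
writeMsa <- function(msa, path, format = c("fasta", "stockholm"), width = 60L) {
  format <- match.arg(format)
  ab <- msaAlphabet(msa)
  seqs <- apply(msaStates(msa), 1L, function(r) paste(ab@symbols[r], collapse = ""))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    for (k in seq_along(seqs)) {
      writeLines(paste0(">", seqIds(msa)[k]), con)
      s <- seqs[k]
      starts <- seq(1, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  } else {
    writeLines("# STOCKHOLM 1.0", con)
    nm <- format(seqIds(msa), width = max(nchar(seqIds(msa))))
    writeLines(paste(nm, seqs), con)
    writeLines("//", con)
  }
  invisible(path)
}

## ---- codon MSA construction ----------------------------------------------

#' Thread coding sequences onto a protein alignment
#'
#' Builds a codon MSA from an amino-acid MSA and the unaligned coding
#' sequences (CDS) of its records, in the style of EMBOSS `tranalign`:
#' each CDS is translated, checked against the ungapped protein sequence,
#' and its codons are threaded into the gap pattern of the protein row.
#' One trailing stop codon, if present, is stripped.
#'
#' @param proteinMsa an [Msa] over the amino-acid alphabet.
#' @param cds named character vector (or `DNAStringSet`) of unaligned
#'   coding sequences, names matching `seqIds(proteinMsa)`.
#' @param code genetic code (default [standardGeneticCode()]).
#' @return an [Msa] over the codon alphabet with the same dimensions and
#'   ids as `proteinMsa`; translating it back reproduces `proteinMsa`.
#' @export
buildCodonMsa <- function(proteinMsa, cds, code = standardGeneticCode()) {
  stopifnot(alphabetTag(msaAlphabet(proteinMsa)) == "aa")
  checkGeneticCode(code)
  if (methods::is(cds, "XStringSet")) cds <- stats::setNames(as.character(cds), names(cds))
  missing <- setdiff(seqIds(proteinMsa), names(cds))
  if (length(missing))
    stop("missing CDS for id(s): ", paste(missing, collapse = ", "))
  aaAb <- msaAlphabet(proteinMsa)
  cAb <- codonAlphabet()
  gapAA <- gapIndex(aaAb)
  out <- matrix(gapIndex(cAb), nSeq(proteinMsa), nCol(proteinMsa))
  for (s in seq_len(nSeq(proteinMsa))) {
    id <- seqIds(proteinMsa)[s]
    dna <- toupper(chartr("u", "t", cds[[id]]))
    if (nchar(dna) %% 3L != 0L)
      stop(sprintf("CDS '%s': length %d not divisible by 3", id, nchar(dna)))
    codons <- substring(dna, seq(1, nchar(dna), by = 3), seq(3, nchar(dna), by = 3))
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"                      # ambiguous codon
    if (length(aa) && aa[length(aa)] == "*") { # strip one trailing stop
      codons <- codons[-length(codons)]
      aa <- aa[-length(aa)]
    }
    prow <- msaStates(proteinMsa)[s, ]
    resCols <- which(prow != gapAA)
    if (length(aa) != length(resCols))
      stop(sprintf("CDS '%s': %d codons but %d aligned residues",
                   id, length(aa), length(resCols)))
    pch <- aaAb@symbols[prow[resCols]]
    mism <- which(aa != pch & aa != "X")
    if (length(mism))
      stop(sprintf("CDS '%s': translation mismatch at residue %d ('%s' vs '%s')",
                   id, mism[1], aa[mism[1]], pch[mism[1]]))
    ci <- match(codons, cAb@symbols)
    ci[is.na(ci)] <- gapIndex(cAb)
    out[s, resCols] <- ci
  }
  Msa(out, cAb, ids = seqIds(proteinMsa), weights = seqWeights(proteinMsa))
}

#' Translate a codon MSA back to amino acids
#'
#' Gap codons, stop codons and ambiguous codons all map to the amino-acid
#' gap state.
#'
#' @param codonMsa an [Msa] over the codon alphabet.
#' @param code genetic code (default [standardGeneticCode()]).
#' @return an [Msa] over the amino-acid alphabet.
#' @export
translateMsa <- function(codonMsa, code = standardGeneticCode()) {
  stopifnot(alphabetTag(msaAlphabet(codonMsa)) == "codon")
  checkGeneticCode(code)
  cAb <- msaAlphabet(codonMsa)
  aaAb <- aminoAcidAlphabet()
  aaOf <- c(unname(code[cAb@symbols[1:64]]), "-")  # 65th = gap
  lut <- match(aaOf, aaAb@symbols)
  lut[is.na(lut)] <- gapIndex(aaAb)                # stops, X -> gap
  st <- matrix(lut[msaStates(codonMsa)], nSeq(codonMsa), nCol(codonMsa))
  Msa(st, aaAb, ids = seqIds(codonMsa), weights = seqWeights(codonMsa))
}

## ---- reweighting ----------------------------------------------------------

#' Identity-based sequence reweighting
#'
#' Each sequence is weighted by 1 / (number of sequences, itself included,
#' whose fraction of identical alignment positions is at least
#' `identityThreshold`).  The sum of the weights is the effective number
#' of sequences, Meff -- the standard mean-field DCA reweighting.
#'
#' @param msa an [Msa].
#' @param identityThreshold pairwise identity fraction in (0, 1];
#'   default 0.8.
#' @return list with components `weights` (length M) and `Meff`.
#' @export
computeWeights <- function(msa, identityThreshold = 0.8) {
  stopifnot(identityThreshold > 0, identityThreshold <= 1)
  M <- nSeq(msa); L <- nCol(msa)
  X <- oneHot(msa, dropGap = FALSE)
  sim <- as.matrix(Matrix::tcrossprod(X)) / L   # fraction identical
  n <- rowSums(sim >= identityThreshold)
  w <- 1 / n
  list(weights = w, Meff = sum(w))
}

# sparse M x (L*q) one-hot encoding; optionally drop the gap state from
# each site block (giving L*(q-1) columns, the DCA/PSICOV gauge).
oneHot <- function(msa, dropGap = FALSE) {
  st <- msaStates(msa)
  M <- nrow(st); L <- ncol(st)
  q <- alphabetSize(msaAlphabet(msa))
  if (dropGap) {
    g <- gapIndex(msaAlphabet(msa))
    stopifnot(g == q)  # gap is last by construction
    keep <- st != g
    i <- row(st)[keep]
    j <- (col(st)[keep] - 1L) * (q - 1L) + st[keep]
    Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(M, L * (q - 1L)))
  } else {
    i <- rep(seq_len(M), L)
    j <- (rep(seq_len(L), each = M) - 1L) * q + as.vector(st)
    Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(M, L * q))
  }
}
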