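#' State alphabets for alignments
#'
#' An `Alphabet` is the finite symbol set a multiple sequence alignment is
#' encoded over: single letters for amino acids, trinucleotide strings for
#' codons.  The gap character is a full member of the alphabet, so the
#' amino-acid alphabet has q = 21 states and the codon alphabet q = 65.
#'
#' @slot symbols ordered character vector of unique tokens; the gap token
#'   is last.
#' @slot gap the gap token (must be a member of `symbols`).
#' @slot tag `"aa"` or `"codon"`.
#' @aliases Alphabet
#' @exportClass Alphabet
setClass("Alphabet",
  representation(symbols = "character", gap = "character", tag = "character"))

setValidity("Alphabet", function(object) {
  msg <- character()
  if (anyDuplicated(object@symbols))
    msg <- c(msg, "alphabet symbols must be unique")
  if (length(object@gap) != 1L || !object@gap %in% object@symbols)
    msg <- c(msg, "gap token must be a single member of 'symbols'")
  if (!object@tag %in% c("aa", "codon"))
    msg <- c(msg, "tag must be 'aa' or 'codon'")
  if (object@tag == "aa" && length(object@symbols) != 21L)
    msg <- c(msg, "amino-acid alphabet must have exactly 21 states")
  if (object@tag == "codon" && length(object@symbols) != 65L)
    msg <- c(msg, "codon alphabet must have exactly 65 states")
  if (length(msg)) msg else TRUE
})

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' The 21-state amino-acid alphabet (20 residues + gap)
#'
#' @return an [Alphabet] with the gap `"-"` as its last (21st) state.
#' @export
#' @examples
#' alphabetSize(aminoAcidAlphabet())  # 21
aminoAcidAlphabet <- function() {
  new("Alphabet", symbols = c(AA_LETTERS, "-"), gap = "-", tag = "aa")
}

#' The 65-state codon alphabet (64 codons + gap)
#'
#' Codons are ordered as in the standard genetic code table
#' (`Biostrings::GENETIC_CODE`); stop codons are retained as ordinary
#' states.  The gap token is `"---"`.
#'
#' @return an [Alphabet] with 65 states.
#' @export
codonAlphabet <- function() {
  new("Alphabet", symbols = c(names(Biostrings::GENETIC_CODE), "---"),
      gap = "---", tag = "codon")
}

#' @describeIn aminoAcidAlphabet number of states q of an alphabet.
#' @param x an [Alphabet].
#' @export
alphabetSize <- function(x) length(x@symbols)

#' @describeIn aminoAcidAlphabet integer index of the gap state.
#' @export
gapIndex <- function(x) match(x@gap, x@symbols)

#' @describeIn aminoAcidAlphabet symbol vector of an alphabet.
#' @export
alphabetSymbols <- function(x) x@symbols

#' @describeIn aminoAcidAlphabet tag (`"aa"` or `"codon"`).
#' @export
alphabetTag <- function(x) x@tag

setMethod("show", "Alphabet", function(object) {
  cat(sprintf("Alphabet <%s>: %d states, gap '%s'\n",
              object@tag, alphabetSize(object), object@gap))
})

#' The standard genetic code
#'
#' A total mapping from each of the 64 codons to a one-letter amino acid
#' or the stop marker `"*"`, taken from `Biostrings::GENETIC_CODE`.
#'
#' @return named character vector of length 64.
#' @export
standardGeneticCode <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

checkGeneticCode <- function(code) {
  if (length(code) != 64L || is.null(names(code)) ||
      anyDuplicated(names(code)) || any(nchar(names(code)) != 3L))
    stop("genetic code must be a named character vector over all 64 codons")
  invisible(code)
}
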