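#' Protein chain coordinates for contact evaluation
#'
#' A minimal representation of one structure chain: per-residue heavy-atom
#' coordinates, the Cb coordinate used by the classical contact
#' definition (Ca for glycine, with a counted fallback to Ca when a
#' non-glycine Cb is unresolved), the one-letter sequence and the
#' resolution used to prioritise structures within a family.
#'
#' @slot id chain identifier (used for deterministic tie-breaking).
#' @slot sequence character vector of one-letter residue codes.
#' @slot cbeta L x 3 matrix of Cb coordinates in Angstrom (rows may be NA
#'   when a residue has no usable atom).
#' @slot atoms list of L matrices (n_atoms x 3) of heavy-atom coordinates.
#' @slot resolution resolution in Angstrom (NA if unknown).
#' @aliases StructureChain
#' @exportClass StructureChain
setClass("StructureChain",
  representation(id = "character", sequence = "character", cbeta = "matrix",
                 atoms = "list", resolution = "numeric"))

setValidity("StructureChain", function(object) {
  msg <- character()
  L <- length(object@sequence)
  if (nrow(object@cbeta) != L) msg <- c(msg, "cbeta must have one row per residue")
  if (length(object@atoms) != L) msg <- c(msg, "atoms must have one entry per residue")
  if (ncol(object@cbeta) != 3L) msg <- c(msg, "cbeta must have 3 columns")
  if (length(msg)) msg else TRUE
})

#' Construct a StructureChain from coordinates
#'
#' @param sequence one-letter residue codes (vector or single string).
#' @param cbeta L x 3 coordinate matrix.
#' @param atoms optional list of per-residue heavy-atom matrices; default
#'   a single atom per residue at the Cb coordinate.
#' @param id identifier.
#' @param resolution resolution in Angstrom.
#' @return a [StructureChain].
#' @export
StructureChain <- function(sequence, cbeta, atoms = NULL, id = "chain",
                           resolution = NA_real_) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  cbeta <- as.matrix(cbeta)
  if (is.null(atoms))
    atoms <- lapply(seq_len(nrow(cbeta)), function(i) cbeta[i, , drop = FALSE])
  new("StructureChain", id = id, sequence = sequence, cbeta = cbeta,
      atoms = atoms, resolution = resolution)
}

#' @describeIn StructureChain number of residues.
#' @param x a [StructureChain].
#' @export
chainLength <- function(x) length(x@sequence)

#' @describeIn StructureChain the one-letter sequence as a single string.
#' @export
chainSequence <- function(x) paste(x@sequence, collapse = "")

setMethod("show", "StructureChain", function(object) {
  cat(sprintf("StructureChain '%s': %d residues, resolution %.2f A\n",
              object@id, chainLength(object), object@resolution))
})

#' Read one chain from a PDB or mmCIF file
#'
#' Uses bio3d; keeps ATOM records of the requested chain, drops
#' hydrogens, and for alternate conformations keeps the
#' highest-occupancy one.  Residues missing a Cb (other than glycine,
#' where Ca is the definition) fall back to Ca; the number of fallbacks
#' is reported as attribute `cbFallbacks`.
#'
#' @param path coordinate file.
#' @param chain chain identifier (default: first chain in the file).
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param resolution optional resolution override in Angstrom.
#' @return a [StructureChain].
#' @export
readStructureChain <- function(path, chain = NULL,
                               format = c("auto", "pdb", "cif"),
                               resolution = NA_real_) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  pdb <- if (format == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records for chain ", chain)
  elem <- if ("elesy" %in% names(at) && !all(is.na(at$elesy))) at$elesy else
    sub("^[0-9]*([A-Za-z]).*", "\\1", at$elety)
  at <- at[toupper(elem) != "H", , drop = FALSE]          # heavy atoms only
  if (!"o" %in% names(at) || all(is.na(at$o))) at$o <- 1
  # highest-occupancy altloc per (residue, atom name)
  key <- paste(at$resno, at$insert, at$elety)
  at <- at[order(key, -at$o), , drop = FALSE]
  at <- at[!duplicated(paste(at$resno, at$insert, at$elety)), , drop = FALSE]
  at <- at[order(at$resno), , drop = FALSE]
  resKey <- paste(at$resno, at$insert)
  resIds <- unique(resKey)
  seq1 <- character(length(resIds))
  cb <- matrix(NA_real_, length(resIds), 3L)
  atoms <- vector("list", length(resIds))
  nFallback <- 0L
  for (r in seq_along(resIds)) {
    sub <- at[resKey == resIds[r], , drop = FALSE]
    seq1[r] <- bio3d::aa321(sub$resid[1])
    atoms[[r]] <- as.matrix(sub[, c("x", "y", "z")])
    pick <- if (seq1[r] == "G") which(sub$elety == "CA") else which(sub$elety == "CB")
    if (!length(pick) && seq1[r] != "G") {
      pick <- which(sub$elety == "CA")
      if (length(pick)) nFallback <- nFallback + 1L
    }
    if (length(pick)) cb[r, ] <- as.numeric(sub[pick[1], c("x", "y", "z")])
  }
  out <- StructureChain(seq1, cb, atoms, id = basename(path),
                        resolution = resolution)
  attr(out, "cbFallbacks") <- nFallback
  out
}

#' Write a chain as a minimal PDB file
#'
#' Writes one CB pseudo-atom per residue (CA for glycine), which is
#' sufficient for the synthetic single-atom chains this package
#' generates.
#'
#' @param chain a [StructureChain].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeChainPdb <- function(chain, path) {
  L <- chainLength(chain)
  aa3 <- bio3d::aa123(chain@sequence)
  ele <- ifelse(chain@sequence == "G", "CA", "CB")
  lines <- sprintf("ATOM  %5d  %-3s%4s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                   seq_len(L), ele, aa3, seq_len(L),
                   chain@cbeta[, 1], chain@cbeta[, 2], chain@cbeta[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Boolean residue-residue contact map
#'
#' @slot contacts symmetric logical L x L matrix.
#' @slot definition `"cbeta"`, `"all_atom"` or `"physical"`.
#' @slot threshold distance threshold in Angstrom.
#' @slot minSeparation minimum sequence separation of recorded pairs.
#' @aliases ContactMap
#' @exportClass ContactMap
setClass("ContactMap",
  representation(contacts = "matrix", definition = "character",
                 threshold = "numeric", minSeparation = "integer"))

setValidity("ContactMap", function(object) {
  msg <- character()
  cm <- object@contacts
  if (!is.logical(cm) || nrow(cm) != ncol(cm))
    msg <- c(msg, "contacts must be a square logical matrix")
  if (any(diag(cm))) msg <- c(msg, "no self-contacts allowed")
  if (!identical(cm, t(cm))) msg <- c(msg, "contacts must be symmetric")
  if (length(msg)) msg else TRUE
})

#' @describeIn ContactMap the logical contact matrix.
#' @param x a [ContactMap].
#' @export
contactMatrix <- function(x) x@contacts

#' @describeIn ContactMap number of contacts (unordered pairs).
#' @export
nContacts <- function(x) sum(x@contacts[upper.tri(x@contacts)])

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap [%s, %.2f A, sep >= %d]: %d residues, %d contacts\n",
              object@definition, object@threshold, object@minSeparation,
              nrow(object@contacts), nContacts(object)))
})

#' Build a ContactMap from a pair list
#'
#' @param pairs 2-column matrix of 1-based residue pairs.
#' @param L number of residues.
#' @param definition,threshold,minSeparation metadata (defaults `"cbeta"`,
#'   8, 5).
#' @return a [ContactMap].
#' @export
contactMapFromPairs <- function(pairs, L, definition = "cbeta",
                                threshold = 8, minSeparation = 5L) {
  cm <- matrix(FALSE, L, L)
  if (length(pairs)) {
    pairs <- as.matrix(pairs)
    cm[pairs] <- TRUE
    cm[pairs[, 2:1, drop = FALSE]] <- TRUE
  }
  diag(cm) <- FALSE
  new("ContactMap", contacts = cm, definition = definition,
      threshold = threshold, minSeparation = as.integer(minSeparation))
}

#' Compute a contact map from a structure chain
#'
#' Three definitions: `"cbeta"` -- Cb-Cb distance (Ca for glycine)
#' `<= threshold` (inclusive); `"all_atom"` -- any heavy-atom pair
#' `<= threshold`; `"physical"` -- any heavy-atom pair strictly
#' `< threshold` (default 3.5 A for this definition).  Pairs separated by
#' fewer than `minSeparation` residues in sequence are excluded.
#' Residues missing all usable coordinates are excluded from every pair;
#' their count is available as attribute `excludedResidues`.
#'
#' @param chain a [StructureChain].
#' @param definition contact definition.
#' @param threshold distance threshold in Angstrom (default 8 for
#'   `cbeta`/`all_atom`, 3.5 for `physical`).
#' @param minSeparation minimum sequence separation (default 5).
#' @return a [ContactMap].
#' @export
contactMap <- function(chain, definition = c("cbeta", "all_atom", "physical"),
                       threshold = NULL, minSeparation = 5L) {
  definition <- match.arg(definition)
  if (is.null(threshold)) threshold <- if (definition == "physical") 3.5 else 8
  stopifnot(threshold > 0)
  L <- chainLength(chain)
  cm <- matrix(FALSE, L, L)
  excluded <- integer(0)
  if (definition == "cbeta") {
    ok <- which(stats::complete.cases(chain@cbeta))
    excluded <- setdiff(seq_len(L), ok)
    if (length(ok) > 1L) {
      d <- as.matrix(stats::dist(chain@cbeta[ok, , drop = FALSE]))
      cm[ok, ok] <- d <= threshold
    }
  } else {
    nat <- vapply(chain@atoms, nrow, integer(1))
    ok <- which(nat > 0L)
    excluded <- setdiff(seq_len(L), ok)
    strict <- definition == "physical"
    for (a in seq_along(ok)) {
      i <- ok[a]
      if (a == length(ok)) break
      for (b in (a + 1L):length(ok)) {
        j <- ok[b]
        dmin <- minInterAtomDistance(chain@atoms[[i]], chain@atoms[[j]])
        cm[i, j] <- cm[j, i] <- if (strict) dmin < threshold else dmin <= threshold
      }
    }
  }
  cm <- cm & abs(row(cm) - col(cm)) >= minSeparation
  diag(cm) <- FALSE
  out <- new("ContactMap", contacts = cm | t(cm), definition = definition,
             threshold = threshold, minSeparation = as.integer(minSeparation))
  attr(out, "excludedResidues") <- length(excluded)
  out
}

minInterAtomDistance <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(max(0, min(d2)))
}

#' Fraction of contacts that are physical contacts
#'
#' The number of residue pairs in physical contact (any heavy-atom pair
#' < 3.5 A) divided by the number of pairs in contact under the chosen
#' definition at `threshold`, both restricted to pairs separated by at
#' least `minSeparation` residues.
#'
#' @param chain a [StructureChain].
#' @param definition `"cbeta"` or `"all_atom"`.
#' @param threshold contact threshold (default 8 A).
#' @param physicalThreshold physical-contact threshold (default 3.5 A,
#'   strict).
#' @param minSeparation minimum sequence separation (default 5).
#' @return fraction in [0, 1].
#' @export
physicalContactFraction <- function(chain, definition = c("cbeta", "all_atom"),
                                    threshold = 8, physicalThreshold = 3.5,
                                    minSeparation = 5L) {
  definition <- match.arg(definition)
  denomMap <- contactMap(chain, definition, threshold, minSeparation)
  denom <- nContacts(denomMap)
  if (denom == 0L)
    stop("no contacts under the chosen definition (degenerate input)")
  phys <- contactMap(chain, "physical", physicalThreshold, minSeparation)
  both <- contactMatrix(phys) & contactMatrix(denomMap)
  sum(both[upper.tri(both)]) / denom
}

#' Map alignment columns to structure residues
#'
#' Global pairwise alignment (match +1, mismatch -1, gap open 5, gap
#' extend 1) between the domain sequence and the ATOM-record sequence;
#' matched positions define the column-to-residue mapping.  Mappings
#' covering less than `minCoverage` of the domain are flagged as failing
#' the inclusion rule (at least 80% of the domain must be resolved).
#'
#' @param domainSeq domain (alignment consensus/reference) sequence, one
#'   string.
#' @param chain a [StructureChain].
#' @param minCoverage coverage threshold (default 0.8).
#' @return list with `map` (data.frame `column`, `residue`), `coverage`,
#'   and `passes` (logical).
#' @export
mapColumnsToStructure <- function(domainSeq, chain, minCoverage = 0.8) {
  stopifnot(nchar(domainSeq) > 0, chainLength(chain) > 0)
  atomSeq <- chainSequence(chain)
  letters <- unique(c(strsplit(domainSeq, "")[[1]], strsplit(atomSeq, "")[[1]]))
  sub <- matrix(-1, length(letters), length(letters),
                dimnames = list(letters, letters))
  diag(sub) <- 1
  aln <- Biostrings::pairwiseAlignment(domainSeq, atomSeq, type = "global",
                                       substitutionMatrix = sub,
                                       gapOpening = 5, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ci <- ri <- 0L
  map <- matrix(0L, 0L, 2L)
  for (k in seq_along(p)) {
    if (p[k] != "-") ci <- ci + 1L
    if (s[k] != "-") ri <- ri + 1L
    if (p[k] != "-" && s[k] != "-" && p[k] == s[k])
      map <- rbind(map, c(ci, ri))
  }
  coverage <- nrow(map) / nchar(domainSeq)
  passes <- coverage >= minCoverage
  if (!passes)
    warning(sprintf("structure covers only %.1f%% of the domain (< %.0f%%)",
                    100 * coverage, 100 * minCoverage))
  list(map = data.frame(column = map[, 1], residue = map[, 2]),
       coverage = coverage, passes = passes)
}

#' Identity column-to-residue mapping
#'
#' @param L number of columns/residues.
#' @return mapping list as returned by [mapColumnsToStructure()].
#' @export
identityMapping <- function(L) {
  list(map = data.frame(column = seq_len(L), residue = seq_len(L)),
       coverage = 1, passes = TRUE)
}
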