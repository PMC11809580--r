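#' Read a FASTA alignment
#'
#' Alignments are stored as `DNAbin` matrices (ape), taxa in rows; all
#' sequences must have equal length.
#'
#' @param path FASTA file.
#' @return a `DNAbin` matrix.
#' @export
read_fasta <- function(path) {
  seqs <- ape::read.FASTA(path)
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences have unequal lengths; not an alignment")
  }
  validate_alignment(as.matrix(seqs))
}

#' Write a FASTA alignment (60-column wrapped)
#' @param aln a `DNAbin` matrix.
#' @param path output file.
#' @export
write_fasta <- function(aln, path) {
  ape::write.dna(aln, path, format = "fasta", colw = 60)
  invisible(path)
}

#' Build an alignment from named character strings (mainly for tests)
#' @param x named character vector of equal-length sequences.
#' @return a `DNAbin` matrix.
#' @export
aln_from_strings <- function(x) {
  stopifnot(!is.null(names(x)), length(unique(nchar(x))) == 1L)
  m <- matrix(unlist(strsplit(tolower(x), "")), nrow = length(x),
              byrow = TRUE, dimnames = list(names(x), NULL))
  validate_alignment(ape::as.DNAbin(m))
}

#' Validate alignment invariants
#' @param aln a `DNAbin` matrix.
#' @return the alignment, invisibly checked.
#' @export
validate_alignment <- function(aln) {
  if (!inherits(aln, "DNAbin") || !is.matrix(aln)) {
    stop("alignment must be a DNAbin matrix")
  }
  if (ncol(aln) < 1L) stop("alignment has no sites")
  if (is.null(rownames(aln)) || anyDuplicated(rownames(aln))) {
    stop("taxa must be uniquely named")
  }
  aln
}

#' Remove one taxon from an alignment
#' @param aln a `DNAbin` matrix.
#' @param s taxon to remove.
#' @return the alignment without `s` (site count unchanged).
#' @export
drop_taxon <- function(aln, s) {
  if (!s %in% rownames(aln)) stop("taxon '", s, "' not in alignment")
  aln[setdiff(rownames(aln), s), , drop = FALSE]
}

## IUPAC ambiguity -> partial-likelihood state vectors (a, c, g, t);
## gaps and unknowns are all-ones (missing data)
iupac_vectors <- local({
  tab <- list(
    a = c(1, 0, 0, 0), c = c(0, 1, 0, 0), g = c(0, 0, 1, 0), t = c(0, 0, 0, 1),
    r = c(1, 0, 1, 0), y = c(0, 1, 0, 1), s = c(0, 1, 1, 0), w = c(1, 0, 0, 1),
    k = c(0, 0, 1, 1), m = c(1, 1, 0, 0),
    b = c(0, 1, 1, 1), d = c(1, 0, 1, 1), h = c(1, 1, 0, 1), v = c(1, 1, 1, 0),
    n = c(1, 1, 1, 1), `-` = c(1, 1, 1, 1), `?` = c(1, 1, 1, 1),
    `.` = c(1, 1, 1, 1), x = c(1, 1, 1, 1), u = c(0, 0, 0, 1)
  )
  function(ch) {
    v <- tab[[ch]]
    if (is.null(v)) c(1, 1, 1, 1) else v
  }
})

## compress an alignment into unique site patterns with weights;
## tips[[taxon]] is a 4 x n_patterns partial-likelihood matrix
aln_patterns <- function(aln, taxa = rownames(aln)) {
  missing <- setdiff(taxa, rownames(aln))
  if (length(missing)) {
    stop("taxa without a sequence: ", paste(missing, collapse = ", "))
  }
  chars <- tolower(as.character(aln[taxa, , drop = FALSE]))
  keys <- apply(chars, 2, paste, collapse = "")
  uniq <- !duplicated(keys)
  pat_id <- match(keys, keys[uniq])
  weights <- tabulate(pat_id, nbins = sum(uniq))
  cols <- which(uniq)
  tips <- lapply(seq_along(taxa), function(i) {
    vapply(chars[i, cols], iupac_vectors, numeric(4))
  })
  names(tips) <- taxa
  list(tips = tips, weights = weights, pattern_index = pat_id,
       n_sites = ncol(aln), n_patterns = length(cols))
}

#' Remove exact duplicate sequences from an alignment
#'
#' Sequences that are byte-for-byte identical (no case folding, no
#' ambiguity matching) are collapsed to their first occurrence in input
#' order. Maximum-likelihood inference is not identifiable with duplicate
#' sequences, so deduplication precedes every leave-one-out analysis.
#'
#' @param aln a `DNAbin` matrix.
#' @param min_taxa error if fewer unique sequences remain (the
#'   leave-one-out loop needs reduced trees with at least 4 leaves).
#' @return the deduplicated alignment, with a `removed` attribute mapping
#'   each dropped taxon to its kept representative.
#' @export
dedupe_alignment <- function(aln, min_taxa = 5L) {
  raw <- apply(as.character(aln), 1, paste, collapse = "")
  keep <- !duplicated(raw)
  removed <- character(0)
  if (any(!keep)) {
    rep_of <- rownames(aln)[match(raw[!keep], raw)]
    removed <- setNames(rep_of, rownames(aln)[!keep])
  }
  out <- aln[keep, , drop = FALSE]
  if (nrow(out) < min_taxa) {
    stop("deduplication leaves ", nrow(out), " taxa; need at least ", min_taxa)
  }
  attr(out, "removed") <- removed
  out
}
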