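# Residue correspondences between two folds. Tau depositions share the
# canonical 2N4R numbering, so the default correspondence simply pairs equal
# residue numbers; that tolerates point mutations (305 I vs S pairs anyway)
# and lets 3R and 4R splicing forms be compared, with the R2 repeat left
# unpaired. Sequence-based Needleman-Wunsch alignment is the fallback for
# chains whose numbering schemes differ.

#' Construct a residue correspondence
#'
#' Pairs are indices into chain A and chain B, strictly increasing in both
#' chains (monotone, no crossings). Segments are the maximal runs in which
#' both residue numbers increment by exactly one per step; windows for RMSD
#' scanning never cross a segment boundary, so splicing gaps and chain
#' breaks bound them.
#'
#' @param chainA,chainB the two [residue_chain] objects.
#' @param pairs two-column integer matrix of (index into A, index into B).
#' @param method label recording how the pairing was made.
#' @param score optional alignment score (sequence mode).
#' @return an object of class `residue_correspondence`.
#' @export
residue_correspondence <- function(chainA, chainB, pairs,
                                   method = "numbering", score = NULL) {
  stopifnot(inherits(chainA, "residue_chain"),
            inherits(chainB, "residue_chain"))
  pairs <- matrix(as.integer(pairs), ncol = 2L,
                  dimnames = list(NULL, c("a", "b")))
  if (nrow(pairs) == 0L) stop("residue_correspondence: no pairs")
  if (any(diff(pairs[, 1]) <= 0L) || any(diff(pairs[, 2]) <= 0L))
    stop("residue_correspondence: indices must be strictly increasing")
  resA <- chainA$resno[pairs[, 1]]
  resB <- chainB$resno[pairs[, 2]]
  if (nrow(pairs) > 1L) {
    new_seg <- c(FALSE, diff(resA) != 1L | diff(resB) != 1L)
    segment <- cumsum(new_seg) + 1L
  } else segment <- 1L
  structure(
    list(pairs = pairs, resnoA = resA, resnoB = resB, segment = segment,
         idA = chainA$chain_id, idB = chainB$chain_id,
         method = method, score = score),
    class = "residue_correspondence"
  )
}

#' @export
print.residue_correspondence <- function(x, ...) {
  cat(sprintf(
    "<residue_correspondence> %s vs %s: %d pairs, %d segment(s), method %s\n",
    x$idA, x$idB, nrow(x$pairs), max(x$segment), x$method))
  invisible(x)
}

#' Correspondence by canonical residue numbering
#'
#' Pairs exactly the residue numbers present in both chains. Differing
#' amino acids at a shared number (point mutants such as 305 I vs S) are
#' paired; numbers present in only one chain (e.g. the R2 repeat absent
#' from 3R isoforms) stay unpaired and split the correspondence into
#' segments.
#'
#' @param chainA,chainB [residue_chain] objects using the same canonical
#'   numbering scheme.
#' @return a [residue_correspondence].
#' @export
correspond_by_numbering <- function(chainA, chainB) {
  shared <- intersect(chainA$resno, chainB$resno)
  if (length(shared) == 0L)
    stop("correspond_by_numbering: no shared residue numbers between '",
         chainA$chain_id, "' and '", chainB$chain_id, "'")
  shared <- sort(shared)
  residue_correspondence(chainA, chainB,
                         cbind(match(shared, chainA$resno),
                               match(shared, chainB$resno)),
                         method = "numbering")
}

#' Correspondence by global sequence alignment
#'
#' Needleman-Wunsch global alignment of the one-letter sequences with the
#' BLOSUM62 substitution matrix; aligned non-gap columns become pairs. Gap
#' penalties default high relative to mismatch scores so that splicing-size
#' gaps, not scattered single gaps, emerge, and mutated positions are
#' matched rather than pushed into gaps. An aligned gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param chainA,chainB non-empty [residue_chain] objects.
#' @param gap_open,gap_extend positive gap penalties.
#' @return a [residue_correspondence] carrying the alignment score.
#' @export
correspond_by_sequence <- function(chainA, chainB, gap_open = 10,
                                   gap_extend = 0.5) {
  sA <- paste(chainA$aa, collapse = "")
  sB <- paste(chainB$aa, collapse = "")
  if (nchar(sA) == 0L || nchar(sB) == 0L)
    stop("correspond_by_sequence: empty chain")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sA), Biostrings::AAString(sB),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- ib <- 0L
  pairs <- matrix(0L, 0L, 2L)
  for (k in seq_along(pa)) {
    if (pa[k] != "-") ia <- ia + 1L
    if (sb[k] != "-") ib <- ib + 1L
    if (pa[k] != "-" && sb[k] != "-")
      pairs <- rbind(pairs, c(ia, ib))
  }
  residue_correspondence(chainA, chainB, pairs, method = "sequence",
                         score = Biostrings::score(aln))
}

#' Export a correspondence as a two-column TSV of residue numbers
#'
#' @param corr a [residue_correspondence].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_correspondence <- function(corr, path) {
  utils::write.table(
    data.frame(resno_a = corr$resnoA, resno_b = corr$resnoB),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
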