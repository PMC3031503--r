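#' Count k-mer occurrences in promoter sequences
#'
#' Builds a motif-count matrix from promoter sequences by exhaustive k-mer
#' scanning: one column for each of the \eqn{4^k} DNA words over
#' \{A,C,G,T\} in lexicographic order, one row per sequence, entries the
#' number of overlapping windows equal to that word. Windows containing a
#' non-ACGT character (e.g. N) match no word and are skipped. With
#' \code{revcomp = TRUE} each window also increments the column of its
#' reverse complement, making counting strand-symmetric.
#'
#' @param seqs a named \code{DNAStringSet} (see \code{\link{readPromoters}})
#'   or a named character vector of DNA sequences.
#' @param k word length, at least 1 and no longer than the longest sequence.
#' @param revcomp also count each window under its reverse complement.
#' @return an integer matrix, sequences x \eqn{4^k} k-mers, suitable as the
#'   motif matrix \eqn{M} of a \linkS4class{GMATDataset}.
#' @examples
#' countKmers(c(g1 = "ACGTACGT"), k = 4)[, "ACGT"]
#' @export
countKmers <- function(seqs, k, revcomp = FALSE) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    .parameterError("k must be a positive integer")
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (length(seqs) == 0L) .parameterError("no sequences given")
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    .validationError("sequences must be named by gene identifier")
  if (anyDuplicated(names(seqs)))
    .validationError("duplicated sequence identifiers")
  if (k > max(Biostrings::width(seqs)))
    .parameterError("k = %d exceeds the longest sequence (%d)",
                    k, max(Biostrings::width(seqs)))
  counts <- Biostrings::oligonucleotideFrequency(seqs, width = k)
  if (revcomp)
    counts <- counts + Biostrings::oligonucleotideFrequency(
      Biostrings::reverseComplement(seqs), width = k)
  rownames(counts) <- names(seqs)
  counts
}

#' Keep the most frequently present motifs
#'
#' Ranks motifs by presence (number of genes in which the count is
#' positive) and keeps the top \code{floor(fraction * m)}. When the
#' presence value at the selection boundary is shared by motifs on both
#' sides of the cut, all motifs with that value are excluded, so the
#' survivor set is unambiguous; ties entirely above the cut are kept.
#' Column order of survivors is preserved.
#'
#' @param M motif count matrix (genes x motifs) with dimnames.
#' @param fraction fraction of motifs to keep, in (0, 1].
#' @return \code{M} restricted to the surviving motif columns.
#' @export
filterFrequentMotifs <- function(M, fraction) {
  .checkLabeledMatrix(M, "motif matrix")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    .parameterError("fraction must be in (0, 1]")
  presence <- colSums(M > 0)
  m <- ncol(M)
  keep <- floor(fraction * m)
  if (keep == 0L) return(M[, integer(0), drop = FALSE])
  srt <- sort(presence, decreasing = TRUE)
  boundary <- srt[keep]
  tied <- keep < m && srt[keep + 1L] == boundary
  sel <- if (tied) presence > boundary else presence >= boundary
  M[, sel, drop = FALSE]
}

#' Binarize a motif count matrix
#'
#' Replaces counts by presence indicators: 1 where the count is positive,
#' 0 otherwise. Labels are unchanged; idempotent.
#'
#' @param M nonnegative motif count matrix with dimnames.
#' @return a 0/1 matrix of the same shape.
#' @export
binarizeMotifs <- function(M) {
  .checkLabeledMatrix(M, "motif matrix")
  if (any(M < 0)) .validationError("motif counts must be nonnegative")
  out <- (M > 0) + 0
  dimnames(out) <- dimnames(M)
  out
}

#' Build a binary gene-by-GO-term matrix
#'
#' Substitutes functional annotation for sequence motifs: the motif matrix
#' slot of the model is replaced by a binary matrix with entry 1 where a
#' gene carries a GO term. The \code{topN} terms annotating the most genes
#' among \code{genes} are selected (ties at the boundary broken by term
#' identifier, lexicographically).
#'
#' @param ann annotation pairs as returned by
#'   \code{\link{readAnnotationPairs}} (data.frame with columns
#'   \code{gene}, \code{term}).
#' @param genes character vector of gene identifiers defining the rows.
#' @param topN number of terms to keep.
#' @return a binary matrix, \code{genes} x selected terms.
#' @export
buildGOMatrix <- function(ann, genes, topN) {
  if (!is.data.frame(ann) || !all(c("gene", "term") %in% names(ann)))
    .validationError("ann must be a data.frame with columns gene and term")
  if (!is.numeric(topN) || length(topN) != 1L || topN < 1 || topN != round(topN))
    .parameterError("topN must be a positive integer")
  if (length(genes) == 0L || anyDuplicated(genes))
    .validationError("genes must be a non-empty set of unique identifiers")
  ann <- unique(ann[ann$gene %in% genes, , drop = FALSE])
  if (nrow(ann) == 0L)
    .validationError("no term annotates any of the listed genes")
  counts <- table(ann$term)
  ord <- order(-as.integer(counts), names(counts), method = "radix")
  terms <- names(counts)[ord][seq_len(min(topN, length(counts)))]
  out <- matrix(0, length(genes), length(terms),
                dimnames = list(genes, terms))
  hit <- ann[ann$term %in% terms, , drop = FALSE]
  out[cbind(match(hit$gene, genes), match(hit$term, terms))] <- 1
  out
}
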