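#' Construct a GMATDataset from its three matrices
#'
#' Builds the aligned container for the bilinear model \eqn{G = M A T + E}.
#' The constructor is strict: gene identifiers (rows of \code{G} and
#' \code{M}) and experiment identifiers (columns of \code{G} and \code{T})
#' must agree exactly, in order. Use \code{\link{alignGMAT}} to intersect
#' and reorder mismatched inputs first.
#'
#' @param G numeric gene x experiment expression matrix with dimnames.
#' @param M numeric gene x motif count matrix with dimnames.
#' @param T numeric TF x experiment expression matrix with dimnames.
#' @return a \linkS4class{GMATDataset}.
#' @examples
#' G <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("e1", "e2")))
#' M <- matrix(rpois(6, 1), 3, 2, dimnames = list(rownames(G), c("mo1", "mo2")))
#' T <- matrix(rnorm(4), 2, 2, dimnames = list(c("tf1", "tf2"), colnames(G)))
#' d <- GMATDataset(G, M, T)
#' gmatDims(d)
#' @export
GMATDataset <- function(G, M, T) {
  .checkLabeledMatrix(G, "expression matrix G")
  .checkLabeledMatrix(M, "motif matrix M")
  .checkLabeledMatrix(T, "TF matrix T")
  if (!identical(rownames(G), rownames(M)))
    .validationError("gene identifiers of G and M differ (order matters); see alignGMAT()")
  if (!identical(colnames(G), colnames(T)))
    .validationError("experiment identifiers of G and T differ (order matters); see alignGMAT()")
  cd <- DataFrame(row.names = colnames(G))
  cd$tfExpr <- t(T)
  rd <- DataFrame(row.names = rownames(G))
  rd$motifCounts <- M
  se <- SummarizedExperiment(assays = list(expr = G), rowData = rd, colData = cd)
  new("GMATDataset", se)
}

#' Align an expression / motif / TF triple on shared identifiers
#'
#' Restricts the three matrices to the genes shared by \code{G} and \code{M}
#' and the experiments shared by \code{G} and \code{T}, reordering everything
#' to \code{G}'s order (one deterministic convention so coefficient ordering
#' is reproducible). Counts of dropped identifiers are reported via
#' \code{message()}.
#'
#' @inheritParams GMATDataset
#' @return a \linkS4class{GMATDataset} on the identifier intersections.
#' @export
alignGMAT <- function(G, M, T) {
  .checkLabeledMatrix(G, "expression matrix G")
  .checkLabeledMatrix(M, "motif matrix M")
  .checkLabeledMatrix(T, "TF matrix T")
  genes <- intersect(rownames(G), rownames(M))
  exps <- intersect(colnames(G), colnames(T))
  if (length(genes) == 0L)
    .alignmentError("no genes shared between G and M")
  if (length(exps) == 0L)
    .alignmentError("no experiments shared between G and T")
  genes <- rownames(G)[rownames(G) %in% genes]   # G's order is canonical
  exps <- colnames(G)[colnames(G) %in% exps]
  dropped <- c(nrow(G) - length(genes), nrow(M) - length(genes),
               ncol(G) - length(exps), ncol(T) - length(exps))
  if (any(dropped > 0L))
    message(sprintf(
      "alignGMAT: dropped %d gene(s) from G, %d from M; %d experiment(s) from G, %d from T",
      dropped[1L], dropped[2L], dropped[3L], dropped[4L]))
  GMATDataset(G[genes, exps, drop = FALSE],
              M[genes, , drop = FALSE],
              T[, exps, drop = FALSE])
}

#' Accessors for the three matrices of a GMATDataset
#'
#' \code{exprMatrix} returns the gene x experiment expression matrix
#' \eqn{G}; \code{motifMatrix} the gene x motif count matrix \eqn{M};
#' \code{tfMatrix} the TF x experiment expression matrix \eqn{T};
#' \code{gmatDims} the named dimension vector \code{(n, p, m, t)} =
#' (genes, experiments, motifs, TFs).
#'
#' @param x a \linkS4class{GMATDataset}.
#' @return a base matrix (or, for \code{gmatDims}, a named integer vector).
#' @name gmat-accessors
NULL

#' @rdname gmat-accessors
#' @export
exprMatrix <- function(x) assay(x, "expr")

#' @rdname gmat-accessors
#' @export
motifMatrix <- function(x) rowData(x)$motifCounts

#' @rdname gmat-accessors
#' @export
tfMatrix <- function(x) t(colData(x)$tfExpr)

#' @rdname gmat-accessors
#' @export
gmatDims <- function(x) {
  c(n = nrow(x), p = ncol(x),
    m = ncol(rowData(x)$motifCounts), t = ncol(colData(x)$tfExpr))
}

#' @describeIn GMATDataset compact display.
#' @param object a \linkS4class{GMATDataset}.
#' @export
setMethod("show", "GMATDataset", function(object) {
  d <- gmatDims(object)
  cat(sprintf(
    "GMATDataset: %d genes x %d experiments, %d motifs, %d TFs\n",
    d["n"], d["p"], d["m"], d["t"]))
  cat("  genes:", paste(head(rownames(object), 4L), collapse = ", "),
      if (nrow(object) > 4L) "..." else "", "\n")
  cat("  experiments:", paste(head(colnames(object), 4L), collapse = ", "),
      if (ncol(object) > 4L) "..." else "", "\n")
})

#' Center a GMATDataset for the centered estimators
#'
#' Removes additive gene and experiment effects before fitting: motif
#' columns of \eqn{M} are centered over genes, TF rows of \eqn{T} over
#' experiments, and \eqn{G} is (by default) double-centered,
#' \eqn{\tilde g_{ij} = g_{ij} - \bar g_{i.} - \bar g_{.j} + \bar g}.
#' Centering reduces correlations among the bilinear predictor products
#' \eqn{m_{ik} t_{lj}} while preserving their correlation with expression,
#' which lowers the variance of the estimated coefficients.
#'
#' @param D a \linkS4class{GMATDataset} with at least 2 genes and 2
#'   experiments.
#' @param gCentering how to center \eqn{G}: \code{"double"} (default; row,
#'   column and grand mean), \code{"row"} or \code{"column"}.
#' @return a centered \linkS4class{GMATDataset} with unchanged labels.
#' @export
centerDataset <- function(D, gCentering = c("double", "row", "column")) {
  gCentering <- match.arg(gCentering)
  d <- gmatDims(D)
  if (d["n"] < 2L || d["p"] < 2L)
    .parameterError("centering needs at least 2 genes and 2 experiments")
  G <- exprMatrix(D)
  M <- motifMatrix(D)
  TT <- tfMatrix(D)
  Mc <- sweep(M, 2L, colMeans(M))
  Tc <- sweep(TT, 1L, rowMeans(TT))
  Gc <- switch(gCentering,
    double = sweep(sweep(G, 1L, rowMeans(G)), 2L, colMeans(G)) + mean(G),
    row = sweep(G, 1L, rowMeans(G)),
    column = sweep(G, 2L, colMeans(G)))
  GMATDataset(Gc, Mc, Tc)
}
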