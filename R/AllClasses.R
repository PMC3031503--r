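#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' GMATDataset: an aligned expression / motif / TF-expression triple
#'
#' Container for the three matrices of the bilinear regulatory model
#' \eqn{G = M A T + E}: the gene-by-experiment expression matrix \eqn{G}
#' (stored as the \code{"expr"} assay), the gene-by-motif count matrix
#' \eqn{M} (a matrix column of \code{rowData}) and the TF-by-experiment
#' expression matrix \eqn{T} (transposed into a matrix column of
#' \code{colData}). Extending \code{SummarizedExperiment} keeps the three
#' matrices aligned under subsetting: \code{x[i, j]} restricts genes and
#' experiments consistently in all of them.
#'
#' @slot .. inherited from \linkS4class{SummarizedExperiment}.
#' @seealso \code{\link{GMATDataset}}, \code{\link{alignGMAT}}
#' @export
setClass("GMATDataset", contains = "SummarizedExperiment")

setValidity("GMATDataset", function(object) {
  if (!"expr" %in% SummarizedExperiment::assayNames(object))
    return("assay 'expr' is missing")
  if (is.null(rowData(object)$motifCounts))
    return("rowData column 'motifCounts' is missing")
  if (is.null(colData(object)$tfExpr))
    return("colData column 'tfExpr' is missing")
  G <- assay(object, "expr")
  M <- rowData(object)$motifCounts
  TT <- colData(object)$tfExpr
  if (nrow(object) < 1L || ncol(object) < 1L)
    return("dataset needs at least one gene and one experiment")
  if (ncol(M) < 1L) return("dataset needs at least one motif")
  if (ncol(TT) < 1L) return("dataset needs at least one TF")
  if (!all(is.finite(G))) return("expression matrix has non-finite values")
  if (!all(is.finite(M))) return("motif matrix has non-finite values")
  if (!all(is.finite(TT))) return("TF matrix has non-finite values")
  TRUE
})

#' GMATFit: an estimated motif-by-TF coefficient matrix
#'
#' Result of fitting the bilinear model: the estimate \eqn{\hat A}
#' (motifs \eqn{\times} TFs), the estimator's name, its hyperparameters and
#' fitting diagnostics (residual sum of squares, iterations, convergence).
#'
#' @slot coefficients numeric matrix, motifs x TFs.
#' @slot method character, estimator name ("ls", "centered-ls", "ridge",
#'   "centered-ridge", "sparse", "correlation").
#' @slot hyperparameters named list of tuning values used.
#' @slot diagnostics named list: at least \code{rss}; iterative fits add
#'   \code{iterations}, \code{converged} and an objective trace.
#' @export
setClass("GMATFit",
  representation(coefficients = "matrix", method = "character",
                 hyperparameters = "list", diagnostics = "list"))

setValidity("GMATFit", function(object) {
  A <- object@coefficients
  if (is.null(rownames(A)) || is.null(colnames(A)))
    return("coefficient matrix must carry motif and TF identifiers")
  if (!all(is.finite(A))) return("coefficients must be finite")
  if (length(object@method) != 1L) return("method must be a single string")
  TRUE
})

#' GMATPath: a sparse-regression regularization path
#'
#' A decreasing \eqn{\lambda} grid, one \linkS4class{GMATFit} per grid point,
#' and the order in which (motif, TF) coefficients first become nonzero as
#' the penalty relaxes.
#'
#' @slot lambdas strictly decreasing positive numeric vector.
#' @slot fits list of \linkS4class{GMATFit}, parallel to \code{lambdas}.
#' @slot entryOrder data.frame with columns \code{motif}, \code{tf},
#'   \code{step} (grid index of first nonzero) and \code{value} (estimate at
#'   that step).
#' @export
setClass("GMATPath",
  representation(lambdas = "numeric", fits = "list", entryOrder = "data.frame"))

setValidity("GMATPath", function(object) {
  if (length(object@lambdas) != length(object@fits))
    return("one fit per lambda required")
  if (any(diff(object@lambdas) >= 0))
    return("lambdas must be strictly decreasing")
  TRUE
})

#' GMATZScores: permutation z-scores for model coefficients
#'
#' @slot zscores numeric matrix (motifs x TFs) of randomization z-scores.
#' @slot permutations integer, number of permuted refits.
#' @slot seed integer seed that generated the permutations.
#' @slot degeneratePairs data.frame (motif, tf) of coefficients whose
#'   randomized estimates had zero spread; their z is 0 by convention.
#' @export
setClass("GMATZScores",
  representation(zscores = "matrix", permutations = "integer",
                 seed = "integer", degeneratePairs = "data.frame"))

setValidity("GMATZScores", function(object) {
  if (!all(is.finite(object@zscores))) return("z-scores must be finite")
  if (object@permutations < 2L) return("at least 2 permutations required")
  TRUE
})

#' GMATSimSpec: generative parameters for a synthetic dataset
#'
#' @slot n,p,m,t dimensions: genes, experiments, motifs, TFs.
#' @slot density fraction of nonzero cells in the true coefficient matrix.
#' @slot coefSD standard deviation of the nonzero coefficients.
#' @slot motifRate Poisson mean of motif counts.
#' @slot tfSD standard deviation of TF expression values.
#' @slot noiseSD standard deviation of the additive Gaussian noise.
#' @slot seed integer RNG seed.
#' @export
setClass("GMATSimSpec",
  representation(n = "integer", p = "integer", m = "integer", t = "integer",
                 density = "numeric", coefSD = "numeric", motifRate = "numeric",
                 tfSD = "numeric", noiseSD = "numeric", seed = "integer"))

setValidity("GMATSimSpec", function(object) {
  if (any(c(object@n, object@p, object@m, object@t) < 1L))
    return("all dimensions must be >= 1")
  if (object@density <= 0 || object@density > 1)
    return("density must be in (0, 1]")
  if (any(c(object@coefSD, object@tfSD, object@noiseSD, object@motifRate) < 0))
    return("coefSD, tfSD, noiseSD and motifRate must be >= 0")
  TRUE
})

#' GMATSim: a simulated dataset with its ground truth
#'
#' @slot dataset the generated \linkS4class{GMATDataset}.
#' @slot trueCoefficients the coefficient matrix the data were generated
#'   from (motifs x TFs; exact zeros off the support).
#' @slot spec the \linkS4class{GMATSimSpec} used.
#' @export
setClass("GMATSim",
  representation(dataset = "GMATDataset", trueCoefficients = "matrix",
                 spec = "GMATSimSpec"))

setValidity("GMATSim", function(object) {
  A <- object@trueCoefficients
  d <- object@dataset
  if (!identical(rownames(A), colnames(rowData(d)$motifCounts)))
    return("true coefficient rows must match motif identifiers")
  if (!identical(colnames(A), colnames(colData(d)$tfExpr)))
    return("true coefficient columns must match TF identifiers")
  TRUE
})
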