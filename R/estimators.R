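#' @importFrom stats coef predict
NULL

.newFit <- function(A, D, method, hyper = list(), diag = list()) {
  dimnames(A) <- list(colnames(motifMatrix(D)), rownames(tfMatrix(D)))
  fit <- new("GMATFit", coefficients = A, method = method,
             hyperparameters = hyper, diagnostics = diag)
  if (is.null(fit@diagnostics$rss))
    fit@diagnostics$rss <- goodnessOfFit(D, fit)$rss
  fit
}

#' @describeIn GMATFit extract the coefficient matrix (motifs x TFs).
#' @param object a \linkS4class{GMATFit}.
#' @param ... unused.
#' @export
setMethod("coef", "GMATFit", function(object, ...) object@coefficients)

#' @describeIn GMATFit compact display.
#' @export
setMethod("show", "GMATFit", function(object) {
  A <- object@coefficients
  cat(sprintf("GMATFit (%s): %d motifs x %d TFs, rss = %.6g\n",
              object@method, nrow(A), ncol(A),
              object@diagnostics$rss))
  if (length(object@hyperparameters))
    cat("  hyperparameters:",
        paste(names(object@hyperparameters),
              vapply(object@hyperparameters, format, character(1L)),
              sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  nonzero coefficients: %d / %d\n", sum(A != 0), length(A)))
})

#' Predicted expression under a fitted bilinear model
#'
#' Computes \eqn{\hat G = M \hat A T}, the model's reconstruction of the
#' expression matrix, labeled like the observed \eqn{G}.
#'
#' @param D a \linkS4class{GMATDataset}.
#' @param fit a \linkS4class{GMATFit} whose motif and TF identifiers match
#'   \code{D}.
#' @return a gene x experiment matrix.
#' @export
predictExpression <- function(D, fit) {
  A <- coef(fit)
  if (!identical(rownames(A), colnames(motifMatrix(D))) ||
      !identical(colnames(A), rownames(tfMatrix(D))))
    .validationError("coefficient labels do not match the dataset")
  out <- motifMatrix(D) %*% A %*% tfMatrix(D)
  dimnames(out) <- dimnames(exprMatrix(D))
  out
}

#' @describeIn GMATFit predicted expression; equivalent to
#'   \code{predictExpression(newdata, object)}.
#' @param newdata a \linkS4class{GMATDataset}.
#' @export
setMethod("predict", "GMATFit", function(object, newdata, ...)
  predictExpression(newdata, object))

#' Decompose the fit of a bilinear model
#'
#' Returns the residual sum of squares \eqn{\|G - M \hat A T\|_F^2}, the
#' total sum of squares around the grand mean of \eqn{G}, and their
#' difference (the explained sum of squares).
#'
#' @inheritParams predictExpression
#' @return a list with components \code{rss}, \code{totalSS},
#'   \code{explainedSS}.
#' @export
goodnessOfFit <- function(D, fit) {
  G <- exprMatrix(D)
  rss <- sum((G - predictExpression(D, fit))^2)
  totalSS <- sum((G - mean(G))^2)
  list(rss = rss, totalSS = totalSS, explainedSS = totalSS - rss)
}

#' Minimum-norm least squares estimate of the coefficient matrix
#'
#' Solves \eqn{\min_A \|G - M A T\|_F^2} and, among all minimizers,
#' returns the one with smallest Frobenius norm,
#' \eqn{\hat A = M^{+} G T^{+}} (Moore-Penrose pseudoinverses). When
#' \eqn{M} has full column rank and \eqn{T} full row rank the minimizer is
#' unique and equals \eqn{(M^\top M)^{-1} M^\top G T^\top (T T^\top)^{-1}}.
#' Rank deficiency is handled by the pseudoinverse cutoff (singular values
#' below \code{max(dim) * eps * sigma1} are treated as zero).
#'
#' @param D a \linkS4class{GMATDataset}.
#' @return a \linkS4class{GMATFit} with method \code{"ls"}.
#' @export
fitLeastSquares <- function(D) {
  A <- .pinv(motifMatrix(D)) %*% exprMatrix(D) %*% .pinv(tfMatrix(D))
  .newFit(A, D, "ls")
}

#' Centered least squares estimate
#'
#' Least squares after centering (see \code{\link{centerDataset}}):
#' removes additive gene and experiment effects so that coefficients are
#' driven by co-variation only. More robust than plain least squares when
#' unmodeled additive influences are present.
#'
#' @inheritParams centerDataset
#' @return a \linkS4class{GMATFit} with method \code{"centered-ls"}.
#' @export
fitCenteredLeastSquares <- function(D, gCentering = "double") {
  fit <- fitLeastSquares(centerDataset(D, gCentering))
  fit@method <- "centered-ls"
  fit@hyperparameters <- list(gCentering = gCentering)
  fit
}

#' Ridge estimate of the coefficient matrix
#'
#' Computes the two-sided ridge estimate
#' \eqn{\hat A = (M^\top M + \lambda_1 I)^{-1} M^\top G T^\top
#' (T T^\top + \lambda_2 I)^{-1}} via linear solves. This is a tractable
#' surrogate for penalizing \eqn{\|A\|_F^2} directly (whose exact solution
#' has no closed matrix form) and reduces to least squares as both
#' penalties vanish.
#'
#' @param D a \linkS4class{GMATDataset}.
#' @param lambda1 ridge penalty on the motif side, \eqn{\ge 0}.
#' @param lambda2 ridge penalty on the TF side, \eqn{\ge 0}.
#' @return a \linkS4class{GMATFit} with method \code{"ridge"}.
#' @export
fitRidge <- function(D, lambda1 = 1, lambda2 = 1) {
  if (lambda1 < 0 || lambda2 < 0)
    .parameterError("ridge penalties must be nonnegative")
  M <- motifMatrix(D); TT <- tfMatrix(D); G <- exprMatrix(D)
  m <- ncol(M); t <- nrow(TT)
  if (lambda1 == 0 && qr(M)$rank < m)
    .singularError("M is rank deficient and lambda1 = 0; use fitLeastSquares()")
  if (lambda2 == 0 && qr(TT)$rank < t)
    .singularError("T is rank deficient and lambda2 = 0; use fitLeastSquares()")
  left <- solve(crossprod(M) + diag(lambda1, m), t(M) %*% G %*% t(TT))
  A <- t(solve(tcrossprod(TT) + diag(lambda2, t), t(left)))
  .newFit(A, D, "ridge", hyper = list(lambda1 = lambda1, lambda2 = lambda2))
}

#' Centered ridge estimate
#'
#' \code{\link{fitRidge}} applied to the centered dataset; combines the
#' stability of ridge shrinkage with the robustness of centering.
#'
#' @inheritParams fitRidge
#' @inheritParams centerDataset
#' @return a \linkS4class{GMATFit} with method \code{"centered-ridge"}.
#' @export
fitCenteredRidge <- function(D, lambda1 = 1, lambda2 = 1,
                             gCentering = "double") {
  fit <- fitRidge(centerDataset(D, gCentering), lambda1, lambda2)
  fit@method <- "centered-ridge"
  fit@hyperparameters <- c(fit@hyperparameters, list(gCentering = gCentering))
  fit
}

#' Soft-thresholding operator
#'
#' \eqn{S_\tau(x) = sign(x) max(|x| - \tau, 0)}, the proximal map of the
#' L1 penalty; applied elementwise in sparse regression.
#'
#' @param x numeric vector or matrix.
#' @param tau threshold, \eqn{\ge 0}.
#' @return \code{x} shrunk towards zero by \code{tau} and clipped at zero.
#' @export
softThreshold <- function(x, tau) {
  if (any(tau < 0)) .parameterError("threshold must be nonnegative")
  sign(x) * pmax(abs(x) - tau, 0)
}

# Smallest penalty at which the sparse solution is exactly zero, under the
# objective ||G - MAT||_F^2 + lambda * ||A||_1.
.lambdaMax <- function(D) {
  2 * max(abs(t(motifMatrix(D)) %*% exprMatrix(D) %*% t(tfMatrix(D))))
}

#' Sparse (L1-penalized) estimate via iterative soft thresholding
#'
#' Minimizes \eqn{F(A) = \|G - M A T\|_F^2 + \lambda \|A\|_1} (entry-wise
#' L1) by proximal gradient iteration from \eqn{A = 0}:
#' \deqn{A \leftarrow S_{\mu\lambda/2}\big(A + \mu M^\top (G - M A T)
#' T^\top\big),}
#' with automatic step size \eqn{\mu = 0.9 / (\sigma_1(M)^2 \sigma_1(T)^2)}
#' (a fraction of the inverse Lipschitz constant of the smooth part, which
#' guarantees descent). Under this scaling the scalar problem has the
#' closed form \eqn{\hat a = S_{\lambda/2}(g)} and the solution is exactly
#' zero for \eqn{\lambda \ge \lambda_{max} = 2 \max |M^\top G T^\top|}.
#' Coefficients with final magnitude below \code{tol} are snapped to
#' exactly zero so that the support is well defined.
#'
#' @param D a \linkS4class{GMATDataset}.
#' @param lambda L1 penalty, \eqn{\ge 0}. Alternatively give
#'   \code{lambdaRatio} to set \eqn{\lambda} as a fraction of
#'   \eqn{\lambda_{max}}.
#' @param lambdaRatio optional fraction of \eqn{\lambda_{max}} used when
#'   \code{lambda} is missing.
#' @param mu step size; \code{NULL} (default) for the automatic choice.
#' @param tol convergence tolerance on the maximum absolute coefficient
#'   change per iteration.
#' @param maxIter iteration cap; on hitting it the fit is returned with
#'   \code{converged = FALSE} and a warning.
#' @return a \linkS4class{GMATFit} with method \code{"sparse"}; diagnostics
#'   carry \code{iterations}, \code{converged} and
#'   \code{objectiveNonIncreasing}.
#' @export
fitSparse <- function(D, lambda = NULL, lambdaRatio = NULL, mu = NULL,
                      tol = 1e-8, maxIter = 10000L) {
  if (is.null(lambda)) {
    if (is.null(lambdaRatio))
      .parameterError("give lambda or lambdaRatio")
    lambda <- lambdaRatio * .lambdaMax(D)
  }
  if (lambda < 0) .parameterError("lambda must be nonnegative")
  M <- motifMatrix(D); TT <- tfMatrix(D); G <- exprMatrix(D)
  if (is.null(mu)) mu <- 0.9 / (.sigma1(M)^2 * .sigma1(TT)^2)
  if (mu <= 0) .parameterError("step size mu must be positive")
  MtM <- crossprod(M)
  TTt <- tcrossprod(TT)
  C <- t(M) %*% G %*% t(TT)        # gradient of the smooth part at 0 is -2C
  gss <- sum(G^2)
  objective <- function(A) {
    gss - 2 * sum(A * C) + sum((MtM %*% A) * (A %*% TTt)) + lambda * sum(abs(A))
  }
  A <- array(0, dim = c(ncol(M), nrow(TT)))
  objPrev <- objective(A)
  monotone <- TRUE
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    Anew <- softThreshold(A + mu * (C - MtM %*% A %*% TTt), mu * lambda / 2)
    obj <- objective(Anew)
    if (obj > objPrev + 1e-9 * max(1, abs(objPrev))) monotone <- FALSE
    delta <- max(abs(Anew - A))
    A <- Anew
    objPrev <- obj
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("fitSparse: not converged after %d iterations (last change %.3g)",
                    iter, delta))
  A[abs(A) < tol] <- 0
  .newFit(A, D, "sparse",
          hyper = list(lambda = lambda, mu = mu, tol = tol, maxIter = maxIter),
          diag = list(iterations = iter, converged = converged,
                      objective = objPrev, objectiveNonIncreasing = monotone))
}

#' Sparse regularization path over a penalty grid
#'
#' Follows the sparse solution over a geometric \eqn{\lambda} grid from
#' \eqn{\lambda_{max}} (where the estimate is exactly zero) down to
#' \eqn{\lambda_{max} \cdot} \code{lambdaMinRatio}, warm-starting each fit
#' at the previous solution. As the penalty relaxes, coefficients become
#' nonzero approximately one by one; the recorded entry order ranks
#' putative motif-TF associations. Ties within a grid step are broken by
#' magnitude at that step, then lexicographically by motif and TF
#' identifier.
#'
#' @param D a \linkS4class{GMATDataset}.
#' @param nLambdas number of grid points, at least 2.
#' @param lambdaMinRatio ratio of the smallest to the largest penalty, in
#'   (0, 1).
#' @param ... further arguments (\code{tol}, \code{maxIter}, \code{mu})
#'   passed to \code{\link{fitSparse}}.
#' @return a \linkS4class{GMATPath}.
#' @export
sparsePath <- function(D, nLambdas = 20L, lambdaMinRatio = 0.01, ...) {
  if (nLambdas < 2L) .parameterError("nLambdas must be at least 2")
  if (lambdaMinRatio <= 0 || lambdaMinRatio >= 1)
    .parameterError("lambdaMinRatio must be in (0, 1)")
  lmax <- .lambdaMax(D)
  if (lmax == 0) .parameterError("M'GT' is identically zero; no path exists")
  lambdas <- exp(seq(log(lmax), log(lmax * lambdaMinRatio),
                     length.out = nLambdas))
  fits <- vector("list", nLambdas)
  warm <- NULL
  for (i in seq_len(nLambdas)) {
    fit <- if (is.null(warm)) fitSparse(D, lambda = lambdas[i], ...)
           else .sparseWarm(D, lambdas[i], warm, ...)
    fits[[i]] <- fit
    warm <- coef(fit)
  }
  motifs <- rownames(coef(fits[[1L]]))
  tfs <- colnames(coef(fits[[1L]]))
  firstStep <- array(NA_integer_, dim = c(length(motifs), length(tfs)))
  firstVal <- array(NA_real_, dim = dim(firstStep))
  for (i in seq_len(nLambdas)) {
    Ai <- coef(fits[[i]])
    hit <- Ai != 0 & is.na(firstStep)
    firstStep[hit] <- i
    firstVal[hit] <- Ai[hit]
  }
  idx <- which(!is.na(firstStep), arr.ind = TRUE)
  ord <- order(firstStep[idx], -abs(firstVal[idx]),
               motifs[idx[, 1L]], tfs[idx[, 2L]], method = "radix")
  entry <- data.frame(motif = motifs[idx[ord, 1L]],
                      tf = tfs[idx[ord, 2L]],
                      step = firstStep[idx][ord],
                      value = firstVal[idx][ord])
  new("GMATPath", lambdas = lambdas, fits = fits, entryOrder = entry)
}

# fitSparse restarted from a warm initial matrix (internal; the public
# entry point always starts from zero, which the lambda_max identity needs).
.sparseWarm <- function(D, lambda, A0, mu = NULL, tol = 1e-8,
                        maxIter = 10000L) {
  M <- motifMatrix(D); TT <- tfMatrix(D); G <- exprMatrix(D)
  if (is.null(mu)) mu <- 0.9 / (.sigma1(M)^2 * .sigma1(TT)^2)
  MtM <- crossprod(M); TTt <- tcrossprod(TT)
  C <- t(M) %*% G %*% t(TT)
  A <- unname(A0)
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    Anew <- softThreshold(A + mu * (C - MtM %*% A %*% TTt), mu * lambda / 2)
    delta <- max(abs(Anew - A))
    A <- Anew
    if (delta < tol) { converged <- TRUE; break }
  }
  A[abs(A) < tol] <- 0
  .newFit(A, D, "sparse",
          hyper = list(lambda = lambda, mu = mu, tol = tol, maxIter = maxIter),
          diag = list(iterations = iter, converged = converged))
}

#' @describeIn GMATPath compact display.
#' @param object a \linkS4class{GMATPath}.
#' @export
setMethod("show", "GMATPath", function(object) {
  cat(sprintf("GMATPath: %d lambdas in [%.4g, %.4g], %d coefficients entered\n",
              length(object@lambdas), min(object@lambdas),
              max(object@lambdas), nrow(object@entryOrder)))
})

#' Correlation-based estimate of the coefficient matrix
#'
#' Estimates each coefficient independently from the third mixed moment of
#' expression, motif presence and TF expression:
#' \deqn{\hat a_{kl} = \frac{\frac{1}{np}\sum_{i,j}(g_{ij}-\bar g)
#' (m_{ik}-\bar m_k)(t_{lj}-\bar t_l)}{Var(m_k)\,Var(t_l)},}
#' with population (divide-by-count) moments. Under the generative reading
#' of the bilinear model, when motif presences and TF expressions are
#' pairwise independent of the other regulators, this recovers
#' \eqn{a_{kl}} using only the data for motif \eqn{k}, TF \eqn{l} and the
#' expression matrix - so it is unaffected by motifs or TFs missing from
#' the data. Coefficients whose motif column or TF row is constant have
#' undefined scale; they are set to 0 and reported in
#' \code{diagnostics$degenerate}, with a warning.
#'
#' @param D a \linkS4class{GMATDataset}.
#' @return a \linkS4class{GMATFit} with method \code{"correlation"}.
#' @export
fitCorrelation <- function(D) {
  G <- exprMatrix(D); M <- motifMatrix(D); TT <- tfMatrix(D)
  n <- nrow(G); p <- ncol(G)
  Mc <- sweep(M, 2L, colMeans(M))
  Tc <- sweep(TT, 1L, rowMeans(TT))
  Gc <- G - mean(G)
  # one motif at a time: coefficient (k, l) touches only motif column k,
  # TF row l and G, so removing other regulators cannot change it at all
  num <- matrix(NA_real_, ncol(M), nrow(TT))
  for (k in seq_len(ncol(M))) {
    vk <- as.vector(crossprod(Gc, Mc[, k]))          # length p
    for (l in seq_len(nrow(TT)))
      num[k, l] <- sum(vk * Tc[l, ]) / (n * p)
  }
  varM <- colMeans(Mc^2)    # population variances
  varT <- rowMeans(Tc^2)
  denom <- outer(varM, varT)
  degenerate <- denom == 0
  A <- num / denom
  A[degenerate] <- 0
  degList <- NULL
  if (any(degenerate)) {
    idx <- which(degenerate, arr.ind = TRUE)
    degList <- data.frame(motif = colnames(M)[idx[, 1L]],
                          tf = rownames(TT)[idx[, 2L]])
    warning(sprintf("fitCorrelation: %d coefficient(s) with a constant motif column or TF row set to 0",
                    nrow(degList)))
  }
  .newFit(A, D, "correlation",
          diag = list(degenerate = degList))
}

#' Fit the bilinear model with a named estimator
#'
#' Single dispatching front door over the individual estimators; the
#' permutation, stability and benchmark machinery route through it.
#'
#' @param D a \linkS4class{GMATDataset}.
#' @param method one of \code{"ls"}, \code{"centered-ls"}, \code{"ridge"},
#'   \code{"centered-ridge"}, \code{"sparse"}, \code{"correlation"}; or a
#'   function \code{(D, ...) -> GMATFit} implementing a custom estimator.
#' @param ... hyperparameters forwarded to the specific estimator
#'   (e.g. \code{lambda1}, \code{lambda2} for ridge; \code{lambda} or
#'   \code{lambdaRatio} for sparse).
#' @return a \linkS4class{GMATFit}.
#' @export
fitGMAT <- function(D, method = c("ls", "centered-ls", "ridge",
                                  "centered-ridge", "sparse", "correlation"),
                    ...) {
  if (is.function(method)) return(method(D, ...))
  method <- match.arg(method)
  switch(method,
    "ls" = fitLeastSquares(D),
    "centered-ls" = fitCenteredLeastSquares(D, ...),
    "ridge" = fitRidge(D, ...),
    "centered-ridge" = fitCenteredRidge(D, ...),
    "sparse" = fitSparse(D, ...),
    "correlation" = fitCorrelation(D))
}
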