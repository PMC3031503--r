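#' Permute an expression matrix for the randomization null
#'
#' Applies one uniformly random permutation to the rows and another to the
#' columns of \eqn{G}, decoupling expression from the motif and TF
#' matrices while preserving the multiset of values and all marginal
#' structure carried by rows and columns. Labels stay attached to their
#' original positions, so the permuted matrix slots straight back into a
#' dataset.
#'
#' @param G numeric matrix with dimnames.
#' @param seed integer seed for the two permutations.
#' @return a matrix of the same shape and labels.
#' @export
permuteExpression <- function(G, seed) {
  .checkLabeledMatrix(G, "expression matrix")
  .withSeed(seed, {
    out <- G[sample(nrow(G)), sample(ncol(G)), drop = FALSE]
    dimnames(out) <- dimnames(G)
    out
  })
}

#' Permutation z-scores for model coefficients
#'
#' Fits the chosen estimator on the observed data and on \code{r} datasets
#' in which \eqn{G} is row-and-column permuted, then standardizes each
#' observed coefficient against its randomized distribution:
#' \deqn{z_{kl} = \frac{\hat a_{kl} - mean_i\, \hat a^{(i)}_{kl}}
#' {sd_i\, \hat a^{(i)}_{kl}}}
#' (population sd over the \code{r} permutations). Large \eqn{|z|} flags
#' coefficients that could not have arisen had expression been independent
#' of motifs and TFs. Pairs whose randomized estimates have zero spread
#' get \eqn{z = 0} and are listed as degenerate rather than infinite.
#'
#' @param D a \linkS4class{GMATDataset}.
#' @param method estimator name, see \code{\link{fitGMAT}}.
#' @param estimatorArgs list of hyperparameters for the estimator.
#' @param r number of permutations, at least 2 (default 30).
#' @param seed integer; permutation \code{i} uses \code{seed + i}.
#' @return a \linkS4class{GMATZScores}.
#' @export
zScores <- function(D, method = "centered-ls", estimatorArgs = list(),
                    r = 30L, seed = 1L) {
  if (r < 2L) .parameterError("r must be at least 2")
  fit <- do.call(fitGMAT, c(list(D = D, method = method), estimatorArgs))
  A <- coef(fit)
  M <- motifMatrix(D); TT <- tfMatrix(D); G <- exprMatrix(D)
  sums <- array(0, dim = dim(A))
  sq <- array(0, dim = dim(A))
  for (i in seq_len(r)) {
    Gi <- permuteExpression(G, seed + i)
    Ai <- tryCatch(
      coef(do.call(fitGMAT,
                   c(list(D = GMATDataset(Gi, M, TT), method = method),
                     estimatorArgs))),
      error = function(e)
        .gmatStop("gmat_estimator_error",
                  "estimator failed on permutation %d: %s", i,
                  conditionMessage(e)))
    sums <- sums + Ai
    sq <- sq + Ai^2
  }
  mu <- sums / r
  sdp <- sqrt(pmax(sq / r - mu^2, 0))
  degenerate <- sdp == 0
  Z <- array(0, dim = dim(A), dimnames = dimnames(A))
  Z[!degenerate] <- (A[!degenerate] - mu[!degenerate]) / sdp[!degenerate]
  degList <- data.frame(motif = character(0), tf = character(0))
  if (any(degenerate)) {
    idx <- which(degenerate, arr.ind = TRUE)
    degList <- data.frame(motif = rownames(A)[idx[, 1L]],
                          tf = colnames(A)[idx[, 2L]])
  }
  new("GMATZScores", zscores = Z, permutations = as.integer(r),
      seed = as.integer(seed), degeneratePairs = degList)
}

#' @describeIn GMATZScores compact display.
#' @param object a \linkS4class{GMATZScores}.
#' @export
setMethod("show", "GMATZScores", function(object) {
  cat(sprintf("GMATZScores: %d motifs x %d TFs, %d permutations (seed %d), %d degenerate pair(s)\n",
              nrow(object@zscores), ncol(object@zscores),
              object@permutations, object@seed,
              nrow(object@degeneratePairs)))
})

#' Accessor for the z-score matrix
#' @param x a \linkS4class{GMATZScores}.
#' @return the motifs x TFs z-score matrix.
#' @export
zscoreMatrix <- function(x) x@zscores

#' F-test of overall model significance
#'
#' Tests whether the fitted bilinear model explains more variance than the
#' grand mean alone: \eqn{F = (ess/df_1)/(rss/df_2)} with
#' \eqn{df_1 = rank(M)\,rank(T)} (the identifiable parameter count, which
#' is smaller than \eqn{m t} when predictors are collinear) and
#' \eqn{df_2 = np - df_1 - 1} (grand mean absorbed). A perfect fit
#' (\eqn{rss = 0}) reports \eqn{p = 0} by convention.
#'
#' @inheritParams predictExpression
#' @return a list with components \code{F}, \code{df1}, \code{df2},
#'   \code{p}.
#' @export
fTest <- function(D, fit) {
  M <- motifMatrix(D); TT <- tfMatrix(D)
  df1 <- qr(M)$rank * qr(TT)$rank
  d <- gmatDims(D)
  df2 <- as.integer(d["n"]) * as.integer(d["p"]) - df1 - 1L
  if (df2 <= 0L) .parameterError("model saturated: df2 = %d", df2)
  g <- goodnessOfFit(D, fit)
  if (g$rss == 0)
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0))
  Fstat <- (g$explainedSS / df1) / (g$rss / df2)
  list(F = Fstat, df1 = df1, df2 = df2,
       p = pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Rank motif-TF pairs by a score matrix
#'
#' Flattens a motifs x TFs score matrix (coefficients or z-scores) into an
#' ordered pair list: most positive first (\code{"largest"}), most
#' negative first (\code{"smallest"}), or by magnitude
#' (\code{"absolute"}). Ties are broken by motif identifier then TF
#' identifier, lexicographically.
#'
#' @param S numeric motifs x TFs matrix with dimnames.
#' @param direction ordering rule.
#' @param top number of pairs to return (capped at \code{m * t}).
#' @return a data.frame with columns \code{motif}, \code{tf}, \code{score}.
#' @export
rankPairs <- function(S, direction = c("largest", "smallest", "absolute"),
                      top = 10L) {
  .checkLabeledMatrix(S, "score matrix")
  direction <- match.arg(direction)
  if (!is.numeric(top) || length(top) != 1L || top < 1)
    .parameterError("top must be at least 1")
  motif <- rep(rownames(S), times = ncol(S))
  tf <- rep(colnames(S), each = nrow(S))
  score <- as.vector(S)
  key <- switch(direction, largest = -score, smallest = score,
                absolute = -abs(score))
  ord <- order(key, motif, tf, method = "radix")
  n <- min(top, length(score))
  data.frame(motif = motif[ord], tf = tf[ord], score = score[ord],
             row.names = NULL)[seq_len(n), ]
}

#' Split-set stability of the top coefficient pairs
#'
#' Randomly splits the experiments into two disjoint halves (sizes
#' \eqn{\lceil p/2 \rceil} and \eqn{\lfloor p/2 \rfloor}), fits the
#' estimator on each half, ranks the motif-TF pairs of each half by
#' coefficient magnitude, and counts the overlap of the two top-\code{k}
#' lists. The overlap is compared against drawing \code{topK} pairs twice
#' at random from the \eqn{m t} pairs with a hypergeometric upper-tail
#' p-value \eqn{P(X \ge overlap)}; this null assumes both halves rank the
#' same universe of pairs.
#'
#' @param D a \linkS4class{GMATDataset} with at least 4 experiments.
#' @param method estimator name, see \code{\link{fitGMAT}}.
#' @param estimatorArgs list of hyperparameters for the estimator.
#' @param topK size of the compared top lists.
#' @param seed integer seed for the split.
#' @return a list with components \code{topK}, \code{overlap},
#'   \code{pValue}, \code{splitSizes}, \code{seed}, \code{topPairs}
#'   (a list with the two top-pair data.frames).
#' @export
splitSetStability <- function(D, method = "centered-ls",
                              estimatorArgs = list(), topK = 10L,
                              seed = 1L) {
  d <- gmatDims(D)
  if (d["p"] < 4L) .parameterError("need at least 4 experiments to split")
  if (topK > d["m"] * d["t"])
    .parameterError("topK exceeds the number of motif-TF pairs")
  p <- as.integer(d["p"])
  perm <- .withSeed(seed, sample(p))
  half1 <- sort(perm[seq_len(ceiling(p / 2))])
  half2 <- sort(perm[-seq_len(ceiling(p / 2))])
  fitHalf <- function(idx, which) {
    Dh <- GMATDataset(exprMatrix(D)[, idx, drop = FALSE], motifMatrix(D),
                      tfMatrix(D)[, idx, drop = FALSE])
    tryCatch(do.call(fitGMAT, c(list(D = Dh, method = method),
                                estimatorArgs)),
             error = function(e)
               .gmatStop("gmat_estimator_error",
                         "estimator failed on half %d: %s", which,
                         conditionMessage(e)))
  }
  tops <- lapply(seq_len(2L), function(h)
    rankPairs(coef(fitHalf(list(half1, half2)[[h]], h)),
              direction = "absolute", top = topK))
  keys <- lapply(tops, function(tp) paste(tp$motif, tp$tf, sep = "\r"))
  overlap <- length(intersect(keys[[1L]], keys[[2L]]))
  N <- as.integer(d["m"]) * as.integer(d["t"])
  pValue <- phyper(overlap - 1L, topK, N - topK, topK, lower.tail = FALSE)
  list(topK = as.integer(topK), overlap = overlap, pValue = pValue,
       splitSizes = c(length(half1), length(half2)),
       seed = as.integer(seed), topPairs = tops)
}
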