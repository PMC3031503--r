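# Fixture builders and independent oracles. Oracles deliberately use
# different routes (scalar loops, MASS::ginv, glmnet, exhaustive
# enumeration) from the implementation they check.

labeled <- function(values, nr, nc, rpre = "g", cpre = "e") {
  matrix(values, nr, nc,
         dimnames = list(paste0(rpre, seq_len(nr)), paste0(cpre, seq_len(nc))))
}

randomDataset <- function(n, p, m, t, seed, rankDeficient = FALSE) {
  set.seed(seed)
  M <- labeled(rnorm(n * m), n, m, "g", "mo")
  TT <- labeled(rnorm(t * p), t, p, "tf", "e")
  if (rankDeficient) {
    if (m >= 2) M[, m] <- M[, 1L]          # collinear motif columns
    if (t >= 2) TT[t, ] <- 2 * TT[1L, ]    # collinear TF rows
  }
  G <- labeled(rnorm(n * p), n, p, "g", "e")
  GMATDataset(G, M, TT)
}

# Minimum-norm solution of the vectorized regression vec(G) ~ (T' x M),
# via an independent pseudoinverse (MASS::ginv), reshaped to m x t.
kroneckerLSOracle <- function(D) {
  M <- motifMatrix(D); TT <- tfMatrix(D); G <- exprMatrix(D)
  X <- kronecker(t(TT), M)
  b <- MASS::ginv(X) %*% as.vector(G)
  matrix(b, ncol(M), nrow(TT), dimnames = list(colnames(M), rownames(TT)))
}

# Scalar triple-loop evaluation of the model prediction.
predictOracle <- function(D, A) {
  M <- motifMatrix(D); TT <- tfMatrix(D)
  n <- nrow(M); p <- ncol(TT)
  out <- matrix(0, n, p, dimnames = dimnames(exprMatrix(D)))
  for (i in seq_len(n)) for (j in seq_len(p)) {
    s <- 0
    for (k in seq_len(ncol(M))) for (l in seq_len(nrow(TT)))
      s <- s + M[i, k] * A[k, l] * TT[l, j]
    out[i, j] <- s
  }
  out
}

# L1-penalized vectorized fit via glmnet coordinate descent. glmnet
# minimizes (1/(2N)) ||y - Xb||^2 + lambda ||b||_1 with N = n*p, so the
# matrix objective ||G - MAT||^2 + lambda ||A||_1 maps to
# lambda_glmnet = lambda / (2 n p).
lassoOracle <- function(D, lambda) {
  M <- motifMatrix(D); TT <- tfMatrix(D); G <- exprMatrix(D)
  X <- kronecker(t(TT), M)
  y <- as.vector(G)
  lamG <- lambda / (2 * length(G))
  # a descending path ending at the target penalty; coordinate descent is
  # far more accurate warm-started along a path than at a single lambda
  fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                        lambda = lamG * 10^seq(2, 0, length.out = 50),
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-16, maxit = 1e7)
  b <- suppressWarnings(
    glmnet::coef.glmnet(fit, s = lamG, exact = TRUE, x = X, y = y))
  matrix(as.numeric(b)[-1L], ncol(M), nrow(TT),
         dimnames = list(colnames(M), rownames(TT)))
}

# Plain cyclic coordinate descent on the vectorized lasso
# min ||y - Xb||^2 + lambda ||b||_1, run to near machine precision.
cdLassoOracle <- function(D, lambda, tol = 1e-13, maxSweeps = 100000L) {
  M <- motifMatrix(D); TT <- tfMatrix(D); G <- exprMatrix(D)
  X <- kronecker(t(TT), M)
  y <- as.vector(G)
  xs <- colSums(X^2)
  b <- numeric(ncol(X))
  r <- y
  for (sweep in seq_len(maxSweeps)) {
    delta <- 0
    for (j in seq_along(b)) {
      old <- b[j]
      rho <- sum(X[, j] * r) + xs[j] * old
      bj <- sign(rho) * max(abs(rho) - lambda / 2, 0) / xs[j]
      if (bj != old) {
        r <- r - X[, j] * (bj - old)
        b[j] <- bj
        delta <- max(delta, abs(bj - old))
      }
    }
    if (delta < tol) break
  }
  matrix(b, ncol(M), nrow(TT), dimnames = list(colnames(M), rownames(TT)))
}

# Brute-force sliding-window k-mer counts for one sequence.
slidingKmerOracle <- function(seq, k, revcomp = FALSE) {
  bases <- c("A", "C", "G", "T")
  words <- bases
  if (k > 1) for (i in seq_len(k - 1))
    words <- as.vector(t(outer(words, bases, paste0)))
  counts <- setNames(integer(length(words)), sort(words))
  rc <- function(w) chartr("ACGT", "TGCA", paste(rev(strsplit(w, "")[[1]]),
                                                 collapse = ""))
  n <- nchar(seq)
  if (n >= k) for (i in seq_len(n - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (!grepl("[^ACGT]", w)) {
      counts[w] <- counts[w] + 1L
      if (revcomp) counts[rc(w)] <- counts[rc(w)] + 1L
    }
  }
  counts
}

# Triple-sum evaluation of the correlation-based coefficient formula.
correlationOracle <- function(D) {
  G <- exprMatrix(D); M <- motifMatrix(D); TT <- tfMatrix(D)
  n <- nrow(G); p <- ncol(G)
  gbar <- mean(G)
  A <- matrix(0, ncol(M), nrow(TT), dimnames = list(colnames(M), rownames(TT)))
  for (k in seq_len(ncol(M))) for (l in seq_len(nrow(TT))) {
    mk <- mean(M[, k]); tl <- mean(TT[l, ])
    num <- 0
    for (i in seq_len(n)) for (j in seq_len(p))
      num <- num + (G[i, j] - gbar) * (M[i, k] - mk) * (TT[l, j] - tl)
    num <- num / (n * p)
    varm <- mean((M[, k] - mk)^2)
    vart <- mean((TT[l, ] - tl)^2)
    A[k, l] <- num / (varm * vart)
  }
  A
}

# Exhaustive pairwise-comparison AUC: over all (positive, negative) cell
# pairs, wins count 1, ties 1/2.
aucOracle <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Hypergeometric upper tail by exhaustive summation of the pmf.
hyperTailOracle <- function(N, topK, overlap) {
  js <- overlap:topK
  sum(choose(topK, js) * choose(N - topK, topK - js)) / choose(N, topK)
}

writeTempTSV <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
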