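identityDataset <- function(G) {
  n <- nrow(G)
  I <- diag(n)
  dimnames(G) <- list(paste0("g", 1:n), paste0("e", 1:n))
  M <- I; dimnames(M) <- list(rownames(G), paste0("mo", 1:n))
  TT <- I; dimnames(TT) <- list(paste0("tf", 1:n), colnames(G))
  GMATDataset(G, M, TT)
}

test_that("prediction equals the scalar double-sum oracle", {
  D <- randomDataset(5, 4, 3, 2, seed = 21)
  set.seed(22)
  A <- matrix(rnorm(6), 3, 2,
              dimnames = list(colnames(motifMatrix(D)), rownames(tfMatrix(D))))
  fit <- new("GMATFit", coefficients = A, method = "external",
             hyperparameters = list(), diagnostics = list(rss = 0))
  expect_equal(predictExpression(D, fit), predictOracle(D, A),
               tolerance = 1e-12)
  # zero coefficients predict zero; identity design reproduces A
  expect_true(all(predictExpression(D, fit0 <- new("GMATFit",
    coefficients = A * 0, method = "x", hyperparameters = list(),
    diagnostics = list(rss = 0))) == 0))
  Di <- identityDataset(matrix(rnorm(9), 3, 3))
  Ai <- matrix(1:9, 3, 3,
               dimnames = list(colnames(motifMatrix(Di)), rownames(tfMatrix(Di))))
  fi <- new("GMATFit", coefficients = Ai, method = "x",
            hyperparameters = list(), diagnostics = list(rss = 0))
  expect_equal(unname(predictExpression(Di, fi)), unname(Ai))
  # label mismatch is rejected
  Abad <- A; rownames(Abad) <- rev(rownames(A))
  expect_error(predictExpression(D, new("GMATFit", coefficients = Abad,
    method = "x", hyperparameters = list(), diagnostics = list(rss = 0))),
    class = "gmat_validation_error")
})

test_that("goodness of fit decomposes the squared error", {
  D <- randomDataset(4, 3, 2, 2, seed = 23)
  fit <- fitLeastSquares(D)
  g <- goodnessOfFit(D, fit)
  G <- exprMatrix(D)
  pred <- predictExpression(D, fit)
  rssLoop <- 0
  for (i in seq_len(nrow(G))) for (j in seq_len(ncol(G)))
    rssLoop <- rssLoop + (G[i, j] - pred[i, j])^2
  expect_equal(g$rss, rssLoop, tolerance = 1e-12)
  expect_equal(g$totalSS, sum((G - mean(G))^2))
  expect_equal(g$explainedSS, g$totalSS - g$rss)
  # zero fit on a grand-mean-centered G leaves rss = total
  Gc <- G - mean(G); dimnames(Gc) <- dimnames(G)
  Dc <- GMATDataset(Gc, motifMatrix(D), tfMatrix(D))
  zero <- new("GMATFit", coefficients = coef(fit) * 0, method = "x",
              hyperparameters = list(), diagnostics = list())
  gz <- goodnessOfFit(Dc, zero)
  expect_equal(gz$rss, gz$totalSS)
})

test_that("least squares returns the identity on an identity design and zero on zero data", {
  Di <- identityDataset(matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(unname(coef(fitLeastSquares(Di))),
               matrix(c(1, 3, 2, 4), 2, 2), tolerance = 1e-12)
  D0 <- randomDataset(5, 4, 3, 2, seed = 24)
  Dz <- GMATDataset(exprMatrix(D0) * 0, motifMatrix(D0), tfMatrix(D0))
  expect_equal(max(abs(coef(fitLeastSquares(Dz)))), 0)
})

test_that("least squares equals the Kronecker-vectorization oracle, including rank-deficient designs", {
  for (seed in 1:6) {
    D <- randomDataset(6, 5, 3, 2, seed = 30 + seed,
                       rankDeficient = seed %% 2 == 0)
    expect_lt(max(abs(coef(fitLeastSquares(D)) - kroneckerLSOracle(D))), 1e-8)
  }
})

test_that("the full-rank closed form matches the pseudoinverse route", {
  D <- randomDataset(8, 6, 3, 2, seed = 40)
  M <- motifMatrix(D); TT <- tfMatrix(D); G <- exprMatrix(D)
  closed <- solve(crossprod(M)) %*% t(M) %*% G %*% t(TT) %*%
    solve(tcrossprod(TT))
  expect_lt(max(abs(coef(fitLeastSquares(D)) - closed)), 1e-8)
})

test_that("the minimum-norm solution family preserves residuals and norm-dominates", {
  D <- randomDataset(6, 5, 3, 3, seed = 41, rankDeficient = TRUE)
  M <- motifMatrix(D); TT <- tfMatrix(D)
  fit <- fitLeastSquares(D)
  A <- coef(fit)
  rss0 <- goodnessOfFit(D, fit)$rss
  Pm <- diag(ncol(M)) - MASS::ginv(M) %*% M
  Pt <- diag(nrow(TT)) - TT %*% MASS::ginv(TT)
  set.seed(42)
  for (i in 1:100) {
    Z1 <- matrix(rnorm(length(A)), nrow(A))
    Z2 <- matrix(rnorm(length(A)), nrow(A))
    Alt <- A + Pm %*% Z1 + Z2 %*% Pt
    dimnames(Alt) <- dimnames(A)
    altFit <- new("GMATFit", coefficients = Alt, method = "x",
                  hyperparameters = list(), diagnostics = list())
    expect_equal(goodnessOfFit(D, altFit)$rss, rss0, tolerance = 1e-6)
    expect_gte(sum(Alt^2), sum(A^2) - 1e-10)
  }
})

test_that("centered least squares ignores additive gene and experiment effects", {
  D <- randomDataset(7, 6, 3, 2, seed = 43)
  base <- coef(fitCenteredLeastSquares(D))
  G <- exprMatrix(D)
  shifted <- GMATDataset(G + 5.5, motifMatrix(D), tfMatrix(D))
  expect_equal(coef(fitCenteredLeastSquares(shifted)), base, tolerance = 1e-9)
  offset <- G + rnorm(nrow(G))          # per-gene offset, recycled by column
  dimnames(offset) <- dimnames(G)
  withOffset <- GMATDataset(offset, motifMatrix(D), tfMatrix(D))
  expect_equal(coef(fitCenteredLeastSquares(withOffset)), base,
               tolerance = 1e-9)
  # an already centered dataset fits identically to plain least squares
  C <- centerDataset(D)
  expect_equal(coef(fitCenteredLeastSquares(C)), coef(fitLeastSquares(C)),
               tolerance = 1e-9)
})

test_that("ridge reproduces its closed form and its scalar case", {
  s <- GMATDataset(labeled(2, 1, 1), labeled(1, 1, 1, "g", "mo"),
                   labeled(1, 1, 1, "tf", "e"))
  expect_equal(unname(coef(fitRidge(s, 1, 1))), matrix(0.5))
  D <- randomDataset(6, 5, 3, 2, seed = 44)
  M <- motifMatrix(D); TT <- tfMatrix(D); G <- exprMatrix(D)
  l1 <- 0.7; l2 <- 1.3
  oracle <- solve(crossprod(M) + l1 * diag(ncol(M))) %*% t(M) %*% G %*%
    t(TT) %*% solve(tcrossprod(TT) + l2 * diag(nrow(TT)))
  expect_lt(max(abs(coef(fitRidge(D, l1, l2)) - oracle)), 1e-10)
})

test_that("ridge converges to least squares as penalties vanish and shrinks monotonically", {
  D <- randomDataset(8, 6, 3, 2, seed = 45)
  ls <- coef(fitLeastSquares(D))
  expect_lt(max(abs(coef(fitRidge(D, 0, 0)) - ls)), 1e-8)
  expect_lt(max(abs(coef(fitRidge(D, 1e-8, 1e-8)) - ls)), 1e-5)
  norms <- vapply(10^seq(-3, 3, length.out = 10), function(l)
    sqrt(sum(coef(fitRidge(D, l, l))^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("zero-penalty ridge on rank-deficient designs redirects to least squares", {
  D <- randomDataset(6, 5, 3, 3, seed = 46, rankDeficient = TRUE)
  expect_error(fitRidge(D, 0, 1), class = "gmat_singular_error")
  expect_error(fitRidge(D, 1, 0), class = "gmat_singular_error")
  expect_s4_class(fitRidge(D, 1, 1), "GMATFit")
})

test_that("centered ridge equals the center-then-ridge composition", {
  D <- randomDataset(7, 5, 3, 2, seed = 47)
  expect_equal(coef(fitCenteredRidge(D, 0.5, 0.8)),
               coef(fitRidge(centerDataset(D), 0.5, 0.8)), tolerance = 1e-12)
  shifted <- GMATDataset(exprMatrix(D) + 3, motifMatrix(D), tfMatrix(D))
  expect_equal(coef(fitCenteredRidge(shifted, 0.5, 0.8)),
               coef(fitCenteredRidge(D, 0.5, 0.8)), tolerance = 1e-9)
})

test_that("soft thresholding shrinks towards zero", {
  expect_equal(softThreshold(3, 1), 2)
  expect_equal(softThreshold(-0.5, 1), 0)
  x <- c(-4.2, 0, 7.7)
  expect_equal(softThreshold(x, 0), x)
  expect_equal(softThreshold(c(-3, 3), 1), c(-2, 2))
})

test_that("sparse regression reproduces the scalar lasso closed form", {
  s <- GMATDataset(labeled(1, 1, 1), labeled(1, 1, 1, "g", "mo"),
                   labeled(1, 1, 1, "tf", "e"))
  expect_equal(unname(coef(fitSparse(s, lambda = 0))), matrix(1),
               tolerance = 1e-7)
  expect_equal(unname(coef(fitSparse(s, lambda = 1))), matrix(0.5),
               tolerance = 1e-7)
  expect_equal(unname(coef(fitSparse(s, lambda = 2))), matrix(0))
})

test_that("unpenalized sparse fits reach the least-squares residual", {
  D <- randomDataset(6, 5, 2, 2, seed = 48)
  fit <- fitSparse(D, lambda = 0, tol = 1e-10, maxIter = 100000L)
  expect_lt(abs(fit@diagnostics$rss - fitLeastSquares(D)@diagnostics$rss),
            1e-6)
})

test_that("sparse estimates agree with a vectorized coordinate-descent lasso oracle", {
  skip_if_not_installed("glmnet")
  for (seed in 1:10) {
    D <- randomDataset(4, 3, 2, 2, seed = 50 + seed)
    fit <- fitSparse(D, lambda = 0.3, tol = 1e-12, maxIter = 200000L)
    expect_lt(max(abs(coef(fit) - lassoOracle(D, 0.3))), 1e-6)
  }
})

test_that("the sparse objective never increases across iterations", {
  D <- randomDataset(8, 6, 3, 3, seed = 61)
  fit <- fitSparse(D, lambdaRatio = 0.05)
  expect_true(fit@diagnostics$objectiveNonIncreasing)
  expect_true(fit@diagnostics$converged)
})

test_that("the sparse solution is exactly zero at and above lambda_max", {
  D <- randomDataset(6, 5, 3, 2, seed = 62)
  lmax <- 2 * max(abs(t(motifMatrix(D)) %*% exprMatrix(D) %*%
                        t(tfMatrix(D))))
  expect_true(all(coef(fitSparse(D, lambda = lmax)) == 0))
  expect_true(all(coef(fitSparse(D, lambda = lmax * 1.5)) == 0))
})

test_that("the regularization path grows its support and orders a dominant signal first", {
  set.seed(63)
  n <- 60; p <- 20; m <- 4; t <- 3
  M <- labeled(rpois(n * m, 1), n, m, "g", "mo")
  TT <- labeled(rnorm(t * p), t, p, "tf", "e")
  A <- matrix(0, m, t, dimnames = list(colnames(M), rownames(TT)))
  A["mo2", "tf2"] <- 10
  A["mo1", "tf1"] <- 1; A["mo3", "tf3"] <- -1
  G <- M %*% A %*% TT + matrix(rnorm(n * p, 0, 0.1), n, p)
  dimnames(G) <- list(rownames(M), colnames(TT))
  D <- GMATDataset(G, M, TT)
  path <- sparsePath(D, nLambdas = 12, lambdaMinRatio = 0.001)
  expect_true(all(coef(path@fits[[1]]) == 0))
  supportSize <- vapply(path@fits, function(f) sum(coef(f) != 0), integer(1))
  expect_gte(supportSize[length(supportSize)], supportSize[1])
  expect_identical(path@entryOrder$motif[1], "mo2")
  expect_identical(path@entryOrder$tf[1], "tf2")
  # the lambda_max screening oracle agrees on the first entrant
  scores <- abs(t(M) %*% G %*% t(TT))
  first <- which(scores == max(scores), arr.ind = TRUE)
  expect_identical(rownames(scores)[first[1]], "mo2")
})

test_that("the correlation estimate matches a triple-sum oracle and vanishes on constant G", {
  D <- randomDataset(3, 2, 2, 2, seed = 64)
  M <- abs(motifMatrix(D))
  D <- GMATDataset(exprMatrix(D), M, tfMatrix(D))
  expect_equal(coef(fitCorrelation(D)), correlationOracle(D),
               tolerance = 1e-12)
  Gconst <- exprMatrix(D) * 0 + 2; dimnames(Gconst) <- dimnames(exprMatrix(D))
  Dc <- GMATDataset(Gconst, M, tfMatrix(D))
  expect_true(all(coef(fitCorrelation(Dc)) == 0))
})

test_that("constant motif columns yield zero coefficients with a degeneracy report", {
  D <- randomDataset(5, 4, 3, 2, seed = 65)
  M <- motifMatrix(D); M[, 2] <- 1
  Dd <- GMATDataset(exprMatrix(D), M, tfMatrix(D))
  expect_warning(fit <- fitCorrelation(Dd), "constant")
  expect_true(all(coef(fit)[2, ] == 0))
  expect_identical(unique(fit@diagnostics$degenerate$motif), "mo2")
})

test_that("all estimators are invariant to consistent gene and experiment permutations", {
  D <- randomDataset(8, 6, 3, 3, seed = 66)
  set.seed(67)
  gi <- sample(8); ei <- sample(6)
  Dp <- GMATDataset(exprMatrix(D)[gi, ei], motifMatrix(D)[gi, ],
                    tfMatrix(D)[, ei])
  for (method in c("ls", "centered-ls", "correlation")) {
    expect_equal(coef(fitGMAT(Dp, method)), coef(fitGMAT(D, method)),
                 tolerance = 1e-9, label = method)
  }
  expect_equal(coef(fitRidge(Dp, 0.5, 0.5)), coef(fitRidge(D, 0.5, 0.5)),
               tolerance = 1e-9)
  expect_equal(coef(fitSparse(Dp, lambdaRatio = 0.05)),
               coef(fitSparse(D, lambdaRatio = 0.05)), tolerance = 1e-6)
})
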