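# Shared numeric helpers.

#' @importFrom stats rnorm rpois pf phyper sd
#' @importFrom utils head
NULL

# Moore-Penrose pseudoinverse via SVD. Singular values below
# max(dim) * eps * sigma_1 are treated as zero (numerical rank cutoff).
.pinv <- function(X) {
  if (length(X) == 0L) return(t(X))
  s <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * s$d[1L]
  pos <- s$d > tol
  if (!any(pos)) return(array(0, dim = rev(dim(X))))
  s$v[, pos, drop = FALSE] %*%
    ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}

# Evaluate expr with a deterministic RNG state, restoring the caller's state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Validate a labeled numeric matrix: dimnames present, unique, non-empty
# identifiers, all values finite.
.checkLabeledMatrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    .validationError("%s must be a numeric matrix", what)
  rn <- rownames(x); cn <- colnames(x)
  if (is.null(rn) || is.null(cn))
    .validationError("%s must carry row and column identifiers", what)
  if (anyNA(rn) || anyNA(cn) || any(rn == "") || any(cn == ""))
    .validationError("%s has empty identifiers", what)
  if (anyDuplicated(rn))
    .validationError("%s has duplicated row identifiers", what)
  if (anyDuplicated(cn))
    .validationError("%s has duplicated column identifiers", what)
  if (!all(is.finite(x)))
    .validationError("%s contains non-finite values", what)
  invisible(x)
}

# Largest singular value (spectral norm).
.sigma1 <- function(X) svd(X, nu = 0L, nv = 0L)$d[1L]
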