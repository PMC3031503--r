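#' Specify a synthetic dataset for the bilinear model
#'
#' Collects the generative parameters for \code{\link{simulateGMAT}}:
#' motif counts are i.i.d. Poisson(\code{motifRate}), TF expression i.i.d.
#' Normal(0, \code{tfSD}^2), the true coefficient matrix has a uniformly
#' random support of \code{round(density * m * t)} cells with
#' Normal(0, \code{coefSD}^2) values (exact zeros elsewhere), and
#' expression is \eqn{G = M A T + E} with i.i.d. Normal(0,
#' \code{noiseSD}^2) noise. Defaults emulate a yeast-compendium aspect
#' ratio (a thousand genes, tens of experiments, motifs and TFs) with a
#' sparse regulatory program.
#'
#' @param n,p,m,t numbers of genes, experiments, motifs and TFs.
#' @param density fraction of nonzero true coefficients, in (0, 1].
#' @param coefSD standard deviation of the nonzero coefficients.
#' @param motifRate Poisson mean of the motif counts.
#' @param tfSD standard deviation of TF expression.
#' @param noiseSD standard deviation of the additive noise.
#' @param seed integer RNG seed; the whole dataset is reproducible from it.
#' @return a \linkS4class{GMATSimSpec}.
#' @export
gmatSimSpec <- function(n = 1000L, p = 80L, m = 40L, t = 50L,
                        density = 0.05, coefSD = 1, motifRate = 0.3,
                        tfSD = 1, noiseSD = 1, seed = 1L) {
  new("GMATSimSpec", n = as.integer(n), p = as.integer(p),
      m = as.integer(m), t = as.integer(t), density = density,
      coefSD = coefSD, motifRate = motifRate, tfSD = tfSD,
      noiseSD = noiseSD, seed = as.integer(seed))
}

#' @describeIn gmatSimSpec expected standard deviation of the noise-free
#'   signal \eqn{M A T} under the spec (useful to set \code{noiseSD}
#'   relative to the signal):
#'   \eqn{\sqrt{s\, c^2 (r + r^2) \tau^2}} with \eqn{s} the support size,
#'   \eqn{c} = \code{coefSD}, \eqn{r} = \code{motifRate},
#'   \eqn{\tau} = \code{tfSD}.
#' @param spec a \linkS4class{GMATSimSpec}.
#' @export
signalSD <- function(spec) {
  s <- round(spec@density * spec@m * spec@t)
  sqrt(s * spec@coefSD^2 * (spec@motifRate + spec@motifRate^2) * spec@tfSD^2)
}

#' @describeIn gmatSimSpec compact display.
#' @param object a \linkS4class{GMATSimSpec}.
#' @export
setMethod("show", "GMATSimSpec", function(object) {
  cat(sprintf(
    "GMATSimSpec: n=%d p=%d m=%d t=%d density=%.3g coefSD=%.3g motifRate=%.3g tfSD=%.3g noiseSD=%.3g seed=%d\n",
    object@n, object@p, object@m, object@t, object@density, object@coefSD,
    object@motifRate, object@tfSD, object@noiseSD, object@seed))
})

#' Generate a synthetic dataset with known coefficients
#'
#' Draws a dataset from the generative form of the bilinear model (see
#' \code{\link{gmatSimSpec}} for the distributions). Identifiers are
#' synthetic: genes \code{g1..gn}, experiments \code{e1..ep}, motifs
#' \code{mo1..mom}, TFs \code{tf1..tft}.
#'
#' @param spec a \linkS4class{GMATSimSpec}.
#' @return a \linkS4class{GMATSim} carrying the dataset and the true
#'   coefficient matrix.
#' @export
simulateGMAT <- function(spec) {
  validObject(spec)
  .withSeed(spec@seed, {
    n <- spec@n; p <- spec@p; m <- spec@m; t <- spec@t
    genes <- paste0("g", seq_len(n)); exps <- paste0("e", seq_len(p))
    motifs <- paste0("mo", seq_len(m)); tfs <- paste0("tf", seq_len(t))
    M <- matrix(rpois(n * m, spec@motifRate), n, m,
                dimnames = list(genes, motifs))
    TT <- matrix(rnorm(t * p, 0, spec@tfSD), t, p,
                 dimnames = list(tfs, exps))
    A <- matrix(0, m, t, dimnames = list(motifs, tfs))
    s <- round(spec@density * m * t)
    if (s > 0) {
      support <- sample(m * t, s)
      A[support] <- rnorm(s, 0, spec@coefSD)
    }
    G <- M %*% A %*% TT + matrix(rnorm(n * p, 0, spec@noiseSD), n, p)
    dimnames(G) <- list(genes, exps)
    new("GMATSim", dataset = GMATDataset(G, M, TT),
        trueCoefficients = A, spec = spec)
  })
}

#' @describeIn GMATSim compact display.
#' @param object a \linkS4class{GMATSim}.
#' @export
setMethod("show", "GMATSim", function(object) {
  d <- gmatDims(object@dataset)
  cat(sprintf("GMATSim: %d genes x %d experiments, %d motifs, %d TFs, %d true nonzero coefficient(s)\n",
              d["n"], d["p"], d["m"], d["t"],
              sum(object@trueCoefficients != 0)))
})

#' Accessors for simulated datasets
#'
#' \code{simDataset} returns the generated \linkS4class{GMATDataset};
#' \code{trueCoefficients} the coefficient matrix the data were generated
#' from.
#'
#' @param x a \linkS4class{GMATSim}.
#' @name sim-accessors
NULL

#' @rdname sim-accessors
#' @export
simDataset <- function(x) x@dataset

#' @rdname sim-accessors
#' @export
trueCoefficients <- function(x) x@trueCoefficients

#' Remove regulators from a simulated dataset
#'
#' Emulates incomplete knowledge of the regulatory layer: a seeded random
#' subset of motif columns and TF rows is removed from \eqn{M} and
#' \eqn{T}, while \eqn{G} is left untouched - it was generated under the
#' full model, so the removed regulators turn into unmodeled additive
#' influence. The true coefficient matrix is restricted to the surviving
#' rows and columns for scoring.
#'
#' @param sim a \linkS4class{GMATSim}.
#' @param dropMotifs,dropTFs fractions in [0, 1) of motifs / TFs to
#'   remove (\code{floor(fraction * count)} of them).
#' @param seed integer seed for the removal.
#' @return a \linkS4class{GMATSim} on the reduced regulator sets.
#' @export
perturbMissing <- function(sim, dropMotifs = 0, dropTFs = 0, seed = 1L) {
  if (dropMotifs < 0 || dropMotifs >= 1 || dropTFs < 0 || dropTFs >= 1)
    .parameterError("drop fractions must be in [0, 1)")
  D <- simDataset(sim)
  M <- motifMatrix(D); TT <- tfMatrix(D)
  m <- ncol(M); t <- nrow(TT)
  nDropM <- floor(dropMotifs * m)
  nDropT <- floor(dropTFs * t)
  if (nDropM >= m || nDropT >= t)
    .parameterError("dropping would leave no motifs or TFs")
  .withSeed(seed, {
    keepM <- sort(setdiff(seq_len(m), sample(m, nDropM)))
    keepT <- sort(setdiff(seq_len(t), sample(t, nDropT)))
    newD <- GMATDataset(exprMatrix(D), M[, keepM, drop = FALSE],
                        TT[keepT, , drop = FALSE])
    new("GMATSim", dataset = newD,
        trueCoefficients = trueCoefficients(sim)[keepM, keepT, drop = FALSE],
        spec = sim@spec)
  })
}

#' Coefficient-recovery ROC AUC
#'
#' Scores how well an estimate ranks the true nonzero coefficients above
#' the true zeros: cells are ordered by \eqn{|\hat a_{kl}|} (activation
#' and repression are treated symmetrically) and the area under the ROC
#' curve against the true support is computed as the Mann-Whitney
#' statistic, ties contributing 1/2. An estimate that is identically zero
#' scores 0.5.
#'
#' @param Ahat estimated coefficient matrix (or a \linkS4class{GMATFit}).
#' @param Atrue true coefficient matrix with identical labels, containing
#'   at least one zero and one nonzero cell.
#' @return the AUC, in [0, 1].
#' @export
recoveryAUC <- function(Ahat, Atrue) {
  if (is(Ahat, "GMATFit")) Ahat <- coef(Ahat)
  if (!identical(dimnames(Ahat), dimnames(Atrue)))
    .validationError("estimate and truth must carry identical labels")
  pos <- Atrue != 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    .parameterError("degenerate truth: need both zero and nonzero cells")
  r <- rank(abs(Ahat))
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Benchmark estimators by coefficient recovery on simulated data
#'
#' Repeatedly simulates datasets, fits every requested estimator and
#' scores each fit by \code{\link{recoveryAUC}} against the generating
#' coefficients; reports per-estimator mean and standard deviation of the
#' AUC across runs. Run \code{i} uses seed \code{seed + i}, so the whole
#' table is reproducible and runs are independent replicates.
#'
#' @param spec a \linkS4class{GMATSimSpec}; its own seed is ignored in
#'   favour of \code{seed + run}.
#' @param estimators either a character vector of estimator names (see
#'   \code{\link{fitGMAT}}) or a named list of
#'   \code{list(method = , args = list())} entries.
#' @param runs number of simulated replicates.
#' @param seed integer base seed.
#' @return a data.frame with columns \code{estimator}, \code{meanAUC},
#'   \code{sdAUC}, \code{runs} (successful run count). A failing
#'   estimator is warned about and excluded from that run's average.
#' @export
runBenchmark <- function(spec, estimators = c("ls", "centered-ls", "ridge",
                                              "centered-ridge",
                                              "correlation"),
                         runs = 20L, seed = 1L) {
  if (runs < 1L) .parameterError("runs must be at least 1")
  if (is.character(estimators)) {
    estimators <- stats::setNames(
      lapply(estimators, function(nm) list(method = nm, args = list())),
      estimators)
  }
  if (is.null(names(estimators)) || any(names(estimators) == ""))
    .validationError("estimators must be named")
  aucs <- matrix(NA_real_, runs, length(estimators),
                 dimnames = list(NULL, names(estimators)))
  for (run in seq_len(runs)) {
    runSpec <- spec
    runSpec@seed <- as.integer(seed + run)
    sim <- simulateGMAT(runSpec)
    for (nm in names(estimators)) {
      est <- estimators[[nm]]
      fit <- tryCatch(
        do.call(fitGMAT, c(list(D = simDataset(sim), method = est$method),
                           est$args)),
        error = function(e) {
          warning(sprintf("run %d: estimator '%s' failed: %s", run, nm,
                          conditionMessage(e)))
          NULL
        })
      if (!is.null(fit))
        aucs[run, nm] <- recoveryAUC(fit, trueCoefficients(sim))
    }
  }
  data.frame(
    estimator = names(estimators),
    meanAUC = unname(colMeans(aucs, na.rm = TRUE)),
    sdAUC = unname(apply(aucs, 2L, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2L) 0 else sd(x)
    })),
    runs = unname(colSums(!is.na(aucs))),
    row.names = NULL)
}
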