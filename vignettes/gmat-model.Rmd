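---
title: "Inferring motif-TF associations with the bilinear G = MAT model"
author: "gmatreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring motif-TF associations with the bilinear G = MAT model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmatreg)
```

## The model

Transcription factors (TFs) regulate genes by binding short sequence
motifs in promoters. `gmatreg` links three observable matrices through a
single bilinear model:

* `G` (`n` genes × `p` experiments): gene expression,
* `M` (`n` genes × `m` motifs): motif occurrence counts in each promoter,
* `T` (`t` TFs × `p` experiments): expression of the TF genes themselves,

via

$$ G = M\,A\,T + E, $$

where `A` (`m` motifs × `t` TFs) is unknown and `E` is noise. Entry
$a_{kl}$ couples motif $k$ to TF $l$: genes carrying motif $k$ respond to
the expression of TF $l$ in proportion to $a_{kl}$ (positive for
activation, negative for repression). Large $|a_{kl}|$ values flag
putative motif–TF associations. Element-wise the model reads
$g_{ij} = \sum_{k,l} m_{ik}\,a_{kl}\,t_{lj} + \varepsilon_{ij}$ — a
linear model in the products $m_{ik} t_{lj}$, the classical growth-curve
(GMANOVA) form with design matrices on both sides of the parameter.

The model rests on three idealizations: expression is driven by TFs
(other influences enter as additive noise), TF effects scale with motif
counts, and the response is linear (a first-order approximation; it
cannot represent combinatorial TF logic). The estimators below are
designed so that coefficients remain recoverable even when the additive
unmodeled influence is large.

## Estimators

All estimators consume a `GMATDataset` (a `SummarizedExperiment` holding
the aligned triple) and return a `GMATFit`.

**Minimum-norm least squares** (`fitLeastSquares`) minimizes
$\|G - MAT\|_F^2$; among all minimizers it returns
$\hat A = M^{+} G\, T^{+}$ with Moore–Penrose pseudoinverses, the unique
minimizer exactly when `M` has full column rank and `T` full row rank, in
which case it equals $(M^\top M)^{-1} M^\top G\, T^\top (TT^\top)^{-1}$.
Singular values below $\max(\mathrm{dim}) \cdot \epsilon \cdot \sigma_1$
are treated as zero; this standard cutoff makes rank decisions
reproducible across platforms.

**Centering** (`centerDataset`, `fitCenteredLeastSquares`,
`fitCenteredRidge`): motif columns are centered over genes, TF rows over
experiments, and `G` is double-centered
($g_{ij} - \bar g_{i.} - \bar g_{.j} + \bar g$). Centering removes
additive per-gene and per-experiment effects — exactly the form taken by
unmodeled influences under the model's assumptions — and reduces
correlations between the bilinear predictors, shrinking coefficient
variance. Double centering of `G` is the default because the predictor
products $\tilde m_{ik} \tilde t_{lj}$ are centered in both indices; for
asymmetric designs `gCentering = "row"` or `"column"` is available.

**Ridge** (`fitRidge`):
$\hat A = (M^\top M + \lambda_1 I)^{-1} M^\top G\, T^\top
(TT^\top + \lambda_2 I)^{-1}$, computed by linear solves. Penalizing
$\|A\|_F^2$ in the vectorized problem has no closed matrix-form solution,
so this two-sided shrinkage is used instead; it reduces to least squares
as $\lambda_1, \lambda_2 \to 0$. Defaults $\lambda_1 = \lambda_2 = 1$ are
a mild shrinkage appropriate for roughly unit-variance inputs; both are
always user-set in earnest analyses. Ridge is applied to the centered
Gram matrices in `fitCenteredRidge` (regularizing the centered rather
than raw design keeps the shrinkage aligned with the variables actually
fitted).

**Sparse regression** (`fitSparse`, `sparsePath`) minimizes
$F(A) = \|G - MAT\|_F^2 + \lambda \|A\|_1$ by proximal-gradient
(iterative soft-thresholding) steps
$A \leftarrow S_{\mu\lambda/2}(A + \mu\, M^\top (G - MAT)\, T^\top)$ from
$A = 0$. Conventions for the L1 objective differ across the literature by
constant factors; ours is pinned by two identities that the tests verify:
the scalar problem has the closed form $\hat a = S_{\lambda/2}(g)$, and
the solution is exactly zero iff
$\lambda \ge \lambda_{max} = 2\max|M^\top G\,T^\top|$. The automatic step
$\mu = 0.9 / (\sigma_1(M)^2 \sigma_1(T)^2)$ is a fraction of the inverse
Lipschitz constant $2\sigma_1(M)^2\sigma_1(T)^2$ of the smooth part, so
the objective descends at every iteration (recorded in the diagnostics
and asserted in the tests). Iteration stops when the largest coefficient
change falls below `tol` (default `1e-8`, `maxIter = 10000`); magnitudes
below `tol` are snapped to exact zeros so the support — and therefore
entry order along a path — is well defined. `sparsePath` follows a
geometric grid from $\lambda_{max}$ downwards with warm starts; the order
in which coefficients first become nonzero approximates the exact
piecewise-linear homotopy (a LARS-type path algorithm is a possible
extension; the grid homotopy recovers the entry order approximately at a
fraction of the cost).

**Correlation estimator** (`fitCorrelation`) reads the model
generatively: with motif presences and TF expression treated as random
variables, pairwise independent of the other regulators,

$$ \hat a_{kl} =
\frac{\tfrac{1}{np}\sum_{i,j}(g_{ij}-\bar g)(m_{ik}-\bar m_k)(t_{lj}-\bar t_l)}
     {\mathrm{Var}(m_k)\,\mathrm{Var}(t_l)}. $$

Population (divide-by-count) moments are used throughout — the plug-in
form of the identity; the sample-moment variant differs by a factor that
vanishes with `n` and `p` and is not exposed. Each coefficient is
computed from its own motif column, TF row and `G` only, one motif at a
time, so removing other motifs or TFs cannot change it even in the last
bit. Coefficients with a constant motif column or TF row are undefined;
they are set to 0 and reported in `diagnostics$degenerate`. Centered
least squares approximates this estimator when regulators are sampled
independently, which is why it shares the robustness to missing
regulators.

## Significance and stability

**Permutation z-scores** (`zScores`): the null hypothesis is that
expression is unrelated to motifs and TFs. `G` is permuted by one random
row permutation and one column permutation (`permuteExpression`), the
estimator is refitted `r` times, and each observed coefficient is
standardized by the mean and population standard deviation of its
randomized estimates. `r = 30` by default: z-scores use only the first
two moments, which stabilize quickly, and the refit cost is `r` full
fits. Pairs with zero randomized spread would give infinite scores; they
get `z = 0` and are listed as degenerate instead (conservative). Note a
sampling caveat: across the $m\,t$ pairs the z-scores share the same `r`
permutations and are therefore correlated, so summaries such as the mean
z over all pairs fluctuate more than independent scores would suggest
(the mean of 100 independent standard normals already has standard
deviation 0.1).

**F-test** (`fTest`) compares the fitted model against the grand mean:
$F = (\mathrm{ESS}/df_1)/(\mathrm{RSS}/df_2)$ with
$df_1 = \mathrm{rank}(M)\,\mathrm{rank}(T)$ and
$df_2 = np - df_1 - 1$. The rank product rather than $m\,t$ counts only
identifiable parameters, which is the correct reference when motif
columns or TF rows are collinear (common for overlapping k-mers). A
perfect fit reports $p = 0$ by convention.

**Split-set stability** (`splitSetStability`) fits the estimator on two
random disjoint halves of the experiments
($\lceil p/2\rceil$/$\lfloor p/2\rfloor$, seeded) and counts the overlap
of the two top-`k` coefficient-magnitude lists. The overlap is referred
to a hypergeometric null — drawing `k` pairs twice at random from all
$m\,t$ pairs — with upper-tail p-value $P(X \ge \mathrm{overlap})$. This
null assumes both halves rank the same universe of pairs; it is a
reconstruction of "better than chance agreement" and is reported as
such. The split is random rather than contiguous so that time-course
structure does not confound the two halves. No multiple-testing
correction is applied across pairs anywhere in the package; if formal
error control over the $m\,t$ tests is needed, it is the user's
responsibility (e.g. `p.adjust`).

## Feature construction

`countKmers` scans promoters for all $4^k$ DNA words with overlapping
windows — the natural reading of "occurrence counts" for motif matrices —
skipping windows that contain non-ACGT characters. Counting is
single-stranded by default; `revcomp = TRUE` adds each window's reverse
complement for strand-symmetric motifs. `filterFrequentMotifs` ranks
motifs by presence (number of genes with a positive count) and keeps the
top fraction; when the presence value at the cut is tied across it, all
motifs with that value are excluded so the survivor set never depends on
arbitrary ordering, while ties entirely above the cut are kept. The
fraction is exposed as a parameter (around 1/3 is a reasonable starting
point for 7-mers). `buildGOMatrix` substitutes curated function for
sequence: a binary gene × term matrix over the `topN` most frequently
annotating terms, ties broken lexicographically by term identifier for
determinism. Annotations are used as given — no propagation through the
GO graph; if ancestor closure is wanted it must be applied upstream.

## The synthetic-data generator

`simulateGMAT` draws from the generative form of the model itself: motif
counts i.i.d. Poisson(`motifRate`), TF expression i.i.d. Normal(0,
`tfSD`²), a uniformly random coefficient support of
`round(density · m · t)` cells with Normal(0, `coefSD`²) values, and
Gaussian noise. Defaults (`n = 1000`, `p = 80`, `m = 40`, `t = 50`,
`density = 0.05`, `motifRate = 0.3`, `tfSD = coefSD = noiseSD = 1`)
emulate a yeast expression compendium's aspect ratio — thousands of
genes, tens of experiments, a sparse regulatory program, motif counts
that are mostly 0 or 1 — at desk scale. The expected signal level has
the closed form used by `signalSD`:
$\mathrm{Var}(g_{ij}) = s\,c^2\,(r + r^2)\,\tau^2$ for support size $s$,
coefficient sd $c$, motif rate $r$ and TF sd $\tau$ (cross terms vanish
because coefficients are independent with mean zero), so benchmarks can
set the noise at the signal's own scale.

What the generator does *not* emulate: correlated experiments (time
courses), motif co-occurrence along promoters, heavy-tailed expression
noise, and any dependence between motif content and TF expression.
Passing benchmarks therefore demonstrate correctness of the estimators
under the model's own assumptions, not performance on real microarray
compendia.

`perturbMissing` removes a random subset of motifs and TFs *after*
generation while leaving `G` untouched, turning the removed regulators
into unmodeled influence — the realistic regime where the regulator
catalogue is incomplete. `recoveryAUC` scores estimators by ranking
cells by $|\hat a_{kl}|$ against the true support (Mann–Whitney with
ties counting ½); magnitude is used because activation and repression
are symmetric in the model. `runBenchmark` averages the AUC over seeded
replicates (`seed + run` per run).

## Problem sizes and numerical choices used by the checks

The package's acceptance-style tests run at fixed, seeded problem
sizes chosen to finish in seconds while leaving no statistical
ambiguity: oracle equivalences on 3–8 gene toys; the recovery benchmark
at `n = 500`, `p = 60`, `m = 20`, `t = 20`, `density = 0.1`, noise sd
equal to the signal sd, 20 replicates; the missing-regulator variant
with 30% of motifs and TFs dropped; the correlation-consistency draw at
`n = 2000`, `p = 50` with a 2 × 2 coefficient panel. The panel is
deliberately minimal: for pairs sharing the true motif or TF, the
estimator's sampling error is of order $|a| / \sqrt{p}$ (≈ 0.14 here),
so bounds on off-support estimates are only meaningful for the pairs
sharing neither index plus a small number of sharing pairs. Null
calibration of the z-scores uses a 200 × 20 dataset with 10 motifs, 10
TFs and `r = 50`; by the correlation caveat above, its mean-z summary
carries sampling noise of about ±0.12 across realizations even though
the scores themselves are calibrated.

Other numerical conventions, collected in one place: pseudoinverse rank
cutoff `max(dim) · eps · σ₁`; ISTA tolerance `1e-8` on the maximum
coefficient change with exact-zero snapping below it; ridge solved by
two linear solves, never explicit inversion, with a classed error
redirecting rank-deficient zero-penalty calls to the pseudoinverse
route; ranking ties broken lexicographically by motif then TF
identifier; the TSV dialect is header row + header column with 17
significant digits so write/read round trips are bit-exact.

## Limitations

* Linearity: combinatorial and saturating TF effects are outside the
  model class; large coefficients mean association, not mechanism.
* The exact piecewise-linear L1 path is approximated by a warm-started
  λ-grid; entry order can differ near ties.
* The hypergeometric stability null and the rank-based F-test degrees of
  freedom are principled reconstructions; both are documented above
  rather than hidden defaults.
* Latent (unobserved) motifs or TFs are not estimated; their additive
  effect is absorbed by centering, which is exactly why the centered
  estimators are preferred.
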