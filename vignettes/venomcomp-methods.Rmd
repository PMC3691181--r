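---
title: "Methods: phylogenetic comparative analysis of venom composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic comparative analysis of venom composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomcomp)
```

## The problem and the model

Snake venoms are mixtures of a modest number of toxin-protein families
(metalloproteinases, phospholipases A2, serine proteinases, CRISPs, ...),
and a venom proteome is summarised as the percentage of total venom protein
contributed by each family. Because species share ancestry, naive
cross-species correlations between venom composition and ecology are
pseudo-replicated: related species are not independent data points. The
package addresses this with the two standard tools of the trade, both built
on the Brownian-motion (BM) covariance implied by a time-calibrated tree.

Under BM with rate $\sigma^2$, a trait's tip values are multivariate normal
with covariance $\sigma^2 V$, where $v_{ij}$ is the shared root-to-tip path
length of tips $i$ and $j$ (`phylo_vcv()`). Everything downstream is a
function of $V$.

**Phylogenetic signal (Blomberg's K).** With the GLS (ancestral) mean
$\hat a = (1'V^{-1}1)^{-1}1'V^{-1}x$,

$$K \;=\; \frac{MSE_0/MSE}{\left[\mathrm{tr}(V) - n/(1'V^{-1}1)\right]/(n-1)},
\qquad
MSE_0 = \frac{(x-\hat a 1)'(x-\hat a 1)}{n-1},\quad
MSE = \frac{(x-\hat a 1)'V^{-1}(x-\hat a 1)}{n-1}.$$

The denominator is the exact BM expectation of the MSE ratio on that tree,
so $K$ is a calibrated, dimensionless descriptor: 1 under BM, near 0 when
trait variation ignores the tree, above 1 when relatives are more similar
than BM predicts. $K$ is invariant to affine trait transforms and to
rescaling all branch lengths — so the time units of the tree (Myr in the
packaged data) never matter for $K$ itself.

Significance is by tip randomization: trait values are reassigned to tips
uniformly at random and $K$ recomputed, `n_perm` times. We permute $K$
itself, and use the one-sided add-one estimator
$p = (1 + \#\{K_{perm} \ge K_{obs}\})/(1 + n_{perm})$, so $p$ is never 0
and is exact-level conservative. Ties count as hits (with a $10^{-12}$
fuzz, which is what makes the star-tree identity below come out as $p = 1$
rather than an accident of floating point). A widely used implementation of
this test permutes a contrasts-variance statistic rather than $K$; the two
are not identical procedures, and this package deliberately permutes $K$,
matching the verbal description of the method it implements.

**PGLS.** The diet–venom regression is GLS with error covariance
$\sigma^2 V$: $\hat\beta = (X'V^{-1}X)^{-1}X'V^{-1}y$, residual variance on
$n-2$ df, a two-sided slope t-test. $V$ is used as-is (fixed $\lambda = 1$);
no ML estimation of $\lambda$ or OU alternatives is attempted — with eight
taxa such estimates would be noise, and the procedure being reproduced used
the fixed-BM default. Multiple testing across the venom traits is
controlled by the Benjamini–Yekutieli critical value
$\alpha/\sum_{i=1}^k 1/i$, applied as a single critical value compared
against raw p-values (not as adjusted p-values); it is valid under
arbitrary dependence, which matters because compositional venom traits are
mutually dependent by construction. For $k=9$ and $\alpha=0.05$ the exact
value is 0.01767; the function returns full precision and any 3-decimal
truncation (0.017) is presentation, not computation.

## Trait preparation

Percent abundances are arcsine-square-root transformed
($\theta = \arcsin\sqrt p$, radians; `mode` declares percent vs proportion
explicitly and is never guessed). The transform stabilises variance near
the 0/1 boundaries and weakens (but does not remove) the unit-sum
dependency among families. The centered-log-ratio alternative is out of
scope by design: its composite axes are hard to interpret and the analysis
chain reproduced here rejected it.

Composite axes are principal components of the **covariance** matrix of the
transformed values. Loadings are reported in the scaled convention
(eigenvector $\times \sqrt\lambda_j$ / variable sd), i.e. the correlation
between variable and component score, whose per-variable squared sums are
at most 1. This convention is fixed by the packaged data themselves: the
diet PCA reproduces the published values exactly (PC1 = 87% of variance,
loadings −0.95 / +0.91) only under covariance-PCA of transformed
proportions with correlation-scaled loadings. Component signs are
underdetermined; internally each component is oriented so its
largest-magnitude loading is positive, and `orient_component()` flips to
any published convention. Note the sign of a PGLS slope against a PC score
inherits this choice.

The family filter keeps families with mean abundance strictly above 1%
that are present (abundance > 0) in at least 6 of the taxa. "Abundance
> 1%" is read as *mean* abundance across taxa: on the packaged table this
is the unique simple reading that retains exactly the seven families the
original analysis kept (it excludes CTL, whose maximum is 2.4% but whose
mean is 0.775%, and svNGF, present in 6 taxa with mean 0.175%). Both
thresholds are parameters.

## The packaged dataset and its limits

`load_fixture()` returns the published composition table (8 taxa × 12
families, percent), the diet table (proportion of mammals and lizards in
the diet), the published K and PGLS tables for cross-reference, and a
tree. Two caveats are part of the data, not bugs:

* The `Agc` (A. c. contortrix) row sums to 87.3, not 100 — the remainder
  of that proteome is unassigned material excluded from the published
  family table. The composition validator therefore takes a row-sum
  tolerance argument.
* The multilocus branch lengths behind the original species tree were
  never published. The packaged tree (`sistrurus_tree_synthetic.nwk`) has
  the correct topology and the two published calibrations (0.49 Myr for
  the Sms–Smm split, 0.77 Myr for the Smb split); every other node age is
  a plausible placeholder (catenatus crown 2 Myr, genus root 7 Myr,
  C. atrox at 12 Myr, A. contortrix at 18 Myr). Consequently K values and
  PGLS slopes computed from it are **illustrative**, and
  `run_full_analysis()` stamps its report accordingly. Quantities that do
  not depend on branch lengths (the filter, transforms, PCAs, diet
  correlation, B-Y value, divergence rates) are exact reproductions.

A related irreproducibility is documented rather than patched: the
published venom PCA summary (PC1/PC2 = 49%/31%, SVMP PC1 loading 0.92)
does not follow from the published composition table under the convention
that exactly reproduces the published diet PCA — the same code yields
46%/30% and 0.66. An extensive search over conventions (raw vs transformed
input, covariance vs correlation matrix, eigenvector vs scaled loadings,
ingroup-only taxa, renormalised rows, alternative family sets) found none
that matches, so the published venom PCA evidently derives from data
differing from the published table. The package reports what the data it
ships actually give; the corresponding acceptance test records the
discrepancy by failing against the published numbers.

## Synthetic data: what it emulates and what it does not

The simulators generate the statistical structure the analysis *assumes*,
with known ground truth:

* `yule_tree()` — forward pure-birth simulation: while $j$ lineages exist
  the next split is $\mathrm{Exp}(j\,b)$, a uniformly chosen lineage
  splits; pendant branches are extended to the stopping time, so trees are
  exactly ultrametric. Trees are rescaled to unit depth by default so that
  $\sigma^2$ means the same thing at any size.
* `simulate_bm()` — per-branch Gaussian increments with variance
  $\sigma^2 \times$ branch length (tip covariance $\sigma^2 V$ by
  construction).
* `simulate_signal()` — multivariate normal with covariance
  $\sigma^2\,V_\lambda$, where $V_\lambda$ multiplies off-diagonals by
  $\lambda$ (`lambda_transform()`): a dial from i.i.d. tips ($\lambda=0$)
  to BM ($\lambda=1$).
* `simulate_composition()` — independent latent BM traits per family,
  softmax to the 100%-simplex (logistic-normal): rows are valid
  compositions while log-ratios keep phylogenetic structure. This is a
  declared stand-in; no claim is made that real venom evolution is
  logistic-normal.
* `simulate_diet_venom()` — diet is BM; venom is
  `true_slope × diet + BM noise`, exactly the PGLS generating model.

Real venom data differ in ways these generators do not emulate:
measurement error in peak integration, within-taxon (individual and
geographic) variation collapsed into pooled samples, non-BM evolution
(selection, bursts), and family abundances that are exactly zero rather
than merely small. Passing calibration tests therefore demonstrates that
the estimators are correct *under their own assumptions* — not that those
assumptions hold for any particular empirical dataset.

All generators take an explicit seed, derive independent substreams via a
fixed 32-bit congruential mix of (seed, stream tag) — so e.g. each column
of a signal screen and each latent family trait gets its own reproducible
stream — and restore the caller's RNG state on exit. Identical (arguments,
seed) give bit-identical output.

## Numerical choices

* $V$ is inverted via Cholesky (`chol2inv`); inputs with reciprocal
  condition number below $10^{-12}$ are rejected with advice to inspect
  branch lengths (zero-length terminal branches and duplicated tips are
  the usual culprits). Polytomies are fine; degenerate $V$ is rejected at
  the point of use, not at tree construction.
* Ultrametricity tolerance: relative $10^{-6}$ of tree depth
  (`is_ultrametric_tree`), used by `graft_outgroup()`, which attaches an
  outgroup above the root given a precomputed divergence time and refuses
  times not exceeding the current depth.
* Newick I/O (via ape) validates on read: ≥ 2 tips, unique non-empty
  labels, finite non-negative lengths on all edges; branch lengths are
  written with 12 significant digits so parse–write round-trips preserve
  lengths to within print precision.
* Permutation p-values use the add-one correction; with `n_perm`
  permutations the smallest attainable p is $1/(n_{perm}+1)$.
* Problem sizes used by the packaged calibration checks: 500 replicates
  for mean-K and slope-recovery checks on a fixed 32-tip tree, 1000
  datasets × 199 permutations for the test-size check on a 16-tip tree,
  100 random instances for the PGLS/whitened-OLS equivalence. These sizes
  put Monte-Carlo error well inside the tolerance bands being checked.

## Known limitations

* Eight taxa is a very small comparative sample; K has low power and PGLS
  slopes have wide intervals at this size. The package reports exact
  statistics but cannot manufacture power.
* No OU/early-burst models, no measurement-error models, no ML $\lambda$,
  no independent-contrasts variant, no centered-log-ratio transform — all
  deliberate scope edges.
* The divergence-rate helper `divergence_rate(shared_pct, time_myr)` is
  the simple quotient $(100-\text{shared})/(10\,t)$ using total elapsed
  time since the split; it returns full precision (e.g. 9.87 for 24%
  shared over 0.77 Myr, 1.02 for 95% over 0.49 Myr).
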