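---
title: "Signature-reversal drug screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-reversal drug screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigreverse)
```

## The screening model

`sigreverse` implements a connectivity-mapping screen for drug
repurposing. The premise: if a disease state up-regulates a set of genes,
a compound that *down*-regulates those same genes may oppose the disease
process. The pipeline ranks a library of drug perturbation signatures by
how strongly each drug's down-regulated genes overlap the disease's
up-regulated genes, then filters the leading candidates by predicted
blood–brain-barrier (BBB) penetration — the second hurdle for any
neuro-active therapeutic.

The screen proceeds in five stages:

1. **Signatures.** Each drug × condition (cell line, dose, time)
   experiment — replicated treatment and control expression profiles —
   is reduced to a *characteristic direction*: the unit vector
   $b \propto \Sigma_\gamma^{-1}(\mu_t - \mu_c)$ with
   $\Sigma_\gamma = (1-\gamma)\hat\Sigma + \gamma\,\nu I$ and
   $\nu = \operatorname{tr}(\hat\Sigma)/p$. This is a regularized
   linear-discriminant direction in gene space; it weights genes by how
   much they separate treatment from control *jointly*, not one at a
   time.
2. **DEG calling.** Coefficients are standardized over genes,
   $z_g = (b_g - \bar b)/\mathrm{sd}(b)$, and genes with two-sided
   normal $p < \alpha$ (default $\alpha = 0.01$) are called up- or
   down-regulated according to the sign of $b_g$.
3. **Reversal scoring.** For disease up-set $S^{up}_i$ and drug
   signature down-set $S^{dn}_j$, the score is the Jaccard index
   $J = |S^{up}_i \cap S^{dn}_j| / |S^{up}_i \cup S^{dn}_j|$. Because a
   drug is profiled under many conditions while the disease signatures
   come from a different platform entirely, only the *highest* Jaccard
   score across a drug's conditions is kept, and the per-drug scores are
   then averaged over the disease signatures. Drugs are ranked by this
   average.
4. **MOA enrichment.** The mechanism-of-action classes of the top-k
   drugs (default 100) are tested for over-representation with the
   upper-tail hypergeometric test against the background of all scored
   drugs, with Benjamini–Hochberg adjustment across classes.
5. **BBB screening.** The top-k candidates are re-ranked by an imported
   per-compound BBB+ probability in $[-1, 1]$ (admetSAR-style QSAR
   output, consumed as a table — the QSAR model itself is external
   third-party work), and the top-n (default 10) are retained.

A per-candidate report quantifies how an individual drug opposes the
disease: the overlap of its best-scoring condition's down-set with the
disease up-set is tested with the upper-tail hypergeometric test over
the shared gene universe, and the overlap genes can be tested for
gene-set enrichment against any GMT library (the same hypergeometric
core, so no external enrichment tool is needed).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `gamma` | 0.5 | covariance shrinkage of the characteristic direction, in $[0,1]$ |
| `alpha` | 0.01 | two-sided z-test threshold for DEG calling |
| `top_k` | 100 | reversal candidates passed to MOA/BBB stages |
| `retain_n` | 10 | compounds retained after BBB re-ranking |

`gamma` interpolates between the raw pooled covariance ($\gamma = 0$,
only usable when samples outnumber genes) and a scaled identity
($\gamma = 1$, where the direction collapses to the normalized mean
difference). With a handful of replicates per condition the pooled
covariance is singular, so some shrinkage is mandatory; 0.5 gives equal
weight to the observed covariance structure and the isotropic prior and
is the package default. The $\gamma = 1$ closed form is kept as a test
anchor. The defaults for `alpha`, `top_k` and `retain_n` are the
conventional choices for this style of screen; all are surfaced as
arguments because they are choices, not laws.

Two further design points were genuinely open and resolved as follows:

* **The z-test statistic.** "z-test on the signature coefficients" does
  not pin down a statistic. We standardize the coefficient vector by its
  own mean and standard deviation across genes and refer to the standard
  normal. This matches the common post-processing of
  characteristic-direction coefficients, is self-contained (no second
  pass over the data), and is verifiably calibrated: on null data the
  DEG rate equals $\alpha$ within Monte-Carlo error (see the test
  suite).
* **Universe intersection before Jaccard.** When the disease and drug
  signatures live on different gene universes, both sets are restricted
  to the intersection before scoring. Without this, genes observable on
  only one platform inflate the union and deflate scores asymmetrically
  across drugs.
* **Aggregation order.** Max-over-conditions happens *before*
  averaging over disease signatures. The two orders genuinely disagree
  (a test constructs such a case), so the order is fixed and verified.
* **Missing BBB scores.** Candidates absent from the BBB table are
  excluded with a warning naming them, never silently: a missing
  prediction is not evidence of impermeability.
* **Degenerate overlap.** The Jaccard score of two empty sets is an
  error, not 0; inside library scoring an empty drug down-set simply
  contributes a score of 0, so a drug is never dropped silently.

## What the synthetic generator emulates

Real inputs for this kind of screen are large external resources: a
perturbation library of ~80,000 signatures over ~1,500 approved drugs,
curated disease signatures, and a QSAR-predicted BBB table. The
`synthetic_config()` module generates structurally identical inputs at
desk scale with *known ground truth*, so every stage is testable
offline:

* a gene universe of 978 genes (landmark scale), ids `G0001...G0978`;
* two disease signatures of `deg_fraction` × 978 ≈ 49 up- and
  down-genes, sharing 50% of their members — emulating one disease
  profiled in two related cell populations;
* a 300-drug × 4-condition library (1,200 signatures). Five planted
  *reversers* capture 30% of each disease up-set in the down-set of
  every condition; five planted *partial reversers* capture 15%;
  background drugs capture 2%. In expression mode each signature is a
  3 vs 3 replicated experiment with unit Gaussian noise and planted
  mean shifts of 2 noise-SD — the simplest model consistent with
  z-scored per-replicate profiles;
* MOA labels in which one planted class collects the reversers and
  partial reversers — mirroring the empirical pattern that a
  pharmacological class acting on the disease pathway concentrates near
  the top of the ranking — with all other drugs spread uniformly over
  19 background classes;
* BBB scores with the planted permeable compounds in $[0.8, 1]$ and
  everything else in $[-1, 0.75]$. The gap between the bands is
  deliberate: it makes "the screen retains exactly the planted set" a
  well-posed exact check rather than a probabilistic one.

The partial reversers serve two purposes: they give the planted MOA
class members throughout the top-k (not only at ranks 1–5), and they
make the MOA enrichment signal robust — with ten of ten class members
in the top 100 the planted class dominates any background class by
chance alone.

Scale choices: 300 drugs × 4 conditions keeps a full expression-mode
screen to a few seconds, so the recovery guarantee can be verified over
50 independent seeds in minutes; the structure (many conditions per
drug, max-then-average aggregation, one enriched class, a BBB band) is
identical to the full-scale screen.

What the generator does **not** emulate: plate effects and batch
structure, dose–response monotonicity, correlated noise across genes,
heavy-tailed expression noise, and real compound chemistry. Passing
tests therefore demonstrate that the pipeline's statistics and ranking
logic are correct and identifiable under clean Gaussian conditions —
not that any particular real-data screen will rank a given drug highly.

## Numerical choices and degenerate inputs

* The characteristic direction is computed inside the sample-spanned
  subspace: the pooled residual matrix has rank at most $n - 2$, its
  thin SVD gives the nonzero eigenpairs of $\hat\Sigma$, and
  $\Sigma_\gamma^{-1} d$ is assembled analytically from them plus the
  isotropic remainder. This is exact — verified against dense $p \times
  p$ inversion — and avoids ever forming a $978 \times 978$ matrix.
* Eigenvalues below $10^{-12}$ of the largest are treated as zero.
* Noise-free replicates (zero pooled covariance) degrade gracefully to
  the normalized mean difference for any $\gamma > 0$; $\gamma = 0$ on
  rank-deficient data is an error instructing the user to shrink.
* An all-zero treatment–control mean difference is a hard error
  (degenerate signal), as is a zero coefficient standard deviation in
  DEG calling.
* Ranking ties break lexicographically by drug id at every stage, so
  all outputs are bit-reproducible; the BBB stage breaks ties by higher
  reversal score first, then drug id.
* All tables are written as UTF-8 TSV with deterministic row order, and
  the run manifest records a hash of the configuration.

## Known limitations

* The z-test treats the standardized coefficients as approximately
  normal. Characteristic-direction coefficients have somewhat heavier
  tails when the true signal is sparse, so at small $\alpha$ the called
  set is conservative relative to the nominal rate on signal-bearing
  data (calibration is exact on null data).
* Jaccard scores are rank statistics here; the pipeline does not attach
  significance to a reversal score itself (no permutation null), only
  to overlaps and enrichments.
* Weighted connectivity statistics (KS-based tau, cosine similarity on
  coefficients) are out of scope; the scoring contract is set overlap.
* GCTX/HDF5 binary parsing is not implemented; inputs are text GCT
  1.2/1.3, GMT and TSV.

## Problem sizes used in validation

The recovery guarantee — all five planted reversers in the top 10 and
the planted MOA class top-enriched — is verified over 50 independent
seeds of the full default-scale expression-mode screen (978 genes ×
1,200 six-sample experiments each), and the DEG-calling calibration
over 100 null experiments; exact-arithmetic oracles cover all
hypergeometric configurations with $N \le 12$ and 1,000 random Jaccard
pairs. These sizes make the whole suite run in about three minutes on a
single core while leaving the statistical checks well-powered.
```{r, eval = FALSE}
# a complete miniature screen
cfg <- synthetic_config(seed = 1)
bundle <- generate_screen_inputs(cfg, mode = "expression")
res <- run_screen(pipeline_config(inputs = bundle))
head(res$scores)   # ranked reversal table
res$moa[1, ]       # top-enriched MOA class
res$bbb_top        # the 10 retained BBB-permeable candidates
```
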