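---
title: "Inferring tyrosine-kinase signaling networks from spectral counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring tyrosine-kinase signaling networks from spectral counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paracne)
```

## The problem

Tyrosine kinases (TKs) act through their phosphorylated isoforms: a kinase's
ability to phosphorylate its substrates tracks its own phospho-state. Over a
large compendium of samples, a genuine TK→substrate relationship therefore
leaves a statistical footprint — mutual information (MI) between the two
peptides' phospho-abundance profiles. Label-free phosphotyrosine LC-MS/MS
quantified by spectral counting yields exactly such a compendium, but with two
awkward properties: the data are *discrete* (counts of matched spectra) and
*very sparse* (the majority of cells are zero, and non-zero counts are skewed
toward small values). Kernel-density MI estimators built for continuous
expression data degenerate here.

`paracne` implements an MI reverse-engineering pipeline built for this data
type, followed by a master-regulator stage that turns the inferred network
into per-sample, pharmacologically actionable predictions, and by the
dose-response statistics used to validate such predictions in cell-line
panels.

## Iterative quantile discretization

The plug-in MI estimator needs the samples partitioned into `M` bins per
peptide. Equal-width bins are meaningless for counts concentrated at 0–3, and
plain quantile bins would split tie groups. The iterative quantile
discretization (IQD) rule used here:

1. sort samples by `(count, original index)`;
2. partition the `n` remaining points over the `m` remaining bins by
   cumulative targets — bin `b` of the round closes at cumulative occupancy
   `round(b·n/m)`;
3. whenever a group of tied values straddles a bin boundary, absorb the whole
   group into the bin where its first sorted member falls, close that bin,
   and restart the partitioning round with what is left;
4. stop when points or bins are exhausted.

Zeros — typically the majority — end up whole in the first bin; the
remainder approaches uniform occupancy as closely as the ties allow. Three
properties are fuzz-tested: no tie group is ever split, labels are monotone
in the count, and all-distinct vectors give occupancies differing by at most
one. The same rule is implemented twice in the repository — iteratively in
the package and recursively in the test suite — and the two are checked for
exact agreement on thousands of generated vectors. Where the requested `M`
exceeds the number of distinct values, the effective bin count is capped
rather than erroring, since the estimator downstream only sees the realized
bins.

## Mutual information, significance, and the choice of the null

MI is the plug-in (bin-count) estimate
$$ I(X,Y) = \log N + \frac{1}{N}\sum_{ij} k_{ij}\,
   \log\frac{k_{ij}}{k_i\,k_j} $$
in nats, with `0·log 0 = 0`. It equals the Shannon MI of the empirical joint
distribution, so it is symmetric and non-negative, and it is verified against
a literal double-sum implementation to 10⁻¹² on random tables.

A subtlety dominates edge calling: the plug-in estimate of *independent*
variables is biased upward by roughly `(Mx−1)(My−1)/2N` nats — about 0.16 at
`N = 250` and ten bins each way. Any fixed MI cutoff, or any null pooled
across peptide pairs with different effective bin counts, is therefore
miscalibrated: the pooled tail is owned by the high-bin pairs and becomes
unreachable for sparse ones. The default test conditions on each pair's
realized discretization: under independence `2N·I` follows a chi-square law
with `(Mx_eff−1)(My_eff−1)` degrees of freedom (the G statistic), which
absorbs the bias term exactly. Edges are kept at `alpha = 0.05` after
Bonferroni correction over all tested pairs. Two alternatives are available:
`mi_pvalue()` is a literal per-pair permutation test (useful at lenient
thresholds; resolving a Bonferroni threshold of ~3·10⁻⁵ per pair would need
tens of thousands of permutations), and `sig_method = "permutation"` is a
pooled permutation null with an exponential tail fit, retained for
comparison with the conservative classic calibration.

Only (kinase peptide, other peptide) pairs are scored — the regulator-centric
design means substrate–substrate pairs never receive MI. Distinct
phosphosites of one gene are eligible as regulator and substrate, so
cis-autophosphorylation edges can be inferred. The number of bins defaults to
`M = 10`; with a gold-standard edge list, `select_bin_number()` sweeps `M`,
scores gene-level precision and sensitivity of the resulting sub-network, and
picks the F1 maximum (the trade-off rule is a package choice; precision and
sensitivity are reported per `M` so any other rule can be applied).

## DPI pruning, bootstrap, consolidation

The data processing inequality states that for a chain `X→Y→Z`,
`I(X,Z) ≤ min(I(X,Y), I(Y,Z))`. In every triangle of retained edges the
weakest edge is removed when its MI falls below `(1 − tolerance)` times the
smaller of the other two; all triangles are scanned before any removal is
applied, so scan order cannot matter. The default tolerance is 0 (strict),
following the original ARACNe convention. The implementation is checked
against exhaustive triangle enumeration on random networks.

Networks are inferred on `B` bootstrap resamples of the samples (default
100). An edge enters the consolidated network when its support count is
significant under a Poisson null whose mean is the expected support of a
random *tested pair* — total support divided by the number of tested pairs —
with Bonferroni correction across observed edges. Normalizing by distinct
observed edges instead would be self-defeating: a perfectly reproducible
network would have mean support `B` and nothing would ever be "above
average". A majority-vote option (`support > B/2`) is provided. The final
MI of an edge is its mean over supporting bootstraps.

Each consolidated edge is annotated with the Spearman correlation of its raw
count rows and its two-sided p-value; edges with a constant row are flagged
and excluded from the negative-fraction denominator. On phospho-data the
expectation is overwhelmingly positive coupling — kinases phosphorylate, so
higher kinase phospho-state means higher substrate phospho-state — and the
package reports the negatively correlated fraction as a quality check.
Peptide-level edges aggregate to one protein-level edge per gene pair
carrying the maximum contributing MI, and the enrichment of TK→TK edges
among all targets is scored by a hypergeometric right tail (the choice of
test is the package's; the universe is the gene set of the matrix).

## Master-regulator analysis (pVIPER)

The per-sample signature scores each peptide against the normal reference
group: `(x − mean(normals)) / s`, with `s` the normal-group standard
deviation floored at the median of nonzero normal SDs. Cell lines and tumors
are unreplicated columns, so a two-sample test per peptide is not defined;
this one-sample standardized difference is the nearest well-defined statistic
and is deliberately simple. The floor keeps zero-variance peptides finite
without inflating well-measured ones.

A kinase's *signalon* is its network substrate set filtered for significant
Spearman correlation with the kinase (p ≤ 0.05 Bonferroni-corrected within
that kinase's candidates); each target carries its correlation sign and an
`|rho|` weight. Negative-sign targets are retained in the object but excluded
from enrichment — with essentially all true coupling positive, a single-tail
analysis is both simpler and better powered than a three-tail scheme.

Enrichment of a signalon in a signature is a weighted Kolmogorov–Smirnov
running sum over the signature ranked by signed score. Hit weights are
`|rho| · |z|`, where `z` is the *rank-normalized* signature (normal quantiles
of the score ranks). Rank normalization is monotone — the ranking is
untouched — but bounds the weights; with raw scores, a single extreme peptide
(routine in majority-zero data with a floored reference SD) dominates both
the observed and the null running sums and the normalized score collapses
toward 1 regardless of signal. The enrichment score is standardized against
a size-matched random-set null (`NES`), with an empirical two-sided p-value
from the same 1000-permutation null (seeded; a sample-permutation null is
impossible for single-sample signatures).

Because the running-sum statistic is bounded, `NES` saturates for small
target sets and is not comparable across regulators with different set
sizes. Regulators are therefore ranked by their calibrated p-values —
transformed to signed normal scores and Stouffer-combined across the
peptides of one gene — with `|NES|` only as a tie-break. Per sample,
p-values are Benjamini–Hochberg adjusted across regulators.

Synergy of a kinase pair is the enrichment of the substrates *shared* by
both signalons, scored against equally sized random subsets of the substrates
unique to either kinase: a sample that specifically hyper-phosphorylates the
shared set — the signature of joint dependence — scores a small one-sided p.
A phosphosite-level rule then classifies samples by *which* sites drive the
prediction: a designated site pair jointly significant calls the sample
combination-sensitive; the first site significant alone or with other
partners calls single-agent sensitivity; otherwise the sample is called
insensitive.

## Drug-combination statistics

Validation-side statistics operate on fractional inhibition: Excess Over
Bliss `fAB − (fA + fB − fA·fB)`, zero exactly on the Bliss surface; IC50 by
log-dose linear interpolation between bracketing design doses (assumption
free; curves that never cross 0.5 return a censored sentinel rather than a
number); the Chou–Talalay combination index `d1/D1 + d2/D2` with labels
strong synergy (CI ≤ 0.8), borderline (0.8 < CI < 1), additive or
antagonistic (CI ≥ 1); and a one-sided Fisher exact test for
prediction-versus-outcome tables, checked against exhaustive hypergeometric
enumeration over all small tables.

## The synthetic-data generator

Every stage is tested against generated data with known ground truth. The
generator emulates a LUAD-like phosphotyrosine compendium:

* 250 samples by default — 156 tumors, 46 cell lines, 48 normals — with 10
  TKs and 100 substrate proteins at default scale;
* each TK drives `edges_per_tk = 8` substrates exactly; a designated pair of
  TKs shares a configurable fraction of its substrates; a few TK→TK edges
  make one kinase's activity depend on another's;
* per-sample latent kinase activities are standard normal in tumors and cell
  lines and tightly distributed (SD 0.25) in normals; substrate latents are
  `coupling_strength` (default 0.8) times the (standardized) parent drive
  plus noise; a fraction of genes emit two phosphosite peptides with
  correlated latents, exercising protein-level aggregation;
* counts are negative binomial (size 4) around
  `mu0 · exp(2.5 · saturate(latent))`, where `saturate` is a soft tanh cap at
  2.5 SD — phosphosite occupancy cannot grow without bound — and `mu0` is
  solved so that a baseline peptide is zero with probability
  `zero_inflation` (default 0.6; a value of 1 reproduces the all-zero
  limit). The defaults give ~55–60 % zero cells, counts ranging to a few
  hundred, and a skewed low-abundance bulk, and make a coupling of 0.8
  detectable at `N = 250` — that is, the planted effect size means what it
  says at the study's sample size.

Spike scenarios plant downstream signal. A spiked sample models a cell line
whose phospho-aberration is driven by designated kinases: its background TK
activity sits at the normal baseline and the designated TKs are elevated by
`spike_magnitude` (default 3) SD. The synergy scenario elevates the *shared*
substrates of a pair directly, leaving the unique substrates at baseline —
joint dependence expresses itself exactly as hyper-phosphorylation of the
common substrates. A spike list with no designated kinase yields baseline
(null) cell lines; the cleanest global null for calibration checks pairs
signalons from a coupled dataset with signatures from its coupling-free twin
(same seed, hence the identical peptide universe).

What the generator does **not** emulate: peptide identity and sequence
context, missingness that depends on the acquisition run, batch structure,
shared-peptide ambiguity between paralogs, and phosphatase-driven negative
regulation (available only as a planted negative-edge fraction). Passing the
recovery suite therefore demonstrates that the algorithms do what they claim
under the stated statistical conditions — not that any particular biological
network would be recovered at these rates.

## Numerical choices and degenerate inputs

* Natural logarithms throughout; only relative comparisons matter.
* Tiny negative MI from floating-point cancellation is clamped to zero.
* `M_effective` is capped by the number of distinct values; constant rows
  discretize to a single bin and carry zero MI.
* Constant rows have undefined Spearman rho; such edges are flagged rather
  than dropped silently.
* All stochastic stages take explicit seeds; bootstrap, permutation and
  generator streams are restored after use so callers' RNG state is not
  clobbered.
* Problem sizes in the test suite: MI oracle checks use 1000 random tables;
  IQD fuzzing uses 10⁴ vectors; network recovery uses ten seeds of the
  default 10-TK/100-substrate/250-sample configuration at `B = 50`;
  master-regulator and synergy recovery use fifty seeds of an
  8-TK/70-substrate/162-sample panel. These sizes were chosen to make the
  recovery estimates stable at desktop runtimes.

## Known limitations

* The significance screen's chi-square null is asymptotic; at very small
  `N` (a few dozen samples) it can be mildly anticonservative for pairs with
  many effective bins. The permutation alternatives are exact but slower.
* The Poisson consolidation assumes exchangeable support noise across pairs;
  strongly heterogeneous per-pair detectability is only partly captured.
* Signalon correlation filtering reuses the same compendium the network was
  inferred from; the two stages are not independent, which matches the
  study design this package models but inflates neither stage's internal
  calibration checks (those use held-out or decoupled data).
* The one-sample signature has no replicate variance estimate for the test
  sample; interpretation is rank-based by construction.
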