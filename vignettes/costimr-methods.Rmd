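---
title: "Methods: dissecting macrophage responses to opposing cues with costimr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting macrophage responses to opposing cues with costimr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costimr)
```

# The scientific problem

Macrophages integrate opposing polarization cues — an inflammatory
stimulus driving an M1-type program (`stimA` throughout this package)
and a resolving stimulus driving an M2-type program (`stimB`). When
both cues arrive at once (`costim`), individual cells may blend the two
transcriptional programs or specialize in one of them. costimr
implements the single-cell analysis chain used to ask that question:

1. derive each stimulus's **core gene program** from UMI counts;
2. quantify cell-to-cell **heterogeneity** of cross-regulated genes
   (Fano factors, masked Spearman networks, program scores);
3. detect **orthogonal (mutually exclusive) expression** via binarized
   pairwise odds ratios;
4. assign each co-stimulated cell a **dominance state** with a
   one-vs-rest neural-network classifier;
5. process **microwell secretion chips** from raw per-well
   fluorescence to positive calls and consensus secretion phenotypes.

Every stage is exercised against the package's own synthetic-data
generators, which plant known ground truth, so the pipeline is testable
end to end without any external dataset.

# Count model and the synthetic generator

Counts are negative binomial with mean $\mu$ and variance
$\mu + \mu^2/\theta$ ($\theta$ = `dispersion`). The generator
(`count_sim_params()` / `simulate_counts()`) carves three disjoint gene
blocks out of the transcriptome: program A, program B, and shared
genes. Under its own stimulus a program gene's mean rises
`induction_fold`-fold; shared genes rise under either stimulus at the
geometric mean of the two folds (this exercises the shared branch of
the set logic without extra parameters). Co-stimulated cells are a
mixture of A-dominant, B-dominant and mixed cells
(`costim_fractions`, assigned deterministically so planted fractions
are exact). In a dominant cell the opposing program's *induced
component* is scaled by `cross_inhibition` $c \in [0,1]$:
$\mu = b\,(1 + (f-1)\,c)$, so $c=1$ means no inhibition and $c=0$
returns the gene to baseline. Mixed cells induce both programs fully.

Reference conditions (the defaults): baseline mean 0.5 UMI — a
moderately expressed gene — 4-fold induction, dispersion 0.5 (strong
overdispersion, typical of UMI counts), 1000 cells per condition,
fractions (0.45, 0.45, 0.10), cross-inhibition 0.2. Dropout is not
modelled separately: NB sampling at sub-unit means produces abundant
zeros on its own.

What the generator does **not** emulate: transcriptome-wide mean
structure, batch effects, doublets, library-size heterogeneity beyond
sampling noise, or gene–gene correlation within a cell beyond the
planted state structure. Passing tests therefore demonstrate that the
algorithms recover the statistical structure they target, not that any
biological claim holds in real data.

# Core programs

`normalize_counts()` uses median-scaled library-size factors
($\mathrm{sf}_i = \mathrm{total}_i / \mathrm{median}$, median exactly
1) and values $\ln(\mathrm{count}/\mathrm{sf} + 1)$. Pooled
deconvolution factors would also fit here; library-size factors keep
the normalization exactly testable (note they are ratios, so scaling
every cell by a common constant changes the values, not the factors).

`differential_expression()` is a per-gene two-sided Wilcoxon rank-sum
test on normalized values with the normal approximation, tie
correction and continuity correction (it matches
`wilcox.test(exact = FALSE, correct = TRUE)` to 1e-10 in the tests),
followed by Benjamini–Hochberg adjustment across all genes. Fold
change is computed on de-logged normalized means with an $\epsilon =
10^{-9}$ pseudocount so silent genes divide cleanly; ratios of
expressed genes are essentially unchanged.

A **core gene** satisfies fold change $\ge$ 1.5, FDR $\le$ 0.05, and
detection (count $\ge$ 1) in $\ge$ 15% of stimulated cells. For
downregulation calls the detection rule is applied to the reference
condition, since a gene silenced in the test condition cannot meet a
test-side detection rule; the thresholds are symmetric
($1/\mathrm{FC} \ge 1.5$). **UCGs** (unique core genes) are the set
difference of the two core programs; **shared** genes the
intersection. `classify_cross_regulation()` labels each UCG
`inhibited` / `augmented` / `unchanged` by re-running the same test,
co-stimulation versus that program's single stimulus.

QC defaults (`qc_filter()`): at least 200 detected genes per cell, at
most twice the median detected-gene count (a conventional doublet
guard), gene detected in at least 3 cells. The downstream contracts do
not depend on these values; they are fully configurable.

# Heterogeneity

**Fano factors** (variance/mean) are computed on size-factor-scaled
*linear* counts with population variance (divide by $n$): the Fano
factor is a linear-scale dispersion measure calibrated to 1 for
Poisson noise, and the population convention makes duplication of the
full cell set an exact invariance. For an NB gene the Fano factor is
$1 + \mu/\theta$.

One subtlety is worth deriving. For a UCG of program B in a costim
population that is half A-dominant (gene near baseline $b$) and half
B-dominant (gene at $f b$), the mixture's Fano factor exceeds the
single-stimulus one only when the between-mode variance term
$\tfrac14 (f b - b)^2$ outruns the drop in the within-mode
NB variance. With near-Poisson noise ($\theta \gtrsim$ a few) the
bimodality dominates and co-stimulation *increases* noise; with strong
overdispersion ($\theta = 0.5$ at these means) the single-stimulus
Fano $1 + f b/\theta$ is already larger, and the shift reverses sign.
The packaged noise-gain check therefore runs at $\theta = 10$, where
the mechanism it demonstrates is the dominant term.

**Masked Spearman networks** (`spearman_network()`) use mid-ranks,
Pearson correlation of ranks, and the $t$ approximation for the
p-value; coefficients with $p > 0.05$ are set to zero. Constant genes
are flagged and reported as $\rho = 0$, $p = 1$. On tie-heavy NB data
the mask's measured type-I level is within the nominal 5% (verified by
simulation in the test suite).

**Program scores** (`ucg_score()`): the literature rarely pins down an
"expression score", so the package declares one — the mean normalized
value over the gene set minus the mean over a seeded uniform sample of
`n_background` $\times$ set-size non-member genes (sampling from the
sorted gene universe, so scores are invariant to column order).
`n_background = 0` gives the plain set mean.

# Orthogonal expression

RNA is binarized at count $\ge$ 2 ("a threshold of 2 detected
transcripts" read inclusively; one isolated function owns the choice).
For each feature pair, the odds ratio is
$(n_{11} n_{00})/(n_{10} n_{01})$ on the 2×2 co-detection table; when
any cell is zero, 0.5 is added to all four cells (Haldane–Anscombe,
flagged per pair) so $\log_2$OR stays finite for display, while the
two-sided Fisher exact p-value — probabilities summed over tables as or
less likely than the observed one — is always computed on the
*uncorrected* table. Entries with $p > 0.05$ are masked to zero; a
surviving negative $\log_2$OR is the signature of mutually exclusive
("orthogonal") expression. No multiple-testing correction is applied
across pairs, deliberately: the mask reproduces the published
construction, and the full p matrix is exposed for users who want to
correct. The Fisher implementation is checked exactly against an
exhaustive fixed-margin enumeration for every table with total
$\le 40$.

# Dominance classification

Two binary MLPs (three tanh hidden layers, 64/32/16, sigmoid output,
cross-entropy, Adam, L2 weight decay $10^{-4}$ — the defaults of the
standard toolkit for this model family) are trained on single-stimulus
cells: classifier A separates `stimA` from the rest of the training
universe, classifier B likewise. Features are normalized values
standardized by training-set mean/SD (stored in the model); training
uses a stratified 80/20 split and optional stratified k-fold
cross-validation. Applied to co-stimulated cells, the two thresholded
probabilities combine to `A-dominant` (+,−), `B-dominant` (−,+),
`mixed` (+,+) or `unclassified` (−,−). Probabilities are clamped to
$[10^{-12}, 1-10^{-12}]$ so a degenerate decision threshold of 1.0
classifies nothing.

Two design points deserve flagging:

* **Training negatives.** With only two single-stimulus classes, the
  classifiers trained "A vs B" are near mirror images: a cell's
  evidence for A is evidence against B, so `mixed` (+,+) and
  `unclassified` (−,−) are both nearly unreachable. Adding control
  cells to the negatives (`include_controls = TRUE`) breaks the
  symmetry — presence of the A program now separates positives from
  controls independently of the B program — and is the configuration
  to use whenever mixed-cell detection matters. The default remains
  the single-stimulus universe.
* **A limit of OvR on UCG-only features.** For a cell expressing both
  programs fully, the class-conditional likelihood on UCG features is
  symmetric between "stimA" and the stimB-containing rest, so even a
  perfectly calibrated classifier scores it at or below 0.5 for both
  classes: fully mixed cells are structurally `unclassified` on that
  feature set. On all genes, shared-program genes break the symmetry
  and mixed cells are recovered as `mixed`. `compare_feature_sets()`
  makes this contrast visible.

Feature-set `cross_inhibited_ucgs` uses the UCGs labelled `inhibited`;
if none are (e.g. simulations without cross-inhibition) it falls back
to all UCGs with a warning rather than failing, since the comparison
remains well defined.

# Secretion processing

The chain is fixed and auditable: **normalize → threshold → transform
→ call → (odds ratios | cluster)**, every stage recording its
parameters.

* **Background normalization**: for each well, the `window` (default
  50) nearest zero-cell wells in row-major array order define the
  local background; a Gaussian is fitted (location = mean, scale = SD)
  and the location subtracted. A flat background cancels exactly;
  a linear drift of slope $s$ leaves a residual bounded by
  $s \cdot \mathrm{window}/2$.
* **Thresholds**: the 99th percentile — linear interpolation between
  order statistics (`quantile()` type 7) — of normalized zero-cell
  intensities, per analyte. Positive calls use a *strict*
  inequality, so at most 1% of zero-cell wells are called by
  construction.
* **Transform**: $\mathrm{asinh}(x / (0.8\,\mathrm{threshold}))$, the
  cofactor-as-divisor convention; monotone, defined for negative
  values, linear near zero and logarithmic above the cofactor.
* **Quantification** is restricted to single-cell wells
  (`cell_count == 1`); pair fractions (A+B−, A−B+, A+B+, A−B−) sum
  to 1. Odds ratios reuse the orthogonality machinery unchanged.

The chip simulator plants Poisson well loading (default 0.5 cells/well,
so a majority of wells are empty and feed the background model), a
smooth separable low-order polynomial drift surface, Gaussian well
noise, and secretor profiles among loaded wells. The default panel
mimics a five-protein readout: three inflammatory profiles, one
resolving, one mixed, the remainder silent; the IL6/Chi3l3 pair never
co-occurs in a profile, planting mutual exclusivity. Profiles that
violate a declared exclusivity pair are rejected at construction.

# Consensus clustering

Base partitions: k-means plus agglomerative clustering with average,
complete and Ward linkage over euclidean and cosine distances (Ward on
euclidean only), each across `k_range` (default 2:16). The
co-occurrence matrix is the fraction of base partitions placing two
wells together; the consensus is average-linkage clustering of
$1 - $co-occurrence cut at `cut_height`, and clusters with fewer than
3 members are discarded (wells marked unassigned).

Two numerical choices matter:

* **The sweep must extend well past the expected number of groups.**
  Low-k members merge nearby profiles by necessity; only the higher-k
  members give the co-occurrence matrix the contrast to separate them.
* **The cut is 0.4, stricter than a bare majority.** Cosine distance
  is scale-invariant: wells containing only noise point in random
  directions, so cosine-based trees spend their entire k budget
  shattering the silent population and *never* separate two profiles
  that differ in a single magnitude-carrying analyte. Those members
  vote "together" regardless of the data, pinning the co-occurrence of
  such profile pairs near the cosine share of the sweep (≈0.44 under
  the defaults). A 0.5 cut would merge them; 0.4 separates every
  planted profile while leaving genuine clusters intact. With sweeps
  free of scale-invariant members, 0.5 behaves as expected and is a
  reasonable setting.

Exactly identical profiles are assigned to a single cluster by
definition (any k-partition of exact ties is arbitrary), and tied
average-linkage heights are guarded against $10^{-16}$-scale
non-monotonicity before cutting.

# Problem sizes and determinism

The packaged checks run at desk scale, chosen so each statistical
claim has comfortable power: 500–2000 cells per condition and 200–500
genes for recovery tests, $10^5$ draws for closed-form anchors
(Poisson Fano, Gaussian percentile), 1000 replicates for mask
calibration, 5000-well chips (≈1500 single-cell wells) for the
end-to-end secretion property over 10 seeds. All randomness flows
through explicit integer seeds (`withr::with_seed`), and generators
are byte-reproducible under a fixed seed.

# Known limitations

* Library-size normalization cannot remove composition effects that
  pooled-deconvolution factors target; with strongly induced programs
  the size factors of stimulated cells absorb some induction.
* The rank-sum normal approximation is inaccurate below ~10 cells per
  group; the package refuses fewer than 2 and the tests operate far
  above that.
* The moving background fit assumes drift varies slowly relative to
  the spacing of `window` zero-cell wells in row-major order; sharp
  spatial steps or strongly anisotropic drift would call for a 2-D
  neighbourhood instead.
* Dominance labels inherit the OvR geometry discussed above: claims
  about mixed-cell fractions should be read against the chosen
  feature set and training universe.
* The classifier is intentionally small and unregularized beyond L2;
  it is a readout of program separability, not a general-purpose cell
  annotator.
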