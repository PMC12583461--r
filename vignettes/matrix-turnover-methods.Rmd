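---
title: "Methods: models, parameters and design choices in matriturn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in matriturn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matriturn)
```

matriturn implements the bespoke computations of an integrated
matrix-turnover analysis of inflamed synovium: matrisome gene-set
enrichment of single cells, differential-expression target
prioritisation, semi-tryptic degradomics, spatial delineation of
collagen-rich and collagen-poor niches, and a phase model of collagen
deposition. This vignette explains each model, its assumptions, the
tunable parameters, and the choices made where the design was genuinely
open. It states no empirical result that the package's tests do not
themselves compute.

## Matrisome enrichment by recovery-curve AUC

Each cell's genes are ranked by raw count (rank 1 = highest). Because the
score depends only on the ranking, no normalisation is applied; any
strictly monotone transform of the counts leaves scores unchanged. Ties —
including the all-zero bulk of a sparse cell — are broken by a seeded
random permutation so results are reproducible for a fixed seed.

For a gene set $S$ and a universe of $G$ genes, the recovery curve
$f(k)$ counts members of $S$ at rank $\le k$. With the rank threshold
$m = \lceil \tau G \rceil$ the score is
$\sum_{k=1}^m f(k) \big/ \sum_{k=1}^m \min(k, |S|) \in [0, 1]$.

**Threshold interpretation.** The analysis this package supports raised
the enrichment threshold "from 5 to 10%". In the AUC algorithm there is
exactly one 5%-default threshold: the fraction of the ranking over which
the recovery curve is integrated. We therefore interpret the raised value
as the top-rank fraction of *genes*, default `auc_top_fraction = 0.10`,
and expose it as a parameter; an assignment threshold over cells would
require the bimodality machinery that is deliberately out of scope.

Curation of the matrisome collection (`curate_matrisome()`) removes
cytokines and chemokines from the Secreted Factors category only;
a symbol shared with another category is retained there, since the
categories express distinct biology.

Cluster summaries follow the standard boxplot convention: quartiles by
the type-7 quantile rule and whiskers at the most extreme values within
1.5 IQR of the hinges.

## Differential expression and target prioritisation

Pseudobulking sums raw counts per (sample, cluster); cells without a
cluster label are excluded and counted in a message. The
negative-binomial route (`dea_pseudobulk_nb()`) is the standard edgeR
pipeline — TMM normalisation, trended/tagwise dispersion, GLM fit and
likelihood-ratio test — with BH adjustment within the tested cluster. At
least two replicate samples per condition are required; fewer is an
error, not a silent fallback.

The hurdle route (`dea_hurdle()`) models log-normalised expression
$\log(1 + 10^4 \cdot c_{gi} / N_i)$ in two parts: a binomial
likelihood-ratio (G) test on the detection rate and a Gaussian
likelihood-ratio test on the positive values, summed as a $\chi^2$ with
one degree of freedom per contributing part. When one group has no
detected cells the continuous part is dropped and the degrees of freedom
reduced; an all-zero gene reports $p = 1$. The reported log2FC is the
difference of mean log-normalised expression converted to log2 units.
This is a self-contained two-part hurdle test in the MAST tradition, not
a re-implementation of any particular package; calibration is established
by simulation (permutation-null uniformity and planted detection-shift
recovery in the test suite).

Marker detection (`find_cluster_markers()`) is one-vs-rest Wilcoxon,
restricted to genes detected in at least 25% of in-cluster cells with
average |log2FC| ≥ 0.25 — both configurable.

**Prioritisation.** Three metrics are computed per (gene, cluster):
method overlap (significant by both human routes with the same
fold-change sign), species conservation (significant in the mouse data by
at least one route with the same sign; symbols matched
case-insensitively, since human symbols are uppercase and mouse symbols
title-case — no ortholog tables at this scale), and the
differential-expression score $|-\log_{10}(p) \cdot \log_2 FC|$. The
score uses the *raw* p value — the formula's own term — while adjusted p
values gate significance; zero p values are clamped to the smallest
positive double and logged. No combination rule for the three metrics
into a single rank is canonical, so the package orders lexicographically
by tier — both flags, then one flag, then none — with the mean score
across the human methods as the within-tier key. Every ingredient
(significance rule `padj < 0.05`, `|log2FC| ≥ 0.25`, the tiering) is a
configurable argument. Genes are restricted to the matrisome collection;
an empty intersection is an error.

Cassette overlap is plain set algebra per stratum and direction; the
shared/unique partition is checked to be disjoint and exhaustive. The
packaged reference cassettes (`remission_cassettes()`) are the lining
(10 up, 13 down) and sub-lining (6 up, 7 down) gene lists shared between
RA remission and frozen-shoulder resolution; `cassette_fixture()` embeds
them in disease-specific DEG lists with disjoint fillers so the expected
intersection sizes are known exactly.

## Degradomics

In-silico digestion cleaves after K or R, suppressing cleavage before
proline — the specificity used by the common search engines — and emits
every peptide spanning at most `digest_missed_cleavages = 2` internal
sites. The proline rule is configurable off.

Terminus classification: a peptide terminus conforms to trypsin if it is
a protein terminus or sits at a tryptic site. Fully tryptic = both
termini conform; semi-tryptic = exactly one — the other terminus is the
footprint of an endogenous protease; non-tryptic = neither. A start
position at or below `nterm_exclusion_limit = 2` counts as the protein
N-terminus to accommodate initiator-methionine loss; consequently a
protein N-terminal peptide is never evidence of endogenous proteolysis
and is removed before ratio statistics. The endogenous cleavage position
is recorded as the residue index on the N-terminal side of the broken
bond (start − 1 for a nonconforming N-terminus, end for a nonconforming
C-terminus); one convention is needed for binning and this one is used
consistently.

Normalisation is median subtraction in log space, per sample; every
sample's post-normalisation median is zero and global scaling cancels.

Semi-tryptic:tryptic ratios come in two modes. Abundance mode emits one
ratio per semi-tryptic peptide — its mean abundance over the condition's
samples divided by the mean tryptic abundance of the protein group —
matching the one-dot-per-peptide presentation of degradation panels.
Whether the tryptic denominator should be pooled per condition or per
sample is not settled; the package pools within condition (a
`sample_condition` map argument), which keeps the estimator stable at
small sample counts. Spectral mode reports total semi-tryptic over total
tryptic counts per group and condition. Both are invariant to global
abundance scaling and to record order.

Cleavage maps bin endogenous cleavage positions into fixed-width
sections, $\lceil pos / w \rceil$, tiling residues 1..L. The default
width follows the 50–100 aa section convention: 50 aa for chains under
1500 residues, 100 aa for longer chains (the long collagen-VI α3 chain is
the motivating case); any width can be forced. The susceptibility overlay
counts predicted-cleavage positions with score ≥ 0.75 per section and
flags sections where observation and prediction co-occur.

The correlation network links proteins with Pearson r strictly above
0.85. The threshold is one-sided by design — anticorrelated proteins are
*not* linked, following the stated edge rule — and configurable.
Zero-variance proteins are excluded with a message. Communities are
Louvain at resolution 0.5 with a seeded search; labels are canonicalised
by each community's alphabetically smallest member so output is
deterministic. Isolated proteins form singleton communities.

## Spatial niches

Local fibre density is the k-nearest-neighbour estimator
$\rho_i = k / (\pi d_k(i)^2)$ with `knn_k = 10` by default. The exact
estimator behind published "nearest neighbour analysis" density scores is
rarely stated; the k-NN form is standard, dimensionally yields
fibres/µm², and at realistic fibre intensities produces densities on the
0.01 fibres/µm² scale of reported section medians. Duplicate fibre
centroids would give infinite density; distances are clamped at 1 µm/1000
with a message. Fibres are split at the *median* density — the cutoff is
data-driven per section, never a fixed constant — with ties assigned
rich for determinism.

Regions of interest: rich fibres are grouped by single-linkage
clustering at `linkage_distance_um` (default 30 µm, about one k-NN
spacing at default intensities), each group's outermost fibres are taken
as its convex hull, and the hull is expanded by `dilation_um = 50` as a
Minkowski sum with a disc (arcs approximated at 64 segments per full
circle, an area error below 0.05%). A concave boundary (alpha-shape) was
considered and rejected for the default: the hull is deterministic,
parameter-free and unambiguous. Groups of fewer than three (or collinear)
fibres become discs/capsules of the dilation radius. Perivascular regions
are discs of `perivascular_radius_um = 50` around vessel centroids,
clipped to the field. Union areas (overlap-corrected) are estimated by
deterministic grid counting at a spacing fine relative to the radius;
per-polygon areas are exact shoelace areas.

Enrichment: every cell is assigned in/out of the rich regions by
boundary-inclusive point-in-polygon; "background" is all cells outside
the rich regions, including cells in perivascular-but-poor tissue. Per
phenotype, a two-sided Fisher exact test on the 2×2 table is reported
with the natural-log odds ratio (Haldane–Anscombe +0.5 when any table
cell is zero), a Wald 95% CI, and BH adjustment across the phenotype
panel of the section. Coverage correlations are Pearson with two-sided
t-based p values and BH adjustment across the panel.

## The turnover phase model

The deposition model translates the clinical picture — cycling between
active disease and remission with protease expression (MMP2/MMP9) out of
phase with inhibitor expression (TIMP3/TIMP4) — into the minimal
quantitative form: sinusoidal waves $P(t) = b_p + A_p \sin(2\pi t/T)$ and
$I(t) = b_i + A_i \sin(2\pi t/T + \varphi)$, thresholded net degradation
capacity $D = \max(0, P - I)$, and collagen dynamics
$dC/dt = s(t) - k_d D C$ with $C$ clipped at zero. No published equations
exist for this conceptual picture; every functional form here is an
explicit package choice, all parameters are exposed, and the tests assert
only the qualitative claims the picture makes (in-phase cancellation,
antiphase asymmetry of deposition between phases) plus numerical
correctness against closed forms. Where several expression channels map
onto one wave (two proteases, two inhibitors), the intended aggregation
is unspecified; the model takes a single aggregate amplitude/baseline per
side, equivalent to summation.

Integration is explicit Euler with a resolution guard (`dt ≤ T/20`
required; defaults use `T/1000`). Euler was chosen over adaptive schemes
deliberately: the dynamics are mild, the scheme is transparent, and
convergence is verified by step-halving (endpoint changes below 0.1% in
the test suite). Phases default to half-periods and are labelled active
where the protease wave exceeds the inhibitor wave on average.

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of (spec, seed) and export ground
truth sufficient to score the downstream stage.

* `simulate_sc_counts()` draws negative-binomial counts (variance
  $\mu + \phi\mu^2$, the standard scRNA-seq parameterisation) with
  gamma-distributed gene means, cluster/condition structure, an optional
  planted program (gene-set multiplier in one cluster) and planted
  condition-DEGs; a second "species" replica carries the shared planted
  DEGs with the same sign under title-case symbols. Defaults: 4 clusters,
  25 cells per cluster per sample, 2000 genes, 4 samples per condition.
  It does not emulate batch effects, ambient RNA, doublets or
  library-size confounding.
* `simulate_degradome()` digests the packaged synthetic toy chains
  (`toy_collagen_synthetic.fasta` — synthetic sequences, not real
  collagens) and plants endogenous cleavage sites whose semi-tryptic
  products appear with condition-dependent rates (defaults 0.4 vs 0.1,
  a strong disease-versus-control contrast); planting on a tryptic site
  is rejected as ambiguous. Abundances are log-normal scaled by the
  cleavage rate; spectral counts are Poisson with rate-scaled means. It
  does not emulate intensity-dependent missingness, FDR filtering or
  modification chemistry.
* `simulate_tissue()` places vessels uniformly, thins fibres to 5%
  inside dark-zone discs, and places cells by rejection sampling with
  per-phenotype odds toward rich or poor tissue. The default study
  conditions — a 600 µm field, 5 vessels, 120 µm dark zones around 80% of
  them, 0.003 fibres/µm² (k = 10 neighbour spacing ≈ 30 µm), 300 cells
  for each of four phenotypes — were fixed once after a design-phase
  power check that an odds-3 preference is reliably detectable through
  the full density→regions→Fisher pipeline; they were not adjusted
  afterwards. The simulator does not emulate cell morphology, lining/
  sub-lining architecture or marker-intensity noise.
* `simulate_abundance_matrix()` gives each block a latent per-sample
  factor plus Gaussian noise, so within-block correlations are
  $1/(1+\sigma^2)$ in expectation and between-block correlations centre
  on zero.

Passing tests on these generators show the pipeline recovers planted
structure of the assumed form; they cannot certify behaviour under real
data's unmodelled features (the lists above).

## Numerical choices and degenerate inputs

* Rank ties: seeded random permutation (never stable order, which would
  bias low-index genes).
* `de_score`: p = 0 clamped to the smallest positive double, logged.
* Fisher tables with zeros: +0.5 on all cells for the log odds ratio and
  CI only; the exact p value needs no correction.
* Density duplicates: k-NN distance floored at 10⁻³ µm, logged.
* Region arcs: 64 segments per circle (128 for perivascular discs);
  union areas by grid counting at ≤ radius/50 spacing.
* Euler guard: `dt > T/20` is an error rather than a warning.
* Readers reject malformed records by name; nothing is silently coerced
  or dropped.

## Problem sizes in the test suite

The suite verifies oracle equality on 200 AUC instances (G ≤ 20), 100
random digests (length ≤ 60), 500 random 2×2 tables (totals ≤ 200) and
1000 BH vectors; recovery and calibration claims use 100 simulation seeds
each (degradation-ratio ordering, spatial preference recovery and null
false-positive control, pseudobulk type-I calibration at 2000 genes and
4+4 samples). These sizes were chosen as the smallest at which the
binomial acceptance margins (e.g. ≥95/100) are meaningful.

## Known limitations

* The hurdle test's Gaussian part assumes approximate normality of
  positive log-normalised expression; at very low detection counts its
  χ² reference is approximate (the discrete part dominates there).
* The convex-hull boundary overstates concave fibre-rich territories;
  an alpha-shape option would tighten them at the cost of a free
  parameter.
* The correlation network uses marginal Pearson correlations; indirect
  correlations are not deconvolved.
* Mouse–human symbol matching by case-insensitive equality misses
  non-orthographic orthologs.
* The turnover model is a conceptual phase model for hypothesis
  articulation, not a fitted kinetic model; none of its parameters are
  identified from data.
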