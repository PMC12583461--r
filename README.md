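# matriturn

Tools for studying extracellular-matrix (ECM) turnover in inflamed joint
tissue — how synovial fibroblasts and myeloid cells build, degrade and
remodel the matrix across cycles of disease activity and remission in
rheumatoid arthritis (RA) and related conditions. The package is aimed at
computational biologists integrating single-cell transcriptomics,
shotgun/TMT proteomics with semi-tryptic (degradomic) searches, and
multiplexed-imaging spatial data of the same tissue.

## What it computes

* **Matrisome enrichment** — per-cell gene-set scores for the matrisome
  categories (collagens, glycoproteins, proteoglycans, ECM-affiliated,
  ECM regulators, secreted factors) via a recovery-curve AUC. With a gene
  universe of size *G* and rank threshold *m* = ⌈0.10·*G*⌉, the score for
  gene set *S* is

  AUC = Σₖ₌₁..ₘ f(k) / Σₖ₌₁..ₘ min(k, |S|),  f(k) = |{s ∈ S : rank(s) ≤ k}|,

  which depends only on the expression ranking of each cell.
* **Differential expression and target prioritisation** — pseudobulk
  negative-binomial likelihood-ratio tests (via edgeR) and a two-part
  hurdle model on log-normalised counts, combined with a three-metric
  prioritisation: overlap between the DEA methods, conservation in a
  second species, and the differential-expression score
  |−log₁₀(pval) · log₂FC|. Cross-disease cassette overlap reports the
  genes shared between, e.g., RA-remission and frozen-shoulder-resolution
  DEG lists.
* **Degradomics** — in-silico trypsin digestion (K/R specificity, proline
  rule, missed cleavages), peptide terminus classification into fully
  tryptic / semi-tryptic / non-tryptic, semi-tryptic:tryptic degradation
  ratios (after removing protein N-terminal peptides), cleavage-site maps
  over 50–100 aa protein sections with protease-susceptibility overlay
  (cutoff 0.75), Welch tests of differential peptide abundance, and
  protein correlation networks (edges at Pearson r > 0.85, Louvain
  communities at resolution 0.5).
* **Spatial niches** — k-nearest-neighbour local fibre density, a median
  density split into fibre-rich and fibre-poor ("dark zone") tissue,
  region-of-interest polygons (single-linkage clusters → convex hull →
  50 µm Minkowski dilation), perivascular discs of 50 µm radius, marker
  coverage percentages, Fisher exact enrichment of cell phenotypes in
  rich regions versus background, and coverage–phenotype correlations.
* **Turnover model** — out-of-phase protease/inhibitor waves
  P(t) = b_p + A_p sin(2πt/T), I(t) = b_i + A_i sin(2πt/T + φ), net
  degradation capacity D = max(0, P − I), and collagen dynamics
  dC/dt = s(t) − k_d·D·C integrated by explicit Euler, with per-phase
  deposition potential.
* **Synthetic data** — generators for cluster-structured
  negative-binomial scRNA-seq counts with planted programs and
  cross-species DEGs, peptide tables with planted endogenous cleavage
  sites and condition-dependent rates, spatial scenes with perivascular
  dark zones and phenotype placement preferences, and block-structured
  abundance matrices — each a pure function of (spec, seed) with exported
  ground truth.

## Worked example

Simulate a degradome with planted endogenous cleavage (rates 0.4 in RA vs
0.1 in OA), classify peptide termini, and compute spectral semi-tryptic
ratios per protein and condition:

```r
library(matriturn)
sim  <- simulate_degradome(degradome_sim_spec(), seed = 1)
pep  <- classify_peptides(sim$peptides, attr(sim$peptides, "proteins"))
prof <- semitryptic_ratio(pep, mode = "spectral",
                          sample_condition = sim$truth$sample_condition)
prof$spectral
#>        group condition semi_counts tryptic_counts       ratio
#> 1 COL6A1_SYN        RA         131           4499 0.029117582
#> 2 COL6A1_SYN        OA          37           4438 0.008337089
#> 3 COL6A2_SYN        RA         134           9843 0.013613736
#> 4 COL6A2_SYN        OA          34          10089 0.003370007
#> 5 COL6A3_SYN        RA         132           8611 0.015329230
#> 6 COL6A3_SYN        OA          28           8635 0.003242617
```

The ratio — semi-tryptic spectral counts over tryptic counts for the same
protein — is the degradation readout: for every synthetic chain it is
3–5× higher in the high-cleavage (RA-like) condition, recovering the
planted contrast.

Cross-disease cassette overlap on the packaged fixture (shared remission
cassettes plus disease-unique fillers):

```r
cs <- cassette_overlap(cassette_fixture()$ra, cassette_fixture()$fs)
cs[, c("stratum", "direction", "n_shared", "n_unique_a", "n_unique_b")]
#>     stratum direction n_shared n_unique_a n_unique_b
#> 1    lining        up       10          5          9
#> 2    lining      down       13          5          5
#> 3 sublining        up        6          5          5
#> 4 sublining      down        7          5          5
```

The shared counts (10/13/6/7) are the sizes of the lining and sub-lining
remission-up/-down cassettes returned by `remission_cassettes()`.

Fully out-of-phase protease/inhibitor waves split a disease cycle into an
active phase that degrades collagen and a remission phase that deposits
it:

```r
par  <- oscillation_params(period = 1, amp_protease = 1, amp_inhibitor = 1,
                           phase_offset = pi, baseline_protease = 1,
                           baseline_inhibitor = 1, synthesis = 0.5,
                           k_degradation = 1, c0 = 1, dt = 1/1000)
phase_deposition_potential(simulate_turnover(par, horizon = 1))
#>   phase_start phase_end     label       mean_D mean_net_rate    delta_C
#> 1         0.0       0.5    active 1.270694e+00    -0.5673545 -0.2847446
#> 2         0.5       1.0 remission 8.864056e-19     0.5000000  0.2500000
```

## Documentation

The methods vignette (`vignettes/matrix-turnover-methods.Rmd`) describes
the models, their assumptions, the default parameters and the design
choices in detail.
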