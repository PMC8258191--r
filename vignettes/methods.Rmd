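---
title: "Estimating mesozooplankton biomass from weighed net samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mesozooplankton biomass from weighed net samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesozoo)
```

## The measurement problem

Direct taxon-level biomass measurement of mesozooplankton works on pooled
individuals: a vertical net haul (0.25 m² mouth, 200-µm mesh) is split with
a Motoda splitter into 1/4, 1/8 or 1/16 depending on plankton density, one
part is diluted to 200 ml, and 2-ml pipette aliquots are sorted to taxon.
The individuals of each taxon are pooled into a pre-weighed aluminium boat,
dried, and weighed to 0.01 mg. Each such weighing carries an additive
container/residue error that is estimated from distilled-water control
boats dried alongside every sample.

`mesozoo` implements the estimation chain that turns these raw weight
gains into areal biomass:

1. **Error subtraction.** The mean control gain \(\bar e\) is subtracted
   from every plankton gain.
2. **Reliability filter.** Records whose corrected gain does not exceed
   \(4\,\mathrm{SD}\) of the controls are flagged unreliable (never
   deleted, excluded from statistics). With the packaged defaults
   (\(\mathrm{SD} = 0.01075\) mg) the threshold is 0.043 mg. The filter is
   applied to the *corrected* gain; comparing against the raw gain is
   available as a configuration switch (`reliable_on = "raw"`).
3. **Formalin correction.** Formaldehyde preservation leaches roughly 40%
   of tissue dry mass once the loss has stabilised; the pre-preservation
   mass is recovered as \(m / (1 - 0.40)\). The exact multiplier
   \(1/0.6 = 1.6667\) is used internally and displayed as 1.67, avoiding
   compounded rounding.
4. **Areal standardization.**
   \(B = m \cdot s \cdot \frac{V_\mathrm{dil}}{V_\mathrm{pip}\,k} / A\)
   with split denominator \(s \in \{4, 8, 16\}\), dilution
   \(V_\mathrm{dil} = 200\) ml, pipette \(V_\mathrm{pip} = 2\) ml, \(k\)
   pooled aliquots and net area \(A = 0.25\) m². Standardization is per
   record because \(k\) may differ between taxa within one haul.
5. **Individual dry weight.** Corrected — but *not* standardized — mass
   divided by the number of pooled individuals.
6. **Carbon and energy content.** Elementwise multiplication of areal
   biomass by taxon-specific factors (mg C/mg DW and J/mg DW) from the
   packaged 28-taxon reference table.

Carbon/energy conversion is applied after the formalin correction and
standardization: the factors are interpreted per mg of living-equivalent
dry mass. The chain is order-invariant over records and a record whose raw
gain equals \(\bar e\) corrects to exactly zero before the formalin step.

Size classes split the community at 1 mm into small (SMZ) and large (LMZ)
mesozooplankton, taken from the reference table with three exceptions:
*Calanus* nauplii are small while copepodites are large (the stages are
weighed separately, so the split is exact), and the two taxa spanning both
classes (*Limacina retroversa*, *Oikopleura* spp.) are assigned wholly to
the large fraction because their pooled weighings are dominated by large
individuals.

## Length–weight evaluation

The formula registry carries three *Calanus* relationships (power in
mg/mm, log-linear, and a power form rescaled by an AFDW:DW ratio of 0.9)
and five *Oithona* methods (a fixed 0.003 mg individual weight, two
log–log and two power forms in µg/µm). Logarithms are base 10 — the
convention of the source literature; base e would put the log-linear
*Calanus* formula far outside the envelope of its two siblings at a
typical 2.5-mm prosome length, and this cross-method consistency is
asserted in the tests.

For each sample the *calculated* mean individual dry weight is the mean of
per-individual evaluations (not the evaluation of the mean length — the
power forms are convex, so the two differ). It is compared with the
*measured* mean: the error- and formalin-corrected, non-standardized
pooled mass divided by the number of weighed individuals. Estimates within
±20% of the measurement (80–120%, boundaries inclusive — the boundary
semantics are a package choice) count as satisfactory. *Calanus* stages
are pooled per sample by default (one mean per taxon per sample); a
stage-split option exists. Event summaries average the relative percent
across stations unweighted, with the SD undefined for single-station
events.

## The multivariate suite

All community analyses operate on the samples × taxa matrix of reliable
areal biomass and are intended to run twice: on the complete matrix and on
the SMZ submatrix.

**Hellinger transformation.** \(y'_{ij} = \sqrt{y_{ij} / y_{i+}}\).
The square root is essential: only with it do rows have unit sums of
squares, Euclidean distances stay bounded by \(\sqrt 2\), and
Euclidean-space methods (PCA, Ward clustering, RDA) become appropriate
for compositional data. The transform is not idempotent; all-zero rows
are left as zeros with a warning.

**PCA** is covariance-based (columns centred, not rescaled) via singular
value decomposition — the convention for transformation-based ordination,
where the transform already equalises taxon scales. Correlation-based PCA
sits behind a flag; scaling 1 (distance biplot) and scaling 2
(correlation biplot) are both available because ordination plots can be
read either way.

**Clustering.** Four linkages (single, complete, UPGMA, Ward) are built by
Lance–Williams agglomeration. Ward is the squared-increment variant on
Euclidean distances (Ward.D2) — two "Ward" conventions circulate and the
choice is stated explicitly. Dendrogram fit is scored by the cophenetic
correlation and by Gower's criterion
\(\sum (d_{ij} - c_{ij})^2\) between original and cophenetic distances;
"Gower distance" here is the dendrogram-fit criterion, not the mixed-data
dissimilarity of the same name, since it is paired with cophenetic
correlation for method selection. The method with the highest cophenetic
correlation wins, ties broken by the smaller Gower criterion. When all
pairwise distances are equal the correlation is undefined (`NA`, flagged)
and selection falls back to the Gower criterion.

**Number of clusters.** Three criteria are computed per candidate \(k\):
the fusion-level gap crossed by the cut, the mean silhouette width
(singletons contribute 0 by convention), and the Pearson correlation
between the original distances and the binary dissimilarity of the
partition (0 within, 1 between clusters — coded so that better partitions
give *higher* correlations). The suggested \(k\) is the majority vote,
ties resolved toward the smallest \(k\), and is advisory: all per-\(k\)
values are emitted so the final choice remains a judgement call, as it is
in practice.

**Species contribution analysis.** For each cluster pair the squared
Euclidean distance between cluster centroids is decomposed per taxon:
\((c_{Aj} - c_{Bj})^2 / \sum_k (c_{Ak} - c_{Bk})^2\), summing to 1.
Taxa at or above twice the average contribution (\(2/n\); 7% for 28 taxa,
13% for 15) are flagged. The exact weighting of the original contribution
method this emulates is not fully specified in the methods literature we
follow; the centroid decomposition satisfies the same normalization and is
documented as the package's definition.

**Seasonality and variation partitioning.** Sampling days are projected on
the unit circle, \((\sin\theta, \cos\theta)\) with
\(\theta = 2\pi\,\mathrm{doy}/365\), so that dates across the turn of the
year are close. The denominator 365 (not 365.25 or 366) changes sample
positions by fractions of a degree — immaterial at eight events per year.
Redundancy-analysis \(R^2\) is the share of total variance of the centred
community matrix captured by its least-squares projection on the
predictors, adjusted by the Ezekiel formula with \(m\) equal to the rank
of the centred predictor matrix, which makes the result invariant to the
coding of the station factor. Two-set partitioning between the station
factor and the circular date predictor yields unique fractions, a shared
fraction and a residual that sum to one exactly; small negative adjusted
fractions are reported as computed and read as zero — they carry no
explanatory power.

## The synthetic survey generator

The generator exists so the whole chain can be tested against known
truth. It draws, per station × event × taxon: a Poisson count (areal
abundance × net area; negative-binomial overdispersion optional),
log-normal individual lengths, and power-law fresh dry weights; thins
individuals by a logistic capture curve (50% retention at 550 µm, scale
60 µm) emulating the 200-µm mesh, which leaves under 10% of 400-µm
individuals and saturates near 1 mm; applies the 40% formalin loss; picks
the Motoda split from haul density (≥8000 individuals → 1/16, ≥4000 →
1/8, else 1/4 — the density thresholds are a package choice); places the
split part's individuals into 100 two-ml aliquots and pools as many
aliquots as the haul density suggests (decided before the aliquot
contents are seen, keeping the areal estimator unbiased); and adds
weighing error \(\mathcal N(0.016, 0.01075)\) mg, censored so a plankton
boat never records a negative gain. Three pure-error control records
accompany every sample. The control SD default 0.01075 mg is back-derived
as 0.043/4 from the reliability threshold; 0.011 is accepted as an
equivalent rounding wherever the tests touch it.

The default scenario covers 3 stations × 8 events × 17 taxon/stage
combinations with seasonal abundance bumps (circular Gaussian over a
winter floor; multipliers below \(10^{-4}\) are treated as true absence):
a *Calanus* copepodite stock dominating annual biomass (≈80–85% of truth
biomass), a pteropod autumn peak, cirripede nauplii whose median length
ramps from 392 µm (1 April) to 703 µm (1 May), copepod nauplii abundant
in spring, amphinomid larvae only at the July event, winter-active
*Metridia*, and ichthyoplankton restricted to spring. Where the design
needed numbers that no source states (per-taxon abundances, length
spreads, allometric truth coefficients), values were chosen once to give
realistic areal biomasses (hundreds to thousands of mg DW/m²) and
individual weights (10⁻⁴–2 mg), and are not tuned thereafter.

What the generator does **not** emulate: advection and patchiness
(counts are independent Poisson), vertical migration or depth
stratification, taxonomic misassignment, drying-time variation, or
taxon-specific formalin loss. Passing recovery tests therefore show that
the arithmetic chain inverts the observation model it assumes — not that
the model captures every property of field data.

## Numerical and testing choices

- Masses are mg and lengths µm everywhere; unit conversion happens only
  inside allometric formula evaluation (mm/µm, mg/µg per formula).
- Taxon names match case-insensitively after whitespace normalization;
  unknown taxa are carried through with missing factors and a warning.
- Monte-Carlo problem sizes: 200 replicate surveys of a trimmed scenario
  (2 stations × 4 events × 5 taxon/stage combinations) for parameter
  recovery, where the per-taxon median relative error stays within ±5%;
  200 pure-noise matrices at the study size (24 samples × 28 taxa) for
  the variation-partitioning null, where all adjusted fractions stay
  ≤ 0.05 in at least 95% of replicates; 100 random instances (n ≤ 7) for
  the clustering oracle equivalence against independent reference
  implementations.
- The cluster-number suggestion, the SCA flags and the method selection
  are all reported with their underlying diagnostics rather than as bare
  answers, mirroring how these decisions are made in applied work.

## Limitations

- The reliability filter interacts with the censored error model near the
  threshold; biomass of rare, light taxa is structurally unmeasurable by
  this design (that is what the filter encodes), so community matrices
  systematically lack them.
- Capture efficiency below ~500 µm makes the SMZ submatrix
  semi-quantitative by construction; analyses on it are comparative, not
  absolute.
- The allometry framework evaluates published formulas; it does not fit
  new length–weight regressions.
- Areal biomass is not normalized by tow depth; the depth-ratio helper
  (1 : 2 : 5.4 for 40/80/215 m) is provided for per-volume comparisons.
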