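---
title: "Methods: genomic prediction for soybean oil and protein content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic prediction for soybean oil and protein content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Genomic selection predicts the genetic merit of unphenotyped breeding
material from genome-wide markers. For soybean seed oil and protein
content — two strongly negatively correlated quantitative traits — a
practical question is whether the large public germplasm panels
(genotyped on a standard SNP array and phenotyped over many trials) can
serve as *training* populations for a breeder's own biparental
population, instead of phenotyping that population itself. The answer
hinges on population structure: public panels split into a cultivated
and a wild cluster, and the usefulness of a panel as a training set
decays with its genetic distance to the breeding population (BP).

`soypred` implements this study design end to end: a synthetic-data
generator standing in for the germplasm panels and the biparental
F\(_{2:6}\) RIL population, genotype QC, phenotype summarisation,
population-structure analysis, five whole-genome regression models, and
the cross-validation and sweep experiments that quantify how training-set
composition, size, and marker number drive prediction ability (PA,
the Pearson correlation between observed values or BLUEs and GEBVs).
The `analysis/` directory runs the whole workflow as numbered scripts.

## The synthetic study populations

The generator emulates the structure the analysis assumes, not soybean
biology in full:

* **Germplasm panels.** Six panels (A–D "cultivated", E–F "wild";
  default sizes 1007/607/965/811/508/243 scaled by 0.2 at desk scale)
  are produced by hierarchical Balding–Nichols drift: per-marker
  ancestral frequencies \(p \sim U(0.05, 0.95)\), a cluster-level Beta
  draw at \(F_{st}\) = `fst_between_cluster` (default 0.30), a
  panel-level draw at `fst_within_cluster` (default 0.05), then
  Hardy–Weinberg binomial genotypes within panel. This gives tunable,
  analytically checkable differentiation (the realized Hudson
  \(F_{st}\) between clusters matches the configured value within
  sampling error) and the two-cluster PCA/UPGMA geometry of real
  panels.
* **Breeding population.** Two fully inbred parents are drawn from
  cluster-I (panel A) allele frequencies, crossed, and advanced five
  selfing generations by single seed descent. Meiosis uses Haldane's
  map function (recombination probability \((1-e^{-2d/100})/2\) for an
  interval of \(d\) cM, no interference), chromosomes assort
  independently, and residual heterozygosity is retained (about
  \(2^{-5}\approx 3\%\) at F6, as in real F\(_{2:6}\) lines). A
  two-locus selfing Markov-chain enumeration serves as the exact oracle
  for recombinant-class frequencies in the tests.
* **Traits.** `n_qtl` markers (default 200) receive (oil, protein)
  effect pairs from a bivariate normal with correlation −0.7,
  reproducing the strong negative genetic correlation of the real
  traits; non-QTL markers have zero effects. Genetic values are
  rescaled to per-trait genetic SDs (1.0 for oil, 1.8 for protein, in %
  seed weight) and centred on the midparent means (oil 20.5, protein
  41), so simulated phenotypes live on a realistic scale; this
  anchoring is cosmetic and configurable.
* **Trial phenotypes.** Records follow
  \(Y_{ijk} = \mu + E_i + R_{j(i)} + G_k + GE_{ik} + \varepsilon_{ijk}\)
  with six environments (two years × three locations) and three
  replicates. Given a target line-mean broad-sense heritability
  \(h^2\) (default 0.9) and a G×E-to-genetic variance ratio (default
  0.1), the residual variance is solved from
  \(h^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{GE}/e +
  \sigma^2_\varepsilon/(re))\), so the realized ANOVA estimate is close
  to target by construction. Environment and replicate variances are
  cosmetic (they cancel from line means and from \(h^2\)). Germplasm
  panels get line-mean phenotypes at the same \(h^2\), which is how
  public descriptor data behave in practice.

### The condensed genetic map

Desk scale uses 2,000 markers where the real array delivers ~40,000.
Had we kept a full-length soybean map (~20 × 120 cM), simulated marker
density would be twenty times sparser than the real array, which
destroys the marker-redundancy regime responsible for the study's
central marker-number plateau. The default map is therefore condensed
to 20 chromosomes × 40 cM: markers per recombination segment stay in
the regime of the real data while a RIL genome still carries on the
order of 50–80 independently segregating segments. Both map length and
marker count are configurable; the spacing is uniform because the real
array's physical spacing carries no information the downstream analyses
use.

### What the generator does *not* emulate

Panel members are unrelated draws from panel frequencies: there is no
linkage disequilibrium, family structure, or selection history inside a
panel, and every causal locus is genotyped. Consequences, made explicit
because they shape the experiment designs below:

* Within-*panel* cross-validation has no close relatives to exploit, so
  its PA is lower than in real panels (which contain pedigree
  structure). The within- vs across-population contrast is therefore
  measured on the RIL family, where relatedness is real and strong —
  exactly the comparison the study itself reports (within-BP
  cross-validation vs panels→BP).
* Across populations, marker effects transfer perfectly (same causal
  loci, same effects, no LD phase to lose). The decline of PA with
  genetic distance is then carried by relatedness decay and by
  allele-frequency divergence (causal loci drifting out of segregation
  in the training panel), a weaker signal than in real data. The
  PA–distance experiment uses a wide four-level \(F_{st}\) gradient
  (0.05–0.8) of equally sized panels predicting the BP, and averages PA
  over three trait-architecture draws per seed, to give the slope
  adequate power over sampling noise.
* LD redundancy between markers exists only inside the RIL family
  (linkage blocks), not between panel members. The marker-number
  plateau is therefore measured by within-BP cross-validation; an
  across-population marker sweep under this generator rises roughly
  like the square root of the number of causal markers retained and
  never plateaus — a property of the LD-free design, not of the method.

Passing tests therefore demonstrate that the pipeline reproduces the
study's qualitative structure under a transparent generative model;
they do not certify PA magnitudes for real soybean panels, which depend
on LD and pedigree structure the generator deliberately omits.

## Genotype handling

Dosages are coded 0/1/2 copies of the **minor** allele, with the
orientation computed on the analysis cohort; at a frequency of exactly
0.5 the alphabetically first allele is kept as the reference, making
the coding deterministic. Cohorts are merged **before** filtering (the
combined set is what the study filtered): marker ids are intersected,
maps checked, cohort B re-oriented onto cohort A's allele labels, and
the minor-allele convention recomputed on the union — a marker can
legitimately flip orientation at this step. QC removes markers with
MAF < 5% or missingness > 10% (both thresholds exclusive on the
removal side: a marker at exactly the threshold survives). Missing
calls are then mean-imputed per marker; LD-aware imputation is out of
scope, and downstream models consume continuous dosages anyway.
Interchange formats are plain-text VCF v4.2 (GT only) and a
sample-by-marker dosage TSV.

## Phenotype summarisation

BLUEs per line are least-squares adjusted means from
\(Y = \mu + E + R(E) + G + \varepsilon\) (prediction averaged over
every environment × replicate cell); for balanced data this equals the
mixed-model BLUE with random environment terms, and degenerate designs
(one environment, one replicate) reduce to the raw record. Variance
components come from the balanced two-way ANOVA by method of moments
(\(\sigma^2_\varepsilon = MS_{err}\), \(\sigma^2_{GE} = (MS_{GE} -
MS_{err})/r\), \(\sigma^2_G = (MS_G - MS_{GE})/(re)\)), truncated at
zero with a warning; unbalanced data fall back to Type-I sums of
squares with a warning rather than REML, because every design in this
workflow is balanced. Broad-sense heritability uses
\(h^2 = \sigma^2_G/(\sigma^2_G + \sigma^2_{GE}/e +
\sigma^2_\varepsilon/(re))\); on mean squares this reduces
algebraically to \((MS_G - MS_{GE})/MS_G\), independent of \(r\) and
\(e\), and both code paths are computed and asserted equal. The trial
literature is ambiguous about the replicate count (two vs three); `r`
is an explicit input everywhere, defaulting to 3 in simulation
configurations — the mean-square route makes \(h^2\) invariant to the
choice.

## Population structure

PCA operates on column-centred dosages without unit-variance scaling
(the common convention for SNP data). Genetic distance is plain
Euclidean distance on 0/1/2 dosages; group-to-group distance is the
mean over all between-group pairs — the aggregation is symmetric,
robust to group size, and a centroid variant is provided
(`group_centroid_distance`) since published group distances rarely
state their aggregation rule. Clustering is UPGMA
(`hclust(method = "average")`), exported as an `ape` tree whose edge
lengths are merge-height differences, so ultrametric input is
reproduced exactly. Training-set optimisation ranks candidates by mean
distance to the BP (ascending, ties broken by sample id), and size
sweeps train on nested prefixes of that ranking.

## Whole-genome regression

* **GRM**: VanRaden method 1, \(G = ZZ'/c\), \(Z = X - 2p\),
  \(c = 2\sum_j p_j(1-p_j)\), with centering frequencies from the joint
  train+test cohort by default (one merged marker set serves both
  populations); training-only frequencies can be supplied. Monomorphic
  markers are dropped with a warning.
* **G-BLUP** is fitted by exact REML: the restricted likelihood of
  \(y = 1\mu + g + \varepsilon\), \(g \sim N(0, \sigma^2_g G)\), is
  profiled over \(\delta = \sigma^2_e/\sigma^2_g\) on the
  eigendecomposition of the training block (computed once) and
  minimised by one-dimensional search on \(\log\delta \in
  [\log 10^{-8}, \log 10^{8}]\) (tolerance \(10^{-10}\); hits on the
  boundary are flagged). GEBVs for all samples follow from the BLUP
  conditional expectation. A zero-variance response short-circuits to
  the boundary with equal GEBVs.
* **RR-BLUP** shares the same REML core through the equivalent kernel
  \(ZZ'\) and recovers marker effects as \(\hat\beta = \sigma^2_\beta
  Z'V^{-1}(y - 1\hat\mu)\). With matched kernels
  (\(\sigma^2_g = c\,\sigma^2_\beta\)) it is algebraically identical to
  G-BLUP; the test suite asserts max-abs GEBV agreement to \(10^{-6}\)
  on held-in and held-out samples — the central algebraic oracle of the
  module.
* **BRR / BL / BayesB** are single-chain Gibbs samplers (Rcpp, R's RNG,
  so chains are bit-reproducible from the seed; default 10,000
  iterations, 2,000 burn-in, no thinning). Priors follow community
  defaults: scaled-inverse-\(\chi^2\) variances with df 5 and scales
  from the heuristic that half the phenotypic variance is genetic;
  the Bayesian LASSO uses the exponential–inverse-Gaussian
  Park–Casella hierarchy with \(\lambda^2 \sim\) Gamma(shape 1.1, rate
  matching the same heuristic at the prior mode); BayesB uses a
  spike-and-slab with marker-specific slab variances (heuristic scale
  divided by the prior inclusion probability) and
  \(\pi \sim\) Beta(2, 2). Posterior means are Rao-Blackwellised (the
  full-conditional mean is averaged rather than the draw), which cuts
  Monte-Carlo error enough that 2,000-iteration chains match the
  closed-form ridge solution to correlation ≥ 0.999 when variances are
  frozen at truth. Cross-validation sweeps may use such reduced chains
  (a logged message notes it); single fits default to the full chain.
* **Prediction** for new cohorts centres new dosages with the
  *training* frequencies stored in the fit — never the new cohort's own
  — and G-BLUP predictions go through \(G_{new,train}\) built from
  stored training genotypes. Fits serialise to JSON and predictions are
  reproducible bit-for-bit from the file.

## Experiment designs

Fold assignment in k-fold cross-validation is a seeded permutation cut
into contiguous blocks (sizes differing by at most one), and PA is
averaged over folds, as the study describes. Across-population
prediction fits once on the full training set and reports a single PA.
The composition sweep evaluates each panel singly plus the nested
prefixes of the distance ordering (A, AB, ABC, …); the size sweep uses
distance-ranked nested subsets; the marker sweep redraws uniform random
marker subsets (`n_repeats` default 100, reduced to 20 in the desk
workflow) and reports mean ± SE (sample SD / \(\sqrt{n}\)). Observed
values for the BP are its BLUEs across environments — the
better-defined target where the source design allows either raw values
or BLUEs.

## Problem sizes used by the default workflow and tests

The shipped analysis runs at desk scale: panels scaled ×0.2
(828 accessions), 2,000 markers on the condensed map, a 175-line BP,
ten-fold cross-validation, 20 marker-subset repeats; the full test
suite completes in a few minutes and the end-to-end workflow in about
three. Full-scale settings (scale = 1, ~40k markers, 100 repeats)
are supported through the same configuration objects.

## Known limitations

* No linkage disequilibrium or family structure within germplasm
  panels, and no untyped causal loci — see the generator section for
  how the experiment designs compensate.
* Variance components by balanced-ANOVA moments, not REML; severely
  unbalanced trials are out of scope.
* Single-trait models only; the negative oil–protein correlation is in
  the data, not in the predictors. Epistasis and G×E prediction models
  are out of scope.
* Mean imputation ignores LD; at the simulated missingness (≤ 10%) the
  effect on the GRM is negligible.
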