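---
title: "Linkage mapping, IBD reconstruction and multi-allelic QTL analysis in polysomic hexaploids"
author: "HexaMapQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage mapping, IBD reconstruction and multi-allelic QTL analysis in polysomic hexaploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HexaMapQTL)
```

# Scope and model

HexaMapQTL targets bi-parental F1 populations of an even-ploidy species
with *polysomic* inheritance — all homologous chromosomes pair at random
as bivalents at meiosis, as in hexaploid chrysanthemum or sweet potato.
Everything below is ploidy-general; the defaults and all validation
studies use ploidy 6.

Three model assumptions run through the whole package:

* **Random bivalent pairing.** A tetraploid has
  `r length(enumerateBivalentPairings(4))` ways of pairing its
  homologues into bivalents; a hexaploid has
  `r length(enumerateBivalentPairings(6))` perfect matchings of its six
  homologues, each equally likely.
  Multivalents, preferential pairing and double reduction are not
  modelled — species with frequent quadrivalents will violate the
  segregation expectations.
* **No crossover interference.** Crossovers are a Poisson process on
  genetic length, so Haldane's function `r = (1 - exp(-2d))/2` converts
  map distance to recombination fraction throughout.
* **Known parental dosages.** Marker dosages of both parents are input
  data (`P1`, `P2` columns of the dosage file); non-missing progeny
  dosages are integers in `0..ploidy`.

Under these assumptions a parent of dosage $d$ transmits $k$ allele
copies with hypergeometric probability
$\binom{d}{k}\binom{p-d}{p/2-k}/\binom{p}{p/2}$, and the F1 dosage
distribution is the convolution over both parents
(`offspringDosageDistribution()`). The segregation chi-square test,
selfing detection (dosages impossible under the cross at more than 2% of
a plant's markers) and the skewness filter all derive from it.

# The pairwise likelihood engine

For two linked loci of one parent, a phase up to homologue relabelling
is the number $s$ of homologues carrying both marker alleles
("shared count", coupling when $s>0$). Given a bivalent
$\{i,j\}$, the transmitted product carries homologue $i$ at both loci
with probability $(1-r)/2$ and $i$ at the first locus with $j$ at the
second with probability $r/2$. Averaging the per-bivalent convolution
over all matchings yields the joint gamete dosage distribution
(`twoLocusGameteDistribution()`); the offspring distribution is the
convolution over the two parents, and the multinomial likelihood of the
observed joint dosage counts is maximized over all phase pairs and an
$r$ grid (step 0.005, golden-section refinement in `estimatePair()`;
grid only in the batched `pairwiseLinkage()`). This replaces a catalogue
of closed-form likelihood functions per segregation-type pair with one
numerical engine; unit tests verify it cell-by-cell against brute-force
enumeration of all pairings × transmissions.

**The null at r = 0.5.** The per-bivalent model retains a subtle
dependence between two same-chromosome loci even at $r=0.5$ when both
dosages exceed one (the bivalent partition correlates the transmitted
counts), and at ploidy 6 that residual dependence differs between
phases. A LOD computed against such a baseline would be phase-dependent
and non-zero in expectation for unlinked pairs. We therefore define
$r=0.5$ as the *independence* null — the product of the two single-locus
distributions — which is what "unlinked" means for markers on different
chromosomes and is phase-free by construction. For simplex markers (the
backbone of the map) the bivalent model already factorizes at 0.5, so
the convention only affects higher-dose pairs near the null.

Repulsion-phase estimates between simplex markers are retained but
carry very little information at this ploidy — the validation suite
shows their sampling variance is more than twice that of coupling
estimates at $n=400$ — which is why all clustering and phasing decisions
below use coupling linkages only.

# Map assembly

* **Backbone**: connected components (single linkage) of the graph on
  each parent's simplex markers with edges at LOD ≥ 10 in coupling.
  Components smaller than 5 markers are excluded from mapping. With
  adequate marker coverage the used clusters are exactly one per
  homologue per chromosome.
* **CLG**: each 1×1 marker is attached to its best coupling-linked
  cluster per parent (most qualifying links at LOD ≥ 5; ties are logged
  and skipped), which associates parent-1 with parent-2 clusters;
  transitive closure of these associations yields the chromosomal
  linkage groups. 1×1 markers are the bridge type because they are
  abundant and link both parents directly; duplex bridging would only
  connect clusters within one parent. The attachment LOD (5) matches the
  assignment threshold for consistency; the clustering LOD (10) is
  deliberately stricter because false backbone merges are irreparable
  downstream.
* **Assignment and phasing**: every remaining marker joins the CLG with
  the most coupling linkages (LOD > 5) to used backbone markers, and
  each allele is placed on the homologue showing at least 5 such
  linkages. A marker whose number of placed alleles differs from its
  parental dosage in either parent stays in the map unphased. CLG are
  numbered by descending backbone-marker count.

# Ordering

Within a CLG, pairwise estimates become distances via Haldane's inverse
(capped at $r=0.49$) with LOD² weights, are embedded in two dimensions
by weighted stress majorization (deterministic classical-scaling start),
and a principal curve — iterated local averaging with a fixed lowess
span of 0.25, refined by a one-dimensional weighted stress polish —
fixes the marker *order*. Positions then come from weighted
least-squares estimation of the adjacent gaps against all pairwise
distances within 20 cM: with the order fixed this is a convex problem
whose normal equations have closed form via two-dimensional cumulative
sums, and the solution is projected onto monotone positions. We
initially used the curve's arc length directly as position, but arc
length systematically stretched map ends and smoothed away true zero
gaps between co-located markers, inflating nearest-marker distances for
the IBD step; the gap least squares reproduces local pairwise distances
essentially unbiasedly while inheriting the curve's global order.

The per-marker **nearest-neighbour fit** is the LOD²-weighted mean
absolute difference (cM) between map distance and pairwise distance over
the marker's 10 nearest *informative* map neighbours (zero-weight pairs,
e.g. between the two parents' simplex markers, are skipped). A raw sum
over a fixed neighbour count would scale with marker density and make a
fixed threshold meaningless; the weighted mean keeps the threshold of
4 cM interpretable as "this marker's local distances are off by more
than 4 cM". Ordering is repeated with markers above the threshold
removed while the total fit decreases. Orientation is deterministic: the
alphabetically first marker lies in the left map half, the leftmost
marker at 0 cM. Markers binned as duplicates re-enter at their
representative's position after ordering.

The same-contig diagnostic (`sameContigRMSE()`) computes the RMSE of
position differences between simplex markers from one transcript contig,
split by same- versus different-homologue phasing; the latter measures
the quality of homologue integration, which relies on the weaker
higher-dose linkages.

# IBD probabilities

Only *fully informative* dosages seed the array: progeny dosage 0 pins
every carrier homologue of the marker to probability 0, dosage equal to
the summed parental dosage pins them to 1 (for a 1×1 marker, dosages 0
and 2 are informative, 1 is not). Every other locus on a homologue takes
$1-r$ or $r$ from the nearest informative marker of that homologue and
individual, with $r$ from Haldane's function on the integrated map.
Flanking informative markers equidistant within 1 cM count as tied and
their implied probabilities are averaged — exact ties essentially never
occur on an estimated map, and a strict one-sided choice is
overconfident whenever positions carry small errors.

**Normalization.** Each parent's six probabilities must sum to 3 at
every locus (three homologues per gamete). We apply a common additive
shift on the log-odds scale, solved by bisection per locus and
individual. A multiplicative rescale — the obvious alternative — drags
pinned values off 0/1 and provably miscalibrates the uncertain ones:
with two homologues pinned at 1 and four at the 0.5 prior it yields
0.375 each, although exactly one of the four is the carrier (rate 0.25);
the log-odds shift returns 0.25. In the pipeline recovery study the
multiplicative version deviated by up to 0.17 in the mid-probability
bins, the log-odds version stays within ±0.05. Homologues with no
markers at all are recovered through this normalization from the other
five.

A natural cubic spline per homologue and individual (linear fallback
below 4 loci) interpolates to 1 cM intervals; values are clamped to
[0, 1] and re-normalized, since clamping slightly perturbs the sums.
Genotype information content per homologue and interval,
$GIC = 1 - \tfrac{2}{n}\sum_i |P_i - \lfloor P_i \rceil|$ with 0.5
rounding down, is 1 at fully informative loci and 0 where all
probabilities are 0.5; it is characteristically lower towards chromosome
ends, where informative markers flank only one side.

This single-marker ("nearest informative") method is deliberately
simple; hidden-Markov multipoint methods would extract more information
from partially informative dosages but are out of scope.

# QTL analysis

At each 1 cM locus the block-corrected phenotype is regressed on the IBD
probabilities of ten homologues — the first homologue of each parent is
the reference class, since every individual inherits exactly three per
parent, making the full twelve-column design singular. The locus
statistic is the overall model-versus-intercept F test (the model
p-value); rank-deficient designs (an empty homologue) are fitted on the
reduced column space and flagged. Genome-wide significance uses the
permutation approach: phenotypes are shuffled across individuals, the
minimum p-value of each permuted genome scan is recorded, and the 5th
percentile of 1000 such minima is the threshold. Per-allele effects come
from twelve separate simple regressions $Y = \mu + \alpha_i X_i$, where
$\hat\alpha_i$ estimates the effect of full presence versus absence of
homologue $i$. Interaction scans are intentionally absent: a full
genotype-class model would need $\binom{6}{3}^2 = 400$ parameters — an
over-fitting machine at any realistic population size; a targeted
two-locus interaction ANOVA (`interactionTest()`) covers the
complementary-allele case. Heritability uses the classical
trial-plus-genotype fixed-effects ANOVA, $H^2 = \sigma_g^2 /
(\sigma_g^2 + \sigma_e^2)$ with $\sigma_g^2 = (MS_G - MS_E)/r$ —
the genotypic share of phenotypic variance after removing the fixed
trial effect.

# The simulator, and what passing tests do and do not show

`designCross()` + `simulateF1()` emulate the study conditions the
package targets: a hexaploid F1 of 400 individuals, chromosomes of
~84–90 cM, abundant simplex markers (the default lays out 60 per
homologue in validation studies), plus duplex and 1×1 markers, with
optional missing-data and dosage-error injection and optional co-located
same-contig marker pairs (offset by 0.5 cM so that same-homologue twins
are not exact duplicates in noise-free data). The simulator draws
pairings uniformly, places crossovers as a Poisson process and records
the full inheritance truth per individual, marker and 1 cM grid point.

It does *not* emulate: dosage-calling error structure of real SNP
arrays (errors are resampled from the offspring distribution,
uncorrelated across markers), segregation distortion, multivalent
pairing or double reduction, varying marker informativeness along the
genome, or population structure. Passing recovery tests therefore shows
the algorithms are correct and well calibrated *under the stated model*,
not that real array data will reach the same accuracy.

Validation studies shipped with the package (also used by
`scripts/acceptance.R`):

* `pairRecoveryStudy()` — 200 replicate n = 400 populations; mean
  $\hat r$ within ±0.02 of the true 0.1 and ≥95% coupling-phase
  recovery.
* `pipelineRecoveryStudy()` — a two-chromosome population (60 simplex
  markers per homologue, n = 400): 12 backbone clusters per parent, 2
  CLG, Kendall tau ≥ 0.95 per CLG, ≥99% phasing accuracy, map length
  within 15%, IBD probabilities calibrated within ±0.1 per decile bin,
  median $|r_{pairwise} - r_{map}|$ ≤ 0.03 at LOD ≥ 20, same-homologue
  contig RMSE below the different-homologue RMSE, and higher GIC
  mid-chromosome than at the ends.
* `qtlCalibrationStudy()` — genome-wide type-I error 5% ± 3% under
  permutation thresholds (200 null replicates × 200 permutations at
  desk scale instead of 1000), and ≥90% of replicates placing the scan
  peak within 5 cM of a QTL explaining 20% of the variance.

Problem sizes in the test-suite versions of these studies (population
sizes of 250–400, two chromosomes, 200 replicates) are the package's
chosen validation scale; they complete in minutes on a single CPU.

# Numerical choices and degenerate inputs

* r grid step 0.005 with golden-section refinement; phase ties within
  1e-9 log-likelihood prefer the larger shared count (more coupling) —
  ties occur at $\hat r \approx 0.5$ where phase is meaningless.
* Pairs with fewer than 20 jointly scored progeny are not estimated;
  a marker with all progeny missing fails the segregation test
  explicitly; a constant phenotype or a sub-30 phenotype/IBD overlap is
  rejected with a clear error; disconnected linkage input to
  `orderCLG()` asks the user to re-cluster.
* Observed dosage cells with zero model probability give a −∞
  log-likelihood (impossible phase), an infinite chi-square (impossible
  segregation) or a data-inconsistency flag (IBD step), never silent
  acceptance.
* All stochastic steps thread a single seed; reruns with the same seed
  are bit-identical.

# Known limitations

* No double reduction or multivalent model — in taxa with appreciable
  quadrivalent frequency, segregation tests will over-reject and
  distances will be biased.
* IBD reconstruction uses only fully informative dosages; long runs of
  higher-dose markers contribute little and GIC drops accordingly.
* The permutation threshold assumes exchangeable individuals (no family
  or spatial structure beyond the block correction of the input
  phenotypes).
* Ordering quality degrades on sparse maps (few markers per homologue),
  where the weighted MDS has little high-LOD information to work with;
  the nearest-neighbour-fit removal then trims map ends first.
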