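# HexaMapQTL

Integrated linkage mapping, haplotype reconstruction and multi-allelic QTL
analysis for polysomic hexaploids.

## The problem

In an outcrossing autopolyploid such as hexaploid chrysanthemum
(2n = 6x), a bi-allelic SNP locus has seven possible dosage scores (0–6),
a parent transmits three of its six homologous chromosomes per gamete,
and homologues pair at meiosis in any of fifteen bivalent configurations.
Classical diploid mapping software cannot estimate recombination between
such markers, and maps built from single-dose markers alone describe
individual homologues rather than chromosomes. Yet a QTL in an F1 of two
hexaploid parents can be driven by any of the twelve parental alleles at
a locus, so trait analysis needs the probability that each parental
homologue was inherited by each offspring — which requires a fully
integrated and *phased* map.

HexaMapQTL implements the complete chain for a bi-parental F1 population
at any even ploidy (defaults are hexaploid):

1. **Dosage QC** — segregation chi-square tests against the polysomic
   expectation (gamete dosages are hypergeometric:
   `P(k) = C(d,k) C(p−d, p/2−k) / C(p, p/2)`), missingness and skewness
   filters, selfing detection, duplicate-marker binning.
2. **Pairwise linkage** — a single generic maximum-likelihood engine for
   the recombination fraction `r`, LOD and phase of *any* marker-type
   pair under completely random bivalent pairing. Phases are summarized
   by the number of homologues carrying both alleles per parent
   ("shared count"; coupling = shared > 0). The joint transmission
   distribution is built numerically from the pairing model, so no
   per-type formula catalogue is needed. `r = 0.5` is the independence
   null, making LOD = 0 for unlinked pairs and phase-free at the null.
3. **Map assembly** — homologue backbone clusters from coupling-linked
   simplex (1×0 / 0×1) markers at LOD ≥ 10, chromosomal linkage groups
   (CLG) bridged by 1×1 markers, then assignment and phasing of all
   marker types via ≥ 5 coupling linkages at LOD > 5.
4. **Ordering** — weighted multidimensional scaling (stress
   majorization, LOD² weights) of Haldane-transformed `r` values,
   principal-curve projection for the order, weighted least-squares gap
   estimation for positions, and iterative removal of markers with a
   nearest-neighbour fit above 4 cM.
5. **IBD probabilities** — per offspring and homologue along each CLG:
   fully informative dosages pin probabilities to 0/1, other loci take
   `1 − r` or `r` from the nearest informative marker (Haldane), each
   parent's six homologues are normalized to sum to 3, a natural cubic
   spline grids everything at 1 cM, and genotype information content
   `GIC = 1 − (2/n) Σ |P_i − ⌊P_i⌉|` summarizes per-locus information.
6. **QTL** — at each grid locus the additive model
   `Y = µ + α₂X₂ + … + α₆X₆ + α₈X₈ + … + α₁₂X₁₂` (homologues 1 and 7 are
   reference classes) with an overall F test, 1000-permutation
   genome-wide thresholds, per-allele effect decomposition, variance
   explained, heritability from a trial × genotype ANOVA, and a
   two-locus interaction test.

A ploidy-general meiosis simulator (uniform bivalent pairings, Poisson
crossovers / Haldane model, no double reduction) generates populations
with known phase and inheritance truth; every stage is validated against
it.

## Worked example

```r
library(HexaMapQTL)

gameteDosageDistribution(6, 3)      # a triplex parent transmits 0..3 copies
#>    0    1    2    3
#> 0.05 0.45 0.45 0.05

set.seed(42)
des <- designCross(nChrom = 2, chromLength = 80, simplexPerHomologue = 20,
                   duplexPerChrom = 20, simplexSimplexPerChrom = 30)
sim <- simulateF1(des, nInd = 400, seed = 42)
sim$dosage
#> DosageMatrix (ploidy 6): 580 markers x 400 individuals
#>   marker types: 0x1 (240), 1x0 (240), 1x1 (60), 0x2 (20), 2x0 (20)
#>   missing calls: 0.00%

res <- runPipeline(dosage = sim$dosage, config = runConfig(seed = 42))
#> input: 580 markers x 400 individuals
#> after filtering: 580 markers, 400 individuals (removed 0 markers, 0 individuals)
#> duplicate binning: 548 unique of 580 markers
#> backbone: 12/12 clusters (P1, P2) from 224/225 used simplex markers
#> CLG: 2 groups; 0 ambiguous bridge markers
#> assigned 548 / 548 unique markers; 548 phased
#> CLG 1: 264 markers ordered over 76.3 cM (4 rounds, 13 removed)
#> CLG 2: 258 markers ordered over 84.5 cM (5 rounds, 13 removed)
#> integrated map: 550 markers (522 unique) on 2 CLG
```

The log mirrors the mapping funnel: all 548 unique markers phase cleanly
(the simulation is noise-free), the twelve backbone clusters per parent
are the 2 chromosomes × 6 homologues, and each CLG's map length is close
to the simulated 80 cM. Scoring the result against the simulator's truth
gives Kendall rank correlations of 0.949 and 0.956 between estimated and
true marker orders. `res$ibdGrid` holds the 1 cM IBD probability arrays
(loci × 400 individuals × 12 homologues per CLG) that feed `qtlScan()`,
`permutationThreshold()` and `perAlleleEffects()`.

A thin command-line front end (`inst/scripts/hexmap.R`) exposes the same
stages as subcommands (`simulate`, `filter`, `linkage`, `cluster`,
`order`, `ibd`, `qtl`, `pipeline`).

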