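---
title: "Methods: RRBS differential methylation, DMR tiling, enrichment and Bliss synergy"
author: "methylsynergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RRBS differential methylation, DMR tiling, enrichment and Bliss synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylsynergy)
library(data.table)
```

## Scope and model

methylsynergy implements the downstream analysis of a multi-group reduced
representation bisulfite sequencing (RRBS) experiment -- the kind of design
used to profile drug-induced methylome remodeling in *Pkd1*-heterozygous
renal epithelial cells (a vehicle control plus several treatment arms, three
biological replicates each) -- together with Bliss-independence scoring of
the matching drug-combination viability plates.

The analysis chain is: per-cytosine call files are read (Bismark
cytosine-report or coverage dialect), opposite-strand calls of each CpG
dinucleotide are merged (methylation is symmetric across strands, so the
minus-strand call at position p+1 belongs to the plus-strand CpG at p),
replicates are united into group-level count matrices keeping CpGs covered
at >= 5x in at least 2 of 3 replicates, differentially methylated cytosines
(DMCs) are called per treatment-vs-control comparison, chained into
differentially methylated regions (DMRs), and the regions are characterized
by odds-ratio enrichment against genomic feature tracks, TSS-distance bins,
5-kb feature-centered methylation profiles, and basal-plus-extension gene
association.

## Per-CpG test

For CpG $i$ with pooled methylated/unmethylated counts $(M_t, U_t)$ in
treatment and $(M_c, U_c)$ in control, the methylation difference is the
coverage-weighted contrast in percentage points,

$$\Delta_i \;=\; 100\left(\frac{M_t}{M_t+U_t} - \frac{M_c}{M_c+U_c}\right),$$

and the default test is a binomial logistic likelihood-ratio test (1 df):
the per-replicate counts are modeled as binomial with a logit-linear group
term, and the model with the term is compared to the pooled-null model. The
group-only model's sufficient statistics are the pooled group counts, so the
likelihood ratio has a closed form which the implementation evaluates
vectorized over all CpGs; a test asserts exact agreement with
`glm(cbind(m, u) ~ group, binomial)` plus `anova(..., test = "LRT")`. A
pooled two-sided Fisher exact test (`fisher_pooled`) is available for
1-vs-1 designs. q-values are Benjamini-Hochberg over all tested CpGs; the
original replicate-aware caller's default q-value method (SLIM) is not
fully specified in the literature we reimplement from, and BH is the
standard, documented choice -- exact DMC counts from the original pipeline
may therefore differ slightly.

A CpG is a DMC when $|\Delta_i| \ge 35$ percentage points (inclusive -- the
cutoff is read as "at or beyond") **and** $q_i < 0.01$ (strict). Direction
is *hyper* iff $\Delta_i > 0$ (methylation gained under treatment).

The model assumes binomial sampling within replicates and no extra-binomial
overdispersion; covariate adjustment is out of scope. With discrete counts
at RRBS-typical depth the LRT is mildly conservative (null rejection just
above 4% at $\alpha = 0.05$ with the default simulator settings), which the
calibration test quantifies.

## DMR tiling

DMCs on one chromosome are chained single-linkage: consecutive DMCs at
most 500 bp apart (inclusive -- the rule describes neighbor distance, not
tile diameter) join one tile. A raw tile spans its outermost member CpGs,
counting both ends, so $k$ CpGs spanning $s..e$ (1-based) give a tile of
width $e - s + 1$. Tiles narrower than 100 bp are extended symmetrically to
100 bp; an odd remainder puts the extra base on the right (the rule's
source is silent on the remainder; fixing it right keeps output
deterministic), and extension clips at position 0. Tiles whose members mix
hyper- and hypomethylation are ambiguous and removed (their fraction is
reported); the region summary is the unweighted mean of member CpG
differences. All region coordinates are emitted 0-based half-open (BED
convention); call files stay 1-based, and the converters between the two
are explicit.

Cross-comparison Venn counts are computed on the union of 2-3 same-direction
DMR sets: connected components under strict >= 1 bp overlap (adjacency does
not connect), each component labeled with the set of comparisons
contributing at least one tile. Components give symmetric, input-order-free
counts; the alternative of counting each comparison's DMRs separately is
not distinguishable from the published totals, and components were chosen
for their symmetry.

## Enrichment

For a DMR set and a feature track, every CpG of the background universe
(the united, filtered CpG set of the control group by default, matching the
background used for motif analysis in this kind of study) is classified
into the 2x2 table *a* (in DMR, in feature), *b* (in DMR, out), *c* (out,
in), *d* (out, out). The odds ratio is $(a/c)/(b/d) = ad/bc$, reported with
its natural logarithm; when $bc = 0$ the OR is flagged infinite (or
undefined when $ad = 0$ too) rather than continuity-corrected, preserving
the plain-OR convention. Significance is the two-sided Fisher exact test,
implemented as hypergeometric tail summation (all tables no more likely
than the observed one, with the conventional 1e-7 relative tie tolerance);
an exhaustive enumeration oracle verifies it exactly on every table with
total at most 40.

TSS-distance enrichment assigns each universe CpG the unsigned, strand-blind
distance to its nearest TSS and computes one OR per distance bin. Default
bin edges are 0, 1 kb, 5 kb, 10 kb, 50 kb, 100 kb with an open final bin;
the published figure highlights "within 1 kb" and "10-50 kb" but does not
print its full edge list, so these edges are the package's fixed choice.
Promoters are 2 kb upstream to 500 bp downstream of the TSS, strand-aware,
clipped at chromosome bounds; intergenic tracks come from half-open interval
subtraction of flattened gene bodies from the genome.

## Profiles

Global summaries are coverage-weighted: mean methylation is
$100\,\Sigma m / \Sigma(\mathrm{cov})$ over all retained CpGs and present
samples. Histograms use left-closed bins with the right edge of the last
bin closed, and report the fractions below 5% and above 95% methylation as
a bimodality proxy.

Feature-centered profiles lay a 5-kb window over each feature's midpoint
(rounded down -- wide features need a defined anchor), flip minus-strand
features so negative offsets are upstream, and report per-bin
coverage-weighted mean methylation pooled over features (50 bins of 100 bp
by default, balancing resolution against per-bin noise). The presentation
curve is a cubic smoothing spline over the bin means; the published curves
use a generalized-additive-model smoother, but the smoother is a plotting
device, so assertions are made on the raw bin means only and the spline is
merely required to stay within the bin-mean range (5-point tolerance).
Whether the original profiles pooled replicates or averaged per-sample
curves is not stated; this implementation pools counts, which weights
samples by coverage.

## Gene association

Genes receive a basal regulatory domain 5 kb upstream / 1 kb downstream of
the TSS (strand-aware), extended in both directions up to 1 Mb or until the
nearest neighboring gene's basal domain -- the documented defaults of the
standard region-to-gene association tool, which the source methods invoke
as "default parameters". Note that two neighboring genes' extensions both
cover the intergenic gap between their basal domains, so a region between
two genes associates with both; this is the tool's documented behavior, and
the package keeps it rather than inventing a partition of the gap. A DMR is
associated with every gene whose domain it overlaps by >= 1 bp.

Associated genes are partitioned by whether any of their DMRs overlaps
their own promoter by >= 1 bp (counting genes, not DMRs; the figure being
emulated is ambiguous between the two, and gene counting matches its
"genes ... that contain a DMR" phrasing). The "top n most hypomethylated"
selection (default 8000) sorts ascending by mean difference with
deterministic (chrom, start) tie-breaks. Cancer roles from a
citation-count table follow the majority rule: more oncogene citations ->
Oncogene, more tumor-suppressor citations -> Tumor Suppressor Gene, equal
and positive -> the dual label, no citations -> Neither (a gene nobody has
characterized is not "both").

## Bliss synergy

For each replicate set, expected combination viability under independence
is the product of the single-drug viabilities, $V_e = V_A V_B$ (fractions
normalized to control); the synergy score is the mean over retained
replicates of $\delta = V_e - V_{\mathrm{obs}}$, and the combination is
synergistic iff the mean is positive. Replicate sets with outlying controls
are excluded first: a control is outlying when it deviates >= 3 SD from the
mean control viability, with mean and sample SD computed leave-one-out over
the other replicates' controls. The leave-one-out form is a deliberate
choice: with the candidate included, the largest standardized deviation
among $n$ points is $(n-1)/\sqrt{n}$, below 3 for $n \le 9$, so an
include-the-candidate reading could never exclude anything at plate-scale
replicate counts and the published rule would be vacuous. Whether the
original 3-SD rule pooled controls across concentrations is unknown; the
package applies it per plate table.

## The synthetic cohort generator

The generator exists so that every stage is testable offline with known
ground truth. Its defaults are the frozen study conditions:

* 4 groups (vehicle control + three treatment arms) x 3 replicates;
* 2 x 10^5 CpG sites placed uniformly over 2 x 25 Mb chromosomes;
* baseline per-CpG methylation from a two-component beta mixture, weights
  (0.45, 0.55), low mode Beta(0.5, 10), high mode Beta(10, 0.5) -- a
  bimodal, somatic-style landscape in which well over half of CpGs sit
  below 5% or above 95% methylation;
* 100 planted non-overlapping 2-kb regions with effects of 40-60
  percentage points (hypomethylation by default), applied to all treatment
  arms; control-side baselines inside planted hypo regions are drawn from
  the high mixture component (hyper regions from the low one) so the
  planted shift is realizable -- biologically, drug-induced
  hypomethylation happens at methylated loci;
* per-sample coverage negative binomial with mean 30 and size 5, plus 5%
  dropout. The mean was fixed at design time from the calibration behavior
  of the pooled LRT across plausible RRBS depths (at 20x the discrete
  counts leave the null rejection rate just under 4%, at 30x just above)
  and is a realistic depth for libraries capturing millions of CpGs at
  >= 5x;
* viability plates with single-drug truths 0.6 and 0.5, optional planted
  synergy $\varepsilon$ (observed combo = $V_AV_B - \varepsilon$ + noise),
  Gaussian noise SD 0.05, and optional planted control outliers.

Every generator is a pure function of its seed (via an isolated RNG scope),
so cohorts, annotations and plates are byte-reproducible. The generator
emulates the *structure* of RRBS data -- bimodality, coverage dispersion,
dropout, replicate designs, regional effects -- but not CpG-density
clustering of restriction fragments, bisulfite conversion failure,
mapping bias, or correlated neighboring-CpG methylation. Tests passing on
synthetic cohorts therefore validate the pipeline's arithmetic and
statistical behavior, not the biology of any particular dataset.

## Problem sizes and verification

The test suite exercises: boundary semantics of the DMC gate on constructed
tables; 500+ random DMC layouts against a brute-force union-find tiling
oracle; every 2x2 table with total <= 40 against exact Fisher enumeration;
null calibration and planted-region recovery on cohorts of 2 x 10^5 CpGs
(3v3, the recovery run at 20x coverage); Bliss null behavior at 10^4
replicates and planted-synergy recovery at 100; and exactness of profiles
on constant methylomes. These sizes make the full suite run in well under a
minute while leaving Monte-Carlo error far below the tested tolerances.
`scripts/acceptance.R` re-runs the same computations from scratch at the
same sizes and writes the resulting quantities as JSON.

## Known limitations

* No overdispersion (beta-binomial) correction in the per-CpG test; with
  strong replicate heterogeneity the LRT would be anticonservative.
* Exact DMC counts of the original pipeline are not reproducible without
  its specific test and q-value method; thresholds, not counts, are the
  contract here.
* Odds ratios with empty cells are flagged, not corrected; downstream
  consumers must handle the flags.
* The gene-association rule reconstructs a tool's documented defaults;
  curated per-gene domain exceptions of that tool are not modeled.
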