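---
title: "Models and methods behind ripscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ripscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripscan)
```

`ripscan` analyses RNA immunoprecipitation sequencing (RIP-seq) of an
RNA-binding protein — the motivating case is a catalytically inactive
Dicer-like enzyme that binds but does not cleave its substrates — and
characterizes the genomic sites it occupies: where the protein binds,
what kind of locus each site is, what small-RNA population the site
produces, whether its sequence can fold into a pre-miRNA-like stem-loop,
and how cytosine methylation behaves over it. This vignette explains each
model, its assumptions, the tunable parameters, and the deliberate design
choices, in the order the pipeline runs them.

## Window-level enrichment model

The genome is tiled into constant-length windows of `window = 100` nt
advancing by `step = 50` nt, so consecutive windows overlap by 50 nt.
Terminal partial windows are not emitted: keeping every window the same
length makes read densities and the downstream minimum-count filter
comparable across the genome, at the cost of leaving at most 99 nt
uncovered per chromosome end. Reads are counted per window with
any-overlap semantics (a read increments every window it shares at least
one nucleotide with) and without regard to strand; stranded logic enters
only in the small-RNA module, where it carries signal.

Counts for window $i$ in sample $j$ are modelled as negative binomial,

$$K_{ij} \sim \mathrm{NB}(\mu_{ij},\ \alpha_i), \qquad
  \mathrm{Var}(K_{ij}) = \mu_{ij} + \alpha_i \mu_{ij}^2,$$

with $\log \mu_{ij} = \beta_{0i} + \beta_{1i} x_j + \log s_j$, where
$x_j$ indicates the IP group and $s_j$ is the sample's size factor. Size
factors are median-of-ratios: the median, over windows with strictly
positive counts in every sample, of the ratio of a sample's count to the
window's geometric mean. Windows containing any zero are excluded from
the median because their geometric mean vanishes; windows with zero
counts in every sample are excluded from testing altogether and flagged.

Per-window dispersions are estimated by method of moments from
*within-group* residual variances of normalized counts. Using
within-group rather than pooled cross-group moments matters: a genuine
binding signal inflates cross-group variance exactly at the windows under
test, which would cannibalize power. A mean–dispersion trend
$\alpha(\mu) = a_1/\mu + a_0$ is then fitted across windows by least
squares (coefficients clamped nonnegative, with a median fallback when
the design is degenerate, e.g. all windows sharing one mean), and the
final dispersion is $\max(\hat\alpha_i, \alpha(\bar\mu_i))$. The maximum,
rather than a fixed-weight average, is deliberate: with three replicates
per group the moment estimator has about four residual degrees of
freedom and frequently collapses to zero; any fixed weight on it
systematically underestimates dispersion for a subset of null windows
and inflates the false discovery proportion at the site level. Taking
the trend as a floor is the conservative sharing rule long used for
few-replicate count data; the recovery checks in the test suite and
acceptance script measure the resulting sensitivity and site-level
false-discovery proportion on the standard scenario directly.

Each window is tested by a Wald test on $\beta_{1}$ from the NB
log-link fit (iteratively reweighted least squares, vectorized across
windows, dispersion fixed at the moderated estimate), two-sided against
the normal reference. A $t$ reference with residual degrees of freedom
was evaluated and rejected: at 3v3 it is markedly over-conservative,
pushing the null rejection rate well below nominal, whereas the normal
reference stays close to it (the null-calibration check in the test
suite measures the realized rate).

Significant windows satisfy all of: Benjamini–Hochberg adjusted
$p < 0.05$ (strict), mean normalized IP count $\ge 50$ (inclusive, IP
replicates only — the filter describes the IP signal, so control counts
do not enter it), and $\log_2$ fold change $> 0$ (the assay seeks
IP-bound RNA; depletion is not a binding site). No independent
filtering, outlier replacement or fold-change shrinkage is applied —
omitting them keeps the procedure exactly reproducible from its
description. Significant windows whose gap is strictly less than 200 nt
(overlapping and bookended windows included) are chained into binding
sites; a site is the union hull of its chain and carries the minimum
adjusted $p$ and the mean normalized IP count over its members.

## Annotation priority

Each site is compared with the annotation records by any-overlap, and
among overlapping records the category earliest in the fixed priority
list (tRNA, rRNA, snoRNA, snRNA, miRNA primary transcript, inverted
repeat, transposable element, pseudogene, ncRNA, protein-coding gene)
wins; sites overlapping nothing are intergenic. Ties within one category
go to the record with the largest overlap, then the leftmost start, so
assignment is a total, order-independent function. miRNA
primary-transcript records are stored pre-enlarged by 100 nt on both
sides, reflecting that fragments captured around a hairpin extend beyond
the annotated precursor. The vocabulary is closed; GFF3 feature types
are mapped onto it via a user-editable table, and unknown categories are
rejected at load time rather than silently dropped.

## Small-RNA accumulation categories

Small-RNA reads are kept if 15–35 nt long, and a region's profile is
built from reads fully contained ("nested") in it: total reads $R$,
per-strand totals, density per 100 nt, the dominant sequence's share $d$
of $R$, and whether any contained sequence maps to a single genomic
position ($k = 1$). Classification is a four-rule decision tree:

* **CAT0** (no/few reads): density $< 5$ per 100 nt;
* **CAT3** (siRNA-like): density $\ge 5$ and strand bias
  $B = \max(R_+, R_-)/\min(R_+, R_-) < 4$;
* **CAT1** (miRNA-like): density $\ge 5$, $B \ge 10$, $d > 0.4$, and a
  uniquely mapping contained sequence exists;
* **CAT2** (proto-miRNA): every other populated, strand-biased case.

$B = +\infty$ when the minority strand has zero reads — "four times more
reads on one strand" is vacuously exceeded. Two cells of the
(density, $B$, $d$, uniqueness) space are not covered by the verbal
rules: $B \in [4, 10)$ with $d > 0.4$, and $B \ge 10$, $d > 0.4$ without
a unique mapper. Both fall to CAT2 with an ambiguity flag — the
proto-miRNA class is the conservative intermediate on the
miRNA-emergence continuum the categories describe. The "at least one
uniquely mapping sequence" condition is satisfied by *any* contained
sequence with $k = 1$, not necessarily the dominant one. Classification
uses raw read counts; the $1/k$ multimapper weight and
reads-per-million scaling apply only to between-sample abundance
comparisons, where each of a sequence's $k$ positions receives
$(\mathrm{count}/k)/\mathrm{library} \times 10^6$.

Metaprofiles rescale each feature body to a fixed number of bins
(default 100) with 500-nt flanks at nucleotide resolution, reverse
minus-strand features, and normalize each locus to its own maximum
before averaging so a handful of highly expressed loci cannot dominate
the mean shape. Peak positions relative to a pre-miRNA are labelled
"within" or "flanking" by the location of the coverage maximum over body
plus flanks, with ties that span both labelled "within"; association
between peak position and any two-level grouping is tested with the
exact two-sided Fisher test.

## Hairpin scanner

A pre-miRNA-like hairpin is modelled as an *ungapped* stem: column $i$
of the left arm pairs with column $i$ (counted from the 3' end) of the
right arm; Watson–Crick pairs and the G·U wobble match (wobble is
routine in plant pre-miRNA stems), everything else — including N — is a
mismatch. No bulges or internal loops are modelled: the defining
criteria speak only of stem length and mismatch count, and a gapped
model would need penalty parameters those criteria do not supply. A
candidate needs a stem of at least `min_stem = 25` columns with at most
`max_mismatch = 10` mismatches and a loop of at least `min_loop = 3` nt
(the sterically minimal hairpin loop). Every candidate lies on one
anti-diagonal of the pairing matrix ($p + q$ constant for all paired
positions $p, q$), so the scanner sweeps each anti-diagonal with a
two-pointer search for maximal runs within the mismatch budget, trims
runs so a reported stem begins and ends on a paired column, and
suppresses candidates wholly contained in another candidate's arms with
no more mismatches. The result is the set of maximal, non-dominated
stems, in deterministic order. An independent brute-force enumeration
over all (anti-diagonal, window) configurations is kept in the test
suite and agrees exactly on hundreds of random sequences.

Two properties of this model are worth stating plainly. First,
reverse-complement symmetry of the candidate set holds exactly only
under Watson–Crick-only pairing (`wobble = FALSE`): a G·U column maps to
A·C — a mismatch — under reverse complement. Second, the default
criteria are *permissive*: an unconstrained ungapped scan of a random
sequence longer than roughly 150 nt almost always contains some
25-column window with at most 10 mismatches, so the fraction of
~240-nt regions with at least one candidate saturates near 1 for sites
and length-matched random controls alike. The sharper discrimination
reported for thermodynamically folded structures requires minimum-free-
energy folding, which is outside this package's scope; the scanner's
discrimination is therefore demonstrated at parameters matched to a
planted structure (stem 30, at most 5 mismatches), where planted
recovery is 100% and the shuffled-sequence false-positive rate is
near 0. Random controls for the false-positive estimate are genomic
intervals drawn to reproduce the sites' length multiset exactly,
avoiding the sites themselves, with seeded, reproducible placement.

## Methylation aggregation

Methylation input is per-cytosine levels in $[0, 1]$ per sequence
context (CG, CHG, CHH; count-based input is divided on read). A region's
level per context is the unweighted mean over the cytosines it contains
— whether the original analyses weighted cytosines by read coverage is
not determinable from their description, and the unweighted mean is the
assumption least sensitive to coverage artefacts. A context with no
covered cytosine in a region is reported missing, never zero: absence of
data is not absence of methylation.

## What the synthetic generator emulates

The generator reproduces the statistical structure the analysis assumes,
at desk scale, with full determinism under a master seed (each stage
derives its own stream, so stages are individually reproducible):

* a 1-Mb single-chromosome genome at Arabidopsis-like 36% GC, with
  non-overlapping annotation records of all ten categories;
* a 3 IP vs 3 control design generated in 50-nt blocks (the tiling
  step): each block draws an NB count with mean $\mu/2$ and dispersion
  $2\alpha$ and places 36-nt reads uniformly inside itself, so *every*
  100-nt window — aligned or half-offset — covers exactly two blocks
  and has marginal mean $\mu = 30$ and variance $\mu + \alpha\mu^2$
  with $\alpha = 0.1$, matching the test's parameterization exactly so
  recovery tests are well-posed (adjacent windows share one block, as
  overlapping windows share reads in real data); 50 planted sites
  spanning the 200-nt fragment-capture width have their IP block means
  multiplied by a fold change of 8, so planted windows have expected
  fold 8;
* small-RNA populations whose density, strand split, dominance and
  mapping multiplicity sit at least twice inside every classifier
  threshold (parameters falling into the undefined classifier cells are
  refused), with CAT1 regions always containing a uniquely mapping
  dominant sequence;
* planted perfect-stem hairpins (stem 30, loop 8) carrying a set number
  of non-pairing substitutions;
* per-cytosine methylation with contexts derived from the actual
  simulated sequence and levels drawn as a clipped Gaussian (sd 0.1)
  around per-region, per-context means drawn from plant-like ranges
  (CG 0.5–0.9, CHG 0.2–0.6, CHH 0.05–0.3).

What it does **not** emulate — and hence what passing recovery tests do
not establish about real data: mappability structure and repeat-driven
multimapping, sequencing error and quality, library-specific biases,
fragment-length variation beyond the fixed capture span, correlated
background (chromatin, expression), and thermodynamic foldability of
real precursor sequences. Problem sizes in the tests (1-Mb genome for
recovery, 20,000 windows for calibration, hundreds of classifier
regions, dozens of hairpin constructs) were chosen as the smallest at
which the law-of-large-numbers statements being tested are stable.

## Numerical choices and degenerate inputs

* IRLS: at most 50 iterations to $10^{-8}$, coefficients clamped to
  $\pm 30$ on the log scale (fold changes beyond $e^{30}$ are
  placeholder saturation, not estimates), fitted means capped at
  $10^{12}$, and the 2×2 normal-equation determinant floored at
  $10^{-12}$.
* Dispersions floored at $10^{-8}$; the trend fit uses windows with
  mean above 1.
* All-zero windows: flagged, excluded from testing, `NA` statistics;
  they never enter the BH family.
* BH: `NA` p-values pass through without counting toward the family
  size.
* Merging: bookended windows (gap 0) merge; gap exactly 200 does not.
* Coordinates: in memory everything is 1-based inclusive `GRanges`, the
  Bioconductor convention; BED and GFF3 conversion happens in the
  readers/writers (`rtracklayer`), and flanking/enlargement clamps at
  chromosome bounds.
* Hairpin scan of a sequence shorter than $2 \cdot \mathrm{min\_stem} +
  \mathrm{min\_loop}$: empty result with a message, not an error.
* Control placement that cannot satisfy the exclusions within the retry
  budget aborts with a diagnostic rather than silently relaxing the
  constraint.

## Known limitations

The enrichment test is a reimplementation in the spirit of established
NB differential-count frameworks, not a numerical replica of any of
them; exact p-values differ from DESeq2's (which adds independent
filtering, outlier handling and shrinkage). The hairpin model is
structural, not thermodynamic, and saturates on long regions at the
default thresholds, as discussed above. The sRNA classifier inherits the
verbal rules' coarseness; the ambiguity flag marks the two cells where
the rules are silent. Methylation aggregation assumes the input levels
are trustworthy point estimates and does not propagate their coverage
uncertainty.
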