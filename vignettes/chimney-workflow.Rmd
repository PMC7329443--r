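---
title: "Methods: comparing chimney metagenomes with hydrovent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing chimney metagenomes with hydrovent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrovent)
```

`hydrovent` implements the quantitative core of a two-sample comparative
metagenome analysis of hydrothermal sulfide chimneys: gene-level abundance
and differential testing, MAG refinement and quantification, replication
rates from coverage trends, rule-based pathway completeness, and vent-fluid
endmember chemistry. This vignette explains each model, its assumptions,
the tunable parameters, and the numerical choices made where the design
was genuinely open. Everything quantitative stated here is computed by the
package's own test suite or acceptance script.

## Gene abundance and differential testing

**Model.** For gene $g$ with $r_g$ mapped reads and length $L_g$ (bp), the
normalized abundance is

$$A_g = \frac{r_g / L_g}{\sum_h r_h / L_h} \times 10^6 ,$$

a TPM-like unit in which every sample sums to one million. The denominator
runs over *all* genes in the supplied table. That choice matters: summing
only over a reported key-gene subset changes every value. We default to
the unrestricted sum (the formula's $\Sigma$ carries no restriction) and
let users pass a pre-filtered table when key-genes-only normalization is
wanted.

Gene-level taxonomy is attributed by sequencing depth: for a symbol, each
taxon's fraction is its genes' summed depth over the symbol's total depth.
For reconstructed 16S rRNA genes the same depth-weighted summation is
used; a `per_gene_average` switch divides by gene count per taxon first
(the two agree when each taxon contributed one gene — the usual case for
full-length reconstructions — and the wording of "average sequencing
depth" does not disambiguate them).

**Testing.** Differential abundance between exactly two metagenomes uses
the raw integer read counts, never the normalized values: exact tests need
counts, and normalization only rescales both margins. For each symbol the
2×2 table is (symbol reads, all-other reads) × (sample A, sample B); the
"non-gene" margin is the total mapped reads to all genes in the table,
consistent with the normalization denominator. The two-sided Fisher
p-value follows the probability-mass rule — sum over all tables with the
observed margins whose hypergeometric probability does not exceed the
observed one — with a $10^{-7}$ relative tolerance on the comparison to
avoid floating-point ties. Confidence intervals for the difference of
proportions use Newcombe's square-and-add composition of the two Wilson
score intervals, and the BH step-up correction runs across the family of
symbols tested in one call (mirroring one comparison panel). Counts are
aggregated per symbol before testing (paralogs pooled); `aggregate =
FALSE` tests individual genes instead.

The suite checks the implementation against a binomial-coefficient
enumeration oracle on every 2×2 table with total $N \le 60$, verifies
empirical type-I error stays at or below 0.06 at nominal 0.05 under the
null (Fisher is conservative), and verifies ≥ 93% empirical coverage of
the Newcombe interval at 95% nominal over 2000 simulated tables.

## MAG refinement

Candidate bins arrive with marker-set completeness $C$ and contamination
$X$ estimates, a contig membership map, per-contig stats, and a pairwise
AAI matrix; all of these are consumed as inputs. The workflow applies, in
order: outlier-contig filtering, AAI dereplication, duplicate-contig
resolution, and the quality gate $C \ge 70$, $X \le 9$ (boundaries
inclusive, as are all boundary comparisons in the package).

**Merging rule.** Two candidate bins with identical taxonomy may merge
when the merged bin's completeness gains at least 10 *percentage points*
over the better member while contamination rises at most 1 point.
Marker-based quality is reported in percent units, and a relative-percent
reading would make the contamination guard nearly vacuous for clean bins
(1% of 2% is 0.02 points), so absolute points is the sensible reading.
`merge_decision()` implements the rule on supplied quality triples; the
pipeline does not synthesize merged-bin quality estimates itself — those
come from the upstream marker tool.

**Outlier contigs.** A member contig is removed when any signature
diverges from the bin consensus: GC beyond `gc_mad_k` (default 3) scaled
MADs of the bin median *and* beyond an absolute floor `gc_min_diff`
(default 0.02); depth outside `depth_fold` (default 3) of the bin median;
or Manhattan distance of its reverse-complement-collapsed tetranucleotide
vector from the bin's length-weighted mean above the `tetra_pct` (default
0.98) quantile of within-bin distances *and* above `tetra_min_fold`
(default 3) times the median distance. The two guards are numerical
tie-downs: a continuous distance distribution always has observations
above its 98th percentile, and a continuous GC distribution always has a
most-extreme member, so the bare percentile/MAD rules would shave one
contig off every bin on every pass and the workflow could never be
idempotent. With the guards, a pass over already-clean bins removes
nothing, and the suite asserts workflow idempotence outright. A GC
deviation under two percentage points, or a tetra distance within 3× the
bin's median, is within-genome variation, not evidence of foreign origin.

**Dereplication.** Pairs at AAI ≥ 99% are population-level duplicates.
Greedy pairwise resolution depends on pair ordering, so the graph of
high-AAI pairs is resolved per connected component: each component keeps
the bin maximizing (completeness, −contamination, bin id) — the id being
a deterministic tie-break. Contigs appearing in several retained bins stay
in the bin with the better quality under the same ordering.

**Quantification.** A MAG's relative abundance is the length-weighted
depth of its member contigs over the length-weighted depth of all contigs
at or above 3 kb (the binning length cutoff); shorter contigs leave both
numerator and denominator, and the remainder to 1 is the unbinned
fraction.

## Replication rates (iRep)

A bacterial population replicating from a single origin over-represents
origin-proximal sequence in proportion to the fraction of cells holding
active forks: with a fraction $f$ of cells carrying one fork at a
uniformly random position, the expected copy number at origin-distance
fraction $x$ is $1 + f(1 - x)$, an origin:terminus ratio of $1 + f$. The
estimator sorts window depths ascending (recovering origin order without
knowing contig arrangement), anchors each window at its rank fraction
$t \in [0, 1]$ over *all* windows, drops the lowest and highest 5%, and
fits ordinary least squares of $\log_2$ depth on $t$; $\mathrm{iRep} =
2^{\text{slope}}$. Anchoring ranks before trimming matters: rescaling the
trimmed set to $[0,1]$ would shrink every slope by the trimmed fraction.

Defaults follow the published procedure the estimator reproduces: 5000-bp
windows, 100-bp slide, 5% per-tail trim, minimum median depth 5×, and
eligibility restricted to bacterial MAGs with ≤ 175 scaffolds/Mb
(inclusive). Zero-depth windows surviving the trim get a pseudodepth of
0.5 and a flag. No GC-bias correction is applied — the synthetic tracks
carry none; the windowing function is the natural hook if one is needed
for real data.

**Accuracy.** On simulated 2-Mb genomes at 50× with Poisson window noise
at read-length granularity, 20-seed mean estimates recover $1 + f$ within
±0.05 for $f \ge 0.25$ (the acceptance suite computes 1.25, 1.49 and 1.97
for $f$ = 0.25, 0.5, 1.0) and increase strictly with $f$. At $f = 0$ the
estimator has a known noise floor: sorting aligns sampling noise into a
spurious gradient, and the fitted slope reflects the spread of the
window-mean distribution, so a non-replicating population reads slightly
above 1 (about 1.06 under these simulation conditions) rather than 1.0
exactly. The floor shrinks with depth and window size; values near 1
should be read as "no detectable replication", not as a precise fraction.

## Pathway completeness rules

Pathway calling is a declarative rule engine over gene-symbol presence.
Each graded pathway carries up to three boolean rules evaluated in the
order complete → uncomplete → partial; the first match wins and no match
is "none" (binary traits: present/absent). Rules combine symbols with
AND/OR and a counting form `n_true(e1, e2, ...) >= k` over gene *groups*;
slash-joined genes (dsrAB, aprAB, nrfA/H) are groups requiring all
members, with an any-member reading available by editing the shipped rule
file — a plain-text serialization (`inst/extdata/pathway_rules.txt`) that
round-trips losslessly through `read_ruleset()`/`write_ruleset()`.

Two source rules needed interpretation. The Sox "partial" clause is read
as: any of soxA/soxX/soxY/soxZ in the absence of soxB, with soxC/soxD
alone not sufficient. The Wood-Ljungdahl "partial" clause is read as at
least two of the three groups (cdhC|cdhB, cdhE|cdhD, cooS) without the
stricter complete/uncomplete conditions. For cytochrome c oxidases,
distinct gene symbols (not subunits of one operon) are counted. All three
readings are package decisions, encoded in the rule file where they can
be inspected and edited. Hydrogenase group labels are consumed as input
from an upstream classifier, and tree-based confirmations (oxidative vs
reductive dsrA, CO-dehydrogenase clades) are out of scope.

Every rule predicate is monotone in symbol presence, so adding a gene can
never lower a level; the suite proves this over 10⁴ random symbol sets
and verifies the engine against independently hand-coded per-pathway
decision functions on every presence pattern (exhaustive up to 2⁸ symbols
per pathway; sampled for the 12-symbol oxidase rule).

## Vent-fluid endmember chemistry

Hydrothermal endmember fluids are Mg-free while seawater carries ~53
mmol/kg, so seawater entrainment during sampling dilutes every species
along a conservative mixing line $c(\phi) = \phi\,c_{sw} + (1 -
\phi)\,c_{em}$. Regressing each species on measured Mg across replicate
samples and taking the intercept at Mg = 0 recovers $c_{em}$. The fit is
ordinary least squares — reported analytical uncertainties are uniform
percentages within a species, so error weighting would be a no-op.
Below-detection values are excluded rather than substituted; negative
intercepts are clipped to 0 and flagged; samples already at Mg = 0
degenerate to an intercept-only fit (the mean); identical nonzero Mg
across samples is an error (no leverage). pH is reported as the lowest
measured value and never regressed. For vents where Mg varies little
(subseafloor mixing before venting), `measured_composition()` reports
means and seawater-relative enrichment instead of extrapolating, and
`conservative_mixing()` provides the expectation against which measured
depletions of H₂ and ΣH₂S are quantified.

On noise-free synthetic mixing the intercepts recover the generator's
endmembers to $10^{-9}$, and with Gaussian noise the intercept error stays
within 3 analytic standard errors in ≥ 99% of seeded trials.

## The synthetic community generator

The generator produces every input the pipeline consumes, with the
statistical structure the analysis assumes, and is itself first-class
tested code. Reads are allocated to genes by one multinomial draw with
probability ∝ taxon weight × gene length (totals are conserved exactly);
per-sample lognormal jitter of taxon weights emulates compositional
dispersion. Coverage tracks implement the single-fork replication model
above — the minimal model consistent with the iRep interpretation — with
Poisson noise per cell; cells default to 100 bp, the read length, because
read placement makes coverage independent at roughly read-length
granularity (per-base cells would understate window-mean noise about
tenfold). Contig metadata carries taxon-specific GC, depth and
tetranucleotide signatures with small within-genome jitter (GC sd 0.005,
depth sd-log 0.05); contamination is injected as fresh short (3–15 kb)
contigs bearing another taxon's true signatures, matching how foreign
scaffolds typically enter bins. Same-taxon bin pairs draw AAI in
[99, 99.9], different-taxon pairs in [75, 94.9]. Fluid samples sit
exactly on the mixing line before Gaussian measurement noise, and
negative generated concentrations are clipped to zero with a message.

What the generator does *not* emulate bounds what passing tests show:
there is no read-level simulation, no sequencing error or assembly
artifacts, no GC-dependent coverage bias, no strain heterogeneity, and
marker-set quality estimates are taken as exact. Green tests demonstrate
the algorithms are implemented correctly under the stated models, not
that the models capture every property of real chimney metagenomes.

## Problem sizes and determinism

Every generator takes a seed and is deterministic given it; the pipeline
rerun on the same inputs writes byte-identical tables. The test suite
uses 2-Mb genomes at 25–80×, communities of 2–3 taxa with 10–30 contigs
per genome, 2000-trial statistical contracts, and 20-seed averages for
the iRep grid; the acceptance script averages 20 seeds of the 2-Mb/50×
simulation. These sizes make the full suite run in a few minutes while
leaving Monte-Carlo error well inside every asserted tolerance.

## Known limitations

* iRep's sorted-noise floor (~1.06 at 50×/5-kb windows) biases estimates
  upward for nearly non-replicating populations; interpret values below
  ~1.1 qualitatively.
* Bin completeness/contamination are consumed, not recomputed: removing
  outlier contigs does not update the quality estimates, exactly as when
  the marker tool is run once upstream.
* The Fisher framework treats reads as independent draws; it ignores
  within-gene overdispersion between biological replicates (there are
  none in a two-sample design).
* The endmember regression assumes conservative (non-reactive) mixing for
  the extrapolated species; reactive species yield intercepts that are
  operational, not thermodynamic, endmembers.
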