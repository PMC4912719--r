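---
title: "Methods: F2 linkage mapping and scaffold anchoring with ddradmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: F2 linkage mapping and scaffold anchoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddradmap)
```

This vignette documents the statistical model, the algorithmic and
numerical choices, and the limits of what the package's simulation-based
tests demonstrate. It is the design record: wherever a decision was
genuinely open, the reasoning is here.

## The experimental design being modelled

The package targets a biparental F2 intercross genotyped at codominant
SNPs by double-digest RAD sequencing (ddRADseq) against a fragmented
draft assembly. Codominant F2 markers segregate 1:2:1
(AA : AH : BB). Calls are coded `A` (homozygous reference parent
allele), `B` (homozygous alternate), `H` (heterozygote), `U` (missing).
Downstream products are a genetic map in Kosambi centimorgans, bin
markers for co-segregating SNP runs, segregation-distortion annotations,
and pseudochromosomes assembled from anchored scaffolds.

## In silico digestion

`find_sites()` scans the forward strand only. Both default library
enzymes (EcoRI `G/AATTC`, MspI `C/CGG`) have palindromic recognition
sites, so a site found on the forward strand is the same physical site
on the reverse strand; scanning both strands would double-count.
Constructing a non-palindromic `enzyme()` raises a warning for this
reason. Matches containing `N` are skipped — an assembly gap cannot be
cut — and overlapping occurrences are all reported. Fragments from
`double_digest()` tile each scaffold exactly (an invariant the tests
enforce), and size selection is inclusive at both bounds, reading a
"250 to 500 bp" window as [250, 500]. The default `ends_mode = "mixed"`
keeps only fragments cut by the two *different* enzymes, which is what
ddRAD adapter chemistry sequences; `"any"` is available because
published fragment counts do not always state the convention.
Coordinates are 0-based half-open internally and in BED output; VCF and
AGP outputs are 1-based per those standards.

## Genotype encoding and the filter cascade

`encode_genotypes()` masks calls with GQ < 20 to `U` (a GQ of exactly 20
is kept — the rule is a strict inequality) and sets calls carrying an
allele absent from both parents to `U` while recording their per-site
fraction. `filter_sites()` then applies six rules in a fixed order, each
with a recorded first-triggering reason:

| order | reason | rule | default |
|---|---|---|---|
| 1 | `qd` | quality-by-depth below threshold | QD < 3 |
| 2 | `cluster` | ≥ `cluster_size` sites within `cluster_window` bp | 3 in 10 bp |
| 3 | `depth` | summed site depth outside window (inclusive) | [40, 10000] |
| 4 | `third_allele` | non-parental-allele call fraction | ≥ 0.05 |
| 5 | `missing` | missing-call fraction | ≥ 0.10 |
| 6 | `parents_het` | both parents heterozygous | — |

Design notes. The "mutation rate per site" criterion is interpreted as
the fraction of non-missing calls carrying a non-parental allele: it is
the only site-level quantity in the data model that matches the phrase,
and "less than 5%" passes means reject at ≥ 0.05. The cluster rule
follows the GATK convention (cluster of 3 within a 10 bp window), with
both numbers configurable since protocols often state only the window.
Depth bounds are summed site depth (not per-sample), and inclusive.
Quality rules run before population rules so that the missing fraction
is computed on GQ-masked data — masking happens before filtering in the
upstream genotyping protocol this models. Absent QD or DP in an input
VCF fails *open* (the site passes that rule) with a warning, because a
missing annotation is not evidence of failure. The cascade is
idempotent, and on simulated data with injected single-rule violations
the rejection set equals the injected set exactly (tested).

## Pairwise linkage: EM estimator and LOD

With gametes parental with probability $(1-r)/2$ each and recombinant
with probability $r/2$ each, the nine two-locus genotype classes have
probabilities $P(\mathrm{AA}) = (1-r)^2/4$,
$P(\mathrm{AH}) = r(1-r)/2$, $P(\mathrm{AB}) = r^2/4$ (and symmetric),
and $P(\mathrm{HH}) = ((1-r)^2 + r^2)/2$. All classes except the double
heterozygote carry a known recombinant-gamete count (0, 1 or 2); the
double heterozygote is a mixture of 0-recombinant (coupling) and
2-recombinant (repulsion) configurations. The E-step assigns it two
recombinant gametes with posterior $r^2/((1-r)^2+r^2)$; the M-step sets
$r$ to expected recombinant gametes over $2n$. Iteration starts at
$r = 0.25$, stops at $|\Delta r| < 10^{-10}$ or 200 iterations, and the
estimate is clamped to $[0, 0.5]$. Pairs with fewer than two individuals
informative at both markers are flagged and reported as $r = 0.5$,
LOD 0. The LOD is
$\sum_c n_c \log_{10}(P_c(\hat r)/P_c(0.5))$, exactly zero at
$\hat r = 0.5$. The estimator is verified against an independent
grid-search maximiser of the same multinomial likelihood on 1,000 random
count tables (agreement within $10^{-3}$, the grid pitch).
`pairwise_linkage()` computes all pairs at once: the nine class counts
for every marker pair are indicator-matrix products, and the EM runs
element-wise on whole matrices.

## Grouping, ordering, singletons

Grouping is single-linkage transitive closure at a LOD threshold
(default 15): any chain of pairs at or above threshold joins two
markers. Single linkage makes the group count monotone non-decreasing in
the threshold, which the tests exploit. Groups are numbered by
descending size, ties by smallest member id.

Ordering minimises the sum of adjacent recombination fractions (SARF): a
greedy nearest-neighbour chain seeded at the maximal-LOD pair, improved
by 2-opt segment reversal to a local optimum. This is a documented,
reproducible heuristic standing in for proprietary commercial ordering
algorithms; for groups of ≤ 8 markers it is verified against the
exhaustive-permutation SARF minimum, and on error-free simulations it
recovers the true order or its exact reversal. All tie-breaks are by
marker id and the reported orientation puts the smaller terminal id
first, so the procedure is deterministic with no seed.

A *singleton* is a call that disagrees with both of the individual's
nearest non-missing flanking calls along the map order — the classic
proxy for a genotyping error at dense marker spacing. Terminal markers
have no flank on one side and are never singletons; the nearest
*non-missing* neighbour is used because "both flanking data" must exist
to disagree. `refine_map()` drops markers with more than 5 singletons
(strictly more: 6 triggers exclusion), reorders affected groups,
recounts, and repeats until stable, with an iteration guard (default 50)
that warns and returns the last state on oscillation. Adjacent map
distances are the Kosambi transform of the adjacent $\hat r$ only — no
multipoint re-estimation — because that matches the resolution at which
the map is consumed downstream.

### Singletons and genuine double recombinants

A caveat that shapes the tests: with two independent gametes per F2
individual, a crossover landing in each of two adjacent intervals —
possibly one per gamete — produces a genotype that differs from both
flanks without any error. No interference model can suppress the
cross-gamete coincidence (the two gametes come from independent
meioses), so error-free data shows singletons at roughly $4r^2$ per
interior call. At SNP-level marker spacing (~0.065 cM between adjacent
markers, the regime in which thousands of SNPs co-segregate into a few
hundred bins) this rate is negligible and the singleton-as-error
heuristic is exact: the error-free zero-singleton check runs there. At
the sparser spacings used for order-recovery tests (~1–4 cM, where
$\hat r$ is resolvable with 96 individuals) genuine double recombinants
appear at the predicted rate, and the tests assert that rate rather
than zero. The two regimes cannot be combined: zero singletons demands
tiny $r$, while order recovery demands enough recombination per interval
to rank markers.

## Bin markers

`bin_cosegregating()` scans each scaffold left to right: a SNP joins the
current bin iff it is within `window_bp` (default 100 kb) of the bin's
*first* member — a fixed window anchored at the bin start, not a sliding
pairwise gap, which keeps the result independent of downstream choices —
and its genotype vector is compatible with the bin consensus (equal
wherever both are non-missing). Missing-tolerant compatibility is the
default because realistic per-sample integrity (~97%) would otherwise
shatter bins on missing calls alone; `strict = TRUE` is available. The
consensus at each individual is the unique non-missing value among
members. Binning runs after grouping and ordering, and the bin-level map
is rebuilt from consensus vectors; the per-LG summary reports mean
marker distance as map length divided by bin *count* (not count − 1),
matching the arithmetic convention of published summary tables, with
half-up rounding to 1 decimal (distances) and 2 decimals (means).

## Segregation distortion

Each mapped marker's non-missing counts are tested against 1:2:1 by
chi-square with 2 df; markers with raw p < 0.05 are flagged. No multiple
testing correction is applied by default — this matches the common
practice of reporting raw distortion at p < 0.05 — and a Bonferroni
option exists. Segregation distortion regions are maximal runs of at
least `min_run` consecutive flagged markers; "more than three adjacent
loci" reads as a default of 4, configurable because published counts
under this definition are not always internally consistent. The run
detector is verified against a brute-force scan on random flag vectors.

## Scaffold anchoring and pseudochromosomes

A scaffold with mapped bins is anchored to the LG holding the majority
of its bins (ties: the LG of its lowest-cM bin); its position is the
mean cM of its bins there. Scaffolds whose bins span several LGs stay
anchored to the majority LG but are flagged as conflicts so the call is
auditable. Orientation uses the sign of the Spearman rank correlation
between within-scaffold bp and cM — a "trend" statistic robust to a
nonlinear cM/bp relation; zero correlation, ties, or a single bin leave
the scaffold unoriented (one bin cannot define a direction).
`build_pseudochromosomes()` concatenates scaffolds per LG in anchor
order with fixed 100 N gaps, writes AGP v2.0 (component type `W`, gap
type `scaffold`, linkage `yes`, evidence `map`), and reports per
chromosome: total length (the sum of scaffold lengths — gap padding is
deliberately excluded so totals equal scaffold-length sums), effective
length (total minus N within scaffolds), linkage distance, and cM/Mb.
Reassembling the emitted AGP against the scaffold sequences reproduces
the pseudochromosome FASTA byte-for-byte (tested).

## The simulator

`sim_config()` defaults describe the emulated study design: 96 F2
individuals, 8 chromosomes with genetic lengths 188.7, 78.4, 40.2,
48.5, 64.5, 63.3, 48.9 and 49.0 cM, 4 scaffolds per chromosome
separated by 100 N gaps, 50 markers per chromosome, and clean calls
(error, missingness and distortion default to 0 and are switched on per
experiment). Physical chromosome length defaults to 500 kb — a
desk-scale stand-in; sequence content only matters to the digestion and
anchoring stages, which are length-agnostic. Parents are idealised as
fully homozygous opposite lines (AA × BB everywhere), so the F1 is
uniformly heterozygous; real mapping parents are often partially
heterozygous cultivars with mixed marker segregation types, which this
generator deliberately does not emulate.

Meiosis is a no-interference Markov chain: along the true marker order
each gamete switches parental origin between adjacent markers with
probability equal to the true adjacent $r$ (the Kosambi-inverse of the
marker spacing). This is the simplest model consistent with pairwise
recombination fractions. Because Kosambi distances assume partial
interference while the generator has none, the recovered map length is
biased by a few percent (upward here, as sampling noise in $\hat r$
inflates adjacent estimates); the 10% recovery tolerance accounts for
this, and the acceptance run reports the observed ratio (~104% at the
default scale).

Viability selection at a configured locus removes individuals carrying
the selected homozygote with probability `s` (rejection sampling of
whole individuals, so linked markers inherit the distortion, which is
what makes SDRs detectable). Genotyping errors flip homozygotes to `H`
and heterozygotes to a random homozygote; missingness masks calls to
`U`; both are logged with coordinates in the truth set. Depth is
negative binomial (mean 500, dispersion 8 — comfortably inside the
[40, 10000] filter window), QD uniform on [10, 40] and GQ uniform on
[30, 99]; only threshold behaviour matters, so no attempt is made at
realistic quality-score distributions, and `inject_bad_sites()` adds
decoy sites violating exactly one rule each for filter tests.

What passing simulation tests does and does not show: the generator
produces exactly the independence structure the estimators assume (no
interference, no linkage disequilibrium beyond the map, homogeneous
error). Real data adds allele-specific bias, depth-correlated error,
segregation types beyond AA × BB, and reference errors; results here
validate the algorithms, not robustness to those artefacts.

## Problem sizes and determinism

Default test and acceptance scales: 400 markers × 96 individuals for
end-to-end runs (pairwise EM on all 79,800 pairs is vectorised and takes
seconds), 1,000 random tables for the EM-vs-grid check, 1,000 random
1 kb sequences for the site-finder oracle, exhaustive permutations up to
8 markers. Every simulation is seeded and byte-reproducible; the mapping
pipeline itself contains no randomness — all tie-breaks are by marker
id.

## Known limitations

- Ordering is a SARF heuristic with 2-opt; it is exhaustively optimal on
  small groups but only locally optimal in general.
- No multipoint likelihood, no sex-specific maps, no dominant
  (C/D-coded) markers.
- Distances come from adjacent pairwise $\hat r$; tightly linked markers
  with zero observed recombinants tie at 0 cM and order within such runs
  falls back to id order (binning exists precisely for this regime).
- The VCF reader handles the minimal GT:GQ / DP,QD subset this pipeline
  needs, not arbitrary VCF.
- Scaffold-coherence ("moving markers of one scaffold together") is
  handled at the anchoring stage, not as an ordering constraint.
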