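---
title: "Species-hypothesis threshold testing for ITS barcodes: methods and design"
author: "barcodeSH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-hypothesis threshold testing for ITS barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeSH)
```

## The problem

Fungal reference databases such as UNITE group ITS sequences into *species
hypotheses* (SHs) by clustering at a grid of pairwise-distance thresholds,
typically 0 to 3% in 0.5% steps (0.5% distance is the same cutoff as 99.5%
similarity). For a complex of recently diverged, morphologically
near-identical (pseudocryptic) species, the threshold choice decides
everything: too coarse and several good species collapse into one SH, too
fine and single species shatter into arbitrary fragments. The question this
package operationalises is: *given a set of reference sequences whose
species assignment is trusted (e.g. from multi-locus phylogenetics and
coalescent species delimitation), which SH threshold recovers exactly those
species?* A second, practical question follows: what can still be said
about short or low-quality records that have to be excluded from the
clustering?

## Distance model

Distances are uncorrected p-distances: for a pair of aligned records, the
compared sites are the columns where **both** residues are unambiguous
bases (`A`, `C`, `G`, `T`), and

$$d = \frac{\text{mismatches}}{\text{compared sites}},
\qquad \text{similarity} = 1 - d.$$

No model correction (JC, K2P, ...) is applied because SH thresholds are
phrased as similarity complements; a corrected distance would change the
meaning of "0.5%". Every IUPAC ambiguity code, the alignment gap `-` and
the missing-data code `?` remove the column from the comparison for that
pair ("pairwise deletion"). This is deliberately conservative: an `R`
might match an `A`, but scoring partial matches would make distances
depend on an arbitrary weighting and make ambiguity-rich records look
artificially close. When fewer than `minOverlap` sites (default 100) are
comparable, the pair's distance is *missing* — not 0, not 1 — and
contributes no edge to clustering. This is how an ITS1-only and an
ITS2-only record relate: there is simply no information, and treating it
as either extreme would fabricate some.

## Clustering and the sweep

An SH at threshold $t$ is a connected component of the graph joining pairs
with $d \le t/100$ (ties at exactly $t$ merge). Single linkage is the
model because it is what makes SH membership *nest*: as $t$ grows, edges
are only added, so clusters only merge, cluster counts are non-increasing,
and the partition at a smaller threshold refines the partition at a larger
one — the familiar nested colour-bar picture. Complete and average linkage
are available behind a flag for sensitivity analysis but do not share the
nesting property and do not accept missing distances.

Against a reference species map, each species at each threshold receives a
status: **resolved** (its members form exactly one cluster containing no
other species' members), **split** (several pure clusters), **merged**
(one cluster that also holds other species), or **mixed** (both at once).
"Strictly distinguished at a threshold" is formalised as resolved, i.e.
exact set equality; query (unlabelled) records never enter the status
computation and are reported with their cluster only. The *minimal
resolving threshold* of a species scope is the smallest grid point at
which every species in the scope is resolved; because resolution is not
monotone in $t$ (a species resolved at 0.5% may be merged at 1%), it is
computed directly rather than from per-species minima. Reports always name
the scope used and state thresholds on both scales (0.5% distance / 99.5%
similarity) to prevent unit confusion.

## Diagnostic positions and placement

Records excluded from clustering are not discarded. A column is
*diagnostic* for a species when its state is fixed — present, unambiguous
and identical in every member — within that species and absent from every
other reference species at that column. The default tolerance is 0
(strict); a `tolerance` knob allows a stated fraction of a species'
members to be gap/ambiguous at the column, since published lists of
distinguishing positions rarely state their tolerance. Queries are never
added to the reference set when the table is computed, so a placed
sequence cannot influence its own diagnostics; in the pipeline the table
is built from the good-quality reference records only.

Placement of a query counts, per species, the diagnostic columns it covers
with a base, and how many match. The verdict rule is deterministic:
`assigned(S)` requires S to be the unique covered species with zero
mismatches and at least `minCovered` covered positions (default 3 — a
single matching position is too fragile against sequencing error to carry
an identification); a unique zero-mismatch species with fewer covered
positions, a tie, or no covered position at all gives `uncertain`; and
`conflicting` means every species the query covers shows at least one
mismatch, i.e. the record matches nothing in the reference — the signature
of a compromised sequence or an unsampled taxon. Unaligned queries are
first threaded onto the reference columns by global pairwise alignment
(match 1, mismatch −1, gap open −5, gap extend −1) against the reference
sharing the most 8-mers; query insertions relative to the reference cannot
be represented in fixed columns and are dropped.

The quality screen mirrors the criteria used to exclude records before
tree building: `partial:ITS1`/`partial:ITS2` when exactly one spacer is
covered at ≥ 50% and the other below 10%; `high_ambiguity` above a 2%
ambiguity fraction; `domain_deviant` when a record differs from the
reference consensus inside the conserved 5.8S at two or more columns
(one difference could be a real rare variant; two in ~160 conserved sites
is a technical red flag).

## The synthetic-data generator

The generator exists so the entire analysis can run, and be tested,
without downloading anything. It simulates the situation the analysis
assumes: a complex of closely related species under the multispecies
coalescent. Units follow the coalescent-delimitation (BP&P) convention —
divergence times $\tau$ and population parameters $\theta$ are both in
expected substitutions per site, so no separate mutation rate exists. In a
population carrying $k$ lineages the next coalescence is exponential with
rate $k(k-1)/\theta$ (a pair coalesces after mean $\theta/2$ and acquires
expected divergence $\theta$); lineages that fail to coalesce pass to the
parent population at its $\tau$. Sequences then evolve site-independently
(JC69 by default, HKY85 optional) along the genealogy, region by region:
ITS1 (220 sites) and ITS2 (230 sites) at the reference rate, 5.8S (160
sites) at 0.1×, optionally a partial LSU (300 sites) at 0.2×. The root
sequence is drawn from the equilibrium frequencies. Inverse-gamma priors
for $\theta$ and $\tau$ use the (shape α, scale β) convention with mean
$\beta/(\alpha-1)$ — stated explicitly because IG conventions vary; the
usual diffuse prior IG(3, 0.002) has mean 0.001.

Database-style degradation is applied afterwards: truncation to a single
spacer (other columns become `?`), IUPAC ambiguities at a stated per-site
rate (each replaced code contains the true base), and substitutions
planted inside 5.8S to create domain-deviant records. Every record's
degradation is recorded in a truth table, and identical configuration plus
seed reproduces every output file byte for byte.

What the generator does **not** emulate: indels (gaps arise only from
truncation, because the analysis consumes a fixed alignment and indels
would add alignment error as a confound), chimeras, rate variation across
sites beyond the region multipliers, and recombination. Tests passing on
synthetic data therefore certify the clustering/evaluation machinery and
the statistical behaviour of distances under the coalescent — not
robustness to alignment error or chimeric reads in real databases.

### The two bundled data sets

`complexPresetModel()` is a five-species tree shaped like a recent
radiation (two subclades; $\tau$ = 0.004 within, 0.012 between;
$\theta$ = 5·10⁻⁴), calibrated so expected within-species divergence sits
well below 0.5% and between-species divergence in the 0.8–2.5% band.
Single 600-site realisations fluctuate around the 0.5%/1% boundaries —
that fragility is real and is precisely what a threshold sweep measures.

`syntheticComplexDataset()` is the deterministic counterpart used by the
examples and the acceptance checks: differences are *planted* rather than
simulated. Five species of four records each carry 3 private fixed
differences (their diagnostic positions), one subclade carries 16
additional shared differences, and two members per species carry one
private substitution. On the 610-site locus this pins the distance
structure (within ≤ 0.33%, closest species pair ≈ 0.98%, subclades
≈ 3.6%), so the sweep gives 15 clusters at 0%, 5 at 0.5% and 2 from 1%
upward, for every seed. Four query records reproduce the classic database
pathologies (ITS2-only: identifiable; ITS1-only covering one diagnostic:
dubious; ambiguity-laden: uncertain; 5.8S-deviant: matches nothing). It is
labelled synthetic everywhere: it stands in for a real reference set whose
sequences live in public databases, and mirrors the published *qualitative*
structure of such a complex, not any real sequence.

```{r sweep}
ds <- syntheticComplexDataset()
refIds <- ds$map$id[ds$map$role == "reference"]
sw <- thresholdSweep(distanceMatrix(ds$alignment[refIds]))
clusterCounts(sw)
minResolvingThreshold(sw, ds$map)
```

## How well does a 600-site barcode do? (what the tests compute)

The acceptance suite repeats a desk-scale experiment: five populations
with $\theta = 0.002$ and all $\tau \ge 0.01$, four samples per species,
a 600-site locus, clustered at 0.5%. Two intrinsic noise sources limit
recovery. First, within-species pair divergence is exponential with mean
$\theta$, so $P(d > 0.5\%) = e^{-2.5} \approx 8\%$ for a single pair, and
the deepest coalescent split of four samples fails to connect at the
threshold in a few percent of replicates. Second, 600 sites make the
0.5% threshold a three-mismatch rule, and a cross-species pair with true
divergence ~2% (expected ~10 mismatches) occasionally realises three or
fewer. Recovery per species × seed therefore lands around 87–93% rather
than higher — a quantitative statement of why short barcodes struggle
exactly where species complexes need them, and why one should check the
threshold against the group of interest instead of assuming a universal
value. The same experiment at the same conditions is what
`scripts/acceptance.R` reports as `msc_species_recovery_pct`.

## Numerical and design choices

* **Edge rule**: $d \le t$ inclusive; ties at the threshold merge, with a
  $10^{-12}$ tolerance so that e.g. 3/600 compares equal to 0.5%.
* **Cluster labels** are the lexicographically smallest member id —
  deterministic and stable under record reordering.
* **`minOverlap` = 100 sites** by default: below that, a p-distance on an
  ITS fragment is dominated by sampling noise. Pairs under the limit are
  missing, never imputed.
* **Degenerate inputs**: empty diagnostic tables are valid (two identical
  species); placement on an empty table is an error; a species whose
  members never connect has no resolving threshold (`NA`), as do datasets
  where two species share identical sequences.
* **Five-number summaries** `(min–)low–mean–high(–max)` use low/high =
  mean ± 1 *sample* SD (n−1), the convention of the standard description
  format; since that convention is not universal the interpretation is
  configurable (5th/95th percentiles as `spread = "quantile"`). After
  rounding, low/high are clamped into [min, max]: for small skewed samples
  mean ± SD can escape the observed range, and the notation's invariant
  min ≤ low ≤ mean ≤ high ≤ max takes precedence. Formatted strings use
  ASCII hyphens; the parser also accepts en-dashes as printed in
  journals.
* **Problem sizes in the test-suite**: 2000 replicates for coalescent
  closed forms (3 Monte-Carlo SEs), 10⁵ sites for the JC69 closed form, 40
  seeds × 5 species for the recovery experiment, 200 random matrices
  (n ≤ 50) against the transitive-closure oracle, 50 simulated alignments
  against the naive diagnostic-column scan. These sizes put Monte-Carlo
  error well below the tested effect sizes while keeping the whole suite
  under half a minute.

## Limitations

Alignment construction is out of scope: records are assumed aligned
(externally, e.g. with an E-INS-i strategy) and trimmed by the user; the
query threading is a placement aid, not a substitute for realignment.
The production SH pipeline of a live database may differ in trimming and
compression details from the p-distance defined here; for that reason the
distance model and compared-site counts are recorded in every report
bundle, so results remain auditable against other definitions. Bayesian
inference of $\theta$ and $\tau$ is not re-implemented — the generator
*consumes* such estimates (or priors) as simulation presets.
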