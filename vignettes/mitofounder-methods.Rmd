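---
title: "Models and methods behind mitofounder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitofounder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitofounder)
```

This vignette explains the models the package implements, the
parameters that matter and their defaults, the design choices made
where several defensible options existed, and what the synthetic-data
validation does and does not demonstrate.

## Mutation notation and site exclusions

Haplotypes are stored as sets of mutation tokens relative to a declared
reference (rCRS or RSRS), in the position-based notation used on
published mutation-annotated trees: a bare nucleotide position is a
transition, a base suffix a transversion to that base, `d` a deletion,
`.1C`-style suffixes insertions (count plus inserted bases), `R`/`Y`
point heteroplasmies, and a leading `@` a reversion. The parser and
renderer round-trip every well-formed token, which the test suite
exercises property-style.

Site exclusions are context-dependent, reflecting standard practice:

* **phylogeny** — np 16519 and the length variation of the poly-C
  stretches around nps 309/315 and of the AC repeat at nps 515–522 are
  too unstable to carry phylogenetic signal. Profiles report the
  repeat indels against varying anchor positions, so any indel token at
  nps 302–316 or 513–524 is dropped; substitutions at those positions
  are kept.
* **clade_id** — additionally ignores np 60 when deciding whether a
  clade deserves a haplogroup label.
* **dating** — drops np 16519 and the hypervariable 16182C/16183C
  transversions. Indels are otherwise counted in ρ by default; a
  `mutation_counter()` switch excludes them, and heteroplasmies
  (drawn as mutations on published trees) can likewise be excluded.

## Tree building

Trees are rooted, with mutations on branches; sampled haplotypes are
always leaves, so an ancestral haplotype observed in the data appears
as a zero-mutation leaf attached to its internal node. Construction is
maximum parsimony:

* up to six haplotypes (and no backbone): exhaustive search over all
  rooted topologies scored by Fitch parsimony with the root state
  fixed, which guarantees the minimum score. The best tree is
  reconstructed with one minimal mutation labelling (ties resolved by
  preferring the parental state) and zero-mutation internal branches
  collapsed into multifurcations.
* larger data: greedy stepwise addition, in order of decreasing profile
  size (ties by sample id; optionally a seeded shuffle). Each haplotype
  attaches where it shares the most derived variants — at a compatible
  node, or by splitting a branch whose mutations it partially shares,
  which is how private variants shared by two haplotypes found new
  internal nodes. Equally good placements resolve to the first in
  deterministic node order; this tie-break is a package convention, not
  an inference.

A user-supplied backbone tree can stand in for curation against a
reference phylogeny: construction then starts from the backbone instead
of a bare root. Haplogroup labels are assigned only to internal nodes
with at least two descendant haplotypes and at least one informative
branch mutation (np 60 is ignored), nesting in the alternating
number/letter style of mtDNA nomenclature.

## The ρ statistic and its error

For a node with $n$ descendant haplotypes, $\rho$ is the mean number of
mutations separating each haplotype from the node, computed over
branches as $\rho = \sum_b m_b n_b / n$ where $m_b$ counts the
mutations on branch $b$ and $n_b$ the haplotypes below it. The
heuristic standard error estimated from the genealogy is
$\sigma = \sqrt{\sum_b n_b^2 m_b}\,/\,n$; under independent Poisson
mutation counts per branch this is exactly the standard deviation of
$\rho$, which the tests verify by Monte-Carlo re-draws. Clade ages are
reported only for labelled clades with at least three mitogenomes by
default; a whitelist argument admits smaller clades that deserve
reporting despite the rule.

## The purifying-selection-corrected clock

Observable mutational divergence outpaces the long-run substitution
rate in young clades, because mildly deleterious variants contribute
to diversity before selection removes them. The package models the
cumulative observable divergence of a lineage of age $t$ years as

$$ d(t) = \frac{t}{3624} + c\,\tau\,(1 - e^{-t/\tau}), $$

a long-run linear clock of one mutation per 3,624 years over the whole
molecule plus a transient excess that accumulates at rate $c$ and
decays with mean lifetime $\tau$. The zero-age rate is pinned to one
mutation per 2,562 years, fixing $c = 1/2562 - 1/3624$ from the two
published endpoint rates; $\tau$ is the single calibrated parameter,
fitted by least squares in divergence space against the packaged
reference table of published (divergence, age) pairs for haplogroup
R0a'b and its subclades (both maximum-likelihood and ρ columns). The
fit gives $\tau \approx 42.8$ kyr and reproduces every tabulated age to
within 0.05 ka; rows can be held out at calibration time to keep their
conversions as genuine predictions, which is how the acceptance script
runs.

The functional form guarantees the properties a correction must have:
$d(t)$ is strictly increasing, ages satisfy
$2562\,d \le \mathrm{age}(d) \le 3624\,d$, and the effective
years-per-mutation $\mathrm{age}(d)/d$ rises monotonically from 2,562
towards 3,624. Inversion is numerical (monotone root finding to
$10^{-8}$ relative tolerance). Confidence intervals transform
$d \pm 1.96\,\mathrm{se}$ through the correction and clip the lower
bound at zero. Maximum-likelihood divergences are accepted as imported
inputs and converted through the same clock; their estimation is out of
scope.

## Founder analysis

A scenario partitions sample regions into source, sink and excluded
(excluded lineages are invisible to both founder qualification and
dating); Palestinian samples can be analysed with Arabia, with the
Fertile Crescent, or left out, and Iran can be toggled out of the
source, matching the sensitivity analyses such studies run. Seven
scenario presets (A–G) cover sinks in Eastern Africa, Arabia + Eastern
Africa, Arabia, the reciprocal Fertile Crescent with and without Iran,
South Asia and Europe.

Each sink leaf walks rootward from its attachment point; the first
ancestor carrying at least one (f1) or two (f2) *derived* branches
leading exclusively into source lineages is its founder node. A
derived branch must carry at least one mutation — a zero-mutation
source tip at the node does not count — which keeps founder matches
off the tips of the source phylogeny and guards against homoplasy and
recent back-migration. Sink leaves sharing a founder node form a
cluster; ρ and σ are then computed over the cluster's sink leaves
only. Leaves with no qualifying ancestor cluster at the root and are
flagged rather than dropped, so the partition of sink lineages is
always complete.

Because the founder method's assumptions do not admit a time-dependent
clock, founder ages are linear: $\rho_f \times 2651$ years, the
intermediate value between the time-zero rate (2,562 yr/mutation) and
the rate at the oldest founder ages (2,667 yr/mutation). The published
intermediate 2,651 is not the arithmetic mean of the endpoints; it is
consumed as a constant. Migration times are scanned on 200-year bins
from 0 to 50 ka: each cluster spreads its mass as a normal density with
mean $\rho_f \times 2651$ and standard deviation
$\sigma_f \times 2651$, truncated at zero and renormalized on the grid
(a degenerate $\sigma_f = 0$ puts all mass in the bin containing the
mean), weighted by sink sample size (equal weighting is available).
The truncated normal is the package's choice where the literature
admits alternatives (for example a Poisson-process likelihood over
candidate times); the spread function is pluggable in principle, and
the scan's mode is the reported migration-time estimate.

## The synthetic-data generator

The simulator emulates the study design the analysis stages expect: a
source deme and a sink deme founded from it by a pulse at a known time
$T$, both descending from a small shared ancestral (refugium) pool.
Demographics follow the sudden-expansion model that star-like mtDNA
clades reflect: both demes sit at a constant post-expansion coalescent
intensity of $5 \times 10^6$ years (about $10^5$ females at a 25-year
generation), while the refugium pool is small (2,000 years, a few tens
of females), so lineages entering the pool coalesce almost immediately
and the collapsed haplotype tree shows a founder node at the pulse with
many mutationally derived source branches. Sample sizes default to 100
source and 50 sink mitogenomes; the pulse defaults to 15 ka.

Mutations are Poisson per branch, either at the linear whole-molecule
rate (one per 3,624 years) or, in corrected mode, with branch means
given by differences of the corrected clock's cumulative divergence at
the branch endpoints — the consistent way to make simulated data obey
the same time-dependent observable rate the dating assumes. Positions
are drawn uniformly (infinite sites) from the molecule minus the
conventionally excluded zones; optional hotspot positions are
oversampled with replacement to generate recurrent mutations and
exercise homoplasy handling. A fixed seed fully determines the output.

Validation against this generator shows that the estimators recover
known truth under the model's own assumptions: ρ times the linear rate
is unbiased for clade age, and the f2 migration scan is centred on the
pulse time (founder-recovery experiments run in corrected mode, since
the 2,651 yr/mutation founder rate is precisely the linear
approximation of the corrected clock over the 0–50 ka scan range). Two
caveats delimit what passing tests mean for real data. First, the
per-replicate scatter of the scan mode is bounded below by Poisson
mutation noise: at $T = 15$ ka and 50 sink samples even a perfect
single-cluster estimator has only about a 73% chance of landing within
±1 ka of the truth, and realistic genealogies (several founder
clusters, attachment lag into the source) sit nearer 60%. Larger sink
samples or younger pulses tighten this. Second, the generator does not
emulate sequencing error, ancient-DNA damage, sampling bias across
populations, or the hand-curated corrections real trees receive, so
recovery results speak to the estimators, not to data quality.

## Numerical and interface choices

* Problem sizes in the shipped experiments were chosen to make the
  whole suite a desk-scale run: 100 replicates at 150 samples for
  founder recovery, 200 replicates at 20 leaves for ρ recovery, 500
  random trees for the estimator identities, and 60 random instances
  against the exhaustive parsimony oracle.
* Trees serialize to newick with branch mutations in `[&m=...]`
  comment blocks and the root profile in `[&root=...]`; branch lengths
  equal mutation counts. Reading plain newick yields zero-mutation
  branches.
* The variant-table dialect is a five-column TSV (`sample_id`,
  `population`, `region`, `range`, space-separated tokens) with the
  reference recorded in a header comment — the simplest form that
  round-trips.
* The rCRS/RSRS difference list is configuration, not a package
  constant: rebasing is a symmetric difference restricted to each
  haplotype's sequenced range, and applying it twice restores the
  original profile.
* Scenario definitions, clock rates and counting switches are plain R
  arguments rather than external configuration files; the numbered
  scripts under `analysis/` are the workflow surface.

## Known limitations

The greedy builder does not guarantee minimal parsimony beyond the
exhaustive-search size, mirroring the heuristic tools it replaces; the
recurrence report flags where homoplasy may have distorted placements.
Founder identification assumes a strict two-population split, so
admixed or intermediate populations must be excluded or assigned by
scenario design. The correction's closed form is a model of the
published calibration rather than a transcription of the original
calculator's internals; within the calibrated range (0–40 ka of
tabulated ages) the two agree to printed precision, but extrapolation
far beyond the deepest calibration point inherits the exponential
form's assumption that the deleterious excess has fully saturated.
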