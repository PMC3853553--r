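---
title: "Diet metabarcoding with the trnL P6 loop: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet metabarcoding with the trnL P6 loop: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnldiet)
```

`trnldiet` reconstructs animal diets from fecal DNA using the chloroplast
trnL (UAA) intron P6 loop, the short (roughly 10–150 bp) hypervariable
region amplified by the universal primer pair *g*/*h*. This vignette is
the package's own account of the models, parameters and numerical choices
behind each stage, and of what the synthetic-data tests do and do not
demonstrate about real data.

## The reference database and discrimination rates

A local reference is built from full trnL intron sequences of the
candidate flora. `extract_p6()` locates the forward-primer site and the
reverse complement of the reverse-primer site, allowing a configurable
number of substitutions per site (no indels inside primer sites, since a
primer either anneals across its footprint or does not), and stores the
insert *between* the primers. Primer sequence is excluded because reads
are primer-trimmed before comparison, so reference and query coordinates
then match. Two or more non-overlapping forward sites make the locus
ambiguous; the reference builder treats this as an error, while the read
trimmer logs and drops such reads, because a single bad read should not
abort a run.

The P6 loop is short and conserved enough that unrelated species often
share a haplotype. `build_haplotype_groups()` therefore partitions the
reference by *exact* sequence identity — the database is Sanger-derived,
so no alignment-based merging is warranted — and labels each multi-member
group at the lowest rank whose single taxon covers all members
(`"Gr. Lauraceae1"` for seven Lauraceae species on one haplotype).
Case is folded; an `N` never counts as matching anything.

Discrimination rates summarize how far the marker can resolve the flora:

* `Rs` = 100 × distinct haplotypes / species;
* `Rf(family)` = 100 × distinct haplotypes among the family's species /
  species in the family;
* `Rg` = 100 × genera owning at least one *genus-exclusive* haplotype /
  genera.

"Distinct haplotype" (rather than "species-diagnostic sequence") is the
reading consistent with published discrimination tables, where a family
with 12 species and 8 distinct sequences reports 67%, and the
genus-exclusive reading of `Rg` is the only one compatible with "genera
with one or more unique sequences". Rates are rounded half-up to integer
percent (half-up to 2 decimals for frequency tables); base R's
round-half-even would disagree with printed tables on exact halves. The
bundled `woodpigeon_family_structure()` table carries a `consistent` flag:
four of its published `Rf` entries (Ebenaceae, Malvaceae, Moraceae,
Verbenaceae) disagree with `round(100 * n_sequences / n_species)` under
every rounding rule, so tests compare against the arithmetic value and
treat those rows as printing artifacts of the source table.

Duplicated species ids in a reference are a hard error, never a silent
deduplication: two records for one species usually mean a curation
mistake upstream.

## Read processing

Reads are routed to samples by their MID tag prefix; tags must be
prefix-unique, and a read matching two tags at equal distance stays
unassigned rather than being guessed. The default tag mismatch budget is
0 — tag chemistry is designed for exact reads, and nothing in the
motivating protocol suggests fuzzy tag matching — but the budget is a
parameter.

After primer trimming, reads shorter than the forward primer or with more
than 10% `N` are rejected and logged; alignment identity on such
fragments is not meaningful. The survivors are dereplicated (unique
sequence, count), ordered by decreasing count with lexicographic
tie-break so every downstream step is deterministic under input shuffles,
and clustered by a greedy centroid pass: a sequence joins the *first*
cluster whose centroid it matches at ≥ 98% global-alignment identity
(end gaps penalized, identity = matches / alignment columns), otherwise
it founds a new cluster. Greedy centroid clustering replaces contig
assembly deliberately: for 66–148 bp single-locus amplicons there is
nothing to assemble, and a 98% identity threshold expresses the same
grouping rule in a fully specifiable way. The centroid is the founding,
most abundant member. Clusters with centroids under 40 bp or fewer than
4 reads are then discarded (boundary values retained), the conventional
guard against sequencing artifacts; every discard is logged with its
reason, and read conservation across all stages is asserted by the test
suite.

Alignment scoring defaults to match +1, mismatch −1, gap open −2, gap
extend −1 (a length-k gap costs 2 + (k−1)). The kernels are compiled
(affine-gap Gotoh) with three exactness-preserving fast paths, each
property-tested against the unrestricted dynamic program:

* identical sequences join without aligning;
* equal-length pairs within Hamming distance 2 use the gap-free identity,
  which is provably score-optimal under the default costs (any gapped
  global alignment of equal-length sequences scores at most L − 5, below
  the gap-free L − 2h for h ≤ 2);
* other clustering comparisons run in a diagonal band wide enough to
  contain every alignment that could reach the identity threshold (an
  alignment with identity ≥ t has at most ⌈L(1−t)/t⌉ gap columns), so
  banded join/reject decisions equal the full DP's.

## Taxonomic assignment

Each retained centroid is scored against every haplotype group with a
semi-global alignment: the query aligns in full, the reference may
overhang for free, and identity is computed over the covered columns
only, so a clean 60 bp fragment of a 90 bp reference scores identity 1.
Hits must reach 95% identity over at least 40 columns; among the
survivors, all groups attaining the exact maximal score tie. Integer
scoring makes "same score" well defined, so no tolerance band is used. A
single winner keeps its group label; a tie is lifted to the lowest rank
containing every member species of every tied group, and a tie spanning
two families is reported as unassigned. The identity/length thresholds
replace a raw BLAST e-value cutoff on purpose: e-values depend on
database size and background parameters that do not transfer between
installations, while identity and covered length are reproducible
everywhere; both knobs sit in `pipeline_config()`.

Clusters from one sample assigned to the same label are summed, giving
the samples × taxa `diet_matrix()`. Assigned plus unassigned reads always
equals the retained total, and raising `min_identity` can only shrink the
assigned tally (both are tested properties).

## Diet summaries

`F_R` (frequency of reads) divides a taxon's reads by all *assigned*
reads — the denominator choice that reproduces published diet tables from
their own read columns; unassigned reads would otherwise silently deflate
every percentage. `F_P` (frequency of presence) takes an explicit sample
denominator because two detection methods compared on one sample set may
have different usable totals (e.g. 48 sequenced samples but 47 with
enough material left for microscopy). Microscopy data enter as a plain
per-sample presence table: the microscopy itself is out of scope, the
comparison statistics are not. Richness comparisons use the Welch
unequal-variance t-test (`stats::t.test`), and monthly composition
restricts to "major" items (present in more than 10% of samples by
default) and normalizes presence counts within calendar months; months
are taken from ISO dates, locale-independently, with no smoothing.

## Community comparisons

Between-island structure is tested three ways. Pearson chi-square
(`stats::chisq.test`, no continuity correction) runs on island-pooled
tables, after dropping all-zero rows/columns with a warning; the pooled
table can be reads or presences, an explicit choice because either
pooling is defensible. Sample-level structure uses the abundance-based
Chao–Jaccard dissimilarity: with U and V the estimated shared-abundance
fractions (corrected upward for unseen shared species via shared
singletons/doubletons; the doubleton count is replaced by 1 when zero,
and U, V are clipped at 1), similarity is UV/(U+V−UV) and d = 1 −
similarity. Identical samples give 0, disjoint supports give 1. In
presence/absence mode the package computes classic Jaccard directly —
applying the abundance estimator to 0/1 data would not reduce to Jaccard
and has no sensible interpretation.

NMDS minimizes Kruskal stress-1,
√(Σ(d̂ − f(d̂))² / Σ d̂²), where f is the isotonic regression of the
configuration distances on the rank order of the input dissimilarities.
Tied dissimilarities form one block sharing a fitted value (mean-rank tie
handling, matching the rank treatment in ANOSIM). Optimization alternates
a Guttman majorization step with the isotonic fit; a backtracking step
halving guarantees the stress trace never increases within a start, which
the tests assert directly. Defaults: k = 2, 20 starts (the first from
classical metric scaling, the rest random), 200 iterations, tolerance
1e−6 on the stress decrease; runs are bit-reproducible from the seed.
ANOSIM ranks all n(n−1)/2 dissimilarities (mean ranks on ties), computes
R = (mean between-group rank − mean within-group rank) / (n(n−1)/4), and
estimates p by label permutations with the add-one estimator
(1 + #{R* ≥ R}) / (1 + n_perm), which cannot report zero. Both are
implemented in-package because their exact tie handling, permutation
scheme and iteration trace are part of the package's contract; `vegan`
serves as an independent oracle in the test suite, where Chao, Jaccard
and ANOSIM R agree with it to machine precision.

## The synthetic-data module

`simulation_config()` encodes the study conditions the package is
designed around, and its defaults are fixed rather than tuned: 222
species in 175 genera and 76 families collapsing to exactly 167 distinct
haplotypes of 66–148 bp; 48 samples split over two islands; per-sample
depths drawn from a normal with mean 743 and SD 338, truncated at 50;
skewed multi-taxon diets (Dirichlet concentration 0.3, mean richness
~6.7 taxa per sample) with one shared dominant taxon forced to ≥ 35% of
reads, mimicking a staple food such as mulberry; island taxon pools of 30
with 30% island-exclusive membership; i.i.d. substitution errors at 1%
per base on the insert (no indels by default, keeping identity arithmetic
transparent; an error applies only to the biological insert, not the tag
or primers); and optional per-taxon multiplicative amplification bias.
Pool size, exclusivity, concentration and dominance were chosen once as
values a field ecologist would call realistic for an oceanic-island
frugivore (roughly 44 detected taxa overall, strongly skewed read
tables); they are parameters, not calibrations.

The generator collapses haplotypes by merging singleton species into an
existing haplotype class, preferring congeners (probability 0.4), then
confamilials (0.5), then anywhere (0.1), until exactly the requested
number of distinct classes remains; the realized discrimination report is
returned as ground truth by construction. Reads are multinomial draws
from diet proportions × bias, wrapped as MID + primer g + mutated insert
+ reverse-complemented primer h, with a per-read source record.

What the synthetic tests show: exact recovery of the constructed
discrimination structure; exact diet-proportion recovery on error-free
reads when the abundance filter is disabled; ≥ 95% of retained, untied
reads assigned consistently with ground truth at 1% error; and an
island contrast that presence-based ANOSIM detects (p < 0.05 at 24
samples per island) while the read-count ANOSIM statistic is depressed by
the dominant shared taxon. What they cannot show: robustness to chimeras,
homopolymer/indel error processes of specific sequencing chemistries,
PCR-cycle stochasticity, degraded-DNA length biases, or reference
incompleteness — none of which the generator emulates. Results on real
data therefore still warrant the usual caution about read counts as
quantities; presence-based summaries are the more conservative companion,
and the package always computes both.

## Numerical and degenerate-input choices

* Percent rounding is half-up (with a 1e−9 fuzz against binary
  representation error): integer percents for discrimination tables, two
  decimals for frequency tables.
* Dereplication order (count desc, then lexicographic) is the single
  source of determinism for clustering; clustering results are invariant
  to any within-tie input shuffle.
* Empty inputs: empty read sets produce empty-but-valid outputs with a
  warning; an empty reference or an all-zero count vector is an error
  (`"no reference loaded"`, `"empty sample"`), since silently returning
  something would hide a broken run.
* A haplotype group whose members span families is labelled at the
  implicit above-family root (`"Gr. Plantae<k>"`); assignment ties that
  rise above family are reported as unassigned rather than given a
  root-level label, because a "plant, unspecified" diet item carries no
  ecological information.
* Problem sizes in the test suite: most tests run on references of 20–40
  species and samples of 100–200 reads; the end-to-end recovery test runs
  the full default conditions (48 samples, ~35k reads) once. These sizes
  were chosen so the whole suite exercises every code path, including one
  full-scale run, while remaining a routine desktop check.

## Known limitations

Exact-identity reference collapsing means a single Sanger miscall
creates a spurious haplotype; the discrimination report will show it as
an extra sequence. The greedy clusterer is order-dependent by design
(deterministic, but a different abundance ranking can change centroid
choices near the threshold). ANOSIM p-values are permutation estimates;
with 999 permutations the smallest reportable p is 1/1000. NMDS finds
local optima; 20 starts make the best-of-starts stable in practice but
carry no global guarantee.
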