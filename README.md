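# trnldiet

Diet metabarcoding analysis with the chloroplast **trnL P6 loop**.

`trnldiet` is an R package for reconstructing the diet of herbivorous and
frugivorous animals from fecal DNA. It targets the standard P6-loop design:
the short hypervariable region of the chloroplast trnL (UAA) intron is
amplified from degraded fecal DNA with the universal primers *g*
(`GGGCAATCCTGAGCCAA`) and *h* (`CCATTGAGTCTCTGCACCTATC`), each sample's
amplicons carry a MID (multiplex identifier) tag, and the pooled reads are
sequenced together. The motivating application is the fecal diet survey of
the critically endangered red-headed wood pigeon (*Columba janthina
nitens*) on the Ogasawara Islands, where the question is how much of the
diet comes from introduced versus native plants; the package generalizes
to any local flora and sample set.

The package covers the whole workflow:

* **Reference database** — extract P6 inserts from full trnL intron
  sequences between the primer sites, collapse identical sequences into
  *haplotype groups* labelled at the lowest covering taxonomic rank
  (species; else `"Gr. <genus|family><k>"`), and report discrimination
  rates: species-level `Rs` = distinct sequences / species, genus-level
  `Rg` = genera with a genus-exclusive sequence / genera, and per-family
  `Rf` = distinct sequences in the family / species in the family (integer
  percent).
* **Read processing** — MID demultiplexing (prefix match, ambiguous reads
  unassigned), primer trimming, dereplication, greedy centroid clustering
  at 98% global-alignment identity, and the standard filters (centroid
  ≥ 40 bp, cluster ≥ 4 reads).
* **Taxonomic assignment** — best semi-global alignment score against the
  haplotype groups with identity/length thresholds; exact score ties are
  lifted to the lowest common ancestor, ties above family become
  unassigned.
* **Diet summaries** — frequency of reads `F_R` (taxon reads / all
  assigned reads), frequency of presence `F_P` (samples containing the
  taxon / sample total, with an explicit denominator so a second detection
  method can use its own), per-sample richness with a Welch t-test, and
  monthly composition of major food items.
* **Community comparisons** — Pearson chi-square on island-pooled tables,
  abundance-based Chao–Jaccard dissimilarity
  (d = 1 − UV/(U+V−UV) with the unseen-shared-species correction),
  NMDS minimizing Kruskal stress-1, and ANOSIM with permutation p-values.
* **Synthetic data** — a first-class simulator that generates taxonomies,
  reference databases with a controlled number of distinct haplotypes,
  island-structured skewed diets, and error-bearing MID-tagged reads with
  full ground truth, so every stage is testable without downloads.

Alignment kernels (affine-gap Gotoh, global and semi-global) are compiled
via Rcpp; Biostrings handles FASTA/FASTQ; vegan is used only as an
independent cross-check in the test suite.

## Worked example

Simulate a small survey with known ground truth, build the reference
database, and run the full pipeline:

```r
library(trnldiet)

cfg <- simulation_config(
  seed = 7, n_species = 30, n_genera = 20, n_families = 8,
  n_haplotypes = 22, n_samples = 8, islands = c(A = 4, B = 4),
  pool_size = 10, depth_mean = 120, depth_sd = 30, error_rate = 0.01
)
ds  <- simulate_dataset(cfg)
db  <- build_reference_db(ds$refs, ds$taxonomy)
discrimination_rates(db$groups, ds$taxonomy)
#> P6-loop discrimination: 30 species, 20 genera, 8 families, 22 distinct sequences
#>   Rs = 73%   Rg = 70%   Rf range = 57-100%

run <- run_pipeline(ds$reads, ds$mids, db$groups, ds$taxonomy,
                    meta = ds$meta, cfg = pipeline_config(seed = 7))
run$log
#> # A tibble: 8 × 2
#>   stage           reads
#>   <chr>           <int>
#> 1 input             964
#> 2 demultiplexed     964
#> 3 mid_unassigned      0
#> 4 primer_rejected     0
#> 5 clustered         964
#> 6 filter_retained   743
#> 7 assigned          743
#> 8 hit_unassigned      0
```

Every input read is accounted for at each stage: here all 964 reads
demultiplex cleanly, 743 survive the ≥ 4-reads-per-cluster filter (the 1%
substitution errors scatter the rest into rare clusters, exactly what the
abundance filter is for), and all retained reads find a reference hit.
`run$summary` is the per-taxon diet table (`label`, `origin`, `n_reads`,
`F_R`, `F_P`), `run$anosim_binary` the presence/absence island contrast,
and `autoplot(run$nmds, groups = ...)` draws the ordination.

The bundled survey table shows the frequency arithmetic on real published
counts — 44 taxa totalling 32,288 assigned reads, where the two dominant
items alone carry over 70% of the reads:

```r
frequency_of_reads(woodpigeon_diet_counts())
#> # A tibble: 44 × 3
#>    label             n_reads   F_R
#>    <chr>               <int> <dbl>
#>  1 Morus australis     11810 36.6
#>  2 Gr. Lauraceae1      11280 34.9
#>  3 Gr. Ficus1           3902 12.1
#>  4 Fagara boninsimae    1328  4.11
#> # ...
```

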