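# thermodiv

Comparative functional-diversity analysis for chemosynthetic hot-spring
community metagenomes.

Hot springs hot enough to exclude photosynthesis host communities fed by
chemical energy, and some of them turn out to be startlingly diverse —
both taxonomically and in the protein functions their metagenomes encode.
`thermodiv` implements the comparative computations used to characterize
that diversity and relate it to spring geochemistry, for anyone who has
per-metagenome predicted proteomes, KO (KEGG Orthology) annotations, MAG
(metagenome-assembled genome) summaries and phylogenies in hand:

- **Protein-family binning** — greedy incremental clustering of proteins
  by local-alignment identity (BLOSUM62, affine gaps), applied as a
  cascade at 90%, 60% and 30% identity with an 80% coverage-of-the-shorter
  criterion, so remote homologs merge stepwise into family bins
  (`cluster_at()`, `cascade()`, `family_abundance()`).
- **Rarefaction** — Monte-Carlo subsampling of family richness at fixed
  depths, with its closed-form hypergeometric companion
  \(E[S] = \sum_f [1 - \binom{N-N_f}{d}/\binom{N}{d}]\)
  (`rarefied_richness()`, `expected_richness()`).
- **Diversity ~ geochemistry** — ordinary least squares of per-spring
  richness on the fluid-mixing proxy log10(SO4/Cl); high ratios indicate
  vapor-phase input mixed with meteoric water, low ratios deep
  chloride-rich reservoir water (`fit_diversity_model()`).
- **KO profiles** — per-metagenome frequency normalization, the centered
  enrichment statistic \(E_{k,s} = (a_{k,s}-\bar a_k)/\bar a_k\) (with S
  samples, S−1 flags a KO exclusive to one metagenome, −1 flags absence),
  category subsetting (e.g. "Energy Metabolism"), Bray–Curtis distances
  and principal-coordinates ordination (`normalize_ko()`,
  `ko_enrichment()`, `subset_category()`, `bray_curtis()`, `pcoa()`).
- **MAG comparisons** — quality filtering (>50% complete, <7%
  contamination, both strict), three-step coverage-normalized relative
  abundance, within-lineage metabolic-differentiation ratios
  (unshared/shared KOs per category) and reciprocal-best-hit average
  amino-acid identity (`filter_mags()`, `mag_relative_abundance()`,
  `differentiation_ratios()`, `aai()`).
- **Tree metrics** — root-to-tip distances and the fraction of a
  phylogeny's branch length attributable to a tagged tip set, in
  clade-exclusive and terminal-branch readings (`root_to_tip()`,
  `branch_fraction()`).
- **A ground-truth generator** — `synthetic_config()` / `generate_study()`
  emit complete synthetic studies (proteomes with planted family
  structure, geochemistry, KO tables with planted exclusive KOs, genome
  pairs with planted shared fractions, MAG tables, trees with tagged
  tips) so every stage above can be validated against known truth.

## Worked example

Generate an 8-spring study whose planted family richness rises at 5
families per log10(SO4/Cl) unit, recover the families by cascade
clustering, and refit the diversity–geochemistry relationship:

```r
library(thermodiv)

cfg <- synthetic_config(seed = 42, n_springs = 8, pool_size = 25,
                        richness_intercept = 12, richness_slope = 5)
study <- generate_study(cfg)

fam <- cascade(study$proteins)          # 90/60/30 identity cascade
tab <- family_abundance(fam)
ncol(tab)                               # 24 families, matching the 24 planted

rich <- rowSums(tab > 0)
fit_diversity_model(
  data.frame(spring_id = names(rich), richness = unname(rich)),
  study$geochem)
#> richness ~ log10(SO4/Cl): slope 5.001, intercept 11.614,
#>   adj R^2 = 0.869, p = 0.000466, n = 8 (0 dropped)
```

The fitted slope (5.001) recovers the planted value (5): springs fed by
end-member water mixing carry proportionally more protein families, and
the clustering did not blur the planted family structure.

KO enrichment flags planted structure analytically. With 8 metagenomes,
a KO found in only one of them attains the maximum enrichment 8 − 1 = 7
there, and −1 wherever it is absent:

```r
enr <- ko_enrichment(normalize_ko(study$ko_table))
k <- study$truth$exclusive_ko_ids[1]
enr[k, study$truth$exclusive_ko_springs[[k]]]
#> [1] 7

pcoa(bray_curtis(normalize_ko(study$ko_table)), k = 2)
#> PCoA: 8 points, 2 axes returned (19.4% + 17.9% of positive-eigenvalue variance)

branch_fraction(study$tree, study$tagged_tips, mode = "exclusive")
#> [1] 0.0567...   # tagged tips hold ~5.7% of total branch length
```

See `vignettes/thermodiv-methods.Rmd` for the full account of the models,
parameter choices and validation design.

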