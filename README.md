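# songculture

Quantitative analysis of how song patterns move between humpback whale
populations.

Male humpback whales (*Megaptera novaeangliae*) sing hierarchically
structured displays — units form phrases, repeated phrases form themes,
themes sung in a stereotyped order form a song cycle — and whole song
types are transmitted between populations, for example from east
Australia (EA) to New Caledonia (NC) with a typical one-year lag. This
package is for bioacousticians and cultural-evolution researchers who
have transcribed song corpora (or want realistic synthetic ones) and need
to quantify how accurately those patterns are learned across populations.

It provides:

* **Sequence similarity** — the Levenshtein-distance similarity index

  `LSI(a, b) = 1 − WLD(a, b) / max(|a|, |b|)`,

  where WLD is an edit distance with unit indel cost and substitution
  cost `(normalized acoustic distance)^β` between unit types (β = 1 by
  default), computed in C++ for full pairwise matrices; unweighted LSI on
  theme sequences for song-cycle comparisons.
* **Cluster-based verification** — average-linkage (UPGMA) dendrograms of
  `1 − LSI` matrices, cophenetic correlation validation (CCC > 0.8 read
  as a good representation), bootstrap cluster support by object
  resampling, dendrogram cuts, and adjusted-Rand agreement against
  transcribed labels; Newick export.
* **Complexity scores** — song-cycle (six variables) and per-theme (three
  variables) composites as first principal components of standardized
  variables, oriented so higher = more complex.
* **Population statistics** — exact small-sample Mann-Whitney rank-sum
  tests (partition-counting null, tie-corrected normal fallback), theme
  occupancy (shared vs population-unique themes) and unique-theme phrase
  shares.
* **A synthetic song-culture generator** — two populations, evolutionary
  and revolutionary song change, one-year transmission lag, singer
  conformity to rendition variants, copy error biased toward acoustically
  similar units, population-unique theme injection — with complete ground
  truth for recovery testing.

## Worked example

Simulate a study-scale corpus (6 song types, 2 populations, 353 cycles),
apply the inclusion rules, verify the song types, and compare the
populations:

```r
library(songculture)

sim    <- simulate_song_culture(preset_config("study_scale", seed = 1))
corpus <- filter_corpus(sim$corpus)
corpus
#> Song corpus: 353 song cycles, 8276 phrase repetitions, 49 theme ids,
#> 12 population-year strata

# do the six song types form well-represented dendrogram branches?
verify_song_assignments(corpus)[c("group", "n_cycles", "ccc", "ccc_pass")]
#>         group n_cycles       ccc ccc_pass
#> 1       Brown       55 0.9609106     TRUE
#> 2  LightBrown       72 0.9776576     TRUE
#> 3 LightPurple       45 0.9470006     TRUE
#> 4      Orange       58 0.9679791     TRUE
#> 5      Purple       65 0.9676083     TRUE
#> 6        Teal       58 0.9743080     TRUE

# which themes are shared, which unique to one population?
occ <- theme_occupancy(corpus)
occupancy_counts(occ)
#> $total
#> [1] 49
#> $shared
#> [1] 37
#> $unique_by_population
#> $unique_by_population$EA
#> [1] 5
#> $unique_by_population$NC
#> [1] 7

# are the two populations' song types equally complex?
scores <- song_type_complexity(corpus)
compare_population_complexity(scores)
#> Mann-Whitney rank-sum: U = 16 (n1 = 6, n2 = 6), p = 0.8182 [exact]
```

Reading the output: every song type's theme-sequence dendrogram has a
cophenetic correlation above the 0.8 adequacy threshold (here 0.95-0.98),
so the trees faithfully represent the similarity structure and the song
types are verifiable as coherent units. Most themes (37 of 49) are shared
between the populations, with a minority unique to one of them — more in
the receiving population, as in the real system. The exact rank-sum test
on the six per-song-type complexity scores finds no population difference
(p = 0.82): the receiving population learned each pattern without
systematic loss of complexity.

The same analysis runs end to end from transcription files with
`run_pipeline(pipeline_config(...))`, which writes similarity matrices
(TSV), dendrograms with bootstrap support (Newick), complexity tables
(CSV + PCA sidecar JSON), test results and an occupancy table under one
output directory, plus a machine-readable `summary.json`. A thin
command-line dispatcher over the same functions is installed at
`inst/cli/songculture.R` (subcommands `simulate`, `verify-themes`,
`verify-songs`, `complexity`, `compare`, `occupancy`, `report`).

The methods vignette (`vignettes/song-culture-analysis.Rmd`) documents
the similarity model, the clustering and bootstrap procedures, the PCA
conventions, the exact test, and the generator's assumptions and
limitations.

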