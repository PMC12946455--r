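# mitocurate

Phylogeny-guided curation of mitochondrial reference databases for eDNA
metabarcoding.

Environmental-DNA studies assign sequencing reads to species by comparing
them against a reference library, so the library's quality bounds the
quality of every downstream biodiversity result. Public repositories,
however, carry misidentified specimens, annotation errors and contaminated
submissions — and simple metadata screens miss most of them. `mitocurate`
curates mitochondrial (mitogenome and single-marker) reference libraries by
checking every record's **taxonomic label against its placement in a
phylogenetic tree**, flagging conflicts for manual review instead of
deleting them blindly, and annotating records that genuinely cannot be told
apart rather than pretending they can.

## What the package does

1. **Filter and subsample GenBank records.** Complete-genome or target-gene
   mode, exclusion of ambiguous organism qualifiers (`cf.`, `sp.`, `ssp.`,
   hybrid `x`), RefSeq-preferring deduplication, and per-species
   subsampling to at most `max_sequences` representatives (default 5) that
   preserves submitter and geographic diversity.
2. **Extract and concatenate marker genes** (the 13 protein-coding genes
   plus 12S/16S) with synonym-tolerant feature matching ("COI" = "CO1" =
   "COX1" = "cytochrome c oxidase subunit I"), joined in the canonical
   vertebrate mitogenome gene order.
3. **Group by taxonomic order** under a 2000-sequence cap
   (first-fit-decreasing packing) and drive external alignment and tree
   inference (MAFFT / FastTree adapters; stubs for offline testing), with
   user outgroups forced into every group for consistent rooting.
4. **Detect taxonomy-vs-topology anomalies** on each rooted tree. Species
   are classified by sequence count and screened with tree-based rules:

   | Sequences | Category | Color | Rule |
   |---|---|---|---|
   | 1 | Type I, singleton | green | leaf's nearest neighborhood shares no rank at or above the flag level (family by default) |
   | 2 | Type II, pairwise conflict | blue | pair not monophyletic; the displaced leaf is flagged, or both when placement is unclear |
   | ≥3 | Type III, cluster discordance | red | leaves outside the species' largest clean clade |

5. **Ingest manual review** (`clustering_anomalies.txt`, `similar.txt`),
   blacklist confirmed errors, and **assemble a versioned release**
   (`MitoDB_vYYMMDD`) in GenBank and FASTA form, where indistinguishable
   records carry a `similar_to=` header tag listing one representative
   accession per confusable species:

   ```
   Microphysogobio_linghensis|NC_086468.1|Concat|o__Cypriniformes|f__Gobionidae|g__Microphysogobio|similar_to= NC_051965.1, NC_086467.1|
   ```

A synthetic-data module (`sim_spec()`, `make_records()`, `make_tree()`)
generates GenBank-style records and rooted trees with planted anomalies and
exact ground truth, so the entire pipeline is testable offline.

## Worked example

```r
library(mitocurate)

# synthetic GenBank-style records with RefSeq twins and "sp." organisms
sim <- make_records(sim_spec(n_orders = 2, families_per_order = 2,
                             genera_per_family = 2, species_per_genus = 3,
                             seqs_per_species = c(1, 4), twin_fraction = 0.3,
                             ambiguous_fraction = 0.1, rng_seed = 7))
cfg <- filter_config("complete", max_sequences = 3, rng_seed = 7)
fo  <- filter_records(sim$records, cfg)
table(fo$rejected$reason)
#> ambiguous_qualifier duplicate_of_refseq
#>                   5                   2
ss <- subsample_records(fo$kept, cfg)
head(ss$summary, 3)
#>   species      n_before n_retained
#> 1 Genaaa_alba         4          2
#> 2 Genaaa_nigra        4          3
#> 3 Genaaa_rubra        3          3

# a rooted tree with one planted anomaly of each type
fx <- make_tree(sim_spec(n_orders = 3, families_per_order = 3,
                         genera_per_family = 2, species_per_genus = 3,
                         seqs_per_species = c(1, 3),
                         planted = c(singleton = 1, pairwise = 1, cluster = 1),
                         rng_seed = 42))
fx$tree
#> <ref_tree> 110 leaves (2 outgroup), 54 ingroup species
detect_anomalies(fx$tree)[, c("accession", "species", "anomaly_type", "color")]
#>   accession  species         anomaly_type color
#> 1 FX000074.1 Novusa_insolita singleton    green
#> 2 FX000025.1 Genabb_nigra    pairwise     blue
#> 3 FX000053.1 Genbba_rubra    cluster      red
```

The three flags recover exactly the three planted anomalies: a relabeled
singleton far from its nominal family (green), the displaced member of a
split pair (blue), and the leaf grafted away from its conspecific cluster
(red). `render_annotated_tree()` writes the color-annotated review PDF;
after editing the flag report, `apply_review()` + `assemble_release()`
produce the versioned database with `cleanlist.txt` / `blacklist.txt` and a
per-family quality table (`error_seq` / `similar_seq` / `others_seq`).

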