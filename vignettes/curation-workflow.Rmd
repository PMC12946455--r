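---
title: "Phylogeny-guided curation of mitochondrial reference libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-guided curation of mitochondrial reference libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocurate)
```

## The problem

Taxonomic assignment of eDNA reads is only as reliable as the reference
library behind it. Public mitochondrial records suffer from three distinct
failure modes: outright misidentification or annotation error (the record
is wrong), legitimate biological ambiguity (recent radiation, mitochondrial
introgression or incomplete lineage sorting make two species' mitogenomes
indistinguishable), and redundancy (hundreds of near-identical submissions
from one survey). A curation workflow has to separate these: delete the
first, *annotate* the second, and thin the third — never the other way
around. `mitocurate` does this by comparing every record's taxonomic label
with its placement on a phylogeny estimated from the records themselves,
and by recording ambiguity explicitly in the released FASTA headers
(`similar_to=` tags) instead of silently dropping or keeping confusable
records.

## Record filtering and subsampling

Record-level screening runs in a fixed order — ambiguous-qualifier screen,
then the mode screen, then RefSeq deduplication — so every rejection
carries one reproducible primary reason. The order itself is a design
choice (cheap screens first); any order yields the same kept set.

* **Qualifier screen.** Organisms containing `cf.`, `sp.`, `ssp.` or a
  hybrid `x` as standalone tokens are excluded by default (`keep_*`
  switches override per qualifier). Token matching matters: `sp.` must
  never fire inside an epithet such as *spilota*, and `x` only counts
  between name parts.
* **Mode screen.** `complete` mode keeps records whose DEFINITION line
  contains a complete-genome phrase (case-insensitive substring over an
  extensible keyword set). `gene` mode additionally keeps fragments that
  contain a target gene and exceed `min_gene_length` (default 400 bp, a
  floor against uninformative fragments; lower it for short-barcode
  applications). Records with *no* feature table at all are retained in
  gene mode — legacy submissions often hold the target region without a
  labeled feature — but still face the length floor.
* **RefSeq dedup.** When a RefSeq (`NC_`) record and INSDC submissions
  share byte-identical sequences, the INSDC copies are redundant and
  dropped. Identical sequences with no RefSeq member are collapsed later,
  at subsampling, so the two stages have disjoint responsibilities.

Species-level subsampling caps each species at `max_sequences` (default 5)
records: identical sequences are collapsed first (RefSeq preferred, then
smallest accession), then one representative is kept per (submitter,
geographic origin) key, and only a remaining excess is resolved by a random
draw. The draw is seeded per species from `(rng_seed, species name)`, so
adding or removing one species never perturbs another species' outcome and
the whole pipeline is order-independent. In gene mode complete genomes are
retained ahead of fragments and fragments fill the quota ranked by
extracted target-gene length — a deterministic ranking, so gene mode needs
no randomness. The submitter key is the first reference's author/consortium
string lowercased with whitespace collapsed, and the geographic key the
`geo_loc_name`/`country` qualifier; these are the closest concrete fields
to "same study, same place". This heuristic trades some genuine
intraspecific diversity for redundancy control; per-species pre-subsample
counts are logged so the trade-off is visible and `max_sequences` can be
retuned.

## Gene extraction

Feature tables name genes inconsistently, so matching uses a validated
synonym table: case-insensitive, word-boundary-anchored patterns per
canonical gene, checked at construction so that no built-in label can match
two genes (the dangerous pairs being COX1/COX3, ND4/ND4L, ATP6/ATP8,
12S/16S). The first matching feature in table order wins when a gene is
annotated twice. Coordinates follow the GenBank convention (1-based
inclusive, `join()`/`complement()` supported, parts concatenated in listed
order, minus-strand features reverse-complemented). Concatenation follows
the canonical vertebrate mitogenome gene order (12S, 16S, ND1, ND2, COX1,
COX2, ATP8, ATP6, COX3, ND3, ND4L, ND4, ND5, ND6, CYTB) regardless of
annotation order; partially annotated records contribute the genes they
have (no gap padding — alignment is the aligner's job), and records with
nothing extractable fall back to their full sequence rather than being
lost.

## Grouping and tree inference

One tree over an entire class of fishes is slow and unstable; trees are
instead built per taxonomic order under a `max_per_file` cap (default
2000). Oversized orders become their own group by design; the rest are
packed first-fit-decreasing, which is deterministic and near-optimal — the
choice of FFD over next-fit is a design decision, as any deterministic
packing satisfies the partition contract. Outgroups are forced into every
group (and excluded from the cap, so the cap uniformly governs ingroup
size) to guarantee every tree can be rooted the same way. Alignment and ML
inference are delegated to MAFFT and FastTree through a two-method adapter
that validates only the contract (IDs preserved, rows equal length, leaf
set preserved) and treats content as opaque; the test suite substitutes
deterministic stubs, so nothing in the package's logic depends on the
external tools being present.

## Anomaly detection

The detector formalizes "clusters far from its expected clade" with two
primitives on the rooted, taxonomy-parsed tree:

* **Neighborhood** of a leaf: walk from its parent toward the root and take
  the first ancestor whose leaf set (excluding the leaf, its conspecifics
  and all outgroups) reaches `min_neighbors` (default 5); if none does, the
  largest such set. This is the smallest phylogenetic context that actually
  says something about placement; very small contexts (a lone sister leaf)
  are unreliable, hence the minimum size.
* **Match level**: the best rank shared with that neighborhood — genus,
  else family, else order, else none. A leaf "passes" when its level
  reaches `flag_level` (family by default; configurable because some
  datasets only support order-level resolution).

Species are then screened by sequence count. Singletons are flagged green
when they fail the level test; a species that is its family's sole
representative in the tree would fail by construction, so with
`monotypic_fallback` (default on) such species are evaluated at order
level instead. Pairs that are not monophyletic have each leaf evaluated
separately: exactly one passing means the other is the displaced one
(blue); zero or two passing means the placement is genuinely unclear and
both are flagged — a deliberate formalization of "unclear clustering" by
the two level tests alone, with no branch-length thresholds. For three or
more sequences, the species' *largest clean clade* (the biggest clade
containing only that species' leaves; ties broken by the clade
neighborhood's match level, then by preorder position; if no two leaves
form a clean clade, the single best-placed leaf) is taken as the core, and
everything outside it is flagged red. Outgroups are never flagged and never
count as neighbors. Multifurcating trees are handled natively — clades are
node leaf-sets, nothing is arbitrarily resolved — because real FastTree
output rooted on an outgroup is frequently non-binary.

Flags are sorted by (color, species, accession) and written as a
tab-separated `clustering_anomalies.txt` (columns: group_id, color,
anomaly_type, species, accession, tree_file, note — the column layout is
this package's own, chosen to make review edits trivially diffable).
`render_annotated_tree()` renders each group tree with flagged leaves in
their flag colors and outgroups in grey; the drawing model is returned as
data so tests assert on it rather than on pixels.

## Review and release

Manual review edits the flag file (delete a row = false positive, keep =
confirmed error) and moves indistinguishable groups into `similar.txt`
(one comma-separated group per line, validated to contain at least two
members and no accession twice; accessions are matched
version-insensitively but stored with versions). `auto_delete` skips review
and confirms every flag. The release step blacklists confirmed accessions,
annotates retained members of similar groups with `similar_to=` tags
naming one representative per *other* species in the group (RefSeq
preferred, else smallest accession, ordered by species name — the record's
own species representative is omitted, matching the worked header
convention), and writes a directory named `MitoDB_vYYMMDD` with curated
GenBank (verbatim original entries, annotations preserved), curated FASTA,
clean/black lists, a summary report and a per-family quality table
(`error_seq` / `similar_seq` / `others_seq`, with proportions normalized to
one per family and log-scaled counts for plotting). Clean and black lists
always partition the post-filter accession set — the bookkeeping invariant
the tests enforce at every scale.

## The synthetic-data module

`make_records()` and `make_tree()` define the study conditions for all
tests. Records are drawn from a nested taxonomy with sequence divergence
tiered at roughly 0.5% within species, 3% within genus and 8% within family
(fixed, field-plausible values; they matter only if the external tools are
exercised for real), realistic DEFINITION lines, feature tables in varied
annotation styles (gene vs product vs note labels, ND6 on the minus
strand), and controllable fractions of RefSeq accessions, identical
RefSeq/INSDC twins and `sp.` organisms. Trees are taxonomy-concordant by
construction, rooted on a two-leaf outgroup clade, and anomalies are
*planted* with exact ground truth: relabeling a one-sequence species into a
foreign family (Type I), grafting one leaf of a pair into a foreign genus
(Type II), or moving a minority of a 4–5-sequence species (Type III).
Plants are kept independent — each touches two families and no family is
touched twice — and touched families are padded to at least
`min_family_leaves` (default 5, matching the detector's default
neighborhood size) so the planted signal cannot leak past the family level
and the truth table is exact rather than approximate. What the generator
does **not** emulate: alignment error, rate heterogeneity, gene-tree
discordance from real coalescent processes, or GenBank's long tail of
format pathologies. Passing the planted-recovery tests therefore
demonstrates the detector's logic, not its error rate on real data, where
"truth" is itself uncertain — which is exactly why the workflow keeps a
manual review step.

## Numerical and scale choices

Test and acceptance runs use 50 concordant trees of 60–300 leaves, 100
planted-anomaly trees, 500 small trees (≤ 12 leaves) for
oracle-equivalence against exhaustive clade enumeration, and 1000
randomized record sets for the filtering contracts — sizes chosen so the
full suite completes in a couple of minutes on one CPU while exercising
every rule at realistic taxonomy shapes. All randomness flows from
explicit seeds; per-species RNG streams are derived by a deterministic
31-bit string hash so results are independent of iteration order.
Degenerate inputs fail loudly with typed conditions (`bad_header`,
`bad_span`, `group_too_small`, `degenerate_tree`, `version_exists`, ...)
rather than propagating silently.

## Known limitations

Order/family resolution from unlabeled GenBank lineages relies on suffix
heuristics (`-formes`, `-idae`) with a user lookup for exceptions — fine
for fishes, incomplete elsewhere. The detector uses topology only; no
branch lengths, support values or statistical placement tests, and no
machine-learning scoring. Subsampling may discard genuine intraspecific
variation. Nuclear markers and automatic database updates are out of
scope.
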