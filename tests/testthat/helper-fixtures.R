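# Shared builders for in-code fixtures. Everything is generated at test time;
# nothing is read from disk.

leaf_h <- function(species, acc, family = "Testidae", order = "Testiformes",
                   genus = sub("_.*", "", species), type = "Concat") {
  paste(species, acc, type, paste0("o__", order), paste0("f__", family),
        paste0("g__", genus), sep = "|")
}

mk_tree <- function(nwk, outgroups = character(0)) {
  as_ref_tree(ape::read.tree(text = nwk), outgroup_ids = outgroups)
}

mk_record <- function(accession, species = "Genus_alpha",
                      genus = sub("_.*", "", species),
                      family = "Testidae", order = "Testiformes",
                      organism = gsub("_", " ", species),
                      definition = paste0(organism,
                                          " mitochondrion, complete genome"),
                      sequence = strrep("ACGT", 150),
                      features = NULL, submitter = "Smith,J.",
                      geo_origin = "Japan") {
  if (is.null(features)) {
    features <- tibble::tibble(
      kind = character(0), gene = character(0), product = character(0),
      note = character(0), start = integer(0), end = integer(0),
      strand = character(0), location = character(0)
    )
  }
  tibble::tibble(
    accession = accession, species = species, genus = genus, family = family,
    order = order, organism = organism, definition = definition,
    record_type = if (is_complete_definition(definition)) "Complete" else "Partial",
    sequence = sequence, features = list(features), submitter = submitter,
    geo_origin = geo_origin, is_refseq = startsWith(accession, "NC_"),
    gb_text = NA_character_
  )
}

feat_row <- function(kind, start, end, strand = "+", gene = "", product = "",
                     note = "") {
  tibble::tibble(
    kind = kind, gene = gene, product = product, note = note,
    start = as.integer(start), end = as.integer(end), strand = strand,
    location = if (strand == "-") paste0("complement(", start, "..", end, ")")
      else paste0(start, "..", end)
  )
}

# Independent reverse-complement oracle (no Biostrings).
rc_oracle <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# Random small labeled tree for oracle-equivalence checks: 4-12 leaves,
# 2-4 species spread over two genera/families.
random_labeled_tree <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(4:12, 1)
    phy <- ape::rtree(n)
    n_sp <- sample(2:4, 1)
    sp_names <- paste0("Gen", letters[seq_len(n_sp)], "_species")
    fams <- paste0(c("Prim", "Secun", "Terti", "Quart"), "idae")[seq_len(n_sp)]
    assign_sp <- sort(sample(seq_len(n_sp), n, replace = TRUE))
    phy$tip.label <- vapply(seq_len(n), function(i) {
      k <- assign_sp[i]
      leaf_h(sp_names[k], sprintf("TT%04d.1", i), family = fams[k],
             order = "Testiformes")
    }, character(1))
    as_ref_tree(phy)
  })
}

# Exhaustive clade enumeration through ape::prop.part — an independent code
# path from the package's own postorder accumulation.
all_clades <- function(tree) {
  phy <- tree$phy
  pp <- ape::prop.part(phy)
  internal <- lapply(pp, as.integer)
  c(internal, as.list(seq_len(ape::Ntip(phy))))
}
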