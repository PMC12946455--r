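#' Partition records into order-level groups for tree inference
#'
#' Building one phylogeny for thousands of sequences is slow and fragile;
#' instead records are grouped by taxonomic order under a per-file cap so
#' trees can be inferred independently (and in parallel). Any order whose
#' count exceeds `max_per_file` becomes its own group without further
#' combination. The remaining orders are sorted by descending count (ties
#' broken alphabetically) and packed first-fit-decreasing into groups whose
#' totals never exceed the cap. Outgroup records are appended to every
#' group — they must be present everywhere for consistent rooting — and are
#' excluded from the cap accounting.
#'
#' @param records Records tibble; every row needs a non-missing `order`.
#' @param max_per_file Cap on ingroup sequences per group (default 2000).
#' @param outgroups Records tibble of outgroup sequences (may be empty).
#' @return Tibble with one row per group: `group_id`, `orders`
#'   (list-column), `n`, `records` (list-column), `outgroups` (list-column).
#' @export
group_by_order <- function(records, max_per_file = 2000, outgroups = NULL) {
  if (is.null(outgroups)) outgroups <- records[0, , drop = FALSE]
  if (any(is.na(records$order) | records$order == "")) {
    bad <- records$accession[is.na(records$order) | records$order == ""]
    abort(paste0("unresolved_order: records lack an order label: ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "mitocurate_unresolved_order")
  }
  counts <- records %>%
    count(.data$order, name = "n") %>%
    arrange(desc(.data$n), .data$order)

  oversized <- counts[counts$n > max_per_file, , drop = FALSE]
  rest <- counts[counts$n <= max_per_file, , drop = FALSE]

  bins <- list()
  for (ord in oversized$order) bins[[length(bins) + 1]] <- ord
  n_oversized <- length(bins)
  bin_load <- rep(Inf, n_oversized)           # oversized bins accept no more
  for (i in seq_len(nrow(rest))) {
    placed <- FALSE
    for (b in seq_along(bins)) {
      if (bin_load[b] + rest$n[i] <= max_per_file) {
        bins[[b]] <- c(bins[[b]], rest$order[i])
        bin_load[b] <- bin_load[b] + rest$n[i]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      bins[[length(bins) + 1]] <- rest$order[i]
      bin_load <- c(bin_load, rest$n[i])
    }
  }

  rows <- map(seq_along(bins), function(b) {
    orders <- bins[[b]]
    recs <- records[records$order %in% orders, , drop = FALSE]
    tibble(
      group_id = sprintf("group_%03d", b),
      orders = list(orders),
      n = nrow(recs),
      records = list(recs),
      outgroups = list(outgroups)
    )
  })
  bind_rows(rows)
}

#' External alignment and tree-inference adapters
#'
#' Alignment and maximum-likelihood inference are delegated to external
#' tools through a minimal adapter so the pipeline treats their content as
#' opaque and the test suite can substitute stubs. An aligner is a list
#' with an `align` function (named sequences in, named aligned sequences
#' out); a tree builder is a list with an `infer` function (named aligned
#' sequences in, Newick string out).
#'
#' `mafft_aligner()` and `fasttree_builder()` wrap the conventional command
#' lines (`mafft --thread N`, `fasttree -nt -fastest`); `stub_aligner()`
#' and `stub_tree_builder()` are deterministic in-process substitutes used
#' in tests.
#'
#' @param path Executable path.
#' @param threads Worker threads for MAFFT.
#' @param args Extra command-line arguments.
#' @return An adapter list.
#' @export
mafft_aligner <- function(path = "mafft", threads = 1, args = "--auto") {
  list(name = "mafft", align = function(seqs) {
    fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".aln")
    on.exit(unlink(c(fin, fout)))
    write_fasta(seqs, fin)
    status <- suppressWarnings(system2(
      path, c("--thread", threads, args, fin),
      stdout = fout, stderr = tempfile()
    ))
    if (!identical(status, 0L)) {
      abort("aligner_failed: mafft exited non-zero",
            class = "mitocurate_aligner_failed")
    }
    read_fasta(fout)
  })
}

#' @rdname mafft_aligner
#' @export
fasttree_builder <- function(path = "fasttree", args = c("-nt", "-fastest")) {
  list(name = "fasttree", infer = function(aln) {
    fin <- tempfile(fileext = ".aln"); fout <- tempfile(fileext = ".nwk")
    on.exit(unlink(c(fin, fout)))
    write_fasta(aln, fin)
    status <- suppressWarnings(system2(path, c(args, fin), stdout = fout,
                                       stderr = tempfile()))
    if (!identical(status, 0L)) {
      abort("treebuilder_failed: fasttree exited non-zero",
            class = "mitocurate_treebuilder_failed")
    }
    paste(readLines(fout, warn = FALSE), collapse = "")
  })
}

#' @rdname mafft_aligner
#' @export
stub_aligner <- function() {
  list(name = "stub", align = function(seqs) {
    w <- max(nchar(seqs))
    vapply(seqs, function(s) {
      paste0(s, strrep("-", w - nchar(s)))
    }, character(1))
  })
}

#' @rdname mafft_aligner
#' @export
stub_tree_builder <- function() {
  list(name = "stub", infer = function(aln) {
    ids <- names(aln)
    if (length(ids) < 2) abort("treebuilder_failed: need >= 2 sequences",
                               class = "mitocurate_treebuilder_failed")
    # deterministic caterpillar over the input order
    nwk <- ids[1]
    for (i in seq_along(ids)[-1]) nwk <- paste0("(", nwk, ",", ids[i], ")")
    paste0(nwk, ";")
  })
}

#' Align a group of sequences through an aligner adapter
#'
#' Runs the adapter and validates its contract: the aligned output must
#' contain exactly the input IDs and all rows must have equal length.
#' Alignment content is otherwise treated as opaque.
#'
#' @param seqs Named character vector of sequences.
#' @param aligner An aligner adapter (see [mafft_aligner()]).
#' @return Named character vector of aligned rows.
#' @export
align_group <- function(seqs, aligner = mafft_aligner()) {
  if (length(seqs) == 0) {
    abort("empty group: nothing to align", class = "mitocurate_empty_group")
  }
  aln <- aligner$align(seqs)
  if (!setequal(names(aln), names(seqs)) || length(aln) != length(seqs)) {
    abort("alignment_corrupt: aligner changed the sequence ID set",
          class = "mitocurate_alignment_corrupt")
  }
  if (length(unique(nchar(aln))) != 1) {
    abort("alignment_corrupt: aligned rows have unequal lengths",
          class = "mitocurate_alignment_corrupt")
  }
  aln
}

#' Infer a tree from an alignment through a builder adapter
#'
#' @param aln Named character vector of aligned rows.
#' @param builder A tree-builder adapter (see [fasttree_builder()]).
#' @return Unrooted Newick string whose leaf labels match the alignment
#'   IDs.
#' @export
infer_tree <- function(aln, builder = fasttree_builder()) {
  nwk <- builder$infer(aln)
  phy <- tryCatch(ape::read.tree(text = nwk), error = function(e) NULL)
  if (is.null(phy) || !setequal(phy$tip.label, names(aln))) {
    abort("tree_corrupt: leaf set does not match alignment IDs",
          class = "mitocurate_tree_corrupt")
  }
  nwk
}

#' Root a Newick tree on its outgroup and parse leaf taxonomy
#'
#' Reroots the tree on the edge subtending the most recent common ancestor
#' of the outgroup leaves (matched by accession, version-insensitively) and
#' parses every leaf's pipe-delimited header into taxonomy. Polytomies are
#' preserved.
#'
#' @param tree Newick string, file path to one, or an `ape::phylo`.
#' @param outgroup_ids Accessions of the outgroup sequences.
#' @return A `ref_tree` object: list with `phy` (rooted `phylo`), `leaves`
#'   (tibble of parsed headers with `tip` index and `is_outgroup`) and
#'   `outgroup_ids`.
#' @export
root_tree <- function(tree, outgroup_ids) {
  phy <- if (inherits(tree, "phylo")) tree
    else if (file.exists(tree[1]) && !grepl("\\(", tree[1])) ape::read.tree(tree)
    else ape::read.tree(text = tree)
  leaves <- parse_header(phy$tip.label)
  og_tips <- which(acc_base(leaves$accession) %in% acc_base(outgroup_ids))
  if (length(og_tips) == 0) {
    abort("outgroup_missing: no outgroup accession found among leaves",
          class = "mitocurate_outgroup_missing")
  }
  if (length(og_tips) < ape::Ntip(phy)) {
    phy <- ape::root(phy, outgroup = og_tips, resolve.root = TRUE)
  }
  as_ref_tree(phy, outgroup_ids = outgroup_ids)
}

#' Wrap a phylo object with parsed leaf taxonomy
#'
#' @param phy An `ape::phylo` whose tip labels use the pipe-delimited header
#'   dialect.
#' @param outgroup_ids Accessions treated as outgroups (may be empty).
#' @return A `ref_tree` object.
#' @export
as_ref_tree <- function(phy, outgroup_ids = character(0)) {
  leaves <- parse_header(phy$tip.label)
  leaves$tip <- seq_len(ape::Ntip(phy))
  leaves$is_outgroup <- acc_base(leaves$accession) %in% acc_base(outgroup_ids)
  structure(list(phy = phy, leaves = leaves, outgroup_ids = outgroup_ids),
            class = "ref_tree")
}

#' @export
print.ref_tree <- function(x, ...) {
  cat("<ref_tree> ", ape::Ntip(x$phy), " leaves (",
      sum(x$leaves$is_outgroup), " outgroup), ",
      length(unique(x$leaves$species[!x$leaves$is_outgroup])),
      " ingroup species\n", sep = "")
  invisible(x)
}

#' Run alignment and tree inference for every group
#'
#' Writes per-group FASTA, alignment and Newick files and returns the
#' rooted, taxonomy-parsed trees.
#'
#' @param groups Tibble from [group_by_order()].
#' @param dir Output directory.
#' @param targets Canonical genes used to build the concatenated input (see
#'   [concat_genes()]).
#' @param aligner,builder Adapters (see [mafft_aligner()]).
#' @param synonyms A [gene_synonyms()] table.
#' @return Named list of `ref_tree` objects, one per group.
#' @export
build_group_trees <- function(groups, dir, targets,
                              aligner = mafft_aligner(),
                              builder = fasttree_builder(),
                              synonyms = gene_synonyms()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (i in seq_len(nrow(groups))) {
    gid <- groups$group_id[i]
    recs <- bind_rows(groups$records[[i]], groups$outgroups[[i]])
    hdr_rec <- recs
    hdr_rec$record_type <- "Concat"
    seqs <- stats::setNames(
      vapply(seq_len(nrow(recs)), function(k) {
        concat_genes(recs[k, ], targets, synonyms)$concat
      }, character(1)),
      format_header(hdr_rec)
    )
    write_fasta(seqs, file.path(dir, paste0(gid, ".fa")))
    aln <- align_group(seqs, aligner)
    write_fasta(aln, file.path(dir, paste0(gid, ".aln")))
    nwk <- infer_tree(aln, builder)
    writeLines(nwk, file.path(dir, paste0(gid, ".nwk")))
    og <- groups$outgroups[[i]]$accession
    out[[gid]] <- if (length(og) > 0) root_tree(nwk, og)
      else as_ref_tree(ape::read.tree(text = nwk))
  }
  out
}
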