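#' Synonym table for mitochondrial marker genes
#'
#' GenBank feature tables name the same gene many ways: 12S may appear as
#' "12S", "12S rRNA", "s-rRNA" or "small subunit ribosomal RNA"; COX1 as
#' "COI", "CO1", "COX1", "COXI" or "cytochrome c oxidase subunit I". The
#' synonym table maps each canonical gene (the 13 protein-coding genes plus
#' the two rRNAs of the vertebrate mitogenome) to a set of case-insensitive,
#' word-boundary-anchored match patterns. Anchoring guards the classic
#' near-collisions: COX1 patterns never match COX3 labels, ND4 never matches
#' ND4L, ATP6 never matches ATP8, 12S never matches 16S. The table is
#' validated at construction: no built-in label may match two genes.
#'
#' @param extra Named list of additional patterns to merge in, e.g.
#'   `list("12S" = "MT-RNR1")`.
#' @return A named list of pattern character vectors, class
#'   `gene_synonyms`.
#' @export
gene_synonyms <- function(extra = NULL) {
  tbl <- list(
    `12S` = c("12S", "12S rRNA", "s-rRNA", "small subunit ribosomal RNA",
              "12S ribosomal RNA", "rrnS"),
    `16S` = c("16S", "16S rRNA", "l-rRNA", "large subunit ribosomal RNA",
              "16S ribosomal RNA", "rrnL"),
    ND1  = c("ND1", "NADH dehydrogenase subunit 1", "nad1", "NADH1"),
    ND2  = c("ND2", "NADH dehydrogenase subunit 2", "nad2", "NADH2"),
    COX1 = c("COI", "CO1", "COX1", "COXI", "cytochrome c oxidase subunit I"),
    COX2 = c("COII", "CO2", "COX2", "COXII", "cytochrome c oxidase subunit II"),
    ATP8 = c("ATP8", "ATPase 8", "ATPase8", "ATP synthase F0 subunit 8"),
    ATP6 = c("ATP6", "ATPase 6", "ATPase6", "ATP synthase F0 subunit 6"),
    COX3 = c("COIII", "CO3", "COX3", "COXIII", "cytochrome c oxidase subunit III"),
    ND3  = c("ND3", "NADH dehydrogenase subunit 3", "nad3", "NADH3"),
    ND4L = c("ND4L", "NADH dehydrogenase subunit 4L", "nad4L"),
    ND4  = c("ND4", "NADH dehydrogenase subunit 4", "nad4", "NADH4"),
    ND5  = c("ND5", "NADH dehydrogenase subunit 5", "nad5", "NADH5"),
    ND6  = c("ND6", "NADH dehydrogenase subunit 6", "nad6", "NADH6"),
    CYTB = c("CYTB", "cytb", "cob", "cytochrome b", "CYB")
  )
  if (is.null(extra)) {
    if (is.null(.syn_cache$default)) {
      validate_synonyms(tbl)
      .syn_cache$default <- structure(tbl, regex = compile_synonyms(tbl),
                                      class = "gene_synonyms")
    }
    return(.syn_cache$default)
  }
  for (g in names(extra)) {
    if (!g %in% names(tbl)) abort(paste0("unknown_gene: ", g),
                                  class = "mitocurate_unknown_gene")
    tbl[[g]] <- unique(c(tbl[[g]], extra[[g]]))
  }
  validate_synonyms(tbl)
  structure(tbl, regex = compile_synonyms(tbl), class = "gene_synonyms")
}

.syn_cache <- new.env(parent = emptyenv())

compile_synonyms <- function(tbl) {
  lapply(tbl, function(pats) {
    paste0("(?:", paste(vapply(pats, pattern_regex, character(1)),
                        collapse = ")|(?:"), ")")
  })
}

# Canonical vertebrate mitogenome gene order used for concatenation.
#' @rdname gene_synonyms
#' @export
mito_gene_order <- function() {
  c("12S", "16S", "ND1", "ND2", "COX1", "COX2", "ATP8", "ATP6", "COX3",
    "ND3", "ND4L", "ND4", "ND5", "ND6", "CYTB")
}

pattern_regex <- function(pattern) {
  paste0("\\b", gsub("([^A-Za-z0-9 ])", "\\\\\\1", pattern), "\\b")
}

label_matches <- function(label, patterns) {
  if (is.na(label) || label == "") return(FALSE)
  any(vapply(patterns, function(p) {
    grepl(pattern_regex(p), label, ignore.case = TRUE, perl = TRUE)
  }, logical(1)))
}

validate_synonyms <- function(tbl) {
  labels <- unlist(tbl, use.names = FALSE)
  owner <- rep(names(tbl), lengths(tbl))
  for (i in seq_along(labels)) {
    hits <- names(tbl)[vapply(tbl, function(p) label_matches(labels[i], p),
                              logical(1))]
    if (!identical(hits, owner[i])) {
      abort(paste0("synonym table ambiguous: label '", labels[i],
                   "' matches ", paste(hits, collapse = ", ")))
    }
  }
  invisible(tbl)
}

#' Synonym-tolerant gene matching on feature labels
#'
#' A feature matches a canonical gene when any of its `gene`, `product` or
#' `note` labels matches any of the gene's patterns, case-insensitively and
#' anchored at word boundaries.
#'
#' @param feature One row of a features tibble (columns `gene`, `product`,
#'   `note`).
#' @param gene Canonical gene name.
#' @param synonyms A [gene_synonyms()] table.
#' @return Logical scalar.
#' @export
match_gene <- function(feature, gene, synonyms = gene_synonyms()) {
  if (!gene %in% names(synonyms)) {
    abort(paste0("unknown_gene: ", gene), class = "mitocurate_unknown_gene")
  }
  rx <- attr(synonyms, "regex", exact = TRUE)
  rx <- if (is.null(rx)) compile_synonyms(synonyms)[[gene]] else rx[[gene]]
  labels <- c(feature$gene[1], feature$product[1], feature$note[1])
  labels <- labels[!is.na(labels) & labels != ""]
  length(labels) > 0 &&
    any(grepl(rx, labels, ignore.case = TRUE, perl = TRUE))
}

record_has_gene <- function(features, gene, synonyms) {
  if (nrow(features) == 0) return(FALSE)
  if (!gene %in% names(synonyms)) {
    abort(paste0("unknown_gene: ", gene), class = "mitocurate_unknown_gene")
  }
  rx <- attr(synonyms, "regex", exact = TRUE)
  rx <- if (is.null(rx)) compile_synonyms(synonyms)[[gene]] else rx[[gene]]
  labels <- c(features$gene, features$product, features$note)
  labels <- labels[!is.na(labels) & labels != ""]
  length(labels) > 0 && any(grepl(rx, labels, ignore.case = TRUE, perl = TRUE))
}

#' Excise a target gene from a record
#'
#' Returns the nucleotide subsequence of the first feature (in feature-table
#' order) matching the gene. Coordinates follow the GenBank convention
#' (1-based, inclusive); `join()` parts are concatenated in listed order and
#' minus-strand features are reverse-complemented. When no feature matches,
#' `NA` is returned and callers fall back to the full sequence.
#'
#' @param record One-row records tibble.
#' @param gene Canonical gene name.
#' @param synonyms A [gene_synonyms()] table.
#' @return The excised sequence, or `NA_character_`.
#' @export
extract_gene <- function(record, gene, synonyms = gene_synonyms()) {
  feats <- record$features[[1]]
  if (is.null(feats) || nrow(feats) == 0) return(NA_character_)
  for (k in seq_len(nrow(feats))) {
    if (match_gene(feats[k, ], gene, synonyms)) {
      loc <- parse_location(feats$location[k])
      if (max(loc$parts$end) > nchar(record$sequence)) {
        abort(paste0("bad_span: feature extends past sequence end in ",
                     record$accession), class = "mitocurate_bad_span")
      }
      s <- paste(substring(record$sequence, loc$parts$start, loc$parts$end),
                 collapse = "")
      if (loc$strand == "-") s <- revcomp(s)
      return(s)
    }
  }
  NA_character_
}

#' Extract and concatenate target genes
#'
#' Excises each target and joins the available ones following the canonical
#' vertebrate mitogenome gene order ([mito_gene_order()]), regardless of
#' feature-table order; targets that cannot be located are skipped. If no
#' target at all can be extracted the full sequence is retained as the
#' concatenation (`fallback_used = TRUE`) to avoid losing records with
#' absent or inconsistent annotation.
#'
#' @param record One-row records tibble.
#' @param targets Canonical gene names (non-empty).
#' @param synonyms A [gene_synonyms()] table.
#' @return List with `per_gene` (named list of sequences, extracted targets
#'   only), `concat`, `full_length` and `fallback_used`.
#' @export
concat_genes <- function(record, targets, synonyms = gene_synonyms()) {
  stopifnot(length(targets) > 0)
  unknown <- setdiff(targets, names(synonyms))
  if (length(unknown) > 0) {
    abort(paste0("unknown_gene: ", paste(unknown, collapse = ", ")),
          class = "mitocurate_unknown_gene")
  }
  ordered <- intersect(mito_gene_order(), targets)
  per_gene <- list()
  for (g in ordered) {
    s <- extract_gene(record, g, synonyms)
    if (!is.na(s)) per_gene[[g]] <- s
  }
  fallback <- length(per_gene) == 0
  list(
    per_gene = per_gene,
    concat = if (fallback) record$sequence else
      paste(unlist(per_gene), collapse = ""),
    full_length = record$sequence,
    fallback_used = fallback
  )
}

#' Write per-gene, concatenated and full-length FASTA outputs
#'
#' Produces the three curated FASTA products for a set of records: one FASTA
#' per target gene (records where the gene was located), `concat.fa`
#' (concatenated targets, falling back to the full sequence when none could
#' be extracted) and `full.fa` (every record's complete sequence). All
#' files use the pipe-delimited header dialect; concatenated entries carry
#' record type `Concat`.
#'
#' @param records Records tibble.
#' @param targets Canonical gene names.
#' @param dir Output directory (created if needed).
#' @param synonyms A [gene_synonyms()] table.
#' @return Tibble of per-record extraction results, invisibly.
#' @export
write_gene_fastas <- function(records, targets, dir,
                              synonyms = gene_synonyms()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- map(seq_len(nrow(records)), function(i) {
    concat_genes(records[i, ], targets, synonyms)
  })
  plain <- format_header(records)
  concat_rec <- records
  concat_rec$record_type <- "Concat"
  concat_hdr <- format_header(concat_rec)

  for (g in intersect(mito_gene_order(), targets)) {
    idx <- which(map_lgl(res, function(r) g %in% names(r$per_gene)))
    if (length(idx) > 0) {
      seqs <- stats::setNames(map_chr(res[idx], function(r) r$per_gene[[g]]),
                              plain[idx])
      write_fasta(seqs, file.path(dir, paste0(g, ".fa")))
    }
  }
  write_fasta(stats::setNames(map_chr(res, "concat"), concat_hdr),
              file.path(dir, "concat.fa"))
  write_fasta(stats::setNames(records$sequence, plain),
              file.path(dir, "full.fa"))
  invisible(tibble(
    accession = records$accession,
    concat = map_chr(res, "concat"),
    fallback_used = map_lgl(res, "fallback_used")
  ))
}
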