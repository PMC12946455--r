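#' Filtering and subsampling configuration
#'
#' Quality control runs in two phases: record-level filtering and
#' species-level subsampling. Two mutually exclusive record-level modes are
#' supported. `complete` mode retains records whose DEFINITION line contains
#' (case-insensitively) a complete-genome keyword. `gene` mode additionally
#' retains partial records that contain any of the `target_genes` (located
#' by synonym-tolerant feature matching, see [match_gene()]) and exceed
#' `min_gene_length`; records with no feature annotations at all are also
#' retained in gene mode, since legacy submissions may hold the target
#' region without a labeled feature.
#'
#' @param mode `"complete"` or `"gene"`.
#' @param target_genes Canonical gene names (see [gene_synonyms()]);
#'   required in gene mode.
#' @param min_gene_length Minimum fragment length in bp (default 400),
#'   screening out very short or low-quality fragments.
#' @param keep_cf,keep_sp,keep_ssp,keep_hybrid Retain records whose organism
#'   carries the corresponding ambiguous qualifier (`cf.`, `sp.`, `ssp.`,
#'   hybrid `x`); all default to FALSE.
#' @param max_sequences Per-species retention quota (default 5).
#' @param rng_seed Global seed; each species draws from an independent
#'   stream derived from `(rng_seed, species name)` so adding one species
#'   never perturbs another's draw.
#' @param complete_keywords Keyword set for the DEFINITION screen
#'   (extensible).
#' @return A `filter_config` list.
#' @export
filter_config <- function(mode = c("complete", "gene"),
                          target_genes = character(0),
                          min_gene_length = 400,
                          keep_cf = FALSE, keep_sp = FALSE,
                          keep_ssp = FALSE, keep_hybrid = FALSE,
                          max_sequences = 5, rng_seed = 1L,
                          complete_keywords = default_complete_keywords()) {
  mode <- match.arg(mode)
  if (min_gene_length <= 0) abort("bad_config: min_gene_length must be > 0",
                                  class = "mitocurate_bad_config")
  if (max_sequences < 1) abort("bad_config: max_sequences must be >= 1",
                               class = "mitocurate_bad_config")
  if (mode == "gene" && length(target_genes) == 0) {
    abort("bad_config: gene mode requires non-empty target_genes",
          class = "mitocurate_bad_config")
  }
  structure(list(
    mode = mode, target_genes = target_genes,
    min_gene_length = min_gene_length,
    keep_cf = keep_cf, keep_sp = keep_sp, keep_ssp = keep_ssp,
    keep_hybrid = keep_hybrid,
    max_sequences = as.integer(max_sequences),
    rng_seed = as.integer(rng_seed),
    complete_keywords = complete_keywords
  ), class = "filter_config")
}

default_complete_keywords <- function() {
  c("complete mitochondrial genome",
    "mitochondrion, complete genome",
    "whole mitochondrion",
    "complete mitogenome",
    "mitochondrial DNA, complete")
}

#' Does a DEFINITION line describe a complete mitogenome?
#'
#' Case-insensitive substring match of the DEFINITION line against the
#' complete-genome keyword set.
#'
#' @param definition Character vector of DEFINITION lines.
#' @param keywords Keyword set (default [default_complete_keywords()]).
#' @return Logical vector.
#' @examples
#' is_complete_definition("Pempheris schwenkii mitochondrion, complete genome")
#' @export
is_complete_definition <- function(definition,
                                   keywords = default_complete_keywords()) {
  d <- tolower(definition)
  d[is.na(d)] <- ""
  Reduce(`|`, lapply(tolower(keywords), function(k) {
    vapply(d, function(x) grepl(k, x, fixed = TRUE), logical(1), USE.NAMES = FALSE)
  }), rep(FALSE, length(d)))
}

#' Detect ambiguous taxonomic qualifiers in an organism name
#'
#' Organism strings carrying `cf.`, `sp.`, `ssp.` or a hybrid cross `x` are
#' taxonomically unreliable and excluded by default. Matching is on
#' standalone whitespace tokens, so "sp." never fires inside an epithet like
#' "spilota", and "x" only matches between name parts. Individual
#' qualifiers can be whitelisted through the `keep_*` config switches.
#'
#' @param organism Character vector of organism strings.
#' @param cfg A [filter_config()].
#' @return Character vector: the first matched qualifier
#'   (`"cf."`, `"sp."`, `"ssp."`, `"x"`) or `NA` if none applies.
#' @examples
#' cfg <- filter_config("complete")
#' has_ambiguous_qualifier("Epinephelus sp. BH-2014", cfg)
#' has_ambiguous_qualifier("Morelia spilota", cfg)
#' @export
has_ambiguous_qualifier <- function(organism, cfg = filter_config("complete")) {
  vapply(organism, function(o) {
    if (is.na(o)) return(NA_character_)
    toks <- tolower(strsplit(str_trim(o), "\\s+")[[1]])
    for (i in seq_along(toks)) {
      t <- toks[i]
      if (t == "cf." && !cfg$keep_cf) return("cf.")
      if (t == "ssp." && !cfg$keep_ssp) return("ssp.")
      if (t == "sp." && !cfg$keep_sp) return("sp.")
      if ((t == "x" || t == "×") && i > 1 && !cfg$keep_hybrid) return("x")
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Remove non-RefSeq duplicates of RefSeq records
#'
#' RefSeq entries (accession prefix `NC_`) are curated representatives;
#' whenever a RefSeq record and one or more INSDC submissions share
#' byte-identical sequence content, the non-RefSeq copies are redundant and
#' rejected with reason `duplicate_of_refseq`. Identical sequences with no
#' RefSeq member are left untouched here (they are collapsed later, at
#' subsampling).
#'
#' @param records Records tibble.
#' @return A list with `kept` (records tibble) and `rejected` (records
#'   tibble plus a `reason` column).
#' @export
refseq_dedup <- function(records) {
  if (nrow(records) == 0) {
    return(list(kept = records, rejected = add_reason(records, character(0))))
  }
  has_nc <- stats::ave(records$is_refseq, records$sequence, FUN = any)
  drop <- has_nc & !records$is_refseq
  list(kept = records[!drop, , drop = FALSE],
       rejected = add_reason(records[drop, , drop = FALSE],
                             rep("duplicate_of_refseq", sum(drop))))
}

add_reason <- function(records, reason) {
  records$reason <- reason
  records
}

#' Record-level filtering
#'
#' Applies the record-level screens in a fixed order: ambiguous-qualifier
#' screen, then the mode screen (complete / gene), then RefSeq-preferring
#' deduplication. Every input record lands in exactly one of `kept` /
#' `rejected`, and each rejection carries a single primary reason:
#' `ambiguous_qualifier`, `not_complete`, `no_target_gene`, `too_short` or
#' `duplicate_of_refseq`.
#'
#' @param records Records tibble from [parse_genbank()].
#' @param cfg A [filter_config()].
#' @param synonyms Gene synonym table for gene mode (see [gene_synonyms()]).
#' @return List with `kept` and `rejected` tibbles (the latter with a
#'   `reason` column).
#' @export
filter_records <- function(records, cfg, synonyms = gene_synonyms()) {
  stopifnot(inherits(cfg, "filter_config"))
  rejected <- add_reason(records[0, , drop = FALSE], character(0))

  qual <- has_ambiguous_qualifier(records$organism, cfg)
  rejected <- bind_rows(rejected,
                        add_reason(records[!is.na(qual), , drop = FALSE],
                                   rep("ambiguous_qualifier", sum(!is.na(qual)))))
  records <- records[is.na(qual), , drop = FALSE]

  complete <- is_complete_definition(records$definition, cfg$complete_keywords)
  if (cfg$mode == "complete") {
    rejected <- bind_rows(rejected,
                          add_reason(records[!complete, , drop = FALSE],
                                     rep("not_complete", sum(!complete))))
    records <- records[complete, , drop = FALSE]
  } else {
    n_feat <- vapply(records$features, nrow, integer(1))
    has_gene <- vapply(seq_len(nrow(records)), function(i) {
      any(vapply(cfg$target_genes, function(g) {
        record_has_gene(records$features[[i]], g, synonyms)
      }, logical(1)))
    }, logical(1))
    long_enough <- nchar(records$sequence) >= cfg$min_gene_length
    keep <- complete | ((has_gene | n_feat == 0) & long_enough)
    reason <- ifelse(!has_gene & n_feat > 0 & !complete, "no_target_gene",
                     "too_short")
    rejected <- bind_rows(rejected,
                          add_reason(records[!keep, , drop = FALSE], reason[!keep]))
    records <- records[keep, , drop = FALSE]
  }

  dd <- refseq_dedup(records)
  list(kept = dd$kept, rejected = bind_rows(rejected, dd$rejected))
}

species_seed <- function(rng_seed, species) {
  (as.integer(rng_seed) + str_hash(species)) %% 2147483647L
}

#' Species-level subsampling
#'
#' Caps each species at `max_sequences` representatives while preserving as
#' much submitter/geography diversity as possible. Byte-identical sequences
#' are collapsed first (RefSeq preferred, else the alphanumerically smallest
#' accession). If more than `max_sequences` distinct sequences remain, the
#' records are collapsed to one representative per (submitter, geographic
#' origin) key — RefSeq preferred, then the longest sequence, then smallest
#' accession — and any remaining excess is resolved uniformly at random with
#' an RNG stream seeded from `(rng_seed, species name)` so draws are
#' reproducible and independent across species. In gene mode complete
#' genomes are retained ahead of fragments and fragments fill the remaining
#' quota ranked by extracted target-gene length (descending, ties by
#' accession); no random draw is needed since the ranking is total.
#'
#' @param records Records tibble for a single species.
#' @param cfg A [filter_config()].
#' @param synonyms Gene synonym table (used in gene mode for ranking).
#' @return List with `retained` (tibble), `overflow` (tibble with `reason`
#'   `duplicate_identical` or `subsample_overflow`) and `n_before` (record
#'   count entering subsampling, the logged pre-subsample supply).
#' @export
subsample_species <- function(records, cfg, synonyms = gene_synonyms()) {
  stopifnot(inherits(cfg, "filter_config"))
  n_before <- nrow(records)
  if (n_before == 0) {
    return(list(retained = records,
                overflow = add_reason(records, character(0)), n_before = 0L))
  }
  if (length(unique(records$species)) > 1) {
    abort("subsample_species expects records of a single species")
  }
  overflow <- add_reason(records[0, , drop = FALSE], character(0))

  # (1) collapse byte-identical sequences
  ord <- order(records$sequence, !records$is_refseq, records$accession)
  r <- records[ord, , drop = FALSE]
  dup <- duplicated(r$sequence)
  overflow <- bind_rows(overflow,
                        add_reason(r[dup, , drop = FALSE],
                                   rep("duplicate_identical", sum(dup))))
  r <- r[!dup, , drop = FALSE]
  r <- r[order(r$accession), , drop = FALSE]

  if (nrow(r) <= cfg$max_sequences) {
    return(list(retained = r, overflow = overflow, n_before = n_before))
  }

  key <- paste(tolower(str_squish(r$submitter)),
               tolower(str_squish(r$geo_origin)), sep = "\r")

  if (cfg$mode == "complete") {
    pref <- order(key, !r$is_refseq, -nchar(r$sequence), r$accession)
    r2 <- r[pref, , drop = FALSE]
    drop <- duplicated(key[pref])
    overflow <- bind_rows(overflow,
                          add_reason(r2[drop, , drop = FALSE],
                                     rep("subsample_overflow", sum(drop))))
    r2 <- r2[!drop, , drop = FALSE]
    r2 <- r2[order(r2$accession), , drop = FALSE]
    if (nrow(r2) > cfg$max_sequences) {
      keep_idx <- withr::with_seed(
        species_seed(cfg$rng_seed, records$species[1]),
        sample(nrow(r2), cfg$max_sequences)
      )
      drop2 <- setdiff(seq_len(nrow(r2)), keep_idx)
      overflow <- bind_rows(overflow,
                            add_reason(r2[drop2, , drop = FALSE],
                                       rep("subsample_overflow", length(drop2))))
      r2 <- r2[sort(keep_idx), , drop = FALSE]
    }
    return(list(retained = r2, overflow = overflow, n_before = n_before))
  }

  # gene mode: complete genomes first, fragments ranked by target-gene length
  complete <- is_complete_definition(r$definition, cfg$complete_keywords)
  glen <- vapply(seq_len(nrow(r)), function(i) {
    lens <- vapply(cfg$target_genes, function(g) {
      s <- extract_gene(r[i, ], g, synonyms)
      if (is.na(s)) 0L else nchar(s)
    }, integer(1))
    max(c(lens, 0L))
  }, integer(1))

  pref <- order(key, !complete, !r$is_refseq, -glen, r$accession)
  drop <- duplicated(key[pref])
  keep1 <- pref[!drop]
  overflow <- bind_rows(overflow,
                        add_reason(r[pref[drop], , drop = FALSE],
                                   rep("subsample_overflow", sum(drop))))
  r2 <- r[keep1, , drop = FALSE]
  complete2 <- complete[keep1]
  glen2 <- glen[keep1]
  rank <- order(!complete2, ifelse(complete2, as.integer(!r2$is_refseq), 1L),
                ifelse(complete2, 0L, -glen2), r2$accession)
  r2 <- r2[rank, , drop = FALSE]
  if (nrow(r2) > cfg$max_sequences) {
    drop2 <- seq(cfg$max_sequences + 1L, nrow(r2))
    overflow <- bind_rows(overflow,
                          add_reason(r2[drop2, , drop = FALSE],
                                     rep("subsample_overflow", length(drop2))))
    r2 <- r2[seq_len(cfg$max_sequences), , drop = FALSE]
  }
  r2 <- r2[order(r2$accession), , drop = FALSE]
  list(retained = r2, overflow = overflow, n_before = n_before)
}

#' Subsample every species and log pre-subsample supply
#'
#' Applies [subsample_species()] per species and returns both the combined
#' outcome and the per-species supply table that is written to the output
#' directory for parameter tuning.
#'
#' @param records Records tibble (post record-level filtering).
#' @param cfg A [filter_config()].
#' @param synonyms Gene synonym table.
#' @param summary_path Optional path for the per-species TSV summary
#'   (columns `species`, `n_before`, `n_retained`).
#' @return List with `retained`, `overflow` and `summary` (tibble).
#' @export
subsample_records <- function(records, cfg, synonyms = gene_synonyms(),
                              summary_path = NULL) {
  species <- sort(unique(records$species))
  parts <- map(species, function(sp) {
    subsample_species(records[records$species == sp, , drop = FALSE],
                      cfg, synonyms)
  })
  retained <- bind_rows(map(parts, "retained"))
  overflow <- bind_rows(map(parts, "overflow"))
  if (nrow(overflow) == 0) overflow <- add_reason(records[0, ], character(0))
  summary <- tibble(
    species = species,
    n_before = map_int(parts, "n_before"),
    n_retained = map_int(parts, function(p) nrow(p$retained))
  )
  if (!is.null(summary_path)) {
    utils::write.table(summary, summary_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(retained = retained, overflow = overflow, summary = summary)
}
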