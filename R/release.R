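#' Apply manual-review decisions to the flag list
#'
#' After manual review the edited `clustering_anomalies.txt` contains only
#' confirmed errors (reviewers delete false-positive rows, and move
#' indistinguishable groups to `similar.txt`). This step partitions the
#' dataset: confirmed flags become the blacklist, everything else is
#' retained, and retained members of similar groups are mapped to their
#' group for header annotation. With `auto_delete` the manual step is
#' skipped and every detected flag is treated as confirmed.
#'
#' @param flags Flags tibble (edited, or raw when `auto_delete`).
#' @param records Post-filter records tibble.
#' @param similar Similar-groups tibble from [read_similar_file()] (or
#'   NULL).
#' @param auto_delete Treat all flags as confirmed without review.
#' @return List with `blacklist` (accessions), `clean_records` (tibble) and
#'   `similar_map` (tibble `accession`, `group_id`).
#' @export
apply_review <- function(flags, records, similar = NULL, auto_delete = FALSE) {
  if (is.null(similar)) similar <- tibble(group_id = integer(0), members = list())
  unknown <- setdiff(acc_base(flags$accession), acc_base(records$accession))
  if (length(unknown) > 0) {
    abort(paste0("unknown_accession: flags reference accessions absent from ",
                 "the dataset: ", paste(unknown, collapse = ", ")),
          class = "mitocurate_unknown_accession")
  }
  sim_acc <- acc_base(unlist(similar$members))
  overlap <- intersect(acc_base(flags$accession), sim_acc)
  if (length(overlap) > 0) {
    abort(paste0("accession both confirmed-flagged and in a similar group: ",
                 paste(overlap, collapse = ", ")),
          class = "mitocurate_review_conflict")
  }
  blacklist <- records$accession[acc_base(records$accession) %in%
                                   acc_base(flags$accession)]
  clean <- records[!records$accession %in% blacklist, , drop = FALSE]
  similar_map <- bind_rows(map(seq_len(nrow(similar)), function(i) {
    tibble(accession = similar$members[[i]], group_id = similar$group_id[i])
  }))
  if (nrow(similar_map) == 0) {
    similar_map <- tibble(accession = character(0), group_id = integer(0))
  }
  # drop group members not retained in the dataset
  similar_map <- similar_map[acc_base(similar_map$accession) %in%
                               acc_base(clean$accession), , drop = FALSE]
  list(blacklist = blacklist, clean_records = clean, similar_map = similar_map)
}

#' Species-level representatives of a similar group
#'
#' A `similar_to=` header names one representative accession per species in
#' the indistinguishable group: the RefSeq (`NC_`) accession when the
#' species has one, otherwise the first accession in alphanumeric order.
#' Output is ordered by species name.
#'
#' @param members Accessions of one similar group.
#' @param records Records tibble used to resolve each accession's species.
#' @return Character vector of representative accessions.
#' @export
select_representatives <- function(members, records) {
  pos <- match(acc_base(members), acc_base(records$accession))
  if (any(is.na(pos))) {
    abort(paste0("unknown_accession: ", paste(members[is.na(pos)], collapse = ", ")),
          class = "mitocurate_unknown_accession")
  }
  d <- tibble(accession = members, species = records$species[pos],
              is_refseq = startsWith(members, "NC_"))
  d %>%
    arrange(.data$species, desc(.data$is_refseq), .data$accession) %>%
    group_by(.data$species) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(.data$species) %>%
    pull(.data$accession)
}

#' Annotated FASTA header for a retained record
#'
#' Records belonging to a similar group get a `similar_to=` segment listing
#' the group's species representatives, excluding the representative of the
#' record's own species (the worked dialect: a record is not "similar to"
#' itself). Records in no group get the plain six-field header.
#'
#' @param record One-row records tibble.
#' @param similar Similar-groups tibble.
#' @param records Full records tibble for representative resolution.
#' @return Header string.
#' @export
annotate_similar_to <- function(record, similar, records) {
  grp <- NULL
  for (i in seq_len(nrow(similar))) {
    if (acc_base(record$accession) %in% acc_base(similar$members[[i]])) {
      grp <- similar$members[[i]]
      break
    }
  }
  if (is.null(grp)) return(format_header(record))
  reps <- select_representatives(grp, records)
  pos <- match(acc_base(reps), acc_base(records$accession))
  own <- records$species[pos] == record$species
  format_header(record, similar_to = reps[!own])
}

#' Assemble the versioned curated database
#'
#' Consolidates retained records into a release directory named
#' `MitoDB_vYYMMDD`: curated GenBank (annotations preserved), curated FASTA
#' with annotated headers, `cleanlist.txt`, `blacklist.txt`, a plain-text
#' summary report and the per-family quality table. The clean and black
#' lists partition the post-filter accession set.
#'
#' @param clean_records Retained records tibble.
#' @param blacklist Accessions removed as confirmed anomalies.
#' @param similar Similar-groups tibble (may be NULL).
#' @param date Release date (`Date` or `"YYYY-MM-DD"`).
#' @param dir Parent output directory.
#' @param top_n Families in the quality table.
#' @return A `mitodb_release` manifest: `version`, `path`, `cleanlist`,
#'   `blacklist`, `n_sequences`, `n_species`, `family_stats`.
#' @export
assemble_release <- function(clean_records, blacklist, similar = NULL,
                             date = Sys.Date(), dir = ".", top_n = 10) {
  if (is.null(similar)) similar <- tibble(group_id = integer(0), members = list())
  version <- paste0("MitoDB_v", format(as.Date(date), "%y%m%d"))
  out <- file.path(dir, version)
  if (dir.exists(out)) {
    abort(paste0("version_exists: ", out), class = "mitocurate_version_exists")
  }
  dir.create(out, recursive = TRUE)

  headers <- vapply(seq_len(nrow(clean_records)), function(i) {
    annotate_similar_to(clean_records[i, ], similar, clean_records)
  }, character(1))
  write_fasta(stats::setNames(clean_records$sequence, headers),
              file.path(out, paste0(version, ".fa")))
  write_genbank(clean_records, file.path(out, paste0(version, ".gb")))
  writeLines(sort(clean_records$accession), file.path(out, "cleanlist.txt"))
  writeLines(sort(blacklist), file.path(out, "blacklist.txt"))

  similar_map <- bind_rows(
    tibble(accession = character(0), group_id = integer(0)),
    map(seq_len(nrow(similar)), function(i) {
      tibble(accession = similar$members[[i]], group_id = similar$group_id[i])
    })
  )
  stats <- family_quality_table(clean_records, blacklist,
                                similar_map, top_n = top_n)
  utils::write.table(stats, file.path(out, "family_quality.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  n_species <- length(unique(clean_records$species))
  summary_lines <- c(
    paste0("version: ", version),
    paste0("sequences: ", nrow(clean_records)),
    paste0("species: ", n_species),
    paste0("blacklisted: ", length(blacklist)),
    paste0("similar-annotated: ",
           sum(acc_base(clean_records$accession) %in%
                 acc_base(unlist(similar$members)))),
    paste0("orders: ", length(unique(stats::na.omit(clean_records$order)))),
    paste0("families: ", length(unique(stats::na.omit(clean_records$family))))
  )
  writeLines(summary_lines, file.path(out, "summary.txt"))

  structure(list(
    version = version, path = out,
    cleanlist = sort(clean_records$accession), blacklist = sort(blacklist),
    n_sequences = nrow(clean_records), n_species = n_species,
    family_stats = stats
  ), class = "mitodb_release")
}

#' @export
print.mitodb_release <- function(x, ...) {
  cat("<mitodb_release> ", x$version, ": ", x$n_sequences, " sequences, ",
      x$n_species, " species (", length(x$blacklist), " blacklisted)\n",
      sep = "")
  invisible(x)
}

#' Per-family annotation-quality table
#'
#' For the `top_n` families by total record count, splits each family's
#' records into erroneous (`error_seq`, blacklisted), ambiguous
#' (`similar_seq`, retained with a similar annotation) and reliable
#' (`others_seq`) sequences, with per-family proportions normalized to 1
#' and log10-scaled counts for plotting.
#'
#' @param records Records tibble (retained records; blacklisted records may
#'   be included or supplied implicitly through `blacklist`).
#' @param blacklist Accessions removed as errors.
#' @param similar_map Tibble `accession`, `group_id` of similar-annotated
#'   records.
#' @param top_n Number of families (default 10).
#' @param all_records Optional tibble covering blacklisted records too (for
#'   family totals); defaults to `records`.
#' @return Tibble with counts, proportions and log-scaled counts per
#'   family.
#' @export
family_quality_table <- function(records, blacklist, similar_map,
                                 top_n = 10, all_records = NULL) {
  pool <- all_records %||% records
  if (any(is.na(pool$family) | pool$family == "")) {
    abort("family label required for every record in the quality table")
  }
  bl <- acc_base(blacklist)
  sim <- acc_base(similar_map$accession)
  counts <- pool %>%
    mutate(
      class = case_when(
        acc_base(.data$accession) %in% bl ~ "error_seq",
        acc_base(.data$accession) %in% sim ~ "similar_seq",
        TRUE ~ "others_seq"
      )
    ) %>%
    count(.data$family, .data$class) %>%
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
  for (cl in c("error_seq", "similar_seq", "others_seq")) {
    if (!cl %in% names(counts)) counts[[cl]] <- 0L
  }
  counts %>%
    mutate(total = .data$error_seq + .data$similar_seq + .data$others_seq) %>%
    arrange(desc(.data$total), .data$family) %>%
    slice_head(n = top_n) %>%
    mutate(
      prop_error = .data$error_seq / .data$total,
      prop_similar = .data$similar_seq / .data$total,
      prop_others = .data$others_seq / .data$total,
      log_error = log10(.data$error_seq + 1),
      log_similar = log10(.data$similar_seq + 1),
      log_others = log10(.data$others_seq + 1)
    )
}

#' Percentage of records removed, at the printed precision
#'
#' Convenience for reporting removal rates, e.g. RefSeq entries removed by
#' phylogenetic conflict, as a percentage rounded to two decimals.
#'
#' @param removed,total Counts.
#' @return `100 * removed / total`, rounded to 2 decimals.
#' @examples
#' removal_percentage(128, 3788)
#' @export
removal_percentage <- function(removed, total) {
  round(100 * removed / total, 2)
}
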