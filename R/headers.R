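#' Pipe-delimited FASTA header dialect
#'
#' Curated FASTA outputs label every sequence with a pipe-delimited header
#' carrying the binomial, accession, record type and three taxonomic ranks:
#'
#' ```
#' Genus_species|Accession|RecordType|o__Order|f__Family|g__Genus
#' ```
#'
#' Records that belong to a group of phylogenetically indistinguishable
#' sequences additionally carry a `similar_to=` segment listing representative
#' accessions of the other species in the group, e.g.
#' `...|g__Microphysogobio|similar_to= NC_051965.1, NC_086467.1|` (note the
#' single space after `=`, the comma-space separators and the terminal pipe).
#'
#' `format_header()` emits this dialect; `parse_header()` inverts it. The two
#' functions are a bijection on valid records: a trailing pipe on a header
#' without a `similar_to=` segment is tolerated when parsing but never
#' emitted.
#'
#' @param records A records tibble with columns `species`, `accession`,
#'   `record_type`, `order`, `family`, `genus` (species in `Genus_species`
#'   underscore form).
#' @param similar_to Representative accessions to append: `NULL`, a character
#'   vector (recycled single header), or a list parallel to the rows of
#'   `records`; empty elements produce plain six-field headers.
#' @return `format_header()`: a character vector of headers.
#'   `parse_header()`: a tibble with columns `species`, `accession`,
#'   `record_type`, `order`, `family`, `genus` and a list-column `similar_to`.
#' @examples
#' rec <- tibble::tibble(
#'   species = "Amblyraja_georgiana", accession = "LOCAL_2025_001",
#'   record_type = "User_sequence", order = "Rajiformes",
#'   family = "Rajidae", genus = "Amblyraja"
#' )
#' h <- format_header(rec)
#' parse_header(h)$accession
#' @export
format_header <- function(records, similar_to = NULL) {
  req <- c("species", "accession", "record_type", "order", "family", "genus")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("records lack columns: ", paste(missing_cols, collapse = ", ")),
          class = "mitocurate_bad_taxonomy")
  }
  ranks <- records[c("order", "family", "genus")]
  if (any(vapply(ranks, function(v) any(is.na(v) | v == ""), logical(1)))) {
    abort("bad_taxonomy: order/family/genus must be complete to format a header",
          class = "mitocurate_bad_taxonomy")
  }
  if (is.character(similar_to)) similar_to <- list(similar_to)
  if (is.null(similar_to)) similar_to <- rep(list(character(0)), nrow(records))
  stopifnot(length(similar_to) == nrow(records))
  base <- paste(records$species, records$accession, records$record_type,
                paste0("o__", records$order), paste0("f__", records$family),
                paste0("g__", records$genus), sep = "|")
  tag <- vapply(similar_to, function(s) {
    if (length(s) == 0) "" else paste0("|similar_to= ", paste(s, collapse = ", "), "|")
  }, character(1))
  paste0(base, tag)
}

#' @rdname format_header
#' @param headers Character vector of headers to parse.
#' @export
parse_header <- function(headers) {
  parts <- strsplit(headers, "|", fixed = TRUE)
  nf <- lengths(parts)  # strsplit drops the empty field after a trailing pipe
  bad <- which(nf < 6 | nf > 7)
  if (length(bad) > 0) {
    abort(paste0("bad_header: expected 6 fields (plus optional similar_to): ",
                 headers[bad[1]]), class = "mitocurate_bad_header")
  }
  field <- function(k) vapply(parts, `[[`, character(1), k)
  f4 <- field(4); f5 <- field(5); f6 <- field(6)
  bad <- which(!startsWith(f4, "o__") | !startsWith(f5, "f__") |
                 !startsWith(f6, "g__"))
  if (length(bad) > 0) {
    abort(paste0("bad_header: missing o__/f__/g__ rank prefixes: ",
                 headers[bad[1]]), class = "mitocurate_bad_header")
  }
  similar_to <- rep(list(character(0)), length(parts))
  for (i in which(nf == 7)) {
    p7 <- parts[[i]][7]
    if (!startsWith(p7, "similar_to=")) {
      abort(paste0("bad_header: seventh field must be similar_to=: ",
                   headers[i]), class = "mitocurate_bad_header")
    }
    sim <- str_trim(strsplit(sub("^similar_to=", "", p7), ",",
                             fixed = TRUE)[[1]])
    similar_to[[i]] <- sim[sim != ""]
  }
  tibble(
    species = field(1), accession = field(2), record_type = field(3),
    order = substring(f4, 4), family = substring(f5, 4),
    genus = substring(f6, 4), similar_to = similar_to
  )
}

#' Read and write curation text files
#'
#' `similar.txt` records groups of sequences judged indistinguishable on the
#' tree during manual review: one group per line, accessions separated by
#' commas. `clustering_anomalies.txt` is the tab-separated flag report written
#' by [detect_anomalies()] and edited during review: columns `group_id`,
#' `color`, `anomaly_type`, `species`, `accession`, `tree_file`, `note`.
#' Blank lines and lines starting with `#` are ignored in both files.
#'
#' @param x File path or literal text.
#' @return `read_similar_file()`: a tibble with `group_id` (integer) and a
#'   list-column `members`. `read_anomaly_file()`: a flags tibble as produced
#'   by [detect_anomalies()].
#' @export
read_similar_file <- function(x) {
  lines <- str_trim(read_text_lines(x))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  members <- map(lines, function(l) {
    m <- str_trim(strsplit(l, ",", fixed = TRUE)[[1]])
    m <- m[m != ""]
    if (length(m) < 2) {
      abort(paste0("group_too_small: a similar group needs >= 2 accessions: ", l),
            class = "mitocurate_group_too_small")
    }
    m
  })
  all_acc <- acc_base(unlist(members))
  if (anyDuplicated(all_acc)) {
    abort(paste0("duplicate accession across similar groups: ",
                 paste(unique(all_acc[duplicated(all_acc)]), collapse = ", ")),
          class = "mitocurate_duplicate_accession")
  }
  tibble(group_id = seq_along(members), members = members)
}

#' @rdname read_similar_file
#' @param groups Tibble from `read_similar_file()` (or with a `members`
#'   list-column).
#' @param path Output file path.
#' @export
write_similar_file <- function(groups, path) {
  writeLines(vapply(groups$members, paste, character(1), collapse = ", "), path)
  invisible(path)
}

anomaly_colors <- c(singleton = "green", pairwise = "blue", cluster = "red")

flag_cols <- c("group_id", "color", "anomaly_type", "species", "accession",
               "tree_file", "note")

#' @rdname read_similar_file
#' @export
read_anomaly_file <- function(x) {
  lines <- read_text_lines(x)
  lines <- lines[str_trim(lines) != "" & !startsWith(str_trim(lines), "#")]
  if (length(lines) == 0 || (length(lines) == 1 && startsWith(lines[1], "group_id"))) {
    return(empty_flags())
  }
  if (startsWith(lines[1], "group_id")) lines <- lines[-1]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(flag_cols))
  if (length(bad) > 0) {
    abort(paste0("bad_flag: expected ", length(flag_cols),
                 " tab-separated fields at line ", bad[1]),
          class = "mitocurate_bad_flag")
  }
  out <- as_tibble(stats::setNames(
    as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE), flag_cols
  ))
  if (!all(out$color %in% anomaly_colors)) {
    abort(paste0("bad_flag: unknown anomaly color: ",
                 paste(setdiff(out$color, anomaly_colors), collapse = ", ")),
          class = "mitocurate_bad_flag")
  }
  if (!all(anomaly_colors[out$anomaly_type] == out$color)) {
    abort("bad_flag: color does not match anomaly_type",
          class = "mitocurate_bad_flag")
  }
  out[c("accession", "species", "anomaly_type", "color", "group_id",
        "tree_file", "note")]
}

#' @rdname read_similar_file
#' @param flags Flags tibble from [detect_anomalies()].
#' @export
write_anomaly_file <- function(flags, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(flag_cols, collapse = "\t"), con)
  if (nrow(flags) > 0) {
    rows <- flags[flag_cols]
    writeLines(do.call(paste, c(as.list(rows), sep = "\t")), con)
  }
  invisible(path)
}

empty_flags <- function() {
  tibble(accession = character(0), species = character(0),
         anomaly_type = character(0), color = character(0),
         group_id = character(0), tree_file = character(0),
         note = character(0))
}
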