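#' Parse GenBank flat files into a records tibble
#'
#' Reads zero or more GenBank flat-file entries and returns one row per
#' entry. Taxonomic ranks are resolved from the ORGANISM lineage lines:
#' GenBank lineages do not label ranks, so the order is taken as the last
#' lineage element matching the order suffix (default `-formes`, covering
#' fishes) and the family as the last element matching `-idae`, both
#' overridable through [taxonomy_rules()] for groups that do not follow the
#' suffix convention. Entries that fail to parse are reported in the
#' `rejects` component with reason `parse_error`, never silently dropped.
#'
#' @param x A file path or literal GenBank text.
#' @param rules A [taxonomy_rules()] list controlling rank resolution.
#' @return A list with components:
#'   * `records`: tibble with columns `accession` (versioned), `species`
#'     (`Genus_species`), `genus`, `family`, `order`, `organism`,
#'     `definition`, `record_type` (`Complete`/`Partial`), `sequence`,
#'     `features` (list-column of feature tibbles), `submitter`,
#'     `geo_origin`, `is_refseq`, `gb_text` (verbatim entry, used to
#'     preserve annotations on re-export).
#'   * `rejects`: tibble with `entry`, `accession`, `reason`.
#' @export
parse_genbank <- function(x, rules = taxonomy_rules()) {
  lines <- read_text_lines(x)
  term <- which(str_trim(lines) == "//")
  starts <- c(1L, head(term, -1) + 1L)
  records <- list()
  rejects <- list()
  if (length(term) > 0) {
    for (i in seq_along(term)) {
      chunk <- lines[starts[i]:term[i]]
      chunk <- chunk[str_trim(chunk) != "" | seq_along(chunk) > 1]
      res <- tryCatch(parse_gb_entry(chunk, rules), error = function(e) e)
      if (inherits(res, "error")) {
        acc <- sub("^ACCESSION\\s+(\\S+).*$", "\\1",
                   grep("^ACCESSION", chunk, value = TRUE)[1])
        rejects[[length(rejects) + 1]] <- tibble(
          entry = i, accession = if (is.na(acc)) NA_character_ else acc,
          reason = "parse_error"
        )
      } else {
        records[[length(records) + 1]] <- res
      }
    }
  }
  list(
    records = if (length(records)) bind_rows(records) else empty_records(),
    rejects = if (length(rejects)) bind_rows(rejects) else
      tibble(entry = integer(0), accession = character(0), reason = character(0))
  )
}

empty_records <- function() {
  tibble(
    accession = character(0), species = character(0), genus = character(0),
    family = character(0), order = character(0), organism = character(0),
    definition = character(0), record_type = character(0),
    sequence = character(0), features = list(), submitter = character(0),
    geo_origin = character(0), is_refseq = logical(0), gb_text = character(0)
  )
}

#' Rank-resolution rules for GenBank lineages
#'
#' GenBank ORGANISM lineages are unlabeled; ranks are recovered by suffix
#' heuristics with optional explicit lookups for taxa that break the
#' convention.
#'
#' @param order_suffix,family_suffix Regular expressions a lineage element
#'   must match to be read as the order / family.
#' @param order_names,family_names Character vectors of lineage elements to
#'   accept verbatim regardless of suffix (user-overridable lookup table).
#' @return A list used by [parse_genbank()].
#' @export
taxonomy_rules <- function(order_suffix = "formes$", family_suffix = "idae$",
                           order_names = character(0),
                           family_names = character(0)) {
  list(order_suffix = order_suffix, family_suffix = family_suffix,
       order_names = order_names, family_names = family_names)
}

parse_gb_entry <- function(chunk, rules) {
  block_at <- function(key) grep(paste0("^", key, "\\b"), chunk)

  # DEFINITION with continuation lines
  di <- block_at("DEFINITION")[1]
  definition <- ""
  if (!is.na(di)) {
    j <- di
    parts <- sub("^DEFINITION\\s+", "", chunk[di])
    while (j + 1 <= length(chunk) && grepl("^\\s{10,}", chunk[j + 1])) {
      j <- j + 1
      parts <- c(parts, str_trim(chunk[j]))
    }
    definition <- paste(parts, collapse = " ")
  }

  ai <- block_at("ACCESSION")[1]
  if (is.na(ai)) abort("entry has no ACCESSION line")
  acc_plain <- strsplit(str_trim(sub("^ACCESSION", "", chunk[ai])), "\\s+")[[1]][1]
  vi <- block_at("VERSION")[1]
  accession <- if (!is.na(vi)) {
    strsplit(str_trim(sub("^VERSION", "", chunk[vi])), "\\s+")[[1]][1]
  } else {
    acc_plain
  }
  if (is.na(accession) || accession == "") abort("empty accession")

  oi <- grep("^\\s{1,3}ORGANISM\\b", chunk)[1]
  organism <- ""
  lineage <- character(0)
  if (!is.na(oi)) {
    organism <- str_trim(sub("^\\s*ORGANISM\\s*", "", chunk[oi]))
    j <- oi
    lin <- character(0)
    while (j + 1 <= length(chunk) && grepl("^\\s{10,}\\S", chunk[j + 1])) {
      j <- j + 1
      lin <- c(lin, str_trim(chunk[j]))
    }
    lineage <- strsplit(sub("\\.$", "", paste(lin, collapse = " ")), ";\\s*")[[1]]
  }

  ord <- resolve_rank(lineage, rules$order_suffix, rules$order_names)
  fam <- resolve_rank(lineage, rules$family_suffix, rules$family_names)

  # submitter: first REFERENCE block's AUTHORS/CONSRTM text
  submitter <- ""
  ri <- block_at("REFERENCE")[1]
  if (!is.na(ri)) {
    au <- grep("^\\s{1,3}(AUTHORS|CONSRTM)\\b", chunk)
    au <- au[au > ri]
    if (length(au) > 0) {
      j <- au[1]
      parts <- str_trim(sub("^\\s*(AUTHORS|CONSRTM)\\s*", "", chunk[j]))
      while (j + 1 <= length(chunk) && grepl("^\\s{10,}\\S", chunk[j + 1]) &&
             !grepl("^\\s{1,3}[A-Z]", chunk[j + 1])) {
        j <- j + 1
        parts <- c(parts, str_trim(chunk[j]))
      }
      submitter <- paste(parts, collapse = " ")
    }
  }

  parsed <- parse_gb_features(chunk)
  geo <- parsed$geo_origin
  if (parsed$organism != "" && organism == "") organism <- parsed$organism

  seq_i <- block_at("ORIGIN")[1]
  sequence <- ""
  if (!is.na(seq_i) && seq_i < length(chunk)) {
    body <- chunk[(seq_i + 1):length(chunk)]
    body <- body[str_trim(body) != "//"]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
  }
  if (sequence == "") abort("entry has empty sequence")

  for (k in seq_len(nrow(parsed$features))) {
    if (parsed$features$end[k] > nchar(sequence) || parsed$features$start[k] < 1) {
      abort("feature span outside sequence")
    }
  }

  toks <- strsplit(organism, "\\s+")[[1]]
  species <- if (length(toks) >= 2) paste(toks[1], toks[2], sep = "_") else toks[1]

  tibble(
    accession = accession,
    species = species %||% NA_character_,
    genus = toks[1] %||% NA_character_,
    family = fam, order = ord, organism = organism,
    definition = definition,
    record_type = if (is_complete_definition(definition)) "Complete" else "Partial",
    sequence = sequence,
    features = list(parsed$features),
    submitter = submitter, geo_origin = geo,
    is_refseq = startsWith(accession, "NC_"),
    gb_text = paste(chunk, collapse = "\n")
  )
}

resolve_rank <- function(lineage, suffix, names_lookup) {
  hit <- lineage[lineage %in% names_lookup | grepl(suffix, lineage)]
  if (length(hit) == 0) NA_character_ else hit[length(hit)]
}

empty_features <- function() {
  tibble(kind = character(0), gene = character(0), product = character(0),
         note = character(0), start = integer(0), end = integer(0),
         strand = character(0), location = character(0))
}

parse_gb_features <- function(chunk) {
  fi <- grep("^FEATURES\\b", chunk)[1]
  out <- list(features = empty_features(), geo_origin = "", organism = "")
  if (is.na(fi)) return(out)
  j <- fi + 1
  feats <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    feats[[length(feats) + 1]] <<- cur
  }
  while (j <= length(chunk) && grepl("^\\s{4,}\\S", chunk[j])) {
    line <- chunk[j]
    if (grepl("^\\s{4,6}\\S", line)) {            # new feature key
      flush(cur)
      key <- strsplit(str_trim(line), "\\s+")[[1]]
      loc <- paste(key[-1], collapse = "")
      while (grepl(",$", loc) && j + 1 <= length(chunk) &&
             grepl("^\\s{15,}[^/]", chunk[j + 1])) {   # wrapped location
        j <- j + 1
        loc <- paste0(loc, str_trim(chunk[j]))
      }
      cur <- list(key = key[1], location = loc, quals = list())
    } else if (grepl("^\\s+/", line)) {           # qualifier
      q <- str_trim(line)
      while (j + 1 <= length(chunk) && grepl("^\\s{15,}[^/]", chunk[j + 1]) &&
             grepl('^/[A-Za-z_]+="', q) && !grepl('"$', q)) {
        j <- j + 1
        q <- paste(q, str_trim(chunk[j]))
      }
      name <- sub("^/([A-Za-z_0-9]+).*$", "\\1", q)
      val <- if (grepl("=", q, fixed = TRUE)) {
        gsub('^"|"$', "", sub("^/[A-Za-z_0-9]+=", "", q))
      } else ""
      if (!is.null(cur)) cur$quals[[name]] <- val
    }
    j <- j + 1
  }
  flush(cur)

  geo <- ""
  org <- ""
  rows <- list()
  for (f in feats) {
    if (f$key == "source") {
      geo <- f$quals[["geo_loc_name"]] %||% f$quals[["country"]] %||% ""
      org <- f$quals[["organism"]] %||% ""
    } else if (f$key %in% c("CDS", "rRNA")) {
      span <- parse_location(f$location)
      rows[[length(rows) + 1]] <- tibble(
        kind = f$key,
        gene = f$quals[["gene"]] %||% "",
        product = f$quals[["product"]] %||% "",
        note = f$quals[["note"]] %||% "",
        start = min(span$parts$start), end = max(span$parts$end),
        strand = span$strand, location = f$location
      )
    }
  }
  out$features <- if (length(rows)) bind_rows(rows) else empty_features()
  out$geo_origin <- geo
  out$organism <- org
  out
}

# GenBank location operators: simple spans, join(), complement(), < and >
# partial-end markers. Returns the ordered parts and the strand.
parse_location <- function(loc) {
  strand <- "+"
  s <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", s)) {
    strand <- "-"
    s <- sub("^complement\\((.*)\\)$", "\\1", s)
  }
  if (grepl("^join\\(", s)) s <- sub("^join\\((.*)\\)$", "\\1", s)
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  pr <- map(parts, function(p) {
    p <- gsub("[<>]", "", p)
    if (grepl("\\.\\.", p)) {
      se <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else {
      se <- rep(as.integer(p), 2)
    }
    if (any(is.na(se)) || se[1] > se[2] || se[1] < 1) {
      abort(paste0("bad_span: ", loc), class = "mitocurate_bad_span")
    }
    tibble(start = se[1], end = se[2])
  })
  list(parts = bind_rows(pr), strand = strand)
}

#' Serialize records to GenBank flat-file format
#'
#' Rows carrying verbatim flat-file text (`gb_text`, populated by
#' [parse_genbank()]) are re-emitted unchanged so all original annotations
#' are preserved; synthetic or user records are serialized from their
#' fields. The serializer and [parse_genbank()] round-trip accession,
#' organism, taxonomy, features and sequence.
#'
#' @param records Records tibble.
#' @param path Output file path.
#' @param use_raw Re-emit verbatim `gb_text` when available (default TRUE).
#' @return `path`, invisibly.
#' @export
write_genbank <- function(records, path, use_raw = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (use_raw && !is.na(r$gb_text) && nzchar(r$gb_text)) {
      txt <- r$gb_text
      if (!grepl("//\\s*$", txt)) txt <- paste0(txt, "\n//")
      writeLines(txt, con)
    } else {
      writeLines(serialize_gb_entry(r), con)
    }
  }
  invisible(path)
}

serialize_gb_entry <- function(r) {
  n <- nchar(r$sequence)
  lineage <- paste0("Eukaryota; Metazoa; Chordata; ",
                    if (!is.na(r$order)) paste0(r$order, "; ") else "",
                    if (!is.na(r$family)) paste0(r$family, ".") else "Unclassified.")
  out <- c(
    sprintf("LOCUS       %-16s%12d bp    DNA     circular VRT 01-JAN-2026",
            acc_base(r$accession), n),
    sprintf("DEFINITION  %s", r$definition),
    sprintf("ACCESSION   %s", acc_base(r$accession)),
    sprintf("VERSION     %s", r$accession),
    sprintf("SOURCE      mitochondrion %s", r$organism),
    sprintf("  ORGANISM  %s", r$organism),
    sprintf("            %s", lineage)
  )
  if (!is.na(r$submitter) && nzchar(r$submitter)) {
    out <- c(out,
             sprintf("REFERENCE   1  (bases 1 to %d)", n),
             sprintf("  AUTHORS   %s", r$submitter),
             "  JOURNAL   Submitted (01-JAN-2026) to the INSDC")
  }
  out <- c(out, "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", n),
           sprintf("                     /organism=\"%s\"", r$organism))
  if (!is.na(r$geo_origin) && nzchar(r$geo_origin)) {
    out <- c(out, sprintf("                     /geo_loc_name=\"%s\"", r$geo_origin))
  }
  feats <- r$features[[1]]
  for (k in seq_len(nrow(feats))) {
    f <- feats[k, ]
    out <- c(out, sprintf("     %-15s %s", f$kind, f$location))
    if (nzchar(f$gene))    out <- c(out, sprintf("                     /gene=\"%s\"", f$gene))
    if (nzchar(f$product)) out <- c(out, sprintf("                     /product=\"%s\"", f$product))
    if (nzchar(f$note))    out <- c(out, sprintf("                     /note=\"%s\"", f$note))
  }
  out <- c(out, "ORIGIN")
  seq <- tolower(r$sequence)
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    line_end <- min(p + 59L, n)
    starts <- seq(p, line_end, by = 10L)
    blocks <- substring(seq, starts, pmin(starts + 9L, line_end))
    out <- c(out, sprintf("%9d %s", p, paste(blocks, collapse = " ")))
  }
  c(out, "//")
}

#' Build a standardized Entrez query for one species
#'
#' Constructs the query used to retrieve a species' complete mitochondrial
#' genome records:
#' `"<Species name>" AND mitochondrion[filter] AND complete genome[title]`.
#' Underscores in the binomial are converted to spaces before templating.
#'
#' @param species_name Binomial, with spaces or underscores.
#' @return The query string (vectorized over `species_name`).
#' @examples
#' build_entrez_query("Pempheris schwenkii")
#' @export
build_entrez_query <- function(species_name) {
  if (any(is.na(species_name) | str_trim(species_name) == "")) {
    abort("empty_species: species name must be non-empty",
          class = "mitocurate_empty_species")
  }
  name <- gsub("_", " ", species_name, fixed = TRUE)
  sprintf('"%s" AND mitochondrion[filter] AND complete genome[title]', name)
}

#' Fetch GenBank records through a pluggable client
#'
#' Network retrieval sits behind a one-function adapter so the pipeline is
#' testable offline: a fetcher takes a character vector of Entrez queries
#' (or accessions) and returns GenBank flat-file text. [canned_fetcher()]
#' returns pre-recorded text keyed by query and is what the test suite
#' uses; a live NCBI client can be supplied by the user in its place.
#'
#' @param queries Character vector of queries or accessions.
#' @param fetcher A function `function(query) -> GenBank text`.
#' @param rules Passed to [parse_genbank()].
#' @return As [parse_genbank()].
#' @export
fetch_genbank <- function(queries, fetcher, rules = taxonomy_rules()) {
  txt <- vapply(queries, fetcher, character(1))
  parse_genbank(paste(txt, collapse = "\n"), rules = rules)
}

#' @rdname fetch_genbank
#' @param responses Named character vector or list mapping query -> GenBank
#'   text.
#' @export
canned_fetcher <- function(responses) {
  force(responses)
  function(query) {
    if (!query %in% names(responses)) {
      abort(paste0("no canned response for query: ", query),
            class = "mitocurate_fetch_error")
    }
    as.character(responses[[query]])
  }
}

#' Read a plain-text species or accession list
#'
#' One entry per line; blank lines and `#` comments are ignored. By
#' convention the outgroup entries occupy the first `n_outgroups` lines.
#'
#' @param x File path or literal text.
#' @param n_outgroups Number of leading lines to treat as outgroups.
#' @return A list with `entries` and `outgroups` character vectors.
#' @export
read_id_list <- function(x, n_outgroups = 0) {
  lines <- str_trim(read_text_lines(x))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  n_outgroups <- min(n_outgroups, length(lines))
  list(outgroups = head(lines, n_outgroups),
       entries = if (n_outgroups > 0) lines[-seq_len(n_outgroups)] else lines)
}
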