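#' Specification for synthetic curation fixtures
#'
#' The synthetic-data generator produces GenBank-like records and rooted
#' trees with known ground truth so every pipeline stage runs offline,
#' without downloads or external tools. A spec fixes a nested taxonomy
#' (orders / families / genera / species), per-species sequence counts,
#' sequence length, the anomalies to plant, and the controllable fractions
#' of RefSeq accessions, RefSeq/INSDC identical twins and ambiguous
#' (`sp.`) organisms.
#'
#' @param n_orders,families_per_order,genera_per_family,species_per_genus
#'   Taxonomy dimensions (all >= 1).
#' @param seqs_per_species Inclusive range (length-2 integer vector, within
#'   1..8) from which each species' sequence count is drawn.
#' @param seq_length Complete-record length in bp (>= 1400 so the fixed
#'   feature coordinates fit).
#' @param planted Named counts of anomalies to plant in [make_tree()]:
#'   `c(singleton = , pairwise = , cluster = )`.
#' @param refseq_fraction Probability that a species' first record is a
#'   RefSeq (`NC_`) accession.
#' @param twin_fraction Probability that a RefSeq record gets an INSDC twin
#'   with byte-identical sequence.
#' @param ambiguous_fraction Probability that a species contributes an
#'   extra record with an ambiguous `sp.` organism.
#' @param complete_fraction Probability that a record is a complete
#'   mitogenome (the rest are 12S fragments).
#' @param min_family_leaves Families touched by a plant are padded to at
#'   least this many leaves so a detector neighborhood of the default size
#'   stays within the family.
#' @param rng_seed Seed; everything downstream is deterministic in it.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_orders = 2, families_per_order = 2,
                     genera_per_family = 2, species_per_genus = 2,
                     seqs_per_species = c(1, 3), seq_length = 1400,
                     planted = c(singleton = 0, pairwise = 0, cluster = 0),
                     refseq_fraction = 0.3, twin_fraction = 0,
                     ambiguous_fraction = 0, complete_fraction = 1,
                     min_family_leaves = 5, rng_seed = 1L) {
  dims <- c(n_orders, families_per_order, genera_per_family, species_per_genus)
  if (any(dims < 1)) abort("bad_spec: all taxonomy counts must be >= 1",
                           class = "mitocurate_bad_spec")
  if (length(seqs_per_species) == 1) {
    seqs_per_species <- rep(seqs_per_species, 2)
  }
  if (seqs_per_species[1] < 1 || seqs_per_species[2] > 8 ||
      seqs_per_species[1] > seqs_per_species[2]) {
    abort("bad_spec: seqs_per_species must be a range within 1..8",
          class = "mitocurate_bad_spec")
  }
  if (seq_length < 1400) {
    abort("bad_spec: seq_length must be >= 1400", class = "mitocurate_bad_spec")
  }
  full <- c(singleton = 0, pairwise = 0, cluster = 0)
  full[names(planted)] <- planted
  structure(list(
    n_orders = n_orders, families_per_order = families_per_order,
    genera_per_family = genera_per_family,
    species_per_genus = species_per_genus,
    seqs_per_species = as.integer(seqs_per_species),
    seq_length = as.integer(seq_length), planted = full,
    refseq_fraction = refseq_fraction, twin_fraction = twin_fraction,
    ambiguous_fraction = ambiguous_fraction,
    complete_fraction = complete_fraction,
    min_family_leaves = as.integer(min_family_leaves),
    rng_seed = as.integer(rng_seed)
  ), class = "sim_spec")
}

greek_stems <- c("Alpha", "Beta", "Gamma", "Delta", "Epsilon", "Zeta", "Eta",
                 "Theta", "Iota", "Kappa", "Lambda", "Mu")
family_tags <- c("prim", "secun", "terti", "quart", "quint", "sext", "sept",
                 "octav")
epithets <- c("rubra", "alba", "nigra", "flava", "viridis", "caerulea",
              "aurea", "fusca", "pallida", "striata", "maculata", "gracilis")

sim_taxonomy <- function(spec) {
  stopifnot(spec$n_orders <= length(greek_stems),
            spec$families_per_order <= length(family_tags),
            spec$genera_per_family <= 12,
            spec$species_per_genus <= length(epithets))
  grid <- expand.grid(
    s = seq_len(spec$species_per_genus), g = seq_len(spec$genera_per_family),
    f = seq_len(spec$families_per_order), o = seq_len(spec$n_orders)
  )[, 4:1]
  genus <- paste0("Gen", letters[grid$o], letters[grid$f], letters[grid$g])
  tibble(
    order = paste0(greek_stems[grid$o], "formes"),
    family = paste0(greek_stems[grid$o], family_tags[grid$f], "idae"),
    genus = genus,
    species = paste0(genus, "_", epithets[grid$s])
  )
}

resample <- function(x, size = 1, ...) x[sample.int(length(x), size, ...)]

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, rate) {
  n <- nchar(seq)
  k <- stats::rbinom(1, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  s <- strsplit(seq, "")[[1]]
  s[pos] <- vapply(s[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                   character(1))
  paste(s, collapse = "")
}

# Fixed feature coordinates of synthetic complete records (fits 1400 bp).
sim_feature_coords <- function() {
  tibble(
    canonical = c("12S", "16S", "COX1", "ND6", "CYTB"),
    kind = c("rRNA", "rRNA", "CDS", "CDS", "CDS"),
    start = c(70L, 1030L, 1210L, 1300L, 1360L),
    end = c(1020L, 1200L, 1290L, 1350L, 1395L),
    strand = c("+", "+", "+", "-", "+")
  )
}

sim_features <- function(style) {
  fc <- sim_feature_coords()
  gene_lbl <- c("12S", "16S", "COX1", "ND6", "CYTB")
  prod_lbl <- c("12S ribosomal RNA", "16S ribosomal RNA",
                "cytochrome c oxidase subunit I",
                "NADH dehydrogenase subunit 6", "cytochrome b")
  alt_prod <- c("small subunit ribosomal RNA",
                "large subunit ribosomal RNA",
                "cytochrome c oxidase subunit I",
                "NADH dehydrogenase subunit 6", "cytochrome b")
  loc <- ifelse(fc$strand == "-",
                paste0("complement(", fc$start, "..", fc$end, ")"),
                paste0(fc$start, "..", fc$end))
  if (style == 1) {
    tibble(kind = fc$kind, gene = gene_lbl, product = "", note = "",
           start = fc$start, end = fc$end, strand = fc$strand, location = loc)
  } else if (style == 2) {
    tibble(kind = fc$kind, gene = "", product = prod_lbl, note = "",
           start = fc$start, end = fc$end, strand = fc$strand, location = loc)
  } else {
    tibble(kind = fc$kind, gene = "", product = alt_prod,
           note = c("s-rRNA", "l-rRNA", "", "", ""),
           start = fc$start, end = fc$end, strand = fc$strand, location = loc)
  }
}

submitter_pool <- c("Smith,J. and Jones,A.", "Tanaka,H.", "Lee,K. and Park,S.",
                    "Garcia,M.", "Fish Barcoding Consortium")
geo_pool <- c("Japan", "Australia", "Brazil", "South Africa", "")

#' Generate synthetic GenBank-style records with ground truth
#'
#' Builds the nested taxonomy of the spec and, per species, derives
#' sequences from a genus ancestor by seeded point substitutions with
#' divergence tiers of roughly 0.5% within species, 3% within genus and 8%
#' within family. Records carry realistic DEFINITION lines (complete
#' mitogenome or 12S fragment), feature tables in varied annotation styles
#' (gene vs product vs note labels, ND6 on the minus strand), submitter and
#' geographic metadata, a controllable fraction of `NC_` accessions,
#' RefSeq/INSDC identical twins and ambiguous `sp.` organisms.
#'
#' @param spec A [sim_spec()].
#' @return List with `records` (records tibble, parseable/serializable via
#'   [write_genbank()] and [parse_genbank()]) and `truth` (tibble
#'   `accession`, `species`, `role` in `regular` / `twin_of:<acc>` /
#'   `ambiguous`).
#' @export
make_records <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  withr::with_seed(spec$rng_seed, {
    tax <- sim_taxonomy(spec)
    counter <- 0L
    next_acc <- function(refseq) {
      counter <<- counter + 1L
      if (refseq) sprintf("NC_9%05d.1", counter) else
        sprintf("AB%06d.1", counter)
    }
    fam_anc <- new.env()
    gen_anc <- new.env()
    rows <- list()
    truth <- list()
    for (i in seq_len(nrow(tax))) {
      t <- tax[i, ]
      if (is.null(fam_anc[[t$family]])) {
        fam_anc[[t$family]] <- random_dna(spec$seq_length)
      }
      if (is.null(gen_anc[[t$genus]])) {
        gen_anc[[t$genus]] <- mutate_dna(fam_anc[[t$family]], 0.04)
      }
      sp_seq <- mutate_dna(gen_anc[[t$genus]], 0.015)
      n <- resample(seq(spec$seqs_per_species[1], spec$seqs_per_species[2]), 1)
      refseq_first <- stats::runif(1) < spec$refseq_fraction
      for (k in seq_len(n)) {
        seq_k <- mutate_dna(sp_seq, 0.0025)
        is_nc <- refseq_first && k == 1
        acc <- next_acc(is_nc)
        complete <- stats::runif(1) < spec$complete_fraction
        organism <- gsub("_", " ", t$species)
        rec <- sim_record_row(t, acc, organism, seq_k, complete,
                              style = sample(1:3, 1))
        rows[[length(rows) + 1]] <- rec
        truth[[length(truth) + 1]] <- tibble(
          accession = acc, species = t$species, role = "regular"
        )
        if (is_nc && stats::runif(1) < spec$twin_fraction) {
          tw_acc <- next_acc(FALSE)
          tw <- rec
          tw$accession <- tw_acc
          tw$is_refseq <- FALSE
          rows[[length(rows) + 1]] <- tw
          truth[[length(truth) + 1]] <- tibble(
            accession = tw_acc, species = t$species,
            role = paste0("twin_of:", acc)
          )
        }
      }
      if (stats::runif(1) < spec$ambiguous_fraction) {
        amb_acc <- next_acc(FALSE)
        organism <- paste0(t$genus, " sp. MC-", i)
        amb <- sim_record_row(t, amb_acc, organism,
                              mutate_dna(sp_seq, 0.0025), TRUE,
                              style = 1)
        amb$species <- paste0(t$genus, "_sp.")
        rows[[length(rows) + 1]] <- amb
        truth[[length(truth) + 1]] <- tibble(
          accession = amb_acc, species = t$species, role = "ambiguous"
        )
      }
    }
    list(records = bind_rows(rows), truth = bind_rows(truth))
  })
}

sim_record_row <- function(t, acc, organism, seq, complete, style) {
  if (complete) {
    definition <- paste0(organism, " mitochondrion, complete genome")
    features <- sim_features(style)[, c("kind", "gene", "product", "note",
                                        "start", "end", "strand", "location")]
    record_type <- "Complete"
  } else {
    seq <- substring(seq, 1, 460)
    definition <- paste0(organism, " 12S ribosomal RNA gene, partial sequence")
    features <- tibble(kind = "rRNA", gene = "", product = "12S ribosomal RNA",
                       note = "", start = 10L, end = 450L, strand = "+",
                       location = "10..450")
    record_type <- "Partial"
  }
  tibble(
    accession = acc, species = t$species, genus = t$genus, family = t$family,
    order = t$order, organism = organism, definition = definition,
    record_type = record_type, sequence = seq, features = list(features),
    submitter = sample(submitter_pool, 1), geo_origin = sample(geo_pool, 1),
    is_refseq = startsWith(acc, "NC_"), gb_text = NA_character_
  )
}

outgroup_leaves <- function() {
  tibble(
    order = "Xenoformes", family = "Xenidae", genus = "Genxen",
    species = c("Genxen_extera", "Genxen_ultima"),
    accession = c("OG000001.1", "OG000002.1")
  )
}

#' Generate a rooted fixture tree with planted anomalies
#'
#' Builds a taxonomy-concordant rooted tree — species clades nested within
#' genus, family and order clades, plus a two-leaf outgroup clade used for
#' rooting — then applies the spec's plants:
#'
#' * `singleton`: a one-sequence species is relabeled as a brand-new
#'   species/genus of a different (existing) family in the same order, so
#'   its physical placement contradicts its label (expected flag: green).
#' * `pairwise`: one leaf of a two-sequence species is detached and
#'   grafted inside a foreign genus of another family in the same order
#'   (expected flag: blue, on the moved leaf).
#' * `cluster`: one or two leaves of a 4-5-sequence species are grafted
#'   into a foreign genus (expected flags: red, on the moved leaves).
#'
#' Families on either side of a plant are padded to `min_family_leaves`
#' leaves so the planted signal is unambiguous at the default neighborhood
#' size. The returned truth table lists exactly the accessions a perfect
#' detector should flag, with their colors.
#'
#' @param spec A [sim_spec()].
#' @return List with `tree` (a rooted `ref_tree`), `truth` (tibble
#'   `accession`, `species`, `anomaly_type`, `color`) and `leaves`
#'   (placement table).
#' @export
make_tree <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  withr::with_seed(spec$rng_seed + 1L, {
    tax <- sim_taxonomy(spec)
    tax$n <- resample(seq(spec$seqs_per_species[1], spec$seqs_per_species[2]),
                      nrow(tax), replace = TRUE)

    n_plants <- spec$planted
    if (sum(n_plants) > 0 && spec$families_per_order < 2) {
      abort("bad_spec: plants need >= 2 families per order",
            class = "mitocurate_bad_spec")
    }
    used <- character(0)
    touched <- character(0)   # families involved in any plant; kept disjoint
    plants <- list()
    # every plant consumes two families of the victim's order (the victim's
    # own and the label/host family), so cap plants per order accordingly
    order_capacity <- stats::setNames(
      rep(spec$families_per_order %/% 2, spec$n_orders),
      unique(tax$order)
    )
    if (sum(n_plants) > sum(order_capacity)) {
      abort("bad_spec: not enough families for the requested plants",
            class = "mitocurate_bad_spec")
    }

    pick_species <- function(ok) {
      cand <- which(ok & !(tax$species %in% used) &
                      !(tax$family %in% touched) &
                      order_capacity[tax$order] >= 1)
      if (length(cand) == 0) {
        abort("bad_spec: not enough species to place all plants",
              class = "mitocurate_bad_spec")
      }
      i <- if (length(cand) == 1) cand else sample(cand, 1)
      used <<- c(used, tax$species[i])
      touched <<- c(touched, tax$family[i])
      order_capacity[tax$order[i]] <<- order_capacity[tax$order[i]] - 1L
      i
    }
    other_family <- function(ord, fam) {
      cand <- setdiff(unique(tax$family[tax$order == ord & tax$family != fam]),
                      touched)
      if (length(cand) == 0) {
        abort("bad_spec: no untouched alternative family in order for a plant",
              class = "mitocurate_bad_spec")
      }
      fam2 <- if (length(cand) == 1) cand else sample(cand, 1)
      touched <<- c(touched, fam2)
      fam2
    }

    # phase 1: choose every victim and force its sequence count
    for (k in seq_len(n_plants[["singleton"]])) {
      i <- pick_species(rep(TRUE, nrow(tax)))
      tax$n[i] <- 1L
      plants[[length(plants) + 1]] <- list(
        type = "singleton", victim = tax$species[i], victim_i = i,
        n_move = 0L,
        new_genus = paste0("Novus", letters[k]),
        new_species = paste0("Novus", letters[k], "_insolita")
      )
    }
    for (k in seq_len(n_plants[["pairwise"]])) {
      ok <- vapply(seq_len(nrow(tax)), function(i) {
        any(tax$genus == tax$genus[i] & tax$species != tax$species[i] &
              !(tax$species %in% used))
      }, logical(1))
      i <- pick_species(ok)
      tax$n[i] <- 2L
      plants[[length(plants) + 1]] <- list(
        type = "pairwise", victim = tax$species[i], victim_i = i, n_move = 1L
      )
    }
    for (k in seq_len(n_plants[["cluster"]])) {
      i <- pick_species(rep(TRUE, nrow(tax)))
      tax$n[i] <- resample(4:5, 1)
      plants[[length(plants) + 1]] <- list(
        type = "cluster", victim = tax$species[i], victim_i = i,
        n_move = if (tax$n[i] == 4L) 1L else sample(1:2, 1)
      )
    }

    # phase 2: choose host / label families
    for (pid in seq_along(plants)) {
      p <- plants[[pid]]
      fam <- other_family(tax$order[p$victim_i], tax$family[p$victim_i])
      if (p$type == "singleton") {
        plants[[pid]]$label_family <- fam
      } else {
        plants[[pid]]$host_family <- fam
        plants[[pid]]$host_genus <-
          sample(unique(tax$genus[tax$family == fam]), 1)
      }
    }

    # phase 3: pad families so each plant's signal is unambiguous at the
    # default neighborhood size. Effective leaves of a family = leaves
    # labeled with it that remain physically inside it.
    effective_leaves <- function(fam) {
      tot <- sum(tax$n[tax$family == fam])
      for (p in plants) {
        if (tax$family[p$victim_i] == fam) tot <- tot - p$n_move
        if (p$type == "singleton" && tax$family[p$victim_i] == fam) {
          tot <- tot - 1L   # relabeled away from this family
        }
      }
      tot
    }
    need <- unique(unlist(lapply(plants, function(p) {
      c(tax$family[p$victim_i],
        if (p$type != "singleton") p$host_family else NULL)
    })))
    for (fam in need) {
      repeat {
        if (effective_leaves(fam) >= spec$min_family_leaves) break
        idx <- which(tax$family == fam & !(tax$species %in% used) &
                       tax$n < 8L)
        if (length(idx) == 0) {
          abort("bad_spec: cannot pad family to the required leaf count",
                class = "mitocurate_bad_spec")
        }
        j <- idx[which.min(tax$n[idx])]
        tax$n[j] <- tax$n[j] + 1L
      }
    }

    # leaf table with physical placement == labels, then apply plants
    ri <- rep(seq_len(nrow(tax)), tax$n)
    leaves <- tibble(order = tax$order[ri], family = tax$family[ri],
                     genus = tax$genus[ri], species = tax$species[ri],
                     seq_i = sequence(tax$n))
    leaves$accession <- sprintf("FX%06d.1", seq_len(nrow(leaves)))
    leaves$p_order <- leaves$order
    leaves$p_family <- leaves$family
    leaves$p_genus <- leaves$genus
    leaves$p_slot <- leaves$species

    truth <- list()
    for (pid in seq_along(plants)) {
      p <- plants[[pid]]
      vi <- which(leaves$species == p$victim)
      if (p$type == "singleton") {
        stopifnot(length(vi) == 1)
        leaves$species[vi] <- p$new_species
        leaves$genus[vi] <- p$new_genus
        leaves$family[vi] <- p$label_family
        truth[[length(truth) + 1]] <- tibble(
          accession = leaves$accession[vi], species = p$new_species,
          anomaly_type = "singleton", color = "green"
        )
      } else {
        mv <- utils::tail(vi, p$n_move)
        leaves$p_family[mv] <- p$host_family
        leaves$p_genus[mv] <- p$host_genus
        leaves$p_slot[mv] <- paste0("zgraft", pid)
        truth[[length(truth) + 1]] <- tibble(
          accession = leaves$accession[mv], species = p$victim,
          anomaly_type = p$type,
          color = unname(anomaly_colors[[p$type]])
        )
      }
    }
    truth <- if (length(truth)) bind_rows(truth) else
      tibble(accession = character(0), species = character(0),
             anomaly_type = character(0), color = character(0))

    og <- outgroup_leaves()
    leaves$record_type <- "Concat"
    leaves$label <- format_header(leaves)
    og$record_type <- "Concat"
    og$label <- format_header(og)

    nwk <- paste0("(", nest_newick(leaves), ",",
                  paren(og$label), ");")
    tree <- root_tree(nwk, og$accession)
    list(tree = tree, truth = truth, leaves = leaves)
  })
}

paren <- function(children) {
  if (length(children) == 1) children else
    paste0("(", paste(children, collapse = ","), ")")
}

nest_newick <- function(leaves) {
  orders <- unique(leaves$p_order)
  paren(vapply(orders, function(o) {
    lo <- leaves[leaves$p_order == o, , drop = FALSE]
    fams <- unique(lo$p_family)
    paren(vapply(fams, function(f) {
      lf <- lo[lo$p_family == f, , drop = FALSE]
      gens <- unique(lf$p_genus)
      paren(vapply(gens, function(g) {
        lg <- lf[lf$p_genus == g, , drop = FALSE]
        slots <- unique(lg$p_slot)
        paren(vapply(slots, function(s) {
          paren(lg$label[lg$p_slot == s])
        }, character(1)))
      }, character(1)))
    }, character(1)))
  }, character(1)))
}
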