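#' Detection parameters
#'
#' The detector decides whether a leaf "clusters with" its own taxon by
#' examining the nearest tree neighborhood of at least `min_neighbors`
#' leaves (ancestor-walk, see [neighborhood()]) and the best taxonomic rank
#' shared with it. A leaf passes when that rank reaches `flag_level`
#' (family by default; genus is stricter, order looser). Species that are
#' the sole representative of their family would then fail by
#' construction, so with `monotypic_fallback` they are evaluated at order
#' level instead.
#'
#' @param min_neighbors Minimum neighborhood size (default 5).
#' @param flag_level Rank a leaf must share with its neighborhood:
#'   `"family"` (default), `"genus"` or `"order"`.
#' @param monotypic_fallback Evaluate sole family representatives at order
#'   level (default TRUE).
#' @return A `detector_config` list.
#' @export
detector_config <- function(min_neighbors = 5,
                            flag_level = c("family", "genus", "order"),
                            monotypic_fallback = TRUE) {
  flag_level <- match.arg(flag_level)
  if (min_neighbors < 1) abort("min_neighbors must be >= 1")
  structure(list(min_neighbors = as.integer(min_neighbors),
                 flag_level = flag_level,
                 monotypic_fallback = monotypic_fallback),
            class = "detector_config")
}

rank_value <- c(none = 0L, order = 1L, family = 2L, genus = 3L)

# Precomputed traversal index for a ref_tree: parents, per-node leaf sets,
# preorder positions.
tree_index <- function(tree) {
  phy <- tree$phy
  ntip <- ape::Ntip(phy)
  nnode <- phy$Nnode
  parent <- integer(ntip + nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- ntip + 1L
  po <- ape::reorder.phylo(phy, "postorder")
  leafset <- vector("list", ntip + nnode)
  for (t in seq_len(ntip)) leafset[[t]] <- t
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]
    ch <- po$edge[k, 2]
    leafset[[p]] <- c(leafset[[p]], leafset[[ch]])
  }
  cw <- ape::reorder.phylo(phy, "cladewise")
  preorder <- integer(ntip + nnode)
  preorder[c(root, cw$edge[, 2])] <- seq_len(nrow(cw$edge) + 1L)
  lv <- tree$leaves[order(tree$leaves$tip), , drop = FALSE]
  list(parent = parent, leafset = leafset, preorder = preorder, root = root,
       ntip = ntip, leaves = lv,
       outgroup_tips = lv$tip[lv$is_outgroup])
}

# Ancestor-walk neighborhood from `node` (tip or internal), excluding the
# tips in `excl` (self, conspecifics, outgroups). Returns the first
# collection of size >= min_neighbors, or the largest one found before
# running out of ancestors.
walk_neighborhood <- function(idx, node, excl, min_neighbors) {
  best <- integer(0)
  p <- idx$parent[node]
  while (p != 0L) {
    nb <- setdiff(idx$leafset[[p]], excl)
    if (length(nb) >= min_neighbors) return(nb)
    if (length(nb) > length(best)) best <- nb
    p <- idx$parent[p]
  }
  best
}

# Best rank shared between a leaf's (or species') taxonomy and a tip set.
shared_rank <- function(idx, taxa, nb_tips) {
  if (length(nb_tips) == 0) return(0L)
  nb <- idx$leaves[match(nb_tips, idx$leaves$tip), , drop = FALSE]
  if (any(nb$genus == taxa$genus)) return(rank_value[["genus"]])
  if (any(nb$family == taxa$family)) return(rank_value[["family"]])
  if (any(nb$order == taxa$order)) return(rank_value[["order"]])
  0L
}

leaf_excl <- function(idx, tip) {
  sp <- idx$leaves$species[match(tip, idx$leaves$tip)]
  union(idx$leaves$tip[idx$leaves$species == sp], idx$outgroup_tips)
}

#' Tree neighborhood of a leaf
#'
#' Walks from the leaf's parent toward the root and returns the first set
#' of at least `min_neighbors` leaves, excluding the leaf itself, its
#' conspecifics and all outgroup leaves. If no ancestor provides enough
#' neighbors the largest available set is returned. This operationalizes
#' "clusters far from its expected clade": the neighborhood is what the
#' leaf actually clusters with.
#'
#' @param tree A `ref_tree`.
#' @param accession Leaf accession (version-insensitive).
#' @param min_neighbors Minimum neighborhood size.
#' @return Character vector of neighbor accessions.
#' @export
neighborhood <- function(tree, accession, min_neighbors = 5) {
  idx <- tree_index(tree)
  if (length(setdiff(idx$leaves$tip, idx$outgroup_tips)) < 2) {
    abort("degenerate_tree: need >= 2 ingroup leaves",
          class = "mitocurate_degenerate_tree")
  }
  tip <- idx$leaves$tip[acc_base(idx$leaves$accession) == acc_base(accession)]
  if (length(tip) != 1) abort(paste0("leaf not found: ", accession))
  nb <- walk_neighborhood(idx, tip, leaf_excl(idx, tip), min_neighbors)
  idx$leaves$accession[match(nb, idx$leaves$tip)]
}

#' Best taxonomic rank shared with a set of leaves
#'
#' Returns `"genus"` if any of the neighbors shares the leaf's genus, else
#' `"family"`, else `"order"`, else `"none"`.
#'
#' @param tree A `ref_tree`.
#' @param accession Leaf accession.
#' @param neighbors Character vector of neighbor accessions.
#' @return One of `"genus"`, `"family"`, `"order"`, `"none"`.
#' @export
match_level <- function(tree, accession, neighbors) {
  idx <- tree_index(tree)
  tip <- idx$leaves$tip[acc_base(idx$leaves$accession) == acc_base(accession)]
  nb_tips <- idx$leaves$tip[acc_base(idx$leaves$accession) %in%
                              acc_base(neighbors)]
  taxa <- idx$leaves[match(tip, idx$leaves$tip), , drop = FALSE]
  names(rank_value)[match(shared_rank(idx, taxa, nb_tips), rank_value)]
}

species_tips <- function(idx, species) {
  setdiff(idx$leaves$tip[idx$leaves$species == species], idx$outgroup_tips)
}

mrca_node <- function(idx, tips) {
  if (length(tips) == 1) return(tips)
  node <- tips[1]
  while (!all(tips %in% idx$leafset[[node]])) node <- idx$parent[node]
  node
}

#' Is a species' leaf set monophyletic with no intruders?
#'
#' TRUE iff the leaves under the most recent common ancestor of the
#' species' leaves are exactly the species' leaves: monophyly with a
#' "clean" MRCA. Outgroup leaves are ignored.
#'
#' @param tree A `ref_tree`.
#' @param species Species name (`Genus_species`).
#' @return Logical scalar.
#' @export
species_clean <- function(tree, species) {
  idx <- tree_index(tree)
  species_clean_idx(idx, species)
}

species_clean_idx <- function(idx, species) {
  tips <- species_tips(idx, species)
  if (length(tips) < 2) {
    abort("species_clean needs >= 2 leaves of the species")
  }
  setequal(idx$leafset[[mrca_node(idx, tips)]], tips)
}

#' Largest clean clade of a scattered species
#'
#' For a species whose leaves do not form a clean clade, identifies the
#' "main clade": among all clades whose leaf set is a subset of the
#' species' leaves, the one of maximal size. Ties are broken by the higher
#' shared rank between the species and the clade's neighborhood, then by
#' the smallest preorder index. If no two leaves form a clean clade the
#' core is the single leaf whose neighborhood matches at the highest rank
#' (ties: smallest accession).
#'
#' @param tree A `ref_tree`.
#' @param species Species name.
#' @param min_neighbors Neighborhood size used for tie-breaking.
#' @return Character vector of core-clade accessions.
#' @export
largest_core_clade <- function(tree, species, min_neighbors = 5) {
  idx <- tree_index(tree)
  tips <- largest_core_idx(idx, species, min_neighbors)
  idx$leaves$accession[match(tips, idx$leaves$tip)]
}

largest_core_idx <- function(idx, species, min_neighbors) {
  tips <- species_tips(idx, species)
  sp_excl <- union(tips, idx$outgroup_tips)
  taxa <- idx$leaves[match(tips[1], idx$leaves$tip), , drop = FALSE]

  sizes <- lengths(idx$leafset)
  cand <- which(sizes <= length(tips))
  cand <- cand[vapply(cand, function(n) all(idx$leafset[[n]] %in% tips),
                      logical(1))]
  cand_sizes <- sizes[cand]
  mx <- max(cand_sizes)

  if (mx == 1) {
    lvl <- vapply(tips, function(t) {
      shared_rank(idx, idx$leaves[match(t, idx$leaves$tip), , drop = FALSE],
                  walk_neighborhood(idx, t, leaf_excl(idx, t), min_neighbors))
    }, integer(1))
    accs <- idx$leaves$accession[match(tips, idx$leaves$tip)]
    best <- tips[order(-lvl, accs)][1]
    return(best)
  }
  top <- cand[cand_sizes == mx]
  if (length(top) > 1) {
    lvl <- vapply(top, function(n) {
      shared_rank(idx, taxa,
                  walk_neighborhood(idx, n, sp_excl, min_neighbors))
    }, integer(1))
    top <- top[order(-lvl, idx$preorder[top])][1]
  }
  idx$leafset[[top[1]]]
}

#' Detect taxonomy-versus-topology anomalies on a rooted tree
#'
#' Groups the ingroup leaves by species and evaluates each species by its
#' sequence count:
#'
#' * **One sequence — Type I, singleton (green).** Flagged when the leaf's
#'   neighborhood shares no rank at or above `flag_level`. If the species
#'   is the sole representative of its family in the tree and
#'   `monotypic_fallback` is on, order-level placement suffices.
#' * **Two sequences — Type II, pairwise conflict (blue).** No flag when
#'   the pair forms a clean clade. Otherwise each leaf is evaluated
#'   against its own neighborhood (conspecific excluded): if exactly one
#'   passes at `flag_level` the other is flagged; if neither or both pass,
#'   the placement is ambiguous and both are flagged.
#' * **Three or more — Type III, cluster discordance (red).** No flag when
#'   the species is clean; otherwise every leaf outside the largest core
#'   clade ([largest_core_clade()]) is flagged.
#'
#' Outgroup leaves are excluded from neighborhoods and never flagged.
#' Flags are sorted by (color, species, accession) so output is
#' deterministic.
#'
#' @param tree A `ref_tree`.
#' @param cfg A [detector_config()].
#' @param group_id,tree_file Provenance strings recorded in each flag.
#' @return A flags tibble: `accession`, `species`, `anomaly_type`
#'   (`singleton`/`pairwise`/`cluster`), `color` (`green`/`blue`/`red`),
#'   `group_id`, `tree_file`, `note`.
#' @export
detect_anomalies <- function(tree, cfg = detector_config(),
                             group_id = "", tree_file = "") {
  stopifnot(inherits(cfg, "detector_config"))
  idx <- tree_index(tree)
  ingroup <- setdiff(idx$leaves$tip, idx$outgroup_tips)
  if (length(ingroup) < 2) {
    abort("degenerate_tree: need >= 2 ingroup leaves",
          class = "mitocurate_degenerate_tree")
  }
  lv <- idx$leaves[match(ingroup, idx$leaves$tip), , drop = FALSE]
  flag_rank <- rank_value[[cfg$flag_level]]
  fam_count <- table(lv$family)
  sp_of_fam <- tapply(lv$species, lv$family, function(s) length(unique(s)))

  rank_name <- function(v) names(rank_value)[match(v, rank_value)]
  rows <- list()
  add_flag <- function(tip, type, note) {
    l <- idx$leaves[match(tip, idx$leaves$tip), , drop = FALSE]
    rows[[length(rows) + 1]] <<- tibble(
      accession = l$accession, species = l$species,
      anomaly_type = type, color = unname(anomaly_colors[[type]]),
      group_id = group_id, tree_file = tree_file, note = note
    )
  }

  for (sp in sort(unique(lv$species))) {
    tips <- species_tips(idx, sp)
    n <- length(tips)
    if (n == 1) {
      t1 <- tips[1]
      taxa <- idx$leaves[match(t1, idx$leaves$tip), , drop = FALSE]
      lvl <- shared_rank(idx, taxa,
                         walk_neighborhood(idx, t1, leaf_excl(idx, t1),
                                           cfg$min_neighbors))
      threshold <- flag_rank
      sole_family <- sp_of_fam[[taxa$family]] == 1
      if (sole_family && cfg$monotypic_fallback) {
        threshold <- rank_value[["order"]]
      }
      if (lvl < threshold) {
        add_flag(t1, "singleton",
                 paste0("placement=", rank_name(lvl),
                        if (sole_family && cfg$monotypic_fallback)
                          " (sole family representative, order-level check)"
                        else ""))
      }
    } else if (n == 2) {
      if (!species_clean_idx(idx, sp)) {
        lvls <- vapply(tips, function(t) {
          shared_rank(idx, idx$leaves[match(t, idx$leaves$tip), , drop = FALSE],
                      walk_neighborhood(idx, t, leaf_excl(idx, t),
                                        cfg$min_neighbors))
        }, integer(1))
        pass <- lvls >= flag_rank
        accs <- idx$leaves$accession[match(tips, idx$leaves$tip)]
        if (sum(pass) == 1) {
          bad <- which(!pass)
          add_flag(tips[bad],
                   "pairwise",
                   paste0("conspecific ", accs[pass], " placed consistently; ",
                          "this leaf at ", rank_name(lvls[bad])))
        } else {
          for (k in seq_along(tips)) {
            add_flag(tips[k], "pairwise",
                     paste0("unclear pair placement (",
                            paste(rank_name(lvls), collapse = "/"), ")"))
          }
        }
      }
    } else {
      if (!species_clean_idx(idx, sp)) {
        core <- largest_core_idx(idx, sp, cfg$min_neighbors)
        for (t in setdiff(tips, core)) {
          add_flag(t, "cluster",
                   paste0("outside core clade of ", length(core), "/", n,
                          " sequences"))
        }
      }
    }
  }
  out <- if (length(rows)) bind_rows(rows) else empty_flags()
  out[order(match(out$color, c("green", "blue", "red")), out$species,
            out$accession), , drop = FALSE]
}

#' Render a color-annotated tree for manual review
#'
#' Builds the drawing model (one row per leaf with its display color:
#' flagged leaves green/blue/red, outgroups grey, all others black) and,
#' when `file` is given, renders it to PDF with `ape::plot.phylo()` for
#' visual inspection. Rendering is a pure output step: the flag list is
#' never modified.
#'
#' @param tree A `ref_tree`.
#' @param flags Flags tibble from [detect_anomalies()].
#' @param file Optional PDF path.
#' @param cex Tip label size.
#' @return The drawing-model tibble (`tip`, `label`, `accession`, `color`,
#'   `is_outgroup`), invisibly when rendering, visibly otherwise.
#' @export
render_annotated_tree <- function(tree, flags, file = NULL, cex = 0.4) {
  lv <- tree$leaves[order(tree$leaves$tip), , drop = FALSE]
  color <- ifelse(lv$is_outgroup, "grey50", "black")
  hit <- match(acc_base(lv$accession), acc_base(flags$accession))
  color[!is.na(hit)] <- flags$color[hit[!is.na(hit)]]
  model <- tibble(tip = lv$tip, label = tree$phy$tip.label[lv$tip],
                  accession = lv$accession, color = color,
                  is_outgroup = lv$is_outgroup)
  if (!is.null(file)) {
    grDevices::pdf(file, width = 8,
                   height = max(4, ape::Ntip(tree$phy) * 0.12))
    on.exit(grDevices::dev.off())
    ape::plot.phylo(tree$phy, tip.color = model$color, cex = cex,
                    no.margin = TRUE)
    return(invisible(model))
  }
  model
}
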