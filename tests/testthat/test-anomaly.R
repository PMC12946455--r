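test_that("neighborhood walks to the nearest sufficient leaf set", {
  h <- c(x = leaf_h("Gena_one", "XX000001.1"),
         y = leaf_h("Genb_two", "XX000002.1"),
         z = leaf_h("Genc_three", "XX000003.1"))
  tr <- mk_tree(sprintf("((%s,%s),%s);", h["x"], h["y"], h["z"]))
  expect_setequal(neighborhood(tr, "XX000001.1", min_neighbors = 1),
                  "XX000002.1")
  expect_setequal(neighborhood(tr, "XX000001.1", min_neighbors = 2),
                  c("XX000002.1", "XX000003.1"))
  # insufficient supply: the maximal collection is returned
  expect_setequal(neighborhood(tr, "XX000001.1", min_neighbors = 99),
                  c("XX000002.1", "XX000003.1"))
})

test_that("neighborhoods exclude conspecifics and outgroups", {
  h <- c(a1 = leaf_h("Gena_one", "XX000001.1"),
         a2 = leaf_h("Gena_one", "XX000002.1"),
         b = leaf_h("Genb_two", "XX000003.1"),
         c = leaf_h("Genc_three", "XX000004.1"),
         o = leaf_h("Outg_root", "OG000001.1", family = "Xenidae",
                    order = "Xenoformes"))
  tr <- mk_tree(sprintf("(((%s,%s),(%s,%s)),%s);", h["a1"], h["a2"], h["b"],
                        h["c"], h["o"]), outgroups = "OG000001.1")
  nb <- neighborhood(tr, "XX000001.1", min_neighbors = 5)
  expect_false("XX000002.1" %in% nb)   # conspecific
  expect_false("OG000001.1" %in% nb)   # outgroup
  expect_setequal(nb, c("XX000003.1", "XX000004.1"))
})

test_that("neighborhood agrees with brute-force ancestor enumeration", {
  for (seed in 1:25) {
    tr <- random_labeled_tree(seed)
    idx <- mitocurate:::tree_index(tr)
    for (tip in idx$leaves$tip) {
      sp <- idx$leaves$species[match(tip, idx$leaves$tip)]
      excl <- idx$leaves$tip[idx$leaves$species == sp]
      for (m in c(1, 3, 5)) {
        got <- mitocurate:::walk_neighborhood(idx, tip, excl, m)
        # oracle: enumerate ancestor leaf sets independently via extract.clade
        anc_sets <- list()
        node <- tip
        repeat {
          node <- idx$parent[node]
          if (node == 0) break
          cl <- match(ape::extract.clade(tr$phy, node)$tip.label,
                      tr$phy$tip.label)
          anc_sets[[length(anc_sets) + 1]] <- setdiff(cl, excl)
        }
        big <- which(lengths(anc_sets) >= m)
        want <- if (length(big)) anc_sets[[big[1]]] else
          anc_sets[[which.max(lengths(anc_sets))]]
        expect_setequal(got, want)
      }
    }
  }
})

test_that("match_level returns the best shared rank", {
  h <- c(q = leaf_h("Gena_query", "QQ000001.1", family = "Primidae"),
         g = leaf_h("Gena_other", "QQ000002.1", family = "Primidae"),
         f = leaf_h("Genb_kin", "QQ000003.1", family = "Primidae"),
         o = leaf_h("Genc_far", "QQ000004.1", family = "Secunidae"))
  tr <- mk_tree(sprintf("(((%s,%s),%s),%s);", h["q"], h["g"], h["f"], h["o"]))
  expect_identical(match_level(tr, "QQ000001.1", c("QQ000002.1", "QQ000004.1")),
                   "genus")
  expect_identical(match_level(tr, "QQ000001.1", c("QQ000003.1", "QQ000004.1")),
                   "family")
  expect_identical(match_level(tr, "QQ000001.1", "QQ000004.1"), "order")

  # exhaustive truth table against an independent set-intersection oracle
  for (seed in 1:10) {
    tr2 <- random_labeled_tree(seed)
    lv <- tr2$leaves
    for (i in seq_len(min(nrow(lv), 6))) {
      others <- lv$accession[-i]
      nb <- sample(others, sample(length(others), 1))
      got <- match_level(tr2, lv$accession[i], nb)
      nbl <- lv[lv$accession %in% nb, ]
      want <- if (lv$genus[i] %in% nbl$genus) "genus"
        else if (lv$family[i] %in% nbl$family) "family"
        else if (lv$order[i] %in% nbl$order) "order"
        else "none"
      expect_identical(got, want)
    }
  }
})

test_that("species cleanliness is exact monophyly with no intruders", {
  h <- c(a1 = leaf_h("Gena_one", "SS000001.1"),
         a2 = leaf_h("Gena_one", "SS000002.1"),
         b = leaf_h("Genb_two", "SS000003.1"),
         c = leaf_h("Genc_three", "SS000004.1"))
  clean <- mk_tree(sprintf("((%s,%s),(%s,%s));", h["a1"], h["a2"], h["b"], h["c"]))
  expect_true(species_clean(clean, "Gena_one"))
  dirty <- mk_tree(sprintf("((%s,%s),(%s,%s));", h["a1"], h["b"], h["a2"], h["c"]))
  expect_false(species_clean(dirty, "Gena_one"))
})

test_that("clean-clade calls agree with exhaustive clade enumeration", {
  n_checked <- 0
  for (seed in 1:200) {
    tr <- random_labeled_tree(seed)
    lv <- tr$leaves
    clades <- all_clades(tr)
    for (sp in unique(lv$species)) {
      tips <- lv$tip[lv$species == sp]
      if (length(tips) < 2) next
      want_clean <- any(vapply(clades, function(cl) setequal(cl, tips),
                               logical(1)))
      expect_identical(species_clean(tr, sp), want_clean)
      n_checked <- n_checked + 1
      if (length(tips) >= 3 && !want_clean) {
        core_acc <- largest_core_clade(tr, sp)
        core <- lv$tip[lv$accession %in% core_acc]
        subsets <- clades[vapply(clades, function(cl) all(cl %in% tips),
                                 logical(1))]
        mx <- max(lengths(subsets))
        expect_equal(length(core), mx)
        if (mx > 1) {
          expect_true(any(vapply(subsets, function(cl) setequal(cl, core),
                                 logical(1))))
        }
      }
    }
  }
  expect_gt(n_checked, 100)
})

test_that("a fully consistent tree produces zero flags", {
  fx <- make_tree(sim_spec(n_orders = 2, families_per_order = 2,
                           genera_per_family = 3, species_per_genus = 3,
                           seqs_per_species = c(1, 3), rng_seed = 17))
  expect_equal(nrow(detect_anomalies(fx$tree)), 0)
})

test_that("each planted anomaly type is recovered with its color", {
  fx <- make_tree(sim_spec(n_orders = 3, families_per_order = 3,
                           genera_per_family = 2, species_per_genus = 3,
                           seqs_per_species = c(1, 3),
                           planted = c(singleton = 1, pairwise = 1,
                                       cluster = 1),
                           rng_seed = 42))
  flags <- detect_anomalies(fx$tree, group_id = "g1", tree_file = "g1.nwk")
  expect_setequal(flags$accession, fx$truth$accession)
  m <- merge(flags, fx$truth, by = "accession")
  expect_identical(m$color.x, m$color.y)
  expect_identical(m$anomaly_type.x, m$anomaly_type.y)
  # color/type bijection in every row
  expect_identical(unname(c(singleton = "green", pairwise = "blue",
                            cluster = "red")[flags$anomaly_type]),
                   flags$color)
  # flags are sorted deterministically
  expect_identical(flags$color, as.character(sort(factor(
    flags$color, levels = c("green", "blue", "red")))))
})

test_that("a pairwise conflict flags the displaced leaf only", {
  # one Centropyge-like pair: one leaf among its congeners, one inside a
  # foreign genus clade of another family
  mk <- function(sp, acc, fam) leaf_h(sp, acc, family = fam)
  good <- mk("Cent_pair", "KU000001.1", "Primidae")
  bad <- mk("Cent_pair", "NC_000099.1", "Primidae")
  kin <- sprintf("(%s,%s)", mk("Cent_kin", "KK000001.1", "Primidae"),
                 mk("Cent_kin2", "KK000002.1", "Primidae"))
  foreign <- vapply(1:5, function(i) {
    mk(paste0("Geni_f", i), sprintf("GG0000%02d.1", i), "Secunidae")
  }, character(1))
  nwk <- sprintf("(((%s,%s),((%s,(%s,%s)),%s)),%s);",
                 good, kin,
                 foreign[1], foreign[2], bad, foreign[3],
                 sprintf("(%s,%s)", foreign[4], foreign[5]))
  tr <- mk_tree(nwk)
  flags <- detect_anomalies(tr, detector_config(min_neighbors = 3))
  expect_equal(nrow(flags[flags$anomaly_type == "pairwise", ]), 1)
  expect_identical(flags$accession[flags$anomaly_type == "pairwise"],
                   "NC_000099.1")
})

test_that("both leaves are flagged when a pair's placement is unclear", {
  # both conspecific leaves scattered among foreign genera of other families
  mk <- function(sp, acc, fam) leaf_h(sp, acc, family = fam)
  p1 <- mk("Lost_pair", "LP000001.1", "Tertidae")
  p2 <- mk("Lost_pair", "LP000002.1", "Tertidae")
  f1 <- vapply(1:4, function(i) mk(paste0("Gena_s", i),
                                   sprintf("FA0000%02d.1", i), "Primidae"),
               character(1))
  f2 <- vapply(1:4, function(i) mk(paste0("Genb_s", i),
                                   sprintf("FB0000%02d.1", i), "Secunidae"),
               character(1))
  nwk <- sprintf("(((%s,%s),(%s,%s)),((%s,%s),(%s,%s)));",
                 f1[1], p1, f1[2], f1[3],
                 f2[1], p2, f2[2], f2[4])
  tr <- mk_tree(nwk)
  flags <- detect_anomalies(tr, detector_config(min_neighbors = 3))
  pw <- flags[flags$anomaly_type == "pairwise", ]
  expect_setequal(pw$accession, c("LP000001.1", "LP000002.1"))
})

test_that("monotypic families fall back to an order-level check", {
  mk <- function(sp, acc, fam) leaf_h(sp, acc, family = fam)
  solo <- mk("Mono_typica", "MT000001.1", "Tertidae")  # only Tertidae leaf
  f1 <- vapply(1:3, function(i) mk(paste0("Gena_s", i),
                                   sprintf("MA0000%02d.1", i), "Primidae"),
               character(1))
  f2 <- vapply(1:3, function(i) mk(paste0("Genb_s", i),
                                   sprintf("MB0000%02d.1", i), "Secunidae"),
               character(1))
  nwk <- sprintf("(((%s,%s,%s),%s),(%s,%s,%s));",
                 f1[1], f1[2], f1[3], solo, f2[1], f2[2], f2[3])
  tr <- mk_tree(nwk)
  # with the fallback (default): order-level placement suffices, no flag
  expect_equal(nrow(detect_anomalies(tr, detector_config(min_neighbors = 3))), 0)
  # without it the sole family representative is flagged green
  flags <- detect_anomalies(
    tr, detector_config(min_neighbors = 3, monotypic_fallback = FALSE))
  expect_identical(flags$accession, "MT000001.1")
  expect_identical(flags$color, "green")
})

test_that("flags are a pure, order-independent function of the tree", {
  fx <- make_tree(sim_spec(n_orders = 3, families_per_order = 3,
                           genera_per_family = 2, species_per_genus = 3,
                           planted = c(cluster = 1, pairwise = 1),
                           rng_seed = 77))
  f1 <- detect_anomalies(fx$tree)
  f2 <- detect_anomalies(fx$tree)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  # ladderizing (re-ordering clades) must not change the flag set
  lad <- as_ref_tree(ape::ladderize(fx$tree$phy), fx$tree$outgroup_ids)
  f3 <- detect_anomalies(lad)
  expect_identical(as.data.frame(f3), as.data.frame(f1))
})

test_that("the drawing model colors flagged leaves and marks outgroups", {
  fx <- make_tree(sim_spec(n_orders = 3, families_per_order = 3,
                           genera_per_family = 2, species_per_genus = 3,
                           planted = c(singleton = 1, pairwise = 1,
                                       cluster = 1),
                           rng_seed = 42))
  flags <- detect_anomalies(fx$tree)
  model <- render_annotated_tree(fx$tree, flags)
  expect_equal(nrow(model), ape::Ntip(fx$tree$phy))
  for (col in c("green", "blue", "red")) {
    expect_setequal(model$accession[model$color == col],
                    flags$accession[flags$color == col])
  }
  expect_true(all(model$color[model$is_outgroup] == "grey50"))
  expect_true(all(model$color[!model$is_outgroup &
                                !model$accession %in% flags$accession] ==
                    "black"))
  # rendering to file is a pure output step
  before <- as.data.frame(flags)
  pdf_file <- withr::local_tempfile(fileext = ".pdf")
  render_annotated_tree(fx$tree, flags, file = pdf_file)
  expect_true(file.exists(pdf_file))
  expect_identical(as.data.frame(flags), before)

  # zero flags: nothing colored
  fx0 <- make_tree(sim_spec(rng_seed = 3))
  m0 <- render_annotated_tree(fx0$tree, detect_anomalies(fx0$tree)[0, ])
  expect_true(all(m0$color[!m0$is_outgroup] == "black"))
})

test_that("degenerate trees are refused", {
  h1 <- leaf_h("Gena_one", "DD000001.1")
  h2 <- leaf_h("Outg_root", "OG000001.1", family = "Xenidae",
               order = "Xenoformes")
  tr <- mk_tree(sprintf("(%s,%s);", h1, h2), outgroups = "OG000001.1")
  expect_error(detect_anomalies(tr), class = "mitocurate_degenerate_tree")
})
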