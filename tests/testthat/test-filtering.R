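cfg0 <- filter_config("complete", rng_seed = 42)

test_that("complete-genome definitions are recognized case-insensitively", {
  expect_true(is_complete_definition(
    "Pempheris schwenkii mitochondrion, complete genome"))
  expect_true(is_complete_definition("Foo bar COMPLETE MITOCHONDRIAL GENOME"))
  expect_true(is_complete_definition("Foo bar whole mitochondrion sequence"))
  expect_false(is_complete_definition(
    "Carassius auratus 12S ribosomal RNA gene, partial sequence"))
  expect_false(is_complete_definition(NA))
  # keyword set is extensible
  expect_true(is_complete_definition("Foo bar complete mt genome",
                                     keywords = "complete mt genome"))
})

test_that("ambiguous qualifiers match standalone tokens only", {
  expect_identical(has_ambiguous_qualifier("Epinephelus sp. BH-2014", cfg0), "sp.")
  expect_identical(
    has_ambiguous_qualifier("Carassius auratus x Cyprinus carpio", cfg0), "x")
  expect_identical(has_ambiguous_qualifier("Gobio cf. gobio", cfg0), "cf.")
  expect_identical(has_ambiguous_qualifier("Salmo trutta ssp. fario", cfg0), "ssp.")
  expect_true(is.na(has_ambiguous_qualifier("Pempheris schwenkii", cfg0)))
  # "sp." must never fire inside an epithet
  expect_true(is.na(has_ambiguous_qualifier("Morelia spilota", cfg0)))
  # overrides suppress individual qualifiers
  cfg_sp <- filter_config("complete", keep_sp = TRUE)
  expect_true(is.na(has_ambiguous_qualifier("Epinephelus sp. BH-2014", cfg_sp)))
  expect_identical(has_ambiguous_qualifier("Gobio cf. gobio", cfg_sp), "cf.")
})

test_that("refseq_dedup drops INSDC twins of RefSeq records only", {
  s <- strrep("ACGT", 100)
  recs <- dplyr::bind_rows(
    mk_record("NC_000001.1", sequence = s),
    mk_record("AB000001.1", sequence = s),
    mk_record("AB000002.1", species = "Genus_beta", sequence = strrep("TTAA", 100)),
    mk_record("AB000003.1", species = "Genus_beta", sequence = strrep("TTAA", 100))
  )
  out <- refseq_dedup(recs)
  expect_identical(out$rejected$accession, "AB000001.1")
  expect_identical(unique(out$rejected$reason), "duplicate_of_refseq")
  # identical non-RefSeq pairs are untouched at this stage
  expect_true(all(c("AB000002.1", "AB000003.1") %in% out$kept$accession))

  # generated twins: exactly the non-NC twin of every pair is removed
  sim <- make_records(sim_spec(rng_seed = 8, refseq_fraction = 1,
                               twin_fraction = 1))
  out2 <- refseq_dedup(sim$records)
  twins <- sim$truth$accession[startsWith(sim$truth$role, "twin_of")]
  expect_setequal(out2$rejected$accession, twins)
  # no kept non-RefSeq record is sequence-identical to a kept RefSeq record
  k <- out2$kept
  for (sq in unique(k$sequence[k$is_refseq])) {
    expect_false(any(!k$is_refseq & k$sequence == sq))
  }
})

test_that("complete and gene modes keep the records their rules dictate", {
  s12 <- function(n) {
    feats <- feat_row("rRNA", 10, n - 10, product = "12S ribosomal RNA")
    feats
  }
  recs <- dplyr::bind_rows(
    lapply(1:6, function(i) {
      mk_record(sprintf("AB1%05d.1", i), species = paste0("Genus_c", i))
    }),
    mk_record("AB200001.1", species = "Genus_f1",
              definition = "Genus f1 12S ribosomal RNA gene, partial sequence",
              sequence = strrep("AC", 300), features = s12(600)),
    mk_record("AB200002.1", species = "Genus_f2",
              definition = "Genus f2 12S ribosomal RNA gene, partial sequence",
              sequence = strrep("AG", 250), features = s12(500)),
    mk_record("AB200003.1", species = "Genus_f3",
              definition = "Genus f3 12S ribosomal RNA gene, partial sequence",
              sequence = strrep("AT", 75), features = s12(150)),
    mk_record("AB200004.1", species = "Genus_amb",
              organism = "Genus sp. XX-1")
  )
  comp <- filter_records(recs, cfg0)
  expect_equal(nrow(comp$kept), 6)
  expect_true("AB200004.1" %in%
                comp$rejected$accession[comp$rejected$reason == "ambiguous_qualifier"])

  gcfg <- filter_config("gene", target_genes = "12S", rng_seed = 42)
  gene <- filter_records(recs, gcfg)
  expect_equal(nrow(gene$kept), 8)
  expect_identical(
    gene$rejected$reason[gene$rejected$accession == "AB200003.1"], "too_short")
  expect_true("AB200004.1" %in% gene$rejected$accession)

  # partition invariant at every stage
  expect_setequal(c(comp$kept$accession, comp$rejected$accession),
                  recs$accession)
  expect_setequal(c(gene$kept$accession, gene$rejected$accession),
                  recs$accession)

  # a 399 bp fragment fails the default 400 bp threshold
  short <- mk_record("AB300001.1", species = "Genus_s",
                     definition = "Genus s 12S ribosomal RNA gene, partial sequence",
                     sequence = paste(rep("A", 399), collapse = ""),
                     features = s12(399))
  out <- filter_records(short, gcfg)
  expect_identical(out$rejected$reason, "too_short")
})

test_that("featureless records are retained in gene mode", {
  rec <- mk_record("AB400001.1", species = "Genus_nf",
                   definition = "Genus nf 12S rRNA gene, partial sequence",
                   sequence = strrep("AC", 300))
  gcfg <- filter_config("gene", target_genes = "12S")
  expect_equal(nrow(filter_records(rec, gcfg)$kept), 1)
  expect_error(filter_config("gene"), class = "mitocurate_bad_config")
})

test_that("subsampling respects the quota and collapses duplicates first", {
  # under quota: everything retained
  r3 <- dplyr::bind_rows(lapply(1:3, function(i) {
    mk_record(sprintf("AB5%05d.1", i), sequence = strrep(c("AC", "AG", "AT")[i], 200))
  }))
  out <- subsample_species(r3, cfg0)
  expect_equal(nrow(out$retained), 3)
  expect_equal(out$n_before, 3)

  # 9 distinct sequences from 3 (submitter, origin) keys -> collapse to 3 keys
  subs <- rep(c("Smith,J.", "Tanaka,H.", "Lee,K."), each = 3)
  geos <- rep("Japan", 9)
  r9 <- dplyr::bind_rows(lapply(1:9, function(i) {
    mk_record(sprintf("AB6%05d.1", i), sequence = strrep(c("A", "C", "G")[
      (i - 1) %% 3 + 1], 100 + i), submitter = subs[i], geo_origin = geos[i])
  }))
  out9 <- subsample_species(r9, cfg0)
  expect_lte(nrow(out9$retained), 5)
  keys <- paste(out9$retained$submitter, out9$retained$geo_origin)
  expect_setequal(unique(keys), unique(paste(subs, geos)))
  expect_equal(out9$n_before, 9)
  # deterministic under a fixed seed, independent of row order
  out9b <- subsample_species(r9[sample(9), ], cfg0)
  expect_identical(out9b$retained$accession, out9$retained$accession)
  # partition
  expect_setequal(c(out9$retained$accession, out9$overflow$accession),
                  r9$accession)
})

test_that("gene-mode subsampling keeps complete genomes then longest fragments", {
  gcfg <- filter_config("gene", target_genes = "12S", rng_seed = 1)
  frag <- function(acc, n, sub) {
    mk_record(acc, species = "Genus_alpha",
              definition = "Genus alpha 12S ribosomal RNA gene, partial sequence",
              sequence = random_seq(n + 20), submitter = sub,
              features = feat_row("rRNA", 10, 9 + n, product = "12S ribosomal RNA"))
  }
  random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                  collapse = "")
  set.seed(99)
  comp <- dplyr::bind_rows(
    mk_record("NC_700001.1", sequence = random_seq(700),
              features = feat_row("rRNA", 10, 660, product = "12S ribosomal RNA"),
              submitter = "A1"),
    mk_record("AB700002.1", sequence = random_seq(700),
              features = feat_row("rRNA", 10, 660, product = "12S ribosomal RNA"),
              submitter = "A2")
  )
  frags <- dplyr::bind_rows(
    frag("AB700010.1", 950, "B1"), frag("AB700011.1", 900, "B2"),
    frag("AB700012.1", 800, "B3"), frag("AB700013.1", 400, "B4"),
    frag("AB700014.1", 400, "B5")
  )
  out <- subsample_species(dplyr::bind_rows(comp, frags), gcfg)
  expect_setequal(out$retained$accession,
                  c("NC_700001.1", "AB700002.1", "AB700010.1", "AB700011.1",
                    "AB700012.1"))
})

test_that("filtering contracts hold across randomized record sets", {
  pools <- lapply(1:6, function(s) {
    make_records(sim_spec(n_orders = 2, species_per_genus = 2,
                          seqs_per_species = c(1, 4), rng_seed = s,
                          complete_fraction = 0.7, twin_fraction = 0.3,
                          ambiguous_fraction = 0.2))$records
  })
  gcfg <- filter_config("gene", target_genes = "12S", rng_seed = 7,
                        max_sequences = 3)
  gcfg_strict <- filter_config("gene", target_genes = "12S", rng_seed = 7,
                               max_sequences = 3, min_gene_length = 500)
  for (i in 1:60) {
    pool <- pools[[(i - 1) %% 6 + 1]]
    set.seed(i)
    sub <- pool[sample(nrow(pool), min(30, nrow(pool))), ]
    fo <- filter_records(sub, gcfg)
    expect_setequal(c(fo$kept$accession, fo$rejected$accession), sub$accession)
    ss <- subsample_records(fo$kept, gcfg)
    expect_setequal(c(ss$retained$accession, ss$overflow$accession),
                    fo$kept$accession)
    expect_true(all(table(ss$retained$species) <= 3))
    # monotonicity: a stricter length threshold never keeps more
    fo2 <- filter_records(sub, gcfg_strict)
    expect_true(all(fo2$kept$accession %in% fo$kept$accession))
    # determinism under permutation
    fo3 <- filter_records(sub[sample(nrow(sub)), ], gcfg)
    ss3 <- subsample_records(fo3$kept, gcfg)
    expect_setequal(ss3$retained$accession, ss$retained$accession)
  }
})
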