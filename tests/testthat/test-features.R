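# Denoising, chimera screening, 97% clustering, taxonomy, tables.

uniques_tbl <- function(seqs, counts, sample = "S1", marker = "COI") {
  tibble::tibble(marker = marker, sequence = seqs,
                 total_abundance = counts, sample_id = sample,
                 count = counts) |>
    dplyr::arrange(dplyr::desc(total_abundance), sequence)
}

test_that("denoise absorption follows the skew rule", {
  set.seed(20)
  a <- random_dna_str(200)
  b <- mutate_dna_str(a, 1)

  one <- denoise(uniques_tbl(a, 50))
  expect_equal(nrow(one), 1)
  expect_equal(one$sequence, a)
  expect_equal(one$zotu_id, "zOTU1")

  # skew(1) = 1/2^(2*1+1) = 1/8: 10/1000 absorbed, 200/1000 kept
  absorbed <- denoise(uniques_tbl(c(a, b), c(1000, 10)))
  expect_equal(dplyr::n_distinct(absorbed$zotu_id), 1)
  expect_equal(sum(absorbed$count), 1010)  # reads conserved

  kept <- denoise(uniques_tbl(c(a, b), c(1000, 200)))
  expect_equal(dplyr::n_distinct(kept$zotu_id), 2)

  expect_error(denoise(uniques_tbl(c(a, b), c(10, 1000))[2:1, ]), "sorted")
})

test_that("pooled and per-sample modes agree on single-library input", {
  set.seed(21)
  a <- random_dna_str(150)
  seqs <- c(a, mutate_dna_str(a, 1), mutate_dna_str(a, 3), random_dna_str(150))
  u <- uniques_tbl(seqs, c(800, 90, 11, 40))
  z1 <- denoise(u, mode = "pooled")
  z2 <- denoise(u, mode = "per_sample")
  expect_identical(z1, z2)
})

test_that("per-sample denoising preserves variants abundant in one library", {
  set.seed(22)
  a <- random_dna_str(200)
  b <- mutate_dna_str(a, 1)
  u <- dplyr::bind_rows(
    tibble::tibble(marker = "COI", sequence = a, sample_id = "S1",
                   count = 5000L),
    tibble::tibble(marker = "COI", sequence = a, sample_id = "S2",
                   count = 800L),
    tibble::tibble(marker = "COI", sequence = b, sample_id = "S2",
                   count = 200L)) |>
    dplyr::group_by(marker, sequence) |>
    dplyr::mutate(total_abundance = sum(count)) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(total_abundance), sequence, sample_id)
  # pooled: 200/5800 = 0.034 <= 1/8 -> absorbed
  expect_equal(dplyr::n_distinct(denoise(u, mode = "pooled")$zotu_id), 1)
  # per-sample: 200/800 = 0.25 > 1/8 in S2 -> survives, counts remapped
  z <- denoise(u, mode = "per_sample")
  expect_equal(dplyr::n_distinct(z$zotu_id), 2)
  expect_equal(sum(z$count), 6000)
})

test_that("denoising conserves reads on simulated data", {
  res <- tiny_pipeline()
  expect_equal(sum(res$zotus$count), sum(res$uniques$count))
})

test_that("chimera screen flags true bimeras and spares parents", {
  set.seed(23)
  p1 <- random_dna_str(253)
  p2 <- mutate_dna_str(p1, 13)  # ~5% divergent
  bim <- form_chimera(p1, p2, 120)
  zz <- tibble::tibble(
    marker = "16S-V4",
    zotu_id = c("zOTU1", "zOTU2", "zOTU3"),
    sequence = c(p1, p2, bim),
    total_abundance = c(1600L, 1600L, 100L),
    sample_id = "S1", count = c(1600L, 1600L, 100L))
  fl <- screen_chimeras(zz)
  expect_equal(fl$chimera, c(FALSE, FALSE, TRUE))
  expect_setequal(na.omit(c(fl$parent_a[3], fl$parent_b[3])),
                  c("zOTU1", "zOTU2"))

  # a query identical to one parent is never flagged
  zz2 <- zz
  zz2$sequence[3] <- p1
  expect_false(screen_chimeras(zz2)$chimera[3])

  # no pair of sufficiently abundant candidates -> not flagged
  zz3 <- zz
  zz3$total_abundance <- c(150L, 150L, 100L)  # < 2x query
  expect_false(screen_chimeras(zz3)$chimera[3])
})

test_that("unrelated sequences are not called chimeric", {
  set.seed(24)
  seqs <- replicate(6, random_dna_str(253))
  zz <- tibble::tibble(
    marker = "16S-V4", zotu_id = paste0("zOTU", 1:6), sequence = seqs,
    total_abundance = c(5000L, 4000L, 3000L, 200L, 150L, 100L),
    sample_id = "S1", count = c(5000L, 4000L, 3000L, 200L, 150L, 100L))
  expect_false(any(screen_chimeras(zz)$chimera))
})

test_that("97% clustering joins near-identical and splits divergent zOTUs", {
  set.seed(25)
  a <- random_dna_str(100)
  b <- mutate_dna_str(a, 1)   # 0.99 identity
  c <- mutate_dna_str(a, 10)  # 0.90 identity
  zz <- tibble::tibble(
    marker = "COI", zotu_id = paste0("zOTU", 1:3), sequence = c(a, b, c),
    total_abundance = c(500L, 100L, 50L), sample_id = "S1",
    count = c(500L, 100L, 50L))
  om <- cluster_97(zz)
  expect_equal(om$otu_id[om$zotu_id == "zOTU1"],
               om$otu_id[om$zotu_id == "zOTU2"])
  expect_false(om$otu_id[om$zotu_id == "zOTU3"] ==
                 om$otu_id[om$zotu_id == "zOTU1"])
  # representative is the most abundant member
  expect_equal(unique(om$representative[om$otu_id == "OTU1"]), "zOTU1")
})

test_that("greedy clustering equals the brute-force oracle on random sets", {
  set.seed(26)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    base <- replicate(max(2, n %/% 4), random_dna_str(80))
    seqs <- unique(vapply(seq_len(n), function(i) {
      mutate_dna_str(sample(base, 1), sample(0:6, 1))
    }, character(1)))
    abund <- sample(10:1000, length(seqs))
    zz <- tibble::tibble(marker = "COI",
                         zotu_id = paste0("zOTU", seq_along(seqs)),
                         sequence = seqs, total_abundance = abund,
                         sample_id = "S1", count = abund) |>
      dplyr::arrange(dplyr::desc(total_abundance), zotu_id)
    zz$zotu_id <- paste0("zOTU", seq_len(nrow(zz)))
    om <- cluster_97(zz)
    oracle <- brute_cluster(zz$sequence, zz$total_abundance)
    # same partition (labels may differ)
    sig <- function(ids, labels) {
      sort(vapply(split(ids, labels),
                  function(x) paste(sort(x), collapse = ","), character(1)),
           method = "radix")
    }
    expect_identical(unname(sig(om$zotu_id, om$otu_id)),
                     unname(sig(zz$zotu_id, oracle)))
  }
})

test_that("taxonomy is truncated to the deepest rank passing its cutoff", {
  set.seed(27)
  ref_seq <- random_dna_str(253)
  db <- tibble::tibble(
    id = c("REF1", "REF2"),
    lineage = c(
      "Bacteria;Bacteroidota;Flavobacteriia;Flavobacteriales;Blattabacteriaceae;Sulcia;Sulcia_muelleri",
      "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacterales;Erwiniaceae;Pantoea;Pantoea_agglomerans"),
    sequence = c(ref_seq, random_dna_str(253)))

  exact <- assign_taxonomy(
    tibble::tibble(feature_id = "f1", sequence = ref_seq), db)
  expect_equal(exact$identity, 1)
  expect_equal(exact$genus, "Sulcia")
  expect_equal(exact$assignment_rank, "species")

  # ~0.92 identity: family rank only (genus cutoff 0.95 not met)
  q <- mutate_dna_str(ref_seq, 20)
  fam <- assign_taxonomy(tibble::tibble(feature_id = "f2", sequence = q), db)
  expect_equal(fam$assignment_rank, "family")
  expect_equal(fam$family, "Blattabacteriaceae")
  expect_true(is.na(fam$genus))

  # far from everything: domain only
  far <- assign_taxonomy(
    tibble::tibble(feature_id = "f3", sequence = random_dna_str(253)), db)
  expect_equal(far$assignment_rank, "domain")
  expect_equal(far$lineage, "Bacteria")

  expect_error(assign_taxonomy(exact, db[0, ]), "empty")
})

test_that("non-host COI hits feed off-target detection", {
  db <- tiny_db()
  run <- tiny_run()
  pip_seq <- run$truth$sources$sequence[
    run$truth$sources$taxon == "Eudorylas_fuscipes"][1]
  tax <- assign_taxonomy(
    tibble::tibble(feature_id = "q", sequence = pip_seq), db$coi)
  expect_equal(tax$family, "Pipunculidae")
  expect_false(tax$genus %in% "Macrosteles")
})

test_that("feature tables are additive over member zOTUs", {
  zz <- tibble::tibble(
    marker = "16S-V4", zotu_id = c("zOTU1", "zOTU1", "zOTU2"),
    sequence = c("AAAA", "AAAA", "AAAC"),
    total_abundance = c(17L, 17L, 3L),
    sample_id = c("S1", "S2", "S1"), count = c(10L, 7L, 3L))
  om <- tibble::tibble(marker = "16S-V4", zotu_id = c("zOTU1", "zOTU2"),
                       otu_id = "OTU1", representative = "zOTU1",
                       rep_sequence = "AAAA")
  tabs <- build_tables(zz, om)
  expect_equal(sum(tabs$zotu$count), 20)
  o1 <- tabs$otu[tabs$otu$sample_id == "S1", ]
  expect_equal(o1$count, 13)  # 10 + 3

  # single sample, single zOTU: both tables 1x1
  z1 <- zz[1, ]
  t1 <- build_tables(z1, om)
  expect_equal(nrow(t1$zotu), 1)
  expect_equal(nrow(t1$otu), 1)
  expect_equal(t1$otu$count, 10)

  # chimera-flagged zOTUs are excluded from both tables
  fl <- tibble::tibble(marker = "16S-V4", zotu_id = "zOTU2", chimera = TRUE)
  t2 <- build_tables(zz, om, chimera_flags = fl)
  expect_false("zOTU2" %in% t2$zotu$feature_id)
  expect_equal(sum(t2$otu$count), 17)
})

test_that("noise-free pipeline zOTU table equals truth composition", {
  res <- tiny_pipeline()
  run <- tiny_run()
  src_seq <- setNames(run$truth$sources$sequence,
                      run$truth$sources$source_id)
  exp_tab <- run$truth$composition |>
    dplyr::mutate(seq = unname(src_seq[source_id])) |>
    dplyr::group_by(marker, seq, sample_id) |>
    dplyr::summarise(count = sum(count), .groups = "drop") |>
    dplyr::group_by(marker, seq) |>
    dplyr::mutate(total = sum(count)) |>
    dplyr::ungroup() |>
    dplyr::filter(total >= 2) |>
    dplyr::select(-total)
  got_tab <- dplyr::select(res$zotus, marker, seq = sequence, sample_id,
                           count)
  j <- dplyr::full_join(exp_tab, got_tab,
                        by = c("marker", "seq", "sample_id"),
                        suffix = c("_exp", "_got"))
  expect_true(all(!is.na(j$count_exp) & !is.na(j$count_got) &
                    j$count_exp == j$count_got))
})
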