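# The synthetic-run generator: reference databases, determinism, the
# no-noise limit, chimera formation, the error model and truth conservation.

test_that("reference databases cover sources and decoys", {
  cfg <- tiny_cfg()
  db <- tiny_db()
  expect_gte(nrow(db$coi), nrow(cfg$species))
  # seven host species -> seven distinct species-level COI entries
  host <- grepl("Cicadellidae", db$coi$lineage)
  expect_equal(sum(grepl("\\|dom", db$coi$id) |
                     grepl("_dom", db$coi$id)), 7)
  # decoy categories present for the non-target filter
  expect_true(any(grepl("Mitochondria", db$s16$lineage)))
  expect_true(any(grepl("Chloroplast", db$s16$lineage)))
  expect_true(any(grepl("^Eukaryota", db$s16$lineage)))
  expect_true(any(grepl("^Archaea", db$s16$lineage)))
  expect_false(anyDuplicated(db$s16$id) > 0)
})

test_that("a multi-operon symbiont emits one 16S record per variant", {
  cfg <- tiny_cfg()
  db <- tiny_db()
  ars <- db$s16[grepl("Arsenophonus", db$s16$id), ]
  # 4 operon variants x 2 regions, one genus label
  expect_equal(nrow(ars), 8)
  expect_true(all(grepl(";Arsenophonus;", ars$lineage)))
})

test_that("simulation is bit-identical for a fixed seed", {
  cfg <- sim_config(n_specimens = 2,
                    n_controls = c(extraction = 1, pcr = 0, index = 0),
                    reads_mean = 150, error_rate = 0.003, chimera_rate = 0.02,
                    seed = 99)
  r1 <- simulate_run(cfg)
  r2 <- simulate_run(cfg)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$truth$composition, r2$truth$composition)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_run(cfg, out_dir = d1)
  simulate_run(cfg, out_dir = d2)
  f1 <- file.path(d1, "S001_R1.fastq.gz")
  f2 <- file.path(d2, "S001_R1.fastq.gz")
  expect_identical(readLines(gzfile(f1)), readLines(gzfile(f2)))
})

test_that("with no noise every read is a primer-flanked truth substring", {
  run <- tiny_run()
  cfg <- tiny_cfg()
  src <- setNames(run$truth$sources$sequence, run$truth$sources$source_id)
  mk <- cfg$markers
  set.seed(1)
  idx <- sample(nrow(run$reads), 60)
  for (i in idx) {
    r <- run$reads[i, ]
    amp <- src[[r$source_id]]
    m <- mk[mk$marker == r$marker, ]
    construct_len <- nchar(amp) + nchar(m$fwd_primer) + nchar(m$rev_primer)
    # strip the (IUPAC-instantiated) primer: the body is the amplicon,
    # followed (for constructs shorter than the read) by read-through into
    # the reverse complement of the reverse primer
    body <- substr(r$fwd_seq, nchar(m$fwd_primer) + 1, nchar(r$fwd_seq))
    k <- min(nchar(body), nchar(amp))
    expect_identical(substr(body, 1, k), substr(amp, 1, k))
    if (nchar(body) > k) {
      tail_seq <- substr(body, k + 1, nchar(body))
      expect_equal(symbiomark:::iupac_mismatch_at(
        tail_seq, substr(revcomp(m$rev_primer), 1, nchar(tail_seq))), 0)
    }
    expect_equal(nchar(r$fwd_seq), min(300, construct_len))
    expect_equal(nchar(r$fwd_qual), nchar(r$fwd_seq))
  }
})

test_that("per-sample truth counts sum to emitted read counts", {
  run <- tiny_run()
  emitted <- dplyr::count(run$reads, sample_id, marker, name = "n_reads")
  truth_n <- dplyr::bind_rows(
    run$truth$composition,
    dplyr::select(run$truth$chimeras, sample_id, marker, source_id, count))
  truth_n <- dplyr::summarise(
    dplyr::group_by(truth_n, sample_id, marker),
    n_truth = sum(count), .groups = "drop")
  j <- dplyr::inner_join(emitted, truth_n, by = c("sample_id", "marker"))
  expect_true(all(j$n_reads == j$n_truth))
})

test_that("controls contain only contaminant-pool taxa", {
  run <- tiny_run()
  ctrl <- run$manifest$sample_id[run$manifest$role != "specimen"]
  comp <- dplyr::left_join(
    dplyr::filter(run$truth$composition, sample_id %in% ctrl),
    run$truth$sources, by = c("marker", "source_id"))
  expect_true(all(comp$category == "contaminant"))
})

test_that("facultative carriage follows the configured prevalence", {
  cfg <- sim_config(n_specimens = 40, seed = 5)
  tr <- simulate_truth(cfg)
  laevis <- tr$specimens[tr$specimens$species_true == "Macrosteles_laevis", ]
  carried <- vapply(laevis$symbionts, function(s) "Arsenophonus" %in% s,
                    logical(1))
  # Binomial(n, 0.822): stay within a generous 99.9% interval
  n <- nrow(laevis)
  expect_gt(sum(carried), qbinom(5e-4, n, 0.822))
  expect_lt(sum(carried), qbinom(1 - 5e-4, n, 0.822))
})

test_that("form_chimera concatenates at the breakpoint and validates it", {
  a <- strrep("A", 20); b <- strrep("C", 20)
  expect_equal(form_chimera(a, b, 10), paste0(strrep("A", 10), strrep("C", 10)))
  expect_equal(form_chimera(a, a, 10), a)  # degenerate identity case
  expect_error(form_chimera(a, b, 0), "interior")
  expect_error(form_chimera(a, b, 20), "interior")
  # 5% divergent parents, midpoint crossover -> ~2.5% divergence to each
  set.seed(42)
  p1 <- random_dna_str(400)
  p2 <- mutate_dna_str(p1, 20)
  ch <- form_chimera(p1, p2, 200)
  expect_lte(hamming(ch, p1) / 400, 0.05)
  expect_lte(hamming(ch, p2) / 400, 0.05)
  expect_equal(hamming(ch, p1) + hamming(ch, p2), 20)
})

test_that("error model: zero rate is the identity, rates are calibrated", {
  set.seed(7)
  s <- random_dna_str(500)
  out <- apply_error_model(s, 0)
  expect_identical(out$sequence, s)
  expect_equal(nchar(out$quality), 500)

  # substitution fraction over many bases ~ error_rate (binomial check)
  rate <- 0.01
  n_sub <- 0; n_tot <- 0
  for (i in 1:20) {
    o <- apply_error_model(s, rate)
    n_sub <- n_sub + hamming(o$sequence, s)
    n_tot <- n_tot + 500
  }
  se <- sqrt(rate * (1 - rate) / n_tot)
  expect_lt(abs(n_sub / n_tot - rate), 3 * se + 1e-9)
  expect_error(apply_error_model(s, 0.2), "error_rate")
})

test_that("quality strings are consistent with the error rate", {
  set.seed(8)
  s <- random_dna_str(300)
  o <- apply_error_model(s, 0.001)
  q <- mean(utf8ToInt(o$quality) - 33)
  expect_lt(abs(q - 30), 6)  # Q ~ -10 log10(0.001) with per-read jitter
})

test_that("zero requested reads yield empty valid FASTQ and zero truth", {
  cfg <- sim_config(n_specimens = 1,
                    n_controls = c(extraction = 1, pcr = 0, index = 0),
                    reads_mean = 0, control_reads_mean = 0, error_rate = 0,
                    chimera_rate = 0, seed = 3)
  d <- withr::local_tempdir()
  run <- simulate_run(cfg, out_dir = d)
  expect_equal(nrow(run$reads), 0)
  expect_equal(sum(run$truth$composition$count), 0)
  ff <- file.path(d, "S001_R1.fastq.gz")
  expect_true(file.exists(ff))
  expect_length(readLines(gzfile(ff)), 0)
})

test_that("index cross-talk leaks reads between libraries, conserving depth", {
  cfg0 <- sim_config(n_specimens = 6, chimera_rate = 0, seed = 77)
  cfg1 <- sim_config(n_specimens = 6, chimera_rate = 0, crosstalk_rate = 0.02,
                     seed = 77)
  tr0 <- simulate_truth(cfg0)
  tr1 <- simulate_truth(cfg1)
  # per-library totals are identical with and without cross-talk
  tot <- function(tr) dplyr::count(tr$composition, sample_id, marker,
                                   wt = count, name = "n")
  expect_equal(dplyr::arrange(tot(tr1), sample_id, marker),
               dplyr::arrange(tot(tr0), sample_id, marker))
  # with cross-talk, controls pick up specimen-only taxa
  ctrl <- tr1$manifest$sample_id[tr1$manifest$role != "specimen"]
  leaked <- dplyr::left_join(
    dplyr::filter(tr1$composition, sample_id %in% ctrl),
    tr1$sources, by = c("marker", "source_id"))
  expect_true(any(leaked$category != "contaminant"))
})
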