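# Rendering ground-truth counts into paired 2x300 reads: primer-flanked
# amplicon constructs, per-base substitution errors with error-consistent
# flat Phred qualities, and FASTQ/manifest/truth output.

#' Form a two-parent PCR chimera
#'
#' Prefix of `parent_a` up to `breakpoint` concatenated with the suffix of
#' `parent_b` after it.
#'
#' @param parent_a,parent_b parent sequences (same marker).
#' @param breakpoint integer position; the chimera takes `parent_a[1..bp]`
#'   and `parent_b[(bp+1)..]`. Must be interior to both parents.
#' @return chimeric sequence string.
#' @examples
#' form_chimera("AAAAAA", "CCCCCC", 3)
#' @export
form_chimera <- function(parent_a, parent_b, breakpoint) {
  if (breakpoint < 1 || breakpoint >= nchar(parent_a) ||
      breakpoint >= nchar(parent_b)) {
    abort("breakpoint must be interior to both parent sequences")
  }
  paste0(substr(parent_a, 1, breakpoint),
         substr(parent_b, breakpoint + 1, nchar(parent_b)))
}

#' Apply a per-base substitution error model to a read
#'
#' Each base is substituted independently with probability `error_rate`;
#' the returned flat quality string is consistent with the realized error
#' probability (mean per-base Phred quality ~ `-10*log10(error_rate)`),
#' with a small per-read jitter.
#'
#' @param read DNA string.
#' @param error_rate substitution probability in `[0, 0.05]`.
#' @return list with `sequence` and `quality` (Phred+33, same length).
#' @export
apply_error_model <- function(read, error_rate) {
  if (error_rate < 0 || error_rate > 0.05) {
    abort("error_rate must be in [0, 0.05]")
  }
  L <- nchar(read)
  qmean <- if (error_rate <= 0) 40 else -10 * log10(error_rate)
  q <- min(41, max(2, round(qmean + rnorm(1, 0, 1.5))))
  if (error_rate > 0 && L > 0) {
    nerr <- rbinom(1, L, error_rate)
    if (nerr > 0) read <- mutate_seq(read, nerr)
  }
  list(sequence = read, quality = strrep(phred_to_qual(q), L))
}

# Build the primer-flanked construct and cut it into a 2x300 pair.
# R1 = first `read_len` bases of (fwd_primer + amplicon + rc(rev_primer));
# R2 = reverse complement of the last `read_len` bases. Primer IUPAC codes
# are instantiated to concrete bases per molecule.
instantiate_primer <- function(primer, k = 1L) {
  ch <- strsplit(primer, "", fixed = TRUE)[[1]]
  cols <- lapply(ch, function(cc) {
    set <- IUPAC_SETS[[cc]]
    if (length(set) == 1) rep(set, k) else sample(set, k, replace = TRUE)
  })
  do.call(paste0, cols)
}

pair_from_amplicon <- function(amplicon, fwd_primer, rev_primer,
                               read_len = 300L) {
  construct <- paste0(fwd_primer, amplicon, revcomp(rev_primer))
  L <- nchar(construct)
  r1 <- substr(construct, 1, pmin(read_len, L))
  r2 <- revcomp(substr(construct, pmax(1, L - read_len + 1), L))
  list(fwd = r1, rev = r2)
}

# Vectorised error model over k reads of a shared length
apply_error_model_n <- function(reads, error_rate) {
  k <- length(reads)
  L <- nchar(reads[1])
  qmean <- if (error_rate <= 0) 40 else -10 * log10(error_rate)
  q <- pmin(41, pmax(2, round(qmean + rnorm(k, 0, 1.5))))
  if (error_rate > 0) {
    nerr <- rbinom(k, L, error_rate)
    hit <- which(nerr > 0)
    for (i in hit) reads[i] <- mutate_seq(reads[i], nerr[i])
  }
  quals <- strrep(vapply(q, phred_to_qual, character(1)), L)
  list(sequence = reads, quality = quals)
}

#' Simulate a complete multi-marker sequencing run
#'
#' Draws the ground truth with [simulate_truth()] and renders every counted
#' source molecule into a paired 2x300 read with marker primers at the 5'
#' ends, substitution errors and flat per-read Phred qualities. Optionally
#' writes gzipped FASTQ pairs, a manifest TSV, reference databases and a
#' truth JSON to `out_dir`. Bit-identical for a fixed config seed.
#'
#' @param config a [sim_config()] object.
#' @param out_dir optional directory; when given, writes
#'   `<sample>_R1.fastq.gz` / `<sample>_R2.fastq.gz`, `manifest.tsv`,
#'   `truth.json`, `refdb_coi.fasta` and `refdb_16s.fasta`.
#' @return invisible list with `reads` (tibble: sample_id, read_id, marker,
#'   source_id, fwd_seq, fwd_qual, rev_seq, rev_qual), `manifest`, `truth`.
#' @export
simulate_run <- function(config, out_dir = NULL) {
  truth <- simulate_truth(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 104729L)

  src_all <- bind_rows(
    select(truth$sources, "marker", "source_id", "sequence"),
    select(truth$chimeras, "marker", "source_id", "sequence"))
  seq_of <- setNames(src_all$sequence, src_all$source_id)
  mk <- config$markers

  emit <- bind_rows(
    truth$composition,
    select(truth$chimeras, "sample_id", "marker", "source_id", "count"))

  out <- vector("list", nrow(emit))
  for (i in seq_len(nrow(emit))) {
    m <- emit$marker[i]
    mrow <- mk[mk$marker == m, ]
    amplicon <- seq_of[[emit$source_id[i]]]
    k <- emit$count[i]
    fp <- instantiate_primer(mrow$fwd_primer, k)
    rp <- instantiate_primer(mrow$rev_primer, k)
    pr <- pair_from_amplicon(amplicon, fp, rp)
    e1 <- apply_error_model_n(pr$fwd, config$error_rate)
    e2 <- apply_error_model_n(pr$rev, config$error_rate)
    out[[i]] <- tibble(
      sample_id = emit$sample_id[i], marker = m,
      source_id = emit$source_id[i],
      fwd_seq = e1$sequence, fwd_qual = e1$quality,
      rev_seq = e2$sequence, rev_qual = e2$quality)
  }
  reads <- bind_rows(out)
  if (nrow(reads)) {
    reads <- reads %>%
      group_by(.data$sample_id) %>%
      mutate(read_id = paste0(.data$sample_id, ":", row_number())) %>%
      ungroup() %>%
      select("sample_id", "read_id", "marker", "source_id",
             "fwd_seq", "fwd_qual", "rev_seq", "rev_qual")
  } else {
    reads <- tibble(sample_id = character(), read_id = character(),
                    marker = character(), source_id = character(),
                    fwd_seq = character(), fwd_qual = character(),
                    rev_seq = character(), rev_qual = character())
  }

  if (!is.null(out_dir)) {
    write_run(reads, truth, out_dir)
  }
  invisible(list(reads = reads, manifest = truth$manifest, truth = truth))
}

# --- on-disk layout ----------------------------------------------------

write_run <- function(reads, truth, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in truth$manifest$sample_id) {
    rr <- reads[reads$sample_id == sid, ]
    write_fastq(rr$fwd_seq, rr$fwd_qual, rr$read_id,
                file.path(out_dir, paste0(sid, "_R1.fastq.gz")))
    write_fastq(rr$rev_seq, rr$rev_qual, rr$read_id,
                file.path(out_dir, paste0(sid, "_R2.fastq.gz")))
  }
  write.table(truth$manifest, file.path(out_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  db <- build_reference_db(truth$config)
  write_refdb_coi(db$coi, file.path(out_dir, "refdb_coi.fasta"))
  write_refdb_16s(db$s16, file.path(out_dir, "refdb_16s.fasta"))
  jsonlite::write_json(
    list(composition = truth$composition,
         chimeras = truth$chimeras,
         sources = truth$sources,
         specimens = truth$specimens[, c("sample_id", "species_true",
                                         "heteroplasmy_carrier",
                                         "mislabeled")]),
    file.path(out_dir, "truth.json"))
  invisible(out_dir)
}

write_fastq <- function(seqs, quals, ids, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  if (length(seqs)) {
    txt <- paste0("@", ids, "\n", seqs, "\n+\n", quals)
    writeLines(txt, con)
  } else {
    # an empty valid FASTQ
    writeLines(character(0), con)
  }
  invisible(path)
}

read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(read_id = sub(" .*", "", names(x)),
         seq = unname(as.character(x)),
         qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' Read a simulated (or real) run directory back into a read-pair tibble
#'
#' Expects `<sample>_R1.fastq.gz` / `<sample>_R2.fastq.gz` per manifest row.
#'
#' @param manifest manifest tibble (see [parse_manifest()]).
#' @param dir directory holding the FASTQ pairs.
#' @return tibble with sample_id, read_id, fwd_seq, fwd_qual, rev_seq,
#'   rev_qual.
#' @export
read_run_fastq <- function(manifest, dir) {
  rows <- lapply(manifest$sample_id, function(sid) {
    f1 <- file.path(dir, paste0(sid, "_R1.fastq.gz"))
    f2 <- file.path(dir, paste0(sid, "_R2.fastq.gz"))
    if (!file.exists(f1)) f1 <- sub("[.]gz$", "", f1)
    if (!file.exists(f2)) f2 <- sub("[.]gz$", "", f2)
    r1 <- read_fastq(f1)
    r2 <- read_fastq(f2)
    stopifnot(identical(r1$read_id, r2$read_id))
    tibble(sample_id = sid, read_id = r1$read_id,
           fwd_seq = r1$seq, fwd_qual = r1$qual,
           rev_seq = r2$seq, rev_qual = r2$qual)
  })
  bind_rows(rows)
}
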