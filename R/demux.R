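# Manifest parsing and primer-based binning of read pairs into marker bins.

MANIFEST_COLS <- c("sample_id", "role", "species_morph", "site", "year",
                   "sex", "nested_pcr_status")
SAMPLE_ROLES <- c("specimen", "control_extraction", "control_pcr",
                  "control_index")

#' Parse a sample manifest TSV
#'
#' Required columns: sample_id, role, species_morph, site, year, sex,
#' nested_pcr_status. Roles must be one of `specimen`, `control_extraction`,
#' `control_pcr`, `control_index`; duplicate sample ids are rejected.
#'
#' @param path path to a tab-separated manifest.
#' @return tibble, one row per library.
#' @export
parse_manifest <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  missing <- setdiff(MANIFEST_COLS, names(df))
  if (length(missing)) {
    abort(paste0("manifest is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) {
    abort(paste0("duplicated sample_id in manifest: ",
                 paste(unique(df$sample_id[duplicated(df$sample_id)]),
                       collapse = ", ")))
  }
  bad <- setdiff(unique(df$role), SAMPLE_ROLES)
  if (length(bad)) {
    abort(paste0("unknown role(s) in manifest: ", paste(bad, collapse = ", ")))
  }
  as_tibble(df[MANIFEST_COLS])
}

# Vectorised IUPAC-aware mismatch count of `pattern` against the substring
# of each sequence starting at `pos`. Sequences shorter than pos+np-1 get Inf.
iupac_mismatch_at <- function(seqs, pattern, pos = 1L) {
  np <- nchar(pattern)
  pr <- strsplit(pattern, "", fixed = TRUE)[[1]]
  mm <- numeric(length(seqs))
  too_short <- nchar(seqs) < pos + np - 1L
  for (i in seq_len(np)) {
    ch <- substring(seqs, pos + i - 1L, pos + i - 1L)
    set <- IUPAC_SETS[[pr[i]]]
    if (is.null(set)) set <- character()
    mm <- mm + !(ch %in% set)
  }
  mm[too_short] <- Inf
  mm
}

# Trim 3' adapter read-through: when the construct is shorter than the read,
# the reverse complement of the opposite primer appears inside the read at a
# position >= len_min + 1. The earliest such match is trimmed off.
trim_readthrough <- function(seqs, quals, rc_primer, len_min, max_mismatch) {
  np <- nchar(rc_primer)
  L <- nchar(seqs)
  pmax_pos <- max(L) - np + 1L
  if (is.infinite(pmax_pos) || pmax_pos < len_min + 1L) {
    return(list(seq = seqs, qual = quals))
  }
  cut <- rep(NA_integer_, length(seqs))
  for (p in seq(len_min + 1L, pmax_pos)) {
    cand <- which(is.na(cut) & L >= p + np - 1L)
    if (!length(cand)) next
    mm <- iupac_mismatch_at(seqs[cand], rc_primer, p)
    hit <- cand[mm <= max_mismatch]
    cut[hit] <- p - 1L
  }
  hit <- which(!is.na(cut))
  if (length(hit)) {
    seqs[hit] <- substr(seqs[hit], 1L, cut[hit])
    quals[hit] <- substr(quals[hit], 1L, cut[hit])
  }
  list(seq = seqs, qual = quals)
}

#' Bin read pairs into marker bins by primer sequence
#'
#' A pair is assigned to a marker iff the forward read starts with the
#' marker's forward primer and the reverse read with its reverse primer,
#' each within `max_mismatch` IUPAC-aware substitutions. Mixed-orientation
#' pairs (forward primer on R2) are detected and the mates swapped. Primers
#' are trimmed on assignment, as is 3' primer read-through for amplicons
#' shorter than the read. Pairs matching no marker, several markers, or
#' conflicting primer pairs stay unassigned with a reason code.
#'
#' @param reads tibble with columns sample_id, read_id, fwd_seq, fwd_qual,
#'   rev_seq, rev_qual.
#' @param markers marker tibble, see [default_markers()].
#' @param max_mismatch maximum IUPAC-aware mismatches per primer (default 2).
#' @return the input tibble with added columns `marker` (NA when
#'   unassigned) and `reason` (`assigned`, `no_primer_match`,
#'   `ambiguous_marker`, `primer_pair_conflict`); assigned rows have primers
#'   trimmed from the sequences and qualities.
#' @export
bin_reads <- function(reads, markers = default_markers(), max_mismatch = 2L) {
  n <- nrow(reads)
  if (n == 0) {
    return(mutate(reads, marker = character(0), reason = character(0)))
  }
  nm <- nrow(markers)
  f1 <- r2 <- f2 <- r1 <- matrix(Inf, n, nm)
  for (j in seq_len(nm)) {
    f1[, j] <- iupac_mismatch_at(reads$fwd_seq, markers$fwd_primer[j])
    r2[, j] <- iupac_mismatch_at(reads$rev_seq, markers$rev_primer[j])
    f2[, j] <- iupac_mismatch_at(reads$rev_seq, markers$fwd_primer[j])
    r1[, j] <- iupac_mismatch_at(reads$fwd_seq, markers$rev_primer[j])
  }
  normal <- f1 <= max_mismatch & r2 <= max_mismatch
  swapped <- f2 <= max_mismatch & r1 <= max_mismatch
  hits <- normal | swapped
  nhit <- rowSums(hits)

  any_fwd <- rowSums(f1 <= max_mismatch | f2 <= max_mismatch) > 0
  any_rev <- rowSums(r2 <= max_mismatch | r1 <= max_mismatch) > 0
  reason <- rep("assigned", n)
  reason[nhit == 0] <- if_else(any_fwd[nhit == 0] & any_rev[nhit == 0],
                               "primer_pair_conflict", "no_primer_match")
  reason[nhit > 1] <- "ambiguous_marker"

  assigned <- nhit == 1
  marker <- rep(NA_character_, n)
  mj <- integer(n)
  mj[assigned] <- apply(hits[assigned, , drop = FALSE], 1, which)
  marker[assigned] <- markers$marker[mj[assigned]]

  out <- reads
  # swap mates for mixed-orientation pairs
  do_swap <- assigned & swapped[cbind(seq_len(n), pmax(mj, 1L))] &
    !normal[cbind(seq_len(n), pmax(mj, 1L))]
  if (any(do_swap)) {
    tmp_s <- out$fwd_seq[do_swap]; tmp_q <- out$fwd_qual[do_swap]
    out$fwd_seq[do_swap] <- out$rev_seq[do_swap]
    out$fwd_qual[do_swap] <- out$rev_qual[do_swap]
    out$rev_seq[do_swap] <- tmp_s
    out$rev_qual[do_swap] <- tmp_q
  }
  # trim primers and read-through per marker
  for (j in seq_len(nm)) {
    idx <- which(assigned & mj == j)
    if (!length(idx)) next
    npf <- nchar(markers$fwd_primer[j])
    npr <- nchar(markers$rev_primer[j])
    out$fwd_seq[idx] <- substring(out$fwd_seq[idx], npf + 1L)
    out$fwd_qual[idx] <- substring(out$fwd_qual[idx], npf + 1L)
    out$rev_seq[idx] <- substring(out$rev_seq[idx], npr + 1L)
    out$rev_qual[idx] <- substring(out$rev_qual[idx], npr + 1L)
    tr <- trim_readthrough(out$fwd_seq[idx], out$fwd_qual[idx],
                           revcomp(markers$rev_primer[j]),
                           markers$len_min[j], max_mismatch)
    out$fwd_seq[idx] <- tr$seq; out$fwd_qual[idx] <- tr$qual
    tr <- trim_readthrough(out$rev_seq[idx], out$rev_qual[idx],
                           revcomp(markers$fwd_primer[j]),
                           markers$len_min[j], max_mismatch)
    out$rev_seq[idx] <- tr$seq; out$rev_qual[idx] <- tr$qual
  }
  out$marker <- marker
  out$reason <- reason
  out
}
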