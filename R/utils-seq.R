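# Low-level sequence utilities shared across the pipeline. Sequences are
# plain uppercase character strings (A/C/G/T plus IUPAC codes in primers);
# Biostrings is used for reverse complements, alignment and FASTA/FASTQ IO.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC code -> the set of bases it matches
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Reverse complement of a DNA string
#'
#' IUPAC ambiguity codes are complemented correctly (via Biostrings).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Hamming distance between two equal-length sequences
#'
#' @param a,b DNA strings of equal length.
#' @return integer count of differing positions; `Inf` if lengths differ.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Count IUPAC-aware mismatches of `primer` against the prefix of `seq`.
# A primer position matches iff the read base is in the primer code's set.
# Returns Inf if the read is shorter than the primer.
primer_mismatches <- function(seq, primer) {
  np <- nchar(primer)
  if (nchar(seq) < np) return(Inf)
  pre <- substr(seq, 1L, np)
  pc <- strsplit(pre, "", fixed = TRUE)[[1]]
  mm <- 0L
  pr <- strsplit(primer, "", fixed = TRUE)[[1]]
  for (i in seq_len(np)) {
    set <- IUPAC_SETS[[pr[i]]]
    if (is.null(set) || !(pc[i] %in% set)) mm <- mm + 1L
  }
  mm
}

# Vectorised primer prefix match over many reads; returns integer mismatches.
primer_mismatches_many <- function(seqs, primer) {
  vapply(seqs, primer_mismatches, numeric(1), primer = primer, USE.NAMES = FALSE)
}

random_dna <- function(n, rng_len) {
  paste(sample(DNA_BASES, rng_len, replace = TRUE), collapse = "")
}

# Generate `n` random sequences of length `len` using the current RNG state.
random_seqs <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Introduce exactly `k` substitutions at distinct positions (never the same
# base), using the current RNG state.
mutate_seq <- function(seq, k) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) {
    ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# Phred+33 helpers ------------------------------------------------------

phred_to_qual <- function(q) {
  intToUtf8(pmin(pmax(round(q), 2L), 41L) + 33L)
}

qual_to_phred <- function(qual) {
  utf8ToInt(qual) - 33L
}

#' Expected number of errors implied by a quality string
#'
#' Sums `10^(-Q/10)` over the Phred+33 quality string.
#'
#' @param qual quality string (Phred+33).
#' @return numeric expected-error value.
#' @export
expected_errors <- function(qual) {
  sum(10^(-qual_to_phred(qual) / 10))
}

# Global pairwise identity: matches / alignment columns, end gaps penalised
# (Needleman-Wunsch "global" alignment). Columns = matches + mismatches +
# inserted + deleted positions.
global_identity <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (la != lb) {
    # end gaps are penalized, so columns >= max length and
    # identity <= min/max; below the shallowest rank cutoff the exact
    # value cannot change any decision
    bound <- min(la, lb) / max(la, lb)
    if (bound < 0.85) return(bound)
  } else {
    mm <- hamming(a, b)
    # near-identical: the ungapped alignment is optimal under the pinned
    # scoring (a gap pair costs far more than a mismatch); clearly-distant:
    # gapped alignment cannot lift identity anywhere near the cutoffs
    if (mm <= 0.05 * la || mm >= 0.3 * la) return((la - mm) / la)
  }
  al <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2),
    gapOpening = 6, gapExtension = 1)
  nm <- Biostrings::nmatch(al)
  nmm <- Biostrings::nmismatch(al)
  ins <- sum(Biostrings::width(unlist(Biostrings::insertion(al))))
  del <- sum(Biostrings::width(unlist(Biostrings::deletion(al))))
  cols <- nm + nmm + ins + del
  if (cols == 0) return(0)
  nm / cols
}

# Substitution distance under end-free alignment (for variant annotation);
# returns list(subs, indels).
variant_distance <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    return(list(subs = hamming(a, b), indels = 0L))
  }
  al <- Biostrings::pairwiseAlignment(a, b, type = "overlap")
  ins <- sum(Biostrings::width(unlist(Biostrings::insertion(al))))
  del <- sum(Biostrings::width(unlist(Biostrings::deletion(al))))
  list(subs = Biostrings::nmismatch(al), indels = ins + del)
}
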