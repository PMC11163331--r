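# Read-pair merging (best ungapped overlap), expected-error quality
# filtering, global dereplication and singleton removal.

# Find the best ungapped overlap offset of s2 (revcomp of R2) against s1.
# `o` is the 1-based position of s2's first base in contig coordinates
# (s1 starts at 1). Candidate offsets come from exact k-mer seeds of s2
# found in s1; a full scan over all offsets (down to overlap 5) is the
# fallback for seed-less (error-laden or non-overlapping) pairs. The
# winner maximizes the alignment score matches - 4*mismatches, so a short
# exact overlap beats long spurious ones; the caller classifies winners
# with overlap below min_overlap as rejections. Returns
# list(o, mismatches, overlap) or NULL.
best_overlap <- function(s1, s2, min_overlap) {
  L1 <- nchar(s1); L2 <- nchar(s2)
  if (L1 == 0 || L2 == 0) return(NULL)
  k <- min(14L, L2)
  cand <- integer(0)
  for (seed_start in c(1L, 15L, 29L)) {
    if (seed_start + k - 1L > L2) break
    seed <- substr(s2, seed_start, seed_start + k - 1L)
    m <- gregexpr(seed, s1, fixed = TRUE)[[1]]
    if (m[1] != -1L) cand <- c(cand, as.integer(m) - seed_start + 1L)
  }
  cand <- unique(cand[cand >= 1L & cand <= L1 - min_overlap + 1L])
  if (!length(cand)) cand <- seq_len(max(L1 - 5L + 1L, 1L))
  v1 <- utf8ToInt(s1); v2 <- utf8ToInt(s2)
  best <- NULL
  for (o in cand) {
    ov_end <- min(L1, o + L2 - 1L)
    ov_len <- ov_end - o + 1L
    if (ov_len < 5L) next
    mm <- sum(v1[o:ov_end] != v2[seq_len(ov_len)])
    score <- (ov_len - mm) - 4L * mm
    if (is.null(best) || score > best$score ||
        (score == best$score && ov_len > best$overlap)) {
      best <- list(o = o, mismatches = mm, overlap = ov_len, score = score)
    }
  }
  best
}

#' Merge one read pair into an amplicon contig
#'
#' Aligns the forward read against the reverse-complemented reverse read
#' with the best ungapped overlap. Accepted iff the overlap is at least
#' `min_overlap` bases and its mismatch fraction at most
#' `max_overlap_mismatch_frac`. Disagreeing overlap bases are resolved to
#' the higher-quality base; the merged quality of an overlap position is
#' the maximum of the two. Primers must already be trimmed.
#'
#' @param fwd_seq,fwd_qual,rev_seq,rev_qual the read pair (reverse mate in
#'   its original orientation).
#' @param min_overlap minimum overlap length (default 20).
#' @param max_overlap_mismatch_frac maximum mismatch fraction in the
#'   overlap (default 0.15).
#' @return list with `merged` (logical), and either `sequence`, `quality`,
#'   `expected_errors` or a rejection `reason`.
#' @export
merge_pair <- function(fwd_seq, fwd_qual, rev_seq, rev_qual,
                       min_overlap = 20L, max_overlap_mismatch_frac = 0.15) {
  s2 <- revcomp(rev_seq)
  q2 <- paste(rev(strsplit(rev_qual, "", fixed = TRUE)[[1]]), collapse = "")
  best <- best_overlap(fwd_seq, s2, min_overlap)
  if (is.null(best) || best$overlap < min_overlap) {
    return(list(merged = FALSE, reason = "short overlap"))
  }
  if (best$mismatches / best$overlap > max_overlap_mismatch_frac) {
    return(list(merged = FALSE, reason = "overlap mismatch"))
  }
  res <- merge_at_offset(fwd_seq, fwd_qual, s2, q2, best$o)
  list(merged = TRUE, sequence = res$seq, quality = res$qual,
       expected_errors = expected_errors(res$qual))
}

# Merge s1/s2 (already oriented, qualities aligned) at offset o.
merge_at_offset <- function(s1, q1, s2, q2, o) {
  L1 <- nchar(s1); L2 <- nchar(s2)
  v1 <- utf8ToInt(s1); v2 <- utf8ToInt(s2)
  w1 <- utf8ToInt(q1); w2 <- utf8ToInt(q2)
  ov_end <- min(L1, o + L2 - 1L)
  idx1 <- o:ov_end
  idx2 <- seq_len(length(idx1))
  take2 <- v1[idx1] != v2[idx2] & w2[idx2] > w1[idx1]
  ov_seq <- v1[idx1]
  ov_seq[take2] <- v2[idx2][take2]
  ov_qual <- pmax(w1[idx1], w2[idx2])
  left_seq <- if (o > 1) v1[1:(o - 1)] else integer(0)
  left_qual <- if (o > 1) w1[1:(o - 1)] else integer(0)
  right_seq <- if (L2 > length(idx2)) v2[(length(idx2) + 1):L2] else integer(0)
  right_qual <- if (L2 > length(idx2)) w2[(length(idx2) + 1):L2] else integer(0)
  list(seq = intToUtf8(c(left_seq, ov_seq, right_seq)),
       qual = intToUtf8(c(left_qual, ov_qual, right_qual)))
}

#' Merge all binned read pairs into contigs
#'
#' Applies [merge_pair()] to every assigned pair, computing the overlap
#' offset once per distinct sequence pair. Unassigned reads are ignored.
#'
#' @param binned output of [bin_reads()].
#' @inheritParams merge_pair
#' @return tibble with sample_id, read_id, marker, merged, reason,
#'   sequence, quality, expected_errors (NA where rejected).
#' @export
merge_pairs <- function(binned, min_overlap = 20L,
                        max_overlap_mismatch_frac = 0.15) {
  x <- filter(binned, !is.na(.data$marker))
  n <- nrow(x)
  if (n == 0) {
    return(tibble(sample_id = character(), read_id = character(),
                  marker = character(), merged = logical(),
                  reason = character(), sequence = character(),
                  quality = character(), expected_errors = numeric()))
  }
  s2 <- revcomp(x$rev_seq)
  uq <- unique(x$rev_qual)
  q2 <- vapply(strsplit(uq, "", fixed = TRUE),
               function(ch) paste(rev(ch), collapse = ""),
               character(1))[match(x$rev_qual, uq)]
  key <- paste0(x$fwd_seq, "\r", s2)
  grp <- match(key, key)
  uniq <- which(grp == seq_len(n))

  merged <- logical(n)
  reason <- rep(NA_character_, n)
  sequence <- rep(NA_character_, n)
  quality <- rep(NA_character_, n)

  for (u in uniq) {
    idx <- which(grp == grp[u])
    best <- best_overlap(x$fwd_seq[u], s2[u], min_overlap)
    if (is.null(best) || best$overlap < min_overlap) {
      reason[idx] <- "short overlap"
      next
    }
    if (best$mismatches / best$overlap > max_overlap_mismatch_frac) {
      reason[idx] <- "overlap mismatch"
      next
    }
    merged[idx] <- TRUE
    for (i in idx) {
      res <- merge_at_offset(x$fwd_seq[i], x$fwd_qual[i], s2[i], q2[i],
                             best$o)
      sequence[i] <- res$seq
      quality[i] <- res$qual
    }
  }
  ee <- rep(NA_real_, n)
  ee[merged] <- vapply(quality[merged], expected_errors, numeric(1),
                       USE.NAMES = FALSE)
  tibble(sample_id = x$sample_id, read_id = x$read_id, marker = x$marker,
         merged = merged,
         reason = if_else(merged, "merged", reason),
         sequence = sequence, quality = quality, expected_errors = ee)
}

#' Expected-error and length filter for merged contigs
#'
#' Keeps a contig iff its expected errors (sum of `10^(-Q/10)`) are at most
#' `max_ee` and its length lies within the marker's accepted amplicon
#' length range.
#'
#' @param contigs output of [merge_pairs()] (merged rows).
#' @param markers marker tibble with `len_min`/`len_max`.
#' @param max_ee maximum expected errors (default 1.0).
#' @return the contig tibble with a logical `keep` column and a `reason`.
#' @export
quality_filter <- function(contigs, markers = default_markers(),
                           max_ee = 1.0) {
  stopifnot(max_ee > 0)
  x <- filter(contigs, .data$merged)
  x <- left_join(x, markers[, c("marker", "len_min", "len_max")],
                 by = "marker")
  len <- nchar(x$sequence)
  in_range <- len >= x$len_min & len <= x$len_max
  ee_ok <- x$expected_errors <= max_ee
  x$keep <- in_range & ee_ok
  x$reason <- case_when(!in_range ~ "length out of range",
                        !ee_ok ~ "expected errors too high",
                        TRUE ~ "pass")
  select(x, -"len_min", -"len_max")
}

#' Dereplicate contigs into unique sequences, removing singletons
#'
#' Groups identical sequences within each marker across all samples,
#' records per-sample counts, removes sequences with a total abundance of
#' one, and orders the result by decreasing total abundance (ties broken
#' lexicographically by sequence).
#'
#' @param contigs filtered contig tibble (rows with `keep = TRUE` are used
#'   if a `keep` column is present).
#' @return long tibble with marker, sequence, total_abundance, sample_id,
#'   count, sorted by decreasing total abundance.
#' @export
dereplicate <- function(contigs) {
  x <- contigs
  if ("keep" %in% names(x)) x <- filter(x, .data$keep)
  if (nrow(x) == 0) {
    return(tibble(marker = character(), sequence = character(),
                  total_abundance = integer(), sample_id = character(),
                  count = integer()))
  }
  x %>%
    count(.data$marker, .data$sequence, .data$sample_id, name = "count") %>%
    group_by(.data$marker, .data$sequence) %>%
    mutate(total_abundance = sum(.data$count)) %>%
    ungroup() %>%
    filter(.data$total_abundance >= 2L) %>%
    arrange(.data$marker, dplyr::desc(.data$total_abundance),
            .data$sequence, .data$sample_id) %>%
    select("marker", "sequence", "total_abundance", "sample_id", "count")
}
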