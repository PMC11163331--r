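# Denoising into zero-radius OTUs, de novo chimera screening, greedy 97%
# clustering, best-hit taxonomy and feature-table construction.

unoise_skew <- function(d, alpha) 1 / 2^(alpha * d + 1)

# Greedy UNOISE pass over sequences sorted by decreasing abundance.
# Returns an integer vector mapping each input index to the index of its
# centroid (itself if it founds one).
greedy_denoise_pass <- function(seqs, abund, alpha, d_max,
                                min_parent_abundance) {
  n <- length(seqs)
  assign_to <- integer(n)
  centroids <- integer(0)
  vecs <- lapply(seqs, utf8ToInt)
  lens <- nchar(seqs)
  for (i in seq_len(n)) {
    best_d <- Inf; best_c <- 0L
    for (cc in centroids) {
      if (lens[cc] != lens[i]) next
      d <- sum(vecs[[cc]] != vecs[[i]])
      if (d > d_max) next
      if (abund[i] / abund[cc] <= unoise_skew(d, alpha)) {
        if (d < best_d || (d == best_d && abund[cc] > abund[best_c])) {
          best_d <- d; best_c <- cc
        }
      }
    }
    if (best_c > 0L) {
      assign_to[i] <- best_c
    } else if (abund[i] >= min_parent_abundance) {
      assign_to[i] <- i
      centroids <- c(centroids, i)
    } else {
      assign_to[i] <- NA_integer_  # resolved in the global mapping stage
    }
  }
  assign_to
}

#' Denoise unique sequences into zero-radius OTUs (zOTUs)
#'
#' UNOISE-style greedy denoising: in decreasing abundance order a unique
#' sequence is absorbed into an existing centroid `C` iff its substitution
#' distance `d` to `C` is at most `d_max` and its abundance ratio to `C` is
#' at most `skew(d) = 1 / 2^(alpha*d + 1)`; otherwise it founds a new
#' centroid.
#'
#' Two modes: `"per_sample"` (default) denoises each library on its own
#' counts, takes the union of all per-sample centroids, and then maps every
#' unique sequence to its nearest centroid within `d_max` — this preserves
#' genuine low-frequency variants (e.g. minor mitochondrial haplotypes)
#' that are abundant enough in some libraries while still removing
#' per-library error clouds. `"pooled"` runs one greedy pass on pooled
#' abundances. Reads are conserved in both modes.
#'
#' @param uniques output of [dereplicate()] (must be sorted by decreasing
#'   total abundance within marker; this is checked).
#' @param alpha UNOISE alpha (default 2).
#' @param d_max maximum substitution distance for absorption (default 10).
#' @param min_parent_abundance minimum abundance for a sequence to found a
#'   centroid (default 2).
#' @param mode `"per_sample"` or `"pooled"`.
#' @return long tibble: marker, zotu_id, sequence, total_abundance,
#'   sample_id, count; ids are abundance-ranked per marker.
#' @export
denoise <- function(uniques, alpha = 2, d_max = 10L,
                    min_parent_abundance = 2L,
                    mode = c("per_sample", "pooled")) {
  mode <- match.arg(mode)
  out <- list()
  for (m in unique(uniques$marker)) {
    um <- filter(uniques, .data$marker == m)
    useq <- distinct(um, .data$sequence, .keep_all = TRUE)
    if (is.unsorted(-useq$total_abundance)) {
      abort("uniques must be sorted by decreasing total abundance")
    }
    seqs <- useq$sequence
    totals <- useq$total_abundance
    counts <- um %>%
      select("sequence", "sample_id", "count")
    cw <- tidyr::pivot_wider(counts, names_from = "sample_id",
                             values_from = "count", values_fill = 0L)
    cmat <- as.matrix(cw[, -1, drop = FALSE])
    rownames(cmat) <- cw$sequence
    cmat <- cmat[seqs, , drop = FALSE]

    if (mode == "pooled") {
      assign_to <- greedy_denoise_pass(seqs, totals, alpha, d_max,
                                       min_parent_abundance)
      cent_idx <- which(assign_to == seq_along(seqs))
      # low-abundance uniques that could not found: nearest centroid or self
      assign_to <- resolve_unassigned(assign_to, seqs, totals, d_max,
                                      cent_idx)
    } else {
      cent_set <- logical(length(seqs))
      for (s in colnames(cmat)) {
        ab <- cmat[, s]
        pres <- which(ab > 0)
        if (!length(pres)) next
        ord <- pres[order(-ab[pres], seqs[pres])]
        a2 <- greedy_denoise_pass(seqs[ord], ab[ord], alpha, d_max,
                                  min_parent_abundance)
        founded <- ord[which(a2 == seq_along(ord))]
        cent_set[founded] <- TRUE
      }
      cent_idx <- which(cent_set)
      # map every unique to its nearest union centroid within d_max
      assign_to <- rep(NA_integer_, length(seqs))
      assign_to[cent_idx] <- cent_idx
      assign_to <- resolve_unassigned(assign_to, seqs, totals, d_max,
                                      cent_idx)
    }

    cent <- sort(unique(assign_to))
    agg <- rowsum(cmat, group = assign_to, reorder = TRUE)
    agg_tot <- rowSums(agg)
    ord <- order(-agg_tot, seqs[as.integer(rownames(agg))])
    agg <- agg[ord, , drop = FALSE]
    cent <- as.integer(rownames(agg))
    ids <- paste0("zOTU", seq_along(cent))
    long <- as_tibble(as.table(agg), .name_repair = "minimal")
    names(long) <- c("idx", "sample_id", "count")
    long$idx <- as.integer(as.character(long$idx))
    long <- filter(long, .data$count > 0)
    pos <- match(long$idx, cent)
    out[[m]] <- tibble(
      marker = m,
      zotu_id = ids[pos],
      sequence = seqs[long$idx],
      total_abundance = unname(rowSums(agg))[pos],
      sample_id = long$sample_id,
      count = as.integer(long$count))
  }
  bind_rows(out) %>%
    arrange(.data$marker, dplyr::desc(.data$total_abundance),
            .data$zotu_id, .data$sample_id)
}

# Assign NA entries (and, in per_sample mode, absorbed uniques) to the
# nearest centroid within d_max; anything unreachable founds its own zOTU.
resolve_unassigned <- function(assign_to, seqs, totals, d_max, cent_idx) {
  vecs <- lapply(seqs, utf8ToInt)
  lens <- nchar(seqs)
  for (i in order(-totals)) {
    if (!is.na(assign_to[i]) && assign_to[i] %in% cent_idx) next
    if (i %in% cent_idx) { assign_to[i] <- i; next }
    best_d <- Inf; best_c <- 0L
    for (cc in cent_idx) {
      if (lens[cc] != lens[i]) next
      d <- sum(vecs[[cc]] != vecs[[i]])
      if (d > d_max) next
      if (d < best_d || (d == best_d && totals[cc] > totals[best_c])) {
        best_d <- d; best_c <- cc
      }
    }
    if (best_c > 0L) {
      assign_to[i] <- best_c
    } else {
      assign_to[i] <- i
      cent_idx <- c(cent_idx, i)
    }
  }
  assign_to
}

#' Screen zOTUs for two-parent PCR chimeras
#'
#' For each query zOTU, candidate parents are more abundant zOTUs of the
#' same marker and length with at least `min_parent_ratio` times the query
#' abundance. The best two-segment model (one crossover, any candidate
#' pair) is compared with the best single parent: the query is flagged as a
#' chimera iff the model reconstructs it strictly better by a margin of at
#' least `score_min` (mismatch reduction normalized by query length) and
#' fits the query to within `max_model_div` mismatch fraction.
#'
#' @param zotus zOTU tibble from [denoise()].
#' @param min_parent_ratio minimum parent/query abundance ratio (default 2).
#' @param score_min minimum normalized mismatch reduction (default 0.01).
#' @param max_model_div maximum mismatch fraction of the chimeric model
#'   against the query (default 0.05).
#' @return tibble with one row per zOTU: marker, zotu_id, chimera (logical),
#'   score, parent_a, parent_b.
#' @export
screen_chimeras <- function(zotus, min_parent_ratio = 2,
                            score_min = 0.01, max_model_div = 0.05) {
  res <- list()
  for (m in unique(zotus$marker)) {
    zz <- zotus %>%
      filter(.data$marker == m) %>%
      distinct(.data$zotu_id, .keep_all = TRUE) %>%
      arrange(dplyr::desc(.data$total_abundance), .data$zotu_id)
    n <- nrow(zz)
    vecs <- lapply(zz$sequence, utf8ToInt)
    lens <- nchar(zz$sequence)
    chimera <- logical(n); score <- rep(NA_real_, n)
    pa <- pb <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      cand <- which(zz$total_abundance >= min_parent_ratio *
                      zz$total_abundance[i] & lens == lens[i])
      cand <- setdiff(cand, i)
      if (length(cand) < 2) next
      L <- lens[i]
      cums <- vapply(cand, function(j) cumsum(vecs[[j]] != vecs[[i]]),
                     numeric(L))
      tot <- cums[L, ]
      best_single <- min(tot)
      # for each crossover k: best prefix parent + best suffix parent
      ks <- seq_len(L - 1)
      pre <- cums[ks, , drop = FALSE]
      suf <- matrix(tot, nrow = length(ks), ncol = length(cand),
                    byrow = TRUE) - pre
      min_pre <- apply(pre, 1, min)
      min_suf <- apply(suf, 1, min)
      model <- min_pre + min_suf
      k_best <- which.min(model)
      best_model <- model[k_best]
      sc <- (best_single - best_model) / L
      score[i] <- sc
      if (best_model < best_single && sc >= score_min &&
          best_model / L <= max_model_div) {
        chimera[i] <- TRUE
        pa[i] <- zz$zotu_id[cand[which.min(pre[k_best, ])]]
        pb[i] <- zz$zotu_id[cand[which.min(suf[k_best, ])]]
      }
    }
    res[[m]] <- tibble(marker = m, zotu_id = zz$zotu_id, chimera = chimera,
                       score = score, parent_a = pa, parent_b = pb)
  }
  bind_rows(res)
}

#' Cluster zOTUs into 97% identity OTUs
#'
#' Greedy centroid clustering in decreasing abundance order: a zOTU joins
#' the first existing OTU whose representative is at least `identity_min`
#' globally identical (matches / alignment columns of a global pairwise
#' alignment, end gaps penalized); otherwise it founds a new OTU. OTU ids
#' are re-ranked by total member abundance.
#'
#' @param zotus zOTU tibble from [denoise()] (chimeras removed).
#' @param identity_min identity threshold (default 0.97).
#' @return tibble mapping zotu_id to otu_id with the representative
#'   zOTU/sequence of each OTU: marker, zotu_id, otu_id, representative,
#'   rep_sequence.
#' @export
cluster_97 <- function(zotus, identity_min = 0.97) {
  res <- list()
  for (m in unique(zotus$marker)) {
    zz <- zotus %>%
      filter(.data$marker == m) %>%
      distinct(.data$zotu_id, .keep_all = TRUE) %>%
      arrange(dplyr::desc(.data$total_abundance), .data$zotu_id)
    n <- nrow(zz)
    otu_of <- integer(n)
    reps <- integer(0)
    for (i in seq_len(n)) {
      hit <- 0L
      for (r in reps) {
        if (global_identity(zz$sequence[i], zz$sequence[r]) >= identity_min) {
          hit <- r; break
        }
      }
      if (hit > 0L) otu_of[i] <- hit else { otu_of[i] <- i; reps <- c(reps, i) }
    }
    tot <- tapply(zz$total_abundance, otu_of, sum)
    rep_idx <- as.integer(names(sort(-tot)))
    otu_ids <- setNames(paste0("OTU", seq_along(rep_idx)),
                        as.character(rep_idx))
    res[[m]] <- tibble(
      marker = m, zotu_id = zz$zotu_id,
      otu_id = unname(otu_ids[as.character(otu_of)]),
      representative = zz$zotu_id[match(otu_of, seq_len(n))],
      rep_sequence = zz$sequence[match(otu_of, seq_len(n))])
  }
  bind_rows(res)
}

DEFAULT_RANK_CUTOFFS <- c(species = 0.97, genus = 0.95, family = 0.90,
                          order = 0.85)
LINEAGE_RANKS <- c("domain", "phylum", "class", "order", "family",
                   "genus", "species")

#' Assign taxonomy by best-hit global alignment against a reference database
#'
#' The lineage of the best hit (ties broken toward the lexicographically
#' smallest reference id) is truncated to the deepest rank whose identity
#' cutoff is met; below the `order` cutoff only the domain is kept.
#'
#' @param features tibble with at least `feature_id` and `sequence`.
#' @param refdb reference tibble from [read_refdb()] /
#'   [build_reference_db()] (`id`, `lineage`, `sequence`).
#' @param rank_cutoffs named identity cutoffs for species/genus/family/order.
#' @return `features` with added columns best_ref, identity,
#'   assignment_rank, lineage (truncated) and one column per rank
#'   (domain..species, NA below the assignment rank).
#' @export
assign_taxonomy <- function(features, refdb,
                            rank_cutoffs = DEFAULT_RANK_CUTOFFS) {
  if (nrow(refdb) == 0) abort("reference database is empty")
  refdb <- arrange(refdb, .data$id)
  n <- nrow(features)
  best_ref <- character(n); identity <- numeric(n)
  for (i in seq_len(n)) {
    ids <- vapply(refdb$sequence, global_identity,
                  numeric(1), a = features$sequence[i], USE.NAMES = FALSE)
    j <- which.max(ids)  # first max = smallest id after the sort
    best_ref[i] <- refdb$id[j]
    identity[i] <- ids[j]
  }
  lin <- refdb$lineage[match(best_ref, refdb$id)]
  parts <- strsplit(lin, ";", fixed = TRUE)
  depth <- vapply(identity, function(p) {
    if (p >= rank_cutoffs[["species"]]) 7L
    else if (p >= rank_cutoffs[["genus"]]) 6L
    else if (p >= rank_cutoffs[["family"]]) 5L
    else if (p >= rank_cutoffs[["order"]]) 4L
    else 1L
  }, integer(1))
  rank_cols <- lapply(seq_along(LINEAGE_RANKS), function(k) {
    vapply(seq_len(n), function(i) {
      if (k <= depth[i] && length(parts[[i]]) >= k) parts[[i]][k]
      else NA_character_
    }, character(1))
  })
  names(rank_cols) <- LINEAGE_RANKS
  out <- features
  out$best_ref <- best_ref
  out$identity <- identity
  out$assignment_rank <- LINEAGE_RANKS[depth]
  out$lineage <- vapply(seq_len(n), function(i) {
    paste(parts[[i]][seq_len(min(depth[i], length(parts[[i]])))],
          collapse = ";")
  }, character(1))
  bind_cols(out, as_tibble(rank_cols))
}

#' Build zOTU- and OTU-level feature tables
#'
#' @param zotus zOTU tibble from [denoise()].
#' @param otu_map mapping from [cluster_97()].
#' @param chimera_flags optional output of [screen_chimeras()]; flagged
#'   zOTUs are excluded from both tables.
#' @return list with `zotu` and `otu` long count tibbles (marker,
#'   feature_id, sequence for zOTUs / rep_sequence for OTUs, sample_id,
#'   count).
#' @export
build_tables <- function(zotus, otu_map, chimera_flags = NULL) {
  zz <- zotus
  if (!is.null(chimera_flags)) {
    bad <- chimera_flags %>% filter(.data$chimera)
    zz <- anti_join(zz, bad, by = c("marker", "zotu_id"))
  }
  ztab <- zz %>%
    select("marker", feature_id = "zotu_id", "sequence", "sample_id",
           "count")
  otab <- zz %>%
    inner_join(otu_map, by = c("marker", "zotu_id")) %>%
    group_by(.data$marker, feature_id = .data$otu_id, .data$rep_sequence,
             .data$sample_id) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    rename(sequence = "rep_sequence") %>%
    select("marker", "feature_id", "sequence", "sample_id", "count")
  list(zotu = ztab, otu = otab)
}
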