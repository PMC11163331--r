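# The decontamination and abundance/depth filters: negative-control-based
# contaminant removal, non-target lineage removal, zOTU thresholds with
# "Others" aggregation, sample exclusion and the 1% display view.

#' Default filtering parameters
#'
#' Thresholds mirror the filtering rules the pipeline applies: a zOTU is
#' specifically considered only with >= 100 reads and >= 5% relative
#' abundance in at least one library; samples need >= 100 COI barcode reads
#' and >= 1000 16S-V4 reads; the display view keeps OTUs exceeding 1%
#' relative abundance in at least one library; a feature is a contaminant
#' when its mean relative abundance across negative controls is at least
#' `contam_ratio` times its mean across specimens.
#'
#' @return named list of thresholds.
#' @export
filter_params <- function() {
  list(min_zotu_reads = 100L, min_zotu_frac = 0.05,
       min_coi_barcode_reads = 100L, min_16s_reads = 1000L,
       display_frac = 0.01, contam_ratio = 1.0)
}

# per-library relative abundance added to a long count table
add_relabund <- function(table) {
  table %>%
    group_by(.data$sample_id) %>%
    mutate(rel_abund = .data$count / sum(.data$count)) %>%
    ungroup()
}

#' Negative-control-based decontamination
#'
#' A feature is flagged as a contaminant iff its mean relative abundance
#' across control libraries is at least `contam_ratio` times its mean
#' relative abundance across specimen libraries; features absent from all
#' controls are never flagged. Controls are pooled across the three
#' library-preparation roles unless `by_role = TRUE`, in which case a
#' feature flagged in any role is removed.
#'
#' @param table long count tibble (feature_id, sample_id, count, ...).
#' @param manifest manifest tibble with sample roles.
#' @param contam_ratio control/specimen mean relative abundance ratio above
#'   which a feature is a contaminant (default 1).
#' @param by_role compare controls per role instead of pooled.
#' @return list with `table` (specimen libraries, contaminants removed) and
#'   `report` (one decision row per feature: decision
#'   contaminant/retained, control and specimen means, ratio).
#' @export
decontaminate <- function(table, manifest, contam_ratio = 1.0,
                          by_role = FALSE) {
  ctrl_ids <- manifest$sample_id[manifest$role != "specimen"]
  spec_ids <- manifest$sample_id[manifest$role == "specimen"]
  ctrl_present <- intersect(ctrl_ids, unique(table$sample_id))
  if (length(ctrl_present) == 0) {
    abort(paste("no control libraries present in the table;",
                "pass the table through unchanged (explicitly) if",
                "decontamination must be skipped"))
  }
  ra <- add_relabund(table)
  feats <- distinct(table, .data$feature_id)

  mean_over <- function(ids) {
    ra %>%
      filter(.data$sample_id %in% ids) %>%
      group_by(.data$feature_id) %>%
      summarise(s = sum(.data$rel_abund), .groups = "drop") %>%
      mutate(m = .data$s / length(ids)) %>%
      select("feature_id", "m")
  }
  spec_mean <- mean_over(intersect(spec_ids, unique(table$sample_id)))

  flag_of <- function(ctrl_set) {
    cm <- mean_over(ctrl_set)
    feats %>%
      left_join(cm, by = "feature_id") %>%
      rename(control_mean = "m") %>%
      left_join(spec_mean, by = "feature_id") %>%
      rename(specimen_mean = "m") %>%
      mutate(control_mean = tidyr::replace_na(.data$control_mean, 0),
             specimen_mean = tidyr::replace_na(.data$specimen_mean, 0),
             ratio = if_else(.data$specimen_mean > 0,
                             .data$control_mean / .data$specimen_mean,
                             Inf),
             contaminant = .data$control_mean > 0 &
               .data$control_mean >= contam_ratio * .data$specimen_mean)
  }

  if (by_role) {
    roles <- unique(manifest$role[manifest$role != "specimen"])
    per_role <- lapply(roles, function(r) {
      ids <- intersect(manifest$sample_id[manifest$role == r], ctrl_present)
      if (length(ids)) mutate(flag_of(ids), role = r) else NULL
    })
    allr <- bind_rows(per_role)
    report <- allr %>%
      group_by(.data$feature_id) %>%
      summarise(control_mean = max(.data$control_mean),
                specimen_mean = first(.data$specimen_mean),
                ratio = max(.data$ratio[is.finite(.data$ratio)], -Inf),
                contaminant = any(.data$contaminant), .groups = "drop")
  } else {
    report <- flag_of(ctrl_present)
  }
  report <- report %>%
    mutate(decision = if_else(.data$contaminant, "contaminant", "retained"))
  bad <- report$feature_id[report$contaminant]
  cleaned <- table %>%
    filter(.data$sample_id %in% spec_ids, !.data$feature_id %in% bad)
  list(table = cleaned, report = report)
}

NON_TARGET_PATTERNS <- c("mitochondria", "chloroplast", "eukaryota",
                         "archaea")

#' Remove non-target lineages from a 16S table
#'
#' Features whose assigned lineage contains mitochondria, chloroplast,
#' Eukaryota or Archaea (case-insensitive) are removed.
#'
#' @param table long count tibble.
#' @param taxonomy tibble with `feature_id` and `lineage`.
#' @return list with `table` (cleaned) and `removed` (feature ids + note).
#' @export
remove_non_target <- function(table, taxonomy) {
  lin <- tolower(taxonomy$lineage)
  hit <- vapply(lin, function(l) {
    any(vapply(NON_TARGET_PATTERNS, grepl, logical(1), x = l, fixed = TRUE))
  }, logical(1), USE.NAMES = FALSE)
  bad <- taxonomy$feature_id[hit]
  removed <- taxonomy %>%
    filter(.data$feature_id %in% bad) %>%
    mutate(note = "non_target_lineage") %>%
    select("feature_id", "lineage", "note")
  list(table = filter(table, !.data$feature_id %in% bad), removed = removed)
}

#' Threshold zOTUs and aggregate the remainder into "Others"
#'
#' A feature is focal iff its total read count is at least
#' `min_zotu_reads` and its relative abundance reaches `min_zotu_frac` in
#' at least one library (both thresholds inclusive). All non-focal features
#' are summed per sample into a single `Others` feature; per-sample totals
#' are conserved exactly.
#'
#' @param table long count tibble.
#' @param min_zotu_reads total-read floor (default 100).
#' @param min_zotu_frac per-library relative abundance floor (default 0.05).
#' @return list with `table` (focal features + `Others` rows) and
#'   `focal_ids`.
#' @export
threshold_zotus <- function(table, min_zotu_reads = 100L,
                            min_zotu_frac = 0.05) {
  ra <- add_relabund(table)
  stats <- ra %>%
    group_by(.data$feature_id) %>%
    summarise(total = sum(.data$count), max_frac = max(.data$rel_abund),
              .groups = "drop")
  focal <- stats$feature_id[stats$total >= min_zotu_reads &
                              stats$max_frac >= min_zotu_frac]
  keep <- filter(table, .data$feature_id %in% focal)
  others <- table %>%
    filter(!.data$feature_id %in% focal) %>%
    group_by(.data$sample_id) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    mutate(feature_id = "Others")
  if ("marker" %in% names(table) && nrow(others) > 0) {
    others$marker <- table$marker[1]
  }
  list(table = bind_rows(keep, others), focal_ids = focal)
}

#' Exclude samples failing the barcode / 16S depth floors
#'
#' A specimen is retained iff its COI barcode zOTU has at least
#' `min_coi_barcode_reads` reads and its 16S-V4 library total is at least
#' `min_16s_reads` (samples below either floor are excluded).
#'
#' @param host_calls tibble from [call_hosts()] with `sample_id` and
#'   `barcode_count`.
#' @param v4_table 16S-V4 long count tibble.
#' @param min_coi_barcode_reads,min_16s_reads depth floors (100 / 1000).
#' @return tibble: sample_id, barcode_reads, v4_reads, retained, reason.
#' @export
exclude_samples <- function(host_calls, v4_table,
                            min_coi_barcode_reads = 100L,
                            min_16s_reads = 1000L) {
  v4 <- v4_table %>%
    group_by(.data$sample_id) %>%
    summarise(v4_reads = sum(.data$count), .groups = "drop")
  out <- host_calls %>%
    select("sample_id", barcode_reads = "barcode_count") %>%
    full_join(v4, by = "sample_id") %>%
    mutate(barcode_reads = tidyr::replace_na(.data$barcode_reads, 0L),
           v4_reads = tidyr::replace_na(.data$v4_reads, 0L),
           retained = .data$barcode_reads >= min_coi_barcode_reads &
             .data$v4_reads >= min_16s_reads,
           reason = case_when(
             .data$barcode_reads < min_coi_barcode_reads &
               .data$v4_reads < min_16s_reads ~ "low COI barcode and 16S depth",
             .data$barcode_reads < min_coi_barcode_reads ~ "low COI barcode depth",
             .data$v4_reads < min_16s_reads ~ "low 16S depth",
             TRUE ~ "retained"))
  out
}

#' Restrict an OTU table to abundant OTUs (display view)
#'
#' Keeps OTUs whose relative abundance reaches `display_frac` in at least
#' one library and reports the mean per-library coverage of the view.
#'
#' @param table OTU-level long count tibble.
#' @param display_frac relative abundance threshold (default 0.01).
#' @return list with `table` (the view), `otu_ids`, and `mean_coverage`
#'   (mean over libraries of the fraction of reads the view captures).
#' @export
display_filter <- function(table, display_frac = 0.01) {
  ra <- add_relabund(table)
  keep <- ra %>%
    group_by(.data$feature_id) %>%
    summarise(max_frac = max(.data$rel_abund), .groups = "drop") %>%
    filter(.data$max_frac >= display_frac) %>%
    pull("feature_id")
  cov <- ra %>%
    group_by(.data$sample_id) %>%
    summarise(cov = sum(.data$rel_abund[.data$feature_id %in% keep]),
              .groups = "drop")
  list(table = filter(table, .data$feature_id %in% keep),
       otu_ids = keep, mean_coverage = mean(cov$cov))
}
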