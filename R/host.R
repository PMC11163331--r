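# Host typing from COI tables: barcode selection, species verification
# against morphology, numt flagging, heteroplasmy calls and off-target
# (parasitoid / endosymbiont) detection with cross-marker reconciliation.

#' Select the host barcode zOTU for every sample
#'
#' The barcode is the most abundant COI zOTU classified to the host genus;
#' ties are broken by zOTU abundance rank (id order). Samples without any
#' host-genus zOTU get no barcode row.
#'
#' @param zotu_table COI zOTU long count tibble (feature_id, sample_id,
#'   count).
#' @param taxonomy taxonomy tibble for the same features (needs `genus`).
#' @param target_genus host genus (default "Macrosteles").
#' @return tibble: sample_id, barcode_zotu, barcode_count, barcode_seq,
#'   species_molecular.
#' @export
select_barcode <- function(zotu_table, taxonomy,
                           target_genus = "Macrosteles") {
  host_feats <- taxonomy %>%
    filter(!is.na(.data$genus), .data$genus == target_genus)
  sel <- zotu_table %>%
    semi_join(host_feats, by = "feature_id") %>%
    mutate(rank = as.integer(sub("^zOTU", "", .data$feature_id))) %>%
    group_by(.data$sample_id) %>%
    arrange(dplyr::desc(.data$count), .data$rank, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  if (!"sequence" %in% names(sel)) {
    sel <- left_join(sel, select(host_feats, "feature_id", "sequence"),
                     by = "feature_id")
  }
  sel %>%
    left_join(select(host_feats, "feature_id", "species"),
              by = "feature_id") %>%
    select("sample_id", barcode_zotu = "feature_id",
           barcode_count = "count", barcode_seq = "sequence",
           species_molecular = "species")
}

#' Verify molecular species identity against morphology
#'
#' @param barcodes output of [select_barcode()].
#' @param manifest manifest tibble with `species_morph`.
#' @return tibble with id_match and a reassignment note for mismatches;
#'   downstream grouping should use `species_molecular`.
#' @export
verify_identity <- function(barcodes, manifest) {
  barcodes %>%
    left_join(select(manifest, "sample_id", "species_morph"),
              by = "sample_id") %>%
    mutate(id_match = !is.na(.data$species_morph) &
             .data$species_morph == .data$species_molecular,
           note = if_else(.data$id_match, "match",
                          paste0("reassigned ", .data$species_morph,
                                 " -> ", .data$species_molecular)))
}

#' Flag numt-like secondary host OTUs
#'
#' A host-genus OTU other than a sample's barcode OTU is numt-like iff, in
#' every library where it occurs, the barcode OTU occurs too and the
#' secondary OTU's library fraction is at most `max_frac`. Violations
#' (e.g. a secondary OTU dominating a library) are logged as anomalies,
#' not numts.
#'
#' @param otu_table COI OTU long count tibble.
#' @param otu_taxonomy taxonomy for OTU features (needs `genus`).
#' @param barcodes output of [select_barcode()].
#' @param otu_map zOTU->OTU mapping from [cluster_97()].
#' @param target_genus host genus.
#' @param max_frac numt library-fraction ceiling (default 0.10).
#' @return list with `numts` (otu_id, n_samples, max_library_frac, verdict)
#'   and `anomalies` (sample-level violations).
#' @export
flag_numts <- function(otu_table, otu_taxonomy, barcodes, otu_map,
                       target_genus = "Macrosteles", max_frac = 0.10) {
  barcode_otu <- barcodes %>%
    left_join(select(otu_map, "zotu_id", "otu_id"),
              by = c(barcode_zotu = "zotu_id")) %>%
    select("sample_id", barcode_otu = "otu_id")
  host_otus <- otu_taxonomy %>%
    filter(!is.na(.data$genus), .data$genus == target_genus) %>%
    pull("feature_id")
  ra <- add_relabund(otu_table)
  cand <- ra %>%
    filter(.data$feature_id %in% host_otus) %>%
    left_join(barcode_otu, by = "sample_id") %>%
    filter(is.na(.data$barcode_otu) |
             .data$feature_id != .data$barcode_otu)
  per_occ <- cand %>%
    mutate(with_barcode = !is.na(.data$barcode_otu),
           under_ceiling = .data$rel_abund <= max_frac)
  verdicts <- per_occ %>%
    group_by(otu_id = .data$feature_id) %>%
    summarise(n_samples = n(),
              max_library_frac = max(.data$rel_abund),
              always_with_barcode = all(.data$with_barcode),
              always_under_ceiling = all(.data$under_ceiling),
              .groups = "drop") %>%
    mutate(verdict = if_else(.data$always_with_barcode &
                               .data$always_under_ceiling,
                             "numt_like", "anomaly"))
  anomalies <- per_occ %>%
    filter(!.data$with_barcode | !.data$under_ceiling) %>%
    mutate(issue = if_else(!.data$with_barcode, "no barcode in library",
                           "secondary host OTU above numt ceiling")) %>%
    select(otu_id = "feature_id", "sample_id", "rel_abund", "issue")
  list(numts = verdicts, anomalies = anomalies)
}

#' Call within-individual mitochondrial variants (heteroplasmy)
#'
#' Non-barcode zOTUs belonging to a sample's barcode OTU are reported as
#' heteroplasmy variants when their per-library read count is at least
#' `min_reads` and their fraction of the barcode OTU's reads in that
#' library at least `min_frac`. With `denominator = "library"` the fraction
#' is taken over the whole COI library instead.
#'
#' @param zotu_table COI zOTU long count tibble (with `sequence`).
#' @param otu_map zOTU->OTU mapping.
#' @param barcodes output of [select_barcode()].
#' @param min_reads read floor (default 100).
#' @param min_frac fraction floor (default 0.05).
#' @param denominator "otu" (reads of the barcode OTU, default) or
#'   "library".
#' @return tibble: sample_id, zotu_id, count, fraction, distance_subs,
#'   has_indels; a sample is heteroplasmic iff it has at least one row.
#' @export
call_heteroplasmy <- function(zotu_table, otu_map, barcodes,
                              min_reads = 100L, min_frac = 0.05,
                              denominator = c("otu", "library")) {
  denominator <- match.arg(denominator)
  z2o <- select(otu_map, "zotu_id", "otu_id")
  barcode_otu <- barcodes %>%
    left_join(z2o, by = c(barcode_zotu = "zotu_id")) %>%
    select("sample_id", "barcode_zotu", "barcode_seq",
           barcode_otu = "otu_id")
  tab <- zotu_table %>%
    left_join(z2o, by = c(feature_id = "zotu_id")) %>%
    inner_join(barcode_otu, by = "sample_id")
  denom <- if (denominator == "otu") {
    tab %>%
      filter(.data$otu_id == .data$barcode_otu) %>%
      group_by(.data$sample_id) %>%
      summarise(denom = sum(.data$count), .groups = "drop")
  } else {
    tab %>%
      group_by(.data$sample_id) %>%
      summarise(denom = sum(.data$count), .groups = "drop")
  }
  calls <- tab %>%
    filter(.data$otu_id == .data$barcode_otu,
           .data$feature_id != .data$barcode_zotu) %>%
    left_join(denom, by = "sample_id") %>%
    mutate(fraction = .data$count / .data$denom) %>%
    filter(.data$count >= min_reads, .data$fraction >= min_frac)
  if (nrow(calls) == 0) {
    return(tibble(sample_id = character(), zotu_id = character(),
                  count = integer(), fraction = numeric(),
                  distance_subs = integer(), has_indels = logical()))
  }
  dists <- purrr::map2(calls$sequence, calls$barcode_seq, variant_distance)
  calls %>%
    mutate(distance_subs = vapply(dists, function(d) as.integer(d$subs),
                                  integer(1)),
           has_indels = vapply(dists, function(d) d$indels > 0,
                               logical(1))) %>%
    select("sample_id", zotu_id = "feature_id", "count", "fraction",
           "distance_subs", "has_indels")
}

#' Detect off-target COI signals (parasitoids, bacterial endosymbionts)
#'
#' COI OTUs with non-host lineages are categorized: an insect lineage
#' outside the host family is a parasitoid candidate; a Rickettsiales
#' lineage is an endosymbiont COI detection; anything else is logged as
#' `other`. Detections with at least `min_reads` reads are tier
#' "detected", the rest "trace".
#'
#' @param otu_table COI OTU long count tibble.
#' @param otu_taxonomy taxonomy for the OTUs (ranked columns).
#' @param host_family host family (default "Cicadellidae").
#' @param min_reads evidence floor for the "detected" tier (default 100).
#' @return tibble: sample_id, otu_id, category, taxon, count, tier.
#' @export
detect_offtarget <- function(otu_table, otu_taxonomy,
                             host_family = "Cicadellidae",
                             min_reads = 100L) {
  cls <- otu_taxonomy %>%
    mutate(category = case_when(
      !is.na(.data$family) & .data$family == host_family ~ "host",
      !is.na(.data$class) & .data$class == "Insecta" ~ "parasitoid",
      !is.na(.data$order) & .data$order == "Rickettsiales" ~
        "endosymbiont_coi",
      TRUE ~ "other")) %>%
    select("feature_id", "category", taxon = "genus", "lineage")
  otu_table %>%
    inner_join(cls, by = "feature_id") %>%
    filter(.data$category != "host", .data$count > 0) %>%
    mutate(tier = if_else(.data$count >= min_reads, "detected", "trace")) %>%
    select("sample_id", otu_id = "feature_id", "category", "taxon",
           "count", "tier")
}

#' Cross-marker co-detection of endosymbiont genera
#'
#' Compares COI-based detections of the given genera with their 16S-based
#' detection per sample.
#'
#' @param coi_detections output of [detect_offtarget()].
#' @param s16_table 16S long count tibble.
#' @param s16_taxonomy taxonomy for the 16S features (needs `genus`).
#' @param sample_ids shared sample universe.
#' @param genera genera to reconcile (default Wolbachia, Rickettsia).
#' @return list with `table` (sample x genus status: both / coi_only /
#'   s16_only / neither) and `agreement` (per genus: fraction of samples
#'   with concordant detection status).
#' @export
cross_marker_codetection <- function(coi_detections, s16_table,
                                     s16_taxonomy, sample_ids,
                                     genera = c("Wolbachia", "Rickettsia")) {
  s16_genus <- s16_table %>%
    inner_join(select(s16_taxonomy, "feature_id", "genus"),
               by = "feature_id") %>%
    filter(.data$genus %in% genera, .data$count > 0) %>%
    distinct(.data$sample_id, .data$genus) %>%
    mutate(in_16s = TRUE)
  coi_genus <- coi_detections %>%
    filter(.data$category == "endosymbiont_coi", .data$taxon %in% genera) %>%
    distinct(.data$sample_id, genus = .data$taxon) %>%
    mutate(in_coi = TRUE)
  grid <- tidyr::expand_grid(sample_id = sample_ids, genus = genera)
  tab <- grid %>%
    left_join(coi_genus, by = c("sample_id", "genus")) %>%
    left_join(s16_genus, by = c("sample_id", "genus")) %>%
    mutate(in_coi = tidyr::replace_na(.data$in_coi, FALSE),
           in_16s = tidyr::replace_na(.data$in_16s, FALSE),
           status = case_when(.data$in_coi & .data$in_16s ~ "both",
                              .data$in_coi ~ "coi_only",
                              .data$in_16s ~ "s16_only",
                              TRUE ~ "neither"))
  agreement <- tab %>%
    group_by(.data$genus) %>%
    summarise(n = n(),
              agreement = mean(.data$in_coi == .data$in_16s),
              both = sum(.data$status == "both"),
              either = sum(.data$in_coi | .data$in_16s),
              .groups = "drop")
  list(table = tab, agreement = agreement)
}
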