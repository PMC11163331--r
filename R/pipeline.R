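# End-to-end orchestration: reads -> bins -> contigs -> uniques -> zOTUs ->
# OTUs -> taxonomy -> decontaminated tables -> host calls.

#' Run the full amplicon pipeline on a set of read pairs
#'
#' Executes primer binning, pair merging, expected-error filtering, global
#' dereplication with singleton removal, denoising, chimera screening (16S
#' markers only), 97% clustering, taxonomy assignment, negative-control
#' decontamination of the 16S tables (at zOTU level, propagated to OTUs),
#' non-target lineage removal, host typing and sample exclusion.
#'
#' @param reads read-pair tibble (sample_id, read_id, fwd_seq, fwd_qual,
#'   rev_seq, rev_qual), e.g. from [read_run_fastq()] or [simulate_run()].
#' @param manifest manifest tibble (see [parse_manifest()]).
#' @param refdb_coi,refdb_16s reference tibbles (id, lineage, sequence).
#' @param markers marker tibble.
#' @param max_ee expected-error filter threshold.
#' @param denoise_mode passed to [denoise()].
#' @param target_genus host genus for barcode selection.
#' @param params filter thresholds, see [filter_params()].
#' @return list of class `symbiomark_run`; see the methods vignette for the
#'   component-by-component walk-through.
#' @export
run_amplicon_pipeline <- function(reads, manifest, refdb_coi, refdb_16s,
                                  markers = default_markers(),
                                  max_ee = 1.0,
                                  denoise_mode = "per_sample",
                                  target_genus = "Macrosteles",
                                  params = filter_params()) {
  reads <- reads[, c("sample_id", "read_id", "fwd_seq", "fwd_qual",
                     "rev_seq", "rev_qual")]
  binned <- bin_reads(reads, markers)
  contigs <- merge_pairs(binned)
  kept <- quality_filter(contigs, markers, max_ee = max_ee)
  uniques <- dereplicate(kept)
  zotus <- denoise(uniques, mode = denoise_mode)

  s16_markers <- names(marker_targets())[marker_targets() == "16S"]
  chim <- screen_chimeras(filter(zotus, .data$marker %in% s16_markers))
  otu_map <- cluster_97(
    anti_join(zotus, filter(chim, .data$chimera),
              by = c("marker", "zotu_id")))
  tables <- build_tables(zotus, otu_map, chimera_flags = chim)

  # taxonomy per marker family
  tax_of <- function(tab, db) {
    feats <- distinct(tab, .data$marker, .data$feature_id, .data$sequence)
    assign_taxonomy(feats, db)
  }
  ztab <- tables$zotu; otab <- tables$otu
  tax_z <- bind_rows(
    tax_of(filter(ztab, .data$marker == "COI"), refdb_coi),
    tax_of(filter(ztab, .data$marker != "COI"), refdb_16s))
  tax_o <- bind_rows(
    tax_of(filter(otab, .data$marker == "COI"), refdb_coi),
    tax_of(filter(otab, .data$marker != "COI"), refdb_16s))

  # host typing on COI
  coi_z <- filter(ztab, .data$marker == "COI")
  coi_o <- filter(otab, .data$marker == "COI")
  barcodes <- select_barcode(coi_z, filter(tax_z, .data$marker == "COI"),
                             target_genus)
  identity_report <- verify_identity(barcodes, manifest)
  coi_map <- filter(otu_map, .data$marker == "COI")
  numts <- flag_numts(coi_o, filter(tax_o, .data$marker == "COI"),
                      barcodes, coi_map, target_genus)
  heteroplasmy <- call_heteroplasmy(
    coi_z, coi_map, barcodes,
    min_reads = params$min_zotu_reads, min_frac = params$min_zotu_frac)
  offtarget <- detect_offtarget(coi_o, filter(tax_o, .data$marker == "COI"))

  # decontamination of 16S tables at zOTU level, propagated to OTU level
  cleaned_z <- list(); cleaned_o <- list(); contam_reports <- list()
  nontarget_removed <- list()
  for (m in intersect(s16_markers, unique(ztab$marker))) {
    zt <- filter(ztab, .data$marker == m)
    dec <- decontaminate(zt, manifest, contam_ratio = params$contam_ratio)
    contam_reports[[m]] <- mutate(dec$report, marker = m)
    nt <- remove_non_target(
      dec$table, filter(tax_z, .data$marker == m) %>%
        select("feature_id", "lineage"))
    nontarget_removed[[m]] <- mutate(nt$removed, marker = m)
    cleaned_z[[m]] <- nt$table
    cleaned_o[[m]] <- nt$table %>%
      inner_join(select(filter(otu_map, .data$marker == m),
                        "zotu_id", "otu_id"),
                 by = c(feature_id = "zotu_id")) %>%
      group_by(marker = .data$marker, feature_id = .data$otu_id,
               .data$sample_id) %>%
      summarise(count = sum(.data$count), .groups = "drop")
  }
  cleaned_zotu <- bind_rows(cleaned_z)
  cleaned_otu <- bind_rows(cleaned_o)

  v4 <- filter(cleaned_zotu, .data$marker == "16S-V4")
  exclusion <- exclude_samples(
    barcodes, v4,
    min_coi_barcode_reads = params$min_coi_barcode_reads,
    min_16s_reads = params$min_16s_reads)
  retained <- exclusion$sample_id[exclusion$retained]

  structure(list(
    binned = binned, contigs = kept, uniques = uniques,
    zotus = zotus, chimera_flags = chim, otu_map = otu_map,
    tables = tables, taxonomy_zotu = tax_z, taxonomy_otu = tax_o,
    barcodes = barcodes, identity_report = identity_report,
    numts = numts, heteroplasmy = heteroplasmy, offtarget = offtarget,
    cleaned_zotu = cleaned_zotu, cleaned_otu = cleaned_otu,
    contaminant_report = bind_rows(contam_reports),
    nontarget_removed = bind_rows(nontarget_removed),
    exclusion = exclusion, retained_samples = retained,
    manifest = manifest, params = params), class = "symbiomark_run")
}

#' @export
print.symbiomark_run <- function(x, ...) {
  cat("<symbiomark_run>\n")
  cat("  samples:", dplyr::n_distinct(x$manifest$sample_id),
      "( retained:", length(x$retained_samples), ")\n")
  for (m in unique(x$zotus$marker)) {
    nz <- dplyr::n_distinct(x$zotus$zotu_id[x$zotus$marker == m])
    no <- dplyr::n_distinct(x$otu_map$otu_id[x$otu_map$marker == m])
    cat(sprintf("  %-9s %4d zOTUs, %4d OTUs\n", m, nz, no))
  }
  invisible(x)
}
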