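# Miniature reference databases emitted by the simulator: a COI database in
# a MIDORI-like dialect (species-name headers + a lineage map) and a 16S
# database in a SILVA-like dialect (taxonomy= headers), including decoy
# records for the non-target filter (mitochondria, chloroplast, Eukaryota,
# Archaea).

#' Build miniature COI and 16S reference databases for a simulation
#'
#' Emits one annotated record per simulated source sequence (species
#' haplotypes, parasitoids, bacterial COI; every 16S operon variant) plus
#' decoy taxa so the non-target lineage filter is exercised: Eukaryota and
#' Archaea 16S decoys in addition to the organelle records.
#'
#' @param config a [sim_config()] object.
#' @return list with `coi` and `s16` tibbles (columns `id`, `lineage`,
#'   `sequence`).
#' @export
build_reference_db <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(config$species) == 0 || nrow(config$symbionts) == 0) {
    abort("species_pool and symbiont_pool must be non-empty")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed * 31L %% .Machine$integer.max + 11L)

  src <- sim_sources(config)
  coi <- src %>%
    filter(.data$marker == "COI", .data$category != "numt") %>%
    mutate(id = paste0("COIREF_", gsub("\\|", "_", .data$source_id))) %>%
    select("id", "lineage", "sequence") %>%
    distinct(.data$sequence, .keep_all = TRUE)

  s16 <- src %>%
    filter(.data$marker == "16S-V4") %>%
    mutate(id = paste0("S16REF_", gsub("\\|", "_", .data$source_id))) %>%
    select("id", "lineage", "sequence") %>%
    distinct(.data$sequence, .keep_all = TRUE)
  # V1-V2 sequences under the same taxonomy (a 16S database covers both
  # amplified regions of the gene)
  s16b <- src %>%
    filter(.data$marker == "16S-V1V2") %>%
    mutate(id = paste0("S16REF_", gsub("\\|", "_", .data$source_id))) %>%
    select("id", "lineage", "sequence") %>%
    distinct(.data$sequence, .keep_all = TRUE)

  decoys <- tibble(
    id = c("S16REF_decoy_euk", "S16REF_decoy_arch"),
    lineage = c(
      "Eukaryota;Opisthokonta;Fungi;Ascomycota;Saccharomycetaceae;Saccharomyces;Saccharomyces_cerevisiae",
      "Archaea;Euryarchaeota;Methanobacteria;Methanobacteriales;Methanobacteriaceae;Methanobrevibacter;Methanobrevibacter_smithii"),
    sequence = random_seqs(2, SIM_AMPLICON_LEN[["16S-V4"]]))

  s16 <- bind_rows(s16, s16b, decoys)
  if (anyDuplicated(coi$id) || anyDuplicated(s16$id)) {
    abort("duplicate taxon labels in reference database")
  }
  list(coi = coi, s16 = s16)
}

#' Write a 16S reference database in SILVA-like FASTA dialect
#'
#' Headers have the form `>id taxonomy=k;p;c;o;f;g;s`.
#'
#' @param db tibble with `id`, `lineage`, `sequence`.
#' @param path output FASTA path.
#' @export
write_refdb_16s <- function(db, path) {
  writeLines(paste0(">", db$id, " taxonomy=", db$lineage, "\n", db$sequence),
             path)
  invisible(path)
}

#' Write a COI reference database in MIDORI-like dialect
#'
#' FASTA headers carry `>id species_name`; the full ranked lineage is
#' written to a sidecar `<path>.lineage.tsv` map.
#'
#' @inheritParams write_refdb_16s
#' @export
write_refdb_coi <- function(db, path) {
  species <- vapply(strsplit(db$lineage, ";", fixed = TRUE),
                    function(x) x[length(x)], character(1))
  writeLines(paste0(">", db$id, " ", species, "\n", db$sequence), path)
  write.table(db[, c("id", "lineage")],
              paste0(path, ".lineage.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference database written by the refdb writers
#'
#' Detects the SILVA-like `taxonomy=` dialect; otherwise expects the
#' MIDORI-like dialect with its `.lineage.tsv` sidecar.
#'
#' @param path FASTA path.
#' @return tibble with `id`, `lineage`, `sequence`.
#' @export
read_refdb <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hdr <- names(x)
  id <- sub(" .*", "", hdr)
  if (any(grepl("taxonomy=", hdr, fixed = TRUE))) {
    lineage <- sub(".*taxonomy=", "", hdr)
  } else {
    side <- paste0(path, ".lineage.tsv")
    if (!file.exists(side)) {
      abort(paste0("lineage map not found: ", side))
    }
    map <- read.table(side, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    lineage <- map$lineage[match(id, map$id)]
  }
  tibble(id = id, lineage = lineage, sequence = unname(as.character(x)))
}

# Synthetic full-length 16S references (one per pool taxon) embedding the
# V1-V2 and V4 amplicons of the taxon's first operon variant; used by the
# cross-region concordance mapping.
build_fulllength_16s <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed * 13L %% .Machine$integer.max + 5L)
  sy <- config$symbionts
  tibble(
    id = paste0("FL_", sy$name),
    taxon = sy$name,
    genus = sy$genus,
    lineage = sy$lineage,
    sequence = vapply(seq_len(nrow(sy)), function(i) {
      v <- sy$variants[[i]]
      paste0(random_seqs(1, 60), v$v1v2[1], random_seqs(1, 120), v$v4[1],
             random_seqs(1, 60))
    }, character(1)))
}
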