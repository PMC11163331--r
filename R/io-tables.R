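# TSV output of feature tables and reports (features as rows, samples as
# columns, matching the downstream-tool dialect) and abundance-annotated
# FASTA for intermediate unique sequences.

#' Write a long count table as a features x samples TSV
#'
#' @param table long count tibble (feature_id, sample_id, count).
#' @param path output path.
#' @export
write_feature_table <- function(table, path) {
  wide <- table %>%
    select("feature_id", "sample_id", "count") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                       values_fill = 0L)
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a features x samples TSV back into a long count tibble
#'
#' @param path TSV path written by [write_feature_table()].
#' @return long tibble (feature_id, sample_id, count) without zero rows.
#' @export
read_feature_table <- function(path) {
  wide <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                               check.names = FALSE,
                               stringsAsFactors = FALSE))
  wide %>%
    tidyr::pivot_longer(-"feature_id", names_to = "sample_id",
                        values_to = "count") %>%
    filter(.data$count > 0) %>%
    mutate(count = as.integer(.data$count))
}

#' Write unique sequences as abundance-annotated FASTA
#'
#' Headers carry the `;size=N` annotation used by downstream denoising
#' tools.
#'
#' @param uniques output of [dereplicate()].
#' @param path output FASTA path.
#' @export
write_uniques_fasta <- function(uniques, path) {
  u <- distinct(uniques, .data$sequence, .keep_all = TRUE)
  writeLines(paste0(">Uniq", seq_len(nrow(u)), ";size=", u$total_abundance,
                    "\n", u$sequence), path)
  invisible(path)
}
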