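# Marker and primer definitions for the three amplified regions:
# insect COI (BF3/BR2), bacterial 16S rRNA V1-V2 (27F/338R) and V4
# (515F/806R). Primer sequences follow the primer literature; `length_range`
# is the accepted merged-amplicon length (primers excluded).

#' Default marker definitions
#'
#' One row per amplified marker region with its forward/reverse primer
#' (IUPAC) and the accepted merged-amplicon length range (bp, without
#' primers). Values can be overridden by passing a modified tibble to the
#' binning and filtering functions.
#'
#' @return a tibble with columns `marker`, `fwd_primer`, `rev_primer`,
#'   `len_min`, `len_max`.
#' @examples
#' default_markers()
#' @export
default_markers <- function() {
  tibble(
    marker = c("COI", "16S-V1V2", "16S-V4"),
    fwd_primer = c("CCHGAYATRGCHTTYCCHCG",  # BF3
                   "AGAGTTTGATCMTGGCTCAG",  # 27F
                   "GTGYCAGCMGCCGCGGTAA"),  # 515F
    rev_primer = c("TCDGGRTGNCCRAARAAYCA",  # BR2
                   "TGCTGCCTCCCGTAGGAGT",   # 338R
                   "GGACTACNVGGGTWTCTAAT"), # 806R
    len_min = c(380L, 270L, 230L),
    len_max = c(460L, 350L, 280L)
  )
}

# Simulated amplicon lengths per marker (constant per marker so that
# substitution-only distances are well defined; real amplicons vary mildly).
SIM_AMPLICON_LEN <- c("COI" = 418L, "16S-V1V2" = 310L, "16S-V4" = 253L)

marker_targets <- function() {
  c("COI" = "COI", "16S-V1V2" = "16S", "16S-V4" = "16S")
}
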