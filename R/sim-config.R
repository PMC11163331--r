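#' Configuration for a synthetic multi-marker sequencing run
#'
#' Builds a validated simulation configuration. Pool tables (species,
#' symbionts, contaminant-bearing taxa, parasitoids) are generated from the
#' seed unless supplied; their defaults emulate a leafhopper cohort with
#' obligate and facultative endosymbionts, organelle 16S, reagent
#' contaminants, heteroplasmy, numts and parasitoid COI (see the methods
#' vignette for the full rationale of every default).
#'
#' @param n_specimens number of insect specimens.
#' @param n_controls named integer vector of water-control library counts
#'   per role: `extraction`, `pcr`, `index`.
#' @param markers marker definition tibble, see [default_markers()].
#' @param species,symbionts,parasitoids,bacterial_coi optional pool tables
#'   overriding the generated defaults.
#' @param error_rate per-base substitution probability in `[0, 0.05]`.
#' @param chimera_rate fraction of amplicons replaced by two-parent PCR
#'   chimeras, in `[0, 0.2]`.
#' @param reads_mean,reads_size negative-binomial mean and size (dispersion)
#'   of per-specimen, per-marker read counts; scalars, or vectors named by
#'   marker for per-marker depths.
#' @param control_reads_mean,control_reads_size same for 16S bins of water
#'   controls (control COI bins are empty).
#' @param coi_conc Dirichlet concentration for within-specimen COI
#'   composition (mitochondrial fractions are tightly regulated).
#' @param phyto_carriage named probabilities of Phytoplasma carriage given
#'   nested-PCR status (`positive`, `negative`, `not_tested`). Nested PCR
#'   is the sensitive screen, so carriage given a positive status is 1;
#'   the much lower amplicon detection fractions emerge from the highly
#'   skewed within-host titre distribution and finite sequencing depth.
#' @param pcr_positive_frac fraction of pre-screened specimens scored
#'   nested-PCR positive.
#' @param mislabel_rate probability that the morphological species label
#'   differs from the molecular identity.
#' @param crosstalk_rate index cross-talk rate (reads leaking between
#'   samples); off by default.
#' @param seed integer seed driving pool generation and the run itself.
#' @return an object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(n_specimens = 5, seed = 1)
#' cfg$n_specimens
#' @export
sim_config <- function(n_specimens = 40,
                       n_controls = c(extraction = 2, pcr = 2, index = 2),
                       markers = default_markers(),
                       species = NULL,
                       symbionts = NULL,
                       parasitoids = NULL,
                       bacterial_coi = NULL,
                       error_rate = 0.001,
                       chimera_rate = 0.01,
                       reads_mean = 2000,
                       reads_size = 4,
                       control_reads_mean = 300,
                       control_reads_size = 2,
                       coi_conc = 300,
                       phyto_carriage = c(positive = 1.0, negative = 0.41,
                                          not_tested = 0.30),
                       pcr_positive_frac = 0.378,
                       mislabel_rate = 10 / 306,
                       crosstalk_rate = 0,
                       seed = 1L) {
  stopifnot(n_specimens >= 1)
  if (!all(c("extraction", "pcr", "index") %in% names(n_controls))) {
    abort("n_controls must name the three control roles: extraction, pcr, index")
  }
  if (error_rate < 0 || error_rate > 0.05) {
    abort("error_rate must be in [0, 0.05]")
  }
  if (chimera_rate < 0 || chimera_rate > 0.2) {
    abort("chimera_rate must be in [0, 0.2]")
  }
  if (!all(c("COI", "16S-V1V2", "16S-V4") %in% markers$marker)) {
    abort("markers must cover at least one COI and one 16S target")
  }
  seed <- as.integer(seed)

  # generate the sequence pools deterministically from the seed
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed * 7757L %% .Machine$integer.max)
  if (is.null(species)) species <- default_species_pool()
  if (is.null(symbionts)) symbionts <- default_symbiont_pool()
  if (is.null(parasitoids)) parasitoids <- default_parasitoid_pool()
  if (is.null(bacterial_coi)) bacterial_coi <- default_bacterial_coi()

  if (anyDuplicated(symbionts$name)) abort("duplicate symbiont names")
  if (anyDuplicated(species$species)) abort("duplicate species names")
  for (i in seq_len(nrow(species))) {
    mh <- species$minor_haps[[i]]
    if (nrow(mh) && any(mh$fraction >= 0.5)) {
      abort("minor haplotype fractions must stay below the dominant fraction")
    }
    nt <- species$numts[[i]]
    if (nrow(nt) && any(nt$mean_frac > 0.10)) {
      abort("numt per-library fractions must be <= 0.10")
    }
  }
  for (i in seq_len(nrow(symbionts))) {
    w <- symbionts$variants[[i]]$weight
    if (any(w <= 0)) abort("operon copy-ratio weights must be positive")
    symbionts$variants[[i]]$weight <- w / sum(w)
  }

  structure(list(
    n_specimens = as.integer(n_specimens),
    n_controls = n_controls,
    markers = markers,
    species = species,
    symbionts = symbionts,
    parasitoids = parasitoids,
    bacterial_coi = bacterial_coi,
    error_rate = error_rate,
    chimera_rate = chimera_rate,
    reads_mean = reads_mean,
    reads_size = reads_size,
    control_reads_mean = control_reads_mean,
    control_reads_size = control_reads_size,
    coi_conc = coi_conc,
    phyto_carriage = phyto_carriage,
    pcr_positive_frac = pcr_positive_frac,
    mislabel_rate = mislabel_rate,
    crosstalk_rate = crosstalk_rate,
    seed = seed
  ), class = "sim_config")
}

# scalar or per-marker (named) simulation parameter lookup
marker_param <- function(x, m) {
  if (!is.null(names(x)) && m %in% names(x)) unname(x[[m]]) else unname(x[1])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_specimens, "specimens,",
      sum(x$n_controls), "controls,",
      nrow(x$markers), "markers, error_rate", x$error_rate,
      ", chimera_rate", x$chimera_rate, ", seed", x$seed, "\n")
  invisible(x)
}
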