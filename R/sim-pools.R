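# Default species / symbiont / contaminant pools for the synthetic-run
# generator. The pools emulate the structure of a leafhopper (Macrosteles)
# cohort: one dominant host species plus six rarer congeners, obligate
# nutritional endosymbionts (Sulcia, Nasuia) in every specimen, a
# high-prevalence facultative symbiont (Arsenophonus) with four divergent
# rRNA-operon variants at fixed copy ratios, patchy facultative symbionts,
# a low-titre plant pathogen (Phytoplasma) with two 50/50 operon variants,
# host organelle 16S (mitochondrion, chloroplast), reagent contaminants
# shared with water controls, and pipunculid parasitoid COI.
#
# Sequences are synthetic: drawn from the RNG seeded by the config seed.
# Related sequences (haplotypes, numts, operon variants) are derived by a
# fixed number of substitutions so that denoising/clustering distances are
# exactly controlled.

# Number of substitutions used when deriving related sequences
NUMT_SUBS <- 17L        # ~4% of 418 bp: separate 97% OTU, outside d_max
OPERON_SUBS_V4 <- 13L   # ~5% of 253 bp: separate 97% OTUs (divergent operons)
OPERON_SUBS_V1V2 <- 16L
PHYTO_VARIANT_SUBS <- 2L # two rRNA variants within one genome, same OTU

default_species_pool <- function() {
  base_coi <- random_seqs(1, SIM_AMPLICON_LEN[["COI"]])
  species <- tibble(
    species = c("Macrosteles_laevis", "Macrosteles_sexnotatus",
                "Macrosteles_cristatus", "Macrosteles_maculosus",
                "Macrosteles_viridigriseus", "Macrosteles_quadrilineatus",
                "Macrosteles_frontalis"),
    genus = "Macrosteles",
    freq = c(0.85, 0.03, 0.04, 0.02, 0.03, 0.02, 0.01)
  )
  # each species' dominant haplotype: ~10% substitutions from a common base
  species$coi_seq <- vapply(seq_len(nrow(species)), function(i) {
    mutate_seq(base_coi, 42L)
  }, character(1))

  # minor mitochondrial haplotypes (heteroplasmy): 1-2 substitutions from
  # the dominant haplotype, carried by a fraction of specimens
  species$minor_haps <- lapply(seq_len(nrow(species)), function(i) {
    sp <- species$species[i]
    if (sp == "Macrosteles_laevis") {
      tibble(seq = mutate_seq(species$coi_seq[i], 1L),
             fraction = 0.20, prevalence = 0.159)
    } else if (sp == "Macrosteles_viridigriseus") {
      tibble(seq = mutate_seq(species$coi_seq[i], 2L),
             fraction = 0.33, prevalence = 0.5)
    } else if (sp == "Macrosteles_quadrilineatus") {
      tibble(seq = mutate_seq(species$coi_seq[i], 1L),
             fraction = 0.15, prevalence = 0.10)
    } else {
      tibble(seq = character(), fraction = numeric(), prevalence = numeric())
    }
  })

  # nuclear mitochondrial paralogs: always co-amplifying at low fraction
  species$numts <- lapply(seq_len(nrow(species)), function(i) {
    if (species$species[i] == "Macrosteles_laevis") {
      tibble(seq = c(mutate_seq(species$coi_seq[i], NUMT_SUBS),
                     mutate_seq(species$coi_seq[i], NUMT_SUBS + 3L)),
             mean_frac = c(0.03, 0.01))
    } else {
      tibble(seq = mutate_seq(species$coi_seq[i], NUMT_SUBS),
             mean_frac = 0.02)
    }
  })

  # facultative symbiont prevalence per species (overrides pool defaults)
  species$symbionts <- list(
    tibble(name = c("Arsenophonus", "Wolbachia", "Rickettsia"),
           prevalence = c(0.822, 0.02, 0.01)),
    tibble(name = "Arsenophonus", prevalence = 0.5),
    tibble(name = c("Arsenophonus", "Cardinium"), prevalence = c(0.5, 0.875)),
    tibble(name = c("Lariskella", "Wolbachia"), prevalence = c(1.0, 0.2)),
    tibble(name = c("Cardinium", "Wolbachia"), prevalence = c(0.67, 0.33)),
    tibble(name = c("Cardinium", "Gammaproteobacterium_X"),
           prevalence = c(1.0, 0.8)),
    tibble(name = character(), prevalence = numeric())
  )
  species
}

# One row per 16S source taxon. `alpha` values (Dirichlet weights) are
# mean relative abundance x per-category concentration: obligate symbionts
# and organelles are tightly regulated (conc 10), facultative/pathogen/
# contaminant taxa highly overdispersed (conc 5), reproducing the wide
# observed ranges (e.g. a 45% mean obligate spanning ~4-84%).
default_symbiont_pool <- function() {
  len1 <- SIM_AMPLICON_LEN[["16S-V1V2"]]
  len4 <- SIM_AMPLICON_LEN[["16S-V4"]]
  pool <- tibble(
    name = c("Sulcia", "Nasuia", "Arsenophonus", "Wolbachia", "Rickettsia",
             "Cardinium", "Lariskella", "Gammaproteobacterium_X",
             "Phytoplasma", "Pantoea",
             "host_mitochondrion", "chloroplast",
             "Ralstonia", "Sphingomonas", "Methylobacterium"),
    genus = c("Sulcia", "Nasuia", "Arsenophonus", "Wolbachia", "Rickettsia",
              "Cardinium", "Lariskella", "Gammaproteobacterium_X",
              "Phytoplasma", "Pantoea", "Mitochondria", "Chloroplast",
              "Ralstonia", "Sphingomonas", "Methylobacterium"),
    category = c("obligate", "obligate", "facultative", "facultative",
                 "facultative", "facultative", "facultative", "facultative",
                 "pathogen", "other", "organelle", "organelle",
                 "contaminant", "contaminant", "contaminant"),
    lineage = c(
      "Bacteria;Bacteroidota;Flavobacteriia;Flavobacteriales;Blattabacteriaceae;Sulcia;Sulcia_muelleri",
      "Bacteria;Proteobacteria;Betaproteobacteria;Burkholderiales;Nasuiaceae;Nasuia;Nasuia_deltocephalinicola",
      "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacterales;Morganellaceae;Arsenophonus;Arsenophonus_sp",
      "Bacteria;Proteobacteria;Alphaproteobacteria;Rickettsiales;Anaplasmataceae;Wolbachia;Wolbachia_sp",
      "Bacteria;Proteobacteria;Alphaproteobacteria;Rickettsiales;Rickettsiaceae;Rickettsia;Rickettsia_sp",
      "Bacteria;Bacteroidota;Cytophagia;Cytophagales;Amoebophilaceae;Cardinium;Cardinium_sp",
      "Bacteria;Proteobacteria;Alphaproteobacteria;Rickettsiales;Midichloriaceae;Lariskella;Lariskella_sp",
      "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacterales;Enterobacteriaceae;Gammaproteobacterium_X;Gammaproteobacterium_X_sp",
      "Bacteria;Tenericutes;Mollicutes;Acholeplasmatales;Acholeplasmataceae;Phytoplasma;Phytoplasma_asteris",
      "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacterales;Erwiniaceae;Pantoea;Pantoea_agglomerans",
      "Bacteria;Proteobacteria;Alphaproteobacteria;Rickettsiales;Mitochondria;Mitochondria;Macrosteles_mitochondrion",
      "Bacteria;Cyanobacteria;Cyanobacteriia;Chloroplast;Chloroplast;Chloroplast;Plant_chloroplast",
      "Bacteria;Proteobacteria;Betaproteobacteria;Burkholderiales;Burkholderiaceae;Ralstonia;Ralstonia_sp",
      "Bacteria;Proteobacteria;Alphaproteobacteria;Sphingomonadales;Sphingomonadaceae;Sphingomonas;Sphingomonas_sp",
      "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Methylobacteriaceae;Methylobacterium;Methylobacterium_sp"),
    mean_abund = c(0.453, 0.266, 0.15, 0.03, 0.02, 0.05, 0.01, 0.04,
                   0.02, 0.002, 0.05, 0.02, 0.004, 0.004, 0.003),
    conc = c(10, 10, 5, 5, 5, 5, 5, 5, 5, 5, 10, 10, 5, 5, 5),
    default_prevalence = c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0.26, 1, 1, 1, 1, 1),
    control_mean = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0.45, 0.35, 0.2),
    dropout_markers = list(character(), "16S-V1V2", character(), character(),
                           character(), character(), character(), character(),
                           character(), character(), character(), character(),
                           character(), character(), character())
  )
  pool$alpha <- pool$mean_abund * pool$conc

  # rRNA operon variants per taxon: Arsenophonus carries four divergent
  # copies at fixed ratios; Phytoplasma two near-identical copies at 50/50;
  # everything else a single copy.
  pool$variants <- lapply(seq_len(nrow(pool)), function(i) {
    v1 <- random_seqs(1, len1)
    v4 <- random_seqs(1, len4)
    nm <- pool$name[i]
    if (nm == "Arsenophonus") {
      tibble(variant = paste0(nm, "_op", 1:4),
             weight = c(0.4, 0.3, 0.2, 0.1),
             v1v2 = c(v1, vapply(1:3, function(k)
               mutate_seq(v1, OPERON_SUBS_V1V2 * k), character(1))),
             v4 = c(v4, vapply(1:3, function(k)
               mutate_seq(v4, OPERON_SUBS_V4 * k), character(1))))
    } else if (nm == "Phytoplasma") {
      tibble(variant = paste0(nm, "_op", 1:2),
             weight = c(0.5, 0.5),
             v1v2 = c(v1, mutate_seq(v1, PHYTO_VARIANT_SUBS)),
             v4 = c(v4, mutate_seq(v4, PHYTO_VARIANT_SUBS)))
    } else {
      tibble(variant = nm, weight = 1, v1v2 = v1, v4 = v4)
    }
  })
  pool
}

default_parasitoid_pool <- function() {
  tibble(
    name = c("Eudorylas_fuscipes", "Pipunculus_omissinervis"),
    genus = c("Eudorylas", "Pipunculus"),
    lineage = c(
      "Animalia;Arthropoda;Insecta;Diptera;Pipunculidae;Eudorylas;Eudorylas_fuscipes",
      "Animalia;Arthropoda;Insecta;Diptera;Pipunculidae;Pipunculus;Pipunculus_omissinervis"),
    prevalence = c(0.036, 0.003),
    mean_frac = c(0.03, 0.02),
    conc = 5,
    coi_seq = random_seqs(2, SIM_AMPLICON_LEN[["COI"]])
  )
}

# COI sequences for Rickettsiales endosymbionts (co-amplified off-target)
default_bacterial_coi <- function() {
  tibble(
    name = c("Wolbachia", "Rickettsia"),
    lineage = c(
      "Bacteria;Proteobacteria;Alphaproteobacteria;Rickettsiales;Anaplasmataceae;Wolbachia;Wolbachia_sp",
      "Bacteria;Proteobacteria;Alphaproteobacteria;Rickettsiales;Rickettsiaceae;Rickettsia;Rickettsia_sp"),
    mean_frac = c(0.01, 0.01),
    codetect_prob = 0.8,
    coi_seq = random_seqs(2, SIM_AMPLICON_LEN[["COI"]])
  )
}
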