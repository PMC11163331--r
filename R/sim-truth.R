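# Ground-truth generation: who is in the cohort, what each specimen carries,
# and how many reads each source sequence contributes per sample and marker.
# Rendering those counts into FASTQ reads lives in sim-reads.R.

#' Source sequences of a simulation configuration
#'
#' One row per (marker, source sequence): host haplotypes, minor haplotypes,
#' numts, parasitoid and bacterial COI, and every 16S rRNA operon variant of
#' every pool taxon.
#'
#' @param config a [sim_config()] object.
#' @return tibble with columns `marker`, `source_id`, `taxon`, `genus`,
#'   `category`, `lineage`, `sequence`.
#' @export
sim_sources <- function(config) {
  sp <- config$species
  coi <- list()
  for (i in seq_len(nrow(sp))) {
    s <- sp$species[i]
    lin <- paste("Animalia;Arthropoda;Insecta;Hemiptera;Cicadellidae",
                 sp$genus[i], s, sep = ";")
    coi[[length(coi) + 1]] <- tibble(
      marker = "COI", source_id = paste0(s, "|dom"), taxon = s,
      genus = sp$genus[i], category = "host_dominant", lineage = lin,
      sequence = sp$coi_seq[i])
    mh <- sp$minor_haps[[i]]
    if (nrow(mh)) {
      coi[[length(coi) + 1]] <- tibble(
        marker = "COI", source_id = paste0(s, "|minor", seq_len(nrow(mh))),
        taxon = s, genus = sp$genus[i], category = "host_minor",
        lineage = lin, sequence = mh$seq)
    }
    nt <- sp$numts[[i]]
    if (nrow(nt)) {
      coi[[length(coi) + 1]] <- tibble(
        marker = "COI", source_id = paste0(s, "|numt", seq_len(nrow(nt))),
        taxon = s, genus = sp$genus[i], category = "numt",
        lineage = lin, sequence = nt$seq)
    }
  }
  pa <- config$parasitoids
  coi[[length(coi) + 1]] <- tibble(
    marker = "COI", source_id = paste0(pa$name, "|coi"), taxon = pa$name,
    genus = pa$genus, category = "parasitoid", lineage = pa$lineage,
    sequence = pa$coi_seq)
  bc <- config$bacterial_coi
  coi[[length(coi) + 1]] <- tibble(
    marker = "COI", source_id = paste0(bc$name, "|coi"), taxon = bc$name,
    genus = bc$name, category = "bacterial_coi", lineage = bc$lineage,
    sequence = bc$coi_seq)

  sy <- config$symbionts
  s16 <- list()
  for (i in seq_len(nrow(sy))) {
    v <- sy$variants[[i]]
    for (m in c("16S-V1V2", "16S-V4")) {
      if (m %in% sy$dropout_markers[[i]]) next
      s16[[length(s16) + 1]] <- tibble(
        marker = m, source_id = paste0(v$variant, "|", m),
        taxon = sy$name[i], genus = sy$genus[i], category = sy$category[i],
        lineage = sy$lineage[i],
        sequence = if (m == "16S-V4") v$v4 else v$v1v2)
    }
  }
  bind_rows(bind_rows(coi), bind_rows(s16))
}

#' Simulate cohort ground truth (manifest, carriage, per-sample read counts)
#'
#' Draws the cohort (species identities, metadata, nested-PCR status),
#' per-specimen symbiont carriage, per-sample/per-marker library sizes
#' (negative binomial) and within-sample composition counts
#' (Dirichlet-multinomial around the pool means), plus PCR chimera events.
#' Controls contain only contaminant-pool taxa. Deterministic for a fixed
#' config seed.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `sim_truth`: a list with `manifest`,
#'   `specimens` (true species and carriage), `sources` (see
#'   [sim_sources()]), `composition` (sample_id, marker, source_id, count)
#'   and `chimeras` (chimeric source rows with parent ids and breakpoints).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  sources <- sim_sources(config)
  sp <- config$species
  sy <- config$symbionts
  n <- config$n_specimens

  # --- cohort assembly -------------------------------------------------
  species_true <- sample(sp$species, n, replace = TRUE, prob = sp$freq)
  mislabel <- runif(n) < config$mislabel_rate
  species_morph <- species_true
  for (i in which(mislabel)) {
    species_morph[i] <- sample(setdiff(sp$species, species_true[i]), 1)
  }
  site <- sample(c("Szczecinek", "Sosnicowice"), n, replace = TRUE)
  year <- sample(2015:2018, n, replace = TRUE)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  pcr <- if_else(runif(n) < config$pcr_positive_frac, "positive", "negative")

  specimen_ids <- sprintf("S%03d", seq_len(n))
  roles <- rep(c("control_extraction", "control_pcr", "control_index"),
               times = c(config$n_controls[["extraction"]],
                         config$n_controls[["pcr"]],
                         config$n_controls[["index"]]))
  control_ids <- sprintf("NC%02d", seq_along(roles))
  manifest <- bind_rows(
    tibble(sample_id = specimen_ids, role = "specimen",
           species_morph = species_morph, site = site, year = year,
           sex = sex, nested_pcr_status = pcr),
    tibble(sample_id = control_ids, role = roles,
           species_morph = NA_character_, site = NA_character_,
           year = NA_integer_, sex = NA_character_,
           nested_pcr_status = "not_tested"))

  # --- per-specimen carriage ------------------------------------------
  sp_idx <- match(species_true, sp$species)
  carriage <- vector("list", n)
  for (i in seq_len(n)) {
    over <- sp$symbionts[[sp_idx[i]]]
    prev <- setNames(sy$default_prevalence, sy$name)
    if (nrow(over)) prev[over$name] <- over$prevalence
    prev[["Phytoplasma"]] <- config$phyto_carriage[[pcr[i]]]
    carried <- sy$name[runif(nrow(sy)) < prev]
    carriage[[i]] <- carried
  }
  mh <- sp$minor_haps[sp_idx]
  het_carrier <- vapply(seq_len(n), function(i) {
    nrow(mh[[i]]) > 0 && runif(1) < mh[[i]]$prevalence[1]
  }, logical(1))
  pa <- config$parasitoids
  para_carrier <- lapply(seq_len(n), function(i) {
    pa$name[runif(nrow(pa)) < pa$prevalence]
  })
  bc <- config$bacterial_coi
  coi_codetect <- lapply(seq_len(n), function(i) {
    hit <- intersect(carriage[[i]], bc$name)
    hit[runif(length(hit)) < bc$codetect_prob[match(hit, bc$name)]]
  })

  specimens <- tibble(
    sample_id = specimen_ids, species_true = species_true,
    species_morph = species_morph, mislabeled = mislabel,
    heteroplasmy_carrier = het_carrier,
    symbionts = carriage, parasitoids = para_carrier,
    coi_codetect = coi_codetect)

  # --- library sizes ---------------------------------------------------
  mk <- config$markers$marker
  depths <- list()
  for (m in mk) {
    depths[[m]] <- setNames(
      c(rnbinom(n, mu = marker_param(config$reads_mean, m),
                size = marker_param(config$reads_size, m)),
        if (marker_targets()[[m]] == "16S") {
          rnbinom(length(control_ids), mu = config$control_reads_mean,
                  size = config$control_reads_size)
        } else rep(0L, length(control_ids))),
      c(specimen_ids, control_ids))
  }

  # --- composition draws ----------------------------------------------
  comp_rows <- list()
  chim_rows <- list()
  s16_markers <- mk[marker_targets()[mk] == "16S"]

  draw_counts <- function(alphas, depth) {
    if (depth == 0 || !length(alphas)) {
      return(integer(length(alphas)))
    }
    g <- rgamma(length(alphas), shape = alphas, rate = 1)
    if (sum(g) == 0) g[] <- 1
    as.integer(rmultinom(1, depth, g / sum(g)))
  }

  seq_by_marker <- split(setNames(sources$sequence, sources$source_id),
                         sources$marker)

  add_chimeras <- function(sample_id, marker, ids, counts, depth) {
    # replace a Binomial(depth, chimera_rate) share of reads with chimeric
    # amplicons formed from abundant same-marker parents; plain vectors
    # throughout (this runs per sample and marker)
    n_chim <- if (config$chimera_rate > 0) {
      rbinom(1, depth, config$chimera_rate)
    } else 0L
    if (n_chim == 0 || length(ids) < 2 || sum(counts > 0) < 2) {
      return(list(ids = ids, counts = counts, chim = NULL))
    }
    seqs <- seq_by_marker[[marker]]
    remaining <- n_chim
    k <- 0L
    ev <- list(source_id = character(), sequence = character(),
               parent_a = character(), parent_b = character(),
               breakpoint = integer(), count = integer(),
               degenerate = logical())
    while (remaining > 0) {
      size <- min(remaining, 1L + stats::rpois(1, 2))
      pool <- which(counts > 1)
      if (length(pool) < 2) break
      par <- sample(pool, 2, prob = counts[pool])
      a <- seqs[[ids[par[1]]]]; b <- seqs[[ids[par[2]]]]
      L <- nchar(a)
      bp <- sample(seq(floor(L / 3), floor(2 * L / 3)), 1)
      # take the chimeric reads away from the parents, keeping the total;
      # shrink the event if the parents cannot spare enough reads
      take1 <- min(ceiling(size / 2), counts[par[1]] - 1L)
      take2 <- min(size - take1, counts[par[2]] - 1L)
      size <- take1 + take2
      if (size <= 0) break
      k <- k + 1L
      ev$source_id[k] <- paste0("chimera|", sample_id, "|", marker, "|", k)
      ev$sequence[k] <- form_chimera(a, b, bp)
      ev$parent_a[k] <- ids[par[1]]
      ev$parent_b[k] <- ids[par[2]]
      ev$breakpoint[k] <- bp
      ev$count[k] <- size
      ev$degenerate[k] <- identical(a, b)
      counts[par] <- counts[par] - c(take1, take2)
      remaining <- remaining - size
    }
    chim <- if (k) {
      tibble(marker = marker, source_id = ev$source_id, taxon = "chimera",
             genus = NA_character_, category = "chimera",
             lineage = NA_character_, sequence = ev$sequence,
             parent_a = ev$parent_a, parent_b = ev$parent_b,
             breakpoint = ev$breakpoint, sample_id = sample_id,
             count = ev$count, degenerate = ev$degenerate)
    } else NULL
    list(ids = ids, counts = counts, chim = chim)
  }

  for (i in seq_len(n)) {
    sid <- specimen_ids[i]
    si <- sp_idx[i]

    # COI alphas: dominant haplotype takes the residual of the host pool
    host_named <- c()
    mhi <- mh[[i]]
    minor_frac <- if (het_carrier[i]) mhi$fraction[1] else 0
    nti <- sp$numts[[si]]
    dom_mean <- 1 - minor_frac - sum(nti$mean_frac)
    alphas <- c(config$coi_conc * dom_mean)
    ids <- paste0(species_true[i], "|dom")
    if (het_carrier[i]) {
      alphas <- c(alphas, config$coi_conc * minor_frac)
      ids <- c(ids, paste0(species_true[i], "|minor1"))
    }
    if (nrow(nti)) {
      alphas <- c(alphas, config$coi_conc * nti$mean_frac)
      ids <- c(ids, paste0(species_true[i], "|numt", seq_len(nrow(nti))))
    }
    for (pn in para_carrier[[i]]) {
      j <- match(pn, pa$name)
      alphas <- c(alphas, pa$conc[j] * pa$mean_frac[j])
      ids <- c(ids, paste0(pn, "|coi"))
    }
    for (bn in coi_codetect[[i]]) {
      j <- match(bn, bc$name)
      alphas <- c(alphas, 5 * bc$mean_frac[j])
      ids <- c(ids, paste0(bn, "|coi"))
    }
    cnt <- draw_counts(alphas, depths[["COI"]][[sid]])
    res <- add_chimeras(sid, "COI", ids, cnt, depths[["COI"]][[sid]])
    comp_rows[[length(comp_rows) + 1]] <-
      list(sample_id = sid, marker = "COI", source_id = res$ids,
           count = res$counts)
    if (!is.null(res$chim)) chim_rows[[length(chim_rows) + 1]] <- res$chim

    # 16S: one taxon-level Dirichlet draw shared by both regions (the same
    # template pool is amplified), then marker dropout + operon split
    carried <- carriage[[i]]
    tax_idx <- which(sy$name %in% carried)
    g <- rgamma(length(tax_idx), shape = sy$alpha[tax_idx], rate = 1)
    if (length(g) && sum(g) == 0) g[] <- 1
    for (m in s16_markers) {
      keep <- !vapply(sy$dropout_markers[tax_idx],
                      function(d) m %in% d, logical(1))
      gi <- g[keep]
      ti <- tax_idx[keep]
      depth <- depths[[m]][[sid]]
      if (length(gi) == 0 || depth == 0) next
      tax_counts <- as.integer(rmultinom(1, depth, gi / sum(gi)))
      ids_m <- character(0); cnt_m <- integer(0)
      for (k in seq_along(ti)) {
        v <- sy$variants[[ti[k]]]
        ids_m <- c(ids_m, paste0(v$variant, "|", m))
        cnt_m <- c(cnt_m, as.integer(rmultinom(1, tax_counts[k], v$weight)))
      }
      res <- add_chimeras(sid, m, ids_m, cnt_m, depth)
      comp_rows[[length(comp_rows) + 1]] <-
        list(sample_id = sid, marker = m, source_id = res$ids,
             count = res$counts)
      if (!is.null(res$chim)) chim_rows[[length(chim_rows) + 1]] <- res$chim
    }
  }

  # controls: contaminant taxa only
  contam_idx <- which(sy$category == "contaminant")
  for (cid in control_ids) {
    for (m in s16_markers) {
      depth <- depths[[m]][[cid]]
      if (depth == 0) next
      alphas <- sy$control_mean[contam_idx] * sy$conc[contam_idx]
      cnt <- draw_counts(alphas, depth)
      ids_m <- character(0); cnt_m <- integer(0)
      for (k in seq_along(contam_idx)) {
        v <- sy$variants[[contam_idx[k]]]
        ids_m <- c(ids_m, paste0(v$variant, "|", m))
        cnt_m <- c(cnt_m, as.integer(rmultinom(1, cnt[k], v$weight)))
      }
      comp_rows[[length(comp_rows) + 1]] <-
        list(sample_id = cid, marker = m, source_id = ids_m, count = cnt_m)
    }
  }

  composition <- if (length(comp_rows) == 0) {
    tibble(sample_id = character(), marker = character(),
           source_id = character(), count = integer())
  } else {
    nrows <- lengths(lapply(comp_rows, `[[`, "source_id"))
    tibble(
      sample_id = rep(vapply(comp_rows, `[[`, character(1), "sample_id"),
                      nrows),
      marker = rep(vapply(comp_rows, `[[`, character(1), "marker"), nrows),
      source_id = unlist(lapply(comp_rows, `[[`, "source_id"),
                         use.names = FALSE),
      count = as.integer(unlist(lapply(comp_rows, `[[`, "count"),
                                use.names = FALSE)))
  }
  composition <- composition %>%
    filter(.data$count > 0) %>%
    select("sample_id", "marker", "source_id", "count")

  # optional index cross-talk: a Binomial(depth, rate) share of each
  # library's reads is replaced by molecules drawn from the run-wide
  # pooled composition of the same marker (reads leaking between samples
  # during indexing/sequencing); totals are conserved
  if (config$crosstalk_rate > 0) {
    composition <- apply_crosstalk(composition, config$crosstalk_rate)
  }
  chimeras <- if (length(chim_rows)) bind_rows(chim_rows) else
    tibble(marker = character(), source_id = character(), taxon = character(),
           genus = character(), category = character(), lineage = character(),
           sequence = character(), parent_a = character(),
           parent_b = character(), breakpoint = integer(),
           sample_id = character(), count = integer(), degenerate = logical())

  structure(list(manifest = manifest, specimens = specimens,
                 sources = sources, composition = composition,
                 chimeras = chimeras, config = config),
            class = "sim_truth")
}

apply_crosstalk <- function(composition, rate) {
  out <- composition
  for (m in unique(out$marker)) {
    idx_m <- which(out$marker == m)
    pool <- out[idx_m, ] %>%
      group_by(.data$source_id) %>%
      summarise(total = sum(.data$count), .groups = "drop")
    for (sid in unique(out$sample_id[idx_m])) {
      rows <- idx_m[out$sample_id[idx_m] == sid]
      depth <- sum(out$count[rows])
      n_leak <- rbinom(1, depth, rate)
      if (n_leak == 0) next
      # remove n_leak reads from the library's own molecules ...
      take <- as.integer(rmultinom(1, n_leak, out$count[rows]))
      out$count[rows] <- out$count[rows] - take
      # ... and replace them with draws from the run-wide pool
      gain <- as.integer(rmultinom(1, n_leak, pool$total))
      hit <- which(gain > 0)
      for (h in hit) {
        j <- rows[match(pool$source_id[h], out$source_id[rows])]
        if (!is.na(j)) {
          out$count[j] <- out$count[j] + gain[h]
        } else {
          out <- bind_rows(out, tibble(
            sample_id = sid, marker = m, source_id = pool$source_id[h],
            count = gain[h]))
        }
      }
    }
  }
  filter(out, .data$count > 0)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>", nrow(x$specimens), "specimens,",
      sum(x$manifest$role != "specimen"), "controls,",
      nrow(x$composition), "composition rows\n")
  invisible(x)
}
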