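# Population-level summaries and statistics: prevalence tables, rRNA-operon
# strain grouping, cross-region concordance, distance matrices, distance-
# based redundancy analysis with permutation ANOVA, chi-square association,
# and nested-PCR concordance.

#' Symbiont prevalence and mean relative abundance by group
#'
#' A retained specimen counts as infected with a taxon iff the taxon's
#' post-filter read count exceeds `detection_floor` (default 0: any
#' retained reads). Groups are defined by the grouping columns present in
#' `groups` (e.g. molecular species, site, year).
#'
#' @param table long count tibble (feature_id, sample_id, count); features
#'   should be pre-aggregated to the taxon of interest (pass a `taxon`
#'   column via `taxonomy` to aggregate by genus).
#' @param taxonomy tibble feature_id -> taxon (e.g. genus); features with
#'   NA taxon are dropped.
#' @param sample_groups tibble with sample_id and grouping columns.
#' @param groups character vector of grouping column names.
#' @param detection_floor reads strictly above this count infected (0).
#' @return tibble: one row per taxon x group with n, n_infected,
#'   prevalence (NA when n = 0) and mean_rel_abund.
#' @export
prevalence <- function(table, taxonomy, sample_groups,
                       groups = c("species_molecular", "site", "year"),
                       detection_floor = 0) {
  groups <- intersect(groups, names(sample_groups))
  table <- table[, c("feature_id", "sample_id", "count")]
  ra <- add_relabund(table) %>%
    inner_join(select(taxonomy, "feature_id", "taxon"), by = "feature_id") %>%
    filter(!is.na(.data$taxon)) %>%
    group_by(.data$sample_id, .data$taxon) %>%
    summarise(count = sum(.data$count), rel_abund = sum(.data$rel_abund),
              .groups = "drop")
  grid <- tidyr::expand_grid(
    sample_id = unique(sample_groups$sample_id),
    taxon = unique(ra$taxon))
  full <- grid %>%
    left_join(ra, by = c("sample_id", "taxon")) %>%
    mutate(count = tidyr::replace_na(.data$count, 0L),
           rel_abund = tidyr::replace_na(.data$rel_abund, 0)) %>%
    inner_join(sample_groups, by = "sample_id")
  out <- full %>%
    group_by(.data$taxon, dplyr::across(dplyr::all_of(groups))) %>%
    summarise(n = dplyr::n_distinct(.data$sample_id),
              n_infected = sum(.data$count > detection_floor),
              mean_rel_abund = mean(.data$rel_abund),
              .groups = "drop") %>%
    mutate(prevalence = if_else(.data$n > 0,
                                .data$n_infected / .data$n, NA_real_))
  out
}

#' Group co-occurring features into candidate rRNA-operon strain groups
#'
#' Same-genus features whose presence patterns and abundance ratios are
#' consistent with fixed per-genome copy ratios are grouped: two features
#' are linked iff they co-occur in at least `copresence_min` of the samples
#' where either occurs and the coefficient of variation of their
#' per-sample abundance ratio (orientation-normalized) across shared
#' samples is at most `ratio_cv_max`. Connected components of size >= 2 are
#' single-strain candidates.
#'
#' A library where one feature of a pair is absent counts against
#' co-presence only when the present partner has at least
#' `min_partner_reads` — an absence next to a handful of partner reads is
#' expected sampling dropout, not evidence of independence.
#'
#' @param table long count tibble restricted to the features of interest
#'   (typically one genus).
#' @param copresence_min minimum co-presence fraction (default 0.9).
#' @param ratio_cv_max maximum abundance-ratio CV (default 0.35).
#' @param min_shared minimum number of shared samples to evaluate a pair
#'   (default 3).
#' @param min_partner_reads partner-count floor for a discordant library
#'   to count as evidence against co-presence (default 20).
#' @return tibble: feature_id, group (integer id), group_size, verdict
#'   (`single_strain_candidate` / `independent`).
#' @export
group_operon_variants <- function(table, copresence_min = 0.9,
                                  ratio_cv_max = 0.35, min_shared = 3L,
                                  min_partner_reads = 20L) {
  wide <- table %>%
    filter(.data$count > 0) %>%
    select("feature_id", "sample_id", "count") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                       values_fill = 0L)
  feats <- wide$feature_id
  m <- as.matrix(wide[, -1, drop = FALSE])
  k <- length(feats)
  adj <- matrix(FALSE, k, k)
  totals <- rowSums(m)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      pi <- m[i, ] > 0; pj <- m[j, ] > 0
      both <- pi & pj
      # discordant libraries are informative only when the present
      # partner is abundant enough that a sampling zero is implausible
      disc <- (pi & !pj & m[i, ] >= min_partner_reads) |
        (pj & !pi & m[j, ] >= min_partner_reads)
      denom <- sum(both) + sum(disc)
      if (denom == 0) next
      if (sum(both) / denom < copresence_min) next
      # ratio stability is judged where both features are quantifiable;
      # a ratio against a 2-read count is counting noise, not biology
      ok <- both & m[i, ] >= min_partner_reads & m[j, ] >= min_partner_reads
      if (sum(ok) < min_shared) next
      a <- m[i, ok]; b <- m[j, ok]
      r <- if (totals[i] >= totals[j]) a / b else b / a
      cv <- stats::sd(r) / mean(r)
      if (is.finite(cv) && cv <= ratio_cv_max) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  # connected components
  comp <- integer(k)
  cur <- 0L
  for (i in seq_len(k)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (comp[v] > 0L) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  sizes <- tabulate(comp)
  tibble(feature_id = feats, group = comp,
         group_size = sizes[comp],
         verdict = if_else(sizes[comp] >= 2L,
                           "single_strain_candidate", "independent"))
}

#' Compare genus-level detection between two 16S regions
#'
#' V4 representatives are mapped to full-length references by best global
#' alignment of the amplicon within the reference; V1-V2 features are
#' mapped against the same reference set; genus-level presence and mean
#' relative abundance are compared per region over samples meeting the
#' per-marker depth floor in both regions.
#'
#' @param v4_table,v1v2_table long count tibbles with `sequence`.
#' @param fulllength_ref tibble `id`, `genus`, `sequence` (full-length 16S).
#' @param min_reads per-marker library floor for inclusion (default 1000).
#' @param min_identity minimum alignment identity for a mapping (0.9).
#' @param min_frac display threshold: a genus is focal in a region when its
#'   relative abundance reaches `min_frac` in at least one library
#'   (default 0.01); region-exclusive calls are made for focal genera only,
#'   so that sampling dropout of trace taxa is not misread as a primer
#'   dropout.
#' @return list with `samples` (shared retained sample ids), `genus_table`
#'   (genus x region detection counts, mean abundance, max library
#'   fraction, focal flags and status: `both` / `v4_only` / `v1v2_only` /
#'   `minor`) and `discordant` (focal genera absent from the other region).
#' @export
compare_regions <- function(v4_table, v1v2_table, fulllength_ref,
                            min_reads = 1000L, min_identity = 0.9,
                            min_frac = 0.01) {
  if (nrow(fulllength_ref) == 0) abort("full-length reference is empty")
  v4_table <- v4_table[, c("feature_id", "sequence", "sample_id", "count")]
  v1v2_table <- v1v2_table[, c("feature_id", "sequence", "sample_id",
                               "count")]
  deep <- function(tab) {
    tab %>%
      group_by(.data$sample_id) %>%
      summarise(total = sum(.data$count), .groups = "drop") %>%
      filter(.data$total >= min_reads) %>%
      pull("sample_id")
  }
  shared <- intersect(deep(v4_table), deep(v1v2_table))
  map_features <- function(tab) {
    feats <- distinct(tab, .data$feature_id, .data$sequence)
    genus <- vapply(feats$sequence, function(s) {
      ids <- vapply(fulllength_ref$sequence, function(ref) {
        al <- Biostrings::pairwiseAlignment(
          s, ref, type = "global-local",
          substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
            match = 1, mismatch = -2),
          gapOpening = 6, gapExtension = 1)
        Biostrings::nmatch(al) / nchar(s)
      }, numeric(1), USE.NAMES = FALSE)
      j <- which.max(ids)
      if (ids[j] >= min_identity) fulllength_ref$genus[j] else NA_character_
    }, character(1), USE.NAMES = FALSE)
    tibble(feature_id = feats$feature_id, genus = genus)
  }
  summarise_region <- function(tab) {
    tab %>%
      filter(.data$sample_id %in% shared) %>%
      add_relabund() %>%
      inner_join(map_features(tab), by = "feature_id") %>%
      filter(!is.na(.data$genus)) %>%
      group_by(.data$genus) %>%
      summarise(n_detected = dplyr::n_distinct(
        .data$sample_id[.data$count > 0]),
        mean_rel_abund = sum(.data$rel_abund) / length(shared),
        max_frac = max(.data$rel_abund),
        .groups = "drop")
  }
  g4 <- summarise_region(v4_table)
  g12 <- summarise_region(v1v2_table)
  genus_table <- full_join(
    rename(g4, n_v4 = "n_detected", abund_v4 = "mean_rel_abund",
           max_frac_v4 = "max_frac"),
    rename(g12, n_v1v2 = "n_detected", abund_v1v2 = "mean_rel_abund",
           max_frac_v1v2 = "max_frac"),
    by = "genus") %>%
    mutate(dplyr::across(c("n_v4", "n_v1v2"),
                         ~ tidyr::replace_na(.x, 0L)),
           dplyr::across(c("abund_v4", "abund_v1v2", "max_frac_v4",
                           "max_frac_v1v2"),
                         ~ tidyr::replace_na(.x, 0)),
           focal_v4 = .data$max_frac_v4 >= min_frac,
           focal_v1v2 = .data$max_frac_v1v2 >= min_frac,
           status = case_when(
             .data$focal_v4 & .data$n_v1v2 == 0 ~ "v4_only",
             .data$focal_v1v2 & .data$n_v4 == 0 ~ "v1v2_only",
             .data$n_v4 > 0 & .data$n_v1v2 > 0 ~ "both",
             TRUE ~ "minor"))
  list(samples = shared, genus_table = genus_table,
       discordant = filter(genus_table, .data$status %in%
                             c("v4_only", "v1v2_only")))
}

#' Pairwise sample distance matrix (Jaccard or Bray-Curtis)
#'
#' Jaccard is computed on presence/absence (`1 - |A n B| / |A u B|`),
#' Bray-Curtis on counts (`sum|x-y| / sum(x+y)`).
#'
#' @param table long count tibble.
#' @param metric "jaccard" or "bray_curtis".
#' @return a `dist` object over samples.
#' @export
distance_matrix <- function(table, metric = c("jaccard", "bray_curtis")) {
  metric <- match.arg(metric)
  wide <- table %>%
    select("sample_id", "feature_id", "count") %>%
    tidyr::pivot_wider(names_from = "feature_id", values_from = "count",
                       values_fill = 0L)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  zero <- rowSums(m) == 0
  if (any(zero)) {
    abort(paste0("all-zero sample(s): ",
                 paste(rownames(m)[zero], collapse = ", ")))
  }
  if (metric == "jaccard") {
    vegan::vegdist(m > 0, method = "jaccard", binary = TRUE)
  } else {
    vegan::vegdist(m, method = "bray")
  }
}

#' Distance-based redundancy analysis with permutation ANOVA
#'
#' Gower-centers the squared distance matrix, projects it onto the one-hot
#' design space of the categorical factors, and reports the fraction of
#' (positive-eigenvalue) variance explained. Per-factor significance comes
#' from sequentially-partitioned pseudo-F statistics with free permutation
#' of sample labels: `p = (1 + #[F_perm >= F_obs]) / (1 + n_perm)`.
#'
#' @param dist a `dist` object (samples in rows).
#' @param factors data frame of categorical factors (rows = samples, in
#'   `dist` order); each must have at least 2 levels.
#' @param n_perm number of permutations (default 999, minimum 99).
#' @param seed RNG seed for the permutations.
#' @return object of class `symbio_dbrda` with `variance_explained`,
#'   per-term `anova` tibble (df, ss, pseudo_f, p), `n_perm`, `seed`.
#' @export
constrained_variance <- function(dist, factors, n_perm = 999, seed = 1L) {
  if (n_perm < 99) abort("n_perm must be at least 99")
  d <- as.matrix(dist)
  n <- nrow(d)
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  stopifnot(nrow(factors) == n)
  G <- gower_center(d)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  total <- sum(ev[ev > sqrt(.Machine$double.eps)])

  terms <- names(factors)
  intercept_only <- length(terms) == 0 ||
    all(vapply(factors, function(f) length(unique(f)) < 2, logical(1)))
  if (!intercept_only) {
    for (t in terms) {
      if (length(unique(factors[[t]])) < 2) {
        abort(paste0("factor '", t, "' has a single level"))
      }
    }
  }

  # cumulative hat matrices for the sequential (by-terms) partition; the
  # design does not change under permutation, only G does, and because H is
  # idempotent tr(HGH) = tr(GH) = sum(G * H)
  H_list <- list(); ranks <- integer(0)
  if (!intercept_only) {
    for (k in seq_along(terms)) {
      X <- stats::model.matrix(
        ~., data = factors[, seq_len(k), drop = FALSE])[, -1, drop = FALSE]
      Xc <- scale(X, center = TRUE, scale = FALSE)
      H_list[[k]] <- hat_matrix(Xc)
      ranks[k] <- qr(Xc)$rank
    }
  }
  fit_stats <- function(G) {
    cum <- vapply(H_list, function(H) sum(G * H), numeric(1))
    list(ss = diff(c(0, cum)), model = cum[length(cum)],
         dfs = diff(c(0L, ranks)))
  }

  if (intercept_only) {
    res <- structure(list(variance_explained = 0,
                          anova = tibble(term = character(), df = integer(),
                                         ss = numeric(), pseudo_f = numeric(),
                                         p = numeric()),
                          total_inertia = total, n_perm = n_perm,
                          seed = seed),
                     class = "symbio_dbrda")
    return(res)
  }

  obs <- fit_stats(G)
  df_model <- sum(obs$dfs)
  df_res <- n - 1 - df_model
  ss_res <- total - obs$model
  f_obs <- (obs$ss / obs$dfs) / (ss_res / df_res)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  exceed <- numeric(length(terms))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    Gp <- G[idx, idx]
    pp <- fit_stats(Gp)
    ss_res_p <- total - pp$model
    f_p <- (pp$ss / pp$dfs) / (ss_res_p / df_res)
    exceed <- exceed + (f_p >= f_obs)
  }
  pvals <- (1 + exceed) / (1 + n_perm)

  structure(list(
    variance_explained = obs$model / total,
    anova = tibble(term = terms, df = obs$dfs, ss = obs$ss,
                   pseudo_f = f_obs, p = pvals),
    total_inertia = total, df_residual = df_res, ss_residual = ss_res,
    n_perm = n_perm, seed = seed), class = "symbio_dbrda")
}

gower_center <- function(d) {
  A <- -0.5 * d^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

hat_matrix <- function(X) {
  if (ncol(X) == 0) return(matrix(0, nrow(X), nrow(X)))
  qrX <- qr(X)
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  Q %*% t(Q)
}

#' @export
print.symbio_dbrda <- function(x, ...) {
  cat("Distance-based redundancy analysis\n")
  cat(sprintf("Variance explained by constraints: %.2f%%\n",
              100 * x$variance_explained))
  if (nrow(x$anova)) {
    cat(sprintf("Permutation ANOVA (%d permutations):\n", x$n_perm))
    print(as.data.frame(x$anova))
  }
  invisible(x)
}

#' @export
tidy.symbio_dbrda <- function(x, ...) x$anova

#' @export
glance.symbio_dbrda <- function(x, ...) {
  tibble(variance_explained = x$variance_explained,
         total_inertia = x$total_inertia,
         n_perm = x$n_perm, seed = x$seed)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Closed form `N (ad - bc)^2 / (r1 r2 c1 c2)` with df = 1; the Yates
#' continuity correction is off by default.
#'
#' @param counts 2x2 non-negative integer matrix with positive margins.
#' @param correct apply the continuity correction.
#' @return object of class `symbio_chisq` with `statistic`, `df`,
#'   `p_value`, `counts`.
#' @export
chi_square_2x2 <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("2x2 table has a zero margin")
  }
  a <- counts[1, 1]; b <- counts[1, 2]
  c <- counts[2, 1]; d <- counts[2, 2]
  N <- sum(counts)
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - N / 2)
  stat <- N * num^2 /
    (sum(counts[1, ]) * sum(counts[2, ]) * sum(counts[, 1]) *
       sum(counts[, 2]))
  structure(list(statistic = stat, df = 1L,
                 p_value = pchisq(stat, 1, lower.tail = FALSE),
                 counts = counts, correct = correct),
            class = "symbio_chisq")
}

#' @export
print.symbio_chisq <- function(x, ...) {
  cat(sprintf("Chi-square test: X^2 = %.4g, df = 1, p = %.4g%s\n",
              x$statistic, x$p_value,
              if (x$correct) " (continuity-corrected)" else ""))
  invisible(x)
}

#' @export
tidy.symbio_chisq <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' @export
glance.symbio_chisq <- function(x, ...) tidy.symbio_chisq(x)

#' Cross-tabulate amplicon detection against external binary labels
#'
#' Builds the (label x amplicon detection) 2x2 contingency table, e.g.
#' nested-PCR Phytoplasma status against any post-filter Phytoplasma reads,
#' with specimen lists per cell. Samples without a label are excluded.
#'
#' @param detections tibble sample_id, detected (logical).
#' @param labels tibble sample_id, label ("positive"/"negative"; anything
#'   else is treated as unlabeled and dropped).
#' @return list with `counts` (2x2 matrix: rows label +/-, cols detected
#'   yes/no), `cells` (specimen lists), `excluded` sample ids.
#' @export
detection_concordance <- function(detections, labels) {
  lab <- labels %>%
    filter(.data$label %in% c("positive", "negative"))
  excluded <- setdiff(labels$sample_id, lab$sample_id)
  x <- lab %>%
    left_join(detections, by = "sample_id") %>%
    mutate(detected = tidyr::replace_na(.data$detected, FALSE))
  counts <- matrix(
    c(sum(x$label == "positive" & x$detected),
      sum(x$label == "positive" & !x$detected),
      sum(x$label == "negative" & x$detected),
      sum(x$label == "negative" & !x$detected)),
    nrow = 2, byrow = TRUE,
    dimnames = list(label = c("positive", "negative"),
                    amplicon = c("detected", "not_detected")))
  cells <- list(
    positive_detected = x$sample_id[x$label == "positive" & x$detected],
    positive_not_detected = x$sample_id[x$label == "positive" & !x$detected],
    negative_detected = x$sample_id[x$label == "negative" & x$detected],
    negative_not_detected = x$sample_id[x$label == "negative" & !x$detected])
  list(counts = counts, cells = cells, excluded = excluded)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
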