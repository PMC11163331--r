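# Prevalence, strain grouping, distances, constrained ordination with
# permutation tests, chi-square, and detection concordance.

test_that("prevalence counts infected fractions per group", {
  tab <- tibble::tibble(feature_id = "zA",
                        sample_id = c("S1", "S2"),
                        count = c(10L, 3L))
  tax <- tibble::tibble(feature_id = "zA", taxon = "Arsenophonus")
  grp <- tibble::tibble(sample_id = paste0("S", 1:4),
                        site = "X")
  out <- prevalence(tab, tax, grp, groups = "site")
  expect_equal(out$n, 4)
  expect_equal(out$prevalence, 0.5)
  expect_equal(out$mean_rel_abund, (1 + 1 + 0 + 0) / 4)

  # empty group: prevalence reported as missing, not zero
  grp2 <- dplyr::bind_rows(grp, tibble::tibble(sample_id = character(),
                                               site = character()))
  out2 <- prevalence(tab, tax, grp2[0, ], groups = "site")
  expect_equal(nrow(out2), 0)
})

test_that("obligate symbionts estimate prevalence 1 on truth tables", {
  cfg <- sim_config(n_specimens = 30, reads_mean = 20000, chimera_rate = 0,
                    seed = 17)
  tr <- simulate_truth(cfg)
  tab <- truth_table(tr, "16S-V4")
  tax <- dplyr::distinct(tab, feature_id, taxon)
  grp <- tibble::tibble(sample_id = tr$specimens$sample_id, cohort = "all")
  out <- prevalence(tab[tab$sample_id %in% grp$sample_id, ], tax, grp,
                    groups = "cohort")
  expect_equal(out$prevalence[out$taxon == "Sulcia"], 1)
  expect_equal(out$prevalence[out$taxon == "Nasuia"], 1)
})

test_that("operon variants group; non-co-occurring features stay apart", {
  # two features always together at ~50/50
  set.seed(40)
  n <- 20
  base <- rpois(n, 300) + 50
  tab <- dplyr::bind_rows(
    tibble::tibble(feature_id = "a", sample_id = paste0("S", 1:n),
                   count = as.integer(round(base * runif(n, 0.48, 0.52)))),
    tibble::tibble(feature_id = "b", sample_id = paste0("S", 1:n),
                   count = as.integer(round(base * runif(n, 0.48, 0.52)))))
  g <- group_operon_variants(tab)
  expect_equal(unique(g$verdict), "single_strain_candidate")
  expect_equal(unique(g$group_size), 2L)

  # never co-occurring -> independent
  tab2 <- dplyr::bind_rows(
    tibble::tibble(feature_id = "a", sample_id = paste0("S", 1:10),
                   count = 100L),
    tibble::tibble(feature_id = "b", sample_id = paste0("S", 11:20),
                   count = 100L))
  g2 <- group_operon_variants(tab2)
  expect_equal(unique(g2$verdict), "independent")
})

test_that("the simulated 4-operon symbiont is one group; obligates split", {
  cfg <- sim_config(n_specimens = 40, reads_mean = 20000, chimera_rate = 0,
                    seed = 23)
  tr <- simulate_truth(cfg)
  tab <- truth_table(tr, "16S-V4")
  spec <- tr$specimens$sample_id
  ars <- tab[tab$taxon == "Arsenophonus" & tab$sample_id %in% spec, ]
  g <- group_operon_variants(ars)
  expect_equal(nrow(g), 4)
  expect_equal(unique(g$group_size), 4L)
  obl <- tab[tab$taxon %in% c("Sulcia", "Nasuia") & tab$sample_id %in% spec, ]
  g2 <- group_operon_variants(obl)
  expect_equal(dplyr::n_distinct(g2$group), 2)
})

test_that("distance matrices match the closed-form definitions", {
  # presence sets {A,B,C} vs {B,C,D}: Jaccard = 1 - 2/4
  tab <- dplyr::bind_rows(
    tibble::tibble(feature_id = c("A", "B", "C"), sample_id = "S1",
                   count = c(4L, 2L, 1L)),
    tibble::tibble(feature_id = c("B", "C", "D"), sample_id = "S2",
                   count = c(1L, 7L, 2L)))
  dj <- distance_matrix(tab, "jaccard")
  expect_equal(as.numeric(dj), 0.5)

  tab2 <- dplyr::bind_rows(
    tibble::tibble(feature_id = "x", sample_id = "S1", count = 2L),
    tibble::tibble(feature_id = "y", sample_id = "S2", count = 2L))
  db <- distance_matrix(tab2, "bray_curtis")
  expect_equal(as.numeric(db), 1.0)

  tab3 <- dplyr::bind_rows(
    tibble::tibble(feature_id = c("x", "y"), sample_id = "S1",
                   count = c(3L, 5L)),
    tibble::tibble(feature_id = c("x", "y"), sample_id = "S2",
                   count = c(3L, 5L)))
  expect_equal(as.numeric(distance_matrix(tab3, "jaccard")), 0)
  expect_equal(as.numeric(distance_matrix(tab3, "bray_curtis")), 0)

  tab4 <- tibble::tibble(feature_id = "x", sample_id = c("S1", "S2"),
                         count = c(0L, 5L))
  expect_error(distance_matrix(tab4, "jaccard"), "S1")
})

test_that("distances agree with brute-force formulas on random tables", {
  set.seed(41)
  for (rep in 1:5) {
    m <- matrix(rpois(6 * 8, 3), nrow = 6,
                dimnames = list(paste0("S", 1:6), paste0("f", 1:8)))
    m[m < 1] <- 0
    m[, 1] <- m[, 1] + 1  # avoid all-zero samples
    tab <- as.data.frame.table(m, stringsAsFactors = FALSE)
    names(tab) <- c("sample_id", "feature_id", "count")
    tab <- tab[tab$count > 0, ]
    dj <- as.matrix(distance_matrix(tibble::as_tibble(tab), "jaccard"))
    db <- as.matrix(distance_matrix(tibble::as_tibble(tab), "bray_curtis"))
    for (i in 1:5) for (j in (i + 1):6) {
      a <- m[i, ]; b <- m[j, ]
      jac <- 1 - sum(a > 0 & b > 0) / sum(a > 0 | b > 0)
      bc <- sum(abs(a - b)) / sum(a + b)
      expect_equal(dj[i, j], jac, tolerance = 1e-12)
      expect_equal(db[i, j], bc, tolerance = 1e-12)
    }
    # metric axioms
    expect_true(isSymmetric(dj))
    expect_true(all(diag(dj) == 0))
    expect_true(all(dj >= 0 & dj <= 1))
  }
})

test_that("constrained variance is 0 for an intercept-only design", {
  set.seed(42)
  m <- matrix(rpois(5 * 6, 5) + 1, nrow = 5,
              dimnames = list(paste0("S", 1:5), paste0("f", 1:6)))
  tab <- as.data.frame.table(m, stringsAsFactors = FALSE)
  names(tab) <- c("sample_id", "feature_id", "count")
  d <- distance_matrix(tibble::as_tibble(tab), "bray_curtis")
  res <- constrained_variance(d, data.frame(g = rep("a", 5)), n_perm = 99)
  expect_equal(res$variance_explained, 0)
})

test_that("two separated clusters explain almost all variance", {
  set.seed(43)
  g1 <- matrix(rpois(5 * 4, 40) + 20, nrow = 5)
  g2 <- matrix(rpois(5 * 4, 40) + 20, nrow = 5)
  m <- cbind(rbind(g1, matrix(0L, 5, 4)), rbind(matrix(0L, 5, 4), g2))
  rownames(m) <- paste0("S", 1:10); colnames(m) <- paste0("f", 1:8)
  tab <- as.data.frame.table(m, stringsAsFactors = FALSE)
  names(tab) <- c("sample_id", "feature_id", "count")
  tab <- tab[tab$count > 0, ]
  d <- distance_matrix(tibble::as_tibble(tab), "bray_curtis")
  fac <- data.frame(grp = rep(c("a", "b"), each = 5))
  res <- constrained_variance(d, fac, n_perm = 999, seed = 2)
  expect_gt(res$variance_explained, 0.9)
  expect_lte(res$anova$p, 0.05)
  # invariance under sample reordering
  idx <- sample(10)
  d2 <- as.matrix(d)[idx, idx]
  res2 <- constrained_variance(stats::as.dist(d2), fac[idx, , drop = FALSE],
                               n_perm = 99, seed = 2)
  expect_equal(res2$variance_explained, res$variance_explained,
               tolerance = 1e-10)
})

test_that("dbRDA agrees with the vegan reference implementation", {
  set.seed(44)
  m <- matrix(rpois(12 * 10, 8), nrow = 12,
              dimnames = list(paste0("S", 1:12), paste0("f", 1:10)))
  m[, 1] <- m[, 1] + 1
  fac <- data.frame(grp = rep(c("a", "b", "c"), each = 4),
                    loc = rep(c("x", "y"), 6))

  # non-Euclidean distance: the constrained inertia matches vegan exactly;
  # the variance fraction differs only in the pinned denominator choice
  # (positive eigenvalues here vs full trace in vegan)
  d <- vegan::vegdist(m, method = "bray")
  ours <- constrained_variance(d, fac, n_perm = 99, seed = 3)
  ref <- vegan::dbrda(d ~ grp + loc, data = fac)
  expect_equal(sum(ours$anova$ss), ref$CCA$tot.chi, tolerance = 1e-8)
  expect_gte(ours$total_inertia, ref$tot.chi)

  # Euclidean-embeddable distance: no negative eigenvalues, so the
  # explained fraction must match vegan exactly
  de <- stats::dist(m)
  ours_e <- constrained_variance(de, fac, n_perm = 99, seed = 3)
  ref_e <- vegan::dbrda(de ~ grp + loc, data = fac)
  expect_equal(ours_e$variance_explained,
               ref_e$CCA$tot.chi / ref_e$tot.chi, tolerance = 1e-8)
})

# independent oracle: pseudo-F for a one-factor design computed from
# scratch, enumerated over all label permutations of a 6-sample instance
test_that("permutation p matches exhaustive enumeration on 6 samples", {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  oracle_f <- function(dm, labels) {
    A <- -0.5 * dm^2
    n <- nrow(dm)
    J <- diag(n) - 1 / n
    G <- J %*% A %*% J
    X <- stats::model.matrix(~labels)[, -1, drop = FALSE]
    Xc <- scale(X, center = TRUE, scale = FALSE)
    H <- Xc %*% solve(crossprod(Xc)) %*% t(Xc)
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    tot <- sum(ev[ev > 1e-12])
    ssm <- sum(diag(H %*% G %*% H))
    dfm <- qr(Xc)$rank
    (ssm / dfm) / ((tot - ssm) / (n - 1 - dfm))
  }
  set.seed(45)
  m <- matrix(rpois(6 * 5, 6) + 1, nrow = 6,
              dimnames = list(paste0("S", 1:6), paste0("f", 1:5)))
  tab <- as.data.frame.table(m, stringsAsFactors = FALSE)
  names(tab) <- c("sample_id", "feature_id", "count")
  d <- distance_matrix(tibble::as_tibble(tab), "bray_curtis")
  labels <- c("a", "a", "a", "b", "b", "b")
  dm <- as.matrix(d)

  f_obs <- oracle_f(dm, labels)
  all_f <- vapply(perms(1:6), function(p) oracle_f(dm[p, p], labels),
                  numeric(1))
  p_exact <- mean(all_f >= f_obs - 1e-12)

  res <- constrained_variance(d, data.frame(g = labels), n_perm = 999,
                              seed = 7)
  # Monte-Carlo error of a 999-permutation estimate
  mc_se <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(res$anova$p - p_exact), 3 * mc_se + 2 / 999)
})

test_that("permutation p is uniform under a shuffled-label null", {
  set.seed(46)
  m <- matrix(rpois(12 * 8, 6) + 1, nrow = 12,
              dimnames = list(paste0("S", 1:12), paste0("f", 1:8)))
  tab <- as.data.frame.table(m, stringsAsFactors = FALSE)
  names(tab) <- c("sample_id", "feature_id", "count")
  d <- distance_matrix(tibble::as_tibble(tab), "bray_curtis")
  ps <- vapply(1:200, function(b) {
    fac <- data.frame(g = sample(rep(c("a", "b"), 6)))
    constrained_variance(d, fac, n_perm = 99, seed = b)$anova$p
  }, numeric(1))
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("chi-square matches the closed form and scales linearly with N", {
  res <- chi_square_2x2(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  expect_equal(res$statistic, 6.66667, tolerance = 1e-5)
  expect_equal(res$df, 1L)

  expect_equal(chi_square_2x2(matrix(c(10, 10, 10, 10), 2))$statistic, 0)

  base <- matrix(c(8, 5, 3, 9), 2)
  expect_equal(chi_square_2x2(base * 2)$statistic,
               2 * chi_square_2x2(base)$statistic, tolerance = 1e-12)

  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "margin")

  # closed form agrees with the standard implementation on random tables
  set.seed(47)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    ours <- chi_square_2x2(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-10)
    ours_c <- chi_square_2x2(tab, correct = TRUE)
    ref_c <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(ours_c$statistic, unname(ref_c$statistic),
                 tolerance = 1e-10)
  }

  td <- tidy(chi_square_2x2(matrix(c(10, 20, 20, 10), 2, byrow = TRUE)))
  expect_equal(td$statistic, 6.66667, tolerance = 1e-5)
})

test_that("detection concordance cross-tabulates with specimen lists", {
  det <- tibble::tibble(sample_id = c("S1", "S3"), detected = TRUE)
  lab <- tibble::tibble(sample_id = paste0("S", 1:5),
                        label = c("positive", "positive", "negative",
                                  "negative", "not_tested"))
  out <- detection_concordance(det, lab)
  expect_equal(out$counts["positive", "detected"], 1)
  expect_equal(out$counts["positive", "not_detected"], 1)
  expect_equal(out$counts["negative", "detected"], 1)
  expect_equal(out$counts["negative", "not_detected"], 1)
  expect_equal(out$cells$positive_detected, "S1")
  expect_equal(out$excluded, "S5")

  # all labels positive, all detected -> [[n,0],[0,0]]
  det2 <- tibble::tibble(sample_id = c("S1", "S2"), detected = TRUE)
  lab2 <- tibble::tibble(sample_id = c("S1", "S2"), label = "positive")
  out2 <- detection_concordance(det2, lab2)
  expect_equal(as.numeric(out2$counts), c(2, 0, 0, 0))
})

test_that("region comparison flags primer-dropout taxa as V4-only", {
  cfg <- sim_config(n_specimens = 25, reads_mean = 20000, chimera_rate = 0,
                    seed = 31)
  tr <- simulate_truth(cfg)
  spec <- tr$specimens$sample_id
  tab <- truth_table(tr)
  fl <- symbiomark:::build_fulllength_16s(cfg)
  v4 <- tab[tab$marker == "16S-V4" & tab$sample_id %in% spec, ]
  v12 <- tab[tab$marker == "16S-V1V2" & tab$sample_id %in% spec, ]
  cr <- compare_regions(v4, v12, fl)
  expect_equal(cr$discordant$genus, "Nasuia")
  expect_equal(cr$discordant$status, "v4_only")

  # no-dropout configuration: focal genus sets identical
  cfg2 <- cfg
  i <- which(cfg2$symbionts$name == "Nasuia")
  cfg2$symbionts$dropout_markers[[i]] <- character()
  tr2 <- simulate_truth(cfg2)
  tab2 <- truth_table(tr2)
  spec2 <- tr2$specimens$sample_id
  cr2 <- compare_regions(
    tab2[tab2$marker == "16S-V4" & tab2$sample_id %in% spec2, ],
    tab2[tab2$marker == "16S-V1V2" & tab2$sample_id %in% spec2, ],
    symbiomark:::build_fulllength_16s(cfg2))
  expect_equal(nrow(cr2$discordant), 0)
  gt <- cr2$genus_table
  expect_setequal(gt$genus[gt$focal_v4], gt$genus[gt$focal_v4 & gt$n_v1v2 > 0])
})

test_that("low-titre pathogen detection underperforms its nested-PCR label", {
  cfg <- sim_config(n_specimens = 120, chimera_rate = 0, seed = 53)
  tr <- simulate_truth(cfg)
  tab <- truth_table(tr, "16S-V4")
  spec <- tr$manifest[tr$manifest$role == "specimen", ]
  phyto <- tab[tab$taxon == "Phytoplasma", ]
  det <- tibble::tibble(
    sample_id = spec$sample_id,
    detected = spec$sample_id %in% phyto$sample_id[phyto$count > 0])
  lab <- tibble::tibble(sample_id = spec$sample_id,
                        label = spec$nested_pcr_status)
  out <- detection_concordance(det, lab)
  cc <- out$counts
  # amplicon sequencing misses part of the PCR-positive specimens
  # (carriage < 1 given a positive screen, plus depth dropout) ...
  expect_lt(cc["positive", "detected"] / sum(cc["positive", ]), 1)
  # ... but detects the pathogen more often in them than in negatives
  expect_gt(cc["positive", "detected"] / sum(cc["positive", ]),
            cc["negative", "detected"] / sum(cc["negative", ]))
  # and the table feeds the chi-square test directly
  res <- chi_square_2x2(cc)
  expect_s3_class(res, "symbio_chisq")
  expect_gte(res$statistic, 0)
})
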