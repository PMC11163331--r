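# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A small noise-free run (8 specimens + 3 controls) plus its pipeline result.
tiny_cfg <- function() {
  sim_config(n_specimens = 8,
             n_controls = c(extraction = 1, pcr = 1, index = 1),
             error_rate = 0, chimera_rate = 0, seed = 421)
}

tiny_run <- function() {
  with_cache("tiny_run", simulate_run(tiny_cfg()))
}

tiny_db <- function() {
  with_cache("tiny_db", build_reference_db(tiny_cfg()))
}

tiny_pipeline <- function() {
  with_cache("tiny_pipeline", {
    run <- tiny_run()
    db <- tiny_db()
    run_amplicon_pipeline(run$reads, run$manifest, db$coi, db$s16)
  })
}

# truth-derived long table with feature sequences for a sim_truth object
truth_table <- function(truth, markers = NULL) {
  tab <- dplyr::left_join(
    truth$composition,
    dplyr::select(truth$sources, "marker", "source_id", "sequence",
                  "taxon", "genus", "category"),
    by = c("marker", "source_id"))
  tab <- dplyr::rename(tab, feature_id = "source_id")
  if (!is.null(markers)) tab <- dplyr::filter(tab, .data$marker %in% markers)
  tab
}

# brute-force IUPAC prefix mismatch counter (independent of the package's
# vectorised matcher)
brute_primer_mismatches <- function(seq, primer) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  p <- strsplit(primer, "")[[1]]
  s <- strsplit(substr(seq, 1, length(p)), "")[[1]]
  if (length(s) < length(p)) return(Inf)
  sum(vapply(seq_along(p), function(i) !(s[i] %in% sets[[p[i]]]),
             logical(1)))
}

# independent re-implementation of the greedy 97% clustering rule,
# structured differently (full identity matrix first, then assignment)
brute_cluster <- function(seqs, abund, identity_min = 0.97) {
  n <- length(seqs)
  ord <- order(-abund, seq_len(n))
  idm <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      idm[i, j] <- idm[j, i] <- symbiomark:::global_identity(seqs[i], seqs[j])
    }
  }
  otu <- integer(n)
  reps <- integer(0)
  for (i in ord) {
    hit <- 0L
    for (r in reps) if (idm[i, r] >= identity_min) { hit <- r; break }
    if (hit > 0L) otu[i] <- hit else { otu[i] <- i; reps <- c(reps, i) }
  }
  otu
}

random_dna_str <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_dna_str <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}
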