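---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes and why:
the models behind each stage, the tunable parameters with their defaults
and units, what the synthetic-data generator does and does not emulate,
the numerical conventions that make results reproducible, and known
limitations.

## The analysis model

A multi-target amplicon run multiplexes three markers per library — the
host COI barcode (BF3/BR2, ~418 bp), bacterial 16S rRNA V1–V2 (27F/338R,
~310 bp) and V4 (515F/806R, ~253 bp) — for several hundred insect
specimens plus water controls drawn at three library-preparation steps
(DNA extraction, first PCR, indexing PCR). The pipeline's job is to turn
the demultiplexed paired reads into (i) verified host identities with
mitochondrial fine structure (heteroplasmy, numts) and off-target
detections, and (ii) decontaminated symbiont community tables with
population-level statistics.

### Primer binning (`bin_reads`)

A pair is assigned to a marker iff the forward read starts with the
marker's forward primer and the reverse read with its reverse primer,
each within `max_mismatch` IUPAC-aware substitutions (default **2** per
primer, no indels: tolerant of sequencing error yet far from the
cross-marker confusion distance for these primer sets — the tolerance is
a convention, stated here because the choice is not forced by anything
else in the design). Mixed-orientation pairs are recognized and the
mates swapped. Primers are trimmed on assignment, and so is 3'
read-through: when the amplicon construct is shorter than the 300-bp
read (the V4 case), the reverse complement of the opposite primer
appears inside the read and is cut at its first IUPAC match past the
marker's minimum amplicon length. Pairs matching no marker, multiple
markers, or a conflicting primer combination stay unassigned with a
reason code, so binning partitions the input exactly.

### Merging and quality filtering (`merge_pair`, `quality_filter`)

Merging maximizes an ungapped overlap score (matches − 4·mismatches)
over candidate offsets found by exact 14-mer seeds (full scan as
fallback). A merge is accepted iff the overlap is ≥ `min_overlap`
(default **20 bp**) with mismatch fraction ≤ **0.15**; disagreeing
bases resolve to the higher-quality base and merged qualities take the
positionwise maximum. Filtering keeps contigs whose expected errors
(EE = Σ 10^(−Q/10)) are at most `max_ee = 1.0` — the field-standard
value; the upstream protocol states quality filtering without a
criterion, so the expected-error rule is adopted — and whose length
falls in the marker's accepted range.

### Dereplication (`dereplicate`)

Exact-sequence grouping is **global** (across samples) with per-sample
counts retained, because downstream thresholds are per-library while
denoising benefits from pooled information; sequences with total
abundance 1 are removed. Whether singletons should be removed per
library or globally is genuinely open; global removal is the stricter
and simpler reading and is what the tests encode.

### Denoising (`denoise`)

UNOISE-style greedy denoising with `alpha = 2` and `d_max = 10`: in
decreasing abundance order, a unique sequence is absorbed into an
existing centroid at substitution distance `d` iff its abundance ratio
to that centroid is at most `skew(d) = 1/2^(alpha·d + 1)` (so 1/8 at
d = 1). The default mode denoises **each library separately**, takes
the union of all per-library centroids, and maps every unique sequence
to its nearest centroid within `d_max` (reads are conserved exactly).
The rationale is biological: a genuine minor mitochondrial haplotype at,
say, 10% of an individual's reads sits below the d = 1 skew threshold
of the pooled dominant haplotype and would be absorbed by a single
pooled pass, yet within its carrier libraries it is far above any
error-cloud abundance. Per-library denoising with a global union keeps
such variants while still removing per-library error structure; a
`mode = "pooled"` single pass is available and the two agree on
single-library input. `min_parent_abundance` (default **2**, i.e. the
post-singleton floor) controls which sequences may found centroids.

### Chimera screening (`screen_chimeras`)

A de novo two-parent model: for each query zOTU, candidate parents are
same-length zOTUs with ≥ `min_parent_ratio = 2` times its abundance;
over all parent pairs and crossover positions the best two-segment
reconstruction is compared with the best single parent. The query is
flagged iff the model is strictly better by `score_min = 0.01`
(mismatch reduction per query base) **and** reconstructs the query to
within `max_model_div = 0.05`. The margin floor is set by geometry: a
bimera of parents at divergence `δ` with crossover at position `k` has
margin `δ·min(k, L−k)/L`, so detecting parents at ≥3% divergence with
interior crossovers requires a floor at or below ~0.01; the model-fit
cap is what keeps unrelated sequences from being flagged by chance
margins. Near-edge crossovers produce chimeras nearly identical to one
parent and are undetectable in principle (and inconsequential).
Screening is applied to the 16S markers only; COI is skipped.

### Clustering and taxonomy (`cluster_97`, `assign_taxonomy`)

Greedy centroid clustering in decreasing abundance order joins a zOTU to
the first OTU whose representative is ≥ 97% globally identical.
Identity is pinned as matches / alignment columns of a global
(end-gap-penalized) pairwise alignment under match = 1, mismatch = −2,
gap open 6, gap extend 1; for equal-length sequences that are clearly
near (≤5% mismatches) or clearly far (≥30%) the ungapped alignment is
provably optimal or decision-irrelevant and is used directly, and
cross-length pairs whose length ratio already bounds identity below
0.85 short-circuit to that bound. Taxonomy is best-hit (ties toward the
lexicographically smallest reference id) with rank cutoffs species 0.97,
genus 0.95, family 0.90, order 0.85, else domain; the species rank
exists because host species verification needs species-level calls.

### Decontamination and filters (`decontaminate`, `threshold_zotus`, …)

A 16S feature is a contaminant iff its mean relative abundance across
control libraries is ≥ `contam_ratio` (default **1.0**) times its mean
across specimens; features absent from all controls are never flagged.
The ratio form is the minimal reading of "compare relative abundances
between controls and specimens"; the parameter is exposed, and controls
are pooled across the three roles by default (per-role stratification is
available). The comparison runs at zOTU level and propagates to OTUs.
Non-target lineages (mitochondria, chloroplast, Eukaryota, Archaea) are
removed from 16S tables. The focus rule keeps zOTUs with ≥ **100**
total reads **and** ≥ **5%** relative abundance in ≥ 1 library (both
inclusive, "at least"); everything else folds into an `Others` feature
that conserves per-sample totals to the read. Specimens need ≥ 100 COI
barcode reads and ≥ 1000 16S-V4 reads (exclusive below the floor:
"less than … were excluded"). The display view keeps OTUs reaching 1%
in ≥ 1 library and reports its mean per-library coverage.

### Host typing

The barcode is the most abundant host-genus COI zOTU per sample.
Molecular identity overrides morphology for downstream grouping, with
mismatches reported. Host-genus OTUs other than the barcode's are
numt-like iff they always co-occur with the barcode and never exceed
10% of a library; violators (e.g. a secondary OTU dominating one
library) are logged as anomalies, not numts — the data cannot say
whether such a case is biology or artifact, so the package only
records it. Heteroplasmy variants are non-barcode zOTUs inside the
barcode OTU with ≥ 100 reads and ≥ 5% of the **barcode OTU's** reads
in that library; the whole-library denominator is available as
`denominator = "library"` because the thresholds' written form admits
both readings. Variant distances are substitutions under end-free
alignment; indel-bearing variants are annotated as possible artifacts.
Off-target COI OTUs are parasitoid candidates when the lineage is
insect but outside the host family (no taxa hard-coded), and
endosymbiont detections when Rickettsiales; a 100-read tier separates
"detected" from "trace".

### Community statistics

Prevalence counts a specimen as infected when a taxon has > 0
post-filter reads (`detection_floor = 0`, configurable) — trace
detections count, matching how facultative symbionts ranging down to
0.004% relative abundance are tallied. Operon-variant grouping links
same-genus features by two criteria: co-presence ≥ 90%, where a
discordant library (one feature absent) counts as evidence only when
the present partner has ≥ 20 reads — an absence next to a handful of
partner reads is expected sampling dropout under fixed copy ratios, not
independence — and a per-library abundance-ratio coefficient of
variation ≤ 0.35 over ≥ 3 shared libraries where both features clear
the same 20-read floor (a ratio against a 2-read count measures
counting noise, not biology). Connected components of size ≥ 2 are
single-strain candidates. (The CV is taken on the linear ratio with the
larger-total feature as numerator: a log-ratio CV is undefined exactly
at the biologically central 50/50 case.) The thresholds separate fixed
genomic copy ratios (counting noise only, CV ≪ 0.35 at quantifiable
depths) from independently fluctuating taxa (CV ~ 0.6 under the
generator's overdispersion). Region concordance
maps V4 representatives onto full-length 16S references by best
global-in-local alignment, maps V1–V2 features onto the same reference
set, and compares genus-level detection; region-exclusive status is
only asserted for genera reaching 1% in some library, so sampling
dropout of trace taxa is not misread as primer failure.

dbRDA is realized exactly as: Gower-center the squared distance matrix
(G = −½·J·D²·J), project onto the centered one-hot design of the
categorical factors, and report trace(HGH) divided by the sum of
**positive** eigenvalues of G (negative eigenvalues of non-Euclidean
Jaccard/Bray–Curtis matrices are excluded from the denominator; the
constrained inertia itself matches vegan's `dbrda` to machine
precision, as the tests verify). Factors are tested sequentially in the
given order with free permutation of samples,
`p = (1 + #\{F_perm ≥ F_obs\}) / (1 + n_perm)`, seed recorded. The 2×2
chi-square uses the closed form `N(ad−bc)²/(r₁r₂c₁c₂)` with df = 1 and
the continuity correction off by default (switchable); which convention
the comparable analyses used is not stated anywhere authoritative, so
it is configuration, not a claim.

## The synthetic-run generator

`sim_config()` freezes a cohort model whose defaults are the study
conditions the package is built around: seven *Macrosteles* species with
a strongly dominant *M. laevis* (85%), 10/306 morphology mislabels,
obligate endosymbionts *Sulcia* (mean 45.3% of the community) and
*Nasuia* (26.6%) in every specimen, *Arsenophonus* at prevalence 0.822
with four divergent rRNA operon copies at fixed 0.4/0.3/0.2/0.1
ratios, patchier facultative symbionts (*Wolbachia*, *Rickettsia*,
*Cardinium*, *Lariskella*, an unnamed Gammaproteobacterium),
*Phytoplasma* carriage conditioned on nested-PCR status (1.0 for
PCR-positive specimens — the nested screen is the sensitive gold
standard — and 0.41 for PCR-negative ones) with a strongly skewed
within-host titre (mean relative abundance 2% with most carriers far
below it), so that amplicon detection of carriers drops out at finite
depth and the detection-given-status fractions emerge near the observed
~0.41 / ~0.19 rather than being wired in; two operon variants at 50/50, host organelle 16S (mitochondrion, chloroplast),
three reagent contaminants shared with water controls, pipunculid
parasitoid COI (~4% of specimens, mostly low-fraction), and
*Wolbachia*/*Rickettsia* COI co-detection at 0.8 given 16S carriage.
Water controls exist for all three preparation roles (2 each by
default, scaling the 24-controls-per-371-specimens ratio) and contain
only contaminant taxa.

Counts are drawn hierarchically: per-sample, per-marker library sizes
are negative binomial (specimen mean 2000, size 4; control mean 300,
size 2 — overdispersed enough that the depth-floor exclusions have
work to do), within-sample composition is Dirichlet-multinomial with
per-taxon concentrations (alpha = mean × 10 for tightly regulated
obligates/organelles, mean × 5 for facultative/contaminant taxa —
producing the wide ranges seen in real data, e.g. a 45%-mean obligate
spanning roughly 4–84%), and one taxon-level draw is shared between the
two 16S regions because both amplify the same template pool.
*Nasuia* carries a V1–V2 primer-mismatch dropout flag, reproducing a
taxon visible in only one region. COI composition gives the dominant
haplotype the residual after minor haplotypes (default
within-individual fraction 0.20 for carriers at prevalence 0.159 —
observed variant fractions span roughly 5–50%, and mitochondrial
fractions are tightly regulated, concentration 300), numts (≤ 10% per
library by construction, ~4% divergent so they cluster apart), and any
parasitoid/bacterial COI. Reads are rendered as the first/last 300
bases of the primer-flanked construct (R2 reverse-complemented; all
amplicons < 560 bp, guaranteeing ≥ 20 bp overlaps), with primer IUPAC
codes instantiated per molecule, per-base substitution errors at
`error_rate` (default 0.001) and flat per-read Phred qualities drawn
around −10·log₁₀(error_rate) (±1.5), so expected-error filtering has a
real signal. PCR chimeras replace a Binomial(depth, `chimera_rate`)
share of a library's reads (default 1%), formed from two abundant
parents at a crossover drawn from the central third of the amplicon —
the detectable regime; near-edge chimeras are nearly identical to a
parent — in events of Poisson-sized read multiplicity so they can
survive singleton removal, with every event recorded in the truth.

What the generator does **not** emulate: indel and homopolymer errors,
position-dependent quality decay, index cross-talk (off by default,
available as `crosstalk_rate`), intragenomic 16S variation beyond the
configured operon sets, chimeras of more than two parents, and real
reference-database breadth (references are miniature and synthetic —
decoys exist for every non-target category, but taxonomy against them
is easier than against SILVA/MIDORI at full scale). Tests passing on
this generator therefore demonstrate the pipeline's internal
correctness — conservation laws, threshold semantics, parameter
recovery under the stated noise model — not field performance on real
MiSeq data.

## Numerical conventions and degenerate inputs

- Ties: dereplication orders by descending abundance then sequence;
  zOTU/OTU ids re-rank by total abundance after each stage; barcode
  ties break toward the lower zOTU rank; taxonomy ties toward the
  smallest reference id. All stated so that reruns are identical.
- Read conservation is exact at every stage and tested: binning
  partitions input; "Others" aggregation and denoising conserve
  counts; per-sample truth counts sum to emitted reads.
- Degenerate inputs are values, not crashes: unmergeable pairs carry a
  reason; samples with zero reads yield empty valid FASTQ; all-zero
  samples are rejected by name in distance computations; an
  intercept-only design returns variance 0; missing controls raise an
  instruction to skip decontamination explicitly.
- Problem sizes in the tests are chosen to keep the full suite in the
  tens of minutes on one core: the round-trip run uses 20 specimens +
  3 controls at mean depth 2000, heteroplasmy recovery 200 specimens
  (COI-focused depths), prevalence recovery 200 truth-level cohorts of
  40 at depth 20000 (deep coverage isolates estimator bias from
  detection dropout, which the Phytoplasma concordance machinery
  exercises separately), and the clustering oracle 100 random
  instances of ≤ 50 sequences.

## Known limitations

- The denoiser's per-sample-union mode can retain a true variant whose
  evidence is strong in only one library; conversely a variant that
  never exceeds the skew threshold in any single library is absorbed
  even if biologically real — an inherent limit of abundance-only
  denoising.
- The 97% clustering is greedy and order-dependent by specification;
  the brute-force oracle pins the exact rule rather than a globally
  optimal clustering.
- The decontamination ratio rule treats all controls alike by default;
  batch- or concentration-aware models are out of scope.
- Taxonomy is nearest-reference with fixed rank cutoffs; no bootstrap
  confidence is attached.
- dbRDA drops negative-eigenvalue inertia from the denominator, so
  explained fractions for non-Euclidean metrics are slightly larger
  than conventions that keep the full trace; the choice is pinned,
  printed, and cross-checked against the constrained inertia of the
  reference implementation.
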