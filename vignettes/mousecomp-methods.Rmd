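---
title: "Methods: quantifying competitive ability between house-mouse populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying competitive ability between house-mouse populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mousecomp)
```

## The scientific setting

`mousecomp` analyses competitive ability between two wild-derived western
house-mouse (*Mus musculus domesticus*) populations — here labelled MC
(Massif Central, France) and CB (Cologne/Bonn, Germany) — from three
complementary data streams:

1. **Dyadic encounter ethograms.** Pairs of one male per population meet in
   a connected cage system for two 10-minute sessions on consecutive days.
   An observer codes timestamped behaviours (attack, chase, flight, ...) and
   notes each animal's compartment every 15 s.
2. **RFID enclosure logs.** Two round arenas, one population raised in each,
   are joined by three tubes carrying an antenna at each end. Every antenna
   pass of a transpondered mouse leaves a timestamped read.
3. **Microsatellite genotypes.** All animals are typed at 13 unlinked
   microsatellite loci, so offspring born after the arenas are connected can
   be classed as pure or mixed (F1) background and attributed to a sire
   population.

The raw observation streams of the motivating experiment are not bundled;
the package instead ships the published per-dyad and per-room summary
tables as worked-example inputs (`example_dyads()`,
`example_sire_counts()`) and provides agent-based generators
(`simulate_dyads()`, `simulate_enclosure()`, `simulate_pedigree()`) that
produce all three streams with ground truth attached, so every inference
stage is testable end to end.

## The statistics kernel

All downstream stages use one self-contained kernel of exact and
permutation tests — nothing is delegated to an opaque fitted model. The
conventions matter for reproducing printed values:

* **Exact binomial** (`binom_exact()`). The two-sided p-value uses the
  *minimum-likelihood* convention: it sums the probabilities of all
  outcomes no more likely than the observed one. A 12-of-13 win split
  against an even null gives `28/8192 = 0.0034`.
* **Proportion test with continuity correction** (`prop_test_cc()`). The
  chi-square statistic is `(|k - n p0| - 1/2)^2 / (n p0 (1 - p0))`, with
  the correction truncated at the observed deviation; one-sided p-values
  take the corresponding normal tail. This is the convention under which
  13-of-15 dyads forming a hierarchy gives p = 0.005 and 10-of-13 CB wins
  gives p = 0.048, while the per-dyad tests above are exact binomials —
  both conventions are exposed because each reproduces a different set of
  published numbers.
* **Rank tests** (`mann_whitney()`, `wilcoxon_signed_rank()`,
  `friedman_rank()`). The rank-sum test reports `min(U, nm - U)` (the
  statistic conventionally printed as W; the published between-population
  weight comparison is min-U = 64). Null distributions are exact — built
  by dynamic programming over rank assignments or sign flips — whenever
  samples are small (both ≤ 20 for the rank-sum, ≤ 25 pairs for the
  signed-rank) and untied; otherwise tie-corrected normal approximations
  with continuity correction are used. Zero paired differences are
  dropped and counted. Because V depends on the direction of differencing
  and the source convention is not recoverable, paired analyses report
  both directions (V = 81 and V = 39 for the dyad weights; the p-value is
  identical).
* **Permutation tests** (`anosim_test()`, `mantel_test()`,
  `permanova_test()`). All permutation p-values use the add-one estimator
  `(1 + #exceedances) / (n_perm + 1)` and take an explicit integer seed
  (default 1234), which is recorded in the result, so every p-value is
  bit-reproducible. Defaults are 999 permutations for ANOSIM and
  PERMANOVA and 9999 for the Mantel test.
* **PERMANOVA** follows the sequential (Type-I) `adonis` construction: the
  response matrix is log(x+1)-transformed and column-standardised,
  Euclidean distances are Gower-centred, and each term's sum of squares is
  the trace of its incremental hat-matrix projection; p-values come from
  permuting raw rows. The transform default mirrors how the latency and
  space-use metrics are usually displayed (log scale) and analysed.
  Rank-deficient terms are dropped with a warning.
* **PCA of behaviour counts** (`pca_counts()`) drops behaviours that make
  up at most 5% of all events (a global filter applied before any
  per-individual normalisation), converts rows to proportions, and
  eigendecomposes the covariance of the centred columns. Component signs
  are fixed by making each component's largest-magnitude loading positive,
  so ordinations are platform-reproducible.

## Encounter analysis

`segment_conflicts()` operationalises live conflict scoring as gap-based
bout segmentation: a conflict is a maximal run of agonistic (offensive or
defensive) events with inter-event gaps of at most `gap_s` seconds
(default 15 s — one location-scan interval). Neutral behaviours never open
or extend a bout. A bout is *decided* when exactly one dyad member shows
defensive behaviour; that member loses. Bouts where both members act
defensively are conservatively classed undecided. The behaviour-to-class
map is configuration, not code (`behavior_classes()`, JSON-loadable);
vocalization is kept neutral even though subordinates vocalize more,
because it is not itself agonistic.

`score_dyads()` pools decided conflicts across both session days and
declares a dominant only when the exact binomial p-value falls below
α = 0.05 *and* the candidate won more than half of the decided conflicts.
The α threshold is not exercised by the bundled example table — every
dyad with conflicts has a significant winner there — but it governs
simulated data. Note a floor effect: a dyad with six decided conflicts
can at best reach p = 0.031 (6–0 split), so very small dyads can never be
significant at the 0.001 level no matter how one-sided they are.

`cage_use()` summarises the 15-s location scans into per-individual visit
proportions over home, neutral and foreign cage, tubes, and the water
bath/escape cage (combined), then runs the Friedman test over the three
main cages (overall and per population), pairwise signed-rank tests with
Bonferroni m = 3, and a between-population comparison of foreign-cage use
(paired within dyads when the design permits).

## Enclosure analysis

`infer_occupancy()` converts a tag's read sequence into arena residency by
a deterministic single pass: the stretch from connection opening to the
first read belongs to the home arena (all mice were born and raised
there); the interval between two consecutive same-side reads — any tube —
belongs to that side's arena; the interval between opposite-side reads is
left *unassigned* and counts as exactly one passage. The one-passage rule
is the minimum-evidence count: an opposite-side pair proves an odd number
of crossings occurred, and one is the conservative choice under missed
detections. Intervals tile the experiment window exactly (time
conservation is asserted in the tests), and with perfect detection the
unassigned time is bounded by the true tube dwell.

Four metrics per mouse follow: touch latency (opening to first read — the
latency clock starts at `t_open`, which is configurable because a
transponder-activation convention would shift it), cross latency (first
read to first foreign-side read; missing, never infinite, if the mouse
never crossed, with pairwise exclusion downstream), passage and session
counts, and assigned home/foreign time. "Session" is not given an
operational definition in the source material; here it is a maximal run
of reads at one antenna with internal gaps ≤ 10 s (configurable), and is
flagged as an interpretation. Mice never read at any antenna are excluded
and reported, mirroring the 16 excluded animals of the motivating study.

`cohort_compare()` then runs per-metric rank-sum comparisons, the two
Pearson correlations (touch vs cross latency; foreign time vs passages),
and a PERMANOVA of the four behavioural metrics on population, sex and
weight in that fixed order.

## Population assignment and parentage

The unsupervised Bayesian clustering used in the original workflow is
replaced by a *supervised two-panel admixture MLE*: founders are labelled
by design in this experiment, so supervision is faithful and keeps the
stage deterministic. `estimate_freqs()` builds per-population allele
frequencies with an additive pseudocount (default 0.5) over the union
allele set. `assign_origin()` maximises
`sum log(q f_A + (1 - q) f_B)` over allele copies (alleles treated
independently, the standard admixture likelihood) by a 0.001-step grid
search with local refinement; `q ≥ 0.9` is pure toward panel A, `q ≤ 0.1`
pure toward panel B, otherwise mixed. The 0.9/0.1 thresholds are not
stated in the source and are configuration with these defaults.
Individuals typed at fewer than 6 loci are unassigned; missing genotypes
are never imputed. Identical panels are detected and flagged
uninformative with q tie-broken to 0.5.

`parent_lod()` is a single-parent likelihood ratio in the CERVUS spirit:
at each locus one offspring allele is transmitted by the candidate —
correctly with probability `1 - ε`, otherwise drawn from the background —
and the other comes from background Hardy–Weinberg frequencies
(room-pooled, pseudocount-smoothed). Mismatching loci therefore penalise
smoothly rather than excluding hard, collapsing to `-Inf` exclusion only
at ε = 0. The default ε = 0.01 is configuration. Trio likelihoods are
deliberately not used; the single-parent form is labelled as such.
`assign_parent_population()` ranks all sex-appropriate adults in the room
(no conception-window filtering, since candidate pools are given without
one), breaks LOD ties by candidate id for determinism, and accepts a
parental population only when the top two candidates agree — the
published consensus rule.

### An information limit worth knowing

At 13 microsatellite loci with divergence around F\_ST ≈ 0.15, the
admixture estimate for a true F1 is unbiased but has a sampling spread of
roughly ±0.15 (one sd) *even when the true panels are known* — the
likelihood simply carries that much information. Mixed/pure
classification at the 0.9/0.1 thresholds is robust to this (≥ 90% of
simulated F1s class as mixed), but per-individual q̂ values should not be
over-read. The validation suite therefore checks the F1 cohort-mean q̂
against 0.5 ± 0.15 and the classification rate, not a per-individual q̂
band that no estimator could satisfy at this locus count.

## The generators

The generators' defaults encode the study conditions: 15 dyads, two
600-second sessions, ~21 conflicts per session of which ~42% are decided
(the observed 638 conflicts / 42.4% decided), a near-deterministic
dominant (win probability 0.95, matching the observed 265-of-271
winner-side tally), and a 10:13 bias of dominance toward CB; 13 loci for
the pedigree generator with divergence 0.15 and 8 alleles per locus (a
typical microsatellite panel width, chosen once); two arenas × three
tubes with per-population movement contrasts that match the *ordering* of
the published metrics (CB explores sooner, crosses more, stays longer)
without claiming magnitudes, and a default antenna detection probability
of 0.95 to emulate the documented technical misses.

Enclosure movement is a memoryless continuous-time Markov chain — the
simplest process yielding the right metric structure; it is a modelling
choice, not a claim about mice. The generators do *not* emulate social
interaction in the enclosures, home-range structure inside an arena,
microsatellite mutation, linkage, or null alleles; passing tests
therefore validate the inference machinery, not these aspects of real
data. A single root seed fans out to one RNG stream per simulated unit
(`seed + component·7919 + unit·1000003 mod 2^31-1`), so enlarging a
simulation never perturbs the draws of earlier units — a property the
tests assert byte-exactly.

## Numerical choices and degenerate inputs

* Grid-then-refine (step 0.001, golden-section refinement) for q̂ keeps the
  admixture MLE deterministic and label-symmetric
  (`q(A,B) + q(B,A) = 1` to within the grid tolerance).
* Alleles absent from a panel receive a floor frequency of 1e-4 rather
  than zero, so a single novel allele cannot veto an assignment.
* All-zero count rows, zero-variance correlations, empty event streams,
  unread tags, all-tied samples and all-zero paired differences are each
  handled explicitly (error, warning + p = 1, or exclusion with a notice —
  see the respective function documentation).
* Validation problem sizes: null calibration uses 200 replicates of
  n = 12–20 with 199 permutations; the occupancy oracle uses 20 mice over
  72 simulated hours at detection 1; parentage recovery uses 50 candidate
  sires and 40 F1 offspring. These sizes give the binomial test on each
  calibration enough resolution while keeping the full validation suite
  around a minute of CPU.

## Known limitations

* The sire-count equal-proportions test is the one-sample corrected
  proportion test on determined offspring; a 2×2 chi-square variant gives
  slightly different per-room p-values for small rooms.
* Passage counts are minimum-evidence counts and strictly undercount when
  detection misses hide an even number of extra crossings.
* The ethogram segmentation is one operationalisation of live conflict
  scoring; bouts separated by less than the gap merge.
* The admixture classes depend on threshold configuration; with highly
  admixed panels (divergence near 0) the stage degrades gracefully to
  "uninformative" rather than producing confident nonsense.
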