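---
title: "Cost-efficiency analysis of functional connectivity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-efficiency analysis of functional connectivity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcost)
```

## The problem this package addresses

After a traumatic brain injury (TBI), resting-state fMRI often shows
*hyperconnectivity*: more, and stronger, temporal correlations between brain
regions than in healthy controls. Whether that response is adaptive is partly
a question of metabolic economy — long, strong connections are expensive to
maintain, so a network that achieves its efficiency through many medium- and
long-range connections is paying a premium. `netcost` implements a
graph-theoretic pipeline for interrogating that trade-off in longitudinal
ROI-level data:

1. build subject-specific weighted connectivity networks with FDR edge
   retention,
2. summarise them with distance-weighted *cost* metrics alongside standard
   graph measures,
3. trace the cost-efficiency trade-off by random edge deletion on a
   group-averaged network,
4. screen brain subsystems for hyper-/hypoconnectivity with an effect-size
   gate, and
5. decompose subsystem cost changes into connection length x strength
   histograms with iso-cost contours.

Because suitable public longitudinal TBI datasets are scarce, the package
ships a synthetic cohort generator with recoverable ground truth; every claim
the test suite makes is a claim about what the pipeline recovers from data
whose true structure is known.

## Network construction

A subject's input is an `n_volumes x n_roi` matrix of ROI mean time series
(optionally extracted from a 4-D array with `extract_roi_timeseries()`, which
averages in-mask voxels within a sphere around each ROI centre). For every
ROI pair we compute the Pearson correlation `r` and its two-sided p-value via
the t-transform with `n_volumes - 2` degrees of freedom. Benjamini-Hochberg
is applied at level `alpha = 0.05` over exactly the `n(n-1)/2` pairs of that
subject — the network is subject-specific, so the multiplicity family is the
subject's own edge set. Surviving edges are stored as `|r|`: the analysis
concerns the magnitude of synchrony (a metabolic proxy), so anticorrelations
count by absolute value, which is also why the test must be two-sided.

Two conventions worth making explicit:

* **Sphere size.** ROI spheres default to a 7.5 mm radius (a 15 mm diameter
  sphere). The radius is a parameter (`sphere_radius_mm`) because parcellation
  conventions differ on whether "15 mm sphere" names a radius or a diameter.
* **Voxel ownership.** A voxel inside two spheres contributes only to the
  nearest ROI centre (ties to the lower `roi_id`), so overlapping spheres
  never double-count signal.

## Connectivity profile

For a network \(G\) with weights \(w_{ij} = |r_{ij}|\) and ROI coordinates in
mm, `connectivity_profile()` reports:

* **Total links** — retained edge count.
* **Network strength** — \(\sum_{i<j} w_{ij}\).
* **Edge cost** — \(c_{ij} = d_{ij} \cdot w_{ij}\), the Euclidean distance
  between the ROI pair times the absolute weight; **network cost** is
  \(\sum_{i<j} c_{ij}\) and **ROI cost/strength** restrict the sums to edges
  incident on one ROI (so summing over ROIs counts each edge twice — the
  handshake identity the tests assert).
* **Clustering** — unweighted local clustering
  \(C_i = 2T_i / (k_i(k_i-1))\) with \(T_i\) the triangle count at node
  \(i\); the set-cardinality numerator over ordered neighbour pairs equals
  twice the triangle count, which is the reading we implement and test
  against a literal neighbour-pair enumeration. Nodes with \(k_i < 2\) get
  \(C_i = 0\). The weighted variant is the Onnela geometric-mean form on
  weights normalised by the maximum weight (the conventional weighted
  generalisation when none is otherwise specified).
* **Global efficiency** —
  \(E(G) = \frac{2}{n(n-1)} \sum_{i<j} 1/d(i,j)\) over shortest-path
  distances, with unreachable pairs contributing 0 (harmonic convention);
  a complete graph has \(E = 1\). The *average shortest path length* reported
  alongside instead **excludes** unreachable pairs (and is `NA` for an empty
  network): mixing the two conventions in one statistic would make sparse
  networks look artificially efficient.

## The cost-efficiency simulation

The simulation asks how much efficiency a group's network retains as it is
made sparser at random:

1. Average the subjects' weighted networks entrywise (`group_average_network`),
   counting an edge absent in a subject as weight 0 — an averaged edge exists
   if any subject has it. (Requiring presence in *all* subjects is the main
   alternative; it discards most of the edge set at realistic FDR densities
   and is available by pre-filtering, but is not the default.)
2. Map each averaged weight \(w\) to a distance \(1.01 - w\)
   (`inverse_network`): the strongest correlation becomes a short but
   non-zero distance of 0.01; disconnected pairs stay disconnected.
3. For each deletion percentage \(X = 1..99\) and each of 50 repetitions,
   delete a uniformly random \(\lfloor X/100 \cdot |E| \rfloor\)-subset of
   edges (restored between repetitions), and record the surviving network's
   total cost and its global efficiency over weighted shortest paths on the
   inverse distances. A full run is exactly \(99 \times 50 = 4950\) records.

The floor rule makes the deletion count well-defined (the behaviour on a
single-edge network at \(X = 50\) — delete nothing — is pinned by a test).
Efficiency uses the weighted inverse-distance paths because that is the only
role the inverse network plays; hop-count efficiency is available via
`efficiency = "unweighted"`.

`run_attack_simulation(nested = TRUE)` replaces independent draws by prefix
deletions of one random edge permutation per repetition. Along such a nested
sequence both cost and efficiency are non-increasing at every step — a sharp
invariant the test suite checks over 50 sequences, which independent draws
(the analysis mode) satisfy only in expectation.

Shortest paths inside the simulation use a compiled dense Floyd-Warshall
sweep rather than repeated Dijkstra: group-averaged networks are
near-complete, and the \(n^3\) sweep with contiguous memory access is what
keeps a full 4950-record run at 264 ROIs in the tens of seconds on one core.
`band_compare()` then bins two runs' records into half-open cost bands
(default width 50000, anchored at 0), and per band reports a pooled-variance
two-sample t-test on efficiency, Bonferroni-adjusted over the tested bands,
with Cohen's d.

## Subsystem screening

`screen_subsystems()` compares, per subsystem, the pooled distribution of
per-ROI strengths (or costs) — all ROIs of the subsystem x all subjects of
the group — between patients and controls: pooled-variance t-test,
Benjamini-Hochberg across the subsystem family, Cohen's d with pooled SD.

**The operative gate is the effect size.** A subsystem is labelled
`hyper`/`hypo` only when \(|d| >\) `d_gate` (default 0.70, i.e. sensitivity
to medium-or-larger effects); the FDR-adjusted p-value is reported alongside
rather than used as the primary filter. This mirrors screening practice in
small clinical samples, where p-gates at conventional levels either pass
almost everything (because pooling inflates the nominal n) or exclude
medium effects the study was designed to find. `require_fdr = TRUE` gives
the conservative conjunction.

Pooling ROIs x subjects treats within-subject ROIs as independent
observations, which they are not — ROI strengths within a subsystem are
strongly correlated within a subject, so the t-test's nominal df overstate
the information content and the procedure is anti-conservative. We keep it
because it is the established screening recipe this pipeline reproduces, and
gate on d rather than p precisely because d does not inherit the inflated
df. For a conservative alternative, aggregate to one value per subject per
subsystem (e.g. `rowMeans` over the subsystem's columns) before calling
`screen_subsystems()`; with 14 vs 12 subjects that analysis is honest but
has little power below d of about 1.

Follow-up contrasts at other time points (`subsystem_followup`,
`ancova_contrast`) adjust for scanner as a categorical covariate:
`lm(values ~ covariate + group)`, with the group effect's
\(\eta_p^2 = SS_{group} / (SS_{group} + SS_{error})\) and a reporting gate of
\(\eta_p^2 \ge 0.06\) (a small-to-medium effect). A single-level covariate
reduces exactly to one-way ANOVA; a design with group aliased by covariate
is rejected as confounded.

`behavior_correlation()` closes the loop with plain bivariate Pearson
correlations between per-subject subsystem cost and behavioural scores.

## Length x strength histograms

For edges incident on a subsystem (within-subsystem edges counted once),
`incident_edge_table()` pools (length, strength) pairs across subjects;
`histogram2d()` bins them — default 10 mm x 0.05 bins over 0-180 mm x 0-1,
half-open with the last bin closed, out-of-range rows clamped into edge bins
with a warning so counts are always conserved. Strength edges are computed
as `(0:20)/20` so that round values like 0.30 sit exactly on bin boundaries.
`difference_histogram()` subtracts two histograms on identical edges, and
`iso_cost_contour()` overlays the hyperbolae \(s = \text{cost}/\ell\): every
point on one contour has the same edge cost (24 can be 40 mm at 0.6 or 60 mm
at 0.4). Contour levels are the arithmetic product of the axes — there is no
other self-consistent choice given the cost definition. Raw counts, not
frequencies, are plotted: the quantity of interest is the number of
connections a group maintains at a given length and strength.

## The synthetic cohort generator

`generate_roi_set()` draws ROI coordinates in a brain-sized bounding box
(140 x 170 x 120 mm) as spatially coherent subsystem clusters (maximin-seeded
centres, Gaussian scatter with 12 mm SD, balanced sizes). Spatial coherence
matters: length-resolved analyses are only meaningful if a subsystem's ROIs
are nearer each other than the background, a property the tests assert.

`generate_cohort()` draws each (subject, time point) panel from a
multivariate normal whose correlation matrix is block-structured:
`base_correlation` (default 0.5) within subsystems, `background_correlation`
(default 0.05) between, plus `effect_map` increments on designated
(group, time, subsystem) blocks — the implanted, recoverable ground truth.
Targets are converted to covariances with unit variances; any indefiniteness
introduced by the increments is repaired by clipping eigenvalues at 1e-6 and
re-normalising to unit diagonal, a standard nearest-PD construction. A block
pushed to a correlation of 1 or more is an error naming the block. Scanner
labels are assigned round-robin and carry no signal unless `scanner_sd`
injects additive per-scanner noise — their default role is purely as the
ANCOVA covariate.

The defaults mirror a longitudinal TBI design: 14 patients at three time
points, 12 controls at two, 145 volumes per scan, three scanners, 264 ROIs
in 20 subsystems.

`generate_behavior()` produces per-panel scores as
\(r \cdot z(\text{cost}) + \sqrt{1-r^2}\,\varepsilon\) on the standardised
per-panel connection cost (all pairs, or one subsystem's incident pairs), so
the population cost-behaviour correlation equals the requested `target_r`.

`generate_cost_contrast_pair()` constructs the matched network pair used to
validate the histogram analysis: two networks sharing a base edge set, one
with extra connections incident on a chosen subsystem drawn at medium length
(40-100 mm) and medium strength (0.2-0.5). The difference histogram then
isolates exactly that implanted signature, deterministically at fixed seed.

**What the generator does not emulate:** hemodynamics, motion and other
structured artefacts, voxel-level spatial autocorrelation, ROI-level
heterogeneity of connectivity (all ROIs in a block are statistically
exchangeable), and any mechanistic model of post-injury reorganisation — the
block-MVN form is a stand-in that makes ground truth recoverable, not a
theory of injury. Consequently, passing tests demonstrate that the pipeline
recovers what it is designed to measure under a known correlation structure
at realistic sample sizes; they do not certify behaviour under real
acquisition artefacts. One concrete caveat: because synthetic ROIs within a
subsystem are exchangeable, pooled-screen effect sizes are, if anything,
better behaved here than in real data, and at toy sizes (a handful of
subjects) the anti-conservative pooling will also flag incidental contrasts
— the screening tests therefore run at the design's 14 vs 12 subjects.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `alpha` | 0.05 | — | FDR level for edge retention and screen p-values |
| `sphere_radius_mm` | 7.5 | mm | 15 mm *diameter* ROI spheres; configurable radius |
| `reps`, `pct` | 50, 1..99 | — | full factorial gives the canonical 4950 records |
| `band_width` | 50000 | cost | cost-band resolution for simulation contrasts |
| `d_gate` | 0.70 | — | medium-effect sensitivity of the subsystem screen |
| `eta_sq_gate` | 0.06 | — | small-to-medium \(\eta_p^2\) for follow-up reporting |
| `length_bins` | 0-180 by 10 | mm | histogram resolution; covers typical inter-ROI distances |
| `strength_bins` | 0-1 by 0.05 | — | exact edges via `(0:20)/20` |
| `base_correlation` | 0.5 | — | within-subsystem coupling of the synthetic cohort |
| `background_correlation` | 0.05 | — | between-subsystem floor |
| `n_volumes` | 145 | volumes | scan length; >= 30 enforced for meaningful p-values |

## Numerical choices and degenerate inputs

* Zero-variance ROI columns abort network construction naming the ROI;
  degenerate-variance subsystems are excluded from the screen's FDR family
  with `p = NA` and a message.
* Bonferroni adjustments are capped at 1; bands with fewer than two records
  on either side are skipped, not fabricated.
* Empty networks: profile of all zeros (path length `NA`), but the attack
  simulation refuses them — 4950 identical zero rows would be noise dressed
  as data.
* Deleted-edge sets use a single seeded stream; the pipeline derives a child
  seed per stage from the root seed, so changing one stage's workload does
  not shift another stage's draws, and every result is bit-reproducible
  under a fixed seed.
* Floyd-Warshall is used for weighted shortest paths (dense regime); the
  unweighted hop distances use breadth-first search via igraph. Both are
  cross-checked against literal triple-loop oracles in the tests.

## Problem sizes used by the test suite

Unit tests run on 5-30 node graphs where brute-force oracles are exact and
fast. The end-to-end checks use the design scale deliberately: the
simulation-shape check runs the full 99 x 50 grid on a 264-ROI group
network; the screen-recovery check runs 20 replicates of a 14-vs-12 cohort
at 145 volumes with a +0.25 implant, plus 20 null replicates; the
edge-retention null check uses 20 independent-noise panels at 145 x 264.
These sizes were chosen as the smallest at which the corresponding claims
are about the study design rather than about toy graphs.

## Known limitations

* Euclidean ROI distance is a lower bound on anatomical wiring length; cost
  in mm x weight understates true metabolic cost for connections that route
  around structures.
* The pooled screen's p-values are anti-conservative by construction (see
  above); treat them as descriptive alongside d.
* Group averaging with absent-as-zero mixes edge prevalence and edge
  strength; the simulation's cost axis reflects both.
* No targeted-attack modes (degree- or betweenness-ordered deletion): the
  analysis is about random sparsification, not vulnerability ranking.
* The generator's exchangeable-ROI blocks make subsystem means cleaner than
  real parcellations; recovery rates reported by the tests are upper bounds
  in that specific sense.
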