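---
title: "Dissociating interdigitated cortical networks within the individual: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating interdigitated cortical networks within the individual: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interdigitate)
```

## The problem

Group-averaged resting-state fMRI yields a small set of canonical
distributed networks — the default network among them. When a single
individual is scanned densely (dozens of sessions) and analyzed within
their own anatomy, such canonical networks can fractionate into
*parallel, interdigitated* networks: two distributed systems whose
regions lie side by side in every cortical zone where either is
represented, at positions that vary from person to person. This package
implements, as tested and reusable code, the full chain of analyses
needed to establish such a fractionation — and, because densely sampled
individual data of this kind are not publicly deposited, a synthetic
surface-fMRI generator that plants the hypothesized structure so every
stage can be validated against a known ground truth.

The pipeline is: simulate (or load) per-session vertex time series on a
two-hemisphere triangulated surface; preprocess; compute quality maps;
build vertex-wise Fisher-z connectivity matrices; discover a dissociated
seed pair in a designated "search zone" (the lateral-prefrontal analog);
select a priori region pairs from discovery sessions; test a balanced
2x2 ANOVA battery on held-out replication sessions; confirm with
data-driven k-means parcellation; and quantify what is lost when one
subject's regions are imposed on another's data.

## The synthetic study and what it does (and does not) emulate

`simulate_study()` generates S subjects x R sessions of T frames at
TR = 1 s on an icosphere mesh built by recursive midpoint subdivision of
an icosahedron (`build_icosphere()`). Each subdivision level L gives
10·4^L + 2 vertices per hemisphere; level 6 reproduces the
40,962-vertex fsaverage6 resolution, and the two hemispheres are
identical disconnected components, matching a combined left+right vertex
set of 81,924 at full scale. The defaults encode the emulated design:
4 subjects, 24 sessions each, one resting run per session (the default
`frames_per_run = 422` corresponds to a 7 m 2 s run at TR = 1 s), with
odd-numbered sessions forming the discovery half and even-numbered
sessions the replication half.

The signal model per vertex v is

x_v(t) = baseline + a_v · w · s_k(v)(t) + g(t) + e_v(t),

with `w` the network loading, `s_k` the unit-variance latent time course
of the network containing v (zero elsewhere), `g` a shared global
signal, `e_v` i.i.d. Gaussian noise, and `a_v` an optional dropout
attenuation. Two vertices of the same network therefore correlate at
r = w²/(w² + sigma²) before filtering — the closed form the unit tests
check — and vertices of different networks are uncorrelated in
expectation. Latent and global time courses are white noise whose FFT
coefficients above 0.08 Hz are zeroed, then variance-normalized: a
brick-wall spectral filter rather than an IIR design, chosen so that the
planted signal is *exactly* band-limited (no stop-band leakage) and
survives the preprocessing low-pass filter by construction.

Network templates (`plant_networks()`) realize the interdigitation:
disjoint geodesic-disc zones are placed at deterministic farthest-point
anchors, and inside every zone each network receives one parcel grown by
nearest-anchor breadth-first search from adjacent anchor vertices —
parcels of different networks share no vertices yet share mesh edges
("side by side"). Per-subject spatial variability is a random walk of
each parcel anchor of at most `jitter_steps` hops inside its zone. The
literature does not quantify inter-subject spatial variability, so
`jitter_steps` is an exposed free parameter (default 2), not a
calibrated value.

What the generator deliberately does **not** model: hemodynamic
convolution, head motion beyond additive nuisance columns, physiological
noise structure, spatial autocorrelation of the noise, susceptibility
physics (dropout is a plain multiplicative attenuation of signal, not
noise), or folded cortical geometry. Passing tests on synthetic data
therefore demonstrate that the *analysis logic* is correct and has the
claimed operating characteristics under the stated signal model — not
that it would behave identically on real BOLD data.

## Preprocessing

`preprocess_session()` applies, in the conventional order: discard of
the first 12 frames (T1 equilibration), temporal low-pass filtering at
0.08 Hz, regression of nuisance variables and their temporal
derivatives, and surface smoothing. Smoothing-before-regression is
available as a switch (`smooth_before_regression`), since pipelines
differ on this point.

Numerical choices worth recording:

* **Filter realization.** Zero-phase 4th-order Butterworth applied
  forward-backward. The single-pass cutoff is pre-corrected by
  (sqrt(2) − 1)^(−1/8) so the −3 dB point of the *combined* two-pass
  response sits at the nominal 0.08 Hz; without this standard
  correction, the two-pass response is already ~2% down at 0.05 Hz,
  inside the band of interest. Each series is demeaned before filtering
  and its mean restored exactly afterwards. The nuisance table is
  filtered identically, so regression operates in the same frequency
  band as the data — otherwise regressing unfiltered regressors can
  reintroduce out-of-band variance.
* **Temporal derivatives.** Backward difference with a leading zero:
  simple, full-rank, and the convention most pipelines use.
* **Surface smoothing.** Iterated symmetric graph heat diffusion,
  `x <- x + (step/d_max)(A − D)x` with step 0.5, which preserves the
  per-frame vertex sum exactly (the operator has unit column sums),
  never mixes hemispheres, and approximates a geodesic Gaussian whose
  per-iteration variance is about `step` squared hops. The iteration
  count comes from sigma = FWHM/sqrt(8 ln 2) converted to hops via a
  nominal mesh edge length. By default that edge length is the
  fsaverage6-equivalent spacing scaled to the mesh in use,
  2^(6 − level) mm, so the standard 2 mm kernel is *sub-resolution*
  (identity) on desk-scale meshes — a 2 mm kernel cannot resolve a
  16 mm edge. Tests that exercise the smoother pass an explicit
  `mesh_edge_mm = 1`.

## Quality metrics

`tsnr()` is the per-vertex mean over standard deviation (denominator
T − 1), with zero-variance vertices flagged `NA` rather than infinite.
`falff()` is the fraction of one-sided spectral *amplitude* (square root
of the periodogram, per the originating method; a raw-power option
exists) in 0.01–0.08 Hz relative to the whole spectrum, DC excluded,
computed on demeaned series. For white noise at TR = 1 s the flat
expected amplitude spectrum gives fALFF ≈ (0.08 − 0.01)/0.5 = 0.14,
which the tests verify by Monte Carlo. QC is computed on raw
(unfiltered) data, since after a 0.08 Hz low-pass the metric is
meaningless by construction.

## Connectivity

`mean_z_matrix()` computes the per-run vertex-wise Pearson matrix,
applies the Fisher transform z = atanh(r) with |r| clipped to
1 − 1e−7 (the clipped value doubles as the documented diagonal
sentinel, excluded from all statistics), and averages across runs.
Runs are summed in `run_id` order so the result is bit-identical under
permutation of the input list. Zero-variance vertices are masked and
excluded downstream. Full 81,924² matrices are not materialized at desk
scale; the package works at configurable subdivision levels and the
acceptance analyses run at levels 2–3.

`test_retest()` correlates the vectorized upper triangles of the
discovery and replication mean matrices. On the default synthetic study
this lands around 0.92 — comparable to the 0.87–0.95 range reported for
densely sampled human data, though that agreement is an analogy, not a
reproduction.

**Reliability and disattenuation.** The source procedure cites
reliability-based dropout estimation without printing a formula, so the
package's `reliability_map()` is a *declared stand-in*: ICC(1,1) across
runs computed per vertex over its 1-hop geodesic neighborhood (runs as
raters, neighborhood vertices as items), clipped to [0, 1].
`disattenuate()` then applies the classical correction for attenuation,
z/sqrt(max(reliability, floor)), with floor 0.04 (at most a 5-fold
boost). Simulations with a planted dropout zone confirm the corrected
map moves toward its no-dropout value on the large majority of affected
network vertices.

## Seed search

The interactive explore-and-record procedure becomes an exhaustive,
deterministic search (`find_seed_pair()`). A candidate seed is *robust*
if its map peaks at z ≥ 0.6 in at least `min_zones` distinct zones
(default 4, echoing the four-lobe motif of canonical distributed
networks — "distributed regions" made countable); *diffuse* if its best
peak only reaches the 0.4 range; *dropout* below that. The second seed
must lie in the same search zone, within `vicinity_hops` of the first
(default: the zone diameter; no distance is stated in the literature),
show z < 0.3 with the first seed's map, and itself be robust.
Candidates are scanned in ascending vertex index and ties break toward
the lowest index, making the search invariant to relabeling up to that
rule. Whether the printed 0.6/0.4 values were hard thresholds or
heuristics in the original interactive procedure is unknowable; here
they are configurable hard thresholds with those defaults.

## The dissociation battery

`select_regions()` picks, per target zone, the vertex most correlated
with seed A and the vertex most correlated with seed B — from discovery
data only. The resulting region set carries a provenance label, and
`run_battery()` *refuses* region sets not derived from discovery data:
the discovery/replication firewall is enforced in code, not by
convention. For each replication session the Fisher-z correlation of
each seed with each target gives a balanced 2x2 design (12 sessions =
12 values per cell), tested by a classical two-way ANOVA
(`stats::aov`; an explicit sums-of-squares oracle in the tests checks
the F statistics to 1e−8) with interaction df (1, 4(n − 1)) = (1, 44).
A *crossover* requires both mean(A→A) > mean(A→B) and
mean(B→B) > mean(B→A); a positive interaction contrast with one failed
direction is *ordinal*. With 4 subjects and 5 zones the battery is 20
tests at alpha 0.01. No multiple-testing correction is applied — the
design argues by convergence of repeated significant results, not by a
corrected single test — but the report prints the expected number of
null false positives (0.2) for transparency. A lone-region mechanism
pairs a zone represented in only one network with a partner zone's
opposite-network region, mirroring how a parahippocampal region can be
paired with a posteromedial one.

Type-I behavior is verified empirically: on null studies (no planted
networks) the significant count across 500 replicate batteries stays at
the alpha level and the interaction p-values are uniform by
Kolmogorov–Smirnov test. The synthetic default plants clean effects in
every zone; it does not model the subject-specific attenuations (e.g. a
weak ventral-region difference in some individuals) that real data
show.

## Parcellation

`kmeans_parcellate()` concatenates sessions in time after per-session
variance normalization of each vertex series and runs `stats::kmeans`
(Euclidean distance on standardized series — equivalent to correlation
distance up to scale; the original MATLAB settings are unstated, so
these defaults are declared, not inferred), best of 10 restarts,
deterministic under a fixed seed. The published analysis used k = 12 on
real cortex, which remains the function default; recovery scoring
against the planted template uses k = planted networks + background.
`match_and_score()` solves the cluster-to-network assignment exactly by
enumeration over injective maps and reports the adjusted Rand index over
all vertices plus per-network Dice. Background vertices participate in
the clustering, as all of cortex did originally.

## Misalignment

`template_regions()` takes each subject's 10 parcel anchors (2 networks
x 5 zones) as that subject's individually tailored regions;
`region_matrix()` computes the 10x10 mean Fisher-z matrix on any
subject's sessions (meshes are registered by construction, so
cross-subject transfer reuses vertex indices, mirroring
surface-registration-based transfer); `block_contrast()` reduces each
matrix to mean within-network minus mean between-network z, and a
spectral sign split of the leading eigenvector gives a 2-cluster
assignment accuracy — quantifying a breakdown the original work showed
visually. In the Monte Carlo property tests the regions come directly
from the (jittered) templates rather than from a per-replicate seed
search: the property under study is degradation caused by spatial
variability alone, and the full discovery-derived path is exercised
end-to-end elsewhere. With jitter at or above the parcel radius the
own-subject contrast exceeds the cross-subject contrast in ≥ 95 of 100
replicate studies; with zero jitter the two are identical, confirming
the degradation is caused by spatial variability and nothing else.

## Orchestration and problem sizes

`run_pipeline()` executes the whole chain from a validated nested
config (`validate_config()` collects *all* problems — unknown keys,
constraint violations — rather than stopping at the first; every key
has a default, so a minimal config is valid), caches stage outputs
under a config-hash key for `resume = TRUE`, and writes CSV tables, a
JSON report, and a markdown summary. All randomness flows from seeds in
the config, so identical config + seed gives identical reports.

Problem sizes used by the shipped analyses and tests, chosen as
desk-scale stand-ins for the full-resolution design: level-2 meshes
(162 vertices/hemisphere) for the end-to-end study analyses (4 subjects
x 24 sessions x 300 frames), level 3 (642/hemisphere) for the
acceptance script, level 1 and parcel-anchor shortcuts for the
500-replicate null calibration and 100-replicate misalignment Monte
Carlos, and level 6 only for the mesh-arithmetic check. The interaction
counts, type-I rates, recovery indices, and contrast orderings these
analyses measure are scale-free properties of the method; the absolute
z levels are not, and no claim is made that they match full-resolution
values.

## Known limitations

* The vertex indexing is 1-based throughout, the natural convention in
  R; external 0-based vertex ids must be shifted on import.
* No R HDF5 or GIFTI bindings are used: the study container is a
  documented plain-text directory layout (CSV/TSV + JSON metadata)
  written by `write_study_container()`. Adapters for binary
  neuroimaging formats are out of scope.
* The ICC-based reliability map is an operationalization of a cited but
  unprinted procedure; results that depend on its exact form (the
  disattenuation demonstration) should be read accordingly.
* The generator's noise is spatially white; real BOLD noise is
  spatially correlated, which would make the seed-search thresholds
  harder to meet at matched SNR than they are here.
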