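---
title: "Molecular networking and discovery-potential statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular networking and discovery-potential statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Untargeted LC-MS/MS surveys of microbial culture extracts — the classical
setting is *Actinomycetes* grown under several culture media, the OSMAC
("one strain, many compounds") strategy — produce millions of fragmentation
spectra of which only a small fraction match any reference library. The
unmatched remainder is the *discovery potential*: chemistry that is detected
but not yet characterized. `molnetr` implements the standard computational
chain used to quantify that potential: spectral cleanup, merging of
near-identical scans into consensus spectra, molecular networking by
modified-cosine similarity, exact and analog library annotation, and
rarefaction / media-overlap statistics over the strains-by-media design. A
seeded synthetic-study generator supplies ground-truthed inputs so every
stage is testable end to end without touching raw depositions.

# The similarity kernel

Two spectra $A$ and $B$ with precursor masses $p_A \le p_B$ and peak lists
$\{(m_i, I_i)\}$ are compared with the **modified cosine**. A peak pair
$(i, j)$ is a candidate when

$$|m_i - m_j| \le \tau \quad\text{or}\quad |m_i + \Delta - m_j| \le \tau,
\qquad \Delta = p_B - p_A,$$

with fragment tolerance $\tau = 0.02$ Da. Intensities are square-root
transformed and each spectrum's transformed vector is scaled to unit
Euclidean norm; the score is

$$S(A,B) = \max_{\sigma} \sum_{(i,j)\in\sigma} \hat I_i \hat I_j$$

over one-to-one assignments $\sigma$ of candidate pairs — a maximum-weight
bipartite matching, so $S \in [0, 1]$ and $S(A, A) = 1$. A pair that
satisfies both the direct and the shifted condition is counted once (and
classed as direct). `n_matched` is the number of pairs in the maximizing
assignment.

Numerical choices:

* **Exact matching, not greedy.** The candidate pair graph is decomposed
  into connected components; each component is solved exactly by
  branch-and-bound over its edges (visited in decreasing weight, pruned by
  the remaining-weight bound). At 0.02 Da tolerance virtually every
  component is a single edge or a disjoint matching, so the exact solver
  costs the same as greedy while being provably optimal; tests verify it
  against exhaustive assignment enumeration. A greedy mode
  (`method = "greedy"`) exists for speed comparisons.
* **Ties.** Among equal-weight assignments the one with more pairs is
  preferred, which makes the reported matched-peak count deterministic.
* **Intensity weighting.** The square-root / unit-norm convention of the
  networking ecosystem; the literature rarely states it, so it is fixed
  here and documented rather than configurable.

# Preprocessing

Each spectrum is cleaned by (1) removing every fragment within ±17 Da of
the precursor (inclusive boundary: $|m - p| \le 17$ is removed — the
conservative reading for stripping residual precursor signal), and (2) a
windowed top-6 filter: a peak survives iff its intensity ranks in the top 6
among all peaks within ±50 Da of *its own* m/z (per-peak sliding
neighborhood, the GNPS convention, not disjoint bins; intensity ties break
toward the lower-m/z peak). Both filters are idempotent, which the tests
assert. Blank runs additionally define a precursor **exclusion list**
(single-linkage deduplication within 0.01 Da — half the precursor
tolerance, since the generator does not model chromatographic retention
windows); sample spectra whose precursor falls on the list are dropped,
emulating in software the per-medium acquisition-time exclusion of culture
medium components.

# Consensus clustering

The clustering step that turns raw scans into "unique MS/MS" is specified
here as deterministic single-linkage: two spectra are joinable iff their
precursors agree within 0.02 Da and their cosine (the precursor delta is
then ≈ 0) is ≥ 0.7; clusters are connected components of the joinability
relation. This is a deliberate, documented simplification of the
multi-round heuristic clustering used by large-scale tools — it is
order-independent, exactly reproducible, and testable against a brute-force
all-pairs oracle, which matters more at desk scale than the heuristics'
speed. Consensus peaks pool the members' peaks, group them by
single-linkage within the fragment tolerance (on a line: split sorted m/z
wherever the adjacent gap exceeds 0.02 Da), emit intensity-weighted mean
m/z and summed intensity per group, and rescale to a maximum of 1000. A
consensus touching any blank member is removed (`max_blank_fraction = 0`;
practice varies, so the fraction is exposed).

# Networking

Edges require cosine ≥ 0.7 **and** ≥ 6 matched peaks. The mutual top-K
filter (K = 10) keeps an edge iff each endpoint ranks in the other's top K
by cosine; ranks are computed on the threshold-filtered edge set (the
behavior of the widely used online workflow; computing ranks before
thresholding is the other defensible reading, and the filter is a separate
function so either composition is available). Connected components are
molecular families; any component above 100 nodes loses its lowest-cosine
edge (ties by lexical edge id), components are recomputed, and the loop
repeats — exact recomputation after every removal, verified against a
step-by-step reference. The stated edge criterion "more than 6 matched
peaks" conflicts with the library criterion "at least 6"; both are
implemented as ≥ `min_matched_peaks` (default 6) and configurable.

# Annotation

Exact dereplication takes, per consensus spectrum, the best library entry
with $|\Delta| \le$ 0.02 Da at the same cosine/matched thresholds (ties:
more matched peaks, then entry id); library spectra pass through the same
preprocessing as queries. Analog (propagated/suspect-style) annotation then
covers the remaining spectra, allowing 0.02 Da $< |\Delta| \le$ 200 Da. The
200 Da cap is a surrogate for curated suspect-library delta lists — wide
enough for common residue and glycosylation offsets, narrow enough to keep
the candidate set chemically plausible. One annotation per mode per
consensus (top hit), so exact and analog sets are disjoint by
construction. `localize_mass_shift()` partitions an analog match's peak
pairs into unshifted and $\Delta$-shifted sets and reports the smallest
shifted fragment — the tightest bound on where the modification lies along
the fragment series. This is an intentionally simplified localization (it
reports shift-carrying fragments, not atom positions). A family is
annotated iff ≥ 1 member is.

# Discovery statistics

The incidence matrix records which strains each item (consensus spectrum or
family) was observed in; the accumulation unit is the **strain**, pooling
its media files (per-file accumulation is available). Rarefaction is
permutation-averaged (default 100 seeded permutations) rather than the
single fixed-order accumulation one would narrate — the order-invariant
estimate — with the fixed order available as a mode. Alongside the
permutation mean the closed-form hypergeometric expectation

$$E[S(k)] = \sum_i \left(1 - \binom{N - n_i}{k}\Big/\binom{N}{k}\right)$$

is reported ($n_i$ = units containing item $i$); for $N \le 5$ the tests
enumerate all $N!$ orderings and confirm exact agreement. Strata (all /
annotated / unannotated × spectra / families) share the same permutations,
so annotated + unannotated = all at every $k$. Media-overlap counts are the
upset-plot decomposition: exclusive counts over exact media combinations
(a partition of the items) plus per-medium set sizes. Annotation rates are
reported under **both** denominators in circulation — annotated raw scans /
all raw scans, and annotated consensus / all consensus — because the two
are conflated in practice; neither is privileged. The pathway × media
matrix counts annotated consensus per culture medium and biosynthetic
pathway and normalizes each pathway row to its maximum.

# The synthetic study generator

The generator emulates the statistical structure the analysis relies on,
with defaults fixed once:

* **Design**: 20 strains × the five media (ISP-2, ISP-4, TSA, NSG, CZP); 60
  molecules in 15 structural families; library fraction 0.13 (the annotation
  regime of large microbial surveys).
* **Molecules**: family base mass uniform on 200–1600 Da; 8–40 fragment
  ions with log-normal (μ=0, σ=1) intensities; further family members add
  cumulative offsets drawn from common biochemical deltas (CH₂ 14.016, H₂O
  18.011, glycine residue 57.021, …) to the precursor and to a suffix of the
  m/z-sorted fragments, emulating a modification site partway along a
  fragment series. Member intensities get a log-normal (σ=0.3) wobble.
* **Ion redundancy**: [M+H]⁺ always; [M+Na]⁺, [2M+H]⁺ and an in-source
  fragment form attached per molecule with probabilities scaled so the mean
  is ~3 ion forms per molecule. Adducts and dimers share the protonated
  fragment ladder (so networking, not clustering, links them); the
  in-source form promotes a high fragment to precursor and keeps its
  sub-peaks.
* **Noise**: 5 ppm Gaussian m/z error on fragments and precursors;
  Poisson(3) uniform noise peaks per spectrum at 1–5% relative intensity.
* **Background**: 8 medium-background molecules, each assigned one medium,
  present in that medium's blank *and* all of its sample files — so the
  exclusion list and the blank-cluster filter both have real work to do.
* **Production**: each molecule produces on a random ~70% subset of media
  with per-medium Bernoulli probability uniform on 0.4–0.9, zero elsewhere
  — media-dependent chemistry for the overlap and pathway analyses.

Everything is a pure function of the design seed; reruns are
byte-identical. What the generator does **not** emulate: fragmentation
chemistry, isotope envelopes, chromatography/co-elution, ion suppression,
charge states > 1. Passing the synthetic-recovery tests therefore
demonstrates the pipeline's algorithmic correctness and its behavior under
calibrated m/z error and redundancy — not performance on real instrument
quirks.

The truth-side reference for annotation recovery (`truth_annotatable()`)
renders every (molecule, ion form) pair noiselessly, preprocesses it, and
searches it against the clean library with the pipeline's own thresholds:
the fraction a perfect run on noiseless data would annotate. The acceptance
test requires the noisy end-to-end annotation fraction to stay within 3
percentage points of it across five generator seeds.

# Problem sizes and runtime

The test suite and the acceptance script run the full study at 20 strains ×
5 media × 60 molecules (~8,000 raw spectra, ~170 consensus) — large enough
for every stage to have nontrivial structure, small enough for a complete
end-to-end run in under a minute on one core. Oracle-equivalence checks use
deliberately tiny instances (≤ 8 peaks for exhaustive matching, ≤ 30 nodes
for graph oracles, ≤ 5 units for exhaustive rarefaction) where brute force
is exact.

# Known limitations

* Single-linkage consensus clustering can chain through gradual precursor
  drift in principle; at 0.02 Da tolerance and 5 ppm error this is not
  observed in the synthetic regime, but a density-aware merge rule would be
  needed for noisier data.
* Charge is carried but not used: precursor m/z enters the modified cosine
  as-is (acquisition with default charge 1); multiply charged species would
  need a charge-corrected delta.
* The analog search is a free-delta surrogate for curated suspect lists; it
  will propose adduct-type deltas (e.g. +21.982 Da) as "analogs", which a
  curated list would label as ion forms of the same molecule.
* `localize_mass_shift()` bounds the modification site on the fragment
  series; it does not attempt atom-level placement.
* Rarefaction stops at the observed units; no richness extrapolation
  (Chao-type estimators are out of scope).

# Reproducing the analysis

```{r, eval = FALSE}
# the five stage drivers, from the repository root:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_preprocess_cluster.R
#   Rscript analysis/03_network.R
#   Rscript analysis/04_annotate.R
#   Rscript analysis/05_discovery_stats.R
# or the one-call equivalent:
library(molnetr)
res <- run_pipeline(pipeline_config(
  out_dir = "results/run", simulate = study_design(seed = 42L),
  seed = 42L))
str(res$summary)
```
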