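---
title: "Models and methods behind nitroPM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nitroPM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitroPM)
```

`nitroPM` analyzes ammonia-oxidizing microorganisms (AOMs) recovered from
PM2.5 filter samples: who is there (marker-gene OTUs, phylogeny), how many
there are (qPCR, cells per m³ of air), how fast the community oxidizes
ammonia (nitrification-potential incubations), and which guild — AOA, AOB
or comammox — plausibly accounts for that rate. This vignette documents the
models, the parameters that matter, the numerical choices, and what the
synthetic-data tests do and do not establish.

## 1. Community structure

**Distances.** For equal-length marker sequences the uncorrected p-distance
is taken over columns where both bases are unambiguous (A/C/G/T); ambiguous
bases and shared gaps drop out of the denominator *pairwise*. Unequal-length
pairs are first aligned globally with free end gaps (match +1, mismatch −1,
gap −2); terminal overhangs are excluded from the denominator. Clone
libraries from a single primer set are near-equal-length, so the alignment
path is a fallback; its scoring is this package's choice and OTU counts on
heterogeneous inputs can be sensitive to it.

**OTUs.** Furthest-neighbour (complete-linkage) agglomeration at a distance
cutoff of 0.03 (97% identity, boundary inclusive): two sequences share an
OTU only if *every* cross-pair distance is ≤ 0.03. This is the classic
conservative choice for clone libraries; single and average linkage are
options. Merge ties resolve to the smallest cluster-index pair, OTUs are
numbered by decreasing abundance, and each representative is the
minimum-summed-distance member (ties lexicographic), so results are fully
deterministic.

**Diversity.** Shannon index in nats (−Σ pᵢ ln pᵢ; base-2 switch
available) and the bias-corrected Chao1, S_obs + n₁(n₁−1)/(2(n₂+1)), which
stays defined when a library has no doubletons. The classic form
n₁²/(2n₂) is available but warns when n₂ = 0. Chao1 ≥ S_obs always, with
equality when there are no singletons.

## 2. Phylogeny

Jukes–Cantor correction d = −(3/4) ln(1 − 4p/3) assumes equal base
frequencies and a single substitution rate; it saturates at p = 0.75, and
such pairs are rejected rather than truncated. Neighbor joining follows the
Saitou–Nei Q-criterion with deterministic tie-breaking (smallest index
pair). For an additive matrix the reconstruction is exact; the test suite
checks tree path lengths against the input matrix to 1e−9 for random trees
of up to 8 leaves. Negative branch-length estimates — a normal NJ artifact
on noisy matrices — are clamped to zero with the deficit shifted to the
sibling edge (total path lengths preserved); raw values are kept in the
tree's `negative_branches` field. Gapped/ambiguous sites are handled by
pairwise deletion; whether complete deletion was used in the reference
analyses is unstated, so pairwise deletion is a documented assumption.

Bootstrap support resamples alignment columns with replacement, rebuilds
the NJ tree per replicate under the same distance model, and scores each
internal bipartition of the point tree by its replicate frequency. The
convention is 1000 replicates; tests use 100 for runtime. One caveat worth
recording: the JC transform is non-additive, so a very short internal edge
flanked by long edges can vanish from the corrected point tree even when
the raw p-distance tree resolves it. The weak-edge ordering test therefore
runs on raw p-distances; JC remains the package default for real data.

## 3. qPCR absolute quantification

Standard curves are ordinary least squares of Cq on log₁₀(copies) over a
10-fold plasmid dilution series; efficiency is 10^(−1/slope) − 1 (slope
−3.3219 ⇔ 100%). Efficiency outside 90–110% or R² < 0.99 triggers a
warning, not an error — reference assays ran 90.6–106.0% with R² > 0.996,
and degraded synthetic plates must still flow through tests. Unknowns are
inverted per replicate (copies = 10^((Cq − intercept)/slope)) and
aggregated as mean ± sd on the linear scale, matching how cell numbers are
reported; a geometric-mean switch exists. `NA` Cq is the no-amplification
sentinel: such replicates are excluded from the mean (a detection-limit
reading), and an all-sentinel sample yields zero copies with an explicit
flag.

Copies become cells via fixed per-cell copy numbers (1 *amoA* per AOA and
per comammox, 2.5 per AOB, 3.6 16S rRNA genes per average prokaryote) and
cells become per-air-volume abundances via
`cells × extract_scaleup / filter_fraction / air_volume`. The reference
protocol extracted 1/4 of each filter and sampled 144 m³ (100 l min⁻¹ for
24 h); elution and template volumes are not printed anywhere, so
`extract_scaleup` is deliberately explicit configuration with no magic
default. Whether AOB abundance is *amoA*- or 16S-based is ambiguous in the
source assays; `copies_per_cell` is per-assay configuration and the package
takes no position.

## 4. Nitrification potential

Incubations follow the suspension technique: net concentration = sample −
blank per analyte and timepoint (negatives preserved and flagged, never
clipped), and the maximum nitrification rate uses the two endpoints:

NNR_max = (NH₄⁺-N_net,0 − NH₄⁺-N_net,t) · Q1 · 1000 / (t · Q2)

with Q1 = 0.25 l, t = 16 h, Q2 = 48 m³ as defaults and 1000 converting mg
to μg. Endpoint arithmetic — not a fitted slope — reproduces all three
reference rates (0.16, 0.15, 0.12 μg (NH₄⁺-N) m⁻³ air h⁻¹, mean 0.14) at
2-decimal rounding, so it is the default; a regression-slope option over
all timepoints is provided. The published formula images were unavailable;
the mg→μg factor is forced by the printed inputs and outputs. The nitrogen
balance report compares cumulative NH₄ consumed against cumulative
NO₂⁻+NO₃⁻ produced; the default "balanced" verdict tolerates a 10% final
imbalance.

## 5. Guild attribution

With Mr_N = 14 g mol⁻¹, a guild's rate is
cells (m⁻³) × r_in (fmol cell⁻¹ h⁻¹) × Mr_N × 10⁻⁹ in μg N m⁻³ h⁻¹ (the
10⁻⁹ is fg→μg, fixed by dimensional analysis). Relative contributions
divide by the measured NNR_max; comammox takes the remainder
1 − RC_AOA − RC_AOB because no comammox cell-specific rate is established —
this remainder form is an inference from the published behaviour of the
model (comammox ≈ 100% under low-activity scenarios), not a printed
formula, and a direct-rate mode accepting a comammox r_in exists for
sensitivity analysis. If RC_AOA + RC_AOB > 1 the pair is rescaled
proportionally to sum to 1, comammox is set to 0 and the result flagged
`clamped`; raw values are always retained. Reported triples sum to 1 by
construction. Heterotrophic ammonia assimilation is deliberately a no-op
(the reference assumption for low-ammonia environments), exposed as a
`heterotroph_discount` fraction defaulting to 0.

The scenario grid crosses r_in,AOA ∈ {0.5, 208} with r_in,AOB ∈ {1, 50}
fmol cell⁻¹ h⁻¹, the literature bracket from freshwater sediment, marine
isolates, drinking-water treatment and wastewater studies. (One figure
caption in the source prints "280" for AOA; the repeated body value 208 is
used.)

## 6. Correlation statistics

Spearman's ρ is the Pearson correlation of mid-ranks (average ranks on
ties). For campaigns of n ≤ 8 samples the two-sided p-value enumerates all
n! permutations — at n = 6 the p grid has resolution 1/720, and the
asymptotic t-approximation is dubious — counting the identity permutation.
Monte Carlo mode adds the identity to numerator and denominator,
(hits + 1)/(n_perm + 1). No multiple-testing correction is applied by
default, mirroring common reporting at this n; Benjamini–Hochberg is a
switch. Published SRCC p-values for n = 6 (e.g. 0.014 at ρ = 0.949) do not
sit on the 1/720 grid; their method is unknown and no attempt is made to
match them.

## 7. The synthetic world

Every pipeline input has a seeded generator whose defaults are the stated
conditions of the reference campaign:

- **Clone communities**: cluster centroids mutated from one ancestor on
  disjoint site sets, so centroid spacing hits `between_divergence`
  exactly; members mutate Binomial(L, within) sites (per-site uniform
  substitution to one of the other 3 bases, no indels — both clustering and
  JC assume substitutions only). Mutation counts are truncated at
  ⌊cutoff·L/2⌋: the separability invariant
  (between > cutoff + 2·within) reads `within` as a bound, and untruncated
  binomial tails would let a cluster's diameter cross the 0.03 cutoff and
  split a planted OTU. Within that budget realized divergences remain
  binomial.
- **qPCR plates**: standards sit exactly on Cq = slope·log₁₀(copies) +
  intercept before Gaussian Cq noise; zero-copy unknowns emit the
  no-amplification sentinel. Default triplicates, ≥4 ten-fold levels.
- **Incubations**: zero-order (constant-rate) ammonia removal — the
  endpoint formula is a two-point linear rate, so the generator's kinetics
  match the estimator's assumption by design — with the comammox share of
  production routed to nitrate and AOA/AOB to nitrite, a constant blank,
  and Gaussian concentration noise truncated at 0 (default timepoints
  0–16 h every 2 h, the reference schedule). Noiseless series balance
  nitrogen exactly and record the true NNR_max and RC triple.
- **Factor tables**: standard-normal factors with planted monotone
  taxon–factor links of sign ±1 (or 0 for null), plus Gaussian noise.

All randomness flows from one integer seed per generator call
(`withr::with_seed`), so identical specs give byte-identical FASTA/CSV.

What green tests establish: the estimators invert the generators they are
pointed at (round trips to 1e−6 or better noiselessly; unbiasedness and
±0.1 log₁₀ recovery at stated noise), and the combinatorial cores match
independent oracles (exhaustive partition search, brute-force path-length
checks). What they do not establish: performance on real bioaerosol data —
no chimeras, PCR bias, primer mismatch, aerosol physics, non-constant
blanks, or Michaelis–Menten substrate limitation are simulated, and the
published per-city abundances and contribution ranges rest on raw data that
was never printed.

## 8. Known limitations

- Alignment scoring for unequal-length sequences is a package choice; OTU
  counts near the cutoff can shift under other scorings.
- The attribution model assumes all detected cells are equally active
  (assumption 4 of the source model); RNA- or SIP-based activity data would
  supersede it.
- Exact permutation p-values are limited to n ≤ 8 (40320 orderings);
  larger designs fall back to the t-approximation or Monte Carlo.
- `nnr_max` endpoint mode uses two measurements and inherits their noise;
  the regression option is preferable for noisy series but was not the
  reference behaviour.
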