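---
title: "Predicting SHAPE reactivity from RNA 3D structure and sieving ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting SHAPE reactivity from RNA 3D structure and sieving ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapesieve)
```

## The problem

SHAPE chemical probing (selective 2'-hydroxyl acylation analyzed by primer
extension) reports the local flexibility of every nucleotide in an RNA: a
reagent such as 1M7 acylates the ribose 2'-hydroxyl, and flexible,
unconstrained nucleotides acquire adducts faster than nucleotides locked by
base pairing, stacking, or ligand contacts. Given a candidate 3D structure,
one can ask the inverse question: *what SHAPE profile would this structure
produce?* If predicted and measured profiles agree, the structure is
SHAPE-compatible; if not, it can be discarded. `shapesieve` implements this
forward model and uses it to rank ("sieve") conformational ensembles.

## The reactivity model

For nucleotide $i$ the predicted reactivity is

$$p_i = SF_i \times e^{SE_i}$$

a product of a *structural factor* and an exponentiated *energy-like
score*:

$$SF_i = (\bar{A}_{SAS}(i) + A_{SAS}^0) \cdot F_{sug}(i) \cdot F_{term}(i),
\qquad
SE_i = \bar{E}_{2D}(i) + \bar{E}_{IE}(i) + E_{lig}(i).$$

The ingredients, all computed from heavy-atom coordinates alone:

* **Interaction energy** $E_{IE}(i) = \sum_m [A \cdot E_{bp}^{(t)}(i,m) + B]
  + \sum_k E_{st}(i,k)$ sums, over all detected base pairs and stacking
  partners of $i$, a typed pair energy (scaled by $A$ with per-pair offset
  $B$) and a polarity-dependent stacking energy — upstream (5') and
  downstream (3') partners carry separate energies, optionally keyed by the
  partner base.
* **2D pairing energy** $E_{2D}(i)$ credits a fixed energy to every
  position paired in the secondary structure extracted from the 3D
  coordinates.
* **Accessibility** $A_{SAS}(i)$ is the Shrake–Rupley accessible surface
  area of the O2' atom probed with a 2.0 Å bead representing the reagent;
  $A_{SAS}^0$ is a "breathing" offset that keeps apparently buried
  positions weakly reactive, acknowledging thermal motion absent from a
  static model.
* **Neighbor smoothing.** A free nucleotide between rigid neighbors is
  less reactive than one between flexible neighbors, so $E_{IE}$, $E_{2D}$
  and $A_{SAS}$ are smoothed over the asymmetric window
  $\{i-1, i, i+1, i+2\}$ with four nonnegative weights per profile
  ($w_j$, $d_j$, $a_j$); at chain ends and backbone breaks the window is
  truncated and renormalized over the retained weights. Smoothing never
  crosses a chain boundary or a break (residue-numbering gap or
  O3'–P distance > 2.5 Å), because averaging across physically
  disconnected nucleotides has no mechanistic meaning. Only these three
  profiles are smoothed; $F_{sug}$, $F_{term}$ and $E_{lig}$ act locally.
* **Sugar pucker** $F_{sug}$: a multiplicative factor looked up from the
  ribose pucker class, which is a pure function of the pseudorotation
  phase $P$ (Altona–Sundaralingam convention, $\nu_2$ as reference,
  quadrant resolved by a two-argument arctangent). C2'-endo sugars are more
  reactive than the A-form C3'-endo reference, consistent with the
  flexibility literature; missing ring atoms yield factor 1.
* **Terminal factor** $F_{term}$: SHAPE constructs append short flexible
  sequences at the 5' and 3' ends, so the outermost positions of each
  chain get a configurable factor by depth.
* **Ligand mask** $E_{lig}$: positions flagged 1 in a user mask (bound by
  a ligand) receive an energy penalty; by default no position interacts.

The model has no explicit temperature: its parameters absorb an average
over the solution conditions of typical SHAPE experiments.

### Parameters and their defaults

Every trainable symbol lives in one config (`default_params()`, YAML
round-trip via `read_params()`/`write_params()`). The shipped values are
deliberately labeled **UNTRAINED-DEFAULTS**: sign-correct, magnitude-sane
values that make fixtures transparent — *not* values fitted to
experimental data, which a user should supply through `--params`:

| parameter | default | units / meaning |
|---|---|---|
| `A`, `B` | 1, 0 | scale and offset on pair energies |
| `e_bp` | canonical −1, other −0.5 | pair energy by type (model units) |
| `e_st_5p`, `e_st_3p` | −0.4, −0.2 | stacking energy by partner polarity |
| `e_2d_pair` | −0.5 | 2D pairing energy per partner |
| `w`, `d`, `a` | (1, 2, 1, 1) | smoothing weights, window {i−1..i+2} |
| `a_sas0` | 10 Å² | breathing offset |
| `f_sug` | C2'-endo 1.5, else 1 | pucker factor |
| `f_term` | 2.0 at depth 1 | terminal factor by depth |
| `e_lig` | −2 | masked-position penalty |

All interaction energies are expected ≤ 0 so that interactions suppress
reactivity through $e^{SE}$; a config violating this draws a warning, not
an error, since a trained model might legitimately place small positive
entries.

## Geometric annotation

The annotators replace external tools with in-package geometric detectors
so that the whole pipeline is self-contained and testable on constructed
coordinates.

**Base pairs** pass four gates (all config-exposed): ring-centroid
pre-filter ≤ 15 Å; at least one polar (N/O) heavy-atom contact ≤ 3.4 Å
between base edges; base-plane normals within 65°; mutual out-of-plane
offset ≤ 2.5 Å (this is what rejects stacked neighbors, which are
otherwise close and parallel). Interacting edges (Watson–Crick, Hoogsteen,
sugar) are voted by inverse-distance-weighted membership of the contacting
atoms, and cis/trans follows from the side each glycosidic bond takes of
the line joining the glycosidic nitrogens, projected into the mean base
plane. `cWW` pairs of AU, GC or GU are canonical.

**Stacking** requires ring-centroid distance in [2.0, 5.5] Å, plane
normals within 30°, and a lateral in-plane centroid offset ≤ 3.5 Å. The
offset gate was chosen against the package's own ideal A-form geometry:
with zero base-pair inclination, sequential pyrimidine ring centroids sit
at ~3.15 Å lateral offset, so a tighter gate would deny the definitional
fact that every sequential neighbor in an A-form helix stacks. 3.5 Å is
within the range of published stacking definitions and remains
configurable.

**2D extraction** keeps canonical pairs only, resolves multiplets in favor
of the pair with the smallest summed contact distances, and assigns
pseudoknot tiers by carving out a maximum non-crossing subset first
(interval dynamic programming, verified in tests against exhaustive
enumeration), then tiering the remainder greedily. Lone pairs are kept —
no minimum-helix-length filter. Whether pseudoknotted pairs feed
$E_{2D}$ is a config flag (`include_pseudoknots`, default `TRUE`).

## Numerical choices

* **SASA sampling** uses a deterministic golden-section spiral (no RNG),
  960 points by default, so surface areas are bit-stable across runs;
  doubling the density moves helix-fixture values by well under 1%.
  vdW radii: C 1.70, N 1.55, O 1.52, P 1.80 Å (config-overridable). The
  probe sees the O2' atom alone — hydrogens are ignored throughout the
  package, since experimental structures usually lack them.
* **Missing data**: a nucleotide without O2' gets a *missing* surface
  area, imputed with the structure median (configurable); a ribose with
  missing ring atoms yields $F_{sug} = 1$; profile positions marked −999
  (or ≤ −500) never enter correlations.
* **Degenerate inputs**: a planar ribose ($\nu_{max} = 0$) has undefined
  phase and is classed `planar/undefined`; correlations require ≥ 3
  jointly observed positions and nonzero variance, otherwise they error
  rather than return NaN.
* **Noise-adjusted correlation.** SHAPE reactivities and their errors are
  approximately log-normal, so the noise-adjusted Pearson correlation
  log-transforms both profiles ($x \mapsto \ln(x + 0.01)$, after clamping
  small negative experimental values in (−500, 0) to zero) and reweights
  each position by $1/(1 + (\sigma_i/\sigma_{obs})^2)$ inside a weighted
  product-moment correlation, with $\sigma_{obs}$ the standard deviation
  of the log-observed profile. Zero noise reduces it to the plain
  correlation of log-profiles; an infinite-noise position drops out
  exactly. This concrete realization is this package's own design (the
  floor $\epsilon = 0.01$ and the inverse-variance weight are
  config-switchable), and the plain Pearson correlation is always
  reported alongside. Predicted profiles are correlated raw — Pearson
  correlation is scale-invariant, so no normalization to a standard SHAPE
  scale is applied before comparison.
* **RMSD** is computed over shared heavy atoms (matched by nucleotide
  index and atom name) after Kabsch superposition with a reflection
  guard; tests cross-check it against an independent quaternion
  superposition to 1e−9.
* **Sieve ranking** sorts by noise-adjusted correlation, then plain
  correlation, then member id — reports are deterministic, and per-member
  failures are logged and skipped rather than aborting a batch.

## What the synthetic fixtures emulate

The generator builds exact-coordinate fixtures so every stage is testable
without downloads:

* **Ideal A-form duplexes** stack a frozen residue template (standard
  base-pair reference frame bases; a C3'-endo ribose/phosphate fitted once
  by constrained least squares) along a 32.7°/2.81 Å helix whose backbone
  closes to |O3'–P| ≈ 1.60 Å. G·U pairs get true wobble geometry: the
  uracil base slides in-plane until the two wobble hydrogen bonds reach
  2.85 Å.
* **Hairpins** add a single-stranded loop grown residue-by-residue along a
  planar constant-turn arc solved so the chain closes onto the far stem
  strand; loop bases splay outward and make no base contacts.
* **Decoys**: `perturb_structure()` adds seeded isotropic Gaussian noise
  (near-native decoys); `scramble_2d_decoy()` rebuilds the same sequence
  as a single-stem fold at a different register (non-native 2D
  constraints), with a pair count within one of the native's.
* **Synthetic profiles**: `synth_shape()` multiplies the model's own
  noiseless prediction by $e^{\xi}$, $\xi \sim N(0, \sigma^2)$ —
  log-normal multiplicative noise matching the assumed error structure.

What passing closed-loop tests shows — and what it does not: profiles are
generated by the same model that predicts them, so recovery of the native
fold demonstrates the *internal consistency* of the pipeline (annotation,
geometry, scoring, correlation and ranking all interlock correctly) and
its noise robustness, not predictive accuracy on laboratory SHAPE data.
Fixtures are idealized: uniform C3'-endo sugars, no inclination/propeller,
no tertiary contacts, no modified residues in loops. Accuracy on real data
is a property of trained parameters, which are out of scope here.

## Study conditions used in tests

The headline ranking experiment uses a 12-nt native hairpin (4-bp stem,
GAAA loop), observation noise $\sigma = 0.1$ on the log scale, 9 scrambled
decoys per replicate, and 100 noise replicates (the first 30 additionally
carry 5 near-native decoys at $\sigma = 0.5$ Å perturbation for the
separation check). These sizes make one full experiment run in a few
minutes on one CPU while leaving the qualitative outcome unambiguous: the
native tops the ranking in ≥ 95% of replicates and near-native decoys
score clearly above scrambled-2D decoys.

## Known limitations

* Annotation gates are declared substitutes for published annotators'
  criteria; bifurcated and water-mediated pairs, base triples, and subtle
  Leontis–Westhof corner cases are out of scope.
* A multi-model file is treated as an ensemble of independent
  conformations; no Boltzmann averaging into one profile is attempted.
* mmCIF, DNA and protein chains are not supported; non-RNA content is
  removed, not modeled.
* The shipped parameter defaults are untrained; quantitative agreement
  with experimental profiles requires user-supplied trained values.

## A worked example

```{r example, eval = FALSE}
native <- build_hairpin(4, "GAAA")
obs <- synth_shape(native, noise_sigma = 0.1, seed = 1)

pred <- predict_profile(native)
glance(pred)
pearson_cor(predicted_profile(pred), obs)

ensemble <- c(
  list(native = native),
  setNames(lapply(1:9, function(k) scramble_2d_decoy(native, seed = k)),
           paste0("decoy", 1:9)))
report <- sieve(ensemble, obs, reference = native)
report
autoplot(report)
```
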