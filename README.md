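# shapesieve

Predict per-nucleotide SHAPE reactivity from an RNA 3D structure, compare
the prediction to experimental SHAPE data, and rank ("sieve")
conformational ensembles by SHAPE compatibility.

SHAPE probing (selective 2'-hydroxyl acylation analyzed by primer
extension) measures the local flexibility of each nucleotide: reagents
like 1M7 acylate the ribose 2'-OH of flexible positions faster than of
positions constrained by pairing, stacking or ligands. `shapesieve`
implements the forward model — given heavy-atom coordinates in PDB format,
what SHAPE profile should this structure produce? — and uses agreement
between predicted and measured profiles to pick native-like structures out
of decoy pools. It is aimed at RNA structural modelers who generate
candidate 3D conformations (simulation snapshots, prediction models, NMR
ensembles) and have a SHAPE profile to select against.

## The model

For nucleotide *i*:

```
p_i  = SF_i * exp(SE_i)
SF_i = (Ā_SAS(i) + A_SAS0) * F_sug(i) * F_term(i)
SE_i = Ē_2D(i) + Ē_IE(i) + E_lig(i)
```

where `E_IE(i) = Σ_m [A·E_bp^(t)(i,m) + B] + Σ_k E_st(i,k)` sums typed
base-pair energies and 5'/3'-polarity-dependent stacking energies over the
pairs and stacks detected geometrically from the coordinates; `E_2D`
credits positions paired in the extracted secondary structure; `A_SAS` is
the Shrake–Rupley accessible surface of the O2' atom probed with a 2.0 Å
bead; `F_sug` corrects for ribose pucker (pseudorotation phase); `F_term`
boosts chain termini; `E_lig` penalizes user-masked ligand-binding
positions. Barred quantities are smoothed over the window
`{i-1, i, i+1, i+2}` with configurable weights. Agreement with an
experimental profile is quantified by the Pearson correlation (PC) and a
noise-adjusted PC computed on log-transformed, inverse-variance-weighted
profiles, respecting the log-normality of SHAPE data.

All model parameters live in a YAML config (`default_params()`,
`read_params()`); the shipped defaults are untrained, sign-correct
placeholders — supply trained values for quantitative work. The methods
vignette (`vignettes/shape-prediction-model.Rmd`) documents every term,
gate and numerical choice.

## A worked example

```r
library(shapesieve)

native <- build_hairpin(4, "GAAA")      # ideal 12-nt hairpin fixture
obs    <- synth_shape(native, noise_sigma = 0.1, seed = 1)

pred <- predict_profile(native)
pred
#> <shape_prediction> hairpin_GCGCGAAAGCGC
#>   12 nucleotides, 4 base pairs (4 canonical), 8 stacking contacts
#>   2D: ((((....))))
#>   reactivity range: [2.669, 28.33]

round(pearson_cor(predicted_profile(pred), obs), 3)
#> [1] 0.994

ensemble <- c(list(native = native),
              setNames(lapply(1:9, function(k) scramble_2d_decoy(native, seed = k)),
                       paste0("decoy", 1:9)))
report <- sieve(ensemble, obs, reference = native)
head(as.data.frame(report), 3)
#>   member_id        pc     na_pc         rmsd rank
#> 1    native 0.9935331 0.9957167 4.830302e-15    1
#> 2    decoy8 0.9261702 0.9172912 2.953053e+00    2
#> 3    decoy5 0.2671990 0.5377946 6.046922e+00    3
```

The stem positions of the hairpin are predicted 3–4× less reactive than
the loop (pairing and stacking suppress reactivity through `exp(SE)`;
buried O2' atoms lower `SF`), and the native structure correlates
near-perfectly with its own noised profile. Decoys sort by structural
similarity: the rank-2 decoy differs from the native by a single stem
register (3 Å RMSD, still-high correlation), while genuinely rearranged
folds drop far down the ranking — the sieve picks the native fold.

A command-line interface wraps the same pipeline:

```sh
Rscript inst/cli/shapesieve.R predict --pdb structure.pdb --shape obs.shape --out results/
Rscript inst/cli/shapesieve.R sieve   --pdb ensemble_dir/ --shape obs.shape \
                                      --reference native.pdb --out results/
Rscript inst/cli/shapesieve.R annotate --pdb structure.pdb --out results/
Rscript inst/cli/shapesieve.R fixtures --kind hairpin --out fixtures/
```

Subcommands: `predict` (feature table, SHAPE-format profile, correlation
report), `sieve` (ranked TSV with optional RMSD column), `annotate`
(pair/stack/geometry tables and dot-bracket), `fixtures` (regenerable test
assets). Every output starts with a version + config-checksum header and
identical inputs give byte-identical outputs.

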