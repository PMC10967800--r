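# hacsurf

Quantitative surface analysis and interpretable classification of **highly
abundant cytoplasmic (HAC) proteins** versus **extracellular proteins** from
predicted 3D structures.

Proteins that are highly expressed in the crowded cytoplasm are under
pressure to avoid nonspecific interactions, misfolding and aggregation, and
their solvent-exposed surfaces are expected to carry measurable signatures
of that adaptation.  `hacsurf` extracts ten physicochemical, structural and
geometrical descriptors from the solvent-accessible surface (SAS) and
solvent-excluded surface (SES) of AlphaFold-style PDB models (single model,
single chain, per-residue pLDDT in the B-factor column) and quantifies each
descriptor's contribution to the HAC/extracellular distinction with an
unpenalized logistic model,

```
ln [ P / (1 - P) ] = beta_0 + sum_i beta_i x_i ,     OR_i = exp(beta_i),
```

where `P` is the probability that a protein is HAC and the `x_i` are the
standardized surface descriptors:

| descriptor | meaning |
|---|---|
| `s_phobic_avg` | mean normalized-consensus hydrophobicity of surface residues |
| `s_pos_area`, `s_neg_area`, `s_charge_avg` | fractions of SAS on Lys/Arg, Asp/Glu, and their sum |
| `s_ah`, `s_bs`, `s_do` | surface fractions of alpha-helix, beta structure, loop/disordered |
| `s_sf` | surface exposure degree: total SAS / protein volume (1/Å) |
| `norm_s_b` | mean normalized pseudo-B-factor of surface residues, from pLDDT via Δ = 1.5·exp[4(0.5 − pLDDT/100)], B = 8π²Δ²/3 |
| `fd` | fractal dimension FD = 2 − d log A_ses / d log R over probe radii 1.0–3.6 Å (2 = smooth, 3 = roughest) |

Every stage is implemented as a tested, reusable function: deterministic
Shrake–Rupley SASA (golden-spiral lattice), a voxel-grid SES estimator
(morphological closing by the probe sphere), the ≥30 % Gly-X-Gly
relative-accessibility surface mask, a simplified Kabsch–Sander secondary
structure assignment, Henderson–Hasselbalch net surface charge,
Pearson/collinearity screening, Cook's-distance outlier removal, repeated
stratified comparison of KNN/RF/SVM/LR with grid-search cross-validation,
and Wald odds-ratio inference.  A synthetic-data module generates ideal
helices, beta-hairpins, random coils, sphere clusters and class-conditional
Gaussian feature tables so that the whole pipeline runs and is validated
without downloading any structure.

## Worked example

Structure side — descriptors for a 120-residue ideal helix (about half a
minute, dominated by the 14-probe SES sweep):

```r
library(hacsurf)
v <- compute_descriptor_vector(
  make_ideal_helix(120, plddt = seq(65, 95, length.out = 120)))
v
#> DescriptorVector helix (120 residues, 85 surface)
#> s_phobic_avg   s_pos_area   s_neg_area s_charge_avg         s_ah         s_bs
#>       0.1607       0.2098       0.2057       0.4155       0.9765       0.0000
#>         s_do         s_sf     norm_s_b           fd
#>       0.0235       1.1911       0.0212       2.0141
#> net_surface_charge: -10.995
```

The helix is read as almost entirely helical (`s_ah` 0.98), very smooth
(`fd` 2.01, near the theoretical minimum of 2), with about 42 % of its
accessible surface on charged residues.

Statistics side — the full training stage on the synthetic benchmark
(668 proteins, class-mean shifts proportional to the published
coefficients, Bayes accuracy calibrated to 80.2 %):

```r
tab <- make_feature_table(hac_benchmark_spec(n_per_class = 334, seed = 7,
                                             full = TRUE))
scr <- pearson_screen(tab[, attr(tab, "descriptors")], tab$label)
scr$result$dropped
#>     descriptor                   reason
#> 1         s_sf nonsignificant_vs_target
#> 2 s_charge_avg    collinear_in_category
#> 3         s_ah    collinear_in_category

x <- tab[, scr$result$kept]
out <- cooks_outlier_removal(x, tab$label)   # 22 rows (3.3 %) removed
x <- x[-out$removed, ]; y <- tab$label[-out$removed]

ev <- compare_models(x, y)                   # 5 seeded 80/20 splits
ev$summary
#>   algorithm mean_accuracy sd_accuracy mean_auc sd_auc
#> 1       knn         0.791      0.0582    0.869 0.0409
#> 2        lr         0.800      0.0428    0.909 0.0375
#> 3        rf         0.802      0.0126    0.891 0.0402
#> 4       svm         0.806      0.0433    0.903 0.0358

wald_report(ev$fits)[, c("descriptor", "beta", "odds_ratio")]
#>               descriptor     beta odds_ratio
#> s_phobic_avg s_phobic_avg -1.41056      0.244
#> s_pos_area     s_pos_area  0.95085      2.588
#> s_neg_area     s_neg_area  1.02288      2.781
#> norm_s_b         norm_s_b -1.06330      0.345
#> s_bs                 s_bs -0.39902      0.671
#> s_do                 s_do -0.00713      0.993
#> fd                     fd -0.47384      0.623
```

The screening reproduces the expected eliminations (`s_sf` insignificant;
the two derived descriptors collinear within their categories), all four
tuned algorithms land near the calibrated 80 % accuracy, and the fitted
coefficient signs recover the generative pattern: both charged-area
fractions push a surface towards HAC, while hydrophobicity, flexibility
(`norm_s_b`), beta structure, disorder and roughness push it away.

`run_extract()` / `run_train()` / `run_pipeline()` orchestrate the same
stages over a directory of PDB files plus a `id,label` manifest CSV, and
`inst/scripts/hacsurf-pipeline.R` wraps them for the shell.

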