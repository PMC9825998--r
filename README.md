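# katpmod

Computational analysis of nucleotide regulation of the ATP-sensitive
potassium (K~ATP~) channel. The K~ATP~ channel — four Kir6.2 pore subunits
plus four SUR1 regulatory subunits — closes when ATP binds an inhibitory
site on Kir6.2 and opens when the membrane lipid PIP₂ binds nearby, coupling
metabolism to electrical activity (and, when mutated, causing neonatal
diabetes). Studying this regulation combines molecular-dynamics ensembles of
the binding sites with patch-clamp fluorometry (PCF), in which channel
current and nucleotide binding (fluorescence quenching of a site-adjacent
ANAP label by TNP-ATP) are measured simultaneously in excised patches.

`katpmod` implements the full analysis chain for such a study, for
electrophysiologists and simulation scientists who want the models and the
corrections in one tested place:

* **Trajectory ensemble statistics** — ligand contact occupancy (heavy-atom
  distance < 4 Å, contacting residues at mean occupancy > 0.4, per
  subunit × repeat), minimum-distance traces with 1 ns running averages,
  hydrogen-bond count distributions (3.5 Å / 30° criterion; k ≤ 3 for
  lysine, k ≤ 5 for arginine donors), per-residue RMSF after superposition,
  pairwise RMSD (Kabsch), and pooled-variance t comparisons.
* **PCF processing** — background subtraction, ANAP band quantification
  (469.5–474.5 nm), single-exponential photobleach correction, Ba²⁺
  zero-current offsets, and bracketed rundown correction producing a tidy
  dose–response table.
* **Dose–response models** — the Hill model with residual current,
  I/I<sub>max</sub> = 1 − I<sub>max</sub> + I<sub>max</sub>/(1 + 10^(h(log₁₀c − log₁₀IC₅₀))),
  and a 4-site Monod–Wyman–Changeux model in which, with x = K<sub>A</sub>·T,
  occupancy = (x(1+x)³ + LDx(1+Dx)³)/((1+x)⁴ + L(1+Dx)⁴) and fractional
  current = L(1+Dx)⁴/((1+x)⁴ + L(1+Dx)⁴) · (1+L)/L; P<sub>open</sub> = L/(L+1).
* **Bayesian fitting** — a built-in No-U-Turn sampler fits the Hill model
  as a mixed-effects model (IC₅₀ varying between patches) and the MWC model
  jointly to current + quenching, with the published priors, the
  4 chains × 4000 iterations / 2000 burn-in protocol, split-chain R̂ and
  effective-sample-size diagnostics, interval summaries and posterior
  IC₅₀ fold-change contrasts.
* **Synthetic data** — ground-truth-labelled Markov switch trajectories,
  H-bond geometries and PCF patch cohorts for end-to-end validation.

## Worked example

Simulate a wild-type-like PCF cohort (8 patches, ATP 1 µM–1 mM, population
IC₅₀ 32.7 µM), reduce it, fit the hierarchical Hill model and contrast a
mutant against it:

```r
library(katpmod)

cfg <- pcf_config(construct_label = "Kir6.2+SUR1", model_kind = "hill",
                  truth = list(log10_ic50 = log10(32.7e-6),
                               between_patch_sd = 0.05, h = 1, imax = 1),
                  concentrations = 10^seq(-6, -3, length.out = 7),
                  n_patches = 8, seed = 7)
pcf <- gen_pcf_dataset(cfg)
tab <- build_dose_response(pcf$recordings)
head(tab, 3)
#>     patch   construct         conc frac_current
#> 1 patch01 Kir6.2+SUR1 1.000000e-06    0.9754696
#> 2 patch01 Kir6.2+SUR1 3.162278e-06    0.9062907
#> 3 patch01 Kir6.2+SUR1 1.000000e-05    0.7685408

fit <- fit_hill_hierarchical(tab, chains = 4, iterations = 2000,
                             burn_in = 1000, seed = 7)
fit
#> <posterior_set> 1000 draws x 4 chains (4000 total), 13 parameters
#>   model: hierarchical_hill; seed 7
#>   max Rhat 1.002, min ESS 2236

summarize_posterior(fit)[1:5, c("param", "median", "lo95", "hi95")]
#>         param  median    lo95    hi95
#>    log10_IC50 -4.4669 -4.5039 -4.4305
#>             h  1.0439  0.9884  1.1095
#>          Imax  0.9912  0.9732  0.9996
#>   sigma_patch  0.0281  0.0021  0.0787
#>     sigma_obs  0.0287  0.0237  0.0355
```

The population median IC₅₀ is 10^−4.4669 M = 34.1 µM — the generating
32.7 µM recovered through the full recording → correction → fitting chain
(the remaining gap is the cohort's own sampling noise). `h` ≈ 1.04 and
`Imax` ≈ 0.99 match the generating slope 1 and full inhibition;
`sigma_patch` ≈ 0.028 estimates the between-patch log₁₀IC₅₀ scatter and
`sigma_obs` ≈ 0.029 the 3% measurement noise.

```r
mut <- gen_hill_table(log10(72.1e-6), n_patches = 6, seed = 8)   # K39R-like
fit_mut <- fit_hill_hierarchical(mut$table, chains = 4, iterations = 2000,
                                 burn_in = 1000, seed = 8)
contrast_fold_change(fit_mut, fit)
#> IC50 fold-change: median 2.02 (95%: 1.7 - 2.38)
```

A mutant generated at 72.1 µM shows a posterior fold-change of ~2.2× truth
(72.1/32.7), here estimated at 2.02 with a 95% interval of 1.7–2.4 —
the shape of a "mutation raises IC₅₀ about two-fold" conclusion.

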