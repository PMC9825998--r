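---
title: "Modelling nucleotide regulation of the KATP channel: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nucleotide regulation of the KATP channel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(katpmod)
```

# Scope

The ATP-sensitive potassium (KATP) channel is an octamer of four Kir6.2 pore
subunits and four SUR1 regulatory subunits. It closes when ATP binds to an
inhibitory site on Kir6.2 and opens when the membrane lipid PIP~2~ binds at
an adjacent site; the balance of the two signals couples cellular metabolism
to membrane excitability, most prominently in pancreatic beta cells.
`katpmod` provides the computational side of a combined simulation and
patch-clamp-fluorometry (PCF) study of this regulation:

* ensemble statistics over molecular-dynamics-style trajectories (ligand
  contact occupancy, minimum-distance traces, hydrogen-bond count
  distributions, per-residue RMSF, pairwise RMSD);
* signal processing that reduces raw PCF recordings (currents plus emission
  spectra) to tidy dose-response tables;
* the two dose-response models — a hierarchical Hill model and a four-site
  Monod-Wyman-Changeux (MWC) model — and fully Bayesian fitting for both,
  with convergence diagnostics and posterior fold-change contrasts;
* a synthetic-data module that generates ground-truth-labelled trajectories,
  hydrogen-bond geometries and PCF cohorts, so every analysis can be
  validated against a known generating process.

The package analyses trajectories; it does not run molecular dynamics, and
the trajectory fixtures are minimal pseudo-molecular systems rather than
proteins — the analyses under test are geometric, and controlled ground
truth matters more than chemical realism.

# Trajectory analyses

A `trajectory_ensemble` is an atom table (with chain, residue and a
`role` of protein / ATP ligand / PIP2 ligand), frame times in ns and
coordinates in Å. Analyses operate on an *analysis window*: by default the
frames with `t > discard_ns`, so that analysing the final 300 ns of a 380 ns
trajectory keeps exactly the frames after 80 ns.

**Contact occupancy** is the fraction of window frames in which a residue's
heavy atoms approach the ligand to strictly less than 4 Å. Both conventions
are deliberate: contacts are conventionally defined over heavy atoms, and
the strict inequality mirrors the "< 4 Å" phrasing used when the quantity is
reported. A residue is called *contacting* when its mean occupancy over all
(subunit × repeat) data points strictly exceeds 0.4. With four subunits and
three repeat simulations each residue contributes 12 data points
(`per_subunit_table()`), which are compared between conditions with a
classical pooled-variance unpaired t-test (`compare_groups()`, significance
flagged at p < 0.01, 95% confidence interval of the mean difference
reported). Each ligand molecule is assigned to the subunit chain it shares
an identifier with, or failing that to the chain whose reference residues it
contacts most often.

**Hydrogen bonds** use the common geometric criterion: donor-acceptor
distance at most 3.5 Å and hydrogen-donor-acceptor angle (vertex at the
donor) at most 30 degrees; both cutoffs are configurable because the source
analyses do not state theirs. Count distributions are reported for
k = 0..3 for lysine-like donors (a single ammonium can donate at most three
bonds) and k = 0..5 for arginine-like donors (a guanidinium spreads up to
five bonds over three amine groups).

**RMSF** is computed after superposing every window frame onto the
window-mean structure by least-squares rigid-body fit over the same
selection — this removes global drift; the choice of the mean structure as
reference is ours, since no fitting reference is stated wherever RMSF
figures are reported. **Pairwise RMSD** superposes every frame pair
independently (Kabsch, SVD) rather than fitting to a single reference,
matching the "pairwise" naming; the matrix is symmetric with a zero
diagonal and is invariant to rigid motion of any frame. The implementation
is validated in the test suite against bio3d's independent least-squares
superposition.

**Running averages** over distance traces use non-overlapping 1 ns block
means with timestamps at block centres. "Running averages of every 1 ns" is
ambiguous between block and sliding means; block means are the default and
a centred sliding window is available via `sliding = TRUE`.

# PCF signal processing

Recordings are reduced patch by patch (`build_dose_response()`):

1. the zero-current offset is the plateau mean (final half) of the terminal
   Ba^2+^ application, which blocks all KATP current; when no Ba^2+^ segment
   exists and only currents are analysed, the offset is 0;
2. each application's current is summarised as the mean of its final 50%
   (a steady-state window; the summary statistic is not stated in the source
   protocols, and the final half is a conservative choice);
3. each test application is expressed as a fraction of the bracketing
   nucleotide-free controls, `mean(test) / mean(mean(pre), mean(post))`.
   Bracketing cancels multiplicative rundown to first order: at 5% rundown
   per application the residual error is below 1%. Fractions above 1
   (activation artefacts) are preserved;
4. spectra are background-subtracted pointwise, the ANAP band is the mean
   intensity between 469.5 and 474.5 nm (inclusive), and bleaching is
   corrected by dividing out a single-exponential decay fitted to the
   zero-nucleotide exposures (nonlinear least squares via minpack.lm, with
   a log-linear fit for initialisation; flat controls yield an identity
   correction). Fractional quenching is 1 minus the corrected band
   intensity normalised to the nearest-in-time corrected control exposure —
   "nearest in time" is our resolution of an unstated normalisation;
5. an optional GFP-crosstalk correction subtracts a configurable fraction
   of the 505-515 nm band from the ANAP band. The coefficient defaults to 0
   because the exact correction formula lives in prior work that this
   package does not reproduce.

# The dose-response models

**Hill.** Fractional current at nucleotide concentration c is
$$I/I_{max} = 1 - I_{max} + \frac{I_{max}}{1 + 10^{\,h(\log_{10} c - \log_{10} IC_{50})}},$$
with the zero-concentration limit handled exactly. `Imax` is the maximal
inhibited fraction, so `1 - Imax` is the residual current at saturation.

**MWC.** A concerted two-conformation model with four independent,
equivalent nucleotide sites. With $x = K_A T$:
$$F/F_{max} = \frac{x(1+x)^3 + LDx(1+Dx)^3}{(1+x)^4 + L(1+Dx)^4}, \qquad
I/I_{max} = \frac{L(1+Dx)^4}{(1+x)^4 + L(1+Dx)^4}\cdot\frac{1+L}{L}.$$
`L` is the open/closed equilibrium constant (ligand-free open probability
L/(L+1), `popen()`); `KA` is the per-site association constant of the
closed state; each bound ligand favours the closed state by the factor
`D` ≤ 1, equivalently the open state binds with the reduced affinity
`D·KA`. F/F~max~ is read as fractional quenching equal to fractional site
occupancy — quenching of the site-adjacent ANAP fluorophore is taken as
directly proportional to TNP-ATP binding — and therefore rises from 0 to 1.
Both functions are verified in the tests against an independent 10-state
partition-function enumeration (2 conformations × 0-4 ligands with binomial
degeneracy) to 1e-10, including the limits occupancy(0) = 0, current(0) = 1
and the D = 1 reduction to independent-site binding with gating decoupled.
Note that the saturation plateau is approached at first order in 1/(Dx).

# Bayesian inference

## Priors

Exactly the stated fitting protocol, with scale entries read as standard
deviations (the convention of the source fitting framework, where a prior
printed as "σ2: 0.3" is a `normal(1, 0.3)` density):

* Hill: h ~ Normal(1, 0.3), Imax ~ Uniform(0, 1),
  log10 IC50 ~ Normal(−4, 1);
* MWC: log10 L ~ Normal(0, 0.7), log10 KA ~ Uniform(2, 6), D ~ Uniform(0, 1).

The protocol does not state priors for the between-patch scatter of
log10 IC50 or for the observation-noise SDs; both receive half-Normal(0, 0.1)
priors — weakly informative on the scales actually observed (fractional
currents of order 1, patch scatter of a few hundredths of a log10 unit).

## The hierarchical Hill model

Within a construct, the population parameters (log10 IC50, h, Imax) are
shared and the log10 IC50 varies between individual excised patches as a
Normal random effect with estimated scale — a mixed-effects dose-response
model. Whether h and Imax were pooled across constructs is not stated;
each construct is fitted separately.

Sampling uses a No-U-Turn sampler written for this package: multinomial
trajectory sampling, dual-averaging step-size adaptation (target acceptance
0.8) with a ±10% per-iteration step-size jitter, and Stan-style windowed
estimation of a dense covariance metric during burn-in. The default
protocol is 4 chains × 4000 iterations including 2000 burn-in, retaining
exactly 8000 draws.

By default (`method = "marginal"`) the patch random effects are integrated
out with 48-node Gauss-Hermite quadrature, so NUTS samples only the five
population-level parameters with exact analytic gradients; per-patch
log10 IC50 draws are then reconstructed exactly by inverse-CDF sampling of
each patch's one-dimensional conditional density on a fine grid (201 points
over ±6 standardised units, with within-cell jitter). This removes the
funnel geometry that makes jointly sampled hierarchical scales mix slowly.
`method = "joint"` samples the non-centred joint posterior directly; the
test suite checks that the two agree, which also validates the quadrature
(48 nodes comfortably resolve the conditional widths that arise here — the
per-patch likelihood in standardised units is never narrower than ~0.2).

Diagnostics are the classic split-chain potential scale reduction statistic
(the rank-normalised variant is not used; the classic form is assumed) and
autocorrelation-based effective sample size with Geyer's initial monotone
sequence, combined across chains. A fit with any Rhat > 1.05 is returned
flagged with a warning, never silently. Contrasts between constructs
subtract the full control posterior from the mutant posterior on the
log10 scale, draw by draw, and report 10^difference — the fold-change in
IC50 — summarised with 50/80/95% central intervals.

## The joint MWC fit

Current inhibition and fluorescence quenching share (L, KA, D); each
observable has its own Gaussian noise SD, so the two likelihood terms are
weighted by their estimated precisions rather than by a fixed ratio (the
source protocol does not state a weighting). Zero-concentration rows enter
through the exact zero-ligand limits; no logarithm of concentration is
taken inside the model functions.

## Numerical choices

* Observation-noise SDs are parameterised as `floor + exp(free)` with
  `sigma_floor = 1e-4` by default. Without a floor, a zero-noise dataset
  makes the posterior non-integrable as σ → 0. For deliberately noise-free
  round-trip fits the tests raise the floor to 0.01 — the posterior at a
  1e-4 floor is extremely stiff (curvatures spanning eight orders of
  magnitude) and slow to traverse, while the recovery tolerance (5%) is two
  orders of magnitude above either floor.
* Bounded parameters are sampled on logit scales and positive scales on log
  scales, with Jacobians; the Hill gradient uses the overflow-safe identity
  u/(1+u)² = w(1−w), w = 1/(1+u).
* Before the first metric update the tree depth is capped at 6: with an
  identity metric a sharply scaled posterior would otherwise force 1024-step
  trajectories; this affects only adaptation speed, never retained draws.
* Chains run sequentially with per-chain seeds derived from the user seed;
  identical seeds give identical draws.

# The synthetic-data module

The generators define the validation conditions:

* **Two-site switch trajectories** emulate a side-chain (such as Kir6.2's
  K39) oscillating between coordination with ATP and PIP~2~: one mobile
  particle per subunit follows a two-state Markov chain over two ligand
  sites with isotropic Gaussian positional noise, with static ligand
  pseudo-atoms marking the sites. The analytic stationary distribution
  (1−p22)/((1−p11)+(1−p22)) is the oracle for occupancy recovery; standard
  errors account for chain autocorrelation via (1+ρ)/(1−ρ), ρ = p11+p22−1.
  Defaults (4 subunits, 3 repeats) reproduce the 12-points-per-residue
  layout of tetramer analyses.
* **H-bond fixtures** place donor/hydrogen/acceptor triplets on mutually
  orthogonal axes so that exactly the requested number satisfy the
  detection criterion per frame (active acceptors at 3.0 Å in line with
  their hydrogen, inactive at 5.0 Å); orthogonality guarantees no
  cross-axis pair can satisfy the 30° angle cutoff, so true counts are
  exact by construction.
* **PCF cohorts** draw per-patch log10 IC50 values from
  Normal(population, between-patch SD) in Hill mode (h and Imax shared, as
  in the fitting protocol) and emit alternating control/test applications
  with multiplicative rundown per application, per-application amplitude
  jitter (the dominant noise on a fractional-current measurement) plus
  small additive sample noise, and — in MWC mode — per-application emission
  spectra with an ANAP peak at 470 nm scaled by (1 − occupancy), a GFP peak
  at 510 nm, a sloping background, single-exponential ANAP photobleaching
  and a terminal Ba^2+^ application. The GFP peak is truncated below
  490 nm, mimicking GFP's sharp blue emission edge; consequently the ANAP
  band is crosstalk-free and zero-noise datasets round-trip exactly, which
  is what makes the processing chain testable to 1e-9. Raw noise magnitudes
  and rundown rates are not reported in the source protocols; the defaults
  (3% amplitude jitter, 2% rundown per application, 60 s bleach constant)
  are our choices of realistic values and are stated in the config, not
  presented as published numbers.

What passing these tests does *not* show: the fixtures have no force
fields, no membrane, no periodic boundary conditions, no correlated
multi-residue motions, and the PCF generator's noise is Gaussian and
uncorrelated across applications. Conclusions about real trajectories and
recordings rest on the correctness of the analysis definitions, which is
what the oracle tests establish.

# Validation experiment sizes

The test suite uses Markov fixtures of 3000-6000 frames × 12 chains, 1000
frames for the RMSF convergence check, 80-frame H-bond fixtures, and
reduced MCMC protocols (2 chains × 600-1500 iterations) for recovery and
coverage checks, with the full 4 × 4000 protocol exercised once against the
published wild-type interval. The coverage experiment uses 20 replicate
cohorts of 8 patches at 3% noise and requires the 95% interval to cover the
generating log10 IC50 in at least 17.

# Known limitations

* The population IC50 posterior median inherits a small (~4%) downward
  shrinkage when the generating Imax lies exactly on the Uniform(0, 1)
  prior boundary, because the posterior median of Imax is then necessarily
  below 1; this is a property of the stated model and priors, not of the
  sampler.
* With 8 patches and a boundary-sitting Imax, the effective sample size of
  the slowest population parameters is around half the retained draws;
  protocols demanding a higher minimum ESS need either more iterations or
  data that identify Imax away from its bound.
* The crosstalk correction is a coefficient subtraction, off by default;
  the quantitative correction used with real spectra lives in prior work.
* XTC/DCD binary trajectories are out of scope; multi-model PDB (and the
  in-memory constructor) are the supported routes in.
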