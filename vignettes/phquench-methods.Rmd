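---
title: "Models and methods behind phquench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phquench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phquench)
```

# Scope

`phquench` reconstructs, as reusable and tested code, the analysis chain
that connects protonation dynamics in the lumen-exposed face of a
stress-related light-harvesting complex (LHCSR1 of *Physcomitrella
patens*) to its photophysical fate: which acidic residues sense lumen pH,
which joint protonation microstates (pMSs) of the coupled E114/E227/E233
triad dominate at each pH, how those microstates reshape the
conformational landscape of the C-terminal domain, and how the resulting
geometries of the L1 lutein / chlorophyll *a*612 pair translate into
excitonic couplings, Marcus charge-separation rates, and the mean
excitation lifetime of the complex.

The raw inputs of such a study — microseconds of constant-pH MD (CpHMD),
tens of microseconds of Gaussian-accelerated MD (GaMD), and QM/MM
ensembles — are cluster-scale objects. The package therefore ships a
first-class synthetic-data module that generates every input with known
ground truth, so that each stage of the analysis can be validated against
an exact oracle.

# The coupled-titration generator

The generator represents a set of titratable acids as an Ising-like
binary model. With $s_i = 1$ for a protonated site (the "P" label) and
$d_i = 1 - s_i$, the dimensionless microstate energy in units of
$k_B T \ln 10$ is

$$E(s) = \sum_i d_i\,(\mathrm{p}K_{a,i}^{\mathrm{int}} - \mathrm{pH})
       + \sum_{i<j} w_{ij}\, d_i d_j .$$

For a single uncoupled site this reproduces Henderson–Hasselbalch
exactly: the protonated fraction is $1/(1 + 10^{\,\mathrm{pH} -
\mathrm{p}K_a})$. A positive $w_{ij}$ penalises joint deprotonation of a
pair, which produces the proton-sharing (anticorrelated) pattern seen for
strongly hydrogen-bonded acid pairs; a negative $w_{ij}$ favours
correlated protonation. Nothing in the source analysis prescribes a
generative model for coupled titration, so the simplest exactly solvable
pairwise model was chosen: `exact_titration()` enumerates all $2^N$
microstates and is the ground truth for every titration test, while
`simulate_coupled_titration()` runs single-flip Metropolis Monte Carlo
(one attempted flip per recorded frame, mirroring the periodic
single-exchange attempts of discrete CpHMD). The magnitude of $w_{ij}$ is
a fixture parameter, not an inference target.

Frames are nominally spaced by `dt_ps = 100` ps, so that the 10-ns
windowing and blocking granularity used throughout corresponds to 100
frames; this is a bookkeeping convention of the generator, since only
frame counts enter the estimators.

# Titration analysis

`fit_hill()` fits the protonated fraction to

$$f(\mathrm{pH}) = \frac{1}{1 + 10^{\,n\,(\mathrm{pH} - \mathrm{p}K_a)}},$$

a decreasing function of pH with Hill coefficient $n > 0$. The fit is a
bounded least-squares problem ($n \in (0, 10]$, $\mathrm{p}K_a \in [0,
14]$) solved with `optim(method = "L-BFGS-B")` from an initial guess that
places the p$K_a$ at the half-maximum crossing. Whether the original
analysis fitted the protonated or the deprotonated fraction is not
documented; the decreasing-protonation convention is adopted here and the
sign of $n$ must be read accordingly.

Two degeneracies return `converged = FALSE` instead of an estimate: flat
curves (fraction range below 0.05) and nonmonotonic curves, flagged when
any increase between consecutive pH points exceeds twice its pooled
bootstrap error. The latter is the signature of a strongly coupled site
(the "up-and-down" E114 case), for which a single-site p$K_a$ is not
defined; `classify_sensor()` reports such sites as
`coupled_undetermined`. Sensor candidates are residues whose fitted
p$K_a$ is upshifted by more than one unit from the water reference of
their class (Glu 4.3, Asp 3.9).

Errors are blocked-bootstrap errors: whole contiguous blocks (default 100
frames = 10 ns) are resampled with replacement within each pH trajectory,
fractions and Hill fits are recomputed per replicate, and two times the
replicate standard deviation is reported. Blocking corrects for the
autocorrelation of the occupancy series; the tests verify both the
i.i.d. limit (block length immaterial) and the correlated case against
the closed-form variance of the mean of an indicator of a Gaussian AR(1)
process.

# Protonation-microstate networks

`encode_microstates()` maps each frame to a k-letter P/D string over the
declared triad order. `estimate_network()` counts transitions at a fixed
lag over all sliding frame pairs and row-normalises; populations are
empirical visit frequencies rather than the stationary eigenvector,
because finite simulations are what the plots describe (the eigenvector
is exposed via `stationary_distribution()` and used as a cross-check for
reversible chains). The full $2^k$ alphabet is retained: never-visited
states keep a self-transition of one and zero population. The lag is not
documented in the source analysis; the default is one windowing unit (100
frames = 10 ns), configurable. Independent replicas may be passed as a
list, in which case counts are merged before normalisation (merged-counts
default). Chapman–Kolmogorov consistency, $\hat T(2\tau) \approx \hat
T(\tau)^2$, is tested on synthetic Markov chains.

# Conformational landscape

`fit_tica()` estimates symmetrised instantaneous and lagged covariances,
applies a ridge $10^{-6}\,\mathrm{tr}(C_0)/p$ to $C_0$ (sin/cos dihedral
features are near-collinear) and solves $C_\tau v = \lambda C_0 v$ by
Cholesky whitening; components are $C_0$-orthonormal, so training
projections have unit variance. The tests require agreement with a dense
non-symmetric generalized-eigensolver oracle to $10^{-8}$ and invariance
of the eigenvalues under invertible feature re-parameterisations.

`cluster_density()` is an in-package implementation of HDBSCAN (core
distances at `min_samples`, mutual-reachability minimum spanning tree,
single-linkage hierarchy, condensation at `min_cluster_size`,
excess-of-mass selection) — no density-based clustering package is part
of this R stack, and the algorithm is small enough to implement and test
directly. Single-cluster selection at the root is disabled, so pure
uniform noise yields zero clusters and all points carry the noise label
`-1`. Labels are deterministic given inputs; tests compare partitions up
to label permutation only. The default `min_cluster_size` of 0.5% of the
frames yields single-digit cluster counts on fixtures sized like the
analysis it emulates. Distances are dense, so the intended regime is up
to a few thousand projected frames.

`reweight_pmf()` recovers unbiased free energies from boosted sampling by
the second-order cumulant expansion,

$$F(\mathrm{bin}) = -k_B T\left[\ln p_{\mathrm{biased}} +
  \beta\langle\Delta V\rangle + \tfrac{1}{2}\beta^2
  \sigma^2_{\Delta V}\right] + C,$$

with $C$ fixing the minimum over reliable bins (count $\ge$ `n_min`,
default 10) to zero. The expansion is exact when the boost is Gaussian
within a bin — the premise of this estimator — and the zero-boost limit
reduces identically to the histogram free energy. The validation fixture
samples a double well $F(x) = 3(x^2-1)^2$ kcal/mol (a $\approx 5\,k_BT$
barrier at 300 K) under a well-filling boost on the support
$x \in [-1.5, 1.5]$, sized so that with $2\times10^5$ frames every
reliable bin holds several hundred samples: the maximum absolute error
then measures reweighting accuracy ($\approx 0.2\,k_BT$) rather than the
Poisson noise of border bins that barely clear `n_min`.

`stratified_sample()` reproduces the composition-preserving selection of
representative frames: per cluster, counts are allocated to pMS strata by
largest-remainder rounding of composition × n and drawn without
replacement within each stratum. `representative_frame()` selects the
frame closest to the cluster mean in projection space, ties going to the
lowest frame index.

# Geometric observables

`build_chlorin_frame()` anchors a right-handed orthonormal frame on a
chlorophyll: origin at Mg, $z$ normal to the least-squares plane of the
four ring nitrogens, $x$ along the in-plane projection of a designated
N→N direction (default: first to third nitrogen in input order — the
atom naming is a convention of the caller and is recorded in the
output), $y = z \times x$. The in-plane sign of displacements therefore
depends on the chosen nitrogen ordering. All observables are tested to be
invariant under global rigid motions to $10^{-8}$ Å.

`coverage_ellipse()` scales the mean-centred covariance ellipse by the
$\chi^2_2$ quantile at the requested coverage (0.40 by default), so the
isotropic unit Gaussian has semi-axes $\sqrt{-2\ln 0.6} \approx 1.011$;
empirical containment is verified by Monte Carlo. `bla()` is the mean
single-bond minus mean double-bond length along a declared conjugated
chain.

# Couplings and kinetics

`tresp_coupling()` evaluates the TrEsp point-charge Coulomb sum
$V_{\mathrm{raw}} = K_e \sum_{ij} q_i q_j / r_{ij}$ with $K_e = 116140$
cm$^{-1}$ Å e$^{-2}$ (vacuum; environment screening is absorbed into the
empirical rescale factor). The conventional factor of 3.7 used for
carotenoid–chlorophyll pairs is applied as a division (attenuation) by
default; the direction of the rescaling is not stated where the factor is
introduced, so the convention is an explicit argument and is recorded in
the outputs. The far field converges to the transition-dipole interaction
computed from the same charges, within 1% at ten times the molecular
extent.

`linear_response()` estimates reorganization energies from
vertical-energy fluctuations, $\lambda_X = \sigma^2_X / (2 k_B T)$, free
energies $G_X = \langle E_X\rangle - \lambda_X$, and the driving force
$\Delta G = G_{CT} - G_{LE}$; the effective LE→CT reorganization energy
is taken as $\sigma^2(\Delta E_{CT,LE})/(2k_BT)$ on paired samples, by
direct analogy with the per-state expression. `marcus_rate()` is the
standard high-temperature nonadiabatic form

$$k = \frac{2\pi}{\hbar} V^2 (4\pi\lambda k_B T)^{-1/2}
      \exp\!\left[-\frac{(\Delta G + \lambda)^2}{4\lambda k_B T}\right],$$

with $\hbar = 5.3088\times10^{-12}$ cm$^{-1}$ s and $k_B = 0.6950348$
cm$^{-1}$ K$^{-1}$; all spectroscopic quantities are in cm$^{-1}$, rates
in s$^{-1}$, lifetimes in ps.

The lifetime model is deliberately coarse: a pool of `n_pool` = 8
chlorophylls in fast excitonic equilibrium, the quencher carrying weight
`p_quencher` = 1/8 (isoenergetic equilibrium; Boltzmann weights can be
supplied when site energies are known), charge separation from the
quencher at $p\,k_{cs}$, recombination of the CT state at $(10\,
\mathrm{ps})^{-1}$, and intrinsic decay at $(4\,\mathrm{ns})^{-1}$ — a
typical chlorophyll *a* fluorescence decay, chosen because the intrinsic
rate used in the original kinetic model is not printed. Back transfer is
on by default and closed by detailed balance, $k_{back} = k_{cs}
e^{\Delta G / k_B T}$; the irreversible scheme (`k_back = 0`) is exposed
because which variant produced the published lifetime table is not
stated. The mean excitation lifetime is the closed-form survival
integral $\tau = \mathbf 1^\top (-A)^{-1} p_0$ of the 2×2 master
equation, verified against numerical integration to $10^{-6}$ relative.

# The demo pipeline and what it does (and does not) show

`run_pipeline()` executes the whole chain on synthetic data from a
single YAML config (`demo_config()`), with every stage seeded from one
master seed by fixed offsets; reruns are byte-identical. The demo
conditions mirror the study design at reduced size: 6 pH values (3–8),
two replicas of 2000 frames per pH for the eight-residue site model, a
10-ns (100-frame) block and lag unit, four carried pMSs with two
enhanced-sampling replicas of 400 frames each over six features, boost
statistics $\langle\Delta V\rangle = 26.0$, $\sigma_{\Delta V} = 6.8$
kcal/mol, 30 stratified samples per cluster, and 30 vertical-energy
samples per cluster with LE/CT means near 15.6/20.7 × 10³ cm$^{-1}$ and a
larger CT spread, so that the fluctuation-based $\lambda$ and $\Delta G$
fall in the physically expected range. The demo's intrinsic p$K_a$
values place the uncoupled residues at their reported effective values
and give the coupled triad a positive E114–E227 interaction (proton
sharing) — enough for E114 to show the characteristic nonmonotonic curve
and be flagged `coupled_undetermined`.

Passing tests on these fixtures demonstrate that the estimators are
correct on data satisfying their assumptions (binary Metropolis
titration, Gaussian boosts and energies, genuinely Markov chains,
well-separated density modes). They do not demonstrate force-field
accuracy, CpHMD/GaMD convergence, or the validity of the electronic
structure inputs — those live upstream of this package's contract, which
starts at protonation/feature/energy time series and transition charges.

# Numerical choices

* Ridge on $C_0$: $10^{-6}\,\mathrm{tr}(C_0)/p$; tICA eigenvalue
  invariance is tested with ridge $\to 0$.
* PMF binning: 50 × 50 uniform bins over the occupied range (40 in the
  demo config); `n_min = 10` frames per reliable bin.
* Hill optimiser: L-BFGS-B with `factr = 10`, `pgtol = 1e-12`; noiseless
  self-consistency to $|\Delta \mathrm{p}K_a| < 10^{-6}$.
* Ties: dominant microstates break population ties alphabetically;
  representative frames break distance ties by lowest index;
  largest-remainder allocation breaks remainder ties by stratum name.
* Degenerate inputs: flat titration curves and all-noise clusterings are
  reported as such (flag / warning), never as estimates.

# Known limitations

* The clustering uses dense distance matrices (O(n²) memory): projected
  sets beyond ~5000 frames should be subsampled.
* No multi-site Hill models; coupled sites are *flagged*, not fitted.
* Free energies are limited to 1-D/2-D cumulant reweighting; no kinetic
  models are built on tICA space.
* The eight-chlorophyll exciton treatment is out of scope; the lifetime
  model is the two-state coarse graining described above.
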