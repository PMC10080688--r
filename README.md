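# phquench

Light-harvesting complexes of the LHCSR family switch photoprotective
quenching on and off in response to thylakoid-lumen pH. Connecting that
switch to molecular detail requires a long analysis chain: constant-pH MD
gives per-residue protonation time series, which become titration curves,
pKa values and protonation microstates; enhanced-sampling MD of the
relevant microstates gives conformational ensembles, which become
free-energy landscapes and representative structures; and QM/MM
calculations on those structures give the couplings and energetics that
set charge-separation rates and excited-state lifetimes.

`phquench` implements that chain as tested, reusable R code, aimed at the
LHCSR1 L1-lutein / chlorophyll *a*612 quenching site but agnostic to the
specific protein. Because the raw trajectories behind such a study are
cluster-scale, the package also ships a synthetic-data module that
generates every input with known ground truth, so each estimator is
validated against an exact oracle.

## What is implemented

* **Titration** — protonation fractions, Hill fits of
  `f(pH) = 1/(1 + 10^{n (pH − pKa)})` by bounded least squares,
  blocked-bootstrap errors (2 × SE), and pH-sensor classification against
  the water references Glu 4.3 / Asp 3.9. Nonmonotonic ("up-and-down")
  curves of coupled residues are flagged rather than fitted.
* **Microstates** — P/D encoding of a residue triad, windowed-fraction
  correlation coupling, and Markov transition networks with empirical
  populations (Chapman–Kolmogorov-tested).
* **Landscape** — tICA by generalized eigendecomposition, an in-package
  HDBSCAN with noise labels, GaMD-style free-energy reweighting by
  second-order cumulant expansion, composition-preserving stratified
  sampling and representative-frame selection.
* **Structure** — chlorin-fixed reference frames, in-plane
  center-of-mass displacements, chi-square coverage ellipses, bond-length
  alternation.
* **Coupling** — TrEsp point-charge excitonic couplings
  (`K_e = 116140 cm⁻¹ Å e⁻²`) with the empirical 3.7 rescale factor.
* **Energetics** — linear-response reorganization energies
  `λ = σ²/(2 k_B T)`, driving forces `G_X = ⟨E_X⟩ − λ_X`, nonadiabatic
  Marcus rates
  `k = (2π/ħ) V² (4πλk_BT)^{−1/2} exp(−(ΔG+λ)²/4λk_BT)`,
  and a coarse-grained two-state excitation-lifetime model with
  detailed-balance back transfer.
* **Synthetic data** — exactly solvable Ising-like coupled titration,
  Gaussian vertical-energy series, boosted samples from known
  free-energy surfaces, toy pigment pairs, and feature matrices with
  per-frame boost records.
* **Pipeline** — `run_pipeline()` drives all stages from one YAML config
  with a single master seed; reruns are byte-identical.

## Worked example

Simulate coupled-titration data for an upshifted glutamate, fit its
titration curve with blocked-bootstrap errors, and classify it:

```r
library(phquench)

m <- site_model(c("E227", "D118"), c("GLU", "ASP"), pKa_int = c(5.7, 4.7))
trajs <- lapply(3:8, function(ph)
  simulate_coupled_titration(m, ph, n_frames = 2000, seed = 40 + ph))
fit <- blocked_bootstrap_pka(trajs, "E227", block_length = 100,
                             n_boot = 1000, seed = 1)
fit
#> hill_fit: pKa = 5.747 +/- 0.0437, n = 1.003 +/- 0.0779
classify_sensor(fit, "GLU")
#> [1] "sensor_candidate"
```

The fitted pKa (5.75 ± 0.04) recovers the generator's ground truth of
5.7 within its 2-sigma bootstrap error, and the residue is classified as
a pH-sensor candidate because its pKa is upshifted by more than one unit
from the Glu water reference of 4.3.

Charge-separation rates and complex lifetimes for two conformational
clusters sharing one (λ, ΔG) set — the rate ratio is exactly the
coupling ratio squared:

```r
rate_table(c(CL2 = 292, CL5 = 199),
           list(screened = list(lambda = 2500, deltaG = -400)))
#>  cluster      set V_cm1 lambda_cm1 dG_cm1    kcs_per_s   tau_ps
#>      CL2 screened   292       2500   -400 4.756381e+12 23.35125
#>      CL5 screened   199       2500   -400 2.209109e+12 25.27197
```

The full synthetic demonstration (titration → microstate networks →
tICA/clustering/PMF → geometry → couplings → rates) runs in well under a
minute:

```r
res <- run_pipeline(demo_config(), "demo_run")
res$fits           # pKa table with sensor classes
res$dominant       # dominant microstate per pH
res$rates          # cluster-by-set rate and lifetime table
```

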