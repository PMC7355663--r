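# melbind

Drug binding to melanin from two assays, extrapolated to pigmented
tissue.

Melanin in the retinal pigment epithelium and choroid (RPE-choroid)
binds many small-molecule drugs nonspecifically and at high capacity.
Because human RPE-choroid holds roughly 35 mg/mL of melanin — far above
any in vitro assay — even a weak bench-top binder can be mostly
melanin-bound in the eye, which drives ocular drug retention, exposure,
and dosing intervals. `melbind` implements the analysis chain that turns
raw binding assays into an in vivo melanin-binding classification, for
pharmacokinetics and drug-discovery scientists working with pigmented
tissues.

## What it computes

**MST dissociation constants.** Microscale-thermophoresis dilution
series are reduced to dose–response points (hot/cold window selection by
signal-to-noise, normalized fluorescence `Fnorm = F̄_hot / F̄_cold`,
automatic fallback to initial-fluorescence mode when ligand changes the
pre-heating counts) and fitted with the quadratic ligand-depletion
model — with `s = c + c_t + K_d`:

    f_b(c) = (s − sqrt(s² − 4 c c_t)) / (2 c_t),   F(c) = U + (B − U) f_b(c)

needed because the melanin target (12.5 µM) sits inside the tested
ligand range. Fits report a 68% confidence half-width (asymptotic 1σ)
and flags (`no_binding`, `wide_ci`, `low_snr`) instead of silent
failures.

**Sips isotherm parameters.** Equilibrium supernatant-depletion data are
converted to bound amounts `B = (c_tot − c_free)/c_mel` (nmol/mg) and
fitted with the Sips (Langmuir–Freundlich) isotherm

    B(L) = B_max L^n / (K_d^n + L^n),   0 < n ≤ 1.5,

with variance-consistent measurement weighting by default.

**Tissue extrapolation and classification.** The mass balance
`c_tot = L + m·B(L)` is solved for the free concentration at any melanin
level (34.8 mg/mL for human RPE-choroid), literature fractions are
rescaled with the dilution equation `fu' = 100/(D(100/fu − 1) + 1)`
(with cassette-dosing correction where needed), and compounds are binned
into four classes: extreme (Kd < 6.5 µM / fu < 0.1%), high (6.5–65 µM /
0.1–1%), intermediate (65–650 µM / 1–10%), low (> 650 µM / > 10%).

**Cross-method statistics.** Target-capacity/Kd ratios, Spearman rank
correlation with exact permutation p-values at small n, and the
through-origin regression of MST Kd on predicted in vivo unbound
fraction that the class limits derive from.

**Synthetic assays.** A seeded generator emulates both assays
(exponential thermophoresis traces, noisy supernatant pairs) so fitters
are validated by parameter-recovery simulation.

## Worked example

Fit a dissociation constant from a (here synthetic) MST series with a
true Kd of 30 µM:

```r
library(melbind)
cfg <- synth_config(true_kd = 30, noise_cv = 0.03, seed = 42)
fit <- fit_kd(generate_mst_series(cfg, n_replicates = 3)$series)
fit
#> MST Kd fit (ligand-depletion model)
#>   mode      : mst
#>   Kd        : 33.56 ± 4.1 uM (68% CI)
#>   signals   : unbound 0.9999, bound 0.6917
#>   SNR       : 24.5
```

The fitted Kd (33.6 ± 4.1 µM) covers the simulated truth within its 68%
interval; the mode tells you thermophoresis (not initial fluorescence)
was analysed, and the SNR is the achieved signal-to-noise of the chosen
hot window.

Re-run the published screening analysis from the packaged parameter
tables:

```r
res <- reproduce_screening_analysis()
res$predictions
#> # A tibble: 11 × 6
#>    compound     method            fu_vitro_pct fu_vivo_pct class_traditional class_mst
#>  1 Chloroquine  sips_mass_balance        0.413     0.00117 extreme           extreme
#>  2 Terazosin    sips_mass_balance        2.80      0.0113  extreme           high
#>  3 Levofloxacin sips_mass_balance       28.6       0.345   high              high
#>  4 Propranolol  sips_mass_balance       31.9       0.897   high              intermediate
#>  5 Papaverine   sips_mass_balance       15.2       0.131   high              high
#>  6 Nadolol      sips_mass_balance       77.7       8.01    intermediate      intermediate
#>  7 Timolol      sips_mass_balance       70.6       5.69    intermediate      intermediate
#>  8 Atropine     dilution_equation       59         3.97    intermediate      low
#>  9 Methotrexate dilution_equation       98        58.5     low               low
#> 10 Quinidine    dilution_equation       16         0.544   high              intermediate
#> 11 Penicillin G dilution_equation        9.2       0.290   high              extreme
res$comparison$rho        # 0.8928571  (Spearman, p = 0.0123)
res$regression$slope      # 64.7 uM per percent unbound
res$regression$kd_limits  # 647, 64.7, 6.47 uM class limits
```

Each row is one compound: the unbound fraction at the in vitro reference
(1 mg/mL melanin) and predicted in human RPE-choroid (34.8 mg/mL), the
route used (mass balance on Sips parameters at 1 µM total, or dilution
scaling of a literature fraction), and the binding class from each
method. Chloroquine, for instance, is 0.41% unbound in vitro but only
0.0012% unbound in vivo — an extreme binder by both methods.

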