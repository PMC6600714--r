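# mefopt

Design tool for metal-enhanced fluorescence (MEF) contrast agents:
photophysical modelling and genetic-algorithm optimization of
fluorophore-conjugated gold/silver nanostructures.

A fluorophore tethered near a plasmonic nanoparticle trades off two
competing near-field effects: FRET-type quenching of its excited state into
the particle's plasmon (rate `QR`, falling off as 1/r⁶ with the separation
`r`) and antenna-like enhancement of its radiative rate (`ER`). `mefopt`
models both channels for an ellipsoidal Au/Ag nanostructure and a dye with
known quantum yield `Q0` and natural lifetime `τ0`, and searches the
conjugate geometry — separation distance plus the three dipole-orientation
angles (θT, θD, θA) — with a real-parameter genetic algorithm. It is aimed
at researchers sizing fluorophore–nanoparticle probes for lifetime-based
bioimaging.

The core quantities, in the field's standard notation:

- orientation factor κ = |cos θT − 3 cos θD cos θA|;
- quenching rate QR = 8.79·10⁻⁵ Q₀ J_fp κ² / (1.344 τ₀ (10 r[nm])⁶), with
  the overlap integral
  J_fp = ∫σ_abs(λ) Ê(λ) λ⁴ dλ / (∫σ_abs(λ) dλ · C_NR · l) between the
  particle absorption cross-section and the normalized dye emission;
- enhancement rate ER = cos²θD/τ₀ · |1 + N(r)/D|² from a quasi-static
  image-dipole model of a prolate spheroid (complex permittivity at the
  longitudinal plasmon resonance);
- differential enhancement factor Γd = ER − QR and the transfer
  efficiencies TrE, TrQ = ER, QR /(ER + QR);
- a two-branch fluorescence lifetime: quenching-dominated
  τ = 1/(QR + 1/τ₀) when the spectral overlap ratio is below 40%,
  MEF-dominated τ = (1 + C₁(TrE, TrQ))·τ₀ at or above it.

Nanoparticle spectra are generated analytically from quasi-static Gans
theory (sphere limit = Rayleigh dipole), or supplied as two-column CSV
files (e.g. exported from a BEM solver). Everything runs offline; three
dyes and five nanostructures ship as presets. See the methods vignette
(`vignettes/mefopt-methods.Rmd`) for the model, its assumptions and the
package's numerical choices.

## Worked example

```r
library(mefopt)

p   <- load_preset("fluorescein", "GNP_r10")   # dye + 10 nm Au sphere
sys <- mef_system(p$dye, p$ns)
sys
#> <mef_system> fluorescein + GNP_r10: overlap=0.397 (quenching branch), Jfp=2.644e+17

cfg <- ga_config(population_size = 60, generations = 80,
                 objective = "inverse_tau", seed = 1)
res <- run_ga(cfg, p$dye, p$ns)
res
#> <mef_ga_result> inverse_tau objective: best cost 0.25 after 55 generations (3300 evaluations)
#>   r=94.58 nm, thetaT=55.77, thetaD=76.06, thetaA=38.76 deg

tab <- distance_scan(res$best_genome, p$dye, p$ns)
optimal_distance(tab)
#> [1] 100
tab[c(1, 10, 100), c("r_nm", "QR_hz", "ER_hz", "tau_ns", "branch")]
#>     r_nm        QR_hz    ER_hz    tau_ns    branch
#> 1      1 4.542651e+09  4858587 0.2086528 quenching
#> 10    10 4.542651e+03  9082612 3.9999273 quenching
#> 100  100 4.542651e-03 14473419 4.0000000 quenching
```

Reading the output: the fluorescein emission band overlaps the gold
sphere's absorption at 39.7%, below the 40% threshold, so the pair is
quenching-dominated. The GA (lifetime objective) pushes the separation
toward large `r` and an orientation with κ ≈ 0, both of which switch the
quenching channel off. The scan shows the 1/r⁶ decay of `QR`: the lifetime
collapses to 0.21 ns at 1 nm separation, recovers to within 10⁻⁴ of the
4 ns natural lifetime by 10 nm, and the optimal spacer sits at the far end
of the scanned range.

A thin command-line wrapper over the same functions ships at
`inst/cli/mefopt.R`:

```sh
Rscript inst/cli/mefopt.R spectra  --config run.yaml
Rscript inst/cli/mefopt.R optimize --config run.yaml --seed 1
Rscript inst/cli/mefopt.R scan     --config run.yaml --result out/ga_result.json
```

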