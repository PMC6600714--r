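---
title: "Modelling and optimizing metal-enhanced fluorescence conjugates"
author: "mefopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and optimizing metal-enhanced fluorescence conjugates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mefopt)
```

## The design problem

A fluorophore held near a gold or silver nanostructure changes its
photophysics in two competing ways. Its excited state can dump energy
non-radiatively into the particle's plasmon — FRET-type quenching with the
characteristic $1/r^6$ distance law — and its radiative rate can be enhanced
by the particle acting as an optical antenna. Which effect wins depends on
the separation distance $r$, the relative dipole orientations, the particle
geometry and material, and on how well the particle's absorption band
overlaps the dye's emission band. `mefopt` models both channels analytically
and searches the geometry space with a real-parameter genetic algorithm
(GA), the use case being the design of fluorophore-conjugated metal
nanostructures as contrast agents for lifetime-based bioimaging.

## The photophysical model

**Orientation factor.** The relative orientation of the fluorophore and
plasmon transition dipoles enters through
$\kappa = |\cos\theta_T - 3\cos\theta_D\cos\theta_A|$, where $\theta_T$ is
the angle between the two dipole moments and $\theta_D$, $\theta_A$ are the
angles each dipole makes with the line joining the centres. On the
$[0^\circ, 90^\circ]$ domain used throughout, $\kappa \in [0, 3]$.

**Quenching rate.** Energy transfer into the particle is modelled as
Förster transfer with the particle as acceptor:
$$QR = \frac{8.79\times10^{-5}\, Q_0\, J_{fp}\, \kappa^2}
        {1.344\, \tau_0\, (10\,r[\mathrm{nm}])^6}\ \mathrm{[Hz]},$$
where $Q_0$ and $\tau_0$ are the dye's quantum yield and natural lifetime
and $J_{fp}$ is the overlap integral between the particle absorption
cross-section $\sigma_{abs}$ and the area-normalized dye emission $\hat E$,
$$J_{fp} = \frac{\int \sigma_{abs}\,\hat E\,\lambda^4\,d\lambda}
        {\int \sigma_{abs}\,d\lambda \cdot C_{NR}\, l},$$
with particle concentration $C_{NR}$ (default 1 nM) and cuvette path $l$
(default 1 cm). The numeric prefactors follow the standard Förster $R_0^6$
convention ($J$ in $\mathrm{M^{-1}cm^{-1}nm^4}$, distance in ångström —
hence the factor 10 on $r$); the constant 1.344 is kept as an opaque part
of the prefactor (plausibly a refractive-index power). $\tau_0$ is
converted to seconds internally so $QR$ is in Hz.

**Enhancement rate.** The radiative enhancement near a prolate spheroid of
long axis $h$ and transverse radius $R$ is
$$ER = \frac{\cos^2\theta_D}{\tau_0}\,\Big|1 + \frac{N(r)}{D}\Big|^2,
\qquad
N(r) = \frac{1}{(2r+h)\,(r(h+r)+R^2)} - I\!\big(r(h+r)\big),
\qquad
D = \frac{2}{(\varepsilon_{res}-1)\,h R^2} + I(0),$$
with the geometry integral
$I(a) = \int_a^\infty 2\,dx\,/\,[(x+R^2)(4x+h^2)^{3/2}]$ and
$\varepsilon_{res}$ the complex metal permittivity at the longitudinal
plasmon resonance wavelength. The grouping of terms above was chosen so
that $N$ and $D$ are dimensionally parallel ($\mathrm{nm^{-3}}$) and the
two physically required limits come out exactly: $ER \to \cos^2\theta_D/\tau_0$
both in the far field ($r \to \infty$, since $N \to 0$) and with no metal
contrast ($\varepsilon_{res} \to 1$, since $|D| \to \infty$). Whether
$\varepsilon_{res}$ is referenced to vacuum or to the medium is
configurable; the default is relative to the medium, consistent with the
solution context of the overlap integral.

**Derived quantities.** The differential enhancement factor is
$\Gamma_d = ER - QR$; the transfer efficiencies are
$TrE = ER/(ER+QR)$ and $TrQ = QR/(ER+QR)$, which sum to one whenever either
rate is nonzero (the fully degenerate case returns $(0,0)$ with a flag).

**Two-branch lifetime.** The lifetime model switches on the spectral
overlap ratio at a 40% threshold. At or above threshold (MEF-dominated),
$$\tau = (1 + C_1)\,\tau_0,\qquad
C_1 = (TrE\cdot TrQ^4)^{1/3}
  \exp\!\Big(\frac{ER-\tau_0}{ER+\tau_0}\Big) - \frac{TrQ}{2}.$$
Below threshold (quenching-dominated) enhancement is neglected
($ER$ and hence $TrE$ set to 0) and
$\tau = 1/(QR + 1/\tau_0)$, which decays from $\tau_0$ as quenching grows
and recovers $\tau_0$ exactly as $r \to \infty$.

The $C_1$ exponent mixes a rate and a time and is therefore not
dimensionally consistent as printed; the default (`const1_units = "mixed"`)
evaluates it with $ER$ in Hz and $\tau_0$ in ns as plain numbers, and a
documented alternative (`"dimensionless"`) substitutes the consistent form
$x = ER\,\tau_0$, $\exp((x-1)/(x+1))$. Note also that in the MEF branch
both rates still enter $C_1$ — we follow the equations rather than the
looser prose description of the branching. If the MEF expression ever turns
nonpositive (a pathology of the empirical $C_1$ form, not a user error) the
lifetime is clamped to a configurable floor with a warning.

**Overlap ratio.** A bounded "percentage of spectral overlap" is needed for
the branch decision but admits several reasonable definitions. The package
uses the area of the pointwise minimum of the two peak-normalized spectra
divided by the area of the peak-normalized emission. This is bounded in
$[0,1]$, equals 1 for identical shapes and 0 for disjoint bands, and is
invariant to the overall scale of either spectrum. It is a definition
choice of this package, distinct from $J_{fp}$.

## Spectra

The upstream reference workflow computed nanoparticle spectra with a
boundary-element electromagnetic solver. `mefopt` instead generates
absorption and scattering cross-sections analytically from quasi-static
Gans theory for prolate spheroids — polarizability per principal axis from
the depolarization factors, $\sigma_{abs} = k\,\mathrm{Im}\,\alpha$,
$\sigma_{sca} = k^4|\alpha|^2/6\pi$ — which keeps the package fully
self-contained; arbitrary spectra (BEM-computed or measured) can be
substituted through the CSV reader and take precedence everywhere
downstream. For rods the longitudinal component alone feeds the overlap
quantities by default (the longitudinal plasmon is the mode that couples);
for spheres all axes coincide. In the sphere limit $h = 2R$ the Gans
formulas reduce to the Rayleigh dipole cross-sections exactly, which the
test suite checks to $10^{-10}$ relative.

Metal permittivities default to analytic fits — a Drude–Lorentz model for
gold (one Lorentz pole for the interband transitions) and a Drude model for
silver — with the medium index defaulting to $n_{med} = 1.33$ (aqueous).
These fits are adequate in the visible/near-IR but are least accurate for
gold below roughly 450 nm; tabulated optical constants can be supplied
instead. Quasi-static theory itself ignores retardation, so resonance
positions for particles much larger than ~50 nm shift relative to full
electromagnetics. These are accepted limitations of the self-contained
default, not of the downstream machinery.

## Numerical choices

* **Quadrature.** Every integral over a stored spectrum uses the trapezoid
  rule on the stored grid — one declared rule everywhere, reproducible and
  order-independent. Dense-grid and adaptive-quadrature evaluations appear
  only as oracles in the test suite.
* **Resampling.** Overlap computations resample both spectra onto the
  union of their grids by linear interpolation with zero extension outside
  the support.
* **The geometry integral $I(a)$** is evaluated in closed form: the
  substitution $s^2 = 4x + h^2$ gives
  $\int 4\,ds/[s^2(s^2-c)]$ with $c = h^2 - 4R^2 \ge 0$, integrated
  analytically via the logarithmic antiderivative. Because the log form
  cancels catastrophically when $\sqrt{c}/s_0$ is small, the equivalent
  convergent series $4\sum_k c^k/[(2k+3)s_0^{2k+3}]$ is used in that
  regime; the crossover at $\sqrt{c}/s_0 = 0.1$ keeps both branches at
  full double precision. The tests compare both branches against adaptive
  double-exponential quadrature of the original integrand.
* **Minimum separation.** $r$ is floored at 0.1 nm to keep the $1/r^6$
  singularity out of reach; the default GA distance bounds start at 1 nm.
* **Ties.** The grid-search reference optimizer and the scan's optimal
  distance break ties toward smaller $r$ (then smaller angles), making
  both order-independent.

## The genetic algorithm

A specimen is an 8-gene real vector. Genes 1–5 all live on the distance
bounds and express the separation through their geometric mean — a
redundant encoding inherited from the reference workflow, retained verbatim
because recombining and mutating five genes perturbs $r$ more smoothly than
a single gene would. Genes 6–8 are the angles $\theta_T, \theta_D, \theta_A$.

Defaults follow the study protocol: population 300, 550 generations, 10%
per-gene mutation. The operators themselves were unspecified upstream and
are this package's choices, all configurable: fitness-proportionate
selection on $f = 1/(\mathrm{cost} - \min + \epsilon)$ with
$\epsilon = 0.01 \times$ the cost spread (tournament-of-2 available),
uniform crossover (single-point available), per-gene uniform-redraw
mutation, elitism of 2 (which makes the best-so-far history provably
non-increasing), and a stall stop after 50 generations without relative
improvement above $10^{-9}$. Two objectives are provided: cost
$= 1/\Gamma_d$ (direct enhancement design) and cost $= 1/\tau$ (lifetime
as an enhancement proxy). Specimens with $\Gamma_d \le 0$ receive a large
finite penalty ordered by the violation, keeping selection pressure smooth
instead of rejecting them. All randomness flows through R's RNG from the
single configured seed, so a (config, seed) pair reproduces a run
bit-for-bit.

Angle bounds default to $[0^\circ, 90^\circ]$: the cosine factors make
wider ranges redundant up to sign. Distance bounds default to
$[1, 100]$ nm, the same range as the post-optimal scan.

## Post-optimal distance scan

After optimization the orientation genes are frozen and the separation is
swept — by default 100 evenly spaced points over 1–100 nm. (The coarse
5-point grid implied by a literal "25 nm resolution" is available via
`n_points = 5`, but the fine grid is the default since the quantities of
interest vary on the few-nm scale at short range.) At each scan distance
all five distance genes are set to $r$ itself, making the gene-to-distance
map bijective for reporting. The scan emits the lifetime, both rates,
$\Gamma_d$ and both efficiencies per row; the optimal separation is the
row with maximal lifetime.

## Presets and the synthetic-system generator

The bundled catalog provides fluorescein, rhodamine green and rhodamine red
plus five nanostructures (10 nm-radius Au/Ag spheres, 40 × 20 nm Au/Ag rods,
a 60 × 25 nm Au rod). The reference study disclosed almost none of its dye
inputs — only fluorescein's 4 ns natural lifetime is fixed by it — so the
remaining quantum yields, lifetimes and Gaussian band parameters are
representative literature-style values stored in one editable JSON file and
documented as artifact choices. Consequently, which dye–nanostructure pairs
land above or below the 40% threshold is an emergent output of the spectral
model: with these defaults the fluorescein–gold-sphere pair classifies as
quenching-dominated (overlap ≈ 0.40) and its scan recovers the 4 ns
asymptote at large separation, while e.g. the fluorescein–silver-rod pair —
MEF-dominated in the reference study — classifies as quenching-dominated
here because the narrow Drude silver resonance sits at 474 nm in this
model. Curve-level reproduction of the reference figures is out of reach
without the undisclosed inputs and is not attempted.

Tests therefore never rely on a preset's branch except where the reference
classification emerges; branch behaviour is tested with
`synthetic_system()`, which builds Gaussian emission and absorption bands
and root-finds the peak separation until the computed overlap ratio hits a
requested target within 0.02. Its lineshapes are truncated at 3.5 FWHM so
that a zero target produces genuinely disjoint spectra on a finite grid.

What passing tests show, and what they do not: the suite verifies the
implemented equations against independent transcriptions to $10^{-12}$,
the analytic spectra against their closed-form limits, and the GA against
an exhaustive grid reference on a coarse problem (population 60, 80
generations, distance bounds 1–30 nm, a $30\times10^3$ grid — sizes chosen
to keep the whole suite under half a minute). None of that validates the
empirical lifetime model itself against measurements; the upstream authors
themselves note the physical model is a proof of concept.

## Worked example

```{r example, eval = FALSE}
p <- load_preset("fluorescein", "GNP_r10")
sys <- mef_system(p$dye, p$ns)
sys

cfg <- ga_config(population_size = 60, generations = 80,
                 objective = "inverse_tau", seed = 1)
res <- run_ga(cfg, p$dye, p$ns)
res

tab <- distance_scan(res$best_genome, p$dye, p$ns)
optimal_distance(tab)
```
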