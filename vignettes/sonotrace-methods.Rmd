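---
title: "Simulating light transport in ultrasonically sculpted virtual optical waveguides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating light transport in ultrasonically sculpted virtual optical waveguides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonotrace)
```

## The physical model

A cylindrical ultrasonic transducer driven at frequency $f$ sets up a radial
standing pressure wave in a compressible medium. Through the
pressure-density-index coupling, the local refractive index becomes

$$n(r, t) = n_0 + \Delta n \, J_0(k_r r)\, \sin(2\pi f t),$$

with $r$ the distance from the cylinder axis, $J_0$ the zeroth-order Bessel
function of the first kind, $k_r = 2\pi f / V_{us}$ the radial component of
the ultrasonic wavevector, and $\Delta n$ the index contrast (proportional to
the drive amplitude). At peak modulation the central lobe of $J_0$ acts as a
gradient-index (GRIN) waveguide sculpted *in situ*: a collimated beam
entering along the axis is periodically refocused, crossing the axis at odd
multiples of the quarter pitch
$z_q = \tfrac{\pi}{2 k_r}\sqrt{2 (n_0 + \Delta n)/\Delta n}$
(the parabolic approximation of the central lobe). A pair $(f, \Delta n)$
whose $k$-th focus lands exactly on the exit plane of a slab of length $L$ is
a *focal configuration of order $k$*; at fixed $L$ these pairs trace
near-hyperbolic curves ($\Delta n \cdot f$ roughly constant) in the
frequency-amplitude plane, the *focal loci*.

Rays in the continuously varying index field follow Hamilton's equations

$$\frac{d\mathbf{v}}{ds} = \nabla n(\mathbf{x}), \qquad
  \frac{d\mathbf{x}}{ds} = \frac{\mathbf{v}}{n(\mathbf{x})},
  \qquad \mathbf{v} \equiv n(\mathbf{x})\,\boldsymbol{\omega},$$

with $s$ arc length and $\boldsymbol{\omega}$ the unit direction. In a turbid
medium the radiance additionally satisfies the radiative transfer equation
with extinction $\sigma_t$, single-scattering albedo $a$ and a
Henyey-Greenstein phase function of anisotropy $g$; the combination of both
effects is the refractive radiative transfer regime this package simulates.
Optical density is quoted as optical depth in mean free paths
($\mathrm{MFP} = 1/\sigma_t$) or transport mean free paths
($\mathrm{TMFP} = 1/(\sigma_t(1-g))$).

## The estimator

`estimate_flux()` is a volumetric particle tracer. Each photon:

1. starts on the source (uniform disk for a collimated beam; for the ideal
   lens, aimed at the on-axis focus) with weight `flux / n_photons`,
   attenuated by the unpolarized Fresnel transmittance of the entry face;
2. freezes an ultrasonic phase $t$ (light transit is ~5 orders of magnitude
   faster than the ultrasonic period, so each path sees a static field;
   temporal averaging happens across paths);
3. alternates free-path sampling in arc length
   ($s = -\ln(1-u)/\sigma_t$) with leapfrog ray bending, until it crosses a
   slab face, wanders beyond the lateral kill radius, or undergoes a volume
   event: weight times $a$, a Henyey-Greenstein deflection, and a next-event
   split (below);
4. on the exit face, is attenuated by the exit Fresnel factor and tallied
   into every detector disk radius it lands inside, decomposed by the number
   of scattering events $N$.

The integrator is a kick-drift-kick leapfrog in arc length. It is
time-reversible and second order (halving the step quarters the endpoint
error against an adaptive Runge-Kutta reference), and it preserves
$|\mathbf{v}| = n(\mathbf{x})$ to well below $10^{-6}$ relative over a 30 mm
slab at the default step. The default step is $\lambda_{us}/20$, one
twentieth of the ultrasonic wavelength — the shortest length scale of the
index field. The compiled core evaluates $J_0$, $J_1$ with classical
polynomial approximations accurate to about $5\times10^{-8}$, cross-checked
in the test suite against R's `besselJ` and a truncated power series; the
R-level field functions use `besselJ` itself.

**Next-event estimation.** A particle tracer alone almost never hits a
50-100 um detector disk through 5-10 MFP of scattering. At every volume
event the core therefore also samples one direction from the uniform cone
subtending the detector disk (computed with straight-line geometry), traces
that sub-path with full non-linear ray bending, and adds its contribution
attenuated by $e^{-\sigma_t \cdot \mathrm{arc}}$. The split and the
phase-function continuation are combined with the balance heuristic of
multiple importance sampling over the two direction densities
(cone-uniform and Henyey-Greenstein), so the combined estimator is unbiased
even though the cone is only an approximation of where curved rays can reach
the disk. The test suite verifies the combination against the closed-form
single-scatter solid-angle flux and, on 0/1/5 MFP scenes, against the plain
estimator. Splits are attempted at every volume event; in very deep scenes
(about 10 MFP) they are almost always attenuated away, and the plain
estimator can be the better use of CPU time — `run_bladder(nee = FALSE)`.

**Boundaries.** Slab faces apply the unpolarized Fresnel factor at the
unperturbed background index ($\Delta n / n_0 \lesssim 4\times10^{-2}$, so
the modulation correction is negligible). The default mode multiplies the
weight by the transmittance and drops the reflected branch — a deliberate
variance-reduction approximation that under total internal reflection
discards the photon; the stochastic branching mode is available where the
reflected light matters. The lateral geometry is an infinite slab with a
kill radius (default ten core radii) standing in for the transducer cavity
wall, which the source does not specify; the bladder comparisons were
checked at 2.7x and 5.3x that radius and the enhancement moved by far less
than its Monte Carlo error.

**Reproducibility.** Every photon draws from its own counter-based
(splitmix64) substream keyed by (seed, photon index), so estimates are
bit-identical across runs and independent of scheduling; sweep cells derive
their seeds from the base seed and the cell index, which is what makes
interrupted sweeps resumable without changing their output.

**Diagnostics.** Weights are conserved exactly: launched flux equals
detected + escaped + absorbed + Fresnel losses + roulette balance +
event-cap bucket to machine precision when splitting is off (the split
estimator redistributes expected weight, so the audit is a plain-estimator
invariant). Russian roulette (survival 0.1) starts below weight $10^{-4}$;
paths are capped at $10^4$ volume events and the capped weight is reported,
never silently dropped.

## Figures of merit

For a focusing method in a turbid slab, with $F_s(r)$ the flux reaching the
target disk of radius $r$ and $F_t(r)$ the same flux in a transparent
reference (water index, same source and ultrasound settings),

$$\mathrm{insertion\_loss}(r) = -10\log_{10}\frac{F_s(r)}{F_t(r)}, \qquad
\mathrm{gain}(r) = \mathrm{loss}^{\mathrm{lens}} - \mathrm{loss}^{\mathrm{US}},$$

$$\mathrm{enhancement}(r) =
  \left(\frac{F_s^{\mathrm{US}}/F_t^{\mathrm{US}}}
             {F_s^{\mathrm{lens}}/F_t^{\mathrm{lens}}} - 1\right)\times 100\%,
\qquad \mathrm{gain} = 10\log_{10}(1 + \mathrm{enhancement}/100).$$

The ideal external lens reference is aberration-free and non-absorptive:
all rays meet at the focus, simulated by aiming the launch fan at the focus
point and switching the ultrasound off. Ultrasound safety enters through the
mechanical index $\mathrm{MI} = P_r/\sqrt{f}$ ($P_r$ in MPa, $f$ in MHz,
diagnostic limit 1.9).

## Design choices on genuinely open points

* **Sound speed.** 1500 m/s, the standard value for water and soft tissue;
  the source material's parameter table garbles this entry.
* **Temporal mode.** The package default samples the phase uniformly over
  one period, the plain temporal average. The experiment drivers do not:
  frequency-amplitude maps are computed at peak modulation (`"peak"`), the
  quasi-static regime in which the focal condition is defined — at 0 MFP the
  peak-phase ridge maximum is limited purely by the boundary Fresnel losses,
  whereas uniform averaging caps it at less than half of that because the
  guide defocuses over most of the cycle. The bladder comparison driver uses
  a 10% duty window centered at peak modulation, the way such a guide is
  operated in practice (the beam gated in sync with the drive). Uniform
  averaging roughly doubles the apparent lens-relative enhancement, for the
  same reason it depresses the maps.
* **Beam aperture for the bladder arms.** Not printed in the source
  analysis, and the enhancement is sensitive to it. We preserve the
  beam-to-core-diameter ratio of the standard sweep setup (500 um beam
  against the ~1.15 mm core of the 1 MHz reference: about one half), i.e.
  beam diameter = core radius, which fills the guide paraxially. A beam
  matched to the full core diameter roughly triples the enhancement; a
  500 um beam at 30.52 MHz (where the core is 19 um) makes the normalized
  comparison meaningless.
* **Safe bladder candidates.** Mapping the MI limit into the
  frequency-contrast plane needs a pressure-to-index coupling that no
  general value exists for; `select_safe_configs()` therefore demands it
  explicitly. The bladder driver avoids it: on the $k$-th locus
  $\Delta n \propto (2k-1)^2/f^2$ while the safety bound grows as
  $\sqrt{f}$, so the three candidate frequencies scale as $(2k-1)^{4/5}$,
  and anchoring the third at the printed 30.52 MHz fixes all of them.
* **Ridge extraction.** Per-frequency 1-D peak finding in the amplitude
  direction with quadratic sub-cell refinement, chained across frequencies
  in $\log(\Delta n \cdot f)$ (constant along an ideal hyperbola). Simple,
  and validated against planted ridges.
* **Uniform beam profile.** The intensity across the source disk is
  uniform; a Gaussian profile would weight the paraxial region more and
  slightly sharpen every focus, but does not change any comparison made
  here.

## What the simulations do and do not show

The scenes are homogeneous slabs with a single Henyey-Greenstein phase
function, no wavelength dependence, no polarization, and no diffraction:
interference ripples around caustics average out in flux integrals but are
genuinely absent from the images. The ultrasound is an ideal cylindrical
standing wave: no propagation loss, no transducer resonance structure, no
pressure-to-index calibration. Agreement of the suite's oracles therefore
validates the transport mathematics, not any particular tissue model; real
media differ in their scattering phase function, heterogeneity and
absorption spectra.

## Problem sizes

The default experiment drivers are sized for a single CPU: sweep grids of
10 x 10 cells at $10^4$ photons per cell with the two selected cells
re-estimated at $10^5$ photons, and bladder comparisons at $10^5$ to
$10^6$ photons per arm (at 10 MFP the per-photon cost is dominated by the
~2.5 um leapfrog step at 30.52 MHz). All headline quantities carry Monte
Carlo standard errors propagated from the per-photon tallies.

## A worked sweep

```{r sweep, eval = FALSE}
cfg <- run_config(tag = "demo", sigma_t_per_m = 166.7,
                  f_list_hz = seq(0.3e6, 1.5e6, length.out = 10),
                  delta_n_list = exp(seq(log(1e-4), log(5e-2), length.out = 10)),
                  n_photons = 1e4, seed = 1, out_dir = "demo_sweep")
grid <- run_sweep(cfg)
loci <- find_focal_loci(attr(grid, "ballistic"))
image(log10(grid$delta_n), grid$f_hz / 1e6, t(grid$flux),
      xlab = "log10 delta_n", ylab = "f [MHz]")
```

The ballistic-design penalty study (`ballistic_penalty_study()`) and the
bladder comparison (`run_bladder()`) are the two packaged end-to-end
analyses; `run_validation_suite()` re-derives the core physics from
independent oracles and is run as part of the test suite.
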