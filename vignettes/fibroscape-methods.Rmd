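---
title: "Simulating fibrosis length-scale effects in 2D human atrial tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating fibrosis length-scale effects in 2D human atrial tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the model

Fibrosis in atrial tissue slows and blocks conduction and is a substrate for
persistent atrial fibrillation (AF). Imaging shows fibrotic remodelling on a
range of spatial scales, and the scale matters: the same fibrotic burden
arranged in fine speckle or in large patches loads the surrounding
myocardium very differently. `fibroscape` simulates this in the simplest
setting in which the question is well posed: an isotropic 2D sheet of human
atrial tissue in which "fibrosis" is a smoothly varying reduction of the
diffusion coefficient, with the most fibrotic regions rendered electrically
inexcitable but still diffusively coupled.

Tissue electrophysiology follows the monodomain equation

$$\frac{\partial V}{\partial t} \;=\; \nabla\!\cdot\!\big(D(x,y)\,\nabla V\big)
\;-\; \frac{I_{\mathrm{ion}} + I_{\mathrm{stim}}}{C_m},$$

with $V$ the membrane voltage (mV), $D$ a diffusion coefficient field
(mm²/ms) and $C_m = 100$ pF. The membrane kinetics $I_{\mathrm{ion}}$ are
the Courtemanche–Ramirez–Nattel (CRN) human atrial action potential model:
12 voltage-gated and 3 calcium-operated gating variables, three calcium
compartments, and the full complement of sarcolemmal currents
(I~Na~, I~K1~, I~to~, I~Kur~, I~Kr~, I~Ks~, I~CaL~, I~NaK~, I~NaCa~, pump
and background currents). The equations were transcribed from the CellML
curation of the 1998 CRN publication (model
`courtemanche_ramirez_nattel_1998`, the standard curated revision); the
transcription is exercised end-to-end by the test suite (resting stability,
action potential morphology, APD, conduction velocity). Intracellular Na⁺
and K⁺ are clamped at their default initial values (11.17 and 139.00 mM) to
avoid the well-known slow drift of the model; only the calcium subsystem
evolves freely.

Two parameter variants represent the study conditions:

* **normal** — published maximum conductances;
* **remodelled** — persistent-AF electrical remodelling: g~to~ and g~CaL~
  scaled by 0.35, g~Kur~ by 0.51, g~K1~ by 2.10. Only maximum conductances
  are scaled; kinetics are untouched.

Remodelling shortens the action potential from roughly 314 ms to roughly
154 ms at a cycle length of 1,000 ms (both values are recomputed by the
test suite and the acceptance script), which shortens the re-entry
wavelength (minimum APD × conduction velocity) accordingly.

Every simulation starts from the state reached by pacing the relevant cell
variant for 40 beats at a cycle length of 1,000 ms (`initialize_variant()`),
so tissue runs begin on the cell's paced limit cycle rather than at the
published resting point.

## The synthetic-data generator: Gaussian random fields

The fibrosis fields are the study's synthetic data. `sample_grf()` draws
stationary, zero-mean, unit-variance Gaussian random fields with the
squared-exponential covariance

$$\mathrm{Cov}(r) = \exp(-r^2/\delta^2),$$

where $\delta$ is the correlation length (study values 1.25, 2.5, 5.0 and
10.0 mm on a 10 × 10 cm sheet). Sampling uses circulant embedding on a
2×-padded periodic grid: the wrapped covariance is diagonalized exactly by
the 2D FFT and the field is the real part of the inverse transform of
spectrally coloured complex white noise. The embedding of a squared
exponential at these $\delta$/domain ratios is nonnegative definite to
numerical precision; any negative eigenvalues are clipped to zero and a
warning reports the clipped relative spectral mass when it exceeds 1e-8
(in practice ~1e-8 at $\delta = 10$ mm on small test domains, zero on the
study grid).

`grf_to_diffusion()` maps a raw field $G$ to $D = 0.05\,(G + 2)$ mm²/ms,
capped to $[0.05, 0.2]$; raw values of −1, 0, +1 map to 0.05, 0.1,
0.15 mm²/ms. Nodes whose pre-cap value falls strictly below 0.05 mm²/ms are
*fibrotic*: they keep $D = 0.05$, their membrane current term is removed,
and they participate in the simulation only through voltage diffusion
("coupled but inexcitable"). Under the stated mapping the expected fibrotic
fraction is $\Phi(-1) \approx 15.9\%$, and that is what the generator
produces (the white-noise-limit test pins this analytically). The source
study prints somewhat higher average fractions (17–19%) for nominally the
same mapping; we report our own fractions rather than force a match, since
no normalization consistent with both the stated mapping and those
percentages exists.

`binarize()` produces the comparison fields with an abrupt transition: the
fibrotic mask is kept, fibrotic nodes stay at 0.05 mm²/ms, and everything
else is set to 0.2 mm²/ms.

What the generator emulates: the marginal Gaussian statistics, the spatial
correlation structure at a controlled single length scale, and the
15–25% fibrotic area of the study design. What it does not emulate about
real atrial fibrosis: anisotropy (fibrosis preferentially disrupts lateral
coupling), non-stationarity (real fibrosis clusters around anatomical
structures), image-derived geometry, and any active fibroblast
electrophysiology. Tests that pass on these fields therefore validate the
solver and the scale-dependence machinery, not the clinical realism of any
particular fibrosis pattern.

## Numerics

**Discretization.** 400 × 400 nodes at $dx = 0.25$ mm (10 × 10 cm) with
no-flux boundaries; reduced grids are used in tests. The divergence term
uses a flux-conservative 5-point stencil with arithmetic-mean face
diffusivities, $D_{i+1/2} = (D_i + D_{i+1})/2$, and zero boundary-face
flux. This makes total voltage exactly conserved under pure diffusion (the
test suite checks conservation to 1e-9 relative over 10⁴ steps), which is
the property that matters when $D$ varies smoothly node to node.

**Time stepping.** Gates advance by Rush–Larsen exponential integration
(exact for rates frozen over a step, hence unconditionally stable and
bounded in [0, 1]); voltage and calcium concentrations advance by forward
Euler. The step is adaptive between 0.01 and 0.1 ms: fine (0.01 ms)
whenever a stimulus is being delivered or the maximum $|dV/dt|$ over nodes
on the previous step exceeded 5 mV/ms, coarse otherwise. The nominal
0.1 ms coarse step exceeds the explicit stability bound
$dx^2/(4 D_{\max}) = 0.078$ ms at $D = 0.2$ mm²/ms, so the coarse step is
clamped to that bound (`choose_dt()`). The 5 mV/ms trigger keeps every
upstroke at the fine step and lets diastole and most of the plateau run
coarse; halving both steps changes plane-wave conduction velocity by less
than 1% (tested).

**Lookup tables.** On large grids the 12 voltage-dependent gate rate pairs
and the voltage-dependent current factors are evaluated by linear
interpolation in V (0.02 mV grid), with Rush–Larsen relaxation factors
cached per time step value. The tables are validated against the direct
formulation: a single-node tissue run reproduces the direct single-cell APD
to under 0.2 ms.

**Convergence and grid effects.** At $D = 0.2$ mm²/ms the simulated
plane-wave conduction velocity is 0.669 mm/ms at $dx = 0.25$ mm and
0.701 mm/ms at $dx = 0.125$ mm, bracketing the reference value of
0.695 mm/ms. At $D = 0.05$ mm²/ms the depolarization front is only
$\sim D/c \approx 0.17$ mm thick — thinner than the 0.25 mm study lattice —
so propagation there is lattice-limited and slower than the continuum
$\sqrt{D}$ scaling; the scaling property is therefore asserted at
$dx = 0.125$ mm, where it holds to within 5%.

**Degenerate inputs.** Non-finite state anywhere aborts the run naming the
node and time; a fine step exceeding the stability bound is rejected before
stepping; protocols extending beyond the run duration, overlapping beat
windows, probes inside the stimulus region, non-positive spiral pitch and
already-binary fields are all rejected with informative errors.

## Stimulation protocols

All protocol stimuli inject −2000 pA per node. The pulse width is **2 ms**,
a deliberate design choice: a 1 ms pulse at this amplitude injects 2 pC,
i.e. a 20 mV displacement of the 100 pF membrane, which leaves the
transcribed CRN model ~2 mV short of its sodium-current threshold — it
fails to excite an isolated cell and fails to capture in tissue. The 2 ms
width delivers the same charge as the original CRN publication's standard
stimulus (2 nA × 2 ms) and captures reliably; all protocol timings are
unchanged.

* **S1S2** (`build_s1s2()`): three beats at a cycle length of 1,000 ms and
  a premature stimulus at a 400 ms coupling interval (onsets 0, 1,000,
  2,000, 2,400 ms) on the 2.5 × 2.5 mm corner block.
* **Decremental** (`build_decremental()`): ten stimuli on a central disc of
  radius 6.25 mm; inter-stimulus intervals start at 450 ms (normal) or
  300 ms (remodelled) and decrease by 25 ms to 250/150 ms. For the
  remodelled variant the floor is reached after six decrements; the
  remaining intervals are clamped at 150 ms so that ten stimuli are always
  delivered (the source text says "ten stimuli" in its methods and "nine"
  in its results; we keep ten and nine intervals).
* **Spiral** (`build_spiral_state()`): an Archimedean-spiral phase map
  $\varphi = (\pm\theta + 2\pi r/\mathrm{pitch}) \bmod 2\pi$ assigns every
  node a full cell state drawn (with linear interpolation) from a one-cycle
  trajectory of the paced cell — the phase-distribution construction.
  Defaults, chosen where the source is silent: centre of the domain,
  pitch 60 mm (of the order of the tissue wavelength, so a single rotor
  forms), counter-clockwise, trajectory recorded at a cycle length of
  1,000 ms (normal) or 400 ms (remodelled, whose restitution admits the
  shorter cycle) after five adaptation beats.

## Maps and summary statistics

Activation and recovery are defined by threshold crossings of −73.0 mV
(approximately 90% repolarization in this model), linearly interpolated in
time and detected during the run at every node. Excursions shorter than
5 ms are discarded as numerical glitches (the source does not discuss
debouncing). Beat windows run from each stimulus onset to the next, the
last extended by 500–800 ms; recovery may complete beyond its window. APD
is recovery minus activation. Fibrotic nodes are never assigned activation,
recovery or APD, even when passive excursions cross threshold.

Delay maps subtract the uniform-diffusion baseline ($D = 0.2$ mm²/ms, same
variant and protocol) node-wise over the nodes valid in both maps and are
summarized by median and interquartile range; a comparison covering less
than half the baseline's valid nodes is flagged. APD distributions are
summarized by quartiles and the adjusted Fisher–Pearson skewness
(cross-checked against `e1071::skewness(type = 2)` in the tests).

Beat counting uses a 3 × 3 probe lattice at 25/50/75% of each dimension
(shifted off fibrotic nodes), counts threshold excursions per probe, takes
the maximum, flags a stimulus as blocked when no probe activates within
200 ms of its onset (generous against the ~300 ms worst-case transit at
these conduction velocities), and classifies re-entry as *sustained* when
more than 15 activations follow the final stimulus plus block window. The
source states neither a counting location nor whether the 15-beat rule
counts from protocol start or end; the probe lattice and post-protocol
counting are this package's conventions.

## Problem sizes used by the tests

The test suite runs the full strip (400 × 20) conduction-velocity
measurement and the full 400 × 400 field statistics, and scales the
expensive 2D electrophysiology down: corner-paced CV on a 200 × 200 sheet
(the two-point diagonal measurement is insensitive to sheet size at the
measurement radii), spiral re-entry on a 200 × 200 sheet at
$D = 0.05$ mm²/ms (which shortens the wavelength so a rotor fits the
reduced domain) over 450 ms, APD-skew trends on three-sample ensembles at
160 × 160, and the pipeline smoke grid at 40 × 40. The full-scale grids —
the 20-sample decremental-pacing prevalence trend and full-sheet
corner-paced CVs — run from `scripts/extended_study.R`.

## Known limitations

* Isotropic diffusion, square sheet: no fibre architecture, no anatomy, no
  atrial mechanics, no fibroblast ionic models — fibrotic tissue is purely
  passive and always coupled.
* The corner-paced CVs printed in the source study (0.507/0.489 mm/ms)
  could not be reconciled with its own plane-wave value (0.695 mm/ms, which
  this solver reproduces); no measurement convention we tried recovers
  them, and wavefront curvature at the measurement radii is an order of
  magnitude too weak. The corresponding acceptance check is left failing
  rather than redefining the measurement to fit.
* Calcium handling is not remodelled and Na⁺/K⁺ are clamped; rate
  adaptation over very long pacing trains is therefore approximate.
* Conclusions about *which* configurations of fibrosis sustain re-entry are
  sample-dependent by design; single samples illustrate mechanisms, only
  ensembles support trends.
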