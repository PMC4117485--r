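---
title: "Measuring the alkaline synaptic-vesicle population with pH-cycling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the alkaline synaptic-vesicle population with pH-cycling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avpdyn)
```

## The measurement problem

After an action-potential train, synaptic vesicles fuse with the plasma
membrane (exocytosis), are retrieved by compensatory endocytosis, and are
then reacidified by the vesicular proton pump. Vesicles that have been
endocytosed but not yet reacidified form the *alkaline vesicle population*
(AVP). With a pH-sensitive marker such as synapto-pHluorin — fluorescent at
pH 7.5, quenched roughly 20-fold at pH 5.5 — the AVP can be isolated
optically: when the bath is switched to pH 5.5, all surface marker is
quenched, and the residual fluorescence above the fully quenched level
comes from internal, still-alkaline vesicles. Cycling the bath between
pH 7.5 and pH 5.5 every 2 s turns a single recording into an interleaved
pair of time courses: the pH 7.5 frames track exo-/endocytosis
(surface + alkaline pools), the pH 5.5 frames track the AVP alone.

`avpdyn` implements this measurement end to end: the kinetic model, a
ground-truthed synthetic data generator, the frame-classification and
image-analysis stages, and the two routes to the endocytosis time constant.

## The kinetic model

Three pools, in "vesicle units" of cumulative release: the surface pool
$S$, the alkaline pool $A$, the reacidified pool $Q$. Exocytosis is a
constant rate $r(t)$ during the stimulus — total release divided by
stimulus duration, so that cumulative release depends only on the number of
action potentials — and endocytosis and reacidification are first order:

$$\frac{dS}{dt} = r(t) - \frac{S}{\tau_{endo}},\qquad
  \frac{dA}{dt} = \frac{S}{\tau_{endo}} - \frac{A}{\tau_{reac}},\qquad
  \frac{dQ}{dt} = \frac{A}{\tau_{reac}}.$$

This is the **ideal** model. The **realistic** model adds the bath: during
pH 5.5 phases, endocytosed vesicles are internalised already acidic and
bypass $A$ entirely ($dA/dt = -A/\tau_{reac}$,
$dQ/dt = A/\tau_{reac} + S/\tau_{endo}$). That asymmetry is the entire
source of the measurement bias studied below.

Defaults are $\tau_{endo} = 17$ s and $\tau_{reac} = 4$ s, literature
values for moderate stimuli at hippocampal boutons; the standard protocol
is 242 s long with 2 s solution exchanges from 28 s and the stimulus at
40 s.

Because the system is piecewise linear-time-invariant, the integrator
propagates the state *exactly* between breakpoints (stimulus edges,
solution exchanges) with matrix exponentials of the 4-by-4 augmented
generator; `method = "rk4"` provides an independent classical integrator.
$Q$ is integrated as part of the state rather than inferred from
book-keeping, so the conservation law $S + A + Q = \text{cumulative
release}$ (machine-precision in practice, tested at $10^{-6}$) is a real
consistency check. The default grid step is 0.05 s; all reported ratios
change by less than $10^{-4}$ under halving.

### Derived quantities

* **Relative AVP size** — peak detectable pH 5.5 signal over peak
  detectable pH 7.5 signal, where the pH 7.5 signal is $S + A$ (internal
  alkaline vesicles fluoresce regardless of bath pH) and the pH 5.5 signal
  is $A$. For cycling runs the maxima are restricted to in-phase samples
  (`detected_only`), because that is all a camera sees. Normalising by
  $\max S$ instead of $\max(S+A)$ is exposed via `normalize = "surface"`;
  the default is the total signal, which is what the experimental ratio of
  trace maxima measures.
* **Underestimation** — $1 - \text{rel}_{realistic}/\text{rel}_{ideal}$.
  Defined on the relative sizes (a ratio of ratios) rather than on raw
  alkaline peaks, since the relative size is the quantity the measurement
  reports. With the default time constants and balanced 2 s phases it
  lies between 31% and 34% across the standard stimulus grid.
* **Surface fluorescence fraction** — $s/(s + (1-s)/q)$ for resting
  surface fraction $s$ and quench factor $q$: the share of resting marker
  fluorescence that the surface pool contributes. For synapto-pHluorin
  ($s = 0.24$, $q = 20$) this is $\approx 86\%$; for VGLUT1-pHluorin
  ($s = 0.03$) only $\approx 38\%$. This single number explains why the
  two markers behave so differently under automatic phase detection
  (below).

```{r}
run_simulation_suite()[, c("n_ap", "frequency_hz", "rel_ideal",
                           "rel_realistic", "underestimation")]
```

## The synthetic data generator

No recordings ship with the package; every downstream stage is instead
tested against data generated by `synth_trace()` / `synth_stack()`, whose
ground truth is known exactly.

The fluorescence model (`fluor_model()`) converts pools into counts. The
marker pool totals `total_pool` vesicle units (default 4 — a labelled
recycling pool several times one stimulus's release; the visibility
arithmetic needs a total marker amount, and this is the one free choice in
it), of which `resting_surface_fraction` rests on the membrane (0.24
synapto-pHluorin-like, 0.03 VGLUT1-pHluorin-like). Per frame, the visible
marker is

* pH 7.5: $s_{pool} + S + A + \text{rest}/q$
* pH 5.5: $(s_{pool} + S)/q + A + \text{rest}/q$

with $\text{rest}$ the quenched interior remainder. Counts are
`scale` (default 1000 per vesicle unit) times that, plus a constant
`background` (100), optional monoexponential bleaching of the
pHluorin-derived part, and additive Gaussian noise (`noise_sd`, default
100 counts). The default noise is chosen so that a single
synapto-pHluorin-like bouton trace has a pH-step flank of ~9 noise s.d. —
comfortably detectable — while the 8-fold smaller VGLUT1-like flank is
not; this is the regime the method's probe-selectivity argument lives in.
Solution exchange is emulated with one intermediate-valued frame per
switch (`ramp_frames = 1`), giving the derivative detector realistic
ramps; ground-truth phase labels always follow the protocol timing
exactly, with the exchange frame carrying the new phase's label.

Image stacks render boutons as peak-normalised 2-D Gaussian spots
(σ = 1.5 px, diffraction-limited at the usual magnification and binning),
16-bit, with Gaussian pixel noise — deliberately simple optics. What the
generator does **not** emulate: Poisson shot noise and EM-gain statistics,
focus drift and lateral shifts (registration is out of scope), bleaching
heterogeneity, vesicle-pool heterogeneity between boutons beyond a scalar
amplitude, and finite perfusion mixing beyond the single ramp frame.
Passing tests therefore demonstrate correctness of the *analysis logic*
under the stated model, not robustness to every pathology of real
recordings.

## Phase separation

Absolute intensity cannot label frames (the stimulus response is
superimposed on the pH square wave), but each exchange produces a steep
flank whose inflection is an extremum of the first derivative. The
splitter boxcar(3)-smooths the trace, takes a centred 3-point difference,
keeps alternating maxima/minima above a threshold and at least
`min_cycle_gap` (1 s) apart, repairs same-sign runs by keeping the
stronger extremum, and labels quiet frames by the most recent marker's
direction. Frames within one frame of a marker, or whose $|f'|$ exceeds
the threshold, are transitions.

Numerical choices: the default threshold is $3\times$ the MAD of $f'$
over the pre-cycling baseline, floored at 5% of the largest flank — the
floor keeps noiseless traces (MAD 0) working; ties are broken toward
larger $|f'|$. The effective dead time is ~3 frames per exchange (ramp
frame + marker neighbourhood + smoothing spread), i.e. 0.3 s at 10 Hz;
`relative_avp_size_model(deadtime = 0.3)` reproduces what the
trace-level measurement can see to within 2%.

For a 3% surface pool the flanks drown in default noise and the marker
count comes out wrong or detection fails with a classed error — the
package's reproduction of why small-surface-pool markers need the static,
not the cycling, protocol.

## Time constants

* **τ_reac** is fitted (`fit_exp_decay`, Levenberg–Marquardt with
  log-linear initialisation) on the acid-phase decay of a *single-switch*
  recording (bath held at pH 5.5 after the stimulus): there the alkaline
  pool drains as a pure exponential with the generating constant, since
  acid-phase endocytosis bypasses it. Under cycling, the post-stimulus
  pH 5.5 decay is a cascade envelope, not $\tau_{reac}$ — the analysis
  reports it, but recovery is only asserted for the single-switch design
  (within 10% at default noise, averaging 30 bouton traces as an
  experimenter averages a coverslip).
* **τ_endo, surface-pool route**: the pH 7.5 minus pH 5.5 difference
  trace is $S(t)$; its post-stimulus decay is monoexponential in
  $\tau_{endo}$. Linear interpolation bridges the disjoint phase
  sampling. Recovery on noiseless traces is within 5% across 8–35 s.
* **τ_endo, deconvolution route**: with endocytosis the only input and
  reacidification the only output of $A$,
  $A = E * R$ with $R(t) = e^{-t/\tau_{reac}}$. The AVP course is first
  smoothed by an alpha-function fit
  $k\,(t-t_0-\text{delay})\,e^{-(t-t_0-\text{delay})/\tau_\alpha}$ (the
  canonical linear-rise form; taken as this package's normative
  definition), resampled at 0.1 s — far finer than the ~4 s effective
  phase sampling, which only the smooth fit makes legitimate —
  zero-padded to twice its length, and divided in the frequency domain
  with a Tikhonov guard
  $\hat A \bar{\hat R}/(|\hat R|^2 + \varepsilon \max|\hat R|^2)$,
  $\varepsilon = 10^{-6}$ by default ($\varepsilon = 0$ reproduces the
  plain division). Forward-convolution round-trips recover
  $\tau_{endo}$ within 3% across the physiological grid. Note that the
  alpha function is only an approximation of the cascade shape, so the
  full alpha-then-deconvolve chain carries a few seconds of systematic
  bias on cascade-shaped inputs — one concrete reason the surface-pool
  route is the more robust of the two.

A caution on single-exponential summaries: the post-peak decay of $A(t)$
is a two-exponential mixture whose fast component has a *negative*
coefficient (the fit starts at a stationary point), so the fitted single
τ can exceed $\tau_{endo}$; the tests pin the fit against a brute-force
grid-search oracle rather than against a naive bracketing claim.

## Bouton detection and colocalization

The stimulation difference image (mean of 3 in-phase frames after minus
before the stimulus) is searched for blobs: local maxima of a
scale-normalised Laplacian-of-Gaussian response (σ = 1.5 px, matched to
the PSF), gated by an intensity threshold (Otsu by default), a connected
above-threshold region of 3–200 px, and a fixed 5×5 ROI that must fit the
frame. Coordinates are 0-based (row, col). On noiseless synthetic
difference images recall and precision exceed 0.95; detection is
translation-equivariant.

Colocalization offers both pixel-based Manders $M_1/M_2$ (intensity
fractions over the partner's above-threshold support; Otsu thresholds by
default, since none are prescribed) and Pearson's $r$, plus an
object-level overlap (fraction of one set's centroids inside the other's
masks). Both pixel- and object-level variants are provided because
published coefficient values do not state which was used; neither is
asserted against experimental numbers. Costes-style significance testing
is out of scope.

## Sizes, defaults, degenerate inputs

The test suite and the `analysis/` drivers run at deliberately moderate
problem sizes — 64×64 to 96×96 px fields with 20–30 boutons, 242 s
recordings at 10 Hz, 30-trace averages, 100-replicate Monte-Carlo fits —
enough for every tolerance above to be meaningful while keeping a full
run around a minute. Degenerate inputs are contracts, not accidents:
flat traces raise a classed phase-detection error, non-decaying segments
return `converged = FALSE` rather than throwing, zero-response recordings
raise an undefined-ratio error, and empty ROI sets are legal results.

## Known limitations

* The kinetic model has no readily-retrievable pool, bulk endocytosis or
  kiss-and-run branch; time constants are stimulus-invariant within a
  simulation.
* The pre-cycling acid test pulse of the experimental protocol is not
  modelled (cycling simply starts at 28 s).
* Bleaching correction is intentionally absent (the analysis pipeline,
  like the original procedure, applies none); the generator can *produce*
  bleached traces for robustness checks.
* The deconvolution assumes time-invariant endocytosis; where that fails
  the surface-pool route should be preferred.
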