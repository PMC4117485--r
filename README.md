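# avpdyn

Kinetics of the alkaline synaptic-vesicle population from pH-cycling
pHluorin fluorescence.

After a stimulus, synaptic vesicles are retrieved from the plasma membrane
by compensatory endocytosis and then reacidified by the vesicular proton
pump. Vesicles caught between those two steps — endocytosed but still
alkaline — form the *alkaline vesicle population* (AVP), a direct optical
readout of membrane scission. With a pH-sensitive marker (synapto-pHluorin,
quenched ~20-fold at pH 5.5) and a bath that cycles between pH 7.5 and
pH 5.5 every 2 s, one recording yields two interleaved time courses: the
pH 7.5 frames track exo-/endocytosis, the pH 5.5 frames track the AVP
alone. `avpdyn` is for experimenters and modellers who use this protocol
and need its analysis chain to be testable.

The core model is a first-order cascade over the surface pool S, alkaline
pool A and reacidified pool Q,

    dS/dt = r(t) − S/τ_endo,   dA/dt = S/τ_endo − A/τ_reac,   dQ/dt = A/τ_reac,

with a constant exocytosis rate r(t) during the stimulus ("ideal" model).
The "realistic" variant adds the measurement's own distortion: during acid
phases, endocytosed vesicles are internalised already acidic and bypass A.
Both are integrated exactly (piecewise matrix exponentials). On top of the
model sit: a ground-truthed synthetic trace/TIFF generator, derivative-based
phase separation, Laplacian-of-Gaussian bouton detection with
Manders/Pearson colocalization, exponential fits for τ_reac and τ_endo
(surface-pool method), and regularised FFT deconvolution of the endocytosis
time course.

## Worked example

Simulate the standard protocol (242 s, 2 s exchanges from 28 s, 200 AP at
20 Hz delivered at 40 s), measure the relative AVP size under cycling, and
compare with the undistorted model:

```r
library(avpdyn)

params <- kinetic_params(tau_endo = 17, tau_reac = 4)
stim   <- stimulus_protocol(n_ap = 200, frequency = 20, start_time = 40)
cyc    <- cycling_protocol(acid_phase_len = 2, alkaline_phase_len = 2,
                           cycling_start = 28, total_duration = 242)

ideal <- simulate_ideal(params, stim, t_end = 242)
real  <- simulate_realistic(params, stim, cyc)

relative_avp_size_model(ideal)                       # 0.1625415
relative_avp_size_model(real, detected_only = TRUE)  # 0.1119722
underestimation(params, stim, cyc)                   # 0.3111165
```

So with literature time constants, about 16% of the peak total response is
alkaline at its maximum, but balanced 2 s cycling detects only ~11% — the
acid phases hide ~31% of the relative pool size. Running the full grid
(`run_simulation_suite()`) keeps this underestimation between 31% and 34%
for every stimulus from 50–400 AP and 10–80 Hz, which is what makes
relative comparisons across stimuli trustworthy despite the bias.

The same chain runs on (synthetic or recorded) image stacks:

```r
map <- bouton_map(c(64, 64), n = 20,
                  responding = rep(c(TRUE, FALSE), c(16, 4)), seed = 1)
ex  <- synth_experiment(params, stim, cyc, map, noise_sd = 10, seed = 2)
res <- run_analysis(ex$stack, stim_start = 40, stim_duration = 10)

nrow(res$rois)                        # 16  (all responding boutons found)
res$relative_size$relative_size       # 0.105
res$tau_endo_surface_fit$tau          # 17.0  (generating value: 17 s)
```

The quench arithmetic that motivates the choice of marker:

```r
surface_fluorescence_fraction(0.24, 20)  # 0.863  synapto-pHluorin
surface_fluorescence_fraction(0.03, 20)  # 0.382  VGLUT1-pHluorin
```

86% of resting synapto-pHluorin fluorescence is surface-derived — large pH
flanks, automatic phase detection works; at 38% (VGLUT1-pHluorin) the
flanks drown in noise and `split_by_derivative()` fails or miscounts
markers, by design.

## Analysis scripts

`analysis/01_simulation_sweeps.R` … `04_deconvolution.R` are thin numbered
drivers over the package: the ideal-vs-realistic sweeps and phase-length
sweep, a synthetic imaging experiment with detection/colocalization
statistics, time-constant recovery tables, and the deconvolution
round-trip grid. Each writes its tables under `results/`.

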