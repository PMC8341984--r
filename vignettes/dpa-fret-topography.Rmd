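---
title: "Mapping intracellular-domain topography with dark-acceptor FRET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping intracellular-domain topography with dark-acceptor FRET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpafret)
```

## The measurement problem

The cytosolic N and C tails of trimeric acid-sensing ion channels are
invisible to crystallography and cryo-EM, yet they gate trafficking and
acid-evoked signaling. `dpafret` implements a fluorescence toolbox for
placing such unresolved segments on an axial coordinate — distance from the
inner membrane leaflet — and for asking whether they move when the channel
is driven into its desensitized state by extracellular acid.

Three experimental modalities feed the chain, and each has a module, a
matching synthetic-data generator, and round-trip tests:

1. voltage-dependent quenching of a fluorescent-protein (FP) donor by
   dipicrylamine (DPA), a dark, anionic acceptor that hops between membrane
   leaflets with voltage (`quench_curve()`, `extract_fv_points()`,
   `fit_boltzmann()`, `invert_distance()`);
2. donor-lifetime FRET (FLIM/TCSPC) with dilution series that separate
   intra-subunit from inter-subunit transfer (`fit_decay()`,
   `fret_efficiency()`, `dilution_plateau()`);
3. dual-channel apparent-FRET recordings during fast pH jumps, together
   with gating kinetics (`delta_fret_app()`, `fit_desensitization()`,
   `fit_recovery()`).

## The two-plane quenching model

A donor at axial distance $R_a$ from a plane of acceptors at surface
density $\sigma$ survives quenching with probability

$$P_\infty(R_a) = \exp\!\left(-\sigma \pi R_0^2
  \int_{R_a^2/R_0^2}^{\infty} \frac{du}{1+u^3}\right),$$

obtained by integrating the single-pair efficiency
$E = 1/(1+(d/R_0)^6)$ over concentric rings of the acceptor plane under
the assumption that acceptors quench independently. The package evaluates
the tail integral with its closed-form antiderivative (relative error at
machine precision; `quench_integral()`), and `mc_quench_oracle()` provides
an independent brute-force check: Poisson-distributed acceptors drawn
uniformly on a large disc, survival computed as $\prod_i (1-E_i)$. The two
routes agree within Monte-Carlo error everywhere we test them, and
$\int_0^\infty du/(1+u^3) = 2\pi/(3\sqrt3)$ anchors the implementation.

DPA sits in the inner leaflet at depolarized potentials (distance $R_a$)
and in the outer leaflet at hyperpolarized potentials (distance
$R_a + 25$ Å). The normalized voltage-dependent quenching is referenced to
the hyperpolarized (least-quenched) state:

$$\Delta F/F_{\mathrm{norm}}(R_a) =
  \frac{P_\infty(R_a+25) - P_\infty(R_a)}{P_\infty(R_a+25)}.$$

The denominator is a design choice — only "subtract and normalize" is fixed
by the physics. We note, and exploit in testing, that every monotone
function of the ratio $P_\infty(R_a)/P_\infty(R_a+25)$ has the *same*
argmax, so the peak position is insensitive to this whole family of
normalizations; only an unnormalized difference curve would move the peak
(to ~29 Å for $R_0=47$ Å), and an unnormalized difference is not a
fluorescence-change fraction.

### How sharp is the "peak"?

```{r peaks}
cfp <- donor_acceptor_system("CFP/DPA", r0 = 47)
yfp <- donor_acceptor_system("YFP/DPA", r0 = 36.5)
crv <- quench_curve(cfp, seq(0, 60, 0.5))
peak_distance(crv)
round(subset(crv, distance_A %in% c(20, 22, 23, 24, 26, 28))$dff_norm, 4)
```

The CFP curve is extraordinarily flat on top: between 22 and 24 Å the
value changes in the fourth decimal. Its exact argmax is 22.9 Å
(`peak_distance()` on a fine grid reports 23), while the midpoint between
the two equal-quenching flanks at 20 and 28 Å is 24 Å — both are defensible
summaries of "where the hump is", and they differ by a full Ångström
because the top is so flat. Curves sampled on grids coarser than about
2 Å read out the flank-midpoint value (24 Å for CFP, 16 Å for the YFP
curve); the fine default grid (0–80 Å, 0.25 Å) reads the exact argmax
(23/15). Users comparing against coarse published curves should be aware
of this sampling sensitivity; the flank values themselves
(`dff_norm(20) ≈ dff_norm(28)` within 0.008) are grid-independent.

`invert_distance()` performs the reverse mapping. A humped curve gives two
candidate distances for any value below the peak; both are always
returned, labelled by limb, and the choice between them is deliberately
left to external evidence (complementary donors, reference structures).
The optional 10 Å chromophore offset — the FP beta-barrel radius — is off
by default because it is an assumption about probe geometry, not a
measurement.

### What the model leaves out

DPA depth is treated as two discrete planes rather than distributions
about each leaflet; acceptor orientation is folded into $\kappa^2 = 2/3$
(prior work indicates minimal orientation dependence for DPA); partial
leaflet occupancy at finite voltages is not modelled — the curve represents
the voltage extremes that the Boltzmann fit of experimental data
extrapolates to.

## Patch clamp fluorometry

`extract_fv_points()` reduces a raw trace to one point per step voltage:
background subtraction, mean fluorescence over the *second quintile* of
each step (20–40 ms of a 100 ms step; late enough for DPA redistribution,
early enough to limit bleaching) divided by the mean over an equal-length
holding window immediately before the step. The first of the four step
families is discarded (acceptor equilibration) and the rest averaged.
The default protocol steps −180 to +120 mV in 30 mV increments from
−15 mV holding.

`fit_boltzmann()` fits
$f(V) = \mathrm{bottom} + (\mathrm{top}-\mathrm{bottom})/(1+e^{(V-V_{50})/k})$,
parameterized so that quenching (fluorescence falling with depolarization)
gives a positive $\Delta F/F = \mathrm{top}-\mathrm{bottom}$ with $k>0$.
Starts come from the data extremes and half-crossing; jittered restarts
and a simplex fallback handle shallow or flat sigmoids (a flat series is
flagged degenerate with $\Delta F/F = 0$). `fit_free_dff()` is the
model-free counterpart, $f(-180) - f(+120)$; on noiseless sigmoids the two
agree to the $e^{-6}$ truncation of the sigmoid at the extreme voltages.

### Generator and noise scale

`simulate_fv_experiment()` emits raw traces at 1 ms sampling in which the
normalized fluorescence–voltage relation is a decreasing Boltzmann pinned
to 1 at the holding potential, so the analysis estimates the generator's
`dff` directly. Noise is Poisson photon statistics (default 500 counts/ms
at the holding fluorescence, a typical photomultiplier flux for a bright
membrane-localized FP) plus 2 % multiplicative readout noise and an
additive background. These defaults put the per-cell estimation error
near 1–2 % of $\Delta F/F$ — the regime in which per-construct standard
errors of 0.01–0.05 across 5–13 cells are dominated by biological
scatter, as observed experimentally. The generator's truth record carries
no biological scatter by default, so round-trip tests measure estimator
error alone. Inter-sweep idle time is not simulated (the extraction uses
only each step and its preceding holding window), keeping 200-cell
simulations inside a test run of seconds.

## FLIM: lifetimes, efficiencies, dilution plateaus

`fit_decay()` tail-fits $A e^{-t/\tau} + c$ to a TCSPC histogram with
Poisson weights $1/\max(n_i, 1)$, starting 0.5 ns after the peak bin by
default — no instrument-response deconvolution, matching mono-exponential
plasma-membrane FLIM practice. `fret_efficiency()` is
$1 - \tau_{DA}/\tau_D$.

`simulate_trimer_mixture()` embodies the dilution-series design: a
dual-labeled subunit co-expressed with unlabeled subunit at ratio $a\!:\!b$
assembles trimers whose other two positions are labeled with probability
$x = a/(a+b)$ (binomial assembly). Efficiencies from the intra-subunit
acceptor, each labeled neighbour, and crowding (transfer to neighbouring
complexes, scaling with $x$) combine by *rate additivity* —
$\tau_{DA} = \tau_D / (1 + \sum_j E_j/(1-E_j))$ — which is the physically
standard combination and keeps total efficiency below 1. The
configuration mixture is summarized as the intensity-weighted lifetime
$\sum a_i \tau_i^2 / \sum a_i \tau_i$, the value a mono-exponential fitter
reports. As $x \to 0$ only the intra-subunit acceptor remains, so the
plateau of the series isolates single-subunit FRET; because donor-centric
measurements are skewed toward higher efficiencies whenever more than one
acceptor is present, the plateau is approached from above.

`dilution_plateau()` estimates that plateau as the mean per-cell
efficiency at the highest dilution (the reported experimental practice)
with a bootstrap CI; a linear-in-$x$ extrapolation to $x=0$ is available
as `method = "fit"` but secondary. Efficiencies are computed per cell and
then averaged, matching per-cell $n$ in experimental summaries.

## pH jumps and kinetics

`delta_fret_app()` works on the acceptor/donor ratio, which cancels any
common multiplicative drift exactly; the same percent-change statistic is
returned per channel so that intrinsically pH-sensitive fluorophores
(YFP's chromophore, notably) can be diagnosed: a donor-only loss of 12 %
with no FRET change shifts the ratio by $+13.6\,\%$, and the generator
`simulate_ph_jump()` reproduces exactly this arithmetic. The default
response window is the late half of a 2 s application, capturing the slow
plateau; no bleed-through correction is attempted, which is why the
statistic is *apparent* FRET — suitable for detecting changes, not for
absolute efficiencies.

Desensitization decays are fitted with one (default) or two exponentials
from the detected current peak; recovery from desensitization uses
$I_t = (1 - e^{-t/\tau})^m$, which is 0 at $t=0$, 1 at $t\to\infty$, and
reduces exactly to mono-exponential recovery at $m = 1$.

## Resampling statistics

`permutation_test()` implements the two-sided randomization test with the
add-one rule $p = (1 + \#\{|T^\ast| \ge |T|\})/(1 + N)$, which cannot
return 0; `exact = TRUE` switches to full enumeration (all label splits,
or all $2^n$ sign flips when paired) with the plain tail fraction, since
enumeration is not an estimator. The default statistic is the mean
difference (the natural choice when nothing further is specified), with
the median available. `holm_bonferroni()` is the step-down adjustment,
cross-checked in tests against `stats::p.adjust`. `wilcoxon_signed_rank()`
computes the exact two-sided signed-rank p-value for any $n$ by dynamic
programming over the (possibly tied, half-integer) ranks, dropping zero
differences with a flag.

Calibration is tested empirically: across 1000 null experiments the
rejection rate at $\alpha = 0.05$ is 0.05 within Monte-Carlo error. The
calibration replicates use 499 iterations each — at that resolution the
add-one rule makes the rejection boundary exact — while the $\ge 10^5$
iteration default is meant for single confirmatory analyses.

## Numerical choices, in brief

* Quenching integral: closed form; cross-checked against adaptive
  quadrature at $10^{-8}$ and against the Monte-Carlo oracle at 3 SE.
* Distance inversion: grid bracketing + bisection on the continuous
  forward model, tolerance $10^{-6}$ in $\Delta F/F_{\mathrm{norm}}$
  units; both limbs always reported.
* Nonlinear fits: Levenberg–Marquardt (`minpack.lm`), data-driven starts,
  jittered restarts, simplex fallback for ill-conditioned sigmoids;
  degenerate inputs (flat series, constant histograms, full recovery
  everywhere) are flagged, not silently fitted.
* Dilution-series parsing: ratio labels `"a:b"` map to labeled fraction
  $a/(a+b)$; non-monotone per-ratio mean lifetimes warn but do not error.
* All generators take a `seed` and are byte-deterministic given one.

## What passing tests do and do not show

The generators reproduce the *statistical structure* the analyses assume:
Poisson photon counts, multiplicative readout noise, binomial trimer
assembly, multiplicative two-channel noise. They do not emulate
photobleaching, series-resistance artifacts, ER background fluorescence,
DPA depth distributions, or bleed-through — all recognized error sources
in the real measurements. Round-trip recovery therefore demonstrates that
the estimators are unbiased and correctly scaled under the stated model,
not that real recordings are free of systematic error.

Problem sizes used by the test-suite checks (chosen to make the Monte-
Carlo error comfortably smaller than each tolerance): $10^5$ replicates
for the quenching oracle, 6- and 200-cell fluorometry batches, $10^6$
photon TCSPC histograms, 1000 null experiments for test calibration,
20-seed kinetics recovery sweeps.
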