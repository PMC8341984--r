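# dpafret

Tools for mapping the axial topography of ion-channel intracellular
domains — the cytosolic tails that X-ray and cryo-EM structures leave
unresolved — from fluorescence measurements, and for detecting their
acid-evoked motions. The package grew out of the analysis chain used to
place the N and C tails of the trimeric acid-sensing ion channel on a
distance axis from the inner membrane leaflet.

## Who it is for

Electrophysiologists and membrane biophysicists running:

* **patch clamp fluorometry with dipicrylamine (DPA) quenching** — a dark,
  anionic FRET acceptor that hops ~25 Å between membrane leaflets with
  voltage, so voltage steps convert donor position into a fluorescence
  change;
* **FLIM / TCSPC donor-lifetime FRET** with co-transfection dilution
  series;
* **dual-channel pH-jump fluorometry** with gating-kinetics analysis.

## The model at the core

A donor at axial distance $R_a$ from an infinite plane of acceptors at
surface density $\sigma$ retains the unquenched fraction

$$P_\infty(R_a) = \exp\!\left(-\sigma\pi R_0^2
  \int_{R_a^2/R_0^2}^{\infty}\frac{du}{1+u^3}\right),
  \qquad E = \frac{1}{1+(d/R_0)^6},$$

evaluated with DPA in the inner leaflet ($R_a$) or outer leaflet
($R_a+25$ Å). The normalized voltage-dependent quenching
$\Delta F/F_\mathrm{norm} = (P_\mathrm{out}-P_\mathrm{in})/P_\mathrm{out}$
is a humped function of distance for a CFP-like donor ($R_0 = 47$ Å) and
a lower-peaked, then monotonically decaying one for YFP ($R_0 = 36.5$ Å);
`invert_distance()` maps measured quenching back to the (up to two)
candidate distances. A Poisson-disc Monte-Carlo oracle
(`mc_quench_oracle()`) independently validates the continuum formula, and
`forster_radius()` / `overlap_integral()` compute $R_0$ from spectra.

Alongside: Boltzmann and fit-free ΔF/F extraction from voltage-step
families, mono-exponential TCSPC lifetime fits with
$E = 1-\tau_{DA}/\tau_D$, dilution-plateau estimation of single-subunit
FRET, apparent-FRET (acceptor/donor ratio) changes during pH jumps,
desensitization and $(1-e^{-t/\tau})^m$ recovery fits, permutation tests
with Holm–Bonferroni correction, and exact Wilcoxon signed-rank tests.
Every pipeline has a seed-deterministic generator (`simulate_*`) emitting
synthetic recordings with the noise structure the analysis assumes.

## Worked example

```r
library(dpafret)

cfp <- donor_acceptor_system("CFP/DPA", r0 = 47)   # sigma = 1.25e-4 /A^2 at 5 uM DPA
crv <- quench_curve(cfp)
peak_distance(crv)
#> [1] 23

invert_distance(0.30, crv)
#> Axial distance candidates for dff_norm = 0.3:
#>   6.05 A (ascending limb)
#>   40.06 A (descending limb)

sim <- simulate_fv_experiment(dff = 0.45, n_cells = 6, seed = 42)
dffs <- sapply(sim$traces, function(tr)
  fit_boltzmann(extract_fv_points(tr, sim$protocol,
                                  background = sim$background))$dff)
sprintf("mean dF/F = %.3f +/- %.3f (n = 6; truth 0.45)",
        mean(dffs), sd(dffs) / sqrt(6))
#> [1] "mean dF/F = 0.450 +/- 0.003 (n = 6; truth 0.45)"

100 * fret_efficiency(4.06, 3.08)   # donor-only vs tandem-construct lifetime
#> [1] 24.13793
```

The quenching curve peaks where a 25 Å DPA displacement produces the
largest fractional fluorescence change: a donor there is maximally
sensitive to leaflet hopping. Measured quenching of 0.30 is consistent
with either a membrane-proximal (~6 Å) or distal (~40 Å) position — the
two limbs of the humped curve — and disambiguation needs a second donor
color or a reference structure. The simulated six-cell experiment
recovers the generator's true ΔF/F of 0.45 with a standard error at the
few-per-mil level, and the lifetime pair 4.06 → 3.08 ns corresponds to
24% FRET efficiency.

Note that the curve's top is very flat (between 22 and 24 Å the value
changes only in the fourth decimal), so the reported peak location is
sensitive to the evaluation grid; see the methods vignette
(`vignettes/dpa-fret-topography.Rmd`) for the full discussion.

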