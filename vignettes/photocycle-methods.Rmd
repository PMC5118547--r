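---
title: "Models and methods behind the photocycle package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the photocycle package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photocycle)
```

## Scope

This package implements the quantitative analysis chain used to
characterize light-driven ion-pumping rhodopsins — in particular inward
proton pumps of the xenorhodopsin family — from four kinds of measurement:
flash-photolysis transient-absorption surfaces, slow single-wavelength
adaptation kinetics, steady-state absorption spectra with HPLC isomer
compositions, and pH traces of illuminated cell suspensions.  Because raw
instrument data for such studies are typically published only as figures, a
seeded synthetic-data module generates every input at the study's
conditions, so the full chain is testable end to end and every analysis
stage can be validated by parameter recovery.

## The kinetic model

A photocycle is modelled as a continuous-time first-order reaction network
over spectrally distinct states.  A flash promotes a fraction $\phi$ of
molecules from the resting state into the primary photoproduct; thereafter
the populations obey

$$\frac{\mathrm{d}\mathbf p}{\mathrm{d}t} = K \mathbf p,$$

where $K_{ji} \ge 0$ ($i \ne j$) is the rate of the $i \to j$ transition
and each diagonal entry is minus its column's off-diagonal sum, so total
population is conserved.  The solution
$\mathbf p(t) = V e^{\Lambda t} V^{-1}\mathbf p_0$ is evaluated by
eigendecomposition.  This is exact at any $t$ and indifferent to
stiffness, which matters here: the default cycle spans almost eight decades
(microseconds to a hundred seconds), where step-wise integration is either
slow or inaccurate.  Only when the eigensystem is defective or
near-degenerate (relative eigenvalue gap below $10^{-9}$, e.g. two
deliberately equal rates) does the propagator fall back to stiff ODE
integration (`lsoda`, rtol $10^{-10}$) and flag the result.  The test suite
holds the analytic propagator to within $10^{-8}$ of a dense ODE oracle on
random chains with rates spanning eight decades, and row sums to 1 within
$10^{-10}$.

The default scheme is the strictly sequential irreversible chain

$$\mathrm{K} \xrightarrow{2\,\mu s} \mathrm{L}
  \xrightarrow{210\,\mu s} \mathrm{M_1}
  \xrightarrow{6.0\,ms} \mathrm{M_2}
  \xrightarrow{200\,ms} \mathrm{P_{13C}}
  \xrightarrow{91\,s} \mathrm{ground},$$

parameterized directly by the five observed lifetimes.  The biphasic
accumulation of the deprotonated-Schiff-base M state is represented by two
sequential states: M$_1$ carries a 50/50 superposition of the L and M bands
(standing in for an L/M equilibrium whose forward and backward rates are
not known), M$_2$ the pure M band.  This reproduces the observed two-step
M rise in a chain that remains triangular, hence analytically exact.
Reversible edges are fully supported by the rate-matrix machinery —
apparent time constants then come from the (no longer triangular)
eigenvalues — but no equilibrium rates are assumed by default; users who
know them supply their own scheme.  The photoexcited fraction per flash is
instrument-dependent and never printed in such studies; it enters only as
an overall amplitude scale, defaulting to $\phi = 0.05$, a typical
single-flash conversion.

Observable phases are the reciprocals of the nonzero eigenvalues of $K$.
For triangular (irreversible sequential) schemes the implementation reads
them off the diagonal, so they equal the edge lifetimes exactly rather than
to solver precision.  Complex eigenvalues are rejected: first-order
networks with non-negative off-diagonal rates of this kind should not
oscillate, and a complex pair indicates a mis-specified scheme.

Synthetic surfaces follow
$\Delta A(t,\lambda) = \sum_s p_s(t)\,[\varepsilon_s(\lambda) -
\varepsilon_\mathrm{g}(\lambda)]$: molecules that never left the ground
state cancel exactly, so $\Delta A$ is linear in $\phi$, and the late-time
surface converges to the (terminal photoproduct $-$ ground) difference
spectrum — the behaviour that identifies a long-lived 13-*cis* state when
the signal fails to return to zero within the observation window.

## Global fitting by variable projection

The measured surface is fit with the separable model

$$\Delta A(t, \lambda) \approx \sum_{i=1}^{n} \mathrm{DAS}_i(\lambda)\,
  e^{-t/\tau_i} + A_\infty(\lambda),$$

with time constants shared across wavelengths.  For any candidate
$\boldsymbol\tau$ the amplitudes solve an ordinary linear least-squares
problem per wavelength; the implementation solves it exactly (one QR
factorization for all wavelengths) and lets the Levenberg–Marquardt
optimizer see only the $n$ nonlinear parameters — the variable-projection
formulation.  This has three practical consequences: the optimizer works in
an $n$-dimensional space regardless of how many wavelengths are probed, the
decay-associated spectra (DAS) are exact conditional optima (the suite
verifies that perturbing any single DAS value raises the RSS), and the fit
is invariant to wavelength permutation and to uniform rescaling of the
data.

Numerical choices:

* **Log-space optimization.** Time constants are optimized as
  $\log_{10}\tau$ with box bounds three decades beyond the observation
  window.  The dynamic range of a photocycle (eight decades) makes linear
  parameterization hopeless.
* **Multi-start.** Initial values matter in multi-exponential fitting; the
  default is 8 starts — one deterministic log-spaced ladder across the
  window, the rest seeded log-uniform draws — keeping the best final RSS.
  Ties are broken toward the smallest spread of log-lifetimes, which makes
  the result deterministic for a given seed.
* **Mandatory offset for truncated windows.** When the slowest process
  (91 s) far outlives the window (2 s), it is statistically a constant; the
  offset spectrum $A_\infty$ absorbs it.  Fitting it as a fifth exponential
  instead would be unidentifiable.
* **Resolution warning.** Two recovered constants within 5% of each other
  flag the fit as "unresolved": the data cannot distinguish them.
* **Weights.** Uniform by default; per-point standard deviations are
  accepted and applied as inverse weights.

Model order is selected by refitting at $n = 0, 1, \dots, n_\mathrm{max}$
and taking the smallest order whose successor improves the RSS by less than
5% (relative).  On the default synthetic surface this selects 4; on pure
noise it selects the offset-only model.

The slow dark-adaptation recovery is fit separately as a single-wavelength
trace (the same engine, one column): the two experiments are measured on
different instruments over disjoint time ranges, and a joint fit would
pretend to information that is not there.

The proton-donor logic for M-decay kinetics works on rise+decay
biexponential fits per pH: if the Schiff base were reprotonated from the
aqueous phase, the M decay would slow roughly tenfold per pH unit; a decay
lifetime that fails to increase with pH (no successive increase beyond a
factor 1.5 by default) therefore indicates an internal donor, a
monotone increase beyond that factor indicates aqueous uptake, and
anything non-monotonic is reported as indeterminate rather than forced
into a class.

## Spectral unmixing and band positions

With isomer fractions known from HPLC, the dark- and light-adapted spectra
are a $2\times2$ linear system per wavelength in the pure all-*trans* and
13-*cis* spectra, solved in closed form.  The determinant is the fraction
difference; below 0.05 the system is refused as ill-conditioned rather
than silently amplifying noise.  Negative recovered absorbances are
reported with a warning, never clipped — they are the natural diagnostic of
wrong input fractions.  Band maxima are located by parabolic interpolation
through the top three samples and reported at fixed 0.1 nm resolution so
results are deterministic; boundary maxima are an error (the band is not
inside the scanned range), and flat plateaus return their midpoint with a
warning.

Synthetic bands are Gaussians in wavenumber ($1/\lambda$), FWHM
3800 cm$^{-1}$, the standard lineshape class for retinal-protein visible
bands; band centres default to 568 nm (pure all-*trans*), 549 nm (pure
13-*cis*), K at +20 nm and L at $-30$ nm from the ground band, and the M
band at 410 nm — a stated assumption, standard for deprotonated-Schiff-base
states, since such studies print no M-band position.  The light-adapted
all-*trans* fraction defaults to 0.50 ("equally distributed" is the usual
qualitative statement); it is configurable.

## HPLC quantification

Peak detection uses topographic prominence above $3\times$ the noise level
(median absolute deviation of the first-differenced signal, scaled by
$\sqrt2$).  Each assignment window — up to two windows per isomer, for the
syn and anti oxime forms, whose areas are summed — is integrated by the
trapezoidal rule after subtracting a straight baseline anchored at the
window edges.  Molar fractions are area ratios, which assumes equal molar
detector response across oxime isomers; that assumption is documented
rather than corrected for, as no response factors are available.  Replicate
statistics use the sample (n−1) standard deviation.  Integration of
well-separated synthetic Gaussian peaks is accurate to better than 1% at
the default signal-to-noise.

## Pumping-assay analysis

Initial slopes are ordinary least-squares fits of pH against time over a
30 s window from light-on (the illumination period spans 0–150 s; "initial"
is not standardized, so the window length is configurable).  Slopes stay in
pH units per second — converting to proton fluxes would require the buffer
capacity of the cell suspension, which is rarely known; a conversion hook
exists but is off by default.  Expression normalization uses hydroxylamine
bleaching: the pigment band referenced to the 360 nm retinal-oxime band
($\varepsilon = 33{,}600\ \mathrm{M^{-1}cm^{-1}}$) yields the pigment's
extinction coefficient and the expressed amount; activities are slopes per
mole, and activity *ratios* between samples are invariant to the oxime
reference value.

Transport classification over a salt × CCCP panel follows the standard
condition logic: a proton pump alkalinizes the medium in every salt and is
abolished by the protonophore CCCP (slope below 20% of its CCCP-free
value); an inward chloride pump requires chloride (abolished in sulfate)
and is *accelerated* by CCCP (above 150%), which relieves the opposing
membrane potential.  Both thresholds are configurable with those defaults.
Panels that fit neither pattern are "none/indeterminate", and a missing
CCCP counterpart is an error, not a guess.

## The synthetic generators

Every generator draws from a fixed substream of one master seed, so
identical configurations give bit-identical data and adding a generator
never perturbs existing fixtures.  Defaults encode the study conditions:
the five lifetimes above; probe wavelengths 360–710 nm in 10 nm steps;
logarithmic times, 30 points per decade from 100 ns to 2 s (sampling grids
are not usually printed; logarithmic coverage of the window is the natural
choice); surface noise s.d. $5\times10^{-4}$; a 600 s, 1 Hz dark-adaptation
trace at 585 nm with noise $10^{-3}$; chromatograms with dark 92:8 and
light 50:50 compositions; and assay panels with base slope
$2\times10^{-3}$ pH s$^{-1}$, suspension saturation constant 200 s (chosen
so the 30 s slope window underestimates the true initial derivative by
under 8%), pH noise $2\times10^{-3}$, and genotype multipliers (wild type
1×, the hyperactive acceptor mutant 3×, impaired mutants 0.05–0.12×)
together with matched bleach spectra so normalization is exercised.

What the generators deliberately do **not** emulate: instrument response
functions and photon shot noise (noise is additive Gaussian), excited-state
(femtosecond) dynamics and quantum yields, temperature dependence of rates,
HPLC gradient drift and retention-time calibration, and action-spectrum
differences between spectrally shifted mutants.  Passing recovery tests on
these fixtures therefore demonstrates the correctness of the estimators
under the stated noise model, not robustness to every artifact of real
instruments.

## Suite sizing

The test suite and the acceptance script regenerate all data at run time;
sizes were chosen so the whole suite runs in seconds: surfaces are
220 × 36 points, stochastic-recovery properties use 12 seeded replicates
(median relative error per recovered lifetime must stay below 10%), the
unmixing-bias property uses 200 replicates of a cheap closed-form solve,
and the oracle-equivalence property uses five random chains of 3–6 states.

## Known limitations

* Decay-associated spectra are descriptive, not mechanistic: with a
  sequential scheme the DAS are linear mixtures of species difference
  spectra, and sign patterns must be interpreted through a scheme.  Target
  analysis (fitting a branched scheme directly to the surface) is out of
  scope.
* The eigen-propagator assumes a diagonalizable rate matrix; genuinely
  defective schemes are handled by the slower ODE path.
* `findLambdaMax` assumes a locally parabolic band top; heavily overlapped
  double maxima should be unmixed first.
* Classification rules are threshold logic, intentionally transparent; they
  do not attach probabilities.
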