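---
title: "Models and methods behind forcequench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind forcequench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(forcequench)
```

`forcequench` simulates and analyses force-clamp AFM recordings of SN2
thiol–disulfide exchange in an eight-repeat I27 polyprotein. This vignette is
the package's account of the models it implements, the parameters that
matter, the numerical choices, and what the passing test suite does and does
not demonstrate.

## The physical model

All computations are at 298 K with `kT = 4.114 pN nm = 0.5925 kcal/mol`
(`fc_constants()`). Forces are in pN, distances internally in nm (Ångström at
the interface), energies in units of kT with explicit conversion from
kcal/mol.

**Cleavage kinetics.** Each solvent-exposed disulfide is cleaved by the
deprotonated thiol at the Bell/Arrhenius rate

$$ r(F) = A\,[\mathrm{S^-}]\,e^{-\Delta G^\ddagger}\,e^{F\Delta x/kT}, $$

with $A = 10^7\ \mathrm{M^{-1}s^{-1}}$ treated as exact,
$[\mathrm{S^-}]$ from the Henderson–Hasselbalch fraction
$1/(1+10^{\mathrm{p}K_a-\mathrm{pH}})$ times the total concentration,
$\Delta G^\ddagger$ the zero-force activation barrier in kT and $\Delta x$
the distance to the transition state. The inverse map
$\Delta G^\ddagger = \ln(A/r_0)$ (`barrier_from_rate()`) and the log-linear
force dependence are exact identities, and the test suite checks both as
machine-precision round trips.

**Reformation thermodynamics.** Reformation of the native bond during a
zero-force quench is the reverse of reduction. With the reduction standard
free energy $\Delta G^\circ$ (negative = reduction spontaneous), the
two-state partition gives
$p_\mathrm{reform} = 1/(1+e^{-\Delta G^\circ / kT})$: exactly 0.5 at
$\Delta G^\circ = 0$ (the cysteine/cystine 50:50 equilibrium), vanishing for
strong reducers such as mesna. `quench_partition()` also offers a three-state
Boltzmann variant that adds the fully-reduced protein (mixed disulfide
attacked by a second solution thiol, producing the thiol homodimer) with
energy $(\Delta G^\circ + \Delta G^\circ_\mathrm{homodimer})/kT$, and an
empirical linear model in pKa (below). The 8 s quench is treated as long
enough for thermodynamic control, so the partitions are time-independent; a
first-order relaxation $p(t) = p_\mathrm{eq}(1-e^{-k_\mathrm{rev}t})$ is
available for sensitivity analysis only.

**The three-level landscape.** `build_landscape()` reduces the profile to
reactant (0), transition state ($\Delta G^\ddagger - F\Delta x/kT$) and
product ($\Delta G^\circ/kT$). The tilted barrier is floored at the higher
well so the object remains a barrier-crossing picture at forces beyond the
regime the assays probe; the flooring is a representational clamp, not a
kinetic claim.

## The compound table

`inst/extdata/compounds.json` holds one record per thiol. Choices worth
stating:

* **Barriers.** For NAC (10.6 kT) and glutathione (11.7 kT) the packaged
  barriers are the values the landscape analysis is expected to recover. For
  Cys-ME, penicillamine and L-cysteine no barrier is tabulated anywhere, but
  their 350 pN cleavage rates at 2 mM thiolate (0.40, 0.58, 2.48 s$^{-1}$)
  are; the packaged barriers invert the Bell relation at those rates with
  $\Delta x = 0.35$ Å, so the generative truth of a simulated cohort *is* the
  experimentally reported kinetics. The remaining four compounds carry
  plausible intermediate barriers.
* **$\Delta x$** is set to 0.35 Å uniformly. Only the 0.33–0.37 Å range is
  established experimentally, per-compound values are not, and the
  "almost parallel" semi-log lines are reproduced by construction.
* **pKa** values are literature-typical numbers spanning ~7–10 (penicillamine
  below cysteine); they are inputs, not results, and everything downstream is
  parameterized by the table.
* **Concentrations.** The controlled experimental variable is the
  *deprotonated* concentration; the table stores total concentration plus pH
  so that the active concentration at pH 7.5 equals the design values: 2 mM
  for the three slow nucleophiles of the fixed-force assay, 1 mM for the
  reformation compounds, and 0.2 / 0.5 mM for NAC / glutathione in the force
  series. The last two are a design choice made once: at 500 pN they keep the
  per-domain cleavage rate below ~4 s$^{-1}$, i.e. resolvable at 1 kHz
  sampling, which is how a force spectroscopist would choose them.
* **Synthetic placeholders.** `dG0_homodimer_kcal_mol` (zero for cysteine by
  cystine symmetry) and the sulfur partial charges `s_charge_e` are editable
  placeholder fixtures, clearly not measured values.

## What the simulator emulates

`simulate_kinetics_trace()` draws per-domain unfolding times from a
force-dependent exponential clock
($k_u(F) = k_u^{150}\,e^{(F-150)\Delta x_u/kT}$, default 10 s$^{-1}$ at
150 pN with $\Delta x_u = 2.5$ Å — chosen so that typically at least five of
the eight domains unfold within the 0.5 s pulse) and cleavage times from an
independent exponential clock per domain, started at that domain's unfolding
time, with the piecewise-constant Bell rate of the protocol segment. Step
sizes are force-independent Gaussians (15 ± 1 nm unfolding, 10 ± 1 nm
reduction); the ideal staircase is passed through a first-order feedback
settling filter (τ = 2 ms, which also stands in for the instrument's 1 kHz
Bessel filtering) and white Gaussian noise (1 nm SD) is added at 1 kHz
sampling. Ground truth is carried in a `true_events` attribute that the
detector never sees.

`simulate_reformation_trace()` replays the same physics through the
five-pulse protocol. During the quench the extension is rendered as ~0 plus
noise; every cleaved bond is assigned an outcome by the chosen quench model,
and all unfolded domains are assumed to refold within the 8 s quench
(refolding kinetics are bookkeeping, not simulated mechanics). In the second
unfolding pulse, domains with a disulfide (intact or reformed) unfold again
as ~15 nm events; bond-less domains re-extend fully at the pulse onset,
inside the settling mask. Only reformed bonds can re-cleave during the probe
pulse. Two realistic artifacts follow and are worth knowing about: domains
that never cleaved in the first high-force pulse can cleave in the probe
pulse (inflating the scored fraction for slow nucleophiles), and reformed
bonds that fail to re-cleave within the probe leave an extension mismatch.
The same-length filter removes most of both, exactly as the experimental
filter would.

What the generator does **not** emulate: worm-like-chain elasticity (step
sizes are fixed Gaussians, extensions are piecewise constant), cantilever
drift or surface detachment, force-dependent step sizes, refolding mechanics
during the quench, and any positional dependence of the disulfide within the
fold. Passing tests therefore demonstrate that the analysis recovers the
parameters of *this* generative model, with the same filters and failure
modes an analyst would face — not that it is robust to every artifact of
real AFM data.

**Seeding.** Every stochastic function takes a `seed`; cohorts derive one
child seed per trajectory by a position counter on the (compound, force,
replicate) grid, so cohorts are reproducible and order-independent, and
distinct trajectories never share an RNG stream.

## Step detection and filtering

Detection is deliberately simple: binary segmentation on the mean within each
constant-force segment, with penalty $10\,\hat\sigma^2\log n$
($\hat\sigma$ from the MAD of first differences — about five times the
spurious-split threshold $2\sigma^2\log n$, tuned once on packaged fixtures),
minimum plateau length `min_dwell_s` (4 ms), and minimum jump `min_step_nm`
(5 nm); sub-threshold jumps are merged iteratively. Plateau levels are means
taken after discarding the feedback-settling window; plateaus shorter than
that window fall back to the settling-deconvolved signal (the one-pole filter
is inverted exactly, trading amplified noise for unbiased levels). The first
time constant after a plain force step is masked from detection; segments
bordering a quench (collapse, bulk re-extension) are masked for the full
~5τ settling of those large excursions.

Classification uses the fingerprint windows 15 ± 4 nm (unfolding) and
10 ± 3 nm (reduction, test/probe pulses only), nearest-window-centre in the
1–2 nm overlap, exact ties left unclassified. Two events closer than the
detector's dwell/settling resolution appear as a single step of summed size,
so each class also has a compound window at twice the single-event size
([17, 26] nm for reductions in the high-force pulses, [22, 38] nm for
unfolding): such steps are scored as two events of half size. The
compound-reduction window starts at 17 nm so genuine ~15 nm unfolding steps
in the high-force pulse are still classified as unfolding — traces showing
them are rejected, preserving the original acceptance rule. Trace filters are
exactly the published ones: 5–8 unfolding events, 5–8 reductions in the test
pulse, no unfolding in the test pulse; for reformation recordings 5–8
first-pulse ruptures and equal initial/probe extensions within 10 nm (one
reduction step — the rule names no tolerance, so the package uses the
smallest step that would signal a missing event).

Residual, quantified imperfections: in the crowded unfolding pulse (aggregate
initial rate ~80 s$^{-1}$ at the default unfolding kinetics) partly-merged
pairs bias individual size estimates so the mean detected unfolding size
sits ~0.3 nm (2%) below the generative 15 nm, and ~2% of events are lost
outright. Both are measured by the test suite on seeded cohorts and stay
within the 0.5 nm fingerprint tolerance; the reduction-class mean is within
~0.1 nm.

## Kinetics, bootstrap, and the landscape fit

`sum_and_normalize()` rebuilds each accepted trace's cumulative reduction
extension from its detected events, aligns it at the test-pulse onset,
normalizes by the trace's own total reduction extension, resamples onto a
common 400-point grid (traces ending early are held at their final value;
censoring is negligible because pulse lengths are sized to about five
expected lifetimes, and `fit_exponential()` warns below three), and averages
pointwise. The fit is unweighted least squares of $1-e^{-rt}$ with the rate
kept positive by optimizing on $\log r$; no offset or amplitude parameter,
since the curve is normalized by construction. `bootstrap_rate()` resamples
recordings with replacement (default 500 resamples), refits each resample,
and reports the spread as the SD; the point estimate is the fit to the full
ensemble, not the bootstrap mean.

`fit_bell()` regresses $\ln(r/[\mathrm{S^-}])$ on force, weighted by inverse
delta-method variances of the log rates ($\mathrm{sd}(\ln r) =
\mathrm{sd}(r)/r$) when bootstrap SDs are present. Regressing on the log
scale rather than fitting the exponential directly matches the straight-line
semi-log presentation of the data and makes the noiseless case an exact
identity. Barrier uncertainty propagates the intercept SE only, with $A$
exact. `fit_pka()` fits the titration logistic with free plateaus by
`nls(algorithm = "port")`, which is robust in the zero-residual limit;
degenerate (flat or decreasing) data are rejected before fitting.

## Reformation scoring and its models

`score_reformation()` pools accepted recordings event-wise: total probe-pulse
re-cleavage events over total first-pulse ruptures, with a bootstrap over
recordings (each recording an independent data point) for the SD. Pooling
event-wise rather than averaging per-trace fractions is a choice; the
bootstrap quantifies the recording-level variability either way.

The pure two-state model predicts near-total reformation for any compound
with $\Delta G^\circ > 0$ and near-zero otherwise — the thermodynamic limits.
The observed behaviour across compounds is a *graded* linear trend in pKa,
which the free energies alone do not reproduce (they ignore steric access
and the protein context). The package therefore ships `empirical_linear`
($p_\mathrm{reform} = \mathrm{clamp}(a\,\mathrm{p}K_a + b,0,1)$, packaged
$a = -0.35$, $b = 3.25$, spanning ~0.8 at pKa 7 to 0 above pKa ~9.3) as the
generative default for simulating compound screens, and the Boltzmann models
for the thermodynamic end-members. Cys-ME reformation cohorts use a 3 s
high-force pulse (5 s for the others), matching the experimental protocol;
the probe pulse defaults to the test-pulse length, keeping the protocol
symmetric.

## Problem sizes and determinism

The packaged checks use the cohort sizes the analyses are designed around:
200 recordings per compound for the fixed-force rates, 100 per force across
300–500 pN for the landscape fits, 50 five-pulse recordings for the
reformation fraction, 500 bootstrap resamples, and $10^4$ draws for the
waiting-time distribution checks. Module tests use smaller seeded cohorts
(20–100 traces) where the property under test does not need ensemble
precision. All randomness flows from explicit seeds; identical seeds give
bit-identical trajectories, files and estimates.

## Known limitations

* The detector's effective resolution is ~4–6 ms; faster event pairs are
  recovered as compound steps (count-correct, half-size) and the unfolding
  size distribution acquires mild tails, as quantified above.
* Rate recovery degrades when per-domain rates approach the inverse
  resolution (~10 s$^{-1}$ at the defaults); the packaged concentrations keep
  the force series below that regime, and users changing concentrations or
  forces should check acceptance rates and the censoring warning.
* The reformation fraction can exceed 1 for slow nucleophiles (intact bonds
  cleaving only in the probe pulse); the extension-match filter suppresses
  but does not eliminate this.
* The three-state quench model consumes homodimer free energies that are
  placeholders; conclusions from `boltzmann3` should be drawn only after
  replacing them.
* Everything is at 298 K; no temperature dependence is modelled.
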