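---
title: "Models and methods: from FRAP recovery to proteome charge"
author: "cytodiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: from FRAP recovery to proteome charge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytodiff)
```

# Overview

Positively charged proteins diffuse dramatically more slowly in the bacterial
and archaeal cytoplasm than negative ones — up to two orders of magnitude —
because they associate nonspecifically with the RNA-rich surface of
ribosomes. `cytodiff` implements the quantitative chain that turns
fluorescence-recovery-after-photobleaching (FRAP) measurements of charged GFP
variants into a screened-electrostatics description of that association:

1. **FRAP fitting** (`fitFrap`): a numerical 1D diffusion model fitted to
   line-profile recovery stacks yields an effective diffusion coefficient
   $D_{\mathrm{eff}}$ per cell.
2. **Two-state algebra** (`effectiveDiffusion`, `freeFraction`,
   `boundFraction`, `kdFromBoundFraction`): under fast exchange between a
   free and a ribosome-bound state,
   $D_{\mathrm{eff}} = f_{\mathrm{free}} D_{\mathrm{free}} +
   (1 - f_{\mathrm{free}}) D_{\mathrm{bound}}$, which converts
   $D_{\mathrm{eff}}$ into a bound fraction and, through a geometric census
   of ribosome surface sites (`estimateSites`), into a dissociation constant.
3. **Electrostatics** (`bindingFreeEnergy`, `fitIonic`, `deffOfCharge`,
   `fitChargeModel`): the ionic-strength dependence of $K_d$ and the charge
   dependence of $D_{\mathrm{eff}}$ are described by a screened
   (Debye–Hückel-type) binding free energy.
4. **Proteome charge** (`netCharge`, `isoelectricPoint`,
   `proteomeDistribution`): Henderson–Hasselbalch net-charge and pI
   calculations put the probe charges in the context of whole proteomes.

Because the original microscope stacks are not deposited, every input can be
generated synthetically with known ground truth (`generateFrapStack`,
`simulateSwitchingWalk`, `generateProteome`), and the test suite exercises
the full chain against those planted truths.

# The FRAP forward model and fit

## Diffusion solver

A bleached fluorescence profile $I(x, t)$ along the long axis of a cell
relaxes by 1D diffusion,
$\partial_t I = D\, \partial_x^2 I$, with **no-flux (reflecting) boundaries**
at the cell poles: no particles cross the ends of the line. `evolveProfile`
integrates this with a Crank–Nicolson scheme on the pixel grid. Internal
sub-steps keep the diffusion number $D\,\Delta t/\Delta x^2 \le 1$; in that
regime the one-step update matrix has non-negative entries with unit row
sums, so the solver obeys the discrete maximum principle, and its column
sums are exactly one, so total intensity is conserved to machine precision.
Sub-steps are exact divisors of the frame interval, so no temporal
interpolation is ever needed; the per-frame propagator is formed once per
distinct frame gap (as a matrix power) and reused.

The solver is validated against the free-space closed form: an initial
Gaussian of width $\sigma_0$ spreads to variance $\sigma_0^2 + 2 D t$
(variances of independent Gaussian displacements add under convolution).
On a domain much wider than $\sqrt{2 D t_{\max}}$ the numerical solution
matches this oracle to a relative $L_2$ error below $10^{-3}$.

## Fitting $D$

`fitFrap` takes the **first post-bleach frame verbatim** as the initial
condition — no parametric bleach shape is assumed — and minimises the squared
deviation between the forward model and all subsequent frames. Two nuisance
parameters, a global multiplicative scale and an additive offset, absorb
acquisition photobleaching and background; for fixed $D$ they have a
closed-form least-squares solution, so the outer problem is a bounded scalar
search over $\log_{10} D$ (coarse 25-point grid, then golden-section
refinement to $10^{-4}$). Default bounds $(10^{-3}, 50)\ \mu m^2/s$ span
everything from membrane proteins to free GFP. The fit is deterministic.

**Normalisation.** When a mean pre-bleach profile is available, the stack is
divided by its *smooth component*: a quadratic fit in position, reduced to
the scalar mean when an F-test (at 0.05) finds no evidence of an illumination
gradient. Dividing by the raw pre-bleach average — typically a mean of only
three frames — would stamp that profile's pixel noise onto every frame as a
static pattern; in simulations at 2% read noise this *doubles* the standard
deviation of the fitted $D$. The gated smooth keeps the intended behaviour
(a genuine illumination gradient is detected and removed) without the noise
injection.

**Identifiability.** A stack whose first-frame dynamic range is below three
times the noise level (estimated from temporal differences over the final
20% of frames) carries no bleach information; it is flagged rather than
fitted, mirroring the ~10% of measured cells that are excluded in practice
for showing no usable bleach.

# The two-state fast-exchange model

When the probe exchanges between free and bound states much faster than the
measurement, the displacement distribution over a frame interval is the
convolution of two Gaussians with variances
$2 D_{\mathrm{free}} f_{\mathrm{free}} \Delta t$ and
$2 D_{\mathrm{bound}} (1 - f_{\mathrm{free}}) \Delta t$, i.e. one Gaussian
with variance $2 D_{\mathrm{eff}} \Delta t$ — a single effective coefficient.
`simulateSwitchingWalk` validates this directly: a two-state switching random
walk at stationary $f_{\mathrm{free}} = 0.5$ between 10 and 0.04 $\mu m^2/s$
with fast exchange yields $D_{\mathrm{eff}} = 5.02\ \mu m^2/s$ within
simulation error and Gaussian displacements, while slow exchange produces the
tell-tale heavy-tailed two-Gaussian mixture (positive excess kurtosis).

Inverting the relation requires choosing $D_{\mathrm{free}}$ and
$D_{\mathrm{bound}}$: the fastest probe variant in each organism defines the
free state, and the ribosome–mRNA coefficient 0.04 $\mu m^2/s$ defines the
bound state. `freeFraction` clamps measurement noise that pushes
$D_{\mathrm{eff}}$ outside $[D_{\mathrm{bound}}, D_{\mathrm{free}}]$ into
$[0,1]$ with a flag rather than erroring, so population histograms can be
processed.

## The binding-site census

The dissociation constant follows from
$f_{\mathrm{bound}} = [\mathrm{site}]/(K_d + [\mathrm{site}])$, valid when
sites far outnumber probes. The site concentration comes from a
back-of-the-envelope census: a 20 nm spherical ribosome has a surface of
1260 nm² (3 s.f.), half of it RNA (630 nm²); a 3.5 nm probe covers 9.6 nm²
(2 s.f.); the ratio gives 66 sites per ribosome, hence 660 µM of sites at
10 µM ribosomes. `estimateSites` performs the census **on those
reported-precision intermediates**, because that is how the published
arithmetic is defined: carried at full precision the ratio is 65.3 and would
round to 65, not the published 66. The function documents this choice; the
difference is immaterial downstream (1.5%).

We also note, without attempting to resolve it, that the cited density of
17000 ribosomes/µm³ corresponds to ~28 µM by Avogadro arithmetic, not the
printed 10 µM; the census takes the printed concentration as its input.

# Screened electrostatic binding

The ionic-strength dependence of the binding free energy uses the
semi-empirical form (originally applied to thrombin–hirudin association)

$$\Delta G_b(I) = \Delta G_{nio} + \Delta G_{io}^0\,
  \frac{e^{-C_1 \sqrt I}}{1 + C_1 \sqrt I},$$

with $K_d = e^{\Delta G_b / RT}$ at a 1 M standard state and $T = 293$ K by
default. The $\sqrt I$ placement of the radical is confirmed numerically:
only this reading reproduces the published parameter triple
$(\Delta G_{nio}, \Delta G_{io}^0, C_1) = (-20\,400\ \mathrm{J/mol},
-28\,900\ \mathrm{J/mol}, 1.53)$ from the three published $(I, K_d)$ points
(0.2 M/6.7 µM, 0.8 M/65 µM, 2.1 M/155 µM) — a check the test suite performs.

`fitIonic` fits in $\Delta G$ (log-$K_d$) space, which equalises the ~20-fold
dynamic range of the $K_d$ values; with three points the solution
interpolates, so the fitting space does not affect the published-triple
check. For fixed $C_1$ the two free energies enter linearly and are profiled
out, leaving a deterministic 1D search over $C_1$ (multi-start grid
$\{0.5, 1, 1.5, 2, 3\}$ plus golden-section refinement).

## Charge dependence and identifiability

Assuming the electrostatic term is linear in probe net charge,
$\Delta G_{io}^0 = \Delta G_{pc} \times q$, composing the four relations
gives `deffOfCharge`:

$$D_{\mathrm{eff}}(q) = \left(1 - \frac{[\mathrm{site}]}
 {[\mathrm{site}] + e^{\Delta G_b(q)/RT}}\right)
 (D_{\mathrm{free}} - D_{\mathrm{bound}}) + D_{\mathrm{bound}}.$$

An important structural point: at a **single** fixed ionic strength,
$\Delta G_{pc}$ and $C_1$ enter only through the product
$\Delta G_{pc} \cdot e^{-C_1\sqrt I}/(1 + C_1\sqrt I)$ — they form a ridge
and cannot be separately recovered from one organism's charge series. This
is a plausible source of the reported discrepancy between per-organism
parameter sets. `fitChargeModel` therefore supports three modes: fixed
$C_1$ (recommended for single-organism data; use the `fitIonic` value),
a free-$C_1$ fit (returns one point on the ridge; only $\Delta G_{nio}$
and the product are meaningful), and a pooled fit with per-point ionic
strengths, in which all three parameters are identifiable. Fitting is least
squares on $\log_{10} D_{\mathrm{eff}}$, weighting slow probes fairly, with
a deterministic multi-start grid refined by `nlminb`. A fit whose optimum
binds nothing anywhere (all bound fractions $< 10^{-6}$, e.g. when all
$D_{\mathrm{eff}}$ equal $D_{\mathrm{free}}$) is flagged as a boundary
solution.

# Protein net charge and isoelectric point

`netCharge` evaluates the Henderson–Hasselbalch sum

$$Z(\mathrm{pH}) = \sum_{b \in \mathrm{basic}} \frac{n_b}{1 + 10^{\mathrm{pH} - pK_{a,b}}}
 - \sum_{a \in \mathrm{acidic}} \frac{n_a}{1 + 10^{pK_{a,a} - \mathrm{pH}}}.$$

Two modes exist. `"ipc"` titrates all groups (termini, D, E, C, Y, H, K, R)
against the IPC_protein pKa set of the Isoelectric Point Calculator;
`"counting"` is the classic approximation counting only D, E, K, R (plus
termini, so that its group structure is a strict subset of ipc mode's)
against an EMBOSS-style textbook table. Both tables ship as versioned CSV
data files; nothing is hard-coded. For a GFP-sized protein the counting mode
typically sits 1–2 charge units above the ipc mode, driven mainly by
cysteine titration (IPC pKa 7.56 — half-deprotonated at pH 7.5) and the
lower IPC lysine pKa. The default pH of 7.5 is a standard cytoplasmic value.
Ambiguity codes (B, Z, X, U, O, J) are non-titratable and warn once per
record.

$Z$ is strictly decreasing in pH, so the isoelectric point is the unique
root; `isoelectricPoint` bisects until $|Z| < 10^{-4}$ and agrees with a
0.001-pH brute-force grid scan to better than 0.002 pH units (a test
oracle). Proteome histograms (`proteomeDistribution`) use unit-width charge
bins centred on integers and 0.25-pH pI bins — conventions chosen here, as
none are published — and can weight proteins by copy number. GO filtering
(`filterCytoplasmic`) selects on the UniProt cytoplasm/cytosol labels
GO:0005737 and GO:0005829.

# Synthetic data: what it emulates, what it does not

`generateFrapStack` emulates the stated acquisition world: a flat pre-bleach
profile in a 3 µm cell, a Gaussian pole bleach (depth 0.6, width one pixel —
the published images show, but do not parameterise, the bleach), 8 pixels /
50 frames / 4 ms for fast probes, and additive homoscedastic Gaussian read
noise (2% of the pre-bleach intensity by default). Poisson shot noise is a
documented non-default option. `frapAcquisition` reproduces the published
protocol change for slow probes (16 pixels, 100 frames, longer intervals, so
the record spans ~3 diffusion times).

The generator does **not** model photophysics (blinking, reversible
bleaching), 3D cell geometry, the confocal point-spread function, nucleoid
exclusion, or cell-to-cell variability in expression level. A green recovery
test therefore establishes that the estimator is accurate *in the stated
world* — unbiased forward model, known noise — not that real-microscope
systematics are handled.

`generateProteome` draws sequences whose Lys/Asp frequencies are calibrated
so the expected net charge (ipc mode, pH 7.5) hits a target mean; GO tags
are assigned to an exact fraction of records and copy numbers are log-normal
(median ~200, sdlog 1.5, a typical bacterial spread). It stands in for real
proteomes in plumbing tests only; it does not emulate genuine amino-acid
composition, domain structure, or the correlation between abundance and
charge.

# Numerical choices and degenerate inputs

* Diffusion number cap 1 per sub-step (positivity of the propagator);
  outer FRAP search tolerance $10^{-4}$ in $\log_{10} D$; `fitIonic`
  refinement tolerance $10^{-10}$ on the rss.
* `fitFrap` reports `converged = FALSE` when the optimum sits at the search
  bounds; non-identifiable stacks carry `identifiable = FALSE` and no D.
* `freeFraction` clamps with a flag; `kdFromBoundFraction` rejects bound
  fractions of exactly 0 or 1 (infinite/zero $K_d$).
* `fitIonic` rejects fewer than three points or duplicated ionic strengths;
  `fitChargeModel` rejects fewer than four points.
* `simulateSwitchingWalk` rejects (rather than silently degrades) time steps
  with $\Delta t \cdot \max(k_{\mathrm{bind}}, k_{\mathrm{release}}) > 0.1$.
* Quartiles use linear interpolation (`quantile` type 7); both means and
  medians are reported, and which one feeds the two-state inversion is a
  pipeline switch (`statistic`, default `"mean"`, the statistic used for the
  published bound-fraction estimates).

# Pipeline

`runPipeline` composes the tested operations — per-stack fits, per-probe
population summaries, two-state inversion, per-organism $K_d$, cross-organism
`fitIonic`, per-organism `fitChargeModel` with $C_1$ fixed to the ionic-fit
value — and serialises a report (JSON + CSV + log). Failures are isolated
per stack and counted, not fatal. Every number in the report is the output
of one exported function; there is no hidden recomputation. Reports are
deterministic given the configuration and seed.

# Known limitations

* The FRAP model is strictly 1D with reflecting ends; rods are treated as
  lines, and bleaching is assumed instantaneous relative to the first frame.
* The two-state inversion inherits the published assumptions: fast exchange,
  the fastest variant defining the free state, ribosomes as the only binding
  partner, sites in excess, and a shared bound-state coefficient across
  organisms.
* Ion binding to proteins (which measurably lowers effective net charge) and
  context-dependent pKa values are out of scope for the charge calculator.
* The charge-model fit at one ionic strength cannot separate
  $\Delta G_{pc}$ from $C_1$ (see above); only the pooled multi-organism fit
  can.
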