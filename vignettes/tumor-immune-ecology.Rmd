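---
title: "Predator-prey models of tumor-immune ecology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predator-prey models of tumor-immune ecology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunecol)
```

## The models

`immunecol` treats the interaction between a tumor cell population and the
cytotoxic arm of the immune system as an ecological community: tumor cells
are prey, effector cells are predators, and the machinery of population
ecology — functional responses, nullclines, stability, community modules —
becomes the analysis toolkit.

### Functional responses

The per-predator (per-effector) kill rate as a function of prey (target)
density is modeled by the generalized form

$$ f(x) = \frac{b\,x^\alpha}{1 + b\,h\,x^\alpha}, $$

where $b$ is the encounter probability per unit prey density, $h$ the
handling time per capture (the time an effector spends at the immunological
synapse), and $\alpha$ an encounter-scaling exponent: $\alpha > 1$ models an
attraction effect (chemo-attractants), $\alpha < 1$ a dilution effect
(safety in numbers). The classical Holling taxonomy falls out of the
parameters: Type I ($h = 0$, $\alpha = 1$, linear), Type II ($h > 0$,
$\alpha \le 1$, saturating), Type III ($h > 0$, $\alpha > 1$, sigmoidal).
Combinations outside those conditions (e.g. $h = 0$, $\alpha \ne 1$) exist
mathematically but have no classical name; `classify_response()` labels them
`GENERALIZED` rather than forcing them into a type. $\alpha = 0$ (a
constant-encounter degeneracy) is rejected at construction.

### Lotka-Volterra

The classic four-parameter system $x' = ax - bxy$, $y' = -cy + d(bxy)$ is
included both as a historical baseline and as a numerical test article: its
interior equilibrium $(x^*, y^*) = (c/(db),\, a/b)$ is a neutrally stable
center, and

$$ H(x, y) = d\,b\,x - c\ln x + b\,y - a\ln y $$

is exactly conserved along orbits. The drift of $H$ along a numerical
trajectory is therefore a sharp measure of integration error
(`conservation_drift()`), and the equilibrium's purely imaginary eigenvalue
pair ($\pm i\sqrt{ac}$) exercises the `MARGINAL` branch of the stability
classifier. Note the equilibrium prey density is $c/(db)$, as forced by the
predator equation written with conversion efficiency $d$ multiplying the
functional response.

### The Allee/injury model

The workhorse model generalizes the prey growth and the predator's reward:

$$ x' = a\,x\,(x - L)(K - x) - f(x)\,y, \qquad
   y' = (d - g)\,f(x)\,y - c\,y. $$

Prey growth is cubic, with carrying capacity $K$ and an Allee extinction
threshold $L$: predator-free populations starting below $L$ collapse,
populations between $L$ and $K$ grow to $K$. (The growth scaling $a$ here
carries units of time$^{-1}$·density$^{-2}$, unlike the L-V birth rate; the
symbol is shared deliberately between the two models, with per-model
documentation.) The predator pays an injury/interference cost $g$ per
capture — for effector cells, exhaustion and inhibitory ligation incurred
while killing — so the net reward per capture is $d - g$, and a predator
with $g \ge d$ cannot persist no matter how abundant the prey.

### The minimal tumor-immune model and its QSS reduction

Effector cells do not eat their prey: killing a tumor cell yields no
nutrient reward, so the ecological "biomass conversion" must be replaced by
an immunological pathway. The minimal three-compartment model routes it
through antigen-presenting cells (APCs):

$$ C' = r\,C\,(1 - C/K_C) - f(C)\,E, \qquad
   A' = s\,f(C)\,E - \mu_A A, \qquad
   E' = \rho\,A - \mu_E E - g\,f(C)\,E. $$

Killing stimulates APCs (rate $s$ per unit kill rate), APCs recruit
effectors (rate $\rho$), effectors decay at $\mu_E$ without stimulation and
are exhausted at rate $g$ per unit kill rate. These ODEs are this package's
concrete instantiation of a verbal mechanism list; the design constraint was
that eliminating the fast APC compartment must reproduce exactly the
predator equation of the Allee/injury model. Setting $A' = 0$ gives
$A^*(C,E) = s f(C) E / \mu_A$ and

$$ E' = (d_\mathrm{eff} - g)\,f(C)\,E - \mu_E E,
   \qquad d_\mathrm{eff} = \frac{\rho\,s}{\mu_A}, $$

with the prey equation untouched (`qss_reduce()` preserves it verbatim).
Two deliberate modeling choices: tumor growth is logistic rather than cubic
(the mechanism list mentions only a carrying capacity; an optional `allee_L`
restores the cubic form), and the APC compartment has no intrinsic source —
APC stimulation is tied solely to killing, so $A \to 0$ when kills stop. A
baseline APC influx is out of scope.

The sign of $d_\mathrm{eff} - g$ decides the character of the reduced
community (`classify_reduced_module()`): if the indirect benefit of tumor
cells to effectors (via APCs) exceeds the direct exhaustion cost, the pair
is predator-prey, with all the concomitant consequences including possible
oscillations; if the direct cost dominates, the pair is competition, and
sustained oscillations are impossible — trajectories in that regime have
monotonically declining effectors, which the test suite checks across a
parameter battery.

`qss_convergence()` quantifies the reduction error: scaling $\mu_A$ and $s$
by a common multiplier $m$ leaves $d_\mathrm{eff}$ (hence the reduced model)
unchanged while the APC compartment relaxes $m$ times faster. At the
package's reference tumor-immune parameter set the relative sup-norm gap
between full and reduced $(C, E)$ trajectories falls roughly tenfold per
decade of $m$ and is below 1% at $m = 1000$.

## Regime classification and the immunoediting parallel

For a Type I response the interior equilibrium of the Allee/injury model
sits at the prey density $x^* = c/((d-g)b)$ where the predator breaks even.
Its position relative to three landmarks determines the dynamical regime:

* $x^* \le L$ — the predator profits even below the prey's extinction
  threshold: **elimination** (both populations ultimately collapse).
* $x^*$ between $L$ and the prey-nullcline hump $(L+K)/2$ — the interior
  equilibrium is unstable (the Hopf side of the hump): a limit cycle
  (**oscillation**) or a collapse (**elimination**), depending on whether
  the cycle clears the extinction floor.
* $x^*$ between the hump and $K$ — stable interior equilibrium:
  **coexistence**.
* $x^* \ge K$ (or $d \le g$) — the prey cannot support the predator:
  **escape** (predator extinct, prey at carrying capacity).

The hump criterion is the standard graphical-stability argument: the trace
of the interior Jacobian has the sign of the prey-nullcline slope at $x^*$.
The elimination/oscillation boundary inside the unstable zone is a
global (homoclinic-type) feature with no printed closed form, so
`classify_regime()` resolves it — and confirms every analytic candidate — by
simulation from a default initial state $(0.75K,\ 0.05K)$: a tumor burden
well above its Allee threshold facing a small immune infiltrate. The
default is exposed because regimes with alternative stable states are
initial-condition dependent. When the analytic candidate and the simulation
verdict disagree the cell is labelled `UNDETERMINED`, a first-class outcome:
near regime boundaries (weakly damped foci, slowly decaying predators) no
finite integration can settle the label, and pretending otherwise would
corrupt the map.

`regime_map()` sweeps predator *inefficiency* $c/(db)$ (the reciprocal of
the efficiency ratio $(bd)/c$) against $L/K$, holding $a$, $K$, $b$, $d$,
$g$ fixed and varying $c$ and $L$ — the axes are otherwise underdetermined,
and this choice keeps every cell a one-parameter change of the base set.
Scanning inefficiency upward at fixed $L/K$, the distinct labels always
appear in the order elimination, oscillation, coexistence, escape
(`check_regime_sequence()` asserts this). Renaming the labels with
`immunoediting_phase()` makes the parallel explicit: as immune efficiency
degrades, the model walks through elimination, a transitional oscillatory
phase, equilibrium, and escape — the immunoediting sequence.

## The immune-web: interaction-matrix diagnostics

`interaction_matrix()` evaluates $a_{ij} = \partial \dot N_i / \partial N_j$
— the local effect of cell type $j$'s density on cell type $i$'s growth
rate — as a finite-difference Jacobian at a supplied state.  The convention
is the derivative of the *total* growth rate, not the per-capita rate: for
positive densities the off-diagonal signs coincide, and the total-rate form
stays well defined on the boundary (zero densities). Classification is
state-dependent by design; effect signs can change with density, so a web
is always "the web at this state".

`classify_pair()` maps the off-diagonal sign pair to the classical community
modules: $(+,-)$ predator-prey, $(-,-)$ competition, $(+,+)$ mutualism, a
$+$ or $-$ against $0$ commensalism or amensalism, $(0,0)$ neutral. At the
reference tumor-immune coexistence state the web comes out as:
tumor–effector *interference competition* when $g > 0$ (each kill costs the
effector), tumor–APC *commensalism* (kills stimulate APCs; APCs do not
touch tumor growth directly), and APC–effector *mutually positive* — the
effector-to-APC coupling through killing is positive whenever tumor cells
are present, so the sign calculus reports mutualism rather than the
one-sided commensalism a purely verbal account might suggest.  In the
QSS-reduced system the APC chain is folded into $d_\mathrm{eff}$ and the
tumor–effector pair flips to predator-prey exactly when
$d_\mathrm{eff} > g$, consistent with `classify_reduced_module()` — an
agreement the test battery checks.

Some published diagnostics attached to these sign patterns (e.g. intraguild
predation "amplifying" one coefficient while diminishing the other) describe
dynamic couplings rather than static signs; they are noted here but not
mechanized.

## Numerical choices

* **Integration.** `deSolve`'s `lsoda`/`lsodar` with defaults
  `rtol = 1e-9`, `atol = 1e-12`, output on a uniform 2000-point grid so
  peak detection is resolution-controlled rather than step-size dependent.
  The L-V conservation drift at these defaults is a few parts in $10^9$
  over $t \in [0, 100]$, and halving tolerances reduces it.
* **Extinction floor.** Any compartment crossing `1e-9` while declining is
  clamped to exactly zero for the remainder (a root-triggered solver event).
  Continuous models otherwise keep populations alive at densities far below
  one cell and let them revive ("atto-foxes"), which would misclassify
  elimination as oscillation. Upward crossings (an APC compartment growing
  from zero) do not trigger the clamp.
* **Oscillation detection.** Strict local maxima of the prey series after a
  burn-in (default 25%; the regime classifier uses 50% so limit cycles are
  settled), with peak amplitudes measured against neighboring troughs and an
  absolute amplitude floor of `1e-4` — the threshold for a "visible"
  oscillation is biologically unquantified, so the floor is a parameter, not
  a constant. Sustained requires $\ge 4$ peaks with last/first amplitude
  ratio in $[0.9, 1.1]$; damped requires $\ge 3$ monotonically shrinking
  amplitudes ending below half the first.
* **Root searches.** Interior equilibria for saturating/sigmoidal responses
  are bracketed on $(10^{-12}, 10K]$ and solved to relative tolerance
  $10^{-12}$ with a Newton polish; since $f$ is nondecreasing the root is
  unique when it exists, so no tie-breaking is ever exercised.
* **Stability tolerance.** Real parts within $10^{-8}$ of zero are
  `MARGINAL`. The finite-difference Jacobian (step $10^{-6}$ scaled by the
  state) reproduces the L-V closed form to ~$10^{-9}$, comfortably inside
  that band.
* **Classifier tolerances.** The regime classifier integrates at
  `rtol = 1e-8`, `atol = 1e-11` — classification needs topology, not
  conservation-grade accuracy — over a horizon `2000 + 100/min(c, aK²)`
  that scales with the slowest rate present.

## The parameter battery

Property tests and the acceptance script draw seeded random parameter sets
(`parameter_battery()`); the generator's ranges are the package's study
conditions. Rates are log-uniform in the windows documented on the help
page; two are worth justifying here. The Allee threshold is drawn in
$[0.05K,\ 0.5K]$ — bounded away from zero because at $L = 0$ the "below
threshold" test case is empty and extinction times diverge; and the
predator nullcline position $x^*/K$ is drawn log-uniformly in $[0.05, 2]$
so the battery actually visits all four regimes instead of concentrating
where random rate combinations happen to land. Problem sizes used by the
shipped checks (200-set L-V and regime batteries, 100-set threshold and
tumor-immune batteries, a $30 \times 10$ regime map) were chosen so the
full suite exercises every classifier branch.

## What the synthetic conditions do and do not show

Everything here is deterministic, well mixed and two-or-three-compartment.
Passing tests demonstrate that the solver, the classifiers and the algebra
are mutually consistent and match independent oracles (conserved quantities,
closed forms, perturbation simulations). They do not show that real tumors
follow these ODEs: there is no demographic noise, no spatial structure, no
cell-type heterogeneity beyond three compartments, no behavioral (ecology-
of-fear) dynamics, and resource/cytokine dynamics enter only implicitly via
the time-scale-separation argument that motivates the QSS reduction. The
regime map is a statement about the model family, and its immunoediting
relabeling is an analogy made precise within that family — not a clinical
predictor.

## Known limitations

* The analytic regime stage covers Type I responses only; other response
  types go through the simulation-only path.
* `UNDETERMINED` map cells are genuinely ambiguous at finite horizons;
  refining them needs continuation methods (Hopf/homoclinic tracing), which
  are out of scope.
* The oscillation detector is amplitude-based; oscillations below the floor
  (small-amplitude clonal cycling) are reported as `NONE` by design.
* Multi-prey/multi-predator webs (apparent competition, indirect mutualism)
  and press-perturbation (inverse-matrix) analysis are not implemented.
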