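---
title: "Methods: simulating ratiometric gradient sensing on a spherical cell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating ratiometric gradient sensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratiosense)
```

## The model

A spherical cell of radius $L$ carries $N_R$ immobile receptors at uniform
random positions on its surface and is exposed to a linear ligand field

$$C(x) = C_0\left(1 + b\,\frac{x\cdot\theta}{L}\right),$$

with mid-point concentration $C_0$, dimensionless steepness $|b| < 1$ and
unit gradient direction $\theta$. Each receptor is a telegraph process:
unbound receptors bind ligand at rate $k_{on} C(x)$ and bound receptors
release it at rate $k_{off}$, so the equilibrium occupancy at position $x$
is $p_R(x) = C(x)/(C(x) + K_d)$ with $K_d = k_{off}/k_{on}$, and the total
switching rate is $\lambda(x) = k_{on} C(x) + k_{off}$.

$N_G$ G proteins perform Brownian motion on the membrane with diffusivity
$D_G$ and carry a binary activity state that is updated on receptor
contact (within the interaction radius $r^*$):

* **ratiometric** — the G protein copies the state of the receptor it
  touches: bound receptors activate, unbound receptors deactivate. Between
  contacts the state persists indefinitely, so each G protein remembers the
  state of the last receptor it met, and the population holds a spatially
  local, temporally smeared record of receptor activity.
* **classical** — contact with a bound receptor activates; deactivation is
  a uniform Poisson decay at rate $k_{gi}$, independent of receptors.

The cell's direction estimate is read out from resultant vectors: the sums
of position vectors of bound receptors ($V_{RL}$), unbound receptors
($V_R$, used as $-V_R$), their difference ($V_C = V_{RL} - V_R$), and
active G proteins ($V_G$). Accuracy is quantified by the noise-to-signal
ratio $\mathrm{NSR} = \operatorname{tr}\operatorname{Cov}(V) /
\lVert \mathbb{E} V \rVert^2$ over independent realizations, and by the
CDF of the angular error against $\theta$ (the uniform-direction baseline
CDF is $(1-\cos\alpha)/2$).

For instantaneous receptor snapshots the NSR of any unbiased estimator is
bounded below by $\operatorname{tr} I^{-1}$, where $I$ is the $2\times 2$
Fisher information of the independent Bernoulli receptor states with
respect to the two tangent-plane degrees of freedom of $\theta$
(`fisher_information()`). In the weak-gradient limit this reduces to

$$\mathrm{NSR} \;\ge\; \frac{6}{N_R b^2}\,\frac{(C_0+K_d)^2}{K_d C_0},$$

minimized at $C_0 = K_d$ (`weak_signal_bound()`). The bound constrains
only estimators built from a single receptor snapshot; a G-protein
population that has accumulated past receptor states can — and in the
sparse-receptor regime does — beat it.

## Default parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| $K_d$ | 6 | nM | dissociation constant |
| $k_{off}$ | 0.1 | 1/s | unbinding rate ($k_{on} = k_{off}/K_d$) |
| $C_0$ | 6 | nM | gradient mid-point (= $K_d$) |
| $b$ | 0.33 | — | gradient steepness |
| $N_R$ | 375 | — | receptors |
| $N_G$ | 2500 | — | G proteins |
| $D_G$ | 0.002 | μm²/s | G-protein diffusivity |
| $L$ | 2.5 | μm | cell radius (yeast scale) |
| $r^*$ | 0.010 | μm | interaction radius |
| $dt$ | 0.02 | s | time step |

The rate trio is specified by $k_{off}$ and $K_d$, with $k_{on}$ derived,
because a rounded $k_{on}$ cannot satisfy $K_d = k_{off}/k_{on}$ exactly.

**Choice of $r^*$ and $dt$.** The cell radius and interaction radius set
the diffusive encounter interval

$$\tau_{dif} \propto \frac{L^2}{N_R D_G}\,\ln\frac{\delta}{r^*},
\qquad \delta = \sqrt{4\pi L^2/N_R},$$

which together with $\lambda$ controls everything interesting in the
model: the correlation of G-protein states ($\lambda\tau_{dif}$), the
classical dose-response bias ($E[N] = 1/(k_{gi}\tau_{dif})$), and
adaptation speed. We therefore fix the encounter timescale rather than the
(unobservable) interaction radius: $r^* = 0.010$ μm at $dt = 0.02$ s gives
a measured mean first-encounter time of $\approx 80$ s at the reference
density $N_R = 375$ (`measure_tau_dif()`), the regime in which the
reference classical rates of order $10^{-2}$/s are meaningful. Encounters
are detected by per-step proximity (nearest receptor within great-circle
distance $r^*$, ties to the lowest index, contact probability 1); because
$r^*$ is calibrated under the same $dt$, the finite-step detection error
is absorbed into the effective radius. The config validator requires the
RMS step $\sqrt{4 D_G dt} \le 1.5\,r^*$ — beyond that the per-step check
degrades qualitatively — and $\max(k_{on}C, k_{off})\,dt \le 0.2$ so
per-step switching probabilities stay in the linear regime. Sweeps over
$D_G$ rescale $dt$ to hold $4 D_G dt$ fixed for the same reason.

The proportionality constant of $\tau_{dif}$ was fitted once against
first-encounter simulations: const $= 2.5$, stable to about $\pm 5\%$ over
$N_R \in [188, 6000]$. All closed-form uses keep the $\propto$ form; the
fitted constant is only used to choose burn-in lengths and snapshot
spacings.

**Update order** within a step: diffuse G proteins → update receptor
states → resolve encounters → apply the G rule. In classical mode decay is
applied before encounter activation, so a G protein that touches a bound
receptor during the step ends the step active. Burn-in defaults to
$\max(10/\lambda(C_0),\, 5\tau_{dif})$: receptor occupancy equilibrates on
$1/\lambda$, and the G-protein collective refreshes once per encounter
interval, so five intervals leave under 1% memory of the initial
condition.

## Randomness and reproducibility

All R-level sampling uses R's RNG; the compiled engine draws a 64-bit seed
from R's stream and then runs a private xoshiro256++ generator (polar
Gaussians) for speed. Every simulation is therefore bit-reproducible from
its config and seed, which the tests assert. Experiment drivers derive
per-replicate seeds from the base seed by fixed offsets and record them in
their result tables.

## Calibration of the classical rate

Classical and ratiometric runs are compared at equal steady-state active-G
abundance. `calibrate_kgi()` runs one ratiometric reference simulation
recording, at each snapshot, every G protein's age since it last touched a
bound receptor. G-protein motion and receptor switching are identical in
the two modes; only the deactivation channel differs, and for the
classical channel the survival probability of an activation is
$e^{-k_{gi}\cdot\mathrm{age}}$. The classical steady-state fraction on the
same trajectory is therefore exactly the mean of that survival over
G proteins and snapshots (G proteins that never met a bound receptor
contribute their initial activity $\tfrac12 e^{-k_{gi}t}$), and bisection
in $\log k_{gi}$ on this deterministic, monotone response finds the
matching rate without re-simulating per iterate — the decay noise is
integrated out analytically, and all encounter noise is shared between
reference and candidate. A direct classical simulation at the calibrated
rate reproduces the reference fraction within Monte-Carlo error (asserted
in the tests). At the reference parameter set the calibration yields
$k_{gi} \approx 0.0079$ s⁻¹.

## The reduced single-receptor model

`simulate_reduced()` strips the geometry away: one telegraph receptor,
$n$ G proteins encountering it at exponential intervals of mean
$\tau_{dif}$, simulated event-by-event (exact; no discretization error).
The exponential-interval renewal assumption is declared: diffusive
encounters on the membrane are only approximately exponential (returns to
a just-visited receptor are clustered), which is one reason the full
calibration is done by simulation rather than by formula.
`exact_reduced_stationary()` builds the generator over (receptor state,
active count) — the count is sufficient by exchangeability — and solves
the stationary distribution by linear algebra. It is the oracle for the
collective-variance formula

$$\operatorname{Var} A_n = p_R(1-p_R)\left[\frac1n +
\left(1-\frac1n\right)\frac{1}{1+\lambda\tau_{dif}}\right],$$

which it matches to numerical precision, and for the classical
dose-response bias $p_{Gc} \approx p_R E[N]/(1+p_R E[N])$. The bias
formula assumes encounters sample near-independent receptor states; the
exact chain shows deviations up to ~30% at $\lambda\tau_{dif} = 1$
shrinking below 10% for $\lambda\tau_{dif} \gtrsim 7$. Bias tests
therefore use $\tau_{dif} = 60$ s, which also matches the encounter
timescale of the full membrane model ($\lambda\tau_{dif} \approx 15$ at
defaults).

## What the experiments show (and at what scale)

Tests and the acceptance script run at desk scale; the observations they
reproduce, with the problem sizes used:

* **Receptor snapshots** (`run_receptor_only()`, 800–1200 independent
  placements): $V_C$ beats $V_{RL}$ and $-V_R$ at $C_0 = K_d$ with NSR
  about half of either (it uses both halves of the data); $V_{RL}$ wins
  below $K_d$, $-V_R$ above; NSR($V_C$) scales as $1/N_R$ (log–log slope
  $-1 \pm 0.15$ over $N_R \in \{375, 1500, 6000\}$) and always sits above
  the Cramér–Rao bound.
* **Full membrane** (`run_steady_state()`, 6–8 replicates × 4 snapshots
  spaced $2\tau_{dif}$): ratiometric $V_{Gr}$ has lower NSR than
  calibrated classical $V_{Gc}$; NSR($V_{Gr}$) falls with $N_G$
  ($N_G \in \{625, 1250, 2500, 5000\}$ at $N_R = 375$); at $N_R = 188$
  NSR($V_{Gr}$) drops below the instantaneous-receptor bound while
  NSR($V_C$) from the same runs respects it.
* **Local (un)biasedness** (`run_binned_activity()`, 12 replicates × 2500
  G proteins in 6 latitude bins): ratiometric binned activity tracks
  $p_R(u)$ closely (front-to-back spread ≈ 0.115 of the 0.140 occupancy
  spread — G proteins drift ~$\sqrt{4 D_G \tau_{dif}}$ between contacts,
  which smears the profile slightly, and within-replicate states are
  correlated, so binomial error bars understate the noise); classical
  activity is distinctly flattened — above $p_R$ at the back, below at
  the front, spread ≈ 0.05.
* **Adaptation** (`run_flip()`, 4 replicates averaged into one direction
  trace): after a 180° gradient reversal the time for the averaged
  $\bar V_{Gr}$ to cross 90° toward the new direction falls with
  $k_{off}$ (0.005 → 0.1 s⁻¹, $K_d$ held by re-deriving $k_{on}$) and
  with $N_R$ (375 → 1500), while raising $D_G$ (0.001 → 0.008 μm²/s)
  speeds adaptation but raises the steady-state NSR — the
  speed-versus-accuracy trade-off of faster membrane mixing.

## Numerical choices and degenerate inputs

* Uniform sphere sampling by normalized Gaussian triples (exactly uniform,
  branch-free); surface diffusion by tangent-plane Gaussian step (per-axis
  variance $2 D dt$) and re-projection, accurate to $O(dt)$ for steps
  $\ll L$ and verified against the planar MSD $4 D dt$ to 5%.
* Empty selections give zero resultants; zero resultants make the angular
  error and NSR error out explicitly rather than return NaN.
* The Fisher matrix errors out when singular (e.g. all receptors on the
  gradient axis). $b = 0$ is rejected for the bound (no information) but
  valid in simulations (isotropy checks).
* Bisection in `calibrate_kgi()` works in $\log k_{gi}$ because plausible
  rates span decades; a reference fraction that even the lower bracket
  cannot reach (receptors pinned bound) returns the bracket edge with a
  flag instead of failing.
* `exact_reduced_stationary()` allows $p_R = 1$ (pinned receptor), where
  the classical chain reduces to a birth–death process with mean
  $E[N]/(1+E[N])$.

## Limitations

The simulator emulates the study conditions, not a full cell: ligand is
never depleted, receptors neither move nor traffic, the RGS/deactivation
machinery is folded into the unbound-receptor contact rule, and gradients
are linear across a perfect sphere. Encounter detection is a per-step
proximity check with contact probability 1, so $r^*$ is an effective
radius tied to $dt$; changing $dt$ without recalibrating $r^*$ changes
the encounter timescale. Passing tests therefore demonstrate the
architecture-level claims (ratiometric unbiasedness, collective memory,
the bound crossing, the calibration point, the adaptation trade-offs)
under these idealizations — they do not validate quantitative predictions
for any particular cell type beyond the parameter regime tabled above.
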