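---
title: "Modelling solute clearance in ultrathin-nanomembrane dialyzers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling solute clearance in ultrathin-nanomembrane dialyzers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanodialyzer)
```

## The physical problem

A miniature dialyzer passes blood through a thin channel bounded on one
side by an impermeable wall and on the other by an ultrathin nanoporous
membrane, with fresh dialysate washing the far side of the membrane.
Because the membrane is tens of nanometres thick — orders of magnitude
thinner than conventional dialysis membranes — transmembrane diffusion is
fast enough that a few square centimetres of membrane can do useful
clearance work, which is what makes a wearable, continuously-operating
device conceivable.

`nanodialyzer` models this configuration under three assumptions:

1. **Plug flow** — the blood velocity is uniform across the channel.
2. **Negligible axial diffusion** — convection dominates transport along
   the channel.
3. **Perfect sink** — the dialysate side holds the solute at zero
   concentration.

Under (1) and (2) each fluid element carries a one-dimensional transient
diffusion problem with it as it traverses the channel, for a residence
time $t = L/v = A a/\dot{Q}$ ($L$ membrane length along the flow, $v$ mean
velocity, $A$ membrane area, $a$ channel height, $\dot{Q}$ volumetric
flow). In dimensionless variables $\bar{x} = x/a$, $\bar{t} = t D_0/a^2$:

$$\frac{\partial \bar{c}}{\partial \bar{t}} =
  \frac{\partial^2 \bar{c}}{\partial \bar{x}^2}, \qquad
  \frac{\partial \bar{c}}{\partial \bar{x}}(0,\bar{t}) = 0, \qquad
  \bar{c}(\bar{x}, 0) = 1,$$

with the membrane at $\bar{x} = 1$ either a perfect sink,
$\bar{c}(1,\bar{t}) = 0$, solved by the cosine series with eigenvalues
$\lambda_n = \pi(n - \tfrac12)$, or a resistive (Robin) boundary

$$\bar{c}(1,\bar{t}) + \beta\,
  \frac{\partial \bar{c}}{\partial \bar{x}}(1,\bar{t}) = 0, \qquad
  \beta = \frac{d/D_m}{a/D_0},$$

whose eigenvalues are the roots of $\tan z_n = 1/(\beta z_n)$ with
coefficients $C_n = 2\sin z_n / (z_n + \sin z_n \cos z_n)$. The
dimensionless resistance $\beta$ compares the membrane's diffusive
resistance ($d/D_m$: thickness over hindered in-pore diffusivity) with the
channel's ($a/D_0$); for ultrathin membranes and small solutes
$\beta \ll 1$ and the sink model applies, while large proteins in small
pores see $\beta \gtrsim 1$. The single-pass fractional clearance is
$f = \text{coverage} \times (1 - \langle\bar{c}\rangle(\bar{t}))$, the
coverage factor accounting multiplicatively for channel width not overlain
by active membrane (0.7 in the benchtop validation device).

## Tunable parameters and their defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| model switch threshold on $\beta$ | 0.2 | — | sink series used below, Robin above; overridable per call |
| membrane thickness $d$ | 50 | nm | representative of silicon-nitride nanomembranes |
| membrane porosity $\varepsilon$ | 0.03 | — | see calibration note below |
| hindrance model | `renkin` | — | pluggable registry; `centerline` (Dechadilok–Deen) also provided |
| coverage | 1 | — | ideal geometry; 0.7 in the benchtop fixture |
| blood viscosity (hydraulics) | 1.0 | mPa·s | water-like; blood (~3) cuts pressure-driven flow 3× — both worth reporting |
| series truncation | adaptive | — | terms kept until the decay factor is below double precision; cap 100 000 |
| 1-D oracle grid | 2001 nodes, $\Delta\bar{t}_0 = 10^{-5}$ | — | second-order accurate; see numerics |
| 2-D oracle grid | 401 × 1500 | — | keeps plug-flow runs within 0.1% of the series |

**Calibration of the membrane description.** The hindered-pore model
$D_m = D_0 \cdot H(\lambda) \cdot \varepsilon$ (with
$\lambda = r_s/r_{pore}$) requires a porosity and thickness that are not
uniquely determined by the clearance targets alone; published porosities
for porous nanocrystalline silicon membranes span roughly 1–15%. We fix
$d = 50$ nm and $\varepsilon = 0.03$ once: with these values the albumin
isocurve at a 50 µm channel returns a mean pore diameter of ≈19 nm, in the
range these membranes are actually fabricated with (tens of nanometres).
Higher porosities push the recovered pore size down (0.15 would give
≈13 nm) because a more open membrane needs narrower pores to hold albumin
leakage at the same target. All design-selection outputs record which
hindrance model produced them, since the hindrance internals are the
largest source of uncertainty in pore-scale predictions.

**Solute library.** The bundled kinetics (generation rates and
physiological concentrations for creatinine, β2-microglobulin and albumin)
follow standard reference values for a 70 kg adult; urea's generation rate
is carried only as its target-clearance ratio 2.3 L/h, so its steady state
is computed as $C_{phys} \times \text{target}/(\dot{Q} f)$, algebraically
identical to $\dot G/(\dot{Q} f)$. The free diffusion coefficients and
Stokes radii (urea $1.38\times10^{-5}$ cm²/s, 0.26 nm; creatinine
$1.0\times10^{-5}$, 0.33 nm; β2-microglobulin $1.3\times10^{-6}$, 1.6 nm;
albumin $6.1\times10^{-7}$, 3.55 nm) are literature values, flagged as
such in the CSV's `source_note` column — they are inputs to the model, not
outputs of it.

## Adequacy under continuous treatment

At steady state, generation balances removal,
$\dot G = \dot{Q}\, C\, f$, so the clearance-volume product $\dot{Q} f$
acts as a renal clearance and the steady-state plasma level is
$C_{ss} = \dot G/(\dot{Q} f)$. Two consequences shape design intuition:
a solute with $f = 0$ (sterically excluded) has no steady state — the
package returns an explicit accumulation marker rather than infinity —
and the sensitivity $\partial C_{ss}/\partial f = -\dot G/(\dot Q f^2)$
grows at small $f$ and is scaled by $\dot Q$, so high-flow designs amplify
small clearance errors into large concentration errors. That argues for
the lowest flow compatible with the targets, which the design selector
encodes.

## Design selection

For a fixed membrane area the selector reduces the design space
lexicographically over a grid of channel heights (default 40 log-spaced
points over 10–500 µm):

1. **Urea isoline** — solve $\dot Q f_{urea}(\dot Q; a, A) = 2.3$ L/h for
   $\dot Q$ by bracketed root finding on [0.001, 100] L/min. Since
   $\dot Q f \propto \sqrt{\dot Q}$ in the short-residence regime the root
   is unique. Urea's $\beta$ is always tiny, so pore size plays no role.
2. **Albumin isocurve** — with $\dot Q(a)$ fixed, solve
   $\dot Q f_{alb}(\text{pore}) = 0.015$ L/h for the pore diameter on
   $(2 r_{s,alb}, 200\,\text{nm}]$. The Robin series is used for every
   evaluation here: it is the general solution, exact for all $\beta > 0$,
   whereas the $\beta$-switch rule would make the objective discontinuous
   near $\beta = 0.2$ and can leave the equation without a zero crossing.
3. **Middle-molecule maximisation** — evaluate
   $\dot Q f_{\beta 2m}$ along the one-parameter family and pick the best
   channel height at or above a user-supplied practicality floor.

With the bundled kinetics the β2-microglobulin clearance saturates once
the membrane dominates its transport: past ~25 µm the curve is a plateau,
flat to well under 1%. A bare argmax would therefore return the largest
height on the grid — and with it a clinically absurd 7.7 L/min blood flow,
since the urea isoline forces $\dot Q$ to grow with $a$. The selector
instead recommends the *smallest* feasible height whose clearance is
within 1% of the constrained maximum: maximal middle-molecule clearance at
the lowest blood flow, which is how we read "practicality". On the default
grid with a 50 µm floor this lands at 53.5 µm, 0.83 L/min and a 19 nm
pore. Direct root solves are used at every grid point; no intermediate
polynomial fitting is involved.

Closed-loop self-consistency — feeding the recommended candidate back
through `fractional_clearance()` reproduces both targets to $10^{-6}$
relative — is asserted in the test suite. Note that the feedback check
must evaluate albumin with `model = "robin"`, matching how the isocurve
was solved.

## Numerical choices

**Series evaluation.** Terms are truncated adaptively once the next
term's decay factor falls below double-precision relevance (cap 100 000).
For $\bar t < 10^{-6}$ the series converge too slowly and the half-space
closed forms take over: $f = 2\sqrt{\bar t/\pi}$ at $\beta = 0$, and its
surface-resistance generalisation
$f = \beta(\mathrm{erfcx}(\sqrt{\bar t}/\beta) - 1) + 2\sqrt{\bar t/\pi}$
otherwise (scaled complementary error function from `pracma`, safe against
overflow at small $\beta$).

**Eigenvalue solving.** One Robin root lives in each interval
$((n-1)\pi, (n-1)\pi + \pi/2)$. Roots are bracketed and refined on the
singularity-free form $\beta z \sin z - \cos z = 0$ (tolerance $10^{-14}$,
Newton-polished); for extreme $\beta$ the root sits within machine
rounding of a bracket end and the asymptotic expressions
$z_n \approx (n-1)\pi + 1/(\beta (n-1)\pi)$ (large $\beta$) or
$z_n \approx \lambda_n(1 - \beta)$ (small $\beta$) are used directly.
Residuals $|z \tan z - 1/\beta|$ stay below $10^{-12}$ for moderate
$\beta$; for $\beta \lesssim 10^{-4}$ that residual form is itself
ill-conditioned (the $1/\beta$ term amplifies rounding), which is why the
solver never works with it directly.

**1-D Crank–Nicolson oracle.** The independent check on the series uses
2001 nodes, mirror-node (second-order) wall and Robin boundaries, and
Crank–Nicolson stepping from $\Delta\bar t = 10^{-5}$ with geometric step
growth (capped at $10^{-3}$) once the initial transient has smoothed. The
sink boundary is incompatible with the uniform initial state, which
excites Crank–Nicolson ringing; four damped implicit-Euler start-up steps
suppress it. Against the series the oracle agrees to
$L_\infty \le 10^{-3}$ over $\bar t \in [10^{-3}, 1]$,
$\beta \in \{0, 0.1, 1, 10\}$, and refinement studies confirm second-order
spatial convergence.

**2-D channel solver.** The steady transport equation
$v(\bar y)\,\partial c/\partial z = D\,\partial^2 c/\partial y^2$ is
marched axially (the axial coordinate playing the role of $\bar t$), with
a plug or Poiseuille profile; the Poiseuille weight $6\bar y(1-\bar y)$ is
floored at $10^{-3}$ at the walls to keep the marching system
non-singular, a harmless modification since that fluid carries essentially
no flux. Fractional clearance uses the flow-weighted (mixing-cup) outlet
mean. Mass accounting (inlet = outlet + integrated membrane flux) closes
to better than 0.5% at production resolution. With a plug profile the 2-D
solve agrees with the analytical model to well under 2% across channel
heights 0.1–1 mm — the ideal-geometry agreement the analytical model
claims — while the parabolic profile clears substantially less at short
residence times (the depleted layer hugs the membrane where the flow is
slow), quantifying what the plug-flow assumption costs.

**Degenerate inputs.** Zero or negative geometry is rejected at
construction. A sterically excluded solute propagates as $\beta = \infty$
and $f = 0$ with an explicit model flag, and as an "accumulates without
bound" row in adequacy tables. Infeasible design targets raise a dedicated
condition class rather than returning `NA`s.

## What the fixtures do and do not show

The benchtop fixture reproduces the validation device's geometry exactly
(10 s residence, 0.2 mm/s, 70% coverage), and the test suite checks the
model's internal consistency plus its agreement with an independent
finite-difference discretisation of the *same* equations. That validates
the mathematics, not the physics: real devices add three-dimensional
geometry (trenches, support structures), developing flow, protein
adsorption, ultrafiltration coupling and pore-size dispersity, none of
which are modelled here. The 3-D finite-element results for practical chip
geometries are explicitly out of scope, and middle-molecule predictions
inherit the hindrance-model uncertainty discussed above — the package
reports which model produced every pore-scale number for exactly that
reason.

## Known limitations

- The dialysate side is always a perfect sink; dialysate-side depletion
  or counterflow profiles are not modelled.
- No convective transmembrane flux: the membrane is a perfect wall for
  ultrafiltration, so convective clearance is ignored.
- The $\beta$-switch rule makes `model = "auto"` predictions mildly
  discontinuous across $\beta = 0.2$ at short residence times; force
  `model = "robin"` where smoothness matters.
- Middle-molecule steady states are sensitive to the unpublished
  hindrance internals and porosity; treat them as order-of-magnitude.
- The parallel-plate hydraulic formula assumes $w/h \gg 1$ and Newtonian
  blood.
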