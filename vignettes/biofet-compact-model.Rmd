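---
title: "A compact model of 2D electrolyte-gated field-effect biosensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A compact model of 2D electrolyte-gated field-effect biosensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofet2d)
```

## The device and the modeling problem

An electrolyte–insulator–semiconductor (EIS) BioFET replaces the metal top
gate of a transistor with an electrolyte contacted by a reference electrode
(the *liquid gate*, $V_{lg}$). The barrier oxide that separates the
electrolyte from the two-dimensional semiconductor channel is functionalized
with receptors; when charged target macromolecules (proteins, DNA fragments)
bind, their charge gates the channel and shifts the drain current. The same
stack without receptors is an ISFET: its amphoteric oxide surface
protonates/deprotonates with pH and produces a pH-dependent current.

`biofet2d` implements this chain as two decoupled stages:

1. **Interface electrostatics** — solve for the potential drop across the
   electrolyte (surface potential $\psi_0$) from charge neutrality between
   the oxide surface charge and the electrolyte countercharge. This drop
   depends on pH, ionic strength and bound-analyte charge but *not* on the
   transistor bias, because the channel sheet charge (mC/m$^2$ scale at
   most) is negligible against the interfacial charges (0.1–1 C/m$^2$
   scale).
2. **Device electrostatics and transport** — with $\psi_0$ fixed, solve the
   double-gate charge balance for the channel chemical potential at source
   and drain, and evaluate a closed-form drift-diffusion drain current.

## Stage 1: the electrolyte side

**Site binding.** Surface hydroxyls exchange protons,
$-\mathrm{MOH}_2^+ \leftrightarrow -\mathrm{MOH} \leftrightarrow
-\mathrm{MO}^-$, with dissociation constants $K_a, K_b$. Eliminating the
species densities gives the closed form
$$\sigma_0 = q N_s\,
  \frac{a_{H^+s}^2 - K_a K_b}{a_{H^+s}^2 + K_b\,a_{H^+s} + K_a K_b},$$
bounded by $\pm qN_s$, with the surface proton activity tied to the bulk by
a Boltzmann factor $a_{H^+s} = 10^{-\mathrm{pH}} e^{-\psi_0/\phi_{th}}$.
The point of zero charge is $\mathrm{pH}_{pzc} = (pK_a + pK_b)/2$.

**Stern layer.** A charge-free layer of capacitance $C_{Stern}$ separates
the surface (potential $\psi_0$) from the outer Helmholtz plane (potential
$\psi_m$): $\psi_0 = \psi_m + \sigma_0/C_{Stern}$.

**Membrane and diffuse layer.** The receptor–target layer is modeled as an
ion-permeable membrane of uniform fixed charge concentration $N_m$
(signed), thick enough to reach local charge neutrality, so its core sits
at the Donnan potential
$\psi_{DP} = \phi_{th}\,\mathrm{asinh}\!\left(N_m/2n_0\right)$ with
$n_0 = N_A i_0$ the per-species ion concentration of the (assumed 1:1)
electrolyte. Integrating the Poisson–Boltzmann equation once from the
zero-field Donnan plateau to the OHP gives the total membrane + diffuse
charge
$$\sigma_{md} = -\,\mathrm{sgn}(\psi_m-\psi_{DP})
  \sqrt{4 q n_0 \phi_{th}\varepsilon_m\!\left[
  \cosh\tfrac{\psi_m}{\phi_{th}} - \cosh\tfrac{\psi_{DP}}{\phi_{th}}
  - \tfrac{\psi_m-\psi_{DP}}{\phi_{th}}\sinh\tfrac{\psi_{DP}}{\phi_{th}}
  \right]}.$$
The prefactor is fixed by requiring that the $N_m = 0$ limit reproduce the
textbook Grahame equation
$\sigma = -\sqrt{8\varepsilon_m k_B T n_0}\,\sinh(\psi_m/2\phi_{th})$
exactly (the identity $\cosh x - 1 = 2\sinh^2 x/2$ makes this algebraic,
and it is enforced to 1e-10 relative tolerance in the test suite). The
radicand is non-negative by convexity of $\cosh$; floating-point noise near
$\psi_m = \psi_{DP}$ is clamped to zero.

**Langmuir binding.** In receptor–target mode the membrane charge follows
equilibrium Langmuir occupancy,
$N_m = (k_q/h_m)\, N_r\, K_c N_t/(1 + K_c N_t)$, where $k_q$ is the signed
number of fundamental charges per bound molecule. $k_q$ is a user input
(typically from a protein protonation-state calculation): for streptavidin
it is positive below the isoelectric point (pI $\approx$ 5.04) and negative
above it, e.g. $+22.3$ at pH 3 and $-15.2$ at pH 9.

**The solve.** Substituting the Stern relation reduces charge neutrality
$\sigma_0(\psi_0) + \sigma_{md}(\psi_m) = 0$ to one scalar equation in
$\psi_0$ whose residual is strictly decreasing ($\sigma_0$ falls with
$\psi_0$, $\sigma_{md}$ falls with $\psi_m$, and $\psi_m$ rises with
$\psi_0$), so the root is unique. `solve_surface_potentials()` brackets it
starting from $[-2, 2]$ V (geometric expansion, hard failure at
$|\psi_0| = 5$ V, which signals inconsistent parameters) and bisects to
machine resolution; a safeguarded-Newton variant is provided and agrees to
better than 1e-10 V on non-degenerate cases. The charge residual at the
solution is required to be below `tol_sigma` = 1e-12 C/m$^2$ — some nine
orders below $qN_s$. One caveat: when $N_s = 0$ the root sits where the
clamped radicand vanishes, and $\cosh$ cancellation flattens the residual
within about 1 nV of the root, so solutions there are exact only to
~1e-9 V (still far below any physical scale in the problem).

```{r interface}
cfg <- preset_table1(pH = 5)
solve_surface_potentials(cfg$site_binding, cfg$electrolyte, cfg$membrane)
```

The pH response of $\psi_0$ is bounded by the Nernst slope
$\ln 10\,\phi_{th} \approx 59.5$ mV/pH at 300 K; with the reference
surface ($N_s = 4\times10^{14}$ cm$^{-2}$, $pK_a = pK_b = 7$) the model
sits within a millivolt of it over pH 2–10.

## Stage 2: the channel side

**Sheet charge.** Two conduction (or valence) valleys in the effective-mass
approximation give an areal density of states
$D_0 = g_1 m_1^*/2\pi\hbar^2 + g_2 m_2^*/2\pi\hbar^2\, e^{-\Delta E_{12}/k_BT}$
and a degenerate quantum capacitance $C_{dq} = q^2 D_0$. With Fermi–Dirac
statistics the n-type sheet charge is
$\sigma_{2D} = -\phi_{th} C_{dq} \log(1 + e^{-\phi_{ch}/\phi_{th}})$, where
$\phi_{ch}$ is the band edge minus the quasi-Fermi level in volts. The
softplus is evaluated with a branch at zero so it neither overflows nor
underflows for $|\phi_{ch}/\phi_{th}|$ up to ~2000.

**Double-gate balance.** At each point along the channel (quasi-Fermi
potential $\phi$, equal to $V_s$ at the source and $V_d$ at the drain),
$$\sigma_{2D}(\phi_{ch}) + C_{tox}(V_{lg} - V_{go} + \psi_0 - \phi + \phi_{ch})
 + C_{box}(V_b - V_{bo} - \phi + \phi_{ch}) = 0 .$$
The electrolyte drop *adds* to the liquid-gate potential: in the
surface-minus-bulk convention used throughout the interface stage, a
positively charged interface raises the potential seen by the channel,
turns an n-type device on earlier, and lowers the threshold voltage. This
is the sign with which the model reproduces the observed response
directions — acidic solutions and positively charged macromolecules
increase the n-channel current; negative membrane charge shifts turn-on to
higher $V_{lg}$. The residual is strictly increasing in $\phi_{ch}$, and
the same bracketed bisection is used (residual $\le$ 1e-12 C/m$^2$).

**Drain current.** In the diffusive regime the current has the closed form
$$I_{ds} = \mu_n \frac{W}{L} C_{dq}\phi_{th}^2\left[
 \left(1+\frac{C_{dq}}{C_{tb}}\right)\frac{u_s^2-u_d^2}{2}
 + \left(e^{-u_d}-e^{-u_s}\right)\right],\qquad
 u = \log(1+e^{-\phi_{ch}/\phi_{th}}),$$
with $C_{tb} = C_{tox} + C_{box}$ and $u_s, u_d$ evaluated at the source
and drain. It vanishes identically at $V_{ds}=0$, is gauge invariant under
common terminal shifts, and mirrors exactly between n- and p-type devices.
Against brute-force integration of $\mu |\sigma_{2D}|\, d\phi$ (with
$\phi_{ch}(\phi)$ solved pointwise) the closed form is exact in the
deep-subthreshold and deep-accumulation limits but is an approximation in
between: its exchange term $e^{-u_d}-e^{-u_s}$ stands in for the exact
integrand contribution $u/(1-e^{-u})$. For the reference device
($C_{dq}/C_{tb} \approx 58$) the deviation peaks at about 0.7% just above
threshold and falls below 0.1% in subthreshold; the error shrinks further
as $C_{dq}/C_{tb}$ grows. The test suite pins this at a 1% regression
bound.

The deep-subthreshold swing follows the capacitive divider,
$SS = \ln 10\,\phi_{th}\,(1 + C_{box}/C_{tox}) \approx 60.6$ mV/dec for
the reference stack, and the simulated curves match it within 2%.

## Sensing figures of merit

```{r sensing}
before <- preset_table1(pH = 3, Ns = 4e16,
                        membrane = streptavidin_membrane(Nt = 0, kq = 22.3))
after <- preset_table1(pH = 3, Ns = 4e16,
                       membrane = streptavidin_membrane(Nt = 100e-15, kq = 22.3))
rep <- sensing_report(before, after)
glance(rep)
```

* **Threshold voltage.** There is no single canonical extraction method in
  the field, so both common ones are provided.
  `constant_current` (default) finds the smallest $V_{lg}$ with
  $I_{ds} \ge I_{th}\,W/L$, $I_{th} = 10^{-7}$ A, interpolating linearly in
  $\log_{10} I_{ds}$ between grid points — exact on an ideal exponential
  subthreshold characteristic. `max_gm` extrapolates $I_{ds}$ to zero from
  the maximum-transconductance point; note that in a model with constant
  mobility $g_m$ grows monotonically in strong inversion, so this method
  extrapolates from the top of the sweep and is grid-dependent — it is
  kept for comparability with experimental practice, and reports always
  name the method used.
* **Threshold shift.** $\Delta V_{th} = V_{th}^{analyte} - V_{th}^{ref}$
  equals $-\Delta\psi_0$ exactly, since $\psi_0$ and $V_{lg}$ enter the
  channel equation through the same capacitance.
* **Current sensitivity.** $S = |I_{after}-I_{before}|/\min(I_b, I_a)$ at a
  common gate bias. The evaluation biases are design choices: subthreshold
  at $V_{th}^{ref} - 0.2$ V (main $V_{ds} = 1$ V), saturation at
  $V_{th}^{ref} + 0.5$ V ($V_{ds} = 1$ V $>$ overdrive), linear at the same
  overdrive with $V_{ds} = 50$ mV. In subthreshold the two curves are
  parallel exponentials, so $S$ plateaus at
  $10^{|\Delta V_{th}|/SS} - 1$ — the maximum the device can deliver — and
  it is ordered subthreshold $>$ saturation $>$ linear, since the on-state
  current depends only algebraically on the overdrive.

With the reference functionalized surface
($N_s = 4\times10^{12}$ cm$^{-2}$), pH 3, 1 mM ionic strength and 100 fM
streptavidin ($K_c N_t = 1$, half occupancy, $N_m \approx 5.1\times10^{20}$
cm$^{-3}$), the model gives $\psi_{DP} = 0.174$ V,
$\Delta V_{th} = -0.102$ V and a subthreshold sensitivity near 25 — the
plateau bound $10^{\Delta\psi_0/SS}-1 \approx 48$ caps what any evaluation
bias can show for this parameter set. Reported experimental sensitivities
around 200 for this system correspond to $\Delta\psi_0 \approx 0.14$ V,
which this parameter set only reaches if the residual hydroxyl site
density after functionalization is a few $10^{11}$–$10^{12}$ cm$^{-2}$:
the site-binding feedback of a more reactive surface buffers the buffer
solution's $\psi_0$ upward and absorbs a third of the Donnan signal. The
residual site density after functionalization is the least constrained
parameter in the model, and sensitivity comparisons should treat it as the
dominant uncertainty.

## Parameters that matter

| Parameter | Meaning | Unit | Reference default |
|---|---|---|---|
| $N_s$ | surface hydroxyl site density | m$^{-2}$ | $4\times10^{18}$ (bare); $4\times10^{16}$ functionalized |
| $pK_a, pK_b$ | surface dissociation constants | — | 7, 7 ($\mathrm{pH}_{pzc} = 7$) |
| $i_0$ | ionic strength | mol/L | $10^{-3}$ |
| $C_{Stern}$ | Stern capacitance | F/m$^2$ | 0.20 |
| $\varepsilon_w, \varepsilon_m$ | electrolyte / membrane permittivity | — | $80\,\varepsilon_0$ both |
| $N_r, K_c, h_m$ | receptor density, binding constant, membrane height | m$^{-2}$, M$^{-1}$, m | $2.3\times10^{17}$, $10^{13}$, $5\times10^{-9}$ |
| $k_q$ | charges per bound molecule | — | user input, pH-dependent |
| $m^*_{1,2}, g_{1,2}, \Delta E_{12}$ | two-valley band structure | —, —, eV | 0.54/0.58, 2/6, 0.07 |
| $C_{tox}, C_{box}$ | oxide capacitances | F/m$^2$ | $7.4\times10^{-3}$, $1.3\times10^{-4}$ |
| $V_{go}, V_{bo}$ | gate offset voltages | V | 0.48, 0 |
| $\mu_n$ | effective mobility | m$^2$/Vs | $20\times10^{-4}$ |
| $T$ | temperature | K | 300 |

The membrane permittivity defaults to the electrolyte value; the two are
listed separately because a dense protein layer can depress
$\varepsilon_m$, which enters $\sigma_{md}$ under the square root. The
temperature is user-settable; every Boltzmann factor and the thermal
voltage derive from it.

## What the simulated studies do and do not capture

The sweep generators reproduce the *study designs* of the reference
experiments: transfer curves across pH (ion sensing), fixed-$N_m$ ladders
(charge sensitivity), salt series (screening), streptavidin titrations and
before/after sensitivity pairs. They are deterministic physics
simulations, not synthetic data with noise: there is no trap-related
hysteresis or drift, no contact resistance, no mobility degradation, no
measurement noise, and binding is pure equilibrium Langmuir occupancy with
no kinetics. Passing the qualitative contracts (curve orderings, shift
directions, screening trends) therefore validates the model logic, not the
instrument-level realism of any particular measured device. The model is
also strictly 1D-electrostatic across the stack and ignores lateral
inhomogeneity of the bound-charge layer.

## Numerical choices

* Root solves: bracketed bisection to machine resolution on the potential,
  with residual tolerance 1e-12 C/m$^2$; both residuals are strictly
  monotone so roots are unique and bracket expansion is safe. Newton is
  offered for the interface solve and cross-checked in tests.
* Degenerate inputs: $N_s = 0$ (inert surface), $N_m = 0$ (no analyte) and
  pH $= \mathrm{pH}_{pzc}$ all collapse to exact zeros of the respective
  charges; $h_m = 0$ and $n_0 = 0$ with $N_m \ne 0$ are rejected as
  degenerate.
* Transfer sweeps default to 201 bias points centred on the turn-on region
  found by a coarse 61-point pre-scan; the brute-force transport oracle in
  the tests integrates on up to $10^4$ quasi-Fermi points.
* All internal quantities are SI (the valley separation is kept in eV);
  the config loader converts the field's customary mixed units (nm,
  cm$^{-2}$, mM, µF/cm$^2$, fM) on entry. Physical constants are CODATA
  2018 values.
* Exported CSVs print doubles with 17 significant digits so re-import is
  bit-exact, and identical configurations produce byte-identical files.

## Known limitations

Beyond the idealizations listed above: the electrolyte is a symmetric 1:1
salt described by a single ionic strength (no ion-specific effects, no
finite ion size); the membrane is charge-neutral in its core (valid when
its thickness exceeds the internal screening length, i.e. for
$|N_m| \gg n_0$); only the Donnan plateau and the integrated charge are
resolved, not the potential profile inside the membrane; the channel is
single-carrier (no ambipolar conduction) with exactly two valleys; and the
decoupling of $\psi_0$ from the channel charge is built in — re-coupling
$\sigma_{2D}$ into the interface balance would change the model class and
is deliberately not offered.
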