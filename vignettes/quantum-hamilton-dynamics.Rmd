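---
title: "State-dependent dynamics of diatomic molecules from complex quantum trajectories"
author: "qhmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-dependent dynamics of diatomic molecules from complex quantum trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qhmd)
```

## The model

A diatomic molecule is reduced to a single particle of reduced mass
$M = M_A M_B/(M_A+M_B)$ moving in the internuclear Morse potential

$$V(\tilde r) = E_D\left(e^{-2(\tilde r - b)} - 2\,e^{-(\tilde r - b)}\right),
\qquad \tilde r = \beta r,\ b = \beta r_0,$$

with minimum $-E_D$ at the equilibrium bond length $r_0$ and dissociation
limit $0$. Internally everything is dimensionless: lengths in $1/\beta$,
times in $M/(\hbar\beta^2)$, energies in $E_D$. The single dimensionless
group $\lambda = \sqrt{2 M E_D}/(\hbar\beta)$ measures the well depth
(number of bound states $\approx \lambda - 1/2$).

Instead of sampling $|\Psi|^2$, the package follows *complex quantum
trajectories*. With $S = -i\hbar\ln\Psi$ the canonical momenta are
$p_q = \partial S/\partial q = -i\hbar\,\partial\ln\Psi/\partial q$, and the
quantum Hamiltonian in spherical coordinates is the classical one plus the
divergence correction $-(i\hbar/2M)\nabla\!\cdot\!\mathbf p$. Substituting
an eigenfunction $\Psi_{n,J,m_J} = R_{n,J}(\tilde r)\,
\Theta_{J,m_J}(\theta)\, e^{i m_J \phi}$ gives the velocity field

$$\frac{d\tilde r}{d\tau} = -i\,\frac{d\ln(\tilde r R)}{d\tilde r}, \qquad
\frac{d\theta}{d\tau} = -\frac{i}{\tilde r^2}
  \left(\frac{d\ln\Theta}{d\theta} + \frac{\cot\theta}{2}\right), \qquad
\frac{d\phi}{d\tau} = \frac{m_J}{\tilde r^2\sin^2\theta}.$$

Because the momenta are slaved to the state, the energy, squared angular
momentum and $L_z$ evaluated along *any* trajectory are algebraic
identities: $H = E_{n,J}$, $L^2 = J(J+1)\hbar^2$, $L_z = m_J\hbar$. This is
the dynamical face of quantization, and it is what
`conserved_quantities()` verifies at every stored step.

## The eigensystem and the Pekeris reduction

The rotating Morse problem is not exactly solvable; the centrifugal term
$J(J+1)/\tilde r^2$ is replaced by its second-order expansion in
$y = e^{-(\tilde r - b)}$ (Pekeris). With $t = 1/b$,

$$\frac{1}{\tilde r^2} \approx \frac{c_0 + c_1 y + c_2 y^2}{b^2},\qquad
c_0 = 1 - 3t + 3t^2,\; c_1 = 4t - 6t^2,\; c_2 = 3t^2 - t,$$

the radial equation keeps Morse form with modified coefficients, giving

$$\eta = \lambda\sqrt{1 + a c_2},\qquad
\alpha = \frac{\lambda(2 - a c_1)}{\sqrt{1 + a c_2}} - 2n - 1,\qquad
a = \frac{J(J+1)}{\lambda^2 b^2},$$

radial eigenfunctions $R_{n,J} = \tilde r^{-1} e^{-z/2} z^{\alpha/2}
L_n^{\alpha}(z)$ with $z = 2\eta\, e^{-(\tilde r - b)}$, and eigenvalues
$E_{n,J}/E_D = a c_0 - \alpha^2/(4\lambda^2)$. At $J = 0$ this is exact
($\alpha = 2\lambda - 2n - 1$, $\eta = \lambda$). Two non-trivial checks
pin the reduction down:

* the $\lambda\to\infty$ quadratic expansion of $E_{n,J}$ in $J(J+1)$
  yields exactly the spectroscopic constants
  $\bar B = \hbar^2/(4 h c I_0)$ ($I_0 = M r_0^2/2$) and
  $\bar D = (\hbar^2/4 b I_0)^2/(h c E_D)$ used by the distortion
  spectrum $\nu = 2\bar B(J{+}1) - 4\bar D (J{+}1)^3$;
* a brute-force finite-difference eigensolve of the reduced radial
  equation reproduces the closed-form $E_{0,1}$ (test suite).

Because the eigenfunctions solve the *reduced* Hamiltonian, the
$H$-diagnostic defaults to the Pekeris-consistent centrifugal factor, for
which $H \equiv E_{n,J}$ is exact; `centrifugal = "exact"` evaluates the
true $1/\tilde r^2$ term instead and exposes the truncation error (about
$10^{-4}$ relative for HCl at $J = 1$, growing with $J$). Both modes are
available precisely so that the approximation error is measurable rather
than hidden.

## Vibration: equilibria and periods by three routes

The radial flow $d\tilde r/d\tau = \tfrac{i}{2}\,w(z)$,
$w = \alpha - z + 2 z L'/L$, is autonomous and is generated by the radial
total potential (internuclear + quantum)

$$V_{\rm Total}(\tilde r) = E_{n,J} + \frac{E_D}{4\lambda^2} w(z)^2 ,$$

whose poles at the Laguerre nodes are the infinite barriers splitting the
$n$-th state into $n+1$ shells. Per shell, four independently computed
positions coincide (to $\sim 10^{-10}$ in $\tilde r$, `coincidence_check()`):
the minimum of $V_{\rm Total}$, the zero of the radial force, the zero of
the complex velocity, and the maximum of the radial probability
$\tilde r^2 R^2$ — for $n = 0$ the closed form
$\tilde r_{\rm eq} = b - \ln(\alpha/2\eta)$, increasing with $J$
(centrifugal stretch).

The vibration period is computed three ways and must agree:

1. **trajectory**: Poincaré-section returns of the integrated contour,
   interpolated with a cubic Hermite step (using the analytic velocity at
   the stored points) and averaged over cycles 2–4 — the first cycle is
   discarded to remove start-up bias, a measurement choice of this package;
2. **residue**: $T = \oint dz/\dot z = 2\pi i/\dot z'(z_{\rm eq})$, which
   collapses to $4\pi/\alpha$ for $n = 0$ — contour-independent, hence the
   quantized period;
3. **force constant**: $T = 2\pi\sqrt{M/K}$ with
   $K = \beta^2 V_{\rm Total}''(\tilde r_{\rm eq})$.

The three routes agree to $10^{-10}$ or better for the built-in molecules;
the *printed* reference periods are reproduced to $\approx 0.1\%$, limited
by the rounded constants used for the reference $\lambda$ values (the
package uses CODATA 2018 $\hbar$; the comparison tolerance of 0.5% in the
tests reflects this, not an accuracy limit of the method).

## Angular dynamics, spin regions and the second-kind branch

For $J = m_J = 0$ the polar equation retains the non-trivial complex
solution $d\theta/d\tau = -i\cot(\theta)/(2\tilde r^2)$. Its flow conserves
$|\cos\theta|$, so the plane splits cleanly: $|\cos\theta_0| < 1$ gives
periodic motion around $\theta = \pi/2$ ($\Omega_0$, zero mean drift),
$|\cos\theta_0| > 1$ gives monotone drift of $\theta_R$ — downward for
$\theta_I > 0$ ($\Omega_-$) and upward for $\theta_I < 0$ ($\Omega_+$) —
carrying mean polar angular momentum
$\langle \tilde r^2\dot\theta\rangle = \mp\hbar/2$. For general states the
drift regions carry $\mp(J + 1/2)\hbar$ while $L_z = m_J\hbar$ exactly.
`classify_spin()` estimates the mean from the endpoint drift of
$\theta_R$ (the exact time integral of the instantaneous rate at fixed
radius, immune to partial-cycle bias), discards the first 10% of the run,
and errors out unless half-window and full-window means agree within 1%
(absolute floor 0.03 $\hbar$ for the zero-mean region).

The polar equation is second order in disguise: its general solution is
$B_1 P_J^{m_J}(\cos\theta) + B_2 Q_J^{m_J}(\cos\theta)$. Two design
decisions matter here:

* **Branch of $Q$.** The package uses the cut-plane second kind
  ($Q_0 = \tfrac12[\log(x{+}1) - \log(x{-}1)]$, decaying as
  $x^{-J-1}$), not the Ferrers form (which differs by $-i\pi/2\,P_J$).
  Only the decaying branch has the large-$|{\rm Im}\,\theta|$ asymptote
  $d\ln Q_J(\cos\theta)/d\theta \to i(J{+}1)\,{\rm sign}(\theta_I)$ that
  makes the $Q$-driven drift *anti-parallel* to the $P$-driven one — the
  anti-spin sub-state. Higher degrees come from the standard three-term
  recurrences seeded at $J = 0, 1$; associated orders from the
  $m$-ascending recurrence. Tests validate the values against an
  independent Neumann-integral oracle and the Legendre ODE residual.
* **Analytic continuation during integration.** $Q$ is multivalued, and
  drifting trajectories wind around the singularities. Rather than
  re-evaluating $Q$ (risking branch-cut jumps mid-trajectory), the angular
  log-derivative $g = \Theta'/\Theta$ is carried as an auxiliary state
  with its Riccati equation
  $dg/d\theta = -\cot\theta\, g - J(J{+}1) + m_J^2/\sin^2\theta - g^2$,
  which continues $g$ analytically along the path. Radial quantities never
  need this: they are rational in the entire function $z(\tilde r)$.

## Rotational spectra

Three models of the $J \to J+1$ absorption wavenumber are provided:
rigid rotor $2\bar B(J{+}1)$; centrifugal distortion
$2\bar B(J{+}1) - 4\bar D(J{+}1)^3$ (from the quadratic eigenvalue
expansion); and the trajectory-based model, which evaluates the classical
rotational energy with the state-dependent dynamics —
$E_{\rm rot}(J) = [(J+\tfrac12)\hbar]^2 / (2 M r_J^2)$ with the mean
angular momentum of the drift regions and the $J$-dependent equilibrium
bond length $r_J$. For HCl the trajectory model lands within 0.4–1.2% of
the measured far-infrared lines over $J = 0..8$, closer than the
distortion model throughout. An ordinary least-squares fit of
$(\bar B, \bar D)$ to the measured lines (design functions $2(J{+}1)$ and
$-4(J{+}1)^3$) is reported for comparison but is deliberately not an
accuracy claim, since fitted constants absorb all model error.

## Numerical choices

* **Integrator**: Dormand–Prince 4/5 (deSolve, `ode45`) on the real
  dimensionless time driving the complex state split into real pairs;
  defaults rtol $10^{-10}$, atol $10^{-12}$. Periods must be resolved to 4
  significant figures; halving the tolerance moves the measured period by
  $< 10^{-6}$ relative.
* **Singularity guard**: steps evaluating within $10^{-10}$ (relative to
  the local derivative scale) of a wavefunction node, or at
  $\theta \in \pi\mathbb Z$, raise an error during direct evaluation; the
  integrator truncates the trajectory there and flags the termination
  reason instead of silently continuing.
* **Default initial conditions**: radial contours start at
  $\tilde r_{\rm eq} + \delta$, $\delta \in \{0.05, 0.1, 0.2\}$; angular
  runs on a grid $\theta_R \in \{\pi/4, \pi/2, 3\pi/4\}$,
  $\theta_I \in \{-3, -1, 0, 1, 3\}$, with the radius frozen at
  $\tilde r_{\rm eq}$ (the configuration in which the spin regions are
  defined). The sources describe families of contours without stating
  their starting points; these grids cover both drift regions and the
  central region.
* **Problem sizes**: test and acceptance runs integrate 5.5 vibration
  periods at 2500 stored points for period measurements and
  $\tau \le 300$ at 3000 points for angular means — enough for the 1%
  mean-stability requirement with comfortable margin on a single core.
* **Physical constants**: CODATA 2018. Reference tables computed with
  rounded constants differ in the 3rd–4th digit; all table comparisons
  therefore use 0.5% tolerances.

## What the built-in data represent — and limits

The four parameter sets (H₂, HCl, O₂, N₂) and the nine measured HCl lines
are transcriptions of standard reference values; they exercise wells from
$\lambda \approx 17$ to $67$. Passing tests demonstrate internal
consistency of the eigensystem, dynamics and spectra for *isolated, rigid*
diatomics in stationary states. They do not probe: non-stationary or
superposition states of the radial problem, many-electron or
condensed-phase effects, intensities or line shapes, hyperfine structure,
or the validity of the Pekeris reduction at high $J$ — the equilibrium
bond length drifts away from $r_0$ as $J$ grows and the expansion
degrades, which is visible as the growing error of the trajectory-based
spectrum at $J = 8$. The identification of the $\Omega_\pm$ drift regions
with spin-$\tfrac12$ sub-states is a labelling convention of the model,
not an assertion about measured spin observables.
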