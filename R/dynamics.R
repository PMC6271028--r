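#' Complex canonical momenta in an eigenstate
#'
#' The canonical momentum conjugate to each spherical coordinate is the
#' logarithmic gradient of the wavefunction, `p_q = -i * d ln(Psi)/d q` in
#' dimensionless units (`p_r` in units of `hbar*beta`, the angular momenta
#' in units of `hbar`); multiply by those scales for SI values.
#'
#' @param eig A `qhm_eigensystem`.
#' @param r_tilde,theta,phi Complex coordinates.
#' @param dimensional If `TRUE`, return SI momenta (kg m/s and J s).
#' @return A list with components `p_r`, `p_theta`, `p_phi`.
#' @export
canonical_momenta <- function(eig, r_tilde, theta, phi = 0 + 0i, dimensional = FALSE) {
  ld <- log_derivatives(eig, r_tilde, theta, phi)
  out <- list(p_r = -1i * ld$dr, p_theta = -1i * ld$dtheta, p_phi = -1i * ld$dphi)
  if (dimensional) {
    k <- physical_constants()
    out$p_r <- out$p_r * k$hbar * eig$molecule$beta
    out$p_theta <- out$p_theta * k$hbar
    out$p_phi <- out$p_phi * k$hbar
  }
  out
}

#' Classical Hamiltonian of the nuclear motion
#'
#' The classical reference model: kinetic energy in spherical coordinates
#' plus the Morse internuclear potential, for explicitly supplied momenta.
#'
#' @param p_r Radial momentum (kg m/s).
#' @param p_theta,p_phi Angular momenta (J s).
#' @param r_tilde,theta Coordinates (dimensionless radius, polar angle).
#' @param p A `molecule_params` object.
#' @return Energy in joules.
#' @export
classical_hamiltonian <- function(p_r, p_theta, p_phi, r_tilde, theta, p) {
  r <- r_tilde / p$beta
  p_r^2 / (2 * p$M) + p_theta^2 / (2 * p$M * r^2) +
    p_phi^2 / (2 * p$M * r^2 * sin(theta)^2) + morse_potential(r_tilde, p)
}

# Squared angular momentum (units hbar^2) along a phase point of the state:
# l_theta^2 + cot^2/4 - d^2 ln(Psi)/d theta^2 + mJ^2/sin^2, with
# l_theta = -i (g + cot(theta)/2). An algebraic identity equal to J(J+1) for
# any solution of the associated Legendre equation.
.l2_at <- function(eig, theta, g = NULL) {
  m <- abs(eig$state$mJ)
  if (is.null(g)) {
    g <- if (eig$state$J == 0L && eig$state$branch == "first_kind")
      rep(0 + 0i, length(theta)) else eig$angular$g(theta)
  }
  ct <- cos(theta) / sin(theta)
  d2 <- -ct * g - eig$state$J * (eig$state$J + 1) + m^2 / sin(theta)^2 - g^2
  lth <- -1i * (g + ct / 2)
  list(l2 = lth^2 + ct^2 / 4 - d2 + m^2 / sin(theta)^2, l_theta = lth)
}

#' Quantum Hamiltonian evaluated on the state
#'
#' Evaluates the complex quantum Hamiltonian (kinetic terms built from the
#' canonical momenta plus the divergence correction, the centrifugal energy
#' and the Morse potential) at arbitrary complex coordinates, with all
#' momenta slaved to the wavefunction. On an eigenstate this is identically
#' the eigenvalue when the centrifugal term uses the same Pekeris reduction
#' that the eigenfunction solves (`centrifugal = "pekeris"`, the default);
#' `"exact"` uses `1/r^2` and reports the approximation error for `J > 0`.
#'
#' @param eig A `qhm_eigensystem`.
#' @param r_tilde,theta,phi Complex coordinates (vectorised).
#' @param centrifugal `"pekeris"` or `"exact"`.
#' @param parts If `TRUE`, also return the individual energy contributions.
#' @return Complex energy in joules (or a list when `parts = TRUE`).
#' @export
quantum_hamiltonian <- function(eig, r_tilde, theta = pi / 2 + 0i, phi = 0 + 0i,
                                centrifugal = c("pekeris", "exact"), parts = FALSE) {
  centrifugal <- match.arg(centrifugal)
  pk <- eig$pk; lam <- eig$const$lam; E_D <- eig$const$E_scale
  radial <- -eig$radial$upp_over_u(r_tilde) / lam^2
  l2 <- .l2_at(eig, theta)$l2
  y <- exp(-(r_tilde - pk$b))
  Fcent <- if (centrifugal == "pekeris") (pk$c0 + pk$c1 * y + pk$c2 * y^2) / pk$b^2 else 1 / r_tilde^2
  Vm <- y^2 - 2 * y
  H <- E_D * (radial + l2 * Fcent / lam^2 + Vm)
  if (!parts) return(H)
  list(H = H, radial_kinetic = E_D * radial, l2_hbar2 = l2,
       centrifugal = E_D * l2 * Fcent / lam^2, V_morse = E_D * Vm)
}

#' State-dependent equations of motion
#'
#' Returns the complex velocity field of the quantum Hamilton equations in
#' dimensionless form:
#' `dr/dtau = -i * d ln(r R)/dr`,
#' `dtheta/dtau = -(i/r^2) * (d ln(Theta)/dtheta + cot(theta)/2)`,
#' `dphi/dtau = mJ / (r^2 sin^2 theta)`.
#' For second-kind or mixed angular branches the angular log-derivative `g`
#' must be supplied (it is carried as a Riccati state by the integrator so
#' the multivalued second-kind function is continued analytically).
#'
#' @param eig A `qhm_eigensystem`.
#' @return A function `(r_tilde, theta, phi, g = NULL)` returning a list
#'   with `vr`, `vtheta`, `vphi` and `vg` (the Riccati rate, `NULL` for the
#'   first-kind branch).
#' @export
equations_of_motion <- function(eig) {
  st <- eig$state
  pure_P <- st$B2 == 0
  J <- st$J; m <- abs(st$mJ); JJ1 <- J * (J + 1)
  function(r_tilde, theta, phi = 0 + 0i, g = NULL) {
    vr <- -1i * eig$radial$dlog_u(r_tilde)
    if (is.null(g)) {
      if (!pure_P) stop("equations_of_motion: second-kind/mixed branch requires the angular log-derivative state g", call. = FALSE)
      g <- if (J == 0L) rep(0 + 0i, length(theta)) else eig$angular$g(theta)
    }
    s <- sin(theta)
    if (any(abs(s) < 1e-10)) stop("singular polar angle (theta at a multiple of pi)", call. = FALSE)
    ct <- cos(theta) / s
    vtheta <- -1i * (g + ct / 2) / r_tilde^2
    vphi <- st$mJ / (r_tilde^2 * s^2)
    vg <- (-ct * g - JJ1 + m^2 / s^2 - g^2) * vtheta
    list(vr = vr, vtheta = vtheta, vphi = vphi, vg = vg)
  }
}

#' Integrate a complex quantum trajectory
#'
#' Adaptive embedded Runge-Kutta (Dormand-Prince 4/5 via deSolve) on the
#' real dimensionless time driving the complex coordinates. Diagnostics
#' (complex H, L^2, L_z) are evaluated at every stored step. Integration is
#' truncated (and flagged) if a step approaches a wavefunction node or a
#' polar-axis singularity.
#'
#' @param eig A `qhm_eigensystem`.
#' @param r0 Initial complex `r_tilde` (default: equilibrium + 0.1).
#' @param theta0,phi0 Initial complex angles.
#' @param tau_max Final dimensionless time.
#' @param n_out Number of stored output points.
#' @param rtol,atol Integrator tolerances.
#' @param fix_r If `TRUE`, hold `r_tilde` fixed at `r0` (angular-only runs).
#' @return A `qhm_trajectory` with fields `tau`, complex `r`, `theta`,
#'   `phi` (and `g` for non-first-kind branches), a `diagnostics` data frame
#'   and integrator statistics.
#' @export
integrate_trajectory <- function(eig, r0 = NULL, theta0 = pi / 2 + 0i, phi0 = 0 + 0i,
                                 tau_max = 2, n_out = 2000, rtol = 1e-10, atol = 1e-12,
                                 fix_r = FALSE) {
  if (is.null(r0)) r0 <- equilibrium_bond_length(eig$state, eig$pk) + 0.1
  r0 <- as.complex(r0); theta0 <- as.complex(theta0); phi0 <- as.complex(phi0)
  rhs <- equations_of_motion(eig)
  carry_g <- eig$state$B2 != 0
  g0 <- if (carry_g) eig$angular$g(theta0) else NULL
  guard <- new.env(); guard$bad_tau <- Inf
  deriv <- function(t, y, parms) {
    r <- complex(real = y[1], imaginary = y[2])
    th <- complex(real = y[3], imaginary = y[4])
    g <- if (carry_g) complex(real = y[7], imaginary = y[8]) else NULL
    v <- tryCatch(rhs(r, th, g = g), error = function(e) NULL)
    bad <- is.null(v) || !all(is.finite(c(Re(v$vr), Im(v$vr), Re(v$vtheta), Im(v$vtheta)))) ||
      max(abs(v$vr), abs(v$vtheta)) > 1e8
    if (bad) {
      guard$bad_tau <- min(guard$bad_tau, t)
      return(list(rep(0, length(y))))
    }
    vr <- if (fix_r) 0 + 0i else v$vr
    dy <- c(Re(vr), Im(vr), Re(v$vtheta), Im(v$vtheta), Re(v$vphi), Im(v$vphi))
    if (carry_g) dy <- c(dy, Re(v$vg), Im(v$vg))
    list(dy)
  }
  y0 <- c(Re(r0), Im(r0), Re(theta0), Im(theta0), Re(phi0), Im(phi0))
  if (carry_g) y0 <- c(y0, Re(g0), Im(g0))
  times <- seq(0, tau_max, length.out = n_out)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "ode45", rtol = rtol, atol = atol)
  keep <- sol[, 1] <= guard$bad_tau
  sol <- sol[keep, , drop = FALSE]
  traj <- list(
    tau = sol[, 1],
    r = complex(real = sol[, 2], imaginary = sol[, 3]),
    theta = complex(real = sol[, 4], imaginary = sol[, 5]),
    phi = complex(real = sol[, 6], imaginary = sol[, 7]),
    g = if (carry_g) complex(real = sol[, 8], imaginary = sol[, 9]) else NULL,
    eig = eig,
    stats = list(rtol = rtol, atol = atol, n_out = n_out, fix_r = fix_r,
                 termination = if (is.finite(guard$bad_tau))
                   sprintf("singularity approach at tau = %.6g", guard$bad_tau) else "tau_max")
  )
  class(traj) <- "qhm_trajectory"
  traj$diagnostics <- conserved_quantities(eig, traj)
  traj
}

#' @export
print.qhm_trajectory <- function(x, ...) {
  cat(sprintf("Complex quantum trajectory: %s (n=%d, J=%d, mJ=%d), %d steps, tau in [0, %.4g]\n",
              x$eig$molecule$name, x$eig$state$n, x$eig$state$J, x$eig$state$mJ,
              length(x$tau), max(x$tau)))
  cat(sprintf("  termination: %s\n", x$stats$termination))
  d <- x$diagnostics
  cat(sprintf("  <H> = %.6g J, max|L2 - J(J+1)hbar^2| = %.3g hbar^2\n",
              mean(Re(d$H)), max(abs(d$L2_hbar2 - x$eig$state$J * (x$eig$state$J + 1)))))
  invisible(x)
}

#' Conserved-quantity diagnostics along a trajectory
#'
#' Evaluates the complex energy `H`, squared angular momentum `L^2` and
#' z-component `L_z` at every stored step. In an eigenstate these are
#' quantized: `H = E_{n,J}`, `L^2 = J(J+1) hbar^2`, `L_z = mJ hbar`.
#'
#' @param eig A `qhm_eigensystem`.
#' @param traj A `qhm_trajectory`.
#' @param centrifugal Passed to [quantum_hamiltonian()].
#' @return A data frame with `tau`, complex `H` (joules), and `L2_hbar2`,
#'   `Lz_hbar` in units of `hbar^2` and `hbar`.
#' @export
conserved_quantities <- function(eig, traj, centrifugal = "pekeris") {
  l2 <- .l2_at(eig, traj$theta, g = traj$g)$l2
  pk <- eig$pk; lam <- eig$const$lam
  y <- exp(-(traj$r - pk$b))
  Fc <- if (centrifugal == "pekeris") (pk$c0 + pk$c1 * y + pk$c2 * y^2) / pk$b^2 else 1 / traj$r^2
  H <- eig$const$E_scale *
    (-eig$radial$upp_over_u(traj$r) / lam^2 + l2 * Fc / lam^2 + y^2 - 2 * y)
  data.frame(tau = traj$tau, H = H, L2_hbar2 = l2,
             Lz_hbar = rep(eig$state$mJ + 0i, length(traj$tau)))
}

#' Quantum potential by energy bookkeeping
#'
#' `Q = H_Psi - T - V_eff`, where `T` is the classical kinetic energy
#' evaluated with the complex trajectory velocities. The total potential is
#' `V_Total = V_eff + Q = H_Psi - T`.
#'
#' @param eig A `qhm_eigensystem`.
#' @param r_tilde,theta,phi Complex coordinates.
#' @param centrifugal Passed to [quantum_hamiltonian()].
#' @return A list with complex `Q`, `V_total`, `T_kinetic` and `V_eff`
#'   (joules).
#' @export
quantum_potential <- function(eig, r_tilde, theta = pi / 2 + 0i, phi = 0 + 0i,
                              centrifugal = "pekeris") {
  E_D <- eig$const$E_scale; lam <- eig$const$lam
  v <- equations_of_motion(eig)(r_tilde, theta, phi)
  T_dimless <- v$vr^2 + r_tilde^2 * v$vtheta^2 + r_tilde^2 * sin(theta)^2 * v$vphi^2
  T_k <- E_D * T_dimless / lam^2
  H <- quantum_hamiltonian(eig, r_tilde, theta, phi, centrifugal = centrifugal)
  Veff <- morse_potential(r_tilde, eig$molecule)
  list(Q = H - T_k - Veff, V_total = H - T_k, T_kinetic = T_k, V_eff = Veff)
}

# Dimensionless radial velocity factor w(z) = alpha - z + 2 z L'/L and its
# z-derivative; dr/dtau = i*w/2, so zeros of w are the radial equilibria.
.radial_w <- function(state, pk, z, deriv = FALSE) {
  n <- state$n; alpha <- pk$alpha
  L <- laguerre_eval(n, alpha, z); Lp <- laguerre_eval(n, alpha, z, 1L)
  .check_node(L + 0i, "r", ref = z * Lp)
  w <- alpha - z + 2 * z * Lp / L
  if (!deriv) return(w)
  Lpp <- laguerre_eval(n, alpha, z, 2L)
  g <- Lp / L
  list(w = w, dw = -1 + 2 * (g + z * (Lpp / L - g^2)))
}

#' Radial total potential (closed form)
#'
#' Along the radial direction the complex dynamics is autonomous and is
#' generated by the state-dependent total potential
#' `V_Total(r) = E_{n,J} + (E_D / 4 lam^2) * w(z)^2`,
#' `w(z) = alpha - z + 2 z L'/L`, which has poles (infinite barriers) at the
#' radial nodes and a minimum in each shell at the zero-velocity equilibria.
#'
#' @param state A `qhm_state`.
#' @param pk Matching `pekeris_constants`.
#' @param const Matching `qhm_constants`.
#' @param r_tilde Dimensionless radius (real or complex, vectorised).
#' @return Energy in joules.
#' @export
total_potential_radial <- function(state, pk, const, r_tilde) {
  z <- pk$z_of_r(r_tilde)
  E <- eigenenergy(state, const)$E
  E + const$E_scale * .radial_w(state, pk, z)^2 / (4 * const$lam^2)
}

#' Radial quantum force
#'
#' The generalized radial force `f_r = -dV_Total/dr` (per physical meter
#' when `dimensional = TRUE`, per unit dimensionless length otherwise).
#' Its zeros coincide with the zero-velocity equilibria and with the maxima
#' of the radial probability.
#'
#' @inheritParams total_potential_radial
#' @return Radial force (vectorised), J per unit dimensionless length; use
#'   [radial_force_si()] for newtons.
#' @export
radial_force <- function(state, pk, const, r_tilde) {
  z <- pk$z_of_r(r_tilde)
  wv <- .radial_w(state, pk, z, deriv = TRUE)
  const$E_scale * z * wv$w * wv$dw / (2 * const$lam^2)
}

#' @rdname radial_force
#' @param p A `molecule_params` object.
#' @export
radial_force_si <- function(state, pk, const, r_tilde, p) {
  radial_force(state, pk, const, r_tilde) * p$beta
}
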