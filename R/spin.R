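#' Exact and large-|Im| asymptotic complex trigonometry
#'
#' For `theta = theta_R + i*theta_I` with `|theta_I| >> 0`,
#' `cos(theta) ~ e^{|theta_I|} (cos(theta_R) -+ i sin(theta_R))/2`,
#' `sin(theta) ~ e^{|theta_I|} (sin(theta_R) +- i cos(theta_R))/2` and
#' `cot(theta) ~ -i*sign(theta_I)`, with relative error bounded by
#' `~ 4 e^{-2|theta_I|}` (conservative). The asymptotic forms are classification
#' bookkeeping only; the dynamics always uses exact trigonometry.
#'
#' @param theta Complex angle(s).
#' @return A list of lists `exact` and `asymptotic` (each with `cos`, `sin`,
#'   `cot`) plus `error_bound`.
#' @export
asymptotic_trig <- function(theta) {
  tR <- Re(theta); tI <- Im(theta)
  sgn <- sign(tI)
  amp <- exp(abs(tI)) / 2
  list(
    exact = list(cos = cos(theta), sin = sin(theta),
                 cot = cos(theta) / sin(theta)),
    asymptotic = list(
      cos = amp * (cos(tR) - 1i * sgn * sin(tR)),
      sin = amp * (sin(tR) + 1i * sgn * cos(tR)),
      cot = -1i * sgn + 0 * theta
    ),
    error_bound = 4 * exp(-2 * abs(tI))
  )
}

#' Integrate the angular (spin) dynamics at fixed bond length
#'
#' Convenience wrapper: integrates the polar/azimuthal dynamics with the
#' radius held at the state's equilibrium bond length, the configuration in
#' which the spin regions are defined.
#'
#' @param eig A `qhm_eigensystem`.
#' @param theta0 Initial complex polar angle.
#' @param tau_max Integration time (dimensionless).
#' @param n_out Stored points.
#' @param ... Passed to [integrate_trajectory()].
#' @return A `qhm_trajectory`.
#' @export
spin_trajectory <- function(eig, theta0, tau_max = 150, n_out = 3000, ...) {
  r_eq <- equilibrium_bond_length(eig$state, eig$pk)
  integrate_trajectory(eig, r0 = r_eq, theta0 = theta0, tau_max = tau_max,
                       n_out = n_out, fix_r = TRUE, ...)
}

#' Classify a complex angular trajectory into spin regions
#'
#' The time-averaged real polar drift defines three regions:
#' `Omega_-` (monotonically decreasing `theta_R`, mean polar angular
#' momentum `-(J + 1/2) hbar`), `Omega_0` (zero-mean periodic motion,
#' quantized `L_z = mJ hbar`) and `Omega_+` (increasing `theta_R`,
#' `+(J + 1/2) hbar`). Means are taken after discarding the first 10% of
#' the trajectory; the first and second halves of the averaging window must
#' agree (stability check), otherwise an error asks for a longer run.
#'
#' @param traj A `qhm_trajectory` (typically from [spin_trajectory()]).
#' @param transient Fraction of the trajectory discarded before averaging.
#' @param tol Stability tolerance for the window-doubling check.
#' @return A `spin_classification` list: `region` (`"Omega-"`, `"Omega0"`,
#'   `"Omega+"`), `mean_dthetaR`, `L_theta_mean` and `L_phi_mean` (units of
#'   `hbar`).
#' @export
classify_spin <- function(traj, transient = 0.1, tol = 0.01) {
  eig <- traj$eig
  i0 <- max(2L, ceiling(transient * length(traj$tau)))
  n <- length(traj$tau)
  # time-averaged L_theta = r^2 <dtheta/dtau>, taken from the endpoint drift
  # (exact time integral of the instantaneous rate at fixed radius, immune
  # to partial-cycle bias of the oscillatory component)
  r2 <- mean(Re(traj$r[i0:n]))^2
  drift <- function(i1) {
    Re(traj$theta[i1] - traj$theta[i0]) / (traj$tau[i1] - traj$tau[i0])
  }
  mean_dthetaR <- drift(n)
  mean_full <- r2 * mean_dthetaR
  mean_half <- r2 * drift(i0 + floor((n - i0) / 2))
  if (abs(mean_full - mean_half) > max(tol * abs(mean_full), 3 * tol))
    stop("classify_spin: mean angular momentum not stable under window doubling; integrate longer", call. = FALSE)
  region <- if (mean_full > 0.25) "Omega+" else if (mean_full < -0.25) "Omega-" else "Omega0"
  out <- list(region = region, mean_dthetaR = mean_dthetaR,
              L_theta_mean = mean_full, L_phi_mean = as.numeric(eig$state$mJ),
              n_steps = n - i0 + 1L)
  class(out) <- "spin_classification"
  out
}

#' @export
print.spin_classification <- function(x, ...) {
  cat(sprintf("Spin region %s: <dtheta_R/dtau> = %.4g, <L_theta> = %.4g hbar, <L_phi> = %.4g hbar\n",
              x$region, x$mean_dthetaR, x$L_theta_mean, x$L_phi_mean))
  invisible(x)
}

#' Spin vs anti-spin dynamics of the two Legendre branches
#'
#' Integrates the angular dynamics generated by the first-kind (P) and
#' second-kind (Q) polar wavefunctions from the same initial condition and
#' compares the mean polar drifts: the second-kind branch drives the angular
#' motion anti-parallel to the first-kind branch, giving the two spin
#' sub-states of one `(n, J, mJ)` level. A mixed branch simulates entangled
#' spin dynamics and still falls in one of the three regions.
#'
#' @param p A `molecule_params` object.
#' @param n,J,mJ Quantum numbers.
#' @param theta0 Common initial complex polar angle.
#' @param tau_max Integration time.
#' @return A list with the two classifications (`P`, `Q`), their
#'   trajectories, and `anti_parallel` (logical).
#' @export
spin_branch_dynamics <- function(p, n = 0, J = 0, mJ = 0,
                                 theta0 = pi / 2 + 3i, tau_max = 150) {
  eP <- eigensystem(qhm_state(n, J, mJ, "first_kind"), p)
  eQ <- eigensystem(qhm_state(n, J, mJ, "second_kind"), p)
  tP <- spin_trajectory(eP, theta0, tau_max)
  tQ <- spin_trajectory(eQ, theta0, tau_max)
  cP <- classify_spin(tP); cQ <- classify_spin(tQ)
  list(P = cP, Q = cQ, traj_P = tP, traj_Q = tQ,
       anti_parallel = sign(cP$mean_dthetaR) == -sign(cQ$mean_dthetaR))
}

#' Rigid-rotor rotational spectrum
#'
#' `nu(J -> J+1) = 2 B_bar (J + 1)` in cm^-1.
#'
#' @param const A `qhm_constants` object.
#' @param J_max Largest lower level.
#' @return A data frame with `J_lower` and `nu_rigid_cm1`.
#' @export
rigid_spectrum <- function(const, J_max = 8L) {
  J <- 0:J_max
  data.frame(J_lower = J, nu_rigid_cm1 = 2 * const$B_bar * (J + 1))
}

#' Centrifugal-distortion (non-rigid) rotational spectrum
#'
#' `nu(J -> J+1) = 2 B_bar (J + 1) - 4 D_bar (J + 1)^3` in cm^-1, with the
#' centrifugal distortion constant from the molecular parameters.
#'
#' @inheritParams rigid_spectrum
#' @return A data frame with `J_lower` and `nu_nonrigid_cm1`.
#' @export
nonrigid_spectrum <- function(const, J_max = 8L) {
  J <- 0:J_max
  data.frame(J_lower = J,
             nu_nonrigid_cm1 = 2 * const$B_bar * (J + 1) - 4 * const$D_bar * (J + 1)^3)
}

#' Trajectory-based (quantum Hamilton) rotational spectrum
#'
#' Uses the classical rotational energy evaluated with the state-dependent
#' dynamics: mean angular momentum `(J + 1/2) hbar` and the J-dependent
#' equilibrium bond length `r_J` of the ground vibrational state, giving
#' `E_rot(J) = ((J + 1/2) hbar)^2 / (2 M r_J^2)` and the transition
#' wavenumber `nu = (E_rot(J+1) - E_rot(J)) / (h c)`.
#'
#' @param p A `molecule_params` object.
#' @param const Matching `qhm_constants` (default: derived from `p`).
#' @param J_max Largest lower level.
#' @return A data frame with `J_lower`, `r_J` and `r_Jp1` (dimensionless
#'   bond lengths) and `nu_qhm_cm1`.
#' @export
qhm_spectrum <- function(p, const = derive_constants(p), J_max = 8L) {
  k <- physical_constants()
  E_rot <- function(J) {
    st <- qhm_state(0L, J, 0L)
    pk <- pekeris_constants(st, const)
    r_eq_m <- equilibrium_bond_length(st, pk) / p$beta
    ((J + 0.5) * k$hbar)^2 / (2 * p$M * r_eq_m^2)
  }
  J <- 0:J_max
  E <- vapply(0:(J_max + 1L), E_rot, numeric(1))
  rj <- vapply(0:(J_max + 1L), function(j)
    equilibrium_bond_length(qhm_state(0L, j, 0L),
                            pekeris_constants(qhm_state(0L, j, 0L), const)), numeric(1))
  data.frame(J_lower = J, r_J = rj[J + 1L], r_Jp1 = rj[J + 2L],
             nu_qhm_cm1 = (E[J + 2L] - E[J + 1L]) / (k$h * k$c_cm))
}

#' Least-squares fit of rotational constants to measured lines
#'
#' Ordinary least squares of measured wavenumbers on the design functions
#' `2(J+1)` and `-4(J+1)^3` (no intercept), returning the best-fit `B_bar`
#' and `D_bar` and fitted line positions.
#'
#' @param J_lower Lower-level quantum numbers.
#' @param nu_cm1 Measured wavenumbers (cm^-1).
#' @return A list with `B_fit`, `D_fit` and `nu_fit_cm1`.
#' @export
fit_spectrum <- function(J_lower, nu_cm1) {
  x1 <- 2 * (J_lower + 1)
  x2 <- -4 * (J_lower + 1)^3
  fit <- stats::lm(nu_cm1 ~ 0 + x1 + x2)
  co <- stats::coef(fit)
  list(B_fit = unname(co[1]), D_fit = unname(co[2]),
       nu_fit_cm1 = unname(stats::fitted(fit)))
}

#' Measured HCl far-infrared rotational lines (built-in fixture)
#'
#' @return A data frame with `J_lower` (0..8) and `nu_exp_cm1`.
#' @export
hcl_lines <- function() {
  path <- system.file("extdata", "hcl_rotational_lines.csv", package = "qhmd")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "hcl_rotational_lines.csv")
  utils::read.csv(path)
}

#' Rotational-spectrum comparison table
#'
#' Per transition `J -> J+1`: rigid, non-rigid and trajectory-based model
#' wavenumbers, the least-squares fitted line (when measured lines are
#' supplied) and relative errors against the measurement.
#'
#' @param p A `molecule_params` object.
#' @param measured Optional data frame with `J_lower` and `nu_exp_cm1`.
#' @param J_max Largest lower level (default: from `measured`, else 8).
#' @return A data frame; the fitted `B_bar`/`D_bar` are attached as
#'   attributes `B_fit` and `D_fit`.
#' @export
spectrum_table <- function(p, measured = NULL, J_max = NULL) {
  const <- derive_constants(p)
  if (is.null(J_max)) J_max <- if (!is.null(measured)) max(measured$J_lower) else 8L
  tab <- merge(rigid_spectrum(const, J_max), nonrigid_spectrum(const, J_max), by = "J_lower")
  tab <- merge(tab, qhm_spectrum(p, const, J_max)[, c("J_lower", "nu_qhm_cm1")], by = "J_lower")
  if (!is.null(measured)) {
    tab <- merge(tab, measured, by = "J_lower")
    ft <- fit_spectrum(measured$J_lower, measured$nu_exp_cm1)
    tab$nu_fit_cm1 <- ft$nu_fit_cm1
    tab$rel_error_qhm <- abs(tab$nu_qhm_cm1 - tab$nu_exp_cm1) / tab$nu_exp_cm1
    tab$rel_error_nonrigid <- abs(tab$nu_nonrigid_cm1 - tab$nu_exp_cm1) / tab$nu_exp_cm1
    attr(tab, "B_fit") <- ft$B_fit
    attr(tab, "D_fit") <- ft$D_fit
  }
  tab
}
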