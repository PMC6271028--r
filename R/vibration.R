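#' Equilibrium bond length of the ground vibrational state
#'
#' For `n = 0` the radial velocity vanishes at `z = alpha`, i.e. at
#' `r_eq = b - ln(alpha / (2 eta))` (dimensionless). Because `alpha/eta`
#' depends on `J`, the equilibrium bond length grows monotonically with
#' rotation.
#'
#' @param state A `qhm_state` with `n = 0` (use [find_equilibria()] for
#'   excited vibrational states).
#' @param pk Matching `pekeris_constants`.
#' @return Dimensionless equilibrium bond length.
#' @export
equilibrium_bond_length <- function(state, pk) {
  if (state$n != 0L)
    return(find_equilibria(state, pk)$r_values[1])
  ratio <- pk$alpha / (2 * pk$eta)
  r_eq <- pk$b - log(ratio)
  if (r_eq <= 0) stop("equilibrium_bond_length: unphysical (non-positive) bond length", call. = FALSE)
  r_eq
}

#' All radial equilibria, nodes and shell structure
#'
#' Finds every finite zero of the radial velocity `dr/dtau` (equivalently of
#' the radial force and of the derivative of the radial probability).
#' Multiplying `w(z) = alpha - z + 2 z L'/L` by `L_n^alpha(z)` gives a
#' polynomial of degree `n + 1` whose positive real roots are the equilibria;
#' the `n` zeros of the Laguerre factor are the infinite-barrier nodes
#' separating the `n + 1` shells.
#'
#' @param state A `qhm_state`.
#' @param pk Matching `pekeris_constants`.
#' @return An `equilibrium_set` list: `z_values`, `r_values` (one stable
#'   equilibrium per shell, innermost first in `r`), `nodes_z`, `nodes_r`,
#'   `stability` and `shell_index`.
#' @export
find_equilibria <- function(state, pk) {
  n <- state$n; alpha <- pk$alpha
  # polynomial coefficients of (alpha - z) L(z) + 2 z L'(z), ascending powers
  k <- 0:n
  tail_prod <- rev(cumprod(c(1, rev(alpha + seq_len(max(n, 1))))))
  Lcoef <- if (n == 0L) 1 else (-1)^k / (factorial(k) * factorial(n - k)) * tail_prod[k + 1L]
  Lpcoef <- if (n == 0L) numeric(0) else Lcoef[-1] * seq_len(n)
  pad <- function(v, len) c(v, numeric(len - length(v)))
  len <- n + 2L
  poly <- pad(alpha * Lcoef, len) - pad(c(0, Lcoef), len) + pad(c(0, 2 * Lpcoef), len)
  roots <- polyroot(poly)
  zr <- roots[abs(Im(roots)) < 1e-8 & Re(roots) > 1e-10]
  z_eq <- sort(Re(zr), decreasing = TRUE)  # decreasing z = increasing r
  nodes_z <- if (n >= 1L) {
    nz <- polyroot(Lcoef)
    sort(Re(nz[abs(Im(nz)) < 1e-8]), decreasing = TRUE)
  } else numeric(0)
  shell <- vapply(z_eq, function(z) sum(nodes_z > z) + 1L, integer(1))
  out <- list(z_values = z_eq,
              r_values = pk$b - log(z_eq / (2 * pk$eta)),
              nodes_z = nodes_z,
              nodes_r = if (length(nodes_z)) pk$b - log(nodes_z / (2 * pk$eta)) else numeric(0),
              stability = rep("stable", length(z_eq)),
              shell_index = shell)
  class(out) <- "equilibrium_set"
  out
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat(sprintf("Radial equilibria: %d stable point(s) in %d shell(s), %d node(s)\n",
              length(x$z_values), max(x$shell_index), length(x$nodes_z)))
  for (i in seq_along(x$z_values))
    cat(sprintf("  shell %d: z_eq = %.6g, r_eq = %.6g\n", x$shell_index[i], x$z_values[i], x$r_values[i]))
  if (length(x$nodes_z))
    cat(sprintf("  nodes at z = %s\n", paste(sprintf("%.6g", x$nodes_z), collapse = ", ")))
  invisible(x)
}

#' Four-way coincidence of the equilibrium position
#'
#' Per shell, locates independently (a) the minimum of the radial total
#' potential, (b) the zero of the radial force, (c) the zero-velocity point
#' and (d) the maximum of the radial probability `r^2 R^2`, each by its own
#' numerical search, and reports all four in `r_tilde`.
#'
#' @param state A `qhm_state`.
#' @param pk Matching `pekeris_constants`.
#' @param const Matching `qhm_constants`.
#' @return A data frame with one row per shell and columns `shell`,
#'   `r_min_Vtotal`, `r_zero_force`, `r_zero_velocity`, `r_max_probability`
#'   and `max_spread` (largest pairwise difference).
#' @export
coincidence_check <- function(state, pk, const) {
  eqs <- find_equilibria(state, pk)
  edges_z <- c(4 * pk$eta, eqs$nodes_z, 1e-8)  # z decreasing <-> r increasing
  res <- lapply(seq_along(eqs$z_values), function(i) {
    z_hi <- edges_z[i]; z_lo <- edges_z[i + 1L]
    # bracket in r, padded away from the infinite barriers
    r_lo <- pk$b - log(z_hi / (2 * pk$eta)) + 1e-4
    r_hi <- pk$b - log(max(z_lo, 1e-6) / (2 * pk$eta)) - 1e-4
    r_hi <- min(r_hi, eqs$r_values[i] + 4)
    # extremum searches are polished past optimize()'s golden-section floor
    # by locating the zero of a central-difference derivative
    polish <- function(f, x0, h = 1e-5) {
      df <- function(x) (f(x + h) - f(x - h)) / (2 * h)
      stats::uniroot(df, c(x0 - 0.02, x0 + 0.02), tol = 1e-14)$root
    }
    vt <- function(r) Re(total_potential_radial(state, pk, const, r))
    r_v <- polish(vt, stats::optimize(vt, c(r_lo, r_hi), tol = 1e-10)$minimum)
    fr <- function(r) Re(radial_force(state, pk, const, r))
    r_f <- stats::uniroot(fr, c(r_v - 0.05, r_v + 0.05), tol = 1e-14)$root
    wz <- function(r) Re(.radial_w(state, pk, pk$z_of_r(r)))
    r_w <- stats::uniroot(wz, c(r_v - 0.05, r_v + 0.05), tol = 1e-14)$root
    rad <- radial_wavefunction(state, pk)
    prob <- function(r) Re(log(r^2 * rad$R(r + 0i)^2))
    r_p <- polish(prob, stats::optimize(function(r) -prob(r), c(r_lo, r_hi), tol = 1e-10)$minimum)
    c(r_v, r_f, r_w, r_p)
  })
  m <- do.call(rbind, res)
  data.frame(shell = seq_along(eqs$z_values),
             r_min_Vtotal = m[, 1], r_zero_force = m[, 2],
             r_zero_velocity = m[, 3], r_max_probability = m[, 4],
             max_spread = apply(m, 1, function(x) diff(range(x))))
}

#' Vibration period from a closed complex trajectory
#'
#' Measures the period by Poincare-section returns: upward crossings of
#' `Im(r) = 0` with `Re(r) > r_eq`, located by local Hermite interpolation
#' (using the stored imaginary radial velocity), averaged over cycles 2-4
#' (the first cycle is discarded to remove start-up bias).
#'
#' @param traj A `qhm_trajectory` of a closed radial contour.
#' @param r_eq Equilibrium position of the contour (default: from the
#'   trajectory's state).
#' @param cycles Which return intervals to average (default `2:4`).
#' @return Dimensionless period.
#' @export
period_from_trajectory <- function(traj, r_eq = NULL, cycles = 2:4) {
  if (is.null(r_eq)) r_eq <- equilibrium_bond_length(traj$eig$state, traj$eig$pk)
  y <- Im(traj$r); tau <- traj$tau
  right <- Re(traj$r) > r_eq
  up <- which(y[-length(y)] < 0 & y[-1] >= 0 & right[-1])
  if (length(up) < max(cycles) + 1L)
    stop(sprintf("period_from_trajectory: trajectory not closed/too short (%d section crossings, need %d)",
                 length(up), max(cycles) + 1L), call. = FALSE)
  rhs <- equations_of_motion(traj$eig)
  cross <- vapply(up, function(i) {
    t0 <- tau[i]; t1 <- tau[i + 1]; h <- t1 - t0
    y0 <- y[i]; y1 <- y[i + 1]
    d0 <- Im(rhs(traj$r[i], traj$theta[i], g = if (!is.null(traj$g)) traj$g[i] else NULL)$vr)
    d1 <- Im(rhs(traj$r[i + 1], traj$theta[i + 1], g = if (!is.null(traj$g)) traj$g[i + 1] else NULL)$vr)
    # cubic Hermite root in [0, 1]
    f <- function(s) {
      s2 <- s * s; s3 <- s2 * s
      (2 * s3 - 3 * s2 + 1) * y0 + (s3 - 2 * s2 + s) * h * d0 +
        (-2 * s3 + 3 * s2) * y1 + (s3 - s2) * h * d1
    }
    t0 + h * stats::uniroot(f, c(0, 1), tol = 1e-14)$root
  }, numeric(1))
  periods <- diff(cross)
  mean(periods[cycles[cycles <= length(periods)]])
}

#' Vibration period from the residue theorem
#'
#' The period of the closed contour around an equilibrium `z_eq` equals
#' `2 pi i / zdot'(z_eq)` (residue of `1/zdot`), independent of the contour.
#' For the ground vibrational state this is `T = 4 pi / alpha`, which at
#' `J = 0` is the quantized `4 pi / (2 lam - 1)`.
#'
#' @param state A `qhm_state`.
#' @param pk Matching `pekeris_constants`.
#' @param shell Which shell's equilibrium (1 = innermost in `z` ordering of
#'   [find_equilibria()]).
#' @return Dimensionless period (real part; the imaginary part is zero to
#'   numerical accuracy).
#' @export
period_residue <- function(state, pk, shell = 1L) {
  if (state$n == 0L) return(4 * pi / pk$alpha)
  eqs <- find_equilibria(state, pk)
  z0 <- eqs$z_values[shell]
  # zdot = (i/2) z (-w(z)); at w(z0)=0, zdot'(z0) = -(i/2) z0 w'(z0)
  dw <- .radial_w(state, pk, z0 + 0i, deriv = TRUE)$dw
  Tj <- 2 * pi * 1i / (-(0.5i) * z0 * dw)
  if (abs(Im(Tj)) > 1e-8 * abs(Re(Tj)))
    warning("period_residue: non-negligible imaginary part in period")
  Re(Tj)
}

#' State-dependent force constant and the period it implies
#'
#' `K` is the curvature of the radial total potential at the equilibrium,
#' taken in physical units (`K = beta^2 * d^2 V_Total / d r_tilde^2`, N/m);
#' the classical relation `T = 2 pi sqrt(M / K)` then reproduces the
#' residue-theorem period.
#'
#' @param state A `qhm_state`.
#' @param pk Matching `pekeris_constants`.
#' @param const Matching `qhm_constants`.
#' @param p A `molecule_params` object.
#' @param shell Which shell's equilibrium.
#' @return A list with `K` (N/m), `T_dimensionless`, `T_seconds` and the
#'   equilibrium used.
#' @export
force_constant <- function(state, pk, const, p, shell = 1L) {
  eqs <- find_equilibria(state, pk)
  z0 <- eqs$z_values[shell]
  wv <- .radial_w(state, pk, z0 + 0i, deriv = TRUE)
  # V = E + (E_D/4 lam^2) w^2; at w = 0: d2V/dr2 = (E_D/2 lam^2) (z dw/dz)^2
  curv_dimless <- Re((z0 * wv$dw)^2) * const$E_scale / (2 * const$lam^2)
  K <- p$beta^2 * curv_dimless
  T_s <- 2 * pi * sqrt(p$M / K)
  T_dimless <- T_s / const$time_scale
  list(K = K, T_dimensionless = T_dimless, T_seconds = T_s,
       z_eq = z0, r_eq = eqs$r_values[shell])
}

#' Vibration periods by three independent routes
#'
#' Compares the period of the state's radial contour obtained from
#' (1) numerical integration of the complex trajectory, (2) the residue
#' theorem and (3) the force constant, and converts to physical period and
#' frequency.
#'
#' @param p A `molecule_params` object.
#' @param state A `qhm_state` (default: ground state).
#' @param delta Real offset of the starting point from equilibrium.
#' @param shell Which shell (for excited vibrational states).
#' @return A `period_report` list with `T_trajectory`, `T_residue`,
#'   `T_force_constant` (dimensionless), `K` (N/m), `T_seconds`, `f_Hz` and
#'   the relative spread of the three routes.
#' @export
period_report <- function(p, state = qhm_state(0, 0), delta = 0.1, shell = 1L) {
  eig <- eigensystem(state, p)
  T_res <- period_residue(state, eig$pk, shell)
  fc <- force_constant(state, eig$pk, eig$const, p, shell)
  eqs <- find_equilibria(state, eig$pk)
  traj <- integrate_trajectory(eig, r0 = eqs$r_values[shell] + delta,
                               tau_max = 5.5 * T_res, n_out = 3000)
  T_traj <- period_from_trajectory(traj, r_eq = eqs$r_values[shell])
  Ts <- c(T_traj, T_res, fc$T_dimensionless)
  out <- list(T_trajectory = T_traj, T_residue = T_res,
              T_force_constant = fc$T_dimensionless, K = fc$K,
              T_seconds = T_res * eig$const$time_scale,
              f_Hz = 1 / (T_res * eig$const$time_scale),
              spread_rel = diff(range(Ts)) / mean(Ts),
              molecule = p$name)
  class(out) <- "period_report"
  out
}

#' @export
print.period_report <- function(x, ...) {
  cat(sprintf("Vibration period report for %s\n", x$molecule))
  cat(sprintf("  T (trajectory)     = %.6g\n  T (residue)        = %.6g\n  T (force constant) = %.6g\n",
              x$T_trajectory, x$T_residue, x$T_force_constant))
  cat(sprintf("  relative spread    = %.3g\n  T = %.4g s,  f = %.4g Hz,  K = %.4g N/m\n",
              x$spread_rel, x$T_seconds, x$f_Hz, x$K))
  invisible(x)
}

#' Ground-state vibration frequency with experimental comparison
#'
#' @param p A `molecule_params` object (its `f_exp`, if present, is the
#'   comparison value unless `f_exp` is supplied).
#' @param f_exp Measured vibration frequency in Hz (optional).
#' @return A one-row data frame: `molecule`, `lam`, `T_dimensionless`,
#'   `T_seconds`, `f_QHM_Hz`, `f_exp_Hz`, `rel_error`.
#' @export
frequency_report <- function(p, f_exp = NULL) {
  const <- derive_constants(p)
  Td <- 4 * pi / (2 * const$lam - 1)
  Ts <- Td * const$time_scale
  f <- 1 / Ts
  fe <- if (!is.null(f_exp)) f_exp else if (!is.null(p$f_exp)) p$f_exp else NA_real_
  data.frame(molecule = p$name, lam = const$lam, T_dimensionless = Td,
             T_seconds = Ts, f_QHM_Hz = f, f_exp_Hz = fe,
             rel_error = if (is.finite(fe)) abs(fe - f) / fe else NA_real_)
}

#' Ground-state vibration summary for the built-in molecules
#'
#' @param molecules Character vector of fixture names.
#' @return A data frame with one row per molecule (see [frequency_report()]).
#' @export
vibration_table <- function(molecules = molecule_fixtures()) {
  do.call(rbind, lapply(molecules, function(nm) frequency_report(load_molecule(nm))))
}
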