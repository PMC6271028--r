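h2 <- load_molecule("H2")
eig00 <- eigensystem(qhm_state(0, 0), h2)

test_that("canonical momenta follow the logarithmic gradient of the state", {
  # ground state: no angular momenta, radial momentum from the closed form
  m <- canonical_momenta(eig00, 1.6 + 0.1i, 0.8 + 0.4i)
  expect_equal(m$p_theta, 0 + 0i)
  expect_equal(m$p_phi, 0 + 0i)
  z <- eig00$pk$z_of_r(1.6 + 0.1i)
  expect_equal(m$p_r, -1i * ((z - eig00$pk$alpha) / 2 - 1 / (1.6 + 0.1i)), tolerance = 1e-12)
  # azimuthal momentum is the magnetic quantum number
  eig11 <- eigensystem(qhm_state(0, 1, 1), h2)
  expect_equal(canonical_momenta(eig11, 1.6, 1.2)$p_phi, 1 + 0i)
  # on the real axis Re(p) = dS_B/dq (zero for a real stationary state with
  # real polar factor) and Im(p) = -d ln R_B/dq
  mr <- canonical_momenta(eig00, 1.7 + 0i, pi / 2 + 0i)
  expect_equal(Re(mr$p_r), 0)
  expect_equal(Im(mr$p_r), -Re(eig00$radial$dlogR(1.7 + 0i)), tolerance = 1e-12)
})

test_that("quantum Hamiltonian is identically the eigenvalue on the state", {
  set.seed(7)
  r <- complex(real = runif(6, 1.2, 2.0), imaginary = runif(6, -0.4, 0.4))
  th <- complex(real = runif(6, 0.4, 2.6), imaginary = runif(6, -1, 1))
  H <- quantum_hamiltonian(eig00, r, th)
  expect_lt(max(abs(H / eig00$energy$E - 1)), 1e-8)
  # also for a rotating state (Pekeris-consistent centrifugal term)
  eig10 <- eigensystem(qhm_state(0, 1, 0), h2)
  H1 <- quantum_hamiltonian(eig10, r, th)
  expect_lt(max(abs(H1 / eig10$energy$E - 1)), 1e-8)
  # the exact 1/r^2 centrifugal term differs only by the Pekeris truncation error
  H1e <- quantum_hamiltonian(eig10, 1.45 + 0i, 1.1 + 0i, centrifugal = "exact")
  expect_lt(abs(H1e / eig10$energy$E - 1), 1e-3)
})

test_that("quantum Hamiltonian = classical Hamiltonian + divergence correction", {
  # H_Psi differs from the classical H at the same (complex) momenta exactly
  # by -(i hbar / 2M) div(p); the divergence is recomputed here by finite
  # differences of the momentum field.
  k <- physical_constants()
  for (spec in list(list(st = qhm_state(0, 0), r = 1.62 + 0.1i, th = 1.0 + 0i),
                    list(st = qhm_state(0, 1, 1), r = 1.55 + 0i, th = 1.2 - 0.4i))) {
    eig <- eigensystem(spec$st, h2)
    r <- spec$r; th <- spec$th
    mom <- canonical_momenta(eig, r, th, dimensional = TRUE)
    Hc <- classical_hamiltonian(mom$p_r, mom$p_theta, mom$p_phi, r, th, h2)
    ptil_r <- function(rr) canonical_momenta(eig, rr, th)$p_r
    ptil_th <- function(tt) canonical_momenta(eig, r, tt)$p_theta
    div_r <- num_deriv(function(rr) rr^2 * ptil_r(rr), r) / r^2
    div_th <- num_deriv(function(tt) sin(tt) * ptil_th(tt), th) / (r^2 * sin(th))
    corr <- -1i * (h2$E_D / eig$const$lam^2) * (div_r + div_th)
    Hq <- quantum_hamiltonian(eig, r, th, centrifugal = "exact")
    expect_equal(Hq, Hc + corr, tolerance = 1e-6)
  }
})

test_that("the angular kinetic terms of a J = 0 state combine to the cot^2/4 spin term", {
  # l_theta^2 + cot^2/4 must cancel identically for Theta = 1
  th <- complex(real = c(0.5, 1.3, 2.2), imaginary = c(0.8, -0.5, 2))
  v <- equations_of_motion(eig00)(1.6 + 0i, th)
  lth <- (1.6 + 0i)^2 * v$vtheta
  expect_lt(max(abs(lth^2 + cos(th)^2 / sin(th)^2 / 4)), 1e-12)
})

test_that("quantum potential bookkeeping closes the energy balance", {
  qp <- quantum_potential(eig00, 1.7 + 0.2i, pi / 2 + 0i)
  H <- quantum_hamiltonian(eig00, 1.7 + 0.2i, pi / 2 + 0i)
  expect_equal(qp$Q + qp$T_kinetic + qp$V_eff, H, tolerance = 1e-10)
  expect_equal(qp$V_total, H - qp$T_kinetic, tolerance = 1e-10)
  # closed-form radial total potential agrees with the bookkeeping at the
  # polar equilibrium theta = pi/2
  vt <- total_potential_radial(eig00$state, eig00$pk, eig00$const, 1.7 + 0.2i)
  expect_equal(vt, qp$V_total, tolerance = 1e-10)
})

test_that("ground-state total potential is the stated Morse-like combination", {
  # V_Total/E_D = exp(-2(r-b)) - (2 - 1/lam) exp(-(r-b)) for n = J = 0
  lam <- eig00$const$lam; b <- eig00$const$b
  r <- seq(1.2, 3, length.out = 7)
  vt <- Re(total_potential_radial(eig00$state, eig00$pk, eig00$const, r)) / h2$E_D
  ref <- exp(-2 * (r - b)) - (2 - 1 / lam) * exp(-(r - b))
  expect_equal(vt, ref, tolerance = 1e-10)
})

test_that("equations of motion reduce to the printed special cases", {
  rhs <- equations_of_motion(eig00)
  r <- 1.5 + 0.2i; th <- 1.1 - 0.7i
  v <- rhs(r, th)
  z <- eig00$pk$z_of_r(r)
  expect_equal(v$vr, -1i * (z - eig00$pk$alpha) / 2, tolerance = 1e-12)
  expect_equal(v$vtheta, -1i * cos(th) / sin(th) / 2 / r^2, tolerance = 1e-12)
  # radial RHS vanishes exactly at z = alpha
  r_eq <- equilibrium_bond_length(eig00$state, eig00$pk)
  expect_lt(abs(rhs(r_eq + 0i, th)$vr), 1e-12)
  # polar-axis singularity is refused
  expect_error(rhs(r, 0 + 0i), "singular polar angle")
  # real-axis Bohmian reduction: for a real stationary state dS_B/dq = 0, so
  # the real part of the complex velocity vanishes (the real Bohmian particle
  # is at rest) while the imaginary part carries -d ln R_B/dq
  vreal <- rhs(1.7 + 0i, pi / 2 + 0i)
  expect_equal(Re(vreal$vr), 0)
  expect_equal(Im(vreal$vr), -Re(eig00$radial$dlog_u(1.7 + 0i)), tolerance = 1e-12)
})

test_that("complex radial trajectories close, conserve the diagnostics and respect equilibria", {
  r_eq <- equilibrium_bond_length(eig00$state, eig00$pk)
  T0 <- period_residue(eig00$state, eig00$pk)
  tr <- integrate_trajectory(eig00, r0 = r_eq + 0.1, tau_max = T0, n_out = 1500)
  expect_identical(tr$stats$termination, "tau_max")
  # returns to the start after one period
  expect_lt(abs(tr$r[length(tr$r)] - tr$r[1]), 1e-6)
  # diagnostics quantized along the whole trajectory
  d <- tr$diagnostics
  expect_lt(max(abs(d$H / eig00$energy$E - 1)), 1e-8)
  expect_lt(max(abs(d$L2_hbar2)), 1e-10)
  expect_lt(max(abs(d$Lz_hbar)), 1e-14)
  # starting exactly at the equilibrium: fixed point
  trf <- integrate_trajectory(eig00, r0 = r_eq + 0i, tau_max = 0.5, n_out = 100)
  expect_lt(max(abs(trf$r - r_eq)), 1e-9)
})

test_that("rotating-state trajectories carry quantized angular momentum", {
  eig10 <- eigensystem(qhm_state(0, 1, 0), h2)
  tr <- integrate_trajectory(eig10, theta0 = pi / 3 + 0.8i, tau_max = 1, n_out = 800)
  expect_lt(max(abs(tr$diagnostics$L2_hbar2 - 2)), 1e-9)
  expect_lt(max(abs(tr$diagnostics$Lz_hbar)), 1e-14)
  expect_lt(max(abs(tr$diagnostics$H / eig10$energy$E - 1)), 1e-8)
  eig11 <- eigensystem(qhm_state(0, 1, 1), h2)
  tr11 <- integrate_trajectory(eig11, theta0 = pi / 2 + 1i, tau_max = 1, n_out = 800)
  expect_lt(max(abs(tr11$diagnostics$L2_hbar2 - 2)), 1e-9)
  expect_lt(max(abs(tr11$diagnostics$Lz_hbar - 1)), 1e-14)
})

test_that("the radial force is restoring, matches -dV/dr and vanishes at the equilibrium", {
  st <- eig00$state; pk <- eig00$pk; cst <- eig00$const
  r_eq <- equilibrium_bond_length(st, pk)
  expect_lt(abs(radial_force(st, pk, cst, r_eq)), 1e-12 * cst$E_scale)
  expect_lt(Re(radial_force(st, pk, cst, r_eq + 0.3)), 0)
  expect_gt(Re(radial_force(st, pk, cst, r_eq - 0.3)), 0)
  for (r in c(1.4, 1.8, 2.2)) {
    fd <- -num_deriv(function(x) total_potential_radial(st, pk, cst, x), r + 0i, h = 1e-6)
    expect_equal(Re(radial_force(st, pk, cst, r)), Re(fd), tolerance = 1e-6)
  }
  expect_equal(radial_force_si(st, pk, cst, 1.6, h2),
               radial_force(st, pk, cst, 1.6) * h2$beta)
})

test_that("trajectory periods are contour-independent and converge with tolerance", {
  r_eq <- equilibrium_bond_length(eig00$state, eig00$pk)
  T0 <- period_residue(eig00$state, eig00$pk)
  periods <- vapply(c(0.05, 0.1, 0.2), function(d) {
    tr <- integrate_trajectory(eig00, r0 = r_eq + d, tau_max = 5.5 * T0, n_out = 2500)
    period_from_trajectory(tr)
  }, numeric(1))
  expect_lt(diff(range(periods)) / mean(periods), 1e-3)
  expect_lt(abs(mean(periods) - T0) / T0, 1e-3)
  # halving the integrator tolerance leaves the measured period unchanged to 1e-6
  tr1 <- integrate_trajectory(eig00, r0 = r_eq + 0.1, tau_max = 5.5 * T0,
                              n_out = 2500, rtol = 1e-10, atol = 1e-12)
  tr2 <- integrate_trajectory(eig00, r0 = r_eq + 0.1, tau_max = 5.5 * T0,
                              n_out = 2500, rtol = 5e-11, atol = 5e-13)
  expect_lt(abs(period_from_trajectory(tr1) - period_from_trajectory(tr2)) /
              period_from_trajectory(tr1), 1e-6)
})
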