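# Independent numerical oracles used by the tests. These never call the
# code paths they are checking.

# Composite Simpson quadrature (complex-valued integrands welcome).
simpson_quad <- function(f, a, b, n = 8000) {
  if (n %% 2 == 1) n <- n + 1
  x <- seq(a, b, length.out = n + 1)
  w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
  h <- (b - a) / n
  sum(w * f(x)) * h / 3
}

# Cut-plane Legendre function of the second kind via the Neumann integral
#   Q_J(z) = 1/2 * int_{-1}^{1} P_J(t) / (z - t) dt,  z off [-1, 1].
oracle_Q <- function(J, z) {
  PJ <- function(t) {
    if (J == 0) return(rep(1, length(t)))
    pm1 <- rep(1, length(t)); p <- t
    if (J > 1) for (k in 1:(J - 1)) {
      pp <- ((2 * k + 1) * t * p - k * pm1) / (k + 1)
      pm1 <- p; p <- pp
    }
    p
  }
  gl <- pracma::gaussLegendre(240, -1, 1)
  sum(gl$w * PJ(gl$x) / (z - gl$x)) / 2
}

# Central finite differences for analytic functions of one complex variable
# (real step direction; valid by analyticity).
num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)
num_deriv2_o4 <- function(f, x, h = 1e-3) {
  (-f(x + 2 * h) + 16 * f(x + h) - 30 * f(x) + 16 * f(x - h) - f(x - 2 * h)) / (12 * h^2)
}

# Brute-force ground eigenvalue of the Pekeris-reduced radial equation by
# second-order finite differences on a uniform r_tilde grid:
#   -(E_D/lam^2) u'' + E_D (C2r y^2 - C1r y + C0r) u = E u,  y = e^{-(r-b)}.
oracle_pekeris_ground_energy <- function(lam, b, C0r, C1r, C2r, N = 1500,
                                         r_lo = NULL, r_hi = NULL) {
  if (is.null(r_lo)) r_lo <- b - 1.2
  if (is.null(r_hi)) r_hi <- b + 3.5
  r <- seq(r_lo, r_hi, length.out = N)
  h <- r[2] - r[1]
  y <- exp(-(r - b))
  V <- C2r * y^2 - C1r * y + C0r
  main <- 2 / (lam^2 * h^2) + V
  off <- rep(-1 / (lam^2 * h^2), N - 1)
  # smallest eigenvalues of the symmetric tridiagonal operator
  M <- diag(main)
  M[cbind(1:(N - 1), 2:N)] <- off
  M[cbind(2:N, 1:(N - 1))] <- off
  min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
}

# Count sign changes of a real function sampled on a grid (node counting).
count_nodes <- function(f, lo, hi, n = 4000) {
  x <- seq(lo, hi, length.out = n)
  v <- f(x)
  sum(diff(sign(v)) != 0)
}

# Numerical contour integral of f around a circle centre z0, radius rho.
contour_integral <- function(f, z0, rho, n = 4096) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  z <- z0 + rho * exp(1i * th)
  dz <- 1i * rho * exp(1i * th)
  sum(f(z) * dz) * (2 * pi / n)
}
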