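#' Rovibrational quantum state of a diatomic molecule
#'
#' Specifies the vibrational quantum number `n`, rotational quantum number
#' `J`, magnetic quantum number `mJ` and the angular solution branch: the
#' polar factor solves the associated Legendre equation, whose general
#' solution is `B1*P_J^mJ + B2*Q_J^mJ` with first- (`P`) and second-kind
#' (`Q`) Legendre functions.
#'
#' @param n Vibrational quantum number (integer >= 0).
#' @param J Rotational quantum number (integer >= 0).
#' @param mJ Magnetic quantum number, `|mJ| <= J`.
#' @param branch `"first_kind"`, `"second_kind"` or `"mixed"`.
#' @param B1,B2 Complex coefficients of the P and Q parts (used for
#'   `branch = "mixed"`; must not both vanish).
#' @return A `qhm_state` object.
#' @export
qhm_state <- function(n, J, mJ = 0, branch = c("first_kind", "second_kind", "mixed"),
                      B1 = NULL, B2 = NULL) {
  branch <- match.arg(branch)
  if (n < 0 || n != round(n)) stop("qhm_state: n must be a non-negative integer", call. = FALSE)
  if (J < 0 || J != round(J)) stop("qhm_state: J must be a non-negative integer", call. = FALSE)
  if (abs(mJ) > J || mJ != round(mJ)) stop("qhm_state: need integer |mJ| <= J", call. = FALSE)
  coef <- switch(branch,
    first_kind  = c(1 + 0i, 0 + 0i),
    second_kind = c(0 + 0i, 1 + 0i),
    mixed = {
      if (is.null(B1) || is.null(B2)) stop("qhm_state: mixed branch needs B1 and B2", call. = FALSE)
      c(as.complex(B1), as.complex(B2))
    })
  if (all(coef == 0)) stop("qhm_state: (B1, B2) must not both be zero", call. = FALSE)
  structure(list(n = as.integer(n), J = as.integer(J), mJ = as.integer(mJ),
                 branch = branch, B1 = coef[1], B2 = coef[2]),
            class = "qhm_state")
}

#' @export
print.qhm_state <- function(x, ...) {
  cat(sprintf("Quantum state (n = %d, J = %d, mJ = %d), angular branch: %s\n",
              x$n, x$J, x$mJ, x$branch))
  if (x$branch == "mixed")
    cat(sprintf("  B1 = %s, B2 = %s\n", format(x$B1), format(x$B2)))
  invisible(x)
}

#' Pekeris constants of the rotating Morse oscillator
#'
#' The centrifugal term `J(J+1)/r^2` is replaced by its second-order
#' expansion in `y = exp(-(r_tilde - b))`, which keeps the radial equation
#' analytically solvable. With `t = 1/b` the expansion coefficients are
#' `c0 = 1 - 3t + 3t^2`, `c1 = 4t - 6t^2`, `c2 = 3t^2 - t`, and with
#' `a = J(J+1)/(lam^2 b^2)` the effective well gives
#' `eta = lam*sqrt(1 + a*c2)` and
#' `alpha = lam*(2 - a*c1)/sqrt(1 + a*c2) - 2n - 1`.
#' For `J = 0` these reduce exactly to `alpha = 2*lam - 2n - 1`, `eta = lam`.
#'
#' @param state A `qhm_state`.
#' @param const A `qhm_constants` object from [derive_constants()].
#' @return A `pekeris_constants` list with `alpha`, `eta`, the expansion
#'   coefficients, and a `z_of_r` map `z = 2*eta*exp(-(r_tilde - b))`.
#' @export
pekeris_constants <- function(state, const) {
  lam <- const$lam; b <- const$b
  t <- 1 / b
  c0 <- 1 - 3 * t + 3 * t^2
  c1 <- 4 * t - 6 * t^2
  c2 <- 3 * t^2 - t
  a <- state$J * (state$J + 1) / (lam^2 * b^2)
  C2r <- 1 + a * c2
  if (C2r <= 0) stop("pekeris_constants: state outside the bound regime (C2 <= 0)", call. = FALSE)
  eta <- lam * sqrt(C2r)
  alpha <- lam * (2 - a * c1) / sqrt(C2r) - 2 * state$n - 1
  if (alpha <= 0)
    stop(sprintf("pekeris_constants: state (n=%d, J=%d) is not bound (alpha = %.3g <= 0)",
                 state$n, state$J, alpha), call. = FALSE)
  out <- list(alpha = alpha, eta = eta, a = a, c0 = c0, c1 = c1, c2 = c2,
              C0r = a * c0, C1r = 2 - a * c1, C2r = C2r,
              lam = lam, b = b, n = state$n, J = state$J,
              z_of_r = function(r_tilde) 2 * eta * exp(-(r_tilde - b)))
  class(out) <- "pekeris_constants"
  out
}

#' Morse potential
#'
#' `V(r_tilde) = E_D * (exp(-2(r_tilde - b)) - 2 exp(-(r_tilde - b)))`:
#' minimum `-E_D` at `r_tilde = b` and dissociation limit 0. Accepts complex
#' `r_tilde`.
#'
#' @param r_tilde Dimensionless radial distance (real or complex).
#' @param p A `molecule_params` object.
#' @return Potential energy in joules.
#' @export
morse_potential <- function(r_tilde, p) {
  b <- p$beta * p$r0
  y <- exp(-(r_tilde - b))
  p$E_D * (y^2 - 2 * y)
}

# Generalized Laguerre polynomial L_n^alpha(z) and derivatives, for complex z.
# Coefficient of z^k: (-1)^k / (k! (n-k)!) * prod_{j=k+1..n} (alpha + j).
laguerre_eval <- function(n, alpha, z, deriv = 0L) {
  if (n == 0L) return(if (deriv == 0L) rep(1 + 0i, length(z)) else rep(0 + 0i, length(z)))
  k <- 0:n
  tail_prod <- rev(cumprod(c(1, rev(alpha + seq_len(n)))))[k + 1L]  # prod_{j=k+1}^{n}(alpha+j)
  coef <- (-1)^k / (factorial(k) * factorial(n - k)) * tail_prod
  for (d in seq_len(deriv)) {
    coef <- coef[-1] * seq_len(length(coef) - 1L)
    if (!length(coef)) return(rep(0 + 0i, length(z)))
  }
  out <- 0 + 0i
  for (i in rev(seq_along(coef))) out <- out * z + coef[i]
  out
}

#' Radial Morse eigenfunction and its logarithmic derivatives
#'
#' `R_{n,J}(r_tilde) = r_tilde^-1 exp(-z/2) z^(alpha/2) L_n^alpha(z)` with
#' `z = 2*eta*exp(-(r_tilde - b))`. All radial quantities are evaluated
#' through `z` (an entire function of `r_tilde`), so logarithmic derivatives
#' are branch-free rational functions of `z`.
#'
#' @param state A `qhm_state`.
#' @param pk A `pekeris_constants` object for the same state.
#' @return A list of vectorised functions of (possibly complex) `r_tilde`:
#'   `R` (the radial wavefunction, principal branch of `z^(alpha/2)`),
#'   `dlog_u` (`d ln(r_tilde * R)/d r_tilde = (z - alpha)/2 - z L'/L`),
#'   `dlogR`, `d2logR`, `upp_over_u` (`u''/u` with `u = r_tilde*R`), and
#'   `z_of_r`.
#' @export
radial_wavefunction <- function(state, pk) {
  n <- state$n; alpha <- pk$alpha
  zf <- pk$z_of_r
  lag <- function(z, d = 0L) laguerre_eval(n, alpha, z, d)
  dlog_u <- function(r_tilde) {
    z <- zf(r_tilde)
    L <- lag(z); Lp <- lag(z, 1L)
    .check_node(L, "r", ref = z * Lp)
    (z - alpha) / 2 - z * Lp / L
  }
  d2log_u <- function(r_tilde) {
    z <- zf(r_tilde)
    L <- lag(z); Lp <- lag(z, 1L); Lpp <- lag(z, 2L)
    .check_node(L, "r", ref = z * Lp)
    g <- Lp / L
    -z / 2 + z * g + z^2 * (Lpp / L - g^2)
  }
  list(
    R = function(r_tilde) {
      z <- zf(r_tilde)
      exp(-z / 2 + (alpha / 2) * log(z)) * lag(z) / r_tilde
    },
    dlog_u = dlog_u,
    d2log_u = d2log_u,
    dlogR = function(r_tilde) dlog_u(r_tilde) - 1 / r_tilde,
    d2logR = function(r_tilde) d2log_u(r_tilde) + 1 / r_tilde^2,
    upp_over_u = function(r_tilde) d2log_u(r_tilde) + dlog_u(r_tilde)^2,
    z_of_r = zf
  )
}

# Node guard: errors on non-finite values, or when |val| is negligible
# relative to the local derivative scale `ref` (log-derivative pole).
.check_node <- function(val, coord, ref = NULL) {
  bad <- !is.finite(Re(val)) | !is.finite(Im(val))
  if (!is.null(ref)) bad <- bad | abs(val) < 1e-10 * pmax(1, abs(ref))
  if (any(bad))
    stop(sprintf("evaluation at a node/singularity of the wavefunction (coordinate %s)", coord),
         call. = FALSE)
  invisible(val)
}

# --- Legendre functions at complex argument -------------------------------

# m = 0 Legendre functions of degree J, both kinds, with derivative in x.
# Q uses the cut-plane second kind, Q_0(x) = (log(x+1) - log(x-1))/2, which
# decays as x^(-J-1) for large |x| (the branch relevant to complex angular
# trajectories; it differs from the Ferrers form by -i*pi/2 * P_J on the real
# interval).
legendre_deg <- function(J, x, kind = c("P", "Q")) {
  kind <- match.arg(kind)
  if (kind == "P") { w0 <- rep(1 + 0i, length(x)); w1 <- x + 0i }
  else { w0 <- (log(x + 1) - log(x - 1)) / 2; w1 <- x * w0 - 1 }
  if (J == 0L) w <- list(w0, w1)[[1]] else if (J == 1L) w <- w1 else {
    wm1 <- w0; w <- w1
    for (k in 1L:(J - 1L)) {
      wp <- ((2 * k + 1) * x * w - k * wm1) / (k + 1)
      wm1 <- w; w <- wp
    }
  }
  wprev <- if (J == 0L) NULL else if (J == 1L) w0 else wm1
  # (1 - x^2) w' = J*(w_{J-1} - x*w_J);  J = 0: P' = 0, Q' = 1/(1-x^2)
  wx <- if (J == 0L) {
    if (kind == "P") rep(0 + 0i, length(x)) else 1 / (1 - x^2)
  } else J * (wprev - x * w) / (1 - x^2)
  list(w = w, wx = wx)
}

# Associated Legendre function w_J^m(cos(theta)) of either kind, with its
# theta-derivative, by the m-ascending recurrence
#   w^{m+1} = -2m (x/s) w^m - (J+m)(J-m+1) w^{m-1},  seeded by w^1 = -s w_J'.
assoc_legendre_theta <- function(J, m, theta, kind = c("P", "Q")) {
  kind <- match.arg(kind)
  stopifnot(m >= 0)
  x <- cos(theta); s <- sin(theta)
  base <- legendre_deg(J, x, kind)
  wm <- vector("list", m + 2L)
  wm[[1L]] <- base$w
  wm[[2L]] <- -s * base$wx
  if (m >= 1L) for (k in 1L:m)
    wm[[k + 2L]] <- -2 * k * (x / s) * wm[[k + 1L]] - (J + k) * (J - k + 1) * wm[[k]]
  val <- wm[[m + 1L]]
  dval <- if (m == 0L) wm[[2L]]
          else -0.5 * ((J + m) * (J - m + 1) * wm[[m]] - wm[[m + 2L]])
  list(value = val, dtheta = dval)
}

#' Polar (angular) wavefunction at complex argument
#'
#' `Theta(theta) = B1 * P_J^mJ(cos theta) + B2 * Q_J^mJ(cos theta)`,
#' evaluable for complex `theta`, with the second kind taken on the cut plane
#' (decaying for large `|cos theta|`). The second logarithmic derivative is
#' obtained from the associated Legendre differential equation, so it is
#' valid for any solution branch.
#'
#' @param state A `qhm_state`.
#' @return A list of vectorised functions of complex `theta`: `Theta`,
#'   `dTheta`, `g` (`= d ln(Theta)/d theta`) and `d2log`
#'   (`= d^2 ln(Theta)/d theta^2`), plus the quantum numbers.
#' @export
angular_wavefunction <- function(state) {
  J <- state$J; m <- abs(state$mJ)
  B1 <- state$B1; B2 <- state$B2
  eval_theta <- function(theta) {
    v <- 0 + 0i; d <- 0 + 0i
    if (B1 != 0) { pp <- assoc_legendre_theta(J, m, theta, "P"); v <- v + B1 * pp$value; d <- d + B1 * pp$dtheta }
    if (B2 != 0) { qq <- assoc_legendre_theta(J, m, theta, "Q"); v <- v + B2 * qq$value; d <- d + B2 * qq$dtheta }
    list(value = v, dtheta = d)
  }
  g <- function(theta) {
    e <- eval_theta(theta)
    .check_node(e$value, "theta", ref = e$dtheta)
    e$dtheta / e$value
  }
  list(
    Theta = function(theta) eval_theta(theta)$value,
    dTheta = function(theta) eval_theta(theta)$dtheta,
    g = g,
    d2log = function(theta) {
      gg <- g(theta)
      -cos(theta) / sin(theta) * gg - J * (J + 1) + m^2 / sin(theta)^2 - gg^2
    },
    J = J, m = m
  )
}

#' Rovibrational eigenvalue and its rotational decomposition
#'
#' `E_{n,J} = E_D * (a*c0 - alpha^2/(4*lam^2))` from the Pekeris-reduced
#' radial problem. The rotational-energy expansion splits `E_{n,J}` into the
#' `J = 0` vibrational ladder, the rigid-rotor term `h*c*B_bar*J(J+1)` and
#' the centrifugal correction `-h*c*D_bar*[J(J+1)]^2`.
#'
#' @param state A `qhm_state`.
#' @param const A `qhm_constants` object.
#' @return A list with `E` (J), `E_vib` (the same state at `J = 0`),
#'   `E_rot_rigid`, `E_rot_centrifugal`, `E_R_expansion`
#'   (= rigid + centrifugal) and `E_R_exact` (= `E - E_vib`), all in joules.
#' @export
eigenenergy <- function(state, const) {
  k <- physical_constants()
  pk <- pekeris_constants(state, const)
  E <- const$E_scale * (pk$C0r - pk$alpha^2 / (4 * const$lam^2))
  st0 <- qhm_state(state$n, 0L, 0L)
  pk0 <- pekeris_constants(st0, const)
  E_vib <- const$E_scale * (-pk0$alpha^2 / (4 * const$lam^2))
  jj <- state$J * (state$J + 1)
  E_rigid <- k$h * k$c_cm * const$B_bar * jj
  E_cent <- -k$h * k$c_cm * const$D_bar * jj^2
  list(E = E, E_vib = E_vib,
       E_rot_rigid = E_rigid, E_rot_centrifugal = E_cent,
       E_R_expansion = E_rigid + E_cent, E_R_exact = E - E_vib)
}

#' Bundle the full eigenfunction of a state
#'
#' Collects molecule parameters, derived constants, Pekeris constants, the
#' radial and angular factors and the eigenvalue of one rovibrational state.
#' The azimuthal factor is `Phi(phi) = exp(1i*mJ*phi)`.
#'
#' @param state A `qhm_state`.
#' @param p A `molecule_params` object.
#' @return A `qhm_eigensystem` list used by all dynamics functions.
#' @export
eigensystem <- function(state, p) {
  const <- derive_constants(p)
  pk <- pekeris_constants(state, const)
  out <- list(state = state, molecule = p, const = const, pk = pk,
              radial = radial_wavefunction(state, pk),
              angular = angular_wavefunction(state),
              energy = eigenenergy(state, const))
  class(out) <- "qhm_eigensystem"
  out
}

#' @export
print.qhm_eigensystem <- function(x, ...) {
  cat(sprintf("Eigensystem: %s, (n = %d, J = %d, mJ = %d), %s branch\n",
              x$molecule$name, x$state$n, x$state$J, x$state$mJ, x$state$branch))
  cat(sprintf("  alpha = %.6g, eta = %.6g, E = %.6g J (%.4f E_D)\n",
              x$pk$alpha, x$pk$eta, x$energy$E, x$energy$E / x$const$E_scale))
  invisible(x)
}

#' Logarithmic gradient of the eigenfunction at a phase point
#'
#' Returns `d ln(Psi)/d r_tilde`, `d ln(Psi)/d theta` and `d ln(Psi)/d phi`
#' at a (complex) coordinate triple. Errors at nodes of the wavefunction,
#' naming the offending coordinate.
#'
#' @param eig A `qhm_eigensystem`.
#' @param r_tilde,theta,phi Complex coordinates.
#' @return A list with components `dr`, `dtheta`, `dphi`.
#' @export
log_derivatives <- function(eig, r_tilde, theta, phi = 0 + 0i) {
  list(dr = eig$radial$dlogR(r_tilde),
       dtheta = if (eig$state$J == 0L && eig$state$branch == "first_kind") {
         rep(0 + 0i, length(theta))
       } else eig$angular$g(theta),
       dphi = rep(1i * eig$state$mJ, length(phi)))
}
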