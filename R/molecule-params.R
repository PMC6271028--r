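#' Physical constants (CODATA 2018)
#'
#' Fixed values of the reduced Planck constant, the Planck constant and the
#' speed of light (in cm/s, the natural unit for wavenumber spectroscopy).
#'
#' @return A list with elements `hbar` (J s), `h` (J s) and `c_cm` (cm/s).
#' @export
physical_constants <- function() {
  list(
    hbar = 1.054571817e-34,
    h    = 6.62607015e-34,
    c_cm = 2.99792458e10
  )
}

# Built-in parameter sets for the four reference diatomics.
# r0: equilibrium bond length (m); M: reduced mass (kg); beta: Morse width
# (1/m); E_D: dissociation energy (J); f_exp: measured ground-state vibration
# frequency (Hz), used only for comparison columns.
.molecule_fixtures <- list(
  H2  = list(name = "H2",  r0 = 74e-12,    M = 0.837e-27, beta = 1.94e10, E_D = 7.11e-19,  f_exp = 12470e10),
  HCl = list(name = "HCl", r0 = 127.5e-12, M = 1.628e-27, beta = 1.81e10, E_D = 7.39e-19,  f_exp = 8652e10),
  O2  = list(name = "O2",  r0 = 148e-12,   M = 13.28e-27, beta = 2.67e10, E_D = 8.28e-19,  f_exp = 4666e10),
  N2  = list(name = "N2",  r0 = 145e-12,   M = 11.63e-27, beta = 2.70e10, E_D = 15.77e-19, f_exp = 6987e10)
)

#' Names of the built-in molecule fixtures
#' @return Character vector of fixture names.
#' @export
molecule_fixtures <- function() names(.molecule_fixtures)

new_molecule_params <- function(name, r0, M, beta, E_D, f_exp = NA_real_) {
  p <- list(name = name, r0 = r0, M = M, beta = beta, E_D = E_D, f_exp = f_exp)
  class(p) <- "molecule_params"
  validate_molecule_params(p)
}

validate_molecule_params <- function(p) {
  if (!is.character(p$name) || length(p$name) != 1L || !nzchar(p$name))
    stop("molecule_params: 'name' must be a nonempty string", call. = FALSE)
  for (f in c("r0", "M", "beta", "E_D")) {
    v <- p[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("molecule_params: field '%s' is missing or non-numeric", f), call. = FALSE)
    if (v <= 0)
      stop(sprintf("molecule_params: field '%s' must be strictly positive (got %g)", f, v), call. = FALSE)
  }
  p
}

#' Load molecule parameters from a fixture name or a config file
#'
#' A source is either one of the built-in names (`"H2"`, `"HCl"`, `"O2"`,
#' `"N2"`) or the path of a flat YAML file with keys `name`, `r0_m`,
#' `reduced_mass_kg`, `beta_per_m`, `E_D_J` (all SI).
#'
#' @param source Fixture name or path to a config file.
#' @return A validated `molecule_params` object with fields `name`, `r0` (m),
#'   `M` (kg), `beta` (1/m), `E_D` (J).
#' @examples
#' load_molecule("HCl")
#' @export
load_molecule <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  if (source %in% names(.molecule_fixtures)) {
    fx <- .molecule_fixtures[[source]]
    return(new_molecule_params(fx$name, fx$r0, fx$M, fx$beta, fx$E_D, fx$f_exp))
  }
  if (!file.exists(source))
    stop(sprintf("unknown molecule fixture or missing config file: '%s'", source), call. = FALSE)
  cfg <- yaml::read_yaml(source)
  need <- c("name", "r0_m", "reduced_mass_kg", "beta_per_m", "E_D_J")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop(sprintf("molecule config is missing key(s): %s", paste(missing, collapse = ", ")), call. = FALSE)
  new_molecule_params(as.character(cfg$name), as.numeric(cfg$r0_m),
                      as.numeric(cfg$reduced_mass_kg), as.numeric(cfg$beta_per_m),
                      as.numeric(cfg$E_D_J),
                      if (!is.null(cfg$f_exp_hz)) as.numeric(cfg$f_exp_hz) else NA_real_)
}

#' @export
print.molecule_params <- function(x, ...) {
  cat(sprintf("Diatomic molecule '%s'\n", x$name))
  cat(sprintf("  r0   = %.4g m\n  M    = %.4g kg\n  beta = %.4g 1/m\n  E_D  = %.4g J\n",
              x$r0, x$M, x$beta, x$E_D))
  invisible(x)
}

#' Derived dimensionless groups and spectroscopic constants
#'
#' Computes the dimensionless Morse depth `lam = sqrt(2*M*E_D)/(hbar*beta)`,
#' the dimensionless equilibrium position `b = beta*r0`, the time scale
#' `M/(hbar*beta^2)` converting dimensionless time to seconds, the rotational
#' constant `B_bar = hbar^2/(4*h*c*I0)` with `I0 = M*r0^2/2`, and the
#' centrifugal distortion constant `D_bar = (hbar^2/(4*b*I0))^2 / (h*c*E_D)`
#' (both in cm^-1).
#'
#' @param p A `molecule_params` object.
#' @return A `qhm_constants` list with `lam`, `b`, `time_scale`, `B_bar`,
#'   `D_bar`, `I0` and `E_scale` (= E_D, the internal energy unit in J).
#' @examples
#' derive_constants(load_molecule("HCl"))$B_bar  # ~ 10.58 cm^-1
#' @export
derive_constants <- function(p) {
  p <- validate_molecule_params(p)
  k <- physical_constants()
  lam <- sqrt(2 * p$M * p$E_D) / (k$hbar * p$beta)
  if (lam <= 0.5)
    stop("derive_constants: lam <= 1/2, the well supports no bound state", call. = FALSE)
  b <- p$beta * p$r0
  I0 <- p$M * p$r0^2 / 2
  B_bar <- k$hbar^2 / (4 * k$h * k$c_cm * I0)
  D_bar <- (k$hbar^2 / (4 * b * I0))^2 / (k$h * k$c_cm * p$E_D)
  out <- list(
    lam = lam, b = b,
    time_scale = p$M / (k$hbar * p$beta^2),
    B_bar = B_bar, D_bar = D_bar, I0 = I0,
    E_scale = p$E_D, molecule = p$name
  )
  class(out) <- "qhm_constants"
  out
}

#' @export
print.qhm_constants <- function(x, ...) {
  cat(sprintf("Derived constants for %s\n", x$molecule))
  cat(sprintf("  lam        = %.6g\n  b          = %.6g\n", x$lam, x$b))
  cat(sprintf("  time scale = %.4g s\n  B_bar      = %.4g cm^-1\n  D_bar      = %.4g cm^-1\n",
              x$time_scale, x$B_bar, x$D_bar))
  invisible(x)
}

#' Convert physical to dimensionless coordinates and back
#'
#' Internal dynamics use the dimensionless radial distance `r_tilde = beta*r`
#' and dimensionless time `tau = t*hbar*beta^2/M`. Both conversions accept
#' complex radial values.
#'
#' @param p A `molecule_params` object.
#' @param r_m Radial distance(s) in meters (may be complex).
#' @param t_s Time(s) in seconds.
#' @return `to_dimensionless` returns a list with `r_tilde` and `tau`;
#'   the inverse functions return meters / seconds.
#' @export
to_dimensionless <- function(p, r_m = NULL, t_s = NULL) {
  k <- physical_constants()
  list(
    r_tilde = if (is.null(r_m)) NULL else p$beta * r_m,
    tau     = if (is.null(t_s)) NULL else t_s * k$hbar * p$beta^2 / p$M
  )
}

#' @rdname to_dimensionless
#' @param r_tilde Dimensionless radial distance(s) (may be complex).
#' @param tau Dimensionless time(s).
#' @export
from_dimensionless <- function(p, r_tilde = NULL, tau = NULL) {
  k <- physical_constants()
  list(
    r_m = if (is.null(r_tilde)) NULL else r_tilde / p$beta,
    t_s = if (is.null(tau)) NULL else tau * p$M / (k$hbar * p$beta^2)
  )
}
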