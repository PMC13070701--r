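#' Augmented Bloch-McConnell generator
#'
#' Builds the 7x7 evolution matrix for two-state exchange under constant
#' B1 irradiation along +x. State layout is
#' `[1, Mx_A, My_A, Mz_A, Mx_B, My_B, Mz_B]`; the first row is identically
#' zero so the leading element stays 1, and its column carries the
#' `R1_S * p_S` recovery drive that relaxes Mz toward the equilibrium
#' populations.
#'
#' @param model an [exchange_model()].
#' @param omega_A,omega_B resonance offsets of states A and B (rad/s).
#' @param omega1 RF field strength (rad/s).
#' @return 7x7 numeric matrix (units 1/s).
#' @export
bm_generator <- function(model, omega_A, omega_B, omega1) {
  stopifnot(is.finite(omega_A), is.finite(omega_B), is.finite(omega1))
  bm_generator_cpp(model$R1_A, model$R2_A, model$R1_B, model$R2_B,
                   model$k_AB, model$k_BA, 1 - model$p_B, model$p_B,
                   omega_A, omega_B, omega1)
}

#' Propagate magnetization under a fixed generator
#'
#' Computes `expm(G * T) %*% M0` by matrix exponentiation.
#'
#' @param G generator matrix from [bm_generator()].
#' @param M0 initial state vector with `M0[1] == 1`.
#' @param T evolution time (s), non-negative.
#' @return the propagated state vector.
#' @export
propagate_bm <- function(G, M0, T) {
  if (T < 0) stop("evolution time T must be >= 0")
  if (abs(M0[1] - 1) > 1e-12) stop("M0[1] must equal 1 (augmented element)")
  drop(propagate_cpp(G, M0, T))
}

kernel_omegas <- function(model, acq, nu1, offsets_ppm) {
  if (any(!is.finite(offsets_ppm))) stop("offsets must be finite")
  angular_frequencies(model, acq, offsets_ppm, nu1)
}

#' Z-spectrum by full Bloch-McConnell propagation
#'
#' For each saturation offset the magnetization starts at thermal
#' equilibrium `[1, 0, 0, p_A, 0, 0, p_B]`, evolves for `acq$T_sat` under
#' the 7x7 generator, and the normalized ground-state intensity
#' `Mz_A(T_sat)/p_A` is returned (the reference experiment is `T_sat = 0`,
#' which gives exactly `p_A`).
#'
#' @inheritParams bm_generator
#' @param acq an [acquisition()] object; `b1_frac_sigma > 0` enables the
#'   Gaussian B1-inhomogeneity average.
#' @param nu1 RF field strength of this profile (Hz).
#' @param offsets_ppm saturation-carrier positions (ppm).
#' @param component `"A"` (default) for the visible ground state or `"B"`
#'   for `Mz_B(T_sat)/p_B`.
#' @return numeric vector of predicted normalized intensities.
#' @export
zspec_matrix <- function(model, acq, nu1, offsets_ppm, component = "A") {
  component <- match.arg(component, c("A", "B"))
  fn <- function(v1) {
    om <- kernel_omegas(model, acq, v1, offsets_ppm)
    out <- zspec_matrix_cpp(model$R1_A, model$R2_A, model$R1_B, model$R2_B,
                            model$k_AB, model$k_BA, 1 - model$p_B, model$p_B,
                            om$omega_A, om$omega_B, om$omega1, acq$T_sat)
    out[, if (component == "A") 1 else 2]
  }
  with_b1_average(fn, acq, nu1)
}

#' Z-spectrum by the analytical spectral kernel
#'
#' Closed-form solution of the same two-site problem: per offset the
#' homogeneous 6x6 exchange generator is diagonalized once and
#' `M(T_sat) = Mss + Re(V exp(Lambda*T_sat) V^-1 (M0 - Mss))` is evaluated,
#' with the exact steady state `Mss = -L^-1 b`. This route is roughly an
#' order of magnitude faster than [zspec_matrix()] and is the engine behind
#' the `"baldwin"` fitting method; the two kernels agree to numerical
#' precision, which the matrix route cross-validates.
#'
#' @inheritParams zspec_matrix
#' @export
zspec_baldwin <- function(model, acq, nu1, offsets_ppm) {
  fn <- function(v1) {
    om <- kernel_omegas(model, acq, v1, offsets_ppm)
    drop(zspec_analytic_cpp(model$R1_A, model$R2_A, model$R1_B, model$R2_B,
                            model$k_AB, model$k_BA, 1 - model$p_B, model$p_B,
                            om$omega_A, om$omega_B, om$omega1,
                            acq$T_sat)$intensity)
  }
  with_b1_average(fn, acq, nu1)
}

#' Effective rotating-frame relaxation rate R1rho
#'
#' Returns the exact R1rho of the two-site problem: minus the real part of
#' the slowest-decaying eigenmode of the homogeneous 6x6 exchange
#' generator, selected by overlap of the eigenvector with the
#' population-weighted tilted effective-field direction. In the
#' no-exchange limit this reduces to the textbook
#' `R1*cos^2(theta) + R2*sin^2(theta)` with `tan(theta) = omega1/Omega`;
#' far off resonance it tends to `R1`.
#'
#' @inheritParams bm_generator
#' @param omega_A,omega_B resonance offsets (rad/s); vectorized.
#' @param omega1 RF field strength (rad/s), must be > 0.
#' @return numeric vector of R1rho values (1/s). Non-finite values signal a
#'   pathological parameter set and are returned as `NaN`, not clipped.
#' @export
r1rho_baldwin <- function(model, omega_A, omega_B, omega1) {
  if (omega1 <= 0) stop("omega1 must be > 0")
  out <- drop(zspec_analytic_cpp(model$R1_A, model$R2_A, model$R1_B,
                                 model$R2_B, model$k_AB, model$k_BA,
                                 1 - model$p_B, model$p_B,
                                 omega_A, omega_B, omega1, 0)$r1rho)
  if (any(!is.finite(out)))
    warning("non-finite R1rho: pathological parameter set")
  out
}

#' Exchange-free Z-spectrum (NoEx control)
#'
#' Exact single-spin Bloch evolution (augmented 4x4 with R1 recovery): the
#' negative-control kernel used to judge whether a profile carries exchange
#' at all.
#'
#' @param R1,R2 longitudinal and transverse relaxation rates (1/s).
#' @param delta_A resonance position (ppm).
#' @inheritParams zspec_matrix
#' @export
zspec_noex <- function(R1, R2, delta_A, acq, nu1, offsets_ppm) {
  check_num(R1, "R1", lower = 0)
  check_num(R2, "R2", lower = 0)
  fn <- function(v1) {
    if (any(!is.finite(offsets_ppm))) stop("offsets must be finite")
    omega <- 2 * pi * (delta_A - offsets_ppm) * acq$larmor_MHz
    drop(zspec_noex_cpp(R1, R2, omega, 2 * pi * v1, acq$T_sat))
  }
  with_b1_average(fn, acq, nu1)
}

#' Gaussian B1-inhomogeneity average
#'
#' Models spatial RF inhomogeneity as a Gaussian distribution of nu1 across
#' the sample volume: the profile is evaluated on a symmetric grid of
#' `n_points` field values spanning `nominal * (1 +/- 2*frac_sigma)` and the
#' intensities are averaged with Gaussian weights renormalized to sum to 1
#' (truncation correction).
#'
#' @param profile_fn function of a single nu1 (Hz) returning an intensity
#'   vector.
#' @param nominal_nu1 nominal RF field strength (Hz).
#' @param frac_sigma fractional standard deviation, in `[0, 0.5]`.
#' @param n_points odd number of quadrature points, >= 1.
#' @return weighted-mean intensity vector.
#' @export
apply_b1_inhomogeneity <- function(profile_fn, nominal_nu1, frac_sigma,
                                   n_points = 11) {
  check_num(frac_sigma, "frac_sigma", lower = 0, upper = 0.5)
  if (n_points < 1 || n_points %% 2 != 1)
    stop("n_points must be an odd integer >= 1")
  if (frac_sigma == 0 || n_points == 1) return(profile_fn(nominal_nu1))
  z <- seq(-2, 2, length.out = n_points)
  w <- dnorm(z)
  w <- w / sum(w)
  nu <- nominal_nu1 * (1 + frac_sigma * z)
  acc <- 0
  for (i in seq_along(nu)) acc <- acc + w[i] * profile_fn(nu[i])
  acc
}

with_b1_average <- function(fn, acq, nu1) {
  if (acq$b1_frac_sigma > 0 && acq$b1_grid_points > 1)
    apply_b1_inhomogeneity(fn, nu1, acq$b1_frac_sigma, acq$b1_grid_points)
  else fn(nu1)
}
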