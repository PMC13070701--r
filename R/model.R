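#' Two-state exchange model
#'
#' Bundles all spin-system and kinetic parameters of one residue undergoing
#' two-state chemical exchange A (ground, visible) <-> B (excited, invisible).
#' The internal parameterization is `(k_ex, p_B)`; the one-way rates
#' `k_AB = p_B * k_ex` and `k_BA = (1 - p_B) * k_ex` are stored as derived
#' quantities so that detailed balance `p_A * k_AB == p_B * k_BA` holds by
#' construction. Alternatively the pair `(k_AB, k_BA)` may be supplied and
#' `(k_ex, p_B)` are derived.
#'
#' Sign convention: `delta_delta` is `delta_B - delta_A` (signed, ppm), so a
#' negative value places the minor-state dip upfield of the ground-state
#' resonance.
#'
#' @param k_ex total exchange rate `k_AB + k_BA` (1/s).
#' @param p_B minor-state fractional population, in (0, 1).
#' @param delta_A ground-state chemical shift (ppm).
#' @param delta_delta chemical-shift difference `delta_B - delta_A` (ppm).
#' @param R1_A,R1_B longitudinal relaxation rates (1/s). `R1_B` defaults to
#'   `R1_A` (it is essentially unconstrained by CEST data).
#' @param R2_A,R2_B transverse relaxation rates (1/s). `R2_B` defaults to
#'   `R2_A`.
#' @param k_AB,k_BA optional one-way rates (1/s); supply both instead of
#'   `k_ex`/`p_B`.
#' @return An object of class `exchange_model`.
#' @examples
#' m <- exchange_model(k_ex = 300, p_B = 0.05, delta_A = 118, delta_delta = -5)
#' m$k_AB  # 15
#' @export
exchange_model <- function(k_ex = NULL, p_B = NULL, delta_A, delta_delta,
                           R1_A = 1.5, R2_A = 10, R1_B = R1_A, R2_B = R2_A,
                           k_AB = NULL, k_BA = NULL) {
  if (is.null(k_ex) && is.null(p_B)) {
    if (is.null(k_AB) || is.null(k_BA))
      stop("supply either (k_ex, p_B) or (k_AB, k_BA)")
    check_num(k_AB, "k_AB", lower = 0)
    check_num(k_BA, "k_BA", lower = 0)
    k_ex <- k_AB + k_BA
    if (k_ex <= 0) stop("k_AB + k_BA must be > 0 to derive p_B")
    p_B <- k_AB / k_ex
  }
  check_num(k_ex, "k_ex", lower = 0)
  check_num(p_B, "p_B", lower = 0, upper = 1, open = TRUE)
  check_num(delta_A, "delta_A")
  check_num(delta_delta, "delta_delta")
  for (nm in c("R1_A", "R1_B", "R2_A", "R2_B"))
    check_num(get(nm), nm, lower = 0)
  structure(list(
    delta_A = delta_A, delta_delta = delta_delta,
    k_ex = k_ex, p_B = p_B,
    k_AB = p_B * k_ex, k_BA = (1 - p_B) * k_ex,
    R1_A = R1_A, R1_B = R1_B, R2_A = R2_A, R2_B = R2_B
  ), class = "exchange_model")
}

#' @export
print.exchange_model <- function(x, ...) {
  cat("Two-state exchange model\n")
  cat(sprintf("  delta_A = %g ppm, delta_delta = %g ppm\n",
              x$delta_A, x$delta_delta))
  cat(sprintf("  k_ex = %g 1/s, p_B = %g  (k_AB = %g, k_BA = %g 1/s)\n",
              x$k_ex, x$p_B, x$k_AB, x$k_BA))
  cat(sprintf("  R1_A = %g, R1_B = %g, R2_A = %g, R2_B = %g 1/s\n",
              x$R1_A, x$R1_B, x$R2_A, x$R2_B))
  invisible(x)
}

#' Acquisition constants
#'
#' Experiment-wide constants shared by all profiles of a project: the 15N
#' Larmor frequency of the static field (which fixes the ppm -> rad/s
#' conversion), the saturation pulse duration, the nominal RF field
#' strengths, and the Gaussian B1-inhomogeneity model.
#'
#' @param larmor_MHz 15N Larmor frequency (MHz), e.g. 80.12 at 18.8 T.
#' @param T_sat saturation pulse duration (s).
#' @param b1_fields nominal RF field strengths nu1 (Hz); joint fitting
#'   requires at least two distinct values.
#' @param b1_frac_sigma fractional standard deviation of the Gaussian B1
#'   distribution across the sample (0 disables the correction).
#' @param b1_grid_points odd number of quadrature points for B1 averaging.
#' @return An object of class `cest_acquisition`.
#' @export
acquisition <- function(larmor_MHz, T_sat, b1_fields,
                        b1_frac_sigma = 0, b1_grid_points = 11) {
  check_num(larmor_MHz, "larmor_MHz", lower = 0, open = TRUE)
  check_num(T_sat, "T_sat", lower = 0)
  if (length(b1_fields) < 1 || any(!is.finite(b1_fields)) ||
      any(b1_fields <= 0))
    stop("b1_fields must be positive finite RF field strengths (Hz)")
  check_num(b1_frac_sigma, "b1_frac_sigma", lower = 0, upper = 0.5)
  if (b1_grid_points < 1 || b1_grid_points %% 2 != 1)
    stop("b1_grid_points must be an odd integer >= 1")
  structure(list(
    larmor_MHz = larmor_MHz, T_sat = T_sat,
    b1_fields = as.numeric(b1_fields),
    b1_frac_sigma = b1_frac_sigma,
    b1_grid_points = as.integer(b1_grid_points)
  ), class = "cest_acquisition")
}

#' CEST profile (Z-spectrum) for one residue at one RF field
#'
#' @param residue_id residue label, e.g. `"A1"` or `"N75"`.
#' @param b1_Hz nominal RF field strength of this profile (Hz).
#' @param offsets_ppm saturation-carrier positions (absolute ppm); stored
#'   sorted ascending.
#' @param intensities normalized intensities I/I0.
#' @param sigmas per-point intensity uncertainty; a scalar is broadcast.
#'   `NULL` marks the uncertainty as unknown (it is then estimated from the
#'   exchange-free baseline before fitting, see [estimate_sigma()]).
#' @return An object of class `cest_profile`.
#' @export
cest_profile <- function(residue_id, b1_Hz, offsets_ppm, intensities,
                         sigmas = NULL) {
  check_num(b1_Hz, "b1_Hz", lower = 0, open = TRUE)
  n <- length(offsets_ppm)
  if (n < 3) stop("a CEST profile needs at least 3 points")
  if (length(intensities) != n)
    stop("offsets_ppm and intensities must have equal length")
  if (any(!is.finite(offsets_ppm)) || any(!is.finite(intensities)))
    stop("offsets and intensities must be finite")
  if (is.null(sigmas)) {
    sigmas <- rep(NA_real_, n)
  } else {
    if (length(sigmas) == 1) sigmas <- rep(sigmas, n)
    if (length(sigmas) != n) stop("sigmas must be scalar or match offsets")
    if (any(!is.finite(sigmas)) || any(sigmas <= 0))
      stop("sigmas must be positive")
  }
  ord <- order(offsets_ppm)
  structure(list(
    residue_id = as.character(residue_id), b1_Hz = b1_Hz,
    offsets_ppm = as.numeric(offsets_ppm)[ord],
    intensities = as.numeric(intensities)[ord],
    sigmas = as.numeric(sigmas)[ord]
  ), class = "cest_profile")
}

#' @export
print.cest_profile <- function(x, ...) {
  cat(sprintf("CEST profile %s @ %g Hz: %d points, %g..%g ppm\n",
              x$residue_id, x$b1_Hz, length(x$offsets_ppm),
              min(x$offsets_ppm), max(x$offsets_ppm)))
  invisible(x)
}

#' Angular frequencies of the rotating-frame problem
#'
#' Converts the chemical-shift geometry to rad/s: `Omega_A = 2*pi *
#' (delta_A - delta_sat) * larmor_MHz` (ppm times MHz equals Hz), `Omega_B`
#' analogously with `delta_A + delta_delta`, and `omega1 = 2*pi*nu1`.
#'
#' @param model an [exchange_model()].
#' @param acq a [acquisition()] object (supplies `larmor_MHz`).
#' @param delta_sat saturation-carrier position(s), ppm; vectorized.
#' @param nu1 RF field strength (Hz).
#' @return list with elements `omega_A`, `omega_B` (same length as
#'   `delta_sat`) and scalar `omega1`, all rad/s.
#' @export
angular_frequencies <- function(model, acq, delta_sat, nu1) {
  list(
    omega_A = 2 * pi * (model$delta_A - delta_sat) * acq$larmor_MHz,
    omega_B = 2 * pi * (model$delta_A + model$delta_delta - delta_sat) *
      acq$larmor_MHz,
    omega1 = 2 * pi * nu1
  )
}

# shared scalar validator: finite, optional bounds; `open` makes both
# bounds strict
check_num <- function(x, name, lower = -Inf, upper = Inf, open = FALSE) {
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x))
    stop(sprintf("%s must be a single finite number", name), call. = FALSE)
  bad <- if (open) (x <= lower || x >= upper) else (x < lower || x > upper)
  if (bad)
    stop(sprintf("%s = %g outside the allowed range %s%g, %g%s", name, x,
                 if (open) "(" else "[", lower, upper,
                 if (open) ")" else "]"), call. = FALSE)
  invisible(x)
}
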