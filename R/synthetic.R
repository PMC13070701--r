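#' Specification of a synthetic CEST benchmark dataset
#'
#' Everything needed to generate a reproducible set of Z-spectra: the
#' residue table, the (shared) kinetics, relaxation defaults, acquisition
#' constants, offset grid and noise levels.
#'
#' @param residues data.frame with columns `id`, `delta_A` (ppm) and
#'   `delta_delta` (ppm).
#' @param k_AB,k_BA forward and reverse exchange rates (1/s).
#' @param R1,R2_A,R2_B relaxation rates (1/s) applied to every residue.
#' @param larmor_MHz,T_sat,b1_fields acquisition constants, see
#'   [acquisition()].
#' @param grid offset grid as `c(start, stop, step)` in ppm; must cover
#'   every `delta_A` and `delta_A + delta_delta` with at least 2 ppm margin.
#' @param intensity_noise_frac 1-sigma Gaussian noise added to each
#'   intensity point.
#' @param b1_error_frac 1-sigma fractional Gaussian miscalibration of the
#'   actual RF field, drawn once per profile; generated profiles carry the
#'   nominal field, so the fit has to absorb the calibration error.
#' @param seed integer seed.
#' @return object of class `cest_synth_spec`.
#' @export
synthetic_spec <- function(residues, k_AB, k_BA, R1 = 1.5, R2_A = 10,
                           R2_B = 10, larmor_MHz = 80.12, T_sat = 0.4,
                           b1_fields = c(10, 100), grid = c(104, 130, 0.25),
                           intensity_noise_frac = 0.02,
                           b1_error_frac = 0.02, seed = 1) {
  stopifnot(is.data.frame(residues),
            all(c("id", "delta_A", "delta_delta") %in% names(residues)))
  if (intensity_noise_frac < 0 || b1_error_frac < 0)
    stop("noise fractions must be >= 0")
  if (length(grid) != 3 || grid[2] <= grid[1] || grid[3] <= 0)
    stop("grid must be c(start, stop, step) with start < stop, step > 0")
  pos <- c(residues$delta_A, residues$delta_A + residues$delta_delta)
  if (min(pos) - grid[1] < 2 || grid[2] - max(pos) < 2)
    stop("offset grid must cover all resonances with >= 2 ppm margin")
  structure(list(
    residues = residues, k_AB = k_AB, k_BA = k_BA,
    R1 = R1, R2_A = R2_A, R2_B = R2_B,
    larmor_MHz = larmor_MHz, T_sat = T_sat, b1_fields = b1_fields,
    grid = grid, intensity_noise_frac = intensity_noise_frac,
    b1_error_frac = b1_error_frac, seed = as.integer(seed)
  ), class = "cest_synth_spec")
}

#' The five-residue validation benchmark
#'
#' A standard two-field benchmark spanning several exchange regimes: five
#' residues with ground-state shifts 118.0, 110.0, 115.0, 120.0 and 125.0
#' ppm and shift differences -5.0, -1.0, 2.0, 2.0 and -3.0 ppm; kinetics
#' `k_AB = 15`, `k_BA = 285` 1/s (so `k_ex = 300` 1/s, `p_B = 0.05`);
#' 15N Larmor frequency 80.12 MHz; `T_sat` 0.4 s; RF fields 10 and 100 Hz;
#' 2% Gaussian errors on both the intensities and the per-profile RF field
#' calibration. Relaxation defaults (R1 = 1.5, R2 = 10 1/s) are typical
#' backbone-15N values at this field; the offset grid (104 to 130 ppm, 0.25
#' ppm step) covers every resonance with margin and resolves the 10 Hz dips.
#'
#' @param seed integer seed.
#' @param intensity_noise_frac,b1_error_frac noise levels; set both to 0
#'   for a deterministic noiseless dataset.
#' @return a [synthetic_spec()].
#' @export
validation_spec <- function(seed = 1, intensity_noise_frac = 0.02,
                            b1_error_frac = 0.02) {
  synthetic_spec(
    residues = data.frame(
      id = paste0("A", 1:5),
      delta_A = c(118, 110, 115, 120, 125),
      delta_delta = c(-5, -1, 2, 2, -3)),
    k_AB = 15, k_BA = 285,
    intensity_noise_frac = intensity_noise_frac,
    b1_error_frac = b1_error_frac, seed = seed)
}

#' Generate a synthetic dataset
#'
#' For every (residue, field) pair the actual RF field is drawn once as
#' `nu1_nominal * (1 + eps)`, `eps ~ N(0, b1_error_frac)`; intensities are
#' the full Bloch-McConnell (matrix-kernel) prediction at the actual field
#' plus per-point Gaussian noise of scale `intensity_noise_frac`. The
#' emitted profiles carry the nominal field and a sigma column equal to the
#' intensity noise fraction (floored at 1e-3 for noiseless datasets so that
#' chi-square weighting stays defined). The RNG is seeded from
#' `spec$seed`, so a given spec always produces a bit-identical dataset.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `profiles` (list of [cest_profile()]), `truth`
#'   (data.frame of generating parameters per residue plus the realized
#'   actual fields per profile in `b1_actual`), `acquisition` and `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "cest_synth_spec"))
  acq <- acquisition(spec$larmor_MHz, spec$T_sat, spec$b1_fields)
  offsets <- seq(spec$grid[1], spec$grid[2], by = spec$grid[3])
  sigma <- max(spec$intensity_noise_frac, 1e-3)
  set.seed(spec$seed)
  profiles <- list()
  b1_actual <- data.frame(residue = character(0), b1_nominal = numeric(0),
                          b1_actual = numeric(0))
  for (i in seq_len(nrow(spec$residues))) {
    r <- spec$residues[i, ]
    m <- exchange_model(k_AB = spec$k_AB, k_BA = spec$k_BA,
                        delta_A = r$delta_A, delta_delta = r$delta_delta,
                        R1_A = spec$R1, R2_A = spec$R2_A, R2_B = spec$R2_B)
    for (nu1 in spec$b1_fields) {
      nu1_actual <- nu1 * (1 + rnorm(1, 0, spec$b1_error_frac))
      ideal <- zspec_matrix(m, acq, nu1_actual, offsets)
      noisy <- ideal + rnorm(length(ideal), 0, spec$intensity_noise_frac)
      profiles[[length(profiles) + 1L]] <-
        cest_profile(r$id, nu1, offsets, noisy, sigma)
      b1_actual <- rbind(b1_actual, data.frame(
        residue = r$id, b1_nominal = nu1, b1_actual = nu1_actual))
    }
  }
  truth <- cbind(spec$residues,
                 k_AB = spec$k_AB, k_BA = spec$k_BA,
                 k_ex = spec$k_AB + spec$k_BA,
                 p_B = spec$k_AB / (spec$k_AB + spec$k_BA),
                 R1 = spec$R1, R2_A = spec$R2_A, R2_B = spec$R2_B)
  list(profiles = profiles, truth = truth, b1_actual = b1_actual,
       acquisition = acq, spec = spec)
}
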