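# Shared fixtures: a benchmark-like model, acquisition constants, and a
# small two-residue dataset cheap enough for repeated fitting in tests.

bench_model <- function(...) {
  args <- modifyList(list(k_ex = 300, p_B = 0.05, delta_A = 118,
                          delta_delta = -5, R1_A = 1.5, R2_A = 10), list(...))
  do.call(exchange_model, args)
}

bench_acq <- function(...) {
  args <- modifyList(list(larmor_MHz = 80.12, T_sat = 0.4,
                          b1_fields = c(10, 100)), list(...))
  do.call(acquisition, args)
}

bench_offsets <- function(step = 0.25) seq(104, 130, by = step)

# two-residue variant of the benchmark on a coarser, narrower grid: a fit
# of this converges in a couple of seconds
small_spec <- function(seed = 1, intensity_noise_frac = 0,
                       b1_error_frac = 0) {
  synthetic_spec(
    residues = data.frame(id = c("A1", "A5"),
                          delta_A = c(118, 125), delta_delta = c(-5, -3)),
    k_AB = 15, k_BA = 285, grid = c(108, 130, 0.5),
    intensity_noise_frac = intensity_noise_frac,
    b1_error_frac = b1_error_frac, seed = seed)
}

# random exchange model drawn inside the default fitting bounds
random_model <- function() {
  exchange_model(k_ex = 10^runif(1, 1, 3.3), p_B = runif(1, 0.005, 0.3),
                 delta_A = runif(1, 110, 125),
                 delta_delta = runif(1, -8, 8),
                 R1_A = runif(1, 0.5, 3), R2_A = runif(1, 2, 40),
                 R2_B = runif(1, 2, 60))
}
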