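#' Fit specification
#'
#' Collects everything that controls a joint fit: the forward kernel, whether
#' kinetics are shared across residues, parameter bounds, and the Monte-Carlo
#' settings.
#'
#' @param method forward model: `"baldwin"` (analytical spectral kernel,
#'   default), `"matrix"` (full 7x7 propagation) or `"noex"` (single-spin
#'   no-exchange control).
#' @param share_kinetics if `TRUE` (default) one `(k_ex, p_B)` pair is shared
#'   by all residues; otherwise each residue gets its own kinetics.
#' @param bounds named list of `[low, high]` bounds; see [default_bounds()].
#'   Partial lists override the defaults element-wise.
#' @param mc_iterations number of Monte-Carlo error iterations (0 =
#'   covariance-only uncertainties).
#' @param seed integer seed for all stochastic steps.
#' @return An object of class `cest_fit_spec`.
#' @export
fit_spec <- function(method = c("baldwin", "matrix", "noex"),
                     share_kinetics = TRUE, bounds = list(),
                     mc_iterations = 0, seed = 1) {
  method <- match.arg(method)
  b <- modifyList(default_bounds(), bounds)
  for (nm in names(b))
    if (length(b[[nm]]) != 2 || b[[nm]][1] >= b[[nm]][2])
      stop(sprintf("bounds$%s must be [low, high] with low < high", nm))
  if (mc_iterations < 0) stop("mc_iterations must be >= 0")
  structure(list(method = method, share_kinetics = isTRUE(share_kinetics),
                 bounds = b, mc_iterations = as.integer(mc_iterations),
                 seed = as.integer(seed)),
            class = "cest_fit_spec")
}

#' Default fit parameter bounds
#'
#' `k_ex` 1..1e5 1/s, `p_B` 1e-4..0.5, `delta_delta` -30..30 ppm,
#' `R1` 0.05..10 1/s, `R2` 0.5..200 1/s. `delta_A` is bounded by the data
#' window of each residue at fit time.
#' @export
default_bounds <- function() {
  list(k_ex = c(1, 1e5), p_B = c(1e-4, 0.5), delta_delta = c(-30, 30),
       R1 = c(0.05, 10), R2 = c(0.5, 200))
}

#' Detect exchange-induced dips in a Z-spectrum
#'
#' Local minima whose depth below the robust baseline (median of the upper
#' intensity quartile) exceeds `snr_threshold * median(sigma)` are reported,
#' deepest first. The deepest dip is the ground-state candidate `delta_A`,
#' the next one the minor-state candidate `delta_B`. Minima closer than
#' three grid steps are merged (deeper one wins). The lowest-B1 profile is
#' the recommended input: weak fields give the narrowest, best-separated
#' dips.
#'
#' @param profile a [cest_profile()].
#' @param snr_threshold detection threshold as a multiple of the median
#'   intensity uncertainty.
#' @return data.frame with columns `position` (ppm) and `depth`, sorted by
#'   depth descending; zero rows if nothing exceeds the threshold.
#' @export
detect_dips <- function(profile, snr_threshold = 3) {
  x <- profile$offsets_ppm
  n <- length(profile$intensities)
  if (n < 3) stop("dip detection needs at least 3 points")
  # 3-point running mean: real dips span several points, single-point noise
  # minima do not
  I <- running_mean3(profile$intensities)
  sig <- profile$sigmas
  med_sig <- if (all(is.na(sig))) provisional_sigma(profile$intensities)
             else median(sig)
  baseline <- median(I[I >= quantile(I, 0.75)])
  cand <- which(vapply(seq_len(n), function(i) {
    lo <- max(1L, i - 2L); hi <- min(n, i + 2L)
    I[i] <= min(I[lo:hi])
  }, logical(1)))
  depth <- baseline - I[cand]
  keep <- depth > snr_threshold * med_sig
  cand <- cand[keep]; depth <- depth[keep]
  if (!length(cand))
    return(data.frame(position = numeric(0), depth = numeric(0)))
  ord <- order(depth, decreasing = TRUE)
  cand <- cand[ord]; depth <- depth[ord]
  step <- median(diff(x))
  pos <- x[cand]
  sel <- logical(length(cand))
  for (i in seq_along(cand)) {
    if (!any(sel) || all(abs(pos[i] - pos[sel]) > 3 * step)) sel[i] <- TRUE
  }
  data.frame(position = pos[sel], depth = depth[sel])
}

running_mean3 <- function(I) {
  n <- length(I)
  out <- I
  if (n >= 3) out[2:(n - 1)] <- (I[1:(n - 2)] + I[2:(n - 1)] + I[3:n]) / 3
  out
}

# robust point-noise estimate from first differences (used when no sigma
# column is available yet)
provisional_sigma <- function(I) {
  s <- median(abs(diff(I))) / (sqrt(2) * 0.6745)
  max(s, 1e-6)
}

#' Estimate the intensity uncertainty of a profile
#'
#' When input files carry no uncertainty column, sigma is estimated as the
#' standard deviation of the intensities at the 20% of offsets farthest
#' from all detected dips (i.e. on the exchange-free baseline).
#'
#' @param profile a [cest_profile()].
#' @return scalar sigma estimate.
#' @export
estimate_sigma <- function(profile) {
  dips <- detect_dips(profile, snr_threshold = 3)
  x <- profile$offsets_ppm
  if (nrow(dips) == 0) return(provisional_sigma(profile$intensities))
  d <- vapply(x, function(xi) min(abs(xi - dips$position)), numeric(1))
  k <- max(3L, ceiling(0.2 * length(x)))
  idx <- order(d, decreasing = TRUE)[seq_len(k)]
  s <- sd(profile$intensities[idx])
  max(s, 1e-6)
}

fill_sigmas <- function(profiles) {
  lapply(profiles, function(p) {
    if (all(is.na(p$sigmas))) p$sigmas <- rep(estimate_sigma(p),
                                              length(p$offsets_ppm))
    p
  })
}

# coarse initialization grids for the kinetic parameters
init_grid_kex <- c(50, 100, 200, 400, 800, 1600)
init_grid_pb <- c(0.005, 0.01, 0.02, 0.05, 0.1)

#' Automatic initial parameter estimates for one residue
#'
#' Two-stage initialization: `delta_A` and `delta_delta` come from
#' [detect_dips()] on the lowest-B1 profile (fallback `delta_delta = +2`
#' ppm, flagged, when no secondary dip is found); `(k_ex, p_B)` from a
#' coarse grid search minimizing the chi-square of the analytical kernel
#' with relaxation held at typical backbone-15N values (R1 = 1.5, R2 = 10
#' 1/s).
#'
#' @param profiles list of [cest_profile()]s of a single residue (one or
#'   more RF fields).
#' @param acq an [acquisition()] object.
#' @return list with elements `model` (the starting [exchange_model()]),
#'   `flags` (character vector of fallbacks taken) and `grid` (the searched
#'   chi-square surface, used internally for shared-kinetics pooling).
#' @export
initial_estimates <- function(profiles, acq) {
  stopifnot(length(profiles) >= 1)
  profiles <- fill_sigmas(profiles)
  low <- profiles[[which.min(vapply(profiles, `[[`, numeric(1), "b1_Hz"))]]
  dips <- detect_dips(low, snr_threshold = 3)
  flags <- character(0)
  if (nrow(dips) >= 1) {
    delta_A <- dips$position[1]
  } else {
    delta_A <- low$offsets_ppm[which.min(low$intensities)]
    flags <- c(flags, "no dip above threshold; delta_A set at global minimum")
  }
  grid_chisq <- function(delta_delta) {
    grid <- expand.grid(k_ex = init_grid_kex, p_B = init_grid_pb)
    grid$chisq <- vapply(seq_len(nrow(grid)), function(i) {
      m <- exchange_model(k_ex = grid$k_ex[i], p_B = grid$p_B[i],
                          delta_A = delta_A, delta_delta = delta_delta,
                          R1_A = 1.5, R2_A = 10)
      sum(vapply(profiles, function(p) {
        pred <- zspec_baldwin(m, acq, p$b1_Hz, p$offsets_ppm)
        sum(((p$intensities - pred) / p$sigmas)^2)
      }, numeric(1)))
    }, numeric(1))
    grid
  }
  if (nrow(dips) >= 2) {
    delta_delta <- dips$position[2] - delta_A
    grid <- grid_chisq(delta_delta)
  } else {
    # coalesced or absent minor dip: try both mirror signs of the default
    # start and keep the better-scoring one
    g_plus <- grid_chisq(2)
    g_minus <- grid_chisq(-2)
    if (min(g_minus$chisq) < min(g_plus$chisq)) {
      delta_delta <- -2; grid <- g_minus
    } else {
      delta_delta <- 2; grid <- g_plus
    }
    flags <- c(flags, sprintf(
      "no secondary dip; delta_delta start defaulted to %+g ppm (mirror sign by grid score)",
      delta_delta))
  }
  i <- which.min(grid$chisq)
  list(model = exchange_model(k_ex = grid$k_ex[i], p_B = grid$p_B[i],
                              delta_A = delta_A, delta_delta = delta_delta,
                              R1_A = 1.5, R2_A = 10),
       flags = flags, grid = grid)
}

#' Reduced chi-square
#'
#' `sum(((obs - calc)/sigma)^2) / (n_data - n_params)`.
#'
#' @param observed,calculated,sigmas equal-length numeric vectors.
#' @param n_params number of fitted parameters; must be < `length(observed)`.
#' @export
reduced_chisq <- function(observed, calculated, sigmas, n_params) {
  n <- length(observed)
  if (length(calculated) != n || length(sigmas) != n)
    stop("observed, calculated and sigmas must have equal length")
  if (n <= n_params)
    stop(sprintf("n_data (%d) must exceed n_params (%d)", n, n_params))
  sum(((observed - calculated) / sigmas)^2) / (n - n_params)
}

# ---- parameter packing -----------------------------------------------------

param_layout <- function(profiles, spec) {
  residues <- unique(vapply(profiles, `[[`, character(1), "residue_id"))
  b <- spec$bounds
  nm <- character(0); lo <- numeric(0); hi <- numeric(0)
  add <- function(name, bound) {
    nm <<- c(nm, name); lo <<- c(lo, bound[1]); hi <<- c(hi, bound[2])
  }
  win <- lapply(residues, function(r) {
    off <- unlist(lapply(profiles[res_of(profiles) == r], `[[`, "offsets_ppm"))
    range(off)
  })
  names(win) <- residues
  if (spec$method == "noex") {
    for (r in residues) {
      add(paste0(r, ".delta_A"), win[[r]])
      add(paste0(r, ".R1_A"), b$R1)
      add(paste0(r, ".R2_A"), b$R2)
    }
  } else {
    if (spec$share_kinetics) {
      add("k_ex", b$k_ex); add("p_B", b$p_B)
    }
    for (r in residues) {
      if (!spec$share_kinetics) {
        add(paste0(r, ".k_ex"), b$k_ex); add(paste0(r, ".p_B"), b$p_B)
      }
      add(paste0(r, ".delta_A"), win[[r]])
      add(paste0(r, ".delta_delta"), b$delta_delta)
      add(paste0(r, ".R1_A"), b$R1)
      add(paste0(r, ".R2_A"), b$R2)
      add(paste0(r, ".R2_B"), b$R2)
    }
  }
  list(residues = residues, names = nm, lower = lo, upper = hi)
}

res_of <- function(profiles) vapply(profiles, `[[`, character(1), "residue_id")

theta_models <- function(theta, layout, spec) {
  names(theta) <- layout$names
  g <- function(n) unname(theta[n])
  out <- list()
  for (r in layout$residues) {
    out[[r]] <- if (spec$method == "noex") {
      list(delta_A = g(paste0(r, ".delta_A")), R1 = g(paste0(r, ".R1_A")),
           R2 = g(paste0(r, ".R2_A")))
    } else {
      kex <- if (spec$share_kinetics) g("k_ex") else g(paste0(r, ".k_ex"))
      pb <- if (spec$share_kinetics) g("p_B") else g(paste0(r, ".p_B"))
      exchange_model(k_ex = kex, p_B = pb,
                     delta_A = g(paste0(r, ".delta_A")),
                     delta_delta = g(paste0(r, ".delta_delta")),
                     R1_A = g(paste0(r, ".R1_A")),
                     R2_A = g(paste0(r, ".R2_A")),
                     R2_B = g(paste0(r, ".R2_B")))
    }
  }
  out
}

predict_profiles <- function(theta, layout, profiles, acq, spec) {
  models <- theta_models(theta, layout, spec)
  lapply(profiles, function(p) {
    m <- models[[p$residue_id]]
    switch(spec$method,
      baldwin = zspec_baldwin(m, acq, p$b1_Hz, p$offsets_ppm),
      matrix = zspec_matrix(m, acq, p$b1_Hz, p$offsets_ppm),
      noex = zspec_noex(m$R1, m$R2, m$delta_A, acq, p$b1_Hz, p$offsets_ppm))
  })
}

start_theta <- function(profiles, acq, layout, spec) {
  residues <- layout$residues
  per_res <- lapply(residues, function(r)
    initial_estimates(profiles[res_of(profiles) == r], acq))
  names(per_res) <- residues
  flags <- unlist(lapply(residues, function(r)
    if (length(per_res[[r]]$flags))
      paste0(r, ": ", per_res[[r]]$flags) else character(0)))
  theta <- setNames(numeric(length(layout$names)), layout$names)
  if (spec$method == "noex") {
    for (r in residues) {
      theta[paste0(r, ".delta_A")] <- per_res[[r]]$model$delta_A
      theta[paste0(r, ".R1_A")] <- 1.5
      theta[paste0(r, ".R2_A")] <- 10
    }
  } else {
    if (spec$share_kinetics) {
      # pool the per-residue chi-square grids and take the joint minimizer
      pooled <- per_res[[1]]$grid
      if (length(residues) > 1)
        for (r in residues[-1]) pooled$chisq <- pooled$chisq +
            per_res[[r]]$grid$chisq
      i <- which.min(pooled$chisq)
      theta["k_ex"] <- pooled$k_ex[i]
      theta["p_B"] <- pooled$p_B[i]
    }
    for (r in residues) {
      m <- per_res[[r]]$model
      if (!spec$share_kinetics) {
        theta[paste0(r, ".k_ex")] <- m$k_ex
        theta[paste0(r, ".p_B")] <- m$p_B
      }
      theta[paste0(r, ".delta_A")] <- m$delta_A
      theta[paste0(r, ".delta_delta")] <- m$delta_delta
      theta[paste0(r, ".R1_A")] <- m$R1_A
      theta[paste0(r, ".R2_A")] <- m$R2_A
      theta[paste0(r, ".R2_B")] <- m$R2_B
    }
  }
  attr(theta, "flags") <- flags
  theta
}

#' Joint multi-field fit of CEST profiles
#'
#' Minimizes the weighted sum of squared residuals over all profiles
#' simultaneously with a bound-constrained Levenberg-Marquardt least-squares
#' algorithm. With `share_kinetics` one `(k_ex, p_B)` pair is common to all
#' residues while `delta_A`, `delta_delta`, `R1_A`, `R2_A`, `R2_B` are
#' per-residue (`R1_B` is tied to `R1_A`, which CEST data cannot separate).
#' Fitting the exchange methods requires profiles at two or more distinct
#' RF field strengths; a single field cannot break the
#' `k_ex`/`p_B`/`R2_B` degeneracy.
#'
#' @param profiles list of [cest_profile()]s spanning >= 2 distinct B1
#'   fields (for the exchange methods).
#' @param acq an [acquisition()] object shared by all profiles.
#' @param spec a [fit_spec()].
#' @param start optional named start vector (as produced by a previous fit's
#'   `$theta`); when `NULL`, automatic initial estimates are used.
#' @return an object of class `cest_fit` with elements `method`, `global`
#'   and `per_residue` parameter tables (value, standard error), `red_chisq`,
#'   `n_data`, `n_params`, `curves` (one data.frame per profile), `theta`,
#'   `convergence`, `flags`, and `mc` (Monte-Carlo errors when
#'   `spec$mc_iterations > 0`).
#' @export
joint_fit <- function(profiles, acq, spec = fit_spec(), start = NULL) {
  stopifnot(length(profiles) >= 1)
  for (p in profiles)
    if (!inherits(p, "cest_profile")) stop("profiles must be cest_profile objects")
  if (spec$method != "noex") {
    nb1 <- length(unique(vapply(profiles, `[[`, numeric(1), "b1_Hz")))
    if (nb1 < 2)
      stop("parameter degeneracy: joint fitting of exchange models requires ",
           "profiles at two or more distinct RF field strengths (B1); got ",
           nb1)
  }
  profiles <- fill_sigmas(profiles)
  layout <- param_layout(profiles, spec)
  flags <- character(0)
  if (is.null(start)) {
    start <- start_theta(profiles, acq, layout, spec)
    flags <- attr(start, "flags")
  } else {
    if (is.null(names(start))) names(start) <- layout$names
    start <- start[layout$names]
  }
  start <- pmin(pmax(unname(start), layout$lower), layout$upper)

  obs <- unlist(lapply(profiles, `[[`, "intensities"))
  sig <- unlist(lapply(profiles, `[[`, "sigmas"))
  resid_fn <- function(theta) {
    pred <- unlist(predict_profiles(theta, layout, profiles, acq, spec))
    (obs - pred) / sig
  }
  fit <- minpack.lm::nls.lm(par = start, lower = layout$lower,
                            upper = layout$upper, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, nprint = 0))
  if (fit$info == 0) stop("least-squares routine rejected the input: ",
                          fit$message)
  if (fit$info == 5)
    flags <- c(flags, "maximum iterations reached without convergence")
  theta <- setNames(unname(fit$par), layout$names)
  n_data <- length(obs)
  n_params <- length(theta)
  pred <- predict_profiles(theta, layout, profiles, acq, spec)
  rchi <- reduced_chisq(obs, unlist(pred), sig, n_params)
  covm <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  se <- if (is.null(covm)) rep(NA_real_, n_params) else sqrt(pmax(diag(covm), 0))
  names(se) <- layout$names

  curves <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    data.frame(residue = p$residue_id, b1_Hz = p$b1_Hz,
               offset_ppm = p$offsets_ppm, I_obs = p$intensities,
               sigma = p$sigmas, I_fit = pred[[i]])
  })

  res <- structure(list(
    method = spec$method, share_kinetics = spec$share_kinetics,
    global = global_table(theta, se, covm, layout, spec),
    per_residue = residue_table(theta, se, layout, spec),
    red_chisq = rchi, n_data = n_data, n_params = n_params,
    curves = curves, theta = theta, se = se,
    lower = setNames(layout$lower, layout$names),
    upper = setNames(layout$upper, layout$names),
    convergence = list(info = fit$info, message = fit$message,
                       niter = fit$niter),
    flags = flags, acq = acq, spec = spec
  ), class = "cest_fit")

  if (spec$mc_iterations > 0)
    res$mc <- monte_carlo_errors(res, profiles, acq, spec)
  res
}

global_table <- function(theta, se, covm, layout, spec) {
  if (spec$method == "noex" || !spec$share_kinetics)
    return(data.frame(param = character(0), value = numeric(0),
                      se = numeric(0)))
  kex <- theta[["k_ex"]]; pb <- theta[["p_B"]]
  # delta-method errors for the derived one-way rates
  kab_se <- kba_se <- NA_real_
  if (!is.null(covm)) {
    V <- covm[1:2, 1:2]
    kab_se <- sqrt(drop(t(c(pb, kex)) %*% V %*% c(pb, kex)))
    kba_se <- sqrt(drop(t(c(1 - pb, -kex)) %*% V %*% c(1 - pb, -kex)))
  }
  data.frame(
    param = c("k_ex", "p_B", "k_AB", "k_BA"),
    value = c(kex, pb, pb * kex, (1 - pb) * kex),
    se = c(se[["k_ex"]], se[["p_B"]], kab_se, kba_se))
}

residue_table <- function(theta, se, layout, spec) {
  rows <- grep(".", names(theta), fixed = TRUE, value = TRUE)
  parts <- strsplit(rows, ".", fixed = TRUE)
  data.frame(
    residue = vapply(parts, `[[`, character(1), 1),
    param = vapply(parts, `[[`, character(1), 2),
    value = unname(theta[rows]),
    se = unname(se[rows]))
}

#' @export
print.cest_fit <- function(x, ...) {
  cat(sprintf("Joint CEST fit (%s kernel): %d points, %d parameters\n",
              x$method, x$n_data, x$n_params))
  cat(sprintf("  reduced chi-square: %.4g\n", x$red_chisq))
  if (nrow(x$global)) {
    g <- x$global
    fm <- function(p) sprintf("%.4g +/- %.2g", g$value[g$param == p],
                              g$se[g$param == p])
    cat(sprintf("  k_ex = %s 1/s, p_B = %s\n", fm("k_ex"), fm("p_B")))
    cat(sprintf("  k_AB = %s 1/s, k_BA = %s 1/s\n", fm("k_AB"), fm("k_BA")))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Monte-Carlo parameter uncertainties
#'
#' Parametric resampling: `mc_iterations` synthetic datasets are built as
#' the best-fit curves plus Gaussian noise of the per-point sigma, each is
#' refit from the best-fit starting point, and the per-parameter standard
#' deviation over iterations is reported. Refits that end on a bound are
#' retained but counted; more than 50% bound-saturated iterations raises a
#' warning flag.
#'
#' @param best a converged [joint_fit()] result.
#' @param profiles the profiles that were fitted.
#' @param acq the [acquisition()] used.
#' @param spec a [fit_spec()] with `mc_iterations >= 2` and `seed` set.
#' @return data.frame with columns `param` and `mc_sd`; attribute
#'   `n_bound_saturated` carries the count of bound-hitting refits and
#'   attribute `flag` a warning string when they exceed half.
#' @export
monte_carlo_errors <- function(best, profiles, acq, spec) {
  if (spec$mc_iterations < 2) stop("mc_iterations must be >= 2")
  profiles <- fill_sigmas(profiles)
  spec_nomc <- spec
  spec_nomc$mc_iterations <- 0L
  set.seed(spec$seed)
  draws <- NULL
  n_bound <- 0L
  for (it in seq_len(spec$mc_iterations)) {
    prof_i <- lapply(seq_along(profiles), function(j) {
      p <- profiles[[j]]
      p$intensities <- best$curves[[j]]$I_fit +
        rnorm(length(p$sigmas), 0, p$sigmas)
      p
    })
    f <- joint_fit(prof_i, acq, spec_nomc, start = best$theta)
    eps <- 1e-8 * pmax(abs(f$upper - f$lower), 1)
    if (any(f$theta <= f$lower + eps | f$theta >= f$upper - eps))
      n_bound <- n_bound + 1L
    row <- f$theta
    if (spec$share_kinetics && spec$method != "noex")
      row <- c(row, k_AB = unname(row["p_B"] * row["k_ex"]),
               k_BA = unname((1 - row["p_B"]) * row["k_ex"]))
    draws <- rbind(draws, row)
  }
  out <- data.frame(param = colnames(draws),
                    mc_sd = apply(draws, 2, sd), row.names = NULL)
  attr(out, "n_bound_saturated") <- n_bound
  if (n_bound > spec$mc_iterations / 2)
    attr(out, "flag") <- "more than half of the Monte-Carlo refits ended on a parameter bound"
  out
}
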