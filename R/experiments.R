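# Experiment drivers: receptor-only snapshot ensembles, steady-state NSR
# sweeps, and gradient-flip adaptation runs.  Replicate counts default to
# desk scale; every result row carries the seeds that produced it.

# Derive a modified config for a sweep point.  koff sweeps hold Kd fixed by
# re-deriving kon; D_G sweeps rescale dt to keep the RMS diffusion step (and
# hence encounter detection) unchanged.
apply_sweep <- function(cfg, param, value) {
  g <- cfg$gradient
  k <- cfg$kinetics
  N_R <- cfg$N_R; N_G <- cfg$N_G; dt <- cfg$dt
  switch(param,
    N_R = { N_R <- value },
    N_G = { N_G <- value },
    C0 = { g <- gradient_spec(value, g$b, g$theta, g$L) },
    koff = {
      k <- kinetic_params(koff = value, Kd = k$Kd, k_gi = k$k_gi,
                          D_G = k$D_G, r_star = k$r_star)
    },
    D_G = {
      dt <- dt * k$D_G / value
      k <- kinetic_params(koff = k$koff, Kd = k$Kd, k_gi = k$k_gi,
                          D_G = value, r_star = k$r_star)
    },
    k_gi = {
      k <- kinetic_params(koff = k$koff, Kd = k$Kd, k_gi = value,
                          D_G = k$D_G, r_star = k$r_star)
    },
    stop("unknown sweep parameter: ", param)
  )
  sim_config(gradient = g, kinetics = k, N_R = N_R, N_G = N_G,
             mode = cfg$mode, dt = dt, t_end = cfg$t_end, burn_in = NULL,
             snapshot_interval = cfg$snapshot_interval, seed = cfg$seed)
}

#' Receptor-only direction sensing from instantaneous snapshots
#'
#' Draws independent instantaneous receptor configurations (uniform
#' placements with Bernoulli states at the local equilibrium occupancy --
#' no G proteins, no dynamics) and evaluates the three receptor estimators
#' V_RL (bound), -V_R (unbound, flipped) and V_C = V_RL - V_R against the
#' true gradient direction, together with the matched Cramér-Rao bound.
#'
#' @param N_R_values receptor counts to test.
#' @param C0_over_Kd_values gradient mid-points, as multiples of Kd.
#' @param replicates independent snapshots per condition.
#' @param b gradient steepness.
#' @param Kd dissociation constant (nM).
#' @param L cell radius (um).
#' @param theta true gradient direction.
#' @param seed integer seed.
#' @return List of class \code{receptor_only_result}: \code{summary} (data
#'   frame: N_R, C0_over_Kd, estimator, nsr, bound_numeric, bound_weak,
#'   replicates), and \code{errors} (named list of angular-error vectors,
#'   one per condition and estimator, for CDFs).
#' @export
run_receptor_only <- function(N_R_values = c(375, 1500, 6000),
                              C0_over_Kd_values = 1, replicates = 1000,
                              b = 0.33, Kd = 6, L = 2.5,
                              theta = c(1, 0, 0), seed = 1L) {
  stopifnot(replicates >= 2)
  set.seed(seed)
  theta <- theta / sqrt(sum(theta^2))
  summary <- NULL
  errors <- list()
  for (N_R in N_R_values) for (ratio in C0_over_Kd_values) {
    g <- gradient_spec(C0 = ratio * Kd, b = b, theta = theta, L = L)
    V <- list(RL = matrix(0, replicates, 3), R = matrix(0, replicates, 3),
              C = matrix(0, replicates, 3))
    bound_num <- numeric(min(replicates, 50))
    for (r in seq_len(replicates)) {
      pos <- sample_uniform_sphere(N_R, L)
      p <- receptor_occupancy(ligand_concentration(pos, g), Kd)
      s <- as.integer(runif(N_R) < p)
      vrl <- resultant_vector(pos, s, "active")
      vr <- resultant_vector(pos, s, "inactive")
      V$RL[r, ] <- vrl
      V$R[r, ] <- vr
      V$C[r, ] <- combined_vector(vrl, vr)
      if (r <= length(bound_num))
        bound_num[r] <- fisher_information(pos, g, Kd)$bound
    }
    key <- sprintf("N_R=%d,C0/Kd=%g", N_R, ratio)
    for (est in c("RL", "R", "C")) {
      samp <- if (est == "R") -V$R else V[[est]]
      ok <- rowSums(samp^2) > 0
      summary <- rbind(summary, data.frame(
        N_R = N_R, C0_over_Kd = ratio, estimator = est,
        nsr = noise_to_signal(V[[est]][ok, , drop = FALSE]),
        bound_numeric = mean(bound_num),
        bound_weak = weak_signal_bound(N_R, b, ratio * Kd, Kd),
        replicates = sum(ok)))
      errors[[paste0(key, ",", est)]] <-
        angular_error(samp[ok, , drop = FALSE], theta)
    }
  }
  structure(list(summary = summary, errors = errors, seed = seed),
            class = "receptor_only_result")
}

#' Steady-state NSR sweep of the full membrane simulation
#'
#' For each sweep value, runs replicate simulations to steady state,
#' collects decorrelated snapshots of the active-G resultant V_G and of the
#' receptor estimators from the same runs, and reports each estimator's NSR
#' together with the matched instantaneous-receptor Cramér-Rao bound
#' (numerical Fisher information averaged over the replicate placements).
#'
#' @param cfg base [sim_config()]; \code{t_end} should cover
#'   \code{n_samples} snapshots at \code{sample_spacing}.
#' @param sweep_param,sweep_values parameter name (\code{"N_R"},
#'   \code{"N_G"}, \code{"koff"}, \code{"D_G"}, \code{"k_gi"}, \code{"C0"})
#'   and values; \code{NULL} runs the base config only.
#' @param replicates independent runs (distinct seeds) per sweep value.
#' @param n_samples snapshots kept per run.
#' @param sample_spacing spacing between kept snapshots (s); defaults to
#'   twice the estimated encounter interval so G-protein states decorrelate.
#' @return List of class \code{steady_state_result}: \code{summary} data
#'   frame (sweep value, estimator, nsr, bound_numeric, n_samples, seeds),
#'   and \code{samples} (list of V matrices per sweep value and estimator).
#' @export
run_steady_state <- function(cfg, sweep_param = NULL, sweep_values = NULL,
                             replicates = 8, n_samples = 4,
                             sample_spacing = NULL) {
  stopifnot(inherits(cfg, "sim_config"), replicates >= 2)
  if (is.null(sweep_param)) {
    sweep_param <- ".base"; sweep_values <- NA
  }
  summary <- NULL
  samples <- list()
  for (iv in seq_along(sweep_values)) {
    cfg_i <- if (sweep_param == ".base") cfg
             else apply_sweep(cfg, sweep_param, sweep_values[iv])
    spacing <- if (is.null(sample_spacing)) {
      2 * tau_dif_calibrated(cfg_i$gradient$L, cfg_i$N_R,
                             cfg_i$kinetics$D_G, cfg_i$kinetics$r_star)
    } else sample_spacing
    cfg_i$snapshot_interval <- spacing
    cfg_i$t_end <- n_samples * spacing
    V <- list(G = NULL, C = NULL, RL = NULL, R = NULL)
    bounds <- numeric(replicates)
    seeds <- cfg$seed + 7919L * iv + seq_len(replicates)
    for (r in seq_len(replicates)) {
      cfg_i$seed <- seeds[r]
      run <- run_simulation(cfg_i)
      for (est in names(V))
        V[[est]] <- rbind(V[[est]], snapshot_vectors(run, est))
      bounds[r] <- fisher_information(run$final_state$receptor_positions,
                                      cfg_i$gradient, cfg_i$kinetics$Kd)$bound
    }
    for (est in names(V)) {
      # sign flip for -V_R leaves the NSR unchanged (cov and ||mean|| both do)
      summary <- rbind(summary, data.frame(
        sweep_param = sweep_param, sweep_value = sweep_values[iv],
        estimator = est, nsr = noise_to_signal(V[[est]]),
        bound_numeric = mean(bounds), n_samples = nrow(V[[est]]),
        seed_first = seeds[1], seed_last = seeds[replicates]))
    }
    samples[[as.character(sweep_values[iv])]] <- V
  }
  structure(list(summary = summary, samples = samples, base_config = cfg),
            class = "steady_state_result")
}

# Encounter-interval estimate using the constant fitted once against
# first-encounter simulations at the default geometry (L = 2.5 um,
# r* = 0.01 um, dt = 0.02 s); stable to ~10% over N_R in [188, 6000].
tau_dif_calibrated <- function(L, N_R, D_G, r_star) {
  tau_dif_estimate(L, N_R, D_G, r_star, const = 2.5)
}

#' Gradient-flip adaptation experiment
#'
#' Runs replicate simulations in which the gradient direction is reversed
#' (theta to -theta) at \code{flip_time}; the per-time-point mean of V_G
#' across replicates is normalized into an averaged direction trace, and
#' the time to adapt is the interval after the flip until that trace
#' crosses 90 degrees toward the new direction.  The steady-state NSR is
#' computed from the pre-flip snapshots.
#'
#' @param cfg base [sim_config()] (ratiometric in the standard protocol).
#' @param flip_time absolute reversal time (s); must exceed the burn-in.
#' @param post_flip_time how long to follow the trace after the flip (s).
#' @param replicates independent runs averaged into the direction trace.
#' @param sweep_param,sweep_values optional parameter sweep as in
#'   [run_steady_state()].
#' @return List of class \code{flip_result}: \code{summary} data frame
#'   (sweep value, adapt_time, nsr_steady, replicates), and \code{traces}
#'   (per sweep value: time, mean-direction matrix, angular error to the
#'   new direction).
#' @export
run_flip <- function(cfg, flip_time = NULL, post_flip_time = 600,
                     replicates = 6, sweep_param = NULL,
                     sweep_values = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(sweep_param)) {
    sweep_param <- ".base"; sweep_values <- NA
  }
  summary <- NULL
  traces <- list()
  for (iv in seq_along(sweep_values)) {
    cfg_i <- if (sweep_param == ".base") cfg
             else apply_sweep(cfg, sweep_param, sweep_values[iv])
    tdif <- tau_dif_calibrated(cfg_i$gradient$L, cfg_i$N_R,
                               cfg_i$kinetics$D_G, cfg_i$kinetics$r_star)
    pre <- max(4 * tdif, 100)
    ft <- if (is.null(flip_time)) cfg_i$burn_in + pre else flip_time
    cfg_i$t_end <- (ft - cfg_i$burn_in) + post_flip_time
    seeds <- cfg$seed + 104729L * iv + seq_len(replicates)
    sumV <- NULL
    preV <- NULL
    tt <- NULL
    for (r in seq_len(replicates)) {
      cfg_i$seed <- seeds[r]
      run <- run_simulation(cfg_i, flip_time = ft)
      vg <- snapshot_vectors(run, "G")
      if (is.null(sumV)) {
        sumV <- vg
        tt <- run$snapshots$t
      } else sumV <- sumV + vg
      keep <- run$snapshots$t <= ft - 2 * tdif
      sel <- which(keep)
      sel <- sel[seq(1, length(sel),
                     by = max(1, round(2 * tdif / cfg_i$snapshot_interval)))]
      preV <- rbind(preV, vg[sel, , drop = FALSE])
    }
    meanV <- sumV / replicates
    new_theta <- -cfg_i$gradient$theta
    adapt <- time_to_adapt(tt, meanV, ft, new_theta)
    nsr <- if (nrow(preV) >= 2) noise_to_signal(preV) else NA_real_
    summary <- rbind(summary, data.frame(
      sweep_param = sweep_param, sweep_value = sweep_values[iv],
      flip_time = ft, adapt_time = adapt, nsr_steady = nsr,
      replicates = replicates, seed_first = seeds[1]))
    traces[[as.character(sweep_values[iv])]] <-
      list(t = tt, mean_V = meanV,
           angular_error = angular_error(meanV, new_theta))
  }
  structure(list(summary = summary, traces = traces, base_config = cfg),
            class = "flip_result")
}

#' Latitude-binned active G fraction versus receptor occupancy
#'
#' Runs replicate simulations to steady state and bins the final G proteins
#' by their position along the gradient axis (u = x . theta / L).  In
#' ratiometric mode the binned active fraction tracks the binned equilibrium
#' receptor occupancy p_R(u) (local unbiasedness); in classical mode it
#' follows the flatter dose-response p_R E[N] / (1 + p_R E[N]).
#'
#' @param cfg a [sim_config()].
#' @param replicates independent runs pooled into the bins.
#' @param nbins number of equal-width bins in u.
#' @return Data frame: \code{u_mid}, \code{n} (G proteins in bin),
#'   \code{frac_active} (observed), \code{p_R} (mean equilibrium occupancy
#'   of the bin's G positions), \code{se} (binomial-scale standard error of
#'   \code{frac_active}).
#' @export
run_binned_activity <- function(cfg, replicates = 6, nbins = 6) {
  stopifnot(inherits(cfg, "sim_config"), replicates >= 1)
  cfg_i <- cfg
  cfg_i$t_end <- cfg$snapshot_interval
  u <- numeric(0); act <- integer(0)
  for (r in seq_len(replicates)) {
    cfg_i$seed <- cfg$seed + r
    run <- run_simulation(cfg_i)
    st <- run$final_state
    u <- c(u, as.numeric(st$g_positions %*% cfg$gradient$theta) /
             cfg$gradient$L)
    act <- c(act, st$g_active)
  }
  edges <- seq(-1, 1, length.out = nbins + 1)
  bin <- cut(u, edges, include.lowest = TRUE)
  pR <- receptor_occupancy(cfg$gradient$C0 * (1 + cfg$gradient$b * u),
                           cfg$kinetics$Kd)
  n <- as.numeric(table(bin))
  frac <- as.numeric(tapply(act, bin, mean))
  data.frame(u_mid = (edges[-1] + edges[-(nbins + 1)]) / 2, n = n,
             frac_active = frac,
             p_R = as.numeric(tapply(pR, bin, mean)),
             se = sqrt(pmax(frac * (1 - frac), 1e-6) / pmax(n, 1)))
}

#' Write small seeded fixture files for the test suite
#'
#' Regeneration with the same seed is bit-identical.
#'
#' @param kind one of \code{"receptor_placement"}, \code{"snapshot_series"},
#'   \code{"reduced_trace"}.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return Path(s) of the files written, invisibly.
#' @export
generate_fixture <- function(kind = c("receptor_placement",
                                      "snapshot_series", "reduced_trace"),
                             seed = 1L, dir = tempdir()) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (kind == "receptor_placement") {
    set.seed(seed)
    pos <- sample_uniform_sphere(50, 2.5)
    path <- file.path(dir, "receptor_placement.csv")
    write.csv(as.data.frame(pos), path, row.names = FALSE)
  } else if (kind == "snapshot_series") {
    cfg <- sim_config(N_R = 60, N_G = 120, t_end = 10, burn_in = 2,
                      snapshot_interval = 1, seed = seed)
    run <- run_simulation(cfg)
    path <- file.path(dir, "snapshot_series.csv")
    write_snapshot_series(run, path)
    path <- c(path, paste0(path, ".json"))
  } else {
    cfg <- reduced_config(n = 10, t_end = 400, seed = seed)
    tr <- simulate_reduced(cfg)
    path <- file.path(dir, "reduced_trace.csv")
    write.csv(data.frame(t = tr$times, A_n = tr$A_n,
                         receptor_state = tr$receptor_state),
              path, row.names = FALSE)
  }
  invisible(path)
}
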