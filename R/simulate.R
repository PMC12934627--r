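# Full membrane simulation driver and the SnapshotSeries container.

snap_cols <- c("t", "VRLx", "VRLy", "VRLz", "VRx", "VRy", "VRz",
               "VCx", "VCy", "VCz", "VGx", "VGy", "VGz",
               "frac_R_active", "frac_G_active")

# Run the compiled engine over one constant-gradient stretch, carrying a
# membrane_state in and out.  Snapshots are recorded for step > skip_steps.
run_segment <- function(state, cfg, conc, nsteps, snap_every, skip_steps = 0,
                        record_ages = FALSE, theta_sign = 1) {
  mode_code <- if (cfg$mode == "classical") 1L else 0L
  k <- cfg$kinetics
  res <- sim_segment_cpp(state$receptor_positions, state$receptor_active,
                         state$g_positions, state$g_active, conc,
                         k$kon, k$koff,
                         if (is.na(k$k_gi)) 0 else k$k_gi,
                         k$D_G, k$r_star, cfg$gradient$L, cfg$dt,
                         as.integer(nsteps), as.integer(snap_every),
                         as.integer(skip_steps), mode_code, record_ages,
                         state$time)
  gpos <- res$g_positions
  attr(gpos, "L") <- cfg$gradient$L
  colnames(gpos) <- c("x", "y", "z")
  new_state <- membrane_state(state$receptor_positions, res$receptor_active,
                              gpos, res$g_active, time = res$t_end)
  snaps <- as.data.frame(res$snapshots)
  names(snaps) <- snap_cols
  if (any(!is.finite(as.matrix(snaps[, 2:13]))))
    stop("internal error: non-finite resultant vector in snapshots")
  list(snapshots = snaps, state = new_state, ages = res$ages)
}

#' Run a full membrane simulation
#'
#' Initializes receptor and G-protein positions and states from \code{cfg},
#' steps the system with the cycle diffuse G -> update receptors -> resolve
#' encounters -> apply the G-state rule, discards \code{burn_in}, and then
#' records, every \code{snapshot_interval}, the four resultant vectors (from
#' bound receptors V_RL, unbound receptors V_R, their difference V_C, and
#' active G proteins V_G) together with the global active fractions.  The
#' run is bit-reproducible for a fixed config and seed.
#'
#' @param cfg a [sim_config()].
#' @param flip_time optional absolute time (s, > \code{burn_in}) at which the
#'   gradient direction is reversed (theta -> -theta), for adaptation
#'   experiments.
#' @param record_ages record, at each snapshot, each G protein's time since
#'   it last touched a bound receptor (used by [calibrate_kgi()]).
#' @return An object of class \code{snapshot_series}: a list with
#'   \code{snapshots} (data frame with columns \code{t}, \code{VRLx..z},
#'   \code{VRx..z}, \code{VCx..z}, \code{VGx..z}, \code{frac_R_active},
#'   \code{frac_G_active}), \code{config}, \code{final_state}, and
#'   optionally \code{ages} (snapshot x G-protein matrix, -1 = never).
#' @examples
#' \donttest{
#' cfg <- sim_config(t_end = 50, burn_in = 20, seed = 42)
#' run <- run_simulation(cfg)
#' head(run$snapshots)
#' }
#' @export
run_simulation <- function(cfg, flip_time = NULL, record_ages = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  state <- initialize_state(cfg)
  conc <- if (cfg$N_R > 0)
    ligand_concentration(state$receptor_positions, cfg$gradient)
  else numeric(0)
  dt <- cfg$dt
  snap_every <- max(1L, round(cfg$snapshot_interval / dt))
  skip <- round(cfg$burn_in / dt)
  total <- skip + round(cfg$t_end / dt)

  if (is.null(flip_time)) {
    seg <- run_segment(state, cfg, conc, total, snap_every, skip,
                       record_ages)
    snaps <- seg$snapshots
    ages <- seg$ages
    state <- seg$state
  } else {
    stopifnot(flip_time > cfg$burn_in,
              flip_time < cfg$burn_in + cfg$t_end)
    n1 <- round(flip_time / dt)
    seg1 <- run_segment(state, cfg, conc, n1, snap_every, skip, record_ages)
    # reversing theta maps each receptor's concentration C0(1+u) -> C0(1-u)
    conc2 <- 2 * cfg$gradient$C0 - conc
    seg2 <- run_segment(seg1$state, cfg, conc2, total - n1, snap_every, 0,
                        record_ages)
    snaps <- rbind(seg1$snapshots, seg2$snapshots)
    ages <- if (record_ages) rbind(seg1$ages, seg2$ages) else NULL
    state <- seg2$state
  }

  out <- list(snapshots = snaps, config = cfg, final_state = state,
              flip_time = flip_time)
  if (record_ages) out$ages <- ages
  class(out) <- "snapshot_series"
  out
}

#' @export
print.snapshot_series <- function(x, ...) {
  cat(sprintf(
    "Snapshot series: %d snapshots, t in [%.1f, %.1f] s (%s mode, seed %d)\n",
    nrow(x$snapshots), min(x$snapshots$t), max(x$snapshots$t),
    x$config$mode, x$config$seed))
  if (!is.null(x$flip_time))
    cat(sprintf("  gradient flipped at t = %.1f s\n", x$flip_time))
  invisible(x)
}

#' Extract resultant-vector samples from a snapshot series
#'
#' @param x a \code{snapshot_series}.
#' @param kind which estimator: bound receptors (\code{"RL"}), unbound
#'   (\code{"R"}), combined (\code{"C"}) or active G proteins (\code{"G"}).
#' @return Matrix (snapshots x 3) of unnormalized resultant vectors.
#' @export
snapshot_vectors <- function(x, kind = c("G", "RL", "R", "C")) {
  kind <- match.arg(kind)
  cols <- paste0("V", kind, c("x", "y", "z"))
  as.matrix(x$snapshots[, cols])
}

#' Write a snapshot series to CSV with a JSON config sidecar
#'
#' @param x a \code{snapshot_series}.
#' @param path CSV output path; the sidecar is written to
#'   \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
write_snapshot_series <- function(x, path) {
  stopifnot(inherits(x, "snapshot_series"))
  write.csv(x$snapshots, path, row.names = FALSE)
  cfg <- x$config
  meta <- list(
    mode = cfg$mode, seed = cfg$seed, dt = cfg$dt, t_end = cfg$t_end,
    burn_in = cfg$burn_in, snapshot_interval = cfg$snapshot_interval,
    N_R = cfg$N_R, N_G = cfg$N_G,
    gradient = cfg$gradient[c("C0", "b", "theta", "L")],
    kinetics = unclass(cfg$kinetics), flip_time = x$flip_time)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read back a snapshot series CSV
#'
#' @param path CSV path written by [write_snapshot_series()].
#' @return Data frame of snapshots (the config sidecar is not re-attached).
#' @export
read_snapshot_series <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(identical(names(df), snap_cols))
  df
}

#' Measure the diffusive encounter interval by simulation
#'
#' Places fresh uniform G proteins on a fixed uniform receptor configuration
#' and records each G protein's first receptor-encounter time; for a
#' Poisson-like encounter process the mean first-encounter time from a
#' uniform start equals the mean encounter interval tau_dif.
#'
#' @param N_R receptor count.
#' @param n_probes number of probe G proteins.
#' @param kinetics a [kinetic_params()] (uses \code{D_G}, \code{r_star}).
#' @param L cell radius (um).
#' @param dt time step (s).
#' @param t_max censoring horizon (s); censored probes enter the estimate
#'   through the exponential tail correction.
#' @return List: \code{tau_dif} (mean, tail-corrected), \code{times} (raw
#'   first-encounter times, NA = censored), \code{frac_censored}.
#' @export
measure_tau_dif <- function(N_R, n_probes = 2000, kinetics = kinetic_params(),
                            L = 2.5, dt = 0.02, t_max = 600) {
  rpos <- sample_uniform_sphere(N_R, L)
  gpos <- sample_uniform_sphere(n_probes, L)
  times <- first_encounter_cpp(rpos, gpos, kinetics$D_G, kinetics$r_star, L,
                               dt, t_max)
  cens <- is.na(times)
  # exponential model MLE with right censoring: sum(times)/n_events
  tau <- (sum(times[!cens]) + sum(cens) * t_max) / max(1, sum(!cens))
  list(tau_dif = tau, times = times, frac_censored = mean(cens))
}
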