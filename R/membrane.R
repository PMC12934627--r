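# Domain types and elementary update rules for the membrane simulation.

#' Kinetic and interaction parameters
#'
#' Ligand binding is a telegraph process with on-rate \code{kon * C(x)} and
#' off-rate \code{koff}; the dissociation constant is \code{Kd = koff/kon}.
#' Any two of \code{kon}, \code{koff}, \code{Kd} determine the third; if all
#' three are supplied they must agree to a relative 1e-6.  \code{k_gi} is the
#' uniform G-protein inactivation rate of the classical model (unused in
#' ratiometric mode), \code{D_G} the G-protein surface diffusivity and
#' \code{r_star} the receptor interaction radius within which a G protein
#' registers an encounter.
#'
#' @param kon on-rate (1/s/nM); defaults to \code{koff/Kd}.
#' @param koff off-rate (1/s).
#' @param Kd dissociation constant (nM).
#' @param k_gi classical inactivation rate (1/s) or \code{NA}.
#' @param D_G G-protein diffusivity (um^2/s).
#' @param r_star interaction radius (um).
#' @return An object of class \code{kinetic_params}.
#' @export
kinetic_params <- function(kon = NULL, koff = 0.1, Kd = 6, k_gi = NA_real_,
                           D_G = 0.002, r_star = 0.010) {
  if (is.null(kon) && !is.null(koff) && !is.null(Kd)) kon <- koff / Kd
  if (is.null(koff)) koff <- kon * Kd
  if (is.null(Kd)) Kd <- koff / kon
  stopifnot(kon >= 0, koff >= 0, Kd >= 0, D_G >= 0, r_star > 0)
  if (kon > 0 && Kd > 0 && abs(Kd - koff / kon) / Kd >= 1e-6)
    stop("inconsistent kon, koff, Kd: Kd must equal koff/kon")
  if (!is.na(k_gi)) stopifnot(k_gi >= 0)
  structure(list(kon = kon, koff = koff, Kd = Kd, k_gi = k_gi,
                 D_G = D_G, r_star = r_star),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "Kinetics: kon = %g /s/nM, koff = %g /s, Kd = %g nM\n", x$kon, x$koff,
    x$Kd))
  cat(sprintf("  D_G = %g um^2/s, r* = %g um, k_gi = %s /s\n", x$D_G,
              x$r_star, format(x$k_gi)))
  invisible(x)
}

#' Full configuration of a membrane simulation
#'
#' @param gradient a [gradient_spec()].
#' @param kinetics a [kinetic_params()].
#' @param N_R,N_G receptor and G-protein counts.
#' @param mode \code{"ratiometric"} or \code{"classical"}.
#' @param dt time step (s).
#' @param t_end simulated time after burn-in (s).
#' @param burn_in equilibration time discarded before recording (s);
#'   \code{NULL} selects \code{max(10/lambda(C0), 5 * tau_dif_estimate)}, long
#'   enough for both receptor occupancy and the G-protein collective memory
#'   (which refreshes once per encounter interval) to decorrelate from the
#'   initial condition.
#' @param snapshot_interval recording interval (s).
#' @param seed integer seed; the simulation is bit-reproducible given the
#'   full config and seed.
#' @return An object of class \code{sim_config}.
#' @details The validator enforces \code{max(kon * Cmax, koff) * dt <= 0.2}
#'   (per-step switching probabilities stay in the linear regime),
#'   \code{4 * D_G * dt <= (L/20)^2} (tangent steps short relative to
#'   curvature) and RMS step \code{sqrt(4 * D_G * dt) <= r_star} (encounters
#'   are checked every step, so steps must not overshoot the interaction
#'   disk).
#' @export
sim_config <- function(gradient = gradient_spec(),
                       kinetics = kinetic_params(),
                       N_R = 375, N_G = 2500,
                       mode = c("ratiometric", "classical"),
                       dt = 0.02, t_end = 400, burn_in = NULL,
                       snapshot_interval = 1, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(gradient, "gradient_spec"),
            inherits(kinetics, "kinetic_params"))
  stopifnot(N_R >= 0, N_R == round(N_R), N_G >= 0, N_G == round(N_G))
  stopifnot(dt > 0, t_end > 0, snapshot_interval >= dt)
  if (mode == "classical" && (is.na(kinetics$k_gi) || kinetics$k_gi <= 0))
    stop("config field 'kinetics$k_gi': classical mode requires k_gi > 0")
  Cmax <- gradient$C0 * (1 + abs(gradient$b))
  if (max(kinetics$kon * Cmax, kinetics$koff) * dt > 0.2)
    stop("config field 'dt': max(kon*C, koff)*dt must be <= 0.2")
  if (4 * kinetics$D_G * dt > (gradient$L / 20)^2)
    stop("config field 'dt': diffusion step too large for the sphere radius")
  if (sqrt(4 * kinetics$D_G * dt) > 1.5 * kinetics$r_star)
    stop("config field 'dt': RMS diffusion step exceeds 1.5 * r_star")
  if (is.null(burn_in)) {
    lam <- switching_rate(gradient$C0, kinetics$kon, kinetics$koff)
    tdif <- if (N_R > 0 && kinetics$D_G > 0)
      tau_dif_estimate(gradient$L, N_R, kinetics$D_G, kinetics$r_star)
    else 0
    burn_in <- max(10 / lam, 5 * tdif)
  }
  stopifnot(burn_in >= 0)
  structure(list(gradient = gradient, kinetics = kinetics,
                 N_R = as.integer(N_R), N_G = as.integer(N_G), mode = mode,
                 dt = dt, t_end = t_end, burn_in = burn_in,
                 snapshot_interval = snapshot_interval,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Membrane simulation config (%s mode)\n", x$mode))
  print(x$gradient)
  print(x$kinetics)
  cat(sprintf("  N_R = %d, N_G = %d, dt = %g s, burn_in = %.1f s, t_end = %g s, seed = %d\n",
              x$N_R, x$N_G, x$dt, x$burn_in, x$t_end, x$seed))
  invisible(x)
}

#' Initialize a membrane state from a configuration
#'
#' Receptor and G-protein positions are uniform on the sphere; each
#' receptor's state is Bernoulli with its local equilibrium occupancy
#' \code{C(x)/(C(x)+Kd)} and each G protein starts active with probability
#' 1/2.
#'
#' @param cfg a [sim_config()].
#' @return An object of class \code{membrane_state} with fields
#'   \code{receptor_positions}, \code{receptor_active}, \code{g_positions},
#'   \code{g_active}, \code{time}.
#' @export
initialize_state <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rpos <- sample_uniform_sphere(cfg$N_R, cfg$gradient$L)
  gpos <- sample_uniform_sphere(cfg$N_G, cfg$gradient$L)
  p <- if (cfg$N_R > 0)
    receptor_occupancy(ligand_concentration(rpos, cfg$gradient),
                       cfg$kinetics$Kd)
  else numeric(0)
  ract <- as.integer(runif(cfg$N_R) < p)
  gact <- as.integer(runif(cfg$N_G) < 0.5)
  membrane_state(rpos, ract, gpos, gact, time = 0)
}

#' Construct a membrane state
#'
#' @param receptor_positions,g_positions point matrices on the sphere.
#' @param receptor_active,g_active binary (0/1) integer vectors.
#' @param time current simulation time (s).
#' @export
membrane_state <- function(receptor_positions, receptor_active, g_positions,
                           g_active, time = 0) {
  stopifnot(nrow(receptor_positions) == length(receptor_active),
            nrow(g_positions) == length(g_active),
            all(receptor_active %in% c(0L, 1L)),
            all(g_active %in% c(0L, 1L)))
  structure(list(receptor_positions = receptor_positions,
                 receptor_active = as.integer(receptor_active),
                 g_positions = g_positions,
                 g_active = as.integer(g_active), time = time),
            class = "membrane_state")
}

#' One telegraph update of all receptor states
#'
#' Over a step of length \code{dt}, an unbound receptor at \code{x} becomes
#' bound with probability \code{1 - exp(-kon * C(x) * dt)} and a bound one
#' unbinds with probability \code{1 - exp(-koff * dt)}, independently across
#' receptors.
#'
#' @param state a [membrane_state()].
#' @param g a [gradient_spec()].
#' @param k a [kinetic_params()].
#' @param dt time step (s); \code{max(kon * C, koff) * dt} must be <= 0.2.
#' @return The state with \code{receptor_active} updated and \code{time}
#'   advanced by \code{dt}.
#' @export
step_receptors <- function(state, g, k, dt) {
  stopifnot(inherits(state, "membrane_state"))
  n <- length(state$receptor_active)
  if (n == 0L) {
    state$time <- state$time + dt
    return(state)
  }
  C <- ligand_concentration(state$receptor_positions, g)
  if (max(k$kon * max(C), k$koff) * dt > 0.2)
    stop("dt too large: max(kon*C, koff)*dt must be <= 0.2")
  p_on <- 1 - exp(-k$kon * C * dt)
  p_off <- 1 - exp(-k$koff * dt)
  u <- runif(n)
  act <- state$receptor_active == 1L
  new <- state$receptor_active
  new[act] <- ifelse(u[act] < p_off, 0L, 1L)
  new[!act] <- ifelse(u[!act] < p_on[!act], 1L, 0L)
  state$receptor_active <- new
  state$time <- state$time + dt
  state
}

#' Pair each G protein with its nearest receptor within r*
#'
#' A G protein is paired with the nearest receptor within great-circle
#' distance \code{r_star} (ties to the lowest receptor index); several G
#' proteins may share one receptor.
#'
#' @param state a [membrane_state()].
#' @param r_star interaction radius (um), > 0.
#' @return Integer vector of length \code{N_G}: receptor index or \code{NA}.
#' @export
find_encounters <- function(state, r_star) {
  stopifnot(inherits(state, "membrane_state"), r_star > 0)
  if (length(state$g_active) == 0L) return(integer(0))
  L <- attr(state$g_positions, "L")
  if (is.null(L)) L <- sqrt(sum(state$g_positions[1, ]^2))
  if (length(state$receptor_active) == 0L)
    return(rep(NA_integer_, length(state$g_active)))
  find_encounters_cpp(state$receptor_positions, state$g_positions, r_star, L)
}

#' Ratiometric G-protein update
#'
#' Every paired G protein copies the current state of its receptor: contact
#' with a bound receptor activates, contact with an unbound receptor
#' deactivates.  Unpaired G proteins keep their state indefinitely -- this
#' persistence is the collective memory that time-averages receptor activity.
#'
#' @param state a [membrane_state()].
#' @param pairing output of [find_encounters()] on this state.
#' @return The state with \code{g_active} updated.
#' @export
update_g_ratiometric <- function(state, pairing) {
  stopifnot(inherits(state, "membrane_state"),
            length(pairing) == length(state$g_active))
  hit <- !is.na(pairing)
  state$g_active[hit] <- state$receptor_active[pairing[hit]]
  state
}

#' Classical G-protein update
#'
#' Active G proteins first decay with probability
#' \code{1 - exp(-k_gi * dt)} (spatially uniform, receptor independent);
#' then every G protein paired with a bound receptor becomes active, so a
#' collision within the step wins over decay.  Pairing with an unbound
#' receptor has no effect.
#'
#' @inheritParams update_g_ratiometric
#' @param k_gi uniform inactivation rate (1/s), > 0.
#' @param dt time step (s).
#' @return The state with \code{g_active} updated.
#' @export
update_g_classical <- function(state, pairing, k_gi, dt) {
  stopifnot(inherits(state, "membrane_state"), k_gi > 0, dt > 0,
            length(pairing) == length(state$g_active))
  n <- length(state$g_active)
  decay <- runif(n) < (1 - exp(-k_gi * dt))
  state$g_active[decay] <- 0L
  hit <- !is.na(pairing) & state$receptor_active[replace(pairing, is.na(pairing), 1L)] == 1L
  hit[is.na(pairing)] <- FALSE
  state$g_active[hit] <- 1L
  state
}
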