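# Closed-form and numerical theory: equilibrium occupancy, switching rate,
# encounter timescale, the Fisher-information Cramér-Rao bound and its
# weak-gradient form, the collective-memory variance and the classical bias.

#' Equilibrium receptor occupancy
#'
#' Probability that a receptor exposed to concentration \code{C} is ligand
#' bound at stationarity: \code{C / (C + Kd)}.
#'
#' @param C ligand concentration (nM), >= 0; vectorized.
#' @param Kd dissociation constant (nM), > 0.
#' @export
receptor_occupancy <- function(C, Kd) {
  stopifnot(all(C >= 0), Kd > 0)
  C / (C + Kd)
}

#' Total receptor switching rate
#'
#' \code{lambda = kon * C + koff}: the relaxation rate of the receptor
#' telegraph process at local concentration \code{C}.
#'
#' @param C concentration (nM); vectorized.
#' @param kon on-rate (1/s/nM).
#' @param koff off-rate (1/s).
#' @export
switching_rate <- function(C, kon, koff) {
  stopifnot(all(C >= 0), kon >= 0, koff >= 0)
  kon * C + koff
}

#' On-rate implied by koff and Kd, in molar units
#'
#' Returns \code{koff / Kd} converted from 1/s/nM to 1/s/M (factor 1e9),
#' the form usually compared with the Smoluchowski diffusion limit.
#'
#' @param koff off-rate (1/s).
#' @param Kd dissociation constant (nM), > 0.
#' @return On-rate in M^-1 s^-1.
#' @examples
#' kon_from_koff_kd(0.1, 6)  # 1.67e7 M^-1 s^-1
#' @export
kon_from_koff_kd <- function(koff, Kd) {
  stopifnot(koff >= 0, Kd > 0)
  koff / Kd * 1e9
}

#' Diffusive encounter timescale (up to a fixed constant)
#'
#' Mean time between successive G-protein--receptor encounters,
#' \code{tau_dif = const * L^2 / (N_R * D_G) * log(delta / r_star)} with
#' \code{delta = sqrt(4 * pi * L^2 / N_R)} the typical receptor spacing.
#' The proportionality constant (default 1) can be fitted once against
#' simulation with [measure_tau_dif()]; all scalings in \code{L}, \code{N_R},
#' \code{D_G} are carried by the formula itself.
#'
#' @param L cell radius (um).
#' @param N_R receptor count.
#' @param D_G G-protein diffusivity (um^2/s).
#' @param r_star interaction radius (um); must be smaller than \code{delta}.
#' @param const multiplicative constant.
#' @return Estimated encounter interval (s).
#' @export
tau_dif_estimate <- function(L, N_R, D_G, r_star, const = 1) {
  stopifnot(L > 0, N_R > 0, D_G > 0, r_star > 0, const > 0)
  delta <- sqrt(4 * pi * L^2 / N_R)
  if (delta <= r_star)
    stop("invalid regime: receptor spacing delta <= r_star ",
         "(interaction disks overlap)")
  const * L^2 / (N_R * D_G) * log(delta / r_star)
}

#' Weak-gradient Cramér-Rao bound on the direction NSR
#'
#' Small-\code{b} closed form of the instantaneous-receptor information
#' bound: \code{NSR >= 6 / (N_R b^2) * (C0 + Kd)^2 / (Kd * C0)}.  Minimized
#' over \code{C0} at \code{C0 = Kd}, where it equals \code{24 / (N_R b^2)}.
#'
#' @param N_R receptor count.
#' @param b gradient steepness.
#' @param C0 mid-point concentration (nM).
#' @param Kd dissociation constant (nM).
#' @export
weak_signal_bound <- function(N_R, b, C0, Kd) {
  stopifnot(N_R > 0, b != 0, C0 > 0, Kd > 0)
  6 / (N_R * b^2) * (C0 + Kd)^2 / (Kd * C0)
}

#' Fisher information and Cramér-Rao bound for a receptor snapshot
#'
#' Receptor states are independent Bernoulli with
#' \code{p_i = C(x_i)/(C(x_i)+Kd)}.  The gradient direction has two degrees
#' of freedom, parameterized in an orthonormal tangent basis at
#' \code{theta}; the 2x2 information matrix is
#' \code{I = sum_i grad(p_i) grad(p_i)^T / (p_i (1 - p_i))} with
#' \code{grad_a(p_i) = dp/dC * C0 * b * (x_i . e_a) / L}, and the bound on
#' the noise-to-signal ratio is \code{trace(I^-1)}.  The bound is invariant
#' under joint rotation of receptors and \code{theta}.
#'
#' @param receptor_positions \code{N_R x 3} matrix on the sphere.
#' @param g a [gradient_spec()] (requires \code{b != 0}).
#' @param Kd dissociation constant (nM).
#' @return A list of class \code{fisher_bound}: \code{info_matrix} (2x2),
#'   \code{bound} (= trace of the inverse), \code{weak_signal_bound} (the
#'   small-b closed form at the same parameters), \code{basis} (the tangent
#'   vectors used).
#' @export
fisher_information <- function(receptor_positions, g, Kd) {
  stopifnot(inherits(g, "gradient_spec"), g$b != 0, Kd > 0)
  x <- receptor_positions
  stopifnot(is.matrix(x), ncol(x) == 3, nrow(x) >= 3)
  e <- tangent_basis(g$theta)
  C <- as.numeric(g$C0 * (1 + g$b * (x %*% g$theta) / g$L))
  p <- C / (C + Kd)
  dpdC <- Kd / (C + Kd)^2
  # gradient of p_i w.r.t. theta, projected on the tangent plane
  g1 <- dpdC * g$C0 * g$b * as.numeric(x %*% e[, 1]) / g$L
  g2 <- dpdC * g$C0 * g$b * as.numeric(x %*% e[, 2]) / g$L
  w <- 1 / (p * (1 - p))
  info <- matrix(c(sum(w * g1 * g1), sum(w * g1 * g2),
                   sum(w * g1 * g2), sum(w * g2 * g2)), 2, 2)
  inv <- tryCatch(solve(info), error = function(e)
    stop("singular information matrix (degenerate receptor placement)"))
  structure(list(info_matrix = info, bound = sum(diag(inv)),
                 weak_signal_bound = weak_signal_bound(nrow(x), g$b, g$C0, Kd),
                 basis = e),
            class = "fisher_bound")
}

# Two orthonormal tangent vectors at unit vector theta.
tangent_basis <- function(theta) {
  u <- if (abs(theta[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(u[2] * theta[3] - u[3] * theta[2],
          u[3] * theta[1] - u[1] * theta[3],
          u[1] * theta[2] - u[2] * theta[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(theta[2] * e1[3] - theta[3] * e1[2],
          theta[3] * e1[1] - theta[1] * e1[3],
          theta[1] * e1[2] - theta[2] * e1[1])
  cbind(e1, e2)
}

#' Stationary variance of the collective G-protein average
#'
#' For \code{n} G proteins sampling one telegraph receptor with occupancy
#' \code{p_R}, switching rate \code{lambda} and mean encounter interval
#' \code{tau_dif}, the stationary variance of the active fraction is
#' \code{p_R (1 - p_R) * (1/n + (1 - 1/n) / (1 + lambda * tau_dif))}.
#' Larger \code{lambda * tau_dif} decorrelates successive samples and drives
#' the variance toward the independent-sample limit \code{p_R(1-p_R)/n}.
#'
#' @param p_R receptor occupancy between 0 and 1.
#' @param n number of G proteins, >= 1.
#' @param lambda receptor switching rate (1/s).
#' @param tau_dif mean encounter interval (s).
#' @export
collective_variance <- function(p_R, n, lambda, tau_dif) {
  stopifnot(all(p_R >= 0 & p_R <= 1), all(n >= 1), all(lambda > 0),
            all(tau_dif > 0))
  p_R * (1 - p_R) * (1 / n + (1 - 1 / n) / (1 + lambda * tau_dif))
}

#' Classical-model dose-response bias
#'
#' Approximate stationary active probability of a classical G protein at a
#' membrane position with receptor occupancy \code{p_R}:
#' \code{p_Gc = p_R E[N] / (1 + p_R E[N])}, where \code{E[N] =
#' tau_off / tau_dif} is the mean number of receptor encounters per decay
#' time.  Unless tuned, \code{p_Gc != p_R}, and the spatial profile of
#' \code{p_Gc} is flatter than that of \code{p_R} -- the origin of the
#' classical model's loss of directional accuracy.
#'
#' @param p_R receptor occupancy between 0 and 1; vectorized.
#' @param E_N mean encounters per classical reset, >= 0.
#' @export
classical_bias <- function(p_R, E_N) {
  stopifnot(all(p_R >= 0 & p_R <= 1), all(E_N >= 0))
  p_R * E_N / (1 + p_R * E_N)
}
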