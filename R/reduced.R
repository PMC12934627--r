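# Reduced single-receptor model: one telegraph receptor, n G proteins
# encountering it at exponential intervals, simulated event-by-event
# (exact), plus an exact continuous-time Markov chain solver used as an
# oracle for the collective-variance and classical-bias formulas.

#' Configuration of the reduced single-receptor model
#'
#' @param n number of G proteins (>= 1).
#' @param C ligand concentration at the receptor (nM).
#' @param kon,koff receptor binding rates (1/s/nM, 1/s).
#' @param tau_dif mean encounter interval per G protein (s); encounter
#'   intervals are exponential (renewal assumption).
#' @param mode \code{"ratiometric"} (G copies the receptor state on contact)
#'   or \code{"classical"} (G activates on contact with a bound receptor and
#'   decays at \code{k_gi}).
#' @param k_gi classical decay rate (1/s); required in classical mode.
#' @param t_end total simulated time (s).
#' @param seed integer seed.
#' @export
reduced_config <- function(n = 25, C = 6, kon = 0.1 / 6, koff = 0.1,
                           tau_dif = 5, mode = c("ratiometric", "classical"),
                           k_gi = NA_real_, t_end = 5000, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n >= 1, n == round(n), C >= 0, kon >= 0, koff >= 0,
            tau_dif > 0, t_end > 0)
  if (mode == "classical" && (is.na(k_gi) || k_gi <= 0))
    stop("classical mode requires k_gi > 0")
  structure(list(n = as.integer(n), C = C, kon = kon, koff = koff,
                 tau_dif = tau_dif, mode = mode, k_gi = k_gi,
                 t_end = t_end, seed = as.integer(seed)),
            class = "reduced_config")
}

#' Event-driven simulation of the reduced model
#'
#' Exact stochastic simulation (no time discretization): the receptor flips
#' on at rate \code{kon * C} and off at rate \code{koff}; each of the
#' \code{n} G proteins independently encounters the receptor at exponential
#' intervals with mean \code{tau_dif}; in ratiometric mode an encountering G
#' protein copies the receptor state, in classical mode it activates only if
#' the receptor is bound and each active G protein decays at rate
#' \code{k_gi}.  The receptor starts at its equilibrium occupancy, G
#' proteins at Bernoulli(occupancy).
#'
#' @param cfg a [reduced_config()].
#' @return An object of class \code{reduced_trace}: data frame-like list
#'   with \code{times} (event times, s), \code{A_n} (active G fraction after
#'   the event), \code{receptor_state} (0/1), plus \code{n} and the config.
#' @export
simulate_reduced <- function(cfg) {
  stopifnot(inherits(cfg, "reduced_config"))
  set.seed(cfg$seed)
  n <- cfg$n
  r_on <- cfg$kon * cfg$C
  r_enc <- n / cfg$tau_dif
  p_eq <- if (r_on + cfg$koff > 0) r_on / (r_on + cfg$koff) else 0
  s <- rbinom(1, 1, p_eq)
  k <- rbinom(1, n, p_eq)
  classical <- cfg$mode == "classical"

  cap <- 1024L
  times <- numeric(cap); A <- numeric(cap); rs <- integer(cap)
  m <- 0L
  t <- 0
  while (t < cfg$t_end) {
    r_flip <- if (s == 1L) cfg$koff else r_on
    r_dec <- if (classical) k * cfg$k_gi else 0
    rtot <- r_flip + r_enc + r_dec
    t <- t + rexp(1, rtot)
    if (t >= cfg$t_end) break
    u <- runif(1) * rtot
    if (u < r_flip) {
      s <- 1L - s
    } else if (u < r_flip + r_enc) {
      # a uniformly chosen G protein meets the receptor
      g_active <- runif(1) < k / n
      if (classical) {
        if (s == 1L && !g_active) k <- k + 1L
      } else {
        if (s == 1L && !g_active) k <- k + 1L
        if (s == 0L && g_active) k <- k - 1L
      }
    } else {
      k <- k - 1L  # classical decay of one active G
    }
    m <- m + 1L
    if (m > cap) {
      cap <- cap * 2L
      length(times) <- cap; length(A) <- cap; length(rs) <- cap
    }
    times[m] <- t; A[m] <- k / n; rs[m] <- s
  }
  structure(list(times = times[seq_len(m)], A_n = A[seq_len(m)],
                 receptor_state = rs[seq_len(m)], n = n, config = cfg),
            class = "reduced_trace")
}

#' @export
print.reduced_trace <- function(x, ...) {
  cat(sprintf("Reduced-model trace: %d events over %.0f s (%s, n = %d)\n",
              length(x$times), x$config$t_end, x$config$mode, x$n))
  invisible(x)
}

#' Time-weighted stationary moments of a reduced trace
#'
#' Each recorded value of the active fraction holds until the next event, so
#' moments are weighted by holding times.  A standard error for the mean is
#' estimated by batch means.
#'
#' @param trace a \code{reduced_trace}.
#' @param burn_in initial time span to discard (s).
#' @param n_batches batch count for the batch-means standard errors.
#' @return List: \code{mean}, \code{variance}, \code{se_mean},
#'   \code{se_variance}.
#' @export
reduced_moments <- function(trace, burn_in = 0, n_batches = 20) {
  stopifnot(inherits(trace, "reduced_trace"))
  t_end <- trace$config$t_end
  tt <- c(trace$times, t_end)
  keep <- trace$times >= burn_in
  t0 <- c(trace$times[keep], t_end)
  a <- trace$A_n[keep]
  w <- diff(t0)
  W <- sum(w)
  mu <- sum(w * a) / W
  v <- sum(w * (a - mu)^2) / W
  # batch means over equal time spans
  edges <- seq(burn_in, t_end, length.out = n_batches + 1)
  bi <- findInterval(t0[-length(t0)], edges, rightmost.closed = TRUE)
  bm <- tapply(w * a, bi, sum) / tapply(w, bi, sum)
  bv <- tapply(w * (a - mu)^2, bi, sum) / tapply(w, bi, sum)
  list(mean = mu, variance = v,
       se_mean = sd(bm) / sqrt(length(bm)),
       se_variance = sd(bv) / sqrt(length(bv)))
}

#' Exact stationary moments of the reduced model
#'
#' Builds the continuous-time generator over states (receptor state, number
#' of active G proteins) -- by exchangeability of the G proteins the count is
#' a sufficient statistic -- and solves the stationary distribution by linear
#' algebra.  Serves as an independent oracle for the collective-variance and
#' classical-bias formulas.
#'
#' @param n G-protein count (small; state space is 2(n+1)).
#' @param p_R receptor occupancy in (0, 1).
#' @param lambda receptor switching rate (1/s).
#' @param tau_dif mean encounter interval (s).
#' @param mode \code{"ratiometric"} or \code{"classical"}.
#' @param k_gi classical decay rate (1/s).
#' @return List: \code{mean} and \code{variance} of the stationary active
#'   fraction, and the full stationary distribution \code{pi} (matrix
#'   2 x (n+1): receptor state by active count).
#' @export
exact_reduced_stationary <- function(n, p_R, lambda, tau_dif,
                                     mode = c("ratiometric", "classical"),
                                     k_gi = NA_real_) {
  mode <- match.arg(mode)
  stopifnot(n >= 1, n == round(n), p_R > 0, p_R <= 1, lambda > 0,
            tau_dif > 0)
  if (mode == "classical") stopifnot(!is.na(k_gi), k_gi > 0)
  n <- as.integer(n)
  r_on <- lambda * p_R       # receptor 0 -> 1
  r_off <- lambda * (1 - p_R)
  nstate <- 2L * (n + 1L)
  idx <- function(s, k) s * (n + 1L) + k + 1L
  Q <- matrix(0, nstate, nstate)
  for (s in 0:1) for (k in 0:n) {
    i <- idx(s, k)
    if (s == 0L) Q[i, idx(1L, k)] <- Q[i, idx(1L, k)] + r_on
    else Q[i, idx(0L, k)] <- Q[i, idx(0L, k)] + r_off
    if (mode == "ratiometric") {
      if (s == 1L && k < n) Q[i, idx(s, k + 1L)] <- (n - k) / tau_dif
      if (s == 0L && k > 0) Q[i, idx(s, k - 1L)] <- k / tau_dif
    } else {
      if (s == 1L && k < n) Q[i, idx(s, k + 1L)] <- (n - k) / tau_dif
      if (k > 0) Q[i, idx(s, k - 1L)] <- Q[i, idx(s, k - 1L)] + k * k_gi
    }
  }
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, nstate))
  b <- c(rep(0, nstate), 1)
  pi_vec <- tryCatch(as.numeric(qr.solve(A, b)),
                     error = function(e) stop("singular generator"))
  # states enumerated as idx(s,k): k fastest within s
  fr <- c((0:n) / n, (0:n) / n)
  mu <- sum(pi_vec * fr)
  v <- sum(pi_vec * fr^2) - mu^2
  list(mean = mu, variance = v,
       pi = matrix(pi_vec, nrow = 2, byrow = TRUE,
                   dimnames = list(receptor = c("off", "on"), active = 0:n)))
}

#' Mean encounters per classical reset
#'
#' \code{E[N] = tau_off / tau_dif}: the expected number of receptor
#' encounters a classical G protein makes during one decay time
#' \code{tau_off = 1/k_gi}.
#'
#' @param tau_off classical decay time (s).
#' @param tau_dif mean encounter interval (s).
#' @export
mean_encounters <- function(tau_off, tau_dif) {
  stopifnot(all(tau_off > 0), all(tau_dif > 0))
  tau_off / tau_dif
}
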