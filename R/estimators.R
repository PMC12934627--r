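# Direction estimators from particle states, and the accuracy and
# adaptation metrics built on them.

#' Resultant vector over particles in a chosen state
#'
#' Sum of the position vectors (from the cell center) of all particles in
#' the selected state.  \code{V_RL} is the resultant of bound receptors,
#' \code{V_R} of unbound receptors and \code{V_G} of active G proteins; each
#' points toward where the selected particles concentrate.
#'
#' @param points \code{n x 3} matrix of particle positions.
#' @param active binary (0/1) vector of length \code{n}.
#' @param select sum over \code{"active"} or \code{"inactive"} particles.
#' @return A 3-vector; the zero vector when no particle is selected.
#' @export
resultant_vector <- function(points, active, select = c("active", "inactive")) {
  select <- match.arg(select)
  stopifnot(is.matrix(points), ncol(points) == 3,
            nrow(points) == length(active), all(active %in% c(0L, 1L)))
  keep <- if (select == "active") active == 1L else active == 0L
  if (!any(keep)) return(c(0, 0, 0))
  colSums(points[keep, , drop = FALSE])
}

#' Combined receptor vector
#'
#' \code{V_C = V_RL - V_R}: bound receptors vote toward high concentration,
#' unbound receptors vote away from low concentration, and the difference
#' pools both.
#'
#' @param V_RL,V_R 3-vectors.
#' @export
combined_vector <- function(V_RL, V_R) {
  stopifnot(length(V_RL) == 3, length(V_R) == 3)
  V_RL - V_R
}

#' Angular error of a direction estimate (degrees)
#'
#' Angle between \code{V} and the true gradient direction \code{theta}, in
#' the 0 to 180 degree range.  For the unbound-receptor estimator, pass \code{-V_R}
#' (its direction estimate is the flipped resultant).
#'
#' @param V a 3-vector (or \code{n x 3} matrix) with non-zero norm(s).
#' @param theta unit 3-vector.
#' @export
angular_error <- function(V, theta) {
  stopifnot(length(theta) == 3)
  theta <- theta / sqrt(sum(theta^2))
  if (is.null(dim(V))) V <- matrix(V, ncol = 3)
  nrm <- sqrt(rowSums(V^2))
  if (any(nrm == 0)) stop("undefined direction: zero resultant vector")
  ct <- as.numeric(V %*% theta) / nrm
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' Empirical CDF of angular errors
#'
#' Standard right-continuous ECDF over the 0 to 180 degree range.  The reference
#' distribution of a direction chosen uniformly at random on the sphere has
#' CDF \code{(1 - cos(alpha))/2}, available as [uniform_angular_cdf()] for
#' baseline comparison.
#'
#' @param errors non-empty numeric vector of angular errors (degrees).
#' @return A function of class \code{ecdf}.
#' @export
empirical_cdf <- function(errors) {
  stopifnot(length(errors) >= 1, all(errors >= 0 & errors <= 180))
  ecdf(errors)
}

#' @rdname empirical_cdf
#' @param alpha angle(s) in degrees.
#' @export
uniform_angular_cdf <- function(alpha) {
  stopifnot(all(alpha >= 0 & alpha <= 180))
  (1 - cos(alpha * pi / 180)) / 2
}

#' Noise-to-signal ratio of a direction estimator
#'
#' For replicate samples of the unnormalized resultant vector \code{V},
#' \code{NSR = trace(Cov(V)) / ||E(V)||^2}: total fluctuation power around
#' the mean vector, relative to the squared signal.  Samples should be
#' independent realizations (independent seeds, or snapshots spaced by well
#' over the decorrelation time).
#'
#' @param samples \code{m x 3} matrix of resultant vectors, \code{m >= 2}.
#' @return Dimensionless NSR >= 0.
#' @export
noise_to_signal <- function(samples) {
  stopifnot(is.matrix(samples), ncol(samples) == 3, nrow(samples) >= 2)
  mu <- colMeans(samples)
  m2 <- sum(mu^2)
  if (m2 == 0) stop("undefined NSR: zero mean vector")
  sum(diag(cov(samples))) / m2
}

#' Summary statistics of a direction estimator
#'
#' Bundles the accuracy metrics for a set of replicate resultant vectors:
#' the NSR, the mean vector, the angular errors against the true direction
#' and their ECDF.
#'
#' @param samples \code{m x 3} matrix of resultant vectors (replicates).
#' @param theta true gradient direction (unit 3-vector).
#' @return An object of class \code{direction_stats}: \code{nsr},
#'   \code{mean_vector}, \code{angular_errors} (degrees), \code{cdf}
#'   (an \code{ecdf} function), \code{n_samples}.
#' @export
direction_stats <- function(samples, theta) {
  stopifnot(is.matrix(samples), ncol(samples) == 3, nrow(samples) >= 2)
  ok <- rowSums(samples^2) > 0
  errs <- angular_error(samples[ok, , drop = FALSE], theta)
  structure(list(nsr = noise_to_signal(samples),
                 mean_vector = colMeans(samples),
                 angular_errors = errs, cdf = empirical_cdf(errs),
                 n_samples = nrow(samples)),
            class = "direction_stats")
}

#' @export
print.direction_stats <- function(x, ...) {
  cat(sprintf("Direction stats over %d samples: NSR = %.4g, median error = %.1f deg\n",
              x$n_samples, x$nsr, stats::median(x$angular_errors)))
  invisible(x)
}

#' Serialize direction statistics
#'
#' Writes a JSON summary (\code{nsr}, \code{n_samples}, \code{mean_vector})
#' and a CSV with the angular-error samples and a CDF grid over
#' the 0 to 180 degree range.
#'
#' @param x a [direction_stats()] object.
#' @param path base path; writes \code{<path>.json} (summary),
#'   \code{<path>_errors.csv} (angular-error samples) and
#'   \code{<path>_cdf.csv} (CDF on a 1-degree grid, with the
#'   uniform-direction reference).
#' @return The paths written, invisibly.
#' @export
write_direction_stats <- function(x, path) {
  stopifnot(inherits(x, "direction_stats"))
  jsonlite::write_json(list(nsr = x$nsr, n_samples = x$n_samples,
                            mean_vector = x$mean_vector),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(angular_error_deg = x$angular_errors),
            paste0(path, "_errors.csv"), row.names = FALSE)
  grid <- seq(0, 180, by = 1)
  write.csv(data.frame(alpha_deg = grid, cdf = x$cdf(grid),
                       cdf_uniform = uniform_angular_cdf(grid)),
            paste0(path, "_cdf.csv"), row.names = FALSE)
  invisible(paste0(path, c(".json", "_errors.csv", "_cdf.csv")))
}

#' Adaptation time after a gradient reversal
#'
#' Given the across-replicate averaged direction trace, the time to adapt is
#' the first time after \code{flip_time} at which the angular error with
#' respect to the new gradient direction drops below 90 degrees, minus
#' \code{flip_time}.
#'
#' @param times increasing time stamps (s).
#' @param directions \code{length(times) x 3} matrix of (mean) direction
#'   vectors.
#' @param flip_time reversal time (s); the trace must extend beyond it.
#' @param new_theta unit 3-vector of the post-flip gradient direction.
#' @return Adaptation time in seconds, or \code{NA} (never crossed).
#' @export
time_to_adapt <- function(times, directions, flip_time, new_theta) {
  stopifnot(length(times) == nrow(directions), max(times) > flip_time)
  post <- times > flip_time
  err <- angular_error(directions[post, , drop = FALSE], new_theta)
  hit <- which(err < 90)
  if (!length(hit)) return(NA_real_)
  times[post][hit[1]] - flip_time
}
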