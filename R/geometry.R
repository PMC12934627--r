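# Sphere geometry, uniform surface sampling, surface Brownian motion and the
# linear ligand field.

#' Specify a linear ligand gradient across a spherical cell
#'
#' The concentration field is \eqn{C(x) = C_0 (1 + b \, (x \cdot \theta)/L)}
#' for points \eqn{x} on the sphere of radius \eqn{L}: \code{C0} is the
#' concentration at the equator (the sphere-average), \code{b} the
#' dimensionless steepness (front-to-back range \eqn{C_0(1 \pm b)}), and
#' \code{theta} the unit vector pointing up-gradient.
#'
#' @param C0 mid-point ligand concentration (nM), > 0.
#' @param b dimensionless gradient steepness, |b| < 1 so that the
#'   concentration stays positive everywhere on the sphere.
#' @param theta gradient direction; any non-zero 3-vector, normalized
#'   internally.
#' @param L cell radius (um).
#' @return An object of class \code{gradient_spec}.
#' @examples
#' g <- gradient_spec(C0 = 6, b = 0.33, theta = c(1, 0, 0), L = 2.5)
#' ligand_concentration(c(2.5, 0, 0), g)  # front of the cell
#' @export
gradient_spec <- function(C0 = 6, b = 0.33, theta = c(1, 0, 0), L = 2.5) {
  stopifnot(is.numeric(C0), length(C0) == 1L, C0 > 0)
  stopifnot(is.numeric(b), length(b) == 1L, abs(b) < 1)
  stopifnot(is.numeric(L), length(L) == 1L, L > 0)
  stopifnot(is.numeric(theta), length(theta) == 3L, all(is.finite(theta)))
  nrm <- sqrt(sum(theta^2))
  if (nrm == 0) stop("theta must be a non-zero direction vector")
  structure(list(C0 = C0, b = b, theta = theta / nrm, L = L),
            class = "gradient_spec")
}

#' @export
print.gradient_spec <- function(x, ...) {
  cat(sprintf("Linear gradient: C0 = %g nM, b = %g, L = %g um\n",
              x$C0, x$b, x$L))
  cat(sprintf("  direction theta = (%.4f, %.4f, %.4f)\n",
              x$theta[1], x$theta[2], x$theta[3]))
  invisible(x)
}

#' Sample points uniformly on a sphere
#'
#' Uniformity is exact: standard-normal 3-vectors are normalized to radius
#' \code{L}, which is rotation invariant and branch free.
#'
#' @param n number of points (>= 0).
#' @param L sphere radius (um), > 0.
#' @return An \code{n x 3} matrix of Cartesian coordinates with
#'   \code{attr(, "L")} set; every row has norm \code{L}.
#' @export
sample_uniform_sphere <- function(n, L = 2.5) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0, n == round(n))
  stopifnot(is.numeric(L), length(L) == 1L, L > 0)
  n <- as.integer(n)
  if (n == 0L) {
    pts <- matrix(numeric(0), nrow = 0, ncol = 3)
  } else {
    z <- matrix(rnorm(3L * n), ncol = 3)
    pts <- z * (L / sqrt(rowSums(z^2)))
  }
  colnames(pts) <- c("x", "y", "z")
  attr(pts, "L") <- L
  pts
}

#' Evaluate the ligand concentration at membrane points
#'
#' @param x a 3-vector or an \code{n x 3} matrix of points on the sphere of
#'   radius \code{g$L} (checked to a relative tolerance of 1e-6).
#' @param g a [gradient_spec()].
#' @return Concentration(s) in nM; strictly positive whenever |b| < 1.
#' @export
ligand_concentration <- function(x, g) {
  stopifnot(inherits(g, "gradient_spec"))
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  stopifnot(ncol(x) == 3)
  r <- sqrt(rowSums(x^2))
  if (any(abs(r - g$L) > 1e-6 * g$L))
    stop("point(s) not on the sphere of radius L")
  as.numeric(g$C0 * (1 + g$b * (x %*% g$theta) / g$L))
}

#' One Brownian step on the sphere surface
#'
#' Each point takes an isotropic Gaussian step in its tangent plane with
#' per-axis variance \code{2 * D * dt} (so the expected squared displacement
#' is \code{4 * D * dt}) and is re-projected to radius \code{L}.  Accurate to
#' O(dt) when the RMS step is much smaller than \code{L}.
#'
#' @param points \code{n x 3} matrix of points on a sphere; the radius is
#'   taken from \code{attr(points, "L")} or from the row norms.
#' @param D diffusion coefficient (um^2/s), >= 0.
#' @param dt time step (s), > 0.
#' @return Updated point matrix of the same shape, rows on the sphere.
#' @export
diffuse_on_sphere <- function(points, D, dt) {
  stopifnot(is.matrix(points), ncol(points) == 3)
  stopifnot(is.numeric(D), length(D) == 1L, D >= 0)
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0)
  n <- nrow(points)
  L <- attr(points, "L")
  if (is.null(L)) L <- if (n > 0) sqrt(sum(points[1, ]^2)) else 1
  if (n == 0L || D == 0) return(points)
  nv <- points / L
  # tangent basis: e1 = normalize(u x n), e2 = n x e1, with u chosen away
  # from the pole of n
  use_z <- abs(nv[, 3]) < 0.9
  u <- cbind(ifelse(use_z, 0, 1), 0, ifelse(use_z, 1, 0))
  e1 <- cbind(u[, 2] * nv[, 3] - u[, 3] * nv[, 2],
              u[, 3] * nv[, 1] - u[, 1] * nv[, 3],
              u[, 1] * nv[, 2] - u[, 2] * nv[, 1])
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(nv[, 2] * e1[, 3] - nv[, 3] * e1[, 2],
              nv[, 3] * e1[, 1] - nv[, 1] * e1[, 3],
              nv[, 1] * e1[, 2] - nv[, 2] * e1[, 1])
  s <- sqrt(2 * D * dt)
  s1 <- rnorm(n, 0, s)
  s2 <- rnorm(n, 0, s)
  out <- points + s1 * e1 + s2 * e2
  out <- out * (L / sqrt(rowSums(out^2)))
  colnames(out) <- c("x", "y", "z")
  attr(out, "L") <- L
  out
}

#' Great-circle distance between points on a sphere
#'
#' @param a,b 3-vectors or \code{n x 3} matrices of points on the sphere of
#'   radius \code{L}.
#' @param L sphere radius.
#' @return Geodesic distance(s), same units as \code{L}.
#' @export
great_circle_distance <- function(a, b, L) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  ct <- rowSums(a * b) / L^2
  L * acos(pmin(1, pmax(-1, ct)))
}
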