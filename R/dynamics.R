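#' Linear Jacobian of a link centre of mass
#'
#' Analytic 2 x 4 Jacobian relating generalized-coordinate velocities to the
#' planar velocity of the centre of mass of one link, obtained by direct
#' differentiation of the chain's centre-of-mass position vectors. Columns
#' for coordinates distal to the link are identically zero.
#'
#' @param link integer in 0..3 (foot, shank, thigh, HAT).
#' @param theta generalized coordinates, degrees (length 4).
#' @param params a [segment_params] object.
#' @return 2 x 4 numeric matrix, m/rad; row 1 is d x / d theta, row 2 d y / d theta.
#' @export
linear_jacobian <- function(link, theta, params) {
  stopifnot(inherits(params, "segment_params"))
  if (!(link %in% 0:3)) stop("`link` must be 0, 1, 2 or 3", call. = FALSE)
  th <- .d2r(as.numeric(theta))
  J <- matrix(0, 2, 4)
  if (link == 0L) {
    r0 <- params$r[["foot"]]
    J[, 1] <- c(-r0 * sin(th[1] + params$theta_c),
                 r0 * cos(th[1] + params$theta_c))
    return(J)
  }
  a <- .link_dirs(th)
  # chain from O out to the link COM: full links L0..L_{link-1}, then the
  # COM offset r_link along the link itself
  len <- c(params$L[seq_len(link)], params$r[[link + 1L]])
  ang <- a[seq_len(link + 1L)]
  for (j in seq_len(link + 1L)) {      # column j = d/d theta_{j-1}
    ks <- j:(link + 1L)
    J[1, j] <- -sum(len[ks] * sin(ang[ks]))
    J[2, j] <-  sum(len[ks] * cos(ang[ks]))
  }
  J
}

#' Angular Jacobian of a link
#'
#' Planar reduction of the angular-velocity Jacobian: the z row only, since
#' the x and y rows vanish in plane motion. For a serial pinned chain the
#' angular velocity of link i is the sum of the first i + 1 generalized
#' velocities, so entry j is 1 for j <= i and 0 otherwise.
#'
#' @param link integer in 0..3.
#' @return 1 x 4 numeric matrix (dimensionless).
#' @export
angular_jacobian <- function(link) {
  if (!(link %in% 0:3)) stop("`link` must be 0, 1, 2 or 3", call. = FALSE)
  matrix(as.numeric(seq_len(4L) <= link + 1L), 1, 4)
}

#' Lagrangian mass matrix of the four-link model
#'
#' Assembles the 4 x 4 generalized mass matrix as the sum over links of
#' `m_i Jv_i' Jv_i + I_i Jw_i' Jw_i`, with the analytic linear Jacobians of
#' [linear_jacobian()] and the scalar z-axis inertias. The result is
#' symmetric, positive definite for physical parameters, and independent of
#' the base angle theta0.
#'
#' @inheritParams linear_jacobian
#' @return 4 x 4 numeric matrix, kg m^2.
#' @export
mass_matrix <- function(theta, params) {
  stopifnot(inherits(params, "segment_params"))
  M <- matrix(0, 4, 4)
  for (link in 0:3) {
    Jv <- linear_jacobian(link, theta, params)
    Jw <- angular_jacobian(link)
    M <- M + params$m[[link + 1L]] * crossprod(Jv) +
             params$I[[link + 1L]] * crossprod(Jw)
  }
  (M + t(M)) / 2
}

#' Whole-body centre-of-mass Jacobian
#'
#' The 2 x 4 Jacobian relating generalized velocities to the planar velocity
#' of the whole-body centre of mass: the mass-weighted mean of the link
#' Jacobians. Row 1 is the anteroposterior (progression, +X anterior) row,
#' row 2 the vertical (support, +Y superior) row.
#'
#' @inheritParams linear_jacobian
#' @return 2 x 4 numeric matrix, m/rad, with rownames `progression`, `support`.
#' @export
com_jacobian <- function(theta, params) {
  stopifnot(inherits(params, "segment_params"))
  total <- sum(params$m)
  if (total <= 0) stop("total model mass must be positive", call. = FALSE)
  J <- matrix(0, 2, 4)
  for (link in 0:3)
    J <- J + params$m[[link + 1L]] * linear_jacobian(link, theta, params)
  J <- J / total
  rownames(J) <- c("progression", "support")
  J
}

#' Gravity and velocity-product generalized forces (verification oracle)
#'
#' Evaluates the gravity vector G and the Coriolis/centrifugal vector V of
#' the full equations of motion `M qdd = G + V + Q`. This is a verification
#' aid for the dynamics (energy-consistency and induced-acceleration oracle
#' tests); the potential computation itself never uses gravity or velocity
#' terms, which drop out of the per-unit-force induced acceleration by
#' construction.
#'
#' G is the exact gradient of the gravitational potential energy; V is built
#' from Christoffel symbols of the mass matrix evaluated by central finite
#' differences (step 1e-6 rad).
#'
#' @inheritParams linear_jacobian
#' @param theta_dot generalized velocities, rad/s (length 4).
#' @param g gravitational acceleration, m/s^2.
#' @return list with `G` and `V`, each a length-4 numeric vector of
#'   generalized forces (N m).
#' @export
eom_terms <- function(theta, theta_dot = rep(0, 4), params, g = 9.81) {
  stopifnot(inherits(params, "segment_params"))
  qd <- as.numeric(theta_dot)
  # G_j = -d(PE)/d theta_j = -g * sum_i m_i * (d y_ci / d theta_j)
  G <- numeric(4)
  for (link in 0:3)
    G <- G - g * params$m[[link + 1L]] * linear_jacobian(link, theta, params)[2, ]

  h <- 1e-6  # rad
  dM <- array(0, c(4, 4, 4))
  for (k in 1:4) {
    e <- numeric(4); e[k] <- .r2d(h)
    dM[, , k] <- (mass_matrix(theta + e, params) -
                  mass_matrix(theta - e, params)) / (2 * h)
  }
  V <- numeric(4)
  if (any(qd != 0)) {
    for (j in 1:4) {
      Gam <- 0.5 * (dM[j, , ] + t(dM[j, , ]) - dM[, , j])
      V[j] <- -as.numeric(t(qd) %*% Gam %*% qd)
    }
  }
  list(G = G, V = V)
}

# Condition-number-guarded SPD solve used by the potential engine.
.solve_spd <- function(M, B, kappa_max = 1e12) {
  kap <- kappa(M, exact = FALSE)
  if (!is.finite(kap) || kap > kappa_max)
    stop(sprintf("mass matrix is singular or ill-conditioned (condition number %.3g > %.3g)",
                 kap, kappa_max), call. = FALSE)
  ch <- tryCatch(chol(M), error = function(e)
    stop("mass matrix is not positive definite", call. = FALSE))
  backsolve(ch, forwardsolve(t(ch), B))
}
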