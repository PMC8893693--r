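test_that("link-0 and link-3 linear Jacobians match their closed forms", {
  p <- fixture_params()
  th <- c(7, -23, 88, -95)
  rad <- deg2rad(th)

  J0 <- linear_jacobian(0, th, p)
  r0 <- p$r[["foot"]]
  expect_equal(J0[, 1], r0 * c(-sin(rad[1] + p$theta_c),
                               cos(rad[1] + p$theta_c)), tolerance = 1e-12)
  expect_equal(J0[, 2:4], matrix(0, 2, 3))

  # link 3: truncated angle sums, entry by entry
  J3 <- linear_jacobian(3, th, p)
  L0 <- p$L[["foot"]]; L1 <- p$L[["shank"]]; L2 <- p$L[["thigh"]]
  r3 <- p$r[["hat"]]
  a0 <- rad[1]; a01 <- sum(rad[1:2]); a02 <- sum(rad[1:3]); a03 <- sum(rad)
  # d/dq of cos(angle + 90 deg) is -sin(angle + 90) = -cos(angle), etc.
  expect_equal(J3[1, ], c(-L0 * cos(a0) - L1 * cos(a01) - L2 * cos(a02) - r3 * cos(a03),
                          -L1 * cos(a01) - L2 * cos(a02) - r3 * cos(a03),
                          -L2 * cos(a02) - r3 * cos(a03),
                          -r3 * cos(a03)), tolerance = 1e-12)
  expect_equal(J3[2, ], c(-L0 * sin(a0) - L1 * sin(a01) - L2 * sin(a02) - r3 * sin(a03),
                          -L1 * sin(a01) - L2 * sin(a02) - r3 * sin(a03),
                          -L2 * sin(a02) - r3 * sin(a03),
                          -r3 * sin(a03)), tolerance = 1e-12)
})

test_that("all four analytic Jacobians agree with central finite differences", {
  p <- fixture_params()
  set.seed(3)
  for (i in 1:30) {
    th <- c(runif(1, -30, 30), runif(1, -60, 20), runif(1, 0, 120),
            runif(1, -160, -20))
    for (link in 0:3) {
      expect_lt(max(abs(linear_jacobian(link, th, p) -
                        fd_linear_jacobian(link, th, p))), 1e-8)
    }
  }
})

test_that("angular Jacobians follow the chain topology", {
  expect_equal(angular_jacobian(0), matrix(c(1, 0, 0, 0), 1))
  expect_equal(angular_jacobian(2), matrix(c(1, 1, 1, 0), 1))
  expect_equal(angular_jacobian(3), matrix(c(1, 1, 1, 1), 1))
})

test_that("mass matrix degenerates correctly and matches the single-pendulum form", {
  p <- fixture_params()
  zero <- segment_params(rep(0, 4), p$L, p$r, rep(0, 4),
                         p$foot_triangle, p$foot_com)
  expect_equal(mass_matrix(c(0, 0, 90, -90), zero), matrix(0, 4, 4))

  solo <- segment_params(c(p$m[["foot"]], 0, 0, 0), p$L, p$r,
                         c(p$I[["foot"]], 0, 0, 0),
                         p$foot_triangle, p$foot_com)
  M <- mass_matrix(c(12, -5, 80, -60), solo)
  expect_equal(M[1, 1], p$I[["foot"]] + p$m[["foot"]] * p$r[["foot"]]^2,
               tolerance = 1e-12)
  expect_equal(M[-1, ], matrix(0, 3, 4))
})

test_that("mass matrix is the Hessian of kinetic energy in generalized velocities", {
  p <- fixture_params()
  # independent kinetic energy: COM velocities by finite-differencing positions
  # along q + qd*t, angular velocities as partial sums of qd
  ke <- function(th, qd) {
    h <- 1e-5
    up <- forward_kinematics(th + (qd * h) * 180 / pi, p)
    dn <- forward_kinematics(th - (qd * h) * 180 / pi, p)
    V <- (up$link_coms - dn$link_coms) / (2 * h)
    w <- cumsum(qd)
    sum(0.5 * p$m * colSums(V^2)) + sum(0.5 * p$I * w^2)
  }
  set.seed(8)
  for (i in 1:5) {
    th <- c(0, runif(1, -40, 0), runif(1, 75, 100), runif(1, -150, -60))
    M <- mass_matrix(th, p)
    # KE is exactly quadratic in qd, so polarization recovers M entrywise
    H <- matrix(0, 4, 4)
    for (j in 1:4) for (k in j:4) {
      ej <- numeric(4); ej[j] <- 1
      ek <- numeric(4); ek[k] <- 1
      H[j, k] <- H[k, j] <-
        ke(th, ej + ek) - ke(th, ej) - ke(th, ek) + ke(th, numeric(4))
    }
    expect_lt(max(abs(M - H)) / max(abs(M)), 1e-6)
  }
})

test_that("mass matrix is symmetric, positive definite, base-angle invariant and scales linearly", {
  p <- fixture_params()
  set.seed(21)
  p2 <- segment_params(2 * p$m, p$L, p$r, 2 * p$I, p$foot_triangle, p$foot_com)
  for (i in 1:20) {
    th <- c(runif(1, -90, 90), runif(1, -60, 20), runif(1, 0, 120),
            runif(1, -160, -20))
    M <- mass_matrix(th, p)
    expect_equal(M, t(M), tolerance = 1e-12)
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
    # independent of the base angle
    expect_equal(M, mass_matrix(th + c(33, 0, 0, 0), p), tolerance = 1e-10)
    # doubling masses and inertias doubles M exactly
    expect_equal(2 * M, mass_matrix(th, p2), tolerance = 1e-12)
  }
})

test_that("COM Jacobian is the mass-weighted link Jacobian and predicts COM velocity", {
  p <- fixture_params()
  th <- c(0, -15, 95, -120)
  # only HAT mass: COM Jacobian equals the link-3 Jacobian
  only3 <- segment_params(c(0, 0, 0, p$m[["hat"]]), p$L, p$r, p$I,
                          p$foot_triangle, p$foot_com)
  expect_equal(unname(com_jacobian(th, only3)), linear_jacobian(3, th, only3),
               tolerance = 1e-12)
  # J_com qd matches finite-difference COM velocity for random qd
  set.seed(5)
  J <- com_jacobian(th, p)
  for (i in 1:5) {
    qd <- runif(4, -1, 1)
    h <- 1e-6
    up <- forward_kinematics(th + qd * h * 180 / pi, p)$com
    dn <- forward_kinematics(th - qd * h * 180 / pi, p)$com
    expect_equal(as.numeric(J %*% qd), (up - dn) / (2 * h), tolerance = 1e-7)
  }
  # theta3 column carries no contribution from links 0-2
  expect_equal(unname(J[, 4]),
               p$m[["hat"]] * linear_jacobian(3, th, p)[, 4] / sum(p$m),
               tolerance = 1e-12)
})

test_that("gravity and velocity terms behave as the equations of motion require", {
  p <- fixture_params()
  # zero velocity: V identically zero
  et <- eom_terms(c(0, -20, 90, -80), numeric(4), p)
  expect_equal(et$V, numeric(4))

  # toy model with the foot COM on the OA line: fully vertical stack has G = 0
  vert <- segment_params(p$m, p$L,
                         c(NA, p$r[["shank"]], p$r[["thigh"]], p$r[["hat"]]),
                         p$I, p$foot_triangle, c(0, p$r[["foot"]]))
  G <- eom_terms(c(0, 0, 0, 0), numeric(4), vert)$G
  expect_lt(max(abs(G)), 1e-10)

  # energy consistency: unforced motion conserves KE + PE
  g <- 9.81
  energy <- function(th, qd) {
    fk <- forward_kinematics(th, p)
    h <- 1e-5
    up <- forward_kinematics(th + (qd * h) * 180 / pi, p)$link_coms
    dn <- forward_kinematics(th - (qd * h) * 180 / pi, p)$link_coms
    V <- (up - dn) / (2 * h)
    ke <- sum(0.5 * p$m * colSums(V^2)) + sum(0.5 * p$I * cumsum(qd)^2)
    ke + g * sum(p$m * fk$link_coms[2, ])
  }
  q <- deg2rad(c(0, -10, 85, -95)); qd <- c(0.1, -0.2, 0.15, 0.05)
  h <- 2e-4
  deriv <- function(q, qd) {
    th <- q * 180 / pi
    et <- eom_terms(th, qd, p, g = g)
    list(qd = qd, qdd = solve(mass_matrix(th, p), et$G + et$V))
  }
  E0 <- energy(q * 180 / pi, qd)
  for (i in 1:50) {
    k1 <- deriv(q, qd)
    k2 <- deriv(q + h / 2 * k1$qd, qd + h / 2 * k1$qdd)
    k3 <- deriv(q + h / 2 * k2$qd, qd + h / 2 * k2$qdd)
    k4 <- deriv(q + h * k3$qd, qd + h * k3$qdd)
    q  <- q  + h / 6 * (k1$qd  + 2 * k2$qd  + 2 * k3$qd  + k4$qd)
    qd <- qd + h / 6 * (k1$qdd + 2 * k2$qdd + 2 * k3$qdd + k4$qdd)
  }
  E1 <- energy(q * 180 / pi, qd)
  expect_lt(abs(E1 - E0) / abs(E0), 1e-6)
})
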