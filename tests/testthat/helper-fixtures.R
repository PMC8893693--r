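# Shared fixtures and oracles. Expensive artifacts (the enumerated grid, the
# full-grid potential sweep) are computed once per test run and cached.

.cache <- new.env(parent = emptyenv())

fixture_params <- function() {
  if (is.null(.cache$params)) .cache$params <- default_segment_params()
  .cache$params
}

fixture_muscles <- function() {
  if (is.null(.cache$muscles)) .cache$muscles <- default_muscles()
  .cache$muscles
}

fixture_provider <- function() {
  if (is.null(.cache$provider))
    .cache$provider <- geometric_provider(fixture_muscles(), fixture_params())
  .cache$provider
}

shared_grid <- function() {
  if (is.null(.cache$grid)) .cache$grid <- enumerate_states(params = fixture_params())
  .cache$grid
}

shared_sweep <- function() {
  if (is.null(.cache$sweep))
    .cache$sweep <- sweep_potentials(shared_grid(), fixture_provider(),
                                     fixture_params())
  .cache$sweep
}

deg2rad <- function(x) x * pi / 180

# Independent forward-kinematics oracle: composes per-joint rotation matrices
# instead of summing angles.
fk_rotation_oracle <- function(theta_deg, params) {
  th <- deg2rad(theta_deg)
  rot <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  R <- diag(2)
  pos <- c(0, 0)
  joints <- list(O = pos)
  up <- c(0, 1)
  lens <- c(params$L[["foot"]], params$L[["shank"]], params$L[["thigh"]])
  for (k in 1:3) {
    R <- R %*% rot(th[k])
    pos <- pos + lens[k] * as.numeric(R %*% up)
    joints[[c("A", "K", "H")[k]]] <- pos
  }
  com0 <- params$r[["foot"]] *
    c(cos(th[1] + params$theta_c), sin(th[1] + params$theta_c))
  coms <- matrix(0, 2, 4); coms[, 1] <- com0
  offs <- c(NA, params$r[["shank"]], params$r[["thigh"]], params$r[["hat"]])
  coms[, 2] <- joints$A + offs[2] * as.numeric(rot(th[1] + th[2]) %*% up)
  coms[, 3] <- joints$K + offs[3] * as.numeric(rot(th[1] + th[2] + th[3]) %*% up)
  coms[, 4] <- joints$H + offs[4] * as.numeric(rot(sum(th)) %*% up)
  list(joints = joints, coms = coms,
       com = as.numeric(coms %*% params$m) / sum(params$m))
}

# central finite differences of a link COM position w.r.t. each coordinate
fd_linear_jacobian <- function(link, theta_deg, params, h_rad = 1e-6) {
  J <- matrix(0, 2, 4)
  h_deg <- h_rad * 180 / pi
  for (j in 1:4) {
    e <- numeric(4); e[j] <- h_deg
    up <- forward_kinematics(theta_deg + e, params)$link_coms[, link + 1L]
    dn <- forward_kinematics(theta_deg - e, params)$link_coms[, link + 1L]
    J[, j] <- (up - dn) / (2 * h_rad)
  }
  J
}

# Forward-integration oracle for induced accelerations: integrate
# M(q) qdd = Q from rest with gravity zeroed (RK4), and return the mean
# accelerations 2*dq/dt^2 and 2*dcom/dt^2.
integrate_push <- function(theta_deg, Q, params, dt = 1e-4, nstep = 20) {
  theta_deg <- unname(as.numeric(theta_deg))
  Q <- unname(as.numeric(Q))
  # integrate the displacement dq from the start state (rather than the
  # absolute angles) so the tiny excursion over dt is not lost to roundoff
  dq <- numeric(4)
  qd <- numeric(4)
  h <- dt / nstep
  deriv <- function(dq, qd) {
    M <- mass_matrix(theta_deg + dq * 180 / pi, params)
    list(qd = qd, qdd = as.numeric(solve(M, Q)))
  }
  for (i in seq_len(nstep)) {
    k1 <- deriv(dq, qd)
    k2 <- deriv(dq + h / 2 * k1$qd, qd + h / 2 * k1$qdd)
    k3 <- deriv(dq + h / 2 * k2$qd, qd + h / 2 * k2$qdd)
    k4 <- deriv(dq + h * k3$qd, qd + h * k3$qdd)
    dq <- dq + h / 6 * (k1$qd  + 2 * k2$qd  + 2 * k3$qd  + k4$qd)
    qd <- qd + h / 6 * (k1$qdd + 2 * k2$qdd + 2 * k3$qdd + k4$qdd)
  }
  # COM displacement via the average of start/end Jacobian rows applied to dq
  # would presuppose the Jacobian under test; instead difference the forward
  # kinematics of the displaced state, which limits precision to ~1e-11 m
  com0 <- forward_kinematics(theta_deg, params)$com
  com1 <- forward_kinematics(theta_deg + dq * 180 / pi, params)$com
  list(qdd = 2 * dq / dt^2,
       com_acc = 2 * (com1 - com0) / dt^2)
}

# Printed sensitivity-analysis reference coefficients (correlation table of
# the source analysis), used only for qualitative sign comparison.
table2_reference <- function() {
  mus <- c("gluteus_maximus", "biceps_femoris", "rectus_femoris", "vasti",
           "gastrocnemius", "soleus", "tibialis_anterior")
  sup <- data.frame(task = "support", muscle = mus,
    foot_position  = c(-0.248, 0.481, -0.860, -0.411, -0.745, -0.735, 0.918),
    pelvis_height  = c(0.855, -0.747, 0.830, 0.930, 0.593, 0.707, -0.726),
    lumbar_flexion = c(0.144, -0.497, 0.528, 0.374, 0.280, 0.324, -0.346),
    pelvic_tilt    = c(0.829, 0.934, -0.893, -0.204, -0.172, -0.193, 0.217))
  pro <- data.frame(task = "progression", muscle = mus,
    foot_position  = c(-0.989, -0.852, 0.237, -0.974, -0.987, -0.989, 0.988),
    pelvis_height  = c(0.672, 0.872, -0.610, 0.532, 0.691, 0.640, -0.612),
    lumbar_flexion = c(0.246, 0.190, 0.133, 0.300, 0.358, 0.345, -0.338),
    pelvic_tilt    = c(0.461, 0.696, -0.846, -0.194, -0.223, -0.216, 0.212))
  wide <- rbind(sup, pro)
  mods <- c("foot_position", "pelvis_height", "lumbar_flexion", "pelvic_tilt")
  long <- reshape(wide, varying = mods, v.names = "r_ref", timevar = "modifier",
                  times = mods, direction = "long")
  rownames(long) <- NULL
  long[c("muscle", "task", "modifier", "r_ref")]
}
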