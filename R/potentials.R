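#' Joint-space induced-acceleration potentials
#'
#' Solves `M P = R_gen` column-wise (Cholesky factorization of the
#' symmetric positive-definite mass matrix; no explicit inversion), giving
#' each muscle's induced generalized acceleration per Newton of muscle
#' force. The solve is guarded by a condition-number check.
#'
#' @param M 4 x 4 mass matrix, kg m^2 (see [mass_matrix()]).
#' @param R_gen 4 x m generalized moment-arm matrix, m/rad
#'   (see [map_to_generalized()]).
#' @param kappa_max condition-number guard; larger values raise an error.
#' @return 4 x m matrix of joint potentials, rad/(N s^2).
#' @export
joint_potentials <- function(M, R_gen, kappa_max = 1e12) {
  R_gen <- as.matrix(R_gen)
  if (!all(dim(M) == c(4L, 4L)) || nrow(R_gen) != 4L)
    stop("`M` must be 4 x 4 and `R_gen` must have 4 rows", call. = FALSE)
  P <- .solve_spd(M, R_gen, kappa_max)
  dimnames(P) <- list(paste0("theta", 0:3), colnames(R_gen))
  P
}

#' Project joint potentials to the support and progression axes
#'
#' Maps joint-space potentials to whole-body centre-of-mass acceleration per
#' Newton via the centre-of-mass Jacobian. Because potentials are defined at
#' zero joint velocity, the Jacobian-rate term of the Cartesian acceleration
#' vanishes and the projection is exact.
#'
#' @param P_joint 4 x m joint-potential matrix (see [joint_potentials()]).
#' @param J_com 2 x 4 centre-of-mass Jacobian (see [com_jacobian()]).
#' @return 2 x m matrix, m/(N s^2); rows `progression` (+X, anterior) and
#'   `support` (+Y, superior).
#' @export
task_potentials <- function(P_joint, J_com) {
  P_joint <- as.matrix(P_joint)
  if (!all(dim(J_com) == c(2L, 4L)) || nrow(P_joint) != 4L)
    stop("`J_com` must be 2 x 4 and `P_joint` must have 4 rows", call. = FALSE)
  out <- J_com %*% P_joint
  rownames(out) <- c("progression", "support")
  out
}

#' Muscle potentials for a single kinematic state
#'
#' Full per-state pipeline: mass matrix from the 2D coordinates, anatomical
#' moment arms from the provider, mapping to generalized coordinates, the
#' joint-space solve and the task-space projection.
#'
#' @param theta generalized coordinates theta0..theta3, degrees.
#' @param pelvic_tilt pelvic tilt, degrees (posterior positive).
#' @param provider a moment-arm provider closure
#'   ([geometric_provider()] or [tabulated_provider()]).
#' @param params a [segment_params] object.
#' @return data frame with one row per muscle: `muscle`, `group`,
#'   `support_potential` and `progression_potential` (m/(N s^2)).
#' @export
#' @examples
#' params <- default_segment_params()
#' prov <- geometric_provider(default_muscles(), params)
#' muscle_potentials(c(0, 0, 90, -90), 0, prov, params)
muscle_potentials <- function(theta, pelvic_tilt, provider, params) {
  msk <- to_msk(theta, pelvic_tilt)
  R_msk <- provider(msk)
  P <- joint_potentials(mass_matrix(theta, params), map_to_generalized(R_msk))
  task <- task_potentials(P, com_jacobian(theta, params))
  groups <- attr(provider, "groups")
  data.frame(muscle = colnames(R_msk),
             group = unname(groups[colnames(R_msk)]),
             support_potential = task["support", ],
             progression_potential = task["progression", ],
             row.names = NULL)
}

#' Sweep muscle potentials over a set of kinematic states
#'
#' Evaluates [muscle_potentials()] for every row of a state grid (see
#' [enumerate_states()]), returning a long table of one row per
#' (state, actuator) with the state's angles and derived metrics attached.
#'
#' @param states data frame in the layout of [enumerate_states()].
#' @param provider a moment-arm provider closure.
#' @param params a [segment_params] object.
#' @return long data frame with columns `state_id`, `muscle`, `group`,
#'   `support_potential`, `progression_potential`, the four 2D coordinates,
#'   the MSK angles and `foot_position` / `pelvis_height`.
#' @export
sweep_potentials <- function(states, provider, params) {
  states <- as.data.frame(states)
  need <- c("theta0", "theta1", "theta2", "theta3", "pelvic_tilt")
  if (!all(need %in% names(states)))
    stop("`states` needs columns theta0..theta3 and pelvic_tilt", call. = FALSE)
  n <- nrow(states)
  groups <- attr(provider, "groups")
  call_provider <- function(i, th, msk) {
    tryCatch(provider(msk), error = function(e)
      stop(sprintf("moment-arm provider failed at state %s (theta1 %g, theta2 %g, theta3 %g, tilt %g): %s",
                   if (!is.null(states$state_id)) states$state_id[i] else i,
                   th[2], th[3], th[4], states$pelvic_tilt[i],
                   conditionMessage(e)), call. = FALSE))
  }
  th1 <- c(states$theta0[1], states$theta1[1], states$theta2[1], states$theta3[1])
  first <- call_provider(1L, th1, to_msk(th1, states$pelvic_tilt[1]))
  m <- ncol(first)
  sup <- matrix(NA_real_, n, m)
  pro <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    th <- c(states$theta0[i], states$theta1[i], states$theta2[i], states$theta3[i])
    msk <- to_msk(th, states$pelvic_tilt[i])
    R_msk <- call_provider(i, th, msk)
    P <- joint_potentials(mass_matrix(th, params), map_to_generalized(R_msk))
    task <- task_potentials(P, com_jacobian(th, params))
    pro[i, ] <- task["progression", ]
    sup[i, ] <- task["support", ]
  }
  muscles <- colnames(first)
  state_cols <- intersect(c("state_id", "theta0", "theta1", "theta2", "theta3",
                            "ankle", "knee", "hip", "lumbar", "pelvic_tilt",
                            "foot_position", "pelvis_height"), names(states))
  out <- states[rep(seq_len(n), each = m), state_cols, drop = FALSE]
  out$muscle <- rep(muscles, times = n)
  out$group <- unname(groups[out$muscle])
  out$support_potential <- as.vector(t(sup))
  out$progression_potential <- as.vector(t(pro))
  rownames(out) <- NULL
  out
}

#' Collapse actuators to muscle groups
#'
#' Combines the potentials of actuators that share a group label (e.g. the
#' two gastrocnemius heads) into one value per state and group, by mean
#' (default) or sum.
#'
#' @param sweep long table from [sweep_potentials()].
#' @param combine `"mean"` or `"sum"`.
#' @return data frame in the same layout with `muscle` replaced by the group
#'   label.
#' @export
collapse_groups <- function(sweep, combine = c("mean", "sum")) {
  combine <- match.arg(combine)
  f <- if (combine == "mean") mean else sum
  keys <- setdiff(names(sweep),
                  c("muscle", "support_potential", "progression_potential"))
  agg <- aggregate(sweep[c("support_potential", "progression_potential")],
                   by = sweep[keys], FUN = f)
  agg$muscle <- agg$group
  agg[order(agg$state_id, agg$muscle),
      c(setdiff(names(sweep), "group"), "group")]
}

#' Mean and standard deviation of potentials per kinematic-parameter value
#'
#' Summarizes a potential sweep by one kinematic modifier: for each distinct
#' value of the modifier and each muscle group, the mean and standard
#' deviation of the support and progression potentials over all states with
#' that value (states weighted uniformly). Continuous modifiers
#' (foot position, pelvis height) are grouped after rounding to 6 decimals.
#'
#' @param sweep long table from [sweep_potentials()].
#' @param by one of `"pelvic_tilt"`, `"lumbar_flexion"`, `"foot_position"`,
#'   `"pelvis_height"`.
#' @param collapse collapse actuators to groups first (see
#'   [collapse_groups()]).
#' @return data frame with columns `muscle`, the modifier value, `n_states`,
#'   and mean/sd of both potentials.
#' @export
aggregate_potentials <- function(sweep,
                                 by = c("pelvic_tilt", "lumbar_flexion",
                                        "foot_position", "pelvis_height"),
                                 collapse = TRUE) {
  by <- match.arg(by)
  if (collapse) sweep <- collapse_groups(sweep)
  val <- .modifier_values(sweep, by)
  if (by %in% c("foot_position", "pelvis_height")) val <- round(val, 6)
  key <- data.frame(muscle = sweep$muscle, value = val)
  agg <- aggregate(sweep[c("support_potential", "progression_potential")],
                   by = key,
                   FUN = function(x) c(mean = mean(x), sd = sd(x)))
  n <- aggregate(list(n_states = sweep$support_potential), by = key, FUN = length)
  out <- data.frame(muscle = agg$muscle, value = agg$value,
                    n_states = n$n_states,
                    support_mean = agg$support_potential[, "mean"],
                    support_sd = agg$support_potential[, "sd"],
                    progression_mean = agg$progression_potential[, "mean"],
                    progression_sd = agg$progression_potential[, "sd"])
  names(out)[names(out) == "value"] <- by
  out[order(out$muscle, out[[by]]), ]
}

# modifier columns used in the figures/correlations; lumbar_flexion flips the
# extension-positive MSK lumbar angle so that positive = flexion, the
# convention in which the sensitivity results are reported
.modifier_values <- function(sweep, modifier) {
  switch(modifier,
         pelvic_tilt = sweep$pelvic_tilt,
         lumbar_flexion = -sweep$lumbar,
         foot_position = sweep$foot_position,
         pelvis_height = sweep$pelvis_height,
         stop(sprintf("unknown kinematic modifier `%s`", modifier), call. = FALSE))
}
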