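neutral_msk <- c(ankle = 0, knee = -90, hip = 90, lumbar = 0, pelvic_tilt = 0)

test_that("a path confined to one segment has zero moment arms everywhere", {
  p <- fixture_params()
  mus <- muscle_def("rigid", data.frame(frame = c("shank", "shank"),
                                        x = c(0.05, 0.30), y = c(0.02, -0.01)))
  expect_equal(spanned_joints(mus), character(0))
  ma <- geometric_moment_arms(mus, neutral_msk, p)
  expect_equal(unname(ma), rep(0, 4))
})

test_that("a line crossing one pin joint has moment arm equal to its offset", {
  p <- fixture_params()
  d <- 0.033
  # vertical line a distance d posterior to the ankle in the neutral upright
  # configuration: local +y is posterior on both foot and shank frames there
  mus <- muscle_def("toy", data.frame(frame = c("shank", "foot"),
                                      x = c(0.20, -d),
                                      y = c(d, p$L[["foot"]] - 0.03)))
  up <- c(ankle = 0, knee = 0, hip = 0, lumbar = 0, pelvic_tilt = 0)
  ma <- geometric_moment_arms(mus, up, p)
  expect_equal(unname(abs(ma[["ankle"]])), d, tolerance = 1e-9)
  expect_lt(ma[["ankle"]], 0)  # posterior line resists dorsiflexion
})

test_that("fixture soleus is a plantarflexor with a plausible lever arm", {
  p <- fixture_params()
  muscles <- fixture_muscles()
  sol <- muscles[[which(vapply(muscles, `[[`, character(1), "name") == "soleus")]]
  ma <- geometric_moment_arms(sol, neutral_msk, p)
  expect_lt(ma[["ankle"]], 0)
  expect_gt(abs(ma[["ankle"]]), 0.02)
  expect_lt(abs(ma[["ankle"]]), 0.06)
  expect_equal(ma[["knee"]], 0)
  # analytic and finite-difference evaluations agree
  ma_fd <- geometric_moment_arms(sol, neutral_msk, p, method = "fd")
  expect_equal(ma, ma_fd, tolerance = 1e-6)
})

test_that("anatomical-to-generalized mapping follows the constant conversion Jacobian", {
  R_msk <- matrix(0, 4, 3,
                  dimnames = list(c("ankle", "knee", "hip", "lumbar"),
                                  c("ank_only", "hip_only", "lum_only")))
  R_msk["ankle", 1] <- 0.04
  R_msk["hip", 2] <- 0.06
  R_msk["lumbar", 3] <- 0.05
  R_gen <- map_to_generalized(R_msk)
  expect_equal(unname(R_gen[, "ank_only"]), c(0, -0.04, 0, 0))
  expect_equal(unname(R_gen[, "hip_only"]), c(0.06, 0.06, 0.06, 0))
  expect_equal(unname(R_gen[, "lum_only"]), c(0.05, 0.05, 0.05, 0.05))

  # flipping a joint's sign convention and its conversion row leaves R_gen alone
  Amap <- rbind(c(0, -1, 0, 0), c(0, 0, -1, 0), c(1, 1, 1, 0), c(1, 1, 1, 1))
  flip <- diag(c(-1, 1, 1, 1))
  expect_equal(t(Amap) %*% R_msk, t(flip %*% Amap) %*% (flip %*% R_msk))
})

test_that("mapped generalized columns equal minus the length gradient over q", {
  p <- fixture_params()
  muscles <- fixture_muscles()
  states <- random_states(20, seed = 31, params = p)
  h <- 1e-6  # rad
  for (i in seq_len(nrow(states))) {
    th <- unlist(states[i, c("theta0", "theta1", "theta2", "theta3")])
    tilt <- states$pelvic_tilt[i]
    for (mus in muscles) {
      R_gen <- map_to_generalized(
        matrix(geometric_moment_arms(mus, to_msk(th, tilt), p), 4, 1))
      fd <- numeric(4)
      for (j in 1:4) {
        e <- numeric(4); e[j] <- h * 180 / pi
        fd[j] <- -(muscle_length(mus, to_msk(th + e, tilt), p) -
                   muscle_length(mus, to_msk(th - e, tilt), p)) / (2 * h)
      }
      expect_lt(max(abs(fd - R_gen[, 1])), 1e-6)
    }
  }
})

test_that("tabulated moment arms interpolate exactly where they should", {
  p <- fixture_params()
  muscles <- fixture_muscles()
  tab <- tabulate_moment_arms(muscles, p, step = 10)
  prov_tab <- tabulated_provider(tab)
  prov_geo <- fixture_provider()
  # exact at grid nodes
  node <- c(ankle = 20, knee = -80, hip = 45, lumbar = -30, pelvic_tilt = 0)
  expect_equal(prov_tab(node), prov_geo(node), tolerance = 1e-12)

  # constant table reproduces the constant everywhere
  const <- data.frame(muscle = "m", joint = "ankle",
                      ankle = seq(0, 40, 10), knee = NA, hip = NA, lumbar = NA,
                      moment_arm_m = -0.04)
  pc <- tabulated_provider(const)
  expect_equal(pc(c(ankle = 17.3, knee = -90, hip = 60, lumbar = 0,
                    pelvic_tilt = 0))["ankle", "m"], -0.04)

  # a linear-in-angle table is reproduced exactly at midpoints
  lin <- data.frame(muscle = "m", joint = "ankle",
                    ankle = seq(0, 40, 10), knee = NA, hip = NA, lumbar = NA,
                    moment_arm_m = 0.01 + 0.002 * seq(0, 40, 10))
  pl <- tabulated_provider(lin)
  expect_equal(pl(c(ankle = 25, knee = -90, hip = 60, lumbar = 0,
                    pelvic_tilt = 0))["ankle", "m"],
               0.01 + 0.002 * 25, tolerance = 1e-12)

  # refusal to extrapolate
  expect_error(pl(c(ankle = 45, knee = -90, hip = 60, lumbar = 0,
                    pelvic_tilt = 0)), "outside the tabulated range")
  # incomplete factorial grids are rejected (one node of a 2-D grid missing)
  two <- expand.grid(ankle = c(0, 20, 40), knee = c(-100, -90, -80))
  two <- data.frame(muscle = "m", joint = "ankle", ankle = two$ankle,
                    knee = two$knee, hip = NA, lumbar = NA,
                    moment_arm_m = -0.03 + 1e-4 * two$ankle)
  expect_silent(tabulated_provider(two))
  expect_error(tabulated_provider(two[-5, ]), "not a full factorial")
})

test_that("muscle definitions are validated", {
  expect_error(muscle_def("x", data.frame(frame = "shank", x = 0, y = 0)),
               "at least two")
  expect_error(muscle_def("x", data.frame(frame = c("shank", "forearm"),
                                          x = c(0, 1), y = c(0, 0))),
               "unknown frame")
  p <- fixture_params()
  degen <- muscle_def("d", data.frame(frame = c("shank", "shank", "foot"),
                                      x = c(0.1, 0.1, 0), y = c(0, 0, 0.02)))
  expect_error(muscle_length(degen, neutral_msk, p), "degenerate")
})
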