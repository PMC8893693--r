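#' Convert 2D-model coordinates to anatomical (MSK) joint angles
#'
#' Maps the four generalized coordinates of the planar chain, plus a pelvic
#' tilt angle, onto anatomical joint angles in the musculoskeletal (MSK)
#' convention: positive ankle dorsiflexion, knee extension, hip flexion,
#' lumbar extension and posterior pelvic tilt. The map is affine:
#' `ankle = -theta1`, `knee = -theta2`,
#' `hip = theta0 + theta1 + theta2 - pelvic_tilt`, `lumbar = hip + theta3`.
#'
#' @param theta generalized coordinates theta0..theta3, degrees (length 4).
#' @param pelvic_tilt pelvic tilt angle, degrees (posterior positive).
#' @return named numeric vector with elements `ankle`, `knee`, `hip`,
#'   `lumbar`, `pelvic_tilt` (degrees).
#' @export
#' @examples
#' to_msk(c(0, 0, 90, -90), 0)  # the sitting reference posture
to_msk <- function(theta, pelvic_tilt = 0) {
  theta <- as.numeric(theta)
  if (length(theta) != 4L) stop("`theta` must have length 4", call. = FALSE)
  hip <- theta[1] + theta[2] + theta[3] - pelvic_tilt
  c(ankle = -theta[2], knee = -theta[3], hip = hip,
    lumbar = hip + theta[4], pelvic_tilt = pelvic_tilt)
}

#' Convert anatomical (MSK) joint angles to 2D-model coordinates
#'
#' Exact algebraic inverse of [to_msk()] under the foot-flat condition
#' `theta0 = 0` used throughout the state enumeration.
#'
#' @param msk named numeric vector (or single-row data frame) with elements
#'   `ankle`, `knee`, `hip`, `lumbar`, `pelvic_tilt`, degrees.
#' @return list with `theta` (length-4 numeric, degrees, `theta0 = 0`) and
#'   `pelvic_tilt` (degrees).
#' @export
from_msk <- function(msk) {
  msk <- .as_msk(msk)
  theta <- c(0, -msk[["ankle"]], -msk[["knee"]],
             msk[["lumbar"]] - msk[["hip"]])
  implied_tilt <- theta[2] + theta[3] - msk[["hip"]]
  if (abs(implied_tilt - msk[["pelvic_tilt"]]) > 1e-9)
    stop(sprintf(paste0("inconsistent MSK state: with theta0 = 0, ankle %.3f / knee %.3f / ",
                        "hip %.3f imply a pelvic tilt of %.3f deg, not %.3f deg"),
                 msk[["ankle"]], msk[["knee"]], msk[["hip"]],
                 implied_tilt, msk[["pelvic_tilt"]]), call. = FALSE)
  list(theta = theta, pelvic_tilt = msk[["pelvic_tilt"]])
}

.msk_fields <- c("ankle", "knee", "hip", "lumbar", "pelvic_tilt")

.as_msk <- function(msk) {
  if (is.data.frame(msk)) msk <- unlist(msk[1, , drop = TRUE])
  msk <- msk[.msk_fields]
  if (anyNA(msk))
    stop("an MSK state needs named elements ankle, knee, hip, lumbar, pelvic_tilt",
         call. = FALSE)
  msk
}

#' Enumerate the constrained sit-to-stand kinematic state grid
#'
#' Builds the Cartesian product of the 2D-model joint ranges observed during
#' the momentum-transfer phase of the sit-to-stand transfer, on a uniform
#' angular grid with the foot flat (`theta0 = 0`), and retains the states
#' whose anatomical hip and lumbar angles fall within their physiological
#' boxes. With the default ranges and 5-degree increment this yields 14,758
#' unique states.
#'
#' Grid arithmetic is integer-based (degrees), so counts are exact and the
#' lexicographic ordering over (theta1, theta2, theta3, pelvic_tilt) is
#' deterministic.
#'
#' @param theta1,theta2,theta3,pelvic_tilt length-2 numeric ranges
#'   (min, max), degrees, bounds inclusive.
#' @param hip,lumbar length-2 numeric retention constraints on the converted
#'   anatomical angles, degrees, bounds inclusive.
#' @param increment grid step, degrees; must divide every range width.
#' @param params a [segment_params] object used for the derived
#'   foot-position and pelvis-height metrics.
#'
#' @return data frame with one row per state: `state_id`, `theta0..theta3`,
#'   the MSK angles `ankle`, `knee`, `hip`, `lumbar`, `pelvic_tilt`
#'   (degrees), and the leg-length-normalized `foot_position` and
#'   `pelvis_height`.
#' @export
#' @examples
#' grid <- enumerate_states(params = default_segment_params())
#' nrow(grid)
enumerate_states <- function(theta1 = c(-40, 0), theta2 = c(75, 100),
                             theta3 = c(-150, -60), pelvic_tilt = c(-60, 20),
                             hip = c(15, 120), lumbar = c(-90, 60),
                             increment = 5,
                             params = default_segment_params()) {
  grid_seq <- function(rng, what) {
    if (length(rng) != 2L || rng[1] > rng[2])
      stop(sprintf("`%s` must be a (min, max) range", what), call. = FALSE)
    if (abs((rng[2] - rng[1]) %% increment) > 1e-9)
      stop(sprintf("`increment` (%g) must divide the width of `%s` (%g)",
                   increment, what, rng[2] - rng[1]), call. = FALSE)
    seq(rng[1], rng[2], by = increment)
  }
  # first factor varies fastest, so listing tilt first and theta1 last gives
  # lexicographic order over (theta1, theta2, theta3, pelvic_tilt)
  g <- expand.grid(pelvic_tilt = grid_seq(pelvic_tilt, "pelvic_tilt"),
                   theta3 = grid_seq(theta3, "theta3"),
                   theta2 = grid_seq(theta2, "theta2"),
                   theta1 = grid_seq(theta1, "theta1"),
                   KEEP.OUT.ATTRS = FALSE)
  g$theta0 <- 0
  g$hip <- g$theta1 + g$theta2 - g$pelvic_tilt
  g$lumbar <- g$hip + g$theta3
  keep <- g$hip >= hip[1] & g$hip <= hip[2] &
          g$lumbar >= lumbar[1] & g$lumbar <= lumbar[2]
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0L)
    stop("no kinematic state satisfies the hip and lumbar constraints for this grid",
         call. = FALSE)
  g$ankle <- -g$theta1
  g$knee <- -g$theta2
  out <- g[, c("theta0", "theta1", "theta2", "theta3",
               "ankle", "knee", "hip", "lumbar", "pelvic_tilt")]
  out$foot_position <- foot_position(out, params)
  out$pelvis_height <- pelvis_height(out, params)
  rownames(out) <- NULL
  cbind(state_id = seq_len(nrow(out)), out)
}

#' Normalized foot position
#'
#' Signed horizontal distance from the hip to the ankle,
#' `L2 sin(hip + pelvic_tilt) - L1 sin(ankle)`, normalized to leg length
#' (L1 + L2). Zero means the ankle is vertically in line with the hip;
#' positive values place the ankle anterior to the hip. The two terms are
#' the knee-to-hip and ankle-to-knee horizontal offsets: hip (plus tilt)
#' flexion carries the hip posterior to the knee, while ankle dorsiflexion
#' with the foot flat carries the knee -- and with it the hip -- anterior
#' over the ankle, so dorsiflexion reduces the anterior foot offset.
#'
#' @param msk named numeric MSK state or a data frame with columns `ankle`,
#'   `hip`, `pelvic_tilt` (degrees); vectorized over rows.
#' @param params a [segment_params] object.
#' @return unitless numeric.
#' @export
foot_position <- function(msk, params) {
  stopifnot(inherits(params, "segment_params"))
  L1 <- params$L[["shank"]]; L2 <- params$L[["thigh"]]
  v <- if (is.data.frame(msk)) msk else as.list(.as_msk(msk))
  (L2 * sin(.d2r(v$hip + v$pelvic_tilt)) - L1 * sin(.d2r(v$ankle))) / (L1 + L2)
}

#' Normalized pelvis height
#'
#' Vertical distance from the ankle to the hip,
#' `L2 cos(hip + pelvic_tilt) + L1 cos(ankle)`, normalized to leg length
#' (L1 + L2). Equals 1 with the leg fully extended vertically.
#'
#' @inheritParams foot_position
#' @return unitless numeric.
#' @export
pelvis_height <- function(msk, params) {
  stopifnot(inherits(params, "segment_params"))
  L1 <- params$L[["shank"]]; L2 <- params$L[["thigh"]]
  v <- if (is.data.frame(msk)) msk else as.list(.as_msk(msk))
  (L2 * cos(.d2r(v$hip + v$pelvic_tilt)) + L1 * cos(.d2r(v$ankle))) / (L1 + L2)
}

#' Random kinematic states for property testing
#'
#' Draws states uniformly either from the enumerated discrete grid
#' (`within_grid = TRUE`) or from the continuous joint-range boxes, with the
#' hip and lumbar retention constraints applied by rejection in both cases.
#'
#' @param n number of states.
#' @param seed integer RNG seed.
#' @param within_grid draw from the 5-degree grid (`TRUE`) or continuously.
#' @param params a [segment_params] object.
#' @return data frame in the layout of [enumerate_states()].
#' @export
random_states <- function(n, seed = 1L, within_grid = TRUE,
                          params = default_segment_params()) {
  stopifnot(n >= 1)
  set.seed(seed)
  if (within_grid) {
    grid <- enumerate_states(params = params)
    return(grid[sample.int(nrow(grid), n, replace = TRUE), , drop = FALSE])
  }
  draw <- function(m) {
    data.frame(theta0 = 0,
               theta1 = stats::runif(m, -40, 0),
               theta2 = stats::runif(m, 75, 100),
               theta3 = stats::runif(m, -150, -60),
               pelvic_tilt = stats::runif(m, -60, 20))
  }
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    d <- draw(max(2L * n, 32L))
    d$hip <- d$theta1 + d$theta2 - d$pelvic_tilt
    d$lumbar <- d$hip + d$theta3
    d <- d[d$hip >= 15 & d$hip <= 120 & d$lumbar >= -90 & d$lumbar <= 60, ]
    out <- rbind(out, d)
  }
  out <- out[seq_len(n), ]
  out$ankle <- -out$theta1
  out$knee <- -out$theta2
  out <- out[, c("theta0", "theta1", "theta2", "theta3",
                 "ankle", "knee", "hip", "lumbar", "pelvic_tilt")]
  out$foot_position <- foot_position(out, params)
  out$pelvis_height <- pelvis_height(out, params)
  rownames(out) <- NULL
  cbind(state_id = seq_len(nrow(out)), out)
}
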