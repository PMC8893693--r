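#' Define a muscle as a polyline path over body-segment frames
#'
#' A muscle (or musculotendon actuator) is an ordered series of attachment
#' points, each fixed in one of the body-segment frames `foot`, `shank`,
#' `thigh`, `pelvis` or `hat`. Frame conventions: origin at the segment's
#' proximal chain joint (foot: toe pivot O; shank: ankle; thigh: knee;
#' pelvis and HAT: hip); local +x along the segment toward its distal joint
#' (for the pelvis, superior at neutral tilt); local +y is +x rotated 90
#' degrees counter-clockwise, i.e. posterior for an upright right limb.
#'
#' @param name muscle name.
#' @param points data frame with columns `frame` (character) and `x`, `y`
#'   (m, local frame coordinates); at least two rows.
#' @param group optional functional group label (e.g. the two gastrocnemius
#'   heads share a group); defaults to `name`.
#' @return object of class `muscle_def`.
#' @export
muscle_def <- function(name, points, group = name) {
  points <- as.data.frame(points)
  if (!all(c("frame", "x", "y") %in% names(points)))
    stop("`points` needs columns frame, x, y", call. = FALSE)
  if (nrow(points) < 2L)
    stop(sprintf("muscle `%s` needs at least two path points", name), call. = FALSE)
  bad <- setdiff(points$frame, names(.frame_index))
  if (length(bad))
    stop(sprintf("muscle `%s`: unknown frame(s) %s (valid: %s)", name,
                 paste(bad, collapse = ", "),
                 paste(names(.frame_index), collapse = ", ")), call. = FALSE)
  structure(list(name = name, group = group,
                 points = points[, c("frame", "x", "y")]),
            class = "muscle_def")
}

# chain position of each attachment frame; anatomical joint c sits between
# frames c - 1 and c (1 ankle, 2 knee, 3 hip, 4 lumbar)
.frame_index <- c(foot = 0L, shank = 1L, thigh = 2L, pelvis = 3L, hat = 4L)
.joint_names <- c("ankle", "knee", "hip", "lumbar")

#' Joints spanned by a muscle
#'
#' A muscle spans anatomical joint c when its path has attachments on both
#' sides of that joint in the foot-shank-thigh-pelvis-HAT chain.
#'
#' @param muscle a [muscle_def].
#' @return character vector, subset of ankle, knee, hip, lumbar.
#' @export
spanned_joints <- function(muscle) {
  idx <- .frame_index[muscle$points$frame]
  .joint_names[vapply(1:4, function(c) any(idx <= c - 1L) && any(idx >= c),
                      logical(1))]
}

# Segment frames (origin, orientation) parameterized by the anatomical joint
# angles, each varying independently with the others held fixed. Orientation
# angles are world CCW angles of the local +x axis.
.msk_frames <- function(msk, params, theta0 = 0) {
  th0 <- .d2r(theta0)
  ank <- .d2r(msk[["ankle"]]); kne <- .d2r(msk[["knee"]])
  hip <- .d2r(msk[["hip"]]);   lum <- .d2r(msk[["lumbar"]])
  phi_f <- th0
  A <- params$L[["foot"]] * c(cos(th0 + pi / 2), sin(th0 + pi / 2))
  phi_s <- th0 - ank + pi / 2
  K <- A + params$L[["shank"]] * c(cos(phi_s), sin(phi_s))
  phi_t <- phi_s - kne
  H <- K + params$L[["thigh"]] * c(cos(phi_t), sin(phi_t))
  phi_p <- phi_t - hip
  phi_h <- phi_p + lum
  list(origins = list(foot = c(0, 0), shank = A, thigh = K,
                      pelvis = H, hat = H),
       angles = c(foot = phi_f, shank = phi_s, thigh = phi_t,
                  pelvis = phi_p, hat = phi_h),
       joint_origins = list(ankle = A, knee = K, hip = H, lumbar = H),
       # sense of frame rotation per unit increase of each joint angle
       joint_sign = c(ankle = -1, knee = -1, hip = -1, lumbar = 1))
}

# world coordinates (n x 2) of a muscle's path points for a given MSK state
.muscle_world_points <- function(muscle, frames) {
  pts <- muscle$points
  out <- matrix(NA_real_, nrow(pts), 2)
  for (i in seq_len(nrow(pts))) {
    fr <- pts$frame[i]
    out[i, ] <- .place_points(cbind(pts$x[i], pts$y[i]),
                              frames$origins[[fr]], frames$angles[[fr]])
  }
  out
}

#' Musculotendon path length
#'
#' Total polyline length of a muscle path in a given kinematic state.
#'
#' @param muscle a [muscle_def].
#' @param msk named MSK state (degrees), see [to_msk()].
#' @param params a [segment_params] object.
#' @param theta0 base (foot) angle, degrees.
#' @return length in m.
#' @export
muscle_length <- function(muscle, msk, params, theta0 = 0) {
  msk <- .as_msk(msk)
  frames <- .msk_frames(msk, params, theta0)
  W <- .muscle_world_points(muscle, frames)
  seg <- diff(W)
  lens <- sqrt(rowSums(seg^2))
  if (any(lens < 1e-12))
    stop(sprintf("muscle `%s` has a degenerate zero-length path segment", muscle$name),
         call. = FALSE)
  sum(lens)
}

#' Tendon-excursion moment arms of a muscle
#'
#' Moment arm about each anatomical joint as minus the partial derivative of
#' the musculotendon path length with respect to that joint angle, the other
#' joint angles held fixed. For polyline paths the derivative is evaluated
#' analytically (each joint rotation moves the attachment points distal to
#' the joint along circles about the joint centre); a central-difference
#' evaluation with a 0.1 degree step is available for cross-checking.
#'
#' Signs follow the anatomical convention: a positive moment arm produces
#' torque toward positive dorsiflexion / knee extension / hip flexion /
#' lumbar extension.
#'
#' @inheritParams muscle_length
#' @param method `"analytic"` (default) or `"fd"`.
#' @param fd_step finite-difference step in degrees (method `"fd"`).
#' @return named numeric length-4 vector (ankle, knee, hip, lumbar), m/rad;
#'   exact zeros at joints the muscle does not span.
#' @export
geometric_moment_arms <- function(muscle, msk, params, theta0 = 0,
                                  method = c("analytic", "fd"),
                                  fd_step = 0.1) {
  method <- match.arg(method)
  msk <- .as_msk(msk)
  spanned <- spanned_joints(muscle)
  ma <- setNames(numeric(4), .joint_names)
  if (method == "fd") {
    h <- .d2r(fd_step)
    for (jn in spanned) {
      up <- dn <- msk
      up[[jn]] <- up[[jn]] + fd_step
      dn[[jn]] <- dn[[jn]] - fd_step
      ma[[jn]] <- -(muscle_length(muscle, up, params, theta0) -
                    muscle_length(muscle, dn, params, theta0)) / (2 * h)
    }
    return(ma)
  }
  frames <- .msk_frames(msk, params, theta0)
  W <- .muscle_world_points(muscle, frames)
  idx <- .frame_index[muscle$points$frame]
  seg <- diff(W)
  lens <- sqrt(rowSums(seg^2))
  if (any(lens < 1e-12))
    stop(sprintf("muscle `%s` has a degenerate zero-length path segment", muscle$name),
         call. = FALSE)
  U <- seg / lens
  for (jn in spanned) {
    c_idx <- match(jn, .joint_names)
    o <- frames$joint_origins[[jn]]
    s <- frames$joint_sign[[jn]]
    # velocity of each path point per unit joint-angle rate
    dW <- matrix(0, nrow(W), 2)
    moving <- idx >= c_idx
    if (any(moving))
      dW[moving, ] <- s * cbind(-(W[moving, 2] - o[2]), W[moving, 1] - o[1])
    dlen <- sum(U * (dW[-1, , drop = FALSE] - dW[-nrow(W), , drop = FALSE]))
    ma[[jn]] <- -dlen
  }
  ma
}

#' Map anatomical-joint moment arms to generalized coordinates
#'
#' Transforms a moment-arm matrix over the anatomical joints into one over
#' the generalized coordinates theta0..theta3 via the constant Jacobian of
#' the 2D-to-MSK angle map, with pelvic tilt held fixed (it is a posture
#' parameter, not a generalized coordinate). A generalized moment-arm column
#' equals minus the gradient of musculotendon length with respect to the
#' generalized coordinates.
#'
#' @param R_msk 4 x m numeric matrix, rows ankle, knee, hip, lumbar (m/rad).
#' @return 4 x m numeric matrix, rows theta0..theta3 (m/rad).
#' @export
map_to_generalized <- function(R_msk) {
  R_msk <- as.matrix(R_msk)
  if (nrow(R_msk) != 4L)
    stop("`R_msk` must have 4 rows (ankle, knee, hip, lumbar)", call. = FALSE)
  # rows: d(msk angle)/d(theta_j); columns theta0..theta3
  Amap <- rbind(ankle  = c(0, -1,  0, 0),
                knee   = c(0,  0, -1, 0),
                hip    = c(1,  1,  1, 0),
                lumbar = c(1,  1,  1, 1))
  R_gen <- t(Amap) %*% R_msk
  rownames(R_gen) <- paste0("theta", 0:3)
  R_gen
}

#' Geometric moment-arm provider
#'
#' Wraps a list of [muscle_def]s into a provider closure: a function taking
#' an MSK state and returning the 4 x m anatomical moment-arm matrix, with
#' muscle names as columns and a `groups` attribute for aggregation.
#'
#' @param muscles list of [muscle_def]s.
#' @param params a [segment_params] object.
#' @return function `(msk) -> R_msk` with attribute `groups`.
#' @export
geometric_provider <- function(muscles, params) {
  stopifnot(length(muscles) >= 1L)
  nm <- vapply(muscles, `[[`, character(1), "name")
  gr <- vapply(muscles, `[[`, character(1), "group")
  f <- function(msk) {
    msk <- .as_msk(msk)
    R <- vapply(muscles, geometric_moment_arms, numeric(4),
                msk = msk, params = params)
    dimnames(R) <- list(.joint_names, nm)
    R
  }
  structure(f, groups = setNames(gr, nm))
}

#' Tabulate moment arms over the anatomical joint-angle ranges
#'
#' Evaluates the geometric moment arms of a set of muscles on a regular grid
#' of the joint angles each muscle spans, producing the long-format table
#' consumed by [tabulated_provider()] (and writable with
#' [write_moment_arm_table()]). Angles a muscle does not span are left `NA`
#' in its rows.
#'
#' @param muscles list of [muscle_def]s.
#' @param params a [segment_params] object.
#' @param ranges named list of (min, max) ranges in degrees for `ankle`,
#'   `knee`, `hip`, `lumbar`; defaults to the enumerated sit-to-stand ranges.
#' @param step grid step, degrees.
#' @return data frame with columns `muscle`, `group`, `joint`, `ankle`,
#'   `knee`, `hip`, `lumbar`, `moment_arm_m`.
#' @export
tabulate_moment_arms <- function(muscles, params,
                                 ranges = list(ankle = c(0, 40),
                                               knee = c(-100, -75),
                                               hip = c(15, 120),
                                               lumbar = c(-90, 60)),
                                 step = 5) {
  rows <- list()
  for (mus in muscles) {
    span <- spanned_joints(mus)
    axes <- lapply(ranges[span], function(r) seq(r[1], r[2], by = step))
    g <- do.call(expand.grid, c(axes, list(KEEP.OUT.ATTRS = FALSE)))
    base <- setNames(rep(0, 5), .msk_fields)  # unspanned angles: neutral
    for (i in seq_len(nrow(g))) {
      msk <- base
      msk[span] <- unlist(g[i, span])
      ma <- geometric_moment_arms(mus, msk, params)
      for (jn in span) {
        row <- data.frame(muscle = mus$name, group = mus$group, joint = jn,
                          ankle = NA_real_, knee = NA_real_,
                          hip = NA_real_, lumbar = NA_real_,
                          moment_arm_m = ma[[jn]])
        row[span] <- as.list(g[i, span])
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# recursive multilinear interpolation on a full factorial grid
.interp_nd <- function(axes, values, x) {
  if (length(axes) == 0L) return(as.numeric(values))
  a <- axes[[1]]
  q <- x[[1]]
  if (q < min(a) - 1e-9 || q > max(a) + 1e-9)
    stop(sprintf("query angle %.3f deg is outside the tabulated range [%g, %g]; extrapolation is not supported",
                 q, min(a), max(a)), call. = FALSE)
  q <- min(max(q, min(a)), max(a))
  i <- findInterval(q, a, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(a) - 1L)
  if (length(a) == 1L) i <- 1L
  slice <- function(k) {
    if (is.null(dim(values))) values[[k]]
    else do.call(`[`, c(list(values, k), rep(list(quote(expr = )),
                                             length(dim(values)) - 1L)))
  }
  if (length(a) == 1L)
    return(.interp_nd(axes[-1], slice(1L), x[-1]))
  t <- (q - a[i]) / (a[i + 1L] - a[i])
  v0 <- .interp_nd(axes[-1], slice(i), x[-1])
  v1 <- .interp_nd(axes[-1], slice(i + 1L), x[-1])
  (1 - t) * v0 + t * v1
}

#' Tabulated moment-arm provider
#'
#' Builds a provider closure from a long-format moment-arm table (e.g. one
#' exported from a musculoskeletal modeling tool, or produced by
#' [tabulate_moment_arms()]). Each (muscle, joint) block must cover a full
#' factorial grid of its angle columns; queries use multilinear
#' interpolation, exact at the grid nodes, and refuse to extrapolate.
#'
#' @param table data frame with columns `muscle`, `joint`, `moment_arm_m`
#'   (meters), optionally `group`, and one column per anatomical angle
#'   (degrees) the moment arm depends on (`NA` where irrelevant).
#' @return function `(msk) -> R_msk` with attribute `groups`.
#' @export
tabulated_provider <- function(table) {
  table <- as.data.frame(table)
  need <- c("muscle", "joint", "moment_arm_m")
  if (!all(need %in% names(table)))
    stop("moment-arm table needs columns muscle, joint, moment_arm_m", call. = FALSE)
  if (is.null(table$group)) table$group <- table$muscle
  muscles <- unique(table$muscle)
  groups <- setNames(table$group[match(muscles, table$muscle)], muscles)

  blocks <- list()
  for (mn in muscles) {
    for (jn in unique(table$joint[table$muscle == mn])) {
      blk <- table[table$muscle == mn & table$joint == jn, , drop = FALSE]
      deps <- .joint_names[vapply(.joint_names, function(a)
        a %in% names(blk) && any(!is.na(blk[[a]])), logical(1))]
      if (length(deps) && any(is.na(blk[deps])))
        stop(sprintf("moment-arm table for %s/%s mixes NA and non-NA angle values",
                     mn, jn), call. = FALSE)
      axes <- lapply(deps, function(a) sort(unique(blk[[a]])))
      names(axes) <- deps
      n_nodes <- prod(vapply(axes, length, integer(1)))
      if (nrow(blk) != n_nodes)
        stop(sprintf("moment-arm table for %s/%s is not a full factorial grid (%d rows, expected %d)",
                     mn, jn, nrow(blk), n_nodes), call. = FALSE)
      if (length(deps)) {
        ord <- do.call(order, rev(blk[deps]))  # first axis varies fastest
        arr <- array(blk$moment_arm_m[ord],
                     dim = vapply(axes, length, integer(1)))
      } else {
        arr <- blk$moment_arm_m[1]
      }
      blocks[[paste(mn, jn, sep = "\r")]] <-
        list(muscle = mn, joint = jn, axes = axes, values = arr)
    }
  }

  f <- function(msk) {
    msk <- .as_msk(msk)
    R <- matrix(0, 4, length(muscles),
                dimnames = list(.joint_names, muscles))
    for (b in blocks) {
      x <- as.list(msk[names(b$axes)])
      R[b$joint, b$muscle] <- .interp_nd(b$axes, b$values, x)
    }
    R
  }
  structure(f, groups = groups)
}

#' Read a muscle-geometry definition from JSON
#'
#' @param path JSON file: an object with a `muscles` array, each entry
#'   having `name`, optional `group`, and `points` (array of objects with
#'   `frame`, `x`, `y` in meters, local segment-frame coordinates).
#' @return list of [muscle_def]s.
#' @export
read_muscles <- function(path) {
  if (!file.exists(path)) stop(sprintf("muscle file not found: %s", path), call. = FALSE)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(js$muscles)) stop(sprintf("%s: missing `muscles` array", path), call. = FALSE)
  ms <- js$muscles
  lapply(seq_len(nrow(ms)), function(i) {
    muscle_def(name = ms$name[i],
               points = as.data.frame(ms$points[[i]]),
               group = if (!is.null(ms$group)) ms$group[i] else ms$name[i])
  })
}

#' Default synthetic muscle set
#'
#' Loads the bundled synthetic sagittal-plane path fixture for the seven
#' analyzed lower-limb muscles (gluteus maximus, biceps femoris long head,
#' rectus femoris, vasti, medial and lateral gastrocnemius, soleus,
#' tibialis anterior; eight actuators, the gastrocnemius contributing two
#' heads to one group). Attachment coordinates are original anatomically
#' plausible approximations, not taken from any subject or published
#' musculoskeletal model; analyses that depend on them are qualitative
#' (signs and trends), not exact-numeric.
#'
#' @return list of [muscle_def]s.
#' @export
default_muscles <- function() {
  read_muscles(system.file("extdata", "muscles_synthetic.json",
                           package = "iaa2d", mustWork = TRUE))
}
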