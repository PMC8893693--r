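#' Segment parameters of the four-link sagittal-plane model
#'
#' Construct the inertial and geometric parameters of the planar body model.
#' The chain is pinned at the toe pivot O and consists of link 0 (foot),
#' link 1 (shank, ankle A to knee K), link 2 (thigh, K to hip H) and link 3
#' (lumped head-arms-torso, HAT, including the pelvis mass).
#'
#' The foot is a rigid triangle with vertices at the posterior calcaneus C,
#' the distal toe T and the ankle A, expressed in the foot frame whose origin
#' O lies on the ground line CT directly below A (so that OA is perpendicular
#' to CT). The foot centre of mass is given as a point in that frame; its
#' polar form (distance `r0` and angle `theta_c` from CT) is derived here.
#'
#' @param masses numeric length-4, link masses in kg (foot, shank, thigh, HAT).
#' @param lengths numeric length-4, in m: `L0` (O to A), `L1` (A to K),
#'   `L2` (K to H) and the HAT reference length `L3` (used only to validate
#'   the HAT centre-of-mass offset).
#' @param com_offsets numeric length-4, distance from each link's proximal
#'   joint to its centre of mass, m. The foot entry is derived from
#'   `foot_com` and may be `NA` on input.
#' @param inertias numeric length-4, moments of inertia about each link's
#'   centre of mass (z axis), kg m^2.
#' @param foot_triangle list with numeric length-2 entries `C`, `T`, `A`:
#'   the foot vertices in the foot frame, m. `C` and `T` must lie on the
#'   ground line (y = 0) with `C` posterior to O and `T` anterior; `A` must
#'   lie directly above O.
#' @param foot_com numeric length-2, foot centre of mass in the foot frame, m.
#'
#' @return An object of class `segment_params`: a list with elements `m`,
#'   `L`, `r`, `I` (named numeric length-4 vectors), `theta_c` (rad),
#'   `foot_triangle` and `foot_com`.
#' @export
#' @examples
#' p <- default_segment_params()
#' sum(p$m)          # total body mass, kg
#' p$L[["shank"]] + p$L[["thigh"]]  # leg length, m
segment_params <- function(masses, lengths, com_offsets, inertias,
                           foot_triangle, foot_com) {
  link_names <- c("foot", "shank", "thigh", "hat")
  chk_len <- function(x, what) {
    if (!is.numeric(x) || length(x) != 4L)
      stop(sprintf("`%s` must be a numeric vector of length 4 (foot, shank, thigh, hat)", what),
           call. = FALSE)
    setNames(as.numeric(x), link_names)
  }
  m <- chk_len(masses, "masses")
  L <- chk_len(lengths, "lengths")
  I <- chk_len(inertias, "inertias")

  if (!is.list(foot_triangle) || !all(c("C", "T", "A") %in% names(foot_triangle)))
    stop("`foot_triangle` must be a list with elements C, T and A", call. = FALSE)
  C <- as.numeric(foot_triangle$C); Tt <- as.numeric(foot_triangle$T)
  A <- as.numeric(foot_triangle$A)
  if (abs(C[2]) > 1e-9 || abs(Tt[2]) > 1e-9)
    stop("foot vertices C and T must lie on the ground line (y = 0)", call. = FALSE)
  if (abs(A[1]) > 1e-9)
    stop("the ankle vertex A must lie directly above the origin O (x = 0), so that OA is perpendicular to CT",
         call. = FALSE)
  if (!(C[1] < 0 && Tt[1] > 0))
    stop("the origin O must lie between C (x < 0) and T (x > 0)", call. = FALSE)
  if (A[2] <= 0) stop("the ankle A must be above the ground (A[2] > 0)", call. = FALSE)
  if (abs(A[2] - L[["foot"]]) > 1e-9)
    stop(sprintf("L0 (%.4f) must equal the height of the ankle vertex A (%.4f)",
                 L[["foot"]], A[2]), call. = FALSE)

  foot_com <- as.numeric(foot_com)
  r0 <- sqrt(sum(foot_com^2))
  theta_c <- atan2(foot_com[2], foot_com[1])
  r <- chk_len(com_offsets, "com_offsets")
  r[["foot"]] <- r0

  if (any(m < 0)) stop("link masses must be non-negative", call. = FALSE)
  if (any(L <= 0)) stop("link lengths must be positive", call. = FALSE)
  if (any(I < 0)) stop("link inertias must be non-negative", call. = FALSE)
  bad <- which(r < 0 | r > L)
  if (length(bad))
    stop(sprintf("centre-of-mass offsets must satisfy 0 <= r <= L; violated for: %s",
                 paste(link_names[bad], collapse = ", ")), call. = FALSE)

  structure(list(m = m, L = L, r = r, I = I, theta_c = theta_c,
                 foot_triangle = list(C = C, T = Tt, A = A),
                 foot_com = foot_com),
            class = "segment_params")
}

#' @export
print.segment_params <- function(x, ...) {
  cat("Four-link sagittal-plane segment parameters\n")
  df <- data.frame(mass_kg = x$m, length_m = x$L, com_offset_m = x$r,
                   inertia_kgm2 = x$I)
  print(round(df, 4))
  cat(sprintf("total mass %.1f kg; leg length (L1 + L2) %.3f m; theta_c %.1f deg\n",
              sum(x$m), x$L[["shank"]] + x$L[["thigh"]], .r2d(x$theta_c)))
  invisible(x)
}

#' Lump rigid-body segments into one equivalent segment
#'
#' Combines several rigidly connected segments (e.g. torso + pelvis into the
#' HAT, or talus + calcaneus + toes into the foot) into a single mass, centre
#' of mass and moment of inertia, using the mass-weighted mean position and
#' the parallel-axis theorem.
#'
#' @param masses numeric vector of segment masses, kg.
#' @param coms segment centre-of-mass positions in a common frame: a numeric
#'   matrix with one row per segment and 2 columns (x, y in m), or a numeric
#'   vector for collinear segments.
#' @param inertias numeric vector of segment moments of inertia about their
#'   own centres of mass, kg m^2.
#'
#' @return list with `mass` (kg), `com` (length-2, m) and `inertia` (kg m^2,
#'   about the lumped centre of mass).
#' @export
#' @examples
#' # two equal point masses at x = 0 and x = 2
#' lump_segments(c(1, 1), c(0, 2), c(0, 0))
lump_segments <- function(masses, coms, inertias) {
  masses <- as.numeric(masses)
  inertias <- as.numeric(inertias)
  if (is.null(dim(coms))) coms <- cbind(as.numeric(coms), 0)
  coms <- as.matrix(coms)
  n <- length(masses)
  if (n < 1L) stop("at least one segment is required", call. = FALSE)
  if (nrow(coms) != n || length(inertias) != n)
    stop("`masses`, `coms` and `inertias` must describe the same number of segments",
         call. = FALSE)
  total <- sum(masses)
  if (total <= 0)
    stop("total lumped mass must be positive (the combined centre of mass is undefined otherwise)",
         call. = FALSE)
  com <- colSums(coms * masses) / total
  d2 <- rowSums(sweep(coms, 2, com)^2)
  list(mass = total, com = com, inertia = sum(inertias + masses * d2))
}

# Cumulative link direction angles (rad) for a 2D state given in radians:
# link k (k >= 1) points along sum(theta_0..theta_{k-1 adjusted}) + 90 deg.
# Index i of the returned vector is the direction of the vector leaving
# joint i (O->A for i = 1, A->K for 2, K->H for 3, H->HAT-COM for 4).
.link_dirs <- function(th) cumsum(th) + pi / 2

#' Forward kinematics of the four-link model
#'
#' Computes the planar positions of the joints (O, A, K, H), the link centres
#' of mass and the whole-body centre of mass for a kinematic state, in the
#' ground frame of the model (origin at the toe pivot O, +X anterior,
#' +Y superior).
#'
#' @param theta numeric length-4, generalized coordinates
#'   (theta0..theta3) in degrees.
#' @param params a [segment_params] object.
#'
#' @return list with `joints` (2 x 4 matrix, columns O, A, K, H),
#'   `link_coms` (2 x 4 matrix, columns foot, shank, thigh, hat) and `com`
#'   (length-2 whole-body centre of mass), all in m.
#' @export
#' @examples
#' fk <- forward_kinematics(c(0, 0, 90, -90), default_segment_params())
#' fk$joints[, "H"]   # hip position in the sitting reference posture
forward_kinematics <- function(theta, params) {
  stopifnot(inherits(params, "segment_params"))
  th <- .d2r(as.numeric(theta))
  if (length(th) != 4L) stop("`theta` must have length 4", call. = FALSE)
  a <- .link_dirs(th)                  # directions of OA, AK, KH, H->HAT com
  O <- c(0, 0)
  A <- O + params$L[["foot"]]  * c(cos(a[1]), sin(a[1]))
  K <- A + params$L[["shank"]] * c(cos(a[2]), sin(a[2]))
  H <- K + params$L[["thigh"]] * c(cos(a[3]), sin(a[3]))
  com0 <- params$r[["foot"]] * c(cos(th[1] + params$theta_c),
                                 sin(th[1] + params$theta_c))
  com1 <- A + params$r[["shank"]] * c(cos(a[2]), sin(a[2]))
  com2 <- K + params$r[["thigh"]] * c(cos(a[3]), sin(a[3]))
  com3 <- H + params$r[["hat"]]   * c(cos(a[4]), sin(a[4]))
  link_coms <- cbind(foot = com0, shank = com1, thigh = com2, hat = com3)
  rownames(link_coms) <- c("x", "y")
  joints <- cbind(O = O, A = A, K = K, H = H)
  rownames(joints) <- c("x", "y")
  com <- as.numeric(link_coms %*% params$m) / sum(params$m)
  list(joints = joints, link_coms = link_coms, com = com)
}

#' Read model parameters from a YAML file
#'
#' Parses a model parameter file with one block per link (`mass_kg`,
#' `length_m` / `ref_length_m`, `com_offset_m` or `com_m`, `inertia_kgm2`)
#' plus the foot-triangle vertices, validating the schema with explicit
#' error messages. See `system.file("extdata", "generic_model.yaml",
#' package = "iaa2d")` for the documented layout.
#'
#' @param path path to the YAML file.
#' @return a [segment_params] object.
#' @export
read_model_params <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$links))
    stop(sprintf("%s: missing top-level `links` block", path), call. = FALSE)
  need <- c("foot", "shank", "thigh", "hat")
  missing_links <- setdiff(need, names(cfg$links))
  if (length(missing_links))
    stop(sprintf("%s: missing link definitions: %s", path,
                 paste(missing_links, collapse = ", ")), call. = FALSE)
  get_field <- function(link, field) {
    v <- cfg$links[[link]][[field]]
    if (is.null(v))
      stop(sprintf("%s: link `%s` is missing field `%s`", path, link, field),
           call. = FALSE)
    as.numeric(v)
  }
  if (is.null(cfg$foot_triangle))
    stop(sprintf("%s: missing `foot_triangle` block (vertices C, T, A)", path),
         call. = FALSE)
  foot_com <- get_field("foot", "com_m")
  if (length(foot_com) != 2L)
    stop(sprintf("%s: foot `com_m` must be an [x, y] pair", path), call. = FALSE)
  tri <- lapply(cfg$foot_triangle, as.numeric)
  segment_params(
    masses      = vapply(need, get_field, numeric(1), field = "mass_kg"),
    lengths     = c(tri$A[2],
                    get_field("shank", "length_m"),
                    get_field("thigh", "length_m"),
                    get_field("hat", "ref_length_m")),
    com_offsets = c(NA_real_,
                    get_field("shank", "com_offset_m"),
                    get_field("thigh", "com_offset_m"),
                    get_field("hat", "com_offset_m")),
    inertias    = vapply(need, get_field, numeric(1), field = "inertia_kgm2"),
    foot_triangle = tri,
    foot_com    = foot_com
  )
}

#' Default generic-adult segment parameters
#'
#' Loads the bundled synthetic anthropometric fixture. Per-link values follow
#' standard anthropometric proportion tables, with both legs lumped into the
#' single modeled limb and the pelvis lumped into the HAT; the totals are
#' constrained to a 75.2 kg body mass and a 0.826 m leg length (L1 + L2).
#' These are generic values, not subject-specific measurements; override
#' them with [read_model_params()] and your own file.
#'
#' @return a [segment_params] object.
#' @export
default_segment_params <- function() {
  read_model_params(system.file("extdata", "generic_model.yaml",
                                package = "iaa2d", mustWork = TRUE))
}
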