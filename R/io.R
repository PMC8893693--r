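# CSV writers share a commented preamble carrying column descriptions and
# units, so every table is self-documenting; readers skip '#' lines.

.write_commented_csv <- function(df, path, preamble) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", preamble), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write / read a kinematic state grid
#'
#' CSV round trip for the output of [enumerate_states()]: angles in degrees,
#' derived metrics unitless, with a commented header preamble.
#'
#' @param grid data frame from [enumerate_states()].
#' @param path file path.
#' @return `write_state_grid` returns the path invisibly; `read_state_grid`
#'   returns the data frame.
#' @export
write_state_grid <- function(grid, path) {
  .write_commented_csv(grid, path, c(
    "kinematic state grid of the four-link sagittal model",
    "theta0..theta3: 2D-model generalized coordinates, degrees",
    "ankle, knee, hip, lumbar, pelvic_tilt: anatomical (MSK) angles, degrees;",
    "  positive = dorsiflexion, knee extension, hip flexion, lumbar extension,",
    "  posterior pelvic tilt",
    "foot_position, pelvis_height: normalized to leg length (L1 + L2), unitless"))
}

#' @rdname write_state_grid
#' @export
read_state_grid <- function(path) {
  read.csv(path, comment.char = "#")
}

#' Write a muscle-potential table
#'
#' @param potentials long table from [sweep_potentials()] or
#'   [muscle_potentials()].
#' @param path file path.
#' @export
write_potentials <- function(potentials, path) {
  .write_commented_csv(potentials, path, c(
    "muscle potentials of the four-link sagittal model",
    "support_potential: induced vertical (+Y) COM acceleration per Newton, m/(N s^2)",
    "progression_potential: induced anteroposterior (+X) COM acceleration per Newton, m/(N s^2)",
    "angles in degrees; foot_position / pelvis_height normalized to leg length"))
}

#' Write / read a long-format moment-arm table
#'
#' @param table data frame from [tabulate_moment_arms()] (or an export from
#'   any musculoskeletal modeling tool in the same layout).
#' @param path file path.
#' @export
write_moment_arm_table <- function(table, path) {
  .write_commented_csv(table, path, c(
    "tabulated muscle moment arms",
    "joint: anatomical joint of the moment arm (ankle, knee, hip, lumbar)",
    "ankle, knee, hip, lumbar: grid angles in degrees (NA = not a dependency)",
    "moment_arm_m: moment arm in meters (per radian); positive toward",
    "  dorsiflexion / knee extension / hip flexion / lumbar extension"))
}

#' @rdname write_moment_arm_table
#' @export
read_moment_arm_table <- function(path) {
  read.csv(path, comment.char = "#")
}

#' Write a correlation report
#'
#' @param report data frame from [correlation_analysis()].
#' @param path file path.
#' @export
write_correlation_report <- function(report, path) {
  .write_commented_csv(report, path, c(
    "Pearson correlations (after rank-based inverse normal transform) between",
    "muscle potentials and kinematic modifications across all enumerated states",
    "r: correlation coefficient; p: two-sided p-value; category: strength band"))
}

#' Write the self-contained fixture bundle
#'
#' Writes every input needed to run the tool with no external data: the
#' generic model parameter file (YAML), the synthetic muscle-geometry
#' fixture (JSON), a moment-arm table generated from that geometry over the
#' anatomical joint ranges at 5-degree steps (CSV), and a small JSON
#' manifest recording the seed. Regeneration with the same seed is
#' byte-identical.
#'
#' @param dir output directory (created if missing).
#' @param seed integer recorded in the manifest and used for any randomized
#'   fixture content (the bundled fixtures themselves are deterministic).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  model_src <- system.file("extdata", "generic_model.yaml",
                           package = "iaa2d", mustWork = TRUE)
  muscle_src <- system.file("extdata", "muscles_synthetic.json",
                            package = "iaa2d", mustWork = TRUE)
  paths <- c(model = file.path(dir, "generic_model.yaml"),
             muscles = file.path(dir, "muscles_synthetic.json"),
             moment_arms = file.path(dir, "moment_arms_synthetic.csv"),
             manifest = file.path(dir, "manifest.json"))
  file.copy(model_src, paths[["model"]], overwrite = TRUE)
  file.copy(muscle_src, paths[["muscles"]], overwrite = TRUE)
  params <- read_model_params(paths[["model"]])
  muscles <- read_muscles(paths[["muscles"]])
  tab <- tabulate_moment_arms(muscles, params)
  tab$moment_arm_m <- signif(tab$moment_arm_m, 12)
  write_moment_arm_table(tab, paths[["moment_arms"]])
  jsonlite::write_json(
    list(seed = seed,
         files = as.list(basename(paths[setdiff(names(paths), "manifest")])),
         description = paste("synthetic fixture bundle for the four-link",
                             "sagittal induced-acceleration model")),
    paths[["manifest"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
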