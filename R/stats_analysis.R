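#' Rank-based inverse normal transform
#'
#' Replaces each value by the normal quantile of its fractional rank,
#' `qnorm((rank - offset) / (n - 2 * offset + 1))`, with the Blom offset
#' 3/8 by default and average ranks for ties. Applied to both variables of
#' a correlation, this makes the subsequent Pearson coefficient invariant
#' under any strictly increasing transform of either variable.
#'
#' @param x numeric vector, length >= 3, not all equal.
#' @param offset rank offset; 3/8 (Blom) by default.
#' @return numeric vector of normal scores.
#' @export
#' @examples
#' rank_inverse_normal(c(10, 2, 5))  # middle value maps to 0
rank_inverse_normal <- function(x, offset = 3 / 8) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("`x` must not contain NA", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("`x` needs at least 3 values", call. = FALSE)
  if (diff(range(x)) == 0)
    stop("all values of `x` are identical; ranks (and the transform) are undefined",
         call. = FALSE)
  r <- rank(x, ties.method = "average")
  qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Pearson correlation with t-based p-value
#'
#' Standard product-moment correlation and its two-sided p-value from the t
#' distribution with n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with elements `r` and `p`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("at least 3 observations are required", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: the Pearson correlation is undefined", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Categorize a correlation coefficient by strength
#'
#' Labels the magnitude of a correlation: very weak (|r| < 0.2), weak
#' (0.20 <= |r| <= 0.39), moderate (0.40 <= |r| <= 0.59), strong
#' (0.60 <= |r| <= 0.79) and very strong (|r| >= 0.8). Bands are applied to
#' the magnitude; the sign is reported separately in the analysis tables.
#'
#' @param r numeric vector of correlation coefficients in [-1, 1].
#' @return character vector of labels.
#' @export
categorize_correlation <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("|r| must not exceed 1", call. = FALSE)
  cut(abs(r), breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf), right = FALSE,
      labels = c("very weak", "weak", "moderate", "strong", "very strong"))
}

#' Correlation analysis of muscle potentials versus kinematic modifications
#'
#' For every muscle group, task (support, progression) and kinematic
#' modifier (foot position, pelvis height, lumbar flexion, pelvic tilt),
#' applies the rank-based inverse normal transform to both the potential and
#' the modifier across all states of a sweep and computes the Pearson
#' correlation, its p-value and its strength category. With the seven
#' bundled muscle groups this emits the 56-row report layout of the
#' sensitivity analysis.
#'
#' Positive coefficients mean the potential increases with a more anterior
#' foot position, a higher pelvis, greater lumbar flexion, or more posterior
#' pelvic tilt. A constant potential column (undefined ranks) is flagged in
#' the `note` column rather than failing the whole analysis.
#'
#' @param sweep long table from [sweep_potentials()], normally over the full
#'   enumerated state grid.
#' @param modifiers kinematic modifiers to test.
#' @param alpha significance level recorded in the `significant` column.
#' @param collapse collapse actuators to muscle groups first.
#' @return data frame with columns `muscle`, `task`, `modifier`, `r`, `p`,
#'   `category`, `significant`, `note`.
#' @export
correlation_analysis <- function(sweep,
                                 modifiers = c("foot_position", "pelvis_height",
                                               "lumbar_flexion", "pelvic_tilt"),
                                 alpha = 0.05, collapse = TRUE) {
  if (collapse) sweep <- collapse_groups(sweep)
  muscles <- unique(sweep$muscle)
  rows <- list()
  for (mus in muscles) {
    sub <- sweep[sweep$muscle == mus, ]
    for (task in c("support", "progression")) {
      pot <- sub[[paste0(task, "_potential")]]
      for (mod in modifiers) {
        val <- .modifier_values(sub, mod)
        res <- tryCatch({
          ct <- pearson_cor(rank_inverse_normal(pot), rank_inverse_normal(val))
          list(r = ct$r, p = ct$p, note = "")
        }, error = function(e) list(r = NA_real_, p = NA_real_,
                                    note = conditionMessage(e)))
        rows[[length(rows) + 1L]] <-
          data.frame(muscle = mus, task = task, modifier = mod,
                     r = res$r, p = res$p,
                     category = as.character(categorize_correlation(res$r)),
                     significant = !is.na(res$p) & res$p < alpha,
                     note = res$note)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lilliefors test for normality
#'
#' Kolmogorov-Smirnov test with estimated mean and variance, using the
#' Dallal-Wilkinson approximation for the p-value. Offered as an optional
#' diagnostic for potential distributions before the rank-based transform
#' (the analysis pipeline applies the transform regardless).
#'
#' @param x numeric vector, length >= 5.
#' @return list with `statistic` (D) and `p` (approximate p-value, capped
#'   to [0, 1]).
#' @export
lilliefors_test <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 5L) stop("at least 5 observations are required", call. = FALSE)
  if (sd(x) == 0) stop("zero variance: normality test is undefined", call. = FALSE)
  z <- (x - mean(x)) / sd(x)
  p_hat <- stats::pnorm(z)
  D <- max(pmax(seq_len(n) / n - p_hat, p_hat - (seq_len(n) - 1) / n))
  # Dallal & Wilkinson (1986) approximation
  nd <- if (n > 100) 100 else n
  Dd <- if (n > 100) D * (n / 100)^0.49 else D
  p <- exp(-7.01256 * Dd^2 * (nd + 2.78019) +
             2.99587 * Dd * sqrt(nd + 2.78019) - 0.122119 +
             0.974598 / sqrt(nd) + 1.67997 / nd)
  list(statistic = D, p = min(max(p, 0), 1))
}
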