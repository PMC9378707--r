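#' Shift component scores to positivity for log transformation
#'
#' Scores include negative values, so before the log-log regression each
#' component's scores are shifted by `offset = round(|min(scores)|) + 1`
#' when the minimum is negative (plain `+1` otherwise). Rounding is
#' half-up by default; the direction is configurable since the convention
#' is a choice (`"ceiling"` always rounds up).
#'
#' @param scores numeric vector.
#' @param rounding `"half_up"` (default) or `"ceiling"`.
#' @return list with `shifted` (all > 0, order preserved) and `offset`.
#' @export
shift_scores <- function(scores, rounding = c("half_up", "ceiling")) {
  if (length(scores) == 0L) stop("empty score vector")
  rounding <- match.arg(rounding)
  mn <- min(scores)
  if (mn < 0) {
    r <- switch(rounding,
                half_up = floor(abs(mn) + 0.5),
                ceiling = ceiling(abs(mn)))
    offset <- r + 1
  } else {
    offset <- 1
  }
  list(shifted = scores + offset, offset = offset)
}

#' Allometric power-law fit of scores on centroid size
#'
#' Tests the relation `Y = a * X^b` between a (shifted, positive) score set
#' Y and centroid size X by ordinary least squares on the log-log form
#' `log Y = b log X + log a`. The allometric coefficient b is the slope;
#' its significance is the two-tailed Student's t-test on the slope with
#' n - 2 degrees of freedom. A nonzero b indicates shape change with size.
#'
#' @param shifted_scores positive numeric vector Y.
#' @param centroid_sizes positive numeric vector X (mm).
#' @return one-row tibble (class `allometry_fit`): `coefficient` (b),
#'   `constant` (a), `t_value`, `p_value`, `n`.
#' @export
fit_allometry <- function(shifted_scores, centroid_sizes) {
  Y <- as.numeric(shifted_scores); X <- as.numeric(centroid_sizes)
  if (length(Y) != length(X)) stop("length mismatch")
  if (length(Y) < 3L) stop("need at least 3 observations")
  if (any(Y <= 0)) stop("scores must be positive (apply shift_scores first)")
  if (any(X <= 0)) stop("centroid sizes must be positive")
  lx <- log(X)
  if (stats::var(lx) < 1e-14) stop("zero variance in log centroid size")
  fit <- stats::lm(log(Y) ~ lx)
  sm <- summary(fit)$coefficients
  out <- tibble::tibble(coefficient = unname(sm["lx", "Estimate"]),
                        constant = exp(unname(sm["(Intercept)", "Estimate"])),
                        t_value = unname(sm["lx", "t value"]),
                        p_value = unname(sm["lx", "Pr(>|t|)"]),
                        n = length(Y))
  class(out) <- c("allometry_fit", class(out))
  out
}

#' Allometry scan over the reported components
#'
#' For every component with contribution rate above `threshold_pct`
#' (default 1%), shifts the scores to positivity and fits the log-log
#' power law against centroid size. Centroid sizes must come from the
#' non-normalized models even when the scores come from the normalized
#' space. In a non-normalized space, PC1 is flagged as the overall size
#' component (rows are kept, flags only). Significance stars mark 0.05
#' (`*`) and 0.01 (`**`).
#'
#' @param space a [fit_shape_pca()] result.
#' @param centroid_sizes per-specimen centroid sizes (mm) from the
#'   non-normalized models; defaults to the sizes recorded on the space.
#' @param threshold_pct contribution threshold for inclusion.
#' @param rounding offset rounding rule, see [shift_scores()].
#' @return tibble with component, dataset (non-normalized | normalized),
#'   coefficient, constant, t_value, p_value, significance, offset,
#'   offset_rounding, n, size_component flag.
#' @export
allometry_scan <- function(space, centroid_sizes = NULL, threshold_pct = 1,
                           rounding = "half_up") {
  stopifnot(inherits(space, "shape_space"))
  cs <- centroid_sizes %||% space$centroid_size
  comps <- select_components(space, threshold_pct)
  dataset <- if (isTRUE(space$normalized)) "normalized" else "non-normalized"
  rows <- lapply(comps, function(k) {
    sh <- shift_scores(space$scores[, k], rounding = rounding)
    f <- fit_allometry(sh$shifted, cs)
    tibble::tibble(component = k, dataset = dataset,
                   coefficient = f$coefficient, constant = f$constant,
                   t_value = f$t_value, p_value = f$p_value,
                   significance = ifelse(f$p_value < 0.01, "**",
                                         ifelse(f$p_value < 0.05, "*", "")),
                   offset = sh$offset, offset_rounding = rounding,
                   n = f$n,
                   size_component = dataset == "non-normalized" & k == 1L)
  })
  dplyr::bind_rows(rows)
}

#' @export
tidy.allometry_fit <- function(x, ...) {
  tibble::tibble(term = c("coefficient", "constant"),
                 estimate = c(x$coefficient, x$constant),
                 statistic = c(x$t_value, NA_real_),
                 p.value = c(x$p_value, NA_real_))
}

#' @export
glance.allometry_fit <- function(x, ...) {
  tibble::tibble(coefficient = x$coefficient, constant = x$constant,
                 t_value = x$t_value, p_value = x$p_value, n = x$n)
}

#' Log-log allometry plot for one component
#'
#' @param space a [fit_shape_pca()] result.
#' @param comp component id.
#' @param centroid_sizes sizes (mm); defaults to those on the space.
#' @param rounding offset rounding rule.
#' @return a ggplot of log shifted score vs log centroid size with the
#'   fitted regression line.
#' @export
plot_allometry <- function(space, comp, centroid_sizes = NULL,
                           rounding = "half_up") {
  cs <- centroid_sizes %||% space$centroid_size
  sh <- shift_scores(space$scores[, comp], rounding = rounding)
  f <- fit_allometry(sh$shifted, cs)
  df <- tibble::tibble(log_size = log(cs), log_score = log(sh$shifted),
                       group = space$group)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_size, y = .data$log_score)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.8) +
    ggplot2::geom_abline(slope = f$coefficient, intercept = log(f$constant)) +
    ggplot2::labs(x = "log centroid size", y = sprintf("log shifted PC%d score", comp),
                  subtitle = sprintf("b = %.3f, t = %.2f, p = %.3g",
                                     f$coefficient, f$t_value, f$p_value)) +
    ggplot2::theme_minimal()
}
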