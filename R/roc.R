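#' ROC area under the curve for one score set
#'
#' Rank-based AUC: the Mann-Whitney U statistic divided by
#' `n_in * n_out`, with ties counted 1/2 — the probability that a random
#' in-group score exceeds a random out-group score. Computed with the named
#' group as positive and the raw score order; values below 0.5 are reported
#' as-is with `direction = -1` rather than silently flipped.
#'
#' @param scores numeric vector.
#' @param labels logical (or coercible) vector, TRUE for the positive group.
#' @return one-row tibble (class `roc_result`): `auc`, `se` (Hanley-McNeil),
#'   `direction` (+1 if auc >= 0.5), `n_in`, `n_out`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be non-empty")
  r <- rank(scores)                       # midranks handle ties as 1/2
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  out <- tibble::tibble(auc = auc, se = .hanley_mcneil_se(auc, n1, n0),
                        direction = ifelse(auc >= 0.5, 1L, -1L),
                        n_in = n1, n_out = n0)
  class(out) <- c("roc_result", class(out))
  out
}

# Hanley & McNeil (1982) standard error of an AUC
.hanley_mcneil_se <- function(A, n1, n0) {
  Q1 <- A / (2 - A)
  Q2 <- 2 * A^2 / (1 + A)
  sqrt((A * (1 - A) + (n1 - 1) * (Q1 - A^2) + (n0 - 1) * (Q2 - A^2)) /
         (n1 * n0))
}

#' Chi-square significance of an AUC against 0.5
#'
#' Standard error by Hanley-McNeil (`Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`);
#' the statistic `((A - 0.5)/SE)^2` is referred to a chi-square with one
#' degree of freedom.
#'
#' @param roc a [roc_auc()] result (or one row of a scan table).
#' @return one-row tibble with `chi_square`, `p_value`, `degenerate`
#'   (TRUE when either class has a single member, where the SE is
#'   unreliable).
#' @export
auc_significance <- function(roc) {
  A <- roc$auc
  se <- .hanley_mcneil_se(A, roc$n_in, roc$n_out)
  degenerate <- roc$n_in < 2L || roc$n_out < 2L
  chi2 <- if (se > 0) ((A - 0.5) / se)^2 else ifelse(A == 0.5, 0, Inf)
  tibble::tibble(chi_square = chi2,
                 p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 degenerate = degenerate)
}

#' One-vs-rest ROC scan of PC scores by group
#'
#' For every group (with at least `min_n` members) and every selected
#' component, the one-vs-rest AUC with its Hanley-McNeil chi-square
#' significance. Within each group, components are ranked by
#' discriminability `max(AUC, 1 - AUC)` (`rank_in_group` 1 = most
#' discriminative; AUCs below 0.5 are reported as-is with their direction
#' flag, so ranking must not penalise the direction). No multiple-testing
#' correction is applied by default, an optional Bonferroni flag is
#' provided.
#'
#' @param space a [fit_shape_pca()] result carrying group labels, or a
#'   scores matrix (then `groups` is required).
#' @param groups group label per specimen (defaults to the space's labels).
#' @param components component ids (default: contribution > 2%).
#' @param alpha significance level (default 0.001).
#' @param min_n minimum group size; smaller groups are skipped with a
#'   message (default 5).
#' @param bonferroni divide alpha by the number of tests.
#' @return tibble with group, component, auc, se, direction, chi_square,
#'   p_value, n_in, n_out, significant, rank_in_group; attribute
#'   `skipped_groups`.
#' @export
one_vs_rest_scan <- function(space, groups = NULL, components = NULL,
                             alpha = 0.001, min_n = 5L, bonferroni = FALSE) {
  if (inherits(space, "shape_space")) {
    scores <- space$scores
    groups <- groups %||% space$group
    components <- components %||% select_components(space, 2)
  } else {
    scores <- as.matrix(space)
    if (is.null(groups)) stop("groups required with a raw score matrix")
    components <- components %||% seq_len(ncol(scores))
  }
  if (anyNA(groups)) stop("group labels contain NA")
  tab <- table(groups)
  skipped <- names(tab)[tab < min_n]
  if (length(skipped))
    message("skipping groups below min_n: ", paste(skipped, collapse = ", "))
  use <- setdiff(names(tab), skipped)
  rows <- list()
  for (gname in use) {
    lab <- groups == gname
    for (k in components) {
      r <- roc_auc(scores[, k], lab)
      s <- auc_significance(r)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = gname, component = k, auc = r$auc, se = r$se,
        direction = r$direction, chi_square = s$chi_square,
        p_value = s$p_value, n_in = r$n_in, n_out = r$n_out)
    }
  }
  out <- dplyr::bind_rows(rows)
  a_eff <- if (bonferroni) alpha / nrow(out) else alpha
  out$significant <- out$p_value < a_eff
  out <- dplyr::mutate(dplyr::group_by(out, .data$group),
                       rank_in_group = rank(-pmax(.data$auc, 1 - .data$auc),
                                            ties.method = "first"))
  out <- dplyr::ungroup(out)
  attr(out, "skipped_groups") <- skipped
  attr(out, "alpha") <- a_eff
  out
}

#' Representative specimens closest to their population mean
#'
#' For each population, the Euclidean distance from every individual to the
#' population mean vector of the measurements; the `k` smallest distances
#' are returned in ascending order, ties broken by specimen id. If `k`
#' exceeds a population's size, all members are returned and the rows are
#' flagged.
#'
#' @param measurements numeric matrix or data frame (specimens x
#'   measurements, no missing values); rownames or `ids` give specimen ids.
#' @param populations population label per specimen.
#' @param k number of representatives per population.
#' @param ids optional specimen ids.
#' @return tibble with population, specimen_id, distance, rank,
#'   short_population (TRUE where the population had fewer than `k`
#'   members).
#' @export
select_representatives <- function(measurements, populations, k = 1L,
                                   ids = NULL) {
  X <- as.matrix(measurements)
  if (anyNA(X)) stop("measurements contain missing values")
  ids <- ids %||% rownames(X) %||% sprintf("S%03d", seq_len(nrow(X)))
  rows <- list()
  for (pop in unique(populations)) {
    i <- which(populations == pop)
    mu <- colMeans(X[i, , drop = FALSE])
    d <- sqrt(rowSums(sweep(X[i, , drop = FALSE], 2, mu)^2))
    ord <- order(d, ids[i])
    take <- utils::head(ord, k)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      population = pop, specimen_id = ids[i][take],
      distance = unname(d[take]),
      rank = seq_along(take), short_population = length(i) < k)
  }
  dplyr::bind_rows(rows)
}
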