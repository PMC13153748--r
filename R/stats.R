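#' Kruskal-Wallis rank-sum comparison across groups
#'
#' Thin wrapper over [stats::kruskal.test()] (H statistic with tie
#' correction, p-value from the chi-square distribution with k-1 degrees of
#' freedom) with explicit handling of the degenerate all-identical input,
#' for which H = 0 and p = 1 are reported with `degenerate = TRUE`.
#'
#' @param groups list of (>= 2) nonempty numeric vectors.
#' @return list of class `shareduse_test`: `statistic`, `p_value`, `method`,
#'   `degenerate`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, 0L) >= 1L))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  if (length(unique(x)) == 1L) {
    return(structure(list(statistic = 0, p_value = 1,
                          method = "kruskal_wallis", degenerate = TRUE),
                     class = "shareduse_test"))
  }
  kt <- stats::kruskal.test(x, g)
  structure(list(statistic = unname(kt$statistic),
                 p_value = unname(kt$p.value),
                 method = "kruskal_wallis", degenerate = FALSE),
            class = "shareduse_test")
}

#' Mann-Whitney U comparison of two samples
#'
#' Two-sided test via [stats::wilcox.test()]'s normal approximation with tie
#' and continuity corrections. The reported statistic is
#' `U = min(U_x, U_y)`. Degenerate inputs where the approximation collapses
#' (all observations identical) report `U = n_x * n_y / 2`, p = 1,
#' `degenerate = TRUE`.
#'
#' @param x,y nonempty numeric vectors.
#' @return list of class `shareduse_test`: `statistic` (U), `p_value`,
#'   `method`, `degenerate`.
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  if (length(unique(c(x, y))) == 1L) {
    return(structure(list(statistic = length(x) * length(y) / 2,
                          p_value = 1, method = "mann_whitney",
                          degenerate = TRUE), class = "shareduse_test"))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))
  ux <- unname(wt$statistic)
  u <- min(ux, length(x) * length(y) - ux)
  p <- wt$p.value
  degenerate <- FALSE
  if (is.na(p)) {  # zero-variance rank configuration
    p <- 1
    degenerate <- TRUE
  }
  structure(list(statistic = u, p_value = min(p, 1),
                 method = "mann_whitney", degenerate = degenerate),
            class = "shareduse_test")
}

#' @export
print.shareduse_test <- function(x, ...) {
  cat("<", x$method, "> statistic = ", format(x$statistic, digits = 4),
      ", p = ", format(x$p_value, digits = 3),
      if (x$degenerate) " (degenerate input)", "\n", sep = "")
  invisible(x)
}
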