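#' Mann-Whitney rank test for two independent groups
#'
#' Wraps the two-sample Wilcoxon rank-sum (Mann-Whitney U) test: exact null
#' distribution when both groups have at most 8 observations and no ties are
#' present, otherwise the tie-corrected normal approximation with continuity
#' correction. Identical constant groups return p = 1 rather than an error.
#'
#' @param a,b Numeric vectors (non-empty).
#' @param alternative Two-sided by default.
#' @return A `group_comparison` object; see [tidy.group_comparison()].
#' @export
mann_whitney <- function(a, b, alternative = "two.sided") {
  stopifnot(length(a) > 0, length(b) > 0)
  if (stats::sd(c(a, b)) == 0 || isTRUE(all.equal(min(c(a, b)),
                                                  max(c(a, b))))) {
    return(.group_comparison("Mann-Whitney", statistic = length(a) *
                               length(b) / 2, p_value = 1))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) <= 8 && length(b) <= 8
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                       correct = TRUE))
  .group_comparison("Mann-Whitney", statistic = unname(wt$statistic),
                    p_value = wt$p.value,
                    details = list(exact = exact, n = c(length(a), length(b))))
}

#' Kruskal-Wallis test with Dunn's post-test
#'
#' Kruskal-Wallis H (rank) test across three or more independent groups,
#' followed by Dunn's pairwise z tests on the mean ranks with tie correction
#' and Bonferroni adjustment over the compared pairs.
#'
#' @param groups A list of numeric vectors (>= 3 groups, each non-empty), or
#'   a data frame with columns `value` and `group`.
#' @return A `group_comparison` object with a `pairwise` tibble (`pair`,
#'   `z`, `p_value`, `p_adjusted`).
#' @export
kruskal_dunn <- function(groups) {
  groups <- .as_group_list(groups)
  if (length(groups) < 3) {
    stop("kruskal_dunn needs >= 3 groups; use mann_whitney() for 2",
         call. = FALSE)
  }
  stopifnot(all(lengths(groups) > 0))
  kw <- stats::kruskal.test(groups)
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  rk <- rank(x)
  mean_rank <- tapply(rk, g, mean)
  ni <- lengths(groups)
  tie_sizes <- table(x)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (n - 1))
  pairs <- utils::combn(length(groups), 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ni[i] + 1 / ni[j]))
    z <- (mean_rank[i] - mean_rank[j]) / se
    tibble::tibble(pair = paste0(names(groups)[i] %||% i, "-",
                                 names(groups)[j] %||% j),
                   z = unname(z),
                   p_value = 2 * stats::pnorm(-abs(z)))
  })
  pw$p_adjusted <- pmin(1, pw$p_value * nrow(pw))
  .group_comparison("Kruskal-Wallis", statistic = unname(kw$statistic),
                    p_value = kw$p.value, pairwise = pw,
                    details = list(df = unname(kw$parameter)))
}

#' Friedman test with Dunn's post-test for matched values
#'
#' Friedman chi-square test on within-row (subject) ranks of a complete
#' subjects-by-conditions matrix, followed by Dunn's pairwise z tests on the
#' condition rank sums, `z = (R_i - R_j) / sqrt(n k (k + 1) / 6)`, with
#' Bonferroni adjustment over the compared pairs.
#'
#' @param m Numeric matrix or data frame, one row per subject, one column
#'   per condition (>= 3 conditions, no missing cells).
#' @return A `group_comparison` object with a `pairwise` tibble.
#' @export
friedman_dunn <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 3) stop("friedman_dunn needs >= 3 conditions", call. = FALSE)
  if (anyNA(m)) {
    stop("matched-values test requires a complete matrix", call. = FALSE)
  }
  n <- nrow(m); k <- ncol(m)
  rk <- t(apply(m, 1, rank))
  rsum <- colSums(rk)
  fr <- stats::friedman.test(m)
  if (is.nan(fr$statistic)) {
    # all within-row ranks tied: no evidence against the null
    fr$statistic <- 0
    fr$p.value <- 1
  }
  cn <- colnames(m) %||% as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  se <- sqrt(n * k * (k + 1) / 6)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(t) {
    i <- pairs[1, t]; j <- pairs[2, t]
    z <- (rsum[i] - rsum[j]) / se
    tibble::tibble(pair = paste0(cn[i], "-", cn[j]), z = unname(z),
                   p_value = 2 * stats::pnorm(-abs(z)))
  })
  pw$p_adjusted <- pmin(1, pw$p_value * nrow(pw))
  .group_comparison("Friedman", statistic = unname(fr$statistic),
                    p_value = fr$p.value, pairwise = pw,
                    details = list(df = unname(fr$parameter), n = n, k = k))
}

.as_group_list <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  groups
}

.group_comparison <- function(test, statistic, p_value, pairwise = NULL,
                              details = list()) {
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 pairwise = pairwise, details = details),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, p = %.4g\n", x$test, x$statistic,
              x$p_value))
  if (!is.null(x$pairwise)) {
    cat("Dunn's post-test (Bonferroni-adjusted):\n")
    print(as.data.frame(x$pairwise), row.names = FALSE)
  }
  invisible(x)
}

#' Tidy and glance methods for group comparisons
#'
#' `tidy()` returns the pairwise post-hoc table (or the global test when no
#' post-test applies); `glance()` returns the one-row global test summary.
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  if (is.null(x$pairwise)) {
    return(tibble::tibble(test = x$test, statistic = x$statistic,
                          p_value = x$p_value))
  }
  dplyr::mutate(x$pairwise, test = x$test, .before = 1)
}

#' @rdname tidy.group_comparison
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(test = x$test, statistic = x$statistic,
                 p_value = x$p_value,
                 n_pairwise = if (is.null(x$pairwise)) 0L
                              else nrow(x$pairwise))
}
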