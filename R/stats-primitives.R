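# Statistical primitives shared by the calling modules.

# two-sample t with the degenerate-variance convention: if both groups are
# essentially constant, equal means give p = 1 (no evidence of difference)
# and unequal means give the 0-limit.
safe_t_test <- function(x, y, paired = FALSE, var.equal = FALSE) {
  eps <- .Machine$double.eps
  if (paired) {
    d <- x - y
    if (stats::sd(d) < eps * max(1, mean(abs(d)))) {
      p <- if (abs(mean(d)) < eps) 1 else 0
      return(list(p.value = p, estimate = mean(d), statistic = NA_real_))
    }
    tt <- stats::t.test(x, y, paired = TRUE)
    return(list(p.value = tt$p.value, estimate = unname(tt$estimate),
                statistic = unname(tt$statistic)))
  }
  degenerate <- stats::sd(x) < eps * max(1, mean(abs(x))) &&
    stats::sd(y) < eps * max(1, mean(abs(y)))
  if (degenerate) {
    p <- if (abs(mean(x) - mean(y)) < eps) 1 else 0
    return(list(p.value = p, estimate = mean(x) - mean(y),
                statistic = NA_real_))
  }
  tt <- stats::t.test(x, y, var.equal = var.equal)
  list(p.value = tt$p.value, estimate = unname(diff(rev(tt$estimate))),
       statistic = unname(tt$statistic))
}

#' Tukey HSD all-pairs comparison (Tukey-Kramer for unequal sizes)
#'
#' For k groups the pairwise statistic is
#' q_ij = |mean_i - mean_j| / sqrt((MSW / 2)(1/n_i + 1/n_j)), with MSW the
#' pooled within-group mean square; the adjusted p-value comes from the
#' studentized-range distribution with k groups and N - k degrees of
#' freedom. At k = 2 the adjusted p equals the two-sided pooled-variance
#' t-test p (q = t sqrt(2)).
#'
#' @param groups Named list of numeric vectors (k >= 2, each of length
#'   >= 2).
#' @return Object of class `tukey_hsd`: a tibble with `group1`, `group2`,
#'   `diff` (mean_2 - mean_1), `q`, `p_adj`, plus attributes `msw` and `df`.
#' @export
tukey_hsd <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  n <- vapply(groups, length, 1L)
  if (any(n < 2)) stop("each group needs at least two values", call. = FALSE)
  k <- length(groups)
  N <- sum(n)
  means <- vapply(groups, mean, 1)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df <- N - k
  msw <- ssw / df
  pairs <- utils::combn(k, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]
    i2 <- pairs[2, j]
    d <- means[i2] - means[i1]
    se <- sqrt((msw / 2) * (1 / n[i1] + 1 / n[i2]))
    if (se == 0) {
      # zero within-group variance everywhere: exact means decide
      p <- if (abs(d) < .Machine$double.eps) 1 else 0
      q <- if (p == 1) 0 else Inf
    } else {
      q <- abs(d) / se
      p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    }
    tibble::tibble(group1 = names(groups)[i1], group2 = names(groups)[i2],
                   diff = unname(d), q = unname(q), p_adj = unname(p))
  })
  structure(res, msw = msw, df = df, k = k,
            class = c("tukey_hsd", class(res)))
}

#' Multiple-testing adjustment
#'
#' Bonferroni (min(1, m p)) or Benjamini-Hochberg step-up.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values, same order as the input.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = switch(method, bonferroni = "bonferroni",
                                     bh = "BH"))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction by default (the Yates-corrected variant is
#' available via `correct = TRUE`); df = 1.
#'
#' @param table 2x2 matrix of non-negative counts; no margin may be zero.
#' @param correct Apply the Yates continuity correction.
#' @return Tibble with `statistic`, `p_value`, `df`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin in 2x2 table", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  tibble::tibble(statistic = unname(ct$statistic),
                 p_value = unname(ct$p.value), df = 1L)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.tukey_hsd <- function(x, ...) {
  tibble::tibble(contrast = paste(x$group2, "-", x$group1),
                 estimate = x$diff, statistic = x$q,
                 adj.p.value = x$p_adj)
}

#' @exportS3Method generics::glance
glance.tukey_hsd <- function(x, ...) {
  tibble::tibble(k = attr(x, "k"), df = attr(x, "df"), msw = attr(x, "msw"),
                 n_significant = sum(x$p_adj < 0.05))
}
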