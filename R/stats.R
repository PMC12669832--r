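#' Significance stars
#'
#' Conventional thresholds: `*` for P <= 0.05, `**` for P <= 0.01, `***`
#' for P < 0.001; `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star strings.
#' @export
significance_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- rep("ns", length(p))
  out[p <= 0.05] <- "*"
  out[p <= 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

test_result <- function(method, statistic, p_value, n, note = NA_character_) {
  tibble::tibble(
    method = method,
    statistic = unname(statistic),
    p_value = unname(p_value),
    n = as.character(n),  # "n" or "n_a,n_b" depending on the test

    stars = significance_stars(p_value),
    note = note
  )
}

#' Paired Wilcoxon signed-rank test
#'
#' Compares per-larva values between two phases (e.g. baseline vs search).
#' Zero differences are dropped (Wilcoxon's convention) and their count
#' recorded in the `note` column. The null distribution is exact for up to
#' 25 non-zero differences without ties, and the tie-corrected normal
#' approximation otherwise.
#'
#' @param x,y Equal-length numeric vectors of paired observations.
#' @return A one-row tibble: `method`, `statistic` (V, the positive-rank
#'   sum), two-sided `p_value`, `n` (non-zero pairs), `stars`, `note`.
#' @export
wilcoxon_paired <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  d <- x - y
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d_nz <- d[d != 0]
  if (length(d_nz) == 0) {
    warning("all paired differences are zero; p = 1")
    return(test_result("wilcoxon_paired", NA_real_, 1, 0L,
                       sprintf("%d zero differences dropped", n_zero)))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(d_nz, exact = length(d_nz) <= 25, correct = TRUE)
  )
  test_result("wilcoxon_paired", ht$statistic, ht$p.value, length(d_nz),
              if (n_zero > 0) sprintf("%d zero differences dropped", n_zero)
              else NA_character_)
}

#' One-sample Wilcoxon signed-rank test
#'
#' Tests whether a sample of scores is symmetric about `mu0` -- used to ask
#' whether the search score differs from random (zone-indifferent)
#' behavior, i.e. from zero.
#'
#' @param scores Numeric vector.
#' @param mu0 Null location (default 0).
#' @return A one-row tibble as in [wilcoxon_paired()].
#' @export
wilcoxon_one_sample <- function(scores, mu0 = 0) {
  stopifnot(length(scores) >= 1)
  res <- wilcoxon_paired(scores, rep(mu0, length(scores)))
  res$method <- "wilcoxon_one_sample"
  res
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent groups (two test
#' conditions). Exact for small tie-free samples, tie-corrected normal
#' approximation otherwise.
#'
#' @param group_a,group_b Numeric vectors.
#' @return A one-row tibble; `statistic` is U for `group_a`, `n` is
#'   `"n_a,n_b"`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  ht <- suppressWarnings(stats::wilcox.test(
    group_a, group_b,
    exact = length(group_a) + length(group_b) <= 50, correct = TRUE
  ))
  test_result("mann_whitney_u", ht$statistic, ht$p.value,
              paste(length(group_a), length(group_b), sep = ","))
}

#' Kruskal-Wallis test with post hoc pairwise comparisons
#'
#' Global rank test across three or more conditions; the tie-corrected H
#' statistic is referred to a chi-square distribution. Pairwise post hoc
#' comparisons (two-sided rank-sum tests with a family-wise Holm
#' correction) are run only when the global test is significant at
#' `alpha`.
#'
#' @param groups Named list of numeric vectors (>= 3 groups).
#' @param alpha Gate for running the post hoc comparisons.
#' @param p_adjust_method Family-wise correction passed to
#'   [stats::p.adjust()].
#' @return List with `global` (one-row tibble) and `posthoc` (tibble of
#'   pairwise comparisons, or `NULL` when the global test is not
#'   significant).
#' @export
kruskal_wallis <- function(groups, alpha = 0.05, p_adjust_method = "holm") {
  stopifnot(is.list(groups), length(groups) >= 3,
            all(lengths(groups) >= 1))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  small <- names(groups)[lengths(groups) < 2]
  if (length(small) > 0) {
    warning("group(s) of size < 2: ", paste(small, collapse = ", "))
  }
  ht <- stats::kruskal.test(groups)
  global <- test_result("kruskal_wallis", ht$statistic, ht$p.value,
                        paste(lengths(groups), collapse = ","))
  posthoc <- NULL
  if (!is.na(ht$p.value) && ht$p.value <= alpha) {
    pairs <- utils::combn(names(groups), 2, simplify = FALSE)
    raw <- lapply(pairs, function(pr) {
      res <- mann_whitney_u(groups[[pr[1]]], groups[[pr[2]]])
      res$method <- "posthoc"
      res$comparison <- paste(pr, collapse = " vs ")
      res
    })
    posthoc <- dplyr::bind_rows(raw)
    posthoc$p_value <- stats::p.adjust(posthoc$p_value, p_adjust_method)
    posthoc$stars <- significance_stars(posthoc$p_value)
    posthoc <- posthoc[, c("comparison", "method", "statistic", "p_value",
                           "n", "stars")]
  }
  list(global = global, posthoc = posthoc)
}
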