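#' Shapiro-Wilk normality check
#'
#' A dataset is treated as normally distributed when the Shapiro-Wilk
#' p-value exceeds 0.05; this gate decides between parametric and
#' rank-based two-group tests downstream. Constant samples (zero
#' variance) are reported as non-normal with `p_value = 0` and a warning.
#'
#' @param values Numeric vector, 3 <= n <= 5000.
#' @param alpha Normality threshold (normal iff p > alpha).
#' @return One-row tibble: `n`, `statistic`, `p_value`, `is_normal`.
#' @export
test_normality <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) abort("Shapiro-Wilk requires at least 3 observations.")
  if (n > 5000) abort("Shapiro-Wilk supports at most 5000 observations.")
  if (sd(values) == 0) {
    warn("Constant sample: normality rejected by convention (p = 0).")
    return(tibble(n = n, statistic = NA_real_, p_value = 0, is_normal = FALSE))
  }
  sw <- shapiro.test(values)
  tibble(n = n, statistic = unname(sw$statistic),
         p_value = sw$p.value, is_normal = sw$p.value > alpha)
}

#' Normality-gated two-group comparison
#'
#' When both groups pass the Shapiro-Wilk gate (p > 0.05), an unpaired
#' two-sided Student t-test with pooled variance is used; otherwise a
#' two-sided Mann-Whitney U test (normal approximation with continuity
#' correction — count-derived ratios tie frequently). Significance is
#' declared at `p < alpha`. No multiple-testing correction is applied
#' here; [compare_timepoints()] optionally adds a Holm-adjusted column.
#'
#' @param a,b Numeric vectors, each n >= 3.
#' @param alpha Significance level.
#' @param label_a,label_b Group labels carried into the result.
#' @return One-row tibble: group labels and sizes, `test`
#'   (`"student_t"` or `"mann_whitney_u"`), `statistic`, `p_value`,
#'   `significant`, and the two gate p-values.
#' @export
compare_groups <- function(a, b, alpha = 0.05,
                           label_a = "a", label_b = "b") {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3 || length(b) < 3)
    abort("Both groups need at least 3 observations.")
  norm_a <- suppressWarnings(test_normality(a))
  norm_b <- suppressWarnings(test_normality(b))
  if (norm_a$is_normal && norm_b$is_normal) {
    ht <- t.test(a, b, var.equal = TRUE)
    test <- "student_t"
  } else {
    ht <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    test <- "mann_whitney_u"
  }
  tibble(group_a = label_a, group_b = label_b,
         n_a = length(a), n_b = length(b),
         test = test, statistic = unname(ht$statistic),
         p_value = ht$p.value, significant = ht$p.value < alpha,
         p_normal_a = norm_a$p_value, p_normal_b = norm_b$p_value)
}

#' All pairwise time-point comparisons of one variable
#'
#' @param data Tibble with columns `timepoint_h` and the chosen variable.
#' @param variable Column to compare (e.g. `"R13"`, `"R15"`, `"APE13"`,
#'   `"APE15"`, `"length_um"`).
#' @param alpha Significance level.
#' @param holm Add a Holm-adjusted p-value column.
#' @return Tibble with one row per unordered time-point pair.
#' @export
compare_timepoints <- function(data, variable = "R13", alpha = 0.05,
                               holm = FALSE) {
  data <- as_tibble(data)
  if (!variable %in% names(data))
    abort(sprintf("Column %s not found.", variable))
  tps <- sort(unique(data$timepoint_h))
  if (length(tps) < 2) abort("Need at least two time points.")
  pairs <- utils::combn(tps, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    t1 <- pairs[1, i]; t2 <- pairs[2, i]
    compare_groups(data[[variable]][data$timepoint_h == t1],
                   data[[variable]][data$timepoint_h == t2],
                   alpha = alpha,
                   label_a = format(t1), label_b = format(t2))
  })
  if (holm) {
    out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
    out$significant_holm <- out$p_holm < alpha
  }
  out
}
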