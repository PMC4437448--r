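# Two-group comparison of per-animal endpoints: mean +/- SD summaries,
# Student (pooled) and Welch t-tests -- including directly from published
# summary statistics -- and the Mann-Whitney U test with exact small-sample
# p-values. Alpha defaults to 0.05; no multiple-testing correction is
# applied (a deliberate fidelity choice, documented as a limitation).

#' Summarize one group of an endpoint
#'
#' @param values Numeric endpoint values for one group (n >= 2).
#' @param group Group name.
#' @return One-row tibble: `group`, `n`, `mean`, `sd` (sample SD, n-1
#'   denominator).
#' @export
summarize_group <- function(values, group = "group") {
  values <- as.numeric(values)
  if (length(values) < 2L || any(!is.finite(values))) {
    abort("Need at least two finite values per group.",
          class = "strokevol_validation_error")
  }
  tibble::tibble(group = group, n = length(values),
                 mean = mean(values), sd = sd(values))
}

#' Summarize an endpoint by group from a results table
#'
#' @param data Per-animal results tibble.
#' @param endpoint Column name of the endpoint.
#' @param group_col Column name of the grouping factor (default `"group"`).
#' @return Tibble with one row per group (`group`, `n`, `mean`, `sd`).
#' @export
summarize_groups <- function(data, endpoint, group_col = "group") {
  if (!endpoint %in% names(data)) {
    abort(paste0("Endpoint column '", endpoint, "' not found."),
          class = "strokevol_validation_error")
  }
  split(data, data[[group_col]]) |>
    purrr::imap(~ summarize_group(.x[[endpoint]], .y)) |>
    purrr::list_rbind()
}

t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2, variant) {
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  list(se = se, df = df)
}

#' Two-sample t-test from summary statistics
#'
#' Computes the classical (pooled-variance) Student or the Welch two-sample
#' t-test directly from per-group mean, SD and n, as needed to reproduce
#' published comparisons when only "mean +/- SD" is available.
#'
#' @param mean1,sd1,n1 Summary of group 1 (sample SD, n-1 denominator).
#' @param mean2,sd2,n2 Summary of group 2.
#' @param variant `"pooled"` (Student, df = n1+n2-2) or `"welch"`
#'   (Satterthwaite df).
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble: `test`, `statistic`, `df`, `p_two_sided`,
#'   `significant`. Degenerate zero-variance input: equal means give p = 1,
#'   different means give p = 0 with a warning.
#' @examples
#' t_test_from_summary(27.1, 11.1, 8, 14.3, 7.2, 8)
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                variant = c("pooled", "welch"),
                                alpha = 0.05) {
  variant <- match.arg(variant)
  if (n1 < 2L || n2 < 2L) {
    abort("Both groups need n >= 2.", class = "strokevol_validation_error")
  }
  if (sd1 < 0 || sd2 < 0) {
    abort("Standard deviations must be non-negative.",
          class = "strokevol_validation_error")
  }
  test_name <- if (variant == "pooled") "t_pooled" else "t_welch"
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) {
      p <- 1
      stat <- 0
      df <- if (variant == "pooled") n1 + n2 - 2 else NA_real_
    } else {
      warn("Both groups have zero variance but different means; p = 0 by convention.")
      p <- 0
      stat <- sign(mean1 - mean2) * Inf
      df <- if (variant == "pooled") n1 + n2 - 2 else NA_real_
    }
    return(tibble::tibble(test = test_name, statistic = stat, df = df,
                          p_two_sided = p, significant = p < alpha))
  }
  parts <- t_from_summary(mean1, sd1, n1, mean2, sd2, n2, variant)
  stat <- (mean1 - mean2) / parts$se
  p <- 2 * pt(-abs(stat), df = parts$df)
  tibble::tibble(test = test_name, statistic = stat, df = parts$df,
                 p_two_sided = p, significant = p < alpha)
}

#' Two-sample t-test on raw values
#'
#' Exactly [t_test_from_summary()] applied to the two groups' sample
#' summaries.
#'
#' @param values1,values2 Numeric vectors (each n >= 2).
#' @inheritParams t_test_from_summary
#' @return One-row tibble as for [t_test_from_summary()].
#' @export
t_test_groups <- function(values1, values2, variant = c("pooled", "welch"),
                          alpha = 0.05) {
  variant <- match.arg(variant)
  s1 <- summarize_group(values1, "g1")
  s2 <- summarize_group(values2, "g2")
  t_test_from_summary(s1$mean, s1$sd, s1$n, s2$mean, s2$sd, s2$n,
                      variant = variant, alpha = alpha)
}

# Number of rank subsets of size n1 from n1+n2 tie-free observations with
# each possible Mann-Whitney U value: the classical recurrence
# c[n1,n2](u) = c[n1-1,n2](u - n2) + c[n1,n2-1](u).
mann_whitney_counts <- function(n1, n2) {
  counts <- vector("list", n2 + 1L)
  for (j in 0:n2) counts[[j + 1L]] <- 1  # n1 = 0: single subset, U = 0
  for (i in seq_len(n1)) {
    new <- vector("list", n2 + 1L)
    new[[1L]] <- 1  # n2 = 0
    for (j in seq_len(n2)) {
      shifted <- c(numeric(j), counts[[j + 1L]])  # c[i-1, j](u - j)
      other <- new[[j]]                           # c[i, j-1](u)
      len <- max(length(shifted), length(other))
      pad <- function(v) c(v, numeric(len - length(v)))
      new[[j + 1L]] <- pad(shifted) + pad(other)
    }
    counts <- new
  }
  counts[[n2 + 1L]]  # counts[u + 1] for u = 0..n1*n2
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties. For tie-free samples with
#' `n1 + n2 <= exact_max` the two-sided p-value is exact: the probability,
#' over all equally likely rank assignments, of a U at least as far from its
#' null mean `n1*n2/2` as observed. Larger or tied samples use the normal
#' approximation with tie correction and a 0.5 continuity correction.
#'
#' @param values1,values2 Numeric vectors (non-empty).
#' @param alpha Significance level.
#' @param exact_max Exact-enumeration threshold on `n1 + n2` (default 12).
#' @return One-row tibble: `test` (`"mann_whitney"`), `statistic` (U of
#'   group 1), `df` (NA), `p_two_sided`, `significant`, `method` (`"exact"`
#'   or `"normal_approx"`).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 2/6
#' @export
mann_whitney_u <- function(values1, values2, alpha = 0.05, exact_max = 12L) {
  values1 <- as.numeric(values1)
  values2 <- as.numeric(values2)
  n1 <- length(values1)
  n2 <- length(values2)
  if (n1 == 0L || n2 == 0L) {
    abort("Both groups must be non-empty.", class = "strokevol_validation_error")
  }
  pooled <- c(values1, values2)
  r <- rank(pooled)  # midranks
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L

  if (!has_ties && n1 + n2 <= exact_max) {
    counts <- mann_whitney_counts(n1, n2)
    u_vals <- seq_along(counts) - 1
    dev <- abs(u_vals - n1 * n2 / 2)
    obs_dev <- abs(u1 - n1 * n2 / 2)
    p <- sum(counts[dev >= obs_dev - 1e-9]) / sum(counts)
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u1 - mu - sign(u1 - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  tibble::tibble(test = "mann_whitney", statistic = u1, df = NA_real_,
                 p_two_sided = p, significant = p < alpha, method = method)
}

#' Compare a cohort's endpoints between two groups
#'
#' Runs the configured tests on each endpoint of a per-animal results table.
#'
#' @param data Per-animal results tibble (one row per animal) with a group
#'   column and endpoint columns.
#' @param endpoints Character vector of endpoint column names.
#' @param tests Tests to run per endpoint: any of `"t_pooled"`, `"t_welch"`,
#'   `"mann_whitney"`.
#' @param group_col Grouping column name (must have exactly two levels).
#' @param alpha Significance level.
#' @return Tibble with one row per endpoint x test: `endpoint`, `test`,
#'   `group1`, `group2`, `statistic`, `df`, `p_two_sided`, `significant`.
#'   The difference direction is `group1 - group2` with groups in sorted
#'   order.
#' @export
compare_cohort <- function(data, endpoints,
                           tests = c("t_pooled", "t_welch", "mann_whitney"),
                           group_col = "group", alpha = 0.05) {
  tests <- match.arg(tests, several.ok = TRUE)
  if (!group_col %in% names(data)) {
    abort(paste0("Group column '", group_col, "' not found."),
          class = "strokevol_validation_error")
  }
  groups <- sort(unique(as.character(data[[group_col]])))
  if (length(groups) != 2L) {
    abort("Cohort comparison needs exactly two groups.",
          class = "strokevol_validation_error")
  }
  missing <- setdiff(endpoints, names(data))
  if (length(missing) > 0L) {
    abort(paste0("Endpoint column(s) not found: ",
                 paste(missing, collapse = ", ")),
          class = "strokevol_validation_error")
  }
  purrr::map(endpoints, function(ep) {
    x1 <- data[[ep]][data[[group_col]] == groups[1L]]
    x2 <- data[[ep]][data[[group_col]] == groups[2L]]
    purrr::map(tests, function(tst) {
      res <- switch(tst,
        t_pooled = t_test_groups(x1, x2, "pooled", alpha),
        t_welch = t_test_groups(x1, x2, "welch", alpha),
        mann_whitney = dplyr::select(mann_whitney_u(x1, x2, alpha), -"method"))
      dplyr::mutate(res, endpoint = ep, group1 = groups[1L],
                    group2 = groups[2L], .before = 1L)
    }) |> purrr::list_rbind()
  }) |>
    purrr::list_rbind() |>
    dplyr::relocate("endpoint", "test", "group1", "group2")
}
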