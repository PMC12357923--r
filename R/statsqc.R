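#' Grubbs critical value
#'
#' Closed-form two-sided critical value for the single-outlier Grubbs test:
#' `((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with `t` the upper
#' `alpha / (2n)` quantile of Student's t on `n - 2` degrees of freedom.
#'
#' @param n Sample size (>= 3).
#' @param alpha Significance level.
#' @return The critical value of the G statistic.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  stopifnot(n >= 3, alpha > 0, alpha < 1)
  t <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' Grubbs single-outlier test
#'
#' Two-sided, single-pass test of the most extreme value,
#' `G = max|x - mean(x)| / sd(x)`, against the closed-form critical value.
#' Used as an outlier screen on small experimental groups. Iterative
#' removal (re-testing after each removal) is available but inflates the
#' type-I error and warns accordingly.
#'
#' @param values Numeric vector, `n >= 3`, nonzero variance.
#' @param alpha Significance level (default 0.05).
#' @param iterative Repeat the test on the reduced sample until no outlier
#'   is flagged.
#' @return A tibble with one row per test pass: `index` (position in the
#'   original vector, `NA` when nothing is flagged), `value`, `g`,
#'   `critical`, `alpha` and `outlier` (logical).
#' @examples
#' grubbs_test(c(1, 1, 1, 1, 1, 10))
#' @export
grubbs_test <- function(values, alpha = 0.05, iterative = FALSE) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  if (length(values) < 3) stop("Grubbs test needs n >= 3")
  if (stats::sd(values) == 0) stop("Grubbs test needs nonzero variance")
  if (iterative) {
    warning("iterative Grubbs removal inflates the type-I error rate")
  }
  idx_orig <- seq_along(values)
  rows <- list()
  repeat {
    n <- length(values)
    if (n < 3 || stats::sd(values) == 0) break
    dev <- abs(values - mean(values))
    i <- which.max(dev)
    g <- dev[i] / stats::sd(values)
    crit <- grubbs_critical(n, alpha)
    flagged <- g > crit
    rows[[length(rows) + 1]] <- tibble::tibble(
      index = if (flagged) idx_orig[i] else NA_integer_,
      value = if (flagged) values[i] else NA_real_,
      g = g,
      critical = crit,
      alpha = alpha,
      n = n,
      outlier = flagged
    )
    if (!flagged || !iterative) break
    values <- values[-i]
    idx_orig <- idx_orig[-i]
  }
  dplyr::bind_rows(rows)
}

#' Relative expression by the delta-delta-Ct method
#'
#' `ddCt = (Ct_target,sample - Ct_ref,sample) - (Ct_target,control -
#' Ct_ref,control)`; fold change is `2^(-ddCt)`. The reference is a single
#' housekeeping gene; with several reference genes pass the mean of their
#' Ct values (arithmetic mean of Ct equals a geometric mean on the
#' expression scale).
#'
#' @param ct_target_sample,ct_ref_sample Target and reference-gene Ct in
#'   the sample of interest.
#' @param ct_target_control,ct_ref_control Same in the control condition.
#' @return A tibble with `dct_sample`, `dct_control`, `ddct` and `fold`.
#' @examples
#' ddct(24, 20, 25, 20)  # one cycle earlier than control: fold 2
#' @export
ddct <- function(ct_target_sample, ct_ref_sample,
                 ct_target_control, ct_ref_control) {
  args <- list(ct_target_sample, ct_ref_sample,
               ct_target_control, ct_ref_control)
  stopifnot(all(vapply(args, function(x) all(is.finite(x)), logical(1))))
  dct_s <- ct_target_sample - ct_ref_sample
  dct_c <- ct_target_control - ct_ref_control
  dd <- dct_s - dct_c
  tibble::tibble(
    dct_sample = dct_s,
    dct_control = dct_c,
    ddct = dd,
    fold = 2^(-dd)
  )
}

#' Percent change of a treated summary relative to control
#'
#' Signed, with "decrease" phrasing: `100 * (control - treated) / control`,
#' so a positive value is a decrease under treatment.
#'
#' @param treated,control Scalar summaries (e.g. group mean AOC).
#' @return Percent decrease (negative when treated exceeds control).
#' @examples
#' percent_change(80.3, 100)  # 19.7% decrease
#' @export
percent_change <- function(treated, control) {
  stopifnot(is.numeric(treated), is.numeric(control))
  if (any(control == 0)) stop("control summary must be nonzero")
  100 * (control - treated) / control
}

#' Mean with SD or SEM dispersion
#'
#' @param values Numeric vector (`n >= 1`; dispersion needs `n >= 2`).
#' @param mode `"SEM"` (default) or `"SD"`.
#' @return A tibble with `mean`, `dispersion` (`NA` when `n < 2`), `mode`
#'   and `n`. SD uses the `n - 1` denominator; SEM is `SD / sqrt(n)`.
#' @examples
#' summarize_stats(c(1, 2, 3), "SEM")
#' @export
summarize_stats <- function(values, mode = c("SEM", "SD")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(values), length(values) >= 1, all(is.finite(values)))
  n <- length(values)
  disp <- if (n >= 2) {
    s <- stats::sd(values)
    if (mode == "SEM") s / sqrt(n) else s
  } else {
    NA_real_
  }
  tibble::tibble(mean = mean(values), dispersion = disp, mode = mode, n = n)
}
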