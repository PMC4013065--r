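# Transform policy, normality screening and outlier removal.

#' Natural-log transform policy for the descriptor table
#'
#' The analysis works on natural-log scale for the size-like descriptors
#' (the flags returned by [descriptor_log_flags()]); shape ratios such as
#' compactness are analysed untransformed. The Shapiro-Wilk screen
#' ([shapiro_screen()]) is advisory: the fixed policy governs which
#' columns are transformed so that runs are reproducible.
#'
#' @param table a descriptor table.
#' @param policy named logical vector mapping descriptor names to
#'   "apply log_e"; defaults to [descriptor_log_flags()]. Names absent
#'   from the table are ignored.
#' @return the table with flagged columns replaced by their natural logs.
#' @export
apply_transforms <- function(table, policy = descriptor_log_flags()) {
  if (is.null(names(policy))) stop("`policy` must be a named logical vector")
  for (col in names(policy)[policy]) {
    if (!col %in% names(table)) next
    v <- table[[col]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad))
      stop(sprintf("non-positive value in log-transform column '%s' (row %d)",
                   col, bad[1]))
    table[[col]] <- log(v)
  }
  table
}

#' Shapiro-Wilk normality screen
#'
#' @param x numeric vector, 3 <= n <= 5000 after dropping NAs, with
#'   non-zero variance.
#' @return a list with elements `W` and `p`.
#' @export
shapiro_screen <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L || length(x) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(x) == 0) stop("constant vector: normality test undefined")
  s <- stats::shapiro.test(x)
  list(W = unname(s$statistic), p = s$p.value)
}

#' Bonferroni outlier test
#'
#' Flags observations whose externally studentized residual is extreme
#' under a Bonferroni-corrected two-sided t test: observation i is an
#' outlier iff `p_i * n < alpha`, where `p_i = 2 P(T_{df} > |t_i|)`.
#' Works on `lm` fits (exact studentized residuals via
#' [stats::rstudent()]) and on `lme`/`lmeResult` fits (normalized
#' residuals, studentized with `df = n - k - 1`). This is a single-pass
#' screen: flagged rows are removed once before the final model fit, with
#' no iteration.
#'
#' @param fit an `lm` or `nlme::lme` fit, or an [fit_lme()] result.
#' @param alpha family-wise significance level (default 0.05).
#' @return a `data.frame` with columns `index`, `t`, `p_raw`,
#'   `p_bonferroni` for the flagged observations (zero rows if none).
#' @export
bonferroni_outlier_test <- function(fit, alpha = 0.05) {
  if (inherits(fit, "lme_result")) fit <- fit$fit
  if (inherits(fit, "lm")) {
    t <- stats::rstudent(fit)
    n <- length(t)
    k <- length(stats::coef(fit))
    df <- n - k - 1
  } else if (inherits(fit, "lme")) {
    r <- stats::residuals(fit, type = "normalized")
    n <- length(r)
    k <- length(nlme::fixef(fit))
    df <- n - k - 1
    # internally standardized -> externally studentized
    z <- r / stats::sd(r)
    z2 <- pmin(z^2, df + k - 1e-8)
    t <- z * sqrt(df / (df + k - z2))
  } else stop("`fit` must be an lm or lme model")
  if (df <= 1) stop("too few observations for the outlier test")
  p <- 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
  flag <- which(p * n < alpha)
  out <- data.frame(index = flag, t = unname(t[flag]),
                    p_raw = unname(p[flag]),
                    p_bonferroni = pmin(1, unname(p[flag]) * n))
  out[order(out$p_raw), , drop = FALSE]
}

#' Remove outlying observations for one descriptor
#'
#' Fits the descriptor's mixed model once, applies
#' [bonferroni_outlier_test()] to the residuals, and drops the flagged
#' rows from the table.
#'
#' @param table a (transformed) descriptor table.
#' @param descriptor response column name.
#' @param alpha family-wise level for the outlier screen.
#' @param ... passed to [fit_lme()].
#' @return the table without flagged rows; the number of removed rows is
#'   recorded in attribute `n_outliers_removed`.
#' @export
remove_outliers <- function(table, descriptor, alpha = 0.05, ...) {
  keep <- !is.na(table[[descriptor]])
  sub <- table[keep, , drop = FALSE]
  fit <- fit_lme(sub, descriptor, ...)
  flagged <- bonferroni_outlier_test(fit, alpha = alpha)
  out <- if (nrow(flagged)) sub[-flagged$index, , drop = FALSE] else sub
  attr(out, "n_outliers_removed") <- nrow(flagged)
  out
}
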