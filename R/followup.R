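#' Repeated-measures 2 x 2 ANOVA on cluster-averaged amplitudes
#'
#' Univariate repeated-measures ANOVA for a fully within-subject 2 x 2
#' design with one observation per subject per cell. With two levels per
#' factor every effect reduces to a paired t-test on a subject-level
#' contrast (main effects on marginal differences, the interaction on the
#' double difference), so each F equals the squared t with df (1, n - 1).
#' Partial eta squared is F / (F + df_denom).
#'
#' @param data tibble with columns `subject`, two factor columns, and a
#'   value column.
#' @param factors character vector naming the two factor columns.
#' @param value name of the value column (default "amplitude").
#' @return tibble: effect, F, df1, df2, p_value, pes (partial eta squared).
#' @export
rm_anova_2x2 <- function(data, factors, value = "amplitude") {
  stopifnot(length(factors) == 2, all(c("subject", factors, value) %in% names(data)))
  f1 <- factor(data[[factors[1]]]); f2 <- factor(data[[factors[2]]])
  if (nlevels(f1) != 2 || nlevels(f2) != 2) stop("both factors must have 2 levels")
  wide <- tapply(data[[value]], list(data$subject, f1, f2), mean)
  if (anyNA(wide)) stop("missing subject x cell combinations")
  n <- dim(wide)[1]
  if (n < 3) stop("need at least 3 subjects")
  contrasts <- list(
    (wide[, 1, 1] + wide[, 1, 2] - wide[, 2, 1] - wide[, 2, 2]) / 2,
    (wide[, 1, 1] - wide[, 1, 2] + wide[, 2, 1] - wide[, 2, 2]) / 2,
    wide[, 1, 1] - wide[, 1, 2] - wide[, 2, 1] + wide[, 2, 2]
  )
  names(contrasts) <- c(factors, paste(factors, collapse = ":"))
  scale <- max(abs(wide), 1)
  purrr::map2_dfr(contrasts, names(contrasts), function(d, nm) {
    if (max(abs(d)) <= 1e-10 * scale) {
      # contrast identically zero (up to rounding): F = 0
      return(tibble::tibble(effect = nm, F = 0, df1 = 1, df2 = n - 1,
                            p_value = 1, pes = 0))
    }
    tt <- tryCatch(stats::t.test(d), error = function(e) NULL)
    if (is.null(tt)) {
      # constant nonzero contrast: infinite F, flagged by p = 0
      return(tibble::tibble(effect = nm, F = Inf, df1 = 1, df2 = n - 1,
                            p_value = 0, pes = 1))
    }
    f <- unname(tt$statistic^2)
    tibble::tibble(
      effect = nm, F = f, df1 = 1, df2 = n - 1,
      p_value = tt$p.value, pes = f / (f + n - 1)
    )
  })
}

.t_row <- function(tt, method) {
  tibble::tibble(
    method = method,
    estimate = unname(if (length(tt$estimate) == 2) diff(rev(tt$estimate)) else tt$estimate),
    t = unname(tt$statistic), df = unname(tt$parameter), p_value = tt$p.value
  )
}

#' Paired, pooled-variance, and Welch t-tests
#'
#' Thin tidy wrappers around [stats::t.test()] returning one-row tibbles
#' (estimate, t, df, p). Welch df follow the Welch-Satterthwaite formula
#' and may be fractional. Zero-variance inputs yield infinite t, flagged
#' via the `degenerate` column.
#'
#' @param x,y numeric vectors (paired: same length).
#' @return one-row tibble: method, estimate, t, df, p_value, degenerate.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    t <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
    out <- tibble::tibble(method = "paired t", estimate = mean(d), t = t,
                          df = length(d) - 1,
                          p_value = if (is.infinite(t)) 0 else 1)
    out$degenerate <- TRUE
    return(out)
  }
  out <- .t_row(stats::t.test(x, y, paired = TRUE), "paired t")
  out$degenerate <- FALSE
  out
}

.two_sample_t <- function(x, y, var_equal, label) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  est <- mean(x) - mean(y)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    # degenerate: both samples constant; t is 0 or signed infinity
    df <- if (var_equal) length(x) + length(y) - 2 else NA_real_
    t <- if (est == 0) 0 else Inf * sign(est)
    return(tibble::tibble(method = label, estimate = est, t = t, df = df,
                          p_value = if (est == 0) 1 else 0, degenerate = TRUE))
  }
  out <- .t_row(stats::t.test(x, y, var.equal = var_equal), label)
  out$degenerate <- FALSE
  out
}

#' @rdname paired_t
#' @export
pooled_t <- function(x, y) .two_sample_t(x, y, TRUE, "pooled t")

#' @rdname paired_t
#' @export
welch_t <- function(x, y) .two_sample_t(x, y, FALSE, "Welch t")
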