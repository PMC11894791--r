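#' Random-intercept linear mixed model with Satterthwaite df
#'
#' Fits `y = X beta + b_subject + e`, with `b_subject ~ N(0, sigma_s^2)` and
#' `e ~ N(0, sigma_e^2)`, by restricted maximum likelihood. The variance
#' ratio `lambda = sigma_s^2 / sigma_e^2` is profiled by one-dimensional
#' optimization (tolerance 1e-10 on the ratio), with closed-form GLS at
#' each step exploiting the grouped structure (per-subject rank-one
#' updates; no general matrix inversion inside the profile).
#'
#' Fixed factors are coded with sum-to-zero contrasts so main effects stay
#' interpretable in the presence of interactions. Per-coefficient t
#' statistics get Satterthwaite denominator degrees of freedom via the
#' delta method over the two variance components, using the analytic
#' gradient of the contrast variance and the inverse expected REML
#' information as the asymptotic covariance of the variance estimates. For
#' balanced designs and purely within-subject contrasts this reproduces
#' the exact residual df (`N_obs - N_subjects - (rank(X) - 1)`).
#'
#' @param data a data frame / tibble.
#' @param formula fixed-effects formula, e.g. `pr ~ category * stimulation`.
#' @param subject name of the grouping column (default "subject").
#' @param reml use REML (default TRUE); FALSE gives maximum likelihood,
#'   needed for information-criterion model comparison.
#' @return an object of class `lmm_ri`; see [tidy.lmm_ri()] /
#'   [glance.lmm_ri()].
#' @export
#' @examples
#' d <- tidyr::expand_grid(subject = sprintf("S%02d", 1:10),
#'                         a = c("x", "y"), b = c("u", "v"))
#' d$y <- rnorm(nrow(d))
#' fit <- fit_lmm_ri(d, y ~ a * b)
#' tidy(fit)
fit_lmm_ri <- function(data, formula, subject = "subject", reml = TRUE) {
  stopifnot(subject %in% names(data))
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  fac <- names(Filter(function(v) is.factor(v) || is.character(v), mf))
  contr <- stats::setNames(rep(list("contr.sum"), length(fac)), fac)
  X <- stats::model.matrix(formula, mf,
                           contrasts.arg = if (length(contr)) contr else NULL)
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design")
  g <- factor(data[[subject]][as.integer(rownames(mf))])
  if (nlevels(g) < 2) stop("need at least 2 subjects")
  if (min(table(g)) < 2) stop("need at least 2 observations per subject")

  N <- length(y); p <- ncol(X)
  # center the response when an intercept is present: identical model, but
  # avoids cancellation in the profiled RSS for responses far from zero
  y_raw <- y
  has_int <- "(Intercept)" %in% colnames(X)
  mu <- if (has_int) mean(y) else 0
  y <- y - mu
  gi <- split(seq_len(N), g)
  ni <- lengths(gi)
  # per-group sums reused at every lambda
  Xg <- t(vapply(gi, function(ix) colSums(X[ix, , drop = FALSE]), numeric(p)))
  if (p == 1) Xg <- matrix(Xg, ncol = 1)
  yg <- vapply(gi, function(ix) sum(y[ix]), numeric(1))
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y^2)

  gls <- function(lambda) {
    ci <- lambda / (1 + lambda * ni)
    A <- XtX - crossprod(Xg * sqrt(ci))
    b <- Xty - crossprod(Xg, ci * yg)
    beta <- solve(A, b)
    rss <- yty - sum(ci * yg^2) - sum(b * beta)
    list(A = A, beta = drop(beta), rss = drop(rss),
         logdet_blocks = sum(log1p(lambda * ni)))
  }
  crit <- function(lambda) {
    f <- gls(lambda)
    if (reml) {
      (N - p) * log(f$rss) + f$logdet_blocks + determinant(f$A)$modulus[1]
    } else {
      N * log(f$rss) + f$logdet_blocks
    }
  }
  opt <- stats::optimize(function(t) crit(exp(t)), c(-25, 25), tol = 1e-10)
  lambda <- exp(opt$minimum)
  if (crit(0) <= opt$objective) lambda <- 0
  f <- gls(lambda)
  sigma2_e <- f$rss / if (reml) N - p else N
  sigma2_s <- lambda * sigma2_e
  vcov_beta <- solve(f$A) * sigma2_e

  ll <- -0.5 * if (reml) {
    (N - p) * log(2 * pi * sigma2_e) + f$logdet_blocks +
      determinant(f$A)$modulus[1] + (N - p)
  } else {
    N * log(2 * pi * sigma2_e) + f$logdet_blocks + N
  }
  n_par <- p + 2
  bic <- -2 * ll + n_par * log(N)

  sat <- .satterthwaite_df(X, gi, ni, sigma2_s, sigma2_e)
  est <- unname(f$beta)
  if (has_int) est[match("(Intercept)", colnames(X))] <-
    est[match("(Intercept)", colnames(X))] + mu
  se <- unname(sqrt(diag(vcov_beta)))
  tval <- est / se
  coefs <- tibble::tibble(
    term = colnames(X), estimate = est, std.error = se, statistic = tval,
    df = sat, p.value = 2 * stats::pt(abs(tval), sat, lower.tail = FALSE)
  )
  structure(
    list(coefficients = coefs, vcov = vcov_beta,
         sigma2_subject = sigma2_s, sigma2_resid = sigma2_e,
         lambda = lambda, logLik = ll, BIC = bic, reml = reml,
         nobs = N, n_subjects = nlevels(g), rank = p,
         formula = formula, subject = subject, response = y_raw,
         data = data),
    class = "lmm_ri"
  )
}

# Satterthwaite df per coefficient: df = 2 f^2 / (grad' Vg grad), where
# f(gamma) = [ (X' V^-1 X)^-1 ]_jj, gamma = (sigma_s^2, sigma_e^2), and
# Vg = 2 * inverse expected REML information of gamma. Ainv_unit is
# (X' Vstar^-1 X)^-1 on the unit-residual scale.
.satterthwaite_df <- function(X, gi, ni, sigma2_s, sigma2_e) {
  N <- nrow(X); p <- ncol(X)
  # dense V^-1 via blocks: V = sigma2_e I + sigma2_s J within subject
  Vinv <- matrix(0, N, N)
  for (k in seq_along(gi)) {
    ix <- gi[[k]]; n_k <- ni[k]
    blk <- -matrix(sigma2_s / (sigma2_e * (sigma2_e + n_k * sigma2_s)), n_k, n_k)
    diag(blk) <- diag(blk) + 1 / sigma2_e
    Vinv[ix, ix] <- blk
  }
  W1 <- Vinv %*% X                       # V^-1 X
  A <- crossprod(X, W1)                  # X' V^-1 X (full scale)
  Ainv <- solve(A)
  # P = V^-1 - V^-1 X A^-1 X' V^-1
  P <- Vinv - W1 %*% tcrossprod(Ainv, W1)
  # G1 = ZZ' (block ones), G2 = I; PG1 assembled from row-blocks of P
  PG1 <- matrix(0, N, N)
  for (k in seq_along(gi)) {
    ix <- gi[[k]]
    PG1[, ix] <- rowSums(P[, ix, drop = FALSE])
  }
  info <- matrix(0, 2, 2)
  info[1, 1] <- 0.5 * sum(PG1 * t(PG1))
  info[1, 2] <- info[2, 1] <- 0.5 * sum(PG1 * t(P))
  info[2, 2] <- 0.5 * sum(P * t(P))
  # asymptotic covariance of the REML variance estimates: inverse information
  Vg <- tryCatch(solve(info), error = function(e) solve(info + diag(1e-12, 2)))
  # gradients of f_j = [A^-1]_jj : df/dg_k = [A^-1 X'V^-1 G_k V^-1 X A^-1]_jj
  B1 <- crossprod(W1, .block_mult(W1, gi))  # X'V^-1 G1 V^-1 X
  B2 <- crossprod(W1)                       # X'V^-1 I V^-1 X
  M1 <- Ainv %*% B1 %*% Ainv
  M2 <- Ainv %*% B2 %*% Ainv
  vapply(seq_len(p), function(j) {
    fj <- Ainv[j, j]
    grad <- c(M1[j, j], M2[j, j])
    denom <- drop(t(grad) %*% Vg %*% grad)
    if (denom <= 0) return(N - p)
    2 * fj^2 / denom
  }, numeric(1))
}

# ZZ' %*% M computed blockwise (column sums repeated within each subject)
.block_mult <- function(M, gi) {
  out <- matrix(0, nrow(M), ncol(M))
  for (ix in gi) {
    cs <- colSums(M[ix, , drop = FALSE])
    out[ix, ] <- matrix(cs, length(ix), ncol(M), byrow = TRUE)
  }
  out
}

#' @export
print.lmm_ri <- function(x, ...) {
  cat(sprintf(
    "<lmm_ri> %s fit: %d obs, %d subjects\nvariance components: subject %.4g, residual %.4g\n",
    if (x$reml) "REML" else "ML", x$nobs, x$n_subjects,
    x$sigma2_subject, x$sigma2_resid
  ))
  print(x$coefficients, ...)
  invisible(x)
}

#' Tidy / glance methods for random-intercept fits
#'
#' @param x an `lmm_ri` fit.
#' @param ... unused.
#' @return `tidy`: one row per fixed-effect coefficient (term, estimate,
#'   std.error, statistic, df, p.value); `glance`: one-row model summary.
#' @method tidy lmm_ri
#' @export
tidy.lmm_ri <- function(x, ...) x$coefficients

#' @rdname tidy.lmm_ri
#' @method glance lmm_ri
#' @export
glance.lmm_ri <- function(x, ...) {
  tibble::tibble(
    sigma2_subject = x$sigma2_subject, sigma2_resid = x$sigma2_resid,
    logLik = x$logLik, BIC = x$BIC, nobs = x$nobs,
    n_subjects = x$n_subjects, reml = x$reml
  )
}

.bf_band <- function(bf) {
  br <- c(0, 1 / 100, 1 / 30, 1 / 10, 1 / 3, 1, 3, 10, 30, 100, Inf)
  lab <- c("extreme for H0", "very strong for H0", "strong for H0",
           "moderate for H0", "anecdotal for H0", "anecdotal for H1",
           "moderate for H1", "strong for H1", "very strong for H1",
           "extreme for H1")
  lab[findInterval(bf, br, rightmost.closed = TRUE, left.open = TRUE) ]
}

#' BIC-approximate Bayes factor between nested mixed models
#'
#' `BF10 = exp((BIC_null - BIC_alt) / 2)`, the Bayesian-information
#' approximation to the Bayes factor in favor of the fuller model. Both
#' models are refit by maximum likelihood on identical data if they were
#' estimated by REML. The evidence label follows the conventional
#' anecdotal / moderate / strong / very strong / extreme bands.
#'
#' This is an approximation, not a reimplementation of default-prior
#' Bayesian ANOVA; it is monotone in the evidence for these designs but
#' its numerical values are not comparable to JZS-prior Bayes factors.
#'
#' @param fit_alt,fit_null `lmm_ri` fits on the same data; `fit_null`'s
#'   fixed terms must be a subset of `fit_alt`'s.
#' @return one-row tibble: bf10, label, method, bic_alt, bic_null.
#' @export
bf10_bic <- function(fit_alt, fit_null) {
  stopifnot(inherits(fit_alt, "lmm_ri"), inherits(fit_null, "lmm_ri"))
  if (fit_alt$nobs != fit_null$nobs ||
      !isTRUE(all.equal(fit_alt$response, fit_null$response))) {
    stop("models were not fit to identical data")
  }
  canon <- function(f) {
    tl <- attr(stats::terms(f), "term.labels")
    vapply(strsplit(tl, ":", fixed = TRUE),
           function(x) paste(sort(x), collapse = ":"), character(1))
  }
  if (!all(canon(fit_null$formula) %in% canon(fit_alt$formula))) {
    stop("models are not nested")
  }
  if (fit_alt$reml) fit_alt <- fit_lmm_ri(fit_alt$data, fit_alt$formula,
                                          fit_alt$subject, reml = FALSE)
  if (fit_null$reml) fit_null <- fit_lmm_ri(fit_null$data, fit_null$formula,
                                            fit_null$subject, reml = FALSE)
  bf <- exp((fit_null$BIC - fit_alt$BIC) / 2)
  tibble::tibble(
    bf10 = bf, label = .bf_band(bf), method = "BIC-approximation",
    bic_alt = fit_alt$BIC, bic_null = fit_null$BIC
  )
}
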