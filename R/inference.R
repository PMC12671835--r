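#' Log-likelihood and score of the FPF distribution
#'
#' For a sample `x` in `(a, b]` with `v_i = (x_i - a)/(b - a)` and
#' `lambda = alpha * theta`, the log-likelihood is
#' \deqn{\ell = n \log\lambda - n\log(b-a) - n\log(1 - e^{-1})
#'   + (\lambda - 1) \sum \log v_i - \sum v_i^\lambda.}
#' `fpf_score()` returns the partial derivatives with respect to `alpha`
#' and `theta`. Because `ell` depends on the shapes only through `lambda`,
#' the exact ridge identity `alpha * d ell/d alpha = theta * d ell/d theta`
#' holds for every sample: individually, `alpha` and `theta` are not
#' identified.
#'
#' @inheritParams fpf-distribution
#' @param x Numeric sample; every value must satisfy `a < x <= b` (values
#'   equal to `b` have finite density and are admitted).
#' @return `fpf_loglik`: a scalar. `fpf_score`: a named length-2 vector
#'   `c(alpha = , theta = )`.
#' @examples
#' x <- rfpf(50, alpha = 1, theta = 1, seed = 1)
#' fpf_loglik(x, alpha = 2, theta = 3) == fpf_loglik(x, alpha = 3, theta = 2)
#' @export
fpf_loglik <- function(x, alpha = 1, theta = 1, a = 0, b = 1) {
  p <- resolve_params(alpha, theta, a, b)
  lv <- check_sample_logv(x, p)
  ll_lambda(p$lambda, lv, width = p$b - p$a)
}

#' @rdname fpf_loglik
#' @export
fpf_score <- function(x, alpha = 1, theta = 1, a = 0, b = 1) {
  p <- resolve_params(alpha, theta, a, b)
  lv <- check_sample_logv(x, p)
  g <- score_lambda(p$lambda, lv)  # d ell / d lambda
  c(alpha = p$theta * g, theta = p$alpha * g)
}

# log v_i with domain checks; the single quantity the likelihood needs
check_sample_logv <- function(x, p) {
  if (length(x) < 1) stop("empty sample.", call. = FALSE)
  if (any(!is.finite(x))) stop("sample contains non-finite values.", call. = FALSE)
  if (any(x <= p$a))
    stop("likelihood undefined: sample value(s) <= a = ", p$a, ".", call. = FALSE)
  if (any(x > p$b))
    stop("sample value(s) above the upper bound b = ", p$b, ".", call. = FALSE)
  log_v(x, p$a, p$b)
}

ll_lambda <- function(lam, lv, width = 1) {
  n <- length(lv)
  n * log(lam) - n * log(width) - n * log(.fpf_c) +
    (lam - 1) * sum(lv) - sum(exp(lam * lv))
}

score_lambda <- function(lam, lv) {
  length(lv) / lam + sum(lv) - sum(exp(lam * lv) * lv)
}

info_lambda <- function(lam, lv) {
  length(lv) / lam^2 + sum(exp(lam * lv) * lv^2)
}

# Solve score_lambda(lam) = 0. The score is strictly decreasing with a
# unique root whenever sum(lv) < 0; bracket geometrically from the Power
# Function closed form lam0 = -n / sum(lv).
solve_lambda <- function(lv) {
  s1 <- sum(lv)
  if (s1 >= 0)
    stop("fit_fpf: degenerate sample (all values at the upper bound); ",
         "the score equation has no root.", call. = FALSE)
  lam0 <- -length(lv) / s1
  lo <- lam0; hi <- lam0
  for (i in 1:80) {
    lo <- lo / 2
    if (score_lambda(lo, lv) > 0) break
  }
  for (i in 1:80) {
    hi <- hi * 2
    if (score_lambda(hi, lv) < 0) break
  }
  if (score_lambda(lo, lv) <= 0 || score_lambda(hi, lv) >= 0)
    stop("fit_fpf: could not bracket the score root in [1e-6, 1e6]-scale ",
         "search.", call. = FALSE)
  r <- uniroot(score_lambda, c(lo, hi), lv = lv, tol = 1e-12)
  r$root
}

#' Maximum-likelihood fit of the FPF distribution
#'
#' The FPF likelihood depends on `(alpha, theta)` only through the product
#' `lambda = alpha * theta`, so the maximisation is one-dimensional: the
#' score equation
#' \deqn{n/\lambda + \sum \log v_i - \sum v_i^\lambda \log v_i = 0}
#' is solved by safeguarded bracketing + root-finding (the score is strictly
#' decreasing in `lambda`, so the root is unique). Individual shape
#' estimates are presentation conveniences: with `mode = "theta-fixed"` the
#' fit reports `alpha-hat = lambda-hat / theta0`, and symmetrically for
#' `mode = "alpha-fixed"`. `mode = "lambda"` reports only the product.
#'
#' When `bounds` is `NULL` the support is resolved by `bounds_rule`:
#' `"zero-to-max"` (default) uses `a = 0`, `b = max(x)` — likelihood-proper
#' because the FPF density is finite at `b` — and `"zero-to-inflated-max"`
#' uses `b = (1 + 1e-6) * max(x)` for users worried about boundary points.
#'
#' @param x Numeric sample (`n >= 2`).
#' @param bounds Optional length-2 numeric `c(a, b)`; overrides
#'   `bounds_rule`.
#' @param bounds_rule Rule used to resolve the support when `bounds` is
#'   missing.
#' @param mode `"lambda"`, `"theta-fixed"` or `"alpha-fixed"`.
#' @param fixed Value at which the partner parameter is fixed (required for
#'   the `*-fixed` modes).
#' @return An object of class `fpf_fit` with elements `lambda`, `se_lambda`,
#'   `loglik`, `mode`, `fixed`, `alpha`, `theta`, `bounds`, `n`, `data`,
#'   `converged`, `score_at_mle`.
#' @examples
#' x <- rfpf(200, alpha = 1, theta = 2, a = 0, b = 1, seed = 42)
#' fit <- fit_fpf(x, bounds = c(0, 1))
#' tidy(fit)
#' @export
fit_fpf <- function(x, bounds = NULL,
                    bounds_rule = c("zero-to-max", "zero-to-inflated-max"),
                    mode = c("lambda", "theta-fixed", "alpha-fixed"),
                    fixed = NULL) {
  mode <- match.arg(mode)
  if (length(x) < 2) stop("fit_fpf needs at least 2 observations.", call. = FALSE)
  bounds <- resolve_bounds(x, bounds, match.arg(bounds_rule))
  p0 <- fpf_params(1, 1, bounds[1], bounds[2])
  lv <- check_sample_logv(x, p0)
  lam <- solve_lambda(lv)
  info <- info_lambda(lam, lv)
  n <- length(x)
  ll <- ll_lambda(lam, lv, width = bounds[2] - bounds[1])

  alpha <- theta <- NA_real_
  if (mode == "theta-fixed") {
    if (is.null(fixed)) stop("`fixed` (theta0) is required.", call. = FALSE)
    theta <- fixed; alpha <- lam / fixed
  } else if (mode == "alpha-fixed") {
    if (is.null(fixed)) stop("`fixed` (alpha0) is required.", call. = FALSE)
    alpha <- fixed; theta <- lam / fixed
  }
  structure(
    list(
      lambda = lam, se_lambda = 1 / sqrt(info), info_lambda = info,
      loglik = ll, mode = mode, fixed = fixed,
      alpha = alpha, theta = theta,
      bounds = bounds, n = n, data = x,
      converged = TRUE, score_at_mle = score_lambda(lam, lv)
    ),
    class = "fpf_fit"
  )
}

resolve_bounds <- function(x, bounds, rule) {
  if (!is.null(bounds)) {
    check_bounds(bounds[1], bounds[2])
    return(as.numeric(bounds))
  }
  switch(rule,
    "zero-to-max" = c(0, max(x)),
    "zero-to-inflated-max" = c(0, (1 + 1e-6) * max(x))
  )
}

#' @export
print.fpf_fit <- function(x, ...) {
  cat("FPF maximum-likelihood fit (n =", x$n, ")\n")
  cat(sprintf("  lambda-hat = %.6g (SE %.3g), log-likelihood %.4f\n",
              x$lambda, x$se_lambda, x$loglik))
  cat(sprintf("  support (%g, %g), mode %s\n",
              x$bounds[1], x$bounds[2], x$mode))
  if (x$mode == "theta-fixed")
    cat(sprintf("  alpha-hat = %.6g at theta = %g\n", x$alpha, x$theta))
  if (x$mode == "alpha-fixed")
    cat(sprintf("  theta-hat = %.6g at alpha = %g\n", x$theta, x$alpha))
  invisible(x)
}

#' @export
logLik.fpf_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n, class = "logLik")
}

#' Observed information of the FPF likelihood
#'
#' Returns the observed information in the identifying product parameter,
#' \deqn{-d^2\ell/d\lambda^2 = n/\lambda^2 + \sum v_i^\lambda (\log v_i)^2,}
#' always positive, together with the 2x2 matrix in `(theta, alpha)`
#' assembled from the chain rule. Because the likelihood is a function of
#' `lambda` alone, that matrix is singular at any stationary point of
#' `lambda` (its determinant vanishes with the score); a `singular`
#' diagnostic flag is attached.
#'
#' @inheritParams fpf_loglik
#' @return A list with `lambda` (scalar information), `matrix` (2x2, rows
#'   and columns ordered theta, alpha), `det`, and `singular`.
#' @export
observed_information <- function(x, alpha = 1, theta = 1, a = 0, b = 1) {
  p <- resolve_params(alpha, theta, a, b)
  lv <- check_sample_logv(x, p)
  lam <- p$lambda
  g1 <- score_lambda(lam, lv)         # d ell / d lambda
  g2 <- -info_lambda(lam, lv)         # d^2 ell / d lambda^2
  # ell(alpha, theta) = G(alpha * theta):
  #   d2/dtheta2 = alpha^2 G'', d2/dalpha2 = theta^2 G'',
  #   cross = G' + lambda G''
  m <- -matrix(c(p$alpha^2 * g2, g1 + lam * g2,
                 g1 + lam * g2, p$theta^2 * g2),
               2, 2, dimnames = list(c("theta", "alpha"), c("theta", "alpha")))
  d <- det(m)
  list(
    lambda = -g2,
    matrix = m,
    det = d,
    singular = abs(d) <= 1e-8 * sum(diag(m))^2
  )
}

#' Wald and bootstrap confidence intervals for an FPF fit
#'
#' `wald_ci()` builds `point +/- z * SE` on the `lambda` scale from the
#' observed information; in the `theta-fixed` / `alpha-fixed` modes the
#' interval is transported to the free shape parameter by dividing by the
#' fixed partner (the map is linear, so no delta approximation is
#' involved). `bootstrap_ci()` resamples the data with replacement,
#' refits `lambda` per resample, and returns the percentile interval.
#'
#' @param fit An [fit_fpf] result.
#' @param level Confidence level (default 0.95).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Optional integer seed for reproducible resampling.
#' @return A one-row tibble with columns `term`, `estimate`, `lower`,
#'   `upper`, `level`, `method` (and `n_boot` for the bootstrap).
#' @examples
#' x <- rfpf(100, alpha = 1, theta = 1, seed = 7)
#' fit <- fit_fpf(x, bounds = c(0, 1))
#' wald_ci(fit)
#' @export
wald_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "fpf_fit"))
  if (!is.finite(fit$se_lambda))
    stop("wald_ci: non-finite standard error.", call. = FALSE)
  z <- qnorm(1 - (1 - level) / 2)
  scale <- ci_scale(fit)
  tibble::tibble(
    term = scale$term,
    estimate = fit$lambda / scale$div,
    lower = (fit$lambda - z * fit$se_lambda) / scale$div,
    upper = (fit$lambda + z * fit$se_lambda) / scale$div,
    level = level, method = "wald"
  )
}

#' @rdname wald_ci
#' @export
bootstrap_ci <- function(fit, n_boot = 1000, level = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "fpf_fit"))
  x <- fit$data
  if (length(x) < 10)
    stop("bootstrap_ci needs at least 10 observations.", call. = FALSE)
  boot <- function() {
    vapply(seq_len(n_boot), function(i) {
      xb <- sample(x, replace = TRUE)
      tryCatch(
        fit_fpf(xb, bounds = fit$bounds)$lambda,
        error = function(e) NA_real_
      )
    }, numeric(1))
  }
  lams <- with_local_seed(seed, boot())
  fail <- sum(is.na(lams))
  if (fail > 0.05 * n_boot)
    stop("bootstrap_ci: ", fail, " of ", n_boot, " resample fits failed.",
         call. = FALSE)
  qs <- quantile(lams, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
  scale <- ci_scale(fit)
  tibble::tibble(
    term = scale$term,
    estimate = fit$lambda / scale$div,
    lower = qs[[1]] / scale$div,
    upper = qs[[2]] / scale$div,
    level = level, method = "bootstrap-percentile", n_boot = n_boot
  )
}

ci_scale <- function(fit) {
  switch(fit$mode,
    "lambda" = list(term = "lambda", div = 1),
    "theta-fixed" = list(term = "alpha", div = fit$theta),
    "alpha-fixed" = list(term = "theta", div = fit$alpha)
  )
}

#' @export
confint.fpf_fit <- function(object, parm, level = 0.95, ...) {
  ci <- wald_ci(object, level = level)
  out <- matrix(c(ci$lower, ci$upper), nrow = 1,
                dimnames = list(ci$term,
                                sprintf("%.1f %%", c((1 - level) / 2,
                                                     1 - (1 - level) / 2) * 100)))
  out
}

#' Tidiers for FPF fits
#'
#' `tidy()` returns one row per reported parameter with Wald intervals;
#' `glance()` returns a one-row model summary.
#'
#' @param x An [fit_fpf] object.
#' @param conf.level Confidence level for the Wald interval.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.fpf_fit <- function(x, conf.level = 0.95, ...) {
  ci <- wald_ci(x, level = conf.level)
  rows <- tibble::tibble(
    term = ci$term,
    estimate = ci$estimate,
    std.error = x$se_lambda / ci_scale(x)$div,
    conf.low = ci$lower,
    conf.high = ci$upper
  )
  if (x$mode != "lambda") {
    rows <- dplyr::bind_rows(
      tibble::tibble(term = "lambda", estimate = x$lambda,
                     std.error = x$se_lambda,
                     conf.low = x$lambda - qnorm(1 - (1 - conf.level) / 2) * x$se_lambda,
                     conf.high = x$lambda + qnorm(1 - (1 - conf.level) / 2) * x$se_lambda),
      rows
    )
  }
  rows
}

#' @rdname tidy.fpf_fit
#' @exportS3Method generics::glance
glance.fpf_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    AIC = 2 * 2 - 2 * x$loglik,
    BIC = 2 * log(x$n) - 2 * x$loglik,
    nobs = x$n,
    lambda = x$lambda,
    converged = x$converged
  )
}
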