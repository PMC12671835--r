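#' Competitor bounded-lifetime models
#'
#' Fitting functions for the seven comparison distributions used alongside
#' the FPF model: the Exponential (ED), Power Function (PFD), alpha-Power
#' Transformed Power Function (APPFD), Weibull-Power Function (WPFD),
#' Kumaraswamy-Power Function (KPFD), Marshall-Olkin Power Function (MOPFD)
#' and Exponentiated Power Function (EPFD). Each returns an `fpf_model`
#' object carrying the estimates, the log-likelihood (total and
#' per-observation), the number of freely estimated parameters `k` used for
#' information criteria, and closures for the fitted density and CDF.
#'
#' Exponential and Power Function maximum-likelihood estimates are closed
#' form; the rest use multi-start box-constrained quasi-Newton optimisation
#' on the log-parameter scale (best log-likelihood wins, ties broken by the
#' smallest parameter norm).
#'
#' @param x Positive numeric sample.
#' @param bounds Length-2 numeric support `c(a, b)` (or `c(0, gamma)` for
#'   the models bounded above by `gamma`).
#' @return An object of class `fpf_model`.
#' @name competitors
NULL

new_fpf_model <- function(name, k, estimates, loglik_i, pdf, cdf, n, bounds,
                          converged = TRUE) {
  structure(
    list(name = name, k = k, estimates = estimates,
         loglik = sum(loglik_i), loglik_i = loglik_i,
         pdf = pdf, cdf = cdf, n = n, bounds = bounds,
         converged = converged),
    class = "fpf_model"
  )
}

#' @export
print.fpf_model <- function(x, ...) {
  est <- paste(sprintf("%s = %.4f", names(x$estimates), x$estimates),
               collapse = ", ")
  cat(sprintf("%s fit (n = %d, k = %d): %s\n  log-likelihood %.4f%s\n",
              x$name, x$n, x$k, est, x$loglik,
              if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' @export
logLik.fpf_model <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @rdname competitors
#' @export
fit_exp_model <- function(x) {
  if (any(x <= 0)) stop("Exponential fit needs strictly positive data.",
                        call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("zero mean.", call. = FALSE)
  rate <- 1 / m
  new_fpf_model(
    "ED", k = 1L, estimates = c(lambda = rate),
    loglik_i = log(rate) - rate * x,
    pdf = function(z) rate * exp(-rate * z),
    cdf = function(z) 1 - exp(-rate * pmax(z, 0)),
    n = length(x), bounds = c(0, Inf)
  )
}

#' @rdname competitors
#' @export
fit_pf <- function(x, bounds) {
  a <- bounds[1]; b <- bounds[2]
  if (any(x <= a) || any(x > b))
    stop("Power Function fit needs data in (a, b].", call. = FALSE)
  lv <- log_v(x, a, b)
  theta <- -length(x) / sum(lv)
  new_fpf_model(
    "PFD", k = 1L, estimates = c(theta = theta),
    loglik_i = log(theta) - log(b - a) + (theta - 1) * lv,
    pdf = function(z) theta / (b - a) * ((z - a) / (b - a))^(theta - 1),
    cdf = function(z) pmin(pmax((z - a) / (b - a), 0), 1)^theta,
    n = length(x), bounds = bounds
  )
}

# Multi-start bounded quasi-Newton on the log-parameter scale. `nll` takes
# the natural-scale parameter vector; `starts` is a matrix of natural-scale
# starting points (one row each).
mle_multistart <- function(nll, starts, box = 10) {
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(log(starts[i, ]), function(lp) nll(exp(lp)),
            method = "L-BFGS-B", lower = -box, upper = box,
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) ||
        fit$value < best$value - 1e-9 ||
        (abs(fit$value - best$value) <= 1e-9 &&
         sum(exp(fit$par)^2) < sum(exp(best$par)^2))) {
      best <- fit
    }
  }
  if (is.null(best)) stop("all optimisation starts failed.", call. = FALSE)
  list(par = unname(exp(best$par)), value = best$value,
       converged = best$convergence == 0)
}

log_spaced_starts <- function(centers, n_each = 5) {
  grids <- lapply(centers, function(c0) c0 * exp(seq(-2, 2, length.out = n_each)))
  as.matrix(expand.grid(grids))
}

#' @rdname competitors
#' @export
fit_aptpf <- function(x, bounds) {
  a <- bounds[1]; b <- bounds[2]
  if (any(x <= a) || any(x > b))
    stop("APT-PF fit needs data in (a, b].", call. = FALSE)
  v <- (x - a) / (b - a)
  lv <- log_v(x, a, b)
  # f = C(alpha) * theta (x-a)^(theta-1)/(b-a)^theta * alpha^(v^theta),
  # C(alpha) = log(alpha)/(alpha - 1), continuous limit 1 at alpha = 1
  logC <- function(al) {
    if (abs(al - 1) < 1e-8) -(al - 1) / 2 + (al - 1)^2 / 3
    else log(log(al) / (al - 1))
  }
  ll_i <- function(par) {
    al <- par[1]; th <- par[2]
    logC(al) + log(th) - log(b - a) + (th - 1) * lv + v^th * log(al)
  }
  nll <- function(par) -sum(ll_i(par))
  starts <- log_spaced_starts(c(1.5, -length(x) / sum(lv)), n_each = 5)
  opt <- mle_multistart(nll, starts)
  al <- opt$par[1]; th <- opt$par[2]
  new_fpf_model(
    "APPFD", k = 2L, estimates = c(alpha = al, theta = th),
    loglik_i = ll_i(opt$par),
    pdf = function(z) {
      vz <- (z - a) / (b - a)
      exp(logC(al)) * th / (b - a) * vz^(th - 1) * al^(vz^th)
    },
    cdf = function(z) {
      vz <- pmin(pmax((z - a) / (b - a), 0), 1)
      if (abs(al - 1) < 1e-8) vz^th else (al^(vz^th) - 1) / (al - 1)
    },
    n = length(x), bounds = bounds, converged = opt$converged
  )
}

#' @rdname competitors
#' @param form Reading of the printed Weibull-Power Function CDF: the
#'   default `"ratio"` uses the odds `x/(b - x)` inside the Weibull
#'   exponent, which is a proper CDF increasing to 1 at `b`. The
#'   `"product"` reading `x^theta (b-x)^theta` is exposed for completeness
#'   by [wpf_cdf] but is not a valid CDF (it returns 0 at `b`), so fitting
#'   with it is refused.
#' @export
fit_wpf <- function(x, bounds, form = c("ratio", "product")) {
  form <- match.arg(form)
  if (form == "product")
    stop("fit_wpf: the 'product' reading is not a valid CDF ",
         "(F(b) = 0); use form = 'ratio'.", call. = FALSE)
  b <- bounds[2]
  if (any(x <= 0) || any(x >= b))
    stop("WPF fit needs data in (0, b).", call. = FALSE)
  w <- x / (b - x)
  lw <- log(w)
  # F = 1 - exp(-a0 * w^kappa); theta and alpha enter only via kappa =
  # theta * alpha, so the fit is over (a0, kappa) and reports the equal
  # split theta = alpha = sqrt(kappa)
  ll_i <- function(par) {
    a0 <- par[1]; ka <- par[2]
    log(a0) + log(ka) + (ka - 1) * lw + log(b) - 2 * log(b - x) - a0 * w^ka
  }
  nll <- function(par) -sum(ll_i(par))
  opt <- mle_multistart(nll, log_spaced_starts(c(1, 1), n_each = 5))
  a0 <- opt$par[1]; ka <- opt$par[2]
  new_fpf_model(
    "WPFD", k = 3L,
    estimates = c(a = a0, theta = sqrt(ka), alpha = sqrt(ka)),
    loglik_i = ll_i(opt$par),
    pdf = function(z) {
      wz <- z / (b - z)
      a0 * ka * wz^(ka - 1) * b / (b - z)^2 * exp(-a0 * wz^ka)
    },
    cdf = function(z) wpf_cdf(z, a = a0, theta = sqrt(ka), alpha = sqrt(ka),
                              b = b, form = "ratio"),
    n = length(x), bounds = c(0, b), converged = opt$converged
  )
}

#' Weibull-Power Function CDF under either reading of its exponent
#'
#' @param q Quantiles.
#' @param a,theta,alpha Positive parameters.
#' @param b Upper support bound.
#' @param form `"ratio"` (proper CDF, the default) or `"product"` (the
#'   literal alternative reading, which is not monotone to 1 and is exposed
#'   only for inspection).
#' @return Numeric vector.
#' @export
wpf_cdf <- function(q, a, theta, alpha, b, form = c("ratio", "product")) {
  form <- match.arg(form)
  ka <- theta * alpha
  if (form == "ratio") {
    q <- pmin(pmax(q, 0), b)
    w <- ifelse(q >= b, Inf, q / (b - q))
    1 - exp(-a * w^ka)
  } else {
    1 - exp(-a * (pmax(q, 0) * pmax(b - q, 0))^ka)
  }
}

#' @rdname competitors
#' @export
fit_kwpf <- function(x, bounds) {
  gam <- bounds[2]
  if (any(x <= 0) || any(x >= gam))
    stop("Kumaraswamy-PF fit needs data in (0, gamma).", call. = FALSE)
  u <- x / gam
  lu <- log(u)
  # F = 1 - (1 - u^kappa)^beta with kappa = theta * alpha (jointly
  # unidentifiable split; reported as theta = alpha = sqrt(kappa))
  ll_i <- function(par) {
    ka <- par[1]; be <- par[2]
    log(ka) + log(be) - log(gam) + (ka - 1) * lu +
      (be - 1) * log1p(-u^ka)
  }
  nll <- function(par) -sum(ll_i(par))
  opt <- mle_multistart(nll, log_spaced_starts(c(1, 1), n_each = 5))
  ka <- opt$par[1]; be <- opt$par[2]
  new_fpf_model(
    "KPFD", k = 2L,
    estimates = c(theta = sqrt(ka), alpha = sqrt(ka), beta = be),
    loglik_i = ll_i(opt$par),
    pdf = function(z) {
      uz <- z / gam
      ka * be / gam * uz^(ka - 1) * (1 - uz^ka)^(be - 1)
    },
    cdf = function(z) {
      uz <- pmin(pmax(z / gam, 0), 1)
      1 - (1 - uz^ka)^be
    },
    n = length(x), bounds = c(0, gam), converged = opt$converged
  )
}

#' @rdname competitors
#' @export
fit_mopf <- function(x, bounds) {
  gam <- bounds[2]
  if (any(x <= 0) || any(x > gam))
    stop("Marshall-Olkin PF fit needs data in (0, gamma].", call. = FALSE)
  u <- x / gam
  lu <- log(u)
  # Standard Marshall-Olkin tilt of the PF CDF:
  #   F = u^beta / (alpha + (1 - alpha) u^beta);  alpha = 1 recovers PF
  ll_i <- function(par) {
    al <- par[1]; be <- par[2]
    p <- u^be
    log(al) + log(be) + be * lu - lu - log(gam) -
      2 * log(al + (1 - al) * p)
  }
  nll <- function(par) -sum(ll_i(par))
  opt <- mle_multistart(nll, log_spaced_starts(c(1, 1), n_each = 5))
  al <- opt$par[1]; be <- opt$par[2]
  new_fpf_model(
    "MOPFD", k = 2L, estimates = c(alpha = al, beta = be),
    loglik_i = ll_i(opt$par),
    pdf = function(z) {
      p <- (z / gam)^be
      al * be * p / (z * (al + (1 - al) * p)^2)
    },
    cdf = function(z) {
      p <- pmin(pmax(z / gam, 0), 1)^be
      p / (al + (1 - al) * p)
    },
    n = length(x), bounds = c(0, gam), converged = opt$converged
  )
}

#' @rdname competitors
#' @export
fit_epf <- function(x, bounds) {
  a <- bounds[1]; b <- bounds[2]
  if (any(x <= a) || any(x >= b))
    stop("Exponentiated PF fit needs data in (a, b).", call. = FALSE)
  s <- (b - x) / (b - a)   # reversed scaled distance
  ls <- log(s)
  # F = (1 - s^theta)^alpha
  ll_i <- function(par) {
    th <- par[1]; al <- par[2]
    log(al) + log(th) - log(b - a) + (th - 1) * ls +
      (al - 1) * log1p(-s^th)
  }
  nll <- function(par) -sum(ll_i(par))
  opt <- mle_multistart(nll, log_spaced_starts(c(1, 1), n_each = 5))
  th <- opt$par[1]; al <- opt$par[2]
  new_fpf_model(
    "EPFD", k = 2L, estimates = c(theta = th, alpha = al),
    loglik_i = ll_i(opt$par),
    pdf = function(z) {
      sz <- (b - z) / (b - a)
      al * th / (b - a) * sz^(th - 1) * (1 - sz^th)^(al - 1)
    },
    cdf = function(z) {
      sz <- pmin(pmax((b - z) / (b - a), 0), 1)
      (1 - sz^th)^al
    },
    n = length(x), bounds = bounds, converged = opt$converged
  )
}

# FPF itself in the common competitor container (k = 2, the conventional
# count for the two printed shape parameters)
fit_fpf_model <- function(x, bounds) {
  fit <- fit_fpf(x, bounds = bounds)
  lam <- fit$lambda
  a <- bounds[1]; b <- bounds[2]
  p <- fpf_params(1, lam, a, b)
  new_fpf_model(
    "FPFD", k = 2L,
    estimates = c(lambda = lam),
    loglik_i = dfpf(x, p, log = TRUE),
    pdf = function(z) dfpf(z, p, strict = FALSE),
    cdf = function(z) pfpf(z, p),
    n = length(x), bounds = bounds
  )
}
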