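#' The Frechet-Power Function distribution
#'
#' Density, log-density, distribution function, survival function, hazard
#' rate, quantile function and random generation for the Frechet-Power
#' Function (FPF) distribution with shape parameters `alpha`, `theta` and
#' known support `(a, b)`.
#'
#' Writing `v = (x - a)/(b - a)` and `lambda = alpha * theta`, the density is
#' \deqn{f(x) = \frac{\lambda}{(b-a)(1 - e^{-1})}\, v^{\lambda - 1}
#'   e^{-v^\lambda}, \qquad a < x < b,}
#' and the distribution function is
#' \deqn{F(x) = \frac{e^{-v^\lambda} - 1}{e^{-1} - 1}.}
#' The family is identified only through `lambda`: any `(alpha, theta)` pair
#' with the same product gives identical values.
#'
#' Boundary conventions: the density at `x = b` is the finite limit
#' `lambda * exp(-1) / ((b - a)(1 - exp(-1)))`; at `x = a` it is 0 for
#' `lambda > 1`, the finite limit for `lambda = 1`, and an error for
#' `lambda < 1` (the density diverges there). With `strict = TRUE`
#' (the default) values outside `[a, b]` are a domain error; with
#' `strict = FALSE` the density is 0 outside. `pfpf()` always clamps to
#' `{0, 1}` outside the support, as plotting and Kolmogorov-Smirnov code
#' requires.
#'
#' @param x Vector of evaluation points.
#' @param q Vector of quantiles.
#' @param p Vector of probabilities in `[0, 1]`.
#' @param n Number of random draws.
#' @param alpha,theta Positive shape parameters. `alpha` may instead be an
#'   [fpf_params] object, in which case `theta`, `a` and `b` are ignored.
#' @param a,b Support bounds, `a < b`.
#' @param log,log.p Logical: return (or accept) log scale values.
#' @param lower.tail Logical: if `FALSE`, probabilities are `P(X > x)`.
#' @param strict Logical: error on points outside the support rather than
#'   returning 0 (density/hazard only).
#'
#' @return `dfpf`, `pfpf`, `sfpf`, `hfpf` and `qfpf` return numeric vectors;
#'   `rfpf` returns a vector of `n` draws.
#' @examples
#' dfpf(0.5, alpha = 1, theta = 1)        # 0.959517...
#' pfpf(0.5, alpha = 1, theta = 1)        # 0.622459...
#' qfpf(0.25, alpha = 0.5, theta = 1, a = 0, b = 10)  # 0.2959...
#' @name fpf-distribution
NULL

#' @rdname fpf-distribution
#' @export
dfpf <- function(x, alpha = 1, theta = 1, a = 0, b = 1, log = FALSE,
                 strict = TRUE) {
  p <- resolve_params(alpha, theta, a, b)
  lam <- p$lambda
  out <- rep(if (log) -Inf else 0, length(x))
  inside <- x > p$a & x < p$b
  at_a <- x == p$a
  at_b <- x == p$b
  outside <- !inside & !at_a & !at_b
  if (strict && any(outside, na.rm = TRUE))
    stop("dfpf: value(s) outside the support [", p$a, ", ", p$b, "].",
         call. = FALSE)
  if (any(at_a) && lam < 1)
    stop("dfpf: density diverges at x = a when lambda < 1.", call. = FALSE)

  width <- p$b - p$a
  lc <- log(lam) - log(width) - log(.fpf_c)
  if (any(inside)) {
    lv <- log_v(x[inside], p$a, p$b)
    lp <- lc + (lam - 1) * lv - exp(lam * lv)
    out[inside] <- if (log) lp else exp(lp)
  }
  if (any(at_b)) out[at_b] <- if (log) lc - 1 else exp(lc - 1)
  if (any(at_a) && lam == 1) out[at_a] <- if (log) lc else exp(lc)
  # lam > 1 at a: limit 0, already filled
  out
}

#' @rdname fpf-distribution
#' @export
pfpf <- function(q, alpha = 1, theta = 1, a = 0, b = 1,
                 lower.tail = TRUE, log.p = FALSE) {
  p <- resolve_params(alpha, theta, a, b)
  v <- pmin(pmax((q - p$a) / (p$b - p$a), 0), 1)
  # F = (1 - exp(-v^lambda)) / (1 - exp(-1)); -expm1 keeps small-v precision
  cdf <- -expm1(-v^p$lambda) / .fpf_c
  cdf <- pmin(cdf, 1)
  if (!lower.tail) cdf <- 1 - cdf
  if (log.p) log(cdf) else cdf
}

#' @rdname fpf-distribution
#' @export
sfpf <- function(q, alpha = 1, theta = 1, a = 0, b = 1) {
  pfpf(q, alpha, theta, a, b, lower.tail = FALSE)
}

#' @rdname fpf-distribution
#' @export
hfpf <- function(x, alpha = 1, theta = 1, a = 0, b = 1, strict = TRUE) {
  p <- resolve_params(alpha, theta, a, b)
  if (any(x >= p$b))
    stop("hfpf: hazard is undefined at x >= b (survival is zero).",
         call. = FALSE)
  dfpf(x, p, strict = strict) / sfpf(x, p)
}

#' @rdname fpf-distribution
#' @export
qfpf <- function(p, alpha = 1, theta = 1, a = 0, b = 1) {
  par <- resolve_params(alpha, theta, a, b)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("qfpf: probabilities must lie in [0, 1].", call. = FALSE)
  # v^lambda = -log(1 + p*(exp(-1) - 1)); log1p for small p accuracy
  vl <- -log1p(p * (exp(-1) - 1))
  q <- par$a + (par$b - par$a) * vl^(1 / par$lambda)
  q[p == 0] <- par$a
  q[p == 1] <- par$b
  q
}

# log((x-a)/(b-a)) computed stably for x near b (v near 1)
log_v <- function(x, a, b) {
  v <- (x - a) / (b - a)
  ifelse(v > 0.5, log1p((x - b) / (b - a)), log(v))
}

#' Classify the hazard-rate shape of an FPF distribution
#'
#' Evaluates the hazard `f/S` on an equispaced interior grid and classifies
#' its shape from the sign sequence of successive differences. Relative
#' changes below `rel_tolerance` count as flat. The grid spans
#' `[a + 1e-4 (b-a), b - 1e-4 (b-a)]` by default to avoid the boundary
#' singularities; a narrower window can be supplied via `interval`.
#'
#' @inheritParams fpf-distribution
#' @param grid_size Number of grid points (at least 50).
#' @param rel_tolerance Relative change below which a difference counts as
#'   flat.
#' @param interval Optional length-2 numeric sub-interval of `(a, b)` on
#'   which to classify.
#' @return An object of class `fpf_hazard_shape`: a list with `label` (one
#'   of `"increasing"`, `"decreasing"`, `"bathtub"`, `"unimodal"`,
#'   `"approximately-constant"`, `"unclassified"`), `grid_size` and
#'   `rel_tolerance`.
#' @examples
#' classify_hazard_shape(alpha = 6, theta = 2)$label     # "increasing"
#' classify_hazard_shape(alpha = 0.3, theta = 0.5)$label # "bathtub"
#' @export
classify_hazard_shape <- function(alpha = 1, theta = 1, a = 0, b = 1,
                                  grid_size = 2001, rel_tolerance = 1e-6,
                                  interval = NULL) {
  p <- resolve_params(alpha, theta, a, b)
  if (grid_size < 50) stop("`grid_size` must be at least 50.", call. = FALSE)
  eps <- 1e-4 * (p$b - p$a)
  lo <- if (is.null(interval)) p$a + eps else interval[1]
  hi <- if (is.null(interval)) p$b - eps else interval[2]
  if (lo <= p$a || hi >= p$b || lo >= hi)
    stop("`interval` must lie strictly inside (a, b).", call. = FALSE)
  grid <- seq(lo, hi, length.out = grid_size)
  h <- hfpf(grid, p)
  d <- diff(h)
  scale <- pmax(abs(h[-1]), abs(h[-length(h)]))
  s <- sign(d)
  s[abs(d) <= rel_tolerance * scale] <- 0
  runs <- rle(s)$values
  runs <- runs[runs != 0]
  label <-
    if (length(runs) == 0) "approximately-constant"
    else if (identical(runs, 1))  "increasing"
    else if (identical(runs, -1)) "decreasing"
    else if (identical(runs, c(-1, 1))) "bathtub"
    else if (identical(runs, c(1, -1))) "unimodal"
    else "unclassified"
  if (label == "unclassified")
    warning("hazard sign pattern has more than two changes; ",
            "rel_tolerance may be too tight.", call. = FALSE)
  structure(
    list(label = label, grid_size = grid_size, rel_tolerance = rel_tolerance),
    class = "fpf_hazard_shape"
  )
}

#' @export
print.fpf_hazard_shape <- function(x, ...) {
  cat("FPF hazard shape:", x$label,
      sprintf("(grid %d, tol %g)\n", x$grid_size, x$rel_tolerance))
  invisible(x)
}
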