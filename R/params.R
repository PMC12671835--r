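#' Parameter set of the Frechet-Power Function distribution
#'
#' Bundles the two shape parameters `alpha` (Frechet-generator shape) and
#' `theta` (Power Function baseline shape) together with the known support
#' bounds `a < b`. The density depends on the shapes only through their
#' product `lambda = alpha * theta`, which is stored alongside: two parameter
#' sets with equal bounds and equal `lambda` describe the same distribution.
#'
#' @param alpha Positive shape parameter of the Frechet generator.
#' @param theta Positive shape parameter of the Power Function baseline.
#' @param a,b Finite support bounds, `a < b`.
#'
#' @return An object of class `fpf_params`: a list with elements `alpha`,
#'   `theta`, `a`, `b` and the derived `lambda`.
#' @examples
#' p <- fpf_params(alpha = 2, theta = 3, a = 0, b = 10)
#' p$lambda  # 6
#' @export
fpf_params <- function(alpha = 1, theta = 1, a = 0, b = 1) {
  check_shapes(alpha, theta)
  check_bounds(a, b)
  structure(
    list(alpha = alpha, theta = theta, a = a, b = b, lambda = alpha * theta),
    class = "fpf_params"
  )
}

#' @export
print.fpf_params <- function(x, ...) {
  cat(sprintf(
    "FPF distribution: alpha = %g, theta = %g (lambda = %g) on (%g, %g)\n",
    x$alpha, x$theta, x$lambda, x$a, x$b
  ))
  invisible(x)
}

#' @export
format.fpf_params <- function(x, ...) {
  sprintf("FPF(alpha = %g, theta = %g; a = %g, b = %g)", x$alpha, x$theta, x$a, x$b)
}

check_shapes <- function(alpha, theta) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be a single finite positive number.", call. = FALSE)
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta <= 0)
    stop("`theta` must be a single finite positive number.", call. = FALSE)
  invisible(TRUE)
}

check_bounds <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L ||
      !is.finite(a) || !is.finite(b))
    stop("Support bounds `a` and `b` must be single finite numbers.", call. = FALSE)
  if (a >= b)
    stop("Support bounds must satisfy a < b (got a = ", a, ", b = ", b, ").",
         call. = FALSE)
  invisible(TRUE)
}

# Accept either an fpf_params object in `alpha` or the four numerics.
resolve_params <- function(alpha, theta, a, b) {
  if (inherits(alpha, "fpf_params")) return(alpha)
  fpf_params(alpha = alpha, theta = theta, a = a, b = b)
}
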