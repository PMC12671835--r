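# Shared test helpers: independent numerical oracles kept deliberately
# separate from the package's own code paths.

# central finite difference of a scalar function
num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# second central difference
num_deriv2 <- function(f, x, h = 1e-4) {
  (f(x + h) - 2 * f(x) + f(x - h)) / h^2
}

# the FPF CDF written directly from its closed form, independent of pfpf()
cdf_oracle <- function(x, lambda, a = 0, b = 1) {
  v <- (x - a) / (b - a)
  (exp(-v^lambda) - 1) / (exp(-1) - 1)
}

# adaptive quadrature of g(x) * pdf over the support; the substitution
# z = ((x-a)/(b-a))^lambda removes the integrable endpoint singularity at a
# for lambda < 1 (the integrand in z is smooth: g(x(z)) e^-z / (1 - e^-1))
fpf_quad <- function(g, alpha, theta = 1, a = 0, b = 1, ...) {
  if (inherits(alpha, "fpf_params")) {
    lam <- alpha$lambda
    a <- alpha$a
    b <- alpha$b
  } else {
    lam <- alpha * theta
  }
  integrate(function(z) g(a + (b - a) * z^(1 / lam)) * exp(-z) / (1 - exp(-1)),
            lower = 0, upper = 1, rel.tol = 1e-10, ...)$value
}

# brute-force grid maximiser of a log-likelihood in one parameter
grid_argmax <- function(ll, grid) grid[which.max(vapply(grid, ll, numeric(1)))]
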