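test_that("exponential fit reproduces the published benchmark estimates", {
  kid <- fit_exp_model(fpf_data("kidney-frailty"))
  expect_equal(unname(kid$estimates["lambda"]), 0.8444, tolerance = 5e-4)
  expect_equal(kid$loglik, -88.8498, tolerance = 1e-3)
  rep_fit <- fit_exp_model(fpf_data("repair-times"))
  expect_equal(unname(rep_fit$estimates["lambda"]), 0.6482, tolerance = 5e-4)
  expect_equal(rep_fit$loglik, -43.0054, tolerance = 1e-3)
  expect_error(fit_exp_model(c(-1, 2)), "positive")
})

test_that("Power Function closed form matches a likelihood grid search", {
  x <- rfpf(60, 1, 0.9, seed = 3)  # any bounded data will do
  f <- fit_pf(x, c(0, 1))
  grid <- exp(seq(log(0.05), log(20), length.out = 4000))
  ll <- function(th) sum(log(th) + (th - 1) * log(x))
  th_grid <- grid_argmax(ll, grid)
  expect_equal(unname(f$estimates["theta"]), th_grid, tolerance = 0.01)
  # uniform data limit: theta-hat near 1
  set.seed(9); u <- runif(5000)
  fu <- fit_pf(u, c(0, 1))
  expect_equal(unname(fu$estimates["theta"]), 1, tolerance = 0.05)
  # affine invariance
  f2 <- fit_pf(2 + 3 * x, c(2, 5))
  expect_equal(f2$estimates, f$estimates, tolerance = 1e-9)
})

test_that("APT-PF density integrates to one and collapses to PF at alpha = 1", {
  x <- seq(0.05, 0.95, length.out = 30)
  f_apt <- function(al, th, z) {
    C <- if (abs(al - 1) < 1e-12) 1 else log(al) / (al - 1)
    C * th * z^(th - 1) * al^(z^th)
  }
  expect_equal(integrate(function(z) f_apt(2, 1.5, z), 0, 1,
                         rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
  pf_d <- 0.76 * x^(0.76 - 1)
  expect_equal(f_apt(1 + 1e-6, 0.76, x), pf_d, tolerance = 1e-5)
  expect_equal(f_apt(1 - 1e-6, 0.76, x), pf_d, tolerance = 1e-5)
})

test_that("APT-PF maximum likelihood recovers simulated parameters", {
  # simulate from APT-PF(alpha = 2, theta = 0.9) by CDF inversion
  al <- 2; th <- 0.9
  set.seed(11)
  u <- runif(3000)
  z <- (log1p(u * (al - 1)) / log(al))^(1 / th)
  fit <- fit_aptpf(z, c(0, 1))
  expect_true(fit$converged)
  # score at the optimum is numerically flat
  ll <- function(p) sum(log(log(p[1]) / (p[1] - 1)) + log(p[2]) +
                          (p[2] - 1) * log(z) + z^p[2] * log(p[1]))
  g <- num_deriv(function(a) ll(c(a, fit$estimates[["theta"]])),
                 fit$estimates[["alpha"]])
  expect_lt(abs(g) / length(z), 1e-4)
  # recovery within a loose band (alpha is weakly identified near 1)
  expect_equal(unname(fit$estimates["theta"]), th, tolerance = 0.15)
})

test_that("Weibull-PF CDF behaves at the endpoints and fitting rejects the product form", {
  expect_equal(wpf_cdf(0, a = 1, theta = 1, alpha = 1, b = 1), 0)
  expect_equal(wpf_cdf(1 - 1e-12, a = 1, theta = 1, alpha = 1, b = 1), 1,
               tolerance = 1e-6)
  # density (odd-Weibull special case a=1, theta*alpha=1) integrates to 1
  dens <- function(z) 1 / (1 - z)^2 * exp(-z / (1 - z))
  expect_equal(integrate(dens, 0, 1)$value, 1, tolerance = 1e-6)
  # CDF from the fitted object matches numerical integration of its pdf
  x <- rfpf(200, 1, 1, seed = 14) * 0.9
  f <- fit_wpf(x, c(0, 1))
  qq <- 0.5
  cdf_num <- integrate(f$pdf, 0, qq, rel.tol = 1e-8)$value
  expect_equal(f$cdf(qq), cdf_num, tolerance = 1e-6)
  expect_error(fit_wpf(x, c(0, 1), form = "product"), "not a valid CDF")
  # the product reading is exposed for inspection and is visibly not a CDF
  expect_equal(wpf_cdf(1, a = 1, theta = 1, alpha = 1, b = 1,
                       form = "product"), 0)
})

test_that("Kumaraswamy-PF reduces to PF and uniform in its special cases", {
  # beta = 1: F = u^kappa; exponent 1 and beta 1: uniform
  x <- seq(0.1, 0.9, by = 0.1)
  kw_cdf <- function(z, ka, be, gam = 1) 1 - (1 - (z / gam)^ka)^be
  expect_equal(kw_cdf(x, 1.7, 1), x^1.7, tolerance = 1e-12)
  expect_equal(kw_cdf(x, 1, 1), x, tolerance = 1e-12)
  # median closed form checked by root-finding on the CDF
  ka <- 1.4913; be <- 2.6179
  med_cf <- (1 - 0.5^(1 / be))^(1 / ka)
  med_rf <- uniroot(function(z) kw_cdf(z, ka, be) - 0.5, c(1e-9, 1 - 1e-9),
                    tol = 1e-12)$root
  expect_equal(med_cf, med_rf, tolerance = 1e-9)
  # fit reports the ridge split theta = alpha = sqrt(kappa)
  xx <- rfpf(300, 1, 1, seed = 31) * 0.95
  f <- fit_kwpf(xx, c(0, 1))
  expect_equal(unname(f$estimates["theta"]), unname(f$estimates["alpha"]))
})

test_that("Marshall-Olkin PF reduces to PF at alpha = 1 and its density normalises", {
  mo_cdf <- function(z, al, be, gam = 1) {
    p <- (z / gam)^be
    p / (al + (1 - al) * p)
  }
  x <- seq(0.05, 0.95, by = 0.05)
  expect_equal(mo_cdf(x, 1, 2.2), x^2.2, tolerance = 1e-12)
  expect_equal(mo_cdf(0, 0.07, 2.47), 0)
  expect_equal(mo_cdf(1, 0.07, 2.47), 1)
  # density by differentiation integrates to 1 at the published test point
  dens <- function(z) {
    al <- 0.0728; be <- 2.4703
    p <- z^be
    al * be * p / (z * (al + (1 - al) * p)^2)
  }
  expect_equal(integrate(dens, 0, 1, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-7)
})

test_that("Exponentiated PF endpoints, uniform case, and quantile inversion", {
  epf_cdf <- function(z, th, al, a = 0, b = 1)
    (1 - ((b - z) / (b - a))^th)^al
  x <- seq(0.05, 0.95, by = 0.05)
  expect_equal(epf_cdf(x, 1, 1), x, tolerance = 1e-12)
  expect_equal(epf_cdf(0, 2.39, 1.44), 0)
  expect_equal(epf_cdf(1, 2.39, 1.44), 1)
  # closed-form quantile vs root-finding
  th <- 2.39; al <- 1.44; u <- 0.3
  q_cf <- 1 - (1 - u^(1 / al))^(1 / th)
  q_rf <- uniroot(function(z) epf_cdf(z, th, al) - u, c(0, 1), tol = 1e-12)$root
  expect_equal(q_cf, q_rf, tolerance = 1e-9)
})

test_that("every competitor CDF is monotone with correct limits", {
  x <- rfpf(150, 1, 1, seed = 41) * 0.98
  fits <- list(
    fit_exp_model(x), fit_pf(x, c(0, 1)), fit_aptpf(x, c(0, 1)),
    fit_wpf(x, c(0, 1)), fit_kwpf(x, c(0, 1)), fit_mopf(x, c(0, 1)),
    fit_epf(x, c(0, 1))
  )
  grid <- seq(1e-6, 1 - 1e-6, length.out = 1000)
  for (f in fits) {
    u <- f$cdf(grid)
    expect_true(all(diff(u) >= -1e-12), info = f$name)
    expect_lt(u[1], 0.05)
    expect_gt(u[length(u)], if (f$name == "ED") 0.4 else 0.95)
    # finite-difference score at the reported optimum is small
    expect_true(f$converged, info = f$name)
  }
})

test_that("fitted pdf closures are consistent with the reported log-likelihood", {
  x <- fpf_data("repair-times")
  b <- c(0, max(x) * (1 + 1e-6))
  fits <- list(fit_pf(x, b), fit_aptpf(x, b), fit_wpf(x, b),
               fit_kwpf(x, b), fit_mopf(x, b), fit_epf(x, b))
  for (fit in fits) {
    expect_equal(sum(log(fit$pdf(x))), fit$loglik, tolerance = 1e-8,
                 info = fit$name)
    expect_length(fit$loglik_i, length(x))
  }
})
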