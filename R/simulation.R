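#' Monte-Carlo study of FPF estimator performance
#'
#' `fpf_sim_cell()` runs one design cell: `reps` datasets of size `n` are
#' drawn from `FPF(alpha, theta)` on `(a, b)` by the inverse transform; per
#' replicate the identifying product `lambda = alpha * theta` is estimated
#' by the one-dimensional score equation and split into the per-parameter
#' estimates `alpha-hat = lambda-hat / theta` (partner fixed at truth) and
#' `theta-hat = lambda-hat / alpha`. Bias, mean squared error and the
#' coverage of the 95% Wald interval (built from the observed information
#' in `lambda` and transported linearly) are summarised per parameter.
#' `fpf_sim_grid()` maps `fpf_sim_cell` over a full design, with one
#' reproducible sub-seed per cell spawned from the master `seed`.
#'
#' Fixing the partner parameter at its true value is the identifiable
#' version of a per-parameter performance study for this family: the
#' likelihood carries information about `lambda` only, so a joint
#' `(alpha, theta)` fit sits on an exact ridge.
#'
#' @inheritParams fpf-distribution
#' @param n Sample size per replicate.
#' @param reps Number of Monte-Carlo replicates (`>= 2`).
#' @param seed Optional integer master seed.
#' @param level Confidence level of the coverage intervals.
#' @param sample_sizes,alphas,thetas Vectors defining the grid.
#' @return A tibble with one row per cell: `n`, `alpha`, `theta`,
#'   `mean_alpha_hat`, `mean_theta_hat`, `bias_alpha`, `bias_theta`,
#'   `mse_alpha`, `mse_theta`, `cp_alpha`, `cp_theta`, `fit_failures`.
#' @examples
#' fpf_sim_cell(n = 50, alpha = 1, theta = 1, reps = 20, seed = 1)
#' @export
fpf_sim_cell <- function(n, alpha, theta, reps = 1000, seed = NULL,
                         a = 0, b = 1, level = 0.95) {
  if (reps < 2) stop("`reps` must be at least 2.", call. = FALSE)
  if (n < 2) stop("`n` must be at least 2.", call. = FALSE)
  check_shapes(alpha, theta)
  lam_true <- alpha * theta
  z <- qnorm(1 - (1 - level) / 2)
  p <- fpf_params(alpha, theta, a, b)

  run <- function() {
    lam_hat <- se <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      u <- pmin(pmax(runif(n), .Machine$double.xmin), 1 - .Machine$double.eps)
      lv <- log_v(qfpf(u, p), a, b)
      res <- tryCatch({
        lam <- solve_lambda(lv)
        c(lam, 1 / sqrt(info_lambda(lam, lv)))
      }, error = function(e) c(NA_real_, NA_real_))
      lam_hat[r] <- res[1]; se[r] <- res[2]
    }
    list(lam_hat = lam_hat, se = se)
  }
  sim <- with_local_seed(seed, run())

  ok <- !is.na(sim$lam_hat)
  failures <- sum(!ok)
  if (failures > 0.01 * reps)
    warning(sprintf("fpf_sim_cell: %d of %d replicate fits failed.",
                    failures, reps), call. = FALSE)
  lam_hat <- sim$lam_hat[ok]
  se <- sim$se[ok]
  cover <- (lam_hat - z * se <= lam_true) & (lam_true <= lam_hat + z * se)

  a_hat <- lam_hat / theta   # alpha estimated, theta fixed at truth
  t_hat <- lam_hat / alpha   # theta estimated, alpha fixed at truth
  tibble::tibble(
    n = n, alpha = alpha, theta = theta,
    mean_alpha_hat = mean(a_hat), mean_theta_hat = mean(t_hat),
    bias_alpha = mean(a_hat) - alpha, bias_theta = mean(t_hat) - theta,
    mse_alpha = mean((a_hat - alpha)^2), mse_theta = mean((t_hat - theta)^2),
    cp_alpha = mean(cover), cp_theta = mean(cover),
    fit_failures = failures
  )
}

#' @rdname fpf_sim_cell
#' @export
fpf_sim_grid <- function(sample_sizes = c(10, 50, 100, 500, 1000),
                         alphas = c(0.5, 1, 2, 3, 5),
                         thetas = c(0.5, 1, 2, 3, 5),
                         reps = 1000, seed = NULL, a = 0, b = 1,
                         level = 0.95) {
  cells <- expand.grid(n = sample_sizes, alpha = alphas, theta = thetas,
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[order(cells$alpha, cells$theta, cells$n), , drop = FALSE]
  sub_seeds <- with_local_seed(
    seed,
    sample.int(.Machine$integer.max - 1L, nrow(cells))
  )
  purrr::pmap(
    list(cells$n, cells$alpha, cells$theta, sub_seeds),
    function(n, al, th, s)
      fpf_sim_cell(n, al, th, reps = reps, seed = s, a = a, b = b,
                   level = level)
  ) |>
    dplyr::bind_rows()
}

#' Quantile table of the FPF distribution
#'
#' Evaluates the closed-form quantile function on a grid of shape-parameter
#' pairs and probabilities.
#'
#' @inheritParams fpf-distribution
#' @param alphas,thetas Equal-length vectors of shape-parameter pairs (one
#'   table row per pair).
#' @param probs Probabilities in `(0, 1)`.
#' @return A tibble with columns `alpha`, `theta` and one `q<prob>` column
#'   per probability (full precision; round for display).
#' @examples
#' fpf_quantile_table(c(0.5, 1), c(1, 1), b = 10)
#' @export
fpf_quantile_table <- function(alphas, thetas,
                               probs = c(0.1, 0.25, 0.5, 0.75, 0.9),
                               a = 0, b = 10) {
  if (length(alphas) != length(thetas))
    stop("`alphas` and `thetas` must have equal length.", call. = FALSE)
  if (any(probs <= 0 | probs >= 1))
    stop("`probs` must lie in (0, 1).", call. = FALSE)
  rows <- purrr::map2(alphas, thetas, function(al, th) {
    q <- qfpf(probs, al, th, a, b)
    out <- tibble::tibble(alpha = al, theta = th)
    out[paste0("q", probs)] <- as.list(q)
    out
  })
  dplyr::bind_rows(rows)
}
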