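#' Benchmark datasets
#'
#' Three published benchmark datasets used throughout the package, embedded
#' in source:
#'
#' * `"kidney-frailty"` — 76 frailty values estimated from recurrence times
#'   of infections in 38 kidney-dialysis patients (McGilchrist & Aisbett).
#' * `"repair-times"` — 30 times between failures of repairable units
#'   (Murthy et al.).
#' * `"ftcanmax"` — 100 annual maximum precipitation values recorded at
#'   Fort Collins, Colorado.
#'
#' Basic checksums (length, sum, range) are asserted on every access.
#'
#' @param name Dataset name.
#' @return `fpf_data()`: a numeric vector. `fpf_datasets()`: a tibble
#'   listing the available datasets.
#' @examples
#' sum(fpf_data("kidney-frailty"))  # 90
#' fpf_datasets()
#' @export
fpf_data <- function(name = c("kidney-frailty", "repair-times", "ftcanmax")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("kidney-frailty", "repair-times", "ftcanmax"))
    stop("unknown dataset; available: kidney-frailty, repair-times, ",
         "ftcanmax.", call. = FALSE)
  x <- .fpf_datasets[[name]]
  chk <- .fpf_checksums[[name]]
  stopifnot(length(x) == chk$n, isTRUE(all.equal(sum(x), chk$sum)),
            min(x) == chk$min, max(x) == chk$max)
  x
}

#' @rdname fpf_data
#' @export
fpf_datasets <- function() {
  tibble::tibble(
    name = c("kidney-frailty", "repair-times", "ftcanmax"),
    n = c(76L, 30L, 100L),
    description = c(
      "Kidney-infection frailty values (McGilchrist & Aisbett)",
      "Times between failures of repairable units (Murthy et al.)",
      "Fort Collins annual maximum precipitation"
    )
  )
}

.fpf_datasets <- list(
  "kidney-frailty" = c(
    0.2, 0.2, 0.4, 0.4, 0.4, 0.4, 0.4, 0.4, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5,
    0.5, 0.5, 0.6, 0.6, 0.6, 0.6, 0.7, 0.7, 0.7, 0.7, 0.7, 0.7, 0.7, 0.7,
    0.8, 0.8, 0.8, 0.8, 1.0, 1.0, 1.1, 1.1, 1.1, 1.1, 1.1, 1.1, 1.2, 1.2,
    1.2, 1.2, 1.2, 1.2, 1.3, 1.3, 1.3, 1.3, 1.4, 1.4, 1.5, 1.5, 1.5, 1.5,
    1.5, 1.5, 1.7, 1.7, 1.7, 1.7, 1.8, 1.8, 1.9, 1.9, 2.1, 2.1, 2.2, 2.2,
    2.3, 2.3, 2.9, 2.9, 3.0, 3.0
  ),
  "repair-times" = c(
    1.43, 0.11, 0.71, 0.77, 2.63, 1.49, 3.46, 2.46, 0.59, 0.74, 1.23, 0.94,
    4.36, 0.40, 1.74, 4.73, 2.23, 0.45, 0.70, 1.06, 1.46, 0.30, 1.82, 2.37,
    0.63, 1.23, 1.24, 1.97, 1.86, 1.17
  ),
  "ftcanmax" = c(
    1.04, 1.15, 1.23, 1.25, 1.28, 1.30, 1.35, 1.36, 1.37, 1.39, 1.41, 1.42,
    1.43, 1.44, 1.45, 1.47, 1.48, 1.49, 1.51, 1.53, 1.54, 1.55, 1.57, 1.58,
    1.59, 1.60, 1.61, 1.63, 1.64, 1.65, 1.67, 1.68, 1.70, 1.71, 1.72, 1.73,
    1.75, 1.76, 1.78, 1.80, 1.82, 1.83, 1.84, 1.85, 1.87, 1.88, 1.90, 1.91,
    1.92, 1.93, 1.95, 1.97, 1.99, 2.01, 2.03, 2.05, 2.07, 2.10, 2.12, 2.14,
    2.16, 2.18, 2.20, 2.22, 2.24, 2.26, 2.28, 2.30, 2.32, 2.34, 2.37, 2.40,
    2.43, 2.46, 2.49, 2.53, 2.57, 2.60, 2.63, 2.67, 2.70, 2.73, 2.77, 2.80,
    2.84, 2.87, 2.91, 2.95, 2.99, 3.03, 3.07, 3.12, 3.16, 3.21, 3.26, 3.31,
    3.36, 3.42, 3.48, 3.54
  )
)

.fpf_checksums <- list(
  "kidney-frailty" = list(n = 76L, sum = 90.0, min = 0.2, max = 3.0),
  "repair-times" = list(n = 30L, sum = 46.28, min = 0.11, max = 4.73),
  "ftcanmax" = list(n = 100L, sum = sum(.fpf_datasets[["ftcanmax"]]),
                    min = 1.04, max = 3.54)
)
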