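#' Intraclass correlation for repeated measurements
#'
#' Two-way (subjects x sessions) ANOVA decomposition of an `n x k` matrix of
#' one scalar measure, returning the single-measure intraclass correlation in
#' two forms:
#'
#' * absolute agreement (two-way, single rater):
#'   `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`
#' * consistency, ICC(3,1): `(MSR - MSE) / (MSR + (k-1) MSE)`
#'
#' The absolute-agreement form additionally penalises systematic session
#' offsets; the consistency form does not. Both are reported because the two
#' labels are often conflated in applied work; agreement is the headline
#' value here.
#'
#' @param data numeric matrix, subjects in rows, sessions in columns
#'   (`n >= 2`, `k >= 2`, no missing cells), or a data frame coercible to one.
#' @param measure label carried into reports.
#' @return an object of class `icc_fit`: list with `icc` (absolute
#'   agreement), `icc_consistency`, mean squares `msr`/`msc`/`mse`, `n`, `k`,
#'   `measure` and `degenerate` (all cells equal, ICC defined as 1).
#' @examples
#' m <- cbind(c(9, 8, 7, 6), c(9.1, 8.1, 6.9, 6.2))
#' icc_single_absolute(m)$icc
#' @export
icc_single_absolute <- function(data, measure = "measure") {
  m <- as.matrix(data)
  storage.mode(m) <- "double"
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) abort("need at least 2 subjects and 2 sessions")
  if (anyNA(m) || !all(is.finite(m))) abort("missing or non-finite cells")

  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  # guard against cancellation: sse is a difference of near-equal sums and a
  # true zero (identical sessions) must give ICC exactly 1
  if (sse < 1e-12 * max(sst, .Machine$double.xmin)) sse <- 0
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  degenerate <- sst < .Machine$double.eps * max(1, grand^2) * n * k
  if (degenerate) {
    icc_a <- icc_c <- 1
  } else {
    icc_a <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    icc_c <- (msr - mse) / (msr + (k - 1) * mse)
  }
  structure(list(icc = icc_a, icc_consistency = icc_c,
                 msr = msr, msc = msc, mse = max(mse, 0),
                 n = n, k = k, measure = measure, degenerate = degenerate),
            class = "icc_fit")
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf("<icc_fit '%s'> n = %d subjects, k = %d sessions\n",
              x$measure, x$n, x$k))
  cat(sprintf("  ICC (absolute agreement, single) = %.6f\n", x$icc))
  cat(sprintf("  ICC (consistency, 3,1)           = %.6f\n", x$icc_consistency))
  if (x$degenerate) cat("  note: all cells equal; ICC defined as 1\n")
  invisible(x)
}

#' @method tidy icc_fit
#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(
    measure = x$measure,
    form = c("absolute_agreement", "consistency"),
    icc = c(x$icc, x$icc_consistency),
    msr = x$msr, msc = x$msc, mse = x$mse, n = x$n, k = x$k
  )
}

#' @method glance icc_fit
#' @export
glance.icc_fit <- function(x, ...) {
  tibble::tibble(measure = x$measure, icc = x$icc,
                 icc_consistency = x$icc_consistency,
                 n = x$n, k = x$k, degenerate = x$degenerate)
}

#' Symmetric percentage error between two replicates
#'
#' `100 |a - b| / ((a + b) / 2)`. The denominator is the replicate mean, so
#' neither measurement is privileged and the result is order-invariant. Both
#' inputs must be positive magnitudes (volumes, areas, distances).
#'
#' @param a,b positive numeric vectors (recycled pairwise).
#' @return percentage error(s).
#' @examples
#' percentage_error(100, 101) # ~0.995
#' @export
percentage_error <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) {
    abort("percentage_error is defined for positive magnitudes only")
  }
  100 * abs(a - b) / ((a + b) / 2)
}

#' Intra-rater reliability report
#'
#' For each measure: both ICC forms plus the mean and SD of the pairwise
#' symmetric percentage error across subjects, as used to assess scan-rescan
#' and registration-reregistration reproducibility.
#'
#' @param data long tibble/data frame with columns `subject`, `session`,
#'   `measure`, `value` — one row per subject x session x measure, exactly
#'   two-plus sessions per subject, no missing cells.
#' @return a tibble, one row per measure: `measure`, `icc`,
#'   `icc_consistency`, `pct_error_mean`, `pct_error_sd`, `n`, `k`.
#' @export
reliability_report <- function(data) {
  data <- as.data.frame(data)
  need <- c("subject", "session", "measure", "value")
  if (!all(need %in% names(data))) {
    abort("need columns subject, session, measure, value")
  }
  out <- lapply(split(data, data$measure), function(d) {
    wide <- tidyr::pivot_wider(tibble::as_tibble(d[, c("subject", "session", "value")]),
                               names_from = "session", values_from = "value")
    m <- as.matrix(wide[, -1, drop = FALSE])
    if (nrow(m) < 2) abort(sprintf("measure '%s': fewer than 2 subjects", d$measure[1]))
    if (anyNA(m)) abort(sprintf("measure '%s': missing session values", d$measure[1]))
    fit <- icc_single_absolute(m, measure = d$measure[1])
    # percentage error over all session pairs within subject
    pe <- apply(m, 1, function(r) {
      pr <- utils::combn(r, 2)
      mean(percentage_error(pr[1, ], pr[2, ]))
    })
    tibble::tibble(measure = d$measure[1], icc = fit$icc,
                   icc_consistency = fit$icc_consistency,
                   pct_error_mean = mean(pe), pct_error_sd = sd(pe),
                   n = fit$n, k = fit$k)
  })
  dplyr::bind_rows(out)
}
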