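#' Poisson log-likelihood kernel of a count vector
#'
#' For a count vector `y`, returns
#' `sum_i y(i) log y(i) - (sum_i y(i)) log(sum_i y(i))`, with the continuity
#' convention `0 * log 0 = 0`. Up to terms that cancel between the null and
#' alternative Poisson models, this is the maximised log-likelihood of a
#' vector of independent Poisson counts, which is why the likelihood-ratio
#' statistic can be written purely in terms of this kernel.
#'
#' @param y Non-negative numeric vector with at least one positive entry.
#' @return A single numeric value (always <= 0).
#' @export
f_stat <- function(y) {
  if (any(y < 0)) stop("counts must be non-negative")
  s <- sum(y)
  if (s == 0) stop("all-zero count vector")
  pos <- y > 0
  sum(y[pos] * log(y[pos])) - s * log(s)
}

#' Maximum-likelihood estimates under the proportional-counts null
#'
#' Under the null model the OTU's counts in sample i are Poisson(lambda(i))
#' and the candidate's are Poisson(rho * lambda(i)) with a single
#' proportionality constant rho across samples. The MLEs are
#' `rho = X2 / X1` and `lambda(i) = X1 * (x1(i) + x2(i)) / (X1 + X2)`,
#' where `X1`, `X2` are the two vectors' totals.
#'
#' @param x1 OTU count vector.
#' @param x2 Candidate count vector (same length).
#' @return A list with elements `rho_hat` and `lambda_hat`.
#' @export
null_mle <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("count vectors must have equal length")
  if (any(x1 < 0) || any(x2 < 0)) stop("counts must be non-negative")
  X1 <- sum(x1)
  X2 <- sum(x2)
  if (X1 == 0) stop("OTU count vector has zero total")
  list(rho_hat = X2 / X1, lambda_hat = X1 * (x1 + x2) / (X1 + X2))
}

#' Likelihood-ratio statistic for the distribution criterion
#'
#' Compares the alternative model (each count has its own Poisson rate) to
#' the null model (candidate rates proportional to OTU rates across samples):
#' `Lambda = -2 * (f(x1 + x2) - f(x1) - f(x2))` with [f_stat()] as `f`.
#' `Lambda` is zero exactly when the two vectors are proportional and
#' non-negative otherwise (the models are nested); tiny negative values from
#' floating-point cancellation are clamped to zero.
#'
#' @inheritParams null_mle
#' @return A single non-negative numeric value.
#' @export
lrt_statistic <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("count vectors must have equal length")
  if (any(x1 < 0) || any(x2 < 0)) stop("counts must be non-negative")
  if (sum(x1) == 0 || sum(x2) == 0) stop("count vector with zero total")
  max(0, -2 * (f_stat(x1 + x2) - f_stat(x1) - f_stat(x2)))
}

#' Likelihood-ratio test of proportional counts across samples
#'
#' The distribution criterion: the statistic from [lrt_statistic()] is
#' referred to the upper tail of a chi-squared distribution with
#' `n_samples - 1` degrees of freedom (the alternative has 2n free Poisson
#' rates, the null n rates plus one proportionality constant). With a single
#' sample there are zero degrees of freedom, the models coincide, and the
#' p-value is 1.
#'
#' In the OTU caller a p-value below the threshold means the candidate and
#' OTU are distributed too differently to merge; these p-values are merge
#' decisions, not significance statements, and are never corrected for
#' multiple testing.
#'
#' @inheritParams null_mle
#' @return A `distotu_lrt` object: list with `statistic`, `df`, `p_value`,
#'   `rho_hat`, `lambda_hat` and `single_sample` (logical flag).
#' @export
lrt_pvalue <- function(x1, x2) {
  stat <- lrt_statistic(x1, x2)
  mle <- null_mle(x1, x2)
  df <- length(x1) - 1L
  single <- df == 0L
  if (single) {
    warning("single-sample comparison has 0 degrees of freedom; p = 1")
  }
  p <- if (single) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(
    list(statistic = stat, df = df, p_value = p,
         rho_hat = mle$rho_hat, lambda_hat = mle$lambda_hat,
         single_sample = single),
    class = "distotu_lrt"
  )
}

#' @export
print.distotu_lrt <- function(x, ...) {
  cat(sprintf(
    "Poisson likelihood-ratio test: Lambda = %.4g, df = %d, p = %.4g\n",
    x$statistic, x$df, x$p_value))
  cat(sprintf("rho_hat = %.4g\n", x$rho_hat))
  invisible(x)
}
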