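#' Pearson chi-squared statistic of a 2-by-n count table
#'
#' The test-of-independence statistic `sum (obs - exp)^2 / exp` over the
#' 2-by-n table whose rows are the two count vectors, with expected counts
#' from the row and column margins. Samples (columns) in which both vectors
#' are zero contribute nothing to the margins and are dropped.
#'
#' @param x1,x2 Non-negative count vectors of equal length.
#' @return A single non-negative numeric value.
#' @export
chi2_statistic <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("count vectors must have equal length")
  if (any(x1 < 0) || any(x2 < 0)) stop("counts must be non-negative")
  keep <- (x1 + x2) > 0
  if (!any(keep)) stop("all-zero table")
  obs <- rbind(x1[keep], x2[keep])
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  pos <- expd > 0
  sum((obs[pos] - expd[pos])^2 / expd[pos])
}

# Draw B top rows of 2-by-n tables with the given margins, uniformly over
# the fixed-margin (multivariate hypergeometric) null, by sequential
# conditional hypergeometric sampling vectorised over simulations.
sample_top_rows <- function(B, r1, col_totals) {
  n <- length(col_totals)
  tops <- matrix(0L, nrow = B, ncol = n)
  rem1 <- rep.int(r1, B)
  rem_total <- sum(col_totals)
  for (j in seq_len(n - 1L)) {
    tops[, j] <- stats::rhyper(B, m = rem1, n = rem_total - rem1,
                               k = col_totals[j])
    rem1 <- rem1 - tops[, j]
    rem_total <- rem_total - col_totals[j]
  }
  tops[, n] <- rem1
  tops
}

#' Monte-Carlo simulated chi-squared test of independence
#'
#' The legacy distribution criterion and the package's gold standard for
#' evaluating the likelihood-ratio test: the null distribution of the
#' Pearson statistic is estimated by sampling `B` random 2-by-n tables with
#' the observed row and column margins (uniform over the fixed-margin null,
#' drawn by sequential conditional hypergeometric sampling). The p-value
#' uses the add-one estimator `(1 + #\{sim >= obs\}) / (B + 1)`, so it is
#' never exactly zero.
#'
#' @inheritParams chi2_statistic
#' @param B Number of simulated tables (default 1e4; use 1e6-1e7 for
#'   gold-standard evaluation runs).
#' @param seed Optional integer seed; when given, the global RNG state is
#'   saved and restored so the call is reproducible without side effects.
#' @param chunk Number of simulations drawn per block (memory control).
#' @return A `distotu_simtest` object: list with `statistic`, `n_sims`,
#'   `p_value` and `seed`.
#' @export
simulate_pvalue <- function(x1, x2, B = 1e4, seed = NULL, chunk = 1e6) {
  if (B < 1) stop("B must be at least 1")
  keep <- (x1 + x2) > 0
  if (sum(x1) == 0 || sum(x2) == 0) {
    stop("degenerate margins: a row of the table is all zero")
  }
  obs <- chi2_statistic(x1, x2)
  x1 <- x1[keep]
  x2 <- x2[keep]
  col_totals <- x1 + x2
  r1 <- sum(x1)
  grand <- sum(col_totals)
  e1 <- r1 * col_totals / grand
  e2 <- (grand - r1) * col_totals / grand

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    })
    set.seed(seed)
  }

  # count sims with statistic >= observed, tolerating floating-point ties
  tol <- 64 * .Machine$double.eps * max(1, obs)
  n_ge <- 0
  left <- B
  while (left > 0) {
    b <- min(left, chunk)
    tops <- sample_top_rows(b, r1, col_totals)
    stat <- as.vector(
      (tops - rep(e1, each = b))^2 %*% (1 / e1) +
      (rep(col_totals, each = b) - tops - rep(e2, each = b))^2 %*% (1 / e2))
    n_ge <- n_ge + sum(stat >= obs - tol)
    left <- left - b
  }
  structure(
    list(statistic = obs, n_sims = as.integer(B),
         p_value = (1 + n_ge) / (B + 1), seed = seed),
    class = "distotu_simtest"
  )
}

#' @export
print.distotu_simtest <- function(x, ...) {
  cat(sprintf(
    "simulated chi-squared test: X2 = %.4g, B = %d, p = %.4g\n",
    x$statistic, x$n_sims, x$p_value))
  invisible(x)
}

# enumerate all top rows t with 0 <= t_j <= col_totals[j], sum t = r1;
# calls fun(t, log_weight) for each, where log_weight = sum lchoose(c_j, t_j)
enumerate_top_rows <- function(col_totals, r1, fun) {
  n <- length(col_totals)
  suffix <- rev(cumsum(rev(col_totals)))
  t <- integer(n)
  recurse <- function(j, remaining, logw) {
    if (j == n) {
      if (remaining <= col_totals[n]) {
        t[n] <<- remaining
        fun(t, logw + lchoose(col_totals[n], remaining))
      }
      return(invisible(NULL))
    }
    lo <- max(0L, remaining - suffix[j + 1L])
    hi <- min(col_totals[j], remaining)
    if (lo > hi) return(invisible(NULL))
    for (v in lo:hi) {
      t[j] <<- v
      recurse(j + 1L, remaining - v, logw + lchoose(col_totals[j], v))
    }
  }
  recurse(1L, r1, 0)
  invisible(NULL)
}

count_top_rows <- function(col_totals, r1) {
  # dynamic-programming count of bounded compositions
  reach <- c(1, rep(0, sum(col_totals)))
  total <- 0L
  for (cj in col_totals) {
    new <- rep(0, length(reach))
    for (v in 0:cj) {
      idx <- seq_len(length(reach) - v)
      new[idx + v] <- new[idx + v] + reach[idx]
    }
    reach <- new
  }
  reach[r1 + 1]
}

#' Exact fixed-margin tail probability (verification oracle)
#'
#' Enumerates every 2-by-n table with the observed margins and sums the
#' multivariate hypergeometric probabilities of tables whose Pearson
#' statistic is at least the observed one. Feasible only for small tables;
#' used to verify [simulate_pvalue()].
#'
#' @inheritParams chi2_statistic
#' @param max_tables Refuse to enumerate more than this many tables.
#' @return Exact p-value in (0, 1].
#' @export
exact_pvalue <- function(x1, x2, max_tables = 1e5) {
  keep <- (x1 + x2) > 0
  if (sum(x1) == 0 || sum(x2) == 0) {
    stop("degenerate margins: a row of the table is all zero")
  }
  obs <- chi2_statistic(x1, x2)
  x1 <- x1[keep]
  x2 <- x2[keep]
  col_totals <- x1 + x2
  r1 <- sum(x1)
  grand <- sum(col_totals)
  n_tables <- count_top_rows(col_totals, r1)
  if (n_tables > max_tables) {
    stop("table too large to enumerate: ", format(n_tables), " tables")
  }
  e1 <- r1 * col_totals / grand
  e2 <- (grand - r1) * col_totals / grand
  log_denom <- lchoose(grand, r1)
  tol <- 64 * .Machine$double.eps * max(1, obs)
  p <- 0
  enumerate_top_rows(col_totals, r1, function(t, logw) {
    stat <- sum((t - e1)^2 / e1) + sum((col_totals - t - e2)^2 / e2)
    if (stat >= obs - tol) p <<- p + exp(logw - log_denom)
  })
  min(p, 1)
}
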