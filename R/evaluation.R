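#' Confusion counts for similar/dissimilar classifications
#'
#' Tallies a predicted classification against a gold-standard one, where
#' each label is `"similar"` (the pair may be merged) or `"dissimilar"`.
#'
#' @param predicted,gold Character vectors of equal length with values
#'   `"similar"` or `"dissimilar"`.
#' @return A `distotu_confusion` list with `true_similars`,
#'   `false_similars`, `false_dissimilars`, `true_dissimilars`.
#' @export
confusion <- function(predicted, gold) {
  if (length(predicted) != length(gold)) {
    stop("predicted and gold label vectors must have equal length")
  }
  lab <- c("similar", "dissimilar")
  if (!all(predicted %in% lab) || !all(gold %in% lab)) {
    stop("labels must be 'similar' or 'dissimilar'")
  }
  structure(
    list(true_similars = sum(predicted == "similar" & gold == "similar"),
         false_similars = sum(predicted == "similar" & gold == "dissimilar"),
         false_dissimilars = sum(predicted == "dissimilar" & gold == "similar"),
         true_dissimilars = sum(predicted == "dissimilar" & gold == "dissimilar")),
    class = "distotu_confusion"
  )
}

#' Sensitivity and specificity of a similar/dissimilar classification
#'
#' With "similar" as the positive class: sensitivity is the percentage of
#' truly similar pairs called similar, specificity the percentage of truly
#' dissimilar pairs called dissimilar.
#'
#' @param cc A `distotu_confusion` from [confusion()].
#' @return Named numeric vector `c(sensitivity, specificity)` in percent;
#'   `NaN` with a warning when a denominator is zero.
#' @export
sensitivity_specificity <- function(cc) {
  pos <- cc$true_similars + cc$false_dissimilars
  neg <- cc$true_dissimilars + cc$false_similars
  if (pos == 0 || neg == 0) {
    warning("a class has no gold-standard members; returning NaN")
  }
  c(sensitivity = 100 * cc$true_similars / pos,
    specificity = 100 * cc$true_dissimilars / neg)
}

#' F1 accuracy with "dissimilar" as the positive class
#'
#' `F1 = 2 TD / (2 TD + FD + FS) * 100`, the harmonic mean of precision and
#' recall for detecting differently-distributed pairs.
#'
#' @param true_dissimilars,false_dissimilars,false_similars Non-negative
#'   counts.
#' @return F1 in percent.
#' @export
f1_score <- function(true_dissimilars, false_dissimilars, false_similars) {
  denom <- 2 * true_dissimilars + false_dissimilars + false_similars
  if (denom == 0) stop("F1 undefined: no positives predicted or present")
  100 * 2 * true_dissimilars / denom
}

#' Pearson correlation with a Fisher-z 95% confidence interval
#'
#' @param xs,ys Paired numeric vectors (at least 4 pairs).
#' @return Named numeric vector `c(r, low, high)` in percent.
#' @export
pearson_ci <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("paired vectors must have equal length")
  if (length(xs) < 4) stop("need at least 4 pairs")
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    stop("correlation undefined for a constant vector")
  }
  ct <- stats::cor.test(xs, ys, method = "pearson", conf.level = 0.95)
  c(r = 100 * unname(ct$estimate),
    low = 100 * ct$conf.int[1], high = 100 * ct$conf.int[2])
}

#' Sweep the likelihood-ratio test threshold against fixed gold labels
#'
#' For each threshold, pairs with `p < threshold` are classified
#' "dissimilar" and tallied against the gold labels. By default the
#' thresholds are geometric midpoints between consecutive observed p-values
#' (plus one below the minimum and one above the maximum), which realises
#' every achievable confusion table unambiguously.
#'
#' @param p_values Numeric vector of likelihood-ratio test p-values.
#' @param gold_labels Character vector (`"similar"`/`"dissimilar"`) from the
#'   gold-standard test, same length.
#' @param thresholds Optional numeric vector of thresholds.
#' @return data.frame with columns `threshold`, `true_dissimilars`,
#'   `false_dissimilars`, `false_similars`, `f1`.
#' @export
threshold_sweep <- function(p_values, gold_labels, thresholds = NULL) {
  if (length(p_values) != length(gold_labels)) {
    stop("p-values and gold labels must have equal length")
  }
  if (is.null(thresholds)) {
    p <- sort(unique(p_values))
    thresholds <- c(p[1] / 2, if (length(p) > 1)
      sqrt(p[-length(p)] * p[-1]), 2 * p[length(p)])
  }
  rows <- lapply(thresholds, function(thr) {
    predicted <- ifelse(p_values < thr, "dissimilar", "similar")
    cc <- confusion(predicted, gold_labels)
    f1 <- if (2 * cc$true_dissimilars + cc$false_dissimilars +
              cc$false_similars == 0) NA_real_ else
      f1_score(cc$true_dissimilars, cc$false_dissimilars, cc$false_similars)
    data.frame(threshold = thr,
               true_dissimilars = cc$true_dissimilars,
               false_dissimilars = cc$false_dissimilars,
               false_similars = cc$false_similars,
               f1 = f1)
  })
  do.call(rbind, rows)
}

#' Genetic-criterion accuracy report
#'
#' Classifies sequence pairs as similar/dissimilar at one or more
#' dissimilarity levels with both the fast Levenshtein metric and the
#' alignment gold standard, and tallies the confusion at each level; also
#' reports the Pearson correlation between the two metrics for pairs whose
#' gold-standard dissimilarity is at most `cor_max_dissim`.
#'
#' @param seq_a,seq_b Character vectors: the two sequences of each pair.
#' @param levels Numeric vector of dissimilarity thresholds (default
#'   `c(0.05, 0.1, 0.2, 0.3)`).
#' @param cor_max_dissim Gold-standard dissimilarity cutoff for the
#'   correlation subset (default 0.1).
#' @return A list with `table` (data.frame: level, confusion counts,
#'   sensitivity, specificity) and `correlation` (from [pearson_ci()], or
#'   NULL if fewer than 4 pairs qualify).
#' @export
evaluate_genetic <- function(seq_a, seq_b,
                             levels = c(0.05, 0.1, 0.2, 0.3),
                             cor_max_dissim = 0.1) {
  fast <- genetic_dissimilarity(seq_a, seq_b)
  gold <- alignment_dissimilarity(seq_a, seq_b)
  rows <- lapply(levels, function(lv) {
    cc <- confusion(ifelse(fast <= lv, "similar", "dissimilar"),
                    ifelse(gold <= lv, "similar", "dissimilar"))
    ss <- suppressWarnings(sensitivity_specificity(cc))
    data.frame(level = lv,
               true_similars = cc$true_similars,
               false_similars = cc$false_similars,
               false_dissimilars = cc$false_dissimilars,
               true_dissimilars = cc$true_dissimilars,
               sensitivity = ss[["sensitivity"]],
               specificity = ss[["specificity"]])
  })
  sel <- gold <= cor_max_dissim
  correlation <- if (sum(sel) >= 4 && stats::sd(fast[sel]) > 0 &&
                     stats::sd(gold[sel]) > 0)
    pearson_ci(fast[sel], gold[sel]) else NULL
  list(table = do.call(rbind, rows), correlation = correlation)
}

#' Distribution-criterion accuracy report
#'
#' Replays the distribution tests recorded in a merge log (or supplied as
#' count-vector pairs): computes the likelihood-ratio p-value and the
#' simulated chi-squared gold-standard p-value for every pair, tallies the
#' confusion at the given thresholds, and sweeps the likelihood-ratio
#' threshold against the fixed gold labels.
#'
#' @param pairs A list of two-element lists `list(x1, x2)` of count vectors,
#'   or a merge-log data.frame from [call_otus()] (its `"distribution"` rows
#'   carry the count vectors).
#' @param lrt_threshold Likelihood-ratio threshold (default 0.001).
#' @param gold_threshold Gold-standard threshold (default 0.001).
#' @param B Simulations for the gold standard (default 1e4).
#' @param seed Optional seed for the simulated test.
#' @return A list with `per_pair` (data.frame of both p-values and labels),
#'   `confusion` (a `distotu_confusion`), `f1`, and `sweep` (from
#'   [threshold_sweep()]).
#' @export
evaluate_distribution <- function(pairs, lrt_threshold = 0.001,
                                  gold_threshold = 0.001, B = 1e4,
                                  seed = NULL) {
  if (is.data.frame(pairs)) {
    pairs <- merge_log_pairs(pairs)
  }
  if (length(pairs) == 0L) {
    return(list(per_pair = data.frame(), confusion = NULL, f1 = NA_real_,
                sweep = data.frame()))
  }
  per <- lapply(seq_along(pairs), function(i) {
    x1 <- pairs[[i]]$x1
    x2 <- pairs[[i]]$x2
    lrt <- lrt_pvalue(x1, x2)
    sim <- simulate_pvalue(x1, x2, B = B,
                           seed = if (is.null(seed)) NULL else seed + i)
    data.frame(pair = i, lrt_p = lrt$p_value, sim_p = sim$p_value)
  })
  per <- do.call(rbind, per)
  per$lrt_label <- ifelse(per$lrt_p < lrt_threshold, "dissimilar", "similar")
  per$gold_label <- ifelse(per$sim_p < gold_threshold, "dissimilar", "similar")
  cc <- confusion(per$lrt_label, per$gold_label)
  f1 <- if (2 * cc$true_dissimilars + cc$false_dissimilars +
            cc$false_similars == 0) NA_real_ else
    f1_score(cc$true_dissimilars, cc$false_dissimilars, cc$false_similars)
  list(per_pair = per, confusion = cc, f1 = f1,
       sweep = threshold_sweep(per$lrt_p, per$gold_label))
}

#' Extract distribution-test count-vector pairs from a merge log
#'
#' @param merge_log Merge-log data.frame from [call_otus()] (or read back
#'   from the `.log.tsv` file written by [write_outputs()]).
#' @return List of `list(x1, x2)` count-vector pairs, one per distribution
#'   test, in evaluation order.
#' @export
merge_log_pairs <- function(merge_log) {
  rows <- merge_log[merge_log$stage == "distribution", , drop = FALSE]
  unpack <- function(s) as.integer(strsplit(s, ",", fixed = TRUE)[[1L]])
  lapply(seq_len(nrow(rows)), function(i) {
    list(x1 = unpack(rows$otu_counts[i]), x2 = unpack(rows$cand_counts[i]))
  })
}
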