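# Independent oracles used across the suite. These deliberately avoid the
# implementation paths they check.

# Full dynamic-programming Levenshtein table, with the same base-matching
# convention as the package (case-insensitive; N matches nothing, not even N).
dp_edit_distance <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1L]]
  cb <- strsplit(toupper(b), "")[[1L]]
  la <- length(ca)
  lb <- length(cb)
  d <- matrix(0L, la + 1L, lb + 1L)
  d[, 1L] <- 0:la
  d[1L, ] <- 0:lb
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      match_ij <- ca[i] == cb[j] && ca[i] != "N"
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L,
                               d[i + 1L, j] + 1L,
                               d[i, j] + if (match_ij) 0L else 1L)
    }
  }
  d[la + 1L, lb + 1L]
}

random_dna_str <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Likelihood-ratio statistic evaluated directly from Poisson log-likelihoods
# at the two models' MLEs (dpois handles the 0 * log 0 limit), independent of
# the closed-form kernel the package uses.
dpois_lrt_oracle <- function(x1, x2) {
  X1 <- sum(x1)
  X2 <- sum(x2)
  lambda <- X1 * (x1 + x2) / (X1 + X2)
  rho <- X2 / X1
  l1 <- sum(dpois(x1, pmax(x1, 1e-300), log = TRUE)) +
    sum(dpois(x2, pmax(x2, 1e-300), log = TRUE))
  l0 <- sum(dpois(x1, pmax(lambda, 1e-300), log = TRUE)) +
    sum(dpois(x2, pmax(rho * lambda, 1e-300), log = TRUE))
  2 * (l1 - l0)
}

# Simulated fixed-margin p-value through r2dtable (R's own uniform
# fixed-margin table sampler), independent of the package's sampler.
r2dtable_pvalue_oracle <- function(x1, x2, B) {
  keep <- (x1 + x2) > 0
  x1 <- x1[keep]
  x2 <- x2[keep]
  obs <- suppressWarnings(
    stats::chisq.test(rbind(x1, x2), correct = FALSE)$statistic)
  tabs <- r2dtable(B, c(sum(x1), sum(x2)), x1 + x2)
  stats <- vapply(tabs, function(tb) {
    suppressWarnings(stats::chisq.test(tb, correct = FALSE)$statistic)
  }, numeric(1))
  (1 + sum(stats >= obs - 1e-8)) / (B + 1)
}

# Table 7-style worked-example counts used in several tests: an OTU and a
# rarer candidate observed across six samples.
example_otu_counts <- c(138, 129, 163, 92, 258, 14)
example_candidate_counts <- c(15, 11, 28, 1, 13, 1)

write_fasta_lines <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

write_counts_lines <- function(counts, path) {
  header <- paste(c("sequence", colnames(counts)), collapse = "\t")
  rows <- vapply(seq_len(nrow(counts)), function(i) {
    paste(c(rownames(counts)[i], counts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  path
}
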