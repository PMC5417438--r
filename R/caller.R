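#' Configuration for the OTU caller
#'
#' @param genetic_threshold Maximum normalised edit dissimilarity for a
#'   candidate to be considered for merging (default 0.1).
#' @param abundance_fold Minimum ratio of OTU total count to candidate total
#'   count for merging to be considered (default 10).
#' @param p_threshold Likelihood-ratio-test p-value below which a candidate
#'   and OTU are considered too differently distributed to merge. Default
#'   5e-4; use 0.001 to mirror the legacy simulated chi-squared criterion at
#'   its conventional threshold, or ~5e-5 when migrating a legacy threshold
#'   of 0.001 (the LRT reproduces the simulated test best at a roughly
#'   twenty-fold smaller threshold).
#' @param max_distribution_tests Cap on how many genetically-eligible OTUs
#'   are distribution-tested per candidate (default `Inf`: all of them, in
#'   order of increasing dissimilarity).
#' @return A `distotu_config` list.
#' @export
caller_config <- function(genetic_threshold = 0.1, abundance_fold = 10,
                          p_threshold = 5e-4, max_distribution_tests = Inf) {
  stopifnot(genetic_threshold > 0, genetic_threshold < 2,
            abundance_fold >= 0,
            p_threshold > 0, p_threshold < 1,
            max_distribution_tests >= 1)
  structure(
    list(genetic_threshold = genetic_threshold,
         abundance_fold = abundance_fold,
         p_threshold = p_threshold,
         max_distribution_tests = max_distribution_tests),
    class = "distotu_config"
  )
}

#' Order candidate sequences by decreasing abundance
#'
#' Sequence IDs sorted by decreasing total count, ties broken by ID in
#' ascending lexicographic (C-locale) order so the caller is deterministic.
#'
#' @param counts Integer count matrix (sequences x samples).
#' @return Character vector of sequence IDs.
#' @export
sort_candidates <- function(counts) {
  totals <- rowSums(counts)
  ids <- rownames(counts)
  ids[order(-totals, ids, method = "radix")]
}

#' OTUs eligible to absorb a candidate
#'
#' Applies the abundance criterion (the OTU's current total count, including
#' prior merges, must be at least `abundance_fold` times the candidate's
#' total) and then the genetic criterion to the abundance-passing OTUs.
#' Eligible OTUs are returned sorted by increasing dissimilarity, ties by
#' OTU creation order (earlier, i.e. more abundant, first).
#'
#' @param cand_seq Candidate nucleotide sequence.
#' @param cand_total Candidate total count.
#' @param otu_seqs Character vector of OTU representative sequences, in
#'   creation order.
#' @param otu_totals Numeric vector of current OTU total counts.
#' @param config A [caller_config()].
#' @return A list with `abundance_pass` (indices of abundance-passing OTUs)
#'   and `eligible` (data.frame of `otu` index and `dissimilarity`, sorted).
#' @export
eligible_otus <- function(cand_seq, cand_total, otu_seqs, otu_totals,
                          config = caller_config()) {
  if (length(otu_seqs) == 0L) {
    return(list(abundance_pass = integer(0),
                eligible = data.frame(otu = integer(0),
                                      dissimilarity = numeric(0))))
  }
  ab <- which(otu_totals >= config$abundance_fold * cand_total)
  if (length(ab) == 0L) {
    return(list(abundance_pass = ab,
                eligible = data.frame(otu = integer(0),
                                      dissimilarity = numeric(0))))
  }
  diss <- genetic_dissimilarity(cand_seq, otu_seqs[ab])
  keep <- diss <= config$genetic_threshold
  ord <- order(diss[keep], ab[keep])
  list(abundance_pass = ab,
       eligible = data.frame(otu = ab[keep][ord],
                             dissimilarity = diss[keep][ord]),
       dissimilarity = diss)
}

#' Call OTUs from dereplicated sequences and per-sample counts
#'
#' The greedy distribution-based OTU caller. Candidates are processed in
#' order of decreasing total abundance; the most abundant sequence founds
#' the first OTU. Each subsequent candidate is compared to the existing
#' OTUs: those passing the abundance criterion have the genetic criterion
#' evaluated, and the genetically-eligible OTUs are distribution-tested in
#' order of increasing dissimilarity with the Poisson likelihood-ratio test.
#' The candidate merges into the first OTU whose test p-value is at least
#' `p_threshold` (its counts are added to the OTU's; the representative
#' sequence never changes); if none qualifies, it founds a new OTU.
#'
#' The result is deterministic: there is no randomness anywhere in the loop
#' and all ties are broken by fixed rules.
#'
#' @param data A `distotu_data` from [validate_inputs()], or a list with
#'   elements `seqs` (named character) and `counts` (integer matrix).
#' @param config A [caller_config()].
#' @return A `distotu_result`: list with `otus` (list of per-OTU lists with
#'   `rep_id`, `rep_seq`, `counts`, `members`), `sample_ids`, `assignments`
#'   (data.frame: candidate, decision, otu), `merge_log` (data.frame with
#'   one row per genetic- or distribution-criterion evaluation: candidate,
#'   otu, stage, value, verdict, otu_counts, cand_counts) and `config`.
#' @export
call_otus <- function(data, config = caller_config()) {
  seqs <- data$seqs
  counts <- data$counts
  stopifnot(identical(sort(names(seqs)), sort(rownames(counts))))
  order_ids <- sort_candidates(counts)

  rep_id <- character(0)
  rep_seq <- character(0)
  otu_counts <- list()
  otu_totals <- numeric(0)
  members <- list()

  log_rows <- vector("list", 0L)
  assign_rows <- vector("list", length(order_ids))

  pack <- function(x) paste(x, collapse = ",")

  for (k in seq_along(order_ids)) {
    cand <- order_ids[k]
    cand_counts <- counts[cand, ]
    cand_total <- sum(cand_counts)
    el <- eligible_otus(seqs[[cand]], cand_total, rep_seq, otu_totals, config)

    # log every genetic-criterion evaluation (abundance-passing pairs)
    if (length(el$abundance_pass) > 0L) {
      d <- el$dissimilarity
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        candidate = cand, otu = rep_id[el$abundance_pass],
        stage = "genetic", value = d,
        verdict = ifelse(d <= config$genetic_threshold, "pass", "fail"),
        otu_counts = NA_character_, cand_counts = NA_character_,
        stringsAsFactors = FALSE)
    }

    merged_into <- NA_integer_
    n_tests <- 0L
    if (nrow(el$eligible) > 0L) {
      for (j in seq_len(nrow(el$eligible))) {
        if (n_tests >= config$max_distribution_tests) break
        o <- el$eligible$otu[j]
        res <- lrt_pvalue(otu_counts[[o]], cand_counts)
        n_tests <- n_tests + 1L
        ok <- res$p_value >= config$p_threshold
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          candidate = cand, otu = rep_id[o], stage = "distribution",
          value = res$p_value, verdict = if (ok) "pass" else "fail",
          otu_counts = pack(otu_counts[[o]]),
          cand_counts = pack(cand_counts),
          stringsAsFactors = FALSE)
        if (ok) {
          merged_into <- o
          break
        }
      }
    }

    if (is.na(merged_into)) {
      i <- length(rep_id) + 1L
      rep_id[i] <- cand
      rep_seq[i] <- seqs[[cand]]
      otu_counts[[i]] <- cand_counts
      otu_totals[i] <- cand_total
      members[[i]] <- cand
      assign_rows[[k]] <- data.frame(candidate = cand, decision = "new_otu",
                                     otu = cand, stringsAsFactors = FALSE)
    } else {
      otu_counts[[merged_into]] <- otu_counts[[merged_into]] + cand_counts
      otu_totals[merged_into] <- otu_totals[merged_into] + cand_total
      members[[merged_into]] <- c(members[[merged_into]], cand)
      assign_rows[[k]] <- data.frame(candidate = cand, decision = "merged",
                                     otu = rep_id[merged_into],
                                     stringsAsFactors = FALSE)
    }
  }

  merge_log <- if (length(log_rows) > 0L) {
    do.call(rbind, log_rows)
  } else {
    data.frame(candidate = character(0), otu = character(0),
               stage = character(0), value = numeric(0),
               verdict = character(0), otu_counts = character(0),
               cand_counts = character(0), stringsAsFactors = FALSE)
  }
  otus <- lapply(seq_along(rep_id), function(i) {
    list(rep_id = rep_id[i], rep_seq = rep_seq[i],
         counts = otu_counts[[i]], members = members[[i]])
  })
  structure(
    list(otus = otus, sample_ids = colnames(counts),
         assignments = do.call(rbind, assign_rows),
         merge_log = merge_log, config = config),
    class = "distotu_result"
  )
}

#' OTU table of a calling result
#'
#' @param result A `distotu_result`.
#' @return Integer matrix: rows are OTU representative IDs, columns samples.
#' @export
otu_table <- function(result) {
  stopifnot(inherits(result, "distotu_result"))
  m <- do.call(rbind, lapply(result$otus, `[[`, "counts"))
  rownames(m) <- vapply(result$otus, `[[`, character(1), "rep_id")
  colnames(m) <- result$sample_ids
  m
}

#' OTU membership map of a calling result
#'
#' @param result A `distotu_result`.
#' @return data.frame with columns `otu` and `member`, one member per row.
#' @export
otu_membership <- function(result) {
  stopifnot(inherits(result, "distotu_result"))
  do.call(rbind, lapply(result$otus, function(o) {
    data.frame(otu = o$rep_id, member = o$members, stringsAsFactors = FALSE)
  }))
}

#' @export
print.distotu_result <- function(x, ...) {
  n_gen <- sum(x$merge_log$stage == "genetic")
  n_dist <- sum(x$merge_log$stage == "distribution")
  cat(sprintf(
    "distotu result: %d sequences -> %d OTUs (%d genetic evaluations, %d distribution tests)\n",
    nrow(x$assignments), length(x$otus), n_gen, n_dist))
  invisible(x)
}
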