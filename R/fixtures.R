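#' Configuration for the synthetic mock-community generator
#'
#' Defaults emulate the scale of a dereplicated, trimmed 16S mock-community
#' benchmark: 187-nt unique sequences distributed over 6 samples, with
#' per-sample Poisson rates between 50 and 500 for the base populations and
#' error-derived variants one order of magnitude rarer.
#'
#' @param n_base_seqs Number of mutually dissimilar base sequences.
#' @param seq_length Sequence length in nucleotides (default 187).
#' @param n_samples Number of samples (default 6).
#' @param error_edits Possible edit counts for a derivative, sampled
#'   uniformly (default `1:2`).
#' @param rho_values Abundance ratios of error derivatives relative to their
#'   base; one error derivative is generated per base per value (default
#'   0.1).
#' @param lambda_range Range of per-sample Poisson rates for base sequences
#'   (default `c(50, 500)`).
#' @param twins Whether each base also gets an "ecological twin": a
#'   sequence-similar variant whose counts are confined to half of the
#'   samples, so that it must not be merged (default TRUE).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return A `distotu_fixture_config` list.
#' @export
fixture_config <- function(n_base_seqs = 10, seq_length = 187,
                           n_samples = 6, error_edits = 1:2,
                           rho_values = 0.1, lambda_range = c(50, 500),
                           twins = TRUE, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(n_base_seqs >= 1, seq_length >= 10, n_samples >= 2,
            all(error_edits >= 1), all(rho_values > 0),
            length(lambda_range) == 2, all(lambda_range > 0))
  structure(
    list(n_base_seqs = n_base_seqs, seq_length = seq_length,
         n_samples = n_samples, error_edits = error_edits,
         rho_values = rho_values, lambda_range = lambda_range,
         twins = twins, seed = as.integer(seed)),
    class = "distotu_fixture_config"
  )
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# apply k random single-character edits (substitution/insertion/deletion,
# uniform over type and position)
mutate_seq <- function(seq, k) {
  chars <- strsplit(seq, "")[[1L]]
  for (i in seq_len(k)) {
    op <- sample(c("sub", "ins", "del"), 1L)
    pos <- sample(length(chars), 1L)
    if (op == "sub") {
      chars[pos] <- sample(setdiff(c("A", "C", "G", "T"), chars[pos]), 1L)
    } else if (op == "ins") {
      chars <- append(chars, sample(c("A", "C", "G", "T"), 1L), after = pos)
    } else if (length(chars) > 1L) {
      chars <- chars[-pos]
    }
  }
  paste(chars, collapse = "")
}

rpois_nonzero <- function(n, lambda) {
  x <- stats::rpois(n, lambda)
  while (sum(x) == 0L) x <- stats::rpois(n, lambda)
  x
}

#' Generate a synthetic mock community with known ground truth
#'
#' Base sequences are random and mutually dissimilar (pairwise normalised
#' edit dissimilarity greater than twice the default genetic threshold).
#' Each base receives, per value in `rho_values`, an "error derivative": a
#' variant within `error_edits` edits whose counts are Poisson with rates
#' proportional to the base's rates (ratio rho) — ground truth says it
#' belongs in the base's OTU. With `twins = TRUE` each base also receives an
#' "ecological twin": a variant within 2 edits whose counts are confined to
#' a random half of the samples where the base's distribution is flat —
#' ground truth says it must stay a separate OTU.
#'
#' @param config A [fixture_config()].
#' @return A `distotu_community`: list with `seqs` (named character vector),
#'   `counts` (integer matrix), `truth` (data.frame: seq_id, otu_id, role)
#'   and `config`.
#' @export
make_community <- function(config) {
  stopifnot(inherits(config, "distotu_fixture_config"))
  set.seed(config$seed)
  n_samples <- config$n_samples

  # mutually dissimilar base sequences
  bases <- character(config$n_base_seqs)
  for (i in seq_len(config$n_base_seqs)) {
    for (attempt in 1:100) {
      cand <- random_dna(config$seq_length)
      if (i == 1L ||
          all(genetic_dissimilarity(cand, bases[seq_len(i - 1L)]) > 0.2)) {
        bases[i] <- cand
        break
      }
    }
    if (!nzchar(bases[i])) {
      stop("could not generate ", config$n_base_seqs,
           " mutually dissimilar sequences of length ", config$seq_length)
    }
  }

  seqs <- character(0)
  counts <- list()
  truth <- list()
  seen <- character(0)

  new_variant <- function(base_seq, k_choices) {
    for (attempt in 1:100) {
      k <- if (length(k_choices) == 1L) k_choices else sample(k_choices, 1L)
      v <- mutate_seq(base_seq, k)
      if (!(v %in% seen) && v != base_seq) return(v)
    }
    stop("could not generate a unique variant sequence")
  }

  for (i in seq_len(config$n_base_seqs)) {
    base_id <- sprintf("base%03d", i)
    lambda <- stats::runif(n_samples, config$lambda_range[1],
                           config$lambda_range[2])
    base_counts <- rpois_nonzero(n_samples, lambda)
    seqs[base_id] <- bases[i]
    seen <- c(seen, bases[i])
    counts[[base_id]] <- base_counts
    truth[[length(truth) + 1L]] <- data.frame(
      seq_id = base_id, otu_id = base_id, role = "base",
      stringsAsFactors = FALSE)

    for (r in seq_along(config$rho_values)) {
      rho <- config$rho_values[r]
      err_id <- sprintf("%s_err%d", base_id, r)
      v <- new_variant(bases[i], config$error_edits)
      seqs[err_id] <- v
      seen <- c(seen, v)
      counts[[err_id]] <- rpois_nonzero(n_samples, rho * lambda)
      truth[[length(truth) + 1L]] <- data.frame(
        seq_id = err_id, otu_id = base_id, role = "error",
        stringsAsFactors = FALSE)
    }

    if (isTRUE(config$twins)) {
      twin_id <- sprintf("%s_twin", base_id)
      v <- new_variant(bases[i], 1:2)
      seqs[twin_id] <- v
      seen <- c(seen, v)
      occupied <- sample(n_samples, floor(n_samples / 2))
      twin_lambda <- rep(0, n_samples)
      # total ~ base total / 20: safely below the abundance criterion yet
      # large enough that zero counts in the unoccupied samples are decisive
      twin_lambda[occupied] <- sum(lambda) / 20 / length(occupied)
      twin_counts <- integer(n_samples)
      twin_counts[occupied] <- rpois_nonzero(length(occupied),
                                             twin_lambda[occupied])
      seqs[twin_id] <- v
      counts[[twin_id]] <- twin_counts
      truth[[length(truth) + 1L]] <- data.frame(
        seq_id = twin_id, otu_id = twin_id, role = "twin",
        stringsAsFactors = FALSE)
    }
  }

  mat <- do.call(rbind, counts)
  storage.mode(mat) <- "integer"
  colnames(mat) <- sprintf("sample%d", seq_len(n_samples))
  structure(
    list(seqs = seqs, counts = mat, truth = do.call(rbind, truth),
         config = config),
    class = "distotu_community"
  )
}

#' Write a synthetic community to FASTA and count-table files
#'
#' @param community A `distotu_community` from [make_community()].
#' @param fasta_path,table_path Output paths.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_community <- function(community, fasta_path, table_path) {
  stopifnot(inherits(community, "distotu_community"))
  set <- Biostrings::DNAStringSet(community$seqs)
  Biostrings::writeXStringSet(set, fasta_path)
  write_count_table(community$counts, table_path)
  invisible(c(fasta = fasta_path, table = table_path))
}

#' Score ground-truth recovery of a calling result
#'
#' @param result A `distotu_result` from [call_otus()].
#' @param truth The `truth` data.frame of the generating community.
#' @return Named numeric vector: `merge_rate` (fraction of error derivatives
#'   assigned to their base's OTU) and `split_rate` (fraction of ecological
#'   twins kept out of their base's OTU), each `NaN` if the role is absent.
#' @export
recovery_rates <- function(result, truth) {
  assigned <- stats::setNames(result$assignments$otu,
                              result$assignments$candidate)
  err <- truth[truth$role == "error", , drop = FALSE]
  twin <- truth[truth$role == "twin", , drop = FALSE]
  merge_rate <- mean(assigned[err$seq_id] == err$otu_id)
  # a twin is correctly split when it is NOT assigned to its base's OTU
  base_of <- sub("_twin$", "", twin$seq_id)
  split_rate <- mean(assigned[twin$seq_id] != base_of)
  c(merge_rate = merge_rate, split_rate = split_rate)
}
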