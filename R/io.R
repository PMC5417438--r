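#' Read dereplicated sequences from a FASTA file
#'
#' Reads a FASTA file of dereplicated amplicon sequences. Sequence IDs are
#' the first whitespace-delimited token of each header line. Sequences are
#' uppercased and must consist of A, C, G, T and N only; degenerate IUPAC
#' codes are rejected because the edit-distance semantics of ambiguity codes
#' are undefined for the genetic criterion.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector: names are sequence IDs, values are
#'   uppercase nucleotide strings, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file is empty: ", path)
  }
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("FASTA file contains an entry with an empty ID")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate sequence ID(s) in FASTA: ",
         paste(utils::head(dup, 10L), collapse = ", "))
  }
  seqs <- toupper(gsub("[ \t\r\n]", "", as.character(set)))
  if (any(!nzchar(seqs))) {
    stop("empty sequence(s) in FASTA: ",
         paste(utils::head(ids[!nzchar(seqs)], 10L), collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("sequence(s) contain characters outside A/C/G/T/N: ",
         paste(utils::head(ids[bad], 10L), collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Read a sequence-by-sample count table
#'
#' Reads a tab-separated count table: the first row is a header whose first
#' cell is an ignorable label followed by sample names; every subsequent row
#' is a sequence ID followed by one non-negative integer count per sample.
#' Rows whose counts sum to zero are rejected, since a dereplicated sequence
#' must have been observed at least once.
#'
#' @param path Path to a tab-separated count table.
#' @return An integer matrix with sequence IDs as row names and sample names
#'   as column names, in file order.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) {
    stop("count table not found: ", path)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop("count table must have a header row and at least one data row: ",
         path)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L) {
    stop("count table header must name at least one sample")
  }
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample name(s) in count table header")
  }
  n_col <- length(header)
  rows <- fields[-1L]
  widths <- lengths(rows)
  if (any(widths != n_col)) {
    stop("ragged row(s) in count table at line(s): ",
         paste(utils::head(which(widths != n_col) + 1L, 10L),
               collapse = ", "))
  }
  ids <- vapply(rows, `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate sequence ID(s) in count table: ",
         paste(utils::head(dup, 10L), collapse = ", "))
  }
  cells <- matrix(unlist(lapply(rows, `[`, -1L)), nrow = length(rows),
                  byrow = TRUE)
  num <- suppressWarnings(as.numeric(cells))
  dim(num) <- dim(cells)
  bad <- which(is.na(num) | num != round(num) | num < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-integer or negative count at row %d (sequence '%s'), column '%s'",
      bad[1L, 1L] + 1L, ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  }
  counts <- matrix(as.integer(num), nrow = length(rows),
                   dimnames = list(ids, sample_ids))
  zero <- rowSums(counts) == 0L
  if (any(zero)) {
    stop("sequence(s) with zero total count: ",
         paste(utils::head(ids[zero], 10L), collapse = ", "))
  }
  counts
}

#' Join sequences and counts into a validated dataset
#'
#' Checks that the FASTA and the count table describe exactly the same set
#' of sequence IDs; a sequence that appears in only one of the two files is
#' an error rather than being silently dropped.
#'
#' @param seqs Named character vector from [read_fasta()].
#' @param counts Integer matrix from [read_count_table()].
#' @return A `distotu_data` object: a list with elements `seqs` (named
#'   character vector, reordered to match the count table rows), `counts`
#'   (integer matrix) and `sample_ids`.
#' @export
validate_inputs <- function(seqs, counts) {
  fasta_ids <- names(seqs)
  table_ids <- rownames(counts)
  only_fasta <- setdiff(fasta_ids, table_ids)
  only_table <- setdiff(table_ids, fasta_ids)
  if (length(only_fasta) > 0L) {
    stop("sequence ID(s) in FASTA but not in count table: ",
         paste(utils::head(only_fasta, 10L), collapse = ", "))
  }
  if (length(only_table) > 0L) {
    stop("sequence ID(s) in count table but not in FASTA: ",
         paste(utils::head(only_table, 10L), collapse = ", "))
  }
  structure(
    list(seqs = seqs[table_ids], counts = counts,
         sample_ids = colnames(counts)),
    class = "distotu_data"
  )
}

#' @export
print.distotu_data <- function(x, ...) {
  cat(sprintf("distotu dataset: %d sequences x %d samples, %d total counts\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

write_count_table <- function(counts, path) {
  df <- data.frame(sequence = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write OTU-calling results to disk
#'
#' Writes three tab-separated files: `<prefix>.otu.tsv` (the OTU table:
#' rows are OTU IDs, i.e. representative sequence IDs, columns are samples),
#' `<prefix>.membership.tsv` (OTU ID and member sequence ID, one member per
#' row) and `<prefix>.log.tsv` (the merge log: one row per criterion
#' evaluation). Per-sample column sums of the OTU table equal those of the
#' input count table.
#'
#' @param result A `distotu_result` from [call_otus()].
#' @param out_prefix Path prefix for the output files.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_outputs <- function(result, out_prefix) {
  stopifnot(inherits(result, "distotu_result"))
  paths <- c(otu_table = paste0(out_prefix, ".otu.tsv"),
             membership = paste0(out_prefix, ".membership.tsv"),
             merge_log = paste0(out_prefix, ".log.tsv"))
  write_count_table(otu_table(result), paths[["otu_table"]])
  memb <- otu_membership(result)
  utils::write.table(memb, paths[["membership"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(result$merge_log, paths[["merge_log"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
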