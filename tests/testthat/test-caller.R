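make_data <- function(seqs, counts) {
  validate_inputs(seqs, counts)
}

test_that("sort_candidates orders by decreasing total, ties by ID", {
  counts <- matrix(c(5L, 10L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_identical(sort_candidates(counts), c("b", "a"))
  counts2 <- matrix(c(5L, 5L), 2, 1, dimnames = list(c("b", "a"), "s1"))
  expect_identical(sort_candidates(counts2), c("a", "b"))
})

test_that("eligible_otus applies abundance then genetic, sorted by similarity", {
  cfg <- caller_config()
  none <- eligible_otus("ACGT", 5, character(0), numeric(0), cfg)
  expect_identical(nrow(none$eligible), 0L)

  # abundance criterion: OTU total must be >= fold * candidate total
  el <- eligible_otus("ACGTACGTAC", 11, "ACGTACGTAC", 100, cfg)
  expect_identical(length(el$abundance_pass), 0L)
  el <- eligible_otus("ACGTACGTAC", 10, "ACGTACGTAC", 100, cfg)
  expect_identical(el$eligible$otu, 1L)

  # two OTUs at dissimilarities 0.02 and 0.01: the closer one first
  s <- paste(rep("ACGT", 25), collapse = "")  # length 100
  sub_at <- function(seq, pos, ch) {
    v <- strsplit(seq, "")[[1L]]
    v[pos] <- ch
    paste(v, collapse = "")
  }
  otu1 <- sub_at(sub_at(s, 3, "T"), 50, "A")  # 0.02
  otu2 <- sub_at(s, 10, "G")                  # 0.01
  el <- eligible_otus(s, 10, c(otu1, otu2), c(1000, 1000), cfg)
  expect_identical(el$eligible$otu, c(2L, 1L))
  expect_true(all(diff(el$eligible$dissimilarity) >= 0))
})

test_that("proportional rare variants merge; ecologically disjoint ones do not", {
  s <- paste(rep("ACGT", 25), collapse = "")
  set.seed(21)
  v_err <- distotu:::mutate_seq(s, 1)
  v_twin <- distotu:::mutate_seq(s, 2)
  seqs <- c(base = s, err = v_err, twin = v_twin)
  counts <- rbind(
    base = c(300L, 200L, 400L, 250L, 350L, 300L),
    err  = c(30L, 20L, 40L, 25L, 35L, 30L),   # exactly proportional
    twin = c(60L, 60L, 60L, 0L, 0L, 0L))      # confined to half the samples
  colnames(counts) <- paste0("s", 1:6)
  res <- call_otus(make_data(seqs, counts), caller_config(p_threshold = 0.001))
  assigned <- setNames(res$assignments$otu, res$assignments$candidate)
  expect_identical(assigned[["base"]], "base")
  expect_identical(assigned[["err"]], "base")   # Lambda = 0 so p = 1
  expect_identical(assigned[["twin"]], "twin")  # LRT rejects proportionality
  expect_identical(length(res$otus), 2L)
  # merged counts accumulate; the representative never changes
  expect_identical(otu_table(res)["base", ], counts["base", ] + counts["err", ])
})

test_that("the caller conserves per-sample counts and is deterministic", {
  comm <- make_community(fixture_config(n_base_seqs = 6, seed = 99))
  cfg <- caller_config(abundance_fold = 5)
  r1 <- call_otus(comm, cfg)
  r2 <- call_otus(comm, cfg)
  expect_identical(r1, r2)
  expect_equal(colSums(otu_table(r1)), colSums(comm$counts))
  expect_setequal(otu_membership(r1)$member, rownames(comm$counts))
  expect_identical(nrow(r1$assignments), nrow(comm$counts))
  expect_lte(length(r1$otus), nrow(comm$counts))
})

test_that("OTU count is monotone non-increasing in the p threshold", {
  comm <- make_community(fixture_config(n_base_seqs = 6, seed = 123))
  thresholds <- c(1e-12, 1e-6, 1e-3, 0.05, 0.5, 0.999999)
  n_otus <- vapply(thresholds, function(p) {
    length(call_otus(comm, caller_config(abundance_fold = 5,
                                         p_threshold = p))$otus)
  }, numeric(1))
  expect_true(all(diff(n_otus) >= 0))
})

test_that("merge log records one assignment per candidate and every test", {
  comm <- make_community(fixture_config(n_base_seqs = 4, seed = 7))
  res <- call_otus(comm, caller_config(abundance_fold = 5))
  expect_setequal(res$assignments$candidate, rownames(comm$counts))
  expect_identical(anyDuplicated(res$assignments$candidate), 0L)
  gen <- res$merge_log[res$merge_log$stage == "genetic", ]
  dist <- res$merge_log[res$merge_log$stage == "distribution", ]
  # every distribution test was preceded by a passing genetic evaluation
  expect_true(all(paste(dist$candidate, dist$otu) %in%
                  paste(gen$candidate, gen$otu)[gen$verdict == "pass"]))
  # logged count vectors reproduce the logged p-values
  pairs <- merge_log_pairs(res$merge_log)
  replayed <- vapply(pairs, function(p) lrt_pvalue(p$x1, p$x2)$p_value,
                     numeric(1))
  expect_equal(replayed, dist$value, tolerance = 1e-12)
})
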