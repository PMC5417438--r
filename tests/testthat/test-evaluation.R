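test_that("confusion tallies the four cells with 'similar' as positive", {
  pred <- c("similar", "similar", "dissimilar", "dissimilar")
  expect_identical(unclass(confusion(pred, pred)),
                   list(true_similars = 2L, false_similars = 0L,
                        false_dissimilars = 0L, true_dissimilars = 2L))
  one_off <- confusion(c("similar", "similar"), c("similar", "dissimilar"))
  expect_identical(one_off$false_similars, 1L)
  expect_error(confusion("similar", c("similar", "similar")), "equal length")
  expect_error(confusion("yes", "similar"), "labels")
})

test_that("sensitivity and specificity reproduce published-style rows", {
  cc <- structure(list(true_similars = 166, false_similars = 11,
                       false_dissimilars = 1, true_dissimilars = 3510),
                  class = "distotu_confusion")
  ss <- sensitivity_specificity(cc)
  expect_equal(round(ss[["sensitivity"]], 1), 99.4)
  expect_equal(round(ss[["specificity"]], 1), 99.7)

  cc2 <- structure(list(true_similars = 484, false_similars = 139,
                        false_dissimilars = 3, true_dissimilars = 3062),
                   class = "distotu_confusion")
  ss2 <- sensitivity_specificity(cc2)
  expect_equal(round(ss2[["sensitivity"]], 1), 99.4)
  expect_equal(round(ss2[["specificity"]], 1), 95.7)

  perfect <- confusion(c("similar", "dissimilar"), c("similar", "dissimilar"))
  expect_equal(sensitivity_specificity(perfect),
               c(sensitivity = 100, specificity = 100))
})

test_that("F1 uses 'dissimilar' as the positive class", {
  expect_equal(round(f1_score(16, 1, 0), 1), 97.0)
  expect_equal(round(f1_score(14, 0, 2), 1), 93.3)
  expect_equal(f1_score(16, 0, 0), 100)
  expect_error(f1_score(0, 0, 0), "undefined")
})

test_that("pearson_ci reports r and a Fisher-z interval in percent", {
  x <- 1:20
  expect_equal(pearson_ci(x, 2 * x + 3)[["r"]], 100)
  set.seed(501)
  a <- rnorm(2000)
  b <- rnorm(2000)
  ci <- pearson_ci(a, b)
  expect_lt(abs(ci[["r"]]), 10)
  expect_lt(ci[["low"]], ci[["r"]])
  expect_gt(ci[["high"]], ci[["r"]])
  expect_error(pearson_ci(1:3, 1:3), "at least 4")
  expect_error(pearson_ci(rep(1, 10), 1:10), "constant")
})

test_that("threshold_sweep is monotone and hits the endpoints", {
  p <- c(1e-6, 1e-4, 0.02, 0.3)
  gold <- c("dissimilar", "dissimilar", "similar", "similar")
  sw <- threshold_sweep(p, gold)
  expect_identical(sw$true_dissimilars[1], 0L)   # below all p-values
  expect_identical(sw$false_similars[1], 2L)
  last <- nrow(sw)
  expect_identical(sw$true_dissimilars[last], 2L) # above all p-values
  expect_identical(sw$false_dissimilars[last], 2L)
  expect_true(all(diff(sw$true_dissimilars) >= 0))
  expect_true(all(diff(sw$false_similars) <= 0))
  # perfect separation attainable between the two label groups
  expect_true(any(sw$f1 == 100, na.rm = TRUE))
})

test_that("evaluate_distribution classifies crafted pairs correctly", {
  pairs <- list(
    list(x1 = c(300L, 200L, 400L), x2 = c(30L, 20L, 40L)),   # proportional
    list(x1 = c(300L, 300L, 300L), x2 = c(90L, 0L, 0L)))     # disjoint-ish
  rep <- evaluate_distribution(pairs, B = 5000, seed = 17)
  expect_identical(rep$per_pair$lrt_label, c("similar", "dissimilar"))
  expect_identical(rep$per_pair$gold_label, c("similar", "dissimilar"))
  expect_identical(rep$confusion$true_dissimilars, 1L)
  expect_identical(rep$confusion$true_similars, 1L)
  expect_equal(rep$f1, 100)
  expect_identical(nrow(evaluate_distribution(list())$per_pair), 0L)
})

test_that("evaluate_genetic scores the fast metric against the aligner", {
  set.seed(502)
  a <- character(0)
  b <- character(0)
  for (i in 1:25) {
    s <- random_dna_str(80)
    a <- c(a, s)
    b <- c(b, distotu:::mutate_seq(s, sample(1:12, 1)))
  }
  rep <- evaluate_genetic(a, b, levels = c(0.05, 0.1))
  expect_identical(nrow(rep$table), 2L)
  totals <- rowSums(rep$table[, c("true_similars", "false_similars",
                                  "false_dissimilars", "true_dissimilars")])
  expect_true(all(totals == 25))
  # on mutation-derived near pairs the Levenshtein metric only overestimates,
  # so gold-dissimilar pairs are essentially never called similar
  expect_true(all(rep$table$specificity >= 90, na.rm = TRUE))
  # confusion agrees with a direct tally of the two metrics
  lev <- genetic_dissimilarity(a, b)
  gold <- alignment_dissimilarity(a, b)
  expect_identical(rep$table$true_similars[2],
                   sum(lev <= 0.1 & gold <= 0.1))
})
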