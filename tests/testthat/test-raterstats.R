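# Diagnostic accuracy and inter-rater agreement statistics.

test_that("confusion counts are exact and validate alignment", {
  fx <- fixture_table()
  perfect <- confusion_counts(fx$truth, fx$truth)
  expect_equal(c(perfect$fn, perfect$fp), c(0L, 0L))
  p2 <- confusion_counts(fixture_calls_named(fx, 2), fx$truth)
  expect_equal(unlist(p2[c("tp", "fn", "fp", "tn")]),
               c(tp = 6, fn = 4, fp = 0, tn = 34))
  p3 <- confusion_counts(fixture_calls_named(fx, 3), fx$truth)
  expect_equal(unlist(p3[c("tp", "fn", "fp", "tn")]),
               c(tp = 9, fn = 1, fp = 9, tn = 25))
  bad <- fx$truth; names(bad)[1] <- "nope"
  expect_error(confusion_counts(fixture_calls_named(fx, 1), bad),
               "case ids")
})

test_that("diagnostic metrics follow their defining ratios", {
  m <- diagnostic_metrics(structure(list(tp = 6, fn = 4, fp = 0, tn = 34),
                                    class = "confusion_counts"))
  expect_equal(unname(m$rounded["specificity"]), 1.00)
  expect_equal(unname(m$rounded["ppv"]), 1.00)
  expect_equal(unname(m$rounded["sensitivity"]), 0.60)
  expect_equal(unname(m$raw["accuracy"]), 40 / 44)
  expect_equal(unname(m$rounded["accuracy"]), 0.91)
  m3 <- diagnostic_metrics(structure(list(tp = 9, fn = 1, fp = 9, tn = 25),
                                     class = "confusion_counts"))
  expect_equal(unname(m3$rounded["ppv"]), 0.50)
  expect_equal(unname(m3$rounded["accuracy"]), 0.77)
  perfect <- diagnostic_metrics(structure(
    list(tp = 10, fn = 0, fp = 0, tn = 34), class = "confusion_counts"))
  expect_true(all(perfect$raw == 1))
  # zero denominators are absent (NA), never zero
  noneg <- diagnostic_metrics(structure(
    list(tp = 10, fn = 0, fp = 0, tn = 0), class = "confusion_counts"))
  expect_true(is.na(noneg$raw["specificity"]))
  expect_true(is.na(noneg$raw["npv"]))
  expect_equal(unname(noneg$raw["sensitivity"]), 1)
  expect_equal(unname(noneg$raw["accuracy"]), 1)
})

test_that("majority vote picks the label of more than half the raters", {
  t3 <- rating_table(matrix(c("cancer", "benign", "cancer",
                              "benign", "benign", "cancer",
                              "cancer", "cancer", "cancer"),
                            nrow = 3, byrow = TRUE))
  expect_equal(unname(majority_vote(t3)), c("cancer", "benign", "cancer"))
  # even rater count: tie rule applies
  t4 <- rating_table(matrix(c("cancer", "cancer", "benign", "benign"),
                            nrow = 1))
  expect_equal(unname(majority_vote(t4)), "benign")
  expect_equal(unname(majority_vote(t4, tie = "cancer")), "cancer")
  fx <- fixture_table()
  mj <- confusion_counts(majority_vote(fx$table), fx$truth)
  expect_equal(unlist(mj[c("tp", "fn", "fp", "tn")]),
               c(tp = 9, fn = 1, fp = 2, tn = 32))
})

test_that("overall agreement equals the pairwise oracle on 200 random tables", {
  set.seed(99)
  for (i in 1:200) {
    tab <- random_rating_table(sample(2:10, 1), sample(2:5, 1))
    expect_equal(overall_agreement(tab), oracle_pairwise_agreement(tab$calls))
  }
  unan <- rating_table(matrix("cancer", 5, 3))
  expect_equal(overall_agreement(unan), 1)
  expect_error(overall_agreement(rating_table(matrix("cancer", 5, 1))),
               "2 raters")
})

test_that("free-marginal kappa is the affine map of observed agreement", {
  fx <- fixture_table()
  k <- free_marginal_kappa(fx$table, 2)
  expect_equal(k$p_overall, 36 / 44)
  expect_equal(k$kappa_free, 2 * 36 / 44 - 1)
  expect_equal(round_half_up(k$kappa_free, 2), 0.64)
  unan <- rating_table(matrix("benign", 44, 3))
  expect_equal(free_marginal_kappa(unan, 2)$kappa_free, 1)
  expect_error(free_marginal_kappa(fx$table, 1), "k_categories")
  # affine & strictly increasing in P_o; kappa = 1 iff P_o = 1
  set.seed(1)
  tabs <- replicate(10, random_rating_table(8, 3), simplify = FALSE)
  ps <- vapply(tabs, overall_agreement, numeric(1))
  ks <- vapply(tabs, function(t) free_marginal_kappa(t, 2)$kappa_free,
               numeric(1))
  expect_equal(ks, 2 * ps - 1)
  expect_equal(ks == 1, ps == 1)
  # k = 4 categories: chance level is 1/4
  expect_equal(free_marginal_kappa(tabs[[1]], 4)$kappa_free,
               (ps[1] - 0.25) / 0.75)
})

test_that("label-swap symmetry swaps sens/spec and ppv/npv only", {
  fx <- fixture_table()
  swap <- function(x) ifelse(x == "cancer", "benign", "cancer")
  calls <- fixture_calls_named(fx, 1)
  m1 <- diagnostic_metrics(confusion_counts(calls, fx$truth))$raw
  m2 <- diagnostic_metrics(confusion_counts(swap(calls),
                                            swap(fx$truth)))$raw
  expect_equal(unname(m2["sensitivity"]), unname(m1["specificity"]))
  expect_equal(unname(m2["specificity"]), unname(m1["sensitivity"]))
  expect_equal(unname(m2["ppv"]), unname(m1["npv"]))
  expect_equal(unname(m2["npv"]), unname(m1["ppv"]))
  expect_equal(unname(m2["accuracy"]), unname(m1["accuracy"]))
  swapped_tab <- rating_table(swap(fx$table$calls),
                              case_ids = fx$table$case_ids)
  expect_equal(overall_agreement(swapped_tab),
               overall_agreement(fx$table))
})

test_that("bootstrap CI is seeded, degenerate-safe and brackets the kappa", {
  fx <- fixture_table()
  ci_a <- kappa_bootstrap_ci(fx$table, n_boot = 2000, seed = 42)
  ci_b <- kappa_bootstrap_ci(fx$table, n_boot = 2000, seed = 42)
  expect_identical(ci_a, ci_b)
  # different seeds: overlapping intervals (the bootstrap distribution is
  # discrete, so the endpoints may coincide, but they must overlap)
  ci_c <- kappa_bootstrap_ci(fx$table, n_boot = 2000, seed = 43)
  expect_lt(ci_a[1], 0.64); expect_gt(ci_a[2], 0.64)
  expect_lt(max(ci_a[1], ci_c[1]), min(ci_a[2], ci_c[2]))
  unan <- rating_table(matrix("cancer", 10, 3))
  expect_equal(kappa_bootstrap_ci(unan, n_boot = 200, seed = 1), c(1, 1))
  expect_error(kappa_bootstrap_ci(fx$table, n_boot = 10), "n_boot")
  one <- rating_table(matrix("cancer", 1, 3))
  expect_error(kappa_bootstrap_ci(one, n_boot = 200), "2 cases")
})

test_that("the fixture satisfies every published marginal", {
  fx <- fixture_table()
  expect_equal(nrow(fx$table$calls), 44L)
  expect_equal(ncol(fx$table$calls), 3L)
  expect_equal(sum(fx$truth == "cancer"), 10L)
  p1 <- confusion_counts(fixture_calls_named(fx, 1), fx$truth)
  expect_equal(unlist(p1[c("tp", "fn", "fp", "tn")]),
               c(tp = 9, fn = 1, fp = 2, tn = 32))
  n_cancer <- rowSums(fx$table$calls == "cancer")
  unanimous <- sum(n_cancer %in% c(0, 3))
  expect_equal(unanimous, 32L)                 # 12 cases split 2-1
})

test_that("ratings survive a CSV round trip", {
  fx <- fixture_table()
  p <- tempfile(fileext = ".csv")
  write_ratings_csv(fx$table, fx$truth, p)
  back <- read_ratings_csv(p)
  expect_identical(back$table$calls, fx$table$calls)
  expect_identical(back$truth, fx$truth)
  expect_error(read_ratings_csv({
    q <- tempfile(fileext = ".csv")
    writeLines("a,b\n1,2", q); q
  }), "case_id")
})

test_that("evaluate_ratings assembles the full report", {
  fx <- fixture_table()
  rep <- evaluate_ratings(fx$table, fx$truth, ci = TRUE, n_boot = 500,
                          seed = 3)
  expect_equal(dim(rep$metrics), c(5L, 4L))
  expect_equal(rep$metrics[["majority"]],
               c(0.90, 0.94, 0.93, 0.82, 0.97))
  expect_length(rep$agreement$ci95, 2L)
})
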