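# a ranked list with the given order and distinct scores
fake_ranked <- function(ids) {
  n <- length(ids)
  structure(list(entries = data.frame(rank = seq_len(n), drug_id = ids,
                                      score = as.numeric(rev(seq_len(n))),
                                      percentile = seq_len(n) / n * 100,
                                      stringsAsFactors = FALSE),
                 n_candidates = n, excluded = character()),
            class = "ranked_drugs")
}

test_that("median percentile picks the middle of the found drugs", {
  r <- fake_ranked(sprintf("d%03d", 1:100))
  expect_equal(as.numeric(median_percentile(r, "d005")), 5)
  m <- median_percentile(r, c("d010", "d020", "d090"))
  expect_equal(as.numeric(m), 20)   # robust to the 90 outlier
  m2 <- median_percentile(r, c("d010", "d020", "missing"))
  expect_equal(as.numeric(m2), 15)  # even count -> midpoint mean
  expect_identical(attr(m2, "n_missing"), 1L)
  expect_message(m3 <- median_percentile(r, "nope"), "no evaluation drug")
  expect_true(is.na(m3))
})

test_that("median percentile equals a sort-and-pick oracle on random positives", {
  set.seed(202)
  r <- fake_ranked(sample(sprintf("d%03d", 1:500)))
  pos <- sample(r$entries$drug_id, 25)
  m <- as.numeric(median_percentile(r, pos))
  pct <- sort(match(pos, r$entries$drug_id) / 500 * 100)
  expect_equal(m, stats::median(pct))
  # invariant to reshuffling drugs ranked below every positive
  worst <- max(match(pos, r$entries$drug_id))
  ids2 <- c(r$entries$drug_id[1:worst],
            sample(r$entries$drug_id[-(1:worst)]))
  expect_equal(as.numeric(median_percentile(fake_ranked(ids2), pos)), m)
})

test_that("paired t-test matches the closed form and its conventions", {
  set.seed(303)
  a <- stats::setNames(runif(30, 0, 100), sprintf("d%02d", 1:30))
  b <- stats::setNames(runif(30, 0, 100), sprintf("d%02d", 1:30))
  res <- paired_rank_test(a, b)
  d <- a - b
  t_oracle <- mean(d) / (stats::sd(d) / sqrt(30))
  expect_equal(res$t, t_oracle, tolerance = 1e-9)
  expect_equal(res$p, 2 * stats::pt(-abs(t_oracle), 29), tolerance = 1e-9)
  expect_identical(res$n, 30L)
  # antisymmetry under swapping the lists
  swapped <- paired_rank_test(b, a)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)
  # identical lists -> t = 0, p = 1; constant shift -> p -> 0
  expect_equal(paired_rank_test(a, a)[c("t", "p")], list(t = 0, p = 1))
  shift <- paired_rank_test(a + 10, a)
  expect_identical(shift$p, 0)
  expect_identical(shift$t, Inf)
  expect_true(is.na(paired_rank_test(a[1], b[1])$t))
})

test_that("paired t-test uses only the overlap of the two lists", {
  a <- stats::setNames(c(10, 20, 30, 40), c("w", "x", "y", "z"))
  b <- stats::setNames(c(15, 25, 35), c("x", "y", "q"))
  res <- paired_rank_test(a, b)
  expect_identical(res$n, 2L)   # x and y only
})

test_that("average precision equals the formula on hand-built lists", {
  r <- fake_ranked(c("p1", "n1", "p2", "n2"))
  pr <- precision_recall(r, c("p1", "p2"))
  expect_equal(pr$average_precision, (1 / 1 + 2 / 3) / 2)
  expect_equal(pr$curve$recall, c(0.5, 1))
  expect_equal(pr$curve$precision, c(1, 2 / 3))
  # all positives on top -> AP 1
  top <- precision_recall(fake_ranked(c("p1", "p2", "n1", "n2")),
                          c("p1", "p2"))
  expect_equal(top$average_precision, 1)
  # missing positives counted, absent from curve
  miss <- precision_recall(r, c("p1", "ghost"))
  expect_identical(miss$n_positives_missing, 1L)
  expect_equal(miss$average_precision, 1)
})

test_that("average precision equals the exhaustive definition on random lists", {
  set.seed(505)
  for (i in 1:10) {
    ids <- sample(sprintf("d%03d", 1:200))
    pos <- sample(ids, 15)
    pr <- precision_recall(fake_ranked(ids), pos)
    expect_equal(pr$average_precision, bf_average_precision(ids, pos),
                 tolerance = 1e-12)
  }
})

test_that("AP of a random permutation concentrates near prevalence", {
  set.seed(606)
  ids <- sprintf("d%03d", 1:200)
  pos <- ids[1:20]
  ap <- replicate(200, precision_recall(fake_ranked(sample(ids)),
                                        pos)$average_precision)
  prevalence <- 0.1
  expect_lt(abs(mean(ap) - prevalence), 3 * stats::sd(ap))
})

test_that("evaluate composes the per-metric oracles into one report", {
  ids <- sprintf("d%03d", 1:50)
  r <- fake_ranked(ids)
  sets <- evaluation_sets(
    drug_id = c("d001", "d005", "d010", "d020", "d030"),
    set_label = c("approved", "potential", "potential", "off_label",
                  "off_label"),
    drug_type = c("targeted_cancer", "targeted_cancer", "non_cancer",
                  "non_cancer", "non_targeted_cancer"))
  rep <- evaluate(r, sets)
  expect_equal(rep$approved_ranks$percentile, 2)          # d001: 1/50
  expect_equal(unname(rep$per_set_median[["potential"]]), 15)   # d005,d010
  expect_equal(unname(rep$per_set_median[["off_label"]]), 50)   # d020,d030
  expect_equal(rep$combined_median, 20)                   # median of 5 drugs
  expect_equal(rep$average_precision,
               bf_average_precision(ids, names(sets$membership)))
  expect_equal(unname(rep$per_type_median[["non_cancer"]]),
               stats::median(c(20, 40)))
})

test_that("comparator-missing drugs leave the medians but not the t-test", {
  r <- fake_ranked(sprintf("d%03d", 1:50))
  sets <- evaluation_sets(c("d002", "d004", "d006"),
                          rep("potential", 3), rep("non_cancer", 3))
  comp <- fake_ranked(sprintf("d%03d", c(4, 6, 30:40)))  # d002 missing
  rep <- evaluate(r, sets, comparator = comp)
  expect_equal(unname(rep$per_set_median[["potential"]]), 8)  # all 3 kept
  expect_identical(rep$paired$combined$n, 2L)                  # d004, d006 only
  expect_identical(rep$paired_scale, "percentile")
  rep2 <- evaluate(r, sets)
  expect_null(rep2$paired)
})
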