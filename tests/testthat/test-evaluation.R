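fake_row <- function(name, acc, ids = sprintf("S%03d", seq_along(acc)),
                     agree = acc * 10, known = rep(10, length(acc))) {
  pq <- matrix(acc, ncol = 1, dimnames = list(ids, "exact_diagnosis"))
  structure(list(name = name, percent = colMeans(pq, na.rm = TRUE) * 100,
                 per_query = pq,
                 agree = matrix(agree, ncol = 1, dimnames = dimnames(pq)),
                 known = matrix(known, ncol = 1, dimnames = dimnames(pq)),
                 query_ids = ids, k = 10, n = length(acc)),
            class = "accordance_row")
}

test_that("accordance is agreements over known neighbors", {
  co <- make_cohort(20, seed = 1)
  co$exact_diagnosis <- c(rep("dx-A", 5), rep("dx-B", 15))
  matches <- data.frame(match_id = co$respondent_id[c(2:5, 6:11)])  # 4 of 10 agree
  expect_equal(accordance(co$respondent_id[1], matches, co, "exact_diagnosis"), 0.4)

  # unknown neighbor values leave the denominator
  co$exact_diagnosis[6:7] <- "unknown"
  expect_equal(accordance(co$respondent_id[1], matches, co, "exact_diagnosis"), 4 / 8)

  # unknown query value makes accordance undefined
  co$exact_diagnosis[1] <- "unknown"
  expect_true(is.na(accordance(co$respondent_id[1], matches, co, "exact_diagnosis")))

  expect_error(accordance(co$respondent_id[1], matches, co, "shoe_size"),
               "unknown property", class = "q53_data_error")
})

test_that("age accordance uses decade bins", {
  co <- make_cohort(11, seed = 2)
  co$age <- c(39L, 31:40)
  matches <- data.frame(match_id = co$respondent_id[2:11])
  # neighbors aged 31..39 fall in the query's 30-39 bin; the 40-year-old does not
  expect_equal(accordance(co$respondent_id[1], matches, co, "age"), 0.9)
})

test_that("evaluate_measure reproduces a hand-computed accordance row", {
  co <- make_cohort(15, seed = 3)
  cfg <- match_config("Manhattan", k = 4)
  row <- evaluate_measure(co, cfg)
  expect_s3_class(row, "accordance_row")
  expect_true(all(row$percent >= 0 & row$percent <= 100))
  for (i in c(1, 8, 15)) {
    m <- find_matches(co, co$respondent_id[i], cfg)
    for (p in c("gender", "age", "exact_diagnosis")) {
      expect_equal(row$per_query[i, p],
                   accordance(co$respondent_id[i], m, co, p), label = p)
    }
  }
})

test_that("perfectly separated clusters give 100% exact-diagnosis accordance", {
  cfg <- synthetic_config(
    composition = c(RD = 36, CD = 12, psychosomatic = 0, healthy = 0, unknown = 0),
    n_rd_diagnoses = 1, n_cd_diagnoses = 1,  # both clusters exceed k + 1 members
    cluster_strength = 1, dontknow_rate = 0)
  co <- generate_cohort(cfg, seed = 4)
  row <- evaluate_measure(co, match_config("Manhattan", k = 10))
  expect_equal(unname(row$percent["exact_diagnosis"]), 100)

  # single-diagnosis cohort: trivially 100 for any measure
  single <- make_cohort(14, n_diag = 1, seed = 5)
  for (m in c("Manhattan", "Cosine", "Hellinger")) {
    r <- evaluate_measure(single, match_config(m, k = 5))
    expect_equal(unname(r$percent["exact_diagnosis"]), 100, label = m)
  }
})

test_that("the random benchmark is seeded, exact on one diagnosis, and unbiased", {
  single <- make_cohort(14, n_diag = 1, seed = 6)
  rb <- random_benchmark(single, k = 5, benchmark_config(replicates = 10, seed = 7))
  expect_equal(unname(rb$percent["exact_diagnosis"]), 100)
  rb2 <- random_benchmark(single, k = 5, benchmark_config(replicates = 10, seed = 7))
  expect_identical(rb$per_query, rb2$per_query)

  # two equal diagnosis groups of 5: expectation 4/9, independent of k
  co <- make_cohort(10, seed = 8)
  co$exact_diagnosis <- rep(c("dx-A", "dx-B"), each = 5)
  expect_equal(expected_random_accordance(co, "exact_diagnosis"), 4 / 9 * 100,
               tolerance = 1e-12)
  rb3 <- random_benchmark(co, k = 3, benchmark_config(replicates = 2000, seed = 9))
  mc <- rb3$per_query[, "exact_diagnosis"]
  se <- stats::sd(mc) / sqrt(length(mc))
  expect_lt(abs(mean(mc) - 4 / 9), 3 * max(se, 1e-3))
})

test_that("expected random accordance handles single categories and unknowns", {
  co <- make_cohort(10, n_diag = 1, seed = 10)
  expect_equal(expected_random_accordance(co, "exact_diagnosis"), 100)
  # with unknowns excluded, the denominator shrinks accordingly
  co$exact_diagnosis[1:2] <- "unknown"
  expect_equal(expected_random_accordance(co, "exact_diagnosis"), 100)
})

test_that("comparing a row with itself gives p = 1", {
  co <- make_cohort(12, seed = 11)
  row <- evaluate_measure(co, match_config("Manhattan", k = 3))
  cmp <- compare_rows(row, row, "exact_diagnosis")
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$statistic, 0)
})

test_that("the exact permutation p equals exhaustive sign-flip enumeration", {
  a <- fake_row("A", c(0.9, 0.8, 0.7, 0.6, 1.0))
  b <- fake_row("B", c(0.5, 0.9, 0.3, 0.6, 0.4))
  cmp <- compare_rows(a, b, "exact_diagnosis", method = "permutation")
  expect_equal(cmp$method, "permutation-exact")
  d <- a$per_query[, 1] - b$per_query[, 1]
  flips <- expand.grid(rep(list(c(-1, 1)), 5))
  stats_all <- apply(flips, 1, function(s) abs(mean(s * d)))
  p_oracle <- mean(stats_all >= abs(mean(d)) - 1e-12)
  expect_equal(cmp$p_value, p_oracle)

  # Monte-Carlo path: valid p-value, deterministic under seed
  big_a <- fake_row("A", runif(40))
  big_b <- fake_row("B", runif(40))
  c1 <- compare_rows(big_a, big_b, "exact_diagnosis", method = "permutation",
                     n_perm = 500, seed = 3)
  c2 <- compare_rows(big_a, big_b, "exact_diagnosis", method = "permutation",
                     n_perm = 500, seed = 3)
  expect_identical(c1$p_value, c2$p_value)
  expect_gt(c1$p_value, 0)
  expect_lte(c1$p_value, 1)
})

test_that("the pooled z-test alternative works and row mismatch errors", {
  a <- fake_row("A", rep(0.8, 20))
  b <- fake_row("B", rep(0.5, 20))
  cmp <- compare_rows(a, b, "exact_diagnosis", method = "z")
  expect_equal(cmp$method, "two-proportion-z")
  expect_lt(cmp$p_value, 0.05)
  expect_true(cmp$statistic > 0)

  short <- fake_row("C", rep(0.5, 10))
  expect_error(compare_rows(a, short, "exact_diagnosis"), "same queries",
               class = "q53_data_error")
  # rows without stored neighbor indices cannot use the label-permutation null
  expect_error(compare_rows(a, b, "exact_diagnosis", method = "label-permutation"),
               "neighbor indices", class = "q53_data_error")
})

test_that("build_table assembles 25 rows with benchmark annotation", {
  co <- make_cohort(30, seed = 12)
  tab <- build_table(co, k = 5, bench = benchmark_config(replicates = 20, seed = 1),
                     pvalues = FALSE)
  expect_equal(nrow(tab$table), 25L)
  expect_true("random" %in% tab$table$measure)
  cells <- as.matrix(tab$table[, names(property_specs())])
  expect_true(all(cells >= 0 & cells <= 100, na.rm = TRUE))

  # rank-equivalent measures produce identical accordance rows
  t2 <- tab$table
  rownames(t2) <- t2$measure
  props <- names(property_specs())
  expect_equal(t2["Manhattan", props], t2["Gower", props],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(t2["Manhattan", props], t2["Minkowski", props],
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(t2["S\u00f8rensen", props], t2["Czekanowski", props],
               ignore_attr = TRUE, tolerance = 1e-12)

  # positive benchmark flags the per-property maximum
  for (p in props) {
    best <- tab$positive_benchmark[[p]]
    v <- t2[setdiff(t2$measure, "random"), p]
    expect_true(all(abs(t2[best, p] - max(v)) < 1e-9), label = p)
  }

  # comparisons are produced on request
  tab2 <- build_table(co, measures = c("Manhattan", "Cosine"), k = 5,
                      bench = benchmark_config(replicates = 20, seed = 1),
                      pvalues = TRUE, n_perm = 200)
  expect_equal(nrow(tab2$comparisons), 2L * 6L * 2L)
  expect_true(all(tab2$comparisons$p_value >= 0 & tab2$comparisons$p_value <= 1))
})

test_that("the embedding is sized, seeded, and separates a clone cluster", {
  co <- make_cohort(10, seed = 13)
  e1 <- embed_cohort(co, seed = 2, max_iter = 120)
  expect_equal(nrow(e1), 10L)
  expect_named(e1, c("respondent_id", "x", "y", "diagnostic_system"))
  e2 <- embed_cohort(co, seed = 2, max_iter = 120)
  expect_identical(e1, e2)
  expect_error(embed_cohort(co[1:4, ]), "at least 5", class = "q53_data_error")

  # a maximally distinct healthy profile ends up tightly clustered
  cfg <- synthetic_config(
    composition = c(RD = 40, CD = 0, psychosomatic = 0, healthy = 12, unknown = 0),
    n_rd_diagnoses = 4, cluster_strength = 1, dontknow_rate = 0)
  co2 <- generate_cohort(cfg, seed = 14)
  emb <- embed_cohort(co2, seed = 3, max_iter = 250)
  xy <- as.matrix(emb[, c("x", "y")])
  h <- emb$diagnostic_system == "healthy"
  dd <- as.matrix(dist(xy))
  within <- mean(dd[h, h][upper.tri(dd[h, h])])
  between <- mean(dd[h, !h])
  expect_lt(within, between)
})
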