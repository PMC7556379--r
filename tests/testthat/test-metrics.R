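test_that("the registry holds exactly the 24 measures in their 8 families", {
  m <- list_measures()
  expect_equal(nrow(m), 24L)
  expect_false(anyDuplicated(m$name) > 0)
  expect_equal(length(unique(m$family)), 8L)
  expect_equal(sum(!m$symmetric), 1L)
  expect_equal(m$name[!m$symmetric], "Neyman")
  expect_equal(m$name[m$orientation == "similarity-used-as-distance"], "Cosine")
  # selection is case-insensitive and tolerant of separators
  expect_equal(compute_distance("MANHATTAN", c(1, 2), c(2, 1)), 2)
  expect_equal(compute_distance("squared chord", c(1, 4), c(1, 4)), 0)
  expect_equal(compute_distance("sorensen", c(1, 2), c(2, 1)),
               compute_distance("S\u00f8rensen", c(1, 2), c(2, 1)))
  expect_error(compute_distance("mahalanobis", c(1, 2), c(2, 1)),
               "valid measures", class = "q53_usage_error")
})

test_that("hand-evaluated distances match the printed formulas", {
  pad <- rep(3, 49)
  expect_equal(compute_distance("Manhattan", c(1, 2, 3, 4, pad), c(4, 3, 2, 1, pad)), 8)
  p <- rep(2, 53); q <- p; q[1] <- q[1] + 3; q[2] <- q[2] + 2
  expect_equal(compute_distance("Euclidean", p, q), sqrt(13))
  q2 <- p; q2[1] <- 5; q2[2] <- 2 + 4  # answers need not exceed 5 for math checks
  expect_equal(compute_distance("Euclidean", p, q2), 5)  # sqrt(9 + 16)
  expect_equal(compute_distance("Cosine", rep(2, 53), rep(4, 53)), 1)  # parallel
  v <- random_answers()
  expect_equal(compute_distance("Jeffreys", v, v), 0)
  expect_equal(compute_distance("Manhattan", v, v), 0)
  expect_equal(compute_distance("Minkowski", c(1, 2, 2), c(4, 2, 2), exponent = 3), 3)
})

test_that("self-distance is 0 for all measures except cosine and Bhattacharyya", {
  set.seed(42)
  v <- random_answers()
  for (m in list_measures()$name) {
    d <- compute_distance(m, v, v)
    expected <- switch(m, Cosine = 1, Bhattacharyya = -log(sum(v)), 0)
    expect_equal(d, expected, tolerance = 1e-12, label = paste0(m, " self-distance"))
  }
})

test_that("all measures except Neyman are swap-symmetric on random vector pairs", {
  set.seed(7)
  meas <- list_measures()
  for (i in 1:25) {
    p <- random_answers(); q <- random_answers()
    for (j in seq_len(nrow(meas))) {
      d1 <- compute_distance(meas$name[j], p, q)
      d2 <- compute_distance(meas$name[j], q, p)
      if (meas$symmetric[j]) {
        expect_equal(d1, d2, tolerance = 1e-12, label = meas$name[j])
      }
    }
  }
  # Neyman is asymmetric in general: denominators differ between orders
  expect_false(isTRUE(all.equal(
    compute_distance("Neyman", c(1, rep(2, 52)), c(4, rep(2, 52))),
    compute_distance("Neyman", c(4, rep(2, 52)), c(1, rep(2, 52))))))
})

test_that("distances are finite and non-negative where the taxonomy requires", {
  set.seed(11)
  extremes <- list(rep(1, 53), rep(5, 53), c(rep(1, 26), rep(5, 27)))
  for (i in 1:20) {
    p <- random_answers(); q <- random_answers()
    for (m in list_measures()$name) {
      d <- compute_distance(m, p, q)
      expect_true(is.finite(d), label = paste0(m, " finite"))
      if (m %in% NONNEG_MEASURES)
        expect_gte(d, 0)
    }
  }
  for (m in list_measures()$name)
    expect_true(is.finite(compute_distance(m, extremes[[1]], extremes[[2]])))
})

test_that("Manhattan, Gower and Minkowski(p=1) rank candidates identically", {
  co <- make_cohort(30, seed = 21)
  a <- answer_matrix(co)
  q <- a[1, ]
  d_man <- apply(a[-1, ], 1, function(r) compute_distance("Manhattan", q, r))
  d_gow <- apply(a[-1, ], 1, function(r) compute_distance("Gower", q, r))
  d_min <- apply(a[-1, ], 1, function(r) compute_distance("Minkowski", q, r, exponent = 1))
  expect_equal(order(d_man), order(d_gow))
  expect_equal(d_man, d_min, tolerance = 1e-12)
  d_sor <- apply(a[-1, ], 1, function(r) compute_distance("S\u00f8rensen", q, r))
  d_cze <- apply(a[-1, ], 1, function(r) compute_distance("Czekanowski", q, r))
  expect_equal(d_sor, d_cze, tolerance = 1e-15)
})

test_that("Avg is sandwiched between half the Manhattan distance and all of it", {
  set.seed(17)
  for (i in 1:50) {
    p <- random_answers(); q <- random_answers()
    man <- compute_distance("Manhattan", p, q)
    avg <- compute_distance("Avg", p, q)
    expect_gte(avg, man / 2)
    expect_lte(avg, man)
  }
})

test_that("pairwise_distances agrees elementwise with compute_distance", {
  co <- make_cohort(10, seed = 31)
  a <- answer_matrix(co)
  for (m in c("Manhattan", "Cosine", "Neyman", "Jensen difference")) {
    pd <- pairwise_distances(m, co)
    for (i in c(1, 4, 10)) for (j in c(2, 7)) {
      expect_equal(pd[i, j], compute_distance(m, a[i, ], a[j, ]),
                   tolerance = 1e-12)
    }
    if (m != "Neyman") expect_equal(pd, t(pd), tolerance = 1e-12)
  }
  # Neyman's matrix is asymmetric in general
  co2 <- make_cohort(5, seed = 32)
  pd <- pairwise_distances("Neyman", co2)
  expect_false(isTRUE(all.equal(pd, t(pd))))
  # two clones sit at Manhattan distance 0
  cc <- make_clone_cohort(2)
  expect_equal(pairwise_distances("Manhattan", cc)[1, 2], 0)
})

test_that("invalid vectors are rejected", {
  expect_error(compute_distance("Manhattan", c(1, 2), c(1, 2, 3)),
               "unequal length", class = "q53_data_error")
  expect_error(compute_distance("Jeffreys", c(0, 2), c(1, 2)),
               "positive", class = "q53_data_error")
  expect_error(compute_distance("Minkowski", c(1, 2), c(2, 1), exponent = 0),
               "exponent", class = "q53_data_error")
})

test_that("unit-sum normalization switch rescales before the formula", {
  set.seed(3)
  p <- random_answers(); q <- random_answers()
  expect_equal(compute_distance("Manhattan", p, q, normalize = TRUE),
               sum(abs(p / sum(p) - q / sum(q))), tolerance = 1e-12)
  expect_equal(compute_distance("Hellinger", p, q, normalize = TRUE),
               sqrt(2 * sum((sqrt(p / sum(p)) - sqrt(q / sum(q)))^2)),
               tolerance = 1e-12)
})
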