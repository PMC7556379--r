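#' Matching-evaluation properties
#'
#' Accordance is evaluated on six respondent properties: gender, age, latency
#' (years with symptoms before diagnosis), disease group, diagnostic system
#' and exact diagnosis. Gender, disease group, diagnostic system and exact
#' diagnosis are compared by categorical equality; age and latency are binned
#' first, since exact-year equality would make accordance on a continuous
#' quantity all but unattainable.
#'
#' Unknown values — the literal token `"unknown"` for disease group and exact
#' diagnosis, `NA` latency — are excluded from both the numerator and the
#' denominator of accordance rather than counted as disagreement. The
#' diagnostic system keeps `"unknown"` as a regular category: it labels the
#' subgroup of respondents without an established diagnosis, which is itself
#' a meaningful group to match within.
#'
#' @param age_breaks Increasing break points for age bins, default decades
#'   `0, 10, ..., 90` (left-closed bins covering the 0-87 age range).
#' @param latency_breaks Increasing break points for latency bins, default
#'   `0, 1, 3, 6, 11, Inf` i.e. <1, 1-2, 3-5, 6-10, >10 years.
#' @return A named list of six property specifications, each with `name`,
#'   `type` (`"categorical"` or `"binned"`) and `breaks`.
#' @export
property_specs <- function(age_breaks = seq(0, 90, by = 10),
                           latency_breaks = c(0, 1, 3, 6, 11, Inf)) {
  stopifnot(all(diff(age_breaks) > 0), all(diff(latency_breaks) > 0))
  specs <- list(
    gender            = list(name = "gender", type = "categorical", breaks = NULL),
    age               = list(name = "age", type = "binned", breaks = age_breaks),
    latency           = list(name = "latency", type = "binned", breaks = latency_breaks),
    disease_group     = list(name = "disease_group", type = "categorical", breaks = NULL),
    diagnostic_system = list(name = "diagnostic_system", type = "categorical", breaks = NULL),
    exact_diagnosis   = list(name = "exact_diagnosis", type = "categorical", breaks = NULL)
  )
  specs
}

.PROPERTY_NAMES <- c("gender", "age", "latency", "disease_group",
                     "diagnostic_system", "exact_diagnosis")

# comparable label per respondent for one property; NA marks "unknown",
# which drops the respondent from that property's accordance terms
.property_values <- function(cohort, spec) {
  switch(spec$name,
    gender = cohort$gender,
    age = as.character(cut(cohort$age, breaks = spec$breaks, right = FALSE)),
    latency = as.character(cut(cohort$latency_years, breaks = spec$breaks,
                               right = FALSE)),
    disease_group = ifelse(cohort$disease_group == "unknown", NA_character_,
                           cohort$disease_group),
    diagnostic_system = cohort$diagnostic_system,
    exact_diagnosis = ifelse(cohort$exact_diagnosis == "unknown", NA_character_,
                             cohort$exact_diagnosis),
    stop_data(paste0("unknown property: ", spec$name))
  )
}

.get_spec <- function(property, specs) {
  if (!property %in% names(specs))
    stop_data(paste0("unknown property '", property, "'; must be one of: ",
                     paste(.PROPERTY_NAMES, collapse = ", ")))
  specs[[property]]
}

#' Accordance of one match list on one property
#'
#' The fraction of a query's matches that agree with the query on a property:
#' agreements divided by the number of matches whose property value is known.
#' Returns `NA` if the query's own value is unknown or no match has a known
#' value.
#'
#' @param query_id Respondent id of the query.
#' @param matches A match data frame from [find_matches()] (or any data frame
#'   with a `match_id` column of cohort ids).
#' @param cohort The cohort both belong to.
#' @param property One of `"gender"`, `"age"`, `"latency"`, `"disease_group"`,
#'   `"diagnostic_system"`, `"exact_diagnosis"`.
#' @param specs Property specifications from [property_specs()].
#' @return A single value in `[0, 1]`, or `NA`.
#' @examples
#' # 4 of 10 matches sharing the exact diagnosis gives 0.4
#' @export
accordance <- function(query_id, matches, cohort, property,
                       specs = property_specs()) {
  spec <- .get_spec(property, specs)
  vals <- .property_values(cohort, spec)
  names(vals) <- cohort$respondent_id
  qv <- vals[[query_id]]
  if (is.na(qv)) return(NA_real_)
  nb <- vals[matches$match_id]
  known <- !is.na(nb)
  if (!any(known)) return(NA_real_)
  mean(nb[known] == qv)
}

# core accordance machinery shared by measure evaluation and the random
# benchmark: given n x k neighbor indices, per-query accordance for all
# six properties plus raw agree/known counts (for the pooled z-test)
.accordance_from_idx <- function(cohort, idx, specs) {
  n <- nrow(cohort)
  props <- names(specs)
  per_query <- matrix(NA_real_, n, length(props), dimnames = list(cohort$respondent_id, props))
  agree <- matrix(0, n, length(props), dimnames = dimnames(per_query))
  known <- matrix(0, n, length(props), dimnames = dimnames(per_query))
  for (p in seq_along(props)) {
    vals <- .property_values(cohort, specs[[p]])
    qv <- vals
    nb <- matrix(vals[idx], nrow = n)
    kn <- !is.na(nb)
    ag <- kn & (nb == matrix(qv, n, ncol(nb)))
    kn_count <- rowSums(kn)
    ag_count <- rowSums(ag)
    acc <- ifelse(kn_count > 0, ag_count / kn_count, NA_real_)
    acc[is.na(qv)] <- NA_real_
    ag_count[is.na(qv)] <- NA_real_
    kn_count[is.na(qv)] <- NA_real_
    per_query[, p] <- acc
    agree[, p] <- ag_count
    known[, p] <- kn_count
  }
  list(per_query = per_query, agree = agree, known = known)
}

.row_object <- function(name, acc, cohort, k, specs, idx = NULL,
                        benchmark = FALSE) {
  labels <- lapply(specs, .property_values, cohort = cohort)
  structure(list(
    name = name,
    percent = colMeans(acc$per_query, na.rm = TRUE) * 100,
    per_query = acc$per_query,
    agree = acc$agree,
    known = acc$known,
    query_ids = cohort$respondent_id,
    labels = labels,   # per-property value vectors, for label permutation
    idx = idx,         # n x k neighbor indices (NULL for the benchmark row)
    benchmark = benchmark,
    k = k, n = nrow(cohort)
  ), class = "accordance_row")
}

# mean accordance over queries for one label vector z and a fixed neighbor
# index matrix; the label-permutation machinery re-evaluates this under
# permuted z while the k-NN graph stays fixed
.mean_accordance <- function(z, idx) {
  n <- length(z)
  nb <- matrix(z[idx], nrow = n)
  kn <- !is.na(nb)
  ag <- kn & (nb == matrix(z, n, ncol(nb)))
  kc <- rowSums(kn)
  acc <- ifelse(kc > 0, rowSums(ag) / kc, NA_real_)
  acc[is.na(z)] <- NA_real_
  mean(acc, na.rm = TRUE)
}

# expectation of random-matching accordance given a label vector (category
# counts only), invariant under any permutation of z
.analytic_accordance <- function(z) {
  n <- length(z)
  u <- sum(is.na(z))
  tab <- table(z[!is.na(z)])
  sum((tab / (n - u)) * ((tab - 1) / (n - 1 - u)))
}

#' Leave-one-out accordance of one measure
#'
#' Matches every respondent against the remaining cohort under `config` and
#' averages, per property, the per-query accordance over all queries whose
#' property value is known.
#'
#' @param cohort A cohort data frame.
#' @param config A [match_config()].
#' @param specs Property specifications from [property_specs()].
#' @return An `accordance_row` object: `percent` (named vector, six mean
#'   accordances in percent), `per_query` (n x 6 matrix of per-query
#'   fractions, `NA` where undefined), raw agreement counts, and metadata.
#' @export
evaluate_measure <- function(cohort, config = match_config(),
                             specs = property_specs()) {
  validate_cohort(cohort)
  a <- answer_matrix(cohort)
  nn <- .knn_all(a, config)
  acc <- .accordance_from_idx(cohort, nn$idx, specs)
  .row_object(config$measure, acc, cohort, config$k, specs, idx = nn$idx)
}

#' Random-benchmark configuration
#'
#' @param replicates Pseudorandom match lists drawn per query (default 100).
#' @param seed Integer seed.
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(replicates = 100L, seed = 1L) {
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) stop_usage("replicates must be >= 1")
  structure(list(replicates = replicates, seed = as.integer(seed)),
            class = "benchmark_config")
}

#' Pseudorandom-matching benchmark (negative benchmark)
#'
#' For every query, draws `replicates` pseudorandom match lists of k distinct
#' non-self respondents and averages their accordance. This is the null model
#' every distance measure is compared against: a measure that cannot beat it
#' carries no matching signal for that property.
#'
#' @param cohort A cohort data frame.
#' @param k Matches per draw.
#' @param bench A [benchmark_config()].
#' @param specs Property specifications from [property_specs()].
#' @return An `accordance_row` object named `"random"`; `per_query` holds each
#'   query's accordance averaged over the replicates, `agree`/`known` hold
#'   per-replicate-averaged counts.
#' @export
random_benchmark <- function(cohort, k = 10L, bench = benchmark_config(),
                             specs = property_specs()) {
  validate_cohort(cohort)
  n <- nrow(cohort)
  k <- as.integer(k)
  if (k >= n) stop_usage(sprintf("k (%d) must be smaller than the cohort size (%d)", k, n))
  reps <- bench$replicates
  props <- names(specs)
  vals <- lapply(specs, .property_values, cohort = cohort)
  per_query <- matrix(NA_real_, n, length(props),
                      dimnames = list(cohort$respondent_id, props))
  agree <- matrix(NA_real_, n, length(props), dimnames = dimnames(per_query))
  known <- matrix(NA_real_, n, length(props), dimnames = dimnames(per_query))
  with_seed(bench$seed, {
    for (i in seq_len(n)) {
      # reps draws of k distinct candidates, skipping the query itself
      draw <- vapply(seq_len(reps), function(r) sample.int(n - 1L, k), integer(k))
      draw <- draw + (draw >= i)   # shift past self
      for (p in seq_along(props)) {
        v <- vals[[p]]
        if (is.na(v[i])) next
        nb <- matrix(v[draw], nrow = k)
        kn <- !is.na(nb)
        ag <- kn & (nb == v[i])
        kc <- colSums(kn)
        acc <- ifelse(kc > 0, colSums(ag) / kc, NA_real_)
        per_query[i, p] <- mean(acc, na.rm = TRUE)
        agree[i, p] <- mean(colSums(ag))
        known[i, p] <- mean(kc)
      }
    }
  })
  .row_object("random", list(per_query = per_query, agree = agree, known = known),
              cohort, k, specs, benchmark = TRUE)
}

#' Compare two accordance rows on one property
#'
#' Three significance methods are available:
#'
#' * `"label-permutation"` (default): permutes the property labels over
#'   respondents while keeping each row's neighbor sets fixed, recomputing
#'   both rows' mean accordance per permutation (the benchmark row is
#'   replaced by its analytic expectation, which is invariant under label
#'   permutation). This is the exact null for "matching accordance above
#'   chance": because leave-one-out per-query accordances are cross-correlated
#'   through shared neighbors, it is the only one of the three whose type-I
#'   rate holds at the nominal level (see the methods vignette).
#' * `"permutation"`: a paired two-sided sign-flip test on the per-query
#'   accordance differences. With 12 or fewer informative queries the full
#'   set of sign assignments is enumerated exactly; otherwise `n_perm` seeded
#'   random flips are used, with the add-one Monte-Carlo estimator. Assumes
#'   independent queries, which the leave-one-out design violates mildly
#'   (anti-conservative).
#' * `"z"`: a pooled two-proportion z-test on match-level agreement counts —
#'   fastest, ignores both pairing and dependence.
#'
#' @param row_a,row_b `accordance_row` objects evaluated on the same cohort.
#' @param property One of the six property names.
#' @param method `"label-permutation"` (default), `"permutation"` or `"z"`.
#' @param n_perm Monte-Carlo permutations / sign flips.
#' @param seed Seed for the Monte-Carlo draws.
#' @param exact For the sign-flip method: force (`TRUE`) or forbid (`FALSE`)
#'   exhaustive enumeration; `NULL` (default) enumerates when at most 12
#'   paired queries remain.
#' @return A `comparison` list: `measure_a`, `measure_b`, `property`,
#'   `statistic` (difference of mean accordances, or the z statistic),
#'   `p_value`, `method`, `n_queries`.
#' @export
compare_rows <- function(row_a, row_b, property,
                         method = c("label-permutation", "permutation", "z"),
                         n_perm = 10000L, seed = 1L, exact = NULL) {
  method <- match.arg(method)
  if (!property %in% colnames(row_a$per_query))
    stop_data(paste0("unknown property: ", property))
  if (!identical(row_a$query_ids, row_b$query_ids))
    stop_data("accordance rows were not evaluated on the same queries")
  x <- row_a$per_query[, property]
  y <- row_b$per_query[, property]
  keep <- !is.na(x) & !is.na(y)
  d <- x[keep] - y[keep]
  m <- length(d)
  if (m == 0L) stop_data("no queries with known property in both rows")

  if (method == "label-permutation") {
    res <- .label_permutation_test(row_a, row_b, property, n_perm, seed)
  } else if (method == "permutation") {
    obs <- mean(d)
    eps <- 1e-12
    do_exact <- if (is.null(exact)) m <= 12L else isTRUE(exact)
    if (do_exact) {
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), m)))
      stat <- abs(signs %*% d) / m
      p <- mean(stat >= abs(obs) - eps)
    } else {
      stat <- with_seed(seed, {
        signs <- matrix(sample(c(-1, 1), m * n_perm, replace = TRUE), m, n_perm)
        abs(colSums(signs * d)) / m
      })
      p <- (1 + sum(stat >= abs(obs) - eps)) / (n_perm + 1)
    }
    res <- list(statistic = obs, p_value = p,
                method = if (do_exact) "permutation-exact" else "permutation")
  } else {
    x1 <- sum(row_a$agree[keep, property]); n1 <- sum(row_a$known[keep, property])
    x2 <- sum(row_b$agree[keep, property]); n2 <- sum(row_b$known[keep, property])
    p1 <- x1 / n1; p2 <- x2 / n2
    pp <- (x1 + x2) / (n1 + n2)
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    z <- if (se == 0) 0 else (p1 - p2) / se
    res <- list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)),
                method = "two-proportion-z")
  }
  structure(c(list(measure_a = row_a$name, measure_b = row_b$name,
                   property = property, n_queries = m), res),
            class = "comparison")
}

# statistic: difference of mean accordance; null: property labels permuted
# over respondents with both rows' neighbor index sets held fixed
.label_permutation_test <- function(row_a, row_b, property, n_perm, seed) {
  for (r in list(row_a, row_b)) {
    if (!isTRUE(r$benchmark) && is.null(r$idx))
      stop_data(paste0("row '", r$name, "' lacks neighbor indices; ",
                       "use method = 'permutation'"))
  }
  if (is.null(row_a$labels) || is.null(row_b$labels) ||
      !identical(row_a$labels[[property]], row_b$labels[[property]]))
    stop_data("accordance rows carry different property labels")
  z <- row_a$labels[[property]]
  row_stat <- function(row, zz) {
    if (isTRUE(row$benchmark)) .analytic_accordance(zz)
    else .mean_accordance(zz, row$idx)
  }
  obs <- row_stat(row_a, z) - row_stat(row_b, z)
  eps <- 1e-12
  # the analytic benchmark value depends on category counts only, so it is
  # constant across label permutations and can be hoisted out of the loop
  a_const <- if (isTRUE(row_a$benchmark)) .analytic_accordance(z) else NULL
  b_const <- if (isTRUE(row_b$benchmark)) .analytic_accordance(z) else NULL
  stat <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    zb <- sample(z)
    sa <- if (is.null(a_const)) .mean_accordance(zb, row_a$idx) else a_const
    sb <- if (is.null(b_const)) .mean_accordance(zb, row_b$idx) else b_const
    sa - sb
  }, 0))
  p <- (1 + sum(abs(stat) >= abs(obs) - eps)) / (n_perm + 1)
  list(statistic = obs, p_value = p, method = "label-permutation")
}

#' Full accordance table with benchmark comparisons
#'
#' Evaluates every requested measure plus the pseudorandom benchmark,
#' assembles the per-measure, per-property mean accordance table (percent),
#' flags per property the best-performing measure(s) as the positive
#' benchmark, and (optionally) computes significance of every measure against
#' both benchmarks.
#'
#' @param cohort A cohort data frame.
#' @param measures Character vector of measure names; default all 24.
#' @param k Matches per query.
#' @param bench A [benchmark_config()].
#' @param specs Property specifications from [property_specs()].
#' @param exponent Minkowski exponent.
#' @param tie_rule,seed Passed to [match_config()].
#' @param pvalues Compute comparisons against the benchmarks (default `TRUE`).
#' @param method,n_perm Passed to [compare_rows()].
#' @return An `accordance_table` list: `table` (data frame, one row per
#'   measure plus `"random"`, columns `measure`, `family` and the six
#'   properties in percent), `positive_benchmark` (per property, the best
#'   measure name(s), ties flagged jointly), `comparisons` (data frame of
#'   p-values vs the negative and positive benchmark, if requested) and
#'   `rows` (the underlying `accordance_row` objects).
#' @export
build_table <- function(cohort, measures = list_measures()$name, k = 10L,
                        bench = benchmark_config(), specs = property_specs(),
                        exponent = 1, tie_rule = "stable", seed = 1L,
                        pvalues = TRUE, method = "label-permutation",
                        n_perm = 10000L) {
  validate_cohort(cohort)
  rows <- lapply(measures, function(m)
    evaluate_measure(cohort, match_config(measure = m, k = k, exponent = exponent,
                                          tie_rule = tie_rule, seed = seed),
                     specs = specs))
  names(rows) <- vapply(rows, `[[`, "", "name")
  rnd <- random_benchmark(cohort, k = k, bench = bench, specs = specs)
  rows$random <- rnd

  fam <- c(stats::setNames(.MEASURES$family, .MEASURES$name),
           random = "(Pseudo)random sampling")
  tab <- data.frame(
    measure = names(rows),
    family = unname(fam[names(rows)]),
    do.call(rbind, lapply(rows, `[[`, "percent")),
    stringsAsFactors = FALSE, row.names = NULL, check.names = FALSE
  )

  props <- names(specs)
  measure_rows <- setdiff(names(rows), "random")
  pos <- lapply(props, function(p) {
    v <- vapply(rows[measure_rows], function(r) r$percent[[p]], 0)
    names(v)[abs(v - max(v)) < 1e-9]
  })
  names(pos) <- props

  comparisons <- NULL
  if (pvalues) {
    cmp <- list()
    for (p in props) {
      best <- rows[[pos[[p]][1]]]
      for (m in measure_rows) {
        cn <- compare_rows(rows[[m]], rnd, p, method = method,
                           n_perm = n_perm, seed = seed)
        cmp[[length(cmp) + 1L]] <- data.frame(
          measure = m, property = p, versus = "negative",
          statistic = cn$statistic, p_value = cn$p_value,
          method = cn$method, stringsAsFactors = FALSE)
        cp <- compare_rows(rows[[m]], best, p, method = method,
                           n_perm = n_perm, seed = seed)
        cmp[[length(cmp) + 1L]] <- data.frame(
          measure = m, property = p, versus = "positive",
          statistic = cp$statistic, p_value = cp$p_value,
          method = cp$method, stringsAsFactors = FALSE)
      }
    }
    comparisons <- do.call(rbind, cmp)
  }
  structure(list(table = tab, positive_benchmark = pos,
                 comparisons = comparisons, rows = rows, k = k),
            class = "accordance_table")
}

#' @export
print.accordance_table <- function(x, ...) {
  tab <- x$table
  tab[.PROPERTY_NAMES] <- lapply(tab[.PROPERTY_NAMES], round, 1)
  cat(sprintf("Leave-one-out matching accordance (percent), k = %d, n = %d\n\n",
              x$k, x$rows[[1]]$n))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Analytic expectation of random-matching accordance
#'
#' Closed-form expectation of the accordance achieved by drawing k distinct
#' non-self matches uniformly at random, for a categorical (or binned)
#' property with category sizes n_c in a cohort of size n containing u
#' respondents whose property value is unknown:
#' \deqn{E = \sum_c \frac{n_c}{n - u} \cdot \frac{n_c - 1}{n - 1 - u} \times 100.}
#' With no unknowns this reduces to \eqn{\sum_c n_c(n_c-1)/(n(n-1)) \times 100}.
#' The expectation is independent of k because the per-query accordance is a
#' ratio over the known matches drawn.
#'
#' @param cohort A cohort data frame.
#' @param property One of the six property names.
#' @param specs Property specifications from [property_specs()].
#' @return Expected accordance in percent.
#' @export
expected_random_accordance <- function(cohort, property = "exact_diagnosis",
                                       specs = property_specs()) {
  spec <- .get_spec(property, specs)
  vals <- .property_values(cohort, spec)
  n <- length(vals)
  u <- sum(is.na(vals))
  if (n - 1L - u <= 0L) stop_data("not enough respondents with known property")
  tab <- table(vals[!is.na(vals)])
  sum((tab / (n - u)) * ((tab - 1) / (n - 1 - u))) * 100
}
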