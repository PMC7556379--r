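#' Matching configuration
#'
#' @param measure Measure name (case-insensitive, see [list_measures()]).
#' @param k Number of matches to return per query (default 10, the list size
#'   chosen as a compromise between offering enough candidates and not
#'   overwhelming the searching user). Must satisfy `1 <= k < n`.
#' @param exponent Minkowski exponent (default 1).
#' @param tie_rule How candidates tied at the k-th distance are ordered:
#'   `"stable"` (default) keeps the cohort input order, fully deterministic;
#'   `"random"` breaks ties pseudorandomly under `seed`. Aliases
#'   `"stable-by-input-order"` and `"random-with-seed"` are accepted.
#' @param seed Integer seed driving the random tie rule.
#' @param normalize Normalize answer vectors to unit sum before the distance
#'   formula (default `FALSE`, i.e. raw codes).
#' @return A `match_config` list used by [find_matches()] and the evaluation
#'   harness.
#' @export
match_config <- function(measure = "Manhattan", k = 10L, exponent = 1,
                         tie_rule = c("stable", "random",
                                      "stable-by-input-order", "random-with-seed"),
                         seed = 1L, normalize = FALSE) {
  tie_rule <- match.arg(tie_rule)
  tie_rule <- if (startsWith(tie_rule, "random")) "random" else "stable"
  key <- .measure_key(measure)  # validates the name
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop_usage("k must be a positive integer")
  structure(list(measure = .MEASURES$name[.MEASURES$key == key], k = k,
                 exponent = exponent, tie_rule = tie_rule,
                 seed = as.integer(seed), normalize = normalize),
            class = "match_config")
}

# leave-one-out k-NN over the answer matrix `a`; returns list(idx, dist):
# n x k matrices of neighbor row indices and their distances
.knn_all <- function(a, config) {
  n <- nrow(a)
  k <- config$k
  if (k >= n) stop_usage(sprintf("k (%d) must be smaller than the cohort size (%d)", k, n))
  idx <- matrix(0L, n, k)
  dst <- matrix(NA_real_, n, k)
  tie_key <- if (config$tie_rule == "random")
    with_seed(config$seed, sample.int(n)) else seq_len(n)
  for (i in seq_len(n)) {
    d <- dist_to_all(config$measure, a[i, ], a, exponent = config$exponent,
                     normalize = config$normalize)
    d[i] <- Inf  # leave-one-out: the query is never its own candidate
    ord <- order(d, tie_key[seq_len(n)])[seq_len(k)]
    idx[i, ] <- ord
    dst[i, ] <- d[ord]
  }
  list(idx = idx, dist = dst)
}

.match_df <- function(query_id, ids, dist) {
  data.frame(query_id = query_id, rank = seq_along(ids), match_id = ids,
             distance = dist, stringsAsFactors = FALSE, row.names = NULL)
}

#' Find the k nearest matches for one respondent
#'
#' Brute-force scan of all other cohort members under the configured measure:
#' the query's distance to every candidate is computed, the query itself is
#' excluded (leave-one-out), and the `k` smallest distances are returned in
#' non-decreasing order. For the cosine coefficient "smallest" means least
#' similar; the value is minimized exactly as registered.
#'
#' @param cohort A cohort data frame.
#' @param query_id A respondent id present in the cohort.
#' @param config A [match_config()].
#' @return A data frame with columns `query_id`, `rank` (1..k), `match_id`,
#'   `distance`, distances non-decreasing.
#' @export
find_matches <- function(cohort, query_id, config = match_config()) {
  a <- answer_matrix(cohort)
  i <- match(query_id, rownames(a))
  if (is.na(i)) stop_data(paste0("unknown query id: ", query_id))
  n <- nrow(a)
  if (config$k >= n)
    stop_usage(sprintf("k (%d) must be smaller than the cohort size (%d)", config$k, n))
  d <- dist_to_all(config$measure, a[i, ], a, exponent = config$exponent,
                   normalize = config$normalize)
  d[i] <- Inf
  tie_key <- if (config$tie_rule == "random")
    with_seed(config$seed, sample.int(n)) else seq_len(n)
  ord <- order(d, tie_key)[seq_len(config$k)]
  .match_df(query_id, rownames(a)[ord], d[ord])
}

#' Find matches for every respondent (leave-one-out)
#'
#' Runs [find_matches()] for every respondent in turn; each query's candidate
#' pool is the remaining n - 1 respondents.
#'
#' @inheritParams find_matches
#' @return A named list (one element per respondent, in cohort order) of
#'   match data frames as returned by [find_matches()].
#' @export
find_all_matches <- function(cohort, config = match_config()) {
  a <- answer_matrix(cohort)
  nn <- .knn_all(a, config)
  ids <- rownames(a)
  out <- lapply(seq_len(nrow(a)), function(i)
    .match_df(ids[i], ids[nn$idx[i, ]], nn$dist[i, ]))
  names(out) <- ids
  out
}
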