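#' @title Distance and similarity measures for answer vectors
#' @description
#' The matching core compares two 53-dimensional answer vectors P and Q
#' (coded answers, all entries >= 1) under 24 measures drawn from eight
#' mathematical families of the classical distance/similarity taxonomy:
#' Minkowski (Lp), L1, intersection, inner product, fidelity/squared-chord,
#' squared L2 (chi-square-like), Shannon entropy, and combined forms.
#'
#' All measures are oriented so that the matcher always *minimizes* the
#' returned value. Cosine is a similarity coefficient and is deliberately
#' registered (and minimized) as-is — minimizing it selects maximally
#' dissimilar respondents, a documented anomaly of this measure set that the
#' evaluation harness reproduces. A corrected `cosine_distance` (1 - cosine)
#' is available under its own name but is not one of the 24 registered
#' measures.
#'
#' The probability-distribution measures (Bhattacharyya, Hellinger,
#' Squared-Chord and the entropy family) are applied to the raw answer codes
#' without normalization by default; `normalize = TRUE` rescales both vectors
#' to unit sum first.
#' @name metrics
NULL

# rowwise measure kernels: pm and qm are m x d matrices, pm the query P
# replicated over rows, qm the candidates Q; each returns a length-m vector.
.row_max <- function(m) m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]

.MEASURE_FUNS <- list(
  manhattan      = function(pm, qm, ex) rowSums(abs(pm - qm)),
  euclidean      = function(pm, qm, ex) sqrt(rowSums((pm - qm)^2)),
  minkowski      = function(pm, qm, ex) rowSums(abs(pm - qm)^ex)^(1 / ex),
  sorensen       = function(pm, qm, ex) rowSums(abs(pm - qm)) / rowSums(pm + qm),
  gower          = function(pm, qm, ex) rowSums(abs(pm - qm)) / ncol(pm),
  canberra       = function(pm, qm, ex) rowSums(abs(pm - qm) / (pm + qm)),
  lorentzian     = function(pm, qm, ex) rowSums(log1p(abs(pm - qm))),
  wavehedges     = function(pm, qm, ex) rowSums(abs(pm - qm) / pmax(pm, qm)),
  czekanowski    = function(pm, qm, ex) rowSums(abs(pm - qm)) / rowSums(pm + qm),
  tanimoto       = function(pm, qm, ex) rowSums(pmax(pm, qm) - pmin(pm, qm)) / rowSums(pmax(pm, qm)),
  jaccard        = function(pm, qm, ex) rowSums((pm - qm)^2) /
                     (rowSums(pm^2) + rowSums(qm^2) - rowSums(pm * qm)),
  dice           = function(pm, qm, ex) rowSums((pm - qm)^2) / (rowSums(pm^2) + rowSums(qm^2)),
  cosine         = function(pm, qm, ex) rowSums(pm * qm) /
                     (sqrt(rowSums(pm^2)) * sqrt(rowSums(qm^2))),
  bhattacharyya  = function(pm, qm, ex) -log(rowSums(sqrt(pm * qm))),
  hellinger      = function(pm, qm, ex) sqrt(2 * rowSums((sqrt(pm) - sqrt(qm))^2)),
  squaredchord   = function(pm, qm, ex) rowSums((sqrt(pm) - sqrt(qm))^2),
  neyman         = function(pm, qm, ex) rowSums((pm - qm)^2 / pm),
  probabilisticsymmetric = function(pm, qm, ex) 2 * rowSums((pm - qm)^2 / (pm + qm)),
  clark          = function(pm, qm, ex) sqrt(rowSums(((pm - qm) / (pm + qm))^2)),
  additivesymmetric = function(pm, qm, ex) rowSums((pm - qm)^2 * (pm + qm) / (pm * qm)),
  jeffreys       = function(pm, qm, ex) rowSums((pm - qm) * log(pm / qm)),
  jensendifference = function(pm, qm, ex)
    rowSums((pm * log(pm) + qm * log(qm)) / 2 - ((pm + qm) / 2) * log((pm + qm) / 2)),
  kumarjohnson   = function(pm, qm, ex) rowSums((pm^2 - qm^2)^2 / (2 * (pm * qm)^1.5)),
  avg            = function(pm, qm, ex) {
    ad <- abs(pm - qm)
    (rowSums(ad) + .row_max(ad)) / 2
  }
)

.MEASURES <- data.frame(
  key = c("manhattan", "euclidean", "minkowski",
          "sorensen", "gower", "canberra", "lorentzian",
          "wavehedges", "czekanowski", "tanimoto", "jaccard", "dice",
          "cosine",
          "bhattacharyya", "hellinger", "squaredchord",
          "neyman", "probabilisticsymmetric", "clark", "additivesymmetric",
          "jeffreys", "jensendifference",
          "kumarjohnson", "avg"),
  name = c("Manhattan", "Euclidean", "Minkowski",
           "S\u00f8rensen", "Gower", "Canberra", "Lorentzian",
           "Wave Hedges", "Czekanowski", "Tanimoto", "Jaccard", "Dice",
           "Cosine",
           "Bhattacharyya", "Hellinger", "Squared-Chord",
           "Neyman", "Probabilistic Symmetric", "Clark", "Additive Symmetric",
           "Jeffreys", "Jensen difference",
           "Kumar-Johnson", "Avg"),
  family = c(rep("Lp Minkowski", 3), rep("L1", 4), rep("Intersection", 5),
             "Inner product", rep("Fidelity/Squared-chord", 3),
             rep("Squared L2", 4), rep("Shannon entropy", 2),
             rep("Combined", 2)),
  symmetric = TRUE,
  orientation = "distance",
  stringsAsFactors = FALSE
)
.MEASURES$symmetric[.MEASURES$key == "neyman"] <- FALSE
.MEASURES$orientation[.MEASURES$key == "cosine"] <- "similarity-used-as-distance"
# self-distance d(P, P): 0 for every measure except the two registry exceptions
.MEASURES$self_value <- ifelse(.MEASURES$key == "cosine", 1, 0)
.MEASURES$self_value[.MEASURES$key == "bhattacharyya"] <- NA  # -log(sum P), vector-dependent

.normalize_measure_name <- function(name) {
  x <- tolower(trimws(name))
  x <- gsub("\u00f8", "o", x)
  x <- gsub("\u2013", "-", x)
  x <- gsub("[ _-]+", "", x)
  x[x == "probsymmetric"] <- "probabilisticsymmetric"
  x[x %in% c("average", "avg")] <- "avg"
  x
}

.measure_key <- function(measure) {
  key <- .normalize_measure_name(measure)
  if (length(key) != 1L || !key %in% .MEASURES$key)
    stop_usage(paste0("unknown measure '", measure, "'; valid measures are: ",
                      paste(.MEASURES$name, collapse = ", ")))
  key
}

#' List the registered distance measures
#'
#' @return A data frame of the 24 registered measures with columns `name`
#'   (canonical, matched case-insensitively everywhere a measure is selected),
#'   `family` (one of 8 families), `symmetric` (`FALSE` only for Neyman) and
#'   `orientation` (`"distance"`, or `"similarity-used-as-distance"` for
#'   cosine, which the matcher minimizes as-is).
#' @examples
#' m <- list_measures()
#' nrow(m)                  # 24
#' length(unique(m$family)) # 8
#' @export
list_measures <- function() {
  .MEASURES[c("name", "family", "symmetric", "orientation")]
}

#' Export the measure registry as JSON
#'
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
measures_json <- function(path = NULL) {
  js <- jsonlite::toJSON(list_measures(), dataframe = "rows", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

.check_vectors <- function(p, q) {
  if (length(p) != length(q))
    stop_data(sprintf("answer vectors of unequal length (%d vs %d)",
                      length(p), length(q)))
  if (any(p <= 0) || any(q <= 0))
    stop_data("answer vectors must have strictly positive entries")
}

# distance from query vector p to every row of the candidate matrix qmat;
# the asymmetric Neyman measure uses the query as its reference (P) term
dist_to_all <- function(measure, p, qmat, exponent = 1, normalize = FALSE) {
  key <- .measure_key(measure)
  if (!is.matrix(qmat)) qmat <- matrix(qmat, nrow = 1)
  if (length(p) != ncol(qmat))
    stop_data(sprintf("answer vectors of unequal length (%d vs %d)",
                      length(p), ncol(qmat)))
  if (any(p <= 0) || any(qmat <= 0))
    stop_data("answer vectors must have strictly positive entries")
  if (key == "minkowski" && (!is.numeric(exponent) || exponent <= 0))
    stop_data("Minkowski exponent must be positive")
  if (normalize) {
    p <- p / sum(p)
    qmat <- qmat / rowSums(qmat)
  }
  pm <- matrix(p, nrow = nrow(qmat), ncol = length(p), byrow = TRUE)
  .MEASURE_FUNS[[key]](pm, qmat, exponent)
}

#' Compute one distance between two answer vectors
#'
#' Evaluates a registered measure on the raw coded answers P and Q
#' (the query and a candidate). All valid answer codes are >= 1, so every
#' denominator and logarithm in the formula set is well defined.
#'
#' @param measure Measure name (case-insensitive; see [list_measures()]).
#' @param p,q Numeric vectors of equal length with strictly positive entries.
#' @param exponent Minkowski exponent, used only by the Minkowski measure
#'   (default 1, which makes it rank-equivalent to Manhattan and Gower).
#' @param normalize If `TRUE`, rescale both vectors to unit sum before
#'   applying the formula (off by default; the registered usage operates on
#'   raw codes).
#' @return A single finite numeric value. For measures flagged symmetric the
#'   value is invariant under swapping `p` and `q`; Neyman is asymmetric and
#'   uses `p` (the query) in its denominator.
#' @examples
#' compute_distance("Manhattan", c(1, 2, 3, 4), c(4, 3, 2, 1))  # 8
#' compute_distance("Euclidean", c(1, 1), c(4, 5))              # 5
#' @export
compute_distance <- function(measure, p, q, exponent = 1, normalize = FALSE) {
  .check_vectors(p, q)
  as.numeric(dist_to_all(measure, p, matrix(q, nrow = 1), exponent = exponent,
                         normalize = normalize))
}

#' Corrected cosine distance (not among the 24 registered measures)
#'
#' `1 - cosine(P, Q)`: zero for parallel vectors, so *minimizing* it matches
#' similar respondents, unlike the registered cosine coefficient.
#'
#' @inheritParams compute_distance
#' @return A single numeric value in `[0, 1]` for positive vectors.
#' @export
cosine_distance <- function(p, q) {
  1 - compute_distance("cosine", p, q)
}

#' All pairwise distances within a cohort
#'
#' @param measure Measure name.
#' @param cohort A cohort data frame, or an answer matrix (rows respondents).
#' @inheritParams compute_distance
#' @return An n x n matrix, dimnames the respondent ids; entry `(i, j)` is the
#'   distance from query i to candidate j. Symmetric for all measures except
#'   Neyman; the diagonal holds each measure's self-distance (0, or 1 for
#'   cosine, or `-log(sum(P))` for Bhattacharyya).
#' @export
pairwise_distances <- function(measure, cohort, exponent = 1, normalize = FALSE) {
  a <- if (is.matrix(cohort)) cohort else answer_matrix(cohort)
  n <- nrow(a)
  if (n < 2L) stop_data("pairwise distances need at least 2 respondents")
  out <- matrix(0, n, n, dimnames = list(rownames(a), rownames(a)))
  for (i in seq_len(n))
    out[i, ] <- dist_to_all(measure, a[i, ], a, exponent = exponent,
                            normalize = normalize)
  out
}
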