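# Hand-built random cohorts, independent of the package's synthetic generator,
# for exercising I/O, matching and evaluation on arbitrary valid data.
make_cohort <- function(n, n_diag = 4, seed = 1, answers_max = 5L) {
  set.seed(seed)
  diag <- sample(paste0("diag-", seq_len(n_diag)), n, replace = TRUE)
  ans <- matrix(sample.int(answers_max, n * 53L, replace = TRUE), n, 53L)
  df <- data.frame(
    respondent_id = sprintf("S%03d", seq_len(n)),
    age = sample(0:87, n, replace = TRUE),
    gender = sample(c("female", "male"), n, replace = TRUE),
    latency_years = ifelse(runif(n) < 0.1, NA_real_, round(rgamma(n, 2, 0.5), 1)),
    disease_group = paste0("group-", match(diag, unique(diag)) %% 3 + 1),
    diagnostic_system = "RD",
    exact_diagnosis = diag,
    stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(ans))
  names(df) <- q53match::cohort_columns()
  df
}

# a cohort whose rows are all clones of one answer vector
make_clone_cohort <- function(n, seed = 1) {
  co <- make_cohort(n, n_diag = 1, seed = seed)
  a <- as.integer(co[1, sprintf("q%02d", 1:53)])
  for (j in seq_len(53)) co[[sprintf("q%02d", j)]] <- a[j]
  co
}

# Direct scalar evaluation of every registered formula, written from the
# formula table (sum/max over coordinates) independently of the package's
# vectorized kernels. Names are the canonical registry names.
oracle_dist <- function(name, p, q, ex = 1) {
  switch(name,
    "Manhattan"    = sum(abs(p - q)),
    "Euclidean"    = sqrt(sum((p - q)^2)),
    "Minkowski"    = (sum(abs(p - q)^ex))^(1 / ex),
    "S\u00f8rensen" = sum(abs(p - q)) / sum(p + q),
    "Gower"        = (1 / length(p)) * sum(abs(p - q)),
    "Canberra"     = sum(abs(p - q) / (p + q)),
    "Lorentzian"   = sum(log(1 + abs(p - q))),
    "Wave Hedges"  = sum(abs(p - q) / pmax(p, q)),
    "Czekanowski"  = sum(abs(p - q)) / sum(p + q),
    "Tanimoto"     = sum(pmax(p, q) - pmin(p, q)) / sum(pmax(p, q)),
    "Jaccard"      = sum((p - q)^2) / (sum(p^2) + sum(q^2) - sum(p * q)),
    "Dice"         = sum((p - q)^2) / (sum(p^2) + sum(q^2)),
    "Cosine"       = sum(p * q) / (sqrt(sum(p^2)) * sqrt(sum(q^2))),
    "Bhattacharyya" = -log(sum(sqrt(p * q))),
    "Hellinger"    = sqrt(2 * sum((sqrt(p) - sqrt(q))^2)),
    "Squared-Chord" = sum((sqrt(p) - sqrt(q))^2),
    "Neyman"       = sum((p - q)^2 / p),
    "Probabilistic Symmetric" = 2 * sum((p - q)^2 / (p + q)),
    "Clark"        = sqrt(sum((abs(p - q) / (p + q))^2)),
    "Additive Symmetric" = sum((p - q)^2 * (p + q) / (p * q)),
    "Jeffreys"     = sum((p - q) * log(p / q)),
    "Jensen difference" = sum((p * log(p) + q * log(q)) / 2 -
                              ((p + q) / 2) * log((p + q) / 2)),
    "Kumar-Johnson" = sum((p^2 - q^2)^2 / (2 * (p * q)^1.5)),
    "Avg"          = (sum(abs(p - q)) + max(abs(p - q))) / 2,
    stop("no oracle for measure ", name)
  )
}

# measures the non-negativity invariant applies to (all except the cosine
# coefficient, Bhattacharyya on raw codes, and Jeffreys)
NONNEG_MEASURES <- setdiff(q53match::list_measures()$name,
                           c("Cosine", "Bhattacharyya", "Jeffreys"))

random_answers <- function(d = 53L) sample.int(5L, d, replace = TRUE)

expect_cohorts_equal <- function(a, b) {
  attr(a, "provenance") <- NULL
  attr(b, "provenance") <- NULL
  rownames(a) <- NULL
  rownames(b) <- NULL
  expect_identical(a, b)
}
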