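# small record-set builder used across tests
make_rs <- function(r, n = NA_integer_, sig = NA_character_,
                    location = NA_character_, year = NA_integer_,
                    df = NA_integer_, ...) {
  as_record_set(tibble::tibble(r = r, n = n, sig_label = sig,
                               location = location, year = year, df = df, ...))
}

# fast vectorised sample correlations of null bivariate-normal data
simulate_null_r <- function(n, reps) {
  x <- matrix(stats::rnorm(n * reps), n)
  y <- matrix(stats::rnorm(n * reps), n)
  sx <- colSums(x); sy <- colSums(y)
  (colSums(x * y) - sx * sy / n) /
    sqrt((colSums(x^2) - sx^2 / n) * (colSums(y^2) - sy^2 / n))
}

# data-level Monte-Carlo power (the oracle the exact integral is checked against)
mc_power <- function(rho, n, reps, alpha = 0.05) {
  x <- matrix(stats::rnorm(n * reps), n)
  y <- rho * x + sqrt(1 - rho^2) * matrix(stats::rnorm(n * reps), n)
  sx <- colSums(x); sy <- colSums(y)
  r <- (colSums(x * y) - sx * sy / n) /
    sqrt((colSums(x^2) - sx^2 / n) * (colSums(y^2) - sy^2 / n))
  mean(abs(r) >= critical_r(n - 2, alpha))
}
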