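# Shared fixture builders for the test-suite.

# Small random regression problem with reproducible seed.
random_problem <- function(seed, n = 20L, p = 3L, noise_sd = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  beta <- rnorm(p, 0, 2)
  y <- 1.5 + drop(X %*% beta) + rnorm(n, 0, noise_sd)
  list(X = X, y = y, beta = beta)
}

# A ranked screen laid out explicitly from a logical activity pattern
# (first entry = best-ranked ligand).
screen_from_pattern <- function(pattern) {
  n <- length(pattern)
  ranked_screen(sprintf("lig_%03d", seq_len(n)), seq(n, 1), pattern)
}

# The perfect 22-active / 6-decoy screen.
perfect_screen_22_28 <- function() {
  screen_from_pattern(rep(c(TRUE, FALSE), c(22L, 6L)))
}

# Brute-force ROC AUC: pairwise active-vs-decoy comparisons with 0.5 for
# score ties.  Independent of the rank-based implementation.
bruteforce_auc <- function(screen) {
  e <- screen$entries
  a <- e$score[e$active]
  d <- e$score[!e$active]
  total <- 0
  for (sa in a) total <- total + sum(sa > d) + 0.5 * sum(sa == d)
  total / (length(a) * length(d))
}

# Brute-force AUAC by integrating the step accumulation function.
bruteforce_auac <- function(screen) {
  e <- screen$entries
  N <- nrow(e)
  found <- cumsum(e$active) / sum(e$active)
  # trapezoid over the piecewise-linear curve through (i/N, found_i)
  x <- c(0, seq_len(N) / N)
  yv <- c(0, found)
  total <- 0
  for (i in seq_len(N)) {
    total <- total + (x[i + 1] - x[i]) * (yv[i] + yv[i + 1]) / 2
  }
  total
}

fixture_path <- function(...) test_path("fixtures", ...)
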