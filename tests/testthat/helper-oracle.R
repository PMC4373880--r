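# Brute-force regression-SS oracle: builds the subject-level design matrix
# explicitly and projects y onto it with an explicit hat matrix. Independent
# of the package's cell-mean weighted-normal-equations path.

oracle_codes <- function(data, coding) {
  codes <- if (coding == "treatment") c(C = 0, T = 1) else c(C = -1, T = 1)
  a <- unname(codes[as.character(data$a)])
  b <- unname(codes[as.character(data$b)])
  cbind(a = a, b = b, ab = a * b)
}

oracle_rss <- function(data, predictors, coding) {
  X <- cbind(1, oracle_codes(data, coding)[, predictors, drop = FALSE])
  P <- X %*% solve(crossprod(X)) %*% t(X)
  yhat <- as.vector(P %*% data$y)
  sum((yhat - mean(data$y))^2)
}

oracle_all_rss <- function(data, coding) {
  subsets <- list(A = "a", B = "b", I = "ab", AB = c("a", "b"),
                  AI = c("a", "ab"), BI = c("b", "ab"),
                  ABI = c("a", "b", "ab"))
  vapply(subsets, function(s) oracle_rss(data, s, coding), numeric(1))
}

# a random small unbalanced sample with random effect sizes
random_sample <- function(seed) {
  withr::with_seed(seed, {
    d <- sample(2:6, 4, replace = TRUE)
    spec <- effect_spec(beta0 = rnorm(1, 10, 3), beta1 = rnorm(1, 0, 4),
                        beta2 = rnorm(1, 0, 4), beta3 = rnorm(1, 0, 4),
                        sigma = runif(1, 2, 12),
                        construction = sample(c("zero_control",
                                                "equal_contribution"), 1))
    generate_sample(d, spec, seed = seed + 1L)
  })
}

# noise-free balanced toy: cell means (10, 14, 14, 22), two subjects per cell
toy_sample <- function() {
  generate_sample(c(2, 2, 2, 2), effect_spec(beta3 = 4, sigma = 0))
}

effect_rows <- function(tbl) tbl[tbl$term != "Residuals", ]
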