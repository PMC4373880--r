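#' Specify the data-generating model for a 2x2 experiment
#'
#' Outcomes are generated from the linear model
#' `Y = beta0 + beta1 * A + beta2 * B + beta3 * A * B + e`, with
#' `e ~ N(0, sigma^2)`, where the numeric values substituted for the factor
#' levels depend on the effect-construction method:
#'
#' * `"zero_control"` substitutes (0, 1): control groups contribute nothing
#'   to the outcome (a no-treatment control), and a multiplicative
#'   interaction raises only the cell where both treatments are given.
#' * `"equal_contribution"` substitutes (-1, 1): control and treatment
#'   groups make equal but opposite contributions, and the interaction
#'   contrasts the concordant diagonal cells with the discordant ones.
#'
#' The interaction code is always the product of the two factor codes. The
#' construction is a property of the simulated world, not of the analysis:
#' generated samples store abstract levels (`C`/`T`) and the analysis coding
#' is chosen later.
#'
#' @param beta0 Intercept (outcome units).
#' @param beta1,beta2 Main-effect coefficients.
#' @param beta3 Interaction coefficient.
#' @param sigma Residual standard deviation (>= 0; 0 gives noise-free data,
#'   useful for checking expected cell means).
#' @param construction Effect-construction method (see Details).
#' @return An object of class `effect_spec`.
#' @examples
#' effect_spec(beta3 = 4)
#' effect_spec(beta3 = 8, construction = "equal_contribution")
#' @export
effect_spec <- function(beta0 = 10, beta1 = 4, beta2 = 4, beta3 = 0, sigma = 10,
                        construction = c("zero_control", "equal_contribution")) {
  construction <- match.arg(construction)
  for (nm in c("beta0", "beta1", "beta2", "beta3", "sigma")) {
    v <- get(nm)
    if (length(v) != 1L || !is.numeric(v) || is.na(v)) {
      abort(paste0("`", nm, "` must be a single number."))
    }
  }
  if (sigma < 0) abort("`sigma` must be non-negative.")
  structure(
    list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
         sigma = sigma, construction = construction),
    class = "effect_spec"
  )
}

#' @export
print.effect_spec <- function(x, ...) {
  cat("<effect_spec> Y = b0 + b1*A + b2*B + b3*A*B + e\n")
  cat(sprintf("  b0 = %g, b1 = %g, b2 = %g, b3 = %g, sigma = %g\n",
              x$beta0, x$beta1, x$beta2, x$beta3, x$sigma))
  codes <- if (x$construction == "zero_control") "(0, 1)" else "(-1, 1)"
  cat(sprintf("  construction: %s, codes %s\n", x$construction, codes))
  invisible(x)
}

# generation codes per construction: value for control, value for treatment
.construction_codes <- function(construction) {
  if (construction == "zero_control") c(0, 1) else c(-1, 1)
}

# noise-free cell means in cell order (0,0), (0,1), (1,0), (1,1)
.mu_vec <- function(spec) {
  cc <- .construction_codes(spec$construction)
  a <- cc[c(1, 1, 2, 2)]
  b <- cc[c(1, 2, 1, 2)]
  spec$beta0 + spec$beta1 * a + spec$beta2 * b + spec$beta3 * a * b
}

#' Expected cell means under an effect specification
#'
#' Evaluates the generating model without noise in each of the four cells,
#' using the numeric codes implied by the spec's construction method. E.g.
#' with all betas (10, 4, 4, 4) the zero-control construction gives cell
#' means (10, 14, 14, 22) while the equal-contribution construction gives
#' (6, 6, 6, 22): the two worlds are not affine relabellings of one another
#' once an interaction is present.
#'
#' @param spec An [effect_spec()].
#' @return A four-row tibble with factor levels, generation codes and the
#'   expected mean `mu`, in cell order (C,C), (C,T), (T,C), (T,T).
#' @examples
#' cell_means(effect_spec(beta3 = 4))
#' @export
cell_means <- function(spec) {
  stopifnot(inherits(spec, "effect_spec"))
  cc <- .construction_codes(spec$construction)
  tibble(
    a = factor(c("C", "C", "T", "T"), levels = c("C", "T")),
    b = factor(c("C", "T", "C", "T"), levels = c("C", "T")),
    code_a = cc[c(1, 1, 2, 2)],
    code_b = cc[c(1, 2, 1, 2)],
    mu = .mu_vec(spec)
  )
}

# normalize a design argument to an integer vector (n00, n01, n10, n11)
.as_design <- function(design) {
  if (is.data.frame(design)) {
    need <- c("n00", "n01", "n10", "n11")
    if (nrow(design) != 1L || !all(need %in% names(design))) {
      abort("A data-frame `design` must be a single row with columns n00, n01, n10, n11.")
    }
    design <- unlist(design[1, need])
  }
  if (!is.numeric(design) || length(design) != 4L || anyNA(design) ||
      any(design != round(design))) {
    abort("`design` must be four integer cell counts (n00, n01, n10, n11).")
  }
  if (any(design < 2)) {
    abort("Every cell needs at least 2 subjects so that each cell has variance.")
  }
  setNames(as.integer(design), c("n00", "n01", "n10", "n11"))
}

# 31-bit polynomial string hash; derives independent, reproducible seed
# streams for every (design, beta3, construction, replicate) combination
.derive_seed <- function(base, key) {
  h <- as.double(base) %% 2147483647
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

.cell_levels <- function(d) {
  tibble(
    a = factor(rep(c("C", "C", "T", "T"), d), levels = c("C", "T")),
    b = factor(rep(c("C", "T", "C", "T"), d), levels = c("C", "T"))
  )
}

#' Generate one simulated 2x2 sample
#'
#' Draws, for each cell, that cell's count of outcomes as the expected cell
#' mean plus independent normal noise with standard deviation `spec$sigma`.
#' Levels are stored abstractly as `C`/`T`; pick the analysis coding later
#' with [nested_fits()] or [anova_2x2()].
#'
#' @param design Cell counts: a numeric vector `(n00, n01, n10, n11)` or a
#'   one-row data frame with those columns (see [study_designs()]).
#' @param spec An [effect_spec()].
#' @param seed Optional integer seed; the global RNG state is left untouched.
#' @return A tibble with columns `a`, `b` (factors `C`/`T`) and `y`.
#' @examples
#' generate_sample(c(30, 30, 30, 30), effect_spec(beta3 = 4), seed = 1)
#' @export
generate_sample <- function(design, spec, seed = NULL) {
  stopifnot(inherits(spec, "effect_spec"))
  d <- .as_design(design)
  mu <- .mu_vec(spec)
  draw <- function() unlist(lapply(1:4, function(j) rnorm(d[j], mu[j], spec$sigma)))
  y <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- .cell_levels(d)
  out$y <- y
  attr(out, "design") <- d
  attr(out, "spec") <- spec
  out
}

#' Generate a paired unbalanced/balanced sample sharing subjects
#'
#' To compare an unbalanced design with its balanced counterpart of the same
#' total size without extra Monte-Carlo noise, both samples are filled from
#' the same simulated subjects as far as possible: per cell a pool of
#' `max(d_cell, balanced_cell)` subjects is drawn once, the unbalanced sample
#' takes the first `d_cell` of the pool and the balanced sample the first
#' `balanced_cell`, so the two samples share `min(d_cell, balanced_cell)`
#' subjects in every cell (common random numbers).
#'
#' @inheritParams generate_sample
#' @param balanced Cell counts of the balanced counterpart; defaults to
#'   `N/4` per cell. Must have the same total as `design`.
#' @return A list with tibbles `unbalanced` and `balanced`.
#' @examples
#' p <- generate_paired(c(20, 20, 20, 60), effect_spec(beta3 = 4), seed = 1)
#' nrow(p$balanced)
#' @export
generate_paired <- function(design, spec, seed = NULL, balanced = NULL) {
  stopifnot(inherits(spec, "effect_spec"))
  d <- .as_design(design)
  N <- sum(d)
  if (is.null(balanced)) {
    if (N %% 4 != 0) abort("N is not divisible by 4; supply `balanced` explicitly.")
    balanced <- rep(N / 4, 4)
  }
  b <- .as_design(balanced)
  if (sum(b) != N) abort("`balanced` must have the same total N as `design`.")
  mu <- .mu_vec(spec)
  pool <- pmax(d, b)
  draw <- function() lapply(1:4, function(j) rnorm(pool[j], mu[j], spec$sigma))
  pools <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  take <- function(counts) {
    out <- .cell_levels(counts)
    out$y <- unlist(lapply(1:4, function(j) pools[[j]][seq_len(counts[j])]))
    out
  }
  u <- take(d)
  attr(u, "design") <- d
  attr(u, "spec") <- spec
  bs <- take(b)
  attr(bs, "design") <- b
  attr(bs, "spec") <- spec
  list(unbalanced = u, balanced = bs)
}
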