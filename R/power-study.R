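#' Monte-Carlo rejection rates for one design under one effect spec
#'
#' Runs `replicates` paired simulations: per replicate a pooled sample is
#' drawn (see [generate_paired()]) so that the unbalanced design and its
#' balanced counterpart share subjects, the unbalanced sample is analysed
#' with Type II and Type III SS, the balanced sample with (sequential)
#' Type I, and rejections of each effect's H0 at level `alpha` are tallied.
#' All fits use the cell-mean least-squares engine, vectorised over
#' replicates; each replicate draws from its own derived seed stream so any
#' replicate can be reproduced in isolation via
#' `generate_paired(design, spec, seed = <derived seed>)`.
#'
#' @inheritParams generate_paired
#' @param replicates Number of Monte-Carlo replicates (study default 1000).
#' @param alpha Test level (study default 0.05).
#' @param seed Base integer seed for the derived per-replicate streams.
#' @param design_id Optional identifier mixed into the seed derivation and
#'   carried into the output (as in [study_designs()]).
#' @param coding Analysis coding; the study uses `"contrast"` throughout.
#' @return A tibble with one row per (method, effect): `design_id`,
#'   `n00 ... n11`, `beta3`, `construction`, `method` (`balanced_ss1`,
#'   `ss2`, `ss3`), `effect`, `rate`, `mc_se = sqrt(rate (1 - rate) / replicates)`,
#'   `replicates`, `alpha`, and `choose_ss2_rate`, the proportion of
#'   replicates in which the interaction was not significant (the rate at
#'   which the "use SS II unless the interaction is significant" rule would
#'   pick SS II).
#' @examples
#' run_cell(c(20, 20, 20, 60), effect_spec(beta3 = 4), replicates = 100, seed = 1)
#' @export
run_cell <- function(design, spec, replicates = 1000, alpha = 0.05, seed = 1L,
                     balanced = NULL, design_id = NULL,
                     coding = c("contrast", "treatment")) {
  stopifnot(inherits(spec, "effect_spec"))
  coding <- match.arg(coding)
  if (replicates < 1 || replicates != round(replicates)) {
    abort("`replicates` must be a positive integer.")
  }
  if (spec$sigma <= 0) abort("Monte-Carlo power needs `sigma` > 0.")
  d <- .as_design(design)
  N <- sum(d)
  if (is.null(balanced)) {
    if (N %% 4 != 0) abort("N not divisible by 4; supply `balanced` explicitly.")
    balanced <- rep(N / 4, 4)
  }
  b <- .as_design(balanced)
  if (sum(b) != N) abort("`balanced` must have the same total N as `design`.")
  mu <- .mu_vec(spec)
  pool <- pmax(d, b)
  id_key <- if (is.null(design_id)) paste(d, collapse = ".") else design_id
  key <- paste(id_key, spec$beta3, spec$construction, sep = "|")

  Xs <- lapply(1:4, function(j) matrix(NA_real_, replicates, pool[j]))
  for (r in seq_len(replicates)) {
    s <- .derive_seed(seed, paste(key, r, sep = "|"))
    vals <- withr::with_seed(s, lapply(1:4, function(j) rnorm(pool[j], mu[j], spec$sigma)))
    for (j in 1:4) Xs[[j]][r, ] <- vals[[j]]
  }

  arm <- function(counts) {
    M <- matrix(NA_real_, replicates, 4)
    ssw <- numeric(replicates)
    for (j in 1:4) {
      Xj <- Xs[[j]][, seq_len(counts[j]), drop = FALSE]
      mj <- rowMeans(Xj)
      M[, j] <- mj
      ssw <- ssw + rowSums(Xj^2) - counts[j] * mj^2
    }
    list(M = M, ss_res = ssw)
  }
  pmat <- function(a, counts, type, order = "A_first") {
    R <- .rss_subsets(counts, a$M, coding)
    ss <- .effect_ss(R, type, order)
    df2 <- sum(counts) - 4
    pf(ss / (a$ss_res / df2), 1, df2, lower.tail = FALSE)
  }
  ua <- arm(d)
  ba <- arm(b)
  p1b <- pmat(ba, b, "I")
  p2 <- pmat(ua, d, "II")
  p3 <- pmat(ua, d, "III")
  choose_ss2 <- mean(p2[, "AB"] >= alpha)

  rate_rows <- function(p, method) {
    r <- colMeans(p < alpha)
    tibble(method = method, effect = c("A", "B", "AB"), rate = unname(r))
  }
  out <- dplyr::bind_rows(
    rate_rows(p1b, "balanced_ss1"),
    rate_rows(p2, "ss2"),
    rate_rows(p3, "ss3")
  )
  dplyr::mutate(out,
    design_id = if (is.null(design_id)) NA_integer_ else as.integer(design_id),
    n00 = d[1], n01 = d[2], n10 = d[3], n11 = d[4],
    beta3 = spec$beta3, construction = spec$construction,
    mc_se = sqrt(.data$rate * (1 - .data$rate) / replicates),
    replicates = as.integer(replicates), alpha = alpha,
    choose_ss2_rate = choose_ss2,
    .before = 1
  ) |>
    dplyr::relocate("method", "effect", "rate", "mc_se",
                    .after = "construction")
}

#' Run the full comparative power study
#'
#' Crosses the supplied designs with the interaction strengths and effect
#' constructions, calling [run_cell()] for every combination with an
#' independent derived seed stream. The defaults are the study conditions:
#' the 34 unbalanced N = 120 designs plus their balanced counterpart,
#' `beta3` in \{0, 4, 8\}, both constructions, intercept 10, main effects 4,
#' residual SD 10, 1000 replicates at alpha 0.05 with contrast-coded
#' analysis.
#'
#' @param designs Tibble of designs (see [study_designs()]); must contain
#'   `design_id`, `n00 ... n11`.
#' @param beta3 Vector of interaction coefficients to simulate.
#' @param construction One or both of `"zero_control"`,
#'   `"equal_contribution"`.
#' @param beta0,beta1,beta2,sigma Remaining generator parameters.
#' @inheritParams run_cell
#' @param verbose Emit a progress message per condition?
#' @return A `power_report` tibble: the row-bound [run_cell()] outputs, with
#'   attributes recording the grid and seed.
#' @examples
#' run_study(study_designs()[1:3, ], beta3 = 0,
#'           construction = "zero_control", replicates = 50, seed = 1)
#' @export
run_study <- function(designs = study_designs(), beta3 = c(0, 4, 8),
                      construction = c("zero_control", "equal_contribution"),
                      beta0 = 10, beta1 = 4, beta2 = 4, sigma = 10,
                      replicates = 1000, alpha = 0.05, seed = 1L,
                      coding = c("contrast", "treatment"), verbose = FALSE) {
  coding <- match.arg(coding)
  construction <- match.arg(construction, several.ok = TRUE)
  designs <- as_tibble(designs)
  if (!all(c("design_id", "n00", "n01", "n10", "n11") %in% names(designs))) {
    abort("`designs` must have columns design_id, n00, n01, n10, n11.")
  }
  grid <- tidyr::expand_grid(i = seq_len(nrow(designs)), b3 = beta3,
                             cons = construction)
  t0 <- Sys.time()
  rows <- purrr::pmap(grid, function(i, b3, cons) {
    drow <- designs[i, ]
    spec <- effect_spec(beta0, beta1, beta2, b3, sigma, cons)
    if (verbose) {
      message(sprintf("design %s, beta3 = %g, %s", drow$design_id, b3, cons))
    }
    run_cell(c(drow$n00, drow$n01, drow$n10, drow$n11), spec,
             replicates = replicates, alpha = alpha, seed = seed,
             design_id = drow$design_id, coding = coding)
  })
  out <- dplyr::bind_rows(rows)
  if (verbose) {
    message(sprintf("%d conditions x %d replicates in %.1f s",
                    nrow(grid), replicates,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  attr(out, "alpha") <- alpha
  attr(out, "replicates") <- as.integer(replicates)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "coding") <- coding
  attr(out, "betas") <- c(beta0 = beta0, beta1 = beta1, beta2 = beta2,
                          sigma = sigma)
  attr(out, "beta3") <- beta3
  attr(out, "construction") <- construction
  class(out) <- c("power_report", class(out))
  out
}

#' Closed-form power oracle via the noncentral F distribution
#'
#' For a given design and effect spec, the noncentrality of each effect's F
#' test is the noise-free SS of that effect under the chosen SS-type
#' adjustment (the engine run on the expected cell means, weighted by the
#' cell counts) divided by the error variance. Power is then the upper tail
#' of the noncentral F(1, N-4, lambda) distribution at the central-F
#' critical value. An effect with zero noise-free SS has lambda 0 and power
#' exactly `alpha`.
#'
#' @inheritParams run_cell
#' @param ss_type `"II"`, `"III"` or `"I"`.
#' @param order Entry order when `ss_type = "I"`.
#' @return A tibble with `effect`, `ss_noisefree`, `lambda`, `power`.
#' @examples
#' analytic_power(c(30, 30, 30, 30), effect_spec(beta3 = 4))
#' @export
analytic_power <- function(design, spec, ss_type = c("II", "III", "I"),
                           alpha = 0.05, coding = c("contrast", "treatment"),
                           order = c("A_first", "B_first")) {
  stopifnot(inherits(spec, "effect_spec"))
  ss_type <- match.arg(ss_type)
  coding <- match.arg(coding)
  order <- match.arg(order)
  if (spec$sigma <= 0) abort("Analytic power needs `sigma` > 0.")
  d <- .as_design(design)
  R <- .rss_subsets(d, matrix(.mu_vec(spec), 1), coding)
  ss <- .effect_ss(R, ss_type, order)[1, ]
  lambda <- ss / spec$sigma^2
  df2 <- sum(d) - 4
  crit <- qf(1 - alpha, 1, df2)
  tibble(
    effect = c("A", "B", "AB"),
    ss_noisefree = unname(ss),
    lambda = unname(lambda),
    power = pf(crit, 1, df2, ncp = unname(lambda), lower.tail = FALSE)
  )
}

.flag_balanced <- function(report) {
  dplyr::mutate(report,
    balanced_design = .data$n00 == .data$n01 & .data$n01 == .data$n10 &
      .data$n10 == .data$n11)
}

#' Mean rejection rates across the unbalanced designs
#'
#' Condenses a power report into the study's headline matrix: for every
#' (construction, beta3, effect) the unweighted mean rejection rate over the
#' unbalanced designs under Type II and Type III SS, next to the balanced
#' rate (the mean over the paired balanced arms, i.e. the mean of
#' 34 x replicates simulations under the default grid). Designs whose four
#' cells are equal are excluded from the unbalanced averages.
#'
#' @param report A `power_report` from [run_study()].
#' @return A tibble with columns `construction`, `beta3`, `effect`,
#'   `balanced`, `ss_ii`, `ss_iii`.
#' @export
summarize_means <- function(report) {
  unb <- dplyr::filter(.flag_balanced(report), !.data$balanced_design)
  if (nrow(unb) == 0) abort("Report contains no unbalanced designs.")
  unb |>
    dplyr::group_by(.data$construction, .data$beta3, .data$method, .data$effect) |>
    dplyr::summarize(rate = mean(.data$rate), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "method", values_from = "rate") |>
    dplyr::rename(balanced = "balanced_ss1", ss_ii = "ss2", ss_iii = "ss3") |>
    dplyr::mutate(effect = factor(.data$effect, levels = c("A", "B", "AB"))) |>
    dplyr::arrange(.data$construction, .data$beta3, .data$effect)
}

#' Classify unbalanced designs against their balanced counterparts
#'
#' For each (construction, beta3, correction method, effect), counts how
#' many unbalanced designs reject H0 at a higher rate than the paired
#' balanced analysis, how many at a lower rate, and how many tie exactly,
#' together with the mean rate difference (delta) within the higher and
#' lower groups. Ties form their own category, which is why the higher and
#' lower percentages need not sum to 100.
#'
#' @param report A `power_report` from [run_study()].
#' @return A `comparison_summary` tibble with columns `construction`,
#'   `beta3`, `method`, `effect`, `n_designs`, `n_higher`, `pct_higher`,
#'   `delta_higher`, `n_lower`, `pct_lower`, `delta_lower`, `n_tied`.
#' @export
compare_to_balanced <- function(report) {
  flagged <- .flag_balanced(report)
  unb <- dplyr::filter(flagged, !.data$balanced_design)
  if (nrow(unb) == 0) abort("Report contains no unbalanced designs.")
  bal <- unb |>
    dplyr::filter(.data$method == "balanced_ss1") |>
    dplyr::select("design_id", "construction", "beta3", "effect",
                  bal_rate = "rate")
  mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  out <- unb |>
    dplyr::filter(.data$method %in% c("ss2", "ss3")) |>
    dplyr::left_join(bal, by = c("design_id", "construction", "beta3", "effect")) |>
    dplyr::mutate(diff = .data$rate - .data$bal_rate) |>
    dplyr::group_by(.data$construction, .data$beta3, .data$method, .data$effect) |>
    dplyr::summarize(
      n_designs = dplyr::n(),
      n_higher = sum(.data$diff > 0),
      pct_higher = 100 * mean(.data$diff > 0),
      delta_higher = mean_or_na(.data$diff[.data$diff > 0]),
      n_lower = sum(.data$diff < 0),
      pct_lower = 100 * mean(.data$diff < 0),
      delta_lower = mean_or_na(.data$diff[.data$diff < 0]),
      n_tied = sum(.data$diff == 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(effect = factor(.data$effect, levels = c("A", "B", "AB"))) |>
    dplyr::arrange(.data$construction, .data$beta3, .data$method, .data$effect)
  class(out) <- c("comparison_summary", class(out))
  out
}

#' Mean coefficient and SS re-estimates in a large balanced design
#'
#' Quantifies congruous versus incongruous analysis: data are generated in a
#' balanced design (study: 250 per cell, N = 1000) under the spec's
#' construction, then the saturated model is fitted under each requested
#' analysis coding. Reported are the mean fitted coefficients and the mean
#' per-effect SS (Type II, which on balanced data equals the common Type
#' I/II value whichever coding is used) over the replicates, plus the
#' residual line. When the analysis coding mimics the construction the
#' generating betas are recovered; when it does not, the coefficients land
#' on the reparameterized scale (e.g. (0,1)-generated data with all betas
#' (10,4,4,4) analysed with (-1,1) gives intercept 15 and interaction 1;
#' the reverse gives intercept 6 and interaction 16).
#'
#' @inheritParams run_cell
#' @param n_per_cell Subjects per cell of the balanced design.
#' @param codings Analysis codings to apply to the same simulated data.
#' @return A tibble with `construction`, `coding`, `term`, `df`,
#'   `beta_true`, `estimate` (mean coefficient; for the residual row the
#'   mean estimated residual SD) and `sumsq` (mean SS).
#' @examples
#' coefficient_summary(effect_spec(beta3 = 4), n_per_cell = 50,
#'                     replicates = 100, seed = 1)
#' @export
coefficient_summary <- function(spec, n_per_cell = 250, replicates = 1000,
                                seed = 1L,
                                codings = c("treatment", "contrast")) {
  stopifnot(inherits(spec, "effect_spec"))
  codings <- match.arg(codings, several.ok = TRUE)
  if (spec$sigma <= 0) abort("`sigma` must be positive.")
  if (n_per_cell < 2) abort("`n_per_cell` must be at least 2.")
  mu <- .mu_vec(spec)
  n <- as.integer(n_per_cell)
  key <- paste("coef", spec$beta3, spec$construction, n, sep = "|")
  M <- matrix(NA_real_, replicates, 4)
  ssw <- numeric(replicates)
  for (r in seq_len(replicates)) {
    s <- .derive_seed(seed, paste(key, r, sep = "|"))
    vals <- withr::with_seed(s, lapply(1:4, function(j) rnorm(n, mu[j], spec$sigma)))
    for (j in 1:4) {
      mj <- mean(vals[[j]])
      M[r, j] <- mj
      ssw[r] <- ssw[r] + sum((vals[[j]] - mj)^2)
    }
  }
  df_res <- 4L * n - 4L
  purrr::map(codings, function(cd) {
    est <- colMeans(.coef_cells(M, cd))
    ss <- colMeans(.effect_ss(.rss_subsets(rep(n, 4), M, cd), "II"))
    tibble(
      construction = spec$construction,
      coding = cd,
      term = c("(Intercept)", "A", "B", "A:B", "Residuals"),
      df = c(NA_integer_, 1L, 1L, 1L, df_res),
      beta_true = c(spec$beta0, spec$beta1, spec$beta2, spec$beta3, spec$sigma),
      estimate = c(unname(est), mean(sqrt(ssw / df_res))),
      sumsq = c(NA_real_, unname(ss), mean(ssw))
    )
  }) |>
    dplyr::bind_rows()
}
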