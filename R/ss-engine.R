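#' Coded design matrix for a 2x2 sample
#'
#' Builds the subject-level design matrix with an intercept, the two factor
#' code columns and their product as the interaction column. Under treatment
#' coding the codes are (0, 1) with `ab_code = 1` only in the (T,T) cell;
#' under contrast (sum-to-zero) coding they are (-1, 1), which makes the
#' interaction column orthogonal to both main-effect columns in a balanced
#' sample. Both codings span the same column space, so fitted cell means of
#' the full model never depend on the coding; only the Type III attribution
#' of main-effect SS does.
#'
#' @param data A sample tibble with columns `a`, `b` (levels `C`/`T`), `y`.
#' @param coding `"contrast"` (-1, 1; the default, recommended for Type III)
#'   or `"treatment"` (0, 1).
#' @return A numeric matrix with columns `(Intercept)`, `a_code`, `b_code`,
#'   `ab_code` and attribute `coding`.
#' @export
build_matrix <- function(data, coding = c("contrast", "treatment")) {
  coding <- match.arg(coding)
  .cell_stats(data) # validates columns, levels and non-empty cells
  codes <- if (coding == "treatment") c(C = 0, T = 1) else c(C = -1, T = 1)
  a <- codes[as.character(data$a)]
  b <- codes[as.character(data$b)]
  X <- cbind(`(Intercept)` = 1, a_code = unname(a), b_code = unname(b),
             ab_code = unname(a * b))
  attr(X, "coding") <- coding
  X
}

#' Nested least-squares fits over all predictor subsets
#'
#' Fits, by weighted normal equations on the cell means (exactly ordinary
#' least squares, since all predictors are constant within cells), the model
#' with intercept plus each of the seven non-empty subsets of \{A, B, AB\},
#' and records each subset's regression sum of squares about the grand mean.
#' These `R(S)` values are the raw material for every SS type and for the
#' commonality (Venn) decomposition: e.g. the sequential SS of B after A is
#' `R({A,B}) - R({A})`. The solve uses a relative singularity tolerance of
#' 1e-10.
#'
#' @inheritParams build_matrix
#' @return An object of class `nested_fits`: the named vector `R` of subset
#'   SS (`A`, `B`, `I`, `AB`, `AI`, `BI`, `ABI`), `ss_total`, `ss_res`
#'   (full-model residual SS), `df_res = N - 4`, `N`, `ncell`, `cell_means`
#'   and the `coding` used.
#' @examples
#' s <- generate_sample(c(20, 20, 20, 60), effect_spec(beta3 = 4), seed = 1)
#' nested_fits(s)$R
#' @export
nested_fits <- function(data, coding = c("contrast", "treatment")) {
  coding <- match.arg(coding)
  cs <- .cell_stats(data)
  N <- sum(cs$n)
  if (N <= 4) abort("Need N > 4 subjects for a full 2x2 model with residual df.")
  R <- .rss_subsets(cs$n, matrix(cs$m, 1), coding)[1, ]
  grand <- sum(cs$n * cs$m) / N
  ss_total <- sum(cs$ssw) + sum(cs$n * (cs$m - grand)^2)
  structure(
    list(R = R, ss_total = ss_total, ss_res = ss_total - R[["ABI"]],
         df_res = N - 4L, N = N, ncell = cs$n, cell_means = cs$m,
         coding = coding),
    class = "nested_fits"
  )
}

#' @export
print.nested_fits <- function(x, ...) {
  cat(sprintf("<nested_fits> 2x2, N = %d, coding = %s\n", x$N, x$coding))
  print(round(x$R, 4))
  cat(sprintf("  residual SS %.4f on %d df (total %.4f)\n",
              x$ss_res, x$df_res, x$ss_total))
  invisible(x)
}

.anova_table <- function(ss, fits, ss_type) {
  msr <- fits$ss_res / fits$df_res
  Fval <- ss / msr
  p <- pf(Fval, 1, fits$df_res, lower.tail = FALSE)
  out <- tibble(
    term = c("A", "B", "A:B", "Residuals"),
    sumsq = c(unname(ss), fits$ss_res),
    df = c(1L, 1L, 1L, fits$df_res),
    statistic = c(unname(Fval), NA_real_),
    p.value = c(unname(p), NA_real_)
  )
  attr(out, "ss_type") <- ss_type
  attr(out, "coding") <- fits$coding
  class(out) <- c("anova_2x2", class(out))
  out
}

#' Sequential (Type I) sums of squares
#'
#' Attributes SS in model-entry order: the first main effect gets its
#' unadjusted SS `R({first})`, the second gets `R({A,B}) - R({first})`, and
#' the interaction gets `R({A,B,AB}) - R({A,B})`. Order matters in unbalanced
#' samples; in balanced samples both orders agree.
#'
#' @param fits A [nested_fits()] object.
#' @param order `"A_first"` or `"B_first"`.
#' @return An `anova_2x2` tibble: `term`, `sumsq`, `df`, `statistic` (F on
#'   1 and N-4 df against the full-model residual), `p.value`.
#' @export
ss_type1 <- function(fits, order = c("A_first", "B_first")) {
  stopifnot(inherits(fits, "nested_fits"))
  order <- match.arg(order)
  ss <- .effect_ss(matrix(fits$R, 1, dimnames = list(NULL, names(fits$R))),
                   "I", order)[1, ]
  .anova_table(ss, fits, paste0("I_", order))
}

#' Type II sums of squares
#'
#' Each main effect is adjusted for the other main effect but not for the
#' interaction: `SS(A) = R({A,B}) - R({B})`, `SS(B) = R({A,B}) - R({A})`.
#' The interaction row carries its unique part `R({A,B,AB}) - R({A,B})`
#' (the component z), as statistical packages conventionally report. Type II
#' main-effect SS are invariant to the factor coding.
#'
#' @param fits A [nested_fits()] object.
#' @return An `anova_2x2` tibble (see [ss_type1()]).
#' @export
ss_type2 <- function(fits) {
  stopifnot(inherits(fits, "nested_fits"))
  ss <- .effect_ss(matrix(fits$R, 1, dimnames = list(NULL, names(fits$R))),
                   "II")[1, ]
  .anova_table(ss, fits, "II")
}

#' Type III sums of squares
#'
#' Each effect is adjusted for all other effects including the interaction:
#' `SS(A) = R({A,B,AB}) - R({B,AB})` and similarly for B; the interaction SS
#' equals its unique part z as in Type II. Because the subsets \{B,AB\} and
#' \{A,AB\} span different spaces under (0,1) and (-1,1) codes, Type III
#' main-effect SS depend on the coding in unbalanced samples; sum-to-zero
#' (-1, 1) coding is the recommended choice.
#'
#' @param fits A [nested_fits()] object.
#' @return An `anova_2x2` tibble (see [ss_type1()]).
#' @export
ss_type3 <- function(fits) {
  stopifnot(inherits(fits, "nested_fits"))
  ss <- .effect_ss(matrix(fits$R, 1, dimnames = list(NULL, names(fits$R))),
                   "III")[1, ]
  .anova_table(ss, fits, "III")
}

#' Commonality (Venn) decomposition of the regression SS
#'
#' Splits the full-model regression SS into seven additive components by
#' inclusion-exclusion over the nested fits: the unique components `t`, `x`,
#' `z` of A, B and the interaction, and the cross-predictive (non-unique)
#' components `w` = common(A, AB), `y` = common(B, AB), `u` = common(A, B)
#' and `v` = common(A, B, AB). Cross-predictive components can be negative
#' (underlapping variance); only the seven together are additive:
#' `t + u + v + w + x + y + z = R({A,B,AB})`. The sum `u + v` equals
#' `R({A}) + R({B}) - R({A,B})` and is invariant to the coding.
#'
#' @param fits A [nested_fits()] object.
#' @return An object of class `venn_components`: a tibble with `component`
#'   (t, u, v, w, x, y, z), `sumsq` and a `role` label.
#' @examples
#' s <- generate_sample(c(20, 20, 20, 60), effect_spec(beta3 = 4), seed = 1)
#' venn_components(nested_fits(s))
#' @export
venn_components <- function(fits) {
  stopifnot(inherits(fits, "nested_fits"))
  R <- fits$R
  comp <- c(
    t = R[["ABI"]] - R[["BI"]],
    u = R[["AI"]] + R[["BI"]] - R[["I"]] - R[["ABI"]],
    v = R[["ABI"]] + R[["A"]] + R[["B"]] + R[["I"]] -
        R[["AB"]] - R[["AI"]] - R[["BI"]],
    w = R[["AB"]] + R[["BI"]] - R[["B"]] - R[["ABI"]],
    x = R[["ABI"]] - R[["AI"]],
    y = R[["AB"]] + R[["AI"]] - R[["A"]] - R[["ABI"]],
    z = R[["ABI"]] - R[["AB"]]
  )
  out <- tibble(
    component = names(comp),
    sumsq = unname(comp),
    role = c("unique A", "common A,B", "common A,B,AB", "common A,AB",
             "unique B", "common B,AB", "unique AB")
  )
  attr(out, "coding") <- fits$coding
  class(out) <- c("venn_components", class(out))
  out
}

#' F tests on an ANOVA table
#'
#' Rejects the per-effect null hypothesis when the upper-tail central-F
#' probability of the observed statistic, on 1 and N-4 df against the
#' full-model residual, falls below `alpha`.
#'
#' @param table An `anova_2x2` tibble from [ss_type1()], [ss_type2()] or
#'   [ss_type3()].
#' @param alpha Nominal test level (study default 0.05).
#' @return A tibble with the effect rows and a logical `reject` column.
#' @export
f_test <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "anova_2x2"), alpha > 0, alpha < 1)
  eff <- dplyr::filter(table, .data$term != "Residuals")
  dplyr::mutate(as_tibble(eff), reject = .data$p.value < alpha)
}

#' One-call ANOVA of a 2x2 sample
#'
#' Convenience wrapper: [nested_fits()] followed by the requested SS type.
#'
#' @inheritParams build_matrix
#' @param type `"II"`, `"III"` or `"I"`.
#' @param order Entry order for Type I.
#' @return An `anova_2x2` tibble.
#' @examples
#' s <- generate_sample(c(20, 20, 20, 60), effect_spec(beta3 = 4), seed = 1)
#' anova_2x2(s, type = "III")
#' @export
anova_2x2 <- function(data, coding = c("contrast", "treatment"),
                      type = c("II", "III", "I"),
                      order = c("A_first", "B_first")) {
  type <- match.arg(type)
  fits <- nested_fits(data, coding)
  switch(type,
    I = ss_type1(fits, order),
    II = ss_type2(fits),
    III = ss_type3(fits)
  )
}

#' Full-model coefficients of a 2x2 sample
#'
#' Least-squares coefficients of the saturated model under the chosen
#' coding, computed from the four cell means (the 4x4 cell-level system is
#' exact). The two codings are linked by the reparameterization
#' `c3 = b3/4`, `c1 = b1/2 + b3/4`, `c2 = b2/2 + b3/4`,
#' `c0 = b0 + (b1 + b2)/2 + b3/4`, where `b` are treatment-coded and `c`
#' contrast-coded coefficients.
#'
#' @inheritParams build_matrix
#' @return A tibble with `term` and `estimate`.
#' @export
coef_2x2 <- function(data, coding = c("contrast", "treatment")) {
  coding <- match.arg(coding)
  cs <- .cell_stats(data)
  est <- .coef_cells(matrix(cs$m, 1), coding)[1, ]
  tibble(term = names(est), estimate = unname(est))
}
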