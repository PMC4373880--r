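#' Tidy the nested-fits subset sums of squares
#'
#' @param x A [nested_fits()] object.
#' @param ... Unused.
#' @return A tibble with `subset`, `predictors` and the regression `sumsq`.
#' @export
tidy.nested_fits <- function(x, ...) {
  tibble(
    subset = names(x$R),
    predictors = vapply(.ss_subsets, paste, character(1), collapse = ","),
    sumsq = unname(x$R)
  )
}

#' One-line summary of a nested fit
#'
#' @param x A [nested_fits()] object.
#' @param ... Unused.
#' @return A one-row tibble: total and residual SS, residual df, N, coding
#'   and the full-model R squared.
#' @export
glance.nested_fits <- function(x, ...) {
  tibble(
    ss_total = x$ss_total, ss_res = x$ss_res, df_res = x$df_res, n = x$N,
    coding = x$coding,
    r.squared = if (x$ss_total > 0) 1 - x$ss_res / x$ss_total else NA_real_
  )
}

#' @export
tidy.anova_2x2 <- function(x, ...) as_tibble(x)

#' @export
glance.anova_2x2 <- function(x, ...) {
  res <- x[x$term == "Residuals", ]
  tibble(ss_type = attr(x, "ss_type"), coding = attr(x, "coding"),
         ss_res = res$sumsq, df_res = res$df)
}

#' @export
tidy.venn_components <- function(x, ...) as_tibble(x)

#' Bar chart of the seven commonality components
#'
#' Unique components (t, x, z) and cross-predictive components (u, v, w, y)
#' of the regression SS; negative bars show underlapping (negative common)
#' variance.
#'
#' @param object A [venn_components()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.venn_components <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object),
    kind = ifelse(.data$component %in% c("t", "x", "z"),
                  "unique", "cross-predictive"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$sumsq,
                                   fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "component", y = "sum of squares", fill = NULL,
                  title = sprintf("Commonality components (%s coding)",
                                  attr(object, "coding")))
}

#' Rejection-rate profiles across designs
#'
#' One panel per (beta3, effect); lines trace the rejection rate over the
#' unbalanced designs for each correction method next to the paired
#' balanced rate.
#'
#' @param object A `power_report` from [run_study()].
#' @param construction Which effect construction to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_report <- function(object,
                                  construction = c("zero_control",
                                                   "equal_contribution"),
                                  ...) {
  construction <- match.arg(construction)
  df <- dplyr::filter(.flag_balanced(object),
                      !.data$balanced_design,
                      .data$construction == !!construction)
  if (nrow(df) == 0) abort("No unbalanced rows for that construction.")
  df <- dplyr::mutate(df, effect = factor(.data$effect, c("A", "B", "AB")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$design_id, y = .data$rate,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_grid(ggplot2::vars(.data$beta3),
                        ggplot2::vars(.data$effect)) +
    ggplot2::labs(x = "design", y = "rejection rate of H0",
                  colour = NULL,
                  title = sprintf("Rejection rates (%s construction)",
                                  construction))
}
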