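#' Enumerate ordered compositions of a total into cells
#'
#' Lists every way to split `n` subjects over `k` distinct cells with at least
#' `min_per_cell` subjects in each cell, in lexicographic order. For a 2x2
#' factorial (`k = 4`) the cells are labelled `n00, n01, n10, n11`, where the
#' first index is the level of factor A and the second the level of factor B
#' (0 = control, 1 = treatment).
#'
#' The number of rows returned equals the stars-and-bars count
#' `choose(n - k * min_per_cell + k - 1, k - 1)`: e.g. 12 subjects go into 4
#' cells in 455 ways unrestricted, and in 35 ways with at least 2 per cell
#' (34 unbalanced patterns plus the balanced 3,3,3,3).
#'
#' @param n Total number of subjects (positive integer).
#' @param k Number of cells (positive integer; 4 for a 2x2 design).
#' @param min_per_cell Minimum subjects per cell. Defaults to 2, the smallest
#'   count that guarantees within-cell variance.
#' @return A tibble with one row per composition: the `k` cell counts plus a
#'   total column `N`. Zero rows when `n < k * min_per_cell`.
#' @examples
#' nrow(enumerate_compositions(12, 4, 0)) # 455
#' enumerate_compositions(8, 4, 2)        # only 2,2,2,2
#' @export
enumerate_compositions <- function(n, k = 4, min_per_cell = 2) {
  if (length(n) != 1L || is.na(n) || n <= 0 || n != round(n)) {
    abort("`n` must be a single positive integer.")
  }
  if (length(k) != 1L || is.na(k) || k <= 0 || k != round(k)) {
    abort("`k` must be a single positive integer.")
  }
  if (min_per_cell < 0 || min_per_cell != round(min_per_cell)) {
    abort("`min_per_cell` must be a non-negative integer.")
  }
  nms <- if (k == 4) c("n00", "n01", "n10", "n11") else paste0("cell_", seq_len(k))
  if (n < k * min_per_cell) {
    out <- as_tibble(setNames(rep(list(integer()), k), nms))
    out$N <- integer()
    return(out)
  }
  m <- .compositions(as.integer(n), as.integer(k), as.integer(min_per_cell))
  colnames(m) <- nms
  out <- as_tibble(m)
  out$N <- as.integer(n)
  out
}

# recursive lexicographic enumeration; k is small (4 for this package)
.compositions <- function(n, k, m) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  parts <- lapply(seq.int(m, n - (k - 1L) * m), function(first) {
    cbind(first, .compositions(n - first, k - 1L, m))
  })
  do.call(rbind, parts)
}

#' Cell-count patterns of the comparative power study
#'
#' The 34 unbalanced 2x2 patterns obtained by splitting 12 base subjects over
#' four cells with at least 2 per cell (the balanced split 3,3,3,3 excluded),
#' numbered 1-34 in lexicographic order of `(n00, n01, n10, n11)`, each scaled
#' by `scale`. At the study scale of 10 every cell holds 20-60 subjects and
#' N = 120. The balanced counterpart is included as `design_id = 0` when
#' `include_balanced = TRUE`.
#'
#' @param scale Positive integer multiplier for every cell count (study: 10).
#' @param include_balanced Include the balanced pattern as design 0?
#' @return A tibble with columns `design_id`, `balanced`, `n00`, `n01`,
#'   `n10`, `n11`, `N`.
#' @examples
#' study_designs()           # 35 rows, N = 120 each
#' study_designs(scale = 1)  # the base-12 patterns
#' @export
study_designs <- function(scale = 10, include_balanced = TRUE) {
  if (length(scale) != 1L || is.na(scale) || scale < 1 || scale != round(scale)) {
    abort("`scale` must be a single positive integer.")
  }
  comp <- enumerate_compositions(12, 4, 2)
  bal <- comp$n00 == 3 & comp$n01 == 3 & comp$n10 == 3 & comp$n11 == 3
  unb <- comp[!bal, ]
  unb$design_id <- seq_len(nrow(unb))
  unb$balanced <- FALSE
  out <- unb
  if (include_balanced) {
    b <- comp[bal, ]
    b$design_id <- 0L
    b$balanced <- TRUE
    out <- dplyr::bind_rows(b, unb)
  }
  out <- dplyr::mutate(out, dplyr::across(c("n00", "n01", "n10", "n11", "N"),
                                          ~ as.integer(.x * scale)))
  dplyr::select(out, "design_id", "balanced", "n00", "n01", "n10", "n11", "N")
}

#' Balanced counterpart design
#'
#' @param scale Positive integer multiplier (study: 10, giving 30 per cell).
#' @return A one-row tibble with the balanced cell counts.
#' @export
balanced_design <- function(scale = 10) {
  d <- study_designs(scale = scale, include_balanced = TRUE)
  dplyr::filter(d, .data$balanced)
}

#' Imbalance indicator per effect
#'
#' For each effect V (main effects A, B and the interaction AB) the signed
#' imbalance is the difference between the number of subjects on the
#' "treatment" side and the "control" side of that effect, divided by N:
#' `U_A = (n10 + n11 - n00 - n01) / N`, `U_B = (n01 + n11 - n00 - n10) / N`,
#' and for the interaction, taking the concordant diagonal cells (0,0) and
#' (1,1) as the positive side (the sum-to-zero view of the interaction
#' contrast), `U_AB = (n00 + n11 - n01 - n10) / N`. Each indicator lies in
#' \[-1, 1\] and is 0 for a balanced design.
#'
#' @param designs A data frame with columns `n00`, `n01`, `n10`, `n11` (one
#'   row per design), e.g. from [study_designs()].
#' @return The input tibble with columns `U_A`, `U_B`, `U_AB` appended.
#' @examples
#' imbalance(study_designs())
#' @export
imbalance <- function(designs) {
  designs <- as_tibble(designs)
  need <- c("n00", "n01", "n10", "n11")
  if (!all(need %in% names(designs))) {
    abort(paste0("`designs` must have columns ", paste(need, collapse = ", "), "."))
  }
  N <- designs$n00 + designs$n01 + designs$n10 + designs$n11
  if (any(N == 0)) abort("Design with N = 0: imbalance is undefined.")
  dplyr::mutate(designs,
    U_A  = (.data$n10 + .data$n11 - .data$n00 - .data$n01) / N,
    U_B  = (.data$n01 + .data$n11 - .data$n00 - .data$n10) / N,
    U_AB = (.data$n00 + .data$n11 - .data$n01 - .data$n10) / N
  )
}
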