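# Internal least-squares core.
#
# Every model fitted here has predictors that are constant within the four
# design cells, so ordinary least squares on N subjects collapses to weighted
# least squares on the four cell means with the cell counts as weights: the
# within-cell variation is orthogonal to every between-cell predictor. All
# regression sums of squares R(S) are therefore computed from cell counts and
# cell means alone, which also lets the Monte-Carlo study evaluate thousands
# of replicates as one matrix product.

# cell-level code columns in cell order (0,0), (0,1), (1,0), (1,1)
.cell_codes <- function(coding) {
  if (coding == "treatment") {
    a <- c(0, 0, 1, 1); b <- c(0, 1, 0, 1)
  } else if (coding == "contrast") {
    a <- c(-1, -1, 1, 1); b <- c(-1, 1, -1, 1)
  } else {
    abort("`coding` must be \"contrast\" or \"treatment\".")
  }
  cbind(a = a, b = b, ab = a * b)
}

# the seven non-empty predictor subsets of {A, B, I}
.ss_subsets <- list(
  A = "a", B = "b", I = "ab",
  AB = c("a", "b"), AI = c("a", "ab"), BI = c("b", "ab"),
  ABI = c("a", "b", "ab")
)

# Regression SS (about the grand mean) of each predictor subset, for every
# row of M at once. Solved by the centred weighted normal equations
#   A_S beta = b_S,  A_S = C'WC - (C'W1)(C'W1)'/N,  b_S = C'Wm - (C'W1)(1'Wm)/N
# with a relative singularity tolerance of 1e-10 on the solve.
#
# ncell: 4 cell counts; M: replicates x 4 matrix of cell means.
# Returns a replicates x 7 matrix with columns A, B, I, AB, AI, BI, ABI.
.rss_subsets <- function(ncell, M, coding, tol = 1e-10) {
  if (is.null(dim(M))) M <- matrix(M, nrow = 1L)
  C <- .cell_codes(coding)
  w <- as.double(ncell)
  N <- sum(w)
  if (N <= 0) abort("Total N must be positive.")
  if (any(w <= 0)) {
    empty <- c("(C,C)", "(C,T)", "(T,C)", "(T,T)")[w <= 0]
    abort(paste0("Rank deficiency: empty cell ", paste(empty, collapse = ", "), "."))
  }
  Msum <- as.vector(M %*% w)
  out <- matrix(NA_real_, nrow(M), length(.ss_subsets),
                dimnames = list(NULL, names(.ss_subsets)))
  for (nm in names(.ss_subsets)) {
    Cs <- C[, .ss_subsets[[nm]], drop = FALSE]
    cw <- colSums(w * Cs)
    A <- crossprod(Cs, w * Cs) - tcrossprod(cw) / N
    if (rcond(A) < tol) {
      abort(paste0("Numerical rank loss solving for subset {", nm, "}."))
    }
    B <- M %*% (w * Cs) - tcrossprod(Msum, cw) / N
    out[, nm] <- rowSums((B %*% solve(A)) * B)
  }
  out
}

# Full-model (saturated) coefficients for every row of M: the cell-level
# design matrix [1 C] is 4x4 and invertible, so the OLS fit reproduces the
# cell means exactly and the coefficients do not depend on the cell counts.
# Returns replicates x 4 matrix: (Intercept), A, B, A:B.
.coef_cells <- function(M, coding) {
  if (is.null(dim(M))) M <- matrix(M, nrow = 1L)
  X <- cbind(1, .cell_codes(coding))
  out <- t(solve(X, t(M)))
  colnames(out) <- c("(Intercept)", "A", "B", "A:B")
  out
}

# per-cell count, mean and within-cell SS of a sample tibble (a, b, y)
.cell_stats <- function(data) {
  need <- c("a", "b", "y")
  if (!all(need %in% names(data))) {
    abort("Sample data must have columns `a`, `b`, `y`.")
  }
  a <- as.character(data$a)
  b <- as.character(data$b)
  if (!all(a %in% c("C", "T")) || !all(b %in% c("C", "T"))) {
    abort("Factor levels must be `C`/`T` (see read_dataset() for recoding).")
  }
  if (!is.numeric(data$y) || anyNA(data$y) || any(!is.finite(data$y))) {
    abort("`y` must be finite numeric.")
  }
  idx <- 2L * (a == "T") + (b == "T") + 1L
  n <- tabulate(idx, 4L)
  if (any(n == 0L)) {
    empty <- c("(C,C)", "(C,T)", "(T,C)", "(T,T)")[n == 0L]
    abort(paste0("Rank deficiency: empty cell ", paste(empty, collapse = ", "), "."))
  }
  sums <- as.vector(rowsum(data$y, idx))
  m <- sums / n
  ssq <- as.vector(rowsum(data$y^2, idx))
  list(n = n, m = m, ssw = ssq - n * m^2)
}

# effect SS (A, B, AB) from the 7 subset SS, per SS type.
# R: matrix replicates x 7 (columns as .rss_subsets).
.effect_ss <- function(R, type, order = c("A_first", "B_first")) {
  order <- match.arg(order)
  switch(type,
    I = if (order == "A_first") {
      cbind(A = R[, "A"], B = R[, "AB"] - R[, "A"], AB = R[, "ABI"] - R[, "AB"])
    } else {
      cbind(A = R[, "AB"] - R[, "B"], B = R[, "B"], AB = R[, "ABI"] - R[, "AB"])
    },
    II = cbind(A = R[, "AB"] - R[, "B"], B = R[, "AB"] - R[, "A"],
               AB = R[, "ABI"] - R[, "AB"]),
    III = cbind(A = R[, "ABI"] - R[, "BI"], B = R[, "ABI"] - R[, "AI"],
                AB = R[, "ABI"] - R[, "AB"]),
    abort("`type` must be one of \"I\", \"II\", \"III\".")
  )
}
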