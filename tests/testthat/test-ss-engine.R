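test_that("design matrix has the specified codes, rank and orthogonality", {
  bal <- generate_sample(c(3, 3, 3, 3), effect_spec(beta3 = 4), seed = 2)
  Xc <- build_matrix(bal, "contrast")
  cp <- crossprod(Xc)
  expect_equal(cp[upper.tri(cp)], rep(0, 6)) # balanced contrast: all orthogonal
  expect_identical(qr(Xc)$rank, 4L)

  Xt <- build_matrix(bal, "treatment")
  expect_equal(unname(Xt[, "ab_code"]),
               as.numeric(bal$a == "T" & bal$b == "T"))

  broken <- bal[bal$a == "C" | bal$b == "C", ]
  expect_error(build_matrix(broken), "\\(T,T\\)")
})

test_that("nested fits reproduce hand least-squares on the noise-free toy", {
  f <- nested_fits(toy_sample())
  expect_equal(unname(f$R[c("A", "B", "AB", "ABI")]), c(72, 72, 144, 152))
  expect_equal(f$ss_res, 0)
  expect_equal(f$df_res, 4L)
  # all-constant outcome: every subset SS is zero
  flat <- tibble::tibble(a = factor(rep(c("C", "T"), each = 4)),
                         b = factor(rep(c("C", "C", "T", "T"), 2)),
                         y = rep(5, 8))
  expect_equal(unname(nested_fits(flat)$R), rep(0, 7))
})

test_that("subset SS match the projection-matrix oracle and are monotone", {
  for (seed in 1:25) {
    s <- random_sample(seed)
    for (coding in c("contrast", "treatment")) {
      f <- nested_fits(s, coding)
      expect_equal(unname(f$R), unname(oracle_all_rss(s, coding)),
                   tolerance = 1e-8, info = sprintf("seed %d %s", seed, coding))
      # monotone in subset inclusion; additive with the residual
      expect_true(all(f$R[c("A", "B")] <= f$R["AB"] + 1e-10))
      expect_true(all(f$R[c("AB", "AI", "BI")] <= f$R["ABI"] + 1e-10))
      expect_equal(f$R[["ABI"]] + f$ss_res, f$ss_total, tolerance = 1e-8)
    }
    # SS I/II building blocks are coding-invariant (same one- and
    # two-main-effect column spaces up to affine maps)
    fc <- nested_fits(s, "contrast")
    ft <- nested_fits(s, "treatment")
    expect_equal(fc$R[c("A", "B", "AB", "ABI")],
                 ft$R[c("A", "B", "AB", "ABI")], tolerance = 1e-8)
  }
})

test_that("SS types satisfy their defining identities and coding behaviour", {
  for (seed in 26:45) {
    s <- random_sample(seed)
    fc <- nested_fits(s, "contrast")
    ft <- nested_fits(s, "treatment")
    R <- fc$R
    t1a <- ss_type1(fc, "A_first")
    t1b <- ss_type1(fc, "B_first")
    t2 <- ss_type2(fc)
    t3 <- ss_type3(fc)
    # sequential SS: both orders are additive decompositions of R(ABI)
    expect_equal(sum(effect_rows(t1a)$sumsq), R[["ABI"]], tolerance = 1e-8)
    expect_equal(sum(effect_rows(t1b)$sumsq), R[["ABI"]], tolerance = 1e-8)
    expect_equal(t1a$sumsq[1], R[["A"]])
    expect_equal(t1b$sumsq[2], R[["B"]])
    # Type II definitions
    expect_equal(t2$sumsq[1:3],
                 unname(c(R["AB"] - R["B"], R["AB"] - R["A"],
                          R["ABI"] - R["AB"])), tolerance = 1e-10)
    # Type III definitions
    expect_equal(t3$sumsq[1:3],
                 unname(c(R["ABI"] - R["BI"], R["ABI"] - R["AI"],
                          R["ABI"] - R["AB"])), tolerance = 1e-10)
    # z is the interaction SS in every type, both codings
    z <- R[["ABI"]] - R[["AB"]]
    expect_equal(t1a$sumsq[3], z)
    expect_equal(t2$sumsq[3], z)
    expect_equal(t3$sumsq[3], z)
    expect_equal(ss_type3(ft)$sumsq[3], z, tolerance = 1e-8)
    # SS I and II are coding-invariant; SS III main effects generally not
    expect_equal(ss_type2(ft)$sumsq, t2$sumsq, tolerance = 1e-8)
    expect_equal(ss_type1(ft, "A_first")$sumsq, t1a$sumsq, tolerance = 1e-8)
  }
})

test_that("on balanced contrast-coded samples all SS types coincide", {
  s <- generate_sample(c(6, 6, 6, 6), effect_spec(beta3 = 4), seed = 99)
  f <- nested_fits(s, "contrast")
  ss <- ss_type1(f, "A_first")$sumsq
  expect_equal(ss_type1(f, "B_first")$sumsq, ss, tolerance = 1e-10)
  expect_equal(ss_type2(f)$sumsq, ss, tolerance = 1e-10)
  expect_equal(ss_type3(f)$sumsq, ss, tolerance = 1e-10)
})

test_that("Type III depends on the coding: toy gives 16 (treatment) vs 72 (contrast)", {
  toy <- toy_sample()
  expect_equal(ss_type3(nested_fits(toy, "treatment"))$sumsq[1], 16)
  expect_equal(ss_type3(nested_fits(toy, "contrast"))$sumsq[1], 72)
})

test_that("commonality components satisfy the inclusion-exclusion identities", {
  toy <- toy_sample()
  v <- venn_components(nested_fits(toy, "contrast"))
  got <- setNames(v$sumsq, v$component)
  expect_equal(got, c(t = 72, u = 0, v = 0, w = 0, x = 72, y = 0, z = 8))

  for (seed in 46:60) {
    s <- random_sample(seed)
    for (coding in c("contrast", "treatment")) {
      f <- nested_fits(s, coding)
      vc <- venn_components(f)
      cmp <- setNames(vc$sumsq, vc$component)
      R <- f$R
      expect_equal(sum(cmp[c("t", "u", "v", "w")]), R[["A"]], tolerance = 1e-8)
      expect_equal(sum(cmp[c("x", "y", "u", "v")]), R[["B"]], tolerance = 1e-8)
      expect_equal(sum(cmp[c("z", "w", "y", "v")]), R[["I"]], tolerance = 1e-8)
      expect_equal(sum(cmp), R[["ABI"]], tolerance = 1e-8)
    }
    # u + v = R(A) + R(B) - R(A,B): identical under both codings
    uv <- function(coding) {
      vc <- venn_components(nested_fits(s, coding))
      sum(vc$sumsq[vc$component %in% c("u", "v")])
    }
    expect_equal(uv("contrast"), uv("treatment"), tolerance = 1e-8)
  }
})

test_that("treatment- and contrast-coded coefficients obey the reparameterization", {
  for (seed in 61:75) {
    s <- random_sample(seed)
    b <- setNames(coef_2x2(s, "treatment")$estimate,
                  coef_2x2(s, "treatment")$term)
    cc <- setNames(coef_2x2(s, "contrast")$estimate,
                   coef_2x2(s, "contrast")$term)
    expect_equal(cc[["A:B"]], b[["A:B"]] / 4, tolerance = 1e-8)
    expect_equal(cc[["A"]], b[["A"]] / 2 + b[["A:B"]] / 4, tolerance = 1e-8)
    expect_equal(cc[["B"]], b[["B"]] / 2 + b[["A:B"]] / 4, tolerance = 1e-8)
    expect_equal(cc[["(Intercept)"]],
                 b[["(Intercept)"]] + (b[["A"]] + b[["B"]]) / 2 + b[["A:B"]] / 4,
                 tolerance = 1e-8)
  }
})

test_that("SS agree with the established ANOVA implementations", {
  library(car)
  for (seed in 76:81) {
    s <- random_sample(seed)
    df <- data.frame(a = s$a, b = s$b, y = s$y)
    fit_t <- stats::lm(y ~ a * b, df,
                       contrasts = list(a = "contr.treatment",
                                        b = "contr.treatment"))
    fit_c <- stats::lm(y ~ a * b, df,
                       contrasts = list(a = "contr.sum", b = "contr.sum"))
    # sequential SS
    seq_ss <- stats::anova(fit_t)
    expect_equal(ss_type1(nested_fits(s))$sumsq[1:3],
                 seq_ss[c("a", "b", "a:b"), "Sum Sq"], tolerance = 1e-8,
                 ignore_attr = TRUE)
    # Type II (coding-free)
    a2 <- car::Anova(fit_t, type = 2)
    expect_equal(ss_type2(nested_fits(s))$sumsq[1:3],
                 a2[c("a", "b", "a:b"), "Sum Sq"], tolerance = 1e-8,
                 ignore_attr = TRUE)
    # Type III under each coding
    a3c <- car::Anova(fit_c, type = 3)
    expect_equal(ss_type3(nested_fits(s, "contrast"))$sumsq[1:3],
                 a3c[c("a", "b", "a:b"), "Sum Sq"], tolerance = 1e-8,
                 ignore_attr = TRUE)
    a3t <- car::Anova(fit_t, type = 3)
    expect_equal(ss_type3(nested_fits(s, "treatment"))$sumsq[1:3],
                 a3t[c("a", "b", "a:b"), "Sum Sq"], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("F tests: degenerate zero-SS effects and an independent p oracle", {
  # cell means all equal but noise present: every effect SS is 0, F = 0, p = 1
  flat <- tibble::tibble(
    a = factor(rep(c("C", "C", "T", "T"), each = 2)),
    b = factor(rep(c("C", "T", "C", "T"), each = 2)),
    y = rep(c(1, -1), 4))
  ft <- f_test(ss_type2(nested_fits(flat)))
  expect_equal(ft$statistic, rep(0, 3))
  expect_equal(ft$p.value, rep(1, 3))
  expect_false(any(ft$reject))

  # p values agree with the F CDF evaluated through the beta distribution
  for (seed in 82:86) {
    s <- random_sample(seed)
    tab <- effect_rows(ss_type3(nested_fits(s)))
    d2 <- nrow(s) - 4
    p_beta <- stats::pbeta(d2 / (d2 + tab$statistic), d2 / 2, 1 / 2)
    expect_equal(tab$p.value, p_beta, tolerance = 1e-10)
  }
})

test_that("tidy and glance expose the fit summaries", {
  f <- nested_fits(toy_sample())
  td <- tidy(f)
  expect_identical(td$subset, c("A", "B", "I", "AB", "AI", "BI", "ABI"))
  expect_equal(td$sumsq, unname(f$R))
  g <- glance(f)
  expect_equal(g$r.squared, 152 / 152)
  expect_identical(glance(ss_type2(f))$ss_type, "II")
})
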