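test_that("TOST behaves correctly on canonical paired samples", {
  # identical pairs: decisive equivalence
  a <- stats::rnorm(20, 10, 1)
  r0 <- tost_equivalence(a, a, margin = 3)
  expect_equal(r0$mean_abs_diff, 0)
  expect_lt(r0$p_tost, 1e-10)
  # mean difference exactly on the margin: boundary one-sided test p = 0.5
  set.seed(5)
  d <- stats::rnorm(20, 0, 0.5)
  d <- d - mean(d) + 3
  r1 <- tost_equivalence(d, rep(0, 20), margin = 3)
  expect_equal(r1$p_tost, 0.5, tolerance = 1e-12)
  # degenerate zero-variance differences
  r2 <- tost_equivalence(rep(1, 5), rep(0, 5), margin = 3)
  expect_equal(r2$p_tost, 0)
  r3 <- tost_equivalence(rep(5, 5), rep(0, 5), margin = 3)
  expect_equal(r3$p_tost, 1)
})

test_that("TOST p is non-increasing in the margin", {
  set.seed(8)
  a <- stats::rnorm(15, 0, 1)
  b <- stats::rnorm(15, 0.4, 1)
  ps <- vapply(seq(0.5, 5, by = 0.25), function(m) {
    tost_equivalence(a, b, margin = m)$p_tost
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("TOST CI matches the paired t interval", {
  set.seed(9)
  a <- stats::rnorm(12, 3, 2)
  b <- stats::rnorm(12, 2, 2)
  r <- tost_equivalence(a, b, margin = 3)
  tt <- stats::t.test(a - b)
  expect_equal(c(r$ci_low, r$ci_high), unname(tt$conf.int),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Steel-Dwass with two groups reduces to the normal Wilcoxon", {
  set.seed(10)
  for (rep in 1:5) {
    g1 <- sample(0:8, 12, replace = TRUE)  # ties on purpose
    g2 <- sample(2:10, 9, replace = TRUE)
    sd2 <- steel_dwass(list(a = g1, b = g2))
    expect_equal(sd2$p[1, 2], oracle_wilcox_p(g1, g2), tolerance = 1e-6)
  }
  # identical groups: no evidence of any difference
  g <- c(1, 2, 3, 4, 5)
  expect_gt(steel_dwass(list(g, g))$p[1, 2], 0.95)
  # fully tied pooled pair: degenerate, p = 1
  expect_equal(steel_dwass(list(rep(2, 4), rep(2, 5)))$p[1, 2], 1)
})

test_that("Steel-Dwass k=3 is close to the permutation reference", {
  groups <- list(a = c(1, 2, 2, 3), b = c(2, 3, 3, 4), c = c(4, 5, 5, 6))
  got <- steel_dwass(groups)
  ref <- oracle_permutation_reference(groups, B = 4000, seed = 2)
  pairs <- utils::combn(3, 2)
  for (k in seq_len(ncol(pairs))) {
    expect_lt(abs(got$p[pairs[1, k], pairs[2, k]] - ref[k]), 0.1)
  }
})

test_that("Tukey HSD matches the base-R reference implementation", {
  set.seed(11)
  groups <- list(a = stats::rnorm(8, 0), b = stats::rnorm(8, 1),
                 c = stats::rnorm(8, 1.2))
  got <- tukey_hsd(groups)
  y <- unlist(groups)
  g <- factor(rep(names(groups), lengths(groups)))
  ref <- stats::TukeyHSD(stats::aov(y ~ g))$g[, "p adj"]
  expect_equal(got$p["b", "a"], unname(ref["b-a"]), tolerance = 1e-4)
  expect_equal(got$p["c", "a"], unname(ref["c-a"]), tolerance = 1e-4)
  expect_equal(got$p["c", "b"], unname(ref["c-b"]), tolerance = 1e-4)
  # unbalanced groups use the Tukey-Kramer correction, as does TukeyHSD
  groups2 <- list(a = stats::rnorm(6), b = stats::rnorm(10, 0.8),
                  c = stats::rnorm(7, 1.5))
  got2 <- tukey_hsd(groups2)
  y2 <- unlist(groups2)
  g2 <- factor(rep(names(groups2), lengths(groups2)))
  ref2 <- stats::TukeyHSD(stats::aov(y2 ~ g2))$g2[, "p adj"]
  expect_equal(got2$p["c", "b"], unname(ref2["c-b"]), tolerance = 1e-4)
})

test_that("Tukey HSD limit cases: equal means and extreme separation", {
  same <- list(a = c(1, 2, 3), b = c(3, 1, 2), c = c(2, 3, 1))
  expect_true(all(tukey_hsd(same)$p >= 0.999))
  sep <- list(a = stats::rnorm(8, 0, 1), b = stats::rnorm(8, 0.2, 1),
              far = stats::rnorm(8, 100, 1))
  expect_lt(tukey_hsd(sep)$p["far", "a"], 1e-6)
  # zero within-group variance: exact 0/1 decisions
  z <- tukey_hsd(list(a = c(1, 1), b = c(1, 1), c = c(2, 2)))
  expect_equal(z$p["a", "b"], 1)
  expect_equal(z$p["a", "c"], 0)
})

test_that("pairwise tables are label-order invariant and shift invariant", {
  set.seed(12)
  groups <- list(a = stats::rnorm(6), b = stats::rnorm(6, 1),
                 c = stats::rnorm(6, 2))
  perm <- groups[c(3, 1, 2)]
  for (fn in list(steel_dwass, tukey_hsd)) {
    t1 <- fn(groups)
    t2 <- fn(perm)
    expect_equal(t2$p["a", "c"], t1$p["a", "c"], tolerance = 1e-12)
    shifted <- lapply(groups, function(g) g + 57.3)
    t3 <- fn(shifted)
    expect_equal(t3$p, t1$p, tolerance = 1e-9)
    expect_true(all(t1$p >= 0 & t1$p <= 1))
    expect_equal(t1$p, t(t1$p))
  }
})
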