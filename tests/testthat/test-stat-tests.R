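# Kappa, Fisher exact, Mann-Whitney, Student's t, group comparison.

test_that("Cohen's kappa closed forms, symmetry and relabel invariance", {
  expect_equal(cohens_kappa(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(cohens_kappa(c(1, 1, 0, 0), c(1, 0, 0, 0)), 0.5)
  set.seed(3)
  a <- sample(c("x", "y", "z"), 300, replace = TRUE)
  b <- sample(c("x", "y", "z"), 300, replace = TRUE)
  k <- cohens_kappa(a, b)
  expect_lt(abs(k), 0.12) # independent raters: near-zero agreement
  expect_equal(cohens_kappa(a, b), cohens_kappa(b, a))
  relabel <- c(x = "B", y = "C", z = "A")
  expect_equal(cohens_kappa(relabel[a], relabel[b]), k)
  expect_equal(cohens_kappa(rep("u", 5), rep("u", 5)), 1)
  expect_error(cohens_kappa(character(0), character(0)), "empty")
})

test_that("Fisher exact matches hypergeometric enumeration", {
  # independent enumeration oracle over all tables with the fixed margins
  enum_fisher <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
    xs <- max(0, k - n):min(k, m)
    probs <- dhyper(xs, m, n, k)
    sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(3, 0, 0, 3), 0.1)
  expect_equal(fisher_exact_2x2(0, 0, 4, 5), 1)
  set.seed(17)
  for (i in 1:200) {
    cells <- rpois(4, 4)
    expect_equal(fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4]),
                 enum_fisher(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
  }
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("Mann-Whitney exact branch enumerates correctly", {
  r <- mann_whitney_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p_two_sided, 0.1) # 2 of the 20 assignments as extreme
  expect_match(r$method, "exact")

  # identical multisets: central U, p = 1
  r <- mann_whitney_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$u, 4.5)
  expect_equal(r$p_two_sided, 1)

  # fully separated 5 vs 5: maximal U
  r <- mann_whitney_test(6:10, 1:5)
  expect_equal(r$u, 25)

  # exact branch with ties agrees with a direct permutation count
  x <- c(1, 1, 2); y <- c(2, 3, 3)
  r <- mann_whitney_test(x, y)
  pool <- c(x, y)
  us <- apply(utils::combn(6, 3), 2, function(i) {
    rk <- rank(c(pool[i], pool[-i]))
    sum(rk[1:3]) - 6
  })
  expect_equal(r$p_two_sided, mean(abs(us - 4.5) >= abs(r$u - 4.5) - 1e-9))

  # large samples: tie-corrected normal approximation equals wilcox.test
  set.seed(23)
  x <- sample(0:5, 40, replace = TRUE)
  y <- sample(1:6, 35, replace = TRUE)
  r <- mann_whitney_test(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(r$p_two_sided, ref$p.value)
  expect_error(mann_whitney_test(numeric(0), 1:3), "non-empty")
})

test_that("pooled t-test closed form and degenerate flags", {
  x <- c(1, 2, 3, 4)
  y <- c(3, 4, 5, 6)
  r <- students_t_test(x, y)
  sp2 <- (3 * var(x) + 3 * var(y)) / 6
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(r$t, t_hand)
  expect_equal(r$df, 6)
  expect_equal(r$p_two_sided, 2 * pt(-abs(t_hand), 6))

  r <- students_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r$t, 0)
  expect_equal(r$p_two_sided, 1)
  expect_true(r$degenerate)
  r <- students_t_test(c(0, 0), c(1, 1))
  expect_true(r$degenerate)
  expect_true(is.infinite(r$t))
})

test_that("group comparison dispatches by variable type", {
  set.seed(6)
  df <- data.frame(
    g = rep(c(1, 0), each = 30),
    cont_same = rep(1:30, 2),
    flag_same = rep(c(0, 1), 30),
    flag_equal_g = rep(c(1, 0), each = 30),
    cont_shift = c(rnorm(30, 2), rnorm(30, 0))
  )
  out <- compare_groups(df, "g",
                        c(cont_same = "continuous", flag_same = "categorical",
                          flag_equal_g = "categorical",
                          cont_shift = "continuous"))
  expect_equal(nrow(out), 4)
  expect_equal(out$p_value[out$variable == "flag_same"], 1)
  expect_lt(out$p_value[out$variable == "flag_equal_g"], 0.001)
  expect_lt(out$p_value[out$variable == "cont_shift"], 0.001)
  expect_gt(out$p_value[out$variable == "cont_same"], 0.9)
  expect_error(compare_groups(df, "g", c(cont_same = "weird")),
               "unknown variable type")
  expect_error(compare_groups(df, "g", c(nope = "continuous")),
               "not in data")
})

test_that("null continuous variables give calibrated type-I p-values", {
  # under H0 the Mann-Whitney p-value should be roughly uniform
  set.seed(88)
  ps <- replicate(200, {
    mann_whitney_test(rnorm(25), rnorm(25))$p_two_sided
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_gt(mean(ps > 0.05), 0.85)
})
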