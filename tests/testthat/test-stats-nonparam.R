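test_that("signed-rank test handles degenerate and textbook cases", {
  expect_warning(r <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_equal(r$p_value, 1)

  r5 <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), rep(0, 5))
  expect_equal(r5$p_value, 0.0625)
  expect_equal(r5$method, "exact")
  expect_error(wilcoxon_signed_rank(c(1, 2), c(0, 0)), "at least 3")
})

test_that("exact signed-rank p equals the enumeration oracle", {
  withr::local_seed(17)
  for (i in 1:15) {
    n <- sample(4:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(wilcoxon_signed_rank(x, y)$p_value,
                 wilcoxon_enum_oracle(x, y), tolerance = 1e-12)
  }
  # with ties in |differences|
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(0, 0, 1, 6, 3, 3)  # |d| = 1,2,2,2,2,3
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               wilcoxon_enum_oracle(x, y), tolerance = 1e-12)
})

test_that("signed-rank p is invariant under sign flip and matches base R", {
  withr::local_seed(18)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               wilcoxon_signed_rank(y, x)$p_value)
  # asymptotic branch against the standard implementation
  x2 <- rnorm(40); y2 <- rnorm(40)
  got <- wilcoxon_signed_rank(x2, y2)$p_value
  want <- stats::wilcox.test(x2, y2, paired = TRUE, exact = FALSE,
                             correct = TRUE)$p.value
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("Mann-Whitney exact enumeration covers separation and ties", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  withr::local_seed(19)
  for (i in 1:10) {
    a <- rnorm(5); b <- rnorm(5)
    expect_equal(mann_whitney_u(a, b)$p_value,
                 mann_whitney_perm_oracle(a, b), tolerance = 1e-12)
    expect_equal(mann_whitney_u(a, b)$p_value,
                 mann_whitney_u(b, a)$p_value)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("shifting one group apart never increases the exact p", {
  withr::local_seed(20)
  a <- rnorm(6); b <- rnorm(6)
  shifts <- c(0, 0.5, 1, 2, 4, 8)
  ps <- vapply(shifts, function(s) mann_whitney_u(a + s, b)$p_value,
               numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("asymptotic p approaches exact p for moderate n", {
  withr::local_seed(21)
  a <- rnorm(13); b <- rnorm(13)
  p_ex <- mann_whitney_perm_oracle(a[1:8], b[1:8])
  p_as <- mann_whitney_u(a[1:8], b[1:8], exact_limit = 0)$p_value
  expect_lt(abs(p_ex - p_as), 0.02)
})

test_that("omnibus tests wrap base R with degenerate guards", {
  m <- matrix(rep(1:3, each = 4), nrow = 4)
  m_same <- matrix(5, nrow = 4, ncol = 3)
  expect_equal(friedman_rank(m_same)$p_value, 1)
  expect_error(friedman_rank(matrix(c(1, NA, 2, 3, 4, 5), 2)), "incomplete")
  expect_lt(friedman_rank(m)$p_value, 0.05)

  expect_equal(kruskal_wallis(list(a = c(1, 1), b = c(1, 1)))$p_value, 1)
  kw <- kruskal_wallis(list(rnorm(5), rnorm(5) + 10, rnorm(5)))
  expect_lt(kw$p_value, 0.05)
})

test_that("Kruskal-Wallis with k=2 agrees with the Mann-Whitney z test", {
  withr::local_seed(22)
  a <- rnorm(15); b <- rnorm(15) + 0.7
  kw <- kruskal_wallis(list(a, b))
  mw <- mann_whitney_u(a, b, exact_limit = 0, correct = FALSE)
  expect_lt(abs(kw$p_value - mw$p_value), 1e-6)
})

test_that("null rejection rate of the omnibus test is calibrated", {
  withr::local_seed(23)
  rej <- vapply(1:10000, function(i) {
    kruskal_wallis(list(rnorm(10), rnorm(10), rnorm(10)))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})

test_that("identical constant groups give adjusted p of 1 everywhere", {
  g <- list(a = rep(1, 5), b = rep(1, 5), c = rep(1, 5))
  expect_true(all(steel_dwass(g)$comparisons$p_adj == 1))
  expect_true(all(steel_test(g, control = "a")$comparisons$p_adj == 1))
})

test_that("Steel-Dwass with k=2 reduces to the rank-sum z test", {
  withr::local_seed(24)
  a <- rnorm(8); b <- rnorm(8) + 1
  sd2 <- steel_dwass(list(a, b))
  z <- sd2$comparisons$z[1]
  expect_equal(sd2$comparisons$p_adj[1], 2 * pnorm(-abs(z)),
               tolerance = 1e-6)
})

test_that("a strongly shifted group is flagged by both post-hoc tests", {
  withr::local_seed(25)
  hits_sd <- 0; hits_other <- 0; hits_steel <- 0
  n_rep <- 300
  for (i in 1:n_rep) {
    g <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10) + 10)
    cmp <- steel_dwass(g)$comparisons
    ac <- cmp$p_adj[cmp$group1 == "a" & cmp$group2 == "c"]
    bc <- cmp$p_adj[cmp$group1 == "b" & cmp$group2 == "c"]
    ab <- cmp$p_adj[cmp$group1 == "a" & cmp$group2 == "b"]
    hits_sd <- hits_sd + (ac < 0.05 && bc < 0.05)
    hits_other <- hits_other + (ab >= 0.05)
    st <- steel_test(g, control = "a")$comparisons
    hits_steel <- hits_steel + (st$p_adj[st$group1 == "c"] < 0.05)
  }
  expect_gte(hits_sd / n_rep, 0.95)
  expect_gte(hits_other / n_rep, 0.9)
  expect_gte(hits_steel / n_rep, 0.95)
})

test_that("Steel quadrature tail matches a Monte-Carlo evaluation", {
  mc_tail <- function(q, m, n = 2e5) {
    w <- rnorm(n)
    mx <- abs(sweep(matrix(rnorm(n * m), n), 1, w, "+")) / sqrt(2)
    mean(apply(mx, 1, max) >= q)
  }
  withr::local_seed(26)
  for (m in 2:3) {
    for (q in c(1.0, 2.0, 2.5)) {
      expect_lt(abs(sleepfp:::steel_max_tail(q, m) - mc_tail(q, m)), 0.01)
    }
  }
  # m = 1 reduces to the two-sided normal tail
  expect_equal(sleepfp:::steel_max_tail(1.96, 1), 2 * pnorm(-1.96),
               tolerance = 1e-6)
})

test_that("test objects tidy into standard tables", {
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), rep(0, 5))
  td <- tidy(r)
  expect_true(all(c("test", "statistic", "p_value", "method") %in% names(td)))
  g <- glance(steel_dwass(list(rnorm(5), rnorm(5), rnorm(5))))
  expect_equal(g$n_comparisons, 3L)
  expect_equal(p_stars(c(0.004, 0.04, 0.4)), c("**", "*", ""))
})
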