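test_that("Mann-Whitney matches exhaustive enumeration for n <= 7", {
  set.seed(11)
  for (n1 in 2:7) {
    for (n2 in c(n1, min(7, n1 + 2))) {
      for (rep in 1:3) {
        x <- rnorm(n1)
        y <- rnorm(n2, mean = rep - 2)
        a <- group_sample("HC", "SL", x)
        b <- group_sample("FOGoff", "SL", y)
        res <- compare_groups(a, b, "non_normal")
        expect_equal(res$test, "mann_whitney_u")
        expect_equal(res$p_value, mw_exact_oracle(x, y), tolerance = 1e-12)
      }
    }
  }
  # {1,2,3} vs {4,5,6}: most extreme of the C(6,3) = 20 orderings
  p <- compare_groups(group_sample("HC", "SL", c(1, 2, 3)),
                      group_sample("FOGoff", "SL", c(4, 5, 6)),
                      "non_normal")$p_value
  expect_equal(p, 2 / 20)
})

test_that("p-values are symmetric in group order and self-tests give 1", {
  set.seed(12)
  x <- rnorm(10)
  y <- rnorm(12, 0.5)
  a <- group_sample("HC", "SP", x)
  b <- group_sample("FOGon", "SP", y)
  for (gate in c("normal", "non_normal")) {
    expect_equal(compare_groups(a, b, gate)$p_value,
                 compare_groups(b, a, gate)$p_value)
  }
  self <- compare_groups(a, group_sample("FOGon", "SP", x), "normal")
  expect_equal(self$p_value, 1, tolerance = 1e-9)
  expect_error(compare_groups(a, group_sample("HC", "SL", x), "normal"),
               class = "freezekin_parameter")
})

test_that("the normality gate classifies clean and heavy-tailed draws", {
  # per-group gate behaviour: a single clean normal group should pass in
  # ~95% of repetitions (Shapiro-Wilk type-I 5%), a heavy-tailed group
  # should fail in the vast majority. (With k groups the conservative
  # any-group rule compounds to ~0.95^k, which the type-I criterion below
  # covers at the whole-procedure level.)
  set.seed(13)
  normal_hits <- 0L
  lognormal_hits <- 0L
  for (rep in 1:100) {
    g <- list(group_sample("HC", "SL", rnorm(20)))
    if (normality_gate(g) == "normal") normal_hits <- normal_hits + 1L
    h <- list(group_sample("HC", "SL", rlnorm(20, sdlog = 1)))
    if (normality_gate(h) == "non_normal") lognormal_hits <- lognormal_hits + 1L
  }
  expect_gte(normal_hits, 90)
  expect_gte(lognormal_hits, 80)
  expect_error(normality_gate(list(group_sample("HC", "SL", rep(1, 10)))),
               class = "freezekin_gate")
  expect_error(normality_gate(list(group_sample("HC", "SL", c(1, 2)))),
               class = "freezekin_gate")
})

test_that("gate + test keeps its nominal type-I error", {
  set.seed(14)
  n_sim <- 1000
  rejections <- 0L
  for (i in seq_len(n_sim)) {
    a <- group_sample("HC", "SL", rnorm(20))
    b <- group_sample("FOGoff", "SL", rnorm(20))
    gate <- normality_gate(list(a, b))
    if (compare_groups(a, b, gate)$p_value < 0.05) {
      rejections <- rejections + 1L
    }
  }
  rate <- rejections / n_sim
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("a 1-SD shift is detected in most repetitions", {
  set.seed(15)
  hits <- 0L
  for (i in 1:200) {
    a <- group_sample("HC", "SL", rnorm(15))
    b <- group_sample("FOGoff", "SL", rnorm(15, mean = 1))
    if (compare_groups(a, b, "normal")$p_value < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / 200, 0.5)
})

test_that("the comparison grid runs the eight study pairs", {
  co <- generate_cohort(cohort_spec(seed = 606))
  long <- cohort_long(co$subjects)
  grid <- run_comparison_grid(long[long$parameter == "SL", ])
  expect_equal(nrow(grid), 8)
  expect_setequal(paste(grid$group_a, grid$group_b),
                  c("HC PDoff", "HC PDon", "HC NOFOGoff", "HC NOFOGon",
                    "HC FOGoff", "HC FOGon", "NOFOGoff FOGoff",
                    "NOFOGon FOGon"))
  expect_true(all(grid$p_value >= 0 & grid$p_value <= 1))
  # HC-only input: all pairs skipped with warnings
  hc_only <- long[long$group == "HC" & long$parameter == "SL", ]
  warns <- testthat::capture_warnings(res <- run_comparison_grid(hc_only))
  expect_equal(nrow(res), 0)
  expect_length(warns, 8)
})

test_that("identical group distributions reject at the nominal rate", {
  set.seed(16)
  sig <- 0L
  n_rep <- 50
  for (i in seq_len(n_rep)) {
    long <- do.call(rbind, lapply(c("HC", "NOFOGoff", "NOFOGon", "FOGoff",
                                    "FOGon"), function(g) {
      data.frame(group = g, parameter = "SL", value = rnorm(15, 1.2, 0.15))
    }))
    long <- pool_pd_groups(long)
    grid <- run_comparison_grid(long)
    sig <- sig + sum(grid$p_value < 0.05)
  }
  expect_lte(sig / (8 * n_rep), 0.10)
})

test_that("star annotations follow the 0.05/0.01/0.001 thresholds", {
  expect_equal(freezekin:::p_stars(c(0.2, 0.04, 0.009, 5e-4)),
               c("", "*", "**", "***"))
})
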