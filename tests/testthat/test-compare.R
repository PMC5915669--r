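test_that("two-sample t matches hand arithmetic and is antisymmetric", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  tt <- pair_t_test(a, b)
  # equal variances: se = sqrt(1/3 + 1/3), t = -3/se
  expect_equal(tt$t, -3 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(round(tt$t, 3), -3.674)
  tt2 <- pair_t_test(b, a)
  expect_equal(tt2$t, -tt$t)
  expect_equal(tt2$p, tt$p)
  expect_equal(tt2$ci_low, -tt$ci_high)
  expect_equal(tt2$ci_high, -tt$ci_low)
  # identical samples: t = 0, p = 1, symmetric CI
  tt3 <- pair_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tt3$t, 0)
  expect_equal(tt3$p, 1)
  expect_equal(tt3$ci_low, -tt3$ci_high)
  # degenerate: both constant
  tt4 <- pair_t_test(c(2, 2), c(2, 2))
  expect_true(tt4$degenerate)
})

test_that("pooled and Welch variants agree when variances are equal", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  expect_equal(pair_t_test(a, b, var_equal = TRUE)$t,
               pair_t_test(a, b, var_equal = FALSE)$t)
  expect_equal(pair_t_test(a, b, var_equal = TRUE)$df, 4)
})

test_that("Hommel adjustment equals the exhaustive closed-testing oracle", {
  expect_equal(hommel_adjust(0.04), 0.04)
  expect_equal(hommel_adjust(c(0.01, 0.02, 0.03)),
               closed_testing_oracle(c(0.01, 0.02, 0.03)))
  set.seed(42)
  grid <- seq(0.005, 1, by = 0.005)
  for (r in 1:200) {
    m <- sample(1:6, 1)
    p <- sample(grid, m, replace = TRUE)
    expect_equal(hommel_adjust(p), closed_testing_oracle(p),
                 tolerance = 1e-12)
  }
  expect_error(hommel_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Hommel is bounded by raw p and Bonferroni, and is monotone", {
  set.seed(7)
  for (r in 1:50) {
    p <- runif(sample(2:6, 1))
    h <- hommel_adjust(p)
    expect_true(all(h >= p - 1e-15))
    expect_true(all(h <= pmin(1, length(p) * p) + 1e-15))
    # raising one raw p never lowers any adjusted p
    j <- sample(seq_along(p), 1)
    p2 <- p; p2[j] <- min(1, p2[j] + runif(1, 0, 1 - p2[j]))
    expect_true(all(hommel_adjust(p2) >= h - 1e-12))
  }
})

test_that("Cohen's d matches hand arithmetic and is scale invariant", {
  expect_equal(cohens_d(c(1, 2, 3), c(4, 5, 6)), 3.0)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- rnorm(20); b <- rnorm(20, 1)
  expect_equal(cohens_d(5 * a + 2, 5 * b + 2), cohens_d(a, b),
               tolerance = 1e-12)
  expect_true(is.na(cohens_d(c(1, 1), c(1, 1))))
})

test_that("effect-size bands reproduce the conventional labels", {
  expect_equal(effect_size_band(0.97), "large-very large")
  expect_equal(effect_size_band(3.18), "huge")
  expect_equal(effect_size_band(0.05), "very small-small")
  expect_equal(effect_size_band(0.002), "very small")
  expect_equal(effect_size_band(2.0), "huge")
  expect_equal(effect_size_band(0.2), "small-medium")
  expect_equal(effect_size_band(c(0.6, 1.0)),
               c("medium-large", "large-very large"))
})

test_that("pairwise comparison produces all pairs with a joint Hommel family", {
  set.seed(9)
  members <- tibble::tibble(
    community = rep(paste0("c", 1:6), each = 30),
    mean4 = rnorm(180, rep(c(8, 8.2, 8.4, 8.6, 8.8, 9), each = 30))
  )
  cmp <- pairwise_compare(members, "mean4")
  expect_equal(nrow(cmp), choose(6, 2))
  expect_equal(cmp$p_adj, hommel_adjust(cmp$p_raw))
  expect_true(all(cmp$p_adj >= cmp$p_raw - 1e-15))
  # ordering: first community of each pair has the larger sample mean
  for (i in seq_len(nrow(cmp))) {
    ma <- mean(members$mean4[members$community == cmp$community_a[i]])
    mb <- mean(members$mean4[members$community == cmp$community_b[i]])
    expect_gte(ma, mb)
    expect_equal(sign(cmp$t[i]), sign(ma - mb))
  }
  # band labels re-derive from d
  expect_equal(cmp$band, effect_size_band(cmp$d))
})

test_that("identical communities show no adjusted significance beyond chance", {
  set.seed(123)
  hits <- replicate(300, {
    members <- tibble::tibble(community = rep(c("a", "b"), each = 60),
                              y = rnorm(120))
    any(pairwise_compare(members, "y")$p_adj < 0.05)
  })
  # nominal 5% level, 300 replicates: allow 3 binomial SDs
  expect_lte(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("an injected shift at n = 200 members is detected decisively", {
  set.seed(321)
  members <- tibble::tibble(
    community = rep(c("a", "b"), each = 200),
    y = c(rnorm(200, 8), rnorm(200, 9))  # one-grade shift, sd 1
  )
  cmp <- pairwise_compare(members, "y")
  expect_lt(cmp$p_adj, 0.001)
})
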