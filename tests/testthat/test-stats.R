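test_that("identical groups give H = 0, p = 1", {
  r <- kruskal_wallis(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(r$H, 0)
  expect_equal(r$p, 1)
  r2 <- kruskal_wallis(list(a = rep(4, 5), b = rep(4, 5)))
  expect_equal(r2$H, 0)
  expect_equal(r2$p, 1)
})

test_that("H matches the hand-rank value on a no-tie example", {
  groups <- list(g1 = 1:4, g2 = 5:8, g3 = 9:12)
  # mean ranks 2.5, 6.5, 10.5; H = 12/(12*13) * (4*2.5^2+4*6.5^2+4*10.5^2) - 3*13
  H_hand <- 12 / (12 * 13) * (4 * 2.5^2 + 4 * 6.5^2 + 4 * 10.5^2) - 3 * 13
  r <- kruskal_wallis(groups)
  expect_equal(r$H, H_hand, tolerance = 1e-12)
  expect_equal(r$df, 2L)
})

test_that("H and p agree with the reference implementation, ties included", {
  set.seed(7)
  for (rep in 1:25) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(i)
      sample(1:8, sample(3:10, 1), replace = TRUE))
    names(groups) <- paste0("g", seq_len(k))
    r <- kruskal_wallis(groups)
    ref <- stats::kruskal.test(unlist(groups),
                               rep(seq_len(k), lengths(groups)))
    expect_equal(r$H, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(8)
  groups <- list(a = rnorm(10), b = rnorm(12, 0.5), c = rnorm(9, 1))
  h1 <- kruskal_wallis(groups)$H
  h2 <- kruskal_wallis(lapply(groups, exp))$H
  h3 <- kruskal_wallis(lapply(groups, function(x) 5 * x - 2))$H
  expect_equal(h1, h2, tolerance = 1e-12)
  expect_equal(h1, h3, tolerance = 1e-12)
})

test_that("null p-values are uniform across permuted labels", {
  set.seed(9)
  p <- replicate(1000, {
    x <- rnorm(36)
    kruskal_wallis(split(x, rep(1:3, each = 12)))$p
  })
  # ranks of finite samples tie occasionally; the tie warning only makes
  # the KS test conservative here
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("with 2 groups and no ties, KW matches the rank-sum normal test", {
  set.seed(10)
  x <- rnorm(60); y <- rnorm(60, 0.3)
  kw <- kruskal_wallis(list(a = x, b = y))
  w <- sum(rank(c(x, y))[1:60]) - 60 * 61 / 2
  z <- (w - 60 * 60 / 2) / sqrt(60 * 60 * 121 / 12)
  p_norm <- 2 * pnorm(-abs(z))
  expect_equal(kw$p, p_norm, tolerance = 0.01)
})

test_that("Dunn's test follows its definition on preselected pairs", {
  groups <- list(a = c(1, 5, 9), b = c(1, 5, 9), c = c(20, 25, 30),
                 d = c(2, 6, 8))
  res <- dunn_preselected(groups, list(c("a", "b"), c("a", "c"), c("a", "d")))
  expect_equal(res$z[1], 0)
  expect_equal(res$p_raw[1], 1)
  expect_equal(res$p_adjusted, pmin(1, res$p_raw * 3))
  expect_error(dunn_preselected(groups, list(c("a", "zzz"))), "unknown")
})

test_that("Dunn's z and p agree with an independent implementation", {
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(3:4, 1)
    groups <- lapply(seq_len(k), function(i)
      sample(seq(0, 20, by = 0.5), sample(4:9, 1), replace = TRUE))
    names(groups) <- letters[seq_len(k)]
    pairs <- list(c("a", "b"), c("a", "c"))
    res <- dunn_preselected(groups, pairs)
    for (i in seq_along(pairs)) {
      want <- dunn_pair_oracle(groups, pairs[[i]][1], pairs[[i]][2])
      expect_equal(res$z[i], want$z, tolerance = 1e-9)
      expect_equal(res$p_raw[i], want$p, tolerance = 1e-9)
    }
  }
})

test_that("significance tiers follow the star convention", {
  expect_equal(significance_tier(c(0.2, 0.04, 0.004, 4e-4, 4e-5)),
               c("ns", "*", "**", "***", "****"))
})

test_that("compare_conditions flags a strong shift and leaves nulls ns", {
  set.seed(12)
  hits <- 0L
  for (rep in 1:10) {
    obs <- data.frame(
      condition = rep(c("ctrl", "stress", "rescue"), each = 40),
      value = c(rnorm(40), rnorm(40, 3), rnorm(40)))
    cmp <- compare_conditions(obs, "metric",
                              list(c("ctrl", "stress"), c("ctrl", "rescue")))
    if (cmp$pairs$tier[1] == "****" && cmp$pairs$tier[2] == "ns")
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)

  flat <- data.frame(condition = rep(c("a", "b"), each = 10), value = 1)
  cmp0 <- compare_conditions(flat, "metric", list(c("a", "b")))
  expect_equal(cmp0$pairs$tier, "ns")
  expect_equal(cmp0$H, 0)
})

test_that("a condition without observations is an error", {
  obs <- data.frame(condition = rep("a", 5), value = 1:5)
  obs <- rbind(obs, data.frame(condition = "b", value = NA_real_))
  expect_error(compare_conditions(obs, "m", list(c("a", "b"))),
               "zero observations")
})
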