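test_that("spearman_test reproduces hand-ranked values and the t approximation", {
  expect_equal(spearman_test(1:10, 1:10)$rho, 1)
  expect_equal(spearman_test(1:10, 10:1)$rho, -1)
  # ranks (1,2,3,4,5) vs (1,3,2,5,4): sum d^2 = 4, rho = 1 - 6*4/(5*24)
  got <- spearman_test(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_equal(got$rho, 0.8)
  set.seed(19)
  x <- rnorm(50); y <- 0.4 * x + rnorm(50)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                   exact = FALSE))
  ours <- spearman_test(x, y)
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
  expect_error(spearman_test(1:2, 2:1), "at least 3")
})

test_that("spearman_test is invariant under strictly monotone transforms", {
  set.seed(20)
  x <- rexp(30); y <- rexp(30)
  base <- spearman_test(x, y)
  expect_equal(spearman_test(log(x), y^3)$rho, base$rho)
  expect_equal(spearman_test(log(x), y^3)$p.value, base$p.value)
})

test_that("exact spearman permutation p agrees with cor.test for small n", {
  set.seed(21)
  x <- rnorm(6); y <- rnorm(6)
  ours <- spearman_test(x, y, exact = TRUE)
  ref <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("kruskal_wallis matches the hand-computed tie-free H", {
  # groups (1,2), (3,4), (5,6) on ranks 1..6: H = 32/7
  got <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(got$statistic, 32 / 7, tolerance = 1e-12)
  expect_equal(got$df, 2)
  expect_equal(got$p.value, pchisq(32 / 7, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  # identical groups: mean ranks equal -> H = 0, p = 1
  same <- kruskal_wallis(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(kruskal_wallis(list(1:3)), "at least 2")
})

test_that("steel_dwass covers all pairs with familywise-calibrated p-values", {
  set.seed(22)
  g <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10) + 4, d = rnorm(10))
  out <- steel_dwass(g)
  expect_identical(nrow(out), 6L)
  expect_true(all(out$p_value >= 0 & out$p_value <= 1))
  sep <- out$p_value[(out$group_a == "c") != (out$group_b == "c")]
  expect_true(all(sep < 0.01))                    # no-overlap pairs
  expect_gt(out$p_value[out$group_a == "a" & out$group_b == "d"], 0.2)
  # identical groups among k -> p ~ 1 for that pair
  g2 <- list(a = 1:6, b = 1:6, c = rnorm(6))
  expect_gt(steel_dwass(g2)$p_value[1], 0.99)
  expect_error(steel_dwass(list(a = 1:5, b = 3)), "b")
  # deterministic
  expect_identical(steel_dwass(g), steel_dwass(g))
})

test_that("steel_dwass z is the tie-corrected standardised rank-sum statistic", {
  a <- c(1, 2, 2, 5); b <- c(2, 3, 7, 9, 11)
  out <- steel_dwass(list(a = a, b = b, c = c(100, 101)))
  r <- rank(c(a, b))
  U <- sum(r[1:4]) - 4 * 5 / 2
  tie <- sum(sapply(table(c(a, b)), function(t) t^3 - t))
  V <- 4 * 5 / 12 * ((9 + 1) - tie / (9 * 8))
  z <- (U - 10) / sqrt(V)
  row <- out[out$group_a == "a" & out$group_b == "b", ]
  expect_equal(row$statistic, z, tolerance = 1e-12)
  expect_equal(row$p_value,
               ptukey(sqrt(2) * abs(z), 3, Inf, lower.tail = FALSE),
               tolerance = 1e-12)
})
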