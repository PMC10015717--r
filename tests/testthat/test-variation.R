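test_that("pairwise variation averages |x_i - x_k| over the pair set", {
  m <- make_expr(rbind(g1 = c(1, 3, 0), g2 = c(2, 2, 2)),
                 genes = c("g1", "g2"), samples = c("a", "b", "c"))
  one <- pairwise_variation(m, pair_set("a", "b", kind = "sibling",
                                        stage = "s1"))
  expect_equal(one$raw_variation, c(2, 0))
  expect_equal(one$mean_expression, c(2, 2))
  # three samples with gene values (0,1,3): all pairs -> (1+3+2)/3 = 2
  m2 <- make_expr(matrix(c(0, 1, 3), 1), genes = "g",
                  samples = c("a", "b", "c"))
  md <- make_meta(c("a", "b", "c"), group = "F3")
  ap <- all_pairs(md, "s1", "F3")
  expect_equal(pairwise_variation(m2, ap)$raw_variation, 2)
  # identical samples -> all zeros
  m3 <- make_expr(cbind(c(1, 2), c(1, 2)), samples = c("a", "b"))
  expect_equal(pairwise_variation(
    m3, pair_set("a", "b", kind = "sibling"))$raw_variation, c(0, 0))
})

test_that("pairwise variation is symmetric in pair order and translation invariant", {
  set.seed(5)
  v <- matrix(runif(40, 0, 3), 10, 4)
  m <- make_expr(v, samples = c("a", "b", "c", "d"))
  p1 <- pair_set(c("a", "c"), c("b", "d"), kind = "sibling", stage = "s")
  p2 <- pair_set(c("b", "d"), c("a", "c"), kind = "sibling", stage = "s")
  expect_equal(pairwise_variation(m, p1)$raw_variation,
               pairwise_variation(m, p2)$raw_variation)
  v2 <- v; v2[3, ] <- v2[3, ] + 1.7          # shift one gene everywhere
  m2 <- make_expr(v2, samples = c("a", "b", "c", "d"))
  expect_equal(pairwise_variation(m2, p1)$raw_variation,
               pairwise_variation(m, p1)$raw_variation)
  expect_error(pairwise_variation(m, p1[0, ]), "empty")
})

test_that("running-median correction matches hand computations and the naive oracle", {
  tab <- data.frame(gene_id = sprintf("g%d", 1:5),
                    mean_expression = c(0.1, 0.5, 1, 2, 3),
                    raw_variation = c(1, 2, 3, 4, 5),
                    pairset_kind = "sibling", stage = "s",
                    stringsAsFactors = FALSE)
  out <- running_median_correction(tab, window = 3)
  expect_equal(out$corrected_variation, rep(0, 5))   # h = (0,1,1,1,0)
  # constant raw variation -> exactly zero everywhere
  tab$raw_variation <- rep(3.3, 5)
  expect_equal(running_median_correction(tab, 3)$corrected_variation,
               rep(0, 5))
  expect_error(running_median_correction(tab, 4), "odd")
  set.seed(77)
  n <- 400
  big <- data.frame(gene_id = sprintf("g%04d", sample(n)),
                    mean_expression = runif(n, 0, 3),
                    raw_variation = rexp(n), stringsAsFactors = FALSE)
  for (w in c(3, 51, 501)) {           # 501 > n exercises global shrink
    got <- running_median_correction(big, w)$corrected_variation
    want <- oracle_runmed_correction(big$mean_expression,
                                     big$raw_variation, big$gene_id, w)
    expect_equal(got, want, tolerance = 1e-12, info = paste("window", w))
  }
})

test_that("correction preserves gene identity and input order", {
  set.seed(8)
  n <- 100
  tab <- data.frame(gene_id = sprintf("g%03d", sample(n)),
                    mean_expression = rnorm(n, 2),
                    raw_variation = rexp(n), stringsAsFactors = FALSE)
  out <- running_median_correction(tab, 21)
  expect_identical(out$gene_id, tab$gene_id)
  expect_identical(out$raw_variation, tab$raw_variation)
  expect_identical(nrow(out), as.integer(n))
})

test_that("correction removes a planted mean-variance trend", {
  set.seed(123)
  n <- 10000
  me <- rgamma(n, 2, scale = 0.75)
  raw <- 0.02 + 0.3 * me + rnorm(n, 0, 0.3)    # monotone trend + noise
  tab <- data.frame(gene_id = sprintf("g%05d", 1:n), mean_expression = me,
                    raw_variation = raw, stringsAsFactors = FALSE)
  out <- running_median_correction(tab, 501)
  expect_gt(cor(raw, me, method = "spearman"), 0.5)
  expect_lt(abs(cor(out$corrected_variation, me, method = "spearman")),
            0.05)
})
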