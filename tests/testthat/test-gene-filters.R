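test_that("pair_differences assembles |x_i - x_k| per gene and pair", {
  m <- make_expr(rbind(c(1, 3, 0), c(2, 2, 5)), samples = c("a", "b", "c"))
  p <- pair_set(c("a", "a", "b"), c("b", "c", "c"),
                kind = "hybrid_all_pairs", stage = "s1")
  d <- pair_differences(m, p)
  expect_equal(unname(d), rbind(c(2, 1, 3), c(0, 3, 3)))
  expect_error(pair_differences(m, pair_set("a", "zz", kind = "sibling")),
               "zz")
})

test_that("genes with deviation far above technical error pass, others do not", {
  g <- 3
  sib <- matrix(rep(c(10, 0, 1), each = 13), nrow = g, ncol = 13,
                byrow = TRUE)
  tech <- matrix(rep(c(0, 0, 1), each = 6), nrow = g, ncol = 6,
                 byrow = TRUE)
  rownames(sib) <- rownames(tech) <- c("sep", "nullg", "same")
  rep <- technical_error_filter(sib, tech, alpha = 0.01)
  expect_true(rep$passed[rep$gene_id == "sep"])
  expect_lt(rep$p_value[rep$gene_id == "sep"], 0.01)
  # the enumeration oracle confirms full separation is significant at 0.01
  expect_lt(oracle_ranksum_p(rep(10, 13), rep(0, 6), "greater"), 0.01)
  expect_false(rep$passed[rep$gene_id == "nullg"])
  expect_false(rep$passed[rep$gene_id == "same"])
  expect_gt(rep$p_value[rep$gene_id == "same"], 0.4)
})

test_that("untestable genes are flagged not-passed, never passed", {
  sib <- matrix(c(5, NA, NA, NA, 5, 4, 3, 2), nrow = 2, byrow = TRUE)
  tech <- matrix(0.01, nrow = 2, ncol = 6)
  rownames(sib) <- rownames(tech) <- c("oneval", "ok")
  rep <- technical_error_filter(sib, tech)
  expect_true(is.na(rep$p_value[rep$gene_id == "oneval"]))
  expect_false(rep$passed[rep$gene_id == "oneval"])
  expect_true(rep$passed[rep$gene_id == "ok"])
})

test_that("technical diff modes: six raw combinations versus per-condition averages", {
  m <- make_expr(matrix(c(1, 2, 4, 8, 0, 0, 1, 1), nrow = 2, byrow = TRUE),
                 samples = sprintf("t%d", 1:4))
  md <- make_meta(sprintf("t%d", 1:4), group = "technical",
                  replicate_of = "c1")
  tp <- technical_pairs(md, "s1")
  expect_identical(length(tp), 1L)
  expect_identical(nrow(tp[[1]]), 6L)             # C(4,2)
  raw <- technical_diffs(m, tp, mode = "raw")
  expect_identical(dim(raw), c(2L, 6L))
  expect_setequal(raw[1, ], c(1, 3, 7, 2, 6, 4))
  avg <- technical_diffs(m, tp, mode = "averaged")
  expect_equal(avg[1, 1], mean(c(1, 3, 7, 2, 6, 4)))
  # a single averaged value per gene cannot feed a rank-sum test
  sib <- matrix(1, 2, 5)
  expect_error(technical_error_filter(sib, avg), ">= 2 technical values")
})

test_that("differential-mean filter selects shifted genes under the two-sided test", {
  set.seed(31)
  base <- matrix(rnorm(3 * 10, mean = 2, sd = 0.1), 3, 10)
  shifted <- base
  shifted[2, ] <- shifted[2, ] + 5
  m_a <- make_expr(pmax(base, 0), genes = c("flat", "shift", "flat2"),
                   samples = sprintf("a%d", 1:10))
  m_b <- make_expr(pmax(shifted, 0) + matrix(rnorm(30, 0, 0.1), 3),
                   genes = c("flat", "shift", "flat2"),
                   samples = sprintf("b%d", 1:10))
  rep <- differential_mean_filter(m_a, m_b, alpha = 0.01)
  expect_true(rep$passed[rep$gene_id == "shift"])
  expect_lt(rep$p_value[rep$gene_id == "shift"], 1e-3)
  expect_false(rep$passed[rep$gene_id == "flat"])
  rep_all <- differential_mean_filter(m_a, m_b, alpha = 1.0)
  expect_true(all(rep_all$passed))
  m_c <- make_expr(matrix(1, 2, 3), genes = c("x", "y"))
  expect_error(differential_mean_filter(m_a, m_c), "universes differ")
})

test_that("identical populations never pass the differential-mean filter", {
  m <- make_expr(matrix(rep(c(1, 2, 3), 4), 3, 4))
  m2 <- make_expr(unclass(m), genes = rownames(m),
                  samples = sprintf("z%d", 1:4))
  rep <- differential_mean_filter(m, m2)
  expect_false(any(rep$passed))
})
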