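test_that("sibling pairing is sex-matched within sibling groups", {
  md <- make_meta(c("a", "b"), sex = c("F", "F"), sibling_group = "sg1")
  p <- sibling_pairs(md, "s1")
  expect_identical(nrow(p), 1L)
  expect_setequal(c(p$sample_a, p$sample_b), c("a", "b"))

  md$sex <- c("F", "M")
  expect_error(sibling_pairs(md, "s1"), "no valid sibling pair")

  md2 <- make_meta(c("a", "b", "c"), sex = "F", sibling_group = "sg1")
  expect_identical(nrow(sibling_pairs(md2, "s1")), 3L)            # C(3,2)
  expect_identical(nrow(sibling_pairs(md2, "s1", disjoint = TRUE)), 1L)

  md3 <- make_meta(c("a", "b"), sex = NA, sibling_group = "sg1")
  expect_error(sibling_pairs(md3, "s1"), "unknown")
})

test_that("generator metadata yields the configured sibling pair counts", {
  cfg <- generator_config(n_genes = 10, seed = 5)
  sim <- simulate_study(cfg)
  counts <- vapply(seq_along(cfg$stages), function(i)
    nrow(sibling_pairs(sim$metadata, cfg$stages[i])), integer(1))
  expect_identical(counts, cfg$n_sibling_pairs)   # 23, 24, 25, 13
})

test_that("all_pairs enumerates n(n-1)/2 unordered pairs", {
  for (n in c(2L, 3L, 5L, 6L, 13L, 50L)) {
    md <- make_meta(sprintf("e%02d", seq_len(n)), group = "F3")
    p <- all_pairs(md, "s1", "F3")
    expect_identical(nrow(p), as.integer(n * (n - 1L) / 2L))
    expect_false(any(p$sample_a == p$sample_b))
    key <- paste(pmin(p$sample_a, p$sample_b), pmax(p$sample_a, p$sample_b))
    expect_identical(anyDuplicated(key), 0L)
  }
  expect_identical(nrow(all_pairs(make_meta(c("e1", "e2", "e3", "e4", "e5"),
                                            group = "F3"), "s1", "F3")), 10L)
  expect_error(all_pairs(make_meta("e1", group = "F3"), "s1", "F3"),
               "at least 2")
})

test_that("cross-population pairing is the full sex-matched bipartite product", {
  md <- rbind(make_meta(sprintf("k%d", 1:4), group = "Kasasa", sex = "F"),
              make_meta(sprintf("o%d", 1:4), group = "Oura", sex = "F"))
  expect_identical(nrow(cross_population_pairs(md, "s1", "Kasasa", "Oura")),
                   16L)
  md2 <- rbind(make_meta(c("k1", "k2"), group = "Kasasa", sex = "F"),
               make_meta(c("o1", "o2"), group = "Oura", sex = "F"))
  expect_identical(nrow(cross_population_pairs(md2, "s1", "Kasasa", "Oura")),
                   4L)
  md3 <- rbind(make_meta(c("k1", "k2"), group = "Kasasa", sex = c("M", "F")),
               make_meta(c("o1", "o2"), group = "Oura", sex = c("M", "F")))
  p3 <- cross_population_pairs(md3, "s1", "Kasasa", "Oura")
  expect_identical(nrow(p3), 2L)
  sex_of <- setNames(md3$sex, md3$sample_id)
  expect_true(all(sex_of[p3$sample_a] == sex_of[p3$sample_b]))
  md4 <- rbind(make_meta("k1", group = "Kasasa", sex = "M"),
               make_meta("o1", group = "Oura", sex = "F"))
  expect_error(cross_population_pairs(md4, "s1", "Kasasa", "Oura"),
               "no sex-matched")
})

test_that("every emitted pair satisfies its kind's matching predicate", {
  sim <- simulate_study(generator_config(n_genes = 10, seed = 9))
  md <- sim$metadata
  info <- function(ids, col) setNames(md[[col]], md$sample_id)[ids]
  for (st in unique(md$stage)) {
    sp <- sibling_pairs(md, st)
    expect_true(all(info(sp$sample_a, "sex") == info(sp$sample_b, "sex")))
    expect_true(all(info(sp$sample_a, "sibling_group") ==
                      info(sp$sample_b, "sibling_group")))
    cp <- cross_population_pairs(md, st, "Kasasa", "Oura")
    expect_true(all(info(cp$sample_a, "group") == "Kasasa"))
    expect_true(all(info(cp$sample_b, "group") == "Oura"))
    expect_true(all(info(cp$sample_a, "sex") == info(cp$sample_b, "sex")))
  }
})

test_that("pair_set rejects self pairs and duplicates", {
  expect_error(pair_set("a", "a", kind = "sibling"), "self-pair")
  expect_error(pair_set(c("a", "b"), c("b", "a"), kind = "sibling"),
               "duplicate")
})
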