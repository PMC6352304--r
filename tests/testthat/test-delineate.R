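# A tiny parameter table for hand-checked arithmetic.
toy_params <- function(diff_p = c(0.2, 0.3, 0.6),
                       ids = c("a", "b", "c"),
                       tr_0 = 0.5, tr_cg = 0.2, a_cp = 0.1) {
  data.frame(genome_id = ids, length = 1000L, diff_p = diff_p,
             tr_0 = tr_0, tr_cg = tr_cg, a_cp = a_cp,
             stringsAsFactors = FALSE)
}

test_that("distances are normalized by the dataset range of each parameter", {
  nd <- normalized_distances(toy_params())
  d <- nd$distances$diff_p
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 1)
  expect_equal(d["b", "c"], 0.75)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(nd$ranges$range[nd$ranges$parameter == "diff_p"], 0.4)
  # zero-range parameters contribute zero distance
  expect_true(all(nd$distances$tr_0 == 0))
  expect_error(normalized_distances(toy_params()[1, ]), "at least 2")
  bad <- toy_params(ids = c("a", "a", "b"))
  expect_error(normalized_distances(bad), "duplicate")
})

test_that("similarity follows s = 100 * (1 - mean distance)", {
  s <- similarity_matrix(toy_params(), subset = "diff_p")
  expect_equal(s["a", "b"], 75)
  expect_equal(s["a", "c"], 0)   # the range-defining pair hits 0
  expect_equal(s["b", "c"], 25)
  expect_equal(diag(unclass(s)), setNames(rep(100, 3), c("a", "b", "c")))
  expect_equal(unclass(s), t(unclass(s)))  # reciprocal
  # identical parameter vectors give similarity 100
  eq <- toy_params(diff_p = c(0.3, 0.3), ids = c("a", "b"))
  expect_equal(similarity_matrix(eq, "s4")["a", "b"], 100)
})

test_that("subset presets resolve to the documented parameter sets", {
  expect_equal(resolve_subset("s2"), c("tr_cg", "diff_p"))
  expect_equal(resolve_subset("s3"), c("tr_cg", "diff_p", "tr_0"))
  expect_equal(resolve_subset("s4"), c("tr_cg", "diff_p", "tr_0", "a_cp"))
  expect_equal(resolve_subset(c("a_cp")), "a_cp")
  expect_error(resolve_subset("gc"), "unknown parameter")
  # the mean over equal per-parameter distances: 4 x 0.02 -> s = 98
  pt <- toy_params(diff_p = c(0, 0.02, 1), tr_0 = c(0, 0.02, 1),
                   tr_cg = c(0, 0.02, 1), a_cp = c(0, 0.02, 1))
  expect_equal(similarity_matrix(pt, "s4")["a", "b"], 98)
})

test_that("delineation calls are strict at the threshold by default", {
  pt <- toy_params(diff_p = c(0, 0.04, 1), ids = c("a", "b", "c"))
  s <- similarity_matrix(pt, "diff_p")  # s(a,b) = 96 exactly
  calls <- delineate(s, threshold = 96)
  ab <- calls[calls$id_a == "a" & calls$id_b == "b", ]
  expect_false(ab$same_species)
  lax <- delineate(s, threshold = 96, strict = FALSE)
  expect_true(lax[lax$id_a == "a" & lax$id_b == "b", "same_species"])
})

test_that("planted clusters yield the expected number of calls", {
  # two planted pairs: intra-similarity ~99, inter ~80
  pt <- data.frame(genome_id = c("a1", "a2", "b1", "b2"), length = 10L,
                   diff_p = c(0, 0.01, 0.99, 1), tr_0 = c(0, 0.01, 0.99, 1),
                   tr_cg = c(0, 0.01, 0.99, 1), a_cp = c(0, 0.01, 0.99, 1))
  s <- similarity_matrix(pt, "s4")
  calls <- delineate(s, threshold = 96)
  expect_equal(nrow(calls), 6L)
  expect_equal(sum(calls$same_species), 2L)
  # pairs are enumerated in lexicographic id order
  expect_identical(calls$id_a, c("a1", "a1", "a1", "a2", "a2", "b1"))
})

test_that("similarities are invariant to affine rescaling of a parameter", {
  set.seed(41)
  pt <- toy_params(diff_p = runif(3), tr_0 = runif(3), tr_cg = runif(3),
                   a_cp = runif(3))
  s1 <- similarity_matrix(pt, "s4")
  pt2 <- pt
  pt2$a_cp <- 3.7 * pt$a_cp - 0.4
  s2 <- similarity_matrix(pt2, "s4")
  expect_equal(s1[, ], s2[, ], tolerance = 1e-12)
})

test_that("adding a range-widening genome changes existing similarities", {
  pt <- toy_params()
  s_before <- similarity_matrix(pt, "diff_p")["a", "b"]
  pt_wide <- rbind(pt, toy_params(diff_p = 1.4, ids = "d"))
  s_after <- similarity_matrix(pt_wide, "diff_p")["a", "b"]
  expect_gt(s_after, s_before)  # wider range shrinks normalized distances
})
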