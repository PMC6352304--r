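test_that("diff_p reproduces the worked 6-mers and is order-sensitive", {
  expect_equal(diff_p(phase_signal("AAAGGG")), pi / 2 / 6)
  expect_equal(round(diff_p(phase_signal("AAAGGG")), 2), 0.26)
  expect_equal(diff_p(phase_signal("AGAGAG")), 5 * pi / 2 / 6)
  expect_equal(round(diff_p(phase_signal("AGAGAG")), 2), 1.31)
  expect_equal(diff_p(phase_signal("AAAA")), 0)
  expect_error(diff_p(phase_signal("A")), "length >= 2")
})

test_that("transition fractions match their worked values", {
  p <- phase_signal("CAGGCAG")
  expect_equal(tr_0(p), 3 / 6)
  expect_equal(tr_cg(p), 2 / 6)
  expect_equal(tr_0(phase_signal("AAAA")), 0)
  expect_equal(tr_0(phase_signal("ACAC")), 1)
  expect_equal(tr_cg(phase_signal("ATAT")), 0)
  expect_equal(tr_cg(phase_signal("GCGC")), 1)
})

test_that("transition fractions equal symbolic dinucleotide counting", {
  set.seed(31)
  for (i in 1:60) {
    s <- rand_seq(sample(2:1500, 1))
    p <- phase_signal(s)
    expect_identical(tr_0(p), oracle_tr_0(s))
    expect_identical(tr_cg(p), oracle_tr_cg(s))
  }
})

test_that("zero phases contribute no zero-crossing transitions", {
  # N and W have phase 0: pairs that include them are not crossings
  expect_equal(tr_0(phase_signal("ANC")), 0)
  expect_equal(tr_0(phase_signal("AWC")), 0)
  expect_equal(tr_0(phase_signal("ACN")), 1 / 2)
})

test_that("long repeats of CAGGCAG converge to the periodic fractions", {
  # circular period pairs CA, AG, GG, GC, CA, AG + boundary GC:
  # 4 of 7 cross zero, 3 of 7 are C/G pairs
  s <- strrep("CAGGCAG", 400)
  p <- phase_signal(s)
  expect_identical(tr_0(p), oracle_tr_0(s))
  expect_equal(tr_0(p), 4 / 7, tolerance = 1e-3)
  expect_equal(tr_cg(p), 3 / 7, tolerance = 1e-3)
})

test_that("a_cp averages the sampled growth angles", {
  # linear ramp of slope 1: every sampled angle is atan(1)
  expect_equal(a_cp(1:100, n = 10), pi / 4)
  # slope 2 with the maximum at 50
  expect_equal(a_cp(2 * (1:50), n = 10), atan(2))
  # uneven rise: direct evaluation at the sampled indices
  set.seed(32)
  v <- cumsum(runif(200, 0, 1))
  i <- pmin(pmax(round((1:10) * which.max(v) / 10), 1), which.max(v))
  expect_equal(a_cp(v, n = 10), mean(atan(v[i] / i)))
  # all-flat signal: angle 0
  expect_equal(a_cp(c(0, rep(0, 99)), n = 1), 0)
  expect_error(a_cp(1:5, n = 10), "smaller n")
})

test_that("compute_parameters is deterministic and rotation-invariant", {
  set.seed(33)
  g <- gc_skew_genome(6000, gc = 0.5, gc_skew = 0.07, id = "g")
  p1 <- compute_parameters(g)
  p2 <- compute_parameters(g)
  expect_identical(p1, p2)
  rot <- rotate_genome(g, 1000)
  p3 <- compute_parameters(rot)
  expect_equal(p3$a_cp, p1$a_cp)
  expect_lte(abs(p3$tr_0 - p1$tr_0), 2 / (6000 - 1))
  expect_lte(abs(p3$tr_cg - p1$tr_cg), 2 / (6000 - 1))
  # ablation flag skips the anchoring rotation
  pno <- compute_parameters(g, rearrange = FALSE)
  expect_equal(pno$tr_cg, tr_cg(phase_signal(g)))
})

test_that("tr_cg of i.i.d. genomes approaches the squared GC fraction", {
  g <- random_genome(1e6, c(0.25, 0.2, 0.2, 0.35), id = "iid", seed = 34)
  p <- phase_signal(g)
  se <- sqrt(0.16 * (1 - 0.16) / 1e6)
  expect_lt(abs(tr_cg(p) - 0.4^2), 3 * se)
  # zero-crossing fraction ~ 2 * P(purine) * P(pyrimidine)
  pur <- 0.25 + 0.2
  expect_lt(abs(tr_0(p) - 2 * pur * (1 - pur)), 3 * sqrt(0.25 / 1e6))
})

test_that("one percent substitutions move the descriptors only slightly", {
  g <- gc_skew_genome(50000, gc = 0.45, gc_skew = 0.06, id = "anc",
                      seed = 35)
  m <- mutate_genome(g, 0.01, id = "mut", seed = 36)
  pa <- compute_parameters(g)
  pb <- compute_parameters(m)
  expect_lt(abs(pa$tr_0 - pb$tr_0), 0.02)
  expect_lt(abs(pa$tr_cg - pb$tr_cg), 0.02)
  expect_lt(abs(pa$diff_p - pb$diff_p), 0.05)
  expect_lt(abs(pa$a_cp - pb$a_cp), 0.05)
})

test_that("parameter tables validate ids and finiteness", {
  gs <- list(wgp_genome(strrep("ACGGT", 50), id = "a"),
             wgp_genome(strrep("GGTCA", 50), id = "b"))
  pt <- compute_parameter_table(gs)
  expect_equal(nrow(pt), 2L)
  expect_equal(attr(pt, "n_acp"), 10L)
  expect_true(attr(pt, "rearranged"))
  gs2 <- list(wgp_genome(strrep("ACGGT", 50), id = "x"),
              wgp_genome(strrep("AGGTC", 50), id = "x"))
  expect_error(compute_parameter_table(gs2), "duplicate genome ids")
})
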