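# Build a wgp_similarity directly from a symmetric matrix of percentages.
as_sim <- function(m, ids) {
  dimnames(m) <- list(ids, ids)
  structure(m, class = c("wgp_similarity", class(m)))
}

# Brute-force confusion oracle: loop over pairs.
oracle_confusion <- function(sim, labels, threshold) {
  ids <- rownames(sim)
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
    pos <- sim[i, j] > threshold
    same <- labels[ids[i]] == labels[ids[j]]
    if (pos && same) tp <- tp + 1L
    else if (pos && !same) fp <- fp + 1L
    else if (!pos && same) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fn = fn, tn = tn, fp = fp)
}

test_that("confusion counts classify labeled pairs correctly", {
  lab <- c(g1 = "s1", g2 = "s1")
  s <- as_sim(matrix(c(100, 99, 99, 100), 2), c("g1", "g2"))
  cc <- confusion_counts(s, lab, 96)
  expect_equal(c(cc$tp, cc$fn, cc$tn, cc$fp), c(1, 0, 0, 0))
  expect_equal(cc$sensitivity, 100)
  expect_true(is.na(cc$specificity))  # no inter-species pairs
  cc2 <- confusion_counts(s, c(g1 = "s1", g2 = "s2"), 96)
  expect_equal(cc2$fp, 1)
  expect_equal(cc2$specificity, 0)
  expect_true(is.na(cc2$sensitivity))
})

test_that("a mixed four-genome dataset splits into all four counts", {
  ids <- c("a1", "a2", "b1", "b2")
  lab <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  m <- matrix(80, 4, 4)
  m[1, 2] <- m[2, 1] <- 99  # intra A above threshold
  m[3, 4] <- m[4, 3] <- 95  # intra B below threshold
  diag(m) <- 100
  s <- as_sim(m, ids)
  cc <- confusion_counts(s, lab, 96)
  expect_equal(c(cc$tp, cc$fn, cc$tn, cc$fp), c(1, 1, 4, 0))
  expect_equal(cc$sensitivity, 50)
  expect_equal(cc$specificity, 100)
  expect_error(confusion_counts(s, lab[-1], 96), "no species label")
})

test_that("confusion counts match a brute-force oracle on random matrices", {
  set.seed(51)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    ids <- sprintf("g%02d", seq_len(n))
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- runif(sum(upper.tri(m)), 80, 100)
    m <- m + t(m); diag(m) <- 100
    s <- as_sim(m, ids)
    lab <- setNames(sample(c("x", "y", "z"), n, replace = TRUE), ids)
    thr <- runif(1, 85, 99)
    cc <- confusion_counts(s, lab, thr)
    expect_equal(c(tp = cc$tp, fn = cc$fn, tn = cc$tn, fp = cc$fp),
                 oracle_confusion(s, lab, thr))
    # sum conservation: totals are threshold-independent
    expect_equal(cc$tp + cc$fn + cc$tn + cc$fp, choose(n, 2))
  }
})

test_that("the default sweep has 17 points with monotone rates", {
  set.seed(52)
  n <- 12
  ids <- sprintf("g%02d", seq_len(n))
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(sum(upper.tri(m)), 85, 100)
  m <- m + t(m); diag(m) <- 100
  s <- as_sim(m, ids)
  lab <- setNames(rep(c("x", "y"), each = n / 2), ids)
  sw <- roc_sweep(s, lab)
  expect_equal(nrow(sw), 17L)
  expect_equal(sw$threshold, 90 + (0:16) * 0.5)
  expect_true(all(diff(sw$sensitivity) <= 1e-12))
  expect_true(all(diff(sw$specificity) >= -1e-12))
  expect_true(all(sw$tp + sw$fn == sw$tp[1] + sw$fn[1]))
  expect_error(roc_sweep(s, lab, t_min = 98, t_max = 90), "t_min")
})

test_that("the subset report stacks sweeps consistently", {
  set.seed(53)
  sim <- simulate_species_clusters(3, 3, 5000, substitution_rate = 0.01,
                                   seed = 53)
  pt <- compute_parameter_table(sim$genomes)
  lab <- label_vector(sim)
  rep <- subset_comparison_report(pt, lab)
  expect_equal(nrow(rep), 7L * 17L)
  expect_setequal(unique(rep$subset),
                  c("diff_p", "tr_0", "tr_cg", "a_cp", "s2", "s3", "s4"))
  # a one-subset report equals the plain sweep
  one <- subset_comparison_report(pt, lab, subsets = list(s4 = "s4"))
  sw <- roc_sweep(similarity_matrix(pt, "s4"), lab)
  expect_equal(one$sensitivity, sw$sensitivity)
  expect_equal(one$specificity, sw$specificity)
})

test_that("single-strain species produce no false negatives", {
  set.seed(54)
  sim <- simulate_species_clusters(4, 1, 4000, seed = 54)
  pt <- compute_parameter_table(sim$genomes)
  sw <- roc_sweep(similarity_matrix(pt, "s4"), label_vector(sim))
  expect_true(all(sw$fn == 0))
  expect_true(all(is.na(sw$sensitivity)))  # no intra pairs at all
})
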