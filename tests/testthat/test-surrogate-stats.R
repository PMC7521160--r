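# Shared statistical machinery: z/p mapping, empirical p, clusters,
# cluster-based permutation test.

test_that("z-to-P mapping matches the standard normal upper tail", {
  expect_equal(z_to_p_one_sided(0), 0.5)
  expect_equal(round(z_to_p_one_sided(2), 4), 0.0228)
  expect_equal(round(z_to_p_one_sided(3), 4), 0.0013)
  expect_true(z_to_p_one_sided(5) > 1e-7 && z_to_p_one_sided(5) < 1e-6)
  expect_equal(z_to_p_one_sided(5), 2.866516e-07, tolerance = 1e-4)
  expect_error(z_to_p_one_sided(Inf), "finite")
})

test_that("surrogate z-scoring uses the sample standard deviation", {
  s <- c(1, 2, 3)
  expect_equal(surrogate_zscore(2, s), 0)
  expect_equal(surrogate_zscore(5, s), 3)
  expect_equal(surrogate_zscore(mean(s) + 2 * stats::sd(s), s), 2)
  expect_error(surrogate_zscore(1, c(2, 2, 2)), "degenerate")
  expect_error(surrogate_zscore(1, 5), "at least 2")
})

test_that("empirical p counts ties and reports beat-all as below 1/n", {
  surr <- stats::rnorm(999)
  expect_equal(empirical_p(10, surr), 0)
  expect_equal(format_empirical_p(empirical_p(10, surr), 1000), "P < 0.001")
  expect_equal(empirical_p(3, rep(3, 100)), 1)
  med <- stats::median(seq_len(101))
  expect_lt(abs(empirical_p(med, seq_len(101)) - 0.5), 0.01)
  # adding a surrogate >= observed never decreases p
  p1 <- empirical_p(1, surr)
  expect_gte(empirical_p(1, c(surr, 2)), p1)
})

test_that("cluster finding enforces 4-connectivity, sign homogeneity and extent", {
  z <- matrix(0, 20, 60)
  expect_length(find_clusters(z, 3), 0)

  z[5:7, 10:21] <- 6
  cl <- find_clusters(z, 5)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$n_bins, 36)
  expect_equal(cl[[1]]$sign, 1)
  expect_equal(cl[[1]]$mass, 216)

  # a one-row line fails the two-frequency-bin rule however extreme
  z2 <- matrix(0, 20, 60)
  z2[4, 1:50] <- 10
  expect_length(find_clusters(z2, 5), 0)

  # negative clusters are found with their own sign
  z3 <- matrix(0, 20, 60)
  z3[2:5, 5:20] <- -8
  cl3 <- find_clusters(z3, 5)
  expect_equal(cl3[[1]]$sign, -1)

  # monotone: raising the level never grows a cluster
  z4 <- matrix(stats::rnorm(1200, sd = 2), 20, 60)
  z4[8:12, 20:40] <- 8
  n3 <- sum(vapply(find_clusters(z4, 3), `[[`, integer(1), "n_bins"))
  n6 <- sum(vapply(find_clusters(z4, 6), `[[`, integer(1), "n_bins"))
  expect_lte(n6, n3)
})

test_that("outline levels span the lowest informative to highest productive z", {
  z <- matrix(0, 20, 60)
  z[5:8, 10:30] <- 4.2
  lv <- choose_outline_levels(z)
  expect_true(all(lv %in% c(3, 4)))
  expect_length(choose_outline_levels(matrix(1, 20, 60)), 0)
  zbig <- matrix(0, 20, 60)
  zbig[5:8, 10:30] <- 30
  expect_equal(choose_outline_levels(zbig), c(3L, 8L, 14L, 19L, 25L))
})

test_that("one-sample cluster permutation detects a planted block and rejects 1x1 effects", {
  set.seed(1)
  x <- array(stats::rnorm(30 * 20 * 20), c(30, 20, 20))
  x[, 5:8, 5:8] <- x[, 5:8, 5:8] + 1
  res <- cluster_permutation_onesample(x, seed = 2)
  sig <- Filter(function(cl) cl$significant, res$clusters)
  expect_gte(length(sig), 1)
  covers <- vapply(sig, function(cl) {
    cl$row_range[1] <= 5 && cl$row_range[2] >= 8 &&
      cl$col_range[1] <= 5 && cl$col_range[2] >= 8
  }, logical(1))
  expect_true(any(covers))
  expect_lt(sig[[which(covers)[1]]]$p, 0.05)

  # an extreme single bin is rejected by the 2x2 extent rule
  x2 <- array(stats::rnorm(30 * 10 * 10, sd = 0.1), c(30, 10, 10))
  x2[, 5, 5] <- x2[, 5, 5] + 10
  res2 <- cluster_permutation_onesample(x2, seed = 3)
  hot_in_cluster <- vapply(res2$clusters, function(cl) {
    any(cl$bins[, 1] == 5 & cl$bins[, 2] == 5)
  }, logical(1))
  expect_false(any(hot_in_cluster))

  # all-zero segments give no clusters, too few segments error
  expect_length(cluster_permutation_onesample(
    array(0, c(5, 8, 8)), seed = 1)$clusters, 0)
  expect_error(cluster_permutation_onesample(array(0, c(2, 8, 8))),
               "insufficient")
})

test_that("permutation test type-I error stays at or below nominal", {
  set.seed(6)
  fp <- mean(replicate(200, {
    xn <- array(stats::rnorm(30 * 15 * 15), c(30, 15, 15))
    r <- cluster_permutation_onesample(xn, n_perm = 200)
    any(vapply(r$clusters, `[[`, logical(1), "significant"))
  }))
  expect_lte(fp, 0.08)
})
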