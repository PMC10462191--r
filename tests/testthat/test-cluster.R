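test_that("channel adjacency follows great-circle distance and stays connected", {
  m <- default_montage()
  expect_false(any(channel_adjacency(m, max_angle = 0)))
  full <- channel_adjacency(m, max_angle = pi + 0.1)
  expect_true(all(full[upper.tri(full)]))
  adj <- channel_adjacency(m)
  expect_true(adj["Fz", "F3"])
  expect_true(adj["Fz", "F4"])
  expect_true(isSymmetric(adj))
  ## connected: breadth-first reach from channel 1
  reached <- logical(34); reached[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !reached)
    reached[nxt] <- TRUE
    frontier <- nxt
  }
  expect_true(all(reached))
})

test_that("compiled permutation clustering matches the reference implementation", {
  set.seed(99)
  m <- mk_small_montage(8)
  adj <- channel_adjacency(m)
  adj_list <- apply(adj, 1, which, simplify = FALSE)
  Tm <- matrix(stats::rnorm(100 * 8 * 20, 0, 1.6), 100)
  cpp <- oddballmmn:::extremal_maxsums_cpp(Tm, 2.1, adj_list, 8, 20)
  ref <- apply(Tm, 1, function(tv) {
    oddballmmn:::extremal_maxsum(tv, 2.1, adj_list, 8, 20)
  })
  expect_equal(cpp, ref, tolerance = 1e-12)
})

test_that("single-point Monte-Carlo p matches the exhaustive sign-flip oracle", {
  adj <- matrix(FALSE, 1, 1)
  set.seed(12)
  for (n in c(6, 8, 10)) {
    d <- stats::rnorm(n, mean = 0.8)
    dev <- array(d, c(n, 1, 1)); std <- array(0, c(n, 1, 1))
    n_perm <- 4000
    res <- cluster_permutation_test(dev, std, adj, n_perm = n_perm, seed = n)
    p_ex <- oracle_exhaustive_signflip_p(d)
    if (nrow(res$clusters) == 0) {
      ## observed t subthreshold: exhaustive p is 1 by the same rule
      expect_equal(p_ex, 1)
    } else {
      ## the (b+1)/(n_perm+1) estimator has expectation
      ## (n_perm p + 1)/(n_perm + 1); compare around it at 2 MC SEs
      expected_p <- (n_perm * p_ex + 1) / (n_perm + 1)
      mc_se <- sqrt(p_ex * (1 - p_ex) / n_perm)
      expect_lt(abs(res$clusters$p - expected_p), 2 * mc_se + 1e-12)
    }
  }
})

test_that("all-zero data produce no clusters and tiny n_perm warns", {
  dev <- array(0, c(6, 2, 4)); std <- array(0, c(6, 2, 4))
  adj <- matrix(TRUE, 2, 2); diag(adj) <- FALSE
  expect_warning(res <- cluster_permutation_test(dev, std, adj, n_perm = 50),
                 "n_perm")
  expect_equal(nrow(res$clusters), 0)
  expect_false(has_significant_cluster(res))
})

test_that("swapping condition labels negates polarities, keeps p-values", {
  set.seed(13)
  n <- 12; nch <- 4; nt <- 10
  m <- mk_small_montage(nch)
  adj <- channel_adjacency(m)
  dev <- array(stats::rnorm(n * nch * nt), c(n, nch, nt))
  dev[, 1:2, 4:7] <- dev[, 1:2, 4:7] - 1.5
  std <- array(stats::rnorm(n * nch * nt), c(n, nch, nt))
  r1 <- cluster_permutation_test(dev, std, adj, n_perm = 600, seed = 5)
  r2 <- cluster_permutation_test(std, dev, adj, n_perm = 600, seed = 5)
  expect_equal(r1$clusters$maxsum, -r2$clusters$maxsum, tolerance = 1e-12)
  expect_equal(r1$clusters$p, r2$clusters$p, tolerance = 1e-12)
})

test_that("clusters respect adjacency, contiguity and sign; members match the map", {
  set.seed(14)
  n <- 10
  m <- mk_small_montage(6)
  adj <- channel_adjacency(m)
  dev <- array(stats::rnorm(n * 6 * 12, 0, 0.5), c(n, 6, 12))
  dev[, 2, 3:6] <- dev[, 2, 3:6] - 2        # negative patch at Fz
  std <- array(stats::rnorm(n * 6 * 12, 0, 0.5), c(n, 6, 12))
  res <- cluster_permutation_test(dev, std, adj, n_perm = 500, seed = 6)
  expect_gt(nrow(res$clusters), 0)
  top <- res$members[[1]]
  tmap <- as.numeric(res$t_map)
  ## every member of one cluster shares the sign and is suprathreshold
  expect_true(all(abs(tmap[top]) > res$t_threshold))
  expect_true(length(unique(sign(tmap[top]))) == 1)
  ## p-values live in [1/(n_perm+1), 1]
  expect_true(all(res$clusters$p >= 1 / 501 & res$clusters$p <= 1))
})

test_that("an injected frontal effect is recovered as a significant negative cluster", {
  set.seed(15)
  hits <- vapply(1:5, function(i) {
    amps <- stats::rnorm(21, -1, 1)
    e <- simulate_cohort_erps(amps, seed = 100 + i)
    adj <- channel_adjacency(default_montage())
    r <- cluster_permutation_test(e$dev, e$std, adj, n_perm = 300,
                                  seed = 200 + i)
    if (!has_significant_cluster(r, "negative")) return(FALSE)
    ## members overlap the injected frontal window region
    cl <- r$members[[which(r$clusters$significant &
                             r$clusters$polarity == "negative")[1]]]
    nch <- 34
    chans <- unique((cl - 1) %% nch + 1)
    times <- unique((cl - 1) %/% nch + 1)
    front <- match(c("F3", "Fz", "F4"), e$labels)
    win <- which(e$time_ms >= 200 & e$time_ms <= 240)
    any(front %in% chans) && any(win %in% times)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
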