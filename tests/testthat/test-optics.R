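test_that("core distances equal the min_pts-th nearest neighbor distance", {
  pts <- cbind(c(0, 1, 2, 10, 11, 12, 30), 0)
  res <- optics_order(pts, optics_config(min_pts = 2L, eps = Inf,
                                         extraction = NULL))
  expect_equal(res$core_distance, c(1, 1, 1, 1, 1, 1, 18))
  expect_setequal(res$order, 1:7)
  dup <- rbind(c(0, 0), c(0, 0), c(5, 5))
  res2 <- optics_order(dup, optics_config(min_pts = 2L, extraction = NULL))
  expect_equal(res2$core_distance[1], 0)
})

test_that("isolated points have undefined core and reachability distances", {
  pts <- cbind(c(0, 100, 200), 0)
  res <- optics_order(pts, optics_config(min_pts = 2L, eps = 1,
                                         extraction = NULL))
  expect_true(all(is.na(res$core_distance)))
  expect_true(all(is.na(res$reachability)))
  lab <- extract_clusters(res, list(mode = "cut", eps_prime = 1))
  expect_true(all(lab$labels == 0L))
})

test_that("a single dense blob with a generous cut is one cluster", {
  set.seed(21)
  pts <- matrix(rnorm(200, sd = 0.5), 100, 2)
  res <- optics_order(pts, optics_config(min_pts = 5L, extraction = NULL))
  lab <- extract_clusters(res, list(mode = "cut",
                                    eps_prime =
                                      max(res$reachability,
                                          na.rm = TRUE) + 1))
  expect_equal(length(setdiff(unique(lab$labels), 0L)), 1L)
  expect_equal(sum(lab$labels == 0L), 0L)
})

test_that("cut-mode extraction matches a DBSCAN oracle on core points", {
  set.seed(22)
  for (i in seq_len(20)) {
    k <- sample(2:4, 1)
    centers <- matrix(runif(k * 2, -8, 8), k, 2)
    blob <- make_blobs(n_per = sample(20:50, 1), centers = centers,
                       sd = runif(1, 0.3, 0.7),
                       n_noise = sample(5:20, 1))
    min_pts <- sample(4:8, 1)
    eps_prime <- runif(1, 0.4, 0.9)
    res <- optics_order(blob$points, optics_config(min_pts = min_pts,
                                                   extraction = NULL))
    lab <- extract_clusters(res, list(mode = "cut",
                                      eps_prime = eps_prime))$labels
    oracle <- dbscan_oracle(blob$points, eps_prime, min_pts)
    core <- oracle$core
    if (sum(core) < 2L) next
    expect_equal(adjusted_rand_index(lab[core], oracle$labels[core]), 1.0)
  }
})

test_that("raising the cut never increases the noise count", {
  set.seed(23)
  blob <- make_blobs(50, rbind(c(0, 0), c(6, 6)), n_noise = 30)
  res <- optics_order(blob$points, optics_config(min_pts = 5L,
                                                 extraction = NULL))
  cuts <- quantile(res$reachability[is.finite(res$reachability)],
                   c(0.2, 0.4, 0.6, 0.8, 1))
  noise <- vapply(cuts, function(ep)
    sum(extract_clusters(res, list(mode = "cut",
                                   eps_prime = ep))$labels == 0L),
    numeric(1))
  expect_true(all(diff(noise) <= 0))
})

test_that("labels are stable under input permutation up to renaming", {
  set.seed(24)
  blob <- make_blobs(40, rbind(c(0, 0), c(7, 0), c(0, 7)), n_noise = 15)
  cfg <- optics_config(min_pts = 5L,
                       extraction = list(mode = "cut", eps_prime = 0.8))
  lab1 <- extract_clusters(optics_order(blob$points, cfg))$labels
  perm <- sample(nrow(blob$points))
  lab2 <- extract_clusters(optics_order(blob$points[perm, ], cfg))$labels
  clustered <- lab1 > 0L & lab2[order(perm)] > 0L
  expect_equal(adjusted_rand_index(lab1[clustered],
                                   lab2[order(perm)][clustered]), 1.0)
})

test_that("xi extraction recovers well-separated blobs", {
  set.seed(25)
  blob <- make_blobs(60, rbind(c(0, 0), c(10, 10)), sd = 0.5,
                     n_noise = 20)
  res <- optics_order(blob$points,
                      optics_config(min_pts = 8L,
                                    extraction = list(mode = "xi",
                                                      xi = 0.05)))
  lab <- extract_clusters(res)$labels
  k <- length(setdiff(unique(lab), 0L))
  expect_gte(k, 2L)
  # each blob's members should be concentrated in one extracted cluster
  for (b in 1:2) {
    members <- lab[blob$labels == b]
    top <- max(table(members[members > 0L]))
    expect_gte(top / length(members), 0.8)
  }
  tab <- table(lab[lab > 0L])
  expect_true(all(tab >= 8L))
})

test_that("the tuner prefers a working candidate and is deterministic", {
  set.seed(26)
  embeddings <- lapply(1:3, function(i)
    make_blobs(50, rbind(c(0, 0), c(8, 8)), n_noise = 25)$points)
  single <- data.frame(min_pts = 5L, quantile = 0.7)
  out1 <- tune_hyperparameters(embeddings, single)
  expect_equal(out1$best, 1L)
  grid <- data.frame(min_pts = c(5L, 70L), quantile = c(0.7, 0.7))
  out2 <- tune_hyperparameters(embeddings, grid)
  expect_equal(out2$config$min_pts, 5L)
  expect_true(out2$scores$score[2] == -Inf ||
                out2$scores$score[2] < out2$scores$score[1])
  out3 <- tune_hyperparameters(embeddings, grid)
  expect_identical(out2$scores, out3$scores)
  expect_error(tune_hyperparameters(embeddings[1], grid), "at least 2")
})

test_that("configuration validation catches bad extraction settings", {
  expect_error(optics_config(min_pts = 1L), "min_pts")
  expect_error(optics_config(extraction = list(mode = "xi", xi = 1.2)),
               "xi")
  expect_error(optics_config(extraction = list(mode = "cut")), "cut")
  expect_error(optics_config(eps = 1,
                             extraction = list(mode = "cut",
                                               eps_prime = 2)),
               "exceed")
  expect_error(optics_order(matrix(0, 1, 2), optics_config(min_pts = 5L)),
               "at least")
})
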