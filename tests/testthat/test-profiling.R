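ridge_oracle <- function(X, y, lambda) {
  # direct closed form on centered data, built independently of fit_ridge
  Xc <- scale(X, scale = FALSE)
  solve(t(Xc) %*% Xc + lambda * diag(ncol(X)),
        t(Xc) %*% (y - mean(y)))
}

test_that("ridge matches the closed-form oracle to 1e-8", {
  set.seed(31)
  for (i in seq_len(10)) {
    X <- matrix(rnorm(240), 40, 6)
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    lambda <- 10^runif(1, -3, 3)
    fit <- fit_ridge(X, y, lambda)
    expect_lt(max(abs(fit$coefficients - drop(ridge_oracle(X, y, lambda)))),
              1e-8)
  }
})

test_that("ridge limits and symmetries hold", {
  set.seed(32)
  X <- matrix(rnorm(200), 50, 4)
  y <- rbinom(50, 1, 0.5)
  fit <- fit_ridge(X, y, 1e12)
  expect_lt(max(abs(fit$coefficients)), 1e-6)
  Xdup <- cbind(a = X[, 1], b = X[, 1], c = X[, 2])
  fit2 <- fit_ridge(Xdup, y, 0.5)
  expect_equal(fit2$coefficients[["a"]], fit2$coefficients[["b"]])
  expect_error(fit_ridge(X, rep(1, 50), 1), "both classes")
  expect_error(fit_ridge(X, y, 0), "positive")
})

test_that("coefficient norms shrink monotonically along the penalty grid", {
  set.seed(33)
  X <- matrix(rnorm(600), 100, 6)
  y <- rbinom(100, 1, 0.3)
  grid <- penalty_grid()
  expect_length(grid, 100L)
  norms <- vapply(grid, function(l)
    sqrt(sum(fit_ridge(X, y, l)$coefficients^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("a degenerate grid reproduces the single fit, normalized", {
  set.seed(34)
  X <- matrix(rnorm(300), 50, 6, dimnames = list(NULL, paste0("v", 1:6)))
  labels <- rep(c(1L, 2L), each = 25)
  grid <- rep(2.5, 100)
  prof <- profile_cluster(X, labels, 1L, grid)
  single <- fit_ridge(X, as.integer(labels == 1L), 2.5)$coefficients
  expect_equal(prof$coefficients, single / max(abs(single)),
               tolerance = 1e-10)
  expect_equal(max(abs(prof$coefficients)), 1)
  expect_equal(prof$n_members, 25L)
})

test_that("profiles ignore noise points and other clusters' identities", {
  set.seed(35)
  X <- matrix(rnorm(1200), 200, 6, dimnames = list(NULL, paste0("v", 1:6)))
  labels <- c(rep(1L, 60), rep(2L, 60), rep(3L, 50), rep(0L, 30))
  grid <- penalty_grid(20)
  p1 <- suppressWarnings(profile_cluster(X, labels, 1L, grid))
  relabeled <- labels
  relabeled[labels == 2L] <- 9L   # renaming another cluster
  p1b <- suppressWarnings(profile_cluster(X, relabeled, 1L, grid))
  expect_identical(p1$coefficients, p1b$coefficients)
  # flipping noise points to a cluster changes the rest class, so the
  # exclusion of noise is load-bearing
  labels_noise_in <- labels
  labels_noise_in[labels == 0L] <- 2L
  p1c <- suppressWarnings(profile_cluster(X, labels_noise_in, 1L, grid))
  expect_false(isTRUE(all.equal(p1$coefficients, p1c$coefficients)))
  expect_warning(profile_cluster(X, labels, 1L, penalty_grid(20)),
                 "100")
})

test_that("a planted signature dominates its cluster's profile", {
  set.seed(36)
  n <- 300
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("v", 1:10)))
  labels <- sample(rep(1:3, each = 100))
  X[labels == 1L, "v7"] <- X[labels == 1L, "v7"] + 3.0
  X <- scale(X)
  prof <- profile_cluster(X, labels, 1L)
  expect_equal(names(which.max(abs(prof$coefficients))), "v7")
})

test_that("importance ranges equal a max-minus-min oracle with top-20 flags", {
  set.seed(37)
  n_var <- 25L
  profiles <- lapply(1:4, function(k) {
    coefs <- runif(n_var, -1, 1)
    names(coefs) <- paste0("v", seq_len(n_var))
    structure(list(cluster_id = k, coefficients = coefs / max(abs(coefs)),
                   penalty_grid = penalty_grid(), n_members = 10L),
              class = "cluster_profile")
  })
  imp <- importance_ranges(profiles)
  expect_equal(sum(imp$top20), 20L)
  M <- sapply(profiles, `[[`, "coefficients")
  oracle <- apply(M, 1, max) - apply(M, 1, min)
  expect_equal(imp$range[match(names(oracle), imp$variable)],
               unname(oracle))
  expect_true(all(diff(imp$range) <= 1e-12))
  flat <- profiles
  for (k in 1:4) flat[[k]]$coefficients[] <- 0.3
  imp_flat <- importance_ranges(flat)
  expect_true(all(imp_flat$range == 0))
  expect_error(importance_ranges(profiles[1]), "at least 2")
})

test_that("label evidence reports top variables and majority category", {
  coefs <- c(a = 1, b = -0.9, c = 0.8, d = 0.7, e = 0.6, f = 0.1)
  prof <- structure(list(cluster_id = 1L, coefficients = coefs,
                         penalty_grid = penalty_grid(), n_members = 20L),
                    class = "cluster_profile")
  domains <- c(a = "psychobehavioral", b = "psychobehavioral",
               c = "psychobehavioral", d = "psychobehavioral",
               e = "psychobehavioral", f = "labs")
  ev <- suggest_labels(list(`1` = prof), domains)[["1"]]
  expect_equal(ev$evidence$variable, c("a", "b", "c", "d", "e"))
  expect_equal(ev$suggested_category, "psychobehavioral")
  # clinical domains collapse to the comorbidity category
  domains2 <- c(a = "labs", b = "vitals", c = "comorbidity",
                d = "sociodemographic", e = "sociodemographic", f = "labs")
  ev2 <- suggest_labels(list(`1` = prof), domains2)[["1"]]
  expect_equal(ev2$suggested_category, "comorbidity")
  # a tie reports both categories, no silent choice
  domains3 <- c(a = "labs", b = "labs", c = "sociodemographic",
                d = "sociodemographic", e = "psychobehavioral", f = "labs")
  ev3 <- suggest_labels(list(`1` = prof), domains3)[["1"]]
  expect_setequal(ev3$suggested_category,
                  c("comorbidity", "sociodemographic"))
})
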