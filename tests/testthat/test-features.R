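test_that("median aggregation matches a sort-and-pick oracle", {
  s1 <- data.frame(patient_id = "a", variable = "x", day = 1, value = 5)
  expect_equal(aggregate_medians(s1)$x, 5)
  s2 <- data.frame(patient_id = "a", variable = "x", day = 1:3,
                   value = c(1, 9, 3))
  expect_equal(aggregate_medians(s2)$x, 3)
  s3 <- data.frame(patient_id = "a", variable = "x", day = 1:4,
                   value = c(1, 9, 3, 5))
  expect_equal(aggregate_medians(s3)$x, 4)  # midpoint of 3 and 5

  set.seed(42)
  series <- data.frame(
    patient_id = sample(sprintf("p%02d", 1:20), 300, replace = TRUE),
    variable = sample(c("x", "y", "z"), 300, replace = TRUE),
    day = sample(0:364, 300, replace = TRUE),
    value = rnorm(300))
  wide <- aggregate_medians(series)
  for (i in seq_len(50)) {
    row <- series[sample(nrow(series), 1), ]
    vals <- sort(series$value[series$patient_id == row$patient_id &
                                series$variable == row$variable])
    m <- length(vals)
    oracle <- if (m %% 2 == 1) vals[(m + 1) / 2]
              else (vals[m / 2] + vals[m / 2 + 1]) / 2
    expect_equal(wide[wide$patient_id == row$patient_id, row$variable],
                 oracle)
  }
  # a patient with no series for a variable gets NA
  expect_true(anyNA(wide[, c("x", "y", "z")]) ||
                all(table(series$patient_id, series$variable) > 0))
})

test_that("PDC equals the day-by-day set-union oracle", {
  expect_equal(compute_pdc(0L, 365L, c(0L, 364L)), 1.0)
  expect_equal(compute_pdc(c(0L, 20L), c(30L, 30L), c(0L, 99L)), 0.5)
  expect_equal(compute_pdc(integer(0), integer(0), c(0L, 99L)), 0)
  expect_error(compute_pdc(0L, 10L, c(5L, 4L)), "empty")
  set.seed(7)
  for (i in seq_len(200)) {
    n_fill <- sample(1:6, 1)
    starts <- sample(-20:400, n_fill)   # some fills overlap window edges
    supplies <- sample(1:90, n_fill, replace = TRUE)
    w <- c(0L, sample(30:364, 1))
    expect_equal(compute_pdc(starts, supplies, w),
                 pdc_oracle(starts, supplies, w))
  }
})

test_that("weighted adherence weights classes by days of therapy", {
  expect_equal(weighted_adherence(c(1, 0), c(300, 100)), 0.75)
  expect_equal(weighted_adherence(c(0.5, NA), c(100, 0)), 0.5)
  expect_true(is.na(weighted_adherence(c(NA, NA), c(0, 0))))
})

test_that("low-variance filter matches direct variance computation", {
  X <- cbind(const = rep(1, 50), ok = rnorm(50))
  out <- low_variance_filter(X)
  expect_equal(out$removed, "const")
  X2 <- matrix(rnorm(500), 50, 10,
               dimnames = list(NULL, paste0("v", 1:10)))
  out2 <- low_variance_filter(X2, min_variance = 0.5)
  keep_oracle <- colnames(X2)[apply(X2, 2, var) >= 0.5]
  expect_equal(colnames(out2$matrix), keep_oracle)
  out3 <- low_variance_filter(X2, min_variance = 0)
  expect_equal(out3$matrix, X2)
  expect_error(low_variance_filter(X[, 1, drop = FALSE] * 0 + 1, 0.01),
               "every column")
})

test_that("correlation pruning removes planted duplicates and nothing else", {
  set.seed(3)
  base <- matrix(rnorm(240), 30, 8,
                 dimnames = list(NULL, paste0("v", 1:8)))
  X <- base
  X[, "v7"] <- X[, "v1"] + rnorm(30, sd = 0.1)  # near-duplicate pair
  X[, "v8"] <- X[, "v2"] * -1 + rnorm(30, sd = 0.1)
  out <- correlation_prune(X, r_max = 0.80)
  R <- abs(cor(out$matrix))
  diag(R) <- 0
  expect_lte(max(R), 0.80)
  expect_setequal(out$removed$dropped,
                  intersect(out$removed$dropped,
                            c("v1", "v7", "v2", "v8")))
  expect_equal(nrow(out$removed), 2L)
  # idempotence: pruning its own output removes nothing
  again <- correlation_prune(out$matrix, r_max = 0.80)
  expect_equal(nrow(again$removed), 0L)
  expect_equal(again$matrix, out$matrix)

  dup <- cbind(a = base[, 1], b = base[, 1])
  out_dup <- correlation_prune(dup)
  expect_equal(ncol(out_dup$matrix), 1L)
  uncor <- matrix(rnorm(3000), 1000, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(ncol(correlation_prune(uncor)$matrix), 3L)
})

test_that("missingness count matches a cell-by-cell oracle", {
  set.seed(9)
  X <- matrix(rnorm(200), 20, 10)
  expect_equal(missingness_count(X), rep(0L, 20))
  mask <- matrix(runif(200) < 0.3, 20, 10)
  X[mask] <- NA
  expect_equal(missingness_count(X), as.integer(rowSums(mask)))
  # invariant to column order
  perm <- sample(10)
  expect_equal(missingness_count(X[, perm]), missingness_count(X))
  X_all <- X; X_all[1, ] <- NA
  expect_equal(missingness_count(X_all)[1], 10L)
})

test_that("FCS imputation preserves observed cells and is deterministic", {
  set.seed(11)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_identical(impute_fcs(X, seed = 1L), X)
  mask <- matrix(runif(300) < 0.15, 100, 3)
  Xm <- X; Xm[mask] <- NA
  done1 <- impute_fcs(Xm, n_cycles = 5L, seed = 1L)
  done2 <- impute_fcs(Xm, n_cycles = 5L, seed = 1L)
  expect_identical(done1, done2)
  expect_identical(done1[!mask], X[!mask])
  expect_false(anyNA(done1))
  Xbad <- Xm; Xbad[, "b"] <- NA
  expect_error(impute_fcs(Xbad, seed = 1L), "fully missing: b")
})

test_that("FCS beats column-mean imputation on correlated data", {
  # bivariate normal rho = 0.9, 10% MCAR on one margin
  wins <- 0L
  for (rep in seq_len(20)) {
    set.seed(100 + rep)
    n <- 300
    x <- rnorm(n)
    y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(n)
    miss <- runif(n) < 0.10
    Xm <- cbind(x = x, y = ifelse(miss, NA, y))
    imp <- impute_fcs(Xm, n_cycles = 5L, seed = 200 + rep)
    rmse_fcs <- sqrt(mean((imp[miss, "y"] - y[miss])^2))
    rmse_mean <- sqrt(mean((mean(y[!miss]) - y[miss])^2))
    if (rmse_fcs < rmse_mean) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("FCS imputes binary variables with Bernoulli draws", {
  set.seed(21)
  n <- 400
  z <- rnorm(n)
  b <- rbinom(n, 1, plogis(2 * z))
  miss <- runif(n) < 0.2
  Xm <- cbind(z = z, b = ifelse(miss, NA, b))
  imp <- impute_fcs(Xm, n_cycles = 5L, seed = 3L)
  expect_true(all(imp[, "b"] %in% c(0, 1)))
  # imputed values should track the conditional probability
  expect_gt(mean(imp[miss & z > 1, "b"]), mean(imp[miss & z < -1, "b"]))
})

test_that("standardization is exact and fit-once/apply-many", {
  tr <- standardize_features(cbind(x = c(0, 2, 4)))
  expect_equal(as.numeric(tr$matrix), c(-1, 0, 1))  # sample SD = 2
  set.seed(5)
  X <- matrix(rnorm(600, 5, 3), 100, 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  tr2 <- standardize_features(X)
  expect_true(all(abs(colMeans(tr2$matrix)) < 1e-8))
  expect_true(all(abs(apply(tr2$matrix, 2, sd) - 1) < 1e-8))
  # applying the stored transform to new data uses the stored parameters
  Xnew <- matrix(rnorm(60, 5, 3), 10, 6,
                 dimnames = list(NULL, paste0("v", 1:6)))
  Znew <- apply_standardization(tr2, Xnew)
  expect_equal(Znew, scale(Xnew, tr2$center, tr2$scale)[, ],
               ignore_attr = TRUE)
  # re-standardizing already-standardized data is not the identity transform
  tr3 <- standardize_features(tr2$matrix)
  expect_false(isTRUE(all.equal(tr3$center, tr2$center)))
  expect_error(standardize_features(cbind(x = rep(2, 5))), "zero-variance")
})

test_that("the full feature pipeline runs in order and records provenance", {
  st <- make_test_structure(k = 2L, size = 100L, background_fraction = 0.2)
  co <- generate_cohort(st, 250L)
  fills <- generate_fill_histories(co, classes = "statin",
                                   adherence_targets = c(grp1 = 0.9,
                                                         grp2 = 0.4,
                                                         background = 0.7),
                                   seed = 8L)
  co <- inject_missingness(co, c(labs = 0.2), seed = 9L)
  series <- generate_repeated_measures(co, seed = 10L)
  fm <- build_feature_matrix(co, series = series, fills = fills,
                             n_cycles = 3L, seed = 11L)
  expect_s3_class(fm, "feature_matrix")
  expect_false(anyNA(fm$matrix))
  expect_true(all(abs(colMeans(fm$matrix)) < 1e-8))
  steps <- vapply(fm$provenance, `[[`, "", "step")
  expect_equal(steps, c("aggregate_medians", "compute_pdc",
                        "low_variance_filter", "correlation_prune",
                        "missingness_count", "impute_fcs", "standardize"))
  expect_true("n_missing" %in% colnames(fm$matrix))
  expect_equal(fm$report$n_original - length(fm$report$removed_low_variance) -
                 nrow(fm$report$removed_correlated) + 1L,
               fm$report$n_retained)  # +1 for the missingness-count feature
  # adherence columns reflect the fill histories, not the raw cohort
  # draws (with one class, per-class PDC duplicates the weighted column
  # and one of the pair is pruned; assert on whichever survived)
  pdc_col <- grep("^pdc", colnames(fm$matrix), value = TRUE)[1]
  expect_lt(mean(fm$matrix[co$true_label == "grp2", pdc_col]),
            mean(fm$matrix[co$true_label == "grp1", pdc_col]))
})
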