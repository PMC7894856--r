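test_that("degenerate structure puts every patient in the single subgroup", {
  st <- make_test_structure(k = 1L, size = 120L)
  co <- generate_cohort(st, n_total = 120L)
  expect_equal(unique(co$true_label), "grp1")
  expect_equal(anyDuplicated(co$patient_id), 0L)
})

test_that("generation is deterministic and label counts match the plan", {
  st <- make_test_structure(k = 3L, size = 100L, background_fraction = 0.25)
  co1 <- generate_cohort(st, n_total = 400L)
  co2 <- generate_cohort(st, n_total = 400L)
  expect_identical(as.data.frame(co1), as.data.frame(co2))
  counts <- table(co1$true_label)
  expect_equal(unname(counts[paste0("grp", 1:3)]), rep(100L, 3),
               ignore_attr = TRUE)
  expect_equal(unname(counts[["background"]]), 100L)
  expect_true(all(co1$risk_percentile >= 75L))
  expect_true(all(co1$inpatient_days_2y >= 0 & co1$ed_visits_2y >= 0))
})

test_that("continuous signature effects are realized at the stated size", {
  # five subgroups of 500, one continuous signature each at d = 3 standard
  # deviations: in-group vs out-group mean difference within 3 SE of d
  st <- make_test_structure(k = 5L, size = 500L, d = 3.0)
  co <- generate_cohort(st, n_total = 2500L)
  dict <- attr(co, "dictionary")
  for (i in seq_len(5L)) {
    s <- st$signatures[i, ]
    sigma <- dict$sigma[dict$name == s$feature]
    grp <- co$true_label == s$subgroup
    diff_z <- (mean(co[[s$feature]][grp]) -
                 mean(co[[s$feature]][!grp])) / sigma
    se <- sqrt(1 / sum(grp) + 1 / sum(!grp))
    expect_lt(abs(diff_z - 3.0), 3 * se)
  }
})

test_that("binary prevalence shifts are realized", {
  dict <- feature_dictionary(seed = 5L)
  p0 <- dict$p[dict$name == "chf"]
  sigs <- data.frame(subgroup = "grp1", feature = "chf",
                     effect = 0.95 - p0, stringsAsFactors = FALSE)
  om <- data.frame(subgroup = c("grp1", "background"), p_mortality = 0.1,
                   mean_ip_days = 2, mean_ed_visits = 1)
  st <- planted_structure(c(grp1 = 600L), sigs, 0, om, dict, seed = 9L)
  co <- generate_cohort(st, n_total = 600L)
  phat <- mean(co$chf)
  expect_lt(abs(phat - 0.95), 3 * sqrt(0.95 * 0.05 / 600))
})

test_that("outcomes follow the per-subgroup outcome model", {
  st <- make_test_structure(k = 2L, size = 500L,
                            p_mortality = c(0.05, 0.40))
  co <- generate_cohort(st, n_total = 1000L)
  for (i in 1:2) {
    p <- st$outcome_model$p_mortality[i]
    grp <- co$true_label == paste0("grp", i)
    expect_lt(abs(mean(co$died_2y[grp]) - p),
              3 * sqrt(p * (1 - p) / sum(grp)))
  }
})

test_that("configuration errors are rejected", {
  dict <- feature_dictionary(seed = 2L)
  om <- data.frame(subgroup = c("g", "background"), p_mortality = 0.1,
                   mean_ip_days = 1, mean_ed_visits = 1)
  expect_error(planted_structure(
    c(g = 10L), data.frame(subgroup = "g", feature = "not_a_feature",
                           effect = 1), 0, om, dict),
    "absent from dictionary")
  st <- make_test_structure(k = 2L, size = 100L)
  expect_error(generate_cohort(st, n_total = 150L), "smaller than")
})

test_that("MCAR masking hits cells at the configured rate", {
  st <- make_test_structure(k = 2L, size = 200L)
  co <- generate_cohort(st, 400L)
  co0 <- inject_missingness(co, c(labs = 0), seed = 3L)
  expect_identical(as.data.frame(co0)[, cohort_feature_names(co0)],
                   attr(co0, "truth"))
  dict <- attr(co, "dictionary")
  lab_vars <- dict$name[dict$domain == "labs"]
  co1 <- inject_missingness(co, c(labs = 1), seed = 3L)
  expect_true(all(is.na(as.matrix(as.data.frame(co1)[, lab_vars]))))
  co2 <- inject_missingness(co, c(labs = 0.2), seed = 3L)
  n_cells <- 400L * length(lab_vars)
  frac <- sum(is.na(as.data.frame(co2)[, lab_vars])) / n_cells
  band <- qbinom(c(0.005, 0.995), n_cells, 0.2) / n_cells
  expect_gte(frac, band[1])
  expect_lte(frac, band[2])
  expect_error(inject_missingness(co, c(labs = 1.4)), "rates")
})

test_that("MAR masking probability is monotone in the conditioning variable", {
  st <- make_test_structure(k = 1L, size = 2000L)
  co <- generate_cohort(st, 2000L)
  co_m <- inject_missingness(co, c(labs = 0.3),
                             mechanism = "MAR_on_utilization", seed = 4L,
                             mar_var = "outpatient_visits",
                             mar_strength = -1.5)
  n_miss <- rowSums(is.na(as.data.frame(co_m)[,
    attr(co, "dictionary")$name[attr(co, "dictionary")$domain == "labs"]]))
  # more visits -> fewer gaps under the negative slope
  expect_lt(cor(co$outpatient_visits, n_miss, method = "spearman"), -0.2)
})

test_that("fill histories realize adherence targets", {
  st <- make_test_structure(k = 1L, size = 200L)
  co <- generate_cohort(st, 200L)
  w <- c(0L, 359L)
  targets <- c(grp1 = 1.0)
  fills <- generate_fill_histories(co, classes = "statin",
                                   adherence_targets = targets,
                                   window = w, seed = 5L)
  pdcs <- vapply(split(fills, fills$patient_id), function(ch)
    pdc_oracle(ch$start_day, ch$days_supplied, w), numeric(1))
  expect_true(all(pdcs == 1.0))
  expect_equal(length(pdcs), 200L)

  fills0 <- generate_fill_histories(co, classes = "statin",
                                    adherence_targets = c(grp1 = 0),
                                    window = w, seed = 5L)
  expect_equal(nrow(fills0), 0L)

  fills5 <- generate_fill_histories(co, classes = "statin",
                                    adherence_targets = c(grp1 = 0.5),
                                    window = w, seed = 5L)
  pdc5 <- vapply(split(fills5, fills5$patient_id), function(ch)
    pdc_oracle(ch$start_day, ch$days_supplied, w), numeric(1))
  m <- mean(pdc5)
  expect_gte(m, 0.45)
  expect_lte(m, 0.55)
  # overlapping fills must occur so the union logic is exercised
  overlaps <- vapply(split(fills5, fills5$patient_id), function(ch) {
    o <- order(ch$start_day)
    any(ch$start_day[o][-1] <
          (ch$start_day[o] + ch$days_supplied[o])[-nrow(ch)])
  }, logical(1))
  expect_true(any(overlaps))
  expect_error(generate_fill_histories(co, classes = character(0)),
               "empty")
})

test_that("repeated measures reproduce cohort values through medians", {
  st <- make_test_structure(k = 1L, size = 150L)
  co <- generate_cohort(st, 150L)
  series <- generate_repeated_measures(co, variables = c("a1c", "sodium"),
                                       noise_frac = 0.05, seed = 6L)
  med <- aggregate_medians(series)
  idx <- match(med$patient_id, co$patient_id)
  expect_gt(cor(med$a1c, co$a1c[idx]), 0.98)
  expect_true(all(series$day >= 0 & series$day <= 364))
})

test_that("cohort round-trips through its on-disk representation", {
  st <- make_test_structure(k = 2L, size = 50L)
  co <- generate_cohort(st, 100L)
  fills <- generate_fill_histories(co, classes = "statin",
                                   adherence_targets = c(grp1 = 0.8,
                                                         grp2 = 0.8),
                                   seed = 7L)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir, fills = fills)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[["cohort"]])
  expect_equal(nrow(back), 100L)
  expect_equal(back$true_label, co$true_label)
})
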