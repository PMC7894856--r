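# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementations they check.

# Day-by-day set-union PDC oracle: walk every day in the window and mark
# coverage from each fill explicitly.
pdc_oracle <- function(start_day, days_supplied, window) {
  days <- window[1]:window[2]
  covered <- rep(FALSE, length(days))
  for (k in seq_along(start_day)) {
    fill_days <- start_day[k]:(start_day[k] + days_supplied[k] - 1L)
    covered[days %in% fill_days] <- TRUE
  }
  mean(covered)
}

# Textbook DBSCAN by breadth-first expansion from core points; neighbor
# counts include the point itself.
dbscan_oracle <- function(points, eps, min_pts) {
  D <- as.matrix(stats::dist(points))
  n <- nrow(D)
  neighbors <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(neighbors, length, integer(1)) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      if (!core[p]) next
      for (q in neighbors[[p]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          queue <- c(queue, q)
        }
      }
    }
  }
  list(labels = labels, core = core)
}

# Blob generator for clustering tests: K Gaussian blobs plus optional
# uniform far-field points.
make_blobs <- function(n_per, centers, sd = 0.5, n_noise = 0L,
                       noise_range = 10) {
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
    cbind(stats::rnorm(n_per, centers[k, 1], sd),
          stats::rnorm(n_per, centers[k, 2], sd))))
  labels <- rep(seq_len(nrow(centers)), each = n_per)
  if (n_noise > 0L) {
    pts <- rbind(pts, cbind(stats::runif(n_noise, -noise_range, noise_range),
                            stats::runif(n_noise, -noise_range, noise_range)))
    labels <- c(labels, rep(0L, n_noise))
  }
  list(points = pts, labels = labels)
}

# A small planted structure over the standard dictionary: `k` subgroups,
# each marked by one continuous signature feature shifted by `d`.
make_test_structure <- function(k = 3L, size = 150L, d = 3.0,
                                background_fraction = 0, seed = 11L,
                                p_mortality = rep(0.2, k)) {
  dict <- feature_dictionary(n_features = NULL, seed = seed)
  conts <- c("a1c", "glucose", "sodium", "ldl", "tsh", "bilirubin", "alt")
  stopifnot(k <= length(conts))
  signatures <- do.call(rbind, lapply(seq_len(k), function(i)
    data.frame(subgroup = paste0("grp", i), feature = conts[i], effect = d,
               stringsAsFactors = FALSE)))
  sizes <- stats::setNames(rep(size, k), paste0("grp", seq_len(k)))
  outcome_model <- data.frame(
    subgroup = c(names(sizes), "background"),
    p_mortality = c(p_mortality, 0.1),
    mean_ip_days = rep(2, k + 1L),
    mean_ed_visits = rep(1, k + 1L), stringsAsFactors = FALSE)
  planted_structure(sizes, signatures, background_fraction, outcome_model,
                    dict, seed = seed)
}
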